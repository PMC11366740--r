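## Internal neural-network machinery: hand-written forward/backward
## passes for the transformer encoder-decoder (and the LSTM/CNN ablation
## backbones) plus the Adam optimizer. Everything operates on plain
## L x d_model matrices; gradient correctness is verified against finite
## differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

## linear ---------------------------------------------------------------
.linF <- function(X, W, b) sweep(X %*% W, 2L, b, "+")
.linB <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

## row-wise layer norm with gain/bias ------------------------------------
.lnF <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(Y = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"),
       xhat = xhat, inv = inv)
}
.lnB <- function(cache, g, dY) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, "*")
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

## softmax over rows -----------------------------------------------------
.softmaxRows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}
.softmaxRowsB <- function(P, dP) P * (dP - rowSums(dP * P))

## multi-head attention --------------------------------------------------
## Xq: Lq x d queries source, Xkv: Lk x d keys/values source.
.mhaF <- function(Xq, Xkv, p, nHeads) {
  d <- ncol(Xq)
  dh <- d %/% nHeads
  Q <- .linF(Xq, p$Wq, p$bq)
  K <- .linF(Xkv, p$Wk, p$bk)
  V <- .linF(Xkv, p$Wv, p$bv)
  heads <- vector("list", nHeads)
  O <- matrix(0, nrow(Xq), d)
  for (j in seq_len(nHeads)) {
    cols <- ((j - 1L) * dh + 1L):(j * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
      sqrt(dh)
    P <- .softmaxRows(S)
    O[, cols] <- P %*% V[, cols, drop = FALSE]
    heads[[j]] <- list(P = P, cols = cols)
  }
  Y <- .linF(O, p$Wo, p$bo)
  list(Y = Y, Q = Q, K = K, V = V, O = O, heads = heads,
       Xq = Xq, Xkv = Xkv)
}
.mhaB <- function(cache, p, nHeads, dY) {
  d <- ncol(cache$Q)
  dh <- d %/% nHeads
  lo <- .linB(cache$O, p$Wo, dY)
  dO <- lo$dX
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (j in seq_len(nHeads)) {
    h <- cache$heads[[j]]
    cols <- h$cols
    Vj <- cache$V[, cols, drop = FALSE]
    dOj <- dO[, cols, drop = FALSE]
    dP <- tcrossprod(dOj, Vj)
    dV[, cols] <- crossprod(h$P, dOj)
    dS <- .softmaxRowsB(h$P, dP) / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  lq <- .linB(cache$Xq, p$Wq, dQ)
  lk <- .linB(cache$Xkv, p$Wk, dK)
  lv <- .linB(cache$Xkv, p$Wv, dV)
  list(dXq = lq$dX, dXkv = lk$dX + lv$dX,
       grads = list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                    Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db))
}

## position-wise feed-forward --------------------------------------------
.ffnF <- function(X, p) {
  Z <- .linF(X, p$W1, p$b1)
  A <- .gelu(Z)
  list(Y = .linF(A, p$W2, p$b2), Z = Z, A = A, X = X)
}
.ffnB <- function(cache, p, dY) {
  l2 <- .linB(cache$A, p$W2, dY)
  dZ <- l2$dX * .geluGrad(cache$Z)
  l1 <- .linB(cache$X, p$W1, dZ)
  list(dX = l1$dX,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

## dropout (inverted; only used during training when rate > 0) -----------
.dropF <- function(X, rate) {
  if (rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - rate) / (1 - rate),
                 nrow(X))
  list(Y = X * mask, mask = mask)
}
.dropB <- function(cache, dY) if (is.null(cache$mask)) dY else dY * cache$mask

## transformer encoder layer: pre-LN blocks (LN before each sublayer,
## residual after; a final LN closes each stack) — trains stably at
## small step counts without warmup sensitivity
.encLayerF <- function(X, p, cfg, training = FALSE) {
  ln1 <- .lnF(X, p$ln1$g, p$ln1$b)
  att <- .mhaF(ln1$Y, ln1$Y, p$attn, cfg$nHeads)
  da <- .dropF(att$Y, if (training) cfg$dropout else 0)
  X1 <- X + da$Y
  ln2 <- .lnF(X1, p$ln2$g, p$ln2$b)
  ff <- .ffnF(ln2$Y, p$ffn)
  df <- .dropF(ff$Y, if (training) cfg$dropout else 0)
  list(Y = X1 + df$Y, att = att, da = da, ln1 = ln1, ff = ff, df = df,
       ln2 = ln2)
}
.encLayerB <- function(cache, p, cfg, dY) {
  dff <- .dropB(cache$df, dY)
  fb <- .ffnB(cache$ff, p$ffn, dff)
  b2 <- .lnB(cache$ln2, p$ln2$g, fb$dX)
  dX1 <- dY + b2$dX
  datt <- .dropB(cache$da, dX1)
  ab <- .mhaB(cache$att, p$attn, cfg$nHeads, datt)
  b1 <- .lnB(cache$ln1, p$ln1$g, ab$dXq + ab$dXkv)
  dX <- dX1 + b1$dX
  list(dX = dX,
       grads = list(attn = ab$grads,
                    ln1 = list(g = b1$dg, b = b1$db),
                    ffn = fb$grads,
                    ln2 = list(g = b2$dg, b = b2$db)))
}

## transformer decoder layer (pre-LN) ------------------------------------
.decLayerF <- function(Y, H, p, cfg, training = FALSE) {
  ln1 <- .lnF(Y, p$ln1$g, p$ln1$b)
  self <- .mhaF(ln1$Y, ln1$Y, p$self, cfg$nHeads)
  ds <- .dropF(self$Y, if (training) cfg$dropout else 0)
  Y1 <- Y + ds$Y
  ln2 <- .lnF(Y1, p$ln2$g, p$ln2$b)
  cross <- .mhaF(ln2$Y, H, p$cross, cfg$nHeads)
  dc <- .dropF(cross$Y, if (training) cfg$dropout else 0)
  Y2 <- Y1 + dc$Y
  ln3 <- .lnF(Y2, p$ln3$g, p$ln3$b)
  ff <- .ffnF(ln3$Y, p$ffn)
  df <- .dropF(ff$Y, if (training) cfg$dropout else 0)
  list(Y = Y2 + df$Y, self = self, ds = ds, ln1 = ln1, cross = cross,
       dc = dc, ln2 = ln2, ff = ff, df = df, ln3 = ln3)
}
.decLayerB <- function(cache, p, cfg, dY) {
  dff <- .dropB(cache$df, dY)
  fb <- .ffnB(cache$ff, p$ffn, dff)
  b3 <- .lnB(cache$ln3, p$ln3$g, fb$dX)
  dY2 <- dY + b3$dX
  dcr <- .dropB(cache$dc, dY2)
  cb <- .mhaB(cache$cross, p$cross, cfg$nHeads, dcr)
  b2 <- .lnB(cache$ln2, p$ln2$g, cb$dXq)
  dY1 <- dY2 + b2$dX
  dse <- .dropB(cache$ds, dY1)
  sb <- .mhaB(cache$self, p$self, cfg$nHeads, dse)
  b1 <- .lnB(cache$ln1, p$ln1$g, sb$dXq + sb$dXkv)
  dYin <- dY1 + b1$dX
  list(dY = dYin, dH = cb$dXkv,
       grads = list(self = sb$grads,
                    ln1 = list(g = b1$dg, b = b1$db),
                    cross = cb$grads,
                    ln2 = list(g = b2$dg, b = b2$db),
                    ffn = fb$grads,
                    ln3 = list(g = b3$dg, b = b3$db)))
}

## single-layer LSTM over a sequence of input rows -----------------------
## X: L x d inputs, hidden size d. Gate order: i, f, o, g.
.lstmF <- function(X, p) {
  L <- nrow(X); d <- ncol(X)
  H <- matrix(0, L, d); C <- matrix(0, L, d)
  gates <- vector("list", L)
  hPrev <- numeric(d); cPrev <- numeric(d)
  for (t in seq_len(L)) {
    z <- as.numeric(X[t, ] %*% p$Wx + hPrev %*% p$Wh) + p$b
    i <- .sigmoid(z[1:d]); f <- .sigmoid(z[d + 1:d])
    o <- .sigmoid(z[2 * d + 1:d]); g <- tanh(z[3 * d + 1:d])
    cNew <- f * cPrev + i * g
    hNew <- o * tanh(cNew)
    gates[[t]] <- list(i = i, f = f, o = o, g = g, cPrev = cPrev,
                       hPrev = hPrev, c = cNew)
    H[t, ] <- hNew; C[t, ] <- cNew
    hPrev <- hNew; cPrev <- cNew
  }
  list(H = H, gates = gates, X = X)
}
.lstmB <- function(cache, p, dH) {
  X <- cache$X
  L <- nrow(X); d <- ncol(X)
  dWx <- matrix(0, d, 4 * d); dWh <- matrix(0, d, 4 * d)
  db <- numeric(4 * d)
  dX <- matrix(0, L, d)
  dhNext <- numeric(d); dcNext <- numeric(d)
  for (t in rev(seq_len(L))) {
    gt <- cache$gates[[t]]
    dh <- dH[t, ] + dhNext
    tc <- tanh(gt$c)
    do_ <- dh * tc
    dc <- dh * gt$o * (1 - tc^2) + dcNext
    di <- dc * gt$g
    dg <- dc * gt$i
    df <- dc * gt$cPrev
    dcNext <- dc * gt$f
    dz <- c(di * gt$i * (1 - gt$i), df * gt$f * (1 - gt$f),
            do_ * gt$o * (1 - gt$o), dg * (1 - gt$g^2))
    dWx <- dWx + outer(X[t, ], dz)
    dWh <- dWh + outer(gt$hPrev, dz)
    db <- db + dz
    dX[t, ] <- as.numeric(p$Wx %*% dz)
    dhNext <- as.numeric(p$Wh %*% dz)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## kernel-3 same-length sequence convolution (zero padding) --------------
## Y[t,] = X[t-1,] Wm1 + X[t,] W0 + X[t+1,] Wp1
.shiftRows <- function(X, by) {
  L <- nrow(X)
  Y <- matrix(0, L, ncol(X))
  if (by == 0L) return(X)
  if (by > 0L && by < L) Y[(by + 1L):L, ] <- X[1:(L - by), , drop = FALSE]
  if (by < 0L && -by < L) Y[1:(L + by), ] <- X[(1L - by):L, , drop = FALSE]
  Y
}
.convSeqF <- function(X, p) {
  Y <- .shiftRows(X, 1L) %*% p$Wm1 + X %*% p$W0 +
    .shiftRows(X, -1L) %*% p$Wp1
  list(Y = sweep(Y, 2L, p$b, "+"), X = X)
}
.convSeqB <- function(cache, p, dY) {
  X <- cache$X
  dX <- .shiftRows(dY %*% t(p$Wm1), -1L) + dY %*% t(p$W0) +
    .shiftRows(dY %*% t(p$Wp1), 1L)
  list(dX = dX,
       grads = list(Wm1 = crossprod(.shiftRows(X, 1L), dY),
                    W0 = crossprod(X, dY),
                    Wp1 = crossprod(.shiftRows(X, -1L), dY),
                    b = colSums(dY)))
}

## CNN residual block: Y = LN(X + gelu(conv(X))) -------------------------
.cnnBlockF <- function(X, p) {
  cv <- .convSeqF(X, p$conv)
  A <- .gelu(cv$Y)
  ln <- .lnF(X + A, p$ln$g, p$ln$b)
  list(Y = ln$Y, cv = cv, ln = ln)
}
.cnnBlockB <- function(cache, p, dY) {
  lb <- .lnB(cache$ln, p$ln$g, dY)
  dA <- lb$dX * .geluGrad(cache$cv$Y)
  cb <- .convSeqB(cache$cv, p$conv, dA)
  list(dX = lb$dX + cb$dX,
       grads = list(conv = cb$grads, ln = list(g = lb$dg, b = lb$db)))
}

## parameter initialization ----------------------------------------------
.xavier <- function(dIn, dOut, seed) {
  matrix(.rnorm1(dIn * dOut, seed, sd = sqrt(2 / (dIn + dOut))), dIn, dOut)
}
## Query/key projections start near the identity (plus a small random
## component): token vectors carry additive positional encodings, so
## identity Q/K gives attention a position-aligned prior at step 0,
## which shortens the slow emergence of cross-modal alignment at the
## small step counts used here. Values/outputs use Xavier init.
.attnInit <- function(d, seed) {
  list(Wq = diag(d) + 0.1 * .xavier(d, d, deriveSeed(seed, "q")),
       bq = numeric(d),
       Wk = diag(d) + 0.1 * .xavier(d, d, deriveSeed(seed, "k")),
       bk = numeric(d),
       Wv = .xavier(d, d, deriveSeed(seed, "v")), bv = numeric(d),
       Wo = .xavier(d, d, deriveSeed(seed, "o")), bo = numeric(d))
}
.lnInit <- function(d) list(g = rep(1, d), b = numeric(d))
.ffnInit <- function(d, dFf, seed) {
  list(W1 = .xavier(d, dFf, deriveSeed(seed, "f1")), b1 = numeric(dFf),
       W2 = .xavier(dFf, d, deriveSeed(seed, "f2")), b2 = numeric(d))
}

.initParams <- function(cfg, vocabEEG, vocabAudio) {
  d <- cfg$dModel
  seed <- cfg$seed
  ## unit-scale ID embeddings: tokens also carry O(1) content features
  ## and positional encodings, so the discrete-ID signal must enter at a
  ## comparable magnitude to be visible to the loss from the start
  p <- list(
    embE = matrix(.rnorm1(vocabEEG * d, deriveSeed(seed, "embE"), 1),
                  vocabEEG, d),
    embA = matrix(.rnorm1(vocabAudio * d, deriveSeed(seed, "embA"), 1),
                  vocabAudio, d),
    maskEmb = .rnorm1(d, deriveSeed(seed, "mask"), 1),
    head = list(W = .xavier(d, vocabAudio, deriveSeed(seed, "head")),
                b = numeric(vocabAudio)))
  if (cfg$backbone == "transformer") {
    p$encLn <- .lnInit(d)
    p$decLn <- .lnInit(d)
    ## aligned conditioning: EEG and audio tokens live on the same
    ## analysis-window grid, so the decoder input at position t also
    ## receives a learned projection of encoder state t
    p$align <- list(W = 0.5 * diag(d) +
                      0.1 * .xavier(d, d, deriveSeed(seed, "align")))
    p$enc <- lapply(seq_len(cfg$dLayers), function(l) {
      s <- deriveSeed(seed, paste0("enc", l))
      list(attn = .attnInit(d, s), ln1 = .lnInit(d),
           ffn = .ffnInit(d, cfg$dFf, s), ln2 = .lnInit(d))
    })
    p$dec <- lapply(seq_len(cfg$dLayers), function(l) {
      s <- deriveSeed(seed, paste0("dec", l))
      list(self = .attnInit(d, deriveSeed(s, "s")), ln1 = .lnInit(d),
           cross = .attnInit(d, deriveSeed(s, "c")), ln2 = .lnInit(d),
           ffn = .ffnInit(d, cfg$dFf, s), ln3 = .lnInit(d))
    })
  } else if (cfg$backbone == "lstm") {
    mk <- function(tag) {
      list(Wx = .xavier(d, 4 * d, deriveSeed(seed, paste0(tag, "x"))),
           Wh = .xavier(d, 4 * d, deriveSeed(seed, paste0(tag, "h"))),
           b = numeric(4 * d))
    }
    p$enc <- mk("lstmE")
    p$dec <- mk("lstmD")
    p$ctx <- list(W = .xavier(d, d, deriveSeed(seed, "ctx")),
                  b = numeric(d))
  } else if (cfg$backbone == "cnn") {
    mkBlock <- function(tag) {
      list(conv = list(Wm1 = .xavier(d, d, deriveSeed(seed, paste0(tag, "m"))),
                       W0 = .xavier(d, d, deriveSeed(seed, paste0(tag, "0"))),
                       Wp1 = .xavier(d, d, deriveSeed(seed, paste0(tag, "p"))),
                       b = numeric(d)),
           ln = .lnInit(d))
    }
    p$enc <- lapply(seq_len(cfg$dLayers), function(l) mkBlock(paste0("ce", l)))
    p$dec <- lapply(seq_len(cfg$dLayers), function(l) mkBlock(paste0("cd", l)))
    p$ctx <- list(W = .xavier(d, d, deriveSeed(seed, "cctx")),
                  b = numeric(d))
  } else {
    stop("unknown backbone: ", cfg$backbone, call. = FALSE)
  }
  p
}

## full core forward/backward --------------------------------------------
## encX: L_e x d encoder input rows; decY: L_a x d decoder input rows.
## encH: optional precomputed encoder hidden matrix (decoder-only runs;
## no encoder caches are produced, so such runs are forward-only).
.coreForward <- function(params, cfg, encX, decY, training = FALSE,
                         encH = NULL) {
  if (cfg$backbone == "transformer") {
    encCaches <- vector("list", cfg$dLayers)
    encLnCache <- NULL
    if (is.null(encH)) {
      H <- encX
      for (l in seq_len(cfg$dLayers)) {
        encCaches[[l]] <- .encLayerF(H, params$enc[[l]], cfg, training)
        H <- encCaches[[l]]$Y
      }
      encLnCache <- .lnF(H, params$encLn$g, params$encLn$b)
      H <- encLnCache$Y
    } else {
      H <- encH
    }
    alignIdx <- pmin(seq_len(nrow(decY)), nrow(H))
    Yd <- decY + H[alignIdx, , drop = FALSE] %*% params$align$W
    decIn <- Yd
    decCaches <- vector("list", cfg$dLayers)
    for (l in seq_len(cfg$dLayers)) {
      decCaches[[l]] <- .decLayerF(Yd, H, params$dec[[l]], cfg, training)
      Yd <- decCaches[[l]]$Y
    }
    decLnCache <- .lnF(Yd, params$decLn$g, params$decLn$b)
    list(H = H, dec = decLnCache$Y, encCaches = encCaches,
         decCaches = decCaches, encLnCache = encLnCache,
         decLnCache = decLnCache, alignIdx = alignIdx, decIn = decIn)
  } else if (cfg$backbone == "lstm") {
    enc <- if (is.null(encH)) .lstmF(encX, params$enc) else list(H = encH)
    ctx <- colMeans(enc$H)
    ctxProj <- as.numeric(ctx %*% params$ctx$W) + params$ctx$b
    U <- sweep(decY, 2L, ctxProj, "+")
    dec <- .lstmF(U, params$dec)
    list(H = enc$H, dec = dec$H, enc = enc, decC = dec, ctx = ctx,
         U = U)
  } else {                                  # cnn
    encCaches <- vector("list", cfg$dLayers)
    if (is.null(encH)) {
      H <- encX
      for (l in seq_len(cfg$dLayers)) {
        encCaches[[l]] <- .cnnBlockF(H, params$enc[[l]])
        H <- encCaches[[l]]$Y
      }
    } else {
      H <- encH
    }
    ctx <- colMeans(H)
    ctxProj <- as.numeric(ctx %*% params$ctx$W) + params$ctx$b
    U <- sweep(decY, 2L, ctxProj, "+")
    decCaches <- vector("list", cfg$dLayers)
    Yd <- U
    for (l in seq_len(cfg$dLayers)) {
      decCaches[[l]] <- .cnnBlockF(Yd, params$dec[[l]])
      Yd <- decCaches[[l]]$Y
    }
    list(H = H, dec = Yd, encCaches = encCaches, decCaches = decCaches,
         ctx = ctx, U = U)
  }
}

.coreBackward <- function(params, cfg, cache, dDec) {
  if (cfg$backbone == "transformer") {
    grads <- list(enc = vector("list", cfg$dLayers),
                  dec = vector("list", cfg$dLayers))
    dln <- .lnB(cache$decLnCache, params$decLn$g, dDec)
    grads$decLn <- list(g = dln$dg, b = dln$db)
    dH <- matrix(0, nrow(cache$H), ncol(cache$H))
    dY <- dln$dX
    for (l in rev(seq_len(cfg$dLayers))) {
      b <- .decLayerB(cache$decCaches[[l]], params$dec[[l]], cfg, dY)
      grads$dec[[l]] <- b$grads
      dY <- b$dY
      dH <- dH + b$dH
    }
    ## aligned-conditioning path: dY is the gradient at the decoder
    ## input sum decY + H[alignIdx,] %*% alignW
    Hsel <- cache$H[cache$alignIdx, , drop = FALSE]
    grads$align <- list(W = crossprod(Hsel, dY))
    dHal <- dY %*% t(params$align$W)
    for (i in seq_along(cache$alignIdx)) {
      dH[cache$alignIdx[i], ] <- dH[cache$alignIdx[i], ] + dHal[i, ]
    }
    eln <- .lnB(cache$encLnCache, params$encLn$g, dH)
    grads$encLn <- list(g = eln$dg, b = eln$db)
    dEnc <- eln$dX
    for (l in rev(seq_len(cfg$dLayers))) {
      b <- .encLayerB(cache$encCaches[[l]], params$enc[[l]], cfg, dEnc)
      grads$enc[[l]] <- b$grads
      dEnc <- b$dX
    }
    list(grads = grads, dEncX = dEnc, dDecY = dY)
  } else if (cfg$backbone == "lstm") {
    db <- .lstmB(cache$decC, params$dec, dDec)
    dU <- db$dX
    dCtxProj <- colSums(dU)
    dCtx <- as.numeric(params$ctx$W %*% dCtxProj)
    gCtx <- list(W = outer(cache$ctx, dCtxProj), b = dCtxProj)
    dHenc <- matrix(dCtx / nrow(cache$H), nrow(cache$H), ncol(cache$H),
                    byrow = TRUE)
    eb <- .lstmB(cache$enc, params$enc, dHenc)
    list(grads = list(enc = eb$grads, dec = db$grads, ctx = gCtx),
         dEncX = eb$dX, dDecY = dU)
  } else {                                  # cnn
    grads <- list(enc = vector("list", cfg$dLayers),
                  dec = vector("list", cfg$dLayers))
    dY <- dDec
    for (l in rev(seq_len(cfg$dLayers))) {
      b <- .cnnBlockB(cache$decCaches[[l]], params$dec[[l]], dY)
      grads$dec[[l]] <- b$grads
      dY <- b$dX
    }
    dU <- dY
    dCtxProj <- colSums(dU)
    dCtx <- as.numeric(params$ctx$W %*% dCtxProj)
    grads$ctx <- list(W = outer(cache$ctx, dCtxProj), b = dCtxProj)
    dH <- matrix(dCtx / nrow(cache$H), nrow(cache$H), ncol(cache$H),
                 byrow = TRUE)
    for (l in rev(seq_len(cfg$dLayers))) {
      b <- .cnnBlockB(cache$encCaches[[l]], params$enc[[l]], dH)
      grads$enc[[l]] <- b$grads
      dH <- b$dX
    }
    list(grads = grads, dEncX = dH, dDecY = dU)
  }
}

## Adam over an arbitrarily nested list of numeric arrays -----------------
.treeZeros <- function(p) {
  if (is.list(p)) lapply(p, .treeZeros) else p * 0
}
## index a parallel tree by name when available, else by position
.treeKeys <- function(a) {
  nm <- names(a)
  if (is.null(nm) || any(!nzchar(nm))) seq_along(a) else nm
}
.treeAdd <- function(a, b) {
  if (is.list(a)) {
    for (k in .treeKeys(a)) a[[k]] <- .treeAdd(a[[k]], b[[k]])
    a
  } else {
    a + b
  }
}
.treeScale <- function(a, s) {
  if (is.list(a)) lapply(a, .treeScale, s = s) else a * s
}
.treeNormSq <- function(a) {
  if (is.list(a)) sum(vapply(a, .treeNormSq, numeric(1))) else sum(a^2)
}
## clip the whole gradient tree to a global L2 norm
.treeClip <- function(g, maxNorm) {
  nrm <- sqrt(.treeNormSq(g))
  if (is.finite(nrm) && nrm > maxNorm) .treeScale(g, maxNorm / nrm) else g
}
.adamInit <- function(params) {
  list(m = .treeZeros(params), v = .treeZeros(params), t = 0L)
}
## lrScale: optional named multipliers applied to top-level parameter
## groups (e.g. a faster linear readout head)
.adamStep <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.98, eps = 1e-8, lrScale = NULL) {
  state$t <- state$t + 1L
  tt <- state$t
  step <- function(p, g, m, v, rate) {
    if (is.list(p)) {
      out <- lapply(.treeKeys(p), function(k) step(p[[k]], g[[k]], m[[k]],
                                                   v[[k]], rate))
      names(out) <- names(p)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^tt)
    vh <- v / (1 - beta2^tt)
    list(p = p - rate * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- lapply(.treeKeys(params), function(k) {
    rate <- lr * (if (!is.null(lrScale) && !is.null(lrScale[[k]]))
      lrScale[[k]] else 1)
    step(params[[k]], grads[[k]], state$m[[k]], state$v[[k]], rate)
  })
  names(out) <- names(params)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = tt))
}
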