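#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' RNG state afterwards, so library calls do not disturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## 32-bit modular helpers on doubles (exact: operands kept below 2^53)
.mul32 <- function(h, p) {
  lo <- h %% 65536
  hi <- h %/% 65536
  (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
}

#' FNV-1a hash of a character string
#'
#' 32-bit Fowler-Noll-Vo hash, used for provenance stamping of configs and
#' run outputs. Not cryptographic.
#'
#' @param x character scalar.
#' @return hexadecimal hash string.
#' @keywords internal
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    ## xor with a byte only touches the low 8 bits
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    h <- .mul32(h, 16777619)
  }
  ## h < 2^32 may exceed .Machine$integer.max; format the halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Stable hash of an R object
#'
#' Canonicalizes the object (recursively sorting list names) before
#' hashing, so the hash is invariant to field order.
#'
#' @param x an R object composed of lists/atomic vectors.
#' @return hexadecimal hash string.
#' @export
#' @examples
#' stableHash(list(a = 1, b = "x")) == stableHash(list(b = "x", a = 1))
stableHash <- function(x) {
  canon <- function(o) {
    if (is.list(o)) {
      nm <- names(o)
      if (!is.null(nm) && any(nzchar(nm))) o <- o[order(nm)]
      lapply(o, canon)
    } else {
      o
    }
  }
  txt <- jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = 10,
                          null = "null", force = TRUE)
  fnv1a(as.character(txt))
}

#' Derive a stage seed from a global seed
#'
#' Fans one global seed out to per-stage seeds via string hashing, so each
#' pipeline stage is independently reproducible.
#'
#' @param seed global integer seed.
#' @param label stage label, e.g. "synth" or "mask/epoch3".
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, label) {
  h <- strtoi(substr(fnv1a(paste0(seed, "/", label)), 1, 7), base = 16L)
  as.integer((h %% 2147483645) + 1)
}

## argument guards -----------------------------------------------------------

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

## fixed RNG stream helpers (deterministic weight init independent of order)
.rnorm1 <- function(n, seed, sd = 1) {
  withSeed(seed, stats::rnorm(n, sd = sd))
}
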