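# NeuroMelody

EEG-driven emotive music generation via discrete token mapping.

## What problem this solves

EEG recorded while people listen to music reflects the music's
emotional content, but both EEG and audio are continuous signals with
no shared, fixed vocabulary — which makes learning a mapping between
them ill-posed. NeuroMelody is an R implementation of a
discretize-then-map pipeline for researchers in affective computing and
music information retrieval:

1. **Features.** EEG trials (32 channels, 128 Hz, 3 s baseline + 60 s
   stimulus) are band-pass filtered 4–45 Hz, baseline-corrected and cut
   into 4 s windows; each window yields a differential-entropy vector
   (per channel and band, DE = ½·ln(2πeσ²) on the band-limited
   variance σ²). Audio windows on the same grid yield mean MFCC
   vectors.
2. **Discretization.** DBSCAN (radius ε, neighborhood size MinPts)
   clusters each modality's window features; each cluster's centroid
   and representative members form an entry of a feature dictionary,
   and windows become discrete dictionary IDs (with a reserved
   *unknown* ID for frames far from every centroid).
3. **Mapping.** A transformer encoder–decoder (implemented from
   scratch, gradients verified by finite differences) reads EEG tokens
   and predicts audio tokens under a masked-prediction objective with
   composite loss **FL = (1 − α)·FLm + α·FLu**, where FLm/FLu are the
   negative log-likelihoods over masked/unmasked positions.
4. **Evaluation.** **Hits@k = (1/n) Σᵢ H(rankᵢ ≤ k)** — the fraction of
   evaluated positions whose reference token ranks in the model's top
   k; chance level is k/V for vocabulary size V. Subjects are split
   8:2 so evaluation is always on held-out people.
5. **Synthesis.** Predicted token IDs render back to audio through mel
   envelope inversion and Griffin–Lim phase reconstruction.

A synthetic generator produces coupled EEG/audio corpora driven by a
shared latent emotional-state Markov chain, so the entire pipeline —
including end-to-end training — is testable with no external data or
network access.

## Worked example

Generate a desk-scale coupled corpus (7 subjects × 2 trials of 60 s,
K = 4 latent states), then train and evaluate the full pipeline —
about a minute on one core:

```r
library(NeuroMelody)

cfg <- synthConfig(nSubjects = 7, nTrials = 2, K = 4, noiseSd = 0.1,
                   seed = 11)
corpus <- genDataset(cfg)
corpus[[1]]$eeg
#> EEGRecording: 32 channels x 8064 samples @ 128 Hz (63.0 s, incl. 3 s baseline)
#>   channels: Fp1 AF3 F7 F3 FC1 FC5 T7 C3 ...

report <- runExperiment(corpus, ablationSpec(dLayers = 2), seed = 1,
                        epochs = 10)
cat("audio vocabulary:", report$vocab$audio, "(chance Hits@1 =",
    round(1 / report$vocab$audio, 3), ")\n")
#> audio vocabulary: 9 (chance Hits@1 = 0.111 )
print(setNames(round(report$hitsMasked$hits, 3),
               paste0("k=", report$hitsMasked$k)))
#>   k=1   k=3   k=5  k=10  k=20
#> 0.688 0.912 0.950 1.000 1.000
report$finalLoss
#>    epoch       flm        flu        fl
#> 10    10 0.4262132 0.07994289 0.3915862
```

Reading the output: DBSCAN found 8 audio clusters (the generator's
4 states × 2 chord voicings) plus the unknown token, so V = 9 and
chance Hits@1 is 0.111. On held-out subjects' masked positions the
trained model ranks the correct audio token first 68.8% of the time
and within the top 3 91.2% of the time; `flm`/`flu` are the final
masked/unmasked losses and `fl` their composite.

Other entry points: `preprocessTrial()`, `trialFeatures()`,
`learnDictionary()`/`encodeSequence()`, `buildModel()`/`fitModel()`/
`generateIds()`, `hitsAtK()`, `reconstructAudio()`, and the staged
`runPipeline()` with YAML configuration (`validateConfig()`). A thin
command-line front end ships in `inst/cli/emomusic.R`. The methods
vignette (`vignettes/emotive-music-pipeline.Rmd`) documents the model,
its assumptions and all tunable parameters.

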