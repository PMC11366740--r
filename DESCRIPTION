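Package: NeuroMelody
Title: EEG-Driven Emotive Music Generation via Discrete Token Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for generating emotive music tokens from
    multichannel electroencephalography (EEG). Continuous EEG and audio
    signals are discretized into token dictionaries by DBSCAN clustering
    of differential-entropy and MFCC features, mapped to each other by a
    transformer encoder-decoder trained with a masked-audio composite
    loss, and evaluated by Hits@k ranking of predicted audio tokens.
    Includes a synthetic coupled EEG/audio generator emulating the
    structure of music-video affect corpora, so the full pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'NeuroMelody-package.R'
    'config.R'
    'discretize.R'
    'evaluate.R'
    'features.R'
    'io-formats.R'
    'model.R'
    'nn-core.R'
    'preproc.R'
    'synthdata.R'
    'tokens.R'
    'utils.R'
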