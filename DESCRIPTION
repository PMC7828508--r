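Package: oaad
Title: Online Auditory Attention Decoding from Streaming EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for online auditory attention detection (AAD) in dichotic
    listening: backward (stimulus-reconstruction) linear decoders estimated by
    ridge regression on lagged EEG, built online from overlapping sliding-window
    snippets and averaged across trials, with Pearson-correlation direction
    classification at one-second resolution. Includes speech-envelope extraction
    (analytic-signal power), offline and causal in-situ EEG preprocessing chains,
    a block-streaming session emulator, a synthetic dichotic-listening EEG
    generator driven by a known lagged forward model, causal moving-average
    smoothing of correlation coefficients, exact binomial chance levels, and a
    window/hop/trial-count parameter grid search.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
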