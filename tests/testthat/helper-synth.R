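# One clean full-protocol recording (default ground truth, default timeline,
# no channel noise), rendered once and shared across test files; rendering
# and conditioning the ~13.7-min multichannel recording costs a few seconds,
# so the results are memoized in this environment.
.shared <- new.env(parent = emptyenv())

shared_recording <- function() {
  if (is.null(.shared$rec)) {
    .shared$rec <- synth_recording(ground_truth(), event_timeline(), seed = 42)
  }
  .shared$rec
}

shared_beats <- function() {
  if (is.null(.shared$beats)) {
    rec <- shared_recording()
    ecg <- preprocess_ecg(rec$channels$ecg$samples, rec$channels$ecg$fs)
    .shared$beats <- detect_r_waves(ecg, fs = 400)
  }
  .shared$beats
}

shared_dzdt <- function() {
  if (is.null(.shared$dzdt)) {
    rec <- shared_recording()
    .shared$dzdt <- preprocess_dzdt(rec$channels$dzdt$samples,
                                    rec$channels$dzdt$fs)
  }
  .shared$dzdt
}
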