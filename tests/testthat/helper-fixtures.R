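# Shared fixtures built in code.

# Noiseless generator configuration for exact closed-loop checks.
quiet_config <- function(seed = 1L, ...) {
  generator_config(seed = seed,
                   noise = list(response_sd_mv = 0, spectral_sd = 0,
                                label_sd = 0, label_bg_sd = 0),
                   ...)
}

# Exact Hill responses over the default OD protocol.
exact_intensity_run <- function(vmax = 40, n = 1, k = 0.1) {
  od <- seq(4, 0, by = -0.2)
  intensity_run(od, hill_response(10^(-od), vmax, n, k))
}

# Match detected centers to truth rows within `tol` px; returns a list with
# recall, precision and the matched index vector.
match_detections <- function(det, truth, tol = 2) {
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    d2 <- (det$row - truth$row[i])^2 + (det$col - truth$col[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol^2) j else NA_integer_
  }, integer(1))
  list(recall = mean(!is.na(matched)),
       precision = length(unique(stats::na.omit(matched))) / nrow(det),
       matched = matched)
}
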