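# Example: preprocessing stride-interval records for band analysis.
#
# Works on a user-downloaded extract of the PhysioNet "Gait in
# Neurodegenerative Disease Database" (https://doi.org/10.13026/C27G6C):
# per-subject text files with columns (time of step, left stride interval).
# This script is illustrative preprocessing with standard signal routines
# and is not exercised by the package's test suite.
#
# Pipeline per subject:
#   1. keep 3.5 min of left-foot stride intervals after a 20 s warm-up;
#   2. clip outliers outside the 1st/96th percentiles and impute them with a
#      weighted moving average of their neighbours;
#   3. sample a linear interpolant at fs = 2 Hz;
#   4. remove a linear trend, high-pass filter (Butterworth) to drop
#      ultra-low frequencies, and standardize to unit variance.
#
# The resulting equal-length series (T = 420 at 2 Hz) can be written as a
# wide CSV and analyzed with:
#   fbam(read_series("strides.csv"), j_grid = 1, l_grid = 2:6)   # one population
#   fbam(read_series("strides.csv"), j_grid = 2:6, l_grid = 2:6) # subpopulations

library(signal)

preprocess_strides <- function(step_time, stride, fs = 2,
                               warmup_s = 20, duration_s = 210) {
  keep <- step_time >= warmup_s & step_time < warmup_s + duration_s
  step_time <- step_time[keep]
  stride <- stride[keep]

  # percentile clipping + weighted moving-average imputation
  qs <- quantile(stride, c(0.01, 0.96))
  bad <- which(stride < qs[1] | stride > qs[2])
  w <- c(1, 2, 4, 2, 1)
  for (i in bad) {
    idx <- pmax(1, pmin(length(stride), i + (-2:2)))
    ok <- setdiff(seq_along(idx), which(idx == i))
    stride[i] <- sum(stride[idx[ok]] * w[ok]) / sum(w[ok])
  }

  # uniform 2 Hz sampling of the linear interpolant
  grid <- seq(step_time[1], step_time[1] + duration_s - 1 / fs, by = 1 / fs)
  x <- approx(step_time, stride, xout = grid, rule = 2)$y

  # detrend, high-pass, standardize
  x <- residuals(lm(x ~ seq_along(x)))
  hp <- signal::butter(4, W = 0.02 / (fs / 2), type = "high")
  x <- as.numeric(signal::filtfilt(hp, x))
  x / sd(x)
}

# Typical use, given files like "control1.ts" with columns (time, left, right):
# series <- t(sapply(files, function(f) {
#   d <- read.table(f)
#   preprocess_strides(d[[1]], d[[2]])
# }))
# write.table(series, "strides.csv", sep = ",", row.names = FALSE,
#             col.names = FALSE)
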