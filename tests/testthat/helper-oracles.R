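# Independent brute-force oracles used across test files.

# Somers' D(response | predictor) by explicit pair counting.
somers_pair_oracle <- function(x, y) {
  con <- 0; dis <- 0; untied_x <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      untied_x <- untied_x + 1
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) con <- con + 1
      if (s < 0) dis <- dis + 1
    }
  }
  (con - dis) / untied_x
}
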