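# Brute-force iterative-proportional-fitting oracle: the classical
# alternating row/column rescaling, independent of the package's ipfFit.
ipfOracle <- function(p, Qi, Qj, iters = 50000L, tol = 1e-11) {
  for (k in seq_len(iters)) {
    p <- p * (Qi / rowSums(p))
    p <- t(t(p) * (Qj / colSums(p)))
    if (max(c(abs(rowSums(p) - Qi), abs(colSums(p) - Qj))) <= tol) break
  }
  p
}
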