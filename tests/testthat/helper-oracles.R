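# Independent reference implementations used to check the package's
# statistics.

# Quadratic-time reference for the BH step-up adjustment.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}
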