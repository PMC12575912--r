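# Brute-force oracles kept deliberately independent of the implementation.

# AUC by exhaustive all-pairs counting (ties count 1/2), double loop.
auc_pair_count <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Parameters of the published group medians, in mm2/s.
lvi_pos_ivim <- list(d = 0.72e-3, dstar = 75.06e-3, f = 0.4156)
lvi_neg_ivim <- list(d = 0.96e-3, dstar = 68.19e-3, f = 0.410)
lvi_pos_dki <- list(dapp = 2.29e-3, kapp = 0.84)
lvi_neg_dki <- list(dapp = 2.69e-3, kapp = 0.70)

rel_err <- function(x, ref) abs(x / ref - 1)

# a simple correlated two-marker binary-outcome instance
make_paired_scores <- function(n_pos, n_neg, shift_a, shift_b, seed) {
  withr::with_seed(seed, {
    y <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    z <- rnorm(n_pos + n_neg)
    list(y = y,
         a = z + shift_a * y + rnorm(n_pos + n_neg, 0, 0.6),
         b = z + shift_b * y + rnorm(n_pos + n_neg, 0, 0.6))
  })
}
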