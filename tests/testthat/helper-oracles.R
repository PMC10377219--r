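# Independent oracles, deliberately coded from textbook formulas and kept
# separate from the implementation paths they check.

# Welch two-sample t statistic and p-value from the closed form
# (Welch-Satterthwaite degrees of freedom, Student-t tail).
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, p_value = 2 * pt(-abs(t), df))
}

# Pearson X^2 computed cell-by-cell from expected counts.
pearson_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Monte-Carlo permutation null for the 2x2 independence test: resample
# tables with the observed margins fixed and count statistics at least as
# extreme as the observed one.
perm_chisq_p <- function(tab, nsim = 1e5, seed = 1) {
  obs <- pearson_oracle(tab)
  set.seed(seed)
  sims <- r2dtable(nsim, rowSums(tab), colSums(tab))
  stats <- vapply(sims, pearson_oracle, numeric(1))
  mean(stats >= obs - 1e-9)
}

# internal helpers exercised directly by the tests
flatten_params <- elstm:::flatten_params

# Small separable cohort + config used by the learnability-style checks.
learnability_config <- function(epochs = 60) {
  training_config(epochs = epochs, batch_size = 64, learning_rate = 0.01,
                  dropout_rate = 0, n_hidden = 8)
}
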