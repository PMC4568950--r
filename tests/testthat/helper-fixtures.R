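# Shared fixtures and tiny independent oracles used across test files.

# Quant-record constructor for hand-built fixtures.
qrec <- function(run, protein, peptide, channel, y,
                 subject = run, standard = FALSE, cohort = "training",
                 batch = "B01") {
  data.frame(run_id = run, cohort_id = cohort, subject_id = subject,
             protein_id = protein, peptide_id = peptide, channel = channel,
             is_standard = standard, batch_id = batch, log2_intensity = y,
             stringsAsFactors = FALSE)
}

# A tiny fully worked two-run fixture: protein X with one peptide, light +
# heavy in both runs; heavy medians 10 and 12.
two_run_fixture <- function() {
  rbind(
    qrec("R1", "X", "X_p1", "heavy", 10),
    qrec("R1", "X", "X_p1", "light", 20),
    qrec("R2", "X", "X_p1", "heavy", 12),
    qrec("R2", "X", "X_p1", "light", 21)
  )
}

# Small noisy cohort reused by several module tests (computed once).
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_crc = 30, n_benign = 10, n_healthy = 20,
                      n_proteins = 15, seed = 42)
    .fixture_env$small <- generate_cohort(cfg)
  }
  .fixture_env$small
}

# case flags aligned to an abundance matrix
case_flags <- function(mat, metadata) {
  metadata$group[match(rownames(mat$values), metadata$subject_id)] == "CRC"
}

# ---- independent oracles ----------------------------------------------

# Brute-force Benjamini-Hochberg by its step-up definition: explicit
# min-over-tails, no vectorized shortcut shared with the implementation.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(j) ps[j] * m / j, 0)
    adj[i] <- min(1, min(tail_vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pairwise-enumeration AUC oracle: half credit for ties.
auc_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  cs <- scores[labels]; ct <- scores[!labels]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Log-likelihood of a 1-predictor logistic model (for the grid oracle).
logit_loglik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log(1 + exp(eta)))
}

# Iteratively refined grid search over (b0, b1); independent of IRLS.
logit_grid_oracle <- function(x, y, span = 8, steps = 41, rounds = 4) {
  center <- c(0, 0)
  for (r in seq_len(rounds)) {
    b0s <- seq(center[1] - span, center[1] + span, length.out = steps)
    b1s <- seq(center[2] - span, center[2] + span, length.out = steps)
    ll <- outer(b0s, b1s, Vectorize(function(a, b) logit_loglik(a, b, x, y)))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    center <- c(b0s[best[1]], b1s[best[2]])
    span <- span * 2.5 / steps   # shrink around the optimum
  }
  center
}
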