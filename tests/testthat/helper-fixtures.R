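# Shared fixtures, all generated in code at test time.

# A small labelled feature matrix with `n_signal` informative columns
# (class-shifted by `shift`) followed by pure-noise columns.
toy_feature_matrix <- function(n_case = 20, n_control = 20, n_signal = 2,
                               n_noise = 8, shift = 3, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  labels <- c(rep("case", n_case), rep("control", n_control))
  x <- matrix(rnorm(n * (n_signal + n_noise)), n)
  for (j in seq_len(n_signal))
    x[labels == "case", j] <- x[labels == "case", j] + shift
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  feature_matrix(x, labels = labels)
}

toy_score_set <- function(case, control, provenance = "held_out_test") {
  score_set(sprintf("S%02d", seq_len(length(case) + length(control))),
            c(case, control),
            c(rep("case", length(case)), rep("control", length(control))),
            provenance = provenance)
}

# Brute-force pairwise-concordance AUC (independent of roc_auc's rank
# formula).
auc_by_pairs <- function(case, control) {
  conc <- 0
  for (a in case) for (b in control)
    conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(case) * length(control))
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments (midranks, so ties are handled).
pvalue_by_enumeration <- function(case, control) {
  pooled <- c(case, control)
  n1 <- length(case)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  sums <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Direct periodized convolve-and-downsample single-level 1D transform,
# used as the wavelet oracle.
dwt1_oracle <- function(x) {
  f <- vocdx:::daub4_filters()
  n <- length(x)
  a <- d <- numeric(n / 2)
  for (k in seq_len(n / 2)) {
    idx <- ((2 * (k - 1) + 0:3) %% n) + 1
    a[k] <- sum(f$h * x[idx])
    d[k] <- sum(f$g * x[idx])
  }
  list(a = a, d = d)
}

# Single-level 2D oracle: 1D oracle down each column, then along each row.
dwt2_oracle <- function(m) {
  ac <- sapply(seq_len(ncol(m)), function(j) dwt1_oracle(m[, j])$a)
  dc <- sapply(seq_len(ncol(m)), function(j) dwt1_oracle(m[, j])$d)
  rowt <- function(b) {
    list(a = t(sapply(seq_len(nrow(b)), function(i) dwt1_oracle(b[i, ])$a)),
         d = t(sapply(seq_len(nrow(b)), function(i) dwt1_oracle(b[i, ])$d)))
  }
  l <- rowt(ac); h <- rowt(dc)
  list(LL = l$a, LH = l$d, HL = h$a, HH = h$d)
}
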