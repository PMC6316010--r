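# Supervised feature selection: per-feature Wilcoxon rank-sum ranking with
# top-k retention, and an all-relevant Boruta shadow-feature procedure
# built on the package's random forest.

selection_result <- function(method, feature_names, p_values, decisions,
                             ranking, n_iterations = NA_integer_,
                             importance = NULL) {
  stopifnot(length(decisions) == length(feature_names),
            all(decisions %in% c("selected", "confirmed", "tentative",
                                 "rejected")))
  if (!is.null(p_values))
    stopifnot(length(p_values) == length(feature_names),
              all(p_values >= 0 & p_values <= 1))
  structure(list(method = method, feature_names = feature_names,
                 p_values = p_values, decisions = decisions,
                 ranking = as.integer(ranking),
                 n_iterations = as.integer(n_iterations),
                 importance = importance),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> method=", x$method, ", ",
      length(x$feature_names), " features (",
      paste(names(table(x$decisions)), table(x$decisions),
            sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

resolve_labels <- function(features, labels) {
  if (is.null(labels) && inherits(features, "feature_matrix"))
    labels <- features$labels
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  labels
}

feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
}

# Exact two-sided p-value under ties: enumerate every group assignment of
# the pooled midranks. Only used when choose(n, n1) is small.
exact_tied_pvalue <- function(values, is_case) {
  r <- rank(values)
  n1 <- sum(is_case)
  obs <- sum(r[is_case])
  mu <- n1 * (length(r) + 1) / 2
  sums <- utils::combn(r, n1, sum)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Two-sided Mann-Whitney p-values for many columns at once. When both
# groups have <= 10 samples the exact distribution is used: pwilcox for
# tie-free columns, full enumeration of group assignments for tied ones.
# Larger groups get the normal approximation with midranks, tie-corrected
# variance and continuity correction. A column with zero rank-sum
# variance (all values tied) gets p = 1.
ranksum_pvalues <- function(x, is_case) {
  rs <- col_ranksum(x, is_case)
  n1 <- rs$n_case
  n2 <- rs$n_control
  n <- n1 + n2
  U <- rs$U
  mu <- n1 * n2 / 2
  sig2 <- (n1 * n2 / 12) * ((n + 1) - rs$tie_term / (n * (n - 1)))
  p <- rep(NA_real_, length(U))
  degenerate <- sig2 <= 0
  p[degenerate] <- 1
  small <- n1 <= 10L && n2 <= 10L && choose(n, n1) <= 5e4
  exact_free <- !rs$has_ties & !degenerate & small
  if (any(exact_free)) {
    u <- U[exact_free]
    lower <- 2 * pwilcox(u, n1, n2)
    upper <- 2 * pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p[exact_free] <- pmin(1, ifelse(u > mu, upper, lower))
  }
  exact_tied <- rs$has_ties & !degenerate & small
  for (j in which(exact_tied))
    p[j] <- exact_tied_pvalue(x[, j], is_case)
  approx <- !exact_free & !exact_tied & !degenerate
  if (any(approx)) {
    dev <- U[approx] - mu
    z <- (abs(dev) - 0.5) / sqrt(sig2[approx]) # continuity correction
    p[approx] <- pmin(1, 2 * pnorm(-pmax(z, 0)))
  }
  p
}

#' Wilcoxon rank-sum feature ranking
#'
#' For every feature, the two-sided Wilcoxon rank-sum (Mann-Whitney)
#' p-value comparing case against control values. The exact distribution
#' is used when both groups have at most 10 samples (closed form for
#' tie-free features, full enumeration of group assignments under ties);
#' larger groups use a tie-corrected, continuity-corrected normal
#' approximation. Features are ranked by ascending p-value, ties broken by
#' ascending feature index. P-values are invariant to strictly monotone
#' transforms of a feature.
#'
#' @param features a [feature_matrix()] or plain numeric matrix.
#' @param labels per-sample `"case"`/`"control"` labels (taken from the
#'   feature matrix if omitted); both classes need >= 2 samples.
#' @return A `selection_result` with per-feature p-values and a full
#'   ranking.
#' @export
wilcoxon_rank <- function(features, labels = NULL) {
  labels <- resolve_labels(features, labels)
  x <- feature_values(features)
  is_case <- labels == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("both classes must be present with at least 2 samples each")
  p <- ranksum_pvalues(x, is_case)
  nm <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  selection_result("wilcoxon_topk", nm, p,
                   decisions = rep("selected", ncol(x)),
                   ranking = order(p, seq_along(p)))
}

#' Retain the k features with smallest p-values
#'
#' Ties are broken by ascending feature index, so the output is stable
#' across runs. If fewer than `k` features exist, all are returned.
#'
#' @param result a `selection_result` from [wilcoxon_rank()].
#' @param k number of features to keep (>= 1).
#' @return Integer vector of feature indices, ordered by ascending
#'   p-value.
#' @export
select_top_k <- function(result, k) {
  stopifnot(inherits(result, "selection_result"), k >= 1)
  if (is.null(result$p_values)) stop("result carries no p-values")
  result$ranking[seq_len(min(as.integer(k), length(result$ranking)))]
}

#' Boruta all-relevant feature selection
#'
#' Each iteration appends a shuffled "shadow" copy of every undecided
#' feature, fits a random forest, and records a hit for every real feature
#' whose importance (out-of-bag permutation Z-score by default) exceeds
#' the maximum shadow importance. After each iteration every undecided
#' feature's hit count is tested against Binomial(iterations, 1/2),
#' two-sided with Bonferroni correction over the full feature set at
#' level `alpha` (making `alpha` a per-run family-wise error rate):
#' significantly high counts are confirmed, significantly low counts
#' rejected. Iteration stops at
#' `max_iter` or when no feature is undecided; leftovers are tentative.
#'
#' @param features a [feature_matrix()] or numeric matrix with >= 2
#'   columns.
#' @param labels per-sample `"case"`/`"control"` labels.
#' @param alpha significance level of the binomial hit test.
#' @param max_iter maximum number of forest iterations.
#' @param forest_size trees per forest.
#' @param seed RNG seed; decisions are deterministic given the seed.
#' @param importance `"permutation"` (out-of-bag permutation importance,
#'   default) or `"impurity"` (total Gini decrease).
#' @return A `selection_result` with decisions
#'   confirmed/tentative/rejected; `ranking` orders the confirmed features
#'   by mean importance.
#' @export
boruta_select <- function(features, labels = NULL, alpha = 0.05,
                          max_iter = 100L, forest_size = 500L, seed = NULL,
                          importance = c("permutation", "impurity")) {
  importance <- match.arg(importance)
  labels <- resolve_labels(features, labels)
  x <- feature_values(features)
  if (ncol(x) < 2L) stop("boruta needs at least 2 features")
  y <- as.integer(labels == "case")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  p <- ncol(x)
  nm <- colnames(x) %||% paste0("f", seq_len(p))
  decisions <- rep("tentative", p)
  hits <- integer(p)
  iters <- integer(p)
  imp_sum <- numeric(p)
  imp_n <- integer(p)
  it <- 0L
  with_seed(seed, {
    while (it < max_iter) {
      und <- which(decisions == "tentative")
      if (!length(und)) break
      it <- it + 1L
      # confirmed features stay in the design (absorbing their share of
      # splits); only rejected features leave. Shadows are shuffled copies
      # of the undecided features, padded with further shuffled copies so
      # the shadow ensemble keeps its original size: the max-shadow bar
      # must stay as strong late in the run as at iteration one, or
      # chance-correlated survivors get confirmed against a weak control.
      conf <- which(decisions == "confirmed")
      xs <- x[, c(und, conf), drop = FALSE]
      sh_idx <- rep(und, length.out = max(length(und), p, 5L))
      shadow <- apply(x[, sh_idx, drop = FALSE], 2L, sample)
      xa <- cbind(xs, shadow)
      fit <- cpp_rf_train(xa, y, as.integer(forest_size),
                          max(1L, floor(sqrt(ncol(xa)))), 1L,
                          importance == "permutation")
      imp <- if (importance == "permutation") fit$imp_zscore
             else fit$imp_impurity
      real_imp <- imp[seq_along(und)]
      shadow_max <- max(imp[ncol(xs) + seq_along(sh_idx)])
      hits[und] <- hits[und] + (real_imp > shadow_max)
      iters[und] <- iters[und] + 1L
      imp_sum[und] <- imp_sum[und] + real_imp
      imp_n[und] <- imp_n[und] + 1L
      # Two-sided binomial hit test. Bonferroni over the full feature set
      # (every feature starts undecided and is tested repeatedly), so
      # alpha is a per-run family-wise error rate: under a global null,
      # a run confirms anything with probability ~alpha.
      m <- p
      p_hi <- pbinom(hits[und] - 1L, iters[und], 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[und], iters[und], 0.5)
      p_two <- pmin(1, 2 * pmin(p_hi, p_lo))
      sig <- p_two * m <= alpha
      high <- hits[und] > iters[und] / 2
      decisions[und[sig & high]] <- "confirmed"
      decisions[und[sig & !high]] <- "rejected"
    }
  })
  mean_imp <- ifelse(imp_n > 0, imp_sum / pmax(imp_n, 1L), -Inf)
  conf <- which(decisions == "confirmed")
  ranking <- conf[order(-mean_imp[conf], conf)]
  selection_result("boruta", nm, NULL, decisions, ranking,
                   n_iterations = it, importance = mean_imp)
}

#' Serialize a selection result to CSV
#'
#' Columns: `feature_name,p_value,decision,rank` (rank is the position in
#' the ranking, empty for unranked features).
#'
#' @param result a `selection_result`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_selection_csv <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  rank <- rep(NA_integer_, length(result$feature_names))
  rank[result$ranking] <- seq_along(result$ranking)
  df <- data.frame(feature_name = result$feature_names,
                   p_value = if (is.null(result$p_values)) NA_real_
                             else result$p_values,
                   decision = result$decisions, rank = rank)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
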