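# ROC construction and the reported diagnostics: AUC (Mann-Whitney
# concordance), Youden operating point with sensitivity / specificity /
# PPV / NPV, stratified percentile-bootstrap confidence intervals, a
# Mann-Whitney p-value on the scores, and PCA / LDA projections for
# visual analyses.

split_scores <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  case <- scores$scores[scores$labels == "case"]
  control <- scores$scores[scores$labels == "control"]
  if (!length(case) || !length(control))
    stop("both classes must be present")
  list(case = case, control = control)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance: the fraction of case-control
#' pairs in which the case scores higher, counting ties as 1/2. Invariant
#' under strictly increasing score transforms; swapping the labels gives
#' `1 - AUC`.
#'
#' @param scores a [score_set()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores) {
  s <- split_scores(scores)
  r <- rank(c(s$case, s$control))
  n1 <- length(s$case)
  n2 <- length(s$control)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC operating point and confusion-matrix metrics
#'
#' With the default `youden` rule the threshold maximizing
#' `sensitivity + specificity - 1` over all distinct score thresholds is
#' chosen (ties resolved toward higher sensitivity, then the lower
#' threshold). A sample is called positive when its score is >= the
#' threshold. PPV is `NA` when no sample is called positive, NPV when
#' none is called negative.
#'
#' @param scores a [score_set()].
#' @param rule `"youden"` or `"fixed_threshold"`.
#' @param t threshold value when `rule = "fixed_threshold"`.
#' @return List with `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv` and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
operating_point <- function(scores, rule = c("youden", "fixed_threshold"),
                            t = NULL) {
  rule <- match.arg(rule)
  split_scores(scores) # validates both classes present
  y <- scores$labels == "case"
  sc <- scores$scores
  metrics_at <- function(thr) {
    pos <- sc >= thr
    tp <- sum(pos & y); fp <- sum(pos & !y)
    fn <- sum(!pos & y); tn <- sum(!pos & !y)
    list(threshold = thr,
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         tp = tp, fp = fp, tn = tn, fn = fn)
  }
  if (rule == "fixed_threshold") {
    stopifnot(!is.null(t))
    return(metrics_at(t))
  }
  cand <- c(sort(unique(sc)), Inf)
  best <- NULL
  for (thr in cand) {
    m <- metrics_at(thr)
    if (is.null(best) ||
        (m$sensitivity + m$specificity) > (best$sensitivity + best$specificity) + 1e-12 ||
        (abs((m$sensitivity + m$specificity) -
             (best$sensitivity + best$specificity)) <= 1e-12 &&
         m$sensitivity > best$sensitivity + 1e-12))
      best <- m
  }
  best
}

#' Stratified percentile bootstrap confidence interval
#'
#' Cases and controls are resampled with replacement within class, so
#' every resample keeps both classes; the 95% percentile interval of the
#' metric across `n_boot` resamples is returned. Deterministic given the
#' seed.
#'
#' @param scores a [score_set()].
#' @param metric function mapping a `score_set` to a number (default
#'   [roc_auc()]).
#' @param n_boot number of resamples (>= 100).
#' @param seed RNG seed.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, metric = roc_auc, n_boot = 2000L,
                         seed = NULL) {
  stopifnot(n_boot >= 100L)
  split_scores(scores)
  ci <- which(scores$labels == "case")
  co <- which(scores$labels == "control")
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ci, replace = TRUE), sample(co, replace = TRUE))
      metric(score_set(scores$sample_ids[idx], scores$scores[idx],
                       scores$labels[idx], provenance = scores$provenance,
                       threshold = scores$threshold))
    }, numeric(1L))
  })
  unname(quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
}

#' Mann-Whitney p-value for class separation of scores
#'
#' Two-sided rank-sum test of case versus control scores: exact for small
#' tie-free groups, tie-corrected normal approximation otherwise.
#' Consistent with [roc_auc()] through the U-AUC identity.
#'
#' @param scores a [score_set()].
#' @return p-value in (0, 1\].
#' @export
score_pvalue <- function(scores) {
  split_scores(scores)
  ranksum_pvalues(matrix(scores$scores, ncol = 1L),
                  scores$labels == "case")[1L]
}

#' PCA projection of a feature matrix
#'
#' Mean-centred orthogonal projection maximizing variance, components
#' ordered by explained variance. Sign convention: within each component
#' the loading of largest magnitude is positive.
#'
#' @param features a [feature_matrix()] or numeric matrix.
#' @param n_components number of components, at most
#'   `min(n_samples, n_features)`.
#' @return Matrix of sample coordinates with attributes
#'   `"explained_variance"` (per component, fraction of total) and
#'   `"loadings"`.
#' @export
project_pca <- function(features, n_components = 2L) {
  x <- feature_values(features)
  if (!nrow(x)) stop("empty input")
  n_components <- as.integer(n_components)
  stopifnot(n_components >= 1L,
            n_components <= min(nrow(x), ncol(x)))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1L))
  rot <- sweep(rot, 2L, flip, "*")
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
  rownames(coords) <- if (inherits(features, "feature_matrix"))
    features$sample_ids else rownames(x)
  ev <- pc$sdev^2
  attr(coords, "explained_variance") <- (ev / sum(ev))[seq_len(k)]
  attr(coords, "loadings") <- rot
  coords
}

#' Fisher linear discriminant projection
#'
#' Projects samples onto the direction(s) maximizing between-class over
#' within-class scatter. The pooled within-class scatter matrix is
#' regularized by a ridge of `eps` times its mean diagonal, which also
#' handles collinear features. For two classes there is a single
#' discriminant direction.
#'
#' @param features a [feature_matrix()] or numeric matrix.
#' @param labels class labels (from the feature matrix if omitted).
#' @param n_components number of discriminant directions (<= classes - 1,
#'   i.e. 1 for the two-class problems handled here).
#' @param eps relative ridge regularization of the within-class scatter.
#' @return Matrix of projected coordinates with attribute
#'   `"direction"`.
#' @export
project_lda <- function(features, labels = NULL, n_components = 1L,
                        eps = 1e-6) {
  labels <- resolve_labels(features, labels)
  x <- feature_values(features)
  stopifnot(n_components == 1L)
  mu1 <- colMeans(x[labels == "case", , drop = FALSE])
  mu0 <- colMeans(x[labels == "control", , drop = FALSE])
  center <- function(m) sweep(m, 2L, colMeans(m), "-")
  sw <- crossprod(center(x[labels == "case", , drop = FALSE])) +
        crossprod(center(x[labels == "control", , drop = FALSE]))
  ridge <- eps * mean(diag(sw))
  if (!is.finite(ridge) || ridge <= 0) ridge <- eps
  w <- tryCatch(solve(sw + diag(ridge, ncol(x)), mu1 - mu0),
                error = function(e)
                  solve(sw + diag(1e-3 * mean(diag(sw)) + 1e-8, ncol(x)),
                        mu1 - mu0))
  w <- w / sqrt(sum(w^2))
  coords <- x %*% w
  rownames(coords) <- if (inherits(features, "feature_matrix"))
    features$sample_ids else rownames(x)
  colnames(coords) <- "LD1"
  attr(coords, "direction") <- w
  coords
}

#' Build a per-classifier ROC report table
#'
#' One row per classifier family with the standard diagnostic columns:
#' AUC with bootstrap CI, Youden-point sensitivity / specificity with CIs,
#' PPV, NPV (at the score set's empirical prevalence), and the
#' Mann-Whitney p-value of the scores. CIs come from a single joint
#' stratified bootstrap, so all metrics of a row are computed on the same
#' resamples.
#'
#' @param score_sets named list of [score_set()] objects, one per
#'   classifier.
#' @param n_boot bootstrap resamples for the CIs.
#' @param seed RNG seed for the bootstrap.
#' @return A `data.frame` with columns
#'   `method,auc,auc_lo,auc_hi,sensitivity,sens_lo,sens_hi,specificity,`
#'   `spec_lo,spec_hi,ppv,npv,p_value,n_case,n_control`.
#' @export
build_report <- function(score_sets, n_boot = 2000L, seed = NULL) {
  stopifnot(length(score_sets) >= 1L)
  if (is.null(names(score_sets)))
    names(score_sets) <- paste0("model", seq_along(score_sets))
  rows <- lapply(names(score_sets), function(nm) {
    sc <- score_sets[[nm]]
    op <- operating_point(sc)
    boot <- with_seed(seed, {
      ci <- which(sc$labels == "case")
      co <- which(sc$labels == "control")
      t(vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(ci, replace = TRUE), sample(co, replace = TRUE))
        ss <- score_set(sc$sample_ids[idx], sc$scores[idx], sc$labels[idx],
                        provenance = sc$provenance, threshold = sc$threshold)
        opb <- operating_point(ss)
        c(roc_auc(ss), opb$sensitivity, opb$specificity)
      }, numeric(3L)))
    })
    q <- apply(boot, 2L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    data.frame(method = nm, auc = roc_auc(sc),
               auc_lo = q[1L, 1L], auc_hi = q[2L, 1L],
               sensitivity = op$sensitivity,
               sens_lo = q[1L, 2L], sens_hi = q[2L, 2L],
               specificity = op$specificity,
               spec_lo = q[1L, 3L], spec_hi = q[2L, 3L],
               ppv = op$ppv, npv = op$npv,
               p_value = score_pvalue(sc),
               n_case = sum(sc$labels == "case"),
               n_control = sum(sc$labels == "control"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a report table
#'
#' CSV serialization of [build_report()] output; `read_report_csv`
#' round-trips it.
#'
#' @param report a report `data.frame`.
#' @param path CSV path.
#' @return The path (`write_report_csv`) or the report (`read_report_csv`).
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
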