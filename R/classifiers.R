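# The four classifier families: L1-penalized (sparse) logistic
# regression, random forest, Gaussian-process classifier with a
# squared-exponential kernel, and an RBF support vector machine solved as
# a quadratic program. Each family exposes a fit/predict pair returning a
# continuous score that is monotone in case-likelihood.
#
# Features are standardized with training-set mean/sd before the
# scale-sensitive families (logistic, GP, SVM); the forest is
# scale-equivariant and sees raw values.

#' Classifier specification
#'
#' @param family one of `"sparse_logistic"`, `"random_forest"`,
#'   `"gaussian_process"`, `"svm"`.
#' @param grid hyperparameter grid: a non-empty list of named lists, one
#'   entry per candidate. Defaults per family: sparse logistic inverse
#'   penalty strength `C` in \{0.01, 0.1, 1, 10\} (lasso penalty
#'   `lambda = 1 / (C n)`); random forest `mtry_frac` in \{1/3, 0.6\} with
#'   500 trees; Gaussian process length-scale multiplier `ls_mult` in
#'   \{0.5, 1, 2, 4\} times the median pairwise distance; SVM box
#'   constraint `C` in \{0.1, 1, 10\} with RBF `gamma = 1/p`.
#' @param seed RNG seed for stochastic families (the forest).
#' @param ntree forest size for the random-forest family.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("sparse_logistic", "random_forest",
                                       "gaussian_process", "svm"),
                            grid = NULL, seed = NULL, ntree = 500L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      sparse_logistic = lapply(c(0.01, 0.1, 1, 10), function(C) list(C = C)),
      random_forest = lapply(c(1 / 3, 0.6), function(f) list(mtry_frac = f)),
      gaussian_process = lapply(c(0.5, 1, 2, 4),
                                function(m) list(ls_mult = m)),
      svm = lapply(c(0.1, 1, 10), function(C) list(C = C)))
  }
  if (!length(grid)) stop("hyperparameter grid must be non-empty")
  structure(list(family = family, grid = grid, seed = seed,
                 ntree = as.integer(ntree)),
            class = "classifier_spec")
}

standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
}

sqdist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

# Fit one family on a plain numeric matrix x and 0/1 response.
fit_family <- function(spec, x, y01, hyper, seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y01))
  family <- spec$family
  std <- if (family == "random_forest") NULL else standardize_fit(x)
  xs <- if (is.null(std)) x else standardize_apply(x, std)
  fit <- switch(family,
    sparse_logistic = {
      lambda <- 1 / (hyper$C * nrow(xs))
      xg <- if (ncol(xs) == 1L) cbind(xs, 0) else xs
      g <- glmnet::glmnet(xg, factor(y01, levels = c(0, 1)),
                          family = "binomial", alpha = 1, lambda = lambda,
                          standardize = FALSE)
      list(glmnet = g, lambda = lambda, padded = ncol(xs) == 1L)
    },
    random_forest = {
      mtry <- max(1L, min(ncol(x), round(hyper$mtry_frac * ncol(x))))
      with_seed(seed, cpp_rf_train(x, as.integer(y01), spec$ntree, mtry, 1L,
                                   FALSE))
    },
    gaussian_process = {
      d <- sqrt(sqdist(xs, xs))
      med <- stats::median(d[upper.tri(d)])
      if (!is.finite(med) || med <= 0) med <- 1
      ls <- hyper$ls_mult * med
      K <- exp(-d^2 / (2 * ls^2))
      noise <- 0.1
      alpha <- solve(K + diag(noise, nrow(xs)), 2 * y01 - 1)
      list(alpha = alpha, xtrain = xs, ls = ls)
    },
    svm = {
      yy <- 2 * y01 - 1
      gamma <- 1 / ncol(xs)
      K <- exp(-gamma * sqdist(xs, xs))
      n <- nrow(xs)
      Dmat <- (K * tcrossprod(yy)) + diag(1e-8, n)
      sol <- quadprog::solve.QP(Dmat, rep(1, n),
                                cbind(yy, diag(n), -diag(n)),
                                c(0, rep(0, n), rep(-hyper$C, n)), meq = 1L)
      a <- pmin(pmax(sol$solution, 0), hyper$C)
      f0 <- as.vector(K %*% (a * yy))
      sv <- a > 1e-8
      margin <- sv & a < hyper$C - 1e-8
      b <- if (any(margin)) mean(yy[margin] - f0[margin])
           else if (any(sv)) mean(yy[sv] - f0[sv]) else 0
      list(alpha = a, y = yy, xtrain = xs, gamma = gamma, b = b)
    })
  structure(list(family = family, fit = fit, std = std, hyper = hyper,
                 threshold = if (family == "random_forest") 0.5 else 0),
            class = "vocdx_model")
}

predict_family <- function(model, x) {
  stopifnot(inherits(model, "vocdx_model"), is.matrix(x))
  xs <- if (is.null(model$std)) x else standardize_apply(x, model$std)
  s <- switch(model$family,
    sparse_logistic = {
      xg <- if (model$fit$padded) cbind(xs, 0) else xs
      as.vector(stats::predict(model$fit$glmnet, xg, type = "link"))
    },
    random_forest = as.vector(cpp_rf_predict(model$fit$trees, x)),
    gaussian_process = {
      Ks <- exp(-sqdist(xs, model$fit$xtrain) / (2 * model$fit$ls^2))
      as.vector(Ks %*% model$fit$alpha)
    },
    svm = {
      Ks <- exp(-model$fit$gamma * sqdist(xs, model$fit$xtrain))
      as.vector(Ks %*% (model$fit$alpha * model$fit$y)) + model$fit$b
    })
  if (!all(is.finite(s))) stop("non-finite classifier scores")
  s
}
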