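# Separable 2D multilevel discrete wavelet transform with the Daubechies
# 4-tap filter pair and periodized boundaries.
#
# Periodization keeps the transform orthonormal, so the coefficient count
# equals the input count, energy is conserved exactly, and the inverse is
# the transpose. A 2-channel orthonormal bank needs an even signal length,
# so at each level an axis is halved only while its current length is even
# (and at least the filter support of 4); an axis that reaches an odd
# length is carried through unchanged. For a 512 x 102 FAIMS matrix the
# dispersion-field axis (102 columns) is therefore transformed once
# (102 -> 51) and the compensation-voltage axis (512 rows) at every level.

# Daubechies 4-tap (2 vanishing moments) analysis filter pair.
daub4_filters <- function() {
  s <- sqrt(3)
  h <- c(1 + s, 3 + s, 3 - s, 1 - s) / (4 * sqrt(2))
  list(h = h, g = c(h[4L], -h[3L], h[2L], -h[1L]))
}

.dwt_cache <- new.env(parent = emptyenv())

# n x n orthogonal analysis operator: rows 1..n/2 low-pass, rest high-pass.
dwt_operator <- function(n) {
  key <- as.character(n)
  W <- .dwt_cache[[key]]
  if (!is.null(W)) return(W)
  stopifnot(n %% 2L == 0L, n >= 4L)
  f <- daub4_filters()
  W <- matrix(0, n, n)
  half <- n / 2L
  for (k in seq_len(half)) {
    cols <- ((2L * (k - 1L) + 0:3) %% n) + 1L
    for (i in 1:4) {
      W[k, cols[i]] <- W[k, cols[i]] + f$h[i]
      W[half + k, cols[i]] <- W[half + k, cols[i]] + f$g[i]
    }
  }
  .dwt_cache[[key]] <- W
  W
}

halvable <- function(n) n %% 2L == 0L && n >= 4L

#' Maximum feasible decomposition depth for a matrix
#'
#' The deepest level at which at least one axis of the (periodized,
#' orthonormal) 2D Daubechies-4 transform can still be halved. An axis is
#' halved only while its running length is even and at least 4; an odd axis
#' is carried through unchanged.
#'
#' @param dim integer vector of length 2 (rows, columns).
#' @return Integer: the maximum number of levels (0 if neither axis can be
#'   transformed at all).
#' @export
max_dwt2_levels <- function(dim) {
  stopifnot(length(dim) == 2L)
  nr <- as.integer(dim[1L]); nc <- as.integer(dim[2L])
  lev <- 0L
  while (halvable(nr) || halvable(nc)) {
    if (halvable(nr)) nr <- nr %/% 2L
    if (halvable(nc)) nc <- nc %/% 2L
    lev <- lev + 1L
  }
  lev
}

#' 2D multilevel Daubechies-4 wavelet decomposition
#'
#' Separable periodized transform. At each level the current approximation
#' band is filtered and downsampled along every axis whose length is even
#' (and >= 4). Band letters give the filter applied per axis, first letter
#' for the row (compensation-voltage) axis, second for the column
#' (dispersion-field) axis; an axis skipped at a level keeps the letter L.
#' With both axes transformed a level yields detail bands LH, HL, HH; with
#' only the row axis transformed it yields a single detail band HL.
#'
#' The transform is orthonormal: the total coefficient count equals the
#' input count, squared-coefficient energy equals input energy, and
#' [dwt2_reconstruct()] inverts it to machine precision.
#'
#' @param x numeric matrix.
#' @param levels decomposition depth, between 1 and [max_dwt2_levels()].
#' @return An object of class `dwt2` with the final approximation band
#'   (`ll`), per-level detail bands (`detail`), and the per-level axis
#'   schedule.
#' @seealso [dwt2_reconstruct()], [dwt2_flatten()]
#' @export
dwt2_decompose <- function(x, levels = 4L) {
  stopifnot(is.matrix(x), is.numeric(x), all(is.finite(x)))
  levels <- as.integer(levels)
  maxlev <- max_dwt2_levels(dim(x))
  if (levels < 1L || levels > maxlev) {
    stop("infeasible level count ", levels, " for a ", nrow(x), " x ",
         ncol(x), " matrix; maximum feasible level is ", maxlev)
  }
  ll <- x
  detail <- vector("list", levels)
  schedule <- vector("list", levels)
  for (lev in seq_len(levels)) {
    dr <- halvable(nrow(ll))
    dc <- halvable(ncol(ll))
    bands <- list()
    if (dr) {
      Wr <- dwt_operator(nrow(ll))
      tmp <- Wr %*% ll
      half <- nrow(ll) / 2L
      lo <- tmp[seq_len(half), , drop = FALSE]
      hi <- tmp[half + seq_len(half), , drop = FALSE]
      if (dc) {
        Wc <- dwt_operator(ncol(ll))
        lo <- lo %*% t(Wc)
        hi <- hi %*% t(Wc)
        halfc <- ncol(ll) / 2L
        bands$LH <- lo[, halfc + seq_len(halfc), drop = FALSE]
        bands$HL <- hi[, seq_len(halfc), drop = FALSE]
        bands$HH <- hi[, halfc + seq_len(halfc), drop = FALSE]
        ll <- lo[, seq_len(halfc), drop = FALSE]
      } else {
        bands$HL <- hi
        ll <- lo
      }
    } else if (dc) {
      Wc <- dwt_operator(ncol(ll))
      tmp <- ll %*% t(Wc)
      halfc <- ncol(ll) / 2L
      bands$LH <- tmp[, halfc + seq_len(halfc), drop = FALSE]
      ll <- tmp[, seq_len(halfc), drop = FALSE]
    }
    detail[[lev]] <- bands
    schedule[[lev]] <- c(rows = dr, cols = dc)
  }
  structure(list(ll = ll, detail = detail, schedule = schedule,
                 levels = levels, dim = dim(x)),
            class = "dwt2")
}

#' Inverse 2D Daubechies-4 wavelet transform
#'
#' Reconstructs the original matrix from a [dwt2_decompose()] object.
#' Because the periodized transform is orthonormal, reconstruction is exact
#' to floating-point round-off.
#'
#' @param dec a `dwt2` object.
#' @return The reconstructed numeric matrix.
#' @export
dwt2_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "dwt2"))
  ll <- dec$ll
  for (lev in rev(seq_len(dec$levels))) {
    sched <- dec$schedule[[lev]]
    bands <- dec$detail[[lev]]
    if (sched[["rows"]]) {
      if (sched[["cols"]]) {
        Wc <- dwt_operator(2L * ncol(ll))
        lo <- cbind(ll, bands$LH) %*% Wc
        hi <- cbind(bands$HL, bands$HH) %*% Wc
      } else {
        lo <- ll
        hi <- bands$HL
      }
      Wr <- dwt_operator(2L * nrow(ll))
      ll <- t(Wr) %*% rbind(lo, hi)
    } else if (sched[["cols"]]) {
      Wc <- dwt_operator(2L * ncol(ll))
      ll <- cbind(ll, bands$LH) %*% Wc
    }
  }
  ll
}

band_names_for <- function(prefix, m) {
  idx <- expand.grid(r = seq_len(nrow(m)), c = seq_len(ncol(m)))
  paste0(prefix, "_", idx$r, "_", idx$c)
}

#' Flatten a wavelet decomposition into a named feature vector
#'
#' Coefficients are emitted in a deterministic order that depends only on
#' the input shape, level count and `keep` rule: levels ascending, bands in
#' the order LH, HL, HH within a level, the final approximation band last,
#' each band column-major. Names follow `L{level}_{band}_{row}_{col}`.
#'
#' @param dec a `dwt2` object.
#' @param keep `"all_levels"` (every subband; the coefficient count then
#'   equals the input count) or `"coarsest_only"` (only the deepest level's
#'   detail bands plus the final approximation band).
#' @return Named numeric vector of wavelet coefficients.
#' @export
dwt2_flatten <- function(dec, keep = c("all_levels", "coarsest_only")) {
  stopifnot(inherits(dec, "dwt2"))
  keep <- match.arg(keep)
  lev_set <- if (keep == "all_levels") seq_len(dec$levels) else dec$levels
  pieces <- list()
  for (lev in lev_set) {
    bands <- dec$detail[[lev]]
    for (bn in c("LH", "HL", "HH"))
      if (!is.null(bands[[bn]])) pieces[[paste0("L", lev, "_", bn)]] <- bands[[bn]]
  }
  pieces[[paste0("L", dec$levels, "_LL")]] <- dec$ll
  out <- unlist(lapply(pieces, as.vector), use.names = FALSE)
  # the name vector is a pure function of (shape, levels, keep): cache it
  key <- paste("nm", paste(dec$dim, collapse = "x"), dec$levels, keep,
               sep = "_")
  nm <- .dwt_cache[[key]]
  if (is.null(nm)) {
    nm <- unlist(lapply(names(pieces), function(pn)
      band_names_for(pn, pieces[[pn]])), use.names = FALSE)
    .dwt_cache[[key]] <- nm
  }
  names(out) <- nm
  out
}
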