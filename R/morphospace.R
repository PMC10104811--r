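# PCA morphospace over normalized elliptic Fourier coefficients.

#' Fit the PCA morphospace
#'
#' Centered, unscaled (covariance-matrix) principal component analysis of the
#' coefficient feature matrix; the coefficients share units, so no
#' standardization is applied. Components with eigenvalue below
#' `1e-12 * total variance` are dropped. Eigenvector signs are fixed
#' deterministically by requiring the largest-magnitude loading of each
#' component to be positive.
#'
#' @param features a `"coef_matrix"` from [coefficient_matrix()] /
#'   [efa_dataset()], or a plain numeric matrix (then `meta` may be supplied).
#' @param meta optional data.frame with `specimen_id`, `group`, `time_slice`
#'   rows matching the matrix; taken from the `coef_matrix` when present.
#' @return object of class `"morphospace"`: `center` (feature means),
#'   `loadings` (orthonormal columns `PC1..PCm`), `eigenvalues` (descending,
#'   sample-variance scale), `var_explained`, `scores` (specimens x PCs) and
#'   `meta`.
#' @export
fit_morphospace <- function(features, meta = NULL) {
  if (inherits(features, "coef_matrix")) {
    meta <- features$meta
    features <- features$x
  }
  x <- as.matrix(features)
  if (nrow(x) < 3) stop("PCA needs at least 3 specimens")
  if (anyNA(x)) stop("missing values in feature matrix")
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var <= 0) stop("constant feature matrix: zero total variance")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  keep <- which(ev > 1e-12 * total_var)
  ev <- ev[keep]
  load <- p$rotation[, keep, drop = FALSE]
  sco <- p$x[, keep, drop = FALSE]
  # deterministic sign convention
  for (j in seq_along(keep)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      sco[, j] <- -sco[, j]
    }
  }
  colnames(load) <- colnames(sco) <- paste0("PC", seq_along(keep))
  if (is.null(meta)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(x)))
    meta <- data.frame(specimen_id = ids, group = "", time_slice = "other",
                       stringsAsFactors = FALSE)
  }
  rownames(sco) <- meta$specimen_id
  structure(list(center = p$center, loadings = load,
                 eigenvalues = unname(ev),
                 var_explained = unname(ev) / sum(ev),
                 scores = sco, meta = meta),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  m <- length(x$eigenvalues)
  cat(sprintf("<morphospace> %d specimens, %d retained PCs\n",
              nrow(x$scores), m))
  k <- min(5, m)
  cat("  variance explained:",
      paste(sprintf("PC%d=%.1f%%", seq_len(k), 100 * x$var_explained[seq_len(k)]),
            collapse = "  "), "\n")
  invisible(x)
}

#' Project feature rows into a fitted morphospace
#'
#' @param object a `"morphospace"`.
#' @param newdata numeric matrix (or `coef_matrix`) with the model's feature
#'   columns; a single feature vector is also accepted.
#' @param ... unused.
#' @return score matrix `(features - center) %*% loadings`.
#' @export
predict.morphospace <- function(object, newdata, ...) {
  if (inherits(newdata, "coef_matrix")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("feature count (", ncol(newdata), ") does not match model (",
         length(object$center), ")")
  sweep(newdata, 2, object$center) %*% object$loadings
}

#' Per-PC score ranges occupied by each group x time-slice subset
#'
#' For each group, time slice and principal component, the minimum, maximum,
#' range and subset size of the (untreated, non-bootstrapped) scores. Every
#' group x slice combination of the labels is emitted; empty subsets get
#' `n = 0` and `NA` range rather than being dropped.
#'
#' @param model a `"morphospace"`.
#' @param pcs integer vector of PC indices (default: all retained).
#' @return data.frame with columns `group`, `time_slice`, `pc`, `min`, `max`,
#'   `range`, `n`.
#' @export
pc_ranges <- function(model, pcs = NULL) {
  stopifnot(inherits(model, "morphospace"))
  if (is.null(pcs)) pcs <- seq_along(model$eigenvalues)
  meta <- model$meta
  if (any(!nzchar(meta$group))) stop("every specimen must carry a group label")
  groups <- unique(meta$group)
  slices <- intersect(TIME_SLICES, unique(meta$time_slice))
  out <- expand.grid(pc = pcs, time_slice = slices, group = groups,
                     stringsAsFactors = FALSE)[, c("group", "time_slice", "pc")]
  out$min <- out$max <- out$range <- NA_real_
  out$n <- 0L
  for (r in seq_len(nrow(out))) {
    sel <- meta$group == out$group[r] & meta$time_slice == out$time_slice[r]
    out$n[r] <- sum(sel)
    if (out$n[r] > 0) {
      v <- model$scores[sel, out$pc[r]]
      out$min[r] <- min(v); out$max[r] <- max(v)
      out$range[r] <- out$max[r] - out$min[r]
    }
  }
  out[, c("group", "time_slice", "pc", "min", "max", "range", "n")]
}
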