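# Elliptic Fourier analysis of closed outlines.
#
# The closed polygon (x(t), y(t)), parameterized by cumulative chord length t
# with perimeter T, is expanded as
#   x(t) = A0 + sum_n a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T)
#   y(t) = C0 + sum_n c_n cos(2 pi n t / T) + d_n sin(2 pi n t / T)
# with the segmentwise closed-form coefficients of the classical outline
# harmonic decomposition: for segments p = 1..K with steps (dx_p, dy_p),
# lengths dt_p and cumulative t_p,
#   a_n = T / (2 n^2 pi^2) * sum_p (dx_p/dt_p) [cos(2 pi n t_p/T) - cos(2 pi n t_{p-1}/T)]
# and b_n, c_n, d_n analogously with sin and dy.

#' Compute elliptic Fourier descriptors of a closed outline
#'
#' @param o an [outline()].
#' @param n_harmonics number of harmonics N (default 20).
#' @return object of class `"efd"`: list with `specimen_id`, `n_harmonics`,
#'   `coef` (N x 4 matrix, columns `a`,`b`,`c`,`d`), `dc` (the centroid
#'   constants `A0`, `C0`), `perimeter` and label metadata.
#' @export
compute_efd <- function(o, n_harmonics = 20L) {
  stopifnot(inherits(o, "outline"))
  N <- as.integer(n_harmonics)
  if (N < 1) stop("n_harmonics must be >= 1")
  pts <- o$points
  K <- nrow(pts)
  nxt <- pts[c(2:K, 1), , drop = FALSE]
  dx <- nxt[, 1] - pts[, 1]
  dy <- nxt[, 2] - pts[, 2]
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) stop("outline '", o$specimen_id, "': zero-length segment")
  Tt <- sum(dt)
  if (Tt <= 0) stop("outline '", o$specimen_id, "': zero perimeter")
  tp <- cumsum(dt)            # t_1 .. t_K = T
  tp0 <- c(0, tp[-K])         # t_0 .. t_{K-1}
  n <- seq_len(N)
  w <- 2 * pi / Tt
  # N x K phase matrices
  Cp <- cos(outer(n, tp) * w) - cos(outer(n, tp0) * w)
  Sp <- sin(outer(n, tp) * w) - sin(outer(n, tp0) * w)
  fx <- dx / dt; fy <- dy / dt
  fac <- Tt / (2 * n^2 * pi^2)
  coef <- cbind(a = fac * as.vector(Cp %*% fx),
                b = fac * as.vector(Sp %*% fx),
                c = fac * as.vector(Cp %*% fy),
                d = fac * as.vector(Sp %*% fy))
  rownames(coef) <- n
  # DC components (outline centroid along the parameterization)
  xi <- c(0, cumsum(dx)[-K]) - fx * tp0
  delta <- c(0, cumsum(dy)[-K]) - fy * tp0
  A0 <- pts[1, 1] + sum(fx / 2 * (tp^2 - tp0^2) + xi * (tp - tp0)) / Tt
  C0 <- pts[1, 2] + sum(fy / 2 * (tp^2 - tp0^2) + delta * (tp - tp0)) / Tt
  structure(list(specimen_id = o$specimen_id, group = o$group,
                 time_slice = o$time_slice, n_harmonics = N, coef = coef,
                 dc = c(A0 = unname(A0), C0 = unname(C0)), perimeter = Tt),
            class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("<%s> %s  [%d harmonics, T=%.4g]\n",
              class(x)[1], x$specimen_id, x$n_harmonics, x$perimeter))
  cat("  harmonic 1: ", paste(sprintf("%s=%.4g", colnames(x$coef), x$coef[1, ]),
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

# rotate the starting point of every harmonic by theta:
# [a b; c d]_n %*% R(n * theta)
.rotate_start <- function(coef, theta) {
  n <- seq_len(nrow(coef))
  cn <- cos(n * theta); sn <- sin(n * theta)
  cbind(a = coef[, "a"] * cn + coef[, "b"] * sn,
        b = -coef[, "a"] * sn + coef[, "b"] * cn,
        c = coef[, "c"] * cn + coef[, "d"] * sn,
        d = -coef[, "c"] * sn + coef[, "d"] * cn)
}

# rotate the shape by -psi: R(-psi) %*% [a b; c d]_n
.rotate_shape <- function(coef, psi) {
  cp <- cos(psi); sp <- sin(psi)
  cbind(a = cp * coef[, "a"] + sp * coef[, "c"],
        b = cp * coef[, "b"] + sp * coef[, "d"],
        c = -sp * coef[, "a"] + cp * coef[, "c"],
        d = -sp * coef[, "b"] + cp * coef[, "d"])
}

#' Normalize elliptic Fourier descriptors on the first harmonic
#'
#' Standardizes size, rotation and digitization starting point using the
#' first-harmonic ellipse: the starting-point phase
#' `theta = atan2(2 (a1 b1 + c1 d1), a1^2 + c1^2 - b1^2 - d1^2) / 2` aligns the
#' parameter origin with the ellipse's semi-major axis (its two pi-separated
#' solutions differ by a sign flip of the even harmonics; the tie is broken
#' deterministically by making the first non-negligible even-harmonic `a`/`c`
#' coefficient positive, a rule invariant under similarity transforms and
#' reflection of the input);
#' the shape is then rotated by `-psi`, `psi = atan2(c1, a1)`, and scaled by
#' the semi-major amplitude `E = sqrt(a1^2 + c1^2)`. After normalization
#' `a1 = 1`, `b1 = c1 = 0` and `|d1| <= 1`; translation information (`A0`,
#' `C0`) is discarded.
#'
#' @param e an `"efd"` object from [compute_efd()].
#' @param allow_reflection if `TRUE`, chirality is also standardized:
#'   mirroring a counterclockwise outline negates the `b_n` and `c_n`
#'   coefficients, so the sign of the first non-negligible `b`/`c`
#'   coefficient is canonicalized (and the reflection recorded), mapping a
#'   shape and its mirror image to identical descriptors. Default `FALSE`:
#'   specimens digitized in a consistent aspect keep their chirality.
#' @return object of class `c("nefd", "efd")` with a `norm` record
#'   (`scale`, `psi`, `theta`, `reflected`).
#' @export
normalize_efd <- function(e, allow_reflection = FALSE) {
  stopifnot(inherits(e, "efd"))
  h1 <- e$coef[1, ]
  theta <- 0.5 * atan2(2 * (h1["a"] * h1["b"] + h1["c"] * h1["d"]),
                       h1["a"]^2 + h1["c"]^2 - h1["b"]^2 - h1["d"]^2)
  theta <- unname(theta)
  co <- .rotate_start(e$coef, theta)
  # the phase formula extremizes the first-harmonic amplitude; make sure the
  # semi-MAJOR axis (not the minor) ends up in the a/c column, so |d1| <= 1
  if (co[1, "b"]^2 + co[1, "d"]^2 > co[1, "a"]^2 + co[1, "c"]^2) {
    theta <- theta + pi / 2
    co <- .rotate_start(e$coef, theta)
  }
  Estar <- sqrt(co[1, "a"]^2 + co[1, "c"]^2)
  if (Estar <= .Machine$double.eps * e$perimeter)
    stop("degenerate first harmonic: cannot normalize '", e$specimen_id, "'")
  psi <- atan2(co[1, "c"], co[1, "a"])
  co <- .rotate_shape(co, psi) / Estar
  # The starting-point phase has two pi-separated solutions (the two ends of
  # the semi-major axis); they differ only by a sign flip of all
  # even-harmonic coefficients. Break the tie intrinsically (invariant under
  # rotation, scaling, translation, start shift AND mirroring -- mirroring a
  # counterclockwise outline negates the b and c coefficients, leaving a and
  # d untouched): make the first non-negligible even-harmonic a/d
  # coefficient positive.
  if (nrow(co) >= 2) {
    ev <- seq(2, nrow(co), by = 2)
    dec <- as.vector(t(co[ev, c("a", "d"), drop = FALSE]))  # a2,d2,a4,d4,...
    hit <- which(abs(dec) > 1e-9)
    if (length(hit) > 0 && dec[hit[1]] < 0) {
      co[ev, ] <- -co[ev, ]
      theta <- theta + pi
      psi <- psi + pi
    }
  }
  theta <- atan2(sin(theta), cos(theta))  # wrap to (-pi, pi]
  psi <- atan2(sin(psi), cos(psi))
  # Optional reflection alignment: mirroring a counterclockwise outline
  # negates the b and c coefficients, so canonicalizing the sign of the
  # first non-negligible b/c coefficient maps a shape and its mirror image
  # to the same descriptor set.
  reflected <- FALSE
  if (allow_reflection) {
    dec <- as.vector(t(co[, c("b", "c"), drop = FALSE]))  # b1,c1,b2,c2,...
    hit <- which(abs(dec) > 1e-9)
    if (length(hit) > 0 && dec[hit[1]] < 0) {
      co[, "b"] <- -co[, "b"]
      co[, "c"] <- -co[, "c"]
      reflected <- TRUE
    }
  }
  rownames(co) <- seq_len(nrow(co))
  out <- e
  out$coef <- co
  out$dc <- c(A0 = 0, C0 = 0)
  out$norm <- list(scale = unname(Estar), psi = unname(psi),
                   theta = theta, reflected = reflected)
  class(out) <- c("nefd", "efd")
  out
}

#' Reconstruct an outline from (possibly truncated) harmonics
#'
#' Evaluates the inverse transform at `n_points` equally spaced parameter
#' values using the first `harmonics_used` harmonics.
#'
#' @param e an `"efd"` or `"nefd"` object.
#' @param n_points number of points to evaluate (default 200).
#' @param harmonics_used number of leading harmonics (default all).
#' @return an [outline()] (built without simplicity validation, since strongly
#'   truncated reconstructions may self-intersect).
#' @export
reconstruct <- function(e, n_points = 200L, harmonics_used = e$n_harmonics) {
  stopifnot(inherits(e, "efd"))
  H <- as.integer(harmonics_used)
  if (H < 1 || H > e$n_harmonics)
    stop("harmonics_used must be in 1..", e$n_harmonics)
  tt <- 2 * pi * (seq_len(n_points) - 1) / n_points
  n <- seq_len(H)
  Cm <- cos(outer(tt, n))   # n_points x H
  Sm <- sin(outer(tt, n))
  x <- e$dc["A0"] + Cm %*% e$coef[n, "a"] + Sm %*% e$coef[n, "b"]
  y <- e$dc["C0"] + Cm %*% e$coef[n, "c"] + Sm %*% e$coef[n, "d"]
  outline(cbind(as.vector(x), as.vector(y)), specimen_id = e$specimen_id,
          group = e$group, time_slice = e$time_slice, validate = FALSE)
}

#' Assemble the PCA feature matrix from normalized descriptors
#'
#' One row per specimen; columns `d1, a2, b2, c2, d2, ..., aN, bN, cN, dN`.
#' The first-harmonic constants `a1 = 1`, `b1 = c1 = 0` are dropped (they
#' carry no variance after normalization) while `d1`, the first-ellipse
#' aspect ratio, is kept; `4 N - 3` columns in total.
#'
#' @param nefds list of `"nefd"` objects sharing the same harmonic count.
#' @return object of class `"coef_matrix"`: list with `x` (feature matrix),
#'   `meta` (specimen_id, group, time_slice) and `n_harmonics`.
#' @export
coefficient_matrix <- function(nefds) {
  stopifnot(is.list(nefds))
  if (length(nefds) == 0) stop("empty descriptor list")
  ok <- vapply(nefds, inherits, TRUE, "nefd")
  if (!all(ok)) stop("all elements must be normalized descriptors (nefd)")
  Ns <- vapply(nefds, function(e) e$n_harmonics, 0L)
  if (length(unique(Ns)) != 1)
    stop("mixed harmonic counts: ", paste(unique(Ns), collapse = ", "))
  N <- Ns[1]
  feat <- t(vapply(nefds, function(e) {
    v <- as.vector(t(e$coef))            # a1 b1 c1 d1 a2 b2 ...
    v[-(1:3)]                            # drop a1, b1, c1
  }, numeric(4 * N - 3)))
  colnames(feat) <- c("d1", as.vector(t(outer(2:N, c("a", "b", "c", "d"),
                                              function(n, l) paste0(l, n)))))
  meta <- data.frame(
    specimen_id = vapply(nefds, function(e) e$specimen_id, ""),
    group = vapply(nefds, function(e) e$group, ""),
    time_slice = vapply(nefds, function(e) e$time_slice, ""),
    row.names = NULL, stringsAsFactors = FALSE)
  rownames(feat) <- meta$specimen_id
  structure(list(x = feat, meta = meta, n_harmonics = N),
            class = "coef_matrix")
}

#' @export
print.coef_matrix <- function(x, ...) {
  cat(sprintf("<coef_matrix> %d specimens x %d coefficients (%d harmonics)\n",
              nrow(x$x), ncol(x$x), x$n_harmonics))
  invisible(x)
}

#' Elliptic Fourier analysis of a whole dataset
#'
#' Convenience wrapper: resamples every outline to `k` points, computes the
#' descriptors, normalizes them on the first harmonic and assembles the
#' feature matrix.
#'
#' @param ds an [outline_set()].
#' @param n_harmonics harmonics per specimen (default 20).
#' @param k arc-length resampling density before analysis (default 200).
#' @param allow_reflection passed to [normalize_efd()].
#' @return a `"coef_matrix"` (see [coefficient_matrix()]).
#' @export
efa_dataset <- function(ds, n_harmonics = 20L, k = 200L,
                        allow_reflection = FALSE) {
  stopifnot(inherits(ds, "outline_set"))
  nefds <- lapply(ds$outlines, function(o) {
    normalize_efd(compute_efd(resample_outline(o, k), n_harmonics),
                  allow_reflection = allow_reflection)
  })
  coefficient_matrix(unname(nefds))
}
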