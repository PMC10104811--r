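# Disparity (sum of variances) with bootstrap + rarefaction, and pairwise
# Welch t-tests between subsets.

#' Derive a reproducible subset seed from a root seed and labels
#'
#' Deterministic string hash (31-adic, modulo the Mersenne prime 2^31 - 1),
#' so that adding or removing one subset never perturbs the draws of the
#' others.
#'
#' @param root integer root seed.
#' @param ... further label components (group, time slice, index, ...).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  s <- paste(c(as.character(root), vapply(list(...), as.character, "")),
             collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# evaluate an expression under a local RNG state (lazy promise: `code` is
# only forced after the seed is set)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Sum of variances of a score matrix
#'
#' The disparity metric: the sum over retained principal components of the
#' sample (n-1 denominator) variance of the subset's scores -- equivalently
#' the trace of the subset's sample covariance matrix.
#'
#' @param scores numeric matrix (specimens x PCs); a vector is treated as one
#'   column.
#' @param pcs optional column indices to restrict to.
#' @return non-negative numeric scalar.
#' @export
sum_of_variances <- function(scores, pcs = NULL) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  scores <- as.matrix(scores)
  if (!is.null(pcs)) scores <- scores[, pcs, drop = FALSE]
  n <- nrow(scores)
  if (n < 2) stop("sum of variances undefined for n < 2")
  mu <- colMeans(scores)
  sum(colSums(scores^2) - n * mu^2) / (n - 1)
}

#' Bootstrap (and rarefy) the disparity of one subset
#'
#' Each replicate draws `m` rows with replacement from the subset's score
#' matrix and records their sum of variances. `m` smaller than the subset
#' size is the rarefaction-based correction for unequal sample sizes: every
#' subset is resampled at the size of the smallest subset it is compared
#' with, so disparity estimates are comparable.
#'
#' @param scores subset score matrix (n x PCs), n >= 2.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param m rarefaction size (2 <= m <= n), or `"none"` / `NULL` for plain
#'   bootstrap at full size.
#' @param seed integer seed; replicates are reproducible and their order is
#'   deterministic.
#' @param group,time_slice optional labels stored in the result.
#' @return object of class `"disparity_boot"`: `group`, `time_slice`, `n`,
#'   `m`, `n_boot`, `seed`, `point_estimate` (sum of variances of the full,
#'   untreated subset) and `replicates` (length `n_boot`).
#' @export
bootstrap_disparity <- function(scores, n_boot = 10000L, m = NULL,
                                seed = 1L, group = "", time_slice = "") {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2) stop("subset size n < 2")
  if (is.null(m) || identical(m, "none")) m <- n
  m <- as.integer(m)
  if (m > n) stop("rarefaction size m (", m, ") exceeds subset size n (", n, ")")
  if (m < 2) stop("rarefaction size m < 2")
  n_boot <- as.integer(n_boot)
  point <- sum_of_variances(scores)
  reps <- with_seed(seed, {
    idx <- matrix(sample.int(n, m * n_boot, replace = TRUE), nrow = m)
    vapply(seq_len(n_boot), function(r) {
      x <- scores[idx[, r], , drop = FALSE]
      mu <- colMeans(x)
      sum(colSums(x^2) - m * mu^2) / (m - 1)
    }, 0)
  })
  structure(list(group = group, time_slice = time_slice, n = n, m = m,
                 n_boot = n_boot, seed = as.integer(seed),
                 point_estimate = point, replicates = reps),
            class = "disparity_boot")
}

#' @export
print.disparity_boot <- function(x, ...) {
  q <- stats::quantile(x$replicates, c(0.025, 0.975), names = FALSE)
  cat(sprintf(
    "<disparity_boot> %s/%s  n=%d m=%d  SoV=%.4g  boot mean=%.4g [%.4g, %.4g]\n",
    if (nzchar(x$group)) x$group else "?",
    if (nzchar(x$time_slice)) x$time_slice else "?",
    x$n, x$m, x$point_estimate, mean(x$replicates), q[1], q[2]))
  invisible(x)
}

#' Welch two-sample t-test between two replicate vectors
#'
#' Computes `t = (mean(a) - mean(b)) / sqrt(var(a)/na + var(b)/nb)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. When both
#' vectors have zero variance the test degenerates: equal means give
#' `t = 0, p = 1`; unequal means give the `p = 0` limit, flagged in the
#' result.
#'
#' @param a,b numeric vectors, length >= 2, finite.
#' @param label_a,label_b optional subset labels.
#' @return data.frame row: `subset_a`, `subset_b`, `t`, `df`, `p_raw`,
#'   `degenerate`.
#' @export
welch_t <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  va <- stats::var(a); vb <- stats::var(b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    degenerate <- TRUE
    if (mean(a) == mean(b)) {
      tt <- 0; df <- length(a) + length(b) - 2; p <- 1
    } else {
      tt <- sign(mean(a) - mean(b)) * Inf
      df <- length(a) + length(b) - 2; p <- 0
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    tt <- unname(ht$statistic); df <- unname(ht$parameter)
    p <- unname(ht$p.value)
  }
  data.frame(subset_a = label_a, subset_b = label_b, t = tt, df = df,
             p_raw = p, degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Pairwise Welch tests between disparity replicate distributions
#'
#' Tests every requested unordered pair of subsets on their bootstrap
#' replicate vectors and applies the Bonferroni correction
#' `p_adjusted = min(1, p_raw * m_comparisons)`. Because the t-test sample
#' size is the number of bootstrap replicates, not the number of specimens,
#' these p-values are strongly anticonservative; results carry the label
#' `"bootstrap-replicate t-tests (anticonservative)"` and a percentile-
#' overlap alternative is available via [percentile_overlap()].
#'
#' @param results named list of `"disparity_boot"` objects (names are the
#'   subset labels; unnamed lists are labelled `group.time_slice`).
#' @param pairs `"all"` for every unordered pair, `"within-group"` for pairs
#'   sharing the same group label, or a two-column matrix/data.frame of
#'   subset labels.
#' @param correction only `"bonferroni"` is implemented.
#' @return data.frame with one row per pair: `subset_a`, `subset_b`, `t`,
#'   `df`, `p_raw`, `p_bonferroni`, `m_comparisons`; attribute `method` set
#'   to the anticonservatism label.
#' @export
pairwise_compare <- function(results, pairs = "all",
                             correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  stopifnot(is.list(results), length(results) >= 2)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- vapply(results, function(r)
      paste(r$group, r$time_slice, sep = "."), "")
  labs <- names(results)
  if (anyDuplicated(labs)) stop("duplicate subset labels")
  if (is.character(pairs) && length(pairs) == 1) {
    cmb <- t(utils::combn(labs, 2))
    if (pairs == "within-group") {
      grp <- vapply(results, function(r) r$group, "")
      names(grp) <- labs
      cmb <- cmb[grp[cmb[, 1]] == grp[cmb[, 2]], , drop = FALSE]
    } else if (pairs != "all") {
      stop("pairs must be 'all', 'within-group' or an explicit 2-column table")
    }
  } else {
    cmb <- as.matrix(pairs)
    if (ncol(cmb) != 2) stop("explicit pairs must have two columns")
    miss <- setdiff(unique(as.vector(cmb)), labs)
    if (length(miss)) stop("unknown subset label(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(cmb) == 0) stop("no comparison pairs selected")
  m <- nrow(cmb)
  rows <- lapply(seq_len(m), function(i) {
    welch_t(results[[cmb[i, 1]]]$replicates, results[[cmb[i, 2]]]$replicates,
            label_a = cmb[i, 1], label_b = cmb[i, 2])
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  out$m_comparisons <- m
  out$degenerate <- NULL
  attr(out, "method") <- "bootstrap-replicate t-tests (anticonservative)"
  out
}

#' Percentile-overlap comparison of two disparity distributions
#'
#' Conservative alternative to the replicate t-test: two subsets are called
#' distinguishable only when their central bootstrap percentile intervals do
#' not overlap.
#'
#' @param a,b `"disparity_boot"` objects or numeric replicate vectors.
#' @param level interval mass (default 0.95).
#' @return list with the two intervals and `overlap` (logical).
#' @export
percentile_overlap <- function(a, b, level = 0.95) {
  ra <- if (inherits(a, "disparity_boot")) a$replicates else as.numeric(a)
  rb <- if (inherits(b, "disparity_boot")) b$replicates else as.numeric(b)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qa <- stats::quantile(ra, pr, names = FALSE)
  qb <- stats::quantile(rb, pr, names = FALSE)
  list(interval_a = qa, interval_b = qb,
       overlap = qa[1] <= qb[2] && qb[1] <= qa[2])
}
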