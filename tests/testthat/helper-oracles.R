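# Independent oracles and fixture builders, kept deliberately separate from
# the implementation paths they check.

# Numerical Fourier-integral oracle: trapezoid (= rectangle, periodic) rule
# over a dense equal-arc-length sampling of the piecewise-linear closed
# curve. Independent of the segmentwise closed form used by compute_efd.
efd_oracle <- function(points, n_harmonics, n_samples = 1e4) {
  n <- nrow(points)
  closed <- rbind(points, points[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                         closed[-(n + 1), , drop = FALSE])^2))
  per <- sum(seg)
  s <- c(0, cumsum(seg))
  tt <- per * (seq_len(n_samples) - 1) / n_samples
  x <- stats::approx(s, closed[, 1], xout = tt, ties = "ordered")$y
  y <- stats::approx(s, closed[, 2], xout = tt, ties = "ordered")$y
  ph <- 2 * pi * tt / per
  coef <- t(vapply(seq_len(n_harmonics), function(k) {
    c(a = 2 * mean(x * cos(k * ph)), b = 2 * mean(x * sin(k * ph)),
      c = 2 * mean(y * cos(k * ph)), d = 2 * mean(y * sin(k * ph)))
  }, numeric(4)))
  list(coef = coef, dc = c(A0 = mean(x), C0 = mean(y)), perimeter = per)
}

# Direct evaluation of the Welch formula (oracle for welch_t / t.test path)
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Covariance-trace oracle for the sum-of-variances statistic
sov_oracle <- function(x) sum(diag(stats::cov(as.matrix(x))))

# Star-shaped random Fourier blob: guaranteed simple, smooth-ish
rand_blob <- function(seed, k = 200, n_modes = 6, amp = 0.12) {
  set.seed(seed)
  phi <- 2 * pi * (seq_len(k) - 1) / k
  r <- rep(1, k)
  for (m in 2:n_modes)
    r <- r + amp * runif(1, 0.2, 1) * cos(m * phi + runif(1, 0, 2 * pi))
  outline(cbind(r * cos(phi), r * sin(phi)), sprintf("blob%d", seed))
}

# Similarity transform + start-vertex relabeling of an outline's points
rigid_copy <- function(o, angle, scale, shift, start) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  P <- o$points %*% R * scale
  P <- sweep(P, 2, -shift)
  n <- nrow(P)
  start <- ((start - 1) %% n) + 1
  if (start > 1) P <- P[c(start:n, 1:(start - 1)), , drop = FALSE]
  outline(P, paste0(o$specimen_id, "_t"))
}

# Two-group, one-archetype design for noise-recovery experiments
two_group_design <- function(noise_a, noise_b, n_a, n_b, seed,
                             slice_a = "extant", slice_b = "extant") {
  arch <- function(nm) archetype(nm, stylet_curvature = 0.7,
                                 tooth_count = 2L, tooth_amplitude = 0.02)
  na <- structure(n_a, names = slice_a)
  nb <- structure(n_b, names = slice_b)
  sampling_design(list(
    list(archetype = arch("grpA"), noise_scale = noise_a, n = na),
    list(archetype = arch("grpB"), noise_scale = noise_b, n = nb)),
    root_seed = seed)
}

# One-group design spread over two time slices (rarefaction experiments)
two_slice_design <- function(noise, n_cret, n_ext, seed) {
  sampling_design(list(
    list(archetype = archetype("grp", stylet_curvature = 0.6),
         noise_scale = noise,
         n = c(cretaceous = n_cret, extant = n_ext))), root_seed = seed)
}

tmp_path <- function(name) {
  d <- tempfile("sty")
  dir.create(d)
  file.path(d, name)
}
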