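# Elliptic Fourier descriptors: closed forms, invariances, reconstruction.

test_that("circle harmonics match the closed-form series", {
  th <- 2 * pi * (0:511) / 512
  o <- outline(cbind(cos(th), sin(th)), "circ")
  e <- compute_efd(o, 20)
  expect_equal(unname(e$coef[1, ]), c(1, 0, 0, 1), tolerance = 1e-3)
  expect_lt(max(abs(e$coef[-1, ])), 1e-3)
  expect_equal(unname(e$dc), c(0, 0), tolerance = 1e-9)
  # normalized circle: (1, 0, 0, 1) at harmonic 1, zeros elsewhere
  ne <- normalize_efd(e)
  expect_equal(unname(ne$coef[1, ]), c(1, 0, 0, 1), tolerance = 1e-3)
  expect_lt(max(abs(ne$coef[-1, ])), 1e-3)
})

test_that("ellipse harmonics match the arc-length closed form", {
  # Under the chord/arc-length parameterization of EFA, a (2,1) ellipse is
  # not a single harmonic (that idealization holds for the elliptic-angle
  # parameterization); the exact series is computed by an independent dense
  # quadrature of the Fourier integrals.
  th <- 2 * pi * (0:2047) / 2048
  o <- outline(cbind(2 * cos(th), sin(th)), "ell")
  e <- compute_efd(o, 10)
  orc <- efd_oracle(o$points, 10, n_samples = 1e5)
  expect_equal(unname(e$coef), unname(orc$coef), tolerance = 1e-3)
  # idealized single-harmonic picture, at parameterization-level tolerance
  expect_equal(unname(e$coef[1, ]), c(2, 0, 0, 1), tolerance = 0.2)
  expect_true(all(abs(e$coef[2:10, ]) < 0.2))
  # b, c vanish exactly by symmetry
  expect_lt(max(abs(e$coef[, c("b", "c")])), 1e-12)
})

test_that("translation moves only the dc component; coefficients are linear in scale", {
  o <- rand_blob(11, 200)
  e <- compute_efd(o, 20)
  ot <- outline(sweep(o$points, 2, c(-10, 5)), "t")
  et <- compute_efd(ot, 20)
  expect_equal(et$coef, e$coef, tolerance = 1e-9)
  expect_equal(unname(et$dc - e$dc), c(10, -5), tolerance = 1e-9)
  e3 <- compute_efd(outline(o$points * 3, "s"), 20)
  expect_equal(e3$coef, 3 * e$coef, tolerance = 1e-9)
  expect_error(compute_efd(o, 0), "n_harmonics")
})

test_that("normalization standardizes the first harmonic and is invariant to similarity transforms", {
  set.seed(42)
  for (s in 1:3) {
    o <- render_archetype(
      archetype(sprintf("sh%d", s), stylet_curvature = 0.3 + 0.2 * s,
                head_exponent = 2 + 0.4 * s), 200)
    n0 <- normalize_efd(compute_efd(o, 20))
    expect_equal(unname(n0$coef[1, c("a", "b", "c")]), c(1, 0, 0),
                 tolerance = 1e-9)
    expect_lte(abs(n0$coef[1, "d"]), 1)
    for (r in 1:10) {
      oc <- rigid_copy(o, runif(1, 0, 2 * pi), runif(1, 0.3, 3),
                       runif(2, -10, 10), sample(nrow(o$points), 1))
      nc <- normalize_efd(compute_efd(oc, 20))
      expect_lt(max(abs(nc$coef - n0$coef)), 1e-6)
    }
    # size removal: 3x-scaled copy identical to 1e-9
    n3 <- normalize_efd(compute_efd(outline(o$points * 3, "x3"), 20))
    expect_equal(n3$coef, n0$coef, tolerance = 1e-9)
    # idempotence: re-normalizing changes nothing
    again <- normalize_efd(n0)
    expect_equal(again$coef, n0$coef, tolerance = 1e-9)
  }
})

test_that("mirroring negates the b and c coefficients; reflection alignment cancels chirality", {
  o <- render_archetype(archetype("chiral", stylet_curvature = 0.6), 200)
  om <- outline(cbind(-o$points[, 1], o$points[, 2]), "mir")
  n1 <- normalize_efd(compute_efd(o, 20))
  n2 <- normalize_efd(compute_efd(om, 20))
  refl <- n1$coef
  refl[, "b"] <- -refl[, "b"]; refl[, "c"] <- -refl[, "c"]
  expect_equal(n2$coef, refl, tolerance = 1e-6)
  expect_equal(n2$coef[1, "d"], n1$coef[1, "d"], tolerance = 1e-9)
  r1 <- normalize_efd(compute_efd(o, 20), allow_reflection = TRUE)
  r2 <- normalize_efd(compute_efd(om, 20), allow_reflection = TRUE)
  expect_equal(r1$coef, r2$coef, tolerance = 1e-6)
  expect_true(xor(r1$norm$reflected, r2$norm$reflected))
})

test_that("reconstruction inverts the transform and improves monotonically with harmonics", {
  # a pure one-harmonic descriptor reconstructs its ellipse exactly
  e <- structure(list(specimen_id = "ell", group = "", time_slice = "other",
                      n_harmonics = 1L,
                      coef = matrix(c(2, 0, 0, 1), 1, 4,
                                    dimnames = list(1, c("a", "b", "c", "d"))),
                      dc = c(A0 = 3, C0 = -2), perimeter = 2 * pi),
                 class = "efd")
  rec <- reconstruct(e, n_points = 360, harmonics_used = 1)
  tt <- 2 * pi * (0:359) / 360
  expect_lt(sqrt(mean((rec$points[, 1] - (3 + 2 * cos(tt)))^2 +
                        (rec$points[, 2] - (-2 + sin(tt)))^2)), 1e-6)

  o <- render_archetype(archetype("sty", stylet_curvature = 0.7,
                                  tooth_count = 3L, tooth_amplitude = 0.02),
                        400)
  ef <- compute_efd(o, 20)
  rms <- vapply(1:20, function(h) {
    r <- reconstruct(ef, n_points = 400, harmonics_used = h)
    sqrt(mean(rowSums((r$points - o$points)^2)))
  }, 0)
  expect_true(all(diff(rms) < 1e-9))  # truncation never helps
  # convergence: all-harmonic reconstruction close to the original
  efull <- compute_efd(o, 60)
  rfull <- reconstruct(efull, n_points = 2000)
  d <- function(A, B) {  # symmetric Hausdorff via cross point distances
    cd <- function(P, Q) max(vapply(seq_len(nrow(P)), function(i)
      min(sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2)), 0))
    max(cd(A, B), cd(B, A))
  }
  expect_lt(d(rfull$points, o$points), 0.01 * polygon_perimeter(o$points))
  expect_error(reconstruct(ef, 100, harmonics_used = 25), "1..20")
})

test_that("the feature matrix drops the normalization constants and keeps d1", {
  os <- lapply(1:3, function(i) rand_blob(i, 150))
  nefds <- lapply(os, function(o) normalize_efd(compute_efd(o, 20)))
  cm <- coefficient_matrix(nefds)
  expect_equal(dim(cm$x), c(3, 77))
  expect_equal(unname(cm$x[, 1]),
               vapply(nefds, function(e) unname(e$coef[1, "d"]), 0))
  # identical outlines give identical rows
  cm2 <- coefficient_matrix(list(nefds[[1]], nefds[[1]]))
  expect_equal(cm2$x[1, ], cm2$x[2, ])
  mixed <- list(nefds[[1]], normalize_efd(compute_efd(os[[2]], 10)))
  expect_error(coefficient_matrix(mixed), "mixed harmonic")
})
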