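# Synthetic head + stylet outline generator.

test_that("archetype bounds are enforced at construction", {
  expect_error(archetype("x", head_length = -1), "head_length")
  expect_error(archetype("x", head_exponent = 12), "head_exponent")
  expect_error(archetype("x", stylet_length = 3), "stylet_length")
  expect_error(archetype("x", stylet_curvature = 2), "stylet_curvature")
  expect_error(archetype("x", tooth_count = 2.5), "tooth_count")
  expect_error(archetype("x", tooth_amplitude = 0.2), "tooth_amplitude")
})

test_that("stylet-free archetypes degenerate to the bare head capsule", {
  # stylet_length = 0: pure superellipse
  a <- archetype("head", head_exponent = 3, stylet_length = 0)
  o <- render_archetype(a, 200)
  w <- a$head_width / 2; l <- a$head_length / 2
  resid <- abs((abs(o$points[, 1] / w))^3 + (abs(o$points[, 2] / l))^3 - 1)
  expect_lt(max(resid), 0.02)
  # circle limit: equal axes, exponent 2 -> first harmonic (1,0,0,1)
  circ <- render_archetype(archetype("circ", head_width = 1,
                                     head_exponent = 2, stylet_length = 0),
                           400)
  ne <- normalize_efd(compute_efd(circ, 10))
  expect_equal(unname(ne$coef[1, ]), c(1, 0, 0, 1), tolerance = 1e-3)
  expect_lt(max(abs(ne$coef[-1, ])), 1e-3)
})

test_that("every rendered and generated outline satisfies the pipeline invariants", {
  d <- default_study_design()
  for (g in d$groups) {
    o <- render_archetype(g$archetype, 200)
    expect_silent(validate_outline(o))
    expect_gt(signed_area(o$points), 0)
  }
  sim <- generate_dataset(two_group_design(0.06, 0.08, 6L, 6L, seed = 11), 150)
  for (o in sim$dataset$outlines) expect_silent(validate_outline(o))
  expect_equal(nrow(sim$ground_truth), 12)
  expect_true(all(c("stylet_curvature", "head_exponent", "seed") %in%
                    names(sim$ground_truth)))
})

test_that("a mirrored archetype yields the mirrored descriptor set", {
  a <- archetype("chir", stylet_curvature = 0.8, tooth_count = 3L,
                 tooth_amplitude = 0.025)
  am <- archetype("chir", stylet_curvature = -0.8, tooth_count = 3L,
                  tooth_amplitude = 0.025)
  n1 <- normalize_efd(compute_efd(render_archetype(a, 200), 20))
  n2 <- normalize_efd(compute_efd(render_archetype(am, 200), 20))
  refl <- n1$coef
  refl[, "b"] <- -refl[, "b"]; refl[, "c"] <- -refl[, "c"]
  expect_equal(n2$coef, refl, tolerance = 1e-6)
  # zero curvature and symmetric teeth: bilaterally symmetric shape
  sym <- normalize_efd(compute_efd(
    render_archetype(archetype("sym", stylet_curvature = 0), 200), 20))
  expect_lt(max(abs(sym$coef[, c("b", "c")])), 1e-6)
})

test_that("generation is deterministic in the root seed and records ground truth", {
  d <- two_group_design(0.05, 0.05, 5L, 5L, seed = 99)
  s1 <- generate_dataset(d, 120)
  s2 <- generate_dataset(d, 120)
  expect_identical(lapply(s1$dataset$outlines, `[[`, "points"),
                   lapply(s2$dataset$outlines, `[[`, "points"))
  expect_identical(s1$ground_truth, s2$ground_truth)
  d3 <- two_group_design(0.05, 0.05, 5L, 5L, seed = 100)
  s3 <- generate_dataset(d3, 120)
  expect_false(identical(s1$dataset$outlines[[1]]$points,
                         s3$dataset$outlines[[1]]$points))
})

test_that("zero noise collapses a subset to identical shapes with zero disparity", {
  d <- sampling_design(list(
    list(archetype = archetype("fixed", stylet_curvature = 0.5),
         noise_scale = 0, n = c(extant = 4L)),
    list(archetype = archetype("vary", stylet_curvature = 0.5),
         noise_scale = 0.05, n = c(extant = 6L))), root_seed = 3)
  sim <- generate_dataset(d, 120)
  pts <- lapply(sim$dataset$outlines[1:4], `[[`, "points")
  expect_equal(pts[[1]], pts[[2]])
  expect_equal(pts[[1]], pts[[4]])
  # both groups are single-slice, so no within-group time pairs exist
  fit <- suppressWarnings(
    disparity_analysis(sim$dataset, k = 120, n_boot = 100, seed = 5))
  sov_fixed <- fit$disparity_table$point_estimate[
    fit$disparity_table$group == "fixed"]
  expect_lt(sov_fixed, 1e-12)
})

test_that("excessive noise triggers the rejection-rate error", {
  d <- sampling_design(list(
    list(archetype = archetype("wild", stylet_length = 2.2,
                               stylet_base_width = 0.35,
                               stylet_curvature = 1.4),
         noise_scale = 0.9, n = c(extant = 4L))), root_seed = 1)
  expect_error(generate_dataset(d, 100), "noise_scale")
})

test_that("disparity rises monotonically with the generative noise scale", {
  mean_sov <- vapply(c(0.01, 0.02, 0.04, 0.08), function(ns) {
    sovs <- vapply(1:3, function(s) {
      sim <- generate_dataset(sampling_design(list(
        list(archetype = archetype("g", stylet_curvature = 0.6),
             noise_scale = ns, n = c(extant = 12L))),
        root_seed = 600 + s), 100)
      m <- fit_morphospace(efa_dataset(sim$dataset, 20, 100))
      sum_of_variances(m$scores)
    }, 0)
    mean(sovs)
  }, 0)
  expect_true(all(diff(mean_sov) > 0))
})

test_that("the default design reproduces the documented sampling record", {
  d <- default_study_design()
  per_slice <- sapply(TIME_SLICES[1:4], function(s)
    sum(vapply(d$groups, function(g)
      if (s %in% names(g$n)) as.integer(g$n[[s]]) else 0L, 0L)))
  expect_equal(unname(per_slice), c(230L, 34L, 12L, 787L))
  expect_equal(sum(per_slice), 1063L)
  # extinction structure: some groups Cretaceous-only, one extant-only,
  # and persistent groups spanning both ends of the record
  spans <- vapply(d$groups, function(g) paste(sort(names(g$n)[g$n > 0]),
                                              collapse = "+"), "")
  expect_true(any(spans == "cretaceous"))
  expect_true(any(spans == "extant"))
  expect_true(any(grepl("cretaceous", spans) & grepl("extant", spans)))
})
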