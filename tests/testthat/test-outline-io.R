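# Readers, writers, validation and resampling of closed outlines.

write_lines <- function(lines, path) writeLines(lines, path)

test_that("TPS reader parses records, reorients clockwise outlines, joins labels", {
  path <- tmp_path("mini.tps")
  # sp1: CCW square; sp2: CW square (negative shoelace area), must be flipped
  write_lines(c(
    "LM=0", "CURVES=1", "POINTS=4",
    "0 0", "1 0", "1 1", "0 1", "IMAGE=ignored.jpg", "ID=sp1",
    "LM=0", "CURVES=1", "POINTS=4",
    "0 0", "0 1", "1 1", "1 0", "SCALE=0.5", "ID=sp2"), path)
  labels <- data.frame(specimen_id = c("sp1", "sp2"),
                       group = c("gA", "gB"),
                       time_slice = c("extant", "cretaceous"))
  ds <- read_tps(path, labels = labels)
  expect_s3_class(ds, "outline_set")
  expect_length(ds, 2)
  expect_equal(nrow(ds$outlines$sp1$points), 4)
  expect_equal(ds$outlines$sp2$group, "gB")
  expect_equal(ds$outlines$sp2$time_slice, "cretaceous")
  # shoelace oracle: both stored counterclockwise
  expect_gt(signed_area(ds$outlines$sp1$points), 0)
  expect_gt(signed_area(ds$outlines$sp2$points), 0)
  # start point kept on reorientation
  expect_equal(ds$outlines$sp2$points[1, ], c(x = 0, y = 0))
  expect_match(ds$provenance[2], "reoriented=TRUE")
  expect_match(ds$provenance[1], "reoriented=FALSE")

  # declared/actual point-count mismatch
  bad <- tmp_path("bad.tps")
  write_lines(c("LM=0", "CURVES=1", "POINTS=100",
                sprintf("%d %d", 0:98, 1:99), "ID=sp1"), bad)
  expect_error(read_tps(bad), "POINTS=100")

  # missing label when labels are required
  expect_error(read_tps(path, labels = labels[1, ]), "no label .*sp2")
})

test_that("Freeman chain codes decode to lattice outlines and enforce closure", {
  path <- tmp_path("chains.txt")
  writeLines("sq 0 0 0 2 4 6 -1", path)
  ds <- read_chaincode(path)
  # hand-decoded: 0=+x, 2=+y, 4=-x, 6=-y from (0,0) -> unit square
  expect_equal(unname(ds$outlines$sq$points),
               matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE))
  expect_gt(signed_area(ds$outlines$sq$points), 0)

  writeLines("bad 0 0 0 9 4 6 -1", path)
  expect_error(read_chaincode(path), "outside 0-7")
  writeLines("open 0 0 0 2 4 -1", path)
  expect_error(read_chaincode(path), "open chain")
  writeLines("noterm 0 0 0 2 4 6", path)
  expect_error(read_chaincode(path), "terminated")
})

test_that("outline validation rejects degenerate and self-intersecting polygons", {
  bowtie <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1), 4, 2, byrow = TRUE)
  expect_error(outline(bowtie, "x"), "not simple")
  expect_error(outline(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), "x"),
               "fewer than")
  expect_error(outline(matrix(c(0, 0, 0, 0, 1, 0, 1, 1), 4, 2, byrow = TRUE),
                       "x"), "repeated consecutive")
  # strict pipeline validation needs 8 distinct points
  sq <- outline(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE), "sq")
  expect_error(validate_outline(sq), "fewer than 8")
  expect_silent(validate_outline(resample_outline(sq, 16)))
  # reorientation idempotence: an already-CCW outline is unchanged
  o2 <- outline(sq$points, "sq")
  expect_identical(o2$points, sq$points)
  expect_false(attr(o2, "reoriented"))
})

test_that("resampling spaces points by arc length and preserves geometry", {
  sq <- outline(matrix(c(0, 0, 2, 0, 2, 2, 0, 2), 4, 2, byrow = TRUE), "sq")
  r4 <- resample_outline(sq, 4)
  expect_equal(r4$points, sq$points)  # quarter-perimeter marks = corners

  th <- 2 * pi * (0:999) / 1000
  circ <- outline(cbind(cos(th), sin(th)), "circ")
  r <- resample_outline(circ, 100)
  expect_true(all(abs(sqrt(rowSums(r$points^2)) - 1) < 1e-3))

  for (s in 1:3) {
    o <- rand_blob(s, k = 400)
    p0 <- polygon_perimeter(o$points)
    expect_lt(abs(polygon_perimeter(resample_outline(o, 200)$points) - p0) / p0,
              0.01)
    # scale equivariance
    o2 <- outline(o$points * 2, "x2")
    expect_equal(resample_outline(o2, 64)$points,
                 2 * resample_outline(o, 64)$points, tolerance = 1e-9)
  }

  degenerate <- outline(matrix(c(0, 0, 0, 0, 0, 0), 3, 2, byrow = TRUE),
                        "pt", validate = FALSE)
  expect_error(resample_outline(degenerate, 8), "zero perimeter")
  expect_error(resample_outline(sq, 2), "at least 3")
})

test_that("TPS round-trip reproduces coordinates to 6 decimals and labels exactly", {
  ds <- outline_set(lapply(1:3, function(i) {
    o <- rand_blob(i, k = 50)
    outline(o$points * 3.7 + i, sprintf("sp%d", i), group = "gA",
            time_slice = "eocene")
  }))
  path <- tmp_path("rt.tps")
  lab <- tmp_path("rt_labels.csv")
  write_tps(ds, path, labels_path = lab)
  back <- read_tps(path, labels = lab)
  expect_equal(names(back$outlines), names(ds$outlines))
  for (id in names(ds$outlines)) {
    expect_equal(back$outlines[[id]]$points, ds$outlines[[id]]$points,
                 tolerance = 1e-6)
    expect_identical(back$outlines[[id]]$group, "gA")
    expect_identical(back$outlines[[id]]$time_slice, "eocene")
  }
})

test_that("coefficient tables have the contracted shape and round-trip", {
  ds <- outline_set(lapply(1:2, function(i)
    outline(rand_blob(i, 120)$points, sprintf("sp%d", i), group = "g",
            time_slice = "extant")))
  cm <- efa_dataset(ds, n_harmonics = 20, k = 120)
  expect_equal(dim(cm$x), c(2, 77))  # 4*20 - 3
  expect_identical(colnames(cm$x)[1:5], c("d1", "a2", "b2", "c2", "d2"))

  path <- tmp_path("coef.csv")
  write_coeff_table(cm, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_length(hdr, 3 + 80 - 3)
  back <- read_coeff_table(path)
  expect_equal(back$x, cm$x, tolerance = 1e-11)  # 12 significant digits
  expect_identical(back$meta, cm$meta)
  # bit-stable writes
  path2 <- tmp_path("coef2.csv")
  write_coeff_table(cm, path2)
  expect_identical(readLines(path), readLines(path2))

  # empty matrix -> header-only CSV
  empty <- cm
  empty$x <- cm$x[0, , drop = FALSE]
  empty$meta <- cm$meta[0, ]
  p3 <- tmp_path("empty.csv")
  write_coeff_table(empty, p3)
  expect_length(readLines(p3), 1)

  dup <- cm
  dup$meta$specimen_id <- c("sp1", "sp1")
  expect_error(write_coeff_table(dup, tmp_path("dup.csv")), "duplicate")
})
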