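# Full-analysis orchestration: the disparity_analysis() model object, the
# file-writing pipeline around it, and the figure builder.

#' Fit the full outline-disparity analysis
#'
#' The package's central fitting function. Runs, in order: group exclusion,
#' arc-length resampling, elliptic Fourier analysis, first-harmonic
#' normalization, covariance PCA, per-PC group/time ranges, bootstrap +
#' rarefaction disparity per group x time-slice subset, and pairwise Welch
#' t-tests on the replicate distributions with Bonferroni correction.
#'
#' @param dataset an [outline_set()] whose specimens carry group and
#'   time-slice labels.
#' @param n_harmonics harmonics per specimen (default 20).
#' @param k arc-length resampling density (default 200).
#' @param allow_reflection passed to [normalize_efd()].
#' @param n_boot bootstrap replicates per subset (default 10000).
#' @param rarefaction `"smaller-group"` (default: within each group, every
#'   time-slice subset is resampled at the size of that group's smallest
#'   eligible subset), a fixed integer size, or `"none"`.
#' @param seed root seed; each subset's bootstrap seed is derived
#'   deterministically from it (see [derive_seed()]).
#' @param exclude_groups group labels dropped before any analysis (the PCA is
#'   fit after exclusion).
#' @param comparisons `"within-group"` (default: time-slice pairs within each
#'   group), `"all"`, or an explicit two-column table of subset labels
#'   (`group.time_slice`).
#' @param min_subset_n subsets smaller than this are skipped with a warning,
#'   not an error (default 2).
#' @return object of class `"disparity_analysis"` with components `meta`,
#'   `features` (the `coef_matrix`), `morphospace`, `ranges`, `disparity`
#'   (named list of `disparity_boot`), `disparity_table`, `tests`, `skipped`
#'   and `call` parameters; see the print/summary/plot methods.
#' @export
disparity_analysis <- function(dataset, n_harmonics = 20L, k = 200L,
                               allow_reflection = FALSE, n_boot = 10000L,
                               rarefaction = "smaller-group", seed = 1L,
                               exclude_groups = character(),
                               comparisons = "within-group",
                               min_subset_n = 2L) {
  stopifnot(inherits(dataset, "outline_set"))
  ds <- filter_groups(dataset, exclude_groups)
  meta0 <- dataset_meta(ds)
  if (any(!nzchar(meta0$group)) || any(!nzchar(meta0$time_slice)))
    stop("every specimen needs a non-empty group and time_slice label")
  features <- efa_dataset(ds, n_harmonics = n_harmonics, k = k,
                          allow_reflection = allow_reflection)
  model <- fit_morphospace(features)
  ranges <- pc_ranges(model)
  meta <- model$meta
  # subsets in deterministic order: group (design order), then time slice
  meta$subset <- paste(meta$group, meta$time_slice, sep = ".")
  subsets <- unique(meta$subset)
  counts <- table(meta$subset)[subsets]
  eligible <- subsets[counts >= max(2L, min_subset_n)]
  skipped <- setdiff(subsets, eligible)
  if (length(skipped))
    warning("skipping subset(s) with n < ", max(2L, min_subset_n), ": ",
            paste(skipped, collapse = ", "))
  if (length(eligible) == 0) stop("no subset large enough for disparity")
  raref_m <- function(lab) {
    if (identical(rarefaction, "none")) return(NULL)
    if (is.numeric(rarefaction)) {
      n_here <- sum(meta$subset == lab)
      return(min(as.integer(rarefaction), n_here))
    }
    g <- meta$group[match(lab, meta$subset)]
    elig_group <- meta$group[match(eligible, meta$subset)]
    min(counts[eligible[elig_group == g]])
  }
  disparity <- lapply(eligible, function(lab) {
    sel <- meta$subset == lab
    g <- meta$group[sel][1]; s <- meta$time_slice[sel][1]
    bootstrap_disparity(model$scores[sel, , drop = FALSE], n_boot = n_boot,
                        m = raref_m(lab), seed = derive_seed(seed, g, s),
                        group = g, time_slice = s)
  })
  names(disparity) <- eligible
  dtab <- do.call(rbind, lapply(disparity, function(d) {
    q <- stats::quantile(d$replicates, c(0.025, 0.975), names = FALSE)
    data.frame(group = d$group, time_slice = d$time_slice, n = d$n, m = d$m,
               n_boot = d$n_boot, seed = d$seed,
               point_estimate = d$point_estimate,
               boot_mean = mean(d$replicates),
               boot_sd = stats::sd(d$replicates),
               boot_q2.5 = q[1], boot_q97.5 = q[2],
               stringsAsFactors = FALSE)
  }))
  rownames(dtab) <- NULL
  tests <- NULL
  can_pair <- length(disparity) >= 2
  if (can_pair) {
    tests <- tryCatch(
      pairwise_compare(disparity, pairs = comparisons),
      error = function(e) {
        warning("no pairwise tests: ", conditionMessage(e))
        NULL
      })
  }
  structure(list(
    meta = meta, features = features, morphospace = model, ranges = ranges,
    disparity = disparity, disparity_table = dtab, tests = tests,
    skipped = skipped,
    params = list(n_harmonics = n_harmonics, k = k,
                  allow_reflection = allow_reflection, n_boot = n_boot,
                  rarefaction = rarefaction, seed = seed,
                  exclude_groups = exclude_groups,
                  comparisons = comparisons)),
    class = "disparity_analysis")
}

#' @export
print.disparity_analysis <- function(x, ...) {
  cat("Outline disparity analysis\n")
  cat(sprintf("  %d specimens, %d harmonics, %d retained PCs\n",
              nrow(x$meta), x$params$n_harmonics,
              length(x$morphospace$eigenvalues)))
  cat(sprintf("  %d group x time subsets (bootstrap n=%d, rarefaction: %s)\n",
              length(x$disparity), x$params$n_boot,
              paste(x$params$rarefaction, collapse = "")))
  if (!is.null(x$tests))
    cat(sprintf("  %d pairwise tests [%s]\n", nrow(x$tests),
                attr(x$tests, "method")))
  invisible(x)
}

#' @export
summary.disparity_analysis <- function(object, ...) {
  structure(list(disparity = object$disparity_table, tests = object$tests,
                 var_explained = object$morphospace$var_explained,
                 skipped = object$skipped, params = object$params),
            class = "summary.disparity_analysis")
}

#' @export
print.summary.disparity_analysis <- function(x, ...) {
  cat("Sum-of-variances disparity (bootstrap", x$params$n_boot,
      "replicates, rarefied):\n")
  print(x$disparity, digits = 4, row.names = FALSE)
  if (length(x$skipped))
    cat("Skipped (n too small):", paste(x$skipped, collapse = ", "), "\n")
  if (!is.null(x$tests)) {
    cat("\nPairwise comparisons --", attr(x$tests, "method"), ":\n")
    print(x$tests, digits = 4, row.names = FALSE)
  }
  cat(sprintf("\nMorphospace: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$var_explained[1],
              if (length(x$var_explained) > 1) 100 * x$var_explained[2] else 0))
  invisible(x)
}

#' Scores, loadings and disparity accessors
#'
#' `scores()` returns the morphospace score matrix with metadata columns.
#' @param x a `"disparity_analysis"`.
#' @return data.frame of specimen metadata and PC scores.
#' @export
scores <- function(x) {
  stopifnot(inherits(x, "disparity_analysis"))
  cbind(x$meta[, c("specimen_id", "group", "time_slice")],
        as.data.frame(x$morphospace$scores, row.names = FALSE))
}

#' Project new outlines into a fitted analysis' morphospace
#'
#' @param object a `"disparity_analysis"`.
#' @param newdata an [outline_set()] (processed with the fit's parameters) or
#'   a feature matrix.
#' @param ... unused.
#' @return score matrix.
#' @export
predict.disparity_analysis <- function(object, newdata, ...) {
  if (inherits(newdata, "outline_set"))
    newdata <- efa_dataset(newdata, n_harmonics = object$params$n_harmonics,
                           k = object$params$k,
                           allow_reflection = object$params$allow_reflection)
  predict(object$morphospace, newdata)
}

#' Plot method for disparity analyses
#'
#' `type = "morphospace"`: PC scatter (default PC1 vs PC2) colored by group,
#' one panel per time slice. `type = "disparity"`: per-subset box summaries
#' of the bootstrap sum-of-variances distributions. `type = "ranges"`:
#' per-PC occupied score ranges as horizontal bars.
#'
#' @param x a `"disparity_analysis"`.
#' @param type one of `"morphospace"`, `"disparity"`, `"ranges"`.
#' @param pcs length-2 PC index vector for the scatter (default c(1, 2)).
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.disparity_analysis <- function(x, type = c("morphospace", "disparity",
                                                "ranges"),
                                    pcs = c(1, 2), ...) {
  type <- match.arg(type)
  meta <- x$meta
  groups <- unique(meta$group)
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")[
    seq_along(groups)]
  names(cols) <- groups
  if (type == "morphospace") {
    slices <- intersect(TIME_SLICES, unique(meta$time_slice))
    sc <- x$morphospace$scores
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(slices)),
                         mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    ve <- x$morphospace$var_explained
    for (s in slices) {
      sel <- meta$time_slice == s
      graphics::plot(sc[, pcs[1]], sc[, pcs[2]], type = "n",
                     xlab = sprintf("PC%d (%.1f%%)", pcs[1], 100 * ve[pcs[1]]),
                     ylab = sprintf("PC%d (%.1f%%)", pcs[2], 100 * ve[pcs[2]]),
                     main = s)
      graphics::points(sc[sel, pcs[1]], sc[sel, pcs[2]], pch = 19, cex = 0.6,
                       col = cols[meta$group[sel]])
    }
  } else if (type == "disparity") {
    reps <- lapply(x$disparity, function(d) d$replicates)
    graphics::boxplot(reps, las = 2, cex.axis = 0.7,
                      ylab = "sum of variances (bootstrap, rarefied)",
                      col = cols[vapply(x$disparity, function(d) d$group, "")],
                      main = "Disparity per group x time subset")
  } else {
    rg <- x$ranges[x$ranges$n > 0 & x$ranges$pc <= 4, ]
    lab <- sprintf("%s.%s PC%d", rg$group, rg$time_slice, rg$pc)
    old <- graphics::par(mar = c(4, 10, 2, 1))
    on.exit(graphics::par(old))
    graphics::plot(NA, xlim = range(c(rg$min, rg$max)),
                   ylim = c(0, nrow(rg) + 1), yaxt = "n", xlab = "PC score",
                   ylab = "", main = "Occupied per-PC ranges")
    graphics::segments(rg$min, seq_len(nrow(rg)), rg$max, seq_len(nrow(rg)),
                       lwd = 3, col = cols[rg$group])
    graphics::axis(2, at = seq_len(nrow(rg)), labels = lab, las = 2,
                   cex.axis = 0.6)
  }
  invisible(x)
}

# ---- configuration ---------------------------------------------------------

#' Build a pipeline configuration
#'
#' Mirrors the tunable parameters of [disparity_analysis()] plus input/output
#' plumbing. Either `input_tps` (+ optional `input_labels`) or a simulate
#' design must be given; `design = "default"` uses [default_study_design()].
#'
#' @param input_tps optional TPS outline file.
#' @param input_labels optional label sidecar CSV for `input_tps`.
#' @param design `"default"`, a [sampling_design()], or `NULL` when reading
#'   files.
#' @param exclude_groups group labels excluded before analysis.
#' @param n_harmonics,resample_k,allow_reflection,n_boot,rarefaction,seed,comparisons,alpha
#'   analysis parameters (defaults: 20, 200, FALSE, 10000, "smaller-group",
#'   1, "within-group", 0.05).
#' @param output_dir directory for the report bundle.
#' @return object of class `"pipeline_config"` (a validated list).
#' @export
pipeline_config <- function(input_tps = NULL, input_labels = NULL,
                            design = "default",
                            exclude_groups = character(),
                            n_harmonics = 20L, resample_k = 200L,
                            allow_reflection = FALSE, n_boot = 10000L,
                            rarefaction = "smaller-group", seed = 1L,
                            comparisons = "within-group", alpha = 0.05,
                            output_dir = "stylospace_out") {
  if (is.null(input_tps) && is.null(design))
    stop("config needs either input_tps or a simulate design")
  if (!is.null(design) && !identical(design, "default") &&
      !inherits(design, "sampling_design"))
    stop("design must be \"default\" or a sampling_design object")
  structure(list(
    input_tps = input_tps, input_labels = input_labels, design = design,
    exclude_groups = exclude_groups, n_harmonics = as.integer(n_harmonics),
    resample_k = as.integer(resample_k),
    allow_reflection = isTRUE(allow_reflection), n_boot = as.integer(n_boot),
    rarefaction = rarefaction, seed = as.integer(seed),
    comparisons = comparisons, alpha = alpha, output_dir = output_dir),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Field names mirror [pipeline_config()] exactly; a config round-trips
#' losslessly (a `sampling_design` object cannot be serialized and must be
#' `"default"` or rebuilt in R).
#'
#' @param path YAML file path.
#' @return for `read_config`, a `"pipeline_config"`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_config
#' @param config a `"pipeline_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(config$design, "sampling_design"))
    stop("cannot serialize a sampling_design; use design = \"default\"")
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

# byte-stable CSV writer: fixed column order, %.12g floats, no quoting
write_csv_stable <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.12g", df[[j]])
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline and write the report bundle
#'
#' Ingests (or simulates) the dataset, applies the group exclusion, fits
#' [disparity_analysis()] and writes, in order: dataset manifest, coefficient
#' CSV, scores CSV + morphospace JSON, per-PC range table, disparity table,
#' pairwise-test table, and a run manifest with seeds, parameters and
#' per-stage record counts. Output is deterministic: identical config and
#' seed give byte-identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @return the fitted `"disparity_analysis"`, invisibly, with the output
#'   paths in attribute `"paths"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$input_tps)) {
    ds <- read_tps(config$input_tps, labels = config$input_labels)
    gt <- NULL
  } else {
    design <- if (identical(config$design, "default"))
      default_study_design() else config$design
    design$root_seed <- config$seed  # the run seed governs all randomness
    sim <- generate_dataset(design, k_points = config$resample_k)
    ds <- sim$dataset
    gt <- sim$ground_truth
  }
  n_ingested <- length(ds)
  ds <- filter_groups(ds, config$exclude_groups)
  fit <- disparity_analysis(
    ds, n_harmonics = config$n_harmonics, k = config$resample_k,
    allow_reflection = config$allow_reflection, n_boot = config$n_boot,
    rarefaction = config$rarefaction, seed = config$seed,
    comparisons = config$comparisons)
  paths <- c(manifest = file.path(out, "dataset_manifest.csv"),
             coefficients = file.path(out, "coefficients.csv"),
             scores = file.path(out, "scores.csv"),
             model = file.path(out, "morphospace_model.json"),
             ranges = file.path(out, "pc_ranges.csv"),
             disparity = file.path(out, "disparity.csv"),
             tests = file.path(out, "tests.csv"),
             run = file.path(out, "run_manifest.json"))
  write_csv_stable(dataset_meta(ds), paths["manifest"])
  if (!is.null(gt))
    write_csv_stable(gt, file.path(out, "ground_truth.csv"))
  write_coeff_table(fit$features, paths["coefficients"])
  write_csv_stable(scores(fit), paths["scores"])
  ms <- fit$morphospace
  jsonlite::write_json(
    list(center = unname(ms$center), loadings = unname(ms$loadings),
         eigenvalues = ms$eigenvalues, var_explained = ms$var_explained),
    paths["model"], digits = NA, auto_unbox = TRUE)
  write_csv_stable(fit$ranges, paths["ranges"])
  write_csv_stable(fit$disparity_table, paths["disparity"])
  if (!is.null(fit$tests)) {
    tst <- fit$tests
    tst$method <- attr(fit$tests, "method")
    write_csv_stable(tst, paths["tests"])
  }
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("stylospace")),
    seed = config$seed,
    params = fit$params,
    test_method = if (!is.null(fit$tests)) attr(fit$tests, "method") else NULL,
    alpha = config$alpha,
    counts = list(ingested = n_ingested, analysed = length(ds),
                  excluded = n_ingested - length(ds),
                  coefficients = nrow(fit$features$x),
                  scores = nrow(ms$scores),
                  subsets = length(fit$disparity),
                  skipped_subsets = fit$skipped,
                  tests = if (is.null(fit$tests)) 0L else nrow(fit$tests))),
    paths["run"], digits = NA, auto_unbox = TRUE, null = "null")
  attr(fit, "paths") <- paths
  invisible(fit)
}

#' Write the standard figures for a fitted analysis
#'
#' PC1-PC2 and PC1-PC3 scatterplots faceted by time slice, bootstrap
#' disparity boxes, and per-PC range bars, as PDF files with deterministic
#' names.
#'
#' @param fit a `"disparity_analysis"` (e.g. from [run_pipeline()]).
#' @param dir output directory.
#' @return character vector of the files written.
#' @export
make_figures <- function(fit, dir = ".") {
  stopifnot(inherits(fit, "disparity_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name, expr) {
    f <- file.path(dir, name)
    grDevices::pdf(f, width = 8, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    files <<- c(files, f)
  }
  emit("morphospace_pc1_pc2.pdf", plot(fit, "morphospace", pcs = c(1, 2)))
  if (length(fit$morphospace$eigenvalues) >= 3)
    emit("morphospace_pc1_pc3.pdf", plot(fit, "morphospace", pcs = c(1, 3)))
  emit("disparity_boxes.pdf", plot(fit, "disparity"))
  emit("pc_ranges.pdf", plot(fit, "ranges"))
  files
}
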