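#' @keywords internal
"_PACKAGE"

#' Recognised time slices
#'
#' The four sampled intervals of the amber record plus the modern fauna,
#' with `"other"` for unassigned material.
#' @export
TIME_SLICES <- c("cretaceous", "eocene", "miocene", "extant", "other")

# ---- geometry helpers -------------------------------------------------------

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counterclockwise orientation under the mathematical y-up
#' convention used throughout the package.
#'
#' @param points two-column numeric matrix of vertices (closing edge implicit).
#' @return signed area (numeric scalar).
#' @export
signed_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#' @param points two-column numeric matrix of vertices.
#' @return total edge length including the closing edge.
#' @export
polygon_perimeter <- function(points) {
  d <- points[c(seq_len(nrow(points))[-1], 1), , drop = FALSE] - points
  sum(sqrt(rowSums(d^2)))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' All pairs of non-adjacent edges are tested for crossing; collinear
#' overlap of non-adjacent edges also counts as a self-intersection.
#'
#' @param points two-column numeric matrix of vertices.
#' @return logical scalar.
#' @export
is_simple_polygon <- function(points) {
  n <- nrow(points)
  if (n < 3) return(FALSE)
  idx <- seq_len(n)
  a1 <- points
  a2 <- points[c(idx[-1], 1), , drop = FALSE]
  # pair indices of non-adjacent edges
  pr <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- pr[, 2] - pr[, 1] > 1 & !(pr[, 1] == 1 & pr[, 2] == n)
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) == 0) return(TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  px <- a1[i, 1]; py <- a1[i, 2]; qx <- a2[i, 1]; qy <- a2[i, 2]
  rx <- a1[j, 1]; ry <- a1[j, 2]; sx <- a2[j, 1]; sy <- a2[j, 2]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  scale <- max(abs(points)) + 1
  eps <- 1e-12 * scale^2
  d1 <- cross(rx, ry, sx, sy, px, py)
  d2 <- cross(rx, ry, sx, sy, qx, qy)
  d3 <- cross(px, py, qx, qy, rx, ry)
  d4 <- cross(px, py, qx, qy, sx, sy)
  proper <- (d1 * d2 < -eps) & (d3 * d4 < -eps)
  if (any(proper)) return(FALSE)
  # degenerate contacts: an endpoint of one edge lying on the other edge
  on_seg <- function(d, ox, oy, ax, ay, bx, by) {
    abs(d) <= eps &
      ox >= pmin(ax, bx) - eps & ox <= pmax(ax, bx) + eps &
      oy >= pmin(ay, by) - eps & oy <= pmax(ay, by) + eps
  }
  touch <- on_seg(d1, px, py, rx, ry, sx, sy) | on_seg(d2, qx, qy, rx, ry, sx, sy) |
    on_seg(d3, rx, ry, px, py, qx, qy) | on_seg(d4, sx, sy, px, py, qx, qy)
  !any(touch)
}

# ---- outline ---------------------------------------------------------------

#' Construct a specimen outline
#'
#' An outline is an ordered, closed sequence of planar points (the last point
#' connects back to the first) together with a specimen id, a group label and
#' a time slice. Outlines are stored counterclockwise; clockwise input is
#' reoriented and the fact recorded in the `reoriented` attribute.
#'
#' @param points two-column numeric matrix (or data.frame) of x,y vertices.
#' @param specimen_id character scalar, unique within a dataset.
#' @param group group label (e.g. `"owllions"`); may be `""` until labels are
#'   joined.
#' @param time_slice one of [TIME_SLICES].
#' @param validate if `TRUE`, enforce the structural invariants (at least
#'   `min_points` distinct vertices, no repeated consecutive vertices, simple
#'   polygon). Validation failure is an error, never a silent repair.
#' @param min_points minimum number of vertices accepted (default 3; the
#'   analysis pipeline itself resamples to far denser outlines).
#' @return an object of class `"outline"`.
#' @export
outline <- function(points, specimen_id = "unnamed", group = "",
                    time_slice = "other", validate = TRUE, min_points = 3L) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || !is.numeric(points))
    stop("`points` must be a two-column numeric matrix")
  colnames(points) <- c("x", "y")
  if (!time_slice %in% TIME_SLICES)
    stop("unknown time_slice '", time_slice, "'; expected one of: ",
         paste(TIME_SLICES, collapse = ", "))
  # drop an explicit closing vertex if present
  n <- nrow(points)
  if (n > 1 && all(points[1, ] == points[n, ])) points <- points[-n, , drop = FALSE]
  reoriented <- FALSE
  if (validate) {
    n <- nrow(points)
    if (n < min_points)
      stop("outline '", specimen_id, "': fewer than ", min_points, " points")
    if (!all(is.finite(points)))
      stop("outline '", specimen_id, "': non-finite coordinates")
    same <- rowSums((points - points[c(2:n, 1), , drop = FALSE])^2) == 0
    if (any(same))
      stop("outline '", specimen_id, "': repeated consecutive points")
    if (nrow(unique(points)) < min_points)
      stop("outline '", specimen_id, "': fewer than ", min_points,
           " distinct points")
    if (!is_simple_polygon(points))
      stop("outline '", specimen_id, "': polygon is not simple ",
           "(self-intersecting)")
    if (signed_area(points) < 0) {
      points <- points[rev(seq_len(n)), , drop = FALSE]
      points <- points[c(n, seq_len(n - 1)), , drop = FALSE]  # keep start point
      reoriented <- TRUE
    }
  }
  structure(
    list(specimen_id = as.character(specimen_id), points = points,
         group = as.character(group), time_slice = time_slice),
    reoriented = reoriented, class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %s  [%d pts, group=%s, slice=%s, perim=%.4g]\n",
              x$specimen_id, nrow(x$points),
              if (nzchar(x$group)) x$group else "?", x$time_slice,
              polygon_perimeter(x$points)))
  invisible(x)
}

#' Strict outline validation for the analysis pipeline
#'
#' Checks the pipeline-entry invariants: at least `min_points` distinct
#' vertices, simple polygon, counterclockwise orientation.
#'
#' @param o an [outline()].
#' @param min_points minimum distinct vertices (default 8).
#' @return `o`, invisibly; errors on violation.
#' @export
validate_outline <- function(o, min_points = 8L) {
  stopifnot(inherits(o, "outline"))
  n <- nrow(o$points)
  if (nrow(unique(o$points)) < min_points)
    stop("outline '", o$specimen_id, "': fewer than ", min_points,
         " distinct points")
  same <- rowSums((o$points - o$points[c(2:n, 1), , drop = FALSE])^2) == 0
  if (any(same)) stop("outline '", o$specimen_id, "': repeated consecutive points")
  if (!is_simple_polygon(o$points))
    stop("outline '", o$specimen_id, "': polygon is not simple")
  if (signed_area(o$points) < 0)
    stop("outline '", o$specimen_id, "': clockwise orientation")
  invisible(o)
}

# ---- dataset ---------------------------------------------------------------

#' Construct a dataset of outlines
#'
#' @param outlines list of [outline()] objects with unique specimen ids.
#' @param provenance character vector of free-text provenance, one per
#'   outline (recycled if length 1).
#' @return an object of class `"outline_set"`.
#' @export
outline_set <- function(outlines, provenance = "") {
  stopifnot(is.list(outlines), all(vapply(outlines, inherits, TRUE, "outline")))
  ids <- vapply(outlines, function(o) o$specimen_id, "")
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  provenance <- rep_len(as.character(provenance), length(outlines))
  names(outlines) <- ids
  structure(list(outlines = outlines, provenance = provenance),
            class = "outline_set")
}

#' @export
length.outline_set <- function(x) length(x$outlines)

#' @export
print.outline_set <- function(x, ...) {
  m <- dataset_meta(x)
  cat(sprintf("<outline_set> %d specimens, %d groups, %d time slices\n",
              nrow(m), length(unique(m$group[nzchar(m$group)])),
              length(unique(m$time_slice))))
  invisible(x)
}

#' Specimen metadata of a dataset
#'
#' @param ds an [outline_set()].
#' @return data.frame with columns `specimen_id`, `group`, `time_slice`,
#'   `n_points`, `provenance`.
#' @export
dataset_meta <- function(ds) {
  stopifnot(inherits(ds, "outline_set"))
  data.frame(
    specimen_id = vapply(ds$outlines, function(o) o$specimen_id, ""),
    group = vapply(ds$outlines, function(o) o$group, ""),
    time_slice = vapply(ds$outlines, function(o) o$time_slice, ""),
    n_points = vapply(ds$outlines, function(o) nrow(o$points), 0L),
    provenance = ds$provenance,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep or drop groups of a dataset
#'
#' @param ds an [outline_set()].
#' @param exclude character vector of group labels to drop.
#' @return filtered [outline_set()].
#' @export
filter_groups <- function(ds, exclude = character()) {
  stopifnot(inherits(ds, "outline_set"))
  if (length(exclude) == 0) return(ds)
  keep <- !vapply(ds$outlines, function(o) o$group %in% exclude, TRUE)
  if (!any(keep)) stop("all specimens excluded; empty dataset")
  outline_set(ds$outlines[keep], ds$provenance[keep])
}

# ---- label sidecar ---------------------------------------------------------

read_label_table <- function(labels) {
  if (is.character(labels) && length(labels) == 1) {
    labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
  }
  labels <- as.data.frame(labels)
  need <- c("specimen_id", "group", "time_slice")
  if (!all(need %in% names(labels)))
    stop("label table must have columns: ", paste(need, collapse = ", "))
  bad <- !labels$time_slice %in% TIME_SLICES
  if (any(bad))
    stop("label table: unknown time_slice value(s): ",
         paste(unique(labels$time_slice[bad]), collapse = ", "))
  labels
}

apply_labels <- function(outlines, labels) {
  ids <- vapply(outlines, function(o) o$specimen_id, "")
  hit <- match(ids, labels$specimen_id)
  if (anyNA(hit))
    stop("labelling error: no label for specimen(s): ",
         paste(ids[is.na(hit)], collapse = ", "))
  for (k in seq_along(outlines)) {
    outlines[[k]]$group <- as.character(labels$group[hit[k]])
    outlines[[k]]$time_slice <- as.character(labels$time_slice[hit[k]])
  }
  outlines
}

# ---- TPS -------------------------------------------------------------------

#' Read outlines from a TPS outline file
#'
#' Parses the outline dialect of the TPS format: records of `LM=0`,
#' `CURVES=1`, `POINTS=<k>`, k whitespace-separated coordinate lines, then
#' `ID=<specimen_id>`. `IMAGE=` and `SCALE=` lines are tolerated and ignored.
#' Points are read in file order and reoriented counterclockwise where needed;
#' reorientation is recorded in the per-record provenance.
#'
#' @param path TPS file path.
#' @param labels optional label table (data.frame or CSV path with columns
#'   `specimen_id`, `group`, `time_slice`); when given, every specimen must
#'   have a label row.
#' @return an [outline_set()].
#' @export
read_tps <- function(path, labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  outlines <- list(); prov <- character()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^(IMAGE|SCALE)=", ln)) { i <- i + 1L; next }
    if (!grepl("^LM=", ln)) stop("TPS parse error at line ", i, ": expected LM=")
    i <- i + 1L
    if (i > length(lines) || !grepl("^CURVES=", lines[i]))
      stop("TPS parse error: expected CURVES= after LM=")
    i <- i + 1L
    if (i > length(lines) || !grepl("^POINTS=", lines[i]))
      stop("TPS parse error: expected POINTS=")
    k <- as.integer(sub("^POINTS=", "", lines[i]))
    if (is.na(k) || k < 1) stop("TPS parse error: bad POINTS value")
    i <- i + 1L
    pts <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > length(lines) || grepl("^(ID|LM|IMAGE|SCALE)=", lines[i]))
        stop("TPS parse error: record declares POINTS=", k,
             " but has fewer coordinate lines",
             if (i <= length(lines) && grepl("^ID=", lines[i]))
               paste0(" (record ", sub("^ID=", "", lines[i]), ")") else "")
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "[[:space:]]+")[[1]]))
      if (length(xy) != 2 || anyNA(xy))
        stop("TPS parse error: bad coordinate line '", lines[i], "'")
      pts[j, ] <- xy
      i <- i + 1L
    }
    while (i <= length(lines) && grepl("^(IMAGE|SCALE)=", lines[i])) i <- i + 1L
    if (i > length(lines) || !grepl("^ID=", lines[i])) {
      if (i <= length(lines) && !grepl("^(LM)=", lines[i]))
        stop("TPS parse error: record declares POINTS=", k,
             " but has extra coordinate lines before ID=")
      stop("TPS parse error: missing ID= line")
    }
    id <- sub("^ID=", "", lines[i])
    i <- i + 1L
    o <- outline(pts, specimen_id = id)
    outlines[[length(outlines) + 1L]] <- o
    prov <- c(prov, sprintf("%s; reoriented=%s", basename(path),
                            attr(o, "reoriented")))
  }
  if (!is.null(labels)) outlines <- apply_labels(outlines, read_label_table(labels))
  outline_set(outlines, prov)
}

#' Write outlines to a TPS outline file
#'
#' Emits exactly the dialect [read_tps()] reads, with coordinates printed to
#' six decimals (the round-trip precision contract).
#'
#' @param ds an [outline_set()].
#' @param path output file path.
#' @param labels_path optional path for a label sidecar CSV
#'   (`specimen_id,group,time_slice`).
#' @return `path`, invisibly.
#' @export
write_tps <- function(ds, path, labels_path = NULL) {
  stopifnot(inherits(ds, "outline_set"))
  con <- file(path, "w"); on.exit(close(con))
  for (o in ds$outlines) {
    cat("LM=0\nCURVES=1\n", file = con, sep = "")
    cat(sprintf("POINTS=%d\n", nrow(o$points)), file = con)
    cat(sprintf("%.6f %.6f\n", o$points[, 1], o$points[, 2]), file = con, sep = "")
    cat(sprintf("ID=%s\n", o$specimen_id), file = con)
  }
  if (!is.null(labels_path)) {
    m <- dataset_meta(ds)[, c("specimen_id", "group", "time_slice")]
    utils::write.csv(m, labels_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ---- Freeman chain codes ---------------------------------------------------

# 8-neighbour steps, direction 0 = +x, counterclockwise
.freeman_steps <- matrix(c(1, 0, 1, 1, 0, 1, -1, 1, -1, 0, -1, -1, 0, -1, 1, -1),
                         ncol = 2, byrow = TRUE)

#' Read outlines from a Freeman chain-code file
#'
#' One record per line: `<specimen_id> <x0> <y0> <d1 d2 ... dn> -1`, with
#' directions d in 0..7 (0 = +x, 1 = +x+y, 2 = +y, ... counterclockwise).
#' The decoded chain must close exactly on the lattice (end point equal to the
#' origin); open chains are a validation error.
#'
#' @param path chain-code file path.
#' @param labels optional label table as in [read_tps()].
#' @return an [outline_set()].
#' @export
read_chaincode <- function(path, labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines); lines <- lines[nzchar(lines)]
  outlines <- list(); prov <- character()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 5) stop("chain-code parse error: short record '", ln, "'")
    id <- tok[1]
    x0 <- suppressWarnings(as.numeric(tok[2]))
    y0 <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(x0) || is.na(y0)) stop("chain-code parse error: bad origin in '", id, "'")
    dig <- suppressWarnings(as.integer(tok[-(1:3)]))
    if (anyNA(dig)) stop("chain-code parse error: non-integer token in '", id, "'")
    if (dig[length(dig)] != -1L)
      stop("chain-code parse error: record '", id, "' not terminated by -1")
    dig <- dig[-length(dig)]
    if (any(dig < 0L | dig > 7L))
      stop("chain-code parse error: record '", id,
           "' has direction digit outside 0-7")
    steps <- .freeman_steps[dig + 1L, , drop = FALSE]
    pts <- cbind(x0 + cumsum(c(0, steps[, 1])), y0 + cumsum(c(0, steps[, 2])))
    last <- pts[nrow(pts), ]
    if (last[1] != x0 || last[2] != y0)
      stop("chain-code validation error: record '", id,
           "' is an open chain (end point != origin)")
    pts <- pts[-nrow(pts), , drop = FALSE]
    o <- outline(pts, specimen_id = id)
    outlines[[length(outlines) + 1L]] <- o
    prov <- c(prov, sprintf("%s; reoriented=%s", basename(path),
                            attr(o, "reoriented")))
  }
  if (!is.null(labels)) outlines <- apply_labels(outlines, read_label_table(labels))
  outline_set(outlines, prov)
}

# ---- resampling ------------------------------------------------------------

#' Resample an outline to equally spaced points by arc length
#'
#' Places `k` points at equal arc-length spacing along the closed polygon,
#' starting at the original first point. The parameterization step that makes
#' outlines of heterogeneous digitization density comparable before elliptic
#' Fourier analysis.
#'
#' @param o an [outline()].
#' @param k number of points (default 200).
#' @return resampled [outline()] (same id and labels).
#' @export
resample_outline <- function(o, k = 200L) {
  stopifnot(inherits(o, "outline"))
  k <- as.integer(k)
  if (k < 3) stop("k must be at least 3")
  pts <- o$points
  n <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] - closed[-(n + 1), , drop = FALSE])^2))
  per <- sum(seg)
  if (per <= 0) stop("degenerate outline: zero perimeter")
  s <- c(0, cumsum(seg))
  target <- per * (seq_len(k) - 1) / k
  x <- stats::approx(s, closed[, 1], xout = target, ties = "ordered")$y
  y <- stats::approx(s, closed[, 2], xout = target, ties = "ordered")$y
  out <- outline(cbind(x, y), specimen_id = o$specimen_id, group = o$group,
                 time_slice = o$time_slice, validate = FALSE)
  attr(out, "reoriented") <- attr(o, "reoriented")
  out
}

# ---- coefficient tables ----------------------------------------------------

#' Write a normalized-coefficient matrix to CSV
#'
#' Columns are `specimen_id,group,time_slice,d1,a2,b2,c2,d2,...,aN,bN,cN,dN`;
#' floats are printed with 12 significant digits so that identical input gives
#' a byte-identical file.
#'
#' @param cm a coefficient matrix as returned by [coefficient_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coeff_table <- function(cm, path) {
  stopifnot(inherits(cm, "coef_matrix"))
  if (anyDuplicated(cm$meta$specimen_id))
    stop("duplicate specimen ids in coefficient matrix")
  header <- c("specimen_id", "group", "time_slice", colnames(cm$x))
  con <- file(path, "w"); on.exit(close(con))
  cat(paste(header, collapse = ","), "\n", file = con, sep = "")
  if (nrow(cm$x) > 0) {
    num <- apply(cm$x, 2, function(v) sprintf("%.12g", v))
    if (is.null(dim(num))) num <- matrix(num, nrow = nrow(cm$x))
    rows <- cbind(cm$meta$specimen_id, cm$meta$group, cm$meta$time_slice, num)
    cat(apply(rows, 1, paste, collapse = ","), file = con, sep = "\n")
    cat("\n", file = con)
  }
  invisible(path)
}

#' Read a normalized-coefficient matrix from CSV
#'
#' Inverse of [write_coeff_table()].
#'
#' @param path CSV path.
#' @return a `coef_matrix` object (see [coefficient_matrix()]).
#' @export
read_coeff_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  need <- c("specimen_id", "group", "time_slice")
  if (!all(need %in% names(df)))
    stop("coefficient CSV must start with columns: ", paste(need, collapse = ", "))
  meta <- df[, need, drop = FALSE]
  meta$specimen_id <- as.character(meta$specimen_id)
  meta$group <- as.character(meta$group)
  meta$time_slice <- as.character(meta$time_slice)
  x <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- meta$specimen_id
  structure(list(x = x, meta = meta,
                 n_harmonics = (ncol(x) + 3L) %/% 4L),
            class = "coef_matrix")
}
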