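#' Whole-shell thickness from sampled outer points
#'
#' For every sampled point on the outer (exocarp) contour, the local
#' thickness is the minimum Euclidean distance to the inner (mesocarp)
#' contour, computed point-to-segment so the answer does not depend on
#' how densely the inner polyline happens to be vertexed. The shell
#' thickness is the arithmetic mean of these local distances converted
#' to millimetres.
#'
#' @param outer_points matrix of sampled outer-contour points
#'   (columns x, y), e.g. from [sample_contour_points()].
#' @param inner_contour closed inner contour matrix.
#' @param scale mm per pixel; must be positive.
#' @return list with `thickness_mm` (mean) and `per_point_mm` (one
#'   distance per sampled outer point).
#' @export
shell_thickness <- function(outer_points, inner_contour, scale) {
  if (is.null(inner_contour) || nrow(inner_contour) < 2L)
    stopf("inner contour is empty or degenerate")
  if (!is.numeric(scale) || scale <= 0) stopf("scale must be positive")
  d_px <- point_polyline_distance(outer_points, inner_contour)
  list(thickness_mm = mean(d_px) * scale, per_point_mm = d_px * scale)
}

#' Measure shell thickness from a binary ring mask
#'
#' One-call wrapper: extracts the two contours, resamples the outer one
#' at equal arc-length spacing and averages nearest distances to the
#' inner contour.
#'
#' @param mask binary ring mask (one component, one hole).
#' @param scale mm per pixel.
#' @param points_per_px outer-contour sampling density
#'   (see [sample_contour_points()]).
#' @param smooth_px contour regularization span in pixels of arc
#'   (see [extract_contours()]); the default 7 removes the half-pixel
#'   rasterization sawtooth that otherwise biases distances downward.
#' @return object of class `shell_sample`: `mask` dimensions, `scale`,
#'   `outer_contour`, `inner_contour`, sampled `outer_points`,
#'   `thickness_mm`, `per_point_mm`, `n_points`.
#' @examples
#' s <- generate_shell_image(100, 20, 0.1)
#' m <- measure_shell(s$mask, scale = 0.1)
#' m$thickness_mm   # ~2.0 mm
#' @export
measure_shell <- function(mask, scale, points_per_px = 3.183,
                          smooth_px = 7) {
  ct <- extract_contours(mask, smooth_px = smooth_px)
  pts <- sample_contour_points(ct$outer, points_per_px = points_per_px)
  th <- shell_thickness(pts, ct$inner, scale)
  structure(list(dim = dim(mask), scale = scale,
                 outer_contour = ct$outer, inner_contour = ct$inner,
                 outer_points = pts, thickness_mm = th$thickness_mm,
                 per_point_mm = th$per_point_mm,
                 n_points = nrow(pts)),
            class = "shell_sample")
}

#' @export
print.shell_sample <- function(x, ...) {
  cat(sprintf(
    "shell_sample: %d x %d px at %.4g mm/px\n  PST = %.4f mm (mean of %d sampled outer points; per-point range %.4f-%.4f)\n",
    x$dim[1L], x$dim[2L], x$scale, x$thickness_mm, x$n_points,
    min(x$per_point_mm), max(x$per_point_mm)))
  invisible(x)
}

#' Pod silhouette geometry: area, perimeter, length, width
#'
#' Area is the foreground pixel count times `scale^2`; perimeter the
#' outer iso-contour arc length times `scale`. Length and width are the
#' side lengths of the axis-aligned bounding box after rotating the
#' silhouette so its principal axis (first principal component of the
#' foreground pixel coordinates) is horizontal; length is always the
#' larger of the two.
#'
#' @param mask binary silhouette matrix (filled shape; a ring is
#'   measured by its outer boundary and pixel count as-is).
#' @param scale mm per pixel.
#' @param smooth_px contour regularization span (pixels of arc) for the
#'   perimeter measurement; raw binary iso-contours overestimate smooth
#'   perimeters by several percent.
#' @return list of class `pod_geometry`: `area_mm2`, `perimeter_mm`,
#'   `length_mm`, `width_mm`.
#' @export
pod_geometry <- function(mask, scale, smooth_px = 7) {
  mask <- binarize_mask(mask)
  if (!any(mask == 1L)) stopf("mask is empty")
  if (!is.numeric(scale) || scale <= 0) stopf("scale must be positive")
  area <- sum(mask) * scale^2

  cl <- grDevices::contourLines(x = seq_len(nrow(mask)),
                                y = seq_len(ncol(mask)),
                                z = mask, levels = 0.5)
  if (length(cl) == 0L) stopf("no contour traced (mask touches border?)")
  polys <- lapply(cl, function(c1) close_contour(cbind(c1$y, c1$x)))
  outer <- polys[[which.max(vapply(polys, function(p)
    abs(polygon_area_signed(p)), 0))]]
  outer <- smooth_contour(outer, smooth_px)
  perim <- contour_perimeter(outer) * scale

  idx <- which(mask == 1L, arr.ind = TRUE)
  xy <- cbind(idx[, 2L], idx[, 1L])              # (x, y)
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2L, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  rot <- sweep(outer, 2L, ctr) %*% ev            # principal axes frame
  ext <- apply(rot, 2L, function(v) diff(range(v))) * scale
  structure(list(area_mm2 = area, perimeter_mm = perim,
                 length_mm = max(ext), width_mm = min(ext)),
            class = "pod_geometry")
}

#' @export
print.pod_geometry <- function(x, ...) {
  cat(sprintf(
    "pod_geometry: PA %.2f mm^2, PP %.2f mm, PL %.2f mm, PW %.2f mm\n",
    x$area_mm2, x$perimeter_mm, x$length_mm, x$width_mm))
  invisible(x)
}

#' Descriptive statistics with coefficient of variation
#'
#' @param values numeric vector, length >= 2, all finite.
#' @return list: `n`, `min`, `max`, `mean`, `sd` (n-1 denominator),
#'   `cv_percent` = 100 * sd / mean.
#' @examples
#' descriptive_stats(c(2, 4, 4, 4, 5, 5, 7, 9))
#' @export
descriptive_stats <- function(values) {
  if (length(values) < 2L) stopf("need at least 2 values")
  if (!all(is.finite(values))) stopf("values must all be finite")
  m <- mean(values)
  if (m == 0) stopf("mean is zero; CV undefined")
  s <- sd(values)
  list(n = length(values), min = min(values), max = max(values),
       mean = m, sd = s, cv_percent = 100 * s / m)
}

#' Read a per-individual phenotype table
#'
#' Expects a delimited text file with an id column and a pod-shell
#' thickness column (any column name containing "pst", case-insensitive;
#' otherwise the first numeric column).
#'
#' @param path TSV/CSV path.
#' @return data.table with columns `id` and `pst_mm`.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path)
  pst_col <- grep("pst", names(dt), ignore.case = TRUE, value = TRUE)
  if (length(pst_col) == 0L) {
    num <- names(dt)[vapply(dt, is.numeric, TRUE)]
    if (length(num) == 0L) stopf("no numeric phenotype column in %s", path)
    pst_col <- num[length(num)]
  }
  id_col <- grep("id", names(dt), ignore.case = TRUE, value = TRUE)
  id <- if (length(id_col)) dt[[id_col[1L]]] else seq_len(nrow(dt))
  out <- data.table(id = id, pst_mm = as.numeric(dt[[pst_col[1L]]]))
  if (anyDuplicated(out$id)) stopf("duplicate individual ids")
  out
}

#' Batch-measure a directory of mask images
#'
#' @param dir directory containing `.png` / `.pgm` ring masks.
#' @param scale mm per pixel applied to every mask.
#' @param points_per_px outer sampling density.
#' @param geometry also compute PA/PP/PL/PW per mask.
#' @return data.table: `id` (file stem), `PST_mm`, `n_points`, and the
#'   geometry columns when requested.
#' @export
measure_mask_dir <- function(dir, scale, points_per_px = 3.183,
                             geometry = TRUE) {
  files <- list.files(dir, pattern = "\\.(png|pgm)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L) stopf("no .png/.pgm masks under %s", dir)
  rows <- lapply(files, function(f) {
    mask <- read_mask(f)
    m <- measure_shell(mask, scale, points_per_px)
    row <- data.table(id = sub("\\.[^.]+$", "", basename(f)),
                      PST_mm = m$thickness_mm, n_points = m$n_points)
    if (geometry) {
      pg <- pod_geometry(mask, scale)
      row[, `:=`(PA = pg$area_mm2, PP = pg$perimeter_mm,
                 PL = pg$length_mm, PW = pg$width_mm)]
    }
    row
  })
  data.table::rbindlist(rows)
}
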