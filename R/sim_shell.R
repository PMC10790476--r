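#' Generate a synthetic shell cross-section mask with known thickness
#'
#' Draws an annulus-like ring: the outer boundary is an ellipse with
#' semi-axes `outer_radius_px` and `outer_radius_px * (1 -
#' eccentricity)`, the inner boundary the ellipse shrunk by
#' `thickness_px` on both semi-axes. Optional smooth per-angle radial
#' jitter roughens both boundaries. Pixels whose centre lies between the
#' two boundaries (a star-shaped, polar test equivalent to a 0.5-level
#' polygon fill) are foreground.
#'
#' The returned ground truth ignores the jitter: it is the mean, over
#' outer-boundary points dense in arc length, of the minimum distance to
#' the noise-free inner boundary, times the pixel scale. For a circular
#' ring this equals `(R - r) * scale` exactly.
#'
#' @param outer_radius_px outer semi-major axis in pixels.
#' @param thickness_px radial shell thickness in pixels; must be
#'   positive and smaller than the inner semi-minor axis allows.
#' @param scale_mm_per_px physical size of one pixel (mm).
#' @param eccentricity axis flattening in `[0, 0.9]`; 0 gives a circle.
#' @param boundary_noise_px SD of the smooth radial jitter (pixels).
#' @param seed optional integer seed (jitter only).
#' @param canvas_px square canvas edge (default 512).
#' @return list of class `shell_sim`: `mask` (integer 0/1 matrix,
#'   rows = y), `truth_mm`, `scale`, and the generating parameters.
#' @examples
#' s <- generate_shell_image(100, 20, 0.1)
#' s$truth_mm
#' @export
generate_shell_image <- function(outer_radius_px, thickness_px,
                                 scale_mm_per_px,
                                 eccentricity = 0,
                                 boundary_noise_px = 0,
                                 seed = NULL,
                                 canvas_px = 512L) {
  if (thickness_px <= 0) stopf("thickness must be positive")
  if (thickness_px >= outer_radius_px * (1 - eccentricity))
    stopf("thickness %.1f px leaves no hole (inner semi-minor axis <= 0)",
          thickness_px)
  if (eccentricity < 0 || eccentricity > 0.9)
    stopf("eccentricity must lie in [0, 0.9]")
  if (scale_mm_per_px <= 0) stopf("scale must be positive")
  set_op_seed(seed, 404L)

  a_out <- outer_radius_px
  b_out <- outer_radius_px * (1 - eccentricity)
  a_in <- a_out - thickness_px
  b_in <- b_out - thickness_px
  if (a_out + abs(boundary_noise_px) * 4 > canvas_px / 2 - 2)
    stopf("ring does not fit the %d px canvas", canvas_px)

  # smooth periodic radial jitter on a dense angle grid
  n_ang <- 1440L
  theta <- seq(0, 2 * pi, length.out = n_ang + 1L)[-(n_ang + 1L)]
  jitter <- function() {
    if (boundary_noise_px <= 0) return(numeric(n_ang))
    raw <- rnorm(n_ang, 0, boundary_noise_px)
    k <- 25L  # circular moving average -> smooth, realistic roughness
    sm <- stats::filter(c(raw, raw, raw), rep(1 / (2 * k + 1), 2 * k + 1))
    sm <- sm[(n_ang + 1L):(2L * n_ang)]
    as.numeric(sm) * boundary_noise_px / max(sd(sm), 1e-12)
  }
  r_ell <- function(a, b) a * b / sqrt((b * cos(theta))^2 +
                                         (a * sin(theta))^2)
  r_out <- r_ell(a_out, b_out) + jitter()
  r_in <- r_ell(a_in, b_in) + jitter()
  if (any(r_in <= 1) || any(r_out - r_in <= 1))
    stopf("parameters produce a degenerate or disconnected ring")

  cx <- (canvas_px + 1) / 2
  col <- matrix(rep(seq_len(canvas_px), each = canvas_px),
                nrow = canvas_px)           # x
  row <- matrix(rep(seq_len(canvas_px), times = canvas_px),
                nrow = canvas_px)           # y
  dx <- col - cx
  dy <- row - cx
  r_pix <- sqrt(dx^2 + dy^2)
  th_pix <- atan2(dy, dx) %% (2 * pi)
  # interpolate boundary radius at each pixel's angle (periodic)
  interp <- function(rfun) {
    approx(x = c(theta, 2 * pi), y = c(rfun, rfun[1L]),
           xout = th_pix, rule = 2)$y
  }
  mask <- (r_pix <= interp(r_out)) & (r_pix >= interp(r_in))
  mask <- matrix(as.integer(mask), nrow = canvas_px)

  truth_mm <- mean_ring_thickness(a_out, b_out, a_in, b_in) *
    scale_mm_per_px
  structure(list(mask = mask, truth_mm = truth_mm,
                 scale = scale_mm_per_px,
                 outer_radius_px = outer_radius_px,
                 thickness_px = thickness_px,
                 eccentricity = eccentricity,
                 boundary_noise_px = boundary_noise_px,
                 canvas_px = canvas_px),
            class = "shell_sim")
}

# dense numerical geometry: mean over arc-length-uniform outer points of
# the min distance to the inner ellipse polyline
mean_ring_thickness <- function(a_out, b_out, a_in, b_in,
                                n_outer = 2000L, n_inner = 2000L) {
  if (a_out == b_out && a_in == b_in) return(a_out - a_in)  # circle
  tt <- seq(0, 2 * pi, length.out = 8L * n_outer)
  ox <- a_out * cos(tt); oy <- b_out * sin(tt)
  arc <- cumsum(c(0, sqrt(diff(ox)^2 + diff(oy)^2)))
  s <- seq(0, arc[length(arc)], length.out = n_outer + 1L)[-(n_outer + 1L)]
  px <- approx(arc, ox, s)$y
  py <- approx(arc, oy, s)$y
  ti <- seq(0, 2 * pi, length.out = n_inner + 1L)[-(n_inner + 1L)]
  inner <- cbind(a_in * cos(ti), b_in * sin(ti))
  d <- point_polyline_distance(cbind(px, py), close_contour(inner))
  mean(d)
}

#' Write a binary mask as a single-channel PNG
#'
#' Foreground pixels become white (255), background black (0).
#'
#' @param mask integer/logical matrix (rows = y).
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask > 0, 1, 0), path)
  invisible(path)
}

#' Read a mask image (PNG or text PGM) as a binary matrix
#'
#' Pixels above half intensity are foreground. PNGs may be grayscale or
#' RGB(A); the first channel is used.
#'
#' @param path `.png` or ASCII `.pgm` (P2) file.
#' @return integer 0/1 matrix (rows = y).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(img > 0.5), nrow = nrow(img))
}

#' Write a binary mask as ASCII PGM (P2)
#'
#' Plain-text image format used for text-only fixtures.
#' @param mask integer/logical matrix.
#' @param path output `.pgm` path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(mask), nrow(mask)), "255"),
             con)
  apply_rows <- apply(mask, 1L, function(r)
    paste(ifelse(r > 0, 255L, 0L), collapse = " "))
  writeLines(apply_rows, con)
  invisible(path)
}

read_pgm <- function(path) {
  toks <- scan(path, what = "", quiet = TRUE, comment.char = "#")
  if (toks[1L] != "P2") stopf("only ASCII PGM (P2) supported: %s", path)
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) stopf("corrupt PGM: %s", path)
  matrix(as.integer(vals > 127L), nrow = h, byrow = TRUE)
}

#' Write the ground-truth sidecar for a simulated shell mask
#'
#' @param shell a `shell_sim` object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_shell_truth <- function(shell, path) {
  stopifnot(inherits(shell, "shell_sim"))
  jsonlite::write_json(
    shell[setdiff(names(shell), "mask")], path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
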