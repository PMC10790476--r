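# Independent oracles used to check package computations. Each is a
# deliberately different route to the same quantity (brute force,
# enumeration, closed form); none calls the code path it validates.

# exhaustive point-to-segment search, scalar arithmetic with explicit
# branches (contrast: the package projects vectorized over segments)
oracle_point_polyline_dist <- function(points, poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    best <- Inf
    for (s in seq_len(nrow(poly) - 1L)) {
      a <- poly[s, ]; b <- poly[s + 1L, ]
      ab <- b - a
      L2 <- sum(ab^2)
      if (L2 == 0) {
        d <- sqrt(sum((p - a)^2))
      } else {
        t <- sum((p - a) * ab) / L2
        if (t < 0) t <- 0
        if (t > 1) t <- 1
        q <- a + t * ab
        d <- sqrt(sum((p - q)^2))
      }
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# two-sided Fisher P by hypergeometric enumeration from lchoose
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  supp <- max(0, k - n):min(k, m)
  lp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  p <- exp(lp)
  p_obs <- p[supp == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# G via the algebraic identity
# G = 2 (sum n ln n - sum row ln row - sum col ln col + N ln N)
oracle_g_llr <- function(a, b, c, d) {
  n <- c(a, b, c, d)
  xlx <- function(x) sum(ifelse(x == 0, 0, x * log(x)))
  2 * (xlx(n) - xlx(c(a + b, c + d)) - xlx(c(a + c, b + d)) +
         xlx(sum(n)))
}

# tricube-weighted mean written as a plain double loop
oracle_tricube <- function(g, pos, window_bp) {
  half <- window_bp / 2
  out <- numeric(length(g))
  for (i in seq_along(g)) {
    num <- 0; den <- 0
    for (j in seq_along(g)) {
      d <- abs(pos[j] - pos[i])
      if (d <= half) {
        k <- (1 - (d / half)^3)^3
        num <- num + k * g[j]
        den <- den + k
      }
    }
    out[i] <- num / den
  }
  out
}

# R type-7 (linear interpolation) percentile written out by hand
oracle_type7_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# mean normal-gap thickness of an elliptical ring: for outer points
# uniform in arc length (by numerical inversion), minimize the distance
# to the inner ellipse with stats::optimize over its parameter
oracle_ellipse_ring_thickness <- function(a_out, b_out, a_in, b_in,
                                          n_outer = 600L) {
  tt <- seq(0, 2 * pi, length.out = 20000L)
  ox <- a_out * cos(tt); oy <- b_out * sin(tt)
  arc <- cumsum(c(0, sqrt(diff(ox)^2 + diff(oy)^2)))
  s <- seq(0, max(arc), length.out = n_outer + 1L)[-(n_outer + 1L)]
  t_of_s <- approx(arc, tt, s, ties = "ordered")$y
  dist_to_inner <- function(px, py) {
    f <- function(u) sqrt((a_in * cos(u) - px)^2 + (b_in * sin(u) - py)^2)
    u0 <- atan2(py / b_in, px / a_in)
    opt <- optimize(f, lower = u0 - pi / 2, upper = u0 + pi / 2)
    opt$objective
  }
  d <- mapply(function(t1) dist_to_inner(a_out * cos(t1), b_out * sin(t1)),
              t_of_s)
  mean(d)
}

# a hand-made threshold set for region-calling tests
make_threshold <- function(upper, lower = NA_real_, level = 0.99,
                           method = "statistic") {
  ts <- data.table::data.table(level = level, lower = lower,
                               upper = upper)
  data.table::setattr(ts, "method", method)
  data.table::setattr(ts, "derivation", "manual")
  data.table::setattr(ts, "class", c("threshold_set", class(ts)))
  ts
}

# filled shapes on an n x n canvas (x = col, y = row, centre mid-canvas)
shape_mask <- function(n, predicate) {
  cx <- (n + 1) / 2
  col <- matrix(rep(seq_len(n), each = n), nrow = n)
  row <- matrix(rep(seq_len(n), times = n), nrow = n)
  matrix(as.integer(predicate(col - cx, row - cx)), nrow = n)
}

disk_mask <- function(n, r) shape_mask(n, function(x, y) x^2 + y^2 <= r^2)

square_ring_mask <- function(n, half_out, half_in) {
  shape_mask(n, function(x, y)
    pmax(abs(x), abs(y)) <= half_out & pmax(abs(x), abs(y)) > half_in)
}

# tiny variant-record table builder for filtering tests
toy_record <- function(chrom = "chr01", pos = 100L, qual = 60,
                       gtA = "0/0", gtB = "1/1",
                       adA = c(40L, 0L), adB = c(0L, 40L),
                       adH = c(40L, 40L), adL = c(40L, 40L)) {
  data.table::data.table(
    chrom = chrom, pos = pos, ref = "A", alt = "G", qual = qual,
    gt_parentA = gtA, gt_parentB = gtB,
    ad_parentA_ref = adA[1], ad_parentA_alt = adA[2],
    ad_parentB_ref = adB[1], ad_parentB_alt = adB[2],
    ad_high_ref = adH[1], ad_high_alt = adH[2],
    ad_low_ref = adL[1], ad_low_alt = adL[2])
}

random_tables <- function(n, depth = 100L, seed = 1L) {
  set.seed(seed)
  f <- runif(n); g <- runif(n)
  data.frame(a = rbinom(n, depth, f), c = rbinom(n, depth, g)) |>
    (\(d) data.frame(a = d$a, b = depth - d$a,
                     c = d$c, d = depth - d$c))()
}
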