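# 2D morphology of a binary mask slice. All contour-based quantities are
# computed on the largest 4-connected component; physical units come from
# the (dy, dx) pixel spacing. Row index = y, column index = x.

# label 4-connected components by iterative label propagation
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[m != 0] <- seq_len(sum(m != 0))
  repeat {
    up <- rbind(lab[-1, , drop = FALSE], 0L)
    dn <- rbind(0L, lab[-nrow(lab), , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], 0L)
    rt <- cbind(0L, lab[, -ncol(lab), drop = FALSE])
    new <- pmax(lab, up, dn, lf, rt)
    new[m == 0] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

largest_component <- function(m) {
  lab <- label_components(m)
  if (all(lab == 0L)) return(m)
  tab <- tabulate(lab[lab > 0])
  (lab == which.max(tab)) * 1L
}

# Moore-neighbour boundary tracing; returns the closed contour as a
# matrix of (row, col) pixel indices and the chain-code steps.
trace_boundary <- function(m) {
  fg <- which(m != 0, arr.ind = TRUE)
  if (nrow(fg) == 1L) return(list(path = fg, steps = integer()))
  # clockwise Moore neighbourhood starting pointing "up"
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  ord <- order(fg[, 1], fg[, 2])
  start <- fg[ord[1], ]
  inside <- function(r, c) r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
    m[r, c] != 0
  path <- matrix(start, ncol = 2)
  cur <- start
  dir <- 6L  # came from the left (scan order guarantees left neighbour empty)
  maxsteps <- 8L * nrow(fg) + 8L
  for (step in seq_len(maxsteps)) {
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + 6L + k) %% 8L  # start search two steps counter-clockwise
      r <- cur[1] + dr[d + 1L]; c <- cur[2] + dc[d + 1L]
      if (inside(r, c)) {
        cur <- c(r, c); dir <- d; found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && nrow(path) > 1L) break
    path <- rbind(path, cur)
  }
  steps <- diff(rbind(path, path[1, , drop = FALSE]))
  list(path = path, steps = steps)
}

# corrected chain-code perimeter (Vossepoel-Smeulders weights 0.948 axial,
# 1.340 diagonal for unit grids), generalised to anisotropic spacing by
# weighting each step's physical length
chain_perimeter <- function(steps, spacing) {
  if (length(steps) == 0L || nrow(steps) == 0L)
    return(2 * (spacing[1] + spacing[2]))
  len <- sqrt((steps[, 1] * spacing[1])^2 + (steps[, 2] * spacing[2])^2)
  diag <- steps[, 1] != 0 & steps[, 2] != 0
  sum(ifelse(diag, len * (1.340 / sqrt(2)), len * 0.948))
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(xy) {
  d <- diff(rbind(xy, xy[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# physical-coordinate corners of a set of pixels (centres at idx * spacing)
pixel_corners <- function(idx, spacing) {
  y <- idx[, 1] * spacing[1]; x <- idx[, 2] * spacing[2]
  hy <- spacing[1] / 2; hx <- spacing[2] / 2
  cbind(c(x - hx, x + hx, x - hx, x + hx),
        c(y - hy, y - hy, y + hy, y + hy))
}

# Feret (caliper) widths of a convex point set over a 1-degree angle sweep
feret_widths <- function(pts) {
  ang <- seq(0, pi, length.out = 181)[-181]
  ca <- cos(ang); sa <- sin(ang)
  proj <- pts %*% rbind(ca, sa)
  apply(proj, 2, max) - apply(proj, 2, min)
}

shape_features <- function(mask, spacing) {
  comp <- largest_component(mask)
  idx <- which(comp != 0, arr.ind = TRUE)
  n <- nrow(idx)
  dy <- spacing[1]; dx <- spacing[2]
  area <- n * dy * dx
  tb <- trace_boundary(comp)
  perim <- chain_perimeter(tb$steps, spacing)
  # convex hull over pixel corners of the boundary (falls back to all pixels)
  bidx <- unique(tb$path)
  corners <- pixel_corners(bidx, spacing)
  h <- grDevices::chull(corners)
  hull <- corners[h, , drop = FALSE]
  cvx_area <- if (nrow(hull) >= 3) polygon_area(hull) else area
  cvx_perim <- if (nrow(hull) >= 2) polygon_perimeter(hull) else perim
  # second-order point moments plus the per-pixel square term (d^2/12)
  y <- idx[, 1] * dy; x <- idx[, 2] * dx
  mu_y <- mean(y); mu_x <- mean(x)
  cyy <- mean((y - mu_y)^2) + dy^2 / 12
  cxx <- mean((x - mu_x)^2) + dx^2 / 12
  cxy <- mean((y - mu_y) * (x - mu_x))
  tr <- cyy + cxx; det <- cyy * cxx - cxy^2
  lam1 <- tr / 2 + sqrt(max(0, tr^2 / 4 - det))
  lam2 <- tr / 2 - sqrt(max(0, tr^2 / 4 - det))
  lam2 <- max(lam2, 1e-12)
  major <- 4 * sqrt(lam1); minor <- 4 * sqrt(lam2)
  ecc <- sqrt(max(0, 1 - lam2 / lam1))
  # scale-normalised central moments for the first three Hu invariants
  m00 <- n
  eta <- function(p, q) {
    sum(((y - mu_y) / sqrt(dy * dx))^p * ((x - mu_x) / sqrt(dy * dx))^q) /
      m00^(1 + (p + q) / 2)
  }
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  hu1 <- e20 + e02
  hu2 <- (e20 - e02)^2 + 4 * e11^2
  hu3 <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  bb_h <- (max(idx[, 1]) - min(idx[, 1]) + 1) * dy
  bb_w <- (max(idx[, 2]) - min(idx[, 2]) + 1) * dx
  fw <- feret_widths(hull)
  feret_max <- max(stats::dist(hull))
  feret_min <- min(fw)
  c(morph_area = area,
    morph_perimeter = perim,
    morph_equivalent_diameter = 2 * sqrt(area / pi),
    morph_circularity = 4 * pi * area / perim^2,
    morph_compactness = perim^2 / (4 * pi * area),
    morph_eccentricity = ecc,
    morph_major_axis_length = major,
    morph_minor_axis_length = minor,
    morph_aspect_ratio = major / minor,
    morph_extent = area / (bb_h * bb_w),
    morph_solidity = min(1, area / max(cvx_area, 1e-12)),
    morph_convexity = min(1, cvx_perim / max(perim, 1e-12)),
    morph_convex_area = cvx_area,
    morph_feret_max = feret_max,
    morph_feret_min = feret_min,
    morph_feret_mean = mean(fw),
    morph_feret_ratio = feret_min / max(feret_max, 1e-12),
    morph_roundness = 4 * area / (pi * major^2),
    morph_hu_moment_1 = hu1,
    morph_hu_moment_2 = hu2,
    morph_hu_moment_3 = hu3)
}
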