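#' Tomogram-like intensity volume
#'
#' A 3-D intensity grid with isotropic voxel spacing and an nm origin (the
#' world position of the center of voxel `[1, 1, 1]`). The study's native
#' spacing is 0.64 nm/voxel; synthetic renders typically use a coarser
#' grid.
#'
#' @param data Numeric 3-D array (x, y, z order).
#' @param voxel_size_nm Voxel edge in nm, > 0.
#' @param origin_nm Length-3 nm offset of the first voxel center.
#' @return An object of class `tomo_volume`.
#' @export
tomo_volume <- function(data, voxel_size_nm, origin_nm = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3, voxel_size_nm > 0,
            length(origin_nm) == 3, all(dim(data) >= 1))
  structure(
    list(data = data, voxel_size_nm = voxel_size_nm,
         origin_nm = as.numeric(origin_nm)),
    class = "tomo_volume"
  )
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels at %.2f nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size_nm))
  invisible(x)
}

#' Render a synthetic tomogram-like volume from a cloud
#'
#' Paints each vesicle as a dark spherical shell (stain-like dark-on-light
#' contrast) and each bridge as a dark cylindrical rod joining the nearest
#' surface points of its pair, then adds Gaussian noise and, optionally,
#' dual-axis missing-wedge degradation (a Fourier-domain mask removing
#' components outside +/-50 degree coverage about both in-plane tilt
#' axes). The grid covers the cloud bounds, padded so every sphere fits.
#'
#' @param cloud A [vesicle_cloud()].
#' @param bridges Optional tibble with columns `id_i`, `id_j` (e.g. from
#'   [chain_bridges()]); these pairs get a rod.
#' @param voxel_size_nm Voxel edge in nm.
#' @param noise_sd Additive Gaussian noise sd (background intensity is 1,
#'   shells are darker by `shell_depth`).
#' @param missing_wedge Apply the dual-axis wedge mask.
#' @param seed Integer seed for the noise draw.
#' @param shell_thickness_nm Membrane shell thickness.
#' @param rod_radius_nm Bridge rod radius.
#' @param shell_depth,rod_depth Intensity decrements for shell and rod.
#' @param wedge_max_tilt_deg Tilt coverage half-angle for the wedge mask.
#' @return A [tomo_volume()].
#' @export
render_volume <- function(cloud, bridges = NULL, voxel_size_nm = 2,
                          noise_sd = 0.05, missing_wedge = FALSE,
                          seed = NULL, shell_thickness_nm = 4,
                          rod_radius_nm = 3, shell_depth = 0.6,
                          rod_depth = 0.4, wedge_max_tilt_deg = 50) {
  stopifnot(inherits(cloud, "vesicle_cloud"))
  v <- cloud$vesicles
  pad <- if (nrow(v) > 0) max(v$radius_nm) + shell_thickness_nm else 0
  lo <- cloud$bounds["min", ] - pad
  hi <- cloud$bounds["max", ] + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size_nm)) + 1L)
  origin <- as.numeric(lo)
  vol <- array(1, dim = dims)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * voxel_size_nm)

  if (nrow(v) > 0) {
    centers <- as.matrix(v[, c("x_nm", "y_nm", "z_nm")])
    out_of_grid <- centers[, 1] + v$radius_nm > hi[1] + voxel_size_nm |
      centers[, 1] - v$radius_nm < lo[1] - voxel_size_nm
    if (any(out_of_grid)) stop("vesicle sphere extends outside the volume grid")
    for (k in seq_len(nrow(v))) {
      lin <- shell_voxels(dims, ax, centers[k, ], v$radius_nm[k],
                          shell_thickness_nm)
      vol[lin] <- vol[lin] - shell_depth
    }
    if (!is.null(bridges) && nrow(bridges) > 0) {
      row_of <- match(c(bridges$id_i, bridges$id_j), v$id)
      if (anyNA(row_of)) stop("bridge ids not present in cloud")
      for (k in seq_len(nrow(bridges))) {
        a <- match(bridges$id_i[k], v$id)
        b <- match(bridges$id_j[k], v$id)
        u <- centers[b, ] - centers[a, ]
        len <- sqrt(sum(u^2))
        if (len == 0) next
        u <- u / len
        p1 <- centers[a, ] + u * v$radius_nm[a]
        p2 <- centers[b, ] - u * v$radius_nm[b]
        lin <- rod_voxels(dims, ax, p1, p2, rod_radius_nm)
        vol[lin] <- vol[lin] - rod_depth
      }
    }
  }

  if (noise_sd > 0) {
    vol <- vol + with_seed(seed, array(stats::rnorm(length(vol), 0, noise_sd),
                                       dim = dims))
  }
  out <- tomo_volume(vol, voxel_size_nm, origin)
  if (missing_wedge) out <- apply_missing_wedge(out, wedge_max_tilt_deg)
  out
}

# subgrid index range covering [center - reach, center + reach] on axis a
axis_window <- function(ax, center, reach) {
  which(ax >= center - reach & ax <= center + reach)
}

# linear voxel indices inside a local window where a condition holds
window_lin_index <- function(dims, ix, iy, iz, mask) {
  loc <- arrayInd(which(mask), c(length(ix), length(iy), length(iz)))
  ix[loc[, 1]] + (iy[loc[, 2]] - 1L) * dims[1] +
    (iz[loc[, 3]] - 1L) * dims[1] * dims[2]
}

shell_voxels <- function(dims, ax, center, radius, thickness) {
  reach <- radius + thickness / 2
  ix <- axis_window(ax[[1]], center[1], reach)
  iy <- axis_window(ax[[2]], center[2], reach)
  iz <- axis_window(ax[[3]], center[3], reach)
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  dx2 <- (ax[[1]][ix] - center[1])^2
  dy2 <- (ax[[2]][iy] - center[2])^2
  dz2 <- (ax[[3]][iz] - center[3])^2
  d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  window_lin_index(dims, ix, iy, iz, abs(d - radius) <= thickness / 2)
}

rod_voxels <- function(dims, ax, p1, p2, rod_radius) {
  lo <- pmin(p1, p2) - rod_radius
  hi <- pmax(p1, p2) + rod_radius
  ix <- which(ax[[1]] >= lo[1] & ax[[1]] <= hi[1])
  iy <- which(ax[[2]] >= lo[2] & ax[[2]] <= hi[2])
  iz <- which(ax[[3]] >= lo[3] & ax[[3]] <= hi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  g <- expand.grid(x = ax[[1]][ix], y = ax[[2]][iy], z = ax[[3]][iz])
  d <- point_segment_distance(as.matrix(g), p1, p2)
  window_lin_index(dims, ix, iy, iz, d <= rod_radius)
}

point_segment_distance <- function(pts, p1, p2) {
  seg <- p2 - p1
  len2 <- sum(seg^2)
  if (len2 == 0) {
    return(sqrt(rowSums(sweep(pts, 2, p1)^2)))
  }
  rel <- sweep(pts, 2, p1)
  t <- pmin(1, pmax(0, (rel %*% seg) / len2))
  proj <- cbind(p1[1] + t * seg[1], p1[2] + t * seg[2], p1[3] + t * seg[3])
  sqrt(rowSums((pts - proj)^2))
}

#' Apply dual-axis missing-wedge degradation
#'
#' Zeroes the Fourier components that neither of two orthogonal in-plane
#' tilt axes with `max_tilt_deg` coverage would sample (the "missing
#' pyramid"), then inverse-transforms. This reproduces the anisotropic
#' resolution loss that makes steeply oriented (high Z-angle) vesicle
#' pairs hard to judge in real tomograms.
#'
#' @param volume A [tomo_volume()].
#' @param max_tilt_deg Tilt coverage half-angle in degrees.
#' @return A degraded [tomo_volume()].
#' @export
apply_missing_wedge <- function(volume, max_tilt_deg = 50) {
  stopifnot(inherits(volume, "tomo_volume"))
  d <- dim(volume$data)
  f <- stats::fft(volume$data)
  fr <- function(n) {
    k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
    k[seq_len(n)] / n
  }
  kx <- abs(fr(d[1])); ky <- abs(fr(d[2])); kz <- abs(fr(d[3]))
  lim <- tan(max_tilt_deg * pi / 180)
  # sampled by the x-tilt series: |kz| <= tan(max) * |kx| (planes tilting
  # about y sweep the x-z plane); dual axis adds the same about x
  mask <- array(FALSE, dim = d)
  for (iz in seq_len(d[3])) {
    mz <- kz[iz]
    keep <- outer(kx * lim >= mz, rep(TRUE, d[2])) |
            outer(rep(TRUE, d[1]), ky * lim >= mz)
    mask[, , iz] <- keep
  }
  mask[1, 1, 1] <- TRUE  # DC always kept
  f[!mask] <- 0
  out <- Re(stats::fft(f, inverse = TRUE)) / prod(d)
  tomo_volume(out, volume$voxel_size_nm, volume$origin_nm)
}

#' Trilinear interpolation of a volume at arbitrary nm points
#'
#' @param volume A [tomo_volume()].
#' @param points N x 3 matrix of nm coordinates.
#' @return Numeric vector of interpolated intensities; `NA` for points
#'   outside the grid.
#' @export
interp_trilinear <- function(volume, points) {
  stopifnot(inherits(volume, "tomo_volume"))
  points <- rbind(points)
  d <- dim(volume$data)
  t <- sweep(points, 2, volume$origin_nm) / volume$voxel_size_nm + 1
  ok <- t[, 1] >= 1 & t[, 1] <= d[1] & t[, 2] >= 1 & t[, 2] <= d[2] &
        t[, 3] >= 1 & t[, 3] <= d[3]
  out <- rep(NA_real_, nrow(points))
  if (!any(ok)) return(out)
  t <- t[ok, , drop = FALSE]
  i0 <- pmin(floor(t), matrix(rep(d - 1L, each = nrow(t)), ncol = 3))
  fr <- t - i0
  v <- volume$data
  g <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  vals <-
    g(0, 0, 0) * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
    g(1, 0, 0) * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
    g(0, 1, 0) * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
    g(0, 0, 1) * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
    g(1, 1, 0) * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
    g(1, 0, 1) * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
    g(0, 1, 1) * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
    g(1, 1, 1) * fr[, 1] * fr[, 2] * fr[, 3]
  out[ok] <- vals
  out
}

#' Extract averaged three-angle views of a vesicle pair
#'
#' Resamples the volume into a frame with the pair axis along x and both
#' centers in the central plane (z = 0), then averages virtual sections
#' spanning `+/- half_span` median diameters in z -- the presentation
#' geometry used for blinded bridge scoring. The `+45` and `-45` degree
#' views rotate the frame about the pair axis before averaging.
#'
#' @param volume A [tomo_volume()].
#' @param c1,c2 Pair centers (nm).
#' @param d_med Median vesicle diameter (nm) of the owning cloud.
#' @param half_span Averaging half-span in median-diameter units (default
#'   0.25).
#' @param fov_nm Side of the square field of view; defaults to the center
#'   distance plus two median diameters.
#' @param pixel_nm Output pixel size; defaults to the voxel size.
#' @return An object of class `pair_views`: list of three matrices
#'   `view_0`, `view_p45`, `view_m45` plus the span used.
#' @export
extract_pair_views <- function(volume, c1, c2, d_med, half_span = 0.25,
                               fov_nm = NULL, pixel_nm = NULL) {
  stopifnot(inherits(volume, "tomo_volume"), d_med > 0)
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  delta <- c2 - c1
  len <- sqrt(sum(delta^2))
  if (len == 0) stop("pair centers coincide")
  if (is.null(fov_nm)) fov_nm <- len + 2 * d_med
  if (is.null(pixel_nm)) pixel_nm <- volume$voxel_size_nm
  mid <- (c1 + c2) / 2
  e1 <- delta / len
  up <- c(0, 0, 1) - sum(c(0, 0, 1) * e1) * e1
  if (sqrt(sum(up^2)) < 1e-8) up <- c(1, 0, 0) - sum(c(1, 0, 0) * e1) * e1
  e3 <- up / sqrt(sum(up^2))
  e2 <- cross3(e3, e1)

  xs <- seq(-fov_nm / 2, fov_nm / 2, by = pixel_nm)
  ys <- xs
  zs <- seq(-half_span * d_med, half_span * d_med, by = volume$voxel_size_nm)
  if (length(zs) == 0) zs <- 0

  view_at <- function(angle_deg) {
    th <- angle_deg * pi / 180
    f2 <- cos(th) * e2 + sin(th) * e3
    f3 <- -sin(th) * e2 + cos(th) * e3
    acc <- matrix(0, length(xs), length(ys))
    grid_xy <- as.matrix(expand.grid(x = xs, y = ys))
    for (z in zs) {
      pts <- cbind(
        mid[1] + grid_xy[, 1] * e1[1] + grid_xy[, 2] * f2[1] + z * f3[1],
        mid[2] + grid_xy[, 1] * e1[2] + grid_xy[, 2] * f2[2] + z * f3[2],
        mid[3] + grid_xy[, 1] * e1[3] + grid_xy[, 2] * f2[3] + z * f3[3]
      )
      vals <- interp_trilinear(volume, pts)
      if (anyNA(vals)) {
        stop(sprintf(
          "pair too close to the volume edge: views need a %.0f nm margin around the midpoint",
          fov_nm / 2
        ))
      }
      acc <- acc + matrix(vals, length(xs), length(ys))
    }
    acc / length(zs)
  }

  structure(
    list(view_0 = view_at(0), view_p45 = view_at(45),
         view_m45 = view_at(-45), half_span = half_span,
         pixel_nm = pixel_nm),
    class = "pair_views"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Automated corridor bridge score for a vesicle pair
#'
#' A simple densitometric stand-in for human scoring of synthetic
#' renders: the mean intensity inside the cylindrical corridor joining the
#' pair's nearest surface points (radius `rod_radius_nm`) is compared with
#' the mean of a surrounding background annulus, in units of the
#' background standard deviation. Higher scores are more bridge-like;
#' a threshold of 2 separates rendered bridged from unbridged pairs at
#' moderate noise.
#'
#' @param volume A [tomo_volume()].
#' @param c1,c2 Centers (nm).
#' @param r1,r2 Radii (nm).
#' @param rod_radius_nm Corridor radius.
#' @param shell_margin_nm Half thickness of the rendered membrane shell;
#'   samples closer than this (plus one voxel) to either sphere surface
#'   are excluded from both regions.
#' @param other_centers,other_radii Optional centers (rows) and radii of
#'   the remaining vesicles; samples inside or on their shells are
#'   excluded too (an observer discounts density belonging to a third
#'   vesicle sitting in the gap).
#' @return A single dimensionless score.
#' @export
corridor_bridge_score <- function(volume, c1, c2, r1, r2,
                                  rod_radius_nm = 3,
                                  shell_margin_nm = 2,
                                  other_centers = NULL,
                                  other_radii = NULL) {
  stopifnot(inherits(volume, "tomo_volume"))
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  u <- c2 - c1
  len <- sqrt(sum(u^2))
  gap <- len - r1 - r2
  if (len == 0 || gap <= 0) {
    stop("degenerate pair geometry: surfaces touch or centers coincide")
  }
  u <- u / len
  p1 <- c1 + u * r1
  p2 <- c2 - u * r2
  step <- volume$voxel_size_nm / 2
  # keep samples clear of the membrane shells (half thickness plus the
  # trilinear support), otherwise shell darkness leaks into every score
  margin <- shell_margin_nm + volume$voxel_size_nm
  clear_of_shells <- function(pts) {
    keep <- sqrt(rowSums(sweep(pts, 2, c1)^2)) > r1 + margin &
      sqrt(rowSums(sweep(pts, 2, c2)^2)) > r2 + margin
    if (!is.null(other_centers) && length(other_radii) > 0) {
      oc <- rbind(other_centers)
      for (k in seq_len(nrow(oc))) {
        keep <- keep &
          sqrt(rowSums(sweep(pts, 2, oc[k, ])^2)) > other_radii[k] + margin
      }
    }
    keep
  }
  pts <- cylinder_points(p1, p2, rod_radius_nm, step)
  keep_c <- clear_of_shells(pts)
  if (!any(keep_c)) {
    # very narrow gap: fall back to the mid-gap disc
    t_mid <- rowSums(sweep(pts, 2, p1) %*% u)
    keep_c <- abs(t_mid - gap / 2) <= step
  }
  corridor <- interp_trilinear(volume, pts[keep_c, , drop = FALSE])
  # background: annulus around the corridor, clear of both membranes
  ann <- cylinder_points(p1, p2, 4 * rod_radius_nm, step)
  rad <- perp_radius(ann, p1, p2)
  keep <- rad > 2 * rod_radius_nm & clear_of_shells(ann)
  background <- interp_trilinear(volume, ann[keep, , drop = FALSE])
  corridor <- corridor[!is.na(corridor)]
  background <- background[!is.na(background)]
  if (!length(corridor) || length(background) < 8) {
    stop("degenerate pair geometry: corridor or background region is empty")
  }
  # median over the corridor: a genuine bridge rod darkens the corridor
  # along its whole length, while a rod or shell merely crossing it only
  # darkens a short stretch and leaves the median near background
  (mean(background) - stats::median(corridor)) /
    max(stats::sd(background), 1e-6)
}

cylinder_points <- function(p1, p2, radius, step) {
  seg <- p2 - p1
  len <- sqrt(sum(seg^2))
  e1 <- seg / len
  tmp <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- cross3(e1, tmp); e2 <- e2 / sqrt(sum(e2^2))
  e3 <- cross3(e1, e2)
  ts <- seq(0, len, by = step)
  rs <- seq(0, radius, by = step)
  angs <- seq(0, 2 * pi, length.out = 9)[-9]
  g <- expand.grid(t = ts, r = rs, a = angs)
  g <- g[g$r > 0 | g$a == 0, ]
  off <- outer(g$r * cos(g$a), e2) + outer(g$r * sin(g$a), e3)
  cbind(p1[1] + g$t * e1[1] + off[, 1],
        p1[2] + g$t * e1[2] + off[, 2],
        p1[3] + g$t * e1[3] + off[, 3])
}

perp_radius <- function(pts, p1, p2) {
  seg <- p2 - p1
  len2 <- sum(seg^2)
  rel <- sweep(pts, 2, p1)
  t <- (rel %*% seg) / len2
  proj <- cbind(p1[1] + t * seg[1], p1[2] + t * seg[2], p1[3] + t * seg[3])
  sqrt(rowSums((pts - proj)^2))
}

#' Score all pairs of a table against a rendered volume
#'
#' Convenience wrapper applying [corridor_bridge_score()] to every row of
#' a pair table (e.g. from [enumerate_pairs()]), skipping touching pairs
#' (score `NA`: bridge presence is unjudgeable when surfaces meet).
#'
#' @param volume A [tomo_volume()].
#' @param cloud The owning [vesicle_cloud()].
#' @param pairs A pair table with `id_i`, `id_j`.
#' @return `pairs` with an added `auto_score` column.
#' @export
score_pairs_auto <- function(volume, cloud, pairs) {
  v <- cloud$vesicles
  scores <- purrr::map_dbl(seq_len(nrow(pairs)), function(k) {
    a <- match(pairs$id_i[k], v$id)
    b <- match(pairs$id_j[k], v$id)
    c1 <- c(v$x_nm[a], v$y_nm[a], v$z_nm[a])
    c2 <- c(v$x_nm[b], v$y_nm[b], v$z_nm[b])
    if (sqrt(sum((c2 - c1)^2)) - v$radius_nm[a] - v$radius_nm[b] <= 0) {
      return(NA_real_)
    }
    other <- setdiff(seq_len(nrow(v)), c(a, b))
    # only vesicles near the pair midpoint can intrude on the corridor
    mid <- (c1 + c2) / 2
    near <- other[sqrt((v$x_nm[other] - mid[1])^2 +
                         (v$y_nm[other] - mid[2])^2 +
                         (v$z_nm[other] - mid[3])^2) <
                    v$radius_nm[other] + sum((c2 - c1)^2)^0.5]
    tryCatch(
      corridor_bridge_score(
        volume, c1, c2, v$radius_nm[a], v$radius_nm[b],
        other_centers = as.matrix(v[near, c("x_nm", "y_nm", "z_nm")]),
        other_radii = v$radius_nm[near]
      ),
      error = function(e) NA_real_
    )
  })
  pairs$auto_score <- scores
  pairs
}

#' Read / write MRC (mode 2) volumes
#'
#' Minimal codec for the MRC2014 interchange format, mode 2 (32-bit
#' float), little-endian: the standard 1024-byte header followed by the
#' raw voxel grid. Voxel size is taken from the cell dimensions
#' (Angstrom) divided by the grid size.
#'
#' @param path File path.
#' @return `read_mrc()` returns a [tomo_volume()]; `write_mrc()` returns
#'   `path` invisibly.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", 3, size = 4, endian = "little")
  maporder <- readBin(con, "integer", 3, size = 4, endian = "little")
  stats3 <- readBin(con, "numeric", 3, size = 4, endian = "little")
  rest <- readBin(con, "integer", 2, size = 4, endian = "little")
  extra <- readBin(con, "integer", 25, size = 4, endian = "little")
  origin <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "raw", 1024 - 4 * 52)
  nx <- ints1[1]; ny <- ints1[2]; nz <- ints1[3]
  if (ints1[4] != 2) stop("only MRC mode 2 (float32) is supported")
  data <- readBin(con, "numeric", nx * ny * nz, size = 4, endian = "little")
  voxel <- if (ints1[8] > 0) cella[1] / 10 / ints1[8] else 1
  tomo_volume(array(data, dim = c(nx, ny, nz)), voxel, origin / 10)
}

#' @rdname read_mrc
#' @param volume A [tomo_volume()].
#' @export
write_mrc <- function(volume, path) {
  stopifnot(inherits(volume, "tomo_volume"))
  d <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(d * volume$voxel_size_nm * 10, 90, 90, 90)), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(volume$data), max(volume$data),
                        mean(volume$data))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little")
  writeBin(integer(25), con, size = 4, endian = "little")
  writeBin(as.numeric(volume$origin_nm * 10), con, size = 4,
           endian = "little")
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  writeBin(as.numeric(stats::sd(volume$data)), con, size = 4,
           endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(volume$data), con, size = 4, endian = "little")
  invisible(path)
}
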