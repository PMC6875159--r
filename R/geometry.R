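#' Normalized surface-to-surface separation of a vesicle pair
#'
#' Separation is the gap between the two sphere surfaces -- center distance
#' minus both radii -- divided by the cloud's median vesicle diameter. This
#' is the quantity a bridge physically spans; it is negative when the
#' spheres overlap and zero when they touch.
#'
#' @param c1,c2 Numeric length-3 centers (nm), or matrices with one row per
#'   vesicle for vectorized use.
#' @param r1,r2 Radii (nm).
#' @param d_med Median vesicle diameter (nm) of the owning cloud; must be
#'   > 0.
#' @return Dimensionless separation(s) in median-diameter units.
#' @export
#' @examples
#' pair_separation(c(0, 0, 0), c(40, 0, 0), 18, 18, 40)  # 0.1
pair_separation <- function(c1, c2, r1, r2, d_med) {
  stopifnot(d_med > 0)
  c1 <- rbind(c1); c2 <- rbind(c2)
  d <- sqrt(rowSums((c1 - c2)^2))
  as.numeric((d - r1 - r2) / d_med)
}

#' Z-angle of a vesicle pair
#'
#' The angle between the axis through both centers and the horizontal
#' plane of the tissue slice (the x-y plane), in degrees within \[0, 90\].
#' Pairs oriented steeply out of plane suffer missing-wedge degradation in
#' tomograms and are excluded from high-confidence surveys.
#'
#' @inheritParams pair_separation
#' @return Angle(s) in degrees.
#' @export
#' @examples
#' z_angle(c(0, 0, 0), c(10, 0, 10))  # 45
z_angle <- function(c1, c2) {
  c1 <- rbind(c1); c2 <- rbind(c2)
  delta <- c2 - c1
  norm <- sqrt(rowSums(delta^2))
  if (any(norm == 0)) stop("z_angle is undefined for identical centers")
  as.numeric(asin(pmin(1, abs(delta[, 3]) / norm)) * 180 / pi)
}

#' All unordered vesicle pairs of a cloud, with geometry
#'
#' The workhorse table behind surveys, histograms and the overlap
#' analysis: every unordered pair (canonically ordered `id_i < id_j`) with
#' its center distance, normalized surface separation, Z-angle, midpoint
#' and docked status.
#'
#' @param cloud A [vesicle_cloud()].
#' @param max_separation Optional pre-filter: keep pairs with
#'   `separation <= max_separation` (median-diameter units).
#' @return A tibble with columns `id_i`, `id_j`, `center_distance_nm`,
#'   `separation`, `z_angle_deg`, `touching`, `docked_status`
#'   (`"neither"`, `"one"`, `"both"`), `mid_x_nm`, `mid_y_nm`, `mid_z_nm`.
#' @export
vesicle_pairs <- function(cloud, max_separation = NULL) {
  stopifnot(inherits(cloud, "vesicle_cloud"))
  v <- cloud$vesicles
  n <- nrow(v)
  if (n < 2) return(empty_pair_table())
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  ci <- as.matrix(v[i, c("x_nm", "y_nm", "z_nm")])
  cj <- as.matrix(v[j, c("x_nm", "y_nm", "z_nm")])
  d_med <- median_diameter(cloud)
  dist_nm <- sqrt(rowSums((ci - cj)^2))
  sep <- (dist_nm - v$radius_nm[i] - v$radius_nm[j]) / d_med
  mid <- (ci + cj) / 2
  docked_n <- as.integer(v$docked[i]) + as.integer(v$docked[j])
  out <- tibble::tibble(
    id_i = pmin(v$id[i], v$id[j]),
    id_j = pmax(v$id[i], v$id[j]),
    center_distance_nm = dist_nm,
    separation = sep,
    z_angle_deg = z_angle(ci, cj),
    touching = sep <= 0,
    docked_status = c("neither", "one", "both")[docked_n + 1L],
    mid_x_nm = mid[, 1], mid_y_nm = mid[, 2], mid_z_nm = mid[, 3]
  )
  out <- dplyr::arrange(out, .data$id_i, .data$id_j)
  if (!is.null(max_separation)) {
    out <- dplyr::filter(out, .data$separation <= max_separation)
  }
  out
}

empty_pair_table <- function() {
  tibble::tibble(
    id_i = integer(), id_j = integer(), center_distance_nm = numeric(),
    separation = numeric(), z_angle_deg = numeric(), touching = logical(),
    docked_status = character(), mid_x_nm = numeric(), mid_y_nm = numeric(),
    mid_z_nm = numeric()
  )
}

#' Neighbor counts per vesicle
#'
#' A neighbor is another vesicle within `cutoff` median diameters of
#' surface separation (default 0.5, the working definition of a
#' neighboring pair).
#'
#' @param cloud A [vesicle_cloud()].
#' @param cutoff Separation cutoff in median-diameter units; must be > 0.
#' @return A tibble with columns `id` and `n_neighbors`, one row per
#'   vesicle, carrying the across-vesicle mean in attribute
#'   `mean_neighbors` (also returned by [mean_neighbors()]).
#' @export
neighbor_counts <- function(cloud, cutoff = 0.5) {
  stopifnot(inherits(cloud, "vesicle_cloud"), cutoff > 0)
  v <- cloud$vesicles
  pairs <- vesicle_pairs(cloud)
  close <- dplyr::filter(pairs, .data$separation <= cutoff)
  tallies <- table(factor(c(close$id_i, close$id_j), levels = v$id))
  out <- tibble::tibble(id = v$id, n_neighbors = as.integer(tallies))
  attr(out, "mean_neighbors") <- if (nrow(out) > 0) mean(out$n_neighbors) else NA_real_
  out
}

#' @rdname neighbor_counts
#' @param counts Output of `neighbor_counts()`.
#' @export
mean_neighbors <- function(counts) {
  attr(counts, "mean_neighbors") %||% mean(counts$n_neighbors)
}

#' Volumetric fraction of a cloud within a box
#'
#' Vesicle crowding, measured as the summed sphere volumes of all vesicles
#' whose centers lie in `box`, divided by the box volume. Spheres are
#' counted whole by center membership; no partial-volume clipping at the
#' box faces.
#'
#' @param cloud A [vesicle_cloud()].
#' @param box A 2 x 3 bounds matrix; defaults to the cloud bounds.
#' @return Dimensionless fraction.
#' @export
volumetric_fraction <- function(cloud, box = cloud$bounds) {
  stopifnot(inherits(cloud, "vesicle_cloud"))
  box <- validate_bounds(box)
  vol_box <- prod(box["max", ] - box["min", ])
  if (vol_box <= 0) stop("box volume must be > 0")
  v <- cloud$vesicles
  if (nrow(v) == 0) return(0)
  coords <- as.matrix(v[, c("x_nm", "y_nm", "z_nm")])
  inside <- centers_in_box(coords, box)
  sum(4 / 3 * pi * v$radius_nm[inside]^3) / vol_box
}

#' Distance from pair midpoints to the nearest docked vesicle
#'
#' For each pair, the distance between the pair's geometric center and the
#' center of the closest docked vesicle, in median-diameter units. Used to
#' profile bridge probability against proximity to the active zone.
#'
#' @param pairs A pair table from [vesicle_pairs()] or
#'   [enumerate_pairs()].
#' @param cloud The owning [vesicle_cloud()]; must contain at least one
#'   docked vesicle.
#' @return `pairs` with an added column `docked_distance` (dimensionless).
#' @export
nearest_docked_distance <- function(pairs, cloud) {
  stopifnot(inherits(cloud, "vesicle_cloud"))
  v <- cloud$vesicles
  docked <- v[v$docked, , drop = FALSE]
  if (nrow(docked) == 0) stop("cloud contains no docked vesicles")
  dc <- as.matrix(docked[, c("x_nm", "y_nm", "z_nm")])
  mid <- as.matrix(pairs[, c("mid_x_nm", "mid_y_nm", "mid_z_nm")])
  d_med <- median_diameter(cloud)
  mins <- apply(mid, 1, function(m) {
    min(sqrt(colSums((t(dc) - m)^2)))
  })
  pairs$docked_distance <- if (nrow(pairs) > 0) mins / d_med else numeric(0)
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
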