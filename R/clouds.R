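#' Construct a vesicle cloud
#'
#' A vesicle cloud is the in-memory stand-in for one tomogram: a table of
#' spheres (center, radius, docked flag) together with an axis-aligned
#' bounding box, an optional active-zone membrane plane, and the per-cloud
#' median vesicle diameter, which is the universal normalized length unit
#' for all downstream analysis. All coordinates and radii are in nm; z is
#' the slab normal (perpendicular to the tissue section).
#'
#' @param vesicles A data frame with columns `id` (integer, unique),
#'   `x_nm`, `y_nm`, `z_nm` (finite), `radius_nm` (> 0) and optionally
#'   `docked` (logical or 0/1; defaults to `FALSE`).
#' @param bounds A 2 x 3 numeric matrix (rows `min`, `max`; columns
#'   `x`, `y`, `z`) in nm. Defaults to the tight bounding box of the
#'   centers. All centers must lie within `bounds`.
#' @param membrane_plane Optional list with numeric length-3 elements
#'   `point` and `normal` (nm) describing the active-zone plasma membrane.
#' @param label Free-text label (genotype, staining group, tomogram id).
#' @param median_diameter_nm Optional median diameter to inherit (used by
#'   [hyperrect_subset()] so a subset keeps its parent's length unit).
#'   Defaults to the median of `2 * radius_nm` (even counts: mean of the
#'   middle two).
#'
#' @return An object of class `vesicle_cloud`: a list with elements
#'   `vesicles` (tibble), `bounds`, `membrane_plane`, `label`,
#'   `median_diameter_nm`.
#' @seealso [median_diameter()], [hyperrect_subset()], [vesicle_pairs()]
#' @export
#' @examples
#' ves <- tibble::tibble(
#'   id = 0:2, x_nm = c(0, 40, 80), y_nm = 0, z_nm = 0,
#'   radius_nm = c(18, 19, 20), docked = c(TRUE, FALSE, FALSE)
#' )
#' cl <- vesicle_cloud(ves, label = "WT")
#' median_diameter(cl)
vesicle_cloud <- function(vesicles, bounds = NULL, membrane_plane = NULL,
                          label = "", median_diameter_nm = NULL) {
  stopifnot(is.data.frame(vesicles))
  needed <- c("id", "x_nm", "y_nm", "z_nm", "radius_nm")
  missing_cols <- setdiff(needed, names(vesicles))
  if (length(missing_cols) > 0) {
    stop("vesicles is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  vesicles <- tibble::as_tibble(vesicles)
  if (!"docked" %in% names(vesicles)) vesicles$docked <- FALSE
  vesicles$docked <- as.logical(vesicles$docked)
  vesicles$id <- as.integer(vesicles$id)
  if (anyDuplicated(vesicles$id)) stop("vesicle ids must be unique")
  coords <- as.matrix(vesicles[, c("x_nm", "y_nm", "z_nm")])
  if (!all(is.finite(coords))) stop("vesicle centers must be finite")
  if (any(!is.finite(vesicles$radius_nm)) || any(vesicles$radius_nm <= 0)) {
    stop("vesicle radii must be finite and > 0")
  }
  if (is.null(bounds)) {
    if (nrow(vesicles) == 0) stop("bounds must be given for an empty cloud")
    bounds <- rbind(min = apply(coords, 2, min), max = apply(coords, 2, max))
    colnames(bounds) <- c("x", "y", "z")
  }
  bounds <- validate_bounds(bounds)
  if (nrow(vesicles) > 0) {
    inside <- centers_in_box(coords, bounds)
    if (!all(inside)) {
      stop(sum(!inside), " vesicle center(s) lie outside the cloud bounds")
    }
  }
  if (!is.null(membrane_plane)) {
    stopifnot(is.list(membrane_plane),
              length(membrane_plane$point) == 3,
              length(membrane_plane$normal) == 3)
    membrane_plane$normal <- membrane_plane$normal /
      sqrt(sum(membrane_plane$normal^2))
  }
  if (is.null(median_diameter_nm)) {
    median_diameter_nm <- if (nrow(vesicles) > 0) {
      stats::median(2 * vesicles$radius_nm)
    } else {
      NA_real_
    }
  }
  structure(
    list(
      vesicles = vesicles,
      bounds = bounds,
      membrane_plane = membrane_plane,
      label = as.character(label),
      median_diameter_nm = median_diameter_nm
    ),
    class = "vesicle_cloud"
  )
}

validate_bounds <- function(bounds) {
  bounds <- as.matrix(bounds)
  if (!all(dim(bounds) == c(2, 3))) {
    stop("bounds must be a 2 x 3 matrix (rows min/max, columns x/y/z)")
  }
  rownames(bounds) <- c("min", "max")
  colnames(bounds) <- c("x", "y", "z")
  if (any(bounds["max", ] < bounds["min", ])) {
    stop("bounds max must be >= min on every axis")
  }
  bounds
}

#' Build an axis-aligned box
#'
#' @param xlim,ylim,zlim Length-2 numeric vectors (nm).
#' @return A 2 x 3 matrix understood by [vesicle_cloud()],
#'   [volumetric_fraction()] and [hyperrect_subset()].
#' @export
box_bounds <- function(xlim, ylim, zlim) {
  validate_bounds(rbind(
    min = c(xlim[1], ylim[1], zlim[1]),
    max = c(xlim[2], ylim[2], zlim[2])
  ))
}

centers_in_box <- function(coords, box, tol = 1e-9) {
  coords[, 1] >= box["min", "x"] - tol & coords[, 1] <= box["max", "x"] + tol &
  coords[, 2] >= box["min", "y"] - tol & coords[, 2] <= box["max", "y"] + tol &
  coords[, 3] >= box["min", "z"] - tol & coords[, 3] <= box["max", "z"] + tol
}

#' @export
print.vesicle_cloud <- function(x, ...) {
  cat("<vesicle_cloud>", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n")
  cat("  vesicles:", nrow(x$vesicles),
      sprintf("(%d docked)", sum(x$vesicles$docked)), "\n")
  cat(sprintf("  median diameter: %.2f nm\n", x$median_diameter_nm))
  b <- x$bounds
  cat(sprintf("  bounds: [%.0f,%.0f] x [%.0f,%.0f] x [%.0f,%.0f] nm\n",
              b[1, 1], b[2, 1], b[1, 2], b[2, 2], b[1, 3], b[2, 3]))
  invisible(x)
}

#' Median vesicle diameter of a cloud
#'
#' The per-tomogram median of vesicle diameters is the standard measure of
#' length for comparisons across tomograms: separations, bridge lengths,
#' neighbor cutoffs and survey margins are all expressed in units of it.
#'
#' @param cloud A [vesicle_cloud()].
#' @param recompute Recompute from the current vesicle table instead of the
#'   cached value (a subset cloud caches its parent's).
#' @return Median diameter in nm. Even-length sets use the mean of the
#'   middle two diameters.
#' @export
median_diameter <- function(cloud, recompute = FALSE) {
  stopifnot(inherits(cloud, "vesicle_cloud"))
  if (nrow(cloud$vesicles) == 0) stop("cannot take the median diameter of an empty cloud")
  if (recompute) stats::median(2 * cloud$vesicles$radius_nm) else cloud$median_diameter_nm
}

#' Subset a cloud to a hyperrectangle
#'
#' Keeps the vesicles whose centers lie inside `box` (membership is by
#' center; spheres are never clipped). The subset inherits the parent
#' cloud's median diameter so normalized quantities stay in the parent's
#' length unit.
#'
#' @param cloud A [vesicle_cloud()].
#' @param box A 2 x 3 bounds matrix (see [box_bounds()]) inside the cloud
#'   bounds.
#' @return A `vesicle_cloud` (possibly with zero vesicles) with
#'   `bounds = box`.
#' @export
hyperrect_subset <- function(cloud, box) {
  stopifnot(inherits(cloud, "vesicle_cloud"))
  box <- validate_bounds(box)
  if (any(box["min", ] < cloud$bounds["min", ] - 1e-9) ||
      any(box["max", ] > cloud$bounds["max", ] + 1e-9)) {
    stop("box must lie inside the cloud bounds")
  }
  coords <- as.matrix(cloud$vesicles[, c("x_nm", "y_nm", "z_nm")])
  keep <- if (nrow(coords) > 0) centers_in_box(coords, box) else logical(0)
  vesicle_cloud(
    cloud$vesicles[keep, , drop = FALSE],
    bounds = box,
    membrane_plane = cloud$membrane_plane,
    label = cloud$label,
    median_diameter_nm = cloud$median_diameter_nm
  )
}

#' Read / write vesicle coordinate tables
#'
#' The on-disk dialect is a delimited text table (comma or tab) with header
#' columns `id`, `x_nm`, `y_nm`, `z_nm`, `radius_nm`, `docked` (0/1) and
#' 0-based ids. Cloud metadata (bounds, membrane plane, label, voxel size)
#' travels in a YAML sidecar.
#'
#' @param path File path. `read_vesicle_table()` sniffs the delimiter from
#'   the extension (`.tsv`/`.txt` = tab, otherwise comma).
#' @param metadata Optional path to a YAML metadata file with keys `bounds`
#'   (list of `xlim`, `ylim`, `zlim`), `membrane_plane` (`point`,
#'   `normal`), `label`.
#' @return `read_vesicle_table()` returns a [vesicle_cloud()];
#'   `write_vesicle_table()` returns `path` invisibly.
#' @export
read_vesicle_table <- function(path, metadata = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  meta <- list(bounds = NULL, membrane_plane = NULL, label = "")
  if (!is.null(metadata)) {
    y <- yaml::read_yaml(metadata)
    if (!is.null(y$bounds)) {
      meta$bounds <- box_bounds(unlist(y$bounds$xlim), unlist(y$bounds$ylim),
                                unlist(y$bounds$zlim))
    }
    if (!is.null(y$membrane_plane)) {
      meta$membrane_plane <- list(point = unlist(y$membrane_plane$point),
                                  normal = unlist(y$membrane_plane$normal))
    }
    if (!is.null(y$label)) meta$label <- y$label
  }
  vesicle_cloud(tab, bounds = meta$bounds,
                membrane_plane = meta$membrane_plane, label = meta$label)
}

#' @rdname read_vesicle_table
#' @param cloud A [vesicle_cloud()] to write.
#' @export
write_vesicle_table <- function(cloud, path, metadata = NULL) {
  stopifnot(inherits(cloud, "vesicle_cloud"))
  tab <- cloud$vesicles
  tab$docked <- as.integer(tab$docked)
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  readr::write_delim(tab, path, delim = delim)
  if (!is.null(metadata)) {
    b <- cloud$bounds
    y <- list(
      label = cloud$label,
      bounds = list(xlim = as.numeric(b[, "x"]), ylim = as.numeric(b[, "y"]),
                    zlim = as.numeric(b[, "z"]))
    )
    if (!is.null(cloud$membrane_plane)) {
      y$membrane_plane <- list(
        point = as.numeric(cloud$membrane_plane$point),
        normal = as.numeric(cloud$membrane_plane$normal)
      )
    }
    yaml::write_yaml(y, metadata)
  }
  invisible(path)
}
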