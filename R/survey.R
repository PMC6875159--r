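#' Pair-survey eligibility criteria
#'
#' The two surveys of the study are preset: `survey_criteria(1)` is the
#' broad initial survey (separation up to 1.5 median diameters, any
#' Z-angle, 1.5-diameter edge margin) and `survey_criteria(2)` the
#' high-confidence survey (separation <= 0.5, Z-angle <= 25 degrees,
#' 0.5-diameter margin). Every threshold is inclusive. At most
#' `max_pairs_per_cloud` pairs are drawn per tomogram (seeded uniform
#' subsample) and tomograms yielding fewer than `min_pairs_per_cloud`
#' eligible pairs are flagged excluded.
#'
#' @param survey 1 or 2 to take a preset, or `NULL` to set fields
#'   directly.
#' @param max_separation Maximum normalized surface separation.
#' @param max_z_angle Maximum Z-angle in degrees, in (0, 90].
#' @param edge_margin Margin from the artificial slab edges, in
#'   median-diameter units (measured from the vesicle surface); a pair is
#'   excluded only when *neither* vesicle clears the margin.
#' @param max_pairs_per_cloud,min_pairs_per_cloud Per-cloud sample limits.
#' @param seed Integer seed for the subsample.
#' @return A list of class `survey_criteria`.
#' @export
survey_criteria <- function(survey = NULL, max_separation = 0.5,
                            max_z_angle = 25, edge_margin = 0.5,
                            max_pairs_per_cloud = 150,
                            min_pairs_per_cloud = 50, seed = 1L) {
  if (!is.null(survey)) {
    if (survey == 1) {
      max_separation <- 1.5; max_z_angle <- 90; edge_margin <- 1.5
    } else if (survey == 2) {
      max_separation <- 0.5; max_z_angle <- 25; edge_margin <- 0.5
    } else {
      stop("survey must be 1 or 2")
    }
  }
  stopifnot(max_separation > 0, max_z_angle > 0, max_z_angle <= 90,
            edge_margin >= 0, max_pairs_per_cloud >= 1,
            min_pairs_per_cloud >= 0)
  structure(
    list(max_separation = max_separation, max_z_angle = max_z_angle,
         edge_margin = edge_margin,
         max_pairs_per_cloud = as.integer(max_pairs_per_cloud),
         min_pairs_per_cloud = as.integer(min_pairs_per_cloud),
         seed = as.integer(seed)),
    class = "survey_criteria"
  )
}

#' @rdname survey_criteria
#' @param path YAML file with the criteria fields.
#' @export
read_survey_criteria <- function(path) {
  do.call(survey_criteria, c(list(survey = NULL), yaml::read_yaml(path)))
}

# clearance of each vesicle surface from the slab's top/bottom faces,
# in median-diameter units
edge_clearance <- function(cloud) {
  v <- cloud$vesicles
  d_med <- median_diameter(cloud)
  zmin <- cloud$bounds["min", "z"]
  zmax <- cloud$bounds["max", "z"]
  (pmin(v$z_nm - zmin, zmax - v$z_nm) - v$radius_nm) / d_med
}

#' Enumerate survey-eligible vesicle pairs
#'
#' Applies the separation, Z-angle and edge-margin filters of `criteria`
#' to every unordered pair of the cloud. The artificial edges created by
#' tissue sectioning are taken as the slab's top and bottom bounding
#' planes; a pair is dropped only when neither of its vesicles clears the
#' margin. If more than `max_pairs_per_cloud` pairs survive, a seeded
#' uniform subsample of exactly that many is kept.
#'
#' @param cloud A [vesicle_cloud()].
#' @param criteria A [survey_criteria()].
#' @return A tibble of pair records (the [vesicle_pairs()] geometry plus
#'   `cloud_label`), with attributes `excluded` (logical: below the
#'   per-cloud minimum) and `n_eligible` (count before subsampling).
#' @export
enumerate_pairs <- function(cloud, criteria = survey_criteria(2)) {
  stopifnot(inherits(cloud, "vesicle_cloud"),
            inherits(criteria, "survey_criteria"))
  pairs <- vesicle_pairs(cloud)
  v <- cloud$vesicles
  clear <- edge_clearance(cloud)
  clear_of <- stats::setNames(clear, v$id)
  keep <- pairs$separation <= criteria$max_separation &
    pairs$z_angle_deg <= criteria$max_z_angle &
    (clear_of[as.character(pairs$id_i)] >= criteria$edge_margin |
     clear_of[as.character(pairs$id_j)] >= criteria$edge_margin)
  out <- pairs[keep, , drop = FALSE]
  n_eligible <- nrow(out)
  if (n_eligible > criteria$max_pairs_per_cloud) {
    idx <- with_seed(criteria$seed,
                     sample.int(n_eligible, criteria$max_pairs_per_cloud))
    out <- out[sort(idx), , drop = FALSE]
  }
  out$cloud_label <- cloud$label
  attr(out, "excluded") <- n_eligible < criteria$min_pairs_per_cloud
  attr(out, "n_eligible") <- n_eligible
  out
}

#' Build a blinded randomized presentation manifest
#'
#' Pools pair sets from several clouds, shuffles them globally (seeded)
#' and assigns stable anonymous presentation ids. The presentation table
#' carries no cloud, group or genotype information; a sealed key table
#' maps presentation ids back to their cloud and pair.
#'
#' @param pair_sets A list of pair tables from [enumerate_pairs()] (each
#'   must carry a distinct `cloud_label`), or a single combined table.
#' @param seed Integer seed for the shuffle.
#' @return A list of class `blind_manifest` with elements `presentation`
#'   (tibble: `presentation_id`) and `key` (tibble: `presentation_id`,
#'   `cloud_label`, `id_i`, `id_j`).
#' @export
blind_manifest <- function(pair_sets, seed = 1L) {
  if (is.data.frame(pair_sets)) pair_sets <- list(pair_sets)
  pooled <- dplyr::bind_rows(pair_sets)
  if (nrow(pooled) == 0) stop("no pairs to present")
  if (!"cloud_label" %in% names(pooled)) pooled$cloud_label <- ""
  dup <- duplicated(pooled[, c("cloud_label", "id_i", "id_j")])
  if (any(dup)) stop("duplicate pair ids across the pooled pair sets")
  ord <- with_seed(seed, sample.int(nrow(pooled)))
  pooled <- pooled[ord, , drop = FALSE]
  pid <- sprintf("P%05d", seq_len(nrow(pooled)))
  structure(
    list(
      presentation = tibble::tibble(presentation_id = pid),
      key = tibble::tibble(
        presentation_id = pid,
        cloud_label = pooled$cloud_label,
        id_i = pooled$id_i,
        id_j = pooled$id_j
      )
    ),
    class = "blind_manifest"
  )
}

#' @rdname blind_manifest
#' @param manifest A `blind_manifest`.
#' @param presentation_path,key_path CSV output paths (the key file is the
#'   sealed unblinding record; keep it away from observers).
#' @export
write_manifest <- function(manifest, presentation_path, key_path) {
  stopifnot(inherits(manifest, "blind_manifest"))
  readr::write_csv(manifest$presentation, presentation_path)
  readr::write_csv(manifest$key, key_path)
  invisible(manifest)
}

#' Ingest observer scores into pair records
#'
#' Joins a score table back through the manifest key onto pair records.
#' Scores use the five-point scale where 1 = "Certain" and 2 = "Likely"
#' count as bridges, 3 = "Can't tell" is retained as ambiguous, and 4/5
#' mean unlikely/certainly not. Observers may additionally flag pairs as
#' touching or mark image quality.
#'
#' @param manifest A [blind_manifest()].
#' @param scores A data frame with columns `presentation_id`, `score`
#'   (integer 1-5) and optionally `touching` (0/1) and `quality`
#'   (`"ok"`, `"bad"`, `"terrible"`). Every manifest id must be scored
#'   exactly once.
#' @param pairs The pooled pair table the manifest was built from (to
#'   recover geometry); optional.
#' @return A tibble with `presentation_id`, `cloud_label`, `id_i`,
#'   `id_j`, `score`, `bridged` (score in {1, 2}), `ambiguous`
#'   (score == 3), `touching`, `quality`, plus geometry columns when
#'   `pairs` is supplied.
#' @export
ingest_scores <- function(manifest, scores, pairs = NULL) {
  stopifnot(inherits(manifest, "blind_manifest"))
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) stop("score table is empty")
  if (!all(c("presentation_id", "score") %in% names(scores))) {
    stop("score table needs columns presentation_id and score")
  }
  unknown <- setdiff(scores$presentation_id, manifest$key$presentation_id)
  if (length(unknown) > 0) {
    stop("unknown presentation ids in score table: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  if (anyDuplicated(scores$presentation_id)) {
    stop("duplicate presentation ids in score table")
  }
  unscored <- setdiff(manifest$key$presentation_id, scores$presentation_id)
  if (length(unscored) > 0) {
    stop(length(unscored), " manifest pair(s) left unscored")
  }
  if (!all(scores$score %in% 1:5)) stop("scores must be integers 1-5")
  if (!"touching" %in% names(scores)) scores$touching <- FALSE
  if (!"quality" %in% names(scores)) scores$quality <- "ok"
  if (!all(scores$quality %in% c("ok", "bad", "terrible"))) {
    stop("quality must be one of ok, bad, terrible")
  }
  out <- dplyr::left_join(manifest$key, scores, by = "presentation_id")
  out$score <- as.integer(out$score)
  out$touching <- as.logical(out$touching)
  out$bridged <- out$score %in% c(1L, 2L)
  out$ambiguous <- out$score == 3L
  if (!is.null(pairs)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(pairs, dplyr::any_of(c(
        "cloud_label", "id_i", "id_j", "center_distance_nm", "separation",
        "z_angle_deg", "docked_status"
      ))),
      by = c("cloud_label", "id_i", "id_j")
    )
  }
  out
}
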