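#' Run the end-to-end synthetic bridge-analysis pipeline
#'
#' Chains every stage of the analysis on simulated data: generate clouds
#' of bridged chains, apply rigid-bridge fixation shrinkage, enumerate
#' survey-eligible pairs, judge each pair for a bridge (either by
#' rendering a synthetic volume and thresholding the automated corridor
#' score, or directly from the generative bridge labels), and compute the
#' bridge statistics. All randomness flows from `seed`.
#'
#' @param sim_config A [simulation_config()] describing each cloud.
#' @param n_clouds Number of independent clouds (stand-ins for
#'   tomograms).
#' @param criteria A [survey_criteria()].
#' @param shrink_fraction,rigid_bridges Passed to [apply_shrinkage()];
#'   default from the config.
#' @param scoring `"render"` scores pairs on a rendered volume with
#'   [corridor_bridge_score()]; `"oracle"` uses the generative labels.
#' @param voxel_size_nm,noise_sd Render settings for `scoring = "render"`.
#' @param score_threshold Corridor score at or above which a pair is
#'   called bridged.
#' @param seed Master seed; per-cloud seeds are derived from it.
#' @return A list of class `bridge_pipeline` with elements `records`
#'   (scored pair table across clouds), `clouds` (per-cloud summary:
#'   pairs, bridge probability, mean neighbors, estimated and true
#'   bridges per vesicle), `histogram` (pooled [separation_histogram()]
#'   of all pairs up to 1 median diameter), and the settings used.
#'   [glance()] summarizes the recovery.
#' @export
run_pipeline <- function(sim_config, n_clouds = 10,
                         criteria = survey_criteria(2),
                         shrink_fraction = NULL, rigid_bridges = TRUE,
                         scoring = c("render", "oracle"),
                         voxel_size_nm = 2, noise_sd = 0.05,
                         score_threshold = 2, seed = 1L) {
  stopifnot(inherits(sim_config, "simulation_config"), n_clouds >= 1)
  scoring <- match.arg(scoring)
  if (is.null(shrink_fraction)) shrink_fraction <- sim_config$shrink_fraction

  cloud_rows <- vector("list", n_clouds)
  record_rows <- vector("list", n_clouds)
  all_seps <- numeric(0)

  for (i in seq_len(n_clouds)) {
    seed_i <- as.integer(seed) * 1000L + i
    cfg <- sim_config
    cfg$seed <- seed_i
    sim <- generate_cloud(cfg)
    shr <- apply_shrinkage(sim, shrink_fraction, rigid_bridges)
    label <- sprintf("sim%03d", i)
    shr$cloud$label <- label

    crit <- criteria
    crit$seed <- seed_i
    pairs <- enumerate_pairs(shr$cloud, crit)
    truth <- chain_bridges(shr)
    pairs <- dplyr::left_join(
      pairs,
      dplyr::mutate(truth[, c("id_i", "id_j")], true_bridged = TRUE),
      by = c("id_i", "id_j")
    )
    pairs$true_bridged <- !is.na(pairs$true_bridged)

    if (scoring == "render") {
      vol <- render_volume(shr$cloud, bridges = truth,
                           voxel_size_nm = voxel_size_nm,
                           noise_sd = noise_sd, seed = seed_i + 500L)
      pairs <- score_pairs_auto(vol, shr$cloud, pairs)
      pairs$bridged <- !is.na(pairs$auto_score) &
        pairs$auto_score >= score_threshold
      pairs <- pairs[!is.na(pairs$auto_score), , drop = FALSE]
    } else {
      pairs$bridged <- pairs$true_bridged
    }

    counts <- neighbor_counts(shr$cloud, cutoff = 0.5)
    nbar <- mean_neighbors(counts)
    p_hat <- if (nrow(pairs) > 0) mean(pairs$bridged) else NA_real_
    n_ves <- nrow(shr$cloud$vesicles)
    cloud_rows[[i]] <- tibble::tibble(
      cloud_label = label,
      n_vesicles = n_ves,
      n_pairs = nrow(pairs),
      excluded = attr(pairs, "excluded") %||% FALSE,
      p_bridge = p_hat,
      mean_neighbors = nbar,
      bpv_estimate = bridges_per_vesicle(p_hat, nbar),
      bpv_true = 2 * nrow(truth) / n_ves
    )
    record_rows[[i]] <- pairs
    all_seps <- c(all_seps,
                  vesicle_pairs(shr$cloud, max_separation = 1)$separation)
  }

  structure(
    list(
      records = dplyr::bind_rows(record_rows),
      clouds = dplyr::bind_rows(cloud_rows),
      histogram = separation_histogram(all_seps, bin_width = 0.05,
                                       max_separation = 1),
      sim_config = sim_config,
      criteria = criteria,
      scoring = scoring,
      shrink_fraction = shrink_fraction,
      seed = as.integer(seed)
    ),
    class = "bridge_pipeline"
  )
}

#' @export
print.bridge_pipeline <- function(x, ...) {
  g <- glance(x)
  cat("<bridge_pipeline>", nrow(x$clouds), "clouds,", nrow(x$records),
      "scored pairs (", x$scoring, "scoring )\n")
  cat(sprintf("  bridges/vesicle: estimated %.2f vs generative %.2f\n",
              g$bpv_estimate, g$bpv_true))
  invisible(x)
}

#' Recovery summary of a pipeline run
#' @param x A `bridge_pipeline`.
#' @param ... Unused.
#' @method glance bridge_pipeline
#' @export
glance.bridge_pipeline <- function(x, ...) {
  cl <- x$clouds[!x$clouds$excluded, , drop = FALSE]
  tibble::tibble(
    n_clouds = nrow(cl),
    n_pairs = sum(cl$n_pairs),
    median_p_bridge = stats::median(cl$p_bridge),
    bpv_estimate = mean(cl$bpv_estimate),
    bpv_true = mean(cl$bpv_true),
    bpv_error = mean(cl$bpv_estimate) - mean(cl$bpv_true)
  )
}

#' Per-cloud results of a pipeline run
#' @param x A `bridge_pipeline`.
#' @param ... Unused.
#' @method tidy bridge_pipeline
#' @export
tidy.bridge_pipeline <- function(x, ...) {
  x$clouds
}

#' Recompute the desk-scale printed quantities
#'
#' Evaluates every quantity of the analysis that derives from in-text
#' constants and counts -- chain-model link numbers, pair percentages,
#' the shrinkage and expansion factors implied by fixed vs unfixed
#' vesicle diameters, and the Yates-corrected chi-square on the
#' short-distance WT vs knockout table -- and compares each with its
#' printed value.
#'
#' @return A tibble with columns `quantity`, `computed`, `printed`,
#'   `consistent`.
#' @export
reproduce_printed_numbers <- function() {
  checks <- list(
    list("chain_links_r4", chain_model_links(4), 1.5),
    list("chain_links_r2.6", round_half_up(chain_model_links(2.6), 1), 1.2),
    list("pct_dko_short_3_of_42", proportion_from_counts(3, 42), 7.1),
    list("pct_wt_short_41_of_112", proportion_from_counts(41, 112), 36.6),
    list("pct_dko_certain_3_of_165", proportion_from_counts(3, 165), 1.8),
    list("pct_wt_certain_18_of_372", proportion_from_counts(18, 372), 4.8),
    list("pct_overlap_bridged_71_of_306",
         proportion_from_counts(71, 306, 0), 23),
    list("pct_overlap_nonbridged_16_of_496",
         proportion_from_counts(16, 496, 0), 3),
    list("pct_overlap_matched_14_of_132",
         proportion_from_counts(14, 132, 0), 11),
    list("shrinkage_pct_39.6_vs_45.6",
         round_half_up(100 * (1 - 39.6 / 45.6), 0), 13),
    list("expansion_pct_45.6_over_39.6",
         round_half_up(100 * (45.6 / 39.6 - 1), 0), 15)
  )
  out <- purrr::map_dfr(checks, function(ch) {
    tibble::tibble(quantity = ch[[1]], computed = ch[[2]], printed = ch[[3]],
                   consistent = isTRUE(all.equal(ch[[2]], ch[[3]])))
  })
  p <- chi2_yates(matrix(c(3, 39, 41, 71), nrow = 2, byrow = TRUE))$p_value
  dplyr::bind_rows(out, tibble::tibble(
    quantity = "chi2_yates_p_short_distance", computed = p, printed = 0.001,
    consistent = p < 0.001
  ))
}
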