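#' Chain-link model: mean bridges per vesicle
#'
#' For vesicles connected into chains of `r` members by `r - 1` bridges,
#' each bridge touches two vesicles, so the mean number of bridges per
#' vesicle is n = (2r - 2) / r: 0 for unconnected vesicles, 1.5 for
#' chains of four, approaching 2 for infinitely long chains.
#'
#' @param r Chain length (real, >= 1; non-integer values express a mean
#'   chain length).
#' @return Mean bridges per vesicle.
#' @export
#' @examples
#' chain_model_links(4)    # 1.5
#' chain_model_links(2.6)  # ~1.23
chain_model_links <- function(r) {
  if (any(r < 1)) stop("chain length r must be >= 1")
  (2 * r - 2) / r
}

#' Per-cloud bridge probability with group summary
#'
#' The study's tomogram-level estimate: for each cloud, the number of
#' pairs judged bridged divided by the number of pairs analyzed; the
#' group summary is the median across clouds with the middle two
#' quartiles (the box convention of the figures).
#'
#' @param records A scored pair table (e.g. from [ingest_scores()]) with
#'   columns `cloud_label` and `bridged`.
#' @param min_pairs Clouds with fewer pairs are dropped with a warning.
#' @return A tibble of class `bridge_probability` with one row per cloud
#'   (`cloud_label`, `n_pairs`, `n_bridged`, `p_bridge`); the group
#'   median and quartiles are available through [glance()].
#' @export
bridge_probability_by_cloud <- function(records, min_pairs = 1) {
  stopifnot(all(c("cloud_label", "bridged") %in% names(records)))
  out <- records |>
    dplyr::group_by(.data$cloud_label) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_bridged = sum(.data$bridged),
      p_bridge = .data$n_bridged / .data$n_pairs,
      .groups = "drop"
    )
  small <- out$n_pairs < min_pairs
  if (any(small)) {
    warning(sum(small), " cloud(s) below the per-cloud pair minimum were dropped")
    out <- out[!small, , drop = FALSE]
  }
  class(out) <- c("bridge_probability", class(out))
  out
}

#' Group summary of per-cloud bridge probabilities
#' @param x A `bridge_probability` table.
#' @param ... Unused.
#' @method glance bridge_probability
#' @export
glance.bridge_probability <- function(x, ...) {
  q <- stats::quantile(x$p_bridge, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    n_clouds = nrow(x), median_p = q[2], q25 = q[1], q75 = q[3]
  )
}

#' Extrapolate bridges per vesicle
#'
#' Multiplies the probability that a neighboring pair is bridged by the
#' mean number of neighbors per vesicle -- the extrapolation used to
#' compare measured connectivity with the chain-link model.
#'
#' @param p_bridge Bridge probability per neighboring pair (>= 0).
#' @param mean_neighbors Mean neighbors per vesicle (>= 0).
#' @return Estimated bridges per vesicle.
#' @export
bridges_per_vesicle <- function(p_bridge, mean_neighbors) {
  stopifnot(all(p_bridge >= 0), all(mean_neighbors >= 0))
  p_bridge * mean_neighbors
}

#' Percentage from counts, rounded half-up
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials, > 0.
#' @param round_to Decimal places (half-up, matching printed convention).
#' @return Percentage.
#' @export
#' @examples
#' proportion_from_counts(3, 42)   # 7.1
#' proportion_from_counts(41, 112) # 36.6
proportion_from_counts <- function(k, n, round_to = 1) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(k < 0) || any(k > n)) stop("k must be within [0, n]")
  round_half_up(100 * k / n, round_to)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Wilson score interval with continuity correction
#'
#' Newcombe's continuity-corrected Wilson score interval for a binomial
#' proportion, the convention used for pooled docked/non-docked pair
#' proportions (default 90% confidence). Bounds are clamped to 0 when
#' `k = 0` and to 1 when `k = n`.
#'
#' @param k Successes.
#' @param n Trials, > 0.
#' @param confidence Confidence level in (0, 1).
#' @return A tibble of class `proportion_ci` with columns `k`, `n`,
#'   `estimate`, `lower`, `upper`, `confidence`.
#' @export
wilson_ci_continuity <- function(k, n, confidence = 0.90) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(k < 0) || any(k > n)) stop("k must be within [0, n]")
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be strictly between 0 and 1")
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  q <- 1 - p
  lower <- (2 * n * p + z^2 - 1 -
              z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) /
    (2 * (n + z^2))
  upper <- (2 * n * p + z^2 + 1 +
              z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) /
    (2 * (n + z^2))
  lower <- ifelse(k == 0, 0, pmax(0, lower))
  upper <- ifelse(k == n, 1, pmin(1, upper))
  out <- tibble::tibble(k = k, n = n, estimate = p, lower = lower,
                        upper = upper, confidence = confidence)
  class(out) <- c("proportion_ci", class(out))
  out
}

#' Tidy a proportion CI
#' @param x A `proportion_ci`.
#' @param ... Unused.
#' @method tidy proportion_ci
#' @export
tidy.proportion_ci <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Chi-square test with Yates continuity correction on a 2 x 2 table
#'
#' Wrapper around the standard continuity-corrected chi-square test of
#' independence, returning a tidy one-row result. All expected counts
#' must be positive.
#'
#' @param table A 2 x 2 matrix of counts (rows = groups, columns =
#'   outcome yes/no), or four counts `a, b, c, d` filled row-wise.
#' @return A tibble with `statistic`, `p_value`, `df`.
#' @export
#' @examples
#' chi2_yates(matrix(c(3, 39, 41, 71), nrow = 2, byrow = TRUE))
chi2_yates <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2, byrow = TRUE)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all marginals of the 2 x 2 table must be positive")
  }
  ht <- stats::chisq.test(table, correct = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter)
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Used for across-tomogram comparisons of per-cloud bridge
#' probabilities between groups. Two-sided.
#'
#' @param a,b Numeric samples (nonempty).
#' @return A tibble with `statistic` (the maximum ECDF difference) and
#'   `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ht <- suppressWarnings(stats::ks.test(a, b))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Histogram of pair separations
#'
#' Fractions of pairs per separation bin in median-diameter units, with a
#' dedicated "touching" bin for separations <= 0 and left-closed
#' right-open bins above it.
#'
#' @param pairs A pair table with a `separation` column, or a numeric
#'   vector of separations.
#' @param bin_width Bin width in median-diameter units, > 0.
#' @param max_separation Upper edge of the last bin; defaults to the
#'   smallest multiple of `bin_width` covering the data.
#' @return A tibble of class `separation_histogram` with columns
#'   `bin_low`, `bin_high`, `touching`, `n`, `fraction`. Fractions sum to
#'   1 whenever any pairs exist; attribute `empty` flags the no-pair
#'   case.
#' @export
separation_histogram <- function(pairs, bin_width = 0.05,
                                 max_separation = NULL) {
  stopifnot(bin_width > 0)
  sep <- if (is.data.frame(pairs)) pairs$separation else as.numeric(pairs)
  sep <- sep[!is.na(sep)]
  pos <- sep[sep > 0]
  if (is.null(max_separation)) {
    max_separation <- if (length(pos) > 0) {
      bin_width * ceiling(max(pos) / bin_width)
    } else {
      bin_width
    }
  }
  edges <- round(seq(0, max_separation, by = bin_width), 9)
  if (edges[length(edges)] < max_separation) {
    edges <- c(edges, max_separation)
  }
  lows <- edges[-length(edges)]
  highs <- edges[-1]
  n_pos <- vapply(seq_along(lows), function(b) {
    sum(pos >= lows[b] & (pos < highs[b] |
                            (b == length(lows) & pos == highs[b])))
  }, integer(1))
  n <- c(sum(sep <= 0), n_pos)
  total <- sum(n)
  out <- tibble::tibble(
    bin_low = c(NA_real_, lows),
    bin_high = c(0, highs),
    touching = c(TRUE, rep(FALSE, length(lows))),
    n = n,
    fraction = if (total > 0) n / total else rep(0, length(n))
  )
  attr(out, "empty") <- total == 0
  attr(out, "bin_width") <- bin_width
  class(out) <- c("separation_histogram", class(out))
  out
}

#' Modal interior bin of a separation histogram
#'
#' @param hist A [separation_histogram()].
#' @return One row of `hist`: the non-touching bin with the highest
#'   fraction (ties broken toward smaller separation).
#' @export
histogram_mode <- function(hist) {
  interior <- hist[!hist$touching, , drop = FALSE]
  interior[which.max(interior$fraction), , drop = FALSE]
}

#' Bridge probability profiled by distance to the nearest docked vesicle
#'
#' For each cloud and each distance bin, the fraction of pairs judged
#' bridged; bins are then averaged (unweighted) across clouds, skipping
#' cloud-bin combinations with no pairs.
#'
#' @param records A scored pair table with `cloud_label`, `bridged` and
#'   `docked_distance` (see [nearest_docked_distance()]).
#' @param bin_edges Distance bin edges in median-diameter units
#'   (left-closed, right-open; default integer steps to 4).
#' @return A tibble with `bin_low`, `bin_high`, `n_clouds`, `p_bridge`.
#' @export
docked_distance_profile <- function(records, bin_edges = 0:4) {
  stopifnot(all(c("cloud_label", "bridged", "docked_distance") %in%
                  names(records)), length(bin_edges) >= 2)
  lows <- bin_edges[-length(bin_edges)]
  highs <- bin_edges[-1]
  per_cloud <- records |>
    dplyr::mutate(bin = findInterval(.data$docked_distance, bin_edges,
                                     rightmost.closed = FALSE)) |>
    dplyr::filter(.data$bin >= 1, .data$bin <= length(lows)) |>
    dplyr::group_by(.data$cloud_label, .data$bin) |>
    dplyr::summarise(p = mean(.data$bridged), .groups = "drop")
  per_cloud |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_clouds = dplyr::n(), p_bridge = mean(.data$p),
                     .groups = "drop") |>
    dplyr::right_join(
      tibble::tibble(bin = seq_along(lows), bin_low = lows, bin_high = highs),
      by = "bin"
    ) |>
    dplyr::arrange(.data$bin) |>
    dplyr::transmute(.data$bin_low, .data$bin_high,
                     n_clouds = dplyr::coalesce(.data$n_clouds, 0L),
                     p_bridge = .data$p_bridge)
}

#' Overlap after reversing shrinkage
#'
#' Expands every vesicle diameter by `factor` (centers fixed) and asks
#' which pairs come to overlap (center distance less than the sum of the
#' expanded radii). Reported for three sets: bridged pairs, non-bridged
#' pairs, and the distance-matched subset of non-bridged pairs whose
#' pre-expansion separation is at most `match_cutoff` -- the control for
#' bridged pairs simply being closer.
#'
#' @param cloud A [vesicle_cloud()].
#' @param bridged_pairs,nonbridged_pairs Pair tables with `id_i`, `id_j`
#'   (geometry is recomputed from the cloud); both must be nonempty.
#' @param factor Diameter expansion factor, > 1 (e.g. `45.6 / 39.6`).
#' @param match_cutoff Pre-expansion separation cutoff for the matched
#'   subset (median-diameter units).
#' @return A tibble with one row per set (`set`, `n`, `n_overlap`,
#'   `fraction`, `percent`).
#' @export
overlap_after_expansion <- function(cloud, bridged_pairs, nonbridged_pairs,
                                    factor = 45.6 / 39.6,
                                    match_cutoff = 0.23) {
  stopifnot(inherits(cloud, "vesicle_cloud"), factor > 1)
  if (nrow(bridged_pairs) == 0) stop("bridged pair set is empty")
  if (nrow(nonbridged_pairs) == 0) stop("non-bridged pair set is empty")
  v <- cloud$vesicles
  d_med <- median_diameter(cloud)
  eval_set <- function(p) {
    a <- match(p$id_i, v$id); b <- match(p$id_j, v$id)
    if (anyNA(a) || anyNA(b)) stop("pair ids not present in cloud")
    dist <- sqrt((v$x_nm[a] - v$x_nm[b])^2 + (v$y_nm[a] - v$y_nm[b])^2 +
                   (v$z_nm[a] - v$z_nm[b])^2)
    sep_before <- (dist - v$radius_nm[a] - v$radius_nm[b]) / d_med
    overlap <- dist < factor * (v$radius_nm[a] + v$radius_nm[b])
    list(sep = sep_before, overlap = overlap)
  }
  br <- eval_set(bridged_pairs)
  nb <- eval_set(nonbridged_pairs)
  matched <- nb$overlap[nb$sep <= match_cutoff]
  rows <- list(
    bridged = br$overlap,
    nonbridged = nb$overlap,
    nonbridged_matched = matched
  )
  purrr::imap_dfr(rows, function(ov, nm) {
    tibble::tibble(
      set = nm, n = length(ov), n_overlap = sum(ov),
      fraction = if (length(ov) > 0) mean(ov) else NA_real_,
      percent = if (length(ov) > 0) round_half_up(100 * mean(ov), 0) else NA_real_
    )
  })
}
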