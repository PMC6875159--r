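#' Configuration for vesicle-cloud simulations
#'
#' Collects every knob of the cloud-formation simulations: chains of
#' `chain_length` vesicles joined by bridges whose normalized rest lengths
#' are drawn from a truncated Normal, placed in an initially empty cube by
#' hard-sphere rejection sampling (or on a regular lattice, or an 85:15
#' random:ordered mixture), then optionally shrunk to emulate aldehyde
#' fixation.
#'
#' Defaults are the wildtype study conditions: 300 nm cubes, chains of
#' four, bridge lengths ~ Normal(0.18, 0.06) median diameters, placement
#' diameter 45.6 nm (the unfixed vesicle size; fixation shrinkage of 13%
#' brings it down to the ~39.6 nm measured in fixed tissue), target
#' volumetric fraction 0.17.
#'
#' @param box_edge Cube edge in nm.
#' @param chain_length Number of vesicles per chain, r >= 1 (r = 1 means
#'   unconnected vesicles).
#' @param bridge_length_mean,bridge_length_sd Normalized bridge rest-length
#'   distribution (median-diameter units).
#' @param bridge_length_min Lower truncation of the rest-length draw, to
#'   avoid degenerate contacts.
#' @param vesicle_diameter_mean,vesicle_diameter_sd Placed vesicle diameter
#'   distribution in nm.
#' @param target_volumetric_fraction Desired summed-sphere-volume / box
#'   volume at generation time (before any shrinkage); must be < 0.74.
#' @param placement `"random"`, `"ordered"` or `"mixture"`.
#' @param ordered_fraction Fraction of chains laid on the lattice in
#'   `"mixture"` mode.
#' @param shrink_fraction Diameter reduction applied by
#'   [apply_shrinkage()]; recorded here as part of the condition.
#' @param seed Integer seed; all randomness in [generate_cloud()] flows
#'   from it.
#' @param max_attempts Whole-chain placement attempts before giving up.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(box_edge = 300,
                              chain_length = 4,
                              bridge_length_mean = 0.18,
                              bridge_length_sd = 0.06,
                              bridge_length_min = 0.02,
                              vesicle_diameter_mean = 45.6,
                              vesicle_diameter_sd = 2.3,
                              target_volumetric_fraction = 0.17,
                              placement = c("random", "ordered", "mixture"),
                              ordered_fraction = 0.15,
                              shrink_fraction = 0.13,
                              seed = 1L,
                              max_attempts = 5000L) {
  placement <- match.arg(placement)
  stopifnot(
    box_edge > 0, chain_length >= 1,
    bridge_length_sd >= 0, bridge_length_min > 0,
    vesicle_diameter_mean > 0, vesicle_diameter_sd >= 0,
    target_volumetric_fraction >= 0, target_volumetric_fraction < 0.74,
    ordered_fraction >= 0, ordered_fraction <= 1,
    shrink_fraction >= 0, shrink_fraction < 1
  )
  structure(
    list(
      box_edge = box_edge,
      chain_length = as.integer(chain_length),
      bridge_length_mean = bridge_length_mean,
      bridge_length_sd = bridge_length_sd,
      bridge_length_min = bridge_length_min,
      vesicle_diameter_mean = vesicle_diameter_mean,
      vesicle_diameter_sd = vesicle_diameter_sd,
      target_volumetric_fraction = target_volumetric_fraction,
      placement = placement,
      ordered_fraction = ordered_fraction,
      shrink_fraction = shrink_fraction,
      seed = as.integer(seed),
      max_attempts = as.integer(max_attempts)
    ),
    class = "simulation_config"
  )
}

#' @rdname simulation_config
#' @param path YAML file mirroring the `simulation_config` fields.
#' @export
read_simulation_config <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}

#' @rdname simulation_config
#' @param config A `simulation_config`.
#' @export
write_simulation_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

runif_sphere <- function(n) {
  # uniform directions on the unit sphere
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  # rejection draw from N(mean, sd) truncated at > lower
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

#' Generate a simulated vesicle cloud of bridged chains
#'
#' Simulates cloud formation by placing chains of vesicles -- rather than
#' individuals -- at random locations in an initially empty cube. Chains
#' are grown link by link: successive link directions are uniform on the
#' sphere and surface gaps are drawn from the truncated Normal rest-length
#' distribution; any placement that would overlap an already-placed sphere
#' (hard-sphere exclusion) or put a center outside the box is rejected and
#' retried. With `chain_length = 1` the generator reduces to random
#' sequential addition of unconnected spheres. `placement = "ordered"`
#' lays all chains on a regular lattice ([generate_ordered_cloud()]);
#' `"mixture"` combines lattice and random placement at
#' `ordered_fraction` : `1 - ordered_fraction`.
#'
#' The number of chains is chosen so the achieved volumetric fraction
#' matches `target_volumetric_fraction`; generation fails (with the
#' attempted fraction in the message) if hard-sphere placement cannot
#' reach it within `max_attempts` per chain.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_cloud`: list with elements
#'   `cloud` (a [vesicle_cloud()]), `chains` (tibble `chain_id`,
#'   `member_rank`, `vesicle_id`, `rest_length`, `rest_length_nm`;
#'   rest lengths are `NA` on each chain's first member and otherwise give
#'   the bridge joining the member to its predecessor), `config`, and
#'   `d_nominal_nm` (the length unit used to convert normalized rest
#'   lengths to nm at generation).
#' @export
#' @examples
#' sim <- generate_cloud(simulation_config(
#'   box_edge = 200, target_volumetric_fraction = 0.05, seed = 7
#' ))
#' volumetric_fraction(sim$cloud)
generate_cloud <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$placement == "ordered") return(generate_ordered_cloud(config))
  with_seed(config$seed, generate_cloud_impl(config))
}

generate_cloud_impl <- function(config) {
  r <- config$chain_length
  d_nom <- config$vesicle_diameter_mean
  box_vol <- config$box_edge^3
  mean_sphere_vol <- 4 / 3 * pi * (d_nom / 2)^3
  n_chains <- max(1L, round(config$target_volumetric_fraction * box_vol /
                              (r * mean_sphere_vol)))
  n_ordered <- if (config$placement == "mixture") {
    as.integer(round(config$ordered_fraction * n_chains))
  } else 0L

  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  chain_rows <- vector("list", n_chains)

  if (n_ordered > 0) {
    lat <- ordered_chain_positions(config, n_ordered)
    centers <- lat$centers
    radii <- lat$radii
    for (k in seq_len(n_ordered)) {
      chain_rows[[k]] <- tibble::tibble(
        chain_id = k, member_rank = seq_len(r),
        rest_length = c(NA_real_, lat$rest_lengths[[k]])
      )
    }
  }

  bmin <- 0
  bmax <- config$box_edge
  for (k in seq.int(n_ordered + 1L, length.out = n_chains - n_ordered)) {
    placed <- FALSE
    for (attempt in seq_len(config$max_attempts)) {
      ch <- try_place_chain(config, centers, radii, bmin, bmax)
      if (!is.null(ch)) {
        centers <- rbind(centers, ch$centers)
        radii <- c(radii, ch$radii)
        chain_rows[[k]] <- tibble::tibble(
          chain_id = k, member_rank = seq_len(r),
          rest_length = c(NA_real_, ch$gaps)
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      achieved <- sum(4 / 3 * pi * radii^3) / box_vol
      stop(sprintf(
        "hard-sphere placement failed at chain %d of %d (volumetric fraction reached %.3f of target %.3f)",
        k, n_chains, achieved, config$target_volumetric_fraction
      ))
    }
  }

  finish_simulated_cloud(config, centers, radii, chain_rows)
}

try_place_chain <- function(config, centers, radii, bmin, bmax,
                            link_retries = 30L) {
  r <- config$chain_length
  d_nom <- config$vesicle_diameter_mean
  new_r <- rtrunc_norm(r, d_nom / 2, config$vesicle_diameter_sd / 2,
                       d_nom / 4)
  c1 <- stats::runif(3, bmin, bmax)
  if (overlaps_any(c1, new_r[1], centers, radii)) return(NULL)
  ch_centers <- matrix(c1, nrow = 1)
  gaps <- numeric(0)
  if (r > 1) {
    for (m in 2:r) {
      ok <- FALSE
      for (t in seq_len(link_retries)) {
        gap <- rtrunc_norm(1, config$bridge_length_mean,
                           config$bridge_length_sd, config$bridge_length_min)
        dir <- runif_sphere(1)
        cm <- ch_centers[m - 1, ] +
          dir[1, ] * (new_r[m - 1] + new_r[m] + gap * d_nom)
        if (any(cm < bmin) || any(cm > bmax)) next
        if (overlaps_any(cm, new_r[m], rbind(centers, ch_centers),
                         c(radii, new_r[seq_len(m - 1)]))) next
        ch_centers <- rbind(ch_centers, cm)
        gaps <- c(gaps, gap)
        ok <- TRUE
        break
      }
      if (!ok) return(NULL)
    }
  }
  list(centers = ch_centers, radii = new_r, gaps = gaps)
}

overlaps_any <- function(center, radius, centers, radii, tol = 1e-9) {
  if (nrow(centers) == 0) return(FALSE)
  d2 <- (centers[, 1] - center[1])^2 + (centers[, 2] - center[2])^2 +
    (centers[, 3] - center[3])^2
  any(d2 < (radii + radius - tol)^2)
}

finish_simulated_cloud <- function(config, centers, radii, chain_rows) {
  dimnames(centers) <- NULL
  radii <- unname(radii)
  n <- nrow(centers)
  vesicles <- tibble::tibble(
    id = seq_len(n) - 1L,
    x_nm = centers[, 1], y_nm = centers[, 2], z_nm = centers[, 3],
    radius_nm = radii, docked = FALSE
  )
  chains <- dplyr::bind_rows(chain_rows)
  chains$vesicle_id <- vesicles$id
  chains$rest_length_nm <- chains$rest_length * config$vesicle_diameter_mean
  chains <- chains[, c("chain_id", "member_rank", "vesicle_id",
                       "rest_length", "rest_length_nm")]
  bounds <- box_bounds(c(0, config$box_edge), c(0, config$box_edge),
                       c(0, config$box_edge))
  structure(
    list(
      cloud = vesicle_cloud(vesicles, bounds = bounds, label = "simulated"),
      chains = chains,
      config = config,
      d_nominal_nm = config$vesicle_diameter_mean
    ),
    class = "simulated_cloud"
  )
}

#' @export
print.simulated_cloud <- function(x, ...) {
  cat("<simulated_cloud>", nrow(x$cloud$vesicles), "vesicles in",
      max(x$chains$chain_id), "chains of", x$config$chain_length, "\n")
  cat(sprintf("  volumetric fraction: %.3f (target %.3f)\n",
              volumetric_fraction(x$cloud),
              x$config$target_volumetric_fraction))
  invisible(x)
}

# Deterministic lattice placement of n_chains straight chains along x.
ordered_chain_positions <- function(config, n_chains) {
  r <- config$chain_length
  d <- config$vesicle_diameter_mean
  gap_nm <- config$bridge_length_mean * d
  chain_len <- r * d + (r - 1) * gap_nm
  edge <- config$box_edge
  if (chain_len > edge) stop("lattice infeasible: chain longer than box edge")
  nx <- max(1L, floor(edge / (chain_len + gap_nm)))
  per_plane <- ceiling(n_chains / nx)
  ny <- max(1L, ceiling(sqrt(per_plane)))
  nz <- max(1L, ceiling(per_plane / ny))
  pitch_y <- edge / ny
  pitch_z <- edge / nz
  if (pitch_y < d || pitch_z < d) {
    stop(sprintf(
      "lattice infeasible: pitch %.1f x %.1f nm cannot hold %.1f nm vesicles",
      pitch_y, pitch_z, d
    ))
  }
  pitch_x <- edge / nx
  centers_list <- vector("list", n_chains)
  radii_list <- vector("list", n_chains)
  rest_list <- vector("list", n_chains)
  k <- 0L
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (k >= n_chains) break
    k <- k + 1L
    x0 <- (ix - 0.5) * pitch_x - chain_len / 2 + d / 2
    y0 <- (iy - 0.5) * pitch_y
    z0 <- (iz - 0.5) * pitch_z
    xs <- x0 + (seq_len(r) - 1) * (d + gap_nm)
    centers_list[[k]] <- cbind(xs, y0, z0)
    radii_list[[k]] <- rep(d / 2, r)
    rest_list[[k]] <- rep(config$bridge_length_mean, max(0, r - 1))
  }
  list(
    centers = do.call(rbind, centers_list),
    radii = unlist(radii_list),
    rest_lengths = rest_list
  )
}

#' Generate an ordered (lattice) cloud of chains
#'
#' Lays straight chains of `chain_length` vesicles (uniform diameter,
#' bridge gaps fixed at `bridge_length_mean`) on a regular cubic lattice
#' with the chain axis along x. Deterministic given the config; errors if
#' the target fraction is not achievable on the lattice.
#'
#' @inheritParams generate_cloud
#' @return A `simulated_cloud` (see [generate_cloud()]).
#' @export
generate_ordered_cloud <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  r <- config$chain_length
  d_nom <- config$vesicle_diameter_mean
  mean_sphere_vol <- 4 / 3 * pi * (d_nom / 2)^3
  n_chains <- max(1L, round(config$target_volumetric_fraction *
                              config$box_edge^3 / (r * mean_sphere_vol)))
  lat <- ordered_chain_positions(config, n_chains)
  chain_rows <- lapply(seq_len(n_chains), function(k) {
    tibble::tibble(chain_id = k, member_rank = seq_len(r),
                   rest_length = c(NA_real_, lat$rest_lengths[[k]]))
  })
  finish_simulated_cloud(config, lat$centers, lat$radii, chain_rows)
}

#' Bridged pairs of a simulated cloud
#'
#' @param sim A `simulated_cloud`.
#' @return Tibble `id_i`, `id_j` (canonical order), `chain_id`,
#'   `rest_length`, `rest_length_nm` -- one row per bridge (consecutive
#'   chain members).
#' @export
chain_bridges <- function(sim) {
  stopifnot(inherits(sim, "simulated_cloud"))
  ch <- dplyr::arrange(sim$chains, .data$chain_id, .data$member_rank)
  ch |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::mutate(prev_id = dplyr::lag(.data$vesicle_id)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_id)) |>
    dplyr::transmute(
      id_i = pmin(.data$prev_id, .data$vesicle_id),
      id_j = pmax(.data$prev_id, .data$vesicle_id),
      chain_id = .data$chain_id,
      rest_length = .data$rest_length,
      rest_length_nm = .data$rest_length_nm
    )
}

#' @rdname chain_bridges
#' @param path CSV path for the chain edge list.
#' @export
write_chain_table <- function(sim, path) {
  readr::write_csv(sim$chains, path)
  invisible(path)
}

#' Apply fixation shrinkage to a cloud
#'
#' Scales every vesicle radius by `1 - shrink_fraction`, emulating the
#' diameter loss that aldehyde fixation causes (about 10-13%). With
#' `rigid_bridges = TRUE` each bridge behaves as a rigid rod: the surface
#' gap of every bridged pair is restored to its rest length (in nm) by
#' translating members along the pair axis, propagated sequentially from
#' each chain's first member, so bridged pairs are dragged closer together
#' while unbridged neighbors drift apart. The cloud's median diameter is
#' re-measured after the transform, as it would be in fixed tissue.
#'
#' @param x A `simulated_cloud` (rigid mode needs its chains) or a bare
#'   [vesicle_cloud()] (non-rigid only).
#' @param shrink_fraction Diameter reduction in \[0, 1).
#' @param rigid_bridges Restore bridged-pair gaps to their rest lengths.
#' @return Same type as `x`, with shrunk radii (and shifted centers in
#'   rigid mode).
#' @export
apply_shrinkage <- function(x, shrink_fraction = NULL, rigid_bridges = TRUE) {
  if (inherits(x, "vesicle_cloud")) {
    stopifnot(!rigid_bridges)
    return(shrink_cloud_radii(x, shrink_fraction))
  }
  stopifnot(inherits(x, "simulated_cloud"))
  if (is.null(shrink_fraction)) shrink_fraction <- x$config$shrink_fraction
  stopifnot(shrink_fraction >= 0, shrink_fraction < 1)
  v <- x$cloud$vesicles
  v$radius_nm <- v$radius_nm * (1 - shrink_fraction)
  if (rigid_bridges && shrink_fraction > 0) {
    ch <- dplyr::arrange(x$chains, .data$chain_id, .data$member_rank)
    pos <- as.matrix(v[, c("x_nm", "y_nm", "z_nm")])
    row_of <- match(ch$vesicle_id, v$id)
    for (cid in unique(ch$chain_id)) {
      rows <- which(ch$chain_id == cid)
      if (length(rows) < 2) next
      for (m in rows[-1]) {
        a <- row_of[m - 1]          # predecessor in this chain
        b <- row_of[m]
        axis <- pos[b, ] - pos[a, ]
        len <- sqrt(sum(axis^2))
        axis <- axis / len
        target <- v$radius_nm[a] + v$radius_nm[b] + ch$rest_length_nm[m]
        pos[b, ] <- pos[a, ] + axis * target
      }
    }
    v$x_nm <- pos[, 1]; v$y_nm <- pos[, 2]; v$z_nm <- pos[, 3]
  }
  out <- x
  out$cloud <- vesicle_cloud(v, bounds = grow_bounds_to_fit(x$cloud$bounds, v),
                             membrane_plane = x$cloud$membrane_plane,
                             label = x$cloud$label)
  out
}

shrink_cloud_radii <- function(cloud, shrink_fraction) {
  stopifnot(shrink_fraction >= 0, shrink_fraction < 1)
  v <- cloud$vesicles
  v$radius_nm <- v$radius_nm * (1 - shrink_fraction)
  vesicle_cloud(v, bounds = cloud$bounds,
                membrane_plane = cloud$membrane_plane, label = cloud$label)
}

# rigid-bridge propagation can push a center marginally past the box face
grow_bounds_to_fit <- function(bounds, vesicles) {
  if (nrow(vesicles) == 0) return(bounds)
  coords <- as.matrix(vesicles[, c("x_nm", "y_nm", "z_nm")])
  rbind(min = pmin(bounds["min", ], apply(coords, 2, min)),
        max = pmax(bounds["max", ], apply(coords, 2, max)))
}

#' Reverse shrinkage by expanding vesicle diameters
#'
#' Scales every radius by `factor` with centers fixed, emulating the
#' reverse of fixation shrinkage (e.g. `factor = 45.6 / 39.6`, about a 15%
#' diameter increase, to restore unfixed vesicle size). Pairs held close
#' by a bridge typically come to overlap after expansion; well-separated
#' unbridged pairs do not.
#'
#' @param x A [vesicle_cloud()] or `simulated_cloud`.
#' @param factor Diameter multiplier, > 0.
#' @return Same type as `x` with expanded radii.
#' @export
apply_expansion <- function(x, factor) {
  stopifnot(factor > 0)
  if (inherits(x, "simulated_cloud")) {
    x$cloud <- apply_expansion(x$cloud, factor)
    return(x)
  }
  stopifnot(inherits(x, "vesicle_cloud"))
  v <- x$vesicles
  v$radius_nm <- v$radius_nm * factor
  vesicle_cloud(v, bounds = x$bounds, membrane_plane = x$membrane_plane,
                label = x$label)
}

#' Simulate diffusion of vesicles by a random walk
#'
#' Every vesicle takes `n_steps` independent isotropic Gaussian steps
#' (per-axis sd `step_sd_nm`), reflected at the bounds. With
#' `exclusion = TRUE` any step that would create a surface overlap with
#' another vesicle is rejected (the vesicle stays put for that step), so
#' hard-sphere exclusion is preserved; with `exclusion = FALSE` vesicles
#' diffuse freely and may come to touch or overlap.
#'
#' @param cloud A [vesicle_cloud()].
#' @param n_steps Number of steps (0 returns the cloud unchanged).
#' @param step_sd_nm Per-axis step standard deviation in nm.
#' @param bounds Reflecting box; defaults to the cloud bounds.
#' @param exclusion Enforce hard-sphere exclusion.
#' @param seed Integer seed.
#' @return A `vesicle_cloud` with updated centers.
#' @export
random_walk <- function(cloud, n_steps = 500, step_sd_nm = 1,
                        bounds = cloud$bounds, exclusion = TRUE,
                        seed = NULL) {
  stopifnot(inherits(cloud, "vesicle_cloud"), n_steps >= 0, step_sd_nm >= 0)
  bounds <- validate_bounds(bounds)
  with_seed(seed, {
    pos <- as.matrix(cloud$vesicles[, c("x_nm", "y_nm", "z_nm")])
    radii <- cloud$vesicles$radius_nm
    n <- nrow(pos)
    if (n > 0 && n_steps > 0) {
      lo <- bounds["min", ]; hi <- bounds["max", ]
      for (s in seq_len(n_steps)) {
        steps <- matrix(stats::rnorm(3 * n, 0, step_sd_nm), ncol = 3)
        for (i in seq_len(n)) {
          prop <- reflect_into(pos[i, ] + steps[i, ], lo, hi)
          if (exclusion && n > 1) {
            others <- pos[-i, , drop = FALSE]
            if (overlaps_any(prop, radii[i], others, radii[-i])) next
          }
          pos[i, ] <- prop
        }
      }
    }
    v <- cloud$vesicles
    v$x_nm <- pos[, 1]; v$y_nm <- pos[, 2]; v$z_nm <- pos[, 3]
    vesicle_cloud(v, bounds = bounds, membrane_plane = cloud$membrane_plane,
                  label = cloud$label,
                  median_diameter_nm = cloud$median_diameter_nm)
  })
}

reflect_into <- function(p, lo, hi) {
  span <- hi - lo
  for (a in 1:3) {
    if (span[a] == 0) { p[a] <- lo[a]; next }
    # fold the coordinate into [lo, hi] by repeated reflection
    x <- (p[a] - lo[a]) %% (2 * span[a])
    p[a] <- lo[a] + if (x <= span[a]) x else 2 * span[a] - x
  }
  p
}
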