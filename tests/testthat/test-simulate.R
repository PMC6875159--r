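test_that("unconnected clouds place hard spheres at the target fraction", {
  cfg <- simulation_config(chain_length = 1,
                           target_volumetric_fraction = 0.07, seed = 41)
  sim <- generate_cloud(cfg)
  expect_equal(nrow(chain_bridges(sim)), 0)
  pairs <- vesicle_pairs(sim$cloud)
  expect_gt(min(pairs$separation), 0)
  expect_equal(volumetric_fraction(sim$cloud), 0.07, tolerance = 0.1)
})

test_that("chain clouds have r-1 bridges per chain with the drawn gaps", {
  cfg <- simulation_config(seed = 42)   # r = 4, fraction 0.17
  sim <- generate_cloud(cfg)
  expect_equal(volumetric_fraction(sim$cloud), 0.17, tolerance = 0.1)

  per_chain <- table(chain_bridges(sim)$chain_id)
  expect_true(all(per_chain == 3))

  # recompute every bridged gap from the placed coordinates
  v <- sim$cloud$vesicles
  br <- chain_bridges(sim)
  a <- match(br$id_i, v$id); b <- match(br$id_j, v$id)
  gap_nm <- sqrt((v$x_nm[a] - v$x_nm[b])^2 + (v$y_nm[a] - v$y_nm[b])^2 +
                   (v$z_nm[a] - v$z_nm[b])^2) -
    v$radius_nm[a] - v$radius_nm[b]
  expect_equal(gap_nm, br$rest_length_nm, tolerance = 1e-9)
  expect_true(all(br$rest_length > cfg$bridge_length_min))

  # hard-sphere exclusion holds for every pair
  expect_gte(min(vesicle_pairs(sim$cloud)$separation), 0)
})

test_that("identical seeds reproduce clouds bit for bit", {
  cfg <- simulation_config(seed = 77)
  expect_identical(generate_cloud(cfg)$cloud$vesicles,
                   generate_cloud(cfg)$cloud$vesicles)
  cl <- make_random_cloud(20)
  expect_identical(random_walk(cl, 20, seed = 5)$vesicles,
                   random_walk(cl, 20, seed = 5)$vesicles)
})

test_that("ordered and mixture placement lay chains on the lattice", {
  cfg <- simulation_config(placement = "ordered", seed = 1)
  sim <- generate_ordered_cloud(cfg)
  expect_gte(min(vesicle_pairs(sim$cloud)$separation), 0)
  # deterministic construction
  expect_identical(sim$cloud$vesicles,
                   generate_ordered_cloud(cfg)$cloud$vesicles)
  per_chain <- table(sim$chains$chain_id)
  expect_true(all(per_chain == cfg$chain_length))

  mix <- generate_cloud(simulation_config(placement = "mixture", seed = 21))
  # lattice chains carry the fixed rest length exactly; random draws never do
  on_lattice <- tapply(mix$chains$rest_length, mix$chains$chain_id,
                       function(x) all(is.na(x) | x == 0.18))
  n_chains <- length(on_lattice)
  expect_equal(sum(on_lattice), round(0.15 * n_chains), tolerance = 1)

  # infeasible lattice is refused
  expect_error(
    generate_ordered_cloud(simulation_config(
      placement = "ordered", box_edge = 100, chain_length = 4,
      target_volumetric_fraction = 0.5
    )),
    "lattice"
  )
})

test_that("rigid-bridge shrinkage preserves bridged gaps and opens others", {
  # zero shrink is the identity
  sim <- generate_cloud(simulation_config(seed = 8))
  same <- apply_shrinkage(sim, 0, rigid_bridges = TRUE)
  expect_equal(same$cloud$vesicles, sim$cloud$vesicles)

  # a single chain: gaps are restored to rest length after 13% shrink
  one <- generate_cloud(simulation_config(
    target_volumetric_fraction = 0.002, seed = 9
  ))
  expect_equal(max(one$chains$chain_id), 1)
  shr <- apply_shrinkage(one, 0.13, rigid_bridges = TRUE)
  v <- shr$cloud$vesicles
  br <- chain_bridges(shr)
  a <- match(br$id_i, v$id); b <- match(br$id_j, v$id)
  gap_nm <- sqrt((v$x_nm[a] - v$x_nm[b])^2 + (v$y_nm[a] - v$y_nm[b])^2 +
                   (v$z_nm[a] - v$z_nm[b])^2) - v$radius_nm[a] - v$radius_nm[b]
  expect_equal(gap_nm, br$rest_length_nm, tolerance = 1e-9)
  expect_equal(v$radius_nm, one$cloud$vesicles$radius_nm * 0.87)

  # unbridged pair: the nm gap opens by exactly shrink * (r1 + r2)
  two <- vesicle_cloud(tibble::tibble(
    id = 0:1, x_nm = c(0, 44), y_nm = 0, z_nm = 0,
    radius_nm = c(18, 20), docked = FALSE
  ))
  shr2 <- apply_shrinkage(two, 0.13, rigid_bridges = FALSE)
  gap_before <- 44 - 38
  gap_after <- 44 - 0.87 * 38
  expect_equal(pair_separation(c(0, 0, 0), c(44, 0, 0),
                               shr2$vesicles$radius_nm[1],
                               shr2$vesicles$radius_nm[2],
                               median_diameter(shr2)) *
                 median_diameter(shr2),
               gap_before + 0.13 * 38)
  expect_equal(gap_after, gap_before + 0.13 * 38)

  # distribution property: bridged gaps unchanged, unbridged gaps larger
  full <- generate_cloud(simulation_config(seed = 10))
  before <- vesicle_pairs(full$cloud)
  shr3 <- apply_shrinkage(full, 0.13, rigid_bridges = TRUE)
  after <- vesicle_pairs(shr3$cloud)
  bkey <- pair_key(chain_bridges(full))
  nb_before <- before$separation[!pair_key(before) %in% bkey &
                                   before$separation <= 0.6]
  nb_after <- after$separation[!pair_key(after) %in% bkey &
                                 after$separation <= 0.6]
  expect_gt(mean(nb_after), mean(nb_before))
})

test_that("expansion scales radii in place", {
  cloud <- make_line_cloud()
  expect_equal(apply_expansion(cloud, 1)$vesicles, cloud$vesicles)
  grown <- apply_expansion(cloud, 45.6 / 39.6)
  expect_equal(grown$vesicles$radius_nm / cloud$vesicles$radius_nm,
               rep(45.6 / 39.6, 3))
  expect_equal(grown$vesicles$x_nm, cloud$vesicles$x_nm)

  # a pair at gap 0.10 median diameters overlaps after 15% expansion
  d_med <- 40
  pairc <- vesicle_cloud(tibble::tibble(
    id = 0:1, x_nm = c(0, 36 + 0.10 * d_med), y_nm = 0, z_nm = 0,
    radius_nm = 18, docked = FALSE
  ), median_diameter_nm = d_med)
  ex <- apply_expansion(pairc, 1.15)
  sep <- pair_separation(c(0, 0, 0), c(40, 0, 0), ex$vesicles$radius_nm[1],
                         ex$vesicles$radius_nm[2], d_med)
  expect_lt(sep, 0)
})

test_that("random walks diffuse, reflect, and respect exclusion", {
  cloud <- make_random_cloud(20)
  expect_equal(random_walk(cloud, 0, seed = 1)$vesicles, cloud$vesicles)

  # with exclusion, hard spheres stay disjoint
  sim <- generate_cloud(simulation_config(
    chain_length = 1, target_volumetric_fraction = 0.12, seed = 5
  ))
  walked <- random_walk(sim$cloud, 60, step_sd_nm = 2, seed = 6)
  expect_gte(min(vesicle_pairs(walked)$separation), 0)
  # bounds are respected
  coords <- as.matrix(walked$vesicles[, c("x_nm", "y_nm", "z_nm")])
  expect_true(all(coords >= 0 & coords <= 300))

  # without exclusion, free diffusion lets vesicles touch
  free <- random_walk(sim$cloud, 150, step_sd_nm = 2, exclusion = FALSE,
                      seed = 9)
  hist <- separation_histogram(vesicle_pairs(free))
  expect_gt(hist$fraction[hist$touching], 0)

  # single-vesicle displacement variance matches n_steps * step_sd^2
  disp <- vapply(1:200, function(s) {
    one <- vesicle_cloud(
      tibble::tibble(id = 0L, x_nm = 5000, y_nm = 5000, z_nm = 5000,
                     radius_nm = 18, docked = FALSE),
      bounds = box_bounds(c(0, 1e4), c(0, 1e4), c(0, 1e4))
    )
    random_walk(one, 50, step_sd_nm = 1, seed = s)$vesicles$x_nm - 5000
  }, numeric(1))
  expect_equal(var(disp), 50, tolerance = 0.3)
})
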