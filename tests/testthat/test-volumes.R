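make_pair_cloud <- function(angle_deg = 0, gap_nm = 8, r = 18,
                            bridged = TRUE, edge = 120) {
  th <- angle_deg * pi / 180
  c1 <- rep(edge / 2, 3)
  u <- c(cos(th), 0, sin(th))
  c2 <- c1 + u * (2 * r + gap_nm)
  ves <- tibble::tibble(id = 0:1, x_nm = c(c1[1], c2[1]),
                        y_nm = c(c1[2], c2[2]), z_nm = c(c1[3], c2[3]),
                        radius_nm = r, docked = FALSE)
  list(
    cloud = vesicle_cloud(ves, bounds = box_bounds(c(0, edge), c(0, edge),
                                                   c(0, edge))),
    c1 = c1, c2 = c2, r = r,
    bridges = if (bridged) tibble::tibble(id_i = 0L, id_j = 1L) else NULL
  )
}

test_that("rendering places dark shells and rods on a light background", {
  empty <- vesicle_cloud(
    tibble::tibble(id = integer(), x_nm = numeric(), y_nm = numeric(),
                   z_nm = numeric(), radius_nm = numeric(),
                   docked = logical()),
    bounds = box_bounds(c(0, 40), c(0, 40), c(0, 40))
  )
  vol0 <- render_volume(empty, voxel_size_nm = 2, noise_sd = 0)
  expect_true(all(vol0$data == 1))

  # radial profile of a single vesicle has its minimum at the radius
  one <- vesicle_cloud(
    tibble::tibble(id = 0L, x_nm = 60, y_nm = 60, z_nm = 60,
                   radius_nm = 18, docked = FALSE),
    bounds = box_bounds(c(0, 120), c(0, 120), c(0, 120))
  )
  vol1 <- render_volume(one, voxel_size_nm = 1, noise_sd = 0)
  radii <- seq(2, 30, by = 1)
  prof <- interp_trilinear(vol1, cbind(60 + radii, 60, 60))
  expect_equal(radii[which.min(prof)], 18, tolerance = 1.5)
  expect_equal(prof[radii > 24], rep(1, sum(radii > 24)))

  # bridged corridor is darker than background; absent bridge leaves it flat
  g <- make_pair_cloud(bridged = TRUE)
  volb <- render_volume(g$cloud, bridges = g$bridges, voxel_size_nm = 2,
                        noise_sd = 0)
  expect_gt(corridor_bridge_score(volb, g$c1, g$c2, g$r, g$r), 0)
  volu <- render_volume(g$cloud, voxel_size_nm = 2, noise_sd = 0)
  expect_equal(corridor_bridge_score(volu, g$c1, g$c2, g$r, g$r), 0,
               tolerance = 1e-6)
  # touching pairs are degenerate for the corridor
  expect_error(corridor_bridge_score(volb, g$c1, g$c1 + c(30, 0, 0), 18, 18),
               "degenerate")
})

test_that("corridor scores classify rendered pairs at threshold 2", {
  set.seed(91)
  labels <- rep(c(TRUE, FALSE), 20)
  scores <- vapply(seq_along(labels), function(k) {
    g <- make_pair_cloud(angle_deg = runif(1, 0, 25),
                         gap_nm = runif(1, 6, 16), bridged = labels[k],
                         edge = 110)
    vol <- render_volume(g$cloud, bridges = g$bridges, voxel_size_nm = 2,
                         noise_sd = 0.05, seed = 9000 + k)
    corridor_bridge_score(vol, g$c1, g$c2, g$r, g$r)
  }, numeric(1))
  called <- scores >= 2
  sens <- mean(called[labels])
  spec <- mean(!called[!labels])
  expect_gte((sens + spec) / 2, 0.9)
})

test_that("pair views average sections in the pair frame", {
  # synthetic intensity field linear in world coordinates: the 0-degree
  # view of a horizontal pair must reproduce the field at the sampled
  # in-plane coordinates, independent of the z-average
  dims <- c(61, 61, 61)
  ax <- (seq_len(61) - 1) * 2
  field <- outer(outer(ax, 2 * ax, "+"), rep(1, 61))  # x + 2y, constant in z
  vol <- tomo_volume(field, voxel_size_nm = 2)
  c1 <- c(30, 60, 60); c2 <- c(90, 60, 60)
  pv <- extract_pair_views(vol, c1, c2, d_med = 36, fov_nm = 40, pixel_nm = 2)
  xs <- seq(-20, 20, by = 2)
  mid <- c(60, 60, 60)
  expected <- outer(mid[1] + xs, rep(1, length(xs))) +
    2 * outer(rep(1, length(xs)), mid[2] + xs)
  expect_equal(pv$view_0, expected, tolerance = 1e-9)
  expect_equal(dim(pv$view_p45), dim(pv$view_0))

  # equivariance: rotating the whole scene about z leaves views unchanged
  mk <- function(th) {
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    cc <- c(60, 60, 60)
    c1 <- cc + as.numeric(rot %*% c(-20, 0, 0))
    c2 <- cc + as.numeric(rot %*% c(20, 0, 0))
    ves <- tibble::tibble(id = 0:1, x_nm = c(c1[1], c2[1]),
                          y_nm = c(c1[2], c2[2]), z_nm = c(c1[3], c2[3]),
                          radius_nm = 18, docked = FALSE)
    cl <- vesicle_cloud(ves, bounds = box_bounds(c(0, 120), c(0, 120),
                                                 c(0, 120)))
    vol <- render_volume(cl, voxel_size_nm = 2, noise_sd = 0)
    extract_pair_views(vol, c1, c2, 36, fov_nm = 70, pixel_nm = 2)
  }
  pa <- mk(0); pb <- mk(30 * pi / 180)
  expect_lt(mean(abs(pa$view_0 - pb$view_0)), 0.03)

  # pairs hugging the edge are refused with the margin in the message
  g <- make_pair_cloud(edge = 120)
  vol2 <- render_volume(g$cloud, voxel_size_nm = 2, noise_sd = 0)
  expect_error(extract_pair_views(vol2, c(2, 2, 2), c(40, 2, 2), 36),
               "margin")
})

test_that("missing-wedge degradation erodes bridge discriminability", {
  discrim <- function(angle, wedge) {
    gb <- make_pair_cloud(angle_deg = angle, bridged = TRUE)
    gu <- make_pair_cloud(angle_deg = angle, bridged = FALSE)
    vb <- render_volume(gb$cloud, bridges = gb$bridges, voxel_size_nm = 2,
                        noise_sd = 0.05, seed = 31, missing_wedge = wedge)
    vu <- render_volume(gu$cloud, voxel_size_nm = 2, noise_sd = 0.05,
                        seed = 31, missing_wedge = wedge)
    corridor_bridge_score(vb, gb$c1, gb$c2, gb$r, gb$r) -
      corridor_bridge_score(vu, gu$c1, gu$c2, gu$r, gu$r)
  }
  for (angle in c(0, 60)) {
    expect_lt(discrim(angle, TRUE), discrim(angle, FALSE))
  }
})

test_that("MRC mode-2 volumes round-trip through disk", {
  set.seed(15)
  vol <- tomo_volume(array(rnorm(20 * 18 * 16), dim = c(20, 18, 16)),
                     voxel_size_nm = 0.64, origin_nm = c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(vol, path)
  back <- read_mrc(path)
  expect_equal(dim(back$data), dim(vol$data))
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$voxel_size_nm, vol$voxel_size_nm, tolerance = 1e-6)
  expect_equal(back$origin_nm, vol$origin_nm, tolerance = 1e-6)
})
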