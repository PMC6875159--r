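test_that("the chain-link model gives (2r-2)/r bridges per vesicle", {
  expect_equal(chain_model_links(4), 1.5)
  expect_equal(chain_model_links(1), 0)
  expect_equal(chain_model_links(2.6), 1.230769, tolerance = 1e-6)
  expect_equal(round(chain_model_links(2.6), 1), 1.2)
  expect_error(chain_model_links(0.9), ">= 1")
  # monotone increasing, bounded above by 2
  rs <- seq(1, 60, by = 0.5)
  vals <- chain_model_links(rs)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 2))
})

test_that("per-cloud bridge probabilities summarize as median and quartiles", {
  rec <- tibble::tibble(
    cloud_label = rep(c("t1", "t2", "t3"), each = 10),
    bridged = c(rep(c(TRUE, FALSE), c(3, 7)),
                rep(c(TRUE, FALSE), c(2, 8)),
                rep(c(TRUE, FALSE), c(1, 9)))
  )
  bp <- bridge_probability_by_cloud(rec)
  expect_equal(sort(bp$p_bridge), c(0.1, 0.2, 0.3))
  expect_equal(glance(bp)$median_p, 0.2)

  # 13-cloud fixture against a sort-based median oracle
  set.seed(31)
  ks <- rbinom(13, 40, 0.35)
  rec13 <- purrr::map_dfr(seq_len(13), function(i) {
    tibble::tibble(cloud_label = sprintf("c%02d", i),
                   bridged = rep(c(TRUE, FALSE), c(ks[i], 40 - ks[i])))
  })
  bp13 <- bridge_probability_by_cloud(rec13)
  expect_equal(glance(bp13)$median_p, sort(ks / 40)[7])

  expect_equal(bridges_per_vesicle(0.5, 3), 1.5)
  expect_equal(bridges_per_vesicle(0, 12), 0)
})

test_that("percentages round half-up to printed precision", {
  expect_equal(proportion_from_counts(3, 42), 7.1)
  expect_equal(proportion_from_counts(41, 112), 36.6)
  expect_equal(proportion_from_counts(0, 5), 0)
  expect_equal(proportion_from_counts(1, 8, 0), 13)  # 12.5 rounds up
  expect_error(proportion_from_counts(3, 0), "> 0")
  expect_error(proportion_from_counts(6, 5), "within")
})

test_that("continuity-corrected Wilson bounds match the score-test oracle", {
  expect_equal(wilson_ci_continuity(0, 20)$lower, 0)
  expect_equal(wilson_ci_continuity(20, 20)$upper, 1)
  for (case in list(c(41, 112), c(4, 68), c(3, 42), c(17, 150))) {
    got <- wilson_ci_continuity(case[1], case[2], 0.90)
    want <- oracle_wilson_cc(case[1], case[2], 0.90)
    expect_equal(got$lower, want[1], tolerance = 1e-6)
    expect_equal(got$upper, want[2], tolerance = 1e-6)
  }
  expect_error(wilson_ci_continuity(1, 10, confidence = 1.2), "between")
  # width shrinks monotonically with n at fixed k/n
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- wilson_ci_continuity(round(0.3 * n), n, 0.90)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Yates-corrected chi-square matches hand computation", {
  flat <- chi2_yates(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  tab <- matrix(c(3, 39, 41, 71), nrow = 2, byrow = TRUE)
  got <- chi2_yates(tab)
  # expected counts from the marginals, then the corrected statistic
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((pmax(abs(tab - E) - 0.5, 0))^2 / E)
  expect_equal(got$statistic, stat, tolerance = 1e-10)
  expect_equal(got$statistic, 11.59, tolerance = 1e-3)
  expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE))
  expect_equal(got$p_value, 6.6e-4, tolerance = 0.01)
  expect_lt(got$p_value, 0.001)

  # swapping the group rows leaves the statistic unchanged
  expect_equal(chi2_yates(tab[2:1, ])$statistic, got$statistic)
  # the correction can only lower the statistic
  uncorr <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  expect_lte(got$statistic, unname(uncorr))
  expect_error(chi2_yates(matrix(c(0, 0, 5, 5), 2, 2)), "marginals")
})

test_that("two-sample KS equals the exhaustive ECDF-difference oracle", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, y)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  set.seed(33)
  a <- rnorm(25); b <- rnorm(35, 0.6)
  got <- ks_two_sample(a, b)
  grid <- sort(c(a, b))
  d_oracle <- max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t),
                             numeric(1))))
  expect_equal(got$statistic, d_oracle)
  expect_lt(got$p_value, 1)
})

test_that("separation histograms bin by brute force with a touching bin", {
  h1 <- separation_histogram(c(0.12, 0.13, 0.14), bin_width = 0.1)
  expect_equal(h1$fraction[h1$bin_low == 0.1 & !h1$touching], 1)
  expect_equal(sum(h1$fraction), 1)

  h0 <- separation_histogram(numeric(0), bin_width = 0.1)
  expect_true(attr(h0, "empty"))
  expect_true(all(h0$fraction == 0))

  set.seed(34)
  seps <- c(runif(200, -0.05, 1), -0.01, 0)
  h <- separation_histogram(seps, bin_width = 0.05)
  expect_equal(h$n[h$touching], sum(seps <= 0))
  for (b in which(!h$touching)) {
    lo <- h$bin_low[b]; hi <- h$bin_high[b]
    is_last <- b == nrow(h)
    want <- sum(seps > 0 & seps >= lo & (seps < hi | (is_last & seps == hi)))
    expect_equal(h$n[b], want)
  }
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)

  # refining the bin width preserves cumulative mass at shared edges
  coarse <- separation_histogram(seps, bin_width = 0.2, max_separation = 1)
  fine <- separation_histogram(seps, bin_width = 0.05, max_separation = 1)
  for (edge in c(0.2, 0.4, 0.6, 0.8)) {
    expect_equal(sum(coarse$fraction[coarse$touching | coarse$bin_high <= edge]),
                 sum(fine$fraction[fine$touching | fine$bin_high <= edge]))
  }
})

test_that("docked-distance profiles average per-cloud probabilities", {
  rec1 <- tibble::tibble(cloud_label = "a", bridged = c(TRUE, FALSE),
                         docked_distance = c(0.5, 0.6))
  expect_equal(docked_distance_profile(rec1, 0:1)$p_bridge, 0.5)

  rec2 <- dplyr::bind_rows(
    tibble::tibble(cloud_label = "a",
                   bridged = rep(c(TRUE, FALSE), c(1, 4)),
                   docked_distance = 0.5),
    tibble::tibble(cloud_label = "b",
                   bridged = rep(c(TRUE, FALSE), c(2, 3)),
                   docked_distance = 0.5)
  )
  expect_equal(docked_distance_profile(rec2, 0:1)$p_bridge, 0.3)

  # brute force over a random fixture with empty cloud-bin skipping
  set.seed(35)
  rec <- tibble::tibble(
    cloud_label = sample(c("a", "b", "c"), 120, replace = TRUE),
    bridged = runif(120) < 0.3,
    docked_distance = runif(120, 0, 4)
  )
  prof <- docked_distance_profile(rec, 0:4)
  for (b in 1:4) {
    vals <- c()
    for (cl in c("a", "b", "c")) {
      sel <- rec$cloud_label == cl & rec$docked_distance >= b - 1 &
        rec$docked_distance < b
      if (any(sel)) vals <- c(vals, mean(rec$bridged[sel]))
    }
    expect_equal(prof$p_bridge[b], mean(vals))
  }
})

test_that("expansion overlap fractions separate bridged from unbridged", {
  # one bridged pair at gap 0.05, two unbridged at 0.05 and 0.45
  d_med <- 40
  ves <- tibble::tibble(
    id = 0:5,
    x_nm = c(0, 38, 200, 238, 400, 456),
    y_nm = 0, z_nm = 0, radius_nm = 18, docked = FALSE
  )
  cloud <- vesicle_cloud(ves, median_diameter_nm = d_med)
  bridged <- tibble::tibble(id_i = 0L, id_j = 1L)
  nonbridged <- tibble::tibble(id_i = c(2L, 4L), id_j = c(3L, 5L))

  out <- overlap_after_expansion(cloud, bridged, nonbridged, factor = 1.15,
                                 match_cutoff = 0.23)
  expect_equal(out$fraction[out$set == "bridged"], 1)       # 2 nm gap closes
  expect_equal(out$fraction[out$set == "nonbridged"], 0.5)  # only the close one
  expect_equal(out$n[out$set == "nonbridged_matched"], 1)
  expect_equal(out$fraction[out$set == "nonbridged_matched"], 1)

  # a barely-expanding factor overlaps nothing
  tiny <- overlap_after_expansion(cloud, bridged, nonbridged,
                                  factor = 1.0001, match_cutoff = 0.23)
  expect_true(all(tiny$fraction == 0))
  expect_error(overlap_after_expansion(cloud, bridged[0, ], nonbridged, 1.15),
               "bridged")
})
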