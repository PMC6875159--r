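# Fixture builders and independent brute-force oracles shared across tests.
# Oracles deliberately use plain loops and base arithmetic, never the
# package's vectorized geometry.

make_line_cloud <- function() {
  # three collinear vesicles, first one docked
  ves <- tibble::tibble(
    id = 0:2, x_nm = c(0, 40, 80), y_nm = 0, z_nm = 0,
    radius_nm = c(18, 19, 20), docked = c(TRUE, FALSE, FALSE)
  )
  vesicle_cloud(ves, bounds = box_bounds(c(-30, 110), c(-30, 30), c(-30, 30)))
}

make_random_cloud <- function(n = 50, seed = 402, edge = 250,
                              n_docked = 4) {
  set.seed(seed)
  ves <- tibble::tibble(
    id = seq_len(n) - 1L,
    x_nm = runif(n, 0, edge), y_nm = runif(n, 0, edge),
    z_nm = runif(n, 0, edge),
    radius_nm = runif(n, 15, 22),
    docked = c(rep(TRUE, n_docked), rep(FALSE, n - n_docked))
  )
  vesicle_cloud(ves, bounds = box_bounds(c(0, edge), c(0, edge), c(0, edge)))
}

oracle_separation <- function(v, i, j, d_med) {
  d <- sqrt((v$x_nm[i] - v$x_nm[j])^2 + (v$y_nm[i] - v$y_nm[j])^2 +
              (v$z_nm[i] - v$z_nm[j])^2)
  (d - v$radius_nm[i] - v$radius_nm[j]) / d_med
}

oracle_z_angle <- function(v, i, j) {
  dx <- v$x_nm[j] - v$x_nm[i]; dy <- v$y_nm[j] - v$y_nm[i]
  dz <- v$z_nm[j] - v$z_nm[i]
  asin(abs(dz) / sqrt(dx^2 + dy^2 + dz^2)) * 180 / pi
}

# all-pairs loop over the survey filters, mirroring the criteria definition
oracle_eligible_pairs <- function(cloud, criteria) {
  v <- cloud$vesicles
  d_med <- median(2 * v$radius_nm)
  zmin <- cloud$bounds["min", "z"]; zmax <- cloud$bounds["max", "z"]
  out <- list()
  n <- nrow(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sep <- oracle_separation(v, i, j, d_med)
      ang <- oracle_z_angle(v, i, j)
      clear_i <- (min(v$z_nm[i] - zmin, zmax - v$z_nm[i]) - v$radius_nm[i]) / d_med
      clear_j <- (min(v$z_nm[j] - zmin, zmax - v$z_nm[j]) - v$radius_nm[j]) / d_med
      if (sep <= criteria$max_separation && ang <= criteria$max_z_angle &&
          (clear_i >= criteria$edge_margin || clear_j >= criteria$edge_margin)) {
        out[[length(out) + 1]] <- c(min(v$id[i], v$id[j]), max(v$id[i], v$id[j]))
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# continuity-corrected score-test inversion for the Wilson oracle
oracle_wilson_cc <- function(k, n, confidence) {
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- k / n
  f <- function(p0) abs(phat - p0) - 1 / (2 * n) - z * sqrt(p0 * (1 - p0) / n)
  lower <- if (k == 0) 0 else uniroot(f, c(1e-12, phat), tol = 1e-12)$root
  upper <- if (k == n) 1 else uniroot(f, c(phat, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}

pair_key <- function(tab) paste(tab$id_i, tab$id_j)
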