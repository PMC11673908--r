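# parameters: cluster scatter, Balance Index, geometry, ratios

# small helper: clusters with prescribed means and optional jitter
clusters_at <- function(means, n = 4, sd = 0, seed = 1) {
  set.seed(seed)
  out <- lapply(means, function(mu) {
    cbind(x = rnorm(n, mu[1], sd), y = rnorm(n, mu[2], sd))
  })
  structure(out, counts = vapply(out, nrow, 1L), fallback_c = 0L,
            class = "marker_clusters")
}

# a simple valid 10-cluster geometry (combined frame, both sides)
default_means <- function() {
  list(A_L = c(-0.14, 0.83), A_R = c(0.14, 0.83),
       B_L = c(-0.16, 0.81), B_R = c(0.16, 0.81),
       C_LR = c(0, 0.57), C_RL = c(0, 0.57),
       D_L = c(-0.18, 0.31), D_R = c(0.18, 0.31),
       E_L = c(-0.02, 0.004), E_R = c(0.02, 0.004))
}

test_that("cluster_stats computes sample SDs and the area product", {
  pts <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  st <- cluster_stats(pts)
  expect_equal(st$sigma_x, sqrt(4 / 3), tolerance = 1e-12)   # 1.1547
  expect_equal(st$sigma_y, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(st$area, 4 / 3, tolerance = 1e-12)            # 1.3333
  expect_equal(cluster_stats(rbind(c(1, 1), c(1, 1)))$area, 0)
  expect_error(cluster_stats(rbind(c(1, 1))), "at least 2")
  # quadratic scaling of the area
  expect_equal(cluster_stats(3 * pts)$area, 9 * st$area, tolerance = 1e-12)
})

test_that("balance index sums the five zone areas and scales quadratically", {
  cl <- clusters_at(default_means(), n = 6, sd = 0.01, seed = 42)
  bi <- balance_index(cl)
  manual <- sum(vapply(cl, function(p) sd(p[, 1]) * sd(p[, 2]), 0))
  expect_equal(bi$bi_raw, manual, tolerance = 1e-12)
  expect_equal(sum(bi$percent), 100, tolerance = 1e-9)
  expect_equal(bi$bi, bi$bi_raw)

  k <- 2.5
  cl_k <- lapply(cl, function(p) p * k)
  attributes(cl_k) <- attributes(cl)
  bi_k <- balance_index(cl_k)
  expect_equal(bi_k$bi_raw, k^2 * bi$bi_raw, tolerance = 1e-9)

  cl0 <- clusters_at(default_means(), n = 4, sd = 0)
  expect_warning(bi0 <- balance_index(cl0), "zero scatter")
  expect_equal(bi0$bi, 0)
  expect_true(all(is.na(bi0$percent)))

  expect_error(balance_index(cl[-1]), "A_L")
})

test_that("BI scale calibration places the optimal threshold at 100", {
  expect_equal(calibrate_bi_scale(c(2, 3), c(0.5, 1)), 100 / 1.5,
               tolerance = 1e-12)                           # 66.67
  # raw threshold 0.5 -> scale 200
  expect_equal(calibrate_bi_scale(c(0.6, 0.9), c(0.1, 0.4)), 200,
               tolerance = 1e-12)
  expect_error(calibrate_bi_scale(c(1, 1), c(1, 1)), "degenerate")
})

test_that("geometry parameters reproduce a planted template exactly", {
  want <- planted_parameters(cohort_template("diabetic"))
  got <- geometry_parameters(sample_marker_clusters(scaled_template("diabetic", 0),
                                                    4, seed = 1))
  for (p in setdiff(parameter_names(), "BI")) {
    expect_equal(got[[p]], want[[p]], tolerance = 1e-9, label = p)
  }
})

test_that("ratios and distances follow from the cluster means", {
  m <- default_means()
  # colinear A, B, C on both transfer paths: AB = 0.1, BC = 0.3 -> Ra = 3
  m$A_L <- c(0, 0.8); m$A_R <- c(0, 0.8)
  m$B_L <- c(0, 0.7); m$B_R <- c(0, 0.7)
  m$C_LR <- c(0, 0.4); m$C_RL <- c(0, 0.4)
  # right-angle D/E layout: legs 3 and 4 (scaled by 0.1) -> DE = 0.5
  m$D_L <- c(-0.3, 0.4); m$D_R <- c(0.3, 0.4)
  m$E_L <- c(-0.6, 0); m$E_R <- c(0.6, 0)
  g <- geometry_parameters(clusters_at(m, n = 3, sd = 0))
  expect_equal(g$AB, 0.1, tolerance = 1e-12)
  expect_equal(g$BC, 0.3, tolerance = 1e-12)
  expect_equal(g$Ra, 3, tolerance = 1e-12)
  expect_equal(g$DE, 0.5, tolerance = 1e-12)   # sqrt(0.3^2 + 0.4^2)

  # degenerate AB -> Ra undefined
  m$A_L <- m$B_L; m$A_R <- m$B_R
  expect_error(geometry_parameters(clusters_at(m, n = 3, sd = 0)),
               "Ra undefined")
})

test_that("geometry is translation invariant; scaling acts linearly/quadratically", {
  cl <- clusters_at(default_means(), n = 5, sd = 0.008, seed = 7)
  g <- geometry_parameters(cl)
  bi <- suppressWarnings(balance_index(cl))

  shift <- c(0.03, -0.2)
  cl_t <- lapply(cl, function(p) sweep(p, 2, shift, `+`))
  attributes(cl_t) <- attributes(cl)
  g_t <- geometry_parameters(cl_t)
  for (p in c("AE", "BD", "AB", "BC", "CD", "DE", "Ra", "Rp")) {
    expect_equal(g_t[[p]], g[[p]], tolerance = 1e-12, label = p)
  }
  expect_equal(g_t$ap_A, g$ap_A + shift[2], tolerance = 1e-12)
  expect_equal(suppressWarnings(balance_index(cl_t))$bi, bi$bi,
               tolerance = 1e-12)

  k <- 3
  cl_k <- lapply(cl, function(p) p * k)
  attributes(cl_k) <- attributes(cl)
  g_k <- geometry_parameters(cl_k)
  for (p in c("AE", "BD", "AB", "BC", "CD", "DE")) {
    expect_equal(g_k[[p]], k * g[[p]], tolerance = 1e-9, label = p)
  }
  expect_equal(g_k$Ra, g$Ra, tolerance = 1e-9)
  expect_equal(g_k$Rp, g$Rp, tolerance = 1e-9)
  expect_equal(suppressWarnings(balance_index(cl_k))$bi, k^2 * bi$bi,
               tolerance = 1e-9)
})

test_that("the gait line AE differs from the sum AB + BD + DE off the line", {
  g <- geometry_parameters(clusters_at(default_means(), n = 3, sd = 0))
  expect_gt(abs(g$AB + g$BD + g$DE - g$AE), 1e-3)
})
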