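# cyclogram: COP combination, marker extraction, transfer intersections

test_that("combine_cop is the force-weighted average with correct limits", {
  # equal forces, symmetric COPs -> midpoint
  eq <- combine_cop(400, -0.1, 0.5, 400, 0.1, 0.5)
  expect_equal(c(eq$x, eq$y), c(0, 0.5))
  # single support collapses to the loaded foot
  ss <- combine_cop(0, NA, NA, 300, 0.07, 0.31)
  expect_equal(c(ss$x, ss$y), c(0.07, 0.31))
  # hand-evaluated weighted mean: F_R = 2 F_L
  wm <- combine_cop(100, 0, 0.2, 200, 0.1, 0.8)
  expect_equal(wm$x, 0.2 / 3, tolerance = 1e-12)
  expect_equal(wm$y, 0.6, tolerance = 1e-12)
  # swing gap: both zero -> undefined, not an error
  sw <- combine_cop(0, NA, NA, 0, NA, NA)
  expect_true(is.na(sw$x) && is.na(sw$y))
})

test_that("combine_cop output is a convex combination of the foot COPs", {
  set.seed(4)
  for (i in 1:50) {
    fl <- runif(1, 0, 800); fr <- runif(1, 0, 800)
    if (fl + fr == 0) next
    xl <- runif(1, -0.2, 0); xr <- runif(1, 0, 0.2)
    yl <- runif(1); yr <- runif(1)
    cc <- combine_cop(fl, xl, yl, fr, xr, yr)
    if (fl > 0 && fr > 0) {
      expect_gte(cc$x, min(xl, xr)); expect_lte(cc$x, max(xl, xr))
      expect_gte(cc$y, min(yl, yr)); expect_lte(cc$y, max(yl, yr))
    }
  }
})

test_that("during single support the cyclogram follows the loaded foot's gait line", {
  gen <- generate_recording(cohort_template("healthy"), study_spec(), seed = 3)
  rec <- gen$recording
  cc <- combined_cop(rec)
  solo <- rec$left$F > 0 & rec$right$F == 0
  expect_true(any(solo))
  expect_equal(cc$x[solo], rec$left$x[solo])
  expect_equal(cc$y[solo], rec$left$y[solo])
})

test_that("foot markers recover a monotone planted path at its extremes", {
  gen <- generate_recording(scaled_template("healthy", 0), study_spec(),
                            seed = 1)
  rec <- gen$recording
  cyc <- assemble_gait_cycles(detect_stance_intervals(rec$left$F, rec$rate),
                              detect_stance_intervals(rec$right$F, rec$rate))
  tpl <- cohort_template("healthy")
  mk <- extract_foot_markers(cyc[[1]], rec)
  expect_equal(unname(mk$E_L[1, "y"]), tpl$ap[["E"]], tolerance = 1e-9)
  expect_equal(unname(mk$A_L[1, "y"]), tpl$ap[["A"]], tolerance = 1e-9)
  expect_equal(unname(mk$D_R[1, "y"]), tpl$ap[["D"]], tolerance = 1e-9)
  expect_equal(unname(mk$B_R[1, "y"]), tpl$ap[["B"]], tolerance = 1e-9)
})

test_that("too-short stances raise a marker error", {
  gen <- generate_recording(cohort_template("healthy"), study_spec(), seed = 6)
  rec <- gen$recording
  cyc <- assemble_gait_cycles(detect_stance_intervals(rec$left$F, rec$rate),
                              detect_stance_intervals(rec$right$F, rec$rate))
  cy <- cyc[[1]]
  rec2 <- rec
  # leave only 2 valid COP samples in the left stance
  idx <- cy$hs_left:cy$to_left
  rec2$left$y[idx[-(1:2)]] <- NA
  expect_error(extract_foot_markers(cy, rec2), "marker error")
})

test_that("transfer intersection solves crossings and falls back symmetrically", {
  xcross <- intersect_transfers(rbind(c(0, 0), c(1, 1)),
                                rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(xcross$point), c(0.5, 0.5))
  expect_identical(xcross$method, "intersection")

  par <- intersect_transfers(rbind(c(0, 0), c(1, 0)),
                             rbind(c(0, 0.1), c(1, 0.1)))
  expect_equal(unname(par$point), c(0.5, 0.05))
  expect_identical(par$method, "closest_approach")

  expect_error(intersect_transfers(rbind(c(0, 0)), rbind(c(0, 1), c(1, 0))),
               "at least 2 points")
})

test_that("intersection matches the brute-force all-pairs oracle on random polylines", {
  set.seed(19)
  hits_checked <- 0L
  for (rep in 1:40) {
    # two crossing random walks with ~10 segments each
    p <- cbind(x = seq(-1, 1, length.out = 11) + rnorm(11, 0, 0.15),
               y = cumsum(rnorm(11, 0, 0.4)))
    q <- cbind(x = seq(1, -1, length.out = 11) + rnorm(11, 0, 0.15),
               y = cumsum(rnorm(11, 0, 0.4)))
    oracle <- brute_intersections(p, q)
    got <- intersect_transfers(p, q)
    if (!is.null(oracle)) {
      first <- oracle[order(oracle[, "i"], oracle[, "s"], oracle[, "j"]), ,
                      drop = FALSE][1, ]
      expect_identical(got$method, "intersection")
      expect_equal(unname(got$point), unname(first[c("x", "y")]),
                   tolerance = 1e-9)
      hits_checked <- hits_checked + 1L
    } else {
      expect_identical(got$method, "closest_approach")
    }
    # result lies within the joint bounding box of both polylines
    box <- rbind(p, q)
    expect_gte(got$point[["x"]], min(box[, 1]) - 1e-9)
    expect_lte(got$point[["x"]], max(box[, 1]) + 1e-9)
  }
  expect_gte(hits_checked, 20L)
})

test_that("marker clusters stack strides and insist on two points per label", {
  gen <- generate_recording(scaled_template("healthy", 0), study_spec(),
                            seed = 1)
  mk <- extract_markers(gen$recording)
  counts <- attr(mk$clusters, "counts")
  expect_true(all(counts == study_spec()$cycles))
  # zero scatter: every stride contributes the identical point
  expect_equal(max(apply(mk$clusters$B_L, 2, function(v) diff(range(v)))), 0,
               tolerance = 1e-12)
  expect_error(collect_clusters(list()), "at least 2")
})

test_that("extracted cluster means recover the planted template geometry", {
  gen <- generate_recording(cohort_template("diabetic"), study_spec(),
                            seed = 77)
  got <- extract_markers(gen$recording)$clusters
  want <- gen$ground_truth$clusters
  for (lab in names(want)) {
    expect_equal(colMeans(got[[lab]]), colMeans(want[[lab]]),
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})
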