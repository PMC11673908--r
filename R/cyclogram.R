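# The combined-COP cyclogram and its ten marker points.

#' Combine left and right COP into the cyclogram COP
#'
#' The cyclogram (butterfly diagram) traces the force-weighted average of the
#' two feet's COP coordinates:
#' x = (F_R x_R + F_L x_L) / (F_R + F_L), and likewise for y. During single
#' support this collapses to the loaded foot's COP; samples where both forces
#' are zero are undefined and returned as `NA` (swing gaps are skipped, not
#' errors).
#'
#' @param f_left,f_right vertical forces (>= 0), vectorized.
#' @param x_left,y_left,x_right,y_right per-foot COP coordinates; may be `NA`
#'   where the corresponding force is zero.
#' @return a data frame with columns `x`, `y`, `F` (total force).
#' @export
combine_cop <- function(f_left, x_left, y_left, f_right, x_right, y_right) {
  if (any(stats::na.omit(c(f_left, f_right)) < 0)) {
    stop("forces must be non-negative")
  }
  f_left[is.na(f_left)] <- 0
  f_right[is.na(f_right)] <- 0
  tot <- f_left + f_right
  # zero-force side contributes nothing; avoid NA * 0 leakage from swing COPs
  zx_l <- ifelse(f_left > 0, x_left, 0); zy_l <- ifelse(f_left > 0, y_left, 0)
  zx_r <- ifelse(f_right > 0, x_right, 0); zy_r <- ifelse(f_right > 0, y_right, 0)
  x <- ifelse(tot > 0, (f_left * zx_l + f_right * zx_r) / tot, NA_real_)
  y <- ifelse(tot > 0, (f_left * zy_l + f_right * zy_r) / tot, NA_real_)
  data.frame(x = x, y = y, F = tot)
}

#' Cyclogram COP series of a whole recording
#'
#' @param rec a normalized [insole_recording()].
#' @return a data frame with columns `t`, `x`, `y`, `F`.
#' @export
combined_cop <- function(rec) {
  stopifnot(inherits(rec, "insole_recording"))
  cc <- combine_cop(rec$left$F, rec$left$x, rec$left$y,
                    rec$right$F, rec$right$x, rec$right$y)
  cbind(t = rec$left$t, cc)
}

# argmin/argmax over a window of a coordinate vector, NA-safe, earliest tie
.arg_extreme <- function(v, window, max = FALSE) {
  idx <- window[1L]:window[2L]
  vals <- v[idx]
  if (all(is.na(vals))) return(NA_integer_)
  if (max) idx[which.max(vals)] else idx[which.min(vals)]
}

#' Extract the E, A, D and B markers of one gait cycle
#'
#' Per side: E is the rearmost (minimum antero-posterior) COP of the foot
#' over its own stance and A the frontmost (maximum), i.e. the endpoints of
#' the gait line; D and B are the minimum and maximum of the *combined* COP
#' over that foot's single-support window, which at sample resolution are the
#' COP positions at contralateral toe-off and contralateral heel strike. Ties
#' are broken by the earliest sample.
#'
#' @param cycle a `gait_cycle` from [assemble_gait_cycles()].
#' @param rec the normalized [insole_recording()].
#' @param min_samples minimum number of valid COP samples per stance
#'   (default 3); shorter stances raise a marker error and the cycle should
#'   be dropped by the caller.
#' @return a named list of 2-column matrices (columns `x`, `y`) with entries
#'   `E_L, A_L, D_L, B_L, E_R, A_R, D_R, B_R`, each a single point.
#' @export
extract_foot_markers <- function(cycle, rec, min_samples = 3L) {
  stopifnot(inherits(cycle, "gait_cycle"))
  cc <- combined_cop(rec)
  stance <- list(L = c(cycle$hs_left, cycle$to_left),
                 R = c(cycle$hs_right, cycle$to_right))
  ss <- list(L = cycle$ss_left, R = cycle$ss_right)
  out <- list()
  for (side in c("L", "R")) {
    foot <- if (side == "L") rec$left else rec$right
    win <- stance[[side]]
    valid <- sum(!is.na(foot$y[win[1L]:win[2L]]))
    if (valid < min_samples) {
      stop("marker error: ", side, " stance has only ", valid,
           " valid COP samples")
    }
    iE <- .arg_extreme(foot$y, win, max = FALSE)
    iA <- .arg_extreme(foot$y, win, max = TRUE)
    iD <- .arg_extreme(cc$y, ss[[side]], max = FALSE)
    iB <- .arg_extreme(cc$y, ss[[side]], max = TRUE)
    if (anyNA(c(iD, iB))) {
      stop("marker error: no valid combined COP in ", side, " single support")
    }
    out[[paste0("E_", side)]] <- cbind(x = foot$x[iE], y = foot$y[iE])
    out[[paste0("A_", side)]] <- cbind(x = foot$x[iA], y = foot$y[iA])
    out[[paste0("D_", side)]] <- cbind(x = cc$x[iD], y = cc$y[iD])
    out[[paste0("B_", side)]] <- cbind(x = cc$x[iB], y = cc$y[iB])
  }
  # physiological ordering along the gait line; violations are warned, kept
  for (side in c("L", "R")) {
    ap <- c(out[[paste0("E_", side)]][, "y"], out[[paste0("D_", side)]][, "y"],
            out[[paste0("B_", side)]][, "y"], out[[paste0("A_", side)]][, "y"])
    if (is.unsorted(ap)) {
      warning("marker ap ordering E <= D <= B <= A violated on side ", side)
    }
  }
  out
}

# segment-segment intersection; returns c(s, t) parameters or NULL
.seg_intersect <- function(p1, p2, q1, q2, eps = 1e-12) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(den) < eps) return(NULL)                  # parallel / degenerate
  b <- q1 - p1
  s <- (b[1L] * d2[2L] - b[2L] * d2[1L]) / den
  t <- (b[1L] * d1[2L] - b[2L] * d1[1L]) / den
  if (s < -eps || s > 1 + eps || t < -eps || t > 1 + eps) return(NULL)
  c(s = min(max(s, 0), 1), t = min(max(t, 0), 1))
}

# closest points between two segments (clamped); returns list(p, q, dist);
# for parallel overlapping segments the midpoint of the overlap is used so
# the closest-approach pair is symmetric in the two polylines
.seg_closest <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  clamp <- function(v) min(max(v, 0), 1)
  if (a <= 1e-30 && e <= 1e-30) { s <- 0; t <- 0 }
  else if (a <= 1e-30) { s <- 0; t <- clamp(f / e) }
  else {
    c_ <- sum(d1 * r)
    if (e <= 1e-30) { t <- 0; s <- clamp(-c_ / a) }
    else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      if (den > 1e-12 * a * e) {
        s <- clamp((b * f - c_ * e) / den)
        t <- (b * s + f) / e
        if (t < 0) { t <- 0; s <- clamp(-c_ / a) }
        else if (t > 1) { t <- 1; s <- clamp((b - c_) / a) }
      } else {
        # parallel: centre of the projection overlap (unique symmetric choice)
        t0 <- sum((q1 - p1) * d1) / a
        t1 <- sum((q2 - p1) * d1) / a
        lo <- max(0, min(t0, t1)); hi <- min(1, max(t0, t1))
        s <- if (lo <= hi) (lo + hi) / 2 else clamp(if (t0 > 1) 1 else 0)
        t <- clamp(sum((p1 + s * d1 - q1) * d2) / e)
      }
    }
  }
  P <- p1 + s * d1; Q <- q1 + t * d2
  list(p = P, q = Q, dist = sqrt(sum((P - Q)^2)))
}

#' Intersect two COP transfer polylines
#'
#' Finds the butterfly intersection point C of two double-support transfer
#' paths. The first proper segment-pair intersection in temporal order of `p`
#' (then of `q`) is returned. When the polylines do not cross (pathological
#' gait), the midpoint of the closest-approach pair of points is returned
#' instead and flagged, so that C clusters keep their size.
#'
#' @param p,q numeric matrices (n x 2, columns x/y) of polyline vertices in
#'   temporal order; each needs at least 2 points.
#' @return a list with `point` (length-2 named vector) and `method`
#'   (`"intersection"` or `"closest_approach"`).
#' @export
intersect_transfers <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) < 2L || nrow(q) < 2L) {
    stop("transfer polylines need at least 2 points")
  }
  for (i in seq_len(nrow(p) - 1L)) {
    # temporally first crossing along p: smallest s over all q segments
    best_s <- Inf
    for (j in seq_len(nrow(q) - 1L)) {
      st <- .seg_intersect(p[i, ], p[i + 1L, ], q[j, ], q[j + 1L, ])
      if (!is.null(st) && st[["s"]] < best_s) best_s <- st[["s"]]
    }
    if (is.finite(best_s)) {
      pt <- p[i, ] + best_s * (p[i + 1L, ] - p[i, ])
      return(list(point = c(x = pt[[1L]], y = pt[[2L]]),
                  method = "intersection"))
    }
  }
  best <- NULL
  for (i in seq_len(nrow(p) - 1L)) {
    for (j in seq_len(nrow(q) - 1L)) {
      cl <- .seg_closest(p[i, ], p[i + 1L, ], q[j, ], q[j + 1L, ])
      if (is.null(best) || cl$dist < best$dist) best <- cl
    }
  }
  mid <- (best$p + best$q) / 2
  list(point = c(x = mid[[1L]], y = mid[[2L]]), method = "closest_approach")
}

# transfer polyline of the combined COP over [from-1, to+1], i.e. from the
# last pure-trailing-foot sample to the first pure-leading-foot sample
.transfer_polyline <- function(cc, from, to) {
  idx <- max(1L, from - 1L):min(nrow(cc), to + 1L)
  m <- as.matrix(cc[idx, c("x", "y")])
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Extract all ten markers of one gait cycle
#'
#' Adds the two intersection points to [extract_foot_markers()]: `C_LR` is
#' the crossing of the cycle's left-to-right transfer with the incoming
#' right-to-left transfer, and `C_RL` the crossing of the outgoing
#' right-to-left transfer with the left-to-right transfer — one C per
#' double-support transfer, labeled by the direction of the later transfer.
#'
#' @inheritParams extract_foot_markers
#' @return a `marker_set`: the list from [extract_foot_markers()] plus
#'   `C_LR`, `C_RL`, and a character vector `c_method` of length 2.
#' @export
extract_cycle_markers <- function(cycle, rec, min_samples = 3L) {
  mk <- extract_foot_markers(cycle, rec, min_samples)
  cc <- combined_cop(rec)
  rl_in <- .transfer_polyline(cc, cycle$hs_left, cycle$to_right_in)
  lr <- .transfer_polyline(cc, cycle$hs_right, cycle$to_left)
  rl_out <- .transfer_polyline(cc, cycle$hs_left_next, cycle$to_right)
  c_lr <- intersect_transfers(lr, rl_in)
  c_rl <- intersect_transfers(rl_out, lr)
  mk$C_LR <- rbind(c_lr$point)
  mk$C_RL <- rbind(c_rl$point)
  mk$c_method <- c(C_LR = c_lr$method, C_RL = c_rl$method)
  class(mk) <- "marker_set"
  mk
}

.cluster_labels <- c("A_L", "A_R", "B_L", "B_R", "C_LR", "C_RL",
                     "D_L", "D_R", "E_L", "E_R")

#' Collect marker clusters across strides
#'
#' Stacks the ten labeled marker points of each accepted stride into ten
#' clusters, the substrate of all cyclogram parameters. Every cluster needs
#' at least 2 points so that standard deviations are defined.
#'
#' @param marker_sets a list of `marker_set` objects (>= 2 accepted strides).
#' @return a `marker_clusters` object: a named list of n x 2 matrices, with
#'   attributes `counts` and `fallback_c` (number of closest-approach C
#'   points).
#' @export
collect_clusters <- function(marker_sets) {
  if (length(marker_sets) < 2L) {
    stop("clustering needs at least 2 accepted strides, got ",
         length(marker_sets))
  }
  out <- lapply(.cluster_labels, function(lab) {
    do.call(rbind, lapply(marker_sets, function(mk) mk[[lab]]))
  })
  names(out) <- .cluster_labels
  short <- names(out)[vapply(out, nrow, 1L) < 2L]
  if (length(short)) {
    stop("cluster(s) with fewer than 2 points: ", paste(short, collapse = ", "))
  }
  fallback <- sum(vapply(marker_sets, function(mk) {
    sum(mk$c_method == "closest_approach")
  }, 1L))
  structure(out, counts = vapply(out, nrow, 1L), fallback_c = fallback,
            class = "marker_clusters")
}

#' @export
print.marker_clusters <- function(x, ...) {
  cat("<marker_clusters> ", paste0(names(x), "(", attr(x, "counts"), ")",
                                   collapse = " "), "\n", sep = "")
  if (attr(x, "fallback_c") > 0) {
    cat("  closest-approach C fallbacks:", attr(x, "fallback_c"), "\n")
  }
  invisible(x)
}

#' Run the marker-extraction pipeline on one recording
#'
#' Detects stance intervals on both feet, assembles and validates gait
#' cycles, extracts the ten markers per stride (dropping and logging cycles
#' that fail), and collects the marker clusters.
#'
#' @param rec a normalized [insole_recording()].
#' @param threshold_rel,min_stance_s see [detect_stance_intervals()].
#' @param band see [validate_steps()].
#' @return a list: `clusters` ([collect_clusters()]), `cycles` (accepted
#'   gait cycles), and `qc` (cluster sizes, fallback-C count, dropped-cycle
#'   log).
#' @export
extract_markers <- function(rec, threshold_rel = 0.05, min_stance_s = 0.2,
                            band = 0.3) {
  stopifnot(inherits(rec, "insole_recording"))
  if (!rec$normalized) stop("recording must be normalized first")
  ivL <- detect_stance_intervals(rec$left$F, rec$rate, threshold_rel,
                                 min_stance_s)
  ivR <- detect_stance_intervals(rec$right$F, rec$rate, threshold_rel,
                                 min_stance_s)
  cycles <- assemble_gait_cycles(ivL, ivR)
  cycles <- validate_steps(cycles, rec, band)
  dropped <- character(0)
  sets <- list()
  for (k in seq_along(cycles)) {
    mk <- tryCatch(extract_cycle_markers(cycles[[k]], rec),
                   error = function(e) conditionMessage(e))
    if (is.character(mk)) dropped <- c(dropped, paste0("cycle ", k, ": ", mk))
    else sets[[length(sets) + 1L]] <- mk
  }
  clusters <- collect_clusters(sets)
  list(clusters = clusters, cycles = cycles,
       qc = list(cluster_sizes = attr(clusters, "counts"),
                 fallback_c = attr(clusters, "fallback_c"),
                 rejected_steps = attr(cycles, "rejections"),
                 dropped_cycles = dropped))
}
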