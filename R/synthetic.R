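# Synthetic two-cohort insole gait data with planted marker geometry.

#' Study design of a synthetic gait experiment
#'
#' Holds the protocol-level constants of a simulated walking study: sampling
#' rate, stride timing, steps per dataset, cohort sizes and the
#' participant-level variability. Defaults emulate a level-walkway protocol:
#' 50 Hz sampling, 12 consecutive steps (= 6 complete gait cycles) per
#' dataset, 1.2 s stride period with 7-sample double-support phases, and two
#' cohorts of 56 impaired datasets over 14 participants and 70 healthy
#' datasets over 15 participants (126 datasets in total).
#'
#' @param n_pos,n_neg datasets per cohort (positive = impaired).
#' @param participants_pos,participants_neg participants per cohort; datasets
#'   are assigned to participants round-robin.
#' @param steps steps per dataset (a step is a half stride); the number of
#'   complete gait cycles is `round(steps / 2)`.
#' @param rate sampling frequency (Hz).
#' @param stride_s stride period (s); `stride_s * rate` must be an even
#'   integer so that events fall on the sample grid.
#' @param ds_samples double-support duration in samples per transfer.
#' @param participant_sd SD of the per-participant random offsets applied to
#'   marker anchor positions (normalized units), drawn once per participant.
#' @param force_peak stance peak vertical force (recording units).
#' @param force_base relative mid-stance force level of the two-hump force
#'   model, in (0, 1).
#' @return a `study_spec` list.
#' @export
study_spec <- function(n_pos = 56, n_neg = 70,
                       participants_pos = 14, participants_neg = 15,
                       steps = 12, rate = 50, stride_s = 1.2,
                       ds_samples = 7, participant_sd = 0.0025,
                       force_peak = 700, force_base = 0.7) {
  n_stride <- round(stride_s * rate)
  if (abs(n_stride - stride_s * rate) > 1e-9 || n_stride %% 2L != 0L) {
    stop("stride_s * rate must be an even integer number of samples")
  }
  stopifnot(n_pos > 0, n_neg > 0, participants_pos > 0, participants_neg > 0,
            steps >= 2, rate > 0, ds_samples >= 2,
            ds_samples < n_stride / 2, force_base > 0, force_base < 1)
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 participants_pos = participants_pos,
                 participants_neg = participants_neg,
                 steps = steps, rate = rate, stride_s = stride_s,
                 n_stride = as.integer(n_stride),
                 half = as.integer(n_stride / 2),
                 ds_samples = as.integer(ds_samples),
                 n_stance = as.integer(n_stride / 2 + ds_samples),
                 cycles = max(1L, as.integer(round(steps / 2))),
                 participant_sd = participant_sd,
                 force_peak = force_peak, force_base = force_base),
            class = "study_spec")
}

# local (0-based) anchor sample indices within one stance
.anchor_idx <- function(spec) {
  c(E = 0L, D = spec$ds_samples, B = spec$half - 1L, A = spec$n_stance - 1L)
}

# stance-local force profile: linear loading/unloading cross-fade ramps over
# the double-support windows (with a 10% initial-contact floor so heel strike
# is sharp at sample resolution) times a two-hump (heel / push-off) M shape
.stance_force <- function(spec) {
  k <- 0:(spec$n_stance - 1L)
  nds <- spec$ds_samples
  ramp <- pmin(1, 0.1 + 0.9 * k / nds, 0.1 + 0.9 * (spec$n_stance - 1 - k) / nds)
  span <- spec$n_stance - 1L
  g <- exp(-((k - 0.25 * span) / (span / 6))^2) +
    exp(-((k - 0.75 * span) / (span / 6))^2)
  m <- spec$force_base + (1 - spec$force_base) * g / max(g)
  spec$force_peak * ramp * m
}

# piecewise-linear stance COP path through the anchor points; after a brief
# loading phase the COP dwells at D until the end of double support (the COP
# rushes through the heel region, then lingers at midfoot), giving the
# transfer path its straight-diagonal butterfly shape
.stance_path <- function(anchors, spec) {
  idx <- .anchor_idx(spec)
  load <- max(1L, as.integer(round(0.45 * spec$ds_samples)))
  ki <- c(idx[["E"]], load, idx[["D"]], idx[["B"]], idx[["A"]])
  vx <- anchors[c(1L, 2L, 2L, 3L, 4L), 1L]
  vy <- anchors[c(1L, 2L, 2L, 3L, 4L), 2L]
  k <- 0:(spec$n_stance - 1L)
  cbind(x = stats::approx(ki, vx, xout = k)$y,
        y = stats::approx(ki, vy, xout = k)$y)
}

# combined-COP transfer polyline, closed form: from the last pure-trailing
# sample (marker B of the push-off foot) to the first pure-leading sample
# (marker D of the loading foot)
.transfer_points <- function(anchors_trail, anchors_lead, spec) {
  f <- .stance_force(spec)
  path_t <- .stance_path(anchors_trail, spec)
  path_l <- .stance_path(anchors_lead, spec)
  nds <- spec$ds_samples
  pts <- matrix(NA_real_, nds + 2L, 2L, dimnames = list(NULL, c("x", "y")))
  pts[1L, ] <- path_t[spec$half, ]                   # B, local half-1
  for (j in 0:(nds - 1L)) {
    kt <- spec$half + j                              # trailing local index
    ft <- f[kt + 1L]; fl <- f[j + 1L]
    pts[j + 2L, ] <- (ft * path_t[kt + 1L, ] + fl * path_l[j + 1L, ]) /
      (ft + fl)
  }
  pts[nds + 2L, ] <- path_l[nds + 1L, ]              # D, local ds_samples
  pts
}

# first crossing of a polyline with the vertical line x = x0
.x_crossing <- function(pts, x0 = 0) {
  dx <- pts[, 1L] - x0
  for (i in seq_len(nrow(pts) - 1L)) {
    if (dx[i] == 0) return(c(x = x0, y = unname(pts[i, 2L])))
    if (dx[i] * dx[i + 1L] < 0) {
      t <- dx[i] / (dx[i] - dx[i + 1L])
      return(c(x = x0,
               y = unname(pts[i, 2L] + t * (pts[i + 1L, 2L] - pts[i, 2L]))))
    }
  }
  NULL
}

#' Cohort template of cyclogram marker geometry and scatter
#'
#' A template fixes, per marker zone and side, the mean position of the
#' marker anchors E, D, B, A (antero-posterior coordinate `ap` in
#' insole-length units, heel = 0; lateral half-width `lat` from the midline,
#' left foot mirrored to negative) and the per-cluster Gaussian scatter
#' `sigma` for zones A--E. The C marker is not an anchor: it emerges as the
#' crossing of the double-support transfer paths and is computed here in
#' closed form (`c_point`).
#'
#' The built-in cohorts encode the geometry contrast between healthy and
#' neuropathy-impaired gait: healthy cyclograms have a long BC and a short AB
#' (the combined COP travels far beyond the forefoot contact point), while
#' impaired cyclograms collapse (short BC, long AB) and scatter more. Scatter
#' magnitudes follow the zone ordering B > D > A > C > E.
#'
#' @param cohort `"healthy"`, `"diabetic"`, or `"custom"` (then supply all
#'   geometry arguments).
#' @param ap named numeric, antero-posterior anchor positions `c(E=,D=,B=,A=)`.
#' @param lat named numeric, lateral anchor half-widths `c(E=,D=,B=,A=)`, all
#'   positive (the transfer diagonals must cross the midline).
#' @param sigma named numeric, per-cluster scatter SD (applied to both
#'   coordinates) `c(A=,B=,C=,D=,E=)`; the C entry is used only when marker
#'   clusters are sampled directly (fast mode).
#' @param lat_offset lateral inter-foot offset (default 0).
#' @param label cohort label stored with generated data.
#' @param spec the [study_spec()] whose timing defines the transfer crossing.
#' @return a `cohort_template` with fields `ap`, `lat`, `sigma`,
#'   `lat_offset`, `label`, `c_point`.
#' @export
cohort_template <- function(cohort = c("healthy", "diabetic", "custom"),
                            ap = NULL, lat = NULL, sigma = NULL,
                            lat_offset = 0, label = NULL,
                            spec = study_spec()) {
  cohort <- match.arg(cohort)
  defaults <- list(
    healthy = list(
      ap = c(E = 0.004, D = 0.306, B = 0.810, A = 0.833),
      lat = c(E = 0.0200, D = 0.1810, B = 0.1627, A = 0.1485),
      sigma = c(A = 0.0059, B = 0.0080, C = 0.0054, D = 0.0067, E = 0.0018)),
    diabetic = list(
      ap = c(E = 0.008, D = 0.377, B = 0.695, A = 0.805),
      lat = c(E = 0.0200, D = 0.1815, B = 0.1471, A = 0.0857),
      sigma = c(A = 0.0078, B = 0.0148, C = 0.0072, D = 0.0110, E = 0.0039))
  )
  if (cohort != "custom") {
    d <- defaults[[cohort]]
    if (is.null(ap)) ap <- d$ap
    if (is.null(lat)) lat <- d$lat
    if (is.null(sigma)) sigma <- d$sigma
    if (is.null(label)) label <- cohort
  }
  if (is.null(ap) || is.null(lat) || is.null(sigma)) {
    stop("custom templates need ap, lat and sigma")
  }
  zones <- c("E", "D", "B", "A")
  stopifnot(all(zones %in% names(ap)), all(zones %in% names(lat)),
            all(c("A", "B", "C", "D", "E") %in% names(sigma)))
  if (any(sigma < 0)) stop("invalid template: scatter SDs must be >= 0")
  if (is.unsorted(ap[zones])) {
    stop("invalid template: ap ordering must be E < D < B < A")
  }
  if (lat[["B"]] <= 0 || lat[["D"]] <= 0) {
    stop("invalid template: B and D lateral half-widths must be positive")
  }
  tpl <- structure(list(ap = ap[zones], lat = lat[zones],
                        sigma = sigma[c("A", "B", "C", "D", "E")],
                        lat_offset = lat_offset,
                        label = if (is.null(label)) "custom" else label),
                   class = "cohort_template")
  poly <- .transfer_points(.template_anchors(tpl, "L"),
                           .template_anchors(tpl, "R"), spec)
  cp <- .x_crossing(poly, lat_offset)
  if (is.null(cp)) {
    stop("invalid template: transfer diagonals do not cross the midline")
  }
  tpl$c_point <- cp
  tpl
}

#' @export
print.cohort_template <- function(x, ...) {
  cat("<cohort_template> '", x$label, "'\n", sep = "")
  cat("  ap:   ", paste(names(x$ap), round(x$ap, 3), sep = "=",
                        collapse = " "), "\n")
  cat("  lat:  ", paste(names(x$lat), round(x$lat, 3), sep = "=",
                        collapse = " "), "\n")
  cat("  sigma:", paste(names(x$sigma), signif(x$sigma, 3), sep = "=",
                        collapse = " "), "\n")
  cat("  C point: (", round(x$c_point[["x"]], 4), ", ",
      round(x$c_point[["y"]], 4), ")\n", sep = "")
  invisible(x)
}

# anchor matrix (rows E, D, B, A; columns x, y) for one side, combined frame
.template_anchors <- function(template, side) {
  s <- if (side == "L") -1 else 1
  cbind(x = s * template$lat + s * template$lat_offset / 2,
        y = template$ap)
}

# apply a participant-level offset (named list zone -> c(d_ap, d_lat))
.offset_template <- function(template, offset) {
  if (is.null(offset)) return(template)
  for (z in names(offset)) {
    if (z == "C") next
    template$ap[[z]] <- template$ap[[z]] + offset[[z]][1L]
    template$lat[[z]] <- max(template$lat[[z]] + offset[[z]][2L], 1e-3)
  }
  if (is.unsorted(template$ap)) {
    # participant draw broke the gait-line ordering; fall back to sorting
    template$ap <- sort(template$ap)
    names(template$ap) <- c("E", "D", "B", "A")
  }
  template
}

# recompute the emergent C point after template modification
.refresh_c_point <- function(template, spec) {
  poly <- .transfer_points(.template_anchors(template, "L"),
                           .template_anchors(template, "R"), spec)
  cp <- .x_crossing(poly, template$lat_offset)
  if (is.null(cp)) stop("transfer diagonals do not cross for this template")
  template$c_point <- cp
  template
}

#' Planted parameter vector of a template
#'
#' The cyclogram parameters a noise-free dataset generated from this template
#' realizes: geometry from the anchor points and the emergent C point, and
#' BI = 0 (no scatter).
#'
#' @param template a [cohort_template()].
#' @return a named list of the 15 parameters.
#' @export
planted_parameters <- function(template) {
  clusters <- .template_clusters(template)
  c(geometry_parameters(clusters), list(BI = 0))
}

# degenerate one-point-per-cluster "clusters" at the template positions
.template_clusters <- function(template) {
  aL <- .template_anchors(template, "L")
  aR <- .template_anchors(template, "R")
  cp <- rbind(template$c_point)
  out <- list(A_L = aL["A", , drop = FALSE], A_R = aR["A", , drop = FALSE],
              B_L = aL["B", , drop = FALSE], B_R = aR["B", , drop = FALSE],
              C_LR = cp, C_RL = cp,
              D_L = aL["D", , drop = FALSE], D_R = aR["D", , drop = FALSE],
              E_L = aL["E", , drop = FALSE], E_R = aR["E", , drop = FALSE])
  lapply(out, function(m) {
    colnames(m) <- c("x", "y")
    m
  })
}

# run fn with a locally-set RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

#' Sample marker clusters directly from a template (fast mode)
#'
#' Draws per-stride marker points around the template positions with
#' independent axis-aligned Gaussian scatter — the marker-level shortcut
#' that skips time-series synthesis. The C clusters are centred on the
#' emergent transfer crossing and use the template's C scatter.
#'
#' @param template a [cohort_template()].
#' @param n_strides number of strides (points per cluster), >= 2.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a `marker_clusters` object.
#' @export
sample_marker_clusters <- function(template, n_strides, seed = NULL) {
  stopifnot(inherits(template, "cohort_template"), n_strides >= 2)
  .with_seed(seed, function() {
    centres <- .template_clusters(template)
    sig <- template$sigma
    zone_of <- function(lab) substr(lab, 1L, 1L)
    out <- lapply(names(centres), function(lab) {
      s <- sig[[zone_of(lab)]]
      ctr <- centres[[lab]]
      m <- cbind(x = stats::rnorm(n_strides, ctr[1L, 1L], s),
                 y = stats::rnorm(n_strides, ctr[1L, 2L], s))
      m
    })
    names(out) <- names(centres)
    structure(out, counts = vapply(out, nrow, 1L), fallback_c = 0L,
              class = "marker_clusters")
  })
}

#' Generate a synthetic insole recording
#'
#' Synthesizes a full 50 Hz dual-insole recording from a cohort template:
#' per-stride stance forces follow a two-hump (heel-strike and push-off)
#' profile with cross-fading double-support ramps, and per-foot COP paths
#' run monotonically from the rearmost marker E through D and B to the
#' frontmost marker A with lateral sway, so that overlapping stances produce
#' crossing transfer diagonals. Per-stride marker anchors are jittered with
#' the template's per-zone scatter. Swing samples carry exactly zero force
#' and invalid COP.
#'
#' @param template a [cohort_template()].
#' @param spec a [study_spec()].
#' @param seed optional integer seed.
#' @param meta metadata list stored with the recording.
#' @return a list with `recording` (an [insole_recording()], normalized) and
#'   `ground_truth`: `events` (planted stance intervals), `markers` (one
#'   `marker_set` per complete cycle), `clusters` (the planted marker
#'   clusters), and `planted` (the template's [planted_parameters()]).
#' @export
generate_recording <- function(template, spec = study_spec(), seed = NULL,
                               meta = list()) {
  stopifnot(inherits(template, "cohort_template"),
            inherits(spec, "study_spec"))
  template <- .refresh_c_point(template, spec)
  .with_seed(seed, function() {
    n_left <- spec$cycles + 2L
    n_right <- n_left - 1L
    hs_l <- (seq_len(n_left) - 1L) * spec$n_stride + 1L
    hs_r <- hs_l[-n_left] + spec$half
    n <- hs_l[n_left] + spec$n_stance - 1L + 3L
    jitter_anchors <- function(side) {
      base <- .template_anchors(template, side)
      nst <- if (side == "L") n_left else n_right
      lapply(seq_len(nst), function(i) {
        base + matrix(stats::rnorm(8L, 0, rep(template$sigma[c("E", "D", "B",
                                                              "A")], 2L)),
                      4L, 2L)
      })
    }
    aL <- jitter_anchors("L")
    aR <- jitter_anchors("R")
    f_prof <- .stance_force(spec)
    mk_series <- function(hs, anch) {
      F <- numeric(n); x <- rep(NA_real_, n); y <- rep(NA_real_, n)
      for (i in seq_along(hs)) {
        idx <- hs[i]:(hs[i] + spec$n_stance - 1L)
        path <- .stance_path(anch[[i]], spec)
        F[idx] <- f_prof
        x[idx] <- path[, 1L]; y[idx] <- path[, 2L]
      }
      data.frame(t = (seq_len(n) - 1L) / spec$rate, F = F, x = x, y = y)
    }
    rec <- insole_recording(mk_series(hs_l, aL), mk_series(hs_r, aR),
                            rate = spec$rate,
                            insole_length = c(L = 250, R = 250),
                            normalized = TRUE,
                            meta = c(meta, list(cohort = template$label)))
    markers <- list()
    for (i in 2:(n_left - 1L)) {                      # complete cycles
      lr <- .transfer_points(aL[[i]], aR[[i]], spec)
      rl_in <- .transfer_points(aR[[i - 1L]], aL[[i]], spec)
      rl_out <- .transfer_points(aR[[i]], aL[[i + 1L]], spec)
      c_lr <- intersect_transfers(lr, rl_in)
      c_rl <- intersect_transfers(rl_out, lr)
      mk <- list(
        E_L = aL[[i]]["E", , drop = FALSE], A_L = aL[[i]]["A", , drop = FALSE],
        D_L = aL[[i]]["D", , drop = FALSE], B_L = aL[[i]]["B", , drop = FALSE],
        E_R = aR[[i]]["E", , drop = FALSE], A_R = aR[[i]]["A", , drop = FALSE],
        D_R = aR[[i]]["D", , drop = FALSE], B_R = aR[[i]]["B", , drop = FALSE],
        C_LR = rbind(c_lr$point), C_RL = rbind(c_rl$point),
        c_method = c(C_LR = c_lr$method, C_RL = c_rl$method))
      class(mk) <- "marker_set"
      markers[[length(markers) + 1L]] <- mk
    }
    events <- rbind(
      data.frame(side = "L", hs = hs_l, to = hs_l + spec$n_stance - 1L),
      data.frame(side = "R", hs = hs_r, to = hs_r + spec$n_stance - 1L))
    list(recording = rec,
         ground_truth = list(events = events, markers = markers,
                             clusters = collect_clusters(markers),
                             planted = planted_parameters(template)))
  })
}

#' Generate a labeled two-cohort synthetic study
#'
#' Draws per-participant random anchor offsets once, assigns datasets to
#' participants round-robin, and generates each dataset independently —
#' either as marker clusters (`mode = "markers"`, fast) or as full insole
#' recordings (`mode = "recording"`). Output is bit-identical for a fixed
#' seed.
#'
#' @param spec a [study_spec()].
#' @param seed integer seed for the whole study.
#' @param mode `"markers"` or `"recording"`.
#' @param templates named list with entries `pos` and `neg`
#'   ([cohort_template()]s); defaults to the built-in diabetic and healthy
#'   templates.
#' @return a `synthetic_study`: list with `datasets` (each holding `id`,
#'   `cohort`, `participant`, and `clusters` or `recording` +
#'   `ground_truth`), plus `spec`, `templates`, `seed`.
#' @export
generate_study <- function(spec = study_spec(), seed = 1,
                           mode = c("markers", "recording"),
                           templates = list(
                             pos = cohort_template("diabetic"),
                             neg = cohort_template("healthy"))) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "study_spec"),
            all(c("pos", "neg") %in% names(templates)))
  .with_seed(seed, function() {
    datasets <- list()
    for (coh in c("pos", "neg")) {
      tpl <- templates[[coh]]
      n_ds <- if (coh == "pos") spec$n_pos else spec$n_neg
      n_pp <- if (coh == "pos") spec$participants_pos else spec$participants_neg
      offsets <- lapply(seq_len(n_pp), function(p) {
        zs <- c("E", "D", "B", "A")
        o <- lapply(zs, function(z) stats::rnorm(2L, 0, spec$participant_sd))
        names(o) <- zs
        o
      })
      pp_of <- rep(seq_len(n_pp), length.out = n_ds)
      sub_seeds <- sample.int(.Machine$integer.max - 1L, n_ds)
      for (d in seq_len(n_ds)) {
        tpl_p <- .refresh_c_point(.offset_template(tpl, offsets[[pp_of[d]]]),
                                  spec)
        id <- sprintf("%s_%03d", tpl$label, d)
        entry <- list(id = id, cohort = tpl$label,
                      participant = sprintf("%s_p%02d", tpl$label, pp_of[d]))
        if (mode == "markers") {
          entry$clusters <- sample_marker_clusters(tpl_p, spec$cycles,
                                                   seed = sub_seeds[d])
          entry$planted <- planted_parameters(tpl_p)
        } else {
          gen <- generate_recording(tpl_p, spec, seed = sub_seeds[d],
                                    meta = list(id = id,
                                                participant = entry$participant))
          entry$recording <- gen$recording
          entry$ground_truth <- gen$ground_truth
        }
        datasets[[length(datasets) + 1L]] <- entry
      }
    }
    structure(list(datasets = datasets, spec = spec, templates = templates,
                   seed = seed, mode = mode),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  coh <- table(vapply(x$datasets, `[[`, "", "cohort"))
  cat("<synthetic_study> ", length(x$datasets), " datasets (",
      paste(names(coh), coh, sep = ": ", collapse = ", "),
      "), mode '", x$mode, "', seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Extract the parameter table of a synthetic study
#'
#' Runs the marker pipeline (recording mode) or the direct cluster path
#' (markers mode) on every dataset and stacks the per-dataset 15-parameter
#' vectors. Failing datasets are skipped with a warning and counted in the
#' attribute `"n_failed"`.
#'
#' @param study a [generate_study()] result.
#' @param bi_scale BI scale constant (default 1 = raw).
#' @return a data frame: `id`, `participant`, `cohort` + the 15 parameters.
#' @export
study_parameters <- function(study, bi_scale = 1) {
  stopifnot(inherits(study, "synthetic_study"))
  rows <- list(); failed <- 0L
  for (ds in study$datasets) {
    row <- tryCatch({
      clusters <- if (!is.null(ds$clusters)) ds$clusters
      else extract_markers(ds$recording)$clusters
      extract_parameters(clusters, bi_scale = bi_scale,
                         meta = list(id = ds$id, participant = ds$participant,
                                     cohort = ds$cohort))
    }, error = function(e) {
      warning("dataset ", ds$id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(row)) failed <- failed + 1L
    else rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- failed
  out
}
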