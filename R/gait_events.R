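# Gait event detection: stance intervals from vertical force, stride assembly.

#' Detect stance intervals from a vertical force trace
#'
#' A stance interval is a maximal run of samples with force at or above a
#' relative threshold, lasting at least `min_stance_s`. The threshold is
#' bootstrapped: a provisional pass at `threshold_rel` times the trace maximum
#' finds candidate stances, and the final threshold is `threshold_rel` times
#' the median per-stance peak force. Detection is therefore invariant to
#' multiplying the trace by any positive constant.
#'
#' @param force numeric vector of vertical force (>= 0).
#' @param rate sampling frequency (Hz).
#' @param threshold_rel relative force threshold (default 0.05, i.e. 5% of
#'   the median stance peak — standard gait practice).
#' @param min_stance_s minimum stance duration in seconds (default 0.2).
#' @return a data frame with columns `hs` (heel-strike sample index) and `to`
#'   (toe-off sample index), 1-based, inclusive; zero rows when no stance is
#'   found.
#' @export
detect_stance_intervals <- function(force, rate, threshold_rel = 0.05,
                                    min_stance_s = 0.2) {
  stopifnot(rate > 0, threshold_rel > 0)
  empty <- data.frame(hs = integer(0), to = integer(0))
  if (!length(force) || max(force, na.rm = TRUE) <= 0) return(empty)
  force[is.na(force)] <- 0
  runs_above <- function(thr) {
    r <- rle(force >= thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(hs = starts[r$values], to = ends[r$values])
  }
  prov <- runs_above(threshold_rel * max(force))
  if (!nrow(prov)) return(empty)
  peaks <- mapply(function(a, b) max(force[a:b]), prov$hs, prov$to)
  iv <- runs_above(threshold_rel * stats::median(peaks))
  min_len <- max(1L, as.integer(round(min_stance_s * rate)))
  iv <- iv[(iv$to - iv$hs + 1L) >= min_len, , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Assemble gait cycles from per-foot stance intervals
#'
#' A complete gait cycle runs from one left heel strike to the next and
#' requires double support at every foot-to-foot transfer: the preceding
#' right stance must overlap the start of the left stance, a right heel
#' strike must fall inside the left stance, and the next left heel strike
#' inside that right stance. Candidate cycles without double-support overlap
#' (running-like input) are rejected; if no cycle survives, an empty list is
#' returned with a warning.
#'
#' @param left,right stance-interval data frames from
#'   [detect_stance_intervals()], sorted by time.
#' @return a list of `gait_cycle` objects, each holding the event sample
#'   indices `hs_left`, `to_right_in` (end of the incoming right-to-left
#'   transfer), `hs_right`, `to_left`, `hs_left_next`, `to_right`, and the
#'   derived windows `ds_rl_in`, `ss_left`, `ds_lr`, `ss_right`, `ds_rl_out`
#'   (each `c(first, last)` sample).
#' @export
assemble_gait_cycles <- function(left, right) {
  cycles <- list()
  if (!nrow(left) || !nrow(right)) {
    warning("no gait cycles: need stance intervals for both feet")
    return(cycles)
  }
  attempted <- 0L
  for (i in seq_len(nrow(left))) {
    hs_l <- left$hs[i]; to_l <- left$to[i]
    p <- which(right$hs < hs_l & right$to >= hs_l)   # overlaps cycle start
    r <- which(right$hs > hs_l & right$hs <= to_l)   # heel-strikes inside
    if (i == nrow(left)) next
    hs_l2 <- left$hs[i + 1L]
    attempted <- attempted + 1L
    if (!length(p) || !length(r)) next
    p <- p[length(p)]; r <- r[1L]
    if (!(hs_l2 > right$hs[r] && hs_l2 <= right$to[r])) next
    cyc <- list(
      hs_left = hs_l, to_right_in = right$to[p], hs_right = right$hs[r],
      to_left = to_l, hs_left_next = hs_l2, to_right = right$to[r]
    )
    # double-support windows are the stance overlaps; single support between
    cyc$ds_rl_in <- c(cyc$hs_left, cyc$to_right_in)
    cyc$ss_left <- c(cyc$to_right_in + 1L, cyc$hs_right - 1L)
    cyc$ds_lr <- c(cyc$hs_right, cyc$to_left)
    cyc$ss_right <- c(cyc$to_left + 1L, cyc$hs_left_next - 1L)
    cyc$ds_rl_out <- c(cyc$hs_left_next, cyc$to_right)
    if (cyc$ss_left[1L] > cyc$ss_left[2L] ||
        cyc$ss_right[1L] > cyc$ss_right[2L]) next  # no single support
    cycles[[length(cycles) + 1L]] <- structure(cyc, class = "gait_cycle")
  }
  if (!length(cycles) && attempted > 0L) {
    warning("no gait cycles with double support found (running-like input?)")
  }
  cycles
}

#' Validate gait cycles against per-recording medians
#'
#' Keeps cycles whose per-foot stance durations and peak forces all lie
#' within a relative band of the per-recording median, emulating the visual
#' screening of force-time curves for regularly distributed steps.
#'
#' @param cycles list of `gait_cycle` objects.
#' @param rec the [insole_recording()] the cycles were detected in.
#' @param band relative half-width of the acceptance band (default 0.3:
#'   keep values within 70%--130% of the median).
#' @return the accepted cycles, with a data frame of rejections (cycle index
#'   and reason) attached as attribute `"rejections"`.
#' @export
validate_steps <- function(cycles, rec, band = 0.3) {
  if (length(cycles) < 3L) {
    stop("step validation needs at least 3 gait cycles, got ", length(cycles))
  }
  feat <- t(vapply(cycles, function(cy) {
    ls <- cy$hs_left:cy$to_left
    rs <- cy$hs_right:cy$to_right
    c(dur_l = length(ls), dur_r = length(rs),
      peak_l = max(rec$left$F[ls]), peak_r = max(rec$right$F[rs]))
  }, numeric(4)))
  med <- apply(feat, 2L, stats::median)
  rel <- sweep(feat, 2L, med, `/`)
  ok <- apply(rel >= 1 - band & rel <= 1 + band, 1L, all)
  rej <- data.frame(cycle = which(!ok),
                    reason = apply(rel[!ok, , drop = FALSE], 1L, function(z) {
                      paste0(colnames(feat)[which.max(abs(z - 1))],
                             " off median by ",
                             round(100 * (z[which.max(abs(z - 1))] - 1)), "%")
                    }))
  if (!any(ok)) stop("step validation rejected every gait cycle")
  out <- cycles[ok]
  attr(out, "rejections") <- rej
  out
}
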