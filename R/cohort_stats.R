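# Classifier evaluation: Mann-Whitney U, rank effect size, ROC, thresholds.

#' Mann-Whitney U test
#'
#' U is computed by the midrank method (ties count one half) and returned
#' for the first sample's orientation: U = #\{x > y\} + 0.5 #\{x = y\}. The
#' two-sided p-value uses the normal approximation with tie and continuity
#' corrections; for small samples an exact permutation p-value over all
#' cohort assignments is available.
#'
#' @param x,y numeric samples (non-empty).
#' @param method `"normal"` (default) or `"exact"` (full enumeration of
#'   cohort assignments; feasible only for small samples).
#' @return a list with `U`, `p`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, method = c("normal", "exact")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(c(x, y))) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "exact") {
    if (choose(N, n1) > 2e5) stop("exact method infeasible for these sizes")
    dev_obs <- abs(U - n1 * n2 / 2)
    combs <- utils::combn(N, n1)
    us <- apply(combs, 2L, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(us - n1 * n2 / 2) >= dev_obs - 1e-12)
  } else {
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  list(U = U, p = p, n1 = n1, n2 = n2)
}

#' Separation constant, effect size and AUC from U
#'
#' With S = U / (n1 n2), where U is taken in the smaller orientation
#' (U <= n1 n2 / 2), the rank-based effect size is r = 1 - 2S and the area
#' under the ROC curve is AUC = 1 - S; hence AUC = (1 + r) / 2. S is the
#' probability that a randomly chosen member of the lower-rated cohort
#' outranks one of the higher-rated cohort.
#'
#' @param U Mann-Whitney U statistic, 0 <= U <= n1*n2 (either orientation;
#'   the smaller orientation is taken internally).
#' @param n1,n2 the two sample sizes.
#' @return a list with `S`, `r`, `auc`.
#' @export
separation <- function(U, n1, n2) {
  stopifnot(n1 > 0, n2 > 0)
  if (U < -1e-9 || U > n1 * n2 + 1e-9) {
    stop("U out of range [0, n1*n2]")
  }
  U <- min(U, n1 * n2 - U)
  S <- U / (n1 * n2)
  list(S = S, r = 1 - 2 * S, auc = 1 - S)
}

#' Label a rank-based effect size
#'
#' r > 0.37: large; 0.3 < r <= 0.37: medium; 0.1 < r <= 0.3: small;
#' r <= 0.1: very small. Only large effects qualify as classifiers.
#'
#' @param r effect size in \[0, 1\].
#' @return one of `"very small"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_label <- function(r) {
  if (!is.finite(r) || r < 0 || r > 1) stop("effect size r must be in [0, 1]")
  if (r > 0.37) "large"
  else if (r > 0.3) "medium"
  else if (r > 0.1) "small"
  else "very small"
}

# classify scores as positive at a threshold under an orientation
.classify_pos <- function(v, thr, orientation) {
  if (orientation == "high") v > thr else v < thr
}

#' ROC curve of a two-cohort score
#'
#' Sweeps candidate thresholds (midpoints of consecutive sorted unique
#' pooled values, plus sentinels at the extremes) and computes the true- and
#' false-positive rates of the rule that flags a dataset as positive
#' (impaired) when its score is above (orientation `"high"`) or below
#' (orientation `"low"`) the threshold. The orientation is chosen
#' automatically so that AUC >= 0.5. Both AUC estimates are returned: the
#' trapezoid of the swept curve and the Mann-Whitney value U / (n1 n2);
#' they agree to numerical precision on tie-free data.
#'
#' @param scores_pos scores of the positive (impaired) cohort.
#' @param scores_neg scores of the negative (healthy) cohort.
#' @return a `roc_result`: list with `orientation`, `thresholds`, `tpr`,
#'   `fpr`, `auc_trapezoid`, `auc_u`, `pooled_median`, and the input scores.
#' @export
roc_curve <- function(scores_pos, scores_neg) {
  scores_pos <- as.numeric(scores_pos); scores_neg <- as.numeric(scores_neg)
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("ROC needs at least 1 value per cohort")
  }
  pooled <- c(scores_pos, scores_neg)
  u <- sort(unique(pooled))
  if (length(u) < 2L) stop("degenerate ROC: all pooled values identical")
  mw <- mann_whitney(scores_pos, scores_neg)
  p_gt <- mw$U / (mw$n1 * mw$n2)           # P(pos > neg) + 0.5 P(=)
  orientation <- if (p_gt >= 0.5) "high" else "low"
  thr <- c(-Inf, (u[-length(u)] + u[-1L]) / 2, Inf)
  tpr <- vapply(thr, function(th) {
    mean(.classify_pos(scores_pos, th, orientation))
  }, 0)
  fpr <- vapply(thr, function(th) {
    mean(.classify_pos(scores_neg, th, orientation))
  }, 0)
  ord <- order(fpr, tpr)
  fo <- fpr[ord]; to <- tpr[ord]
  auc_trap <- sum(diff(fo) * (to[-1L] + to[-length(to)]) / 2)
  structure(list(orientation = orientation, thresholds = thr,
                 tpr = tpr, fpr = fpr,
                 auc_trapezoid = auc_trap, auc_u = max(p_gt, 1 - p_gt),
                 pooled_median = stats::median(pooled),
                 scores_pos = scores_pos, scores_neg = scores_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", round(x$auc_u, 4),
      "(trapezoid", paste0(round(x$auc_trapezoid, 4), ");"),
      "positive =", x$orientation, "scores;",
      length(x$thresholds), "thresholds\n")
  invisible(x)
}

#' Optimal classification threshold
#'
#' Selects the threshold maximizing the geometric mean of sensitivity and
#' specificity, G = sqrt(TPR * TNR). Ties are broken by the larger Youden
#' index J = TPR + TNR - 1, then by the threshold closest to the pooled
#' median. Sentinel (infinite) thresholds are never optimal on a
#' non-degenerate curve.
#'
#' @param roc a [roc_curve()] result.
#' @return a list with `threshold`, `G`, `tpr`, `tnr`, `youden`.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  fin <- is.finite(roc$thresholds)
  thr <- roc$thresholds[fin]
  tpr <- roc$tpr[fin]; tnr <- 1 - roc$fpr[fin]
  if (!length(thr)) stop("degenerate ROC: no finite thresholds")
  g <- sqrt(tpr * tnr)
  j <- tpr + tnr - 1
  best <- which(g >= max(g) - 1e-12)
  if (length(best) > 1L) best <- best[j[best] >= max(j[best]) - 1e-12]
  if (length(best) > 1L) {
    best <- best[which.min(abs(thr[best] - roc$pooled_median))]
  }
  best <- best[1L]
  list(threshold = thr[best], G = g[best], tpr = tpr[best], tnr = tnr[best],
       youden = j[best])
}

#' Confusion percentages at a threshold
#'
#' True positives and false negatives as percentages of the positive cohort
#' size, true negatives and false positives as percentages of the negative
#' cohort size. Values are exact (unrounded); reports round to 2 decimals.
#'
#' @param scores_pos,scores_neg cohort scores.
#' @param threshold classification threshold.
#' @param orientation `"high"` (positive when score > threshold) or `"low"`.
#' @return a list with `tp_pct`, `fn_pct`, `tn_pct`, `fp_pct`, `se`, `sp`.
#' @export
confusion_percent <- function(scores_pos, scores_neg, threshold,
                              orientation = c("high", "low")) {
  orientation <- match.arg(orientation)
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both cohorts must be non-empty")
  }
  tp <- 100 * mean(.classify_pos(scores_pos, threshold, orientation))
  tn <- 100 * mean(!.classify_pos(scores_neg, threshold, orientation))
  list(tp_pct = tp, fn_pct = 100 - tp, tn_pct = tn, fp_pct = 100 - tn,
       se = tp, sp = tn)
}

#' Compare two cohorts across all cyclogram parameters
#'
#' Builds the classifier-evaluation table: per parameter the cohort medians,
#' Mann-Whitney U and p, separation constant S, effect size r and its label,
#' and AUC; for parameters with a large effect (r > 0.37) also the optimal
#' threshold, the confusion percentages, sensitivity and specificity.
#' Parameters with non-finite values in either cohort are reported as
#' all-NA rows with a warning. The statistical unit is the dataset.
#'
#' @param params_pos,params_neg data frames of per-dataset parameter
#'   vectors (positive = impaired cohort, negative = healthy), with the
#'   columns of [parameter_names()]; at least 2 datasets per cohort.
#' @param parameters which columns to compare (default all 15).
#' @param calibrate_bi if `TRUE` (default), rescale the BI column of both
#'   cohorts with [calibrate_bi_scale()] before computing medians and
#'   thresholds, so the optimal BI threshold is exactly 100. Rank statistics
#'   (U, p, r, AUC) are scale-invariant and unaffected.
#' @param mw_method p-value method, see [mann_whitney()].
#' @return a `cohort_comparison` data frame with one row per parameter and
#'   the BI scale (if calibrated) in attribute `"bi_scale"`.
#' @export
compare_cohorts <- function(params_pos, params_neg,
                            parameters = parameter_names(),
                            calibrate_bi = TRUE,
                            mw_method = "normal") {
  if (nrow(params_pos) < 2L || nrow(params_neg) < 2L) {
    stop("need at least 2 datasets per cohort")
  }
  missing <- setdiff(parameters, intersect(names(params_pos),
                                           names(params_neg)))
  if (length(missing)) {
    stop("parameter column(s) missing: ", paste(missing, collapse = ", "))
  }
  bi_scale <- NULL
  if (calibrate_bi && "BI" %in% parameters) {
    bi_scale <- tryCatch(
      calibrate_bi_scale(params_pos$BI, params_neg$BI),
      error = function(e) {
        warning("BI calibration skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(bi_scale)) {
      params_pos$BI <- params_pos$BI * bi_scale
      params_neg$BI <- params_neg$BI * bi_scale
    }
  }
  na_row <- function(par) {
    data.frame(parameter = par, median_pos = NA_real_, median_neg = NA_real_,
               U = NA_real_, S = NA_real_, p = NA_real_, r = NA_real_,
               effect = NA_character_, auc = NA_real_,
               orientation = NA_character_, threshold = NA_real_,
               tp_pct = NA_real_, fn_pct = NA_real_, tn_pct = NA_real_,
               fp_pct = NA_real_, se = NA_real_, sp = NA_real_)
  }
  rows <- lapply(parameters, function(par) {
    xp <- params_pos[[par]]; xn <- params_neg[[par]]
    if (any(!is.finite(xp)) || any(!is.finite(xn))) {
      warning("non-finite values for parameter ", par, "; row reported as NA")
      return(na_row(par))
    }
    mw <- mann_whitney(xp, xn, method = mw_method)
    sep <- separation(mw$U, mw$n1, mw$n2)
    row <- na_row(par)
    row$median_pos <- stats::median(xp)
    row$median_neg <- stats::median(xn)
    row$U <- mw$U; row$S <- sep$S; row$p <- mw$p; row$r <- sep$r
    row$effect <- effect_label(sep$r); row$auc <- sep$auc
    if (sep$r > 0.37) {
      roc <- roc_curve(xp, xn)
      opt <- optimal_threshold(roc)
      conf <- confusion_percent(xp, xn, opt$threshold, roc$orientation)
      row$orientation <- roc$orientation
      row$threshold <- opt$threshold
      row$tp_pct <- conf$tp_pct; row$fn_pct <- conf$fn_pct
      row$tn_pct <- conf$tn_pct; row$fp_pct <- conf$fp_pct
      row$se <- conf$se; row$sp <- conf$sp
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_pos") <- nrow(params_pos)
  attr(out, "n_neg") <- nrow(params_neg)
  attr(out, "bi_scale") <- bi_scale
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' Round a cohort comparison for reporting
#'
#' Medians and thresholds to 3 decimals, percentages to 2, r/S/AUC to 3,
#' p to 4 — the layout used in printed comparison tables.
#'
#' @param comparison a [compare_cohorts()] table.
#' @return a plain data frame with rounded values.
#' @export
format_comparison <- function(comparison) {
  tab <- as.data.frame(comparison)
  r3 <- c("median_pos", "median_neg", "S", "r", "auc", "threshold")
  r2 <- c("tp_pct", "fn_pct", "tn_pct", "fp_pct", "se", "sp")
  tab[r3] <- lapply(tab[r3], round, digits = 3)
  tab[r2] <- lapply(tab[r2], round, digits = 2)
  tab$p <- signif(tab$p, 2)
  tab
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison> ", attr(x, "n_pos"), " positive vs ",
      attr(x, "n_neg"), " negative datasets", sep = "")
  if (!is.null(attr(x, "bi_scale"))) {
    cat("; BI scale", signif(attr(x, "bi_scale"), 5))
  }
  cat("\n")
  print(format_comparison(x))
  invisible(x)
}

#' Correlate a parameter with the Balance Index
#'
#' Ordinary least-squares fit between (optionally log10-transformed)
#' parameter values and BI values, quantifying how much of a geometry
#' parameter's variation the balance state explains.
#'
#' @param values parameter values (response).
#' @param bi_values Balance Index values (predictor).
#' @param transform_x,transform_y `"identity"` or `"log10"` per axis;
#'   log10 requires strictly positive values.
#' @return a `correlation_result`: list with `slope`, `intercept`,
#'   `r_squared`, `p`, `n`, `transform`.
#' @export
correlate_with_bi <- function(values, bi_values,
                              transform_x = c("log10", "identity"),
                              transform_y = c("identity", "log10")) {
  transform_x <- match.arg(transform_x)
  transform_y <- match.arg(transform_y)
  ok <- is.finite(values) & is.finite(bi_values)
  x <- bi_values[ok]; y <- values[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  tf <- function(v, t) {
    if (t == "log10") {
      if (any(v <= 0)) stop("log10 transform requires positive values")
      log10(v)
    } else v
  }
  x <- tf(x, transform_x); y <- tf(y, transform_y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined R^2: zero variance on one axis")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p = unname(sm$coefficients[2L, 4L]),
                 n = length(x),
                 transform = c(x = transform_x, y = transform_y)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> R^2 =", round(x$r_squared, 4),
      " p =", signif(x$p, 3), " n =", x$n,
      " (x:", x$transform[["x"]], ", y:", x$transform[["y"]], ")\n")
  invisible(x)
}
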