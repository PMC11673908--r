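# The 15 cyclogram parameters: marker geometry, distance ratios, Balance Index.

#' Per-cluster scatter statistics
#'
#' Sample means and standard deviations (n - 1 denominator) of a marker
#' cluster; the scattering area is the product sigma_x * sigma_y.
#'
#' @param points an n x 2 matrix (columns x, y), n >= 2.
#' @return a one-row data frame: `n`, `mean_x`, `mean_y`, `sigma_x`,
#'   `sigma_y`, `area`.
#' @export
cluster_stats <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) {
    stop("cluster statistics need at least 2 points, got ", nrow(points))
  }
  sx <- stats::sd(points[, 1L]); sy <- stats::sd(points[, 2L])
  data.frame(n = nrow(points),
             mean_x = mean(points[, 1L]), mean_y = mean(points[, 2L]),
             sigma_x = sx, sigma_y = sy, area = sx * sy)
}

.zones <- c("A", "B", "C", "D", "E")

# cluster labels belonging to each zone (left+right, or the two C directions)
.zone_labels <- list(A = c("A_L", "A_R"), B = c("B_L", "B_R"),
                     C = c("C_LR", "C_RL"), D = c("D_L", "D_R"),
                     E = c("E_L", "E_R"))

#' Balance Index from marker clusters
#'
#' For each of the five marker zones A--E the left and right scattering
#' areas (sigma_x * sigma_y per cluster; the two C directions for zone C)
#' are summed; the Balance Index is the sum of the five zone areas,
#' optionally rescaled. With zero scatter the BI is 0 and the percentage
#' contributions are undefined (`NA`, with a warning).
#'
#' @param clusters a [collect_clusters()] result (all ten clusters, each with
#'   at least 2 points).
#' @param scale positive scale constant applied to the raw BI; see
#'   [calibrate_bi_scale()] for the convention that places the optimal
#'   threshold at BI = 100.
#' @return a `balance_index` object: list with `zones` (named numeric,
#'   scaled), `bi_raw`, `bi`, `scale`, `percent` (named numeric summing to
#'   100).
#' @export
balance_index <- function(clusters, scale = 1) {
  stopifnot(scale > 0)
  missing <- setdiff(unlist(.zone_labels), names(clusters))
  if (length(missing)) {
    stop("missing marker cluster(s): ", paste(missing, collapse = ", "))
  }
  areas <- vapply(.zone_labels, function(labs) {
    sum(vapply(labs, function(l) cluster_stats(clusters[[l]])$area, 0))
  }, 0)
  bi_raw <- sum(areas)
  if (bi_raw > 0) {
    percent <- 100 * areas / bi_raw
  } else {
    warning("zero scatter: BI = 0, percentage contributions undefined")
    percent <- rep(NA_real_, length(areas))
    names(percent) <- names(areas)
  }
  structure(list(zones = scale * areas, bi_raw = bi_raw,
                 bi = scale * bi_raw, scale = scale, percent = percent),
            class = "balance_index")
}

#' @export
print.balance_index <- function(x, ...) {
  cat("<balance_index> BI =", signif(x$bi, 6),
      if (x$scale != 1) paste0("(raw ", signif(x$bi_raw, 6),
                               ", scale ", signif(x$scale, 6), ")"), "\n")
  tab <- rbind(area = signif(x$zones, 4), percent = round(x$percent, 1))
  print(tab)
  invisible(x)
}

#' Calibrate the Balance Index scale
#'
#' The raw BI depends on insole-length-normalized units; for reporting it is
#' multiplied by a constant chosen so that the ROC-optimal threshold between
#' the impaired and healthy cohorts sits exactly at BI = 100.
#'
#' @param bi_impaired,bi_healthy raw BI values of the two cohorts.
#' @return the scale constant, 100 / (raw optimal threshold).
#' @export
calibrate_bi_scale <- function(bi_impaired, bi_healthy) {
  roc <- roc_curve(bi_impaired, bi_healthy)
  thr <- optimal_threshold(roc)
  if (!is.finite(thr$threshold) || thr$threshold <= 0) {
    stop("BI calibration failed: non-positive optimal threshold")
  }
  100 / thr$threshold
}

# Euclidean distance between two points (length-2 or 1x2)
.dist2 <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))

#' Geometry parameters of the cyclogram (items 1--14)
#'
#' Positions and distances are computed between cluster mean positions and
#' averaged over sides. Same-side pairs: gait line AE, single-support line
#' BD, AB and DE. Transfer pairs follow the butterfly path B -> C -> D:
#' BC pairs B_L with C_LR and B_R with C_RL; CD pairs C_LR with D_R and C_RL
#' with D_L. The antero-posterior positions of A, B, D, E are side-averaged
#' cluster means; ap C and lat C average the two C clusters. Ra = BC/AB and
#' Rp = CD/DE.
#'
#' @param clusters a [collect_clusters()] result.
#' @return a named list of the 14 geometry parameters: `AE, BD, ap_C, lat_C,
#'   ap_A, ap_B, ap_D, ap_E, AB, BC, CD, DE, Ra, Rp` (all dimensionless,
#'   insole-length-normalized).
#' @export
geometry_parameters <- function(clusters) {
  mu <- lapply(clusters[.cluster_labels], function(p) colMeans(as.matrix(p)))
  side_mean <- function(lab) mean(c(mu[[paste0(lab, "_L")]][2L],
                                    mu[[paste0(lab, "_R")]][2L]))
  d_side <- function(a, b) {
    (.dist2(mu[[paste0(a, "_L")]], mu[[paste0(b, "_L")]]) +
       .dist2(mu[[paste0(a, "_R")]], mu[[paste0(b, "_R")]])) / 2
  }
  AB <- d_side("A", "B")
  DE <- d_side("D", "E")
  BC <- (.dist2(mu$B_L, mu$C_LR) + .dist2(mu$B_R, mu$C_RL)) / 2
  CD <- (.dist2(mu$C_LR, mu$D_R) + .dist2(mu$C_RL, mu$D_L)) / 2
  if (AB <= 0) stop("Ra undefined: distance AB is zero")
  if (DE <= 0) stop("Rp undefined: distance DE is zero")
  list(
    AE = d_side("A", "E"),
    BD = d_side("B", "D"),
    ap_C = mean(c(mu$C_LR[2L], mu$C_RL[2L])),
    lat_C = mean(c(mu$C_LR[1L], mu$C_RL[1L])),
    ap_A = side_mean("A"), ap_B = side_mean("B"),
    ap_D = side_mean("D"), ap_E = side_mean("E"),
    AB = AB, BC = BC, CD = CD, DE = DE,
    Ra = BC / AB, Rp = CD / DE
  )
}

#' Names of the 15 cyclogram parameters
#' @return character vector in report order.
#' @export
parameter_names <- function() {
  c("AE", "BD", "ap_C", "lat_C", "ap_A", "ap_B", "ap_D", "ap_E",
    "AB", "BC", "CD", "DE", "Ra", "Rp", "BI")
}

#' The full 15-parameter vector of one dataset
#'
#' Combines [geometry_parameters()] (items 1--14) with the Balance Index
#' (item 15) into a one-row data frame, optionally prefixed with metadata.
#'
#' @param clusters a [collect_clusters()] result.
#' @param bi_scale BI scale constant (default 1, i.e. raw units).
#' @param meta optional named list of metadata columns (id, cohort, ...).
#' @return a one-row data frame with the metadata and the 15 parameters.
#' @export
extract_parameters <- function(clusters, bi_scale = 1, meta = list()) {
  geo <- geometry_parameters(clusters)
  bi <- suppressWarnings(balance_index(clusters, scale = bi_scale))
  row <- c(geo, list(BI = bi$bi))
  out <- as.data.frame(c(meta, row), stringsAsFactors = FALSE)
  attr(out, "balance_index") <- bi
  out
}
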