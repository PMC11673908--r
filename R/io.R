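# Reading, writing and constructing insole recordings.

#' Construct an insole recording
#'
#' An insole recording holds synchronized per-foot time series of vertical
#' force and centre-of-pressure (COP) coordinates, sampled on a uniform grid.
#' COP coordinates are only defined while the foot carries load; swing-phase
#' samples hold `NA`.
#'
#' @param left,right data frames with columns `t` (s), `F` (vertical force,
#'   recording units, >= 0), `x` (lateral COP) and `y` (antero-posterior COP).
#'   Both feet must share the same time base.
#' @param rate sampling frequency in Hz.
#' @param insole_length named numeric vector `c(L = , R = )`, physical insole
#'   length in mm. May be `NA` when the recording is already normalized.
#' @param normalized logical; `TRUE` when COP coordinates are already
#'   insole-length-normalized (y in \[0, 1\] heel to toe, x with the lateral
#'   midline at 0 and the left foot mirrored).
#' @param meta list of free-form metadata (participant id, dataset id, cohort
#'   label, ...).
#'
#' @return an object of class `insole_recording`.
#' @export
insole_recording <- function(left, right, rate,
                             insole_length = c(L = NA_real_, R = NA_real_),
                             normalized = FALSE, meta = list()) {
  for (nm in c("t", "F", "x", "y")) {
    if (!nm %in% names(left) || !nm %in% names(right)) {
      stop("foot samples must have columns t, F, x, y (missing: ", nm, ")")
    }
  }
  if (nrow(left) != nrow(right)) {
    stop("left and right series must have the same length")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  if (nrow(left) >= 2L) {
    dt <- diff(left$t)
    if (any(dt <= 0) || max(abs(dt - 1 / rate)) > 1e-6 / rate + 1e-9) {
      stop("t must be strictly increasing with uniform spacing 1/rate")
    }
  }
  if (any(stats::na.omit(left$F) < 0) || any(stats::na.omit(right$F) < 0)) {
    stop("forces must be non-negative")
  }
  structure(
    list(left = as.data.frame(left), right = as.data.frame(right),
         rate = rate, insole_length = insole_length,
         normalized = isTRUE(normalized), meta = meta),
    class = "insole_recording"
  )
}

#' @export
print.insole_recording <- function(x, ...) {
  n <- nrow(x$left)
  cat("<insole_recording> ", n, " samples @ ", x$rate, " Hz (",
      round(n / x$rate, 2), " s), ",
      if (x$normalized) "normalized" else "raw", " coordinates\n", sep = "")
  loaded <- sum(x$left$F > 0 | x$right$F > 0)
  cat("  loaded samples: ", loaded, "; meta: ",
      if (length(x$meta)) paste(names(x$meta), unlist(x$meta), sep = "=",
                                collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

#' Construct a sensor layout
#'
#' Maps each pressure sensor of an insole to its position in the insole frame
#' and its active area, as needed to convert per-sensor pressures into total
#' force and COP.
#'
#' @param id unique sensor identifiers.
#' @param x,y sensor centre positions in the insole frame (mm).
#' @param area sensor active areas (mm^2), all positive.
#' @return an object of class `sensor_layout` (a data frame).
#' @export
sensor_layout <- function(id, x, y, area) {
  if (anyDuplicated(id)) stop("sensor ids must be unique")
  if (any(area <= 0)) stop("sensor areas must be positive")
  structure(data.frame(id = as.character(id), x = x, y = y, area = area),
            class = c("sensor_layout", "data.frame"))
}

#' Convert per-sensor pressures to force and COP
#'
#' Total vertical force is the area-weighted sum of sensor pressures,
#' F = sum(p_i a_i); the COP is the force-weighted centroid of the sensor
#' positions, COP = sum(p_i a_i pos_i) / F. When the total force is below
#' `tol` times the largest force seen in the frame set, the COP is undefined
#' and returned as `NA` (the foot is in swing).
#'
#' @param pressures a named numeric vector (one frame, names = sensor ids) or
#'   a numeric matrix with one row per frame and sensor ids as column names.
#' @param layout a [sensor_layout()].
#' @param tol relative force tolerance below which the COP is marked invalid.
#' @return a data frame with columns `F`, `x`, `y` (one row per frame).
#' @export
pressure_to_force_cop <- function(pressures, layout, tol = 1e-9) {
  if (is.null(dim(pressures))) {
    pressures <- matrix(pressures, nrow = 1L,
                        dimnames = list(NULL, names(pressures)))
  }
  ids <- colnames(pressures)
  if (is.null(ids)) stop("pressures must carry sensor ids as names")
  unknown <- setdiff(ids, layout$id)
  if (length(unknown)) {
    stop("unknown sensor id(s): ", paste(unknown, collapse = ", "))
  }
  if (any(pressures < 0)) stop("pressures must be non-negative")
  m <- match(ids, layout$id)
  a <- layout$area[m]
  w <- sweep(pressures, 2L, a, `*`)          # p_i * a_i per sensor
  F <- rowSums(w)
  x <- as.vector(w %*% layout$x[m])
  y <- as.vector(w %*% layout$y[m])
  valid <- F > tol * max(F, 0)
  out <- data.frame(F = F,
                    x = ifelse(valid, x / F, NA_real_),
                    y = ifelse(valid, y / F, NA_real_))
  out
}

#' Normalize an insole recording to insole lengths
#'
#' Divides both COP coordinates of each foot by that foot's insole length so
#' that the antero-posterior coordinate runs from 0 (heel end) to 1 (toe end),
#' and mirrors the left foot's lateral coordinate about its insole midline so
#' that both feet share one lateral frame (right-positive). Idempotent:
#' recordings already flagged as normalized are returned unchanged.
#'
#' @param rec an [insole_recording()].
#' @param mirror_left mirror the left foot's lateral coordinate (default TRUE).
#' @return the normalized recording (flag set).
#' @export
normalize_recording <- function(rec, mirror_left = TRUE) {
  stopifnot(inherits(rec, "insole_recording"))
  if (rec$normalized) return(rec)
  len <- rec$insole_length
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("insole lengths must be known and positive to normalize")
  }
  rec$left$x <- rec$left$x / len[["L"]] * if (mirror_left) -1 else 1
  rec$left$y <- rec$left$y / len[["L"]]
  rec$right$x <- rec$right$x / len[["R"]]
  rec$right$y <- rec$right$y / len[["R"]]
  rec$normalized <- TRUE
  rec
}

# canonical long-form column order for recording CSV files
.rec_cols <- c("t", "fL", "xL", "yL", "fR", "xR", "yR")

#' Read an insole recording from CSV
#'
#' The canonical dialect is a long-form CSV with named columns
#' `t, fL, xL, yL, fR, xR, yR`; other column names can be mapped through
#' `config$columns`. Swing-phase COP cells may be empty or `NA`.
#'
#' @param path CSV file path.
#' @param config list: `rate` (Hz; inferred from `t` when absent),
#'   `insole_length` (named `c(L=,R=)`, mm), `normalized` flag, `columns`
#'   (named character vector mapping canonical to file column names), `meta`.
#' @return an [insole_recording()].
#' @export
read_recording <- function(path, config = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nf != nf[1L])
  if (length(bad)) {
    stop("parse error in ", path, ": ragged row at line ", bad[1L])
  }
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- .rec_cols
  map <- config$columns
  if (!is.null(map)) cols[match(names(map), cols)] <- unname(map)
  missing <- cols[!cols %in% names(df)]
  if (length(missing)) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  num <- lapply(df[cols], function(v) suppressWarnings(as.numeric(v)))
  bad_t <- which(is.na(num[[1L]]))
  if (length(bad_t)) {
    stop("parse error in ", path, ": non-numeric time at data line ", bad_t[1L])
  }
  rate <- config$rate
  if (is.null(rate)) rate <- 1 / stats::median(diff(num[[1L]]))
  len <- config$insole_length
  if (is.null(len)) len <- c(L = NA_real_, R = NA_real_)
  insole_recording(
    left = data.frame(t = num[[1]], F = num[[2]], x = num[[3]], y = num[[4]]),
    right = data.frame(t = num[[1]], F = num[[5]], x = num[[6]], y = num[[7]]),
    rate = rate, insole_length = len,
    normalized = isTRUE(config$normalized) || is.null(config$normalized),
    meta = if (is.null(config$meta)) list() else config$meta
  )
}

#' Write an insole recording to CSV
#'
#' @param rec an [insole_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "insole_recording"))
  df <- data.frame(t = rec$left$t,
                   fL = rec$left$F, xL = rec$left$x, yL = rec$left$y,
                   fR = rec$right$F, xR = rec$right$x, yR = rec$right$y)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a parameter table
#'
#' One row per dataset: metadata columns plus the 15 named cyclogram
#' parameters. Round-trips through CSV at full double precision.
#'
#' @param table a data frame of per-dataset parameters.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_parameters <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, NA)
  # %.17g round-trips doubles exactly through text
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, check.names = FALSE)
}

#' Write a cohort comparison report as JSON
#'
#' Serializes a [compare_cohorts()] table (plus any attached metadata) to
#' JSON, rounding medians to 3 decimals and percentages to 2, mirroring the
#' usual presentation of such tables.
#'
#' @param comparison a `cohort_comparison` table.
#' @param path output JSON path.
#' @param extra optional named list merged into the report (seed, config
#'   hash, ...).
#' @return `path`, invisibly.
#' @export
write_report <- function(comparison, path, extra = list()) {
  tab <- format_comparison(comparison)
  report <- c(list(comparison = tab,
                   bi_scale = attr(comparison, "bi_scale")), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}
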