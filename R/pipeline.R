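# Orchestration: simulate -> extract -> compare, with config and manifests.

# stable hash of a config list, for provenance stamping of outputs
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[order(names(config))], f)
  unname(tools::md5sum(f))
}

.pkg_version <- function() {
  as.character(utils::packageVersion("cyclogait"))
}

# merge user config over defaults
.merge_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  out <- defaults
  out[names(config)] <- config
  out
}

#' Simulate a synthetic study to disk
#'
#' Generates a two-cohort study and writes one recording CSV plus one
#' ground-truth JSON per dataset, and a `manifest.csv` listing them.
#'
#' @param config list (or YAML path) with any of: `out_dir` (required),
#'   `seed` (default 1), `steps`, `n_pos`, `n_neg`, plus any other
#'   [study_spec()] argument.
#' @return the manifest data frame, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- .merge_config(config, list(seed = 1))
  if (is.null(cfg$out_dir)) stop("config error: out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec_args <- intersect(names(cfg), names(formals(study_spec)))
  spec <- do.call(study_spec, cfg[spec_args])
  study <- generate_study(spec, seed = cfg$seed, mode = "recording")
  manifest <- do.call(rbind, lapply(study$datasets, function(ds) {
    file <- paste0(ds$id, ".csv")
    write_recording(ds$recording, file.path(cfg$out_dir, file))
    gt <- file.path(cfg$out_dir, paste0(ds$id, "_truth.json"))
    jsonlite::write_json(
      list(planted = ds$ground_truth$planted,
           events = ds$ground_truth$events),
      gt, auto_unbox = TRUE, digits = NA)
    data.frame(id = ds$id, cohort = ds$cohort, participant = ds$participant,
               file = file)
  }))
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, version = .pkg_version(),
         config_hash = .config_hash(cfg)),
    file.path(cfg$out_dir, "simulate_meta.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Extract cyclogram parameters for every dataset of a study
#'
#' Reads the recordings listed in `manifest.csv`, runs the marker pipeline
#' and writes `parameters.csv` (one row per dataset, 15 named parameter
#' columns plus metadata). Per-dataset failures are logged and skipped; the
#' run completes with a nonzero failure count in the sidecar metadata.
#'
#' @param config list (or YAML path) with `in_dir` (required), `out_dir`
#'   (default `in_dir`), detection settings `threshold_rel`, `min_stance_s`,
#'   `validation_band`, and `bi_scale` (default 1).
#' @return the parameter table, invisibly (attribute `"n_failed"` set).
#' @export
run_extract <- function(config) {
  cfg <- .merge_config(config, list(threshold_rel = 0.05, min_stance_s = 0.2,
                                    validation_band = 0.3, bi_scale = 1))
  if (is.null(cfg$in_dir)) stop("config error: in_dir is required")
  if (is.null(cfg$out_dir)) cfg$out_dir <- cfg$in_dir
  man_path <- file.path(cfg$in_dir, "manifest.csv")
  if (!file.exists(man_path)) stop("config error: no manifest at ", man_path)
  manifest <- utils::read.csv(man_path)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    row <- tryCatch({
      rec <- read_recording(file.path(cfg$in_dir, manifest$file[i]),
                            config = list(normalized = TRUE))
      mk <- extract_markers(rec, threshold_rel = cfg$threshold_rel,
                            min_stance_s = cfg$min_stance_s,
                            band = cfg$validation_band)
      extract_parameters(mk$clusters, bi_scale = cfg$bi_scale,
                         meta = list(id = manifest$id[i],
                                     participant = manifest$participant[i],
                                     cohort = manifest$cohort[i]))
    }, error = function(e) conditionMessage(e))
    if (is.character(row)) {
      failures <- c(failures, paste0(manifest$id[i], ": ", row))
      message("dataset ", manifest$id[i], " failed: ", row)
    } else {
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop("every dataset failed extraction")
  table <- do.call(rbind, rows)
  write_parameters(table, file.path(cfg$out_dir, "parameters.csv"))
  jsonlite::write_json(
    list(version = .pkg_version(), config_hash = .config_hash(cfg),
         n_datasets = nrow(table), n_failed = length(failures),
         failures = failures),
    file.path(cfg$out_dir, "extract_meta.json"), auto_unbox = TRUE)
  attr(table, "n_failed") <- length(failures)
  invisible(table)
}

#' Compare the two cohorts of an extracted parameter table
#'
#' Splits `parameters.csv` by cohort label, runs [compare_cohorts()] with BI
#' calibration, and writes the comparison as JSON (`report.json`) and CSV
#' (`report.csv`).
#'
#' @param config list (or YAML path) with `in_dir` (directory holding
#'   `parameters.csv`; required), `out_dir` (default `in_dir`), `positive`
#'   (cohort label of the impaired group; default the rarer label), and
#'   `calibrate_bi` (default TRUE).
#' @return the `cohort_comparison`, invisibly.
#' @export
run_compare <- function(config) {
  cfg <- .merge_config(config, list(calibrate_bi = TRUE))
  if (is.null(cfg$in_dir)) stop("config error: in_dir is required")
  if (is.null(cfg$out_dir)) cfg$out_dir <- cfg$in_dir
  table <- read_parameters(file.path(cfg$in_dir, "parameters.csv"))
  labs <- unique(table$cohort)
  if (length(labs) != 2L) {
    stop("config error: expected exactly 2 cohort labels, found ",
         length(labs))
  }
  pos <- cfg$positive
  if (is.null(pos)) pos <- labs[which.min(tabulate(match(table$cohort, labs)))]
  if (!pos %in% labs) stop("config error: unknown positive cohort ", pos)
  cmp <- compare_cohorts(table[table$cohort == pos, ],
                         table[table$cohort != pos, ],
                         calibrate_bi = isTRUE(cfg$calibrate_bi))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report(cmp, file.path(cfg$out_dir, "report.json"),
               extra = list(positive = pos, version = .pkg_version(),
                            config_hash = .config_hash(cfg)))
  utils::write.csv(format_comparison(cmp),
                   file.path(cfg$out_dir, "report.csv"), row.names = FALSE)
  invisible(cmp)
}
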