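#' @keywords internal
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' @keywords internal
read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(sprintf("%s: file is empty: %s", what, path))
  names(df) <- tolower(names(df))
  check_columns(df, required, what)
  df
}

#' Read a long-format extracellular-flux plate export
#'
#' Expected columns: `well`, `group`, `donor`, `measurement_index`,
#' `time_min`, `ocr`, `ecar` (case-insensitive).
#'
#' @param path CSV file.
#' @return validated data.frame ordered by well and measurement index.
#' @export
read_flux_plate <- function(path) {
  df <- read_checked_csv(path, c("well", "group", "donor",
                                 "measurement_index", "time_min", "ocr",
                                 "ecar"), "flux plate CSV")
  df[order(df$well, df$measurement_index), , drop = FALSE]
}

#' Read the per-well cell-count sidecar
#'
#' Expected columns: `well`, `cells`.
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_cell_counts <- function(path) {
  read_checked_csv(path, c("well", "cells"), "cell-count CSV")
}

#' Assemble well traces from plate and cell-count tables
#'
#' @param plate data.frame from [read_flux_plate()].
#' @param counts data.frame from [read_cell_counts()].
#' @return list of [well_trace()] objects.
#' @export
assemble_traces <- function(plate, counts) {
  lapply(split(plate, plate$well), function(w) {
    cells <- counts$cells[counts$well == w$well[1]]
    if (length(cells) != 1) {
      stop(sprintf("well %s has no (or duplicate) cell count", w$well[1]))
    }
    well_trace(well = w$well[1], time_min = w$time_min, ocr = w$ocr,
               ecar = w$ecar, cell_count = cells, group = w$group[1],
               donor = w$donor[1])
  })
}

#' Read a passage log
#'
#' Expected columns: `donor`, `group`, `day`, `plated`, `live`, `dead`;
#' optional `volume` (mean cell volume, um^3).
#'
#' @param path CSV file.
#' @return data.frame with the column names used by [build_trajectory()].
#' @export
read_passage_log <- function(path) {
  df <- read_checked_csv(path, c("donor", "group", "day", "plated", "live",
                                 "dead"), "passage log CSV")
  names(df)[match(c("plated", "live", "dead"), names(df))] <-
    c("cells_plated", "live_harvested", "dead_harvested")
  if ("volume" %in% names(df)) {
    names(df)[names(df) == "volume"] <- "mean_cell_volume"
  }
  df[order(df$donor, df$day), , drop = FALSE]
}

#' Read a tidy longitudinal marker table
#'
#' Expected columns: `donor`, `group`, `day`, `marker`, `value`.
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_marker_table <- function(path) {
  read_checked_csv(path, c("donor", "group", "day", "marker", "value"),
                   "marker CSV")
}

#' Read a qPCR well table
#'
#' Expected columns: `sample`, `target`, `well`, `ct`; optional
#' `standard_quantity` for standard-curve wells.
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_qpcr_table <- function(path) {
  read_checked_csv(path, c("sample", "target", "well", "ct"), "qPCR CSV")
}

#' Read a telomere run table
#'
#' Expected columns: `sample`, `run_index`, `t`, `s` (telomere and
#' single-copy abundances). A `ts_ratio` column is added.
#'
#' @param path CSV file.
#' @return validated data.frame with `ts_ratio = t / s`.
#' @export
read_telomere_runs <- function(path) {
  df <- read_checked_csv(path, c("sample", "run_index", "t", "s"),
                         "telomere run CSV")
  if (any(df$t <= 0) || any(df$s <= 0)) stop("T and S must be positive")
  df$ts_ratio <- df$t / df$s
  df
}

#' Read an mtDNA breakpoint table
#'
#' Expected columns: `sample`, `timepoint_day`, `bp5`, `bp3`,
#' `heteroplasmy_percent`, `type`. Heteroplasmy is accepted as percent or
#' fraction and auto-detected by range: any value above 1 means percent
#' (the detection is logged via `message()`). Output heteroplasmy is a
#' fraction in `[0, 1]` and `type` is normalized to `kind`.
#'
#' @param path CSV file.
#' @return validated data.frame with `heteroplasmy` (fraction) and `kind`.
#' @export
read_breakpoints <- function(path) {
  df <- read_checked_csv(path, c("sample", "timepoint_day", "bp5", "bp3",
                                 "heteroplasmy_percent", "type"),
                         "breakpoint CSV")
  h <- df$heteroplasmy_percent
  if (any(h > 1)) {
    message("heteroplasmy detected as percent (values > 1); dividing by 100")
    h <- h / 100
  } else {
    message("heteroplasmy detected as fraction (all values <= 1)")
  }
  if (any(h < 0 | h > 1)) stop("heteroplasmy outside [0, 100%]")
  df$heteroplasmy <- h
  df$kind <- tolower(df$type)
  df
}

#' Read a cohort outcome table
#'
#' Expected columns: `cohort`, `outcome`, `unit`, `mean_pat`, `sd_pat`,
#' `n_pat`, `mean_ctl`, `sd_ctl`, `n_ctl` (SDs may be empty/NA for
#' aggregate-only cohorts).
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_cohort_table <- function(path) {
  read_checked_csv(path, c("cohort", "outcome", "unit", "mean_pat",
                           "sd_pat", "n_pat", "mean_ctl", "sd_ctl",
                           "n_ctl"), "cohort CSV")
}

#' Write a results table as TSV
#'
#' Numeric columns are written at full precision so a write-read round trip
#' is lossless.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' @param x named list of results/metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a simulated plate (data plus ground truth) to a directory
#'
#' Emits `plate.csv` and `cells.csv` in the dialect the readers consume,
#' with the generator's ground truth next to them in `truth.json`.
#'
#' @param sim a [simulate_plate()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulated_plate <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plate <- do.call(rbind, lapply(sim$traces, function(tr) {
    data.frame(well = tr$well, group = tr$group, donor = tr$donor,
               measurement_index = seq_along(tr$time_min),
               time_min = tr$time_min, ocr = tr$ocr, ecar = tr$ecar,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(plate, file.path(dir, "plate.csv"), row.names = FALSE)
  cells <- data.frame(
    well = vapply(sim$traces, function(t) t$well, character(1)),
    cells = vapply(sim$traces, function(t) t$cell_count, numeric(1))
  )
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write_run_summary(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

# default analysis windows (days): whole-lifespan, early-life, and the
# window used for epigenetic-aging slopes
.default_windows <- list(lifespan = c(20, 150), early_life = c(20, 50),
                         aging_rate = c(25, 75))

#' Read and validate a run configuration
#'
#' YAML file with optional keys `constants_preset`, `windows` (named
#' `[lo, hi]` pairs), `hayflick_rule`, `cutoffs` (`heteroplasmy`, `ct_max`,
#' `cv_inspect`, `cv_reject`, `dixon_alpha`, `duplicate_tolerance`) and
#' `seed`. Missing keys take package defaults; unknown keys are an error so
#' typos do not silently change an analysis.
#'
#' @param path YAML file, or `NULL` for the all-defaults configuration.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("constants_preset", "windows", "hayflick_rule", "cutoffs",
             "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(
    constants_preset = "glucose_mookerjee",
    windows = .default_windows,
    hayflick_rule = "rate",
    cutoffs = list(heteroplasmy = 0.05, ct_max = 33, cv_inspect = 0.02,
                   cv_reject = 0.1, dixon_alpha = 0.05,
                   duplicate_tolerance = 0.07),
    seed = 1
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$hayflick_rule %in% c("rate", "window")) {
    stop("hayflick_rule must be 'rate' or 'window'")
  }
  for (w in cfg$windows) {
    if (length(w) != 2 || w[1] > w[2]) stop("windows must be [lo, hi] pairs")
  }
  structure(cfg, class = "run_config")
}
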