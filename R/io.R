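obs_schema <- c(subject = "c", train_duration_s = "d",
                pulse_frequency_pps = "d", price_s = "d",
                sweep_type = "c", survey = "i", time_allocation = "d")

#' Read and validate an observation table
#'
#' Long-format CSV, one row per time-allocation measurement:
#' `subject`, `train_duration_s`, `pulse_frequency_pps`, `price_s`,
#' `sweep_type`, `survey`, `time_allocation`. Schema mismatches are
#' reported by column name; out-of-range values (allocation outside
#' `[0, 1]`, non-positive prices/frequencies/durations, durations outside
#' the declared condition set) are reported with data line numbers.
#'
#' @param path CSV file path.
#' @param durations Optional declared train-duration set; when given, any
#'   other duration is a validation error.
#' @return A validated observation tibble.
#' @export
read_observations <- function(path, durations = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obs <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(names(obs_schema), names(obs))
  if (length(missing_cols))
    stop("observation file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(obs)) + 1L  # header is line 1
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond))
      stop("invalid observations (", what, ") at line(s): ",
           paste(utils::head(line[which(cond | is.na(cond))], 10), collapse = ", "),
           call. = FALSE)
  }
  bad(obs$time_allocation < 0 | obs$time_allocation > 1,
      "time_allocation outside [0, 1]")
  bad(obs$pulse_frequency_pps <= 0, "non-positive pulse frequency")
  bad(obs$price_s <= 0, "non-positive price")
  bad(obs$train_duration_s <= 0, "non-positive train duration")
  if (!is.null(durations))
    bad(!vapply(obs$train_duration_s,
                function(d) any(abs(d - durations) < 1e-9), logical(1)),
        "train duration outside the declared condition set")
  obs
}

#' Write an observation table
#'
#' @param observations Observation tibble (see [read_observations()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_observations <- function(observations, path) {
  missing_cols <- setdiff(names(obs_schema), names(observations))
  if (length(missing_cols))
    stop("observation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  readr::write_csv(observations[, names(obs_schema)], path)
  invisible(path)
}

#' Assemble the shift report
#'
#' One row per subject and location parameter with the median bootstrap
#' shift (long minus short train duration), its percentile confidence
#' interval, and the star convention: starred when the 95% interval
#' excludes zero. The per-duration ceilings are included so altitude
#' changes are visible alongside location shifts.
#'
#' @param shifts Named list of shift tables (one per subject, from
#'   [shift_inference()]); names are subject labels.
#' @param fits Optional named list of `mountain_fit`s (same names) used to
#'   report the per-duration `ta_max` estimates.
#' @return A report tibble. Empty input yields an empty report with a
#'   warning.
#' @export
assemble_shift_report <- function(shifts, fits = NULL) {
  if (length(shifts) == 0L) {
    warning("no shift estimates supplied; empty report")
    return(tibble::tibble(subject = character(), parameter = character(),
                          median_diff = numeric(), lower = numeric(),
                          upper = numeric(), significant = logical(),
                          star = character()))
  }
  if (is.null(names(shifts)) || any(names(shifts) == ""))
    names(shifts) <- paste0("subject", seq_along(shifts))
  rows <- lapply(names(shifts), function(sub) {
    s <- shifts[[sub]]
    out <- tibble::tibble(subject = sub, parameter = s$parameter,
                          median_diff = s$median_diff, lower = s$lower,
                          upper = s$upper, significant = s$significant,
                          star = ifelse(s$significant, "*", ""))
    f <- fits[[sub]]
    if (!is.null(f)) {
      for (d in f$durations) {
        nm <- par_name("ta_max", d)
        if (nm %in% names(f$estimates))
          out[[nm]] <- f$estimates[[nm]]
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Run manifest for reproducibility
#'
#' A content hash of the configuration plus the seeds, resample count and
#' package version: enough to re-run a pipeline stage and obtain
#' bit-identical outputs.
#'
#' @param config Any R object describing the run configuration.
#' @param seed Root seed in force.
#' @param B Bootstrap resample count (if applicable).
#' @return A named list (`config_hash`, `seed`, `B`, `package_version`,
#'   `r_version`).
#' @export
run_manifest <- function(config, seed = NA_integer_, B = NA_integer_) {
  list(config_hash = rlang::hash(config),
       seed = seed, B = B,
       package_version = as.character(utils::packageVersion("rewardmountain")),
       r_version = as.character(getRversion()))
}
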