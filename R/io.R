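#' Write an FMSF trace to CSV
#'
#' Two columns \code{time_s,fluorescence_au}, comma separator, decimal
#' point, UTF-8, header mandatory; one file per subject per measurement.
#'
#' @param trace An \code{\link{fmsf_trace}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fmsf_trace"))
  df <- data.frame(time_s = trace$time, fluorescence_au = trace$fluorescence)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an FMSF trace from CSV
#'
#' Validates the schema (\code{time_s,fluorescence_au} header), strict
#' time monotonicity and uniform sampling; the sampling rate is inferred
#' from the time column.
#'
#' @param path File path.
#' @param tol Relative tolerance on time-step uniformity.
#' @return An \code{\link{fmsf_trace}}.
#' @export
read_trace <- function(path, tol = 1e-4) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!identical(names(df)[1:2], c("time_s", "fluorescence_au")))
    stop("schema error in ", path,
         ": expected header 'time_s,fluorescence_au' (line 1)")
  steps <- diff(df$time_s)
  bad <- which(steps <= 0)
  if (length(bad))
    stop(sprintf("non-monotone time at line %d of %s", bad[1] + 2L, path))
  step <- stats::median(steps)
  off <- which(abs(steps - step) > tol * step)
  if (length(off))
    stop(sprintf("irregular sampling at line %d of %s (step %.6g vs %.6g s)",
                 off[1] + 2L, path, steps[off[1]], step))
  fmsf_trace(df$fluorescence_au, sampling_rate = 1 / step,
             time = df$time_s, tol = tol * 10)
}

cohort_columns <- c("subject_id", "group", "sex", "age", "bmi", "sbp",
                    "dbp", "smoking", "depression", "hashimoto",
                    "hypertension", "hypercholesterolemia", "diabetes")
cohort_flag_columns <- cohort_columns[8:13]
valid_groups <- c("AA", "AU", "control")

#' Read a cohort metadata table
#'
#' CSV with columns \code{subject_id, group, sex, age, bmi, sbp, dbp} and
#' the 0/1 comorbidity flags \code{smoking, depression, hashimoto,
#' hypertension, hypercholesterolemia, diabetes}. Group labels must be
#' one of AA, AU, control; duplicate subject ids are an error; unknown
#' columns are ignored with a warning.
#'
#' @param path File path.
#' @return Data frame of subject records.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        colClasses = c(subject_id = "character",
                                       group = "character",
                                       sex = "character"))
  need <- setdiff(c("subject_id", "group"), names(df))
  if (length(need))
    stop("cohort table missing column(s): ", paste(need, collapse = ", "))
  extra <- setdiff(names(df), cohort_columns)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  if (nrow(df) == 0L) {
    warning("cohort table is empty")
    return(df)
  }
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$group), valid_groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(valid_groups, collapse = "/"), ")")
  for (fl in intersect(cohort_flag_columns, names(df))) {
    if (!all(df[[fl]] %in% c(0L, 1L)))
      stop("flag column ", fl, " must be 0/1")
    df[[fl]] <- as.integer(df[[fl]])
  }
  df
}

#' Write a cohort metadata table
#'
#' @param cohort Data frame of subject records.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a per-subject parameter table
#'
#' One row per subject with the FMSF parameter fields; missing values are
#' serialized as empty strings.
#'
#' @param parameters Data frame from \code{\link{analyze_cohort}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameter_table <- function(parameters, path) {
  utils::write.csv(parameters, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a run manifest
#'
#' Records tool version, configuration snapshot, content digests of input
#' files, the master seed, a timestamp and per-stage record counts, so a
#' run can be audited and reproduced.
#'
#' @param config List of configuration values used.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param seed Master seed of the run.
#' @param counts Named list/vector of per-stage record counts.
#' @return List of class \code{"fmsf_manifest"}.
#' @export
build_manifest <- function(config = list(), inputs = character(),
                           seed = NA_integer_, counts = list()) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  structure(list(
    tool = "fmsf",
    version = as.character(utils::packageVersion("fmsf")),
    configuration = config,
    input_digests = digests,
    master_seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    record_counts = as.list(counts)),
    class = "fmsf_manifest")
}

#' Write the analysis report
#'
#' Emits a summary CSV shaped like a clinical comparison table (rows =
#' parameters, one "mean +/- SD (n)" column per group including the
#' pooled patient column), a comparisons JSON, the run manifest JSON, and
#' a plain-text narrative naming the parameters that differ at p < 0.05
#' (unadjusted; a footnote states that no multiple-testing correction is
#' applied). Re-running with identical inputs reproduces the summary CSV
#' byte for byte.
#'
#' @param summaries Long-format summary from \code{\link{summarize_groups}}.
#' @param comparisons Named list of \code{\link{compare_groups}} results
#'   (may be empty).
#' @param manifest A \code{\link{build_manifest}} result, or \code{NULL}.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(summaries, comparisons = list(), manifest = NULL,
                         out_dir = ".") {
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("empty summaries; nothing to report")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  params <- unique(summaries$parameter)
  groups <- unique(summaries$group)
  wide <- data.frame(parameter = params)
  for (g in groups) {
    col <- vapply(params, function(p) {
      r <- summaries[summaries$parameter == p & summaries$group == g, ]
      if (nrow(r) == 0L) return("")
      sprintf("%.1f ± %s (n=%d)", r$mean,
              if (is.na(r$sd)) "NA" else sprintf("%.1f", r$sd), r$n)
    }, character(1))
    wide[[g]] <- col
  }
  files <- character()
  summary_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(wide, summary_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  files <- c(files, summary_path)

  comp_path <- file.path(out_dir, "comparisons.json")
  jsonlite::write_json(lapply(comparisons, unclass), comp_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, comp_path)

  if (!is.null(manifest)) {
    man_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(unclass(manifest), man_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, man_path)
  }

  narr_path <- file.path(out_dir, "report.txt")
  lines <- c("FMSF cohort report", "")
  if (length(comparisons) == 0L) {
    lines <- c(lines, "no comparisons performed")
  } else {
    sig <- names(comparisons)[vapply(comparisons, function(x)
      isTRUE(x$significant), logical(1))]
    lines <- c(lines,
               if (length(sig))
                 paste0("parameters differing at p < 0.05: ",
                        paste(sig, collapse = ", "))
               else "no parameter differs at p < 0.05",
               "",
               "note: p-values are unadjusted; no multiple-testing",
               "correction is applied.")
  }
  writeLines(lines, narr_path, useBytes = TRUE)
  files <- c(files, narr_path)
  invisible(files)
}
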