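#' Analyze every trace of a cohort into a parameter table
#'
#' Runs \code{\link{fmsf}} on each trace and joins the derived parameters
#' onto the subject metadata.
#'
#' @param traces Named list of \code{\link{fmsf_trace}} objects, names =
#'   subject ids.
#' @param metadata Data frame with at least \code{subject_id} and
#'   \code{group} columns (see \code{\link{read_cohort_table}}).
#' @param protocol,bands Analysis settings, see \code{\link{fmsf}}.
#' @return Data frame: metadata columns followed by the FMSF parameter
#'   columns, one row per subject.
#' @export
analyze_cohort <- function(traces, metadata, protocol = fmsf_protocol(),
                           bands = fmsf_bands()) {
  if (is.null(names(traces)) || anyNA(names(traces)))
    stop("traces must be a named list keyed by subject_id")
  missing_tr <- setdiff(metadata$subject_id, names(traces))
  if (length(missing_tr))
    stop("no trace for subject(s): ", paste(missing_tr, collapse = ", "))
  pars <- do.call(rbind, lapply(metadata$subject_id, function(id)
    coef(fmsf(traces[[id]], protocol, bands))))
  rownames(pars) <- NULL
  cbind(metadata, as.data.frame(pars))
}

#' Apply the cohort exclusion rules
#'
#' Removes subjects with evident mitochondrial dysfunction — a negative
#' ischemic response (IRmax < 0) — or an unmeasurable IRmax, then any
#' optional sex restriction and comorbidity-flag exclusions, in that
#' order. Every removal is logged with its reason; subjects are never
#' silently dropped.
#'
#' @param cohort Data frame with one row per subject, containing at least
#'   \code{subject_id}, \code{group} and \code{IRmax}.
#' @param exclude_negative_ir Apply the IRmax < 0 rule (default TRUE).
#' @param sex Optional single value; subjects with a different \code{sex}
#'   are excluded.
#' @param exclude_flags Character vector of 0/1 flag columns; subjects
#'   with the flag set are excluded, in the order given.
#' @return List with \code{retained} (data frame), \code{excluded} (data
#'   frame with an added \code{reason} column) and \code{counts} (table of
#'   retained subjects per group).
#' @examples
#' coh <- data.frame(subject_id = paste0("s", 1:4),
#'                   group = c("AA", "AA", "AU", "control"),
#'                   IRmax = c(10, -2, 8, 12))
#' apply_exclusions(coh)$counts
#' @export
apply_exclusions <- function(cohort, exclude_negative_ir = TRUE,
                             sex = NULL, exclude_flags = character()) {
  stopifnot(is.data.frame(cohort), "IRmax" %in% names(cohort))
  reason <- rep(NA_character_, nrow(cohort))
  mark <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  if (exclude_negative_ir) {
    mark(is.na(cohort$IRmax), "unmeasurable ischemic response")
    mark(!is.na(cohort$IRmax) & cohort$IRmax < 0,
         "negative ischemic response (IRmax < 0)")
  }
  if (!is.null(sex))
    mark(cohort$sex != sex, paste0("sex restriction (", sex, " only)"))
  for (fl in exclude_flags) {
    if (!fl %in% names(cohort)) stop("unknown exclusion flag column: ", fl)
    mark(cohort[[fl]] == 1, paste0("comorbidity flag: ", fl))
  }
  keep <- is.na(reason)
  retained <- cohort[keep, , drop = FALSE]
  excluded <- cohort[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  if (nrow(retained) == 0L)
    warning("all subjects excluded; empty cohort returned")
  list(retained = retained, excluded = excluded,
       counts = table(retained$group))
}

#' Choose a two-group test by a Shapiro-Wilk normality gate
#'
#' Returns the two-sample t-test when the Shapiro-Wilk test does not
#' reject normality in either group (p >= alpha in both), and the
#' Mann-Whitney U test otherwise. The gate is applied on the scale
#' actually compared (e.g. log-transformed flowmotion).
#'
#' @param a,b Numeric vectors of the two groups (NA dropped); each needs
#'   at least 3 non-missing values.
#' @param alpha Significance level of the normality gate.
#' @return \code{"t_test"} or \code{"mann_whitney"}.
#' @export
choose_test <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("insufficient data for normality gate (need n >= 3 per group)")
  normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)   # degenerate: not normal
    stats::shapiro.test(x)$p.value >= alpha
  }
  if (normal(a) && normal(b)) "t_test" else "mann_whitney"
}

#' Compare a parameter between two groups
#'
#' Runs the test selected by \code{\link{choose_test}} (or a forced
#' choice): a two-tailed two-sample t-test — Welch by default, since group
#' spreads of FMSF parameters commonly differ severalfold; classical
#' pooled-variance by flag — or the Mann-Whitney U test (exact enumeration
#' when both groups have <= 8 subjects, normal approximation with tie and
#' continuity correction otherwise). Significance is flagged at p < 0.05;
#' no multiple-testing adjustment is applied.
#'
#' @param a,b Numeric vectors of the two groups (NA dropped).
#' @param test \code{NULL} (gate decides), \code{"t_test"} or
#'   \code{"mann_whitney"}.
#' @param alpha Gate significance level.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param parameter Optional parameter name recorded on the result.
#' @param group_labels Length-2 character vector of group names.
#' @return An object of class \code{"fmsf_comparison"}: parameter name,
#'   test used, statistic, two-sided p-value, significance flag and per-
#'   group n/mean/SD.
#' @examples
#' compare_groups(rnorm(20), rnorm(20, 1))
#' @export
compare_groups <- function(a, b, test = NULL, alpha = 0.05,
                           var_equal = FALSE, parameter = NA_character_,
                           group_labels = c("A", "B")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  if (is.null(test)) test <- choose_test(a, b, alpha)
  test <- match.arg(test, c("t_test", "mann_whitney"))
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    warning("zero variance in both groups with equal means; p = 1 by convention")
    statistic <- 0; p <- 1
  } else if (test == "t_test") {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    exact <- length(a) <= 8L && length(b) <= 8L
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    statistic <- unname(ht$statistic); p <- ht$p.value
  }
  grp <- function(x) list(n = length(x), mean = mean(x),
                          sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  out <- list(parameter = parameter, test = test, statistic = statistic,
              p_value = p, significant = p < 0.05,
              groups = stats::setNames(list(grp(a), grp(b)), group_labels))
  class(out) <- "fmsf_comparison"
  out
}

#' @export
print.fmsf_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.3f, p = %.4g%s\n",
              if (is.na(x$parameter)) "comparison" else x$parameter,
              x$test, x$statistic, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  for (g in names(x$groups)) {
    gi <- x$groups[[g]]
    cat(sprintf("  %s: n = %d, mean = %.3f, sd = %.3f\n",
                g, gi$n, gi$mean, gi$sd))
  }
  invisible(x)
}

#' Normality-gated correlation
#'
#' Pearson's correlation when both marginals pass the Shapiro-Wilk gate,
#' Spearman's rank correlation otherwise.
#'
#' @param x,y Paired numeric vectors (pairs with NA dropped; >= 4 complete
#'   pairs required).
#' @param alpha Gate significance level.
#' @return List with \code{method} (\code{"pearson"}/\code{"spearman"}),
#'   \code{estimate} and \code{p_value}; all-NA result with a warning for
#'   constant input.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(list(method = NA_character_, estimate = NA_real_,
                p_value = NA_real_))
  }
  gate <- function(v) stats::shapiro.test(v)$p.value >= alpha
  method <- if (gate(x) && gate(y)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value)
}

#' Per-group summary table with a pooled patient column
#'
#' Computes n, mean and sample SD (n - 1 denominator) of each parameter
#' for every group and for the pooled patient groups (default AA + AU).
#' SD is reported missing for groups of one; empty groups are omitted
#' with a warning. The pooled mean is the n-weighted mean of the subgroup
#' means by construction.
#'
#' @param cohort Data frame with a \code{group} column and the parameter
#'   columns.
#' @param parameters Character vector of parameter columns to summarize.
#' @param pooled Character vector of group labels pooled into a combined
#'   column (\code{NULL} for none).
#' @return Long-format data frame with columns \code{parameter},
#'   \code{group}, \code{n}, \code{mean}, \code{sd}.
#' @export
summarize_groups <- function(cohort,
                             parameters = c("FM", "NEURO", "NOI", "RHR",
                                            "IRmax", "HRmax", "HS"),
                             pooled = c("AA", "AU")) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  missing_p <- setdiff(parameters, names(cohort))
  if (length(missing_p))
    stop("parameter column(s) not in cohort: ",
         paste(missing_p, collapse = ", "))
  groups <- unique(as.character(cohort$group))
  sets <- stats::setNames(lapply(groups, function(g)
    which(cohort$group == g)), groups)
  if (!is.null(pooled) && all(pooled %in% groups))
    sets[[paste(pooled, collapse = " + ")]] <-
      which(cohort$group %in% pooled)
  out <- NULL
  for (g in names(sets)) {
    idx <- sets[[g]]
    if (length(idx) == 0L) {
      warning("group ", g, " is empty; row omitted")
      next
    }
    for (p in parameters) {
      v <- cohort[[p]][idx]
      v <- v[!is.na(v)]
      out <- rbind(out, data.frame(
        parameter = p, group = g, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_))
    }
  }
  out
}

#' Gate-and-test comparison of every parameter between two groups
#'
#' Convenience wrapper: for each parameter, applies the normality gate on
#' the analysis scale and compares the two subject sets. Log-scale
#' parameters (\code{logFM}, \code{logNEURO}, \code{logHS}) can be listed
#' directly to compare on the log scale.
#'
#' @param cohort Data frame with \code{group} and parameter columns.
#' @param groups Length-2 character vector of group labels; the first may
#'   be a pooled label like \code{"AA + AU"} covering several groups.
#' @param parameters Parameter columns to compare.
#' @return Named list of \code{\link{compare_groups}} results.
#' @export
compare_cohort <- function(cohort, groups = c("AA + AU", "control"),
                           parameters = c("logFM", "logNEURO", "NOI",
                                          "RHR", "IRmax", "HRmax",
                                          "logHS")) {
  pick <- function(lab) {
    members <- trimws(strsplit(lab, "+", fixed = TRUE)[[1]])
    cohort[cohort$group %in% members, , drop = FALSE]
  }
  ga <- pick(groups[1]); gb <- pick(groups[2])
  if (nrow(ga) == 0L || nrow(gb) == 0L)
    stop("empty comparison group")
  out <- lapply(parameters, function(p)
    compare_groups(ga[[p]], gb[[p]], parameter = p,
                   group_labels = groups))
  stats::setNames(out, parameters)
}
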