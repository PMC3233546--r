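#' Pearson correlation with a test of r = 0
#'
#' Product-moment correlation between two paired series with the standard
#' two-sided t test of the null r = 0 on n - 2 degrees of freedom
#' (t = r * sqrt((n - 2) / (1 - r^2))). Pairs with a missing value in
#' either series are dropped pairwise.
#'
#' @param x,y paired numeric series.
#' @param alpha significance cutoff, default 0.05.
#' @return list (class `concordance_result`): `n_pairs`, `r`, `t_stat`,
#'   `p`, `significant`.
#' @export
pearson_with_test <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    stop(sprintf("need at least 3 complete pairs, got %d", n), call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a series: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(n_pairs = n,
                 r = unname(ct$estimate),
                 t_stat = unname(ct$statistic),
                 p = ct$p.value,
                 significant = ct$p.value < alpha),
            class = "concordance_result")
}

#' Per-patient CA-125 / marker concordance across a cohort
#'
#' Computes [pearson_with_test()] between CA-125 and the methylation-marker
#' concentration for every patient's serial draws. Patients whose series
#' cannot be tested (too few complete pairs, or a constant series) are
#' reported as untestable with NA statistics rather than dropped.
#'
#' @param cohort list of [patient_series()] objects.
#' @param alpha significance cutoff, default 0.05.
#' @return list with `results` (data.frame patient_id, n_pairs, r, t_stat,
#'   p, significant, untestable) and `n_significant`.
#' @export
cohort_concordance <- function(cohort, alpha = 0.05) {
  if (length(cohort) == 0) stop("empty patient cohort", call. = FALSE)
  rows <- lapply(cohort, function(ps) {
    stopifnot(inherits(ps, "patient_series"))
    res <- tryCatch(
      pearson_with_test(ps$draws$ca125, ps$draws$marker_conc, alpha),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(patient_id = ps$patient_id, n_pairs = NA_integer_,
                 r = NA_real_, t_stat = NA_real_, p = NA_real_,
                 significant = NA, untestable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = ps$patient_id, n_pairs = res$n_pairs,
                 r = res$r, t_stat = res$t_stat, p = res$p,
                 significant = res$significant, untestable = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results,
       n_significant = sum(results$significant, na.rm = TRUE))
}

#' Post-resection drop relative to baseline
#'
#' For one patient, compares the first draw collected after surgery with
#' the baseline (first) draw, independently for CA-125 and the methylation
#' marker: `TRUE` means a strict decrease. Errors if the series has no
#' post-surgery draw (untestable).
#'
#' @param series a [patient_series()].
#' @return named logical `c(ca125 = ..., marker = ...)`.
#' @export
post_resection_drop <- function(series) {
  stopifnot(inherits(series, "patient_series"))
  d <- series$draws
  post <- which(d$week > series$surgery_week)
  if (length(post) == 0) {
    stop(sprintf("patient %s: no draw after surgery week %g — untestable",
                 series$patient_id, series$surgery_week), call. = FALSE)
  }
  first_post <- min(post)
  c(ca125 = d$ca125[first_post] < d$ca125[1],
    marker = d$marker_conc[first_post] < d$marker_conc[1])
}

#' Area under the ROC curve by midrank statistic
#'
#' `AUC = (#{case > control} + 0.5 * #{case = control}) / (n_case *
#' n_control)` — the Mann-Whitney U statistic scaled to \[0, 1\], computed
#' via midranks. Ties contribute half credit.
#'
#' @param case_values,control_values numeric vectors of the marker level in
#'   cases and controls.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(case_values, control_values) {
  n1 <- length(case_values); n0 <- length(control_values)
  if (n1 == 0 || n0 == 0) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (anyNA(case_values) || anyNA(control_values)) {
    stop("missing values in ROC input", call. = FALSE)
  }
  r <- rank(c(case_values, control_values))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Stratified bootstrap: cases and controls are resampled with replacement
#' within their own group, the AUC recomputed each time, and the
#' `level`-percentile interval reported. Deterministic under `seed`.
#'
#' @param case_values,control_values as in [roc_auc()].
#' @param n_boot bootstrap resamples, >= 100; default 2000.
#' @param level confidence level, default 0.95.
#' @param seed integer seed (`NULL` uses the session RNG stream).
#' @return list (class `roc_result`): `auc` (on the observed data),
#'   `ci_low`, `ci_high`, `n_boot`, `level`, `seed`.
#' @export
bootstrap_auc_ci <- function(case_values, control_values, n_boot = 2000,
                             level = 0.95, seed = NULL) {
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  auc <- roc_auc(case_values, control_values)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      roc_auc(sample(case_values, replace = TRUE),
              sample(control_values, replace = TRUE))
    }, numeric(1))
  })
  if (length(unique(boots)) == 1) {
    warning("degenerate bootstrap distribution: CI collapses to a point",
            call. = FALSE)
  }
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(auc = auc, ci_low = qs[1], ci_high = qs[2],
                 n_boot = as.integer(n_boot), level = level, seed = seed),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f [%.0f%% CI %.4f-%.4f], %d bootstrap resamples\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}
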