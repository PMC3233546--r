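#' Construct a beta-value cohort
#'
#' Container for an Infinium-style DNA methylation experiment: a probe x
#' sample matrix of beta values (fractional methylation, in \[0, 1\]), the
#' matching matrix of detection p-values, a group label per sample and a
#' subject identifier used to collapse technical replicates.
#'
#' @param beta numeric matrix, probes in rows, samples in columns; dimnames
#'   required. Values in \[0, 1\] or `NA`.
#' @param detection_p numeric matrix of detection p-values with the same
#'   dimensions and dimnames as `beta`. A p-value above the QC threshold
#'   (conventionally 0.05) marks a failed measurement.
#' @param groups named character vector mapping each sample id to `"tumor"`
#'   or `"pbl"`.
#' @param replicate_of named character vector mapping each sample id to a
#'   subject id; technical replicates of one subject share a value. Defaults
#'   to each sample being its own subject.
#'
#' @return An object of class `beta_cohort`.
#' @export
beta_cohort <- function(beta, detection_p, groups, replicate_of = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix", call. = FALSE)
  }
  if ((nrow(beta) > 0 && is.null(rownames(beta))) || is.null(colnames(beta))) {
    stop("`beta` must have probe rownames and sample colnames", call. = FALSE)
  }
  if (!is.matrix(detection_p) || !identical(dim(beta), dim(detection_p))) {
    stop("`detection_p` must be a matrix with the same shape as `beta`",
         call. = FALSE)
  }
  if (!identical(dimnames(beta), dimnames(detection_p))) {
    stop("`beta` and `detection_p` dimnames disagree", call. = FALSE)
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (%.4g)",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                 beta[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  samples <- colnames(beta)
  if (is.null(names(groups)) || !all(samples %in% names(groups))) {
    stop("`groups` must be named and cover every sample", call. = FALSE)
  }
  groups <- groups[samples]
  if (!all(groups %in% c("tumor", "pbl"))) {
    stop("sample groups must be 'tumor' or 'pbl'; got: ",
         paste(setdiff(unique(groups), c("tumor", "pbl")), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(replicate_of)) {
    replicate_of <- stats::setNames(samples, samples)
  }
  if (!all(samples %in% names(replicate_of))) {
    stop("`replicate_of` must cover every sample", call. = FALSE)
  }
  replicate_of <- replicate_of[samples]
  structure(
    list(beta = beta, detection_p = detection_p,
         groups = groups, replicate_of = replicate_of),
    class = "beta_cohort"
  )
}

#' @export
print.beta_cohort <- function(x, ...) {
  cat(sprintf("beta_cohort: %d probes x %d samples (%d tumor, %d PBL)\n",
              nrow(x$beta), ncol(x$beta),
              sum(x$groups == "tumor"), sum(x$groups == "pbl")))
  invisible(x)
}

#' @export
dim.beta_cohort <- function(x) dim(x$beta)

probe_ids <- function(cohort) rownames(cohort$beta)

sample_ids <- function(cohort) colnames(cohort$beta)

tumor_ids <- function(cohort) names(cohort$groups)[cohort$groups == "tumor"]

pbl_ids <- function(cohort) names(cohort$groups)[cohort$groups == "pbl"]

# keep: character vector of probe ids to retain (order preserved)
subset_probes <- function(cohort, keep) {
  keep <- intersect(probe_ids(cohort), keep)
  beta_cohort(cohort$beta[keep, , drop = FALSE],
              cohort$detection_p[keep, , drop = FALSE],
              cohort$groups, cohort$replicate_of)
}

#' Per-stage filter report
#'
#' Records what a single filtering stage did: its name, the probe counts in
#' and out, and the ids it removed. `probes_out == probes_in - length(removed)`
#' by construction.
#'
#' @param stage stage name.
#' @param probes_in,removed_probe_ids input probe count and removed ids.
#' @return An object of class `filter_report`.
#' @export
filter_report <- function(stage, probes_in, removed_probe_ids) {
  structure(
    list(stage = stage,
         probes_in = probes_in,
         probes_out = probes_in - length(removed_probe_ids),
         removed_probe_ids = removed_probe_ids),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %d -> %d probes (%d removed)\n",
              x$stage, x$probes_in, x$probes_out,
              length(x$removed_probe_ids)))
  invisible(x)
}

#' Collapse a list of filter reports to a funnel table
#'
#' @param reports list of `filter_report` objects from successive stages.
#' @return data.frame with columns stage, probes_in, probes_out, removed.
#' @export
funnel_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(stage = r$stage, probes_in = r$probes_in,
               probes_out = r$probes_out,
               removed = length(r$removed_probe_ids),
               stringsAsFactors = FALSE)
  }))
}
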