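#' Drop probes that failed detection QC in any sample
#'
#' A probe is removed if its detection p-value exceeds `alpha` in ANY sample
#' (tumors and all PBL replicates, before replicate averaging).
#'
#' @param cohort a [beta_cohort()].
#' @param alpha detection p-value threshold, in (0, 1); default 0.05.
#' @return list of `cohort` (filtered) and `report` (a [filter_report()]).
#' @export
drop_failed_probes <- function(cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "beta_cohort"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(cohort$detection_p)) {
    stop("cohort has no detection p-value matrix", call. = FALSE)
  }
  failed <- apply(cohort$detection_p > alpha, 1, any, na.rm = FALSE)
  failed[is.na(failed)] <- TRUE   # missing detection p counts as failed
  removed <- probe_ids(cohort)[failed]
  list(cohort = subset_probes(cohort, probe_ids(cohort)[!failed]),
       report = filter_report("detection_qc", nrow(cohort$beta), removed))
}

#' Drop SNP- or repeat-annotated probes
#'
#' Removes probes whose annotation carries a SNP flag or a RepeatMasker
#' repeat flag. Every probe in the cohort must have an annotation record
#' with explicit logical flags; an unannotated probe is an error, never a
#' silent keep.
#'
#' @param cohort a [beta_cohort()].
#' @param annotation data.frame with columns probe_id, snp_flag, repeat_flag.
#' @return list of `cohort` and `report`.
#' @export
drop_annotated_probes <- function(cohort, annotation) {
  stopifnot(inherits(cohort, "beta_cohort"))
  need <- c("probe_id", "snp_flag", "repeat_flag")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- probe_ids(cohort)
  m <- match(ids, annotation$probe_id)
  if (anyNA(m)) {
    stop("unannotated probes: ",
         paste(utils::head(ids[is.na(m)], 5), collapse = ", "),
         call. = FALSE)
  }
  snp <- annotation$snp_flag[m]
  rpt <- annotation$repeat_flag[m]
  if (anyNA(snp) || anyNA(rpt) || !is.logical(snp) || !is.logical(rpt)) {
    stop("snp_flag and repeat_flag must be non-missing logicals",
         call. = FALSE)
  }
  drop <- snp | rpt
  list(cohort = subset_probes(cohort, ids[!drop]),
       report = filter_report("snp_repeat", length(ids), ids[drop]))
}

#' Collapse PBL technical replicates to per-subject averages
#'
#' PBL replicates of one subject are averaged (arithmetic mean beta per
#' probe); the collapsed detection p-value is the maximum over replicates,
#' the conservative choice (a subject fails if any replicate failed).
#' Tumor samples pass through untouched.
#'
#' @param cohort a [beta_cohort()].
#' @return A [beta_cohort()] with one column per PBL subject.
#' @export
average_replicates <- function(cohort) {
  stopifnot(inherits(cohort, "beta_cohort"))
  subj <- cohort$replicate_of
  # replicate groups must not span tumor and PBL
  for (s in unique(subj)) {
    g <- unique(cohort$groups[names(subj)[subj == s]])
    if (length(g) > 1) {
      stop(sprintf("replicate group '%s' spans groups: %s", s,
                   paste(g, collapse = ", ")), call. = FALSE)
    }
  }
  tum <- tumor_ids(cohort)
  pbl_subjects <- unique(subj[pbl_ids(cohort)])
  beta_cols <- lapply(pbl_subjects, function(s) {
    cols <- names(subj)[subj == s]
    rowMeans(cohort$beta[, cols, drop = FALSE])
  })
  detp_cols <- lapply(pbl_subjects, function(s) {
    cols <- names(subj)[subj == s]
    apply(cohort$detection_p[, cols, drop = FALSE], 1, max)
  })
  beta <- cbind(cohort$beta[, tum, drop = FALSE],
                do.call(cbind, beta_cols))
  detp <- cbind(cohort$detection_p[, tum, drop = FALSE],
                do.call(cbind, detp_cols))
  colnames(beta) <- colnames(detp) <- c(tum, pbl_subjects)
  groups <- setNames(c(rep("tumor", length(tum)),
                       rep("pbl", length(pbl_subjects))),
                     c(tum, pbl_subjects))
  beta_cohort(beta, detp, groups)
}

#' Drop probes methylated in PBL
#'
#' Removes probes whose averaged beta is greater than OR EQUAL to
#' `threshold` in any PBL subject — the inclusive rule: a probe at exactly
#' the threshold is excluded. Replicates must already be collapsed with
#' [average_replicates()].
#'
#' @param cohort a [beta_cohort()] with averaged PBL columns.
#' @param threshold PBL beta cutoff in (0, 1); default 0.2.
#' @return list of `cohort` and `report`.
#' @export
drop_pbl_methylated <- function(cohort, threshold = 0.2) {
  stopifnot(inherits(cohort, "beta_cohort"))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  pbl <- pbl_ids(cohort)
  if (length(pbl) == 0) stop("no PBL samples in cohort", call. = FALSE)
  high <- apply(cohort$beta[, pbl, drop = FALSE] >= threshold, 1, any)
  ids <- probe_ids(cohort)
  list(cohort = subset_probes(cohort, ids[!high]),
       report = filter_report("pbl_beta", length(ids), ids[high]))
}

#' Rank probes by tumor-versus-leukocyte separation
#'
#' For each probe, takes the least methylated tumor (`t_low`, the T_L
#' statistic) and the most methylated PBL subject (`pbl_high`, PBL_H) and
#' ranks by `delta = t_low - pbl_high` descending. Probes with
#' `delta <= 0` — i.e. some blood sample at least as methylated as some
#' tumor — are eliminated. Ties in delta break by probe id ascending so the
#' ranking is deterministic.
#'
#' @param cohort a [beta_cohort()] with averaged PBL columns and no missing
#'   beta values (survivors of the QC filter are complete by construction).
#' @param annotation optional data.frame (probe_id, gene_symbol) used to
#'   carry gene symbols into the output.
#' @return data.frame (probe_id, gene_symbol, t_low, pbl_high, delta, rank)
#'   sorted by rank.
#' @export
rank_by_separation <- function(cohort, annotation = NULL) {
  stopifnot(inherits(cohort, "beta_cohort"))
  tum <- tumor_ids(cohort)
  pbl <- pbl_ids(cohort)
  if (length(tum) == 0 || length(pbl) == 0) {
    stop("need at least one tumor and one PBL sample", call. = FALSE)
  }
  bt <- cohort$beta[, tum, drop = FALSE]
  bp <- cohort$beta[, pbl, drop = FALSE]
  if (anyNA(bt) || anyNA(bp)) {
    bad <- probe_ids(cohort)[apply(is.na(bt), 1, any) | apply(is.na(bp), 1, any)]
    stop("missing beta values among surviving probes: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  t_low <- apply(bt, 1, min)
  pbl_high <- apply(bp, 1, max)
  delta <- t_low - pbl_high
  keep <- delta > 0
  ids <- probe_ids(cohort)[keep]
  out <- data.frame(probe_id = ids,
                    gene_symbol = rep(NA_character_, length(ids)),
                    t_low = t_low[keep], pbl_high = pbl_high[keep],
                    delta = delta[keep], stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    out$gene_symbol <- annotation$gene_symbol[match(out$probe_id,
                                                    annotation$probe_id)]
  }
  out <- out[order(-out$delta, out$probe_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Take the top-ranked markers
#'
#' Returns the first `k` records by rank. With `unique_genes = TRUE`, only
#' the best-ranked probe per gene symbol is kept before truncation (probes
#' without a gene symbol are kept individually). Asking for more markers
#' than exist returns the whole list.
#'
#' @param ranked data.frame from [rank_by_separation()].
#' @param k number of markers to keep (>= 1).
#' @param unique_genes collapse to one probe per gene first.
#' @return data.frame, first `k` surviving records, ranks as in the input.
#' @export
select_top_markers <- function(ranked, k = 15, unique_genes = FALSE) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  out <- ranked
  if (unique_genes && nrow(out) > 0) {
    has_gene <- !is.na(out$gene_symbol)
    first <- !duplicated(out$gene_symbol) | !has_gene
    out <- out[first, , drop = FALSE]
  }
  utils::head(out, k)
}

#' Run the full marker-selection cascade
#'
#' Detection-p QC, SNP/repeat exclusion, PBL replicate averaging,
#' PBL-methylation exclusion, separation ranking and top-k selection, in
#' that order, collecting a [filter_report()] per stage.
#'
#' @param cohort a [beta_cohort()] with raw PBL replicates.
#' @param annotation probe annotation data.frame.
#' @param alpha detection p-value threshold (default 0.05).
#' @param pbl_threshold PBL beta exclusion cutoff (default 0.2, inclusive).
#' @param top_k number of markers to carry forward (default 15).
#' @param unique_genes collapse to one probe per gene before truncation.
#' @return list with `markers` (top-k data.frame), `ranked` (full ranking),
#'   `reports` (list of filter_reports incl. a `separation` stage),
#'   `cohort` (post-filter, replicate-averaged).
#' @export
select_markers <- function(cohort, annotation, alpha = 0.05,
                           pbl_threshold = 0.2, top_k = 15,
                           unique_genes = FALSE) {
  s1 <- drop_failed_probes(cohort, alpha)
  s2 <- drop_annotated_probes(s1$cohort, annotation)
  avg <- average_replicates(s2$cohort)
  s3 <- drop_pbl_methylated(avg, pbl_threshold)
  ranked <- rank_by_separation(s3$cohort, annotation)
  sep_removed <- setdiff(probe_ids(s3$cohort), ranked$probe_id)
  reports <- list(s1$report, s2$report, s3$report,
                  filter_report("separation", nrow(s3$cohort$beta),
                                sep_removed))
  if (top_k > nrow(ranked)) {
    warning(sprintf("requested top %d markers but only %d ranked; keeping all",
                    top_k, nrow(ranked)), call. = FALSE)
  }
  markers <- select_top_markers(ranked, top_k, unique_genes)
  list(markers = markers, ranked = ranked, reports = reports,
       cohort = s3$cohort)
}

#' Summarize marker beta distributions per group across cohorts
#'
#' Cross-cohort verification summary: for each selected marker and each
#' (cohort, group) cell, the median, quartiles and n of the beta values.
#' A marker absent from a cohort is recorded with NA summaries, not an
#' error.
#'
#' @param cohorts named list of [beta_cohort()] objects.
#' @param marker_ids character vector of probe ids.
#' @return data.frame (marker_id, cohort, group, n, q1, median, q3).
#' @export
summarize_group_distributions <- function(cohorts, marker_ids) {
  stopifnot(is.list(cohorts), length(names(cohorts)) == length(cohorts))
  rows <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    for (g in unique(co$groups)) {
      cols <- names(co$groups)[co$groups == g]
      for (m in marker_ids) {
        if (m %in% probe_ids(co)) {
          v <- co$beta[m, cols]
          qs <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                names = FALSE)
          rows[[length(rows) + 1L]] <-
            data.frame(marker_id = m, cohort = cn, group = g,
                       n = sum(!is.na(v)), q1 = qs[1], median = qs[2],
                       q3 = qs[3], stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <-
            data.frame(marker_id = m, cohort = cn, group = g, n = 0L,
                       q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
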