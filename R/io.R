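#' Read a beta cohort from TSV/CSV files
#'
#' The beta and detection-p matrices are TSVs with probe ids in the first
#' column and one column per sample; the sample sheet is a CSV with columns
#' `sample_id`, `group` (`tumor`/`pbl`) and `subject_id`. Validation
#' failures name the offending probe, sample or line.
#'
#' @param beta_path,detp_path paths to the beta and detection p-value TSVs.
#' @param samples_path path to the sample-sheet CSV.
#' @return A [beta_cohort()].
#' @export
read_beta_matrix <- function(beta_path, detp_path, samples_path) {
  read_mat <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
  beta <- read_mat(beta_path)
  detp <- read_mat(detp_path)
  if (!identical(dim(beta), dim(detp)) ||
      !identical(dimnames(beta), dimnames(detp))) {
    stop("beta and detection-p matrices disagree in shape or labels",
         call. = FALSE)
  }
  sheet <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "subject_id")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sheet) == 0) stop("sample sheet is empty", call. = FALSE)
  bad <- which(!sheet$group %in% c("tumor", "pbl"))
  if (length(bad) > 0) {
    stop(sprintf("unknown group '%s' at sample sheet line %d",
                 sheet$group[bad[1]], bad[1] + 1L), call. = FALSE)
  }
  missing_samp <- setdiff(colnames(beta), sheet$sample_id)
  if (length(missing_samp) > 0) {
    stop("samples absent from sample sheet: ",
         paste(missing_samp, collapse = ", "), call. = FALSE)
  }
  beta_cohort(beta, detp,
              stats::setNames(sheet$group, sheet$sample_id),
              stats::setNames(sheet$subject_id, sheet$sample_id))
}

#' Write a beta cohort to TSV/CSV files
#'
#' Inverse of [read_beta_matrix()]: writes `beta.tsv`, `detection_p.tsv`
#' and `samples.csv` under `dir`.
#'
#' @param cohort a [beta_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the three paths.
#' @export
write_beta_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "beta_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, path) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths <- file.path(dir, c("beta.tsv", "detection_p.tsv", "samples.csv"))
  write_mat(cohort$beta, paths[1])
  write_mat(cohort$detection_p, paths[2])
  utils::write.csv(
    data.frame(sample_id = names(cohort$groups),
               group = unname(cohort$groups),
               subject_id = unname(cohort$replicate_of),
               stringsAsFactors = FALSE),
    paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write ranked markers to TSV
#'
#' @param ranked data.frame from [rank_by_separation()].
#' @param path output path.
#' @export
write_ranked_markers <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read serial patient series from CSV
#'
#' One row per draw, columns `patient_id`, `week`, `ca125_u_per_ml`,
#' `marker_molecules_per_ml`, `surgery_week`, `relapse_week` (empty = no
#' relapse). Rows are grouped by patient and ordered by week.
#'
#' @param path series CSV path.
#' @return named list of [patient_series()] objects.
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "week", "ca125_u_per_ml",
            "marker_molecules_per_ml", "surgery_week")
  if (!all(need %in% names(df))) {
    stop("series CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"relapse_week" %in% names(df)) df$relapse_week <- NA_real_
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$week), , drop = FALSE]
    patient_series(
      patient_id = as.character(d$patient_id[1]),
      draws = data.frame(week = d$week, ca125 = d$ca125_u_per_ml,
                         marker_conc = d$marker_molecules_per_ml),
      surgery_week = d$surgery_week[1],
      relapse_week = d$relapse_week[1],
      baseline_is_presurgery = d$week[1] <= d$surgery_week[1])
  })
  out[order(names(out))]
}

#' Write serial patient series to CSV
#'
#' @param cohort named list of [patient_series()] objects.
#' @param path output path.
#' @export
write_series <- function(cohort, path) {
  rows <- lapply(cohort, function(ps) {
    data.frame(patient_id = ps$patient_id,
               week = ps$draws$week,
               ca125_u_per_ml = ps$draws$ca125,
               marker_molecules_per_ml = ps$draws$marker_conc,
               surgery_week = ps$surgery_week,
               relapse_week = ps$relapse_week,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read digital plate counts from CSV
#'
#' Columns: `sample_id`, `plate_id`, `wells_total`, `wells_positive`,
#' `volume_assayed_ul` (volume per plate; summed per sample).
#'
#' @param path plate CSV path.
#' @return named list of [digital_plate_set()] objects.
#' @export
read_plates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "wells_total", "wells_positive",
            "volume_assayed_ul")
  if (!all(need %in% names(df))) {
    stop("plate CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$sample_id), function(d) {
    digital_plate_set(as.character(d$sample_id[1]),
                      d[, c("wells_total", "wells_positive"), drop = FALSE],
                      sum(d$volume_assayed_ul))
  })
}

#' Write a combined analysis report to TSV files
#'
#' Writes whichever report components are supplied: the probe-filter funnel
#' (`funnel.tsv`), MethyLight screen outcomes (`screen.tsv`), digital
#' quantifications (`digital.tsv`) and per-patient concordance
#' (`concordance.tsv`).
#'
#' @param dir output directory.
#' @param reports list of [filter_report()]s, or `NULL`.
#' @param screen result of [screen_markers()], or `NULL`.
#' @param quants list of `digital_quant`s, or `NULL`.
#' @param concordance result of [cohort_concordance()], or `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(dir, reports = NULL, screen = NULL, quants = NULL,
                         concordance = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(reports)) w(funnel_table(reports), "funnel.tsv")
  if (!is.null(screen)) w(screen$outcomes, "screen.tsv")
  if (!is.null(quants)) {
    w(do.call(rbind, lapply(quants, function(q) {
      data.frame(sample_id = q$sample_id,
                 molecules_detected = q$molecules_detected,
                 molecules_estimated = q$molecules_estimated,
                 concentration_per_ml = q$concentration,
                 saturated = q$saturated, stringsAsFactors = FALSE)
    })), "digital.tsv")
  }
  if (!is.null(concordance)) w(concordance$results, "concordance.tsv")
  invisible(paths)
}
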