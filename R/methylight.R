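#' ALU-reaction DNA quality gate
#'
#' A bisulfite-converted DNA sample is usable only if its ALU-repeat control
#' MethyLight reaction amplified with a cycle threshold strictly below
#' `max_ct` (default 21 cycles): a high or absent ALU Ct means too little
#' amplifiable DNA. Undetected (`NA`) fails, it is not an error.
#'
#' @param ct ALU Ct value(s); `NA` = undetected.
#' @param max_ct QC ceiling in cycles, default 21 (strict `<`).
#' @return logical, `TRUE` where the sample passes.
#' @export
alu_qc <- function(ct, max_ct = 21) {
  if (max_ct <= 0) stop("`max_ct` must be > 0", call. = FALSE)
  !is.na(ct) & ct < max_ct
}

#' M.SssI positive-control gate
#'
#' A MethyLight assay is valid only if it amplifies fully methylated
#' (M.SssI-treated) control DNA. Pass iff the control Ct is present and
#' within the assay's cycle ceiling.
#'
#' @param ct M.SssI-control Ct value(s); `NA` = no amplification.
#' @param max_cycles PCR cycle ceiling defining "undetected"; default 50.
#' @return logical, `TRUE` where the assay is valid.
#' @export
mssi_gate <- function(ct, max_cycles = 50) {
  !is.na(ct) & ct > 0 & ct <= max_cycles
}

#' PBL counter-screen on MethyLight Ct values
#'
#' A candidate marker passes the leukocyte counter-screen only if EVERY
#' control PBL sample shows a Ct above `min_ct` (default 35) or no
#' amplification at all: any PBL sample amplifying at or below the cutoff
#' reveals background methylation in normal blood.
#'
#' @param cts numeric vector of Ct values, one per PBL sample (`NA` =
#'   undetected).
#' @param min_ct cutoff in cycles, default 35 (pass requires strict `>`).
#' @return list (class `screen_outcome`): `passed`, `stage = "pbl_ct"`,
#'   `evidence` (the Ct values).
#' @export
pbl_counter_screen <- function(cts, min_ct = 35) {
  if (length(cts) == 0) stop("no PBL Ct values supplied", call. = FALSE)
  passed <- all(is.na(cts) | cts > min_ct)
  structure(list(stage = "pbl_ct", passed = passed, evidence = cts),
            class = "screen_outcome")
}

#' Percent of Methylated Reference (PMR)
#'
#' Relative quantification of methylated template by the double-delta-Ct
#' method: the target reaction is normalized to an ALU repeat control within
#' each DNA, and the sample's normalized level is scaled to that of fully
#' methylated (M.SssI-treated) reference DNA, times 100.
#'
#' `pmr = 100 * 2^-((ct_target_sample - ct_alu_sample) -
#'                  (ct_target_ref - ct_alu_ref))`
#'
#' An undetected target in the sample (with valid ALU) means no methylation
#' detected: PMR 0. An undetected ALU in either DNA makes normalization
#' impossible and is an error.
#'
#' @param ct_target_sample,ct_alu_sample target and ALU Ct in the sample.
#' @param ct_target_ref,ct_alu_ref target and ALU Ct in the M.SssI
#'   reference.
#' @return PMR, a non-negative unitless percentage.
#' @export
compute_pmr <- function(ct_target_sample, ct_alu_sample,
                        ct_target_ref, ct_alu_ref) {
  if (is.na(ct_alu_sample) || is.na(ct_alu_ref)) {
    stop("undetected ALU control: PMR normalization impossible",
         call. = FALSE)
  }
  if (is.na(ct_target_ref)) {
    stop("undetected target in the M.SssI reference: assay invalid",
         call. = FALSE)
  }
  if (is.na(ct_target_sample)) return(0)
  ddct <- (ct_target_sample - ct_alu_sample) - (ct_target_ref - ct_alu_ref)
  100 * 2^(-ddct)
}

#' Categorize a PMR value
#'
#' Three-bin categorization of methylation level: `low` below `low_max`,
#' `high` above `high_min`, `mid` in the closed interval between them
#' (boundaries 10 and 50 land in `mid`).
#'
#' @param pmr PMR value(s), >= 0.
#' @param low_max lower bin boundary, default 10.
#' @param high_min upper bin boundary, default 50.
#' @return character vector in `c("low", "mid", "high")`.
#' @export
categorize_pmr <- function(pmr, low_max = 10, high_min = 50) {
  if (any(is.na(pmr))) stop("PMR must not be missing", call. = FALSE)
  if (any(pmr < 0)) stop("PMR must be non-negative", call. = FALSE)
  if (low_max >= high_min) stop("low_max must be < high_min", call. = FALSE)
  ifelse(pmr < low_max, "low", ifelse(pmr > high_min, "high", "mid"))
}

#' Control-plasma PMR screen
#'
#' A marker intended for blood-based detection must be near-silent in
#' plasma from healthy controls: pass iff every control plasma PMR is
#' strictly below `cutoff` (default 5).
#'
#' @param pmrs PMR values, one per control plasma.
#' @param cutoff default 5.
#' @return `screen_outcome` list with stage `"plasma_pmr"`.
#' @export
plasma_screen <- function(pmrs, cutoff = 5) {
  if (length(pmrs) == 0) stop("no control plasma PMR values", call. = FALSE)
  structure(list(stage = "plasma_pmr", passed = all(pmrs < cutoff),
                 evidence = pmrs),
            class = "screen_outcome")
}

#' Fraction of tumors positive for a marker
#'
#' @param pmrs PMR values, one per tumor.
#' @param cutoff positivity threshold, default 20 (positive requires
#'   strict `>`).
#' @return fraction of tumors with PMR above the cutoff.
#' @export
tumor_positivity <- function(pmrs, cutoff = 20) {
  if (length(pmrs) == 0) stop("no tumor PMR values", call. = FALSE)
  mean(pmrs > cutoff)
}

#' Run the full MethyLight verification cascade over a marker panel
#'
#' Stages run left to right — assay design, M.SssI positive control, PBL Ct
#' counter-screen, control-plasma PMR, tumor PMR positivity — and
#' short-circuit: a marker failing a stage records no outcome for later
#' stages.
#'
#' @param panel a panel as returned by [generate_methylight_panel()]:
#'   list with `markers` (marker_id, designable, mssi_ct), `pbl_ct`,
#'   `plasma_pmr`, `tumor_pmr` data.frames.
#' @param pbl_min_ct PBL counter-screen cutoff (default 35).
#' @param plasma_pmr_max control plasma cutoff (default 5).
#' @param tumor_pmr_min tumor positivity cutoff (default 20).
#' @param require_all_tumors if `TRUE` (default) the final stage passes
#'   only when every tumor is positive.
#' @return list with `outcomes` (data.frame marker_id, stage, passed,
#'   evidence) and `survivors` (marker ids passing all stages).
#' @export
screen_markers <- function(panel, pbl_min_ct = 35, plasma_pmr_max = 5,
                           tumor_pmr_min = 20, require_all_tumors = TRUE) {
  mk <- panel$markers
  outcomes <- list()
  note <- function(id, stage, passed, evidence) {
    outcomes[[length(outcomes) + 1L]] <<-
      data.frame(marker_id = id, stage = stage, passed = passed,
                 evidence = evidence, stringsAsFactors = FALSE)
  }
  survivors <- character(0)
  for (i in seq_len(nrow(mk))) {
    id <- mk$marker_id[i]
    if (!isTRUE(mk$designable[i])) {
      note(id, "design", FALSE, "assay design infeasible")
      next
    }
    note(id, "design", TRUE, "assay designed")
    if (!mssi_gate(mk$mssi_ct[i])) {
      note(id, "mssi", FALSE, "M.SssI control did not amplify")
      next
    }
    note(id, "mssi", TRUE, sprintf("M.SssI Ct %.1f", mk$mssi_ct[i]))
    cts <- panel$pbl_ct$ct[panel$pbl_ct$marker_id == id]
    sc <- pbl_counter_screen(cts, pbl_min_ct)
    note(id, "pbl_ct", sc$passed,
         paste(ifelse(is.na(cts), "ND", sprintf("%.1f", cts)),
               collapse = "/"))
    if (!sc$passed) next
    pl <- panel$plasma_pmr$pmr[panel$plasma_pmr$marker_id == id]
    sp <- plasma_screen(pl, plasma_pmr_max)
    note(id, "plasma_pmr", sp$passed, sprintf("max PMR %.2f", max(pl)))
    if (!sp$passed) next
    tu <- panel$tumor_pmr$pmr[panel$tumor_pmr$marker_id == id]
    frac <- tumor_positivity(tu, tumor_pmr_min)
    ok <- if (require_all_tumors) frac == 1 else frac > 0
    note(id, "tumor_pmr", ok, sprintf("%.0f%% tumors positive", 100 * frac))
    if (ok) survivors <- c(survivors, id)
  }
  list(outcomes = do.call(rbind, outcomes), survivors = survivors)
}
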