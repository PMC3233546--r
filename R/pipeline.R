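#' Pipeline configuration
#'
#' All stage thresholds in one place, with the discovery-and-verification
#' defaults: detection p-value 0.05, PBL beta exclusion at 0.2 (inclusive),
#' top 15 markers, ALU QC Ct < 21, PBL counter-screen Ct > 35, control
#' plasma PMR < 5, tumor positivity PMR > 20, digital saturation caveat at
#' 15 hits per 96-well plate, 2000 bootstrap resamples, significance alpha
#' 0.05.
#'
#' @param alpha detection p-value threshold.
#' @param pbl_beta PBL beta exclusion cutoff (inclusive).
#' @param top_k markers carried to verification.
#' @param unique_genes collapse ranking to one probe per gene.
#' @param alu_max_ct ALU QC ceiling, cycles.
#' @param pbl_min_ct PBL counter-screen cutoff, cycles.
#' @param plasma_pmr_max control plasma PMR cutoff.
#' @param tumor_pmr_min tumor positivity PMR cutoff.
#' @param saturation_hits digital saturation caveat, hits per 96 wells.
#' @param boot bootstrap resamples for the AUC CI.
#' @param sig_alpha significance cutoff for the concordance test.
#' @param n_cases,n_controls baseline serum cohort sizes for the ROC stage.
#' @param n_patients serial patients for the longitudinal stage.
#' @param seed master seed; every stage's randomness derives from it.
#' @param out_dir directory for output tables (`NULL` = no files written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, pbl_beta = 0.2, top_k = 15,
                            unique_genes = FALSE, alu_max_ct = 21,
                            pbl_min_ct = 35, plasma_pmr_max = 5,
                            tumor_pmr_min = 20, saturation_hits = 15,
                            boot = 2000, sig_alpha = 0.05,
                            n_cases = 16L, n_controls = 8L,
                            n_patients = 9L, seed = 1L, out_dir = NULL) {
  cfg <- list(alpha = alpha, pbl_beta = pbl_beta, top_k = top_k,
              unique_genes = unique_genes, alu_max_ct = alu_max_ct,
              pbl_min_ct = pbl_min_ct, plasma_pmr_max = plasma_pmr_max,
              tumor_pmr_min = tumor_pmr_min,
              saturation_hits = saturation_hits, boot = boot,
              sig_alpha = sig_alpha, n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save / load a pipeline configuration
#'
#' Lossless round-trip through a plain-text file (R expression syntax).
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `save_config` returns the path invisibly; `load_config` the
#'   configuration.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  dput(unclass(config), file = path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- dget(path)
  do.call(pipeline_config, cfg)
}

#' Run the end-to-end discovery and verification pipeline on synthetic data
#'
#' Simulates a discovery cohort with planted markers, runs the
#' marker-selection cascade, screens a MethyLight verification panel,
#' quantifies a baseline case/control serum cohort by Digital MethyLight
#' with ROC analysis, and evaluates longitudinal CA-125 concordance on a
#' serial patient cohort whose two channels share the latent tumor-burden
#' trajectory. Every stage's randomness derives from `config$seed`; the
#' same configuration yields identical results and files.
#'
#' @param config a [pipeline_config()].
#' @param sim a [sim_config()] for the discovery cohort; its seed is
#'   overridden by `config$seed`.
#' @return list with `selection` (from [select_markers()]), `truth`,
#'   `screen` (from [screen_markers()]), `quants`, `roc` (a `roc_result`),
#'   `concordance`, `drops` (per-patient post-resection drop calls) and
#'   `funnel` (stage-count data.frame).
#' @export
run_pipeline <- function(config = pipeline_config(), sim = sim_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # -- discovery: simulate cohort, run the filtering cascade
  sim$seed <- seed
  gen <- generate_infinium_cohort(sim)
  sel <- select_markers(gen$cohort, gen$annotation, alpha = config$alpha,
                        pbl_threshold = config$pbl_beta,
                        top_k = config$top_k,
                        unique_genes = config$unique_genes)
  funnel <- funnel_table(sel$reports)
  message(paste(sprintf("%s: %d -> %d", funnel$stage, funnel$probes_in,
                        funnel$probes_out), collapse = "; "))

  # -- verification: MethyLight panel screen sized to the selected set
  n_panel <- nrow(sel$markers)
  panel <- generate_methylight_panel(panel_config(
    n_markers = max(n_panel, 5L),
    n_design_fail = min(3L, max(n_panel - 2L, 0L)),
    seed = seed + 11L))
  screen <- screen_markers(panel, pbl_min_ct = config$pbl_min_ct,
                           plasma_pmr_max = config$plasma_pmr_max,
                           tumor_pmr_min = config$tumor_pmr_min)

  # -- baseline serum cohort: digital quantification + ROC
  case_conc <- with_seed(seed + 21L,
                         stats::rlnorm(config$n_cases,
                                       meanlog = log(150), sdlog = 0.9))
  quants <- vector("list", config$n_cases + config$n_controls)
  for (i in seq_len(config$n_cases)) {
    plates <- generate_digital_plates(case_conc[i], volume_ul = 100,
                                      sample_id = sprintf("case%02d", i),
                                      seed = seed + 30L + i)
    quants[[i]] <- quantify_sample(plates,
                                   saturation_hits = config$saturation_hits)
  }
  # controls: no tumor burden, rare background molecules (~0.25 per sample)
  for (j in seq_len(config$n_controls)) {
    plates <- generate_digital_plates(2.5, volume_ul = 100,
                                      sample_id = sprintf("ctrl%02d", j),
                                      seed = seed + 60L + j)
    quants[[config$n_cases + j]] <-
      quantify_sample(plates, saturation_hits = config$saturation_hits)
  }
  concs <- vapply(quants, function(q) q$concentration, numeric(1))
  roc <- bootstrap_auc_ci(concs[seq_len(config$n_cases)],
                          concs[config$n_cases + seq_len(config$n_controls)],
                          n_boot = config$boot, seed = seed + 97L)

  # -- longitudinal: serial patients sharing the burden latent
  relapses <- rep(c(48, 54, 60, NA), length.out = config$n_patients)
  patients <- lapply(seq_len(config$n_patients), function(i) {
    generate_patient_series(
      trajectory_config(relapse_week = relapses[i], seed = seed + 200L + i),
      patient_id = sprintf("P%d", i))
  })
  conc_res <- cohort_concordance(patients, alpha = config$sig_alpha)
  drops <- t(vapply(patients, post_resection_drop, logical(2)))
  rownames(drops) <- vapply(patients, function(p) p$patient_id, character(1))

  if (!is.null(config$out_dir)) {
    write_report(config$out_dir, reports = sel$reports, screen = screen,
                 quants = quants, concordance = conc_res)
    write_ranked_markers(sel$markers,
                         file.path(config$out_dir, "top_markers.tsv"))
  }

  list(selection = sel, truth = gen$truth, screen = screen, quants = quants,
       roc = roc, concordance = conc_res, drops = drops, funnel = funnel)
}
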