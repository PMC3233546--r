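#' @importFrom stats rbeta rpois runif rlnorm rnorm setNames quantile median
NULL

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulations are reproducible without clobbering the
# session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Beta distribution parameterized by (mean, precision): shape1 = m * s,
# shape2 = (1 - m) * s. Easier to state planted effect sizes than raw (a, b).
beta_params <- function(mean, precision) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("beta-distribution mean must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(precision) || precision <= 0) {
    stop("beta-distribution precision must be positive", call. = FALSE)
  }
  list(mean = mean, precision = precision,
       shape1 = mean * precision, shape2 = (1 - mean) * precision)
}

rbeta_mp <- function(n, dist) rbeta(n, dist$shape1, dist$shape2)

#' Configuration for the simulated Infinium cohort
#'
#' Defaults emulate the discovery cohort the pipeline targets: a 27,578-probe
#' methylation array run on 41 ovarian tumors and 2 PBL (peripheral blood
#' leukocyte) subjects, each PBL subject in technical duplicate. A small set
#' of "planted" marker probes is highly methylated in every tumor and nearly
#' unmethylated in PBL; a fraction of probes is methylated in PBL (and
#' tumors) to exercise the leukocyte counter-filter; a fraction of
#' probe-by-sample cells carries a failed detection p-value; SNP/repeat
#' annotation flags are sprinkled over non-planted probes.
#'
#' @param n_probes number of array probes.
#' @param n_tumors number of tumor samples.
#' @param n_pbl_subjects number of PBL subjects (each run in duplicate).
#' @param n_replicates technical replicates per PBL subject.
#' @param n_planted_markers number of planted tumor-specific marker probes.
#' @param planted_tumor_beta,planted_pbl_beta,background_beta,pbl_high_beta
#'   two-element numeric vectors `c(mean, precision)` for the beta
#'   distributions of planted probes in tumors, planted probes in PBL,
#'   background probes (all groups) and PBL-methylated probes (all groups).
#' @param pbl_high_fraction fraction of probes methylated in PBL.
#' @param fail_fraction fraction of probe-by-sample cells with detection
#'   p-value > 0.05 (drawn uniform on (0.05, 1]).
#' @param snp_fraction,repeat_fraction fractions of probes flagged as
#'   SNP-overlapping / repeat-overlapping in the annotation.
#' @param probes_per_gene mean probes per gene locus used when assigning
#'   gene symbols (the 27K array averages ~1.9).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_probes = 27578L,
                       n_tumors = 41L,
                       n_pbl_subjects = 2L,
                       n_replicates = 2L,
                       n_planted_markers = 40L,
                       planted_tumor_beta = c(mean = 0.70, precision = 50),
                       planted_pbl_beta = c(mean = 0.02, precision = 50),
                       background_beta = c(mean = 0.08, precision = 10),
                       pbl_high_beta = c(mean = 0.55, precision = 8),
                       pbl_high_fraction = 0.30,
                       fail_fraction = 0.002,
                       snp_fraction = 0.03,
                       repeat_fraction = 0.02,
                       probes_per_gene = 1.9,
                       seed = 1L) {
  fracs <- c(pbl_high_fraction = pbl_high_fraction,
             fail_fraction = fail_fraction,
             snp_fraction = snp_fraction,
             repeat_fraction = repeat_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_planted_markers > n_probes) {
    stop("n_planted_markers cannot exceed n_probes", call. = FALSE)
  }
  if (n_tumors < 1 || n_pbl_subjects < 1 || n_replicates < 1) {
    stop("sample counts must be >= 1", call. = FALSE)
  }
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_tumors = as.integer(n_tumors),
    n_pbl_subjects = as.integer(n_pbl_subjects),
    n_replicates = as.integer(n_replicates),
    n_planted_markers = as.integer(n_planted_markers),
    planted_tumor_beta = beta_params(planted_tumor_beta[[1]], planted_tumor_beta[[2]]),
    planted_pbl_beta = beta_params(planted_pbl_beta[[1]], planted_pbl_beta[[2]]),
    background_beta = beta_params(background_beta[[1]], background_beta[[2]]),
    pbl_high_beta = beta_params(pbl_high_beta[[1]], pbl_high_beta[[2]]),
    pbl_high_fraction = pbl_high_fraction,
    fail_fraction = fail_fraction,
    snp_fraction = snp_fraction,
    repeat_fraction = repeat_fraction,
    probes_per_gene = probes_per_gene,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an Infinium-style discovery cohort with planted markers
#'
#' Draws per-group beta values from the configured beta distributions, builds
#' the matching detection p-value matrix with engineered failed cells, and a
#' probe annotation with gene symbols and SNP/repeat flags. Planted marker
#' probes are exempt from simulated QC failures and annotation flags so that
#' the planted truth is recoverable by a correct filtering cascade; probes
#' methylated in PBL ("pbl_high") are disjoint from the planted set.
#'
#' @param config a [sim_config()].
#' @return list with elements:
#'   \describe{
#'     \item{cohort}{a [beta_cohort()]}
#'     \item{annotation}{data.frame (probe_id, gene_symbol, snp_flag,
#'       repeat_flag)}
#'     \item{truth}{list with `planted_probe_ids`, `pbl_high_probe_ids`,
#'       `failed_cells` (data.frame probe_id/sample_id), `flagged_probe_ids`}
#'   }
#' @export
generate_infinium_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    np <- config$n_probes
    probe_id <- sprintf("cg%07d", seq_len(np))

    tumor_samples <- sprintf("T%02d", seq_len(config$n_tumors))
    pbl_samples <- as.vector(t(outer(
      seq_len(config$n_pbl_subjects), seq_len(config$n_replicates),
      function(s, r) sprintf("PBL%d_rep%d", s, r))))
    samples <- c(tumor_samples, pbl_samples)
    n_t <- length(tumor_samples)
    n_p <- length(pbl_samples)

    groups <- setNames(c(rep("tumor", n_t), rep("pbl", n_p)), samples)
    replicate_of <- setNames(
      c(tumor_samples, rep(sprintf("PBL%d", seq_len(config$n_pbl_subjects)),
                           each = config$n_replicates)),
      samples)

    # probe roles: planted, pbl_high, background (disjoint)
    planted <- sample(probe_id, config$n_planted_markers)
    n_high <- round(config$pbl_high_fraction * np)
    pool <- setdiff(probe_id, planted)
    pbl_high <- sample(pool, min(n_high, length(pool)))

    beta <- matrix(rbeta_mp(np * length(samples), config$background_beta),
                   nrow = np, dimnames = list(probe_id, samples))
    if (length(pbl_high) > 0) {
      beta[pbl_high, ] <- rbeta_mp(length(pbl_high) * length(samples),
                                   config$pbl_high_beta)
    }
    if (length(planted) > 0) {
      beta[planted, tumor_samples] <- rbeta_mp(length(planted) * n_t,
                                               config$planted_tumor_beta)
      beta[planted, pbl_samples] <- rbeta_mp(length(planted) * n_p,
                                             config$planted_pbl_beta)
    }

    # detection p: failed cells uniform on (0.05, 1], others uniform [0, 0.05];
    # planted probes never fail (truth must survive QC)
    detp <- matrix(runif(np * length(samples), 0, 0.05),
                   nrow = np, dimnames = list(probe_id, samples))
    eligible <- setdiff(probe_id, planted)
    fail_mask <- matrix(runif(length(eligible) * length(samples)) <
                          config$fail_fraction,
                        nrow = length(eligible))
    idx <- which(fail_mask, arr.ind = TRUE)
    failed_cells <- data.frame(probe_id = eligible[idx[, 1]],
                               sample_id = samples[idx[, 2]],
                               stringsAsFactors = FALSE)
    if (nrow(failed_cells) > 0) {
      detp[cbind(match(failed_cells$probe_id, probe_id),
                 match(failed_cells$sample_id, samples))] <-
        runif(nrow(failed_cells), 0.05 + 1e-9, 1)
    }

    # gene symbols: ~probes_per_gene probes per locus, shuffled assignment
    n_genes <- max(1L, ceiling(np / config$probes_per_gene))
    gene_symbol <- sprintf("GENE%05d",
                           sample(rep_len(seq_len(n_genes), np)))
    snp_flag <- rep(FALSE, np)
    repeat_flag <- rep(FALSE, np)
    elig_idx <- match(eligible, probe_id)
    snp_flag[sample(elig_idx, round(config$snp_fraction * np))] <- TRUE
    repeat_flag[sample(elig_idx, round(config$repeat_fraction * np))] <- TRUE

    annotation <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                             snp_flag = snp_flag, repeat_flag = repeat_flag,
                             stringsAsFactors = FALSE)

    list(
      cohort = beta_cohort(beta, detp, groups, replicate_of),
      annotation = annotation,
      truth = list(planted_probe_ids = sort(planted),
                   pbl_high_probe_ids = sort(pbl_high),
                   failed_cells = failed_cells,
                   flagged_probe_ids = probe_id[snp_flag | repeat_flag])
    )
  })
}

#' Configuration for a simulated post-resection patient trajectory
#'
#' The latent quantity is tumor burden (arbitrary units): constant at
#' `baseline_burden` up to `surgery_week`, exponential decay at
#' `clearance_rate` per week after surgery, and exponential regrowth at
#' `regrowth_rate` per week after `relapse_week` (if any). Both observed
#' channels are driven by the same burden: CA-125 (U/ml) is
#' `ca125_floor + ca125_scale * burden`, perturbed by multiplicative
#' lognormal noise with coefficient of variation `ca125_noise_cv`; the
#' methylated-molecule count in the assayed serum volume is Poisson with
#' mean `molecule_scale * burden * volume_ml`. Defaults sketch an
#' advanced-stage patient sampled roughly every six weeks for ~90 weeks,
#' relapsing at week 48, with 100 ul of serum assayed per draw.
#'
#' @param baseline_burden burden at baseline (arbitrary units, > 0 for cases).
#' @param clearance_rate post-surgery burden decay, per week (>= 0).
#' @param relapse_week week of relapse, or `NA` for no relapse.
#' @param regrowth_rate post-relapse burden growth, per week (>= 0).
#' @param ca125_scale U/ml of CA-125 per burden unit.
#' @param ca125_floor baseline non-tumor CA-125 production, U/ml.
#' @param ca125_noise_cv lognormal coefficient of variation of CA-125.
#' @param molecule_scale methylated molecules per ml serum per burden unit.
#' @param draw_weeks sorted weeks (since baseline) of the serial draws.
#' @param serum_volume_ul serum-equivalent volume assayed per draw, ul.
#' @param surgery_week week of surgery (0 = baseline drawn at surgery).
#' @param seed integer seed.
#' @return A `trajectory_config` list, validated.
#' @export
trajectory_config <- function(baseline_burden = 1,
                              clearance_rate = 0.5,
                              relapse_week = 48,
                              regrowth_rate = 0.08,
                              ca125_scale = 300,
                              ca125_floor = 10,
                              ca125_noise_cv = 0.2,
                              molecule_scale = 200,
                              draw_weeks = seq(0, 90, by = 6),
                              serum_volume_ul = 100,
                              surgery_week = 0,
                              seed = 1L) {
  if (baseline_burden < 0) stop("baseline_burden must be >= 0", call. = FALSE)
  if (clearance_rate < 0 || regrowth_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  if (ca125_noise_cv < 0) stop("ca125_noise_cv must be >= 0", call. = FALSE)
  if (length(draw_weeks) == 0 || is.unsorted(draw_weeks, strictly = TRUE)) {
    stop("draw_weeks must be non-empty and strictly increasing", call. = FALSE)
  }
  if (serum_volume_ul <= 0) stop("serum_volume_ul must be > 0", call. = FALSE)
  cfg <- list(baseline_burden = baseline_burden,
              clearance_rate = clearance_rate,
              relapse_week = relapse_week,
              regrowth_rate = regrowth_rate,
              ca125_scale = ca125_scale,
              ca125_floor = ca125_floor,
              ca125_noise_cv = ca125_noise_cv,
              molecule_scale = molecule_scale,
              draw_weeks = draw_weeks,
              serum_volume_ul = serum_volume_ul,
              surgery_week = surgery_week,
              seed = as.integer(seed))
  class(cfg) <- "trajectory_config"
  cfg
}

# Piecewise-exponential burden curve; vectorized over weeks.
burden_at <- function(config, weeks) {
  b <- rep(config$baseline_burden, length(weeks))
  post <- weeks > config$surgery_week
  b[post] <- config$baseline_burden *
    exp(-config$clearance_rate * (weeks[post] - config$surgery_week))
  if (!is.na(config$relapse_week)) {
    rel <- weeks > config$relapse_week
    b_rel <- config$baseline_burden *
      exp(-config$clearance_rate * (config$relapse_week - config$surgery_week))
    b[rel] <- b_rel * exp(config$regrowth_rate *
                            (weeks[rel] - config$relapse_week))
  }
  b
}

#' Simulate a serial post-resection serum series for one patient
#'
#' @param config a [trajectory_config()].
#' @param patient_id identifier carried into the output.
#' @return A `patient_series` object: list with `patient_id`, `draws`
#'   (data.frame week, ca125, marker_count, marker_conc, true_burden),
#'   `surgery_week`, `relapse_week`, `baseline_is_presurgery`,
#'   `serum_volume_ul`.
#' @export
generate_patient_series <- function(config = trajectory_config(),
                                    patient_id = "P1") {
  stopifnot(inherits(config, "trajectory_config"))
  with_seed(config$seed, {
    wk <- config$draw_weeks
    burden <- burden_at(config, wk)
    vol_ml <- config$serum_volume_ul / 1000

    # lognormal noise with unit mean and the configured CV
    if (config$ca125_noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$ca125_noise_cv^2))
      noise <- rlnorm(length(wk), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else noise <- rep(1, length(wk))
    ca125 <- (config$ca125_floor + config$ca125_scale * burden) * noise

    count <- rpois(length(wk), config$molecule_scale * burden * vol_ml)
    conc <- count / vol_ml

    patient_series(
      patient_id = patient_id,
      draws = data.frame(week = wk, ca125 = ca125,
                         marker_count = count, marker_conc = conc,
                         true_burden = burden),
      surgery_week = config$surgery_week,
      relapse_week = config$relapse_week,
      baseline_is_presurgery = wk[1] <= config$surgery_week,
      serum_volume_ul = config$serum_volume_ul
    )
  })
}

#' Construct a patient series object
#'
#' @param patient_id identifier.
#' @param draws data.frame with at least `week`, `ca125`, `marker_conc`;
#'   weeks strictly increasing, values non-negative (NA allowed for missing).
#' @param surgery_week,relapse_week week of surgery / relapse (`NA` = none).
#' @param baseline_is_presurgery whether the first draw precedes surgery.
#' @param serum_volume_ul assayed serum volume per draw.
#' @return A `patient_series` object.
#' @export
patient_series <- function(patient_id, draws, surgery_week,
                           relapse_week = NA,
                           baseline_is_presurgery = TRUE,
                           serum_volume_ul = 100) {
  need <- c("week", "ca125", "marker_conc")
  if (!all(need %in% names(draws))) {
    stop("draws must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(draws$week, strictly = TRUE)) {
    stop("draw weeks must be strictly increasing", call. = FALSE)
  }
  if (any(draws$ca125 < 0, na.rm = TRUE) ||
      any(draws$marker_conc < 0, na.rm = TRUE)) {
    stop("ca125 and marker_conc must be non-negative", call. = FALSE)
  }
  structure(list(patient_id = patient_id, draws = draws,
                 surgery_week = surgery_week, relapse_week = relapse_week,
                 baseline_is_presurgery = baseline_is_presurgery,
                 serum_volume_ul = serum_volume_ul),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("patient_series %s: %d draws over weeks %g-%g (surgery wk %g%s)\n",
              x$patient_id, nrow(x$draws), min(x$draws$week),
              max(x$draws$week), x$surgery_week,
              if (is.na(x$relapse_week)) ", no relapse"
              else sprintf(", relapse wk %g", x$relapse_week)))
  invisible(x)
}

#' Simulate Digital MethyLight plates from a known concentration
#'
#' Molecules entering each plate are Poisson with mean
#' `concentration * volume_ml * detection_efficiency`; molecules land in
#' wells uniformly at random and a well is positive iff it received at least
#' one molecule. This is the generative model inverted by the
#' most-probable-number correction in [estimate_molecules()].
#'
#' @param concentration true methylated molecules per ml serum.
#' @param volume_ul serum-equivalent volume per plate, ul (default 100).
#' @param wells wells per plate (default 96).
#' @param n_plates number of plates for the sample.
#' @param detection_efficiency fraction of molecules detected (default 1;
#'   real bisulfite recovery is lossy).
#' @param sample_id identifier carried into the output.
#' @param seed integer seed.
#' @return A `digital_plate_set`: list with `sample_id`, `plates`
#'   (data.frame plate_id, wells_total, wells_positive, molecules_true),
#'   `volume_assayed_ul` (total across plates).
#' @export
generate_digital_plates <- function(concentration, volume_ul = 100,
                                    wells = 96L, n_plates = 1L,
                                    detection_efficiency = 1,
                                    sample_id = "S1", seed = NULL) {
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  if (wells < 1) stop("wells must be >= 1", call. = FALSE)
  if (detection_efficiency < 0 || detection_efficiency > 1) {
    stop("detection_efficiency must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    vol_ml <- volume_ul / 1000
    lambda <- concentration * vol_ml * detection_efficiency
    plates <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
      m <- rpois(1, lambda)
      pos <- if (m > 0) length(unique(sample.int(wells, m, replace = TRUE))) else 0L
      data.frame(plate_id = sprintf("plate%d", p), wells_total = as.integer(wells),
                 wells_positive = as.integer(pos), molecules_true = m)
    }))
    digital_plate_set(sample_id, plates,
                      volume_assayed_ul = volume_ul * n_plates)
  })
}

#' Construct a digital plate set
#'
#' @param sample_id identifier.
#' @param plates data.frame with `wells_total` and `wells_positive` per plate.
#' @param volume_assayed_ul total serum-equivalent volume across plates, ul.
#' @return A `digital_plate_set` object.
#' @export
digital_plate_set <- function(sample_id, plates, volume_assayed_ul) {
  if (!all(c("wells_total", "wells_positive") %in% names(plates))) {
    stop("plates must have wells_total and wells_positive", call. = FALSE)
  }
  if (any(plates$wells_positive < 0 | plates$wells_positive > plates$wells_total)) {
    stop("wells_positive must lie in [0, wells_total]", call. = FALSE)
  }
  if (volume_assayed_ul <= 0) stop("volume_assayed_ul must be > 0", call. = FALSE)
  structure(list(sample_id = sample_id, plates = plates,
                 volume_assayed_ul = volume_assayed_ul),
            class = "digital_plate_set")
}

#' Configuration for a simulated MethyLight verification panel
#'
#' Emulates the inputs of the MethyLight verification stage for a candidate
#' marker panel: per-marker design feasibility, amplification of the fully
#' methylated (M.SssI-treated) positive control, Ct values against excess PBL
#' DNA from control subjects, PMR values in control plasmas, and PMR values
#' in tumors. Counts default to a 15-marker panel in which 3 fail assay
#' design, 1 fails the M.SssI control, 3 are methylated in PBL, 7 more are
#' methylated in control plasma, and 1 survives to the tumor-positivity
#' check.
#'
#' @param n_markers panel size.
#' @param n_design_fail markers unsuitable for assay design.
#' @param n_mssi_fail designable markers failing the M.SssI control.
#' @param n_pbl_methylated markers methylated in control PBL (Ct < 35).
#' @param n_plasma_methylated markers showing PMR >= 5 in some control plasma.
#' @param n_pbl number of control PBL samples (default 2).
#' @param n_plasma number of control plasma samples (default 10).
#' @param n_tumors number of tumors for the positivity check (default 15).
#' @param seed integer seed.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_markers = 15L, n_design_fail = 3L,
                         n_mssi_fail = 1L, n_pbl_methylated = 3L,
                         n_plasma_methylated = 7L, n_pbl = 2L,
                         n_plasma = 10L, n_tumors = 15L, seed = 1L) {
  if (n_design_fail + n_mssi_fail + n_pbl_methylated + n_plasma_methylated >
      n_markers) {
    stop("engineered failure counts exceed panel size", call. = FALSE)
  }
  structure(list(n_markers = as.integer(n_markers),
                 n_design_fail = as.integer(n_design_fail),
                 n_mssi_fail = as.integer(n_mssi_fail),
                 n_pbl_methylated = as.integer(n_pbl_methylated),
                 n_plasma_methylated = as.integer(n_plasma_methylated),
                 n_pbl = as.integer(n_pbl), n_plasma = as.integer(n_plasma),
                 n_tumors = as.integer(n_tumors), seed = as.integer(seed)),
            class = "panel_config")
}

#' Simulate MethyLight verification-panel measurements
#'
#' Markers methylated in a control compartment draw low Ct (< 35) or high
#' PMR there; clean markers draw Ct above 35 or are undetected (`NA`), and
#' low PMR. Surviving markers show tumor PMR above 20 in every tumor.
#'
#' @param config a [panel_config()].
#' @return list with `markers` (data.frame marker_id, designable, mssi_ct,
#'   role), `pbl_ct` (data.frame marker_id, sample_id, ct; `NA` ct =
#'   undetected), `plasma_pmr` and `tumor_pmr` (data.frames marker_id,
#'   sample_id, pmr).
#' @export
generate_methylight_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, {
    ids <- sprintf("MK%02d", seq_len(config$n_markers))
    role <- rep("clean", config$n_markers)
    pool <- seq_len(config$n_markers)
    take <- function(n, what) {
      sel <- sample(pool, n)
      role[sel] <<- what
      pool <<- setdiff(pool, sel)
      sel
    }
    take(config$n_design_fail, "design_fail")
    take(config$n_mssi_fail, "mssi_fail")
    take(config$n_pbl_methylated, "pbl_methylated")
    take(config$n_plasma_methylated, "plasma_methylated")

    designable <- role != "design_fail"
    mssi_ct <- ifelse(!designable, NA_real_,
                      ifelse(role == "mssi_fail", NA_real_,
                             runif(config$n_markers, 24, 32)))

    pbl_ct <- expand.grid(marker_id = ids,
                          sample_id = sprintf("PBL%d", seq_len(config$n_pbl)),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pbl_ct$ct <- ifelse(pbl_ct$marker_id %in% ids[role == "pbl_methylated"],
                        runif(nrow(pbl_ct), 28, 34.5),
                        ifelse(runif(nrow(pbl_ct)) < 0.5,
                               runif(nrow(pbl_ct), 35.5, 45), NA_real_))

    plasma_pmr <- expand.grid(marker_id = ids,
                              sample_id = sprintf("PL%02d", seq_len(config$n_plasma)),
                              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    plasma_pmr$pmr <- ifelse(
      plasma_pmr$marker_id %in% ids[role == "plasma_methylated"] &
        stats::ave(seq_len(nrow(plasma_pmr)), plasma_pmr$marker_id,
                   FUN = seq_along) == 1,
      runif(nrow(plasma_pmr), 6, 40),      # at least one plasma over cutoff
      runif(nrow(plasma_pmr), 0, 2))

    tumor_pmr <- expand.grid(marker_id = ids,
                             sample_id = sprintf("TU%02d", seq_len(config$n_tumors)),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tumor_pmr$pmr <- runif(nrow(tumor_pmr), 25, 120)

    list(markers = data.frame(marker_id = ids, designable = designable,
                              mssi_ct = mssi_ct, role = role,
                              stringsAsFactors = FALSE),
         pbl_ct = pbl_ct, plasma_pmr = plasma_pmr, tumor_pmr = tumor_pmr)
  })
}
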