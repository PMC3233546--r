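#' Synthetic nine-patient serial serum table
#'
#' A SYNTHETIC stand-in for a longitudinal verification dataset: nine
#' ovarian cancer patients with serial post-resection serum draws carrying
#' paired CA-125 (U/ml) and methylation-marker (molecules/ml serum)
#' measurements. Six of the nine patients (#1, #2, #5, #14, #15, #17) are
#' constructed so that the sample Pearson correlation between the two
#' channels equals, exactly, 0.97, 0.81, 0.70, 0.97, 0.95 and 0.74
#' respectively; the remaining three (#8, #18, #21) have small correlations
#' that do not reach significance at alpha 0.05. CA-125 trajectories come
#' from the piecewise-exponential burden model of [generate_patient_series()];
#' the marker channel is then built by an exact-correlation (Gram-Schmidt)
#' construction, so the per-patient correlation structure is known by
#' construction rather than estimated. These are not the measurements of
#' any real patient.
#'
#' @param seed integer seed for the stochastic parts (CA-125 noise and the
#'   residual direction); the target correlations are exact for every seed.
#' @return list of nine [patient_series()] objects, named by patient id.
#' @export
synthetic_serial_table <- function(seed = 101L) {
  spec <- data.frame(
    patient_id = c("1", "2", "5", "8", "14", "15", "17", "18", "21"),
    n_follow = c(16L, 19L, 23L, 12L, 15L, 18L, 21L, 14L, 9L),
    target_r = c(0.97, 0.81, 0.70, 0.10, 0.97, 0.95, 0.74, -0.15, 0.12),
    relapse = c(48, 54, 60, 42, 48, 66, NA, 60, 36),
    stringsAsFactors = FALSE
  )
  out <- vector("list", nrow(spec))
  names(out) <- spec$patient_id
  for (i in seq_len(nrow(spec))) {
    n <- spec$n_follow[i]
    cfg <- trajectory_config(
      draw_weeks = seq(0, by = 6, length.out = n),
      relapse_week = spec$relapse[i],
      seed = seed + i
    )
    ps <- generate_patient_series(cfg, patient_id = spec$patient_id[i])
    x <- ps$draws$ca125
    y <- with_seed(seed + 100L + i,
                   exact_correlation_partner(x, spec$target_r[i]))
    # scale to a plausible molecules/ml range, strictly non-negative;
    # a positive affine map leaves the correlation untouched
    y <- 5 + 60 * (y - min(y))
    ps$draws$marker_conc <- y
    ps$draws$marker_count <- round(y * ps$serum_volume_ul / 1000)
    out[[i]] <- ps
  }
  out
}

# Build y with sample correlation to x exactly equal to r: project a random
# direction orthogonal to x, standardize both, and mix with weights
# (r, sqrt(1 - r^2)).
exact_correlation_partner <- function(x, r) {
  n <- length(x)
  stopifnot(n >= 3, abs(r) <= 1, stats::sd(x) > 0)
  repeat {
    e <- stats::rnorm(n)
    e_perp <- stats::residuals(stats::lm(e ~ x))
    if (stats::sd(e_perp) > 0) break
  }
  zx <- as.numeric(scale(x))
  ze <- as.numeric(scale(e_perp))
  r * zx + sqrt(1 - r^2) * ze
}
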