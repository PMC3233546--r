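#' Estimate molecules on one digital PCR plate
#'
#' `naive` counts one molecule per positive well. `poisson` applies the
#' most-probable-number correction `-N * ln(1 - k/N)` for N wells of which
#' k are positive, accounting for wells that received more than one
#' molecule under uniform random assignment. A fully positive plate
#' (k = N) carries no information about the upper tail and is an error
#' under the Poisson method.
#'
#' @param wells_positive k, positive wells (0..N).
#' @param wells_total N, wells on the plate (default 96).
#' @param method `"poisson"` (default) or `"naive"`.
#' @return estimated number of molecules loaded on the plate.
#' @export
estimate_molecules <- function(wells_positive, wells_total = 96L,
                               method = c("poisson", "naive")) {
  method <- match.arg(method)
  k <- wells_positive; n <- wells_total
  if (n < 1) stop("wells_total must be >= 1", call. = FALSE)
  if (k < 0 || k > n) {
    stop(sprintf("wells_positive (%d) must lie in [0, wells_total = %d]",
                 k, n), call. = FALSE)
  }
  if (method == "naive") return(as.numeric(k))
  if (k == n) {
    stop("all wells positive: plate saturated beyond Poisson estimation",
         call. = FALSE)
  }
  -n * log(1 - k / n)
}

# Saturation caveat: more than `hits_per_96` positive wells per 96 wells
# means multiple molecules per well are likely; threshold scales with plate
# size.
is_saturated <- function(wells_positive, wells_total, hits_per_96 = 15) {
  wells_positive > hits_per_96 * wells_total / 96
}

#' Quantify methylated molecules per ml serum for one sample
#'
#' Sums molecule estimates across the sample's plates (corrections are
#' applied per plate, since dilution into wells is per plate) and scales to
#' a per-ml concentration by `1000 / volume_assayed_ul`. The sample is
#' flagged saturated if any plate exceeds `saturation_hits` positive wells
#' per 96 (scaled to the plate size): such counts can under-represent the
#' true molecule number.
#'
#' @param plates a [digital_plate_set()].
#' @param method `"poisson"` (default) or `"naive"`, see
#'   [estimate_molecules()].
#' @param saturation_hits caveat threshold, positive wells per 96-well
#'   plate; default 15.
#' @return list (class `digital_quant`): `sample_id`, `molecules_detected`
#'   (raw positive wells summed), `molecules_estimated`, `concentration`
#'   (molecules per ml serum), `saturated`, `volume_assayed_ul`.
#' @export
quantify_sample <- function(plates, method = c("poisson", "naive"),
                            saturation_hits = 15) {
  method <- match.arg(method)
  stopifnot(inherits(plates, "digital_plate_set"))
  if (nrow(plates$plates) == 0) stop("no plates for sample", call. = FALSE)
  k <- plates$plates$wells_positive
  n <- plates$plates$wells_total
  est <- sum(vapply(seq_along(k),
                    function(i) estimate_molecules(k[i], n[i], method),
                    numeric(1)))
  structure(list(
    sample_id = plates$sample_id,
    molecules_detected = sum(k),
    molecules_estimated = est,
    concentration = est * 1000 / plates$volume_assayed_ul,
    saturated = any(is_saturated(k, n, saturation_hits)),
    volume_assayed_ul = plates$volume_assayed_ul
  ), class = "digital_quant")
}

#' @export
print.digital_quant <- function(x, ...) {
  cat(sprintf(
    "digital_quant %s: %d positive wells, %.2f molecules est., %.1f/ml%s\n",
    x$sample_id, x$molecules_detected, x$molecules_estimated,
    x$concentration, if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Positive/negative detection call for a quantified sample
#'
#' @param quant a `digital_quant` from [quantify_sample()].
#' @param min_molecules minimum raw detected molecules to call positive;
#'   default 1.
#' @return logical.
#' @export
detection_call <- function(quant, min_molecules = 1) {
  if (min_molecules < 1) stop("min_molecules must be >= 1", call. = FALSE)
  quant$molecules_detected >= min_molecules
}
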