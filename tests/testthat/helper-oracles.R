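# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementation.

# Full marker-selection cascade on raw matrices; returns the retained
# probe ids with their separation delta, sorted by delta desc / id asc.
brute_select <- function(beta, detp, groups, replicate_of, annotation,
                         alpha = 0.05, pbl_threshold = 0.2) {
  probes <- rownames(beta)
  samples <- colnames(beta)

  keep <- character(0)
  for (p in probes) {
    ok <- TRUE
    for (s in samples) if (detp[p, s] > alpha) ok <- FALSE
    if (ok) keep <- c(keep, p)
  }
  keep2 <- character(0)
  for (p in keep) {
    i <- which(annotation$probe_id == p)
    if (!annotation$snp_flag[i] && !annotation$repeat_flag[i]) {
      keep2 <- c(keep2, p)
    }
  }
  pbl_samples <- samples[groups[samples] == "pbl"]
  tumor_samples <- samples[groups[samples] == "tumor"]
  subjects <- unique(replicate_of[pbl_samples])
  pbl_avg <- matrix(NA_real_, nrow = length(keep2), ncol = length(subjects),
                    dimnames = list(keep2, subjects))
  for (p in keep2) for (sj in subjects) {
    cols <- pbl_samples[replicate_of[pbl_samples] == sj]
    tot <- 0
    for (cc in cols) tot <- tot + beta[p, cc]
    pbl_avg[p, sj] <- tot / length(cols)
  }
  keep3 <- character(0)
  for (p in keep2) {
    high <- FALSE
    for (sj in subjects) if (pbl_avg[p, sj] >= pbl_threshold) high <- TRUE
    if (!high) keep3 <- c(keep3, p)
  }
  out <- data.frame(probe_id = character(0), delta = numeric(0),
                    stringsAsFactors = FALSE)
  for (p in keep3) {
    t_low <- Inf
    for (s in tumor_samples) t_low <- min(t_low, beta[p, s])
    pbl_high <- -Inf
    for (sj in subjects) pbl_high <- max(pbl_high, pbl_avg[p, sj])
    d <- t_low - pbl_high
    if (d > 0) {
      out <- rbind(out, data.frame(probe_id = p, delta = d,
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(-out$delta, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Product-moment correlation and t test from first principles.
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, t = t, p = p)
}

# AUC by exhaustive pair counting with half credit for ties.
brute_auc <- function(cases, controls) {
  wins <- 0
  for (a in cases) for (b in controls) {
    if (a > b) wins <- wins + 1
    else if (a == b) wins <- wins + 0.5
  }
  wins / (length(cases) * length(controls))
}

# Small discovery cohort used across tests (fast but realistic structure).
small_sim <- function(seed, n_probes = 400L, n_planted = 20L) {
  sim_config(n_probes = n_probes, n_planted_markers = n_planted,
             fail_fraction = 0.005, seed = seed)
}

# Hand-built 4-sample toy cohort: 2 tumors, 1 PBL subject in duplicate.
toy_cohort <- function(beta_rows, detp_value = 0.01) {
  probes <- names(beta_rows)
  beta <- do.call(rbind, beta_rows)
  colnames(beta) <- c("T1", "T2", "PBL1_rep1", "PBL1_rep2")
  rownames(beta) <- probes
  detp <- matrix(detp_value, nrow = nrow(beta), ncol = 4,
                 dimnames = dimnames(beta))
  beta_cohort(beta, detp,
              c(T1 = "tumor", T2 = "tumor",
                PBL1_rep1 = "pbl", PBL1_rep2 = "pbl"),
              c(T1 = "T1", T2 = "T2",
                PBL1_rep1 = "PBL1", PBL1_rep2 = "PBL1"))
}
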