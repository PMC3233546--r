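test_that("detection QC removes exactly the probes that failed anywhere", {
  co <- toy_cohort(list(p1 = c(0.5, 0.6, 0.1, 0.1),
                        p2 = c(0.3, 0.4, 0.2, 0.2),
                        p3 = c(0.7, 0.8, 0.0, 0.0)),
                   detp_value = 0)
  res <- drop_failed_probes(co)
  expect_identical(rownames(res$cohort$beta), c("p1", "p2", "p3"))
  expect_length(res$report$removed_probe_ids, 0)

  # one failure in one of the samples condemns the probe
  co$detection_p["p2", "T2"] <- 0.06
  res <- drop_failed_probes(co)
  expect_identical(res$report$removed_probe_ids, "p2")
  expect_identical(rownames(res$cohort$beta), c("p1", "p3"))
})

test_that("engineered failures are removed exactly, verified by exhaustive scan", {
  set.seed(31)
  beta <- matrix(runif(10 * 4), nrow = 10,
                 dimnames = list(sprintf("p%02d", 1:10),
                                 c("T1", "T2", "PBL1_rep1", "PBL1_rep2")))
  detp <- matrix(runif(40, 0, 0.05), nrow = 10, dimnames = dimnames(beta))
  fails <- rbind(c(2, 1), c(5, 4), c(9, 2))
  detp[fails] <- c(0.06, 0.5, 0.99)
  co <- beta_cohort(beta, detp,
                    c(T1 = "tumor", T2 = "tumor",
                      PBL1_rep1 = "pbl", PBL1_rep2 = "pbl"))
  res <- drop_failed_probes(co)
  # oracle: exhaustive scan over all cells
  expected <- rownames(beta)[apply(detp, 1, function(r) any(r > 0.05))]
  expect_setequal(res$report$removed_probe_ids, expected)
  expect_setequal(res$report$removed_probe_ids, c("p02", "p05", "p09"))
})

test_that("SNP/repeat exclusion removes the union of flags and demands annotation", {
  co <- toy_cohort(setNames(
    lapply(1:20, function(i) runif(4)), sprintf("p%02d", 1:20)))
  ann <- data.frame(probe_id = sprintf("p%02d", 1:20),
                    gene_symbol = "G", snp_flag = FALSE, repeat_flag = FALSE,
                    stringsAsFactors = FALSE)
  # all flags false: identity
  res <- drop_annotated_probes(co, ann)
  expect_identical(rownames(res$cohort$beta), sprintf("p%02d", 1:20))

  # 4 SNP + 3 repeat + 1 flagged both = 7 removed (set union)
  ann$snp_flag[c(1, 2, 3, 4)] <- TRUE
  ann$repeat_flag[c(5, 6, 7)] <- TRUE
  ann$snp_flag[8] <- TRUE; ann$repeat_flag[8] <- TRUE
  res <- drop_annotated_probes(co, ann)
  expect_length(res$report$removed_probe_ids, 8)
  expect_setequal(res$report$removed_probe_ids, sprintf("p%02d", 1:8))

  # unannotated probe: explicit error, never a silent keep
  expect_error(drop_annotated_probes(co, ann[-1, ]), "unannotated")
})

test_that("replicate averaging takes arithmetic means and conservative detection p", {
  co <- toy_cohort(list(p1 = c(0.5, 0.6, 0.10, 0.30),
                        p2 = c(0.4, 0.4, 0.25, 0.25)))
  co$detection_p["p1", "PBL1_rep1"] <- 0.01
  co$detection_p["p1", "PBL1_rep2"] <- 0.04
  avg <- average_replicates(co)
  expect_identical(colnames(avg$beta), c("T1", "T2", "PBL1"))
  expect_equal(avg$beta["p1", "PBL1"], 0.20)
  expect_equal(avg$beta["p2", "PBL1"], 0.25)  # identical replicates
  expect_equal(avg$detection_p["p1", "PBL1"], 0.04)  # max over replicates
  expect_identical(avg$beta[, c("T1", "T2")], co$beta[, c("T1", "T2")])
})

test_that("two-subject replicate averaging matches hand-computed means", {
  beta <- matrix(c(0.5, 0.6, 0.10, 0.20, 0.02, 0.06,
                   0.4, 0.3, 0.30, 0.10, 0.40, 0.20),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"),
                                 c("T1", "T2", "PBL1_a", "PBL1_b",
                                   "PBL2_a", "PBL2_b")))
  detp <- matrix(0.01, 2, 6, dimnames = dimnames(beta))
  co <- beta_cohort(beta, detp,
                    setNames(c("tumor", "tumor", rep("pbl", 4)),
                             colnames(beta)),
                    setNames(c("T1", "T2", "PBL1", "PBL1", "PBL2", "PBL2"),
                             colnames(beta)))
  avg <- average_replicates(co)
  expect_identical(colnames(avg$beta), c("T1", "T2", "PBL1", "PBL2"))
  expect_equal(unname(avg$beta["p1", c("PBL1", "PBL2")]), c(0.15, 0.04))
  expect_equal(unname(avg$beta["p2", c("PBL1", "PBL2")]), c(0.20, 0.30))
})

test_that("a replicate group spanning tumor and PBL is rejected", {
  co <- toy_cohort(list(p1 = c(0.5, 0.6, 0.1, 0.1)))
  co$replicate_of["T2"] <- "PBL1"
  expect_error(average_replicates(co), "spans")
})

test_that("PBL filter applies the inclusive >= rule in any subject", {
  mk <- function(b1, b2) {
    beta <- matrix(c(0.5, 0.6, b1, b2), nrow = 1,
                   dimnames = list("p1", c("T1", "T2", "PBL1", "PBL2")))
    detp <- matrix(0.01, 1, 4, dimnames = dimnames(beta))
    beta_cohort(beta, detp,
                setNames(c("tumor", "tumor", "pbl", "pbl"), colnames(beta)))
  }
  expect_length(drop_pbl_methylated(mk(0.00, 0.00))$report$removed_probe_ids, 0)
  # exactly at the threshold: excluded (>= rule, not >)
  expect_identical(drop_pbl_methylated(mk(0.20, 0.01))$report$removed_probe_ids,
                   "p1")
  # any-subject rule: one subject below, one above
  expect_identical(drop_pbl_methylated(mk(0.19, 0.21))$report$removed_probe_ids,
                   "p1")
  # no PBL samples present
  beta <- matrix(0.5, 1, 2, dimnames = list("p1", c("T1", "T2")))
  co <- beta_cohort(beta, beta * 0,
                    c(T1 = "tumor", T2 = "tumor"))
  expect_error(drop_pbl_methylated(co), "no PBL")
})

test_that("separation ranking computes T_L - PBL_H and drops delta <= 0", {
  beta <- matrix(c(0.50, 0.60, 0.70, 0.10, 0.15,
                   0.30, 0.20, 0.90, 0.25, 0.10,
                   0.05, 0.06, 0.07, 0.01, 0.02,
                   0.00, 0.00, 0.00, 0.00, 0.00),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("A", "B", "C", "D"),
                                 c("T1", "T2", "T3", "PBL1", "PBL2")))
  detp <- matrix(0.01, 4, 5, dimnames = dimnames(beta))
  co <- beta_cohort(beta, detp,
                    setNames(c(rep("tumor", 3), "pbl", "pbl"),
                             colnames(beta)))
  rk <- rank_by_separation(co)
  expect_identical(rk$probe_id, c("A", "C"))       # B delta<0, D delta=0
  expect_equal(rk$delta, c(0.35, 0.03))
  expect_equal(rk$t_low, c(0.50, 0.05))
  expect_equal(rk$pbl_high, c(0.15, 0.02))
  expect_identical(rk$rank, 1:2)
})

test_that("ranking refuses missing beta values among survivors", {
  co <- toy_cohort(list(p1 = c(NA, 0.6, 0.1, 0.1)))
  expect_error(rank_by_separation(co), "missing beta")
})

test_that("top-marker selection truncates and optionally collapses genes", {
  rk <- data.frame(probe_id = c("a", "b", "c", "d"),
                   gene_symbol = c("G1", "G1", "G2", "G3"),
                   t_low = 0.9, pbl_high = 0.1,
                   delta = c(0.8, 0.7, 0.6, 0.5), rank = 1:4,
                   stringsAsFactors = FALSE)
  expect_identical(nrow(select_top_markers(rk, 10)), 4L)  # k > length
  expect_identical(select_top_markers(rk, 2)$probe_id, c("a", "b"))
  # unique genes: the rank-2 probe of gene G1 is skipped, ranks 1 and 3 kept
  got <- select_top_markers(rk, 2, unique_genes = TRUE)
  expect_identical(got$rank, c(1L, 3L))
})

test_that("k = 15 on a long ranked list returns 15 markers", {
  g <- generate_infinium_cohort(sim_config(n_probes = 1000L,
                                           n_planted_markers = 30L,
                                           seed = 8))
  sel <- select_markers(g$cohort, g$annotation, top_k = 15)
  expect_identical(nrow(sel$markers), 15L)
})

test_that("cascade matches an independent brute-force reimplementation", {
  for (s in c(1, 2, 3)) {
    g <- generate_infinium_cohort(sim_config(n_probes = 50L,
                                             n_planted_markers = 5L,
                                             fail_fraction = 0.01,
                                             seed = s))
    sel <- suppressWarnings(select_markers(g$cohort, g$annotation, top_k = 15))
    oracle <- brute_select(g$cohort$beta, g$cohort$detection_p,
                           g$cohort$groups, g$cohort$replicate_of,
                           g$annotation)
    expect_identical(sel$ranked$probe_id, oracle$probe_id)
    expect_equal(sel$ranked$delta, oracle$delta)
  }
})

test_that("stage reports reconcile and survivors shrink monotonically", {
  g <- generate_infinium_cohort(small_sim(17))
  sel <- select_markers(g$cohort, g$annotation, top_k = 15)
  f <- funnel_table(sel$reports)
  expect_equal(f$probes_out, f$probes_in - f$removed)
  # output of stage i feeds stage i+1
  expect_equal(f$probes_in[-1], f$probes_out[-nrow(f)])
  expect_true(all(diff(f$probes_out) <= 0))
})

test_that("permuting sample columns changes no output", {
  g <- generate_infinium_cohort(small_sim(19))
  sel1 <- select_markers(g$cohort, g$annotation, top_k = 15)
  perm <- sample(ncol(g$cohort$beta))
  co2 <- beta_cohort(g$cohort$beta[, perm], g$cohort$detection_p[, perm],
                     g$cohort$groups, g$cohort$replicate_of)
  sel2 <- select_markers(co2, g$annotation, top_k = 15)
  expect_identical(sel1$ranked$probe_id, sel2$ranked$probe_id)
  expect_equal(sel1$ranked$delta, sel2$ranked$delta)
  expect_equal(funnel_table(sel1$reports)$probes_out,
               funnel_table(sel2$reports)$probes_out)
})

test_that("planted markers are recovered and PBL-high probes never survive", {
  for (s in 1:20) {
    g <- generate_infinium_cohort(sim_config(n_probes = 300L,
                                             n_planted_markers = 15L,
                                             seed = 100 + s))
    sel <- select_markers(g$cohort, g$annotation, top_k = 15)
    expect_true(all(g$truth$planted_probe_ids %in% sel$ranked$probe_id))
    expect_true(all(sel$ranked$delta[match(g$truth$planted_probe_ids,
                                           sel$ranked$probe_id)] > 0))
    expect_length(intersect(g$truth$pbl_high_probe_ids,
                            rownames(sel$cohort$beta)), 0)
  }
})

test_that("group summaries report medians and quartiles, with misses flagged", {
  co <- toy_cohort(list(p1 = c(0.1, 0.2, 0.3, 0.4)))
  s <- summarize_group_distributions(list(main = co), "p1")
  tum <- s[s$group == "tumor", ]
  expect_equal(tum$median, 0.15)
  expect_identical(tum$n, 2L)
  # even-count median across four values
  beta <- matrix(c(0.1, 0.2, 0.3, 0.4), nrow = 1,
                 dimnames = list("p1", c("T1", "T2", "T3", "T4")))
  co4 <- beta_cohort(beta, beta * 0, setNames(rep("tumor", 4), colnames(beta)))
  s4 <- summarize_group_distributions(list(m = co4), "p1")
  expect_equal(s4$median, 0.25)
  # absent marker: missing summary, not an error
  sm <- summarize_group_distributions(list(m = co4), c("p1", "nope"))
  expect_true(all(is.na(sm$median[sm$marker_id == "nope"])))
  expect_identical(sm$n[sm$marker_id == "nope"], 0L)
})

test_that("discovery and replication cohorts from one config agree in medians", {
  cfg1 <- sim_config(n_probes = 500L, n_planted_markers = 20L, seed = 301)
  cfg2 <- sim_config(n_probes = 500L, n_planted_markers = 20L, seed = 302)
  g1 <- generate_infinium_cohort(cfg1)
  g2 <- generate_infinium_cohort(cfg2)
  # planted probe ids differ between seeds; compare group-level medians of
  # each cohort's own planted set, which share the generating distribution
  tum1 <- names(g1$cohort$groups)[g1$cohort$groups == "tumor"]
  tum2 <- names(g2$cohort$groups)[g2$cohort$groups == "tumor"]
  m1 <- apply(g1$cohort$beta[g1$truth$planted_probe_ids, tum1], 1, median)
  m2 <- apply(g2$cohort$beta[g2$truth$planted_probe_ids, tum2], 1, median)
  se <- sqrt(stats::var(m1) / length(m1) + stats::var(m2) / length(m2))
  expect_lt(abs(mean(m1) - mean(m2)), 3 * se)
})
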