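test_that("sim_config validates its arguments", {
  expect_s3_class(sim_config(), "tmt_sim_config")
  expect_error(sim_config(n_spikein = 300, n_proteins = 100), "n_spikein")
  expect_error(sim_config(missing_rate_random = 1.5), "missing_rate_random")
  expect_error(sim_config(spike_concentrations = c(1, 2)), "per condition")
  ## infeasible allocation: 4 x 2 + 2 refs = 10 > 9 channels
  expect_error(sim_config(channels_per_run = 9), "channels")
})

test_that("allocate_design produces the requested layout", {
  ann <- allocate_design(sim_config(seed = 5))
  expect_equal(nrow(ann), 15 * 10)  # 15 runs x 10 channels
  perrun <- table(ann$Run)
  expect_true(all(perrun == 10))
  ## 2 refs + 4x2 endogenous per run
  expect_equal(sum(ann$Condition == "Norm"), 2 * 15)
  ## allocation constant across techreps within a mixture
  a1 <- ann[ann$Run == "Mixture1_Rep1", c("Channel", "Condition")]
  a2 <- ann[ann$Run == "Mixture1_Rep2", c("Channel", "Condition")]
  expect_equal(a1$Condition[order(a1$Channel)], a2$Condition[order(a2$Channel)])

  ## unbalanced per-mixture counts honored
  B <- matrix(c(3, 2, 2, 2,
                2, 3, 2, 1), 2, 4, byrow = TRUE)
  cfgu <- sim_config(M = 2, T = 1, B = B, n_reference = 1, seed = 6)
  annu <- allocate_design(cfgu)
  t1 <- table(annu$Condition[annu$Mixture == "Mixture1"])
  expect_equal(as.vector(t1[c("1", "0.667", "0.5", "0.125")]), c(3, 2, 2, 2))
  t2 <- table(annu$Condition[annu$Mixture == "Mixture2"])
  expect_equal(as.vector(t2[c("1", "0.667", "0.5", "0.125")]), c(2, 3, 2, 1))
})

test_that("true fold changes reproduce the concentration ratios", {
  tf <- true_fold_changes(sim_config())
  get <- function(lb) tf$true_FC[tf$Label == lb]
  expect_equal(get("1/0.5"), 2)        # 500 / 250
  expect_equal(get("0.5/0.125"), 4)    # 250 / 62.5
  expect_equal(get("1/0.125"), 8)      # 500 / 62.5
  expect_equal(get("0.667/0.125"), 5.328)  # 333 / 62.5
  expect_equal(get("1/0.667"), 500 / 333)
  expect_equal(get("0.667/0.5"), 333 / 250)
})

test_that("noiseless two-condition spike-in recovers log2FC exactly", {
  cfg <- sim_config(M = 1, T = 1, conditions = c("hi", "lo"),
                    spike_concentrations = c(1, 0.5), B = 2, n_reference = 0,
                    channels_per_run = 4, n_proteins = 3, n_spikein = 3,
                    features_per_protein = 2, sigma_channel_noise = 0,
                    sigma_run = 0, missing_rate_random = 0,
                    mnar_threshold = -Inf, seed = 8)
  sim <- simulate_controlled_mixture(cfg)
  x <- merge(sim$psm, sim$annotation, by = c("Run", "Channel"))
  lg <- log2(x$Intensity)
  d <- tapply(lg, list(x$PeptideIon, x$Condition), mean)
  expect_equal(unname(d[, "hi"] - d[, "lo"]), rep(1, nrow(d)))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_proteins = 8, n_spikein = 1, M = 2, T = 2, seed = 9)
  s1 <- simulate_controlled_mixture(cfg)
  s2 <- simulate_controlled_mixture(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_controlled_mixture(sim_config(n_proteins = 8, n_spikein = 1,
                                               M = 2, T = 2, seed = 10))
  expect_false(identical(s1$psm$Intensity, s3$psm$Intensity))
})

test_that("empirical spike log2FC and missingness rate match the configuration", {
  cfg <- sim_config(n_proteins = 100, n_spikein = 100, M = 2, T = 1,
                    missing_rate_random = 0, mnar_threshold = -Inf,
                    sigma_channel_noise = 0.2, seed = 11)
  sim <- simulate_controlled_mixture(cfg)
  x <- merge(sim$psm, sim$annotation, by = c("Run", "Channel"))
  lg <- log2(x$Intensity)
  prot_fc <- tapply(lg, list(x$ProteinName, x$Condition), mean)
  est <- prot_fc[, "1"] - prot_fc[, "0.5"]
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 3 * se + 1e-9)

  ## MCAR rate within binomial tolerance (MNAR disabled)
  cfg2 <- sim_config(n_proteins = 60, n_spikein = 0, M = 2, T = 1,
                     missing_rate_random = 0.2, mnar_threshold = -Inf,
                     seed = 12)
  sim2 <- simulate_controlled_mixture(cfg2)
  fr <- unique(sim2$psm[, c("PeptideIon", "Run")])
  miss_fr <- tapply(is.na(sim2$psm$Intensity),
                    paste(sim2$psm$PeptideIon, sim2$psm$Run), all)
  phat <- mean(miss_fr)
  n <- length(miss_fr)
  expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("add_biological_variation follows the subject-level protocol", {
  ann <- make_annotation(M = 2, T = 3, conditions = c("A", "B"), B = 2,
                         n_ref = 1)
  pst <- make_summaries(ann, c("P1", "P2"), function(cond, run, bio) 10)

  expect_error(add_biological_variation(pst, -0.1), "nonnegative")
  expect_identical(add_biological_variation(pst, 0), pst)

  z <- add_biological_variation(pst, 0.2, seed = 13)
  eps <- z$Abundance - pst$Abundance
  ## identical shift for all techreps of a subject, per protein
  key <- paste(z$Protein, z$Mixture, z$Condition, z$BioReplicate)
  endo <- z$Condition != "Norm"
  pershift <- tapply(eps[endo], key[endo], function(v) max(v) - min(v))
  expect_true(all(pershift < 1e-12))
  ## reference channels untouched
  expect_true(all(eps[!endo] == 0))
  ## distinct subjects get distinct draws
  expect_gt(length(unique(round(eps[endo], 10))), 4)

  ## 10^4 draws at sigma_s = 0.2: sample SD in [0.19, 0.21]
  annb <- make_annotation(M = 1, T = 1, conditions = c("A", "B"), B = 5)
  pstb <- make_summaries(annb, sprintf("Q%04d", 1:1000),
                         function(cond, run, bio) 0)
  zb <- add_biological_variation(pstb, 0.2, seed = 14)
  expect_gt(sd(zb$Abundance), 0.19)
  expect_lt(sd(zb$Abundance), 0.21)
})

test_that("simulate_protein_summaries carries truth and respects spikes", {
  cfg <- sim_config(n_proteins = 12, n_spikein = 3, n_reference = 0,
                    channels_per_run = 8, M = 3, T = 2, seed = 15)
  sim <- simulate_protein_summaries(cfg, sigma_resid = 0.05)
  expect_equal(nrow(sim$summaries), 12 * 3 * 2 * 8)
  expect_equal(sum(sim$truth$proteins$Spike), 3)
  fc <- sim$truth$fold_changes
  expect_equal(sort(unique(fc$Label)), sort(true_fold_changes(cfg)$Label))
  expect_true(all(fc$true_log2FC[!(fc$Protein %in%
    sim$truth$proteins$Protein[sim$truth$proteins$Spike])] == 0))
  ## spike condition means separated by the configured log2FC
  s <- sim$summaries[sim$summaries$Protein == "P0001", ]
  cm <- tapply(s$Abundance, s$Condition, mean)
  expect_equal(unname(cm["1"] - cm["0.125"]), 3, tolerance = 0.2)
})
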