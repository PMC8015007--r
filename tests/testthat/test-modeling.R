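design_of <- function(ann) experiment_design(ann)

test_that("choose_model follows the design", {
  expect_equal(choose_model(design_of(make_annotation(M = 5, T = 3)))$label,
               "full")
  expect_equal(choose_model(design_of(make_annotation(M = 1, T = 1)))$label,
               "single_run")
  expect_equal(choose_model(design_of(make_annotation(M = 3, T = 1)))$label,
               "multi_mixture")
  expect_equal(choose_model(design_of(make_annotation(M = 1, T = 3)))$label,
               "single_mixture_techrep")
})

test_that("noiseless balanced single-run fit recovers the condition difference exactly", {
  ann <- make_annotation(M = 1, T = 1, conditions = c("A", "B"), B = 3)
  pst <- make_summaries(ann, "P1", function(cond, run, bio) {
    ifelse(cond == "A", 5, 7)
  })
  fit <- fit_protein(pst, choose_model(design_of(ann)))
  expect_true(fit$converged)
  expect_equal(fit$model_used, "single_run")
  expect_equal(unname(fit$coef["B"] - fit$coef["A"]), 2)
  expect_equal(fit$s2, 0)
})

test_that("REML variance components match closed-form balanced ANOVA estimators", {
  set.seed(31)
  ## balanced one-way random layout realized as M=1, T=3 with subjects
  ann <- make_annotation(M = 1, T = 3, conditions = c("A", "B"), B = 5)
  subj <- unique(ann$BioReplicate[ann$Condition != "Norm"])
  for (rep in 1:3) {
    sub_eff <- setNames(rnorm(length(subj), 0, 0.5), subj)
    pst <- make_summaries(ann, "P1", function(cond, run, bio) {
      ifelse(cond == "A", 10, 11) + sub_eff[bio] + rnorm(length(cond), 0, 0.3)
    })
    ## pure one-way random-effects layout: subject is the only random term
    spec1 <- list(label = "single_mixture_techrep",
                  has_mixture_effect = FALSE, has_techrep_effect = FALSE,
                  has_subject_effect = TRUE)
    fit <- fit_protein(pst, spec1)
    expect_equal(fit$terms, "Subject")
    d <- pst[pst$Condition != "Norm", ]
    ## method-of-moments estimators from the classical nested ANOVA
    ms <- lapply(split(d, d$BioReplicate), function(g) g$Abundance)
    k <- length(ms); n <- 3
    msw <- sum(vapply(ms, function(v) sum((v - mean(v))^2), numeric(1))) /
      (k * (n - 1))
    gm <- vapply(ms, mean, numeric(1))
    cond_of <- vapply(split(d$Condition, d$BioReplicate), `[`, character(1), 1)
    ssb <- sum(vapply(split(gm, cond_of), function(v) {
      sum((v - mean(v))^2)
    }, numeric(1)))
    msb <- n * ssb / (k - 2)
    sS2 <- max((msb - msw) / n, 0)
    expect_equal(unname(fit$varcomp[grep("Subject", names(fit$varcomp))]),
                 sS2, tolerance = 1e-6)
    expect_equal(fit$s2, msw, tolerance = 1e-6)
  }
})

test_that("Satterthwaite df is exact in the balanced subject design", {
  set.seed(32)
  ann <- make_annotation(M = 1, T = 3, conditions = c("A", "B"), B = 8)
  subj <- unique(ann$BioReplicate[ann$Condition != "Norm"])
  sub_eff <- setNames(rnorm(length(subj), 0, 0.3), subj)
  pst <- make_summaries(ann, "P1", function(cond, run, bio) {
    ifelse(cond == "A", 0, 1) + sub_eff[bio] + rnorm(length(cond), 0, 0.2)
  })
  spec1 <- list(label = "single_mixture_techrep",
                has_mixture_effect = FALSE, has_techrep_effect = FALSE,
                has_subject_effect = TRUE)
  fit <- fit_protein(pst, spec1)
  res <- test_contrast(fit, c(A = 1, B = -1))
  ## between-subject stratum df = n_subjects - n_conditions = 14
  expect_equal(res$DF, 14, tolerance = 1e-2)
  ## and the estimate equals the difference of condition means
  d <- pst[pst$Condition != "Norm", ]
  cm <- tapply(d$Abundance, d$Condition, mean)
  expect_equal(res$log2FC, unname(cm["A"] - cm["B"]), tolerance = 1e-8)
})

test_that("balanced-design equivalence: full-model contrast equals difference of condition means", {
  set.seed(33)
  ann <- make_annotation(M = 5, T = 3, conditions = c("A", "B", "C", "D"),
                         B = 2)
  subj <- unique(ann$BioReplicate[ann$Condition != "Norm"])
  mix <- unique(ann$Mixture)
  runs <- unique(ann$Run)
  for (rep in 1:3) {
    sub_eff <- setNames(rnorm(length(subj), 0, 0.2), subj)
    mix_eff <- setNames(rnorm(length(mix), 0, 0.3), mix)
    run_eff <- setNames(rnorm(length(runs), 0, 0.15), runs)
    pst <- make_summaries(ann, "P1", function(cond, run, bio) {
      base <- c(A = 10, B = 10.5, C = 9.5, D = 12)[cond]
      mr <- sub("_R[0-9]+$", "", run)
      base + mix_eff[mr] + run_eff[run] + sub_eff[bio] +
        rnorm(length(cond), 0, 0.2)
    })
    fit <- fit_protein(pst, choose_model(design_of(ann)))
    d <- pst[pst$Condition != "Norm", ]
    cm <- tapply(d$Abundance, d$Condition, mean)
    for (pair in list(c("A", "B"), c("C", "D"), c("A", "D"))) {
      ct <- setNames(c(1, -1), pair)
      res <- test_contrast(fit, ct)
      expect_equal(res$log2FC, unname(cm[pair[1]] - cm[pair[2]]),
                   tolerance = 1e-8)
    }
  }
})

test_that("per-protein reduction drops random terms without replication", {
  set.seed(34)
  ann <- make_annotation(M = 3, T = 1, conditions = c("A", "B"), B = 3)
  pst <- make_summaries(ann, "P1", function(cond, run, bio) {
    ifelse(cond == "A", 10, 11) + rnorm(length(cond), 0, 0.2)
  })
  ## protein observed in one mixture only: Mixture term dropped
  pst1 <- pst[pst$Mixture == "M1", ]
  fit <- fit_protein(pst1, choose_model(design_of(ann)))
  expect_false("Mixture" %in% fit$terms)
  expect_true(fit$converged)
})

test_that("fit_protein propagates issue codes", {
  ann <- make_annotation(M = 1, T = 1, conditions = c("A", "B"), B = 2)
  pst <- make_summaries(ann, "P1", function(cond, run, bio) 10)
  spec <- choose_model(design_of(ann))

  one <- pst[pst$Condition == "A", ]
  expect_equal(fit_protein(one, spec)$issue, "oneConditionMissing")

  none <- pst
  none$Abundance <- NA_real_
  expect_equal(fit_protein(none, spec)$issue, "completeMissing")

  res <- test_contrast(fit_protein(one, spec), c(A = 1, B = -1))
  expect_equal(res$issue, "oneConditionMissing")
  expect_true(is.na(res$pvalue))
})

test_that("estimate_eb_prior matches moment-matching theory and the limma oracle", {
  ## zero excess dispersion: d0 = Inf with the log-scale bias correction
  s2 <- rep(2, 50); df <- rep(10, 50)
  pr <- estimate_eb_prior(s2, df)
  expect_equal(pr$d0, Inf)
  expect_equal(pr$s0_sq, exp(log(2) - digamma(5) + log(5)))

  ## single protein: identity prior (no moderation)
  pr1 <- estimate_eb_prior(3, 10)
  expect_equal(pr1$d0, 0)
  m <- moderate(5, 8, pr1)
  expect_equal(m$s2_mod, 5)
  expect_equal(m$df_mod, 8)

  ## Monte-Carlo recovery of a known scaled inverse-chi-square ensemble
  set.seed(35)
  d0 <- 8; s0 <- 0.05; df <- 12; n <- 5000
  truevar <- d0 * s0 / stats::rchisq(n, d0)
  s2obs <- truevar * stats::rchisq(n, df) / df
  pr <- estimate_eb_prior(s2obs, rep(df, n))
  expect_lt(abs(pr$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.15)

  skip_if_not_installed("limma")
  fd <- limma::fitFDist(s2obs, df1 = rep(df, n))
  expect_equal(pr$d0, fd$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, fd$scale, tolerance = 1e-6)
})

test_that("moderate follows the shrinkage formula and its limits", {
  expect_equal(moderate(2, 3, list(d0 = 0, s0_sq = NA))$s2_mod, 2)
  expect_equal(moderate(2, 3, list(d0 = Inf, s0_sq = 1))$s2_mod, 1)
  expect_equal(moderate(2, 3, list(d0 = Inf, s0_sq = 1))$df_mod, 1e6)
  m <- moderate(2, 3, list(d0 = 3, s0_sq = 1))
  expect_equal(m$s2_mod, 1.5)
  expect_equal(m$df_mod, 6)
  ## moderation always lies between the estimate and the prior
  set.seed(36)
  for (i in 1:50) {
    s2 <- stats::rchisq(1, 5); d0 <- stats::rchisq(1, 4); s0 <- stats::rchisq(1, 3)
    sm <- moderate(s2, 7, list(d0 = d0, s0_sq = s0))$s2_mod
    expect_gte(sm, min(s2, s0) - 1e-12)
    expect_lte(sm, max(s2, s0) + 1e-12)
  }
})

test_that("adjust_bh matches hand values and the sort-based oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  set.seed(37)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
  ## monotone nondecreasing in p
  p <- sort(runif(100))
  expect_true(all(diff(adjust_bh(p)) >= -1e-12))
})

test_that("test_contrast validates weights and detects missing conditions", {
  ann <- make_annotation(M = 1, T = 1, conditions = c("A", "B", "C"), B = 3)
  set.seed(38)
  pst <- make_summaries(ann, "P1", function(cond, run, bio) {
    rnorm(length(cond), 10, 0.1)
  })
  fit <- fit_protein(pst, choose_model(design_of(ann)))
  expect_error(test_contrast(fit, c(A = 1, B = -0.5)), "sum to 0")
  res <- test_contrast(fit, c(A = 1, D = -1))
  expect_equal(res$issue, "oneConditionMissing")
})

test_that("spike-in contrast estimates are unbiased at n = 30 channels per condition", {
  set.seed(39)
  ## 5 mixtures x 3 techreps, B = 2 -> 30 channels per condition
  cfg <- sim_config(n_proteins = 40, n_spikein = 40, n_reference = 0,
                    channels_per_run = 8, conditions = c("A", "B", "C", "D"),
                    spike_concentrations = c(2, 1, 1, 1), seed = 40)
  sim <- simulate_protein_summaries(cfg,
                                    spike_log2fc = c(A = 1, B = 0, C = 0, D = 0))
  pst <- add_biological_variation(sim$summaries, sigma_s = 0.1, seed = 41)
  cm <- make_all_pairs_contrasts(c("A", "B"))
  res <- group_comparison(pst, cm)
  expect_lt(abs(mean(res$log2FC) - 1), 0.05)
})

test_that("group_comparison orchestrates labels, testability and BH denominators", {
  set.seed(42)
  cfg <- sim_config(n_proteins = 25, n_spikein = 0, n_reference = 0,
                    channels_per_run = 8, M = 2, T = 2, seed = 43)
  sim <- simulate_protein_summaries(cfg)
  pst <- add_biological_variation(sim$summaries, sigma_s = 0.1, seed = 44)
  ## make one protein untestable: single summary in every condition but one
  drop <- pst$Protein == "P0001" &
    !(pst$Run == "Mixture1_Rep1" & pst$Channel %in% unique(pst$Channel)[1:3])
  pst$Abundance[drop] <- NA
  cm <- make_all_pairs_contrasts(c("1", "0.667", "0.5", "0.125"))
  res <- group_comparison(pst, cm)
  expect_equal(nrow(res), 25 * 6)
  expect_equal(length(unique(res$Label)), 6)
  fits <- attr(res, "fits")
  expect_false(fits$Testable[fits$Protein == "P0001"])
  ## untestable protein excluded from the BH denominator
  lab <- res[res$Label == "1/0.5", ]
  expect_true(is.na(lab$pvalue[lab$Protein == "P0001"]))
  manual <- adjust_bh(lab$pvalue)
  expect_equal(lab$adj.pvalue, manual)
  expect_true(all(lab$adj.pvalue >= lab$pvalue - 1e-12, na.rm = TRUE))
  ## empty input
  empty <- group_comparison(pst[0, ], cm)
  expect_equal(nrow(empty), 0)
})
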