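## Fixture builders and independent oracles shared across the test files.
## All fixtures are generated in code; nothing is read from disk except
## files the tests themselves write to tempdir().

## ---- fixtures ----------------------------------------------------------

## Canonical PSM record rows from compact arguments.
make_records <- function(protein, ion, spectrum, run, channel, intensity,
                         fraction = NA_character_, interference = NA_real_) {
  data.frame(ProteinName = protein, PeptideIon = ion, SpectrumId = spectrum,
             Run = run, Fraction = fraction, Channel = channel,
             Intensity = intensity, Interference = interference,
             stringsAsFactors = FALSE)
}

## Small annotation: M mixtures x T techreps, conditions each with B
## bioreps, plus n_ref reference channels, assigned to channels in order.
make_annotation <- function(M = 1, T = 1, conditions = c("A", "B"), B = 2,
                            n_ref = 0) {
  C <- length(conditions)
  channels <- tmtstat::tmt_channels(max(C * B + n_ref, 2))[seq_len(C * B + n_ref)]
  rows <- list()
  for (m in seq_len(M)) {
    cond <- c(rep("Norm", n_ref), rep(conditions, each = B))
    bio <- c(rep("Norm", n_ref),
             paste0("M", m, "_", rep(conditions, each = B), "_",
                    rep(seq_len(B), C)))
    for (t in seq_len(T)) {
      rows[[length(rows) + 1L]] <- data.frame(
        Run = sprintf("M%d_R%d", m, t), Channel = channels,
        Condition = cond, BioReplicate = bio,
        Mixture = paste0("M", m), TechRepMixture = as.character(t),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Protein-summary rows directly from an annotation and an abundance
## generator function(condition, run, bioreplicate) -> numeric.
make_summaries <- function(ann, proteins, fun) {
  do.call(rbind, lapply(proteins, function(p) {
    data.frame(Protein = p, Mixture = ann$Mixture,
               TechRepMixture = ann$TechRepMixture, Run = ann$Run,
               Channel = ann$Channel, Condition = ann$Condition,
               BioReplicate = ann$BioReplicate,
               Abundance = fun(ann$Condition, ann$Run, ann$BioReplicate),
               NumFeatures = 1L, stringsAsFactors = FALSE)
  }))
}

## ---- independent oracles ----------------------------------------------

## Median polish oracle: stats::medpolish (independent sweep
## implementation), same convergence semantics.
oracle_medpolish <- function(x, tol = 1e-4, max_iter = 100L) {
  mp <- suppressWarnings(stats::medpolish(x, eps = tol, maxiter = max_iter, na.rm = TRUE,
                         trace.iter = FALSE))
  list(overall = mp$overall, row = mp$row, col = mp$col,
       residuals = mp$residuals)
}

## BH oracle: sort-based reference implementation via stats::p.adjust.
oracle_bh <- function(p) stats::p.adjust(p, method = "BH")

## AUC oracle: explicit pair counting (Mann-Whitney with 0.5 for ties).
oracle_auc <- function(score_pos, score_neg) {
  wins <- 0
  for (sp in score_pos) {
    wins <- wins + sum(sp > score_neg) + 0.5 * sum(sp == score_neg)
  }
  wins / (length(score_pos) * length(score_neg))
}

## Balanced one-way random-effects ANOVA method-of-moments estimators.
oracle_oneway_varcomp <- function(y, group) {
  k <- length(unique(group))
  n <- length(y) / k
  gm <- tapply(y, group, mean)
  msb <- n * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[group])^2) / (k * (n - 1))
  c(sigma_between2 = max((msb - msw) / n, 0), sigma2 = msw)
}
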