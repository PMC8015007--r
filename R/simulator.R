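## Synthetic TMT experiments with known ground truth: a PSM-level
## controlled-mixture generator (UPS1-style spike-in dilution series with a
## pooled reference channel) and a summary-level biological-variation
## augmentation Z = Y + eps, eps ~ N(0, sigma_s^2).

#' Simulation configuration
#'
#' Defaults describe the controlled-mixture benchmark: 5 mixtures, 3
#' technical replicate runs each, a TMT 10-plex with 4 spike-in
#' concentrations (500, 333, 250, 62.5 fmol, i.e. 1/0.667/0.5/0.125 of the
#' highest amount) in duplicate plus two pooled-reference channels.
#'
#' @param M Number of mixtures.
#' @param T Technical replicate runs per mixture.
#' @param conditions Condition labels, one per spike-in concentration.
#' @param spike_concentrations Positive amounts (one per condition) whose
#'   ratios are the true fold changes.
#' @param B Biological replicates per condition per mixture; a scalar, or
#'   an `M x C` matrix for unbalanced designs.
#' @param n_reference Reference (pooled) channels per run.
#' @param channels_per_run Number of reporter channels in the plex.
#' @param n_proteins,n_spikein Total and differentially abundant protein
#'   counts.
#' @param features_per_protein Either a fixed count or a list
#'   `list(type = "poisson", mean = m)` giving `1 + Poisson(m - 1)`
#'   features per protein.
#' @param base_mean,base_sd Mean and SD of per-protein baseline log2
#'   abundance.
#' @param sigma_feature SD of per-feature (ionization) effects on the log2
#'   scale.
#' @param sigma_run SD of per-run additive shifts (log2 scale).
#' @param sigma_channel_noise SD of per-cell measurement noise (log2
#'   scale).
#' @param missing_rate_random Probability that a feature is entirely
#'   missing in a run (failed identification), completely at random.
#' @param mnar_threshold log2 intensity below which cells are left-censored
#'   (`-Inf` disables); `mnar_prob_scale > 0` instead censors
#'   probabilistically with a logistic probability of that scale.
#' @param reference_pool Reference channels carry the pooled mean of the
#'   condition amounts? (default `TRUE`)
#' @param seed Integer seed; every generator call is reproducible given the
#'   config.
#' @return A validated `tmt_sim_config` list.
#' @export
sim_config <- function(M = 5, T = 3,
                       conditions = c("1", "0.667", "0.5", "0.125"),
                       spike_concentrations = c(500, 333, 250, 62.5),
                       B = 2, n_reference = 2, channels_per_run = 10,
                       n_proteins = 200, n_spikein = 2,
                       features_per_protein = list(type = "poisson", mean = 5),
                       base_mean = 16, base_sd = 1.5,
                       sigma_feature = 1, sigma_run = 0.5,
                       sigma_channel_noise = 0.2,
                       missing_rate_random = 0.1,
                       mnar_threshold = 12, mnar_prob_scale = 0,
                       reference_pool = TRUE, seed = 1L) {
  cfg <- list(M = M, T = T, conditions = as.character(conditions),
              spike_concentrations = spike_concentrations, B = B,
              n_reference = n_reference, channels_per_run = channels_per_run,
              n_proteins = n_proteins, n_spikein = n_spikein,
              features_per_protein = features_per_protein,
              base_mean = base_mean, base_sd = base_sd,
              sigma_feature = sigma_feature, sigma_run = sigma_run,
              sigma_channel_noise = sigma_channel_noise,
              missing_rate_random = missing_rate_random,
              mnar_threshold = mnar_threshold,
              mnar_prob_scale = mnar_prob_scale,
              reference_pool = reference_pool, seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A simulation configuration list.
#' @export
validate_sim_config <- function(cfg) {
  C <- length(cfg$conditions)
  if (length(cfg$spike_concentrations) != C) {
    stop("validation error: one spike concentration per condition required",
         call. = FALSE)
  }
  if (any(cfg$spike_concentrations <= 0)) {
    stop("validation error: spike concentrations must be positive",
         call. = FALSE)
  }
  if (cfg$n_spikein > cfg$n_proteins) {
    stop("validation error: n_spikein must not exceed n_proteins",
         call. = FALSE)
  }
  if (cfg$missing_rate_random < 0 || cfg$missing_rate_random > 1) {
    stop("validation error: missing_rate_random must lie in [0, 1]",
         call. = FALSE)
  }
  if (is.matrix(cfg$B)) {
    if (nrow(cfg$B) != cfg$M || ncol(cfg$B) != C) {
      stop("validation error: B matrix must be M x C", call. = FALSE)
    }
  }
  cfg$Bmat <- if (is.matrix(cfg$B)) cfg$B else
    matrix(cfg$B, cfg$M, C)
  dimnames(cfg$Bmat) <- list(paste0("Mixture", seq_len(cfg$M)),
                             cfg$conditions)
  need <- max(rowSums(cfg$Bmat)) + cfg$n_reference
  if (cfg$channels_per_run < need) {
    stop("infeasible allocation: design requires ", need,
         " channels per run but only ", cfg$channels_per_run,
         " are available", call. = FALSE)
  }
  structure(cfg, class = "tmt_sim_config")
}

.n_features <- function(cfg, n) {
  fp <- cfg$features_per_protein
  if (is.numeric(fp)) return(rep(as.integer(fp), n))
  1L + rpois(n, max(fp$mean - 1, 0))
}

#' Allocate the experimental design
#'
#' Randomly (but reproducibly) assigns condition x biological replicate
#' pairs and reference channels to the reporter channels of each mixture;
#' the allocation is shared by all technical replicate runs of the mixture.
#'
#' @param cfg A `tmt_sim_config` (see [sim_config()]).
#' @return Annotation data frame (one row per run x channel) as accepted by
#'   [validate_annotation()].
#' @export
allocate_design <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  channels <- tmt_channels(cfg$channels_per_run)
  rows <- list()
  for (m in seq_len(cfg$M)) {
    cells <- c(rep("Norm", cfg$n_reference),
               unlist(lapply(cfg$conditions, function(cd)
                 rep(cd, cfg$Bmat[m, cd]))))
    bio <- c(rep("Norm", cfg$n_reference),
             unlist(lapply(cfg$conditions, function(cd) {
               nb <- cfg$Bmat[m, cd]
               if (nb == 0) character(0)
               else paste("Mixture", m, "_", cd, "_", seq_len(nb), sep = "")
             })))
    slots <- sample(cfg$channels_per_run, length(cells))
    for (t in seq_len(cfg$T)) {
      rows[[length(rows) + 1L]] <- data.frame(
        Run = sprintf("Mixture%d_Rep%d", m, t),
        Channel = channels[slots],
        Condition = cells,
        BioReplicate = bio,
        Mixture = paste0("Mixture", m),
        TechRepMixture = as.character(t),
        stringsAsFactors = FALSE)
    }
  }
  validate_annotation(do.call(rbind, rows))
}

#' Ground-truth fold changes of a configuration
#'
#' All-pairs true log2 fold changes implied by the spike-in amounts
#' (pairs ordered higher/lower concentration, labeled `"A/B"`).
#'
#' @param cfg A `tmt_sim_config`.
#' @return Data frame with `Label`, `ConditionA`, `ConditionB`,
#'   `true_log2FC`, `true_FC`.
#' @export
true_fold_changes <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  conc <- setNames(cfg$spike_concentrations, cfg$conditions)
  ord <- names(sort(conc, decreasing = TRUE))
  pairs <- utils::combn(ord, 2)
  data.frame(
    Label = paste(pairs[1, ], pairs[2, ], sep = "/"),
    ConditionA = pairs[1, ], ConditionB = pairs[2, ],
    true_log2FC = log2(conc[pairs[1, ]] / conc[pairs[2, ]]),
    true_FC = conc[pairs[1, ]] / conc[pairs[2, ]],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a controlled-mixture experiment at the PSM level
#'
#' Generates raw reporter-ion intensities for a spike-in dilution series:
#' per protein a baseline abundance, per feature an ionization effect, per
#' run an additive shift; spike-in proteins' channel means are offset by
#' the log2 amount of the channel's condition (reference channels by the
#' log2 pooled mean amount when `reference_pool`), plus Gaussian cell
#' noise. Whole feature-runs are removed completely at random at
#' `missing_rate_random`, and cells below `mnar_threshold` are
#' left-censored (or probabilistically when `mnar_prob_scale > 0`).
#'
#' @param cfg A `tmt_sim_config` (see [sim_config()]).
#' @return List with `psm` (canonical PSM records), `annotation`, and
#'   `truth` (list with `proteins`: per-protein spike flag, and
#'   `fold_changes`: per-comparison true fold changes, zero log2FC for
#'   background proteins).
#' @export
simulate_controlled_mixture <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  ann <- allocate_design(cfg)   # seeds with cfg$seed
  set.seed(cfg$seed + 1L)
  conc <- setNames(cfg$spike_concentrations, cfg$conditions)
  rel <- log2(conc / max(conc))
  ref_rel <- log2(mean(conc) / max(conc))
  prots <- sprintf("P%04d", seq_len(cfg$n_proteins))
  spike <- c(rep(TRUE, cfg$n_spikein),
             rep(FALSE, cfg$n_proteins - cfg$n_spikein))
  base <- rnorm(cfg$n_proteins, cfg$base_mean, cfg$base_sd)
  nfeat <- .n_features(cfg, cfg$n_proteins)
  runs <- unique(ann$Run)
  run_shift <- setNames(rnorm(length(runs), 0, cfg$sigma_run), runs)
  chan_offset <- function(p, condition) {
    if (!spike[p]) return(0)
    if (condition == "Norm") {
      if (cfg$reference_pool) ref_rel else 0
    } else rel[condition]
  }
  out <- vector("list", cfg$n_proteins)
  for (p in seq_len(cfg$n_proteins)) {
    feats <- paste0(prots[p], "_F", seq_len(nfeat[p]))
    feff <- rnorm(nfeat[p], 0, cfg$sigma_feature)
    grid <- merge(data.frame(Feature = feats, feff = feff,
                             stringsAsFactors = FALSE),
                  ann, by = NULL)
    off <- vapply(grid$Condition, function(cd) chan_offset(p, cd), numeric(1))
    x <- base[p] + grid$feff + run_shift[grid$Run] + off +
      rnorm(nrow(grid), 0, cfg$sigma_channel_noise)
    ## MCAR: whole feature-run identification failures
    fr <- unique(grid[, c("Feature", "Run")])
    dropfr <- fr[runif(nrow(fr)) < cfg$missing_rate_random, , drop = FALSE]
    if (nrow(dropfr) > 0) {
      bad <- paste(grid$Feature, grid$Run) %in% paste(dropfr$Feature, dropfr$Run)
      x[bad] <- NA_real_
    }
    ## MNAR: left-censoring of low-abundance cells
    if (cfg$mnar_prob_scale > 0) {
      pc <- 1 / (1 + exp((x - cfg$mnar_threshold) / cfg$mnar_prob_scale))
      x[!is.na(x) & runif(length(x)) < pc] <- NA_real_
    } else if (is.finite(cfg$mnar_threshold)) {
      x[!is.na(x) & x < cfg$mnar_threshold] <- NA_real_
    }
    out[[p]] <- data.frame(
      ProteinName = prots[p],
      PeptideIon = grid$Feature,
      SpectrumId = paste(grid$Feature, grid$Run, sep = "@"),
      Run = grid$Run,
      Fraction = NA_character_,
      Channel = grid$Channel,
      Intensity = 2^x,
      Interference = NA_real_,
      stringsAsFactors = FALSE)
  }
  psm <- do.call(rbind, out)
  rownames(psm) <- NULL
  tf <- true_fold_changes(cfg)
  fc <- do.call(rbind, lapply(seq_len(nrow(tf)), function(i) {
    data.frame(Protein = prots, Label = tf$Label[i],
               true_log2FC = ifelse(spike, tf$true_log2FC[i], 0),
               stringsAsFactors = FALSE)
  }))
  truth <- list(
    proteins = data.frame(Protein = prots, Spike = spike,
                          stringsAsFactors = FALSE),
    fold_changes = fc)
  list(psm = psm, annotation = ann, truth = truth)
}

#' Simulate protein-level summaries directly
#'
#' Generates normalized protein summaries for a multi-mixture design
#' without passing through the PSM level: per protein a baseline, plus
#' Gaussian mixture, run and residual effects, and condition offsets for
#' spike-in proteins. This is the parametric stand-in for the summary-level
#' simulation protocol in which biological variation is added to existing
#' protein summaries with [add_biological_variation()].
#'
#' @param cfg A `tmt_sim_config`; `n_reference = 0` is typical here.
#' @param sigma_mixture,sigma_run_residual,sigma_resid SDs of the mixture,
#'   run-within-mixture and residual technical effects on the log2 scale
#'   (post-normalization scales; defaults 0.1, 0.1, 0.2).
#' @param resid_df Between-protein heterogeneity of the residual variance:
#'   per-protein variances are drawn from a scaled inverse-chi-square with
#'   `resid_df` prior degrees of freedom and scale `sigma_resid^2` (the
#'   model underlying EB moderation; real protein summaries are strongly
#'   heteroscedastic). `Inf` gives every protein the same variance.
#' @param spike_log2fc log2 fold change of spike-in proteins per condition,
#'   named by condition; default derived from the configured
#'   concentrations.
#' @return List with `summaries` (a `tmt_protein_summaries` table) and
#'   `truth` as in [simulate_controlled_mixture()].
#' @export
simulate_protein_summaries <- function(cfg, sigma_mixture = 0.1,
                                       sigma_run_residual = 0.1,
                                       sigma_resid = 0.2, resid_df = 6,
                                       spike_log2fc = NULL) {
  cfg <- validate_sim_config(cfg)
  ann <- allocate_design(cfg)
  set.seed(cfg$seed + 2L)
  conc <- setNames(cfg$spike_concentrations, cfg$conditions)
  if (is.null(spike_log2fc)) spike_log2fc <- log2(conc / max(conc))
  prots <- sprintf("P%04d", seq_len(cfg$n_proteins))
  spike <- c(rep(TRUE, cfg$n_spikein),
             rep(FALSE, cfg$n_proteins - cfg$n_spikein))
  base <- rnorm(cfg$n_proteins, cfg$base_mean, cfg$base_sd)
  sig_p <- if (is.finite(resid_df)) {
    sigma_resid * sqrt(resid_df / stats::rchisq(cfg$n_proteins, resid_df))
  } else rep(sigma_resid, cfg$n_proteins)
  runs <- unique(ann$Run)
  mixes <- unique(ann$Mixture)
  rows <- vector("list", cfg$n_proteins)
  for (p in seq_len(cfg$n_proteins)) {
    meff <- setNames(rnorm(length(mixes), 0, sigma_mixture), mixes)
    reff <- setNames(rnorm(length(runs), 0, sigma_run_residual), runs)
    off <- ifelse(ann$Condition == "Norm",
                  if (cfg$reference_pool) log2(mean(conc) / max(conc)) else 0,
                  spike_log2fc[ann$Condition])
    off[is.na(off)] <- 0
    if (!spike[p]) off <- rep(0, nrow(ann))
    y <- base[p] + meff[ann$Mixture] + reff[ann$Run] + off +
      rnorm(nrow(ann), 0, sig_p[p])
    rows[[p]] <- data.frame(
      Protein = prots[p], Mixture = ann$Mixture,
      TechRepMixture = ann$TechRepMixture, Run = ann$Run,
      Channel = ann$Channel, Condition = ann$Condition,
      BioReplicate = ann$BioReplicate, Abundance = y,
      NumFeatures = NA_integer_, stringsAsFactors = FALSE)
  }
  pst <- do.call(rbind, rows)
  rownames(pst) <- NULL
  tf <- true_fold_changes(cfg)
  fc <- do.call(rbind, lapply(seq_len(nrow(tf)), function(i) {
    lfc <- spike_log2fc[tf$ConditionA[i]] - spike_log2fc[tf$ConditionB[i]]
    data.frame(Protein = prots, Label = tf$Label[i],
               true_log2FC = ifelse(spike, lfc, 0),
               stringsAsFactors = FALSE)
  }))
  list(summaries = structure(pst, class = c("tmt_protein_summaries",
                                            "data.frame")),
       truth = list(proteins = data.frame(Protein = prots, Spike = spike,
                                          stringsAsFactors = FALSE),
                    fold_changes = fc))
}

#' Add simulated biological variation to protein summaries
#'
#' Implements the summary-level simulation protocol
#' `Z_mtcb = Y_mtcb + eps_mcb`, `eps_mcb ~ iid N(0, sigma_s^2)`: one draw
#' per protein and biological subject (mixture, condition, bioreplicate),
#' added identically to all technical replicate runs of that subject.
#' Reference channels are untouched.
#'
#' @param pst Protein summary table.
#' @param sigma_s Biological standard deviation (log2 scale), >= 0.
#' @param seed Integer seed.
#' @return The summary table with perturbed `Abundance`.
#' @export
add_biological_variation <- function(pst, sigma_s, seed = 1L) {
  if (sigma_s < 0) stop("sigma_s must be nonnegative", call. = FALSE)
  if (sigma_s == 0) return(pst)
  set.seed(as.integer(seed))
  endo <- pst$Condition != "Norm"
  key <- paste(pst$Protein, pst$Mixture, pst$Condition, pst$BioReplicate,
               sep = "\r")
  ukey <- unique(key[endo])
  eps <- setNames(rnorm(length(ukey), 0, sigma_s), ukey)
  pst$Abundance[endo] <- pst$Abundance[endo] + unname(eps[key[endo]])
  pst
}

#' Write simulated data as TSV files
#'
#' @param sim Output of [simulate_controlled_mixture()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written `psm.tsv`, `annotation.tsv`,
#'   `truth.tsv` files, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("psm.tsv", "annotation.tsv", "truth.tsv"))
  ## long-dialect schema, re-readable with read_psm_report(dialect = "long")
  psm <- data.frame(ProteinName = sim$psm$ProteinName,
                    PeptideSequence = sim$psm$PeptideIon,
                    Charge = 2L,
                    PSM = sim$psm$SpectrumId,
                    Run = sim$psm$Run,
                    Fraction = sim$psm$Fraction,
                    Channel = sim$psm$Channel,
                    Intensity = sprintf("%.17g", sim$psm$Intensity),
                    stringsAsFactors = FALSE)
  psm$Intensity[psm$Intensity == "NA"] <- "NA"
  write.table(psm, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$annotation[, c("Run", "Channel", "Condition",
                                 "BioReplicate", "Mixture",
                                 "TechRepMixture")],
              paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- merge(sim$truth$fold_changes, sim$truth$proteins, by = "Protein")
  write.table(tr, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
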