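## Per-protein linear mixed-effects modeling of normalized protein
## summaries, empirical-Bayes moderation of the residual variance, and
## contrast-based tests for differential abundance.
##
## Model family (sum-to-zero condition effects, intercept-free
## parameterization used internally):
##   Y_mtcb = mu + Mixture_m + TechRep(Mixture)_t(m) + Condition_c
##            + Subject_mcb + eps_mtcb
## with Mixture ~ N(0, sM2), TechRep(Mixture) ~ N(0, sT2),
## Subject ~ N(0, sS2), eps ~ N(0, s2).  Designs (or per-protein data
## patterns) that cannot identify a term use a reduced model.

.issue_levels <- c("none", "oneConditionMissing", "completeMissing",
                   "unestimableContrast", "fitFailed")

#' Choose the protein-level model for a design
#'
#' Picks the member of the model family supported by the experimental
#' design: `full` (mixture + technical replicate + subject random effects)
#' when there are multiple mixtures and technical replicates;
#' `multi_mixture` (mixture only; each subject measured once, so the
#' subject effect is confounded with the residual) when M > 1 and T = 1;
#' `single_mixture_techrep` (technical replicate + subject) when M = 1 and
#' T > 1; and the fixed-effects one-way model `single_run` when M = T = 1.
#' Random terms that the protein's own observed data cannot identify are
#' dropped later, at fit time.
#'
#' @param design Experimental design (see [experiment_design()]).
#' @return A `ModelSpec` list with `label` and logical flags
#'   `has_mixture_effect`, `has_techrep_effect`, `has_subject_effect`.
#' @export
choose_model <- function(design) {
  M <- design$M
  anyT <- any(design$T > 1)
  label <- if (M > 1 && anyT) "full"
    else if (M > 1) "multi_mixture"
    else if (anyT) "single_mixture_techrep"
    else "single_run"
  list(label = label,
       has_mixture_effect = M > 1,
       has_techrep_effect = anyT,
       has_subject_effect = anyT)
}

## ---- Satterthwaite machinery -------------------------------------------
## REML deviance as a function of the variance parameters, built on lme4's
## modular API.  Parameterized on the variance scale
## v = (var_1, ..., var_q, sigma^2); theta_k = sqrt(v_k / sigma^2).
## A = 2 * H^{-1} (H = finite-difference Hessian of the REML deviance)
## approximates the covariance of the variance-parameter estimates;
## the df of a contrast c is 2 (c'Vc)^2 / (g' A g) with g the gradient of
## c'Vc in v.  Validated against the exact classical df in balanced
## designs.

.fd_hessian <- function(f, x, h) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in seq.int(i + 1L, p)) {
      ej <- rep(0, p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

.satt_machinery <- function(devfun, fm, n, p_fixed) {
  env <- environment(devfun)
  np <- n - p_fixed
  theta_hat <- lme4::getME(fm, "theta")
  s2_hat <- sigma(fm)^2
  v_hat <- c(unname(theta_hat^2 * s2_hat), s2_hat)
  dev_full <- function(theta, s2) {
    dp <- devfun(theta)
    r2 <- env$resp$wrss() + env$pp$sqrL(1)
    dp - np * (1 + log(2 * pi * r2 / np)) + np * log(2 * pi * s2) + r2 / s2
  }
  devv <- function(v) {
    s2 <- v[length(v)]
    dev_full(sqrt(pmax(v[-length(v)], 0) / s2), s2)
  }
  vcovv <- function(v) {
    s2 <- v[length(v)]
    devfun(sqrt(pmax(v[-length(v)], 0) / s2))
    s2 * tcrossprod(env$pp$RXi())
  }
  h <- pmax(abs(v_hat) * 1e-3, 1e-8)
  A <- tryCatch({
    H <- .fd_hessian(devv, v_hat, h)
    2 * solve(H)
  }, error = function(e) NULL)
  list(v = v_hat, h = h, A = A, vcovv = vcovv, np = np)
}

## Satterthwaite df and (optionally residual-variance-substituted) variance
## of a single contrast vector cc on the fixed effects.
.satt_contrast <- function(sm, cc, s2_sub = NULL) {
  v <- sm$v
  q <- length(v)
  cvc <- drop(t(cc) %*% sm$vcovv(v) %*% cc)
  df <- sm$np
  if (!is.null(sm$A)) {
    g <- numeric(q)
    for (k in seq_len(q)) {
      e <- rep(0, q); e[k] <- sm$h[k]
      g[k] <- (drop(t(cc) %*% sm$vcovv(v + e) %*% cc) -
               drop(t(cc) %*% sm$vcovv(v - e) %*% cc)) / (2 * sm$h[k])
    }
    den <- drop(t(g) %*% sm$A %*% g)
    if (is.finite(den) && den > 0) {
      df_s <- 2 * cvc^2 / den
      if (is.finite(df_s) && df_s > 0) df <- min(df_s, sm$np)
    }
  }
  var_sub <- if (is.null(s2_sub)) cvc else {
    vs <- v
    vs[q] <- s2_sub
    drop(t(cc) %*% sm$vcovv(vs) %*% cc)
  }
  list(cvc = cvc, df = df, var_sub = var_sub)
}

## df of the residual variance itself: 2 s2^2 / Var(s2_hat).
.satt_resid_df <- function(sm) {
  q <- length(sm$v)
  if (is.null(sm$A) || !is.finite(sm$A[q, q]) || sm$A[q, q] <= 0) return(sm$np)
  df <- 2 * sm$v[q]^2 / sm$A[q, q]
  if (!is.finite(df) || df <= 0) sm$np else min(df, sm$np)
}

## ---- Per-protein fit ---------------------------------------------------

.term_candidates <- function(spec, drop_subject = FALSE) {
  terms <- character(0)
  if (spec$has_mixture_effect) terms <- c(terms, "Mixture")
  if (spec$has_techrep_effect) terms <- c(terms, "TechRep")
  if (spec$has_subject_effect && !drop_subject) terms <- c(terms, "Subject")
  terms
}

## Per-protein reduction: a random term is kept only when the observed data
## give it at least two levels and it is not confounded with another term
## or the residual.
.reduce_terms <- function(d, terms) {
  keep <- character(0)
  nmix <- length(unique(d$Mixture))
  nrun <- length(unique(d$Run))
  if ("Mixture" %in% terms && nmix >= 2) keep <- c(keep, "Mixture")
  if ("TechRep" %in% terms && nrun >= 2 && nrun > nmix)
    keep <- c(keep, "TechRep")
  if ("Subject" %in% terms) {
    nsub <- length(unique(d$Subject))
    reps <- table(d$Subject)
    if (nsub >= 2 && any(reps >= 2) && nsub < nrow(d))
      keep <- c(keep, "Subject")
  }
  keep
}

.rand_formula <- function(terms) {
  map <- c(Mixture = "(1 | Mixture)", TechRep = "(1 | Run)",
           Subject = "(1 | Subject)")
  paste(map[terms], collapse = " + ")
}

#' Fit the protein-level model for one protein
#'
#' Fits the normalized summaries of one protein by REML with the random
#' terms supported by the design and by the protein's own data pattern
#' (terms with fewer than two observed levels are dropped). On a singular
#' fit or non-convergence, random terms are dropped in the order
#' TechRep, Mixture, Subject and the model refit; with no random terms left
#' the fixed-effects model is fit by least squares.
#'
#' @param d Data frame of one protein's summaries with columns `Abundance`,
#'   `Condition`, `Mixture`, `TechRepMixture`, `Run`, `BioReplicate`
#'   (reference-channel rows must already be excluded).
#' @param spec Model specification from [choose_model()].
#' @param drop_subject Deliberately omit the subject random effect
#'   (benchmarking aid; default `FALSE`).
#' @return A `FitResult` list: `protein`, `model_used`, `terms`,
#'   `coef` (per-condition means), `varcomp`, `s2`, `df_res`, `converged`,
#'   `singular`, `issue`, and internal Satterthwaite state.
#' @export
fit_protein <- function(d, spec, drop_subject = FALSE) {
  d <- d[!is.na(d$Abundance) & d$Condition != "Norm", , drop = FALSE]
  out <- list(protein = d$Protein[1], model_used = spec$label,
              terms = character(0), coef = NULL, varcomp = NULL,
              s2 = NA_real_, df_res = NA_real_, converged = FALSE,
              singular = FALSE, issue = "none", satt = NULL)
  if (nrow(d) == 0) { out$issue <- "completeMissing"; return(out) }
  if (length(unique(d$Condition)) < 2) {
    out$issue <- "oneConditionMissing"
    return(out)
  }
  d$Condition <- factor(d$Condition)
  d$Subject <- d$BioReplicate
  terms <- .reduce_terms(d, .term_candidates(spec, drop_subject))
  drop_order <- c("TechRep", "Mixture", "Subject")
  repeat {
    fit <- .fit_once(d, terms)
    if (!is.null(fit) && !fit$singular) break
    if (!is.null(fit) && fit$singular) out$singular <- TRUE
    nxt <- intersect(drop_order, terms)
    if (length(nxt) == 0) break
    terms <- setdiff(terms, nxt[1])
  }
  if (is.null(fit)) { out$issue <- "fitFailed"; return(out) }
  out$terms <- terms
  out[c("coef", "varcomp", "s2", "df_res", "satt", "unscaled_vcov")] <-
    fit[c("coef", "varcomp", "s2", "df_res", "satt", "unscaled_vcov")]
  out$converged <- TRUE
  out
}

## One REML (or least-squares) fit attempt; NULL on failure.
.fit_once <- function(d, terms) {
  if (length(terms) == 0) return(.fit_lm(d))
  form <- as.formula(paste("Abundance ~ 0 + Condition +",
                           .rand_formula(terms)))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  res <- tryCatch(suppressMessages(suppressWarnings({
    lf <- lme4::lFormula(form, data = d, REML = TRUE, control = ctrl)
    devfun <- do.call(lme4::mkLmerDevfun, lf)
    opt <- lme4::optimizeLmer(devfun, control = ctrl$optCtrl)
    fm <- lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
    list(lf = lf, devfun = devfun, fm = fm)
  })), error = function(e) NULL)
  if (!is.null(res) && !is.null(res$fm@optinfo$conv$opt) &&
      res$fm@optinfo$conv$opt < 0) res <- NULL
  if (is.null(res)) return(NULL)
  fm <- res$fm
  theta <- lme4::getME(fm, "theta")
  singular <- any(theta < 1e-4)
  beta <- lme4::fixef(fm)
  names(beta) <- sub("^Condition", "", names(beta))
  s2 <- sigma(fm)^2
  vc <- setNames(unname(theta^2 * s2), names(theta))
  sm <- .satt_machinery(res$devfun, fm, n = nrow(d),
                        p_fixed = length(beta))
  list(coef = beta, varcomp = vc, s2 = s2,
       df_res = .satt_resid_df(sm), satt = sm,
       unscaled_vcov = NULL, singular = singular)
}

.fit_lm <- function(d) {
  fm <- tryCatch(lm(Abundance ~ 0 + Condition, data = d),
                 error = function(e) NULL)
  if (is.null(fm)) return(NULL)
  beta <- coef(fm)
  names(beta) <- sub("^Condition", "", names(beta))
  df_res <- fm$df.residual
  if (df_res <= 0) df_res <- 0
  s2 <- if (df_res > 0) sum(fm$residuals^2) / df_res else 0
  X <- model.matrix(fm)
  list(coef = beta, varcomp = numeric(0), s2 = s2, df_res = df_res,
       satt = NULL, unscaled_vcov = solve(crossprod(X)), singular = FALSE)
}

## ---- Empirical-Bayes moderation ---------------------------------------

## Newton inversion of the trigamma function (solve trigamma(x) = y).
.trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Matches the first two moments of the log residual variances to the
#' theory of a scaled F / log-chi-square distribution (the standard
#' moderated-t prior): given per-protein residual variances `s2` with
#' residual degrees of freedom `df`, estimates the prior degrees of freedom
#' `d0` and prior variance `s0_sq`. When the dispersion of the log
#' variances does not exceed what sampling alone explains, `d0 = Inf` is
#' returned (complete shrinkage to `s0_sq`).
#'
#' @param s2 Numeric vector of residual variance estimates.
#' @param df Numeric vector of their residual degrees of freedom.
#' @return `EBPrior` list with `d0` and `s0_sq`.
#' @export
estimate_eb_prior <- function(s2, df) {
  ok <- is.finite(s2) & is.finite(df) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  n <- length(s2)
  if (n < 2) {
    return(list(d0 = 0, s0_sq = if (n == 1) s2 else NA_real_))
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- mean((e - emean)^2 * n / (n - 1)) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderate a residual variance with an EB prior
#'
#' Posterior (moderated) variance
#' `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)` and augmented degrees of
#' freedom `df + d0`. With `d0 = 0` the estimate is returned unchanged;
#' with `d0 = Inf` the moderated variance is `s0_sq` and the degrees of
#' freedom are capped at `1e6`.
#'
#' @param s2 Residual variance estimate.
#' @param df Its residual degrees of freedom.
#' @param prior `EBPrior` from [estimate_eb_prior()].
#' @return List with `s2_mod` and `df_mod`.
#' @export
moderate <- function(s2, df, prior) {
  d0 <- prior$d0
  if (!is.finite(d0)) {
    return(list(s2_mod = prior$s0_sq, df_mod = 1e6))
  }
  if (d0 == 0 || !is.finite(prior$s0_sq)) {
    return(list(s2_mod = s2, df_mod = df))
  }
  list(s2_mod = (d0 * prior$s0_sq + df * s2) / (d0 + df),
       df_mod = df + d0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment implemented directly: for ordered p-values
#' `p_(1) <= ... <= p_(m)`, `adj_(i) = min_{j >= i} m p_(j) / j`, capped
#' at 1. Missing p-values stay missing and do not count toward `m`.
#'
#' @param p Numeric vector of p-values (may contain `NA`).
#' @return Vector of adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok], decreasing = TRUE)
  ro <- ok[o]
  adj <- cummin(m / seq.int(m, 1) * p[ro])
  out[ro] <- pmin(adj, 1)
  out
}

#' Test a contrast between conditions
#'
#' Computes the contrast estimate (log2 fold change), its moderated
#' standard error (the model's fixed-effect covariance with the residual
#' variance replaced by the moderated variance), Satterthwaite degrees of
#' freedom augmented by the prior degrees of freedom, and a two-sided
#' t-test p-value.
#'
#' @param fit `FitResult` from [fit_protein()].
#' @param contrast Named numeric vector of condition weights summing to 0.
#' @param prior `EBPrior`; defaults to no moderation.
#' @param label Comparison label for the result row.
#' @return One-row data frame: `Protein`, `Label`, `log2FC`, `SE`, `DF`,
#'   `tvalue`, `pvalue`, `issue`.
#' @export
test_contrast <- function(fit, contrast, prior = list(d0 = 0, s0_sq = NA_real_),
                          label = NULL) {
  if (abs(sum(contrast)) > 1e-8) {
    stop("contrast weights must sum to 0", call. = FALSE)
  }
  if (is.null(label)) {
    pos <- names(contrast)[contrast > 0]
    neg <- names(contrast)[contrast < 0]
    label <- paste(paste(pos, collapse = "+"), paste(neg, collapse = "+"),
                   sep = " vs ")
  }
  row <- data.frame(Protein = fit$protein %||% NA_character_, Label = label,
                    log2FC = NA_real_, SE = NA_real_, DF = NA_real_,
                    tvalue = NA_real_, pvalue = NA_real_,
                    issue = "none", stringsAsFactors = FALSE)
  if (fit$issue != "none") { row$issue <- fit$issue; return(row) }
  used <- names(contrast)[contrast != 0]
  if (!all(used %in% names(fit$coef))) {
    row$issue <- "oneConditionMissing"
    return(row)
  }
  if (anyNA(fit$coef[used])) {
    row$issue <- "unestimableContrast"
    return(row)
  }
  cc <- setNames(rep(0, length(fit$coef)), names(fit$coef))
  cc[used] <- contrast[used]
  est <- drop(sum(cc * fit$coef))
  mod <- moderate(fit$s2, fit$df_res, prior)
  if (!is.null(fit$satt)) {
    sc <- .satt_contrast(fit$satt, cc, s2_sub = mod$s2_mod)
    var_mod <- sc$var_sub
    df <- sc$df
  } else {
    var_mod <- mod$s2_mod * drop(t(cc) %*% fit$unscaled_vcov %*% cc)
    df <- fit$df_res
  }
  d0 <- prior$d0
  df_tot <- if (is.finite(d0)) df + d0 else 1e6
  df_tot <- min(df_tot, 1e6)
  if (!is.finite(var_mod) || var_mod < 0 || df_tot <= 0) {
    row$issue <- "unestimableContrast"
    return(row)
  }
  if (var_mod == 0) {
    ## degenerate noiseless fit: a zero estimate is definitionally null
    if (abs(est) < 1e-12) {
      row$log2FC <- est; row$SE <- 0; row$DF <- df_tot
      row$tvalue <- 0; row$pvalue <- 1
    } else {
      row$issue <- "unestimableContrast"
    }
    return(row)
  }
  se <- sqrt(var_mod)
  tv <- est / se
  row$log2FC <- est
  row$SE <- se
  row$DF <- df_tot
  row$tvalue <- tv
  row$pvalue <- 2 * pt(-abs(tv), df = df_tot)
  row
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Testability: more than one summary value in more than one condition.
.is_testable <- function(d) {
  d <- d[!is.na(d$Abundance) & d$Condition != "Norm", , drop = FALSE]
  if (nrow(d) == 0) return(FALSE)
  sum(table(d$Condition) > 1) > 1
}

#' Group comparison: full modeling and inference across proteins
#'
#' Orchestrates the modeling stage: per protein, chooses and fits the
#' model, pools the residual variances into the empirical-Bayes prior,
#' tests all requested contrasts with moderated standard errors, and
#' adjusts p-values by Benjamini-Hochberg within each comparison label.
#' Proteins failing the testability rule (more than one summary value in
#' more than one condition) are reported with an issue code and excluded
#' from the BH denominator.
#'
#' @param pst Normalized protein summary table (reference rows are ignored
#'   here).
#' @param contrasts Numeric matrix, rows = comparison labels, columns =
#'   condition names, entries = weights (each row sums to 0). See
#'   [make_all_pairs_contrasts()].
#' @param moderation Apply EB moderation? (default `TRUE`)
#' @param drop_subject Omit the subject random term everywhere
#'   (benchmarking aid; default `FALSE`).
#' @return A `tmt_comparison_result` data frame with columns `Protein`,
#'   `Label`, `log2FC`, `SE`, `DF`, `tvalue`, `pvalue`, `adj.pvalue`,
#'   `issue`, plus attributes `prior` and `fits` (per-protein model label,
#'   variance components and residual df).
#' @export
group_comparison <- function(pst, contrasts, moderation = TRUE,
                             drop_subject = FALSE) {
  stopifnot(is.matrix(contrasts), !is.null(rownames(contrasts)),
            !is.null(colnames(contrasts)))
  if (any(abs(rowSums(contrasts)) > 1e-8)) {
    stop("every contrast row must sum to 0", call. = FALSE)
  }
  d <- as.data.frame(pst)
  d <- d[d$Condition != "Norm", , drop = FALSE]
  ann <- unique(d[, c("Run", "Channel", "Condition", "BioReplicate",
                      "Mixture", "TechRepMixture")])
  if (nrow(d) == 0 || length(unique(d$Protein)) == 0) {
    out <- data.frame(Protein = character(0), Label = character(0),
                      log2FC = numeric(0), SE = numeric(0), DF = numeric(0),
                      tvalue = numeric(0), pvalue = numeric(0),
                      adj.pvalue = numeric(0), issue = character(0),
                      stringsAsFactors = FALSE)
    return(structure(out, prior = NULL, fits = NULL,
                     class = c("tmt_comparison_result", "data.frame")))
  }
  spec <- choose_model(experiment_design(ann))
  prots <- unique(d$Protein)
  fits <- vector("list", length(prots))
  names(fits) <- prots
  testable <- logical(length(prots))
  names(testable) <- prots
  for (pr in prots) {
    dp <- d[d$Protein == pr, , drop = FALSE]
    testable[pr] <- .is_testable(dp)
    if (!testable[pr]) {
      dpo <- dp[!is.na(dp$Abundance), , drop = FALSE]
      issue <- if (nrow(dpo) == 0) "completeMissing"
        else if (length(unique(dpo$Condition)) < 2) "oneConditionMissing"
        else "unestimableContrast"
      fits[[pr]] <- list(protein = pr, model_used = spec$label,
                         issue = issue, converged = FALSE,
                         coef = NULL, s2 = NA_real_, df_res = NA_real_,
                         satt = NULL, varcomp = NULL, terms = character(0),
                         singular = FALSE)
    } else {
      fits[[pr]] <- fit_protein(dp, spec, drop_subject = drop_subject)
    }
  }
  prior <- if (moderation) {
    estimate_eb_prior(
      vapply(fits, function(f) f$s2 %||% NA_real_, numeric(1)),
      vapply(fits, function(f) f$df_res %||% NA_real_, numeric(1)))
  } else list(d0 = 0, s0_sq = NA_real_)
  rows <- vector("list", length(prots) * nrow(contrasts))
  k <- 0L
  for (pr in prots) {
    for (lab in rownames(contrasts)) {
      k <- k + 1L
      cvec <- contrasts[lab, colnames(contrasts), drop = TRUE]
      cvec <- setNames(as.numeric(cvec), colnames(contrasts))
      rows[[k]] <- test_contrast(fits[[pr]], cvec, prior = prior,
                                 label = lab)
    }
  }
  out <- do.call(rbind, rows)
  out$adj.pvalue <- NA_real_
  for (lab in unique(out$Label)) {
    ii <- out$Label == lab
    out$adj.pvalue[ii] <- adjust_bh(out$pvalue[ii])
  }
  fit_info <- data.frame(
    Protein = prots,
    Model = vapply(fits, function(f) f$model_used %||% NA_character_, character(1)),
    Terms = vapply(fits, function(f) paste(f$terms, collapse = "+"), character(1)),
    SigmaSubject2 = vapply(fits, function(f) {
      vc <- f$varcomp
      if (is.null(vc)) return(NA_real_)
      nm <- grep("Subject", names(vc), value = TRUE)
      if (length(nm) == 0) NA_real_ else unname(vc[nm[1]])
    }, numeric(1)),
    SigmaMixture2 = vapply(fits, function(f) {
      vc <- f$varcomp
      if (is.null(vc)) return(NA_real_)
      nm <- grep("Mixture", names(vc), value = TRUE)
      if (length(nm) == 0) NA_real_ else unname(vc[nm[1]])
    }, numeric(1)),
    SigmaRun2 = vapply(fits, function(f) {
      vc <- f$varcomp
      if (is.null(vc)) return(NA_real_)
      nm <- grep("^Run", names(vc), value = TRUE)
      if (length(nm) == 0) NA_real_ else unname(vc[nm[1]])
    }, numeric(1)),
    Sigma2 = vapply(fits, function(f) f$s2 %||% NA_real_, numeric(1)),
    DFres = vapply(fits, function(f) f$df_res %||% NA_real_, numeric(1)),
    Singular = vapply(fits, function(f) isTRUE(f$singular), logical(1)),
    Testable = unname(testable),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, prior = prior, fits = fit_info,
            class = c("tmt_comparison_result", "data.frame"))
}

#' All-pairs contrast matrix
#'
#' Builds the contrast matrix comparing every ordered pair of conditions
#' (first over second), labeled `"A/B"`.
#'
#' @param conditions Character vector of condition names; pairs are formed
#'   in the given order.
#' @return Contrast matrix suitable for [group_comparison()].
#' @export
make_all_pairs_contrasts <- function(conditions) {
  pairs <- utils::combn(conditions, 2)
  cm <- matrix(0, ncol(pairs), length(conditions),
               dimnames = list(paste(pairs[1, ], pairs[2, ], sep = "/"),
                               conditions))
  for (i in seq_len(ncol(pairs))) {
    cm[i, pairs[1, i]] <- 1
    cm[i, pairs[2, i]] <- -1
  }
  cm
}

#' Read a contrast matrix from a TSV file
#'
#' Rows are comparison labels (first column `Label`), remaining columns are
#' condition names with numeric weights.
#'
#' @param path TSV path.
#' @return Contrast matrix.
#' @export
read_contrasts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .require_columns(df, "Label", "contrast file")
  m <- as.matrix(df[, setdiff(names(df), "Label"), drop = FALSE])
  rownames(m) <- df$Label
  storage.mode(m) <- "double"
  m
}
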