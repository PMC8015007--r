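## Protein summarization: per protein and MS run, impute left-censored
## missing feature intensities under an accelerated-failure-time (AFT)
## model, then summarize channels with Tukey's median polish.

#' Tukey's median polish
#'
#' Iteratively sweeps row and column medians (starting with rows) out of a
#' two-way table, accumulating them into row effects, column effects and an
#' overall term, ignoring missing cells. Iteration stops when the sum of
#' absolute residuals is zero or its relative change drops below `tol`, or
#' after `max_iter` full sweeps. On observed cells the decomposition
#' satisfies `x ~ overall + row + col + residual`.
#'
#' @param x Numeric matrix, possibly with missing cells.
#' @param tol Relative convergence tolerance on the sum of absolute
#'   residuals (default `1e-4`).
#' @param max_iter Maximum number of sweeps (default 100).
#' @return List with `overall`, `row` (row effects), `col` (column
#'   effects), `residuals`, `converged` and `iterations`.
#' @export
median_polish <- function(x, tol = 1e-4, max_iter = 100L) {
  stopifnot(is.matrix(x), nrow(x) >= 1, ncol(x) >= 1)
  if (all(is.na(x))) stop("median_polish: all cells are missing", call. = FALSE)
  z <- x
  overall <- 0
  r <- setNames(numeric(nrow(x)), rownames(x))
  cl <- setNames(numeric(ncol(x)), colnames(x))
  oldsum <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(z, 1L, median, na.rm = TRUE)
    z <- z - rdelta
    r <- r + rdelta
    delta <- median(cl, na.rm = TRUE)
    cl <- cl - delta
    overall <- overall + delta
    cdelta <- apply(z, 2L, median, na.rm = TRUE)
    z <- sweep(z, 2L, cdelta, check.margin = FALSE)
    cl <- cl + cdelta
    delta <- median(r, na.rm = TRUE)
    r <- r - delta
    overall <- overall + delta
    newsum <- sum(abs(z), na.rm = TRUE)
    converged <- newsum == 0 || abs(newsum - oldsum) < tol * newsum
    if (converged) break
    oldsum <- newsum
  }
  list(overall = overall, row = r, col = cl, residuals = z,
       converged = converged, iterations = iter)
}

#' Impute left-censored missing intensities with an AFT model
#'
#' Fits a log-location-scale (Gaussian) accelerated-failure-time regression
#' of the log2 intensities on feature and channel main effects, treating
#' missing cells as left-censored at the censoring threshold, and replaces
#' eligible missing cells with the model prediction capped at the
#' threshold. A missing cell is eligible only when its feature has at least
#' one observed channel in the run and its channel has at least one
#' observed feature; features (rows) or channels (columns) that were never
#' quantified stay missing entirely. Observed cells are never modified.
#'
#' The censoring threshold is `censor_mult` times the minimum observed log2
#' intensity in the matrix (missingness in TMT data predominantly arises
#' from low-abundance analytes).
#'
#' @param x Numeric matrix of log2 intensities, rows = features, columns =
#'   channels of one run.
#' @param censor_mult Multiplier applied to the minimum observed value to
#'   form the censoring threshold (default 1).
#' @return List with `x` (imputed matrix) and `imputed` (logical matrix of
#'   filled cells). If the AFT fit fails the input is returned unchanged
#'   with a message.
#' @export
aft_impute <- function(x, censor_mult = 1) {
  stopifnot(is.matrix(x))
  out <- list(x = x, imputed = matrix(FALSE, nrow(x), ncol(x)))
  if (nrow(x) < 2 || !anyNA(x) || all(is.na(x))) return(out)
  row_ok <- rowSums(!is.na(x)) > 0
  col_ok <- colSums(!is.na(x)) > 0
  eligible <- is.na(x) & outer(row_ok, col_ok, "&")
  if (!any(eligible)) return(out)
  thr <- censor_mult * min(x, na.rm = TRUE)
  sub <- x[row_ok, col_ok, drop = FALSE]
  d <- data.frame(
    y  = as.vector(sub),
    f  = factor(rep(seq_len(nrow(sub)), ncol(sub))),
    ch = factor(rep(seq_len(ncol(sub)), each = nrow(sub))))
  d$event <- ifelse(is.na(d$y), 0, 1)
  d$yy <- ifelse(is.na(d$y), thr, d$y)
  form <- if (ncol(sub) > 1) yy2 ~ f + ch else yy2 ~ f
  d$yy2 <- survival::Surv(d$yy, d$event, type = "left")
  fit <- tryCatch(
    suppressWarnings(survival::survreg(form, data = d, dist = "gaussian")),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(coef(fit))) {
    message("aft_impute: AFT fit failed; skipping imputation")
    return(out)
  }
  need <- which(is.na(d$y))
  pred <- predict(fit, newdata = d[need, , drop = FALSE])
  pred <- pmin(pred, thr)
  sub_imp <- sub
  sub_imp[need] <- pred
  xi <- x
  xi[row_ok, col_ok] <- sub_imp
  xi[!eligible & is.na(x)] <- NA_real_
  out$x <- xi
  out$imputed <- eligible
  out
}

#' Summarize one protein in one run
#'
#' Runs [aft_impute()] (optionally) and [median_polish()] on the
#' feature-by-channel matrix and returns per-channel abundances
#' `Y = overall + column effect`. Channels with neither observed nor
#' imputed cells get a missing summary. Single-feature proteins bypass the
#' polish: their (possibly imputed) intensities are the summaries.
#'
#' @param x Numeric matrix of log2 intensities (features x channels).
#' @param impute Apply AFT imputation first? (default `TRUE`)
#' @param censor_mult Passed to [aft_impute()].
#' @param tol,max_iter Passed to [median_polish()].
#' @return Named numeric vector of channel summaries (names = column
#'   names), with attribute `n_features` (features with any data).
#' @export
summarize_protein_run <- function(x, impute = TRUE, censor_mult = 1,
                                  tol = 1e-4, max_iter = 100L) {
  stopifnot(is.matrix(x))
  keep <- rowSums(!is.na(x)) > 0
  nfeat <- sum(keep)
  if (nfeat == 0) {
    return(structure(setNames(rep(NA_real_, ncol(x)), colnames(x)),
                     n_features = 0L))
  }
  x <- x[keep, , drop = FALSE]
  if (impute) x <- aft_impute(x, censor_mult = censor_mult)$x
  if (nrow(x) == 1) {
    y <- setNames(as.vector(x), colnames(x))
  } else {
    mp <- median_polish(x, tol = tol, max_iter = max_iter)
    y <- mp$overall + mp$col
    y[colSums(!is.na(x)) == 0] <- NA_real_
  }
  structure(y, n_features = as.integer(nfeat))
}

#' Summarize all proteins across all runs
#'
#' Builds, per protein and run, the feature-by-channel matrix from the
#' feature table (channels in annotation order) and summarizes it with
#' [summarize_protein_run()].
#'
#' @param ft A `tmt_feature_table`, typically after
#'   [global_median_normalize()].
#' @param impute Apply AFT imputation? (default `TRUE`)
#' @param censor_mult,tol,max_iter Passed down.
#' @return A `tmt_protein_summaries` data frame with columns `Protein`,
#'   `Mixture`, `TechRepMixture`, `Run`, `Channel`, `Condition`,
#'   `BioReplicate`, `Abundance`, `NumFeatures`.
#' @export
summarize_proteins <- function(ft, impute = TRUE, censor_mult = 1,
                               tol = 1e-4, max_iter = 100L) {
  ann <- unique(as.data.frame(ft)[, c("Run", "Channel", "Mixture",
                                      "TechRepMixture", "Condition",
                                      "BioReplicate")])
  res <- vector("list", 0L)
  for (run in unique(ft$Run)) {
    fr <- ft[ft$Run == run, , drop = FALSE]
    chs <- ann$Channel[ann$Run == run]
    for (prot in unique(fr$ProteinName)) {
      fp <- fr[fr$ProteinName == prot, , drop = FALSE]
      feats <- unique(fp$Feature)
      m <- matrix(NA_real_, length(feats), length(chs),
                  dimnames = list(feats, chs))
      m[cbind(match(fp$Feature, feats), match(fp$Channel, chs))] <-
        fp$log2Intensity
      y <- summarize_protein_run(m, impute = impute,
                                 censor_mult = censor_mult,
                                 tol = tol, max_iter = max_iter)
      res[[length(res) + 1L]] <- data.frame(
        Protein = prot, Run = run, Channel = chs,
        Abundance = unname(y),
        NumFeatures = attr(y, "n_features"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  idx <- match(paste(out$Run, out$Channel, sep = "\r"),
               paste(ann$Run, ann$Channel, sep = "\r"))
  out$Mixture <- ann$Mixture[idx]
  out$TechRepMixture <- ann$TechRepMixture[idx]
  out$Condition <- ann$Condition[idx]
  out$BioReplicate <- ann$BioReplicate[idx]
  out <- out[, c("Protein", "Mixture", "TechRepMixture", "Run", "Channel",
                 "Condition", "BioReplicate", "Abundance", "NumFeatures")]
  rownames(out) <- NULL
  structure(out, class = c("tmt_protein_summaries", "data.frame"))
}

#' Write protein summaries as TSV
#'
#' @param pst A `tmt_protein_summaries` table.
#' @param path Output path.
#' @export
write_protein_summaries <- function(pst, path) {
  write.table(as.data.frame(pst), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
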