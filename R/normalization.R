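## Two normalization layers: global median equalization of spectrum-level
## log2 intensities, and local (per-protein) reference-channel normalization
## of protein summaries.

#' Global median normalization between channels
#'
#' Equalizes the median log2 reporter intensity of every (run, channel)
#' column across the whole experiment. Each column is shifted by
#' `g - m_rc`, where `m_rc` is the column median over observed features and
#' `g` is the median of all column medians, so the overall intensity scale
#' is preserved. Columns without any observed intensity are left untouched
#' with a warning.
#'
#' @param ft A `tmt_feature_table` (see [build_feature_table()]).
#' @return The feature table with shifted `log2Intensity`.
#' @export
global_median_normalize <- function(ft) {
  col <- paste(ft$Run, ft$Channel, sep = "\r")
  med <- tapply(ft$log2Intensity, col, median, na.rm = TRUE)
  empty <- names(med)[is.na(med)]
  if (length(empty) > 0) {
    warning("skipping (run, channel) column(s) with no observed intensities: ",
            paste(gsub("\r", "/", empty), collapse = ", "), call. = FALSE)
  }
  g <- median(med, na.rm = TRUE)
  shift <- g - med
  shift[is.na(shift)] <- 0
  ft$log2Intensity <- ft$log2Intensity + as.vector(shift[col])
  ft
}

#' Local protein-level normalization with reference channels
#'
#' For each protein, equalizes its summaries in the reference ("Norm")
#' channels of every run to the median of the reference summaries across
#' runs: the per-run shift (median over runs minus the run's reference
#' summary) is added to every channel summary of the protein in that run.
#' When a run carries several reference channels, their arithmetic mean on
#' the log2 scale is used. Runs in which the protein has no reference
#' summary are left unshifted and flagged in the `NormIssue` column.
#'
#' @param pst Protein summary table (see [summarize_proteins()]), with
#'   `Condition == "Norm"` rows marking the reference channels.
#' @return The summary table with shifted `Abundance` and a logical
#'   `NormIssue` column marking unshifted runs.
#' @export
reference_channel_normalize <- function(pst) {
  if (!any(pst$Condition == "Norm")) {
    stop("no reference channels (condition \"Norm\") in the design; ",
         "skip reference normalization (no-reference mode) instead",
         call. = FALSE)
  }
  pst$NormIssue <- FALSE
  ref <- pst[pst$Condition == "Norm" & !is.na(pst$Abundance), , drop = FALSE]
  key <- paste(ref$Protein, ref$Run, sep = "\r")
  refmean <- tapply(ref$Abundance, key, mean)
  refprot <- sub("\r.*$", "", names(refmean))
  shift_of <- unlist(lapply(split(seq_along(refmean), refprot), function(ii) {
    m <- median(refmean[ii])
    setNames(m - refmean[ii], names(refmean)[ii])
  }), use.names = FALSE)
  names(shift_of) <- unlist(lapply(split(names(refmean), refprot), identity),
                            use.names = FALSE)
  pk <- paste(pst$Protein, pst$Run, sep = "\r")
  sh <- as.vector(shift_of[pk])
  miss <- is.na(sh)
  pst$Abundance <- pst$Abundance + ifelse(miss, 0, sh)
  pst$NormIssue <- miss & !is.na(pst$Abundance)
  pst
}
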