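## PSM report import and feature construction.
##
## Canonical PSM record columns:
##   ProteinName, PeptideIon, SpectrumId, Run, Fraction, Channel, Intensity,
##   Interference
## Intensity is on the raw (not log) scale; zero and negative raw intensities
## are treated as missing before the log2 transform.

.psm_cols <- c("ProteinName", "PeptideIon", "SpectrumId", "Run", "Fraction",
               "Channel", "Intensity", "Interference")

#' Channel names of common TMT plexes
#'
#' @param plex Number of channels (6, 10, 11 or 16).
#' @return Character vector of reporter channel names in mass order.
#' @export
tmt_channels <- function(plex = 10) {
  full <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
            "130N", "130C", "131", "131C", "132N", "132C", "133N",
            "133C", "134N")
  if (plex == 6) return(c("126", "127", "128", "129", "130", "131"))
  if (plex >= 1 && plex <= 16) return(full[seq_len(plex)])
  stop("unsupported plex size: ", plex)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop("schema error in ", what, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

.as_missing_nonpositive <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  x[!is.na(x) & x <= 0] <- NA_real_
  x
}

#' Read a PSM-level quantification report
#'
#' Reads a tab- or comma-separated PSM report in one of several dialects and
#' returns canonical long-format PSM records, one row per
#' (spectrum, run, channel). Zero and negative intensities are converted to
#' missing values.
#'
#' Dialects:
#' \describe{
#'   \item{`long`}{columns `ProteinName`, `PeptideSequence`, `Charge`,
#'     `PSM`, `Run`, `Channel`, `Intensity`; optional `Fraction`,
#'     `Interference`.}
#'   \item{`wide`}{same identification columns but one intensity column per
#'     channel (given via `channels`, default the TMT 10-plex names).}
#'   \item{`pd_like`}{Proteome-Discoverer-style export: `Master Protein
#'     Accessions`, `Annotated Sequence`, `Charge`, `First Scan`,
#'     `Spectrum File`, intensity columns `Abundance: <channel>`, optional
#'     `Fraction` and `Isolation Interference [%]`.}
#'   \item{`mq_like`}{MaxQuant-style evidence export: `Proteins`,
#'     `Modified sequence`, `Charge`, `MS/MS scan number`, `Raw file`,
#'     intensity columns `Reporter intensity <k>`, optional `Fraction`.}
#' }
#'
#' @param path Path to the report file.
#' @param dialect One of `"long"`, `"wide"`, `"pd_like"`, `"mq_like"`.
#' @param channels Channel names for the wide dialects; defaults to
#'   [tmt_channels()] names found among the columns.
#' @param sep Field separator; `"\t"` by default, use `","` for CSV.
#' @return A data frame of canonical PSM records.
#' @export
read_psm_report <- function(path, dialect = c("long", "wide", "pd_like", "mq_like"),
                            channels = NULL, sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty-input error: no rows in ", path, call. = FALSE)
  rec <- switch(dialect,
    long    = .parse_long(df),
    wide    = .parse_wide(df, channels),
    pd_like = .parse_pd(df, channels),
    mq_like = .parse_mq(df, channels))
  validate_psm_records(rec)
}

.parse_long <- function(df) {
  .require_columns(df, c("ProteinName", "PeptideSequence", "Charge", "PSM",
                         "Run", "Channel", "Intensity"), "long PSM report")
  data.frame(
    ProteinName  = as.character(df$ProteinName),
    PeptideIon   = paste(df$PeptideSequence, df$Charge, sep = "_"),
    SpectrumId   = as.character(df$PSM),
    Run          = as.character(df$Run),
    Fraction     = if ("Fraction" %in% names(df)) as.character(df$Fraction) else NA_character_,
    Channel      = as.character(df$Channel),
    Intensity    = .as_missing_nonpositive(df$Intensity),
    Interference = if ("Interference" %in% names(df)) suppressWarnings(as.numeric(df$Interference)) else NA_real_,
    stringsAsFactors = FALSE)
}

.melt_wide <- function(df, id, channel_cols) {
  out <- do.call(rbind, lapply(channel_cols, function(ch) {
    r <- id
    r$Channel <- ch
    r$Intensity <- .as_missing_nonpositive(df[[ch]])
    r
  }))
  rownames(out) <- NULL
  out
}

.find_channel_cols <- function(df, channels, prefix = "") {
  if (!is.null(channels)) {
    cols <- paste0(prefix, channels)
    .require_columns(df, cols, "wide PSM report")
    return(setNames(cols, channels))
  }
  cand <- tmt_channels(16)
  cols <- paste0(prefix, cand)
  keep <- cols %in% names(df)
  if (!any(keep)) {
    stop("schema error in wide PSM report: missing required column(s): ",
         "no reporter channel columns found (expected e.g. ",
         paste0(prefix, "126"), ")", call. = FALSE)
  }
  setNames(cols[keep], cand[keep])
}

.parse_wide <- function(df, channels) {
  .require_columns(df, c("ProteinName", "PeptideSequence", "Charge", "PSM",
                         "Run"), "wide PSM report")
  chcols <- .find_channel_cols(df, channels)
  id <- data.frame(
    ProteinName  = as.character(df$ProteinName),
    PeptideIon   = paste(df$PeptideSequence, df$Charge, sep = "_"),
    SpectrumId   = as.character(df$PSM),
    Run          = as.character(df$Run),
    Fraction     = if ("Fraction" %in% names(df)) as.character(df$Fraction) else NA_character_,
    Interference = if ("Interference" %in% names(df)) suppressWarnings(as.numeric(df$Interference)) else NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(names(chcols), function(ch) {
    r <- id
    r$Channel <- ch
    r$Intensity <- .as_missing_nonpositive(df[[chcols[[ch]]]])
    r
  }))
  rownames(out) <- NULL
  out[, .psm_cols]
}

.parse_pd <- function(df, channels) {
  .require_columns(df, c("Master Protein Accessions", "Annotated Sequence",
                         "Charge", "First Scan", "Spectrum File"),
                   "Proteome-Discoverer-like PSM report")
  chcols <- .find_channel_cols(df, channels, prefix = "Abundance: ")
  id <- data.frame(
    ProteinName  = as.character(df$`Master Protein Accessions`),
    PeptideIon   = paste(df$`Annotated Sequence`, df$Charge, sep = "_"),
    SpectrumId   = paste(df$`Spectrum File`, df$`First Scan`, sep = "_"),
    Run          = as.character(df$`Spectrum File`),
    Fraction     = if ("Fraction" %in% names(df)) as.character(df$Fraction) else NA_character_,
    Interference = if ("Isolation Interference [%]" %in% names(df))
      suppressWarnings(as.numeric(df$`Isolation Interference [%]`)) else NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(names(chcols), function(ch) {
    r <- id
    r$Channel <- ch
    r$Intensity <- .as_missing_nonpositive(df[[chcols[[ch]]]])
    r
  }))
  rownames(out) <- NULL
  out[, .psm_cols]
}

.parse_mq <- function(df, channels) {
  .require_columns(df, c("Proteins", "Modified sequence", "Charge",
                         "MS/MS scan number", "Raw file"),
                   "MaxQuant-like PSM report")
  rep_cols <- grep("^Reporter intensity [0-9]+$", names(df), value = TRUE)
  if (length(rep_cols) == 0) {
    stop("schema error in MaxQuant-like PSM report: missing required ",
         "column(s): Reporter intensity <k>", call. = FALSE)
  }
  k <- as.integer(sub("^Reporter intensity ", "", rep_cols))
  rep_cols <- rep_cols[order(k)]
  chn <- if (!is.null(channels)) channels else tmt_channels(16)[seq_along(rep_cols)]
  id <- data.frame(
    ProteinName  = as.character(df$Proteins),
    PeptideIon   = paste(df$`Modified sequence`, df$Charge, sep = "_"),
    SpectrumId   = paste(df$`Raw file`, df$`MS/MS scan number`, sep = "_"),
    Run          = as.character(df$`Raw file`),
    Fraction     = if ("Fraction" %in% names(df)) as.character(df$Fraction) else NA_character_,
    Interference = NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_along(rep_cols), function(i) {
    r <- id
    r$Channel <- chn[i]
    r$Intensity <- .as_missing_nonpositive(df[[rep_cols[i]]])
    r
  }))
  rownames(out) <- NULL
  out[, .psm_cols]
}

#' Validate canonical PSM records
#'
#' Checks the PSM record invariants: intensities missing or positive, and
#' (SpectrumId, Run, Channel) unique.
#'
#' @param records Data frame of canonical PSM records.
#' @return The validated records, invisibly unchanged.
#' @export
validate_psm_records <- function(records) {
  .require_columns(records, .psm_cols, "PSM records")
  key <- paste(records$SpectrumId, records$Run, records$Channel, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (spectrum, run, channel) in PSM records", call. = FALSE)
  }
  stopifnot(all(is.na(records$Intensity) | records$Intensity > 0))
  records
}

#' Read a run/channel annotation table
#'
#' The annotation maps each (Run, Channel) to Condition, BioReplicate,
#' Mixture and TechRepMixture. Reference channels carry the reserved
#' condition label `"Norm"`.
#'
#' @param path Path to a TSV/CSV file with columns `Run`, `Channel`,
#'   `Condition`, `BioReplicate`, `Mixture`, `TechRepMixture`.
#' @param sep Field separator.
#' @return Data frame of annotation rows with a logical column
#'   `IsReference`.
#' @export
read_annotation <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_annotation(df)
}

#' Validate an annotation table
#'
#' @param ann Data frame with the annotation columns (see
#'   [read_annotation()]).
#' @return The annotation with canonical character columns and the
#'   `IsReference` flag.
#' @export
validate_annotation <- function(ann) {
  .require_columns(ann, c("Run", "Channel", "Condition", "BioReplicate",
                          "Mixture", "TechRepMixture"), "annotation")
  for (cl in c("Run", "Channel", "Condition", "BioReplicate", "Mixture",
               "TechRepMixture")) {
    ann[[cl]] <- as.character(ann[[cl]])
  }
  key <- paste(ann$Run, ann$Channel, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("validation error: duplicate (run, channel) in annotation: ",
         paste(gsub("\r", "/", dup), collapse = ", "), call. = FALSE)
  }
  rm2 <- unique(ann[, c("Run", "Mixture", "TechRepMixture")])
  if (anyDuplicated(rm2$Run)) {
    bad <- unique(rm2$Run[duplicated(rm2$Run)])
    stop("validation error: run(s) mapped to more than one ",
         "(mixture, techrep) pair: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann$IsReference <- ann$Condition == "Norm"
  ann
}

#' Remove shared peptides and sparse spectra
#'
#' Drops all records of peptide ions mapped to more than one protein, and
#' spectra whose fraction of missing reporter channels exceeds
#' `max_missing_fraction`.
#'
#' @param records Canonical PSM records.
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   channels per spectrum (default 0.5).
#' @return Filtered PSM records (possibly empty).
#' @export
filter_shared_and_sparse <- function(records, max_missing_fraction = 0.5) {
  if (nrow(records) == 0) return(records)
  nprot <- tapply(records$ProteinName, records$PeptideIon,
                  function(p) length(unique(p)))
  shared <- names(nprot)[nprot > 1]
  records <- records[!(records$PeptideIon %in% shared), , drop = FALSE]
  if (nrow(records) == 0) return(records)
  spec <- paste(records$SpectrumId, records$Run, sep = "\r")
  mfrac <- tapply(is.na(records$Intensity), spec, mean)
  drop <- names(mfrac)[mfrac > max_missing_fraction]
  records <- records[!(spec %in% drop), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Keep one best spectrum per peptide ion and run
#'
#' When several spectra quantify the same peptide ion within a run, a single
#' best spectrum is retained, chosen lexicographically by: fewest missing
#' channels, then highest summed intensity, then lowest interference score,
#' then first spectrum id.
#'
#' @param records Canonical PSM records.
#' @return PSM records with exactly one spectrum per (peptide ion, run).
#' @export
select_best_spectrum <- function(records) {
  if (nrow(records) == 0) return(records)
  spec <- paste(records$PeptideIon, records$Run, records$SpectrumId, sep = "\r")
  grp  <- paste(records$PeptideIon, records$Run, sep = "\r")
  agg <- data.frame(
    spec  = tapply(spec, spec, `[`, 1),
    grp   = tapply(grp, spec, `[`, 1),
    sid   = tapply(records$SpectrumId, spec, `[`, 1),
    nmiss = as.vector(tapply(is.na(records$Intensity), spec, sum)),
    total = as.vector(tapply(records$Intensity, spec, function(x) sum(x, na.rm = TRUE))),
    intf  = as.vector(tapply(records$Interference, spec, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) Inf else x[1]
    })),
    stringsAsFactors = FALSE)
  agg <- agg[order(agg$grp, agg$nmiss, -agg$total, agg$intf, agg$sid), ]
  best <- agg$spec[!duplicated(agg$grp)]
  out <- records[spec %in% best, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain each peptide ion in a single fraction
#'
#' In fractionated experiments a peptide ion may be quantified in several
#' fractions; it is kept only in the fraction with the highest mean
#' intensity (across its channels and runs), ties broken by highest maximal
#' intensity, then by fraction id order.
#'
#' @param records Canonical PSM records.
#' @return PSM records with one fraction per peptide ion.
#' @export
deduplicate_fractions <- function(records) {
  if (nrow(records) == 0 || all(is.na(records$Fraction))) return(records)
  pf <- paste(records$PeptideIon, records$Fraction, sep = "\r")
  agg <- data.frame(
    pf   = tapply(pf, pf, `[`, 1),
    ion  = tapply(records$PeptideIon, pf, `[`, 1),
    frac = tapply(records$Fraction, pf, `[`, 1),
    mn   = as.vector(tapply(records$Intensity, pf, function(x) mean(x, na.rm = TRUE))),
    mx   = as.vector(tapply(records$Intensity, pf, function(x) {
      if (all(is.na(x))) -Inf else max(x, na.rm = TRUE)
    })),
    stringsAsFactors = FALSE)
  agg$mn[is.nan(agg$mn)] <- -Inf
  agg <- agg[order(agg$ion, -agg$mn, -agg$mx, agg$frac), ]
  keep <- agg$pf[!duplicated(agg$ion)]
  out <- records[pf %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the canonical feature table
#'
#' Joins filtered PSM records to the annotation, log2-transforms the
#' intensities and summarizes the experimental design. Each peptide ion is a
#' feature (the converter filters guarantee one spectrum per ion and run).
#' Proteins that cannot possibly satisfy the testability rule (more than one
#' summary value in more than one condition) are flagged, not dropped.
#'
#' @param records Canonical PSM records, already passed through
#'   [filter_shared_and_sparse()], [select_best_spectrum()] and
#'   [deduplicate_fractions()].
#' @param annotation Validated annotation (see [read_annotation()]).
#' @return A `tmt_feature_table`: a data frame with columns `ProteinName`,
#'   `Feature`, `Run`, `Channel`, `Mixture`, `TechRepMixture`, `Condition`,
#'   `BioReplicate`, `log2Intensity`, with attributes `design` (see
#'   [experiment_design()]) and `flagged_proteins`.
#' @export
build_feature_table <- function(records, annotation) {
  annotation <- validate_annotation(annotation)
  key <- function(r, c) paste(r, c, sep = "\r")
  ak <- key(annotation$Run, annotation$Channel)
  rk <- key(records$Run, records$Channel)
  missing_ann <- !(rk %in% ak)
  if (any(missing_ann)) {
    off <- unique(gsub("\r", "/", rk[missing_ann]))
    stop("join error: (run, channel) present in records but absent from ",
         "annotation: ", paste(utils::head(off, 10), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(rk, ak)
  ft <- data.frame(
    ProteinName   = records$ProteinName,
    Feature       = records$PeptideIon,
    Run           = records$Run,
    Channel       = records$Channel,
    Mixture       = annotation$Mixture[idx],
    TechRepMixture = annotation$TechRepMixture[idx],
    Condition     = annotation$Condition[idx],
    BioReplicate  = annotation$BioReplicate[idx],
    log2Intensity = log2(records$Intensity),
    stringsAsFactors = FALSE)
  design <- experiment_design(annotation)
  flagged <- .flag_untestable(ft)
  structure(ft, design = design, flagged_proteins = flagged,
            class = c("tmt_feature_table", "data.frame"))
}

## Proteins for which "more than one summary value in more than one
## condition" cannot hold even with complete summarization success.
.flag_untestable <- function(ft) {
  obs <- ft[!is.na(ft$log2Intensity) & ft$Condition != "Norm", ]
  if (nrow(obs) == 0) return(unique(ft$ProteinName))
  slots <- unique(obs[, c("ProteinName", "Condition", "Run", "Channel")])
  tab <- table(slots$ProteinName, slots$Condition)
  ok <- rowSums(tab > 1) > 1
  c(setdiff(unique(ft$ProteinName), rownames(tab)), rownames(tab)[!ok])
}

#' Summarize the experimental design from an annotation
#'
#' @param annotation Validated annotation table.
#' @return List with elements `M` (number of mixtures), `T` (named vector of
#'   technical replicate counts per mixture), `conditions` (excluding
#'   `"Norm"`), `bioreps` (condition x mixture table of biological replicate
#'   counts), `has_reference`, and `balanced`.
#' @export
experiment_design <- function(annotation) {
  annotation <- validate_annotation(annotation)
  mixtures <- sort(unique(annotation$Mixture))
  runs <- unique(annotation[, c("Run", "Mixture", "TechRepMixture")])
  Tm <- vapply(mixtures,
               function(m) length(unique(runs$TechRepMixture[runs$Mixture == m])),
               integer(1))
  names(Tm) <- mixtures
  endo <- annotation[!annotation$IsReference, , drop = FALSE]
  conditions <- sort(unique(endo$Condition))
  bio <- unique(endo[, c("Mixture", "Condition", "BioReplicate")])
  btab <- table(bio$Condition, bio$Mixture)
  balanced <- length(unique(as.vector(btab))) == 1
  list(M = length(mixtures), T = Tm, conditions = conditions,
       bioreps = btab, has_reference = any(annotation$IsReference),
       balanced = balanced)
}

#' Write / read a feature table as TSV
#'
#' `write_feature_table()` stores the long-format table with full precision
#' so that `read_feature_table()` round-trips bit-for-bit.
#'
#' @param ft A `tmt_feature_table`.
#' @param path Output/input path.
#' @return `read_feature_table()` returns the feature table (design
#'   attributes are reconstructed from the table itself).
#' @export
write_feature_table <- function(ft, path) {
  out <- as.data.frame(ft)
  out$log2Intensity <- sprintf("%.17g", out$log2Intensity)
  out$log2Intensity[out$log2Intensity == "NA"] <- "NA"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(log2Intensity = "character"),
                   check.names = FALSE)
  df$log2Intensity <- as.numeric(df$log2Intensity)
  for (cl in setdiff(names(df), "log2Intensity")) df[[cl]] <- as.character(df[[cl]])
  ann <- unique(df[, c("Run", "Channel", "Condition", "BioReplicate",
                       "Mixture", "TechRepMixture")])
  structure(df, design = experiment_design(ann),
            flagged_proteins = .flag_untestable(df),
            class = c("tmt_feature_table", "data.frame"))
}
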