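#' Target-decoy q-values
#'
#' Concatenated target-decoy estimation: FDR(t) = #decoys at or above t over
#' max(1, #targets at or above t), optionally with the +1 decoy correction;
#' q is the minimum FDR over all thresholds at or below the PSM's score, so
#' q-values are non-increasing in score.
#'
#' @param psms PSM data.frame with `hyperscore` and `is_decoy` columns.
#' @param plus_one apply the +1 decoy correction to the numerator.
#' @return the input with `q_value` filled (decoys get the q of their
#'   threshold too).
#' @export
qvalues <- function(psms, plus_one = FALSE) {
  n <- nrow(psms)
  if (n == 0L) return(psms)
  if (!any(psms$is_decoy)) {
    warning("no decoy PSMs present; all q-values set to 0")
    psms$q_value <- 0
    return(psms)
  }
  o <- order(psms$hyperscore, decreasing = TRUE)
  dec <- cumsum(psms$is_decoy[o]) + as.integer(plus_one)
  tgt <- cumsum(!psms$is_decoy[o])
  fdr <- dec / pmax(tgt, 1)
  # equal scores share the FDR of the last tied entry
  s <- psms$hyperscore[o]
  for (i in rev(seq_len(n - 1L))) if (s[i] == s[i + 1L]) fdr[i] <- fdr[i + 1L]
  q <- rev(cummin(rev(fdr)))
  psms$q_value[o] <- q
  psms
}

#' Filter identifications at an FDR threshold
#'
#' Keeps target PSMs with q at or below the threshold; decoys are dropped
#' from the report. At the peptide level, each peptide group (sequence plus
#' modification set, including the labile offset label) is represented by
#' its best-scoring PSM before filtering.
#'
#' @param psms PSM data.frame with q-values (see [qvalues()]).
#' @param level `"psm"` or `"peptide"`.
#' @param threshold FDR threshold in (0, 1].
#' @return filtered data.frame.
#' @export
filter_fdr <- function(psms, level = c("psm", "peptide"), threshold = 0.01) {
  level <- match.arg(level)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (nrow(psms) == 0L) return(psms)
  if (level == "peptide") {
    key <- paste(psms$peptide, psms$mods, psms$offset_label,
                 psms$labile_offset, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(psms)), key), function(ii) {
      ii[order(-psms$hyperscore[ii])][1]
    }), use.names = FALSE)
    psms <- psms[sort(keep), , drop = FALSE]
  }
  out <- psms[!psms$is_decoy & psms$q_value <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the PSM report table
#'
#' Tab-separated, UTF-8, '.' decimal separator, fixed column order.
#'
#' @param psms PSM data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  cols <- c("scan", "peptide", "mods", "labile_offset", "offset_label",
            "charge", "precursor_delta_ppm", "hyperscore", "delta_score",
            "matched_b", "matched_y", "remainder_evidence",
            "localization_site", "localization_scores", "is_decoy", "q_value")
  missing <- setdiff(cols, names(psms))
  if (length(missing) > 0L) {
    stop("PSM table lacks column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.table(psms[, cols, drop = FALSE], file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a PSM report written by [write_psm_table()]
#'
#' @param path TSV path.
#' @return PSM data.frame.
#' @export
read_psm_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(scan = "character", mods = "character",
                                   offset_label = "character",
                                   remainder_evidence = "character",
                                   localization_scores = "character"))
}
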