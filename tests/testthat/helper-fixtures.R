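# Fixture builders; everything is generated in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

fx_random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Tryptic-friendly random proteome: K/R sprinkled so digests yield peptides
# in the searched length range.
fx_proteins <- function(n, seed = 1, min_len = 40, max_len = 80) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    res <- sample(AA20, len, replace = TRUE)
    cut <- seq(10, len - 1, by = sample(8:14, 1))
    res[cut] <- sample(c("K", "R"), length(cut), replace = TRUE)
    res[len] <- sample(c("K", "R"), 1)
    paste(res, collapse = "")
  }, character(1))
  data.frame(accession = sprintf("PROT%03d", seq_len(n)), description = "",
             sequence = seqs, is_decoy = FALSE, stringsAsFactors = FALSE)
}

fx_write_fasta <- function(proteins, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(c(paste0(">", proteins$accession[i], " ",
                        proteins$description[i]),
                 proteins$sequence[i]), con)
  }
  path
}

fx_phospho_spec <- function(max_per_peptide = 1L,
                            fragment_remainders = -18.01056,
                            diagnostic_mz = numeric(0),
                            diagnostic_min_intensity = 0) {
  labile_mod_spec("phospho", 79.96633, c("S", "T", "Y"),
                  max_per_peptide = max_per_peptide,
                  diagnostic_mz = diagnostic_mz,
                  diagnostic_min_intensity = diagnostic_min_intensity,
                  fragment_remainders = fragment_remainders)
}

# Minimal mzML document with optional zlib-compressed peak arrays.
fx_write_mzml <- function(path, spectra, ms1 = TRUE, compress = FALSE) {
  enc <- function(x) {
    raw <- writeBin(as.numeric(x), raw(), size = 8, endian = "little")
    if (compress) raw <- memCompress(raw, type = "gzip")
    jsonlite::base64_enc(raw)
  }
  comp_cv <- if (compress) {
    '<cvParam accession="MS:1000574" name="zlib compression" value=""/>'
  } else {
    '<cvParam accession="MS:1000576" name="no compression" value=""/>'
  }
  arr <- function(x, acc, name) {
    paste0('<binaryDataArray encodedLength="0">',
           '<cvParam accession="MS:1000523" name="64-bit float" value=""/>',
           comp_cv,
           sprintf('<cvParam accession="%s" name="%s" value=""/>', acc, name),
           '<binary>', enc(x), '</binary></binaryDataArray>')
  }
  blocks <- character(0)
  if (ms1) {
    blocks <- paste0(
      '<spectrum id="scan=1" index="0" defaultArrayLength="2">',
      '<cvParam accession="MS:1000511" name="ms level" value="1"/>',
      '<binaryDataArrayList count="2">',
      arr(c(400.1, 500.2), "MS:1000514", "m/z array"),
      arr(c(10, 20), "MS:1000515", "intensity array"),
      '</binaryDataArrayList></spectrum>')
  }
  for (s in spectra) {
    blocks <- c(blocks, paste0(
      sprintf('<spectrum id="%s" index="%d" defaultArrayLength="%d">',
              s$scan, length(blocks), length(s$mz)),
      '<cvParam accession="MS:1000511" name="ms level" value="2"/>',
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon>',
      sprintf('<cvParam accession="MS:1000744" name="selected ion m/z" value="%.6f"/>',
              s$premz),
      sprintf('<cvParam accession="MS:1000041" name="charge state" value="%d"/>',
              s$z),
      '</selectedIon></selectedIonList></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      arr(s$mz, "MS:1000514", "m/z array"),
      arr(s$intensity, "MS:1000515", "intensity array"),
      '</binaryDataArrayList></spectrum>'))
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="run1"><spectrumList count="', length(blocks), '">',
    paste(blocks, collapse = ""), '</spectrumList></run></mzML>')
  writeLines(doc, path)
  path
}

# Search + FDR convenience used by the mode-comparison tests.
fx_run_search <- function(spectra, db, params, threshold = 0.01,
                          preprocess_args = list()) {
  psms <- search_dataset(spectra, db, params,
                         preprocess_args = preprocess_args)
  if (nrow(psms) == 0L) return(list(psms = psms, accepted = psms))
  psms <- suppressWarnings(qvalues(psms))
  list(psms = psms, accepted = filter_fdr(psms, threshold = threshold))
}

fx_psms_for_benchmark <- function(scan) {
  data.frame(scan = scan, peptide = "PEPK", mods = "", labile_offset = 80,
             offset_label = "x", charge = 2L, precursor_delta_ppm = 0,
             hyperscore = 10, delta_score = 1, matched_b = 4L,
             matched_y = 4L, remainder_evidence = "",
             localization_site = 1L, localization_scores = "",
             is_decoy = FALSE, q_value = 0, stringsAsFactors = FALSE)
}

# Count accepted PSMs whose peptide matches the simulator's truth.
fx_true_count <- function(accepted, truth) {
  if (nrow(accepted) == 0L) return(0L)
  m <- match(accepted$scan, truth$scan)
  sum(!is.na(m) & accepted$peptide == truth$peptide[m])
}
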