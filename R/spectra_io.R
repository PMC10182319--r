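#' Construct a centroided MS2 spectrum
#'
#' @param scan scan identifier (character scalar).
#' @param premz precursor m/z in Dalton.
#' @param z precursor charge, integer >= 1.
#' @param mz,intensity numeric peak vectors; peaks are sorted ascending by m/z
#'   on construction.
#' @param activation free-text activation label (e.g. "HCD").
#' @return an object of class `ltm_spectrum`.
#' @export
spectrum <- function(scan, premz, z, mz, intensity, activation = "HCD") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0L) {
    if (any(mz <= 0)) stop("peak m/z must be > 0")
    if (any(intensity < 0)) stop("peak intensity must be >= 0")
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  structure(list(scan = as.character(scan), premz = as.numeric(premz),
                 z = as.integer(z), activation = activation,
                 mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "ltm_spectrum")
}

#' @export
print.ltm_spectrum <- function(x, ...) {
  cat(sprintf("<ltm_spectrum %s  %d+  m/z %.4f  %d peaks>\n",
              x$scan, x$z, x$premz, length(x$mz)))
  invisible(x)
}

#' Precursor neutral mass of a spectrum
#'
#' @param s an `ltm_spectrum`.
#' @return z * (precursor m/z - proton mass).
#' @export
precursor_neutral_mass <- function(s) {
  s$z * (s$premz - PROTON_MASS)
}

#' Read spectra from MGF or mzML
#'
#' One `ltm_spectrum` per MS2 scan; MS1 scans are skipped. MGF entries with no
#' CHARGE line are emitted once per charge in `assumed_charges`, sharing their
#' scan id.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mgf"` or `"mzml"`.
#' @param assumed_charges integer vector of charges assumed when an entry
#'   carries none.
#' @return list of `ltm_spectrum`.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml"),
                         assumed_charges = c(2L, 3L)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", mzml = "mzml",
                     stop("cannot infer spectrum format from extension '",
                          ext, "'"))
  }
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (format == "mgf") read_mgf(path, assumed_charges = assumed_charges)
  else read_mzml(path, assumed_charges = assumed_charges)
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path, assumed_charges = c(2L, 3L)) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("garbled MGF (unbalanced BEGIN/END IONS) in ", path)
  }
  out <- list()
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    hdr <- block[kv]
    keys <- sub("=.*$", "", hdr)
    vals <- sub("^[^=]*=", "", hdr)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else paste0("scan_", k)
    if (!"PEPMASS" %in% keys) stop("MGF entry '", title, "' lacks PEPMASS")
    premz <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "[ \t]+")[[1]][1])
    if (is.na(premz)) stop("unparseable PEPMASS in MGF entry '", title, "'")
    charges <- if ("CHARGE" %in% keys) {
      ch <- as.integer(gsub("[^0-9]", "", vals[match("CHARGE", keys)]))
      if (is.na(ch)) stop("unparseable CHARGE in MGF entry '", title, "'")
      ch
    } else as.integer(assumed_charges)
    pk <- block[!kv]
    pk <- pk[nzchar(trimws(pk))]
    if (length(pk) > 0L) {
      m <- do.call(rbind, strsplit(trimws(pk), "[ \t]+"))
      mz <- as.numeric(m[, 1]); it <- as.numeric(m[, 2])
      if (anyNA(mz) || anyNA(it)) stop("unparseable peak line in MGF entry '", title, "'")
    } else {
      mz <- numeric(0); it <- numeric(0)
    }
    for (z in charges) {
      out[[length(out) + 1L]] <- spectrum(title, premz, z, mz, it)
    }
  }
  out
}

#' Write spectra to MGF
#'
#' @param spectra list of `ltm_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$scan),
                 sprintf("PEPMASS=%.6f", s$premz),
                 sprintf("CHARGE=%d+", s$z)), con)
    if (length(s$mz) > 0L) {
      writeLines(sprintf("%.6f %.4f", s$mz, s$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

# Decode one mzML <binaryDataArray> node: base64, optional zlib, 32/64-bit.
.decode_binary_array <- function(node, ns) {
  cvs <- xml2::xml_find_all(node, ".//d1:cvParam", ns)
  accs <- xml2::xml_attr(cvs, "accession")
  is64 <- "MS:1000523" %in% accs
  is32 <- "MS:1000521" %in% accs
  zlib <- "MS:1000574" %in% accs
  b64 <- xml2::xml_text(xml2::xml_find_first(node, ".//d1:binary", ns))
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  size <- if (is64 || !is32) 8L else 4L
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = "little")
}

#' @rdname read_spectra
#' @export
read_mzml <- function(path, assumed_charges = c(2L, 3L)) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable mzML '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(d1 = xml2::xml_ns(doc)[[1]])
  scans <- xml2::xml_find_all(doc, "//d1:spectrum", ns)
  out <- list()
  for (sc in scans) {
    lvl <- xml2::xml_find_first(
      sc, ".//d1:cvParam[@accession='MS:1000511']", ns)
    if (inherits(lvl, "xml_missing")) next
    if (xml2::xml_attr(lvl, "value") != "2") next
    id <- xml2::xml_attr(sc, "id")
    selected <- xml2::xml_find_first(sc, ".//d1:selectedIon", ns)
    if (inherits(selected, "xml_missing")) {
      stop("MS2 scan '", id, "' in ", path, " has no selected ion")
    }
    premz <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
      selected, ".//d1:cvParam[@accession='MS:1000744']", ns), "value"))
    zn <- xml2::xml_find_first(
      selected, ".//d1:cvParam[@accession='MS:1000041']", ns)
    charges <- if (inherits(zn, "xml_missing")) as.integer(assumed_charges)
               else as.integer(xml2::xml_attr(zn, "value"))
    arrays <- xml2::xml_find_all(sc, ".//d1:binaryDataArray", ns)
    mz <- numeric(0); it <- numeric(0)
    for (a in arrays) {
      accs <- xml2::xml_attr(xml2::xml_find_all(a, ".//d1:cvParam", ns),
                             "accession")
      v <- .decode_binary_array(a, ns)
      if ("MS:1000514" %in% accs) mz <- v
      if ("MS:1000515" %in% accs) it <- v
    }
    if (length(mz) != length(it)) {
      stop("m/z and intensity arrays disagree in scan '", id, "' of ", path)
    }
    for (z in charges) out[[length(out) + 1L]] <- spectrum(id, premz, z, mz, it)
  }
  out
}

#' Remove neutral-loss peaks dominated by their parent peak
#'
#' A peak p is removed iff some peak q exists with q.mz - loss within
#' tolerance of p.mz and p less intense than q, for any configured loss —
#' the engine-side counterpart of "neutral loss peaks that are less intense
#' than the corresponding nonloss peak are removed prior to search".
#' Tolerance is in ppm of the heavier (parent) peak. Idempotent.
#'
#' @param s an `ltm_spectrum`.
#' @param losses positive neutral-loss masses in Dalton.
#' @param tol_ppm matching tolerance in ppm.
#' @return filtered `ltm_spectrum`.
#' @export
remove_neutral_losses <- function(s, losses = default_neutral_losses(),
                                  tol_ppm = 20) {
  n <- length(s$mz)
  if (n == 0L || length(losses) == 0L) return(s)
  stopifnot(all(losses > 0))
  drop <- logical(n)
  for (loss in losses) {
    target <- s$mz - loss      # expected loss-peak position for each parent q
    tol <- tol_ppm * 1e-6 * s$mz
    for (q in seq_len(n)) {
      if (target[q] <= 0) next
      hits <- which(abs(s$mz - target[q]) <= tol[q])
      drop[hits[s$intensity[hits] < s$intensity[q]]] <- TRUE
    }
  }
  spectrum(s$scan, s$premz, s$z, s$mz[!drop], s$intensity[!drop],
           s$activation)
}

#' Collapse isotope envelopes to their monoisotopic peak
#'
#' Greedy envelope collapse: scanning peaks in descending intensity, peaks
#' spaced +k * 1.0033548/z (k = 1, 2; z = 1..max_charge) above a more intense
#' peak within tolerance, with intensity below `ratio_cap` times the
#' monoisotopic peak, are removed.
#'
#' @param s an `ltm_spectrum`.
#' @param max_charge maximum fragment charge considered for isotope spacing.
#' @param tol_ppm matching tolerance in ppm (of the heavier peak).
#' @param ratio_cap maximum successor/monoisotopic intensity ratio removed.
#' @return deisotoped `ltm_spectrum`.
#' @export
deisotope <- function(s, max_charge = 2L, tol_ppm = 10, ratio_cap = 1.0) {
  n <- length(s$mz)
  if (n < 2L) return(s)
  keep <- rep(TRUE, n)
  ord <- order(s$intensity, decreasing = TRUE)
  for (i in ord) {
    if (!keep[i]) next
    for (z in seq_len(max_charge)) {
      for (k in 1:2) {
        succ_mz <- s$mz[i] + k * ISOTOPE_SPACING / z
        tol <- tol_ppm * 1e-6 * succ_mz
        hits <- which(keep & abs(s$mz - succ_mz) <= tol &
                        s$intensity < s$intensity[i] &
                        s$intensity <= ratio_cap * s$intensity[i])
        keep[hits] <- FALSE
      }
    }
  }
  spectrum(s$scan, s$premz, s$z, s$mz[keep], s$intensity[keep], s$activation)
}

#' Default neutral losses removed before search
#'
#' Water, ammonia and phosphoric acid.
#' @return numeric vector of masses in Dalton.
#' @export
default_neutral_losses <- function() {
  k <- labile_constants()
  c(k$water, k$ammonia, k$phosphoric_acid)
}

#' Cap and normalize a spectrum for scoring
#'
#' Keeps the `n_max` most intense peaks, rescales so the base peak equals
#' `norm_ceiling`, and flags spectra with fewer than `min_peaks` peaks as
#' unsearchable. Diagnostic-ion gate thresholds are expressed on this
#' normalized scale.
#'
#' @param s an `ltm_spectrum`.
#' @param n_max maximum retained peaks.
#' @param min_peaks minimum peaks for a searchable spectrum.
#' @param norm_ceiling base-peak intensity after normalization.
#' @return an `ltm_processed_spectrum` (an `ltm_spectrum` with a `searchable`
#'   flag).
#' @export
preprocess_spectrum <- function(s, n_max = 150L, min_peaks = 5L,
                                norm_ceiling = 100) {
  stopifnot(n_max >= min_peaks, min_peaks >= 1L)
  mz <- s$mz; it <- s$intensity
  if (length(mz) > n_max) {
    keep <- order(it, decreasing = TRUE)[seq_len(n_max)]
    keep <- sort(keep)
    mz <- mz[keep]; it <- it[keep]
  }
  if (length(it) > 0L && max(it) > 0) it <- it * (norm_ceiling / max(it))
  out <- spectrum(s$scan, s$premz, s$z, mz, it, s$activation)
  out$searchable <- length(mz) >= min_peaks
  class(out) <- c("ltm_processed_spectrum", class(out))
  out
}
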