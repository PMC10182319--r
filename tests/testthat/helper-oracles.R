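# Independent oracles: deliberately simple, loop-based re-implementations of
# the documented contracts, kept free of the package's vectorized code paths.

# Brute-force digest: every substring whose boundaries are valid cut points
# (start of protein or after K/R; end of protein or after K/R) with at most
# `missed` internal cut sites, plus Met-clipped variants of N-terminal
# peptides.
oracle_digest <- function(sequence, missed, min_len, max_len,
                          clip_met = TRUE) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cuts <- which(res %in% c("K", "R"))          # cleavage after these
  is_start <- c(TRUE, seq_len(n - 1) %in% cuts) # residue i starts a peptide
  is_end <- seq_len(n) %in% c(cuts, n)          # residue j ends a peptide
  out <- character(0)
  for (i in which(is_start)) {
    for (j in which(is_end)) {
      if (j < i) next
      internal <- sum(cuts >= i & cuts < j)
      if (internal > missed) next
      len <- j - i + 1
      if (len >= min_len && len <= max_len) {
        out <- c(out, substr(sequence, i, j))
      }
      if (clip_met && i == 1 && res[1] == "M" && j >= 2) {
        len2 <- j - 1
        if (len2 >= min_len && len2 <= max_len) {
          out <- c(out, substr(sequence, 2, j))
        }
      }
    }
  }
  sort(unique(out))
}

# Independent residue table (published monoisotopic values, 5 dp) for
# checking mass arithmetic without reusing the package's element table.
ORACLE_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

oracle_peptide_mass <- function(sequence) {
  sum(ORACLE_RESIDUE[strsplit(sequence, "")[[1]]]) + 18.01056
}

# Greedy unique matching, linear scan: ions visited in ascending m/z within
# each series pool; nearest unused peak within ppm tolerance wins.
oracle_match <- function(peak_mz, ion_mz, tol_ppm, used = NULL) {
  if (is.null(used)) used <- rep(FALSE, length(peak_mz))
  out <- rep(NA_integer_, length(ion_mz))
  for (i in order(ion_mz)) {
    tol <- tol_ppm * 1e-6 * ion_mz[i]
    best <- NA_integer_; bestd <- Inf
    for (p in seq_along(peak_mz)) {
      if (used[p]) next
      d <- abs(peak_mz[p] - ion_mz[i])
      if (d <= tol && d < bestd) { best <- p; bestd <- d }
    }
    if (!is.na(best)) { out[i] <- best; used[best] <- TRUE }
  }
  out
}

# Direct-formula hyperscore over an ion table (columns series, mz) plus
# optional peptide-remainder m/z values.
oracle_hyperscore <- function(s, ions, tol_ppm, rem_mz = numeric(0)) {
  matched <- rep(NA_integer_, nrow(ions))
  for (sr in unique(ions$series)) {
    sel <- which(ions$series == sr)
    matched[sel] <- oracle_match(s$mz, ions$mz[sel], tol_ppm)
  }
  hit <- !is.na(matched)
  pre <- hit & ions$series %in% c("b", "c")
  suf <- hit & ions$series %in% c("y", "z")
  n_pre <- sum(pre); n_suf <- sum(suf)
  sum_pre <- sum(s$intensity[matched[pre]])
  sum_suf <- sum(s$intensity[matched[suf]])
  if (length(rem_mz) > 0) {
    pm <- oracle_match(s$mz, rem_mz, tol_ppm)
    sum_suf <- sum_suf + sum(s$intensity[pm[!is.na(pm)]])
  }
  log10(factorial(min(n_pre, 64)) * factorial(min(n_suf, 64)) *
          max(sum_pre, 1) * max(sum_suf, 1))
}

# Theoretical singly charged b/y ions by explicit summation (prefix/suffix
# loops, no cumsum), using the package residue constants.
oracle_by_ions <- function(sequence, site_deltas = numeric(nchar(sequence)),
                           charge = 1L) {
  rm <- labileMS::residue_masses()
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  rows <- list()
  for (i in 1:(n - 1)) {
    b <- 0
    for (k in 1:i) b <- b + rm[[res[k]]] + site_deltas[k]
    y <- 18.0105646837  # H2O
    for (k in (n - i + 1):n) y <- y + rm[[res[k]]] + site_deltas[k]
    for (z in seq_len(charge)) {
      rows[[length(rows) + 1L]] <- data.frame(
        series = c("b", "y"), ordinal = i, charge = z,
        mz = c((b + z * 1.00727646688) / z, (y + z * 1.00727646688) / z))
    }
  }
  do.call(rbind, rows)
}

# Brute-force q-values: FDR at every threshold, take the running minimum.
oracle_qvalues <- function(scores, is_decoy) {
  vapply(seq_along(scores), function(i) {
    ts <- sort(unique(scores[scores <= scores[i]]))
    min(vapply(ts, function(t) {
      d <- sum(is_decoy & scores >= t)
      g <- sum(!is_decoy & scores >= t)
      d / max(g, 1)
    }, numeric(1)))
  }, numeric(1))
}

# Exhaustive reference search: no index, plain loops, one labile spec.
# Mirrors the documented algorithm (gate, offsets, complete-loss vs remainder
# pathways, tie-breaks) with independent candidate retrieval and scoring.
oracle_ref_search <- function(s, peptides, spec, params) {
  stopifnot(length(params$labile_specs) <= 1L)
  prec <- s$z * (s$premz - 1.00727646688)
  tol <- params$precursor_tol_ppm * 1e-6 * prec
  gate <- TRUE
  if (!is.null(spec) && spec$diagnostic_min_intensity > 0 &&
      length(spec$diagnostic_mz) > 0) {
    total <- 0
    for (dmz in spec$diagnostic_mz) {
      dd <- abs(s$mz - dmz)
      ok <- which(dd <= params$fragment_tol_ppm * 1e-6 * dmz)
      if (length(ok) > 0) total <- total + s$intensity[ok[which.min(dd[ok])]]
    }
    gate <- total >= spec$diagnostic_min_intensity
  }
  offsets <- 0
  counts <- 0L
  if (!is.null(spec) && gate && params$mode != "nonlabile") {
    for (k in seq_len(spec$max_per_peptide)) {
      offsets <- c(offsets, k * spec$offset)
      counts <- c(counts, k)
    }
  }
  best <- NULL
  for (oi in seq_along(offsets)) {
    for (pi in seq_len(nrow(peptides))) {
      if (abs(prec - offsets[oi] - peptides$mass[pi]) > tol) next
      sq <- peptides$sequence[pi]
      ions <- oracle_by_ions(sq, charge = if (s$z <= 2) 1L else 2L)
      cand_scores <- numeric(0)
      details <- list()
      if (counts[oi] == 0L) {
        sc <- oracle_hyperscore(s, ions, params$fragment_tol_ppm)
        cand_scores <- sc
        details <- list(list(site = NA, nmatch = NA))
      } else {
        rem_mz <- if (length(spec$peptide_remainders) > 0) {
          unlist(lapply(seq_len(s$z), function(z) {
            (peptides$mass[pi] + spec$peptide_remainders +
               z * 1.00727646688) / z
          }))
        } else numeric(0)
        base_sc <- oracle_hyperscore(s, ions, params$fragment_tol_ppm, rem_mz)
        sc <- base_sc
        if (counts[oi] == 1L && length(spec$fragment_remainders) > 0) {
          sites <- if ("*" %in% spec$residues) seq_len(nchar(sq)) else
            which(strsplit(sq, "")[[1]] %in% spec$residues)
          n <- nchar(sq)
          for (site in sites) {
            for (r in spec$fragment_remainders) {
              cover <- ifelse(ions$series == "b", site <= ions$ordinal,
                              site >= n - ions$ordinal + 1)
              v <- ions[cover, , drop = FALSE]
              v$mz <- v$mz + r / v$charge
              sc2 <- oracle_hyperscore(s, rbind(ions, v),
                                       params$fragment_tol_ppm, rem_mz)
              if (sc2 > sc) sc <- sc2
            }
          }
        }
        cand_scores <- sc
        details <- list(list(site = NA, nmatch = NA))
      }
      rec <- list(sequence = sq, score = cand_scores,
                  n_mods = counts[oi], labile = counts[oi] > 0)
      if (is.null(best) ||
          rec$score > best$score + 1e-12 ||
          (abs(rec$score - best$score) <= 1e-12 &&
             (rec$n_mods < best$n_mods ||
                (rec$n_mods == best$n_mods && !rec$labile && best$labile) ||
                (rec$n_mods == best$n_mods && rec$labile == best$labile &&
                   rec$sequence < best$sequence)))) {
        best <- rec
      }
    }
  }
  best
}
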