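#' Define a labile modification for search
#'
#' @param label short label (e.g. "phospho", "ADPr").
#' @param offset modification (offset) mass in Dalton; must be nonzero.
#' @param residues allowed residues (single letters; `"*"` means any residue,
#'   `"n^"` the peptide N terminus).
#' @param max_per_peptide maximum copies per peptide (offsets for k copies
#'   are k * offset).
#' @param diagnostic_mz diagnostic-ion m/z values (matched verbatim; many
#'   published values follow the hydrogen-atom convention).
#' @param diagnostic_min_intensity minimum summed diagnostic intensity, on
#'   the normalized scale of [preprocess_spectrum()]; 0 disables gating.
#' @param peptide_remainders neutral remainder masses added to the intact
#'   peptide mass.
#' @param fragment_remainders remainder masses (may be negative) added to
#'   site-covering backbone fragments; used for localization.
#' @return an `ltm_labile_spec`.
#' @export
labile_mod_spec <- function(label, offset, residues = "*",
                            max_per_peptide = 1L, diagnostic_mz = numeric(0),
                            diagnostic_min_intensity = 0,
                            peptide_remainders = numeric(0),
                            fragment_remainders = numeric(0)) {
  if (offset == 0) stop("labile offset mass must be nonzero")
  if (max_per_peptide < 1L) stop("max_per_peptide must be >= 1")
  if (diagnostic_min_intensity < 0) stop("diagnostic threshold must be >= 0")
  structure(list(label = label, offset = offset, residues = residues,
                 max_per_peptide = as.integer(max_per_peptide),
                 diagnostic_mz = diagnostic_mz,
                 diagnostic_min_intensity = diagnostic_min_intensity,
                 peptide_remainders = peptide_remainders,
                 fragment_remainders = fragment_remainders),
            class = "ltm_labile_spec")
}

#' Search parameter set
#'
#' @param precursor_tol_ppm,fragment_tol_ppm mass tolerances in ppm.
#' @param mode `"nonlabile"`, `"labile"` or `"hybrid"`.
#' @param series fragment series searched (subset of b/y/c/z; HCD-style
#'   searches use b/y only, AIETD-style add c/z).
#' @param fixed_mods named residue-delta vector.
#' @param var_mods list of [variable_mod()].
#' @param max_var cap on placed variable modifications per peptide.
#' @param labile_specs list of [labile_mod_spec()]; required for labile and
#'   hybrid modes, forbidden in nonlabile mode.
#' @param total_mod_cap cap on placed + offset modifications in hybrid mode.
#' @param min_matched minimum matched backbone fragments for a reportable
#'   PSM.
#' @param isotope_errors precursor isotope errors considered (multiples of
#'   the 13C spacing subtracted from the observed precursor mass).
#' @param max_frag_charge `NA` to use 1 for precursor z <= 2 and 2 above.
#' @return an `ltm_search_params`.
#' @export
search_params <- function(precursor_tol_ppm = 20, fragment_tol_ppm = 10,
                          mode = c("labile", "nonlabile", "hybrid"),
                          series = c("b", "y"), fixed_mods = NULL,
                          var_mods = list(), max_var = 3L,
                          labile_specs = list(), total_mod_cap = max_var,
                          min_matched = 4L, isotope_errors = c(0L, 1L, 2L),
                          max_frag_charge = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0)
  if (mode != "nonlabile" && length(labile_specs) == 0L) {
    stop("mode '", mode, "' requires at least one labile_mod_spec")
  }
  if (mode == "nonlabile" && length(labile_specs) > 0L) {
    stop("nonlabile mode must not carry labile_mod_spec blocks")
  }
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm, mode = mode,
                 series = series, fixed_mods = fixed_mods,
                 var_mods = var_mods, max_var = as.integer(max_var),
                 labile_specs = labile_specs,
                 total_mod_cap = as.integer(total_mod_cap),
                 min_matched = as.integer(min_matched),
                 isotope_errors = as.integer(isotope_errors),
                 max_frag_charge = max_frag_charge),
            class = "ltm_search_params")
}

.frag_charge_for <- function(params, precursor_z) {
  if (!is.na(params$max_frag_charge)) return(as.integer(params$max_frag_charge))
  if (precursor_z <= 2L) 1L else 2L
}

#' Diagnostic-ion gate
#'
#' TRUE iff the summed intensity of the nearest matching peak for each
#' configured diagnostic m/z (within tolerance) reaches the spec's threshold.
#' Spectra failing the gate are searched for zero-offset candidates only.
#'
#' @param s a preprocessed spectrum.
#' @param spec an `ltm_labile_spec`.
#' @param tol_ppm matching tolerance in ppm.
#' @return logical scalar.
#' @export
diagnostic_gate <- function(s, spec, tol_ppm = 10) {
  if (spec$diagnostic_min_intensity <= 0) return(TRUE)
  if (length(spec$diagnostic_mz) == 0L) return(TRUE)
  total <- 0
  for (dmz in spec$diagnostic_mz) {
    tol <- tol_ppm * 1e-6 * dmz
    hits <- which(abs(s$mz - dmz) <= tol)
    if (length(hits) > 0L) {
      nearest <- hits[which.min(abs(s$mz[hits] - dmz))]
      total <- total + s$intensity[nearest]
    }
  }
  total >= spec$diagnostic_min_intensity
}

# Offset rows permitted for a spectrum given per-spec gate results. Mixed
# multi-spec offsets require every involved spec's gate to pass.
.allowed_offsets <- function(labile_specs, mode, gate) {
  tbl <- .offset_table(labile_specs, mode)
  if (nrow(tbl) == 0L || mode == "nonlabile") return(tbl)
  keep <- vapply(seq_len(nrow(tbl)), function(r) {
    if (tbl$count[r] == 0L) return(TRUE)
    used <- tbl$spec_used[[r]]
    all(gate[used])
  }, logical(1))
  tbl[keep, , drop = FALSE]
}

#' Candidate peptides for a spectrum at each allowed mass offset
#'
#' For each allowed offset o (0 always; labile count-multiples only when the
#' corresponding diagnostic gate passed), returns index entries with
#' |precursor_neutral - o - entry_mass| within the precursor tolerance.
#'
#' @param s an `ltm_spectrum`.
#' @param idx an `ltm_mass_index`.
#' @param specs list of `ltm_labile_spec`.
#' @param mode search mode.
#' @param tol_ppm precursor tolerance in ppm (of the observed precursor
#'   neutral mass).
#' @param gate_result logical vector, one per spec (as from
#'   [diagnostic_gate()]).
#' @return data.frame of entries with added `offset`, `offset_label`,
#'   `offset_count`, `offset_spec` columns.
#' @export
candidates_for <- function(s, idx, specs, mode = "labile", tol_ppm = 20,
                           gate_result = rep(TRUE, length(specs))) {
  prec <- precursor_neutral_mass(s)
  tol <- tol_ppm * 1e-6 * prec
  offs <- .allowed_offsets(specs, mode, gate_result)
  out <- list()
  for (r in seq_len(nrow(offs))) {
    hits <- query_index(idx, prec - offs$offset[r] - tol,
                        prec - offs$offset[r] + tol)
    if (nrow(hits) == 0L) next
    hits$offset <- offs$offset[r]
    hits$offset_label <- offs$label[r]
    hits$offset_count <- offs$count[r]
    hits$offset_spec <- offs$spec_idx[r]
    out[[length(out) + 1L]] <- hits
  }
  if (length(out) == 0L) {
    empty <- idx$entries[0, , drop = FALSE]
    empty$offset <- numeric(0); empty$offset_label <- character(0)
    empty$offset_count <- integer(0); empty$offset_spec <- integer(0)
    return(empty)
  }
  do.call(rbind, out)
}

# Greedy unique matching of theoretical m/z values against a sorted peak
# list. Ions are visited in ascending m/z; each ion takes the nearest (by
# ppm) unused peak within tolerance. Uniqueness is enforced within one pool.
# Returns the matched peak index per ion (NA if unmatched).
.match_pool <- function(peak_mz, ion_mz, tol_ppm, used = NULL) {
  np <- length(peak_mz)
  match_idx <- rep(NA_integer_, length(ion_mz))
  if (np == 0L || length(ion_mz) == 0L) return(match_idx)
  if (is.null(used)) used <- logical(np)
  ord <- order(ion_mz)
  for (i in ord) {
    tol <- tol_ppm * 1e-6 * ion_mz[i]
    lo <- ion_mz[i] - tol; hi <- ion_mz[i] + tol
    a <- findInterval(lo, peak_mz, left.open = TRUE) + 1L
    b <- findInterval(hi, peak_mz)
    if (b < a) next
    cand <- a:b
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) next
    best <- cand[which.min(abs(peak_mz[cand] - ion_mz[i]))]
    match_idx[i] <- best
    used[best] <- TRUE
  }
  match_idx
}

#' Hyperscore a spectrum against a theoretical ion list
#'
#' X!Tandem-style score: ions are greedily matched to their nearest peak
#' within tolerance (each peak used at most once per fragment series); with
#' N_b, N_y the matched prefix-series (b/c) and suffix-series (y/z) counts
#' and sum(I) the matched intensity sums,
#' score = log10(N_b! * N_y! * max(sum I_b, 1) * max(sum I_y, 1)).
#' Factorial counts are capped at 64 and evaluated via log-gamma. Remainder
#' ion variants count toward their parent series; matched peptide-remainder
#' peaks contribute intensity to the suffix sum but no counts.
#'
#' @param s a preprocessed spectrum.
#' @param ions data.frame from [theoretical_ions()] (optionally with
#'   remainder variants appended).
#' @param tol_ppm fragment tolerance in ppm.
#' @param remainder_peaks optional data.frame from [peptide_remainder_mzs()].
#' @return list with `score`, `n_prefix`, `n_suffix`, `sum_prefix`,
#'   `sum_suffix`, `n_remainder_frag` (matched fragment-remainder variants),
#'   `pep_remainder_int`, `pep_remainder_n`, and `matched` (per-ion peak
#'   index).
#' @export
hyperscore <- function(s, ions, tol_ppm = 10, remainder_peaks = NULL) {
  matched <- rep(NA_integer_, nrow(ions))
  for (sr in unique(ions$series)) {
    sel <- ions$series == sr
    matched[sel] <- .match_pool(s$mz, ions$mz[sel], tol_ppm)
  }
  hit <- !is.na(matched)
  pre <- hit & ions$series %in% c("b", "c")
  suf <- hit & ions$series %in% c("y", "z")
  n_pre <- sum(pre); n_suf <- sum(suf)
  sum_pre <- sum(s$intensity[matched[pre]])
  sum_suf <- sum(s$intensity[matched[suf]])
  pep_int <- 0; pep_n <- 0L
  if (!is.null(remainder_peaks) && nrow(remainder_peaks) > 0L) {
    pm <- .match_pool(s$mz, remainder_peaks$mz, tol_ppm)
    pep_n <- sum(!is.na(pm))
    pep_int <- sum(s$intensity[pm[!is.na(pm)]])
  }
  sum_suf_eff <- sum_suf + pep_int
  score <- (lgamma(min(n_pre, 64L) + 1) + lgamma(min(n_suf, 64L) + 1) +
              log(max(sum_pre, 1)) + log(max(sum_suf_eff, 1))) / log(10)
  list(score = score, n_prefix = n_pre, n_suffix = n_suf,
       sum_prefix = sum_pre, sum_suffix = sum_suf,
       n_remainder_frag = sum(hit & ions$remainder != 0),
       pep_remainder_int = pep_int, pep_remainder_n = pep_n,
       matched = matched)
}

# Allowed labile sites of `spec` on a sequence.
.labile_sites <- function(sequence, spec) {
  if ("*" %in% spec$residues) return(seq_len(nchar(sequence)))
  .allowed_positions(sequence, spec$residues)
}

#' Score a labile (mass-offset) candidate
#'
#' Computes the complete-loss pathway (base ions plus peptide-remainder
#' evidence) and, for each configured fragment remainder and each allowed
#' site, the pathway with remainder variants at that site; returns the best,
#' with exact ties broken toward complete loss. Per-site best scores are
#' retained for localization. Multi-copy or mixed-modification offsets score
#' through the complete-loss pathway only and are never localized.
#'
#' @param s a preprocessed spectrum.
#' @param f an `ltm_modform` with nonzero offset.
#' @param spec the generating `ltm_labile_spec` (or NULL for mixed offsets).
#' @param params an `ltm_search_params`.
#' @return list: `score`, `detail` (best pathway's [hyperscore()] result),
#'   `pathway` (`"complete_loss"` or `"remainder"`), `site_scores` (named
#'   numeric, or NULL), `site_rem_matched` (remainder-variant matches per
#'   site), `best_site` (NA unless a remainder pathway won).
#' @export
score_labile <- function(s, f, spec, params) {
  stopifnot(f$offset != 0)
  maxz <- .frag_charge_for(params, s$z)
  ions <- theoretical_ions(f, params$series, maxz, params$fixed_mods)
  rem_peaks <- NULL
  if (!is.null(spec) && length(spec$peptide_remainders) > 0L) {
    rem_peaks <- peptide_remainder_mzs(f, spec$peptide_remainders,
                                       charges = seq_len(s$z))
  }
  base <- hyperscore(s, ions, params$fragment_tol_ppm, rem_peaks)
  best <- list(score = base$score, detail = base, pathway = "complete_loss",
               site_scores = NULL, site_rem_matched = NULL,
               best_site = NA_integer_)
  if (is.null(spec) || f$offset_count != 1L ||
      length(spec$fragment_remainders) == 0L) {
    return(best)
  }
  sites <- .labile_sites(f$sequence, spec)
  if (length(sites) == 0L) return(best)
  site_scores <- stats::setNames(rep(base$score, length(sites)),
                                 as.character(sites))
  site_rem <- stats::setNames(integer(length(sites)), as.character(sites))
  for (si in seq_along(sites)) {
    for (r in spec$fragment_remainders) {
      variants <- apply_fragment_remainder(ions, f, sites[si], r)
      if (nrow(variants) == 0L) next
      sc <- hyperscore(s, rbind(ions, variants), params$fragment_tol_ppm,
                       rem_peaks)
      if (sc$score > site_scores[si] ||
          (sc$score == site_scores[si] && sc$n_remainder_frag > site_rem[si])) {
        site_scores[si] <- sc$score
        site_rem[si] <- sc$n_remainder_frag
        if (sc$score > best$score) {  # ties stay with complete loss
          best <- list(score = sc$score, detail = sc, pathway = "remainder",
                       site_scores = NULL, site_rem_matched = NULL,
                       best_site = sites[si])
        }
      }
    }
  }
  best$site_scores <- site_scores
  best$site_rem_matched <- site_rem
  best
}

#' Localize a labile modification from fragment-remainder evidence
#'
#' Reports the allowed site whose remainder-variant pathway scores best. A
#' single allowed site is trivially localized; the result is "unlocalized"
#' when all sites tie or when no site-discriminating remainder ion matched,
#' and always for multi-copy labile forms.
#'
#' @param scored result of [score_labile()].
#' @param f the winning `ltm_modform`.
#' @return list with `site` (integer or NA), `localized` flag and
#'   `site_scores`.
#' @export
localize <- function(scored, f) {
  ss <- scored$site_scores
  if (f$offset_count != 1L || is.null(ss)) {
    return(list(site = NA_integer_, localized = FALSE, site_scores = ss))
  }
  sites <- as.integer(names(ss))
  if (length(sites) == 1L) {
    return(list(site = sites, localized = TRUE, site_scores = ss))
  }
  top <- which(ss == max(ss))
  if (length(top) != 1L || scored$site_rem_matched[top] < 1L) {
    return(list(site = NA_integer_, localized = FALSE, site_scores = ss))
  }
  list(site = sites[top], localized = TRUE, site_scores = ss)
}

# Score one candidate modform, returning an internal PSM candidate record.
.score_candidate <- function(s, f, params) {
  if (f$offset_count == 0L) {
    maxz <- .frag_charge_for(params, s$z)
    ions <- theoretical_ions(f, params$series, maxz, params$fixed_mods)
    h <- hyperscore(s, ions, params$fragment_tol_ppm)
    scored <- list(score = h$score, detail = h, pathway = "intact",
                   site_scores = NULL, site_rem_matched = NULL,
                   best_site = NA_integer_)
  } else {
    spec <- if (!is.na(f$offset_spec)) params$labile_specs[[f$offset_spec]]
            else NULL
    scored <- score_labile(s, f, spec, params)
  }
  list(form = f, scored = scored)
}

.mods_string <- function(f) {
  parts <- character(0)
  if (NROW(f$var_mods) > 0L) {
    o <- order(f$var_mods$pos)
    parts <- sprintf("%s@%d", f$var_mods$label[o], f$var_mods$pos[o])
  }
  paste(parts, collapse = ";")
}

# Deterministic candidate ordering: score desc, then fewer total mods,
# nonlabile before labile, then sequence, then offset label.
.candidate_order <- function(cands) {
  score <- vapply(cands, function(x) x$scored$score, numeric(1))
  nmods <- vapply(cands, function(x) NROW(x$form$var_mods) +
                    x$form$offset_count, numeric(1))
  labile <- vapply(cands, function(x) as.numeric(x$form$offset_count > 0L),
                   numeric(1))
  seqs <- vapply(cands, function(x) x$form$sequence, character(1))
  labs <- vapply(cands, function(x) x$form$offset_label, character(1))
  order(-score, nmods, labile, seqs, labs)
}

#' Search one spectrum against an indexed peptide database
#'
#' Enumerates candidates for the configured mode — nonlabile: placed
#' variable-modification forms at offset zero; labile: zero-offset forms
#' plus gated mass-offset candidates; hybrid: the union, including forms
#' carrying both placed modifications and an offset — scores each, and
#' returns the top-scoring PSM with a deterministic tie-break (fewer mods,
#' nonlabile first, lexicographic sequence). The runner-up score is the best
#' score among candidates with a different peptide sequence.
#'
#' @param s an `ltm_spectrum` or `ltm_processed_spectrum` (raw spectra are
#'   preprocessed with defaults).
#' @param db database from [build_search_db()].
#' @param params an `ltm_search_params`.
#' @return a one-row PSM data.frame, or NULL for unsearchable spectra or
#'   spectra with no candidate reaching `min_matched`.
#' @export
search_spectrum <- function(s, db, params) {
  if (!inherits(s, "ltm_processed_spectrum")) s <- preprocess_spectrum(s)
  if (!isTRUE(s$searchable)) return(NULL)
  prec <- precursor_neutral_mass(s)
  gate <- vapply(params$labile_specs, function(sp) {
    diagnostic_gate(s, sp, params$fragment_tol_ppm)
  }, logical(1))
  offs <- .allowed_offsets(params$labile_specs, params$mode, gate)
  multis <- .var_mod_multisets(params$var_mods, params$max_var)
  tol <- params$precursor_tol_ppm * 1e-6 * prec
  cands <- list()
  seen <- character(0)
  for (counts in multis) {
    placed_delta <- if (length(counts) == 0L) 0 else
      sum(vapply(seq_along(counts), function(i) {
        counts[i] * params$var_mods[[i]]$delta
      }, numeric(1)))
    n_placed <- sum(counts)
    for (r in seq_len(nrow(offs))) {
      n_off <- offs$count[r]
      if (params$mode == "hybrid" &&
          n_placed + n_off > params$total_mod_cap) next
      if (params$mode == "labile" && n_off > 0L && n_placed > 0L &&
          n_placed + n_off > params$total_mod_cap) next
      for (e in params$isotope_errors) {
        want <- prec - e * ISOTOPE_SPACING - placed_delta - offs$offset[r]
        hits <- query_index(db$index, want - tol, want + tol)
        if (nrow(hits) == 0L) next
        for (hrow in seq_len(nrow(hits))) {
          entry <- hits[hrow, , drop = FALSE]
          key <- paste(entry$sequence, paste(counts, collapse = ","),
                       offs$label[r], offs$count[r], sep = "|")
          if (key %in% seen) next
          seen <- c(seen, key)
          placements <- .placements_for_counts(entry$sequence, counts,
                                               params$var_mods)
          for (pl in placements) {
            f <- modform(entry$sequence, entry$mass, pl,
                         offset = offs$offset[r],
                         offset_label = offs$label[r],
                         offset_count = n_off,
                         offset_spec = offs$spec_idx[r],
                         is_decoy = entry$is_decoy,
                         accession = entry$accession)
            cands[[length(cands) + 1L]] <- .score_candidate(s, f, params)
          }
        }
      }
    }
  }
  if (length(cands) == 0L) return(NULL)
  matched_n <- vapply(cands, function(x) {
    x$scored$detail$n_prefix + x$scored$detail$n_suffix
  }, numeric(1))
  cands <- cands[matched_n >= params$min_matched]
  if (length(cands) == 0L) return(NULL)
  ord <- .candidate_order(cands)
  win <- cands[[ord[1]]]
  seqs <- vapply(cands, function(x) x$form$sequence, character(1))
  other <- which(seqs != win$form$sequence)
  runner <- if (length(other) > 0L)
    max(vapply(cands[other], function(x) x$scored$score, numeric(1))) else 0
  .psm_row(s, win, runner, params)
}

# Placements of an explicit per-mod count vector on one sequence.
.placements_for_counts <- function(sequence, counts, var_mods, cap = 256L) {
  sets <- list(data.frame(pos = integer(0), delta = numeric(0),
                          label = character(0), stringsAsFactors = FALSE))
  for (mi in seq_along(counts)) {
    ci <- counts[mi]
    if (ci == 0L) next
    mod <- var_mods[[mi]]
    pos <- .allowed_positions(sequence, mod$residues)
    if (length(pos) < ci) return(list())
    combos <- if (length(pos) == 1L) list(pos) else
      utils::combn(pos, ci, simplify = FALSE)
    sets <- unlist(lapply(sets, function(base) {
      lapply(combos, function(cb) {
        if (any(cb %in% base$pos)) return(NULL)
        rbind(base, data.frame(pos = cb, delta = mod$delta,
                               label = mod$label, stringsAsFactors = FALSE))
      })
    }), recursive = FALSE)
    sets <- Filter(Negate(is.null), sets)
    if (length(sets) > cap) {
      warning("placement cap exceeded for peptide ", sequence, "; truncated")
      sets <- sets[seq_len(cap)]
    }
  }
  sets
}

.psm_row <- function(s, win, runner, params) {
  f <- win$form
  d <- win$scored$detail
  loc <- localize(win$scored, f)
  total_mass <- modform_mass(f)
  prec <- precursor_neutral_mass(s)
  loc_scores <- if (!is.null(win$scored$site_scores)) {
    paste(sprintf("%s:%.4f", names(win$scored$site_scores),
                  win$scored$site_scores), collapse = ";")
  } else ""
  rem_ev <- sprintf("fragR=%d;pepR=%d", d$n_remainder_frag, d$pep_remainder_n)
  data.frame(
    scan = s$scan, peptide = f$sequence, mods = .mods_string(f),
    labile_offset = f$offset, offset_label = f$offset_label,
    charge = s$z,
    precursor_delta_ppm = ppm_diff(prec, total_mass),
    hyperscore = win$scored$score,
    delta_score = max(win$scored$score - runner, 0),
    matched_b = d$n_prefix, matched_y = d$n_suffix,
    remainder_evidence = rem_ev,
    localization_site = if (loc$localized) loc$site else NA_integer_,
    localization_scores = loc_scores,
    is_decoy = f$is_decoy, q_value = NA_real_,
    stringsAsFactors = FALSE)
}

#' Assemble a searchable database
#'
#' Digests targets, adds reversed decoys, and builds the peptide mass index.
#'
#' @param proteins target protein data.frame from [read_fasta()].
#' @param add_decoys reverse-decoy the targets first.
#' @param decoy_prefix decoy accession prefix.
#' @inheritParams digest
#' @return list with `proteins`, `peptides`, `index`.
#' @export
build_search_db <- function(proteins, enzyme = "stricttrypsin", missed = 2L,
                            min_len = 7L, max_len = 50L, clip_met = TRUE,
                            fixed_mods = NULL, add_decoys = TRUE,
                            decoy_prefix = "rev_") {
  if (add_decoys && !any(proteins$is_decoy)) {
    proteins <- rbind(proteins, make_decoys(proteins, decoy_prefix))
  }
  peptides <- digest_proteins(proteins, enzyme, missed, min_len, max_len,
                              clip_met, fixed_mods)
  list(proteins = proteins, peptides = peptides, index = build_index(peptides))
}

#' Search a list of spectra
#'
#' Preprocesses each spectrum (unless already processed), searches it, and
#' keeps the best PSM per scan id (charge-assumed duplicates compete).
#'
#' @param spectra list of `ltm_spectrum`.
#' @param db database from [build_search_db()].
#' @param params an `ltm_search_params`.
#' @param preprocess_args list of arguments for [preprocess_spectrum()].
#' @return data.frame of PSMs (possibly zero rows).
#' @export
search_dataset <- function(spectra, db, params, preprocess_args = list()) {
  rows <- list()
  for (s in spectra) {
    ps <- do.call(preprocess_spectrum, c(list(s), preprocess_args))
    psm <- search_spectrum(ps, db, params)
    if (!is.null(psm)) rows[[length(rows) + 1L]] <- psm
  }
  if (length(rows) == 0L) return(.empty_psm_table())
  tab <- do.call(rbind, rows)
  # best per scan id across assumed-charge duplicates
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$scan), function(ii) {
    ii[order(-tab$hyperscore[ii], tab$peptide[ii])][1]
  }), use.names = FALSE)
  tab <- tab[sort(keep), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

.empty_psm_table <- function() {
  data.frame(scan = character(0), peptide = character(0), mods = character(0),
             labile_offset = numeric(0), offset_label = character(0),
             charge = integer(0), precursor_delta_ppm = numeric(0),
             hyperscore = numeric(0), delta_score = numeric(0),
             matched_b = integer(0), matched_y = integer(0),
             remainder_evidence = character(0),
             localization_site = integer(0),
             localization_scores = character(0), is_decoy = logical(0),
             q_value = numeric(0), stringsAsFactors = FALSE)
}
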