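#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @param decoy_prefix accession prefix marking decoy entries.
#' @return data.frame with columns `accession`, `description`, `sequence`,
#'   `is_decoy`. Sequences are uppercased and `*` stripped.
#' @export
read_fasta <- function(path, decoy_prefix = "rev_") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  hdr <- names(aa)
  accession <- sub("[ \t].*$", "", hdr)
  description <- ifelse(grepl("[ \t]", hdr), sub("^[^ \t]+[ \t]+", "", hdr), "")
  sequence <- gsub("*", "", toupper(as.character(aa)), fixed = TRUE)
  empty <- !nzchar(sequence)
  if (any(empty)) {
    stop("FASTA record with no sequence: ",
         paste(accession[empty], collapse = ", "))
  }
  if (anyDuplicated(accession)) {
    warning("duplicate FASTA accession(s): ",
            paste(unique(accession[duplicated(accession)]), collapse = ", "),
            " (keeping all)")
  }
  data.frame(accession = accession, description = description,
             sequence = sequence,
             is_decoy = startsWith(accession, decoy_prefix),
             stringsAsFactors = FALSE)
}

#' Reverse-sequence decoy proteins
#'
#' One decoy per target, full sequence reversal, accession prefixed.
#'
#' @param proteins data.frame as from [read_fasta()].
#' @param prefix decoy accession prefix.
#' @return data.frame of decoy records.
#' @export
make_decoys <- function(proteins, prefix = "rev_") {
  if (any(proteins$is_decoy)) stop("refusing to build decoys of decoys")
  rev_seq <- vapply(strsplit(proteins$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), character(1))
  data.frame(accession = paste0(prefix, proteins$accession),
             description = paste("decoy of", proteins$accession),
             sequence = rev_seq, is_decoy = TRUE, stringsAsFactors = FALSE)
}

# Strict-trypsin cut sites: after every K or R, including before Pro.
.cleavage_sites <- function(sequence, enzyme = "stricttrypsin") {
  if (enzyme != "stricttrypsin") stop("unsupported enzyme: ", enzyme)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  which(res %in% c("K", "R"))
}

#' In-silico enzymatic digest of one protein
#'
#' Strict trypsin (cleavage after K/R at every occurrence, including before
#' Pro), up to `missed` missed cleavages. With `clip_met`, N-terminal
#' peptides of Met-initiated proteins are emitted both with and without the
#' leading Met.
#'
#' @param protein one-row data.frame (or list) with `accession`, `sequence`,
#'   `is_decoy`.
#' @param enzyme only `"stricttrypsin"` is implemented.
#' @param missed allowed missed cleavages (>= 0).
#' @param min_len,max_len peptide length bounds.
#' @param clip_met emit N-terminal-Met-clipped variants.
#' @param fixed_mods named residue-delta vector applied to peptide masses.
#' @return data.frame with `sequence`, `accession`, `missed`, `met_clipped`,
#'   `is_decoy`, `mass`.
#' @export
digest <- function(protein, enzyme = "stricttrypsin", missed = 2L,
                   min_len = 7L, max_len = 50L, clip_met = TRUE,
                   fixed_mods = NULL) {
  stopifnot(missed >= 0L)
  seqs <- protein$sequence
  sites <- .cleavage_sites(seqs, enzyme)
  bounds <- c(0L, sites[sites < nchar(seqs)], nchar(seqs))
  n_frag <- length(bounds) - 1L
  out_seq <- character(0); out_missed <- integer(0); out_clip <- logical(0)
  for (i in seq_len(n_frag)) {
    for (j in i:min(n_frag, i + missed)) {
      pep <- substr(seqs, bounds[i] + 1L, bounds[j + 1L])
      mc <- j - i
      if (nchar(pep) >= min_len && nchar(pep) <= max_len) {
        out_seq <- c(out_seq, pep); out_missed <- c(out_missed, mc)
        out_clip <- c(out_clip, FALSE)
      }
      if (clip_met && i == 1L && startsWith(seqs, "M")) {
        clipped <- substr(pep, 2L, nchar(pep))
        if (nchar(clipped) >= min_len && nchar(clipped) <= max_len) {
          out_seq <- c(out_seq, clipped); out_missed <- c(out_missed, mc)
          out_clip <- c(out_clip, TRUE)
        }
      }
    }
  }
  if (length(out_seq) == 0L) {
    return(data.frame(sequence = character(0), accession = character(0),
                      missed = integer(0), met_clipped = logical(0),
                      is_decoy = logical(0), mass = numeric(0),
                      stringsAsFactors = FALSE))
  }
  mass <- vapply(out_seq, peptide_mass, numeric(1), fixed_mods = fixed_mods,
                 USE.NAMES = FALSE)
  data.frame(sequence = out_seq,
             accession = rep(protein$accession, length(out_seq)),
             missed = out_missed, met_clipped = out_clip,
             is_decoy = rep(isTRUE(protein$is_decoy), length(out_seq)),
             mass = mass, stringsAsFactors = FALSE)
}

#' Digest a whole protein set into a deduplicated peptide table
#'
#' Shared peptides collapse to one entry whose `accession` holds a
#' semicolon-joined set of parents; a peptide found in both targets and
#' decoys counts as target.
#'
#' @inheritParams digest
#' @param proteins data.frame of proteins.
#' @return data.frame of unique peptide entries.
#' @export
digest_proteins <- function(proteins, enzyme = "stricttrypsin", missed = 2L,
                            min_len = 7L, max_len = 50L, clip_met = TRUE,
                            fixed_mods = NULL) {
  pieces <- lapply(seq_len(nrow(proteins)), function(i) {
    digest(proteins[i, ], enzyme, missed, min_len, max_len, clip_met,
           fixed_mods)
  })
  tab <- do.call(rbind, pieces)
  if (is.null(tab) || nrow(tab) == 0L) return(tab)
  acc <- tapply(tab$accession, tab$sequence,
                function(a) paste(sort(unique(a)), collapse = ";"))
  dec <- tapply(tab$is_decoy, tab$sequence, function(x) all(x))
  mc <- tapply(tab$missed, tab$sequence, min)
  clip <- tapply(tab$met_clipped, tab$sequence, any)
  mass <- tapply(tab$mass, tab$sequence, function(x) x[1])
  sq <- names(acc)
  data.frame(sequence = sq, accession = as.character(acc[sq]),
             missed = as.integer(mc[sq]), met_clipped = as.logical(clip[sq]),
             is_decoy = as.logical(dec[sq]), mass = as.numeric(mass[sq]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' A variable-modification definition
#'
#' @param label short label (e.g. "phospho").
#' @param residues character vector of single-letter residues, optionally
#'   including `"n^"` for the peptide N terminus.
#' @param delta mass delta in Dalton.
#' @param max maximum occurrences per peptide.
#' @return a `ltm_var_mod` list.
#' @export
variable_mod <- function(label, residues, delta, max = 1L) {
  structure(list(label = label, residues = residues, delta = delta,
                 max = as.integer(max)), class = "ltm_var_mod")
}

# Positions in `sequence` where `mod` may sit (0 = N terminus).
.allowed_positions <- function(sequence, residues) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- which(res %in% residues)
  if ("n^" %in% residues) pos <- c(0L, pos)
  as.integer(pos)
}

# All multisets of variable mods with total count <= max_var and per-mod
# count <= mod$max. Returns a list of integer count vectors (one per mod).
.var_mod_multisets <- function(var_mods, max_var) {
  if (length(var_mods) == 0L || max_var == 0L) {
    return(list(integer(0)))
  }
  grids <- lapply(var_mods, function(m) 0:min(m$max, max_var))
  grid <- expand.grid(grids)
  keep <- rowSums(grid) <= max_var
  lapply(which(keep), function(i) as.integer(grid[i, ]))
}

#' Enumerate modified forms of a peptide
#'
#' Produces every placement of at most `max_var` variable modifications on
#' allowed residues, combined (in `labile`/`hybrid` modes) with site-free
#' labile mass offsets at each multiple of each labile modification mass up
#' to its per-peptide maximum. In `hybrid` mode the total of placed variable
#' mods and labile offset counts is capped by `total_mod_cap`.
#'
#' @param entry one-row peptide data.frame (needs `sequence`, `mass`).
#' @param var_mods list of [variable_mod()].
#' @param max_var cap on placed variable modifications.
#' @param labile_specs list of [labile_mod_spec()].
#' @param mode `"nonlabile"`, `"labile"` or `"hybrid"`.
#' @param total_mod_cap cap on placed + offset modifications (hybrid).
#' @param max_forms combinatorial guard; above it the peptide is skipped
#'   with a warning and an empty result.
#' @return list of `ltm_modform`.
#' @export
enumerate_modforms <- function(entry, var_mods = list(), max_var = 3L,
                               labile_specs = list(),
                               mode = c("nonlabile", "labile", "hybrid"),
                               total_mod_cap = max_var, max_forms = 512L) {
  mode <- match.arg(mode)
  seqs <- entry$sequence
  placements <- .placements_for(seqs, var_mods, max_var)
  if (is.null(placements)) {
    warning("combinatorial cap exceeded for peptide ", seqs, "; skipped")
    return(list())
  }
  offset_tbl <- .offset_table(labile_specs, mode)
  out <- list()
  for (pl in placements) {
    n_placed <- NROW(pl)
    for (k in seq_len(nrow(offset_tbl))) {
      n_off <- offset_tbl$count[k]
      if (mode == "hybrid" && n_placed + n_off > total_mod_cap) next
      out[[length(out) + 1L]] <- modform(
        sequence = seqs, base_mass = entry$mass, var_mods = pl,
        offset = offset_tbl$offset[k], offset_label = offset_tbl$label[k],
        offset_count = n_off, offset_spec = offset_tbl$spec_idx[k],
        is_decoy = isTRUE(entry$is_decoy), accession = entry$accession)
      if (length(out) > max_forms) {
        warning("combinatorial cap exceeded for peptide ", seqs, "; skipped")
        return(list())
      }
    }
  }
  out
}

# All site placements for every allowed variable-mod multiset.
# Returns a list of data.frames (pos, delta, label), or NULL past the cap.
.placements_for <- function(sequence, var_mods, max_var, cap = 4096L) {
  multis <- .var_mod_multisets(var_mods, max_var)
  out <- list()
  for (counts in multis) {
    sets <- list(data.frame(pos = integer(0), delta = numeric(0),
                            label = character(0), stringsAsFactors = FALSE))
    ok <- TRUE
    for (mi in seq_along(counts)) {
      ci <- counts[mi]
      if (ci == 0L) next
      mod <- var_mods[[mi]]
      pos <- .allowed_positions(sequence, mod$residues)
      if (length(pos) < ci) { ok <- FALSE; break }
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
      if (length(sets) > cap) return(NULL)
    }
    if (ok) out <- c(out, sets)
  }
  out
}

# Offset variants allowed in each mode: count 0 always; per-spec multiples
# k * offset up to each spec's per-peptide max, and sums across different
# labile mods. `spec_idx` identifies the spec for pure single-spec offsets
# (NA for mixed combinations, which score through the complete-loss path).
.offset_table <- function(labile_specs, mode) {
  offset <- 0; label <- ""; count <- 0L
  spec_idx <- NA_integer_; spec_used <- list(integer(0))
  if (mode != "nonlabile" && length(labile_specs) > 0L) {
    grid <- expand.grid(lapply(labile_specs, function(sp) 0:sp$max_per_peptide))
    for (r in seq_len(nrow(grid))) {
      counts <- as.integer(grid[r, ])
      total <- sum(counts)
      if (total == 0L) next
      used <- which(counts > 0L)
      off <- sum(vapply(used, function(i) counts[i] * labile_specs[[i]]$offset,
                        numeric(1)))
      lab <- paste(vapply(used, function(i) {
        if (counts[i] == 1L) labile_specs[[i]]$label
        else paste0(counts[i], "x", labile_specs[[i]]$label)
      }, character(1)), collapse = "+")
      offset <- c(offset, off); label <- c(label, lab)
      count <- c(count, total)
      spec_idx <- c(spec_idx, if (length(used) == 1L) used else NA_integer_)
      spec_used[[length(spec_used) + 1L]] <- used
    }
  }
  tbl <- data.frame(offset = offset, label = label, count = count,
                    spec_idx = spec_idx, stringsAsFactors = FALSE)
  tbl$spec_used <- spec_used
  tbl
}

#' Construct a modified peptide form
#'
#' @param sequence peptide sequence.
#' @param base_mass unmodified (fixed-mods-applied) neutral mass.
#' @param var_mods data.frame of placed modifications (`pos`, `delta`,
#'   `label`); may be empty.
#' @param offset labile mass offset in Dalton (0 for none).
#' @param offset_label,offset_count label and count of the labile mod.
#' @param offset_spec index of the generating labile spec (NA for mixed
#'   multi-spec offsets).
#' @param is_decoy,accession provenance.
#' @return an `ltm_modform`.
#' @export
modform <- function(sequence, base_mass, var_mods = NULL, offset = 0,
                    offset_label = "", offset_count = 0L,
                    offset_spec = NA_integer_, is_decoy = FALSE,
                    accession = "") {
  if (is.null(var_mods)) {
    var_mods <- data.frame(pos = integer(0), delta = numeric(0),
                           label = character(0), stringsAsFactors = FALSE)
  }
  structure(list(sequence = sequence, base_mass = base_mass,
                 var_mods = var_mods, offset = offset,
                 offset_label = offset_label,
                 offset_count = as.integer(offset_count),
                 offset_spec = as.integer(offset_spec),
                 is_decoy = is_decoy, accession = accession),
            class = "ltm_modform")
}

#' Total neutral mass of a modform (including the labile offset)
#' @param f an `ltm_modform`.
#' @return mass in Dalton.
#' @export
modform_mass <- function(f) {
  f$base_mass + sum(f$var_mods$delta) + f$offset
}

#' Build a peptide mass index
#'
#' Entries sorted by neutral mass for exact window retrieval.
#'
#' @param entries peptide data.frame with a `mass` column.
#' @return an `ltm_mass_index`.
#' @export
build_index <- function(entries) {
  o <- order(entries$mass)
  structure(list(entries = entries[o, , drop = FALSE],
                 mass = entries$mass[o]), class = "ltm_mass_index")
}

#' Query a mass index window
#'
#' @param idx an `ltm_mass_index`.
#' @param lo,hi inclusive mass window bounds in Dalton.
#' @return data.frame of entries with lo <= mass <= hi.
#' @export
query_index <- function(idx, lo, hi) {
  i <- findInterval(lo, idx$mass, left.open = TRUE) + 1L
  j <- findInterval(hi, idx$mass)
  if (j < i) return(idx$entries[0, , drop = FALSE])
  idx$entries[i:j, , drop = FALSE]
}
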