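#' Simulation parameters for synthetic labile-modification spectra
#'
#' The generator emulates the fragmentation phenomenology of labile
#' modifications: per site-covering backbone fragment, the modification is
#' lost with probability `p_loss` (emitting the unmodified-fragment peak),
#' otherwise the intact-modification peak is emitted; upon loss a fragment
#' remainder peak (base + remainder) is additionally emitted with
#' `frag_remainder_prob`. Diagnostic ions and peptide-remainder ions are
#' emitted with their own probabilities, noise peaks are added, and all m/z
#' values are jittered by Gaussian ppm noise.
#'
#' @param p_loss per-fragment modification-loss probability in \[0, 1\].
#' @param frag_remainder_prob probability a lost-modification fragment also
#'   leaves a remainder peak.
#' @param frag_remainders remainder mass(es) in Dalton (one drawn per event).
#' @param pep_remainder_prob,pep_remainders emission probability and masses
#'   of intact-peptide remainder ions.
#' @param diag_prob,diag_mz,diag_intensity diagnostic-ion emission
#'   probability (per configured ion), m/z list, and intensity range.
#' @param detect_prob backbone fragment detection probability; the 0.6
#'   default reflects that collisional-activation spectra typically reveal
#'   about half of the theoretical b/y ladder.
#' @param frag_intensity backbone intensity range (log-uniform draw).
#' @param noise_frac noise peaks as a fraction of emitted signal peaks.
#' @param noise_mz,noise_intensity noise peak m/z and intensity ranges.
#' @param jitter_ppm Gaussian m/z jitter (standard deviation, ppm).
#' @param charges precursor charge values sampled uniformly.
#' @return an `ltm_sim_params`.
#' @export
sim_params <- function(p_loss = 1.0, frag_remainder_prob = 0,
                       frag_remainders = numeric(0),
                       pep_remainder_prob = 0, pep_remainders = numeric(0),
                       diag_prob = 0.9, diag_mz = numeric(0),
                       diag_intensity = c(20, 100), detect_prob = 0.6,
                       frag_intensity = c(10, 100), noise_frac = 0.1,
                       noise_mz = c(150, 1500), noise_intensity = c(1, 20),
                       jitter_ppm = 3, charges = c(2L, 3L)) {
  probs <- c(p_loss, frag_remainder_prob, pep_remainder_prob, diag_prob,
             detect_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (noise_frac < 0) stop("noise_frac must be >= 0")
  structure(list(p_loss = p_loss, frag_remainder_prob = frag_remainder_prob,
                 frag_remainders = frag_remainders,
                 pep_remainder_prob = pep_remainder_prob,
                 pep_remainders = pep_remainders, diag_prob = diag_prob,
                 diag_mz = diag_mz, diag_intensity = diag_intensity,
                 detect_prob = detect_prob, frag_intensity = frag_intensity,
                 noise_frac = noise_frac, noise_mz = noise_mz,
                 noise_intensity = noise_intensity, jitter_ppm = jitter_ppm,
                 charges = as.integer(charges)), class = "ltm_sim_params")
}

# Deterministic per-spectrum RNG stream from (seed, scan index).
.spectrum_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Draw modified peptides for simulation
#'
#' Samples (with replacement) from the tryptic digest of the supplied
#' proteins, keeping peptides with at least one allowed site, and places the
#' modification on an allowed site chosen uniformly.
#'
#' @param proteins protein data.frame (targets only).
#' @param n number of peptides.
#' @param spec the `ltm_labile_spec` being simulated.
#' @param seed RNG seed.
#' @param n_mods copies of the modification per peptide (distinct sites).
#' @param fixed_mods named residue-delta vector.
#' @inheritParams digest
#' @return list of `ltm_modform` with a `sites` element (true site vector).
#' @export
sample_peptides <- function(proteins, n, spec, seed = 1L, n_mods = 1L,
                            missed = 2L, min_len = 7L, max_len = 50L,
                            fixed_mods = NULL) {
  stopifnot(n >= 1L)
  peptides <- digest_proteins(proteins, missed = missed, min_len = min_len,
                              max_len = max_len, fixed_mods = fixed_mods)
  ok <- vapply(peptides$sequence, function(sq) {
    length(.labile_sites(sq, spec)) >= n_mods
  }, logical(1))
  pool <- peptides[ok, , drop = FALSE]
  if (nrow(pool) == 0L) {
    stop("no digest peptide offers ", n_mods, " allowed site(s) for '",
         spec$label, "'")
  }
  set.seed(seed)
  picks <- sample.int(nrow(pool), n, replace = TRUE)
  lapply(picks, function(i) {
    sq <- pool$sequence[i]
    sites <- .labile_sites(sq, spec)
    chosen <- if (length(sites) == 1L) sites else sort(sample(sites, n_mods))
    f <- modform(sq, pool$mass[i], offset = n_mods * spec$offset,
                 offset_label = spec$label, offset_count = n_mods,
                 accession = pool$accession[i])
    f$sites <- chosen
    f
  })
}

#' Simulate one spectrum of a modified peptide
#'
#' @param f an `ltm_modform` with a `sites` element (true modification
#'   sites); `offset_count` 0 with empty `sites` simulates an unmodified
#'   peptide.
#' @param spec the `ltm_labile_spec` (masses for remainders/diagnostics come
#'   from `sp`, not from here; `spec$offset` supplies the intact-ion shift).
#' @param sp an `ltm_sim_params`.
#' @param seed RNG seed for this spectrum.
#' @param scan scan identifier.
#' @param series fragment series emitted.
#' @param fixed_mods named residue-delta vector.
#' @return list with `spectrum` (`ltm_spectrum`) and `truth`
#'   (one-row data.frame).
#' @export
simulate_spectrum <- function(f, spec, sp, seed = 1L, scan = "sim_1",
                              series = c("b", "y"), fixed_mods = NULL) {
  set.seed(seed)
  z <- if (length(sp$charges) == 1L) sp$charges else sample(sp$charges, 1L)
  ions <- theoretical_ions(f, series, 1L, fixed_mods)
  n <- nchar(f$sequence)
  sites <- f$sites
  if (is.null(sites)) sites <- integer(0)
  mz <- numeric(0); it <- numeric(0)
  for (i in seq_len(nrow(ions))) {
    if (stats::runif(1) > sp$detect_prob) next
    covered <- sites[.ion_covers_site(ions$series[i], ions$ordinal[i], n, sites)]
    inten <- .runif_log(1, sp$frag_intensity)
    if (length(covered) == 0L) {
      mz <- c(mz, ions$mz[i]); it <- c(it, inten)
      next
    }
    # per covered site decide loss; intact sites shift the ion by the offset
    lost <- stats::runif(length(covered)) <= sp$p_loss
    emit_mz <- ions$mz[i] + sum(!lost) * spec$offset
    mz <- c(mz, emit_mz); it <- c(it, inten)
    if (any(lost) && length(sp$frag_remainders) > 0L &&
        stats::runif(1) <= sp$frag_remainder_prob) {
      r <- if (length(sp$frag_remainders) == 1L) sp$frag_remainders
           else sample(sp$frag_remainders, 1L)
      mz <- c(mz, emit_mz + r)
      it <- c(it, .runif_log(1, sp$frag_intensity))
    }
  }
  pep_neutral <- f$base_mass + sum(f$var_mods$delta)
  if (length(sp$pep_remainders) > 0L) {
    for (r in sp$pep_remainders) {
      if (stats::runif(1) <= sp$pep_remainder_prob) {
        mz <- c(mz, mz_from_mass(pep_neutral + r, 1L))
        it <- c(it, .runif_log(1, sp$frag_intensity))
      }
    }
  }
  for (dmz in sp$diag_mz) {
    if (stats::runif(1) <= sp$diag_prob) {
      mz <- c(mz, dmz)
      it <- c(it, stats::runif(1, sp$diag_intensity[1], sp$diag_intensity[2]))
    }
  }
  n_noise <- round(sp$noise_frac * length(mz))
  if (n_noise > 0L) {
    mz <- c(mz, stats::runif(n_noise, sp$noise_mz[1], sp$noise_mz[2]))
    it <- c(it, stats::runif(n_noise, sp$noise_intensity[1],
                             sp$noise_intensity[2]))
  }
  if (sp$jitter_ppm > 0 && length(mz) > 0L) {
    mz <- mz * (1 + stats::rnorm(length(mz), 0, sp$jitter_ppm * 1e-6))
  }
  # merge duplicate m/z (within 1e-6) by intensity summation
  if (length(mz) > 1L) {
    o <- order(mz); mz <- mz[o]; it <- it[o]
    grp <- cumsum(c(TRUE, diff(mz) > 1e-6))
    mz <- as.numeric(tapply(mz, grp, function(x) x[1]))
    it <- as.numeric(tapply(it, grp, sum))
  }
  premz <- mz_from_mass(modform_mass(f), z)
  s <- spectrum(scan, premz, z, mz, it)
  truth <- data.frame(scan = scan, peptide = f$sequence,
                      n_mods = f$offset_count,
                      sites = paste(sites, collapse = ";"),
                      offset = f$offset, mod_label = f$offset_label,
                      charge = z, stringsAsFactors = FALSE)
  list(spectrum = s, truth = truth)
}

#' Simulate a labeled dataset
#'
#' @param proteins protein data.frame to draw true peptides from.
#' @param spec the `ltm_labile_spec` simulated.
#' @param sp an `ltm_sim_params`.
#' @param n_spectra number of spectra.
#' @param seed master seed; each spectrum derives its own stream from
#'   (seed, index).
#' @param mgf_path,truth_path optional output files (MGF and TSV).
#' @param n_mods modification copies per peptide (scalar or vector recycled
#'   over spectra; 0 yields unmodified-peptide spectra).
#' @param scan_prefix scan id prefix.
#' @inheritParams simulate_spectrum
#' @return list with `spectra` (list), `truth` (data.frame) and the paths.
#' @export
simulate_dataset <- function(proteins, spec, sp, n_spectra, seed = 1L,
                             mgf_path = NULL, truth_path = NULL, n_mods = 1L,
                             series = c("b", "y"), fixed_mods = NULL,
                             scan_prefix = "sim") {
  stopifnot(n_spectra >= 1L)
  n_mods <- rep_len(as.integer(n_mods), n_spectra)
  spectra <- vector("list", n_spectra)
  truths <- vector("list", n_spectra)
  counts <- sort(unique(n_mods))
  forms_by_count <- list()
  for (k in counts) {
    nk <- sum(n_mods == k)
    if (k == 0L) {
      forms <- sample_peptides(proteins, nk, spec, seed = .spectrum_seed(seed, -1L),
                               n_mods = 1L, fixed_mods = fixed_mods)
      forms <- lapply(forms, function(f) {
        f$offset <- 0; f$offset_label <- ""; f$offset_count <- 0L
        f$sites <- integer(0)
        f
      })
    } else {
      forms <- sample_peptides(proteins, nk, spec, seed = .spectrum_seed(seed, k),
                               n_mods = k, fixed_mods = fixed_mods)
    }
    forms_by_count[[as.character(k)]] <- forms
  }
  taken <- stats::setNames(rep(0L, length(counts)), as.character(counts))
  for (i in seq_len(n_spectra)) {
    k <- as.character(n_mods[i])
    taken[k] <- taken[k] + 1L
    f <- forms_by_count[[k]][[taken[k]]]
    res <- simulate_spectrum(f, spec, sp, seed = .spectrum_seed(seed, i),
                             scan = sprintf("%s_%05d", scan_prefix, i),
                             series = series, fixed_mods = fixed_mods)
    spectra[[i]] <- res$spectrum
    truths[[i]] <- res$truth
  }
  truth <- do.call(rbind, truths)
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(spectra = spectra, truth = truth, mgf_path = mgf_path,
       truth_path = truth_path)
}
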