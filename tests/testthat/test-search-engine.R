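adpr_diag <- c(136.06232, 250.09401)

test_that("diagnostic gate sums nearest-match intensities against threshold", {
  s <- preprocess_spectrum(
    spectrum("s", 500, 2L, c(136.0623, 250.0940, 400.1), c(30, 40, 100)),
    min_peaks = 1L, norm_ceiling = 100)
  gate50 <- labile_mod_spec("ADPr", 541.06111, "*", diagnostic_mz = adpr_diag,
                            diagnostic_min_intensity = 50)
  gate80 <- labile_mod_spec("ADPr", 541.06111, "*", diagnostic_mz = adpr_diag,
                            diagnostic_min_intensity = 80)
  expect_true(diagnostic_gate(s, gate50, 10))
  expect_false(diagnostic_gate(s, gate80, 10))
  nogate <- labile_mod_spec("ADPr", 541.06111, "*",
                            diagnostic_mz = adpr_diag,
                            diagnostic_min_intensity = 0)
  expect_true(diagnostic_gate(s, nogate, 10))
  empty <- preprocess_spectrum(spectrum("s", 500, 2L, 900.5, 10),
                               min_peaks = 1L)
  expect_false(diagnostic_gate(empty, gate50, 10))
})

test_that("raising the gate threshold never admits more spectra", {
  set.seed(55)
  spec_of <- function(thr) {
    labile_mod_spec("ADPr", 541.06111, "*", diagnostic_mz = adpr_diag,
                    diagnostic_min_intensity = thr)
  }
  spectra <- lapply(1:100, function(i) {
    mz <- sort(c(sample(c(136.06232, 250.09401),
                        sample(0:2, 1)), runif(20, 300, 1200)))
    preprocess_spectrum(spectrum(paste0("s", i), 600, 2L, mz,
                                 runif(length(mz), 1, 100)),
                        min_peaks = 1L)
  })
  prev <- rep(TRUE, 100)
  for (thr in c(0, 5, 20, 50, 90, 200)) {
    cur <- vapply(spectra, diagnostic_gate, logical(1), spec = spec_of(thr))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("candidates_for retrieves entries at gated offsets", {
  entries <- data.frame(sequence = c("AAAA", "BBBB"),
                        mass = c(1000.5, 1300.7), is_decoy = FALSE,
                        accession = "X", stringsAsFactors = FALSE)
  idx <- build_index(entries)
  spec <- labile_mod_spec("ADPr", 541.06111, "*")
  s <- spectrum("s", mz_from_mass(1541.56111, 2L), 2L, c(100, 200), c(1, 1))
  got <- candidates_for(s, idx, list(spec), "labile", 20, TRUE)
  expect_equal(got$sequence, "AAAA")
  expect_equal(got$offset, 541.06111)
  s0 <- spectrum("s", mz_from_mass(1000.5, 2L), 2L, c(100, 200), c(1, 1))
  got0 <- candidates_for(s0, idx, list(spec), "labile", 20, TRUE)
  expect_equal(got0$offset, 0)
  gated <- candidates_for(s, idx, list(spec), "labile", 20, FALSE)
  expect_equal(nrow(gated), 0L)
})

test_that("hyperscore follows the log-factorial formula", {
  # no matching peaks -> 0
  s_none <- preprocess_spectrum(spectrum("s", 500, 2L, 1200.5, 10),
                                min_peaks = 1L, norm_ceiling = 10)
  ions <- data.frame(series = c("b", "b", "y"), ordinal = 1:3, charge = 1L,
                     mz = c(200.1, 300.2, 400.3), remainder = 0,
                     site = NA_integer_)
  expect_equal(hyperscore(s_none, ions, 10)$score, 0)
  # N_b = 2 (100, 50), N_y = 1 (200): log10(2! * 1! * 150 * 200)
  s2 <- spectrum("s", 500, 2L, c(200.1, 300.2, 400.3), c(100, 50, 200))
  s2 <- preprocess_spectrum(s2, min_peaks = 1L, norm_ceiling = 200)
  h <- hyperscore(s2, ions, 10)
  expect_equal(h$score, log10(60000), tolerance = 1e-10)
  expect_equal(round(h$score, 5), 4.77815)
  expect_equal(h$n_prefix, 2L)
  expect_equal(h$n_suffix, 1L)
})

test_that("hyperscore equals the brute-force matcher on random pairs", {
  set.seed(202)
  for (i in 1:200) {
    sq <- paste(sample(AA20, sample(6:18, 1), replace = TRUE), collapse = "")
    f <- modform(sq, peptide_mass(sq))
    ions <- theoretical_ions(f, c("b", "y"), sample(1:2, 1))
    # peaks: a subset of true ions (jittered inside tolerance) plus noise
    take <- sample(nrow(ions), sample(2:nrow(ions), 1))
    mz <- c(ions$mz[take] * (1 + runif(length(take), -4e-6, 4e-6)),
            runif(12, 150, 1600))
    s <- preprocess_spectrum(
      spectrum("s", 600, 2L, mz, runif(length(mz), 1, 100)),
      min_peaks = 1L, norm_ceiling = 100)
    got <- hyperscore(s, ions, 10)
    want <- oracle_hyperscore(s, ions, 10)
    expect_equal(got$score, want, tolerance = 1e-9)
  }
})

test_that("peptide-remainder evidence adds intensity but no counts", {
  sq <- "SAMPLEK"
  f <- modform(sq, peptide_mass(sq), offset = 541.06111,
               offset_label = "ADPr", offset_count = 1L, offset_spec = 1L)
  ions <- theoretical_ions(f, c("b", "y"), 1L)
  remp <- peptide_remainder_mzs(f, c(114.03169, 193.99802), 1L)
  mz <- c(ions$mz[c(1, 8)], remp$mz[1])
  s <- preprocess_spectrum(spectrum("s", 600, 2L, mz, c(50, 80, 60)),
                           min_peaks = 1L, norm_ceiling = 80)
  with_rem <- hyperscore(s, ions, 10, remp)
  without <- hyperscore(s, ions, 10)
  expect_equal(with_rem$n_prefix, without$n_prefix)
  expect_equal(with_rem$n_suffix, without$n_suffix)
  expect_equal(with_rem$pep_remainder_n, 1L)
  expect_gt(with_rem$score, without$score)
  want <- oracle_hyperscore(s, ions, 10, remp$mz)
  expect_equal(with_rem$score, want, tolerance = 1e-9)
})

test_that("score_labile prefers the remainder pathway when planted", {
  spec <- fx_phospho_spec()
  params <- search_params(mode = "labile", labile_specs = list(spec),
                          isotope_errors = 0L)
  sq <- "SAMSAEK"  # sites at 1 and 4
  f <- modform(sq, peptide_mass(sq), offset = 79.96633,
               offset_label = "phospho", offset_count = 1L, offset_spec = 1L)
  ions <- theoretical_ions(f, c("b", "y"), 1L)
  site <- 4L
  vari <- apply_fragment_remainder(ions, f, site, -18.01056)
  mz <- c(ions$mz, vari$mz)
  s <- preprocess_spectrum(
    spectrum("s", mz_from_mass(modform_mass(f), 2L), 2L, mz,
             rep(50, length(mz))), min_peaks = 1L)
  got <- score_labile(s, f, spec, params)
  expect_equal(got$pathway, "remainder")
  expect_equal(got$best_site, site)
  loc <- localize(got, f)
  expect_true(loc$localized)
  expect_equal(loc$site, site)
  # complete loss only: remainder adds nothing, tie-break to complete loss
  s2 <- preprocess_spectrum(
    spectrum("s", mz_from_mass(modform_mass(f), 2L), 2L, ions$mz,
             rep(50, nrow(ions))), min_peaks = 1L)
  got2 <- score_labile(s2, f, spec, params)
  expect_equal(got2$pathway, "complete_loss")
  expect_false(localize(got2, f)$localized)
  # without configured fragment remainders the score is the base score
  spec_norem <- fx_phospho_spec(fragment_remainders = numeric(0))
  params2 <- search_params(mode = "labile", labile_specs = list(spec_norem),
                           isotope_errors = 0L)
  got3 <- score_labile(s, f, spec_norem, params2)
  expect_equal(got3$pathway, "complete_loss")
  expect_equal(got3$score, hyperscore(s, ions, 10)$score)
})

test_that("single allowed site localizes trivially", {
  spec <- fx_phospho_spec()
  sq <- "AGSAGAK"  # single S
  f <- modform(sq, peptide_mass(sq), offset = 79.96633,
               offset_label = "phospho", offset_count = 1L, offset_spec = 1L)
  params <- search_params(mode = "labile", labile_specs = list(spec),
                          isotope_errors = 0L)
  ions <- theoretical_ions(f, c("b", "y"), 1L)
  s <- preprocess_spectrum(
    spectrum("s", mz_from_mass(modform_mass(f), 2L), 2L, ions$mz,
             rep(50, nrow(ions))), min_peaks = 1L)
  got <- score_labile(s, f, spec, params)
  loc <- localize(got, f)
  expect_true(loc$localized)
  expect_equal(loc$site, 3L)
})

test_that("hybrid competition picks the pathway matching the fragmentation", {
  prot <- fx_proteins(6, seed = 8)
  db <- build_search_db(prot)
  spec <- fx_phospho_spec()
  ph_var <- variable_mod("phospho", c("S", "T", "Y"), 79.96633, 1L)
  p_hybrid <- search_params(mode = "hybrid", var_mods = list(ph_var),
                            max_var = 1L, labile_specs = list(spec),
                            total_mod_cap = 1L, isotope_errors = 0L)
  p_lab <- search_params(mode = "labile", labile_specs = list(spec),
                         isotope_errors = 0L)
  p_non <- search_params(mode = "nonlabile", var_mods = list(ph_var),
                         max_var = 1L, isotope_errors = 0L)
  for (lability in c(0, 1)) {
    sp <- sim_params(p_loss = lability, frag_remainder_prob = 0,
                     detect_prob = 1, noise_frac = 0, jitter_ppm = 0,
                     charges = 2L)
    sim <- simulate_dataset(prot, spec, sp, 12, seed = 31 + lability)
    winners <- lapply(sim$spectra, search_spectrum, db = db, p = p_hybrid)
    winners <- winners[!vapply(winners, is.null, logical(1))]
    offsets <- vapply(winners, function(w) w$labile_offset, numeric(1))
    if (lability == 0) {
      expect_true(all(offsets == 0))          # intact: variable-mod form wins
      expect_true(all(vapply(winners, function(w) nzchar(w$mods),
                             logical(1))))
    } else {
      expect_true(mean(offsets > 0) > 0.9)    # full loss: offset form wins
    }
    # hybrid dominance: winner score >= each single-mode winner score
    for (s in sim$spectra[1:6]) {
      hy <- search_spectrum(s, db, p_hybrid)
      la <- search_spectrum(s, db, p_lab)
      no <- search_spectrum(s, db, p_non)
      for (one in list(la, no)) {
        if (!is.null(one) && !is.null(hy)) {
          expect_gte(hy$hyperscore + 1e-9, one$hyperscore)
        }
      }
    }
  }
})

test_that("search results carry delta scores and respect min_matched", {
  prot <- fx_proteins(8, seed = 12)
  db <- build_search_db(prot)
  spec <- fx_phospho_spec()
  params <- search_params(mode = "labile", labile_specs = list(spec),
                          isotope_errors = 0L)
  sp <- sim_params(p_loss = 1, frag_remainder_prob = 1,
                   frag_remainders = -18.01056, detect_prob = 1,
                   noise_frac = 0, jitter_ppm = 0, charges = 2L)
  sim <- simulate_dataset(prot, spec, sp, 10, seed = 77)
  psms <- search_dataset(sim$spectra, db, params)
  expect_gt(nrow(psms), 0)
  expect_true(all(psms$hyperscore >= 0))
  expect_true(all(psms$delta_score >= 0))
  expect_true(all(psms$matched_b + psms$matched_y >= 4))
  m <- match(psms$scan, sim$truth$scan)
  expect_true(mean(psms$peptide == sim$truth$peptide[m]) > 0.9)
  # unsearchable spectrum yields NULL
  thin <- preprocess_spectrum(spectrum("t", 500, 2L, 100.5, 5),
                              min_peaks = 5L)
  expect_null(search_spectrum(thin, db, params))
})
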