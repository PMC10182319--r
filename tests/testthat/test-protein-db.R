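test_that("read_fasta parses, uppercases and strips stops", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|ONE first protein", "pept", "idek*",
               ">P2", "AAAKR"), path)
  got <- read_fasta(path)
  expect_equal(nrow(got), 2L)
  expect_equal(got$accession, c("sp|P1|ONE", "P2"))
  expect_equal(got$description[1], "first protein")
  expect_equal(got$sequence[1], "PEPTIDEK")
  expect_false(any(got$is_decoy))
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "PEPK", ">A", "MMMK"), dup)
  expect_warning(read_fasta(dup), "duplicate")
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">EMPTYACC", "", ">B", "PEPK"), bad)
  expect_error(read_fasta(bad), "EMPTYACC")
})

test_that("strict trypsin digests match the brute-force cleaver", {
  # strict rule: cleavage proceeds even before proline
  got <- digest(list(accession = "X", sequence = "PEPKRPR", is_decoy = FALSE),
                missed = 0L, min_len = 1L, max_len = 50L, clip_met = FALSE)
  expect_setequal(got$sequence, c("PEPK", "R", "PR"))
  expect_setequal(got$sequence, oracle_digest("PEPKRPR", 0, 1, 50, FALSE))
  # Met clipping emits both variants of N-terminal peptides
  got2 <- digest(list(accession = "X", sequence = "MAKRSTK", is_decoy = FALSE),
                 missed = 1L, min_len = 1L, max_len = 50L, clip_met = TRUE)
  expect_setequal(got2$sequence, oracle_digest("MAKRSTK", 1, 1, 50, TRUE))
  # no cut sites at all: whole chain, zero missed cleavages
  got3 <- digest(list(accession = "X", sequence = "ACDEFGHILM",
                      is_decoy = FALSE), missed = 2L, min_len = 1L,
                 max_len = 50L, clip_met = FALSE)
  expect_equal(got3$sequence, "ACDEFGHILM")
  expect_equal(got3$missed, 0L)
})

test_that("digest equals brute force over random proteins and settings", {
  set.seed(101)
  for (i in 1:100) {
    sq <- fx_random_protein(sample(20:200, 1))
    missed <- sample(0:2, 1)
    got <- digest(list(accession = "X", sequence = sq, is_decoy = FALSE),
                  missed = missed, min_len = 4L, max_len = 30L,
                  clip_met = TRUE)
    expect_setequal(unique(got$sequence),
                    oracle_digest(sq, missed, 4, 30, TRUE))
    expect_true(all(got$missed <= missed))
    expect_true(all(abs(got$mass -
                          vapply(got$sequence, peptide_mass, numeric(1))) <
                      1e-9))
  }
})

test_that("decoys are reversed, prefixed and preserve mass structure", {
  prot <- data.frame(accession = c("A", "B"), description = "",
                     sequence = c("PEPTIDEK", "MSSTRAAK"), is_decoy = FALSE)
  dec <- make_decoys(prot)
  expect_equal(dec$sequence[1], "KEDITPEP")
  expect_equal(dec$accession, c("rev_A", "rev_B"))
  expect_equal(nrow(dec), nrow(prot))
  expect_error(make_decoys(dec), "decoys of decoys")
  # protein reversal preserves composition exactly; digest statistics match
  # closely (cut-site structure shifts by one residue at segment ends)
  prots <- fx_proteins(20, seed = 3)
  rev_prots <- make_decoys(prots)
  expect_equal(vapply(prots$sequence, peptide_mass, numeric(1),
                      USE.NAMES = FALSE),
               vapply(rev_prots$sequence, peptide_mass, numeric(1),
                      USE.NAMES = FALSE))
  t_pep <- digest_proteins(prots, min_len = 7L, max_len = 50L)
  d_pep <- digest_proteins(rev_prots, min_len = 7L, max_len = 50L)
  expect_lt(abs(nrow(t_pep) - nrow(d_pep)) / nrow(t_pep), 0.1)
  expect_lt(abs(mean(nchar(t_pep$sequence)) - mean(nchar(d_pep$sequence))),
            2)
  expect_lt(abs(mean(t_pep$mass) - mean(d_pep$mass)), 200)
})

test_that("modform enumeration covers placements and offset ladders", {
  entry <- data.frame(sequence = "ASK", mass = peptide_mass("ASK"),
                      is_decoy = FALSE, accession = "X")
  ph_var <- variable_mod("phospho", c("S", "T", "Y"), 79.96633, 1L)
  nl <- enumerate_modforms(entry, list(ph_var), 1L, list(), "nonlabile")
  expect_length(nl, 2L)  # unmodified + phospho at S2
  placed <- Filter(function(f) nrow(f$var_mods) == 1, nl)
  expect_equal(placed[[1]]$var_mods$pos, 2L)
  spec <- fx_phospho_spec(max_per_peptide = 1L)
  lab <- enumerate_modforms(entry, list(), 0L, list(spec), "labile")
  expect_length(lab, 2L)
  expect_setequal(vapply(lab, `[[`, numeric(1), "offset"), c(0, 79.96633))
  entry2 <- data.frame(sequence = "SSK", mass = peptide_mass("SSK"),
                       is_decoy = FALSE, accession = "X")
  spec2 <- fx_phospho_spec(max_per_peptide = 2L)
  lab2 <- enumerate_modforms(entry2, list(), 0L, list(spec2), "labile")
  expect_setequal(round(vapply(lab2, `[[`, numeric(1), "offset"), 5),
                  c(0, 79.96633, 159.93266))
})

test_that("modform counts match the closed-form combinatorics", {
  # k sites, max m placed mods: sum over j of choose(k, j)
  entry <- data.frame(sequence = "SSSSAK", mass = peptide_mass("SSSSAK"),
                      is_decoy = FALSE, accession = "X")
  ph <- variable_mod("phospho", "S", 79.96633, 3L)
  forms <- enumerate_modforms(entry, list(ph), 3L, list(), "nonlabile")
  expect_length(forms, sum(choose(4, 0:3)))
  # hybrid: placed j + offsets k with j + k <= cap
  spec <- fx_phospho_spec(max_per_peptide = 3L)
  hy <- enumerate_modforms(entry, list(ph), 3L, list(spec), "hybrid",
                           total_mod_cap = 3L)
  want <- sum(vapply(0:3, function(j) {
    choose(4, j) * length(0:(3 - j))
  }, numeric(1)))
  expect_length(hy, want)
})

test_that("mass index windows agree with a linear scan", {
  set.seed(77)
  entries <- data.frame(sequence = sprintf("P%04d", 1:1000),
                        mass = runif(1000, 500, 4000),
                        is_decoy = FALSE, accession = "X")
  idx <- build_index(entries)
  for (i in 1:100) {
    lo <- runif(1, 400, 4100)
    hi <- lo + runif(1, 0, 300)
    got <- query_index(idx, lo, hi)
    want <- entries[entries$mass >= lo & entries$mass <= hi, ]
    expect_setequal(got$sequence, want$sequence)
  }
  expect_equal(nrow(query_index(idx, 100, 101)), 0L)
  expect_equal(nrow(query_index(idx, 0, 1e6)), 1000L)
})
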