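# Monoisotopic atomic masses (IUPAC/CODATA), >= 9 decimal places.
# These reproduce every composition-derivable workflow constant at 5 dp.
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207117
)

#' Physical constants for m/z arithmetic
#'
#' `PROTON_MASS` is the mass of a proton (the charge carrier used for all
#' internally computed m/z values); `HYDROGEN_MASS` is the mass of a neutral
#' hydrogen atom (the convention behind many published diagnostic-ion m/z
#' values, e.g. protonated adenine at 136.06232); `ISOTOPE_SPACING` is the
#' 13C-12C mass difference used for deisotoping and isotope-error handling.
#'
#' @format Length-one numeric values in Dalton.
#' @export
PROTON_MASS <- 1.00727646688

#' @rdname PROTON_MASS
#' @export
HYDROGEN_MASS <- 1.00782503207

#' @rdname PROTON_MASS
#' @export
ISOTOPE_SPACING <- 1.0033548378

# Residue elemental compositions; residue masses are derived from these so
# that additivity (peptide mass = sum of residues + H2O) holds to machine
# precision rather than to the rounding of a transcribed table.
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2", P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS", L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3", Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS", H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2", W = "C11H10N2O"
)

#' Parse an elemental formula into a composition
#'
#' A composition is a named integer vector of element counts (e.g.
#' `c(C = 15, H = 21, N = 5, O = 13, P = 2)` for ADP-ribose). Only the
#' elements C, H, N, O, P, S are supported; counts default to 1 when omitted.
#'
#' @param formula character scalar such as `"H2O"` or `"C15H21N5O13P2"`.
#' @return named integer vector of element counts.
#' @examples
#' parse_composition("C5H7O6P")
#' @export
parse_composition <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (formula == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula) || length(parts) == 0L) {
    bad <- substr(formula, 1L, 8L)
    stop("malformed composition string near '", bad, "'")
  }
  el <- sub("[0-9]+$", "", parts)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", parts)))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(el, names(.ELEMENT_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  }
  comp <- tapply(cnt, factor(el, levels = unique(el)), sum)
  stats::setNames(as.integer(comp), names(comp))
}

#' Monoisotopic mass of a composition
#'
#' @param comp named integer vector as returned by [parse_composition()].
#' @return monoisotopic mass in Dalton; 0 for the empty composition.
#' @export
mass_of <- function(comp) {
  if (length(comp) == 0L) return(0.0)
  if (is.null(names(comp)) || any(!nzchar(names(comp)))) {
    stop("composition must be a named vector of element counts")
  }
  unknown <- setdiff(names(comp), names(.ELEMENT_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  }
  if (any(comp < 0)) stop("negative element count in finalized composition")
  sum(.ELEMENT_MASS[names(comp)] * as.numeric(comp))
}

.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA,
                        function(f) mass_of(parse_composition(f)), numeric(1))
.WATER_MASS <- mass_of(c(H = 2L, O = 1L))
.NH3_MASS <- mass_of(c(N = 1L, H = 3L))

#' Residue monoisotopic masses
#'
#' @param fixed_mods optional named numeric vector of fixed-modification
#'   deltas keyed by single-letter residue (e.g. `c(C = 57.02146)` for
#'   carbamidomethylation); added to the corresponding residue masses.
#' @return named numeric vector over the 20 canonical residues.
#' @export
residue_masses <- function(fixed_mods = NULL) {
  m <- .RESIDUE_MASS
  if (!is.null(fixed_mods) && length(fixed_mods) > 0L) {
    bad <- setdiff(names(fixed_mods), names(m))
    if (length(bad) > 0L) stop("fixed mod on unknown residue: ",
                               paste(bad, collapse = ", "))
    m[names(fixed_mods)] <- m[names(fixed_mods)] + as.numeric(fixed_mods)
  }
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus H2O plus any positional modification deltas.
#' Position 0 is reserved for the N terminus.
#'
#' @param sequence peptide sequence over the 20 canonical residues.
#' @param mods optional data.frame (or NULL) with columns `pos` and `delta`.
#' @param fixed_mods see [residue_masses()].
#' @return neutral mass in Dalton.
#' @export
peptide_mass <- function(sequence, mods = NULL, fixed_mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  rm <- residue_masses(fixed_mods)
  bad <- setdiff(res, names(rm))
  if (length(bad) > 0L) {
    stop("non-canonical residue in sequence: ", paste(unique(bad), collapse = ", "))
  }
  m <- sum(rm[res]) + .WATER_MASS
  if (!is.null(mods) && NROW(mods) > 0L) {
    if (any(mods$pos < 0L | mods$pos > nchar(sequence))) {
      stop("modification position outside peptide")
    }
    m <- m + sum(mods$delta)
  }
  m
}

#' m/z from neutral mass
#'
#' @param neutral neutral mass in Dalton.
#' @param z integer charge >= 1.
#' @param carrier `"proton"` (default; all internal m/z computation) or
#'   `"hydrogen"` (the hydrogen-atom convention many printed diagnostic-ion
#'   masses follow). User-supplied diagnostic/remainder m/z values are matched
#'   verbatim elsewhere, so the convention here only matters for values the
#'   package itself derives.
#' @return m/z = (neutral + z * carrier) / z.
#' @export
mz_from_mass <- function(neutral, z, carrier = c("proton", "hydrogen")) {
  carrier <- match.arg(carrier)
  if (any(z < 1L)) stop("charge must be >= 1")
  cm <- if (carrier == "proton") PROTON_MASS else HYDROGEN_MASS
  (neutral + z * cm) / z
}

#' Relative mass error in parts per million
#'
#' @param observed observed mass or m/z.
#' @param theoretical theoretical mass or m/z, must be > 0.
#' @return 1e6 * (observed - theoretical) / theoretical.
#' @export
ppm_diff <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

# Built-in workflow mass constants. Composition-derivable values are computed
# from formulas; the remaining printed values (4SU nucleoside/base, the three
# large ADP-ribose diagnostics, the Arg-side-chain remainder) are stored
# verbatim because no composition reproduces them at the printed precision.
.labile_constants <- function() {
  hm <- HYDROGEN_MASS
  list(
    phospho = mass_of(parse_composition("HPO3")),          # +79.96633
    phosphoric_acid = mass_of(parse_composition("H3PO4")), # 97.97690
    water = .WATER_MASS,                                   # 18.01056
    ammonia = .NH3_MASS,                                   # 17.02655
    adp_ribose = mass_of(parse_composition("C15H21N5O13P2")),        # 541.06111
    adpr_diag_adenine = mass_of(parse_composition("C5H5N5")) + hm,   # 136.06232
    adpr_diag_adenosine = mass_of(parse_composition("C10H11N5O3")) + hm, # 250.09401
    adpr_diag_348 = 348.07036,  # verbatim; composition not confidently assigned
    adpr_diag_428 = 428.03669,  # verbatim
    adpr_diag_584 = 584.09018,  # verbatim; mouse-tissue searches only
    adpr_rem_ribose = mass_of(parse_composition("C5H6O3")),      # 114.03169
    adpr_rem_ribose_p = mass_of(parse_composition("C5H7O6P")),   # 193.99802
    adpr_rem_ribose_p2 = mass_of(parse_composition("C5H10O10P2")),  # 291.97492
    adpr_rem_adp = mass_of(parse_composition("C10H16O13P2")),    # 406.00661
    adpr_arg_fragment_rem = -42.0205,  # verbatim; printed as loss of CN2H2
    fouru_nucleoside = 226.0594,       # verbatim; 4SU intact nucleoside
    fouru_base = 94.0168               # verbatim; 4SU base after ribose loss
  )
}

#' Built-in modification mass constants
#'
#' Monoisotopic masses used by the shipped workflow templates: the phospho
#' offset (+HPO3) and phosphoric-acid/water/ammonia neutral losses; the
#' ADP-ribose offset with its adenine-derived diagnostic ions and
#' ribose/phosphoribose peptide-remainder series; and the 4-thiouridine
#' RNA-crosslink nucleoside/base offsets. Values derivable from an elemental
#' composition are computed from it at run time; the rest are the published
#' values stored verbatim.
#'
#' @return named list of masses in Dalton.
#' @export
labile_constants <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- .labile_constants()
    cache
  }
})
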