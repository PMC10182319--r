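#' Theoretical backbone fragment ions of a modified peptide form
#'
#' Generates b/y (and optionally c/z-dot) ions at ordinals 1..n-1 for charges
#' 1..`max_frag_charge`. Placed variable modifications shift every ion whose
#' residue span contains the modified position (an N-terminal mod at position
#' 0 rides on every prefix ion). The labile mass offset shifts no fragment
#' ion — under the complete-loss model only the precursor carries it.
#'
#' Series arithmetic: b = prefix residue sum; y = suffix residue sum + H2O;
#' c = b + NH3; z = y - NH3 + H (the ETD-standard z-dot radical).
#'
#' @param f an `ltm_modform`.
#' @param series character subset of `c("b","y","c","z")`.
#' @param max_frag_charge maximum fragment charge.
#' @param fixed_mods named residue-delta vector.
#' @return data.frame with columns `series`, `ordinal`, `charge`, `mz`,
#'   `remainder` (0 for base ions), `site` (NA for base ions).
#' @export
theoretical_ions <- function(f, series = c("b", "y"), max_frag_charge = 1L,
                             fixed_mods = NULL) {
  stopifnot(length(series) > 0L, all(series %in% c("b", "y", "c", "z")))
  res <- strsplit(f$sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  rm <- residue_masses(fixed_mods)
  delta <- numeric(n)               # per-residue variable-mod deltas
  nterm_delta <- 0
  if (NROW(f$var_mods) > 0L) {
    for (r in seq_len(nrow(f$var_mods))) {
      p <- f$var_mods$pos[r]
      if (p == 0L) nterm_delta <- nterm_delta + f$var_mods$delta[r]
      else delta[p] <- delta[p] + f$var_mods$delta[r]
    }
  }
  masses <- rm[res] + delta
  prefix <- cumsum(masses)[-n] + nterm_delta       # neutral b_i, i = 1..n-1
  suffix <- cumsum(rev(masses))[-n] + .WATER_MASS  # neutral y_i = last i residues + H2O
  neutral <- list(
    b = prefix,
    y = suffix,
    c = prefix + .NH3_MASS,
    z = suffix - .NH3_MASS + HYDROGEN_MASS
  )
  out <- list()
  for (sr in series) {
    for (z in seq_len(max_frag_charge)) {
      out[[length(out) + 1L]] <- data.frame(
        series = sr, ordinal = seq_len(n - 1L), charge = z,
        mz = mz_from_mass(neutral[[sr]], z), remainder = 0,
        site = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Does ion (series, ordinal) of an n-residue peptide cover position `site`?
# Prefix series (b/c) span residues 1..i; suffix series (y/z) span n-i+1..n.
# Site 0 (N terminus) belongs to the prefix ions only.
.ion_covers_site <- function(series, ordinal, n, site) {
  pre <- series %in% c("b", "c")
  (pre & site <= ordinal) | (!pre & site >= n - ordinal + 1L & site >= 1L)
}

#' Fragment-remainder variants of backbone ions
#'
#' For each base ion whose residue span covers `site`, adds a variant shifted
#' by `remainder` (which may be negative, e.g. -18.01056 for net water loss
#' after phosphoric-acid loss). Ions not covering the site are not
#' duplicated; a zero remainder is degenerate and yields no variants.
#'
#' @param ions base ions from [theoretical_ions()].
#' @param f the `ltm_modform` the ions belong to.
#' @param site residue position (1-based) carrying the labile modification.
#' @param remainder remainder mass in Dalton.
#' @return data.frame of additional variant ions (same columns as input).
#' @export
apply_fragment_remainder <- function(ions, f, site, remainder) {
  n <- nchar(f$sequence)
  if (site < 1L || site > n) stop("remainder site outside peptide")
  if (remainder == 0) return(ions[0, , drop = FALSE])
  cover <- .ion_covers_site(ions$series, ions$ordinal, n, site)
  v <- ions[cover, , drop = FALSE]
  if (nrow(v) == 0L) return(v)
  v$mz <- v$mz + remainder / v$charge
  v$remainder <- remainder
  v$site <- as.integer(site)
  rownames(v) <- NULL
  v
}

#' Peptide-remainder ion m/z values
#'
#' The intact peptide (without the labile offset, with any placed variable
#' mods) plus each configured remainder mass, at each charge.
#'
#' @param f an `ltm_modform`.
#' @param remainders numeric remainder masses in Dalton (0 gives the
#'   complete-loss unmodified-peptide ion).
#' @param charges integer charges.
#' @return data.frame with `mz`, `remainder`, `charge`, `label`.
#' @export
peptide_remainder_mzs <- function(f, remainders, charges = 1L) {
  base <- f$base_mass + sum(f$var_mods$delta)
  grid <- expand.grid(remainder = remainders, charge = as.integer(charges))
  data.frame(mz = mz_from_mass(base + grid$remainder, grid$charge),
             remainder = grid$remainder, charge = grid$charge,
             label = sprintf("pepR%+.5f/%d", grid$remainder, grid$charge),
             stringsAsFactors = FALSE)
}
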