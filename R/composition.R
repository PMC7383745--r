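#' Glycan composition
#'
#' A composition is a count vector over the residue alphabet
#' \{Hex, HexNAc, Pen, Me, dHex\}. The deoxyhexose count is kept separately
#' when it is known (e.g. after an MS/MS loss of 146.06 Da); at the MS1 level
#' a deoxyhexose is indistinguishable from one pentose plus one methyl group
#' and can be folded with [fold_dhex()].
#'
#' @param hex,hexnac,pen,me,dhex non-negative integer residue counts.
#' @return An object of class `glycan_composition`.
#' @examples
#' os3231 <- glycan_composition(hex = 3, hexnac = 2, pen = 3, me = 1)
#' ion_mz(os3231)  # 1343.46, the 'Kei' group marker
#' @seealso [neutral_mass()], [ion_mz()], [format_os_code()]
#' @export
glycan_composition <- function(hex = 0, hexnac = 0, pen = 0, me = 0, dhex = 0) {
  counts <- c(hex = hex, hexnac = hexnac, pen = pen, me = me, dhex = dhex)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("residue counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format_os_code(x))
  if (x$dhex > 0) cat(sprintf("  [dHex%d kept unfolded]", x$dhex))
  cat(sprintf("  (Hex%d HexNAc%d Pen%d Me%d dHex%d), neutral mass %.4f Da\n",
              x$hex, x$hexnac, x$pen, x$me, x$dhex, neutral_mass(x)))
  invisible(x)
}

#' @export
`==.glycan_composition` <- function(e1, e2) {
  identical(unclass(fold_dhex(e1)), unclass(fold_dhex(e2)))
}

#' Fold deoxyhexoses into pentose + methyl
#'
#' Replaces every dHex by one Pen plus one Me. Because dHex and Pen+Me share
#' the elemental formula C6H10O4, mass is exactly preserved; the folded form
#' is the canonical composition used by the "os" code and by MS1 matching.
#'
#' @param x a `glycan_composition`.
#' @return The folded `glycan_composition` (dHex count zero).
#' @export
fold_dhex <- function(x) {
  stopifnot(inherits(x, "glycan_composition"))
  if (x$dhex == 0) return(x)
  glycan_composition(x$hex, x$hexnac, x$pen + x$dhex, x$me + x$dhex, 0)
}

#' Sum of residue masses (no water, no adduct)
#' @noRd
residue_mass <- function(x, constants = mass_constants()) {
  x$hex * constants$hex + x$hexnac * constants$hexnac +
    x$pen * constants$pen + x$me * constants$me + x$dhex * constants$dhex
}

#' Neutral monoisotopic mass of a glycan composition
#'
#' The mass of the free reducing oligosaccharide: the sum of dehydrated
#' residue masses plus one water for the reducing terminus. Additive over
#' residue counts; the empty composition returns the water mass.
#'
#' @param x a `glycan_composition`.
#' @param constants mass constant set, see [mass_constants()].
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(x, constants = mass_constants()) {
  stopifnot(inherits(x, "glycan_composition"))
  residue_mass(x, constants) + constants$water
}

#' m/z of a glycan ion
#'
#' Computes the mass-to-charge ratio of an adducted glycan. MALDI spectra of
#' underivatized glycans are dominated by singly charged sodium adducts
#' (`[M+Na]+`), the default here. Reduced glycans (alditols, as used for
#' LC-ESI work) gain two hydrogen atoms relative to the reducing form.
#' Multiply charged ions add one charge carrier per charge and divide by the
#' charge.
#'
#' @param x a `glycan_composition`.
#' @param adduct `"sodiated"` or `"protonated"`.
#' @param charge positive integer charge state.
#' @param reduced logical; `TRUE` for the alditol (reduced) form.
#' @param constants mass constant set.
#' @return m/z value.
#' @examples
#' ion_mz(parse_os_code("os4223"))              # 1401.5, 'Hel' main glycan
#' ion_mz(glycan_composition(hex = 5, hexnac = 3))  # 1460.5, Man5Gn
#' @export
ion_mz <- function(x, adduct = c("sodiated", "protonated"), charge = 1L,
                   reduced = FALSE, constants = mass_constants()) {
  adduct <- match.arg(adduct)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  carrier <- switch(adduct,
                    sodiated = constants$sodium_cation,
                    protonated = constants$proton)
  m <- neutral_mass(x, constants)
  if (reduced) m <- m + 2 * constants$hydrogen
  (m + charge * carrier) / charge
}

#' Round half away from zero at a fixed number of decimals
#'
#' Mass values in reports are rounded half-up (1343.455 -> 1343.46), the
#' convention followed by printed MALDI tables, rather than R's banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_mz <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
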