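#' Monoisotopic mass constants for glycan residues and adducts
#'
#' Residue masses are the monoisotopic masses of the dehydrated
#' monosaccharide units as they occur inside a glycan chain, fixed at five
#' decimal places: hexose (Hex), N-acetylhexosamine (HexNAc), pentose (Pen),
#' a methyl increment (Me, replacing H by CH3), and deoxyhexose (dHex).
#' A deoxyhexose has the same elemental formula (C6H10O4) as a methylated
#' pentose, so `dhex == pen + me` holds exactly; this identity is what lets
#' MS1 compositions fold a deoxyhexose into one pentose plus one methyl.
#' The sodium cation mass is electron-corrected.
#'
#' @param versioned logical; if `TRUE`, attach the constant-set version
#'   string as an attribute.
#' @return Named list of masses in Da: `hex`, `hexnac`, `pen`, `me`, `dhex`,
#'   `water`, `sodium_cation`, `proton`, `hydrogen`.
#' @examples
#' k <- mass_constants()
#' stopifnot(k$dhex == k$pen + k$me)
#' @export
mass_constants <- function(versioned = FALSE) {
  k <- list(
    hex           = 162.05282,
    hexnac        = 203.07937,
    pen           = 132.04226,
    me            = 14.01565,
    dhex          = 146.05791,
    water         = 18.01056,
    sodium_cation = 22.98922,
    proton        = 1.00728,
    hydrogen      = 1.00783
  )
  if (versioned) attr(k, "version") <- .mass_constants_version
  k
}

.mass_constants_version <- "1.0"

#' Export the mass constants as versioned JSON
#'
#' Writes the constant set together with its version string so that
#' downstream annotation reports are traceable to the exact arithmetic used.
#'
#' @param path file to write; defaults to stdout.
#' @return `path`, invisibly.
#' @export
write_mass_constants <- function(path = stdout()) {
  obj <- c(list(version = .mass_constants_version), mass_constants())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
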