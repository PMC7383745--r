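#' In-silico core alpha-1,6-fucosyltransferase transfer
#'
#' Models the substrate test used to confirm the identity of the Man5Gn
#' glycan (Hex5HexNAc3): human core alpha-1,6-fucosyltransferase transfers a
#' single fucose onto the reducing-end GlcNAc of an N-glycan that carries an
#' antennary GlcNAc (the GlcNAc-transferase-I product). Man5 itself
#' (Hex5HexNAc2, no free antennary GlcNAc) is not a substrate and is
#' refused; so is any composition that is already core-fucosylated, since a
#' single transfer is modelled.
#'
#' @param x a `glycan_composition`; must carry at least three HexNAc (the
#'   chitobiose core plus the antennary GlcNAc) and no dHex.
#' @return `x` plus one dHex; the sodiated m/z increases by exactly the dHex
#'   residue mass (146.06 Da), e.g. Man5Gn 1460.5 -> 1606.6.
#' @examples
#' add_core_fucose(glycan_composition(hex = 5, hexnac = 3))
#' @export
add_core_fucose <- function(x) {
  stopifnot(inherits(x, "glycan_composition"))
  if (x$dhex > 0) {
    stop("composition is already core-fucosylated; a single transfer is modelled",
         call. = FALSE)
  }
  if (x$hexnac < 3) {
    stop(paste("not a core alpha-1,6-fucosyltransferase substrate:",
               "an antennary GlcNAc (HexNAc >= 3, as in Man5Gn = Hex5HexNAc3)",
               "is required"), call. = FALSE)
  }
  glycan_composition(x$hex, x$hexnac, x$pen, x$me, x$dhex + 1L)
}

#' PNGase release class from core evidence
#'
#' PNGase F does not cleave N-glycans carrying alpha-1,3-linked fucose on the
#' reducing-end GlcNAc, whereas PNGase A does. Core-fucosylated glycans
#' (e.g. the dominant 'Ori' glycan at m/z 1269.5) therefore emerge only in
#' PNGase A digests; everything else is released by both enzymes.
#'
#' @param core a [core_evidence()] object.
#' @return `"A_only"` when `core13fucose == "yes"`, otherwise `"F_and_A"`.
#' @export
pngase_release <- function(core) {
  stopifnot(inherits(core, "core_evidence"))
  if (identical(core$core13fucose, "yes")) "A_only" else "F_and_A"
}
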