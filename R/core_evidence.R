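.yn <- c("yes", "no", "unknown")

#' Core-substitution evidence
#'
#' Records what a LIFT spectrum says about substitution of the chitobiose
#' core. Logical closure is applied on construction:
#'
#' * an unsubstituted chitobiose implies an unsubstituted GlcNAc-1 and an
#'   unsubstituted GlcNAc-2;
#' * a substituted GlcNAc-2 implies the chitobiose is not unsubstituted;
#' * core alpha-1,3-fucose sits on GlcNAc-1, so it implies GlcNAc-1 is
#'   substituted (and the chitobiose with it);
#' * an unsubstituted GlcNAc-1 rules core fucose out.
#'
#' Contradictory claims (e.g. unsubstituted chitobiose together with a
#' substituted GlcNAc-2) are an error.
#'
#' @param glcnac1_unsubstituted,chitobiose_unsubstituted,glcnac2_substituted,core13fucose
#'   one of `"yes"`, `"no"`, `"unknown"`.
#' @param methylated_hexnac_loss logical; the second GlcNAc was lost as a
#'   methylated residue (217.09 Da).
#' @param supporting_ions optional data frame of matched fragment ions.
#' @param inconsistent logical; set by [infer_core()] when matched ions
#'   conflict.
#' @return An object of class `core_evidence`.
#' @export
core_evidence <- function(glcnac1_unsubstituted = "unknown",
                          chitobiose_unsubstituted = "unknown",
                          glcnac2_substituted = "unknown",
                          core13fucose = "unknown",
                          methylated_hexnac_loss = FALSE,
                          supporting_ions = NULL,
                          inconsistent = FALSE) {
  g1 <- match.arg(glcnac1_unsubstituted, .yn)
  chb <- match.arg(chitobiose_unsubstituted, .yn)
  g2 <- match.arg(glcnac2_substituted, .yn)
  fuc <- match.arg(core13fucose, .yn)
  if (chb == "yes" && g2 == "yes") {
    stop("contradictory evidence: unsubstituted chitobiose together with substituted GlcNAc-2",
         call. = FALSE)
  }
  if (fuc == "yes" && g1 == "yes") {
    stop("contradictory evidence: core 1,3-fucose together with unsubstituted GlcNAc-1",
         call. = FALSE)
  }
  if (chb == "yes" && fuc == "yes") {
    stop("contradictory evidence: core 1,3-fucose together with unsubstituted chitobiose",
         call. = FALSE)
  }
  # closure
  if (chb == "yes") {
    g1 <- "yes"
    g2 <- "no"
  }
  if (g2 == "yes") chb <- "no"
  if (fuc == "yes") {
    g1 <- "no"
    chb <- "no"
  }
  if (g1 == "yes") fuc <- "no"
  structure(list(glcnac1_unsubstituted = g1,
                 chitobiose_unsubstituted = chb,
                 glcnac2_substituted = g2,
                 core13fucose = fuc,
                 methylated_hexnac_loss = isTRUE(methylated_hexnac_loss),
                 supporting_ions = supporting_ions,
                 inconsistent = isTRUE(inconsistent)),
            class = "core_evidence")
}

#' @export
print.core_evidence <- function(x, ...) {
  cat("<core_evidence>\n")
  cat(sprintf("  GlcNAc-1 unsubstituted : %s\n", x$glcnac1_unsubstituted))
  cat(sprintf("  chitobiose unsubstituted: %s\n", x$chitobiose_unsubstituted))
  cat(sprintf("  GlcNAc-2 substituted   : %s\n", x$glcnac2_substituted))
  cat(sprintf("  core 1,3-fucose        : %s\n", x$core13fucose))
  if (x$methylated_hexnac_loss) cat("  (second GlcNAc lost as methylated residue)\n")
  if (x$inconsistent) cat("  WARNING: conflicting ion evidence\n")
  cat(sprintf("  PNGase release class   : %s\n", pngase_release(x)))
  invisible(x)
}

#' Compare two evidence objects on their four status fields
#' @noRd
core_status <- function(x) {
  c(g1 = x$glcnac1_unsubstituted, chb = x$chitobiose_unsubstituted,
    g2 = x$glcnac2_substituted, fuc = x$core13fucose,
    me = as.character(x$methylated_hexnac_loss))
}

#' Infer chitobiose-core substitution from matched LIFT fragments
#'
#' Applies, in order, the reading rules for reducing-end neutral losses:
#'
#' * R1 — a direct loss of 221.09 Da (the reducing GlcNAc with its water)
#'   shows GlcNAc-1 carries no substituent.
#' * R2 — consecutive losses of 221.09 then 203.08 Da (or 217.09 Da for a
#'   methylated second GlcNAc) show the whole chitobiose core is
#'   unsubstituted.
#' * R3 — when no fragment lacking both core GlcNAcs is observed but a
#'   complementary b/y pair splitting exactly at the chitobiose (the y ion
#'   retaining HexNAc2 plus at least one further residue) is, the second
#'   GlcNAc must carry the substituent.
#' * R4 — when the 221.09 loss never occurs directly but only after a
#'   146.06 Da (deoxyhexose) loss, GlcNAc-1 carries core 1,3-linked fucose;
#'   R4 is evaluated before GlcNAc-1 status is declared unknown.
#'
#' Evidence only accumulates: fields not decided by any rule stay
#' `"unknown"`; a direct 221.09 loss co-occurring with the fucose cascade is
#' flagged inconsistent rather than silently overwritten.
#'
#' @param matches a [match_lift()] result.
#' @param precursor optional; defaults to the precursor stored in `matches`.
#' @return A [core_evidence()] object with the matched ions attached.
#' @export
infer_core <- function(matches, precursor = NULL) {
  stopifnot(inherits(matches, "lift_match"))
  if (is.null(precursor)) precursor <- matches$precursor
  m <- matches$matched
  has <- function(lab) any(m$kind == "neutral-loss" & m$label == lab)
  loss1 <- has("-1 Gn")
  loss2 <- has("-2 Gn")
  loss2me <- has("-2 Gn(Me)")
  dhex <- has("-dHex")
  cascade <- has("-dHex-1 Gn")

  # complementary pair splitting at the chitobiose: both members matched,
  # y side retaining exactly the two core GlcNAcs plus >= 1 other residue
  pair_found <- FALSE
  py <- m[m$kind == "y" & m$hexnac == 2 & (m$hex + m$pen + m$me) > 0, ,
          drop = FALSE]
  if (nrow(py)) {
    pb <- m$pair_id[m$kind == "b"]
    pair_found <- any(py$pair_id %in% pb)
  }

  g1 <- if (loss1) "yes" else "unknown"
  chb <- if (loss1 && (loss2 || loss2me)) "yes" else "unknown"
  g2 <- "unknown"
  if (!loss2 && !loss2me && pair_found) g2 <- "yes"
  fuc <- if (loss1) "no" else if (dhex && cascade) "yes" else "unknown"
  if (fuc == "yes") g1 <- "no"
  inconsistent <- loss1 && cascade && dhex

  core_evidence(glcnac1_unsubstituted = g1,
                chitobiose_unsubstituted = chb,
                glcnac2_substituted = g2,
                core13fucose = fuc,
                methylated_hexnac_loss = loss1 && loss2me,
                supporting_ions = m,
                inconsistent = inconsistent)
}
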