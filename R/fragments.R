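#' Enumerate theoretical b/y fragments and canonical neutral losses
#'
#' For a sodiated precursor composition, enumerates every bipartition of the
#' (dHex-folded) composition as a complementary b/y ion pair, plus the
#' canonical reducing-end neutral-loss ladder used to read chitobiose-core
#' substitution from LIFT spectra:
#'
#' * `-1 Gn`: loss of the reducing GlcNAc (221.09 Da = HexNAc + water),
#' * `-2 Gn`: consecutive loss of both core GlcNAcs (221.09 + 203.08),
#' * `-2 Gn(Me)`: the second GlcNAc lost as a methylated residue
#'   (221.09 + 217.09), emitted when the precursor carries a methyl,
#' * `-dHex` and `-dHex-1 Gn`: the core-fucose loss cascade (146.06, then
#'   221.09), emitted when the folded composition admits a deoxyhexose.
#'
#' Ion arithmetic: a y ion retains the reducing end, `m(y) = residues +
#' water + Na`; a b ion retains the non-reducing end, `m(b) = residues +
#' Na`; hence for every pair `m(b) + m(y) = precursor m/z + Na` exactly.
#' Internal (by) ions are isobaric with b ions of the same retained
#' composition at this level and are not listed separately; inference rules
#' use only b/y/neutral-loss evidence.
#'
#' @param precursor a `glycan_composition` with `hexnac >= 2` (the
#'   chitobiose core every N-glycan carries).
#' @param constants mass constant set.
#' @return Data frame: `kind` (`"y"`, `"b"`, `"neutral-loss"`), `label`
#'   (retained os code, or the loss label), retained counts `hex`,
#'   `hexnac`, `pen`, `me`, `mz`, and `pair_id` linking complementary b/y
#'   rows (`NA` for losses). Order is deterministic.
#' @examples
#' fr <- enumerate_fragments(parse_os_code("os3231"))
#' fr[fr$label == "-1 Gn", ]   # the 1122.4 y1-type loss
#' @export
enumerate_fragments <- function(precursor, constants = mass_constants()) {
  stopifnot(inherits(precursor, "glycan_composition"))
  p <- fold_dhex(precursor)
  if (p$hexnac < 2) {
    stop("precursor must contain the chitobiose core (HexNAc >= 2)",
         call. = FALSE)
  }
  na <- constants$sodium_cation
  w <- constants$water
  res_mass <- function(h, n, pe, m) {
    h * constants$hex + n * constants$hexnac + pe * constants$pen +
      m * constants$me
  }
  prec_mz <- res_mass(p$hex, p$hexnac, p$pen, p$me) + w + na

  g <- expand.grid(hex = 0:p$hex, hexnac = 0:p$hexnac, pen = 0:p$pen,
                   me = 0:p$me, KEEP.OUT.ATTRS = FALSE)
  total <- g$hex + g$hexnac + g$pen + g$me
  full <- p$hex + p$hexnac + p$pen + p$me
  g <- g[total > 0 & total < full, , drop = FALSE]
  g <- g[order(g$hex, g$hexnac, g$pen, g$me), , drop = FALSE]

  os_of <- function(h, n, pe, m) {
    format_os_code(glycan_composition(h, n, pe, m))
  }
  n_pair <- nrow(g)
  pairs <- if (n_pair) {
    y_mz <- res_mass(g$hex, g$hexnac, g$pen, g$me) + w + na
    b_mz <- prec_mz + na - y_mz
    rbind(
      data.frame(kind = "y",
                 label = mapply(os_of, g$hex, g$hexnac, g$pen, g$me),
                 hex = g$hex, hexnac = g$hexnac, pen = g$pen, me = g$me,
                 mz = y_mz, pair_id = seq_len(n_pair),
                 stringsAsFactors = FALSE),
      data.frame(kind = "b",
                 label = mapply(os_of, p$hex - g$hex, p$hexnac - g$hexnac,
                                p$pen - g$pen, p$me - g$me),
                 hex = p$hex - g$hex, hexnac = p$hexnac - g$hexnac,
                 pen = p$pen - g$pen, me = p$me - g$me,
                 mz = b_mz, pair_id = seq_len(n_pair),
                 stringsAsFactors = FALSE))
  } else NULL

  loss_row <- function(label, d_hex, d_hexnac, d_pen, d_me, d_water) {
    data.frame(kind = "neutral-loss", label = label,
               hex = p$hex - d_hex, hexnac = p$hexnac - d_hexnac,
               pen = p$pen - d_pen, me = p$me - d_me,
               mz = prec_mz - res_mass(d_hex, d_hexnac, d_pen, d_me) -
                 d_water * w,
               pair_id = NA_integer_, stringsAsFactors = FALSE)
  }
  losses <- list(loss_row("-1 Gn", 0, 1, 0, 0, 1),
                 loss_row("-2 Gn", 0, 2, 0, 0, 1))
  if (p$me >= 1) {
    losses <- c(losses, list(loss_row("-2 Gn(Me)", 0, 2, 0, 1, 1)))
  }
  if (p$pen >= 1 && p$me >= 1) {
    losses <- c(losses, list(loss_row("-dHex", 0, 0, 1, 1, 0),
                             loss_row("-dHex-1 Gn", 0, 1, 1, 1, 1)))
  }
  out <- rbind(pairs, do.call(rbind, losses))
  rownames(out) <- NULL
  attr(out, "precursor_mz") <- prec_mz
  attr(out, "precursor_os") <- format_os_code(p)
  class(out) <- c("fragment_ions", "data.frame")
  out
}

#' Match a LIFT (MS2) spectrum against theoretical fragments
#'
#' Matches every theoretical fragment of the precursor composition to the
#' nearest observed peak within `tol`; peaks explained by no hypothesis are
#' reported separately. The declared precursor m/z of the spectrum must
#' agree with the composition's sodiated m/z within `ms1_tol`.
#'
#' @param s a `glyco_spectrum` with `level = "MS2"`.
#' @param precursor the assigned `glycan_composition`.
#' @param tol MS2 matching tolerance in Da (LIFT masses deviate up to
#'   ~0.3 Da from theory).
#' @param ms1_tol allowed discrepancy between the declared precursor m/z
#'   and the composition.
#' @return List of class `lift_match`: `matched` (fragment rows plus
#'   `obs_mz`, `intensity`, `error`), `unmatched_peaks` (data frame), and
#'   `precursor`.
#' @export
match_lift <- function(s, precursor, tol = 0.3, ms1_tol = 0.5) {
  stopifnot(inherits(s, "glyco_spectrum"))
  if (s$level != "MS2") stop("match_lift expects an MS2 spectrum", call. = FALSE)
  frags <- enumerate_fragments(precursor)
  prec_mz <- attr(frags, "precursor_mz")
  if (is.na(s$precursor_mz) || abs(s$precursor_mz - prec_mz) > ms1_tol) {
    stop(sprintf(
      "declared precursor m/z %.3f inconsistent with composition %s (%.3f)",
      s$precursor_mz, format_os_code(precursor), prec_mz), call. = FALSE)
  }
  pk <- s$peaks
  obs_mz <- rep(NA_real_, nrow(frags))
  obs_int <- rep(NA_real_, nrow(frags))
  for (i in seq_len(nrow(frags))) {
    if (!nrow(pk)) break
    d <- abs(pk$mz - frags$mz[i])
    j <- which.min(d)
    if (d[j] <= tol) {
      obs_mz[i] <- pk$mz[j]
      obs_int[i] <- pk$intensity[j]
    }
  }
  hit_peak <- vapply(pk$mz, function(z) any(abs(frags$mz - z) <= tol),
                     logical(1))
  matched <- frags[!is.na(obs_mz), , drop = FALSE]
  matched$obs_mz <- obs_mz[!is.na(obs_mz)]
  matched$intensity <- obs_int[!is.na(obs_mz)]
  matched$error <- matched$obs_mz - matched$mz
  class(matched) <- "data.frame"
  rownames(matched) <- NULL
  structure(list(matched = matched,
                 unmatched_peaks = pk[!hit_peak, , drop = FALSE],
                 precursor = precursor,
                 precursor_mz = prec_mz,
                 tol = tol),
            class = "lift_match")
}

#' @export
print.lift_match <- function(x, ...) {
  cat(sprintf("<lift_match> precursor %s (m/z %.2f): %d fragments matched, %d peaks unexplained\n",
              format_os_code(x$precursor), x$precursor_mz,
              nrow(x$matched), nrow(x$unmatched_peaks)))
  invisible(x)
}
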