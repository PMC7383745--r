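#' Oligomannosidic anchor compositions
#'
#' The Man5-Man9 glycans (Hex5..9 HexNAc2) present in essentially every
#' sample; their sodiated ions serve as internal calibrants.
#'
#' @param n_hex integer vector of hexose counts.
#' @return List of `glycan_composition` objects.
#' @export
oligomannose_anchors <- function(n_hex = 5:9) {
  lapply(n_hex, function(h) glycan_composition(hex = h, hexnac = 2L))
}

#' Internal recalibration on oligomannosidic glycans
#'
#' Finds the observed peaks nearest to each anchor's theoretical sodiated
#' m/z within a coarse window, fits a linear correction
#' `true = offset + slope * observed` by least squares, and applies it to
#' every peak. With fewer than two matched anchors the spectrum is returned
#' unchanged with a warning. The least-squares family contains the identity
#' map, so the fit can never increase the anchors' residual sum of squares.
#'
#' @param s a `glyco_spectrum` (MS1).
#' @param anchors list of anchor compositions, default Man5-Man9.
#' @param coarse_tol matching window in Da for locating anchors
#'   pre-calibration.
#' @return The recalibrated spectrum, `calibrated = TRUE`, with a
#'   `calibration` element recording offset, slope, the matched anchors and
#'   their residuals before and after correction.
#' @export
recalibrate <- function(s, anchors = oligomannose_anchors(),
                        coarse_tol = 0.5) {
  stopifnot(inherits(s, "glyco_spectrum"))
  theor <- vapply(anchors, ion_mz, numeric(1))
  obs <- rep(NA_real_, length(theor))
  for (i in seq_along(theor)) {
    if (!nrow(s$peaks)) break
    d <- abs(s$peaks$mz - theor[i])
    j <- which.min(d)
    if (d[j] <= coarse_tol) obs[i] <- s$peaks$mz[j]
  }
  ok <- !is.na(obs)
  if (sum(ok) < 2) {
    warning("fewer than 2 oligomannosidic anchors matched; spectrum left uncalibrated")
    s$calibration <- list(matched = sum(ok), offset = 0, slope = 1,
                          applied = FALSE)
    return(s)
  }
  fit <- stats::lm(theor[ok] ~ obs[ok])
  co <- stats::coef(fit)
  s$peaks$mz <- as.numeric(co[1] + co[2] * s$peaks$mz)
  s$calibrated <- TRUE
  s$calibration <- list(
    matched = sum(ok), offset = unname(co[1]), slope = unname(co[2]),
    applied = TRUE,
    anchor_mz = theor[ok],
    residual_before = unname(theor[ok] - obs[ok]),
    residual_after = unname(theor[ok] - (co[1] + co[2] * obs[ok])))
  s
}

.default_bounds <- list(hex = c(0L, 12L), hexnac = c(2L, 4L),
                        pen = c(0L, 4L), me = c(0L, 8L))

# composition grid over a bound box, with sodiated singly charged m/z
.composition_grid <- local({
  cache <- new.env(parent = emptyenv())
  function(bounds) {
    key <- paste(unlist(bounds), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- mass_constants()
    g <- expand.grid(hex = bounds$hex[1]:bounds$hex[2],
                     hexnac = bounds$hexnac[1]:bounds$hexnac[2],
                     pen = bounds$pen[1]:bounds$pen[2],
                     me = bounds$me[1]:bounds$me[2],
                     KEEP.OUT.ATTRS = FALSE)
    g$mz <- g$hex * k$hex + g$hexnac * k$hexnac + g$pen * k$pen +
      g$me * k$me + k$water + k$sodium_cation
    cache[[key]] <- g
    g
  }
})

#' Enumerate glycan compositions matching a mass
#'
#' Exhaustively searches the bound box of residue counts for compositions
#' whose sodiated singly charged m/z falls within `tol` of the query. The
#' default bounds (Hex 0-12, HexNAc 2-4, Pen 0-4, Me 0-8) cover every
#' composition reported for the 13 glyco-groups. Results are returned in the
#' folded (Pen+Me) canonical form; compositions that could alternatively
#' contain a deoxyhexose (at least one Pen and one Me) are flagged as
#' isobaric dHex aliases, an ambiguity MS1 cannot resolve.
#'
#' Ordering is deterministic: by absolute mass error, then total residue
#' count (simplest first), then lexicographically on (Hex, HexNAc, Pen, Me).
#' The result set is monotone in `tol`.
#'
#' @param mz query m/z (sodiated, singly charged assumed).
#' @param tol matching tolerance in Da.
#' @param bounds list with elements `hex`, `hexnac`, `pen`, `me`, each a
#'   `c(min, max)` pair.
#' @return Data frame of class `composition_matches` with columns `os`,
#'   `hex`, `hexnac`, `pen`, `me`, `mz`, `error` (observed - theoretical),
#'   `ppm`, `dhex_alias`. Zero rows when nothing matches (an unassigned
#'   peak, not an error).
#' @examples
#' decompose_mass(1343.46)        # includes os3231
#' @export
decompose_mass <- function(mz, tol = 0.15, bounds = .default_bounds) {
  stopifnot(is.numeric(mz), length(mz) == 1L, tol > 0)
  g <- .composition_grid(bounds)
  err <- mz - g$mz
  hit <- which(abs(err) <= tol)
  res <- g[hit, c("hex", "hexnac", "pen", "me"), drop = FALSE]
  res$mz <- g$mz[hit]
  res$error <- err[hit]
  res$ppm <- 1e6 * res$error / res$mz
  total <- res$hex + res$hexnac + res$pen + res$me
  o <- order(abs(res$error), total, res$hex, res$hexnac, res$pen, res$me)
  res <- res[o, , drop = FALSE]
  res$dhex_alias <- res$pen >= 1 & res$me >= 1
  res$os <- vapply(seq_len(nrow(res)), function(i) {
    format_os_code(glycan_composition(res$hex[i], res$hexnac[i],
                                      res$pen[i], res$me[i]))
  }, character(1))
  rownames(res) <- NULL
  res <- res[, c("os", "hex", "hexnac", "pen", "me", "mz", "error", "ppm",
                 "dhex_alias")]
  class(res) <- c("composition_matches", "data.frame")
  res
}

#' Annotate an MS1 spectrum with glycan compositions
#'
#' Runs [decompose_mass()] on every peak above the intensity floor and
#' records the best candidate (smallest absolute error, simplest
#' composition) per peak. Oligomannosidic compositions are flagged: the
#' unmethylated ones (HexNAc2, Pen0, Me0) form the internal-calibrant anchor
#' class; methylated oligomannose (HexNAc2, Pen0, Me > 0) is flagged
#' separately because the per-spectrum methylation ceiling is itself a group
#' diagnostic.
#'
#' @param s a `glyco_spectrum`, level MS1. Annotating an uncalibrated
#'   spectrum is permitted (the caller waives recalibration).
#' @param tol matching tolerance in Da.
#' @param intensity_floor fraction of the base-peak intensity below which
#'   peaks are skipped (default 1 %). Use 0 to annotate everything.
#' @param bounds passed to [decompose_mass()].
#' @return Data frame of class `glyco_annotation`: one row per annotated
#'   peak with columns `mz`, `intensity`, `rel_intensity`, `os`, `hex`,
#'   `hexnac`, `pen`, `me`, `error`, `ppm`, `n_candidates`, `is_anchor`,
#'   `is_oligomannose`. Peaks with no candidate get `NA` assignment columns.
#' @export
annotate_spectrum <- function(s, tol = 0.15, intensity_floor = 0.01,
                              bounds = .default_bounds) {
  stopifnot(inherits(s, "glyco_spectrum"))
  if (s$level != "MS1") stop("annotate_spectrum expects an MS1 spectrum",
                             call. = FALSE)
  pk <- s$peaks
  if (!nrow(pk)) {
    out <- data.frame(mz = numeric(0), intensity = numeric(0),
                      rel_intensity = numeric(0), os = character(0),
                      hex = integer(0), hexnac = integer(0), pen = integer(0),
                      me = integer(0), error = numeric(0), ppm = numeric(0),
                      n_candidates = integer(0), is_anchor = logical(0),
                      is_oligomannose = logical(0))
    class(out) <- c("glyco_annotation", "data.frame")
    return(out)
  }
  base <- max(pk$intensity)
  keep <- if (base > 0) pk$intensity >= intensity_floor * base else
    rep(TRUE, nrow(pk))
  pk <- pk[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pk)), function(i) {
    cand <- decompose_mass(pk$mz[i], tol = tol, bounds = bounds)
    if (nrow(cand) == 0) {
      data.frame(mz = pk$mz[i], intensity = pk$intensity[i],
                 rel_intensity = pk$intensity[i] / base,
                 os = NA_character_, hex = NA_integer_, hexnac = NA_integer_,
                 pen = NA_integer_, me = NA_integer_, error = NA_real_,
                 ppm = NA_real_, n_candidates = 0L,
                 is_anchor = FALSE, is_oligomannose = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      top <- cand[1, ]
      data.frame(mz = pk$mz[i], intensity = pk$intensity[i],
                 rel_intensity = pk$intensity[i] / base,
                 os = top$os, hex = top$hex, hexnac = top$hexnac,
                 pen = top$pen, me = top$me, error = top$error,
                 ppm = top$ppm, n_candidates = nrow(cand),
                 is_anchor = top$hexnac == 2L && top$pen == 0L && top$me == 0L,
                 is_oligomannose = top$hexnac == 2L && top$pen == 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- s$sample_id
  attr(out, "tol") <- tol
  class(out) <- c("glyco_annotation", "data.frame")
  out
}

#' @export
print.glyco_annotation <- function(x, ...) {
  cat(sprintf("<glyco_annotation> %d peaks, %d assigned (tol %.2f Da)\n",
              nrow(x), sum(!is.na(x$os)), attr(x, "tol")))
  print.data.frame(utils::head(as.data.frame(x), 20), digits = 6)
  if (nrow(x) > 20) cat("...\n")
  invisible(x)
}

#' Detect 14-Da methylation ladders
#'
#' Groups assigned peaks whose compositions differ only in the methyl count
#' and are consecutive in Me (mass spacing 14.016 Da): the classic signature
#' of O-methylation. Also reports the per-spectrum maximum methyl count seen
#' on oligomannosidic glycans, the feature that separates lightly methylated
#' groups (up to three methyls) from heavily methylated ones (up to seven).
#'
#' @param ann a `glyco_annotation`.
#' @return List of class `methyl_ladders` with elements `ladders` (data
#'   frame: `base_os`, `top_os`, `length`, `hex`, `hexnac`, `pen`, `me_min`,
#'   `me_max`) and `oligomannose_max_me` (integer; 0 when oligomannose is
#'   present but unmethylated, `NA` when none is assigned).
#' @export
detect_methyl_ladder <- function(ann) {
  stopifnot(inherits(ann, "glyco_annotation"))
  a <- ann[!is.na(ann$os), , drop = FALSE]
  ladders <- list()
  if (nrow(a)) {
    key <- paste(a$hex, a$hexnac, a$pen, sep = "/")
    for (k in unique(key)) {
      me <- sort(unique(a$me[key == k]))
      if (length(me) < 2) next
      runs <- split(me, cumsum(c(1L, diff(me) != 1L)))
      for (r in runs) {
        if (length(r) < 2) next
        g <- a[key == k & a$me == r[1], ][1, ]
        ladders[[length(ladders) + 1L]] <- data.frame(
          base_os = format_os_code(glycan_composition(g$hex, g$hexnac, g$pen,
                                                      min(r))),
          top_os = format_os_code(glycan_composition(g$hex, g$hexnac, g$pen,
                                                     max(r))),
          length = length(r), hex = g$hex, hexnac = g$hexnac, pen = g$pen,
          me_min = min(r), me_max = max(r), stringsAsFactors = FALSE)
      }
    }
  }
  ladders <- if (length(ladders)) do.call(rbind, ladders) else
    data.frame(base_os = character(0), top_os = character(0),
               length = integer(0), hex = integer(0), hexnac = integer(0),
               pen = integer(0), me_min = integer(0), me_max = integer(0))
  om <- a$is_oligomannose
  structure(list(
    ladders = ladders,
    oligomannose_max_me = if (any(om)) max(a$me[om]) else NA_integer_),
    class = "methyl_ladders")
}

#' @export
print.methyl_ladders <- function(x, ...) {
  cat(sprintf("<methyl_ladders> %d ladder(s); oligomannose max Me = %s\n",
              nrow(x$ladders), x$oligomannose_max_me))
  if (nrow(x$ladders)) print.data.frame(x$ladders)
  invisible(x)
}
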