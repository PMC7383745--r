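#' Classify an annotated spectrum into a glyco-group
#'
#' Scores each registry profile against the composition assignments of an
#' MS1 spectrum. A diagnostic counts as matched when some annotated peak's
#' chosen composition equals its os code; "dominant" diagnostics must in
#' addition reach the dominance threshold (default 25 % of the base peak).
#' Required diagnostics weigh 2, supporting diagnostics 1, and the
#' oligomannose-methylation range (where a profile declares one) weighs 1
#' as a series predicate scored against [detect_methyl_ladder()]'s
#' per-spectrum maximum. A forbidden diagnostic present above the dominance
#' threshold zeroes the profile's score; forbidden masses are matched on
#' raw peak m/z with a wider presence window, since zeroing guards a gross
#' pattern mismatch and should not hinge on a borderline composition
#' assignment.
#'
#' The best group is reported as `"orphan"` when no score reaches the
#' orphan threshold; a mixture flag is raised when the runner-up also
#' scores high, which both models genuinely mixed commercial products and,
#' inevitably, fires for the MS1-confusable sibling groups.
#'
#' @param ann a `glyco_annotation` from [annotate_spectrum()].
#' @param ladders a `methyl_ladders` object; computed from `ann` if omitted.
#' @param registry a `glyco_registry`.
#' @param dominance_threshold fraction of base-peak intensity a "dominant"
#'   diagnostic must reach.
#' @param orphan_threshold minimum best score for a group call.
#' @param mixture_threshold second-best score at which the mixture flag is
#'   raised.
#' @param forbidden_tol m/z window (Da) for the raw-peak forbidden check.
#' @return Object of class `glyco_classification`: `scores` (named numeric,
#'   sorted decreasing), `best`, `mixture_flag`, `evidence` (per group, the
#'   matched/missing/violated diagnostics).
#' @export
classify_pattern <- function(ann, ladders = detect_methyl_ladder(ann),
                             registry = builtin_registry(),
                             dominance_threshold = 0.25,
                             orphan_threshold = 0.5,
                             mixture_threshold = 0.35,
                             forbidden_tol = 0.4) {
  stopifnot(inherits(ann, "glyco_annotation"))
  assigned <- ann[!is.na(ann$os), , drop = FALSE]
  max_me <- ladders$oligomannose_max_me

  rel_of <- function(os) {
    r <- assigned$rel_intensity[assigned$os == os]
    if (length(r)) max(r) else 0
  }
  scores <- numeric(length(registry))
  names(scores) <- names(registry)
  matched_n <- scores
  evidence <- vector("list", length(registry))
  names(evidence) <- names(registry)

  for (g in names(registry)) {
    p <- registry[[g]]
    req <- p$required
    req_rel <- vapply(req$os, rel_of, numeric(1))
    req_ok <- ifelse(req$dominant, req_rel >= dominance_threshold, req_rel > 0)
    sup_ok <- vapply(p$supporting$os, rel_of, numeric(1)) > 0
    me_has <- !is.null(p$oligomannose_me)
    me_ok <- me_has && !is.na(max_me) &&
      max_me >= p$oligomannose_me[1] && max_me <= p$oligomannose_me[2]

    violated <- character(0)
    if (nrow(p$forbidden)) {
      for (i in seq_len(nrow(p$forbidden))) {
        near <- abs(ann$mz - p$forbidden$mz[i]) <= forbidden_tol
        if (any(near & ann$rel_intensity >= dominance_threshold)) {
          violated <- c(violated, p$forbidden$os[i])
        }
      }
    }
    num <- 2 * sum(req_ok) + sum(sup_ok) + as.integer(me_ok)
    den <- 2 * nrow(req) + nrow(p$supporting) + as.integer(me_has)
    scores[g] <- if (length(violated)) 0 else num / den
    matched_n[g] <- num
    evidence[[g]] <- list(
      required_matched = req$os[req_ok],
      required_missing = req$os[!req_ok],
      supporting_matched = p$supporting$os[sup_ok],
      methylation_ok = if (me_has) me_ok else NA,
      forbidden_violated = violated)
  }

  # deterministic ranking: score, matched diagnostic weight, then name
  o <- order(-scores, -matched_n, names(scores))
  scores <- scores[o]
  best <- if (scores[1] >= orphan_threshold) names(scores)[1] else "orphan"
  mixture <- length(scores) > 1 && scores[2] >= mixture_threshold &&
    best != "orphan"
  structure(list(scores = scores,
                 best = best,
                 mixture_flag = mixture,
                 oligomannose_max_me = max_me,
                 evidence = evidence,
                 thresholds = c(dominance = dominance_threshold,
                                orphan = orphan_threshold,
                                mixture = mixture_threshold)),
            class = "glyco_classification")
}

#' @export
print.glyco_classification <- function(x, ...) {
  cat(sprintf("<glyco_classification> best: %s%s\n", x$best,
              if (x$mixture_flag) " (possible mixture)" else ""))
  top <- utils::head(x$scores, 5)
  cat("  scores:", paste(sprintf("%s %.2f", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.glyco_classification <- function(object, ...) {
  print(object)
  b <- if (object$best == "orphan") names(object$scores)[1] else object$best
  ev <- object$evidence[[b]]
  cat(sprintf("  evidence for %s:\n", b))
  cat("    required matched:", paste(ev$required_matched, collapse = ", "), "\n")
  if (length(ev$required_missing)) {
    cat("    required missing:", paste(ev$required_missing, collapse = ", "), "\n")
  }
  if (length(ev$supporting_matched)) {
    cat("    supporting matched:", paste(ev$supporting_matched, collapse = ", "), "\n")
  }
  if (!is.na(ev$methylation_ok)) {
    cat(sprintf("    oligomannose methylation in range: %s (max Me %s)\n",
                ev$methylation_ok, object$oligomannose_max_me))
  }
  if (length(ev$forbidden_violated)) {
    cat("    forbidden violated:", paste(ev$forbidden_violated, collapse = ", "), "\n")
  }
  invisible(object)
}

#' Annotate and classify a spectrum in one step
#'
#' Convenience pipeline: optional recalibration on oligomannosidic anchors,
#' composition annotation, methylation-ladder detection, and glyco-group
#' classification.
#'
#' @param s a `glyco_spectrum` (MS1).
#' @param tol MS1 matching tolerance in Da.
#' @param recalibrate logical; recalibrate on Man5-Man9 first.
#' @param ... passed to [classify_pattern()].
#' @return A `glyco_classification`; the annotation is attached as
#'   attribute `"annotation"`.
#' @export
classify_spectrum <- function(s, tol = 0.15, recalibrate = FALSE, ...) {
  stopifnot(inherits(s, "glyco_spectrum"))
  if (recalibrate) s <- recalibrate(s)
  ann <- annotate_spectrum(s, tol = tol)
  cl <- classify_pattern(ann, ...)
  attr(cl, "annotation") <- ann
  cl
}
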