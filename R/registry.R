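#' Built-in glyco-group registry
#'
#' Loads the packaged diagnostic registry of the 13 named glyco-groups
#' (Kei, Hel, Jos, Ori, Raa, Now, Sun, Sol, Jar, Gov, Ama, Asp, Pit). Each
#' profile carries required, supporting and forbidden diagnostic masses
#' (with their os codes), an optional allowed range for the maximum methyl
#' count on oligomannosidic glycans, an optional methylation-ladder rule,
#' and the methylation ceiling used by the spectrum simulator.
#'
#' On load every listed m/z is checked against the package's own mass
#' arithmetic (agreement to 0.05 Da) and required and forbidden sets are
#' checked for disjointness.
#'
#' @param path YAML registry file; defaults to the packaged registry, which
#'   is editable and versioned.
#' @return A named list of `glyco_group_profile` objects, class
#'   `glyco_registry`, with the registry version as an attribute.
#' @export
builtin_registry <- function(path = system.file("extdata", "glyco_groups.yaml",
                                                package = "glycofinger")) {
  raw <- yaml::read_yaml(path)
  profiles <- lapply(raw$groups, function(g) {
    as_diag <- function(entries, dominant_default = FALSE) {
      if (!length(entries)) {
        return(data.frame(os = character(0), mz = numeric(0),
                          dominant = logical(0), stringsAsFactors = FALSE))
      }
      data.frame(
        os = vapply(entries, `[[`, character(1), "os"),
        mz = vapply(entries, `[[`, numeric(1), "mz"),
        dominant = vapply(entries, function(e) {
          isTRUE(e$dominant) || dominant_default
        }, logical(1)),
        stringsAsFactors = FALSE)
    }
    required <- as_diag(g$required)
    supporting <- as_diag(g$supporting)
    forbidden <- as_diag(g$forbidden, dominant_default = TRUE)
    for (d in list(required, supporting, forbidden)) {
      if (!nrow(d)) next
      comp_mz <- vapply(d$os, os_mz, numeric(1))
      bad <- abs(comp_mz - d$mz) > 0.05
      if (any(bad)) {
        stop(sprintf("registry entry %s/%s: printed m/z %.2f disagrees with computed %.3f",
                     g$name, d$os[bad][1], d$mz[bad][1], comp_mz[bad][1]),
             call. = FALSE)
      }
    }
    if (any(required$os %in% forbidden$os)) {
      stop(sprintf("registry group %s: required and forbidden sets overlap", g$name),
           call. = FALSE)
    }
    structure(list(
      name = g$name,
      required = required,
      supporting = supporting,
      forbidden = forbidden,
      oligomannose_me = if (is.null(g$oligomannose_me)) NULL else
        as.integer(g$oligomannose_me),
      ladder = g$ladder,
      sim_oligo_me_max = as.integer(g$sim_oligo_me_max),
      notes = g$notes), class = "glyco_group_profile")
  })
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  structure(profiles, class = "glyco_registry", version = raw$version)
}

#' @export
print.glyco_registry <- function(x, ...) {
  cat(sprintf("<glyco_registry> v%s, %d groups: %s\n",
              attr(x, "version"), length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
print.glyco_group_profile <- function(x, ...) {
  cat(sprintf("<glyco_group_profile> '%s'\n", x$name))
  cat("  required:  ", paste(sprintf("%s (%.1f%s)", x$required$os,
                                     x$required$mz,
                                     ifelse(x$required$dominant, ", dominant", "")),
                             collapse = "; "), "\n")
  if (nrow(x$supporting)) {
    cat("  supporting:", paste(sprintf("%s (%.1f)", x$supporting$os,
                                       x$supporting$mz), collapse = "; "), "\n")
  }
  if (nrow(x$forbidden)) {
    cat("  forbidden: ", paste(sprintf("%s (%.1f)", x$forbidden$os,
                                       x$forbidden$mz), collapse = "; "), "\n")
  }
  if (!is.null(x$oligomannose_me)) {
    cat(sprintf("  oligomannose max Me in [%d, %d]\n",
                x$oligomannose_me[1], x$oligomannose_me[2]))
  }
  invisible(x)
}

#' MS1 confusability of glyco-group profiles
#'
#' Computes the pairwise Jaccard overlap of the required diagnostic mass
#' sets and flags group pairs that MS1 alone cannot separate without series
#' rules:
#'
#' * required sets identical — distinguished only by the
#'   oligomannose-methylation range (Raa/Now, Gov/Ama);
#' * required sets differing by a single diagnostic (Sol/Jar, separated
#'   only by 1460.5);
#' * one group's required diagnostics a subset of the other's
#'   required-plus-supporting set (the Jar-family subtypes against Sol),
#'   unless a forbidden diagnostic of the smaller profile is a dominant
#'   required mass of the larger one, in which case the forbidden rule
#'   separates them reliably.
#'
#' @param registry a `glyco_registry`.
#' @return List of class `confusability_report`: `overlap` (13 x 13
#'   matrix, diagonal 1) and `flagged` (data frame with columns `group1`,
#'   `group2`, `reason`).
#' @export
confusability_report <- function(registry = builtin_registry()) {
  stopifnot(inherits(registry, "glyco_registry"))
  nm <- names(registry)
  req <- lapply(registry, function(p) p$required$os)
  n <- length(nm)
  ov <- matrix(0, n, n, dimnames = list(nm, nm))
  flagged <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      u <- union(req[[i]], req[[j]])
      ov[i, j] <- if (length(u)) length(intersect(req[[i]], req[[j]])) / length(u) else 1
    }
  }
  # j's profile is recoverable inside an i-type spectrum when j's required
  # masses all occur among i's diagnostics and none of j's forbidden masses
  # is a dominant required mass of i (which would zero j reliably)
  subset_confusable <- function(i, j) {
    pi <- registry[[i]]
    pj <- registry[[j]]
    all(req[[j]] %in% c(req[[i]], pi$supporting$os)) &&
      !any(pj$forbidden$os %in%
             pi$required$os[pi$required$dominant])
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sym <- union(setdiff(req[[i]], req[[j]]), setdiff(req[[j]], req[[i]]))
      if (length(sym) == 0) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          group1 = nm[i], group2 = nm[j],
          reason = "identical required masses; separated only by oligomannose methylation",
          stringsAsFactors = FALSE)
      } else if (length(sym) == 1) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          group1 = nm[i], group2 = nm[j],
          reason = sprintf("separated only by %s (m/z %.1f)", sym, os_mz(sym)),
          stringsAsFactors = FALSE)
      } else if (subset_confusable(i, j) || subset_confusable(j, i)) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          group1 = nm[i], group2 = nm[j],
          reason = "one group's required diagnostics nested in the other's diagnostic set",
          stringsAsFactors = FALSE)
      }
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(group1 = character(0), group2 = character(0),
               reason = character(0))
  structure(list(overlap = ov, flagged = flagged),
            class = "confusability_report")
}

#' @export
print.confusability_report <- function(x, ...) {
  cat("<confusability_report> MS1-confusable pairs:\n")
  if (nrow(x$flagged)) print.data.frame(x$flagged) else cat("  none\n")
  invisible(x)
}

#' Pairs of groups a classifier may legitimately confuse at MS1
#' @noRd
confusable_pairs <- function(registry = builtin_registry()) {
  f <- confusability_report(registry)$flagged
  if (!nrow(f)) return(character(0))
  paste(pmin(f$group1, f$group2), pmax(f$group1, f$group2), sep = "/")
}
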