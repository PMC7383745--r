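#' Monophyly of glyco-groups on a phylogenetic tree
#'
#' Restates the qualitative claim that glycan-pattern groups track the
#' ITS1-5.8S-ITS2 rDNA phylogeny as a testable statistic: for every
#' glyco-group, is the set of leaves carrying that label monophyletic on
#' the supplied tree? Unlabelled leaves (outgroups, reference accessions)
#' are ignored throughout: a group is monophyletic when the labelled
#' descendants of its most recent common ancestor are exactly its own
#' leaves. A non-monophyletic group is called paraphyletic when the
#' complementary set of labelled leaves is itself monophyletic, and
#' polyphyletic otherwise. Singleton groups are trivially monophyletic.
#'
#' Unrooted input is midpoint-rooted (unit branch lengths are assumed when
#' the tree carries none); internal-node labels such as bootstrap values
#' parse and are ignored. The statistic is invariant under leaf-order
#' permutation.
#'
#' @param tree an `ape` `phylo` object, or a path to / string of Newick.
#' @param labels named character vector mapping leaf names to group names,
#'   or a two-column data frame `(leaf, group)`.
#' @return Object of class `glyco_concordance`: `status` (named character:
#'   `"monophyletic"`, `"paraphyletic"`, `"polyphyletic"`), `n_leaves`
#'   (per group), and `concordance` (fraction of groups monophyletic).
#' @examples
#' tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
#' group_monophyly(tr, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
#' @export
group_monophyly <- function(tree, labels) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]),
                              as.character(labels[[1]]))
  }
  if (!all(names(labels) %in% tree$tip.label)) {
    missing <- setdiff(names(labels), tree$tip.label)
    stop(sprintf("labelled leaves not in tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("at least two glyco-groups are required", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (!ape::is.rooted(tree)) {
    tree <- phangorn::midpoint(tree)
  }
  labelled <- names(labels)
  is_clade <- function(tips) {
    if (length(tips) <= 1) return(TRUE)
    mrca <- ape::getMRCA(tree, tips)
    desc <- tree$tip.label[phangorn::Descendants(tree, mrca, "tips")[[1]]]
    setequal(intersect(desc, labelled), tips)
  }
  groups <- sort(unique(labels))
  status <- vapply(groups, function(g) {
    tips <- labelled[labels == g]
    if (is_clade(tips)) return("monophyletic")
    if (is_clade(setdiff(labelled, tips))) "paraphyletic" else "polyphyletic"
  }, character(1))
  structure(list(status = status,
                 n_leaves = vapply(groups, function(g) sum(labels == g),
                                   integer(1)),
                 concordance = mean(status == "monophyletic")),
            class = "glyco_concordance")
}

#' @export
print.glyco_concordance <- function(x, ...) {
  cat(sprintf("<glyco_concordance> %.2f of %d groups monophyletic\n",
              x$concordance, length(x$status)))
  df <- data.frame(group = names(x$status), n = x$n_leaves, status = x$status,
                   row.names = NULL)
  print.data.frame(df)
  invisible(x)
}

#' Read a leaf -> glyco-group label map from a two-column TSV
#'
#' @param path TSV/whitespace file with leaf names in the first column and
#'   group names in the second; `#` comments and a header line are allowed.
#' @return Named character vector suitable for [group_monophyly()].
#' @export
read_group_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) && !is.na(suppressWarnings(df[1, 1])) &&
      tolower(df[1, 1]) %in% c("leaf", "tip", "sample")) {
    df <- df[-1, , drop = FALSE]
  }
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
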