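test_that("interleaved groups on a star tree are polyphyletic", {
  tr <- ape::read.tree(text = "(a1:1,b1:1,a2:1,b2:1);")
  res <- group_monophyly(tr, c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  expect_identical(unname(res$status), c("polyphyletic", "polyphyletic"))
  expect_identical(res$concordance, 0)
})

test_that("contiguous group blocks are all monophyletic", {
  sim <- simulate_labeled_tree(n_groups = 4, n_per_group = 4, mix_rate = 0,
                               seed = 71)
  res <- group_monophyly(sim$tree, sim$labels)
  expect_true(all(res$status == "monophyletic"))
  expect_identical(res$concordance, 1)
})

test_that("a grade is called paraphyletic, scattered leaves polyphyletic", {
  tr <- ape::read.tree(text = "((a1:1,(a2:1,(b1:1,b2:1):1):1):1,a3:1);")
  res <- group_monophyly(tr, c(a1 = "A", a2 = "A", a3 = "A",
                               b1 = "B", b2 = "B"))
  expect_identical(res$status[["A"]], "paraphyletic")
  expect_identical(res$status[["B"]], "monophyletic")
  tr2 <- ape::read.tree(text = "(((a1:1,b1:1):1,(a2:1,b2:1):1):1,(a3:1,b3:1):1);")
  res2 <- group_monophyly(tr2, c(a1 = "A", a2 = "A", a3 = "A",
                                 b1 = "B", b2 = "B", b3 = "B"))
  expect_identical(unname(res2$status), c("polyphyletic", "polyphyletic"))
})

test_that("singleton groups are trivially monophyletic", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,b1:1);")
  res <- group_monophyly(tr, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_identical(res$status[["B"]], "monophyletic")
  expect_identical(res$concordance, 1)
})

test_that("unlabelled reference leaves are ignored", {
  # an unlabelled accession inside the A clade must not break A's monophyly
  tr <- ape::read.tree(text = "(((a1:1,ref:1):1,a2:1):1,(b1:1,b2:1):1);")
  res <- group_monophyly(tr, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(all(res$status == "monophyletic"))
})

test_that("bootstrap values as node labels parse and are ignored", {
  tr <- ape::read.tree(text = "((a1:1,a2:1)98:1,(b1:1,b2:1)77:1);")
  res <- group_monophyly(tr, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_identical(res$concordance, 1)
})

test_that("the statistic is invariant under leaf-order permutation", {
  sim <- simulate_labeled_tree(n_groups = 3, n_per_group = 4, mix_rate = 0.3,
                               seed = 72)
  res1 <- group_monophyly(sim$tree, sim$labels)
  perm <- sample(seq_along(sim$labels))
  res2 <- group_monophyly(sim$tree, sim$labels[perm])
  expect_identical(res1$status, res2$status)
})

test_that("label maps load from two-column TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# map", "leaf\tgroup", "a1\tA", "b1\tB"), path)
  lab <- read_group_labels(path)
  expect_identical(lab, c(a1 = "A", b1 = "B"))
})

test_that("invalid label maps are rejected", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,b1:1);")
  expect_error(group_monophyly(tr, c(zz = "A", a1 = "A", b1 = "B")),
               "not in tree")
  expect_error(group_monophyly(tr, c(a1 = "A", a2 = "A")),
               "at least two")
})

test_that("concordance declines as labels are mixed across the tree", {
  mean_conc <- vapply(c(0, 0.5), function(r) {
    mean(vapply(1:20, function(i) {
      sim <- simulate_labeled_tree(n_groups = 5, n_per_group = 5,
                                   mix_rate = r, seed = 73 + i)
      group_monophyly(sim$tree, sim$labels)$concordance
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean_conc[2], mean_conc[1])
  expect_identical(mean_conc[1], 1)
})
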