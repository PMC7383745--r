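test_that("published complementary ions of os3231 are enumerated", {
  fr <- enumerate_fragments(parse_os_code("os3231"))
  y <- fr[fr$kind == "y" & fr$hex == 1 & fr$hexnac == 2 & fr$pen == 0 &
            fr$me == 0, ]
  expect_identical(nrow(y), 1L)
  expect_equal(round_mz(y$mz, 1), 609.2)
  b <- fr[fr$kind == "b" & fr$pair_id == y$pair_id, ]
  expect_equal(round_mz(b$mz, 1), 757.2)
})

test_that("published os2221 ions and the y1 neutral loss are enumerated", {
  fr <- enumerate_fragments(parse_os_code("os2221"))
  y <- fr[fr$kind == "y" & fr$hex == 0 & fr$hexnac == 2 & fr$pen == 1 &
            fr$me == 0, ]
  expect_equal(round_mz(y$mz, 1), 579.2)
  gn1 <- fr[fr$label == "-1 Gn", ]
  expect_equal(round_mz(gn1$mz, 1), 828.3)
})

test_that("every b/y pair satisfies the complementarity identity", {
  k <- mass_constants()
  for (os in c("os3231", "os2221", "os4223", "os3312")) {
    fr <- enumerate_fragments(parse_os_code(os))
    prec <- attr(fr, "precursor_mz")
    pairs <- fr[!is.na(fr$pair_id), ]
    for (pid in unique(pairs$pair_id)) {
      pq <- pairs[pairs$pair_id == pid, ]
      expect_equal(sum(pq$mz), prec + k$sodium_cation, tolerance = 1e-9)
    }
  }
})

test_that("fragment count matches brute-force sub-composition enumeration", {
  for (os in c("os2210", "os1211", "os0300")) {
    p <- parse_os_code(os)
    n_sub <- 0L
    for (h in 0:p$hex) for (n in 0:p$hexnac) for (pe in 0:p$pen)
      for (m in 0:p$me) {
        tot <- h + n + pe + m
        if (tot > 0 && tot < p$hex + p$hexnac + p$pen + p$me) n_sub <- n_sub + 1L
      }
    fr <- enumerate_fragments(p)
    expect_identical(sum(fr$kind == "y"), n_sub)
    expect_identical(sum(fr$kind == "b"), n_sub)
  }
})

test_that("canonical loss ladder appears with the right gating", {
  fr <- enumerate_fragments(parse_os_code("os3231"))
  expect_setequal(fr$label[fr$kind == "neutral-loss"],
                  c("-1 Gn", "-2 Gn", "-2 Gn(Me)", "-dHex", "-dHex-1 Gn"))
  # no methyl, no pentose: only the plain GlcNAc losses are possible
  fr2 <- enumerate_fragments(glycan_composition(hex = 5, hexnac = 2))
  expect_setequal(fr2$label[fr2$kind == "neutral-loss"], c("-1 Gn", "-2 Gn"))
})

test_that("a precursor without the chitobiose core is rejected", {
  expect_error(enumerate_fragments(glycan_composition(hex = 3, hexnac = 1)),
               "chitobiose")
})

test_that("a simulated LIFT spectrum matches its own fragment set completely", {
  p <- parse_os_code("os4223")
  fr <- enumerate_fragments(p)
  s <- glyco_spectrum(fr$mz, rep(10, nrow(fr)), level = "MS2",
                      precursor_mz = attr(fr, "precursor_mz"))
  m <- match_lift(s, p, tol = 0.3)
  expect_identical(nrow(m$matched), nrow(fr))
  expect_identical(nrow(m$unmatched_peaks), 0L)
})

test_that("the -1 Gn loss of the 'Kei' precursor is matched at 1122.4", {
  p <- parse_os_code("os3231")
  s <- glyco_spectrum(c(1343.46 - 221.09), 100, level = "MS2",
                      precursor_mz = 1343.46)
  m <- match_lift(s, p, tol = 0.3)
  expect_true("-1 Gn" %in% m$matched$label)
})

test_that("decoy peaks at non-glycan masses stay unmatched", {
  p <- parse_os_code("os3231")
  sim <- simulate_ms2(p, core_archetypes()$glcnac2_substituted,
                      decoy_peaks = 3, seed = 41)
  m <- match_lift(sim$spectrum, p, tol = 0.3)
  expect_identical(nrow(m$unmatched_peaks), 3L)
})

test_that("an inconsistent declared precursor m/z is an error", {
  s <- glyco_spectrum(c(609.2), 100, level = "MS2", precursor_mz = 1500.0)
  expect_error(match_lift(s, parse_os_code("os3231")), "inconsistent")
})
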