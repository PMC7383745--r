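archetype_precursors <- list(
  glcnac2_substituted = "os3231",         # 'Kei'-style reading
  chitobiose_free = "os4223",             # 'Hel'-style
  chitobiose_free_methylated = "os3312",  # 'Sun'-style (methylated GlcNAc)
  core13fucose = "os4213")                # 'Ori'-style (PNGase A only)

test_that("each archetype is recovered from its noiseless LIFT spectrum", {
  arch <- core_archetypes()
  for (nm in names(arch)) {
    p <- parse_os_code(archetype_precursors[[nm]])
    sim <- simulate_ms2(p, arch[[nm]])
    got <- infer_core(match_lift(sim$spectrum, p))
    truth <- arch[[nm]]
    for (f in c("glcnac1_unsubstituted", "chitobiose_unsubstituted",
                "glcnac2_substituted", "core13fucose",
                "methylated_hexnac_loss")) {
      expect_identical(got[[f]], truth[[f]], info = paste(nm, f))
    }
  }
})

test_that("the 'Kei' reading implies substitution of GlcNAc-2", {
  p <- parse_os_code("os3231")
  sim <- simulate_ms2(p, core_archetypes()$glcnac2_substituted)
  ev <- infer_core(match_lift(sim$spectrum, p))
  expect_identical(ev$glcnac1_unsubstituted, "yes")
  expect_identical(ev$glcnac2_substituted, "yes")
  expect_identical(ev$chitobiose_unsubstituted, "no")
})

test_that("consecutive GlcNAc losses read as an unsubstituted chitobiose", {
  p <- parse_os_code("os4223")
  sim <- simulate_ms2(p, core_archetypes()$chitobiose_free)
  ev <- infer_core(match_lift(sim$spectrum, p))
  expect_identical(ev$chitobiose_unsubstituted, "yes")
  expect_identical(ev$glcnac1_unsubstituted, "yes")
  expect_false(ev$methylated_hexnac_loss)
})

test_that("core fucose shows only as the 146-then-221 cascade", {
  p <- parse_os_code("os4213")
  sim <- simulate_ms2(p, core_archetypes()$core13fucose)
  # the direct -221 loss must be absent from the simulated peak list
  direct <- attr(enumerate_fragments(p), "precursor_mz") - 221.09
  expect_false(any(abs(sim$spectrum$peaks$mz - direct) < 0.3))
  ev <- infer_core(match_lift(sim$spectrum, p))
  expect_identical(ev$core13fucose, "yes")
  expect_identical(ev$glcnac1_unsubstituted, "no")
  expect_identical(pngase_release(ev), "A_only")
})

test_that("an empty match set stays entirely unknown", {
  p <- parse_os_code("os3231")
  s <- glyco_spectrum(numeric(0), numeric(0), level = "MS2",
                      precursor_mz = os_mz("os3231"))
  ev <- infer_core(match_lift(s, p))
  expect_identical(ev$glcnac1_unsubstituted, "unknown")
  expect_identical(ev$chitobiose_unsubstituted, "unknown")
  expect_identical(ev$glcnac2_substituted, "unknown")
  expect_identical(ev$core13fucose, "unknown")
})

test_that("adding consistent ions never flips a yes", {
  p <- parse_os_code("os3231")
  sim <- simulate_ms2(p, core_archetypes()$glcnac2_substituted)
  base_ev <- infer_core(match_lift(sim$spectrum, p))
  fr <- enumerate_fragments(p)
  # candidate pairs must stay clear of the neutral-loss ladder: an ion
  # isobaric with a -2 Gn loss would be conflicting, not consistent,
  # evidence at composition level
  loss_mz <- fr$mz[fr$kind == "neutral-loss"]
  extra_pairs <- unique(fr$pair_id[fr$kind == "y" & fr$hexnac == 2 &
                                     fr$hex + fr$pen + fr$me > 0])
  clear <- vapply(extra_pairs, function(pid) {
    all(vapply(fr$mz[!is.na(fr$pair_id) & fr$pair_id == pid],
               function(z) all(abs(z - loss_mz) > 0.35), logical(1)))
  }, logical(1))
  for (pid in extra_pairs[clear][1:4]) {
    add <- fr$mz[!is.na(fr$pair_id) & fr$pair_id == pid]
    s2 <- glyco_spectrum(c(sim$spectrum$peaks$mz, add),
                         c(sim$spectrum$peaks$intensity, rep(5, length(add))),
                         level = "MS2", precursor_mz = sim$spectrum$precursor_mz)
    ev2 <- infer_core(match_lift(s2, p))
    for (f in c("glcnac1_unsubstituted", "glcnac2_substituted")) {
      if (base_ev[[f]] == "yes") expect_identical(ev2[[f]], "yes", info = f)
    }
  }
})

test_that("a direct 221 loss alongside the fucose cascade is flagged", {
  p <- parse_os_code("os4213")
  fr <- enumerate_fragments(p)
  mz <- fr$mz[fr$label %in% c("-1 Gn", "-dHex", "-dHex-1 Gn")]
  s <- glyco_spectrum(mz, rep(100, 3), level = "MS2",
                      precursor_mz = attr(fr, "precursor_mz"))
  ev <- infer_core(match_lift(s, p))
  expect_true(ev$inconsistent)
})

test_that("contradictory evidence is rejected at construction", {
  expect_error(core_evidence(chitobiose_unsubstituted = "yes",
                             glcnac2_substituted = "yes"), "contradictory")
  expect_error(core_evidence(core13fucose = "yes",
                             glcnac1_unsubstituted = "yes"), "contradictory")
})

test_that("logical closure is applied on construction", {
  ev <- core_evidence(chitobiose_unsubstituted = "yes")
  expect_identical(ev$glcnac1_unsubstituted, "yes")
  expect_identical(ev$glcnac2_substituted, "no")
  ev2 <- core_evidence(core13fucose = "yes")
  expect_identical(ev2$glcnac1_unsubstituted, "no")
})
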