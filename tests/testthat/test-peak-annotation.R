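test_that("recalibration on exact anchors is the identity", {
  s <- exact_spectrum(c("os5200", "os6200", "os7200", "os8200", "os9200"))
  out <- recalibrate(s)
  expect_true(out$calibrated)
  expect_equal(out$calibration$offset, 0, tolerance = 1e-8)
  expect_equal(out$calibration$slope, 1, tolerance = 1e-10)
  expect_equal(out$peaks$mz, s$peaks$mz, tolerance = 1e-8)
})

test_that("linear drift is corrected to small anchor residuals", {
  theor <- vapply(c("os5200", "os6200", "os7200", "os8200", "os9200"),
                  os_mz, numeric(1))
  drifted <- 0.15 + (1 + 2e-5) * theor
  s <- glyco_spectrum(drifted, rep(50, 5))
  out <- recalibrate(s)
  expect_true(out$calibrated)
  expect_lt(max(abs(out$calibration$residual_after)), 0.02)
  expect_lt(max(abs(out$peaks$mz - theor)), 0.02)
})

test_that("too few anchors leaves the spectrum unchanged with a warning", {
  s <- exact_spectrum("os3231")
  expect_warning(out <- recalibrate(s), "fewer than 2")
  expect_false(out$calibrated)
  expect_equal(out$peaks$mz, s$peaks$mz)
})

test_that("recalibration never degrades anchor residuals", {
  set.seed(31)
  theor <- vapply(c("os5200", "os6200", "os7200", "os8200", "os9200"),
                  os_mz, numeric(1))
  for (i in 1:10) {
    obs <- theor + rnorm(5, 0, 0.1)
    s <- glyco_spectrum(obs, rep(50, 5))
    out <- recalibrate(s)
    expect_lte(sum(out$calibration$residual_after^2),
               sum(out$calibration$residual_before^2) + 1e-12)
  }
})

test_that("mass decomposition finds the published assignments", {
  hits <- decompose_mass(1343.46, tol = 0.15)
  expect_true("os3231" %in% hits$os)
  hits <- decompose_mass(1296.5, tol = 0.15)
  expect_true("os3312" %in% hits$os)
  # unassignable mass: empty result, not an error
  expect_identical(nrow(decompose_mass(905.0, tol = 0.05)), 0L)
})

test_that("mass decomposition agrees with the nested-loop oracle", {
  set.seed(32)
  for (mz in runif(50, 900, 2600)) {
    fast <- decompose_mass(mz, tol = 0.15)
    slow <- brute_force_decompose(mz, tol = 0.15)
    expect_identical(comp_key(fast), comp_key(slow), info = sprintf("m/z %.4f", mz))
  }
})

test_that("decomposition is monotone in tolerance and deterministically ordered", {
  for (mz in c(1343.46, 1460.5, 2079.7)) {
    k1 <- comp_key(decompose_mass(mz, tol = 0.05))
    k2 <- comp_key(decompose_mass(mz, tol = 0.15))
    k3 <- comp_key(decompose_mass(mz, tol = 0.40))
    expect_true(all(k1 %in% k2) && all(k2 %in% k3))
  }
  a <- decompose_mass(1343.5, tol = 0.3)
  b <- decompose_mass(1343.5, tol = 0.3)
  expect_identical(a, b)
  expect_true(all(diff(abs(a$error)) >= -1e-12))
})

test_that("annotation recovers compositions and flags the anchor class", {
  sim <- simulate_ms1("Hel", 1, mass_noise_ppm = 0, decoy_rate = 0, seed = 5)[[1]]
  ann <- annotate_spectrum(sim$spectrum, intensity_floor = 0)
  hel <- ann[abs(ann$mz - 1401.5) < 0.2, ]
  expect_identical(hel$os, "os4223")
  expect_true(all(ann$is_anchor[ann$os %in% c("os5200", "os9200")]))
  expect_false(any(ann$is_anchor[ann$os == "os4223"]))
})

test_that("annotation of an empty spectrum is empty", {
  s <- glyco_spectrum(numeric(0), numeric(0))
  expect_identical(nrow(annotate_spectrum(s)), 0L)
})

test_that("annotation is invariant to input peak order", {
  set.seed(33)
  mz <- vapply(c("os3231", "os5200", "os6200", "os3230"), os_mz, numeric(1))
  int <- c(100, 15, 15, 80)
  perm <- sample(seq_along(mz))
  a1 <- annotate_spectrum(glyco_spectrum(mz, int))
  a2 <- annotate_spectrum(glyco_spectrum(mz[perm], int[perm]))
  attr(a1, "sample_id") <- attr(a2, "sample_id") <- NULL
  expect_equal(a1, a2)
})

test_that("methylation ladders are detected with base and top compositions", {
  s <- exact_spectrum(c("os4221", "os4222", "os4223", "os5200"),
                      c(36, 60, 100, 15))
  lad <- detect_methyl_ladder(annotate_spectrum(s))
  expect_identical(nrow(lad$ladders), 1L)
  expect_identical(lad$ladders$base_os, "os4221")
  expect_identical(lad$ladders$top_os, "os4223")
  expect_identical(lad$ladders$length, 3L)
  expect_identical(lad$oligomannose_max_me, 0L)
})

test_that("no ladder is reported without consecutive methyl steps", {
  s <- exact_spectrum(c("os4221", "os4223"))  # gap at os4222
  lad <- detect_methyl_ladder(annotate_spectrum(s))
  expect_identical(nrow(lad$ladders), 0L)
})

test_that("heavily methylated oligomannose reaches the published ceiling", {
  sim <- simulate_ms1("Ama", 1, mass_noise_ppm = 0, decoy_rate = 0, seed = 6)[[1]]
  lad <- detect_methyl_ladder(annotate_spectrum(sim$spectrum,
                                                intensity_floor = 0))
  expect_identical(lad$oligomannose_max_me, 7L)
})

test_that("peak lists round-trip through the two-column text format", {
  s <- exact_spectrum(c("os3231", "os5200"), c(100, 15), sample_id = "x")
  path <- withr::local_tempfile(fileext = ".txt")
  write_peaklist(s, path)
  r <- read_peaklist(path)
  expect_equal(r$peaks, s$peaks)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "mz,intensity", "1343.46,100", "1257.42,15"), csv)
  r2 <- read_peaklist(csv)
  expect_equal(r2$peaks$mz, c(1257.42, 1343.46))
})
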