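#' Theoretical template peaks for one glyco-group
#'
#' Intensity templates are rank-based (dominant 100, supporting 30,
#' oligomannose anchors 15, methylation ladders decaying by 0.6 per step):
#' only the ordinal intensity structure of the published patterns is
#' asserted, since no intensity tables exist.
#'
#' @param profile a `glyco_group_profile`.
#' @return Data frame with `mz` (theoretical), `intensity` (template
#'   units), `os`, `kind` (`"diagnostic"` or `"oligomannose"`).
#' @noRd
template_peaks <- function(profile) {
  rows <- list()
  add <- function(os, intensity, kind) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mz = os_mz(os), intensity = intensity, os = os, kind = kind,
      stringsAsFactors = FALSE)
  }
  req <- profile$required
  for (i in seq_len(nrow(req))) {
    add(req$os[i], if (req$dominant[i]) 100 else 30, "diagnostic")
  }
  for (os in profile$supporting$os) add(os, 30, "diagnostic")
  if (!is.null(profile$ladder)) {
    top <- parse_os_code(profile$ladder$top_os)
    for (s in seq_len(profile$ladder$steps)) {
      if (top$me - s < 0) break
      add(format_os_code(glycan_composition(top$hex, top$hexnac, top$pen,
                                            top$me - s)),
          100 * 0.6^s, "diagnostic")
    }
  }
  for (h in 5:9) {
    for (m in 0:profile$sim_oligo_me_max) {
      add(format_os_code(glycan_composition(hex = h, hexnac = 2, me = m)),
          15 * 0.6^m, "oligomannose")
    }
  }
  df <- do.call(rbind, rows)
  # duplicates (e.g. a supporting mass also generated by the ladder): keep max
  df <- df[order(df$os, -df$intensity), , drop = FALSE]
  df <- df[!duplicated(df$os), , drop = FALSE]
  df[order(df$mz), , drop = FALSE]
}

# all theoretical masses any registry group can emit; decoys must stay clear
.exclusion_masses <- function(registry) {
  unique(unlist(lapply(registry, function(p) {
    template_peaks(p)$mz
  })))
}

#' Simulate labelled MS1 MALDI spectra
#'
#' Generates peak lists with the statistical structure the annotation and
#' classification stages assume: group-diagnostic peaks and oligomannosidic
#' anchor series (with group-specific methylation ladders) at rank-based
#' template intensities, log-normal intensity dispersion, per-peak Gaussian
#' ppm mass error followed by a linear calibration drift, uniformly placed
#' decoy peaks kept at least 1 Da away from any theoretical glycan mass,
#' and optional contamination by a second group. One RNG stream is derived
#' per spectrum from `(seed, index)` so any subset reproduces.
#'
#' @param group glyco-group name (must be in the registry).
#' @param n_spectra number of spectra to generate.
#' @param mass_noise_ppm standard deviation of the Gaussian ppm mass error.
#' @param calibration_drift numeric `c(offset_da, slope)`; observed m/z is
#'   `offset + slope * true`.
#' @param intensity_sigma log-normal dispersion of intensities.
#' @param decoy_rate Poisson mean number of decoy peaks per spectrum.
#' @param contaminant optional second group name.
#' @param contaminant_fraction relative abundance of the contaminant in
#'   `[0, 1)`.
#' @param seed integer seed (mandatory: spectra are labelled ground truth
#'   and must reproduce).
#' @param registry a `glyco_registry`.
#' @return List of `labeled_spectrum` objects, each a list with elements
#'   `spectrum` (a `glyco_spectrum`), `truth_group`, and `truth` (data
#'   frame: theoretical `mz`, `os` (`NA` for decoys), `kind`).
#' @export
simulate_ms1 <- function(group, n_spectra = 1L, mass_noise_ppm = 50,
                         calibration_drift = c(0, 1),
                         intensity_sigma = 0.3, decoy_rate = 2,
                         contaminant = NULL, contaminant_fraction = 0,
                         seed, registry = builtin_registry()) {
  if (missing(seed)) stop("a seed is mandatory for reproducible ground truth",
                          call. = FALSE)
  if (!group %in% names(registry)) {
    stop(sprintf("unknown glyco-group '%s'", group), call. = FALSE)
  }
  if (!is.null(contaminant) && !contaminant %in% names(registry)) {
    stop(sprintf("unknown contaminant group '%s'", contaminant), call. = FALSE)
  }
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("contaminant_fraction must be in [0, 1)", call. = FALSE)
  }
  stopifnot(mass_noise_ppm >= 0, intensity_sigma >= 0, decoy_rate >= 0)
  template <- template_peaks(registry[[group]])
  if (!is.null(contaminant) && contaminant_fraction > 0) {
    ct <- template_peaks(registry[[contaminant]])
    ct$intensity <- ct$intensity * contaminant_fraction
    template <- rbind(template, ct)
    template <- template[order(template$os, -template$intensity), ]
    template <- template[!duplicated(template$os), ]
    template <- template[order(template$mz), ]
  }
  excl <- .exclusion_masses(registry)

  lapply(seq_len(n_spectra), function(i) {
    set.seed((as.integer(seed) + 104729L * i) %% .Machine$integer.max)
    n <- nrow(template)
    inten <- template$intensity * exp(stats::rnorm(n, 0, intensity_sigma))
    mz_true <- template$mz
    mz_obs <- mz_true * (1 + stats::rnorm(n, 0, mass_noise_ppm * 1e-6))
    n_decoy <- stats::rpois(1, decoy_rate)
    dec_mz <- numeric(0)
    while (length(dec_mz) < n_decoy) {
      cand <- stats::runif(1, 900, 2600)
      if (all(abs(cand - excl) > 1)) dec_mz <- c(dec_mz, cand)
    }
    dec_int <- 10 * exp(stats::rnorm(n_decoy, 0, intensity_sigma))
    all_mz <- c(mz_obs, dec_mz)
    all_mz <- calibration_drift[1] + calibration_drift[2] * all_mz
    spec <- glyco_spectrum(all_mz, c(inten, dec_int), level = "MS1",
                           sample_id = sprintf("%s-sim-%d", group, i))
    truth <- data.frame(
      mz = c(mz_true, dec_mz),
      os = c(template$os, rep(NA_character_, n_decoy)),
      kind = c(template$kind, rep("decoy", n_decoy)),
      stringsAsFactors = FALSE)
    structure(list(spectrum = spec, truth_group = group, truth = truth),
              class = "labeled_spectrum")
  })
}

#' @export
print.labeled_spectrum <- function(x, ...) {
  cat(sprintf("<labeled_spectrum> group %s, %d peaks (%d decoys)\n",
              x$truth_group, nrow(x$spectrum$peaks),
              sum(x$truth$kind == "decoy")))
  invisible(x)
}

#' The four core-evidence archetypes
#'
#' Named reference evidence patterns spanning the inference rules: a free
#' GlcNAc-1 with substituted GlcNAc-2 (the 'Kei'-style os3231 reading), a
#' fully unsubstituted chitobiose ('Hel'-style), the same with a methylated
#' second GlcNAc ('Sun'-style), and core 1,3-fucose on GlcNAc-1
#' ('Ori'-style, PNGase-A-only release).
#'
#' @return Named list of [core_evidence()] objects.
#' @export
core_archetypes <- function() {
  list(
    glcnac2_substituted = core_evidence(glcnac1_unsubstituted = "yes",
                                        glcnac2_substituted = "yes"),
    chitobiose_free = core_evidence(chitobiose_unsubstituted = "yes"),
    chitobiose_free_methylated = core_evidence(
      chitobiose_unsubstituted = "yes", methylated_hexnac_loss = TRUE),
    core13fucose = core_evidence(core13fucose = "yes"))
}

#' Simulate a labelled LIFT (MS2) spectrum
#'
#' Emits the fragment set consistent with a declared core-substitution
#' truth: the direct reducing-GlcNAc loss only when GlcNAc-1 is free, the
#' consecutive two-GlcNAc loss ladder for an unsubstituted chitobiose (the
#' methylated variant when requested), a complementary b/y pair splitting
#' at the chitobiose when GlcNAc-2 carries the substituent, and the
#' deoxyhexose-then-GlcNAc cascade (with the direct loss suppressed) for
#' core 1,3-fucose. At zero noise, [infer_core()] on the result reproduces
#' the truth exactly. Contradictory truth specifications are rejected by
#' [core_evidence()].
#'
#' @param precursor a `glycan_composition`.
#' @param core_truth a [core_evidence()] object (or list of its arguments).
#' @param mass_noise_ppm Gaussian ppm error on fragment m/z.
#' @param decoy_peaks number of non-glycan decoy peaks to add.
#' @param seed integer seed; required when any randomness is requested.
#' @return A `labeled_spectrum` whose `spectrum` is MS2 and which carries
#'   `truth_core`.
#' @export
simulate_ms2 <- function(precursor, core_truth, mass_noise_ppm = 0,
                         decoy_peaks = 0, seed = NULL) {
  stopifnot(inherits(precursor, "glycan_composition"))
  if (!inherits(core_truth, "core_evidence")) {
    core_truth <- do.call(core_evidence, core_truth)
  }
  if ((mass_noise_ppm > 0 || decoy_peaks > 0) && is.null(seed)) {
    stop("a seed is required when noise or decoys are requested", call. = FALSE)
  }
  p <- fold_dhex(precursor)
  if (identical(core_truth$core13fucose, "yes") && !(p$pen >= 1 && p$me >= 1)) {
    stop("core 1,3-fucose truth requires a composition admitting a deoxyhexose (Pen >= 1 and Me >= 1)",
         call. = FALSE)
  }
  frags <- enumerate_fragments(p)
  want <- character(0)
  if (identical(core_truth$core13fucose, "yes")) {
    want <- c(want, "-dHex", "-dHex-1 Gn")
  } else if (identical(core_truth$glcnac1_unsubstituted, "yes")) {
    want <- c(want, "-1 Gn")
  }
  if (identical(core_truth$chitobiose_unsubstituted, "yes")) {
    want <- c(want, if (core_truth$methylated_hexnac_loss) "-2 Gn(Me)" else "-2 Gn")
  }
  sel <- frags[frags$kind == "neutral-loss" & frags$label %in% want, ,
               drop = FALSE]
  inten <- rep(100, nrow(sel))
  if (identical(core_truth$glcnac2_substituted, "yes")) {
    # complementary pair splitting at the chitobiose: y = HexNAc2 + one
    # further residue (preferring Hex, the galactose-on-GlcNAc-2 case)
    extra <- if (p$hex >= 1) c(1, 2, 0, 0) else if (p$pen >= 1)
      c(0, 2, 1, 0) else c(0, 2, 0, 1)
    ypick <- frags$kind == "y" & frags$hex == extra[1] &
      frags$hexnac == extra[2] & frags$pen == extra[3] & frags$me == extra[4]
    pid <- frags$pair_id[ypick][1]
    pair <- frags[!is.na(frags$pair_id) & frags$pair_id == pid, , drop = FALSE]
    sel <- rbind(sel, pair)
    inten <- c(inten, ifelse(pair$kind == "y", 80, 60))
  }
  mz <- sel$mz
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  if (mass_noise_ppm > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz), 0, mass_noise_ppm * 1e-6))
  }
  if (decoy_peaks > 0) {
    dec <- numeric(0)
    while (length(dec) < decoy_peaks) {
      cand <- stats::runif(1, 300, attr(frags, "precursor_mz") - 10)
      if (all(abs(cand - frags$mz) > 1)) dec <- c(dec, cand)
    }
    mz <- c(mz, dec)
    inten <- c(inten, rep(5, decoy_peaks))
  }
  spec <- glyco_spectrum(mz, inten, level = "MS2",
                         precursor_mz = attr(frags, "precursor_mz"),
                         sample_id = paste0(format_os_code(p), "-lift-sim"))
  structure(list(spectrum = spec,
                 truth_group = NA_character_,
                 truth = sel,
                 truth_core = core_truth),
            class = "labeled_spectrum")
}

#' Simulate a glyco-group-labelled phylogenetic tree
#'
#' Builds a backbone tree whose groups are attached as perfectly
#' monophyletic blocks (each group a clade of its leaves, clades strung
#' along a caterpillar backbone, unit branch lengths), then perturbs the
#' leaf labels: each leaf is, with probability `mix_rate`, reassigned to a
#' uniformly chosen different group. At `mix_rate = 0` every group is
#' monophyletic and the concordance is 1; concordance decreases in
#' expectation as `mix_rate` grows.
#'
#' @param n_groups number of glyco-groups.
#' @param n_per_group leaves per group.
#' @param mix_rate label-mixing probability in `[0, 1]`.
#' @param seed integer seed.
#' @return List with elements `tree` (an `ape` `phylo`) and `labels`
#'   (named character vector, leaf -> group).
#' @export
simulate_labeled_tree <- function(n_groups = 6, n_per_group = 5,
                                  mix_rate = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_groups >= 2, n_per_group >= 1, mix_rate >= 0, mix_rate <= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  groups <- sprintf("G%02d", seq_len(n_groups))
  clade <- function(tips) {
    if (length(tips) == 1) return(paste0(tips, ":1"))
    paste0("(", clade(tips[1]), ",", clade(tips[-1]), "):1")
  }
  subtrees <- lapply(seq_len(n_groups), function(i) {
    clade(sprintf("%s_l%d", groups[i], seq_len(n_per_group)))
  })
  backbone <- Reduce(function(a, b) paste0("(", a, ",", b, "):1"), subtrees)
  tree <- ape::read.tree(text = paste0(backbone, ";"))
  labels <- rep(groups, each = n_per_group)
  names(labels) <- unlist(lapply(seq_len(n_groups), function(i) {
    sprintf("%s_l%d", groups[i], seq_len(n_per_group))
  }))
  flip <- stats::runif(length(labels)) < mix_rate
  for (i in which(flip)) {
    labels[i] <- sample(setdiff(groups, labels[i]), 1)
  }
  list(tree = tree, labels = labels)
}
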