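# Independent oracles kept deliberately naive: plain nested loops over the
# residue alphabet, no reuse of package internals beyond the constants.

brute_force_decompose <- function(mz, tol, bounds = list(hex = c(0, 12),
                                                         hexnac = c(2, 4),
                                                         pen = c(0, 4),
                                                         me = c(0, 8))) {
  k <- mass_constants()
  hits <- list()
  for (h in bounds$hex[1]:bounds$hex[2]) {
    for (n in bounds$hexnac[1]:bounds$hexnac[2]) {
      for (p in bounds$pen[1]:bounds$pen[2]) {
        for (m in bounds$me[1]:bounds$me[2]) {
          theo <- h * k$hex + n * k$hexnac + p * k$pen + m * k$me +
            k$water + k$sodium_cation
          if (abs(mz - theo) <= tol) {
            hits[[length(hits) + 1L]] <- c(hex = h, hexnac = n, pen = p, me = m)
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(hex = integer(0), hexnac = integer(0),
                      pen = integer(0), me = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, hits))
  df[order(df$hex, df$hexnac, df$pen, df$me), , drop = FALSE]
}

# composition-set key for order-independent comparison
comp_key <- function(df) {
  sort(paste(df$hex, df$hexnac, df$pen, df$me, sep = "/"))
}

random_composition <- function(max_count = 6, hexnac_min = 0) {
  glycan_composition(hex = sample(0:max_count, 1),
                     hexnac = sample(hexnac_min:max(max_count, hexnac_min), 1),
                     pen = sample(0:4, 1),
                     me = sample(0:6, 1),
                     dhex = sample(0:2, 1))
}

# spectrum made directly from compositions at their exact sodiated m/z
exact_spectrum <- function(os_codes, intensities = NULL, ...) {
  mz <- vapply(os_codes, os_mz, numeric(1))
  if (is.null(intensities)) intensities <- rep(100, length(mz))
  glyco_spectrum(mz, intensities, ...)
}
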