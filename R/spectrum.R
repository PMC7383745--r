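#' Construct a peak-list spectrum
#'
#' Container for a centroided peak list. Peaks are stored sorted by
#' ascending m/z; MS2 spectra must declare the precursor m/z.
#'
#' @param mz numeric vector of positive m/z values.
#' @param intensity numeric vector of non-negative intensities.
#' @param level `"MS1"` or `"MS2"`.
#' @param precursor_mz precursor m/z (required when `level = "MS2"`).
#' @param sample_id optional sample identifier.
#' @param calibrated logical; set by [recalibrate()].
#' @return An object of class `glyco_spectrum`: a list with elements
#'   `peaks` (data frame with columns `mz`, `intensity`), `level`,
#'   `precursor_mz`, `sample_id`, `calibrated`.
#' @export
glyco_spectrum <- function(mz, intensity, level = c("MS1", "MS2"),
                           precursor_mz = NULL, sample_id = NA_character_,
                           calibrated = FALSE) {
  level <- match.arg(level)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (length(mz) && (any(!is.finite(mz)) || any(mz <= 0))) {
    stop("m/z values must be positive and finite", call. = FALSE)
  }
  if (length(intensity) && any(intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (level == "MS2" && is.null(precursor_mz)) {
    stop("an MS2 spectrum requires precursor_mz", call. = FALSE)
  }
  o <- order(mz)
  structure(
    list(peaks = data.frame(mz = as.numeric(mz[o]),
                            intensity = as.numeric(intensity[o])),
         level = level,
         precursor_mz = if (is.null(precursor_mz)) NA_real_ else precursor_mz,
         sample_id = sample_id,
         calibrated = isTRUE(calibrated)),
    class = "glyco_spectrum")
}

#' @export
print.glyco_spectrum <- function(x, ...) {
  cat(sprintf("<glyco_spectrum> %s, %d peaks%s%s%s\n",
              x$level, nrow(x$peaks),
              if (!is.na(x$precursor_mz))
                sprintf(", precursor m/z %.2f", x$precursor_mz) else "",
              if (!is.na(x$sample_id)) paste0(", sample ", x$sample_id) else "",
              if (x$calibrated) ", recalibrated" else ""))
  if (nrow(x$peaks)) {
    cat(sprintf("  m/z range %.2f - %.2f, base peak %.2f\n",
                min(x$peaks$mz), max(x$peaks$mz),
                x$peaks$mz[which.max(x$peaks$intensity)]))
  }
  invisible(x)
}

#' @export
plot.glyco_spectrum <- function(x, main = x$sample_id, ...) {
  if (!nrow(x$peaks)) {
    graphics::plot.new()
    return(invisible(x))
  }
  graphics::plot(x$peaks$mz, x$peaks$intensity, type = "h",
                 xlab = "m/z", ylab = "intensity",
                 main = if (is.na(main)) "" else main, ...)
  invisible(x)
}

#' Read a two-column peak list
#'
#' Reads the plain-text peak-list format used for MALDI export: two columns
#' (m/z, intensity) separated by whitespace, tabs or commas, with an
#' optional header line and `#` comments.
#'
#' @param path file path.
#' @param level,precursor_mz,sample_id passed to [glyco_spectrum()];
#'   `sample_id` defaults to the file name.
#' @return A `glyco_spectrum`.
#' @export
read_peaklist <- function(path, level = "MS1", precursor_mz = NULL,
                          sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(sample_id)) sample_id <- basename(path)
  if (!length(lines)) {
    return(glyco_spectrum(numeric(0), numeric(0), level = level,
                          precursor_mz = precursor_mz, sample_id = sample_id))
  }
  sep <- if (grepl(",", lines[1], fixed = TRUE)) "," else ""
  first <- utils::read.table(text = lines[1], sep = sep,
                             stringsAsFactors = FALSE)
  header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  df <- utils::read.table(text = lines, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("peak list must have two columns (mz, intensity)",
                         call. = FALSE)
  glyco_spectrum(as.numeric(df[[1]]), as.numeric(df[[2]]), level = level,
                 precursor_mz = precursor_mz, sample_id = sample_id)
}

#' Write a spectrum as a two-column peak list
#'
#' @param x a `glyco_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "glyco_spectrum"))
  utils::write.table(x$peaks, path, sep = "\t", row.names = FALSE,
                     col.names = c("mz", "intensity"), quote = FALSE)
  invisible(path)
}
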