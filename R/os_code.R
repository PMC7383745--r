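#' Format a composition as an "os" code
#'
#' The shorthand used throughout Chlorella glycomics: `"os"` followed by the
#' counts of hexoses, HexNAcs, pentoses and methyl groups, each a single
#' digit, or bracketed when 10 or more (`os[10]213`). Deoxyhexoses are folded
#' into Pen+Me first, since the code has no dHex field.
#'
#' @param x a `glycan_composition`.
#' @return A character scalar such as `"os3231"`.
#' @examples
#' format_os_code(glycan_composition(hex = 3, hexnac = 2, pen = 3, me = 1))
#' @export
format_os_code <- function(x) {
  stopifnot(inherits(x, "glycan_composition"))
  x <- fold_dhex(x)
  fmt <- function(n) if (n >= 10) sprintf("[%d]", n) else as.character(n)
  paste0("os", fmt(x$hex), fmt(x$hexnac), fmt(x$pen), fmt(x$me))
}

#' Parse an "os" code into a glycan composition
#'
#' Inverse of [format_os_code()]: accepts exactly four fields after the
#' `"os"` prefix, each either a single digit or a bracketed multi-digit
#' count. Malformed codes raise an error reporting the character position at
#' which parsing failed.
#'
#' @param code character scalar, e.g. `"os3231"` or `"os[12]213"`.
#' @return A `glycan_composition` (dHex always zero: the code is the folded
#'   form).
#' @examples
#' parse_os_code("os[10]213")
#' @export
parse_os_code <- function(code) {
  if (!is.character(code) || length(code) != 1L) {
    stop("os code must be a single character string", call. = FALSE)
  }
  if (substr(code, 1, 2) != "os") {
    stop("malformed os code at position 1: expected \"os\" prefix", call. = FALSE)
  }
  pos <- 3L
  n <- nchar(code)
  counts <- integer(4)
  for (i in 1:4) {
    if (pos > n) {
      stop(sprintf("malformed os code at position %d: expected a count field", pos),
           call. = FALSE)
    }
    ch <- substr(code, pos, pos)
    if (ch == "[") {
      close <- regexpr("]", substr(code, pos, n), fixed = TRUE)
      if (close < 0) {
        stop(sprintf("malformed os code at position %d: unclosed bracket", pos),
             call. = FALSE)
      }
      digits <- substr(code, pos + 1L, pos + close - 2L)
      if (!grepl("^[0-9]+$", digits)) {
        stop(sprintf("malformed os code at position %d: non-digit in bracket", pos + 1L),
             call. = FALSE)
      }
      counts[i] <- as.integer(digits)
      pos <- pos + close
    } else if (grepl("^[0-9]$", ch)) {
      counts[i] <- as.integer(ch)
      pos <- pos + 1L
    } else {
      stop(sprintf("malformed os code at position %d: unexpected character \"%s\"", pos, ch),
           call. = FALSE)
    }
  }
  if (pos <= n) {
    stop(sprintf("malformed os code at position %d: trailing characters", pos),
         call. = FALSE)
  }
  glycan_composition(counts[1], counts[2], counts[3], counts[4], 0)
}

#' Sodiated m/z of an os code
#'
#' Convenience wrapper: `os_mz("os3231")` is
#' `ion_mz(parse_os_code("os3231"))`.
#'
#' @param code os code string.
#' @param ... passed to [ion_mz()].
#' @return m/z value.
#' @export
os_mz <- function(code, ...) ion_mz(parse_os_code(code), ...)
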