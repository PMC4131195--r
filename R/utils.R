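`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages here use the
#' conventional half-up rule so that e.g. a true-positive rate of 97.55
#' prints as 97.6.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## 0-based half-open interval overlap width; vectorised
overlap_width0 <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

## any >= min_bp overlap of (s, e) against a set of intervals
overlaps_any0 <- function(s, e, starts, ends, min_bp = 1L) {
  if (length(starts) == 0L) return(FALSE)
  any(pmin(e, ends) - pmax(s, starts) >= min_bp)
}

## reverse complement for plain character vectors of DNA
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## left-align a character matrix into padded text lines
align_columns <- function(m) {
  w <- apply(nchar(m), 2, max)
  for (j in seq_len(ncol(m)))
    m[, j] <- formatC(m[, j], width = w[j], flag = "-")
  trimws(apply(m, 1, paste, collapse = "  "), "right")
}

stop_usage <- function(...) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
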