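#' @keywords internal
"_PACKAGE"

LN10 <- log(10)

#' Reverse complement of top-strand DNA strings
#'
#' Minimal vectorised reverse complement over the strict {A,C,G,T} alphabet.
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

stop_codons <- c("TAA", "TAG", "TGA")

#' @noRd
assert_scalar_int <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x))
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  as.integer(x)
}
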