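#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils read.table write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Validate that `x` is a single non-degenerate DNA string; returns it upper-cased.
check_dna <- function(x, min_len = 1L, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  x <- toupper(x)
  if (nchar(x) < min_len)
    stop(what, " must have at least ", min_len, " bases, got ", nchar(x),
         call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters outside {A,C,G,T}: ", x, call. = FALSE)
  x
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. Only the
#' non-degenerate alphabet A/C/G/T is accepted; primers with IUPAC ambiguity
#' codes cannot be scored because the dimer score is defined over exact
#' complementarity.
#'
#' @param x character vector of DNA sequences (5'->3').
#' @return character vector of reverse complements (5'->3').
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

gc_fraction <- function(x) {
  stringi::stri_count_charclass(x, "[GCgc]") / nchar(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
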