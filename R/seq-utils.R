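## Low-level DNA string helpers shared across modules.
## Sequences are plain upper-case character scalars over {A,C,G,T,N};
## Biostrings is used at IO boundaries and for pairwise alignment.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
PURINES <- c("A", "G")

#' Random DNA sequence at a given GC fraction
#'
#' Draws i.i.d. bases with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#' Uses the current RNG state.
#'
#' @param n sequence length (nt).
#' @param gc GC fraction in \[0, 1\].
#' @return A character scalar of length-`n` DNA.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  chars_to_seq(DNA_BASES[idx])
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N (case-insensitive).
#' @return Upper-case reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(ch) paste0(ch, collapse = "")

## Hamming distance between equal-length strings (count of differing sites).
hamming <- function(a, b) {
  ca <- seq_to_chars(a); cb <- seq_to_chars(b)
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

## Fraction of N characters in a sequence.
n_fraction <- function(x) {
  ch <- seq_to_chars(toupper(x))
  if (length(ch) == 0) return(0)
  mean(ch == "N")
}

## GC percent over non-N bases; NA if no valid bases.
gc_percent <- function(x) {
  ch <- seq_to_chars(toupper(x))
  valid <- ch %in% DNA_BASES
  if (!any(valid)) return(NA_real_)
  100 * mean(ch[valid] %in% c("G", "C"))
}

## Transition partner of each base (A<->G, C<->T).
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

## The two transversion partners of each base.
TRANSVERSIONS <- list(
  A = c("C", "T"), G = c("C", "T"),
  C = c("A", "G"), T = c("A", "G")
)

## 1-based inclusive substring; clips to [1, nchar].
substr_clip <- function(x, start, end) {
  n <- nchar(x)
  start <- max(1L, start); end <- min(n, end)
  if (start > end) return("")
  substr(x, start, end)
}
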