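# DNA alphabet helpers. Sequences are plain uppercase character strings over
# {A,C,G,T,N}; internally bases are encoded A=1, C=2, G=3, T=4, N=NA so that
# weight-matrix lookups propagate NA through windows that touch an ambiguous
# base.

DNA_BASES <- c("A", "C", "G", "T")

.encode_dna <- function(seq) {
  x <- utf8ToInt(toupper(seq))
  code <- rep(NA_integer_, 256L)
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  bad <- !(x %in% c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"),
                    utf8ToInt("T"), utf8ToInt("N")))
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: '",
         intToUtf8(x[which(bad)[1L]]), "'")
  }
  code[x]
}

.decode_dna <- function(codes) {
  chars <- c("A", "C", "G", "T")[codes]
  chars[is.na(codes)] <- "N"
  paste(chars, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Complements A<->T, C<->G (N maps to N) and reverses. Case is folded to
#' upper case.
#'
#' @param seq A single DNA string over \{A,C,G,T,N\}.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("ACGTN")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  flipped <- chartr("ACGTN", "TGCAN", toupper(seq))
  paste(rev(strsplit(flipped, "", fixed = TRUE)[[1L]]), collapse = "")
}

# reverse complement on the integer encoding; NA (= N) stays NA
.revcomp_codes <- function(codes) {
  rev(5L - codes)
}

# draw a random DNA string of length `len` from a background model
.random_dna <- function(len, background) {
  paste(sample(DNA_BASES, len, replace = TRUE, prob = background),
        collapse = "")
}
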