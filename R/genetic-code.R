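#' Bacterial genetic code and per-position codon degeneracy
#'
#' Site classification rests on the degeneracy of each codon position: a
#' position is fourfold-synonymous (`"4s"`) when all four nucleotides leave
#' the encoded amino acid unchanged, twofold (`"2s"`) when exactly two do,
#' threefold (`"3s"`, the isoleucine third position) when three do, and
#' nonsynonymous (`"ns"`) when any change alters the amino acid.  Changes to
#' stop codons never count as synonymous.  The classification is derived at
#' runtime from the genetic code (the bacterial code shares its amino-acid
#' assignments with the standard table) and checked in the test suite against
#' a frozen copy shipped in `inst/extdata/codon_degeneracy.tsv`.
#'
#' @return A tibble with one row per codon: `codon`, `aa` (one-letter amino
#'   acid, `"*"` for stops), and `class1`, `class2`, `class3` giving the
#'   degeneracy class of each position (`NA` for stop codons).
#' @export
#' @examples
#' codon_degeneracy_table() |> dplyr::filter(codon == "GCT")
codon_degeneracy_table <- function() {
  tibble::tibble(
    codon = CODONS(),
    aa = AA64(),
    class1 = DEG_CLASS()[, 1],
    class2 = DEG_CLASS()[, 2],
    class3 = DEG_CLASS()[, 3]
  )
}

#' Classify the three positions of a codon by degeneracy
#'
#' @param codon Character vector of 3-mers over `{A,C,G,T}` (sense strand).
#'   Stop codons and codons with ambiguity codes are errors; callers are
#'   expected to exclude START/STOP codons and skip ambiguous codons upstream.
#' @return A tibble with columns `codon`, `class1`, `class2`, `class3`.
#' @export
#' @examples
#' classify_codon(c("GCT", "AAA", "ATA"))
classify_codon <- function(codon) {
  codon <- toupper(codon)
  idx <- match(codon, CODONS())
  if (anyNA(idx)) {
    stop("not a valid unambiguous codon: ",
         paste(unique(codon[is.na(idx)]), collapse = ", "))
  }
  if (any(AA64()[idx] == "*")) {
    stop("stop codon passed to classify_codon(): ",
         paste(unique(codon[AA64()[idx] == "*"]), collapse = ", "))
  }
  cls <- DEG_CLASS()
  tibble::tibble(codon = codon,
                 class1 = cls[idx, 1], class2 = cls[idx, 2], class3 = cls[idx, 3])
}

# ---- internal derived tables (built once, cached) ---------------------------

BASES <- c("A", "C", "G", "T")

.build_code_tables <- function() {
  gc <- Biostrings::GENETIC_CODE  # amino-acid map identical to bacterial table 11
  codons <- as.vector(t(outer(
    as.vector(t(outer(BASES, BASES, paste0))), BASES, paste0)))
  # codons are ordered so that index = 16*(b1-1) + 4*(b2-1) + b3 with A,C,G,T = 1..4
  aa <- unname(gc[codons])
  letters3 <- matrix(unlist(strsplit(codons, "")), ncol = 3, byrow = TRUE)
  deg <- matrix(NA_character_, 64, 3)
  for (i in seq_len(64)) {
    if (aa[i] == "*") next
    for (p in 1:3) {
      variants <- vapply(BASES, function(b) {
        s <- letters3[i, ]
        s[p] <- b
        unname(gc[paste(s, collapse = "")])
      }, character(1))
      n_syn <- sum(variants == aa[i])
      deg[i, p] <- c("ns", "2s", "3s", "4s")[n_syn]
    }
  }
  list(codons = codons, aa = aa, letters = letters3, deg = deg)
}

.code_tables <- function() {
  if (is.null(.skewsel_cache$code)) .skewsel_cache$code <- .build_code_tables()
  .skewsel_cache$code
}

CODONS <- function() .code_tables()$codons
AA64 <- function() .code_tables()$aa
DEG_CLASS <- function() .code_tables()$deg
CODON_LETTERS <- function() .code_tables()$letters

# Integer codon index (1..64) of stop codons.
STOP_IDX <- function() which(AA64() == "*")

# ---- nucleotide-level helpers ----------------------------------------------

# ASCII lookup: A/C/G/T (and lowercase) -> 1..4, everything else NA.
.base_lut <- local({
  lut <- rep(NA_integer_, 128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut
})

# One string -> integer vector over 1..4 (NA for ambiguity codes).
dna_to_int <- function(x) {
  stopifnot(length(x) == 1L)
  .base_lut[utf8ToInt(x)]
}

int_to_dna <- function(i) intToUtf8(utf8ToInt("ACGT")[i])

# Complement in integer coding: A<->T (1<->4), C<->G (2<->3).
comp_int <- function(i) 5L - i

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Codon indices (1..64) from an integer-coded sequence; length must be 3k.
codon_index <- function(ints) {
  m <- matrix(ints, ncol = 3, byrow = TRUE)
  16L * (m[, 1] - 1L) + 4L * (m[, 2] - 1L) + m[, 3]
}
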