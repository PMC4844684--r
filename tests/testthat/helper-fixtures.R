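# Shared fixtures, all built in code.

# Random plus-strand sequence of length n (seeded by caller).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# The worked 10-kb toy annotation: three operons on a circular chromosome.
toy_genome <- function(seed = 42) {
  set.seed(seed)
  feats <- tibble::tibble(
    start = c(100L, 2300L, 6000L),
    end = c(2000L, 4000L, 9500L),
    strand = c("+", "-", "+"),
    kind = "operon",
    id = c("op1", "op2", "op3"))
  annotated_genome("toy", random_dna(10000L), ori = 0L, features = feats)
}

# A small genome holding explicit gene sequences.  `genes` is a tibble with
# columns sense (sequence incl. start/stop), strand, start (plus-strand
# position); filler bases are "A".
genome_with_genes <- function(genes, L, genome_id = "mini") {
  seq <- rep("A", L)
  feats <- purrr::pmap_dfr(genes, function(sense, strand, start, ...) {
    plus <- if (strand == "-") revcomp(sense) else sense
    n <- nchar(plus)
    stopifnot(start + n <= L)
    seq[(start + 1):(start + n)] <<- strsplit(plus, "")[[1]]
    tibble::tibble(start = start, end = start + n, strand = strand,
                   kind = "gene",
                   id = paste0("g", start))
  })
  annotated_genome(genome_id, paste(seq, collapse = ""), ori = 0L,
                   features = feats)
}

# Noise-free observed-skew table for synthetic parameter values: the exact
# forward-model skews for a set of genomes, in observed_skews() layout.
exact_skew_table <- function(mu_io, tau, s_rna, s_total, f) {
  purrr::map_dfr(seq_along(mu_io), function(i) {
    mu4 <- tau * mu_io[i]
    rows <- tibble::tibble(
      site_class = c("io", "4s", "4s", "ns", "ns"),
      strand = c("leading", "leading", "lagging", "leading", "lagging"),
      skew = c(mu_io[i],
               forward_skew(mu4, s_rna, "leading"),
               forward_skew(mu4, s_rna, "lagging"),
               f * forward_skew(mu4, s_total, "leading"),
               f * forward_skew(mu4, s_total, "lagging")))
    dplyr::bind_rows(dplyr::mutate(rows, pair = "AT"),
                     dplyr::mutate(rows, pair = "GC")) |>
      dplyr::mutate(genome_id = sprintf("g%02d", i), denom = 1e6, flag = "ok")
  })
}

# Independent exact enumeration of null-model class skews at GC content g:
# codon probabilities are the i.i.d. product conditioned on non-stop, and
# per-position degeneracy is re-derived here from the genetic code without
# using the package's classification tables.
enumerate_null_skews <- function(g) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  codons <- names(code)
  cnt <- list()
  for (cls in c("ns", "2s", "3s", "4s")) {
    cnt[[cls]] <- c(A = 0, C = 0, G = 0, T = 0)
  }
  pr <- vapply(codons, function(cd) {
    prod(p[strsplit(cd, "")[[1]]])
  }, numeric(1))
  pr[code == "*"] <- 0
  pr <- pr / sum(pr)
  for (i in seq_along(codons)) {
    if (code[i] == "*") next
    s <- strsplit(codons[i], "")[[1]]
    for (pos in 1:3) {
      nsyn <- sum(vapply(bases, function(b) {
        v <- s; v[pos] <- b
        code[paste(v, collapse = "")] == code[i]
      }, logical(1)))
      cls <- c("ns", "2s", "3s", "4s")[nsyn]
      cnt[[cls]][s[pos]] <- cnt[[cls]][s[pos]] + pr[i]
    }
  }
  purrr::map_dfr(names(cnt), function(cls) {
    x <- cnt[[cls]]
    tibble::tibble(site_class = cls,
                   at = unname((x["A"] - x["T"]) / (x["A"] + x["T"])),
                   gc = unname((x["G"] - x["C"]) / (x["G"] + x["C"])))
  })
}
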