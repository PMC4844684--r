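#' Per-gene codon counts of an annotated genome
#'
#' Extracts each gene's sense-strand coding sequence (START codon and
#' trailing STOP dropped, as in [count_sites()]), tallies codons and labels
#' genes with their replication strand.  Genes with non-triplet length,
#' internal stops, or ambiguity codons are skipped.
#'
#' @param genome A rotated [annotated_genome] (`ori = 0`).
#' @return Tibble `gene_id`, `replication_strand`, `codon`, `n`.
#' @export
gene_codon_counts <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"), genome$ori == 0L)
  genes <- genome$features[genome$features$kind == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), replication_strand = character(),
                          codon = character(), n = integer()))
  }
  genes <- assign_replication_strand(genes, genome$length)
  purrr::map_dfr(unique(genes$id), function(fid) {
    rows <- genes[genes$id == fid, , drop = FALSE]
    seq <- feature_sequence(genome$sequence, rows)
    ints <- dna_to_int(seq)
    if (length(ints) %% 3 != 0 || length(ints) < 6) return(NULL)
    idx <- codon_index(ints)[-1]
    if (length(idx) && !is.na(idx[length(idx)]) &&
        idx[length(idx)] %in% STOP_IDX()) {
      idx <- idx[-length(idx)]
    }
    if (any(idx %in% STOP_IDX(), na.rm = TRUE)) return(NULL)
    idx <- idx[!is.na(idx)]
    tab <- tabulate(idx, 64)
    keep <- which(tab > 0)
    tibble::tibble(gene_id = fid,
                   replication_strand = rows$replication_strand[1],
                   codon = CODONS()[keep], n = tab[keep])
  })
}

# Default wobble-pairing selective constraints (reference tAI values):
# positions 1-4 are Watson-Crick pairs (s = 0); 5: G:U wobble (anticodon G
# reading codon-ending U); 6: I:C (anticodon A read as inosine against C);
# 7: I:A; 8: U:G (anticodon U reading codon-ending G); 9: the
# lysidine-modified CAU anticodon reading AUA (prokaryotes).
TAI_S_DEFAULT <- c(0, 0, 0, 0, 0.41, 0.28, 0.9999, 0.68, 0.89)

#' Relative tRNA adaptiveness of each sense codon
#'
#' Absolute adaptiveness of codon *i* is
#' \eqn{W_i = \sum_j (1 - s_j)\, t_j} over the anticodons *j* recognising
#' it — the Watson-Crick partner plus the wobble partner determined by the
#' codon's third base — where \eqn{t_j} is the genomic tRNA gene copy number
#' and \eqn{s_j} the pairing-specific selective constraint.  Relative
#' adaptiveness is \eqn{w_i = W_i / \max W}; codons with \eqn{w_i = 0} are
#' assigned the geometric mean of the non-zero values, as in the reference
#' implementation.
#'
#' @param pool tRNA pool: tibble with columns `anticodon` (5'-to-3'
#'   trinucleotide) and `copies`, or a named numeric vector.
#' @param s Length-9 constraint vector in `[0, 1]` (see `TAI_S_DEFAULT`).
#' @return Tibble `codon`, `W`, `w` for the 61 sense codons.
#' @export
tai_weights <- function(pool, s = TAI_S_DEFAULT) {
  t_of <- .pool_vec(pool)
  if (sum(t_of) == 0) stop("empty tRNA pool")
  stopifnot(length(s) == 9, all(s >= 0), all(s <= 1))
  p <- 1 - s
  codons <- CODONS()
  sense <- which(AA64() != "*")
  anti <- function(cod) revcomp(cod)
  W <- setNames(numeric(length(codons)), codons)
  for (i in sense) {
    cod <- codons[i]
    third <- substr(cod, 3, 3)
    stem <- substr(cod, 1, 2)
    wc <- anti(cod)
    W[cod] <- switch(third,
      "T" = p[1] * t_of[wc] + p[5] * t_of[anti(paste0(stem, "C"))],
      "C" = p[2] * t_of[wc] + p[6] * t_of[anti(paste0(stem, "T"))],
      "A" = p[3] * t_of[wc] + p[7] * t_of[anti(paste0(stem, "T"))],
      "G" = p[4] * t_of[wc] + p[8] * t_of[anti(paste0(stem, "A"))])
  }
  # prokaryote special case: AUA is additionally read by the
  # lysidine-modified CAU anticodon (shared with the initiator pool)
  W["ATA"] <- p[3] * t_of["TAT"] + p[9] * t_of["CAT"]
  W <- W[codons[sense]]
  w <- W / max(W)
  if (any(w == 0)) {
    w[w == 0] <- exp(mean(log(w[w > 0])))
  }
  tibble::tibble(codon = codons[sense], W = unname(W), w = unname(w))
}

.pool_vec <- function(pool) {
  v <- if (is.data.frame(pool)) setNames(pool$copies, toupper(pool$anticodon))
       else setNames(as.numeric(pool), toupper(names(pool)))
  if (any(v < 0)) stop("negative tRNA copy numbers")
  out <- setNames(numeric(64), CODONS())
  out[names(v)] <- v
  out
}

#' tRNA adaptation index of genes
#'
#' The tAI of a gene is the geometric mean of the relative adaptiveness
#' values \eqn{w} of its codons (weighted by codon multiplicity); it serves
#' as a proxy for expression level, higher meaning more highly expressed.
#'
#' @param gene_codons Tibble `gene_id`, `codon`, `n` (e.g. from
#'   [gene_codon_counts()]).
#' @param pool,s As in [tai_weights()].
#' @return Tibble `gene_id`, `tai` (scores in (0, 1]).
#' @export
#' @examples
#' pool <- tibble::tibble(anticodon = c("AGC", "GGC"), copies = c(2, 1))
#' genes <- tibble::tibble(gene_id = "g1", codon = c("GCT", "GCC"), n = c(3, 1))
#' tai(genes, pool)
tai <- function(gene_codons, pool, s = TAI_S_DEFAULT) {
  ws <- tai_weights(pool, s)
  d <- dplyr::inner_join(gene_codons, ws, by = "codon")
  if (!nrow(d)) stop("no sense codons shared between genes and weights")
  d |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(tai = exp(sum(.data$n * log(.data$w)) / sum(.data$n)),
                     .groups = "drop")
}

#' Stratify genes into expression bins by tAI and pool their skews
#'
#' Within each replication strand, genes are ranked by tAI from low to high
#' and split into `k` equal-sized bins (Q1 = lowest, Qk = highest; ties
#' broken by stable gene order).  For each bin the fourfold and
#' nonsynonymous site counts are pooled and their skews computed, together
#' with bin GC content and mean amino-acid cost.
#'
#' @param gene_codons Tibble `gene_id`, `replication_strand`, `codon`, `n`.
#' @param pool tRNA pool for [tai()].
#' @param k Number of bins (default 5 quintiles).
#' @param aa_costs Amino-acid cost table.
#' @param s Wobble constraint vector.
#' @return Tibble `replication_strand`, `bin`, `n_genes`, `gc`,
#'   `mean_aa_cost`, and pooled skews `at_4s`, `gc_4s`, `at_ns`, `gc_ns`.
#' @export
bin_by_expression <- function(gene_codons, pool, k = 5,
                              aa_costs = load_costs(type = "aa"),
                              s = TAI_S_DEFAULT) {
  scores <- tai(gene_codons, pool, s)
  d <- dplyr::inner_join(gene_codons, scores, by = "gene_id")
  strands <- split(d, d$replication_strand)
  purrr::map_dfr(strands, function(dd) {
    genes <- dd |>
      dplyr::distinct(.data$gene_id, .data$tai) |>
      dplyr::arrange(.data$tai)
    if (nrow(genes) < k) stop("fewer than k genes on strand")
    genes$bin <- paste0("Q", ceiling(seq_len(nrow(genes)) / (nrow(genes) / k)))
    dd <- dplyr::inner_join(dd, genes[, c("gene_id", "bin")], by = "gene_id")
    dd |>
      dplyr::group_by(.data$replication_strand, .data$bin) |>
      dplyr::group_modify(function(x, key) {
        counts <- numeric(64)
        at <- match(x$codon, CODONS())
        for (i in seq_len(nrow(x))) counts[at[i]] <- counts[at[i]] + x$n[i]
        m <- .class_letter_counts(counts)
        nt <- colSums(m)
        sk <- function(cls, p1, p2) {
          (m[cls, p1] - m[cls, p2]) / (m[cls, p1] + m[cls, p2])
        }
        tibble::tibble(
          n_genes = dplyr::n_distinct(x$gene_id),
          gc = (nt["G"] + nt["C"]) / sum(nt),
          mean_aa_cost = mean_aa_cost(counts, aa_costs),
          at_4s = sk("4s", "A", "T"), gc_4s = sk("4s", "G", "C"),
          at_ns = sk("ns", "A", "T"), gc_ns = sk("ns", "G", "C"))
      }) |>
      dplyr::ungroup()
  })
}
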