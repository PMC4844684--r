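#' Tally nucleotides per site class and replication strand
#'
#' Pools A/T/G/C counts over all protein-coding genes of each replication
#' strand (sense-strand sequence, START codon and trailing STOP dropped,
#' remaining positions classified by codon degeneracy) and over all
#' interoperonic regions (already in leading-strand orientation).  Genes with
#' non-triplet length or internal stop codons are skipped with a warning;
#' codons containing ambiguity codes are skipped individually.
#'
#' @param genome A rotated [annotated_genome] (`ori = 0`).
#' @param regions Interoperonic regions from [extract_interoperonic()]
#'   (may be `NULL` to tally coding sites only).
#' @return A tibble with columns `genome_id`, `site_class` (`"io"`, `"ns"`,
#'   `"2s"`, `"3s"`, `"4s"`), `strand` (`"leading"`/`"lagging"`;
#'   interoperonic counts are reported under `"leading"` as they are
#'   expressed in leading-strand orientation), and counts `a`, `t`, `g`, `c`.
#' @export
count_sites <- function(genome, regions = NULL) {
  stopifnot(inherits(genome, "annotated_genome"), genome$ori == 0L)
  genes <- genome$features[genome$features$kind == "gene", , drop = FALSE]
  codon_tally <- list(leading = integer(64), lagging = integer(64))
  skipped <- character()

  if (nrow(genes)) {
    genes <- assign_replication_strand(genes, genome$length)
    for (fid in unique(genes$id)) {
      rows <- genes[genes$id == fid, , drop = FALSE]
      seq <- feature_sequence(genome$sequence, rows)
      rs <- rows$replication_strand[1]
      ints <- dna_to_int(seq)
      if (length(ints) %% 3 != 0 || length(ints) < 6) {
        skipped <- c(skipped, paste0(fid, " (non-triplet or too short)")); next
      }
      idx <- codon_index(ints)          # NA where a codon holds an ambiguity code
      idx <- idx[-1]                    # drop annotated START regardless of identity
      if (length(idx) && !is.na(idx[length(idx)]) &&
          idx[length(idx)] %in% STOP_IDX()) {
        idx <- idx[-length(idx)]        # drop trailing STOP
      }
      if (any(idx %in% STOP_IDX(), na.rm = TRUE)) {
        skipped <- c(skipped, paste0(fid, " (internal stop)")); next
      }
      idx <- idx[!is.na(idx)]
      codon_tally[[rs]] <- codon_tally[[rs]] + tabulate(idx, nbins = 64)
    }
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped), " gene(s): ",
            paste(head(skipped, 5), collapse = "; "),
            if (length(skipped) > 5) " ..." else "")
  }

  coding <- purrr::map_dfr(c("leading", "lagging"), function(rs) {
    m <- .class_letter_counts(codon_tally[[rs]])
    tibble::tibble(site_class = rownames(m), strand = rs,
                   a = unname(m[, "A"]), t = unname(m[, "T"]),
                   g = unname(m[, "G"]), c = unname(m[, "C"]))
  })

  io <- NULL
  if (!is.null(regions) && nrow(regions)) {
    ints <- unlist(lapply(regions$sequence, dna_to_int), use.names = FALSE)
    n <- tabulate(ints, nbins = 4)
    io <- tibble::tibble(site_class = "io", strand = "leading",
                         a = n[1], t = n[4], g = n[3], c = n[2])
  }
  dplyr::mutate(dplyr::bind_rows(io, coding), genome_id = genome$genome_id,
                .before = 1)
}

# 64-vector of codon counts -> matrix of letter counts per degeneracy class.
.class_letter_counts <- function(codon_counts) {
  cls <- DEG_CLASS(); letters <- CODON_LETTERS()
  out <- matrix(0, nrow = 4, ncol = 4,
                dimnames = list(c("ns", "2s", "3s", "4s"), BASES))
  for (p in 1:3) {
    ok <- !is.na(cls[, p]) & codon_counts > 0
    for (i in which(ok)) {
      out[cls[i, p], letters[i, p]] <- out[cls[i, p], letters[i, p]] +
        codon_counts[i]
    }
  }
  out
}

#' Compute observed AT and GC skews from site counts
#'
#' The AT skew is \eqn{\gamma_{AT} = (A - T)/(A + T)} and the GC skew
#' \eqn{\gamma_{GC} = (G - C)/(G + C)} over the sites of each class and
#' strand.  Zero denominators give a flagged-undefined (`NA`) skew and
#' boundary values (\eqn{|\gamma| = 1}) are flagged so downstream estimation
#' can reject them; neither is ever silently reported as 0.
#'
#' @param counts Site counts from [count_sites()] (columns `genome_id`,
#'   `site_class`, `strand`, `a`, `t`, `g`, `c`).
#' @return A tibble with columns `genome_id`, `site_class`, `strand`, `pair`
#'   (`"AT"`/`"GC"`), `skew`, `denom`, `flag` (`"ok"`, `"undefined"`,
#'   `"boundary"`).
#' @export
observed_skews <- function(counts) {
  long <- dplyr::bind_rows(
    dplyr::transmute(counts, .data$genome_id, .data$site_class, .data$strand,
                     pair = "AT", num = .data$a - .data$t,
                     denom = .data$a + .data$t),
    dplyr::transmute(counts, .data$genome_id, .data$site_class, .data$strand,
                     pair = "GC", num = .data$g - .data$c,
                     denom = .data$g + .data$c))
  dplyr::mutate(long,
    skew = dplyr::if_else(.data$denom > 0, .data$num / .data$denom, NA_real_),
    flag = dplyr::case_when(
      denom == 0 ~ "undefined",
      abs(num) == denom ~ "boundary",
      TRUE ~ "ok"),
    num = NULL)
}

#' Restrict site counts to complementary-symmetric flanking contexts
#'
#' Re-tallies sites keeping only positions whose immediate neighbours are
#' complementary-symmetric — the left neighbour equals the complement of the
#' right neighbour (CxG, GxC, TxA, AxT) — so that a site's local context is
#' identical on both strands.  Neighbours are resolved on the sense strand
#' within each gene's coding sequence (START/STOP removed) and within each
#' interoperonic region; first/last positions, which lack a neighbour, are
#' excluded.
#'
#' @inheritParams count_sites
#' @return A tibble in the same shape as [count_sites()].
#' @export
filter_symmetric_context <- function(genome, regions = NULL) {
  stopifnot(inherits(genome, "annotated_genome"), genome$ori == 0L)
  genes <- genome$features[genome$features$kind == "gene", , drop = FALSE]
  acc <- list(
    leading = matrix(0, 4, 4, dimnames = list(c("ns", "2s", "3s", "4s"), BASES)),
    lagging = matrix(0, 4, 4, dimnames = list(c("ns", "2s", "3s", "4s"), BASES)))
  if (nrow(genes)) {
    genes <- assign_replication_strand(genes, genome$length)
    for (fid in unique(genes$id)) {
      rows <- genes[genes$id == fid, , drop = FALSE]
      seq <- feature_sequence(genome$sequence, rows)
      rs <- rows$replication_strand[1]
      ints <- dna_to_int(seq)
      if (length(ints) %% 3 != 0 || length(ints) < 9) next
      ints <- ints[-(1:3)]  # drop START
      idx <- codon_index(ints)
      if (!is.na(idx[length(idx)]) && idx[length(idx)] %in% STOP_IDX()) {
        ints <- ints[seq_len(length(ints) - 3)]
        idx <- idx[-length(idx)]
      }
      if (any(idx %in% STOP_IDX(), na.rm = TRUE)) next
      n <- length(ints)
      if (n < 3) next
      pos <- 2:(n - 1)
      sym <- !is.na(ints[pos - 1]) & !is.na(ints[pos + 1]) & !is.na(ints[pos]) &
        ints[pos - 1] == comp_int(ints[pos + 1])
      keep <- pos[sym]
      if (!length(keep)) next
      codon_of <- (keep - 1L) %/% 3L + 1L
      pos_in <- (keep - 1L) %% 3L + 1L
      cls <- DEG_CLASS()[cbind(idx[codon_of], pos_in)]
      ok <- !is.na(cls)
      if (!any(ok)) next
      tt <- table(factor(cls[ok], levels = c("ns", "2s", "3s", "4s")),
                  factor(BASES[ints[keep[ok]]], levels = BASES))
      acc[[rs]] <- acc[[rs]] + unclass(tt)
    }
  }
  coding <- purrr::map_dfr(c("leading", "lagging"), function(rs) {
    m <- acc[[rs]]
    tibble::tibble(site_class = rownames(m), strand = rs,
                   a = unname(m[, "A"]), t = unname(m[, "T"]),
                   g = unname(m[, "G"]), c = unname(m[, "C"]))
  })
  io <- NULL
  if (!is.null(regions) && nrow(regions)) {
    cnt <- integer(4)
    for (s in regions$sequence) {
      v <- dna_to_int(s)
      n <- length(v)
      if (n < 3) next
      pos <- 2:(n - 1)
      keep <- pos[!is.na(v[pos - 1]) & !is.na(v[pos + 1]) & !is.na(v[pos]) &
                    v[pos - 1] == comp_int(v[pos + 1])]
      if (length(keep)) cnt <- cnt + tabulate(v[keep], nbins = 4)
    }
    io <- tibble::tibble(site_class = "io", strand = "leading",
                         a = cnt[1], t = cnt[4], g = cnt[3], c = cnt[2])
  }
  dplyr::mutate(dplyr::bind_rows(io, coding), genome_id = genome$genome_id,
                .before = 1)
}

# ---- counts TSV dialect ------------------------------------------------------

#' Write / read site counts in the published column dialect
#'
#' The wide TSV uses one row per genome with columns `Aio`..`Cio` for
#' interoperonic counts and `<base><class><strand>` for coding counts, where
#' class `1` = nonsynonymous, `2` = twofold, `4` = fourfold and strand `le` /
#' `la` = leading / lagging (e.g. `A1le` = number of A's at nonsynonymous
#' sites on the leading strand).  Threefold (`3s`) counts are omitted from
#' the file, matching the published layout; they are excluded from all
#' estimation anyway.  Published count tables in this dialect can therefore
#' be used as drop-in inputs to [observed_skews()] via [read_site_counts()].
#'
#' @param counts Tidy counts from [count_sites()].
#' @param path File path.
#' @return `write_site_counts()` returns `path` invisibly;
#'   `read_site_counts()` returns a tidy counts tibble.
#' @export
write_site_counts <- function(counts, path) {
  keep <- counts[counts$site_class %in% c("io", "ns", "2s", "4s"), , drop = FALSE]
  wide <- dplyr::mutate(keep,
    tag = dplyr::case_when(
      site_class == "io" ~ "io",
      TRUE ~ paste0(substr(site_class, 1, 1) |>
                      (\(x) ifelse(x == "n", "1", x))(),
                    ifelse(strand == "leading", "le", "la"))))
  long <- tidyr::pivot_longer(wide, cols = c("a", "t", "g", "c"),
                              names_to = "base", values_to = "n")
  long$col <- paste0(toupper(long$base), long$tag)
  out <- tidyr::pivot_wider(long[, c("genome_id", "col", "n")],
                            names_from = "col", values_from = "n")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, cols = -"genome_id",
                              names_to = "col", values_to = "n")
  long$base <- tolower(substr(long$col, 1, 1))
  long$tag <- substr(long$col, 2, nchar(long$col))
  long$site_class <- dplyr::case_when(
    long$tag == "io" ~ "io",
    substr(long$tag, 1, 1) == "1" ~ "ns",
    substr(long$tag, 1, 1) == "2" ~ "2s",
    substr(long$tag, 1, 1) == "4" ~ "4s")
  long$strand <- dplyr::case_when(
    long$tag == "io" ~ "leading",
    endsWith(long$tag, "le") ~ "leading",
    endsWith(long$tag, "la") ~ "lagging")
  out <- tidyr::pivot_wider(
    long[, c("genome_id", "site_class", "strand", "base", "n")],
    names_from = "base", values_from = "n")
  dplyr::arrange(out, .data$genome_id, .data$site_class, .data$strand)
}
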