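# Synonymous-family table of the bacterial code: family id = amino acid
# (so Leu, Ser, Arg are 6-fold families and Ile is the single 3-fold one).
.codon_families <- function() {
  if (is.null(.skewsel_cache$fam)) {
    aa <- AA64()
    sense <- which(aa != "*")
    fam <- split(CODONS()[sense], aa[sense])
    .skewsel_cache$fam <- fam
  }
  .skewsel_cache$fam
}

#' Wright's effective number of codons (Nc)
#'
#' Composition statistic of overall codon usage bias per gene: for each
#' synonymous family the codon homozygosity is estimated as
#' \eqn{\hat F = (n \sum \hat p_i^2 - 1)/(n - 1)} (with *n* codons in the
#' family and \eqn{\hat p_i} the within-family codon frequencies), and
#' \deqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6,}
#' where \eqn{\bar F_k} averages \eqn{\hat F} over the families with *k*
#' synonymous codons (the isoleucine 3-fold family enters via
#' \eqn{\bar F_3}).  Missing \eqn{\bar F_3} falls back to the mean of
#' \eqn{\bar F_2} and \eqn{\bar F_4}; other missing size classes fall back
#' to the mean \eqn{\hat F} of the remaining families.  Values are clamped
#' to the theoretical range [20, 61]; a gene with no family holding at
#' least two codons gets `NA`.
#'
#' @param gene_codons Tibble `gene_id`, `codon`, `n`.
#' @return Tibble `gene_id`, `nc`.
#' @export
effective_number_of_codons <- function(gene_codons) {
  fams <- .codon_families()
  fam_size <- vapply(fams, length, integer(1))
  fam_of <- setNames(rep(names(fams), fam_size), unlist(fams))
  gene_codons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(x, key) {
      tibble::tibble(nc = .nc_one(setNames(x$n, x$codon), fams, fam_size))
    }) |>
    dplyr::ungroup()
}

.nc_one <- function(counts, fams, fam_size) {
  f_hat <- rep(NA_real_, length(fams))
  names(f_hat) <- names(fams)
  for (a in names(fams)) {
    n_i <- counts[fams[[a]]]
    n_i[is.na(n_i)] <- 0
    n <- sum(n_i)
    if (fam_size[[a]] < 2 || n < 2) next
    p <- n_i / n
    f_hat[a] <- (n * sum(p^2) - 1) / (n - 1)
  }
  mean_k <- function(k) {
    v <- f_hat[fam_size == k]
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else NA_real_
  }
  f2 <- mean_k(2); f3 <- mean_k(3); f4 <- mean_k(4); f6 <- mean_k(6)
  if (is.na(f3)) f3 <- mean(c(f2, f4), na.rm = TRUE)
  fallback <- mean(f_hat[!is.na(f_hat) & f_hat > 0])
  if (is.nan(fallback)) return(NA_real_)
  if (is.na(f2)) f2 <- fallback
  if (is.na(f3) || is.nan(f3)) f3 <- fallback
  if (is.na(f4)) f4 <- fallback
  if (is.na(f6)) f6 <- fallback
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(nc, 20), 61)
}

# The eight codon families whose third position is fourfold-degenerate.
.fourfold_prefixes <- function() {
  pref <- unique(substr(CODONS(), 1, 2))
  keep <- vapply(pref, function(p) {
    idx <- match(paste0(p, BASES), CODONS())
    all(DEG_CLASS()[idx, 3] == "4s")
  }, logical(1))
  pref[keep]
}

#' Identify preferred codons from the usage-bias gradient
#'
#' Within each fourfold codon family, computes Spearman's correlation
#' between a codon's within-family relative frequency across genes and the
#' genes' Nc values.  The preferred codon of a family is the codon with the
#' strongest negative correlation that is significant at a Bonferroni
#' threshold of `0.05 / n` (with *n* the family size): preferred codons are
#' used *more* in more biased (low-Nc) genes.  A genome-level 2x2 Fisher
#' test then asks whether preferred codons end in T rather than A (and in C
#' rather than G) more often than expected among fourfold codons.
#'
#' @param gene_codons Tibble `gene_id`, `codon`, `n`.
#' @param nc Per-gene Nc tibble from [effective_number_of_codons()]
#'   (computed internally when `NULL`).
#' @param alpha Family-wise significance level before the per-family
#'   Bonferroni division (default 0.05).
#' @return A list of class `cub_result`: `correlations` (codon, family,
#'   rho, p, preferred), `preferred` (one row per family with a winner),
#'   and `ending_tests` (Fisher odds ratios and p-values for T-over-A and
#'   C-over-G endings).  Constant Nc across genes yields no preferred
#'   codons (with a warning).
#' @export
preferred_codons <- function(gene_codons, nc = NULL, alpha = 0.05) {
  if (is.null(nc)) nc <- effective_number_of_codons(gene_codons)
  genes <- unique(gene_codons$gene_id)
  if (length(genes) < 30) {
    warning("preferred-codon detection with < 30 genes is underpowered")
  }
  nc_of <- setNames(nc$nc, nc$gene_id)
  if (sd(nc_of, na.rm = TRUE) == 0 || all(is.na(nc_of))) {
    warning("Nc constant across genes: correlations undefined, ",
            "no preferred codons")
    cors <- tibble::tibble(codon = character(), family = character(),
                           rho = numeric(), p = numeric(),
                           preferred = logical())
    return(structure(list(correlations = cors,
                          preferred = cors,
                          ending_tests = NULL), class = "cub_result"))
  }
  prefixes <- .fourfold_prefixes()
  all_codons <- as.vector(t(outer(prefixes, BASES, paste0)))
  # dense genes x codons count matrix
  gi <- match(gene_codons$gene_id, genes)
  ci <- match(gene_codons$codon, all_codons)
  keep <- !is.na(ci)
  M <- matrix(0, nrow = length(genes), ncol = length(all_codons),
              dimnames = list(genes, all_codons))
  M[cbind(gi[keep], ci[keep])] <- M[cbind(gi[keep], ci[keep])] +
    gene_codons$n[keep]
  y <- nc_of[genes]
  rho <- p <- setNames(rep(NA_real_, length(all_codons)), all_codons)
  for (pref in prefixes) {
    fam_codons <- paste0(pref, BASES)
    sub <- M[, fam_codons, drop = FALSE]
    tot <- rowSums(sub)
    use <- tot > 0 & is.finite(y)
    freq <- sub[use, , drop = FALSE] / tot[use]
    yy <- y[use]
    for (cc in fam_codons) {
      sp <- .spearman_approx(freq[, cc], yy)
      rho[cc] <- sp$rho
      p[cc] <- sp$p
    }
  }
  cors <- tibble::tibble(codon = all_codons,
                         family = rep(prefixes, each = 4),
                         rho = unname(rho), p = unname(p))
  n_fam <- 4L
  cors$preferred <- FALSE
  for (pref in prefixes) {
    rows <- which(cors$family == pref)
    cand <- rows[!is.na(cors$rho[rows]) & !is.na(cors$p[rows]) &
                   cors$rho[rows] < 0 & cors$p[rows] < alpha / n_fam]
    if (length(cand)) {
      cors$preferred[cand[which.min(cors$rho[cand])]] <- TRUE
    }
  }
  pref_tbl <- cors[cors$preferred, , drop = FALSE]
  ending_test <- function(e1, e2) {
    sub <- cors[substr(cors$codon, 3, 3) %in% c(e1, e2), , drop = FALSE]
    tab <- table(factor(substr(sub$codon, 3, 3), levels = c(e1, e2)),
                 factor(sub$preferred, levels = c(TRUE, FALSE)))
    ft <- fisher.test(tab)
    tibble::tibble(comparison = paste0(e1, "-over-", e2),
                   odds_ratio = unname(ft$estimate), p = ft$p.value,
                   n_preferred_1 = tab[1, 1], n_preferred_2 = tab[2, 1])
  }
  structure(list(
    correlations = cors,
    preferred = pref_tbl,
    ending_tests = dplyr::bind_rows(ending_test("T", "A"),
                                    ending_test("C", "G"))),
    class = "cub_result")
}

# Spearman correlation with the standard t-distribution approximation for
# the p-value (ranks with midrank ties, df = n - 2).
.spearman_approx <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x[ok]), rank(y[ok]))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' @export
print.cub_result <- function(x, ...) {
  cat("<cub_result>", nrow(x$preferred), "preferred codons in",
      dplyr::n_distinct(x$correlations$family), "fourfold families\n")
  if (!is.null(x$ending_tests)) print(x$ending_tests)
  invisible(x)
}
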