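#' Sample random non-stop codons with given nucleotide frequencies
#'
#' Codons are drawn with i.i.d. nucleotide positions and stop codons
#' rejected, so the returned codons follow the product distribution
#' conditioned on being sense codons.
#'
#' @param n Number of codons.
#' @param p Length-4 probability vector over A, C, G, T.
#' @return Integer vector of codon indices (1..64, sense only).
#' @keywords internal
sample_codon_idx <- function(n, p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("degenerate nucleotide frequency vector")
  }
  out <- integer(0)
  tries <- 0L
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.25) + 100L
    idx <- codon_index(sample.int(4L, 3L * m, replace = TRUE, prob = p))
    out <- c(out, idx[!(idx %in% STOP_IDX())])
    tries <- tries + 1L
    if (tries > 50L) stop("rejection sampling failed: stop-codon rate too high")
  }
  out[seq_len(n)]
}

# Skews per site class from a 64-long codon count vector.
.codon_counts_to_skews <- function(codon_counts) {
  m <- .class_letter_counts(codon_counts)
  tibble::tibble(
    site_class = rep(rownames(m), 2),
    pair = rep(c("AT", "GC"), each = nrow(m)),
    skew = c((m[, "A"] - m[, "T"]) / (m[, "A"] + m[, "T"]),
             (m[, "G"] - m[, "C"]) / (m[, "G"] + m[, "C"])))
}

#' Null simulation: skews of random genomes without mutation bias or selection
#'
#' Generates random "genomes" of i.i.d. non-stop codons with equal A/T and
#' equal G/C frequencies (so every basepair is unskewed by construction)
#' across a range of GC contents, classifies sites by codon degeneracy, and
#' returns the AT and GC skews per site class and genome.  Any non-zero skew
#' is attributable purely to the exclusion of stop codons from the codon
#' table; the cross-genome medians at nonsynonymous sites are the null
#' expectations against which observed genomic skews are compared.
#'
#' @param n_genomes Number of random genomes (default 1200).
#' @param gc_range GC contents are equally spaced over this interval
#'   (default 20--80%).
#' @param n_codons Sense codons per genome (default 1e6).
#' @param seed Seed for reproducibility (`NULL` to use the caller's RNG
#'   state).
#' @return Tibble `genome`, `gc`, `site_class`, `pair`, `skew`.
#' @seealso [null_skew_medians()]
#' @export
simulate_null_genomes <- function(n_genomes = 1200, gc_range = c(0.2, 0.8),
                                  n_codons = 1e6, seed = NULL) {
  stopifnot(gc_range[1] > 0, gc_range[2] < 1, gc_range[1] <= gc_range[2])
  if (!is.null(seed)) set.seed(seed)
  gcs <- seq(gc_range[1], gc_range[2], length.out = n_genomes)
  purrr::map_dfr(seq_len(n_genomes), function(i) {
    g <- gcs[i]
    p <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)  # A, C, G, T
    idx <- sample_codon_idx(n_codons, p)
    dplyr::mutate(.codon_counts_to_skews(tabulate(idx, 64)),
                  genome = i, gc = g, .before = 1)
  })
}

#' Cross-genome median skews of a null ensemble
#'
#' @param x Output of [simulate_null_genomes()].
#' @return Tibble `site_class`, `pair`, `median_skew`.
#' @export
null_skew_medians <- function(x) {
  x |>
    dplyr::group_by(.data$site_class, .data$pair) |>
    dplyr::summarise(median_skew = median(.data$skew, na.rm = TRUE),
                     .groups = "drop")
}

#' Simulate the codon-table cost trade-off over a GC-content x skew grid
#'
#' For each combination of GC content and skew, random sense codons are
#' drawn with nucleotide frequencies
#' \eqn{P(A) = (1-gc)(1+\gamma_{AT})/2}, \eqn{P(T) = (1-gc)(1-\gamma_{AT})/2},
#' \eqn{P(G) = gc(1+\gamma_{GC})/2}, \eqn{P(C) = gc(1-\gamma_{GC})/2}
#' (the maximum-entropy sequence model consistent with the marginal GC
#' content and skews), stop codons rejected, and the mean synthesis cost of
#' the encoded amino acids and of the nucleotides themselves recorded.  In
#' mode `"AT-only"`/`"GC-only"` the grid skew is applied to one basepair
#' type with the other held at zero; in mode `"both"` the same skew applies
#' to both, as in the published grid.
#'
#' @param gc_values GC contents (default 10--90% in steps of 10%).
#' @param skew_values Skews (default -0.8 to 0.8 in steps of 0.2).
#' @param n_codons Codons per grid point (default 1e6).
#' @param aa_costs,nt_costs Cost tables ([load_costs()]).
#' @param mode `"both"`, `"AT-only"` or `"GC-only"`.
#' @param seed Seed (`NULL` for caller's RNG state).
#' @return Tibble `gc`, `at_skew`, `gc_skew` (the generating parameters),
#'   `obs_at_skew`, `obs_gc_skew` (realised overall skews among sense
#'   codons), `mean_aa_cost`, `mean_nt_cost`, `n_codons`.
#' @export
simulate_tradeoff_grid <- function(gc_values = seq(0.1, 0.9, by = 0.1),
                                   skew_values = seq(-0.8, 0.8, by = 0.2),
                                   n_codons = 1e6,
                                   aa_costs = load_costs(type = "aa"),
                                   nt_costs = load_costs(type = "nt"),
                                   mode = c("both", "AT-only", "GC-only"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(gc = gc_values, skew = skew_values)
  aa_vec <- .cost_vec(aa_costs)
  nt_vec <- .cost_vec(nt_costs)
  purrr::pmap_dfr(grid, function(gc, skew) {
    at_s <- if (mode == "GC-only") 0 else skew
    gc_s <- if (mode == "AT-only") 0 else skew
    p <- c((1 - gc) * (1 + at_s) / 2, gc * (1 - gc_s) / 2,
           gc * (1 + gc_s) / 2, (1 - gc) * (1 - at_s) / 2)
    idx <- sample_codon_idx(n_codons, p)
    counts <- tabulate(idx, 64)
    nt <- numeric(4)
    for (pos in 1:3) {
      nt <- nt + vapply(1:4, function(b)
        sum(counts[CODON_LETTERS()[, pos] == BASES[b]]), numeric(1))
    }
    names(nt) <- c("A", "C", "G", "U")[match(BASES, BASES)]
    names(nt) <- c("A", "C", "G", "T")
    tibble::tibble(
      gc = gc, at_skew = at_s, gc_skew = gc_s,
      obs_at_skew = (nt["A"] - nt["T"]) / (nt["A"] + nt["T"]),
      obs_gc_skew = (nt["G"] - nt["C"]) / (nt["G"] + nt["C"]),
      mean_aa_cost = mean_aa_cost(counts, aa_vec),
      mean_nt_cost = mean_nt_cost(nt, nt_vec),
      n_codons = n_codons)
  })
}

#' Ground-truth parameter set for the synthetic genome generator
#'
#' Bundles the evolutionary parameters (per basepair type) and the
#' structural layout of a synthetic circular chromosome.  The defaults are
#' the reference study conditions used throughout the package's validation:
#' a moderate mutational bias amplified 1.5-fold in transcripts, selection
#' against expensive nucleotides in transcription and for them in
#' translation, and roughly a third of nonsynonymous sites free.
#'
#' @param mu_io Interoperonic (replication) mutational bias per pair;
#'   length-2 named vector (`AT`, `GC`) or a single value used for both.
#' @param tau Transcription amplification factor.
#' @param s_rna,s_aa Scaled selection coefficients (transcription /
#'   translation channel), per pair as for `mu_io`.
#' @param f Free-site fraction of nonsynonymous positions, per pair.
#'   Must satisfy `f <= 2 * p_at / (2 * p_at + 1)` (and the GC analogue):
#'   the generator realises the fixed `1 - f` fraction partly through
#'   composition-balanced invariant positions, which caps the attainable
#'   pooled free fraction.
#' @param p_at Probability that a drawn site belongs to an A/T (rather than
#'   G/C) basepair; 0.5 gives a 50% GC genome at drawn sites.
#' @param n_operons Number of operons (even; half per replichore).
#' @param genes_per_operon,codons_per_gene Gene layout; `codons_per_gene`
#'   is rounded up to a multiple of 4 (the generator's codon-block size).
#' @param io_len Length of each interoperonic gap (bases); must exceed the
#'   extraction minimum plus twice the 5'-trim.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(mu_io = 0.05, tau = 1.5, s_rna = -0.3,
                            s_aa = 0.8, f = 0.35, p_at = 0.5,
                            n_operons = 40, genes_per_operon = 1,
                            codons_per_gene = 5000, io_len = 2700) {
  pairify <- function(x) {
    if (is.null(names(x))) setNames(rep_len(x, 2), c("AT", "GC")) else
      x[c("AT", "GC")]
  }
  truth <- list(mu_io = pairify(mu_io), tau = tau, s_rna = pairify(s_rna),
                s_aa = pairify(s_aa), f = pairify(f), p_at = p_at,
                n_operons = as.integer(n_operons),
                genes_per_operon = as.integer(genes_per_operon),
                codons_per_gene = as.integer(4 * ceiling(codons_per_gene / 4)),
                io_len = as.integer(io_len))
  stopifnot(all(abs(truth$mu_io) < 1), all(abs(truth$mu_io * tau) < 1),
            truth$p_at > 0, truth$p_at < 1,
            truth$n_operons %% 2 == 0, truth$n_operons >= 2,
            truth$io_len >= 400)
  f_cap <- c(AT = 2 * p_at / (2 * p_at + 1),
             GC = 2 * (1 - p_at) / (2 * (1 - p_at) + 1))
  if (any(truth$f <= 0) || any(truth$f > f_cap)) {
    stop("inconsistent structural parameters: f must lie in (0, ",
         "2*p/(2*p+1)] for the pair probability p")
  }
  structure(truth, class = "synthetic_truth")
}

# Draw n site states for one basepair pair: returns integer letters.
# first/second are the integer codes of the expensive/cheap base of the pair.
.draw_pair_sites <- function(n, prob_first, first, second) {
  ifelse(runif(n) < prob_first, first, second)
}

# Draw n model sites (pair choice + equilibrium state).  Returns integer
# letter codes.  gam is a named c(AT=, GC=) vector of target skews.
.draw_sites <- function(n, p_at, gam) {
  is_at <- runif(n) < p_at
  p_first <- ifelse(is_at, (1 + gam[["AT"]]) / 2, (1 + gam[["GC"]]) / 2)
  first <- ifelse(is_at, 1L, 3L)   # A or G
  second <- ifelse(is_at, 4L, 2L)  # T or C
  ifelse(runif(n) < p_first, first, second)
}

#' Generate a synthetic annotated genome from known evolutionary parameters
#'
#' Builds a circular chromosome (origin at coordinate 0, terminus antipodal)
#' whose interoperonic, fourfold-synonymous and nonsynonymous sites are
#' drawn from the mutation-selection-drift equilibrium with the supplied
#' ground truth, so that running the full analysis pipeline on the output
#' should recover the generating parameters.  Operons alternate between the
#' plus and minus strand within each replichore, covering all four
#' strand-by-half combinations.
#'
#' Coding sequence is assembled from four codon templates in balanced
#' 4-codon blocks.  Each block carries four model-drawn nonsynonymous
#' positions, four invariant nonsynonymous positions whose letters are
#' exactly composition-balanced (one each of A, T, G, C per block, hence
#' zero pooled skew), one-to-two model-drawn fourfold positions, and
#' invariant positions falling only in twofold/threefold classes (which are
#' excluded from estimation).  The invariant NS letters realise part of the
#' functionally fixed site fraction; the free-draw probability within drawn
#' NS sites is rescaled per basepair type so the pooled NS skew equals
#' `f * forward_skew(tau * mu_io, s_rna + s_aa, strand)` in expectation.
#' Fourfold sites follow `forward_skew(tau * mu_io, s_rna, strand)` and
#' interoperonic sites `forward_skew(mu_io, 0, leading)` in leading-strand
#' orientation.  No in-frame stop codons can occur; every gene gets an ATG
#' start and TAA stop (dropped again by the classifier).
#'
#' @param truth A [synthetic_truth()] object.
#' @param genome_id Identifier for the genome.
#' @param seed Seed (`NULL` to use the caller's RNG state).
#' @return List with elements `genome` (an [annotated_genome] with
#'   `ori = 0`), `operons` and `origin` (tibbles in the input-TSV dialects,
#'   1-based), and `truth`.
#' @export
generate_synthetic_genome <- function(truth = synthetic_truth(),
                                      genome_id = "synthetic1", seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  p_at <- truth$p_at
  mu4 <- truth$tau * truth$mu_io
  gam_4s <- function(strand) c(
    AT = forward_skew(mu4[["AT"]], truth$s_rna[["AT"]], strand),
    GC = forward_skew(mu4[["GC"]], truth$s_rna[["GC"]], strand))
  gam_ns <- function(strand) c(
    AT = forward_skew(mu4[["AT"]], truth$s_rna[["AT"]] + truth$s_aa[["AT"]], strand),
    GC = forward_skew(mu4[["GC"]], truth$s_rna[["GC"]] + truth$s_aa[["GC"]], strand))
  # Free-draw probability so the pooled NS skew is f * model skew despite the
  # balanced invariant letters (2 per pair per 4-codon block, 4 drawn sites).
  f_prime <- c(
    AT = truth$f[["AT"]] * (4 * p_at + 2) / (4 * p_at),
    GC = truth$f[["GC"]] * (4 * (1 - p_at) + 2) / (4 * (1 - p_at)))
  gam_io <- c(AT = forward_skew(truth$mu_io[["AT"]], 0, "leading"),
              GC = forward_skew(truth$mu_io[["GC"]], 0, "leading"))

  gene_codons <- function(n, strand) {
    # templates cycle T1, TG, TA, TT within each block of 4 codons
    tmpl <- rep_len(1:4, n)
    # drawn NS letters: free sites from the NS equilibrium, fixed from 50/50
    is_at <- runif(n) < p_at
    free <- runif(n) < ifelse(is_at, f_prime[["AT"]], f_prime[["GC"]])
    gns <- gam_ns(strand)
    p_first <- ifelse(free, ifelse(is_at, (1 + gns[["AT"]]) / 2,
                                   (1 + gns[["GC"]]) / 2), 0.5)
    ns_draw <- ifelse(runif(n) < p_first, ifelse(is_at, 1L, 3L),
                      ifelse(is_at, 4L, 2L))
    four_draw <- .draw_sites(n, p_at, gam_4s(strand))
    C <- 2L; G <- 3L; A <- 1L; T <- 4L
    c1 <- ifelse(tmpl == 1L, ns_draw,
                 ifelse(tmpl == 2L, G, ifelse(tmpl == 3L, A, T)))
    c2 <- ifelse(tmpl == 1L, C, ns_draw)
    # third position: drawn fourfold site when the prefix is a 4-fold family,
    # else an invariant C landing in a 2s/3s class
    four_ok <- (tmpl == 1L) |
      (tmpl == 2L & c2 != A) |
      (tmpl >= 3L & c2 == C)
    c3 <- ifelse(four_ok, four_draw, C)
    as.vector(rbind(c1, c2, c3))
  }

  n_per_half <- truth$n_operons %/% 2L
  segs <- character(0)
  feats <- list()
  pos <- 0L
  op_counter <- 0L
  gene_counter <- 0L
  halves_bp <- integer(2)
  for (half in 1:2) {
    for (j in seq_len(n_per_half)) {
      # interoperonic gap, drawn in leading orientation
      io <- .draw_sites(truth$io_len, p_at, gam_io)
      io_str <- int_to_dna(io)
      if (half == 2L) io_str <- revcomp(io_str)
      segs <- c(segs, io_str)
      pos <- pos + truth$io_len
      # operon: alternate strand; leading iff (+ & half1) or (- & half2)
      op_strand <- if (j %% 2L == 1L) "+" else "-"
      rep_strand <- if ((op_strand == "+") == (half == 1L)) "leading" else "lagging"
      op_counter <- op_counter + 1L
      op_start <- pos
      for (k in seq_len(truth$genes_per_operon)) {
        gene_counter <- gene_counter + 1L
        body <- int_to_dna(gene_codons(truth$codons_per_gene, rep_strand))
        sense <- paste0("ATG", body, "TAA")
        plus <- if (op_strand == "+") sense else revcomp(sense)
        glen <- nchar(sense)
        feats[[length(feats) + 1]] <- tibble::tibble(
          start = pos, end = pos + glen, strand = op_strand, kind = "gene",
          id = sprintf("gene%04d", gene_counter), part = 1L)
        segs <- c(segs, plus)
        pos <- pos + glen
      }
      feats[[length(feats) + 1]] <- tibble::tibble(
        start = op_start, end = pos, strand = op_strand, kind = "operon",
        id = sprintf("op%03d", op_counter), part = 1L)
    }
    halves_bp[half] <- pos - sum(halves_bp)
  }
  sequence <- paste(segs, collapse = "")
  genome <- annotated_genome(genome_id, sequence, ori = 0L,
                             features = dplyr::bind_rows(feats))
  ops <- genome$features[genome$features$kind == "operon", , drop = FALSE]
  list(
    genome = genome,
    operons = tibble::tibble(genome_id = genome_id, operon_id = ops$id,
                             start = ops$start + 1L, end = ops$end,
                             strand = ops$strand),
    origin = tibble::tibble(genome_id = genome_id, ori_start = 1L),
    truth = truth)
}

#' Write a synthetic genome to standard files
#'
#' Emits FASTA (sequence), GFF3 (gene features), the operon and origin TSVs
#' in the dialects accepted by [read_genome()], and the ground truth as
#' JSON.
#'
#' @param x Output of [generate_synthetic_genome()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_synthetic_genome <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gid <- x$genome$genome_id
  fa <- file.path(dir, paste0(gid, ".fasta"))
  writeLines(c(paste0(">", gid), .wrap_seq(x$genome$sequence)), fa)
  genes <- x$genome$features[x$genome$features$kind == "gene", , drop = FALSE]
  gff <- c("##gff-version 3",
           sprintf("%s\tskewsel\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   gid, genes$start + 1L, genes$end, genes$strand, genes$id))
  writeLines(gff, file.path(dir, paste0(gid, ".gff")))
  readr::write_tsv(x$operons, file.path(dir, paste0(gid, "_operons.tsv")))
  readr::write_tsv(x$origin, file.path(dir, paste0(gid, "_origin.tsv")))
  jsonlite::write_json(unclass(x$truth), file.path(dir, paste0(gid, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.wrap_seq <- function(s, width = 70) {
  n <- nchar(s)
  starts <- seq(1, n, by = width)
  substring(s, starts, pmin(starts + width - 1, n))
}

#' Simulate a multi-genome study and run the site-counting pipeline
#'
#' Generates `n_genomes` synthetic genomes from a common ground truth and
#' pushes each through the standard pipeline (interoperonic extraction,
#' site counting, observed skews), returning the pooled skew table ready
#' for [fit_skew_model()].
#'
#' @param n_genomes Number of genomes.
#' @param truth A [synthetic_truth()].
#' @param seed Study seed; genome g uses RNG stream continuation from it.
#' @return List with `skews` (all genomes) and `truth`.
#' @export
simulate_skew_study <- function(n_genomes = 100, truth = synthetic_truth(),
                                seed = 1) {
  set.seed(seed)
  skews <- purrr::map_dfr(seq_len(n_genomes), function(g) {
    sim <- generate_synthetic_genome(truth, genome_id = sprintf("sim%03d", g))
    regions <- extract_interoperonic(sim$genome)
    observed_skews(count_sites(sim$genome, regions))
  })
  list(skews = skews, truth = truth)
}
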