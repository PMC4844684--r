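#' Load a nucleotide or amino-acid synthesis-cost table
#'
#' Cost tables are TSVs with columns `name` (one-letter nucleotide `A/C/G/U`
#' or one-letter amino-acid code), `cost` (high-energy phosphate bonds, ATP
#' units, for de novo synthesis) and `source` (free-text label).  Two
#' fixtures ship with the package: `aa_costs.tsv`, the published
#' aerobic-respiration E. coli amino-acid costs, and
#' `nt_costs_synthetic.tsv`, a constructed nucleotide table (synthetic — no
#' flux-balance recomputation is done here) that satisfies the established
#' cost orderings A>U, G>C, C>U, G>A and G+C>A+U.  Any conforming TSV, e.g.
#' lifestyle-specific variants, can be supplied instead.
#'
#' @param path Path to a cost TSV; the default loads the packaged fixture of
#'   the requested `type`.
#' @param type `"aa"` (expects all 20 amino acids) or `"nt"` (expects
#'   A, C, G, U).
#' @return A tibble `name`, `cost`, `source`, validated for completeness and
#'   strictly positive costs.
#' @export
#' @examples
#' load_costs(type = "nt")
load_costs <- function(path = NULL, type = c("aa", "nt")) {
  type <- match.arg(type)
  if (is.null(path)) {
    file <- if (type == "aa") "aa_costs.tsv" else "nt_costs_synthetic.tsv"
    path <- system.file("extdata", file, package = "skewsel", mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("name", "cost") %in% names(tab)))
  if (!"source" %in% names(tab)) tab$source <- basename(path)
  required <- if (type == "aa") {
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  } else {
    c("A", "C", "G", "U")
  }
  missing <- setdiff(required, tab$name)
  if (length(missing)) {
    stop("cost table is missing entries: ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(tab$cost) | tab$cost <= 0)) {
    stop("cost table has non-positive or missing costs")
  }
  tibble::as_tibble(tab[match(required, tab$name),
                        c("name", "cost", "source")])
}

# Named cost vector from a table or vector.
.cost_vec <- function(costs) {
  if (is.data.frame(costs)) setNames(costs$cost, costs$name) else costs
}

#' Mean amino-acid synthesis cost of a codon composition
#'
#' Count-weighted average cost of the amino acids encoded by a set of sense
#' codons under the bacterial codon table.
#'
#' @param codon_counts Named numeric vector (`names` = codons) or a 64-long
#'   unnamed vector in the package's codon-index order.  Stop codons must
#'   have zero counts.
#' @param costs Amino-acid cost table from [load_costs()] (or a named
#'   vector).
#' @return Mean cost in ATP units (`NA` with a warning when the total count
#'   is zero).
#' @export
mean_aa_cost <- function(codon_counts, costs = load_costs(type = "aa")) {
  cv <- .cost_vec(costs)
  counts <- .as_codon_counts(codon_counts)
  if (any(counts[STOP_IDX()] > 0)) stop("stop codons in codon counts")
  aa <- AA64()
  sense <- aa != "*"
  tot <- sum(counts[sense])
  if (tot == 0) {
    warning("zero total codon count: mean cost undefined")
    return(NA_real_)
  }
  sum(counts[sense] * cv[aa[sense]]) / tot
}

#' Mean nucleotide synthesis cost of a base composition
#'
#' Count-weighted average cost over the RNA alphabet; DNA `T` counts are
#' priced as `U` (transcript framing).
#'
#' @param nt_counts Named numeric vector over `A`, `C`, `G` and `U` (or `T`).
#' @param costs Nucleotide cost table from [load_costs()] (or a named
#'   vector).
#' @return Mean cost in ATP units per nucleotide (`NA` with a warning on a
#'   zero total).
#' @export
mean_nt_cost <- function(nt_counts, costs = load_costs(type = "nt")) {
  cv <- .cost_vec(costs)
  nm <- names(nt_counts)
  if (is.null(nm)) stop("nt_counts must be named")
  nm[nm == "T"] <- "U"
  if (!all(nm %in% c("A", "C", "G", "U"))) stop("unknown nucleotide names")
  tot <- sum(nt_counts)
  if (tot == 0) {
    warning("zero total nucleotide count: mean cost undefined")
    return(NA_real_)
  }
  sum(nt_counts * cv[nm]) / tot
}

# Accept named codon counts or a 64-vector in index order.
.as_codon_counts <- function(x) {
  if (!is.null(names(x))) {
    idx <- match(names(x), CODONS())
    if (anyNA(idx)) stop("unknown codons: ",
                         paste(names(x)[is.na(idx)], collapse = ", "))
    out <- numeric(64)
    out[idx] <- out[idx] + as.numeric(x)
    out
  } else {
    stopifnot(length(x) == 64)
    as.numeric(x)
  }
}
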