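#' Count sites for one or more genomes from standard input files
#'
#' Orchestrates [read_genome()], [rotate_to_origin()],
#' [extract_interoperonic()] and [count_sites()] for each genome and
#' optionally writes the pooled counts in the wide TSV dialect
#' ([write_site_counts()]).  Genomes without a replication-origin entry are
#' skipped and reported in the returned `errors` attribute rather than
#' aborting the run.
#'
#' @param fasta,gff Character vectors of file paths (one per genome; `gff`
#'   may be `NULL`).
#' @param operons,origins Paths to the operon and origin TSVs shared by all
#'   genomes (or per-genome vectors).
#' @param out Optional output TSV path.
#' @return Tidy counts tibble for all processed genomes; attribute
#'   `errors` holds a tibble of skipped genomes and reasons.
#' @export
run_count <- function(fasta, gff = NULL, operons = NULL, origins = NULL,
                      out = NULL) {
  n <- length(fasta)
  gff <- rep_len(gff %||% list(NULL), n)
  operons <- rep_len(operons %||% list(NULL), n)
  origins <- rep_len(origins %||% list(NULL), n)
  errors <- list()
  counts <- purrr::map_dfr(seq_len(n), function(i) {
    res <- tryCatch({
      g <- read_genome(fasta[[i]], gff = gff[[i]], operons = operons[[i]],
                       origins = origins[[i]])
      g <- rotate_to_origin(g)
      regions <- extract_interoperonic(g)
      count_sites(g, regions)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <<- tibble::tibble(
        input = fasta[[i]], error = conditionMessage(res))
      return(NULL)
    }
    res
  })
  if (length(errors)) {
    err <- dplyr::bind_rows(errors)
    warning(nrow(err), " genome(s) skipped; see attr(, 'errors')")
    attr(counts, "errors") <- err
  }
  if (!is.null(out)) write_site_counts(counts, out)
  counts
}

#' Fit the skew model from a counts table and write tidy outputs
#'
#' @param counts Tidy counts tibble (or path to a wide counts TSV).
#' @param mode,tau,f,boot Passed to [fit_skew_model()].
#' @param out_dir Optional directory; writes `params.tsv` (tidy per-genome
#'   estimates) and `global_fit.json` (tau/f with CIs).
#' @return The `skew_fit` object.
#' @export
run_fit <- function(counts, mode = "fit-global", tau = NULL, f = NULL,
                    boot = 1000, out_dir = NULL) {
  if (is.character(counts)) counts <- read_site_counts(counts)
  fit <- fit_skew_model(observed_skews(counts), mode = mode, tau = tau,
                        f = f, boot = boot)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(tidy(fit), file.path(out_dir, "params.tsv"))
    jsonlite::write_json(glance(fit), file.path(out_dir, "global_fit.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  fit
}

#' Run one of the package's simulations
#'
#' @param kind `"null"` (no-selection random genomes), `"tradeoff"` (codon
#'   table cost trade-off grid) or `"genome"` (synthetic annotated genome).
#' @param ... Passed to [simulate_null_genomes()],
#'   [simulate_tradeoff_grid()] or [generate_synthetic_genome()].
#' @param out_dir Optional output directory (TSV for the first two kinds;
#'   FASTA/GFF3/TSV/JSON via [write_synthetic_genome()] for `"genome"`).
#' @param seed Seed forwarded to the simulator.
#' @return The simulation result (tibble or genome bundle).
#' @export
run_simulate <- function(kind = c("null", "tradeoff", "genome"), ...,
                         out_dir = NULL, seed = 1) {
  kind <- match.arg(kind)
  res <- switch(kind,
    null = simulate_null_genomes(..., seed = seed),
    tradeoff = simulate_tradeoff_grid(..., seed = seed),
    genome = {
      set.seed(seed)
      generate_synthetic_genome(...)
    })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (kind == "genome") {
      write_synthetic_genome(res, out_dir)
    } else {
      readr::write_tsv(res, file.path(out_dir, paste0(kind, "_simulation.tsv")))
      if (kind == "null") {
        readr::write_tsv(null_skew_medians(res),
                         file.path(out_dir, "null_medians.tsv"))
      }
    }
  }
  res
}
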