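#' Construct an annotated circular genome
#'
#' Container for one circular prokaryotic chromosome: the plus-strand
#' sequence, the replication-origin coordinate, and oriented feature
#' intervals (genes, operons, tRNAs, rRNAs).  Internal coordinates are
#' 0-based half-open on the plus strand; features wrapping the coordinate
#' origin are stored as two fragments sharing an `id` (distinguished by
#' `part`).
#'
#' @param genome_id Character scalar.
#' @param sequence Plus-strand DNA as a single string over `{A,C,G,T}`.
#' @param ori 0-based replication-origin position, `0 <= ori < nchar(sequence)`.
#' @param features Tibble with columns `start`, `end` (0-based half-open),
#'   `strand` (`"+"`/`"-"`), `kind` (`"gene"`, `"operon"`, `"tRNA"`, `"rRNA"`),
#'   `id`, and optionally `part` (fragment index for wrapped features).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, sequence, ori = 0L, features = NULL) {
  L <- nchar(sequence)
  if (is.null(features)) {
    features <- tibble::tibble(start = integer(), end = integer(),
                               strand = character(), kind = character(),
                               id = character(), part = integer())
  }
  if (!"part" %in% names(features)) features$part <- 1L
  stopifnot(L > 0, ori >= 0, ori < L,
            all(features$start >= 0), all(features$end <= L),
            all(features$start < features$end),
            all(features$strand %in% c("+", "-")))
  structure(list(genome_id = genome_id, sequence = toupper(sequence),
                 length = L, ori = as.integer(ori),
                 features = tibble::as_tibble(features)),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$genome_id, ": ", x$length, " bp circular, ori = ",
      x$ori, ", ", nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' Read a genome with its annotation, operons and replication origin
#'
#' Reads the plus-strand chromosome sequence (largest FASTA record when a
#' file holds several), gene/tRNA/rRNA features from GFF3, operons from a
#' DOOR-style TSV (`genome_id`, `operon_id`, `start`, `end`, `strand`;
#' 1-based inclusive) and the replication origin from a DoriC-style TSV
#' (`genome_id`, `ori_start`, 1-based; the first matching row is used when a
#' genome has several entries).  All coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param fasta,gff Paths to the FASTA and GFF3 files.
#' @param operons,origins Paths to operon and origin TSVs (may be `NULL`;
#'   `origins` may also be a single origin coordinate, 1-based).
#' @param genome_id Identifier used to select rows in the TSVs; defaults to
#'   the first word of the FASTA header of the chosen record.
#' @return An [annotated_genome].
#' @export
read_genome <- function(fasta, gff = NULL, operons = NULL, origins = NULL,
                        genome_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0) stop("no sequences in ", fasta)
  biggest <- which.max(Biostrings::width(seqs))
  sequence <- as.character(seqs[[biggest]])
  if (is.null(genome_id)) {
    genome_id <- strsplit(names(seqs)[biggest], "\\s+")[[1]][1]
  }
  feats <- list()
  if (!is.null(gff)) {
    g <- ape::read.gff(gff)
    keep <- g$type %in% c("gene", "tRNA", "rRNA")
    g <- g[keep, , drop = FALSE]
    if (nrow(g)) {
      ids <- sub(".*?ID=([^;]+).*", "\\1", g$attributes)
      ids[!grepl("ID=", g$attributes)] <-
        paste0("feat", seq_len(sum(!grepl("ID=", g$attributes))))
      feats$gff <- tibble::tibble(
        start = as.integer(g$start) - 1L, end = as.integer(g$end),
        strand = as.character(g$strand),
        kind = ifelse(g$type == "gene", "gene", as.character(g$type)),
        id = ids, part = 1L)
    }
  }
  if (!is.null(operons)) {
    op <- readr::read_tsv(operons, show_col_types = FALSE)
    op <- op[op$genome_id == genome_id, , drop = FALSE]
    if (nrow(op)) {
      feats$op <- tibble::tibble(
        start = as.integer(op$start) - 1L, end = as.integer(op$end),
        strand = as.character(op$strand), kind = "operon",
        id = as.character(op$operon_id), part = 1L)
    }
  }
  ori <- 0L
  if (!is.null(origins)) {
    if (is.numeric(origins)) {
      ori <- as.integer(origins) - 1L
    } else {
      orit <- readr::read_tsv(origins, show_col_types = FALSE)
      hit <- which(orit$genome_id == genome_id)
      if (length(hit) == 0) {
        stop("genome ", genome_id, " has no replication-origin entry")
      }
      ori <- as.integer(orit$ori_start[hit[1]]) - 1L  # first entry wins
    }
  }
  annotated_genome(genome_id, sequence, ori = ori,
                   features = dplyr::bind_rows(feats))
}

#' Rotate a genome so that the replication origin sits at coordinate 0
#'
#' Shifts all coordinates by `-ori` modulo the chromosome length and rotates
#' the sequence accordingly.  Features that come to straddle the new
#' coordinate origin are split into two fragments sharing their `id`.
#'
#' @param genome An [annotated_genome].
#' @return The rotated [annotated_genome] with `ori = 0`.
#' @export
rotate_to_origin <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  L <- genome$length
  ori <- genome$ori
  if (ori == 0L) return(genome)
  sequence <- paste0(substr(genome$sequence, ori + 1L, L),
                     substr(genome$sequence, 1L, ori))
  f <- genome$features
  if (nrow(f)) {
    s <- (f$start - ori) %% L
    e <- s + (f$end - f$start)  # may exceed L: wrapped
    wrapped <- e > L
    plain <- dplyr::mutate(f[!wrapped, , drop = FALSE],
                           start = s[!wrapped], end = e[!wrapped])
    wrap <- f[wrapped, , drop = FALSE]
    frag <- dplyr::bind_rows(
      dplyr::mutate(wrap, start = s[wrapped], end = L, part = 1L),
      dplyr::mutate(wrap, start = 0L, end = e[wrapped] - L, part = 2L))
    f <- dplyr::arrange(dplyr::bind_rows(plain, frag), .data$start, .data$id)
  }
  annotated_genome(genome$genome_id, sequence, ori = 0L, features = f)
}

#' Assign features to the leading or lagging replication strand
#'
#' With the origin at coordinate 0 and the terminus assumed antipodal, the
#' replication fork travels rightwards along the plus strand on the first
#' half of the chromosome `[0, L/2)` and along the minus strand on the second
#' half.  A gene is transcribed co-directionally with the fork — i.e. lies on
#' the leading strand — iff it is on the plus strand in the first half or on
#' the minus strand in the second half.  Features are assigned by their
#' midpoint; a wrapped feature (two fragments sharing an `id`) is assigned by
#' the midpoint of the re-joined interval.
#'
#' @param features Tibble of oriented intervals (`start`, `end`, `strand`,
#'   `id`, optionally `part`), 0-based half-open, on a genome rotated so that
#'   `ori = 0`.
#' @param L Chromosome length in bases.
#' @return The tibble with an added `replication_strand` column
#'   (`"leading"`/`"lagging"`).
#' @export
#' @examples
#' f <- tibble::tibble(start = 1L, end = 4L, strand = "+", id = "g1")
#' assign_replication_strand(f, L = 10)$replication_strand  # "leading"
assign_replication_strand <- function(features, L) {
  stopifnot(all(features$end > features$start))
  if (!"part" %in% names(features)) features$part <- 1L
  mid <- .feature_midpoints(features, L)
  first_half <- mid < L / 2
  features$replication_strand <- ifelse(
    (features$strand == "+") == first_half, "leading", "lagging")
  features
}

# Midpoint per row, re-joining wrapped fragments (shared id, part 1 at the
# right edge and part 2 at 0) so the midpoint is computed on the circle.
.feature_midpoints <- function(features, L) {
  mid <- (features$start + features$end) / 2
  multi <- features$id[duplicated(features$id)]
  for (fid in unique(multi)) {
    rows <- which(features$id == fid)
    lens <- features$end[rows] - features$start[rows]
    p1 <- rows[which(features$part[rows] == 1L)][1]
    m <- (features$start[p1] + sum(lens) / 2) %% L
    mid[rows] <- m
  }
  mid
}

#' Extract interoperonic (presumed non-transcribed) regions
#'
#' Takes the complement of all annotated features on the circular chromosome,
#' trims `trim5` bases from each gap where the gap abuts the 5' end of a
#' feature (the start of a plus-strand feature or the end of a minus-strand
#' feature; gaps flanked only by 3' ends are kept untrimmed), discards gaps
#' shorter than `min_len` after trimming, splits any surviving region that
#' straddles the half-chromosome boundary at `L/2`, and expresses every
#' region in leading-strand orientation: regions in the second half are
#' reverse-complemented.
#'
#' @param genome A rotated [annotated_genome] (`ori = 0`) whose features
#'   include genes/operons and tRNA/rRNA annotations.
#' @param min_len Minimum region length after trimming (bases).
#' @param trim5 Bases removed where a gap abuts a feature's 5' end.
#' @return Tibble with one row per oriented region: `start`, `end`
#'   (plus-strand coordinates of this fragment; a region wrapping coordinate
#'   0 contributes separate rows), `half` (1 or 2), and `sequence`
#'   (leading-strand orientation).
#' @export
extract_interoperonic <- function(genome, min_len = 100L, trim5 = 60L) {
  stopifnot(inherits(genome, "annotated_genome"), genome$ori == 0L)
  L <- genome$length
  f <- genome$features
  if (nrow(f) == 0) stop("genome has no annotated features")

  # Merged feature cover on the circle.
  ord <- order(f$start)
  iv <- cbind(f$start[ord], f$end[ord])
  merged <- list()
  cur <- iv[1, ]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= cur[2]) cur[2] <- max(cur[2], iv[i, 2])
      else { merged[[length(merged) + 1]] <- cur; cur <- iv[i, ] }
    }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)

  # Gaps between consecutive merged blocks; the last gap wraps the circle.
  n <- nrow(m)
  gaps <- list()
  for (i in seq_len(n)) {
    gs <- m[i, 2]
    ge <- if (i < n) m[i + 1, 1] else m[1, 1] + L  # wrap: coordinates may exceed L
    if (ge > gs) gaps[[length(gaps) + 1]] <- c(gs, ge)
  }
  if (length(gaps) == 0) stop("features tile the whole chromosome: no gaps")

  # 5' trim: positions immediately upstream of a plus feature's start, and
  # immediately downstream of a minus feature's end.
  five_starts <- f$start[f$strand == "+"]   # trim [start - trim5, start)
  five_ends <- f$end[f$strand == "-"]       # trim [end, end + trim5)

  out <- list()
  for (g in gaps) {
    gs <- g[1]; ge <- g[2]
    # trim at the right edge if the following feature starts a plus 5' end
    if (any(five_starts %% L == ge %% L)) ge <- ge - trim5
    # trim at the left edge if the preceding feature ends a minus 5' end
    if (any(five_ends %% L == gs %% L)) gs <- gs + trim5
    if (ge - gs < min_len) next
    out[[length(out) + 1]] <- c(gs, ge)
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          half = integer(), sequence = character()))
  }

  # Split at L/2 and at L (the wrap point), then orient by half.
  half_b <- floor(L / 2)
  pieces <- list()
  for (g in out) {
    cuts <- sort(unique(c(g[1], g[2],
                          half_b[half_b > g[1] & half_b < g[2]],
                          L[L > g[1] & L < g[2]],
                          (L + half_b)[(L + half_b) > g[1] & (L + half_b) < g[2]])))
    for (i in seq_len(length(cuts) - 1)) {
      pieces[[length(pieces) + 1]] <- c(cuts[i], cuts[i + 1])
    }
  }
  purrr::map_dfr(pieces, function(p) {
    s <- p[1] %% L
    e <- s + (p[2] - p[1])
    half <- if (s < half_b) 1L else 2L
    seqs <- substr(genome$sequence, s + 1L, e)
    if (half == 2L) seqs <- revcomp(seqs)
    tibble::tibble(start = as.integer(s), end = as.integer(e),
                   half = half, sequence = seqs)
  })
}

# Sense-strand sequence of one feature row-set (fragments of a wrapped
# feature in `part` order), relative to the plus-strand `sequence`.
feature_sequence <- function(sequence, rows) {
  rows <- rows[order(rows$part), , drop = FALSE]
  s <- paste(substr(rep(sequence, nrow(rows)), rows$start + 1L, rows$end),
             collapse = "")
  if (rows$strand[1] == "-") s <- revcomp(s) else s
}
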