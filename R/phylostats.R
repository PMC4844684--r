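#' Phylogenetically independent contrasts of a genome-level trait
#'
#' Cross-genome statistics must account for shared ancestry: related
#' genomes are not independent observations.  Felsenstein's independent
#' contrasts transform *n* leaf values on a rooted tree with branch lengths
#' into *n - 1* standardised, mutually independent differences.  The
#' computation (post-order traversal with branch-length-weighted ancestral
#' values and pruning-augmented branches) is delegated to `ape::pic()`;
#' leaves missing from `values` (or non-finite) are pruned with a message.
#'
#' @param tree A rooted `phylo` tree with branch lengths, ideally
#'   ultrametric (checked to tolerance 1e-6; a warning is issued
#'   otherwise).  Its tip labels must cover the genomes analysed.
#' @param values Named numeric vector (names = tip labels) or a two-column
#'   data frame (`genome_id`, `value`).
#' @return Tibble `node` (internal node id in the pruned tree), `contrast`.
#' @export
independent_contrasts <- function(tree, values) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(values)) {
    values <- setNames(as.numeric(values[[2]]), as.character(values[[1]]))
  }
  values <- values[is.finite(values)]
  keep <- intersect(tree$tip.label, names(values))
  if (length(keep) < 2) stop("need at least two tips with finite values")
  if (length(keep) < length(tree$tip.label)) {
    message("pruning ", length(tree$tip.label) - length(keep),
            " tip(s) without finite values")
    tree <- ape::keep.tip(tree, keep)
  }
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warning("tree is not ultrametric to tolerance 1e-6")
  }
  zero_term <- which(tree$edge.length <= 0 &
                       tree$edge[, 2] <= length(tree$tip.label))
  if (length(zero_term)) {
    stop("zero-length terminal branch at node(s) ",
         paste(tree$edge[zero_term, 2], collapse = ", "))
  }
  pic <- ape::pic(values[tree$tip.label], tree, scaled = TRUE)
  tibble::tibble(node = as.integer(names(pic)), contrast = unname(pic))
}

#' Correlation between two contrast sets (through the origin)
#'
#' Contrasts have arbitrary sign and zero expectation, so their association
#' is measured by the correlation through the origin,
#' \eqn{r = \sum c_x c_y / \sqrt{\sum c_x^2 \sum c_y^2}}, with a two-sided
#' t-test on *n - 1* degrees of freedom.
#'
#' @param cx,cy Contrast tibbles from [independent_contrasts()] (matched by
#'   `node`) or plain numeric vectors of equal length.
#' @return Tibble `r`, `p`, `n`; `r` is `NA`-flagged when either set has
#'   zero variance.
#' @export
correlation_on_contrasts <- function(cx, cy) {
  x <- if (is.data.frame(cx)) cx$contrast else as.numeric(cx)
  y <- if (is.data.frame(cy)) cy$contrast else as.numeric(cy)
  if (is.data.frame(cx) && is.data.frame(cy)) {
    m <- dplyr::inner_join(cx, cy, by = "node", suffix = c("_x", "_y"))
    x <- m$contrast_x; y <- m$contrast_y
  }
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  sxx <- sum(x^2); syy <- sum(y^2)
  if (sxx == 0 || syy == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  }
  r <- sum(x * y) / sqrt(sxx * syy)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(n - 1) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  tibble::tibble(r = r, p = p, n = n)
}

#' Exact binomial sign test on selection coefficients
#'
#' Fraction of negative values and the exact two-sided binomial p-value
#' against the null of equal probability of either sign.
#'
#' @param values Numeric vector (non-finite values dropped).
#' @return Tibble `fraction_negative`, `n_negative`, `n`, `p`.
#' @export
sign_binomial_test <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  k <- sum(values < 0)
  bt <- binom.test(k, length(values), p = 0.5)
  tibble::tibble(fraction_negative = k / length(values), n_negative = k,
                 n = length(values), p = bt$p.value)
}

#' Lifestyle model: does intracellularity attenuate selection?
#'
#' Regresses contrasts of a scaled selection coefficient on contrasts of
#' lifestyle (intracellular vs free-living, coded 0/1 before contrast
#' computation), genomic GC content and genome length, with the full
#' interaction structure `S ~ INTRA * GC * L` fitted through the origin
#' (standard for contrasts).  Backward elimination then repeatedly drops
#' the least significant term (p > `alpha`) whose removal respects
#' marginality — no main effect leaves while one of its interactions
#' remains — until every surviving term is significant, and reports the
#' terms, their coefficients and the AIC trace (each reduction is expected
#' to lower the AIC; the trace lets the caller verify it did).
#'
#' @param data Tibble of contrasts with columns `s` (response), `intra`,
#'   `gc`, `len`.
#' @param alpha Significance threshold for "non-significant" (default 0.05).
#' @return List of class `lifestyle_fit`: `terms` (tibble of surviving
#'   terms with estimates and p-values; zero rows if everything was
#'   eliminated), `aic_trace`, `formula`, `model` (the final `lm`, `NULL`
#'   when empty).
#' @export
lifestyle_model <- function(data, alpha = 0.05) {
  stopifnot(all(c("s", "intra", "gc", "len") %in% names(data)))
  data <- data[complete.cases(data[, c("s", "intra", "gc", "len")]), ]
  terms_now <- c("intra", "gc", "len",
                 "intra:gc", "intra:len", "gc:len", "intra:gc:len")
  fit_terms <- function(tt) {
    fml <- if (length(tt)) {
      stats::reformulate(c("0", tt), response = "s")
    } else {
      s ~ 0
    }
    stats::lm(fml, data = data)
  }
  model <- fit_terms(terms_now)
  if (qr(model)$rank < length(terms_now)) {
    stop("collinear design: cannot fit the full interaction model")
  }
  aic_trace <- AIC(model)
  droppable <- function(tt) {
    vars <- strsplit(tt, ":", fixed = TRUE)
    vapply(seq_along(tt), function(i) {
      !any(vapply(seq_along(tt), function(j) {
        i != j && all(vars[[i]] %in% vars[[j]])
      }, logical(1)))
    }, logical(1))
  }
  repeat {
    if (!length(terms_now)) break
    sm <- summary(model)$coefficients
    pvals <- setNames(sm[, "Pr(>|t|)"], rownames(sm))
    ok <- droppable(terms_now)
    cand_p <- vapply(terms_now, function(t) {
      hit <- which(rownames(sm) == t | rownames(sm) == gsub(":", ":", t))
      if (length(hit)) pvals[hit[1]] else NA_real_
    }, numeric(1))
    cand_p[is.nan(cand_p)] <- 1  # zero-variance coefficient: uninformative
    cand_p[!ok] <- NA_real_
    if (all(is.na(cand_p)) || max(cand_p, na.rm = TRUE) <= alpha) break
    worst <- terms_now[which.max(cand_p)]
    terms_now <- setdiff(terms_now, worst)
    model <- fit_terms(terms_now)
    aic_trace <- c(aic_trace, AIC(model))
  }
  if (length(terms_now)) {
    sm <- summary(model)$coefficients
    terms_tbl <- tibble::tibble(term = rownames(sm),
                                estimate = sm[, "Estimate"],
                                p = sm[, "Pr(>|t|)"])
  } else {
    terms_tbl <- tibble::tibble(term = character(), estimate = numeric(),
                                p = numeric())
    model <- NULL
  }
  structure(list(terms = terms_tbl, aic_trace = aic_trace,
                 formula = if (length(terms_now))
                   paste("s ~ 0 +", paste(terms_now, collapse = " + "))
                 else "s ~ 0",
                 model = model),
            class = "lifestyle_fit")
}

#' @export
print.lifestyle_fit <- function(x, ...) {
  cat("<lifestyle_fit>", x$formula, "\n")
  print(x$terms)
  invisible(x)
}
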