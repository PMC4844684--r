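test_that("tAI is the geometric mean of relative adaptiveness values", {
  # One dominant anticodon (AGC reads GCT) and one minor (TTT reads AAA):
  # W(GCT) = 4, W(AAA) = 1, so w = 1 and 0.25 and a balanced two-codon gene
  # scores sqrt(0.25) = 0.5.
  pool <- tibble::tibble(anticodon = c("AGC", "TTT"), copies = c(4, 1))
  genes <- tibble::tibble(gene_id = "g1", codon = c("GCT", "AAA"), n = c(1, 1))
  expect_equal(tai(genes, pool)$tai, 0.5)
  # a gene made only of the best-adapted codon scores 1
  best <- tibble::tibble(gene_id = "g2", codon = "GCT", n = 7)
  expect_equal(tai(best, pool)$tai, 1)
  # scale invariance in copy numbers
  pool10 <- dplyr::mutate(pool, copies = copies * 10)
  expect_equal(tai(genes, pool10)$tai, tai(genes, pool)$tai)
  expect_error(tai(genes, tibble::tibble(anticodon = "AGC", copies = 0)),
               "empty")
})

test_that("codon multiplicities weight the geometric mean", {
  pool <- tibble::tibble(anticodon = c("AGC", "TTT"), copies = c(4, 1))
  genes <- tibble::tibble(gene_id = "g1", codon = c("GCT", "AAA"), n = c(3, 1))
  expect_equal(tai(genes, pool)$tai, (1^3 * 0.25)^(1 / 4))
})

test_that("Wright's Nc spans its theoretical range", {
  fams <- skewsel:::.codon_families()
  one_per_family <- purrr::map_dfr(names(fams), function(a) {
    tibble::tibble(gene_id = "g1", codon = fams[[a]][1], n = 50)
  })
  expect_equal(effective_number_of_codons(one_per_family)$nc, 20)
  uniform <- purrr::map_dfr(names(fams), function(a) {
    tibble::tibble(gene_id = "g2", codon = fams[[a]], n = 600)
  })
  expect_gt(effective_number_of_codons(uniform)$nc, 59.5)
})

test_that("Nc matches a hand-computed two-family case", {
  # Lys 3:1 -> F = 0.5; Phe 2:2 -> F = 1/3; F2 = 5/12, all fallbacks 5/12:
  # Nc = 2 + 18 / (5/12) = 45.2
  g <- tibble::tibble(gene_id = "g1",
                      codon = c("AAA", "AAG", "TTT", "TTC"),
                      n = c(3, 1, 2, 2))
  expect_equal(effective_number_of_codons(g)$nc, 2 + 18 * 12 / 5,
               tolerance = 1e-9)
})

test_that("expression bins are equal-sized and order-invariant", {
  pool <- tibble::tibble(anticodon = c("AGC", "GGC", "TGC", "CGC"),
                         copies = c(8, 4, 2, 1))
  set.seed(51)
  genes <- purrr::map_dfr(1:10, function(i) {
    n_best <- i  # increasing adaptation with index
    tibble::tibble(gene_id = sprintf("g%02d", i),
                   replication_strand = "leading",
                   codon = c("GCT", "GCA"), n = c(n_best, 11 - n_best))
  })
  bins <- bin_by_expression(genes, pool, k = 5)
  expect_equal(nrow(bins), 5L)
  expect_true(all(bins$n_genes == 2))
  shuffled <- genes[sample(nrow(genes)), ]
  bins2 <- bin_by_expression(shuffled, pool, k = 5)
  expect_equal(dplyr::arrange(bins2, bin), dplyr::arrange(bins, bin))
  expect_error(bin_by_expression(genes[1:6, ], pool, k = 5), "fewer than k")
})

test_that("planted usage gradients yield the planted preferred codon", {
  set.seed(52)
  n_genes <- 60
  nc <- tibble::tibble(gene_id = sprintf("g%02d", 1:n_genes),
                       nc = seq(21, 60, length.out = n_genes))
  genes <- purrr::map_dfr(1:n_genes, function(i) {
    # low-Nc (biased) genes use GCT heavily; high-Nc genes use the family
    # uniformly
    w_gct <- 30 - round(25 * (i - 1) / (n_genes - 1))
    tibble::tibble(gene_id = sprintf("g%02d", i),
                   codon = c("GCT", "GCA", "GCC", "GCG"),
                   n = c(w_gct, 5, 5, 5))
  })
  res <- suppressWarnings(preferred_codons(genes, nc = nc))
  ala <- res$preferred[res$preferred$family == "GC", ]
  expect_equal(ala$codon, "GCT")
  # identical usage in every gene: nothing can be preferred
  flat <- purrr::map_dfr(1:n_genes, function(i) {
    tibble::tibble(gene_id = sprintf("g%02d", i),
                   codon = c("GCT", "GCA"), n = c(3, 3))
  })
  res2 <- suppressWarnings(preferred_codons(flat, nc = nc))
  expect_equal(nrow(res2$preferred), 0L)
  # constant Nc: correlations undefined
  nc_const <- dplyr::mutate(nc, nc = 45)
  expect_warning(res3 <- preferred_codons(genes, nc = nc_const), "constant")
  expect_equal(nrow(res3$preferred), 0L)
})
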