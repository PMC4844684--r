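test_that("contrasts reproduce the textbook two-taxon case", {
  tree <- ape::read.tree(text = "(a:1,b:1);")
  out <- independent_contrasts(tree, c(a = 3, b = 1))
  expect_equal(nrow(out), 1L)
  expect_equal(abs(out$contrast), 2 / sqrt(2), tolerance = 1e-12)
})

test_that("a constant trait has all-zero contrasts", {
  set.seed(61)
  tree <- ape::rcoal(8)
  vals <- setNames(rep(3.7, 8), tree$tip.label)
  out <- independent_contrasts(tree, vals)
  expect_equal(out$contrast, rep(0, 7))
})

test_that("contrast regression equals a brute-force GLS computation", {
  # On any tree, the slope of y on x from contrasts through the origin must
  # equal the GLS slope under the Brownian covariance matrix.
  set.seed(62)
  for (rep in 1:3) {
    tree <- ape::rcoal(6)
    V <- ape::vcv(tree)
    x <- setNames(rnorm(6), tree$tip.label)
    y <- setNames(2 * x + rnorm(6, sd = 0.5), tree$tip.label)
    cx <- independent_contrasts(tree, x)$contrast
    cy <- independent_contrasts(tree, y)$contrast
    slope_pic <- sum(cx * cy) / sum(cx^2)
    Vi <- solve(V[names(x), names(x)])
    X <- cbind(1, x)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    expect_equal(slope_pic, unname(beta[2, 1]), tolerance = 1e-10)
  }
})

test_that("missing tips are pruned before contrast computation", {
  set.seed(63)
  tree <- ape::rcoal(6)
  vals <- setNames(rnorm(6), tree$tip.label)
  vals[1] <- NA
  expect_message(out <- independent_contrasts(tree, vals), "pruning 1")
  expect_equal(nrow(out), 4L)
})

test_that("contrast correlation handles exact and degenerate cases", {
  cx <- c(1, -2, 0.5, 3)
  expect_equal(correlation_on_contrasts(cx, 2 * cx)$r, 1)
  cy <- c(2, 1, 0, 0)  # orthogonal to cx: 1*2 - 2*1 + 0 + 0 = 0
  expect_equal(correlation_on_contrasts(cx, cy)$r, 0, tolerance = 1e-12)
  expect_true(is.na(correlation_on_contrasts(cx, rep(0, 4))$r))
})

test_that("contrast correlation recovers a known Brownian co-evolution", {
  set.seed(64)
  rs <- vapply(1:5, function(i) {
    tree <- ape::rcoal(200)
    V <- ape::vcv(tree)
    Cv <- chol(V)
    z1 <- rnorm(200); z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(200)
    x <- setNames(drop(t(Cv) %*% z1), tree$tip.label)
    y <- setNames(drop(t(Cv) %*% z2), tree$tip.label)
    correlation_on_contrasts(independent_contrasts(tree, x),
                             independent_contrasts(tree, y))$r
  }, numeric(1))
  expect_lt(abs(median(rs) - 0.8), 0.1)
})

test_that("the sign test matches exact binomial enumeration", {
  expect_equal(sign_binomial_test(c(rep(-1, 8), 1, 2))$p, 0.109375)
  expect_equal(sign_binomial_test(c(rep(-1, 5), rep(1, 5)))$p, 1)
  out <- sign_binomial_test(rep(1, 10))
  expect_equal(out$p, 2 * (1 / 2)^10)
  expect_equal(out$fraction_negative, 0)
  expect_error(sign_binomial_test(numeric(0)), "no finite")
})

test_that("lifestyle model keeps a planted attenuation term", {
  set.seed(69)
  n <- 250
  d <- tibble::tibble(intra = rnorm(n), gc = rnorm(n), len = rnorm(n))
  d$s <- 0.8 * d$intra - 1.5 * d$gc + rnorm(n, sd = 0.5)
  fit <- lifestyle_model(d)
  expect_true(all(c("intra", "gc") %in% fit$terms$term))
  expect_false("intra:gc:len" %in% fit$terms$term)
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_gt(est["intra"], 0)  # attenuating direction for a negative S
  expect_equal(unname(est["gc"]), -1.5, tolerance = 0.15)
})

test_that("pure noise eliminates every lifestyle term", {
  set.seed(66)
  n <- 300
  d <- tibble::tibble(intra = rnorm(n), gc = rnorm(n), len = rnorm(n),
                      s = rnorm(n))
  fit <- lifestyle_model(d)
  expect_equal(nrow(fit$terms), 0L)
  expect_equal(fit$formula, "s ~ 0")
})

test_that("an exact linear response keeps only its generating term", {
  set.seed(67)
  n <- 200
  d <- tibble::tibble(intra = rnorm(n), gc = rnorm(n), len = rnorm(n))
  d$s <- 2 * d$gc + rnorm(n, sd = 1e-4)
  fit <- lifestyle_model(d)
  expect_equal(fit$terms$term, "gc")
  expect_equal(fit$terms$estimate, 2, tolerance = 1e-3)
})
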