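test_that("forward skew reproduces closed-form reference values", {
  expect_equal(forward_skew(0, 0, "leading"), 0)
  expect_equal(forward_skew(0, 0, "lagging"), 0)
  expect_equal(forward_skew(0.2, 0, "leading"), 0.2)
  expect_equal(forward_skew(0.2, 0, "lagging"), -0.2)
  # kappa = 1.5, e^S = 0.6065307
  expect_equal(forward_skew(0.2, -0.5, "leading"), -0.04723228, tolerance = 1e-6)
  expect_equal(forward_skew(0.2, -0.5, "lagging"), -0.42414258, tolerance = 1e-6)
  expect_equal(equilibrium_prob(0, 0, "leading"), 0.5)
  expect_equal(equilibrium_prob(0.2, -0.5, "leading"), 0.47638386,
               tolerance = 1e-6)
  # selection dominates in the strong limit
  expect_gt(equilibrium_prob(0.2, 20, "leading"), 1 - 1e-6)
})

test_that("inversions are exact over the full parameter grid", {
  grid <- expand.grid(mu = seq(-0.9, 0.9, by = 0.1),
                      s = seq(-5, 5, by = 0.5))
  gl <- forward_skew(grid$mu, grid$s, "leading")
  gg <- forward_skew(grid$mu, grid$s, "lagging")
  expect_true(all(abs(gl) < 1) && all(abs(gg) < 1))
  expect_equal(invert_s(gl, gg), grid$s, tolerance = 1e-9)
  expect_equal(invert_mu(gl, gg), grid$mu, tolerance = 1e-9)
  expect_equal(s_from_single_strand(gl, grid$mu, "leading"), grid$s,
               tolerance = 1e-9)
  expect_equal(s_from_single_strand(gg, grid$mu, "lagging"), grid$s,
               tolerance = 1e-9)
})

test_that("forward model is antisymmetric and monotone", {
  mu <- seq(-0.8, 0.8, by = 0.2)
  s <- seq(-3, 3, by = 0.75)
  for (m in mu) {
    # relabelling the basepair (swap expensive/cheap) negates both mu and S
    # and flips the skew on either strand
    expect_equal(forward_skew(-m, -s, "leading"),
                 -forward_skew(m, s, "leading"))
    expect_equal(forward_skew(-m, -s, "lagging"),
                 -forward_skew(m, s, "lagging"))
    # the strands differ only by the sign with which selection combines
    # with the mutation-rate ratio
    expect_equal(forward_skew(m, s, "leading"),
                 -forward_skew(m, -s, "lagging"))
    expect_true(all(diff(forward_skew(m, s, "leading")) > 0))
  }
  for (ss in s) {
    expect_true(all(diff(forward_skew(mu, ss, "leading")) > 0))
  }
})

test_that("boundary skews give flagged NA estimates, not infinities", {
  expect_true(is.na(invert_s(1, 0.2)))
  expect_true(is.na(invert_mu(-1, 0.2)))
  expect_true(is.na(s_from_single_strand(1, 0.2, "leading")))
})

test_that("Monte-Carlo equilibrium draws recover the generating parameters", {
  set.seed(101)
  n <- 1e5
  mu <- 0.2; s <- -0.5
  p_lead <- equilibrium_prob(mu, s, "leading")
  p_lag <- equilibrium_prob(mu, s, "lagging")
  g_lead <- 2 * rbinom(1, n, p_lead) / n - 1
  g_lag <- 2 * rbinom(1, n, p_lag) / n - 1
  se_g <- function(p) 2 * sqrt(p * (1 - p) / n)
  # delta method: dS/dgamma = 1/(1 - gamma^2) per strand
  tl <- forward_skew(mu, s, "leading"); tg <- forward_skew(mu, s, "lagging")
  se_s <- sqrt((se_g(p_lead) / (1 - tl^2))^2 + (se_g(p_lag) / (1 - tg^2))^2)
  expect_lt(abs(invert_s(g_lead, g_lag) - s), 3 * se_s)
  se_mu <- 0.5 * se_s * (1 - mu^2)  # same quadratic form scaled by d(mu)/d(logkappa)
  expect_lt(abs(invert_mu(g_lead, g_lag) - mu), 3 * se_mu)
})

test_that("tau is the least-squares slope through the origin", {
  d <- tibble::tibble(mu_io = c(0.1, -0.2, 0.05), mu_4s = 1.5 * mu_io)
  fit <- estimate_tau(d)
  expect_equal(fit$tau, 1.5)
  expect_equal(fit$ci_hi - fit$ci_lo, 0)

  d2 <- tibble::tibble(mu_io = c(0.1, 0.2, -0.1), mu_4s = c(0.15, 0.35, -0.16))
  expect_equal(estimate_tau(d2)$tau, 0.101 / 0.06, tolerance = 1e-12)

  one <- estimate_tau(tibble::tibble(mu_io = 0.2, mu_4s = 0.3))
  expect_equal(one$tau, 1.5)
  expect_true(is.na(one$ci_lo))

  expect_error(estimate_tau(tibble::tibble(mu_io = c(0, 0), mu_4s = c(0, 0))),
               "undefined slope")
})

test_that("f is recovered exactly from noise-free model skews", {
  tau <- 1.5; f_true <- 0.5; s_tot <- 0.4
  mu_io <- seq(0.02, 0.12, length.out = 8)
  d <- tibble::tibble(
    mu_io = mu_io,
    gamma_ns_lead = f_true * forward_skew(tau * mu_io, s_tot, "leading"),
    gamma_ns_lag = f_true * forward_skew(tau * mu_io, s_tot, "lagging"))
  fit <- estimate_f(d, tau = tau, boot = 0)
  expect_equal(fit$f, f_true, tolerance = 1e-4)
  expect_equal(fit$n_excluded, 0L)
})

test_that("selection decomposes additively across channels", {
  tau <- 1; mu_io <- 0.1
  skews <- exact_skew_table(mu_io, tau, s_rna = -0.3, s_total = 0.4, f = 1)
  mu_prime <- tibble::tibble(genome_id = "g01", pair = c("AT", "GC"),
                             mu_prime = tau * mu_io)
  out <- decompose_selection(skews, mu_prime, f = 1)
  for (st in c("leading", "lagging", "mean")) {
    sub <- out[out$strand == st, ]
    expect_equal(sub$value[sub$quantity == "s_rna"], c(-0.3, -0.3),
                 tolerance = 1e-9)
    expect_equal(sub$value[sub$quantity == "s_aa"], c(0.7, 0.7),
                 tolerance = 1e-9)
  }
})

test_that("the full fit recovers noise-free global parameters", {
  mu_io <- seq(-0.05, 0.15, length.out = 6)
  mu_io <- mu_io[mu_io != 0]
  skews <- exact_skew_table(mu_io, tau = 1.4, s_rna = -0.25, s_total = 0.55,
                            f = 0.4)
  fit <- fit_skew_model(skews, boot = 0)
  expect_s3_class(fit, "skew_fit")
  g <- glance(fit)
  expect_equal(g$tau, c(1.4, 1.4), tolerance = 1e-6)
  expect_equal(g$f, c(0.4, 0.4), tolerance = 1e-3)
  p <- tidy(fit)
  s_aa <- p$value[p$quantity == "s_aa" & p$strand == "mean"]
  expect_equal(s_aa, rep(0.8, length(s_aa)), tolerance = 1e-3)
  expect_equal(nrow(fit$excluded), 0L)
})

test_that("genomes with boundary skews are excluded from global fits", {
  mu_io <- c(0.05, 0.08, 0.1, 0.12)
  skews <- exact_skew_table(mu_io, tau = 1.5, s_rna = -0.3, s_total = 0.5,
                            f = 0.35)
  bad <- skews$genome_id == "g01" & skews$site_class == "4s" &
    skews$strand == "leading" & skews$pair == "AT"
  skews$skew[bad] <- 1
  fit <- fit_skew_model(skews, boot = 0)
  expect_equal(nrow(fit$excluded), 1L)
  expect_equal(fit$excluded$genome_id, "g01")
  expect_equal(fit$excluded$pair, "AT")
})
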