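#' Equilibrium skew predicted by the mutation-selection-drift model
#'
#' At a two-state site (A/T or G/C basepair) whose population is essentially
#' always fixed (mutation rates well below \eqn{1/N_e}), the stationary
#' probability of each state follows from balancing the two fixation fluxes,
#' giving a closed-form skew.  Writing the mutational bias as
#' \eqn{\mu = (v - u)/(v + u)} (with \eqn{u} the rate from the cheap to the
#' expensive base on the leading strand and \eqn{v} the reverse rate) and
#' \eqn{\kappa = (1 + \mu)/(1 - \mu) = v/u}, the expected skew towards the
#' first-listed (more expensive) base — A over T, G over C — is
#' \deqn{\gamma_{lead} = \frac{\kappa e^S - 1}{\kappa e^S + 1}, \qquad
#'       \gamma_{lag} = \frac{e^S/\kappa - 1}{e^S/\kappa + 1},}
#' where \eqn{S = 2 N_e s} is the scaled selection coefficient favouring the
#' expensive base (so the paper-level expectation is \eqn{S_{RNA} < 0}:
#' selection prefers the cheaper T/U and C in transcripts).  On the lagging
#' strand the roles of \eqn{u} and \eqn{v} swap.  At \eqn{S = 0} the skew
#' reduces to \eqn{\mu} on the leading and \eqn{-\mu} on the lagging strand.
#'
#' @param mu Mutational bias \eqn{\mu \in (-1, 1)}; vectorised.
#' @param s_coef Scaled selection coefficient \eqn{S = 2 N_e s}; vectorised.
#' @param strand `"leading"` or `"lagging"` (recycled).
#' @return Skew values strictly inside \eqn{(-1, 1)}.
#' @export
#' @examples
#' forward_skew(0.2, 0, "leading")   # 0.2: mutation bias alone
#' forward_skew(0.2, -0.5, "lagging")
forward_skew <- function(mu, s_coef, strand = c("leading", "lagging")) {
  strand <- .check_strand(strand, length(mu), length(s_coef))
  stopifnot(all(abs(mu) < 1), all(is.finite(s_coef)))
  kappa <- (1 + mu) / (1 - mu)
  k <- ifelse(strand == "leading", kappa, 1 / kappa)
  x <- k * exp(s_coef)
  (x - 1) / (x + 1)
}

#' Stationary probability of the expensive allele at a site
#'
#' The probability that a two-state site is fixed for the first-listed
#' (expensive) nucleotide, \eqn{P = (1 + \gamma)/2} with \eqn{\gamma} from
#' [forward_skew()]; equivalently \eqn{\kappa e^S / (1 + \kappa e^S)} on the
#' leading strand.
#'
#' @inheritParams forward_skew
#' @return Probabilities in \eqn{(0, 1)}.
#' @export
equilibrium_prob <- function(mu, s_coef, strand = c("leading", "lagging")) {
  (1 + forward_skew(mu, s_coef, strand)) / 2
}

#' Invert the skew model: selection coefficient from a strand pair of skews
#'
#' Combining the leading- and lagging-strand model equations eliminates the
#' mutation-rate ratio and yields the exact inversion
#' \deqn{S = \tfrac{1}{2}\,\ln\frac{(1+\gamma_{lead})(1+\gamma_{lag})}
#'       {(1-\gamma_{lead})(1-\gamma_{lag})}.}
#'
#' @param gamma_lead,gamma_lag Observed skews on the leading and lagging
#'   strand, each in \eqn{(-1, 1)}; boundary or missing skews give `NA`
#'   (flagged estimation failure), never an infinite value.
#' @return Scaled selection coefficients.
#' @export
invert_s <- function(gamma_lead, gamma_lag) {
  out <- 0.5 * log((1 + gamma_lead) * (1 + gamma_lag) /
                     ((1 - gamma_lead) * (1 - gamma_lag)))
  out[!is.finite(out) | abs(gamma_lead) >= 1 | abs(gamma_lag) >= 1] <- NA_real_
  out
}

#' Invert the skew model: mutational bias from a strand pair of skews
#'
#' Eliminating \eqn{S} instead gives
#' \deqn{\kappa^2 = \frac{(1+\gamma_{lead})(1-\gamma_{lag})}
#'       {(1-\gamma_{lead})(1+\gamma_{lag})}, \qquad
#'       \mu = \frac{\kappa - 1}{\kappa + 1}.}
#' Applied to fourfold-synonymous skews this is the amplified mutational
#' bias of transcribed sequence, \eqn{\mu^{4s}}.
#'
#' @inheritParams invert_s
#' @return Mutational bias estimates in \eqn{(-1, 1)} (`NA` on boundary input).
#' @export
invert_mu <- function(gamma_lead, gamma_lag) {
  k2 <- (1 + gamma_lead) * (1 - gamma_lag) /
    ((1 - gamma_lead) * (1 + gamma_lag))
  kappa <- sqrt(k2)
  out <- (kappa - 1) / (kappa + 1)
  out[!is.finite(out) | abs(gamma_lead) >= 1 | abs(gamma_lag) >= 1] <- NA_real_
  out
}

#' Selection coefficient from a single strand's skew and a known bias
#'
#' When the mutational bias is known (e.g. approximated as \eqn{\tau \mu^{io}}
#' from interoperonic regions), each strand yields its own estimate:
#' \deqn{S_{lead} = \ln\frac{1+\gamma}{1-\gamma} - \ln\kappa, \qquad
#'       S_{lag} = \ln\frac{1+\gamma}{1-\gamma} + \ln\kappa.}
#'
#' @param gamma Observed skew in \eqn{(-1, 1)}.
#' @param mu Mutational bias at these sites, \eqn{|\mu| < 1}.
#' @inheritParams forward_skew
#' @return Scaled selection coefficients (`NA` on boundary skews).
#' @export
s_from_single_strand <- function(gamma, mu, strand = c("leading", "lagging")) {
  strand <- .check_strand(strand, length(gamma), length(mu))
  lk <- log((1 + mu) / (1 - mu))
  out <- log((1 + gamma) / (1 - gamma)) + ifelse(strand == "leading", -lk, lk)
  out[!is.finite(out) | abs(gamma) >= 1 | abs(mu) >= 1] <- NA_real_
  out
}

.check_strand <- function(strand, ...) {
  strand <- match.arg(strand, c("leading", "lagging"), several.ok = TRUE)
  n <- max(..., length(strand))
  rep_len(strand, n)
}

#' Global amplification factor by regression through the origin
#'
#' Transcription amplifies the replication mutational bias by a
#' species-independent factor \eqn{\tau}, estimated as the least-squares
#' slope through the origin of \eqn{\mu^{4s}} on \eqn{\mu^{io}} across
#' genomes, \eqn{\hat\tau = \sum \mu^{io}\mu^{4s} / \sum (\mu^{io})^2},
#' with a normal-theory 95% confidence interval from the slope's standard
#' error (df = n - 1).
#'
#' @param data Tibble with columns `mu_io`, `mu_4s` and optionally `pair`;
#'   the fit is done separately per `pair` when present.  Rows with missing
#'   values are dropped.
#' @param conf_level Confidence level for the interval.
#' @return Tibble with columns `pair` (if supplied), `tau`, `se`, `ci_lo`,
#'   `ci_hi`, `n_genomes`.  The CI is `NA` with fewer than 2 genomes.
#' @export
estimate_tau <- function(data, conf_level = 0.95) {
  grp <- if ("pair" %in% names(data)) "pair" else character()
  fit_one <- function(d) {
    d <- d[is.finite(d$mu_io) & is.finite(d$mu_4s), , drop = FALSE]
    n <- nrow(d)
    if (n < 1 || all(d$mu_io == 0)) stop("undefined slope: no usable mutational bias")
    tau <- sum(d$mu_io * d$mu_4s) / sum(d$mu_io^2)
    if (n >= 2) {
      resid <- d$mu_4s - tau * d$mu_io
      se <- sqrt(sum(resid^2) / (n - 1) / sum(d$mu_io^2))
      tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
      ci <- tau + c(-1, 1) * tcrit * se
    } else {
      se <- NA_real_; ci <- c(NA_real_, NA_real_)
    }
    tibble::tibble(tau = tau, se = se, ci_lo = ci[1], ci_hi = ci[2],
                   n_genomes = n)
  }
  if (length(grp)) {
    dplyr::group_modify(dplyr::group_by(data, .data$pair), ~fit_one(.x)) |>
      dplyr::ungroup()
  } else {
    fit_one(data)
  }
}

#' Free-site fraction by agreement of mutational-bias estimates
#'
#' A fraction \eqn{f} of nonsynonymous positions is taken to evolve
#' effectively neutrally while the rest are frozen by selection on protein
#' function and contribute no skew, so the pooled NS skew is the model skew
#' scaled by \eqn{f}.  The global \eqn{f} (one per basepair type) is the
#' value that makes the NS-derived mutational bias agree best with the
#' 4s-level bias \eqn{\tau\mu^{io}}: it minimises
#' \deqn{\sum_g \left[\hat\mu\!\left(\gamma^{NS}_{lead}/f,\;
#'   \gamma^{NS}_{lag}/f\right) - \tau\,\mu^{io}_g\right]^2}
#' over \eqn{f \in (0.01, 1]} (bounded scalar minimisation, tolerance 1e-6).
#' Genomes whose rescaled skew would leave the model domain
#' (\eqn{|\gamma|/f \ge 1}) are excluded from that candidate's objective.
#' The confidence interval is a seeded bootstrap over genomes.
#'
#' @param data Tibble with columns `gamma_ns_lead`, `gamma_ns_lag`, `mu_io`
#'   and optionally `pair` (fit separately per pair).
#' @param tau Global amplification factor; a single value, or a tibble from
#'   [estimate_tau()] with a `pair` column when `data` has pairs.
#' @param boot Number of bootstrap resamples for the CI (0 to skip).
#' @param conf_level Confidence level.
#' @param lower Lower edge of the search interval.
#' @return Tibble with `pair` (if supplied), `f`, `ci_lo`, `ci_hi`,
#'   `n_genomes`, `n_excluded` (genomes outside the model domain at the
#'   optimum).
#' @export
estimate_f <- function(data, tau, boot = 1000, conf_level = 0.95,
                       lower = 0.01) {
  fit_one <- function(d, tau1) {
    d <- d[is.finite(d$gamma_ns_lead) & is.finite(d$gamma_ns_lag) &
             is.finite(d$mu_io), , drop = FALSE]
    if (nrow(d) == 0) stop("no usable genomes for f estimation")
    target <- tau1 * d$mu_io
    obj <- function(f, rows = seq_len(nrow(d))) {
      gl <- d$gamma_ns_lead[rows] / f
      gg <- d$gamma_ns_lag[rows] / f
      ok <- abs(gl) < 1 & abs(gg) < 1
      if (!any(ok)) return(Inf)
      sum((invert_mu(gl[ok], gg[ok]) - target[rows][ok])^2)
    }
    opt <- optimize(obj, c(lower, 1), tol = 1e-6)
    f_hat <- opt$minimum
    n_excl <- sum(abs(d$gamma_ns_lead / f_hat) >= 1 |
                    abs(d$gamma_ns_lag / f_hat) >= 1)
    ci <- c(NA_real_, NA_real_)
    if (boot > 0 && nrow(d) >= 3) {
      bs <- vapply(seq_len(boot), function(b) {
        rows <- sample.int(nrow(d), nrow(d), replace = TRUE)
        optimize(function(f) obj(f, rows), c(lower, 1), tol = 1e-6)$minimum
      }, numeric(1))
      alpha <- (1 - conf_level) / 2
      ci <- unname(quantile(bs, c(alpha, 1 - alpha)))
    }
    tibble::tibble(f = f_hat, ci_lo = ci[1], ci_hi = ci[2],
                   n_genomes = nrow(d), n_excluded = n_excl)
  }
  if ("pair" %in% names(data)) {
    taus <- if (is.data.frame(tau)) setNames(tau$tau, tau$pair) else
      setNames(rep_len(tau, 2), c("AT", "GC"))
    dplyr::group_modify(dplyr::group_by(data, .data$pair),
                        ~fit_one(.x, taus[[.y$pair]])) |>
      dplyr::ungroup()
  } else {
    fit_one(data, tau)
  }
}

#' Decompose selection into transcription and translation components
#'
#' Selection pressures from transcription (nucleotide cost, \eqn{S_{RNA}})
#' and translation (amino-acid cost, \eqn{S_{AA}}) are additive on the
#' scaled-coefficient scale: \eqn{S = S_{RNA}} at fourfold-synonymous sites
#' and \eqn{S = S_{RNA} + S_{AA}} at nonsynonymous sites.  Per genome,
#' strand and basepair type this function computes
#' \eqn{S_{RNA} = S(\gamma^{4s}, \mu')}, \eqn{S_{tot} = S(\gamma^{NS}/f, \mu')}
#' via [s_from_single_strand()], and \eqn{S_{AA} = S_{tot} - S_{RNA}},
#' with \eqn{\mu'} the amplified mutational bias at transcribed sites
#' (\eqn{\tau\mu^{io}} in global mode, or the genome's own
#' \eqn{\hat\mu^{4s}} in per-genome mode).  A strand-mean (arithmetic) of
#' each quantity is appended.
#'
#' @param skews Observed skews ([observed_skews()] layout) for one or more
#'   genomes, containing `4s` and `ns` rows for both strands.
#' @param mu_prime Tibble `genome_id`, `pair`, `mu_prime` with the amplified
#'   mutational bias to use at transcribed sites.
#' @param f Free-site fraction: single value or tibble with `pair`, `f`.
#' @return Tidy tibble `genome_id`, `pair`, `quantity` (`"s_rna"`,
#'   `"s_total"`, `"s_aa"`), `strand` (`"leading"`, `"lagging"`, `"mean"`),
#'   `value`, `flag`.
#' @export
decompose_selection <- function(skews, mu_prime, f) {
  f_tbl <- if (is.data.frame(f)) f else
    tibble::tibble(pair = c("AT", "GC"), f = rep_len(f, 2))
  wide <- skews |>
    dplyr::filter(.data$site_class %in% c("4s", "ns")) |>
    dplyr::select("genome_id", "site_class", "strand", "pair", "skew") |>
    tidyr::pivot_wider(names_from = c("site_class", "strand"),
                       values_from = "skew") |>
    dplyr::left_join(mu_prime, by = c("genome_id", "pair")) |>
    dplyr::left_join(f_tbl, by = "pair")
  per_strand <- purrr::map_dfr(c("leading", "lagging"), function(st) {
    g4 <- wide[[paste0("4s_", st)]]
    gns <- wide[[paste0("ns_", st)]] / wide$f
    gns[abs(gns) >= 1] <- NA_real_  # outside model domain: flagged non-estimable
    s_rna <- s_from_single_strand(g4, wide$mu_prime, st)
    s_tot <- s_from_single_strand(gns, wide$mu_prime, st)
    tibble::tibble(genome_id = rep(wide$genome_id, 3),
                   pair = rep(wide$pair, 3),
                   quantity = rep(c("s_rna", "s_total", "s_aa"),
                                  each = nrow(wide)),
                   strand = st,
                   value = c(s_rna, s_tot, s_tot - s_rna))
  })
  means <- per_strand |>
    tidyr::pivot_wider(names_from = "strand", values_from = "value") |>
    dplyr::mutate(strand = "mean", value = (.data$leading + .data$lagging) / 2,
                  leading = NULL, lagging = NULL)
  out <- dplyr::bind_rows(per_strand, means)
  dplyr::mutate(out, flag = dplyr::if_else(is.finite(.data$value),
                                           "ok", "flagged"))
}

#' Fit the full mutation-selection-drift skew model across genomes
#'
#' End-to-end estimation from observed skews: per-genome mutational bias
#' \eqn{\mu^{io}} (the interoperonic skew itself) and \eqn{\mu^{4s}} (via
#' [invert_mu()] on fourfold-site skews); global amplification \eqn{\tau}
#' per basepair type ([estimate_tau()]); global free-site fraction \eqn{f}
#' ([estimate_f()]); and the per-genome selection decomposition
#' ([decompose_selection()]).  Genomes with undefined or boundary skews in
#' any required cell are excluded from the global fits and flagged.
#'
#' @param skews Observed skews for >= 1 genome ([observed_skews()] layout;
#'   global mode needs >= 3 genomes).
#' @param mode `"fit-global"` (fit tau and f), `"fixed"` (use supplied
#'   `tau`/`f`), or `"per-genome"` (use each genome's own \eqn{\hat\mu^{4s}}
#'   as \eqn{\mu'}, as in the lifestyle analysis; `f` must be supplied).
#' @param tau,f Fixed values (single numbers or per-pair tibbles) for modes
#'   that do not fit them.
#' @param boot Bootstrap resamples for the f confidence interval.
#' @return An object of class `skew_fit`: list with `params` (tidy per-genome
#'   estimates), `global` (tau/f with CIs per pair), `mode`, and `excluded`
#'   (genome/pair combinations left out of global fits).  [tidy.skew_fit()]
#'   and [glance.skew_fit()] return the tibbles.
#' @export
fit_skew_model <- function(skews, mode = c("fit-global", "fixed", "per-genome"),
                           tau = NULL, f = NULL, boot = 1000) {
  mode <- match.arg(mode)
  need <- skews |>
    dplyr::filter(.data$site_class %in% c("io", "4s", "ns")) |>
    dplyr::mutate(cell = dplyr::if_else(.data$site_class == "io", "io",
                                        paste0(.data$site_class, "_", .data$strand)))
  wide <- need |>
    dplyr::select("genome_id", "pair", "cell", "skew") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "skew")
  wide$mu_io <- wide$io
  wide$mu_4s <- invert_mu(wide$`4s_leading`, wide$`4s_lagging`)
  usable <- stats::complete.cases(
    wide[, c("mu_io", "mu_4s", "ns_leading", "ns_lagging")]) &
    abs(wide$mu_io) < 1
  excluded <- wide[!usable, c("genome_id", "pair")]

  if (mode == "fit-global") {
    if (sum(usable) < 3) stop("global fit needs >= 3 usable genomes")
    tau_tbl <- estimate_tau(wide[usable, c("pair", "mu_io", "mu_4s")])
    f_tbl <- estimate_f(
      dplyr::transmute(wide[usable, ], .data$pair,
                       gamma_ns_lead = .data$ns_leading,
                       gamma_ns_lag = .data$ns_lagging, .data$mu_io),
      tau = tau_tbl, boot = boot)
  } else {
    if (is.null(f) || (mode == "fixed" && is.null(tau))) {
      stop("mode '", mode, "' needs tau/f supplied")
    }
    tau_tbl <- if (is.data.frame(tau)) tau else
      tibble::tibble(pair = c("AT", "GC"), tau = rep_len(tau %||% NA_real_, 2),
                     se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     n_genomes = NA_integer_)
    f_tbl <- if (is.data.frame(f)) f else
      tibble::tibble(pair = c("AT", "GC"), f = rep_len(f, 2),
                     ci_lo = NA_real_, ci_hi = NA_real_,
                     n_genomes = NA_integer_, n_excluded = NA_integer_)
  }

  mu_prime <- if (mode == "per-genome") {
    dplyr::transmute(wide, .data$genome_id, .data$pair, mu_prime = .data$mu_4s)
  } else {
    tt <- setNames(tau_tbl$tau, tau_tbl$pair)
    dplyr::transmute(wide, .data$genome_id, .data$pair,
                     mu_prime = tt[.data$pair] * .data$mu_io)
  }
  sel <- decompose_selection(skews, mu_prime, f_tbl[, c("pair", "f")])
  mu_rows <- dplyr::bind_rows(
    dplyr::transmute(wide, .data$genome_id, .data$pair, quantity = "mu_io",
                     strand = "mean", value = .data$mu_io),
    dplyr::transmute(wide, .data$genome_id, .data$pair, quantity = "mu_4s",
                     strand = "mean", value = .data$mu_4s)) |>
    dplyr::mutate(flag = dplyr::if_else(is.finite(.data$value), "ok", "flagged"))
  params <- dplyr::arrange(dplyr::bind_rows(mu_rows, sel),
                           .data$genome_id, .data$pair, .data$quantity)
  structure(list(params = params,
                 global = dplyr::full_join(
                   dplyr::rename(tau_tbl, tau_ci_lo = "ci_lo",
                                 tau_ci_hi = "ci_hi", tau_n = "n_genomes"),
                   dplyr::rename(f_tbl, f_ci_lo = "ci_lo", f_ci_hi = "ci_hi",
                                 f_n = "n_genomes"),
                   by = "pair"),
                 mode = mode, excluded = excluded),
            class = "skew_fit")
}

#' @export
print.skew_fit <- function(x, ...) {
  cat("<skew_fit> mode =", x$mode, "\n")
  print(x$global)
  cat(dplyr::n_distinct(x$params$genome_id), "genomes;",
      nrow(x$excluded), "genome/pair cells excluded from global fits\n")
  invisible(x)
}

#' Broom-style accessors for skew-model fits
#'
#' `tidy()` returns the per-genome parameter estimates (one row per genome,
#' basepair type, quantity and strand); `glance()` returns the one-row-per-
#' pair global summary (tau and f with confidence intervals).
#'
#' @param x A `skew_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.skew_fit <- function(x, ...) x$params

#' @rdname tidy.skew_fit
#' @export
glance.skew_fit <- function(x, ...) x$global

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

`%||%` <- function(a, b) if (is.null(a)) b else a
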