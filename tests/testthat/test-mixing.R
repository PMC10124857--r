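two_sources <- function(mu1 = c(-22, 10), mu2 = c(-26, 8), sd1 = c(1, 0.5),
                        sd2 = c(1, 0.5)) {
  tibble::tibble(
    source = rep(c("s1", "s2"), each = 2),
    isotope = rep(c("C13", "N15"), 2),
    mean = c(mu1, mu2), sd = c(sd1, sd2), n = 4
  )
}

zero_tef <- tibble::tibble(isotope = c("C13", "N15"), mean = c(0, 0), sd = c(0, 0))

fast_settings <- function(seed = 1) {
  mcmc_settings(iterations = 6000, burn_in = 1000, thin = 5, chains = 4, seed = seed)
}

test_that("log-posterior is symmetric for a consumer midway between symmetric sources", {
  src <- two_sources()
  midway <- tibble::tibble(d13c = -24, d15n = 9) # midpoint of the two means
  lp <- function(p1) mixing_log_posterior(c(p1, 1 - p1), c(0.5, 0.5), midway, src, zero_tef)
  expect_equal(lp(0.3), lp(0.7))
  expect_equal(lp(0.1), lp(0.9))
})

test_that("log-posterior at p = (1, 0) reduces to the single-source density", {
  src <- two_sources()
  tef <- tibble::tibble(isotope = c("C13", "N15"), mean = c(0.4, 3.4), sd = c(0, 0))
  consumer <- tibble::tibble(d13c = -22 + 0.4, d15n = 10 + 3.4) # exactly mu1 + c
  lp <- mixing_log_posterior(c(1, 0), c(1, 1), consumer, src, tef)
  # Gaussian log-density at the mode, per isotope, plus the Dirichlet constant
  expected <- dnorm(0, 0, sqrt(1^2 + 1^2), log = TRUE) +
    dnorm(0, 0, sqrt(0.5^2 + 1^2), log = TRUE) + lgamma(2)
  expect_equal(lp, expected)
})

test_that("log-posterior matches an independently coded direct evaluation", {
  set.seed(41)
  src <- two_sources(sd1 = c(2.2, 0.8), sd2 = c(0.7, 0.3))
  tef <- trophic_enrichment("standard")
  consumers <- tibble::tibble(d13c = rnorm(7, -24, 1.5), d15n = rnorm(7, 11, 1))
  for (p1 in c(0.2, 0.5, 0.9)) {
    for (s in list(c(0.3, 0.7), c(2, 1))) {
      got <- mixing_log_posterior(c(p1, 1 - p1), s, consumers, src, tef)
      mu <- matrix(c(-22, 10, -26, 8), 2, 2, byrow = TRUE)
      sg <- matrix(c(2.2, 0.8, 0.7, 0.3), 2, 2, byrow = TRUE)
      want <- direct_mixing_loglik(c(p1, 1 - p1), s, cbind(consumers$d13c, consumers$d15n),
                                   mu, sg, c(0.4, 3.4), c(1.3, 1.0)) + lgamma(2)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("log-posterior rejects invalid inputs", {
  src <- two_sources()
  cons <- tibble::tibble(d13c = -24, d15n = 9)
  expect_error(mixing_log_posterior(c(0.6, 0.6), c(1, 1), cons, src, zero_tef), "simplex")
  expect_error(mixing_log_posterior(c(0.5, 0.5), c(0, 0), cons,
                                    two_sources(sd1 = c(0, 0), sd2 = c(0, 0)),
                                    zero_tef), "degenerate")
})

test_that("Gelman-Rubin diagnostic behaves at its analytic extremes", {
  set.seed(71)
  ch <- rnorm(500)
  expect_lte(gelman_rubin(cbind(ch, ch, ch)), 1 + 1e-6) # identical chains
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_lt(gelman_rubin(iid), 1.01)
  apart <- cbind(rnorm(200, 0, 1), rnorm(200, 10, 1)) # between-variance dominates
  expect_gt(gelman_rubin(apart), 3)
  expect_error(gelman_rubin(list(rnorm(100), rnorm(99))), "equal length")
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("Gelman-Rubin agrees with the reference implementation", {
  skip_if_not_installed("coda")
  set.seed(72)
  # long chains with modestly separated means: the reference estimator's
  # degrees-of-freedom correction vanishes at this length
  chains <- lapply(c(0, 0.15, -0.1, 0.05), function(m) rnorm(2000, m))
  ours <- gelman_rubin(chains)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE)$psrf[1]
  expect_gt(ours, 1.001) # the separation is detectable
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("sampler is deterministic given seed and settings", {
  src <- two_sources()
  set.seed(1); cons <- tibble::tibble(d13c = rnorm(8, -24, 1), d15n = rnorm(8, 9, 0.5))
  s <- fast_settings(seed = 99)
  a <- run_mixing(cons, src, zero_tef, s)
  b <- run_mixing(cons, src, zero_tef, s)
  expect_identical(a$proportion_samples, b$proportion_samples)
  expect_identical(a$residual_sd_samples, b$residual_sd_samples)
  expect_identical(tidy(a), tidy(b))
})

test_that("every retained proportion draw lies on the simplex", {
  src <- two_sources()
  cons <- tibble::tibble(d13c = c(-24, -23.5), d15n = c(9, 9.2))
  fit <- run_mixing(cons, src, zero_tef, fast_settings(3))
  P <- fit$proportion_samples
  expect_true(all(P >= 0))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_equal(nrow(P), 4 * 1000)
})

test_that("a consumer midway between TEF-corrected sources splits 50/50", {
  src <- two_sources()
  midway <- tibble::tibble(d13c = -24, d15n = 9)
  fit <- run_mixing(midway, src, zero_tef, fast_settings(11))
  expect_true(fit$converged)
  expect_equal(unname(fit$summary$median[fit$summary$source == "s1"]), 0.5,
               tolerance = 0.03)
})

test_that("consumers clustered at one source drive its share above 0.9", {
  set.seed(51)
  src <- two_sources(mu1 = c(-22, 10), mu2 = c(-28, 6),
                     sd1 = c(0.3, 0.2), sd2 = c(0.3, 0.2))
  cons <- tibble::tibble(d13c = rnorm(15, -22, 0.2), d15n = rnorm(15, 10, 0.2))
  fit <- run_mixing(cons, src, zero_tef, fast_settings(5))
  med_s1 <- fit$summary$median[fit$summary$source == "s1"]
  expect_gt(med_s1, 0.9)
  # and agrees with the brute-force grid posterior
  grid_med <- grid_mixing_median(cons, src, zero_tef, first_source = "s1")
  expect_equal(unname(med_s1), grid_med, tolerance = 0.02)
})

test_that("posterior medians track the brute-force grid posterior", {
  set.seed(52)
  src <- two_sources(sd1 = c(2.2, 0.8), sd2 = c(0.7, 0.3))
  tef <- trophic_enrichment("standard")
  cons <- tibble::tibble(d13c = rnorm(12, -24.5, 1), d15n = rnorm(12, 12, 0.8))
  fit <- run_mixing(cons, src, tef, fast_settings(6))
  grid_med <- grid_mixing_median(cons, src, tef, first_source = "s1")
  expect_equal(unname(fit$summary$median[fit$summary$source == "s1"]), grid_med,
               tolerance = 0.02)
})

test_that("swapping source labels swaps the posterior", {
  set.seed(53)
  src <- two_sources()
  cons <- tibble::tibble(d13c = rnorm(10, -23.2, 0.8), d15n = rnorm(10, 9.6, 0.5))
  fwd <- run_mixing(cons, src, zero_tef, fast_settings(7))
  swapped <- src
  swapped$source <- rep(c("s2", "s1"), each = 2)
  bwd <- run_mixing(cons, swapped, zero_tef, fast_settings(7))
  m_fwd <- setNames(fwd$summary$median, fwd$summary$source)
  m_bwd <- setNames(bwd$summary$median, bwd$summary$source)
  # the distribution formerly labelled s1 is now labelled s2: medians swap
  expect_equal(unname(m_fwd["s1"]), unname(m_bwd["s2"]), tolerance = 0.03)
  expect_equal(unname(m_fwd["s2"]), unname(m_bwd["s1"]), tolerance = 0.03)
})

test_that("posterior predictive check calibrates on self-generated data", {
  design <- wild_design(seed = 21)
  wild <- gen_wild_consumers(design)
  fit <- run_mixing(wild, design$sources, design$tef, fast_settings(8))
  ppc <- posterior_predictive_check(fit)
  expect_equal(nrow(ppc), nrow(wild) * 2)
  cov <- attr(ppc, "coverage")
  expect_gte(cov, 0.35)
  expect_lte(cov, 0.65)
})

test_that("posterior predictive check flags a far-outside consumer and empty input", {
  src <- two_sources()
  cons <- tibble::tibble(d13c = c(-24, -24 + 10), d15n = c(9, 9 + 10))
  fit <- run_mixing(cons, src, zero_tef, fast_settings(9))
  ppc <- posterior_predictive_check(fit)
  outlier <- dplyr::filter(ppc, consumer == 2)
  expect_true(all(!outlier$inside))

  empty_fit <- fit
  empty_fit$consumers <- fit$consumers[0, , drop = FALSE]
  empty_ppc <- posterior_predictive_check(empty_fit)
  expect_equal(nrow(empty_ppc), 0)
})

test_that("scenario comparison is reproducible and runs on minimal groups", {
  wild <- gen_wild_consumers(wild_design(seed = 31))
  src <- mixing_sources()
  same_tef <- list(a = trophic_enrichment("standard"),
                   b = trophic_enrichment("standard"))
  cmp <- compare_tef_scenarios(wild, src, same_tef, fast_settings(10))
  sm <- cmp$summary
  a <- dplyr::filter(sm, scenario == "a") |> dplyr::select(-scenario)
  b <- dplyr::filter(sm, scenario == "b") |> dplyr::select(-scenario)
  # identical TEF scenarios under the same root seed give identical chains
  expect_identical(a, b)

  single <- wild[1, ]
  cmp1 <- compare_tef_scenarios(single, src, settings = fast_settings(12))
  expect_true(all(cmp1$summary$upper - cmp1$summary$lower > 0.3)) # wide CIs
})

test_that("non-converged runs are flagged with a warning", {
  src <- two_sources()
  cons <- tibble::tibble(d13c = -24, d15n = 9)
  tiny <- mcmc_settings(iterations = 60, burn_in = 10, thin = 1, chains = 2, seed = 1)
  expect_warning(fit <- run_mixing(cons, src, zero_tef, tiny),
                 "not converged|R-hat")
  expect_false(fit$converged)
})

test_that("MCMC settings are validated", {
  expect_error(mcmc_settings(iterations = 500, burn_in = 1000), "exceed")
  expect_error(mcmc_settings(thin = 0), "thin")
  expect_error(mcmc_settings(chains = 1), "chains")
})
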