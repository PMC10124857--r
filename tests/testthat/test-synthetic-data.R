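test_that("generators are pure functions of design and seed", {
  a <- gen_feeding_trial(trial_design(seed = 42))
  b <- gen_feeding_trial(trial_design(seed = 42))
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(a, pa); readr::write_csv(b, pb)
  expect_identical(readLines(pa), readLines(pb)) # byte-identical CSV

  expect_identical(gen_wild_consumers(wild_design(seed = 7)),
                   gen_wild_consumers(wild_design(seed = 7)))
  expect_identical(gen_gut_contents(n = 100, seed = 5),
                   gen_gut_contents(n = 100, seed = 5))
  expect_false(identical(gen_gut_contents(n = 100, seed = 5),
                         gen_gut_contents(n = 100, seed = 6)))
})

test_that("trial generator honours the sampling design", {
  trial <- gen_feeding_trial(trial_design(seed = 13))
  fish <- dplyr::filter(trial, role == "trial_fish", day > 0)
  expect_equal(nrow(fish), 64)
  expect_equal(sort(unique(fish$day)), c(14, 31, 42, 55, 63))
  per_day <- dplyr::count(fish, day)$n
  expect_equal(per_day, c(12, 12, 12, 12, 16))
  # round-robin allocation balances diets within each day
  counts <- dplyr::count(fish, day, diet_group)$n
  expect_true(all(counts %in% 3:4))
  expect_gt(sum(trial$role == "prey"), 0)
  # generated data satisfy the fitting chain's preconditions by construction
  expect_no_error(fit_both_isotopes(trial))
})

test_that("noise-free trial fish lie exactly on the model curve", {
  d <- trial_design(seed = 3, residual_sd = c(C13 = 0, N15 = 0),
                    delta0_sd = c(C13 = 0, N15 = 0))
  trial <- gen_feeding_trial(d)
  truth <- attr(trial, "truth")
  fish <- apply_fish_lipid_rule(dplyr::filter(trial, role == "trial_fish", day > 0))
  pm <- truth$prey_means
  fish <- dplyr::inner_join(fish, pm, by = "diet_group")
  expect_equal(
    fish$d13c_norm,
    predict_delta(fish$day, truth$delta0[["C13"]], fish$d13c_prey,
                  truth$disc[["C13"]], truth$tau[["C13"]]),
    tolerance = 1e-12
  )
  expect_equal(
    fish$d15n,
    predict_delta(fish$day, truth$delta0[["N15"]], fish$d15n_prey,
                  truth$disc[["N15"]], truth$tau[["N15"]]),
    tolerance = 1e-12
  )
})

test_that("generated prey moments converge to the design distributions", {
  diets <- tibble::tibble(
    diet_group = "krill", n_prey = 10000, cn_mean = 7.52, cn_sd = 0.5,
    d13c_mean = -29.5, d13c_sd = 1.32, d15n_mean = 3.63, d15n_sd = 0.3
  )
  d <- trial_design(diets = diets, seed = 17)
  prey <- dplyr::filter(gen_feeding_trial(d), role == "prey")
  # sample mean within 3 standard errors of the design mean
  expect_lt(abs(mean(prey$d13c) - -29.5), 3 * 1.32 / sqrt(10000))
  expect_lt(abs(sd(prey$d13c) - 1.32), 3 * 1.32 / sqrt(2 * 10000))
  expect_lt(abs(mean(prey$d15n) - 3.63), 3 * 0.3 / sqrt(10000))
})

test_that("wild generator reduces to point masses when all spread is removed", {
  src <- tibble::tibble(
    source = rep(c("benthic", "dreissenid"), each = 2),
    isotope = rep(c("C13", "N15"), 2),
    mean = c(-22.3, 9.4, -25.5, 8.3), sd = 0, n = 4
  )
  tef <- tibble::tibble(isotope = c("C13", "N15"), mean = c(0.4, 3.4), sd = c(0, 0))
  d <- wild_design(
    size_classes = tibble::tibble(label = "all", lo = 40, hi = 100, n = 12,
                                  p_dreissenid = 1),
    sources = src, tef = tef, sigma_res = c(C13 = 0, N15 = 0),
    fish_cn = c(mean = 3.0, sd = 0), seed = 2
  )
  wild <- gen_wild_consumers(d)
  expect_equal(wild$d13c, rep(-25.5 + 0.4, 12))
  expect_equal(wild$d15n, rep(8.3 + 3.4, 12))
})

test_that("wild generator closes the loop through the mixing model at 50/50", {
  src <- tibble::tibble(
    source = rep(c("a", "dreissenid"), each = 2),
    isotope = rep(c("C13", "N15"), 2),
    mean = c(-22, 10, -26, 8), sd = c(1, 0.5, 1, 0.5), n = 4
  )
  tef <- tibble::tibble(isotope = c("C13", "N15"), mean = c(0, 0), sd = c(0, 0))
  d <- wild_design(
    size_classes = tibble::tibble(label = "all", lo = 40, hi = 100, n = 40,
                                  p_dreissenid = 0.5),
    sources = src, tef = tef, sigma_res = c(C13 = 0.3, N15 = 0.3), seed = 23
  )
  wild <- gen_wild_consumers(d)
  fit <- run_mixing(wild, src, tef,
                    mcmc_settings(iterations = 6000, burn_in = 1000, thin = 5,
                                  chains = 4, seed = 3))
  med <- fit$summary$median[fit$summary$source == "dreissenid"]
  expect_equal(unname(med), 0.5, tolerance = 0.1)
})

test_that("gut generator honours its degenerate settings", {
  all_empty <- gen_gut_contents(n = 40, empty_rate = 1, unident_rate = 0, seed = 4)
  s <- summarize_guts(all_empty)
  expect_equal(s$pct_empty, 100L)
  expect_equal(s$n_identifiable, 0L)

  flat <- tibble::tibble(taxon = c("chironomid", "dreissenid"), a = 40, b = 0)
  all_full <- gen_gut_contents(n = 60, occurrence_curves = flat,
                               empty_rate = 0, unident_rate = 0, seed = 5)
  foo <- foo_by_bin(all_full, default_size_bins())
  expect_true(all(foo$foo[!is.na(foo$foo)] == 100))
})

test_that("monotone dreissenid occurrence curve yields a monotone FOO trend", {
  guts <- gen_gut_contents(n = 2000, seed = 6)
  foo <- foo_by_bin(guts, default_size_bins())
  dre <- dplyr::filter(foo, taxon == "dreissenid") |>
    dplyr::arrange(size_bin)
  # non-decreasing across the four bins, within binomial noise at this n
  expect_true(all(diff(dre$foo) > -5))
  expect_gt(dre$foo[4], dre$foo[1] + 30)
})

test_that("ingested dreissenid lengths respect the gape limit", {
  guts <- gen_gut_contents(n = 500, seed = 8)
  all_lengths <- unlist(guts$dreissenid_lengths_mm)
  expect_gt(length(all_lengths), 0)
  expect_true(all(all_lengths >= 1 & all_lengths <= 12))
  # mussels recovered only from fish recorded as containing dreissenids
  with_len <- lengths(guts$dreissenid_lengths_mm) > 0
  expect_true(all(guts$dreissenid[with_len] > 0))
})

test_that("design validation rejects impossible settings", {
  expect_error(trial_design(sampling_days = c(10, 5)), "increasing")
  expect_error(trial_design(fish_per_day = c(1, 2)), "per sampling day")
  expect_error(trial_design(residual_sd = c(C13 = -1, N15 = 0.5)), "SD")
  expect_error(wild_design(size_classes = tibble::tibble(
    label = "x", lo = 1, hi = 2, n = 3, p_dreissenid = 1.2)), "p_dreissenid")
  expect_error(gen_gut_contents(empty_rate = 0.9, unident_rate = 0.3), "probabilit")
})
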