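#' Feeding-trial simulation design
#'
#' Describes a multi-diet feeding trial for the synthetic-data generator.
#' Defaults mirror the study's conditions: four diet groups with the packaged
#' prey signatures ([goby_prey_table()], per-specimen SDs recovered as
#' SE x sqrt(n)), sampling on days 14, 31, 42, 55 and 63 with
#' (12, 12, 12, 12, 16) fish per date (64 post-baseline fish), a shared day-0
#' baseline of -24.9 per-mil (SD 2.6) d13C and 14.4 (SD 0.6) d15N, true
#' parameters disc = -0.41 / tau = 0.0229 (C) and disc = 4.04 / tau = 0.0192
#' (N), residual SDs 1.31 and 0.55 per-mil, and fish C:N 3.33 (SD 0.21).
#'
#' @param diets Tibble with columns `diet_group`, `n_prey`, `cn_mean`,
#'   `cn_sd`, `d13c_mean`, `d13c_sd`, `d15n_mean`, `d15n_sd` (per-specimen
#'   SDs).
#' @param sampling_days Strictly increasing positive sampling days.
#' @param fish_per_day Fish sampled per date: a scalar or one count per day.
#' @param n_day0 Number of day-0 baseline fish.
#' @param delta0_mean,delta0_sd Named per-isotope (`C13`, `N15`) day-0 mean
#'   and between-fish SD.
#' @param true_disc,true_tau Named per-isotope true discrimination (per-mil)
#'   and turnover rate (day^-1).
#' @param residual_sd Named per-isotope residual SD around the trajectory.
#' @param fish_cn Fish C:N `c(mean, sd)`.
#' @param seed Integer seed.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(diets = NULL,
                         sampling_days = c(14, 31, 42, 55, 63),
                         fish_per_day = c(12, 12, 12, 12, 16),
                         n_day0 = 10,
                         delta0_mean = c(C13 = -24.9, N15 = 14.4),
                         delta0_sd = c(C13 = 2.6, N15 = 0.6),
                         true_disc = c(C13 = -0.41, N15 = 4.04),
                         true_tau = c(C13 = 0.0229, N15 = 0.0192),
                         residual_sd = c(C13 = 1.31, N15 = 0.55),
                         fish_cn = c(mean = 3.33, sd = 0.21),
                         seed = 1L) {
  if (is.null(diets)) {
    prey <- dplyr::filter(goby_prey_table(), .data$diet_group != "round_goby")
    diets <- dplyr::transmute(
      prey,
      diet_group = .data$diet_group,
      n_prey = .data$n,
      cn_mean = .data$cn_mean, cn_sd = .data$cn_se * sqrt(.data$n),
      d13c_mean = .data$d13c_mean, d13c_sd = .data$d13c_se * sqrt(.data$n),
      d15n_mean = .data$d15n_mean, d15n_sd = .data$d15n_se * sqrt(.data$n)
    )
  }
  if (any(diff(sampling_days) <= 0) || any(sampling_days <= 0)) {
    abort("`sampling_days` must be strictly increasing and > 0")
  }
  if (length(fish_per_day) == 1) {
    fish_per_day <- rep(fish_per_day, length(sampling_days))
  }
  if (length(fish_per_day) != length(sampling_days)) {
    abort("`fish_per_day` must be a scalar or one count per sampling day")
  }
  if (any(residual_sd < 0) || any(delta0_sd < 0)) abort("SDs must be >= 0")
  if (any(true_tau <= 0)) abort("true tau must be > 0")
  structure(
    list(diets = diets, sampling_days = sampling_days,
         fish_per_day = fish_per_day, n_day0 = n_day0,
         delta0_mean = delta0_mean, delta0_sd = delta0_sd,
         true_disc = true_disc, true_tau = true_tau,
         residual_sd = residual_sd, fish_cn = fish_cn, seed = as.integer(seed)),
    class = "trial_design"
  )
}

# invert the lipid rule: report a raw d13c whose normalized value is `norm`
raw_from_normalized <- function(norm, cn, threshold = 3.5) {
  ifelse(cn > threshold, norm + 3.32 - 0.99 * cn, norm)
}

#' Simulate a feeding trial
#'
#' Emits day-0 baseline fish, post-baseline fish allocated round-robin across
#' diet groups on each sampling day, and per-diet prey reference specimens.
#' Each fish's lipid-normalized d13C (and its d15N) follows the first-order
#' approach to the diet-plus-discrimination equilibrium
#' ([predict_delta()] at the design's true parameters and design prey means)
#' plus Normal residual noise; raw d13C is back-computed so that
#' [apply_fish_lipid_rule()] recovers the trajectory value exactly. Fully
#' reproducible from the design's seed.
#'
#' The generated table carries an attribute `truth` (true parameters, day-0
#' means and design prey means, the latter lipid-normalized for carbon) for
#' parameter-recovery studies.
#'
#' @param design A [trial_design()].
#' @return A samples tibble (see [read_samples()] for the schema) with
#'   `attr(, "truth")`.
#' @export
#' @examples
#' trial <- gen_feeding_trial(trial_design(seed = 42))
#' dplyr::count(trial, role)
gen_feeding_trial <- function(design = trial_design()) {
  if (!inherits(design, "trial_design")) abort("`design` must come from trial_design()")
  set.seed(design$seed)
  diets <- design$diets
  n_diet <- nrow(diets)

  prey_means <- tibble::tibble(
    diet_group = diets$diet_group,
    d13c_prey = normalize_lipid_d13c(diets$d13c_mean, diets$cn_mean),
    d15n_prey = diets$d15n_mean
  )

  draw_cn <- function(n) pmax(rnorm(n, design$fish_cn["mean"], design$fish_cn["sd"]), 2.5)

  # day-0 baseline fish (values in normalized space, raw back-computed)
  cn0 <- draw_cn(design$n_day0)
  day0 <- tibble::tibble(
    sample_id = sprintf("fish_d0_%02d", seq_len(design$n_day0)),
    role = "trial_fish",
    diet_group = diets$diet_group[(seq_len(design$n_day0) - 1) %% n_diet + 1],
    day = 0,
    length_mm = round(rnorm(design$n_day0, 40.6, 5.9)),
    weight_g = round(pmax(rnorm(design$n_day0, 0.79, 0.15), 0.2), 2),
    d13c = raw_from_normalized(
      rnorm(design$n_day0, design$delta0_mean["C13"], design$delta0_sd["C13"]), cn0),
    d15n = rnorm(design$n_day0, design$delta0_mean["N15"], design$delta0_sd["N15"]),
    cn_ratio = cn0
  )

  # post-baseline fish, round-robin over diets within each sampling date
  fish <- purrr::map2_dfr(design$sampling_days, design$fish_per_day, function(d, nf) {
    grp <- diets$diet_group[(seq_len(nf) - 1) %% n_diet + 1]
    pm <- prey_means[match(grp, prey_means$diet_group), ]
    cn <- draw_cn(nf)
    frac <- d / max(design$sampling_days)
    mu_c <- predict_delta(rep(d, nf), design$delta0_mean["C13"], pm$d13c_prey,
                          design$true_disc["C13"], design$true_tau["C13"])
    mu_n <- predict_delta(rep(d, nf), design$delta0_mean["N15"], pm$d15n_prey,
                          design$true_disc["N15"], design$true_tau["N15"])
    tibble::tibble(
      sample_id = sprintf("fish_d%02d_%02d", d, seq_len(nf)),
      role = "trial_fish",
      diet_group = grp,
      day = d,
      length_mm = round(rnorm(nf, 40.6 + (45.3 - 40.6) * frac, 5.9)),
      weight_g = round(pmax(rnorm(nf, 0.79 + (1.13 - 0.79) * frac, 0.15), 0.2), 2),
      d13c = raw_from_normalized(mu_c + rnorm(nf, 0, design$residual_sd["C13"]), cn),
      d15n = mu_n + rnorm(nf, 0, design$residual_sd["N15"]),
      cn_ratio = cn
    )
  })

  # prey reference specimens per diet
  prey <- purrr::pmap_dfr(diets, function(diet_group, n_prey, cn_mean, cn_sd,
                                          d13c_mean, d13c_sd, d15n_mean, d15n_sd, ...) {
    tibble::tibble(
      sample_id = sprintf("prey_%s_%02d", diet_group, seq_len(n_prey)),
      role = "prey",
      diet_group = diet_group,
      day = NA_real_,
      length_mm = NA_real_,
      weight_g = NA_real_,
      d13c = rnorm(n_prey, d13c_mean, d13c_sd),
      d15n = rnorm(n_prey, d15n_mean, d15n_sd),
      cn_ratio = pmax(rnorm(n_prey, cn_mean, cn_sd), 1)
    )
  })

  out <- validate_samples(dplyr::bind_rows(day0, fish, prey))
  attr(out, "truth") <- list(
    disc = design$true_disc, tau = design$true_tau,
    delta0 = design$delta0_mean, prey_means = prey_means,
    residual_sd = design$residual_sd
  )
  out
}

#' Wild-consumer simulation design
#'
#' Describes wild consumers drawn from the mixing model's own generative
#' structure. Defaults mirror the field survey: three size classes of 20, 14
#' and 11 fish spanning 33-117 mm, the packaged lake end-member sources, the
#' experimentally determined enrichment scenario, and true dreissenid
#' (pelagic-pathway) shares of 0.54, 0.59 and 0.76 that increase with size —
#' the diet shift the gut contents show.
#'
#' @param size_classes Tibble with columns `label`, `lo`, `hi` (mm), `n`,
#'   `p_dreissenid` (remaining share goes to the other source(s) equally).
#' @param sources Long source table (default [mixing_sources()]).
#' @param tef Trophic enrichment under which consumers are generated.
#' @param sigma_res Named per-isotope residual SD added to the mixture
#'   variance.
#' @param fish_cn Fish C:N `c(mean, sd)` for the lipid rule.
#' @param seed Integer seed.
#' @return A list of class `wild_design`.
#' @export
wild_design <- function(size_classes = tibble::tibble(
                          label = c("<=70mm", "71-100mm", ">100mm"),
                          lo = c(33, 71, 101), hi = c(70, 100, 117),
                          n = c(20, 14, 11),
                          p_dreissenid = c(0.54, 0.59, 0.76)
                        ),
                        sources = mixing_sources(),
                        tef = trophic_enrichment("experimental"),
                        sigma_res = c(C13 = 0.5, N15 = 0.5),
                        fish_cn = c(mean = 3.33, sd = 0.21),
                        seed = 1L) {
  if (any(size_classes$p_dreissenid < 0 | size_classes$p_dreissenid > 1)) {
    abort("`p_dreissenid` must be within [0, 1]")
  }
  if (any(sigma_res < 0)) abort("`sigma_res` must be >= 0")
  check_sources(sources)
  check_tef(tef)
  structure(
    list(size_classes = size_classes, sources = sources, tef = tef,
         sigma_res = sigma_res, fish_cn = fish_cn, seed = as.integer(seed)),
    class = "wild_design"
  )
}

#' Simulate wild consumers from the mixing structure
#'
#' Per size class, draws `n` consumers from the two-isotope normal mixing
#' model: mean `sum_k p_k (mu_ik + c_i)` and variance
#' `sum_k p_k^2 (sigma_ik^2 + sigma_c,i^2) + sigma_res,i^2` per isotope, with
#' `p` determined by the class's dreissenid share. Lengths are uniform
#' integers within the class range; raw d13C is back-computed from the
#' model-space (lipid-normalized) value using each fish's C:N.
#'
#' @param design A [wild_design()].
#' @return A samples tibble of `wild_fish` rows with `attr(, "truth")` (the
#'   per-class proportions and the generating TEF).
#' @export
gen_wild_consumers <- function(design = wild_design()) {
  if (!inherits(design, "wild_design")) abort("`design` must come from wild_design()")
  set.seed(design$seed)
  sm <- source_matrices(design$sources)
  tv <- tef_vectors(design$tef)
  other <- setdiff(sm$sources, "dreissenid")
  if (!"dreissenid" %in% sm$sources) {
    abort("`sources` must include a 'dreissenid' source")
  }

  out <- purrr::pmap_dfr(design$size_classes, function(label, lo, hi, n, p_dreissenid) {
    p <- setNames(numeric(length(sm$sources)), sm$sources)
    p["dreissenid"] <- p_dreissenid
    p[other] <- (1 - p_dreissenid) / length(other)
    stats_iso <- lapply(1:2, function(i) {
      m <- sum(p * (sm$mu[, i] + tv$mean[i]))
      v <- sum(p^2 * (sm$sigma[, i]^2 + tv$sd[i]^2)) + design$sigma_res[i]^2
      c(m, sqrt(v))
    })
    cn <- pmax(rnorm(n, design$fish_cn["mean"], design$fish_cn["sd"]), 2.5)
    tibble::tibble(
      sample_id = sprintf("wild_%s_%02d", gsub("[^0-9A-Za-z]", "", label), seq_len(n)),
      role = "wild_fish",
      diet_group = NA_character_,
      day = NA_real_,
      length_mm = as.numeric(lo + floor(runif(n) * (hi - lo + 1))),
      weight_g = NA_real_,
      d13c = raw_from_normalized(rnorm(n, stats_iso[[1]][1], stats_iso[[1]][2]), cn),
      d15n = rnorm(n, stats_iso[[2]][1], stats_iso[[2]][2]),
      cn_ratio = cn
    )
  })
  out <- validate_samples(out)
  attr(out, "truth") <- list(
    size_classes = design$size_classes, tef = design$tef,
    sigma_res = design$sigma_res
  )
  out
}

#' Default size-dependent prey occurrence curves
#'
#' Logistic-in-length presence probabilities `plogis(a + b * length_mm)` per
#' taxon, shaped like the field pattern: cladocerans and chironomids dominate
#' small fish, dreissenids rise steeply with length, amphipods/snails/
#' trichopterans occur at low flat rates.
#'
#' @return A tibble with columns `taxon`, `a`, `b`.
#' @export
default_occurrence_curves <- function() {
  tibble::tribble(
    ~taxon,        ~a,     ~b,
    "cladoceran",   2.15, -0.0435,
    "chironomid",   2.06, -0.0224,
    "dreissenid",  -3.84,  0.0549,
    "amphipod",    -1.73,  0,
    "snail",       -2.20,  0,
    "trichoptera", -2.44,  0
  )
}

#' Simulate gut-content records
#'
#' Per fish: length uniform (integer mm) over `length_range`; with
#' probability `empty_rate` the gut is empty, with probability
#' `unident_rate` it holds only unidentifiable material; otherwise each
#' taxon is present with its length-dependent logistic probability and, when
#' present, has count `1 + Poisson(1)`. A fish whose Bernoulli draws all fail
#' is recorded as unidentifiable-only. Dreissenid shell lengths, when
#' present, grow linearly with goby length (slope `1/5.07` mm per mm) with
#' 1-mm noise, truncated to \[1, `gape_limit_mm`\] (largest mussel a goby can
#' take; default 12 mm).
#'
#' Defaults emulate the field survey: 226 fish, lengths 17-120 mm, empty and
#' unidentifiable-only rates 19/226 and 7/226.
#'
#' @param n Number of fish.
#' @param length_range `c(min, max)` fish length in mm.
#' @param occurrence_curves Tibble `taxon`, `a`, `b` (see
#'   [default_occurrence_curves()]).
#' @param empty_rate,unident_rate Probabilities of an empty or
#'   unidentifiable-only gut.
#' @param gape_limit_mm Maximum ingestible dreissenid length.
#' @param seed Integer seed.
#' @return A gut record tibble with a `dreissenid_lengths_mm` list-column.
#' @export
#' @examples
#' guts <- gen_gut_contents(n = 50, seed = 3)
#' summarize_guts(guts)
gen_gut_contents <- function(n = 226, length_range = c(17, 120),
                             occurrence_curves = default_occurrence_curves(),
                             empty_rate = 19 / 226, unident_rate = 7 / 226,
                             gape_limit_mm = 12, seed = 1L) {
  if (empty_rate < 0 || empty_rate > 1 || unident_rate < 0 ||
      empty_rate + unident_rate > 1) {
    abort("`empty_rate` and `unident_rate` must be probabilities summing to <= 1")
  }
  set.seed(as.integer(seed))
  taxa <- occurrence_curves$taxon
  len <- length_range[1] + floor(runif(n) * (diff(length_range) + 1))
  u <- runif(n)
  state <- ifelse(u < empty_rate, "empty",
                  ifelse(u < empty_rate + unident_rate, "unident", "content"))

  counts <- matrix(0L, n, length(taxa), dimnames = list(NULL, taxa))
  dlen <- vector("list", n)
  for (j in seq_len(n)) {
    dlen[[j]] <- numeric(0)
    if (state[j] != "content") next
    pr <- stats::plogis(occurrence_curves$a + occurrence_curves$b * len[j])
    present <- runif(length(taxa)) < pr
    counts[j, present] <- 1L + rpois(sum(present), 1)
    if (isTRUE(present[match("dreissenid", taxa)])) {
      m <- counts[j, "dreissenid"]
      dlen[[j]] <- pmin(pmax(round(len[j] / 5.07 + rnorm(m, 0, 1)), 1), gape_limit_mm)
    }
  }
  has_content <- state == "content" & rowSums(counts) > 0

  out <- tibble::tibble(
    fish_id = sprintf("gut_%03d", seq_len(n)),
    length_mm = as.numeric(len),
    is_empty = state == "empty",
    has_identifiable_content = has_content
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  out$dreissenid_lengths_mm <- dlen
  validate_guts(out)
  out
}
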