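#' Prey reference values from the round goby feeding trial
#'
#' Measured isotope summaries (mean, SE, n) for the four prey items offered in
#' the 63-day feeding trial, plus the mean muscle C:N of the experimental
#' gobies. These are the packaged defaults for [trial_design()] and the worked
#' examples; SEs are per-item standard errors of the mean.
#'
#' @return A tibble with one row per prey item (plus a `round_goby` C:N row)
#'   and columns `diet_group`, `n`, `cn_mean`, `cn_se`, `d13c_mean`, `d13c_se`,
#'   `d13c_norm_mean`, `d13c_norm_se`, `d15n_mean`, `d15n_se`. The
#'   `d13c_norm_*` columns are the published lipid-normalized values; the
#'   package recomputes them from `d13c_mean` and `cn_mean` (the normalization
#'   is affine, so it commutes with the mean).
#' @seealso [normalize_lipid_d13c()], [trial_design()]
#' @export
#' @examples
#' goby_prey_table()
goby_prey_table <- function() {
  tibble::tribble(
    ~diet_group,       ~n, ~cn_mean, ~cn_se, ~d13c_mean, ~d13c_se, ~d13c_norm_mean, ~d13c_norm_se, ~d15n_mean, ~d15n_se,
    "chilean_mussel",   4,     5.25,   0.07,     -17.15,     0.58,          -15.28,          0.55,       9.95,     0.36,
    "chironomid",       6,     4.84,   0.15,     -22.94,     0.42,          -21.47,          0.53,       2.64,     1.42,
    "dreissenid",       4,     4.79,   0.11,     -26.91,     0.28,          -25.49,          0.34,       8.31,     0.15,
    "krill",            4,     7.52,   1.62,     -29.50,     0.66,          -25.37,          1.38,       3.63,     0.15,
    "round_goby",      69,     3.33,   0.21,         NA,       NA,              NA,            NA,         NA,       NA
  )
}

#' End-member source distributions for the lake mixing model
#'
#' Lake food-source isotope distributions (mean, SD, n per isotope) for the
#' two mixing end members: pooled benthic macroinvertebrates (amphipods +
#' chironomids, detrital pathway) and dreissenid mussels (pelagic pathway).
#' Dreissenids are roughly 3 per-mil more d13C-depleted and 1 per-mil more
#' d15N-depleted than the benthic pool.
#'
#' @return A tibble in long source format: columns `source`, `isotope`
#'   (`"C13"`/`"N15"`), `mean`, `sd`, `n`.
#' @seealso [run_mixing()], [wild_design()]
#' @export
#' @examples
#' mixing_sources()
mixing_sources <- function() {
  tibble::tribble(
    ~source,       ~isotope, ~mean, ~sd, ~n,
    "benthic",     "C13",    -22.3, 2.2,  3,
    "benthic",     "N15",      9.4, 0.8,  3,
    "dreissenid",  "C13",    -25.5, 0.7,  4,
    "dreissenid",  "N15",      8.3, 0.3,  4
  )
}

#' Trophic enrichment (discrimination) factor scenarios
#'
#' The two discrimination-factor scenarios compared by the mixing analysis:
#'
#' * `"standard"`: the Post (2002) meta-analysis means widely used in aquatic
#'   food-web studies, 0.4 +/- 1.3 per-mil for d13C and 3.4 +/- 1.0 for d15N
#'   (mean +/- SD).
#' * `"experimental"`: the feeding-trial estimates for round goby,
#'   -0.41 +/- 0.32 for d13C and 4.04 +/- 0.32 for d15N (mean +/- SE; the SE
#'   is the only spread the trial supplies, so it is used as the scenario SD
#'   by default).
#'
#' @param scenario `"standard"` or `"experimental"`.
#' @return A tibble with columns `isotope`, `mean`, `sd`.
#' @export
#' @examples
#' trophic_enrichment("standard")
#' trophic_enrichment("experimental")
trophic_enrichment <- function(scenario = c("standard", "experimental")) {
  scenario <- match.arg(scenario)
  if (scenario == "standard") {
    tibble::tibble(isotope = c("C13", "N15"), mean = c(0.4, 3.4), sd = c(1.3, 1.0))
  } else {
    tibble::tibble(isotope = c("C13", "N15"), mean = c(-0.41, 4.04), sd = c(0.32, 0.32))
  }
}

# validate a TEF tibble supplied by the user
check_tef <- function(tef) {
  if (!is.data.frame(tef) || !all(c("isotope", "mean", "sd") %in% names(tef))) {
    abort("`tef` must be a data frame with columns isotope, mean, sd")
  }
  if (!all(c("C13", "N15") %in% tef$isotope)) {
    abort("`tef` must contain rows for isotopes C13 and N15")
  }
  if (any(tef$sd < 0)) abort("TEF sd must be >= 0")
  tef
}

# validate a long source table (source, isotope, mean, sd, n)
check_sources <- function(sources) {
  need <- c("source", "isotope", "mean", "sd", "n")
  if (!is.data.frame(sources) || !all(need %in% names(sources))) {
    abort("`sources` must be a data frame with columns source, isotope, mean, sd, n")
  }
  if (any(sources$sd < 0)) abort("source sd must be >= 0")
  if (any(sources$n < 1)) abort("source n must be >= 1")
  sources
}
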