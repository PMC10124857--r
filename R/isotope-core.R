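#' Delta notation from isotope abundance ratios
#'
#' Converts heavy/light isotope abundance ratios to per-mil delta values
#' relative to a standard: `delta = (r_sample / r_standard - 1) * 1000`.
#' For carbon the conventional standard is VPDB, for nitrogen atmospheric N2.
#'
#' @param r_sample Positive heavy/light abundance ratio(s) of the sample.
#' @param r_standard Positive abundance ratio(s) of the reference standard.
#' @return Per-mil delta value(s), vectorized over both arguments.
#' @export
#' @examples
#' compute_delta(0.0112372, 0.0112372)  # 0
#' compute_delta(1.01, 1.00)            # 10
compute_delta <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(r_sample <= 0)) {
    abort("`r_sample` must be a positive, finite abundance ratio")
  }
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    abort("`r_standard` must be a positive, finite abundance ratio")
  }
  (r_sample - r_standard) / r_standard * 1000
}

#' Lipid normalization of delta-13C from the C:N ratio
#'
#' Corrects bulk-tissue d13C for lipid content using the mass C:N ratio:
#' `normalized = d13c - 3.32 + 0.99 * cn_ratio`. Lipids are d13C-depleted, so
#' lipid-rich (high C:N) tissue reads artificially low; the correction is
#' affine, adding exactly 0.99 per-mil per unit C:N, and is exactly zero at
#' C:N = 3.32/0.99.
#'
#' @param d13c Raw d13C value(s), per-mil.
#' @param cn_ratio Positive mass C:N ratio(s).
#' @return Lipid-normalized d13C, per-mil.
#' @export
#' @examples
#' normalize_lipid_d13c(-22.94, 4.84)  # -21.47
normalize_lipid_d13c <- function(d13c, cn_ratio) {
  if (any(!is.finite(d13c))) abort("`d13c` must be finite")
  if (any(!is.finite(cn_ratio)) || any(cn_ratio <= 0)) {
    abort("`cn_ratio` must be positive and finite")
  }
  d13c - 3.32 + 0.99 * cn_ratio
}

#' Apply the tissue-dependent lipid-normalization rule to a sample table
#'
#' Prey (food item) tissue is always lipid-normalized. Fish muscle is lean
#' enough that the correction only matters at elevated lipid content, so fish
#' d13C is normalized only when C:N strictly exceeds `threshold` (default
#' 3.5); at or below the threshold the raw value is kept.
#'
#' The input d13C column is never overwritten: the result gains a
#' `d13c_norm` column plus a logical `lipid_normalized` flag, so re-applying
#' the rule can never double-correct.
#'
#' @param samples A data frame with columns `role` (`"trial_fish"`,
#'   `"wild_fish"` or `"prey"`), `d13c` and `cn_ratio`.
#' @param threshold Fish C:N above which normalization is applied
#'   (strict inequality). Default 3.5.
#' @return The input as a tibble with `d13c_norm` and `lipid_normalized`
#'   columns appended (replaced if already present).
#' @seealso [normalize_lipid_d13c()]
#' @export
#' @examples
#' fish <- tibble::tibble(role = "trial_fish", d13c = -24, cn_ratio = c(3.0, 3.72))
#' apply_fish_lipid_rule(fish)
apply_fish_lipid_rule <- function(samples, threshold = 3.5) {
  need <- c("role", "d13c", "cn_ratio")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("`samples` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_role <- setdiff(unique(samples$role), c("trial_fish", "wild_fish", "prey"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  samples |>
    tibble::as_tibble() |>
    dplyr::mutate(
      lipid_normalized = .data$role == "prey" |
        (.data$role %in% c("trial_fish", "wild_fish") & .data$cn_ratio > threshold),
      d13c_norm = dplyr::if_else(
        .data$lipid_normalized,
        normalize_lipid_d13c(.data$d13c, .data$cn_ratio),
        .data$d13c
      )
    )
}

#' Read an isotope sample table from CSV
#'
#' Reads the `samples.csv` schema: columns `sample_id`, `role`, `diet_group`,
#' `day`, `length_mm`, `weight_g`, `d13c`, `d15n`, `cn_ratio` (header
#' required, '.' decimal separator, empty cell = missing). Validates roles,
#' finite deltas and positive C:N.
#'
#' @param path Path to the CSV file.
#' @return A tibble of samples.
#' @export
read_samples <- function(path) {
  samples <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      role = readr::col_character(),
      diet_group = readr::col_character(),
      day = readr::col_double(),
      length_mm = readr::col_double(),
      weight_g = readr::col_double(),
      d13c = readr::col_double(),
      d15n = readr::col_double(),
      cn_ratio = readr::col_double()
    )
  )
  validate_samples(samples)
}

#' Read a source distribution table from CSV
#'
#' Reads the `sources.csv` schema: columns `source`, `isotope`, `mean`,
#' `sd`, `n`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of per-source, per-isotope distributions.
#' @export
read_sources <- function(path) {
  sources <- readr::read_csv(
    path,
    col_types = readr::cols(
      source = readr::col_character(),
      isotope = readr::col_character(),
      mean = readr::col_double(),
      sd = readr::col_double(),
      n = readr::col_double()
    )
  )
  check_sources(sources)
}

# shared validation for sample tables (CSV or generated)
validate_samples <- function(samples) {
  need <- c("sample_id", "role", "d13c", "d15n", "cn_ratio")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample table missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_role <- setdiff(unique(samples$role), c("trial_fish", "wild_fish", "prey"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (any(!is.finite(samples$d13c)) || any(abs(samples$d13c) >= 1000) ||
      any(!is.finite(samples$d15n)) || any(abs(samples$d15n) >= 1000)) {
    abort("delta values must be finite and |delta| < 1000 per-mil")
  }
  if (any(!is.finite(samples$cn_ratio)) || any(samples$cn_ratio <= 0)) {
    abort("cn_ratio must be positive")
  }
  trial <- samples[samples$role == "trial_fish", ]
  if (nrow(trial) > 0 &&
      (!"day" %in% names(samples) || anyNA(trial$day) ||
       !"diet_group" %in% names(samples) || anyNA(trial$diet_group))) {
    abort("trial_fish samples must have day and diet_group set")
  }
  prey <- samples[samples$role == "prey", ]
  if (nrow(prey) > 0 && (!"diet_group" %in% names(samples) || anyNA(prey$diet_group))) {
    abort("prey samples must have diet_group set")
  }
  tibble::as_tibble(samples)
}
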