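#' Gut-content tables
#'
#' Gut records are plain tibbles: one row per fish with `fish_id`,
#' `length_mm`, logical `is_empty` and `has_identifiable_content` flags, and
#' one non-negative integer count column per prey taxon. An optional
#' `dreissenid_lengths_mm` list-column carries measured mussel lengths.
#' Fragmented mussels are assumed already resolved to whole-animal counts
#' (umbo pairs counted as one mussel) by the ingest or generator layer.
#'
#' @param records A gut record tibble.
#' @return `gut_taxa()` returns the taxon column names; `validate_guts()`
#'   returns the records invisibly after checking the flag invariants.
#' @name gut-records
NULL

gut_reserved_cols <- c("fish_id", "length_mm", "is_empty",
                       "has_identifiable_content", "size_bin",
                       "dreissenid_lengths_mm")

#' @rdname gut-records
#' @export
gut_taxa <- function(records) {
  setdiff(names(records)[vapply(records, is.numeric, logical(1))],
          gut_reserved_cols)
}

#' @rdname gut-records
#' @export
validate_guts <- function(records) {
  need <- c("fish_id", "length_mm", "is_empty", "has_identifiable_content")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("gut records missing column(s): ", paste(miss, collapse = ", ")))
  }
  taxa <- gut_taxa(records)
  counts <- as.matrix(records[taxa])
  if (length(taxa) > 0 && nrow(records) > 0) {
    if (any(counts < 0)) abort("prey counts must be non-negative")
    any_prey <- rowSums(counts) > 0
    if (any(records$is_empty & any_prey)) {
      abort("is_empty guts cannot have positive prey counts")
    }
    if (any(records$is_empty & records$has_identifiable_content)) {
      abort("is_empty guts cannot have identifiable content")
    }
    if (any(any_prey & !records$has_identifiable_content)) {
      abort("guts with positive prey counts must have has_identifiable_content = TRUE")
    }
  }
  invisible(tibble::as_tibble(records))
}

#' Percent frequency of occurrence of a prey taxon
#'
#' FOO = 100 x (number of fish whose gut contains the taxon) / (number of
#' fish with identifiable gut content). Fish with empty guts or only
#' unidentifiable material are excluded from the denominator. Presence is all
#' that matters: a count of 50 contributes the same as a count of 1.
#'
#' @param records Gut record tibble (see [gut_taxa()]).
#' @param taxon Name of a taxon count column.
#' @return FOO as a percentage in \[0, 100\].
#' @export
#' @examples
#' guts <- tibble::tibble(
#'   fish_id = as.character(1:10), length_mm = 50,
#'   is_empty = rep(c(TRUE, FALSE), c(2, 8)),
#'   has_identifiable_content = rep(c(FALSE, TRUE), c(2, 8)),
#'   chironomid = c(0, 0, 1, 2, 1, 5, 0, 0, 0, 0)
#' )
#' frequency_of_occurrence(guts, "chironomid")  # 50
frequency_of_occurrence <- function(records, taxon) {
  validate_guts(records)
  if (!taxon %in% names(records)) abort(paste0("no taxon column `", taxon, "`"))
  denom <- sum(records$has_identifiable_content)
  if (denom == 0) abort("no fish with identifiable gut content (zero denominator)")
  100 * sum(records$has_identifiable_content & records[[taxon]] > 0) / denom
}

#' Consumer size bins
#'
#' `size_binning()` builds a validated set of contiguous, closed,
#' non-overlapping length intervals; `default_size_bins()` gives the
#' study's four 25-mm bins (17-42, 43-68, 69-94, 95-120 mm), chosen because a
#' size-dependent diet shift occurs between 70 and 100 mm. Bins are closed on
#' both ends; with integer-mm lengths (non-integer lengths are rounded to the
#' nearest mm before binning) no boundary ambiguity arises.
#'
#' @param lo,hi Numeric vectors of bin endpoints (inclusive), same length,
#'   sorted and non-overlapping.
#' @param labels Optional bin labels; default `"lo-hi mm"`.
#' @return A tibble with columns `lo`, `hi`, `label`.
#' @export
#' @examples
#' default_size_bins()
size_binning <- function(lo, hi, labels = NULL) {
  if (length(lo) != length(hi) || length(lo) == 0) {
    abort("`lo` and `hi` must be equal-length, non-empty")
  }
  if (any(hi < lo)) abort("each bin needs hi >= lo")
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  if (length(lo) > 1 && any(lo[-1] <= hi[-length(hi)])) {
    abort("bins overlap")
  }
  if (is.null(labels)) labels <- sprintf("%g-%gmm", lo, hi) else labels <- labels[ord]
  tibble::tibble(lo = lo, hi = hi, label = labels)
}

#' @rdname size_binning
#' @export
default_size_bins <- function() {
  size_binning(lo = c(17, 43, 69, 95), hi = c(42, 68, 94, 120))
}

#' Assign gut records to size bins
#'
#' Adds a `size_bin` factor column. Lengths are rounded to the nearest mm
#' first; lengths falling in no bin are routed to an `"out-of-range"` level
#' with a warning, so the partition always conserves the record count.
#'
#' @param records Gut record tibble with `length_mm`.
#' @param binning A [size_binning()] tibble.
#' @return `records` with a `size_bin` column appended.
#' @export
assign_bins <- function(records, binning = default_size_bins()) {
  if (!is.data.frame(binning) || !all(c("lo", "hi", "label") %in% names(binning))) {
    abort("`binning` must come from size_binning()")
  }
  size_binning(binning$lo, binning$hi, binning$label) # re-validate
  len <- round(records$length_mm)
  idx <- rep(NA_integer_, length(len))
  for (b in seq_len(nrow(binning))) {
    idx[len >= binning$lo[b] & len <= binning$hi[b]] <- b
  }
  labs <- c(binning$label, "out-of-range")
  idx[is.na(idx)] <- nrow(binning) + 1L
  if (any(idx > nrow(binning)) && length(len) > 0) {
    n_out <- sum(idx > nrow(binning))
    if (n_out > 0) warn(sprintf("%d record(s) outside all bins routed to 'out-of-range'", n_out))
  }
  out <- tibble::as_tibble(records)
  out$size_bin <- factor(labs[idx], levels = labs)
  if (!any(out$size_bin == "out-of-range")) {
    out$size_bin <- factor(as.character(out$size_bin), levels = binning$label)
  }
  out
}

#' Frequency of occurrence by size bin
#'
#' Computes FOO for each taxon within each size bin and ranks taxa within
#' bins by FOO (ties broken alphabetically), flagging the top-`k`
#' contributors per bin. Bins with zero identifiable fish get `NA` FOO
#' (undefined, not zero).
#'
#' @param records Gut record tibble.
#' @param binning A [size_binning()] tibble.
#' @param taxa Taxon columns to summarise (default: all).
#' @param top_k How many top taxa to flag per bin (default 3).
#' @return A tibble: `size_bin`, `taxon`, `n_identifiable`, `foo`, `rank`,
#'   `is_top`.
#' @export
foo_by_bin <- function(records, binning = default_size_bins(), taxa = NULL,
                       top_k = 3) {
  validate_guts(records)
  if (is.null(taxa)) taxa <- gut_taxa(records)
  if (length(taxa) == 0) abort("no taxon columns to summarise")
  binned <- assign_bins(records, binning)
  out <- binned |>
    tidyr::pivot_longer(dplyr::all_of(taxa), names_to = "taxon",
                        values_to = "count") |>
    dplyr::group_by(.data$size_bin, .data$taxon) |>
    dplyr::summarise(
      n_identifiable = sum(.data$has_identifiable_content),
      n_with = sum(.data$has_identifiable_content & .data$count > 0),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      foo = dplyr::if_else(.data$n_identifiable > 0,
                           100 * .data$n_with / pmax(.data$n_identifiable, 1L),
                           NA_real_)
    ) |>
    dplyr::arrange(dplyr::desc(.data$foo), .data$taxon, .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::if_else(is.na(.data$foo), NA_integer_,
                            as.integer(dplyr::row_number())),
      is_top = !is.na(.data$rank) & .data$rank <= top_k
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$size_bin, .data$rank)
  # empty bins (no records at all) still appear with NA
  tidyr::complete(out, size_bin = binned$size_bin |> levels() |> factor(),
                  taxon = taxa)
}

#' Summary counts of gut states
#'
#' Totals of empty guts, guts with only unidentifiable material, and guts
#' with identifiable content, with display percentages rounded to the nearest
#' integer.
#'
#' @param records Gut record tibble (may be empty).
#' @return A one-row tibble: `n_total`, `n_empty`, `pct_empty`,
#'   `n_unidentifiable_only`, `pct_unidentifiable_only`, `n_identifiable`.
#' @export
summarize_guts <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(n_total = 0L, n_empty = 0L, pct_empty = 0L,
                          n_unidentifiable_only = 0L,
                          pct_unidentifiable_only = 0L, n_identifiable = 0L))
  }
  validate_guts(records)
  n <- nrow(records)
  n_empty <- sum(records$is_empty)
  n_unid <- sum(!records$is_empty & !records$has_identifiable_content)
  tibble::tibble(
    n_total = n,
    n_empty = n_empty,
    pct_empty = as.integer(round(100 * n_empty / n)),
    n_unidentifiable_only = n_unid,
    pct_unidentifiable_only = as.integer(round(100 * n_unid / n)),
    n_identifiable = sum(records$has_identifiable_content)
  )
}

#' Plot frequency of occurrence by size bin
#'
#' @param foo_table Output of [foo_by_bin()].
#' @param top_only Plot only each bin's top-ranked taxa?
#' @return A ggplot bar chart of FOO per taxon, faceted by size bin.
#' @export
plot_foo <- function(foo_table, top_only = FALSE) {
  dat <- if (top_only) dplyr::filter(foo_table, .data$is_top) else foo_table
  ggplot2::ggplot(dplyr::filter(dat, !is.na(.data$foo)),
                  ggplot2::aes(x = .data$taxon, y = .data$foo)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$size_bin)) +
    ggplot2::labs(x = NULL, y = "Frequency of occurrence (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
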