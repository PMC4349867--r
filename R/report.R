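# Reproduction of the derived columns (frequencies, confidence intervals,
# fold increases, percentages, per-colony averages) of published count
# tables from a UV-mutagenesis sectoring study of W303-1A x YJM789 hybrid
# diploids (wild-type and repair-deficient strains). The raw counts ship as
# TSV fixtures; every derived number is recomputed here from those counts.

#' Load a packaged count-table fixture
#'
#' @param name one of `"sectoring"`, `"event_counts"`, `"break_types"`,
#'   `"single_colonies"`.
#' @return the fixture as a tibble.
#' @export
loh_counts <- function(name = c("sectoring", "event_counts", "break_types",
                                "single_colonies")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "sectorloh")
  if (!nzchar(path)) abort(sprintf("fixture %s not found", name))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  comment = "#")
}

#' Sectored-colony frequencies and fold increases
#'
#' Recomputes, from raw sectored/total colony counts, the sectoring
#' frequency (two significant figures, and as a percentage at one decimal),
#' its exact 95% confidence interval, the crossover rate (twice the
#' frequency) and the fold increase over each row's unirradiated baseline
#' (and, where given, an alternative cross-strain baseline).
#'
#' @param counts fixture tibble (default: the packaged one) with columns
#'   `id`, `sectored`, `total`, `freq` (used when raw counts are
#'   unavailable), `baseline`, `alt_baseline`.
#' @return tibble with `frequency`, `freq_2sf`, `pct`, `ci_lo`, `ci_hi`,
#'   `co_rate`, `fold`, `alt_fold` columns appended.
#' @examples
#' report_sectoring() |> dplyr::select(id, freq_2sf, pct, fold)
#' @export
report_sectoring <- function(counts = loh_counts("sectoring")) {
  .stopifnot_cols(counts, c("id", "sectored", "total", "freq", "baseline"),
                  "`counts`")
  est <- map(seq_len(nrow(counts)), function(i) {
    if (!is.na(counts$sectored[i]) && !is.na(counts$total[i])) {
      sector_frequency(counts$sectored[i], counts$total[i])
    } else {
      tibble(k = NA_integer_, n = NA_integer_, frequency = counts$freq[i],
             ci_lo = NA_real_, ci_hi = NA_real_)
    }
  })
  est <- bind_rows(est)
  out <- counts |>
    mutate(
      frequency = est$frequency,
      freq_2sf = signif(.data$frequency, 2),
      pct = round(100 * .data$frequency, 1),
      ci_lo = est$ci_lo, ci_hi = est$ci_hi,
      co_rate = crossover_rate(.data$frequency)
    )
  base_freq <- out$frequency[match(out$baseline, out$id)]
  alt_freq <- out$frequency[match(out$alt_baseline, out$id)]
  out$fold <- ifelse(is.na(base_freq), NA_real_,
                     format_fold(fold_change(out$frequency, base_freq)))
  out$alt_fold <- ifelse(is.na(alt_freq), NA_real_,
                         format_fold(fold_change(out$frequency, alt_freq)))
  out
}

#' SCB/DSCB percentages from break-type counts
#'
#' Percentage of single-chromatid-break events among classified selected
#' events, and among all (selected plus unselected) events, rounded to the
#' nearest integer as displayed in the source tables. Where a printed total
#' differs from the selected+unselected sum, the fixture's re-entered totals
#' are used.
#'
#' @param counts fixture tibble with `sel_scb`, `sel_dscb`, `unsel_scb`,
#'   `unsel_dscb`, `total_scb`, `total_dscb`.
#' @return tibble with `pct_scb_selected`, `pct_scb_total`,
#'   `pct_dscb_total` appended.
#' @export
report_break_types <- function(counts = loh_counts("break_types")) {
  .stopifnot_cols(counts, c("sel_scb", "sel_dscb", "total_scb", "total_dscb"),
                  "`counts`")
  counts |>
    mutate(
      pct_scb_selected = round(100 * .data$sel_scb /
                                 (.data$sel_scb + .data$sel_dscb)),
      pct_scb_total = round(100 * .data$total_scb /
                              (.data$total_scb + .data$total_dscb)),
      pct_dscb_total = round(100 * .data$total_dscb /
                               (.data$total_scb + .data$total_dscb))
    )
}

#' Per-sector event averages and between-strain ratios
#'
#' Average numbers of interstitial, crossover, BIR and total LOH events per
#' sectored colony, and the ratio of a strain's per-sector crossover average
#' to a reference strain's (as a percentage).
#'
#' @param counts fixture tibble with `id`, `interstitial`, `crossovers`,
#'   `bir`, `total`, `sectors`.
#' @param ratio_id,ratio_ref ids of the strain and reference strain for the
#'   crossover ratio (defaults compare the resolvase mutant at its dose to
#'   wild-type at the equitoxic dose).
#' @return list: `table` (averages appended), `crossover_ratio_pct`.
#' @export
report_event_rates <- function(counts = loh_counts("event_counts"),
                               ratio_id = "mus81_15", ratio_ref = "WT_15") {
  .stopifnot_cols(counts, c("id", "interstitial", "crossovers", "bir",
                            "total", "sectors"), "`counts`")
  tab <- counts |>
    mutate(
      ave_interstitial = .data$interstitial / .data$sectors,
      ave_crossovers = .data$crossovers / .data$sectors,
      ave_bir = .data$bir / .data$sectors,
      ave_total = .data$total / .data$sectors
    )
  a <- tab$ave_crossovers[tab$id == ratio_id]
  b <- tab$ave_crossovers[tab$id == ratio_ref]
  list(table = tab,
       crossover_ratio_pct = round(100 * fold_change(a, b)))
}

#' Per-colony averages and fold changes for single-colony analyses
#'
#' For strains too UV-sensitive for the sectoring assay, LOH events are
#' scored in single colonies; this recomputes the per-colony averages and
#' each strain's fold change in average total LOH events relative to the
#' reference strain.
#'
#' @param counts fixture tibble with `id`, `interstitial`, `co_bir`,
#'   `total`, `colonies`.
#' @param ref_id reference strain id (default `"rad14"`).
#' @return tibble with `ave_interstitial`, `ave_co_bir`, `ave_total` and
#'   `fold_vs_ref` appended.
#' @export
report_single_colonies <- function(counts = loh_counts("single_colonies"),
                                   ref_id = "rad14") {
  .stopifnot_cols(counts, c("id", "interstitial", "co_bir", "total",
                            "colonies"), "`counts`")
  out <- counts |>
    mutate(
      ave_interstitial = .data$interstitial / .data$colonies,
      ave_co_bir = .data$co_bir / .data$colonies,
      ave_total = .data$total / .data$colonies
    )
  ref <- out$ave_total[out$id == ref_id]
  mutate(out, fold_vs_ref = format_fold(fold_change(.data$ave_total, ref)))
}

#' Full printed-table reproduction report
#'
#' Recomputes every derived column of the packaged count fixtures.
#'
#' @return named list of the four reproduced tables.
#' @export
loh_report <- function() {
  list(
    sectoring = report_sectoring(),
    break_types = report_break_types(),
    event_rates = report_event_rates(),
    single_colonies = report_single_colonies()
  )
}
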