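#' Pipeline run configuration
#'
#' Bundles every tunable of the simulate-genotype-classify-report pipeline.
#' All stochastic stages derive their seeds from the single master `seed`,
#' so a configuration fully determines the output. The configuration
#' round-trips losslessly through its YAML file form
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param seed master seed.
#' @param n_colonies sectored colonies to simulate.
#' @param n_markers markers in the map.
#' @param noise list of [noise_model()] arguments.
#' @param rates list of [event_rates()] arguments.
#' @param thresholds list of [calling_thresholds()] arguments.
#' @param flank,min_markers smoothing/segmentation parameters.
#' @param mad_constant MAD convention for the split rule (1 = raw).
#' @param keep_ratios write per-sector ratio tables (large; default TRUE).
#' @return list of class `loh_run_config`.
#' @export
run_config <- function(seed = 1, n_colonies = 12, n_markers = 13000,
                       noise = list(), rates = list(), thresholds = list(),
                       flank = 3, min_markers = 3, mad_constant = 1,
                       keep_ratios = TRUE) {
  cfg <- list(seed = as.integer(seed), n_colonies = as.integer(n_colonies),
              n_markers = as.integer(n_markers), noise = noise,
              rates = rates, thresholds = thresholds,
              flank = as.integer(flank), min_markers = as.integer(min_markers),
              mad_constant = mad_constant, keep_ratios = isTRUE(keep_ratios))
  # validate by construction
  do.call(noise_model, cfg$noise)
  do.call(event_rates, cfg$rates)
  do.call(calling_thresholds, cfg$thresholds)
  if (cfg$n_colonies < 1) abort("invalid config field: n_colonies")
  if (cfg$n_markers < 16) abort("invalid config field: n_markers")
  structure(cfg, class = "loh_run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg an `loh_run_config` (for writing).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) abort("config file must carry an explicit `seed` field")
  empty_list <- function(x) if (is.null(x) || length(x) == 0) list() else x
  run_config(seed = raw$seed, n_colonies = raw$n_colonies %||% 12,
             n_markers = raw$n_markers %||% 13000,
             noise = empty_list(raw$noise), rates = empty_list(raw$rates),
             thresholds = empty_list(raw$thresholds),
             flank = raw$flank %||% 3, min_markers = raw$min_markers %||% 3,
             mad_constant = raw$mad_constant %||% 1,
             keep_ratios = raw$keep_ratios %||% TRUE)
}

#' Write a TSV artifact with a provenance header
#'
#' Every pipeline output carries a comment header naming the package
#' version and the master seed that produced it.
#'
#' @param x data frame.
#' @param path output path.
#' @param seed master seed recorded in the header.
#' @export
write_loh_tsv <- function(x, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sectorloh %s; seed=%s",
                     as.character(packageVersion("sectorloh")), seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a pipeline TSV artifact
#'
#' @param path TSV path (provenance header lines are skipped).
#' @return tibble.
#' @export
read_loh_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Run the full pipeline: simulate, genotype, classify, report
#'
#' Simulates `n_colonies` sectored colonies on a fresh marker map, genotypes
#' and classifies each, and writes all artifacts (marker map, ratio tables,
#' segments, events, per-colony summaries, printed-table reproduction
#' report, and an enrichment table when element annotations are supplied)
#' under `out_dir`. Identical configurations produce bit-identical output
#' trees. On failure, partial outputs are removed.
#'
#' @param cfg an [run_config()].
#' @param out_dir output directory (created; must not exist or be empty).
#' @param elements optional element annotation tibble (`chrom`, `start`,
#'   `end`, `class`) for breakpoint enrichment.
#' @param quiet suppress progress messages.
#' @return invisibly, a list of the main result tables.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, elements = NULL,
                         quiet = FALSE) {
  if (!inherits(cfg, "loh_run_config")) abort("`cfg` must be a run_config()")
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    abort("`out_dir` exists and is not empty")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- TRUE
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE), add = TRUE)

  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  seed <- cfg$seed
  logf("sectorloh %s pipeline; master seed %d", packageVersion("sectorloh"), seed)
  logf("colonies=%d markers=%d flank=%d min_markers=%d mad_constant=%g",
       cfg$n_colonies, cfg$n_markers, cfg$flank, cfg$min_markers,
       cfg$mad_constant)

  genome <- loh_genome()
  noise <- do.call(noise_model, cfg$noise)
  rates <- do.call(event_rates, cfg$rates)
  thresholds <- do.call(calling_thresholds, cfg$thresholds)
  logf("noise: copy2=%g copy1=%g copy0=%g sigma=%g", noise$mean_copy2,
       noise$mean_copy1, noise$mean_copy0, noise$sigma)
  logf("thresholds: het=[%g,%g] hom_hi=%g hom_lo=%g", thresholds$het_lo,
       thresholds$het_hi, thresholds$hom_hi, thresholds$hom_lo)

  markers <- build_marker_map(genome, cfg$n_markers, seed = derive_seed(seed, 7L))
  write_loh_tsv(markers, file.path(out_dir, "marker_map.tsv"), seed)

  all_events <- list()
  all_planted <- list()
  all_segments <- list()
  for (i in seq_len(cfg$n_colonies)) {
    cid <- sprintf("colony%03d", i)
    sim <- simulate_colony(markers, genome, rates, noise,
                           seed = derive_seed(seed, 100L + i), colony = cid)
    if (cfg$keep_ratios) {
      for (sec in c("D1", "D2")) {
        write_loh_tsv(
          filter(sim$ratios, .data$sector == sec),
          file.path(out_dir, sprintf("ratios_%s_%s.tsv", cid, sec)), seed)
      }
    }
    g1 <- genotype_sample(filter(sim$ratios, .data$sector == "D1"),
                          thresholds, cfg$flank, cfg$min_markers)
    g2 <- genotype_sample(filter(sim$ratios, .data$sector == "D2"),
                          thresholds, cfg$flank, cfg$min_markers)
    ev <- classify_colony(g1$segments, g2$segments, markers, colony = cid,
                          genome = genome, ratios = sim$ratios, noise = noise,
                          mad_constant = cfg$mad_constant)
    all_events[[i]] <- ev
    all_planted[[i]] <- sim$events
    all_segments[[i]] <- bind_rows(
      mutate(g1$segments, colony = cid, .before = 1),
      mutate(g2$segments, colony = cid, .before = 1)
    )
    logf("%s: %d planted events, %d classified", cid,
         nrow(sim$events), nrow(ev))
  }
  events <- bind_rows(all_events)
  planted <- bind_rows(all_planted)
  segments <- bind_rows(all_segments)
  summaries <- if (nrow(events)) summarize_colony(events) else
    tibble(colony = character())

  write_loh_tsv(planted, file.path(out_dir, "planted_events.tsv"), seed)
  write_loh_tsv(segments, file.path(out_dir, "segments.tsv"), seed)
  write_loh_tsv(events, file.path(out_dir, "events.tsv"), seed)
  write_loh_tsv(summaries, file.path(out_dir, "colony_summaries.tsv"), seed)

  rep <- loh_report()
  write_loh_tsv(rep$sectoring, file.path(out_dir, "report_sectoring.tsv"), seed)
  write_loh_tsv(rep$break_types, file.path(out_dir, "report_break_types.tsv"), seed)
  write_loh_tsv(rep$event_rates$table,
                file.path(out_dir, "report_event_rates.tsv"), seed)
  write_loh_tsv(rep$single_colonies,
                file.path(out_dir, "report_single_colonies.tsv"), seed)

  enr <- NULL
  if (!is.null(elements) && nrow(events)) {
    mask <- coverage_mask(genome)
    regions <- derive_breakpoint_regions(events, mask)
    enr <- enrichment_table(elements, regions, mask)
    write_loh_tsv(enr, file.path(out_dir, "enrichment.tsv"), seed)
    logf("enrichment: %d classes tested", sum(enr$tested))
  }
  logf("pipeline complete: %d events in %d colonies", nrow(events),
       cfg$n_colonies)
  ok <- TRUE
  invisible(list(markers = markers, planted = planted, events = events,
                 summaries = summaries, report = rep, enrichment = enr))
}
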