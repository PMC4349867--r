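# Hand-laid sector patterns on an evenly spaced one-chromosome map.
tiny_pair <- function(st1, st2, n = length(st1)) {
  mm <- even_markers(n)
  list(markers = mm,
       d1 = segments_from_states(mm, st1, min_markers = 1),
       d2 = segments_from_states(mm, st2, min_markers = 1))
}

test_that("sector matching produces joint blocks at the union of breakpoints", {
  p <- tiny_pair(rep("HET", 40), rep("HET", 40))
  b <- match_sectors(p$d1, p$d2, p$markers)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$state_d1, b$state_d2), c("HET", "HET"))

  # identical transition position in the two sectors
  st1 <- c(rep("HET", 20), rep("HOM_W", 20))
  st2 <- c(rep("HET", 20), rep("HOM_Y", 20))
  p <- tiny_pair(st1, st2)
  b <- match_sectors(p$d1, p$d2, p$markers)
  expect_equal(nrow(b), 2)
  expect_equal(b$state_d1, c("HET", "HOM_W"))
  expect_equal(b$state_d2, c("HET", "HOM_Y"))

  # 3 segments vs 2: blocks split at the union of the breakpoints
  st1 <- c(rep("HET", 10), rep("HOM_W", 15), rep("HET", 15))
  st2 <- c(rep("HET", 30), rep("HOM_Y", 10))
  p <- tiny_pair(st1, st2)
  b <- match_sectors(p$d1, p$d2, p$markers)
  expect_lte(nrow(b), 4)
  expect_equal(nrow(b), 4)
})

test_that("mismatched marker maps are rejected", {
  p <- tiny_pair(rep("HET", 20), rep("HET", 20))
  other <- even_markers(20, len = 5e5)
  other$id <- sprintf("x%04d", 1:20)
  expect_error(match_sectors(p$d1, p$d2, other), "marker map")
})

test_that("crossover patterns classify per the sectored-colony taxonomy", {
  g <- single_chrom_genome()
  n <- 60
  # simple crossover: identical transition, opposite distal haplotypes
  p <- tiny_pair(c(rep("HET", 30), rep("HOM_W", 30)),
                 c(rep("HET", 30), rep("HOM_Y", 30)))
  ev <- classify_colony(p$d1, p$d2, p$markers, genome = g)
  expect_equal(ev$class, "CO_SIMPLE")
  expect_equal(ev$break_type, "UNCLASSIFIED")
  expect_equal(ev$category, "CROSSOVER")

  # 3:1: donor homozygosity extends the tract in one sector only
  p <- tiny_pair(c(rep("HET", 30), rep("HOM_W", 30)),
                 c(rep("HET", 40), rep("HOM_Y", 20)))
  ev <- classify_colony(p$d1, p$d2, p$markers, genome = g)
  expect_equal(ev$class, "CO_3TO1")
  expect_equal(ev$break_type, "SCB")
  expect_equal(ev$donor, "W")
  expect_equal(ev$sector, "D1")

  # 4:0: the whole tract is donor-homozygous in both sectors
  p <- tiny_pair(c(rep("HET", 30), rep("HOM_W", 30)),
                 c(rep("HET", 30), rep("HOM_W", 10), rep("HOM_Y", 20)))
  ev <- classify_colony(p$d1, p$d2, p$markers, genome = g)
  expect_equal(ev$class, "CO_4TO0")
  expect_equal(ev$break_type, "DSCB")

  # hybrid: one-sector part proximal, shared part adjacent to the exchange
  p <- tiny_pair(c(rep("HET", 25), rep("HOM_W", 35)),
                 c(rep("HET", 32), rep("HOM_W", 8), rep("HOM_Y", 20)))
  ev <- classify_colony(p$d1, p$d2, p$markers, genome = g)
  expect_equal(ev$class, "CO_HYBRID")
  expect_equal(ev$break_type, "DSCB")
})

test_that("one-sector patterns classify as BIR (terminal) or NCO (interstitial)", {
  g <- single_chrom_genome()
  p <- tiny_pair(c(rep("HET", 40), rep("HOM_W", 20)), rep("HET", 60))
  ev <- classify_colony(p$d1, p$d2, p$markers, genome = g)
  expect_equal(ev$class, "BIR_TERMINAL")
  expect_equal(ev$category, "BIR")
  expect_match(ev$flags, "possible_second_division_crossover")

  p <- tiny_pair(c(rep("HET", 20), rep("HOM_W", 6), rep("HET", 34)),
                 rep("HET", 60))
  ev <- classify_colony(p$d1, p$d2, p$markers, genome = g)
  expect_equal(ev$class, "NCO_INTERSTITIAL")
  expect_equal(ev$category, "INTERSTITIAL")
  expect_equal(ev$pattern, "3:1")
  expect_equal(ev$break_type, "SCB")
})

test_that("left-arm terminal events mirror the right-arm logic", {
  g <- single_chrom_genome()
  p <- tiny_pair(c(rep("HOM_W", 25), rep("HET", 35)),
                 c(rep("HOM_Y", 20), rep("HET", 40)))
  ev <- classify_colony(p$d1, p$d2, p$markers, genome = g)
  expect_equal(ev$class, "CO_3TO1")
  expect_equal(ev$side, "left")
  expect_equal(ev$donor, "W")
})

test_that("deletions and single-colony terminal LOH are categorized separately", {
  g <- single_chrom_genome()
  p <- tiny_pair(c(rep("HET", 20), rep("DEL_W", 5), rep("HET", 35)),
                 rep("HET", 60))
  ev <- classify_colony(p$d1, p$d2, p$markers, genome = g)
  expect_equal(ev$class, "DELETION")
  expect_equal(ev$donor, "W")
  expect_equal(ev$category, "OTHER")

  # single-colony mode: terminal LOH pools crossovers and BIR
  mm <- even_markers(60)
  d1 <- segments_from_states(mm, c(rep("HET", 40), rep("HOM_Y", 20)))
  ev <- classify_colony(d1, NULL, mm, genome = g)
  expect_equal(ev$class, "TERMINAL_LOH")
  expect_equal(ev$category, "CO_BIR")
  d2 <- segments_from_states(mm, c(rep("HET", 20), rep("HOM_Y", 6),
                                   rep("HET", 34)))
  ev2 <- classify_colony(d2, NULL, mm, genome = g)
  expect_equal(ev2$class, "NCO_INTERSTITIAL")
  expect_equal(ev2$category, "INTERSTITIAL")
})

test_that("aneuploidy is detected from summed channel ratios", {
  mm <- even_markers(200)
  g <- single_chrom_genome()
  for (cp in c(1, 3)) {
    ev <- tibble::tibble(chrom = "chrT", class = "ANEUPLOIDY", start = 1,
                         end = 1e6, donor = "W", sector = "D1", copies = cp)
    tr <- plant_events(mm, ev, g)
    rt <- simulate_ratios(tr$truth, noise_model(), seed = cp)
    an <- detect_aneuploidy(rt)
    expect_equal(nrow(an), 1)
    expect_equal(an$sector, "D1")
    expect_equal(an$copies, as.integer(cp))
    expect_equal(an$donor, "W")
  }
  # disomic colonies are never flagged
  tr0 <- plant_events(mm, NULL, g)
  rt0 <- simulate_ratios(tr0$truth, noise_model(), seed = 5)
  expect_equal(nrow(detect_aneuploidy(rt0)), 0)
})

test_that("break-type assignment follows the conversion-pattern diagnosis", {
  ev <- tibble::tibble(
    class = c("CO_3TO1", "CO_4TO0", "CO_HYBRID", "CO_SIMPLE",
              "NCO_INTERSTITIAL", "NCO_INTERSTITIAL", "BIR_TERMINAL"),
    pattern = c("3:1", "4:0", "hybrid", NA, "3:1", "4:0", NA)
  )
  out <- assign_break_type(ev)
  expect_equal(out$break_type,
               c("SCB", "DSCB", "DSCB", "UNCLASSIFIED", "SCB", "DSCB", NA))
})

test_that("the split rule separates distant blocks and merges close ones", {
  base <- tibble::tibble(
    colony = "c1", chrom = "chrT", class = "NCO_INTERSTITIAL",
    category = "INTERSTITIAL", break_type = "SCB", donor = "W", sector = "D1",
    pattern = "3:1", region_start = NA_real_, region_end = NA_real_,
    tract_kb = c(5, 5), side = NA_character_, n_markers = 5L, flags = ""
  )
  far <- dplyr::mutate(base, tract_start = c(1e5, 1.55e5),
                       tract_end = c(1.05e5, 1.6e5))  # 50 kb gap
  near <- dplyr::mutate(base, tract_start = c(1e5, 1.07e5),
                        tract_end = c(1.05e5, 1.12e5))  # 2 kb gap
  out_far <- split_distant_events(far, tract_median = 6.4, tract_mad = 3)
  out_near <- split_distant_events(near, tract_median = 6.4, tract_mad = 3)
  expect_equal(nrow(out_far), 2)
  expect_equal(nrow(out_near), 1)
  expect_equal(out_near$tract_start, 1e5)
  expect_equal(out_near$tract_end, 1.12e5)
  expect_match(out_near$flags, "merged_nearby_block")
})

test_that("event count is monotone non-increasing in the split threshold", {
  # exhaustive over all gap layouts of 4 blocks on a small grid
  gaps_grid <- expand.grid(g1 = c(1, 5, 20), g2 = c(1, 5, 20), g3 = c(1, 5, 20))
  for (i in seq_len(nrow(gaps_grid))) {
    gaps <- as.numeric(gaps_grid[i, ]) * 1000
    starts <- cumsum(c(1e5, 3000 + gaps))
    ev <- tibble::tibble(
      colony = "c1", chrom = "chrT", class = "NCO_INTERSTITIAL",
      category = "INTERSTITIAL", break_type = "SCB", donor = "W",
      sector = "D1", pattern = "3:1",
      tract_start = starts, tract_end = starts + 3000,
      region_start = NA_real_, region_end = NA_real_, tract_kb = 3,
      side = NA_character_, n_markers = 4L, flags = ""
    )
    counts <- vapply(c(0, 1, 2.5, 6, 11, 25), function(thr) {
      nrow(split_distant_events(ev, tract_median = thr, tract_mad = 0))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("split threshold uses median + 2 * MAD with selectable convention", {
  lens <- c(2, 4, 6, 8, 20)
  expect_equal(split_threshold_kb(lens), 6 + 2 * 2)  # raw MAD = 2
  expect_equal(split_threshold_kb(lens, mad_constant = 1.4826),
               6 + 2 * stats::mad(lens))
})

test_that("colony summaries count categories with exclusions", {
  ev <- tibble::tibble(
    colony = "c1",
    chrom = c("chrI", "chrII", "chrIII", "chrV", "chrV"),
    class = c("CO_3TO1", "NCO_INTERSTITIAL", "BIR_TERMINAL", "CO_SIMPLE",
              "DELETION"),
    category = c("CROSSOVER", "INTERSTITIAL", "BIR", "CROSSOVER", "OTHER")
  )
  s <- summarize_colony(ev)
  expect_equal(s$n_interstitial, 1)
  expect_equal(s$n_crossover, 2)
  expect_equal(s$n_bir, 1)
  expect_equal(s$n_total, 4)
  expect_equal(s$n_deletion, 1)
  # excluding the selected chromosome drops its events
  s2 <- summarize_colony(ev, exclude_chrom = "chrV")
  expect_equal(s2$n_crossover, 1)
  expect_equal(s2$n_total, 3)
  expect_equal(nrow(summarize_colony(ev[0, ])), 0)
})

test_that("reported crossovers always have opposite distal haplotypes", {
  mm <- build_marker_map(n_markers = 3000, seed = 6)
  for (s in 1:6) {
    sim <- simulate_colony(mm, seed = s, colony = "c",
                           noise = noise_model(sigma = 0))
    g1 <- genotype_sample(dplyr::filter(sim$ratios, sector == "D1"))
    g2 <- genotype_sample(dplyr::filter(sim$ratios, sector == "D2"))
    ev <- classify_colony(g1$segments, g2$segments, mm, ratios = sim$ratios)
    co <- ev[ev$category == "CROSSOVER", ]
    for (i in seq_len(nrow(co))) {
      b <- match_sectors(g1$segments, g2$segments, mm)
      last <- if (is.na(co$side[i]) || co$side[i] == "right") {
        dplyr::slice_tail(dplyr::filter(b, chrom == co$chrom[i]), n = 1)
      } else {
        dplyr::slice_head(dplyr::filter(b, chrom == co$chrom[i]), n = 1)
      }
      expect_true(grepl("^HOM_", last$state_d1))
      expect_true(grepl("^HOM_", last$state_d2))
      expect_false(last$state_d1 == last$state_d2)
    }
  }
})
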