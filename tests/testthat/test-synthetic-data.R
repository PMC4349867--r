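test_that("marker maps have forced counts, valid positions, proportional allocation", {
  mm <- build_marker_map(loh_genome(), n_markers = 13000, seed = 1)
  expect_equal(nrow(mm), 13000)
  expect_setequal(unique(mm$chrom), loh_genome()$chrom)
  glen <- setNames(loh_genome()$length, loh_genome()$chrom)
  expect_true(all(mm$pos >= 1 & mm$pos <= glen[mm$chrom]))
  # sorted, unique within chromosome
  by_chrom <- split(mm$pos, mm$chrom)
  expect_true(all(vapply(by_chrom, function(p) !is.unsorted(p, strictly = TRUE),
                         logical(1))))
  # allocation tracks chromosome length
  cnt <- table(mm$chrom)[loh_genome()$chrom]
  expect_gt(cor(as.numeric(cnt), loh_genome()$length), 0.999)
})

test_that("exhaustive placement fills a saturated chromosome", {
  g <- tibble::tibble(chrom = "chr1", length = 1000L, cen = 500L)
  mm <- build_marker_map(g, n_markers = 1000, seed = 0)
  expect_equal(mm$pos, 1:1000)
})

test_that("marker maps are seed-deterministic with seed-independent allocation", {
  a <- build_marker_map(n_markers = 2000, seed = 7)
  b <- build_marker_map(n_markers = 2000, seed = 7)
  c <- build_marker_map(n_markers = 2000, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$pos, c$pos))
  expect_identical(table(a$chrom), table(c$chrom))
})

test_that("marker map sizing errors are raised", {
  g <- tibble::tibble(chrom = "chr1", length = 100L, cen = 50L)
  expect_error(build_marker_map(g, n_markers = 101, seed = 1), "exceeds")
  expect_error(build_marker_map(loh_genome(), n_markers = 10, seed = 1),
               "per chromosome")
})

test_that("no planted events yields an all-heterozygous truth", {
  mm <- even_markers(50)
  tr <- plant_events(mm, NULL, single_chrom_genome())
  expect_true(all(tr$truth$state == "HET"))
  expect_true(all(tr$truth$cn_w == 1 & tr$truth$cn_y == 1))
  expect_equal(nrow(tr$events), 0)
})

test_that("a simple crossover flips the two daughters reciprocally", {
  mm <- even_markers(100)
  ev <- tibble::tibble(chrom = "chrT", class = "CO_SIMPLE",
                       start = 5e5, end = 5e5)
  tr <- plant_events(mm, ev, single_chrom_genome())
  d1 <- dplyr::filter(tr$truth, sector == "D1")
  d2 <- dplyr::filter(tr$truth, sector == "D2")
  expect_true(all(d1$state[d1$pos > 5e5] == "HOM_W"))
  expect_true(all(d2$state[d2$pos > 5e5] == "HOM_Y"))
  expect_true(all(d1$state[d1$pos <= 5e5] == "HET"))
  expect_true(all(d2$state[d2$pos <= 5e5] == "HET"))
})

test_that("BIR is terminal homozygosity in exactly one sector", {
  mm <- even_markers(100)
  ev <- tibble::tibble(chrom = "chrT", class = "BIR_TERMINAL",
                       start = 7e5, end = 1e6, donor = "W", sector = "D1")
  tr <- plant_events(mm, ev, single_chrom_genome())
  d1 <- dplyr::filter(tr$truth, sector == "D1")
  d2 <- dplyr::filter(tr$truth, sector == "D2")
  expect_true(all(d1$state[d1$pos >= 7e5] == "HOM_W"))
  expect_true(all(d1$state[d1$pos < 7e5] == "HET"))
  expect_true(all(d2$state == "HET"))
})

test_that("planted crossover patterns realize the 3:1 / 4:0 / hybrid allele counts", {
  mm <- even_markers(200)
  g <- single_chrom_genome()
  for (cls in c("CO_3TO1", "CO_4TO0", "CO_HYBRID")) {
    ev <- tibble::tibble(chrom = "chrT", class = cls, start = 5e5, end = 6e5,
                         donor = "W", sector = "D1")
    tr <- plant_events(mm, ev, g)
    wide <- tidyr::pivot_wider(tr$truth[, c("sector", "pos", "cn_w")],
                               names_from = "sector", values_from = "cn_w")
    tract <- wide[wide$pos >= 5e5 & wide$pos <= 6e5, ]
    donor_copies <- tract$D1 + tract$D2
    if (cls == "CO_3TO1") expect_true(all(donor_copies == 3))
    if (cls == "CO_4TO0") expect_true(all(donor_copies == 4))
    if (cls == "CO_HYBRID") expect_setequal(unique(donor_copies), c(3, 4))
    # reciprocal distal to the tract
    distal <- wide[wide$pos > 6e5, ]
    expect_true(all(distal$D1 == 2 & distal$D2 == 0))
  }
})

test_that("event validation rejects overlap and warns on empty tracts", {
  mm <- even_markers(100)
  g <- single_chrom_genome()
  ev <- tibble::tibble(chrom = c("chrT", "chrT"),
                       class = c("NCO_INTERSTITIAL", "NCO_INTERSTITIAL"),
                       start = c(1e5, 1.5e5), end = c(2e5, 2.5e5))
  expect_error(plant_events(mm, ev, g), "overlap")
  # tract between two adjacent markers -> zero markers, retained with warning
  gap_ev <- tibble::tibble(chrom = "chrT", class = "NCO_INTERSTITIAL",
                           start = mm$pos[10] + 1, end = mm$pos[11] - 1)
  expect_warning(tr <- plant_events(mm, gap_ev, g), "no markers")
  expect_equal(nrow(tr$events), 1)
})

test_that("noiseless ratios hit the channel means exactly", {
  mm <- even_markers(10)
  g <- single_chrom_genome()
  ev <- tibble::tibble(chrom = "chrT", class = "NCO_INTERSTITIAL",
                       start = 4e5, end = 6e5, donor = "W", sector = "D1")
  tr <- plant_events(mm, ev, g)
  rt <- simulate_ratios(tr$truth, noise_model(sigma = 0), seed = 1)
  het <- rt[tr$truth$state == "HET", ]
  hom <- rt[tr$truth$state == "HOM_W", ]
  expect_true(all(het$ratio_w == 1.0 & het$ratio_y == 1.0))
  expect_true(all(hom$ratio_w == 1.8 & hom$ratio_y == 0.2))
})

test_that("lognormal noise is centred: mean log-ratio within 3 SE of 0", {
  g <- tibble::tibble(chrom = "chr1", length = 2e7L, cen = 1e7L)
  mm <- build_marker_map(g, n_markers = 10000, seed = 3)
  tr <- plant_events(mm, NULL, g)
  sigma <- 0.1
  rt <- simulate_ratios(tr$truth, noise_model(sigma = sigma), seed = 42)
  lw <- log(rt$ratio_w)  # HET: mean 1.0, so log-ratio ~ N(0, sigma)
  se <- sigma / sqrt(length(lw))
  expect_lt(abs(mean(lw)), 3 * se)
  expect_equal(sd(lw), sigma, tolerance = 0.05)
})

test_that("negative noise sigma is rejected", {
  expect_error(noise_model(sigma = -0.1), "sigma")
  expect_error(noise_model(mean_copy2 = 0.5), "mean")
})

test_that("simulation is bit-identical under a fixed seed", {
  mm <- build_marker_map(n_markers = 1000, seed = 2)
  a <- simulate_colony(mm, seed = 9, colony = "c1")
  b <- simulate_colony(mm, seed = 9, colony = "c1")
  expect_identical(a, b)
  c <- simulate_colony(mm, seed = 10, colony = "c1")
  expect_false(identical(a$ratios, c$ratios))
})

test_that("rate-mode colonies plant detectable tracts and honour reciprocity", {
  mm <- build_marker_map(n_markers = 4000, seed = 4)
  for (s in 1:5) {
    sim <- simulate_colony(mm, seed = s, colony = sprintf("c%d", s))
    ev <- sim$events
    conv <- ev[ev$class %in% c("CO_3TO1", "CO_4TO0", "CO_HYBRID",
                               "NCO_INTERSTITIAL"), ]
    if (nrow(conv)) {
      n_in <- mapply(function(ch, s0, e0) {
        sum(mm$chrom == ch & mm$pos >= s0 & mm$pos <= e0)
      }, conv$chrom, conv$start, conv$end)
      expect_true(all(n_in >= 3))
    }
    # reciprocity: distal to every crossover the two sectors carry opposite
    # haplotypes
    co <- ev[grepl("^CO_", ev$class), ]
    for (i in seq_len(nrow(co))) {
      distal <- if (co$side[i] == "right") {
        dplyr::filter(sim$truth, chrom == co$chrom[i], pos > co$end[i])
      } else {
        dplyr::filter(sim$truth, chrom == co$chrom[i], pos < co$start[i])
      }
      wide <- tidyr::pivot_wider(distal[, c("sector", "pos", "state")],
                                 names_from = "sector", values_from = "state")
      expect_true(all(wide$D1 != wide$D2))
      expect_true(all(grepl("^HOM_", wide$D1) & grepl("^HOM_", wide$D2)))
    }
  }
})
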