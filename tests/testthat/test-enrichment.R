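test_that("BED intervals convert to the 1-based inclusive frame", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t0\t100\ttRNA", "chrII\t999\t2000\ttRNA"), path)
  bed <- read_bed(path)
  expect_equal(bed$start, c(1L, 1000L))
  expect_equal(bed$end, c(100L, 2000L))
  expect_equal(bed$class, c("tRNA", "tRNA"))
})

test_that("interval merging and mask clipping behave like set operations", {
  x <- tibble::tibble(chrom = c("chrT", "chrT", "chrT"),
                      start = c(100, 150, 400), end = c(200, 250, 500))
  m <- merge_intervals(x)
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(100, 400))
  expect_equal(m$end, c(250, 500))

  mask <- tibble::tibble(chrom = "chrT", start = 180, end = 450)
  clipped <- clip_to_mask(x, mask)
  expect_equal(sum(clipped$end - clipped$start + 1),
               (250 - 180 + 1) + (450 - 400 + 1))
})

test_that("breakpoint regions follow the flanking-marker rule and the mask", {
  ev <- tibble::tibble(
    colony = "c1", chrom = "chrT",
    class = c("NCO_INTERSTITIAL", "CO_SIMPLE"),
    region_start = c(99000, 200000), region_end = c(106000, 201000),
    tract_start = c(100000, NA), tract_end = c(105000, NA)
  )
  mask <- tibble::tibble(chrom = "chrT", start = 1, end = 1e6)
  reg <- derive_breakpoint_regions(ev, mask, mode = "conversion")
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(99000, 106000))
  reg_all <- derive_breakpoint_regions(ev, mask, mode = "all")
  expect_equal(nrow(reg_all), 2)

  # clipping to a mask boundary
  mask2 <- tibble::tibble(chrom = "chrT", start = 102000, end = 1e6)
  reg2 <- derive_breakpoint_regions(ev, mask2, mode = "conversion")
  expect_equal(c(reg2$start, reg2$end), c(102000, 106000))

  # region entirely outside the mask is dropped
  mask3 <- tibble::tibble(chrom = "chrT", start = 5e5, end = 1e6)
  reg3 <- derive_breakpoint_regions(ev, mask3, mode = "conversion")
  expect_equal(nrow(reg3), 0)
  expect_equal(attr(reg3, "dropped"), 1)
})

test_that("overlap counting matches a brute-force per-element scan", {
  set.seed(6)
  for (i in 1:10) {
    regions <- tibble::tibble(
      chrom = "chrT",
      start = sort(sample.int(9e5, 10)) )
    regions$end <- regions$start + sample.int(2e4, 10)
    el_start <- sample.int(9.5e5, 40)
    elements <- tibble::tibble(chrom = "chrT", start = el_start,
                               end = el_start + sample.int(5e3, 40))
    got <- count_overlaps(regions, elements)
    el_m <- merge_intervals(elements)
    brute <- sum(vapply(seq_len(nrow(el_m)), function(j) {
      any(el_m$start[j] <= regions$end & el_m$end[j] >= regions$start)
    }, logical(1)))
    expect_equal(got, brute)
  }
  expect_equal(count_overlaps(tibble::tibble(chrom = character(),
                                             start = numeric(),
                                             end = numeric()),
                              tibble::tibble(chrom = "chrT", start = 1,
                                             end = 10)), 0L)
})

test_that("observed counts are invariant to splitting regions into sub-regions", {
  regions <- tibble::tibble(chrom = "chrT", start = 1000, end = 5000)
  halves <- tibble::tibble(chrom = "chrT", start = c(1000, 3001),
                           end = c(3000, 5000))
  elements <- tibble::tibble(chrom = "chrT", start = c(500, 2900, 4800),
                             end = c(900, 3200, 6000))
  expect_equal(count_overlaps(regions, elements),
               count_overlaps(halves, elements))
})

test_that("expected counts are length-proportional and additive", {
  mask <- tibble::tibble(chrom = "chrT", start = 1, end = 1e6)
  elements <- tibble::tibble(chrom = "chrT",
                             start = seq(1000, 991000, by = 10000))
  elements$end <- elements$start + 100
  regions <- tibble::tibble(chrom = "chrT", start = 1, end = 1e5)
  expect_equal(expected_count(elements, regions, mask), 100 * 0.1)
  # fraction 1 recovers the full element count
  expect_equal(expected_count(elements, mask, mask), 100)
  # zero-length region set
  expect_equal(expected_count(elements, regions[0, ], mask), 0)
  # additivity over a disjoint partition of the regions
  parts <- tibble::tibble(chrom = "chrT", start = c(1, 50001),
                          end = c(50000, 1e5))
  expect_equal(expected_count(elements, parts[1, ], mask) +
                 expected_count(elements, parts[2, ], mask),
               expected_count(elements, parts, mask))
  expect_error(expected_count(elements, regions, mask[0, ]), "zero total")
})

test_that("step-up FDR adjustment matches hand computation and p.adjust", {
  expect_equal(multiple_test_correction(0.04), 0.04)
  expect_equal(multiple_test_correction(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(multiple_test_correction(rep(1, 5)), rep(1, 5))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(multiple_test_correction(p), p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
  # monotone non-decreasing in raw-p rank order
  p <- runif(25)
  adj <- multiple_test_correction(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(multiple_test_correction(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted enrichment is detected as over-representation", {
  mask <- tibble::tibble(chrom = "chrT", start = 1, end = 1e6)
  regions <- tibble::tibble(chrom = "chrT", start = 1, end = 1e5)  # 10% of mask
  set.seed(8)
  inside <- tibble::tibble(chrom = "chrT",
                           start = sort(sample.int(95000, 25)))
  inside$end <- inside$start + 50
  outside_start <- sort(sample(150000:990000, 30))
  spread <- tibble::tibble(chrom = "chrT", start = outside_start,
                           end = outside_start + 50)
  elements <- dplyr::bind_rows(dplyr::mutate(inside, class = "planted"),
                               dplyr::mutate(spread, class = "background"))
  tab <- enrichment_table(elements, regions, mask)
  planted <- tab[tab$class == "planted", ]
  expect_equal(planted$direction, "over")
  expect_lt(planted$p, 1e-6)
  expect_true(all(tab$p_adj >= tab$p, na.rm = TRUE))
  # class with no elements in the mask is untested
  far <- tibble::tibble(chrom = "chrZ", start = 1, end = 10, class = "absent")
  tab2 <- enrichment_table(dplyr::bind_rows(elements, far), regions, mask)
  expect_false(tab2$tested[tab2$class == "absent"])
})

test_that("permutation expectation agrees with the closed form", {
  mask <- tibble::tibble(chrom = "chrT", start = 1, end = 1e6)
  regions <- tibble::tibble(chrom = "chrT",
                            start = seq(1e4, 9.1e5, by = 1e5))
  regions$end <- regions$start + 1e4
  set.seed(9)
  st <- sort(sample.int(9.9e5, 60))
  elements <- tibble::tibble(chrom = "chrT", start = st, end = st + 100)
  perm <- permutation_expected(elements, regions, mask, n_shuffle = 400,
                               seed = 2)
  closed <- expected_count(elements, regions, mask)
  expect_lt(abs(perm$mean_overlap - closed),
            4 * perm$sd_overlap / sqrt(400) + 0.5)
})

test_that("interval set operations match the IRanges oracle on random sets", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    x <- tibble::tibble(chrom = sample(c("chrA", "chrB", "chrC"), n, TRUE),
                        start = sample.int(1000, n, TRUE))
    x$end <- x$start + sample.int(60, n, TRUE)
    m <- merge_intervals(x)
    ir <- lapply(split(IRanges::IRanges(x$start, x$end), x$chrom),
                 IRanges::reduce)
    ref <- dplyr::bind_rows(lapply(names(ir), function(ch) {
      tibble::tibble(chrom = ch, start = IRanges::start(ir[[ch]]),
                     end = IRanges::end(ir[[ch]]))
    }))
    ref <- dplyr::arrange(ref, chrom, start)
    expect_equal(m$chrom, ref$chrom)
    expect_equal(m$start, ref$start)
    expect_equal(m$end, as.numeric(ref$end))

    mask <- tibble::tibble(chrom = c("chrA", "chrB"),
                           start = c(100, 200), end = c(600, 800))
    cl <- clip_to_mask(x, mask)
    ref2 <- dplyr::bind_rows(lapply(1:2, function(k) {
      ch <- mask$chrom[k]
      xi <- IRanges::reduce(IRanges::IRanges(x$start[x$chrom == ch],
                                             x$end[x$chrom == ch]))
      ii <- IRanges::intersect(xi, IRanges::IRanges(mask$start[k], mask$end[k]))
      tibble::tibble(chrom = ch, start = IRanges::start(ii),
                     end = IRanges::end(ii))
    }))
    expect_equal(nrow(cl), nrow(ref2))
    expect_equal(cl$start, ref2$start)
    expect_equal(cl$end, as.numeric(ref2$end))
  }
})
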