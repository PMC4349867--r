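# Interval tables are tibbles (chrom, start, end), 1-based inclusive.
# The set operations below are vectorised base-R implementations (sort +
# running max), fast enough to run thousands of enrichment datasets; the
# test suite cross-checks them against IRanges reduce/intersect.

.empty_intervals <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric())
}

#' Merge overlapping intervals
#'
#' Overlapping or bookended (zero-gap) intervals on one chromosome are
#' collapsed into one.
#'
#' @param x interval tibble (`chrom`, `start`, `end`).
#' @return tibble of disjoint, sorted intervals.
#' @export
merge_intervals <- function(x) {
  .stopifnot_cols(x, c("chrom", "start", "end"), "`x`")
  n <- nrow(x)
  if (n == 0) return(x[, c("chrom", "start", "end")])
  o <- order(x$chrom, x$start, x$end)
  ch <- x$chrom[o]; s <- x$start[o]; e <- x$end[o]
  run_max <- stats::ave(e, ch, FUN = cummax)
  new_grp <- c(TRUE, ch[-1] != ch[-n] | s[-1] > run_max[-n] + 1)
  last <- c(new_grp[-1], TRUE)  # last row of each merged group
  tibble(chrom = ch[new_grp], start = s[new_grp], end = run_max[last])
}

#' Intersect intervals with a coverage mask
#'
#' @param x interval tibble.
#' @param mask mask tibble of intervals (merged internally).
#' @return tibble of the piecewise intersections, disjoint and sorted (an
#'   interval straddling a mask boundary is clipped; one entirely outside
#'   the mask is dropped).
#' @export
clip_to_mask <- function(x, mask) {
  if (!nrow(x)) return(x[, c("chrom", "start", "end")])
  xm <- merge_intervals(x)
  mm <- merge_intervals(mask)
  pieces <- list()
  for (ch in intersect(unique(xm$chrom), unique(mm$chrom))) {
    xs <- xm$start[xm$chrom == ch]; xe <- xm$end[xm$chrom == ch]
    ms <- mm$start[mm$chrom == ch]; me <- mm$end[mm$chrom == ch]
    for (j in seq_along(ms)) {
      lo <- pmax(xs, ms[j]); hi <- pmin(xe, me[j])
      keep <- lo <= hi
      if (any(keep)) {
        pieces[[length(pieces) + 1]] <-
          tibble(chrom = ch, start = lo[keep], end = hi[keep])
      }
    }
  }
  if (!length(pieces)) return(.empty_intervals())
  arrange(bind_rows(pieces), .data$chrom, .data$start)
}

.total_width <- function(x) {
  if (!nrow(x)) return(0)
  sum(as.numeric(x$end) - as.numeric(x$start) + 1)
}

#' Read a BED file into the package's 1-based interval frame
#'
#' BED input is 0-based, half-open; intervals are converted to 1-based
#' inclusive coordinates on load. A class label is taken from `class_col`
#' (BED name column) when present.
#'
#' @param path BED file path.
#' @param class_col column index holding the element class (default 4);
#'   ignored when the file has fewer columns.
#' @return tibble `chrom`, `start`, `end` and, when available, `class`.
#' @export
read_bed <- function(path, class_col = 4) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 3) abort("BED file must have at least 3 columns")
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]])
  )
  if (ncol(raw) >= class_col) out$class <- as.character(raw[[class_col]])
  out
}

#' Derive breakpoint localisation regions from classified events
#'
#' The DNA lesion initiating a recombination event lies near the transitions
#' between heterozygous and homozygous markers. For conversion-bearing events
#' the region is the interval between the heterozygous sites flanking the
#' conversion tract; for crossovers without a detectable conversion it is the
#' transition uncertainty interval. Regions are clipped to the array coverage
#' mask; events falling entirely outside it are dropped (and recorded in the
#' `dropped` attribute).
#'
#' @param events classified event tibble from [classify_colony()].
#' @param mask coverage mask tibble, e.g. [coverage_mask()].
#' @param mode `"conversion"` uses only conversion-bearing events;
#'   `"all"` additionally includes simple-crossover and BIR transition
#'   intervals.
#' @return interval tibble of breakpoint regions (clipped to the mask), with
#'   attribute `total_bp`.
#' @export
derive_breakpoint_regions <- function(events, mask,
                                      mode = c("conversion", "all")) {
  mode <- match.arg(mode)
  conv <- c("CO_3TO1", "CO_4TO0", "CO_HYBRID", "NCO_INTERSTITIAL")
  keep <- if (mode == "conversion") events$class %in% conv
    else events$class %in% c(conv, "CO_SIMPLE", "BIR_TERMINAL", "TERMINAL_LOH")
  ev <- events[keep, , drop = FALSE]
  reg <- tibble(
    chrom = ev$chrom,
    start = ifelse(is.na(ev$region_start), ev$tract_start, ev$region_start),
    end = ifelse(is.na(ev$region_end), ev$tract_end, ev$region_end)
  )
  reg <- filter(reg, !is.na(.data$start), !is.na(.data$end))
  mm <- merge_intervals(mask)
  in_mask <- .overlap_flags(reg, split(mm, mm$chrom))
  clipped <- clip_to_mask(reg[in_mask, , drop = FALSE], mask)
  attr(clipped, "total_bp") <- .total_width(merge_intervals(clipped))
  attr(clipped, "dropped") <- sum(!in_mask)
  clipped
}

# Per-interval overlap flags against a merged (disjoint, start-sorted)
# target list split by chromosome. With disjoint sorted targets, [s, e]
# overlaps iff the last target starting at or before e ends at or after s.
.overlap_flags <- function(el, tgt_split) {
  out <- rep(FALSE, nrow(el))
  for (ch in unique(el$chrom)) {
    t <- tgt_split[[ch]]
    if (is.null(t)) next
    sel <- el$chrom == ch
    idx <- findInterval(el$end[sel], t$start)
    out[sel] <- idx >= 1 & t$end[pmax(idx, 1L)] >= el$start[sel]
  }
  out
}

.overlap_hits <- function(el, tgt_split) {
  sum(.overlap_flags(el, tgt_split))
}

#' Count elements overlapping breakpoint regions
#'
#' Elements of a class are merged, then each merged element is counted at
#' most once if it overlaps any region by at least 1 bp.
#'
#' @param regions breakpoint region tibble.
#' @param elements element interval tibble (one class).
#' @return integer count.
#' @export
count_overlaps <- function(regions, elements) {
  if (!nrow(regions) || !nrow(elements)) return(0L)
  el <- merge_intervals(elements)
  tgt <- merge_intervals(regions)
  .overlap_hits(el, split(tgt, tgt$chrom))
}

#' Expected element count under length-proportional random placement
#'
#' Under a uniform random distribution of elements over the analyzable
#' genome, the expected number falling in the breakpoint regions is the
#' number of (mask-restricted) elements times the fraction of the mask
#' length the regions cover.
#'
#' @param elements element interval tibble (one class).
#' @param regions breakpoint region tibble (already clipped to the mask).
#' @param mask coverage mask tibble.
#' @return numeric expected count.
#' @export
expected_count <- function(elements, regions, mask) {
  mask_bp <- .total_width(merge_intervals(mask))
  if (mask_bp == 0) abort("mask has zero total length")
  n_el <- nrow(merge_intervals(clip_to_mask(elements, mask)))
  region_bp <- .total_width(merge_intervals(regions))
  n_el * region_bp / mask_bp
}

#' Step-up false-discovery-rate adjustment
#'
#' The step-up procedure of Benjamini and Hochberg: with p-values sorted
#' ascending, `adjusted[i] = min over j >= i of (p[j] * m / j)`, capped at 1.
#'
#' @param pvals p-values in `[0, 1]` (NAs passed through).
#' @return adjusted p-values in the original order.
#' @examples
#' multiple_test_correction(c(0.01, 0.02, 0.03, 0.04))
#' @export
multiple_test_correction <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) abort("p-values must be in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m) {
    o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}

#' Enrichment of genomic element classes at LOH breakpoints
#'
#' For each element class, compares the observed number of elements inside
#' the breakpoint regions with the expectation under random placement, by a
#' chi-square goodness-of-fit test on the (inside, outside) split, followed
#' by step-up FDR correction across classes. Classes with expected count
#' below 1 (or no elements in the mask) are reported untested.
#'
#' @param elements element tibble with a `class` column (or a named list of
#'   interval tibbles).
#' @param regions breakpoint regions (clipped to the mask).
#' @param mask coverage mask.
#' @param q significance level on adjusted p-values (default 0.05).
#' @return tibble of class `loh_enrichment`: `class`, `n_elements`,
#'   `observed`, `expected`, `p`, `p_adj`, `direction`
#'   (over/under/none), `tested`.
#' @export
enrichment_table <- function(elements, regions, mask, q = 0.05) {
  if (is.data.frame(elements)) {
    .stopifnot_cols(elements, c("chrom", "start", "end", "class"), "`elements`")
    elements <- split(select(elements, "chrom", "start", "end"),
                      elements$class)
  }
  mask_m <- merge_intervals(mask)
  reg_m <- merge_intervals(regions)
  mask_split <- split(mask_m, mask_m$chrom)
  reg_split <- split(reg_m, reg_m$chrom)
  mask_bp <- .total_width(mask_m)
  region_bp <- .total_width(reg_m)
  if (mask_bp == 0) abort("mask has zero total length")
  rows <- imap(elements, function(el, cls) {
    el_m <- merge_intervals(el)
    # pre-filter to the mask: elements with no mask overlap are excluded
    in_mask <- .overlap_hits(el_m, mask_split)
    n_el <- in_mask
    obs <- if (nrow(el_m)) .overlap_hits(el_m, reg_split) else 0L
    exp_in <- n_el * region_bp / mask_bp
    tested <- n_el > 0 && exp_in >= 1 && (n_el - exp_in) > 0
    p <- if (tested) {
      chi_square_gof(c(obs, n_el - obs), c(exp_in, n_el - exp_in))$p.value
    } else NA_real_
    tibble(class = cls, n_elements = n_el, observed = obs,
           expected = exp_in, p = p, tested = tested)
  })
  out <- bind_rows(rows)
  out$p_adj <- multiple_test_correction(out$p)
  out$direction <- dplyr::case_when(
    !out$tested | is.na(out$p_adj) | out$p_adj > q ~ "none",
    out$observed > out$expected ~ "over",
    out$observed < out$expected ~ "under",
    TRUE ~ "none"
  )
  out <- select(out, "class", "n_elements", "observed", "expected", "p",
                "p_adj", "direction", "tested")
  class(out) <- c("loh_enrichment", class(out))
  out
}

#' Permutation alternative for the expected overlap count
#'
#' Re-places the breakpoint regions uniformly at random within the mask
#' (preserving their lengths) and counts element overlaps, as a cross-check
#' on the closed-form length-proportional expectation.
#'
#' @param elements element interval tibble (one class).
#' @param regions breakpoint regions.
#' @param mask coverage mask.
#' @param n_shuffle number of shuffles (default 1000).
#' @param seed integer seed.
#' @return tibble `mean_overlap`, `sd_overlap`, `n_shuffle`.
#' @export
permutation_expected <- function(elements, regions, mask, n_shuffle = 1000,
                                 seed = 1) {
  set.seed(derive_seed(seed, 6L))
  mask_m <- merge_intervals(mask)
  widths <- as.numeric(mask_m$end - mask_m$start + 1)
  cum <- cumsum(widths)
  total <- cum[length(cum)]
  reg_m <- merge_intervals(regions)
  lens <- reg_m$end - reg_m$start + 1
  el_m <- merge_intervals(clip_to_mask(elements, mask))
  counts <- vapply(seq_len(n_shuffle), function(i) {
    u <- runif(length(lens)) * total
    j <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1), nrow(mask_m))
    off <- floor(u - c(0, cum)[j])
    start <- mask_m$start[j] + off
    end <- pmin(start + lens - 1, mask_m$end[j])
    count_overlaps(tibble(chrom = mask_m$chrom[j], start = start, end = end),
                   el_m)
  }, numeric(1))
  tibble(mean_overlap = mean(counts), sd_overlap = sd(counts),
         n_shuffle = n_shuffle)
}
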