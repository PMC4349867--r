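.category_of <- function(class) {
  dplyr::case_when(
    class == "NCO_INTERSTITIAL" ~ "INTERSTITIAL",
    class %in% c("CO_SIMPLE", "CO_3TO1", "CO_4TO0", "CO_HYBRID") ~ "CROSSOVER",
    class == "BIR_TERMINAL" ~ "BIR",
    class == "TERMINAL_LOH" ~ "CO_BIR",
    TRUE ~ "OTHER"
  )
}

.is_hom <- function(s) s %in% c("HOM_W", "HOM_Y")
.is_del <- function(s) s %in% c("DEL_W", "DEL_Y")

#' Align the two sectors of a colony into joint state blocks
#'
#' Expands each sector's segments back to per-marker states on the shared
#' marker map and collapses the paired states into maximal blocks over which
#' neither sector changes state. Markers not covered by a segment in both
#' sectors (uncalled or absorbed) are skipped.
#'
#' @param d1,d2 segment tibbles for the two daughters, from
#'   [segment_genome()], built on the same marker map.
#' @param markers the shared marker map.
#' @return tibble of joint blocks: `chrom`, `start`, `end` (first/last marker
#'   position), `n_markers`, `state_d1`, `state_d2`.
#' @export
match_sectors <- function(d1, d2, markers) {
  .stopifnot_cols(markers, c("chrom", "pos"), "`markers`")
  for (nm in c("d1", "d2")) {
    segs <- get(nm)
    .stopifnot_cols(segs, c("chrom", "start", "end", "state"), paste0("`", nm, "`"))
    ids <- c(segs$first_id, segs$last_id)
    ids <- ids[!is.na(ids)]
    if (length(ids) && "id" %in% names(markers) && !all(ids %in% markers$id)) {
      abort("segments were not built on the supplied marker map")
    }
  }
  s1 <- .expand_states(d1, markers)
  s2 <- .expand_states(d2, markers)
  keep <- !is.na(s1) & !is.na(s2)
  mk <- markers[keep, , drop = FALSE]
  pair <- paste(s1[keep], s2[keep], sep = "|")
  mk |>
    mutate(pair = pair) |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      r <- rle(df$pair)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      st <- strsplit(r$values, "|", fixed = TRUE)
      tibble(
        start = df$pos[starts], end = df$pos[ends],
        n_markers = r$lengths,
        state_d1 = vapply(st, `[`, "", 1),
        state_d2 = vapply(st, `[`, "", 2)
      )
    }) |>
    ungroup()
}

# Per-marker state implied by a segment list (NA where uncovered).
.expand_states <- function(segments, markers) {
  out <- rep(NA_character_, nrow(markers))
  for (ch in unique(segments$chrom)) {
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    sel <- which(markers$chrom == ch)
    if (!length(sel)) next
    pos <- markers$pos[sel]
    j <- findInterval(pos, segs$start)
    ok <- j >= 1 & pos <= segs$end[pmax(j, 1)]
    out[sel[ok]] <- segs$state[j[ok]]
  }
  out
}

#' Detect whole-chromosome copy-number anomalies
#'
#' The summed W+Y ratio of a marker is copy-number informative while being
#' insensitive to which haplotype is retained: a disomic marker (heterozygous
#' or homozygous) sums to `mean_copy2 + mean_copy0` or `2 * mean_copy1`,
#' whereas monosomy and trisomy shift the chromosome-wide mean toward the
#' 1-copy and 3-copy expectations. A chromosome is flagged when its mean
#' total ratio is nearer a 1- or 3-copy expectation than the 2-copy one and
#' the departure exceeds `z_threshold` standard errors.
#'
#' @param ratios long ratio tibble (`sector`, `chrom`, `ratio_w`, `ratio_y`).
#' @param noise the [noise_model()] describing the channel means.
#' @param z_threshold z-score a departure must exceed (default 6).
#' @return tibble: `sector`, `chrom`, `copies` (1 or 3), `donor` (retained
#'   haplotype for monosomy, duplicated haplotype for trisomy), `mean_total`.
#' @export
detect_aneuploidy <- function(ratios, noise = noise_model(), z_threshold = 6) {
  .stopifnot_cols(ratios, c("sector", "chrom", "ratio_w", "ratio_y"), "`ratios`")
  e1 <- noise$mean_copy1 + noise$mean_copy0
  e2 <- 2 * noise$mean_copy1
  e3 <- noise$mean_copy2 + noise$mean_copy1
  ratios |>
    group_by(.data$sector, .data$chrom) |>
    summarise(
      mean_total = mean(.data$ratio_w + .data$ratio_y),
      se = sd(.data$ratio_w + .data$ratio_y) / sqrt(n()),
      mean_w = mean(.data$ratio_w), mean_y = mean(.data$ratio_y),
      .groups = "drop"
    ) |>
    mutate(
      copies = c(1L, 2L, 3L)[apply(
        cbind(abs(.data$mean_total - e1), abs(.data$mean_total - e2),
              abs(.data$mean_total - e3)), 1, which.min)],
      z = ifelse(is.na(.data$se) | .data$se == 0,
                 ifelse(abs(.data$mean_total - e2) > 0, Inf, 0),
                 abs(.data$mean_total - e2) / .data$se),
      donor = ifelse(.data$mean_w > .data$mean_y, "W", "Y")
    ) |>
    filter(.data$copies != 2L, .data$z > z_threshold) |>
    select("sector", "chrom", "copies", "donor", "mean_total")
}

# -- pattern classification ---------------------------------------------------

# One event-record row; coordinates are marker positions bounding the tract
# (tract_*) and the flanking localisation interval (region_*).
.event_row <- function(chrom, class, donor = NA_character_,
                       sector = NA_character_, pattern = NA_character_,
                       tract_start = NA_real_, tract_end = NA_real_,
                       region_start = NA_real_, region_end = NA_real_,
                       side = NA_character_, n_markers = NA_integer_,
                       flags = "") {
  tibble(chrom = chrom, class = class, donor = donor, sector = sector,
         pattern = pattern, tract_start = tract_start, tract_end = tract_end,
         region_start = region_start, region_end = region_end, side = side,
         n_markers = n_markers, flags = flags)
}

# Is block (s1, s2) a conversion-like block, and of what form?
# Returns NA, "one1" (tract in D1), "one2", or "shared".
.conv_form <- function(s1, s2) {
  if (.is_hom(s1) && s2 == "HET") return("one1")
  if (s1 == "HET" && .is_hom(s2)) return("one2")
  if (.is_hom(s1) && s1 == s2) return("shared")
  NA_character_
}

.conv_donor <- function(s1, s2, form) {
  switch(form, one1 = .hap_of_hom(s1), one2 = .hap_of_hom(s2),
         shared = .hap_of_hom(s1), NA_character_)
}

# Classify the conversion tract blocks collected next to a crossover or in an
# interior run. `blocks` rows are in chromosome order.
.tract_pattern <- function(blocks) {
  forms <- unname(mapply(.conv_form, blocks$state_d1, blocks$state_d2))
  donors <- unname(mapply(.conv_donor, blocks$state_d1, blocks$state_d2, forms))
  sectors <- ifelse(forms == "one1", "D1", ifelse(forms == "one2", "D2", "both"))
  pattern <- if (all(forms == "shared")) "4:0"
    else if (all(forms %in% c("one1", "one2"))) "3:1"
    else "hybrid"
  flags <- character(0)
  donor <- donors[1]
  if (length(unique(donors)) > 1) {
    flags <- c(flags, "complex_tract")
    tab <- tapply(blocks$n_markers, donors, sum)
    donor <- names(tab)[which.max(tab)]
  }
  sector <- if (pattern == "4:0") "both"
    else if (all(sectors[forms != "shared"] == "D1")) "D1"
    else if (all(sectors[forms != "shared"] == "D2")) "D2"
    else {
      flags <- c(flags, "complex_tract")
      "both"
    }
  if (pattern == "3:1" && length(unique(sectors)) > 1) flags <- c(flags, "complex_tract")
  list(pattern = pattern, donor = donor, sector = sector,
       flags = paste(unique(flags), collapse = ";"))
}

# Classify one chromosome of a paired colony from its joint blocks.
# `min_conv_markers`: a candidate crossover conversion tract narrower than
# this collapses into the transition (the two sectors' uncertainty intervals
# then overlap, the operational definition of an identical transition).
.classify_chrom_paired <- function(blocks, min_conv_markers = 2) {
  events <- list()
  b <- blocks

  # deletion blocks: record, then treat that sector as HET for the rest
  for (sec in c("state_d1", "state_d2")) {
    del <- .is_del(b[[sec]])
    if (any(del)) {
      r <- rle(del)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      for (j in which(r$values)) {
        rows <- starts[j]:ends[j]
        lost <- sub("^DEL_", "", b[[sec]][rows[1]])
        events[[length(events) + 1]] <- .event_row(
          chrom = b$chrom[1], class = "DELETION", donor = lost,
          sector = if (sec == "state_d1") "D1" else "D2",
          tract_start = b$start[rows[1]], tract_end = b$end[rows[length(rows)]],
          region_start = if (rows[1] > 1) b$end[rows[1] - 1] else NA_real_,
          region_end = if (rows[length(rows)] < nrow(b)) b$start[rows[length(rows)] + 1] else NA_real_,
          n_markers = sum(b$n_markers[rows])
        )
        b[[sec]][rows] <- "HET"
      }
    }
  }
  # re-merge after deletion relabelling
  pair <- paste(b$state_d1, b$state_d2, sep = "|")
  r <- rle(pair)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  b <- tibble(
    chrom = b$chrom[1],
    start = b$start[starts], end = b$end[ends],
    n_markers = vapply(seq_along(starts), function(j)
      sum(b$n_markers[starts[j]:ends[j]]), integer(1)),
    state_d1 = b$state_d1[starts], state_d2 = b$state_d2[ends]
  )

  m <- nrow(b)
  consumed <- rep(FALSE, m)

  classify_terminal <- function(end_idx, step, side) {
    s1 <- b$state_d1[end_idx]; s2 <- b$state_d2[end_idx]
    if (!(.is_hom(s1) || .is_hom(s2))) return(NULL)
    if (s1 == "HET" || s2 == "HET" || (.is_hom(s1) && .is_hom(s2) && s1 == s2)) {
      # terminal homozygosity not reciprocal: BIR-like (one sector), or a
      # shared terminal run (flagged)
      shared <- .is_hom(s1) && s1 == s2
      sec_col <- if (shared || .is_hom(s1)) "state_d1" else "state_d2"
      hap <- .hap_of_hom(b[[sec_col]][end_idx])
      target <- b[[sec_col]][end_idx]
      other_col <- if (sec_col == "state_d1") "state_d2" else "state_d1"
      j <- end_idx
      while (TRUE) {
        nxt <- j + step
        if (nxt < 1 || nxt > m || consumed[nxt]) break
        same_form <- b[[sec_col]][nxt] == target &&
          ((shared && b[[other_col]][nxt] == target) ||
             (!shared && b[[other_col]][nxt] == "HET"))
        if (!same_form) break
        j <- nxt
      }
      rows <- sort(c(seq(end_idx, j, by = step)))
      consumed[rows] <<- TRUE
      prev <- if (step == -1L) min(rows) - 1 else max(rows) + 1
      flags <- "possible_second_division_crossover"
      if (shared) flags <- paste(flags, "terminal_shared", sep = ";")
      return(.event_row(
        chrom = b$chrom[1], class = "BIR_TERMINAL", donor = hap,
        sector = if (shared) "both" else if (sec_col == "state_d1") "D1" else "D2",
        tract_start = b$start[min(rows)], tract_end = b$end[max(rows)],
        region_start = if (side == "right" && prev >= 1) b$end[prev] else NA_real_,
        region_end = if (side == "left" && prev <= m) b$start[prev] else NA_real_,
        side = side, n_markers = sum(b$n_markers[rows]), flags = flags
      ))
    }
    if (!(.is_hom(s1) && .is_hom(s2) && s1 != s2)) return(NULL)
    # reciprocal terminal homozygosity: a crossover; walk inward over
    # conversion-like blocks
    j <- end_idx
    conv <- integer(0)
    while (TRUE) {
      nxt <- j + step
      if (nxt < 1 || nxt > m || consumed[nxt]) break
      form <- .conv_form(b$state_d1[nxt], b$state_d2[nxt])
      if (is.na(form)) break
      conv <- c(conv, nxt)
      j <- nxt
    }
    conv <- sort(conv)
    rows <- sort(c(end_idx, conv))
    consumed[rows] <<- TRUE
    prev <- if (step == -1L) min(rows) - 1 else max(rows) + 1
    term_flag <- if (prev < 1 || prev > m) "whole_chromosome" else ""
    if (length(conv) == 0 || sum(b$n_markers[conv]) < min_conv_markers) {
      if (length(conv)) consumed[conv] <<- TRUE
      # transition uncertainty intervals overlap: crossover without
      # detectable conversion
      lo <- if (prev >= 1 && prev <= m) {
        if (side == "right") b$end[prev] else b$start[prev]
      } else NA_real_
      hi <- if (side == "right") b$start[min(setdiff(rows, conv))] else b$end[max(setdiff(rows, conv))]
      return(.event_row(
        chrom = b$chrom[1], class = "CO_SIMPLE",
        region_start = if (side == "right") lo else hi,
        region_end = if (side == "right") hi else lo,
        side = side, n_markers = 0L, flags = term_flag
      ))
    }
    cb <- b[conv, , drop = FALSE]
    tp <- .tract_pattern(cb)
    class <- switch(tp$pattern, "3:1" = "CO_3TO1", "4:0" = "CO_4TO0",
                    hybrid = "CO_HYBRID")
    flags <- paste(c(tp$flags[nzchar(tp$flags)], term_flag[nzchar(term_flag)]),
                   collapse = ";")
    # localisation interval: flanking heterozygous marker to the first marker
    # of the reciprocal terminal region
    flank <- if (prev >= 1 && prev <= m) {
      if (side == "right") b$end[prev] else b$start[prev]
    } else NA_real_
    recip <- if (side == "right") b$start[end_idx] else b$end[end_idx]
    .event_row(
      chrom = b$chrom[1], class = class, donor = tp$donor, sector = tp$sector,
      pattern = tp$pattern,
      tract_start = min(cb$start), tract_end = max(cb$end),
      region_start = if (side == "right") flank else recip,
      region_end = if (side == "right") recip else flank,
      side = side, n_markers = sum(cb$n_markers), flags = flags
    )
  }

  if (m >= 1) {
    ev_r <- classify_terminal(m, -1L, "right")
    if (!is.null(ev_r)) events[[length(events) + 1]] <- ev_r
    if (!consumed[1]) {
      ev_l <- classify_terminal(1L, +1L, "left")
      if (!is.null(ev_l)) events[[length(events) + 1]] <- ev_l
    }
  }

  # interior runs of non-(HET,HET) blocks -> interstitial conversions
  interior <- !consumed & !(b$state_d1 == "HET" & b$state_d2 == "HET")
  if (any(interior)) {
    r <- rle(interior)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      rows <- starts[j]:ends[j]
      forms <- mapply(.conv_form, b$state_d1[rows], b$state_d2[rows])
      if (any(is.na(forms))) {
        # not a recognizable conversion pattern; record with a caveat
        events[[length(events) + 1]] <- .event_row(
          chrom = b$chrom[1], class = "NCO_INTERSTITIAL",
          tract_start = b$start[rows[1]], tract_end = b$end[rows[length(rows)]],
          region_start = if (rows[1] > 1) b$end[rows[1] - 1] else NA_real_,
          region_end = if (rows[length(rows)] < m) b$start[rows[length(rows)] + 1] else NA_real_,
          n_markers = sum(b$n_markers[rows]), flags = "unrecognized_pattern"
        )
        next
      }
      cb <- b[rows, , drop = FALSE]
      tp <- .tract_pattern(cb)
      events[[length(events) + 1]] <- .event_row(
        chrom = b$chrom[1], class = "NCO_INTERSTITIAL", donor = tp$donor,
        sector = tp$sector, pattern = tp$pattern,
        tract_start = min(cb$start), tract_end = max(cb$end),
        region_start = if (rows[1] > 1) b$end[rows[1] - 1] else NA_real_,
        region_end = if (rows[length(rows)] < m) b$start[rows[length(rows)] + 1] else NA_real_,
        n_markers = sum(cb$n_markers), flags = tp$flags
      )
    }
  }
  if (length(events)) bind_rows(events) else NULL
}

# Single-colony mode: one genotype vector; terminal LOH cannot be split into
# crossover vs BIR, so it is pooled as TERMINAL_LOH / category CO_BIR.
.classify_chrom_single <- function(segs) {
  events <- list()
  b <- segs
  m <- nrow(b)
  del <- .is_del(b$state)
  if (any(del)) {
    for (j in which(del)) {
      events[[length(events) + 1]] <- .event_row(
        chrom = b$chrom[1], class = "DELETION",
        donor = sub("^DEL_", "", b$state[j]),
        tract_start = b$start[j], tract_end = b$end[j],
        region_start = if (j > 1) b$end[j - 1] else NA_real_,
        region_end = if (j < m) b$start[j + 1] else NA_real_,
        n_markers = b$n_markers[j]
      )
    }
  }
  hom <- .is_hom(b$state)
  for (j in which(hom)) {
    terminal_right <- j == m
    terminal_left <- j == 1
    hap <- .hap_of_hom(b$state[j])
    if (terminal_right || terminal_left) {
      events[[length(events) + 1]] <- .event_row(
        chrom = b$chrom[1], class = "TERMINAL_LOH", donor = hap,
        tract_start = b$start[j], tract_end = b$end[j],
        region_start = if (j > 1) b$end[j - 1] else NA_real_,
        region_end = if (j < m) b$start[j + 1] else NA_real_,
        side = if (terminal_right && !terminal_left) "right"
               else if (terminal_left && !terminal_right) "left" else NA_character_,
        n_markers = b$n_markers[j],
        flags = if (terminal_left && terminal_right) "whole_chromosome" else ""
      )
    } else {
      events[[length(events) + 1]] <- .event_row(
        chrom = b$chrom[1], class = "NCO_INTERSTITIAL", donor = hap,
        tract_start = b$start[j], tract_end = b$end[j],
        region_start = b$end[j - 1], region_end = b$start[j + 1],
        n_markers = b$n_markers[j]
      )
    }
  }
  if (length(events)) bind_rows(events) else NULL
}

#' Assign the inferred break type of classified events
#'
#' 3:1 conversion tracts diagnose a single-chromatid break (SCB); 4:0 and
#' 3:1/4:0 hybrid tracts diagnose a double sister-chromatid break (DSCB).
#' Crossovers without a detectable conversion tract cannot be classified and
#' are marked UNCLASSIFIED; BIR, deletion and aneuploidy events carry no
#' break-type call.
#'
#' @param events event tibble with `class` and `pattern` columns.
#' @return the tibble with a `break_type` column.
#' @export
assign_break_type <- function(events) {
  .stopifnot_cols(events, c("class"), "`events`")
  pattern <- if ("pattern" %in% names(events)) events$pattern else NA_character_
  mutate(events, break_type = dplyr::case_when(
    class == "CO_3TO1" ~ "SCB",
    class %in% c("CO_4TO0", "CO_HYBRID") ~ "DSCB",
    class == "CO_SIMPLE" ~ "UNCLASSIFIED",
    class == "NCO_INTERSTITIAL" & pattern %in% "3:1" ~ "SCB",
    class == "NCO_INTERSTITIAL" & pattern %in% c("4:0", "hybrid") ~ "DSCB",
    class == "NCO_INTERSTITIAL" ~ "UNCLASSIFIED",
    TRUE ~ NA_character_
  ))
}

#' Conversion-tract split threshold
#'
#' Widely separated LOH blocks on one chromosome are treated as distinct
#' events when the heterozygous gap between them exceeds the median
#' conversion tract length plus two median absolute deviations. By default
#' the raw MAD (no 1.4826 consistency factor) is used; `mad_constant =
#' 1.4826` selects the normal-consistent convention.
#'
#' @param lengths_kb conversion tract lengths in kb.
#' @param mad_constant scale factor for [stats::mad()] (default 1).
#' @return threshold in kb (`median + 2 * MAD`).
#' @export
split_threshold_kb <- function(lengths_kb, mad_constant = 1) {
  lengths_kb <- lengths_kb[!is.na(lengths_kb)]
  if (!length(lengths_kb)) return(Inf)
  median(lengths_kb) + 2 * mad(lengths_kb, constant = mad_constant)
}

#' Split or merge nearby LOH blocks into events
#'
#' LOH blocks on one chromosome separated by a heterozygous gap larger than
#' `tract_median + 2 * tract_mad` (kb) remain distinct events; blocks with a
#' smaller gap are merged into a single event whose tract spans both. When an
#' interstitial block merges with a crossover or BIR event the latter's class
#' is retained. Gaps are measured between the original block coordinates, so
#' the number of reported events is non-increasing in the threshold.
#'
#' @param events classified event tibble.
#' @param tract_median,tract_mad median and MAD of the conversion tract
#'   lengths, in kb. Defaults are computed from the events themselves.
#' @param mad_constant see [split_threshold_kb()].
#' @return the event tibble after merging.
#' @export
split_distant_events <- function(events, tract_median = NULL, tract_mad = NULL,
                                 mad_constant = 1) {
  if (is.null(events) || nrow(events) == 0) return(events)
  if (is.null(tract_median) || is.null(tract_mad)) {
    lens <- events$tract_kb[!is.na(events$tract_kb)]
    thr <- split_threshold_kb(lens, mad_constant)
  } else {
    if (tract_median < 0 || tract_mad < 0) abort("median and MAD must be >= 0")
    thr <- tract_median + 2 * tract_mad
  }
  if (!is.finite(thr)) return(events)
  thr_bp <- thr * 1000

  key <- paste(if ("colony" %in% names(events)) events$colony else "",
               events$chrom, sep = "\r")
  out <- map(split(events, key), function(ev) {
    mergeable <- ev$class %in% c("NCO_INTERSTITIAL", "CO_3TO1", "CO_4TO0",
                                 "CO_HYBRID", "BIR_TERMINAL", "TERMINAL_LOH") &
      !is.na(ev$tract_start)
    fixed <- ev[!mergeable, , drop = FALSE]
    ev <- ev[mergeable, , drop = FALSE]
    if (nrow(ev) < 2) return(bind_rows(ev, fixed))
    ev <- ev[order(ev$tract_start), , drop = FALSE]
    gap <- ev$tract_start[-1] - ev$tract_end[-nrow(ev)]
    grp <- cumsum(c(1, as.integer(gap > thr_bp)))
    merged <- map(split(seq_len(nrow(ev)), grp), function(rows) {
      if (length(rows) == 1) return(ev[rows, , drop = FALSE])
      sub <- ev[rows, , drop = FALSE]
      anchor_i <- which(sub$class != "NCO_INTERSTITIAL")
      anchor <- if (length(anchor_i)) sub[anchor_i[1], , drop = FALSE]
        else sub[1, , drop = FALSE]
      anchor$tract_start <- min(sub$tract_start)
      anchor$tract_end <- max(sub$tract_end)
      anchor$region_start <- suppressWarnings(min(sub$region_start, na.rm = TRUE))
      anchor$region_end <- suppressWarnings(max(sub$region_end, na.rm = TRUE))
      anchor$region_start[!is.finite(anchor$region_start)] <- NA_real_
      anchor$region_end[!is.finite(anchor$region_end)] <- NA_real_
      anchor$n_markers <- sum(sub$n_markers, na.rm = TRUE)
      anchor$flags <- paste(unique(c(
        unlist(strsplit(sub$flags[nzchar(sub$flags)], ";")), "merged_nearby_block"
      )), collapse = ";")
      anchor
    })
    bind_rows(bind_rows(merged), fixed)
  })
  out <- bind_rows(out)
  ord_cols <- intersect(c("colony", "chrom", "tract_start", "region_start"), names(out))
  arrange(out, across(all_of(ord_cols)))
}

# Conversion-tract length in kb: midpoint of the downstream localisation
# interval minus midpoint of the upstream one.
.add_tract_kb <- function(events, chrom_lengths) {
  if (is.null(events) || nrow(events) == 0) return(events)
  conv <- events$class %in% c("CO_3TO1", "CO_4TO0", "CO_HYBRID",
                              "NCO_INTERSTITIAL")
  rs <- events$region_start
  re <- events$region_end
  flag_end <- conv & (is.na(rs) | is.na(re))
  rs[conv & is.na(rs)] <- 1
  re[conv & is.na(re)] <- chrom_lengths[events$chrom[conv & is.na(re)]]
  up_mid <- floor((rs + events$tract_start) / 2)
  dn_mid <- floor((events$tract_end + re) / 2)
  events$tract_kb <- ifelse(conv, (dn_mid - up_mid) / 1000, NA_real_)
  events$flags[flag_end] <- vapply(events$flags[flag_end], function(f) {
    paste(unique(c(unlist(strsplit(f[nzchar(f)], ";")), "chrom_end")), collapse = ";")
  }, "")
  events
}

#' Classify the LOH events of one colony
#'
#' Pairs the two sector samples of a sectored colony (or takes a single
#' colony), matches their segmentations on the shared marker map, and applies
#' the LOH pattern taxonomy: reciprocal terminal homozygosity is a crossover
#' (simple, 3:1, 4:0 or hybrid according to its conversion tract); terminal
#' homozygosity in one sector only is break-induced replication (with the
#' caveat that a second-division crossover gives the same pattern);
#' interstitial homozygosity is a conversion unassociated with a crossover;
#' hemizygous runs are deletions; chromosome-wide copy anomalies (detected
#' from the summed channel ratios when `ratios` are supplied) are
#' aneuploidies. Break types are then assigned and nearby blocks merged by
#' the distance rule of [split_distant_events()].
#'
#' @param d1 segment tibble for the first daughter (or the single colony).
#' @param d2 segment tibble for the second daughter, or NULL for
#'   single-colony mode.
#' @param markers the shared marker map.
#' @param colony colony identifier.
#' @param genome genome tibble (for chromosome lengths).
#' @param ratios optional long ratio tibble for aneuploidy detection.
#' @param noise,z_threshold passed to [detect_aneuploidy()].
#' @param split apply [split_distant_events()] (default TRUE).
#' @param tract_median,tract_mad,mad_constant split-rule parameters.
#' @param min_conv_markers minimum markers for a crossover-adjacent
#'   conversion tract to count as detected (default 2).
#' @return event tibble: `colony`, `chrom`, `class`, `category`,
#'   `break_type`, `donor`, `sector`, `pattern`, `tract_start`, `tract_end`,
#'   `region_start`, `region_end`, `tract_kb`, `side`, `n_markers`, `flags`.
#' @export
classify_colony <- function(d1, d2 = NULL, markers, colony = "colony1",
                            genome = loh_genome(), ratios = NULL,
                            noise = noise_model(), z_threshold = 6,
                            split = TRUE, tract_median = NULL,
                            tract_mad = NULL, mad_constant = 1,
                            min_conv_markers = 2) {
  chrom_lengths <- setNames(genome$length, genome$chrom)
  events <- list()
  aneu_chrom <- character(0)
  if (!is.null(ratios)) {
    an <- detect_aneuploidy(ratios, noise, z_threshold)
    if (nrow(an)) {
      aneu_chrom <- unique(an$chrom)
      for (i in seq_len(nrow(an))) {
        events[[length(events) + 1]] <- .event_row(
          chrom = an$chrom[i], class = "ANEUPLOIDY", donor = an$donor[i],
          sector = an$sector[i],
          tract_start = 1, tract_end = chrom_lengths[[an$chrom[i]]],
          flags = paste0("copies=", an$copies[i])
        )
      }
    }
  }

  if (is.null(d2)) {
    segs <- d1[!d1$chrom %in% aneu_chrom, , drop = FALSE]
    for (ch in unique(segs$chrom)) {
      ev <- .classify_chrom_single(segs[segs$chrom == ch, , drop = FALSE])
      if (!is.null(ev)) events[[length(events) + 1]] <- ev
    }
  } else {
    blocks <- match_sectors(d1, d2, markers)
    blocks <- blocks[!blocks$chrom %in% aneu_chrom, , drop = FALSE]
    for (ch in unique(blocks$chrom)) {
      bc <- blocks[blocks$chrom == ch, , drop = FALSE]
      if (all(bc$state_d1 == "UNCALLED" | bc$state_d2 == "UNCALLED")) next
      ev <- .classify_chrom_paired(bc, min_conv_markers)
      if (!is.null(ev)) events[[length(events) + 1]] <- ev
    }
  }
  if (!length(events)) {
    return(tibble(
      colony = character(), chrom = character(), class = character(),
      category = character(), break_type = character(), donor = character(),
      sector = character(), pattern = character(), tract_start = numeric(),
      tract_end = numeric(), region_start = numeric(), region_end = numeric(),
      tract_kb = numeric(), side = character(), n_markers = integer(),
      flags = character()
    ))
  }
  events <- bind_rows(events)
  events <- .add_tract_kb(events, chrom_lengths)
  events <- assign_break_type(events)
  events <- mutate(events, colony = colony, category = .category_of(class),
                   .before = 1)
  if (split) {
    events <- split_distant_events(events, tract_median, tract_mad, mad_constant)
  }
  select(events, "colony", "chrom", "class", "category", "break_type",
         "donor", "sector", "pattern", "tract_start", "tract_end",
         "region_start", "region_end", "tract_kb", "side", "n_markers",
         "flags")
}

#' Summarize a colony's events as category counts
#'
#' @param events event tibble for one colony (or several; counts are summed
#'   per colony when a `colony` column is present).
#' @param exclude_chrom optional chromosome name(s) to exclude, e.g. the
#'   chromosome carrying the selected sectoring marker, so that only
#'   unselected events are counted.
#' @return one row per colony: `n_interstitial`, `n_crossover`, `n_bir`,
#'   `n_co_bir`, `n_total` (sum of the previous four), `n_deletion`,
#'   `n_aneuploidy`.
#' @export
summarize_colony <- function(events, exclude_chrom = NULL) {
  if (!is.null(exclude_chrom)) {
    events <- filter(events, !.data$chrom %in% exclude_chrom)
  }
  grp <- intersect("colony", names(events))
  out <- events |>
    group_by(across(all_of(grp))) |>
    summarise(
      n_interstitial = sum(.data$category == "INTERSTITIAL"),
      n_crossover = sum(.data$category == "CROSSOVER"),
      n_bir = sum(.data$category == "BIR"),
      n_co_bir = sum(.data$category == "CO_BIR"),
      n_deletion = sum(.data$class == "DELETION"),
      n_aneuploidy = sum(.data$class == "ANEUPLOIDY"),
      .groups = "drop"
    ) |>
    mutate(n_total = .data$n_interstitial + .data$n_crossover + .data$n_bir +
             .data$n_co_bir,
           .before = "n_deletion")
  out
}
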