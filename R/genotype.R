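#' Ratio-calling thresholds
#'
#' Band thresholds for converting a pair of allele-specific hybridization
#' ratios into a marker genotype. A marker is heterozygous when both channels
#' sit in the heterozygous band `[het_lo, het_hi]` around 1; homozygous for a
#' haplotype when that channel is at least `hom_hi` and the other at most
#' `hom_lo`; hemizygous (one homolog deleted) when one channel is at most
#' `hom_lo` while the other stays in the heterozygous band. Anything else is
#' left uncalled.
#'
#' @param het_lo,het_hi bounds of the heterozygous band.
#' @param hom_hi minimum ratio of the retained channel for a homozygous call.
#' @param hom_lo maximum ratio of the absent channel.
#' @return a list of class `loh_thresholds`.
#' @export
calling_thresholds <- function(het_lo = 0.7, het_hi = 1.3,
                               hom_hi = 1.4, hom_lo = 0.5) {
  if (!(het_hi < hom_hi)) abort("thresholds must satisfy het_hi < hom_hi")
  if (!(hom_lo < het_lo)) abort("thresholds must satisfy hom_lo < het_lo")
  if (het_lo >= het_hi) abort("thresholds must satisfy het_lo < het_hi")
  structure(list(het_lo = het_lo, het_hi = het_hi,
                 hom_hi = hom_hi, hom_lo = hom_lo),
            class = "loh_thresholds")
}

#' Call per-marker genotype states from hybridization ratios
#'
#' @param ratios tibble with `ratio_w` and `ratio_y` columns (plus any
#'   identifying columns, which are preserved).
#' @param thresholds a [calling_thresholds()] object.
#' @return the input tibble with a `state` column appended
#'   (HET, HOM_W, HOM_Y, DEL_W, DEL_Y or UNCALLED).
#' @examples
#' tibble::tibble(ratio_w = c(1, 1.8, 1.35), ratio_y = c(1, 0.2, 1.35)) |>
#'   call_marker_states()
#' @export
call_marker_states <- function(ratios, thresholds = calling_thresholds()) {
  .stopifnot_cols(ratios, c("ratio_w", "ratio_y"), "`ratios`")
  w <- ratios$ratio_w
  y <- ratios$ratio_y
  if (any(!is.finite(w)) || any(!is.finite(y))) abort("ratios must be finite")
  if (any(w < 0) || any(y < 0)) abort("ratios must be non-negative")
  t <- thresholds
  het_w <- w >= t$het_lo & w <= t$het_hi
  het_y <- y >= t$het_lo & y <= t$het_hi
  state <- rep("UNCALLED", length(w))
  state[het_w & het_y] <- "HET"
  state[w >= t$hom_hi & y <= t$hom_lo] <- "HOM_W"
  state[y >= t$hom_hi & w <= t$hom_lo] <- "HOM_Y"
  state[w <= t$hom_lo & het_y] <- "DEL_W"
  state[y <= t$hom_lo & het_w] <- "DEL_Y"
  mutate(ratios, state = state)
}

# Smooth one chromosome's state vector: one pass of (a) isolated-miscall
# repair on the subsequence of called markers (uncalled markers are skipped
# when counting flanking consensus), then (b) consensus fill of uncalled
# markers.
.smooth_vector <- function(x, flank) {
  idx_c <- which(x != "UNCALLED")
  if (length(idx_c) == 0) return(x)
  xc <- x[idx_c]
  r <- rle(xc)
  k <- length(r$values)
  if (k >= 3) {
    j <- 2:(k - 1)
    fix <- j[r$lengths[j] == 1L &
               r$values[j - 1] == r$values[j + 1] &
               r$values[j] != r$values[j - 1] &
               r$lengths[j - 1] >= flank & r$lengths[j + 1] >= flank]
    if (length(fix)) {
      r$values[fix] <- r$values[fix - 1]
      xc <- inverse.rle(r)
      x[idx_c] <- xc
    }
  }
  unc <- which(x == "UNCALLED")
  if (length(unc)) {
    runs <- rle(xc)
    runlen <- rep(runs$lengths, runs$lengths)  # run length at each called marker
    li <- findInterval(unc, idx_c)  # index of nearest called marker at/left
    ok <- li >= 1 & li < length(idx_c)
    ok[ok] <- xc[li[ok]] == xc[li[ok] + 1] &
      runlen[li[ok]] >= flank & runlen[li[ok] + 1] >= flank
    x[unc[ok]] <- xc[li[ok]]
  }
  x
}

#' Smooth isolated miscalls and fill uncalled markers
#'
#' A single called marker whose state disagrees with at least `flank`
#' identically-called markers on both sides (uncalled markers are skipped
#' when locating the flanks) is reassigned to the flanking state. Uncalled
#' markers inherit the flanking state when the nearest called markers on the
#' two sides agree, each sitting in a run of at least `flank` markers (so a
#' fill never manufactures consensus out of isolated miscalls). The pass is
#' applied once; markers inside a called run of length two or more are never
#' changed.
#'
#' @param calls tibble with `chrom`, `pos` and `state` columns (optionally
#'   `sector`), as from [call_marker_states()].
#' @param flank consensus run length required on each side (default 3).
#' @return the input tibble with `state` smoothed.
#' @export
smooth_calls <- function(calls, flank = 3) {
  .stopifnot_cols(calls, c("chrom", "state"), "`calls`")
  .check_count(flank, "flank", min = 1)
  grp <- intersect(c("sector", "chrom"), names(calls))
  calls |>
    group_by(across(all_of(grp))) |>
    mutate(state = .smooth_vector(.data$state, flank)) |>
    ungroup()
}

#' Segment a chromosome's calls into maximal same-state runs
#'
#' Uncalled markers are skipped: they neither start, end nor split a segment.
#' Runs of a non-heterozygous state covering fewer than `min_markers` markers
#' are absorbed into the surrounding heterozygous state (recorded in the
#' `absorbed` attribute); this guards against noise-induced micro-segments at
#' the cost of a documented sensitivity floor of `min_markers` markers per
#' detectable tract.
#'
#' @param calls tibble with `chrom`, `pos`, `id`, `state` (optionally
#'   `sector`).
#' @param min_markers minimum markers for a non-HET segment (default 3).
#' @return tibble of segments: `chrom`, `start`, `end` (positions of the
#'   first/last marker, 1-based inclusive), `state`, `n_markers`,
#'   `first_id`, `last_id` (plus `sector` if present). Attribute `absorbed`
#'   lists suppressed micro-runs.
#' @export
segment_genome <- function(calls, min_markers = 3) {
  .stopifnot_cols(calls, c("chrom", "pos", "state"), "`calls`")
  .check_count(min_markers, "min_markers", min = 1)
  has_id <- "id" %in% names(calls)
  grp <- intersect(c("sector", "chrom"), names(calls))
  absorbed <- list()

  seg_one <- function(df, key) {
    df <- df[df$state != "UNCALLED", , drop = FALSE]
    if (nrow(df) == 0) return(NULL)
    st <- df$state
    r <- rle(st)
    # absorb short non-HET runs into the surrounding state: when the two
    # neighbouring runs agree, into that state; otherwise into HET
    repeat {
      short <- which(r$values != "HET" & r$lengths < min_markers)
      if (!length(short)) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      j <- short[which.min(r$lengths[short])]  # shortest micro-run first
      k <- length(r$values)
      host <- if (j > 1 && j < k && r$values[j - 1] == r$values[j + 1]) {
        r$values[j - 1]
      } else if (j == 1 && k > 1) {
        r$values[2]          # chromosome-edge micro-run: only one neighbour
      } else if (j == k && k > 1) {
        r$values[k - 1]
      } else "HET"
      absorbed[[length(absorbed) + 1]] <<- tibble(
        chrom = df$chrom[1], state = r$values[j],
        start = df$pos[starts[j]], end = df$pos[ends[j]],
        n_markers = r$lengths[j], absorbed_into = host
      )
      st[starts[j]:ends[j]] <- host
      r <- rle(st)
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    out <- tibble(
      chrom = df$chrom[1],
      start = df$pos[starts], end = df$pos[ends],
      state = r$values, n_markers = r$lengths,
      first_id = if (has_id) df$id[starts] else NA_character_,
      last_id = if (has_id) df$id[ends] else NA_character_
    )
    if ("sector" %in% names(df)) out <- mutate(out, sector = df$sector[1], .before = 1)
    out
  }

  pieces <- calls |>
    dplyr::group_split(across(all_of(grp)))
  segs <- bind_rows(map(pieces, seg_one))
  attr(segs, "absorbed") <- if (length(absorbed)) bind_rows(absorbed) else NULL
  segs
}

#' Transitions between adjacent segments
#'
#' One transition per adjacent segment pair on a chromosome. The breakpoint is
#' only localized to the interval between the last marker of the left segment
#' and the first marker of the right segment; `midpoint` is the floor of the
#' mean of those two positions.
#'
#' @param segments segment tibble from [segment_genome()].
#' @return tibble: `chrom`, `left_state`, `right_state`, `left_pos`,
#'   `right_pos`, `midpoint` (plus `sector` if present).
#' @export
find_transitions <- function(segments) {
  .stopifnot_cols(segments, c("chrom", "start", "end", "state"), "`segments`")
  grp <- intersect(c("sector", "chrom"), names(segments))
  segments |>
    group_by(across(all_of(grp))) |>
    dplyr::reframe(
      left_state = head(.data$state, -1),
      right_state = tail(.data$state, -1),
      left_pos = head(.data$end, -1),
      right_pos = tail(.data$start, -1)
    ) |>
    mutate(midpoint = floor((.data$left_pos + .data$right_pos) / 2))
}

#' Genotype one sector sample end to end
#'
#' Convenience wrapper: threshold calling, smoothing, segmentation.
#'
#' @inheritParams call_marker_states
#' @inheritParams smooth_calls
#' @inheritParams segment_genome
#' @return list with `calls` (smoothed per-marker states) and `segments`.
#' @export
genotype_sample <- function(ratios, thresholds = calling_thresholds(),
                            flank = 3, min_markers = 3) {
  calls <- call_marker_states(ratios, thresholds) |> smooth_calls(flank)
  list(calls = calls, segments = segment_genome(calls, min_markers))
}
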