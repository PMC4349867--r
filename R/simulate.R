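#' Multiplicative noise model for allele-specific hybridization ratios
#'
#' Each marker's channel ratio is drawn as `mean(copy count) * exp(N(0, sigma))`:
#' a lognormal scatter around a copy-number-dependent mean. A ratio of 1 in a
#' channel corresponds to one copy of that allele (the heterozygous state in a
#' diploid); two copies hybridize brighter and zero copies leave residual
#' background. Copy counts above 2 (trisomy) extrapolate linearly.
#'
#' @param mean_copy2,mean_copy1,mean_copy0 mean ratio at 2, 1 and 0 allele
#'   copies; must be strictly decreasing and non-negative.
#' @param sigma standard deviation of the log-scale noise (>= 0).
#' @return an object of class `loh_noise_model`.
#' @examples
#' noise_model(sigma = 0)  # noiseless means
#' @export
noise_model <- function(mean_copy2 = 1.8, mean_copy1 = 1.0, mean_copy0 = 0.2,
                        sigma = 0.15) {
  if (!(mean_copy2 > mean_copy1 && mean_copy1 > mean_copy0 && mean_copy0 >= 0)) {
    abort("channel means must satisfy mean_copy2 > mean_copy1 > mean_copy0 >= 0")
  }
  if (sigma < 0) abort("`sigma` must be >= 0")
  structure(
    list(mean_copy2 = mean_copy2, mean_copy1 = mean_copy1,
         mean_copy0 = mean_copy0, sigma = sigma),
    class = "loh_noise_model"
  )
}

#' @export
print.loh_noise_model <- function(x, ...) {
  cat(sprintf(
    "<loh_noise_model> means (copy 2/1/0): %.3g / %.3g / %.3g; sigma = %.3g\n",
    x$mean_copy2, x$mean_copy1, x$mean_copy0, x$sigma
  ))
  invisible(x)
}

# Mean channel ratio for an integer allele copy count; linear beyond 2 copies.
.channel_mean <- function(cn, noise) {
  m <- c(noise$mean_copy0, noise$mean_copy1, noise$mean_copy2)
  out <- ifelse(cn <= 2, m[pmin(cn, 2) + 1],
                noise$mean_copy2 + (cn - 2) * (noise$mean_copy2 - noise$mean_copy1))
  out
}

.event_classes <- c(
  "CO_SIMPLE", "CO_3TO1", "CO_4TO0", "CO_HYBRID",
  "NCO_INTERSTITIAL", "BIR_TERMINAL", "DELETION", "ANEUPLOIDY"
)

# Fill optional event columns with defaults and validate tracts.
.normalize_events <- function(events, genome) {
  events <- as_tibble(events)
  .stopifnot_cols(events, c("chrom", "class", "start", "end"), "`events`")
  if (!all(events$class %in% .event_classes)) {
    abort(sprintf("unknown event class; must be one of %s",
                  paste(.event_classes, collapse = ", ")))
  }
  n <- nrow(events)
  if (!"donor" %in% names(events)) events$donor <- rep("W", n)
  if (!"sector" %in% names(events)) events$sector <- rep("D1", n)
  if (!"side" %in% names(events)) events$side <- rep("right", n)
  if (!"mid" %in% names(events)) events$mid <- rep(NA_real_, n)
  if (!"copies" %in% names(events)) events$copies <- rep(NA_real_, n)
  events$copies[events$class == "ANEUPLOIDY" & is.na(events$copies)] <- 1
  if (!all(events$donor %in% c("W", "Y"))) abort("`donor` must be \"W\" or \"Y\"")
  if (!all(events$sector %in% c("D1", "D2"))) abort("`sector` must be \"D1\" or \"D2\"")
  if (!all(events$side %in% c("left", "right"))) abort("`side` must be \"left\" or \"right\"")

  glen <- setNames(genome$length, genome$chrom)
  if (!all(events$chrom %in% names(glen))) abort("event chromosome not in genome")
  bad <- events$start > events$end | events$start < 1 |
    events$end > glen[events$chrom]
  if (any(bad)) abort("event tracts must satisfy 1 <= start <= end <= chromosome length")

  # Terminal events run to the telomere on their side.
  term <- events$class == "BIR_TERMINAL"
  events$end[term & events$side == "right"] <- glen[events$chrom[term & events$side == "right"]]
  events$start[term & events$side == "left"] <- 1

  hyb <- events$class == "CO_HYBRID" & is.na(events$mid)
  events$mid[hyb] <- floor((events$start[hyb] + events$end[hyb]) / 2)

  an <- events$class == "ANEUPLOIDY"
  events$start[an] <- 1
  events$end[an] <- glen[events$chrom[an]]
  if (any(!events$copies[an] %in% c(1, 3))) {
    abort("ANEUPLOIDY events must have `copies` 1 (monosomy) or 3 (trisomy)")
  }

  # Span a class occupies on the chromosome (for the overlap check): terminal
  # classes extend from the tract to the telomere on their side.
  span_lo <- events$start
  span_hi <- events$end
  co <- events$class %in% c("CO_SIMPLE", "CO_3TO1", "CO_4TO0", "CO_HYBRID", "BIR_TERMINAL")
  span_hi[co & events$side == "right"] <- glen[events$chrom[co & events$side == "right"]]
  span_lo[co & events$side == "left"] <- 1
  events$.span_lo <- span_lo
  events$.span_hi <- span_hi

  split_ev <- split(events, events$chrom)
  for (ev in split_ev) {
    if (nrow(ev) > 1) {
      ev <- ev[order(ev$.span_lo), ]
      if (any(ev$.span_lo[-1] <= ev$.span_hi[-nrow(ev)])) {
        abort(sprintf("events on %s overlap in tract coordinates", ev$chrom[1]))
      }
    }
  }
  # Break-type implied by the conversion pattern each class realizes.
  events$break_type <- dplyr::case_when(
    events$class %in% c("CO_3TO1", "NCO_INTERSTITIAL") ~ "SCB",
    events$class %in% c("CO_4TO0", "CO_HYBRID") ~ "DSCB",
    events$class == "CO_SIMPLE" ~ "UNCLASSIFIED",
    TRUE ~ NA_character_
  )
  events
}

#' Plant recombination events into a hybrid diploid and derive sector truth
#'
#' Applies a list of recombination events to an all-heterozygous two-sector
#' colony, realizing the canonical sectored-colony LOH patterns: a reciprocal
#' crossover leaves the two daughters homozygous for opposite haplotypes
#' distal to the exchange; a 3:1 conversion tract extends one daughter's
#' homozygosity; a 4:0 tract is homozygous for the donor in both daughters;
#' break-induced replication produces terminal homozygosity in one daughter
#' only; interstitial conversions, segmental deletions and whole-chromosome
#' aneuploidy affect a single daughter.
#'
#' @param markers marker map tibble from [build_marker_map()].
#' @param events tibble with columns `chrom`, `class`, `start`, `end` and
#'   optional `donor` ("W"/"Y"), `sector` ("D1"/"D2"), `side`
#'   ("left"/"right": which telomere terminal classes run to), `mid`
#'   (boundary between the one-sector and shared parts of a hybrid tract) and
#'   `copies` (1 or 3, aneuploidy only). For `DELETION`, `donor` names the
#'   *lost* haplotype. Events on one chromosome must not overlap.
#' @param genome genome tibble the markers were built on.
#' @return a list with `truth` (tibble: `sector`, `chrom`, `pos`, `id`,
#'   `state`, `cn_w`, `cn_y`) and `events` (the validated event tibble).
#' @examples
#' mm <- build_marker_map(loh_genome(), 500, seed = 1)
#' ev <- tibble::tibble(chrom = "chrVII", class = "CO_SIMPLE",
#'                      start = 6e5, end = 6e5)
#' tr <- plant_events(mm, ev)
#' table(tr$truth$state, tr$truth$sector)
#' @export
plant_events <- function(markers, events = NULL, genome = loh_genome()) {
  .stopifnot_cols(markers, c("chrom", "pos", "id"), "`markers`")
  base <- tibble(
    chrom = markers$chrom, pos = markers$pos, id = markers$id,
    state = "HET", cn_w = 1L, cn_y = 1L
  )
  truth <- bind_rows(
    mutate(base, sector = "D1", .before = 1),
    mutate(base, sector = "D2", .before = 1)
  )
  if (is.null(events) || nrow(as_tibble(events)) == 0) {
    empty <- tibble(
      chrom = character(), class = character(), start = numeric(),
      end = numeric(), donor = character(), sector = character(),
      side = character(), mid = numeric(), copies = numeric(),
      break_type = character()
    )
    return(list(truth = truth, events = empty))
  }
  events <- .normalize_events(events, genome)
  glen <- setNames(genome$length, genome$chrom)

  set_state <- function(truth, sector, chrom, lo, hi, hap, del = FALSE, cn = NULL) {
    sel <- truth$sector == sector & truth$chrom == chrom &
      truth$pos >= lo & truth$pos <= hi
    if (del) {
      # `hap` is the lost haplotype
      truth$state[sel] <- paste0("DEL_", hap)
      truth$cn_w[sel] <- if (hap == "W") 0L else 1L
      truth$cn_y[sel] <- if (hap == "Y") 0L else 1L
    } else {
      truth$state[sel] <- .hom_state(hap)
      truth$cn_w[sel] <- if (hap == "W") 2L else 0L
      truth$cn_y[sel] <- if (hap == "Y") 2L else 0L
    }
    truth
  }

  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    d <- ev$donor
    o <- .other_hap(d)
    s1 <- ev$sector                      # daughter receiving the donor product
    s2 <- if (s1 == "D1") "D2" else "D1"
    L <- glen[[ev$chrom]]
    right <- ev$side == "right"
    # distal region beyond the exchange/tract, toward the telomere on `side`
    distal <- function(from) if (right) c(from, L) else c(1, from)

    n_in <- sum(markers$chrom == ev$chrom & markers$pos >= ev$start &
                  markers$pos <= ev$end)
    if (ev$class %in% c("CO_3TO1", "CO_4TO0", "CO_HYBRID", "NCO_INTERSTITIAL",
                        "DELETION", "BIR_TERMINAL") && n_in == 0) {
      warn(sprintf("planted %s tract on %s [%d, %d] contains no markers",
                   ev$class, ev$chrom, as.integer(ev$start), as.integer(ev$end)))
    }

    if (ev$class == "CO_SIMPLE") {
      bp <- if (right) ev$end else ev$start
      dz <- if (right) c(bp + 1, L) else c(1, bp - 1)
      truth <- set_state(truth, s1, ev$chrom, dz[1], dz[2], d)
      truth <- set_state(truth, s2, ev$chrom, dz[1], dz[2], o)
    } else if (ev$class == "CO_3TO1") {
      # donor homozygosity covers tract + distal in s1; s2 flips beyond tract
      sp1 <- if (right) c(ev$start, L) else c(1, ev$end)
      dz <- if (right) c(ev$end + 1, L) else c(1, ev$start - 1)
      truth <- set_state(truth, s1, ev$chrom, sp1[1], sp1[2], d)
      truth <- set_state(truth, s2, ev$chrom, dz[1], dz[2], o)
    } else if (ev$class == "CO_4TO0") {
      sp1 <- if (right) c(ev$start, L) else c(1, ev$end)
      truth <- set_state(truth, s1, ev$chrom, sp1[1], sp1[2], d)
      truth <- set_state(truth, s2, ev$chrom, ev$start, ev$end, d)
      dz <- if (right) c(ev$end + 1, L) else c(1, ev$start - 1)
      truth <- set_state(truth, s2, ev$chrom, dz[1], dz[2], o)
    } else if (ev$class == "CO_HYBRID") {
      # shared (4:0) part sits adjacent to the exchange point
      sp1 <- if (right) c(ev$start, L) else c(1, ev$end)
      truth <- set_state(truth, s1, ev$chrom, sp1[1], sp1[2], d)
      shared <- if (right) c(ev$mid, ev$end) else c(ev$start, ev$mid)
      truth <- set_state(truth, s2, ev$chrom, shared[1], shared[2], d)
      dz <- if (right) c(ev$end + 1, L) else c(1, ev$start - 1)
      truth <- set_state(truth, s2, ev$chrom, dz[1], dz[2], o)
    } else if (ev$class == "NCO_INTERSTITIAL") {
      truth <- set_state(truth, s1, ev$chrom, ev$start, ev$end, d)
    } else if (ev$class == "BIR_TERMINAL") {
      truth <- set_state(truth, s1, ev$chrom, ev$start, ev$end, d)
    } else if (ev$class == "DELETION") {
      truth <- set_state(truth, s1, ev$chrom, ev$start, ev$end, d, del = TRUE)
    } else if (ev$class == "ANEUPLOIDY") {
      sel <- truth$sector == s1 & truth$chrom == ev$chrom
      if (ev$copies == 1) {
        # monosomy retaining the donor homolog: the other haplotype is lost
        truth$state[sel] <- paste0("DEL_", o)
        truth$cn_w[sel] <- if (d == "W") 1L else 0L
        truth$cn_y[sel] <- if (d == "Y") 1L else 0L
      } else {
        # trisomy: extra copy of the donor homolog, markers remain heterozygous
        truth$cn_w[sel] <- if (d == "W") 2L else 1L
        truth$cn_y[sel] <- if (d == "Y") 2L else 1L
      }
    }
  }
  events$.span_lo <- NULL
  events$.span_hi <- NULL
  list(truth = truth, events = events)
}

#' Simulate allele-specific hybridization ratio tables
#'
#' Draws a W-channel and Y-channel ratio for every marker of every sector as
#' the copy-count mean times lognormal multiplicative noise
#' (`mean * exp(N(0, sigma))`). At `sigma = 0` the ratios equal the channel
#' means exactly, giving a noiseless table for round-trip verification.
#'
#' @param truth sector truth tibble from [plant_events()] (`$truth`).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return a tibble `sector`, `chrom`, `pos`, `id`, `ratio_w`, `ratio_y`.
#' @export
simulate_ratios <- function(truth, noise = noise_model(), seed = 1) {
  .stopifnot_cols(truth, c("sector", "chrom", "pos", "id", "cn_w", "cn_y"),
                  "`truth`")
  if (!inherits(noise, "loh_noise_model")) abort("`noise` must be a noise_model()")
  set.seed(derive_seed(seed, 2L))
  n <- nrow(truth)
  e_w <- if (noise$sigma > 0) exp(rnorm(n, 0, noise$sigma)) else rep(1, n)
  e_y <- if (noise$sigma > 0) exp(rnorm(n, 0, noise$sigma)) else rep(1, n)
  tibble(
    sector = truth$sector, chrom = truth$chrom, pos = truth$pos, id = truth$id,
    ratio_w = .channel_mean(truth$cn_w, noise) * e_w,
    ratio_y = .channel_mean(truth$cn_y, noise) * e_y
  )
}
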