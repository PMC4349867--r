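#' Per-colony recombination event rates
#'
#' Study-condition defaults for the rate-based generator: mean numbers of
#' events per sectored colony, matching a UV-irradiated NER-deficient diploid
#' (interstitial conversions 3.9, crossovers 1.5, BIR 1.3 per sector pair,
#' with occasional deletions and rare aneuploidy). Crossovers are split
#' between simple crossovers (no detectable conversion) and conversion-bearing
#' ones; the conversion-bearing class mix realizes the 76% SCB / 24% DSCB
#' proportion (3:1 tracts are SCB; 4:0 and hybrid tracts are DSCB).
#'
#' @param interstitial,crossover,bir,deletion,aneuploidy Poisson means per
#'   colony for each category.
#' @param co_simple_frac fraction of crossovers without a detectable
#'   conversion tract.
#' @param scb_frac among conversion-bearing crossovers, fraction that are 3:1
#'   (SCB); the remainder split equally between 4:0 and hybrid (DSCB).
#' @param nco_median_kb,co_median_kb,tract_sdlog lognormal tract-length
#'   parameters (medians in kb) for interstitial and crossover-associated
#'   conversion tracts.
#' @return a list of class `loh_event_rates`.
#' @export
event_rates <- function(interstitial = 3.9, crossover = 1.5, bir = 1.3,
                        deletion = 0.33, aneuploidy = 0.05,
                        co_simple_frac = 0.2, scb_frac = 0.76,
                        nco_median_kb = 4.3, co_median_kb = 8.7,
                        tract_sdlog = 0.6) {
  vals <- c(interstitial = interstitial, crossover = crossover, bir = bir,
            deletion = deletion, aneuploidy = aneuploidy)
  if (any(vals < 0)) abort("event rates must be >= 0")
  if (co_simple_frac < 0 || co_simple_frac > 1 || scb_frac < 0 || scb_frac > 1) {
    abort("fractions must be in [0, 1]")
  }
  structure(
    list(interstitial = interstitial, crossover = crossover, bir = bir,
         deletion = deletion, aneuploidy = aneuploidy,
         co_simple_frac = co_simple_frac, scb_frac = scb_frac,
         nco_median_kb = nco_median_kb, co_median_kb = co_median_kb,
         tract_sdlog = tract_sdlog),
    class = "loh_event_rates"
  )
}

# Draw a tract [start, end] inside [lo, hi] containing >= min_markers markers
# of `mpos` (sorted positions on one chromosome); for hybrid tracts both
# halves must each cover >= min_markers. Extends the tract deterministically
# if rejection sampling fails.
.draw_tract <- function(mpos, lo, hi, median_kb, sdlog, min_markers,
                        hybrid = FALSE) {
  need <- if (hybrid) 2 * min_markers else min_markers
  inside <- mpos[mpos >= lo & mpos <= hi]
  if (length(inside) < need + 2) return(NULL)
  for (try in 1:40) {
    len <- exp(rnorm(1, log(median_kb * 1000), sdlog))
    len <- min(len, (hi - lo) * 0.9)
    start <- floor(runif(1, lo, hi - len))
    end <- floor(start + len)
    mid <- if (hybrid) floor((start + end) / 2) else NA_real_
    k <- sum(inside >= start & inside <= end)
    ok <- if (hybrid) {
      sum(inside >= start & inside < mid) >= min_markers &&
        sum(inside >= mid & inside <= end) >= min_markers
    } else k >= min_markers
    if (ok) return(list(start = start, end = end, mid = mid))
  }
  # deterministic fallback: take a run of `need` consecutive markers
  i0 <- sample.int(length(inside) - need, 1)
  start <- inside[i0] - 1
  end <- inside[i0 + need - 1] + 1
  mid <- if (hybrid) floor((inside[i0 + min_markers - 1] + inside[i0 + min_markers]) / 2) else NA_real_
  list(start = start, end = end, mid = mid)
}

#' Simulate one sectored colony with planted events
#'
#' Draws per-category event counts from Poisson distributions with the
#' [event_rates()] means, places at most one event per chromosome arm
#' (aneuploidy occupies a whole free chromosome), assigns random donor
#' haplotypes and sectors, and returns the ground truth plus noisy ratio
#' tables for both daughters. Planted conversion tracts always cover at least
#' `min_tract_markers` markers (each half of a hybrid tract separately), so
#' every planted event is above the pipeline's documented detection floor.
#'
#' @param markers marker map.
#' @param genome genome tibble.
#' @param rates an [event_rates()] object.
#' @param noise a [noise_model()].
#' @param seed integer seed for this colony.
#' @param colony colony identifier string.
#' @param min_tract_markers minimum markers per planted conversion tract.
#' @return list with `colony`, `events` (planted truth, with `colony` column),
#'   `truth` (per-marker states) and `ratios` (both sectors).
#' @export
simulate_colony <- function(markers, genome = loh_genome(),
                            rates = event_rates(), noise = noise_model(),
                            seed = 1, colony = "colony1",
                            min_tract_markers = 3) {
  set.seed(derive_seed(seed, 3L))
  arm_margin <- 15000  # keep tracts clear of telomere/centromere
  arms <- bind_rows(
    tibble(chrom = genome$chrom, side = "left",
           lo = arm_margin, hi = genome$cen - 5000),
    tibble(chrom = genome$chrom, side = "right",
           lo = genome$cen + 5000, hi = genome$length - arm_margin)
  )
  arms <- filter(arms, .data$hi - .data$lo > 60000)
  arms <- arms[sample.int(nrow(arms)), ]
  used <- rep(FALSE, nrow(arms))

  n_cat <- c(
    ANEUPLOIDY = rpois(1, rates$aneuploidy),
    crossover = rpois(1, rates$crossover),
    BIR_TERMINAL = rpois(1, rates$bir),
    NCO_INTERSTITIAL = rpois(1, rates$interstitial),
    DELETION = rpois(1, rates$deletion)
  )
  mpos_by_chrom <- split(markers$pos, markers$chrom)
  evs <- list()

  take_arm <- function() {
    i <- which(!used)[1]
    if (is.na(i)) return(NULL)
    used[i] <<- TRUE
    arms[i, ]
  }

  for (cat in names(n_cat)) {
    for (k in seq_len(n_cat[[cat]])) {
      donor <- sample(c("W", "Y"), 1)
      sector <- sample(c("D1", "D2"), 1)
      if (cat == "ANEUPLOIDY") {
        # needs a whole chromosome with both arms unused
        free <- vapply(unique(arms$chrom), function(ch) {
          all(!used[arms$chrom == ch])
        }, logical(1))
        ch <- names(free)[free][1]
        if (is.na(ch) || is.null(ch)) next
        used[arms$chrom == ch] <- TRUE
        evs[[length(evs) + 1]] <- tibble(
          chrom = ch, class = "ANEUPLOIDY", start = 1,
          end = genome$length[genome$chrom == ch], donor = donor,
          sector = sector, side = "right", mid = NA_real_,
          copies = sample(c(1, 3), 1)
        )
        next
      }
      arm <- take_arm()
      if (is.null(arm)) next
      mpos <- mpos_by_chrom[[arm$chrom]]
      cls <- switch(cat,
        crossover = {
          u <- runif(1)
          if (u < rates$co_simple_frac) "CO_SIMPLE"
          else {
            v <- runif(1)
            if (v < rates$scb_frac) "CO_3TO1"
            else if (v < rates$scb_frac + (1 - rates$scb_frac) / 2) "CO_4TO0"
            else "CO_HYBRID"
          }
        },
        cat
      )
      if (cls == "CO_SIMPLE") {
        # breakpoint in the central part of the arm so both flanks have markers
        span <- arm$hi - arm$lo
        bp <- floor(runif(1, arm$lo + 0.2 * span, arm$hi - 0.2 * span))
        evs[[length(evs) + 1]] <- tibble(
          chrom = arm$chrom, class = cls, start = bp, end = bp, donor = donor,
          sector = sector, side = arm$side, mid = NA_real_, copies = NA_real_
        )
      } else if (cls == "BIR_TERMINAL") {
        span <- arm$hi - arm$lo
        tr <- .draw_tract(mpos, arm$lo + 0.2 * span, arm$hi,
                          rates$co_median_kb, rates$tract_sdlog,
                          min_tract_markers)
        if (is.null(tr)) next
        start <- if (arm$side == "right") tr$start else 1
        end <- if (arm$side == "right") {
          genome$length[genome$chrom == arm$chrom]
        } else tr$end
        evs[[length(evs) + 1]] <- tibble(
          chrom = arm$chrom, class = cls, start = start, end = end,
          donor = donor, sector = sector, side = arm$side, mid = NA_real_,
          copies = NA_real_
        )
      } else {
        med <- if (cls == "NCO_INTERSTITIAL") rates$nco_median_kb else rates$co_median_kb
        span <- arm$hi - arm$lo
        tr <- .draw_tract(mpos, arm$lo + 0.15 * span, arm$hi - 0.15 * span,
                          med, rates$tract_sdlog, min_tract_markers,
                          hybrid = (cls == "CO_HYBRID"))
        if (is.null(tr)) next
        evs[[length(evs) + 1]] <- tibble(
          chrom = arm$chrom, class = cls, start = tr$start, end = tr$end,
          donor = donor, sector = sector, side = arm$side, mid = tr$mid,
          copies = NA_real_
        )
      }
    }
  }

  events <- if (length(evs)) bind_rows(evs) else NULL
  planted <- plant_events(markers, events, genome)
  ratios <- simulate_ratios(planted$truth, noise, seed = derive_seed(seed, 4L))
  pl_ev <- planted$events
  if (nrow(pl_ev)) pl_ev <- mutate(pl_ev, colony = colony, .before = 1)
  list(colony = colony, events = pl_ev, truth = planted$truth, ratios = ratios)
}
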