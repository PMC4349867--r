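#' Hybrid diploid genome model
#'
#' A 16-chromosome genome model at the scale of the *S. cerevisiae* nuclear
#' genome (~12 Mb), with approximate centromere positions. This is the
#' coordinate frame for the synthetic W303-1A x YJM789 hybrid diploid in which
#' recombination events are planted; chromosome and centromere coordinates are
#' the standard reference values rounded to the base pair.
#'
#' @return a tibble with columns `chrom` (character), `length` (bp) and
#'   `cen` (centromere midpoint, bp).
#' @examples
#' loh_genome()
#' @export
loh_genome <- function() {
  tibble(
    chrom = paste0("chr", c(
      "I", "II", "III", "IV", "V", "VI", "VII", "VIII",
      "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI"
    )),
    length = c(
      230218L, 813184L, 316620L, 1531933L, 576874L, 270161L, 1090940L,
      562643L, 439888L, 745751L, 666816L, 1078177L, 924431L, 784333L,
      1091291L, 948066L
    ),
    cen = c(
      151465L, 238207L, 114385L, 449711L, 151987L, 148510L, 496920L,
      105586L, 355629L, 436307L, 440129L, 150828L, 268031L, 628758L,
      326584L, 555957L
    )
  )
}

.check_genome <- function(genome) {
  .stopifnot_cols(genome, c("chrom", "length"), "`genome`")
  if (any(genome$length <= 0)) abort("all chromosome lengths must be > 0")
  if (anyDuplicated(genome$chrom)) abort("chromosome names must be unique")
  genome
}

#' Build a heterozygous SNP marker map
#'
#' Allocates `n_markers` heterozygous markers to chromosomes in proportion to
#' chromosome length (largest-remainder rounding, at least one marker per
#' chromosome) and draws marker positions uniformly without replacement within
#' each chromosome. The default marker count matches the ~13,000 SNPs
#' interrogated by the whole-genome arrays the pipeline emulates.
#'
#' @param genome genome tibble as returned by [loh_genome()].
#' @param n_markers total number of markers (>= number of chromosomes).
#' @param seed integer seed; the same seed reproduces the map bit-identically.
#' @return a tibble with columns `chrom`, `pos` (1-based bp) and `id`, sorted
#'   by chromosome then position.
#' @examples
#' mm <- build_marker_map(loh_genome(), n_markers = 1000, seed = 1)
#' dplyr::count(mm, chrom)
#' @export
build_marker_map <- function(genome = loh_genome(), n_markers = 13000, seed = 1) {
  genome <- .check_genome(genome)
  n_markers <- .check_count(n_markers, "n_markers", min = 1)
  if (n_markers < nrow(genome)) {
    abort("`n_markers` must be at least one marker per chromosome")
  }
  if (n_markers > sum(as.numeric(genome$length))) {
    abort("`n_markers` exceeds the number of available bp positions in the genome")
  }

  # Largest-remainder allocation proportional to length, floor of 1 per chrom.
  share <- genome$length / sum(as.numeric(genome$length)) * n_markers
  alloc <- pmax(1L, floor(share))
  rem <- n_markers - sum(alloc)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    take <- rep_len(ord, rem)
    alloc <- alloc + tabulate(take, nbins = nrow(genome))
  } else if (rem < 0) {
    ord <- order(share - floor(share))
    i <- 1
    while (rem < 0) {
      j <- ord[i]
      if (alloc[j] > 1L) {
        alloc[j] <- alloc[j] - 1L
        rem <- rem + 1L
      }
      i <- if (i == length(ord)) 1 else i + 1
    }
  }
  if (any(alloc > genome$length)) {
    abort("marker allocation exceeds chromosome length; reduce `n_markers`")
  }

  set.seed(derive_seed(seed, 1L))
  out <- map2(genome$chrom, seq_len(nrow(genome)), function(chrom, i) {
    tibble(chrom = chrom, pos = sort(sample.int(genome$length[i], alloc[i])))
  })
  out <- bind_rows(out)
  out$chrom <- factor(out$chrom, levels = genome$chrom)
  out <- arrange(out, .data$chrom, .data$pos)
  out$chrom <- as.character(out$chrom)
  out$id <- sprintf("m%05d", seq_len(nrow(out)))
  out
}

#' Array coverage mask
#'
#' Genome regions considered analyzable by the array. Regions within
#' `telomere_trim` bp of either chromosome end are excluded, reflecting the
#' repeated, near-telomeric sequence that SNP arrays cannot interrogate.
#'
#' @param genome genome tibble.
#' @param telomere_trim bp trimmed from each chromosome end (default 10 kb).
#' @return tibble of disjoint intervals `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @export
coverage_mask <- function(genome = loh_genome(), telomere_trim = 10000) {
  genome <- .check_genome(genome)
  out <- tibble(
    chrom = genome$chrom,
    start = pmin(telomere_trim + 1, genome$length),
    end = pmax(genome$length - telomere_trim, 1)
  )
  filter(out, .data$start <= .data$end)
}
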