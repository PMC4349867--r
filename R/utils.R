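#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number across all_of desc lag lead
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dfr map2 pmap imap keep
#' @importFrom stats rnorm median mad qbeta pchisq pnorm dhyper quantile rpois
#'   runif sd setNames
#' @importFrom utils head tail packageVersion
NULL

# Genotype states used throughout. HOM_W / HOM_Y: homozygous for the W303-1A-
# or YJM789-derived haplotype; DEL_W / DEL_Y: the named haplotype is lost
# (hemizygous for the other one).
.loh_states <- c("HET", "HOM_W", "HOM_Y", "DEL_W", "DEL_Y", "UNCALLED")

.other_hap <- function(h) ifelse(h == "W", "Y", "W")

.hom_state <- function(h) paste0("HOM_", h)

.hap_of_hom <- function(state) sub("^HOM_", "", state)

#' Derive a stage seed from a master seed
#'
#' All stochastic stages draw their seed deterministically from the run's
#' master seed, so a single integer reproduces the whole analysis.
#'
#' @param seed master seed (integer).
#' @param stage small integer offset distinguishing the stage.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage = 0L) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(stage)) %% 2147483587)
}

.check_count <- function(x, name, min = 0) {
  if (length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  invisible(as.integer(x))
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
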