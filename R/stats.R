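#' Result container for the package's hypothesis tests
#'
#' @param method test name.
#' @param statistic test statistic (may be NA).
#' @param p.value two-sided p-value.
#' @param details list of extra fields.
#' @return object of class `loh_test`.
#' @keywords internal
new_loh_test <- function(method, statistic, p.value, details = list()) {
  structure(list(method = method, statistic = statistic, p.value = p.value,
                 details = details),
            class = "loh_test")
}

#' @export
print.loh_test <- function(x, ...) {
  cat(sprintf("\n\t%s\n\n", x$method))
  if (!is.na(x$statistic)) cat(sprintf("statistic = %.6g, ", x$statistic))
  cat(sprintf("p-value = %.4g (two-sided)\n", x$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.loh_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p.value = x$p.value)
}

#' @exportS3Method generics::glance
glance.loh_test <- function(x, ...) tidy(x)

#' Sectored-colony frequency with exact confidence interval
#'
#' Frequency of sectored colonies among total colonies screened, with an
#' exact (Clopper-Pearson) 95% confidence interval.
#'
#' @param k number of sectored colonies.
#' @param n total colonies screened (> 0).
#' @param conf_level confidence level (default 0.95).
#' @return one-row tibble: `k`, `n`, `frequency`, `ci_lo`, `ci_hi`.
#' @examples
#' sector_frequency(23, 4853)
#' @export
sector_frequency <- function(k, n, conf_level = 0.95) {
  .check_count(k, "k"); .check_count(n, "n", min = 1)
  if (k > n) abort("`k` must not exceed `n`")
  a <- (1 - conf_level) / 2
  lo <- if (k == 0) 0 else qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  tibble(k = k, n = n, frequency = k / n, ci_lo = lo, ci_hi = hi)
}

#' Mitotic crossover rate from the sectoring frequency
#'
#' Only half of reciprocal crossovers segregate the two homozygous products
#' into different daughter cells, so the crossover rate is twice the observed
#' frequency of sectored colonies.
#'
#' @param freq a frequency (numeric) or a [sector_frequency()] tibble.
#' @return numeric rate, or the tibble with `rate` columns appended.
#' @export
crossover_rate <- function(freq) {
  if (is.data.frame(freq)) {
    mutate(freq, rate = 2 * .data$frequency,
           rate_lo = 2 * .data$ci_lo, rate_hi = 2 * .data$ci_hi)
  } else {
    2 * freq
  }
}

#' Fold change between two frequencies or per-colony means
#'
#' @param a,b numerators: single numeric values (frequencies or means);
#'   `b` must be positive.
#' @return the ratio `a / b`.
#' @seealso [format_fold()] for the table display convention.
#' @export
fold_change <- function(a, b) {
  if (any(!is.na(b) & b <= 0)) abort("fold_change denominator must be > 0")
  a / b
}

#' Display convention for fold changes
#'
#' Folds of 10 or more are rounded to the nearest integer; smaller folds to
#' two decimals.
#'
#' @param x numeric fold change(s).
#' @return numeric, rounded per the convention.
#' @export
format_fold <- function(x) {
  ifelse(abs(x) >= 10, round(x), round(x, 2))
}

#' Median with percentile-bootstrap confidence interval
#'
#' @param lengths numeric vector (e.g. conversion tract lengths in kb);
#'   at least 2 values.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param conf_level confidence level (default 0.95).
#' @return one-row tibble: `n`, `median`, `ci_lo`, `ci_hi`.
#' @export
median_with_ci <- function(lengths, n_boot = 10000, seed = 1,
                           conf_level = 0.95) {
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) < 2) abort("need at least 2 values")
  .check_count(n_boot, "n_boot", min = 1000)
  set.seed(derive_seed(seed, 5L))
  boots <- vapply(seq_len(n_boot), function(i) {
    median(sample(lengths, replace = TRUE))
  }, numeric(1))
  a <- (1 - conf_level) / 2
  ci <- quantile(boots, c(a, 1 - a), names = FALSE)
  tibble(n = length(lengths), median = median(lengths),
         ci_lo = ci[1], ci_hi = ci[2])
}

# Exact null distribution of the Mann-Whitney U statistic by dynamic
# programming on the recursion c(i, j, u) = c(i-1, j, u-j) + c(i, j-1, u)
# (Gaussian binomial coefficients); counts[u + 1] = number of the
# choose(m + n, m) rank arrangements with U = u.
.u_counts <- function(m, n) {
  len <- m * n + 1
  delta <- c(1, rep(0, len - 1))
  prev <- rep(list(delta), n + 1)  # i = 0 row: U must be 0
  for (i in seq_len(m)) {
    cur <- vector("list", n + 1)
    cur[[1]] <- delta               # j = 0: U must be 0
    for (j in seq_len(n)) {
      shifted <- c(rep(0, j), prev[[j + 1]][seq_len(len - j)])
      cur[[j + 1]] <- shifted + cur[[j]]
    }
    prev <- cur
  }
  prev[[n + 1]]
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test for a location difference between two samples. When the
#' smaller sample has at most `exact_max` observations and there are no
#' ties, the p-value is computed from the exact permutation distribution of
#' the U statistic (enumerated by dynamic programming); otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest min(nx, ny) for which the exact path is used
#'   (default 8).
#' @return an `loh_test` with the U statistic for `x`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(m, n) <= exact_max && !ties) {
    counts <- .u_counts(m, n)
    total <- sum(counts)
    # two-sided by symmetry of the U distribution around mn/2
    u_lo <- min(u, m * n - u)
    u_hi <- m * n - u_lo
    p <- (sum(counts[seq_len(u_lo + 1)]) +
            sum(counts[seq(u_hi + 1, m * n + 1)])) / total
    p <- min(1, p)
    return(new_loh_test("Mann-Whitney test (exact)", u, p,
                        details = list(n_x = m, n_y = n)))
  }
  N <- m + n
  mu <- m * n / 2
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_corr)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  new_loh_test("Mann-Whitney test (normal approximation)", u, p,
               details = list(n_x = m, n_y = n, z = z))
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of the tables whose probability does
#' not exceed that of the observed table (within a small relative
#' tolerance for floating-point safety).
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`, or a
#'   2x2 matrix as `a` alone.
#' @return an `loh_test`.
#' @examples
#' fisher_exact(9, 1, 2, 2)  # p = 0.18 at two decimals
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    tab <- a
    if (!all(dim(tab) == c(2, 2))) abort("matrix input must be 2x2")
    b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]; a <- tab[1, 1]
  }
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != floor(cnt))) abort("counts must be non-negative integers")
  if (sum(cnt) == 0) abort("table must have at least one positive margin")
  r1 <- a + b
  c1 <- a + c
  N <- sum(cnt)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(support, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_loh_test("Fisher exact test", NA_real_, min(1, p),
               details = list(table = matrix(cnt, 2, byrow = TRUE)))
}

#' Chi-square goodness-of-fit test
#'
#' Statistic `sum((obs - exp)^2 / exp)` referred to a chi-square distribution
#' with `length(observed) - 1` degrees of freedom.
#'
#' @param observed observed counts.
#' @param expected expected counts (> 0), same length.
#' @return an `loh_test`.
#' @export
chi_square_gof <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    abort("`observed` and `expected` must have the same length")
  }
  if (any(expected <= 0)) abort("expected counts must be > 0")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  p <- pchisq(stat, df, lower.tail = FALSE)
  new_loh_test("Chi-square goodness-of-fit test", stat, p,
               details = list(df = df))
}
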