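#' @keywords internal
"_PACKAGE"

## formatted stop/warning helpers
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the
#' Benjamini-Hochberg step-up procedure. `NA` entries are carried through
#' unadjusted and do not count towards the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values (FDR), same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv)
  ranked <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}

## sample skewness: m3 / m2^(3/2)
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

## excess kurtosis: m4 / m2^2 - 3
sample_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

## deterministic lexicographic sort (C locale) so alignment is reproducible
## across platforms regardless of collation settings
lex_sort <- function(x) sort(x, method = "radix")

## two-sample Kolmogorov-Smirnov comparison with set-oriented semantics:
## alternative "less" means values of `x` tend to be SMALLER than `y`
## (x's empirical CDF lies above y's), "greater" the opposite.
## stats::ks.test uses the CDF convention, so the sides are swapped here.
ks_compare <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) stopf("both samples must be nonempty")
  alt_r <- switch(alternative,
    two_sided = "two.sided",
    less      = "greater",  # x stochastically smaller => CDF of x above y's
    greater   = "less"
  )
  ht <- suppressWarnings(stats::ks.test(x, y, alternative = alt_r))
  list(
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    alternative = alternative,
    n_x = length(x),
    n_y = length(y)
  )
}

## Spearman rank correlation that returns NA (not an error/warning) when
## either vector is constant
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}
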