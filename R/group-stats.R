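#' Welch two-sample t-test between group samples
#'
#' Unequal-variance (Welch) two-sample t-test with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value, as used to compare scalar
#' pipeline outputs (vessel density, NVC peak and AUC) between groups.
#' Degenerate inputs follow fixed conventions: two zero-variance groups
#' with equal means give `t = 0, p = 1`; zero variance with unequal means
#' gives an infinite statistic and the smallest representable p.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic` (t), `p_value` (two-sided), `df`,
#'   `estimate` (mean difference a - b), `n_a`, `n_b`.
#' @export
two_sample_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need n >= 2", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1, df = length(a) + length(b) - 2,
                  estimate = 0, n_a = length(a), n_b = length(b)))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                p_value = .Machine$double.xmin,
                df = length(a) + length(b) - 2,
                estimate = mean(a) - mean(b),
                n_a = length(a), n_b = length(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), estimate = mean(a) - mean(b),
       n_a = length(a), n_b = length(b))
}

# asymptotic Kolmogorov survival function Q(lambda)
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Two-sample Kolmogorov-Smirnov comparison of distributions
#'
#' Compares two distributions via the supremum gap between their empirical
#' CDFs. `mode = "sample"` (default, the statistically faithful reading)
#' tests the raw per-segment samples using [stats::ks.test()] with the
#' asymptotic p-value. `mode = "histogram"` reproduces figure-style
#' comparisons of mode-normalized diameter histograms: the inputs must be
#' two [diameter_histogram()] objects; D is the largest gap between the
#' CDFs implied by the raw bin counts and the p-value uses the asymptotic
#' Kolmogorov distribution with effective size `n_a n_b / (n_a + n_b)`.
#'
#' @param a,b numeric samples, or `diameter_histogram` objects for
#'   `mode = "histogram"`.
#' @param mode `"sample"` or `"histogram"`.
#' @return list with `D`, `p_value`, `n_a`, `n_b`, `mode`.
#' @export
ks_two_sample <- function(a, b, mode = c("sample", "histogram")) {
  mode <- match.arg(mode)
  if (mode == "histogram") {
    if (!inherits(a, "diameter_histogram") || !inherits(b, "diameter_histogram"))
      stop("histogram mode needs two diameter_histogram objects",
           call. = FALSE)
    if (length(a$counts) != length(b$counts))
      stop("histograms must share binning", call. = FALSE)
    Fa <- cumsum(a$counts) / sum(a$counts)
    Fb <- cumsum(b$counts) / sum(b$counts)
    D <- max(abs(Fa - Fb))
    na <- sum(a$counts); nb <- sum(b$counts)
    ne <- na * nb / (na + nb)
    return(list(D = D, p_value = kolmogorov_q(sqrt(ne) * D),
                n_a = na, n_b = nb, mode = mode))
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both samples must be nonempty", call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(ht$statistic), p_value = ht$p.value,
       n_a = length(a), n_b = length(b), mode = mode)
}

#' Logarithmic trend of group mean CBF versus age
#'
#' Least-squares fit of `mean = a + b log(age)` through per-group means, a
#' descriptive summary of the temporal evolution of CBF with age (a guide
#' to the eye, not an inferential model — no standard errors are attached).
#'
#' @param ages_months ages in months, all > 0, at least two distinct.
#' @param means group mean CBF values (same length).
#' @return an object of class `log_trend_fit`: list with `a` (intercept),
#'   `b` (slope per log month), `rss`, `fitted`, and `predict(ages)`.
#' @examples
#' fit <- fit_log_trend(c(12, 18, 24), 10 + 5 * log(c(12, 18, 24)))
#' fit$b  # 5
#' @export
fit_log_trend <- function(ages_months, means) {
  ages_months <- as.numeric(ages_months); means <- as.numeric(means)
  if (any(ages_months <= 0))
    stop("ages must be positive for a logarithmic trend", call. = FALSE)
  if (length(unique(ages_months)) < 2L)
    stop("need at least two distinct ages", call. = FALSE)
  if (length(ages_months) != length(means))
    stop("'ages_months' and 'means' differ in length", call. = FALSE)
  fit <- stats::lm(means ~ log(ages_months))
  co <- unname(stats::coef(fit))
  structure(list(a = co[1], b = co[2], rss = sum(stats::resid(fit)^2),
                 fitted = unname(stats::fitted(fit)),
                 predict = function(ages) co[1] + co[2] * log(ages)),
            class = "log_trend_fit")
}

#' @export
print.log_trend_fit <- function(x, ...) {
  cat(sprintf("<log_trend_fit: mean = %.4g + %.4g log(age), RSS = %.3g>\n",
              x$a, x$b, x$rss))
  invisible(x)
}
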