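#' Rank association and distribution assessment
#'
#' Tie-aware Spearman correlation (Pearson correlation of mid-ranks, the
#' right convention when one variable is an ordinal pain category with
#' heavy ties), permutation and asymptotic p-values, pairs-bootstrap
#' percentile confidence intervals, and Shapiro-Wilk normality summaries
#' with Q-Q and histogram series for external plotting.
#'
#' @name association_distribution
NULL

#' Spearman rank correlation (mid-ranks)
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   variable is constant.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 0.8944
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort_validation("x and y must have equal length", "pulpdx_bad_value")
  }
  if (length(x) < 3) abort_validation("need n >= 3", "pulpdx_bad_value")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("constant variable: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' p-value for a Spearman correlation
#'
#' `"permutation"` (default, suited to n = 13): the proportion of `b`
#' random permutations of `y` whose absolute correlation meets or exceeds
#' the observed one, with the plus-one correction
#' `(1 + count) / (1 + b)`. `"asymptotic"`: the t approximation with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param method `"permutation"` or `"asymptotic"`.
#' @param b Number of permutations (permutation method).
#' @param seed Integer seed (permutation method).
#' @return A two-sided p-value.
#' @export
correlation_pvalue <- function(x, y, method = c("permutation", "asymptotic"),
                               b = 10000, seed = 20250307) {
  method <- match.arg(method)
  rho <- spearman_rho(x, y)
  if (is.na(rho)) abort_validation("constant input", "pulpdx_bad_value")
  n <- length(x)
  if (method == "asymptotic") {
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * stats::pt(-abs(tstat), df = n - 2))
  }
  rx <- rank(x)
  ry <- rank(y)
  with_seed(seed, {
    hits <- sum(vapply(seq_len(b), function(i) {
      abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12
    }, logical(1)))
    (1 + hits) / (1 + b)
  })
}

#' Pairs-bootstrap percentile CI for a bivariate statistic
#'
#' Resamples `(x, y)` pairs with replacement and takes the percentile
#' interval of the statistic. Resamples on which the statistic is
#' undefined (`NA`, e.g. a constant variable under heavy ties) are
#' redrawn, up to `10 * b` total attempts.
#'
#' @param x,y Paired numeric vectors.
#' @param statistic Function of `(x, y)` returning a scalar (default
#'   [spearman_rho()]).
#' @param b Number of resamples (`>= 100`).
#' @param confidence Confidence level.
#' @param seed Integer seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci_statistic <- function(x, y, statistic = spearman_rho,
                                   b = 10000, confidence = 0.95,
                                   seed = 20250307) {
  if (b < 100) abort_validation("b must be >= 100", "pulpdx_bad_value")
  if (length(x) != length(y)) {
    abort_validation("x and y must have equal length", "pulpdx_bad_value")
  }
  n <- length(x)
  stats_out <- numeric(b)
  with_seed(seed, {
    kept <- 0L
    attempts <- 0L
    while (kept < b) {
      if (attempts >= 10L * b) {
        abort_validation("too many undefined bootstrap resamples", "pulpdx_bootstrap_cap")
      }
      attempts <- attempts + 1L
      idx <- sample.int(n, n, replace = TRUE)
      val <- suppressWarnings(statistic(x[idx], y[idx]))
      if (!is.na(val)) {
        kept <- kept + 1L
        stats_out[kept] <- val
      }
    }
  })
  alpha <- 1 - confidence
  q <- stats::quantile(stats_out, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Shapiro-Wilk normality assessment with plot series
#'
#' W statistic and p-value via the Royston approximation
#' ([stats::shapiro.test()]), Q-Q points at the `(i - 0.375) / (n + 0.25)`
#' plotting positions, and a histogram series under the Freedman-Diaconis
#' bin rule — the data behind a Q-Q panel and histogram/density panel.
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return A `normality_result` list: `w_statistic`, `p_value`,
#'   `qq_points` (data frame `theoretical`, `sample`), `histogram` (data
#'   frame `lower`, `upper`, `count`), `n`. Constant input gives `NA`
#'   statistics with a `constant` flag.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) abort_validation("need 3 <= n <= 5000", "pulpdx_bad_value")
  if (anyNA(values)) abort_validation("missing values not allowed", "pulpdx_bad_value")
  constant <- stats::var(values) == 0
  sorted <- sort(values)
  qq <- data.frame(
    theoretical = stats::qnorm((seq_len(n) - 0.375) / (n + 0.25)),
    sample = sorted
  )
  breaks <- if (constant) c(sorted[1] - 0.5, sorted[1] + 0.5) else {
    h <- grDevices::nclass.FD(values)
    seq(min(values), max(values), length.out = h + 1)
  }
  counts <- if (constant) n else {
    graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  }
  hist_df <- data.frame(lower = utils::head(breaks, -1),
                        upper = utils::tail(breaks, -1),
                        count = counts)
  if (constant) {
    return(structure(list(w_statistic = NA_real_, p_value = NA_real_,
                          qq_points = qq, histogram = hist_df,
                          n = n, constant = TRUE),
                     class = "normality_result"))
  }
  sw <- stats::shapiro.test(values)
  structure(
    list(w_statistic = unname(sw$statistic), p_value = sw$p.value,
         qq_points = qq, histogram = hist_df, n = n, constant = FALSE),
    class = "normality_result"
  )
}
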