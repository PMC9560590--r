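#' Statistical test result container
#'
#' Uniform container for the package's statistical battery: test name,
#' statistic, degrees of freedom (scalar or pair), two-sided p-value, the
#' Bonferroni-corrected p-value (when a family has been applied), the
#' sample size, and the family size.
#'
#' @param test test name.
#' @param statistic statistic value.
#' @param df degrees of freedom (scalar or length-2).
#' @param p two-sided p-value.
#' @param n sample size used.
#' @param estimate optional effect estimate (e.g. Pearson r, mean diff).
#' @param m family size for correction; `NA` if uncorrected.
#' @return object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, df, p, n, estimate = NA_real_,
                        m = NA_integer_) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p-value outside [0, 1]")
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 p_corrected = if (is.na(m)) NA_real_ else min(1, m * p),
                 n = n, estimate = estimate, m = m),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g (n = %d)\n",
              x$test, x$statistic, paste(x$df, collapse = ", "), x$p, x$n))
  if (!is.na(x$p_corrected))
    cat(sprintf("  Bonferroni (m = %d): p = %.4g\n", x$m, x$p_corrected))
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test: `t = mean(d) / (sd(d)/sqrt(n))` on the
#' differences `post - pre`, df = n - 1.  All-zero differences give
#' t = 0, p = 1 (no change at all); non-zero constant differences have an
#' undefined t and raise an error.
#'
#' @param pre,post paired numeric vectors of equal length (n >= 2).
#' @return a [stat_result].
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("'pre' and 'post' lengths differ")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  d <- post - pre
  if (sd(d) == 0) {
    if (all(d == 0))
      return(stat_result("paired_t", 0, n - 1, 1, n, estimate = 0))
    stop("paired differences have zero variance; t is undefined")
  }
  res <- t.test(post, pre, paired = TRUE)
  stat_result("paired_t", unname(res$statistic), unname(res$parameter),
              res$p.value, n, estimate = mean(d))
}

#' Two-sample pooled-variance t-test
#'
#' Student's t with pooled variance (df = n1 + n2 - 2), two-sided.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a [stat_result].
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      stop("both groups constant and equal; t is undefined")
    # constant unequal groups: infinite separation
    return(stat_result("two_sample_t", sign(mean(a) - mean(b)) * Inf,
                       length(a) + length(b) - 2, 0,
                       length(a) + length(b),
                       estimate = mean(a) - mean(b)))
  }
  res <- t.test(a, b, var.equal = TRUE)
  stat_result("two_sample_t", unname(res$statistic),
              unname(res$parameter), res$p.value, length(a) + length(b),
              estimate = mean(a) - mean(b))
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA: F with between df = k - 1 and
#' within df = N - k.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return a [stat_result] with `df = c(between, within)`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  if (var(y) == 0) stop("zero total variance; F is undefined")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- oneway.test(y ~ g, var.equal = TRUE)
  stat_result("anova_oneway", unname(res$statistic),
              unname(res$parameter), res$p.value, length(y))
}

#' Pearson correlation
#'
#' Pearson's r with the exact t-based two-sided p-value
#' (`t = r * sqrt(n-2) / sqrt(1-r^2)`, df = n - 2); `estimate` is r and
#' `r_squared` its square.
#'
#' @param x,y numeric vectors of equal length (n >= 3, both nonconstant).
#' @return a [stat_result] with an extra `r_squared` field.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3) stop("need n >= 3 for a correlation")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input; correlation is undefined")
  res <- cor.test(x, y, method = "pearson")
  out <- stat_result("pearson", unname(res$statistic),
                     unname(res$parameter), res$p.value, length(x),
                     estimate = unname(res$estimate))
  out$r_squared <- out$estimate^2
  out
}

#' Ordinary least squares GLM
#'
#' Fits `response ~ predictors` by OLS with an intercept always included;
#' returns coefficients with per-coefficient t statistics and two-sided
#' p-values.  A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param response numeric vector.
#' @param predictors data.frame or matrix of predictor columns.
#' @return list with `coefficients` (named vector), `results` (list of
#'   per-coefficient [stat_result]s), `fit` (the underlying `lm`).
#' @export
glm_fit <- function(response, predictors) {
  x <- as.data.frame(predictors)
  n <- length(response)
  if (n <= ncol(x) + 1)
    stop("need n > number of predictors + 1 (n = ", n, ", p = ",
         ncol(x), ")")
  dat <- cbind(data.frame(.response = response), x)
  fit <- if (ncol(x) == 0L) lm(.response ~ 1, data = dat)
         else lm(.response ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  results <- lapply(rownames(sm), function(nm)
    stat_result(paste0("glm:", nm), sm[nm, "t value"], fit$df.residual,
                sm[nm, "Pr(>|t|)"], n, estimate = sm[nm, "Estimate"]))
  names(results) <- rownames(sm)
  list(coefficients = coef(fit), results = results, fit = fit)
}

#' Bonferroni correction
#'
#' `p -> min(1, m * p)` for a family of `m` tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m family size (>= number of p-values).
#' @return corrected p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values))
    stop("family size m must be >= number of p-values")
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Minimal sample size for detecting a correlation
#'
#' Fisher z approximation for a two-sided Pearson correlation test:
#' `n = ceiling(((z_{1-alpha/2} + z_{power}) / C)^2 + 3)` with
#' `C = 0.5 * log((1 + r) / (1 - r))`.
#'
#' @param r target correlation (0 < r < 1).
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @return minimal integer n.
#' @export
required_n_correlation <- function(r, alpha = 0.05, power = 0.80) {
  if (!(r > 0 && r < 1)) stop("'r' must be in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
  if (!(power > 0 && power < 1)) stop("'power' must be in (0, 1)")
  cc <- 0.5 * log((1 + r) / (1 - r))
  as.integer(ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) / cc)^2 + 3))
}

#' Power of a correlation test at a given sample size (Fisher z)
#'
#' Companion to [required_n_correlation]: the approximate power of the
#' two-sided test of zero correlation when the true correlation is `r`.
#'
#' @inheritParams required_n_correlation
#' @param n sample size (> 3).
#' @return approximate power in (0, 1).
#' @export
power_correlation <- function(r, n, alpha = 0.05) {
  if (n <= 3) stop("'n' must exceed 3")
  cc <- 0.5 * log((1 + r) / (1 - r))
  pnorm(abs(cc) * sqrt(n - 3) - qnorm(1 - alpha / 2))
}

#' Collect stat results into a tidy table
#'
#' One row per test with a shared Bonferroni family across the whole
#' table (the family used is logged in the `family` column).
#'
#' @param results named list of [stat_result]s.
#' @param family family size; defaults to the number of tests.
#' @return data.frame with columns test, statistic, df, p, p_corrected,
#'   family, n.
#' @export
stat_table <- function(results, family = length(results)) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(test = nm, statistic = r$statistic,
               df = paste(r$df, collapse = ";"), p = r$p,
               p_corrected = min(1, family * r$p), family = family,
               n = r$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
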