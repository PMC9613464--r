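## Limiting-dilution analysis under the single-hit Poisson model.
##
## Each animal injected with d cells engrafts with probability
## 1 - exp(-f d), where f is the frequency of active (stem) cells. The
## likelihood over assay rows (dose d_i, tested n_i, responders r_i) is
##   L(f) = prod_i (1 - exp(-f d_i))^r_i * exp(-f d_i)^(n_i - r_i),
## equivalent to a binomial GLM with complementary log-log link and
## log-dose offset. Estimation is by a bracketed root of the score
## equation in log(f); confidence bounds are Wald intervals on log(f)
## using expected (Fisher) information, with a likelihood-ratio option.

#' Construct / validate a limiting-dilution assay table
#'
#' @param x A data frame with columns `dose`, `tested`, `responders`.
#' @return The validated `lda_assay` data frame.
#' @export
lda_assay <- function(x) {
  x <- as.data.frame(x)
  need <- c("dose", "tested", "responders")
  if (!all(need %in% names(x)))
    abort("assay must have columns dose, tested, responders")
  x <- x[need]
  if (nrow(x) < 1) abort("assay needs at least one row")
  if (any(!is.finite(as.matrix(x)))) abort("assay values must be finite")
  if (any(x$dose <= 0)) abort("doses must be positive")
  if (any(x$tested < 1)) abort("tested must be >= 1")
  if (any(x$responders < 0 | x$responders > x$tested))
    abort("responders must satisfy 0 <= responders <= tested")
  class(x) <- c("lda_assay", "data.frame")
  x
}

## score and expected information in theta = log(f)
lda_score <- function(theta, d, n, r) {
  mu <- exp(theta) * d
  p <- -expm1(-mu)                       # 1 - exp(-mu), stable for small mu
  sum(r * mu * exp(-mu) / p - (n - r) * mu)
}

lda_expected_info <- function(theta, d, n) {
  mu <- exp(theta) * d
  p <- -expm1(-mu)
  sum(n * mu^2 * exp(-mu) / p)
}

lda_loglik <- function(theta, d, n, r) {
  mu <- exp(theta) * d
  p <- -expm1(-mu)
  sum(r * log(p) - (n - r) * mu)
}

#' Estimate active-cell frequency from a limiting-dilution assay
#'
#' Maximum-likelihood fit of the single-hit Poisson model, with a
#' confidence interval on the log-frequency scale. Frequencies are also
#' reported as denominators (`1/f`), the convention of limiting-dilution
#' tables: the *lower* frequency bound corresponds to the *larger*
#' denominator.
#'
#' If every animal responded there is no finite MLE (`boundary_flag =
#' "infinite"`); if none responded the MLE is zero (`boundary_flag =
#' "zero"`). In both cases no interval is returned.
#'
#' @param assay An [lda_assay()] data frame (or coercible).
#' @param conf_level Confidence level in (0, 1); default 0.95.
#' @param ci_method `"wald"` (default): `exp(log f_hat +/- z * se)` with
#'   the standard error from expected Fisher information at the MLE;
#'   `"lrt"`: profile likelihood-ratio bounds.
#' @return A `frequency_estimate` list: `f_hat`, `denom_hat`, `ci_denom`
#'   (named `lower`/`upper` *frequency* bounds as denominators, so
#'   `lower >= upper` numerically), `se_log_f`, `boundary_flag`,
#'   `conf_level`, `assay`.
#' @examples
#' tab2 <- lda_assay(data.frame(dose = c(30000, 7500, 1875, 469),
#'                              tested = c(3, 4, 6, 5),
#'                              responders = c(3, 4, 6, 4)))
#' estimate_frequency(tab2)  # 1/286.4 (1/803.9 - 1/102)
#' @export
estimate_frequency <- function(assay, conf_level = 0.95,
                               ci_method = c("wald", "lrt")) {
  assay <- lda_assay(assay)
  ci_method <- match.arg(ci_method)
  stopifnot(conf_level > 0, conf_level < 1)
  d <- assay$dose; n <- assay$tested; r <- assay$responders

  res <- structure(list(f_hat = NA_real_, denom_hat = NA_real_,
                        ci_denom = c(lower = NA_real_, upper = NA_real_),
                        se_log_f = NA_real_, boundary_flag = "none",
                        conf_level = conf_level, ci_method = ci_method,
                        assay = assay),
                   class = "frequency_estimate")
  if (all(r == n)) {
    res$boundary_flag <- "infinite"
    res$f_hat <- Inf; res$denom_hat <- 0
    return(res)
  }
  if (all(r == 0)) {
    res$boundary_flag <- "zero"
    res$f_hat <- 0; res$denom_hat <- Inf
    return(res)
  }

  ## initial value: pooled closed form over partially-responding rows,
  ## else -log(overall negative fraction) / mean dose
  part <- r > 0 & r < n
  f0 <- if (any(part)) mean(-log(1 - r[part] / n[part]) / d[part])
        else -log(sum(n - r) / sum(n)) / mean(d)
  theta0 <- log(f0)

  ## the score is strictly decreasing in theta; bracket then root-find
  lo <- theta0; hi <- theta0
  while (lda_score(lo, d, n, r) < 0) lo <- lo - 1
  while (lda_score(hi, d, n, r) > 0) hi <- hi + 1
  theta_hat <- stats::uniroot(lda_score, c(lo, hi), d = d, n = n, r = r,
                              tol = 1e-12)$root
  f_hat <- exp(theta_hat)
  info <- lda_expected_info(theta_hat, d, n)
  se <- 1 / sqrt(info)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_theta <- if (ci_method == "wald") {
    theta_hat + c(-1, 1) * z * se
  } else {
    ll0 <- lda_loglik(theta_hat, d, n, r)
    crit <- stats::qchisq(conf_level, df = 1) / 2
    dev <- function(th) ll0 - lda_loglik(th, d, n, r) - crit
    lo_b <- theta_hat - 1
    while (dev(lo_b) < 0) lo_b <- lo_b - 1
    hi_b <- theta_hat + 1
    while (dev(hi_b) < 0) hi_b <- hi_b + 1
    c(stats::uniroot(dev, c(lo_b, theta_hat), tol = 1e-10)$root,
      stats::uniroot(dev, c(theta_hat, hi_b), tol = 1e-10)$root)
  }

  res$f_hat <- f_hat
  res$denom_hat <- 1 / f_hat
  res$se_log_f <- se
  ## lower frequency <-> larger denominator
  res$ci_denom <- c(lower = 1 / exp(ci_theta[1]), upper = 1 / exp(ci_theta[2]))
  res
}

#' @export
print.frequency_estimate <- function(x, digits = 1, ...) {
  cat("Single-hit limiting-dilution frequency estimate\n")
  if (x$boundary_flag != "none") {
    cat(sprintf("  boundary: %s (no finite MLE / interval)\n", x$boundary_flag))
    return(invisible(x))
  }
  cat(sprintf("  Estimated frequency: 1/%s\n", round(x$denom_hat, digits)))
  cat(sprintf("  %g%% interval: 1/%s (lower) - 1/%s (upper)\n",
              100 * x$conf_level,
              round(x$ci_denom[["lower"]], digits),
              round(x$ci_denom[["upper"]], digits)))
  cat(sprintf("  se(log f) = %.4f [%s]\n", x$se_log_f, x$ci_method))
  invisible(x)
}

#' One-line frequency table in the style of limiting-dilution reports
#'
#' @param est A `frequency_estimate`.
#' @param digits Decimals for the denominators (default 1).
#' @return A one-row data frame with columns `lower_frequency`,
#'   `estimated_frequency`, `upper_frequency` rendered as `"1/<denom>"`.
#' @export
format_frequency_table <- function(est, digits = 1) {
  stopifnot(inherits(est, "frequency_estimate"))
  fmt <- function(x) paste0("1/", round(x, digits))
  data.frame(lower_frequency = fmt(est$ci_denom[["lower"]]),
             estimated_frequency = fmt(est$denom_hat),
             upper_frequency = fmt(est$ci_denom[["upper"]]))
}

#' Monte-Carlo calibration of the frequency estimator
#'
#' Simulates assays from a known frequency, refits each, and reports the
#' fraction of finite-MLE replicates whose confidence interval covers the
#' truth, together with the median relative bias of the denominator.
#' Boundary replicates (all or no responders) are counted and excluded
#' from coverage.
#'
#' @param true_f True frequency.
#' @param doses,mice_per_dose Assay design, as in [simulate_lda_assay()].
#' @param n_reps Number of replicates (`>= 1`).
#' @param seed Root seed; replicate `i` uses [child_seed()]`(seed, i)`.
#' @param conf_level,ci_method Passed to [estimate_frequency()].
#' @return A list: `coverage`, `n_finite`, `n_boundary`,
#'   `median_rel_bias` (of `denom_hat` about `1/true_f`), `denom_hats`.
#' @export
lda_coverage_sim <- function(true_f, doses, mice_per_dose, n_reps = 1000,
                             seed = 1, conf_level = 0.95,
                             ci_method = "wald") {
  stopifnot(n_reps >= 1)
  denom_true <- 1 / true_f
  cover <- logical(0); denoms <- numeric(0); n_boundary <- 0L
  for (i in seq_len(n_reps)) {
    a <- simulate_lda_assay(true_f, doses, mice_per_dose,
                            seed = child_seed(seed, i))
    est <- estimate_frequency(a, conf_level = conf_level, ci_method = ci_method)
    if (est$boundary_flag != "none") {
      n_boundary <- n_boundary + 1L
      next
    }
    denoms <- c(denoms, est$denom_hat)
    ## lower frequency bound = larger denominator
    cover <- c(cover, denom_true <= est$ci_denom[["lower"]] &&
                      denom_true >= est$ci_denom[["upper"]])
  }
  list(coverage = mean(cover), n_finite = length(cover),
       n_boundary = n_boundary,
       median_rel_bias = stats::median(denoms / denom_true - 1),
       denom_hats = denoms)
}

#' Compare two limiting-dilution frequencies
#'
#' Wald test of equality on the log-frequency scale: the log ratio of the
#' two MLEs with standard error `sqrt(se_a^2 + se_b^2)`.
#'
#' @param assay_a,assay_b Two assays (or `frequency_estimate` objects).
#' @return A list: `ratio` (`f_a / f_b`), `log_ratio`, `se`, `z`,
#'   `p_value`.
#' @export
compare_frequencies <- function(assay_a, assay_b) {
  fit <- function(a, which) {
    est <- if (inherits(a, "frequency_estimate")) a else estimate_frequency(a)
    if (est$boundary_flag != "none")
      abort(sprintf("assay_%s has a boundary estimate (%s); no finite comparison",
                    which, est$boundary_flag))
    est
  }
  ea <- fit(assay_a, "a"); eb <- fit(assay_b, "b")
  lr <- log(ea$f_hat) - log(eb$f_hat)
  se <- sqrt(ea$se_log_f^2 + eb$se_log_f^2)
  z <- lr / se
  list(ratio = exp(lr), log_ratio = lr, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}
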