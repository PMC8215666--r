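#' @title Two-sample MR estimators
#' @description Summary-data Mendelian randomization estimators. Writing
#'   \eqn{\beta_{Xj}, \sigma_{Xj}} and \eqn{\beta_{Yj}, \sigma_{Yj}} for the
#'   exposure and outcome associations of instrument j, the per-SNP ratio
#'   estimate is \eqn{\hat\theta_j = \beta_{Yj}/\beta_{Xj}} with inverse
#'   variance weight \eqn{w_j = (\beta_{Xj}/\sigma_{Yj})^2}. All inference
#'   uses the normal reference distribution.
#' @name estimators
NULL

new_mr_result <- function(method, estimate, se, p, ci_low, ci_high, n_snps,
                          q_statistic = NA_real_, scale_factor = NA_real_) {
  structure(data.frame(
    method = method, estimate = estimate, se = se,
    ci_low = ci_low, ci_high = ci_high, p = p, n_snps = n_snps,
    q_statistic = q_statistic, scale_factor = scale_factor,
    stringsAsFactors = FALSE
  ), class = c("mr_result", "data.frame"))
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  for (col in c("estimate", "se", "ci_low", "ci_high", "q_statistic",
                "scale_factor")) {
    y[[col]] <- round(y[[col]], digits)
  }
  y$p <- signif(y$p, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Normal-theory confidence interval and two-sided p-value
#'
#' `CI = estimate +/- z_(1-alpha/2) * se`; `p = 2 * (1 - Phi(|estimate/se|))`.
#'
#' @param estimate Point estimate.
#' @param se Positive standard error.
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @return List with `ci_low`, `ci_high`, `p`.
#' @examples
#' ci_and_p(-0.0208, 0.7275)  # CI about (-1.447, 1.405), p about 0.977
#' @export
ci_and_p <- function(estimate, se, alpha = 0.05) {
  stopifnot(all(se > 0), alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  list(ci_low = estimate - z * se, ci_high = estimate + z * se,
       p = 2 * stats::pnorm(-abs(estimate / se)))
}

.check_iset <- function(iset, min_snps = 1L, method = "estimation") {
  stopifnot(inherits(iset, "instrument_set"))
  ins <- iset$instruments
  if (nrow(ins) < min_snps) {
    stop(method, " requires at least ", min_snps, " instrument(s), got ",
         nrow(ins))
  }
  if (any(ins$beta_exposure == 0)) {
    stop("zero exposure beta for ",
         paste(ins$SNP[ins$beta_exposure == 0], collapse = ", "),
         ": ratio estimate undefined")
  }
  ins
}

#' Wald ratio estimate for a single instrument
#'
#' The single-SNP causal estimate \eqn{\beta_Y/\beta_X} with first-order
#' standard error \eqn{\sigma_Y/|\beta_X|} (exposure uncertainty ignored,
#' appropriate for strong instruments).
#'
#' @param instrument One-row harmonized instrument `data.frame` (or an
#'   `instrument_set` with a single instrument).
#' @param alpha Two-sided significance level.
#' @return An `mr_result` with `method = "wald"`.
#' @export
wald_ratio <- function(instrument, alpha = 0.05) {
  ins <- if (inherits(instrument, "instrument_set")) {
    .check_iset(instrument, 1L, "wald_ratio")
  } else instrument
  stopifnot(nrow(ins) == 1L)
  if (ins$beta_exposure == 0) stop("zero exposure beta: ratio undefined")
  est <- ins$beta_outcome / ins$beta_exposure
  se <- ins$se_outcome / abs(ins$beta_exposure)
  cp <- ci_and_p(est, se, alpha)
  new_mr_result("wald", est, se, cp$p, cp$ci_low, cp$ci_high, 1L)
}

#' Inverse-variance-weighted (IVW) estimator
#'
#' Combines per-SNP ratio estimates with inverse-variance weights
#' \eqn{w_j = (\beta_{Xj}/\sigma_{Yj})^2}:
#' \deqn{\hat\theta = \frac{\sum_j \beta_{Xj}\beta_{Yj}\sigma_{Yj}^{-2}}
#'                         {\sum_j \beta_{Xj}^2 \sigma_{Yj}^{-2}},}
#' equivalently the weighted through-origin regression of \eqn{\beta_Y} on
#' \eqn{\beta_X}. The fixed-effects standard error is
#' \eqn{(\sum_j w_j)^{-1/2}}; under the multiplicative random-effects model
#' it is inflated by \eqn{\phi = \max(1, \sqrt{Q/(J-1)})}, where Q is
#' Cochran's heterogeneity statistic, so between-instrument heterogeneity
#' widens the interval but never narrows it. `model = "auto"` uses fixed
#' effects for J <= 3 and multiplicative random effects otherwise.
#'
#' @param iset An `instrument_set` with J >= 1 instruments.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @param alpha Two-sided significance level.
#' @return An `mr_result` with `method = "ivw"`; `q_statistic` holds Q
#'   (J >= 2) and `scale_factor` the applied SE inflation.
#' @export
mr_ivw <- function(iset, model = c("auto", "random", "fixed"), alpha = 0.05) {
  model <- match.arg(model)
  ins <- .check_iset(iset, 1L, "IVW")
  J <- nrow(ins)
  if (model == "random" && J == 1L) {
    warning("single instrument: random-effects model falls back to fixed",
            call. = FALSE)
    model <- "fixed"
  }
  use_random <- model == "random" || (model == "auto" && J > 3L)

  w <- (ins$beta_exposure / ins$se_outcome)^2
  est <- sum(ins$beta_exposure * ins$beta_outcome / ins$se_outcome^2) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- if (J >= 2L) sum(w * (ins$beta_outcome / ins$beta_exposure - est)^2)
       else NA_real_
  phi <- if (use_random) max(1, sqrt(Q / (J - 1))) else 1
  se <- se_fixed * phi
  cp <- ci_and_p(est, se, alpha)
  new_mr_result("ivw", est, se, cp$p, cp$ci_low, cp$ci_high, J,
                q_statistic = Q, scale_factor = phi)
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (\hat\theta_j - \theta_{ref})^2} with the IVW weights;
#' under homogeneity Q is approximately chi-square with J - 1 degrees of
#' freedom. Large Q signals dispersion of the per-SNP ratio estimates around
#' the reference (pleiotropy, or a mixture of instrument effects), and feeds
#' the multiplicative random-effects scale of [mr_ivw()].
#'
#' @param iset An `instrument_set` with J >= 2 instruments.
#' @param reference_estimate Reference causal estimate (typically the IVW
#'   estimate; defaults to it).
#' @return List with `q`, `df`, `p`, and `contributions` (per-SNP terms,
#'   named by SNP).
#' @export
cochran_q <- function(iset, reference_estimate = NULL) {
  ins <- .check_iset(iset, 2L, "Cochran's Q")
  if (is.null(reference_estimate)) {
    reference_estimate <- mr_ivw(iset, model = "fixed")$estimate
  }
  w <- (ins$beta_exposure / ins$se_outcome)^2
  contrib <- w * (ins$beta_outcome / ins$beta_exposure - reference_estimate)^2
  q <- sum(contrib)
  df <- nrow(ins) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE),
       contributions = setNames(contrib, ins$SNP))
}

# weighted median of x with weights w: order x, normalize w, and take the
# value at cumulative weight 1/2 (cumulative sums shifted by half-weight,
# linear interpolation between bracketing order statistics)
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(x[1])
  if (cs[length(cs)] <= 0.5) return(x[length(x)])
  i <- max(which(cs < 0.5))
  x[i] + (x[i + 1] - x[i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
}

#' Weighted-median estimator
#'
#' The weighted median of the per-SNP ratio estimates under the IVW weights:
#' consistent as long as instruments carrying at least half of the total
#' weight are valid, which makes it the standard sensitivity analysis against
#' a minority of pleiotropic instruments. The standard error comes from a
#' parametric bootstrap: exposure and outcome betas are redrawn from normal
#' distributions centred at their observed values with their reported
#' standard errors, the weighted median recomputed, and the SE taken as the
#' standard deviation over draws.
#'
#' @param iset An `instrument_set` with J >= 3 instruments.
#' @param n_bootstrap Number of bootstrap draws (default 10000).
#' @param seed Integer seed for the bootstrap; mandatory for reproducibility.
#' @param alpha Two-sided significance level.
#' @return An `mr_result` with `method = "wm"`.
#' @export
mr_weighted_median <- function(iset, n_bootstrap = 10000, seed, alpha = 0.05) {
  ins <- .check_iset(iset, 3L, "weighted median")
  if (missing(seed) || is.null(seed)) {
    stop("the weighted-median bootstrap requires an explicit seed")
  }
  stopifnot(n_bootstrap >= 2)
  J <- nrow(ins)
  w <- (ins$beta_exposure / ins$se_outcome)^2
  est <- weighted_median_point(ins$beta_outcome / ins$beta_exposure, w)

  boot <- local_seed(seed, {
    bx <- matrix(stats::rnorm(J * n_bootstrap, ins$beta_exposure,
                              ins$se_exposure), nrow = J)
    by <- matrix(stats::rnorm(J * n_bootstrap, ins$beta_outcome,
                              ins$se_outcome), nrow = J)
    vapply(seq_len(n_bootstrap), function(b) {
      ok <- bx[, b] != 0
      weighted_median_point(by[ok, b] / bx[ok, b],
                            (bx[ok, b] / ins$se_outcome[ok])^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  if (se == 0) se <- .Machine$double.eps  # degenerate: identical ratios
  cp <- ci_and_p(est, se, alpha)
  new_mr_result("wm", est, se, cp$p, cp$ci_low, cp$ci_high, J)
}

#' MR-Egger regression
#'
#' Weighted least squares of \eqn{\beta_{Yj}} on \eqn{\beta_{Xj}} with
#' weights \eqn{\sigma_{Yj}^{-2}} and a free intercept, after orienting every
#' instrument to a non-negative exposure effect (both betas negated when
#' \eqn{\beta_{Xj} < 0}, required for the intercept's interpretation). The
#' slope estimates the causal effect under the InSIDE assumption (pleiotropic
#' effects independent of instrument strength); the intercept estimates the
#' average directional pleiotropic effect, and its two-sided normal test is
#' the standard test for directional pleiotropy. Both standard errors are
#' inflated by \eqn{\phi = \max(1, \sqrt{RSS_w/(J-2)})}, the multiplicative
#' residual scale floored at 1.
#'
#' @param iset An `instrument_set` with J >= 3 instruments and variation in
#'   the exposure betas.
#' @param alpha Two-sided significance level.
#' @return A two-row `mr_result` with methods `"egger-slope"` and
#'   `"egger-intercept"`; both rows carry the shared `scale_factor`.
#' @export
mr_egger <- function(iset, alpha = 0.05) {
  ins <- .check_iset(iset, 3L, "MR-Egger")
  J <- nrow(ins)
  flip <- ins$beta_exposure < 0
  bx <- ifelse(flip, -ins$beta_exposure, ins$beta_exposure)
  by <- ifelse(flip, -ins$beta_outcome, ins$beta_outcome)
  if (stats::sd(bx) == 0) {
    stop("degenerate design: no variation in |beta_exposure|")
  }
  wt <- 1 / ins$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = wt)
  s <- summary(fit)
  # model-based SEs are sqrt(diag((X'WX)^-1)) * sigma_hat; rescale so the
  # residual scale is floored at 1 rather than estimated freely
  sigma <- s$sigma  # sqrt(RSS_w / (J - 2))
  phi <- max(1, sigma)
  se <- s$coefficients[, "Std. Error"] / sigma * phi
  est <- stats::coef(fit)
  cp_slope <- ci_and_p(est[["bx"]], se[["bx"]], alpha)
  cp_int <- ci_and_p(est[["(Intercept)"]], se[["(Intercept)"]], alpha)
  rbind(
    new_mr_result("egger-slope", est[["bx"]], se[["bx"]], cp_slope$p,
                  cp_slope$ci_low, cp_slope$ci_high, J, scale_factor = phi),
    new_mr_result("egger-intercept", est[["(Intercept)"]],
                  se[["(Intercept)"]], cp_int$p, cp_int$ci_low,
                  cp_int$ci_high, J, scale_factor = phi)
  )
}

# evaluate expr under a fixed RNG state, restoring the caller's state
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
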