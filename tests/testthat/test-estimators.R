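test_that("ci_and_p reproduces normal-theory intervals and p-values", {
  r <- ci_and_p(-0.0208, 0.7275)
  expect_equal(r$ci_low, -1.447, tolerance = 1e-3)
  expect_equal(r$ci_high, 1.405, tolerance = 1e-3)
  expect_equal(r$p, 0.977, tolerance = 1e-3)
  r0 <- ci_and_p(0, 1)
  expect_equal(r0$p, 1)
  expect_equal(r0$ci_low, -r0$ci_high)
  r1 <- ci_and_p(2, 0.5, alpha = 2 * pnorm(-1))  # one-sigma interval
  expect_equal(r1$ci_low, 1.5)
  expect_equal(r1$ci_high, 2.5)
  expect_error(ci_and_p(1, 0), "se")
})

test_that("Wald ratio is the outcome/exposure ratio with first-order SE", {
  r <- wald_ratio(make_iset(0.5, 0.05, 0.1, 0.05)$instruments)
  expect_equal(r$estimate, 0.2)
  expect_equal(r$se, 0.1)
  expect_equal(wald_ratio(make_iset(0.5, 0.05, 0, 0.05)$instruments)$estimate, 0)
  # negative exposure beta: SE stays positive
  rn <- wald_ratio(make_iset(-0.5, 0.05, 0.1, 0.05)$instruments)
  expect_equal(rn$estimate, -0.2)
  expect_equal(rn$se, 0.1)
  expect_error(wald_ratio(make_iset(0, 0.05, 0.1, 0.05)$instruments), "zero")
})

test_that("IVW equals weighted through-origin regression", {
  set.seed(31)
  for (i in 1:10) {
    J <- sample(3:12, 1)
    iset <- make_iset(runif(J, 0.05, 0.3) * sample(c(-1, 1), J, TRUE),
                      runif(J, 0.01, 0.03), rnorm(J, 0, 0.05),
                      runif(J, 0.01, 0.1))
    est <- mr_ivw(iset, model = "fixed")
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = iset$instruments,
              weights = 1 / iset$instruments$se_outcome^2)
    expect_equal(est$estimate, unname(coef(fit)))
    # fixed-effects SE from the analytic weight sum
    w <- (iset$instruments$beta_exposure / iset$instruments$se_outcome)^2
    expect_equal(est$se, 1 / sqrt(sum(w)))
  }
})

test_that("single-instrument IVW reduces to the Wald ratio", {
  iset <- make_iset(0.0963, 0.0195, 0.0018, 0.0004)
  expect_equal(mr_ivw(iset)$estimate, wald_ratio(iset$instruments)$estimate)
  expect_equal(mr_ivw(iset)$se, wald_ratio(iset$instruments)$se)
  expect_warning(r <- mr_ivw(iset, model = "random"), "falls back to fixed")
  expect_equal(r$estimate, wald_ratio(iset$instruments)$estimate)
})

test_that("IVW is permutation-invariant and null under null outcomes", {
  set.seed(5)
  J <- 8
  iset <- make_iset(runif(J, 0.05, 0.3), runif(J, 0.01, 0.03),
                    rnorm(J), runif(J, 0.5, 1))
  base <- mr_ivw(iset)
  perm <- iset
  ord <- sample(J)
  perm$instruments <- perm$instruments[ord, ]
  got <- mr_ivw(perm)
  expect_equal(got$estimate, base$estimate)
  expect_equal(got$se, base$se)
  null_iset <- make_iset(runif(J, 0.05, 0.3), runif(J, 0.01, 0.03),
                         rep(0, J), runif(J, 0.5, 1))
  expect_equal(mr_ivw(null_iset)$estimate, 0)
})

test_that("IVW estimate is invariant to uniform outcome-SE rescaling", {
  set.seed(13)
  J <- 6
  iset <- make_iset(runif(J, 0.05, 0.3), runif(J, 0.01, 0.03),
                    rnorm(J, 0.02, 0.05), runif(J, 0.01, 0.1))
  scaled <- iset
  scaled$instruments$se_outcome <- 2 * scaled$instruments$se_outcome
  a <- mr_ivw(iset, model = "fixed")
  b <- mr_ivw(scaled, model = "fixed")
  expect_equal(a$estimate, b$estimate)
  expect_equal(b$se, 2 * a$se)
  # the same rescaling quarters every weight, hence quarters Q
  expect_equal(cochran_q(scaled)$q, cochran_q(iset)$q / 4)
})

test_that("auto model selection: fixed for J <= 3, random above", {
  set.seed(17)
  mk <- function(J) make_iset(runif(J, 0.1, 0.3), runif(J, 0.01, 0.03),
                              rnorm(J, 0, 0.1), runif(J, 0.02, 0.1))
  i3 <- mk(3)
  expect_equal(mr_ivw(i3, "auto")$se, mr_ivw(i3, "fixed")$se)
  i4 <- mk(4)
  expect_equal(mr_ivw(i4, "auto")$se, mr_ivw(i4, "random")$se)
  # random-effects SE is never below fixed (scale floored at 1)
  expect_gte(mr_ivw(i4, "random")$se, mr_ivw(i4, "fixed")$se)
})

test_that("Cochran's Q vanishes for identical ratios and sums per-SNP terms", {
  iset <- make_iset(c(0.1, 0.2, 0.4), rep(0.02, 3),
                    c(0.05, 0.10, 0.20), rep(0.03, 3))  # all ratios 0.5
  q <- cochran_q(iset)
  expect_equal(q$q, 0)
  expect_equal(q$df, 2)

  # the CP -> eGFR instruments: Q by direct summation, dominated by rs2976950
  iset2 <- fixture_iset("cp_egfr")
  est <- mr_ivw(iset2, "fixed")$estimate
  ins <- iset2$instruments
  q_direct <- sum((ins$beta_exposure / ins$se_outcome)^2 *
                  (ins$beta_outcome / ins$beta_exposure - est)^2)
  q2 <- cochran_q(iset2)
  expect_equal(q2$q, q_direct)
  expect_gt(q2$q, 15)
  expect_lt(q2$q, 30)
  expect_equal(names(which.max(q2$contributions)), "rs2976950")
  expect_gt(q2$contributions[["rs2976950"]] / q2$q, 0.5)
  expect_error(cochran_q(make_iset(0.1, 0.02, 0.1, 0.02)), "at least 2")
})

test_that("weighted median interpolates cumulative weights correctly", {
  # equal weights, ratios {1, 2, 10}: construct sy so weights are equal
  iset <- make_iset(bx = c(0.1, 0.1, 0.1), sx = rep(0.01, 3),
                    by = c(0.1, 0.2, 1.0), sy = rep(0.05, 3))
  r <- mr_weighted_median(iset, n_bootstrap = 100, seed = 1)
  expect_equal(r$estimate, 2)

  # equal weights and odd J: equals the plain median of the ratios
  set.seed(23)
  for (i in 1:5) {
    J <- sample(c(5, 7, 9), 1)
    by <- rnorm(J, 0.05, 0.2)
    iset_j <- make_iset(rep(0.1, J), rep(0.01, J), by, rep(0.05, J))
    r_j <- mr_weighted_median(iset_j, n_bootstrap = 10, seed = i)
    expect_equal(r_j$estimate, median(by / 0.1))
  }

  # brute-force percentile oracle at J = 3 with unequal weights
  bx <- c(0.2, 0.1, 0.3); sy <- c(0.04, 0.02, 0.09)
  by <- c(0.02, 0.05, 0.15)
  w <- (bx / sy)^2
  ratios <- by / bx
  ord <- order(ratios)
  ws <- w[ord] / sum(w)
  cs <- cumsum(ws) - ws / 2
  i <- max(which(cs < 0.5))
  oracle <- ratios[ord][i] +
    (ratios[ord][i + 1] - ratios[ord][i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
  r3 <- mr_weighted_median(make_iset(bx, rep(0.01, 3), by, sy),
                           n_bootstrap = 10, seed = 2)
  expect_equal(r3$estimate, oracle)

  expect_error(mr_weighted_median(make_iset(c(0.1, 0.2), rep(0.01, 2),
                                            c(0.1, 0.2), rep(0.05, 2)),
                                  seed = 1),
               "at least 3")
  expect_error(mr_weighted_median(iset, n_bootstrap = 10), "seed")
})

test_that("weighted-median bootstrap is seed-reproducible and tight for
           identical ratios", {
  iset <- make_iset(c(0.1, 0.2, 0.3), rep(1e-5, 3),
                    c(0.05, 0.10, 0.15), rep(1e-5, 3))  # all ratios 0.5
  r <- mr_weighted_median(iset, n_bootstrap = 500, seed = 99)
  expect_equal(r$estimate, 0.5)
  expect_lt(r$se, 1e-3)
  r2 <- mr_weighted_median(iset, n_bootstrap = 500, seed = 99)
  expect_identical(r$se, r2$se)
})

test_that("MR-Egger recovers exact linear structure", {
  # exact proportionality: slope = c, intercept = 0
  bx <- c(0.1, 0.2, 0.35, 0.5)
  iset <- make_iset(bx, rep(0.01, 4), 0.3 * bx, c(0.02, 0.03, 0.04, 0.05))
  r <- mr_egger(iset)
  expect_equal(r$estimate[r$method == "egger-slope"], 0.3)
  expect_equal(r$estimate[r$method == "egger-intercept"], 0,
               tolerance = 1e-12)

  # exact affine structure: intercept recovered too
  iset2 <- make_iset(bx, rep(0.01, 4), 0.02 + 0.3 * bx,
                     c(0.02, 0.03, 0.04, 0.05))
  r2 <- mr_egger(iset2)
  expect_equal(r2$estimate[r2$method == "egger-slope"], 0.3)
  expect_equal(r2$estimate[r2$method == "egger-intercept"], 0.02)
  expect_error(mr_egger(make_iset(rep(0.2, 3), rep(0.01, 3),
                                  c(0.1, 0.2, 0.3), rep(0.05, 3))),
               "degenerate")
})

test_that("MR-Egger matches the closed-form WLS oracle; adding a constant
           shifts only the intercept", {
  # closed form from the weighted normal equations
  wls_oracle <- function(bx, by, w) {
    xb <- sum(w * bx) / sum(w)
    yb <- sum(w * by) / sum(w)
    slope <- sum(w * (bx - xb) * (by - yb)) / sum(w * (bx - xb)^2)
    c(intercept = yb - slope * xb, slope = slope)
  }
  set.seed(41)
  bx <- runif(6, 0.05, 0.4)  # all positive: orientation is a no-op
  by <- 0.2 * bx + rnorm(6, 0, 0.03)
  sy <- runif(6, 0.02, 0.08)
  o <- wls_oracle(bx, by, 1 / sy^2)
  r <- mr_egger(make_iset(bx, rep(0.01, 6), by, sy))
  expect_equal(r$estimate[r$method == "egger-slope"], unname(o["slope"]))
  expect_equal(r$estimate[r$method == "egger-intercept"],
               unname(o["intercept"]))

  shifted <- mr_egger(make_iset(bx, rep(0.01, 6), by + 0.05, sy))
  expect_equal(shifted$estimate[shifted$method == "egger-slope"],
               unname(o["slope"]))
  expect_equal(shifted$estimate[shifted$method == "egger-intercept"],
               unname(o["intercept"]) + 0.05)
})

test_that("Egger with zero intercept reproduces the fixed-effects IVW slope", {
  set.seed(43)
  bx <- runif(5, 0.05, 0.4)
  by <- rnorm(5, 0.1 * bx, 0.02)
  sy <- runif(5, 0.02, 0.08)
  iset <- make_iset(bx, rep(0.01, 5), by, sy)
  constrained <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(mr_ivw(iset, "fixed")$estimate, unname(coef(constrained)))
})

test_that("all estimators are invariant to joint sign flips", {
  set.seed(47)
  J <- 7
  bx <- runif(J, 0.05, 0.4) * sample(c(-1, 1), J, TRUE)
  by <- 0.15 * bx + rnorm(J, 0, 0.02)
  sy <- runif(J, 0.02, 0.08)
  a <- make_iset(bx, rep(0.01, J), by, sy)
  b <- make_iset(-bx, rep(0.01, J), -by, sy)
  expect_equal(mr_ivw(a)$estimate, mr_ivw(b)$estimate)
  expect_equal(mr_ivw(a)$se, mr_ivw(b)$se)
  expect_equal(mr_weighted_median(a, 50, seed = 3)$estimate,
               mr_weighted_median(b, 50, seed = 3)$estimate)
  ea <- mr_egger(a)
  eb <- mr_egger(b)
  expect_equal(ea$estimate, eb$estimate)
  expect_equal(ea$se, eb$se)
})

test_that("result invariants hold across estimators on the fixture sets", {
  for (dir in c("cp_egfr", "cp_bun", "egfr_cp", "bun_cp")) {
    iset <- fixture_iset(dir)
    res <- rbind(mr_ivw(iset),
                 mr_weighted_median(iset, 200, seed = 8),
                 mr_egger(iset))
    expect_true(all(res$se > 0))
    expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
    expect_true(all(res$p > 0 & res$p <= 1))
    expect_equal(res$ci_high - res$estimate, qnorm(0.975) * res$se)
  }
})
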