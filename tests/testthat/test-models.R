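# synthetic mixed-model data with known structure
sim_lmm_data <- function(n_birds = 10, trips = 2, per_trip = 10,
                         beta = c(2, 1.5), bird_sd = 1, trip_sd = 0.5,
                         resid_sd = 1, seed = 1) {
  set.seed(seed)
  d <- expand.grid(obs = seq_len(per_trip), trip = seq_len(trips),
                   bird = seq_len(n_birds))
  d$bird_id <- sprintf("b%02d", d$bird)
  d$trip_id <- sprintf("b%02d_t%d", d$bird, d$trip)
  d$x <- runif(nrow(d), 0, 10)
  be <- rnorm(n_birds, 0, bird_sd)[d$bird]
  te <- rnorm(n_birds * trips, 0, trip_sd)[
    as.integer(factor(d$trip_id))]
  d$y <- beta[1] + beta[2] * d$x + be + te + rnorm(nrow(d), 0, resid_sd)
  d
}

test_that("the mixed model recovers coefficients in the zero-noise limit", {
  d <- sim_lmm_data(bird_sd = 0, trip_sd = 0, resid_sd = 1e-8)
  m <- suppressWarnings(fit_lmm(d, y ~ x))
  expect_equal(m$coefficients["(Intercept)", "estimate"], 2,
               tolerance = 1e-6)
  expect_equal(m$coefficients["x", "estimate"], 1.5, tolerance = 1e-6)
})

test_that("variance components are recovered across replicates", {
  rel_err <- sapply(1:8, function(s) {
    d <- sim_lmm_data(n_birds = 20, trips = 2, per_trip = 5,
                      bird_sd = 1, trip_sd = 0, resid_sd = 1, seed = s)
    m <- suppressWarnings(fit_lmm(d, y ~ x))
    c(bird = abs(m$varcomp[["bird_id"]] - 1),
      resid = abs(m$varcomp[["Residual"]] - 1))
  })
  expect_lt(median(rel_err["bird", ]), 0.5)
  expect_lt(median(rel_err["resid", ]), 0.5)
})

test_that("one trip per bird flags a singular fit with zero trip variance", {
  d <- sim_lmm_data(n_birds = 12, trips = 1, per_trip = 8, trip_sd = 0)
  expect_warning(m <- fit_lmm(d, y ~ x), "singular")
  expect_true(m$singular)
  expect_equal(m$varcomp[["trip_id:bird_id"]], 0, tolerance = 1e-6)
})

test_that("rank-deficient fixed effects are rejected by name", {
  d <- sim_lmm_data()
  d$x2 <- 2 * d$x
  expect_error(fit_lmm(d, y ~ x + x2), "aliased.*x2")
  expect_error(fit_lmm(d, y ~ x + nosuch), "not in data")
  d$x[1] <- NA
  expect_error(fit_lmm(d, y ~ x), "missing values")
})

test_that("marginal effects follow the closed form of the linear predictor", {
  d <- sim_lmm_data(seed = 3)
  d$z <- runif(nrow(d), -2, 2)
  d$y <- 1 + 2 * d$x + 3 * d$z + 0.5 * d$x * d$z + rnorm(nrow(d), 0, 0.01)
  m <- suppressWarnings(fit_lmm(d, y ~ x * z))
  b <- stats::setNames(m$coefficients[, "estimate"], rownames(m$coefficients))
  # pure main effect: slope times delta
  m0 <- suppressWarnings(fit_lmm(d, y ~ x))
  b0 <- m0$coefficients["x", "estimate"]
  expect_equal(marginal_effect(m0, "x", 3), 3 * b0, tolerance = 1e-8)
  # with an interaction, evaluated at a stated z
  expect_equal(marginal_effect(m, "x", 2, at = list(z = 1)),
               2 * (b[["x"]] + b[["x:z"]] * 1), tolerance = 1e-8)
  # default holds covariates at their sample means
  expect_equal(marginal_effect(m, "x", 2),
               2 * (b[["x"]] + b[["x:z"]] * mean(d$z)), tolerance = 1e-8)
  expect_warning(marginal_effect(m, "x", 100), "beyond")
  expect_error(marginal_effect(m, "nope", 1), "not a fixed effect")
})

test_that("marginal/conditional R-squared follow the variance partition", {
  r2 <- r2_mixed(list(var_fixed = 2, var_random = 1, var_resid = 1))
  expect_equal(unname(r2), c(0.5, 0.75))
  expect_equal(unname(r2_mixed(list(var_fixed = 2, var_random = 0,
                                    var_resid = 2))), c(0.5, 0.5))
  expect_equal(unname(r2_mixed(list(var_fixed = 0, var_random = 1,
                                    var_resid = 1))[1]), 0)
  expect_error(r2_mixed(list(var_fixed = 1)), "var_random")

  # on fitted models the conditional never falls below the marginal
  for (s in 1:3) {
    d <- sim_lmm_data(seed = s)
    m <- suppressWarnings(fit_lmm(d, y ~ x))
    expect_gte(m$r2_conditional, m$r2_marginal)
    expect_true(m$r2_marginal >= 0 && m$r2_conditional <= 1)
  }
})

test_that("fractional logit handles flat, planted and boundary responses", {
  # flat response at one half: zero intercept on the logit scale
  d0 <- sim_lmm_data(n_birds = 6, per_trip = 5)
  d0$y <- 0.5
  m0 <- fit_fractional_logit(d0, y ~ 1)
  expect_equal(m0$coefficients["(Intercept)", "estimate"], 0,
               tolerance = 1e-6)

  # planted logit-linear slope recovered within 2 SE at n = 2000
  set.seed(11)
  d <- sim_lmm_data(n_birds = 20, trips = 2, per_trip = 50,
                    bird_sd = 0, trip_sd = 0, resid_sd = 0)
  d$x <- runif(nrow(d), 0, 10)
  eta <- -0.5 + 0.3 * d$x + rnorm(20, 0, 0.3)[as.integer(factor(d$bird_id))]
  mu <- stats::plogis(eta)
  phi <- 12
  d$y <- stats::rbeta(nrow(d), mu * phi, (1 - mu) * phi)
  m <- fit_fractional_logit(d, y ~ x)
  est <- m$coefficients["x", "estimate"]
  se <- m$coefficients["x", "se"]
  expect_lt(abs(est - 0.3), 2 * se)
  expect_gte(m$r2_conditional, m$r2_marginal)

  # exact 0/1 responses are admissible under quasi-likelihood
  d$y[1:3] <- c(0, 1, 0)
  expect_no_error(fit_fractional_logit(d, y ~ x))
  d$y[1] <- 1.2
  expect_error(fit_fractional_logit(d, y ~ x), "outside")
})

test_that("Tukey contrasts separate shifted groups and reduce to t for k = 2", {
  set.seed(8)
  d <- sim_lmm_data(n_birds = 12, trips = 2, per_trip = 6,
                    bird_sd = 0.3, trip_sd = 0, resid_sd = 1)
  d$grp <- factor(rep(c("a", "b", "c"), length.out = nrow(d)))
  d$y <- d$y + ifelse(d$grp == "c", 5, 0)   # one group shifted by 5 sd
  m <- suppressWarnings(fit_lmm(d, y ~ x + grp))
  ct <- pairwise_contrasts(m, "grp")
  expect_equal(nrow(ct), 3)
  expect_lt(ct$p.value[ct$contrast == "a - c"], 0.001)
  expect_lt(ct$p.value[ct$contrast == "b - c"], 0.001)
  expect_gt(ct$p.value[ct$contrast == "a - b"], 0.05)

  # two-level factor: Tukey equals the unadjusted two-sided t test
  d2 <- d[d$grp != "c", ]
  d2$grp <- droplevels(d2$grp)
  m2 <- suppressWarnings(fit_lmm(d2, y ~ grp))
  ct2 <- pairwise_contrasts(m2, "grp")
  tt <- summary(emmeans::contrast(
    emmeans::emmeans(m2$fit, "grp", data = d2), "pairwise", adjust = "none"))
  expect_equal(ct2$p.value, tt$p.value, tolerance = 1e-6)
  expect_error(pairwise_contrasts(m2, "species"), "not in the model")
})

test_that("backward simplification drops null interactions and keeps mains", {
  kept_mains <- 0; dropped_int <- 0
  for (s in 1:5) {
    d <- sim_lmm_data(n_birds = 12, trips = 2, per_trip = 8, seed = s + 40)
    d$z <- runif(nrow(d), 0, 4)
    d$y <- d$y + 2 * d$z     # mains only, no true interaction
    bs <- suppressWarnings(backward_simplify(d, y ~ x * z))
    terms <- rownames(bs$result$term_tests)
    if (!"x:z" %in% terms) dropped_int <- dropped_int + 1
    if (all(c("x", "z") %in% terms)) kept_mains <- kept_mains + 1
  }
  expect_gte(dropped_int, 4)
  expect_equal(kept_mains, 5)
})

test_that("a significant top interaction halts simplification with a split flag", {
  set.seed(2)
  d <- sim_lmm_data(n_birds = 12, trips = 2, per_trip = 10)
  d$z <- runif(nrow(d), -2, 2)
  d$y <- d$y + 3 * d$x * d$z          # strong planted interaction
  bs <- suppressWarnings(backward_simplify(d, y ~ x * z))
  expect_true(bs$split_recommended)
  expect_equal(nrow(bs$eliminated), 0)
  expect_true("x:z" %in% rownames(bs$result$term_tests))

  # alpha = 1 always returns the full model unchanged
  bs2 <- suppressWarnings(backward_simplify(d, y ~ x * z, alpha = 1))
  expect_equal(nrow(bs2$eliminated), 0)
  expect_true("x:z" %in% rownames(bs2$result$term_tests))
})

test_that("linear trend recovers exact and noisy slopes", {
  t <- 1:20
  lt <- suppressWarnings(linear_trend(t, 2 * t))
  expect_equal(lt$slope, 2, tolerance = 1e-10)
  expect_lt(lt$p, 1e-12)

  set.seed(4)
  ok <- replicate(50, {
    y <- 0.5 * (1:40) + rnorm(40)
    f <- linear_trend(1:40, y)
    abs(f$slope - 0.5) < 2 * f$se
  })
  expect_gte(mean(ok), 0.85)

  # type-I error close to nominal under white noise
  set.seed(5)
  rej <- mean(replicate(400, linear_trend(1:40, rnorm(40))$p < 0.05))
  expect_gt(rej, 0.015); expect_lt(rej, 0.1)

  expect_error(linear_trend(c(1, 2), c(1, 2)), "at least 3")
  expect_error(linear_trend(rep(1, 5), rnorm(5)), "constant time")
})
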