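# Model layer: ground-speed linear mixed models with trip-within-bird
# random intercepts, marginal effects, fractional-logit models of the
# flight-to-wind offset, marginal/conditional R-squared, Tukey-adjusted
# pairwise contrasts, backward simplification, and a linear-trend utility.

#' Fit a Gaussian linear mixed model with nested random intercepts
#'
#' Random intercepts for bird and trip-within-bird, fitted by REML.
#' Term-level tests are Type-III F tests with Satterthwaite denominator
#' degrees of freedom.
#'
#' @param data Data frame; must contain `bird_id` and `trip_id` plus the
#'   model variables, with no missing values in them.
#' @param fixed Fixed-effects formula, e.g.
#'   `ground_speed ~ wind_speed * ddir_fw`.
#' @param random Random-effects term as a string (default
#'   `"(1 | bird_id / trip_id)"`).
#' @return A `model_result`: the fit, a coefficient table, variance
#'   components, marginal/conditional R-squared, log-likelihood/deviance,
#'   Type-III term tests and a singular-fit flag.
#' @export
fit_lmm <- function(data, fixed, random = "(1 | bird_id / trip_id)") {
  vars <- all.vars(fixed)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("model variable(s) not in data: ",
                         paste(miss, collapse = ", "))
  if (anyNA(data[, vars])) stop("missing values in model columns")
  X <- stats::model.matrix(fixed[-2], data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient fixed effects; aliased: ",
         paste(aliased, collapse = ", "))
  }
  # with one trip per bird the trip-within-bird term duplicates the bird
  # grouping and is not identifiable: drop it and report it as zero
  trip_dropped <- FALSE
  if (random == "(1 | bird_id / trip_id)" &&
      all(tapply(data$trip_id, data$bird_id,
                 function(x) length(unique(x))) == 1)) {
    random <- "(1 | bird_id)"
    trip_dropped <- TRUE
  }
  form <- stats::as.formula(paste(deparse(fixed[[2]]), "~",
                                  paste(deparse(fixed[[3]], width.cutoff = 500),
                                        collapse = " "),
                                  "+", random))
  fit <- lmerTest::lmer(form, data = data, REML = TRUE)
  singular <- lme4::isSingular(fit) || trip_dropped
  if (singular) warning("singular mixed-model fit (a variance component is 0)")
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")[seq_len(ncol(co))]
  vc <- as.data.frame(lme4::VarCorr(fit))
  if (trip_dropped) {
    vc <- rbind(vc, data.frame(grp = "trip_id:bird_id", var1 = "(Intercept)",
                               var2 = NA, vcov = 0, sdcor = 0))
  }
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  an <- tryCatch(as.data.frame(stats::anova(fit, type = 3)),
                 error = function(e) NULL)
  res <- structure(
    list(fit = fit, family = "gaussian", formula = form, data = data,
         coefficients = co, varcomp = varcomp,
         loglik = as.numeric(stats::logLik(fit)),
         deviance = stats::deviance(fit, REML = FALSE),
         term_tests = an, singular = singular),
    class = "model_result"
  )
  r2 <- r2_mixed(res)
  res$r2_marginal <- r2[["R2_marginal"]]
  res$r2_conditional <- r2[["R2_conditional"]]
  res
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s: %s\n", x$family,
              paste(deparse(x$formula), collapse = " ")))
  print(round(x$coefficients, 4))
  cat("variance components:\n")
  print(round(x$varcomp, 4))
  if (!is.null(x$r2_marginal)) {
    cat(sprintf("R2 marginal %.3f, conditional %.3f%s\n",
                x$r2_marginal, x$r2_conditional,
                if (isTRUE(x$singular)) " (singular fit)" else ""))
  }
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R-squared: marginal = fixed-effect variance over
#' (fixed + random + residual); conditional adds the random-effect
#' variance to the numerator. The fixed-effect variance is the variance of
#' the fixed-effect linear predictor over the data. For logit-family
#' models the residual variance is the standard logistic constant
#' pi^2 / 3.
#'
#' @param result A `model_result`, or a list with numeric elements
#'   `var_fixed`, `var_random`, `var_resid`.
#' @return Named vector `R2_marginal`, `R2_conditional`.
#' @export
r2_mixed <- function(result) {
  if (is.list(result) && !inherits(result, "model_result")) {
    vf <- result$var_fixed; vr <- result$var_random; ve <- result$var_resid
    if (is.null(vf) || is.null(vr) || is.null(ve)) {
      stop("need var_fixed, var_random and var_resid")
    }
  } else {
    if (is.null(result$varcomp)) stop("missing variance components")
    if (result$family == "gaussian") {
      pred_fixed <- stats::predict(result$fit, re.form = NA)
      ve <- result$varcomp[["Residual"]]
    } else {
      pred_fixed <- result$eta_fixed
      ve <- pi^2 / 3
    }
    vf <- stats::var(pred_fixed)
    vr <- sum(result$varcomp[names(result$varcomp) != "Residual"])
  }
  denom <- vf + vr + ve
  c(R2_marginal = vf / denom, R2_conditional = (vf + vr) / denom)
}

#' Marginal effect of a covariate change
#'
#' Difference in the fixed-effect prediction when `variable` increases by
#' `delta`, all other covariates held at stated values (defaults: sample
#' means for numeric covariates, reference level for factors).
#'
#' @param result A `model_result` from [fit_lmm()].
#' @param variable Name of a fixed-effect covariate.
#' @param delta Increase applied to `variable`.
#' @param at Named list of covariate values to hold fixed.
#' @return The change in the response (same units as the response).
#' @export
marginal_effect <- function(result, variable, delta, at = list()) {
  data <- result$data
  vars <- all.vars(result$formula[[3]])
  vars <- setdiff(vars, c("bird_id", "trip_id"))
  if (!variable %in% vars) stop("'", variable, "' is not a fixed effect")
  base <- list()
  for (v in vars) {
    if (!is.null(at[[v]])) {
      base[[v]] <- at[[v]]
    } else if (is.numeric(data[[v]])) {
      base[[v]] <- mean(data[[v]])
    } else {
      f <- factor(data[[v]])
      base[[v]] <- factor(levels(f)[1], levels = levels(f))
    }
  }
  nd0 <- as.data.frame(base, stringsAsFactors = FALSE)
  nd1 <- nd0
  nd1[[variable]] <- nd1[[variable]] + delta
  rng <- range(data[[variable]])
  if (nd1[[variable]] > rng[2] || nd1[[variable]] < rng[1]) {
    warning("marginal effect evaluated beyond the observed range of ",
            variable)
  }
  p <- stats::predict(result$fit, newdata = rbind(nd0, nd1), re.form = NA)
  unname(p[2] - p[1])
}

#' Fractional-logit model of a [0, 1] response with random intercepts
#'
#' Logit-link quasi-binomial mean/variance model on a continuous
#' proportion (e.g. the flight-to-wind offset divided by 180), with
#' bird and trip-within-bird random intercepts, fitted by penalised
#' quasi-likelihood. Responses of exactly 0 or 1 are admissible.
#'
#' @param data Data frame with `bird_id`, `trip_id` and model variables.
#' @param fixed Fixed-effects formula; the response must lie in [0, 1].
#' @return A `model_result` (coefficients on the logit scale).
#' @export
fit_fractional_logit <- function(data, fixed) {
  resp <- stats::model.frame(fixed, data)[[1]]
  if (any(resp < 0 | resp > 1)) stop("response outside [0, 1]")
  fit <- tryCatch(
    suppressWarnings(MASS::glmmPQL(
      fixed, random = ~ 1 | bird_id / trip_id,
      family = stats::quasibinomial(), data = data, verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate response (e.g. no residual variation): the random
    # structure is not estimable; quasi-binomial GLM with zero components
    g <- suppressWarnings(stats::glm(fixed, family = stats::quasibinomial(),
                                     data = data))
    s <- summary(g)$coefficients
    co <- data.frame(estimate = s[, 1], se = s[, 2],
                     df = g$df.residual, t = s[, 3], p = s[, 4],
                     row.names = rownames(s))
    res <- structure(
      list(fit = g, family = "fractional_logit", formula = fixed,
           data = data, coefficients = co,
           varcomp = c(bird_id = 0, `trip_id:bird_id` = 0),
           eta_fixed = as.numeric(stats::predict(g, type = "link")),
           loglik = NA_real_, deviance = stats::deviance(g),
           term_tests = NULL, singular = TRUE),
      class = "model_result")
    r2 <- r2_mixed(res)
    res$r2_marginal <- r2[["R2_marginal"]]
    res$r2_conditional <- r2[["R2_conditional"]]
    return(res)
  }
  tt <- summary(fit)$tTable
  co <- data.frame(estimate = tt[, "Value"], se = tt[, "Std.Error"],
                   df = tt[, "DF"], t = tt[, "t-value"],
                   p = tt[, "p-value"])
  vc <- nlme::VarCorr(fit)
  # rows: bird intercept, trip-in-bird intercept, residual
  vals <- suppressWarnings(as.numeric(vc[, "Variance"]))
  varcomp <- c(bird_id = vals[2], `trip_id:bird_id` = vals[4])
  eta <- as.numeric(stats::predict(fit, level = 0))
  res <- structure(
    list(fit = fit, family = "fractional_logit", formula = fixed,
         data = data, coefficients = co, varcomp = varcomp,
         eta_fixed = eta, loglik = NA_real_, deviance = NA_real_,
         term_tests = NULL, singular = any(vals < 1e-8, na.rm = TRUE)),
    class = "model_result"
  )
  r2 <- r2_mixed(res)
  res$r2_marginal <- r2[["R2_marginal"]]
  res$r2_conditional <- r2[["R2_conditional"]]
  res
}

#' Tukey-adjusted pairwise contrasts of adjusted means
#'
#' All pairwise differences of least-squares (estimated marginal) means of
#' a factor, at stated covariate values, with studentized-range (Tukey)
#' p-value adjustment.
#'
#' @param result A `model_result` from [fit_lmm()].
#' @param factor_name Factor among the fixed effects.
#' @param at Named list of covariate values passed to the reference grid.
#' @return Data frame of contrasts with estimates, SEs and adjusted p.
#' @export
pairwise_contrasts <- function(result, factor_name, at = list()) {
  if (!factor_name %in% all.vars(result$formula[[3]])) {
    stop("factor '", factor_name, "' not in the model")
  }
  em <- emmeans::emmeans(result$fit, specs = factor_name, at = at,
                         data = result$data)
  as.data.frame(emmeans::contrast(em, method = "pairwise",
                                  adjust = "tukey"))
}

# order of an anova-table term label: number of ':' separated variables
term_order <- function(term) lengths(strsplit(term, ":", fixed = TRUE))

#' Backward simplification of a mixed-model interaction hierarchy
#'
#' Repeatedly drops the highest-order interaction with the largest
#' Type-III p-value at or above `alpha` and refits; main effects are never
#' dropped. If every interaction of the current highest order is
#' significant, simplification stops and the result is flagged
#' `split_recommended` (interpretation should proceed on data subsets).
#'
#' @param data Data frame.
#' @param fixed Full fixed-effects formula.
#' @param alpha Retention threshold (default 0.05).
#' @param random Random-effects term as in [fit_lmm()].
#' @return List: `result` (final `model_result`), `eliminated` (data frame
#'   log of dropped terms), `split_recommended` (flag).
#' @export
backward_simplify <- function(data, fixed, alpha = 0.05,
                              random = "(1 | bird_id / trip_id)") {
  current <- fixed
  log_rows <- list()
  split_flag <- FALSE
  repeat {
    res <- fit_lmm(data, current, random = random)
    an <- res$term_tests
    if (is.null(an) || nrow(an) == 0) break
    terms <- rownames(an)
    pvals <- an[["Pr(>F)"]]
    ords <- term_order(terms)
    if (max(ords) < 2) break             # only main effects left
    top <- which(ords == max(ords))
    droppable <- top[pvals[top] >= alpha]
    if (!length(droppable)) {
      split_flag <- TRUE                 # highest-order interaction significant
      break
    }
    worst <- droppable[which.max(pvals[droppable])]
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      term = terms[worst], p = pvals[worst], stringsAsFactors = FALSE)
    keep <- setdiff(terms, terms[worst])
    current <- stats::reformulate(keep,
                                  response = deparse(current[[2]]))
  }
  list(result = res,
       eliminated = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(term = character(), p = numeric()),
       split_recommended = split_flag)
}

#' Ordinary least-squares linear trend
#'
#' @param time Numeric time axis (any unit).
#' @param value Response.
#' @return List with `slope` (per unit time), `se`, `p`.
#' @export
linear_trend <- function(time, value) {
  ok <- is.finite(time) & is.finite(value)
  if (sum(ok) < 3) stop("need at least 3 points")
  if (stats::sd(time[ok]) < 1e-12) stop("constant time axis")
  fit <- stats::lm(value[ok] ~ time[ok])
  s <- summary(fit)$coefficients
  list(slope = s[2, 1], se = s[2, 2], p = s[2, 4])
}
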