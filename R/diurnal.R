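# Diurnal timing: per-bird hourly class proportions and a cyclic-spline
# binomial model of how those proportions move over the day.

#' Per-bird hourly class proportions
#'
#' For each bird and local hour with at least one point, the proportion of
#' points in each class (e.g. trip section, or wind category), with the
#' bird-hour denominator recorded for binomial weighting. Proportions sum
#' to 1 over classes within each bird-hour.
#'
#' @param points Data frame with `bird_id`, `timestamp` and the class
#'   column.
#' @param class_col Name of the class column.
#' @param config A [study_config()] (local-time offset).
#' @return Data frame `bird_id`, `hour`, `class`, `proportion`, `n`.
#' @export
hourly_proportions <- function(points, class_col, config = study_config()) {
  stopifnot(class_col %in% names(points))
  cls <- factor(points[[class_col]])
  hour <- floor(local_hour(points$timestamp, config))
  tab <- table(bird_id = points$bird_id, hour = hour, class = cls)
  d <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(d) <- c("bird_id", "hour", "class", "count")
  d$hour <- as.integer(d$hour)
  totals <- stats::aggregate(count ~ bird_id + hour, data = d, sum)
  names(totals)[3] <- "n"
  d <- merge(d, totals, by = c("bird_id", "hour"))
  d <- d[d$n > 0, , drop = FALSE]
  d$proportion <- d$count / d$n
  d <- d[order(d$bird_id, d$hour, d$class),
         c("bird_id", "hour", "class", "proportion", "n")]
  rownames(d) <- NULL
  d
}

#' Cyclic-spline diurnal proportion model
#'
#' Weighted quasi-binomial model of hourly class proportions on a cyclic
#' regression-spline basis of local hour (period 24, default basis size
#' 5), with class-specific smooths and a bird random intercept. For two
#' complementary classes the hour-by-class interaction question reduces
#' to whether the reference class's proportion depends on hour, tested by
#' the cyclic smooth's significance; with three or more classes the
#' class-specific departures are fitted as ordered-factor difference
#' smooths and their tests combined by Bonferroni.
#'
#' @param proportions Output of [hourly_proportions()].
#' @param k Cyclic basis size (>= 3).
#' @return List: `fit` (class-specific model), `fit_shared`,
#'   `interaction_p`, `curves` (fitted hourly proportions per class on a
#'   0-23 grid, bird effect excluded).
#' @export
fit_diurnal_model <- function(proportions, k = 5) {
  if (k < 3) stop("cyclic basis size k must be at least 3")
  d <- proportions
  d$class <- factor(d$class)
  d$bird_id <- factor(d$bird_id)
  if (nlevels(d$class) < 2) stop("need at least 2 classes")
  knots <- list(hour = c(0, 24))
  has_re <- nlevels(d$bird_id) > 1
  re <- if (has_re) " + s(bird_id, bs = 're')" else ""
  excl <- if (has_re) "s(bird_id)" else NULL
  if (nlevels(d$class) == 2) {
    # two complementary classes carry one binomial observation per
    # bird-hour: the class-by-hour interaction question reduces to
    # whether the first class's proportion depends on hour at all
    ref <- levels(d$class)[1]
    da <- d[d$class == ref, , drop = FALSE]
    f0 <- stats::as.formula(paste("proportion ~ 1", re))
    f1 <- stats::as.formula(paste(
      "proportion ~ s(hour, bs = 'cc', k = ", k, ")", re))
    m0 <- mgcv::gam(f0, family = stats::quasibinomial(), weights = da$n,
                    data = da, knots = knots, method = "REML")
    m1 <- mgcv::gam(f1, family = stats::quasibinomial(), weights = da$n,
                    data = da, knots = knots, method = "REML")
    st <- summary(m1)$s.table
    p_int <- st["s(hour)", "p-value"]
    if (is.na(p_int)) p_int <- 1
    grid <- expand.grid(hour = 0:23, class = levels(d$class))
    grid$bird_id <- factor(levels(d$bird_id)[1], levels = levels(d$bird_id))
    fa <- as.numeric(stats::predict(m1, newdata = grid[grid$class == ref, ],
                                    type = "response", exclude = excl))
    grid$fitted <- ifelse(grid$class == ref, fa[grid$hour + 1],
                          1 - fa[grid$hour + 1])
  } else {
    # difference-smooth parameterisation: an ordered-factor by-variable
    # yields per-class departure smooths from the shared curve, each with
    # a well-calibrated significance test
    d$class_o <- as.ordered(d$class)
    f_shared <- stats::as.formula(paste(
      "proportion ~ class + s(hour, bs = 'cc', k = ", k, ")", re))
    f_byclass <- stats::as.formula(paste(
      "proportion ~ class + s(hour, bs = 'cc', k = ", k,
      ") + s(hour, bs = 'cc', k = ", k, ", by = class_o)", re))
    m0 <- mgcv::gam(f_shared, family = stats::quasibinomial(),
                    weights = d$n, data = d, knots = knots, method = "REML")
    m1 <- mgcv::gam(f_byclass, family = stats::quasibinomial(),
                    weights = d$n, data = d, knots = knots, method = "REML")
    st <- summary(m1)$s.table
    diff_rows <- grep("class_o", rownames(st))
    p_int <- if (length(diff_rows)) {
      min(1, min(st[diff_rows, "p-value"]) * length(diff_rows))  # Bonferroni
    } else {
      1
    }
    grid <- expand.grid(hour = 0:23, class = levels(d$class))
    grid$class_o <- as.ordered(grid$class)
    grid$bird_id <- factor(levels(d$bird_id)[1], levels = levels(d$bird_id))
    grid$fitted <- as.numeric(stats::predict(m1, newdata = grid,
                                             type = "response",
                                             exclude = excl))
    grid <- grid[, c("hour", "class", "fitted", "bird_id")]
  }
  list(fit = m1, fit_shared = m0, interaction_p = p_int,
       curves = grid[, c("hour", "class", "fitted")])
}

#' Evaluate the cyclic basis continuity of a diurnal fit
#'
#' Fitted values of the class-specific model at hour 0 and hour 24 (same
#' clock instant); used to verify seam continuity.
#'
#' @param model Output of [fit_diurnal_model()].
#' @return Data frame with per-class fits at hour 0 and 24.
#' @export
diurnal_seam <- function(model) {
  d <- model$fit$model
  cls <- if ("class" %in% names(d)) levels(d$class) else "all"
  grid <- expand.grid(hour = c(0, 24), class = cls)
  if ("class" %in% names(d)) {
    grid$class <- factor(grid$class, levels = levels(d$class))
  }
  if ("class_o" %in% names(d)) grid$class_o <- as.ordered(grid$class)
  excl <- NULL
  if ("bird_id" %in% names(d)) {
    grid$bird_id <- factor(levels(d$bird_id)[1], levels = levels(d$bird_id))
    excl <- "s(bird_id)"
  }
  grid$fitted <- as.numeric(stats::predict(model$fit, newdata = grid,
                                           type = "response",
                                           exclude = excl))
  grid
}
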