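# Aggregation of 1-s wet/dry events to a binary per-interval foraging
# indicator, and a four-state expectation-maximisation binary clustering
# of (velocity, turning angle). The clustering is a self-contained
# quadrant-seeded 4-component Gaussian-mixture EM in the spirit of the
# published binary-clustering algorithm, with states labelled LL/LH/HL/HH
# (low/high velocity x low/high turn) via per-variable delimiters.

#' Aggregate dive events to a binary foraging flag
#'
#' A track point at time t gets flag 1 iff at least one `wet_in` event
#' falls in the half-open window (t - interval, t].
#'
#' @param dives Data frame with `bird_id`, `timestamp`, `event`.
#' @param trackpoints Data frame with `bird_id`, `timestamp`.
#' @param interval_min Window length, minutes.
#' @return Integer vector (0/1) aligned with `trackpoints`.
#' @export
aggregate_dives <- function(dives, trackpoints, interval_min = 15) {
  flag <- integer(nrow(trackpoints))
  if (nrow(dives) == 0) return(flag)
  wet <- dives[dives$event == "wet_in", , drop = FALSE]
  for (b in unique(trackpoints$bird_id)) {
    ti <- which(trackpoints$bird_id == b)
    wb <- as.numeric(wet$timestamp[wet$bird_id == b])
    if (!length(wb)) next
    tt <- as.numeric(trackpoints$timestamp[ti])
    lo <- tt - interval_min * 60
    # count wet_in events with lo < t_event <= tt
    n_in <- findInterval(tt, sort(wb)) - findInterval(lo, sort(wb))
    flag[ti] <- as.integer(n_in > 0)
  }
  flag
}

dmvnorm2 <- function(x, mu, sigma) {
  # bivariate normal density, x: n x 2
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[1, 2], sigma[1, 1]),
                2, 2) / det_s
  d <- sweep(x, 2, mu)
  q <- d[, 1]^2 * inv[1, 1] + 2 * d[, 1] * d[, 2] * inv[1, 2] +
    d[, 2]^2 * inv[2, 2]
  exp(-q / 2) / (2 * pi * sqrt(det_s))
}

#' Fit the four-state binary movement clustering
#'
#' Quadrant-seeded 4-component bivariate Gaussian-mixture EM on
#' (velocity, turning angle). Components are initialised from the four
#' quadrants of the per-variable median split; the M-step uses moment
#' updates with a covariance floor; iteration stops when the
#' log-likelihood gain falls below `tol`. States are labelled LL, LH, HL,
#' HH by ranking component means: the two lowest velocity means are "L"
#' velocity, and within each velocity pair the lower turn mean is "L"
#' turn. Delimiters are midpoints between the low-pair and high-pair
#' means on each variable.
#'
#' @param velocity Numeric vector, m/s.
#' @param turning_angle Numeric vector, degrees [0, 180].
#' @param max_iter Maximum EM iterations.
#' @param tol Log-likelihood convergence tolerance.
#' @return An `embc_model`: component means/covariances/weights,
#'   delimiters, log-likelihood trace, convergence flag and the training
#'   state labels.
#' @export
embc_fit <- function(velocity, turning_angle, max_iter = 500, tol = 1e-6) {
  ok <- is.finite(velocity) & is.finite(turning_angle)
  x <- cbind(velocity[ok], turning_angle[ok])
  n <- nrow(x)
  if (n < 40) stop("need at least 40 points with finite velocity and turn")
  if (stats::sd(x[, 1]) < 1e-9 || stats::sd(x[, 2]) < 1e-9) {
    stop("degenerate input: a clustering variable is constant; ",
         "consider fewer states")
  }
  med <- apply(x, 2, stats::median)
  quad <- 1L + (x[, 1] > med[1]) * 2L + (x[, 2] > med[2]) * 1L
  # quadrant order: 1 = LL, 2 = LH, 3 = HL, 4 = HH
  K <- 4L
  mu <- matrix(0, K, 2); sig <- vector("list", K); w <- numeric(K)
  global_cov <- stats::cov(x)
  for (k in 1:K) {
    xk <- x[quad == k, , drop = FALSE]
    if (nrow(xk) < 3) {
      mu[k, ] <- med + 0.1 * c(k, -k)
      sig[[k]] <- global_cov
      w[k] <- 1e-3
    } else {
      mu[k, ] <- colMeans(xk)
      sig[[k]] <- stats::cov(xk)
      w[k] <- nrow(xk) / n
    }
  }
  w <- w / sum(w)
  floor_cov <- function(s) {
    eps <- 1e-6 * sum(diag(s)) / 2 + 1e-10
    s + diag(eps, 2)
  }
  sig <- lapply(sig, floor_cov)
  ll_trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    dens <- sapply(1:K, function(k) w[k] * dmvnorm2(x, mu[k, ], sig[[k]]))
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rs
    if (it > 1 && ll - ll_trace[it - 1L] < tol) {
      converged <- TRUE
      break
    }
    nk <- colSums(resp)
    for (k in 1:K) {
      if (nk[k] < 1e-8) next
      mu[k, ] <- colSums(resp[, k] * x) / nk[k]
      d <- sweep(x, 2, mu[k, ])
      s <- crossprod(d * sqrt(resp[, k])) / nk[k]
      sig[[k]] <- floor_cov(s)
    }
    w <- nk / n
  }
  # label components: two lowest velocity means -> L velocity, then by turn
  vel_rank <- order(mu[, 1])
  low_v <- vel_rank[1:2]; high_v <- vel_rank[3:4]
  lab <- character(K)
  lab[low_v[order(mu[low_v, 2])]] <- c("LL", "LH")
  lab[high_v[order(mu[high_v, 2])]] <- c("HL", "HH")
  delim_v <- (mean(mu[low_v, 1]) + mean(mu[high_v, 1])) / 2
  low_t <- c(which(lab == "LL"), which(lab == "HL"))
  high_t <- c(which(lab == "LH"), which(lab == "HH"))
  delim_t <- (mean(mu[low_t, 2]) + mean(mu[high_t, 2])) / 2
  model <- structure(
    list(means = mu, covariances = sig, weights = w, labels = lab,
         delimiters = c(velocity = delim_v, turn = delim_t),
         loglik_trace = ll_trace, converged = converged,
         n = n),
    class = "embc_model"
  )
  model$train_states <- embc_classify(model, x[, 1], x[, 2])
  model
}

#' @export
print.embc_model <- function(x, ...) {
  cat(sprintf("<embc_model> 4 states, n = %d, %sconverged (%d iterations)\n",
              x$n, if (x$converged) "" else "NOT ", length(x$loglik_trace)))
  for (k in 1:4) {
    cat(sprintf("  %s: weight %.3f, velocity %.2f m/s, turn %.1f deg\n",
                x$labels[k], x$weights[k], x$means[k, 1], x$means[k, 2]))
  }
  cat(sprintf("  delimiters: velocity %.2f m/s, turn %.1f deg\n",
              x$delimiters[1], x$delimiters[2]))
  invisible(x)
}

#' Classify points with a fitted movement-state model
#'
#' Assigns each point to the maximum-responsibility state; ties are broken
#' toward the larger mixing weight, then the fixed order LL < LH < HL <
#' HH.
#'
#' @param model A fitted [embc_fit()] model.
#' @param velocity,turning_angle Numeric vectors.
#' @return Character vector of state labels (NA for non-finite inputs).
#' @export
embc_classify <- function(model, velocity, turning_angle) {
  if (!inherits(model, "embc_model")) stop("model is not a fitted embc_model")
  out <- rep(NA_character_, length(velocity))
  ok <- is.finite(velocity) & is.finite(turning_angle)
  if (!any(ok)) return(out)
  x <- cbind(velocity[ok], turning_angle[ok])
  dens <- sapply(1:4, function(k) {
    model$weights[k] * dmvnorm2(x, model$means[k, ], model$covariances[[k]])
  })
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1)
  label_order <- match(model$labels, c("LL", "LH", "HL", "HH"))
  pick <- apply(dens, 1, function(p) {
    best <- which(p == max(p))
    if (length(best) > 1) {
      bw <- best[model$weights[best] == max(model$weights[best])]
      best <- bw[order(label_order[bw])][1]
    }
    best
  })
  out[ok] <- model$labels[pick]
  out
}
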