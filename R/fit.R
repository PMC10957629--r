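#' Default parameter box for Wood-curve fitting
#'
#' Liberal bounds for the multi-start fit, derived from the data: the
#' baseline `d` spans `[0, max(y)]`, the peak time `m` spans 5 minutes to
#' 1.5 times the last sampling time, the decay rate `c` spans
#' `[1e-4, 1]` per minute, and the implied peak height spans 0.01 to 10
#' times the observed data range.  Narrow boxes invite convergence
#' failures; implausible optima are removed later by [curate_pois()].
#'
#' @param times,values the series the box is calibrated on.
#' @return List with elements `m`, `c`, `d`, `height`, each `c(lo, hi)`.
#' @export
wood_bounds <- function(times, values) {
  rng <- diff(range(values, na.rm = TRUE))
  if (!is.finite(rng) || rng <= 0) rng <- max(abs(values), 1, na.rm = TRUE)
  list(m      = c(5, 1.5 * max(times)),
       c      = c(1e-4, 1),
       d      = c(0, max(values, na.rm = TRUE)),
       height = c(0.01 * rng, 10 * rng))
}

#' Random starting values for the multi-start fit
#'
#' Draws `n_starts` parameter sets spanning the bounding box: `m` and `d`
#' uniform, `c` and the implied peak height log-uniform (the amplitude
#' `a` is derived from the height).  Deterministic given `seed`.
#'
#' @param times,values numeric vectors; the series to be fitted
#'   (missing values allowed in `values`).
#' @param n_starts number of starts (default 500).
#' @param seed integer seed for the draw.
#' @param bounds parameter box as from [wood_bounds()].
#' @return List of [wood_params()] objects of length `n_starts`.
#' @export
make_starts <- function(times, values, n_starts = 500, seed = 1,
                        bounds = wood_bounds(times, values)) {
  if (!is.numeric(n_starts) || n_starts < 1)
    stop("'n_starts' must be a positive integer")
  n_starts <- as.integer(n_starts)
  ok <- is.finite(values)
  if (sum(ok) < 5)
    stop("need at least 5 non-missing points to fit a Wood curve")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- runif(n_starts, bounds$m[1], bounds$m[2])
  cc <- exp(runif(n_starts, log(bounds$c[1]), log(bounds$c[2])))
  d <- runif(n_starts, bounds$d[1], bounds$d[2])
  A <- exp(runif(n_starts, log(bounds$height[1]), log(bounds$height[2])))
  lapply(seq_len(n_starts), function(i)
    wood_params(a = wood_a_from_height(A[i], m[i], cc[i]),
                m = m[i], c = cc[i], d = d[i]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# profiled residual sum of squares: for fixed (m, c) the model
# y = d + A k(t) is linear in (A, d); solve the 2x2 normal equations and
# clamp to A >= 0, 0 <= d <= max(y).  `lt` is log(t) precomputed.
.wood_profile_rss <- function(par, t, y, dmax, lt = log(t)) {
  m <- par[1]; cc <- par[2]
  b <- m * cc
  lk <- b * (lt - log(m)) - cc * (t - m)
  lk[t == 0] <- -Inf
  k <- exp(lk)
  n <- length(y)
  sk <- sum(k); skk <- sum(k * k); sy <- sum(y); sky <- sum(k * y)
  det <- n * skk - sk * sk
  if (!is.finite(det) || det <= 1e-12 * n * skk) {
    A <- 0; d <- sy / n
  } else {
    A <- (n * sky - sk * sy) / det
    d <- (sy - A * sk) / n
  }
  if (!is.finite(A) || A < 0) {           # refit with A pinned at 0
    A <- 0; d <- sy / n
  }
  if (d < 0) {                            # refit with d pinned at 0
    d <- 0; A <- max(sky / skk, 0)
  } else if (d > dmax) {
    d <- dmax; A <- max((sky - d * sk) / skk, 0)
  }
  r <- y - d - A * k
  list(rss = sum(r * r), A = A, d = d, r = r, k = k)
}

# gradient of the profiled rss wrt (m, c) by the envelope theorem
# (exact at an interior (A, d) optimum, a descent direction otherwise)
.wood_profile_grad <- function(par, t, y, dmax, lt = log(t)) {
  m <- par[1]; cc <- par[2]
  pr <- .wood_profile_rss(par, t, y, dmax, lt)
  L <- lt - log(m)
  Ak <- pr$A * pr$k
  gm <- ifelse(t == 0, 0, Ak * cc * L)
  gc <- ifelse(t == 0, 0, Ak * (m * L - (t - m)))
  -2 * c(sum(pr$r * gm), sum(pr$r * gc))
}

# rss and analytic gradient in the (A, m, c, d) parameterization used
# by the final polish
.wood_full_rss <- function(p, t, y, lt = log(t)) {
  r <- y - wood_eval_norm(p[1], p[2], p[3], p[4], t)
  sum(r * r)
}
.wood_full_grad <- function(p, t, y, lt = log(t)) {
  A <- p[1]; m <- p[2]; cc <- p[3]; d <- p[4]
  L <- lt - log(m)
  k <- exp(ifelse(t == 0, -Inf, m * cc * L - cc * (t - m)))
  r <- y - d - A * k
  Ak <- A * k
  gm <- ifelse(t == 0, 0, Ak * cc * L)
  gc <- ifelse(t == 0, 0, Ak * (m * L - (t - m)))
  -2 * c(sum(r * k), sum(r * gm), sum(r * gc), sum(r))
}

#' Fit a Wood curve to one time series
#'
#' Multi-start bounded nonlinear least squares on the concentration
#' scale.  One deterministic data-driven start (peak where the data
#' peak) is tried ahead of the random starts, which stabilizes fits at
#' small start counts.  Each start is refined by a local optimizer (the
#' amplitude and baseline are profiled out in closed form for the given
#' peak time and decay rate, then all four parameters are polished
#' jointly under box constraints); the converged start with the smallest
#' residual sum of squares wins, ties broken by start order.  A start
#' that finishes on a bound counts as converged — implausible parameter
#' values are a matter for [curate_pois()], not the optimizer.
#'
#' At least five non-missing points are required (four parameters plus
#' one); eight or more are recommended for a reliable fit.  Missing
#' values are dropped pairwise.
#'
#' @param times sampling times in minutes.
#' @param values concentrations; `NA` allowed.
#' @param n_starts number of random starts (default 500; smaller values
#'   are usually adequate for clean data).
#' @param seed integer seed for start generation.
#' @param bounds parameter box, see [wood_bounds()].
#' @return Object of class `woodfit` with components `params`
#'   ([wood_params()] or `NULL`), `rss`, `sigma`, `n_points`,
#'   `n_starts`, `converged`, `seed`, and the data used.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`, `simulate`.
#' @examples
#' t <- seq(0, 180, by = 20)
#' y <- wood_eval(wood_params(0.5, 45, 0.04, 100), t)
#' fit <- fit_wood(t, y, n_starts = 25, seed = 1)
#' coef(fit)
#' @export
fit_wood <- function(times, values, n_starts = 500, seed = 1,
                     bounds = wood_bounds(times, values)) {
  ok <- is.finite(values) & is.finite(times)
  t <- times[ok]; y <- values[ok]
  if (length(t) < 5)
    stop("need at least 5 non-missing points to fit a Wood curve (got ",
         length(t), ")")
  if (anyDuplicated(t))
    stop("duplicate time points within one series")
  o <- order(t); t <- t[o]; y <- y[o]

  starts <- make_starts(t, y, n_starts = n_starts, seed = seed,
                        bounds = bounds)
  dmax <- bounds$d[2]
  lower <- c(bounds$m[1], bounds$c[1])
  upper <- c(bounds$m[2], bounds$c[2])

  # data-driven start ahead of the random ones: peak where the data
  # peak, decay rate giving a moderate shape exponent b = 2
  m0 <- min(max(t[which.max(y)], lower[1] + 1e-6), upper[1] - 1e-6)
  c0 <- min(max(2 / m0, lower[2]), upper[2])
  starts <- c(list(list(m = m0, c = c0)), starts)

  lt <- log(t)
  best <- NULL
  for (i in seq_along(starts)) {
    s <- starts[[i]]
    opt <- tryCatch(
      nlminb(c(s$m, s$c),
             function(p) .wood_profile_rss(p, t, y, dmax, lt)$rss,
             gradient = function(p)
               .wood_profile_grad(p, t, y, dmax, lt),
             lower = lower, upper = upper,
             control = list(rel.tol = 1e-8, iter.max = 200)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective - 1e-12)
      best <- list(objective = opt$objective, par = opt$par, start = i)
  }
  if (is.null(best)) {
    return(.woodfit_failed(t, y, n_starts, seed, "no start converged"))
  }

  # joint polish over (A, m, c, d) under the box
  pr <- .wood_profile_rss(best$par, t, y, dmax, lt)
  p0 <- c(A = max(pr$A, bounds$height[1] * 1e-6),
          m = best$par[1], c = best$par[2], d = min(max(pr$d, 0), dmax))
  pol <- tryCatch(
    optim(p0, .wood_full_rss, gr = .wood_full_grad, t = t, y = y,
          lt = lt, method = "L-BFGS-B",
          lower = c(1e-12, bounds$m[1], bounds$c[1], 0),
          upper = c(Inf, bounds$m[2], bounds$c[2], dmax),
          control = list(maxit = 200, factr = 1e4)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) &&
      pol$value <= best$objective)
    p0 <- pol$par
  rss <- .wood_full_rss(p0, t, y, lt)

  params <- tryCatch(
    wood_params(a = unname(wood_a_from_height(p0[1], p0[2], p0[3])),
                m = unname(p0[2]), c = unname(p0[3]), d = unname(p0[4])),
    error = function(e) NULL)
  if (is.null(params))
    return(.woodfit_failed(t, y, n_starts, seed, "degenerate optimum"))

  n <- length(t)
  structure(list(params = params, rss = rss,
                 sigma = sqrt(rss / max(n - 4, 1)),
                 n_points = n, n_starts = n_starts,
                 converged = TRUE, seed = seed,
                 failure_reason = NA_character_,
                 times = t, values = y),
            class = "woodfit")
}

.woodfit_failed <- function(t, y, n_starts, seed, reason) {
  structure(list(params = NULL, rss = NA_real_, sigma = NA_real_,
                 n_points = length(t), n_starts = n_starts,
                 converged = FALSE, seed = seed, failure_reason = reason,
                 times = t, values = y),
            class = "woodfit")
}

#' @export
print.woodfit <- function(x, digits = 4, ...) {
  cat("Wood curve fit (", x$n_points, " points, ", x$n_starts,
      " starts)\n", sep = "")
  if (x$converged) {
    print(round(unlist(x$params), digits))
    cat("RSS:", format(x$rss, digits = digits),
        " residual sd:", format(x$sigma, digits = digits), "\n")
  } else {
    cat("did not converge:", x$failure_reason, "\n")
  }
  invisible(x)
}

#' @export
coef.woodfit <- function(object, ...) {
  if (!object$converged)
    return(c(a = NA_real_, m = NA_real_, c = NA_real_, d = NA_real_,
             b = NA_real_))
  unlist(object$params)
}

#' @export
fitted.woodfit <- function(object, ...) {
  if (!object$converged) return(rep(NA_real_, object$n_points))
  wood_eval(object$params, object$times)
}

#' @export
residuals.woodfit <- function(object, ...) {
  object$values - fitted(object)
}

#' @export
predict.woodfit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
       else if (is.list(newdata)) newdata$Time else newdata
  if (!object$converged) return(rep(NA_real_, length(t)))
  wood_eval(object$params, t)
}

#' @export
simulate.woodfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a failed fit")
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, object$sigma)))
}

#' @export
summary.woodfit <- function(object, t_f = max(object$times), ...) {
  pois <- if (object$converged)
    c(AUC = poi_auc(object$params, t_f),
      Height = poi_height(object$params),
      Time2Max = poi_time2max(object$params))
  else c(AUC = NA_real_, Height = NA_real_, Time2Max = NA_real_)
  structure(list(fit = object, pois = pois, t_f = t_f),
            class = "summary.woodfit")
}

#' @export
print.summary.woodfit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("Parameters of interest (t_f = ", x$t_f, " min):\n", sep = "")
  print(round(x$pois, digits))
  invisible(x)
}

#' @export
plot.woodfit <- function(x, npoints = 200, ...) {
  plot(x$times, x$values, xlab = "Time (min)",
       ylab = "Concentration", ...)
  if (x$converged) {
    tt <- seq(min(x$times), max(x$times), length.out = npoints)
    graphics::lines(tt, wood_eval(x$params, tt))
  }
  invisible(x)
}

# deterministic per-series seed derived from the study seed and the
# series key, so a single-series refit reproduces pipeline results
series_seed <- function(seed, participant, intervention, analyte) {
  key <- paste(participant, intervention, analyte, sep = "\r")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483113L
  as.integer((as.numeric(seed) * 379 + h) %% 2147483629 + 1)
}

#' Fit Wood curves to every series of a study
#'
#' Splits the study table by participant, intervention and analyte and
#' fits each series with [fit_wood()].  Per-series failures (too few
#' points, no convergence) are recorded in the result, never raised.
#' Per-series seeds are derived deterministically from the study seed
#' and the series key, so refitting one series in isolation reproduces
#' the pipeline result.
#'
#' @param table a [study_table()].
#' @param n_starts,seed passed to [fit_wood()] (per-series seeds are
#'   derived from `seed`).
#' @param bounds optional fixed parameter box; default recalibrates
#'   [wood_bounds()] per series.
#' @return A data frame of class `woodfit_table` with one row per
#'   series: keys, `a`, `m`, `c`, `d`, `b`, `rss`, `sigma`, `n_points`,
#'   `t_max`, `converged`, `failure_reason`.
#' @export
fit_all <- function(table, n_starts = 500, seed = 1, bounds = NULL) {
  stopifnot(inherits(table, "study_table"))
  keys <- unique(as.data.frame(table)[c("Participant", "Period",
                                        "Intervention", "Analyte")])
  rownames(keys) <- NULL
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- table[table$Participant == keys$Participant[i] &
                 table$Period == keys$Period[i] &
                 table$Intervention == keys$Intervention[i] &
                 table$Analyte == keys$Analyte[i], ]
    sseed <- series_seed(seed, keys$Participant[i],
                         keys$Intervention[i], keys$Analyte[i])
    row <- data.frame(keys[i, , drop = FALSE],
                      a = NA_real_, m = NA_real_, c = NA_real_,
                      d = NA_real_, b = NA_real_, rss = NA_real_,
                      sigma = NA_real_,
                      n_points = sum(is.finite(sub$Value)),
                      t_max = suppressWarnings(
                        max(sub$Time[is.finite(sub$Value)], -Inf)),
                      converged = FALSE,
                      failure_reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (row$n_points < 5) {
      row$failure_reason <- "fewer than 5 usable points"
    } else {
      fit <- tryCatch(
        fit_wood(sub$Time, sub$Value, n_starts = n_starts, seed = sseed,
                 bounds = if (is.null(bounds))
                   wood_bounds(sub$Time, sub$Value) else bounds),
        error = function(e) .woodfit_failed(sub$Time, sub$Value,
                                            n_starts, sseed,
                                            conditionMessage(e)))
      row$converged <- fit$converged
      row$failure_reason <- fit$failure_reason
      if (fit$converged) {
        row[c("a", "m", "c", "d", "b")] <- unlist(fit$params)
        row$rss <- fit$rss
        row$sigma <- fit$sigma
      }
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("woodfit_table", "data.frame")
  attr(res, "seed") <- seed
  attr(res, "n_starts") <- n_starts
  res
}
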