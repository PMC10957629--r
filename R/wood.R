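#' Wood curve parameters
#'
#' Constructs and validates the four parameters of the baseline-extended
#' Wood curve
#' \deqn{y(t) = d + a \, t^{b} e^{-c t}, \qquad b = m c,}
#' a rise-peak-decay response over a baseline, originally used for
#' lactation curves and well suited to postprandial concentration time
#' courses.  The curve attains its maximum at \eqn{t = m}, so `m` is
#' directly the time-to-maximum; `c` (1/minutes) governs the return to
#' baseline, `a` scales the amplitude, and `d` is the baseline
#' concentration.  The shape exponent `b = m * c` is always derived,
#' never a free parameter.
#'
#' @param a amplitude scale, strictly positive.
#' @param m time of the peak maximum in minutes, strictly positive.
#' @param c decay rate per minute, strictly positive.
#' @param d baseline concentration, non-negative.
#' @return An object of class `wood_params`: a named list with elements
#'   `a`, `m`, `c`, `d` and the derived `b`.
#' @seealso [wood_eval()], [fit_wood()], [poi_auc()]
#' @examples
#' p <- wood_params(a = 2, m = 40, c = 0.05, d = 100)
#' p$b              # 2
#' wood_eval(p, 40) # the curve maximum
#' @export
wood_params <- function(a, m, c, d) {
  stopifnot(is.numeric(a), is.numeric(m), is.numeric(c), is.numeric(d),
            length(a) == 1L, length(m) == 1L, length(c) == 1L,
            length(d) == 1L)
  if (!is.finite(a) || a <= 0) stop("'a' must be finite and > 0")
  if (!is.finite(m) || m <= 0) stop("'m' must be finite and > 0")
  if (!is.finite(c) || c <= 0) stop("'c' must be finite and > 0")
  if (!is.finite(d) || d < 0)  stop("'d' must be finite and >= 0")
  structure(list(a = a, m = m, c = c, d = d, b = m * c),
            class = "wood_params")
}

as_wood_params <- function(x) {
  if (inherits(x, "wood_params")) return(x)
  x <- as.list(x)
  wood_params(x$a, x$m, x$c, x$d)
}

#' @export
print.wood_params <- function(x, digits = 4, ...) {
  cat("Wood curve parameters:\n")
  print(round(unlist(x), digits))
  invisible(x)
}

#' Evaluate a Wood curve
#'
#' Computes \eqn{d + a t^{b} e^{-ct}} with \eqn{b = mc}.  Internally the
#' curve is evaluated in the peak-normalized form
#' \eqn{d + A (t/m)^b e^{-c(t-m)}} with \eqn{A = a m^b e^{-b}} the peak
#' height, which is numerically stable for large shape exponents where
#' \eqn{t^b} would overflow.  At `t = 0` the value is exactly `d`.
#'
#' @param params a [wood_params()] object (or a list/named vector with
#'   elements `a`, `m`, `c`, `d`).
#' @param t vector of times in minutes, all non-negative.
#' @return Numeric vector of concentrations, one per element of `t`.
#' @examples
#' wood_eval(wood_params(1, 60, 0.05, 100), c(0, 30, 60))
#' @export
wood_eval <- function(params, t) {
  p <- as_wood_params(params)
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and >= 0")
  # log height at the peak: log A = log a + b log m - b
  logA <- log(p$a) + p$b * log(p$m) - p$b
  wood_eval_norm(exp(logA), p$m, p$c, p$d, t)
}

# peak-normalized evaluation: d + A * (t/m)^b * exp(-c (t - m)); A is the
# peak height, so the kernel is bounded by 1 and never overflows.
wood_eval_norm <- function(A, m, c, d, t) {
  b <- m * c
  lk <- b * log(t / m) - c * (t - m)
  lk[t == 0] <- -Inf
  d + A * exp(lk)
}

# convert (A, m, c) back to the conventional amplitude a = A / (m^b e^-b);
# clamped away from 0/Inf so extreme shape exponents cannot underflow the
# positivity of a
wood_a_from_height <- function(A, m, c) {
  b <- m * c
  unname(pmin(pmax(exp(log(A) - b * log(m) + b), 1e-300), 1e300))
}
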