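#' Time to the peak maximum
#'
#' For the Wood curve the time of the maximum is the parameter `m`
#' itself, independent of the other parameters.
#'
#' @param params a [wood_params()] object.
#' @return Minutes from the meal to the curve maximum.
#' @export
poi_time2max <- function(params) {
  as_wood_params(params)$m
}

#' Peak height above baseline
#'
#' The maximum of the Wood curve relative to its baseline,
#' \eqn{a (b/c)^b e^{-b}} with \eqn{b = mc}; identical to
#' `wood_eval(params, m) - d`.  Computed on the log scale for stability.
#'
#' @param params a [wood_params()] object.
#' @return Concentration above baseline at the peak.
#' @export
poi_height <- function(params) {
  p <- as_wood_params(params)
  exp(log(p$a) + p$b * (log(p$b / p$c)) - p$b)
}

#' Area under the curve above baseline
#'
#' Analytic AUC of the Wood response relative to the baseline `d`,
#' integrated from the meal up to `t_f`:
#' \deqn{\mathrm{AUC}(t_f) = \int_0^{t_f} a t^b e^{-ct}\,dt
#'   = \frac{a\,\gamma(b + 1,\, c t_f)}{c^{b+1}},}
#' where \eqn{\gamma(q, x) = \int_0^x z^{q-1} e^{-z} dz} is the lower
#' incomplete gamma function (shape first, integration limit second).
#' Evaluated via the regularized gamma CDF (`pgamma`) on the log scale,
#' so it is stable for large shape exponents.
#'
#' @param params a [wood_params()] object.
#' @param t_f upper integration limit in minutes, strictly positive.
#' @return Concentration x minutes above baseline.
#' @examples
#' poi_auc(wood_params(1, 60, 0.05, 100), t_f = 240)  # ~957800
#' @export
poi_auc <- function(params, t_f) {
  p <- as_wood_params(params)
  if (!is.numeric(t_f) || any(!is.finite(t_f) & t_f != Inf) || any(t_f <= 0))
    stop("'t_f' must be > 0")
  q <- p$b + 1
  exp(log(p$a) + lgamma(q) - q * log(p$c) +
        pgamma(p$c * t_f, q, log.p = TRUE))
}

#' Extract parameters of interest from a fit table
#'
#' Computes AUC, Height and Time2Max analytically for every converged
#' fit; failed fits yield all-missing records.  The AUC integration
#' limit defaults to the last observed time of each series, avoiding
#' extrapolation beyond the data; a global `t_f` can override it.
#'
#' @param fits a `woodfit_table` from [fit_all()].
#' @param t_f optional global upper integration limit (minutes).
#' @return A data frame of class `poi_table`: keys, `AUC`, `Height`,
#'   `Time2Max`, `t_f`, `flags` (semicolon-separated curation flags,
#'   empty before curation).
#' @export
extract_pois <- function(fits, t_f = NULL) {
  stopifnot(inherits(fits, "woodfit_table") || is.data.frame(fits))
  n <- nrow(fits)
  tf <- if (is.null(t_f)) fits$t_max else rep(t_f, n)
  key_cols <- intersect(c("Participant", "Period", "Intervention",
                          "Analyte"), names(fits))
  out <- data.frame(as.data.frame(fits)[key_cols],
                    AUC = NA_real_, Height = NA_real_,
                    Time2Max = NA_real_, t_f = tf,
                    flags = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!isTRUE(fits$converged[i])) next
    p <- wood_params(fits$a[i], fits$m[i], fits$c[i], fits$d[i])
    out$AUC[i] <- poi_auc(p, tf[i])
    out$Height[i] <- poi_height(p)
    out$Time2Max[i] <- poi_time2max(p)
  }
  class(out) <- c("poi_table", "data.frame")
  out
}

#' Plausibility rules for curation
#'
#' Default plausible ranges: AUC strictly positive, peak height in
#' (0, 1000) concentration units, time-to-maximum in (15, 200) minutes.
#' Curve parameters default to positivity only (`d` may be 0): the fit
#' is run with liberal bounds and curation is the real guard.  Note
#' that for aggregated amino-acid totals much larger heights and AUCs
#' are expected; supply wider rules for those analytes.
#'
#' @param AUC,Height,Time2Max,a,m,c,d length-2 numeric `c(lo, hi)`
#'   open-interval limits per quantity (use `-Inf`/`Inf` to disable a
#'   side).
#' @return A list of class `curation_rules`.
#' @export
curation_rules <- function(AUC = base::c(0, Inf),
                           Height = base::c(0, 1000),
                           Time2Max = base::c(15, 200),
                           a = base::c(0, Inf), m = base::c(0, Inf),
                           c = base::c(0, Inf),
                           d = base::c(-Inf, Inf)) {
  rules <- list(AUC = AUC, Height = Height, Time2Max = Time2Max,
                a = a, m = m, c = c, d = d)
  for (nm in names(rules)) {
    r <- rules[[nm]]
    if (!is.numeric(r) || length(r) != 2L || r[1] >= r[2])
      stop("rule for '", nm, "' must be c(lo, hi) with lo < hi")
  }
  structure(rules, class = "curation_rules")
}

#' Curate parameters of interest
#'
#' Replaces every PoI outside its plausible range by `NA` and flags it;
#' a curve-parameter violation removes all three PoIs of that series
#' (the whole fit is suspect).  Values inside their ranges are never
#' altered, so curation is idempotent.  All intervals are open: a value
#' exactly on a bound is removed.
#'
#' @param pois a `poi_table` from [extract_pois()].
#' @param fits the matching `woodfit_table` (needed for the
#'   curve-parameter checks; optional, parameter rules are skipped
#'   without it).
#' @param rules a [curation_rules()] object.
#' @return A list with elements `pois` (the curated `poi_table`) and
#'   `report` (one row per removal: keys, `quantity`, `value`,
#'   `lower`, `upper`).
#' @export
curate_pois <- function(pois, fits = NULL, rules = curation_rules()) {
  stopifnot(inherits(rules, "curation_rules"))
  out <- pois
  rep_rows <- list()
  add_flag <- function(cur, flag) ifelse(cur == "", flag,
                                         paste(cur, flag, sep = ";"))
  outside <- function(v, r) is.finite(v) & (v <= r[1] | v >= r[2])

  if (!is.null(fits)) {
    key_p <- do.call(paste, c(pois[c("Participant", "Intervention",
                                     "Analyte")], sep = "\r"))
    key_f <- do.call(paste, c(fits[c("Participant", "Intervention",
                                     "Analyte")], sep = "\r"))
    idx <- match(key_p, key_f)
    for (par in c("a", "m", "c", "d")) {
      v <- fits[[par]][idx]
      bad <- which(outside(v, rules[[par]]))
      for (i in bad) {
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          pois[i, c("Participant", "Intervention", "Analyte")],
          quantity = paste0("param_", par), value = v[i],
          lower = rules[[par]][1], upper = rules[[par]][2])
        out$AUC[i] <- out$Height[i] <- out$Time2Max[i] <- NA_real_
        out$flags[i] <- add_flag(out$flags[i], paste0("param_", par))
      }
    }
  }
  for (poi in c("AUC", "Height", "Time2Max")) {
    v <- out[[poi]]
    bad <- which(outside(v, rules[[poi]]))
    for (i in bad) {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        pois[i, c("Participant", "Intervention", "Analyte")],
        quantity = poi, value = v[i],
        lower = rules[[poi]][1], upper = rules[[poi]][2])
      out[[poi]][i] <- NA_real_
      out$flags[i] <- add_flag(out$flags[i], tolower(poi))
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows)
            else data.frame(Participant = character(),
                            Intervention = character(),
                            Analyte = character(),
                            quantity = character(), value = numeric(),
                            lower = numeric(), upper = numeric())
  rownames(report) <- NULL
  list(pois = out, report = report)
}
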