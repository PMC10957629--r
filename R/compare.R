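#' Specification of the intervention-comparison model
#'
#' Defaults follow the standard analysis for crossover uptake trials:
#' each PoI is modelled as
#' `PoI ~ Intervention + Period + (1 | Participant)` with Period a
#' categorical fixed effect (carryover is not expected, but time trends
#' are checked for) and Participant a random intercept; AUC is compared
#' as a ratio (the response is log-transformed before fitting and the
#' contrast back-transformed), Height and Time2Max as differences;
#' tests of test-vs-reference contrasts use the Kenward-Roger
#' small-sample degrees-of-freedom approximation (Satterthwaite
#' available as a faster alternative); p-values are Holm-adjusted
#' within each PoI across analytes and contrasts.
#'
#' @param include_period include the Period fixed effect (default TRUE).
#' @param contrast_type named character vector giving `"ratio"` or
#'   `"difference"` per PoI.
#' @param level confidence level in (0, 1), default 0.95.
#' @param adjust multiplicity method within each PoI family:
#'   `"holm"`, `"bonferroni"` or `"none"`.
#' @param df_method `"kenward-roger"` or `"satterthwaite"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(include_period = TRUE,
                       contrast_type = c(AUC = "ratio",
                                         Height = "difference",
                                         Time2Max = "difference"),
                       level = 0.95,
                       adjust = c("holm", "bonferroni", "none"),
                       df_method = c("kenward-roger", "satterthwaite")) {
  stopifnot(level > 0, level < 1,
            all(contrast_type %in% c("ratio", "difference")))
  structure(list(include_period = isTRUE(include_period),
                 contrast_type = contrast_type,
                 level = level,
                 adjust = match.arg(adjust),
                 df_method = match.arg(df_method)),
            class = "model_spec")
}

#' Fit the mixed model for one analyte and one PoI
#'
#' Fits `PoI ~ Intervention + Period + (1 | Participant)` (Period
#' omitted when `include_period = FALSE` or only one period is present)
#' on the non-missing PoI values of one analyte.  For ratio-type PoIs
#' the response is log-transformed first; non-positive values are
#' dropped with a warning (curation should already have removed them).
#' The Intervention factor is releveled so the reference is the
#' baseline, making the remaining Intervention coefficients the
#' test-vs-reference contrasts on the (possibly log) response scale.
#'
#' @param pois a `poi_table`.
#' @param poi one of `"AUC"`, `"Height"`, `"Time2Max"`.
#' @param analyte analyte label.
#' @param reference reference intervention label.
#' @param spec a [model_spec()].
#' @return List of class `poi_model`: the `lmerModLmerTest` fit,
#'   `poi`, `analyte`, `log_scale`, `n_used`, `data`.
#'   Returns `NULL` (with a warning) when fewer than 2 interventions
#'   have at least 3 usable values.
#' @export
fit_poi_model <- function(pois, poi, analyte, reference,
                          spec = model_spec()) {
  stopifnot(poi %in% c("AUC", "Height", "Time2Max"))
  df <- as.data.frame(pois)
  df <- df[df$Analyte == analyte & is.finite(df[[poi]]), ]
  log_scale <- identical(unname(spec$contrast_type[poi]), "ratio")
  if (log_scale && any(df[[poi]] <= 0)) {
    warning(sum(df[[poi]] <= 0), " non-positive ", poi,
            " value(s) dropped before log transform (analyte ",
            analyte, ")")
    df <- df[df[[poi]] > 0, ]
  }
  counts <- table(df$Intervention)
  if (length(counts) < 2 || sum(counts >= 3) < 2) {
    warning("analyte '", analyte, "', ", poi,
            ": not enough data for a comparison; skipped")
    return(NULL)
  }
  if (!reference %in% names(counts))
    stop("reference intervention '", reference,
         "' absent for analyte '", analyte, "'")
  dat <- data.frame(
    y = if (log_scale) log(df[[poi]]) else df[[poi]],
    Intervention = stats::relevel(factor(df$Intervention),
                                  ref = reference),
    Participant = factor(df$Participant),
    Period = if ("Period" %in% names(df)) factor(df$Period)
             else factor(rep(1, nrow(df))))
  use_period <- spec$include_period && nlevels(dat$Period) > 1
  form <- if (use_period)
    y ~ Intervention + Period + (1 | Participant)
  else y ~ Intervention + (1 | Participant)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = dat, REML = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. constant response): the random intercept is
    # not estimable; fall back to the fixed-effects model
    fform <- if (use_period) y ~ Intervention + Period
             else y ~ Intervention
    fit <- lm(fform, data = dat)
  }
  structure(list(model = fit, poi = poi, analyte = analyte,
                 log_scale = log_scale, n_used = nrow(dat),
                 reference = reference, data = dat),
            class = "poi_model")
}

#' @export
print.poi_model <- function(x, ...) {
  cat("Mixed model for", x$poi, "of analyte", x$analyte,
      if (x$log_scale) "(log scale)" else "", "\n")
  print(x$model)
  invisible(x)
}

# per-coefficient estimate/se/df/p for the intervention coefficients,
# using the requested df approximation
.intervention_tests <- function(pm, spec) {
  fit <- pm$model
  if (inherits(fit, "lm")) {            # degenerate-data fallback
    cs <- coef(summary(fit))
    idx <- grep("^Intervention", rownames(cs))
    out <- data.frame(est = cs[idx, 1], se = cs[idx, 2],
                      df = fit$df.residual)
    out$test <- sub("^Intervention", "", rownames(cs)[idx])
    out$t <- out$est / out$se
    out$p <- 2 * pt(-abs(out$t), out$df)
    out$p[out$se == 0] <- ifelse(out$est[out$se == 0] == 0, 1, 0)
    out$method <- "classical"
    return(out)
  }
  beta <- lme4::fixef(fit)
  idx <- grep("^Intervention", names(beta))
  levs <- sub("^Intervention", "", names(beta)[idx])
  out <- NULL
  method <- spec$df_method
  if (spec$df_method == "kenward-roger") {
    out <- tryCatch({
      vadj <- pbkrtest::vcovAdj(fit)
      res <- lapply(seq_along(idx), function(j) {
        L <- as.numeric(seq_along(beta) == idx[j])
        df <- pbkrtest::Lb_ddf(L, vcov(fit), vadj)
        se <- sqrt(drop(t(L) %*% as.matrix(vadj) %*% L))
        c(est = unname(beta[idx[j]]), se = se, df = df)
      })
      as.data.frame(do.call(rbind, res))
    }, error = function(e) NULL)   # singular fits: fall through
    if (is.null(out)) method <- "satterthwaite"
  }
  if (is.null(out)) {
    cs <- coef(summary(fit))  # lmerTest: Satterthwaite df column
    out <- data.frame(est = cs[idx, "Estimate"],
                      se = cs[idx, "Std. Error"],
                      df = cs[idx, "df"])
  }
  # degenerate zero-variance fits can yield df = 0/NaN; fall back to
  # the classical residual df so deterministic data still give a CI
  ndf <- nrow(stats::model.matrix(fit))
  pdf <- ncol(stats::model.matrix(fit))
  out$df[!is.finite(out$df) | out$df < 0.5] <- max(ndf - pdf, 1)
  out$test <- levs
  out$t <- out$est / out$se
  out$p <- 2 * pt(-abs(out$t), out$df)
  # exact (zero-residual) data: the contrast is known without error
  out$p[out$se == 0] <- ifelse(out$est[out$se == 0] == 0, 1, 0)
  out$method <- method
  out
}

#' Test-vs-reference contrasts for fitted PoI models
#'
#' One row per (analyte, PoI, test intervention): the contrast against
#' the reference, its confidence interval and p-value.  Difference
#' contrasts are on the response scale; ratio contrasts are estimated
#' on the log scale and back-transformed (estimate and CI
#' exponentiated).  `p_adjusted` is computed within each PoI family
#' across analytes and contrasts by the configured method.
#'
#' @param models list of `poi_model` objects (NULL entries are skipped).
#' @param spec a [model_spec()].
#' @return Data frame of class `poi_comparison`: `Analyte`, `PoI`,
#'   `contrast`, `type`, `estimate`, `ci_low`, `ci_high`, `p_raw`,
#'   `p_adjusted`, `n_used`, `df_method`.
#' @export
contrasts_vs_reference <- function(models, spec = model_spec()) {
  models <- Filter(Negate(is.null), models)
  if (!length(models))
    return(.empty_comparison())
  rows <- lapply(models, function(pm) {
    tt <- .intervention_tests(pm, spec)
    alpha <- 1 - spec$level
    half <- qt(1 - alpha / 2, tt$df) * tt$se
    est <- tt$est
    lo <- est - half; hi <- est + half
    type <- unname(spec$contrast_type[pm$poi])
    if (pm$log_scale) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
    data.frame(Analyte = pm$analyte, PoI = pm$poi,
               contrast = paste(tt$test, "vs", pm$reference),
               type = type, estimate = est, ci_low = lo, ci_high = hi,
               p_raw = tt$p, p_adjusted = NA_real_, n_used = pm$n_used,
               df = tt$df, df_method = tt$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (poi in unique(out$PoI)) {
    i <- out$PoI == poi
    out$p_adjusted[i] <- p.adjust(out$p_raw[i], method = spec$adjust)
  }
  rownames(out) <- NULL
  class(out) <- c("poi_comparison", "data.frame")
  out
}

.empty_comparison <- function() {
  structure(data.frame(Analyte = character(), PoI = character(),
                       contrast = character(), type = character(),
                       estimate = numeric(), ci_low = numeric(),
                       ci_high = numeric(), p_raw = numeric(),
                       p_adjusted = numeric(), n_used = integer(),
                       df = numeric(), df_method = character()),
            class = c("poi_comparison", "data.frame"))
}

#' Compare all test interventions against the reference
#'
#' Fits the per-analyte, per-PoI mixed models and assembles the full
#' contrast table.  The workhorse of the final analysis stage.
#'
#' @param pois a `poi_table` (curated, optionally imputed).
#' @param reference reference intervention label.
#' @param spec a [model_spec()].
#' @param pois_to_compare PoIs to analyse (default all three).
#' @return A `poi_comparison` data frame, see
#'   [contrasts_vs_reference()].
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_design(seed = 7))
#' fits <- fit_all(sim$table, n_starts = 25, seed = 7)
#' pois <- curate_pois(extract_pois(fits), fits)$pois
#' compare_pois(pois, reference = reference_intervention(sim$table))
#' }
#' @export
compare_pois <- function(pois, reference, spec = model_spec(),
                         pois_to_compare = c("AUC", "Height",
                                             "Time2Max")) {
  models <- list()
  for (an in unique(pois$Analyte))
    for (poi in pois_to_compare)
      models[[paste(an, poi)]] <-
        fit_poi_model(pois, poi, an, reference, spec)
  contrasts_vs_reference(models, spec)
}

#' Per-intervention summary of PoIs
#'
#' Count, mean and standard deviation of the non-missing values of each
#' PoI per analyte and intervention.
#'
#' @param pois a `poi_table`.
#' @return Data frame: `Analyte`, `PoI`, `Intervention`, `n`, `mean`,
#'   `sd` (`sd` is `NA` for single values, `mean` for empty cells).
#' @export
summarize_pois <- function(pois) {
  df <- as.data.frame(pois)
  cells <- unique(df[c("Analyte", "Intervention")])
  rows <- list()
  for (i in seq_len(nrow(cells)))
    for (poi in c("AUC", "Height", "Time2Max")) {
      v <- df[df$Analyte == cells$Analyte[i] &
              df$Intervention == cells$Intervention[i], poi]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        Analyte = cells$Analyte[i], PoI = poi,
        Intervention = cells$Intervention[i], n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$Analyte, out$PoI, out$Intervention), , drop = FALSE]
}
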