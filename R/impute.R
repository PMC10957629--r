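#' Quantile-spread features of the raw time courses
#'
#' For every (participant, intervention, analyte) series, the 0.2 and
#' 0.8 quantiles of the non-missing raw values and their difference —
#' a robust estimate of the spread of the time course, and the sole
#' predictor used for non-responder imputation.  Quantiles use linear
#' interpolation between order statistics (R type 7), fixed across the
#' package for reproducibility.
#'
#' @param table a [study_table()].
#' @return Data frame with one row per series: keys, `q20`, `q80`,
#'   `spread`, `n_obs`.  Series with fewer than 2 observed values get
#'   `NA` features.
#' @export
spread_features <- function(table) {
  df <- as.data.frame(table)
  keys <- c("Participant", "Intervention", "Analyte")
  split_idx <- split(seq_len(nrow(df)), df[keys], drop = TRUE)
  rows <- lapply(split_idx, function(ix) {
    v <- df$Value[ix]
    v <- v[is.finite(v)]
    q <- if (length(v) >= 2) quantile(v, c(0.2, 0.8), names = FALSE,
                                      type = 7)
         else c(NA_real_, NA_real_)
    data.frame(df[ix[1], keys], q20 = q[1], q80 = q[2],
               spread = q[2] - q[1], n_obs = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$Participant, out$Intervention, out$Analyte), ,
      drop = FALSE]
}

#' Impute non-responder AUC and Height from the raw-data spread
#'
#' Missing PoIs can reflect genuine non-response: no measurable uptake,
#' hence no peak to fit.  For those series a low estimate is more
#' truthful than a missing value.  Per analyte and per target PoI, a
#' simple least-squares regression of the observed PoI on the
#' 0.2/0.8-quantile spread is trained on the responders and used to
#' predict the missing values, floored at 0.  Time2Max is never imputed
#' (without a peak there is no maximum to locate).
#'
#' A missing value is classified as non-response — rather than a
#' data-quality casualty — when its raw spread is below
#' `spread_fraction` times the median responder spread for that
#' analyte.  Observed PoIs are never altered.
#'
#' @param pois a `poi_table` (usually curated).
#' @param features spread features from [spread_features()].
#' @param targets subset of `c("AUC", "Height")`.
#' @param min_responders minimum responder series per analyte to train
#'   the regression (default 3); analytes below it are skipped with a
#'   warning.
#' @param spread_fraction non-response classification threshold as a
#'   fraction of the median responder spread (default 0.5).
#' @return List with `pois` (the imputed `poi_table`; imputed entries
#'   flagged `imputed_auc` / `imputed_height`) and `report` (one row
#'   per imputed value: keys, `target`, `spread`, `imputed`,
#'   `intercept`, `slope`, `n_responders`).
#' @export
impute_pois <- function(pois, features, targets = c("AUC", "Height"),
                        min_responders = 3, spread_fraction = 0.5) {
  targets <- match.arg(targets, c("AUC", "Height"), several.ok = TRUE)
  out <- pois
  key_p <- do.call(paste, c(pois[c("Participant", "Intervention",
                                   "Analyte")], sep = "\r"))
  key_f <- do.call(paste, c(features[c("Participant", "Intervention",
                                       "Analyte")], sep = "\r"))
  spread <- features$spread[match(key_p, key_f)]
  rep_rows <- list()
  for (an in unique(pois$Analyte)) {
    in_an <- pois$Analyte == an
    for (target in targets) {
      v <- pois[[target]]
      resp <- in_an & is.finite(v) & is.finite(spread)
      n_resp <- sum(resp)
      if (n_resp < min_responders) {
        warning("analyte '", an, "': only ", n_resp,
                " responders; ", target, " not imputed")
        next
      }
      med_spread <- median(spread[resp])
      cand <- which(in_an & !is.finite(v) & is.finite(spread) &
                      spread < spread_fraction * med_spread)
      if (!length(cand)) next
      fit <- lm(y ~ x, data = data.frame(y = v[resp], x = spread[resp]))
      cf <- coef(fit)
      if (is.na(cf[2])) cf[2] <- 0  # constant spread among responders
      pred <- pmax(cf[1] + cf[2] * spread[cand], 0)
      out[[target]][cand] <- unname(pred)
      flag <- paste0("imputed_", tolower(target))
      out$flags[cand] <- ifelse(out$flags[cand] == "", flag,
                                paste(out$flags[cand], flag, sep = ";"))
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        pois[cand, c("Participant", "Intervention", "Analyte")],
        target = target, spread = spread[cand], imputed = unname(pred),
        intercept = unname(cf[1]), slope = unname(cf[2]),
        n_responders = n_resp, stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows)
            else data.frame(Participant = character(),
                            Intervention = character(),
                            Analyte = character(), target = character(),
                            spread = numeric(), imputed = numeric(),
                            intercept = numeric(), slope = numeric(),
                            n_responders = integer())
  rownames(report) <- NULL
  list(pois = out, report = report)
}
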