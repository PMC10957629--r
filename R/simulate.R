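# population curve parameters for the default design: nine essential
# amino acids at realistic fasting baselines (umol/L) with reference
# peak heights of roughly 20-50% of baseline, peaking around 35 min;
# test interventions peak later (45 / 55 min) and somewhat lower,
# emulating slower, less complete uptake.
.default_truth <- function(interventions, analytes, reference) {
  base <- c(His = 80, Ile = 65, Leu = 130, Lys = 180, Met = 25,
            Phe = 60, Thr = 140, Trp = 55, Val = 230)
  hgt <- c(His = 25, Ile = 60, Leu = 120, Lys = 120, Met = 15,
           Phe = 20, Thr = 50, Trp = 25, Val = 120)
  n <- length(analytes)
  # match known amino acids by name; recycle over the table otherwise
  idx <- match(analytes, names(base))
  idx[is.na(idx)] <- ((which(is.na(idx)) - 1) %% length(base)) + 1
  d <- unname(base[idx])
  H <- unname(hgt[idx])
  tests <- setdiff(interventions, reference)
  mm <- setNames(rep(35, length(interventions)), interventions)
  hh <- setNames(rep(1, length(interventions)), interventions)
  if (length(tests) >= 1) { mm[tests[1]] <- 45; hh[tests[1]] <- 0.85 }
  if (length(tests) >= 2) { mm[tests[2]] <- 55; hh[tests[2]] <- 0.70 }
  out <- expand.grid(Intervention = interventions, Analyte = analytes,
                     stringsAsFactors = FALSE)
  out$m <- mm[out$Intervention]
  out$c <- 0.04
  out$d <- d[match(out$Analyte, analytes)]
  A <- H[match(out$Analyte, analytes)] * hh[out$Intervention]
  out$a <- wood_a_from_height(A, out$m, out$c)
  out
}

#' Design of a synthetic crossover uptake study
#'
#' Describes a complete generative model for a postprandial crossover
#' trial: 12 participants receiving 3 protein interventions (one
#' reference) across 3 periods in a balanced Latin-square rotation, 10
#' sampling times within 3 hours, and 9 essential amino acids — the
#' typical design of such studies.  Participant heterogeneity enters as
#' an additive Gaussian baseline shift and a multiplicative log-normal
#' amplitude shift per participant x analyte; measurement noise is
#' additive Gaussian on the concentration scale.
#'
#' @param n_participants number of participants (default 12).
#' @param interventions intervention labels; the first is the reference
#'   unless `reference` says otherwise.
#' @param reference reference intervention label.
#' @param n_periods number of periods (default: one per intervention).
#' @param times sampling grid in minutes.
#' @param analytes analyte labels (default the 9 essential amino
#'   acids).
#' @param true_params population curve parameters: data frame with
#'   columns `Intervention`, `Analyte`, `a`, `m`, `c`, `d`; default a
#'   realistic built-in table.
#' @param baseline_sd sd of the participant baseline shift (umol/L).
#' @param log_amp_sd sd of the participant log-amplitude shift.
#' @param noise_sd residual measurement sd (umol/L).
#' @param period_effect additive shift per period (scalar per-period
#'   step or vector of length `n_periods`; default 0).
#' @param nonresponse_rate probability that a participant x analyte
#'   series has near-zero amplitude across all interventions.
#' @param seed integer seed.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_participants = 12,
                       interventions = c("REF", "TESTA", "TESTB"),
                       reference = interventions[1],
                       n_periods = length(interventions),
                       times = c(0, 15, 30, 45, 60, 75, 90, 120, 150,
                                 180),
                       analytes = c("His", "Ile", "Leu", "Lys", "Met",
                                    "Phe", "Thr", "Trp", "Val"),
                       true_params = NULL,
                       baseline_sd = 8, log_amp_sd = 0.15,
                       noise_sd = 5, period_effect = 0,
                       nonresponse_rate = 0, seed = 1) {
  stopifnot(n_participants >= 1, length(interventions) >= 1,
            reference %in% interventions,
            n_periods <= length(interventions),
            baseline_sd >= 0, log_amp_sd >= 0, noise_sd >= 0,
            nonresponse_rate >= 0, nonresponse_rate <= 1)
  if (is.null(true_params))
    true_params <- .default_truth(interventions, analytes, reference)
  need <- expand.grid(Intervention = interventions, Analyte = analytes,
                      stringsAsFactors = FALSE)
  key_n <- paste(need$Intervention, need$Analyte)
  key_t <- paste(true_params$Intervention, true_params$Analyte)
  if (!all(key_n %in% key_t))
    stop("true_params must cover every intervention x analyte")
  if (length(period_effect) == 1)
    period_effect <- period_effect * (seq_len(n_periods) - 1)
  stopifnot(length(period_effect) == n_periods)
  structure(list(n_participants = n_participants,
                 interventions = interventions, reference = reference,
                 n_periods = n_periods, times = times,
                 analytes = analytes, true_params = true_params,
                 baseline_sd = baseline_sd, log_amp_sd = log_amp_sd,
                 noise_sd = noise_sd, period_effect = period_effect,
                 nonresponse_rate = nonresponse_rate,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Synthetic crossover design: ", x$n_participants,
      " participants x ", length(x$interventions),
      " interventions (reference ", x$reference, ") x ",
      length(x$times), " times x ", length(x$analytes),
      " analytes; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a crossover study with known ground truth
#'
#' Generates concentrations as Wood curves plus Gaussian noise under
#' the design's balanced rotation (participant i receives intervention
#' `(i + period) mod k` so Period and Intervention are orthogonal).
#' Per participant x analyte, the baseline `d` is shifted by
#' `N(0, baseline_sd)` (truncated so d >= 0) and the amplitude `a` is
#' scaled by `exp(N(0, log_amp_sd))`; with probability
#' `nonresponse_rate` the amplitude of the whole participant x analyte
#' series is multiplied by 0.02, emulating a non-responder.  Fully
#' reproducible from the design seed.
#'
#' @param design a [sim_design()].
#' @return List with `table` (a [study_table()]) and `truth` (one row
#'   per participant x intervention x analyte: realized curve
#'   parameters, true `AUC` up to the last sampling time, `Height`,
#'   `Time2Max`, and a `nonresponder` flag).
#' @examples
#' sim <- simulate_study(sim_design(seed = 42))
#' nrow(sim$table)   # 12 * 3 * 10 * 9 = 3240
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  d <- design
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(d$seed)

  participants <- sprintf("P%02d", seq_len(d$n_participants))
  k <- length(d$interventions)
  tp_key <- paste(d$true_params$Intervention, d$true_params$Analyte)

  n_an <- length(d$analytes)
  base_shift <- matrix(rnorm(d$n_participants * n_an, 0, d$baseline_sd),
                       d$n_participants, n_an)
  amp_shift <- matrix(exp(rnorm(d$n_participants * n_an, 0,
                                d$log_amp_sd)),
                      d$n_participants, n_an)
  nonresp <- matrix(runif(d$n_participants * n_an) < d$nonresponse_rate,
                    d$n_participants, n_an)

  recs <- list(); truth <- list()
  for (i in seq_len(d$n_participants)) {
    for (per in seq_len(d$n_periods)) {
      iv <- d$interventions[((i - 1 + per - 1) %% k) + 1]
      for (j in seq_len(n_an)) {
        an <- d$analytes[j]
        tp <- d$true_params[match(paste(iv, an), tp_key), ]
        a_i <- tp$a * amp_shift[i, j] * if (nonresp[i, j]) 0.02 else 1
        d_i <- max(tp$d + base_shift[i, j], 0)
        p_i <- wood_params(a_i, tp$m, tp$c, d_i)
        mu <- wood_eval(p_i, d$times) + d$period_effect[per]
        y <- mu + rnorm(length(d$times), 0, d$noise_sd)
        recs[[length(recs) + 1L]] <- data.frame(
          Participant = participants[i], Period = per,
          Intervention = iv, Time = d$times, Analyte = an, Value = y,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          Participant = participants[i], Intervention = iv,
          Analyte = an, a = a_i, m = tp$m, c = tp$c, d = d_i,
          b = tp$m * tp$c,
          AUC = poi_auc(p_i, max(d$times)),
          Height = poi_height(p_i),
          Time2Max = poi_time2max(p_i),
          nonresponder = nonresp[i, j], stringsAsFactors = FALSE)
      }
    }
  }
  table <- study_table(do.call(rbind, recs), reference = d$reference,
                       roster = d$analytes)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(table = table, truth = truth)
}

#' Null version of a design: no intervention effect
#'
#' Returns the design with every intervention's true curve parameters
#' replaced by the reference intervention's, so all true AUC ratios are
#' 1 and all true Height / Time2Max differences are 0.  Used for
#' type-I-error and coverage studies.
#'
#' @param design a [sim_design()].
#' @return A [sim_design()] under the global null.
#' @export
null_design <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  tp <- design$true_params
  key <- paste(design$reference, tp$Analyte)
  ref_rows <- match(key, paste(tp$Intervention, tp$Analyte))
  tp[c("a", "m", "c", "d")] <- tp[ref_rows, c("a", "m", "c", "d")]
  design$true_params <- tp
  design
}

#' Derive an effect scenario from a base design
#'
#' Scales the amplitude `a` of one test intervention so that its true
#' AUC equals `auc_ratio` times the reference AUC for every analyte
#' (AUC is linear in `a`, so the scaling is exact).  Alternatively a
#' target height difference can be requested; since Height is also
#' linear in `a` with the shape fixed, the two constraints conflict
#' unless consistent — the AUC ratio wins and the realized height
#' difference is whatever the scaled parameters imply (readable from
#' the returned design's `true_params`).
#'
#' @param base a [sim_design()].
#' @param auc_ratio desired true AUC ratio test/reference (> 0), or
#'   `NULL` to leave AUC alone.
#' @param height_diff desired true Height difference (test minus
#'   reference), used only when `auc_ratio` is `NULL`.
#' @param intervention which test intervention to modify (default the
#'   first non-reference label).
#' @param t_f AUC integration limit for the ratio (default the last
#'   sampling time).
#' @return A [sim_design()] with adjusted `true_params`.
#' @export
simulate_effect_scenario <- function(base, auc_ratio = NULL,
                                     height_diff = NULL,
                                     intervention = NULL,
                                     t_f = max(base$times)) {
  stopifnot(inherits(base, "sim_design"))
  tests <- setdiff(base$interventions, base$reference)
  if (!length(tests)) stop("design has no test intervention")
  if (is.null(intervention)) intervention <- tests[1]
  stopifnot(intervention %in% tests)
  if (!is.null(auc_ratio) && (!is.finite(auc_ratio) || auc_ratio <= 0))
    stop("'auc_ratio' must be > 0")
  tp <- base$true_params
  for (an in base$analytes) {
    i_ref <- which(tp$Intervention == base$reference & tp$Analyte == an)
    i_tst <- which(tp$Intervention == intervention & tp$Analyte == an)
    p_ref <- wood_params(tp$a[i_ref], tp$m[i_ref], tp$c[i_ref],
                         tp$d[i_ref])
    p_tst <- wood_params(tp$a[i_tst], tp$m[i_tst], tp$c[i_tst],
                         tp$d[i_tst])
    if (!is.null(auc_ratio)) {
      target <- auc_ratio * poi_auc(p_ref, t_f)
      tp$a[i_tst] <- tp$a[i_tst] * target / poi_auc(p_tst, t_f)
      if (!is.null(height_diff)) {
        realized <- poi_height(wood_params(tp$a[i_tst], tp$m[i_tst],
                                           tp$c[i_tst], tp$d[i_tst])) -
          poi_height(p_ref)
        if (abs(realized - height_diff) > 1e-8 * max(1, abs(height_diff)))
          message("analyte ", an, ": AUC constraint honoured; ",
                  "realized height difference ",
                  format(realized, digits = 4))
      }
    } else if (!is.null(height_diff)) {
      target <- poi_height(p_ref) + height_diff
      if (target <= 0)
        stop("height_diff would make the true height non-positive")
      tp$a[i_tst] <- tp$a[i_tst] * target / poi_height(p_tst)
    }
  }
  out <- base
  out$true_params <- tp
  out
}
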