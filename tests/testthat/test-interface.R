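make_small_sim <- function(seed = 31) {
  simulate_study(sim_design(n_participants = 6,
                            analytes = c("Leu", "Val", "Met"),
                            seed = seed))
}

test_that("time-course panels render and write image files", {
  sim <- make_small_sim()
  f <- file.path(tempdir(), "tc.png")
  out <- plot_timecourses(sim$table, participants = c("P01", "P02"),
                          file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  fits <- fit_all(sim$table[sim$table$Participant %in%
                              c("P01", "P02"), ],
                  n_starts = 8, seed = 31)
  obj <- plot_timecourses(sim$table, participants = c("P01", "P02"),
                          fits = fits)
  expect_s3_class(obj, "trellis")
  expect_error(plot_timecourses(sim$table, participants = "P99"),
               "unknown participant")
  expect_error(plot_timecourses(sim$table, analytes = "Xyz"),
               "unknown analyte")
})

test_that("PCA arrangements yield the documented row counts", {
  sim <- simulate_study(sim_design(seed = 13))
  pc_pi <- pca_scores(sim$table, "per-participant-intervention")
  expect_equal(nrow(pc_pi$scores), 36)     # 12 participants x 3 meals
  pc_p <- pca_scores(sim$table, "per-participant")
  expect_equal(nrow(pc_p$scores), 12)
  pc_s <- pca_scores(sim$table, "per-series")
  expect_equal(nrow(pc_s$scores), 12 * 3 * 9)
  f <- file.path(tempdir(), "pca.png")
  plot(pc_pi, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("PCA scores match a spectral-decomposition oracle", {
  sim <- make_small_sim(5)
  pc <- pca_scores(sim$table, "per-participant-intervention",
                   centering = "row")
  # oracle: rebuild the row-centered matrix and eigen-decompose
  df <- as.data.frame(sim$table)
  rk <- paste(df$Participant, df$Intervention, sep = "\r")
  ck <- paste(df$Analyte, df$Time, sep = "\r")
  mat <- tapply(df$Value, list(rk, ck), mean)
  mat <- sweep(mat, 1, rowMeans(mat))
  matc <- sweep(mat, 2, colMeans(mat))
  ev <- eigen(crossprod(matc) / (nrow(matc) - 1))
  scores_oracle <- matc %*% ev$vectors
  for (j in 1:3) {
    r <- cor(pc$scores[, j], scores_oracle[, j])
    expect_equal(abs(r), 1, tolerance = 1e-8)   # up to sign
    expect_equal(sd(pc$scores[, j]), sd(scores_oracle[, j]),
                 tolerance = 1e-8)
  }
  expect_error(pca_scores(sim$table[1:20, ]), "at least 3 rows")
})

test_that("PCA mean-fills missing cells with a warning", {
  sim <- make_small_sim(6)
  tab <- sim$table
  tab$Value[5] <- NA
  expect_warning(pc <- pca_scores(tab), "filled")
  expect_false(anyNA(pc$scores))
})

test_that("PoI dot plot shows curated values only on the curated side", {
  sim <- make_small_sim(7)
  fits <- fit_all(sim$table, n_starts = 8, seed = 7)
  pois <- extract_pois(fits)
  cur <- curate_pois(pois, fits)
  f <- file.path(tempdir(), "dot.png")
  plot_poi_dotplot(pois, cur$pois, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  empty <- pois; empty$AUC <- empty$Height <- empty$Time2Max <- NA_real_
  expect_warning(plot_poi_dotplot(empty, empty), "no finite")
})

test_that("forest plot highlights intervals that exclude the null", {
  res <- data.frame(Analyte = c("Leu", "Val"), PoI = "AUC",
                    contrast = "TEST vs REF", type = "ratio",
                    estimate = c(1.3, 1.1), ci_low = c(1.1, 0.9),
                    ci_high = c(1.5, 1.3), p_raw = c(0.01, 0.4),
                    p_adjusted = c(0.02, 0.4), n_used = 24,
                    df = 10, df_method = "kenward-roger",
                    stringsAsFactors = FALSE)
  class(res) <- c("poi_comparison", "data.frame")
  f <- file.path(tempdir(), "forest.pdf")
  plot_forest(res, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # the highlight rule itself: CI excluding 1 for ratios
  expect_true(res$ci_low[1] > 1)        # highlighted
  expect_true(res$ci_low[2] < 1 && res$ci_high[2] > 1)  # not
  expect_error(plot_forest(res[0, ]), "empty")
})

test_that("the pipeline writes a complete, reproducible run directory", {
  sim <- simulate_study(sim_design(n_participants = 6,
                                   analytes = c("Leu", "Val"),
                                   seed = 15))
  input <- file.path(tempdir(), "study_in.csv")
  write_study(sim$table, input)
  run_once <- function(dir) {
    cfg <- pipeline_config(
      input = input, outdir = dir, reference = "REF", seed = 15,
      n_starts = 8, plots = FALSE,
      model = model_spec(df_method = "satterthwaite"))
    run_pipeline(cfg)
  }
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  r1 <- run_once(d1); r2 <- run_once(d2)
  need <- c("study_long.csv", "validation.csv", "fits.csv",
            "pois_uncurated.csv", "pois_curated.csv",
            "curation_report.csv", "pois_imputed.csv",
            "imputation_report.csv", "results_responders.csv",
            "results_imputed.csv", "summary_pois.csv", "run_log.txt")
  for (f in need) expect_true(file.exists(file.path(d1, f)), label = f)
  for (f in setdiff(need, "run_log.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_equal(nrow(r1$fits), 6 * 3 * 2)
  expect_equal(nrow(r1$results), 2 * 3 * 2)  # 2 tests x 3 PoIs x 2 analytes
})

test_that("disabling imputation yields a responders-only run", {
  sim <- simulate_study(sim_design(n_participants = 6,
                                   analytes = "Leu", seed = 16))
  input <- file.path(tempdir(), "study_in2.csv")
  write_study(sim$table, input)
  dir <- file.path(tempdir(), "run_noimp")
  cfg <- pipeline_config(input = input, outdir = dir,
                         reference = "REF", seed = 16, n_starts = 8,
                         impute = FALSE, plots = FALSE,
                         model = model_spec(df_method = "satterthwaite"))
  res <- run_pipeline(cfg)
  expect_null(res$imputation)
  expect_false(file.exists(file.path(dir, "imputation_report.csv")))
  expect_true(all(res$results$analysis == "responders-only"))
})

test_that("YAML configuration round-trips into a pipeline config", {
  yml <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("reference: REF",
               "seed: 3",
               "n_starts: 10",
               "curation:",
               "  Height: [0, 2000]",
               "model:",
               "  include_period: false",
               "  adjust: bonferroni"), yml)
  cfg <- read_pipeline_config(yml)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$n_starts, 10)
  expect_equal(cfg$curation$Height, c(0, 2000))
  expect_false(cfg$model$include_period)
  expect_equal(cfg$model$adjust, "bonferroni")
})

test_that("manual exclusions blank the listed measurements", {
  sim <- simulate_study(sim_design(n_participants = 6,
                                   analytes = "Leu", seed = 17))
  input <- file.path(tempdir(), "study_in3.csv")
  write_study(sim$table, input)
  drop <- data.frame(Participant = "P01", Intervention = "REF",
                     Analyte = "Leu", Time = 30)
  dir <- file.path(tempdir(), "run_drop")
  cfg <- pipeline_config(input = input, outdir = dir,
                         reference = "REF", seed = 17, n_starts = 8,
                         drop = drop, impute = FALSE, plots = FALSE,
                         model = model_spec(df_method = "satterthwaite"))
  res <- run_pipeline(cfg)
  v <- res$table$Value[res$table$Participant == "P01" &
                       res$table$Intervention == "REF" &
                       res$table$Time == 30]
  expect_true(all(is.na(v)))
})
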