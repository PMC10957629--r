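test_that("spread features follow the fixed quantile definition", {
  df <- expand.grid(Participant = "P1", Period = 1L,
                    Intervention = "REF", Time = seq(0, 90, by = 10),
                    Analyte = "Leu", stringsAsFactors = FALSE)
  df$Value <- seq(0, 90, by = 10)
  tab <- study_table(df, reference = "REF")
  sf <- spread_features(tab)
  # type-7 quantiles of 0,10,...,90: q20 = 18, q80 = 72
  expect_equal(sf$q20, 18)
  expect_equal(sf$q80, 72)
  expect_equal(sf$spread, 54)
  # constant series has zero spread
  df$Value <- 100
  expect_equal(spread_features(study_table(df, reference = "REF"))$spread,
               0)
  # missing values excluded; < 2 observed values -> NA features
  df$Value <- c(100, NA, 200, rep(NA, 7))
  sf2 <- spread_features(study_table(df, reference = "REF"))
  expect_equal(sf2$n_obs, 2L)
  expect_equal(sf2$spread, 0.6 * 100)   # quantiles of {100, 200}
  df$Value <- c(100, rep(NA, 9))
  sf3 <- spread_features(study_table(df, reference = "REF"))
  expect_true(is.na(sf3$spread))
})

test_that("imputation reproduces the closed-form regression prediction", {
  # responders lie exactly on AUC = 50 * spread
  feats <- data.frame(Participant = sprintf("P%d", 1:7),
                      Intervention = "REF", Analyte = "Leu",
                      q20 = 0, q80 = c(10, 20, 30, 40, 50, 2, 60),
                      spread = c(10, 20, 30, 40, 50, 2, 60),
                      n_obs = 10, stringsAsFactors = FALSE)
  pois <- data.frame(Participant = sprintf("P%d", 1:7),
                     Intervention = "REF", Analyte = "Leu",
                     AUC = c(500, 1000, 1500, 2000, 2500, NA, NA),
                     Height = c(5, 10, 15, 20, 25, NA, NA),
                     Time2Max = NA_real_, t_f = 180, flags = "",
                     stringsAsFactors = FALSE)
  class(pois) <- c("poi_table", "data.frame")
  imp <- impute_pois(pois, feats)
  # spread 2 < 0.5 * median responder spread (30) -> imputed at 100
  expect_equal(imp$pois$AUC[6], 50 * 2, tolerance = 1e-8)
  expect_equal(imp$pois$Height[6], 0.5 * 2, tolerance = 1e-8)
  # spread 60 is not a non-responder -> left missing
  expect_true(is.na(imp$pois$AUC[7]))
  # Time2Max is never imputed
  expect_true(all(is.na(imp$pois$Time2Max)))
  # observed values are untouched, bit for bit
  expect_identical(imp$pois$AUC[1:5], pois$AUC[1:5])
  expect_match(imp$pois$flags[6], "imputed_auc")
  expect_equal(imp$report$slope[imp$report$target == "AUC"], 50,
               tolerance = 1e-8)
})

test_that("a constant responder PoI imputes that constant", {
  feats <- data.frame(Participant = sprintf("P%d", 1:5),
                      Intervention = "REF", Analyte = "Leu",
                      q20 = 0, q80 = c(10, 20, 30, 40, 1),
                      spread = c(10, 20, 30, 40, 1), n_obs = 10,
                      stringsAsFactors = FALSE)
  pois <- data.frame(Participant = sprintf("P%d", 1:5),
                     Intervention = "REF", Analyte = "Leu",
                     AUC = c(777, 777, 777, 777, NA),
                     Height = 10, Time2Max = 40, t_f = 180,
                     flags = "", stringsAsFactors = FALSE)
  class(pois) <- c("poi_table", "data.frame")
  imp <- impute_pois(pois, feats, targets = "AUC")
  expect_equal(imp$pois$AUC[5], 777, tolerance = 1e-8)
})

test_that("too few responders leaves values missing with a warning", {
  feats <- data.frame(Participant = c("P1", "P2"),
                      Intervention = "REF", Analyte = "Leu",
                      q20 = 0, q80 = c(30, 1), spread = c(30, 1),
                      n_obs = 10, stringsAsFactors = FALSE)
  pois <- data.frame(Participant = c("P1", "P2"),
                     Intervention = "REF", Analyte = "Leu",
                     AUC = c(1000, NA), Height = c(10, NA),
                     Time2Max = c(40, NA), t_f = 180, flags = "",
                     stringsAsFactors = FALSE)
  class(pois) <- c("poi_table", "data.frame")
  expect_warning(imp <- impute_pois(pois, feats, targets = "AUC"),
                 "responders")
  expect_true(is.na(imp$pois$AUC[2]))
})

test_that("imputation error shrinks with more responders", {
  gen <- function(n, seed) {
    set.seed(seed)
    spread <- runif(n + 5, 5, 50)
    auc <- 40 * spread + rnorm(n + 5, 0, 30)
    feats <- data.frame(Participant = sprintf("P%d", seq_len(n + 5)),
                        Intervention = "REF", Analyte = "Leu",
                        q20 = 0, q80 = spread, spread = spread,
                        n_obs = 10, stringsAsFactors = FALSE)
    # last 5 are non-responders with tiny spread and known truth
    feats$spread[n + 1:5] <- runif(5, 0.5, 2)
    truth <- 40 * feats$spread[n + 1:5]
    pois <- data.frame(feats[c("Participant", "Intervention",
                               "Analyte")],
                       AUC = c(auc[seq_len(n)], rep(NA, 5)),
                       Height = 1, Time2Max = 40, t_f = 180,
                       flags = "", stringsAsFactors = FALSE)
    class(pois) <- c("poi_table", "data.frame")
    imp <- impute_pois(pois, feats, targets = "AUC")
    mean(abs(imp$pois$AUC[n + 1:5] - truth))
  }
  err_small <- mean(vapply(1:8, function(s) gen(10, s), numeric(1)))
  err_large <- mean(vapply(1:8, function(s) gen(100, s + 100),
                           numeric(1)))
  expect_lt(err_large, err_small)
})
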