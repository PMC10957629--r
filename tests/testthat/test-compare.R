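test_that("deterministic multiplicative data give an exact ratio", {
  pois <- expand.grid(Participant = sprintf("P%02d", 1:6),
                      Intervention = c("REF", "TEST"),
                      stringsAsFactors = FALSE)
  pois$Analyte <- "Leu"
  pois$Period <- rep(1:2, each = 6)
  base <- rep(c(100, 120, 140, 160, 180, 200), 2)
  pois$AUC <- ifelse(pois$Intervention == "TEST", 2, 1) * base
  pois$Height <- base + 10 * (pois$Intervention == "TEST")
  pois$Time2Max <- 40
  pois$t_f <- 180; pois$flags <- ""
  class(pois) <- c("poi_table", "data.frame")
  res <- suppressWarnings(
    compare_pois(pois, "REF", model_spec(include_period = FALSE)))
  auc <- res[res$PoI == "AUC", ]
  expect_equal(auc$estimate, 2, tolerance = 1e-6)
  expect_lt(auc$ci_high - auc$ci_low, 1e-5)
  hgt <- res[res$PoI == "Height", ]
  expect_equal(hgt$estimate, 10, tolerance = 1e-6)
  t2m <- res[res$PoI == "Time2Max", ]
  expect_equal(t2m$estimate, 0, tolerance = 1e-8)
})

test_that("ratio contrasts equal exponentiated log-scale differences", {
  pois <- toy_poi_table(n_part = 10, ratio = 0.8, seed = 2)
  spec <- model_spec(df_method = "satterthwaite")
  res <- compare_pois(pois, "REF", spec, pois_to_compare = "AUC")
  pm <- fit_poi_model(pois, "AUC", "Leu", "REF", spec)
  logdiff <- lme4::fixef(pm$model)[["InterventionTEST"]]
  expect_equal(res$estimate, exp(logdiff), tolerance = 1e-12)
  expect_true(res$type == "ratio")
  expect_gt(res$estimate, 0)
})

test_that("contrasts are equivariant under shift and scale", {
  pois <- toy_poi_table(n_part = 10, ratio = 0.9, seed = 3)
  spec <- model_spec(df_method = "satterthwaite")
  res <- compare_pois(pois, "REF", spec)
  shifted <- pois; shifted$Height <- shifted$Height + 500
  res_s <- compare_pois(shifted, "REF", spec)
  h <- res$PoI == "Height"
  expect_equal(res_s$estimate[h], res$estimate[h], tolerance = 1e-6)
  expect_equal(res_s$ci_low[h], res$ci_low[h], tolerance = 1e-5)
  scaled <- pois; scaled$AUC <- scaled$AUC * 7.3
  res_k <- compare_pois(scaled, "REF", spec)
  a <- res$PoI == "AUC"
  expect_equal(res_k$estimate[a], res$estimate[a], tolerance = 1e-9)
  expect_equal(res_k$p_raw[a], res$p_raw[a], tolerance = 1e-9)
})

test_that("Kenward-Roger and Satterthwaite agree on balanced data", {
  pois <- toy_poi_table(n_part = 12, ratio = 0.85, seed = 4)
  r_kr <- compare_pois(pois, "REF",
                       model_spec(df_method = "kenward-roger"))
  r_sa <- compare_pois(pois, "REF",
                       model_spec(df_method = "satterthwaite"))
  expect_equal(r_kr$estimate, r_sa$estimate, tolerance = 1e-8)
  expect_equal(r_kr$df, r_sa$df, tolerance = 0.1)
  expect_equal(r_kr$p_raw, r_sa$p_raw, tolerance = 1e-4)
})

test_that("contrast estimates match the estimated-marginal-means oracle", {
  skip_if_not_installed("emmeans")
  pois <- toy_poi_table(n_part = 10, ratio = 0.75, seed = 5)
  spec <- model_spec(df_method = "satterthwaite")
  res <- compare_pois(pois, "REF", spec, pois_to_compare = "AUC")
  pm <- fit_poi_model(pois, "AUC", "Leu", "REF", spec)
  em <- emmeans::emmeans(pm$model, "Intervention")
  ct <- as.data.frame(emmeans::contrast(em, "trt.vs.ctrl", ref = 1))
  expect_equal(res$estimate, exp(ct$estimate), tolerance = 1e-8)
  expect_equal(res$p_raw, ct$p.value, tolerance = 1e-4)
})

test_that("period fixed effect defaults in, and drops out harmlessly", {
  pois <- toy_poi_table(n_part = 12, ratio = 1, seed = 6)
  spec_p <- model_spec(df_method = "satterthwaite")
  spec_np <- model_spec(include_period = FALSE,
                        df_method = "satterthwaite")
  pm <- fit_poi_model(pois, "AUC", "Leu", "REF", spec_p)
  expect_true("Period2" %in% names(lme4::fixef(pm$model)))
  r1 <- compare_pois(pois, "REF", spec_p, pois_to_compare = "AUC")
  r2 <- compare_pois(pois, "REF", spec_np, pois_to_compare = "AUC")
  # no true period effect: estimates agree within simulation error
  expect_equal(r1$estimate, r2$estimate, tolerance = 0.05)
})

test_that("insufficient data is skipped; missing reference errors", {
  pois <- toy_poi_table(n_part = 2, seed = 7)
  expect_warning(res <- compare_pois(pois, "REF",
                                     pois_to_compare = "AUC"),
                 "not enough data")
  expect_equal(nrow(res), 0)
  pois2 <- toy_poi_table(n_part = 8, seed = 8)
  expect_error(suppressWarnings(
    fit_poi_model(pois2, "AUC", "Leu", "WHEY", model_spec())),
    "reference")
})

test_that("non-positive values are dropped before the log transform", {
  pois <- toy_poi_table(n_part = 8, seed = 9)
  pois$AUC[1] <- -5
  expect_warning(pm <- fit_poi_model(pois, "AUC", "Leu", "REF",
                                     model_spec()),
                 "non-positive")
  expect_equal(pm$n_used, nrow(pois) - 1)
})

test_that("Holm adjustment is applied within each PoI family", {
  pois <- rbind(toy_poi_table(n_part = 8, ratio = 0.8, seed = 10),
                toy_poi_table(n_part = 8, ratio = 0.9, seed = 11,
                              analyte = "Val"))
  class(pois) <- c("poi_table", "data.frame")
  res <- compare_pois(pois, "REF",
                      model_spec(df_method = "satterthwaite"))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  for (poi in unique(res$PoI)) {
    i <- res$PoI == poi
    expect_equal(res$p_adjusted[i],
                 p.adjust(res$p_raw[i], method = "holm"))
  }
})

test_that("summaries report count, mean and sd per cell", {
  pois <- data.frame(Participant = c("P1", "P2", "P3", "P1"),
                     Intervention = c("REF", "REF", "REF", "TEST"),
                     Analyte = "Leu",
                     AUC = c(1, 2, 3, 10), Height = c(5, NA, NA, 7),
                     Time2Max = c(NA, NA, NA, NA), t_f = 180,
                     flags = "", stringsAsFactors = FALSE)
  class(pois) <- c("poi_table", "data.frame")
  s <- summarize_pois(pois)
  auc_ref <- s[s$PoI == "AUC" & s$Intervention == "REF", ]
  expect_equal(auc_ref$n, 3); expect_equal(auc_ref$mean, 2)
  expect_equal(auc_ref$sd, 1)
  hgt_test <- s[s$PoI == "Height" & s$Intervention == "TEST", ]
  expect_equal(hgt_test$n, 1); expect_true(is.na(hgt_test$sd))
  t2m <- s[s$PoI == "Time2Max" & s$Intervention == "REF", ]
  expect_equal(t2m$n, 0); expect_true(is.na(t2m$mean))
})

test_that("an unbalanced deletion still yields a model fit", {
  pois <- toy_poi_table(n_part = 10, ratio = 0.8, seed = 12)
  res_full <- compare_pois(pois, "REF",
                           model_spec(df_method = "satterthwaite"),
                           pois_to_compare = "AUC")
  pois$AUC[3] <- NA   # delete one participant-intervention cell
  res_del <- compare_pois(pois, "REF",
                          model_spec(df_method = "satterthwaite"),
                          pois_to_compare = "AUC")
  expect_equal(res_del$n_used, res_full$n_used - 1)
  expect_equal(res_del$estimate, res_full$estimate, tolerance = 0.1)
})
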