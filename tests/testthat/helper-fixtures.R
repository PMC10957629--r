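# shared fixtures: small deterministic study tables and series built in
# code; fits in tests use few starts (clean synthetic data converges
# quickly and the multi-start default is exercised separately)

default_times <- c(0, 15, 30, 45, 60, 75, 90, 120, 150, 180)

make_series <- function(params, times = default_times, noise_sd = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wood_eval(params, times) + rnorm(length(times), 0, noise_sd)
}

# 2 participants x 1 period x 3 times x 2 analytes (12 records)
tiny_long <- function() {
  expand.grid(Participant = c("P1", "P2"), Period = 1L,
              Intervention = "REF", Time = c(0, 30, 60),
              Analyte = c("Leu", "Val"), stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE) |>
    transform(Value = 100 + Time / 10)
}

# draw valid Wood parameters spanning the plausible box
random_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- runif(1, 20, 120)
    cc <- exp(runif(1, log(0.01), log(0.1)))
    d <- runif(1, 20, 300)
    H <- exp(runif(1, log(10), log(300)))
    wood_params(a = postprandial:::wood_a_from_height(H, m, cc),
                m = m, c = cc, d = d)
  })
}

# a small fitted poi_table for comparison tests, built directly
toy_poi_table <- function(n_part = 8, ratio = 1, seed = 1,
                          analyte = "Leu") {
  set.seed(seed)
  df <- expand.grid(Participant = sprintf("P%02d", seq_len(n_part)),
                    Intervention = c("REF", "TEST"),
                    stringsAsFactors = FALSE)
  df$Analyte <- analyte
  # alternate the sequence so Period and Intervention are not confounded
  first_ref <- as.integer(factor(df$Participant)) %% 2 == 1
  df$Period <- ifelse(first_ref == (df$Intervention == "REF"), 1L, 2L)
  part_eff <- rnorm(n_part, 0, 0.2)[match(df$Participant,
                                          sprintf("P%02d",
                                                  seq_len(n_part)))]
  df$AUC <- exp(log(5000) + log(ratio) * (df$Intervention == "TEST") +
                  part_eff + rnorm(nrow(df), 0, 0.1))
  df$Height <- 100 + 10 * (df$Intervention == "TEST") +
    10 * part_eff + rnorm(nrow(df), 0, 3)
  df$Time2Max <- 40 + 5 * part_eff + rnorm(nrow(df), 0, 2)
  df$t_f <- 180
  df$flags <- ""
  class(df) <- c("poi_table", "data.frame")
  df
}
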