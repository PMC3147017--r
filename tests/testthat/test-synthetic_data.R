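test_that("noiseless ideal chase is exactly exponential", {
  truth <- ref_params()
  k_tot <- truth$K_Sec + truth$K_Deg + truth$K_Dil
  des <- experiment_design(truth, noise_cv = 0,
                           intracellular_background = 0,
                           sulfate_residual_init = 0, dropout_prob = 0,
                           replicates = 1, seed = 3)
  ser <- generate_experiment(des)$series
  intra <- ser[ser$compartment == "intracellular", ]
  expect_equal(intra$frac32, exp(-k_tot * intra$time_min),
               tolerance = 1e-12)
})

test_that("the impurity background adds on top of the true fraction", {
  truth <- ref_params()
  k_tot <- truth$K_Sec + truth$K_Deg + truth$K_Dil
  des <- experiment_design(truth, noise_cv = 0,
                           intracellular_background = 0.02,
                           sulfate_residual_init = 0, dropout_prob = 0,
                           replicates = 1, seed = 3)
  ex <- generate_experiment(des)
  ser <- ex$series
  intra <- ser[ser$compartment == "intracellular", ]
  # observations are clipped to [0, 1], which only affects t = 0 here
  expect_equal(intra$frac32,
               pmin(exp(-k_tot * intra$time_min) + 0.02, 1),
               tolerance = 1e-12)
  # extracellular observations carry no background
  extra <- ser[ser$compartment == "extracellular", ]
  expect_equal(extra$frac32, ex$truth$clean_fractions$frac_e,
               tolerance = 1e-12)
})

test_that("extracellular 32S fraction never falls below intracellular", {
  for (s in 1:5) {
    truth <- random_params(s)
    des <- experiment_design(truth, noise_cv = 0,
                             intracellular_background = 0,
                             dropout_prob = 0, replicates = 1,
                             seed = s)
    ser <- generate_experiment(des)$series
    fi <- ser$frac32[ser$compartment == "intracellular"]
    fe <- ser$frac32[ser$compartment == "extracellular"]
    expect_true(all(fe >= fi - 1e-12))
  }
})

test_that("media sulfate washes out from its residual and stays below 1%", {
  truth <- ref_params()
  des <- experiment_design(truth, noise_cv = 0, dropout_prob = 0,
                           replicates = 1, seed = 3)
  ser <- generate_experiment(des)$series
  media <- ser[ser$compartment == "media_small_molecule", ]
  expect_equal(media$frac32,
               0.01 * exp(-truth$K_Dil * media$time_min),
               tolerance = 1e-12)
  expect_true(all(media$frac32 <= 0.01))
})

test_that("generation is deterministic given the seed and varies across
           seeds and replicates", {
  truth <- ref_params()
  a <- generate_experiment(experiment_design(truth, seed = 11))
  b <- generate_experiment(experiment_design(truth, seed = 11))
  c <- generate_experiment(experiment_design(truth, seed = 12))
  expect_identical(a$series, b$series)
  expect_false(identical(a$series, c$series))
  expect_setequal(unique(a$series$replicate_id), c("R1", "R2"))
  r1 <- a$series[a$series$replicate_id == "R1" &
                   a$series$compartment == "intracellular", "frac32"]
  r2 <- a$series[a$series$replicate_id == "R2" &
                   a$series$compartment == "intracellular", "frac32"]
  expect_false(identical(r1[seq_len(min(length(r1), length(r2)))],
                         r2[seq_len(min(length(r1), length(r2)))]))
  expect_error(experiment_design(truth), "seed")
})

test_that("low observations are flagged against the limit of
           quantification", {
  truth <- ref_params()
  des <- experiment_design(truth, noise_cv = 0,
                           intracellular_background = 0,
                           sulfate_residual_init = 0, dropout_prob = 0,
                           replicates = 1, loq_frac32 = 0.005, seed = 3)
  ser <- generate_experiment(des)$series
  intra <- ser[ser$compartment == "intracellular", ]
  expect_identical(intra$below_loq, intra$frac32 < 0.005)
})

test_that("emit/read round-trips the series and the truth sidecar", {
  truth <- ref_params()
  ex <- generate_experiment(experiment_design(truth, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  paths <- emit_experiment(ex, path)
  back <- read_labeling_csv(path)
  expect_equal(back$frac32, ex$series$frac32, tolerance = 1e-12)
  expect_equal(back$time_min, ex$series$time_min)
  expect_identical(back$below_loq, ex$series$below_loq)
  expect_identical(back$replicate_id, ex$series$replicate_id)
  truth_back <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth_back$params$K_Sec, truth$K_Sec)
  expect_equal(truth_back$K_total, ex$truth$K_total)

  # header-only file round-trips too
  empty <- ex$series[0, ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_labeling_csv(empty, p2)
  expect_equal(nrow(read_labeling_csv(p2)), 0)
})

test_that("decay-CI calibration: 95% intervals cover the true K_tot at the
           nominal rate", {
  truth <- ref_params()
  k_tot <- truth$K_Sec + truth$K_Deg + truth$K_Dil
  covered <- vapply(1:200, function(i) {
    des <- experiment_design(truth, times = mc_times(),
                             intracellular_background = 0,
                             sulfate_residual_init = 0, dropout_prob = 0,
                             replicates = 1, seed = 5000 + i)
    ser <- generate_experiment(des)$series
    keep <- !(ser$compartment == "intracellular" & ser$time_min >= 140)
    rg <- fit_decay(transform_for_regression(ser[keep, ]))
    rg$ci95_lo <= -k_tot && -k_tot <= rg$ci95_hi
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
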