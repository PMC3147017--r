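test_that("constant background is subtracted from intracellular points", {
  ts <- rbind(
    make_series(c(20, 140, 200, 300), c(0.43, 0.03, 0.03, 0.03)),
    make_series(c(20, 200), c(0.50, 0.40), compartment = "extracellular"))
  out <- correct_background(ts)
  expect_equal(attr(out, "background")[["R1"]], 0.03)
  expect_equal(out$frac32[out$time_min == 20 &
                            out$compartment == "intracellular"], 0.40)
  # extracellular records untouched
  expect_equal(out$frac32[out$compartment == "extracellular"],
               c(0.50, 0.40))
})

test_that("zero post-cutoff signal leaves the series unchanged and the
           correction is idempotent on clean data", {
  ts <- make_series(c(0, 30, 60, 150, 200), c(1, 0.5, 0.25, 0, 0))
  once <- correct_background(ts)
  expect_equal(once$frac32, ts$frac32)
  twice <- correct_background(once)
  expect_equal(twice$frac32, once$frac32)
})

test_that("missing post-cutoff points refuse the correction loudly", {
  ts <- make_series(c(0, 30, 60), c(1, 0.5, 0.25))
  expect_error(correct_background(ts), "refused.*R1")
})

test_that("background correction recovers the decay constant from
           contaminated data", {
  k_true <- 0.025
  t_obs <- c(seq(0, 120, 10), seq(150, 480, 30))
  ts <- make_series(t_obs, 0.95 * exp(-k_true * t_obs) + 0.02)
  corrected <- correct_background(ts)
  keep <- corrected$time_min < 140
  fit_c <- fit_decay(transform_for_regression(corrected[keep, ]))
  expect_equal(fit_c$K_total, k_true, tolerance = 0.05)
  # uncorrected regression is biased low (background flattens the tail)
  fit_u <- fit_decay(transform_for_regression(ts[keep, ]))
  expect_lt(fit_u$K_total, 0.95 * k_true)
})

test_that("log transform normalizes by the earliest usable point and
           excludes untransformable ones", {
  ts <- make_series(c(0, 10, 20, 30, 40), c(0.5, 0.25, 0, 0.1, 0.125),
                    below_loq = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- transform_for_regression(ts)
  expect_equal(out$y, log(c(0.5, 0.25, 0.125) / 0.5))
  expect_equal(attr(out, "excluded")[["R1"]], 2)

  same <- make_series(c(0, 10, 20), rep(0.3, 3))
  expect_equal(transform_for_regression(same)$y, rep(0, 3))

  few <- make_series(c(0, 10, 20), c(0.5, 0, 0))
  expect_error(transform_for_regression(few), "fewer than 3")
})

test_that("noiseless exponential decay transforms to an exact line", {
  k <- 0.0249
  t <- seq(0, 110, 10)
  ts <- make_series(t, exp(-k * t))
  out <- transform_for_regression(ts)
  fit <- fit_decay(out)
  expect_equal(fit$slope, -k, tolerance = 1e-12)
  expect_equal(fit$ci95_hi - fit$ci95_lo, 0, tolerance = 1e-10)
  # slope is invariant to rescaling the normalization reference
  out2 <- transform_for_regression(make_series(t, exp(-k * t) * 0.21))
  expect_equal(fit_decay(out2)$slope, fit$slope, tolerance = 1e-12)
})

test_that("a non-negative slope is rejected with the replicate named", {
  ts <- make_series(c(0, 10, 20, 30), c(0.2, 0.3, 0.4, 0.5),
                    replicate_id = "R7")
  expect_error(fit_decay(transform_for_regression(ts)), "R7")
})

test_that("K_Dil comes from the dilution rate under the viability gate", {
  expect_equal(estimate_K_Dil(ref_cultivation()), 0.1 / 60)
  expect_equal(estimate_K_Dil(cultivation_record(0.0998, 91.8, 507.5)),
               0.001663, tolerance = 1e-3)
  expect_error(cultivation_record(0, 91.8, 507.5), "dilution_rate")
  low_viab <- cultivation_record(0.1, 91.8, 507.5, viability = 0.95)
  expect_error(estimate_K_Dil(low_viab), "viability")
})

test_that("K_Sec follows the steady-state concentration ratio", {
  expect_equal(estimate_K_Sec(ref_cultivation(), 0.1 / 60),
               0.0092, tolerance = 2e-3)
  eq <- cultivation_record(0.1, 100, 100)
  expect_equal(estimate_K_Sec(eq, 0.1 / 60), 0.1 / 60)
  # an empty supernatant cannot be constructed as a cultivation record,
  # but the relation itself degrades continuously to zero
  tiny <- cultivation_record(0.1, 100, 1e-12)
  expect_equal(estimate_K_Sec(tiny, 0.1 / 60), 0, tolerance = 1e-12)
})

test_that("K_Deg is the slope magnitude minus the known constants", {
  expect_equal(estimate_K_Deg(0.0249, 0.0092, 0.00167), 0.01403,
               tolerance = 1e-6)
  expect_error(estimate_K_Deg(0.0249, 0.0200, 0.0049), "non-positive")
  expect_equal(estimate_K_Deg(0.0151 + 0.0092 + 0.00167, 0.0092, 0.00167),
               0.0151)
})

test_that("compute_rates reproduces the flux table relations", {
  cult <- ref_cultivation()
  tab <- compute_rates(0.0092, 0.0151, 0.1 / 60, cult)
  q <- setNames(tab$q_ug_g_h, tab$flux)
  expect_equal(q[["Dil"]], 9.18, tolerance = 1e-6)
  expect_equal(q[["Sec"]], 50.7, tolerance = 2e-3)
  expect_equal(q[["Pi"]], q[["Sec"]] + q[["Deg"]] + q[["Dil"]])
  expect_equal(sum(tab$percent_of_qPi[tab$flux != "Pi"]), 100)

  # degenerate: only dilution removes protein
  only_dil <- compute_rates(1e-12, 1e-12, 0.1 / 60, cult)
  qd <- setNames(only_dil$q_ug_g_h, only_dil$flux)
  expect_equal(qd[["Pi"]], qd[["Dil"]], tolerance = 1e-8)
})

test_that("replicate spread is summarised as relative STD", {
  s <- propagate_uncertainty(c(0.0240, 0.0258))
  expect_equal(s$mean, 0.0249)
  expect_equal(s$rel_std, 0.0511, tolerance = 1e-2)
  expect_equal(propagate_uncertainty(c(0.5, 0.5))$rel_std, 0)
  expect_true(is.na(propagate_uncertainty(0.5)$rel_std))
})

test_that("reported STDs on synthetic duplicates stay in a plausible band", {
  truth <- ref_params()
  rels <- vapply(1:100, function(i) {
    des <- experiment_design(truth, times = mc_times(), dropout_prob = 0,
                             seed = 300 + i)
    fit <- suppressWarnings(
      estimate_fluxes(generate_experiment(des)$series, des$cultivation))
    fit$uncertainty$rel_std[fit$uncertainty$quantity == "K_Deg"]
  }, numeric(1))
  expect_true(all(rels >= 0 & rels < 0.2))
})

test_that("the media 32S gate warns and can hard-fail", {
  ok <- rbind(make_series(c(0, 60, 150), c(1, 0.2, 0.01)),
              make_series(c(0, 60), c(0.009, 0.004),
                          compartment = "media_small_molecule"))
  expect_silent(chk <- check_media_labeling(ok))
  expect_true(chk$ok)
  bad <- ok
  bad$frac32[bad$compartment == "media_small_molecule"][1] <- 0.05
  expect_warning(check_media_labeling(bad), "residual unlabeled")
  expect_error(check_media_labeling(bad, hard_fail = TRUE),
               "residual unlabeled")
})

test_that("full chain on noiseless data is an identity", {
  truth <- ref_params()
  des <- experiment_design(truth, noise_cv = 0,
                           intracellular_background = 0,
                           sulfate_residual_init = 0, dropout_prob = 0,
                           seed = 1)
  ex <- generate_experiment(des)
  fit <- estimate_fluxes(ex$series, des$cultivation, background = "none")
  expect_equal(fit$constants$K_Sec, truth$K_Sec, tolerance = 1e-6)
  expect_equal(fit$constants$K_Deg, truth$K_Deg, tolerance = 1e-6)
  expect_equal(fit$constants$K_Dil, truth$K_Dil, tolerance = 1e-6)
  q <- setNames(fit$estimates$q_ug_g_h, fit$estimates$flux)
  expect_equal(q[["Pi"]], truth$q_Pi, tolerance = 1e-6)
})
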