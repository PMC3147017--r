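#' @importFrom stats rbinom rnorm runif
NULL

#' Design of an in-silico continuous 34S labeling experiment
#'
#' Collects everything the generator needs: the ground-truth kinetic
#' parameters, the cultivation record (derived from the truth's steady
#' state when omitted), the sampling schedule and the noise model.
#' Defaults emulate the chemostat labeling experiment the package is built
#' around: 8 h of chase sampled every 10 min (up to 6 samples per hour),
#' two independent cultivations, 5% multiplicative measurement noise (the
#' instrument's long-term repeatability), a constant impurity background on
#' the intracellular immunoprecipitates, a residual unlabeled-sulfate
#' fraction below 1% washing out at the dilution rate, a limit of
#' quantification on the isotope ratio, and sporadic sample dropouts.
#'
#' @param truth [kinetic_params()] ground truth.
#' @param cultivation Optional [cultivation_record()]; default: the truth's
#'   analytic steady state with `D = K_Dil * 60` and viability 0.995.
#' @param times Sampling times in minutes since labeling start; default
#'   `seq(0, duration_min, by = 10)`.
#' @param duration_min Chase duration (min), default 480.
#' @param replicates Number of independent cultivations, default 2.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise, default 0.05.
#' @param intracellular_background Constant impurity 32S fraction added to
#'   intracellular observations, default 0.02.
#' @param sulfate_residual_init Initial 32S fraction of the media
#'   small-molecule sulfur pool, default 0.01; washes out first-order at
#'   `K_Dil` and feeds a matching share of 32S into new synthesis.
#' @param loq_frac32 Limit of quantification: observations below it are
#'   flagged `below_loq`, default 0.005.
#' @param dropout_prob Probability that any protein measurement is lost,
#'   default 0.1.
#' @param seed Mandatory integer seed; every stochastic draw flows from it.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(truth, cultivation = NULL, times = NULL,
                              duration_min = 480, replicates = 2,
                              noise_cv = 0.05,
                              intracellular_background = 0.02,
                              sulfate_residual_init = 0.01,
                              loq_frac32 = 0.005, dropout_prob = 0.1,
                              seed) {
  stopifnot(inherits(truth, "kinetic_params"))
  if (missing(seed) || !is.finite(seed)) {
    stop("a seed is mandatory for the synthetic-data generator",
         call. = FALSE)
  }
  if (is.null(times)) times <- seq(0, duration_min, by = 10)
  if (duration_min <= 0 || any(times < 0)) {
    stop("duration and sampling times must be non-negative", call. = FALSE)
  }
  fracs <- c(intracellular_background, sulfate_residual_init, loq_frac32,
             dropout_prob)
  if (any(fracs < 0 | fracs > 1) || noise_cv < 0) {
    stop("noise/background/loq/dropout settings must be fractions in [0,1]",
         call. = FALSE)
  }
  if (is.null(cultivation)) {
    st <- steady_state(truth)
    cultivation <- cultivation_record(dilution_rate = truth$K_Dil * 60,
                                      P_i = st$P_i, P_e = st$P_e,
                                      viability = 0.995)
  }
  stopifnot(inherits(cultivation, "cultivation_record"))
  structure(
    list(truth = truth, cultivation = cultivation, times = sort(times),
         duration_min = duration_min, replicates = replicates,
         noise_cv = noise_cv,
         intracellular_background = intracellular_background,
         sulfate_residual_init = sulfate_residual_init,
         loq_frac32 = loq_frac32, dropout_prob = dropout_prob,
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

# Exact 32S pool trajectories during the chase.  From a fully-32S steady
# state, the intracellular 32S pool decays at K_tot while residual 32S
# sulfate (fraction r0 washing out at K_Dil) feeds a small 32S synthesis
# term; the extracellular 32S pool follows through secretion and harvest.
# Linear system, solved in closed form (confluent branch when K_Har hits
# another eigenvalue, which is the rule since K_Har = K_Dil).
label_chase_fractions <- function(truth, times, r0) {
  a <- truth$K_Sec + truth$K_Deg + truth$K_Dil
  d <- truth$K_Dil
  h <- truth$K_Har
  st <- steady_state(truth)
  B <- if (r0 > 0) (truth$q_Pi / 60) * r0 / (a - d) else 0
  A <- st$P_i - B
  P_i32 <- A * exp(-a * times) + B * exp(-d * times)
  P_e32 <- st$P_e * exp(-h * times) +
    truth$K_Sec * (conv_exp(A, a, h, times) + conv_exp(B, d, h, times))
  data.frame(time_min = times,
             frac_i = P_i32 / st$P_i,
             frac_e = P_e32 / st$P_e,
             frac_media = r0 * exp(-d * times))
}

#' Generate a synthetic 34S labeling experiment
#'
#' Simulates the chase exactly (closed-form solution of the linear label
#' kinetics starting from a fully-32S steady state), then applies the
#' observation model per replicate: the constant intracellular impurity
#' background is added, every measurement is multiplied by unit-mean
#' lognormal noise with the design's CV, values below the limit of
#' quantification are flagged, observations are clipped to `[0, 1]`, and
#' protein measurements drop out at random.  The media small-molecule 32S
#' series is emitted alongside the two protein series.
#'
#' @param design An [experiment_design()].
#' @return List with `series` (a labeling time-series data.frame, see
#'   [validate_labeling()]) and `truth` (ground-truth record: parameters,
#'   cultivation, background, sulfate residual, noiseless fractions).
#' @examples
#' truth <- kinetic_params(143.1, 0.0092, 0.0151, 0.1 / 60)
#' des <- experiment_design(truth, seed = 42)
#' exp <- generate_experiment(des)
#' head(exp$series)
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(design$seed)
  clean <- label_chase_fractions(design$truth, design$times,
                                 design$sulfate_residual_init)
  s <- design$noise_cv
  sdlog <- sqrt(log(1 + s^2))
  draw_noise <- function(n) {
    if (s == 0) rep(1, n) else exp(rnorm(n, -sdlog^2 / 2, sdlog))
  }
  n_t <- nrow(clean)
  rows <- list()
  for (r in seq_len(design$replicates)) {
    rid <- paste0("R", r)
    obs_i <- (clean$frac_i + design$intracellular_background) *
      draw_noise(n_t)
    obs_e <- clean$frac_e * draw_noise(n_t)
    obs_m <- clean$frac_media * draw_noise(n_t)
    one <- function(comp, obs) {
      data.frame(replicate_id = rid, compartment = comp,
                 time_min = clean$time_min,
                 frac32 = pmin(pmax(obs, 0), 1),
                 below_loq = obs < design$loq_frac32)
    }
    intra <- one("intracellular", obs_i)
    extra <- one("extracellular", obs_e)
    media <- one("media_small_molecule", obs_m)
    if (design$dropout_prob > 0) {
      keep_i <- runif(n_t) >= design$dropout_prob
      keep_e <- runif(n_t) >= design$dropout_prob
      intra <- intra[keep_i, , drop = FALSE]
      extra <- extra[keep_e, , drop = FALSE]
    }
    rows[[rid]] <- rbind(intra, extra, media)
  }
  series <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  series <- validate_labeling(series)
  truth <- list(
    params = design$truth,
    cultivation = design$cultivation,
    K_total = design$truth$K_Sec + design$truth$K_Deg + design$truth$K_Dil,
    intracellular_background = design$intracellular_background,
    sulfate_residual_init = design$sulfate_residual_init,
    noise_cv = design$noise_cv, seed = design$seed,
    clean_fractions = clean
  )
  list(series = series, truth = truth)
}

#' Write a generated experiment to disk
#'
#' Emits the labeling series as the CSV dialect consumed by the estimation
#' chain plus a JSON ground-truth sidecar (`<stem>_truth.json`).  The CSV
#' round-trips losslessly through [read_labeling_csv()].
#'
#' @param experiment Output of [generate_experiment()].
#' @param path Path of the time-series CSV to write.
#' @return Invisibly, the paths written (`series`, `truth`).
#' @export
emit_experiment <- function(experiment, path) {
  write_labeling_csv(experiment$series, path)
  truth_path <- sub("\\.csv$", "", path)
  truth_path <- paste0(truth_path, "_truth.json")
  tr <- experiment$truth
  payload <- list(
    params = tr$params[c("q_Pi", "K_Sec", "K_Deg", "K_Dil", "K_Har")],
    q_Sec_max = tr$params$q_Sec_max,
    cultivation = unclass(tr$cultivation),
    K_total = tr$K_total,
    intracellular_background = tr$intracellular_background,
    sulfate_residual_init = tr$sulfate_residual_init,
    noise_cv = tr$noise_cv, seed = tr$seed
  )
  jsonlite::write_json(payload, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(series = path, truth = truth_path))
}
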