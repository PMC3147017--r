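# Chemostat reference conditions used across the suite: D = 0.1 h^-1,
# measured P_i = 91.8 and P_e = 507.5 ug per g YDM, and the published
# time constants.
ref_params <- function(...) {
  args <- utils::modifyList(
    list(q_Pi = 143.1, K_Sec = 0.0092, K_Deg = 0.0151, K_Dil = 0.1 / 60),
    list(...))
  do.call(kinetic_params, args)
}

ref_cultivation <- function() {
  cultivation_record(dilution_rate = 0.1, P_i = 91.8, P_e = 507.5,
                     viability = 0.995)
}

# random positive parameter sets for property-style checks
random_params <- function(rng_seed) {
  set.seed(rng_seed)
  kinetic_params(q_Pi = runif(1, 10, 500),
                 K_Sec = runif(1, 1e-4, 0.05),
                 K_Deg = runif(1, 1e-4, 0.05),
                 K_Dil = runif(1, 5e-4, 0.01),
                 K_Har = runif(1, 5e-4, 0.01))
}

# hand-built labeling table (one replicate unless stated otherwise)
make_series <- function(time_min, frac32, compartment = "intracellular",
                        replicate_id = "R1", below_loq = FALSE) {
  data.frame(replicate_id = replicate_id, compartment = compartment,
             time_min = time_min, frac32 = frac32, below_loq = below_loq)
}

# independent matrix-exponential oracle for the uncapped linear system:
# augment (P_i, P_e, 1) so the constant source becomes linear
expm_pools <- function(params, init, times) {
  M <- rbind(
    c(-(params$K_Sec + params$K_Deg + params$K_Dil), 0, params$q_Pi / 60),
    c(params$K_Sec, -params$K_Har, 0),
    c(0, 0, 0))
  y0 <- c(init$P_i, init$P_e, 1)
  out <- t(vapply(times, function(t) {
    as.numeric(Matrix::expm(M * t) %*% y0)[1:2]
  }, numeric(2)))
  data.frame(time_min = times, P_i = out[, 1], P_e = out[, 2])
}

# sampling schedule used for the Monte-Carlo studies: a 12-point decay
# window plus a post-cutoff window for background estimation
mc_times <- function() c(seq(0, 110, by = 10), seq(150, 480, by = 30))
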