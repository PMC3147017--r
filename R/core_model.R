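#' @importFrom stats setNames
NULL

# Secretion flux into the medium (ug g^-1 min^-1): linear in P_i up to the
# optional capacity cap.  The cap acts on the flux term only, so it is
# continuous in P_i and the intracellular balance is unaffected.
secretion_flux <- function(P_i, params) {
  flux <- params$K_Sec * P_i
  if (!is.null(params$q_Sec_max)) flux <- pmin(flux, params$q_Sec_max / 60)
  flux
}

check_pool_state <- function(state, isotope) {
  need <- if (isotope) c("P_i32", "P_i34", "P_e32", "P_e34") else
    c("P_i", "P_e")
  miss <- setdiff(need, names(state))
  if (length(miss) > 0) {
    stop("pool state is missing components: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(unlist(state[need])))) {
    stop("pool state components must be finite", call. = FALSE)
  }
  if (any(unlist(state[need]) < 0)) {
    stop("pool state components must be non-negative", call. = FALSE)
  }
  invisible(state)
}

#' Right-hand side of the pool ordinary differential equations
#'
#' Time derivatives (ug g^-1 min^-1) of the protein pools.  The
#' intracellular pool gains by formation (`q_Pi`, converted from per-hour to
#' per-minute here) and loses first-order to secretion, degradation and
#' dilution into daughter cells; the extracellular pool gains the secretion
#' flux (optionally capped at `q_Sec_max`) and loses first-order to harvest:
#'
#' \deqn{dP_i/dt = q_{Pi}/60 - (K_{Sec}+K_{Deg}+K_{Dil}) P_i}
#' \deqn{dP_e/dt = s(P_i) - K_{Har} P_e,\quad
#'       s(P_i) = \min(K_{Sec} P_i,\; q_{Sec,max}/60)}
#'
#' With `isotope = TRUE` the state is split into 32S and 34S pools.  Each
#' isotope pool is removed by the same first-order operators; newly formed
#' protein is routed entirely to the 34S pool, the premise of a continuous
#' 34S labeling in which residual 32S sulfate is negligible.  The secretion
#' flux is split between isotopes in proportion to their intracellular
#' share, so a capacity cap throttles both pools alike.
#'
#' @param state Named list or vector with `P_i`, `P_e` (or, isotope-resolved,
#'   `P_i32`, `P_i34`, `P_e32`, `P_e34`), in ug per g YDM.
#' @param params A [kinetic_params()] object.
#' @param isotope Logical; interpret the state as isotope-resolved.
#' @return Named numeric vector of derivatives, ug g^-1 min^-1.
#' @examples
#' p <- kinetic_params(143.1, 0.0092, 0.0151, 0.1 / 60)
#' ode_rhs(list(P_i = 91.8, P_e = 507.5), p)  # ~0: steady state
#' @export
ode_rhs <- function(state, params, isotope = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  check_pool_state(state, isotope)
  k_out <- params$K_Sec + params$K_Deg + params$K_Dil
  if (!isotope) {
    dP_i <- params$q_Pi / 60 - k_out * state$P_i
    dP_e <- secretion_flux(state$P_i, params) - params$K_Har * state$P_e
    return(c(dP_i = dP_i, dP_e = dP_e))
  }
  P_i <- state$P_i32 + state$P_i34
  s_tot <- secretion_flux(P_i, params)
  share32 <- if (P_i > 0) state$P_i32 / P_i else 0
  dP_i32 <- -k_out * state$P_i32
  dP_i34 <- params$q_Pi / 60 - k_out * state$P_i34
  dP_e32 <- s_tot * share32 - params$K_Har * state$P_e32
  dP_e34 <- s_tot * (1 - share32) - params$K_Har * state$P_e34
  c(dP_i32 = dP_i32, dP_i34 = dP_i34, dP_e32 = dP_e32, dP_e34 = dP_e34)
}

#' Simulate the pool kinetics over time
#'
#' Integrates the pool equations with a stiff-capable implicit solver
#' (\code{deSolve::ode}, lsoda) on a user-supplied time grid in minutes.
#' The uncapped system is linear, and the numeric solution agrees with its
#' closed-form solution ([analytic_pools()]) to the solver tolerances.
#'
#' @param params A [kinetic_params()] object.
#' @param init Named list/vector of initial pool sizes; either `P_i`, `P_e`
#'   or the four isotope-resolved components (which switches the model to
#'   isotope-resolved form).
#' @param times Strictly increasing numeric vector of output times (min).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A data.frame with column `time_min` and one column per pool;
#'   isotope-resolved runs also carry the reconstructed totals `P_i`, `P_e`.
#' @examples
#' p <- kinetic_params(143.1, 0.0092, 0.0151, 0.1 / 60)
#' traj <- simulate_pools(p, list(P_i = 0, P_e = 0), seq(0, 480, 30))
#' tail(traj, 2)
#' @export
simulate_pools <- function(params, init, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be a strictly increasing vector of length >= 2",
         call. = FALSE)
  }
  init <- as.list(init)
  isotope <- all(c("P_i32", "P_i34", "P_e32", "P_e34") %in% names(init))
  check_pool_state(init, isotope)
  comps <- if (isotope) c("P_i32", "P_i34", "P_e32", "P_e34") else
    c("P_i", "P_e")
  y0 <- setNames(as.numeric(init[comps]), comps)
  rhs <- function(t, y, parms) {
    list(unname(ode_rhs(as.list(y), parms, isotope = isotope)))
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    diag <- utils::capture.output(deSolve::diagnostics(sol))
    stop("ODE solver failed to converge:\n", paste(diag, collapse = "\n"),
         call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time_min"
  if (isotope) {
    out$P_i <- out$P_i32 + out$P_i34
    out$P_e <- out$P_e32 + out$P_e34
  }
  out
}

# exp-difference kernel: c * (exp(-r t) - exp(-h t)) / (h - r), with the
# confluent limit c * t * exp(-h t) when r == h (always hit when
# K_Har == K_Dil).  Vectorised over t.
conv_exp <- function(c0, r, h, t) {
  if (abs(h - r) < 1e-12) c0 * t * exp(-h * t)
  else c0 * (exp(-r * t) - exp(-h * t)) / (h - r)
}

#' Closed-form trajectory of the uncapped linear model
#'
#' Exact solution of the uncapped two-pool system from an arbitrary initial
#' condition: the intracellular pool relaxes mono-exponentially to its
#' steady state and the extracellular pool follows as a bi-exponential
#' (with the confluent `t exp(-Kt)` branch when `K_Har` equals the total
#' intracellular removal constant).  Used as the independent oracle for
#' [simulate_pools()] and in the synthetic-data generator.
#'
#' @inheritParams simulate_pools
#' @param q_Pi_override Optional formation rate (ug g^-1 h^-1) replacing
#'   `params$q_Pi`, e.g. 0 for a chase without synthesis.
#' @return data.frame with `time_min`, `P_i`, `P_e`.
#' @export
analytic_pools <- function(params, init, times, q_Pi_override = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.null(params$q_Sec_max)) {
    stop("analytic_pools() covers the uncapped (linear) model only",
         call. = FALSE)
  }
  init <- as.list(init)
  check_pool_state(init, isotope = FALSE)
  q <- if (is.null(q_Pi_override)) params$q_Pi else q_Pi_override
  a <- params$K_Sec + params$K_Deg + params$K_Dil
  h <- params$K_Har
  if (a <= 0 || h <= 0) {
    stop("total removal and harvest constants must be positive",
         call. = FALSE)
  }
  P_i_inf <- (q / 60) / a
  A <- init$P_i - P_i_inf
  P_i <- P_i_inf + A * exp(-a * times)
  P_e_inf <- params$K_Sec * P_i_inf / h
  # dP_e/dt = K_Sec P_i - h P_e; particular + homogeneous parts
  P_e <- P_e_inf + (init$P_e - P_e_inf) * exp(-h * times) +
    params$K_Sec * conv_exp(A, a, h, times)
  data.frame(time_min = times, P_i = P_i, P_e = P_e)
}

#' Steady state of the pool model
#'
#' Closed-form fixed point of the pool equations.  Uncapped:
#' \deqn{P_i^* = (q_{Pi}/60)/(K_{Sec}+K_{Deg}+K_{Dil}),\quad
#'       P_e^* = K_{Sec} P_i^* / K_{Har}.}
#' With a secretion cap the extracellular balance is piecewise: the influx
#' saturates at `q_Sec_max/60` once `K_Sec * P_i^*` exceeds it, which
#' happens for formation rates above the switch point
#' `q_Pi_switch = q_Sec_max * (K_Sec+K_Deg+K_Dil) / K_Sec` (ug g^-1 h^-1);
#' beyond it `P_e^*` plateaus at `(q_Sec_max/60)/K_Har`.  The intracellular
#' steady state is unaffected by the cap.
#'
#' @param params A [kinetic_params()] object with positive total removal and
#'   harvest constants.
#' @return List with `P_i`, `P_e` (ug per g YDM) and, when capped,
#'   `capped` (logical: is the cap active at this steady state) and
#'   `q_Pi_switch`.
#' @examples
#' steady_state(kinetic_params(143.1, 0.0092, 0.0151, 0.1 / 60))
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  k_out <- params$K_Sec + params$K_Deg + params$K_Dil
  if (k_out <= 0) {
    stop("no steady state: total intracellular removal constant is zero",
         call. = FALSE)
  }
  if (params$K_Har <= 0) {
    stop("no steady state: K_Har must be positive", call. = FALSE)
  }
  P_i <- (params$q_Pi / 60) / k_out
  P_e <- secretion_flux(P_i, params) / params$K_Har
  out <- list(P_i = P_i, P_e = P_e)
  if (!is.null(params$q_Sec_max)) {
    out$capped <- params$K_Sec * P_i >= params$q_Sec_max / 60
    out$q_Pi_switch <- if (params$K_Sec > 0)
      params$q_Sec_max * k_out / params$K_Sec else Inf
  }
  out
}
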