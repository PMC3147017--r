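#' Kinetic parameters of the protein secretion model
#'
#' Bundles the rate constants and the formation rate that define the
#' two-pool model of intra- and extracellular recombinant protein in a
#' chemostat.  Units follow the convention used throughout the package:
#' time constants `K` in min^-1, rates `q` in ug per g yeast dry mass (YDM)
#' per hour.  The factor-60 conversion between the two time bases happens
#' inside the model functions, never in user code.
#'
#' @param q_Pi Intracellular protein formation rate (ug g^-1 h^-1).
#' @param K_Sec Secretion time constant (min^-1).
#' @param K_Deg Intracellular degradation time constant (min^-1).
#' @param K_Dil Dilution-by-growth time constant (min^-1), i.e. the specific
#'   growth rate expressed per minute.
#' @param K_Har Harvest time constant (min^-1).  At >= 99% viability the
#'   dilution rate equals the specific growth rate, so `K_Har` defaults to
#'   `K_Dil`.
#' @param q_Sec_max Optional maximum secretion rate (ug g^-1 h^-1).  When
#'   set, the secretion flux into the medium is capped at this value;
#'   `NULL` means unconstrained.
#'
#' @return An object of class `kinetic_params` (a validated named list).
#' @examples
#' p <- kinetic_params(q_Pi = 143.1, K_Sec = 0.0092, K_Deg = 0.0151,
#'                     K_Dil = 0.1 / 60)
#' steady_state(p)
#' @export
kinetic_params <- function(q_Pi, K_Sec, K_Deg, K_Dil, K_Har = K_Dil,
                           q_Sec_max = NULL) {
  vals <- c(q_Pi = q_Pi, K_Sec = K_Sec, K_Deg = K_Deg, K_Dil = K_Dil,
            K_Har = K_Har)
  if (any(!is.finite(vals))) {
    stop("all kinetic parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("rate constants and q_Pi must be non-negative, got: ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  if (!is.null(q_Sec_max)) {
    if (!is.finite(q_Sec_max) || q_Sec_max <= 0) {
      stop("q_Sec_max, when given, must be a positive finite number",
           call. = FALSE)
    }
  }
  structure(
    list(q_Pi = q_Pi, K_Sec = K_Sec, K_Deg = K_Deg, K_Dil = K_Dil,
         K_Har = K_Har, q_Sec_max = q_Sec_max),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters of the secretion model\n")
  cat(sprintf("  q_Pi  = %g ug g^-1 h^-1 (formation)\n", x$q_Pi))
  cat(sprintf("  K_Sec = %g min^-1 (secretion,   t1/2 = %.1f min)\n",
              x$K_Sec, if (x$K_Sec > 0) half_time(x$K_Sec) else NA))
  cat(sprintf("  K_Deg = %g min^-1 (degradation, t1/2 = %.1f min)\n",
              x$K_Deg, if (x$K_Deg > 0) half_time(x$K_Deg) else NA))
  cat(sprintf("  K_Dil = %g min^-1 (dilution,    t1/2 = %.1f min)\n",
              x$K_Dil, if (x$K_Dil > 0) half_time(x$K_Dil) else NA))
  cat(sprintf("  K_Har = %g min^-1 (harvest)\n", x$K_Har))
  if (!is.null(x$q_Sec_max)) {
    cat(sprintf("  q_Sec_max = %g ug g^-1 h^-1 (secretion cap)\n",
                x$q_Sec_max))
  }
  invisible(x)
}

#' Chemostat cultivation record
#'
#' Measured quantities of a steady-state chemostat cultivation needed by the
#' estimation chain: the dilution rate, the average intra- and extracellular
#' product concentrations per gram yeast dry mass, and the culture
#' viability.  A viability of at least 0.99 is required before the dilution
#' rate may be equated with the specific growth rate; functions that rely on
#' that identity refuse lower viabilities.
#'
#' @param dilution_rate Chemostat dilution rate D (h^-1).
#' @param P_i Intracellular product concentration (ug per g YDM).
#' @param P_e Extracellular product concentration (ug per g YDM).
#' @param viability Fraction of viable cells in `[0, 1]` (default 0.995).
#'
#' @return An object of class `cultivation_record`.
#' @export
cultivation_record <- function(dilution_rate, P_i, P_e, viability = 0.995) {
  if (!is.finite(dilution_rate) || dilution_rate <= 0) {
    stop("dilution_rate must be > 0 (h^-1)", call. = FALSE)
  }
  if (!is.finite(P_i) || P_i <= 0 || !is.finite(P_e) || P_e <= 0) {
    stop("P_i and P_e concentrations must be > 0 (ug per g YDM)",
         call. = FALSE)
  }
  if (!is.finite(viability) || viability < 0 || viability > 1) {
    stop("viability must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(dilution_rate = dilution_rate, P_i = P_i, P_e = P_e,
         viability = viability),
    class = "cultivation_record"
  )
}

#' @export
print.cultivation_record <- function(x, ...) {
  cat("Chemostat cultivation record\n")
  cat(sprintf("  D = %g h^-1, viability = %.3f\n", x$dilution_rate,
              x$viability))
  cat(sprintf("  P_i = %g, P_e = %g ug per g YDM\n", x$P_i, x$P_e))
  invisible(x)
}

#' Half time of a first-order process
#'
#' Converts a first-order time constant into the corresponding half time,
#' `t1/2 = ln(2) / K`.
#'
#' @param K First-order time constant (min^-1); must be positive.
#' @return Half time in minutes.
#' @examples
#' half_time(0.1 / 60)   # dilution at D = 0.1 h^-1: 415.9 min
#' half_time(0.0092)     # secretion: 75.3 min
#' @export
half_time <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("half_time() requires a positive time constant", call. = FALSE)
  }
  log(2) / K
}
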