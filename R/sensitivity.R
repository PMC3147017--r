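SWEEP_PARAMS <- c("t_half_Deg", "t_half_Sec", "q_Pi")

# apply a multiplicative fold to one sweep axis; half-time axes act on the
# underlying rate constant (K = ln2 / t_half, so fold f on t_half divides K
# by f)
apply_fold <- function(params, axis, fold) {
  switch(axis,
    q_Pi = { params$q_Pi <- params$q_Pi * fold },
    t_half_Deg = { params$K_Deg <- params$K_Deg / fold },
    t_half_Sec = { params$K_Sec <- params$K_Sec / fold },
    stop("unknown sweep axis: ", axis, call. = FALSE)
  )
  params
}

axis_value <- function(params, axis) {
  switch(axis,
    q_Pi = params$q_Pi,
    t_half_Deg = half_time(params$K_Deg),
    t_half_Sec = half_time(params$K_Sec)
  )
}

#' Specification of a pairwise sensitivity sweep
#'
#' Defines which two parameters are varied against each other, over which
#' multiplicative fold range, on how fine a grid, and under which optional
#' secretion-capacity cap.  Admissible axes are `t_half_Deg`, `t_half_Sec`
#' and `q_Pi`; half-time axes are converted to rate constants before the
#' model is evaluated.  Fold factors are log-spaced, so "10-fold
#' improvement" and "10-fold worsening" are symmetric around the baseline.
#'
#' @param pair Character vector of two distinct axis names.
#' @param fold_range Positive fold bounds, default `c(0.1, 10)`.
#' @param n_grid Grid points per axis (>= 2), default 41.
#' @param cap Optional `q_Sec_max` (ug g^-1 h^-1) applied during the sweep.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(pair, fold_range = c(0.1, 10), n_grid = 41,
                       cap = NULL) {
  pair <- as.character(pair)
  if (length(pair) != 2 || anyDuplicated(pair) ||
      !all(pair %in% SWEEP_PARAMS)) {
    stop("pair must name two distinct axes among: ",
         paste(SWEEP_PARAMS, collapse = ", "), call. = FALSE)
  }
  if (length(fold_range) != 2 || any(fold_range <= 0) ||
      fold_range[1] >= fold_range[2]) {
    stop("fold_range must be two increasing positive numbers",
         call. = FALSE)
  }
  if (n_grid < 2) stop("n_grid must be >= 2", call. = FALSE)
  structure(list(pair = pair, fold_range = fold_range, n_grid = n_grid,
                 cap = cap),
            class = "sweep_spec")
}

#' Steady-state titer ratio between two parameter sets
#'
#' Ratio of extracellular steady-state concentrations,
#' `steady_state(modified)$P_e / steady_state(baseline)$P_e`.
#'
#' @param baseline,modified [kinetic_params()] objects.
#' @return Dimensionless fold change.
#' @examples
#' base <- kinetic_params(143.1, 0.0092, 0.0151, 0.1 / 60)
#' up <- base; up$q_Pi <- base$q_Pi * 10
#' fold_change(base, up)  # exactly 10 (linearity)
#' @export
fold_change <- function(baseline, modified) {
  stopifnot(inherits(baseline, "kinetic_params"),
            inherits(modified, "kinetic_params"))
  base_Pe <- steady_state(baseline)$P_e
  if (base_Pe <= 0) {
    stop("baseline steady-state titer is zero; fold change undefined",
         call. = FALSE)
  }
  steady_state(modified)$P_e / base_Pe
}

#' Pairwise parameter sweep of the steady-state titer
#'
#' Evaluates the steady-state extracellular titer on a grid of
#' multiplicative fold factors applied to the two chosen parameters.  Fold
#' factors here multiply the named quantity itself: lengthening `t_half_Deg`
#' (slower degradation), lengthening `t_half_Sec` (slower secretion) or
#' raising `q_Pi`.  "Improvement" therefore means larger `t_half_Deg` fold,
#' smaller `t_half_Sec` fold, larger `q_Pi` fold.
#'
#' @param baseline [kinetic_params()] starting point (the measured values).
#' @param spec A [sweep_spec()].
#' @return An object of class `titer_surface`: list with `grid` (long
#'   data.frame: `axis1_fold`, `axis2_fold`, `axis1_value`, `axis2_value`,
#'   `P_e`, `fold_change`), `P_e_matrix` (axis1 in rows), `folds1`,
#'   `folds2`, `pair`, `baseline_P_e`, `cap`.
#' @export
sweep_titer <- function(baseline, spec) {
  stopifnot(inherits(baseline, "kinetic_params"),
            inherits(spec, "sweep_spec"))
  base <- baseline
  base$q_Sec_max <- spec$cap
  if (!is.null(spec$cap)) {
    base_flux <- 60 * secretion_flux(steady_state(baseline)$P_i, baseline)
    if (spec$cap < base_flux) {
      stop(sprintf(paste0("secretion cap %.4g ug g^-1 h^-1 is below the ",
                          "baseline secretion flux %.4g: ill-posed ",
                          "baseline"), spec$cap, base_flux), call. = FALSE)
    }
  }
  baseline_P_e <- steady_state(base)$P_e
  folds <- exp(seq(log(spec$fold_range[1]), log(spec$fold_range[2]),
                   length.out = spec$n_grid))
  # make sure the baseline (fold 1, fold 1) is on the grid
  if (!any(abs(folds - 1) < 1e-12)) folds <- sort(c(folds, 1))
  grid <- expand.grid(axis1_fold = folds, axis2_fold = folds,
                      KEEP.OUT.ATTRS = FALSE)
  eval1 <- function(f1, f2) {
    p <- apply_fold(apply_fold(base, spec$pair[1], f1), spec$pair[2], f2)
    st <- steady_state(p)
    c(st$P_e, axis_value(p, spec$pair[1]), axis_value(p, spec$pair[2]))
  }
  vals <- mapply(eval1, grid$axis1_fold, grid$axis2_fold)
  grid$axis1_value <- vals[2, ]
  grid$axis2_value <- vals[3, ]
  grid$P_e <- vals[1, ]
  grid$fold_change <- grid$P_e / baseline_P_e
  structure(
    list(grid = grid,
         P_e_matrix = matrix(grid$P_e, nrow = length(folds),
                             dimnames = list(format(folds, digits = 4),
                                             format(folds, digits = 4))),
         folds1 = folds, folds2 = folds, pair = spec$pair,
         baseline_P_e = baseline_P_e, cap = spec$cap),
    class = "titer_surface"
  )
}

#' @export
print.titer_surface <- function(x, ...) {
  cat(sprintf("Titer surface: %s x %s, %d x %d grid\n", x$pair[1],
              x$pair[2], length(x$folds1), length(x$folds2)))
  cat(sprintf("  baseline P_e = %.4g ug g^-1%s\n", x$baseline_P_e,
              if (is.null(x$cap)) "" else
                sprintf(", secretion cap %.4g ug g^-1 h^-1", x$cap)))
  cat(sprintf("  P_e range: %.4g .. %.4g (fold change %.3g .. %.3g)\n",
              min(x$grid$P_e), max(x$grid$P_e), min(x$grid$fold_change),
              max(x$grid$fold_change)))
  invisible(x)
}

#' Plateau of the secreted titer under a secretion-capacity cap
#'
#' With the secretion flux capped at `q_Sec_max`, the extracellular titer
#' cannot exceed `(q_Sec_max/60) / K_Har`, whatever further improvement of
#' formation or degradation.  This reports that plateau and, from the
#' piecewise steady state, the smallest single-parameter change that
#' brings the secretion flux up to the cap: the fold on `q_Pi` (linear) and
#' the fold on `t_half_Deg` needed so that `K_Sec * P_i*` reaches
#' `q_Sec_max/60`.  An infinite `t_half_Deg` fold means no slowdown of
#' degradation alone can reach the cap.
#'
#' @param baseline [kinetic_params()] (uncapped baseline values).
#' @param cap `q_Sec_max` in ug g^-1 h^-1; must not be below the baseline
#'   secretion flux.  `Inf` means no plateau.
#' @return List with `plateau_P_e`, `baseline_q_Sec`, `q_Pi_fold`,
#'   `t_half_Deg_fold` (NA entries when `cap = Inf`).
#' @export
plateau_analysis <- function(baseline, cap) {
  stopifnot(inherits(baseline, "kinetic_params"))
  st <- steady_state(baseline)
  q_Sec_base <- 60 * baseline$K_Sec * st$P_i
  if (is.infinite(cap)) {
    return(list(plateau_P_e = NA_real_, baseline_q_Sec = q_Sec_base,
                q_Pi_fold = NA_real_, t_half_Deg_fold = NA_real_))
  }
  if (cap < q_Sec_base) {
    stop("cap is below the baseline secretion flux", call. = FALSE)
  }
  plateau_P_e <- (cap / 60) / baseline$K_Har
  # q_Sec scales linearly with q_Pi
  q_Pi_fold <- cap / q_Sec_base
  # via degradation: K_Sec * (q_Pi/60) / (K_Sec + K_Deg' + K_Dil) = cap/60
  k_needed <- baseline$K_Sec * baseline$q_Pi / cap
  K_Deg_new <- k_needed - baseline$K_Sec - baseline$K_Dil
  t_half_Deg_fold <- if (K_Deg_new > 0) baseline$K_Deg / K_Deg_new else Inf
  list(plateau_P_e = plateau_P_e, baseline_q_Sec = q_Sec_base,
       q_Pi_fold = q_Pi_fold, t_half_Deg_fold = t_half_Deg_fold)
}

#' Write a titer surface as CSV
#'
#' Long-format dump of the sweep grid (one row per grid node) in the same
#' column order the `sensitivity` subcommand documents.
#'
#' @param surface A `titer_surface` from [sweep_titer()].
#' @param path Output file.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "titer_surface"))
  utils::write.csv(surface$grid[c("axis1_fold", "axis2_fold", "axis1_value",
                                  "axis2_value", "P_e", "fold_change")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
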