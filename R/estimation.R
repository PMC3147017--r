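#' @importFrom stats coef confint lm predict sd
NULL

#' Subtract the immunoprecipitation impurity background
#'
#' Cell-lysate immunoprecipitates carry impurities that contribute a
#' residual 32S signal.  Once enough half-lives of secretion and degradation
#' have elapsed (by default 140 min after labeling start), the remaining
#' intracellular 32S signal is attributed to that background.  The
#' background level `b` is estimated per replicate as the mean intracellular
#' `frac32` at `time_min >= cutoff_min` and subtracted (floored at zero)
#' from every intracellular point of that replicate.  Extracellular and
#' media records pass through unchanged, since impurities are only seen in
#' the lysate immunoprecipitates.
#'
#' @param ts Labeling time series (see [validate_labeling()]).
#' @param cutoff_min Time (min) from which the intracellular signal is
#'   treated as pure background; default 140.
#' @param method `"constant"` (default) subtracts the mean post-cutoff
#'   level, treating impurity carryover as time-invariant; `"linear"`
#'   extrapolates a linear time trend fitted to the post-cutoff points back
#'   towards the beginning of the labeling.
#' @return The corrected series, with the per-replicate background levels
#'   (the mean post-cutoff signal) attached as attribute `"background"`.
#' @export
correct_background <- function(ts, cutoff_min = 140,
                               method = c("constant", "linear")) {
  method <- match.arg(method)
  validate_labeling(ts)
  intra <- ts$compartment == "intracellular"
  reps <- unique(ts$replicate_id[intra])
  bg <- setNames(numeric(length(reps)), reps)
  for (r in reps) {
    post <- intra & ts$replicate_id == r & ts$time_min >= cutoff_min
    if (!any(post)) {
      stop("background correction refused for replicate '", r,
           "': no intracellular points at or after ", cutoff_min,
           " min", call. = FALSE)
    }
    sel <- intra & ts$replicate_id == r
    bg[r] <- mean(ts$frac32[post])
    if (method == "linear" && sum(post) >= 2 &&
        length(unique(ts$time_min[post])) >= 2) {
      trend <- lm(frac32 ~ time_min, data = ts[post, ])
      b_at <- pmax(stats::predict(
        trend, newdata = data.frame(time_min = ts$time_min[sel])), 0)
    } else {
      b_at <- bg[r]
    }
    ts$frac32[sel] <- pmax(ts$frac32[sel] - b_at, 0)
  }
  attr(ts, "background") <- bg
  ts
}

#' Log-transform intracellular decay for linear regression
#'
#' The chase of pre-existing 32S protein decays as
#' `frac32(t) = frac32(0) * exp(-K_tot * t)` with
#' `K_tot = K_Sec + K_Deg + K_Dil`, so `y = ln(frac32 / frac32_ref)` is
#' linear in time with slope `-K_tot`.  The reference is the earliest
#' usable intracellular point of each replicate; because the regression
#' keeps a free intercept the choice only shifts the intercept, never the
#' slope.  Points flagged `below_loq` or with non-positive corrected
#' `frac32` cannot be log-transformed and are excluded (and counted).
#'
#' @param ts Background-corrected labeling series.
#' @return data.frame with `replicate_id`, `time_min`, `y`, with the number
#'   of excluded points per replicate as attribute `"excluded"`.
#' @export
transform_for_regression <- function(ts) {
  validate_labeling(ts)
  intra <- ts[ts$compartment == "intracellular", , drop = FALSE]
  out <- list()
  excluded <- c()
  for (r in unique(intra$replicate_id)) {
    d <- intra[intra$replicate_id == r, , drop = FALSE]
    d <- d[order(d$time_min), , drop = FALSE]
    usable <- !d$below_loq & d$frac32 > 0
    excluded[r] <- sum(!usable)
    d <- d[usable, , drop = FALSE]
    if (nrow(d) < 3) {
      stop("replicate '", r, "': fewer than 3 usable intracellular points ",
           "after exclusions (", nrow(d), " left)", call. = FALSE)
    }
    ref <- d$frac32[1]
    out[[r]] <- data.frame(replicate_id = r, time_min = d$time_min,
                           y = log(d$frac32 / ref))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "excluded") <- excluded
  res
}

#' Fit the log-linear 32S decay per replicate
#'
#' Ordinary least squares of the transformed signal `y` on time with a free
#' intercept, per replicate.  The slope estimates `-K_tot`, the sum of the
#' secretion, degradation and dilution time constants; a 95% confidence
#' interval from the t-distribution accompanies it.  A non-negative fitted
#' slope indicates a failed labeling and is rejected.
#'
#' @param pairs data.frame from [transform_for_regression()] (columns
#'   `replicate_id`, `time_min`, `y`).
#' @return data.frame with one row per replicate: `replicate_id`, `slope`
#'   (min^-1, negative), `intercept`, `ci95_lo`, `ci95_hi` (on the slope),
#'   `K_total` (= -slope), `n_points`, `sigma` (residual standard error).
#' @export
fit_decay <- function(pairs) {
  stopifnot(all(c("replicate_id", "time_min", "y") %in% names(pairs)))
  rows <- lapply(unique(pairs$replicate_id), function(r) {
    d <- pairs[pairs$replicate_id == r, , drop = FALSE]
    if (nrow(d) < 3) {
      stop("replicate '", r, "': regression needs >= 3 points",
           call. = FALSE)
    }
    fit <- lm(y ~ time_min, data = d)
    slope <- unname(coef(fit)["time_min"])
    if (!is.finite(slope) || slope >= 0) {
      stop("replicate '", r, "': fitted slope is not negative (",
           format(slope), "); no 32S decay detected", call. = FALSE)
    }
    ci <- suppressWarnings(confint(fit, "time_min", level = 0.95))
    ci[!is.finite(ci)] <- slope  # zero-residual fits: degenerate interval
    data.frame(replicate_id = r, slope = slope,
               intercept = unname(coef(fit)["(Intercept)"]),
               ci95_lo = ci[1], ci95_hi = ci[2], K_total = -slope,
               n_points = nrow(d),
               sigma = suppressWarnings(summary(fit)$sigma))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Dilution time constant from the chemostat dilution rate
#'
#' At a culture viability of at least 99% the dilution rate D equals the
#' specific growth rate, so the dilution-by-growth time constant is simply
#' D converted to the per-minute time base: `K_Dil = D / 60`.
#'
#' @param cult A [cultivation_record()].
#' @return `K_Dil` in min^-1.
#' @export
estimate_K_Dil <- function(cult) {
  stopifnot(inherits(cult, "cultivation_record"))
  if (cult$viability < 0.99) {
    stop("viability ", cult$viability, " is below 0.99: the dilution rate ",
         "cannot be equated with the specific growth rate", call. = FALSE)
  }
  cult$dilution_rate / 60
}

#' Secretion time constant from the steady-state concentration ratio
#'
#' At chemostat steady state the extracellular balance gives
#' `K_Sec = K_Dil * P_e / P_i`: the quotient of extra- and intracellular
#' product concentration multiplied by the dilution time constant.
#'
#' @param cult A [cultivation_record()].
#' @param K_Dil Dilution time constant (min^-1).
#' @return `K_Sec` in min^-1.
#' @export
estimate_K_Sec <- function(cult, K_Dil) {
  stopifnot(inherits(cult, "cultivation_record"))
  if (cult$P_i <= 0) stop("P_i must be positive", call. = FALSE)
  K_Dil * cult$P_e / cult$P_i
}

#' Degradation time constant by subtraction
#'
#' The fitted decay slope magnitude is the sum of the three removal
#' constants, so `K_Deg = K_total - K_Sec - K_Dil`.  A non-positive result
#' means the independently determined `K_Sec + K_Dil` already exceeds the
#' measured total removal — a model inconsistency that is reported, not
#' silently clipped.
#'
#' @param K_total Magnitude of the fitted decay slope (min^-1).
#' @param K_Sec,K_Dil Secretion and dilution time constants (min^-1).
#' @return `K_Deg` in min^-1.
#' @export
estimate_K_Deg <- function(K_total, K_Sec, K_Dil) {
  K_Deg <- K_total - K_Sec - K_Dil
  bad <- K_Deg <= 0
  if (any(bad)) {
    stop("K_Deg would be non-positive: K_total = ",
         paste(format(K_total[bad]), collapse = ", "), ", K_Sec = ",
         format(K_Sec), ", K_Dil = ", format(K_Dil),
         " (K_Sec + K_Dil >= K_total)", call. = FALSE)
  }
  K_Deg
}

#' Flux table from the time constants
#'
#' Converts the three removal time constants into fluxes via the measured
#' intracellular concentration, `q_X = K_X * P_i * 60` (ug g^-1 h^-1), and
#' closes the balance: at steady state everything that is secreted,
#' degraded or passed to daughter cells was formed before, so
#' `q_Pi = q_Sec + q_Deg + q_Dil` by construction.  Half times and the
#' percent partition of `q_Pi` are reported alongside.
#'
#' @param K_Sec,K_Deg,K_Dil Time constants (min^-1), all positive.
#' @param cult A [cultivation_record()] providing `P_i`.
#' @return data.frame of class `flux_estimates` with rows `Pi`, `Deg`,
#'   `Sec`, `Dil` and columns `flux`, `q_ug_g_h`, `K_per_min`,
#'   `half_time_min`, `percent_of_qPi`.
#' @examples
#' cult <- cultivation_record(0.1, 91.8, 507.5)
#' K_Dil <- estimate_K_Dil(cult)
#' K_Sec <- estimate_K_Sec(cult, K_Dil)
#' compute_rates(K_Sec, 0.0151, K_Dil, cult)
#' @export
compute_rates <- function(K_Sec, K_Deg, K_Dil, cult) {
  stopifnot(inherits(cult, "cultivation_record"))
  if (any(c(K_Sec, K_Deg, K_Dil) <= 0)) {
    stop("all time constants must be positive", call. = FALSE)
  }
  K <- c(Sec = K_Sec, Deg = K_Deg, Dil = K_Dil)
  q <- K * cult$P_i * 60
  q_Pi <- sum(q)
  out <- data.frame(
    flux = c("Pi", "Deg", "Sec", "Dil"),
    q_ug_g_h = c(q_Pi, q[["Deg"]], q[["Sec"]], q[["Dil"]]),
    K_per_min = c(NA_real_, K[["Deg"]], K[["Sec"]], K[["Dil"]]),
    half_time_min = c(NA_real_, half_time(K[["Deg"]]),
                      half_time(K[["Sec"]]), half_time(K[["Dil"]])),
    percent_of_qPi = 100 * c(q_Pi, q[["Deg"]], q[["Sec"]], q[["Dil"]]) / q_Pi
  )
  class(out) <- c("flux_estimates", "data.frame")
  out
}

#' Relative standard deviations across replicates
#'
#' Spread of replicate-level estimates, reported the way chemostat
#' duplicates are usually summarised: sample standard deviation divided by
#' the mean.  Quantities with a single replicate get `NA` instead of a
#' spurious zero.
#'
#' @param values Numeric vector of replicate-level values of one quantity,
#'   or a data.frame whose numeric columns are summarised column-wise.
#' @return For a vector, a list with `mean`, `sd`, `rel_std`; for a
#'   data.frame, a data.frame with one row per numeric column.
#' @examples
#' propagate_uncertainty(c(0.0240, 0.0258))  # rel_std ~ 5.1%
#' @export
propagate_uncertainty <- function(values) {
  summarise1 <- function(v) {
    v <- v[is.finite(v)]
    m <- mean(v)
    s <- if (length(v) >= 2) sd(v) else NA_real_
    list(mean = m, sd = s, rel_std = if (is.na(s)) NA_real_ else s / m)
  }
  if (is.data.frame(values)) {
    num <- names(values)[vapply(values, is.numeric, logical(1))]
    rows <- lapply(num, function(nm) {
      s <- summarise1(values[[nm]])
      data.frame(quantity = nm, mean = s$mean, sd = s$sd,
                 rel_std = s$rel_std)
    })
    return(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  }
  summarise1(values)
}

#' Check the residual 32S level of the media sulfate pool
#'
#' The decay analysis assumes that newly synthesised protein carries
#' essentially no 32S, which holds only while the 32S fraction of the
#' small-molecule sulfur pool in the medium stays below about 1%.  This
#' gate inspects the `media_small_molecule` records and warns — or, with
#' `hard_fail = TRUE`, errors — when the maximum exceeds the threshold.
#'
#' @param ts Labeling series.
#' @param threshold Maximum tolerated media 32S fraction (default 0.01).
#' @param hard_fail Error instead of warn when exceeded.
#' @return List with `max_frac32` (NA when no media records) and `ok`.
#' @export
check_media_labeling <- function(ts, threshold = 0.01, hard_fail = FALSE) {
  validate_labeling(ts)
  media <- ts$frac32[ts$compartment == "media_small_molecule"]
  if (length(media) == 0) {
    return(list(max_frac32 = NA_real_, ok = NA))
  }
  mx <- max(media)
  ok <- mx <= threshold
  if (!ok) {
    msg <- sprintf(paste0("media small-molecule 32S fraction reaches %.3f,",
                          " above the %.3f threshold: residual unlabeled",
                          " sulfate may bias the decay slopes"),
                   mx, threshold)
    if (hard_fail) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  list(max_frac32 = mx, ok = ok)
}

#' Full estimation chain: labeling series to flux table
#'
#' Runs the complete inference: media-labeling gate, per-replicate impurity
#' background correction, log transform, per-replicate decay regression,
#' time constants from the cultivation record (`K_Dil` from the dilution
#' rate, `K_Sec` from the steady-state concentration ratio), per-replicate
#' `K_Deg` by subtraction, and the flux table with across-replicate
#' relative standard deviations.
#'
#' @param ts Labeling time series.
#' @param cult A [cultivation_record()].
#' @param cutoff_min Background cutoff passed to [correct_background()].
#' @param background `"constant"` (default) or `"linear"` background
#'   correction, or `"none"` to skip it; with `"none"` every usable
#'   intracellular point enters the regression (no cutoff window applies),
#'   which is exact when the data carry no impurity background.
#' @param media_threshold Gate threshold for [check_media_labeling()].
#' @param media_hard_fail Treat a media gate violation as an error.
#' @return List of class `secflux_fit`:
#'   `estimates` (the [compute_rates()] table using mean K_Deg),
#'   `constants` (K_Dil, K_Sec, K_Deg mean and per replicate, K_total),
#'   `regressions` (per-replicate [fit_decay()] rows),
#'   `uncertainty` (rel. STDs of K_total, K_Deg, q_Deg, q_Pi across
#'   replicates), `background`, `excluded`, `media_check`.
#' @export
estimate_fluxes <- function(ts, cult, cutoff_min = 140,
                            background = c("constant", "linear", "none"),
                            media_threshold = 0.01,
                            media_hard_fail = FALSE) {
  background <- match.arg(background)
  validate_labeling(ts)
  media <- check_media_labeling(ts, media_threshold,
                                hard_fail = media_hard_fail)
  if (background == "none") {
    corrected <- ts
    attr(corrected, "background") <- setNames(
      numeric(0), character(0))
    reg_input <- corrected
  } else {
    corrected <- correct_background(ts, cutoff_min = cutoff_min,
                                    method = background)
    # regression window: points past the cutoff are background, not signal
    reg_input <- corrected[!(corrected$compartment == "intracellular" &
                               corrected$time_min >= cutoff_min), ,
                           drop = FALSE]
  }
  pairs <- transform_for_regression(reg_input)
  regs <- fit_decay(pairs)

  K_Dil <- estimate_K_Dil(cult)
  K_Sec <- estimate_K_Sec(cult, K_Dil)
  K_Deg_rep <- estimate_K_Deg(regs$K_total, K_Sec, K_Dil)
  K_Deg <- mean(K_Deg_rep)

  per_rep <- data.frame(replicate_id = regs$replicate_id,
                        K_total = regs$K_total, K_Deg = K_Deg_rep,
                        q_Deg = K_Deg_rep * cult$P_i * 60)
  per_rep$q_Pi <- per_rep$q_Deg + (K_Sec + K_Dil) * cult$P_i * 60
  unc <- propagate_uncertainty(per_rep[c("K_total", "K_Deg", "q_Deg",
                                         "q_Pi")])

  structure(
    list(estimates = compute_rates(K_Sec, K_Deg, K_Dil, cult),
         constants = list(K_Dil = K_Dil, K_Sec = K_Sec, K_Deg = K_Deg,
                          K_Deg_per_replicate = setNames(K_Deg_rep,
                                                         regs$replicate_id),
                          K_total_mean = mean(regs$K_total)),
         regressions = regs,
         uncertainty = unc,
         background = attr(corrected, "background"),
         excluded = attr(pairs, "excluded"),
         media_check = media),
    class = "secflux_fit"
  )
}

#' @export
print.secflux_fit <- function(x, ...) {
  cat("Intracellular flux estimates (34S pulse-chase)\n\n")
  print(format(x$estimates, digits = 4), row.names = FALSE)
  cat(sprintf("\nMean decay slope magnitude K_total = %.4g min^-1 (%d replicate%s)\n",
              x$constants$K_total_mean, nrow(x$regressions),
              if (nrow(x$regressions) == 1) "" else "s"))
  if (!is.na(x$media_check$max_frac32)) {
    cat(sprintf("Media small-molecule 32S max: %.3f%%\n",
                100 * x$media_check$max_frac32))
  }
  invisible(x)
}

#' Reference flux table from printed constants
#'
#' Convenience path for the case where the decay slopes are not available
#' but a degradation time constant is: builds the complete flux table from
#' a cultivation record and `K_Deg` alone, deriving `K_Dil` and `K_Sec`
#' from the steady-state relations.
#'
#' @param cult A [cultivation_record()].
#' @param K_Deg Degradation time constant (min^-1).
#' @return A `flux_estimates` table, with the constants as attribute
#'   `"constants"`.
#' @export
reference_flux_table <- function(cult, K_Deg) {
  K_Dil <- estimate_K_Dil(cult)
  K_Sec <- estimate_K_Sec(cult, K_Dil)
  out <- compute_rates(K_Sec, K_Deg, K_Dil, cult)
  attr(out, "constants") <- list(K_Dil = K_Dil, K_Sec = K_Sec,
                                 K_Deg = K_Deg)
  out
}
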