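# In-silico experiments: one-at-a-time +/-50% sensitivity scan over a diurnal
# light regime, and the step-change light protocol with initial-slope and
# 2-h mean-response statistics.

#' One-at-a-time sensitivity scan
#'
#' Reruns the simulation with each adjustable parameter (the eleven calibrated
#' parameters, plus the mesophyll conductance `g_m` and the stomatal density
#' `SD`) scaled by `1 - fraction` and `1 + fraction` in turn, all others held
#' at their baseline values, and reports the ratio of the photoperiod mean of
#' `A` and of `g_s` to the baseline run. The photoperiod is the lights-on
#' window (`PPFD > 0`); a ratio of 1 means no impact.
#'
#' @param params Baseline [model_parameters()].
#' @param consts A [leaf_constants()] object.
#' @param fconsts A [farquhar_constants()] object.
#' @param env An [environment_series()] describing the diurnal light regime.
#' @param fraction Relative alteration (0.5 = +/-50%).
#' @param parameters Character vector of parameters to scan; defaults to the
#'   full adjustable set plus `g_m` and `SD`.
#' @param output_times Simulation output grid; defaults to the tabulated
#'   times of `env`.
#' @param ... Passed to [simulate_gas_exchange()].
#'
#' @return A data frame of class `sensitivity_result` with columns
#'   `parameter`, `direction` (`"-"`/`"+"`/`"baseline"`), `factor`,
#'   `A_ratio`, `gs_ratio`. The baseline row is exactly (1, 1); failed
#'   variant runs are recorded as `NA` with a warning.
#' @export
sensitivity_scan <- function(params = model_parameters(),
                             consts = leaf_constants(),
                             fconsts = farquhar_constants(),
                             env, fraction = 0.5, parameters = NULL,
                             output_times = NULL, ...) {
  stopifnot(inherits(env, "environment_series"))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  if (is.null(parameters))
    parameters <- c(names(unclass(params)), "SD")
  if (is.null(output_times)) output_times <- env$time

  run_mean <- function(p, cc) {
    sim <- simulate_gas_exchange(env, p, cc, fconsts,
                                 output_times = output_times, ...)
    on_idx <- sim$ppfd > 0
    c(A = mean(sim$A[on_idx]), g_s = mean(sim$g_s[on_idx]))
  }
  base <- run_mean(params, consts)

  rows <- list(data.frame(parameter = "baseline", direction = "baseline",
                          factor = 1, A_ratio = 1, gs_ratio = 1))
  for (nm in parameters) {
    for (dir in c("-", "+")) {
      fac <- if (dir == "-") 1 - fraction else 1 + fraction
      res <- tryCatch({
        if (nm == "SD") {
          cc <- consts; cc$SD <- consts$SD * fac
          run_mean(params, cc)
        } else {
          pl <- unclass(params); pl[[nm]] <- pl[[nm]] * fac
          run_mean(do.call(model_parameters, pl), consts)
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("sensitivity variant ", nm, dir, " failed: ",
                conditionMessage(res), call. = FALSE)
        res <- c(A = NA_real_, g_s = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, direction = dir, factor = fac,
        A_ratio = unname(res["A"] / base["A"]),
        gs_ratio = unname(res["g_s"] / base["g_s"]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Initial slope of a conductance response
#'
#' Ordinary least-squares slope of `g_s` against time over the window
#' `(t_step, t_step + window]` after a perturbation.
#'
#' @param time Time (s).
#' @param g_s Stomatal conductance (mol m^-2 s^-1).
#' @param t_step Time of the perturbation (s).
#' @param window Regression window length (s), default 600 s (10 min).
#' @return A list with `slope_per_s` (mol m^-2 s^-1 per s) and
#'   `slope_per_h` (mol m^-2 s^-1 per h).
#' @export
initial_slope <- function(time, g_s, t_step = 0, window = 600) {
  idx <- time > t_step & time <= t_step + window
  if (sum(idx) < 3)
    stop("need at least 3 points in the regression window", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(g_s[idx] ~ time[idx]))[2])
  list(slope_per_s = slope, slope_per_h = slope * 3600)
}

#' Step-change light experiment
#'
#' Simulates the standard step protocol — 30 min at 100 umol m^-2 s^-1
#' followed by a step to 1000 umol m^-2 s^-1 for 2 h, constant `Ca` = 400
#' umol mol^-1 and leaf temperature 25 C — for a reference parameter set and
#' a list of single-parameter variants (each scaling exactly one of `SD`,
#' `k_i`, `alpha_L`, ... by a given factor). Every run is initialised at its
#' own steady state under the pre-step light. For each run the initial
#' conductance slope over the first 10 min after the step is estimated by
#' ordinary least squares, and each variant's mean `A` and mean `W_i` over the
#' 2-h post-step window are compared with the reference as
#' `100 * (variant - reference) / reference`.
#'
#' @param params Reference [model_parameters()].
#' @param consts A [leaf_constants()] object.
#' @param fconsts A [farquhar_constants()] object.
#' @param variants Named list of scale factors, e.g.
#'   `list(SD = 0.5, k_i = 2, alpha_L = 0.5)`; names are parameter names or
#'   `"SD"`.
#' @param ppfd_low,ppfd_high Pre- and post-step light levels (umol m^-2 s^-1).
#' @param t_low,t_high Durations of the two phases (s).
#' @param Ca Atmospheric CO2 (umol mol^-1).
#' @param T_leaf Leaf temperature (C).
#' @param dt Output sampling interval (s).
#' @param slope_window Initial-slope regression window (s).
#' @param wi_aggregation `"mean_instantaneous"` (default) averages the
#'   instantaneous `W_i = A/g_s`; `"ratio_of_means"` uses
#'   `mean(A)/mean(g_s)`.
#' @param ... Passed to [simulate_gas_exchange()].
#'
#' @return An object of class `step_change_result`: a list with `reference`
#'   (trajectory + slope) and `variants`, each with the trajectory, its
#'   `slope` (per s and per h), and `dA_pct` / `dWi_pct`, the percent change
#'   of the 2-h post-step mean of `A` and `W_i` relative to the reference.
#' @export
step_change_experiment <- function(params = model_parameters(),
                                   consts = leaf_constants(),
                                   fconsts = farquhar_constants(),
                                   variants = list(SD = 0.5, k_i = 2,
                                                   alpha_L = 0.5),
                                   ppfd_low = 100, ppfd_high = 1000,
                                   t_low = 1800, t_high = 7200,
                                   Ca = 400, T_leaf = 25, dt = 10,
                                   slope_window = 600,
                                   wi_aggregation = c("mean_instantaneous",
                                                      "ratio_of_means"),
                                   ...) {
  wi_aggregation <- match.arg(wi_aggregation)
  env <- environment_series(
    time = c(-t_low, 0, 0, t_high), PPFD = c(ppfd_low, ppfd_low,
                                             ppfd_high, ppfd_high),
    Ca = Ca, T_leaf = T_leaf, interp = "constant")
  times <- seq(-t_low, t_high, by = dt)

  run_one <- function(p, cc) {
    ss <- steady_state(ppfd_low, p, cc, fconsts, Ca = Ca, T_leaf = T_leaf)
    sim <- simulate_gas_exchange(env, p, cc, fconsts, init = ss$state,
                                 output_times = times, ...)
    post <- sim$time > 0
    wi <- if (wi_aggregation == "mean_instantaneous")
      mean(sim$W_i[post]) else mean(sim$A[post]) / mean(sim$g_s[post])
    list(trajectory = sim,
         slope = initial_slope(sim$time, sim$g_s, t_step = 0,
                               window = slope_window),
         mean_A = mean(sim$A[post]), mean_Wi = wi)
  }

  ref <- run_one(params, consts)
  var_out <- list()
  for (nm in names(variants)) {
    fac <- variants[[nm]]
    if (nm == "SD") {
      cc <- consts; cc$SD <- consts$SD * fac
      v <- run_one(params, cc)
    } else {
      pl <- unclass(params)
      if (!nm %in% names(pl)) stop("unknown variant parameter: ", nm, call. = FALSE)
      pl[[nm]] <- pl[[nm]] * fac
      v <- run_one(do.call(model_parameters, pl), consts)
    }
    v$factor <- fac
    v$dA_pct <- 100 * (v$mean_A - ref$mean_A) / ref$mean_A
    v$dWi_pct <- 100 * (v$mean_Wi - ref$mean_Wi) / ref$mean_Wi
    var_out[[nm]] <- v
  }
  structure(list(reference = ref, variants = var_out,
                 protocol = list(ppfd_low = ppfd_low, ppfd_high = ppfd_high,
                                 t_low = t_low, t_high = t_high, Ca = Ca,
                                 T_leaf = T_leaf, dt = dt,
                                 wi_aggregation = wi_aggregation)),
            class = "step_change_result")
}

#' @export
print.step_change_result <- function(x, ...) {
  cat(sprintf("Step-change experiment: %g -> %g umol m^-2 s^-1\n",
              x$protocol$ppfd_low, x$protocol$ppfd_high))
  cat(sprintf("  reference initial g_s slope: %.3g mol m^-2 s^-1 h^-1\n",
              x$reference$slope$slope_per_h))
  for (nm in names(x$variants)) {
    v <- x$variants[[nm]]
    cat(sprintf("  %s x%g: mean A %+.2f%%, mean W_i %+.2f%%, slope %.3g /h\n",
                nm, v$factor, v$dA_pct, v$dWi_pct, v$slope$slope_per_h))
  }
  invisible(x)
}
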