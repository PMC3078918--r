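#' Fit a spot's progress curve to the exponential-association model
#'
#' The background-subtracted signal of each spot is fitted by nonlinear
#' least squares to
#' \deqn{y = y_0 + y_{max} (1 - e^{-k c})}
#' with `c` the pump-cycle number at which the image was recorded. The fit
#' is done in cycle units; conversion to minutes happens only when the
#' initial velocity is evaluated. When the nonlinear fit fails (or returns
#' a non-positive rate constant) the spot is kept on a fallback path: the
#' slope of an ordinary least-squares line over the first five points is
#' reported as the velocity, flagged `fallback`.
#'
#' @param series data.frame with columns `cycle`, `signal`, `background`
#'   (one spot's time series, >= 5 points).
#' @param cycles_per_min pumping rate, used for the minute-based velocity.
#' @param second_point_cycle cycle at which the initial tangent is taken
#'   (default cycle 4, the second imaged point, about 2 min).
#' @param qc_time_min time (min) of the quality-control signal `s20`.
#' @return object of class `exp_fit`: list with `y0`, `ymax`, `k`, their
#'   standard errors, `v` (initial velocity, signal units/min), `v_cycle`,
#'   `v0` (tangent at cycle 0), `rss`, `converged`, `fallback`, `s20`,
#'   `saturated`, `n_points`.
#' @export
#' @examples
#' s <- simulate_spot(50, 1000, noise_off())
#' fit <- fit_exponential(s)
#' c(fit$ymax, fit$k, fit$v0)
fit_exponential <- function(series, cycles_per_min = 2,
                            second_point_cycle = 4, qc_time_min = 20) {
  stopifnot(all(c("cycle", "signal", "background") %in% names(series)))
  if (nrow(series) < 5L) stop("need at least 5 time points", call. = FALSE)
  if (length(series$signal) != length(series$background)) {
    stop("signal and background lengths differ", call. = FALSE)
  }
  y <- series$signal - series$background
  cyc <- series$cycle
  ok <- is.finite(y) & is.finite(cyc)
  if (!any(ok)) stop("all-NaN series", call. = FALSE)
  y <- y[ok]; cyc <- cyc[ok]
  if (length(y) < 5L) stop("need at least 5 finite time points", call. = FALSE)
  ord <- order(cyc)
  y <- y[ord]; cyc <- cyc[ord]

  qc_cycle <- qc_time_min * cycles_per_min
  s20 <- y[which.min(abs(cyc - qc_cycle))]

  # starting values by variable projection: for fixed k the model is linear
  # in (y0, ymax), so profile them out and scan k on a log grid. This keeps
  # the fit well-initialised even on near-linear curves (k -> 0), where a
  # log-linearised estimate is useless.
  y0_0 <- y[1L]
  span <- max(y[length(y)] - y[1L], 1e-8)
  kgrid <- 10^seq(-5, 0.5, length.out = 45)
  prof <- vapply(kgrid, function(k) {
    basis <- 1 - exp(-k * cyc)
    f <- stats::lm.fit(cbind(1, basis), y)
    c(sum(f$residuals^2), f$coefficients)
  }, numeric(3))
  best <- which.min(prof[1L, ])
  k0 <- kgrid[best]
  y0_0 <- prof[2L, best]
  span <- max(prof[3L, best], 1e-8)

  # raw Levenberg-Marquardt (residual-function interface): robust to the
  # zero-residual case that arises when refitting noiseless curves.
  # Two stages: a default-tolerance fit, then a tight polish from its
  # optimum -- the polish matters for near-linear curves (k -> 0), where
  # the (y0, ymax, k) ridge leaves the first stage short of the optimum.
  resid_fn <- function(par) par[1L] + par[2L] * (1 - exp(-par[3L] * cyc)) - y
  run_lm <- function(start, ctrl) tryCatch(
    minpack.lm::nls.lm(par = start, lower = c(-Inf, 0, 1e-9),
                       upper = c(Inf, Inf, 10), fn = resid_fn,
                       control = ctrl),
    error = function(e) NULL)
  fit <- run_lm(c(y0 = y0_0, ymax = span, k = k0),
                minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(fit)) {
    polish <- run_lm(fit$par,
                     minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                                ptol = 1e-15))
    if (!is.null(polish) && polish$deviance <= fit$deviance) fit <- polish
  }

  make <- function(y0, ymax, k, se, rss, converged, fallback, v_fallback) {
    v <- if (converged) ymax * k * exp(-k * second_point_cycle) * cycles_per_min
         else v_fallback
    structure(list(y0 = y0, ymax = ymax, k = k,
                   y0_se = se[1L], ymax_se = se[2L], k_se = se[3L],
                   v = v, v_cycle = second_point_cycle,
                   v0 = if (converged) ymax * k * cycles_per_min else v_fallback,
                   rss = rss, converged = converged, fallback = fallback,
                   s20 = s20,
                   saturated = converged && (1 - exp(-k * 2)) > 0.999,
                   n_points = length(y), cycles_per_min = cycles_per_min),
              class = "exp_fit")
  }

  if (!is.null(fit) && all(is.finite(fit$par))) {
    cf <- fit$par
    if (cf[["k"]] > 1e-8) {
      se <- tryCatch(suppressWarnings(
        summary(fit)$coefficients[, "Std. Error"]),
        error = function(e) rep(NA_real_, 3))
      return(make(cf[["y0"]], cf[["ymax"]], cf[["k"]], unname(se),
                  fit$deviance, TRUE, FALSE, NA_real_))
    }
  }
  # fallback: linear slope over the first five points, per minute
  head5 <- seq_len(5L)
  sl <- stats::coef(stats::lm(y[head5] ~ cyc[head5]))[2L]
  make(y[1L], NA_real_, NA_real_, rep(NA_real_, 3), NA_real_,
       FALSE, TRUE, unname(sl) * cycles_per_min)
}

#' Initial velocity from a fitted progress curve
#'
#' Evaluates the tangent of the fitted exponential at the chosen cycle,
#' converted to minutes:
#' \deqn{v = y_{max} \, k \, e^{-k c} \cdot \mathrm{cycles/min}}
#' The default cycle 4 is the second imaged point (about 2 min) under the
#' default imaging scheme; `second_point_cycle = 0` gives the tangent at the
#' reaction start.
#'
#' @param fit an `exp_fit` from [fit_exponential()].
#' @param second_point_cycle cycle at which to take the tangent.
#' @return initial velocity (signal units / min).
#' @export
#' @examples
#' fit <- fit_exponential(simulate_spot(50, 1000, noise_off()))
#' initial_velocity(fit)      # tangent at cycle 4
#' initial_velocity(fit, 0)   # tangent at cycle 0, recovers 50
initial_velocity <- function(fit, second_point_cycle = 4) {
  stopifnot(inherits(fit, "exp_fit"))
  if (fit$fallback) return(fit$v)
  if (!is.finite(fit$ymax) || !is.finite(fit$k)) {
    stop("non-finite fit parameters", call. = FALSE)
  }
  fit$ymax * fit$k * exp(-fit$k * second_point_cycle) * fit$cycles_per_min
}

#' Extract initial velocities for every spot of a dataset
#'
#' Groups a long-format dataset by run condition and spot, fits each time
#' series with [fit_exponential()] and tabulates the velocities with their
#' QC fields. Per-spot fit failures are propagated as fallback rows, never
#' fatal.
#'
#' @param dataset long data.frame with columns `construct`, `control`,
#'   `enzyme_pmol`, `atp_uM`, `replicate`, `peptide_id`, `conc_uM`, `cycle`,
#'   `signal`, `background` (e.g. from [simulate_experiment()]).
#' @param second_point_cycle,cycles_per_min,qc_time_min see
#'   [fit_exponential()].
#' @return data.frame with one row per (condition, peptide, concentration,
#'   replicate): the grouping columns plus `v`, `v0`, `y0`, `ymax`, `k`,
#'   `converged`, `fallback`, `saturated`, `s20`, `n_points`.
#' @export
extract_rates <- function(dataset, second_point_cycle = 4,
                          cycles_per_min = 2, qc_time_min = 20) {
  keys <- c("construct", "control", "enzyme_pmol", "atp_uM", "replicate",
            "peptide_id", "conc_uM")
  empty <- data.frame(construct = character(), control = character(),
                      enzyme_pmol = numeric(), atp_uM = numeric(),
                      replicate = integer(), peptide_id = character(),
                      conc_uM = numeric(), v = numeric(), v0 = numeric(),
                      y0 = numeric(), ymax = numeric(), k = numeric(),
                      converged = logical(), fallback = logical(),
                      saturated = logical(), s20 = numeric(),
                      n_points = integer(), stringsAsFactors = FALSE)
  if (is.null(dataset) || nrow(dataset) == 0L) return(empty)
  stopifnot(all(c(keys, "cycle", "signal", "background") %in% names(dataset)))
  grp <- interaction(dataset[keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(dataset)), grp), function(ix) {
    d <- dataset[ix, ]
    fit <- fit_exponential(d[order(d$cycle), c("cycle", "signal", "background")],
                           cycles_per_min = cycles_per_min,
                           second_point_cycle = second_point_cycle,
                           qc_time_min = qc_time_min)
    cbind(d[1L, keys, drop = FALSE],
          data.frame(v = fit$v, v0 = fit$v0, y0 = fit$y0, ymax = fit$ymax,
                     k = fit$k, converged = fit$converged,
                     fallback = fit$fallback, saturated = fit$saturated,
                     s20 = fit$s20, n_points = fit$n_points))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$construct, out$control, out$enzyme_pmol, out$atp_uM,
                   out$peptide_id, out$conc_uM, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  out
}
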