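#' Normalize a rate table to a reference peptide
#'
#' Expresses initial velocities relative to the construct's activity on a
#' reference spot (by default 1000 uM STA5A_687_699), then per pmol of
#' enzyme: within each construct every velocity is scaled by
#' `ref_value / v_ref` and divided by the enzyme amount of its run. The
#' reference cell itself maps to `ref_value / pmol`. `ref_value = 100`
#' gives the percent-of-reference scale; simulation round-trips can instead
#' pass the known reference activity to express results on the ground-truth
#' scale.
#'
#' @param rate_table data.frame from [extract_rates()] (needs `construct`,
#'   `peptide_id`, `conc_uM`, `enzyme_pmol`, `v`).
#' @param reference_peptide,reference_conc_uM the reference spot.
#' @param ref_value normalized value assigned to the reference spot
#'   (before the per-pmol division).
#' @param per_pmol divide by each run's enzyme amount.
#' @return `rate_table` with `v` replaced by the normalized velocity and a
#'   `v_raw` column holding the input values.
#' @export
normalize_activity <- function(rate_table,
                               reference_peptide = "STA5A_687_699",
                               reference_conc_uM = 1000, ref_value = 100,
                               per_pmol = TRUE) {
  stopifnot(nrow(rate_table) > 0)
  out <- list()
  for (construct in unique(rate_table$construct)) {
    rt <- rate_table[rate_table$construct == construct, , drop = FALSE]
    ref <- rt[rt$peptide_id == reference_peptide &
                rt$conc_uM == reference_conc_uM &
                rt$control == "none", , drop = FALSE]
    v_ref <- mean(ref$v)
    if (!nrow(ref) || !is.finite(v_ref) || v_ref <= 0) {
      stop("missing or non-positive reference velocity (",
           reference_peptide, " at ", reference_conc_uM, " uM) for construct ",
           construct, call. = FALSE)
    }
    rt$v_raw <- rt$v
    rt$v <- ref_value * rt$v / v_ref
    if (per_pmol) rt$v <- rt$v / rt$enzyme_pmol
    out[[construct]] <- rt
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the Michaelis-Menten dependence of velocity on ATP
#'
#' Nonlinear least-squares fit of
#' \deqn{v = V_{max,app} [ATP] / (K_m + [ATP])}
#' to velocities measured over an ATP titration at fixed peptide
#' concentration. Standard errors come from the fit covariance. A fitted
#' Km beyond four times the largest ATP concentration flags the result as
#' extrapolated (non-saturating titration).
#'
#' @param atp_uM ATP concentrations (uM); at least 4 distinct levels with
#'   at least one nonzero. Alternatively a data.frame with columns
#'   `atp_uM` and `v`.
#' @param v velocities (ignored when `atp_uM` is a data.frame).
#' @param weighting `"relative"` (default) scales residuals by the
#'   predicted velocity, appropriate for the multiplicative noise of
#'   fluorescence read-outs and giving calibrated standard errors under
#'   it; `"none"` is the unweighted least-squares fit.
#' @return object of class `mm_fit`: list with `km_uM`, `km_se`,
#'   `vmax_app`, `vmax_se`, `r_squared`, `n_points`, `extrapolated`,
#'   `converged`.
#' @export
#' @examples
#' atp <- c(12.5, 25, 50, 100, 200, 400)
#' fit_mm_atp(atp, 100 * atp / (50 + atp))
fit_mm_atp <- function(atp_uM, v = NULL,
                       weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(atp_uM)) {
    v <- atp_uM$v
    atp_uM <- atp_uM$atp_uM
  }
  ok <- is.finite(atp_uM) & is.finite(v)
  atp_uM <- atp_uM[ok]; v <- v[ok]
  if (length(unique(atp_uM)) < 4L || all(atp_uM == 0)) {
    stop("need >= 4 distinct ATP levels with at least one nonzero",
         call. = FALSE)
  }
  vmax0 <- max(v)
  km0 <- atp_uM[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(atp_uM[atp_uM > 0])
  # the weight floor keeps the zero-ATP anchor from dominating
  floor_w <- 0.05 * max(abs(v))
  resid_fn <- function(par) {
    pred <- par[1L] * atp_uM / (par[2L] + atp_uM)
    r <- pred - v
    if (weighting == "relative") r / pmax(abs(pred), floor_w) else r
  }
  fit <- minpack.lm::nls.lm(
    par = c(vmax = vmax0, km = km0), lower = c(0, 1e-6), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- fit$par
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) c(vmax = NA_real_, km = NA_real_))
  tss <- sum((v - mean(v))^2)
  rss <- sum((v - cf[["vmax"]] * atp_uM / (cf[["km"]] + atp_uM))^2)
  structure(list(km_uM = unname(cf[["km"]]), km_se = unname(se[["km"]]),
                 vmax_app = unname(cf[["vmax"]]),
                 vmax_se = unname(se[["vmax"]]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n_points = length(v),
                 extrapolated = unname(cf[["km"]]) > 4 * max(atp_uM),
                 converged = fit$info %in% 1:4),
            class = "mm_fit")
}

#' Catalytic efficiency from the linear low-concentration regime
#'
#' When the peptide concentration is well below its Michaelis constant the
#' velocity-versus-concentration relation is linear and Vmax/Km is its
#' slope. Replicate velocities are averaged per concentration, then an
#' ordinary least-squares line with free intercept is fitted over the
#' selected range. By default all concentration levels enter the fit; with
#' `truncate = TRUE` the highest concentration is dropped (repeatedly)
#' while doing so raises R-squared by more than `truncate_gain`.
#'
#' @param conc_uM peptide concentrations (uM), or a data.frame with columns
#'   `conc_uM` and `v` (replicate rows allowed).
#' @param v velocities (ignored when `conc_uM` is a data.frame).
#' @param truncate enable top-point truncation.
#' @param truncate_gain minimum R-squared gain to drop the top level.
#' @param force_origin fit through the origin instead of a free intercept.
#' @return object of class `efficiency_fit`: list with `vmax_km` (slope),
#'   `slope_se`, `r_squared`, `intercept`, `conc_used`, `n_levels`,
#'   `non_substrate` (negative slope flag).
#' @export
#' @examples
#' concs <- c(100, 300, 400, 600, 750, 1000)
#' efficiency_from_linear(concs, 0.1 * concs)
efficiency_from_linear <- function(conc_uM, v = NULL, truncate = FALSE,
                                   truncate_gain = 0.05,
                                   force_origin = FALSE) {
  if (is.data.frame(conc_uM)) {
    v <- conc_uM$v
    conc_uM <- conc_uM$conc_uM
  }
  ok <- is.finite(conc_uM) & is.finite(v)
  means <- tapply(v[ok], conc_uM[ok], mean)
  concs <- as.numeric(names(means))
  ord <- order(concs)
  concs <- concs[ord]; means <- as.numeric(means)[ord]
  if (length(concs) < 3L) {
    stop("need >= 3 concentration levels", call. = FALSE)
  }
  ols <- function(x, y) {
    fit <- if (force_origin) stats::lm(y ~ 0 + x) else stats::lm(y ~ x)
    # noiseless round-trips fit exactly; the perfect-fit warning is expected
    sm <- suppressWarnings(summary(fit))
    cf <- sm$coefficients
    slope_row <- if (force_origin) 1L else 2L
    list(slope = cf[slope_row, 1L], se = cf[slope_row, 2L],
         intercept = if (force_origin) 0 else cf[1L, 1L],
         r2 = sm$r.squared)
  }
  cur <- ols(concs, means)
  used <- concs
  if (truncate) {
    while (length(used) > 3L) {
      cand <- ols(used[-length(used)], means[seq_len(length(used) - 1L)])
      if (cand$r2 - cur$r2 > truncate_gain) {
        used <- used[-length(used)]
        means <- means[seq_along(used)]
        cur <- cand
      } else break
    }
  }
  structure(list(vmax_km = unname(cur$slope), slope_se = unname(cur$se),
                 r_squared = cur$r2, intercept = unname(cur$intercept),
                 conc_used = used, n_levels = length(used),
                 non_substrate = unname(cur$slope) < 0),
            class = "efficiency_fit")
}

#' Catalytic-efficiency table for every (construct, peptide) pair
#'
#' Runs [efficiency_from_linear()] on each construct/peptide cell of a
#' (typically normalized) rate table measured at a single ATP level.
#'
#' @param rate_table data.frame with `construct`, `peptide_id`, `conc_uM`,
#'   `v` (replicate rows allowed); reaction rows only (`control == "none"`
#'   is selected when a `control` column is present).
#' @param atp_uM restrict to this ATP level when an `atp_uM` column is
#'   present (default 400, the near-saturating level); `NULL` uses all rows.
#' @param ... forwarded to [efficiency_from_linear()].
#' @return data.frame with one row per (construct, peptide): `vmax_km`,
#'   `vmax_km_se`, `r_squared`, `intercept`, `n_levels`, `non_substrate`.
#' @export
efficiency_table <- function(rate_table, atp_uM = 400, ...) {
  rt <- rate_table
  if ("control" %in% names(rt)) rt <- rt[rt$control == "none", , drop = FALSE]
  if (!is.null(atp_uM) && "atp_uM" %in% names(rt)) {
    rt <- rt[rt$atp_uM == atp_uM, , drop = FALSE]
  }
  stopifnot(nrow(rt) > 0)
  grp <- interaction(rt$construct, rt$peptide_id, drop = TRUE)
  rows <- lapply(split(rt, grp), function(d) {
    fit <- efficiency_from_linear(d[, c("conc_uM", "v")], ...)
    data.frame(construct_id = d$construct[1L], peptide_id = d$peptide_id[1L],
               vmax_km = fit$vmax_km, vmax_km_se = fit$slope_se,
               r_squared = fit$r_squared, intercept = fit$intercept,
               n_levels = fit$n_levels, non_substrate = fit$non_substrate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$construct_id, out$peptide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
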