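#' Steady-state microvascular mapping
#'
#' Analytic comparators computed from the same GESFIDE pre/post pair: the
#' contrast-agent-induced relaxation-rate changes delta-R2* (FID echoes) and
#' delta-R2 (spin echo), the steady-state blood volume fraction
#' \deqn{BVf = 3\,\Delta R_2^* / (\gamma B_0 \Delta\chi_{USPIO})}
#' and the vessel size index
#' \deqn{VSI = 0.867\sqrt{ADC/(\gamma B_0 \Delta\chi_{USPIO})}\,
#'       (\Delta R_2^*/\Delta R_2)^{3/2},}
#' with all susceptibilities in SI units (so the 1/3 static-dephasing
#' prefactor applies; the familiar 4pi/3 form belongs to cgs
#' susceptibilities), plus the multiparametric quantitative BOLD (mqBOLD)
#' oxygenation fit
#' \deqn{S(t) = Cte\,e^{-t/T_2}\,
#'       e^{-BVf\,\gamma B_0 \Delta\chi_0 Hct (1 - StO_2)\, t / 3}}
#' applied to multi-gradient-echo decays beyond 10 ms.
#'
#' @name steadystate
NULL

#' Contrast-induced R2* change from the FID echoes
#'
#' Least-squares slope of `ln(pre/post)` against time over the pre-pulse
#' (FID) echoes; echo 1 is skipped as transient by default.
#'
#' @param pre,post `mrvf_signal` objects or magnitude vectors.
#' @param fid_echoes Indices of FID echoes used for the fit (default 2:8).
#' @param echo_times Echo times (ms) when bare vectors are given.
#' @return delta-R2* in 1/s, or `NA` (excluded) on non-positive signals.
#' @export
delta_r2star <- function(pre, post, fid_echoes = 2:8, echo_times = NULL) {
  if (inherits(pre, "mrvf_signal")) { echo_times <- pre$times
    pre <- pre$signal; post <- post$signal }
  stopifnot(length(fid_echoes) >= 2, max(fid_echoes) <= length(pre))
  s_pre <- pre[fid_echoes]; s_post <- post[fid_echoes]
  if (any(!is.finite(s_pre)) || any(!is.finite(s_post)) ||
      any(s_pre <= 0) || any(s_post <= 0)) return(NA_real_)
  t_s <- echo_times[fid_echoes] * 1e-3
  y <- log(s_pre / s_post)
  unname(stats::coef(stats::lm(y ~ t_s))[2])
}

#' Contrast-induced R2 change from the spin echo
#'
#' `ln(pre/post) / t` evaluated at the echo nearest the spin-echo time.
#'
#' @param pre,post `mrvf_signal` objects or magnitude vectors.
#' @param se_time Spin-echo time, ms.
#' @param echo_times Echo times (ms) when bare vectors are given.
#' @return delta-R2 in 1/s, or `NA` (excluded) on non-positive signals.
#' @export
delta_r2 <- function(pre, post, se_time = 60, echo_times = NULL) {
  if (inherits(pre, "mrvf_signal")) { echo_times <- pre$times
    pre <- pre$signal; post <- post$signal }
  i <- which.min(abs(echo_times - se_time))
  if (!is.finite(pre[i]) || !is.finite(post[i]) || pre[i] <= 0 ||
      post[i] <= 0) return(NA_real_)
  log(pre[i] / post[i]) / (echo_times[i] * 1e-3)
}

#' Steady-state blood volume fraction
#'
#' @param dr2star delta-R2*, 1/s.
#' @param physics An `mrvf_physics`.
#' @return BVf as a fraction.
#' @export
#' @examples
#' ph <- physics_constants()
#' bvf_steadystate(73.34, ph)  # ~0.05
bvf_steadystate <- function(dr2star, physics = physics_constants()) {
  3 * dr2star / (physics$gamma * physics$b0 * physics$delta_chi_uspio * 1e-6)
}

#' Vessel size index
#'
#' @param dr2star delta-R2*, 1/s.
#' @param dr2 delta-R2, 1/s (must be positive).
#' @param adc ADC, um^2/s.
#' @param physics An `mrvf_physics`.
#' @param prefactor Dimensionless prefactor of the VSI expression (default
#'   0.867 with SI susceptibilities; configurable because published variants
#'   differ in the susceptibility unit convention they assume).
#' @return VSI in micrometers; `NA` (excluded) when `dr2 <= 0`.
#' @export
vsi <- function(dr2star, dr2, adc, physics = physics_constants(),
                prefactor = 0.867) {
  out <- rep(NA_real_, length(dr2))
  adc <- rep(adc, length.out = length(dr2))
  ok <- is.finite(dr2) & dr2 > 0 & is.finite(dr2star)
  scale <- physics$gamma * physics$b0 * physics$delta_chi_uspio * 1e-6  # 1/s
  out[ok] <- prefactor * sqrt(adc[ok] / scale) * (dr2star[ok] / dr2[ok])^1.5
  out
}

#' mqBOLD oxygen saturation fit
#'
#' Fits `S(t) = Cte * exp(-t/T2) * exp(-A (1 - StO2) t)` with
#' `A = BVf * gamma * B0 * delta_chi0 * Hct / 3` to a multi-gradient-echo
#' decay over echoes beyond `fit_after` ms, for (Cte, StO2). Nonlinear least
#' squares started from the log-linear solution; non-convergence or StO2
#' outside \[0, 1\] yields `NA` (excluded voxel).
#'
#' @param mge_signal Magnitude decay.
#' @param echo_times Echo times, ms.
#' @param t2 T2 of the voxel, ms.
#' @param bvf Blood volume fraction (fraction in (0, 0.17]).
#' @param physics An `mrvf_physics`.
#' @param fit_after Fit window lower bound, ms (default 10).
#' @return StO2 as a fraction, or `NA`.
#' @export
qbold_sto2 <- function(mge_signal, echo_times, t2, bvf,
                       physics = physics_constants(), fit_after = 10) {
  stopifnot(t2 > 0)
  if (!is.finite(bvf) || bvf <= 0 || bvf > 0.17) return(NA_real_)
  win <- echo_times > fit_after
  if (sum(win) < 3) return(NA_real_)
  s <- mge_signal[win]; t_s <- echo_times[win] * 1e-3
  if (any(!is.finite(s)) || any(s <= 0)) return(NA_real_)
  A <- bvf * physics$gamma * physics$b0 * physics$delta_chi0 * 1e-6 *
    physics$hct / 3                                       # 1/s at StO2 = 0
  # log-linear start: slope = -1/T2 - A (1 - StO2)
  co <- stats::coef(stats::lm(log(s) ~ t_s))
  sto2_0 <- 1 - (-co[2] - 1000 / t2) / A
  cte_0 <- exp(co[1])
  fit <- try(minpack.lm::nlsLM(
    s ~ cte * exp(-t_s * 1000 / t2) * exp(-A * (1 - sto2) * t_s),
    start = list(cte = cte_0, sto2 = min(max(sto2_0, 0), 1)),
    lower = c(0, -0.5), upper = c(Inf, 1.5),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NA_real_)
  sto2 <- unname(stats::coef(fit)["sto2"])
  if (sto2 < 0 || sto2 > 1) return(NA_real_)
  sto2
}

#' Mono-exponential T2 fit
#'
#' Log-linear least-squares fit of a multi-spin-echo decay, the standard
#' estimator for MSME T2 mapping.
#'
#' @param signal Magnitude decay.
#' @param echo_times Echo times, ms.
#' @return T2 in ms, or `NA` on non-positive input or non-decaying fit.
#' @export
t2_fit <- function(signal, echo_times) {
  if (any(!is.finite(signal)) || any(signal <= 0)) return(NA_real_)
  co <- stats::coef(stats::lm(log(signal) ~ echo_times))
  if (co[2] >= 0) return(NA_real_)
  unname(-1 / co[2])
}

#' Validity ranges and exclusion of steady-state maps
#'
#' Voxels outside the validity ranges of the analytic methods are excluded:
#' ADC 0-3500 um^2/s, BVf 0-17\%, VSI 0-50 um, StO2 0-100\%.
#'
#' @param bvf,vsi,sto2,adc Numeric vectors/arrays (fractions for bvf/sto2,
#'   um for vsi, um^2/s for adc); `NULL` entries are not tested.
#' @return Logical exclusion indicator of the common shape.
#' @export
steadystate_exclusion <- function(bvf = NULL, vsi = NULL, sto2 = NULL,
                                  adc = NULL) {
  ex <- NULL
  fold <- function(ex, bad) if (is.null(ex)) bad else ex | bad
  rng <- function(x, lo, hi) !is.finite(x) | x < lo | x > hi
  if (!is.null(adc)) ex <- fold(ex, rng(adc, 0, 3500))
  if (!is.null(bvf)) ex <- fold(ex, rng(bvf, 0, 0.17))
  if (!is.null(vsi)) ex <- fold(ex, rng(vsi, 0, 50))
  if (!is.null(sto2)) ex <- fold(ex, rng(sto2, 0, 1))
  ex
}

#' Steady-state maps from pre/post echo volumes
#'
#' Volume-level wrapper: computes delta-R2*, delta-R2, steady-state BVf and
#' VSI per voxel from pre/post GESFIDE volumes and an ADC map, applying the
#' printed validity ranges.
#'
#' @param pre4d,post4d 4D arrays (x, y, slice, echo).
#' @param echo_times Echo times, ms.
#' @param adc_map 3D ADC array, um^2/s.
#' @param physics An `mrvf_physics`.
#' @param fid_echoes FID echo indices for the delta-R2* fit.
#' @param se_time Spin-echo time, ms.
#' @return An object of class `mrvf_ss_maps`: list of 3D arrays `delta_r2`,
#'   `delta_r2_star`, `bvf_ss`, `vsi`, and `excluded`.
#' @export
steadystate_maps <- function(pre4d, post4d, echo_times, adc_map,
                             physics = physics_constants(),
                             fid_echoes = 2:8, se_time = 60) {
  if (!identical(dim(pre4d), dim(post4d)))
    stop("pre and post volumes have different shapes", call. = FALSE)
  shp <- dim(pre4d)[1:3]
  if (!identical(dim(adc_map), shp))
    stop("ADC map shape does not match the echo volumes", call. = FALSE)
  mk <- function() array(NA_real_, shp)
  dr2s <- mk(); dr2 <- mk()
  for (k in seq_len(shp[3])) for (j in seq_len(shp[2])) for (i in seq_len(shp[1])) {
    p <- pre4d[i, j, k, ]; q <- post4d[i, j, k, ]
    dr2s[i, j, k] <- delta_r2star(p, q, fid_echoes, echo_times)
    dr2[i, j, k] <- delta_r2(p, q, se_time, echo_times)
  }
  bvf <- bvf_steadystate(dr2s, physics)
  v <- vsi(dr2s, dr2, adc_map, physics)
  dim(v) <- shp
  excl <- steadystate_exclusion(bvf = bvf, vsi = v, adc = adc_map)
  structure(list(delta_r2 = dr2, delta_r2_star = dr2s, bvf_ss = bvf,
                 vsi = v, excluded = excl),
            class = "mrvf_ss_maps")
}
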