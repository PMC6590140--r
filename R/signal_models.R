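# Forward signal models: the physics the fitters invert.

#' EPG echo amplitudes for a CPMG train
#'
#' Extended-phase-graph recursion for a 90x excitation followed by `etl`
#' refocusing pulses of actual angle `refocus_actual` (B1-scaled), with T2
#' decay of transverse configuration states and T1 decay of longitudinal
#' states over each half echo-spacing, ideal crushers, and echo i read as
#' |F0| after the i-th pulse.  At 180 degrees this reduces exactly to
#' mono-exponential decay exp(-i*te/t2).
#'
#' @param t2,t1 relaxation times (ms).
#' @param protocol a [grase_protocol()].
#' @param refocus_actual actual refocusing angle beta in (0, 180] degrees.
#' @return numeric vector of `etl` echo amplitudes (unit magnetization).
#' @export
epg_cpmg_decay <- function(t2, t1, protocol = grase_protocol(),
                           refocus_actual = protocol$refocus_nominal) {
  stopifnot(inherits(protocol, "grase_protocol"))
  if (refocus_actual <= 0 || refocus_actual > 180)
    stop("refocusing angle must be in (0, 180]")
  as.numeric(cpp_epg_cpmg(t2, t1, protocol$te, protocol$etl, refocus_actual))
}

#' Multi-component CPMG decay
#'
#' Linear combination of EPG decays over a T2 component set; models tissue
#' water as a sum of exponential-like pools with a common T1.
#'
#' @param weights non-negative component weights.
#' @param t2_times component T2 times (ms), same length as `weights`.
#' @param t1 common T1 (ms).
#' @param protocol a [grase_protocol()].
#' @param refocus_actual refocusing angle (degrees).
#' @return echo amplitude vector (length `etl`).
#' @export
multicomponent_decay <- function(weights, t2_times, t1,
                                 protocol = grase_protocol(),
                                 refocus_actual = protocol$refocus_nominal) {
  if (length(weights) != length(t2_times))
    stop("weights and t2_times must have equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  A <- cpp_epg_basis(as.numeric(t2_times), t1, protocol$te, protocol$etl,
                     refocus_actual)
  as.numeric(A %*% weights)
}

#' Spoiled gradient-echo (SPGR) steady-state signal
#'
#' `S = m0 sin(k a) (1 - E1) / (1 - cos(k a) E1)`, `E1 = exp(-tr/t1)`.
#' Vectorized over any argument.
#'
#' @param m0 equilibrium magnetization (a.u.).
#' @param t1 longitudinal relaxation time (ms).
#' @param alpha nominal flip angle (degrees).
#' @param tr repetition time (ms).
#' @param b1_scale transmit-field scale kappa (actual/nominal flip).
#' @return signal (a.u.).
#' @export
spgr_signal <- function(m0, t1, alpha, tr, b1_scale = 1) {
  if (any(t1 <= 0)) stop("t1 must be positive")
  a <- b1_scale * alpha * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' IR-SPGR signal (simplified single-recovery form)
#'
#' `S = |m0 sin(k a) (1 - 2 eff exp(-ti/t1) + exp(-tr_total/t1))|`; the
#' readout train's perturbation of recovery is compressed into the single
#' effective recovery period `ir_tr_total`.
#'
#' @param m0,t1 magnetization and T1 (ms).
#' @param protocol an [mcdespot_protocol()] (uses `ir_ti`, `ir_alpha`,
#'   `ir_tr_total`, `inv_efficiency`).
#' @param b1_scale transmit scale kappa.
#' @param inv_efficiency overrides the protocol inversion efficiency.
#' @return signal magnitude (a.u.).
#' @export
irspgr_signal <- function(m0, t1, protocol = mcdespot_protocol(),
                          b1_scale = 1,
                          inv_efficiency = protocol$inv_efficiency) {
  stopifnot(inv_efficiency > 0, inv_efficiency <= 1)
  a <- b1_scale * protocol$ir_alpha * pi / 180
  abs(m0 * sin(a) * (1 - 2 * inv_efficiency * exp(-protocol$ir_ti / t1) +
                       exp(-protocol$ir_tr_total / t1)))
}

#' Balanced SSFP steady-state signal
#'
#' Steady state of (rotation by kappa*alpha about x) followed by (precession
#' by theta = 2*pi*delta_f0*tr + phase_cycle about z with E1/E2 relaxation),
#' solved as a 3x3 linear system per voxel (vectorized Cramer's rule);
#' magnitude read at TE = tr/2.
#'
#' @param m0,t1,t2 magnetization and relaxation times (ms); `t2 <= t1`.
#' @param alpha flip angle (degrees).
#' @param tr repetition time (ms).
#' @param delta_f0 off-resonance (Hz).
#' @param phase_cycle RF phase-cycling increment (degrees).
#' @param b1_scale transmit scale kappa.
#' @return signal magnitude (a.u.).
#' @export
bssfp_signal <- function(m0, t1, t2, alpha, tr, delta_f0 = 0,
                         phase_cycle = 180, b1_scale = 1) {
  if (any(t2 > t1)) stop("t2 must not exceed t1")
  a <- b1_scale * alpha * pi / 180
  th <- 2 * pi * delta_f0 * tr / 1000 + phase_cycle * pi / 180
  e1 <- exp(-tr / t1); e2 <- exp(-tr / t2)
  ca <- cos(a); sa <- sin(a); ct <- cos(th); st <- sin(th)
  # A = I - D Rz(theta) Rx(a), c = (0, 0, (1-E1) m0)
  a11 <- 1 - e2 * ct; a12 <- e2 * st * ca; a13 <- -e2 * st * sa
  a21 <- -e2 * st;    a22 <- 1 - e2 * ct * ca; a23 <- e2 * ct * sa
  a31 <- 0;           a32 <- -e1 * sa;         a33 <- 1 - e1 * ca
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  if (any(abs(det) < 1e-14)) stop("singular bSSFP steady-state system")
  c3 <- (1 - e1) * m0
  # Cramer: replace column k by (0, 0, c3)
  mx <- (c3 * (a12 * a23 - a13 * a22)) / det
  my <- (c3 * (a13 * a21 - a11 * a23)) / det
  mz <- (c3 * (a11 * a22 - a12 * a21)) / det
  # after-pulse transverse, half-TR T2 decay; precession phase is global
  mxp <- mx
  myp <- my * ca - mz * sa
  exp(-tr / 2 / t2) * sqrt(mxp^2 + myp^2)
}

#' Two-pool mcDESPOT parameter set
#'
#' @param m0 total magnetization (a.u.).
#' @param f_m myelin-water fraction in `[0, 1)`.
#' @param t1_m,t1_f,t2_m,t2_f pool relaxation times (ms), myelin < free.
#' @param k_mf myelin-to-free exchange rate (1/s); the reverse rate follows
#'   from detailed balance `k_fm = k_mf f_m / (1 - f_m)`.
#' @param delta_f0 off-resonance (Hz).
#' @param b1_scale transmit scale kappa.
#' @return named numeric vector of class `two_pool_params`.
#' @export
two_pool_params <- function(m0 = 1, f_m = 0.15, t1_m = 400, t1_f = 1100,
                            t2_m = 20, t2_f = 80, k_mf = 9, delta_f0 = 0,
                            b1_scale = 1) {
  stopifnot(f_m >= 0, f_m < 1, t1_m > 0, t1_f > 0, t2_m > 0, t2_f > 0,
            k_mf >= 0)
  if (t2_m >= t2_f) stop("t2_m must be < t2_f")
  if (t1_m >= t1_f) stop("t1_m must be < t1_f")
  structure(c(m0 = m0, f_m = f_m, t1_m = t1_m, t1_f = t1_f, t2_m = t2_m,
              t2_f = t2_f, k_mf = k_mf, delta_f0 = delta_f0,
              b1_scale = b1_scale), class = "two_pool_params")
}

#' Two-pool steady-state signal set for the full mcDESPOT protocol
#'
#' SPGR signals from the longitudinal Bloch-McConnell steady state, bSSFP
#' signals from the 6-dimensional rotation-evolution fixed point (both phase
#' cycles), and one IR-SPGR signal (per-pool closed form; exchange during
#' the inversion delay is neglected).
#'
#' @param params a [two_pool_params()].
#' @param protocol an [mcdespot_protocol()].
#' @return named numeric vector: `spgr_<alpha>`, `bssfp_<cycle>_<alpha>`,
#'   `irspgr`.
#' @export
two_pool_signals <- function(params, protocol = mcdespot_protocol()) {
  stopifnot(inherits(params, "two_pool_params"),
            inherits(protocol, "mcdespot_protocol"))
  s <- cpp_two_pool_signals(unclass(params), protocol$spgr_tr,
                            protocol$spgr_alphas, protocol$bssfp_tr,
                            protocol$bssfp_alphas,
                            protocol$bssfp_phase_cycles,
                            protocol$ir_ti, protocol$ir_alpha,
                            protocol$ir_tr_total, protocol$inv_efficiency)
  if (any(!is.finite(s))) stop("non-finite two-pool signal")
  names(s) <- c(paste0("spgr_", protocol$spgr_alphas),
                paste0("bssfp_", rep(protocol$bssfp_phase_cycles,
                                     each = length(protocol$bssfp_alphas)),
                       "_", rep(protocol$bssfp_alphas, 2)),
                "irspgr")
  s
}

#' MT-off / MT-on image pair
#'
#' The saturation image is modeled as `Ms = M0 (1 - delta)` with `M0` the
#' SPGR steady state at the MT protocol settings; ground-truth MTR is
#' therefore exactly `100 * delta` before noise.
#'
#' @param m0_map,t1_map,delta_map arrays (or scalars) of magnetization, T1
#'   (ms) and saturation fraction delta in `[0, 1)`.
#' @param protocol an [mt_protocol()].
#' @param b1_scale transmit scale.
#' @return list with elements `m0_img` and `ms_img`.
#' @export
mt_pair <- function(m0_map, t1_map, delta_map, protocol = mt_protocol(),
                    b1_scale = 1) {
  if (any(delta_map >= 1) || any(delta_map < 0))
    stop("mt_delta must be in [0, 1)")
  M0 <- spgr_signal(m0_map, pmax(t1_map, 1e-6), protocol$alpha, protocol$tr,
                    b1_scale)
  M0[t1_map <= 0] <- 0
  list(m0_img = M0, ms_img = M0 * (1 - delta_map))
}

#' Add Rician magnitude noise
#'
#' `out = |x + n1 + i n2|` with independent Gaussian channel noise of
#' standard deviation `sigma = reference / snr`.  Uses the current RNG state.
#'
#' @param x signal array/vector (noise-free magnitudes).
#' @param snr signal-to-noise ratio (> 0); `Inf` returns `x` unchanged.
#' @param reference signal level defining sigma; defaults to `max(x)`.
#' @return noisy magnitudes, same shape as `x`.
#' @export
add_rician_noise <- function(x, snr, reference = max(x)) {
  stopifnot(snr > 0)
  if (!is.finite(snr)) return(x)
  sigma <- reference / snr
  n <- length(x)
  out <- sqrt((x + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (is.array(x)) out <- array(out, dim(x))
  out
}
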