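# Voxelwise inversion of the forward models: regularized NNLS T2 spectra
# (MWF-G), DESPOT1-HIFI (qT1, B1), DESPOT2-FM (T2, B0), stochastic region
# contraction (MWF-D) and MTR.

#' Logarithmic T2 grid for spectrum fitting
#' @param n number of grid points.
#' @param range (min, max) T2 in ms.
#' @return numeric vector, strictly increasing.
#' @export
t2_grid <- function(n = 40, range = c(15, 2000)) {
  stopifnot(n >= 2, range[1] > 0, range[2] > range[1])
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Regularization configuration for the T2 spectrum fit
#'
#' Tikhonov regularization picks the smallest weight mu whose data-term
#' chi-squared lies within `chi2_factor` times the unregularized minimum
#' (bisection on log mu).
#'
#' @param mode `"tikhonov"` or `"none"`.
#' @param chi2_factor inflation band, both entries >= 1.
#' @param max_iter bisection iteration cap.
#' @return list of class `reg_config`.
#' @export
reg_config <- function(mode = c("tikhonov", "none"),
                       chi2_factor = c(1.02, 1.025), max_iter = 25) {
  mode <- match.arg(mode)
  stopifnot(all(chi2_factor >= 1), chi2_factor[2] > chi2_factor[1])
  structure(list(mode = mode, chi2_factor = chi2_factor,
                 max_iter = as.integer(max_iter)), class = "reg_config")
}

#' Stochastic region contraction configuration
#'
#' @param bounds 6x2 matrix of (lower, upper) search bounds for
#'   `f_m`, `t1_m`, `t1_f`, `t2_m`, `t2_f`, `k_mf` (ms / 1/s).
#' @param n_samples uniform draws per iteration.
#' @param n_retain best samples kept to define the contracted box.
#' @param n_iterations contraction iterations.
#' @param contraction_tol stop when all box widths fall below this fraction
#'   of the original widths.
#' @param polish apply a bounded Levenberg-Marquardt refinement to the best
#'   sample (recommended: the objective has long flat valleys).
#' @param polish_iter LM iteration cap.
#' @return list of class `src_config`.
#' @export
src_config <- function(bounds = default_src_bounds(), n_samples = 5000,
                       n_retain = 50, n_iterations = 6,
                       contraction_tol = 1e-3, polish = TRUE,
                       polish_iter = 60) {
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 6, ncol(bounds) == 2,
            all(bounds[, 1] <= bounds[, 2]),
            n_retain < n_samples, n_iterations >= 1, contraction_tol > 0)
  structure(list(bounds = bounds, n_samples = as.integer(n_samples),
                 n_retain = as.integer(n_retain),
                 n_iterations = as.integer(n_iterations),
                 contraction_tol = contraction_tol, polish = polish,
                 polish_iter = as.integer(polish_iter)),
            class = "src_config")
}

#' @rdname src_config
#' @export
default_src_bounds <- function() {
  b <- rbind(f_m = c(0, 0.35), t1_m = c(200, 700), t1_f = c(700, 2500),
             t2_m = c(5, 40), t2_f = c(40, 150), k_mf = c(0.5, 40))
  colnames(b) <- c("lower", "upper")
  b
}

#' Fit a T2 spectrum to one echo decay (EPG + regularized NNLS)
#'
#' The refocusing angle beta is estimated by golden-section minimization of
#' the unregularized NNLS residual over `beta_range` (design matrices are
#' EPG decays of the grid T2s at the candidate beta; ties break toward 180).
#' At the estimated beta the non-negative spectrum is solved, optionally with
#' Tikhonov regularization per [reg_config()].
#'
#' @param decay echo magnitude vector of length `protocol$etl`.
#' @param protocol a [grase_protocol()].
#' @param grid T2 grid (ms) from [t2_grid()].
#' @param reg a [reg_config()].
#' @param t1_assumed T1 (ms) used in the EPG design matrix.
#' @param beta_range refocusing search interval (degrees).
#' @param beta_tol golden-section tolerance (degrees).
#' @return list of class `t2_spectrum`: `weights`, `refocus_estimate`,
#'   `residual_norm`, `mu`, `reg_converged`, `grid`.
#' @export
fit_t2_spectrum <- function(decay, protocol = grase_protocol(),
                            grid = t2_grid(), reg = reg_config(),
                            t1_assumed = 1000, beta_range = c(90, 180),
                            beta_tol = 0.5) {
  if (length(decay) != protocol$etl)
    stop("decay length must equal the echo train length")
  if (any(decay < 0)) stop("echo magnitudes must be non-negative")
  if (all(decay == 0)) stop("all-zero decay")
  f <- fit_t2_many(matrix(decay, ncol = 1), protocol, grid, reg, t1_assumed,
                   beta_range, beta_tol)
  structure(list(weights = f$weights[, 1], refocus_estimate = f$beta[1],
                 residual_norm = sqrt(f$residual[1]), mu = f$mu[1],
                 reg_converged = f$reg_converged[1] == 1, grid = grid),
            class = "t2_spectrum")
}

# matrix version: columns of Y are decays
fit_t2_many <- function(Y, protocol, grid, reg, t1_assumed = 1000,
                        beta_range = c(90, 180), beta_tol = 0.5) {
  mode <- if (reg$mode == "tikhonov") 1L else 0L
  res <- cpp_fit_t2_many(Y, grid, protocol$te, t1_assumed,
                         beta_range[1], beta_range[2], beta_tol, 0.25,
                         mode, reg$chi2_factor[1], reg$chi2_factor[2],
                         reg$max_iter)
  if (mode == 1L && any(res$reg_converged == 0))
    warning(sum(res$reg_converged == 0),
            " voxel(s): mu search did not land in the chi2 band; ",
            "unregularized solution used")
  res
}

#' Myelin water fraction from a T2 spectrum
#'
#' Ratio of spectrum weight inside the inclusive myelin-water window to the
#' total weight.  A zero total returns `NA` (masked voxel), not an error.
#'
#' @param spectrum a `t2_spectrum`, or a bare weight vector.
#' @param grid T2 grid (ms); defaults to the spectrum's own grid.
#' @param window inclusive (low, high) window in ms.
#' @return fraction in `[0, 1]`, or `NA` if the spectrum is empty.
#' @export
mwf_from_spectrum <- function(spectrum, grid = NULL, window = c(10, 40)) {
  w <- if (inherits(spectrum, "t2_spectrum")) spectrum$weights else spectrum
  if (is.null(grid))
    grid <- if (inherits(spectrum, "t2_spectrum")) spectrum$grid
      else stop("grid required")
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(w[grid >= window[1] & grid <= window[2]]) / tot
}

#' Linearized DESPOT1 (fixed flip-angle scale)
#'
#' Regression of `S/sin(k a)` on `S/tan(k a)`: the slope is `E1`, giving
#' `t1 = -tr / log(slope)`; the intercept gives `m0`.
#'
#' @param spgr matrix (voxels x flip angles) or vector of SPGR signals.
#' @param alphas flip angles (degrees).
#' @param tr repetition time (ms).
#' @param kappa flip-angle scale (scalar or per-voxel).
#' @return list of per-voxel `t1`, `m0`, `slope` (NA where `E1` is outside
#'   (0, 1)).
#' @export
despot1_linear <- function(spgr, alphas, tr, kappa = 1) {
  S <- if (is.matrix(spgr)) spgr else matrix(spgr, nrow = 1)
  na <- length(alphas)
  stopifnot(ncol(S) == na, na >= 2)
  a <- outer(kappa, alphas * pi / 180)     # nvox x na
  y <- S / sin(a); x <- S / tan(a)
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x^2); sxy <- rowSums(x * y)
  slope <- (na * sxy - sx * sy) / (na * sxx - sx^2)
  inter <- (sy - slope * sx) / na
  bad <- !is.finite(slope) | slope <= 0 | slope >= 1
  t1 <- -tr / log(slope)
  m0 <- inter / (1 - slope)
  t1[bad] <- NA_real_; m0[bad] <- NA_real_
  list(t1 = t1, m0 = m0, slope = slope)
}

# HIFI objective: joint SPGR + IR-SPGR squared residual at per-voxel kappa
hifi_resid <- function(kappa, S, s_ir, protocol) {
  d1 <- despot1_linear(S, protocol$spgr_alphas, protocol$spgr_tr, kappa)
  t1 <- d1$t1; m0 <- d1$m0
  a <- outer(kappa, protocol$spgr_alphas * pi / 180)
  e1 <- exp(-protocol$spgr_tr / t1)
  pred <- m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
  r <- rowSums((pred - S)^2)
  pred_ir <- irspgr_signal(m0, t1, protocol, b1_scale = kappa)
  r <- r + (pred_ir - s_ir)^2
  r[!is.finite(r)] <- Inf
  r
}

#' DESPOT1-HIFI: joint T1 / M0 / B1 fit
#'
#' Nests the linearized DESPOT1 solve inside a 1-D search over the
#' flip-angle scale kappa, scored by the joint squared residual of the SPGR
#' series and the IR-SPGR scan (coarse grid then per-voxel golden-section;
#' fully vectorized over voxels).
#'
#' @param spgr matrix (voxels x flip angles) or vector.
#' @param irspgr IR-SPGR signal (per voxel).
#' @param protocol an [mcdespot_protocol()].
#' @param kappa_range search interval for the B1 scale.
#' @param n_grid coarse-grid resolution.
#' @param tol golden-section tolerance on kappa.
#' @return list of per-voxel `t1` (ms), `m0`, `kappa`; voxels with no valid
#'   linearized solution anywhere in the kappa range are NA.
#' @export
fit_despot1_hifi <- function(spgr, irspgr, protocol = mcdespot_protocol(),
                             kappa_range = c(0.5, 1.6), n_grid = 23,
                             tol = 1e-4) {
  S <- if (is.matrix(spgr)) spgr else matrix(spgr, nrow = 1)
  nv <- nrow(S)
  stopifnot(length(irspgr) == nv)
  ks <- seq(kappa_range[1], kappa_range[2], length.out = n_grid)
  best <- rep(Inf, nv); kbest <- rep(ks[1], nv)
  for (k in ks) {
    r <- hifi_resid(rep(k, nv), S, irspgr, protocol)
    upd <- r < best
    best[upd] <- r[upd]; kbest[upd] <- k
  }
  step <- ks[2] - ks[1]
  lo <- pmax(kappa_range[1], kbest - step)
  hi <- pmin(kappa_range[2], kbest + step)
  gr <- (sqrt(5) - 1) / 2
  c1 <- hi - gr * (hi - lo); d1 <- lo + gr * (hi - lo)
  fc <- hifi_resid(c1, S, irspgr, protocol)
  fd <- hifi_resid(d1, S, irspgr, protocol)
  while (max(hi - lo) > tol) {
    left <- fc < fd
    hi[left] <- d1[left]; lo[!left] <- c1[!left]
    c1 <- hi - gr * (hi - lo); d1 <- lo + gr * (hi - lo)
    fc <- hifi_resid(c1, S, irspgr, protocol)
    fd <- hifi_resid(d1, S, irspgr, protocol)
  }
  kappa <- (lo + hi) / 2
  d1fit <- despot1_linear(S, protocol$spgr_alphas, protocol$spgr_tr, kappa)
  list(t1 = d1fit$t1, m0 = d1fit$m0, kappa = kappa)
}

# bSSFP model ratio for despot2: signals for all (cycle, alpha) at unit m0
despot2_model <- function(t2, df0, t1, kappa, protocol) {
  nb <- length(protocol$bssfp_alphas)
  out <- matrix(0, length(t2), 2 * nb)
  for (c in 1:2) for (i in seq_len(nb)) {
    out[, (c - 1) * nb + i] <-
      bssfp_signal(1, t1, pmin(t2, t1), protocol$bssfp_alphas[i],
                   protocol$bssfp_tr, df0,
                   protocol$bssfp_phase_cycles[c], kappa)
  }
  out
}

despot2_resid <- function(t2, df0, B, t1, kappa, protocol) {
  G <- despot2_model(t2, df0, t1, kappa, protocol)
  m0 <- rowSums(B * G) / rowSums(G^2)
  list(resid = rowSums((B - m0 * G)^2), m0 = m0)
}

#' DESPOT2-FM: T2 and B0 from phase-cycled bSSFP
#'
#' Nonlinear least squares over (t2, delta_f0, m0) against the single-pool
#' bSSFP forward model across both phase cycles, with m0 solved in closed
#' form, a multi-start grid over delta_f0 in (-1/2tr, 1/2tr) to avoid
#' off-resonance aliasing, and alternating golden-section refinement.
#' delta_f0 is reported as the principal value; with magnitude data its sign
#' is not identifiable.
#'
#' @param bssfp matrix (voxels x 2*n_alphas), cycle-major column order
#'   matching the protocol (first all alphas of cycle 1, then cycle 2).
#' @param t1,kappa per-voxel T1 (ms) and B1 scale from DESPOT1-HIFI.
#' @param protocol an [mcdespot_protocol()].
#' @param t2_range search interval (ms); the upper bound is additionally
#'   capped at T1 per voxel.
#' @param n_t2,n_df0 coarse-grid resolution.
#' @param rounds alternating refinement rounds.
#' @return list of per-voxel `t2`, `delta_f0`, `m0` (NA where T1 is NA).
#' @export
fit_despot2_fm <- function(bssfp, t1, kappa, protocol = mcdespot_protocol(),
                           t2_range = c(5, 500), n_t2 = 12, n_df0 = 9,
                           rounds = 2) {
  B <- if (is.matrix(bssfp)) bssfp else matrix(bssfp, nrow = 1)
  nv <- nrow(B)
  stopifnot(ncol(B) == 2 * length(protocol$bssfp_alphas),
            length(t1) == nv, length(kappa) %in% c(1L, nv))
  if (length(kappa) == 1) kappa <- rep(kappa, nv)
  valid <- is.finite(t1) & t1 > 0
  t1w <- ifelse(valid, t1, 1000)
  fmax <- 1000 / (2 * protocol$bssfp_tr)   # Hz
  t2s <- exp(seq(log(t2_range[1]), log(min(t2_range[2], 3000)),
                 length.out = n_t2))
  dfs <- seq(0, fmax, length.out = n_df0)  # magnitude data: sign unidentified
  best <- rep(Inf, nv); t2b <- rep(t2s[1], nv); dfb <- rep(0, nv)
  for (t2c in t2s) for (dfc in dfs) {
    r <- despot2_resid(rep(t2c, nv), rep(dfc, nv), B, t1w, kappa, protocol)$resid
    upd <- is.finite(r) & (r < best)
    best[upd] <- r[upd]; t2b[upd] <- t2c; dfb[upd] <- dfc
  }
  gr <- (sqrt(5) - 1) / 2
  golden <- function(lo, hi, fn, iters = 18) {
    # vectorized golden section with single-point updates per iteration
    c1 <- hi - gr * (hi - lo); d1 <- lo + gr * (hi - lo)
    fc <- fn(c1); fd <- fn(d1)
    for (i in seq_len(iters)) {
      left <- fc < fd
      hi[left] <- d1[left]; lo[!left] <- c1[!left]
      d1[left] <- c1[left]; fd[left] <- fc[left]
      c1[!left] <- d1[!left]; fc[!left] <- fd[!left]
      newpt <- ifelse(left, hi - gr * (hi - lo), lo + gr * (hi - lo))
      fnew <- fn(newpt)
      c1[left] <- newpt[left]; fc[left] <- fnew[left]
      d1[!left] <- newpt[!left]; fd[!left] <- fnew[!left]
    }
    (lo + hi) / 2
  }
  t2step <- exp(diff(log(t2s))[1]); dfstep <- diff(dfs)[1]
  for (r in seq_len(rounds)) {
    t2b <- golden(pmax(t2_range[1], t2b / t2step),
                  pmin(pmin(t2_range[2], t1w), t2b * t2step),
                  function(v) despot2_resid(v, dfb, B, t1w, kappa, protocol)$resid)
    dfb <- golden(pmax(0, dfb - dfstep), pmin(fmax, dfb + dfstep),
                  function(v) despot2_resid(t2b, v, B, t1w, kappa, protocol)$resid)
  }
  # joint Gauss-Newton polish on (log t2, df0) with m0 profiled out;
  # coordinate search alone converges slowly along the curved (t2, df0) valley
  resid_vec <- function(t2, df0) {
    G <- despot2_model(t2, df0, t1w, kappa, protocol)
    m0 <- rowSums(B * G) / rowSums(G^2)
    B - m0 * G
  }
  cur <- rowSums(resid_vec(t2b, dfb)^2)
  for (it in 1:6) {
    r0 <- resid_vec(t2b, dfb)
    h1 <- 0.001; h2 <- 0.25
    J1 <- (resid_vec(t2b * exp(h1), dfb) - r0) / h1
    J2 <- (resid_vec(t2b, dfb + h2) - r0) / h2
    a11 <- rowSums(J1^2); a12 <- rowSums(J1 * J2); a22 <- rowSums(J2^2)
    g1 <- rowSums(J1 * r0); g2 <- rowSums(J2 * r0)
    det <- a11 * a22 - a12^2
    d1 <- -(a22 * g1 - a12 * g2) / det
    d2 <- -(a11 * g2 - a12 * g1) / det
    ok2 <- is.finite(d1) & is.finite(d2)
    d1[!ok2] <- 0; d2[!ok2] <- 0
    t2n <- pmin(pmin(t2_range[2], t1w),
                pmax(t2_range[1], t2b * exp(pmax(-0.5, pmin(0.5, d1)))))
    dfn <- pmin(fmax, pmax(0, dfb + pmax(-dfstep, pmin(dfstep, d2))))
    new <- rowSums(resid_vec(t2n, dfn)^2)
    take <- is.finite(new) & (new < cur)
    t2b[take] <- t2n[take]; dfb[take] <- dfn[take]; cur[take] <- new[take]
  }
  fin <- despot2_resid(t2b, dfb, B, t1w, kappa, protocol)
  t2b[!valid] <- NA_real_; dfb[!valid] <- NA_real_
  m0 <- fin$m0; m0[!valid] <- NA_real_
  list(t2 = t2b, delta_f0 = dfb, m0 = m0)
}

#' Stochastic region contraction fit of the two-pool mcDESPOT model
#'
#' Iteratively samples parameter vectors uniformly in a contracting box,
#' scores them by the squared residual between block-normalized model and
#' data (SPGR block; joint bSSFP block over both phase cycles), retains the
#' best, contracts, and polishes the best sample with bounded
#' Levenberg-Marquardt.  Uses the current RNG state.
#'
#' @param signals matrix (voxels x 21): 7 SPGR, then 7 bSSFP of the first
#'   phase cycle, then 7 of the second (or a length-21/22 vector; an
#'   appended IR-SPGR element is ignored).
#' @param kappa,delta_f0 per-voxel B1 scale and off-resonance (Hz) from the
#'   DESPOT1/DESPOT2 stages.
#' @param src an [src_config()].
#' @param protocol an [mcdespot_protocol()].
#' @return list with `estimates` (voxels x 6 matrix: f_m, t1_m, t1_f, t2_m,
#'   t2_f, k_mf), `mwf_d` (= f_m), `score`.
#' @export
fit_mcdespot_src <- function(signals, kappa = 1, delta_f0 = 0,
                             src = src_config(),
                             protocol = mcdespot_protocol()) {
  ns <- length(protocol$spgr_alphas); nb <- length(protocol$bssfp_alphas)
  S <- if (is.matrix(signals)) signals else matrix(signals, nrow = 1)
  if (ncol(S) == ns + 2 * nb + 1) S <- S[, seq_len(ns + 2 * nb), drop = FALSE]
  stopifnot(ncol(S) == ns + 2 * nb)
  nv <- nrow(S)
  if (length(kappa) == 1) kappa <- rep(kappa, nv)
  if (length(delta_f0) == 1) delta_f0 <- rep(delta_f0, nv)
  kappa2 <- ifelse(is.finite(kappa), kappa, 1)
  df2 <- ifelse(is.finite(delta_f0), delta_f0, 0)
  fit <- cpp_src_fit_many(t(S), kappa2, df2, src$bounds,
                          protocol$spgr_tr, protocol$spgr_alphas,
                          protocol$bssfp_tr, protocol$bssfp_alphas,
                          protocol$bssfp_phase_cycles,
                          src$n_samples, src$n_retain, src$n_iterations,
                          src$contraction_tol, src$polish, src$polish_iter)
  est <- t(fit$estimates)
  colnames(est) <- c("f_m", "t1_m", "t1_f", "t2_m", "t2_f", "k_mf")
  est[!is.finite(kappa), ] <- NA_real_
  list(estimates = est, mwf_d = est[, "f_m"], score = as.numeric(fit$score))
}

#' Magnetization transfer ratio map
#'
#' `MTR = 100 (M0 - Ms) / M0`; voxels with `M0` at or below the background
#' threshold are masked to `NA`.
#'
#' @param m0_img,ms_img arrays of identical shape (MT-off, MT-on).
#' @param threshold background `M0` threshold (absolute units).
#' @return MTR array in percent units with NA where masked.
#' @export
compute_mtr <- function(m0_img, ms_img, threshold = 0) {
  if (!identical(dim(m0_img), dim(ms_img)) ||
      length(m0_img) != length(ms_img))
    stop("M0 and Ms images must have the same shape")
  out <- 100 * (m0_img - ms_img) / m0_img
  out[!is.finite(out) | m0_img <= threshold] <- NA_real_
  out
}

#' Fit all quantitative maps for one subject
#'
#' Runs the four fitters voxelwise inside the brain mask and returns a
#' quantitative map set on the acquisition grid.  A missing MT acquisition
#' yields a map set with `mtr` flagged absent (the other maps are fitted),
#' mirroring cohorts where some subjects lack the MT scan.
#'
#' @param acq list with 4D arrays `grase` (x,y,z,echo), `spgr`
#'   (x,y,z,alpha), `bssfp` (x,y,z, cycle-major alpha), 3D `irspgr`, and
#'   optionally `mt` (x,y,z,2: off,on); plus `brain_mask` (logical) and
#'   `affine`.
#' @param protocols list from [default_protocols()].
#' @param grid,reg,src fitting configurations.
#' @param t1_assumed EPG design-matrix T1 (ms).
#' @param modalities subset of `c("grase", "mcdespot", "mtr")` to fit;
#'   skipped modalities are flagged absent.
#' @return list of class `quant_map_set`: `maps` (named list of
#'   [volume_record()]s: mwf_g, mwf_d, qt1, t2, mtr, b1, b0), `validity`,
#'   `absent` (character vector of missing modalities).
#' @export
fit_subject <- function(acq, protocols = default_protocols(),
                        grid = t2_grid(), reg = reg_config(),
                        src = src_config(), t1_assumed = 1000,
                        modalities = c("grase", "mcdespot", "mtr")) {
  stopifnot(is.list(acq), !is.null(acq$brain_mask),
            all(modalities %in% c("grase", "mcdespot", "mtr")))
  mask <- acq$brain_mask
  dims <- dim(mask)
  aff <- if (is.null(acq$affine)) diag(4) else acq$affine
  idx <- which(mask)
  nv <- length(idx)
  blank <- function() array(NA_real_, dims)
  fill <- function(v) { a <- blank(); a[idx] <- v; a }
  flat <- function(x4d) {
    nt <- dim(x4d)[4]
    m <- matrix(0, nv, nt)
    for (t in seq_len(nt)) m[, t] <- x4d[, , , t][idx]
    m
  }
  absent <- character()
  nav <- rep(NA_real_, nv)

  # GRASE -> T2 spectrum -> MWF-G
  if ("grase" %in% modalities && !is.null(acq$grase)) {
    G <- flat(acq$grase)
    tfit <- fit_t2_many(t(G), protocols$grase, grid, reg, t1_assumed,
                        beta_tol = 1)
    mwf_g <- apply(tfit$weights, 2, mwf_from_spectrum, grid = grid)
    beta <- tfit$beta
  } else {
    absent <- c(absent, "mwf_g")
    mwf_g <- beta <- nav
  }

  # mcDESPOT: HIFI -> FM -> SRC
  if ("mcdespot" %in% modalities && !is.null(acq$spgr)) {
    Sp <- flat(acq$spgr); Ir <- acq$irspgr[idx]; Bs <- flat(acq$bssfp)
    hifi <- fit_despot1_hifi(Sp, Ir, protocols$mcdespot)
    # slightly coarser search than the single-voxel default: map-scale runtime
    fm <- fit_despot2_fm(Bs, hifi$t1, hifi$kappa, protocols$mcdespot,
                         n_t2 = 10, n_df0 = 7, rounds = 1)
    srcfit <- fit_mcdespot_src(cbind(Sp, Bs), hifi$kappa, fm$delta_f0, src,
                               protocols$mcdespot)
  } else {
    absent <- c(absent, "mwf_d", "qt1")
    hifi <- list(t1 = nav, m0 = nav, kappa = nav)
    fm <- list(t2 = nav, delta_f0 = nav, m0 = nav)
    srcfit <- list(mwf_d = nav)
  }

  # MTR
  if (!"mtr" %in% modalities || is.null(acq$mt)) {
    absent <- c(absent, "mtr")
    mtr <- blank()
  } else {
    thr <- 0.05 * max(acq$mt[, , , 1])
    mtr_full <- compute_mtr(acq$mt[, , , 1], acq$mt[, , , 2], threshold = thr)
    mtr <- blank(); mtr[idx] <- mtr_full[idx]
  }

  vol <- function(a, units, modality)
    volume_record(a, aff, units = units, modality = modality,
                  validity = array(is.finite(a), dims))
  maps <- list(
    mwf_g = vol(fill(mwf_g), "fraction", "mwf_g"),
    mwf_d = vol(fill(srcfit$mwf_d), "fraction", "mwf_d"),
    qt1 = vol(fill(hifi$t1), "ms", "qt1"),
    t2 = vol(fill(fm$t2), "ms", "t2"),
    mtr = vol(mtr, "percent", "mtr"),
    b1 = vol(fill(hifi$kappa), "ratio", "b1"),
    b0 = vol(fill(fm$delta_f0), "Hz", "b0"),
    refocus = vol(fill(beta), "degrees", "refocus"))
  structure(list(maps = maps, absent = absent, brain_mask = mask,
                 affine = aff), class = "quant_map_set")
}
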