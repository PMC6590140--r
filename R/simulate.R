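# Forward simulation of the four acquisitions from a subject's ground truth.
# Within a subject each tissue class has one realized parameter set, so clean
# signals are computed once per class and scattered onto the grid before
# Rician noise is added voxel by voxel.

# two-pool parameters used by the mcDESPOT forward model for a tissue class.
# The class's scalar T1 is split into myelin/free pool T1s by fixed factors;
# single-component classes (CSF) collapse to one pool.
class_two_pool <- function(cp) {
  short <- which.min(cp$t2_times)
  if (length(cp$t2_times) == 1 || cp$mwf <= 0) {
    return(two_pool_params(m0 = cp$pd, f_m = 0,
                           t1_m = cp$t1 * 0.45, t1_f = cp$t1,
                           t2_m = min(cp$t2_times) * 0.25,
                           t2_f = min(cp$t2_times[length(cp$t2_times)], cp$t1),
                           k_mf = 0))
  }
  long_t2 <- max(cp$t2_times)
  two_pool_params(m0 = cp$pd, f_m = min(cp$mwf, 0.9),
                  t1_m = cp$t1 * 0.45, t1_f = min(cp$t1 * 1.15, 4500),
                  t2_m = cp$t2_times[short],
                  t2_f = min(long_t2, cp$t1 * 1.15 - 1),
                  k_mf = cp$k_mf)
}

#' Simulate all four acquisitions for one subject
#'
#' GRASE echoes come from the multi-component EPG decay; SPGR/IR-SPGR/bSSFP
#' from the two-pool steady-state models; the MT pair from the saturation
#' fraction.  Rician noise is added per sequence with sigma = reference /
#' SNR, the reference being the mean white-matter first-echo signal for
#' GRASE and the maximum brain signal for the other sequences.  Uses the
#' current RNG state.
#'
#' @param subject a `subject_truth`.
#' @param protocols list from [default_protocols()].
#' @param snr named per-sequence SNRs (see [cohort_config()]); use `Inf` for
#'   noise-free data.
#' @param b1_scale transmit-field scale applied to all sequences.
#' @param include_mt simulate the MT pair? (`FALSE` mirrors subjects whose
#'   MT scan was skipped.)
#' @param geometry optional [phantom_geometry()]; sets the output affine.
#' @return list with arrays `grase`, `spgr`, `bssfp`, `irspgr`, `mt`
#'   (absent if `include_mt = FALSE`), `brain_mask`, `affine`.
#' @export
simulate_acquisitions <- function(subject, protocols = default_protocols(),
                                  snr = c(grase = 100, spgr = 100,
                                          bssfp = 100, irspgr = 100,
                                          mt = 100),
                                  b1_scale = 1, include_mt = TRUE,
                                  geometry = NULL) {
  stopifnot(inherits(subject, "subject_truth"))
  labels <- subject$labels
  dims <- dim(labels)
  pr <- protocols
  etl <- pr$grase$etl
  ns <- length(pr$mcdespot$spgr_alphas)
  nb <- length(pr$mcdespot$bssfp_alphas)

  grase <- array(0, c(dims, etl))
  spgr <- array(0, c(dims, ns))
  bssfp <- array(0, c(dims, 2 * nb))
  irspgr <- array(0, dims)
  mt <- array(0, c(dims, 2))

  class_labels <- c(csf = LABELS[["csf"]], gm = LABELS[["gm"]],
                    wm = LABELS[["wm"]], subcortical = LABELS[["subcortical"]],
                    lesion = LABELS[["lesion"]])
  wm_first_echo <- NA_real_
  for (nm in names(subject$class_params)) {
    cp <- subject$class_params[[nm]]
    sel <- labels == class_labels[[nm]]
    if (!any(sel)) next
    g <- cp$pd * multicomponent_decay(cp$t2_weights, cp$t2_times, cp$t1,
                                      pr$grase, b1_scale * pr$grase$refocus_nominal)
    if (nm == "wm") wm_first_echo <- g[1]
    tp <- class_two_pool(cp)
    tp["b1_scale"] <- b1_scale
    s <- two_pool_signals(tp, pr$mcdespot)
    mtp <- mt_pair(cp$pd, cp$t1, cp$mt_delta, pr$mt, b1_scale)
    for (e in seq_len(etl)) grase[, , , e][sel] <- g[e]
    for (i in seq_len(ns)) spgr[, , , i][sel] <- s[i]
    for (i in seq_len(2 * nb)) bssfp[, , , i][sel] <- s[ns + i]
    irspgr[sel] <- s[ns + 2 * nb + 1]
    mt[, , , 1][sel] <- mtp$m0_img
    mt[, , , 2][sel] <- mtp$ms_img
  }
  if (!is.finite(wm_first_echo)) wm_first_echo <- max(grase)

  grase <- add_rician_noise(grase, snr[["grase"]], reference = wm_first_echo)
  spgr <- add_rician_noise(spgr, snr[["spgr"]], reference = max(spgr))
  bssfp <- add_rician_noise(bssfp, snr[["bssfp"]], reference = max(bssfp))
  irspgr <- add_rician_noise(irspgr, snr[["irspgr"]], reference = max(irspgr))
  out <- list(grase = grase, spgr = spgr, bssfp = bssfp, irspgr = irspgr,
              brain_mask = labels != LABELS[["background"]],
              affine = diag_affine(if (is.null(geometry)) c(1, 1, 1)
                                   else geometry$voxel_size))
  if (include_mt)
    out$mt <- add_rician_noise(mt, snr[["mt"]], reference = max(mt))
  out
}
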