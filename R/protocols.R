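# Acquisition protocol constructors.  Defaults are the study protocol of the
# 3T comparison this package models: a 32-echo GRASE train, a 7+7(+IR)
# mcDESPOT series and a single-offset MT pair.

#' GRASE multi-echo T2 protocol
#'
#' @param te echo spacing (ms).
#' @param etl echo train length.
#' @param tr repetition time (ms).
#' @param refocus_nominal nominal refocusing flip angle (degrees).
#' @return list of class `grase_protocol`.
#' @export
grase_protocol <- function(te = 10, etl = 32, tr = 1000, refocus_nominal = 180) {
  stopifnot(te > 0, etl >= 2, tr > 0, refocus_nominal > 0, refocus_nominal <= 180)
  if (etl * te >= tr) stop("echo train (etl*te) must fit inside TR")
  structure(list(te = te, etl = as.integer(etl), tr = tr,
                 refocus_nominal = refocus_nominal), class = "grase_protocol")
}

#' mcDESPOT protocol (SPGR + IR-SPGR + phase-cycled bSSFP)
#'
#' @param spgr_tr,spgr_alphas SPGR repetition time (ms) and flip angles (deg).
#' @param bssfp_tr,bssfp_alphas bSSFP repetition time (ms) and flip angles (deg).
#' @param bssfp_phase_cycles RF phase-cycling increments (deg); two cycles are
#'   required for off-resonance (B0) correction.
#' @param ir_ti,ir_alpha,ir_tr inversion time, flip angle and readout TR of the
#'   IR-SPGR scan.
#' @param ir_tr_total effective recovery period of the IR-SPGR sequence (ms);
#'   the acquisition-loop structure is compressed into this single number.
#' @param inv_efficiency inversion efficiency in (0, 1].
#' @return list of class `mcdespot_protocol`.
#' @export
mcdespot_protocol <- function(spgr_tr = 6.5,
                              spgr_alphas = c(2, 3, 4, 6, 9, 13, 18),
                              bssfp_tr = 5.8,
                              bssfp_alphas = c(7, 11, 15, 19, 24, 30, 47),
                              bssfp_phase_cycles = c(0, 180),
                              ir_ti = 450, ir_alpha = 5, ir_tr = 6.5,
                              ir_tr_total = 3000, inv_efficiency = 1) {
  stopifnot(spgr_tr > 0, bssfp_tr > 0, ir_ti > 0, ir_tr > 0, ir_tr_total > 0,
            all(spgr_alphas > 0), all(spgr_alphas < 180),
            all(bssfp_alphas > 0), all(bssfp_alphas < 180),
            ir_alpha > 0, ir_alpha < 180,
            inv_efficiency > 0, inv_efficiency <= 1,
            length(bssfp_phase_cycles) == 2)
  structure(list(spgr_tr = spgr_tr, spgr_alphas = spgr_alphas,
                 bssfp_tr = bssfp_tr, bssfp_alphas = bssfp_alphas,
                 bssfp_phase_cycles = bssfp_phase_cycles,
                 ir_ti = ir_ti, ir_alpha = ir_alpha, ir_tr = ir_tr,
                 ir_tr_total = ir_tr_total, inv_efficiency = inv_efficiency),
            class = "mcdespot_protocol")
}

#' Magnetization transfer protocol
#'
#' The MT saturation pulse parameters are metadata: the forward model
#' parameterizes saturation directly through the per-voxel saturation
#' fraction delta, so ground-truth MTR is exactly 100*delta.
#'
#' @param offset off-resonance of the saturation pulse (Hz, below water).
#' @param tr repetition time (ms).
#' @param alpha excitation flip angle (degrees).
#' @return list of class `mt_protocol`.
#' @export
mt_protocol <- function(offset = 1100, tr = 85, alpha = 18) {
  stopifnot(offset > 0, tr > 0, alpha > 0, alpha < 180)
  structure(list(offset = offset, tr = tr, alpha = alpha),
            class = "mt_protocol")
}

#' Bundle of all four protocols
#' @param grase,mcdespot,mt protocol objects (defaults as above).
#' @return named list.
#' @export
default_protocols <- function(grase = grase_protocol(),
                              mcdespot = mcdespot_protocol(),
                              mt = mt_protocol()) {
  list(grase = grase, mcdespot = mcdespot, mt = mt)
}
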