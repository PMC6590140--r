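# Ground-truth tissue parameterization.  The source study publishes no
# quantitative ground truth for any tissue; these are literature-typical 3T
# values chosen to give realistic map contrast, and everything is
# configurable.

#' Per-class tissue parameters
#'
#' Each class carries a T1 (ms), a small set of T2 components
#' (time ms, weight) summing to 1, an MT saturation fraction delta
#' (ground-truth MTR = 100*delta), a relative proton density, exchange and
#' two-pool T1 mapping used by the mcDESPOT forward model, and a
#' between-subject coefficient of variation.
#'
#' The true myelin water fraction of a class is defined as the summed weight
#' of T2 components with 10 <= T2 <= 40 ms.
#'
#' @param classes named list overriding/extending the built-in defaults
#'   (`csf`, `gm`, `wm`, `subcortical`).
#' @param cv default between-subject coefficient of variation applied to
#'   t1, t2 times, myelin weight, mt_delta and proton density.
#' @return list of class `tissue_params`.
#' @export
tissue_params <- function(classes = list(), cv = 0.05) {
  stopifnot(cv >= 0)
  defaults <- list(
    csf = list(t1 = 4000, t2_times = 2000, t2_weights = 1,
               mt_delta = 0.02, pd = 1.00, k_mf = 0),
    gm = list(t1 = 1300, t2_times = c(20, 90), t2_weights = c(0.03, 0.97),
              mt_delta = 0.30, pd = 0.85, k_mf = 9),
    wm = list(t1 = 900, t2_times = c(20, 80), t2_weights = c(0.12, 0.88),
              mt_delta = 0.40, pd = 0.70, k_mf = 9),
    subcortical = list(t1 = 1100, t2_times = c(20, 85),
                       t2_weights = c(0.08, 0.92),
                       mt_delta = 0.35, pd = 0.80, k_mf = 9))
  for (nm in names(classes)) defaults[[nm]] <- utils::modifyList(
    if (is.null(defaults[[nm]])) list() else defaults[[nm]], classes[[nm]])
  for (nm in names(defaults)) {
    cl <- defaults[[nm]]
    stopifnot(cl$t1 > 0, all(cl$t2_times > 0), all(cl$t2_weights >= 0),
              cl$mt_delta >= 0, cl$mt_delta < 1, cl$pd > 0, cl$k_mf >= 0)
    if (abs(sum(cl$t2_weights) - 1) > 1e-8)
      stop("t2_weights must sum to 1 for class ", nm)
    if (is.null(cl$cv)) defaults[[nm]]$cv <- cv
  }
  structure(defaults, class = "tissue_params")
}

#' True myelin water fraction of a T2 component set
#' @param t2_times,t2_weights component times (ms) and weights.
#' @param window inclusive myelin-water window (ms).
#' @return summed weight of components inside the window.
#' @export
mwf_true <- function(t2_times, t2_weights, window = c(10, 40)) {
  sum(t2_weights[t2_times >= window[1] & t2_times <= window[2]])
}

#' Focal white-matter lesion model
#'
#' Lesion counts follow a negative binomial truncated to `count_range`; the
#' untruncated mean is solved so the truncated mean equals `count_mean`.
#' Radii are log-normal.  Parameter shifts reproduce the qualitative lesion
#' signature of relapsing-remitting MS: myelin water down, T1 up, MT
#' saturation down, water (proton density and long T2) up.
#'
#' @param count_mean,count_dispersion,count_range truncated negative-binomial
#'   lesion count model (per patient).
#' @param radius_meanlog,radius_sdlog log-normal lesion radius (mm).
#' @param mwf_scale,t1_scale,mt_delta_scale,pd_scale,long_t2_scale
#'   multiplicative shifts applied inside lesions.
#' @param perilesion_radius dilation radius (mm) defining perilesional tissue.
#' @return list of class `lesion_model`.
#' @export
lesion_model <- function(count_mean = 26.5, count_dispersion = 3,
                         count_range = c(3L, 71L),
                         radius_meanlog = log(2.35), radius_sdlog = 0.35,
                         mwf_scale = 0.4, t1_scale = 1.4,
                         mt_delta_scale = 0.7, pd_scale = 1.1,
                         long_t2_scale = 1.2, perilesion_radius = 2) {
  stopifnot(perilesion_radius > 0, count_mean > 0, count_dispersion > 0,
            count_range[1] >= 0, count_range[2] > count_range[1],
            mwf_scale >= 0, mwf_scale <= 1, t1_scale > 0,
            mt_delta_scale >= 0, mt_delta_scale <= 1, pd_scale > 0,
            long_t2_scale > 0)
  if (count_mean <= count_range[1] || count_mean >= count_range[2])
    stop("count_mean must lie inside count_range")
  structure(list(count_mean = count_mean, count_dispersion = count_dispersion,
                 count_range = as.integer(count_range),
                 radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
                 mwf_scale = mwf_scale, t1_scale = t1_scale,
                 mt_delta_scale = mt_delta_scale, pd_scale = pd_scale,
                 long_t2_scale = long_t2_scale,
                 perilesion_radius = perilesion_radius),
            class = "lesion_model")
}

# mean of a negative binomial truncated to [lo, hi]
trunc_nbinom_mean <- function(mu, size, lo, hi) {
  k <- lo:hi
  p <- dnbinom(k, size = size, mu = mu)
  sum(k * p) / sum(p)
}

# untruncated mu achieving a given truncated mean
solve_nbinom_mu <- function(target, size, lo, hi) {
  uniroot(function(mu) trunc_nbinom_mean(mu, size, lo, hi) - target,
          interval = c(1e-6, hi), tol = 1e-8)$root
}

# draw one truncated negative-binomial count (rejection sampling)
draw_lesion_count <- function(model) {
  mu <- solve_nbinom_mu(model$count_mean, model$count_dispersion,
                        model$count_range[1], model$count_range[2])
  for (i in 1:10000) {
    k <- rnbinom(1, size = model$count_dispersion, mu = mu)
    if (k >= model$count_range[1] && k <= model$count_range[2]) return(k)
  }
  stop("lesion count rejection sampling failed")
}

#' Cohort configuration
#'
#' @param n_controls,n_patients cohort sizes (controls >= 2 so the control SD
#'   is defined).
#' @param seed integer RNG seed; a fixed seed reproduces the cohort exactly.
#' @param geometry a [phantom_geometry()].
#' @param tissues a [tissue_params()].
#' @param lesions a [lesion_model()].
#' @param snr per-sequence signal-to-noise ratios (Rician magnitude noise).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 38, n_patients = 24, seed = 1,
                          geometry = phantom_geometry(),
                          tissues = tissue_params(),
                          lesions = lesion_model(),
                          snr = c(grase = 100, spgr = 100, bssfp = 100,
                                  irspgr = 100, mt = 100)) {
  stopifnot(n_controls >= 2, n_patients >= 0, all(snr > 0))
  req <- c("grase", "spgr", "bssfp", "irspgr", "mt")
  if (!all(req %in% names(snr))) stop("snr must name: ", paste(req, collapse = ", "))
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 seed = as.integer(seed), geometry = geometry,
                 tissues = tissues, lesions = lesions, snr = snr),
            class = "cohort_config")
}
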