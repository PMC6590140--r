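# Synthetic subjects: between-subject parameter sampling, focal WM lesion
# placement, mask morphology and on-disk cohort generation.

#' Sample one subject's ground truth
#'
#' Within a subject every voxel of a tissue class shares the class's realized
#' parameters: per class and parameter, value = class mean x a log-normal
#' multiplicative deviation whose coefficient of variation is the class `cv`
#' (sdlog = sqrt(log(1 + cv^2)), meanlog = -sdlog^2/2, so the mean is
#' unbiased).  Uses the current RNG state; seed with [set.seed()].
#'
#' @param tissues a [tissue_params()].
#' @param labels label volume from [build_label_volume()].
#' @param group `"control"` or `"patient"`.
#' @param subject_id identifier string.
#' @return list of class `subject_truth` with elements `labels`,
#'   `class_params` (realized per-class parameters incl. `mwf`),
#'   `lesion_mask`, `perilesion_mask`, `lesion_count`, `subject_id`, `group`.
#' @export
sample_subject <- function(tissues, labels, group = c("control", "patient"),
                           subject_id = "subj") {
  group <- match.arg(group)
  stopifnot(inherits(tissues, "tissue_params"))
  draw <- function(mean, cv, n = 1) {
    if (cv < 0) stop("CV < 0")
    if (cv == 0) return(rep(mean, n)[seq_len(n)])
    sdl <- sqrt(log(1 + cv^2))
    mean * exp(rnorm(n, -sdl^2 / 2, sdl))
  }
  cls <- lapply(tissues, function(cl) {
    t2t <- draw(1, cl$cv) * cl$t2_times          # shared factor: spacing kept
    w <- cl$t2_weights
    if (length(w) > 1) {                          # jitter the myelin weight
      short <- which.min(cl$t2_times)
      w[short] <- min(0.9, draw(cl$t2_weights[short], cl$cv))
      w[-short] <- (1 - w[short]) * cl$t2_weights[-short] /
        sum(cl$t2_weights[-short])
    }
    list(t1 = draw(cl$t1, cl$cv),
         t2_times = t2t, t2_weights = w,
         mwf = mwf_true(t2t, w),
         mt_delta = min(0.95, draw(cl$mt_delta, cl$cv)),
         pd = draw(cl$pd, cl$cv),
         k_mf = cl$k_mf)
  })
  names(cls) <- names(tissues)
  structure(list(labels = labels, class_params = cls,
                 lesion_mask = array(FALSE, dim(labels)),
                 perilesion_mask = array(FALSE, dim(labels)),
                 lesion_count = 0L,
                 subject_id = subject_id, group = group),
            class = "subject_truth")
}

#' Dilate a binary mask by a physical radius
#'
#' A voxel is set in the output iff its center lies within `radius` mm
#' (Euclidean) of the center of some input voxel; anisotropic voxel sizes are
#' honored.  Radii smaller than the smallest voxel dimension return the input.
#'
#' @param mask logical 3D array.
#' @param radius dilation radius (mm), > 0.
#' @param voxel_size mm triple.
#' @return logical array, superset of `mask`.
#' @export
dilate_mask <- function(mask, radius, voxel_size) {
  stopifnot(radius > 0, length(voxel_size) == 3, all(voxel_size > 0))
  n <- dim(mask)
  rng <- floor(radius / voxel_size)
  out <- array(FALSE, n)
  for (dx in -rng[1]:rng[1]) for (dy in -rng[2]:rng[2]) for (dz in -rng[3]:rng[3]) {
    if (sum((c(dx, dy, dz) * voxel_size)^2) > radius^2) next
    sx <- seq_len(n[1]) + dx; keepx <- sx >= 1 & sx <= n[1]
    sy <- seq_len(n[2]) + dy; keepy <- sy >= 1 & sy <= n[2]
    sz <- seq_len(n[3]) + dz; keepz <- sz >= 1 & sz <= n[3]
    out[which(keepx), which(keepy), which(keepz)] <-
      out[which(keepx), which(keepy), which(keepz)] |
      mask[sx[keepx], sy[keepy], sz[keepz]]
  }
  out
}

# realized lesion parameters from a subject's WM parameters + shift model
lesion_params_from_wm <- function(wm, model) {
  short <- which.min(wm$t2_times)
  w <- wm$t2_weights
  w[short] <- w[short] * model$mwf_scale
  w[-short] <- (1 - w[short]) * wm$t2_weights[-short] /
    sum(wm$t2_weights[-short])
  t2t <- wm$t2_times
  t2t[-short] <- t2t[-short] * model$long_t2_scale
  list(t1 = wm$t1 * model$t1_scale,
       t2_times = t2t, t2_weights = w,
       mwf = mwf_true(t2t, w),
       mt_delta = wm$mt_delta * model$mt_delta_scale,
       pd = wm$pd * model$pd_scale,
       k_mf = wm$k_mf)
}

#' Place focal WM lesions in a patient subject
#'
#' Draws a truncated negative-binomial lesion count and log-normal radii,
#' places spherical lesions at uniformly drawn WM voxel centers (rejecting
#' placements whose captured voxels would leave the WM + existing-lesion
#' support), relabels captured voxels as lesion, and derives the perilesional
#' rim as dilation(lesion, perilesion_radius) minus the lesion itself.
#' Lesions smaller than the voxel may capture no voxel; they still count
#' toward the per-patient lesion count (sub-resolution lesions).
#'
#' @param subject a `subject_truth` with `group == "patient"`.
#' @param model a [lesion_model()].
#' @param geometry the [phantom_geometry()] that produced the labels.
#' @param max_retries placement retries per lesion before giving up.
#' @return the subject with lesion/perilesion masks, updated labels and
#'   `class_params$lesion` filled in.
#' @export
place_lesions <- function(subject, model, geometry, max_retries = 200) {
  stopifnot(inherits(subject, "subject_truth"))
  if (subject$group != "patient") stop("lesions are only placed in patients")
  vs <- geometry$voxel_size
  labels <- subject$labels
  n_lesions <- draw_lesion_count(model)
  if (n_lesions == 0) { subject$lesion_count <- 0L; return(subject) }
  wm_idx <- which(labels == LABELS[["wm"]])
  if (length(wm_idx) == 0) stop("no WM voxels to place lesions in")
  dims <- dim(labels)
  co <- grid_coords(geometry)
  lesion <- array(FALSE, dims)
  placed <- 0L
  for (i in seq_len(n_lesions)) {
    r <- exp(rnorm(1, model$radius_meanlog, model$radius_sdlog))
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      support <- which(labels == LABELS[["wm"]] | lesion)
      center_idx <- support[ceiling(runif(1) * length(support))]
      ci <- arrayInd(center_idx, dims)
      # uniform placement within the chosen voxel, so the expected captured
      # volume equals the sphere volume (sub-voxel lesions may capture none)
      cmm <- c(co[[1]][ci[1]], co[[2]][ci[2]], co[[3]][ci[3]]) +
        runif(3, -0.5, 0.5) * vs
      rv <- ceiling(r / vs)
      xr <- max(1, ci[1] - rv[1]):min(dims[1], ci[1] + rv[1])
      yr <- max(1, ci[2] - rv[2]):min(dims[2], ci[2] + rv[2])
      zr <- max(1, ci[3] - rv[3]):min(dims[3], ci[3] + rv[3])
      d2 <- outer(outer((co[[1]][xr] - cmm[1])^2, (co[[2]][yr] - cmm[2])^2, "+"),
                  (co[[3]][zr] - cmm[3])^2, "+")
      cap <- which(d2 <= r^2, arr.ind = TRUE)
      if (nrow(cap) == 0) { ok <- TRUE; break }  # sub-resolution lesion
      vox <- cbind(xr[cap[, 1]], yr[cap[, 2]], zr[cap[, 3]])
      lab_cap <- labels[vox]
      if (all(lab_cap == LABELS[["wm"]] | lesion[vox])) {
        lesion[vox] <- TRUE
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("lesion demand exceeds available WM volume ",
                  "(placement failed after ", max_retries, " retries)")
    placed <- placed + 1L
  }
  labels[lesion] <- LABELS[["lesion"]]
  peri <- dilate_mask(lesion, model$perilesion_radius, vs) & !lesion
  subject$labels <- labels
  subject$lesion_mask <- lesion
  subject$perilesion_mask <- peri
  subject$lesion_count <- n_lesions
  subject$class_params$lesion <-
    lesion_params_from_wm(subject$class_params$wm, model)
  subject
}

#' Materialize a per-voxel parameter volume
#'
#' @param subject a `subject_truth`.
#' @param param one of `"t1"`, `"mwf"`, `"mt_delta"`, `"pd"`.
#' @return numeric array; background voxels are 0.
#' @export
subject_param_volume <- function(subject, param = c("t1", "mwf", "mt_delta", "pd")) {
  param <- match.arg(param)
  out <- array(0, dim(subject$labels))
  for (nm in names(subject$class_params)) {
    lab <- if (nm == "lesion") LABELS[["lesion"]] else LABELS[[nm]]
    out[subject$labels == lab] <- subject$class_params[[nm]][[param]]
  }
  out
}

#' Generate a cohort on disk
#'
#' Writes one directory per subject (label volume, lesion and perilesion
#' masks as NIfTI, realized class parameters as JSON) plus a cohort
#' `manifest.json`.  Deterministic for a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param out_dir writable output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(config$seed)
  labels0 <- build_label_volume(config$geometry)
  aff <- diag_affine(config$geometry$voxel_size)
  ids <- c(sprintf("control_%02d", seq_len(config$n_controls)),
           sprintf("patient_%02d", seq_len(config$n_patients)))
  groups <- rep(c("control", "patient"),
                c(config$n_controls, config$n_patients))
  entries <- list()
  for (i in seq_along(ids)) {
    subj <- sample_subject(config$tissues, labels0, groups[i], ids[i])
    if (groups[i] == "patient")
      subj <- place_lesions(subj, config$lesions, config$geometry)
    sdir <- file.path(out_dir, ids[i])
    dir.create(sdir, showWarnings = FALSE)
    write_volume(volume_record(subj$labels, aff, units = "label",
                               modality = "labels"),
                 file.path(sdir, "labels.nii.gz"), dtype = "uint8")
    write_volume(volume_record(array(as.integer(subj$lesion_mask),
                                     dim(subj$labels)), aff,
                               units = "mask", modality = "lesion_mask"),
                 file.path(sdir, "lesion_mask.nii.gz"), dtype = "uint8")
    write_volume(volume_record(array(as.integer(subj$perilesion_mask),
                                     dim(subj$labels)), aff,
                               units = "mask", modality = "perilesion"),
                 file.path(sdir, "perilesion_mask.nii.gz"), dtype = "uint8")
    jsonlite::write_json(subj$class_params,
                         file.path(sdir, "class_params.json"),
                         auto_unbox = TRUE, digits = NA)
    entries[[i]] <- list(subject_id = ids[i], group = groups[i],
                         lesion_count = subj$lesion_count,
                         lesion_voxels = sum(subj$lesion_mask))
  }
  manifest <- list(seed = config$seed, n_controls = config$n_controls,
                   n_patients = config$n_patients,
                   grid_shape = config$geometry$grid_shape,
                   voxel_size = config$geometry$voxel_size,
                   subjects = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
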