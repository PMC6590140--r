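# Parametric phantom geometry: nested ellipsoids standing in for atlas-derived
# tissue masks.  Labels: 0 background, 1 CSF (ventricles), 2 cortical GM
# shell, 3 WM, 4 subcortical gray, 5 lesion (assigned later).

LABELS <- c(background = 0L, csf = 1L, gm = 2L, wm = 3L, subcortical = 4L,
            lesion = 5L)

#' Phantom geometry
#'
#' Defines the grid and the nested tissue regions (all radii/offsets in mm,
#' regions centered on the grid center): an outer brain ellipsoid whose shell
#' is cortical GM, a WM ellipsoid, two CSF "ventricles" and two subcortical
#' gray blobs carved out of the WM.
#'
#' @param grid_shape integer triple, each >= 16.
#' @param voxel_size mm triple, all > 0.
#' @param brain_radii,wm_radii outer-brain and WM ellipsoid semi-axes (mm).
#' @param ventricle_radii,ventricle_offset CSF ellipsoid semi-axes and the
#'   +/- x offset of the two ventricles (mm).
#' @param subcortical_radii,subcortical_offset same for the subcortical blobs.
#' @return list of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_shape = c(32L, 32L, 32L),
                             voxel_size = c(6, 6, 6),
                             brain_radii = c(72, 60, 54),
                             wm_radii = c(57, 48, 42),
                             ventricle_radii = c(10, 7, 7),
                             ventricle_offset = 12,
                             subcortical_radii = c(12, 9, 9),
                             subcortical_offset = 30) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16),
            length(voxel_size) == 3, all(voxel_size > 0))
  for (r in list(brain_radii, wm_radii, ventricle_radii, subcortical_radii))
    if (any(r <= 0)) stop("configuration error: region radius <= 0")
  if (any(wm_radii >= brain_radii))
    stop("configuration error: WM ellipsoid must nest inside the brain")
  fov <- grid_shape * voxel_size
  if (any(2 * brain_radii > fov))
    stop("configuration error: brain exceeds the grid field of view")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 brain_radii = brain_radii, wm_radii = wm_radii,
                 ventricle_radii = ventricle_radii,
                 ventricle_offset = ventricle_offset,
                 subcortical_radii = subcortical_radii,
                 subcortical_offset = subcortical_offset),
            class = "phantom_geometry")
}

# mm coordinates of voxel centers relative to the grid center, per axis
grid_coords <- function(geometry) {
  lapply(1:3, function(i) {
    n <- geometry$grid_shape[i]; v <- geometry$voxel_size[i]
    (seq_len(n) - (n + 1) / 2) * v
  })
}

inside_ellipsoid <- function(co, center, radii) {
  d1 <- ((co[[1]] - center[1]) / radii[1])^2
  d2 <- ((co[[2]] - center[2]) / radii[2])^2
  d3 <- ((co[[3]] - center[3]) / radii[3])^2
  outer(outer(d1, d2, "+"), d3, "+") <= 1
}

#' Build the tissue label volume
#'
#' Every voxel receives exactly one label; later regions override earlier
#' ones so the regions are mutually exclusive by construction.
#'
#' @param geometry a [phantom_geometry()].
#' @return integer 3D array of labels (see `LABELS`).
#' @export
build_label_volume <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  co <- grid_coords(geometry)
  lab <- array(LABELS[["background"]], dim = geometry$grid_shape)
  lab[inside_ellipsoid(co, c(0, 0, 0), geometry$brain_radii)] <- LABELS[["gm"]]
  lab[inside_ellipsoid(co, c(0, 0, 0), geometry$wm_radii)] <- LABELS[["wm"]]
  for (s in c(-1, 1)) {
    lab[inside_ellipsoid(co, c(s * geometry$subcortical_offset, 0, 0),
                         geometry$subcortical_radii) &
          lab == LABELS[["wm"]]] <- LABELS[["subcortical"]]
    lab[inside_ellipsoid(co, c(s * geometry$ventricle_offset, 0, 0),
                         geometry$ventricle_radii) &
          lab %in% c(LABELS[["wm"]], LABELS[["subcortical"]])] <- LABELS[["csf"]]
  }
  lab
}

#' Convenience tissue masks from a label volume
#' @param labels integer label array.
#' @return named list of logical arrays (brain = all non-background).
#' @export
label_masks <- function(labels) {
  m <- lapply(LABELS, function(v) labels == v)
  m$brain <- labels != LABELS[["background"]]
  m
}
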