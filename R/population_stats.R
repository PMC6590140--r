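# Group-level machinery: normative control mean/SD maps, patient Z-maps,
# voxelwise inter-method Spearman correlation, tissue histograms, ROI
# summaries with lesion/perilesion exclusion, and group difference tests.

as_data <- function(x) if (inherits(x, "qm_volume")) x$data else x

#' Voxelwise control mean and SD maps
#'
#' Arithmetic mean and sample SD (n-1 denominator) across subjects,
#' computed only where every subject is valid (finite); elsewhere NA.
#'
#' @param maps list of per-subject volumes (arrays or `qm_volume`s) on a
#'   common grid.
#' @param mask optional logical array restricting the computation.
#' @return list of class `cohort_stats`: `mean`, `sd`, `n_subjects`.
#' @export
cohort_mean_sd <- function(maps, mask = NULL) {
  stopifnot(length(maps) >= 2)
  arrays <- lapply(maps, as_data)
  d <- dim(arrays[[1]])
  for (a in arrays) if (!identical(dim(a), d)) stop("grid mismatch across subjects")
  X <- vapply(arrays, as.vector, numeric(prod(d)))
  ok <- rowSums(!is.finite(X)) == 0
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  mu <- rep(NA_real_, nrow(X)); sdv <- rep(NA_real_, nrow(X))
  mu[ok] <- rowMeans(X[ok, , drop = FALSE])
  sdv[ok] <- sqrt(rowSums((X[ok, , drop = FALSE] - mu[ok])^2) / (ncol(X) - 1))
  structure(list(mean = array(mu, d), sd = array(sdv, d),
                 n_subjects = length(maps)), class = "cohort_stats")
}

#' Z-normalize a subject map against control statistics
#'
#' `z = (value - control mean) / control SD`, masked (NA) where the SD is 0
#' or undefined.
#'
#' @param map subject volume (array or `qm_volume`).
#' @param stats a [cohort_mean_sd()] result computed from controls only.
#' @return Z array (dimensionless).
#' @export
zmap <- function(map, stats) {
  stopifnot(inherits(stats, "cohort_stats"))
  x <- as_data(map)
  if (!identical(dim(x), dim(stats$mean))) stop("grid mismatch")
  z <- (x - stats$mean) / stats$sd
  z[!is.finite(z) | stats$sd == 0] <- NA_real_
  z
}

#' Voxelwise Spearman correlation between two modalities across subjects
#'
#' At each voxel, the rank correlation (average ranks for ties) across the
#' subject dimension between the two map sets.  Voxels where any subject is
#' invalid, or where either modality is constant across subjects, are NA.
#'
#' @param maps_a,maps_b lists of per-subject volumes, same subjects in the
#'   same order.
#' @param mask optional logical array.
#' @return list of class `correlation_map`: `rho` (array), `n` (subjects).
#' @export
voxelwise_spearman <- function(maps_a, maps_b, mask = NULL) {
  n <- length(maps_a)
  if (length(maps_b) != n) stop("subject lists differ in length")
  if (n < 4) stop("need at least 4 subjects")
  A <- vapply(lapply(maps_a, as_data), as.vector, numeric(length(as_data(maps_a[[1]]))))
  B <- vapply(lapply(maps_b, as_data), as.vector, numeric(nrow(A) * 0 + nrow(A)))
  d <- dim(as_data(maps_a[[1]]))
  ok <- rowSums(!is.finite(A)) == 0 & rowSums(!is.finite(B)) == 0
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  rho <- rep(NA_real_, nrow(A))
  if (any(ok)) {
    RA <- t(apply(A[ok, , drop = FALSE], 1, rank))
    RB <- t(apply(B[ok, , drop = FALSE], 1, rank))
    ra <- RA - rowMeans(RA); rb <- RB - rowMeans(RB)
    den <- sqrt(rowSums(ra^2) * rowSums(rb^2))
    r <- rowSums(ra * rb) / den
    r[den == 0] <- NA_real_          # constant across subjects
    rho[ok] <- pmin(1, pmax(-1, r))
  }
  structure(list(rho = array(rho, d), n = n), class = "correlation_map")
}

#' Two-tailed critical value of the Spearman correlation
#'
#' Smallest rho whose two-tailed p-value is at or below `alpha`.  For
#' `n > 8` the t-approximation `t = rho sqrt((n-2)/(1-rho^2))` with `n-2`
#' degrees of freedom is inverted; for `n <= 8` the exact permutation null
#' distribution of Spearman's rho is enumerated.
#'
#' @param n number of subjects (>= 4).
#' @param alpha two-tailed level in (0, 1).
#' @return critical rho in (0, 1).
#' @export
spearman_critical_value <- function(n, alpha = 0.05) {
  stopifnot(n >= 4)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n <= 8) {
    perms <- all_permutations(n)
    base <- seq_len(n)
    rhos <- apply(perms, 1, function(p) cor(base, p))
    rhos <- round(rhos, 12)
    ts <- sort(unique(abs(rhos)))
    for (t in ts) if (mean(abs(rhos) >= t) <= alpha) return(t)
    return(1)
  }
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Per-tissue normalized histograms of a correlation map
#'
#' @param corr a `correlation_map` (or rho array).
#' @param tissue_masks named list of disjoint logical arrays.
#' @param breaks histogram breaks over [-1, 1].
#' @return data.frame with columns `tissue`, `mid`, `density`, `count`;
#'   densities integrate to 1 per tissue.  Empty masks yield no rows and a
#'   warning.
#' @export
tissue_histograms <- function(corr, tissue_masks,
                              breaks = seq(-1, 1, length.out = 41)) {
  rho <- if (inherits(corr, "correlation_map")) corr$rho else corr
  acc <- array(0L, dim(rho))
  for (m in tissue_masks) {
    if (any(acc[m] > 0)) stop("tissue masks must be disjoint")
    acc[m] <- acc[m] + 1L
  }
  out <- list()
  for (nm in names(tissue_masks)) {
    v <- rho[tissue_masks[[nm]]]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      warning("empty mask for tissue ", nm)
      next
    }
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    out[[nm]] <- data.frame(tissue = nm, mid = h$mids, density = h$density,
                            count = h$counts)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-subject ROI summary with lesion/perilesion exclusion
#'
#' Mean map value per region over `roi & !lesion & !perilesion` (for
#' patients this is normal-appearing tissue by construction), plus separate
#' `lesion` and `perilesion` rows when those masks are non-empty.  Regions
#' emptied by the exclusion are flagged absent (NA mean).
#'
#' @param map_set a `quant_map_set` (or named list of volumes/arrays).
#' @param roi_masks named list of logical arrays.
#' @param lesion_mask,perilesion_mask logical arrays (empty for controls).
#' @param subject_id,group identifiers copied into the rows.
#' @return data.frame: `subject_id`, `group`, `region`, `modality`, `mean`,
#'   `n_voxels`, `absent`.
#' @export
roi_summary <- function(map_set, roi_masks, lesion_mask = NULL,
                        perilesion_mask = NULL, subject_id = "subj",
                        group = "control") {
  maps <- if (inherits(map_set, "quant_map_set")) map_set$maps else map_set
  d <- dim(as_data(maps[[1]]))
  if (is.null(lesion_mask)) lesion_mask <- array(FALSE, d)
  if (is.null(perilesion_mask)) perilesion_mask <- array(FALSE, d)
  excl <- lesion_mask | perilesion_mask
  rows <- list()
  regions <- c(roi_masks,
               if (any(lesion_mask)) list(lesion = lesion_mask),
               if (any(perilesion_mask)) list(perilesion = perilesion_mask))
  keepers <- names(regions) %in% c("lesion", "perilesion")
  for (i in seq_along(regions)) {
    nm <- names(regions)[i]
    sel <- regions[[i]]
    if (!keepers[i]) sel <- sel & !excl
    for (mod in names(maps)) {
      v <- as_data(maps[[mod]])[sel]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject_id, group = group, region = nm, modality = mod,
        mean = if (length(v)) mean(v) else NA_real_,
        n_voxels = length(v), absent = length(v) == 0L)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group differences per region and modality
#'
#' Two-sided Mann-Whitney U test of control vs patient per-subject ROI
#' means, with Bonferroni-Holm correction across regions within each
#' modality.  Samples that are entirely tied give p = 1.
#'
#' @param roi_table data.frame of stacked [roi_summary()] rows for all
#'   subjects (needs `group`, `region`, `modality`, `mean`).
#' @param control_group,patient_group level names in `group`.
#' @return data.frame: `region`, `modality`, group means, `p_raw`,
#'   `p_adjusted`.
#' @export
group_difference <- function(roi_table, control_group = "control",
                             patient_group = "patient") {
  df <- roi_table[is.finite(roi_table$mean), ]
  out <- list()
  for (mod in unique(df$modality)) {
    sub <- df[df$modality == mod, ]
    regions <- setdiff(unique(sub$region), c("lesion", "perilesion"))
    ps <- rep(NA_real_, length(regions))
    ms <- list()
    for (i in seq_along(regions)) {
      x <- sub$mean[sub$region == regions[i] & sub$group == control_group]
      y <- sub$mean[sub$region == regions[i] & sub$group == patient_group]
      if (length(x) < 3 || length(y) < 3)
        stop("need at least 3 subjects per group (region ", regions[i], ")")
      ps[i] <- if (length(unique(c(x, y))) == 1) 1 else
        suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
      ms[[i]] <- c(mean(x), mean(y))
    }
    out[[mod]] <- data.frame(
      region = regions, modality = mod,
      control_mean = vapply(ms, `[`, 0, 1),
      patient_mean = vapply(ms, `[`, 0, 2),
      p_raw = ps, p_adjusted = holm_correct(ps))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
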