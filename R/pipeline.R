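# Orchestration: an in-memory cohort analysis driver (simulate -> fit ->
# normative stats -> ROC -> inter-method comparison) and a disk-based staged
# pipeline with resumable artifacts.

#' Abnormality direction per modality
#'
#' In lesions, myelin-water fractions and MTR fall while qT1 rises; the ROC
#' sweep is signed accordingly.
#' @param direction `"signed"` (default) or `"abs"` for a |Z| sweep.
#' @return named character vector for the four modalities.
#' @export
modality_directions <- function(direction = c("signed", "abs")) {
  direction <- match.arg(direction)
  if (direction == "abs")
    return(c(mwf_g = "abs", mwf_d = "abs", qt1 = "abs", mtr = "abs"))
  c(mwf_g = "low_abnormal", mwf_d = "low_abnormal",
    qt1 = "high_abnormal", mtr = "low_abnormal")
}

# reduced-cost SRC settings used for whole-cohort map fitting; single-voxel
# accuracy work should use the full src_config() defaults
pipeline_src_config <- function() {
  src_config(n_samples = 90, n_retain = 12, n_iterations = 3,
             polish = TRUE, polish_iter = 6)
}

#' Run the full cohort analysis in memory
#'
#' Simulates every subject of the configured cohort, fits the four
#' quantitative maps, builds control normative statistics and patient
#' Z-maps, computes per-patient ROC/AUC against the ground-truth lesion
#' masks, the inter-method AUC comparison, ROI summaries with
#' lesion/perilesion exclusion and group tests.
#'
#' The SRC settings default to a reduced-cost configuration
#' (90 draws x 3 iterations + short LM polish per voxel) so a
#' 38-control / 24-patient cohort at 32^3 fits in a desktop-minutes budget;
#' pass `src = src_config()` for the full-accuracy settings.
#'
#' @param config a [cohort_config()].
#' @param protocols list from [default_protocols()].
#' @param src an [src_config()] for the mcDESPOT stage.
#' @param direction ROC sweep convention, see [modality_directions()].
#' @param keep_maps keep all fitted maps in the result (memory permitting).
#' @param verbose print per-subject progress.
#' @return list of class `cohort_analysis` with elements `config`, `stats`
#'   (per modality [cohort_mean_sd()]), `zmaps` (patients x modalities),
#'   `rocs`, `auc` (matrix), `comparison` ([compare_methods()]),
#'   `roi_table`, `group_tests`, `lesion_truth` (per-patient masks),
#'   `subjects` (per-subject metadata), and `maps` if `keep_maps`.
#' @export
run_cohort_analysis <- function(config = cohort_config(),
                                protocols = default_protocols(),
                                src = pipeline_src_config(),
                                direction = "signed",
                                keep_maps = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  labels0 <- build_label_volume(config$geometry)
  masks0 <- label_masks(labels0)
  dirs <- modality_directions(direction)
  modalities <- names(dirs)

  ids <- c(sprintf("control_%02d", seq_len(config$n_controls)),
           sprintf("patient_%02d", seq_len(config$n_patients)))
  groups <- rep(c("control", "patient"),
                c(config$n_controls, config$n_patients))
  maps <- vector("list", length(ids))
  lesions <- vector("list", length(ids))
  perilesions <- vector("list", length(ids))
  meta <- vector("list", length(ids))
  roi_rows <- list()

  for (i in seq_along(ids)) {
    t0 <- proc.time()[3]
    subj <- sample_subject(config$tissues, labels0, groups[i], ids[i])
    if (groups[i] == "patient")
      subj <- place_lesions(subj, config$lesions, config$geometry)
    acq <- simulate_acquisitions(subj, protocols, config$snr,
                                 geometry = config$geometry)
    fit <- fit_subject(acq, protocols, src = src)
    marr <- lapply(fit$maps[modalities], function(v) v$data)
    maps[[i]] <- marr
    lesions[[i]] <- subj$lesion_mask
    perilesions[[i]] <- subj$perilesion_mask
    # per-subject ROI summary over pre-lesion tissue regions
    wm_mask <- subj$labels == LABELS[["wm"]] | subj$lesion_mask
    rois <- list(wm = wm_mask, gm = masks0$gm, subcortical = masks0$subcortical)
    roi_rows[[i]] <- roi_summary(marr, rois, subj$lesion_mask,
                                 subj$perilesion_mask, ids[i], groups[i])
    meta[[i]] <- list(subject_id = ids[i], group = groups[i],
                      lesion_count = subj$lesion_count,
                      lesion_voxels = sum(subj$lesion_mask),
                      truth = subj$class_params)
    if (verbose)
      message(sprintf("%s fitted in %.1fs (lesion voxels: %d)", ids[i],
                      proc.time()[3] - t0, sum(subj$lesion_mask)))
  }

  is_ctrl <- groups == "control"
  stats <- lapply(modalities, function(m)
    cohort_mean_sd(lapply(maps[is_ctrl], `[[`, m), mask = masks0$brain))
  names(stats) <- modalities

  pat_idx <- which(!is_ctrl)
  zmaps <- list(); rocs <- list()
  auc <- matrix(NA_real_, length(pat_idx), length(modalities),
                dimnames = list(ids[pat_idx], modalities))
  for (j in seq_along(pat_idx)) {
    i <- pat_idx[j]
    analysis_mask <- masks0$brain & !perilesions[[i]]
    zm <- lapply(modalities, function(m) zmap(maps[[i]][[m]], stats[[m]]))
    names(zm) <- modalities
    zmaps[[ids[i]]] <- zm
    if (!any(lesions[[i]])) next   # sub-resolution patient: ROC undefined
    for (m in modalities) {
      r <- roc_curve(zm[[m]], lesions[[i]], analysis_mask, dirs[[m]],
                     subject_id = ids[i], modality = m)
      rocs[[paste(ids[i], m, sep = ".")]] <- r
      auc[j, m] <- r$auc
    }
  }

  roi_table <- do.call(rbind, c(roi_rows, list(make.row.names = FALSE)))
  group_tests <- if (any(!is_ctrl)) group_difference(roi_table) else NULL
  comparison <- if (sum(stats::complete.cases(auc)) >= 3)
    compare_methods(auc) else NULL

  structure(list(config = config, stats = stats, zmaps = zmaps, rocs = rocs,
                 auc = auc, comparison = comparison, roi_table = roi_table,
                 group_tests = group_tests,
                 lesion_truth = lesions[pat_idx],
                 perilesion_truth = perilesions[pat_idx],
                 tissue_masks = masks0, subjects = meta,
                 maps = if (keep_maps) maps else NULL,
                 groups = groups, ids = ids),
            class = "cohort_analysis")
}

#' Voxelwise inter-method correlation analysis of a fitted cohort
#'
#' Spearman correlation maps across control subjects for every modality
#' pair, restricted to voxels valid in all subjects and both modalities,
#' with per-tissue histograms.
#'
#' @param analysis a `cohort_analysis` run with `keep_maps = TRUE`.
#' @param pairs 2-column matrix of modality name pairs; default all 6.
#' @return named list per pair: `correlation_map` plus `histograms`.
#' @export
cohort_correlations <- function(analysis, pairs = NULL) {
  if (is.null(analysis$maps))
    stop("run_cohort_analysis(keep_maps = TRUE) required")
  modalities <- colnames(analysis$auc)
  if (is.null(pairs)) pairs <- t(utils::combn(modalities, 2))
  ctrl <- which(analysis$groups == "control")
  tm <- analysis$tissue_masks
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    cm <- voxelwise_spearman(lapply(analysis$maps[ctrl], `[[`, a),
                             lapply(analysis$maps[ctrl], `[[`, b),
                             mask = tm$brain)
    hist <- tissue_histograms(cm, list(wm = tm$wm, gm = tm$gm,
                                       subcortical = tm$subcortical))
    out[[paste(a, b, sep = "_vs_")]] <- list(correlation = cm,
                                             histograms = hist)
  }
  out
}

# ---------------------------------------------------------------------------
# staged on-disk pipeline

PIPELINE_STAGES <- c("simulate", "fit", "zmap", "corrmap", "roi-stats",
                     "lesion-roc", "compare-auc")

need_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact ", path, "; run stage '", producer, "' first",
         call. = FALSE)
  path
}

#' Run the staged pipeline on disk
#'
#' Stages (in order): `simulate` writes ground truth + acquisitions,
#' `fit` writes quantitative maps, `zmap` writes control mean/SD and patient
#' Z volumes, `corrmap` writes Spearman correlation volumes + histograms,
#' `roi-stats` writes the ROI table and group tests, `lesion-roc` writes
#' per-patient ROC tables and the AUC matrix, `compare-auc` writes the
#' inter-method comparison.  Stages are resumable: each reads its inputs
#' from `out_dir` and errors naming the producing stage if they are absent.
#'
#' @param config a [cohort_config()].
#' @param out_dir output root.
#' @param stages subset of the stage names, kept in pipeline order.
#' @param protocols protocol list.
#' @param src SRC settings for the `fit` stage.
#' @param fit_modalities modality subset for the `fit` stage (see
#'   [fit_subject()]).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = PIPELINE_STAGES,
                         protocols = default_protocols(),
                         src = pipeline_src_config(),
                         fit_modalities = c("grase", "mcdespot", "mtr")) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  aff <- diag_affine(config$geometry$voxel_size)
  manifest_path <- file.path(out_dir, "manifest.json")
  log_path <- file.path(out_dir, "log.jsonl")
  log_line <- function(...) {
    rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path,
        append = TRUE)
  }

  if ("simulate" %in% stages) {
    log_line(stage = "simulate", seed = config$seed)
    generate_cohort(config, out_dir)
    set.seed(config$seed + 1L)
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    for (i in seq_len(nrow(man$subjects))) {
      id <- man$subjects$subject_id[i]
      sdir <- file.path(out_dir, id)
      labels <- read_volume(file.path(sdir, "labels.nii.gz"))$data
      cp <- jsonlite::read_json(file.path(sdir, "class_params.json"),
                                simplifyVector = TRUE)
      subj <- structure(list(labels = array(as.integer(labels), dim(labels)),
                             class_params = cp,
                             lesion_mask = read_volume(file.path(sdir, "lesion_mask.nii.gz"))$data > 0,
                             perilesion_mask = read_volume(file.path(sdir, "perilesion_mask.nii.gz"))$data > 0,
                             subject_id = id, group = man$subjects$group[i]),
                        class = "subject_truth")
      acq <- simulate_acquisitions(subj, protocols, config$snr,
                                   geometry = config$geometry)
      for (nm in c("grase", "spgr", "bssfp", "mt")) {
        if (is.null(acq[[nm]])) next
        write_volume(volume_record(acq[[nm]], aff, units = "au", modality = nm),
                     file.path(sdir, paste0(nm, ".nii.gz")))
      }
      write_volume(volume_record(acq$irspgr, aff, units = "au",
                                 modality = "irspgr"),
                   file.path(sdir, "irspgr.nii.gz"))
      sidecar <- list(grase = unclass(protocols$grase),
                      mcdespot = unclass(protocols$mcdespot),
                      mt = unclass(protocols$mt))
      jsonlite::write_json(sidecar, file.path(sdir, "protocols.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  man <- jsonlite::read_json(need_artifact(manifest_path, "simulate"),
                             simplifyVector = TRUE)
  subjects <- man$subjects
  modalities <- names(modality_directions())

  if ("fit" %in% stages) {
    log_line(stage = "fit", seed = config$seed + 2L)
    set.seed(config$seed + 2L)
    for (i in seq_len(nrow(subjects))) {
      sdir <- file.path(out_dir, subjects$subject_id[i])
      acq <- list(
        grase = read_volume(need_artifact(file.path(sdir, "grase.nii.gz"),
                                          "simulate"))$data,
        spgr = read_volume(file.path(sdir, "spgr.nii.gz"))$data,
        bssfp = read_volume(file.path(sdir, "bssfp.nii.gz"))$data,
        irspgr = read_volume(file.path(sdir, "irspgr.nii.gz"))$data,
        affine = aff)
      mtp <- file.path(sdir, "mt.nii.gz")
      if (file.exists(mtp)) acq$mt <- read_volume(mtp)$data
      labels <- read_volume(file.path(sdir, "labels.nii.gz"))$data
      acq$brain_mask <- labels > 0
      fit <- fit_subject(acq, protocols, src = src,
                         modalities = fit_modalities)
      for (m in names(fit$maps))
        write_volume(fit$maps[[m]], file.path(sdir, paste0(m, ".nii.gz")))
    }
  }

  ctrl_ids <- subjects$subject_id[subjects$group == "control"]
  pat_ids <- subjects$subject_id[subjects$group == "patient"]
  read_map <- function(id, m)
    read_volume(need_artifact(file.path(out_dir, id, paste0(m, ".nii.gz")),
                              "fit"))$data

  if ("zmap" %in% stages) {
    log_line(stage = "zmap")
    for (m in modalities) {
      st <- cohort_mean_sd(lapply(ctrl_ids, read_map, m = m))
      write_volume(volume_record(st$mean, aff, modality = paste0(m, "_mean")),
                   file.path(out_dir, paste0("control_mean_", m, ".nii.gz")))
      write_volume(volume_record(st$sd, aff, modality = paste0(m, "_sd")),
                   file.path(out_dir, paste0("control_sd_", m, ".nii.gz")))
      for (id in pat_ids) {
        z <- zmap(read_map(id, m), st)
        write_volume(volume_record(z, aff, units = "z",
                                   modality = paste0("z_", m)),
                     file.path(out_dir, id, paste0("z_", m, ".nii.gz")))
      }
    }
  }

  if ("corrmap" %in% stages) {
    log_line(stage = "corrmap")
    labels <- read_volume(file.path(out_dir, ctrl_ids[1], "labels.nii.gz"))$data
    tm <- label_masks(array(as.integer(labels), dim(labels)))
    prs <- t(utils::combn(modalities, 2))
    hist_rows <- list()
    for (r in seq_len(nrow(prs))) {
      a <- prs[r, 1]; b <- prs[r, 2]
      cm <- voxelwise_spearman(lapply(ctrl_ids, read_map, m = a),
                               lapply(ctrl_ids, read_map, m = b),
                               mask = tm$brain)
      write_volume(volume_record(cm$rho, aff, units = "rho",
                                 modality = paste0(a, "_", b)),
                   file.path(out_dir, paste0("spearman_", a, "_", b, ".nii.gz")))
      h <- tissue_histograms(cm, list(wm = tm$wm, gm = tm$gm,
                                      subcortical = tm$subcortical))
      h$pair <- paste(a, b, sep = "_vs_")
      hist_rows[[r]] <- h
    }
    write.table(do.call(rbind, hist_rows),
                file.path(out_dir, "correlation_histograms.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if ("roi-stats" %in% stages) {
    log_line(stage = "roi-stats")
    rows <- list()
    for (i in seq_len(nrow(subjects))) {
      id <- subjects$subject_id[i]
      labels <- read_volume(file.path(out_dir, id, "labels.nii.gz"))$data
      labels <- array(as.integer(labels), dim(labels))
      les <- read_volume(file.path(out_dir, id, "lesion_mask.nii.gz"))$data > 0
      per <- read_volume(file.path(out_dir, id, "perilesion_mask.nii.gz"))$data > 0
      marr <- lapply(setNames(modalities, modalities), read_map, id = id)
      rois <- list(wm = labels == LABELS[["wm"]] | les,
                   gm = labels == LABELS[["gm"]],
                   subcortical = labels == LABELS[["subcortical"]])
      rows[[i]] <- roi_summary(marr, rois, les, per, id, subjects$group[i])
    }
    tab <- do.call(rbind, rows)
    write.table(tab, file.path(out_dir, "roi_table.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    if (length(pat_ids) >= 3) {
      gt <- group_difference(tab)
      write.table(gt, file.path(out_dir, "group_tests.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
  }

  if ("lesion-roc" %in% stages) {
    log_line(stage = "lesion-roc")
    dirs <- modality_directions()
    auc_rows <- list()
    for (id in pat_ids) {
      les <- read_volume(file.path(out_dir, id, "lesion_mask.nii.gz"))$data > 0
      per <- read_volume(file.path(out_dir, id, "perilesion_mask.nii.gz"))$data > 0
      labels <- read_volume(file.path(out_dir, id, "labels.nii.gz"))$data
      amask <- labels > 0 & !per
      if (!any(les)) next
      aucs <- setNames(rep(NA_real_, length(modalities)), modalities)
      for (m in modalities) {
        zf <- need_artifact(file.path(out_dir, id, paste0("z_", m, ".nii.gz")),
                            "zmap")
        r <- roc_curve(read_volume(zf)$data, les, amask, dirs[[m]],
                       subject_id = id, modality = m)
        write.table(data.frame(threshold = r$thresholds, fpr = r$fpr,
                               tpr = r$tpr),
                    file.path(out_dir, id, paste0("roc_", m, ".tsv")),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        aucs[m] <- r$auc
      }
      auc_rows[[id]] <- data.frame(subject_id = id, t(aucs))
    }
    write.table(do.call(rbind, auc_rows), file.path(out_dir, "auc_matrix.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if ("compare-auc" %in% stages) {
    log_line(stage = "compare-auc")
    tab <- utils::read.delim(need_artifact(file.path(out_dir, "auc_matrix.tsv"),
                                           "lesion-roc"))
    X <- as.matrix(tab[, -1, drop = FALSE])
    rownames(X) <- tab$subject_id
    cmp <- compare_methods(X)
    write.table(cmp$summary, file.path(out_dir, "auc_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(friedman = cmp$friedman,
                              pairwise = cmp$pairwise),
                         file.path(out_dir, "auc_tests.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
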