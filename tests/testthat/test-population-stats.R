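test_that("cohort mean/SD maps match closed forms and a streaming oracle", {
  d <- c(6, 6, 6)
  same <- replicate(5, array(3.5, d), simplify = FALSE)
  st <- cohort_mean_sd(same)
  expect_true(all(st$sd == 0))
  expect_true(all(st$mean == 3.5))

  a <- array(1, d); b <- array(2, d)
  st2 <- cohort_mean_sd(list(a, b))
  expect_true(all(st2$mean == 1.5))
  expect_equal(st2$sd[1], 1 / sqrt(2))   # |a-b|/sqrt(2), n-1 denominator

  set.seed(51)
  maps <- replicate(38, array(rnorm(prod(d)), d), simplify = FALSE)
  st3 <- cohort_mean_sd(maps)
  # streaming-moments oracle (Welford)
  mu <- array(0, d); m2 <- array(0, d)
  for (k in seq_along(maps)) {
    delta <- maps[[k]] - mu
    mu <- mu + delta / k
    m2 <- m2 + delta * (maps[[k]] - mu)
  }
  expect_lt(max(abs(st3$mean - mu)), 1e-12)
  expect_lt(max(abs(st3$sd - sqrt(m2 / 37))), 1e-12)
  expect_error(cohort_mean_sd(list(a, array(0, c(5, 5, 5)))), "grid")
})

test_that("Z-maps normalize against control statistics", {
  d <- c(5, 5, 5)
  set.seed(52)
  maps <- replicate(10, array(rnorm(125, 10, 2), d), simplify = FALSE)
  st <- cohort_mean_sd(maps)
  expect_true(all(abs(zmap(st$mean, st)) < 1e-12))
  expect_equal(zmap(st$mean + 2 * st$sd, st), array(2, d))
  # affine equivariance: rescaling units leaves Z unchanged
  maps_ms <- lapply(maps, function(m) 1000 * m + 5)
  st_ms <- cohort_mean_sd(maps_ms)
  expect_equal(zmap(1000 * maps[[1]] + 5, st_ms), zmap(maps[[1]], st),
               tolerance = 1e-9)
  # held-out controls: ~95% of Z within +-2 under Gaussian variation
  set.seed(53)
  big <- replicate(40, array(rnorm(4096), c(16, 16, 16)), simplify = FALSE)
  stb <- cohort_mean_sd(big[1:38])
  zh <- abs(c(zmap(big[[39]], stb), zmap(big[[40]], stb)))
  expect_gt(mean(zh < 2), 0.92)
  expect_lt(mean(zh < 2), 0.98)
})

test_that("voxelwise Spearman: rank invariance and null calibration", {
  d <- c(10, 10, 10)
  set.seed(54)
  A <- replicate(12, array(rnorm(1000), d), simplify = FALSE)
  B <- lapply(A, exp)                       # strictly monotone transform
  cm <- voxelwise_spearman(A, B)
  expect_true(all(abs(cm$rho - 1) < 1e-12))
  cmn <- voxelwise_spearman(A, lapply(A, function(x) -x))
  expect_true(all(abs(cmn$rho + 1) < 1e-12))
  expect_error(voxelwise_spearman(A[1:3], B[1:3]), "4 subjects")

  # null: fraction above the two-tailed critical value ~ alpha
  set.seed(55)
  n <- 38
  A2 <- replicate(n, array(rnorm(10000), c(100, 10, 10)), simplify = FALSE)
  B2 <- replicate(n, array(rnorm(10000), c(100, 10, 10)), simplify = FALSE)
  rho <- voxelwise_spearman(A2, B2)$rho
  crit <- spearman_critical_value(n, 0.05)
  frac <- mean(abs(rho) > crit)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
  # constant voxel masked
  A3 <- lapply(1:6, function(i) array(1, c(2, 2, 2)))
  B3 <- replicate(6, array(rnorm(8), c(2, 2, 2)), simplify = FALSE)
  expect_true(all(is.na(voxelwise_spearman(A3, B3)$rho)))
})

test_that("Spearman critical value: t-approximation and exact enumeration", {
  expect_lt(spearman_critical_value(38, 1 - 1e-9), 0.01)   # alpha -> 1 limit
  # exact oracle at n = 5: enumerate all 120 permutations independently
  perms <- perms_of(5)
  rhos <- round(apply(perms, 1, function(p) cor(1:5, p)), 12)
  cands <- sort(unique(abs(rhos)))
  crit5 <- cands[which(vapply(cands, function(t) mean(abs(rhos) >= t), 0)
                       <= 0.05)][1]
  expect_equal(spearman_critical_value(5, 0.05), crit5)
  expect_error(spearman_critical_value(10, 0), "alpha")
})

test_that("tissue histograms normalize and mix correctly", {
  rho <- array(runif(27, -1, 1), c(3, 3, 3))
  m1 <- array(FALSE, c(3, 3, 3)); m1[1, 1, 1] <- TRUE
  h1 <- tissue_histograms(rho, list(a = m1))
  expect_equal(sum(h1$count), 1)                    # single unit spike
  expect_equal(sum(h1$density * diff(seq(-1, 1, length.out = 41))[1]), 1)

  m2 <- !m1
  h <- tissue_histograms(rho, list(a = m1, b = m2))
  for (cl in c("a", "b")) {
    dens <- h$density[h$tissue == cl]
    expect_equal(sum(dens) * 0.05, 1, tolerance = 1e-12)
  }
  # pooled histogram = voxel-count-weighted mixture of class histograms
  hp <- tissue_histograms(rho, list(all = m1 | m2))
  expect_equal(hp$count, h$count[h$tissue == "a"] + h$count[h$tissue == "b"])
  expect_equal(hp$density,
               (1 * h$density[h$tissue == "a"] +
                  26 * h$density[h$tissue == "b"]) / 27, tolerance = 1e-12)
  expect_error(tissue_histograms(rho, list(a = m1, b = m1)), "disjoint")
  expect_warning(tissue_histograms(rho, list(e = array(FALSE, c(3, 3, 3)))),
                 "empty")
})

test_that("ROI summaries exclude lesional and perilesional tissue", {
  d <- c(8, 8, 8)
  roi <- array(FALSE, d); roi[1:4, , ] <- TRUE
  map <- array(1, d)
  # control: full ROI mean
  rs <- roi_summary(list(x = map), list(roi = roi), subject_id = "c",
                    group = "control")
  expect_equal(rs$mean[rs$region == "roi"], 1)
  expect_equal(rs$n_voxels[rs$region == "roi"], sum(roi))

  # patient: lesion covering half the ROI at value 5 -> NAWM mean exactly 1
  les <- array(FALSE, d); les[1:2, , ] <- TRUE
  map2 <- map; map2[les] <- 5
  rs2 <- roi_summary(list(x = map2), list(roi = roi), lesion_mask = les,
                     subject_id = "p", group = "patient")
  expect_equal(rs2$mean[rs2$region == "roi"], 1)
  expect_equal(rs2$mean[rs2$region == "lesion"], 5)

  # partition identity: count-weighted class means = whole-mask mean
  set.seed(56)
  mp <- array(rnorm(prod(d)), d)
  m_a <- array(FALSE, d); m_a[1:3, , ] <- TRUE
  m_b <- array(FALSE, d); m_b[4:8, , ] <- TRUE
  ra <- roi_summary(list(x = mp), list(a = m_a, b = m_b, all = m_a | m_b))
  wa <- ra$n_voxels[ra$region == "a"]; wb <- ra$n_voxels[ra$region == "b"]
  expect_equal((wa * ra$mean[ra$region == "a"] +
                  wb * ra$mean[ra$region == "b"]) / (wa + wb),
               ra$mean[ra$region == "all"], tolerance = 1e-12)

  # ROI emptied by exclusion: flagged absent
  rs3 <- roi_summary(list(x = map), list(roi = roi), lesion_mask = roi,
                     subject_id = "p2", group = "patient")
  expect_true(rs3$absent[rs3$region == "roi"])
})

test_that("group difference test: identity, null calibration and power", {
  mk_tab <- function(xc, xp, region = "wm", modality = "m") {
    rbind(data.frame(subject_id = paste0("c", seq_along(xc)), group = "control",
                     region = region, modality = modality, mean = xc,
                     n_voxels = 10, absent = FALSE),
          data.frame(subject_id = paste0("p", seq_along(xp)), group = "patient",
                     region = region, modality = modality, mean = xp,
                     n_voxels = 10, absent = FALSE))
  }
  set.seed(57)
  g <- group_difference(mk_tab(rnorm(10), rnorm(10)))
  expect_equal(g$p_adjusted, g$p_raw)     # single region: no correction
  expect_equal(group_difference(mk_tab(rep(1, 5), rep(1, 5)))$p_raw, 1)

  # type-I error calibration at alpha = 0.05 (Mann-Whitney, n = 10/10)
  set.seed(58)
  rej <- mean(replicate(10000, {
    suppressWarnings(wilcox.test(rnorm(10), rnorm(10),
                                 exact = FALSE)$p.value) < 0.05
  }))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)

  # power: 3-SD shift across 8 regions, all Holm-significant
  set.seed(59)
  tabs <- do.call(rbind, lapply(1:8, function(r)
    mk_tab(rnorm(20), rnorm(20) + 3, region = paste0("r", r))))
  gp <- group_difference(tabs)
  expect_true(all(gp$p_adjusted < 0.05))
  expect_true(all(gp$p_adjusted >= gp$p_raw))
})
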