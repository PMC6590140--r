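mk_masks <- function(nles = 30, ntot = 1000) {
  d <- c(10, 10, 10)
  les <- array(FALSE, d); les[seq_len(nles)] <- TRUE
  amask <- array(TRUE, d)
  list(les = les, amask = amask, d = d)
}

test_that("ROC curve: separation, endpoints, monotonicity", {
  m <- mk_masks()
  z <- array(0, m$d)
  z[m$les] <- -10                       # every lesion voxel beyond every other
  z[!m$les] <- rnorm(sum(!m$les))
  r <- roc_curve(z, m$les, m$amask, "low_abnormal")
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))

  # high_abnormal direction mirrors
  r2 <- roc_curve(-z, m$les, m$amask, "high_abnormal")
  expect_equal(r2$auc, 1)
  expect_error(roc_curve(z, array(FALSE, m$d), m$amask), "empty lesion")
  bad <- m$les; badmask <- m$amask; badmask[1] <- FALSE
  expect_error(roc_curve(z, m$les, badmask), "subset")
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(61)
  for (rep in 1:100) {
    m <- mk_masks(nles = sample(5:50, 1))
    z <- array(rnorm(1000), m$d)
    if (rep %% 3 == 0) z <- array(sample(seq(-3, 3, by = 0.5), 1000, TRUE), m$d)
    # exact threshold grid (the 512-cutoff quantile fallback is approximate)
    r <- roc_curve(z, m$les, m$amask, "low_abnormal", max_thresholds = 1e6)
    x <- -z[m$les]; y <- -z[!m$les]    # score convention: larger = abnormal
    U <- sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), 0))
    expect_equal(r$auc, U / (length(x) * length(y)), tolerance = 1e-12)
  }
})

test_that("null Z-maps give chance-level AUC", {
  set.seed(62)
  aucs <- replicate(1000, {
    m <- mk_masks(nles = 20)
    z <- array(rnorm(1000), m$d)
    roc_curve(z, m$les, m$amask, "low_abnormal")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("vertical ROC averaging", {
  m <- mk_masks()
  z <- array(rnorm(1000), m$d); z[m$les] <- z[m$les] - 3
  r <- roc_curve(z, m$les, m$amask, "low_abnormal")
  # at jump-free FPR values the averaged single curve is the curve itself
  # (verticals take the upper value, the right-continuous convention)
  grid <- unique(r$fpr)
  expected <- as.numeric(tapply(r$tpr, r$fpr, max))
  avg1 <- average_roc_at_fixed_fpr(list(r), fpr_grid = grid)
  expect_equal(avg1$tpr, expected, tolerance = 1e-12)

  perfect <- list(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  nullr <- list(fpr = c(0, 1), tpr = c(0, 1))
  avg <- average_roc_at_fixed_fpr(list(perfect, nullr), fpr_grid = 0.5)
  expect_equal(avg$tpr, 0.75)
  set.seed(63)
  rs <- replicate(4, {
    m2 <- mk_masks(20)
    z2 <- array(rnorm(1000), m2$d); z2[m2$les] <- z2[m2$les] - 1
    roc_curve(z2, m2$les, m2$amask, "low_abnormal")
  }, simplify = FALSE)
  av <- average_roc_at_fixed_fpr(rs)
  expect_true(all(diff(av$tpr) >= -1e-12))
})

test_that("Friedman test matches hand computation and stats::friedman.test", {
  X <- matrix(rep(c(1, 2, 3), each = 3), 3, 3)  # all subjects rank 1<2<3
  fr <- friedman_test(X)
  expect_equal(fr$chi2, 6)
  expect_equal(fr$df, 2)

  same <- matrix(5, 4, 3)
  fr0 <- friedman_test(same)
  expect_equal(fr0$chi2, 0)
  expect_equal(fr0$p, 1)

  set.seed(64)
  for (rep in 1:20) {
    Y <- matrix(rnorm(4 * 4), 4, 4)
    ours <- friedman_test(Y)
    ref <- stats::friedman.test(Y)
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(1, 4, 2)), "3 methods")
})

test_that("Friedman chi2 matches exhaustive enumeration at n=4, k=3", {
  # exact null distribution by enumerating all (3!)^4 per-subject rankings
  perms <- perms_of(3)
  grids <- expand.grid(1:6, 1:6, 1:6, 1:6)
  chi_all <- apply(grids, 1, function(g) {
    R <- rbind(perms[g[1], ], perms[g[2], ], perms[g[3], ], perms[g[4], ])
    friedman_test(R)$chi2
  })
  # observed matrix with untied within-subject ranks
  X <- rbind(c(0.1, 0.5, 0.9), c(0.3, 0.2, 0.8), c(0.1, 0.9, 0.5),
             c(0.2, 0.6, 0.7))
  fr <- friedman_test(X)
  p_exact <- mean(chi_all >= fr$chi2 - 1e-12)
  # the chi-square approximation should be close to the exact tail here
  expect_lt(abs(fr$p - p_exact), 0.08)
  # and the statistic itself must be reproduced by the rank-sum formula
  R <- t(apply(X, 1, rank))
  expect_equal(fr$chi2,
               12 * 4 / (3 * 4) * sum((colMeans(R) - 2)^2), tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank: exact values and enumeration oracle", {
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))
  expect_equal(w$W, 21)
  expect_equal(w$p, 2 / 64)
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p, 1)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(wilcoxon_signed_rank(x, y)$p, wilcoxon_signed_rank(y, x)$p)

  # exhaustive sign-pattern enumeration for n <= 10 (no ties)
  set.seed(65)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    d <- rnorm(n)
    while (any(duplicated(abs(d)))) d <- rnorm(n)
    w <- wilcoxon_signed_rank(d, rep(0, n))
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wdist <- signs %*% r
    p_exact <- min(1, 2 * min(mean(Wdist <= w$W), mean(Wdist >= w$W)))
    expect_equal(w$p, p_exact, tolerance = 1e-12)
  }
})

test_that("Holm correction: example, properties, brute-force oracle", {
  expect_equal(holm_correct(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.2), 0.2)
  set.seed(66)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_correct(p)
    expect_equal(adj, holm_brute(p), tolerance = 1e-14)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("compare_methods: summaries, ties, effect-size ranking", {
  set.seed(67)
  X <- matrix(runif(24 * 4, 0.5, 1), 24, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  cmp <- compare_methods(X)
  expect_equal(cmp$summary$mean_auc, unname(colMeans(X)))
  expect_equal(cmp$summary$sd_auc, unname(apply(X, 2, sd)))
  expect_equal(cmp$summary$min_auc, unname(apply(X, 2, min)))
  expect_equal(cmp$summary$max_auc, unname(apply(X, 2, max)))
  expect_equal(nrow(cmp$pairwise), 6)
  expect_true(all(cmp$pairwise$p_holm >= cmp$pairwise$p_raw))

  # identical columns: omnibus p = 1, no significant post hocs
  Xt <- matrix(rep(runif(24), 4), 24, 4)
  cmpt <- compare_methods(Xt)
  expect_equal(cmpt$friedman$p, 1)
  expect_true(all(cmpt$pairwise$p_holm == 1))

  # one method with doubled effect size wins with a Holm-significant test
  set.seed(68)
  base <- matrix(qnorm(runif(24 * 4, 0.5, 0.99)), 24, 4)
  base[, 2] <- base[, 2] + 1.5      # doubled lesion contrast, in z-units
  Xa <- pnorm(base / sqrt(2))
  colnames(Xa) <- c("m1", "m2", "m3", "m4")
  cmpa <- compare_methods(Xa)
  expect_equal(cmpa$summary$method[which.max(cmpa$summary$mean_auc)], "m2")
  win <- cmpa$pairwise[cmpa$pairwise$method_a == "m2" |
                         cmpa$pairwise$method_b == "m2", ]
  expect_true(any(win$p_holm < 0.05))

  # incomplete subjects are dropped
  Xm <- X; Xm[3, 2] <- NA
  expect_message(cmpm <- compare_methods(Xm), "excluded")
  expect_equal(cmpm$n_subjects, 23)
})
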