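# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use different algorithms / code paths from the
# package implementations they check.

tiny_geometry <- function() {
  phantom_geometry(grid_shape = c(16, 16, 16), voxel_size = c(10, 10, 10),
                   brain_radii = c(60, 50, 45), wm_radii = c(45, 38, 33),
                   ventricle_radii = c(8, 6, 6), ventricle_offset = 10,
                   subcortical_radii = c(10, 8, 8), subcortical_offset = 24)
}

tiny_config <- function(n_controls = 4, n_patients = 3, seed = 42, ...) {
  cohort_config(n_controls = n_controls, n_patients = n_patients, seed = seed,
                geometry = tiny_geometry(),
                lesions = lesion_model(radius_meanlog = log(5),
                                       radius_sdlog = 0.3), ...)
}

fast_src <- function() {
  src_config(n_samples = 60, n_retain = 10, n_iterations = 2,
             polish_iter = 6)
}

# Isochromat Bloch-simulation CPMG oracle: explicit spin ensemble with a
# uniform grid of per-half-period dephasing angles (exact ideal-crusher
# average for dephasing orders below nspin), 90x excitation, refocusing
# about y, T1 decay of Mz without regrowth.
iso_cpmg_oracle <- function(t2, t1, te, etl, beta_deg, nspin = 4096) {
  phis <- 2 * pi * (seq_len(nspin) - 0.5) / nspin
  e2 <- exp(-te / 2 / t2); e1 <- exp(-te / 2 / t1)
  b <- beta_deg * pi / 180
  M <- rbind(rep(0, nspin), rep(-1, nspin), rep(0, nspin))
  rot_z <- function(M, phi) rbind(cos(phi) * M[1, ] - sin(phi) * M[2, ],
                                  sin(phi) * M[1, ] + cos(phi) * M[2, ], M[3, ])
  rot_y <- function(M, b) rbind(cos(b) * M[1, ] + sin(b) * M[3, ], M[2, ],
                                -sin(b) * M[1, ] + cos(b) * M[3, ])
  relax <- function(M) M * c(e2, e2, e1)
  echoes <- numeric(etl)
  for (i in seq_len(etl)) {
    M <- rot_z(relax(M), phis)
    M <- rot_y(M, b)
    M <- rot_z(relax(M), phis)
    echoes[i] <- sqrt(mean(M[1, ])^2 + mean(M[2, ])^2)
  }
  echoes
}

# single-pool bSSFP oracle: iterate the rotation-relaxation recursion to its
# fixed point, then read out at TE = TR/2
bssfp_iter_oracle <- function(m0, t1, t2, alpha, tr, df0 = 0,
                              phase_cycle = 180, b1 = 1, n_iter = 2e5) {
  a <- b1 * alpha * pi / 180
  th <- 2 * pi * df0 * tr / 1000 + phase_cycle * pi / 180
  e1 <- exp(-tr / t1); e2 <- exp(-tr / t2)
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
               byrow = TRUE)
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  D <- diag(c(e2, e2, e1))
  cvec <- c(0, 0, (1 - e1) * m0)
  Tm <- D %*% Rz %*% Rx
  s <- c(0, 0, m0)
  for (i in seq_len(n_iter)) s <- Tm %*% s + cvec
  sp <- Rx %*% s
  exp(-tr / 2 / t2) * sqrt(sp[1]^2 + sp[2]^2)
}

# two-pool bSSFP oracle: iterate the full 6x6 rotation-evolution recursion;
# matrix exponentials from eigen decompositions (R linear algebra)
two_pool_bssfp_oracle <- function(pv, tr, alpha, cycle, n_iter = 2e5) {
  kmf <- pv[["k_mf"]] / 1000; fm <- pv[["f_m"]]
  kfm <- if (fm < 1) kmf * fm / (1 - fm) else 0
  AL <- matrix(c(-1 / pv[["t1_m"]] - kmf, kfm,
                 kmf, -1 / pv[["t1_f"]] - kfm), 2, 2, byrow = TRUE)
  AT <- matrix(c(-1 / pv[["t2_m"]] - kmf, kfm,
                 kmf, -1 / pv[["t2_f"]] - kfm), 2, 2, byrow = TRUE)
  CL <- c(pv[["m0"]] * fm / pv[["t1_m"]], pv[["m0"]] * (1 - fm) / pv[["t1_f"]])
  expm_r <- function(A, t) {
    e <- eigen(A)
    Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  }
  EL <- expm_r(AL, tr); ET <- expm_r(AT, tr)
  bL <- solve(AL, (EL - diag(2)) %*% CL)
  th <- 2 * pi * pv[["delta_f0"]] * tr / 1000 + cycle * pi / 180
  Rth <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  a <- pv[["b1_scale"]] * alpha * pi / 180
  D <- matrix(0, 6, 6)
  D[1:4, 1:4] <- kronecker(ET, Rth)
  D[5:6, 5:6] <- EL
  R <- diag(6)
  R[2, 2] <- cos(a); R[2, 5] <- -sin(a); R[5, 2] <- sin(a); R[5, 5] <- cos(a)
  R[4, 4] <- cos(a); R[4, 6] <- -sin(a); R[6, 4] <- sin(a); R[6, 6] <- cos(a)
  b <- c(0, 0, 0, 0, bL)
  s <- c(0, 0, 0, 0, fm * pv[["m0"]], (1 - fm) * pv[["m0"]])
  for (i in seq_len(n_iter)) s <- D %*% (R %*% s) + b
  sp <- R %*% s
  ETh <- expm_r(AT, tr / 2)
  m <- ETh %*% rbind(c(sp[1], sp[2]), c(sp[3], sp[4]))
  sqrt((m[1, 1] + m[2, 1])^2 + (m[1, 2] + m[2, 2])^2)
}

# brute-force Holm step-down: reject hypotheses one at a time at level
# alpha/(remaining); adjusted p = smallest alpha at which rejected
holm_brute <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  o <- order(p)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# all permutations of 1..n (iterative, independent of the package's recursion)
perms_of <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    new <- matrix(0L, nrow(out) * k, k)
    r <- 0L
    for (i in seq_len(nrow(out))) for (pos in seq_len(k)) {
      new[r + 1, ] <- append(out[i, ], k, after = pos - 1)
      r <- r + 1L
    }
    out <- new
  }
  out
}
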