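# Estimators: spherical means, DTI, NODDI, SANDI, peak extraction.

test_that("spherical means normalize by b0 and close the forward loop", {
  proto <- fx_protocol()
  st <- shell_table(proto)
  # constant signal 0.8 with b0 = 1
  sig <- matrix(0.8, 1, nrow(proto))
  sig[1, proto$b == 0] <- 1
  sm <- spherical_mean(sig, st)
  expect_equal(unname(sm$sphmean[1, sm$b > 0]), rep(0.8, 5))
  expect_equal(sm$sphmean[1, sm$b == 0], 1)
  # closure: an orientation-independent noiseless signal reproduces the
  # forward spherical-mean curve exactly ...
  want <- sandi_sphmean(sandi_params(0.4, 0.4, 7, 1.7, 1.2),
                        shell_table(proto)$b)
  s_iso <- matrix(want[protocol_shell_index(proto)], 1)
  sm2 <- spherical_mean(s_iso, st)
  expect_equal(unname(sm2$sphmean[1, ]), want, tolerance = 1e-12)
  # ... and the 30/60-direction average of an oriented stick mixture
  # matches it to direction-set quadrature accuracy
  pars <- tibble::tibble(f_ec = 0.4, f_in = 0.4, r_s = 7, D_in = 1.7,
                         D_ec = 1.2, mux = 1, muy = 0, muz = 0)
  s_dir <- simulate_signals(pars, proto, model = "sandi",
                            noise_model = "none")
  sm3 <- spherical_mean(s_dir, st)
  expect_equal(unname(sm3$sphmean[1, ]), want, tolerance = 2e-3)
  # zero b0 flags the location
  sig0 <- matrix(0, 1, nrow(proto))
  expect_false(spherical_mean(sig0, st)$valid)
  # noise averaging: shell-mean SE scales ~ sd/sqrt(60)
  reps <- t(replicate(400, {
    x <- add_noise(rep(0.5, 60), 20, "gaussian")
    mean(x)
  }))
  expect_equal(sd(reps), (1 / 20) / sqrt(60), tolerance = 0.15)
})

test_that("DTI weighted LLS recovers noiseless tensors exactly", {
  proto <- fx_protocol()
  set.seed(41)
  n <- 30
  sigs <- matrix(NA_real_, n, nrow(proto))
  truth <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) {
    A <- matrix(rnorm(9, sd = 0.4), 3)
    D <- crossprod(A) + diag(0.2, 3)
    truth[i, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    sigs[i, ] <- tensor_signal(tensor_params(D), proto)
  }
  f <- fit_dti(sigs, proto)
  est <- cbind(f$dxx, f$dyy, f$dzz, f$dxy, f$dxz, f$dyz)
  expect_lt(max(abs(est - truth)) / max(abs(truth)), 1e-8)
  # only b <= max_b volumes enter the design
  expect_equal(attr(f, "n_volumes"), sum(proto$b <= 1.2))
})

test_that("DTI on noisy isotropic voxels gives low FA, unbiased MD", {
  proto <- fx_protocol()
  n <- 500
  pars <- tibble::tibble(dxx = 1, dyy = 1, dzz = 1, dxy = 0, dxz = 0,
                         dyz = 0)[rep(1, n), ]
  s <- simulate_signals(pars, proto, model = "dti", snr = 50,
                        noise_model = "rician", seed = 77)
  f <- fit_dti(s, proto)
  expect_lt(median(f$fa), 0.1)
  expect_lt(abs(median(f$md) - 1) / 1, 0.05)
})

test_that("NODDI inverse crime: noiseless parameters recovered", {
  proto <- fx_protocol()
  cases <- list(
    list(f_iso = 0.1, f_in = 0.6, kappa = 4, mu = c(0.3, 0.5, 0.8)),
    list(f_iso = 0.05, f_in = 0.35, kappa = 1.5, mu = c(1, 0, 0)),
    list(f_iso = 0.25, f_in = 0.75, kappa = 16, mu = c(0, 1, 1))
  )
  for (cs in cases) {
    p <- noddi_params(cs$f_iso, cs$f_in, cs$kappa, mu = cs$mu)
    s <- noddi_signal(p, proto)
    f <- fit_noddi(matrix(s, 1), proto)
    expect_lt(abs(f$f_in - cs$f_in), 1e-3)
    expect_lt(abs(f$odi - odi_from_kappa(cs$kappa)), 1e-3)
  }
})

test_that("NODDI estimates are invariant to volume order and detect CSF", {
  proto <- fx_protocol()
  p <- noddi_params(0.1, 0.5, 3, mu = c(0.2, -0.4, 0.9))
  s <- noddi_signal(p, proto)
  f1 <- fit_noddi(matrix(s, 1), proto)
  set.seed(5)
  perm <- sample(nrow(proto))
  proto_p <- proto[perm, ]
  class(proto_p) <- class(proto)
  attr(proto_p, "delta") <- attr(proto, "delta")
  attr(proto_p, "Delta") <- attr(proto, "Delta")
  f2 <- fit_noddi(matrix(s[perm], 1), proto_p)
  expect_equal(f1$f_in, f2$f_in, tolerance = 1e-6)
  expect_equal(f1$odi, f2$odi, tolerance = 1e-6)
  # pure-CSF ground truth recovered as (almost) all isotropic fraction
  s_csf <- add_noise(noddi_signal(noddi_params(1, 0.5, 1), proto), 50,
                     "rician", seed = 6)
  f_csf <- fit_noddi(matrix(s_csf, 1), proto)
  expect_gte(f_csf$f_iso, 0.95)
})

test_that("SANDI inverse crime and derived-map identity", {
  b <- c(0, 0.5, 1.2, 2.4, 4, 6)
  truth <- c(f_ec = 0.3, f_in = 0.5, r_s = 8, D_in = 1.7, D_ec = 1.0)
  y <- sandi_sphmean(sandi_params(0.3, 0.5, 8, 1.7, 1.0), b)
  # fully-free contract: all five parameters within 1%
  f5 <- fit_sandi(matrix(y, 1), b, free_d_in = TRUE)
  expect_lt(max(abs(unlist(f5[1, 1:5]) - truth) / truth), 0.01)
  # default (fixed D_in) estimator: remaining four within 1%
  f4 <- fit_sandi(matrix(y, 1), b)
  expect_lt(max(abs(unlist(f4[1, c(1, 2, 3, 5)]) - truth[c(1, 2, 3, 5)]) /
                  truth[c(1, 2, 3, 5)]), 0.01)
  expect_equal(f4$D_in, 1.7)
  # derived fractions sum to one exactly
  expect_equal(f4$fneurite + f4$fsoma + f4$fextracellular, 1)
  expect_error(fit_sandi(matrix(y[1:4], 1), b[1:4]), ">= 4 nonzero")
})

test_that("SANDI detects a pure-extracellular voxel at SNR 50", {
  proto <- fx_protocol()
  pars <- tibble::tibble(f_ec = 1, f_in = 0.5, r_s = 8, D_in = 1.7,
                         D_ec = 1.0)[rep(1, 20), ]
  # zero-mean noise: both spurious tissue fractions vanish
  sg <- simulate_signals(pars, proto, model = "sandi", snr = 50,
                         noise_model = "gaussian", seed = 9)
  fg <- fit_sandi(spherical_mean(sg, shell_table(proto))$sphmean,
                  shell_table(proto)$b, seed = 2)
  expect_lte(median(fg$fneurite), 0.05)
  expect_lte(median(fg$fsoma), 0.05)
  # magnitude noise: the uncorrected Rician floor at high b (~0.025 of
  # S0 at SNR 50) is absorbed as a small spurious stick fraction; the
  # fit stays within that documented bias allowance
  sr <- simulate_signals(pars, proto, model = "sandi", snr = 50,
                         noise_model = "rician", seed = 9)
  fr <- fit_sandi(spherical_mean(sr, shell_table(proto))$sphmean,
                  shell_table(proto)$b, seed = 2)
  expect_lte(median(fr$fneurite), 0.07)
  expect_lte(median(fr$fsoma), 0.05)
})

test_that("principal peaks come from eigenvectors or SH maxima", {
  proto <- fx_protocol()
  s <- tensor_signal(tensor_params(diag(c(1.7, 0.3, 0.3))), proto)
  f <- fit_dti(matrix(s, 1), proto)
  pk <- principal_peak(f)
  expect_equal(abs(pk$px), 1, tolerance = 1e-6)
  # isotropic voxel is flagged undefined
  s_iso <- tensor_signal(tensor_params(diag(1, 3)), proto)
  pk_iso <- principal_peak(fit_dti(matrix(s_iso, 1), proto))
  expect_true(pk_iso$flagged)
  expect_true(is.na(pk_iso$px))
  # SH of a delta-like fODF: peak within 1 degree of its orientation
  set.seed(8)
  axis <- c(0.1, -0.2, 0.97); axis <- axis / sqrt(sum(axis^2))
  grid <- matrix(rnorm(3 * 600), ncol = 3)
  grid <- grid / sqrt(rowSums(grid^2))
  odf <- exp(20 * (as.numeric(grid %*% axis)^2 - 1)) # sharp antipodal lobe
  B <- sh_eval(grid, 8)
  coefs <- solve(crossprod(B) + diag(1e-8, ncol(B)), crossprod(B, odf))
  pk_sh <- principal_peak(matrix(coefs, 1))
  ang <- acos(min(abs(sum(c(pk_sh$px, pk_sh$py, pk_sh$pz) * axis)), 1)) *
    180 / pi
  expect_lt(ang, 1)
})
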