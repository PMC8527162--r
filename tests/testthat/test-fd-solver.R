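# Finite-difference solver validation.  Comparisons use the pairs with
# separations <= 7 cm: the longest pairs are removed by the standard
# preprocessing in every pipeline, and the grid-dispersion residual of the
# 2.5 mm stencil concentrates there.

test_that("uniform phantoms reproduce the homogeneous closed form within 5%", {
  probe <- fx_probe()
  rho <- separations(probe)
  sel <- rho <= 7
  uni <- voxel_phantom(array(1L, c(56, 56, 20)), 0.25,
                       list(fat = optical_props(0.02, 5)), chest_depth = 2)
  m <- fluence_heterogeneous(uni, probe)
  phi <- fluence_semi_infinite(optical_props(0.02, 5), rho)
  relerr <- abs(exp(m$log_amplitude - log(Mod(phi))) - 1)
  expect_lt(max(relerr[sel]), 0.05)
})

test_that("identical layers match the closed form across random draws", {
  probe <- fx_probe()
  rho <- separations(probe)
  sel <- rho <= 7
  set.seed(314)
  for (i in 1:5) {
    pr <- optical_props(runif(1, 0.02, 0.1), runif(1, 5, 8))
    med <- suppressWarnings(two_layer_medium(pr, pr,
      chestwall_geometry(runif(1, 1.5, 3), 0)))
    m <- fluence_two_layer(med, probe, method = "fd", spacing = 0.25)
    phi <- fluence_semi_infinite(pr, rho)
    relerr <- abs(exp(m$log_amplitude - log(Mod(phi))) - 1)
    pherr <- abs(m$phase - dotprops:::unwrap_by_rho(rho, -Arg(phi)))
    expect_lt(max(relerr[sel]), 0.05)
    expect_lt(max(pherr[sel]), 0.05)
  }
})

test_that("a flat two-label phantom agrees with the analytic two-layer model", {
  probe <- fx_probe()
  rho <- separations(probe)
  sel <- rho <= 7
  med <- two_layer_medium(optical_props(0.032, 6.8), optical_props(0.12, 7),
                          chestwall_geometry(2, 0))
  m_fd <- fluence_two_layer(med, probe, method = "fd", spacing = 0.25)
  m_an <- fluence_two_layer(med, probe)
  relerr <- abs(exp(m_fd$log_amplitude - m_an$log_amplitude) - 1)
  expect_lt(max(relerr[sel]), 0.05)
})

test_that("tilted-interface solves stay consistent with the analytic model", {
  # the analytic route treats tilt through the local midpoint depth; the FD
  # route resolves the tilted plane on the grid.  They are different
  # approximations and must stay close on the pairs the pipeline uses.
  probe <- fx_probe()
  sel <- separations(probe) <= 7
  med <- two_layer_medium(optical_props(0.05, 7), optical_props(0.15, 7),
                          chestwall_geometry(2, 10))
  m_fd <- fluence_two_layer(med, probe, method = "fd", spacing = 0.25)
  m_an <- fluence_two_layer(med, probe)
  expect_lt(max(abs(m_fd$log_amplitude - m_an$log_amplitude)[sel]), 0.12)
  expect_lt(max(abs(m_fd$phase - m_an$phase)[sel]), 0.06)
})

test_that("halving the grid step changes log-amplitude by less than 1%", {
  src <- matrix(c(0, 1.5), 1)
  det <- cbind(c(-2.5, -1, 1, 2.5), rep(-1.5, 4))
  la <- lapply(c(0.25, 0.125), function(h) {
    nx <- round(12 / h); ny <- round(8 / h); nz <- round(4 / h)
    phi <- fd_forward(array(0.05, c(nx, ny, nz)), array(7, c(nx, ny, nz)),
                      h, c(-6, -4), src, det)
    log(Mod(phi[1, ]))
  })
  expect_lt(max(abs((la[[2]] - la[[1]]) / la[[1]])), 0.01)
})

test_that("the discrete system is reciprocal under source-detector swap", {
  # two-label medium on a small grid; source and detector exchanged
  h <- 0.25
  nx <- 48; ny <- 28; nz <- 20
  mua <- array(0.04, c(nx, ny, nz)); musp <- array(8, c(nx, ny, nz))
  chest <- seq_len(nz) * h > 2
  mua[, , chest] <- 0.15; musp[, , chest] <- 6
  a <- c(-1.7, 1.5); b <- c(2.3, -1.5)
  phi_ab <- fd_forward(mua, musp, h, c(-6, -3.5), matrix(a, 1),
                       matrix(b, 1))
  phi_ba <- fd_forward(mua, musp, h, c(-6, -3.5), matrix(b, 1),
                       matrix(a, 1))
  expect_equal(log(Mod(phi_ba[1, 1])), log(Mod(phi_ab[1, 1])),
               tolerance = 1e-3)
  expect_equal(Arg(phi_ba[1, 1]), Arg(phi_ab[1, 1]), tolerance = 1e-3)
})

test_that("an embedded 1-cm lesion perturbs log-amplitude by under 10%", {
  probe <- fx_probe()
  ph0 <- compress_and_downsample(generate_digital_phantom(0.6, 2, seed = 3))
  ph1 <- compress_and_downsample(generate_digital_phantom(0.6, 2, seed = 3,
    lesion = list(center = c(0, 0, 1.5), radius = 0.5, mua = 0.2, musp = 7)))
  m0 <- fluence_heterogeneous(ph0, probe)
  m1 <- fluence_heterogeneous(ph1, probe)
  expect_lt(max(abs((m1$log_amplitude - m0$log_amplitude) /
                      m0$log_amplitude)), 0.10)
})

test_that("the solver rejects invalid inputs", {
  expect_error(fd_forward(array(-0.1, c(4, 4, 4)), array(7, c(4, 4, 4)),
                          0.25, c(0, 0), matrix(0, 1, 2), matrix(1, 1, 2)),
               "positive")
  expect_error(fd_forward(array(0.1, c(200, 200, 40)),
                          array(7, c(200, 200, 40)),
                          0.25, c(0, 0), matrix(0, 1, 2), matrix(1, 1, 2)),
               "too large")
  # phantom must cover the probe footprint with margin
  small <- voxel_phantom(array(1L, c(20, 20, 10)), 0.25,
                         list(fat = optical_props(0.02, 5)), chest_depth = 2)
  expect_error(fluence_heterogeneous(small, fx_probe()), "margin")
})
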