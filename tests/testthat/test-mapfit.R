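test_that("normalisation divides by the per-sequence b = 0 mean", {
  dims <- c(2, 2, 1)
  idx <- the_index
  vol <- array(1, c(dims, nrow(idx)))
  ## constant voxel: everything normalises to 1
  st <- normalize_signals(dwi_stack(vol * 3.7, idx))
  expect_true(all(st$volume == 1))
  ## scale invariance: scaling one voxel leaves its normalised signals alone
  p <- microstructure_params(15, 0.4, 2)
  tab <- forward_signal_table(p, the_protocol)
  vol1 <- array(rep(tab$signal, each = prod(dims)), c(dims, nrow(idx)))
  vol2 <- vol1
  vol2[1, 1, 1, ] <- vol2[1, 1, 1, ] * 7.3
  n1 <- normalize_signals(dwi_stack(vol1, idx))
  n2 <- normalize_signals(dwi_stack(vol2, idx))
  expect_equal(n1$volume, n2$volume)
  ## forward-model signals are already normalised: identity
  expect_equal(n1$volume[1, 1, 1, ], tab$signal)
})

test_that("noiseless fits recover the group-level test points to < 1%", {
  for (tp in list(c(17.26, 0.38, 1.88), c(24.13, 0.24, 2.24))) {
    tab <- signal_table(tp[1], tp[2], tp[3])
    names(tab)[names(tab) == "signal"] <- "signal"
    fit <- fit_voxel(tab, the_protocol)
    expect_true(fit$converged)
    expect_equal(fit$params$d, tp[1], tolerance = 0.01)
    expect_equal(fit$params$v_in, tp[2], tolerance = 0.01)
    expect_equal(fit$params$d_ex, tp[3], tolerance = 0.01)
    expect_equal(fit$cellularity, tp[2] / tp[1] * 100, tolerance = 0.01)
    expect_false(any(fit$at_bound))
  }
})

test_that("a purely Gaussian voxel drives v_in to the boundary", {
  idx <- the_index
  tab <- data.frame(label = idx$label, b = idx$b, nsa = idx$nsa,
                    signal = exp(-idx$b * 1e-3 * 1.0))
  fit <- fit_voxel(tab, the_protocol)
  expect_lt(fit$params$v_in, 1e-4)
  expect_equal(fit$params$d_ex, 1.0, tolerance = 1e-4)
  expect_true(fit$at_bound["v_in"])
})

test_that("fit_voxel enforces its preconditions and stays inside bounds", {
  tab <- signal_table(15, 0.4, 2)
  expect_error(fit_voxel(tab[tab$label == "pgse", ], the_protocol),
               "diffusion times")
  ## noisy fits never escape the box
  set.seed(7)
  for (i in 1:10) {
    noisy <- signal_table(24, 0.2, 2.4, snr = 15)
    fit <- fit_voxel(noisy, the_protocol)
    if (!fit$converged) next
    b <- fit_bounds()
    th <- c(fit$params$d, fit$params$v_in, fit$params$d_ex)
    expect_true(all(th >= b$lower - 1e-9 & th <= b$upper + 1e-9))
  }
})

test_that("fitting is deterministic", {
  set.seed(5)
  tab <- signal_table(17, 0.35, 1.9, snr = 25)
  f1 <- fit_voxel(tab, the_protocol)
  f2 <- fit_voxel(tab, the_protocol)
  expect_identical(f1, f2)
})

test_that("fit_adc recovers exact and noisy monoexponential decays", {
  b <- seqp$b_values
  ## exact: slope equals the generating ADC
  expect_equal(fit_adc(exp(-b * 1.3e-3), b, seqp$nsa), 1.30)
  ## Rician noise, SNR 50, 500 replicates: mean within 2%
  set.seed(21)
  sd <- 1 / (50 * sqrt(seqp$nsa))
  adcs <- replicate(500, {
    s <- sqrt((exp(-b * 1.0e-3) + rnorm(length(b), 0, sd))^2 +
                rnorm(length(b), 0, sd)^2)
    fit_adc(s, b, seqp$nsa)
  })
  expect_equal(mean(adcs), 1.0, tolerance = 0.02)
})

test_that("two-compartment ADC is higher at 50 Hz than at PGSE", {
  set.seed(3)
  for (i in 1:20) {
    p <- microstructure_params(runif(1, 6, 40), runif(1, 0.1, 0.9),
                               runif(1, 0.5, 3))
    adc50 <- fit_adc(impulsed_signal(p, seq50, seq50$b_values),
                     seq50$b_values, seq50$nsa)
    adc0 <- fit_adc(impulsed_signal(p, seqp, seqp$b_values),
                    seqp$b_values, seqp$nsa)
    expect_gte(adc50, adc0 - 1e-9)
  }
})

test_that("fit_volume agrees with fit_voxel and flags coverage", {
  idx <- the_index
  p <- microstructure_params(17.26, 0.38, 1.88)
  tab <- forward_signal_table(p, the_protocol)
  dims <- c(3, 3, 3)
  vol <- array(rep(tab$signal, each = prod(dims)), c(dims, nrow(idx)))
  mask <- array(FALSE, dims); mask[2, 2, 2] <- TRUE
  maps <- fit_volume(dwi_stack(vol, idx), mask, the_protocol)
  vfit <- fit_voxel(tab, the_protocol)
  expect_equal(maps$d[2, 2, 2], vfit$params$d)
  expect_equal(maps$v_in[2, 2, 2], vfit$params$v_in)
  expect_equal(maps$cellularity[2, 2, 2],
               maps$v_in[2, 2, 2] / maps$d[2, 2, 2] * 100)
  expect_true(maps$converged[2, 2, 2])
  expect_false(maps$at_bound[2, 2, 2])   # interior truth touches no bound
  expect_true(all(is.na(maps$d[!mask])))
  expect_false(any(maps$converged[!mask]))
  expect_equal(maps$adc_pgse[2, 2, 2],
               fit_adc(tab$signal[tab$label == "pgse"], seqp$b_values,
                       seqp$nsa))
  expect_error(fit_volume(dwi_stack(vol, idx), array(FALSE, dims),
                          the_protocol), "empty mask")
})
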