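test_that("sphere eigenbasis matches the Bessel-derivative roots", {
  eig <- sphere_eigen(R = 10, d_in = 1.56, K = 20)
  ## first root of d/dx j1(x) = 0
  expect_equal(eig$alpha_n[1], 2.0815759778, tolerance = 1e-9)
  expect_true(all(diff(eig$alpha_n) > 0))
  ## independent check: dense scan of j1' sign changes
  j1p <- function(x) (x^2 - 2) * sin(x) + 2 * x * cos(x)
  xs <- seq(0.5, 12, by = 1e-4)
  sc <- xs[which(diff(sign(j1p(xs))) != 0)][1:3]
  expect_equal(eig$alpha_n[1:3], sc, tolerance = 1e-3)
  ## variance sum rule: sum B_n -> R^2/5
  expect_equal(sum(eig$b_n), 10^2 / 5, tolerance = 1e-3)
  ## rates scale linearly in d_in at fixed R
  eig2 <- sphere_eigen(R = 10, d_in = 3.12, K = 20)
  expect_equal(eig2$lambda_n, 2 * eig$lambda_n)
})

test_that("closed-form attenuation matches the quadrature evaluation", {
  for (s in list(seq25, seq50, seqp)) {
    b <- max(s$b_values)
    g <- gradient_amplitude_from_b(s, b)
    wf <- build_waveform(s, g, dt = 0.002)
    for (d in c(8, 16, 30)) {
      lnS_closed <- b * 1e-3 * impulsed:::intra_adc(d, s, d_in = 1.56)
      lnS_quad <- gpa_logsignal_quadrature(wf, d / 2, 1.56)
      expect_equal(lnS_closed, lnS_quad, tolerance = 1e-6)
    }
  }
})

test_that("truncation order is converged at K = 20", {
  for (s in list(seq25, seq50, seqp)) {
    b <- max(s$b_values)
    p <- microstructure_params(12, 1, 1.0)
    s20 <- intracellular_signal(p, s, b, K = 20)
    s50 <- intracellular_signal(p, s, b, K = 50)
    expect_lt(abs(s20 - s50), 1e-5)
  }
})

test_that("two-compartment signal has the right limits and monotonicity", {
  p <- microstructure_params(15, 0.4, 2.0)
  for (s in list(seq25, seq50, seqp)) {
    expect_equal(impulsed_signal(p, s, 0), 1)
    ## v_in = 0 collapses to the extracellular exponential
    p0 <- microstructure_params(15, 0, 2.0)
    b <- s$b_values
    expect_equal(impulsed_signal(p0, s, b), exp(-b * 1e-3 * 2.0))
    ## v_in = 1 collapses to the intracellular compartment
    p1 <- microstructure_params(15, 1, 2.0)
    expect_equal(impulsed_signal(p1, s, b), intracellular_signal(p1, s, b))
  }
  ## monotone non-increasing in b for random parameter draws
  set.seed(42)
  bgrid <- seq(0, 1800, by = 100)
  for (i in 1:100) {
    pr <- microstructure_params(runif(1, 5, 50), runif(1), runif(1, 0, 3))
    for (s in list(seq25, seqp)) {
      sig <- impulsed_signal(pr, s, bgrid)
      expect_true(all(diff(sig) <= 1e-12))
    }
  }
})

test_that("implied ADC decreases with diffusion time (50 Hz >= 25 Hz >= PGSE)", {
  for (d in c(5, 12, 25, 50)) {
    p <- microstructure_params(d, 0.5, 2.0)
    adc <- vapply(list(seq50, seq25, seqp), function(s) {
      b <- max(s$b_values)
      -log(impulsed_signal(p, s, b)) / (b * 1e-3)
    }, numeric(1))
    expect_true(all(diff(adc) <= 1e-10))
  }
})

test_that("Monte Carlo engine reproduces free Gaussian diffusion", {
  g <- gradient_amplitude_from_b(seqp, 1000)
  wf <- build_waveform(seqp, g, dt = 0.01)
  p <- list(d = 15, d_in = 1.1)
  s_mc <- mc_sphere_signal(p, wf, n_walkers = 3e4, step_dt = 0.05,
                           seed = 3, reflect = FALSE)
  ## MC standard error ~ 0.005 at 3e4 walkers
  expect_equal(s_mc, exp(-1000 * 1e-3 * 1.1), tolerance = 0.02)
  ## zero gradient: signal is exactly 1
  wf0 <- build_waveform(seqp, 0, dt = 0.05)
  expect_identical(mc_sphere_signal(p, wf0, n_walkers = 500, seed = 1), 1)
  ## seeded determinism
  s1 <- mc_sphere_signal(p, wf, n_walkers = 2000, seed = 11)
  s2 <- mc_sphere_signal(p, wf, n_walkers = 2000, seed = 11)
  expect_identical(s1, s2)
})

test_that("GPA tracks the Monte Carlo oracle across cell sizes and sequences", {
  ## scaled-down grid; the strict 0.01/1e5-walker comparison runs in the
  ## acceptance suite
  set.seed(1)
  for (s in list(seq25, seq50, seqp)) {
    b <- max(s$b_values)
    g <- gradient_amplitude_from_b(s, b)
    wf <- build_waveform(s, g, dt = 0.01)
    for (d in c(10, 20)) {
      for (d_in in c(1.2, 2.0)) {
        p <- list(d = d, d_in = d_in)
        s_gpa <- intracellular_signal(
          microstructure_params(d, 1, 1, d_in = d_in), s, b)
        s_mc <- mc_sphere_signal(p, wf, n_walkers = 8000, step_dt = 0.1,
                                 seed = 100 + d)
        expect_lt(abs(s_gpa - s_mc), 0.03)
      }
    }
  }
})

test_that("smaller cells attenuate less at short diffusion time and high b", {
  ## direction fixed by the GPA/MC-validated forward model
  s_small <- intracellular_signal(microstructure_params(5, 1, 1), seq25, 1000)
  s_large <- intracellular_signal(microstructure_params(20, 1, 1), seq25, 1000)
  expect_gte(s_small, s_large)
})
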