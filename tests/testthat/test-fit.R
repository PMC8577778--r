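test_that("noiseless self-generated spectra are recovered within 1%", {
  truth <- aedes_debye("pair")
  sp <- synth_spectrum(truth$eps, params_sigma = truth$sigma)
  fit <- fit_debye(sp, n_relaxations = 2)

  rel <- function(a, b) abs(a / b - 1)
  expect_lt(rel(fit$params_eps$eps_inf, truth$eps$eps_inf), 0.01)
  expect_true(all(rel(fit$params_eps$delta_eps, truth$eps$delta_eps) < 0.01))
  expect_true(all(rel(fit$params_eps$tau, truth$eps$tau) < 0.01))
  expect_true(all(rel(fit$params_sigma$delta_eps,
                      truth$sigma$delta_eps) < 0.01))
  expect_true(all(rel(fit$params_sigma$tau, truth$sigma$tau) < 0.01))
  expect_lt(rel(fit$params_sigma$sigma_s, truth$sigma$sigma_s), 0.01)
  expect_gt(fit$r_squared_eps, 0.9999)
  expect_gt(fit$r_squared_sigma, 0.9999)
})

test_that("single-relaxation truth is recovered by the 1-relaxation fit", {
  truth <- debye_params(4.2, 14, 11e-12, sigma_s = 1.1)
  sp <- synth_spectrum(truth)
  fit <- fit_debye(sp, n_relaxations = 1)
  expect_lt(abs(fit$params_eps$tau / truth$tau - 1), 0.01)
  expect_lt(abs(fit$params_eps$delta_eps / truth$delta_eps - 1), 0.01)
  expect_lt(abs(fit$params_sigma$sigma_s / truth$sigma_s - 1), 0.01)
})

test_that("two relaxations beat one on noisy two-relaxation data", {
  truth <- aedes_debye("pair")
  sp <- synth_spectrum(truth$eps, params_sigma = truth$sigma,
                       noise = noise_model(0.01, 0.01, seed = 42))
  f2 <- fit_debye(sp, 2)
  f1 <- fit_debye(sp, 1)
  expect_gt(f2$r_squared_eps, f1$r_squared_eps)
  expect_gt(f2$r_squared_sigma, f1$r_squared_sigma)
})

test_that("degenerate and under-determined spectra fail loudly", {
  few <- permittivity_spectrum(5e9, 10, 1)
  expect_error(fit_debye(few, 1), "points")
  flat <- permittivity_spectrum(dak_tl_grid(),
                                rep(10, 265), rep(0, 265))
  expect_error(fit_debye(flat, 2), "degenerate")
})

test_that("joint mode returns a single consistent parameter set", {
  truth <- debye_params(4.5, c(5, 13), c(3.5e-12, 14.7e-12), sigma_s = 1.3)
  sp <- synth_spectrum(truth)   # one model generates both quantities
  fit <- fit_debye(sp, 2, mode = "joint")
  expect_identical(fit$params_eps, fit$params_sigma)
  expect_lt(abs(fit$params_eps$eps_inf / truth$eps_inf - 1), 0.01)
  expect_lt(abs(fit$params_eps$sigma_s / truth$sigma_s - 1), 0.01)
  expect_true(all(abs(fit$params_eps$tau / truth$tau - 1) < 0.01))
})
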