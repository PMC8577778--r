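test_that("Debye evaluation reproduces closed-form limits", {
  # static limit of a single relaxation: eps' -> eps_inf + delta_eps
  dp <- debye_params(eps_inf = 3, delta_eps = 10, tau = 10e-12)
  low <- evaluate_debye(dp, 1)          # 1 Hz ~ static
  expect_equal(low[["eps_real"]], 13, tolerance = 1e-9)
  expect_lt(low[["eps_imag"]], 1e-9)

  # two-relaxation mosquito fit at 240 GHz
  e240 <- evaluate_debye(aedes_debye("eps"), 240e9)
  expect_equal(e240[["eps_real"]], 4.744, tolerance = 1e-3)

  # infinite-frequency limit approaches eps_inf
  ehi <- evaluate_debye(aedes_debye("eps"), 1e15)
  expect_equal(ehi[["eps_real"]], 4.544, tolerance = 1e-4)

  expect_error(evaluate_debye(aedes_debye("eps"), -1), "frequency")
})

test_that("loss factor / conductivity conversion round-trips", {
  expect_identical(loss_to_conductivity(0, 5e9), 0)
  expect_equal(loss_to_conductivity(12, 60e9), 40.05, tolerance = 1e-3)
  x <- c(0.3, 1, 12)
  expect_equal(conductivity_to_loss(loss_to_conductivity(x, 7.3e9), 7.3e9),
               x, tolerance = 1e-15)
  expect_error(loss_to_conductivity(1, 0), "frequency")
})

test_that("in-medium wavelength matches hand arithmetic", {
  e240 <- evaluate_debye(aedes_debye("eps"), 240e9)[["eps_real"]]
  expect_equal(wavelength_in_medium(240e9, e240) * 1e6, 573.5,
               tolerance = 1e-4)
  expect_equal(wavelength_in_medium(1e9, 1), rf_constants$c0 / 1e9)
  expect_equal(wavelength_in_medium(60e9, 4), 2.498e-3, tolerance = 1e-3)
  expect_error(wavelength_in_medium(-1, 2), "frequency")
  expect_error(wavelength_in_medium(1e9, 0), "eps_real")
})

test_that("coaxial-probe grid has the documented structure", {
  g <- dak_tl_grid()
  expect_length(g, 265)
  expect_equal(g[1], 5e9)
  expect_equal(g[length(g)], 67e9)
  expect_false(is.unsorted(g, strictly = TRUE))
  expect_true(all(abs(diff(g) - 50e6) < 1 | abs(diff(g) - 250e6) < 1))
})

test_that("fitted-row curves show the measured trends", {
  f <- seq(2e9, 300e9, by = 1e8)
  er <- evaluate_debye(aedes_debye("eps"), f)$eps_real
  sg <- evaluate_debye(aedes_debye("sigma"), f)$sigma_s_per_m
  expect_true(all(diff(er) < 0))   # permittivity falls with frequency
  expect_true(all(diff(sg) > 0))   # conductivity rises with frequency

  # exactly one interior loss-factor maximum on the probe band
  fg <- seq(6e9, 67e9, by = 1e7)
  ei <- evaluate_debye(aedes_debye("sigma"), fg)$eps_imag
  d <- diff(sign(diff(ei)))
  expect_equal(sum(d == -2), 1)
  expect_equal(loss_peak_frequency(aedes_debye("sigma")) / 1e9, 9.4,
               tolerance = 1 / 9.4)
})

test_that("spectrum CSV round-trips and validates columns", {
  sp <- synth_spectrum(aedes_debye("eps"),
                       params_sigma = aedes_debye("sigma"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  sp2 <- read_spectrum_csv(path)
  expect_equal(sp2$frequency_hz, sp$frequency_hz)
  expect_equal(sp2$eps_real, sp$eps_real, tolerance = 1e-12)
  expect_equal(attr(sp2, "temperature_c"), 22)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("frequency_hz,eps_real\n1e9,5", bad)
  expect_error(read_spectrum_csv(bad), "sigma_s_per_m")
})

test_that("parameter validation rejects unphysical Debye sets", {
  expect_error(debye_params(0, 1, 1e-12), "eps_inf")
  expect_error(debye_params(2, -1, 1e-12), "delta_eps")
  expect_error(debye_params(2, 1, 0), "tau")
  expect_error(debye_params(2, 1, 1e-12, sigma_s = -1), "sigma_s")
  # relaxations stored sorted by descending tau
  dp <- debye_params(2, c(1, 2), c(1e-12, 5e-12))
  expect_equal(dp$tau, c(5e-12, 1e-12))
  expect_equal(dp$delta_eps, c(2, 1))
})
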