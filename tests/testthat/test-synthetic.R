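test_that("noiseless synthesis equals direct Debye evaluation", {
  tr <- aedes_debye("pair")
  sp <- synth_spectrum(tr$eps, params_sigma = tr$sigma)
  cv <- debye_curve(tr$eps, tr$sigma, dak_tl_grid())
  expect_identical(sp$eps_real, cv$eps_real)
  expect_identical(sp$sigma_s_per_m, cv$sigma_s_per_m)
  expect_equal(attr(sp, "provenance"), "synthetic")
})

test_that("noise is reproducible under a seed and scales as stated", {
  tr <- aedes_debye("pair")
  nm <- noise_model(0.04, 0.05, seed = 11)
  a <- synth_spectrum(tr$eps, params_sigma = tr$sigma, noise = nm)
  b <- synth_spectrum(tr$eps, params_sigma = tr$sigma, noise = nm)
  expect_identical(a$eps_real, b$eps_real)
  c <- synth_spectrum(tr$eps, params_sigma = tr$sigma,
                      noise = noise_model(0.04, 0.05, seed = 12))
  expect_false(identical(a$eps_real, c$eps_real))

  # empirical relative sd over the 265 grid points within 30% of nominal
  truth <- debye_curve(tr$eps, tr$sigma, dak_tl_grid())
  sd_emp <- sd(a$eps_real / truth$eps_real - 1)
  expect_lt(abs(sd_emp / 0.04 - 1), 0.30)
})

test_that("phantom hits its length and volume targets", {
  spec <- phantom_spec()   # male defaults, 6 legs
  h <- 25e-6
  ph <- make_phantom(spec, h = h)
  m <- model_metrics(ph$model)
  expect_lt(abs(m$body_length_mm - spec$body_length * 1e3), h * 1e3 + 1e-9)
  expect_lt(abs(m$volume_mm3 / (spec$total_volume * 1e9) - 1), 0.05)

  # a specimen-length target is met to within one voxel
  sp2 <- phantom_spec(body_length = 3.586e-3, total_volume = 0.913e-9)
  m2 <- model_metrics(make_phantom(sp2, h = h)$model)
  expect_lt(abs(m2$body_length_mm - 3.586), h * 1e3 + 1e-9)
})

test_that("legs add their analytic cylinder volume", {
  # fat legs so the thin-cylinder voxelization error stays small
  legged <- phantom_spec(n_legs = 6L, proboscis_length = 0,
                         leg_radius = 1e-4, leg_length = 1.5e-3)
  h <- 25e-6
  mdl <- make_phantom(legged, h = h)$model
  v_leg_vox <- sum(mdl$labels == 4L) * h^3
  v_leg_analytic <- 6 * pi * legged$leg_radius^2 * legged$leg_length
  expect_lt(abs(v_leg_vox / v_leg_analytic - 1), 0.05)

  # removing the legs leaves the legless trunk volume
  legless <- remove_parts(mdl, "legs")
  expect_equal(sum(legless$occupancy) + sum(mdl$labels == 4L),
               sum(mdl$occupancy))
})

test_that("phantom generation is deterministic and labels partition", {
  spec <- phantom_spec()
  a <- make_phantom(spec, h = 50e-6)
  b <- make_phantom(spec, h = 50e-6)
  expect_identical(a$model$labels, b$model$labels)
  lab <- a$model$labels
  expect_true(all((lab != 0L) == a$model$occupancy))
  expect_true(all(lab %in% 0:5))
  # every major part present
  expect_true(all(c(1L, 2L, 3L, 4L) %in% unique(as.vector(lab))))
})

test_that("emitted mesh is watertight and consistent with the mask", {
  ph <- make_phantom(quick_phantom_spec(), h = 50e-6)
  expect_gt(ph$mesh$n_facets, 0)
  expect_true(is_watertight(ph$mesh))
  # voxelizing the emitted mesh reproduces the mask (1-voxel shell slack)
  v2 <- voxelize(ph$mesh, 50e-6)
  expect_equal(sum(v2$occupancy), sum(ph$model$occupancy),
               tolerance = 0.02)
  # mesh encloses exactly the voxel volume
  expect_equal(mesh_volume(ph$mesh),
               sum(ph$model$occupancy) * (50e-6)^3, tolerance = 1e-9)
})

test_that("sphere phantom volume matches the analytic sphere", {
  sp <- make_sphere_phantom(1e-3, 25e-6)
  vol <- sum(sp$model$occupancy) * (25e-6)^3
  expect_lt(abs(vol / (4 / 3 * pi * 1e-9) - 1), 0.01)
  expect_true(is_watertight(sp$mesh))
})

test_that("infeasible phantom specs error", {
  bad <- phantom_spec(total_volume = 1e-12)  # far below head+thorax volume
  expect_error(make_phantom(bad, h = 50e-6), "infeasible")
})
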