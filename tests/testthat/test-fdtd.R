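# Solver-level checks on deliberately tiny domains; the full
# sphere-vs-Mie validation lives in the acceptance suite.

make_blob <- function(n = 3L, h = 30e-6) {
  occ <- array(TRUE, c(n, n, n))
  voxel_model(occ, h)
}

test_that("period rule reproduces the protocol anchors", {
  expect_equal(required_periods(2e9, 4e-3), 7L)
  expect_equal(required_periods(240e9, 4e-3), 35L)
  for (f in c(2e9, 6e9, 24e9, 90e9, 240e9)) {
    l <- 4e-3
    expect_gt(required_periods(f, l), 2 * l / (rf_constants$c0 / f))
  }
  # interior frequencies fall between the anchors
  p60 <- required_periods(60e9, 4e-3)
  expect_true(p60 > 7 && p60 <= 35)
})

test_that("absorbed-power integration has the right weights", {
  # 1 mm^3 of sigma = 1 S/m in a uniform 1 V/m (rms) field -> 1 nW
  blk <- voxel_model(array(TRUE, c(10, 10, 10)), 1e-4)
  dom <- simulation_domain(blk, 1, 1)
  nd <- dom$dims
  sol <- list(ex = array(1 + 0i, c(nd[1], nd[2] + 1, nd[3] + 1)),
              ey = array(0i, c(nd[1] + 1, nd[2], nd[3] + 1)),
              ez = array(0i, c(nd[1] + 1, nd[2] + 1, nd[3])))
  expect_equal(compute_pabs(sol, dom), 1e-9, tolerance = 1e-12)
})

test_that("domain construction validates its invariants", {
  blk <- make_blob()
  expect_error(simulation_domain(blk, 5, 1, pml = list(cells = 3)), "PML")
  expect_error(simulation_domain(blk, 5, 1, gap_cells = 2), "air gap")
  dom <- simulation_domain(blk, 5, 1)
  # grid rule: 30 um pitch is too coarse for a very high permittivity
  expect_error(run_fdtd(dom, plane_wave(c(1, 0, 0), c(0, 0, 1), 240e9,
                                        e_rms = 1)),
               NA)
  dom_hi <- simulation_domain(make_blob(h = 300e-6), 25, 1)
  expect_error(run_fdtd(dom_hi, plane_wave(c(1, 0, 0), c(0, 0, 1), 240e9)),
               "grid rule")
  expect_error(plane_wave(c(1, 0, 0), c(1, 0, 0), 1e9), "orthogonal")
})

test_that("lossless scatterers absorb nothing and runs are deterministic", {
  blob <- make_blob()
  dom <- simulation_domain(blob, 4, 0)
  w <- plane_wave(c(1, 0, 0), c(0, 0, 1), 240e9)
  sol <- run_fdtd(dom, w)
  expect_true(sol$converged)
  expect_identical(sol$pabs_volume, 0)            # sigma = 0 exactly
  expect_lt(sol$pabs, 1e-13)                      # flux residual is noise
  sol2 <- run_fdtd(dom, w)
  expect_identical(sol$ex, sol2$ex)
  expect_identical(sol$pabs, sol2$pabs)
})

test_that("solver is linear and respects cube symmetry", {
  d <- aedes_at(240e9)
  blob <- make_blob()
  dom <- simulation_domain(blob, d$eps_real, d$sigma)
  p1 <- run_fdtd(dom, plane_wave(c(1, 0, 0), c(0, 0, 1), 240e9, e_rms = 1))
  p2 <- run_fdtd(dom, plane_wave(c(1, 0, 0), c(0, 0, 1), 240e9, e_rms = 2))
  expect_equal(p2$pabs / p1$pabs, 4, tolerance = 1e-6)
  expect_equal(p2$pabs_volume / p1$pabs_volume, 4, tolerance = 1e-6)

  # a cube is invariant under (k, e) -> (rotated k, rotated e)
  p3 <- run_fdtd(dom, plane_wave(c(0, 0, 1), c(1, 0, 0), 240e9))
  expect_equal(p3$pabs / p1$pabs, 1, tolerance = 1e-3)

  # energy sanity: absorbed power below incident power on the cross-section
  area <- prod(dim(blob$occupancy)[2:3]) * blob$spacing^2
  expect_lt(p1$pabs, 1^2 / rf_constants$eta0 * area * 10)

  # phasor-based and cycle-averaged time-domain power agree
  expect_equal(p1$pabs_volume / utils::tail(p1$pabs_trace, 1), 1,
               tolerance = 0.02)
})

test_that("field slices are normalized to 0 dB at the maximum", {
  d <- aedes_at(240e9)
  blob <- make_blob()
  dom <- simulation_domain(blob, d$eps_real, d$sigma)
  sol <- run_fdtd(dom, plane_wave(c(1, 0, 0), c(0, 0, 1), 240e9))
  sl <- field_slice_db(sol, dom)
  expect_true(all(sl <= 0))
  expect_true(is.matrix(sl) || length(dim(sl)) == 3)
})
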