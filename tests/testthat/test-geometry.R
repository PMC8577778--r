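test_that("STL read/write round-trips in both formats", {
  cube <- unit_cube_mesh(1e-3)  # 1 mm cube
  expect_equal(cube$n_facets, 12)
  expect_equal(mesh_volume(cube), 1e-9, tolerance = 1e-12)
  expect_true(is_watertight(cube))

  for (fmt in c("ascii", "binary")) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(cube, path, format = fmt)
    back <- read_stl(path)
    expect_equal(back$n_facets, 12)
    expect_equal(sort(as.vector(back$vertices)),
                 sort(as.vector(cube$vertices)), tolerance = 1e-6)
    expect_equal(mesh_volume(back), 1e-9, tolerance = 1e-6)
  }
})

test_that("malformed STL files produce diagnostic errors", {
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(unit_cube_mesh(), path, format = "binary")
  raw <- readBin(path, "raw", n = file.info(path)$size)
  writeBin(raw[1:200], path)   # truncate mid-facet
  expect_error(read_stl(path), "byte")

  bad <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0", "    endloop", "  endfacet",
               "endsolid x"), bad)
  expect_error(read_stl(bad), "malformed")
})

test_that("voxelization matches analytic volumes", {
  # unit cube at h = 0.25: all 4x4x4 centers lie inside
  cube <- unit_cube_mesh()
  v <- voxelize(cube, 0.25, body_axis = 1)
  expect_equal(sum(v$occupancy), 64)

  # 1 mm sphere at 25 um: volume within 1% of 4*pi*r^3/3
  sph <- make_sphere_phantom(1e-3, 25e-6, mesh_n = 96)
  vm <- voxelize(sph$mesh, 25e-6)
  vol <- sum(vm$occupancy) * (25e-6)^3
  expect_lt(abs(vol / (4 / 3 * pi * 1e-9) - 1), 0.01)

  expect_error(voxelize(rf_mesh(matrix(0, 3, 3))[c()], 1e-3))
})

test_that("voxel volume converges and is translation-robust", {
  mesh <- sphere_mesh(1e-3, n = 96)
  vol_true <- 4 / 3 * pi * 1e-9
  err <- sapply(c(100e-6, 50e-6), function(h) {
    abs(sum(voxelize(mesh, h)$occupancy) * h^3 / vol_true - 1)
  })
  expect_lt(err[2], err[1])

  shifted <- rf_mesh(sweep(mesh$vertices, 2, c(11.3e-6, 7.9e-6, 3.1e-6), "+"))
  v1 <- sum(voxelize(mesh, 25e-6)$occupancy)
  v2 <- sum(voxelize(shifted, 25e-6)$occupancy)
  expect_lt(abs(v2 / v1 - 1), 0.02)
})

test_that("model metrics follow closed forms", {
  v <- voxelize(unit_cube_mesh(1e-3), 0.25e-3, body_axis = 1)
  m <- model_metrics(v)
  expect_equal(m$volume_mm3, 1, tolerance = 1e-9)
  expect_equal(m$diagonal_mm, sqrt(3), tolerance = 1e-9)
  expect_equal(m$body_length_mm, 1, tolerance = 1e-9)
  empty <- voxel_model(array(FALSE, c(2, 2, 2)), 1e-3)
  expect_error(model_metrics(empty), "empty")
})

test_that("body-part partition is exact and disjoint", {
  ph <- make_phantom(quick_phantom_spec(), h = 50e-6)
  v <- ph$model
  parts <- partition_parts(v, c("head", "thorax", "abdomen"))
  occs <- sapply(parts, function(p) sum(p$occupancy))
  expect_equal(sum(occs), sum(v$labels %in% 1:3))
  # pairwise disjoint
  expect_equal(sum(parts$head$occupancy & parts$thorax$occupancy), 0)
  expect_equal(sum(parts$head$occupancy & parts$abdomen$occupancy), 0)

  # whole-domain box reproduces the model
  d <- dim(v$occupancy)
  box <- rbind(v$origin, v$origin + d * v$spacing)
  whole <- partition_parts(v, list(box))[[1]]
  expect_equal(whole$occupancy, v$occupancy)

  # disjoint boxes share no voxels
  mid <- v$origin[1] + d[1] * v$spacing / 2
  b1 <- rbind(v$origin, c(mid, v$origin[2:3] + d[2:3] * v$spacing))
  b2 <- rbind(c(mid, v$origin[2:3]), v$origin + d * v$spacing)
  two <- partition_parts(v, list(b1, b2))
  expect_equal(sum(two[[1]]$occupancy & two[[2]]$occupancy), 0)

  out_box <- rbind(v$origin - 1, v$origin)
  expect_error(partition_parts(v, list(out_box)), "outside")
})

test_that("part removal composes and reports volume fractions", {
  ph <- make_phantom(phantom_spec(n_legs = 6L), h = 25e-6)
  v <- ph$model
  same <- remove_parts(v, character())
  expect_equal(attr(same, "volume_fraction"), 1.0)
  expect_equal(same$occupancy, v$occupancy)

  legless <- remove_parts(v, "legs")
  trunk_frac <- sum(v$labels %in% c(1:3, 5)) / sum(v$occupancy)
  expect_equal(attr(legless, "volume_fraction"), trunk_frac,
               tolerance = 1e-12)
  # analytic expectation: trunk / total within 2%
  spec <- phantom_spec(n_legs = 6L)
  v_legs <- 6 * pi * spec$leg_radius^2 * spec$leg_length
  expect_equal(attr(legless, "volume_fraction"),
               1 - v_legs / spec$total_volume, tolerance = 0.02)
})

test_that("removing one leg then the rest equals removing all legs", {
  ph <- make_phantom(phantom_spec(n_legs = 2L), h = 50e-6)
  v <- ph$model
  # clear one leg via a box around it, then remove the remaining label
  leg_idx <- which(v$labels == 4L, arr.ind = TRUE)
  one <- leg_idx[leg_idx[, 3] == leg_idx[1, 3], , drop = FALSE]
  all_removed <- remove_parts(v, "legs")
  seq_removed <- remove_parts(remove_parts(v, "legs"), "legs")
  expect_equal(seq_removed$occupancy, all_removed$occupancy)
})
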