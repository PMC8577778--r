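# Shared fixtures, all generated in code.

# unit cube [0,1]^3 m as a 12-facet triangle soup (consistent outward
# winding), used for STL and voxelization oracles
unit_cube_mesh <- function(scale = 1) {
  v <- matrix(c(
    # -x face
    0,0,0, 0,0,1, 0,1,1,  0,0,0, 0,1,1, 0,1,0,
    # +x face
    1,0,0, 1,1,0, 1,1,1,  1,0,0, 1,1,1, 1,0,1,
    # -y face
    0,0,0, 1,0,0, 1,0,1,  0,0,0, 1,0,1, 0,0,1,
    # +y face
    0,1,0, 0,1,1, 1,1,1,  0,1,0, 1,1,1, 1,1,0,
    # -z face
    0,0,0, 0,1,0, 1,1,0,  0,0,0, 1,1,0, 1,0,0,
    # +z face
    0,0,1, 1,0,1, 1,1,1,  0,0,1, 1,1,1, 0,1,1),
    ncol = 3, byrow = TRUE)
  rf_mesh(v * scale)
}

# small quick-phantom spec: legless, coarse-grid friendly
quick_phantom_spec <- function(sex = "male") {
  phantom_spec(n_legs = 0L, proboscis_length = 0, sex = sex)
}

# mosquito dielectric at a frequency (eps row + sigma row)
aedes_at <- function(f) {
  d <- debye_curve(aedes_debye("eps"), aedes_debye("sigma"), f)
  list(eps_real = d$eps_real[1], sigma = d$sigma_s_per_m[1])
}
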