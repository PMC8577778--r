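# Synthetic inputs with known ground truth: noisy Debye spectra on the
# coaxial-probe measurement grid, a parametric mosquito-like phantom
# with labeled body parts, and homogeneous-sphere phantoms for the
# analytic (Mie) oracle.

# run code under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Multiplicative measurement-noise model for synthetic spectra
#'
#' Independent multiplicative factors per frequency,
#' `1 + sd * z` with `z` standard normal truncated at 3.5 sd (so factors
#' stay positive at the percent-level sds typical of probe uncertainty).
#' Defaults match the inter-sample relative deviations observed for the
#' mosquito homogenate (4.04% on \eqn{\epsilon'}, 5.81% on \eqn{\sigma}).
#'
#' @param relative_sd_eps relative standard deviation on \eqn{\epsilon'}.
#' @param relative_sd_sigma relative standard deviation on \eqn{\sigma}.
#' @param seed integer RNG seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(relative_sd_eps = 0.0404,
                        relative_sd_sigma = 0.0581, seed = 1L) {
  stopifnot(relative_sd_eps >= 0, relative_sd_sigma >= 0)
  structure(list(relative_sd_eps = relative_sd_eps,
                 relative_sd_sigma = relative_sd_sigma,
                 seed = as.integer(seed)), class = "noise_model")
}

.trunc_normal <- function(n, sd) {
  z <- rnorm(n)
  z <- pmin(pmax(z, -3.5), 3.5)
  1 + sd * z
}

#' Generate a synthetic permittivity spectrum from Debye parameters
#'
#' Evaluates \eqn{\epsilon'} from `params` and \eqn{\sigma} from
#' `params_sigma` (defaulting to `params`, i.e. a single consistent
#' model) on the given grid, then applies independent multiplicative
#' noise. A fixed seed yields identical output.
#'
#' @param params [debye_params()] for the real part.
#' @param grid frequency grid in Hz (default [dak_tl_grid()]).
#' @param noise a [noise_model()], or `NULL` for a noiseless spectrum.
#' @param params_sigma optional separate [debye_params()] for the
#'   conductivity (the two-row convention of [aedes_debye()]).
#' @param temperature degrees C tag.
#' @return A [permittivity_spectrum()] with provenance `"synthetic"`.
#' @examples
#' tr <- aedes_debye("pair")
#' sp <- synth_spectrum(tr$eps, params_sigma = tr$sigma,
#'                      noise = noise_model(0.01, 0.01, seed = 7))
#' @export
synth_spectrum <- function(params, grid = dak_tl_grid(), noise = NULL,
                           params_sigma = NULL, temperature = 22) {
  if (is.null(params_sigma)) params_sigma <- params
  curve <- debye_curve(params, params_sigma, grid)
  er <- curve$eps_real
  sg <- curve$sigma_s_per_m
  if (!is.null(noise) &&
      (noise$relative_sd_eps > 0 || noise$relative_sd_sigma > 0)) {
    fac <- .with_seed(noise$seed, {
      list(e = .trunc_normal(length(grid), noise$relative_sd_eps),
           s = .trunc_normal(length(grid), noise$relative_sd_sigma))
    })
    er <- er * fac$e
    sg <- sg * fac$s
  }
  permittivity_spectrum(grid, er, sg, temperature = temperature,
                        provenance = "synthetic")
}

#' Specification of a parametric mosquito-like phantom
#'
#' The phantom is a union of analytic solids aligned along one grid
#' axis: a spherical head, a spherical thorax (slightly inflated so the
#' segments fuse), a prolate-ellipsoid abdomen whose transverse radius
#' is solved to hit the target volume, an optional cylindrical
#' proboscis, and up to six cylindrical legs rooted in the thorax.
#' Defaults target the male-specimen means (body length 3.544 mm,
#' volume 0.812 mm^3); `sex = "female"` targets the female means
#' (4.015 mm, 1.196 mm^3).
#'
#' @param body_length pronotum-to-abdomen-tip target, metres (1--10 mm).
#' @param total_volume target occupied volume, m^3.
#' @param n_legs integer 0--6.
#' @param leg_radius,leg_length leg cylinder dimensions, metres.
#' @param proportions head/thorax/abdomen fractions of body length
#'   (must sum to 1).
#' @param proboscis_length proboscis length, metres (0 disables it).
#' @param axis body alignment axis (1, 2, 3 or "x", "y", "z").
#' @param sex `"male"` or `"female"` preset for length/volume targets
#'   (ignored if `body_length`/`total_volume` are given explicitly).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(body_length = NULL, total_volume = NULL,
                         n_legs = 6L, leg_radius = 5e-5, leg_length = 1.8e-3,
                         proportions = c(head = 0.15, thorax = 0.30,
                                         abdomen = 0.55),
                         proboscis_length = 0.8e-3, axis = 1L,
                         sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (is.null(body_length))
    body_length <- if (sex == "male") 3.544e-3 else 4.015e-3
  if (is.null(total_volume))
    total_volume <- if (sex == "male") 0.812e-9 else 1.196e-9
  stopifnot(body_length >= 1e-3, body_length <= 10e-3,
            n_legs %in% 0:6, leg_radius > 0, leg_length >= 0,
            abs(sum(proportions) - 1) < 1e-9, all(proportions > 0),
            total_volume > 0)
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  structure(list(body_length = body_length, total_volume = total_volume,
                 n_legs = as.integer(n_legs), leg_radius = leg_radius,
                 leg_length = leg_length, proportions = proportions,
                 proboscis_length = proboscis_length,
                 axis = as.integer(axis), sex = sex),
            class = "phantom_spec")
}

# mask of an axis-aligned-free cylinder on marginal coordinate vectors
.cylinder_mask <- function(xs, ys, zs, base, dir, len, r) {
  co <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  v <- sweep(co, 2, base)
  t <- as.vector(v %*% dir)
  d2 <- rowSums((v - outer(t, dir))^2)
  m <- t >= 0 & t <= len & d2 <= r^2
  array(m, dim = c(length(xs), length(ys), length(zs)))
}

.ellipsoid_mask <- function(xs, ys, zs, center, semi) {
  qx <- ((xs - center[1]) / semi[1])^2
  qy <- ((ys - center[2]) / semi[2])^2
  qz <- ((zs - center[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

#' Build a labeled mosquito-like phantom
#'
#' Generates the voxel mask directly from the analytic solids (voxel
#' occupied iff its center is inside a solid) and emits the matching
#' watertight voxel-surface mesh. Deterministic; the achieved body
#' length is within one voxel of the target and the achieved volume
#' within 5% of the target (the abdomen transverse radius is solved on
#' the grid in two fixed-point iterations).
#'
#' @param spec a [phantom_spec()].
#' @param h voxel pitch in metres (default 25 um).
#' @return A list with elements `model` (labeled [voxel_model()]) and
#'   `mesh` (an [rf_mesh()]).
#' @export
make_phantom <- function(spec, h = 25e-6) {
  stopifnot(inherits(spec, "phantom_spec"), h > 0)
  L <- spec$body_length
  fr <- spec$proportions
  r_head <- fr[["head"]] * L / 2
  a_thx <- fr[["thorax"]] * L / 2 * 1.12   # inflated to fuse the segments
  a_abd <- fr[["abdomen"]] * L / 2
  gam <- 1.25                              # thorax/abdomen width ratio
  c_head <- c(fr[["head"]] * L / 2, 0, 0)  # centers along local x
  c_thx <- c(fr[["head"]] * L + fr[["thorax"]] * L / 2, 0, 0)
  c_abd <- c(fr[["head"]] * L + fr[["thorax"]] * L + a_abd, 0, 0)

  v_head <- 4 / 3 * pi * r_head^3
  v_legs <- spec$n_legs * pi * spec$leg_radius^2 * spec$leg_length
  v_prob <- if (spec$proboscis_length > 0)
    pi * (0.8 * spec$leg_radius)^2 * spec$proboscis_length else 0
  # thorax (prolate, transverse radius gam*b) and abdomen (prolate,
  # transverse radius b) share the transverse scale b, solved for the
  # volume target
  v_rem <- spec$total_volume - v_head - v_legs - v_prob
  if (v_rem <= 0)
    stop("infeasible phantom spec: target volume too small for the ",
         "head/leg geometry")
  b_abd <- sqrt(3 * v_rem / (4 * pi * (a_thx * gam^2 + a_abd)))

  # leg roots on the thorax surface, pointing down-and-out; the root
  # depends on the transverse scale b, so legs are placed inside build()
  make_legs <- function(b) {
    if (spec$n_legs == 0) return(list())
    out <- list()
    fracs <- c(0.30, 0.50, 0.70)
    dirs_ax <- c(-0.35, 0, 0.35)
    q <- 0
    for (side in c(1, -1)) for (p in 1:3) {
      q <- q + 1
      if (q > spec$n_legs) break
      d <- c(dirs_ax[p], side * 0.55, -0.70)
      d <- d / sqrt(sum(d^2))
      anchor <- c_thx + c((fracs[p] - 0.5) * fr[["thorax"]] * L, 0, 0)
      # distance from the anchor to the thorax ellipsoid surface along d
      t_surf <- 1 / sqrt((d[1] / a_thx)^2 + (d[2] / (gam * b))^2 +
                           (d[3] / (gam * b))^2)
      out[[q]] <- list(base = anchor + 0.97 * t_surf * d, dir = d)
    }
    out
  }

  build <- function(b) {
    leg_defs <- make_legs(b)
    w <- max(gam * b, r_head)
    lo <- c(-if (spec$proboscis_length > 0) spec$proboscis_length else 0,
            -w, -w)
    hi <- c(L, w, w)
    if (length(leg_defs)) {
      for (ld in leg_defs) {
        tip <- ld$base + spec$leg_length * ld$dir
        lo <- pmin(lo, tip - spec$leg_radius, ld$base - spec$leg_radius)
        hi <- pmax(hi, tip + spec$leg_radius, ld$base + spec$leg_radius)
      }
    }
    origin <- lo - 1.5 * h
    dims <- as.integer(ceiling((hi - origin) / h) + 2L)
    xs <- origin[1] + (seq_len(dims[1]) - 0.5) * h
    ys <- origin[2] + (seq_len(dims[2]) - 0.5) * h
    zs <- origin[3] + (seq_len(dims[3]) - 0.5) * h

    lab <- array(0L, dims)
    # order fixes the label where solids overlap: later wins
    if (spec$proboscis_length > 0) {
      m <- .cylinder_mask(xs, ys, zs, c(-spec$proboscis_length, 0, 0),
                          c(1, 0, 0), spec$proboscis_length + h,
                          0.8 * spec$leg_radius)
      lab[m] <- 5L
    }
    for (ld in leg_defs) {
      m <- .cylinder_mask(xs, ys, zs, ld$base, ld$dir, spec$leg_length,
                          spec$leg_radius)
      lab[m] <- 4L
    }
    lab[.ellipsoid_mask(xs, ys, zs, c_abd, c(a_abd, b, b))] <- 3L
    lab[.ellipsoid_mask(xs, ys, zs, c_head, rep(r_head, 3))] <- 1L
    lab[.ellipsoid_mask(xs, ys, zs, c_thx, c(a_thx, gam * b, gam * b))] <- 2L
    lab
  }

  # fixed-point corrections of the shared transverse radius on the grid
  for (it in 1:3) {
    lab <- build(b_abd)
    vol <- sum(lab != 0L) * h^3
    if (it == 3 || abs(vol - spec$total_volume) < 0.01 * spec$total_volume)
      break
    v_bdep <- max(sum(lab %in% c(2L, 3L)) * h^3, h^3)  # scales with b^2
    need <- v_bdep + (spec$total_volume - vol)
    if (need <= 0) stop("infeasible phantom spec: trunk volume collapsed")
    b_abd <- b_abd * sqrt(need / v_bdep)
  }

  perm <- switch(spec$axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
  if (spec$axis != 1L) lab <- aperm(lab, perm)
  occ <- lab != 0L
  model <- voxel_model(occ, h, origin = c(0, 0, 0), labels = lab,
                       body_axis = spec$axis)
  list(model = model, mesh = voxel_surface_mesh(model))
}

#' Triangulated sphere mesh (UV parameterization)
#'
#' @param radius metres.
#' @param center length-3, metres.
#' @param n number of longitude divisions (latitudes are `n/2`).
#' @return An [rf_mesh()]; watertight by construction.
#' @export
sphere_mesh <- function(radius, center = c(0, 0, 0), n = 48L) {
  stopifnot(radius > 0, n >= 8)
  nlat <- as.integer(n / 2)
  th <- seq(0, pi, length.out = nlat + 1)   # polar angle rings
  ph <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring <- function(i) {
    if (i == 1) return(matrix(center + c(0, 0, radius), 1, 3, byrow = TRUE))
    if (i == nlat + 1) return(matrix(center + c(0, 0, -radius), 1, 3,
                                     byrow = TRUE))
    cbind(center[1] + radius * sin(th[i]) * cos(ph),
          center[2] + radius * sin(th[i]) * sin(ph),
          center[3] + radius * cos(th[i]))
  }
  rings <- lapply(seq_len(nlat + 1), ring)
  tris <- list()
  add <- function(a, b, d) tris[[length(tris) + 1L]] <<- rbind(a, b, d)
  for (i in 1:nlat) {
    up <- rings[[i]]; dn <- rings[[i + 1]]
    for (j in 1:n) {
      j2 <- if (j == n) 1L else j + 1L
      if (i == 1) {
        add(up[1, ], dn[j, ], dn[j2, ])
      } else if (i == nlat) {
        add(up[j, ], dn[1, ], up[j2, ])
      } else {
        add(up[j, ], dn[j, ], dn[j2, ])
        add(up[j, ], dn[j2, ], up[j2, ])
      }
    }
  }
  rf_mesh(do.call(rbind, tris))
}

#' Homogeneous-sphere phantom for the analytic oracle
#'
#' The voxel mask is computed analytically (voxel center inside the
#' sphere), independent of the mesh path; the mesh is a smooth UV
#' triangulation of the same sphere.
#'
#' @param radius sphere radius, metres.
#' @param h voxel pitch, metres.
#' @param mesh_n longitude divisions for the emitted mesh.
#' @return List with `model` (a [voxel_model()], label `"other"`) and
#'   `mesh` (an [rf_mesh()]).
#' @export
make_sphere_phantom <- function(radius, h, mesh_n = 64L) {
  stopifnot(radius > 0, h > 0)
  half <- ceiling(radius / h) + 2L
  n <- 2L * half
  xs <- (seq_len(n) - half - 0.5) * h
  occ <- .ellipsoid_mask(xs, xs, xs, c(0, 0, 0), rep(radius, 3))
  lab <- array(0L, dim(occ)); lab[occ] <- 5L
  model <- voxel_model(occ, h, origin = rep(-half * h, 3), labels = lab)
  list(model = model, mesh = sphere_mesh(radius, n = mesh_n))
}
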