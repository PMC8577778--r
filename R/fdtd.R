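# R-side interface to the FDTD solver: simulation-domain construction
# from a voxel model, the period rule, solver invocation, phasor
# assembly, absorbed-power integration and field-slice export.

#' Define an incident plane wave
#'
#' @param k_hat unit propagation direction (length-3).
#' @param e_hat unit polarization, orthogonal to `k_hat`.
#' @param frequency Hz (> 0).
#' @param e_rms incident RMS electric field strength, V/m (default 1,
#'   the dosimetry reference; rescale results with [scale_pabs()]).
#' @param ramp_periods raised-cosine turn-on length in periods.
#' @return A list of class `plane_wave`.
#' @export
plane_wave <- function(k_hat, e_hat, frequency, e_rms = 1,
                       ramp_periods = 2) {
  k_hat <- as.numeric(k_hat); e_hat <- as.numeric(e_hat)
  stopifnot(length(k_hat) == 3, length(e_hat) == 3,
            frequency > 0, e_rms > 0, ramp_periods >= 0)
  k_hat <- k_hat / sqrt(sum(k_hat^2))
  e_hat <- e_hat / sqrt(sum(e_hat^2))
  if (abs(sum(k_hat * e_hat)) > 1e-9)
    stop("e_hat must be orthogonal to k_hat")
  structure(list(k_hat = k_hat, e_hat = e_hat, frequency = frequency,
                 e_rms = e_rms, ramp_periods = ramp_periods),
            class = "plane_wave")
}

#' Simulation periods required for steady state
#'
#' At least twice the body size divided by the free-space wavelength,
#' plus a transit margin, and never less than a frequency-interpolated
#' floor running from 7 periods at 2 GHz to 35 at 240 GHz
#' (log-frequency interpolation, clamped).
#'
#' @param f frequency, Hz.
#' @param l largest body dimension, metres.
#' @param margin additional periods on the transit bound.
#' @return Integer number of periods.
#' @examples
#' required_periods(2e9, 4e-3)    # 7
#' required_periods(240e9, 4e-3)  # 35
#' @export
required_periods <- function(f, l, margin = 2) {
  stopifnot(f > 0, l > 0)
  lambda0 <- rf_constants$c0 / f
  transit <- ceiling(2 * l / lambda0) + margin
  interp <- 7 + 28 * log(f / 2e9) / log(120)
  floor_p <- ceiling(pmin(35, pmax(7, interp)))
  as.integer(max(transit, floor_p))
}

# material arrays at the staggered E-component positions.
# averaging = "edge": mean over the 2x2 voxel cells sharing the edge
# (the transverse-plane neighbors); "cell": nearest lower cell.
.component_material <- function(cellarr, comp, averaging = "edge") {
  d <- dim(cellarr)
  tdims <- switch(comp,
                  x = c(d[1], d[2] + 1L, d[3] + 1L),
                  y = c(d[1] + 1L, d[2], d[3] + 1L),
                  z = c(d[1] + 1L, d[2] + 1L, d[3]))
  pdim <- d + 2L
  P <- array(cellarr[1] * 0 + .vacuum_of(cellarr), pdim)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cellarr
  out <- array(0, tdims)
  if (comp == "x") {
    ii <- 2:(d[1] + 1); jj <- 1:(d[2] + 1); kk <- 1:(d[3] + 1)
    if (averaging == "edge")
      out[] <- (P[ii, jj, kk] + P[ii, jj + 1, kk] +
                P[ii, jj, kk + 1] + P[ii, jj + 1, kk + 1]) / 4
    else out[] <- P[ii, jj, kk]
  } else if (comp == "y") {
    ii <- 1:(d[1] + 1); jj <- 2:(d[2] + 1); kk <- 1:(d[3] + 1)
    if (averaging == "edge")
      out[] <- (P[ii, jj, kk] + P[ii + 1, jj, kk] +
                P[ii, jj, kk + 1] + P[ii + 1, jj, kk + 1]) / 4
    else out[] <- P[ii, jj, kk]
  } else {
    ii <- 1:(d[1] + 1); jj <- 1:(d[2] + 1); kk <- 2:(d[3] + 1)
    if (averaging == "edge")
      out[] <- (P[ii, jj, kk] + P[ii + 1, jj, kk] +
                P[ii, jj + 1, kk] + P[ii + 1, jj + 1, kk]) / 4
    else out[] <- P[ii, jj, kk]
  }
  out
}

.vacuum_of <- function(cellarr) attr(cellarr, "vacuum_value")

#' Build an FDTD simulation domain from a voxel model
#'
#' Embeds the model in free space with an air gap and a
#' perfectly-matched-layer (PML) absorber on all six faces. Material
#' values at the staggered field positions are the mean of the voxel
#' cells sharing each edge (`averaging = "edge"`) or taken from one
#' cell (`averaging = "cell"`, plain staircase).
#'
#' @param model a [voxel_model()]; occupied voxels get the insect
#'   material, empty voxels free space.
#' @param eps_real,sigma homogeneous insect material (scalars), or 3D
#'   arrays matching the model dimensions.
#' @param pml list: `cells` (thickness, >= 6), `order` (polynomial
#'   grading), `r0` (target reflection), `alpha` (CPML low-frequency
#'   stabilization, S/m).
#' @param gap_cells free-space cells between the model and the PML
#'   (>= 4).
#' @param averaging `"edge"` or `"cell"`.
#' @return A list of class `simulation_domain`.
#' @export
simulation_domain <- function(model, eps_real, sigma,
                              pml = list(cells = 10L, order = 3,
                                         r0 = 1e-6, alpha = 0.05),
                              gap_cells = 6L, averaging = c("edge", "cell")) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(model, "voxel_model"))
  pml <- modifyList(list(cells = 10L, order = 3, r0 = 1e-6, alpha = 0.05),
                    pml)
  if (pml$cells < 6L) stop("PML must be at least 6 cells thick")
  if (gap_cells < 4L) stop("need at least a 4-cell air gap")
  d <- dim(model$occupancy)
  pad <- as.integer(pml$cells + gap_cells)
  nd <- d + 2L * pad
  eps_cells <- array(1, nd)
  sig_cells <- array(0, nd)
  core <- function(a) list((pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]),
                           (pad + 1):(pad + d[3]))[[a]]
  eps_in <- if (length(eps_real) == 1) {
    tmp <- array(1, d); tmp[model$occupancy] <- eps_real; tmp
  } else { stopifnot(identical(dim(eps_real), d)); eps_real }
  sig_in <- if (length(sigma) == 1) {
    tmp <- array(0, d); tmp[model$occupancy] <- sigma; tmp
  } else { stopifnot(identical(dim(sigma), d)); sigma }
  eps_cells[core(1), core(2), core(3)] <- eps_in
  sig_cells[core(1), core(2), core(3)] <- sig_in
  attr(eps_cells, "vacuum_value") <- 1
  attr(sig_cells, "vacuum_value") <- 0

  structure(list(
    h = model$spacing,
    dims = nd,
    pad = pad,
    model = model,
    pml = pml,
    averaging = averaging,
    eps = list(x = .component_material(eps_cells, "x", averaging),
               y = .component_material(eps_cells, "y", averaging),
               z = .component_material(eps_cells, "z", averaging)),
    sigma = list(x = .component_material(sig_cells, "x", averaging),
                 y = .component_material(sig_cells, "y", averaging),
                 z = .component_material(sig_cells, "z", averaging)),
    eps_max = max(eps_in)), class = "simulation_domain")
}

# incident-field RMS complex phasor at the staggered positions of one
# component; convention E(t) = Re(A exp(-i w t)), A = P + iQ,
# E(t) = P cos + Q sin; returns A / sqrt(2)
.incident_phasor <- function(domain, wave, comp) {
  h <- domain$h
  nd <- domain$dims
  td <- switch(comp, x = c(nd[1], nd[2] + 1, nd[3] + 1),
               y = c(nd[1] + 1, nd[2], nd[3] + 1),
               z = c(nd[1] + 1, nd[2] + 1, nd[3]))
  off <- switch(comp, x = c(0.5, 0, 0), y = c(0, 0.5, 0), z = c(0, 0, 0.5))
  r0 <- nd * h / 2
  xs <- ((seq_len(td[1]) - 1) + off[1]) * h - r0[1]
  ys <- ((seq_len(td[2]) - 1) + off[2]) * h - r0[2]
  zs <- ((seq_len(td[3]) - 1) + off[3]) * h - r0[3]
  k <- wave$k_hat
  w <- 2 * pi * wave$frequency
  phase <- outer(outer(k[1] * xs, k[2] * ys, "+"), k[3] * zs, "+") *
    (w / rf_constants$c0)
  a <- sqrt(2) * wave$e_rms * wave$e_hat[match(comp, c("x", "y", "z"))]
  # E_inc = A g sin(w t - phase): P = -A sin(phase), Q = A cos(phase)
  (complex(real = -a * sin(phase), imaginary = a * cos(phase))) / sqrt(2)
}

#' Boundary-faithful simulation domain for a homogeneous sphere
#'
#' Builds a [simulation_domain()] whose material arrays use a locally
#' conformal effective medium at the sphere surface instead of the
#' plain voxel staircase. Each staggered sample is treated as a small
#' capacitor network: the complex permittivity
#' \eqn{\hat\epsilon = \epsilon' - j\sigma/(\omega\epsilon_0)} is
#' averaged harmonically along the field direction (series path through
#' sphere and air, using the exact chord fraction of the sphere on each
#' sub-line) and arithmetically across the transverse dual face
#' (parallel paths). This is the standard subcell
#' effective-permittivity treatment of a dielectric interface; it
#' removes the staircase boundary bias that otherwise dominates the
#' absorbed power of a strongly lossy sphere at coarse grids. The
#' mixing acts on \eqn{\hat\epsilon}, so the domain is specific to one
#' frequency.
#'
#' Used to validate the solver against the Mie series; insect models
#' keep the plain voxel staircase of [simulation_domain()], matching
#' how voxelized specimen models are simulated.
#'
#' @param radius sphere radius, metres.
#' @param h grid pitch, metres.
#' @param eps_real,sigma sphere material.
#' @param frequency Hz (enters the complex mixing).
#' @param pml,gap_cells as in [simulation_domain()].
#' @param n_sub transverse subsamples per edge (per axis).
#' @return A `simulation_domain`.
#' @export
conformal_sphere_domain <- function(radius, h, eps_real, sigma, frequency,
                                    pml = list(cells = 10L, order = 3,
                                               r0 = 1e-6, alpha = 0.05),
                                    gap_cells = 6L, n_sub = 4L) {
  base <- make_sphere_phantom(radius, h)$model
  dom <- simulation_domain(base, eps_real, sigma, pml = pml,
                           gap_cells = gap_cells)
  w <- 2 * pi * frequency
  eps_hat <- complex(real = eps_real,
                     imaginary = -sigma / (w * rf_constants$eps0))
  nd <- dom$dims
  ctr <- nd * h / 2
  soff <- ((seq_len(n_sub) - 0.5) / n_sub - 0.5)  # in units of h
  for (comp in c("x", "y", "z")) {
    td <- dim(dom$eps[[comp]])
    off <- switch(comp, x = c(0.5, 0, 0), y = c(0, 0.5, 0),
                  z = c(0, 0, 0.5))
    xs <- ((seq_len(td[1]) - 1) + off[1]) * h - ctr[1]
    ys <- ((seq_len(td[2]) - 1) + off[2]) * h - ctr[2]
    zs <- ((seq_len(td[3]) - 1) + off[3]) * h - ctr[3]
    ax <- match(comp, c("x", "y", "z"))
    acc <- array(0 + 0i, td)
    for (a in soff) for (b in soff) {
      sh <- list(c(0, a, b), c(a, 0, b), c(a, b, 0))[[ax]] * h
      X <- xs + sh[1]; Y <- ys + sh[2]; Z <- zs + sh[3]
      # squared transverse distance from the sphere center, and the
      # line coordinate along the edge direction
      if (ax == 1) {
        rho2 <- outer(outer(X * 0, Y^2, "+"), Z^2, "+")
        u <- outer(outer(X, Y * 0, "+"), Z * 0, "+")
      } else if (ax == 2) {
        rho2 <- outer(outer(X^2, Y * 0, "+"), Z^2, "+")
        u <- outer(outer(X * 0, Y, "+"), Z * 0, "+")
      } else {
        rho2 <- outer(outer(X^2, Y^2, "+"), Z^2 * 0, "+")
        u <- outer(outer(X * 0, Y * 0, "+"), Z, "+")
      }
      half_chord <- sqrt(pmax(radius^2 - rho2, 0))
      frac <- pmax(pmin(u + h / 2, half_chord) -
                     pmax(u - h / 2, -half_chord), 0) / h
      acc <- acc + 1 / (frac / eps_hat + (1 - frac))  # series (harmonic)
    }
    eff <- acc / n_sub^2                              # parallel (mean)
    dom$eps[[comp]] <- Re(eff)
    dom$sigma[[comp]] <- pmax(-Im(eff) * w * rf_constants$eps0, 0)
  }
  dom$averaging <- "conformal"
  dom$eps_max <- eps_real
  dom
}

#' Run a single-frequency FDTD exposure simulation
#'
#' Leapfrog Yee updates with a conductivity term; the incident plane
#' wave (smooth raised-cosine turn-on) is applied in the
#' scattered-field formulation, and single-frequency phasors are
#' extracted by discrete Fourier projection over the final whole
#' periods after the cycle-averaged absorbed power has converged.
#'
#' @param domain a [simulation_domain()].
#' @param wave a [plane_wave()].
#' @param conv_tol relative change of cycle-averaged absorbed power
#'   between consecutive periods accepted as steady state.
#' @param max_periods hard cap before giving up (the partial trace is
#'   returned in the error).
#' @param dft_periods whole periods used for phasor projection.
#' @param courant Courant factor (fraction of the 3D stability bound).
#' @param enforce_grid_rule error if `h` exceeds one tenth of the
#'   in-medium wavelength.
#' @return A list of class `field_solution`: complex RMS phasor arrays
#'   `ex`, `ey`, `ez` of the total field, `pabs_trace` (W, per period),
#'   `converged`, `periods`, `pabs` (W, whole body).
#' @export
run_fdtd <- function(domain, wave, conv_tol = 1e-3, max_periods = 80L,
                     dft_periods = 2L, courant = 0.98,
                     enforce_grid_rule = TRUE) {
  stopifnot(inherits(domain, "simulation_domain"),
            inherits(wave, "plane_wave"))
  f <- wave$frequency
  h <- domain$h
  lam_med <- wavelength_in_medium(f, domain$eps_max)
  if (enforce_grid_rule && h > lam_med / 10 * (1 + 1e-9))
    stop(sprintf(paste0("grid rule violated: h = %.3g m exceeds ",
                        "lambda_medium/10 = %.3g m at %.3g GHz"),
                 h, lam_med / 10, f / 1e9))
  T <- 1 / f
  dt0 <- courant * h / (rf_constants$c0 * sqrt(3))
  spp <- as.integer(ceiling(T / dt0))
  dt <- T / spp

  occ_idx <- which(domain$model$occupancy, arr.ind = TRUE)
  if (nrow(occ_idx) > 0) {
    ext <- apply(occ_idx, 2, function(i) diff(range(i)) + 1) * h
    l <- sqrt(sum(ext^2))
  } else l <- max(domain$dims) * h
  minp <- required_periods(f, l)

  r0 <- domain$dims * h / 2
  res <- fdtd_run_cpp(as.integer(domain$dims), h, dt,
                      as.numeric(domain$eps$x), as.numeric(domain$sigma$x),
                      as.numeric(domain$eps$y), as.numeric(domain$sigma$y),
                      as.numeric(domain$eps$z), as.numeric(domain$sigma$z),
                      as.integer(domain$pml$cells), domain$pml$order,
                      domain$pml$r0, domain$pml$alpha,
                      wave$k_hat, wave$e_hat, r0, f,
                      sqrt(2) * wave$e_rms, wave$ramp_periods,
                      as.integer(minp), as.integer(max_periods),
                      conv_tol, as.integer(dft_periods), spp)
  if (!res$converged)
    stop(sprintf(paste0("FDTD did not converge within %d periods ",
                        "(last cycle-averaged Pabs %.4g W)"),
                 max_periods, utils::tail(res$pabs_trace, 1)))

  nd <- domain$dims
  shape <- list(x = c(nd[1], nd[2] + 1, nd[3] + 1),
                y = c(nd[1] + 1, nd[2], nd[3] + 1),
                z = c(nd[1] + 1, nd[2] + 1, nd[3]))
  mk <- function(cs, sn, comp) {
    ph <- complex(real = cs, imaginary = sn) / sqrt(2)  # scattered, RMS
    dim(ph) <- shape[[comp]]
    ph + .incident_phasor(domain, wave, comp)
  }
  sol <- structure(list(
    ex = mk(res$ex_cos, res$ex_sin, "x"),
    ey = mk(res$ey_cos, res$ey_sin, "y"),
    ez = mk(res$ez_cos, res$ez_sin, "z"),
    pabs_trace = res$pabs_trace,
    converged = res$converged,
    periods = res$periods,
    dt = res$dt, steps_per_period = res$steps_per_period,
    wave = wave), class = "field_solution")
  sol$pabs_volume <- compute_pabs(sol, domain)
  sol$pabs <- compute_pabs_flux(sol, domain)
  sol
}

#' Absorbed power by Poynting power balance
#'
#' Net time-averaged Poynting flux of the total field into a closed
#' box surrounding the insect, evaluated in the air gap where the
#' discretized fields are smooth. In steady state this equals the
#' absorbed power; unlike the volume integral of
#' \eqn{\sigma |E|^2}, it carries no staircase boundary-layer bias, so
#' it is the whole-body estimator used by [run_fdtd()] (`pabs`), with
#' the volume integral retained for per-part resolution
#' ([compute_pabs()]).
#'
#' @param solution a `field_solution`.
#' @param domain its [simulation_domain()].
#' @param margin air cells between the model bounding box and the
#'   integration box.
#' @return Absorbed power in watts.
#' @export
compute_pabs_flux <- function(solution, domain, margin = 2L) {
  nd <- domain$dims
  h <- domain$h
  w <- 2 * pi * solution$wave$frequency
  jwm <- complex(imaginary = w * 1.25663706212e-6)

  ex <- solution$ex; ey <- solution$ey; ez <- solution$ez
  d1 <- function(a, ax) {  # forward difference along axis ax
    d <- dim(a)
    i1 <- lapply(d, seq_len); i2 <- i1
    i1[[ax]] <- 1:(d[ax] - 1); i2[[ax]] <- 2:d[ax]
    (do.call(`[`, c(list(a), i2, drop = FALSE)) -
       do.call(`[`, c(list(a), i1, drop = FALSE))) / h
  }
  # H phasors at the Yee H positions, from the discrete Faraday law
  hx <- (d1(ez, 2) - d1(ey, 3)) / jwm          # (Nx+1, Ny, Nz)
  hy <- (d1(ex, 3) - d1(ez, 1)) / jwm          # (Nx,  Ny+1, Nz)
  hz <- (d1(ey, 1) - d1(ex, 2)) / jwm          # (Nx,  Ny, Nz+1)

  occ_idx <- which(domain$model$occupancy, arr.ind = TRUE)
  if (nrow(occ_idx) == 0) return(0)   # vacuum: nothing absorbs
  lo <- apply(occ_idx, 2, min) + domain$pad - margin   # cell indices
  hi <- apply(occ_idx, 2, max) + domain$pad + margin
  stopifnot(all(lo >= 2), all(hi <= nd - 1))

  av <- function(a, ax) {  # 2-point average along axis ax
    d <- dim(a)
    i1 <- lapply(d, seq_len); i2 <- i1
    i1[[ax]] <- 1:(d[ax] - 1); i2[[ax]] <- 2:d[ax]
    (do.call(`[`, c(list(a), i2, drop = FALSE)) +
       do.call(`[`, c(list(a), i1, drop = FALSE))) / 2
  }
  nx <- nd[1]; ny <- nd[2]; nz <- nd[3]
  # Poynting components at face centers of the cell grid. Index p in
  # the face-normal direction means the grid plane at coordinate p*h
  # (0-based), p = 1 .. N-1; the other two indices are cell indices.
  # Each field is interpolated only along the axes where its Yee
  # position does not already coincide with the face center.
  sxf <- Re(av(ey, 3)[2:nx, , , drop = FALSE] *
              Conj(av(av(hz, 1), 3)) -
            av(ez, 2)[2:nx, , , drop = FALSE] *
              Conj(av(av(hy, 1), 2)))
  syf <- Re(av(ez, 1)[, 2:ny, , drop = FALSE] *
              Conj(av(av(hx, 1), 2)) -
            av(ex, 3)[, 2:ny, , drop = FALSE] *
              Conj(av(av(hz, 2), 3)))
  szf <- Re(av(ex, 2)[, , 2:nz, drop = FALSE] *
              Conj(av(av(hy, 2), 3)) -
            av(ey, 1)[, , 2:nz, drop = FALSE] *
              Conj(av(av(hx, 1), 3)))
  jr <- lo[2]:hi[2]; kr <- lo[3]:hi[3]; ir <- lo[1]:hi[1]
  net_in <- h^2 * (
    sum(sxf[lo[1] - 1L, jr, kr]) - sum(sxf[hi[1], jr, kr]) +
    sum(syf[ir, lo[2] - 1L, kr]) - sum(syf[ir, hi[2], kr]) +
    sum(szf[ir, jr, lo[3] - 1L]) - sum(szf[ir, jr, hi[3]]))
  max(net_in, 0)
}

# labels at component positions (nearest lower cell, matching the
# "cell" staircase); returns integer array shaped like the component
.component_labels <- function(domain, comp) {
  lab <- domain$model$labels
  d <- dim(domain$model$occupancy)
  full <- array(0L, domain$dims)
  if (is.null(lab)) {
    lab <- array(0L, d); lab[domain$model$occupancy] <- 5L
  }
  pad <- domain$pad
  full[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]),
       (pad + 1):(pad + d[3])] <- lab
  attr(full, "vacuum_value") <- 0L
  m <- .component_material(full, comp, averaging = "cell")
  storage.mode(m) <- "integer"
  m
}

#' Absorbed RF power from a converged field solution
#'
#' \eqn{P_{abs} = \sum \sigma |E_{rms}|^2 h^3} over the insect cells
#' (or a selected body-part region).
#'
#' @param solution a `field_solution` from [run_fdtd()].
#' @param domain the [simulation_domain()] it was computed on.
#' @param region `NULL` for the whole body, or part label names/ids
#'   (see [voxel_model()]).
#' @return Absorbed power in watts.
#' @export
compute_pabs <- function(solution, domain, region = NULL) {
  h3 <- domain$h^3
  total <- 0
  for (comp in c("x", "y", "z")) {
    sg <- domain$sigma[[comp]]
    e2 <- Mod(solution[[paste0("e", comp)]])^2
    if (is.null(region)) {
      total <- total + sum(sg * e2) * h3
    } else {
      ids <- .resolve_labels(domain$model, region)
      lab <- .component_labels(domain, comp)
      sel <- lab %in% ids
      total <- total + sum(sg[sel] * e2[sel]) * h3
    }
  }
  total
}

#' Normalized field-magnitude slice in dB
#'
#' Extracts a mid-plane (default mid-sagittal) slice of
#' \eqn{20\log_{10}(|E|/|E|_{max})}, with \eqn{|E|} the RMS magnitude
#' interpolated to cell centers and the maximum taken over the whole
#' domain.
#'
#' @param solution a `field_solution`.
#' @param domain its [simulation_domain()].
#' @param normal slice normal axis (1, 2, 3 or "x", "y", "z").
#' @param index slice index (default: middle of the domain).
#' @return A numeric matrix of dB values with attribute `"h"`.
#' @export
field_slice_db <- function(solution, domain, normal = 2L, index = NULL) {
  if (is.character(normal)) normal <- match(normal, c("x", "y", "z"))
  nd <- domain$dims
  # cell-centred |E|^2: average the two staggered samples per component
  avg2 <- function(a, ax) {
    d <- dim(a)
    idx1 <- lapply(d, seq_len); idx2 <- idx1
    idx1[[ax]] <- 1:(d[ax] - 1); idx2[[ax]] <- 2:d[ax]
    (do.call(`[`, c(list(a), idx1, drop = FALSE)) +
       do.call(`[`, c(list(a), idx2, drop = FALSE))) / 2
  }
  ex2 <- avg2(avg2(Mod(solution$ex)^2, 2), 3)
  ey2 <- avg2(avg2(Mod(solution$ey)^2, 1), 3)
  ez2 <- avg2(avg2(Mod(solution$ez)^2, 1), 2)
  emag <- sqrt(ex2 + ey2 + ez2)
  if (is.null(index)) index <- ceiling(nd[normal] / 2)
  sl <- switch(normal, emag[index, , ], emag[, index, ], emag[, , index])
  db <- 20 * log10(pmax(sl, 1e-300) / max(emag))
  attr(db, "h") <- domain$h
  db
}
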