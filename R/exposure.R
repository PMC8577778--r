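# The far-field exposure protocol: 12 standard plane waves, frequency
# sweeps, random orientations, per-body-part absorbed power, quadratic
# field rescaling, group comparison (Kolmogorov-Smirnov) and
# sensitivity experiments.

#' The twelve standard exposure plane waves
#'
#' Six propagation directions along the Cartesian axes, two orthogonal
#' polarizations each. Ordering convention: directions
#' (+x, -x, +y, -y, +z, -z), and for each direction the polarizations
#' along the remaining axes in axis order; wave ids 1--12.
#'
#' @param f frequency, Hz.
#' @param e_rms incident RMS field strength, V/m.
#' @return List of 12 [plane_wave()] objects.
#' @export
standard_12_waves <- function(f, e_rms = 1) {
  axes <- diag(3)
  out <- list()
  for (d in 1:3) for (s in c(1, -1)) {
    k <- s * axes[, d]
    pol_axes <- setdiff(1:3, d)
    for (p in pol_axes)
      out[[length(out) + 1L]] <- plane_wave(k, axes[, p], f, e_rms)
  }
  out
}

#' Random incidence/polarization plane waves
#'
#' Propagation directions uniform on the sphere; polarization angle
#' uniform in the plane orthogonal to each direction. Reproducible
#' under `seed`.
#'
#' @param n number of waves (>= 1).
#' @param seed integer seed.
#' @param f frequency, Hz.
#' @param e_rms RMS field strength, V/m.
#' @return List of `n` [plane_wave()] objects.
#' @export
random_waves <- function(n, seed, f, e_rms = 1) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      z <- runif(1, -1, 1)
      phi <- runif(1, 0, 2 * pi)
      k <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
      ref <- if (abs(k[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- c(k[2] * ref[3] - k[3] * ref[2],
             k[3] * ref[1] - k[1] * ref[3],
             k[1] * ref[2] - k[2] * ref[1])
      u <- u / sqrt(sum(u^2))
      v <- c(k[2] * u[3] - k[3] * u[2],
             k[3] * u[1] - k[1] * u[3],
             k[1] * u[2] - k[2] * u[1])
      psi <- runif(1, 0, 2 * pi)
      plane_wave(k, cos(psi) * u + sin(psi) * v, f, e_rms)
    })
  })
}

#' Rescale absorbed power to another incident field strength
#'
#' Absorbed power scales quadratically with the incident field:
#' \eqn{P_{abs}(E) = P_{abs}(1\,V/m) \cdot E^2}.
#'
#' @param p_at_1Vpm absorbed power at 1 V/m, W.
#' @param e_real incident RMS field strength, V/m.
#' @return Absorbed power, W.
#' @examples
#' scale_pabs(2.37e-9, 61.5)  # at the 2 GHz general-public reference level
#' @export
scale_pabs <- function(p_at_1Vpm, e_real) {
  stopifnot(all(p_at_1Vpm >= 0), all(e_real >= 0))
  p_at_1Vpm * e_real^2
}

#' Far-field (Fraunhofer) distance bound
#'
#' The far-field condition is \eqn{r \gg 2 l^2/\lambda}; this returns
#' \eqn{2 l^2/\lambda} for the largest dimension `l`.
#'
#' @param l largest dimension of source or body, metres (>= 0).
#' @param f frequency, Hz.
#' @return Distance in metres.
#' @export
far_field_min_distance <- function(l, f) {
  stopifnot(l >= 0, f > 0)
  2 * l^2 / (rf_constants$c0 / f)
}

#' Exposure protocol configuration
#'
#' @param frequencies_ghz frequencies to simulate.
#' @param waves `"standard12"` or `"random"`.
#' @param n_waves,seed random-wave count and seed (ignored for the
#'   standard set).
#' @param e_rms incident RMS field strength, V/m.
#' @param voxel_um voxel pitch in micrometres. When the model is given
#'   as a [phantom_spec()], the pitch used at each frequency is
#'   `min(voxel_um, lambda_medium/10)` and the phantom is rebuilt on
#'   that grid, mirroring per-frequency regridding.
#' @param parts body-part labels reported separately.
#' @param pml,gap_cells,averaging,conv_tol,max_periods,dft_periods
#'   forwarded to [simulation_domain()] / [run_fdtd()].
#' @return A list of class `exposure_config`.
#' @export
exposure_config <- function(frequencies_ghz = c(2, 6, 12, 24, 60, 90, 120, 240),
                            waves = c("standard12", "random"),
                            n_waves = 30L, seed = 1L, e_rms = 1,
                            voxel_um = 25,
                            parts = c("head", "thorax", "abdomen", "legs"),
                            pml = list(cells = 10L, order = 3, r0 = 1e-6,
                                       alpha = 0.05),
                            gap_cells = 6L,
                            averaging = "edge",
                            conv_tol = 1e-3, max_periods = 80L,
                            dft_periods = 2L) {
  waves <- match.arg(waves)
  stopifnot(all(frequencies_ghz > 0), e_rms > 0, voxel_um > 0)
  structure(list(frequencies_ghz = frequencies_ghz, waves = waves,
                 n_waves = as.integer(n_waves), seed = as.integer(seed),
                 e_rms = e_rms, voxel_um = voxel_um, parts = parts,
                 pml = pml, gap_cells = gap_cells, averaging = averaging,
                 conv_tol = conv_tol, max_periods = as.integer(max_periods),
                 dft_periods = as.integer(dft_periods)),
            class = "exposure_config")
}

#' Read an exposure configuration from a YAML key/value file
#'
#' Recognized keys mirror the [exposure_config()] arguments:
#' `frequencies_ghz`, `waves`, `n_waves`, `seed`, `e_rms`, `voxel_um`,
#' `parts`, `gap_cells`, `conv_tol`, `max_periods`, `dft_periods`, and
#' nested `pml:` (`cells`, `order`, `r0`, `alpha`). Unknown keys are an
#' error (they are usually typos that would silently change a run).
#'
#' @param path YAML file path.
#' @return An [exposure_config()].
#' @export
config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  known <- names(formals(exposure_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(exposure_config, raw)
}

.dielectric_at <- function(dielectric, f) {
  if (inherits(dielectric, "debye_params"))
    dielectric <- list(eps = dielectric, sigma = dielectric)
  stopifnot(is.list(dielectric), inherits(dielectric$eps, "debye_params"),
            inherits(dielectric$sigma, "debye_params"))
  cv <- debye_curve(dielectric$eps, dielectric$sigma, f)
  list(eps_real = cv$eps_real[1], sigma = cv$sigma_s_per_m[1])
}

#' Run the far-field exposure protocol
#'
#' For each frequency: evaluate the dielectric rows, build the
#' simulation domain (grid rule and period rule applied), run every
#' plane wave, and record whole-body and per-part absorbed power.
#' Deterministic given the configuration (random waves are seeded).
#'
#' @param model a labeled [voxel_model()], a [phantom_spec()] (rebuilt
#'   per frequency at the pitch the grid rule allows), or the list
#'   returned by [make_phantom()].
#' @param dielectric a [debye_params()] or a list with elements `eps`
#'   and `sigma` (the two-row convention, default [aedes_debye()]).
#' @param config an [exposure_config()].
#' @param model_id identifier recorded in the result table.
#' @return An `exposure_result`: a data frame with columns `model`,
#'   `frequency_hz`, `wave_id`, `part` (`"whole"` plus each labeled
#'   part), `pabs_w` and `volume_m3`, with the configuration attached
#'   as attribute `config`.
#' @export
run_protocol <- function(model, dielectric = aedes_debye("pair"),
                         config = exposure_config(), model_id = "model1") {
  stopifnot(inherits(config, "exposure_config"))
  if (is.list(model) && !is.null(model$model) &&
      inherits(model$model, "voxel_model")) model <- model$model
  is_spec <- inherits(model, "phantom_spec")
  if (!is_spec) stopifnot(inherits(model, "voxel_model"))
  rows <- list()
  for (fg in config$frequencies_ghz) {
    f <- fg * 1e9
    dl <- .dielectric_at(dielectric, f)
    lam10 <- wavelength_in_medium(f, max(dl$eps_real, 1)) / 10
    if (is_spec) {
      h_f <- min(config$voxel_um * 1e-6, lam10)
      mdl <- make_phantom(model, h = h_f)$model
    } else {
      mdl <- model
      if (mdl$spacing > lam10 * (1 + 1e-9))
        stop(sprintf(paste0("grid rule violated at %.3g GHz: model pitch ",
                            "%.3g um > lambda_medium/10 = %.3g um"),
                     fg, mdl$spacing * 1e6, lam10 * 1e6))
    }
    dom <- simulation_domain(mdl, dl$eps_real, dl$sigma, pml = config$pml,
                             gap_cells = config$gap_cells,
                             averaging = config$averaging)
    waves <- if (config$waves == "standard12")
      standard_12_waves(f, config$e_rms)
    else random_waves(config$n_waves, config$seed, f, config$e_rms)
    part_ids <- if (!is.null(mdl$labels))
      intersect(config$parts, names(.part_legend)[
        .part_legend %in% unique(as.vector(mdl$labels))])
    else character()
    vol_whole <- sum(mdl$occupancy) * mdl$spacing^3
    for (w in seq_along(waves)) {
      sol <- tryCatch(
        run_fdtd(dom, waves[[w]], conv_tol = config$conv_tol,
                 max_periods = config$max_periods,
                 dft_periods = config$dft_periods),
        error = function(e)
          stop(sprintf("solver failure at %g GHz, wave %d: %s",
                       fg, w, conditionMessage(e)), call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        model = model_id, frequency_hz = f, wave_id = w, part = "whole",
        pabs_w = sol$pabs, volume_m3 = vol_whole)
      for (p in part_ids) {
        occp <- mdl$labels == .part_legend[[p]]
        rows[[length(rows) + 1L]] <- data.frame(
          model = model_id, frequency_hz = f, wave_id = w, part = p,
          pabs_w = compute_pabs(sol, dom, region = p),
          volume_m3 = sum(occp) * mdl$spacing^3)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("exposure_result", "data.frame")
  out
}

#' Two-sample Kolmogorov--Smirnov comparison
#'
#' The statistic is computed directly from the empirical CDFs
#' (\eqn{D = \sup_x |F_1(x) - F_2(x)|}); the p-value uses the
#' asymptotic Kolmogorov distribution with the usual finite-sample
#' effective size.
#'
#' @param x,y numeric samples.
#' @return List with `statistic` and `p_value`.
#' @export
ks_statistic <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  pts <- sort(unique(c(x, y)))
  d <- max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
  n <- length(x) * length(y) / (length(x) + length(y))
  lam <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  list(statistic = d, p_value = min(max(p, 0), 1))
}

#' Aggregate exposure results across models and groups
#'
#' Per-model and per-group mean/min/max absorbed power by frequency,
#' frequency-pair ratios of the grand mean (over all models and waves),
#' and a two-sample Kolmogorov--Smirnov comparison between two groups
#' on the pooled per-wave whole-body values.
#'
#' @param results an `exposure_result` or list of them (rbind-ed).
#' @param groups optional named list mapping group name to model ids.
#' @return List with `per_model` (data frame), `per_group` (or `NULL`),
#'   `ratio` (function of two frequencies in Hz), and `ks` (or `NULL`;
#'   present when `groups` has exactly two entries).
#' @export
aggregate_exposure <- function(results, groups = NULL) {
  if (is.list(results) && !inherits(results, "data.frame"))
    results <- do.call(rbind, results)
  stopifnot(nrow(results) >= 1)
  whole <- results[results$part == "whole", ]
  per_model <- do.call(rbind, lapply(
    split(whole, list(whole$model, whole$frequency_hz), drop = TRUE),
    function(d) data.frame(model = d$model[1], frequency_hz = d$frequency_hz[1],
                           mean_w = mean(d$pabs_w), min_w = min(d$pabs_w),
                           max_w = max(d$pabs_w), n = nrow(d))))
  rownames(per_model) <- NULL
  per_group <- NULL; ks <- NULL
  if (!is.null(groups)) {
    if (any(lengths(groups) < 1)) stop("every group needs at least one model")
    gm <- lapply(names(groups), function(g) {
      d <- whole[whole$model %in% groups[[g]], ]
      do.call(rbind, lapply(split(d, d$frequency_hz), function(s)
        data.frame(group = g, frequency_hz = s$frequency_hz[1],
                   mean_w = mean(s$pabs_w), min_w = min(s$pabs_w),
                   max_w = max(s$pabs_w), n = nrow(s))))
    })
    per_group <- do.call(rbind, gm); rownames(per_group) <- NULL
    if (length(groups) == 2) {
      a <- whole$pabs_w[whole$model %in% groups[[1]]]
      b <- whole$pabs_w[whole$model %in% groups[[2]]]
      ks <- ks_statistic(a, b)
    }
  }
  ratio <- function(f_num, f_den) {
    num <- whole$pabs_w[whole$frequency_hz == f_num]
    den <- whole$pabs_w[whole$frequency_hz == f_den]
    if (!length(num) || !length(den))
      stop("no results at one of the requested frequencies")
    mean(num) / mean(den)
  }
  list(per_model = per_model, per_group = per_group, ratio = ratio, ks = ks)
}

#' Sensitivity experiments around a protocol run
#'
#' Re-runs the protocol under dielectric perturbations
#' (\eqn{\epsilon' \pm 4.04\%}, \eqn{\sigma \pm 5.81\%}, the measured
#' inter-sample deviations), under a refined grid, and with the legs
#' removed, reporting the maximal relative deviation of whole-body
#' absorbed power for each perturbation.
#'
#' @param model,dielectric,config as in [run_protocol()].
#' @param experiments subset of
#'   `c("dielectric", "grid", "legs")`.
#' @param eps_rel,sigma_rel dielectric perturbation magnitudes.
#' @param refined_voxel_um grid pitch for the refinement experiment.
#' @return A list with the baseline `exposure_result` and, per
#'   experiment, the perturbed results and `max_rel_dev` (plus
#'   `mean_ratio` for the leg experiment).
#' @export
sensitivity_suite <- function(model, dielectric = aedes_debye("pair"),
                              config = exposure_config(),
                              experiments = c("dielectric", "grid", "legs"),
                              eps_rel = 0.0404, sigma_rel = 0.0581,
                              refined_voxel_um = 15) {
  experiments <- match.arg(experiments, several.ok = TRUE)
  base <- run_protocol(model, dielectric, config)
  bw <- base$pabs_w[base$part == "whole"]
  out <- list(baseline = base)
  pair <- if (inherits(dielectric, "debye_params"))
    list(eps = dielectric, sigma = dielectric) else dielectric

  if ("dielectric" %in% experiments) {
    # scaling every term of a row scales the whole curve by that factor
    scale_row <- function(p, fac)
      debye_params(p$eps_inf * fac, p$delta_eps * fac, p$tau,
                   p$sigma_s * fac)
    devs <- c()
    runs <- list()
    for (se in c(1 + eps_rel, 1 - eps_rel)) {
      d2 <- list(eps = scale_row(pair$eps, se), sigma = pair$sigma)
      r <- run_protocol(model, d2, config)
      runs[[sprintf("eps_%+.2f%%", (se - 1) * 100)]] <- r
      devs <- c(devs, max(abs(r$pabs_w[r$part == "whole"] / bw - 1)))
    }
    for (ss in c(1 + sigma_rel, 1 - sigma_rel)) {
      d2 <- list(eps = pair$eps, sigma = scale_row(pair$sigma, ss))
      r <- run_protocol(model, d2, config)
      runs[[sprintf("sigma_%+.2f%%", (ss - 1) * 100)]] <- r
      devs <- c(devs, max(abs(r$pabs_w[r$part == "whole"] / bw - 1)))
    }
    out$dielectric <- list(runs = runs, max_rel_dev = max(devs))
  }
  if ("grid" %in% experiments) {
    cfg2 <- config; cfg2$voxel_um <- refined_voxel_um
    if (!inherits(model, "phantom_spec"))
      stop("grid-refinement experiment needs a phantom_spec model")
    r <- run_protocol(model, dielectric, cfg2)
    common <- intersect(unique(base$frequency_hz), unique(r$frequency_hz))
    b2 <- base[base$part == "whole" & base$frequency_hz %in% common, ]
    r2 <- r[r$part == "whole" & r$frequency_hz %in% common, ]
    out$grid <- list(result = r,
                     max_rel_dev = max(abs(r2$pabs_w / b2$pabs_w - 1)))
  }
  if ("legs" %in% experiments) {
    if (inherits(model, "phantom_spec")) {
      spec2 <- model; spec2$n_legs <- 0L
      # keep the trunk identical: subtract the leg volume from the target
      spec2$total_volume <- model$total_volume -
        model$n_legs * pi * model$leg_radius^2 * model$leg_length
      r <- run_protocol(spec2, dielectric, config)
    } else {
      r <- run_protocol(remove_parts(model, "legs"), dielectric, config)
    }
    rw <- r$pabs_w[r$part == "whole"]
    out$legs <- list(result = r, max_rel_dev = max(abs(rw / bw - 1)),
                     mean_ratio = mean(rw) / mean(bw))
  }
  out
}
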