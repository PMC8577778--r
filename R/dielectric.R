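# Debye dielectric model with static conduction: evaluation, unit
# conversions, measurement grid, and the built-in Aedes aegypti
# homogenate parameter sets.

#' Construct a Debye parameter set
#'
#' A multi-relaxation Debye model of a conductive dielectric:
#' \deqn{\epsilon'(\omega) = \epsilon_\infty +
#'   \sum_i \frac{\Delta\epsilon_i}{1 + (\omega\tau_i)^2}}
#' \deqn{\epsilon''(\omega) = \frac{\sigma_s}{\omega\epsilon_0} +
#'   \sum_i \frac{\Delta\epsilon_i\,\omega\tau_i}{1 + (\omega\tau_i)^2}}
#' with conductivity \eqn{\sigma(\omega) = \epsilon''\,\omega\epsilon_0}.
#'
#' @param eps_inf relative permittivity at infinite frequency (> 0).
#' @param delta_eps numeric vector of relaxation strengths
#'   \eqn{\Delta\epsilon_i} (each >= 0).
#' @param tau numeric vector of relaxation times in seconds (each > 0),
#'   same length as `delta_eps`. Relaxations are stored sorted by
#'   descending `tau`.
#' @param sigma_s static conductivity in S/m (>= 0).
#' @return An object of class `debye_params`.
#' @examples
#' dp <- debye_params(eps_inf = 4.544,
#'                    delta_eps = c(4.978, 13.24),
#'                    tau = c(3.493e-12, 14.68e-12))
#' evaluate_debye(dp, 240e9)
#' @export
debye_params <- function(eps_inf, delta_eps = numeric(), tau = numeric(),
                         sigma_s = 0) {
  stopifnot(is.numeric(eps_inf), length(eps_inf) == 1L, is.finite(eps_inf),
            is.numeric(delta_eps), is.numeric(tau),
            length(delta_eps) == length(tau),
            is.numeric(sigma_s), length(sigma_s) == 1L)
  if (eps_inf <= 0) stop("eps_inf must be > 0")
  if (any(delta_eps < 0)) stop("all delta_eps must be >= 0")
  if (any(tau <= 0)) stop("all tau must be > 0")
  if (sigma_s < 0) stop("sigma_s must be >= 0")
  ord <- order(tau, decreasing = TRUE)
  structure(list(eps_inf = eps_inf,
                 delta_eps = as.numeric(delta_eps[ord]),
                 tau = as.numeric(tau[ord]),
                 sigma_s = as.numeric(sigma_s)),
            class = "debye_params")
}

#' @export
print.debye_params <- function(x, ...) {
  cat("Debye parameters (", length(x$tau), " relaxation",
      if (length(x$tau) != 1L) "s", ")\n", sep = "")
  cat("  eps_inf =", format(x$eps_inf), "\n")
  for (i in seq_along(x$tau))
    cat(sprintf("  relaxation %d: delta_eps = %g, tau = %g ps\n",
                i, x$delta_eps[i], x$tau[i] * 1e12))
  cat("  sigma_s =", format(x$sigma_s), "S/m\n")
  invisible(x)
}

#' Built-in dielectric parameter sets for *Aedes aegypti* homogenate
#'
#' Two-relaxation Debye parameter sets fitted to coaxial-probe
#' (5--67 GHz) dielectric spectroscopy of homogenized *Aedes aegypti*
#' at 22 degrees C. The real-part row (`"eps"`) and the conductivity row
#' (`"sigma"`) were fitted separately to \eqn{\epsilon'} and
#' \eqn{\sigma}; the pipeline evaluates each quantity from its own row.
#' The conductivity row carries no \eqn{\epsilon_\infty} (the loss model
#' does not use one); it is stored as `eps_inf = 1` and never read for
#' \eqn{\epsilon''} or \eqn{\sigma}.
#'
#' @param which `"eps"` for the real-part fit, `"sigma"` for the
#'   conductivity fit, or `"pair"` for a two-element list with both.
#' @return A `debye_params` object, or a named list of two for
#'   `which = "pair"`.
#' @examples
#' aedes_debye("eps")
#' evaluate_debye(aedes_debye("sigma"), 9.4e9)["sigma"]
#' @export
aedes_debye <- function(which = c("eps", "sigma", "pair")) {
  which <- match.arg(which)
  eps <- debye_params(eps_inf = 4.544,
                      delta_eps = c(4.978, 13.24),
                      tau = c(3.493e-12, 14.68e-12),
                      sigma_s = 0)
  sig <- debye_params(eps_inf = 1,
                      delta_eps = c(4.213, 12.89),
                      tau = c(2.477e-12, 12.23e-12),
                      sigma_s = 1.297)
  switch(which, eps = eps, sigma = sig, pair = list(eps = eps, sigma = sig))
}

#' @rdname aedes_debye
#' @export
aedes_fit2_eps <- function() aedes_debye("eps")

#' @rdname aedes_debye
#' @export
aedes_fit2_sigma <- function() aedes_debye("sigma")

#' Evaluate a Debye model at given frequencies
#'
#' @param params a [debye_params()] object.
#' @param f frequency in Hz (vectorized, all > 0).
#' @return For scalar `f`, a named numeric vector
#'   `c(eps_real, eps_imag, sigma)`; for vector `f`, a data frame with
#'   columns `frequency_hz`, `eps_real`, `eps_imag`, `sigma_s_per_m`.
#' @examples
#' evaluate_debye(aedes_debye("eps"), 240e9)
#' @export
evaluate_debye <- function(params, f) {
  stopifnot(inherits(params, "debye_params"), is.numeric(f))
  if (any(f <= 0)) stop("frequency must be > 0")
  w <- 2 * pi * f
  er <- rep(params$eps_inf, length(f))
  ei <- params$sigma_s / (w * rf_constants$eps0)
  for (i in seq_along(params$tau)) {
    wt <- w * params$tau[i]
    er <- er + params$delta_eps[i] / (1 + wt^2)
    ei <- ei + params$delta_eps[i] * wt / (1 + wt^2)
  }
  sig <- ei * w * rf_constants$eps0
  if (length(f) == 1L)
    c(eps_real = er, eps_imag = ei, sigma = sig)
  else
    data.frame(frequency_hz = f, eps_real = er, eps_imag = ei,
               sigma_s_per_m = sig)
}

#' Convert between loss factor and conductivity
#'
#' \eqn{\sigma = \epsilon''\,2\pi f\,\epsilon_0} and its inverse.
#'
#' @param eps_imag dielectric loss factor \eqn{\epsilon''} (dimensionless).
#' @param sigma conductivity in S/m.
#' @param f frequency in Hz (> 0).
#' @return Conductivity in S/m (`loss_to_conductivity`) or loss factor
#'   (`conductivity_to_loss`).
#' @examples
#' loss_to_conductivity(12, 60e9)
#' conductivity_to_loss(loss_to_conductivity(12, 60e9), 60e9)
#' @export
loss_to_conductivity <- function(eps_imag, f) {
  if (any(f <= 0)) stop("frequency must be > 0")
  eps_imag * 2 * pi * f * rf_constants$eps0
}

#' @rdname loss_to_conductivity
#' @export
conductivity_to_loss <- function(sigma, f) {
  if (any(f <= 0)) stop("frequency must be > 0")
  sigma / (2 * pi * f * rf_constants$eps0)
}

#' Wavelength inside a dielectric medium
#'
#' \eqn{\lambda = c / (f \sqrt{\epsilon'})}. The loss contribution to the
#' phase constant is neglected, matching the usual grid-sizing rule.
#'
#' @param f frequency in Hz (> 0).
#' @param eps_real real relative permittivity (> 0).
#' @return Wavelength in metres.
#' @examples
#' wavelength_in_medium(240e9, evaluate_debye(aedes_debye("eps"), 240e9)[["eps_real"]])
#' @export
wavelength_in_medium <- function(f, eps_real) {
  if (any(f <= 0)) stop("frequency must be > 0")
  if (any(eps_real <= 0)) stop("eps_real must be > 0")
  rf_constants$c0 / (f * sqrt(eps_real))
}

#' Coaxial-probe measurement frequency grid
#'
#' The 5--67 GHz open-coaxial-probe grid used for the dielectric
#' spectra: 50 MHz steps on 5--6 GHz inclusive, then 250 MHz steps from
#' 6.25 to 67 GHz (265 points in total).
#'
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @examples
#' length(dak_tl_grid())
#' @export
dak_tl_grid <- function() {
  c(seq(5e9, 6e9, by = 50e6), seq(6.25e9, 67e9, by = 250e6))
}

#' Construct a permittivity spectrum
#'
#' Frequency-sampled relative permittivity and conductivity, as measured
#' by dielectric spectroscopy or generated synthetically.
#'
#' @param frequencies Hz, strictly increasing, all > 0.
#' @param eps_real real relative permittivity per frequency (> 0).
#' @param sigma conductivity in S/m per frequency (>= 0).
#' @param temperature sample temperature in degrees C (default 22).
#' @param provenance one of `"measured"`, `"synthetic"`, `"extrapolated"`.
#' @return An object of class `permittivity_spectrum` (also a data frame
#'   with columns `frequency_hz`, `eps_real`, `sigma_s_per_m`).
#' @export
permittivity_spectrum <- function(frequencies, eps_real, sigma,
                                  temperature = 22,
                                  provenance = c("measured", "synthetic",
                                                 "extrapolated")) {
  provenance <- match.arg(provenance)
  stopifnot(length(frequencies) == length(eps_real),
            length(frequencies) == length(sigma))
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  if (any(eps_real <= 0)) stop("eps_real must be > 0")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  structure(data.frame(frequency_hz = as.numeric(frequencies),
                       eps_real = as.numeric(eps_real),
                       sigma_s_per_m = as.numeric(sigma)),
            temperature_c = temperature, provenance = provenance,
            class = c("permittivity_spectrum", "data.frame"))
}

#' Read / write a permittivity spectrum CSV
#'
#' The CSV carries a header `frequency_hz, eps_real, sigma_s_per_m` and
#' optionally a leading comment line `# temperature_c: <value>`.
#'
#' @param path file path.
#' @param spectrum a [permittivity_spectrum()].
#' @return `read_spectrum_csv` returns a `permittivity_spectrum`;
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  temp <- 22
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("temperature_c:\\s*([0-9.+-eE]+)", first))[[1]]
    if (length(m) == 2L) temp <- as.numeric(m[2])
  }
  d <- read.csv(path, comment.char = "#")
  need <- c("frequency_hz", "eps_real", "sigma_s_per_m")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("spectrum CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  permittivity_spectrum(d$frequency_hz, d$eps_real, d$sigma_s_per_m,
                        temperature = temp, provenance = "measured")
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_c: %g", attr(spectrum, "temperature_c")),
             con)
  write.csv(as.data.frame(unclass(spectrum))[
    , c("frequency_hz", "eps_real", "sigma_s_per_m")],
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
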