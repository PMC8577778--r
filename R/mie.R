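# Mie series for a homogeneous lossy sphere in a plane wave.
# Serves as the closed-form absorption oracle against which the FDTD
# solver is validated; implemented from the standard recurrences
# (logarithmic-derivative downward recursion, Riccati-Bessel upward).

#' Mie efficiencies of a homogeneous sphere
#'
#' Extinction, scattering and absorption efficiencies of a homogeneous
#' sphere with complex relative permittivity
#' \eqn{\hat\epsilon = \epsilon' - j\,\sigma/(\omega\epsilon_0)} in
#' vacuum. The series is truncated at the usual size-parameter rule
#' \eqn{N = x + 4x^{1/3} + 2} and the truncation is verified converged
#' (extending the order changes the result by < 1e-10 relative).
#'
#' @param radius sphere radius in metres (> 0).
#' @param eps_real real relative permittivity.
#' @param sigma conductivity, S/m.
#' @param f frequency, Hz (> 0).
#' @return Named list with `q_ext`, `q_sca`, `q_abs`, `x` (size
#'   parameter) and `n_terms`.
#' @export
mie_efficiencies <- function(radius, eps_real, sigma, f) {
  if (radius <= 0 || f <= 0) stop("radius and frequency must be > 0")
  w <- 2 * pi * f
  lambda0 <- rf_constants$c0 / f
  x <- 2 * pi * radius / lambda0
  eps_hat <- complex(real = eps_real, imaginary = sigma / (w * rf_constants$eps0))
  m <- sqrt(eps_hat)                      # exp(-i w t) convention, Im(m) >= 0

  n_stop <- ceiling(x + 4 * x^(1 / 3) + 2)
  compute <- function(nmax) {
    mx <- m * x
    nmx <- max(nmax, ceiling(Mod(mx))) + 16L
    d <- complex(length.out = nmx)
    for (n in seq(nmx - 1L, 1L)) {
      rn <- (n + 1) / mx
      d[n] <- rn - 1 / (d[n + 1] + rn)
    }
    psi_m1 <- cos(x); psi0 <- sin(x)
    chi_m1 <- -sin(x); chi0 <- cos(x)
    qe <- 0; qs <- 0
    psi_nm1 <- psi0; chi_nm1 <- chi0
    psi_prev <- psi_m1; chi_prev <- chi_m1
    for (n in seq_len(nmax)) {
      psi <- (2 * n - 1) / x * psi_nm1 - psi_prev
      chi <- (2 * n - 1) / x * chi_nm1 - chi_prev
      xi <- complex(real = psi, imaginary = -chi)
      xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
      da <- d[n] / m + n / x
      db <- d[n] * m + n / x
      a_n <- (da * psi - psi_nm1) / (da * xi - xi_nm1)
      b_n <- (db * psi - psi_nm1) / (db * xi - xi_nm1)
      qe <- qe + (2 * n + 1) * Re(a_n + b_n)
      qs <- qs + (2 * n + 1) * (Mod(a_n)^2 + Mod(b_n)^2)
      psi_prev <- psi_nm1; chi_prev <- chi_nm1
      psi_nm1 <- psi; chi_nm1 <- chi
    }
    c(q_ext = 2 / x^2 * qe, q_sca = 2 / x^2 * qs)
  }
  q1 <- compute(n_stop)
  q2 <- compute(n_stop + 8L)
  if (any(abs(q2 - q1) > 1e-10 * pmax(abs(q2), 1e-300)))
    stop("Mie series not converged at truncation order ", n_stop)
  list(q_ext = unname(q2["q_ext"]), q_sca = unname(q2["q_sca"]),
       q_abs = unname(q2["q_ext"] - q2["q_sca"]), x = x,
       n_terms = n_stop + 8L)
}

#' Plane-wave power absorbed by a homogeneous lossy sphere (Mie)
#'
#' Absorption efficiency from the Mie series times the geometric cross
#' section \eqn{\pi r^2} times the incident power density
#' \eqn{E_{rms}^2/\eta_0}.
#'
#' @inheritParams mie_efficiencies
#' @param e_rms incident RMS electric field strength, V/m.
#' @return Absorbed power in watts.
#' @examples
#' d <- debye_curve(aedes_debye("eps"), aedes_debye("sigma"), 60e9)
#' mie_absorbed_power(0.5e-3, d$eps_real, d$sigma_s_per_m, 60e9)
#' @export
mie_absorbed_power <- function(radius, eps_real, sigma, f, e_rms = 1) {
  q <- mie_efficiencies(radius, eps_real, sigma, f)
  q$q_abs * pi * radius^2 * e_rms^2 / rf_constants$eta0
}

#' Quasi-static (Rayleigh) absorbed power of a small lossy sphere
#'
#' Closed form for \eqn{r \ll \lambda}: the internal field of a sphere in
#' a uniform field is \eqn{3/(\hat\epsilon + 2)} times the applied field,
#' so \eqn{P = \sigma\,|3/(\hat\epsilon+2)|^2 E_{rms}^2\,(4\pi r^3/3)}.
#'
#' @inheritParams mie_absorbed_power
#' @return Absorbed power in watts.
#' @export
rayleigh_absorbed_power <- function(radius, eps_real, sigma, f, e_rms = 1) {
  w <- 2 * pi * f
  eps_hat <- complex(real = eps_real,
                     imaginary = -sigma / (w * rf_constants$eps0))
  sigma * Mod(3 / (eps_hat + 2))^2 * e_rms^2 * 4 / 3 * pi * radius^3
}
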