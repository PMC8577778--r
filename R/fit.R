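# Bounded Levenberg-Marquardt fitting of Debye models to measured
# permittivity spectra, with a deterministic multi-start over
# log-spaced relaxation times to avoid label swapping between the
# relaxations.

.tau_lower <- 0.1e-12
.tau_upper <- 100e-12

# deterministic multi-start tau grids (seconds)
.tau_starts <- function(n_relaxations) {
  g <- c(0.5e-12, 2e-12, 8e-12, 30e-12)
  if (n_relaxations == 1L) {
    lapply(g, identity)
  } else {
    out <- list()
    for (i in seq_along(g)) for (j in seq_along(g))
      if (g[j] > g[i]) out[[length(out) + 1L]] <- c(g[i], g[j])
    out
  }
}

.eps_model <- function(p, f, n) {
  # p = (eps_inf, delta_eps[1..n], tau[1..n])
  w <- 2 * pi * f
  er <- rep(p[1], length(f))
  for (i in seq_len(n)) {
    wt <- w * p[1 + n + i]
    er <- er + p[1 + i] / (1 + wt^2)
  }
  er
}

.sigma_model <- function(p, f, n) {
  # p = (sigma_s, delta_eps[1..n], tau[1..n])
  w <- 2 * pi * f
  ei <- p[1] / (w * rf_constants$eps0)
  for (i in seq_len(n)) {
    wt <- w * p[1 + n + i]
    ei <- ei + p[1 + i] * wt / (1 + wt^2)
  }
  ei * w * rf_constants$eps0
}

.r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

.lm_multistart <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("Debye fit failed: no start converged")
  best
}

#' Fit a Debye model to a permittivity spectrum
#'
#' Bounded nonlinear least squares (Levenberg--Marquardt) with
#' relative (scale-free) residuals and a deterministic multi-start over
#' log-spaced relaxation times (\eqn{\tau \in [0.1, 100]} ps,
#' \eqn{\Delta\epsilon \ge 0}, \eqn{\sigma_s \ge 0}).
#'
#' In `mode = "separate"` (the default) the real part \eqn{\epsilon'} and
#' the conductivity \eqn{\sigma} are fitted independently, yielding one
#' parameter row per quantity; in `mode = "joint"` a single parameter set
#' minimizes the pooled relative residual of both quantities.
#'
#' @param spectrum a [permittivity_spectrum()].
#' @param n_relaxations 1 or 2.
#' @param mode `"separate"` or `"joint"`.
#' @return An object of class `debye_fit` with elements `params_eps`,
#'   `params_sigma` ([debye_params()]; identical in joint mode),
#'   `r_squared_eps`, `r_squared_sigma`, `residuals` (list with `eps`
#'   and `sigma` relative residuals), `n_relaxations`, and `mode`.
#' @examples
#' truth <- aedes_debye("pair")
#' sp <- synth_spectrum(truth$eps, params_sigma = truth$sigma)
#' fit <- fit_debye(sp, 2)
#' fit$r_squared_eps
#' @export
fit_debye <- function(spectrum, n_relaxations = 2,
                      mode = c("separate", "joint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "permittivity_spectrum"),
            n_relaxations %in% c(1L, 2L))
  n <- as.integer(n_relaxations)
  f <- spectrum$frequency_hz
  er <- spectrum$eps_real
  sg <- spectrum$sigma_s_per_m
  n_free <- if (mode == "joint") 2L + 2L * n else 1L + 2L * n
  if (length(f) < 3L * n_free)
    stop("Debye fit failed: spectrum has ", length(f),
         " points, need at least ", 3L * n_free)
  if (sd(er) / mean(er) < 1e-12 && sd(sg) / max(mean(sg), 1e-30) < 1e-12)
    stop("Debye fit failed: degenerate (constant) spectrum")

  d_tot <- max(max(er) - min(er), 1e-3)
  lower_e <- c(0.1, rep(0, n), rep(.tau_lower, n))
  upper_e <- c(Inf, rep(Inf, n), rep(.tau_upper, n))
  lower_s <- c(0, rep(0, n), rep(.tau_lower, n))
  upper_s <- c(Inf, rep(Inf, n), rep(.tau_upper, n))

  if (mode == "separate") {
    starts_e <- lapply(.tau_starts(n), function(tt)
      c(max(min(er), 0.2), rep(d_tot / n, n), tt))
    fe <- .lm_multistart(function(p) .eps_model(p, f, n) / er - 1,
                         starts_e, lower_e, upper_e)
    starts_s <- lapply(.tau_starts(n), function(tt)
      c(0.5 * min(sg), rep(10 / n, n), tt))
    fs <- .lm_multistart(function(p) .sigma_model(p, f, n) / pmax(sg, 1e-30) - 1,
                         starts_s, lower_s, upper_s)
    pe <- fe$par; ps <- fs$par
    params_eps <- debye_params(pe[1], pe[2:(1 + n)], pe[(2 + n):(1 + 2 * n)],
                               sigma_s = 0)
    params_sigma <- debye_params(1, ps[2:(1 + n)], ps[(2 + n):(1 + 2 * n)],
                                 sigma_s = ps[1])
    pred_e <- .eps_model(pe, f, n)
    pred_s <- .sigma_model(ps, f, n)
  } else {
    # p = (eps_inf, sigma_s, delta_eps[1..n], tau[1..n])
    joint_resid <- function(p) {
      pe <- c(p[1], p[3:(2 + n)], p[(3 + n):(2 + 2 * n)])
      ps <- c(p[2], p[3:(2 + n)], p[(3 + n):(2 + 2 * n)])
      c(.eps_model(pe, f, n) / er - 1,
        .sigma_model(ps, f, n) / pmax(sg, 1e-30) - 1)
    }
    starts <- lapply(.tau_starts(n), function(tt)
      c(max(min(er), 0.2), 0.5 * min(sg), rep(d_tot / n, n), tt))
    fj <- .lm_multistart(joint_resid,
                         c(0.1, 0, rep(0, n), rep(.tau_lower, n)),
                         upper = c(Inf, Inf, rep(Inf, n), rep(.tau_upper, n)),
                         starts = starts)
    p <- fj$par
    params_eps <- debye_params(p[1], p[3:(2 + n)], p[(3 + n):(2 + 2 * n)],
                               sigma_s = p[2])
    params_sigma <- params_eps
    pred_e <- .eps_model(c(p[1], p[3:(2 + n)], p[(3 + n):(2 + 2 * n)]), f, n)
    pred_s <- .sigma_model(c(p[2], p[3:(2 + n)], p[(3 + n):(2 + 2 * n)]), f, n)
  }

  structure(list(
    params_eps = params_eps,
    params_sigma = params_sigma,
    r_squared_eps = .r_squared(er, pred_e),
    r_squared_sigma = .r_squared(sg, pred_s),
    residuals = list(eps = pred_e / er - 1,
                     sigma = pred_s / pmax(sg, 1e-30) - 1),
    frequencies = f,
    n_relaxations = n,
    mode = mode), class = "debye_fit")
}

#' @export
print.debye_fit <- function(x, ...) {
  cat(sprintf("Debye fit (%d relaxation%s, %s mode)\n", x$n_relaxations,
              if (x$n_relaxations != 1L) "s" else "", x$mode))
  cat(sprintf("  R^2 eps' = %.6f, R^2 sigma = %.6f\n",
              x$r_squared_eps, x$r_squared_sigma))
  cat("eps' row: "); print(x$params_eps)
  if (x$mode == "separate") { cat("sigma row: "); print(x$params_sigma) }
  invisible(x)
}

#' Evaluate a fitted (or given) Debye parameter pair on a frequency grid
#'
#' The real part is evaluated from the \eqn{\epsilon'} row and the
#' conductivity/loss from the \eqn{\sigma} row, mirroring the
#' two-row convention of [aedes_debye()].
#'
#' @param params_eps,params_sigma [debye_params()] rows, or a
#'   `debye_fit` as `params_eps` (its rows are used).
#' @param f frequencies in Hz.
#' @return A data frame `frequency_hz, eps_real, eps_imag, sigma_s_per_m`.
#' @export
debye_curve <- function(params_eps, params_sigma = NULL, f) {
  if (inherits(params_eps, "debye_fit")) {
    params_sigma <- params_eps$params_sigma
    params_eps <- params_eps$params_eps
  }
  if (is.null(params_sigma)) params_sigma <- params_eps
  ev_e <- evaluate_debye(params_eps, f)
  ev_s <- evaluate_debye(params_sigma, f)
  if (length(f) == 1L) {
    data.frame(frequency_hz = f, eps_real = ev_e[["eps_real"]],
               eps_imag = ev_s[["eps_imag"]],
               sigma_s_per_m = ev_s[["sigma"]])
  } else {
    data.frame(frequency_hz = f, eps_real = ev_e$eps_real,
               eps_imag = ev_s$eps_imag, sigma_s_per_m = ev_s$sigma_s_per_m)
  }
}

#' Locate the loss-factor peak of a Debye model
#'
#' Finds the frequency of the local maximum of \eqn{\epsilon''(f)} on an
#' open interval, by fine-grid scan refined with golden-section search.
#'
#' @param params a [debye_params()] (typically the conductivity row).
#' @param f_min,f_max interval bounds in Hz.
#' @return Frequency of the maximum, Hz.
#' @examples
#' loss_peak_frequency(aedes_debye("sigma")) / 1e9
#' @export
loss_peak_frequency <- function(params, f_min = 6e9, f_max = 67e9) {
  grid <- seq(f_min, f_max, length.out = 4001)
  ei <- evaluate_debye(params, grid)$eps_imag
  i <- which.max(ei)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  optimize(function(f) evaluate_debye(params, f)[["eps_imag"]],
           lower = lo, upper = hi, maximum = TRUE, tol = 1)$maximum
}
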