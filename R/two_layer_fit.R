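# Two-layer inverse fitting by Nelder-Mead.
#
# Given the interface geometry (depth + tilt, read from the co-registered
# ultrasound image or from simulation truth), the four optical properties
# (mua, musp, mua_chest, musp_chest) are recovered by minimizing the
# weighted squared mismatch between the measured and modelled log-amplitude
# and phase over the valid pairs.  Optimization runs in log-parameter space
# (positivity for free); each residual channel is scaled by the standard
# deviation of the corresponding measured channel so amplitude and phase
# contribute comparably.

#' Two-layer Nelder-Mead fit
#'
#' @param m a preprocessed \code{fd_measurement} (126 pairs).
#' @param geom the known \code{chestwall_geometry}.
#' @param probe the \code{probe_layout}.
#' @param omega angular modulation frequency, rad/s.
#' @param n_index refractive index.
#' @param init optional initial quadruple (mua, musp, mua_chest,
#'   musp_chest); by default the tissue layer is initialized from the
#'   slope-based fit and the chest layer at (0.17, 7) cm^-1, the middle of
#'   the training parameter range.
#' @param max_iter Nelder-Mead iteration cap; hitting it yields a result
#'   flagged \code{converged = FALSE}, not an error.  The reported
#'   \code{iterations} count is the number of forward-model evaluations
#'   (roughly 2-3 per simplex iteration).
#' @param reltol relative convergence tolerance of the simplex.
#' @param max_restarts fresh-simplex restarts before accepting a stall.
#' @return a \code{dot_fit} with method "twolayer".
#' @examples
#' \donttest{
#' probe <- default_probe()
#' geom <- chestwall_geometry(2, 0)
#' med <- two_layer_medium(optical_props(0.02, 7), optical_props(0.12, 7), geom)
#' m <- preprocess_measurement(fluence_two_layer(med, probe))
#' fit_two_layer(m, geom, probe)
#' }
#' @export
fit_two_layer <- function(m, geom, probe, omega = default_omega(),
                          n_index = 1.4, init = NULL, max_iter = 500L,
                          reltol = 1e-10, max_restarts = 3L) {
  stopifnot(inherits(m, "fd_measurement"), inherits(geom, "chestwall_geometry"),
            inherits(probe, "probe_layout"))
  v <- m$valid_mask
  if (sum(v) < 8L) stop("too few valid pairs for a four-parameter fit")
  model <- two_layer_model_fn(probe, geom, omega, n_index)
  s_amp <- stats::sd(m$log_amplitude[v])
  s_ph <- stats::sd(m$phase[v])
  if (s_amp == 0 || s_ph == 0) stop("degenerate measurement: zero channel spread")
  obj <- function(theta) {
    pr <- exp(theta)
    md <- model(pr[1], pr[2], pr[3], pr[4])
    mean(((md$log_amplitude[v] - m$log_amplitude[v]) / s_amp)^2) +
      mean(((md$phase[v] - m$phase[v]) / s_ph)^2)
  }
  if (is.null(init)) {
    tissue0 <- tryCatch(slope_to_props(fit_slopes(m), omega, n_index),
                        error = function(e) optical_props(0.05, 7))
    init <- c(tissue0$mua, tissue0$musp, 0.17, 7)
  }
  init <- pmin(pmax(as.numeric(init), 1e-3), 30)
  # Nelder-Mead with simplex restarts: a fresh simplex is spawned at the
  # incumbent until a run both terminates by tolerance and fails to
  # improve on its starting value (guards against premature stalls)
  par <- log(init)
  value <- obj(par)
  total_evals <- 0L
  converged <- FALSE
  for (run in seq_len(max_restarts + 1L)) {
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = reltol))
    total_evals <- total_evals + unname(opt$counts[1])
    improved <- value - opt$value > 10 * reltol * (abs(value) + reltol)
    par <- opt$par
    value <- opt$value
    if (opt$convergence == 0L && !improved) {
      converged <- TRUE
      break
    }
  }
  dot_fit(exp(par), method = "twolayer",
          iterations = total_evals,
          residual = value,
          converged = converged,
          details = list(init = init, geom = geom))
}
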