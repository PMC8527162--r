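# Source / detector gain calibration.
#
# Individual detectors have different gains and individual sources different
# powers, so raw measurements are
#   log A_raw = log|g_s| + log|g_d| + log A_model,
#   phase_raw = arg(g_s) + arg(g_d) + phase_model.
# A homogeneous reference measurement with known properties identifies the
# gains by two linear least-squares fits (log-amplitude and phase solved
# separately).  The gauge is fixed by forcing the first source gain to
# modulus 1, phase 0; this also removes the sources-up / detectors-down
# null direction of the indicator design.

#' Source and detector gain set
#'
#' @param source_gains complex vector of 9 source gains (first must be 1).
#' @param detector_gains complex vector of 14 detector gains.
#' @return object of class \code{gain_set}.
#' @export
gain_set <- function(source_gains, detector_gains) {
  if (length(source_gains) != 9L || length(detector_gains) != 14L)
    stop("need 9 source gains and 14 detector gains")
  source_gains <- as.complex(source_gains)
  detector_gains <- as.complex(detector_gains)
  if (any(Mod(c(source_gains, detector_gains)) <= 0))
    stop("all gain moduli must be positive")
  if (Mod(Mod(source_gains[1]) - 1) > 1e-8 || abs(Arg(source_gains[1])) > 1e-8)
    stop("gauge violation: first source gain must have modulus 1 and phase 0")
  structure(list(source_gains = source_gains, detector_gains = detector_gains),
            class = "gain_set")
}

#' @export
print.gain_set <- function(x, ...) {
  cat("gain set (gauge: source 1 = 1+0i)\n")
  cat("  source moduli:  ", paste(sprintf("%.3f", Mod(x$source_gains)), collapse = " "), "\n")
  cat("  detector moduli:", paste(sprintf("%.3f", Mod(x$detector_gains)), collapse = " "), "\n")
  invisible(x)
}

# per-pair complex gain product in the canonical order
pair_gains <- function(gains) {
  idx <- pair_index()
  gains$source_gains[idx$source] * gains$detector_gains[idx$detector]
}

#' Fit source/detector gains from a homogeneous reference measurement
#'
#' Least-squares estimate of the 9 source and 14 detector gains from a raw
#' measurement collected on a homogeneous medium of known optical
#' properties.  Residuals between the raw data and the semi-infinite model
#' are regressed on source/detector indicator columns, separately for
#' log-amplitude (log-moduli) and phase (gain phases).
#'
#' @param raw \code{fd_measurement} from the homogeneous reference (126 pairs).
#' @param reference_props known \code{optical_props} of the reference medium.
#' @param probe the \code{probe_layout} used.
#' @param omega angular modulation frequency, rad/s.
#' @param n_index refractive index of the reference medium.
#' @return a \code{gain_set}.
#' @export
fit_gains <- function(raw, reference_props, probe, omega = default_omega(),
                      n_index = 1.33) {
  stopifnot(inherits(raw, "fd_measurement"))
  if (length(raw$separations) != 126L)
    stop("gain fitting needs the full 126-pair measurement")
  valid <- raw$valid_mask
  if (sum(valid) < 23L)
    stop("need at least 23 valid pairs to identify 9 + 14 gains")
  idx <- pair_index()
  rho <- separations(probe)
  phi <- fluence_semi_infinite(reference_props, rho, omega, n_index)
  model_la <- log(Mod(phi))
  model_ph <- unwrap_by_rho(rho, -Arg(phi))

  # indicator design: sources 2..9 and detectors 1..14 (source 1 is gauge)
  X <- matrix(0, sum(valid), 8 + 14)
  sv <- idx$source[valid]; dv <- idx$detector[valid]
  rows <- seq_len(sum(valid))
  has_src <- sv > 1L
  X[cbind(rows[has_src], sv[has_src] - 1L)] <- 1
  X[cbind(rows, 8L + dv)] <- 1
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    miss_s <- setdiff(2:9, unique(sv))
    miss_d <- setdiff(1:14, unique(dv))
    stop("gain system is rank deficient; unidentifiable gains: ",
         paste(c(sprintf("source %d", miss_s), sprintf("detector %d", miss_d)),
               collapse = ", "))
  }
  beta_la <- qr.coef(qrX, raw$log_amplitude[valid] - model_la[valid])
  beta_ph <- qr.coef(qrX, raw$phase[valid] - model_ph[valid])
  src <- complex(modulus = exp(c(0, beta_la[1:8])),
                 argument = c(0, beta_ph[1:8]))
  det <- complex(modulus = exp(beta_la[9:22]), argument = beta_ph[9:22])
  gain_set(src, det)
}

#' Apply (or synthesize) a gain calibration
#'
#' \code{apply_calibration} removes fitted gains from a raw measurement:
#' \code{log_amplitude - log|g_s g_d|} and \code{phase - arg(g_s g_d)}
#' per pair; the validity mask is untouched.  \code{apply_gains} is the
#' inverse operation, used to synthesize raw instrument data.
#'
#' @param raw an \code{fd_measurement} with 126 pairs.
#' @param gains a \code{gain_set}.
#' @return an \code{fd_measurement}.
#' @export
apply_calibration <- function(raw, gains) {
  stopifnot(inherits(raw, "fd_measurement"), inherits(gains, "gain_set"))
  if (length(raw$separations) != 126L)
    stop("calibration expects the full 126-pair measurement")
  g <- pair_gains(gains)
  fd_measurement(raw$separations,
                 raw$log_amplitude - log(Mod(g)),
                 raw$phase - Arg(g),
                 modulation_freq = raw$modulation_freq,
                 valid_mask = raw$valid_mask,
                 meta = raw$meta)
}

#' @rdname apply_calibration
#' @export
apply_gains <- function(raw, gains) {
  stopifnot(inherits(raw, "fd_measurement"), inherits(gains, "gain_set"))
  g <- pair_gains(gains)
  fd_measurement(raw$separations,
                 raw$log_amplitude + log(Mod(g)),
                 raw$phase + Arg(g),
                 modulation_freq = raw$modulation_freq,
                 valid_mask = raw$valid_mask,
                 meta = raw$meta)
}

#' Export / import gains as JSON
#' @param gains a \code{gain_set}.
#' @param path file to write; if NULL the JSON string is returned.
#' @export
gains_to_json <- function(gains, path = NULL) {
  js <- jsonlite::toJSON(list(
    source_modulus = Mod(gains$source_gains),
    source_phase = Arg(gains$source_gains),
    detector_modulus = Mod(gains$detector_gains),
    detector_phase = Arg(gains$detector_gains)), digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname gains_to_json
#' @param json path or JSON string.
#' @export
gains_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  gain_set(complex(modulus = x$source_modulus, argument = x$source_phase),
           complex(modulus = x$detector_modulus, argument = x$detector_phase))
}
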