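# Acquisition protocols: one row per measurement, describing the b-tensor
# (magnitude, normalized anisotropy, symmetry-axis orientation), the centroid
# frequency of the encoding waveform, and the relaxation weighting (TE, TR).
# Frequencies are stored internally in rad/s; files use Hz.

#' Build an acquisition protocol
#'
#' @param b b-tensor magnitude (trace), ms/um^2; must include at least one
#'   `b = 0` measurement.
#' @param b_delta Normalized b-tensor anisotropy in \[-0.5, 1\]
#'   (1 linear, 0 spherical, -0.5 planar).
#' @param theta_enc,phi_enc Encoding symmetry-axis angles (rad).
#' @param omega_cent Centroid angular frequency (rad/s).
#' @param te Echo time (s).
#' @param tr Repetition time (s); must exceed `te`.
#' @return A `data.frame` of class `idmc_protocol` with `M` attribute rows.
#' @examples
#' protocol(b = c(0, 1), b_delta = 0, theta_enc = 0, phi_enc = 0,
#'          omega_cent = 2 * pi * 10, te = 0.05, tr = 5)
#' @export
protocol <- function(b, b_delta, theta_enc, phi_enc, omega_cent, te, tr) {
  p <- data.frame(b = b, b_delta = b_delta, theta_enc = theta_enc,
                  phi_enc = phi_enc, omega_cent = omega_cent,
                  te = te, tr = tr)
  class(p) <- c("idmc_protocol", "data.frame")
  validate_protocol(p)
}

#' Validate an acquisition protocol
#'
#' @param p Protocol data frame.
#' @return `p`, after checking `b >= 0`, `b_delta` in \[-0.5, 1\],
#'   `omega_cent >= 0`, `te > 0`, `tr > te`, and the presence of at least one
#'   `b = 0` measurement.
#' @export
validate_protocol <- function(p) {
  req <- c("b", "b_delta", "theta_enc", "phi_enc", "omega_cent", "te", "tr")
  missing <- setdiff(req, names(p))
  if (length(missing))
    stop("protocol is missing column(s): ", paste(missing, collapse = ", "))
  for (col in req)
    if (!is.numeric(p[[col]]) || anyNA(p[[col]]))
      stop("protocol column '", col, "' must be numeric and complete")
  if (any(p$b < 0)) stop("b must be nonnegative")
  if (any(p$b_delta < -0.5 - 1e-12 | p$b_delta > 1 + 1e-12))
    stop("b_delta must lie in [-0.5, 1]")
  if (any(p$omega_cent < 0)) stop("omega_cent must be nonnegative")
  if (any(p$te <= 0)) stop("te must be positive")
  if (any(p$tr <= p$te)) stop("tr must exceed te")
  if (!any(p$b == 0)) stop("protocol must contain at least one b = 0 measurement")
  p
}

#' Number of measurements in a protocol
#' @param p Protocol.
#' @return Integer count of acquisitions.
#' @export
n_meas <- function(p) nrow(p)

#' Read an acquisition protocol from CSV
#'
#' Expects columns `b_ms_per_um2`, `b_delta`, `theta_enc_rad`, `phi_enc_rad`,
#' `omega_cent_hz`, `te_s`, `tr_s` (one row per measurement); the frequency
#' column is converted from Hz to rad/s on read.
#'
#' @param path CSV file path.
#' @return Validated protocol.
#' @examples
#' p <- read_protocol(system.file("extdata", "example_protocol.csv",
#'                                package = "idmc"))
#' n_meas(p)
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  d <- read.csv(path)
  req <- c("b_ms_per_um2", "b_delta", "theta_enc_rad", "phi_enc_rad",
           "omega_cent_hz", "te_s", "tr_s")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop("protocol file is missing column(s): ", paste(missing, collapse = ", "))
  for (col in req)
    if (!is.numeric(d[[col]]) || anyNA(d[[col]]))
      stop("protocol column '", col, "' must be numeric and complete")
  protocol(b = d$b_ms_per_um2, b_delta = d$b_delta,
           theta_enc = d$theta_enc_rad, phi_enc = d$phi_enc_rad,
           omega_cent = 2 * pi * d$omega_cent_hz,
           te = d$te_s, tr = d$tr_s)
}

#' Write an acquisition protocol to CSV
#'
#' Inverse of [read_protocol()]; frequencies are written in Hz.
#'
#' @param p Protocol.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(p, path) {
  validate_protocol(p)
  d <- data.frame(b_ms_per_um2 = p$b, b_delta = p$b_delta,
                  theta_enc_rad = p$theta_enc, phi_enc_rad = p$phi_enc,
                  omega_cent_hz = p$omega_cent / (2 * pi),
                  te_s = p$te, tr_s = p$tr)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Hash of the acquisition settings
#'
#' Cheap content digest used to refuse matching a signal against a dictionary
#' built under a different protocol.
#'
#' @param p Protocol.
#' @return Character scalar.
#' @export
protocol_hash <- function(p) {
  cols <- c("b", "b_delta", "theta_enc", "phi_enc", "omega_cent", "te", "tr")
  v <- unlist(lapply(cols, function(cl) round(p[[cl]], 10)))
  paste0("p", nrow(p), "-", format(sum(v * seq_along(v)) %% 1e9, digits = 12))
}
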