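#' Construct a four-parameter Hill dose-response curve
#'
#' A compound's dose-response law \eqn{E(d) = E_0 + (E_{max}-E_0) /
#' (1 + (EC_{50}/d)^\alpha)}: baseline effect `e0`, maximum effect `emax`,
#' median-effect dose `ec50` and Hill coefficient `slope`. Effects are
#' fractions in \[0, 1\]; doses are in whatever unit the data use.
#'
#' @param name Compound label.
#' @param ec50 Median-effect dose (same units as the data, > 0).
#' @param slope Hill coefficient (dimensionless, non-zero).
#' @param e0 Baseline effect at zero dose (fraction, default 0).
#' @param emax Maximum effect (fraction, default 1); `e0 <= emax <= 1`.
#' @return An object of class `"hill_curve"`.
#' @examples
#' midazolam <- hill_curve("midazolam", ec50 = 0.144, slope = 4.8)
#' hill_effect(midazolam, c(0, 0.144, 0.288))
#' @export
hill_curve <- function(name, ec50, slope, e0 = 0, emax = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in list(ec50, slope, e0, emax))
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v)))
      stop("hill_curve parameters must be finite numeric scalars", call. = FALSE)
  if (ec50 <= 0) stop("'ec50' must be > 0", call. = FALSE)
  if (slope == 0) stop("'slope' must be non-zero", call. = FALSE)
  if (e0 < 0 || e0 > emax || emax > 1)
    stop("require 0 <= e0 <= emax <= 1", call. = FALSE)
  structure(list(name = name, e0 = e0, emax = emax, ec50 = ec50, slope = slope),
            class = "hill_curve")
}

#' Evaluate a Hill curve
#'
#' @param curve A [hill_curve()].
#' @param dose Vector of non-negative doses.
#' @return Effect fraction(s); `e0` at dose 0, approaching `emax` as the dose
#'   grows (for positive slope).
#' @export
hill_effect <- function(curve, dose) {
  stopifnot(inherits(curve, "hill_curve"))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and >= 0", call. = FALSE)
  out <- numeric(length(dose))
  pos <- dose > 0
  out[!pos] <- curve$e0
  if (any(pos))
    out[pos] <- curve$e0 + (curve$emax - curve$e0) /
      (1 + (curve$ec50 / dose[pos])^curve$slope)
  out
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("Hill curve '%s': E0 = %g, Emax = %g, EC50 = %g, slope = %g\n",
              x$name, x$e0, x$emax, x$ec50, x$slope))
  invisible(x)
}
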