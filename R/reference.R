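## Literature reference surfaces used for comparison with the Hill-type
## null-interaction model: generalized concentration addition (GCA),
## Chou-Talalay exclusive/non-exclusive, the implicit Loewe concentration-
## addition equation, and the linear truncation of the Minto/Fidler
## potency-fraction expansions.

two_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) == 2,
            all(vapply(curves, inherits, TRUE, "hill_curve")))
  curves
}

#' Generalized concentration addition surface
#'
#' `u = (a_max m_a + b_max m_b) / (1 + a_max m_a + b_max m_b)` with
#' `m_i = d_i / ec50_i`. Valid for unit Hill slopes and zero baselines;
#' handles partial agonists (different maxima).
#'
#' @param curves List of two [hill_curve()] objects with `slope = 1` and
#'   `e0 = 0`.
#' @param doses Length-2 dose vector or a two-column matrix.
#' @return Effect fraction(s).
#' @export
u_gca <- function(curves, doses) {
  curves <- two_curves(curves)
  if (any(vapply(curves, `[[`, 0, "slope") != 1))
    stop("u_gca requires both Hill slopes equal to 1", call. = FALSE)
  if (any(vapply(curves, `[[`, 0, "e0") != 0))
    stop("u_gca requires zero baselines", call. = FALSE)
  D <- if (is.null(dim(doses))) matrix(doses, ncol = 2) else as.matrix(doses)
  if (any(D < 0)) stop("doses must be >= 0", call. = FALSE)
  m <- sweep(D, 2, vapply(curves, `[[`, 0, "ec50"), "/")
  s <- m[, 1] * curves[[1]]$emax + m[, 2] * curves[[2]]$emax
  s / (1 + s)
}

#' Chou-Talalay median-effect surfaces
#'
#' Exclusive form: `u = umax (m_a + m_b)^gamma / (1 + (m_a + m_b)^gamma)`;
#' the non-exclusive form adds the product `m_a m_b` inside the bracket.
#' Both assume a shared maximum effect and slope.
#'
#' @param m_a,m_b Median-effect scaled doses of the two compounds.
#' @param gamma Shared Hill slope.
#' @param umax Shared maximum effect.
#' @param exclusive Use the mutually exclusive form (default `TRUE`)?
#' @return Effect fraction(s).
#' @export
u_chou <- function(m_a, m_b, gamma = 1, umax = 1, exclusive = TRUE) {
  if (any(m_a < 0) || any(m_b < 0)) stop("scaled doses must be >= 0", call. = FALSE)
  s <- m_a + m_b + if (exclusive) 0 else m_a * m_b
  umax * s^gamma / (1 + s^gamma)
}

#' Implicit Loewe concentration-addition effect
#'
#' Solves `1 = m_a / (u/(a_max - u))^{1/gamma_a} +
#' m_b / (u/(b_max - u))^{1/gamma_b}` for the effect `u`. Zero doses
#' short-circuit to the other compound's Hill effect.
#'
#' @param curves List of two [hill_curve()] objects (zero baselines,
#'   positive slopes).
#' @param doses Length-2 non-negative dose vector.
#' @param tol Convergence tolerance on `|lhs - 1|` (default 1e-10).
#' @return Effect fraction.
#' @export
ca_effect <- function(curves, doses, tol = 1e-10) {
  curves <- two_curves(curves)
  d <- as.numeric(doses)
  stopifnot(length(d) == 2, all(is.finite(d)), all(d >= 0))
  if (any(vapply(curves, `[[`, 0, "slope") <= 0))
    stop("ca_effect requires positive slopes", call. = FALSE)
  if (d[1] == 0) return(hill_effect(curves[[2]], d[2]))
  if (d[2] == 0) return(hill_effect(curves[[1]], d[1]))
  m <- d / vapply(curves, `[[`, 0, "ec50")
  amax <- curves[[1]]$emax; bmax <- curves[[2]]$emax
  ga <- curves[[1]]$slope; gb <- curves[[2]]$slope
  lhs <- function(u)
    m[1] / (u / (amax - u))^(1 / ga) + m[2] / (u / (bmax - u))^(1 / gb)
  lo <- 1e-12; hi <- min(amax, bmax) - 1e-12
  if (lhs(hi) > 1) stop("no concentration-addition root in (0, min(amax, bmax))",
                        call. = FALSE)
  ## lhs is strictly decreasing in u; bisect then polish with uniroot
  root <- stats::uniroot(function(u) lhs(u) - 1, c(lo, hi), tol = 1e-14)$root
  if (abs(lhs(root) - 1) > tol)
    stop("concentration-addition solver did not converge", call. = FALSE)
  root
}

#' Linear potency-fraction mixing of slope and maximum effect
#'
#' The linear truncation of the potency-fraction polynomial expansions:
#' `gamma(theta) = alpha * theta + beta * (1 - theta)` and the analogous
#' expression for the maximum effect. With `theta = m_a / (m_a + m_b)` these
#' equal the dose-weighted mixing functions of the null-interaction surface.
#'
#' @param slopes,maxima Numeric pair `(compound a, compound b)`.
#' @param theta Potency fraction in \[0, 1\].
#' @return Mixed slope / maximum effect.
#' @export
minto_linear_gamma <- function(slopes, theta) {
  stopifnot(length(slopes) == 2, all(theta >= 0 & theta <= 1))
  slopes[1] * theta + slopes[2] * (1 - theta)
}

#' @rdname minto_linear_gamma
#' @export
minto_linear_umax <- function(maxima, theta) {
  stopifnot(length(maxima) == 2, all(theta >= 0 & theta <= 1))
  maxima[1] * theta + maxima[2] * (1 - theta)
}
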