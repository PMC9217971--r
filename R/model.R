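## Mixture response-surface model: n Hill curves + per-compound perturbations
## + k-tuple interaction terms. Evaluation is in the dose domain throughout;
## the log-dose form exists only inside pde_residual().

subset_ids <- function(n) {
  ## all compound subsets of size >= 2, ordered by size then lexicographically
  out <- list()
  for (k in 2:n) out <- c(out, utils::combn(n, k, simplify = FALSE))
  out
}

subset_key <- function(s) paste(s, collapse = ",")

#' Number of free parameters of the full-interaction surface
#'
#' Three perturbations per compound plus three parameters for every subset of
#' two or more compounds: `3n + 3(2^n - n - 1) = 3(2^n - 1)`.
#'
#' @param n Number of mixture components (integer >= 2).
#' @return Integer parameter count (9, 21, 45 for n = 2, 3, 4).
#' @export
parameter_count <- function(n) {
  if (!(is.numeric(n) && length(n) == 1L && is.finite(n) && n == round(n) && n >= 2))
    stop("'n' must be an integer >= 2", call. = FALSE)
  as.integer(3 * (2^n - 1))
}

#' Inactive perturbation set for n compounds
#'
#' Per compound: additive shift of the maximum effect (`d_emax`), additive
#' slope shift (`d_slope`) and a multiplicative EC50 scale factor (`d_m50`,
#' equal to `exp(delta_x50)`). Inactive values are (0, 0, 1).
#'
#' @param n Number of compounds.
#' @return List of three numeric vectors of length `n`.
#' @export
perturbation_set <- function(n) {
  list(d_emax = numeric(n), d_slope = numeric(n), d_m50 = rep(1, n))
}

#' Inactive interaction set for n compounds
#'
#' One triple per subset S of 2..n compounds: position interaction `d_m`
#' (enters the dose bracket with the |S|-th root of the product of scaled
#' doses), maximum-effect interaction `d_emax` and slope interaction
#' `d_slope`. Inactive values are (0, 0, 0).
#'
#' @param n Number of compounds.
#' @return Named list keyed by subset (e.g. `"1,2"`), each a numeric triple
#'   `c(d_m, d_emax, d_slope)`.
#' @export
interaction_set <- function(n) {
  subs <- subset_ids(n)
  out <- lapply(subs, function(s) c(d_m = 0, d_emax = 0, d_slope = 0))
  names(out) <- vapply(subs, subset_key, "")
  out
}

#' Construct a mixture response-surface model
#'
#' Bundles the pure-compound Hill curves with a perturbation set and an
#' interaction set. With every perturbation/interaction entry inactive the
#' model is the null-interaction surface [u_null()]; otherwise it is the
#' full-interaction surface [u_ricc()].
#'
#' @param curves List of [hill_curve()] objects (length n >= 2).
#' @param perturbations Optional [perturbation_set()]; default inactive.
#' @param interactions Optional [interaction_set()]; default inactive.
#'   Partial lists are accepted: entries are matched by subset key and the
#'   rest stay inactive.
#' @param umin_mode `"constant"` (default; the baseline is dose-independent)
#'   or `"mixed"` (dose-weighted average of the compound baselines).
#' @param umin_value Baseline effect used when `umin_mode = "constant"`;
#'   defaults to the first curve's `e0`.
#' @return An object of class `"ricc_model"`.
#' @examples
#' a <- hill_curve("a", ec50 = 1, slope = 2)
#' b <- hill_curve("b", ec50 = 3, slope = 4)
#' m <- ricc_model(list(a, b), interactions = list("1,2" = c(0.5, 0.3, 1)))
#' u_ricc(m, c(1, 3))
#' @export
ricc_model <- function(curves, perturbations = NULL, interactions = NULL,
                       umin_mode = c("constant", "mixed"), umin_value = NULL) {
  stopifnot(is.list(curves), length(curves) >= 2)
  if (!all(vapply(curves, inherits, TRUE, "hill_curve")))
    stop("'curves' must be a list of hill_curve objects", call. = FALSE)
  n <- length(curves)
  umin_mode <- match.arg(umin_mode)
  pert <- perturbation_set(n)
  if (!is.null(perturbations)) {
    for (f in names(pert))
      if (!is.null(perturbations[[f]])) {
        stopifnot(length(perturbations[[f]]) == n)
        pert[[f]] <- as.numeric(perturbations[[f]])
      }
  }
  if (any(pert$d_m50 <= 0)) stop("'d_m50' entries must be > 0", call. = FALSE)
  inter <- interaction_set(n)
  if (!is.null(interactions)) {
    bad <- setdiff(names(interactions), names(inter))
    if (length(bad))
      stop("unknown interaction subset(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (k in names(interactions)) {
      v <- as.numeric(interactions[[k]])
      stopifnot(length(v) == 3)
      inter[[k]] <- c(d_m = v[1], d_emax = v[2], d_slope = v[3])
    }
  }
  emax <- vapply(curves, `[[`, 0, "emax")
  if (any(emax + pert$d_emax > 1 + 1e-12))
    stop("per-compound maximum effects must satisfy emax + d_emax <= 1",
         call. = FALSE)
  if (is.null(umin_value)) umin_value <- curves[[1]]$e0
  structure(list(curves = curves, pert = pert, inter = inter,
                 umin_mode = umin_mode, umin_value = umin_value),
            class = "ricc_model")
}

model_names <- function(model) vapply(model$curves, `[[`, "", "name")

#' @export
print.ricc_model <- function(x, ...) {
  n <- length(x$curves)
  active <- sum(param_active(x))
  cat(sprintf("Mixture response-surface model: %d compounds (%s)\n",
              n, paste(model_names(x), collapse = ", ")))
  cat(sprintf("  %d of %d perturbation/interaction parameters active%s\n",
              active, parameter_count(n),
              if (active == 0) " (null-interaction surface)" else ""))
  invisible(x)
}

param_active <- function(model) {
  n <- length(model$curves)
  act <- c(model$pert$d_emax != 0, model$pert$d_slope != 0,
           model$pert$d_m50 != 1)
  for (v in model$inter) act <- c(act, v != 0)
  act
}

check_doses <- function(d, n) {
  d <- as.numeric(d)
  if (length(d) != n)
    stop(sprintf("dose vector must have length %d", n), call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("doses must be finite and >= 0", call. = FALSE)
  d
}

as_dose_matrix <- function(model, doses) {
  n <- length(model$curves)
  if (is.data.frame(doses)) doses <- as.matrix(doses)
  if (is.null(dim(doses))) doses <- matrix(doses, ncol = n, byrow = FALSE,
                                           dimnames = NULL)
  if (ncol(doses) != n)
    stop(sprintf("dose matrix must have %d columns", n), call. = FALSE)
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("doses must be finite and >= 0", call. = FALSE)
  doses
}

#' Median-effect scaled doses
#'
#' `m_i = d_i / (ec50_i * d_m50_i)` when `shifted`, `m_i = d_i / ec50_i`
#' otherwise.
#'
#' @param model A [ricc_model()].
#' @param doses Dose vector (length n) or matrix (one row per dose point).
#' @param shifted Apply the multiplicative EC50 perturbations `d_m50`?
#' @return Matrix of scaled doses with one row per dose point.
#' @export
scaled_doses <- function(model, doses, shifted = TRUE) {
  D <- as_dose_matrix(model, doses)
  ec50 <- vapply(model$curves, `[[`, 0, "ec50")
  div <- if (shifted) ec50 * model$pert$d_m50 else ec50
  sweep(D, 2, div, "/")
}

## Core evaluator. Returns u plus the effective surface functions used by the
## PDE right-hand side. `strict_null` forces every perturbation/interaction
## inactive and uses unshifted scaled doses.
surface_eval <- function(model, doses, strict_null = FALSE) {
  D <- as_dose_matrix(model, doses)
  n <- ncol(D)
  curves <- model$curves
  emax <- vapply(curves, `[[`, 0, "emax")
  e0 <- vapply(curves, `[[`, 0, "e0")
  alpha <- vapply(curves, `[[`, 0, "slope")
  m <- scaled_doses(model, D, shifted = !strict_null)
  M <- rowSums(m)
  subs <- subset_ids(n)
  keys <- vapply(subs, subset_key, "")
  ## |S|-th roots of products of scaled doses, one column per subset
  R <- vapply(subs, function(s) {
    exp(rowSums(log(pmax(m[, s, drop = FALSE], 0))) / length(s))
  }, numeric(nrow(m)))
  R <- matrix(R, nrow = nrow(m))
  R[!is.finite(R)] <- 0  # log(0) rows: any zero dose kills the subset term
  d_m <- vapply(model$inter, `[`, 0, 1)[keys]
  d_em <- vapply(model$inter, `[`, 0, 2)[keys]
  d_sl <- vapply(model$inter, `[`, 0, 3)[keys]
  if (strict_null) d_m[] <- d_em[] <- d_sl[] <- 0
  pe <- if (strict_null) perturbation_set(n) else model$pert

  pos <- M > 0
  umin <- if (model$umin_mode == "constant") rep(model$umin_value, nrow(m)) else {
    v <- rep(model$umin_value, nrow(m))
    v[pos] <- as.vector(m[pos, , drop = FALSE] %*% e0) / M[pos]
    v
  }
  u <- umin
  umax_eff <- gamma_eff <- rep(NA_real_, nrow(m))
  if (any(pos)) {
    mp <- m[pos, , drop = FALSE]; Rp <- R[pos, , drop = FALSE]; Mp <- M[pos]
    Dp <- Mp + rowSums(Rp)
    umax_eff[pos] <- as.vector(mp %*% emax) / Mp +
      (as.vector(mp %*% pe$d_emax) + as.vector(Rp %*% d_em)) / Dp
    gamma_eff[pos] <- as.vector(mp %*% alpha) / Mp +
      (as.vector(mp %*% pe$d_slope) + as.vector(Rp %*% d_sl)) / Dp
    B <- Mp + as.vector(Rp %*% d_m)
    if (any(B < 0)) {
      worst <- which.min(B)
      j <- which.min(d_m * Rp[worst, ])
      stop(sprintf(paste0("dose bracket is negative at a requested dose: ",
                          "interaction term d_m for subset {%s} is too negative"),
                   keys[j]), call. = FALSE)
    }
    B <- pmax(B, 1e-300)
    u[pos] <- umin[pos] + (umax_eff[pos] - umin[pos]) / (1 + B^(-gamma_eff[pos]))
  }
  list(u = u, umin = umin, umax = umax_eff, gamma = gamma_eff)
}

#' Null-interaction response surface
#'
#' The non-interacting reference surface: a Hill-type function of the summed
#' scaled doses whose maximum effect and slope are the dose-weighted averages
#' of the pure-compound values. All perturbation and interaction parameters
#' of the model are ignored. At the zero-dose point the continuous limit
#' `u_min` is returned.
#'
#' @inheritParams scaled_doses
#' @return Effect fraction(s), one per dose point.
#' @export
u_null <- function(model, doses) {
  stopifnot(inherits(model, "ricc_model"))
  surface_eval(model, doses, strict_null = TRUE)$u
}

#' Full-interaction response surface
#'
#' The generalized Hill surface including per-compound perturbations and
#' k-tuple interaction terms (k-th roots of products of scaled doses). With
#' all parameters inactive this reduces to [u_null()]; in the pure-compound
#' limit it reduces to the (perturbed) single-drug Hill curve.
#'
#' @inheritParams scaled_doses
#' @return Effect fraction(s), one per dose point.
#' @export
u_ricc <- function(model, doses) {
  stopifnot(inherits(model, "ricc_model"))
  surface_eval(model, doses, strict_null = FALSE)$u
}

#' @export
predict.ricc_model <- function(object, newdata, type = c("full", "null"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, model_names(object), drop = FALSE])
  if (type == "full") u_ricc(object, newdata) else u_null(object, newdata)
}

#' Residual of the Riccati partial differential equation
#'
#' Central-difference estimate of \eqn{\sum_i \partial u/\partial x_i} in
#' log-dose space minus the right-hand side
#' \eqn{\gamma (u - u_{min})(u_{max} - u) / (u_{max} - u_{min})} evaluated
#' with the model's effective (perturbed) slope and maximum-effect functions.
#' Vanishes as the step shrinks when the surface solves the PDE.
#'
#' @param model A [ricc_model()].
#' @param log_dose_point Vector of finite log-doses (natural log).
#' @param step Finite-difference step (default 1e-5).
#' @param type Evaluate the `"full"` ([u_ricc()]) or `"null"` ([u_null()])
#'   surface.
#' @return Residual scalar.
#' @export
pde_residual <- function(model, log_dose_point, step = 1e-5,
                         type = c("full", "null")) {
  type <- match.arg(type)
  n <- length(model$curves)
  x <- as.numeric(log_dose_point)
  if (length(x) != n || any(!is.finite(x)))
    stop("'log_dose_point' must be a finite vector of length n", call. = FALSE)
  strict <- type == "null"
  f <- function(xx) surface_eval(model, exp(xx), strict_null = strict)$u
  lhs <- 0
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- step
    lhs <- lhs + (f(x + e) - f(x - e)) / (2 * step)
  }
  at <- surface_eval(model, exp(x), strict_null = strict)
  rhs <- at$gamma * (at$u - at$umin) * (at$umax - at$u) / (at$umax - at$umin)
  lhs - rhs
}
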