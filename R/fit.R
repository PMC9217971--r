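## Constrained nonlinear estimation of mixture-surface parameters.
## Pure-compound curves are always fitted first and held fixed while the
## perturbation/interaction parameters of the mixture surface are estimated
## by bounded Levenberg-Marquardt least squares from a seeded Latin-hypercube
## multistart.

#' Names of the free parameters of a full-interaction surface
#'
#' Perturbations per compound (`d_emax.<name>`, `d_slope.<name>`,
#' `d_m50.<name>`) followed by the interaction triples per subset
#' (`d_m.<a:b>`, `d_emax.<a:b>`, `d_slope.<a:b>`), subsets ordered by size
#' then lexicographically.
#'
#' @param curves List of [hill_curve()] objects.
#' @return Character vector of length `3 (2^n - 1)`.
#' @export
parameter_names <- function(curves) {
  nm <- vapply(curves, `[[`, "", "name")
  n <- length(nm)
  pert <- c(paste0("d_emax.", nm), paste0("d_slope.", nm), paste0("d_m50.", nm))
  inter <- unlist(lapply(subset_ids(n), function(s) {
    lab <- paste(nm[s], collapse = ":")
    paste0(c("d_m.", "d_emax.", "d_slope."), lab)
  }))
  c(pert, inter)
}

inactive_values <- function(names) {
  v <- numeric(length(names))
  v[startsWith(names, "d_m50.")] <- 1
  names(v) <- names
  v
}

#' Parameter activity masks
#'
#' A mask is a named logical vector over [parameter_names()]; masked-off
#' entries are pinned at their inactive values (0, or 1 for the `d_m50`
#' scale factors). `interaction_mask()` activates the interaction triples
#' only (optionally restricted to given subset labels such as `"a:b"`),
#' reproducing the reduced models in which all perturbations vanish.
#'
#' @param curves List of [hill_curve()] objects.
#' @param subsets For `interaction_mask()`: subset labels to activate
#'   (default all), e.g. `"midazolam:propofol"`.
#' @param exclude Parameter names to deactivate.
#' @return Named logical vector.
#' @export
full_mask <- function(curves, exclude = character()) {
  nm <- parameter_names(curves)
  stats::setNames(!(nm %in% exclude), nm)
}

#' @rdname full_mask
#' @export
empty_mask <- function(curves) {
  nm <- parameter_names(curves)
  stats::setNames(logical(length(nm)), nm)
}

#' @rdname full_mask
#' @export
interaction_mask <- function(curves, subsets = NULL, exclude = character()) {
  nm <- parameter_names(curves)
  is_inter <- grepl(":", nm, fixed = TRUE)
  if (!is.null(subsets)) {
    lab <- sub("^d_(m|emax|slope)\\.", "", nm)
    is_inter <- is_inter & lab %in% subsets
  }
  stats::setNames(is_inter & !(nm %in% exclude), nm)
}

## Build a ricc_model from base curves + a full-length named parameter vector
params_to_model <- function(base_curves, values, umin_mode = "constant",
                            umin_value = NULL) {
  nm <- vapply(base_curves, `[[`, "", "name")
  n <- length(nm)
  pert <- list(d_emax = unname(values[paste0("d_emax.", nm)]),
               d_slope = unname(values[paste0("d_slope.", nm)]),
               d_m50 = unname(values[paste0("d_m50.", nm)]))
  inter <- interaction_set(n)
  subs <- subset_ids(n)
  for (i in seq_along(subs)) {
    lab <- paste(nm[subs[[i]]], collapse = ":")
    inter[[i]] <- c(d_m = unname(values[paste0("d_m.", lab)]),
                    d_emax = unname(values[paste0("d_emax.", lab)]),
                    d_slope = unname(values[paste0("d_slope.", lab)]))
  }
  ricc_model(base_curves, perturbations = pert, interactions = inter,
             umin_mode = umin_mode, umin_value = umin_value)
}

#' Default box bounds for surface parameters
#'
#' Additive maximum-effect shifts in \[-1, 1\] clipped so that
#' `emax_i + d_emax_i <= 1`; slope shifts in \[-20, 20\]; EC50 scale factors
#' in \[0.01, 100\]; position interactions `d_m` in \[-1.9, 50\] (the lower
#' bound keeps the dose bracket positive); interaction maximum-effect terms
#' in \[-1, 1\] and slope interactions in \[-20, 20\].
#'
#' @param curves List of [hill_curve()] objects.
#' @return List with named `lower` and `upper` vectors.
#' @export
default_bounds <- function(curves) {
  nm <- parameter_names(curves)
  cn <- vapply(curves, `[[`, "", "name")
  emax <- vapply(curves, `[[`, 0, "emax")
  lower <- upper <- inactive_values(nm)
  lower[startsWith(nm, "d_emax.")] <- -1
  upper[startsWith(nm, "d_emax.")] <- 1
  lower[startsWith(nm, "d_slope.")] <- -20
  upper[startsWith(nm, "d_slope.")] <- 20
  lower[startsWith(nm, "d_m50.")] <- 0.01
  upper[startsWith(nm, "d_m50.")] <- 100
  lower[startsWith(nm, "d_m.")] <- -1.9
  upper[startsWith(nm, "d_m.")] <- 50
  ## per-compound maximum effects may not exceed 1
  for (i in seq_along(cn)) {
    pn <- paste0("d_emax.", cn[i])
    upper[pn] <- min(upper[pn], 1 - emax[i])
    lower[pn] <- max(lower[pn], -emax[i])
  }
  list(lower = lower, upper = upper)
}

#' Fit a pure-compound Hill curve
#'
#' Least-squares fit of the rows in which only `compound` is dosed. By
#' default the baseline and maximum effect are fixed (`e0 = 0`, `emax = 1`)
#' and only `ec50` (on the log scale) and the slope are estimated; set
#' `fit_baseline = TRUE` to free all four parameters. A deterministic grid
#' of starting values makes the fit reproducible.
#'
#' @param table A dose-response table (see [read_table()]).
#' @param compound Compound (column) name.
#' @param e0,emax Fixed baseline/maximum effect.
#' @param fit_baseline Also estimate `e0` and `emax`?
#' @return An object of class `"hill_fit"`: the fitted [hill_curve()] in
#'   `$curve` plus fit statistics.
#' @export
fit_pure <- function(table, compound, e0 = 0, emax = 1, fit_baseline = FALSE) {
  compounds <- attr(table, "compounds")
  if (!compound %in% compounds) stop("unknown compound: ", compound, call. = FALSE)
  D <- as.matrix(table[, compounds, drop = FALSE])
  keep <- D[, compound] > 0 & rowSums(D[, setdiff(compounds, compound),
                                        drop = FALSE] > 0) == 0
  d <- D[keep, compound]; y <- table$effect[keep]
  k <- if (fit_baseline) 4L else 2L
  if (length(d) < k)
    stop(sprintf("need at least %d single-drug rows for %s", k, compound),
         call. = FALSE)
  if (diff(range(y)) == 0)
    stop("degenerate data: constant effect for ", compound, call. = FALSE)
  resid_fn <- function(p) {
    cv <- list(ec50 = exp(p[1]), slope = p[2],
               e0 = if (fit_baseline) p[3] else e0,
               emax = if (fit_baseline) p[4] else emax)
    y - (cv$e0 + (cv$emax - cv$e0) / (1 + (cv$ec50 / d)^cv$slope))
  }
  lr <- log(range(d))
  lower <- c(lr[1] - log(100), 0.05, if (fit_baseline) c(0, 0))
  upper <- c(lr[2] + log(100), 50, if (fit_baseline) c(1, 1))
  best <- NULL
  for (s in c(0.5, 1, 2, 4, 8, 16))
    for (le in stats::quantile(log(d), c(0.25, 0.5, 0.75))) {
      p0 <- c(le, s, if (fit_baseline) c(min(y), max(y)))
      f <- tryCatch(minpack.lm::nls.lm(p0, lower = lower, upper = upper,
             fn = resid_fn,
             control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$deviance < best$deviance))
        best <- f
    }
  if (is.null(best)) stop("pure-compound fit failed for ", compound, call. = FALSE)
  p <- best$par
  curve <- hill_curve(compound, ec50 = exp(p[1]), slope = p[2],
                      e0 = if (fit_baseline) p[3] else e0,
                      emax = if (fit_baseline) p[4] else emax)
  st <- fit_statistics(y, hill_effect(curve, d), k)
  structure(c(list(curve = curve, doses = d, observed = y), st),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  print(x$curve)
  cat(sprintf("  n = %d, RMSE = %.4f, adj. r2 = %.4f, AIC = %.2f\n",
              x$n_obs, x$rmse, x$adjusted_r2, x$aic))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  with(object$curve, c(e0 = e0, emax = emax, ec50 = ec50, slope = slope))
}

lhs_starts <- function(n_starts, lower, upper, seed) {
  k <- length(lower)
  if (n_starts < 1) return(matrix(numeric(0), ncol = k))
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, k)
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

#' Fit a full-interaction mixture surface
#'
#' Bounded least squares over the active parameters of `mask`, with the
#' pure-compound curves held fixed. The optimizer is Levenberg-Marquardt
#' restarted from a seeded Latin-hypercube of `n_starts` points (plus the
#' inactive-parameter start and any `extra_starts`); the best residual sum
#' of squares wins, making the fit deterministic for a given seed.
#'
#' @param table Dose-response table; all its rows enter the objective
#'   (pure-compound rows constrain the perturbation parameters through the
#'   pure-compound limits of the surface).
#' @param base_curves List of fitted [hill_curve()] objects, one per
#'   compound column of `table` (order defines the compound order).
#' @param mask Named logical parameter mask (default: all interaction
#'   triples active, no perturbations). See [full_mask()].
#' @param bounds Optional list with `lower`/`upper` named vectors
#'   (default [default_bounds()]).
#' @param n_starts Number of Latin-hypercube starts (default 16).
#' @param seed Integer seed for the start design.
#' @param extra_starts Optional matrix (or vector) of additional full-length
#'   named starting values.
#' @param umin_value Constant baseline of the surface (default: first
#'   curve's `e0`).
#' @return An object of class `"ricc_fit"` with the fitted model, estimates
#'   and standard errors, fit statistics (`rss`, `rmse`, `adjusted_r2`,
#'   `aic`), the Wilcoxon-Mann-Whitney and Shapiro-Wilk p-values, and a log
#'   of every optimizer start with its final RSS.
#' @export
fit_mixture <- function(table, base_curves, mask = NULL, bounds = NULL,
                        n_starts = 16, seed = 1, extra_starts = NULL,
                        umin_value = NULL) {
  compounds <- attr(table, "compounds")
  nm_curves <- unname(vapply(base_curves, `[[`, "", "name"))
  if (!identical(sort(nm_curves), sort(unname(compounds))))
    stop("base_curves do not match the table's compounds", call. = FALSE)
  base_curves <- unname(base_curves[match(compounds, nm_curves)])
  pn <- parameter_names(base_curves)
  if (is.null(mask)) mask <- interaction_mask(base_curves)
  stopifnot(is.logical(mask), identical(names(mask), pn))
  if (is.null(bounds)) bounds <- default_bounds(base_curves)
  obs <- table$effect
  D <- as.matrix(table[, compounds, drop = FALSE])
  n <- length(obs); k <- sum(mask)
  inact <- inactive_values(pn)

  make_model <- function(p_act) {
    v <- inact; v[mask] <- p_act
    params_to_model(base_curves, v, umin_value = umin_value)
  }
  resid_fn <- function(p_act) {
    u <- tryCatch(u_ricc(make_model(p_act), D), error = function(e) NULL)
    if (is.null(u)) return(rep(1e3, n))
    obs - u
  }

  if (k == 0) {
    model <- params_to_model(base_curves, inact, umin_value = umin_value)
    pred <- u_ricc(model, D)
    st <- fit_statistics(obs, pred, 0)
    return(new_ricc_fit(model, mask, numeric(0), numeric(0), st, obs, pred,
                        table, base_curves, starts = data.frame()))
  }

  lower <- bounds$lower[mask]; upper <- bounds$upper[mask]
  starts <- rbind(inact[mask], lhs_starts(n_starts - 1, lower, upper, seed))
  if (!is.null(extra_starts)) {
    es <- if (is.null(dim(extra_starts))) matrix(extra_starts, nrow = 1,
      dimnames = list(NULL, names(extra_starts))) else extra_starts
    starts <- rbind(starts, pmin(pmax(es[, pn[mask], drop = FALSE],
                                      rep(lower, each = nrow(es))),
                                 rep(upper, each = nrow(es))))
  }
  best <- NULL; start_log <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(minpack.lm::nls.lm(starts[i, ], lower = lower, upper = upper,
           fn = resid_fn,
           control = minpack.lm::nls.lm.control(maxiter = 400)),
           error = function(e) NULL)
    start_log[[i]] <- data.frame(start = i,
      rss = if (is.null(f)) NA_real_ else f$deviance,
      converged = !is.null(f))
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance)) best <- f
  }
  if (is.null(best)) stop("all optimizer starts failed to converge", call. = FALSE)
  est <- stats::setNames(best$par, pn[mask])
  model <- make_model(est)
  pred <- u_ricc(model, D)
  st <- fit_statistics(obs, pred, k)
  se <- param_se(resid_fn, est, st$rss, n, k, lower, upper)
  new_ricc_fit(model, mask, est, se, st, obs, pred, table, base_curves,
               starts = do.call(rbind, start_log), seed = seed)
}

## numerical Jacobian-based standard errors at the optimum
param_se <- function(resid_fn, est, rss, n, k, lower, upper) {
  if (n <= k) return(stats::setNames(rep(NA_real_, k), names(est)))
  J <- matrix(0, n, k)
  for (j in seq_len(k)) {
    h <- max(1e-6, 1e-6 * abs(est[j]))
    up <- pmin(est + h * (seq_len(k) == j), upper)
    dn <- pmax(est - h * (seq_len(k) == j), lower)
    J[, j] <- (resid_fn(dn) - resid_fn(up)) / (up[j] - dn[j])
  }
  sigma2 <- rss / (n - k)
  cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(cv)) rep(NA_real_, k) else sqrt(pmax(diag(cv), 0))
  stats::setNames(se, names(est))
}

new_ricc_fit <- function(model, mask, est, se, st, obs, pred, table,
                         base_curves, starts, seed = NA, trail = NULL) {
  res <- obs - pred
  structure(list(model = model, mask = mask, par = est, se = se,
                 rss = st$rss, rmse = st$rmse, adjusted_r2 = st$adjusted_r2,
                 aic = st$aic, loglik = st$loglik,
                 mw_p = mw_test(obs, pred),
                 shapiro_p = if (diff(range(res)) > 0) shapiro_test(res) else NA_real_,
                 n_obs = st$n_obs, n_params = st$n_params,
                 observed = obs, fitted_values = pred,
                 table = table, base_curves = base_curves,
                 starts = starts, seed = seed, trail = trail),
            class = "ricc_fit")
}

#' @export
print.ricc_fit <- function(x, ...) {
  cat(sprintf("Full-interaction surface fit: %d of %d parameters active\n",
              x$n_params, length(x$mask)))
  if (x$n_params > 0) {
    cat("  ", paste(names(x$par), collapse = ", "), "\n")
  } else cat("  (null-interaction surface; no free parameters)\n")
  cat(sprintf("  n = %d, RMSE = %.4f, AIC = %.2f, MW p = %.3f\n",
              x$n_obs, x$rmse, x$aic, x$mw_p))
  invisible(x)
}

#' @export
summary.ricc_fit <- function(object, ...) {
  tab <- if (object$n_params > 0)
    data.frame(estimate = object$par, std_error = object$se,
               t_value = object$par / object$se)
  else data.frame(estimate = numeric(0))
  out <- list(coefficients = tab, rss = object$rss, rmse = object$rmse,
              adjusted_r2 = object$adjusted_r2, aic = object$aic,
              mw_p = object$mw_p, shapiro_p = object$shapiro_p,
              n_obs = object$n_obs, n_params = object$n_params,
              trail = object$trail)
  class(out) <- "summary.ricc_fit"
  out
}

#' @export
print.summary.ricc_fit <- function(x, ...) {
  cat("Full-interaction response-surface fit\n\n")
  if (nrow(x$coefficients)) {
    print(round(x$coefficients, 4))
  } else cat("No active parameters (null-interaction surface)\n")
  cat(sprintf("\nn = %d, k = %d, RSS = %.5f, RMSE = %.4f, adj. r2 = %.4f\n",
              x$n_obs, x$n_params, x$rss, x$rmse, x$adjusted_r2))
  cat(sprintf("AIC = %.2f, MW p = %.3f, Shapiro-Wilk p = %.3f\n",
              x$aic, x$mw_p, x$shapiro_p))
  if (!is.null(x$trail)) {
    cat("\nElimination trail (accepted removals):\n")
    print(x$trail$accepted)
  }
  invisible(x)
}

#' @export
coef.ricc_fit <- function(object, ...) object$par

#' @export
fitted.ricc_fit <- function(object, ...) object$fitted_values

#' @export
residuals.ricc_fit <- function(object, ...) object$observed - object$fitted_values

#' @export
predict.ricc_fit <- function(object, newdata = NULL,
                             type = c("full", "null", "synergy"), ...) {
  type <- match.arg(type)
  D <- if (is.null(newdata)) {
    as.matrix(object$table[, attr(object$table, "compounds"), drop = FALSE])
  } else if (is.data.frame(newdata)) {
    as.matrix(newdata[, model_names(object$model), drop = FALSE])
  } else newdata
  switch(type,
         full = u_ricc(object$model, D),
         null = u_null(object$model, D),
         synergy = u_ricc(object$model, D) - u_null(object$model, D))
}

#' @export
simulate.ricc_fit <- function(object, nsim = 1, seed = NULL, noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- object$rmse
  if (is.null(seed)) seed <- 1
  D <- object$table[, attr(object$table, "compounds"), drop = FALSE]
  lapply(seq_len(nsim), function(i) {
    spec <- synthetic_spec(object$model, doses = D, noise_sd = noise_sd,
                           seed = seed + i - 1)
    generate_table(spec)
  })
}

#' @export
plot.ricc_fit <- function(x, ...) {
  if (length(x$model$curves) == 2) {
    sf <- synergy_surface(x, n_grid = 101)
    plot(sf, ...)
    pts <- x$table[, attr(x$table, "compounds")]
    mix <- rowSums(pts > 0) == 2
    graphics::points(log10(pts[mix, 1]), log10(pts[mix, 2]), pch = 4)
  } else {
    graphics::plot(x$fitted_values, x$observed,
                   xlab = "fitted effect", ylab = "observed effect", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
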