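#' AIC-guided backward parameter elimination
#'
#' Starting from `start_mask` (default: all parameters active), repeatedly
#' refits the surface with each single active parameter removed and accepts
#' the removal with the lowest AIC, stopping when no removal lowers the AIC
#' of the current model. Ties are broken by removing the parameter with the
#' smallest `|estimate| / SE`. Removed `d_m50` factors are pinned at 1, all
#' other parameters at 0.
#'
#' @inheritParams fit_mixture
#' @param start_mask Initial parameter mask (default [full_mask()]).
#' @param step_starts Latin-hypercube starts per candidate refit (each
#'   candidate is additionally warm-started from the current estimates).
#' @return A `"ricc_fit"` whose `$trail` records every candidate AIC per
#'   step (`$trail$candidates`) and the accepted removals
#'   (`$trail$accepted`).
#' @export
reduce_model <- function(table, base_curves, start_mask = NULL, bounds = NULL,
                         n_starts = 16, step_starts = 8, seed = 1,
                         umin_value = NULL) {
  compounds <- attr(table, "compounds")
  nm_curves <- unname(vapply(base_curves, `[[`, "", "name"))
  base_curves <- unname(base_curves[match(compounds, nm_curves)])
  if (is.null(start_mask)) start_mask <- full_mask(base_curves)
  pn <- names(start_mask)
  current <- fit_mixture(table, base_curves, start_mask, bounds = bounds,
                         n_starts = n_starts, seed = seed,
                         umin_value = umin_value)
  candidates <- list(); accepted <- list(); step <- 0L
  repeat {
    active <- names(current$par)
    if (!length(active)) break
    step <- step + 1L
    cand_fits <- vector("list", length(active))
    warm <- inactive_values(pn); warm[names(current$par)] <- current$par
    for (i in seq_along(active)) {
      mask_i <- current$mask
      mask_i[active[i]] <- FALSE
      w <- warm
      w[active[i]] <- inactive_values(pn)[active[i]]
      cand_fits[[i]] <- fit_mixture(table, base_curves, mask_i, bounds = bounds,
                                    n_starts = step_starts, seed = seed + step,
                                    extra_starts = w, umin_value = umin_value)
    }
    aics <- vapply(cand_fits, `[[`, 0, "aic")
    candidates[[step]] <- data.frame(step = step, removed = active, aic = aics,
                                     row.names = NULL)
    if (min(aics) >= current$aic) break
    best <- which(aics == min(aics))
    if (length(best) > 1) {
      z <- abs(current$par[active[best]]) / current$se[active[best]]
      z[!is.finite(z)] <- Inf
      best <- best[which.min(z)]
    } else best <- best[1]
    accepted[[step]] <- data.frame(step = step, removed = active[best],
                                   aic = aics[best],
                                   rmse = cand_fits[[best]]$rmse,
                                   n_params = cand_fits[[best]]$n_params,
                                   row.names = NULL)
    current <- cand_fits[[best]]
  }
  current$trail <- list(candidates = do.call(rbind, candidates),
                        accepted = if (length(accepted))
                          do.call(rbind, accepted) else
                          data.frame(step = integer(), removed = character(),
                                     aic = numeric(), rmse = numeric(),
                                     n_params = integer()))
  current
}
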