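# Shared builders: the anesthetic pure-compound curves as printed in the
# source data analysis, random valid models for property tests, and table
# subsetting by compound pair.

anesthetic_curves <- function() {
  list(hill_curve("midazolam", ec50 = 0.144, slope = 4.8),
       hill_curve("propofol", ec50 = 1.078, slope = 11.1),
       hill_curve("alfentanil", ec50 = 0.093, slope = 5.7))
}

# rows involving only the given compounds (pure rows of each + their mixtures)
subset_compounds <- function(tab, compounds) {
  all_cm <- attr(tab, "compounds")
  D <- as.matrix(tab[, all_cm, drop = FALSE])
  others <- setdiff(all_cm, compounds)
  keep <- rowSums(D[, others, drop = FALSE] > 0) == 0 & rowSums(D > 0) > 0
  dose_table(tab[keep, c(compounds, "effect")], compounds = compounds)
}

# transition rows of a mixture ray: drop rows after the first effect = 1
mixture_transition_rows <- function(tab, compounds) {
  all_cm <- attr(tab, "compounds")
  D <- as.matrix(tab[, all_cm, drop = FALSE])
  mix <- rowSums(D[, compounds, drop = FALSE] > 0) == length(compounds) &
    rowSums(D[, setdiff(all_cm, compounds), drop = FALSE] > 0) == 0
  idx <- which(mix)
  sat <- which(tab$effect[idx] >= 1)
  if (length(sat)) idx <- idx[seq_len(sat[1])]
  idx
}

random_curves <- function(n) {
  lapply(seq_len(n), function(i)
    hill_curve(paste0("c", i),
               ec50 = exp(stats::runif(1, -1, 1)),
               slope = stats::runif(1, 1, 8),
               e0 = 0,
               emax = stats::runif(1, 0.7, 1)))
}

# random valid full-interaction model (perturbations + interactions active)
random_model <- function(n, seed, with_pert = TRUE, with_inter = TRUE) {
  set.seed(seed)
  curves <- random_curves(n)
  emax <- vapply(curves, `[[`, 0, "emax")
  pert <- if (with_pert)
    list(d_emax = stats::runif(n, -0.1, pmin(0.1, 1 - emax)),
         d_slope = stats::runif(n, -0.5, 0.5),
         d_m50 = exp(stats::runif(n, -0.3, 0.3)))
  else NULL
  inter <- NULL
  if (with_inter) {
    inter <- interaction_set(n)
    for (k in names(inter))
      inter[[k]] <- c(stats::runif(1, -0.5, 1.5), stats::runif(1, -0.15, 0.15),
                      stats::runif(1, -1, 1))
  }
  ricc_model(curves, perturbations = pert, interactions = inter)
}
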