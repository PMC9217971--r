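#' Anesthetic hypnosis dose-response data
#'
#' Hypnosis responses (fraction of subjects hypnotized, 0 to 1) for
#' midazolam, propofol and alfentanil given alone, in the three pairwise
#' combinations and as a ternary mixture, with doses in mg/kg. Mixture rows
#' follow fixed-ratio (ray) designs. The table ships as a plain-text file
#' under `inst/extdata/`.
#'
#' @return A validated dose-response table (data.frame with columns
#'   `midazolam`, `propofol`, `alfentanil`, `effect` and attributes
#'   `compounds` and `units`).
#' @examples
#' tab <- load_anesthetics()
#' nrow(tab)
#' @export
load_anesthetics <- function() {
  path <- system.file("extdata", "anesthetics_hypnosis.csv",
                      package = "riccsurf", mustWork = TRUE)
  read_table(path, compounds = c("midazolam", "propofol", "alfentanil"),
             effect_col = "effect", units = "mg/kg")
}

#' Specify a synthetic dose-response study
#'
#' Defines the ground-truth surface, dose design and noise level of a
#' simulated study. The default design covers every compound alone at six
#' log-spaced doses around its EC50 (two decades) plus a full factorial
#' mixture grid at four levels per compound, so single-drug curves and
#' mixture parameters are both identifiable.
#'
#' @param model Ground-truth [ricc_model()].
#' @param doses Optional data.frame/matrix of dose vectors (columns in
#'   compound order). Must dose every compound alone at >= 4 levels.
#' @param noise_sd Gaussian effect-noise standard deviation (>= 0).
#' @param seed Integer seed used by [generate_table()].
#' @param clip Clip simulated effects to \[0, 1\]?
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(model, doses = NULL, noise_sd = 0.02, seed = 1,
                           clip = FALSE) {
  stopifnot(inherits(model, "ricc_model"), noise_sd >= 0)
  nm <- model_names(model)
  n <- length(nm)
  ec50 <- vapply(model$curves, `[[`, 0, "ec50")
  if (is.null(doses)) {
    pure <- do.call(rbind, lapply(seq_len(n), function(i) {
      d <- matrix(0, 6, n)
      d[, i] <- ec50[i] * 2^seq(-2.5, 2.5, length.out = 6)
      d
    }))
    mix <- as.matrix(expand.grid(lapply(seq_len(n), function(i)
      ec50[i] * 2^c(-1.5, -0.5, 0.5, 1.5))))
    doses <- rbind(pure, unname(mix))
  }
  doses <- as.matrix(doses)
  colnames(doses) <- nm
  if (any(doses < 0) || any(!is.finite(doses)))
    stop("doses must be finite and >= 0", call. = FALSE)
  for (i in seq_len(n)) {
    alone <- doses[, i] > 0 & rowSums(doses[, -i, drop = FALSE] > 0) == 0
    if (length(unique(doses[alone, i])) < 4)
      stop("design must dose every compound alone at >= 4 levels", call. = FALSE)
  }
  structure(list(model = model, doses = doses, noise_sd = noise_sd,
                 seed = as.integer(seed), clip = isTRUE(clip)),
            class = "synthetic_spec")
}

#' Simulate a dose-response table from a known surface
#'
#' Evaluates the ground-truth full-interaction surface at the design doses
#' and adds seeded Gaussian noise. The returned table carries the spec in
#' attribute `"truth"` for recovery scoring.
#'
#' @param spec A [synthetic_spec()].
#' @return A dose-response table; reproducible for a given seed.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  u <- u_ricc(spec$model, spec$doses)
  set.seed(spec$seed)
  eff <- u + stats::rnorm(length(u), sd = spec$noise_sd)
  if (spec$clip) eff <- pmin(pmax(eff, 0), 1)
  df <- as.data.frame(spec$doses)
  df$effect <- eff
  tab <- dose_table(df, compounds = model_names(spec$model),
                    units = "", validate_effect = FALSE)
  attr(tab, "truth") <- spec
  tab
}
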