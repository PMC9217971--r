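#' Construct a validated dose-response table
#'
#' A plain data.frame with one dose column per compound and an `effect`
#' column (fraction in \[0, 1\]), carrying the compound order and dose units
#' as attributes.
#'
#' @param data data.frame with the dose and effect columns.
#' @param compounds Character vector of dose column names (defines order).
#' @param effect_col Name of the effect column (stored as `effect`).
#' @param units Free-text dose units.
#' @param validate_effect Require effects within \[0, 1\]? (Synthetic
#'   unclipped tables may exceed the range.)
#' @return The validated table, class `c("dose_table", "data.frame")`.
#' @export
dose_table <- function(data, compounds, effect_col = "effect", units = "",
                       validate_effect = TRUE) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(compounds, effect_col), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(data) < 1) stop("table has no rows", call. = FALSE)
  out <- data[, c(compounds, effect_col)]
  names(out) <- c(compounds, "effect")
  for (cn in compounds) {
    bad <- which(!is.finite(out[[cn]]) | out[[cn]] < 0)
    if (length(bad))
      stop(sprintf("negative or non-finite dose in column '%s', row %s",
                   cn, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (validate_effect) {
    bad <- which(!is.finite(out$effect) | out$effect < 0 | out$effect > 1)
    if (length(bad))
      stop("effect outside [0, 1] in row ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(out, compounds = compounds, units = units,
            class = c("dose_table", "data.frame"))
}

#' Read a delimited dose-response table
#'
#' Comma or tab separated text with a header; lines starting with `#` are
#' comments. Percent-scale effect columns are divided by 100 exactly once.
#'
#' @param path File path.
#' @param compounds Dose column names; default: every column except the
#'   effect column.
#' @param effect_col Effect column name.
#' @param scale `"fraction"` (default) or `"percent"`.
#' @param sep Field separator; autodetected from the header when `NULL`.
#' @param units Free-text dose units.
#' @return A validated [dose_table()].
#' @export
read_table <- function(path, compounds = NULL, effect_col = "effect",
                       scale = c("fraction", "percent"), sep = NULL,
                       units = "") {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 10)
    header <- header[!startsWith(header, "#")][1]
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE)
  if (!effect_col %in% names(raw))
    stop("missing effect column '", effect_col, "'", call. = FALSE)
  if (is.null(compounds)) compounds <- setdiff(names(raw), effect_col)
  if (scale == "percent") raw[[effect_col]] <- raw[[effect_col]] / 100
  dose_table(raw, compounds = compounds, effect_col = effect_col, units = units)
}

## serializable representation of a fit (schema_version 1); full double
## precision floats, round-trips through JSON
as_fit_list <- function(fit) {
  stopifnot(inherits(fit, "ricc_fit"))
  list(schema_version = 1L,
       compounds = model_names(fit$model),
       curves = lapply(fit$base_curves, function(cv)
         cv[c("name", "e0", "emax", "ec50", "slope")]),
       mask = as.list(fit$mask),
       estimates = as.list(fit$par),
       std_errors = as.list(fit$se),
       statistics = list(rss = fit$rss, rmse = fit$rmse,
                         adjusted_r2 = fit$adjusted_r2, aic = fit$aic,
                         mw_p = fit$mw_p, shapiro_p = fit$shapiro_p,
                         n_obs = fit$n_obs, n_params = fit$n_params),
       trail = if (is.null(fit$trail)) NULL else
         list(accepted = fit$trail$accepted, candidates = fit$trail$candidates))
}

#' Write / read fit results as JSON
#'
#' All floats are serialized at full double precision; reading returns the
#' same values, so results round-trip exactly.
#'
#' @param fit A `"ricc_fit"` object.
#' @param path Output / input file path.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` the parsed
#'   result list.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(as_fit_list(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' Export a synergy surface as delimited text + JSON
#'
#' Writes `<prefix>_axes.json` (axis dose vectors, bounds, compound names)
#' and `<prefix>_values.tsv` (the value grid; for three compounds in long
#' format with one row per grid node).
#'
#' @param surface A [synergy_surface()].
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_surface <- function(surface, prefix) {
  stopifnot(inherits(surface, "synergy_surface"))
  axes_path <- paste0(prefix, "_axes.json")
  val_path <- paste0(prefix, "_values.tsv")
  jsonlite::write_json(list(schema_version = 1L,
                            compounds = names(surface$axes),
                            axes = surface$axes,
                            bounds = surface$bounds),
                       axes_path, auto_unbox = TRUE, digits = NA)
  if (length(surface$axes) == 2) {
    m <- surface$values
    dimnames(m) <- lapply(surface$axes, format)
    utils::write.table(m, val_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    g <- expand.grid(surface$axes, KEEP.OUT.ATTRS = FALSE)
    g$value <- as.vector(surface$values)
    utils::write.table(g, val_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(axes_path, val_path))
}
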