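#' Dose grid axes spanning a table's experimental ranges
#'
#' Per compound: 0, then `n_grid` log-spaced points from one tenth of the
#' lowest non-zero observed dose up to the highest observed dose.
#'
#' @param table A [dose_table()].
#' @param n_grid Log-spaced points per axis (default 201).
#' @return Named list of axis dose vectors.
#' @export
dose_axes <- function(table, n_grid = 201) {
  compounds <- attr(table, "compounds")
  axes <- lapply(compounds, function(cn) {
    d <- table[[cn]]
    hi <- max(d)
    lo <- min(d[d > 0]) / 10
    c(0, exp(seq(log(lo), log(hi), length.out = n_grid)))
  })
  names(axes) <- compounds
  axes
}

#' Evaluate the synergy surface of a fitted mixture model
#'
#' The pointwise difference between the full-interaction and the
#' null-interaction surface, `u_ricc - u_null`, on a dose grid. Positive
#' values are synergism, negative antagonism.
#'
#' @param fit A `"ricc_fit"` (its model supplies both surfaces) or a
#'   [ricc_model()].
#' @param null_model Optional explicit null model; must share compound
#'   order and pure-compound curves with the full model.
#' @param axes Named list of dose axis vectors; defaults to [dose_axes()]
#'   of the fit's table.
#' @param n_grid Grid points per axis when axes are derived from a table.
#' @param bounds Optional 2 x n matrix of per-compound search bounds
#'   (default: the axis ranges).
#' @return An object of class `"synergy_surface"`: `axes`, `values`
#'   (n-dimensional array), `bounds`, and the underlying model.
#' @export
synergy_surface <- function(fit, null_model = NULL, axes = NULL,
                            n_grid = 201, bounds = NULL) {
  model <- if (inherits(fit, "ricc_fit")) fit$model else fit
  stopifnot(inherits(model, "ricc_model"))
  if (!is.null(null_model)) {
    stopifnot(inherits(null_model, "ricc_model"))
    same <- identical(model_names(null_model), model_names(model)) &&
      isTRUE(all.equal(lapply(null_model$curves, unclass),
                       lapply(model$curves, unclass)))
    if (!same)
      stop("null and full models must share compound order and pure-compound curves",
           call. = FALSE)
  }
  if (is.null(axes)) {
    if (!inherits(fit, "ricc_fit"))
      stop("supply 'axes' when no fitted table is available", call. = FALSE)
    axes <- dose_axes(fit$table, n_grid = n_grid)
  }
  n <- length(model$curves)
  stopifnot(length(axes) == n)
  if (is.null(names(axes))) names(axes) <- model_names(model)
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  vals <- u_ricc(model, grid) - u_null(model, grid)
  values <- array(vals, dim = vapply(axes, length, 0L))
  if (is.null(bounds)) {
    bounds <- vapply(axes, function(a) range(a[a > 0]), numeric(2))
  }
  structure(list(axes = axes, values = values, bounds = bounds,
                 model = model),
            class = "synergy_surface")
}

## reflect a point into [lo, hi] coordinate-wise (billiard reflection)
reflect_box <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + pmin(y, 2 * w - y)
}

#' Locate peak synergism and antagonism
#'
#' Global maximum and minimum of a synergy surface over its grid, refined by
#' Nelder-Mead in log-dose space (bounded by reflection at the search box).
#' The refined maximum is never below the grid maximum (resp. above for the
#' minimum).
#'
#' @param surface A [synergy_surface()].
#' @param refine Run the local refinement (default `TRUE`)?
#' @return List with elements `maximum` and `minimum`, each of class
#'   `"surface_extremum"` holding `doses`, `value` and `kind`.
#' @export
find_extrema <- function(surface, refine = TRUE) {
  stopifnot(inherits(surface, "synergy_surface"))
  model <- surface$model
  syn <- function(d) u_ricc(model, d) - u_null(model, d)
  lo <- log(surface$bounds[1, ]); hi <- log(surface$bounds[2, ])
  one <- function(kind) {
    sgn <- if (kind == "maximum") 1 else -1
    idx <- which(sgn * surface$values == max(sgn * surface$values))[1]
    pos <- arrayInd(idx, dim(surface$values))
    doses <- vapply(seq_along(surface$axes),
                    function(j) surface$axes[[j]][pos[j]], 0)
    value <- surface$values[idx]
    if (refine) {
      start <- pmin(pmax(doses, exp(lo)), exp(hi))  # zero nodes -> box edge
      opt <- stats::optim(log(start), function(z) {
        -sgn * syn(exp(reflect_box(z, lo, hi)))
      }, method = "Nelder-Mead",
      control = list(maxit = 500, reltol = 1e-12))
      cand <- exp(reflect_box(opt$par, lo, hi))
      v <- syn(cand)
      if (sgn * v >= sgn * value) { doses <- cand; value <- v }
    }
    structure(list(doses = stats::setNames(doses, names(surface$axes)),
                   value = value, kind = kind),
              class = "surface_extremum")
  }
  list(maximum = one("maximum"), minimum = one("minimum"))
}

#' @export
print.surface_extremum <- function(x, ...) {
  cat(sprintf("Surface %s: %+.4f (%.1f%%) at (%s)\n", x$kind, x$value,
              100 * x$value,
              paste(sprintf("%s = %.4g", names(x$doses), x$doses),
                    collapse = ", ")))
  invisible(x)
}

#' Extract iso-effect / iso-synergy level sets
#'
#' For two compounds: contour polylines (marching squares) on the positive
#' part of the dose grid. For three compounds: iso-surface triangles by
#' marching tetrahedra. Coordinates are doses.
#'
#' @param x A [synergy_surface()] or a [ricc_model()].
#' @param levels Numeric effect (or synergy) levels.
#' @param axes Dose axes (required when `x` is a model).
#' @param what Surface to contour when `x` is a model or a refitted grid is
#'   needed: `"full"`, `"null"` or `"synergy"`.
#' @return Named list, one entry per level: for 2-D a list of data.frames
#'   (polyline vertices); for 3-D a data.frame of triangle vertices with a
#'   `triangle` index column. Levels outside the value range give an empty
#'   set with a warning.
#' @export
iso_levels <- function(x, levels, axes = NULL,
                       what = c("full", "null", "synergy")) {
  what <- match.arg(what)
  if (inherits(x, "synergy_surface") && what == "synergy") {
    axes <- x$axes
    pos_axes <- lapply(axes, function(a) a[a > 0])
    keep <- lapply(axes, function(a) which(a > 0))
    vals <- do.call(`[`, c(list(x$values), keep, list(drop = FALSE)))
  } else {
    model <- if (inherits(x, "synergy_surface")) x$model else x
    stopifnot(inherits(model, "ricc_model"))
    if (is.null(axes) && inherits(x, "synergy_surface")) axes <- x$axes
    if (is.null(axes)) stop("supply 'axes'", call. = FALSE)
    pos_axes <- lapply(axes, function(a) a[a > 0])
    grid <- as.matrix(expand.grid(pos_axes, KEEP.OUT.ATTRS = FALSE))
    v <- switch(what,
                full = u_ricc(model, grid),
                null = u_null(model, grid),
                synergy = u_ricc(model, grid) - u_null(model, grid))
    vals <- array(v, dim = vapply(pos_axes, length, 0L))
  }
  n <- length(pos_axes)
  out <- lapply(levels, function(lv) {
    if (lv < min(vals) || lv > max(vals)) {
      warning(sprintf("level %g outside surface range [%g, %g]", lv,
                      min(vals), max(vals)), call. = FALSE)
      return(if (n == 2) list() else
               data.frame(triangle = integer(0)))
    }
    if (n == 2) {
      cl <- grDevices::contourLines(x = log(pos_axes[[1]]),
                                    y = log(pos_axes[[2]]),
                                    z = vals, levels = lv)
      lapply(cl, function(p) {
        df <- data.frame(exp(p$x), exp(p$y))
        names(df) <- names(pos_axes)
        df
      })
    } else if (n == 3) {
      marching_tetrahedra(pos_axes, vals, lv)
    } else stop("iso_levels supports 2 or 3 compounds", call. = FALSE)
  })
  names(out) <- paste0("level_", format(levels))
  out
}

## iso-surface triangles for a 3-d grid by tetrahedral decomposition;
## interpolation is linear in log-dose, returned coordinates are doses
marching_tetrahedra <- function(axes, vals, level) {
  lx <- log(axes[[1]]); ly <- log(axes[[2]]); lz <- log(axes[[3]])
  nx <- length(lx); ny <- length(ly); nz <- length(lz)
  ## cube corner offsets (i, j, k) indexed 1..8
  corner <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                  c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  tets <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))
  verts <- list(); tri <- 0L
  for (i in seq_len(nx - 1)) for (j in seq_len(ny - 1)) for (k in seq_len(nz - 1)) {
    cv <- vapply(1:8, function(c8) {
      o <- corner[c8, ]
      vals[i + o[1], j + o[2], k + o[3]]
    }, 0)
    if (min(cv) > level || max(cv) < level) next
    cp <- cbind(lx[i + corner[, 1]], ly[j + corner[, 2]], lz[k + corner[, 3]])
    for (t in 1:6) {
      id <- tets[t, ]
      tv <- cv[id]; tp <- cp[id, , drop = FALSE]
      above <- tv > level
      ns <- sum(above)
      if (ns == 0 || ns == 4) next
      ## edges crossing the level
      cross <- list()
      for (a in 1:3) for (b in (a + 1):4) {
        if (above[a] != above[b]) {
          w <- (level - tv[a]) / (tv[b] - tv[a])
          cross[[length(cross) + 1]] <- tp[a, ] + w * (tp[b, ] - tp[a, ])
        }
      }
      pts <- do.call(rbind, cross)
      if (nrow(pts) == 3) {
        tri <- tri + 1L
        verts[[length(verts) + 1]] <- cbind(triangle = tri, pts)
      } else if (nrow(pts) == 4) {
        ## split the quad into two triangles (fan around vertex 1)
        tri <- tri + 1L
        verts[[length(verts) + 1]] <- cbind(triangle = tri, pts[c(1, 2, 3), ])
        tri <- tri + 1L
        verts[[length(verts) + 1]] <- cbind(triangle = tri, pts[c(1, 3, 4), ])
      }
    }
  }
  if (!length(verts)) return(data.frame(triangle = integer(0)))
  m <- do.call(rbind, verts)
  out <- data.frame(triangle = as.integer(m[, 1]), exp(m[, 2]), exp(m[, 3]),
                    exp(m[, 4]))
  names(out)[2:4] <- names(axes)
  out
}

#' @export
print.synergy_surface <- function(x, ...) {
  cat(sprintf("Synergy surface (u_ricc - u_null): %s grid over %s\n",
              paste(dim(x$values), collapse = " x "),
              paste(names(x$axes), collapse = ", ")))
  cat(sprintf("  value range [%.4f, %.4f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.synergy_surface <- function(x, nlevels = 12, ...) {
  if (length(x$axes) != 2)
    stop("plotting is implemented for two compounds", call. = FALSE)
  px <- x$axes[[1]][x$axes[[1]] > 0]; py <- x$axes[[2]][x$axes[[2]] > 0]
  z <- x$values[x$axes[[1]] > 0, x$axes[[2]] > 0]
  graphics::contour(log10(px), log10(py), z, nlevels = nlevels,
                    xlab = paste0("log10 dose ", names(x$axes)[1]),
                    ylab = paste0("log10 dose ", names(x$axes)[2]), ...)
  invisible(x)
}
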