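# Fixed-point location, eigenvalue classification, damped-oscillation
# onsets, and two-parameter stability maps.

#' Locate the fixed points of a model
#'
#' For the built-in designs the repressor equation is solved exactly for
#' \eqn{y} at each \eqn{x} (its nullcline), reducing the problem to a
#' one-dimensional root search for the activator equation on a dense
#' logarithmic grid; each bracket is polished by Newton iteration on the
#' full planar system.  Custom models use a two-dimensional multi-start
#' Newton search seeded from sign structure on the grid.
#'
#' @param model an \code{oscillator_model}.
#' @param search_box numeric vector \code{c(xmin, xmax, ymin, ymax)}
#'   bounding the search (defaults cover all physical equilibria).
#' @param grid_density number of grid points per decade (built-in designs)
#'   or per axis (custom models); at least 16.
#' @return A list of \code{fixed_point} records, each with coordinates,
#'   eigenvalues, a stability class and the residual norm of the vector
#'   field (guaranteed below 1e-9).  An empty list if no fixed point lies
#'   in the box.
#' @export
find_fixed_points <- function(model, search_box = NULL,
                              grid_density = 200) {
  stopifnot(inherits(model, "oscillator_model"))
  if (grid_density < 16) stop("grid_density must be at least 16")
  if (is.null(search_box))
    search_box <- if (.is_custom(model)) c(-5, 5, -5, 5)
      else c(1e-9, 1e4, 0, 1e6)
  if (!.is_custom(model) &&
      (search_box[1] <= 0 || search_box[2] <= search_box[1]))
    stop("search_box x-range must be positive and increasing")

  pts <- if (.is_custom(model))
    .fp_candidates_2d(model, search_box, grid_density)
  else
    .fp_candidates_1d(model, search_box, grid_density)

  roots <- list()
  for (pt in pts) {
    sol <- .newton_polish(model, pt[1], pt[2])
    if (is.null(sol)) next
    xmin <- if (!.is_custom(model) && model$params$beta == 0) 0
      else search_box[1]
    if (sol$x < xmin - 1e-12 || sol$x > search_box[2] ||
        sol$y < search_box[3] - 1e-12 || sol$y > search_box[4]) next
    dup <- any(vapply(roots, function(r)
      abs(r$x - sol$x) + abs(r$y - sol$y) < 1e-6, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- sol
  }
  roots <- roots[order(vapply(roots, `[[`, numeric(1), "x"))]
  lapply(roots, function(r) .classify_point(model, r$x, r$y))
}

# 1-D reduction: y slaved to its nullcline, scan the activator residual
.fp_candidates_1d <- function(model, box, density) {
  ndec <- log10(box[2] / box[1])
  xs <- 10^seq(log10(box[1]), log10(box[2]),
               length.out = max(64L, ceiling(ndec * density)))
  nc <- nullclines(model, xs)
  yv <- nc$y_y
  Fv <- .x_residual(model, xs, yv)
  idx <- which(Fv[-length(Fv)] * Fv[-1] < 0)
  out <- list()
  # boundary equilibrium on the x = 0 axis (basal activator production
  # vanishes only when beta = 0)
  if (model$params$beta == 0) {
    y0 <- .yy0(model)
    if (abs(.x_residual(model, 0, y0)) < 1e-12)
      out <- list(c(0, y0))
  }
  c(out, lapply(idx, function(i) {
    r <- stats::uniroot(function(x) {
      y <- nullclines(model, x)$y_y
      .x_residual(model, x, y)
    }, c(xs[i], xs[i + 1]), tol = 1e-13)
    y <- nullclines(model, r$root)$y_y
    c(r$root, y)
  }))
}

# repressor nullcline value at x = 0
.yy0 <- function(model) {
  p <- model$params
  if (model$design == "smolen") {
    if (p$m == 1L && p$sigma > 0)
      (-1 + sqrt(1 + 4 * p$sigma * p$delta * p$gamma)) / (2 * p$sigma)
    else .smolen_yy(model, 1e-12)
  } else p$delta * p$gamma
}

# activator-equation residual with y on the repressor nullcline
.x_residual <- function(model, x, y) {
  p <- model$params
  r <- .regulation(model, x, y)
  if (model$design == "design2")
    p$beta * r$H - x * (1 + p$sigma_prime * y)
  else
    p$beta * r$H - x
}

.fp_candidates_2d <- function(model, box, density) {
  density <- min(density, 64L)  # per axis for the planar search
  xs <- seq(box[1], box[2], length.out = density)
  ys <- seq(box[3], box[4], length.out = density)
  grid <- expand.grid(x = xs, y = ys)
  v <- osc_rhs(model, grid$x, grid$y)
  nrm <- sqrt(v[, 1]^2 + v[, 2]^2)
  ord <- order(nrm)[seq_len(min(50L, nrow(grid)))]
  lapply(ord, function(i) c(grid$x[i], grid$y[i]))
}

.newton_polish <- function(model, x, y, max_iter = 60L, tol = 1e-12) {
  nonneg <- !.is_custom(model)
  for (i in seq_len(max_iter)) {
    f <- drop(osc_rhs(model, x, y))
    if (sqrt(sum(f^2)) < tol) return(list(x = x, y = y))
    J <- osc_jacobian(model, x, y)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # damped Newton to stay in the admissible quadrant
    lam <- 1
    repeat {
      xn <- x - lam * step[1]; yn <- y - lam * step[2]
      if (!nonneg || (xn >= 0 && yn >= 0)) break
      lam <- lam / 2
      if (lam < 1e-8) return(NULL)
    }
    if (abs(xn - x) + abs(yn - y) < 1e-15 * (1 + abs(x) + abs(y))) {
      x <- xn; y <- yn
      f <- drop(osc_rhs(model, x, y))
      return(if (sqrt(sum(f^2)) < 1e-9) list(x = x, y = y) else NULL)
    }
    x <- xn; y <- yn
  }
  f <- drop(osc_rhs(model, x, y))
  if (sqrt(sum(f^2)) < 1e-9) list(x = x, y = y) else NULL
}

.classify_point <- function(model, x, y) {
  J <- osc_jacobian(model, x, y)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  stab <- .stability_class(ev)
  f <- drop(osc_rhs(model, x, y))
  structure(list(x = x, y = y, eigenvalues = ev, stability = stab,
                 residual = sqrt(sum(f^2))),
            class = "fixed_point")
}

.stability_class <- function(ev, im_tol = 1e-9) {
  re <- Re(ev); im <- Im(ev)
  if (all(abs(im) < im_tol) && prod(re) < 0) return("saddle")
  complex_pair <- any(abs(im) > im_tol)
  if (max(re) < 0) {
    if (complex_pair) "stable-focus" else "stable-node"
  } else {
    if (complex_pair) "unstable-focus" else "unstable-node"
  }
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point> (%.6g, %.6g)  %s\n", x$x, x$y, x$stability))
  cat(sprintf("  eigenvalues: %.4g%+.4gi, %.4g%+.4gi  residual %.2e\n",
              Re(x$eigenvalues[1]), Im(x$eigenvalues[1]),
              Re(x$eigenvalues[2]), Im(x$eigenvalues[2]), x$residual))
  invisible(x)
}

#' Classify a single equilibrium
#'
#' Refines the supplied point by Newton iteration to residual below 1e-9
#' and classifies it from the eigenvalues of the analytic Jacobian.  A
#' stable focus (complex pair, negative real part) marks locally damped
#' oscillations; an unstable focus is the local signature of sustained
#' oscillation around the point.
#'
#' @param model an \code{oscillator_model}.
#' @param point numeric \code{c(x, y)} with vector-field residual below
#'   1e-6.
#' @return A \code{fixed_point} record.
#' @export
classify_fixed_point <- function(model, point) {
  f0 <- drop(osc_rhs(model, point[1], point[2]))
  if (sqrt(sum(f0^2)) > 1e-6)
    stop("point is not an equilibrium (residual ",
         format(sqrt(sum(f0^2))), " > 1e-6)")
  sol <- .newton_polish(model, point[1], point[2])
  if (is.null(sol)) stop("Newton refinement of the equilibrium failed")
  .classify_point(model, sol$x, sol$y)
}

.scannable <- c("alpha", "beta", "gamma", "sigma", "sigma_prime", "delta")

#' Onset of damped oscillations along a parameter scan
#'
#' Finds the smallest value of a control parameter at which the system has
#' a stable fixed point with complex eigenvalues (locally damped
#' oscillations), bracketing the transition by bisection to a relative
#' tolerance of 1e-4.
#'
#' @param model template \code{oscillator_model}; all parameters other than
#'   the control are taken from it.
#' @param control one of \code{"alpha"}, \code{"beta"}, \code{"gamma"},
#'   \code{"sigma"}, \code{"sigma_prime"}, \code{"delta"}.
#' @param range positive interval \code{c(lo, hi)} scanned upward.
#' @param n_scan number of (log-spaced) pilot points.
#' @return The critical control value, or \code{NA} if the eigenvalues of
#'   every stable fixed point stay real across the range.  If several
#'   stable equilibria coexist with conflicting classifications at the
#'   onset a warning is issued and the attribute \code{"conflict"} is set.
#' @export
damped_onset <- function(model, control, range, n_scan = 400) {
  stopifnot(control %in% .scannable, length(range) == 2L, all(range > 0),
            range[2] > range[1])
  state <- function(v) {
    args <- stats::setNames(list(v), control)
    fps <- find_fixed_points(do.call(set_params, c(list(model), args)))
    stable <- Filter(function(f) startsWith(f$stability, "stable"), fps)
    if (!length(stable)) return("none")
    damped <- vapply(stable, function(f) f$stability == "stable-focus",
                     logical(1))
    if (all(damped)) "damped" else if (any(damped)) "conflict" else "real"
  }
  vs <- 10^seq(log10(range[1]), log10(range[2]), length.out = n_scan)
  st <- vapply(vs, state, character(1))
  hit <- which(st %in% c("damped", "conflict"))
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1L) return(vs[1])
  lo <- vs[i - 1]; hi <- vs[i]
  while ((hi - lo) / hi > 1e-5) {
    mid <- sqrt(lo * hi)
    if (state(mid) %in% c("damped", "conflict")) hi <- mid else lo <- mid
  }
  out <- hi
  if (state(hi) == "conflict") {
    warning("multiple stable equilibria with conflicting classifications ",
            "at the onset")
    attr(out, "conflict") <- TRUE
  }
  out
}

#' Stability map over a two-parameter plane
#'
#' Labels every cell of a parameter grid from the eigenvalues of its fixed
#' points: \code{"no-oscillation"} (a stable equilibrium with real
#' eigenvalues and no instability), \code{"damped"} (a stable focus), or
#' \code{"sustained-candidate"} (no stable equilibrium at all, so a limit
#' cycle must absorb the dynamics).
#'
#' @param model template \code{oscillator_model}.
#' @param plane character vector of two scannable parameter names.
#' @param grid1,grid2 positive parameter grids for the two axes.
#' @return A \code{stability_map} object: list with the grids, a class
#'   matrix (\code{grid1} rows) and matrices \code{re_lambda_max},
#'   \code{im_lambda} of the leading eigenvalue parts.
#' @export
stability_map <- function(model, plane, grid1, grid2) {
  stopifnot(length(plane) == 2L, all(plane %in% .scannable),
            all(grid1 > 0), all(grid2 > 0))
  cls <- matrix(NA_character_, length(grid1), length(grid2))
  rel <- iml <- matrix(NA_real_, length(grid1), length(grid2))
  for (i in seq_along(grid1)) for (j in seq_along(grid2)) {
    args <- stats::setNames(list(grid1[i]), plane[1])
    args[[plane[2]]] <- grid2[j]
    mij <- do.call(set_params, c(list(model), args))
    fps <- find_fixed_points(mij)
    if (!length(fps)) { cls[i, j] <- "no-oscillation"; next }
    stable <- Filter(function(f) startsWith(f$stability, "stable"), fps)
    lead <- fps[[which.max(vapply(fps, function(f) Re(f$eigenvalues[1]),
                                  numeric(1)))]]
    rel[i, j] <- Re(lead$eigenvalues[1])
    iml[i, j] <- abs(Im(lead$eigenvalues[1]))
    cls[i, j] <- if (!length(stable)) "sustained-candidate"
      else if (any(vapply(stable, function(f) f$stability == "stable-focus",
                          logical(1)))) "damped"
      else "no-oscillation"
  }
  structure(list(model = model, plane = plane, grid1 = grid1, grid2 = grid2,
                 class = cls, re_lambda_max = rel, im_lambda = iml),
            class = "stability_map")
}

#' @export
as.data.frame.stability_map <- function(x, ...) {
  data.frame(p1 = rep(x$grid1, times = length(x$grid2)),
             p2 = rep(x$grid2, each = length(x$grid1)),
             class = as.vector(x$class),
             re_lambda_max = as.vector(x$re_lambda_max),
             im_lambda = as.vector(x$im_lambda))
}

#' @export
print.stability_map <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("no-oscillation", "damped",
                                          "sustained-candidate")))
  cat("<stability_map>", x$plane[1], "x", x$plane[2], "grid",
      length(x$grid1), "x", length(x$grid2), "\n")
  print(tab)
  invisible(x)
}
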