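# Rate laws, analytic Jacobians and nullclines.

# Regulation factors and their partial derivatives at (x, y), vectorized.
# H is the activator-promoter factor, G the repressor-promoter factor.
.regulation <- function(model, x, y, derivs = FALSE) {
  p <- model$params
  a <- p$alpha; s <- p$sigma; sp <- p$sigma_prime
  n <- p$n; m <- p$m
  xn <- x^n; ym <- y^m
  num <- 1 + a * xn
  satx <- 1 + xn
  num_x <- a * n * x^(n - 1)
  satx_x <- n * x^(n - 1)
  Gx_shared <- (num_x * satx - num * satx_x) / satx^2

  out <- switch(model$design,
    design1 = , atkinson = {
      den <- satx + s * ym
      list(H = num / den, G = num / satx,
           Hx = if (derivs) (num_x * den - num * satx_x) / den^2,
           Hy = if (derivs) -num * s * m * y^(m - 1) / den^2,
           Gx = if (derivs) Gx_shared, Gy = if (derivs) 0 * x)
    },
    design2 = {
      list(H = num / satx, G = num / satx,
           Hx = if (derivs) Gx_shared, Hy = if (derivs) 0 * x,
           Gx = if (derivs) Gx_shared, Gy = if (derivs) 0 * x)
    },
    design3 = , generalized = {
      den2 <- 1 + s * ym
      list(H = num / (satx * den2), G = num / satx,
           Hx = if (derivs) Gx_shared / den2,
           Hy = if (derivs) -num * s * m * y^(m - 1) / (satx * den2^2),
           Gx = if (derivs) Gx_shared, Gy = if (derivs) 0 * x)
    },
    smolen = {
      den <- satx + s * ym
      Hx <- if (derivs) (num_x * den - num * satx_x) / den^2
      Hy <- if (derivs) -num * s * m * y^(m - 1) / den^2
      list(H = num / den, G = num / den, Hx = Hx, Hy = Hy, Gx = Hx, Gy = Hy)
    },
    stop("no closed-form regulation for design ", model$design))
  out
}

#' Evaluate the vector field of a model
#'
#' Returns \eqn{(dx/d\tau, dy/d\tau)} at the given nondimensional state(s).
#' Vectorized over \code{x} and \code{y}.
#'
#' @param model an \code{oscillator_model}.
#' @param x,y nonnegative state coordinates (activator, repressor).
#' @return A two-column matrix with columns \code{dx} and \code{dy}.
#' @export
osc_rhs <- function(model, x, y) {
  stopifnot(inherits(model, "oscillator_model"))
  if (.is_custom(model)) {
    v <- mapply(function(xi, yi) model$rhs(xi, yi), x, y)
    return(cbind(dx = v[1, ], dy = v[2, ]))
  }
  if (any(x < 0) || any(y < 0))
    stop("state components must be nonnegative")
  p <- model$params
  r <- .regulation(model, x, y)
  dx <- if (model$design == "design2")
    p$delta * (p$beta * r$H - x * (1 + p$sigma_prime * y))
  else
    p$delta * (p$beta * r$H - x)
  dy <- p$delta * p$gamma * r$G - y
  cbind(dx = dx, dy = dy)
}

#' Analytic Jacobian of a model at a state
#'
#' @inheritParams osc_rhs
#' @return A 2x2 matrix of partial derivatives of the vector field.
#' @export
osc_jacobian <- function(model, x, y) {
  stopifnot(inherits(model, "oscillator_model"),
            length(x) == 1L, length(y) == 1L)
  if (.is_custom(model)) {
    if (is.function(model$jacobian)) return(model$jacobian(x, y))
    return(.fd_jacobian(model, x, y))
  }
  if (x < 0 || y < 0) stop("state components must be nonnegative")
  p <- model$params
  r <- .regulation(model, x, y, derivs = TRUE)
  if (model$design == "design2") {
    j11 <- p$delta * (p$beta * r$Hx - (1 + p$sigma_prime * y))
    j12 <- -p$delta * p$sigma_prime * x
  } else {
    j11 <- p$delta * (p$beta * r$Hx - 1)
    j12 <- p$delta * p$beta * r$Hy
  }
  j21 <- p$delta * p$gamma * r$Gx
  j22 <- p$delta * p$gamma * r$Gy - 1
  matrix(c(j11, j12, j21, j22), 2L, 2L, byrow = TRUE,
         dimnames = list(c("dx", "dy"), c("x", "y")))
}

# central finite differences; fallback for custom models and test oracle
.fd_jacobian <- function(model, x, y, h = 1e-6) {
  f <- function(xx, yy) drop(osc_rhs(model, xx, yy))
  cbind((f(x + h, y) - f(x - h, y)) / (2 * h),
        (f(x, y + h) - f(x, y - h)) / (2 * h))
}

#' Nullclines of a model
#'
#' Solves \eqn{dx/d\tau = 0} and \eqn{dy/d\tau = 0} for the repressor level
#' \eqn{y} as a function of activator level \eqn{x}.  \code{y_x} is the
#' activator nullcline (\code{NA} where no nonnegative solution exists);
#' \code{y_y} the repressor nullcline.  Fixed points sit at their
#' intersections.
#'
#' @param model an \code{oscillator_model} with a built-in design.
#' @param x_grid strictly positive, sorted activator values.
#' @return A data frame with columns \code{x}, \code{y_x}, \code{y_y}.
#' @export
nullclines <- function(model, x_grid) {
  stopifnot(inherits(model, "oscillator_model"))
  if (.is_custom(model)) stop("nullclines need a built-in design")
  if (length(x_grid) == 0L) stop("x_grid is empty")
  if (any(x_grid <= 0) || is.unsorted(x_grid))
    stop("x_grid must be positive and sorted")
  p <- model$params
  xn <- x_grid^p$n
  num <- 1 + p$alpha * xn
  satx <- 1 + xn

  y_y <- switch(model$design,
    smolen = .smolen_yy(model, x_grid),
    p$delta * p$gamma * num / satx)

  v <- switch(model$design,
    design1 = , atkinson = , smolen =
      (p$beta * num / x_grid - satx) / p$sigma,
    design3 = , generalized =
      (p$beta * num / (x_grid * satx) - 1) / p$sigma,
    design2 =
      (p$beta * num / (x_grid * satx) - 1) / p$sigma_prime)
  y_x <- if (model$design == "design2") {
    ifelse(v >= 0, v, NA_real_)
  } else {
    ifelse(v >= 0, v^(1 / p$m), NA_real_)
  }
  data.frame(x = x_grid, y_x = y_x, y_y = y_y)
}

# repressor nullcline of the shared-promoter (Smolen) model: solves
# delta*gamma*(1+alpha x^n)/(1+x^n+sigma y^m) = y for y >= 0.
.smolen_yy <- function(model, x_grid) {
  p <- model$params
  xn <- x_grid^p$n
  num <- p$delta * p$gamma * (1 + p$alpha * xn)
  satx <- 1 + xn
  if (p$m == 1L) {
    # sigma*y^2 + satx*y - num = 0
    if (p$sigma == 0) return(num / satx)
    (-satx + sqrt(satx^2 + 4 * p$sigma * num)) / (2 * p$sigma)
  } else {
    vapply(seq_along(x_grid), function(i) {
      f <- function(y) num[i] / (satx[i] + p$sigma * y^p$m) - y
      upper <- num[i] / satx[i]
      if (upper == 0) return(0)
      stats::uniroot(f, c(0, upper), tol = 1e-12)$root
    }, numeric(1))
  }
}
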