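# Trajectory integration and oscillation verdicts.

#' Integrate a trajectory of a model
#'
#' Adaptive error-controlled integration (via \pkg{deSolve}; the built-in
#' designs use a compiled right-hand side).  The output step is kept small
#' enough for reliable peak detection.
#'
#' @param model an \code{oscillator_model}.
#' @param init nonnegative initial state \code{c(x, y)}.
#' @param t_end integration horizon in units of \eqn{1/\delta_R}.
#' @param tol relative tolerance of the integrator.
#' @param dt output step; by default \code{min(0.05, P/50)} where \eqn{P}
#'   is a local period estimate from the imaginary part of the leading
#'   eigenvalue when one is available.
#' @return An \code{osc_orbit}: a matrix with columns \code{time},
#'   \code{x}, \code{y}, carrying the model as an attribute.
#' @export
integrate_orbit <- function(model, init = c(0.1, 0.1), t_end, tol = 1e-8,
                            dt = NULL) {
  stopifnot(inherits(model, "oscillator_model"), t_end > 0)
  if (!.is_custom(model) && any(init < 0))
    stop("initial state must be nonnegative")
  if (is.null(dt)) dt <- min(0.05, .period_guess(model) / 50)
  times <- seq(0, t_end, by = dt)
  out <- if (.is_custom(model)) {
    f <- function(t, s, p) list(drop(osc_rhs(model, s[1], s[2])))
    deSolve::ode(init, times, f, NULL, method = "lsoda",
                 rtol = tol, atol = tol * 1e-2)
  } else {
    deSolve::ode(init, times, func = "osc_derivs", parms = .parm_vector(model),
                 dllname = "oscdesign", initfunc = "osc_initmod",
                 method = "lsoda", rtol = tol, atol = tol * 1e-2)
  }
  if (attr(out, "istate")[1] < 0)
    stop("integration failed (possible stiffness) for design ",
         model$design, " at ",
         paste(names(model$params), unlist(model$params), sep = "=",
               collapse = ", "))
  m <- unclass(out)[, 1:3, drop = FALSE]
  colnames(m) <- c("time", "x", "y")
  structure(m, class = c("osc_orbit", "matrix"), model = model)
}

# rough period scale from the least-stable focus, used only to pick an
# output step; falls back to the repressor timescale
.period_guess <- function(model) {
  if (.is_custom(model)) return(2 * pi)
  im <- tryCatch({
    fps <- find_fixed_points(model)
    ims <- vapply(fps, function(f) abs(Im(f$eigenvalues[1])), numeric(1))
    max(ims)
  }, error = function(e) 0)
  if (is.finite(im) && im > 1e-8) 2 * pi / im else 2 * pi
}

# strict local maxima / minima indices of a series (plateaus collapsed)
.peaks <- function(v) {
  d <- diff(v)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sign(d[nz])
  turn <- which(s[-length(s)] > 0 & s[-1] < 0)
  nz[turn] + 1L
}
.troughs <- function(v) .peaks(-v)

# sub-sample refinement of peak time and height by a parabola through the
# three samples around each maximum; removes the sampling jitter that
# would otherwise dominate the peak-consistency test
.refine_peaks <- function(tt, x, idx) {
  idx <- idx[idx > 1L & idx < length(x)]
  if (!length(idx)) return(list(t = numeric(0), h = numeric(0)))
  a <- x[idx - 1L]; b <- x[idx]; c <- x[idx + 1L]
  den <- a - 2 * b + c
  delta <- ifelse(abs(den) > 1e-300, 0.5 * (a - c) / den, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  dt <- c(diff(tt), tt[length(tt)] - tt[length(tt) - 1L])
  list(t = tt[idx] + delta * dt[idx],
       h = b - 0.25 * (a - c) * delta)
}

#' Summarize an orbit into an oscillation verdict
#'
#' Discards an initial transient, then inspects successive maxima of the
#' activator coordinate.  The verdict is \code{"sustained"} when at least
#' \code{n_peaks_min} consecutive maxima agree in height and spacing to
#' within the stated relative tolerances, \code{"damped"} when maxima decay
#' monotonically toward a limit, \code{"steady"} when the state settles
#' without oscillation, and \code{"undecided"} when the window is too short
#' to tell (a longer \code{t_end} is then needed).
#'
#' @param orbit an \code{osc_orbit}, or any matrix/data frame with columns
#'   \code{time} and \code{x} (optionally \code{y}).
#' @param transient_frac fraction of the window discarded as transient.
#' @param n_peaks_min minimum number of consistent successive maxima.
#' @param eps_amp,eps_per relative tolerances on peak height and spacing.
#' @return An \code{orbit_summary}: verdict, period (sustained only),
#'   peak-to-trough amplitudes of both variables, spikiness (full width at
#'   half maximum over period; low values are pulse-like), and the time
#'   span discarded.
#' @export
summarize_orbit <- function(orbit, transient_frac = 0.5, n_peaks_min = 8,
                            eps_amp = 0.01, eps_per = 0.01) {
  orbit <- as.matrix(as.data.frame(orbit))
  tt <- orbit[, "time"]; x <- orbit[, "x"]
  y <- if ("y" %in% colnames(orbit)) orbit[, "y"] else rep(NA_real_, length(x))
  cut <- tt >= tt[1] + transient_frac * (tt[length(tt)] - tt[1])
  transient <- tt[which(cut)[1]] - tt[1]
  tt <- tt[cut]; x <- x[cut]; y <- y[cut]
  if (length(tt) < 16L) stop("trajectory too short to summarize")

  res <- list(verdict = "steady", period = NA_real_,
              amplitude_x = NA_real_, amplitude_y = NA_real_,
              spikiness = NA_real_, transient_discarded = transient,
              n_peaks = 0L)

  pk <- .peaks(x)
  rngx <- diff(range(x))
  scale <- max(abs(x), 1e-12)
  if (length(pk) < 3L || rngx < 1e-4 * scale) {
    # no usable maxima: steady (flat) or still relaxing
    res$verdict <- if (rngx < 1e-4 * scale) "steady" else "undecided"
    return(structure(res, class = "orbit_summary"))
  }

  ref <- .refine_peaks(tt, x, pk)
  hts <- ref$h; tp <- ref$t
  spac <- diff(tp)
  k <- min(length(pk) - 1L, max(n_peaks_min, 8L))
  last_h <- utils::tail(hts, k + 1L)
  last_s <- utils::tail(spac, k)
  href <- mean(last_h)
  consistent <- length(last_h) >= n_peaks_min &&
    max(abs(last_h - href)) <= eps_amp * abs(href) &&
    max(abs(last_s - mean(last_s))) <= eps_per * mean(last_s)

  tr <- .troughs(x)
  if (consistent) {
    res$verdict <- "sustained"
    res$period <- mean(last_s)
    res$n_peaks <- length(pk)
    win <- tt >= tp[length(tp)] - 3.5 * res$period
    res$amplitude_x <- diff(range(x[win]))
    if (!all(is.na(y))) res$amplitude_y <- diff(range(y[win]))
    res$spikiness <- .spikiness(tt[win], x[win], res$period)
    return(structure(res, class = "orbit_summary"))
  }

  # decaying successive maxima: either damped relaxation onto a focus
  # (cycle amplitude -> 0) or a transient still converging onto a limit
  # cycle from outside (amplitude -> finite).  Distinguish them by the
  # geometric (Aitken) extrapolation of the per-cycle amplitude.
  dh <- diff(hts)
  decaying <- length(hts) >= 3L && all(dh <= 1e-9 * abs(href)) &&
    (hts[1] - hts[length(hts)]) > 1e-3 * max(abs(hts[1]), 1e-12)
  res$n_peaks <- length(pk)
  if (decaying) {
    tro <- .refine_peaks(tt, -x, .troughs(x))
    amps <- vapply(seq_along(tp), function(k) {
      nxt <- which(tro$t > tp[k])
      if (length(nxt)) hts[k] + tro$h[nxt[1]] else NA_real_
    }, numeric(1))
    amps <- amps[is.finite(amps)]
    a_inf <- if (length(amps) >= 3L) {
      n3 <- length(amps)
      a1 <- amps[n3 - 2L]; a2 <- amps[n3 - 1L]; a3 <- amps[n3]
      den <- a1 + a3 - 2 * a2
      ai <- if (abs(den) > 1e-300) (a1 * a3 - a2^2) / den else a3
      if (is.finite(ai)) ai else a3
    } else if (length(amps)) amps[length(amps)] else 0
    a_first <- if (length(amps)) amps[1] else 0
    if (a_inf <= max(0.05 * a_first, 1e-4 * scale)) {
      res$verdict <- "damped"
      return(structure(res, class = "orbit_summary"))
    }
    res$verdict <- "undecided"   # still relaxing onto a finite cycle
    return(structure(res, class = "orbit_summary"))
  }
  res$verdict <- "undecided"
  structure(res, class = "orbit_summary")
}

# full width at half maximum of the last full cycles, relative to period
.spikiness <- function(tt, x, period) {
  if (length(tt) < 8L || !is.finite(period) || period <= 0) return(NA_real_)
  lo <- min(x); hi <- max(x)
  half <- (lo + hi) / 2
  above <- x >= half
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  widths <- (tt[ends] - tt[starts])[r$values]
  # drop clipped first/last runs
  if (r$values[1] && length(widths) > 1L) widths <- widths[-1]
  if (r$values[length(r$values)] && length(widths) > 1L)
    widths <- widths[-length(widths)]
  if (!length(widths)) return(NA_real_)
  min(max(mean(widths) / period, 1e-6), 1)
}

#' @export
print.orbit_summary <- function(x, ...) {
  cat("<orbit_summary>", x$verdict)
  if (identical(x$verdict, "sustained"))
    cat(sprintf(": period %.4g, amplitude x %.4g y %.4g, spikiness %.3g",
                x$period, x$amplitude_x, x$amplitude_y, x$spikiness))
  cat("\n")
  invisible(x)
}

#' Asymptotic verdict for a model
#'
#' Decides whether the model settles to a steady state, exhibits damped
#' oscillations, or reaches a sustained limit cycle, and measures the
#' cycle when there is one.
#'
#' When no stable equilibrium exists the trajectory (which is bounded,
#' since production saturates) must approach a limit cycle, so the orbit
#' is integrated and measured, extending the horizon (doubling, up to
#' \code{t_cap}) until enough consistent peaks accumulate.  When stable
#' equilibria exist the verdict is read from their eigenvalues
#' (\code{"damped"} for a stable focus); set \code{eigen_screen = FALSE}
#' to force the purely trajectory-based verdict instead.  The
#' eigenvalue screen cannot see a stable cycle that coexists with a stable
#' equilibrium (the narrow hysteresis window of a subcritical Hopf); the
#' bifurcation scanner covers that case by parameter continuation.
#'
#' @param model an \code{oscillator_model}.
#' @param init initial state.
#' @param t_start initial integration horizon.
#' @param t_cap maximum horizon; past it the verdict is
#'   \code{"undecided"}.
#' @param eigen_screen use fixed-point eigenvalues to shortcut clearly
#'   non-oscillatory cells.
#' @param tol integrator relative tolerance.
#' @return An \code{orbit_summary} (verdict possibly \code{"undecided"}).
#' @export
classify_asymptotics <- function(model, init = c(0.1, 0.1), t_start = 120,
                                 t_cap = 2000, eigen_screen = TRUE,
                                 tol = 1e-8) {
  fps <- if (.is_custom(model)) list() else find_fixed_points(model)
  stable <- Filter(function(f) startsWith(f$stability, "stable"), fps)

  if (eigen_screen && !.is_custom(model) && length(stable)) {
    verdict <- if (any(vapply(stable, function(f)
      f$stability == "stable-focus", logical(1)))) "damped" else "steady"
    return(structure(list(verdict = verdict, period = NA_real_,
                          amplitude_x = NA_real_, amplitude_y = NA_real_,
                          spikiness = NA_real_, transient_discarded = 0,
                          n_peaks = 0L),
                     class = "orbit_summary"))
  }

  t_end <- t_start
  repeat {
    orb <- integrate_orbit(model, init, t_end, tol = tol)
    s <- summarize_orbit(orb)
    if (s$verdict != "undecided") return(s)
    if (t_end >= t_cap) return(s)
    t_end <- min(2 * t_end, t_cap)
  }
}
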