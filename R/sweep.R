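# Two-dimensional (beta, gamma) period maps and cross-design comparisons.

#' Default transcription-strength grids
#'
#' Log-spaced grids bracketing all parameter pairs studied in the package
#' examples: \eqn{\beta \in [10^{-2}, 10]}, \eqn{\gamma \in [10^{-3}, 1]}.
#'
#' @param n points per axis.
#' @return A list with components \code{beta} and \code{gamma}.
#' @export
default_grids <- function(n = 60) {
  list(beta = 10^seq(-2, 1, length.out = n),
       gamma = 10^seq(-3, 0, length.out = n))
}

#' Period map over the (beta, gamma) plane
#'
#' Classifies every grid cell of transcription-strength space into
#' steady / damped / sustained and measures period, amplitudes and
#' spikiness of the limit cycle on sustained cells.  Cells whose fixed
#' points are all unstable must oscillate (trajectories are bounded) and
#' are integrated to measure the cycle; cells with a stable equilibrium
#' are labeled from its eigenvalues (see
#' \code{\link{classify_asymptotics}}).  Cells still unresolved at the
#' integration cap are flagged undecided.
#'
#' @param model template \code{oscillator_model} (its \code{beta} and
#'   \code{gamma} are overridden cell by cell).
#' @param beta_grid,gamma_grid strictly increasing positive grids.
#' @param t_cap per-cell integration budget in units of \eqn{1/\delta_R}.
#' @param progress print a dot per completed row.
#' @return A \code{period_map}: grids plus matrices \code{verdict}
#'   (character), \code{period}, \code{amp_x}, \code{amp_y},
#'   \code{spikiness}, with \code{beta_grid} indexing rows.
#' @export
sweep_2d <- function(model, beta_grid = default_grids()$beta,
                     gamma_grid = default_grids()$gamma, t_cap = 2000,
                     progress = FALSE) {
  stopifnot(all(beta_grid > 0), all(gamma_grid > 0),
            !is.unsorted(beta_grid, strictly = TRUE),
            !is.unsorted(gamma_grid, strictly = TRUE))
  nb <- length(beta_grid); ng <- length(gamma_grid)
  verdict <- matrix(NA_character_, nb, ng)
  period <- amp_x <- amp_y <- spik <- matrix(NA_real_, nb, ng)
  for (i in seq_len(nb)) {
    for (j in seq_len(ng)) {
      mij <- set_params(model, beta = beta_grid[i], gamma = gamma_grid[j])
      s <- classify_asymptotics(mij, t_cap = t_cap)
      verdict[i, j] <- s$verdict
      period[i, j] <- s$period
      amp_x[i, j] <- s$amplitude_x
      amp_y[i, j] <- s$amplitude_y
      spik[i, j] <- s$spikiness
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(model = model, beta_grid = beta_grid,
                 gamma_grid = gamma_grid, verdict = verdict,
                 period = period, amp_x = amp_x, amp_y = amp_y,
                 spikiness = spik),
            class = "period_map")
}

#' Fraction of parameter space with sustained oscillations
#'
#' @param map a \code{period_map}.
#' @param max_undecided maximal tolerated fraction of undecided cells.
#' @return The sustained-cell fraction, with attribute \code{"count"}
#'   (sustained cells) and \code{"total"}.
#' @export
oscillatory_fraction <- function(map, max_undecided = 0.01) {
  stopifnot(inherits(map, "period_map"))
  und <- mean(map$verdict == "undecided")
  if (und > max_undecided)
    stop(sprintf("map has %.1f%% undecided cells (limit %.1f%%)",
                 100 * und, 100 * max_undecided))
  f <- mean(map$verdict == "sustained")
  attr(f, "count") <- sum(map$verdict == "sustained")
  attr(f, "total") <- length(map$verdict)
  f
}

#' Compare period maps across designs
#'
#' Summarizes each map by its oscillatory fraction and the distribution of
#' periods and activator amplitudes over sustained cells.  The period
#' spread statistic P95/P5 separates integrator-like designs (SNIC-bounded
#' bands, long-tailed periods) from resonator-like ones (Hopf-bounded,
#' characteristic frequency).
#'
#' @param maps named list of \code{period_map}s sharing identical grids.
#' @return A \code{design_comparison}: data frame of summary statistics
#'   plus the per-design period and amplitude samples.
#' @export
compare_designs <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "period_map")))
  ref <- maps[[1]]
  for (m in maps[-1])
    if (!isTRUE(all.equal(m$beta_grid, ref$beta_grid)) ||
        !isTRUE(all.equal(m$gamma_grid, ref$gamma_grid)))
      stop("maps must share identical grids")
  if (is.null(names(maps)))
    names(maps) <- vapply(maps, function(m) m$model$design, character(1))
  qs <- function(v) stats::quantile(v, c(0.05, 0.5, 0.95), na.rm = TRUE,
                                    names = FALSE)
  rows <- lapply(names(maps), function(nm) {
    m <- maps[[nm]]
    sus <- m$verdict == "sustained"
    pq <- qs(m$period[sus]); aq <- qs(m$amp_x[sus])
    data.frame(design = nm, fraction = mean(sus), n_sustained = sum(sus),
               period_p5 = pq[1], period_p50 = pq[2], period_p95 = pq[3],
               period_spread = pq[3] / pq[1],
               amp_p5 = aq[1], amp_p50 = aq[2], amp_p95 = aq[3])
  })
  structure(list(summary = do.call(rbind, rows),
                 periods = lapply(maps, function(m)
                   m$period[m$verdict == "sustained"]),
                 amplitudes = lapply(maps, function(m)
                   m$amp_x[m$verdict == "sustained"])),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("<design_comparison>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Period map of the shared-promoter (Smolen-type) oscillator
#'
#' Convenience wrapper building the competitive shared-promoter model and
#' sweeping the default transcription-strength grids.  In this circuit the
#' activator must be at least a dimer and a substantial degradation-rate
#' ratio is required; with a monomeric activator, or at
#' \eqn{\Delta = 1}, the oscillatory region is empty.
#'
#' @param delta degradation-rate ratio.
#' @param alpha,sigma promoter parameters.
#' @param n,m Hill exponents (activator, repressor; repressor is a
#'   monomer by default).
#' @param ... forwarded to \code{\link{sweep_2d}}.
#' @return A \code{period_map}.
#' @export
smolen_sweep <- function(delta = 4, alpha = 50, sigma = 1, n = 2, m = 1,
                         ...) {
  model <- oscillator_model("smolen", alpha = alpha, sigma = sigma,
                            delta = delta, n = n, m = m)
  sweep_2d(model, ...)
}

#' @export
print.period_map <- function(x, ...) {
  tab <- table(factor(x$verdict,
                      levels = c("steady", "damped", "sustained",
                                 "undecided")))
  cat(sprintf("<period_map> %s, %d x %d cells\n",
              x$model$design, length(x$beta_grid), length(x$gamma_grid)))
  print(tab)
  sus <- x$verdict == "sustained"
  if (any(sus))
    cat(sprintf("  period (sustained): median %.3g, range [%.3g, %.3g]\n",
                stats::median(x$period[sus], na.rm = TRUE),
                min(x$period[sus], na.rm = TRUE),
                max(x$period[sus], na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.period_map <- function(x, ...) {
  data.frame(beta = rep(x$beta_grid, times = length(x$gamma_grid)),
             gamma = rep(x$gamma_grid, each = length(x$beta_grid)),
             verdict = as.vector(x$verdict),
             period = as.vector(x$period),
             amp_x = as.vector(x$amp_x),
             amp_y = as.vector(x$amp_y))
}

#' @export
plot.period_map <- function(x, main = NULL, ...) {
  z <- x$period
  z[x$verdict != "sustained"] <- NA
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(log10(x$beta_grid), log10(x$gamma_grid), z, col = pal,
                  xlab = expression(log[10] ~ beta),
                  ylab = expression(log[10] ~ gamma),
                  main = main %||% sprintf("%s period map", x$model$design),
                  useRaster = TRUE, ...)
  # dark blue marks cells without sustained oscillations
  zz <- ifelse(x$verdict == "sustained", NA_real_, 1)
  graphics::image(log10(x$beta_grid), log10(x$gamma_grid), zz,
                  col = "#00008B", add = TRUE, useRaster = TRUE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
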