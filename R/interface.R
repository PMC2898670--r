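# Run-configuration layer: validated configs, task dispatch, provenance,
# and human-readable reports.

#' Build a validated run configuration
#'
#' @param task one of \code{"simulate"}, \code{"bifurcation"},
#'   \code{"sweep"}, \code{"noise-compare"}, \code{"reproduce-figure"}.
#' @param design design id (or vector of ids where the task compares
#'   designs); ignored by \code{"reproduce-figure"}.
#' @param params named list of model parameters passed to
#'   \code{\link{oscillator_model}}.
#' @param control,range,n control parameter, range and grid size for
#'   \code{"bifurcation"}.
#' @param grid_n per-axis grid size for sweeps.
#' @param t_end horizon for \code{"simulate"}.
#' @param figure figure id for \code{"reproduce-figure"}: one of 3, 4, 5,
#'   6, 7, 9, 10.
#' @param seed integer seed for stochastic tasks.
#' @param outdir output directory (created if needed).
#' @param figures also emit PNG figures.
#' @return A \code{run_config} list.
#' @export
run_config <- function(task, design = "design3", params = list(),
                       control = "beta", range = c(0.01, 10), n = 101,
                       grid_n = 60, t_end = 100, figure = NULL, seed = 1,
                       outdir = tempfile("oscdesign-run-"),
                       figures = FALSE) {
  tasks <- c("simulate", "bifurcation", "sweep", "noise-compare",
             "reproduce-figure")
  if (length(task) != 1L || !task %in% tasks)
    stop("task must be one of: ", paste(tasks, collapse = ", "))
  if (task == "reproduce-figure") {
    if (is.null(figure) || !figure %in% c(3, 4, 5, 6, 7, 9, 10))
      stop("figure must be one of 3, 4, 5, 6, 7, 9, 10")
  } else {
    for (d in design) .match_design(d)  # validates
    # validate parameters by constructing the model
    do.call(oscillator_model, c(list(design = design[1]), params))
  }
  structure(list(task = task, design = design, params = params,
                 control = control, range = range, n = n, grid_n = grid_n,
                 t_end = t_end, figure = figure, seed = seed,
                 outdir = outdir, figures = figures),
            class = "run_config")
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  config$outdir <- NULL  # hash the scientific configuration only
  writeLines(as.character(jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE, digits = NA,
                                           null = "null")), tf)
  unname(tools::md5sum(tf))
}

.write_provenance <- function(config, dir) {
  prov <- list(config = unclass(config), config_hash = .config_hash(config),
               package = "oscdesign",
               version = as.character(utils::packageVersion("oscdesign")),
               seed = config$seed, timestamp = format(Sys.time()))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.model_from_config <- function(config, design = config$design[1]) {
  do.call(oscillator_model, c(list(design = design), config$params))
}

#' Execute a run configuration
#'
#' Dispatches the configured task, writes CSV/JSON outputs plus a
#' provenance record (configuration, its hash, package version, seed) to
#' the output directory, and returns the computed objects invisibly.
#' Reruns with an identical configuration reproduce identical numbers.
#'
#' @param config a \code{run_config}.
#' @return Invisibly, a list with the computed objects and
#'   \code{outdir}.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  out <- switch(config$task,
    "simulate" = .task_simulate(config),
    "bifurcation" = .task_bifurcation(config),
    "sweep" = .task_sweep(config),
    "noise-compare" = .task_noise(config),
    "reproduce-figure" = .task_figure(config))
  .write_provenance(config, config$outdir)
  invisible(c(out, list(outdir = config$outdir)))
}

.task_simulate <- function(config) {
  res <- list()
  for (d in config$design) {
    m <- .model_from_config(config, d)
    orb <- integrate_orbit(m, t_end = config$t_end)
    s <- classify_asymptotics(m)
    utils::write.csv(as.data.frame(unclass(orb)),
                     file.path(config$outdir,
                               sprintf("trajectory-%s.csv", d)),
                     row.names = FALSE)
    jsonlite::write_json(unclass(s),
                         file.path(config$outdir,
                                   sprintf("summary-%s.json", d)),
                         auto_unbox = TRUE, digits = NA, na = "null")
    res[[d]] <- list(orbit = orb, summary = s)
  }
  res
}

.task_bifurcation <- function(config) {
  res <- list()
  for (d in config$design) {
    m <- .model_from_config(config, d)
    vals <- 10^seq(log10(config$range[1]), log10(config$range[2]),
                   length.out = config$n)
    diag <- scan_control(m, config$control, vals)
    utils::write.csv(as.data.frame(diag),
                     file.path(config$outdir, sprintf("diagram-%s.csv", d)),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(diag$events, function(e)
        list(kind = e$kind, control = e$control,
             control_value = e$control_value)),
      file.path(config$outdir, sprintf("events-%s.json", d)),
      auto_unbox = TRUE, digits = NA)
    res[[d]] <- diag
  }
  res
}

.task_sweep <- function(config) {
  g <- default_grids(config$grid_n)
  res <- list()
  for (d in config$design) {
    m <- .model_from_config(config, d)
    map <- sweep_2d(m, g$beta, g$gamma)
    utils::write.csv(as.data.frame(map),
                     file.path(config$outdir, sprintf("map-%s.csv", d)),
                     row.names = FALSE)
    if (config$figures) .png_map(map, config$outdir, sprintf("map-%s.png", d))
    res[[d]] <- map
  }
  if (length(res) > 1L) {
    cmp <- compare_designs(res)
    utils::write.csv(cmp$summary,
                     file.path(config$outdir, "comparison.csv"),
                     row.names = FALSE)
    res$comparison <- cmp
  }
  res
}

.task_noise <- function(config) {
  nc <- noise_induced_analysis(seed = config$seed)
  utils::write.csv(nc$summary, file.path(config$outdir, "noise-summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(nc$intervals, unname),
                       file.path(config$outdir, "noise-intervals.json"),
                       digits = NA)
  list(noise = nc)
}

.task_figure <- function(config) {
  fig <- config$figure
  o <- config$outdir
  sub <- function(task, ...) {
    cfg <- run_config(task, ..., outdir = o, seed = config$seed,
                      grid_n = config$grid_n, figures = config$figures)
    run(cfg)
  }
  switch(as.character(fig),
    "3" = sub("sweep", design = c("design1", "design3"),
              params = list(alpha = 50, delta = 10, sigma = 1)),
    "4" = {
      r1 <- sub("bifurcation", design = c("design1", "design3"),
                params = list(alpha = 50, delta = 10, sigma = 1,
                              gamma = 0.01),
                control = "beta", range = c(0.02, 2), n = 101)
      r2 <- sub("bifurcation", design = c("design1", "design3"),
                params = list(alpha = 50, delta = 10, sigma = 1,
                              gamma = 0.05),
                control = "beta", range = c(0.02, 2), n = 101)
      list(gamma_0.01 = r1, gamma_0.05 = r2)
    },
    "5" = {
      r1 <- sub("bifurcation", design = c("design1", "design3"),
                params = list(alpha = 50, beta = 1.58, gamma = 0.079,
                              sigma = 1),
                control = "delta", range = c(1, 40), n = 101)
      r2 <- sub("bifurcation", design = c("design1", "design3"),
                params = list(alpha = 50, beta = 0.2, gamma = 0.04,
                              sigma = 1),
                control = "delta", range = c(1, 40), n = 101)
      list(set_A = r1, set_B = r2)
    },
    "6" = sub("simulate", design = c("design1", "design3"),
              params = list(alpha = 50, delta = 11, beta = 1.58,
                            gamma = 0.079, sigma = 1),
              t_end = 60),
    "7" = {
      res <- list()
      for (m_exp in 1:3) {
        mod <- oscillator_model("generalized", alpha = 50, delta = 1,
                                n = 3, m = m_exp)
        g <- default_grids(config$grid_n)
        map <- sweep_2d(mod, g$beta, g$gamma)
        utils::write.csv(as.data.frame(map),
                         file.path(o, sprintf("map-generalized-m%d.csv",
                                              m_exp)),
                         row.names = FALSE)
        res[[sprintf("m%d", m_exp)]] <- map
      }
      res
    },
    "9" = sub("sweep", design = c("atkinson", "design3"),
              params = list(alpha = 50, delta = 10, sigma = 1)),
    "10" = {
      g <- default_grids(config$grid_n)
      map <- smolen_sweep(delta = 4, beta_grid = g$beta,
                          gamma_grid = g$gamma)
      utils::write.csv(as.data.frame(map),
                       file.path(o, "map-smolen.csv"), row.names = FALSE)
      list(smolen = map)
    })
}

.png_map <- function(map, dir, file) {
  grDevices::png(file.path(dir, file), width = 800, height = 700)
  on.exit(grDevices::dev.off())
  plot(map)
}

#' Summarize a run directory as markdown
#'
#' Reads the provenance record and the CSV/JSON outputs of a completed
#' \code{\link{run}} and renders a short markdown report (verdict counts,
#' oscillatory fractions, detected events).
#'
#' @param bundle the \code{outdir} of a completed run, or the list
#'   returned by \code{\link{run}}.
#' @return A character vector of markdown lines.
#' @export
report <- function(bundle) {
  dir <- if (is.character(bundle)) bundle else bundle$outdir
  if (is.null(dir) || !dir.exists(dir)) stop("no run directory found")
  pf <- file.path(dir, "provenance.json")
  if (!file.exists(pf)) stop("missing provenance.json; incomplete bundle")
  prov <- jsonlite::fromJSON(pf)
  lines <- c(sprintf("# oscdesign run report"),
             sprintf("- task: `%s`", prov$config$task),
             sprintf("- config hash: `%s`", prov$config_hash),
             sprintf("- seed: %s", prov$seed), "")
  for (f in list.files(dir, pattern = "^map-.*\\.csv$", full.names = TRUE)) {
    d <- utils::read.csv(f)
    frac <- mean(d$verdict == "sustained")
    und <- sum(d$verdict == "undecided")
    lines <- c(lines,
               sprintf("- `%s`: oscillatory fraction %.4f (%d cells)%s",
                       basename(f), frac, nrow(d),
                       if (und > 0)
                         sprintf(", **%d undecided cells flagged**", und)
                       else ""))
  }
  cmpf <- file.path(dir, "comparison.csv")
  if (file.exists(cmpf)) {
    cmp <- utils::read.csv(cmpf)
    lines <- c(lines, "", "## Design comparison",
               sprintf("- %s: fraction %.4f, period spread (P95/P5) %.3g",
                       cmp$design, cmp$fraction, cmp$period_spread))
    if (nrow(cmp) > 1L) {
      best <- cmp$design[which.max(cmp$fraction)]
      lines <- c(lines, sprintf("- widest oscillatory region: **%s**", best))
    }
  }
  for (f in list.files(dir, pattern = "^events-.*\\.json$",
                       full.names = TRUE)) {
    ev <- jsonlite::fromJSON(f)
    if (length(ev))
      lines <- c(lines, "", sprintf("## Events (`%s`)", basename(f)),
                 sprintf("- %s at %s = %.5g", ev$kind, ev$control,
                         ev$control_value))
  }
  for (f in list.files(dir, pattern = "^summary-.*\\.json$",
                       full.names = TRUE)) {
    s <- jsonlite::fromJSON(f)
    lines <- c(lines,
               sprintf("- `%s`: verdict %s%s", basename(f), s$verdict,
                       if (identical(s$verdict, "sustained"))
                         sprintf(", period %.4g (units of 1/delta_R)",
                                 s$period) else ""))
  }
  lines
}
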