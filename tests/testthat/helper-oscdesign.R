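# Shared fixtures: reference parameter sets, planar normal forms, and a
# cache so expensive sweeps/diagrams are computed once per session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

ref_model <- function(design, ...) {
  defaults <- list(alpha = 50, delta = 10, sigma = 1)
  args <- utils::modifyList(defaults, list(...))
  if (design == "design2") { args$sigma <- NULL; args$sigma_prime <- 1 }
  do.call(oscillator_model, c(list(design = design), args))
}

fig6_model <- function(design)
  ref_model(design, beta = 1.58, gamma = 0.079, delta = 11)

# supercritical Hopf normal form, rotation frequency 1
hopf_normal_form <- function(mu) oscillator_model("custom",
  rhs = function(x, y) c(mu * x - y - x * (x^2 + y^2),
                         x + mu * y - y * (x^2 + y^2)),
  jacobian = function(x, y)
    matrix(c(mu - 3 * x^2 - y^2, -1 - 2 * x * y,
             1 - 2 * x * y, mu - x^2 - 3 * y^2), 2, 2, byrow = TRUE))

# saddle-node on an invariant circle: attracting unit circle with
# theta' = mu - sin(theta); period 2*pi/sqrt(mu^2 - 1) for mu > 1
snic_normal_form <- function(mu) oscillator_model("custom",
  rhs = function(x, y) {
    r2 <- x^2 + y^2
    th <- mu - y / max(sqrt(r2), 1e-12)
    c(x * (1 - r2) - y * th, y * (1 - r2) + x * th)
  })

random_admissible_states <- function(n, seed = 42) {
  set.seed(seed)
  cbind(x = 10^stats::runif(n, -2, 1.3), y = 10^stats::runif(n, -2, 1.3))
}

# reference bifurcation scans (used by several test files)
diagram_design1_g05 <- function()
  cached("dI_g05", function()
    scan_control(ref_model("design1", gamma = 0.05), "beta",
                 10^seq(log10(0.02), log10(2), length.out = 80)))

diagram_design3_g05 <- function()
  cached("dIII_g05", function()
    scan_control(ref_model("design3", gamma = 0.05), "beta",
                 10^seq(log10(0.02), log10(8), length.out = 80)))

diagram_design3_g01 <- function()
  cached("dIII_g01", function()
    scan_control(ref_model("design3", gamma = 0.01), "beta",
                 10^seq(log10(0.02), log10(2), length.out = 80)))

# reference 60x60 period maps at alpha = 50, delta = 10, sigma = 1
ref_map <- function(design) {
  cached(paste0("map60_", design), function() {
    g <- default_grids(60)
    sweep_2d(ref_model(design), g$beta, g$gamma)
  })
}
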