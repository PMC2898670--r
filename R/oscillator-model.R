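#' @useDynLib oscdesign, .registration = TRUE
NULL

# Internal design registry.  `code` is the integer passed to the compiled
# right-hand side; `n`/`m` give the fixed or default Hill (multimerization)
# exponents of activator and repressor.
.designs <- list(
  design1     = list(code = 1L, n = 2L, m = 2L, fixed_exp = TRUE,
                     label = "Design I (competitive binding)"),
  design2     = list(code = 2L, n = 2L, m = 2L, fixed_exp = TRUE,
                     label = "Design II (post-translational inhibition)"),
  design3     = list(code = 3L, n = 2L, m = 2L, fixed_exp = TRUE,
                     label = "Design III (non-competitive binding)"),
  generalized = list(code = 4L, n = 2L, m = 2L, fixed_exp = FALSE,
                     label = "Generalized non-competitive Hill model"),
  atkinson    = list(code = 5L, n = 4L, m = 4L, fixed_exp = TRUE,
                     label = "Atkinson full-competition model (tetramers)"),
  smolen      = list(code = 6L, n = 2L, m = 1L, fixed_exp = FALSE,
                     label = "Smolen shared-promoter competition model")
)

.design_aliases <- c(
  "i" = "design1", "design_i" = "design1", "design i" = "design1",
  "competition" = "design1", "design1" = "design1",
  "ii" = "design2", "design_ii" = "design2", "design ii" = "design2",
  "design2" = "design2",
  "iii" = "design3", "design_iii" = "design3", "design iii" = "design3",
  "non-competition" = "design3", "design3" = "design3",
  "generalized" = "generalized", "gen" = "generalized",
  "atkinson" = "atkinson", "atk" = "atkinson",
  "smolen" = "smolen", "smo" = "smolen",
  "custom" = "custom"
)

.match_design <- function(design) {
  key <- .design_aliases[tolower(design)]
  if (is.na(key))
    stop("unknown design '", design, "'; use one of: ",
         paste(unique(.design_aliases), collapse = ", "), call. = FALSE)
  unname(key)
}

#' Construct a two-gene oscillator model
#'
#' Builds a nondimensional activator--repressor circuit model.  The
#' activator gene is positively autoregulated and (except for the
#' post-translational design) negatively regulated by the repressor at its
#' promoter; the repressor gene is activated by the activator.  With time
#' measured in units of the repressor protein lifetime \eqn{1/\delta_R} and
#' both transcription--translation strengths scaled by the activator
#' degradation rate \eqn{\delta_A}, the families are
#' \describe{
#'   \item{\code{"design1"} (competition)}{\eqn{\dot x = \Delta[\beta(1+\alpha x^2)/(1+x^2+\sigma y^2) - x]};
#'     activator and repressor bind mutually exclusively, so their promoter
#'     occupancies sum in the denominator.}
#'   \item{\code{"design2"} (post-translational)}{\eqn{\dot x = \Delta[\beta(1+\alpha x^2)/(1+x^2) - x(1+\sigma' y)]};
#'     the repressor catalyses activator degradation instead of binding DNA.}
#'   \item{\code{"design3"} (non-competition)}{\eqn{\dot x = \Delta[\beta(1+\alpha x^2)/\{(1+x^2)(1+\sigma y^2)\} - x]};
#'     each factor has its own site, so occupancy factors multiply
#'     (equivalently a \eqn{\sigma x^2 y^2} cross term appears).}
#'   \item{\code{"generalized"}}{Design III with free integer Hill exponents
#'     \eqn{n} (activator) and \eqn{m} (repressor).}
#'   \item{\code{"atkinson"}}{the Design I form with quartic terms
#'     (\eqn{n = m = 4}), the effective model of a circuit in which paired
#'     dimers loop DNA.}
#'   \item{\code{"smolen"}}{both genes read the same competitively regulated
#'     promoter, with a monomeric repressor by default:
#'     \eqn{\dot x = \Delta[\beta(1+\alpha x^n)/(1+x^n+\sigma y^m) - x]} and the
#'     same regulation factor in the repressor gene.}
#' }
#' All designs except \code{"smolen"} share the repressor law
#' \eqn{\dot y = \Delta\gamma(1+\alpha x^n)/(1+x^n) - y}.
#'
#' A \code{"custom"} design takes user-supplied \code{rhs(x, y, ...)} and
#' optional \code{jacobian(x, y, ...)} functions; it is intended for planar
#' normal-form systems used to validate the bifurcation classifiers.
#'
#' @param design design id (case-insensitive; \code{"I"}, \code{"II"},
#'   \code{"III"}, \code{"design1"}, ..., \code{"generalized"},
#'   \code{"atkinson"}, \code{"smolen"}, \code{"custom"}).
#' @param alpha fold-activation of the activator-bound promoter relative to
#'   the basal state (dimensionless, > 1 for an activator).
#' @param beta activator transcription--translation strength (dimensionless).
#' @param gamma repressor transcription--translation strength (dimensionless).
#' @param sigma DNA-binding ratio of the repressor multimer relative to the
#'   activator's (dimensionless).
#' @param sigma_prime strength of repressor-catalysed activator degradation;
#'   only meaningful (and only accepted) for \code{"design2"}.
#' @param delta ratio of degradation rates \eqn{\Delta = \delta_A/\delta_R};
#'   must be positive.
#' @param n,m integer Hill exponents of activator and repressor.  Fixed at
#'   2 for designs I--III, at 4 for \code{"atkinson"}; free for
#'   \code{"generalized"} and \code{"smolen"}.
#' @param rhs,jacobian functions for \code{design = "custom"}:
#'   \code{rhs(x, y)} returns \code{c(dx, dy)}; \code{jacobian(x, y)} a
#'   2x2 matrix.  Extra model parameters should be captured in their
#'   closures.
#'
#' @return An object of class \code{oscillator_model}.
#' @examples
#' m <- oscillator_model("design3", alpha = 50, beta = 1.58, gamma = 0.079,
#'                       delta = 11)
#' osc_rhs(m, 0.5, 0.5)
#' @export
oscillator_model <- function(design, alpha = 50, beta = 1, gamma = 0.1,
                             sigma = 1, sigma_prime = NULL, delta = 10,
                             n = NULL, m = NULL,
                             rhs = NULL, jacobian = NULL) {
  key <- .match_design(design)

  if (identical(key, "custom")) {
    if (!is.function(rhs))
      stop("a custom design requires an `rhs(x, y)` function")
    mod <- structure(list(design = "custom", rhs = rhs, jacobian = jacobian,
                          params = list()),
                     class = "oscillator_model")
    return(mod)
  }

  reg <- .designs[[key]]
  if (is.null(n)) n <- reg$n
  if (is.null(m)) m <- reg$m
  .check_exponent(n, "n"); .check_exponent(m, "m")
  if (reg$fixed_exp && (n != reg$n || m != reg$m))
    stop(sprintf("%s has fixed Hill exponents n = %d, m = %d", reg$label,
                 reg$n, reg$m))

  if (!is.null(sigma_prime) && key != "design2")
    stop("sigma_prime is the catalytic-degradation strength of design2 ",
         "and cannot be set for ", key)
  if (is.null(sigma_prime)) sigma_prime <- if (key == "design2") 1 else 0

  for (nm in c("alpha", "beta", "gamma", "sigma", "sigma_prime", "delta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter `", nm, "` must be a finite nonnegative number")
  }
  if (delta <= 0) stop("delta (= delta_A/delta_R) must be > 0")

  structure(list(design = key,
                 params = list(alpha = alpha, beta = beta, gamma = gamma,
                               sigma = sigma, sigma_prime = sigma_prime,
                               delta = delta,
                               n = as.integer(n), m = as.integer(m))),
            class = "oscillator_model")
}

.check_exponent <- function(v, name) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
      v < 1 || abs(v - round(v)) > 1e-8)
    stop("Hill exponent `", name,
         "` must be a positive integer (multimer degree)")
  invisible(TRUE)
}

# parameter vector handed to the compiled right-hand side
.parm_vector <- function(model) {
  p <- model$params
  c(.designs[[model$design]]$code, p$alpha, p$beta, p$gamma, p$sigma,
    p$sigma_prime, p$delta, p$n, p$m)
}

.is_custom <- function(model) identical(model$design, "custom")

#' Replace named parameters of a model
#'
#' Convenience used by parameter scans: returns a copy of the model with
#' the given parameters replaced (revalidated through the constructor).
#'
#' @param model an \code{oscillator_model}.
#' @param ... named parameter values, e.g. \code{beta = 0.3}.
#' @return A new \code{oscillator_model}.
#' @export
set_params <- function(model, ...) {
  stopifnot(inherits(model, "oscillator_model"))
  if (.is_custom(model))
    stop("set_params() does not apply to custom models")
  upd <- list(...)
  bad <- setdiff(names(upd), c("alpha", "beta", "gamma", "sigma",
                               "sigma_prime", "delta", "n", "m"))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(model$params, upd)
  if (model$design != "design2") {
    sp <- NULL
  } else {
    sp <- p$sigma_prime
  }
  oscillator_model(model$design, alpha = p$alpha, beta = p$beta,
                   gamma = p$gamma, sigma = p$sigma, sigma_prime = sp,
                   delta = p$delta, n = p$n, m = p$m)
}

#' @export
print.oscillator_model <- function(x, ...) {
  if (.is_custom(x)) {
    cat("<oscillator_model: custom planar vector field>\n")
    return(invisible(x))
  }
  cat("<oscillator_model>", .designs[[x$design]]$label, "\n")
  p <- x$params
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g, sigma = %g%s\n",
              p$alpha, p$beta, p$gamma, p$sigma,
              if (x$design == "design2")
                sprintf(", sigma' = %g", p$sigma_prime) else ""))
  cat(sprintf("  delta = %g (delta_A/delta_R), exponents n = %d, m = %d\n",
              p$delta, p$n, p$m))
  invisible(x)
}

#' Serialize a model to JSON and back
#'
#' @param model an \code{oscillator_model} (built-in designs only).
#' @return \code{model_to_json}: a JSON string; \code{model_from_json}: an
#'   \code{oscillator_model}.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "oscillator_model"))
  if (.is_custom(model)) stop("custom models cannot be serialized")
  jsonlite::toJSON(c(list(design = model$design), model$params),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname model_to_json
#' @param json JSON string produced by \code{model_to_json}.
#' @export
model_from_json <- function(json) {
  spec <- jsonlite::fromJSON(json)
  oscillator_model(spec$design, alpha = spec$alpha, beta = spec$beta,
                   gamma = spec$gamma, sigma = spec$sigma,
                   sigma_prime = if (spec$design == "design2")
                     spec$sigma_prime else NULL,
                   delta = spec$delta, n = spec$n, m = spec$m)
}

#' Convert a nondimensional period to hours
#'
#' Model time is measured in units of the repressor lifetime
#' \eqn{1/\delta_R}, so a dimensionless period \eqn{P} corresponds to
#' \eqn{P/\delta_R} hours.
#'
#' @param period_nondim dimensionless period(s).
#' @param delta_R repressor degradation rate in \eqn{h^{-1}}; must be > 0.
#' @return Period(s) in hours.
#' @examples
#' to_hours(2, 0.02)  # 100 h
#' @export
to_hours <- function(period_nondim, delta_R) {
  if (!is.numeric(delta_R) || length(delta_R) != 1L || !is.finite(delta_R) ||
      delta_R <= 0)
    stop("delta_R must be a positive rate (per hour)")
  period_nondim / delta_R
}
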