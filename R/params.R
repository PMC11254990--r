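#' Structural pharmacokinetic parameters on the unbound scale
#'
#' Container for one individual's docetaxel parameters. Disposition is
#' parameterised for the unbound drug (a three-compartment mammillary model
#' with linear elimination); total concentrations are obtained from the
#' unbound prediction through a route-specific fraction unbound, because the
#' IV formulation carries additional polysorbate-80 binding that the oral
#' tablets do not.
#'
#' Units: clearances in L/h, volumes in L, `ka` in 1/h, `tlag` in h;
#' `f_oral`, `fu_iv` and `fu_po` are dimensionless fractions in (0, 1].
#' Setting `q2_u` and/or `q3_u` to zero removes the corresponding peripheral
#' compartment, giving two- and one-compartment disposition as special cases.
#'
#' @param cl_u Unbound clearance (L/h), > 0.
#' @param v1_u Unbound central volume (L), > 0.
#' @param v2_u,v3_u Unbound peripheral volumes (L), >= 0.
#' @param q2_u,q3_u Unbound inter-compartmental clearances (L/h), >= 0.
#' @param ka First-order absorption rate constant (1/h), > 0.
#' @param tlag Absorption lag time (h), >= 0.
#' @param f_oral Absolute oral bioavailability, in (0, 1].
#' @param fu_iv,fu_po Fraction unbound after IV / oral dosing, in (0, 1].
#' @return An object of class `structural_params` (a named list).
#' @examples
#' p <- structural_params(cl_u = 8570, v1_u = 1200, v2_u = 3700, v3_u = 58500,
#'                        q2_u = 1040, q3_u = 1940, ka = 0.35, tlag = 0.5,
#'                        f_oral = 0.25, fu_iv = 0.0067, fu_po = 0.0102)
#' total_cl_from_unbound(p$cl_u, p$fu_iv)
#' @export
structural_params <- function(cl_u, v1_u, v2_u = 0, v3_u = 0,
                              q2_u = 0, q3_u = 0,
                              ka = 1, tlag = 0, f_oral = 1,
                              fu_iv = 1, fu_po = 1) {
  p <- list(cl_u = cl_u, v1_u = v1_u, v2_u = v2_u, v3_u = v3_u,
            q2_u = q2_u, q3_u = q3_u, ka = ka, tlag = tlag,
            f_oral = f_oral, fu_iv = fu_iv, fu_po = fu_po)
  p <- lapply(p, as.numeric)
  class(p) <- "structural_params"
  validate_structural_params(p)
  p
}

#' @rdname structural_params
#' @param params An object to validate.
#' @export
validate_structural_params <- function(params) {
  stopifnot(inherits(params, "structural_params"))
  num <- unlist(params)
  if (any(!is.finite(num)))
    stop("structural parameters must be finite: ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  chk <- function(cond, msg) if (!cond) stop("invalid structural parameters: ", msg)
  chk(params$cl_u > 0, "cl_u must be > 0")
  chk(params$v1_u > 0, "v1_u must be > 0")
  chk(params$v2_u >= 0 && params$v3_u >= 0, "peripheral volumes must be >= 0")
  chk(params$q2_u >= 0 && params$q3_u >= 0, "inter-compartmental clearances must be >= 0")
  chk(params$q2_u == 0 || params$v2_u > 0, "v2_u must be > 0 when q2_u > 0")
  chk(params$q3_u == 0 || params$v3_u > 0, "v3_u must be > 0 when q3_u > 0")
  chk(params$ka > 0, "ka must be > 0")
  chk(params$tlag >= 0, "tlag must be >= 0")
  chk(params$f_oral > 0 && params$f_oral <= 1, "f_oral must be in (0, 1]")
  chk(params$fu_iv > 0 && params$fu_iv <= 1, "fu_iv must be in (0, 1]")
  chk(params$fu_po > 0 && params$fu_po <= 1, "fu_po must be in (0, 1]")
  invisible(params)
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Unbound-scale structural PK parameters:\n")
  print(unlist(x))
  invisible(x)
}

.theta_names <- function() {
  c("cl_u", "v1_u", "v2_u", "v3_u", "q2_u", "q3_u",
    "ka", "tlag", "f_oral", "fu_iv", "fu_po")
}

#' Population pharmacokinetic model
#'
#' Typical structural values plus the stochastic components of the population
#' model: log-normal between-subject variability (exponential eta model) and
#' a combined additive + proportional residual-error model for each observable
#' (total and unbound concentration), with an optional correlation `rho_l2`
#' between the standardized residuals of the total and unbound measurement
#' taken from the same blood sample (the "L2" structure).
#'
#' @param theta A [structural_params()] object of typical values.
#' @param omega_sd Named numeric vector of between-subject standard deviations
#'   on the log scale; names must be structural parameter names. Parameters
#'   not named (or named with value 0) carry no variability.
#' @param omega_corr Optional correlation matrix for the etas of the
#'   parameters named in `omega_sd` (default: identity, i.e. a diagonal
#'   omega matrix).
#' @param sigma_add Named numeric vector `c(total = , unbound = )` of additive
#'   residual SDs in ng/mL.
#' @param sigma_prop Named numeric vector `c(total = , unbound = )` of
#'   proportional residual SDs (fractions).
#' @param rho_l2 Correlation of the standardized residual pair from one blood
#'   sample, in (-1, 1).
#' @return An object of class `population_model`.
#' @seealso [sample_individuals()], [apply_residual_error()],
#'   [default_population_model()]
#' @export
population_model <- function(theta,
                             omega_sd = numeric(0),
                             omega_corr = NULL,
                             sigma_add = c(total = 0, unbound = 0),
                             sigma_prop = c(total = 0, unbound = 0),
                             rho_l2 = 0) {
  validate_structural_params(theta)
  omega_sd <- omega_sd[omega_sd != 0]
  if (length(omega_sd)) {
    if (is.null(names(omega_sd)) || !all(names(omega_sd) %in% .theta_names()))
      stop("omega_sd must be named with structural parameter names")
    if (any(omega_sd < 0)) stop("omega_sd must be >= 0")
  }
  if (!is.null(omega_corr)) {
    k <- length(omega_sd)
    if (!is.matrix(omega_corr) || any(dim(omega_corr) != k))
      stop("omega_corr must be a ", k, " x ", k, " matrix")
    if (any(abs(omega_corr - t(omega_corr)) > 1e-12) || any(diag(omega_corr) != 1))
      stop("omega_corr must be a symmetric correlation matrix")
  }
  sigma_add <- .sigma_vec(sigma_add, "sigma_add")
  sigma_prop <- .sigma_vec(sigma_prop, "sigma_prop")
  if (any(sigma_add < 0) || any(sigma_prop < 0))
    stop("residual error magnitudes must be >= 0")
  if (!is.finite(rho_l2) || abs(rho_l2) >= 1)
    stop("rho_l2 must lie strictly within (-1, 1)")
  structure(list(theta = theta, omega_sd = omega_sd, omega_corr = omega_corr,
                 sigma_add = sigma_add, sigma_prop = sigma_prop,
                 rho_l2 = rho_l2),
            class = "population_model")
}

.sigma_vec <- function(x, what) {
  if (is.null(names(x))) {
    if (length(x) == 1) x <- c(total = unname(x), unbound = unname(x))
    else if (length(x) == 2) names(x) <- c("total", "unbound")
    else stop(what, " must name observables 'total' and 'unbound'")
  }
  if (!all(c("total", "unbound") %in% names(x)))
    stop(what, " must name observables 'total' and 'unbound'")
  x[c("total", "unbound")]
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model\n  typical values:\n")
  print(unlist(x$theta))
  cat("  BSV (log-scale SD):\n")
  if (length(x$omega_sd)) print(x$omega_sd) else cat("    none\n")
  cat("  residual error: additive (ng/mL) ",
      paste(sprintf("%s=%g", names(x$sigma_add), x$sigma_add), collapse = ", "),
      "; proportional ",
      paste(sprintf("%s=%g", names(x$sigma_prop), x$sigma_prop), collapse = ", "),
      "\n  L2 residual correlation rho = ", x$rho_l2, "\n", sep = "")
  invisible(x)
}

#' Default docetaxel population model
#'
#' A complete population model anchored to the values reported for the joint
#' IV / oral-plus-encequidar analysis: unbound clearance 8570 L/h, oral
#' bioavailability 25%, fraction unbound 0.67% (IV) and 1.02% (oral), and
#' unbound volumes whose total-scale steady-state volume is about 425 L
#' (total clearance about 57.3 L/h). The remaining typical values,
#' between-subject variabilities and residual-error magnitudes are synthetic
#' defaults chosen to be realistic for docetaxel; they are documented in the
#' package vignette and are not fitted estimates.
#'
#' @return A [population_model()].
#' @examples
#' pop <- default_population_model()
#' total_cl_from_unbound(pop$theta$cl_u, pop$theta$fu_iv)  # ~57.4 L/h
#' @export
default_population_model <- function() {
  theta <- structural_params(
    cl_u = 8570, v1_u = 1200, v2_u = 3700, v3_u = 58500,
    q2_u = 1040, q3_u = 1940,
    ka = 0.35, tlag = 0.5, f_oral = 0.25,
    fu_iv = 0.0067, fu_po = 0.0102)
  population_model(
    theta = theta,
    omega_sd = c(cl_u = 0.35, v1_u = 0.30, v2_u = 0.25, v3_u = 0.25,
                 q2_u = 0.25, q3_u = 0.25, ka = 0.45, f_oral = 0.30,
                 fu_iv = 0.15, fu_po = 0.15),
    sigma_add = c(total = 0.5, unbound = 0.02),
    sigma_prop = c(total = 0.20, unbound = 0.25),
    rho_l2 = 0.5)
}

#' Read or write a model configuration file
#'
#' The configuration is a YAML (or JSON) document with sections `theta`,
#' `omega` and `sigma`, keys matching the structural parameter names. `omega`
#' holds log-scale SDs (section `sd`) and an optional correlation matrix
#' (section `corr`); `sigma` holds `add`, `prop` and `rho_l2`. Values from a
#' fitted-model table (for example a supplementary parameter table) can be
#' dropped in verbatim.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `read_model_config()` returns a [population_model()];
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$theta)) stop("config must contain a 'theta' section")
  theta <- do.call(structural_params, as.list(cfg$theta))
  omega_sd <- numeric(0)
  omega_corr <- NULL
  if (!is.null(cfg$omega)) {
    omega_sd <- unlist(cfg$omega$sd)
    if (!is.null(cfg$omega$corr)) {
      omega_corr <- do.call(rbind, lapply(cfg$omega$corr, as.numeric))
      dimnames(omega_corr) <- NULL
    }
  }
  sig <- cfg$sigma
  population_model(theta, omega_sd = omega_sd, omega_corr = omega_corr,
                   sigma_add = unlist(sig$add %||% c(total = 0, unbound = 0)),
                   sigma_prop = unlist(sig$prop %||% c(total = 0, unbound = 0)),
                   rho_l2 = sig$rho_l2 %||% 0)
}

#' @rdname read_model_config
#' @param pop A [population_model()] to serialize.
#' @export
write_model_config <- function(pop, path) {
  stopifnot(inherits(pop, "population_model"))
  cfg <- list(theta = lapply(unclass(pop$theta), unname),
              omega = list(sd = as.list(pop$omega_sd)),
              sigma = list(add = as.list(pop$sigma_add),
                           prop = as.list(pop$sigma_prop),
                           rho_l2 = pop$rho_l2))
  if (!is.null(pop$omega_corr))
    cfg$omega$corr <- apply(pop$omega_corr, 1, as.numeric, simplify = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
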