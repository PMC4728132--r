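#' Model parameters for the Cdc42/Bem1-GEF polarity model
#'
#' Constructs the parameter set of the membrane-cytosol reaction-diffusion
#' model. Membrane-bound GDP-Cdc42 (`Cdc42Dm`) is loaded with GTP by the
#' Bem1-GEF complex, either membrane-associated (`BemGEFm`, rate `k2a`) or
#' already bound to GTP-Cdc42 (`BemGEF42`, rate `k3`); GAP-driven hydrolysis
#' is first order (`k2b`); the GDI shuttles GDP-Cdc42 between cytoplasm and
#' membrane (`k5a`, `k5b`); the Bem1-GEF complex attaches/detaches (`k1a`,
#' `k1b`), binds GTP-Cdc42 from the membrane (`k4a`/`k4b`) or directly from
#' the cytoplasm (`k7`). Membrane attachment of Bem1-GEF is subject to
#' Gaussian white noise of strength `s`.
#'
#' Defaults are the published parameter set for this model. Concentrations
#' are carried in uM; membrane fields are shell concentrations, so a
#' polarized peak reaches order 10^2-10^3 uM. Totals are cytosol-equivalent:
#' `total = eta * spatial-mean(membrane species) + cytosol pool`.
#'
#' @param k1a,k1b Bem1-GEF cytosol->membrane and membrane->cytosol rates (1/s).
#' @param s Strength of the Gaussian white noise on Bem1-GEF membrane
#'   attachment (applied mass-neutrally against the cytosolic pool).
#' @param k2a GEF-catalyzed nucleotide exchange by BemGEFm (1/(uM s)).
#' @param k2b GAP-mediated GTP hydrolysis (1/s).
#' @param k3 Nucleotide exchange catalyzed by BemGEF42 (1/(uM s)).
#' @param k4a,k4b BemGEFm + Cdc42T binding (1/(uM s)) and unbinding (1/s).
#' @param k5a,k5b GDI-mediated Cdc42D cytosol->membrane (1/s) and
#'   membrane->cytosol (1/s) exchange.
#' @param k7 Recruitment of cytosolic Bem1-GEF by GTP-Cdc42 (1/(uM s)).
#' @param Dm Membrane diffusion coefficient, shared by all membrane species
#'   (um^2/s).
#' @param eta Membrane-to-cytoplasm volume ratio (dimensionless).
#' @param area_A Membrane surface area (um^2).
#' @param total_cdc42,total_bemgef Conserved totals (uM, cytosol-equivalent).
#' @return An object of class `polar_params`: a named list of rates and
#'   geometry with all entries validated non-negative.
#' @examples
#' p <- default_parameters()
#' p$k2b  # 1.75 1/s
#' @export
model_parameters <- function(k1a = 10, k1b = 10, s = 1e-4,
                             k2a = 0.16, k2b = 1.75, k3 = 0.35,
                             k4a = 10, k4b = 10, k5a = 36, k5b = 0.65,
                             k7 = 10, Dm = 0.0025, eta = 0.01,
                             area_A = 25 * pi,
                             total_cdc42 = 1, total_bemgef = 0.017) {
  p <- list(k1a = k1a, k1b = k1b, s = s, k2a = k2a, k2b = k2b, k3 = k3,
            k4a = k4a, k4b = k4b, k5a = k5a, k5b = k5b, k7 = k7,
            Dm = Dm, eta = eta, area_A = area_A,
            total_cdc42 = total_cdc42, total_bemgef = total_bemgef)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x < 0, logical(1))
  if (any(bad))
    stop("parameters must be single non-negative finite numbers: ",
         paste(names(p)[bad], collapse = ", "))
  structure(p, class = "polar_params")
}

#' Default (published) parameter set
#'
#' @return The default `polar_params` object (see [model_parameters()]).
#' @export
default_parameters <- function() model_parameters()

#' @export
print.polar_params <- function(x, ...) {
  cat("Cdc42/Bem1-GEF polarity model parameters\n")
  cat(sprintf("  rates (1/s): k1a=%g k1b=%g k2b=%g k4b=%g k5a=%g k5b=%g\n",
              x$k1a, x$k1b, x$k2b, x$k4b, x$k5a, x$k5b))
  cat(sprintf("  rates (1/(uM s)): k2a=%g k3=%g k4a=%g k7=%g\n",
              x$k2a, x$k3, x$k4a, x$k7))
  cat(sprintf("  Dm=%g um^2/s  eta=%g  A=%g um^2  noise s=%g\n",
              x$Dm, x$eta, x$area_A, x$s))
  cat(sprintf("  totals (uM, cytosol-equivalent): Cdc42=%g BemGEF=%g\n",
              x$total_cdc42, x$total_bemgef))
  invisible(x)
}

#' Read / write a parameter set as a flat key-value config file
#'
#' Plain YAML with keys named as the rate-constant symbols
#' (`k1a`, ..., `k7`, `s`, `Dm`, `eta`, `area_A`, `total_cdc42`,
#' `total_bemgef`). Unknown keys are an error; missing keys take defaults.
#'
#' @param path File path.
#' @param params A `polar_params` object.
#' @return `read_parameters()` returns a `polar_params`;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(model_parameters))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  do.call(model_parameters, vals)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "polar_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
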