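#' Model parameter set
#'
#' Constructs and validates the full parameter vector of the virus-host
#' coevolution model family.
#'
#' @param l immunity decay rate (immune -> sensitive flow), per unit time, >= 0.
#' @param e immunity acquisition rate (sensitive -> immune upon surviving an
#'   encounter), per unit time, >= 0.
#' @param d virus death rate, > 0.
#' @param M virus reproduction rate (dimensionless burst factor), > 0.
#' @param b encounter rate coefficient, > 0.
#' @param a host density-dependence coefficient; `a = 0` gives Malthusian
#'   (exponential) host growth, `a > 0` logistic growth.
#' @param k steepness of the immunity decline with virus density, > 0 (used
#'   only in virus-dependent immunity mode).
#' @param s innate immunity of sensitive hosts, 0 < s < 1.
#' @param p_const constant immunity level of the immune class,
#'   s <= p_const <= 1 (used only in constant immunity mode).
#'
#' @details The growth rates of both host classes are fixed at 1 (the time
#'   unit of the model); they are not exposed as parameters.
#'
#' @return An object of class `"vh_params"` (a named list).
#' @export
vh_params <- function(l = 0.1, e = 0.5, d = 1, M = 100, b = 0.05, a = 0,
                      k = 0.1, s = 0.2, p_const = NA_real_) {
  p <- list(l = l, e = e, d = d, M = M, b = b, a = a, k = k, s = s,
            p_const = p_const)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L)
      stop("parameter '", nm, "' must be a single numeric value", call. = FALSE)
  }
  if (p$l < 0 || p$e < 0 || p$a < 0)
    stop("rates l, e and coefficient a must be nonnegative", call. = FALSE)
  if (p$d <= 0 || p$M <= 0 || p$b <= 0 || p$k <= 0)
    stop("d, M, b, k must be strictly positive", call. = FALSE)
  if (p$s <= 0 || p$s >= 1)
    stop("innate immunity s must satisfy 0 < s < 1", call. = FALSE)
  if (!is.na(p$p_const) && (p$p_const < p$s || p$p_const > 1))
    stop("constant immunity p_const must satisfy s <= p_const <= 1",
         call. = FALSE)
  structure(p, class = "vh_params")
}

#' Model variant specification
#'
#' Selects one of the model variants: two- or three-component state, Malthusian
#' or logistic host growth, constant or virus-density-dependent immunity.
#'
#' @param components `"two"` (immune hosts x, viruses z) or `"three"`
#'   (immune x, sensitive y, viruses z).
#' @param growth `"malthusian"` (requires `a = 0`) or `"logistic"`
#'   (requires `a > 0`).
#' @param immunity `"constant"` (uses `p_const`) or `"virus_dependent"`
#'   (immunity `p(z) = (1 - s) exp(-k z) + s`).
#'
#' @return An object of class `"vh_model"`.
#' @export
vh_model <- function(components = c("three", "two"),
                     growth = c("logistic", "malthusian"),
                     immunity = c("virus_dependent", "constant")) {
  m <- structure(list(components = match.arg(components),
                      growth = match.arg(growth),
                      immunity = match.arg(immunity)),
                 class = "vh_model")
  m
}

#' @export
print.vh_model <- function(x, ...) {
  cat(sprintf("<vh_model> %s-component, %s growth, %s immunity\n",
              x$components, x$growth, x$immunity))
  invisible(x)
}

#' @export
print.vh_params <- function(x, ...) {
  vals <- vapply(unclass(x), function(v) format(v, digits = 6), character(1))
  cat("<vh_params> ", paste(names(vals), vals, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Check model/params consistency; stops on violation.
check_model_params <- function(model, params) {
  stopifnot(inherits(model, "vh_model"), inherits(params, "vh_params"))
  if (model$growth == "malthusian" && params$a != 0)
    stop("malthusian growth requires a = 0", call. = FALSE)
  if (model$growth == "logistic" && params$a <= 0)
    stop("logistic growth requires a > 0", call. = FALSE)
  if (model$immunity == "constant" && is.na(params$p_const))
    stop("constant immunity mode requires p_const", call. = FALSE)
  invisible(TRUE)
}

# Number of state variables of a model variant.
n_components <- function(model) if (model$components == "three") 3L else 2L

# Canonical state names for a model variant.
state_names <- function(model) {
  if (model$components == "three") c("x", "y", "z") else c("x", "z")
}

# Coerce/validate a state vector for a model variant.
as_state <- function(state, model) {
  n <- n_components(model)
  if (length(state) != n)
    stop("state must have ", n, " components for a ", model$components,
         "-component model", call. = FALSE)
  state <- as.numeric(state)
  if (any(!is.finite(state)))
    stop("state must be finite", call. = FALSE)
  if (any(state < 0))
    stop("state coordinates must be nonnegative", call. = FALSE)
  names(state) <- state_names(model)
  state
}
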