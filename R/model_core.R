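#' Host immunity as a function of virus density
#'
#' In virus-dependent mode the immunity of the immune host class declines
#' monotonically with the virus load, `p(z) = (1 - s) exp(-k z) + s`: it is
#' maximal (1) at zero virus density and tends to the innate level `s` as the
#' virus density grows. In constant mode it is simply `p_const`.
#'
#' @param z virus density (>= 0), vectorized.
#' @param params a [vh_params()] object.
#' @param mode `"virus_dependent"` or `"constant"`.
#' @return Immunity level(s) in `[s, 1]`.
#' @export
immunity <- function(z, params, mode = c("virus_dependent", "constant")) {
  mode <- match.arg(mode)
  if (any(z < 0)) stop("virus density z must be nonnegative", call. = FALSE)
  if (mode == "constant") {
    if (is.na(params$p_const))
      stop("constant immunity mode requires p_const", call. = FALSE)
    rep_len(params$p_const, length(z))
  } else {
    (1 - params$s) * exp(-params$k * z) + params$s
  }
}

#' Derivative of the immunity law with respect to virus density
#'
#' Equals `k (s - p(z))` in virus-dependent mode (always <= 0) and 0 in
#' constant mode.
#'
#' @inheritParams immunity
#' @return dp/dz, vectorized over `z`.
#' @export
immunity_derivative <- function(z, params,
                                mode = c("virus_dependent", "constant")) {
  mode <- match.arg(mode)
  if (any(z < 0)) stop("virus density z must be nonnegative", call. = FALSE)
  if (mode == "constant") rep_len(0, length(z))
  else params$k * (params$s - immunity(z, params, mode))
}

#' Right-hand side of the coevolution model
#'
#' Time derivatives of the population densities. Three-component model:
#' \deqn{dx/dt = x(1 - l - a(x+y)) - b x z (1-p) + e s y z}
#' \deqn{dy/dt = y + l x - a y (x+y) - b y z (1-s) - e s y z}
#' \deqn{dz/dt = z(-d + b M (x(1-p) + y(1-s)) - b (x p + y s))}
#' Two-component model:
#' \deqn{dx/dt = x(1 - a x - b z (1-p)), \quad
#'       dz/dt = z(-d - b x p + b M x (1-p))}
#' with the immunity `p` evaluated according to the model's immunity mode.
#'
#' @param model a [vh_model()] object.
#' @param state nonnegative state vector `(x, y, z)` or `(x, z)`.
#' @param params a [vh_params()] object.
#' @return Named numeric vector of time derivatives.
#' @export
vh_rhs <- function(model, state, params) {
  check_model_params(model, params)
  state <- as_state(state, model)
  vh_rhs_raw(model, state, params)
}

# RHS without validation (hot path for the integrator / root finders).
vh_rhs_raw <- function(model, state, params) {
  p <- immunity_value(state[[length(state)]], params, model$immunity)
  l <- params$l; e <- params$e; d <- params$d; M <- params$M
  b <- params$b; a <- params$a; s <- params$s
  if (model$components == "three") {
    x <- state[[1L]]; y <- state[[2L]]; z <- state[[3L]]
    c(x = x * (1 - l - a * (x + y)) - b * x * z * (1 - p) + e * s * y * z,
      y = y + l * x - a * y * (x + y) - b * y * z * (1 - s) - e * s * y * z,
      z = z * (-d + b * M * (x * (1 - p) + y * (1 - s)) -
                 b * (x * p + y * s)))
  } else {
    x <- state[[1L]]; z <- state[[2L]]
    c(x = x * (1 - a * x - b * z * (1 - p)),
      z = z * (-d - b * x * p + b * M * x * (1 - p)))
  }
}

# scalar immunity without input checks
immunity_value <- function(z, params, mode) {
  if (mode == "constant") params$p_const
  else (1 - params$s) * exp(-params$k * z) + params$s
}

immunity_slope <- function(z, params, mode) {
  if (mode == "constant") 0
  else params$k * (params$s - immunity_value(z, params, mode))
}

#' Analytic Jacobian of the coevolution model
#'
#' Matrix of partial derivatives of [vh_rhs()] with respect to the state,
#' with the immunity derivative `dp/dz` included in the virus column.
#'
#' @inheritParams vh_rhs
#' @return A square numeric matrix (3x3 or 2x2) with dimnames set to the
#'   state names.
#' @export
vh_jacobian <- function(model, state, params) {
  check_model_params(model, params)
  state <- as_state(state, model)
  vh_jacobian_raw(model, state, params)
}

vh_jacobian_raw <- function(model, state, params) {
  z <- state[[length(state)]]
  p <- immunity_value(z, params, model$immunity)
  pz <- immunity_slope(z, params, model$immunity)
  l <- params$l; e <- params$e; d <- params$d; M <- params$M
  b <- params$b; a <- params$a; s <- params$s
  if (model$components == "three") {
    x <- state[[1L]]; y <- state[[2L]]
    J <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    J[1, 1] <- 1 - l - a * (2 * x + y) - b * z * (1 - p)
    J[1, 2] <- -a * x + e * s * z
    J[1, 3] <- -b * x * (1 - p) + b * x * z * pz + e * s * y
    J[2, 1] <- l - a * y
    J[2, 2] <- 1 - a * (x + 2 * y) - b * z * (1 - s) - e * s * z
    J[2, 3] <- -b * y * (1 - s) - e * s * y
    J[3, 1] <- z * b * (M * (1 - p) - p)
    J[3, 2] <- z * b * (M * (1 - s) - s)
    J[3, 3] <- -d + b * M * (x * (1 - p) + y * (1 - s)) -
      b * (x * p + y * s) - b * (M + 1) * x * z * pz
    J
  } else {
    x <- state[[1L]]
    J <- matrix(0, 2, 2, dimnames = list(c("x", "z"), c("x", "z")))
    J[1, 1] <- 1 - 2 * a * x - b * z * (1 - p)
    J[1, 2] <- -b * x * (1 - p) + b * x * z * pz
    J[2, 1] <- z * b * (M * (1 - p) - p)
    J[2, 2] <- -d + b * x * (M * (1 - p) - p) - b * (M + 1) * x * z * pz
    J
  }
}
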