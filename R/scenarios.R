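#' Named scenarios
#'
#' A registry of named parameter fixtures covering the documented dynamical
#' regimes of the model family: the Malthusian quasi-chaotic regime (fig1),
#' the logistic stable-equilibrium / limit-cycle / quasi-chaotic cascade in
#' the virus reproduction rate (fig2, fig3, fig4, fig5_6), the fold domains
#' of the two-component logistic model (af1_domain0/1/2), the two-parameter
#' Hopf-curve settings (af4_eH, af4_lH, af4_sH) and a conservative
#' two-component demonstration (conservative_demo). The virus death rate
#' defaults to `d = 1` wherever the reference setting leaves it unstated
#' (noted in each provenance string).
#'
#' @param name scenario identifier; see Details.
#' @return Object of class `"vh_scenario"`: list with `name`, `model`,
#'   `params`, `init` (a state vector or the string `"at_equilibrium"`),
#'   `perturb` (relative perturbation applied to equilibrium starts),
#'   `t_end`, `provenance`, and optional Hopf-curve fields (`free_param`,
#'   `M_grid`, `bracket`).
#' @export
scenario <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  sc <- reg[[name]]
  sc$name <- name
  structure(sc, class = "vh_scenario")
}

#' @rdname scenario
#' @export
scenario_names <- function() names(scenario_registry())

scenario_registry <- function() {
  fig2_params <- vh_params(l = 0.1, e = 0.5, d = 1, M = 98.225, b = 0.05,
                           a = 1, k = 0.1, s = 0.2)
  af1_params <- vh_params(l = 0.1, e = 0.5, d = 1, M = 25, b = 0.1, a = 1,
                          k = 1, s = 0.15)
  list(
    fig1 = list(
      model = vh_model("three", "malthusian", "virus_dependent"),
      params = vh_params(l = 0.9, e = 0.1, d = 1, M = 100, b = 0.01, a = 0,
                         k = 0.5, s = 0.1),
      init = c(x = 0.07, y = 0.15, z = 22.25), perturb = 0, t_end = 1e4,
      provenance = "Reference Malthusian aperiodic-oscillation parameter set (l > e regime)"),
    fig2 = list(
      model = vh_model("three", "logistic", "virus_dependent"),
      params = fig2_params,
      init = "at_equilibrium", perturb = 0.01, t_end = 20000,
      provenance = "Reference logistic family at M = 98.225: coexistence equilibrium with weakly damped oscillations (d = 1 default)"),
    fig3 = list(
      model = vh_model("three", "logistic", "virus_dependent"),
      params = set_param(fig2_params, "M", 98.226),
      init = "at_equilibrium", perturb = 0.5, t_end = 30000,
      provenance = "Reference logistic family at M = 98.226: large coexisting limit cycle (d = 1 default)"),
    fig4 = list(
      model = vh_model("three", "logistic", "virus_dependent"),
      params = set_param(fig2_params, "M", 98.226),
      init = "at_equilibrium", perturb = 0.5, t_end = 30000,
      provenance = "Reference logistic family at M = 98.226: established limit-cycle phase curve, window 5000 < t < 30000"),
    fig5_6 = list(
      model = vh_model("three", "logistic", "virus_dependent"),
      params = set_param(fig2_params, "M", 500),
      init = "at_equilibrium", perturb = 0.5, t_end = 20000,
      provenance = "Reference logistic family far above threshold (M = 500): large relaxation oscillations"),
    af1_domain0 = list(
      model = vh_model("two", "logistic", "virus_dependent"),
      params = set_param(af1_params, "M", 12),
      init = c(x = 0.5, z = 5), perturb = 0, t_end = 2000,
      provenance = "Two-component logistic fold diagram, domain 0: no interior equilibria at M = 12"),
    af1_domain1 = list(
      model = vh_model("two", "logistic", "virus_dependent"),
      params = af1_params,
      init = c(x = 0.5, z = 5), perturb = 0, t_end = 2000,
      provenance = "Two-component logistic fold diagram, domain 1: saddle + stable node/spiral at M = 25"),
    af1_domain2 = list(
      model = vh_model("two", "logistic", "virus_dependent"),
      params = set_param(af1_params, "M", 100),
      init = c(x = 0.5, z = 5), perturb = 0, t_end = 2000,
      provenance = "Two-component logistic fold diagram, domain 2: spiral inside an unstable limit cycle at M = 100"),
    af4_eH = list(
      model = vh_model("three", "logistic", "virus_dependent"),
      params = vh_params(l = 0.1, e = 0.5, d = 1, M = 100, b = 0.05, a = 1,
                         k = 0.2, s = 0.2),
      init = "at_equilibrium", perturb = 0, t_end = NA_real_,
      free_param = "e", M_grid = c(700, 750, 800, 850, 900),
      bracket = c(0.02, 2),
      provenance = "Hopf curve e_H(M) at l = 0.1, s = 0.2, b = 0.05, k = 0.2 (d = 1 default)"),
    af4_lH = list(
      model = vh_model("three", "logistic", "virus_dependent"),
      params = vh_params(l = 0.1, e = 0.5, d = 1, M = 100, b = 0.05, a = 1,
                         k = 0.2, s = 0.2),
      init = "at_equilibrium", perturb = 0, t_end = NA_real_,
      free_param = "l", M_grid = c(700, 750, 800),
      bracket = c(0.01, 0.8),
      provenance = "Hopf curve l_H(M) at e = 0.5, s = 0.2, b = 0.05, k = 0.2 (d = 1 default)"),
    af4_sH = list(
      model = vh_model("three", "logistic", "virus_dependent"),
      params = vh_params(l = 0.1, e = 0.5, d = 1, M = 100, b = 0.05, a = 1,
                         k = 0.2, s = 0.2),
      init = "at_equilibrium", perturb = 0, t_end = NA_real_,
      free_param = "s", M_grid = c(450, 550, 650),
      bracket = c(0.05, 0.3),
      provenance = "Hopf curve s_H(M) at l = 0.1, e = 0.5, b = 0.05, k = 0.2 (d = 1 default)"),
    conservative_demo = list(
      model = vh_model("two", "malthusian", "constant"),
      params = vh_params(l = 0.1, e = 0.5, d = 1, M = 100, b = 0.01, a = 0,
                         k = 0.1, s = 0.2, p_const = 0.5),
      init = c(x = 1.5, z = 150), perturb = 0, t_end = 1e4,
      provenance = "Conservative two-component Malthusian model with constant immunity p = 0.5 (package demonstration scenario)")
  )
}

#' @export
print.vh_scenario <- function(x, ...) {
  cat(sprintf("<vh_scenario> %s: %s-component %s/%s; t_end = %s\n  %s\n",
              x$name, x$model$components, x$model$growth, x$model$immunity,
              format(x$t_end), x$provenance))
  invisible(x)
}

#' Resolve a scenario's initial state
#'
#' Scenarios may declare `init = "at_equilibrium"`, meaning the interior
#' equilibrium of the scenario's parameters perturbed by a relative offset.
#' With a `seed`, the perturbation direction is randomized (recorded in the
#' result's attributes); otherwise the deterministic uniform offset
#' `state * (1 + perturb)` is used.
#'
#' @param sc a `vh_scenario`.
#' @param seed optional integer seed for a random perturbation direction.
#' @return Initial state vector.
#' @export
scenario_init <- function(sc, seed = NULL) {
  if (!identical(sc$init, "at_equilibrium")) return(sc$init)
  eqs <- interior_equilibria(sc$model, sc$params)
  if (length(eqs) == 0L)
    stop("scenario '", sc$name, "' has no interior equilibrium to start from",
         call. = FALSE)
  st <- eqs[[1L]]$state
  if (is.null(seed)) {
    st * (1 + sc$perturb)
  } else {
    set.seed(seed)
    dir <- stats::rnorm(length(st))
    dir <- dir / sqrt(sum(dir^2))
    out <- pmax(st * (1 + sc$perturb * dir), 1e-8)
    attr(out, "seed") <- seed
    out
  }
}

#' Round-trip a scenario through its flat serialized form
#'
#' Scenarios serialize to a flat key-value list (JSON-compatible) and back
#' without loss; used by the command-line interface config handling.
#'
#' @param sc a `vh_scenario`.
#' @return A flat named list.
#' @export
scenario_serialize <- function(sc) {
  out <- list(name = sc$name,
              components = sc$model$components, growth = sc$model$growth,
              immunity = sc$model$immunity, t_end = sc$t_end,
              perturb = sc$perturb, provenance = sc$provenance)
  out <- c(out, stats::setNames(unclass(sc$params),
                                paste0("param_", names(sc$params))))
  if (is.character(sc$init)) out$init <- sc$init
  else out <- c(out, stats::setNames(as.list(sc$init),
                                     paste0("init_", names(sc$init))))
  out
}

#' @rdname scenario_serialize
#' @param flat a flat list produced by [scenario_serialize()].
#' @export
scenario_deserialize <- function(flat) {
  pn <- grep("^param_", names(flat), value = TRUE)
  params <- do.call(vh_params, stats::setNames(flat[pn], sub("^param_", "", pn)))
  init <- if (!is.null(flat$init)) flat$init else {
    inn <- grep("^init_", names(flat), value = TRUE)
    stats::setNames(as.numeric(unlist(flat[inn])), sub("^init_", "", inn))
  }
  structure(list(name = flat$name,
                 model = vh_model(flat$components, flat$growth, flat$immunity),
                 params = params, init = init, perturb = flat$perturb,
                 t_end = flat$t_end, provenance = flat$provenance),
            class = "vh_scenario")
}
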