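#' Time integration of the coevolution models
#'
#' Adaptive-step integration (deSolve's lsoda family, with the analytic
#' Jacobian supplied) with dense output at a fixed sampling step, extinction
#' event recording and a blow-up guard that truncates the run when any
#' coordinate exceeds an overflow bound.
#'
#' The quasi-chaotic regimes are tolerance-sensitive: the defaults
#' (`rtol = 1e-9`, `atol = 1e-12`) are tight enough that regime-level
#' statistics are robust, although individual chaotic trajectories are only
#' shadowing-level accurate pointwise.
#'
#' @inheritParams vh_rhs
#' @param init initial state (nonnegative, length matching the variant).
#' @param t_end final time (> 0).
#' @param dt output sampling step (default 0.1 time units).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param floor extinction floor: crossings below it are recorded as events
#'   (default 1e-12).
#' @param overflow blow-up guard; integration stops when any coordinate
#'   exceeds it (default 1e12).
#' @return Object of class `"vh_trajectory"`: list with `times`, `states`
#'   (matrix, one column per state variable), `events` (data frame of
#'   time/label), `model`, `params`, and `stats` (tolerances, sampling step).
#' @export
integrate_model <- function(model, params, init, t_end, dt = 0.1,
                            rtol = 1e-9, atol = 1e-12, floor = 1e-12,
                            overflow = 1e12) {
  check_model_params(model, params)
  init <- as_state(init, model)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  nms <- state_names(model)
  func <- function(t, y, parms) list(vh_rhs_raw(model, y, params))
  jacf <- function(t, y, parms) vh_jacobian_raw(model, y, params)
  rootf <- function(t, y, parms) max(y) - overflow
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  sol <- deSolve::lsodar(y = init, times = times, func = func, parms = NULL,
                         jacfunc = jacf, rootfunc = rootf,
                         rtol = rtol, atol = atol, maxsteps = 50000)
  tms <- sol[, 1L]
  states <- sol[, nms, drop = FALSE]
  events <- data.frame(time = numeric(0), label = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(attr(sol, "iroot")) && tms[length(tms)] < t_end - dt / 2) {
    events <- rbind(events, data.frame(time = tms[length(tms)],
                                       label = "unbounded"))
  }
  for (nm in nms) {
    below <- which(states[, nm] < floor)
    if (length(below) > 0L)
      events <- rbind(events,
                      data.frame(time = tms[below[1L]],
                                 label = paste0("extinction_", nm)))
  }
  structure(list(times = tms, states = states, events = events,
                 model = model, params = params,
                 stats = list(rtol = rtol, atol = atol, dt = dt,
                              n_out = length(tms))),
            class = "vh_trajectory")
}

#' @export
print.vh_trajectory <- function(x, ...) {
  cat(sprintf("<vh_trajectory> %d samples over t in [%g, %g]%s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              if (nrow(x$events)) paste0("; events: ",
                paste(x$events$label, collapse = ", ")) else ""))
  invisible(x)
}

#' Write a trajectory to CSV with a metadata sidecar
#'
#' The CSV has header `t,x,y,z` (or `t,x,z` for two-component models); the
#' sidecar `<path>.meta.json` records the model variant, parameters,
#' tolerances and events.
#'
#' @param traj a `vh_trajectory`.
#' @param path output CSV path.
#' @param digits significant digits for serialization (default 12).
#' @return `path`, invisibly.
#' @export
trajectory_to_csv <- function(traj, path, digits = 12) {
  df <- data.frame(t = signif(traj$times, digits),
                   signif(traj$states, digits), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(model = unclass(traj$model),
               params = unclass(traj$params),
               stats = traj$stats,
               events = traj$events)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Conserved quantity of the two-component Malthusian constant-immunity model
#'
#' With Malthusian host growth (`a = 0`) and constant immunity `p`, the
#' two-component model is conservative with invariant
#' \deqn{G(x, z) = \ln|z| + d \ln|x| - b(M(1-p) - p) x - b(1-p) z.}
#'
#' @param x,z host and virus densities (> 0), vectorized.
#' @param params a [vh_params()] object (uses `p_const`).
#' @return Value(s) of G.
#' @export
hamiltonian_value <- function(x, z, params) {
  p <- params$p_const
  if (is.na(p)) stop("hamiltonian_value requires p_const", call. = FALSE)
  log(z) + params$d * log(x) -
    params$b * (params$M * (1 - p) - p) * x - params$b * (1 - p) * z
}

#' Conservation monitor: drift of the invariant along a trajectory
#'
#' Integrates the two-component Malthusian constant-immunity model and returns
#' the maximum absolute drift of the invariant G from its initial value, a
#' direct measure of integrator fidelity on the conservative case.
#'
#' The monitor defaults to tighter tolerances (`rtol = 1e-11`,
#' `atol = 1e-14`) than generic integration: in a conservative system errors
#' accumulate secularly instead of being damped, and wide orbits of the
#' center pass through regions of fast motion where the invariant is
#' sensitive to step error.
#'
#' @param params a [vh_params()] object with `a = 0` and `p_const` set.
#' @param init initial state `(x, z)`, both > 0.
#' @param t_end integration horizon (default 1e4).
#' @param rtol,atol integration tolerances (conservation-monitor defaults).
#' @param ... passed to [integrate_model()] (sampling step, guards).
#' @return List with `drift` (max |G(t) - G(0)|) and the `trajectory`.
#' @export
hamiltonian_drift <- function(params, init, t_end = 1e4, rtol = 1e-11,
                              atol = 1e-14, ...) {
  if (params$a != 0)
    stop("the conservative case requires Malthusian growth (a = 0)",
         call. = FALSE)
  if (is.na(params$p_const))
    stop("the conservative case requires constant immunity", call. = FALSE)
  if (any(init <= 0)) stop("init must be strictly positive", call. = FALSE)
  model <- vh_model("two", "malthusian", "constant")
  traj <- integrate_model(model, params, init, t_end, rtol = rtol,
                          atol = atol, ...)
  G <- hamiltonian_value(traj$states[, "x"], traj$states[, "z"], params)
  list(drift = max(abs(G - G[1L])), trajectory = traj)
}
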