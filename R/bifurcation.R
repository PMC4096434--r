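#' @title Bifurcation localization
#' @description Locates the organizing bifurcations of the model family: the
#'   transcritical exchange of stability between the virus-free state A and
#'   the coexistence state B, the Hopf threshold in the virus reproduction
#'   rate (and two-parameter Hopf curves), the saddle-node of the
#'   two-component logistic model with virus-dependent immunity, and the
#'   codimension-2 Bogdanov-Takens point organizing them.
#' @name bifurcation
NULL

new_bifpoint <- function(kind, param_name, param_value, equilibrium,
                         omega = NA_real_, diagnostics = list()) {
  structure(list(kind = kind, param_name = param_name,
                 param_value = param_value, equilibrium = equilibrium,
                 omega = omega, diagnostics = diagnostics),
            class = "vh_bifpoint")
}

#' @export
print.vh_bifpoint <- function(x, ...) {
  cat(sprintf("<vh_bifpoint> %s at %s = %.8g%s\n", x$kind, x$param_name,
              x$param_value,
              if (is.finite(x$omega)) sprintf(" (omega = %.6g)", x$omega)
              else ""))
  invisible(x)
}

set_param <- function(params, name, value) {
  if (!name %in% names(params))
    stop("unknown parameter '", name, "'", call. = FALSE)
  params[[name]] <- value
  params
}

#' Transcritical threshold of the virus reproduction rate
#'
#' For the logistic model the virus-free equilibrium A exchanges stability
#' with the coexistence equilibrium at
#' \deqn{M^{tc} = (a d + b s) / (b (1 - s)):}
#' the third eigenvalue of A crosses zero there and the interior virus
#' density tends to zero from above.
#'
#' @param params a [vh_params()] object with `a > 0`.
#' @return The threshold value of `M`.
#' @export
transcritical_M <- function(params) {
  if (params$a <= 0)
    stop("transcritical threshold applies to the logistic model (a > 0)",
         call. = FALSE)
  if (params$s >= 1) stop("s must be < 1", call. = FALSE)
  (params$a * params$d + params$b * params$s) / (params$b * (1 - params$s))
}

# Eigenvalue of A that crosses at the transcritical point, as a function of M.
lambda3_A <- function(model, params) {
  A <- trivial_equilibria(model, params)[[2L]]
  ev <- eigen(vh_jacobian(model, A$state, params), only.values = TRUE)$values
  max(Re(ev))
}

#' Numeric crossing of the A-eigenvalue (transcritical cross-check)
#'
#' Finds the zero of the leading eigenvalue of the virus-free state A as a
#' function of `M` by bisection; independent numeric counterpart of
#' [transcritical_M()].
#'
#' @inheritParams vh_rhs
#' @param bracket interval of `M` straddling the crossing (default: the
#'   closed form +/- 50%).
#' @return The crossing value of `M`.
#' @export
transcritical_crossing <- function(model, params, bracket = NULL) {
  check_model_params(model, params)
  if (is.null(bracket)) {
    m0 <- transcritical_M(params)
    bracket <- c(0.5 * m0, 1.5 * m0)
  }
  stats::uniroot(function(M) lambda3_A(model, set_param(params, "M", M)),
                 bracket, tol = 1e-12)$root
}

# Continue the interior equilibrium to a new parameter value: Newton from the
# reference state, falling back to a full scan (nearest root in z).
continue_equilibrium <- function(model, params, ref_state, tol = 1e-10) {
  sys <- eq_system(model, params)
  sol <- newton_solve(sys$f, sys$jac, ref_state)
  if (sol$converged && sol$fnorm <= tol && all(sol$root > 0)) {
    st <- stats::setNames(as.numeric(sol$root), state_names(model))
    return(new_equilibrium(st, model, params, "interior", "none"))
  }
  eqs <- interior_equilibria(model, params, tol = tol)
  if (length(eqs) == 0L) return(NULL)
  zr <- ref_state[[length(ref_state)]]
  dz <- vapply(eqs, function(e) abs(e$state[[length(e$state)]] - zr),
               numeric(1))
  eqs[[which.min(dz)]]
}

# Real part and frequency of the leading complex eigenvalue pair at the
# interior equilibrium continued to param value v. Returns c(re, im) or NULL.
pair_re_at <- function(model, params, param_name, v, ref_state,
                       im_tol = 1e-8) {
  pm <- set_param(params, param_name, v)
  eq <- continue_equilibrium(model, pm, ref_state)
  if (is.null(eq)) return(NULL)
  ev <- eigen(vh_jacobian_raw(model, eq$state, pm), only.values = TRUE)$values
  cplx <- ev[abs(Im(ev)) > im_tol]
  if (length(cplx) < 2L) return(list(re = NA_real_, im = NA_real_, eq = eq))
  i <- which.max(Re(cplx))
  list(re = Re(cplx[i]), im = abs(Im(cplx[i])), eq = eq)
}

#' Hopf threshold by bisection on the complex-pair real part
#'
#' Continues the interior equilibrium across a parameter bracket and bisects
#' on the sign of the real part of its leading complex eigenvalue pair. At
#' the returned value the pair is on the imaginary axis (within tolerance),
#' with frequency `omega` and a finite-difference transversality estimate.
#'
#' @inheritParams vh_rhs
#' @param param_name parameter to vary (default `"M"`).
#' @param bracket length-2 interval straddling the stability change.
#' @param max_iter bisection iterations (default 60).
#' @param re_tol stop when `|Re|` of the pair falls below this (default 1e-10).
#' @return A `vh_bifpoint` of kind `"hopf"` with `omega > 0`; diagnostics
#'   carry the residual real part and the transversality derivative.
#' @export
hopf_threshold <- function(model, params, param_name = "M", bracket,
                           max_iter = 60L, re_tol = 1e-10) {
  check_model_params(model, params)
  lo <- min(bracket); hi <- max(bracket)
  eq0 <- interior_equilibria(model, set_param(params, param_name, lo))
  if (length(eq0) == 0L)
    stop("no interior equilibrium at the lower bracket end", call. = FALSE)
  ref <- eq0[[1L]]$state
  plo <- pair_re_at(model, params, param_name, lo, ref)
  if (is.null(plo) || !is.finite(plo$re))
    stop("complex pair collapses to real eigenvalues at lower bracket end",
         call. = FALSE)
  ref_hi <- plo$eq$state
  phi <- pair_re_at(model, params, param_name, hi, ref_hi)
  if (is.null(phi) || !is.finite(phi$re))
    stop("complex pair collapses to real eigenvalues at upper bracket end",
         call. = FALSE)
  if (sign(plo$re) == sign(phi$re))
    stop("no sign change of the pair real part over the bracket",
         call. = FALSE)
  ref <- plo$eq$state
  mid <- lo; pm_mid <- plo
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    pm_mid <- pair_re_at(model, params, param_name, mid, ref)
    if (is.null(pm_mid) || !is.finite(pm_mid$re))
      stop("equilibrium or complex pair lost during bisection", call. = FALSE)
    ref <- pm_mid$eq$state
    if (abs(pm_mid$re) < re_tol) break
    if (sign(pm_mid$re) == sign(plo$re)) { lo <- mid; plo <- pm_mid }
    else hi <- mid
  }
  h <- max(1e-6 * abs(mid), 1e-8)
  rp <- pair_re_at(model, params, param_name, mid + h, ref)
  rm <- pair_re_at(model, params, param_name, mid - h, ref)
  trans <- if (!is.null(rp) && !is.null(rm) && is.finite(rp$re) &&
               is.finite(rm$re)) (rp$re - rm$re) / (2 * h) else NA_real_
  new_bifpoint("hopf", param_name, mid, pm_mid$eq, omega = pm_mid$im,
               diagnostics = list(re_residual = pm_mid$re,
                                  transversality = trans,
                                  bracket = c(lo, hi)))
}

#' Two-parameter Hopf curve
#'
#' Traces the Hopf boundary in the `(M, free_param)` plane: for each `M` on
#' the grid the threshold in the free parameter (`e`, `l` or `s`) is found by
#' [hopf_threshold()], re-using the previous point to seed the bracket.
#'
#' @inheritParams vh_rhs
#' @param free_param one of `"e"`, `"l"`, `"s"`.
#' @param M_grid increasing vector of `M` values.
#' @param bracket initial bracket in the free parameter for the first grid
#'   point.
#' @return List with `points` (list of `vh_bifpoint`, each annotated with its
#'   `M`) and `gaps` (grid values without a bracketable crossing).
#' @export
hopf_curve <- function(model, params, free_param = c("e", "l", "s"),
                       M_grid, bracket) {
  free_param <- match.arg(free_param)
  pts <- list(); gaps <- numeric(0)
  br <- sort(bracket)
  for (M in M_grid) {
    pm <- set_param(params, "M", M)
    hp <- tryCatch(hopf_threshold(model, pm, free_param, br),
                   error = function(e) NULL)
    if (is.null(hp)) {
      # expand the bracket around the previous solution
      ctr <- mean(br); wid <- diff(br)
      for (f in c(2, 4, 8)) {
        br_try <- ctr + c(-1, 1) * wid * f / 2
        if (free_param == "s") br_try <- pmin(pmax(br_try, 1e-3), 0.999)
        else br_try <- pmax(br_try, 1e-6)
        hp <- tryCatch(hopf_threshold(model, pm, free_param, br_try),
                       error = function(e) NULL)
        if (!is.null(hp)) break
      }
    }
    if (is.null(hp)) { gaps <- c(gaps, M); next }
    hp$M <- M
    pts[[length(pts) + 1L]] <- hp
    v <- hp$param_value
    br <- v * c(0.7, 1.3)
    if (free_param == "s") br <- pmin(pmax(br, 1e-3), 0.999)
  }
  list(points = pts, gaps = gaps)
}

#' Hopf curve as a two-column data frame
#'
#' @param curve result of [hopf_curve()].
#' @param free_param name used for the second column.
#' @return Data frame with columns `M` and the free parameter.
#' @export
hopf_curve_to_df <- function(curve, free_param = "value") {
  df <- data.frame(M = vapply(curve$points, function(p) p$M, numeric(1)),
                   value = vapply(curve$points, function(p) p$param_value,
                                  numeric(1)))
  names(df)[2L] <- free_param
  df
}

#' Saddle-node threshold of the two-component logistic model
#'
#' With virus-dependent immunity, interior equilibria of the two-component
#' logistic model appear in a fold: below a threshold `M*` there are none,
#' above it a saddle B1 and a stable node/spiral B2. The threshold is located
#' by bisection on the interior-equilibrium count and polished by Newton on
#' the system {equilibrium conditions, Det J = 0} in `(x, z, M)`.
#'
#' @param params a [vh_params()] object with `a > 0`.
#' @param bracket interval of `M` with zero roots at the lower end and two at
#'   the upper end.
#' @param tol Newton residual tolerance (default 1e-11).
#' @return A `vh_bifpoint` of kind `"saddle_node"`; diagnostics carry the
#'   Det J and Trace J values at the fold.
#' @export
saddle_node_threshold <- function(params, bracket, tol = 1e-11) {
  model <- vh_model("two", "logistic", "virus_dependent")
  check_model_params(model, params)
  count_at <- function(M)
    length(interior_equilibria(model, set_param(params, "M", M)))
  lo <- min(bracket); hi <- max(bracket)
  if (count_at(lo) != 0L || count_at(hi) < 2L)
    stop("bracket must have 0 interior equilibria at the lower end and ",
         ">= 2 at the upper end", call. = FALSE)
  for (i in seq_len(40L)) {
    mid <- (lo + hi) / 2
    if (count_at(mid) == 0L) lo <- mid else hi <- mid
    if (hi - lo < 1e-8) break
  }
  eqs <- interior_equilibria(model, set_param(params, "M", hi))
  st <- eqs[[1L]]$state
  start <- c(st[["x"]], st[["z"]], hi)
  if (length(eqs) >= 2L) {
    st2 <- eqs[[2L]]$state
    start <- c((st[["x"]] + st2[["x"]]) / 2, (st[["z"]] + st2[["z"]]) / 2, hi)
  }
  Ffun <- function(v) {
    pm <- set_param(params, "M", v[3L])
    sys <- eq_system(model, pm)
    J <- vh_jacobian_raw(model, c(x = v[1L], z = v[2L]), pm)
    c(sys$f(v[1:2]), J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
  }
  sol <- newton_solve(Ffun, function(v) fd_jacobian(Ffun, v), start,
                      tol = tol, maxit = 200L)
  if (!sol$converged)
    stop("saddle-node Newton polish did not converge (best residual ",
         format(sol$fnorm), ")", call. = FALSE)
  v <- sol$root
  pm <- set_param(params, "M", v[3L])
  eq <- new_equilibrium(c(x = v[1L], z = v[2L]), model, pm, "interior",
                        "none")
  J <- vh_jacobian_raw(model, eq$state, pm)
  new_bifpoint("saddle_node", "M", v[3L], eq,
               diagnostics = list(detJ = det(J), traceJ = sum(diag(J)),
                                  bisection_bracket = c(lo, hi)))
}

# Central finite-difference Jacobian of a vector map.
fd_jacobian <- function(f, v, h_rel = 1e-7) {
  n <- length(v)
  f0 <- f(v)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(v[j]), 1)
    vp <- v; vp[j] <- vp[j] + h
    vm <- v; vm[j] <- vm[j] - h
    J[, j] <- (f(vp) - f(vm)) / (2 * h)
  }
  J
}

#' Bogdanov-Takens point of the two-component logistic model
#'
#' Solves the four-equation system {two equilibrium conditions, Det J = 0,
#' Trace J = 0} for `(x, z, M, k)` by damped Newton from a coarse grid of
#' starts seeded at interior equilibria, holding `b`, `d`, `s` (and `a`)
#' fixed. At the solution the Jacobian has a double-zero eigenvalue.
#'
#' @param params a [vh_params()] object with `a > 0` fixing `b`, `d`, `s`.
#' @param M_grid,k_grid coarse start grids (defaults cover M in 5..200,
#'   k in 0.2..4).
#' @param tol residual tolerance (default 1e-9).
#' @return A `vh_bifpoint` of kind `"bogdanov_takens"`; `param_value` is the
#'   critical `M`, diagnostics carry the critical `k`, the Det/Trace
#'   residuals and the Jacobian eigenvalues at the located point.
#' @export
bogdanov_takens_locate <- function(params,
                                   M_grid = c(5, 10, 20, 50, 100, 200),
                                   k_grid = c(0.2, 0.5, 1, 2, 4),
                                   tol = 1e-9) {
  model <- vh_model("two", "logistic", "virus_dependent")
  check_model_params(model, params)
  Ffun <- function(v) {
    if (v[3L] <= 0 || v[4L] <= 0) return(rep(NA_real_, 4L))
    pm <- set_param(set_param(params, "M", v[3L]), "k", v[4L])
    sys <- eq_system(model, pm)
    J <- vh_jacobian_raw(model, c(x = v[1L], z = v[2L]), pm)
    c(sys$f(v[1:2]),
      J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1],
      J[1, 1] + J[2, 2])
  }
  best <- NULL
  for (k in k_grid) for (M in M_grid) {
    pm <- set_param(set_param(params, "M", M), "k", k)
    eqs <- tryCatch(interior_equilibria(model, pm), error = function(e) list())
    for (eq in eqs) {
      start <- c(eq$state[["x"]], eq$state[["z"]], M, k)
      sol <- newton_solve(Ffun, function(v) fd_jacobian(Ffun, v), start,
                          tol = tol, maxit = 200L)
      if (is.null(best) || sol$fnorm < best$fnorm) best <- sol
      if (sol$converged && all(sol$root > 0)) {
        v <- sol$root
        pmc <- set_param(set_param(params, "M", v[3L]), "k", v[4L])
        eqc <- new_equilibrium(c(x = v[1L], z = v[2L]), model, pmc,
                               "interior", "none")
        J <- vh_jacobian_raw(model, eqc$state, pmc)
        return(new_bifpoint("bogdanov_takens", "M", v[3L], eqc,
                            diagnostics = list(k = v[4L], detJ = det(J),
                                               traceJ = sum(diag(J)),
                                               eigenvalues = eigen(J)$values)))
      }
    }
  }
  stop("Bogdanov-Takens search did not converge; best residual ",
       format(if (is.null(best)) NA else best$fnorm), call. = FALSE)
}

#' Numeric supercriticality check of a Hopf point
#'
#' A supercritical Hopf bifurcation births a stable limit cycle whose
#' amplitude grows as the square root of the distance past the threshold.
#' This check integrates the model at several offsets above the located
#' threshold until the cycle establishes, measures the amplitude of the virus
#' oscillation, and fits the scaling exponent of amplitude versus offset
#' (0.5 expected for a supercritical bifurcation).
#'
#' @param hp a `vh_bifpoint` of kind `"hopf"` (threshold in `M`).
#' @inheritParams vh_rhs
#' @param offsets positive offsets in `M` above the threshold (default
#'   `c(0.01, 0.02, 0.05, 0.1)` of the threshold value).
#' @param t_cap hard cap on the per-offset integration horizon.
#' @return List with `slope` (fitted exponent), `amplitudes`, `offsets`,
#'   `stable_cycle_above` (a stable cycle established at every offset), and
#'   `supercritical` (stable cycles plus square-root amplitude scaling,
#'   `|slope - 0.5| < 0.2`). A stable cycle above threshold whose amplitude
#'   does not follow the square-root law indicates that the branch observed
#'   is not the locally bifurcating one (e.g. a coexisting large cycle
#'   reached after a subcritical or degenerate Hopf).
#' @export
supercriticality_check <- function(hp, model, params, offsets = NULL,
                                   t_cap = 2e5) {
  if (!inherits(hp, "vh_bifpoint") || hp$kind != "hopf")
    stop("hp must be a Hopf vh_bifpoint", call. = FALSE)
  if (is.null(offsets)) offsets <- c(0.01, 0.02, 0.05, 0.1) * hp$param_value
  amps <- rep(NA_real_, length(offsets))
  for (i in seq_along(offsets)) {
    pm <- set_param(params, hp$param_name, hp$param_value + offsets[i])
    eq <- continue_equilibrium(model, pm, hp$equilibrium$state)
    if (is.null(eq)) next
    ev <- eigen(vh_jacobian_raw(model, eq$state, pm),
                only.values = TRUE)$values
    lam <- max(Re(ev[abs(Im(ev)) > 1e-10]))
    omg <- max(abs(Im(ev)))
    if (!is.finite(lam) || lam <= 0) next
    period <- 2 * pi / omg
    t_end <- min(t_cap, 20 / lam + 60 * period)
    init <- eq$state * (1 + 0.01)
    traj <- integrate_model(model, pm, init, t_end, dt = period / 50)
    n <- length(traj$times)
    w1 <- traj$states[seq(floor(0.6 * n), floor(0.8 * n)), "z"]
    w2 <- traj$states[seq(floor(0.8 * n), n), "z"]
    a1 <- (max(w1) - min(w1)) / 2
    a2 <- (max(w2) - min(w2)) / 2
    if (a2 > 0 && abs(a1 - a2) / a2 < 0.1) amps[i] <- a2
  }
  ok <- is.finite(amps) & amps > 0
  slope <- if (sum(ok) >= 2L)
    unname(stats::coef(stats::lm(log(amps[ok]) ~ log(offsets[ok])))[2L])
  else NA_real_
  list(slope = slope, amplitudes = amps, offsets = offsets,
       stable_cycle_above = all(ok),
       supercritical = all(ok) && is.finite(slope) && abs(slope - 0.5) < 0.2)
}

#' Backward-time test for the unstable limit cycle
#'
#' For the two-component logistic model with virus-dependent immunity, above
#' a second threshold the stable spiral B2 sits inside an unstable limit
#' cycle. Reversing time makes that cycle attracting: integrating the
#' time-reversed flow from a small perturbation of B2 should converge to a
#' closed orbit, detected via the regularity of successive virus-density
#' peaks.
#'
#' @param params a [vh_params()] object with `a > 0`.
#' @param t_end backward-time horizon (default 2000).
#' @param peak_cv_tol coefficient-of-variation threshold on terminal peaks
#'   (default 0.01).
#' @return List with `found` (logical), `peak_cv`, the perturbed start, and
#'   the backward trajectory.
#' @export
backward_cycle_check <- function(params, t_end = 2000, peak_cv_tol = 0.01) {
  model <- vh_model("two", "logistic", "virus_dependent")
  eqs <- interior_equilibria(model, params)
  if (length(eqs) < 2L)
    stop("expected two interior equilibria (saddle + spiral)", call. = FALSE)
  stab <- lapply(eqs, stability_analyze, model = model, params = params)
  i2 <- which(vapply(stab, function(s)
    s$class_label %in% c("stable_spiral", "stable_node"), logical(1)))
  if (length(i2) == 0L)
    stop("no stable interior equilibrium found", call. = FALSE)
  B2 <- eqs[[i2[1L]]]
  init <- B2$state * (1 + 0.01)
  func <- function(t, y, parms) list(-vh_rhs_raw(model, y, params))
  times <- seq(0, t_end, by = 0.05)
  sol <- deSolve::lsoda(y = init, times = times, func = func, parms = NULL,
                        rtol = 1e-9, atol = 1e-12, maxsteps = 50000)
  z <- sol[, "z"]
  n <- length(z)
  tail_i <- seq(floor(0.5 * n), n)
  pk <- find_peaks(sol[tail_i, 1L], z[tail_i])
  bounded <- all(is.finite(z)) && max(z) < 1e12
  found <- bounded && length(pk$values) >= 5L &&
    stats::sd(pk$values) / mean(pk$values) < peak_cv_tol
  list(found = found,
       peak_cv = if (length(pk$values) >= 2L)
         stats::sd(pk$values) / mean(pk$values) else NA_real_,
       start = init, equilibrium = B2,
       trajectory = list(times = sol[, 1L], states = sol[, -1L]))
}
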