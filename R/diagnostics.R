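#' @title Long-run regime diagnostics
#' @description Classifies the long-run dynamics of a model run into the
#'   regime taxonomy (extinction, stable equilibrium, limit cycle,
#'   quasi-chaotic oscillations, unbounded growth) and quantifies
#'   quasi-chaos with peak statistics and a Benettin-type largest Lyapunov
#'   exponent estimate.
#' @name diagnostics
NULL

# Local maxima of a sampled series by three-point comparison with parabolic
# refinement of the peak time and value.
find_peaks <- function(times, values) {
  n <- length(values)
  if (n < 3L) return(list(times = numeric(0), values = numeric(0)))
  i <- which(values[2:(n - 1)] > values[1:(n - 2)] &
               values[2:(n - 1)] >= values[3:n]) + 1L
  if (length(i) == 0L) return(list(times = numeric(0), values = numeric(0)))
  # parabolic refinement through the three samples around each peak
  y0 <- values[i - 1L]; y1 <- values[i]; y2 <- values[i + 1L]
  denom <- y0 - 2 * y1 + y2
  off <- ifelse(abs(denom) > 0, 0.5 * (y0 - y2) / denom, 0)
  off <- pmax(pmin(off, 0.5), -0.5)
  dt <- times[i + 1L] - times[i]
  list(times = times[i] + off * dt,
       values = y1 - 0.25 * (y0 - y2) * off)
}

#' Peak statistics of a trajectory coordinate
#'
#' Detects local maxima of one coordinate (three-point comparison with
#' parabolic refinement) and summarizes their regularity: the coefficient of
#' variation of the maxima values (`peak_cv`) and the inter-peak intervals.
#' Regular peaks (small `peak_cv`, near-constant intervals) indicate a limit
#' cycle; irregular peaks indicate quasi-chaotic oscillations.
#'
#' @param traj a `vh_trajectory` (or a list with `times` and `states`).
#' @param coordinate state variable to analyze (default `"z"`).
#' @param window optional time interval `c(t0, t1)` restricting the analysis.
#' @return List with `times`, `values` (refined maxima), `peak_cv`,
#'   `intervals`, and `insufficient` (`TRUE` when fewer than 10 maxima were
#'   found, in which case the statistics are reported as `NA`).
#' @export
peak_statistics <- function(traj, coordinate = "z", window = NULL) {
  tms <- traj$times
  vals <- traj$states[, coordinate]
  if (!is.null(window)) {
    keep <- tms >= window[1L] & tms <= window[2L]
    tms <- tms[keep]; vals <- vals[keep]
  }
  pk <- find_peaks(tms, vals)
  if (length(pk$values) < 10L) {
    return(list(times = pk$times, values = pk$values, peak_cv = NA_real_,
                intervals = diff(pk$times), insufficient = TRUE))
  }
  list(times = pk$times, values = pk$values,
       peak_cv = stats::sd(pk$values) / mean(pk$values),
       intervals = diff(pk$times), insufficient = FALSE)
}

#' Largest Lyapunov exponent (tangent-linear Benettin estimate)
#'
#' Evolves the model together with a tangent perturbation governed by the
#' analytic Jacobian, renormalizing the perturbation every `tau` time units
#' and averaging the log growth factors over the post-transient window. The
#' estimate is reported with a standard error computed across the two halves
#' of the averaging window.
#'
#' @inheritParams integrate_model
#' @param t_transient transient discarded before averaging (default 200).
#' @param t_window averaging window length (default 500).
#' @param tau renormalization interval (default 1 time unit).
#' @param rtol,atol integration tolerances (defaults 1e-9 / 1e-12).
#' @return List with `lle` (per unit time), `se` (split-half standard
#'   error), `tau`, and `n_renorm`.
#' @export
largest_lyapunov <- function(model, params, init, t_transient = 200,
                             t_window = 500, tau = 1, rtol = 1e-9,
                             atol = 1e-12) {
  check_model_params(model, params)
  init <- as_state(init, model)
  n <- n_components(model)
  # settle onto the attractor
  func <- function(t, y, parms) list(vh_rhs_raw(model, y, params))
  jacf <- function(t, y, parms) vh_jacobian_raw(model, y, params)
  # integrate the transient in chunks to keep per-call step budgets modest
  u <- as.numeric(init)
  t_done <- 0
  while (t_done < t_transient) {
    t_next <- min(t_done + 1000, t_transient)
    base <- deSolve::lsoda(y = u, times = c(t_done, t_next), func = func,
                           parms = NULL, jacfunc = jacf,
                           rtol = rtol, atol = atol, maxsteps = 1e5)
    u <- as.numeric(base[nrow(base), -1L])
    t_done <- t_next
  }
  if (any(!is.finite(u)) || max(abs(u)) > 1e12)
    stop("trajectory unbounded during transient; cannot estimate exponent",
         call. = FALSE)
  delta <- rep(1 / sqrt(n), n)
  aug_func <- function(t, y, parms) {
    s <- y[seq_len(n)]; v <- y[n + seq_len(n)]
    J <- vh_jacobian_raw(model, s, params)
    list(c(vh_rhs_raw(model, s, params), as.numeric(J %*% v)))
  }
  n_renorm <- ceiling(t_window / tau)
  logs <- numeric(n_renorm)
  for (i in seq_len(n_renorm)) {
    sol <- deSolve::lsoda(y = c(u, delta), times = c(0, tau), func = aug_func,
                          parms = NULL, rtol = rtol, atol = atol,
                          maxsteps = 1e5)
    y <- as.numeric(sol[nrow(sol), -1L])
    u <- y[seq_len(n)]
    v <- y[n + seq_len(n)]
    r <- sqrt(sum(v^2))
    logs[i] <- log(r)
    delta <- v / r
    if (any(!is.finite(u)) || max(abs(u)) > 1e12)
      stop("trajectory unbounded during averaging window", call. = FALSE)
  }
  # drop the initial renormalizations while the tangent vector aligns with
  # the dominant direction (their growth factors reflect the alignment
  # transient, not the exponent)
  drop <- max(10L, ceiling(0.1 * n_renorm))
  kept <- logs[seq(drop + 1L, n_renorm)]
  half <- floor(length(kept) / 2)
  m1 <- mean(kept[seq_len(half)]) / tau
  m2 <- mean(kept[seq(half + 1L, length(kept))]) / tau
  list(lle = mean(kept) / tau, se = abs(m1 - m2) / 2, tau = tau,
       n_renorm = n_renorm)
}

#' Classify the long-run dynamical regime
#'
#' Integrates the model, discards a transient fraction of the run, and labels
#' the terminal behavior:
#' \itemize{
#'   \item `unbounded` if the blow-up guard fired;
#'   \item `extinction` if a population coordinate ends below the floor;
#'   \item `stable_equilibrium` if the terminal window stays within `tol_eq`
#'     of a computed equilibrium;
#'   \item `limit_cycle` if the virus-density peaks are regular
#'     (`peak_cv < cv_tol`) with a near-constant inter-peak interval;
#'   \item `quasi_chaotic` if bounded, aperiodic, and the largest Lyapunov
#'     exponent exceeds `lle_threshold`;
#'   \item `undetermined` otherwise.
#' }
#'
#' @inheritParams integrate_model
#' @param t_end integration horizon.
#' @param transient_frac fraction of the run discarded as transient
#'   (default 0.5).
#' @param tol_eq distance threshold for the stable-equilibrium label
#'   (default 1e-4).
#' @param cv_tol peak-regularity threshold for the limit-cycle label
#'   (default 0.01).
#' @param lle_threshold positive-exponent threshold for the quasi-chaotic
#'   label (default 1e-3 per unit time).
#' @param lle_window averaging window passed to [largest_lyapunov()].
#' @return Object of class `"vh_regime"`: list with `label`, `evidence`
#'   (distance to equilibrium, peak_cv, period estimate, lle, boundedness),
#'   and `window`.
#' @export
classify_regime <- function(model, params, init, t_end, dt = 0.1,
                            transient_frac = 0.5, tol_eq = 1e-4,
                            cv_tol = 0.01, lle_threshold = 1e-3,
                            lle_window = 500, floor = 1e-12, ...) {
  if (t_end * (1 - transient_frac) < 10 * dt)
    stop("t_end too short for the transient discard", call. = FALSE)
  traj <- integrate_model(model, params, init, t_end, dt = dt,
                          floor = floor, ...)
  window <- c(t_end * transient_frac, t_end)
  ev <- list(distance_to_equilibrium = NA_real_, peak_cv = NA_real_,
             period_estimate = NA_real_, lle = NA_real_, lle_se = NA_real_,
             bounded = TRUE)
  mk <- function(label) structure(list(label = label, evidence = ev,
                                       window = window, trajectory = traj),
                                  class = "vh_regime")
  if (any(traj$events$label == "unbounded")) {
    ev$bounded <- FALSE
    return(mk("unbounded"))
  }
  final <- traj$states[nrow(traj$states), ]
  if (any(final < floor)) return(mk("extinction"))

  eqs <- tryCatch(vh_equilibria(model, params), error = function(e) list())
  term_i <- traj$times >= t_end - 0.1 * (t_end - window[1L])
  term <- traj$states[term_i, , drop = FALSE]
  if (length(eqs) > 0L) {
    dmin <- min(vapply(eqs, function(eq) {
      max(apply(abs(sweep(term, 2L, eq$state)), 1L, max))
    }, numeric(1)))
    ev$distance_to_equilibrium <- dmin
    if (dmin < tol_eq) return(mk("stable_equilibrium"))
  }

  ps <- peak_statistics(traj, "z", window = window)
  ev$peak_cv <- ps$peak_cv
  if (!ps$insufficient) {
    iv <- ps$intervals
    ev$period_estimate <- stats::median(iv)
    regular_period <- stats::sd(iv) / mean(iv) < 0.05
    # guard against decaying spirals: a genuine cycle keeps its amplitude
    keep <- traj$times >= window[1L]
    zt <- traj$states[keep, "z"]
    nz <- length(zt)
    amp1 <- diff(range(zt[seq_len(floor(nz / 2))]))
    amp2 <- diff(range(zt[seq(floor(nz / 2) + 1L, nz)]))
    steady <- amp2 > 0.5 * amp1
    if (is.finite(ps$peak_cv) && ps$peak_cv < cv_tol && regular_period &&
        steady)
      return(mk("limit_cycle"))
  }

  lle <- tryCatch(
    largest_lyapunov(model, params, init, t_transient = window[1L],
                     t_window = lle_window),
    error = function(e) NULL)
  if (!is.null(lle)) {
    ev$lle <- lle$lle
    ev$lle_se <- lle$se
    if (lle$lle > lle_threshold) return(mk("quasi_chaotic"))
  }
  mk("undetermined")
}

#' @export
print.vh_regime <- function(x, ...) {
  cat(sprintf("<vh_regime> %s (peak_cv = %s, lle = %s, dist_eq = %s)\n",
              x$label,
              format(x$evidence$peak_cv, digits = 3),
              format(x$evidence$lle, digits = 3),
              format(x$evidence$distance_to_equilibrium, digits = 3)))
  invisible(x)
}

#' Flatten a regime report to a one-row data frame
#'
#' @param report a `vh_regime`.
#' @param name optional scenario name column.
#' @return One-row data frame (TSV-ready).
#' @export
regime_to_df <- function(report, name = NA_character_) {
  data.frame(scenario = name, label = report$label,
             distance_to_equilibrium = report$evidence$distance_to_equilibrium,
             peak_cv = report$evidence$peak_cv,
             period_estimate = report$evidence$period_estimate,
             lle = report$evidence$lle,
             bounded = report$evidence$bounded,
             window_start = report$window[1L], window_end = report$window[2L],
             stringsAsFactors = FALSE)
}
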