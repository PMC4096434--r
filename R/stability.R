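#' Eigenvalue stability analysis of an equilibrium
#'
#' Computes the eigenvalues of the analytic Jacobian at an equilibrium and
#' classifies the fixed point by the sign pattern of the real parts, with a
#' hyperbolicity tolerance separating genuine spirals from centers and other
#' non-hyperbolic cases.
#'
#' Classes: `stable_node` / `stable_spiral` (all real parts negative, without /
#' with an imaginary pair), `unstable_node` / `unstable_spiral` (all real
#' parts positive), `saddle` (real parts of both signs), `center` (all real
#' parts within tolerance of zero with a nonzero imaginary pair),
#' `nonhyperbolic` (some real part within tolerance of zero otherwise).
#'
#' @param eq a `vh_equilibrium` (residual below `res_tol`).
#' @inheritParams vh_rhs
#' @param hyper_tol hyperbolicity tolerance on `|Re(lambda)|` (default 1e-8).
#' @param res_tol maximum accepted equilibrium residual (default 1e-8).
#' @return An object of class `"vh_stability"`: list with `eigenvalues`
#'   (complex, sorted by descending real part, ties by descending imaginary
#'   part), `class_label`, and `leading_real`.
#' @export
stability_analyze <- function(eq, model, params, hyper_tol = 1e-8,
                              res_tol = 1e-8) {
  if (!inherits(eq, "vh_equilibrium"))
    stop("eq must be a vh_equilibrium", call. = FALSE)
  if (eq$residual > res_tol)
    stop("equilibrium residual ", format(eq$residual),
         " exceeds tolerance; refine before analyzing", call. = FALSE)
  J <- vh_jacobian(model, eq$state, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  ev <- ev[order(-Re(ev), -Im(ev))]
  structure(list(eigenvalues = ev,
                 class_label = classify_eigenvalues(ev, hyper_tol),
                 leading_real = Re(ev[1L])),
            class = "vh_stability")
}

#' @export
print.vh_stability <- function(x, ...) {
  cat(sprintf("<vh_stability> %s; eigenvalues: %s\n", x$class_label,
              paste(format(x$eigenvalues, digits = 6), collapse = ", ")))
  invisible(x)
}

# Sign-pattern classification with hyperbolicity tolerance.
classify_eigenvalues <- function(ev, hyper_tol = 1e-8) {
  re <- Re(ev); im <- Im(ev)
  near0 <- abs(re) < hyper_tol
  has_im <- any(abs(im) > hyper_tol)
  if (all(near0) && has_im) return("center")
  if (any(near0)) return("nonhyperbolic")
  if (all(re < 0)) return(if (has_im) "stable_spiral" else "stable_node")
  if (all(re > 0)) return(if (has_im) "unstable_spiral" else "unstable_node")
  "saddle"
}

#' Closed-form eigenvalue check at the trivial equilibria
#'
#' The three-component model has eigenvalues `{1, -d, 1-l}` at the origin `O`
#' (hence `O` is always unstable) and, in the logistic case, eigenvalues
#' `{-l, -1, (b(M(1-s)-s) - d a)/a}` at the virus-free state `A(0, 1/a, 0)`.
#' This check compares the numerically computed Jacobian spectra with those
#' closed forms.
#'
#' @inheritParams vh_rhs
#' @param tol agreement tolerance (default 1e-9).
#' @return `TRUE` if all closed forms match within `tol`.
#' @export
closed_form_eigen_check <- function(model, params, tol = 1e-9) {
  check_model_params(model, params)
  if (model$components != "three")
    stop("closed-form check applies to the three-component model",
         call. = FALSE)
  eqs <- trivial_equilibria(model, params)
  O <- eqs[[1L]]
  evO <- sort(Re(eigen(vh_jacobian(model, O$state, params),
                       only.values = TRUE)$values))
  expO <- sort(c(1, -params$d, 1 - params$l))
  ok <- max(abs(evO - expO)) < tol
  if (params$a > 0) {
    A <- eqs[[2L]]
    evA <- sort(Re(eigen(vh_jacobian(model, A$state, params),
                         only.values = TRUE)$values))
    expA <- sort(c(-params$l, -1,
                   (params$b * (params$M * (1 - params$s) - params$s) -
                      params$d * params$a) / params$a))
    ok <- ok && max(abs(evA - expA)) < tol
  }
  ok
}

#' Instability of the Malthusian three-component interior equilibrium
#'
#' For the Malthusian model with virus-dependent immunity, the unique interior
#' equilibrium is unstable: one eigenvalue is real and negative while the
#' other two form a complex pair with positive real part, so trajectories
#' spiral away from it (the origin of the quasi-chaotic oscillations).
#'
#' For steep immunity decline the destabilization is real but exponentially
#' small: the pair's real part scales with the adaptive-immunity excess
#' `alpha = p(z_e) - s = (1 - s) exp(-k z_e)`, which underflows double
#' precision once `k z_e` exceeds about 55 while the equilibrium itself is
#' unaffected. When the real part is below direct eigenvalue resolution, its
#' sign is determined by continuation in `k`: the ratio `Re(pair)/alpha` is a
#' smooth, strictly positive function of `k` along the equilibrium branch, so
#' it is evaluated at smaller `k` where `alpha` is representable and its sign
#' is carried to the target `k` (reported as `sign_method = "continuation"`).
#'
#' @param params a [vh_params()] object with `a = 0`.
#' @inheritParams stability_analyze
#' @return The `vh_stability` report at the interior equilibrium, with extra
#'   elements: `equilibrium`, `pair_re_sign` (+1, -1 or `NA`), `sign_method`
#'   (`"direct"` or `"continuation"`), `continuation` (data frame of the
#'   k-continuation evidence when used), and `statement_pattern` (`TRUE` when
#'   the spectrum has one negative real eigenvalue and a destabilizing
#'   complex pair).
#' @export
malthusian_interior_instability <- function(params, hyper_tol = 1e-8) {
  model <- vh_model("three", "malthusian", "virus_dependent")
  eqs <- interior_equilibria(model, params)
  if (length(eqs) == 0L)
    stop("no interior equilibrium at these parameters", call. = FALSE)
  rep_ <- stability_analyze(eqs[[1L]], model, params, hyper_tol = 0)
  ev <- rep_$eigenvalues
  cplx <- ev[abs(Im(ev)) > hyper_tol]
  re_pair <- if (length(cplx) == 2L) max(Re(cplx)) else NA_real_
  resolve_tol <- 1e-12
  if (is.finite(re_pair) && abs(re_pair) > resolve_tol) {
    rep_$pair_re_sign <- sign(re_pair)
    rep_$sign_method <- "direct"
    rep_$continuation <- NULL
  } else {
    cont <- malthusian_pair_continuation(params, resolve_tol)
    rep_$continuation <- cont
    if (!is.null(cont) && nrow(cont) >= 3L && all(cont$re_pair > 0) &&
        all(cont$ratio > 0)) {
      rep_$pair_re_sign <- 1
      rep_$sign_method <- "continuation"
    } else {
      rep_$pair_re_sign <- NA_real_
      rep_$sign_method <- "unresolved"
    }
  }
  n_neg_real <- sum(abs(Im(ev)) < hyper_tol & Re(ev) < 0)
  rep_$statement_pattern <- (n_neg_real == 1L) && (length(cplx) == 2L) &&
    identical(rep_$pair_re_sign, 1)
  rep_$equilibrium <- eqs[[1L]]
  rep_
}

# Evaluate the pair real part at decreasing immunity steepness k until it is
# directly resolvable; returns the (k, alpha, Re, Re/alpha) evidence table.
malthusian_pair_continuation <- function(params, resolve_tol = 1e-12,
                                         n_points = 4L, max_steps = 60L) {
  model <- vh_model("three", "malthusian", "virus_dependent")
  k <- params$k
  rows <- list()
  for (i in seq_len(max_steps)) {
    k <- k * 0.85
    pm <- params
    pm$k <- k
    eqs <- interior_equilibria(model, pm)
    if (length(eqs) == 0L) next
    st <- eqs[[1L]]$state
    alpha <- (1 - pm$s) * exp(-k * st[["z"]])
    ev <- eigen(vh_jacobian_raw(model, st, pm), only.values = TRUE)$values
    cplx <- ev[abs(Im(ev)) > 1e-8]
    if (length(cplx) != 2L) next
    re <- max(Re(cplx))
    if (abs(re) <= 100 * resolve_tol) next
    rows[[length(rows) + 1L]] <- data.frame(k = k, alpha = alpha,
                                            re_pair = re, ratio = re / alpha)
    if (length(rows) >= n_points) break
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Flatten stability reports into the TSV scan schema
#'
#' @param reports list of `vh_stability` objects.
#' @return Data frame with eigenvalue real/imaginary parts and class labels.
#' @export
stability_to_df <- function(reports) {
  rows <- lapply(reports, function(r) {
    ev <- r$eigenvalues
    ev <- c(ev, rep(NA_complex_, 3 - length(ev)))
    data.frame(re1 = Re(ev[1]), im1 = Im(ev[1]), re2 = Re(ev[2]),
               im2 = Im(ev[2]), re3 = Re(ev[3]), im3 = Im(ev[3]),
               class = r$class_label, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
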