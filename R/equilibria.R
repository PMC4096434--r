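#' @title Equilibria of the coevolution models
#' @description Tools to enumerate the trivial equilibria and to locate all
#'   interior (all-positive) equilibria of every model variant. Interior
#'   equilibria are found by a scalar reduction in the virus density `z`:
#'   summing the two host equations and eliminating the encounter terms with
#'   the virus equation yields a quadratic for the host total `u = x + y`
#'   (linear in the Malthusian case); for each root branch, `x` and `y` follow
#'   from a linear solve, and the remaining equilibrium condition becomes a
#'   scalar function of `z` that is bracketed on a grid and bisected. Every
#'   root is then re-polished by damped Newton iteration on the full
#'   equilibrium system.
#' @name equilibria
NULL

new_equilibrium <- function(state, model, params, kind, branch = "none") {
  res <- vh_rhs_raw(model, state, params)
  structure(list(state = state, residual = max(abs(res)), kind = kind,
                 branch = branch), class = "vh_equilibrium")
}

#' @export
print.vh_equilibrium <- function(x, ...) {
  cat(sprintf("<vh_equilibrium> %s (%s): (%s), residual %.2e\n", x$kind,
              x$branch, paste(signif(x$state, 6), collapse = ", "),
              x$residual))
  invisible(x)
}

#' Trivial equilibria (extinction and virus-free states)
#'
#' The origin `O` (all populations extinct) exists for every variant. The
#' logistic variants additionally have the virus-free carrying-capacity state
#' `A`: `(0, 1/a, 0)` for the three-component model (sensitive hosts only) and
#' `(1/a, 0)` for the two-component model.
#'
#' @inheritParams vh_rhs
#' @return List of `vh_equilibrium` objects.
#' @export
trivial_equilibria <- function(model, params) {
  check_model_params(model, params)
  n <- n_components(model)
  out <- list(new_equilibrium(stats::setNames(rep(0, n), state_names(model)),
                              model, params, "trivial_O"))
  if (params$a > 0) {
    A <- if (n == 3L) c(x = 0, y = 1 / params$a, z = 0)
         else c(x = 1 / params$a, z = 0)
    out <- c(out, list(new_equilibrium(A, model, params, "boundary_A")))
  }
  out
}

# Equilibrium system with the z factor removed from the virus equation:
# F1 = P, F2 = Q (three-comp) and the virus balance divided by z. Returns
# list(f, jac) closures over an unconstrained numeric state vector.
eq_system <- function(model, params) {
  l <- params$l; e <- params$e; d <- params$d; M <- params$M
  b <- params$b; a <- params$a; s <- params$s
  mode <- model$immunity
  if (model$components == "three") {
    f <- function(v) {
      x <- v[1L]; y <- v[2L]; z <- v[3L]
      p <- immunity_value(z, params, mode)
      c(x * (1 - l - a * (x + y)) - b * x * z * (1 - p) + e * s * y * z,
        y + l * x - a * y * (x + y) - b * y * z * (1 - s) - e * s * y * z,
        -d + b * M * (x * (1 - p) + y * (1 - s)) - b * (x * p + y * s))
    }
    jac <- function(v) {
      x <- v[1L]; y <- v[2L]; z <- v[3L]
      p <- immunity_value(z, params, mode)
      pz <- immunity_slope(z, params, mode)
      matrix(c(
        1 - l - a * (2 * x + y) - b * z * (1 - p),
        -a * x + e * s * z,
        -b * x * (1 - p) + b * x * z * pz + e * s * y,
        l - a * y,
        1 - a * (x + 2 * y) - b * z * (1 - s) - e * s * z,
        -b * y * (1 - s) - e * s * y,
        b * (M * (1 - p) - p),
        b * (M * (1 - s) - s),
        -b * (M + 1) * x * pz), 3, 3, byrow = TRUE)
    }
  } else {
    f <- function(v) {
      x <- v[1L]; z <- v[2L]
      p <- immunity_value(z, params, mode)
      c(1 - a * x - b * z * (1 - p),
        -d + b * x * (M * (1 - p) - p))
    }
    jac <- function(v) {
      x <- v[1L]; z <- v[2L]
      p <- immunity_value(z, params, mode)
      pz <- immunity_slope(z, params, mode)
      matrix(c(-a, -b * (1 - p) + b * z * pz,
               b * (M * (1 - p) - p), -b * (M + 1) * x * pz),
             2, 2, byrow = TRUE)
    }
  }
  list(f = f, jac = jac)
}

# Damped Newton on a square system. Returns list(root, fnorm, converged).
newton_solve <- function(f, jac, start, tol = 1e-12, maxit = 100L) {
  v <- as.numeric(start)
  fv <- f(v)
  if (any(!is.finite(fv))) return(list(root = v, fnorm = Inf, converged = FALSE))
  for (it in seq_len(maxit)) {
    nf <- max(abs(fv))
    if (nf < tol) return(list(root = v, fnorm = nf, converged = TRUE))
    J <- jac(v)
    step <- tryCatch(solve(J, fv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(root = v, fnorm = nf, converged = FALSE))
    lam <- 1
    repeat {
      vn <- v - lam * step
      fn <- f(vn)
      if (all(is.finite(fn)) && max(abs(fn)) < nf) break
      lam <- lam / 2
      if (lam < 1e-10) return(list(root = v, fnorm = nf, converged = FALSE))
    }
    v <- vn; fv <- fn
  }
  list(root = v, fnorm = max(abs(fv)), converged = max(abs(fv)) < tol)
}

# Host total u = x + y at an equilibrium with virus density z: roots of
# a (M+1) u^2 - (M+1 - b z) u + d z = 0 (linear when a = 0). Returns named
# numeric vector (possibly empty) with names "plus"/"minus" or "none".
host_total_branches <- function(z, params) {
  M <- params$M; b <- params$b; a <- params$a; d <- params$d
  if (a == 0) {
    den <- M + 1 - b * z
    if (den <= 0) return(numeric(0))
    stats::setNames(d * z / den, "none")
  } else {
    disc <- (M + 1 - b * z)^2 - 4 * a * d * (M + 1) * z
    if (disc < 0) return(numeric(0))
    sq <- sqrt(disc)
    stats::setNames(c((M + 1 - b * z + sq), (M + 1 - b * z - sq)) /
                      (2 * a * (M + 1)), c("plus", "minus"))
  }
}

# Given z and a host-total branch u, recover (x, y) from the linear system
# {x + y = u, sensitive-host balance y(1 - a u - b z(1-s) - e s z) + l x = 0}.
# (The sensitive-host balance is used for the split because it is linear in
# (x, y) and stays well conditioned when the immunity p(z) is close to the
# innate level s, where a split based on the immunity contrast degenerates.)
three_comp_xy <- function(z, u, params, mode) {
  c2 <- 1 - params$a * u - params$b * z * (1 - params$s) -
    params$e * params$s * z
  den <- params$l - c2
  if (abs(den) < 1e-14) return(NULL)
  x <- -c2 * u / den
  c(x = x, y = u - x, z = z)
}

# Scalar function of z whose roots are interior equilibria (three-component):
# the virus balance (divided by z) evaluated on the reduced (x(z), y(z), z).
# The host-total branch already enforces the summed host balance together
# with the virus balance, so a root satisfies the full equilibrium system.
three_comp_gz <- function(z, branch, params, mode) {
  u <- host_total_branches(z, params)
  if (!(branch %in% names(u))) return(NA_real_)
  st <- three_comp_xy(z, u[[branch]], params, mode)
  if (is.null(st)) return(NA_real_)
  b <- params$b; M <- params$M; s <- params$s
  p <- immunity_value(z, params, mode)
  -params$d + b * M * (st[["x"]] * (1 - p) + st[["y"]] * (1 - s)) -
    b * (st[["x"]] * p + st[["y"]] * s)
}

# Closed-form interior equilibrium of the three-component model with constant
# immunity equal to the innate level (p_const = s): the host total follows the
# two-component reduction and the x/y split balances immunity decay against
# acquisition.
three_comp_psplit_closed_form <- function(params) {
  l <- params$l; e <- params$e; d <- params$d; M <- params$M
  b <- params$b; a <- params$a; s <- params$s
  den <- b * (M * (1 - s) - s)
  if (den <= 0) return(NULL)
  u <- d / den
  z <- (1 - a * u) / (b * (1 - s))
  if (z <= 0) return(NULL)
  if (l <= 0) return(NULL)  # with no immunity decay the split degenerates
  y <- u * l / (l + e * s * z)
  c(x = u - y, y = y, z = z)
}

#' Interior (all-positive) equilibria
#'
#' Locates every equilibrium with all coordinates strictly positive, by the
#' scalar z-reduction described in [equilibria], followed by damped-Newton
#' polishing of the full equilibrium system. The search domain is
#' `0 < z < (1 + M)/b` (the bound within which any interior equilibrium must
#' lie; see [equilibrium_bound_check()]).
#'
#' @inheritParams vh_rhs
#' @param n_grid number of bracketing grid points in `z` (default 2000).
#' @param tol residual tolerance on the polished equilibrium (default 1e-10).
#' @return List of `vh_equilibrium` objects (empty if none exists).
#' @export
interior_equilibria <- function(model, params, n_grid = 2000L, tol = 1e-10) {
  check_model_params(model, params)
  z_max <- (1 + params$M) / params$b
  sys <- eq_system(model, params)
  roots <- list()
  add_root <- function(start, branch) {
    sol <- newton_solve(sys$f, sys$jac, start)
    if (!sol$converged || sol$fnorm > tol) return(invisible(NULL))
    v <- sol$root
    if (any(v <= 0)) return(invisible(NULL))
    roots[[length(roots) + 1L]] <<- list(state = v, branch = branch)
    invisible(NULL)
  }

  if (model$components == "three") {
    if (model$immunity == "constant" &&
        abs(params$p_const - params$s) < 1e-12) {
      cf <- three_comp_psplit_closed_form(params)
      if (!is.null(cf)) add_root(cf, "none")
    } else {
      z_hi <- z_max
      if (params$a > 0) {
        # the host-total quadratic has real roots only below the smaller zero
        # of its discriminant; concentrate the grid there
        M1 <- params$M + 1; b <- params$b; ad <- params$a * params$d
        cc <- 2 * b + 4 * ad
        z_disc <- M1 * (cc - sqrt(cc^2 - 4 * b^2)) / (2 * b^2)
        if (is.finite(z_disc) && z_disc > 0) z_hi <- min(z_max, z_disc)
      }
      zs <- scan_grid(z_hi, n_grid)
      branches <- if (params$a == 0) "none" else c("plus", "minus")
      for (br in branches) {
        g <- vapply(zs, three_comp_gz, numeric(1), branch = br,
                    params = params, mode = model$immunity)
        ok <- is.finite(g)
        idx <- which(ok[-length(ok)] & ok[-1] &
                       g[-length(g)] * g[-1] <= 0 & g[-length(g)] != 0)
        for (i in idx) {
          zr <- tryCatch(
            suppressWarnings(stats::uniroot(
              three_comp_gz, c(zs[i], zs[i + 1]), branch = br,
              params = params, mode = model$immunity, tol = 1e-12)$root),
            error = function(e) NA_real_)
          if (!is.finite(zr)) next
          u <- host_total_branches(zr, params)
          if (!(br %in% names(u))) next
          st <- three_comp_xy(zr, u[[br]], params, model$immunity)
          if (!is.null(st)) add_root(st, br)
        }
      }
    }
  } else {
    # two-component: x(z) = d / (b (M - p(z)(M+1))) from the virus balance;
    # roots of phi(z) = 1 - a x(z) - b z (1 - p(z)).
    phi <- function(z) {
      p <- immunity_value(z, params, model$immunity)
      den <- params$b * (params$M - p * (params$M + 1))
      if (den <= 0) return(NA_real_)
      1 - params$a * params$d / den - params$b * z * (1 - p)
    }
    if (model$immunity == "constant") {
      p <- params$p_const
      den <- params$b * (params$M * (1 - p) - p)
      if (den > 0) {
        xbar <- params$d / den
        zbar <- (1 - params$a * xbar) / (params$b * (1 - p))
        if (zbar > 0) add_root(c(x = xbar, z = zbar), "none")
      }
    } else {
      zs <- scan_grid(z_max, n_grid)
      g <- vapply(zs, phi, numeric(1))
      ok <- is.finite(g)
      idx <- which(ok[-length(ok)] & ok[-1] &
                     g[-length(g)] * g[-1] <= 0 & g[-length(g)] != 0)
      for (i in idx) {
        zr <- tryCatch(
          stats::uniroot(function(z) phi(z), c(zs[i], zs[i + 1]),
                         tol = 1e-12)$root,
          error = function(e) NA_real_)
        if (!is.finite(zr)) next
        p <- immunity_value(zr, params, model$immunity)
        den <- params$b * (params$M - p * (params$M + 1))
        if (den <= 0) next
        add_root(c(x = params$d / den, z = zr), "none")
      }
    }
  }

  dedupe_equilibria(roots, model, params)
}

# Bracketing grid in z: linear over (0, z_max) plus a geometric prefix so
# roots hugging the z = 0 boundary (where the immunity term varies fastest)
# are not stepped over.
scan_grid <- function(z_max, n_grid) {
  lin <- seq(z_max / n_grid, z_max * (1 - 1e-9), length.out = n_grid)
  geo <- z_max * 10^seq(-8, -log10(n_grid), length.out = 200L)
  sort(unique(c(geo, lin)))
}

# Merge roots closer than 1e-6 in z and wrap as vh_equilibrium objects.
dedupe_equilibria <- function(roots, model, params, z_tol = 1e-6) {
  if (length(roots) == 0L) return(list())
  zs <- vapply(roots, function(r) r$state[[length(r$state)]], numeric(1))
  o <- order(zs)
  keep <- list()
  last_z <- -Inf
  for (i in o) {
    if (zs[i] - last_z > z_tol) {
      keep[[length(keep) + 1L]] <- roots[[i]]
      last_z <- zs[i]
    }
  }
  lapply(keep, function(r) {
    st <- stats::setNames(as.numeric(r$state), state_names(model))
    new_equilibrium(st, model, params, "interior", r$branch)
  })
}

#' All equilibria of a model variant
#'
#' Convenience wrapper combining [trivial_equilibria()] and
#' [interior_equilibria()].
#'
#' @inheritParams interior_equilibria
#' @return List of `vh_equilibrium` objects.
#' @export
vh_equilibria <- function(model, params, n_grid = 2000L, tol = 1e-10) {
  c(trivial_equilibria(model, params),
    interior_equilibria(model, params, n_grid = n_grid, tol = tol))
}

#' Brute-force multistart search for interior equilibria
#'
#' Independent cross-check of [interior_equilibria()]: damped Newton on the
#' full equilibrium system from many starts spread (log in `z`, linear in the
#' host coordinates) over a search box, with converged all-positive roots
#' deduplicated. The default box is the invariant-region bound: host totals
#' below `u_max` and `z` below `(1 + M)/b`.
#'
#' @inheritParams vh_rhs
#' @param n_starts number of Newton starts (default 216).
#' @param u_max upper bound for host coordinates (default `1/a` for logistic,
#'   50 for Malthusian variants).
#' @param tol residual tolerance (default 1e-10).
#' @return List of `vh_equilibrium` objects.
#' @export
equilibria_multistart <- function(model, params, n_starts = 216L,
                                  u_max = NULL, tol = 1e-10) {
  check_model_params(model, params)
  if (is.null(u_max)) u_max <- if (params$a > 0) 1 / params$a else 50
  z_max <- (1 + params$M) / params$b
  sys <- eq_system(model, params)
  n <- n_components(model)
  k <- max(3L, ceiling(n_starts^(1 / n)))
  z_grid <- z_max * 10^seq(-4, 0, length.out = k) * (1 - 1e-9)
  h_grid <- u_max * seq(0.02, 0.98, length.out = k)
  starts <- if (n == 3L) {
    as.matrix(expand.grid(x = h_grid, y = h_grid, z = z_grid))
  } else {
    as.matrix(expand.grid(x = h_grid, z = z_grid))
  }
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    sol <- newton_solve(sys$f, sys$jac, starts[i, ])
    if (!sol$converged || sol$fnorm > tol) next
    v <- sol$root
    if (any(v <= 0)) next
    if (v[length(v)] > z_max * 1.000001) next
    if (sum(v[-length(v)]) > u_max * 100) next
    roots[[length(roots) + 1L]] <- list(state = v, branch = "none")
  }
  dedupe_equilibria(roots, model, params)
}

#' Invariant-region check for logistic three-component equilibria
#'
#' Any interior equilibrium of the logistic three-component model must satisfy
#' `0 <= x + y < 1` and `z < (1 + M)/b` (with `a = 1`): equilibria live in a
#' bounded box whose virus extent is set by the reproduction rate `M`.
#'
#' @param eq a `vh_equilibrium` (interior, logistic three-component).
#' @param params a [vh_params()] object.
#' @return `TRUE` if the bound holds (strictly), else `FALSE`.
#' @export
equilibrium_bound_check <- function(eq, params) {
  if (!inherits(eq, "vh_equilibrium") || length(eq$state) != 3L)
    stop("equilibrium_bound_check expects a three-component equilibrium",
         call. = FALSE)
  if (params$a <= 0)
    stop("equilibrium bound applies to the logistic model (a > 0)",
         call. = FALSE)
  u <- eq$state[["x"]] + eq$state[["y"]]
  (u >= 0) && (u < 1) && (eq$state[["z"]] < (1 + params$M) / params$b)
}

#' Independence of the Malthusian equilibrium virus density from M
#'
#' For the three-component Malthusian model with virus-dependent immunity, the
#' virus coordinate of the interior equilibrium does not depend on the virus
#' reproduction rate `M` (while the host coordinates shrink as `M` grows).
#' This helper evaluates the equilibrium across a grid of `M` values.
#'
#' @param params a [vh_params()] object with `a = 0`.
#' @param M_values numeric vector of virus reproduction rates.
#' @return Named numeric vector of equilibrium `z` per `M` (`NA` where no
#'   interior equilibrium exists).
#' @export
malthusian_z_independence <- function(params, M_values) {
  model <- vh_model("three", "malthusian", "virus_dependent")
  vapply(M_values, function(M) {
    pm <- params
    pm$M <- M
    eqs <- interior_equilibria(model, pm)
    if (length(eqs) == 0L) NA_real_ else eqs[[1L]]$state[["z"]]
  }, numeric(1)) -> zs
  stats::setNames(zs, as.character(M_values))
}

#' Export a list of equilibria as a data frame
#'
#' @param eqs list of `vh_equilibrium` objects.
#' @param model,params the model variant and parameters they belong to.
#' @return A data frame with one row per equilibrium (TSV-ready).
#' @export
equilibria_to_df <- function(eqs, model, params) {
  rows <- lapply(eqs, function(eq) {
    st <- eq$state
    data.frame(model = model$components, growth = model$growth,
               immunity_mode = model$immunity,
               l = params$l, e = params$e, d = params$d, M = params$M,
               b = params$b, a = params$a, k = params$k, s = params$s,
               p_const = params$p_const,
               x_e = st[["x"]],
               y_e = if ("y" %in% names(st)) st[["y"]] else NA_real_,
               z_e = st[["z"]],
               residual = eq$residual, kind = eq$kind, branch = eq$branch,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
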