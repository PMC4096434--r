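test_that("trivial equilibria: origin always, virus-free state only with
           logistic growth", {
  p <- fig2_params()
  eqs <- trivial_equilibria(model3_log, p)
  expect_length(eqs, 2L)
  expect_equal(eqs[[1]]$kind, "trivial_O")
  expect_equal(unname(eqs[[2]]$state), c(0, 1, 0))  # A(0, 1/a, 0), a = 1
  pm <- fig1_params()
  expect_length(trivial_equilibria(model3_mal, pm), 1L)
  eq2 <- trivial_equilibria(model2_log, af1_params())
  expect_length(eq2, 2L)
  expect_equal(unname(eq2[[2]]$state), c(1, 0))  # A(1/a, 0)
})

test_that("logistic three-component scan recovers the reference coexistence
           equilibrium", {
  t0 <- Sys.time()
  eqs <- interior_equilibria(model3_log, fig2_params())
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_length(eqs, 1L)
  st <- eqs[[1]]$state
  expect_equal(st[["x"]], 0.279, tolerance = 0.0005 / 0.279)
  expect_equal(st[["y"]], 0.013, tolerance = 0.0005 / 0.013)
  expect_equal(st[["z"]], 20.24, tolerance = 0.005 / 20.24)
  expect_lt(eqs[[1]]$residual, 1e-10)
})

test_that("Malthusian constant-immunity closed forms are reproduced", {
  # three-component, p_const = s: host total splits by decay vs acquisition
  p <- vh_params(l = 0.3, e = 0.2, d = 1, M = 50, b = 0.02, a = 0, k = 0.1,
                 s = 0.25, p_const = 0.25)
  m <- vh_model("three", "malthusian", "constant")
  eqs <- interior_equilibria(m, p)
  expect_length(eqs, 1L)
  u <- p$d / (p$b * (p$M * (1 - p$s) - p$s))
  z <- 1 / (p$b * (1 - p$s))
  x <- u * p$e * p$s / (p$l * p$b * (1 - p$s) + p$e * p$s)
  expect_equal(unname(eqs[[1]]$state), c(x, u - x, z), tolerance = 1e-9)

  # two-component, constant p: B(d / (b(M(1-p)-p)), 1 / (b(1-p)))
  p2 <- vh_params(d = 1, b = 0.01, M = 100, a = 0, s = 0.2, p_const = 0.5)
  m2 <- vh_model("two", "malthusian", "constant")
  eqs2 <- interior_equilibria(m2, p2)
  expect_length(eqs2, 1L)
  expect_equal(eqs2[[1]]$state[["x"]], 1 / (0.01 * 49.5), tolerance = 1e-9)
  expect_equal(eqs2[[1]]$state[["z"]], 200, tolerance = 1e-9)
  expect_lt(eqs2[[1]]$residual, 1e-10)
})

test_that("interior equilibria are strictly positive with tiny residuals", {
  set.seed(23)
  for (i in 1:20) {
    logistic <- i %% 2 == 0
    p <- random_params(logistic)
    m <- vh_model("three", if (logistic) "logistic" else "malthusian",
                  "virus_dependent")
    for (eq in interior_equilibria(m, p)) {
      expect_true(all(eq$state > 0))
      expect_lt(eq$residual, 1e-10)
      expect_lt(eq$state[["z"]], (1 + p$M) / p$b)
    }
  }
})

test_that("logistic interior equilibria satisfy the invariant-region bound", {
  eqs <- interior_equilibria(model3_log, fig2_params())
  expect_true(equilibrium_bound_check(eqs[[1]], fig2_params()))
  expect_equal(0.279 + 0.013, 0.292)
  expect_lt(20.24, (1 + 98.225) / 0.05)
  # boundary case x + y = 1 exactly is excluded (strict inequality)
  fake <- structure(list(state = c(x = 0.6, y = 0.4, z = 5), residual = 0,
                         kind = "interior", branch = "none"),
                    class = "vh_equilibrium")
  expect_false(equilibrium_bound_check(fake, fig2_params()))
  # property over random logistic draws with a = 1
  set.seed(31)
  n_checked <- 0
  while (n_checked < 50) {
    p <- random_params(logistic = TRUE)
    p$a <- 1
    for (eq in interior_equilibria(model3_log, p)) {
      expect_true(equilibrium_bound_check(eq, p))
      n_checked <- n_checked + 1
    }
  }
})

test_that("Malthusian equilibrium virus density does not depend on M", {
  zs <- malthusian_z_independence(fig1_params(), c(2, 10, 100, 1000))
  expect_true(all(is.finite(zs)))
  expect_lt(diff(range(zs)), 1e-8)
  # host coordinates shrink as M grows while z stays put
  xs <- vapply(c(10, 100, 1000), function(M) {
    interior_equilibria(model3_mal, fig1_params(M))[[1]]$state[["x"]]
  }, numeric(1))
  expect_true(all(diff(xs) < 0))
})

test_that("equilibrium count bounds hold per variant", {
  set.seed(17)
  for (i in 1:15) {
    pm <- random_params()
    expect_lte(length(interior_equilibria(model3_mal, pm)), 1L)
    expect_lte(length(interior_equilibria(model2_mal, pm)), 1L)
    pl <- random_params(logistic = TRUE)
    expect_lte(length(interior_equilibria(model2_log, pl)), 2L)
  }
})

test_that("whenever a Malthusian interior equilibrium exists,
           immunity there is below the virus replacement level", {
  set.seed(41)
  found <- 0
  for (i in 1:30) {
    p <- random_params()
    eqs <- interior_equilibria(model3_mal, p)
    if (length(eqs) == 1L) {
      found <- found + 1
      pz <- immunity(eqs[[1]]$state[["z"]], p)
      expect_lt(pz, p$M / (p$M + 1))
    }
  }
  expect_gt(found, 5)
})

test_that("scalar reduction agrees with brute-force multistart search", {
  set.seed(53)
  for (i in 1:8) {
    logistic <- i %% 2 == 0
    p <- random_params(logistic)
    m <- vh_model("three", if (logistic) "logistic" else "malthusian",
                  "virus_dependent")
    red <- interior_equilibria(m, p)
    brute <- equilibria_multistart(m, p)
    expect_length(brute, length(red))
    if (length(red) > 0 && length(brute) == length(red)) {
      zr <- sort(vapply(red, function(e) e$state[["z"]], numeric(1)))
      zb <- sort(vapply(brute, function(e) e$state[["z"]], numeric(1)))
      expect_equal(zr, zb, tolerance = 1e-8)
    }
  }
})

test_that("two-component logistic fold domains have the expected counts", {
  expect_length(interior_equilibria(model2_log, af1_params(12)), 0L)
  eqs <- interior_equilibria(model2_log, af1_params(25))
  expect_length(eqs, 2L)
  eqs100 <- interior_equilibria(model2_log, af1_params(100))
  expect_length(eqs100, 2L)
})

test_that("equilibria export to the TSV scan schema", {
  p <- fig2_params()
  eqs <- vh_equilibria(model3_log, p)
  df <- equilibria_to_df(eqs, model3_log, p)
  expect_equal(nrow(df), length(eqs))
  expect_true(all(c("model", "growth", "x_e", "y_e", "z_e", "residual",
                    "kind", "branch") %in% names(df)))
  expect_equal(df$kind, c("trivial_O", "boundary_A", "interior"))
})
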