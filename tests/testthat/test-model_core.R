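test_that("immunity law obeys its limits and matches direct evaluation", {
  p <- vh_params(s = 0.2, k = 0.1)
  # no virus: full adaptive immunity
  expect_equal(immunity(0, p), 1)
  # saturating virus load: innate immunity only
  expect_lt(immunity(300, p) - p$s, 1e-9)
  # direct evaluation at the reference point
  expect_equal(immunity(20.24, p), (1 - 0.2) * exp(-0.1 * 20.24) + 0.2,
               tolerance = 1e-12)
  expect_equal(immunity(20.24, p), 0.305701, tolerance = 1e-5 / 0.3)
  # constant mode ignores z
  pc <- vh_params(s = 0.2, p_const = 0.7)
  expect_equal(immunity(c(0, 5, 500), pc, "constant"), rep(0.7, 3))
  expect_error(immunity(-1, p), "nonnegative")
})

test_that("immunity is bounded in [s, 1] and monotone non-increasing", {
  set.seed(42)
  for (i in 1:25) {
    p <- random_params()
    z <- sort(runif(50, 0, 500))
    v <- immunity(z, p)
    expect_true(all(v >= p$s - 1e-12 & v <= 1 + 1e-12))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("immunity derivative equals k(s - p) and a finite difference", {
  p <- vh_params(s = 0.2, k = 0.1)
  expect_equal(immunity_derivative(0, p), 0.1 * (0.2 - 1))
  expect_equal(immunity_derivative(20.24, p),
               0.1 * (0.2 - immunity(20.24, p)), tolerance = 1e-12)
  expect_equal(immunity_derivative(20.24, p), -0.0105701, tolerance = 1e-4)
  h <- 1e-6
  fd <- (immunity(20.24 + h, p) - immunity(20.24 - h, p)) / (2 * h)
  expect_equal(immunity_derivative(20.24, p), fd, tolerance = 1e-8)
  expect_equal(immunity_derivative(7, vh_params(p_const = 0.5), "constant"), 0)
  expect_true(all(immunity_derivative(seq(0, 50, by = 5), p) <= 0))
})

test_that("rhs vanishes at the origin and matches an independent assembly", {
  set.seed(7)
  for (logistic in c(FALSE, TRUE)) {
    p <- random_params(logistic)
    growth <- if (logistic) "logistic" else "malthusian"
    m3 <- vh_model("three", growth, "virus_dependent")
    m2 <- vh_model("two", growth, "virus_dependent")
    expect_equal(unname(vh_rhs(m3, c(0, 0, 0), p)), c(0, 0, 0))
    expect_equal(unname(vh_rhs(m2, c(0, 0), p)), c(0, 0))
    p_fun <- function(z) (1 - p$s) * exp(-p$k * z) + p$s
    for (i in 1:20) {
      st3 <- random_state(3)
      expect_equal(unname(vh_rhs(m3, st3, p)), oracle_rhs3(st3, p, p_fun),
                   tolerance = 1e-13)
      st2 <- random_state(2)
      expect_equal(unname(vh_rhs(m2, st2, p)), oracle_rhs2(st2, p, p_fun),
                   tolerance = 1e-13)
    }
  }
})

test_that("rhs is small at the documented coexistence point of the reference
           logistic scenario", {
  m3 <- vh_model("three", "logistic", "virus_dependent")
  r <- vh_rhs(m3, c(0.279, 0.013, 20.24), fig2_params())
  # host balances within the rounding of the reference coordinates
  expect_lt(abs(r[["x"]]), 5e-3)
  expect_lt(abs(r[["y"]]), 5e-3)
  # virus balance is amplified by z ~ 20, so its rounding tolerance is larger
  expect_lt(abs(r[["z"]]), 5e-2)
})

test_that("orthant faces are invariant", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params(logistic = i %% 2 == 0)
    m3 <- vh_model("three", if (p$a > 0) "logistic" else "malthusian",
                   "virus_dependent")
    y <- runif(1, 0, 2); z <- runif(1, 0, 50); x <- runif(1, 0, 2)
    r <- vh_rhs(m3, c(0, y, z), p)
    expect_gte(r[["x"]], 0)          # dx/dt = e s y z at x = 0
    expect_equal(unname(vh_rhs(m3, c(x, y, 0), p)[["z"]]), 0)  # z = 0 plane
    expect_gte(vh_rhs(m3, c(x, 0, z), p)[["y"]], 0)  # dy/dt = l x at y = 0
  }
})

test_that("analytic Jacobian agrees with finite differences of the rhs", {
  set.seed(99)
  worst <- 0
  for (i in 1:100) {
    logistic <- i %% 2 == 0
    p <- random_params(logistic)
    growth <- if (logistic) "logistic" else "malthusian"
    two <- i %% 3 == 0
    m <- vh_model(if (two) "two" else "three", growth,
                  if (i %% 5 == 0) "constant" else "virus_dependent")
    if (m$immunity == "constant") p$p_const <- runif(1, p$s, 1)
    st <- random_state(if (two) 2 else 3)
    J <- vh_jacobian(m, st, p)
    Jfd <- fd_jac_of_rhs(m, st, p)
    worst <- max(worst, max(abs(J - Jfd) / (abs(Jfd) + 1)))
  }
  expect_lt(worst, 1e-6)
})

test_that("Jacobian eigenvalues at the trivial equilibria match closed forms", {
  m3 <- vh_model("three", "logistic", "virus_dependent")
  p <- fig2_params()
  evO <- eigen(vh_jacobian(m3, c(0, 0, 0), p), only.values = TRUE)$values
  expect_equal(sort(Re(evO)), sort(c(1, -p$d, 1 - p$l)), tolerance = 1e-12)
  evA <- eigen(vh_jacobian(m3, c(0, 1, 0), p), only.values = TRUE)$values
  lam3 <- p$b * (p$M * (1 - p$s) - p$s) - p$d  # a = 1
  expect_equal(sort(Re(evA)), sort(c(-p$l, -1, lam3)), tolerance = 1e-9)
  expect_equal(lam3, 0.05 * (98.225 * 0.8 - 0.2) - 1, tolerance = 1e-12)
  expect_gt(lam3, 0)  # A is unstable at these parameters
})

test_that("constant immunity at the innate level reduces the three-component
           model to the two-component host-total system", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_params(logistic = i %% 2 == 0)
    p$p_const <- p$s
    growth <- if (p$a > 0) "logistic" else "malthusian"
    m3 <- vh_model("three", growth, "constant")
    m2 <- vh_model("two", growth, "constant")
    st <- random_state(3)
    r3 <- vh_rhs(m3, st, p)
    r2 <- vh_rhs(m2, c(st[["x"]] + st[["y"]], st[["z"]]), p)
    expect_equal(unname(r3[["x"]] + r3[["y"]]), unname(r2[["x"]]),
                 tolerance = 1e-12)
    expect_equal(unname(r3[["z"]]), unname(r2[["z"]]), tolerance = 1e-12)
  }
})

test_that("invalid states and parameters are rejected", {
  m3 <- vh_model("three", "logistic", "virus_dependent")
  p <- fig2_params()
  expect_error(vh_rhs(m3, c(-0.1, 0.5, 1), p), "nonnegative")
  expect_error(vh_rhs(m3, c(0.1, 0.5), p), "3 components")
  expect_error(vh_params(s = 1.2), "0 < s < 1")
  expect_error(vh_params(d = 0), "strictly positive")
  expect_error(vh_params(s = 0.3, p_const = 0.1), "p_const")
  expect_error(vh_rhs(vh_model("three", "malthusian"), c(1, 1, 1),
                      fig2_params()), "a = 0")
})
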