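test_that("the origin is always unstable with the closed-form spectrum", {
  p <- vh_params(d = 1, l = 0.1)
  m <- vh_model("three", "malthusian", "virus_dependent")
  p$a <- 0
  O <- trivial_equilibria(m, p)[[1]]
  rep_ <- stability_analyze(O, m, p)
  expect_equal(sort(Re(rep_$eigenvalues)), c(-1, 0.9, 1), tolerance = 1e-12)
  expect_equal(rep_$class_label, "saddle")
  expect_gt(rep_$leading_real, 0)
})

test_that("closed-form spectra at O and A hold across random parameter
           draws, with the threshold degeneracies flagged", {
  set.seed(77)
  for (i in 1:100) {
    p <- random_params(logistic = TRUE)
    m <- vh_model("three", "logistic", "virus_dependent")
    expect_true(closed_form_eigen_check(m, p))
  }
  # l = 1 makes the third eigenvalue at O vanish
  p <- vh_params(l = 1, d = 1, a = 0)
  m <- vh_model("three", "malthusian", "virus_dependent")
  O <- trivial_equilibria(m, p)[[1]]
  expect_equal(stability_analyze(O, m, p)$class_label, "nonhyperbolic")
  # M at the transcritical value makes the third eigenvalue at A vanish
  pl <- vh_params(a = 1, d = 1, b = 0.05, s = 0.2)
  pl$M <- transcritical_M(pl)
  ml <- vh_model("three", "logistic", "virus_dependent")
  A <- trivial_equilibria(ml, pl)[[2]]
  evA <- stability_analyze(A, ml, pl)
  expect_lt(min(abs(Re(evA$eigenvalues))), 1e-9)
})

test_that("eigenvalues are sorted by descending real part", {
  p <- fig2_params()
  m <- vh_model("three", "logistic", "virus_dependent")
  eq <- interior_equilibria(m, p)[[1]]
  rep_ <- stability_analyze(eq, m, p)
  expect_true(all(diff(Re(rep_$eigenvalues)) <= 1e-12))
  expect_equal(rep_$leading_real, Re(rep_$eigenvalues[1]))
})

test_that("the two-component Malthusian constant-immunity interior point is
           a center", {
  p <- vh_params(d = 1, b = 0.01, M = 100, a = 0, s = 0.2, p_const = 0.5)
  m <- vh_model("two", "malthusian", "constant")
  eq <- interior_equilibria(m, p)[[1]]
  rep_ <- stability_analyze(eq, m, p)
  expect_equal(rep_$class_label, "center")
  expect_true(all(abs(Re(rep_$eigenvalues)) < 1e-10))
  expect_true(all(abs(Im(rep_$eigenvalues)) > 0.01))
})

test_that("two-component Malthusian interior point with declining immunity
           has positive determinant and trace (unstable node/spiral)", {
  set.seed(13)
  m <- vh_model("two", "malthusian", "virus_dependent")
  found <- 0; resolvable <- 0
  for (i in 1:20) {
    p <- random_params()
    eqs <- interior_equilibria(m, p)
    if (length(eqs) == 0L) next
    found <- found + 1
    st <- eqs[[1]]$state
    J <- vh_jacobian(m, st, p)
    expect_gt(det(J), 0)
    # the destabilizing trace is proportional to the adaptive-immunity excess
    # alpha = p(z) - s, which underflows for steep immunity decline; strict
    # positivity is asserted where alpha is numerically representable
    alpha <- (1 - p$s) * exp(-p$k * st[["z"]])
    if (alpha > 1e-10) {
      resolvable <- resolvable + 1
      expect_gt(sum(diag(J)), 0)
      rep_ <- stability_analyze(eqs[[1]], m, p,
                                hyper_tol = min(1e-8, alpha * 1e-3))
      expect_true(rep_$class_label %in% c("unstable_node", "unstable_spiral"))
    } else {
      expect_gt(sum(diag(J)), -1e-12)  # underflowed to rounding noise
    }
  }
  expect_gt(found, 5)
  expect_gt(resolvable, 2)
})

test_that("two-component logistic constant-immunity stability follows the
           positivity of the coexistence point", {
  set.seed(19)
  m <- vh_model("two", "logistic", "constant")
  for (i in 1:20) {
    p <- random_params(logistic = TRUE)
    p$p_const <- runif(1, p$s, min(0.95, p$M / (p$M + 1)))
    eqs <- interior_equilibria(m, p)
    A <- trivial_equilibria(m, p)[[2]]
    repA <- stability_analyze(A, m, p)
    positive_B <- p$b * (p$M * (1 - p$p_const) - p$p_const) - p$a * p$d > 0
    if (positive_B) {
      expect_length(eqs, 1L)
      repB <- stability_analyze(eqs[[1]], m, p)
      expect_true(repB$class_label %in% c("stable_node", "stable_spiral"))
      expect_equal(repA$class_label, "saddle")
    } else {
      expect_length(eqs, 0L)
      expect_equal(repA$class_label, "stable_node")
    }
  }
})

test_that("Malthusian interior equilibrium is destabilized by the
           virus-dependent immunity across the M grid", {
  for (M in c(2, 10, 100, 1000)) {
    rep_ <- malthusian_interior_instability(fig1_params(M))
    ev <- rep_$eigenvalues
    # one strictly negative real eigenvalue
    expect_equal(sum(abs(Im(ev)) < 1e-8 & Re(ev) < 0), 1L)
    # a complex pair whose real part is positive (by continuation where the
    # immunity excess underflows direct eigenvalue resolution)
    expect_equal(rep_$pair_re_sign, 1)
    expect_true(rep_$statement_pattern)
  }
  # at the reference parameters the excess is below double resolution,
  # so the sign must come from the continuation evidence
  rep_ <- malthusian_interior_instability(fig1_params(100))
  expect_equal(rep_$sign_method, "continuation")
  expect_true(all(rep_$continuation$ratio > 0))
})

test_that("direct destabilization is measurable at gentler immunity decline
           and grows with the steepness coefficient", {
  p <- fig1_params(100)
  res <- lapply(c(0.05, 0.1, 0.15), function(k) {
    p$k <- k
    malthusian_interior_instability(p)
  })
  for (r in res) {
    expect_equal(r$sign_method, "direct")
    expect_true(r$statement_pattern)
    expect_true(r$class_label %in%
                  c("unstable_spiral", "saddle", "nonhyperbolic"))
  }
  # l < e variant behaves the same way
  p2 <- vh_params(l = 0.1, e = 0.5, d = 1, M = 100, b = 0.01, a = 0,
                  k = 0.1, s = 0.1)
  r2 <- malthusian_interior_instability(p2)
  expect_equal(r2$pair_re_sign, 1)
})

test_that("stability reports flatten into the scan schema", {
  p <- fig2_params()
  m <- vh_model("three", "logistic", "virus_dependent")
  eqs <- vh_equilibria(m, p)
  df <- stability_to_df(lapply(eqs, stability_analyze, model = m, params = p))
  expect_equal(nrow(df), 3L)
  expect_true(all(c("re1", "im1", "re3", "class") %in% names(df)))
  expect_error(stability_analyze(
    structure(list(state = c(x = 1, y = 1, z = 1), residual = 1,
                   kind = "interior", branch = "none"),
              class = "vh_equilibrium"), m, p),
    "residual")
})
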