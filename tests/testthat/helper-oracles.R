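# Independent re-implementations used as oracles, written directly from the
# model definition in a different algebraic arrangement than the package code.

# Three-component right-hand side assembled term by term via per-process flows.
oracle_rhs3 <- function(state, pr, p_fun) {
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  p <- p_fun(z)
  growth_x <- x
  growth_y <- y
  decay_flow <- pr$l * x                 # immune -> sensitive
  crowding_x <- pr$a * x * (x + y)
  crowding_y <- pr$a * y * (x + y)
  kill_x <- pr$b * x * z * (1 - p)       # successful infections of immune hosts
  kill_y <- pr$b * y * z * (1 - pr$s)
  acquire <- pr$e * pr$s * y * z         # sensitive -> immune conversions
  virus_gain <- pr$b * pr$M * (x * (1 - p) + y * (1 - pr$s)) * z
  virus_loss <- pr$d * z + pr$b * (x * p + y * pr$s) * z
  c(growth_x - decay_flow - crowding_x - kill_x + acquire,
    growth_y + decay_flow - crowding_y - kill_y - acquire,
    virus_gain - virus_loss)
}

oracle_rhs2 <- function(state, pr, p_fun) {
  x <- state[[1]]; z <- state[[2]]
  p <- p_fun(z)
  c(x - pr$a * x^2 - pr$b * x * z * (1 - p),
    -pr$d * z - pr$b * x * z * p + pr$b * pr$M * x * z * (1 - p))
}

# Central finite-difference Jacobian of the packaged rhs.
fd_jac_of_rhs <- function(model, state, params, h_rel = 1e-6) {
  n <- length(state)
  J <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(state[j]), 1e-2)
    sp <- state; sp[j] <- sp[j] + h
    sm <- state; sm[j] <- max(sm[j] - h, 0)
    J[, j] <- (vh_rhs(model, sp, params) - vh_rhs(model, sm, params)) /
      (sp[j] - sm[j])
  }
  J
}

# Random valid parameter draw (moderate regime so equilibria are resolvable).
random_params <- function(logistic = FALSE) {
  vh_params(l = runif(1, 0.05, 1.2),
            e = runif(1, 0.05, 1),
            d = runif(1, 0.5, 2),
            M = 10^runif(1, 1, 2.5),
            b = 10^runif(1, -2, -0.7),
            a = if (logistic) runif(1, 0.5, 2) else 0,
            k = runif(1, 0.05, 1),
            s = runif(1, 0.05, 0.5))
}

random_state <- function(n = 3) {
  st <- c(runif(n - 1, 0.01, 2), 10^runif(1, -1, 1.7))
  names(st) <- if (n == 3) c("x", "y", "z") else c("x", "z")
  st
}

fig1_params <- function(M = 100)
  vh_params(l = 0.9, e = 0.1, d = 1, M = M, b = 0.01, a = 0, k = 0.5, s = 0.1)

fig2_params <- function(M = 98.225)
  vh_params(l = 0.1, e = 0.5, d = 1, M = M, b = 0.05, a = 1, k = 0.1, s = 0.2)

af1_params <- function(M = 25)
  vh_params(l = 0.1, e = 0.5, d = 1, M = M, b = 0.1, a = 1, k = 1, s = 0.15)

model3_log <- vh_model("three", "logistic", "virus_dependent")
model3_mal <- vh_model("three", "malthusian", "virus_dependent")
model2_log <- vh_model("two", "logistic", "virus_dependent")
model2_mal <- vh_model("two", "malthusian", "virus_dependent")
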