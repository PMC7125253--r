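# toy mixed-effects models sharing the production FOCE objective surface,
# plus their independent likelihood oracles

toy_linear_model <- function() {
  # f_ij = theta1 + theta2 * x_ij + eta1 + eta2 * x_ij, additive error
  fupkpd:::nlmm_model(
    pred = function(pop, eta, sd) pop$theta[1] + pop$theta[2] * sd$x +
      eta[["e1"]] + eta[["e2"]] * sd$x,
    resvar = function(pop, sd, f) rep(pop$sigma2, length(f)),
    eta_names_fn = function(pop) names(pop$omega2),
    name = "toy-linear")
}

toy_subjects <- function() {
  set.seed(31)
  lapply(1:3, function(i) {
    x <- c(0, 1, 2, 3)
    list(id = i, x = x, y = 1.5 + 0.8 * x + rnorm(1, 0, 0.3) +
           rnorm(1, 0, 0.2) * x + rnorm(4, 0, 0.15))
  })
}

# exact Gaussian marginal -2 log-likelihood from the mixed-model covariance
closed_form_m2ll <- function(pop, subs) {
  total <- 0
  for (sd in subs) {
    Z <- cbind(1, sd$x)
    V <- Z %*% diag(pop$omega2) %*% t(Z) + diag(pop$sigma2, length(sd$x))
    r <- sd$y - (pop$theta[1] + pop$theta[2] * sd$x)
    total <- total + determinant(V)$modulus[1] +
      drop(t(r) %*% solve(V, r)) + length(r) * log(2 * pi)
  }
  total
}

# one-subject proportional-error toy and its quadrature oracle
toy_prop_model <- function() {
  fupkpd:::nlmm_model(
    pred = function(pop, eta, sd) pop$theta * exp(eta[["e1"]]),
    resvar = function(pop, sd, f) f^2 * pop$sigma2,
    eta_names_fn = function(pop) names(pop$omega2),
    name = "toy-prop")
}

quadrature_m2ll <- function(theta, omega2, sigma2, y) {
  marg <- integrate(function(eta) {
    f <- theta * exp(eta)
    dnorm(y, f, f * sqrt(sigma2)) * dnorm(eta, 0, sqrt(omega2))
  }, -1, 1, rel.tol = 1e-12)$value
  -2 * log(marg)
}
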