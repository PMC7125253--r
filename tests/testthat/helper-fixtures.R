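# shared fixtures: final-model parameters and small study designs

final_pop <- function(column = "bootstrap") fu_final_model(column)

typical_params <- function(slope = 2.82, ...) {
  individual_parameters(CL = 249, Vc = 5.56, Vp = 28.5, Q = 14.8,
                        CLm = 121, Vm = 96.7, CIRC0 = 6.86, MTT = 281,
                        slope = slope, ...)
}

study_regimen <- function(dose = 1000, bsa = 1.95) {
  regimen_cvi(dose, bsa = bsa, days = 5)
}

# zero-variability copy of a population parameter set
novar_pop <- function(pop = final_pop(), sigma_floor = 0) {
  pop$omega2[] <- 0
  pop$sigma2[] <- sigma_floor
  pop
}

small_design <- function(n = 6, ...) {
  study_design(n_subjects = n, ...)
}

# brute-force numeric PK oracle: integrates the three-state linear system
# segment by segment with deSolve at tight tolerance
desolve_pk_oracle <- function(params, regimen, times) {
  rhs <- function(t, y, parms) {
    with(params, {
      cp <- y[1] / Vc
      list(c(parms$rate - (CL + Q) / Vc * y[1] + Q / Vp * y[2],
             Q / Vc * y[1] - Q / Vp * y[2],
             Fm * CL * cp - CLm / Vm * y[3]))
    })
  }
  stops <- sort(unique(c(0, regimen$start, regimen$start + regimen$duration,
                         times)))
  y <- c(0, 0, 0)
  out <- matrix(NA_real_, length(times), 3)
  for (k in seq_len(length(stops) - 1)) {
    t0 <- stops[k]; t1 <- stops[k + 1]
    bolus <- regimen$amount[regimen$duration == 0 & abs(regimen$start - t0) < 1e-12]
    if (length(bolus)) y[1] <- y[1] + sum(bolus)
    if (any(abs(times - t0) < 1e-12)) out[abs(times - t0) < 1e-12, ] <- rep(y, each = sum(abs(times - t0) < 1e-12))
    active <- regimen$duration > 0 & regimen$start <= t0 + 1e-12 &
      t0 < regimen$start + regimen$duration - 1e-12
    rate <- sum(regimen$amount[active] / regimen$duration[active])
    sol <- deSolve::lsoda(y, c(t0, t1), rhs, parms = list(rate = rate),
                          rtol = 1e-11, atol = 1e-13)
    y <- as.numeric(sol[nrow(sol), -1])
  }
  if (any(abs(times - stops[length(stops)]) < 1e-12)) {
    sel <- abs(times - stops[length(stops)]) < 1e-12
    out[sel, ] <- rep(y, each = sum(sel))
  }
  # interior times were all included as stops, so every row is filled
  out
}
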