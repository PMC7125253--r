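# Structural model: analytic PK, PD transit chain, AUC and nadir extraction.

test_that("constant infusion reaches the closed-form steady state for parent and metabolite", {
  p <- typical_params()
  # 1950 mg/day for long enough to be at steady state
  reg <- regimen(amount = 81.25 * 2000, start = 0, duration = 2000)
  pk <- pk_profile(p, reg, times = 1999)
  expect_equal(pk$cp_5fu, 81.25 / 249, tolerance = 1e-4)       # rate / CL
  expect_equal(pk$cp_5fuh2, 0.85 * 249 * (81.25 / 249) / 121,  # Fm CL Css / CLm
               tolerance = 1e-4)
})

test_that("zero dose yields identically zero concentrations", {
  p <- typical_params()
  pk <- pk_profile(p, regimen(amount = 0, start = 0, duration = 10),
                   times = c(0, 1, 5, 50))
  expect_true(all(pk$cp_5fu == 0))
  expect_true(all(pk$cp_5fuh2 == 0))
})

test_that("analytic PK matches a fine-tolerance numeric ODE oracle on random draws", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (i in 1:20) {
    p <- individual_parameters(
      CL = runif(1, 50, 400), Vc = runif(1, 2, 40), Vp = runif(1, 5, 60),
      Q = runif(1, 2, 40), CLm = runif(1, 40, 200), Vm = runif(1, 30, 150))
    reg <- regimen(amount = c(runif(1, 100, 1000), runif(1, 1000, 9000)),
                   start = c(0, runif(1, 0, 10)),
                   duration = c(0, runif(1, 10, 120)))
    times <- sort(runif(8, 0.5, 150))
    got <- pk_profile(p, reg, times)
    want <- desolve_pk_oracle(p, reg, times)
    expect_lt(max(abs(got$cp_5fu - want[, 1] / p$Vc) /
                    pmax(abs(want[, 1] / p$Vc), 1e-8)), 1e-6)
    expect_lt(max(abs(got$cp_5fuh2 - want[, 3] / p$Vm) /
                    pmax(abs(want[, 3] / p$Vm), 1e-8)), 1e-6)
  }
})

test_that("PK mass balance holds with elimination switched off", {
  p <- individual_parameters(CL = 0, Vc = 5.56, Vp = 28.5, Q = 14.8,
                             CLm = 121, Vm = 96.7)
  # CL = 0 also stops metabolite formation, so total PK amount = dosed amount
  reg <- regimen(amount = c(500, 4800), start = c(0, 2), duration = c(0, 48))
  times <- c(1, 10, 25, 50, 100)
  st <- fupkpd:::cpp_pk_states(fupkpd:::ind_par_vector(p),
                               fupkpd:::regimen_events(reg), times)
  dosed <- 500 + 4800 * pmin(pmax(times - 2, 0), 48) / 48
  expect_lt(max(abs(rowSums(st) - dosed) / dosed), 1e-8)
})

test_that("PK obeys superposition of regimens", {
  p <- typical_params()
  r1 <- regimen(amount = 2000, start = 0, duration = 24)
  r2 <- regimen(amount = c(500, 3000), start = c(6, 12), duration = c(0, 36))
  r12 <- regimen(amount = c(2000, 500, 3000), start = c(0, 6, 12),
                 duration = c(24, 0, 36))
  times <- c(3, 6, 12, 24, 30, 48, 60)
  s1 <- pk_profile(p, r1, times)
  s2 <- pk_profile(p, r2, times)
  s12 <- pk_profile(p, r12, times)
  expect_equal(s12$cp_5fu, s1$cp_5fu + s2$cp_5fu, tolerance = 1e-9)
  expect_equal(s12$cp_5fuh2, s1$cp_5fuh2 + s2$cp_5fuh2, tolerance = 1e-9)
})

test_that("overlapping infusions are summed, not rejected", {
  p <- typical_params()
  two <- regimen(amount = c(1200, 1200), start = c(0, 0), duration = c(24, 24))
  one <- regimen(amount = 2400, start = 0, duration = 24)
  expect_equal(pk_profile(p, two, 10)$cp_5fu, pk_profile(p, one, 10)$cp_5fu,
               tolerance = 1e-10)
})

test_that("PD chain stays at baseline when the drug effect is absent", {
  p <- typical_params(slope = 0)
  tr <- solve_pkpd(p, study_regimen(), times = seq(0, 1000, by = 10))
  expect_lt(max(abs(tr$wbc - p$CIRC0)), 1e-6 * p$CIRC0)
  expect_lt(max(abs(tr$Prol - p$CIRC0)), 1e-6 * p$CIRC0)
})

test_that("without feedback the proliferating pool decays exponentially under constant effect", {
  # tiny central volume and negligible distribution: cp sits at steady
  # state almost instantly, so E_drug is effectively constant from t = 0
  e <- 0.4
  css <- 81.25 / 249
  p <- individual_parameters(CL = 249, Vc = 0.001, Vp = 1, Q = 1e-6,
                             CLm = 121, Vm = 96.7, CIRC0 = 6.86, MTT = 281,
                             gamma = 0, slope = e / css)
  reg <- regimen(amount = 81.25 * 600, start = 0, duration = 600)
  tr <- solve_pkpd(p, reg, times = c(100, 300))
  ktr <- 4 / 281
  expect_equal(tr$Prol, 6.86 * exp(-ktr * e * tr$time), tolerance = 1e-4)
})

test_that("AUC accumulator reproduces rectangles, additivity and dose/CL", {
  p <- typical_params()
  reg <- study_regimen()
  tr <- solve_pkpd(p, reg, times = seq(0, 144, by = 0.5))
  # near steady state between 48 h and 72 h the 24-h AUC is daily dose / CL
  expect_equal(auc_window(tr, c(48, 72), "5FU"), 1950 / 249, tolerance = 1e-3)
  # additivity
  expect_equal(auc_window(tr, c(0, 60), "5FU") + auc_window(tr, c(60, 120), "5FU"),
               auc_window(tr, c(0, 120), "5FU"), tolerance = 1e-10)
  # zero concentration
  p0 <- typical_params()
  tr0 <- solve_pkpd(p0, regimen(amount = 0, start = 0, duration = 1),
                    times = seq(0, 48, by = 1))
  expect_equal(auc_window(tr0, c(0, 48), "5FU"), 0)
  expect_error(auc_window(tr, c(72, 48)), "t1 >= t0")
  expect_error(auc_window(tr, c(0, 1000)), "span")
})

test_that("AUC accumulator is non-decreasing and the trajectory non-negative", {
  p <- typical_params()
  tr <- solve_pkpd(p, study_regimen(), times = seq(0, 1080, by = 2))
  expect_true(all(diff(tr$auc_5fu) >= -1e-12))
  expect_true(all(diff(tr$auc_5fuh2) >= -1e-12))
  expect_true(all(as.matrix(tr[, -1]) >= 0))
  expect_equal(tr$wbc[1], p$CIRC0)
})

test_that("nadir search finds grid minima and refines to 0.01 h", {
  # bare parabola series (no attached model): grid minimum
  tt <- seq(0, 300, by = 1)
  fake <- data.frame(time = tt, wbc = 5 + (tt - 100)^2 / 1000)
  class(fake) <- c("fu_trajectory", "data.frame")
  nad <- find_nadir(fake)
  expect_equal(nad$t_nadir, 100)
  expect_equal(nad$wbc_nadir, 5)
  # flat trajectory: earliest-time tie-break
  p0 <- typical_params(slope = 0)
  tr0 <- solve_pkpd(p0, study_regimen(), times = seq(0, 900, by = 10))
  nad0 <- find_nadir(tr0)
  expect_equal(nad0$t_nadir, 0)
  expect_equal(nad0$wbc_nadir, p0$CIRC0)
  # refined search on the real model agrees with a very fine grid
  p <- typical_params()
  tr <- solve_pkpd(p, study_regimen(), times = seq(0, 1080, by = 12))
  nad1 <- find_nadir(tr)
  fine <- solve_pkpd(p, study_regimen(), times = seq(500, 700, by = 0.01))
  expect_equal(nad1$wbc_nadir, min(fine$wbc), tolerance = 1e-7)
  expect_lt(abs(nad1$t_nadir - fine$time[which.min(fine$wbc)]), 0.02)
})

test_that("an unbracketed nadir is reported as an error", {
  p <- typical_params()
  tr <- solve_pkpd(p, study_regimen(), times = seq(0, 360, by = 4))
  expect_error(find_nadir(tr), "not bracketed")
})

test_that("nadir deepens with slope and with infusion rate", {
  nadir_at <- function(slope, dose) {
    tr <- suppressWarnings(
      solve_pkpd(typical_params(slope = slope), study_regimen(dose = dose),
                 times = seq(0, 1080, by = 6)))
    suppressWarnings(find_nadir(tr)$wbc_nadir)
  }
  by_slope <- vapply(c(0.5, 1.17, 2, 2.82, 4), nadir_at, 0, dose = 1000)
  expect_true(all(diff(by_slope) < 0))
  by_dose <- vapply(c(400, 650, 1000, 1400, 2000), nadir_at, 0, slope = 1.17)
  expect_true(all(diff(by_dose) < 0))
})

test_that("invalid structural inputs are rejected", {
  expect_error(individual_parameters(CL = NaN, Vc = 5, Vp = 20, Q = 10,
                                     CLm = 100, Vm = 90), "finite")
  expect_error(individual_parameters(CL = 249, Vc = -1, Vp = 20, Q = 10,
                                     CLm = 100, Vm = 90), "positive")
  expect_error(individual_parameters(CL = 249, Vc = 5, Vp = 20, Q = 10,
                                     CLm = 100, Vm = 90, Fm = 1.2), "Fm")
  expect_error(regimen(amount = -5), ">= 0")
  p <- typical_params()
  expect_error(pk_profile(p, study_regimen(), times = c(3, 2, 1)), "sorted")
  expect_error(pk_profile(p, study_regimen(), times = c(-1, 2)), "non-negative")
})

test_that("drug effect above one warns but still integrates", {
  p <- typical_params(slope = 40)  # E_drug ~ 13 at steady state
  expect_warning(tr <- solve_pkpd(p, study_regimen(), times = seq(0, 240, 4)),
                 "net cell loss")
  expect_true(all(is.finite(tr$wbc)))
})

test_that("Michaelis-Menten elimination reduces to the linear model at high Km", {
  p_lin <- typical_params(slope = 1.17)
  # Vmax / Km = CL in the low-concentration limit
  p_mm <- individual_parameters(CL = 249, Vc = 5.56, Vp = 28.5, Q = 14.8,
                                CLm = 121, Vm = 96.7, CIRC0 = 6.86, MTT = 281,
                                slope = 1.17, Vmax = 249 * 1e4, Km = 1e4)
  tt <- c(24, 96, 120, 121, 200)
  lin <- solve_pkpd(p_lin, study_regimen(), tt)
  mm <- solve_pkpd(p_mm, study_regimen(), tt)
  expect_equal(mm$cp_5fu, lin$cp_5fu, tolerance = 1e-4)
  expect_equal(mm$wbc, lin$wbc, tolerance = 1e-4)
  # with a Km in the observed concentration range elimination saturates:
  # steady-state concentration must exceed the linear prediction
  p_sat <- individual_parameters(CL = 249, Vc = 5.56, Vp = 28.5, Q = 14.8,
                                 CLm = 121, Vm = 96.7, CIRC0 = 6.86,
                                 MTT = 281, slope = 1.17,
                                 Vmax = 249 * 0.4, Km = 0.4)
  # saturated elimination raises exposure enough that E_drug exceeds 1
  sat <- suppressWarnings(solve_pkpd(p_sat, study_regimen(), tt))
  expect_gt(sat$cp_5fu[3], lin$cp_5fu[3])
})

test_that("regimen YAML serialisation round-trips", {
  reg <- regimen_folfirinox_5fu(bsa = 1.95)
  path <- tempfile(fileext = ".yaml")
  write_regimen(reg, path)
  back <- read_regimen(path)
  expect_equal(as.data.frame(back), as.data.frame(reg))
  unlink(path)
})

test_that("trajectory CSV export contains the documented columns", {
  tr <- solve_pkpd(typical_params(), study_regimen(), times = seq(0, 240, 24))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path)
  expect_named(back, c("time", "cp_5fu", "cp_5fuh2", "wbc"))
  expect_equal(back$wbc, tr$wbc, tolerance = 1e-12)
  unlink(path)
})
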