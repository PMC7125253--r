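# Synthetic study generator: cohorts, observation tables, file round-trips.

test_that("cohort generation is reproducible and honours the design", {
  design <- study_design()
  c1 <- generate_cohort(design, seed = 5)
  c2 <- generate_cohort(design, seed = 5)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 30)
  expect_equal(sum(c1$COMED), 14)          # exact split 14/30
  expect_true(all(c1$BSA >= 1.48 & c1$BSA <= 2.33))
  expect_true(all(c1$DOSE %in% c(650, 1000)))
  c3 <- generate_cohort(design, seed = 6)
  expect_false(identical(c1$BSA, c3$BSA))
})

test_that("invalid designs are rejected", {
  expect_error(study_design(n_subjects = 0), "n_subjects")
  expect_error(study_design(comedication_fraction = 1.4), "comedication_fraction")
  expect_error(study_design(wbc_days = c(0, 40)), "672")
})

test_that("datasets are reproducible and regenerating them keeps the cohort fixed", {
  design <- small_design(4)
  pop <- final_pop()
  coh <- generate_cohort(design, seed = 3)
  d1 <- simulate_dataset(coh, pop, design, seed = 3)
  d2 <- simulate_dataset(coh, pop, design, seed = 3)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # dataset stream is offset from the cohort stream: a fresh cohort with the
  # same master seed is unchanged
  expect_identical(generate_cohort(design, seed = 3), coh)
})

test_that("per-protocol record counts match the sampling schedule", {
  design <- study_design(n_subjects = 8, wbc_retention = 1)
  pop <- final_pop()
  coh <- generate_cohort(design, seed = 2)
  tab <- simulate_dataset(coh, pop, design, seed = 2)
  for (id in coh$ID) {
    sub <- tab[tab$ID == id, ]
    expect_equal(sum(sub$AMT > 0), 1)                    # one infusion event
    expect_equal(sum(sub$DVID == 1), 9)                  # 9 5FU samples
    expect_equal(sum(sub$DVID == 2), 9)                  # 9 5FUH2 samples
    expect_equal(sum(sub$DVID == 3), length(design$wbc_days))
    # pre-dose concentration records are zero and flagged BQL
    pre <- sub[sub$TIME == 0 & sub$DVID %in% 1:2, ]
    expect_true(all(pre$DV == 0))
    expect_true(all(pre$BLQ == 1))
  }
  # infusion encodes the BSA-converted daily dose over 120 h
  s1 <- tab[tab$ID == 1 & tab$AMT > 0, ]
  expect_equal(s1$AMT, coh$DOSE[1] * coh$BSA[1] * 5)
  expect_equal(s1$RATE, s1$AMT / 120)
})

test_that("thinned WBC schedule averages out near the reported density", {
  design <- study_design(n_subjects = 60)
  pop <- final_pop()
  coh <- generate_cohort(design, seed = 8)
  tab <- simulate_dataset(coh, pop, design, seed = 8)
  per_subj <- tapply(tab$DVID == 3, tab$ID, sum)
  # 135 observations / 29 patients ~ 4.7 per subject
  expect_gt(mean(per_subj), 3.6)
  expect_lt(mean(per_subj), 5.8)
})

test_that("zero variability reproduces the typical predictions exactly", {
  design <- small_design(3, wbc_retention = 1)
  pop0 <- novar_pop()
  coh <- generate_cohort(design, seed = 4)
  tab <- simulate_dataset(coh, pop0, design, seed = 4)
  for (id in coh$ID) {
    s <- coh[coh$ID == id, ]
    ip <- individual_params(pop0, numeric(),
                            subject(id, s$BSA, s$COMED == 1, s$DOSE))
    reg <- regimen_cvi(s$DOSE, bsa = s$BSA, days = 5)
    sub <- tab[tab$ID == id & tab$MDV == 0, ]
    tr <- solve_pkpd(ip, reg, sort(unique(sub$TIME)))
    for (k in seq_len(nrow(sub))) {
      row <- sub[k, ]
      want <- switch(row$DVID, tr$cp_5fu, tr$cp_5fuh2, tr$wbc)[
        match(row$TIME, tr$time)]
      expect_equal(row$DV, want, tolerance = 1e-10)
    }
  }
})

test_that("baseline WBC mean matches the log-normal mean identity", {
  design <- study_design(n_subjects = 400)
  pop <- final_pop()
  coh <- generate_cohort(design, seed = 10)
  tab <- simulate_dataset(coh, pop, design, seed = 10)
  base <- tab$DV[tab$DVID == 3 & tab$TIME == 0]
  om2 <- pop$omega2[["CIRC0"]]
  expect_equal(mean(base), pop$theta[["CIRC0"]] * exp(om2 / 2),
               tolerance = 0.03)
})

test_that("the BQL fraction is monotone in the limit of quantification", {
  pop <- final_pop()
  frac <- vapply(c(0.005, 0.05, 0.2), function(l) {
    design <- study_design(n_subjects = 12,
                           lloq = c("5fu" = l, "5fuh2" = 0.01))
    coh <- generate_cohort(design, seed = 12)
    tab <- simulate_dataset(coh, pop, design, seed = 12)
    mean(tab$BLQ[tab$DVID == 1])
  }, 0)
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], frac[1])
})

test_that("observation tables round-trip through CSV with provenance sidecar", {
  design <- small_design(3)
  pop <- final_pop()
  tab <- simulate_dataset(generate_cohort(design, seed = 1), pop, design,
                          seed = 1)
  path <- tempfile(fileext = ".csv")
  write_table(tab, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 1)
  expect_equal(side$package, "fupkpd")
  back <- read_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab)[, names(back)],
               tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))
})

test_that("table validation rejects malformed inputs", {
  design <- small_design(2)
  pop <- final_pop()
  tab <- simulate_dataset(generate_cohort(design, seed = 1), pop, design,
                          seed = 1)
  path <- tempfile(fileext = ".csv")

  bad <- tab; bad$DVID[5] <- 4L
  expect_error(write_table(bad, path), "unknown DVID")

  bad <- tab[, setdiff(names(tab), "RATE")]
  expect_error(fupkpd:::validate_obs_table(bad), "missing mandatory column")

  bad <- tab; bad$TIME[2] <- 999  # later records have earlier times
  expect_error(fupkpd:::validate_obs_table(bad), "not sorted")

  # observation before any dose record
  bad <- tab[tab$AMT == 0, ]
  expect_error(fupkpd:::validate_obs_table(bad), "before any dose")

  file.create(path)
  expect_error(read_table(path), "no records")
  unlink(path)
  expect_error(read_table(path), "not found")
})
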