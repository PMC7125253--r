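#' Synthetic study design
#'
#' Describes the sampling and dosing design of the continuous-infusion 5FU
#' study that the synthetic-data generator emulates: 30 subjects (5 women,
#' 25 men), BSA with median 1.95 m2 and observed range 1.48-2.33 m2, 650 or
#' 1000 mg/m2/day as a 120-h continuous infusion, 14/30 with cisplatin
#' co-medication, PK samples at pre-dose, 36, 48 and 108 h, end of infusion
#' and 5/30/60/90 min thereafter, and WBC counts at baseline and one to
#' three times per week until day 28.
#'
#' @param n_subjects number of subjects (default 30).
#' @param dose_levels 5FU dose levels, mg/m2/day.
#' @param dose_weights assignment probabilities of `dose_levels` (the study
#'   does not report the split; default 50:50).
#' @param infusion_days infusion length in days (default 5, i.e. 120 h).
#' @param comedication_fraction fraction of subjects on cisplatin.
#' @param comedication_exact if `TRUE` (default) exactly
#'   `round(fraction * n)` subjects are co-medicated; otherwise Bernoulli.
#' @param female_fraction fraction of women (default 5/30).
#' @param bsa_median,bsa_sd,bsa_range truncated-normal BSA model (m2).
#' @param pk_times PK sampling times (h); the default encodes the protocol
#'   schedule with end of infusion at `24 * infusion_days`.
#' @param wbc_days WBC sampling days (baseline plus about twice weekly to
#'   day 28; exact per-patient days are not published, only totals).
#' @param wbc_retention per-visit retention probability of post-baseline WBC
#'   samples, thinning the schedule to about 4.7 observations per subject as
#'   in the study (135 counts / 29 patients).
#' @param lloq named lower limits of quantification, mg/L.
#' @return An object of class `fu_study_design`.
#' @export
study_design <- function(n_subjects = 30L,
                         dose_levels = c(650, 1000),
                         dose_weights = c(0.5, 0.5),
                         infusion_days = 5,
                         comedication_fraction = 14 / 30,
                         comedication_exact = TRUE,
                         female_fraction = 5 / 30,
                         bsa_median = 1.95, bsa_sd = 0.20,
                         bsa_range = c(1.48, 2.33),
                         pk_times = NULL,
                         wbc_days = c(0, 5, 8, 12, 15, 19, 22, 26),
                         wbc_retention = 0.52,
                         lloq = c("5fu" = 0.005, "5fuh2" = 0.01)) {
  eoi <- 24 * infusion_days
  if (is.null(pk_times))
    pk_times <- c(0, 36, 48, 108, eoi, eoi + c(5, 30, 60, 90) / 60)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (comedication_fraction < 0 || comedication_fraction > 1)
    stop("comedication_fraction must lie in [0, 1]", call. = FALSE)
  if (any(pk_times < 0) || any(pk_times > 672) ||
      any(wbc_days * 24 > 672) || any(wbc_days < 0))
    stop("sampling times must lie within [0, 672] h", call. = FALSE)
  if (length(dose_weights) != length(dose_levels))
    stop("dose_weights must match dose_levels", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 dose_levels = dose_levels,
                 dose_weights = dose_weights / sum(dose_weights),
                 infusion_days = infusion_days,
                 comedication_fraction = comedication_fraction,
                 comedication_exact = isTRUE(comedication_exact),
                 female_fraction = female_fraction,
                 bsa_median = bsa_median, bsa_sd = bsa_sd,
                 bsa_range = bsa_range,
                 pk_times = sort(pk_times), wbc_days = sort(wbc_days),
                 wbc_retention = wbc_retention, lloq = lloq),
            class = "fu_study_design")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a virtual cohort
#'
#' Draws subject-level covariates according to the study design: BSA from a
#' normal distribution centred on the cohort median, truncated to the
#' observed range by rejection; sex as Bernoulli; dose level per the design
#' weights; co-medication as an exact split (default) or Bernoulli.
#' Reproducible under a fixed seed.
#'
#' @param design a [study_design()].
#' @param seed integer seed.
#' @return An object of class `fu_cohort`: a data frame with columns `ID`,
#'   `BSA`, `SEX` (`"F"`/`"M"`), `COMED` (0/1), `DOSE` (mg/m2/day).
#' @export
generate_cohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "fu_study_design"))
  n <- design$n_subjects
  with_seed(seed, {
    bsa <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        b <- rnorm(1, design$bsa_median, design$bsa_sd)
        if (b >= design$bsa_range[1] && b <= design$bsa_range[2]) break
      }
      bsa[i] <- b
    }
    sex <- ifelse(runif(n) < design$female_fraction, "F", "M")
    dose <- design$dose_levels[
      sample.int(length(design$dose_levels), n, replace = TRUE,
                 prob = design$dose_weights)]
    if (design$comedication_exact) {
      k <- round(design$comedication_fraction * n)
      comed <- integer(n)
      comed[sample.int(n, k)] <- 1L
    } else {
      comed <- rbinom(n, 1, design$comedication_fraction)
    }
    out <- data.frame(ID = seq_len(n), BSA = round(bsa, 3), SEX = sex,
                      COMED = comed, DOSE = dose)
    attr(out, "seed") <- seed
    class(out) <- c("fu_cohort", "data.frame")
    out
  })
}

#' Simulate an observation table from a cohort
#'
#' For every subject, interindividual random effects are drawn from the
#' log-normal IIV model, the individual PKPD trajectory is solved, model
#' predictions are read at the design's sampling times, and proportional
#' residual error is applied per observation type. Concentrations below the
#' type-specific LLOQ are flagged BQL (`BLQ = 1`); the pre-dose PK sample is
#' zero by construction and flagged BQL. WBC visits after baseline are
#' retained with the design's per-visit retention probability.
#'
#' The dataset draw uses an RNG stream offset from `seed` so that
#' regenerating observations does not reshuffle a cohort generated with the
#' same master seed.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param pop a [population_parameters()] object used as true values.
#' @param design the [study_design()].
#' @param seed integer seed.
#' @return An object of class `fu_obs_table`: a long-format data frame in
#'   the NONMEM-style dialect with columns `ID`, `TIME`, `AMT`, `RATE`,
#'   `DV`, `DVID` (0 dose, 1 = 5FU, 2 = 5FUH2, 3 = WBC), `MDV`, `BLQ`,
#'   `BSA`, `COMED`, `DOSE`.
#' @export
simulate_dataset <- function(cohort, pop, design, seed = 1L) {
  stopifnot(inherits(cohort, "fu_cohort") || is.data.frame(cohort),
            inherits(pop, "fu_pop_params"), inherits(design, "fu_study_design"))
  dataset_seed <- (as.integer(seed) + 777L) %% .Machine$integer.max
  om2 <- pop$omega2
  n_edrug <- 0L
  with_seed(dataset_seed, {
    rows <- vector("list", nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      s <- cohort[i, ]
      eta <- setNames(rnorm(length(om2)) * sqrt(om2), names(om2))
      subj <- subject(s$ID, bsa = s$BSA, comedication = s$COMED == 1,
                      dose_per_m2 = s$DOSE)
      ip <- individual_params(pop, eta, subj)
      reg <- regimen_cvi(s$DOSE, bsa = s$BSA, days = design$infusion_days)
      wbc_t <- design$wbc_days * 24
      keep <- c(TRUE, runif(length(wbc_t) - 1) < design$wbc_retention)
      wbc_t <- wbc_t[keep]
      utimes <- sort(unique(c(design$pk_times, wbc_t)))
      tr <- withCallingHandlers(
        tryCatch(
          solve_pkpd(ip, reg, utimes),
          error = function(e) stop("integration failed for subject ", s$ID,
                                   " (CL=", signif(ip$CL, 4), ", Vc=",
                                   signif(ip$Vc, 4), "): ",
                                   conditionMessage(e), call. = FALSE)),
        warning = function(w) {
          if (grepl("net cell loss", conditionMessage(w))) {
            n_edrug <<- n_edrug + 1L
            invokeRestart("muffleWarning")
          }
        })
      at <- function(v, tq) v[match(tq, tr$time)]
      pk_t <- design$pk_times
      pred1 <- at(tr$cp_5fu, pk_t)
      pred2 <- at(tr$cp_5fuh2, pk_t)
      pred3 <- at(tr$wbc, wbc_t)
      obs1 <- residual_error(pred1, pop$sigma2[["prop_5fu"]], rnorm(length(pred1)))
      obs2 <- residual_error(pred2, pop$sigma2[["prop_5fuh2"]], rnorm(length(pred2)))
      obs3 <- residual_error(pred3, pop$sigma2[["prop_wbc"]], rnorm(length(pred3)))
      amt <- reg$amount
      dose_row <- data.frame(ID = s$ID, TIME = 0, AMT = amt,
                             RATE = amt / reg$duration, DV = NA_real_,
                             DVID = 0L, MDV = 1L, BLQ = 0L)
      ob <- function(tq, dv, dvid, lloq) {
        blq <- if (is.na(lloq)) rep(0L, length(dv)) else as.integer(dv < lloq)
        data.frame(ID = s$ID, TIME = tq, AMT = 0, RATE = 0, DV = dv,
                   DVID = dvid, MDV = 0L, BLQ = blq)
      }
      sub_rows <- rbind(dose_row,
                        ob(pk_t, obs1, 1L, design$lloq[["5fu"]]),
                        ob(pk_t, obs2, 2L, design$lloq[["5fuh2"]]),
                        ob(wbc_t, obs3, 3L, NA))
      sub_rows <- sub_rows[order(sub_rows$TIME, sub_rows$DVID), ]
      sub_rows$BSA <- s$BSA
      sub_rows$COMED <- s$COMED
      sub_rows$DOSE <- s$DOSE
      rows[[i]] <- sub_rows
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    class(out) <- c("fu_obs_table", "data.frame")
    if (n_edrug > 0)
      warning("drug effect exceeded 1 (net cell loss) for ", n_edrug,
              " subject(s)", call. = FALSE)
    out
  })
}

obs_table_columns <- c("ID", "TIME", "AMT", "RATE", "DV", "DVID", "MDV",
                       "BLQ", "BSA", "COMED", "DOSE")

validate_obs_table <- function(tab, file = "table") {
  if (!nrow(tab)) stop("no records in ", file, call. = FALSE)
  missing <- setdiff(obs_table_columns, names(tab))
  if (length(missing))
    stop("missing mandatory column(s) in ", file, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(tab$DVID %in% 0:3))
    stop("unknown DVID value(s): ",
         paste(unique(setdiff(tab$DVID, 0:3)), collapse = ", "), call. = FALSE)
  obs <- tab[tab$MDV == 0, ]
  if (any(!is.finite(obs$DV)) || any(obs$DV < 0))
    stop("observation values must be finite and >= 0", call. = FALSE)
  for (id in unique(tab$ID)) {
    ti <- tab$TIME[tab$ID == id]
    if (is.unsorted(ti))
      stop("times not sorted within subject ", id, call. = FALSE)
    sub <- tab[tab$ID == id, ]
    post <- sub$TIME[sub$MDV == 0 & sub$TIME > 0]
    if (length(post)) {
      dose_t <- sub$TIME[sub$AMT > 0]
      if (!length(dose_t) || min(dose_t) > min(post))
        stop("subject ", id, " has post-dose observations before any dose record",
             call. = FALSE)
    }
  }
  invisible(tab)
}

#' Read and write observation tables
#'
#' Lossless CSV round-trip of the NONMEM-style rectangular dialect (columns
#' `ID, TIME, AMT, RATE, DV, DVID, MDV, BLQ, BSA, COMED, DOSE`). On write, a
#' sidecar JSON file (`<path>.json`) records the generating seed (when
#' known) and package version for provenance. On read the table is
#' validated: mandatory columns present, times sorted within subject, DVID
#' within the documented set, at least one dose record before the first
#' post-dose observation of every subject.
#'
#' @param tab an observation table.
#' @param path CSV file path.
#' @return `read_table` returns a validated `fu_obs_table`; `write_table`
#'   returns `path` invisibly.
#' @export
write_table <- function(tab, path) {
  validate_obs_table(tab)
  write.csv(as.data.frame(tab)[, obs_table_columns], path, row.names = FALSE,
            na = ".")
  sidecar <- list(seed = attr(tab, "seed"),
                  package = "fupkpd",
                  version = as.character(packageVersion("fupkpd")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("no records in ", path, call. = FALSE)
  tab <- tryCatch(read.csv(path, na.strings = c(".", "NA")),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  validate_obs_table(tab, file = path)
  class(tab) <- c("fu_obs_table", "data.frame")
  tab
}
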