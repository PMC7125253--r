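#' Population PKPD parameters
#'
#' Container for the population model: fixed effects `theta`,
#' interindividual variances `omega2` (log-normal, diagonal), residual
#' proportional-error variances `sigma2` and structural constants. IIV is
#' carried by exactly the parameters named in `omega2`; in the final study
#' model these are `CL`, `Vc`, `CLm`, `Vm` and `CIRC0`.
#'
#' @param theta named numeric vector with elements `CL`, `Vc`, `Vp`, `Q`,
#'   `CLm`, `Vm`, `CIRC0`, `MTT`, `slope_mono`, `slope_comb`, `theta_bsa`
#'   (fractional change in both clearances per m2 difference from the
#'   reference BSA; may be negative).
#' @param omega2 named numeric vector of IIV variances (log scale); names
#'   must be a subset of `c("CL", "Vc", "CLm", "Vm", "CIRC0")`.
#' @param sigma2 named numeric vector of proportional residual variances
#'   with elements `prop_5fu`, `prop_5fuh2`, `prop_wbc`.
#' @param fixed list of structural constants: `Fm` (default 0.85), `gamma`
#'   (default 0.17), `n_transit` (default 3), `bsa_ref` (default 1.95 m2).
#' @return An object of class `fu_pop_params`.
#' @export
population_parameters <- function(theta, omega2, sigma2,
                                  fixed = list(Fm = 0.85, gamma = 0.17,
                                               n_transit = 3L, bsa_ref = 1.95)) {
  th_names <- c("CL", "Vc", "Vp", "Q", "CLm", "Vm", "CIRC0", "MTT",
                "slope_mono", "slope_comb", "theta_bsa")
  if (!all(th_names %in% names(theta)))
    stop("theta must contain: ", paste(setdiff(th_names, names(theta)),
                                       collapse = ", "), call. = FALSE)
  theta <- theta[th_names]
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  if (any(theta[setdiff(th_names, "theta_bsa")] <= 0))
    stop("all theta except theta_bsa must be strictly positive", call. = FALSE)
  iiv_names <- c("CL", "Vc", "CLm", "Vm", "CIRC0")
  if (!all(names(omega2) %in% iiv_names))
    stop("omega2 names must be among: ", paste(iiv_names, collapse = ", "),
         call. = FALSE)
  if (any(omega2 < 0) || any(!is.finite(omega2)))
    stop("omega2 must be finite and >= 0", call. = FALSE)
  sg_names <- c("prop_5fu", "prop_5fuh2", "prop_wbc")
  if (!all(sg_names %in% names(sigma2)))
    stop("sigma2 must contain: ", paste(sg_names, collapse = ", "), call. = FALSE)
  sigma2 <- sigma2[sg_names]
  if (any(sigma2 < 0) || any(!is.finite(sigma2)))
    stop("sigma2 must be finite and >= 0", call. = FALSE)
  fixed <- modifyList(list(Fm = 0.85, gamma = 0.17, n_transit = 3L,
                           bsa_ref = 1.95), fixed)
  structure(list(theta = theta, omega2 = omega2, sigma2 = sigma2,
                 fixed = fixed),
            class = "fu_pop_params")
}

#' @export
print.fu_pop_params <- function(x, ...) {
  cat("Population PKPD parameters\n")
  cat("theta:\n"); print(signif(x$theta, 4))
  cat("omega2 (IIV variances, %CV):\n")
  print(round(100 * sqrt(exp(x$omega2) - 1), 1))
  cat("sigma2 (proportional residual variances):\n"); print(signif(x$sigma2, 3))
  cat(sprintf("fixed: Fm %.3g, gamma %.3g, n_transit %d, bsa_ref %.3g m2\n",
              x$fixed$Fm, x$fixed$gamma, as.integer(x$fixed$n_transit),
              x$fixed$bsa_ref))
  invisible(x)
}

#' Packaged final-model parameter sets
#'
#' Loads the packaged parameter file carrying the two reported columns of
#' the final-model estimates: the direct NONMEM estimates and the bootstrap
#' medians. IIV magnitudes are stored in the file as %CV and converted to
#' log-normal variances via `omega2 = log(1 + (CV/100)^2)`.
#'
#' @param column `"bootstrap"` (default) or `"nonmem"`.
#' @return A [population_parameters()] object.
#' @examples
#' fu_final_model("bootstrap")$theta[["CL"]]
#' @export
fu_final_model <- function(column = c("bootstrap", "nonmem")) {
  column <- match.arg(column)
  path <- system.file("extdata", "final_model_parameters.yaml",
                      package = "fupkpd", mustWork = TRUE)
  read_parameters(path, column = column)
}

#' Read or write population parameters as YAML
#'
#' The file holds one or more named columns (parameter sets), each with
#' `theta`, `iiv_cv` (as %CV) and `sigma2` blocks, plus a shared `fixed`
#' block. `write_parameters` writes a single-column file.
#'
#' @param path file path.
#' @param column which column to load (defaults to the first).
#' @param pop a [population_parameters()] object.
#' @param name column name to write under.
#' @return `read_parameters` returns [population_parameters()];
#'   `write_parameters` returns `path` invisibly.
#' @export
read_parameters <- function(path, column = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$columns) || !length(y$columns))
    stop("no parameter columns in ", path, call. = FALSE)
  column <- column %||% names(y$columns)[1]
  if (!column %in% names(y$columns))
    stop("unknown parameter column '", column, "'; available: ",
         paste(names(y$columns), collapse = ", "), call. = FALSE)
  col <- y$columns[[column]]
  fixed <- y$fixed %||% list()
  cv <- unlist(col$iiv_cv)
  population_parameters(
    theta = unlist(col$theta),
    omega2 = log(1 + (cv / 100)^2),
    sigma2 = unlist(col$sigma2),
    fixed = fixed)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(pop, path, name = "estimates") {
  stopifnot(inherits(pop, "fu_pop_params"))
  cols <- list()
  cols[[name]] <- list(
    theta = as.list(pop$theta),
    iiv_cv = as.list(round(100 * sqrt(exp(pop$omega2) - 1), 6)),
    sigma2 = as.list(pop$sigma2))
  yaml::write_yaml(list(columns = cols, fixed = pop$fixed), path)
  invisible(path)
}

#' Study subject
#'
#' @param id subject identifier.
#' @param bsa body surface area (m2), plausibility-checked to (1.0, 3.0).
#' @param comedication logical: cisplatin co-medication.
#' @param dose_per_m2 assigned 5FU dose (mg/m2/day).
#' @param covariates optional named list of additional covariates (age,
#'   weight, sex, genotype classes, ...).
#' @return An object of class `fu_subject`.
#' @export
subject <- function(id, bsa, comedication = FALSE, dose_per_m2 = 1000,
                    covariates = list()) {
  if (!is.numeric(bsa) || bsa < 1.0 || bsa > 3.0)
    stop("BSA outside plausible range (1.0-3.0 m2)", call. = FALSE)
  structure(list(id = id, bsa = bsa, comedication = isTRUE(comedication),
                 dose_per_m2 = dose_per_m2, covariates = covariates),
            class = "fu_subject")
}

#' Map population parameters and random effects to an individual
#'
#' Typical values are scaled by the covariate model, then log-normal IIV is
#' applied: `P_i = theta_P * cov_factor * exp(eta_P)`. Both clearances share
#' a single linear BSA factor `1 + theta_bsa * (BSA - bsa_ref)` applied
#' before the random effect. The drug-effect slope is `slope_comb` for
#' cisplatin-comedicated subjects and `slope_mono` otherwise. Parameters not
#' named in `omega2` take their typical value.
#'
#' @param pop a [population_parameters()] object.
#' @param eta named numeric vector of random effects; names must match
#'   `names(pop$omega2)` (missing entries are treated as 0).
#' @param subj a [subject()].
#' @return An [individual_parameters()] object.
#' @examples
#' pop <- fu_final_model()
#' individual_params(pop, eta = c(CL = 0.1), subject(1, bsa = 2.1))
#' @export
individual_params <- function(pop, eta = numeric(), subj) {
  stopifnot(inherits(pop, "fu_pop_params"), inherits(subj, "fu_subject"))
  if (length(eta)) {
    if (is.null(names(eta)) || !all(names(eta) %in% names(pop$omega2)))
      stop("eta names must match names(pop$omega2)", call. = FALSE)
  }
  e <- setNames(numeric(5), c("CL", "Vc", "CLm", "Vm", "CIRC0"))
  e[names(eta)] <- eta
  th <- pop$theta
  cov_cl <- 1 + th[["theta_bsa"]] * (subj$bsa - pop$fixed$bsa_ref)
  if (cov_cl <= 0)
    stop("BSA covariate factor is non-positive for BSA = ", subj$bsa,
         " (theta_bsa = ", th[["theta_bsa"]], "); clearance would be invalid",
         call. = FALSE)
  individual_parameters(
    CL = th[["CL"]] * cov_cl * exp(e[["CL"]]),
    Vc = th[["Vc"]] * exp(e[["Vc"]]),
    Vp = th[["Vp"]],
    Q = th[["Q"]],
    CLm = th[["CLm"]] * cov_cl * exp(e[["CLm"]]),
    Vm = th[["Vm"]] * exp(e[["Vm"]]),
    Fm = pop$fixed$Fm,
    CIRC0 = th[["CIRC0"]] * exp(e[["CIRC0"]]),
    MTT = th[["MTT"]],
    gamma = pop$fixed$gamma,
    slope = if (subj$comedication) th[["slope_comb"]] else th[["slope_mono"]],
    n_transit = pop$fixed$n_transit)
}

#' Apply proportional residual error to a model prediction
#'
#' `y = pred * (1 + sqrt(sigma2) * eps)`, so that `Var(y | pred) =
#' pred^2 * sigma2`. Observations are floored at zero (a draw more than
#' `1/sqrt(sigma2)` below the mean would otherwise be negative).
#'
#' @param pred non-negative model prediction (concentration or count).
#' @param sigma2 proportional-error variance (>= 0).
#' @param eps standard-normal draw(s), same length as `pred` or length 1.
#' @return Perturbed observation(s).
#' @export
residual_error <- function(pred, sigma2, eps) {
  if (length(sigma2) != 1L || !is.finite(sigma2) || sigma2 < 0)
    stop("sigma2 must be a single finite value >= 0", call. = FALSE)
  if (any(pred < 0)) stop("predictions must be >= 0", call. = FALSE)
  pmax(pred * (1 + sqrt(sigma2) * eps), 0)
}
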