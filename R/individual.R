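#' Individual-level PKPD parameters
#'
#' Parameters of the structural model for one subject: two-compartment 5FU
#' disposition with linear elimination, one-compartment 5FUH2 metabolite
#' (formation fraction `Fm`), and the transit-compartment myelosuppression
#' chain. The proliferation, transit and circulating-pool rate constants are
#' tied together, `kprol = ktr = kcirc = (n_transit + 1) / MTT`.
#'
#' @param CL 5FU total clearance (L/h).
#' @param Vc 5FU central volume (L).
#' @param Vp 5FU peripheral volume (L).
#' @param Q intercompartmental clearance (L/h).
#' @param CLm 5FUH2 clearance (L/h).
#' @param Vm 5FUH2 volume (L).
#' @param Fm fraction of 5FU converted to 5FUH2 (default 0.85).
#' @param CIRC0 baseline circulating leukocyte count (1e9/L).
#' @param MTT mean transit time of the maturation chain (h).
#' @param gamma feedback exponent of `(CIRC0 / Circ)^gamma` (default 0.17).
#' @param slope linear drug-effect coefficient (L/mg), `E_drug = slope * Cp`.
#' @param n_transit number of transit compartments (default 3).
#' @param emax,ec50 optional Emax drug-effect model (`E_drug = emax * Cp /
#'   (ec50 + Cp)`); used instead of `slope` when both are supplied.
#' @param Vmax,Km optional Michaelis-Menten elimination (mg/h, mg/L); when
#'   supplied they replace the linear clearance `CL` and the model is
#'   integrated fully numerically.
#' @return An object of class `fu_ind_params` (a named list).
#' @export
individual_parameters <- function(CL, Vc, Vp, Q, CLm, Vm, Fm = 0.85,
                                  CIRC0 = 6.86, MTT = 281, gamma = 0.17,
                                  slope = 0, n_transit = 3L,
                                  emax = NULL, ec50 = NULL,
                                  Vmax = NULL, Km = NULL) {
  p <- list(CL = CL, Vc = Vc, Vp = Vp, Q = Q, CLm = CLm, Vm = Vm, Fm = Fm,
            CIRC0 = CIRC0, MTT = MTT, gamma = gamma, slope = slope,
            n_transit = as.integer(n_transit),
            emax = emax, ec50 = ec50, Vmax = Vmax, Km = Km)
  validate_ind_params(p)
  class(p) <- "fu_ind_params"
  p
}

validate_ind_params <- function(p) {
  num <- c("CL", "Vc", "Vp", "Q", "CLm", "Vm", "Fm", "CIRC0", "MTT", "gamma",
           "slope")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  pos <- c("Vc", "Vp", "Q", "CLm", "Vm", "CIRC0", "MTT")
  for (nm in pos) if (p[[nm]] <= 0)
    stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  if (p$CL < 0) stop("CL must be >= 0", call. = FALSE)
  if (p$Fm < 0 || p$Fm > 1) stop("Fm must lie in [0, 1]", call. = FALSE)
  if (p$slope < 0) stop("slope must be >= 0", call. = FALSE)
  if (p$gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (p$n_transit < 1L) stop("n_transit must be >= 1", call. = FALSE)
  if (!is.null(p$Vmax) && (p$Vmax <= 0 || is.null(p$Km) || p$Km <= 0))
    stop("Michaelis-Menten elimination needs Vmax > 0 and Km > 0", call. = FALSE)
  if (!is.null(p$emax) && (is.null(p$ec50) || p$ec50 <= 0))
    stop("Emax drug effect needs ec50 > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.fu_ind_params <- function(x, ...) {
  cat("Individual PKPD parameters (mg, L, h, 1e9/L):\n")
  cat(sprintf("  PK: CL %.4g, Vc %.4g, Vp %.4g, Q %.4g | 5FUH2: CLm %.4g, Vm %.4g, Fm %.3g\n",
              x$CL, x$Vc, x$Vp, x$Q, x$CLm, x$Vm, x$Fm))
  cat(sprintf("  PD: CIRC0 %.4g, MTT %.4g h (ktr %.4g /h), gamma %.3g, slope %.4g, n_transit %d\n",
              x$CIRC0, x$MTT, (x$n_transit + 1) / x$MTT, x$gamma, x$slope,
              x$n_transit))
  if (!is.null(x$Vmax))
    cat(sprintf("  Michaelis-Menten elimination: Vmax %.4g mg/h, Km %.4g mg/L\n",
                x$Vmax, x$Km))
  invisible(x)
}

ind_par_vector <- function(p) {
  v <- c(CL = p$CL, Vc = p$Vc, Vp = p$Vp, Q = p$Q, CLm = p$CLm, Vm = p$Vm,
         Fm = p$Fm, CIRC0 = p$CIRC0, MTT = p$MTT, gamma = p$gamma,
         slope = p$slope)
  if (!is.null(p$emax)) v <- c(v, emax = p$emax, ec50 = p$ec50)
  if (!is.null(p$Vmax)) v <- c(v, Vmax = p$Vmax, Km = p$Km)
  v
}
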