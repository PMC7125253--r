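#' Dosing regimens
#'
#' A regimen is a table of intravenous dosing events for 5FU: boluses
#' (`duration = 0`) and constant-rate infusions (`duration > 0`). Amounts are
#' absolute milligrams; times are hours from the start of the treatment
#' course. Overlapping infusions are summed.
#'
#' @param amount numeric vector of dose amounts (mg), all non-negative.
#' @param start numeric vector of event start times (h), non-negative.
#' @param duration numeric vector of infusion durations (h); `0` denotes a
#'   bolus. Infusion rate is `amount / duration`.
#' @return An object of class `fu_regimen`: a data frame with columns
#'   `amount`, `start`, `duration`, sorted by start time.
#' @examples
#' # 1000 mg/m2/day for 5 days as continuous infusion, BSA 1.95 m2
#' regimen(amount = 1000 * 1.95 * 5, start = 0, duration = 120)
#' @export
regimen <- function(amount, start = 0, duration = 0) {
  n <- max(length(amount), length(start), length(duration))
  amount <- rep_len(as.numeric(amount), n)
  start <- rep_len(as.numeric(start), n)
  duration <- rep_len(as.numeric(duration), n)
  if (any(!is.finite(amount)) || any(!is.finite(start)) || any(!is.finite(duration)))
    stop("regimen events must be finite", call. = FALSE)
  if (any(amount < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  if (any(start < 0)) stop("event start times must be >= 0", call. = FALSE)
  if (any(duration < 0)) stop("durations must be >= 0", call. = FALSE)
  o <- order(start, duration)
  out <- data.frame(amount = amount[o], start = start[o], duration = duration[o])
  class(out) <- c("fu_regimen", "data.frame")
  out
}

#' @export
print.fu_regimen <- function(x, ...) {
  cat(sprintf("5FU regimen: %d dosing event(s), total %.0f mg\n",
              nrow(x), sum(x$amount)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Continuous venous infusion regimen from a BSA-normalised daily dose
#'
#' The study regimen: `dose_per_m2` mg/m2/day infused at constant rate for
#' `days` days (a single uninterrupted infusion of `24 * days` hours).
#'
#' @param dose_per_m2 daily dose in mg/m2/day (650 or 1000 in the study).
#' @param bsa body surface area in m2 used to convert to absolute dose.
#' @param days infusion length in days (default 5, i.e. 120 h).
#' @return A [regimen()].
#' @export
regimen_cvi <- function(dose_per_m2, bsa = 1.95, days = 5) {
  regimen(amount = dose_per_m2 * bsa * days, start = 0, duration = 24 * days)
}

#' 5FU component of the FOLFIRINOX regimen
#'
#' 400 mg/m2 bolus followed by 2400 mg/m2 infused over 46 h (single course;
#' other components of the regimen are not modelled).
#'
#' @inheritParams regimen_cvi
#' @return A [regimen()].
#' @export
regimen_folfirinox_5fu <- function(bsa = 1.95) {
  regimen(amount = c(400, 2400) * bsa, start = c(0, 0), duration = c(0, 46))
}

#' 5FU component of the de Gramont regimen
#'
#' 300 mg/m2 bolus followed by 300 mg/m2 infused over 24 h (day-1 sequence of
#' a single course).
#'
#' @inheritParams regimen_cvi
#' @return A [regimen()].
#' @export
regimen_degramont_5fu <- function(bsa = 1.95) {
  regimen(amount = c(300, 300) * bsa, start = c(0, 0), duration = c(0, 24))
}

#' Read or write a regimen as YAML
#'
#' Serialises the event table as a list of `{kind, amount, start, duration}`
#' entries so regimens can be version-controlled alongside analysis scripts.
#'
#' @param x a [regimen()].
#' @param path file path.
#' @return `write_regimen` returns `path` invisibly; `read_regimen` returns a
#'   [regimen()].
#' @export
write_regimen <- function(x, path) {
  stopifnot(inherits(x, "fu_regimen"))
  ev <- lapply(seq_len(nrow(x)), function(i) list(
    kind = if (x$duration[i] > 0) "infusion" else "bolus",
    amount = x$amount[i], start = x$start[i], duration = x$duration[i]))
  yaml::write_yaml(list(events = ev), path)
  invisible(path)
}

#' @rdname write_regimen
#' @export
read_regimen <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$events) || !length(y$events))
    stop("no dosing events in ", path, call. = FALSE)
  ev <- do.call(rbind, lapply(y$events, function(e) {
    data.frame(amount = as.numeric(e$amount), start = as.numeric(e$start),
               duration = as.numeric(e$duration %||% 0))
  }))
  regimen(ev$amount, ev$start, ev$duration)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# events matrix for the C++ solver
regimen_events <- function(x) {
  stopifnot(inherits(x, "fu_regimen"))
  as.matrix(x[, c("amount", "start", "duration")])
}
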