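#' Visual predictive check
#'
#' Simulates replicate datasets under the design embedded in an observation
#' table (same subjects, dosing and sampling times; new random effects and
#' residual errors per replicate) and compares observed percentiles per time
#' bin with the simulation-based confidence bands of the same percentiles.
#'
#' Bins default to the nominal protocol times for concentrations and
#' 3.5-day windows for WBC counts. Bins holding fewer than two observations
#' are merged into their left neighbour with a warning.
#'
#' @param data an observation table.
#' @param pop a [population_parameters()] object (typically fit estimates).
#' @param n_simulations number of replicate simulations (>= 100 for stable
#'   bands; smaller values are allowed for smoke tests).
#' @param seed integer seed.
#' @param dvid observation type to check: 1 (5FU), 2 (5FUH2) or 3 (WBC).
#' @param breaks optional numeric vector of bin edges (h).
#' @param probs percentiles summarised (default 2.5th, 50th, 97.5th).
#' @param conf level of the simulation band per percentile (default 95%).
#' @param lloq named lower limits of quantification (mg/L) applied to the
#'   simulated concentrations so the below-quantification censoring of the
#'   observed data is mirrored in every replicate; without this the
#'   simulated low percentiles would be biased low relative to observed
#'   percentiles computed from quantifiable records only.
#' @return An object of class `fu_vpc`: a data frame per bin and percentile
#'   with observed value and simulated band (`lo`, `hi`), plus metadata.
#' @export
vpc <- function(data, pop, n_simulations = 500L, seed = 1L, dvid = 1L,
                breaks = NULL, probs = c(0.025, 0.5, 0.975), conf = 0.95,
                lloq = c("5fu" = 0.005, "5fuh2" = 0.01)) {
  stopifnot(inherits(pop, "fu_pop_params"))
  validate_obs_table(data)
  if (n_simulations < 1) stop("n_simulations must be >= 1", call. = FALSE)
  obs <- data[data$MDV == 0 & data$DVID == dvid & data$BLQ == 0, ]
  if (!nrow(obs)) stop("no observations with DVID = ", dvid, call. = FALSE)
  if (is.null(breaks)) {
    breaks <- if (dvid == 3L) {
      seq(0, max(obs$TIME) + 84, by = 84)  # 3.5-day bins for WBC
    } else {
      t0 <- sort(unique(obs$TIME))
      c(-Inf, t0[-1] - diff(t0) / 2, Inf)
    }
  }
  bin <- cut(obs$TIME, breaks, include.lowest = TRUE)
  # merge bins with < 2 observations into the left neighbour
  counts <- table(bin)
  if (any(counts > 0 & counts < 2)) {
    warning("bins with fewer than 2 observations merged", call. = FALSE)
    lv <- levels(bin)
    for (j in which(counts < 2 & counts > 0)) {
      target <- max(1L, j - 1L)
      bin[bin == lv[j]] <- lv[target]
    }
  }
  bin <- droplevels(bin)
  subs <- prepare_subjects(data)
  model <- pkpd_model()
  om2 <- pop$omega2
  lloq_d <- if (dvid == 1L) lloq[["5fu"]] else if (dvid == 2L) lloq[["5fuh2"]]
            else -Inf
  obs_q <- tapply(obs$DV, bin, quantile, probs = probs, names = FALSE)
  bin_t <- tapply(obs$TIME, bin, median)
  # index of each observation row of this dvid within the per-subject layout
  sim_one <- function() {
    dv <- numeric(nrow(obs))  # below-LLOQ draws are censored to NA below
    pos <- 1L
    for (sd in subs) {
      eta <- setNames(rnorm(length(om2)) * sqrt(om2), names(om2))
      sel <- which(sd$dvid == dvid)
      if (!length(sel)) next
      f <- model$pred(pop, eta, sd)
      key <- c("prop_5fu", "prop_5fuh2", "prop_wbc")[dvid]
      dv[pos:(pos + length(sel) - 1L)] <-
        residual_error(f[sel], pop$sigma2[[key]], rnorm(length(sel)))
      pos <- pos + length(sel)
    }
    dv
  }
  # observation rows are ordered by subject then time within prepare layout;
  # rebuild the same ordering for the observed table
  ord <- order(match(obs$ID, vapply(subs, function(s) s$id, obs$ID[1])),
               obs$TIME, obs$DVID)
  obs_sorted <- obs[ord, ]
  bin_sorted <- bin[ord]
  with_seed(seed, {
    sims <- replicate(n_simulations, {
      dv <- sim_one()
      dv[dv < lloq_d] <- NA  # same quantification limit as the observed data
      vapply(levels(bin_sorted), function(l) {
        v <- dv[bin_sorted == l]
        if (all(is.na(v))) rep(NA_real_, length(probs))
        else quantile(v, probs = probs, names = FALSE, na.rm = TRUE)
      }, numeric(length(probs)))
    })
  })
  # sims: probs x bins x n_sim
  a <- (1 - conf) / 2
  out <- do.call(rbind, lapply(seq_along(levels(bin_sorted)), function(b) {
    lvl <- levels(bin_sorted)[b]
    data.frame(bin = lvl,
               time = unname(bin_t[lvl]),
               percentile = 100 * probs,
               observed = unname(obs_q[[lvl]]),
               sim_lo = apply(sims[, b, , drop = FALSE], 1, quantile, a,
                              na.rm = TRUE),
               sim_median = apply(sims[, b, , drop = FALSE], 1, median,
                                  na.rm = TRUE),
               sim_hi = apply(sims[, b, , drop = FALSE], 1, quantile, 1 - a,
                              na.rm = TRUE))
  }))
  rownames(out) <- NULL
  structure(list(table = out, dvid = dvid, n_simulations = n_simulations,
                 seed = seed),
            class = "fu_vpc")
}

#' @export
print.fu_vpc <- function(x, ...) {
  cat(sprintf("VPC (DVID %d, %d simulations)\n", x$dvid, x$n_simulations))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fraction of VPC bins covering the observed percentiles
#'
#' Calibration summary: the share of (bin, percentile) cells whose observed
#' value lies inside the simulated confidence band. For data simulated from
#' the same model this should be close to the band's nominal level.
#'
#' @param x a [vpc()] result.
#' @return A single number in `[0, 1]`.
#' @export
vpc_coverage <- function(x) {
  stopifnot(inherits(x, "fu_vpc"))
  with(x$table, mean(observed >= sim_lo & observed <= sim_hi, na.rm = TRUE))
}

#' Plot a visual predictive check
#'
#' Observed percentiles (lines and points) over the simulation-based
#' confidence bands (ribbons), faceted by percentile.
#'
#' @param x a [vpc()] result.
#' @param log_y logarithmic y axis (conventional for concentrations).
#' @return A ggplot object.
#' @export
plot_vpc <- function(x, log_y = x$dvid %in% c(1L, 2L)) {
  stopifnot(inherits(x, "fu_vpc"))
  tab <- x$table
  tab$percentile <- factor(paste0("P", tab$percentile),
                           levels = paste0("P", sort(unique(tab$percentile))))
  g <- ggplot2::ggplot(tab, ggplot2::aes(x = time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_lo, ymax = sim_hi,
                                      fill = percentile), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = observed, colour = percentile)) +
    ggplot2::geom_point(ggplot2::aes(y = observed, colour = percentile)) +
    ggplot2::labs(x = "time (h)",
                  y = c("5FU (mg/L)", "5FUH2 (mg/L)",
                        "WBC (1e9/L)")[x$dvid]) +
    ggplot2::theme_minimal()
  if (log_y) g <- g + ggplot2::scale_y_log10()
  g
}
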