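#' Decoy-antibody dose-response curve
#'
#' Simulates 24 h of decoy treatment at each dose and reports the
#' fractional reduction of total ligand-receptor complexes relative to
#' dose 0: `response = 1 - complexes(dose)/complexes(0)`. Deterministic;
#' `response(0) = 0` by construction.
#'
#' @param sys `autocrine_system`; a decoy section must be present (use
#'   [default_decoy()]) — its dose field is swept.
#' @param doses numeric vector of antibody doses (molar), >= 0.
#' @param hours simulation span.
#' @param integrated if `TRUE`, use time-integrated complexes instead of
#'   the 24 h endpoint as the signaling readout.
#' @return `dose_response_curve`: data.frame with columns `dose` and
#'   `response`, plus attributes `baseline` (complexes/cell at dose 0)
#'   and `metadata`.
#' @export
decoy_dose_response <- function(sys, doses, hours = 24, integrated = FALSE) {
  if (is.null(sys$decoy))
    stop("system has no decoy specification; add one via default_decoy()",
         call. = FALSE)
  .dose_response(sys, doses, "decoy.dose", hours, integrated)
}

#' Protease-inhibitor dose-response curve
#'
#' As [decoy_dose_response()], sweeping the inhibitor dose: the inhibitor
#' reversibly binds the free sheddase, scaling the release flux by the
#' uninhibited protease fraction.
#'
#' @inheritParams decoy_dose_response
#' @export
inhibitor_dose_response <- function(sys, doses, hours = 24,
                                    integrated = FALSE) {
  if (is.null(sys$inhibitor))
    stop("system has no inhibitor specification; add one via ",
         "default_inhibitor()", call. = FALSE)
  .dose_response(sys, doses, "inhibitor.dose", hours, integrated)
}

.signal <- function(traj, integrated) {
  if (!integrated) return(total_complexes(traj))
  ctot <- rowSums(traj$state[, paste0("C.", names(traj$sys$ligands)),
                             drop = FALSE])
  sum(diff(traj$time) * (utils::head(ctot, -1) + utils::tail(ctot, -1)) / 2)
}

.dose_response <- function(sys, doses, path, hours, integrated) {
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  doses <- sort(unique(as.numeric(doses)))
  baseline <- .signal(simulate_system(set_parameter(sys, path, 0),
                                      hours = hours), integrated)
  if (baseline <= 0)
    stop("baseline complexes are zero; no signaling to inhibit",
         call. = FALSE)
  response <- vapply(doses, function(d) {
    if (d == 0) return(0)
    1 - .signal(simulate_system(set_parameter(sys, path, d),
                                hours = hours), integrated) / baseline
  }, numeric(1))
  structure(data.frame(dose = doses, response = response),
            baseline = baseline,
            metadata = list(path = path, hours = hours,
                            integrated = integrated),
            class = c("dose_response_curve", "data.frame"))
}

#' Default log-spaced dose grid
#'
#' Eight doses log-spaced over `lo`..`hi` times a reference concentration
#' (typically the decoy K_D or inhibitor K_i), plus dose 0.
#'
#' @param reference reference concentration (molar).
#' @param lo,hi span multipliers.
#' @param n number of non-zero doses.
#' @return numeric dose vector (molar) starting at 0.
#' @export
dose_grid <- function(reference, lo = 1e-2, hi = 1e3, n = 8) {
  c(0, 10^seq(log10(reference * lo), log10(reference * hi),
              length.out = n))
}

#' IC50 from a dose-response curve by log-linear interpolation
#'
#' Finds the dose at which the response crosses 0.5, interpolating
#' linearly in log-dose. The simulated ODE curve is the ground truth, so
#' no parametric (Hill) fit is imposed. If the curve never reaches 0.5,
#' a bound is returned rather than an error; if 0.5 is only reached at or
#' beyond the grid edge the result is flagged as extrapolated.
#'
#' @param curve `dose_response_curve` (or data.frame with `dose`,
#'   `response`), response monotone non-decreasing up to 1e-6 jitter.
#' @return list of class `ic50_result`: `ic50` (molar, `NA` if no
#'   crossing), `bracketed` (logical), `bound` (`NA` or "ic50 > max dose"
#'   descriptor), `method`.
#' @export
ic50_from_curve <- function(curve) {
  d <- curve$dose
  r <- curve$response
  if (is.unsorted(d)) stop("doses must be increasing", call. = FALSE)
  if (any(diff(r) < -1e-6))
    stop("response is not monotone non-decreasing (beyond solver jitter)",
         call. = FALSE)
  out <- list(ic50 = NA_real_, bracketed = FALSE, bound = NA_character_,
              method = "log-linear interpolation")
  class(out) <- "ic50_result"
  if (max(r) < 0.5) {
    out$bound <- paste0("ic50 > ", format(max(d)))
    out$ic50_lower_bound <- max(d)
    return(out)
  }
  i <- which(r >= 0.5)[1]
  if (i == 1L || d[i - 1] <= 0) { # crossing at/below first positive dose
    out$ic50 <- d[i]
    out$bracketed <- FALSE
    out$bound <- paste0("ic50 <= ", format(d[i]))
    return(out)
  }
  if (r[i] == 0.5) {
    out$ic50 <- d[i]
    out$bracketed <- TRUE
    return(out)
  }
  ld <- log10(d[(i - 1):i])
  rr <- r[(i - 1):i]
  out$ic50 <- 10^(ld[1] + (0.5 - rr[1]) / (rr[2] - rr[1]) * (ld[2] - ld[1]))
  out$bracketed <- TRUE
  out
}

#' @export
print.ic50_result <- function(x, ...) {
  if (is.na(x$ic50)) {
    cat("IC50: no crossing;", x$bound, "\n")
  } else {
    cat(sprintf("IC50 = %.4g M (%s; %s)\n", x$ic50,
                if (x$bracketed) "bracketed" else "extrapolated", x$method))
  }
  invisible(x)
}

#' Sweep a system parameter and tabulate an intervention response
#'
#' For each value on `grid`, sets `path` (see [set_parameter()]) and
#' evaluates the requested response metric, holding everything else
#' frozen. Used for the affinity and diffusivity dependence of decoy
#' efficacy.
#'
#' @param sys `autocrine_system` with the relevant intervention section.
#' @param path dot-separated parameter path (e.g. `"ligands.HBEGF.K_D"`).
#' @param grid numeric vector of values (base units).
#' @param response one of `"decoy_ic50"`, `"inhibitor_ic50"`,
#'   `"capture_fraction"`.
#' @param doses dose grid for the IC50 responses (molar); defaults to
#'   [dose_grid()] around the decoy K_D or inhibitor K_i.
#' @param hours simulation span.
#' @return data.frame: one row per grid value with columns `swept_value`,
#'   `response`, `metric`, `bracketed`.
#' @export
sweep_parameter <- function(sys, path, grid,
                            response = c("decoy_ic50", "inhibitor_ic50",
                                         "capture_fraction"),
                            doses = NULL, hours = 24) {
  response <- match.arg(response)
  if (!length(grid) || !is.numeric(grid))
    stop("grid must be a non-empty numeric vector", call. = FALSE)
  rows <- lapply(grid, function(v) {
    s <- set_parameter(sys, path, v)
    if (response == "capture_fraction") {
      val <- capture_fraction(simulate_system(s, hours = hours))
      data.frame(swept_value = v, response = val,
                 metric = response, bracketed = NA)
    } else {
      if (is.null(doses))
        doses <- if (response == "decoy_ic50")
          dose_grid(s$decoy$K_D) else dose_grid(s$inhibitor$K_i)
      curve <- if (response == "decoy_ic50")
        decoy_dose_response(s, doses, hours = hours)
      else inhibitor_dose_response(s, doses, hours = hours)
      ic <- ic50_from_curve(curve)
      data.frame(swept_value = v, response = ic$ic50,
                 metric = response, bracketed = ic$bracketed)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "path") <- path
  out
}
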