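#' Construct a relaxation decay series
#'
#' @param delay_ms relaxation delays in milliseconds (>= 4 distinct).
#' @param height peak heights (finite).
#' @param replicate logical flag marking duplicate-delay measurements.
#' @param resid optional residue number.
#' @return object of class \code{relaxation_series} (a data.frame).
#' @export
relaxation_series <- function(delay_ms, height, replicate = FALSE,
                              resid = NA_integer_) {
  if (any(!is.finite(height))) stop("non-finite height(s)")
  if (length(unique(delay_ms)) < 4L)
    stop("need at least 4 distinct relaxation delays")
  out <- data.frame(delay_ms = delay_ms, height = height,
                    replicate = replicate)
  attr(out, "resid") <- resid
  class(out) <- c("relaxation_series", "data.frame")
  out
}

#' Fit a mono-exponential decay rate
#'
#' Nonlinear least-squares fit of \code{I(t) = I0 * exp(-R * t)} to peak
#' heights, initialized from the log-linear regression of the positive
#' heights. Delays are in ms; the rate is reported in 1/s. A fit that fails
#' to converge or returns a non-positive rate marks the series unfit.
#'
#' @param series a \code{relaxation_series}, or a numeric vector of delays
#'   in ms when \code{height} is given.
#' @param height peak heights (when \code{series} is a delay vector).
#' @return list with \code{rate} (1/s), \code{initial_height},
#'   \code{rate_se} (asymptotic standard error, 1/s), \code{ok} flag.
#' @export
fit_monoexponential <- function(series, height = NULL) {
  if (!is.null(height)) series <- relaxation_series(series, height)
  t_s <- series$delay_ms / 1000
  h <- series$height
  pos <- h > 0
  if (sum(pos) < 3L)
    return(list(rate = NA_real_, initial_height = NA_real_,
                rate_se = NA_real_, ok = FALSE))
  init <- stats::lm(log(h[pos]) ~ t_s[pos])
  r0 <- max(-unname(stats::coef(init)[2]), 1e-6)
  i0 <- exp(unname(stats::coef(init)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(h ~ I0 * exp(-R * t_s),
                      start = list(I0 = i0, R = r0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(rate = NA_real_, initial_height = NA_real_,
                rate_se = NA_real_, ok = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["R", "Std. Error"],
                 error = function(e) NA_real_)
  ok <- is.finite(cf[["R"]]) && cf[["R"]] > 0
  list(rate = unname(cf[["R"]]), initial_height = unname(cf[["I0"]]),
       rate_se = unname(se), ok = ok)
}

#' Replicate-based uncertainty of a fitted rate
#'
#' Estimates the per-point relative noise SD from duplicate-delay pairs
#' (half the absolute pair difference, scaled by \code{sqrt(pi)/2} for the
#' half-normal expectation of |d|/2 relative to the pair mean), then
#' refits the rate over \code{n_draws} Monte-Carlo resamples of the fitted
#' curve perturbed by that noise. The SD of the refitted rates is the
#' reported uncertainty. Without duplicate pairs the asymptotic
#' fit-covariance standard error is returned with a warning.
#'
#' @param series a \code{relaxation_series} containing duplicate delays
#'   (rows marked \code{replicate}, or repeated \code{delay_ms} values).
#' @param n_draws Monte-Carlo resamples (default 500).
#' @param seed integer seed.
#' @return list with \code{rate_uncertainty} (1/s), \code{noise_sd}
#'   (relative), \code{method}.
#' @export
estimate_rate_uncertainty <- function(series, n_draws = 500L, seed = 1L) {
  base_fit <- fit_monoexponential(series)
  if (!base_fit$ok) stop("cannot estimate uncertainty: base fit failed")
  dup_delays <- unique(series$delay_ms[duplicated(series$delay_ms)])
  if (length(dup_delays) < 2L) {
    warning("fewer than 2 duplicate delay pairs; falling back to fit-covariance uncertainty")
    return(list(rate_uncertainty = base_fit$rate_se, noise_sd = NA_real_,
                method = "fit-covariance"))
  }
  rel <- vapply(dup_delays, function(d) {
    h <- series$height[series$delay_ms == d][1:2]
    abs(diff(h)) / mean(h)
  }, numeric(1))
  # |h1 - h2| / mean ~ half-normal with mean 2*sigma_rel/sqrt(pi)
  noise_sd <- mean(rel) / 2 * sqrt(pi)
  t_s <- series$delay_ms / 1000
  mu <- base_fit$initial_height * exp(-base_fit$rate * t_s)
  rates <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      h <- mu * (1 + rnorm(length(mu), 0, noise_sd))
      f <- fit_monoexponential(relaxation_series(series$delay_ms, h))
      if (f$ok) f$rate else NA_real_
    }, numeric(1))
  })
  list(rate_uncertainty = stats::sd(rates, na.rm = TRUE),
       noise_sd = noise_sd, method = "duplicate-monte-carlo")
}

#' Fit relaxation rates for a table of residues
#'
#' @param decays data.frame with columns \code{resid}, \code{delay_ms},
#'   \code{height} (the decay-table TSV dialect).
#' @param uncertainty estimate replicate-based uncertainties as well.
#' @param n_draws,seed Monte-Carlo settings for the uncertainty.
#' @return object of class \code{rate_result}: data.frame with
#'   \code{resid}, \code{rate} (1/s), \code{rate_se},
#'   \code{rate_uncertainty}, \code{ok}; unfit residues carry NA and are
#'   excluded downstream with a warning.
#' @export
fit_relaxation_rates <- function(decays, uncertainty = FALSE,
                                 n_draws = 500L, seed = 1L) {
  rows <- lapply(split(decays, decays$resid), function(d) {
    ser <- relaxation_series(d$delay_ms, d$height, resid = d$resid[1])
    f <- fit_monoexponential(ser)
    unc <- NA_real_
    if (uncertainty && f$ok) {
      u <- tryCatch(suppressWarnings(
        estimate_rate_uncertainty(ser, n_draws = n_draws,
                                  seed = seed + d$resid[1])),
        error = function(e) NULL)
      if (!is.null(u)) unc <- u$rate_uncertainty
    }
    data.frame(resid = d$resid[1], rate = f$rate, rate_se = f$rate_se,
               rate_uncertainty = unc, ok = f$ok)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$resid), , drop = FALSE]
  rownames(out) <- NULL
  if (any(!out$ok))
    warning(sum(!out$ok), " residue(s) failed to fit and are flagged unfit")
  class(out) <- c("rate_result", "data.frame")
  out
}

#' Heteronuclear NOE from saturated/unsaturated peak heights
#'
#' \code{NOE(r) = height_sat(r) / height_unsat(r)} over residues common to
#' both lists; invariant to any common scaling. Lower values indicate
#' faster ps-ns backbone motion.
#'
#' @param saturated,unsaturated \code{peak_list}s from the interleaved
#'   experiments.
#' @return data.frame with \code{resid} and \code{noe}.
#' @export
compute_noe <- function(saturated, unsaturated) {
  common <- intersect(saturated$resid, unsaturated$resid)
  if (!length(common)) stop("no residues shared between peak lists")
  hs <- saturated$height[match(common, saturated$resid)]
  hu <- unsaturated$height[match(common, unsaturated$resid)]
  bad <- hu == 0
  if (any(bad)) {
    warning("residue(s) with zero unsaturated height excluded: ",
            paste(common[bad], collapse = ", "))
    common <- common[!bad]
    hs <- hs[!bad]
    hu <- hu[!bad]
  }
  data.frame(resid = common, noe = hs / hu)
}

#' Mutant-minus-wild-type relaxation difference profiles
#'
#' Computes \code{delta X = X_variant - X_wt} per residue for any of R1,
#' R2, and NOE, with a significance band per dataset of
#' \code{10 percent trimmed mean +/- k sigma} (sigma on the trimmed set,
#' the same machinery as the chemical-shift threshold). Values outside the
#' band are flagged significant, annotated with the flexibility direction:
#' positive delta-R1/delta-R2 and negative delta-NOE indicate a more
#' flexible mutant.
#'
#' @param wt,variant named lists of per-residue data.frames; recognized
#'   names are \code{R1}, \code{R2} (each \code{resid}/\code{rate}) and
#'   \code{NOE} (\code{resid}/\code{noe}).
#' @param trim tail fraction (default 0.10).
#' @param k sigma multiplier (default 1.5).
#' @return list per dataset: data.frame with \code{resid}, \code{delta},
#'   \code{significant}, \code{direction}, plus attributes \code{center},
#'   \code{band} (lower/upper).
#' @export
delta_relaxation <- function(wt, variant, trim = 0.10, k = 1.5) {
  out <- list()
  for (nm in intersect(names(wt), names(variant))) {
    col <- if (toupper(nm) == "NOE") "noe" else "rate"
    a <- wt[[nm]]
    b <- variant[[nm]]
    if ("ok" %in% names(a)) a <- a[a$ok, , drop = FALSE]
    if ("ok" %in% names(b)) b <- b[b$ok, , drop = FALSE]
    common <- intersect(a$resid, b$resid)
    if (length(common) < 5L) stop("need at least 5 common residues for ", nm)
    d <- b[[col]][match(common, b$resid)] - a[[col]][match(common, a$resid)]
    ts <- trimmed_stats(d, trim = trim)
    lo <- ts$mean - k * ts$sd
    hi <- ts$mean + k * ts$sd
    sig <- d < lo | d > hi
    more_flex <- if (toupper(nm) == "NOE") d < 0 else d > 0
    tb <- data.frame(resid = common, delta = d, significant = sig,
                     direction = ifelse(more_flex, "mutant more flexible",
                                        "wt more flexible"))
    attr(tb, "center") <- ts$mean
    attr(tb, "band") <- c(lower = lo, upper = hi)
    out[[nm]] <- tb
  }
  if (!length(out)) stop("no common datasets between wt and variant")
  out
}

# gyromagnetic ratio of 15N relative to 1H (magnitude)
GAMMA_N_OVER_H <- 0.101329

#' Summary statistics of fitted relaxation times
#'
#' Mean and SD of T1 = 1000/R1 and T2 = 1000/R2 in ms over fitted
#' residues, plus an advisory isotropic rotational-correlation-time
#' estimate from the mean T1/T2 ratio via the standard single-field
#' approximation \code{tau_c = sqrt(6 T1/T2 - 7) / (4 pi nu_N)}, where
#' nu_N is the 15N Larmor frequency at the given spectrometer field.
#'
#' @param r1,r2 \code{rate_result} tables (1/s) for the longitudinal and
#'   transverse experiments.
#' @param spectrometer_frequency 1H field in MHz (default 600).
#' @return list with \code{t1_mean_ms}, \code{t1_sd_ms}, \code{t2_mean_ms},
#'   \code{t2_sd_ms}, \code{n}, \code{tau_c_ns} (NA when T1/T2 < 7/6).
#' @export
summarize_rates <- function(r1, r2, spectrometer_frequency = 600) {
  keep1 <- r1$ok & is.finite(r1$rate) & r1$rate > 0
  keep2 <- r2$ok & is.finite(r2$rate) & r2$rate > 0
  if (sum(keep1) < 5L || sum(keep2) < 5L)
    stop("need at least 5 fitted residues in each dataset")
  t1 <- 1000 / r1$rate[keep1]
  t2 <- 1000 / r2$rate[keep2]
  ratio <- mean(t1) / mean(t2)
  tau <- NA_real_
  if (ratio >= 7 / 6) {
    nu_n <- spectrometer_frequency * 1e6 * GAMMA_N_OVER_H  # Hz
    tau <- sqrt(6 * ratio - 7) / (4 * pi * nu_n) * 1e9     # ns
  }
  list(t1_mean_ms = mean(t1), t1_sd_ms = stats::sd(t1),
       t2_mean_ms = mean(t2), t2_sd_ms = stats::sd(t2),
       n = c(t1 = sum(keep1), t2 = sum(keep2)), tau_c_ns = tau)
}
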