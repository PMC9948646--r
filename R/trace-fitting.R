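#' Fit the quench model to a stopped-flow trace
#'
#' Nonlinear least-squares fit of the three-compartment stretched-exponential
#' quench model ([predict_fluorescence()]) to a quencher-mix trace on the fit
#' window (default 2 ms to 1 s). Free parameters are F(0,q), F(inf,q), beta,
#' and tau0; K_SV and \[Tl+\]e are held fixed. The fit runs in a transformed,
#' unconstrained parameterization (logistic for beta in (0, 1\], logs for
#' tau0 > 0 and for the plateau gap F(0,q) - F(inf,q) >= 0) so the bounds
#' never produce active-set artifacts, using Levenberg-Marquardt. Plateaus
#' are initialized from the first and last 5% of samples, tau0 from the
#' half-quench time, beta at 0.9; on non-convergence up to `n_starts`
#' jittered restarts are tried (jitter seeded by `seed`). A failed fit is
#' returned explicitly (flag `fit_failure`), never silently.
#'
#' @param trace A quencher-mix [fluorescence_trace()].
#' @param ksv,tl_ext Fixed Stern-Volmer coefficient (1/M) and extravesicular
#'   Tl+ (M).
#' @param window Fit window `c(t_min, t_max)` in s. Default `c(0.002, 1)`.
#' @param r2_flag Flag threshold: fits with r^2 below it get `low_r2`.
#'   Default 0.95.
#' @param f0b Optional buffer-mix fluorescence; when given, plateau
#'   combinations implying negative compartments are flagged
#'   `nonphysical_plateau`.
#' @param n_starts Maximum number of jittered starts. Default 3.
#' @param seed Seed for the restart jitter.
#' @return An object of class `trace_fit`: list with `params`
#'   ([quench_params()]), `rate0` (= [initial_rate()] of the fit), `r2`,
#'   `qc_flags` (character subset of `low_r2`, `nonphysical_plateau`,
#'   `outlier_rejected`, `fit_failure`), `converged`, `n_obs`.
#' @export
fit_trace <- function(trace, ksv = 60, tl_ext = 0.025, window = c(0.002, 1),
                      r2_flag = 0.95, f0b = NA_real_, n_starts = 3, seed = 1L) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (!identical(attr(trace, "mix_type"), "quencher")) {
    stop("`fit_trace` expects a quencher-mix trace")
  }
  keep <- trace$time >= window[1] & trace$time <= window[2]
  t <- trace$time[keep]; y <- trace$signal[keep]
  if (length(t) < 50) stop("fewer than 50 samples in the fit window")
  k <- ksv * tl_ext

  model <- function(th) {
    finfq <- exp(th[1]); gap <- exp(th[2])
    beta <- stats::plogis(th[3]); tau0 <- exp(th[4])
    f0q <- finfq + gap
    g <- 1 - exp(1 - (1 + t / tau0)^beta)
    (finfq * (1 + k) - f0q) / k + (1 + k) / k * gap / (1 + k * g)
  }

  # initialization from the data
  n5 <- max(5L, ceiling(0.05 * length(t)))
  f0q0 <- mean(y[seq_len(n5)])
  finfq0 <- mean(y[seq.int(length(y) - n5 + 1L, length(y))])
  gap0 <- max(f0q0 - finfq0, 1e-4 * max(abs(f0q0), 1e-12))
  finfq0 <- max(finfq0, 1e-6 * gap0)
  half <- which(y <= finfq0 + gap0 / 2)
  tau00 <- if (length(half)) max(t[half[1]], 1e-4) else stats::median(t)
  th0 <- c(log(finfq0), log(gap0), stats::qlogis(0.9), log(tau00))

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) th0 else th0 + stats::rnorm(4, 0, 0.3)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = function(th) y - model(th),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$info %in% 1:4) break
  }

  flags <- character(0)
  if (is.null(best)) {
    flags <- "fit_failure"
    out <- list(params = NULL, rate0 = NA_real_, r2 = NA_real_,
                qc_flags = flags, converged = FALSE, n_obs = length(t))
    class(out) <- "trace_fit"
    return(out)
  }

  th <- best$par
  finfq <- exp(th[1]); f0q <- finfq + exp(th[2])
  beta <- stats::plogis(th[3]); tau0 <- exp(th[4])
  params <- quench_params(tau0 = tau0, beta = min(beta, 1), f0q = f0q,
                          finfq = finfq, ksv = ksv, tl_ext = tl_ext, f0b = f0b)
  r2 <- 1 - best$deviance / sum((y - mean(y))^2)
  converged <- best$info %in% 1:4
  if (!converged) flags <- c(flags, "fit_failure")
  if (is.finite(r2) && r2 < r2_flag) flags <- c(flags, "low_r2")
  if (is.finite(f0b)) {
    cs <- suppressWarnings(decompose_compartments(f0b, f0q, finfq, ksv, tl_ext))
    if (cs$nonphysical || min(cs$f_extra, cs$f_intra, cs$f_unq) < 0) {
      flags <- c(flags, "nonphysical_plateau")
    }
  }
  out <- list(params = params, rate0 = initial_rate(params), r2 = r2,
              qc_flags = flags, converged = converged, n_obs = length(t))
  class(out) <- "trace_fit"
  out
}

#' @export
print.trace_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("Trace fit: FAILED\n")
    return(invisible(x))
  }
  cat(sprintf("Trace fit: rate0 = %.3f 1/s, beta = %.3f, tau0 = %.4f s, r2 = %.4f\n",
              x$rate0, x$params$beta, x$params$tau0, x$r2))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Flag outlier traces within a mixing session
#'
#' Automated surrogate for the visual rejection of bad mixing reactions (air
#' bubbles etc.): a trace is flagged `outlier_rejected` when its fitted
#' initial rate deviates from the session median by more than `k` times the
#' session MAD. Because the raw MAD collapses to zero when a majority of
#' rates coincide, the fence scale is floored at 5% of the median rate. If
#' more than `max_reject` of the session would be rejected the whole session
#' is refused as bad (error of class `session_quality_error`).
#'
#' @param results List of [fit_trace()] results (>= 3).
#' @param k Fence multiplier. Default 5.
#' @param max_reject Maximum tolerated rejected fraction. Default 0.3.
#' @return The list with `outlier_rejected` added to the flags of rejected
#'   fits; non-rejected fits are untouched.
#' @export
reject_bad_traces <- function(results, k = 5, max_reject = 0.3) {
  stopifnot(is.list(results), length(results) >= 3)
  rates <- vapply(results, function(r) r$rate0, numeric(1))
  if (any(!is.finite(rates))) stop("all fits must have finite rate0")
  med <- stats::median(rates)
  scale <- max(stats::mad(rates, constant = 1), 0.05 * abs(med))
  bad <- abs(rates - med) > k * scale
  if (mean(bad) > max_reject) {
    stop(structure(class = c("session_quality_error", "error", "condition"),
                   list(message = sprintf(
                     "session quality: %d of %d traces rejected (> %.0f%%)",
                     sum(bad), length(bad), 100 * max_reject),
                     call = sys.call(-1))))
  }
  for (i in which(bad)) {
    results[[i]]$qc_flags <- union(results[[i]]$qc_flags, "outlier_rejected")
  }
  results
}

#' Session mean rate over non-rejected traces
#'
#' @param results List of [fit_trace()] results, typically after
#'   [reject_bad_traces()].
#' @return Mean `rate0` over fits not flagged `outlier_rejected` or
#'   `fit_failure`.
#' @export
session_rate <- function(results) {
  keep <- vapply(results, function(r) {
    !any(c("outlier_rejected", "fit_failure") %in% r$qc_flags)
  }, logical(1))
  mean(vapply(results[keep], function(r) r$rate0, numeric(1)))
}

#' Summarize rates across independent LUV preparations
#'
#' Assay protocol: each drug is measured on independently prepared LUV
#' batches, in duplicate by default. With two preparations the result is
#' reported as mean +/- range/2; when the relative spread range/(2 mean)
#' exceeds 0.3 the drug is escalated to triplicate, and with three or more
#' preparations the dispersion is the sample SD.
#'
#' @param rates Numeric vector of per-preparation mean rates (>= 2 values).
#' @return A list of class `replicate_summary`: `mean_rate`, `dispersion`,
#'   `dispersion_kind` (`"half_range"` or `"sd"`), `n_preps`,
#'   `needs_triplicate` (only meaningful at n = 2).
#' @export
summarize_replicates <- function(rates) {
  stopifnot(is.numeric(rates))
  n <- length(rates)
  if (n < 2) stop("need at least 2 preparations")
  m <- mean(rates)
  if (n == 2) {
    disp <- diff(range(rates)) / 2
    out <- list(mean_rate = m, dispersion = disp, dispersion_kind = "half_range",
                n_preps = 2L, needs_triplicate = (disp / m) > 0.3)
  } else {
    out <- list(mean_rate = m, dispersion = stats::sd(rates),
                dispersion_kind = "sd", n_preps = as.integer(n),
                needs_triplicate = FALSE)
  }
  class(out) <- "replicate_summary"
  out
}
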