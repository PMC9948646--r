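#' Kinetic parameters of the Tl+ fluorescence-quench model
#'
#' Bundles the parameters of the Stern-Volmer / modified-stretched-exponential
#' model of Tl+-induced quench of ANTS fluorescence in gramicidin-doped LUVs:
#' the Stern-Volmer coefficient `ksv`, the extravesicular quencher
#' concentration `tl_ext`, the influx time-scale `tau0`, the dispersity
#' exponent `beta` (1 for a homogeneous vesicle population, < 1 with
#' dispersity in size and channel density), and the plateau fluorescences of
#' the quencher-mix trace, `f0q` at time zero and `finfq` at infinite time.
#' `f0b`, the buffer-mix (unquenched) fluorescence, is optional and only
#' needed for the compartment decomposition.
#'
#' @param tau0 Time-scale parameter (s), > 0.
#' @param beta Dispersity exponent, in (0, 1].
#' @param f0q Fluorescence at t = 0 under quencher mixing (arbitrary units).
#' @param finfq Asymptotic fluorescence under quencher mixing; `f0q >= finfq >= 0`.
#' @param ksv Stern-Volmer coefficient (1/M). Default 60, the value for Tl+
#'   quenching of ANTS.
#' @param tl_ext Extravesicular Tl+ concentration (M). Default 0.025.
#' @param f0b Optional buffer-mix fluorescence (arbitrary units).
#' @return An object of class `quench_params`.
#' @seealso [predict_fluorescence()], [initial_rate()], [tl_internal()]
#' @export
quench_params <- function(tau0, beta, f0q, finfq, ksv = 60, tl_ext = 0.025,
                          f0b = NA_real_) {
  stopifnot(is.numeric(tau0), length(tau0) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(f0q), length(f0q) == 1L,
            is.numeric(finfq), length(finfq) == 1L)
  if (!is.finite(tau0) || tau0 <= 0) stop("`tau0` must be > 0")
  if (!is.finite(beta) || beta <= 0 || beta > 1) stop("`beta` must be in (0, 1]")
  if (!is.finite(ksv) || ksv <= 0) stop("`ksv` must be > 0")
  if (!is.finite(tl_ext) || tl_ext < 0) stop("`tl_ext` must be >= 0")
  if (finfq < 0 || f0q < finfq) stop("requires f0q >= finfq >= 0")
  structure(list(ksv = ksv, tl_ext = tl_ext, tau0 = tau0, beta = beta,
                 f0q = f0q, finfq = finfq, f0b = f0b),
            class = "quench_params")
}

#' @export
print.quench_params <- function(x, ...) {
  cat("Quench model parameters\n")
  cat(sprintf("  K_SV = %g 1/M, [Tl+]e = %g M  (K_SV.[Tl+]e = %g)\n",
              x$ksv, x$tl_ext, x$ksv * x$tl_ext))
  cat(sprintf("  tau0 = %g s, beta = %g\n", x$tau0, x$beta))
  cat(sprintf("  F(0,q) = %g, F(inf,q) = %g", x$f0q, x$finfq))
  if (is.finite(x$f0b)) cat(sprintf(", F(0,b) = %g", x$f0b))
  cat(sprintf("\n  initial rate = %g 1/s\n", initial_rate(x)))
  invisible(x)
}

#' Intravesicular Tl+ concentration as a function of time
#'
#' The modified stretched exponential describing volume-averaged Tl+ influx
#' into a dispersed vesicle population:
#' \deqn{[Tl^+]_i(t) = [Tl^+]_e (1 - \exp\{1 - (1 + t/\tau_0)^\beta\}).}
#' It is 0 at t = 0, monotone non-decreasing, and approaches `tl_ext` as
#' t grows. With beta = 1 it reduces to single-exponential filling with rate
#' 1/tau0.
#'
#' @param t Time (s), vectorized; negative times are rejected.
#' @param params A [quench_params()] object.
#' @return Intravesicular Tl+ concentration (M), same length as `t`.
#' @export
tl_internal <- function(t, params) {
  stopifnot(inherits(params, "quench_params"), is.numeric(t))
  if (any(t < 0)) stop("negative `t` not allowed")
  params$tl_ext * (1 - exp(1 - (1 + t / params$tau0)^params$beta))
}

#' Model fluorescence of a quencher-mix trace
#'
#' Three-compartment time course of the quench trace: the extravesicular dye
#' is quenched within the instrument dead time, the unquenchable vesicles
#' never quench, and the gramicidin-conducting vesicles quench as Tl+ flows
#' in. In terms of the quencher-mix plateaus it reads
#' \deqn{F(t) = \frac{F(\infty,q)(1 + K_{SV}[Tl^+]_e) - F(0,q)}{K_{SV}[Tl^+]_e}
#'   + \frac{1 + K_{SV}[Tl^+]_e}{K_{SV}[Tl^+]_e}\,
#'     \frac{F(0,q) - F(\infty,q)}{1 + K_{SV}[Tl^+]_i(t)}.}
#' At `ksv * tl_ext` = 1.5 the two prefactors are the familiar 2.5/1.5 pair.
#'
#' @inheritParams tl_internal
#' @return Fluorescence (arbitrary units), equal to `f0q` at t = 0, monotone
#'   non-increasing, approaching `finfq`.
#' @export
predict_fluorescence <- function(t, params) {
  stopifnot(inherits(params, "quench_params"))
  k <- params$ksv * params$tl_ext
  tli <- tl_internal(t, params)
  (params$finfq * (1 + k) - params$f0q) / k +
    (1 + k) / k * (params$f0q - params$finfq) / (1 + params$ksv * tli)
}

#' Initial fluorescence-quench rate
#'
#' Magnitude of the initial slope of the quench trace normalized by the
#' quenchable amplitude F(0,q) - F(inf,q):
#' \deqn{Rate(0) = (1 + K_{SV}[Tl^+]_e)\,\beta/\tau_0,}
#' i.e. 2.5 beta/tau0 at the standard K_SV = 60 1/M, \[Tl+\]e = 25 mM. The
#' underlying slope is negative (fluorescence decreases); the rate is
#' reported as a positive magnitude.
#'
#' @param params A [quench_params()] object.
#' @return Initial quench rate (1/s).
#' @export
initial_rate <- function(params) {
  stopifnot(inherits(params, "quench_params"))
  (1 + params$ksv * params$tl_ext) * params$beta / params$tau0
}

#' Decompose initial fluorescence into its three compartments
#'
#' Splits the unquenched (buffer-mix) fluorescence `f0b` into the
#' extravesicular, quenchable-intravesicular, and unquenchable contributions
#' using the three experimental observables:
#' \deqn{F_{extra} = (F(0,b) - F(0,q)) (1+k)/k, \quad
#'       F_{intra} = (F(0,q) - F(\infty,q)) (1+k)/k, \quad
#'       F_{unq} = (F(\infty,q)(1+k) - F(0,b))/k,}
#' with k = K_SV \[Tl+\]e. The three components always sum to `f0b` exactly.
#' Plateau noise can produce the non-physical ordering
#' `f0b < f0q` or negative components; these are preserved (never clamped)
#' and flagged so QC can see them.
#'
#' @param f0b Buffer-mix fluorescence at t = 0.
#' @param f0q Quencher-mix fluorescence at t = 0.
#' @param finfq Quencher-mix fluorescence at t = infinity.
#' @param ksv Stern-Volmer coefficient (1/M).
#' @param tl_ext Extravesicular Tl+ concentration (M).
#' @return A list of class `compartment_split` with fields `f_extra`,
#'   `f_intra`, `f_unq`, and logical `nonphysical`.
#' @export
decompose_compartments <- function(f0b, f0q, finfq, ksv = 60, tl_ext = 0.025) {
  stopifnot(is.numeric(f0b), is.numeric(f0q), is.numeric(finfq))
  k <- ksv * tl_ext
  if (k <= 0) stop("requires ksv * tl_ext > 0")
  nonphysical <- !(f0b >= f0q && f0q >= finfq && finfq >= 0)
  if (nonphysical) {
    warning("non-physical plateau ordering (expected f0b >= f0q >= finfq >= 0); ",
            "components preserved for QC", call. = FALSE)
  }
  out <- list(
    f_extra = (f0b - f0q) * (1 + k) / k,
    f_intra = (f0q - finfq) * (1 + k) / k,
    f_unq   = (finfq * (1 + k) - f0b) / k,
    nonphysical = nonphysical
  )
  class(out) <- "compartment_split"
  out
}
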