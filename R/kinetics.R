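#' Kinetic parameters of one cleavage reaction
#'
#' Bundles the rate-law constants and initial concentrations of a single
#' protease cleavage reaction under product inhibition. Units are fixed
#' package-wide: concentrations in micromolar, time in minutes, rates in
#' \eqn{\mathrm{min}^{-1}}.
#'
#' @param kcat Catalytic turnover rate, per minute. Must be >= 0.
#' @param K_M Michaelis constant, micromolar. Must be > 0.
#' @param K_P Product-inhibition constant (dissociation constant of the
#'   cut-off UBL module rebinding the protease), micromolar. Must be > 0.
#' @param E0 Total enzyme concentration, micromolar. Must be >= 0.
#' @param S0 Initial substrate concentration, micromolar. Must be >= 0.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(kcat = 1, K_M = 10, K_P = 10, E0 = 0.5, S0 = 100)
#' @export
kinetic_params <- function(kcat, K_M, K_P, E0, S0) {
  check_nonneg_finite(kcat, "kcat")
  check_pos_finite(K_M, "K_M")
  check_pos_finite(K_P, "K_P")
  check_nonneg_finite(E0, "E0")
  check_nonneg_finite(S0, "S0")
  structure(list(kcat = kcat, K_M = K_M, K_P = K_P, E0 = E0, S0 = S0),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (uM, min):\n")
  cat(sprintf("  kcat = %g /min, K_M = %g uM, K_P = %g uM\n",
              x$kcat, x$K_M, x$K_P))
  cat(sprintf("  E0 = %g uM, S0 = %g uM\n", x$E0, x$S0))
  invisible(x)
}

#' Instantaneous state of a cleavage reaction
#'
#' Holds the remaining intact substrate and accumulated inhibitory product
#' at one point in time. The second, non-inhibitory cleavage product is
#' produced 1:1 with `P` and is not tracked separately, so mass
#' conservation reads `S + P = S0`.
#'
#' @param S Remaining intact substrate, micromolar (>= 0).
#' @param P Inhibitory product (free UBL module), micromolar (>= 0).
#' @param t Elapsed time, minutes (>= 0).
#'
#' @return An object of class `reaction_state`.
#' @export
reaction_state <- function(S, P, t = 0) {
  check_nonneg_finite(S, "S")
  check_nonneg_finite(P, "P")
  check_nonneg_finite(t, "t")
  structure(list(S = S, P = P, t = t), class = "reaction_state")
}

#' Apparent first-order cleavage rate
#'
#' Wraps an apparent rate constant \eqn{k_{app}} together with its
#' provenance. When the rate comes from a saturated single point
#' (fraction cleaved indistinguishable from 1) the rate is unidentifiable
#' and is represented as a censored lower bound instead of a number.
#'
#' @param k_app Apparent first-order rate, per minute (>= 0), or `NA` for
#'   a censored (lower-bound) result.
#' @param provenance One of `"from-parameters"`, `"single-point"`,
#'   `"fitted"`.
#' @param se Asymptotic standard error of `k_app` (fitted rates only).
#' @param lower_bound Logical; `TRUE` when only a lower bound on the rate
#'   is identifiable (saturated observation).
#' @param conditions Optional named list of assay conditions (substrate,
#'   temp_C, s0_uM, nacl_mM) used when comparing rates.
#'
#' @return An object of class `apparent_rate`.
#' @export
apparent_rate <- function(k_app,
                          provenance = c("from-parameters", "single-point",
                                         "fitted"),
                          se = NA_real_, lower_bound = FALSE,
                          conditions = NULL) {
  provenance <- match.arg(provenance)
  if (!lower_bound) {
    check_nonneg_finite(k_app, "k_app")
  }
  structure(list(k_app = k_app, provenance = provenance, se = se,
                 lower_bound = lower_bound, conditions = conditions),
            class = "apparent_rate")
}

#' @export
print.apparent_rate <- function(x, ...) {
  if (isTRUE(x$lower_bound)) {
    cat(sprintf("Apparent cleavage rate: censored (saturated observation; %s)\n",
                x$provenance))
  } else if (is.finite(x$se)) {
    cat(sprintf("Apparent cleavage rate: k_app = %.5g /min (se %.2g, %s)\n",
                x$k_app, x$se, x$provenance))
  } else {
    cat(sprintf("Apparent cleavage rate: k_app = %.5g /min (%s)\n",
                x$k_app, x$provenance))
  }
  invisible(x)
}

#' Cleavage velocity under full product inhibition
#'
#' Rate law for a cleavage reaction in which the cut-off UBL module
#' competes with the intact substrate for the protease:
#' \deqn{v = \frac{k_{cat} E_0 S}{K_M (1 + P/K_P + S/K_M)}}
#' Free enzyme is never tracked; the law uses total `E0` (tight-binding
#' depletion of enzyme by product is not modelled).
#'
#' @param state A [reaction_state()].
#' @param params A [kinetic_params()].
#' @return Cleavage velocity, micromolar per minute.
#' @examples
#' p <- kinetic_params(kcat = 1, K_M = 10, K_P = 5, E0 = 1, S0 = 15)
#' rate_full(reaction_state(S = 10, P = 5), p)  # 1/3 uM/min
#' @export
rate_full <- function(state, params) {
  stopifnot(inherits(state, "reaction_state"),
            inherits(params, "kinetic_params"))
  S <- state$S
  P <- state$P
  if (S == 0 || params$E0 == 0) return(0)
  params$kcat * params$E0 * S /
    (params$K_M * (1 + P / params$K_P + S / params$K_M))
}

#' Cleavage velocity under the equal-affinity assumption
#'
#' Simplified rate law obtained by assuming substrate and inhibitory
#' product bind the protease with the same affinity (`K_P = K_M`), which
#' is plausible because the cut-off UBL module shares essentially the
#' whole interaction interface with the intact substrate:
#' \deqn{v = \frac{k_{cat} E_0 S}{K_M + P + S}}
#' The `K_P` field of `params` is ignored.
#'
#' @inheritParams rate_full
#' @return Cleavage velocity, micromolar per minute.
#' @export
rate_equal_affinity <- function(state, params) {
  stopifnot(inherits(state, "reaction_state"),
            inherits(params, "kinetic_params"))
  S <- state$S
  P <- state$P
  if (S == 0 || params$E0 == 0) return(0)
  params$kcat * params$E0 * S / (params$K_M + P + S)
}

#' Apparent first-order rate from kinetic parameters
#'
#' Under the equal-affinity assumption and the stoichiometric substitution
#' `P = S0 - S`, the progress equation collapses to first-order decay of
#' substrate with rate
#' \deqn{k_{app} = \frac{k_{cat} E_0}{K_M + S_0}}
#'
#' @param params A [kinetic_params()].
#' @return An [apparent_rate()] with provenance `"from-parameters"`.
#' @examples
#' kapp_from_params(kinetic_params(1, 10, 10, E0 = 1, S0 = 90))  # 0.01 /min
#' @export
kapp_from_params <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  apparent_rate(params$kcat * params$E0 / (params$K_M + params$S0),
                provenance = "from-parameters")
}

#' Fraction cleaved under single-exponential progress
#'
#' Closed-form cleaved fraction at time `t` for first-order substrate
#' decay: \eqn{f(t) = 1 - e^{-k_{app} t}}. This is the quantity gels are
#' quantified for ("completeness of cleavage"); the remaining intact
#' fraction is its complement \eqn{e^{-k_{app} t}}.
#'
#' @param rate An [apparent_rate()] or a bare non-negative rate in
#'   \eqn{\mathrm{min}^{-1}}.
#' @param t Time(s), minutes; each must be >= 0. Vectorised over `t`.
#' @return Fraction cleaved in `[0, 1]`, same length as `t`.
#' @examples
#' fraction_cleaved(log(2) / 15, t = c(15, 30))  # 0.50, 0.75
#' @export
fraction_cleaved <- function(rate, t) {
  k <- if (inherits(rate, "apparent_rate")) rate$k_app else rate
  check_nonneg_finite(k, "k_app")
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("domain error: 't' must be finite and >= 0", call. = FALSE)
  }
  1 - exp(-k * t)
}

# input guards shared across the package ------------------------------------

check_nonneg_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("domain error: '%s' must be finite and >= 0", name),
         call. = FALSE)
  }
  invisible(x)
}

check_pos_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("domain error: '%s' must be finite and > 0", name),
         call. = FALSE)
  }
  invisible(x)
}
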