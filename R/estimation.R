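#' Cleavage time course
#'
#' Sampled progress of one cleavage reaction: fraction cleaved at strictly
#' increasing times, with the assay conditions attached so that rates are
#' only ever compared at matched conditions.
#'
#' @param times Minutes, strictly increasing.
#' @param fraction_cleaved Values in `[0, 1]`, same length as `times`.
#' @param substrate,protease Labels.
#' @param temp_C Incubation temperature, Celsius.
#' @param nacl_mM NaCl concentration, millimolar.
#' @param s0_uM Initial substrate concentration, micromolar.
#' @return Object of class `time_course` (a `data.frame` with condition
#'   metadata in attributes).
#' @export
time_course <- function(times, fraction_cleaved,
                        substrate = NA_character_, protease = NA_character_,
                        temp_C = NA_real_, nacl_mM = NA_real_,
                        s0_uM = NA_real_) {
  if (length(times) != length(fraction_cleaved)) {
    stop("data error: 'times' and 'fraction_cleaved' lengths differ",
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times, strictly = TRUE)) {
    stop("domain error: 'times' must be strictly increasing and >= 0",
         call. = FALSE)
  }
  check_fraction(fraction_cleaved, "fraction_cleaved")
  out <- data.frame(time_min = times, fraction_cleaved = fraction_cleaved)
  attr(out, "conditions") <- list(substrate = substrate, protease = protease,
                                  temp_C = temp_C, nacl_mM = nacl_mM,
                                  s0_uM = s0_uM)
  class(out) <- c("time_course", "data.frame")
  out
}

#' Protease titration series
#'
#' Fraction cleaved versus enzyme concentration at fixed substrate
#' concentration, incubation time and temperature — the readout of a
#' lowest-lane-fully-cut titration gel.
#'
#' @param enzyme_concs Micromolar, strictly increasing.
#' @param fraction_cleaved Values in `[0, 1]`, one per concentration.
#' @param s0_uM Substrate concentration, micromolar.
#' @param time_min Incubation time, minutes.
#' @param temp_C Temperature, Celsius.
#' @param substrate,protease Labels.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(enzyme_concs, fraction_cleaved,
                             s0_uM = NA_real_, time_min = NA_real_,
                             temp_C = NA_real_,
                             substrate = NA_character_,
                             protease = NA_character_) {
  if (length(enzyme_concs) != length(fraction_cleaved)) {
    stop("data error: concentration and fraction lengths differ",
         call. = FALSE)
  }
  if (length(enzyme_concs) == 0) {
    stop("data error: empty titration series", call. = FALSE)
  }
  if (any(!is.finite(enzyme_concs)) || any(enzyme_concs < 0) ||
      is.unsorted(enzyme_concs, strictly = TRUE)) {
    stop("domain error: 'enzyme_concs' must be strictly increasing and >= 0",
         call. = FALSE)
  }
  check_fraction(fraction_cleaved, "fraction_cleaved")
  out <- data.frame(enzyme_uM = enzyme_concs,
                    fraction_cleaved = fraction_cleaved)
  attr(out, "conditions") <- list(substrate = substrate, protease = protease,
                                  temp_C = temp_C, nacl_mM = NA_real_,
                                  s0_uM = s0_uM, time_min = time_min)
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Apparent rate from a single time point
#'
#' Inverts the single-exponential progress model: a lane showing fraction
#' `f` cleaved after `t` minutes implies
#' \eqn{k_{app} = -\ln(1 - f)/t}. A saturated point (`f = 1` at gel
#' resolution) carries no rate information and yields a censored
#' lower-bound result rather than a number.
#'
#' @param f Fraction cleaved, in `[0, 1]`.
#' @param t Time, minutes (> 0).
#' @param conditions Optional condition list attached to the result.
#' @return An [apparent_rate()] with provenance `"single-point"`.
#' @examples
#' kapp_single_point(0.50, 15)  # ln(2)/15 ~= 0.0462 /min
#' @export
kapp_single_point <- function(f, t, conditions = NULL) {
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f < 0 || f > 1) {
    stop("domain error: 'f' must be a single value in [0, 1]", call. = FALSE)
  }
  check_pos_finite(t, "t")
  if (f == 1) {
    return(apparent_rate(NA_real_, provenance = "single-point",
                         lower_bound = TRUE, conditions = conditions))
  }
  apparent_rate(-log(1 - f) / t, provenance = "single-point",
                conditions = conditions)
}

#' Fit an apparent rate to a multi-point time course
#'
#' Nonlinear least squares of the one-parameter model
#' \eqn{f(t) = 1 - e^{-k t}} — no intercept and no free amplitude, since
#' the model forces completion at 1. Saturated points (`f = 1` within
#' measurement resolution `sat_eps`) carry no rate information: they are
#' excluded when at least two unsaturated points remain, and otherwise
#' treated as right-censored at `1 - censor_eps`.
#'
#' @param course A [time_course()] (or data.frame with `time_min`,
#'   `fraction_cleaved`).
#' @param sat_eps Saturation resolution: points with
#'   `f >= 1 - sat_eps` count as saturated (default 0, i.e. only exact 1).
#' @param censor_eps Fraction offset used when censored points must be
#'   retained (default 0.01).
#' @return An [apparent_rate()] with provenance `"fitted"` and an
#'   asymptotic standard error.
#' @examples
#' tc <- time_course(c(5, 15, 30, 60), 1 - exp(-0.0462 * c(5, 15, 30, 60)))
#' kapp_fit(tc)
#' @export
kapp_fit <- function(course, sat_eps = 0, censor_eps = 0.01) {
  t <- course$time_min
  f <- course$fraction_cleaved
  keep <- t > 0
  t <- t[keep]; f <- f[keep]
  sat <- f >= 1 - sat_eps
  if (all(sat) && length(f) > 0) {
    stop("unidentifiable: all usable points are saturated", call. = FALSE)
  }
  if (sum(!sat) >= 2) {
    t <- t[!sat]; f <- f[!sat]
  } else if (any(sat)) {
    f[sat] <- 1 - censor_eps
  }
  if (length(t) < 2) {
    stop("data error: need >= 2 usable points with t > 0", call. = FALSE)
  }
  # start from the single-point rule at the most informative point
  mid <- which.min(abs(f - 0.5))
  k0 <- if (f[mid] > 0 && f[mid] < 1) -log(1 - f[mid]) / t[mid] else
    max(-log(1 - pmin(f, 0.99)) / t)
  k0 <- max(k0, 1e-8)
  fit <- minpack.lm::nlsLM(f ~ 1 - exp(-k * t),
                           data = data.frame(t = t, f = f),
                           start = list(k = k0),
                           lower = 0,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)[["k"]]
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  apparent_rate(est, provenance = "fitted", se = se,
                conditions = attr(course, "conditions"))
}

#' Molar fold excess of substrate over enzyme
#'
#' The average number of substrate molecules available per protease
#' molecule; when cleavage is near complete it is the average number of
#' substrate molecules each protease molecule has turned over.
#'
#' @param S0 Substrate concentration, micromolar.
#' @param E0 Enzyme concentration, micromolar (> 0).
#' @return `S0 / E0`, dimensionless.
#' @examples
#' fold_excess(100, 0.001)  # 1 nM enzyme vs 100 uM substrate: 1e5
#' @export
fold_excess <- function(S0, E0) {
  check_nonneg_finite(S0, "S0")
  check_pos_finite(E0, "E0")
  S0 / E0
}

#' Minimal enzyme concentration for near-complete cleavage
#'
#' The titration-gel readout: the lowest tested protease concentration
#' whose cleaved fraction reaches the threshold. Noisy, non-monotone
#' series still return the smallest passing concentration, but carry a
#' quality warning when any higher concentration fails — preserving the
#' visual "lowest lane fully cut" logic while surfacing inconsistency.
#'
#' @param series A [titration_series()].
#' @param threshold Near-complete cleavage threshold, in `(0, 1]`
#'   (default 0.95; gel standards resolve roughly 5% increments).
#' @return Object of class `min_conc`: list with `conc_uM` (or `NA`),
#'   `censored` (`TRUE` when nothing passed; the result is then the bound
#'   "greater than `max_tested_uM`"), `upper_bound_only` (`TRUE` when the
#'   lowest tested lane already passed), `nonmonotone_warning`,
#'   `threshold`, `max_tested_uM` and `conditions`.
#' @export
min_complete_conc <- function(series, threshold = 0.95) {
  if (!inherits(series, "titration_series")) {
    stop("data error: 'series' must be a titration_series", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("domain error: 'threshold' must be in (0, 1]", call. = FALSE)
  }
  pass <- series$fraction_cleaved >= threshold
  res <- list(conc_uM = NA_real_, censored = FALSE, upper_bound_only = FALSE,
              nonmonotone_warning = FALSE, threshold = threshold,
              max_tested_uM = max(series$enzyme_uM),
              conditions = attr(series, "conditions"))
  if (!any(pass)) {
    res$censored <- TRUE
  } else {
    i <- which(pass)[1]
    res$conc_uM <- series$enzyme_uM[i]
    res$upper_bound_only <- (i == 1)
    res$nonmonotone_warning <- any(!pass[i:length(pass)])
  }
  structure(res, class = "min_conc")
}

#' @export
print.min_conc <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Minimal complete-cleavage concentration: > %g uM (censored, threshold %.2f)\n",
                x$max_tested_uM, x$threshold))
  } else {
    cat(sprintf("Minimal complete-cleavage concentration: %s%g uM (threshold %.2f)\n",
                if (x$upper_bound_only) "<= " else "", x$conc_uM, x$threshold))
    if (x$nonmonotone_warning) {
      cat("  warning: a higher tested concentration fell below threshold\n")
    }
  }
  invisible(x)
}

#' Compare two activity measurements as a fold difference
#'
#' Works on a pair of [apparent_rate()]s (higher rate = more active) or a
#' pair of [min_conc] results (lower concentration = more active; the
#' ratio is inverted). Conditions must match on substrate, temperature,
#' substrate concentration and NaCl — the axes typically varied between
#' assays — before any comparison is made. Censored inputs propagate to a
#' bounded ("at least"-type) verdict.
#'
#' @param a,b Two objects of the same kind (`apparent_rate` or
#'   `min_conc`).
#' @return List with `fold` (>= 1), `faster` (`"a"` or `"b"`), `kind`, and
#'   `is_bound` (`TRUE` when a censored input makes the fold a bound).
#' @export
compare_activity <- function(a, b) {
  if (inherits(a, "apparent_rate") && inherits(b, "apparent_rate")) {
    check_conditions_match(a$conditions, b$conditions)
    ab <- bound_ratio(a$k_app, b$k_app,
                      a_bound = isTRUE(a$lower_bound),
                      b_bound = isTRUE(b$lower_bound))
    return(list(fold = ab$fold, faster = ab$larger, kind = "rate",
                is_bound = ab$is_bound))
  }
  if (inherits(a, "min_conc") && inherits(b, "min_conc")) {
    check_conditions_match(a$conditions, b$conditions)
    # lower concentration = more active; censored min-conc is a LOWER bound
    # on concentration, hence an UPPER bound on activity
    va <- if (a$censored) a$max_tested_uM else a$conc_uM
    vb <- if (b$censored) b$max_tested_uM else b$conc_uM
    ab <- bound_ratio(1 / va, 1 / vb, a_bound = a$censored,
                      b_bound = b$censored, bound_is_upper = TRUE)
    return(list(fold = ab$fold, faster = ab$larger, kind = "min-conc",
                is_bound = ab$is_bound))
  }
  stop("comparison error: 'a' and 'b' must both be apparent_rate or both min_conc",
       call. = FALSE)
}

bound_ratio <- function(va, vb, a_bound = FALSE, b_bound = FALSE,
                        bound_is_upper = FALSE) {
  if (a_bound && b_bound) {
    stop("comparison error: both inputs censored; no fold computable",
         call. = FALSE)
  }
  if (is.na(va) || is.na(vb)) {
    stop("comparison error: censored rate has no numeric value; compare via min_conc bounds",
         call. = FALSE)
  }
  if (va >= vb) {
    list(fold = va / vb, larger = "a", is_bound = a_bound || b_bound)
  } else {
    list(fold = vb / va, larger = "b", is_bound = a_bound || b_bound)
  }
}

check_conditions_match <- function(ca, cb) {
  if (is.null(ca) || is.null(cb)) return(invisible(TRUE))
  axes <- c("substrate", "temp_C", "s0_uM", "nacl_mM")
  bad <- character(0)
  for (ax in axes) {
    va <- ca[[ax]]; vb <- cb[[ax]]
    if (is.null(va) || is.null(vb)) next
    if (is.na(va) || is.na(vb)) next
    if (!identical(va, vb)) bad <- c(bad, ax)
  }
  if (length(bad)) {
    stop(sprintf("comparison error: conditions differ on: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Over-digestion fold
#'
#' Factor by which the applied protease concentration exceeds the minimal
#' concentration sufficient for near-complete cleavage under matched
#' conditions. When the minimal concentration is only known as a bound
#' (from a censored or lowest-lane-passing titration), the fold is
#' reported as the corresponding bound.
#'
#' @param E_used Applied enzyme concentration, micromolar (> 0).
#' @param E_min Minimal sufficient concentration: a positive number or a
#'   [min_conc] result.
#' @return List with `fold` and `bound` (`"none"`, `"lower"` when the
#'   true fold is at least `fold`).
#' @examples
#' overdigestion_fold(20, 0.001)  # 20 uM applied vs 1 nM sufficient
#' @export
overdigestion_fold <- function(E_used, E_min) {
  check_pos_finite(E_used, "E_used")
  if (inherits(E_min, "min_conc")) {
    if (E_min$censored) {
      stop("data error: minimal concentration censored above the tested range; over-digestion fold undefined",
           call. = FALSE)
    }
    # upper-bound-only min conc ("< x uM") makes the fold a lower bound
    bound <- if (E_min$upper_bound_only) "lower" else "none"
    return(list(fold = E_used / E_min$conc_uM, bound = bound))
  }
  check_pos_finite(E_min, "E_min")
  list(fold = E_used / E_min, bound = "none")
}

check_fraction <- function(f, name) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop(sprintf("domain error: '%s' must lie in [0, 1]", name),
         call. = FALSE)
  }
  invisible(f)
}
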