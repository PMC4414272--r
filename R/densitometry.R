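#' A cleavage-standard lane
#'
#' One lane of a cleavage-standard gel: defined volumes of fully cleaved
#' and uncleaved sample mixed to a known cleaved fraction, with the
#' densitometry intensities of the full-length band and the C-terminal
#' cleavage product (CCP) band.
#'
#' @param known_fraction Mixing fraction of fully cleaved sample, `[0,1]`.
#' @param intensity_fl Full-length band intensity, arbitrary units >= 0.
#' @param intensity_ccp CCP band intensity, arbitrary units >= 0.
#' @return Object of class `standard_point`.
#' @export
standard_point <- function(known_fraction, intensity_fl, intensity_ccp) {
  check_fraction(known_fraction, "known_fraction")
  check_nonneg_finite(intensity_fl, "intensity_fl")
  check_nonneg_finite(intensity_ccp, "intensity_ccp")
  structure(list(known_fraction = known_fraction,
                 intensity_fl = intensity_fl,
                 intensity_ccp = intensity_ccp),
            class = "standard_point")
}

#' Default cleavage-standard mixing ladder
#'
#' Fractions bracketing the calls a titration gel has to make
#' ("near complete", "about half"): 0, 0.10, 0.25, 0.50, 0.75, 0.90, 1.
#' @return Numeric vector of mixing fractions.
#' @export
default_standard_ladder <- function() c(0, 0.10, 0.25, 0.50, 0.75, 0.90, 1)

#' Calibrate band intensities against a cleavage standard
#'
#' Fits the one-parameter response model
#' \deqn{f_{obs} = \frac{I_{ccp}}{I_{ccp} + r \, I_{fl}}}
#' where `r` is the per-mole staining ratio of the CCP band relative to
#' the full-length band (Coomassie response scales roughly with mass, so
#' the two bands of a cleavage reaction stain differently per mole). `r`
#' is found by least squares of the observed ratio against the known
#' mixing fractions; endpoint lanes (fraction 0 or 1) are consistent with
#' any `r` and constrain the fit only through their being reproduced
#' exactly.
#'
#' @param points A list of [standard_point()]s, or a `data.frame` with
#'   columns `known_fraction`, `intensity_fl`, `intensity_ccp`. Needs at
#'   least two distinct known fractions, at least one of them interior.
#' @return Object of class `standard_curve`: list with `r`, `residuals`,
#'   and the calibration `points`.
#' @export
build_standard_curve <- function(points) {
  df <- as_standard_df(points)
  if (length(unique(df$known_fraction)) < 2) {
    stop("calibration error: need >= 2 distinct known fractions",
         call. = FALSE)
  }
  interior <- df$known_fraction > 0 & df$known_fraction < 1
  if (!any(interior)) {
    stop("calibration error: need at least one interior (0 < f < 1) standard to identify the response factor",
         call. = FALSE)
  }
  obj <- function(log_r) {
    r <- exp(log_r)
    pred <- df$intensity_ccp / (df$intensity_ccp + r * df$intensity_fl)
    sum((pred - df$known_fraction)^2)
  }
  opt <- stats::optimize(obj, interval = c(log(1e-4), log(1e4)), tol = 1e-10)
  r <- exp(opt$minimum)
  pred <- df$intensity_ccp / (df$intensity_ccp + r * df$intensity_fl)
  structure(list(r = r, residuals = pred - df$known_fraction, points = df),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Cleavage-standard calibration: response factor r = %.4g (%d lanes, RMS residual %.3g)\n",
              x$r, nrow(x$points), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Mass-proportional default calibration
#'
#' When no mixed standards are available, the per-mole staining ratio is
#' approximated by the mass ratio of the two bands (Coomassie binding is
#' roughly mass-proportional).
#'
#' @param mass_ccp,mass_fl Molecular masses (any common unit) of the CCP
#'   and full-length species.
#' @return A `standard_curve` with `r = mass_ccp / mass_fl` and no lanes.
#' @export
mass_ratio_curve <- function(mass_ccp, mass_fl) {
  check_pos_finite(mass_ccp, "mass_ccp")
  check_pos_finite(mass_fl, "mass_fl")
  structure(list(r = mass_ccp / mass_fl, residuals = numeric(0),
                 points = data.frame(known_fraction = numeric(0),
                                     intensity_fl = numeric(0),
                                     intensity_ccp = numeric(0))),
            class = "standard_curve")
}

#' Fraction cleaved from band intensities
#'
#' Converts one lane's full-length and CCP band intensities into fraction
#' cleaved through the fitted response factor:
#' `f = ccp / (ccp + r * fl)`, clamped to `[0, 1]`. Vectorised.
#'
#' @param fl Full-length band intensity (>= 0).
#' @param ccp CCP band intensity (>= 0).
#' @param curve A [build_standard_curve()] result (or [mass_ratio_curve()]).
#' @return Fraction cleaved in `[0, 1]`.
#' @export
fraction_from_bands <- function(fl, ccp, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  check_nonneg_finite(fl, "fl")
  check_nonneg_finite(ccp, "ccp")
  if (length(fl) != length(ccp)) {
    stop("data error: 'fl' and 'ccp' lengths differ", call. = FALSE)
  }
  if (any(fl == 0 & ccp == 0)) {
    stop("data error: empty lane (both band intensities zero)",
         call. = FALSE)
  }
  pmin(pmax(ccp / (ccp + curve$r * fl), 0), 1)
}

as_standard_df <- function(points) {
  if (is.data.frame(points)) {
    need <- c("known_fraction", "intensity_fl", "intensity_ccp")
    miss <- setdiff(need, names(points))
    if (length(miss)) {
      stop(sprintf("data error: missing columns: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    return(points[need])
  }
  if (is.list(points) && all(vapply(points, inherits, logical(1),
                                    "standard_point"))) {
    return(do.call(rbind, lapply(points, function(p) {
      data.frame(known_fraction = p$known_fraction,
                 intensity_fl = p$intensity_fl,
                 intensity_ccp = p$intensity_ccp)
    })))
  }
  stop("data error: 'points' must be standard_point objects or a data.frame",
       call. = FALSE)
}
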