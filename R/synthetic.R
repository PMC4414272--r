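#' Densitometry noise model
#'
#' Variability of Coomassie band quantification: multiplicative
#' log-normal intensity noise with a given coefficient of variation, an
#' additive baseline offset, and optional direct additive noise on
#' fractions (for assays recorded as fractions rather than intensities).
#'
#' @param intensity_cv CV of multiplicative log-normal band noise
#'   (default 0.10, typical gel-to-gel densitometry repeatability).
#' @param baseline Additive intensity offset (default 0).
#' @param fraction_sigma SD of additive Gaussian noise applied directly
#'   to fractions (default 0); noisy fractions are clamped to `[0, 1]`.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(intensity_cv = 0.10, baseline = 0,
                        fraction_sigma = 0) {
  check_nonneg_finite(intensity_cv, "intensity_cv")
  check_nonneg_finite(baseline, "baseline")
  check_nonneg_finite(fraction_sigma, "fraction_sigma")
  structure(list(intensity_cv = intensity_cv, baseline = baseline,
                 fraction_sigma = fraction_sigma), class = "noise_model")
}

# One global seed governs independent per-generator streams through a
# counter-based split: each generator hashes (seed, stream label) into its
# own substream seed, so adding a generator never reshuffles existing ones.
split_seed <- function(seed, stream) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) || seed < 0) {
    stop("domain error: 'seed' must be a single non-negative integer",
         call. = FALSE)
  }
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((seed * 48271 + h * 16807) %% 2147483647L)
}

with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(split_seed(seed, stream))
  expr
}

lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

noisy_fraction <- function(f, noise) {
  if (noise$fraction_sigma > 0) {
    f <- f + stats::rnorm(length(f), sd = noise$fraction_sigma)
  }
  pmin(pmax(f, 0), 1)
}

bands_from_fraction <- function(f, response_factor, noise, scale = 1000) {
  fl <- scale * (1 - f) * lognorm_noise(length(f), noise$intensity_cv) +
    noise$baseline
  ccp <- scale * response_factor * f *
    lognorm_noise(length(f), noise$intensity_cv) + noise$baseline
  data.frame(intensity_fl = fl, intensity_ccp = ccp)
}

#' Generate a synthetic cleavage time course
#'
#' Emulates a time-course gel: the true progress curve comes from the
#' numerically integrated product-inhibited model ([simulate_ode()]),
#' observation noise is applied per the noise model, and raw band
#' intensities can be produced through the densitometry forward model.
#' Deterministic for a fixed seed; with zero noise the fractions equal
#' the ODE solution exactly.
#'
#' @param params A [kinetic_params()].
#' @param times Sampling times, minutes (0 prepended when absent).
#' @param noise A [noise_model()].
#' @param seed Global seed; the generator draws from its own substream.
#' @param bands If `TRUE`, attach `intensity_fl` / `intensity_ccp`
#'   columns built from the noiseless fractions via the forward model.
#' @param response_factor Per-mole staining ratio used for band synthesis.
#' @param conditions Optional named list (substrate, protease, temp_C,
#'   nacl_mM) recorded on the result.
#' @return A [time_course()]; when `bands = TRUE`, with intensity columns.
#' @export
gen_timecourse <- function(params, times, noise = noise_model(), seed = 1,
                           bands = FALSE, response_factor = 1,
                           conditions = list()) {
  sim <- simulate_ode(params, times)
  f_true <- sim$course$fraction_cleaved
  with_stream_seed(seed, "timecourse", {
    f_obs <- noisy_fraction(f_true, noise)
    tc <- time_course(sim$course$time_min, f_obs,
                      substrate = conditions$substrate %||% NA_character_,
                      protease = conditions$protease %||% NA_character_,
                      temp_C = conditions$temp_C %||% NA_real_,
                      nacl_mM = conditions$nacl_mM %||% NA_real_,
                      s0_uM = params$S0)
    if (bands) {
      b <- bands_from_fraction(f_true, response_factor, noise)
      tc$intensity_fl <- b$intensity_fl
      tc$intensity_ccp <- b$intensity_ccp
    }
    tc
  })
}

#' Generate a synthetic protease titration series
#'
#' Fraction cleaved after a fixed incubation for each enzyme
#' concentration, computed from the apparent-rate law (k_app linear in
#' E0) and the single-exponential progress model, then noised. The
#' noiseless series is strictly increasing in enzyme concentration.
#'
#' @param kcat,K_M,S0 Kinetic constants shared across the series
#'   (per-minute, micromolar, micromolar).
#' @param enzyme_concs Strictly increasing enzyme concentrations,
#'   micromolar (may start at 0).
#' @param time Incubation time, minutes.
#' @param noise A [noise_model()] (uses `fraction_sigma`).
#' @param seed Global seed.
#' @param temp_C,substrate,protease Recorded conditions.
#' @return A [titration_series()].
#' @export
gen_titration <- function(kcat, K_M, S0, enzyme_concs, time,
                          noise = noise_model(), seed = 1,
                          temp_C = NA_real_, substrate = NA_character_,
                          protease = NA_character_) {
  check_nonneg_finite(enzyme_concs, "enzyme_concs")
  f_true <- vapply(enzyme_concs, function(E0) {
    p <- kinetic_params(kcat, K_M, K_M, E0, S0)
    fraction_cleaved(kapp_from_params(p), time)
  }, numeric(1))
  with_stream_seed(seed, "titration", {
    titration_series(enzyme_concs, noisy_fraction(f_true, noise),
                     s0_uM = S0, time_min = time, temp_C = temp_C,
                     substrate = substrate, protease = protease)
  })
}

#' Generate a synthetic cross-reactivity grid
#'
#' Emulates an all-against-all digestion panel from a planted specificity
#' matrix of relative activities (cognate = 1, off-target < 1, zero = no
#' cleavage). Each cell's fraction is the single-exponential outcome with
#' the cognate apparent rate scaled by the planted relative activity;
#' zero activity gives fraction 0 before noise.
#'
#' @param specificity Non-negative numeric matrix, proteases in rows,
#'   substrates in columns, with dimnames; entry = relative activity.
#' @param cognate Named character vector substrate -> cognate protease.
#' @param conditions List with `kcat`, `K_M`, `S0`, `E0`, `time_min`,
#'   `temp_C` defining the over-digestion incubation.
#' @param noise A [noise_model()] (uses `fraction_sigma`).
#' @param seed Global seed.
#' @return A [crossreact_grid()].
#' @export
gen_crossreact <- function(specificity, cognate,
                           conditions = list(kcat = 1, K_M = 10, S0 = 100,
                                             E0 = 20, time_min = 180,
                                             temp_C = 25),
                           noise = noise_model(), seed = 1) {
  if (!is.matrix(specificity) || any(specificity < 0) ||
      is.null(rownames(specificity)) || is.null(colnames(specificity))) {
    stop("domain error: 'specificity' must be a non-negative matrix with dimnames",
         call. = FALSE)
  }
  base <- kinetic_params(conditions$kcat, conditions$K_M, conditions$K_M,
                         conditions$E0, conditions$S0)
  k_base <- kapp_from_params(base)$k_app
  cells <- expand.grid(protease = rownames(specificity),
                       substrate = colnames(specificity),
                       stringsAsFactors = FALSE)
  f_true <- mapply(function(p, s) {
    fraction_cleaved(k_base * specificity[p, s], conditions$time_min)
  }, cells$protease, cells$substrate)
  with_stream_seed(seed, "crossreact", {
    cells$enzyme_uM <- conditions$E0
    cells$fraction_cleaved <- noisy_fraction(f_true, noise)
    cells$time_min <- conditions$time_min
    cells$temp_C <- conditions$temp_C %||% NA_real_
    crossreact_grid(cells, cognate)
  })
}

#' Generate synthetic cleavage-standard lanes
#'
#' Emulates mixing defined volumes of fully cleaved and uncleaved sample:
#' band intensities proportional to the molar amount of each species
#' times its staining response, perturbed by the intensity noise model.
#'
#' @param ladder Mixing fractions in `[0, 1]`
#'   (default [default_standard_ladder()]).
#' @param response_factor Planted per-mole staining ratio of the CCP band.
#' @param noise A [noise_model()].
#' @param seed Global seed.
#' @return `data.frame` of standard lanes (`known_fraction`,
#'   `intensity_fl`, `intensity_ccp`).
#' @export
gen_standards <- function(ladder = default_standard_ladder(),
                          response_factor = 1, noise = noise_model(),
                          seed = 1) {
  check_fraction(ladder, "ladder")
  check_pos_finite(response_factor, "response_factor")
  with_stream_seed(seed, "standards", {
    b <- bands_from_fraction(ladder, response_factor, noise)
    data.frame(known_fraction = ladder, b)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
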