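#' Describe one synthetic feature block
#'
#' A block emulates one neuroimaging modality: a high-dimensional feature
#' matrix whose columns load on a (partly shared, partly block-specific)
#' function of age, a latent health factor, and a block-private latent
#' variable, plus i.i.d. Gaussian noise. Block-wise missingness is either
#' absent, completely at random (MCAR) or age-dependent (age_MAR, missing
#' probability following a logistic curve in age whose intercept is
#' calibrated so the marginal missingness matches `miss_rate`).
#'
#' @param name Block name (e.g. `"meg"`, `"fmri"`, `"mri"`).
#' @param n_features Number of features (columns).
#' @param shared_signal_weight Loading weight of the age signal shared with
#'   the other blocks (unitless).
#' @param private_signal_weight Loading weight of the block-private latent
#'   variable (unitless).
#' @param health_weight Loading weight of the latent health factor that also
#'   drives the behavioral scores; this is the device that makes brain-age
#'   delta associations recoverable with known ground truth.
#' @param noise_sd Standard deviation of the additive feature noise.
#' @param nonlinearity Shape of the age signal: `"linear"`, `"quadratic"`
#'   or `"saturating"`.
#' @param missingness `"none"`, `"MCAR"` or `"age_MAR"`.
#' @param miss_rate Marginal missingness fraction in `[0, 1]`.
#' @param mar_slope Per-year logit slope of the age_MAR mechanism.
#' @return A `block_spec` list.
#' @export
block_spec <- function(name, n_features,
                       shared_signal_weight = 1,
                       private_signal_weight = 1,
                       health_weight = 0.3,
                       noise_sd = 1,
                       nonlinearity = c("linear", "quadratic", "saturating"),
                       missingness = c("none", "MCAR", "age_MAR"),
                       miss_rate = 0,
                       mar_slope = 0) {
  nonlinearity <- match.arg(nonlinearity)
  missingness <- match.arg(missingness)
  if (n_features < 1L) abort("`n_features` must be >= 1.")
  if (miss_rate < 0 || miss_rate > 1) abort("`miss_rate` must be in [0, 1].")
  structure(
    list(name = name, n_features = as.integer(n_features),
         shared_signal_weight = shared_signal_weight,
         private_signal_weight = private_signal_weight,
         health_weight = health_weight, noise_sd = noise_sd,
         nonlinearity = nonlinearity, missingness = missingness,
         miss_rate = miss_rate, mar_slope = mar_slope),
    class = "block_spec")
}

#' Describe one synthetic behavioral score
#'
#' @param name Score name.
#' @param age_poly_coefs Coefficients of the polynomial age trend, applied to
#'   powers 1..K of the standardized age.
#' @param health_loading Loading on the latent health factor shared with the
#'   feature blocks.
#' @param noise_sd Standard deviation of the score noise.
#' @return A `score_spec` list.
#' @export
score_spec <- function(name, age_poly_coefs = 0, health_loading = 0,
                       noise_sd = 1) {
  structure(list(name = name, age_poly_coefs = age_poly_coefs,
                 health_loading = health_loading, noise_sd = noise_sd),
            class = "score_spec")
}

#' Assemble a simulation configuration
#'
#' The default age range is uniform on 18--88 years, matching the life-span
#' cohort design the package targets.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Two-element `(low, high)` age range in years.
#' @param block_specs List of [block_spec()] objects.
#' @param score_specs Optional list of [score_spec()] objects.
#' @param seed Master integer seed; every stochastic component derives its
#'   own stream from it, so a config fully determines the dataset.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects, age_range = c(18, 88),
                              block_specs, score_specs = list(), seed = 1L) {
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    abort("`age_range` must be (low, high) with low < high.")
  }
  if (!length(block_specs)) abort("at least one block spec is required.")
  names(block_specs) <- vapply(block_specs, `[[`, "", "name")
  if (anyDuplicated(names(block_specs))) abort("duplicate block names.")
  structure(list(n_subjects = as.integer(n_subjects),
                 age_range = as.numeric(age_range),
                 block_specs = block_specs, score_specs = score_specs,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# age signal on a standardized scale; empirically re-standardized so the
# loading weights keep their meaning across nonlinearities
age_signal <- function(age, nonlinearity) {
  z <- (age - mean(age)) / sd(age)
  f <- switch(nonlinearity,
              linear = z,
              quadratic = z^2,
              saturating = tanh(1.5 * z))
  (f - mean(f)) / sd(f)
}

calibrate_mar_intercept <- function(age, slope, rate) {
  centered <- age - mean(age)
  target <- function(a) mean(plogis(a + slope * centered)) - rate
  uniroot(target, lower = -50, upper = 50, tol = 1e-10)$root
}

#' Generate a multimodal dataset with known ground truth
#'
#' Ages are drawn uniformly in the configured range; a standard-normal latent
#' health variable is drawn per subject; each block is a loading matrix
#' applied to `(f(age), health, private latent)` plus Gaussian noise, with a
#' per-block availability mask drawn from its missingness mechanism.
#' Deterministic given the config (same seed, bit-identical data).
#'
#' @param config A [simulation_config()].
#' @return A `multimodal_dataset`: `subjects` (tibble with `subject_id`,
#'   `age`, `health`), `blocks` (named list of feature matrices), `masks`
#'   (named list of logical availability vectors) and the config.
#' @export
simulate_multimodal <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))

  age <- with_seed(derive_seed(config$seed, 11L),
                   runif(n, config$age_range[1], config$age_range[2]))
  health <- with_seed(derive_seed(config$seed, 23L), rnorm(n))

  blocks <- list()
  masks <- list()
  for (b in seq_along(config$block_specs)) {
    spec <- config$block_specs[[b]]
    out <- with_seed(derive_seed(config$seed, 100L + b), {
      f_age <- age_signal(age, spec$nonlinearity)
      private <- rnorm(n)
      latent <- cbind(spec$shared_signal_weight * f_age,
                      spec$health_weight * health,
                      spec$private_signal_weight * private)
      loading <- matrix(rnorm(3L * spec$n_features), nrow = 3L)
      x <- latent %*% loading +
        spec$noise_sd * matrix(rnorm(n * spec$n_features), nrow = n)
      mask <- switch(spec$missingness,
        none = rep(TRUE, n),
        MCAR = runif(n) >= spec$miss_rate,
        age_MAR = {
          if (spec$miss_rate <= 0) rep(TRUE, n) else {
            a0 <- calibrate_mar_intercept(age, spec$mar_slope, spec$miss_rate)
            runif(n) >= plogis(a0 + spec$mar_slope * (age - mean(age)))
          }
        })
      list(x = x, mask = mask)
    })
    if (!any(out$mask)) {
      abort(sprintf("block '%s' would have zero observed subjects.",
                    spec$name))
    }
    rownames(out$x) <- ids
    colnames(out$x) <- sprintf("%s_f%03d", spec$name,
                               seq_len(spec$n_features))
    blocks[[spec$name]] <- out$x
    masks[[spec$name]] <- out$mask
  }

  structure(list(
    subjects = tibble(subject_id = ids, age = age, health = health),
    blocks = blocks, masks = masks, config = config),
    class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("<multimodal_dataset> %d subjects, %d blocks\n",
              nrow(x$subjects), length(x$blocks)))
  for (b in names(x$blocks)) {
    cat(sprintf("  %s: %d features, %d/%d observed\n", b, ncol(x$blocks[[b]]),
                sum(x$masks[[b]]), nrow(x$subjects)))
  }
  invisible(x)
}

#' Generate behavioral scores tied to the dataset's latent health
#'
#' Each score is a polynomial trend in (standardized) age plus a loading on
#' the latent health factor plus Gaussian noise. The returned tibble carries
#' the ground-truth specs as an attribute for recovery tests.
#'
#' @param dataset A [simulate_multimodal()] result.
#' @param score_specs List of [score_spec()]; defaults to the config's.
#' @return Tibble with `subject_id` and one column per score.
#' @export
simulate_scores <- function(dataset, score_specs = NULL) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  score_specs <- score_specs %||% dataset$config$score_specs
  if (!length(score_specs)) abort("no score specs supplied.")
  age <- dataset$subjects$age
  z <- (age - mean(age)) / sd(age)
  out <- tibble(subject_id = dataset$subjects$subject_id)
  for (k in seq_along(score_specs)) {
    spec <- score_specs[[k]]
    trend <- 0
    for (d in seq_along(spec$age_poly_coefs)) {
      trend <- trend + spec$age_poly_coefs[d] * z^d
    }
    noise <- with_seed(derive_seed(dataset$config$seed, 500L + k),
                       rnorm(length(age)))
    out[[spec$name]] <- trend +
      spec$health_loading * dataset$subjects$health + spec$noise_sd * noise
  }
  attr(out, "ground_truth") <- score_specs
  out
}

#' Describe a synthetic oscillatory multichannel recording
#'
#' @param n_channels Number of channels.
#' @param fs Sampling frequency in Hz.
#' @param duration Duration in seconds.
#' @param one_over_f_exponent Spectral exponent beta of the `1/f^beta`
#'   background (0 = white noise).
#' @param alpha_peak_hz Center frequency of the alpha component, or `NULL`
#'   for none.
#' @param alpha_power Variance of the alpha component.
#' @param band_powers Named list mapping band names (see
#'   [frequency_bands()]) to added band-limited variance.
#' @param envelope_coupling Target correlation of the amplitude envelopes of
#'   the two `coupled_channels` (requires an alpha component).
#' @param coupled_channels Two channel indices carrying the coupled
#'   envelopes.
#' @param seed Integer seed.
#' @return An `oscillatory_spec` list.
#' @export
oscillatory_spec <- function(n_channels = 2L, fs = 200, duration = 60,
                             one_over_f_exponent = 1, alpha_peak_hz = NULL,
                             alpha_power = 1, band_powers = list(),
                             envelope_coupling = 0,
                             coupled_channels = c(1L, 2L), seed = 1L) {
  if (!is.null(alpha_peak_hz) &&
      (alpha_peak_hz <= 0 || alpha_peak_hz >= fs / 2)) {
    abort("`alpha_peak_hz` must lie in (0, fs/2).")
  }
  if (abs(envelope_coupling) > 1) {
    abort("`envelope_coupling` must be in [-1, 1].")
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration,
                 one_over_f_exponent = one_over_f_exponent,
                 alpha_peak_hz = alpha_peak_hz, alpha_power = alpha_power,
                 band_powers = band_powers,
                 envelope_coupling = envelope_coupling,
                 coupled_channels = as.integer(coupled_channels),
                 seed = as.integer(seed)),
            class = "oscillatory_spec")
}

# spectrally shape white noise by gain(f); exact target spectrum in
# expectation (FFT filter)
shaped_noise <- function(n, fs, gain) {
  w <- rnorm(n)
  wf <- fft(w)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)  # two-sided frequency axis
  g <- gain(f)
  g[1L] <- 0  # remove DC
  x <- Re(fft(wf * g, inverse = TRUE)) / n
  x
}

lowpass_noise <- function(n, fs, cutoff) {
  x <- shaped_noise(n, fs, function(f) as.numeric(f > 0 & f <= cutoff))
  (x - mean(x)) / sd(x)
}

#' Generate a synthetic multichannel oscillatory signal
#'
#' Each channel is colored noise with power proportional to `f^-beta`, plus
#' an optional narrow-band alpha component and optional band-limited
#' components with specified variances. The amplitude envelopes of two
#' designated channels can be correlated at a target value, implemented by
#' amplitude-modulating an alpha-band carrier with partially shared slow
#' modulators.
#'
#' @param spec An [oscillatory_spec()].
#' @return A `multichannel_signal`: list with `data` (channels x samples
#'   matrix) and `fs`.
#' @export
simulate_oscillatory <- function(spec) {
  stopifnot(inherits(spec, "oscillatory_spec"))
  n <- round(spec$fs * spec$duration)
  bands <- frequency_bands()
  with_seed(spec$seed, {
    x <- matrix(0, nrow = spec$n_channels, ncol = n)
    for (ch in seq_len(spec$n_channels)) {
      if (spec$one_over_f_exponent != 0) {
        bg <- shaped_noise(n, spec$fs, function(f) {
          ifelse(f > 0, f^(-spec$one_over_f_exponent / 2), 0)
        })
      } else {
        bg <- rnorm(n)
      }
      x[ch, ] <- bg
      for (bn in names(spec$band_powers)) {
        row <- bands[bands$band == bn | bands$ascii == bn, ]
        if (nrow(row) != 1L) abort(sprintf("unknown band '%s'.", bn))
        comp <- shaped_noise(n, spec$fs, function(f) {
          as.numeric(f >= row$low & f <= row$high)
        })
        comp <- comp / sd(comp) * sqrt(spec$band_powers[[bn]])
        x[ch, ] <- x[ch, ] + comp
      }
    }
    if (!is.null(spec$alpha_peak_hz) && spec$alpha_power > 0) {
      t <- seq_len(n) / spec$fs
      rho <- spec$envelope_coupling
      z0 <- lowpass_noise(n, spec$fs, 1)
      for (ch in seq_len(spec$n_channels)) {
        if (ch %in% spec$coupled_channels && rho != 0) {
          zi <- sqrt(abs(rho)) * z0 * (if (ch == spec$coupled_channels[2L])
            sign(rho) else 1) + sqrt(1 - abs(rho)) * lowpass_noise(n, spec$fs, 1)
        } else {
          zi <- lowpass_noise(n, spec$fs, 1)
        }
        am <- 1 + 0.4 * pmax(pmin(zi, 2), -2)
        carrier <- cos(2 * pi * spec$alpha_peak_hz * t + runif(1, 0, 2 * pi))
        comp <- am * carrier
        comp <- comp / sd(comp) * sqrt(spec$alpha_power)
        x[ch, ] <- x[ch, ] + comp
      }
    }
    structure(list(data = x, fs = spec$fs), class = "multichannel_signal")
  })
}

#' @export
print.multichannel_signal <- function(x, ...) {
  cat(sprintf("<multichannel_signal> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Canonical frequency-band definitions
#'
#' Nine bands spanning 0.1--100 Hz as commonly used for life-span M/EEG
#' feature extraction, with ASCII aliases for file naming.
#'
#' @return Tibble with columns `band`, `ascii`, `low`, `high` (Hz).
#' @export
frequency_bands <- function() {
  tibble(
    band = c("low", "δ", "θ", "α", "β1", "β2",
             "γ1", "γ2", "γ3"),
    ascii = c("low", "delta", "theta", "alpha", "beta_low", "beta_high",
              "gamma_lo", "gamma_mid", "gamma_high"),
    low = c(0.1, 1.5, 4, 8, 15, 26, 35, 50, 76),
    high = c(1.5, 4, 8, 15, 26, 35, 50, 74, 100))
}
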