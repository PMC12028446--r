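# Signal conditioning, center-of-pressure computation, and the three sway
# metrics (95% prediction ellipse area, mean velocity, median frequency).

#' Construct a CoP series
#'
#' Anterior–posterior (`cop_x`, positive anterior) and medial–lateral
#' (`cop_y`, positive right) center-of-pressure displacements in cm at a
#' fixed sampling rate.
#'
#' @param cop_x,cop_y numeric displacement series (cm).
#' @param sample_rate sampling frequency (Hz).
#' @return an object of class `cop_series`.
#' @export
cop_series <- function(cop_x, cop_y, sample_rate = 100) {
  if (length(cop_x) != length(cop_y)) stopf("cop_x and cop_y lengths differ")
  if (length(cop_x) < 2) stopf("a CoP series needs at least 2 samples")
  if (!all(is.finite(cop_x)) || !all(is.finite(cop_y))) {
    stopf("CoP series must be finite")
  }
  if (sample_rate <= 0) stopf("sample_rate must be > 0")
  structure(list(cop_x = as.numeric(cop_x), cop_y = as.numeric(cop_y),
                 sample_rate = sample_rate),
            class = "cop_series")
}

#' @export
print.cop_series <- function(x, ...) {
  cat(sprintf("<cop_series> %d samples @ %g Hz (%.1f s)\n",
              length(x$cop_x), x$sample_rate,
              length(x$cop_x) / x$sample_rate))
  invisible(x)
}

#' Zero-lag Butterworth low-pass filter
#'
#' The conventional "n-th order zero-lag" smoother of biomechanics: a
#' Butterworth design of half the requested order applied forward and
#' backward, giving the full effective order with exactly zero phase.
#' Edge transients are controlled by reflection padding (1 s by default,
#' shortened on short signals).
#'
#' @param x numeric series, uniformly sampled.
#' @param sample_rate sampling frequency (Hz).
#' @param cutoff cutoff frequency (Hz); must be below Nyquist.
#' @param order effective filter order; even (default 4, realized as a
#'   2nd-order design applied twice).
#' @return filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, sample_rate, cutoff = 10, order = 4) {
  if (order < 2 || order %% 2 != 0) stopf("order must be a positive even integer")
  if (cutoff >= sample_rate / 2) {
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff, sample_rate / 2)
  }
  if (cutoff <= 0) stopf("cutoff must be > 0")
  n <- length(x)
  if (n <= 3 * (order + 1)) {
    stopf("signal too short (%d samples) for stable order-%d filtering", n, order)
  }
  bf <- signal::butter(order / 2, cutoff / (sample_rate / 2), type = "low")
  npad <- min(round(sample_rate), n - 1)
  # odd (point-reflected) extension keeps the signal level continuous;
  # the two-pass difference equation itself runs compiled
  as.numeric(iir_filtfilt(bf$b, bf$a, as.numeric(x), npad))
}

#' Compute the CoP trajectory from a force-platform trial
#'
#' Channels are low-pass filtered first (10 Hz effective 4th-order zero-lag
#' Butterworth by default), then the standard applied-load formulas give
#' the displacements: `cop_x = -(My + z_offset * Fx) / Fz` and
#' `cop_y = (Mx - z_offset * Fy) / Fz` (meters, converted to cm on output).
#' `z_offset` is the distance from the platform surface to the sensor
#' plane; 0 for a surface-referenced platform.
#'
#' @param trial a [force_plate_trial()].
#' @param z_offset sensor-plane offset (m), default 0.
#' @param cutoff,order filter settings, see [lowpass_filter()].
#' @param filter logical; disable to get the raw algebraic CoP.
#' @param fz_min minimum admissible |Fz| (N): samples below this indicate
#'   the participant was not standing on the platform.
#' @return a [cop_series()] in cm.
#' @export
compute_cop <- function(trial, z_offset = 0, cutoff = 10, order = 4,
                        filter = TRUE, fz_min = 50) {
  stopifnot(inherits(trial, "force_plate_trial"))
  fx <- trial$fx; fy <- trial$fy; fz <- trial$fz
  mx <- trial$mx; my <- trial$my
  if (filter) {
    fx <- lowpass_filter(fx, trial$sample_rate, cutoff, order)
    fy <- lowpass_filter(fy, trial$sample_rate, cutoff, order)
    fz <- lowpass_filter(fz, trial$sample_rate, cutoff, order)
    mx <- lowpass_filter(mx, trial$sample_rate, cutoff, order)
    my <- lowpass_filter(my, trial$sample_rate, cutoff, order)
  }
  low <- which(abs(fz) < fz_min)
  if (length(low)) {
    stopf("|Fz| below %g N at sample %d: no standing load present",
          fz_min, low[1])
  }
  cop_x <- -(my + z_offset * fx) / fz * 100
  cop_y <- (mx - z_offset * fy) / fz * 100
  cop_series(cop_x, cop_y, trial$sample_rate)
}

#' 95% prediction ellipse area of a CoP trajectory
#'
#' Area of the ellipse expected to contain a given fraction of CoP points
#' under a bivariate-normal sway model:
#' `area = pi * q * sqrt(lambda1 * lambda2)`, where the lambdas are the
#' eigenvalues of the 2x2 sample covariance and `q` is the chi-square
#' quantile with 2 degrees of freedom (5.99146 at 95%).
#'
#' @param cop a [cop_series()].
#' @param conf coverage probability (default 0.95).
#' @return area in cm^2 (0, with a warning, for a degenerate point cloud).
#' @export
ellipse_area <- function(cop, conf = 0.95) {
  stopifnot(inherits(cop, "cop_series"))
  n <- length(cop$cop_x)
  if (n < 3) stopf("ellipse_area needs at least 3 samples")
  S <- stats::cov(cbind(cop$cop_x, cop$cop_y))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (all(ev == 0)) {
    warnf("all CoP points identical; ellipse area is 0")
    return(0)
  }
  pi * stats::qchisq(conf, df = 2) * sqrt(prod(ev))
}

#' Mean sway velocity
#'
#' Total resultant CoP path length divided by the trial duration
#' `(n - 1) / sample_rate`.
#'
#' @param cop a [cop_series()].
#' @return mean velocity in cm/s.
#' @export
mean_velocity <- function(cop) {
  stopifnot(inherits(cop, "cop_series"))
  path <- sum(sqrt(diff(cop$cop_x)^2 + diff(cop$cop_y)^2))
  path / ((length(cop$cop_x) - 1) / cop$sample_rate)
}

#' Welch power spectral density estimate
#'
#' Mean-removed series split into Hann-tapered segments with 50% overlap;
#' one-sided periodograms averaged across segments. Returned as a list
#' with `freq` (Hz) and `power` (arbitrary density units).
#'
#' @param x numeric series.
#' @param sample_rate sampling frequency (Hz).
#' @param window_sec segment length in seconds (default 5).
#' @param overlap fractional overlap between segments (default 0.5).
#' @export
welch_psd <- function(x, sample_rate, window_sec = 5, overlap = 0.5) {
  n <- length(x)
  L <- round(window_sec * sample_rate)
  if (n < L) stopf("need at least one full %g s window (%d samples), got %d",
                   window_sec, L, n)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1)) # Hann
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  scale <- sum(w^2) * sample_rate
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    P <- Mod(stats::fft(seg))^2 / scale
    half <- P[seq_len(nf)]
    # double the interior bins to fold negative frequencies into one side
    if (L %% 2 == 0) half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    else half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1L) * sample_rate / L,
       power = acc / length(starts))
}

.median_freq_1d <- function(x, sample_rate, window_sec, overlap) {
  psd <- welch_psd(x, sample_rate, window_sec, overlap)
  tot <- sum(psd$power)
  if (tot <= 0) return(NA_real_)
  cum <- cumsum(psd$power)
  target <- tot / 2
  i <- which(cum >= target)[1]
  if (i == 1L) return(psd$freq[1L])
  prev <- cum[i - 1L]
  frac <- (target - prev) / (cum[i] - prev)
  psd$freq[i - 1L] + frac * (psd$freq[i] - psd$freq[i - 1L])
}

#' Median frequency of a CoP trajectory
#'
#' Frequency splitting the Welch power spectrum into equal-power halves
#' (linear interpolation between bins), computed per axis on the
#' mean-removed series and averaged across the two axes.
#'
#' @param cop a [cop_series()].
#' @param window_sec Welch segment length (s), default 5.
#' @param overlap segment overlap fraction, default 0.5.
#' @return median frequency in Hz (0, with a warning, for a constant series).
#' @export
median_frequency <- function(cop, window_sec = 5, overlap = 0.5) {
  stopifnot(inherits(cop, "cop_series"))
  fx <- .median_freq_1d(cop$cop_x, cop$sample_rate, window_sec, overlap)
  fy <- .median_freq_1d(cop$cop_y, cop$sample_rate, window_sec, overlap)
  if (is.na(fx) && is.na(fy)) {
    warnf("zero total power on both axes; median frequency reported as 0")
    return(0)
  }
  mean(c(fx, fy), na.rm = TRUE)
}

#' Average the three sway metrics over a condition's trials
#'
#' Each metric is computed per trial, then arithmetically averaged over the
#' (1–3) available trials. Fewer than 3 trials triggers a warning but still
#' returns the mean of what is available.
#'
#' @param cops list of [cop_series()] belonging to one participant-condition.
#' @param n_expected expected number of trials (default 3).
#' @param ... passed to [median_frequency()].
#' @return a list with elements `area` (cm^2), `mean_velocity` (cm/s) and
#'   `median_frequency` (Hz).
#' @export
condition_features <- function(cops, n_expected = 3L, ...) {
  if (length(cops) == 0) stopf("no trials supplied for this condition")
  if (length(cops) < n_expected) {
    warnf("only %d of %d trials available; averaging what is present",
          length(cops), n_expected)
  }
  list(
    area = mean(vapply(cops, ellipse_area, numeric(1))),
    mean_velocity = mean(vapply(cops, mean_velocity, numeric(1))),
    median_frequency = mean(vapply(cops, median_frequency, numeric(1), ...))
  )
}

#' Sway features for every participant-condition in a cohort
#'
#' Runs [compute_cop()] on every trial and [condition_features()] on every
#' participant-condition cell, returning a long data frame with one row per
#' participant x condition.
#'
#' @param cohort a `cohort_recordings` object.
#' @param ... passed to [compute_cop()] (filter settings, `z_offset`, ...).
#' @return data frame with columns `participant_id`, `surface`, `vision`,
#'   `area`, `mean_velocity`, `median_frequency`.
#' @export
cohort_sway_features <- function(cohort, ...) {
  stopifnot(inherits(cohort, "cohort_recordings"))
  key <- vapply(cohort$trials, function(tr) {
    paste(tr$participant_id, tr$surface, tr$vision, sep = "\r")
  }, character(1))
  groups <- split(cohort$trials, key)
  rows <- lapply(groups, function(trs) {
    cops <- lapply(trs, compute_cop, ...)
    fe <- suppressWarnings(condition_features(cops))
    data.frame(participant_id = trs[[1]]$participant_id,
               surface = trs[[1]]$surface, vision = trs[[1]]$vision,
               area = fe$area, mean_velocity = fe$mean_velocity,
               median_frequency = fe$median_frequency,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
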