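# Synthetic inputs: canonical dynamical systems with known invariants and
# paired pseudo-MEG/EMG beta-band recordings with planted burstiness and a
# controllable shared envelope component.

#' Integrate the Lorenz system
#'
#' Fixed-step fourth-order Runge-Kutta integration of the Lorenz equations
#' (dx/dt = sigma (y - x), dy/dt = x (rho - z) - y, dz/dt = x y - beta z).
#' A transient is discarded before samples are returned, so the trajectory
#' lies on the attractor for the standard chaotic parameters.
#'
#' @param n number of samples to return (after the transient).
#' @param dt integration step in model-time units (> 0).
#' @param sigma,rho,beta Lorenz parameters; the defaults (10, 28, 8/3) give
#'   the classical chaotic attractor with largest Lyapunov exponent
#'   approximately 0.906 per model-time unit.
#' @param x0 initial state (length 3).
#' @param transient number of initial steps to discard (default 1000, i.e.
#'   10 model-time units at dt = 0.01).
#' @return An `n` x 3 matrix of states, sampled every `dt`.
#' @export
lorenz_trajectory <- function(n, dt = 0.01, sigma = 10, rho = 28,
                              beta = 8 / 3, x0 = c(1, 1, 20),
                              transient = 1000L) {
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")
  f <- function(s) c(sigma * (s[2] - s[1]),
                     s[1] * (rho - s[3]) - s[2],
                     s[1] * s[2] - beta * s[3])
  s <- as.double(x0)
  total <- n + transient
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(total)) {
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > transient) out[i - transient, ] <- s
  }
  out
}

#' Lorenz x-coordinate as a signal
#'
#' Scalar observable of the Lorenz system, used as a ground-truth fixture for
#' Lyapunov-exponent and correlation-dimension estimators.  The sampling rate
#' is `1/dt`, so estimator output in 1/s equals model-time-unit rates.
#'
#' @inheritParams lorenz_trajectory
#' @return A [beta_signal] holding the x-coordinate, `fs = 1/dt`.
#' @examples
#' s <- gen_lorenz(2000)
#' max(abs(s$samples)) < 25
#' @export
gen_lorenz <- function(n = 20000, dt = 0.01, sigma = 10, rho = 28,
                       beta = 8 / 3, x0 = c(1, 1, 20), transient = 1000L) {
  traj <- lorenz_trajectory(n, dt, sigma, rho, beta, x0, transient)
  beta_signal(traj[, 1], fs = 1 / dt, kind = "lorenz")
}

#' Largest Lyapunov exponent of the Lorenz flow (Benettin method)
#'
#' Reference value for validating trajectory-based estimators: integrates a
#' tangent vector alongside the flow with the variational equation (both by
#' fixed-step RK4), renormalizing at every step; the exponent is the mean log
#' stretching rate per unit time.  This route is independent of any
#' delay-embedding estimator.
#'
#' @inheritParams lorenz_trajectory
#' @param n_steps number of accumulation steps after the transient.
#' @return Largest Lyapunov exponent in 1/model-time-unit (about 0.906 for
#'   the standard parameters).
#' @export
benettin_lorenz_le <- function(n_steps = 20000, dt = 0.01, sigma = 10,
                               rho = 28, beta = 8 / 3, x0 = c(1, 1, 20),
                               transient = 1000L) {
  f <- function(s) c(sigma * (s[2] - s[1]),
                     s[1] * (rho - s[3]) - s[2],
                     s[1] * s[2] - beta * s[3])
  jac <- function(s) matrix(c(-sigma, sigma, 0,
                              rho - s[3], -1, -s[1],
                              s[2], s[1], -beta), 3, 3, byrow = TRUE)
  step <- function(s, v) {
    k1 <- f(s);              l1 <- jac(s) %*% v
    s2 <- s + dt / 2 * k1
    k2 <- f(s2);             l2 <- jac(s2) %*% (v + dt / 2 * l1)
    s3 <- s + dt / 2 * k2
    k3 <- f(s3);             l3 <- jac(s3) %*% (v + dt / 2 * l2)
    s4 <- s + dt * k3
    k4 <- f(s4);             l4 <- jac(s4) %*% (v + dt * l3)
    list(s = s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4),
         v = v + dt / 6 * (l1 + 2 * l2 + 2 * l3 + l4))
  }
  s <- as.double(x0)
  v <- c(1, 0, 0)
  for (i in seq_len(transient)) {
    st <- step(s, v)
    s <- st$s
    v <- st$v / sqrt(sum(st$v^2))
  }
  acc <- 0
  for (i in seq_len(n_steps)) {
    st <- step(s, v)
    s <- st$s
    nv <- sqrt(sum(st$v^2))
    acc <- acc + log(nv)
    v <- st$v / nv
  }
  acc / (n_steps * dt)
}

#' Fractional Brownian motion by circulant embedding
#'
#' Exact-covariance (Davies-Harte) synthesis of fractional Gaussian noise,
#' cumulatively summed to fractional Brownian motion.  Used as the
#' ground-truth fixture for the Higuchi fractal-dimension estimator, whose
#' theoretical value for fBm is FD = 2 - H.
#'
#' @param n number of samples.
#' @param hurst Hurst exponent H, strictly inside (0, 1).
#' @param fs nominal sampling rate attached to the output signal.
#' @param seed RNG seed.
#' @return A [beta_signal] of length `n` (kind `"fbm"`), unit-variance
#'   increments.
#' @examples
#' b <- gen_fbm(1000, hurst = 0.5, seed = 1)
#' @export
gen_fbm <- function(n, hurst, fs = 1, seed = 1L) {
  if (!is.finite(hurst) || hurst <= 0 || hurst >= 1)
    stop("`hurst` must lie strictly inside (0, 1)")
  # fGn autocovariance
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                abs(k - 1)^(2 * hurst))
  cemb <- c(g, g[n:2])                    # circulant first row, length 2n
  lam <- Re(fft(cemb))
  lam[lam < 0 & lam > -1e-8] <- 0
  if (any(lam < 0))
    stop("circulant embedding not nonnegative definite for this H/n")
  m <- 2L * n
  w <- complex(m)
  z <- with_seed(seed, rnorm(m))
  w[1] <- sqrt(lam[1]) * z[1]
  w[n + 1] <- sqrt(lam[n + 1]) * z[2]
  re <- z[seq(3, by = 2, length.out = n - 1)]
  im <- z[seq(4, by = 2, length.out = n - 1)]
  w[2:n] <- sqrt(lam[2:n] / 2) * complex(real = re, imaginary = im)
  w[m:(n + 2)] <- Conj(w[2:n])
  fgn <- Re(fft(w, inverse = TRUE))[1:n] / sqrt(m)
  beta_signal(cumsum(fgn), fs = fs, kind = "fbm")
}

#' Default AR(2) coefficients with a beta-band resonance
#'
#' Places a complex pole pair at modulus `pole_mod` and frequency `f0`,
#' giving a stationary Gaussian process with a spectral peak near `f0` --
#' a linear null signal for surrogate type-I-error testing.
#'
#' @param f0 resonance frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param pole_mod pole modulus in (0, 1); closer to 1 = sharper resonance.
#' @return Numeric vector `c(phi1, phi2)`.
#' @export
ar2_beta_coefs <- function(f0 = 20, fs = 1000, pole_mod = 0.98) {
  th <- 2 * pi * f0 / fs
  c(2 * pole_mod * cos(th), -pole_mod^2)
}

#' Stationary Gaussian AR process
#'
#' @param n number of samples.
#' @param ar AR coefficients (default [ar2_beta_coefs()]: AR(2) resonant
#'   near 20 Hz at fs = 1000).  An empty/zero vector gives white noise.
#' @param fs sampling rate attached to the output.
#' @param sd innovation standard deviation.
#' @param seed RNG seed.
#' @return A [beta_signal] (kind `"ar_linear"`).
#' @export
gen_ar_linear <- function(n, ar = ar2_beta_coefs(), fs = 1000, sd = 1,
                          seed = 1L) {
  ar <- as.double(ar)
  if (length(ar) > 0 && any(ar != 0)) {
    roots <- polyroot(c(1, -ar))
    if (any(Mod(roots) <= 1 + 1e-12))
      stop("unstable AR coefficients: characteristic roots inside unit circle")
    x <- with_seed(seed, as.double(arima.sim(list(ar = ar), n = n, sd = sd)))
  } else {
    x <- with_seed(seed, rnorm(n, sd = sd))
  }
  beta_signal(x, fs = fs, kind = "ar_linear")
}

#' Pure sinusoid
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param freq frequency in Hz.
#' @param amp amplitude.
#' @param phase initial phase in radians.
#' @return A [beta_signal] (kind `"sine"`).
#' @export
gen_sine <- function(n, fs = 1000, freq = 20, amp = 1, phase = 0) {
  t <- (seq_len(n) - 1) / fs
  beta_signal(amp * sin(2 * pi * freq * t + phase), fs = fs, kind = "sine")
}

#' Gaussian white noise
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param sd standard deviation.
#' @param seed RNG seed.
#' @return A [beta_signal] (kind `"white_noise"`).
#' @export
gen_white_noise <- function(n, fs = 1000, sd = 1, seed = 1L) {
  beta_signal(with_seed(seed, rnorm(n, sd = sd)), fs = fs,
              kind = "white_noise")
}

# Shot-noise burst envelope: 1 + sum_i a_i * gauss(t - t_i; fwhm), with burst
# times homogeneous Poisson and amplitudes Gamma(shape 2, scale amp_scale).
burst_envelope <- function(n, fs, burst_rate, burst_fwhm, burst_amp_scale,
                           seed) {
  env <- rep(1, n)
  if (burst_amp_scale <= 0 || burst_rate <= 0) return(env)
  dur <- n / fs
  with_seed(seed, {
    n_bursts <- rpois(1, burst_rate * dur)
    if (n_bursts > 0) {
      t_burst <- runif(n_bursts, 0, dur)
      amps <- rgamma(n_bursts, shape = 2, scale = burst_amp_scale)
      s <- burst_fwhm / (2 * sqrt(2 * log(2)))
      half <- ceiling(4 * s * fs)
      for (b in seq_len(n_bursts)) {
        c0 <- round(t_burst[b] * fs)
        lo <- max(1L, c0 - half)
        hi <- min(n, c0 + half)
        if (lo > hi) next
        tt <- (lo:hi - 1) / fs - t_burst[b]
        env[lo:hi] <- env[lo:hi] + amps[b] * exp(-tt^2 / (2 * s^2))
      }
    }
  })
  env
}

#' Paired pseudo-MEG/EMG beta-band recordings
#'
#' Emulates two simultaneously recorded beta-band channels whose amplitude
#' envelopes share a controllable common component.  Each channel is an
#' independent Gaussian-noise carrier band-passed to 13-30 Hz (unit
#' variance), multiplied by an envelope
#' `e_ch = (1 - shared_fraction) * e_indep_ch + shared_fraction * e_shared`,
#' where each `e` is `1 + sum_i a_i gauss(t - t_i; fwhm)` with Poisson burst
#' times and Gamma(2, burst_amp_scale) amplitudes, plus additive white noise.
#' With `burst_amp_scale = 0` the channels reduce to unmodulated narrowband
#' Gaussian noise, whose normalized-envelope coefficient of variation is the
#' Rayleigh value sqrt(4/pi - 1) = 0.523.
#'
#' @param fs sampling rate in Hz (default 1000).
#' @param duration recording length in seconds (default 600, i.e. two 5 min
#'   task blocks).
#' @param seed master seed; channels draw from derived child streams.
#' @param burst_rate expected bursts per second.
#' @param burst_fwhm burst full width at half maximum, seconds.
#' @param burst_amp_scale Gamma scale of burst amplitudes (0 = no bursts).
#' @param shared_fraction mixing weight of the shared envelope, in [0, 1].
#' @param noise_sd standard deviation of additive broadband noise.
#' @param subject_id identifier attached to both channels.
#' @return A list with elements `meg` and `emg`, both [beta_signal]s
#'   (kind `"bursty_beta"`).
#' @examples
#' pair <- gen_bursty_beta(duration = 30, seed = 7)
#' @export
gen_bursty_beta <- function(fs = 1000, duration = 600, seed = 1L,
                            burst_rate = 1, burst_fwhm = 0.15,
                            burst_amp_scale = 1.5, shared_fraction = 0.3,
                            noise_sd = 0.05, subject_id = NA_character_) {
  if (!is.finite(shared_fraction) || shared_fraction < 0 ||
      shared_fraction > 1)
    stop("`shared_fraction` must lie in [0, 1]")
  n <- round(fs * duration)
  e_sh <- burst_envelope(n, fs, burst_rate, burst_fwhm, burst_amp_scale,
                         child_seed(seed, 1))
  chan <- function(ich, modality) {
    e_ind <- burst_envelope(n, fs, burst_rate, burst_fwhm, burst_amp_scale,
                            child_seed(seed, 2, ich))
    e <- (1 - shared_fraction) * e_ind + shared_fraction * e_sh
    carrier <- with_seed(child_seed(seed, 3, ich), rnorm(n))
    carrier <- fft_cosine_filter(carrier, fs, lo = 13, hi = 30,
                                 transition = 2)
    carrier <- carrier / sd(carrier)
    x <- e * carrier
    if (noise_sd > 0)
      x <- x + noise_sd * with_seed(child_seed(seed, 4, ich), rnorm(n))
    beta_signal(x, fs = fs, subject_id = subject_id, modality = modality,
                kind = "bursty_beta")
  }
  list(meg = chan(1L, "MEG"), emg = chan(2L, "EMG"))
}
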