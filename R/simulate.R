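#' Raised-cosine sensor activation pulse
#'
#' Unit-normalized activation weight of a sensor as a function of the
#' stance fraction `t`: zero outside `[onset, offset]`, a smooth raised
#' cosine `0.5 * (1 - cos(2*pi*(t - onset)/(offset - onset)))` inside,
#' peaking at 1 at the interval midpoint. The simplest smooth pulse that
#' reproduces the sequential heel-to-toe activation seen on real insoles.
#'
#' @param onset,offset activation interval as stance fractions,
#'   `0 <= onset < offset <= 1`.
#' @param t stance fraction(s) at which to evaluate; vectorized.
#' @return activation weight(s) in `[0, 1]`.
#' @export
activation_profile <- function(onset, offset, t) {
  if (!(onset >= 0 && onset < offset && offset <= 1)) {
    stop("need 0 <= onset < offset <= 1")
  }
  w <- 0.5 * (1 - cos(2 * pi * (t - onset) / (offset - onset)))
  w[t < onset | t > offset] <- 0
  w
}

#' Simulation configuration for synthetic gait recordings
#'
#' Defaults emulate comfortable self-selected walking on a 16-sensor
#' insole sampled at 100 Hz: 0.6 s stance / 0.4 s swing alternation,
#' sequential zone activation from rearfoot through toes, peak total
#' force calibrated to body weight, small Gaussian sensor noise and
#' independent per-sample dropout. The `anomaly` modes inject one
#' non-physiological step (by default the middle one) that a correct
#' segmentation must reject: `"shuffle"` pins the CoP in the posterior
#' third (rearfoot-only loading), `"short_contact"` shortens ground
#' contact to 150 ms, `"low_force"` scales pressures so the total force
#' never reaches the 15 N detection threshold.
#'
#' @param n_steps number of simulated steps.
#' @param sample_rate sampling rate in Hz (default 100).
#' @param stance_duration,swing_duration phase durations in s.
#' @param body_weight peak vertical force target in N.
#' @param zone_onset_offset named list of `c(onset, offset)` stance
#'   fractions for zones rearfoot, midfoot, forefoot, toes.
#' @param peak_pressure_scale named per-zone relative pressure amplitudes;
#'   the absolute scale is set by calibrating the noise-free peak total
#'   force to `body_weight`.
#' @param noise_sd additive Gaussian noise s.d. in N cm^-2, applied to
#'   loaded samples and clipped at zero.
#' @param missing_prob independent per-sample dropout probability.
#' @param seed RNG seed; identical configs give bit-identical recordings.
#' @param anomaly one of "none", "shuffle", "short_contact", "low_force".
#' @param anomaly_step 1-based index of the anomalous step (default: the
#'   middle step).
#' @return an object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_steps = 10,
                            sample_rate = 100,
                            stance_duration = 0.6,
                            swing_duration = 0.4,
                            body_weight = 700,
                            zone_onset_offset = list(
                              rearfoot = c(0.00, 0.45),
                              midfoot  = c(0.15, 0.65),
                              forefoot = c(0.35, 0.90),
                              toes     = c(0.55, 1.00)),
                            peak_pressure_scale = c(
                              rearfoot = 1.4, midfoot = 0.9,
                              forefoot = 1.2, toes = 0.8),
                            noise_sd = 0.3,
                            missing_prob = 0.01,
                            seed = 1,
                            anomaly = c("none", "shuffle", "short_contact",
                                        "low_force"),
                            anomaly_step = NULL) {
  anomaly <- match.arg(anomaly)
  zones <- c("rearfoot", "midfoot", "forefoot", "toes")
  stopifnot(n_steps >= 0, sample_rate > 0,
            stance_duration > 0, swing_duration > 0, body_weight > 0,
            noise_sd >= 0, missing_prob >= 0, missing_prob < 1,
            all(zones %in% names(zone_onset_offset)),
            all(zones %in% names(peak_pressure_scale)))
  for (z in zones) {
    oo <- zone_onset_offset[[z]]
    if (!(length(oo) == 2 && oo[1] >= 0 && oo[1] < oo[2] && oo[2] <= 1)) {
      stop("zone_onset_offset$", z, " must satisfy 0 <= onset < offset <= 1")
    }
  }
  if (zone_onset_offset$rearfoot[1] >= zone_onset_offset$toes[1]) {
    stop("heel must strike first: rearfoot onset < toes onset")
  }
  if (anomaly != "none") {
    if (n_steps < 1) stop("anomaly injection needs n_steps >= 1")
    if (is.null(anomaly_step)) anomaly_step <- ceiling(n_steps / 2)
    stopifnot(anomaly_step >= 1, anomaly_step <= n_steps)
  }
  structure(
    list(n_steps = as.integer(n_steps), sample_rate = sample_rate,
         stance_duration = stance_duration, swing_duration = swing_duration,
         body_weight = body_weight, zone_onset_offset = zone_onset_offset,
         peak_pressure_scale = peak_pressure_scale, noise_sd = noise_sd,
         missing_prob = missing_prob, seed = as.integer(seed),
         anomaly = anomaly, anomaly_step = anomaly_step),
    class = "gait_sim_config"
  )
}

# Evaluate RNG-dependent code under a fixed seed, restoring the caller's
# RNG state afterwards so simulation never perturbs the session.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a multichannel plantar-pressure recording
#'
#' Generates a seeded walking recording on the given layout: an initial
#' swing phase, then `n_steps` stance/swing alternations. Each stance
#' loads the four anatomical zones with raised-cosine pulses in
#' heel-to-toe order (small per-sensor onset jitter and amplitude
#' variation), with the noise-free peak total force calibrated to
#' `body_weight`. Gaussian noise (clipped at zero) is added to loaded
#' samples and samples drop out independently with `missing_prob`
#' (encoded `NA`). With `anomaly = "none"` every simulated stance
#' satisfies both physiological segmentation criteria (force > 15 N for
#' at least 200 ms; posterior-to-anterior CoP roll-over).
#'
#' @param config a `gait_sim_config`.
#' @param layout the `insole_layout` to simulate on.
#' @return a `pressure_recording`.
#' @export
simulate_recording <- function(config, layout) {
  stopifnot(inherits(config, "gait_sim_config"),
            inherits(layout, "insole_layout"))
  validate_standard_layout(layout)
  fs <- config$sample_rate
  ns <- max(2L, round(config$stance_duration * fs))
  nw <- max(1L, round(config$swing_duration * fs))
  n  <- config$n_steps
  total <- nw + n * (ns + nw)
  zone <- layout$sensors$zone
  area <- layout$sensors$area

  # calibrate absolute pressure scale so the noise-free peak total force
  # matches body weight
  tg <- seq(0, 1, length.out = 201)
  f0 <- rep(0, length(tg))
  for (z in names(config$zone_onset_offset)) {
    oo <- config$zone_onset_offset[[z]]
    f0 <- f0 + config$peak_pressure_scale[[z]] *
      activation_profile(oo[1], oo[2], tg) * sum(area[zone == z])
  }
  pressure_unit <- config$body_weight / max(f0)

  with_seed(config$seed, {
    onset  <- vapply(zone, function(z) config$zone_onset_offset[[z]][1], 0)
    offset <- vapply(zone, function(z) config$zone_onset_offset[[z]][2], 0)
    # within each zone, posterior sensors load first (progressive
    # anterior roll of the contact area, as on real insoles)
    sx <- layout$sensors$x
    for (z in unique(zone)) {
      in_z <- zone == z
      span <- diff(range(sx[in_z]))
      if (span > 0) {
        onset[in_z] <- onset[in_z] +
          0.06 * (sx[in_z] - min(sx[in_z])) / span
      }
    }
    jit_on  <- stats::runif(16, -0.02, 0.02)
    jit_off <- stats::runif(16, -0.02, 0.02)
    onset  <- pmax(0, pmin(onset + jit_on, 0.9))
    offset <- pmax(onset + 0.05, pmin(offset + jit_off, 1))
    amp <- pressure_unit *
      vapply(zone, function(z) config$peak_pressure_scale[[z]], 0) *
      stats::runif(16, 0.9, 1.1)

    P <- matrix(0, nrow = total, ncol = 16)
    for (s in seq_len(n)) {
      start <- nw + (s - 1L) * (ns + nw)
      ks <- ns
      scale <- 1
      mode <- if (config$anomaly != "none" && s == config$anomaly_step)
        config$anomaly else "none"
      if (mode == "short_contact") ks <- max(2L, round(0.15 * fs))
      if (mode == "low_force") scale <- 10 / config$body_weight
      tt <- (seq_len(ks) - 1) / (ks - 1)
      step <- t(vapply(seq_len(16), function(i) {
        amp[i] * scale * activation_profile(onset[i], offset[i], tt)
      }, numeric(ks)))
      if (mode == "shuffle") step[zone != "rearfoot", ] <- 0
      P[start + seq_len(ks), ] <- t(step)
    }
    if (config$noise_sd > 0) {
      loaded <- P > 0
      P[loaded] <- pmax(0, P[loaded] +
                          stats::rnorm(sum(loaded), 0, config$noise_sd))
    }
    if (config$missing_prob > 0) {
      P[stats::runif(length(P)) < config$missing_prob] <- NA
    }
    pressure_recording(P, sample_rate = fs, side = layout$side)
  })
}
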