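# Synthetic-movie simulator: scattered soma-like disks on a dim background,
# per-cell calcium transients with fast rise and slower exponential decay,
# asynchronous or network-burst firing, shot + read noise. Every simulated
# movie carries its ground truth so downstream stages can be scored.

#' Transient kinetics for the double-exponential calcium kernel
#'
#' Each firing event contributes
#' `A * (1 - exp(-(t - t0)/rise_tau)) * exp(-(t - t0)/decay_tau)`,
#' rescaled so its peak equals `A`. Defaults are on the scale of a fast
#' genetically encoded indicator (GCaMP6f-like): ~0.1 s rise, ~0.7 s decay.
#'
#' @param rise_tau rise time constant, seconds (0 < rise_tau < decay_tau).
#' @param decay_tau decay time constant, seconds.
#' @param amplitude_mean mean event amplitude, dF units (> 0).
#' @param amplitude_cv coefficient of variation of event amplitudes
#'   (fraction >= 0; 0 means every event has amplitude `amplitude_mean`).
#' @return a `transient_kinetics` list.
#' @export
transient_kinetics <- function(rise_tau = 0.1, decay_tau = 0.7,
                               amplitude_mean = 1, amplitude_cv = 0.2) {
  stopifnot(rise_tau > 0, decay_tau > rise_tau, amplitude_mean > 0,
            amplitude_cv >= 0)
  structure(list(rise_tau = rise_tau, decay_tau = decay_tau,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv),
            class = "transient_kinetics")
}

#' Acquisition noise model
#'
#' @param baseline_intensity background photon level in camera counts (> 0);
#'   cell brightness is expressed relative to this baseline.
#' @param shot_noise if `TRUE`, every pixel value is Poisson-resampled.
#' @param gaussian_sd read-noise standard deviation, counts (>= 0).
#' @param background_gradient fractional left-to-right illumination ramp
#'   (0 = flat field).
#' @return a `noise_model` list.
#' @export
noise_model <- function(baseline_intensity = 1000, shot_noise = TRUE,
                        gaussian_sd = 10, background_gradient = 0.1) {
  stopifnot(baseline_intensity > 0, gaussian_sd >= 0)
  structure(list(baseline_intensity = baseline_intensity,
                 shot_noise = isTRUE(shot_noise),
                 gaussian_sd = gaussian_sd,
                 background_gradient = background_gradient),
            class = "noise_model")
}

#' Simulation configuration
#'
#' Defaults follow the acquisition regime the pipeline targets: 250 frames
#' at 5 Hz over a field of scattered somata imaged at low magnification.
#'
#' @param n_cells number of cells (>= 1).
#' @param field_size `(H, W)` in pixels.
#' @param frame_rate Hz (> 0); default 5.
#' @param n_frames frames per acquisition; default 250.
#' @param cell_radius_range `(min, max)` soma radius in pixels (>= 2).
#' @param event_rate per-cell firing rate, Hz. In `network_bursts` mode this
#'   is the independent background rate added on top of shared bursts.
#' @param sync_mode `"asynchronous"`, `"network_bursts"`, or `"mixed"`
#'   (half the cells follow bursts, half fire independently).
#' @param burst_rate network burst rate, Hz (network modes).
#' @param participation probability that a cell joins any given network
#'   burst (0-1).
#' @param kinetics a [transient_kinetics()].
#' @param noise a [noise_model()].
#' @param amplitude_scale global multiplier applied to event amplitudes.
#' @param clustered if `TRUE`, cells are placed as close pairs
#'   (centre-to-centre 1.2 x radius) to exercise watershed splitting;
#'   otherwise a minimum spacing of 2.5 x radius is enforced by rejection
#'   sampling.
#' @param seed integer root seed; every stochastic stage derives its
#'   sub-streams from it, so a config is fully reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 30, field_size = c(160, 160), frame_rate = 5,
                       n_frames = 250, cell_radius_range = c(4, 6),
                       event_rate = 0.05, sync_mode = "asynchronous",
                       burst_rate = 0.05, participation = 0.9,
                       kinetics = transient_kinetics(),
                       noise = noise_model(), amplitude_scale = 1,
                       clustered = FALSE, seed = 1L) {
  sync_mode <- match.arg(sync_mode, c("asynchronous", "network_bursts", "mixed"))
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  if (frame_rate <= 0) stop("'frame_rate' must be > 0")
  if (event_rate < 0 || burst_rate < 0)
    stop("event and burst rates must be non-negative")
  if (participation < 0 || participation > 1)
    stop("'participation' must lie in [0, 1]")
  if (min(cell_radius_range) < 2) stop("cell radii must be >= 2 px")
  stopifnot(inherits(kinetics, "transient_kinetics"),
            inherits(noise, "noise_model"), length(field_size) == 2L)
  structure(list(n_cells = as.integer(n_cells),
                 field_size = as.integer(field_size),
                 frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 cell_radius_range = cell_radius_range,
                 event_rate = event_rate, sync_mode = sync_mode,
                 burst_rate = burst_rate, participation = participation,
                 kinetics = kinetics, noise = noise,
                 amplitude_scale = amplitude_scale,
                 clustered = isTRUE(clustered), seed = as.integer(seed)),
            class = "sim_config")
}

# one deterministic sub-seed per named stream, derived from the root seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate firing-event times
#'
#' Asynchronous mode draws an independent homogeneous Poisson train per cell
#' at `event_rate`. Network-burst mode draws shared burst times as a Poisson
#' process at `burst_rate`; each cell joins each burst with probability
#' `participation` and additionally fires independent background events at
#' `event_rate`. Mixed mode applies the burst rule to the first half of the
#' cells and the asynchronous rule to the rest.
#'
#' @param config a [sim_config()].
#' @return list with `event_times` (list of sorted numeric vectors, seconds,
#'   one per cell) and `burst_times` (numeric vector; empty in asynchronous
#'   mode).
#' @export
simulate_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  duration <- config$n_frames / config$frame_rate
  seeds <- derive_seeds(config$seed, config$n_cells + 1L)
  burst_times <- numeric(0)
  if (config$sync_mode %in% c("network_bursts", "mixed")) {
    burst_times <- with_seed(seeds[config$n_cells + 1L], {
      n <- stats::rpois(1, config$burst_rate * duration)
      sort(stats::runif(n, 0, duration))
    })
  }
  bursty <- switch(config$sync_mode,
    asynchronous   = rep(FALSE, config$n_cells),
    network_bursts = rep(TRUE, config$n_cells),
    mixed          = seq_len(config$n_cells) <= ceiling(config$n_cells / 2))
  event_times <- lapply(seq_len(config$n_cells), function(k) {
    with_seed(seeds[k], {
      n_bg <- stats::rpois(1, config$event_rate * duration)
      ev <- stats::runif(n_bg, 0, duration)
      if (bursty[k] && length(burst_times)) {
        join <- stats::runif(length(burst_times)) < config$participation
        ev <- c(ev, burst_times[join])
      }
      sort(ev)
    })
  })
  list(event_times = event_times, burst_times = burst_times)
}

# peak-normalized double-exponential kernel evaluated at times >= 0
transient_kernel <- function(t, rise_tau, decay_tau) {
  t_peak <- rise_tau * log1p(decay_tau / rise_tau)
  peak <- (1 - exp(-t_peak / rise_tau)) * exp(-t_peak / decay_tau)
  ifelse(t < 0, 0, (1 - exp(-t / rise_tau)) * exp(-t / decay_tau) / peak)
}

#' Render noise-free dF traces from event times
#'
#' Each event adds a peak-normalized double-exponential transient; events
#' sum linearly. Events live in continuous time and the trace is sampled at
#' frame midtimes `(t - 1) / frame_rate`.
#'
#' @param event_times list of numeric vectors (seconds), one per cell.
#' @param kinetics a [transient_kinetics()].
#' @param frame_rate Hz.
#' @param n_frames number of samples.
#' @param amplitudes optional list matching `event_times` giving per-event
#'   amplitudes; defaults to `amplitude_mean` for every event (the
#'   `amplitude_cv = 0` case).
#' @return numeric matrix, cells x frames, all values >= 0.
#' @export
render_traces <- function(event_times, kinetics, frame_rate, n_frames,
                          amplitudes = NULL) {
  stopifnot(inherits(kinetics, "transient_kinetics"), frame_rate > 0,
            n_frames >= 1)
  tt <- (seq_len(n_frames) - 1) / frame_rate
  out <- matrix(0, nrow = length(event_times), ncol = n_frames)
  for (k in seq_along(event_times)) {
    ev <- event_times[[k]]
    if (!length(ev)) next
    amp <- if (is.null(amplitudes)) rep(kinetics$amplitude_mean, length(ev))
           else amplitudes[[k]]
    tr <- numeric(n_frames)
    for (j in seq_along(ev)) {
      tr <- tr + amp[j] * transient_kernel(tt - ev[j], kinetics$rise_tau,
                                           kinetics$decay_tau)
    }
    out[k, ] <- tr
  }
  out
}

# draw per-event amplitudes (truncated-at-zero normal with given CV)
draw_amplitudes <- function(event_times, kinetics, amplitude_scale, seed) {
  seeds <- derive_seeds(seed + 1L, max(1L, length(event_times)))
  lapply(seq_along(event_times), function(k) {
    n <- length(event_times[[k]])
    if (!n) return(numeric(0))
    mu <- kinetics$amplitude_mean * amplitude_scale
    if (kinetics$amplitude_cv == 0) return(rep(mu, n))
    with_seed(seeds[k],
              pmax(0.05 * mu, stats::rnorm(n, mu, kinetics$amplitude_cv * mu)))
  })
}

# place cell centres by rejection sampling with a minimum spacing of
# 2.5 x radius, or as tight pairs at 1.2 x radius when clustered
place_cells <- function(config) {
  H <- config$field_size[1]; W <- config$field_size[2]
  rr <- config$cell_radius_range
  seeds <- derive_seeds(config$seed + 2L, 2L)
  with_seed(seeds[1], {
    radii <- stats::runif(config$n_cells, rr[1], rr[2])
    margin <- max(radii) + 2
    centers <- matrix(NA_real_, config$n_cells, 2)
    if (config$clustered) {
      k <- 1L
      tries <- 0L
      while (k <= config$n_cells && tries < 20000L) {
        tries <- tries + 1L
        c1 <- c(stats::runif(1, margin, H - 1 - margin),
                stats::runif(1, margin, W - 1 - margin))
        ang <- stats::runif(1, 0, 2 * pi)
        c2 <- c1 + 1.2 * radii[k] * c(sin(ang), cos(ang))
        cand <- rbind(c1, if (k + 1L <= config$n_cells) c2)
        prev <- centers[seq_len(k - 1L), , drop = FALSE]
        ok <- all(cand[, 1] >= margin & cand[, 1] <= H - 1 - margin &
                  cand[, 2] >= margin & cand[, 2] <= W - 1 - margin)
        if (ok && nrow(prev)) {
          d <- sqrt(outer(cand[, 1], prev[, 1], "-")^2 +
                    outer(cand[, 2], prev[, 2], "-")^2)
          ok <- all(d >= 2.5 * max(radii))
        }
        if (ok) {
          centers[k, ] <- cand[1, ]
          if (nrow(cand) > 1L) centers[k + 1L, ] <- cand[2, ]
          k <- k + nrow(cand)
        }
      }
      if (k <= config$n_cells) stop("could not place clustered cells; field too small")
    } else {
      for (k in seq_len(config$n_cells)) {
        placed <- FALSE
        for (try in seq_len(20000L)) {
          cand <- c(stats::runif(1, margin, H - 1 - margin),
                    stats::runif(1, margin, W - 1 - margin))
          prev <- centers[seq_len(k - 1L), , drop = FALSE]
          if (!nrow(prev) ||
              all(sqrt((cand[1] - prev[, 1])^2 + (cand[2] - prev[, 2])^2) >=
                  2.5 * max(radii))) {
            centers[k, ] <- cand; placed <- TRUE; break
          }
        }
        if (!placed) stop("could not place cells; field too small for n_cells")
      }
    }
    list(centers = centers, radii = radii)
  })
}

#' Render a 16-bit movie from ground truth
#'
#' Pixel model per frame:
#' `baseline * (1 + gradient) * (1 + sum_cells disk_weight * dF_cell(t))`
#' restructured as background plus per-cell disk contributions scaled by the
#' baseline, then optional Poisson (shot) resampling, additive Gaussian read
#' noise, and clipping to the 16-bit range. Cell profiles are flat disks
#' with a 1-px cosine roll-off at the rim.
#'
#' @param truth ground-truth list with `cell_centers` (cells x 2, 0-based
#'   row/col), `cell_radii`, and `true_traces` (cells x frames dF matrix).
#' @param noise a [noise_model()].
#' @param field_size `(H, W)` pixels.
#' @param frame_rate Hz.
#' @param seed integer seed for the noise draws.
#' @return a [cal_movie()] of integer counts in `[0, 65535]`.
#' @export
render_movie <- function(truth, noise, field_size, frame_rate, seed = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  H <- field_size[1]; W <- field_size[2]
  centers <- truth$cell_centers; radii <- truth$cell_radii
  if (any(centers[, 1] < 0 | centers[, 1] > H - 1 |
          centers[, 2] < 0 | centers[, 2] > W - 1))
    stop("cell center outside field")
  n_frames <- ncol(truth$true_traces)
  base <- noise$baseline_intensity
  grad <- 1 + noise$background_gradient *
    ((seq_len(W) - 1) / max(1, W - 1) - 0.5)
  background <- matrix(base, H, W) * matrix(grad, H, W, byrow = TRUE)

  # per-cell disk footprint: indices + weights, computed once
  disks <- lapply(seq_len(nrow(centers)), function(k) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]; R <- radii[k]
    rows <- max(0, floor(r0 - R - 2)):min(H - 1, ceiling(r0 + R + 2))
    cols <- max(0, floor(c0 - R - 2)):min(W - 1, ceiling(c0 + R + 2))
    g <- expand.grid(row = rows, col = cols)
    d <- sqrt((g$row - r0)^2 + (g$col - c0)^2)
    w <- ifelse(d <= R - 1, 1,
                ifelse(d >= R, 0, 0.5 * (1 + cos(pi * (d - (R - 1))))))
    keep <- w > 0
    list(idx = g$row[keep] + 1L + (g$col[keep]) * H, w = w[keep])
  })

  movie <- array(0, dim = c(n_frames, H, W))
  frame <- background
  for (t in seq_len(n_frames)) {
    fr <- background
    for (k in seq_along(disks)) {
      dff <- truth$true_traces[k, t]
      if (dff != 0) fr[disks[[k]]$idx] <- fr[disks[[k]]$idx] +
          disks[[k]]$w * base * dff
    }
    movie[t, , ] <- fr
  }
  if (noise$shot_noise || noise$gaussian_sd > 0) {
    movie <- with_seed(seed, {
      v <- as.numeric(movie)
      if (noise$shot_noise) v <- stats::rpois(length(v), v)
      if (noise$gaussian_sd > 0)
        v <- v + stats::rnorm(length(v), 0, noise$gaussian_sd)
      array(v, dim = dim(movie))
    })
  }
  movie[] <- round_half_away(pmin(65535, pmax(0, movie)))
  cal_movie(movie, frame_rate)
}

#' Simulate a complete ground-truthed acquisition
#'
#' Runs [simulate_events()], draws event amplitudes, renders noise-free
#' truth traces with [render_traces()], places cells, and renders the movie
#' with [render_movie()]. Fully deterministic given `config` (including its
#' seed).
#'
#' @param config a [sim_config()].
#' @param condition_label free-text label stored in the ground truth.
#' @return list with `movie` (a [cal_movie()]) and `truth` (cell centers and
#'   radii, per-cell event times, true dF traces, label).
#' @export
simulate_movie <- function(config, condition_label = config$sync_mode) {
  ev <- simulate_events(config)
  amps <- draw_amplitudes(ev$event_times, config$kinetics,
                          config$amplitude_scale, config$seed)
  traces <- render_traces(ev$event_times, config$kinetics, config$frame_rate,
                          config$n_frames, amplitudes = amps)
  pos <- place_cells(config)
  truth <- list(cell_centers = pos$centers, cell_radii = pos$radii,
                event_times = ev$event_times, burst_times = ev$burst_times,
                true_traces = traces, condition_label = condition_label)
  movie <- render_movie(truth, config$noise, config$field_size,
                        config$frame_rate, seed = config$seed + 3L)
  list(movie = movie, truth = truth)
}

#' Named simulation presets for culture conditions
#'
#' Three configs emulating the qualitative regimes the pipeline is meant to
#' discriminate: `immature_control` — unsynchronized, low-amplitude signals
#' typical of young cultures; `mature_control` — regular network bursts with
#' moderate participation; `cytokine_like` — network bursts with higher
#' amplitude and participation than the immature control (the
#' direction-of-effect of inflammatory-cytokine treatment of young
#' cultures).
#'
#' @param name one of `"immature_control"`, `"mature_control"`,
#'   `"cytokine_like"`.
#' @param seed root seed stored in the config.
#' @param n_cells,field_size passed through to [sim_config()].
#' @return a [sim_config()].
#' @export
condition_preset <- function(name, seed = 1L, n_cells = 30,
                             field_size = c(160, 160)) {
  name <- match.arg(name,
    c("immature_control", "mature_control", "cytokine_like"))
  switch(name,
    immature_control = sim_config(
      n_cells = n_cells, field_size = field_size, sync_mode = "asynchronous",
      event_rate = 0.06,
      kinetics = transient_kinetics(amplitude_mean = 0.4, amplitude_cv = 0.25),
      seed = seed),
    mature_control = sim_config(
      n_cells = n_cells, field_size = field_size, sync_mode = "network_bursts",
      event_rate = 0.01, burst_rate = 0.05, participation = 0.75,
      kinetics = transient_kinetics(amplitude_mean = 1.0, amplitude_cv = 0.25),
      seed = seed),
    cytokine_like = sim_config(
      n_cells = n_cells, field_size = field_size, sync_mode = "network_bursts",
      event_rate = 0.01, burst_rate = 0.05, participation = 0.95,
      kinetics = transient_kinetics(amplitude_mean = 1.5, amplitude_cv = 0.25),
      seed = seed))
}
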