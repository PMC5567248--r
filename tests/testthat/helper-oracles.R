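# Independent brute-force reference implementations used to check the
# package's vectorized/structured code. Deliberately written as plain
# loops, sharing no code with the package internals.

# sliding-median outlier removal, double loop with explicit reflection
oracle_remove_outliers <- function(img, radius, delta) {
  H <- nrow(img); W <- ncol(img)
  reflect <- function(i, n) {
    # reflect index into 1..n (edge handling: mirror without repeating edge
    # beyond one bounce; inputs here never exceed one bounce)
    if (i < 1) return(1 - i)
    if (i > n) return(2 * n + 1 - i)
    i
  }
  out <- img
  for (r in seq_len(H)) for (c in seq_len(W)) {
    vals <- numeric(0)
    for (dr in -radius:radius) for (dc in -radius:radius) {
      vals <- c(vals, img[reflect(r + dr, H), reflect(c + dc, W)])
    }
    m <- median(vals)
    if (img[r, c] - m > delta) out[r, c] <- m
  }
  out
}

# connected-component count by stack-based flood fill
oracle_component_count <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  offs <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  count <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (mask[r0, c0] <= 0 || seen[r0, c0]) next
    count <- count + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(offs))) {
        rr <- p[1] + offs[i, 1]; cc <- p[2] + offs[i, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] > 0 && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  count
}

# binary erosion/dilation with a 3x3 cross, looped
oracle_open_cross <- function(mask, iterations = 1) {
  H <- nrow(mask); W <- ncol(mask)
  get0 <- function(m, r, c) if (r < 1 || r > H || c < 1 || c > W) 0 else m[r, c]
  erode1 <- function(m) {
    out <- m
    for (r in seq_len(H)) for (c in seq_len(W)) {
      out[r, c] <- min(m[r, c], get0(m, r - 1, c), get0(m, r + 1, c),
                       get0(m, r, c - 1), get0(m, r, c + 1))
    }
    out
  }
  dilate1 <- function(m) {
    out <- m
    for (r in seq_len(H)) for (c in seq_len(W)) {
      out[r, c] <- max(m[r, c], get0(m, r - 1, c), get0(m, r + 1, c),
                       get0(m, r, c - 1), get0(m, r, c + 1))
    }
    out
  }
  out <- mask
  for (i in seq_len(iterations)) out <- erode1(out)
  for (i in seq_len(iterations)) out <- dilate1(out)
  out
}

# exhaustive isodata iteration on the raw pixel values (not the histogram
# shortcut): threshold t where t == floor((mean(below) + mean(above)) / 2)
oracle_isodata <- function(values) {
  t <- floor(mean(values))
  for (i in 1:1000) {
    lo <- values[values <= t]; hi <- values[values > t]
    m1 <- if (length(lo)) mean(lo) else t
    m2 <- if (length(hi)) mean(hi) else t
    t_new <- floor((m1 + m2) / 2)
    if (t_new == t) return(t)
    t <- t_new
  }
  t
}

# ---- waveform oracle: plain-loop crossing search --------------------------

oracle_state_levels <- function(trace, n_bins = 100) {
  lo <- min(trace); hi <- max(trace)
  bw <- (hi - lo) / n_bins
  breaks <- lo + (hi - lo) * (0:n_bins) / n_bins
  counts <- rep(0L, n_bins)
  for (x in trace) {
    # left-closed bins (a value on an interior boundary belongs to the bin
    # above it); the maximum goes into the last bin
    b <- n_bins
    for (j in seq_len(n_bins)) if (x < breaks[j + 1]) { b <- j; break }
    counts[b] <- counts[b] + 1L
  }
  centers <- lo + (seq_len(n_bins) - 0.5) * bw
  half <- floor(n_bins / 2)
  best_lo <- 1; for (b in seq_len(half)) if (counts[b] > counts[best_lo]) best_lo <- b
  best_hi <- half + 1
  for (b in (half + 1):n_bins) if (counts[b] > counts[best_hi]) best_hi <- b
  list(low = centers[best_lo], high = centers[best_hi])
}

oracle_crossings <- function(x, t, ref, up) {
  times <- numeric(0)
  for (i in seq_len(length(x) - 1)) {
    if (up && x[i] < ref && x[i + 1] >= ref)
      times <- c(times, t[i] + (ref - x[i]) / (x[i + 1] - x[i]) * (t[i + 1] - t[i]))
    if (!up && x[i] > ref && x[i + 1] <= ref)
      times <- c(times, t[i] + (ref - x[i]) / (x[i + 1] - x[i]) * (t[i + 1] - t[i]))
  }
  times
}

oracle_features <- function(trace, frame_rate, n_bins = 100) {
  na_row <- list(n_pulses = 0, amplitude = NA, pulse_width_s = NA,
                 frequency_hz = NA, rise_time_s = NA, fall_time_s = NA,
                 slew_pos = NA, slew_neg = NA, duty_cycle = NA)
  if (max(trace) == min(trace)) return(na_row)
  sl <- oracle_state_levels(trace, n_bins)
  span <- sl$high - sl$low
  mid <- sl$low + 0.5 * span
  lo_ref <- sl$low + 0.1 * span
  up_ref <- sl$low + 0.9 * span
  tt <- (seq_along(trace) - 1) / frame_rate
  pm <- oracle_crossings(trace, tt, mid, TRUE)
  nm <- oracle_crossings(trace, tt, mid, FALSE)
  pl <- oracle_crossings(trace, tt, lo_ref, TRUE)
  pu <- oracle_crossings(trace, tt, up_ref, TRUE)
  nu <- oracle_crossings(trace, tt, up_ref, FALSE)
  nl <- oracle_crossings(trace, tt, lo_ref, FALSE)
  # pair each rising mid crossing with the next falling one; never reuse a
  # falling crossing
  rises <- numeric(0); falls <- numeric(0)
  last_fall <- -Inf
  for (tp in pm) {
    if (tp <= last_fall) next
    cand <- nm[nm > tp]
    if (!length(cand)) break
    rises <- c(rises, tp); falls <- c(falls, cand[1])
    last_fall <- cand[1]
  }
  n <- length(rises)
  if (!n) return(na_row)
  rt <- ft <- sp <- sn <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- pl[pl <= rises[i]]; b <- pu[pu >= rises[i]]
    if (length(a) && length(b)) {
      rt[i] <- min(b) - max(a)
      sp[i] <- (up_ref - lo_ref) / rt[i]
    }
    a <- nu[nu <= falls[i]]; b <- nl[nl >= falls[i]]
    if (length(a) && length(b)) {
      ft[i] <- min(b) - max(a)
      sn[i] <- -(up_ref - lo_ref) / ft[i]
    }
  }
  mean_na <- function(v) if (all(is.na(v))) NA else mean(v[!is.na(v)])
  widths <- falls - rises
  periods <- if (n >= 2) diff(rises) else numeric(0)
  list(n_pulses = n, amplitude = span,
       pulse_width_s = mean(widths),
       frequency_hz = if (n >= 2) 1 / mean(periods) else NA,
       rise_time_s = mean_na(rt), fall_time_s = mean_na(ft),
       slew_pos = mean_na(sp), slew_neg = mean_na(sn),
       duty_cycle = if (n >= 2) mean(widths) / mean(periods) else NA)
}

# draw a synthetic GCaMP-like test trace (independent of the simulator)
random_burst_trace <- function(n_frames = 400, frame_rate = 5,
                               n_events = 6, amp = 1, rise = 0.2,
                               decay = 1.2) {
  tt <- (seq_len(n_frames) - 1) / frame_rate
  ev <- sort(runif(n_events, 2, max(tt) - 2))
  tr <- numeric(n_frames)
  for (e in ev) {
    s <- tt - e
    k <- ifelse(s < 0, 0, (1 - exp(-s / rise)) * exp(-s / decay))
    tr <- tr + amp * runif(1, 0.7, 1.3) * k / max(k)
  }
  tr
}

# disk mask helper for morphology/watershed tests
disk_mask <- function(H, W, centers, radii) {
  m <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(H)) for (c in seq_len(W)) {
      if ((r - centers[i, 1])^2 + (c - centers[i, 2])^2 <= radii[i]^2)
        m[r, c] <- 1
    }
  }
  m
}
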