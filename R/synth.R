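# Ground-truth generator: synthetic cells, spike-driven calcium traces
# and rendered movies, so every pipeline stage can be benchmarked against
# known truth. Fully deterministic under a fixed seed.

#' Generate non-overlapping synthetic cells
#'
#' Dart-throwing placement of `n_cells` circular somata. `disk` mode
#' emulates nucleus-labeled cells (uniformly filled spots); `ring` mode
#' emulates cytosolic labeling excluded from the nucleus (bright ring,
#' dark interior; the nucleus occupies half the cell radius).
#'
#' @param n_cells number of cells.
#' @param mode `"disk"` or `"ring"`.
#' @param field `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @param radius cell radius, um (default 4).
#' @param min_gap minimal edge-to-edge gap between cells, um (default 2).
#' @param seed RNG seed.
#' @param max_attempts dart throws before giving up.
#' @return A list of class `synth_cells`: `masks` (list of pixel
#'   matrices, pairwise disjoint), `nucleus` (inner pixel sets; `ring`
#'   mode), `centers` (`n x 2`, row/col), `mode`, `field`, `pixel_size`,
#'   `radius`, plus a ready [roi_map()] in `$rois`.
#' @export
make_cells <- function(n_cells, mode = c("disk", "ring"),
                       field = c(128, 128), pixel_size = 1, radius = 4,
                       min_gap = 2, seed = 1L, max_attempts = 20000L) {
  mode <- match.arg(mode)
  set.seed(seed)
  r_px <- radius / pixel_size
  gap_px <- min_gap / pixel_size
  min_d <- 2 * r_px + gap_px
  centers <- matrix(numeric(0), 0, 2)
  att <- 0L
  while (nrow(centers) < n_cells && att < max_attempts) {
    att <- att + 1L
    cand <- c(stats::runif(1, r_px + 1, field[1] - r_px),
              stats::runif(1, r_px + 1, field[2] - r_px))
    if (nrow(centers) == 0L ||
        min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >=
        min_d)
      centers <- rbind(centers, cand)
  }
  if (nrow(centers) < n_cells)
    stop("cell packing failed: placed ", nrow(centers), " of ", n_cells)
  disk_px <- function(cy, cx, r) {
    rr <- max(1L, floor(cy - r)):min(field[1], ceiling(cy + r))
    cc <- max(1L, floor(cx - r)):min(field[2], ceiling(cx + r))
    g <- expand.grid(row = rr, col = cc)
    g <- g[(g$row - cy)^2 + (g$col - cx)^2 <= r^2, , drop = FALSE]
    cbind(row = as.integer(g$row), col = as.integer(g$col))
  }
  masks <- lapply(seq_len(n_cells), function(i)
    disk_px(centers[i, 1], centers[i, 2], r_px))
  nucleus <- if (mode == "ring")
    lapply(seq_len(n_cells), function(i)
      disk_px(centers[i, 1], centers[i, 2], r_px / 2))
  else vector("list", n_cells)
  structure(list(masks = masks, nucleus = nucleus, centers = centers,
                 mode = mode, field = as.integer(field),
                 pixel_size = pixel_size, radius = radius,
                 rois = roi_map(masks, field_dim = field)),
            class = "synth_cells")
}

#' Generate spike-driven ground-truth calcium traces
#'
#' Spikes are the superposition of background Poisson firing, assembly
#' events (each event of an assembly recruits each member independently
#' with `within_prob`) and, optionally, stimulus-locked firing with
#' Gaussian tuning around per-cell preferred values. The noiseless trace
#' is the spike train convolved with an instantaneous-rise,
#' exponential-decay kernel `amplitude * exp(-t / tau_decay)`; the
#' observed trace adds multiplicative slow drift and Gaussian noise:
#' `observed = true_dff * (1 + drift * t) + N(0, noise_sigma)`.
#'
#' @param n_cells number of cells.
#' @param duration recording length, seconds.
#' @param frame_rate Hz.
#' @param tau_decay indicator decay constant, s (default 0.25, GCaMP6f).
#' @param amplitude dF/F0 per spike (scalar or per-cell).
#' @param noise_sigma additive noise SD in dF/F0 units (default 0.05).
#' @param memberships list of planted assembly member index vectors.
#' @param assembly_event_rate assembly activation rate, Hz per assembly.
#' @param within_prob per-member recruitment probability per assembly
#'   event (default 0.3).
#' @param background_rate background firing rate, Hz (scalar or per cell;
#'   per-cell rates allow, e.g., matching member and non-member total
#'   rates when assemblies add event-driven spikes).
#' @param drift relative baseline drift slope, 1/s (default 0).
#' @param events optional [event_timeline()] for stimulus-locked firing.
#' @param preferred_values per-cell preferred variable value (with
#'   `events`).
#' @param tuning_sigma Gaussian tuning width in variable units (with
#'   `events`); `Inf` for untuned cells is allowed per cell.
#' @param response_prob peak per-event spiking probability at the
#'   preferred value (default 1).
#' @param seed RNG seed.
#' @return A list of class `ground_truth`: `spikes` (`n x T` counts),
#'   `spike_times` (list, seconds), `true_dff`, `observed` (`n x T`),
#'   `memberships`, `assembly_frames` (list of activation frames),
#'   `preferred_values`, `params`.
#' @export
make_activity <- function(n_cells, duration, frame_rate, tau_decay = 0.25,
                          amplitude = 1, noise_sigma = 0.05,
                          memberships = list(), assembly_event_rate = 0,
                          within_prob = 0.3, background_rate = 0.05,
                          drift = 0, events = NULL, preferred_values = NULL,
                          tuning_sigma = NULL, response_prob = 1,
                          seed = 1L) {
  stopifnot(assembly_event_rate >= 0, background_rate >= 0)
  set.seed(seed)
  nt <- round(duration * frame_rate)
  amplitude <- rep_len(amplitude, n_cells)
  bg <- rep_len(background_rate, n_cells)
  # column-major fill: lambda of length n_cells recycles per cell
  spikes <- matrix(stats::rpois(n_cells * nt, bg / frame_rate),
                   n_cells, nt)
  assembly_frames <- vector("list", length(memberships))
  if (length(memberships) && assembly_event_rate > 0) {
    for (a in seq_along(memberships)) {
      evf <- which(stats::runif(nt) < assembly_event_rate / frame_rate)
      assembly_frames[[a]] <- evf
      for (f in evf) {
        rec <- memberships[[a]][stats::runif(length(memberships[[a]])) <
                                  within_prob]
        spikes[rec, f] <- spikes[rec, f] + 1L
      }
    }
  }
  if (!is.null(events)) {
    stopifnot(!is.null(preferred_values), !is.null(tuning_sigma))
    ts_ <- rep_len(tuning_sigma, n_cells)
    for (j in seq_len(nrow(events))) {
      f <- round(events$time_s[j] * frame_rate) + 1L
      if (f < 1L || f > nt) next
      p <- response_prob *
        exp(-(events$value[j] - preferred_values)^2 / (2 * ts_^2))
      p[!is.finite(ts_)] <- response_prob
      fire <- stats::runif(n_cells) < p
      spikes[fire, f] <- spikes[fire, f] + 1L
    }
  }
  # kernel convolution: recursive exponential filter (exact for the
  # instantaneous-rise single-exponential kernel sampled at frame times)
  decay <- exp(-1 / (tau_decay * frame_rate))
  true_dff <- matrix(0, n_cells, nt)
  for (i in seq_len(n_cells)) {
    x <- spikes[i, ] * amplitude[i]
    acc <- 0
    for (t in seq_len(nt)) {
      acc <- acc * decay + x[t]
      true_dff[i, t] <- acc
    }
  }
  tsec <- (seq_len(nt) - 1) / frame_rate
  observed <- sweep(true_dff, 2, 1 + drift * tsec, `*`) +
    matrix(stats::rnorm(n_cells * nt, 0, noise_sigma), n_cells, nt)
  spike_times <- lapply(seq_len(n_cells), function(i) {
    f <- which(spikes[i, ] > 0)
    rep((f - 1) / frame_rate, spikes[i, f])
  })
  structure(list(spikes = spikes, spike_times = spike_times,
                 true_dff = true_dff, observed = observed,
                 memberships = memberships,
                 assembly_frames = assembly_frames,
                 preferred_values = preferred_values,
                 params = list(duration = duration, frame_rate = frame_rate,
                               tau_decay = tau_decay, amplitude = amplitude,
                               noise_sigma = noise_sigma,
                               assembly_event_rate = assembly_event_rate,
                               within_prob = within_prob,
                               background_rate = background_rate,
                               drift = drift, seed = seed)),
            class = "ground_truth")
}

#' Render a synthetic fluorescence movie
#'
#' Each frame is `background + sum_i profile_i * (1 + dff_i(t)) +
#' neuropil_field * (1 + 0.3 * neuropil_trace(t))`, rigidly jittered per
#' frame, plus Gaussian pixel noise. The neuropil trace is a standardized
#' low-pass moving average of the population-mean dff (so neuropil signals
#' are strongly mutually correlated and `neuropil_gain` sets the
#' contamination amplitude directly); within cells the neuropil field is
#' scaled by `alpha_inside`, emulating partial-volume contamination
#' `F_measured = F_soma + alpha * F_neuropil`.
#'
#' @param cells a `synth_cells`.
#' @param gt a `ground_truth`; the movie renders the noiseless `true_dff`
#'   and adds its own pixel noise, so trace-level noise is controlled by
#'   `pixel_noise` here rather than by `gt`'s `noise_sigma`.
#' @param frame_rate Hz (for the neuropil low-pass width).
#' @param background background intensity, a.u. (default 0.1).
#' @param cell_level resting cell intensity, a.u. (default 1; ring nuclei
#'   render at 25% of it).
#' @param neuropil_gain amplitude of the shared neuropil signal (default
#'   0; set > 0 to emulate contamination).
#' @param alpha_inside neuropil contamination factor within cell pixels
#'   (default 0.9).
#' @param jitter_sd per-frame rigid jitter SD, pixels (default 0).
#' @param pixel_noise Gaussian pixel noise SD, a.u. (default 0.01).
#' @param seed RNG seed.
#' @return A list: `movie` (a [movie_stack()]), `shifts` (`T x 2` true
#'   (dy, dx)), `neuropil_trace`.
#' @export
render_movie <- function(cells, gt, frame_rate = gt$params$frame_rate,
                         background = 0.1, cell_level = 1,
                         neuropil_gain = 0, alpha_inside = 0.9,
                         jitter_sd = 0, pixel_noise = 0.01, seed = 1L) {
  set.seed(seed)
  nt <- ncol(gt$true_dff)
  nr <- cells$field[1]; nc <- cells$field[2]
  base <- matrix(background, nr, nc)
  profile <- vector("list", length(cells$masks))
  for (i in seq_along(cells$masks)) {
    pr <- matrix(0, nr, nc)
    pr[cells$masks[[i]]] <- cell_level
    if (!is.null(cells$nucleus[[i]])) pr[cells$nucleus[[i]]] <- 0.25 * cell_level
    profile[[i]] <- pr
  }
  np_field <- matrix(neuropil_gain, nr, nc)
  for (i in seq_along(cells$masks))
    np_field[cells$masks[[i]]] <- neuropil_gain * alpha_inside
  w <- max(1L, round(frame_rate))   # ~1 s low-pass
  np_trace <- as.numeric(zoo::rollapply(zoo::zoo(colMeans(gt$true_dff)),
                                        width = w, FUN = mean,
                                        partial = TRUE, align = "center"))
  # standardize so neuropil_gain sets the contamination amplitude directly
  if (stats::sd(np_trace) > 0)
    np_trace <- (np_trace - mean(np_trace)) / stats::sd(np_trace)
  shifts <- cbind(stats::rnorm(nt, 0, jitter_sd),
                  stats::rnorm(nt, 0, jitter_sd))
  if (jitter_sd == 0) shifts[] <- 0
  data <- array(0, dim = c(nr, nc, nt))
  for (t in seq_len(nt)) {
    img <- base + np_field * (1 + 0.3 * np_trace[t])
    for (i in seq_along(profile))
      img <- img + profile[[i]] * (1 + gt$true_dff[i, t])
    if (any(shifts[t, ] != 0)) {
      # content moves by +(dy, dx), matching estimate_displacements output
      img <- .translate_bilinear(img, -shifts[t, 1], -shifts[t, 2])
      img[is.na(img)] <- background
    }
    data[, , t] <- img + matrix(stats::rnorm(nr * nc, 0, pixel_noise),
                                nr, nc)
  }
  list(movie = movie_stack(data, frame_rate, cells$pixel_size),
       shifts = shifts, neuropil_trace = np_trace)
}
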