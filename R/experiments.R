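#' Sweep coupling-coefficient triplets (stimulation cartography)
#'
#' For every `(k1, k2, k3)` triplet on the supplied grid, runs `n_reps`
#' seeded simulations of a single 50 s, 1 uA stimulation epoch on the
#' discharge-regime model and scores the mean detected HPD duration over a
#' one-minute analysis window covering the epoch.  Child seeds derive from
#' the master seed and the (triplet, replicate) index, so the map is
#' reproducible and independent of evaluation order.
#'
#' @param k1,k2,k3 Numeric vectors of coupling values (mV/uA); the grid is
#'   their Cartesian product.
#' @param n_reps Replicates per triplet (default 5).
#' @param window Analysis window length (s), default 60, starting at the
#'   epoch onset (the model, unlike an amplifier, is observable during
#'   stimulation).
#' @param stim_duration Epoch length (s), default 50.
#' @param amplitude Epoch current (uA), default 1.
#' @param preset Model preset name (default `"hpd_regime"`).
#' @param inmf An [inmf_config()]; default uses the preset's `K`.
#' @param seed Master seed.
#' @param detect_args List of extra arguments for [detect_hpd()].  A
#'   detector calibrated on a discharge-free background-preset reference is
#'   supplied automatically (conditions are compared with one fixed
#'   detector, as with a detector calibrated on a baseline recording);
#'   pass `ph` here to override it.
#' @return A `triplet_map`: long-format data frame with one row per
#'   (triplet, replicate): columns `k1, k2, k3, rep, seed,
#'   mean_hpd_duration_s, relative_duration, energy, peak_count`.
#' @export
sweep_triplets <- function(k1, k2, k3, n_reps = 5, window = 60,
                           stim_duration = 50, amplitude = 1,
                           preset = "hpd_regime", inmf = inmf_config(),
                           seed = 1, detect_args = list()) {
  stopifnot(n_reps >= 1, window > 0)
  grid <- expand.grid(k1 = k1, k2 = k2, k3 = k3, rep = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$k1, grid$k2, grid$k3, grid$rep), , drop = FALSE]
  rownames(grid) <- NULL
  pre <- model_preset(preset)
  if (is.null(detect_args$ph))
    detect_args$ph <- background_detector(pre$params, child_seed(seed, 0))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    trip <- coupling_triplet(g$k1, g$k2, g$k3)
    # seed from the triplet's values, so maps are identical whatever the
    # axis ordering or grid the triplet appears in
    child <- child_seed(seed, round(1e3 * g$k1), round(1e3 * g$k2),
                        round(1e3 * g$k3), g$rep)
    sc <- tryCatch(
      score_stim_window(pre, trip, inmf, child, window, stim_duration,
                        amplitude, detect_args),
      error = function(e) stop("triplet (", g$k1, ", ", g$k2, ", ", g$k3,
                               "), rep ", g$rep, ": ", conditionMessage(e)))
    cbind(g, seed = child, sc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("triplet_map", "data.frame")
  out
}

#' Guard intervals around stimulation edges
#'
#' Intervals `[edge - pre, edge + post]` around each stimulation on/off
#' time, for [detect_hpd()]'s `exclude_peaks`: the instantaneous current
#' steps leave broadband transients in the band-passed trace that would
#' otherwise be scored as discharges.
#'
#' @param edges Numeric vector of stimulation on/off times (s).
#' @param pre,post Guard extent before/after each edge (s).
#' @return A two-column matrix of intervals.
#' @export
stim_edge_guard <- function(edges, pre = 0.2, post = 0.5) {
  cbind(edges - pre, edges + post)
}

# detector calibrated on a discharge-free background-preset trace
background_detector <- function(params, seed, duration = 60, ...) {
  bg <- params
  ref <- bandpass(simulate_lfp(bg, duration, seed = seed))
  calibrate_ph(ref$samples^2, ...)
}

# deterministic child-seed derivation, kept below 2^31
child_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) s <- (s * 69069 + 1234567 * as.double(k)) %% 2147483647
  as.integer(s)
}

# simulate one stimulated window and score detected discharges; peaks near
# the stimulation edges are excluded (filter transients of the current step)
score_stim_window <- function(pre, trip, inmf, seed, window, stim_duration,
                              amplitude, detect_args = list()) {
  set.seed(seed)
  dur <- max(window, stim_duration + 10)
  fs <- pre$params$fs
  sched <- sample_schedule(inmf, dur)
  mod <- modulation_signal(sched, inmf$K, fs, dur)
  drive <- numeric(round(dur * fs))
  i1 <- min(length(drive), round(stim_duration * fs))
  drive[1:i1] <- amplitude
  off <- membrane_offsets(trip, drive)
  sig <- simulate_lfp(pre$params, dur, modulation = mod, offsets = off)
  if (is.null(detect_args$exclude_peaks))
    detect_args$exclude_peaks <- stim_edge_guard(c(0, stim_duration))
  tb <- do.call(detect_hpd, c(list(sig), detect_args))
  w <- window_signal(sig, 0, window)
  keep <- tb$onset < window
  tb2 <- event_table(tb$onset[keep], pmin(tb$offset[keep], window),
                     tb$peaks[keep])
  ft <- event_features(w, tb2, t_win = window)
  n_ev <- nrow(tb2)
  data.frame(mean_hpd_duration_s = if (n_ev) ft$total_duration / n_ev else 0,
             relative_duration = ft$relative_duration,
             energy = ft$energy, peak_count = ft$peak_count)
}

#' Boxplot-style summary of one condition
#'
#' Median, quartiles, 1.5 IQR whiskers and outliers of per-window feature
#' samples, as drawn in condition boxplots.
#'
#' @param label Condition label (e.g. `"baseline"`, `"CS"`, `"AS"`).
#' @param samples Numeric feature samples (one per analysis window).
#' @return A `condition_summary` list: `label`, `samples`, `median`, `q1`,
#'   `q3`, `whiskers` (extreme samples within 1.5 IQR of the quartiles) and
#'   `outliers`.
#' @export
condition_summary <- function(label, samples) {
  stopifnot(is.character(label), is.numeric(samples), length(samples) > 0)
  q <- unname(quantile(samples, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- samples >= lo & samples <= hi
  structure(list(label = label, samples = samples,
                 median = q[2], q1 = q[1], q3 = q[3],
                 whiskers = c(min(samples[inside]), max(samples[inside])),
                 outliers = samples[!inside]),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("%s: median %.3g [Q1 %.3g, Q3 %.3g], whiskers [%.3g, %.3g], %d outlier(s), n = %d\n",
              x$label, x$median, x$q1, x$q3, x$whiskers[1], x$whiskers[2],
              length(x$outliers), length(x$samples)))
  invisible(x)
}

#' Simulate a full stimulation protocol session and score each condition
#'
#' Simulates the whole session (discharge-regime model + INMF), converts
#' the protocol drive through the interface circuit and coupling triplet
#' into per-population offsets, and scores discharge features in one
#' analysis window per epoch, plus matched stimulation-free baseline
#' windows before the first epoch.
#'
#' Epoch windows start at the epoch onset by default (`score = "stim"`):
#' the model is observable during stimulation, and its stimulation effect
#' is instantaneous, with no plasticity carrying it beyond the epoch.
#' `score = "post"` instead emulates the in vivo setting where amplifiers
#' saturate during stimulation: the window starts at the epoch end.  With
#' `blank = TRUE` the simulated trace is additionally zeroed during epochs
#' (saturation emulation) before detection.
#'
#' @param protocol A [stim_protocol()] (see [build_protocol()]).
#' @param triplet A [coupling_triplet()] applied to all epochs (the per
#'   epoch `sign` column flips it for inverted sub-sessions).
#' @param preset Model preset name (default `"hpd_regime"`).
#' @param inmf An [inmf_config()].
#' @param circuit An [interface_circuit()]; the drive passes through it in
#'   the protocol's drive mode.
#' @param window Analysis window length (s), default 60.
#' @param score `"stim"` or `"post"`, see above.
#' @param blank Zero the trace during epochs before detection (default
#'   `FALSE`).
#' @param n_baseline Number of baseline windows carved from the
#'   pre-stimulation span (default: as many as fit before the first epoch,
#'   capped at the epoch count).
#' @param seed Master seed.
#' @param detect_args List of extra arguments for [detect_hpd()].
#' @return A list of class `protocol_result`: `windows` (data frame with
#'   one row per scored window: `condition`, `epoch`, `from`, `to` and the
#'   feature columns) and `summaries` (per-condition
#'   [condition_summary()] of relative duration).
#' @export
run_protocol <- function(protocol, triplet, preset = "hpd_regime",
                         inmf = inmf_config(), circuit = interface_circuit(),
                         window = 60, score = c("stim", "post"),
                         blank = FALSE, n_baseline = NULL, seed = 1,
                         detect_args = list()) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(triplet, "coupling_triplet"))
  score <- match.arg(score)
  pre <- model_preset(preset)
  fs <- pre$params$fs
  if (is.null(detect_args$ph))
    detect_args$ph <- background_detector(pre$params, child_seed(seed, 0))
  session_end <- max(protocol$onset + protocol$duration) + window + 10
  dur <- session_end
  set.seed(child_seed(seed, 1))
  sched <- sample_schedule(inmf, dur)
  mod <- modulation_signal(sched, inmf$K, fs, dur)
  drive <- protocol_drive(protocol, fs, dur)
  resp <- interface_response(circuit, drive,
                             mode = attr(protocol, "mode"), dt = 1 / fs)
  off <- membrane_offsets(triplet, resp$current)
  sig <- simulate_lfp(pre$params, dur, modulation = mod, offsets = off)
  if (blank) {
    sig$samples[drive != 0] <- 0
  }
  if (is.null(detect_args$exclude_peaks))
    detect_args$exclude_peaks <- stim_edge_guard(
      c(protocol$onset, protocol$onset + protocol$duration))
  tb <- do.call(detect_hpd, c(list(sig), detect_args))

  win_from <- if (score == "stim") protocol$onset
              else protocol$onset + protocol$duration
  esign <- if (is.null(protocol$sign)) rep(1, nrow(protocol))
           else protocol$sign
  wins <- data.frame(condition = ifelse(esign >= 0, "stim", "stim_inverted"),
                     epoch = seq_len(nrow(protocol)),
                     from = win_from, to = win_from + window)
  first <- min(protocol$onset)
  nb <- floor(first / window)
  if (!is.null(n_baseline)) nb <- min(nb, n_baseline)
  nb <- min(nb, nrow(protocol))
  if (nb > 0) {
    bfrom <- (seq_len(nb) - 1) * window
    wins <- rbind(data.frame(condition = "baseline", epoch = NA_integer_,
                             from = bfrom, to = bfrom + window), wins)
  }
  feats <- lapply(seq_len(nrow(wins)), function(i) {
    f <- window_features(sig, tb, wins$from[i], wins$to[i])
    data.frame(total_duration = f$total_duration,
               relative_duration = f$relative_duration,
               energy = f$energy, peak_count = f$peak_count, rms = f$rms)
  })
  windows <- cbind(wins, do.call(rbind, feats))
  summaries <- lapply(split(windows$relative_duration, windows$condition),
                      function(v) NULL)
  summaries <- lapply(names(summaries), function(cond)
    condition_summary(cond,
                      windows$relative_duration[windows$condition == cond]))
  names(summaries) <- vapply(summaries, `[[`, "", "label")
  structure(list(windows = windows, summaries = summaries,
                 events = tb, schedule = sched),
            class = "protocol_result")
}

# clip the event table to a window and compute features there
window_features <- function(sig, tb, from, to) {
  keep <- tb$offset > from & tb$onset < to
  tb2 <- event_table(pmax(tb$onset[keep], from),
                     pmin(tb$offset[keep], to), tb$peaks[keep])
  w <- window_signal(sig, from, to)
  event_features(w, tb2, t_win = to - from)
}

#' Mann-Whitney comparison of two feature samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact null distribution
#' when both groups have at most 20 observations and no ties, normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Non-empty numeric feature samples.
#' @return List with `statistic` (U, for the first sample), `p_value` and
#'   `method`.
#' @examples
#' compare_conditions(1:8, 11:18)$statistic   # U = 0
#' @export
compare_conditions <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) == 0 || length(b) == 0) stop("empty sample group")
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
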