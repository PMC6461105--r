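#' Two-state interconversion rates
#'
#' Container for the rate constants of a two-state conformational exchange.
#' `k_active` is the rate of leaving the inactive conformation
#' (inactive -> active, the exit rate of the inactive state) and
#' `k_inactive` the rate of adopting it (active -> inactive). Residence
#' times are the reciprocals of these rates and the stationary fraction of
#' the inactive conformation is `k_inactive / (k_active + k_inactive)`.
#'
#' @param k_active inactive -> active rate constant (s^-1); must be > 0.
#' @param k_inactive active -> inactive rate constant (s^-1); must be >= 0.
#'   Zero makes the active state absorbing and is intended only for
#'   degenerate simulator tests.
#' @return An object of class `"two_state_rates"`.
#' @examples
#' r <- two_state_rates(2.1, 2.4)
#' stationary_inactive(r)  # 2.4 / 4.5
#' @export
two_state_rates <- function(k_active, k_inactive) {
  stopifnot(is.numeric(k_active), length(k_active) == 1L, is.finite(k_active),
            is.numeric(k_inactive), length(k_inactive) == 1L,
            is.finite(k_inactive))
  if (k_active <= 0)
    stop("k_active must be strictly positive, got ", k_active)
  if (k_inactive < 0)
    stop("k_inactive must be non-negative, got ", k_inactive)
  structure(list(k_active = k_active, k_inactive = k_inactive),
            class = "two_state_rates")
}

#' @export
print.two_state_rates <- function(x, ...) {
  cat("Two-state rates: k_active =", x$k_active,
      "s^-1, k_inactive =", x$k_inactive, "s^-1\n")
  cat("  stationary fraction inactive:",
      format(stationary_inactive(x), digits = 4), "\n")
  invisible(x)
}

#' Stationary fraction of the inactive conformation
#'
#' @param rates a [two_state_rates()] object.
#' @return `k_inactive / (k_active + k_inactive)`.
#' @export
stationary_inactive <- function(rates) {
  stopifnot(inherits(rates, "two_state_rates"))
  rates$k_inactive / (rates$k_active + rates$k_inactive)
}

#' Emission model for the quench reporter
#'
#' Per-frame intensities are drawn from a log-normal distribution whose
#' mode equals the noiseless level of the frame. `mode_high` is the
#' fluorescent (unquenched) level, `mode_low` the quenched level; the shape
#' parameters are the log-scale spreads of the scatter around each level.
#' Defaults give a 3:1 mode ratio with well-resolved peaks.
#'
#' @param mode_high fluorescent-state intensity mode (a.u.).
#' @param mode_low quenched-state intensity mode (a.u.).
#' @param shape_high,shape_low log-scale spread of the per-frame scatter
#'   around each level. Zero means no scatter.
#' @param baseline additive background (a.u.).
#' @return An object of class `"emission_model"`.
#' @export
emission_model <- function(mode_high = 90, mode_low = 30,
                           shape_high = 0.2, shape_low = 0.2,
                           baseline = 0) {
  stopifnot(is.numeric(mode_high), is.numeric(mode_low),
            mode_high > mode_low, mode_low >= 0,
            shape_high >= 0, shape_low >= 0, baseline >= 0)
  structure(list(mode_high = mode_high, mode_low = mode_low,
                 shape_high = shape_high, shape_low = shape_low,
                 baseline = baseline),
            class = "emission_model")
}

#' Simulation configuration
#'
#' Acquisition settings mirror the single-molecule TIRF experiment: 80 ms
#' per frame and 500 frames per molecule by default. `polarity` maps the
#' conformations onto intensity levels: `"inactive-low"` is the
#' activation-loop reporter in which the inactive conformation quenches the
#' dyes (K224C/S283C-like); `"inactive-high"` the inverted construct
#' (M373C/S283C-like).
#'
#' @param rates a [two_state_rates()] object.
#' @param emission an [emission_model()].
#' @param frame_interval frame duration in seconds.
#' @param n_frames frames per molecule.
#' @param n_molecules molecules in the ensemble.
#' @param polarity `"inactive-low"` or `"inactive-high"`.
#' @param seed integer seed; recorded in all outputs.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(rates, emission = emission_model(),
                       frame_interval = 0.08, n_frames = 500,
                       n_molecules = 100,
                       polarity = c("inactive-low", "inactive-high"),
                       seed = 1L) {
  stopifnot(inherits(rates, "two_state_rates"),
            inherits(emission, "emission_model"),
            frame_interval > 0, n_frames >= 1, n_molecules >= 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  polarity <- match.arg(polarity)
  structure(list(rates = rates, emission = emission,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 n_molecules = as.integer(n_molecules),
                 polarity = polarity, seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a continuous-time two-state path
#'
#' Draws a realization of the telegraph process: alternating exponentially
#' distributed dwells, in the inactive state with exit rate `k_active` and
#' in the active state with exit rate `k_inactive`.
#'
#' @param rates a [two_state_rates()] object.
#' @param duration total path duration in seconds (> 0).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so ensembles are reproducible from a single seed).
#' @param initial_state `"stationary"` draws the starting conformation from
#'   the stationary distribution (molecules are observed at equilibrium);
#'   `"inactive"` or `"active"` fix it.
#' @return An object of class `"state_path"`: a list with `inactive`
#'   (logical per segment), `duration_s` (segment dwell lengths; the final
#'   segment is truncated at `duration`), `t_end` (segment end times) and
#'   `duration` (total span).
#' @examples
#' p <- sample_state_path(two_state_rates(2.1, 2.4), 100, seed = 1)
#' sum(p$duration_s[p$inactive]) / p$duration  # time fraction inactive
#' @export
sample_state_path <- function(rates, duration, seed = NULL,
                              initial_state = c("stationary", "inactive",
                                                "active")) {
  stopifnot(inherits(rates, "two_state_rates"))
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration)
      || duration <= 0)
    stop("duration must be a positive finite number of seconds, got ",
         duration)
  initial_state <- match.arg(initial_state)
  if (!is.null(seed)) set.seed(seed)

  first_inactive <- switch(initial_state,
    stationary = stats::runif(1) < stationary_inactive(rates),
    inactive = TRUE,
    active = FALSE)

  exit_rate <- function(inactive)
    if (inactive) rates$k_active else rates$k_inactive

  inactive <- logical(0)
  dwell <- numeric(0)
  total <- 0
  state <- first_inactive
  repeat {
    r <- exit_rate(state)
    if (r <= 0) {            # absorbing state: one dwell spans the rest
      inactive <- c(inactive, state)
      dwell <- c(dwell, duration - total)
      total <- duration
      break
    }
    # draw dwells in batches for speed; alternate states strictly
    n_batch <- max(16L, ceiling((duration - total) * r * 1.2))
    d <- stats::rexp(n_batch, rate = r)
    # states alternate, so only every other dwell has this rate; draw the
    # other state's dwells too unless it is absorbing
    r2 <- exit_rate(!state)
    if (r2 <= 0) {
      # next state absorbs: take one dwell of current state, then absorb
      inactive <- c(inactive, state)
      dwell <- c(dwell, d[1])
      total <- total + d[1]
      if (total >= duration) {
        dwell[length(dwell)] <- dwell[length(dwell)] - (total - duration)
        total <- duration
        break
      }
      state <- !state
      next
    }
    d2 <- stats::rexp(n_batch, rate = r2)
    dd <- as.vector(rbind(d, d2))           # interleave: state, !state, ...
    ss <- rep(c(state, !state), n_batch)
    cum <- total + cumsum(dd)
    keep <- which(cum >= duration)
    if (length(keep) > 0) {
      k <- keep[1]
      dd <- dd[seq_len(k)]
      ss <- ss[seq_len(k)]
      dd[k] <- dd[k] - (cum[k] - duration)
      inactive <- c(inactive, ss)
      dwell <- c(dwell, dd)
      total <- duration
      break
    } else {
      inactive <- c(inactive, ss)
      dwell <- c(dwell, dd)
      total <- cum[length(cum)]
      state <- state                         # even count keeps parity
    }
  }
  structure(list(inactive = inactive, duration_s = dwell,
                 t_end = cumsum(dwell), duration = duration),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat("Two-state path:", length(x$duration_s), "segments over",
      x$duration, "s;", sum(x$duration_s[x$inactive]) / x$duration * 100,
      "% inactive\n")
  invisible(x)
}

# Per-frame fractional occupancy of the inactive state, by exact
# time-weighting of sub-frame dwells. The cumulative inactive time is
# piecewise linear in t with knots at the segment boundaries, so linear
# interpolation at the frame edges is exact.
frame_occupancy <- function(path, n_frames, frame_interval) {
  span <- n_frames * frame_interval
  if (path$duration < span - 1e-9)
    stop("state path (", path$duration, " s) is shorter than the ",
         "acquisition window (", span, " s)")
  knots <- c(0, path$t_end)
  cum_inactive <- c(0, cumsum(path$duration_s * path$inactive))
  edges <- seq(0, span, by = frame_interval)
  # guard against floating-point overrun at the last edge
  edges[length(edges)] <- min(edges[length(edges)], knots[length(knots)])
  ci <- stats::approx(knots, cum_inactive, xout = edges, ties = "ordered")$y
  occ <- diff(ci) / frame_interval
  pmin(pmax(occ, 0), 1)
}

#' Integrate a state path into a framewise intensity trace
#'
#' Each frame's noiseless level is the time-weighted mixture of the two
#' state intensities within that frame, so a conformational switch occurs
#' within a single frame rather than between frames. Log-normal scatter
#' (mode-preserving) is then applied around the level.
#'
#' @param path a `"state_path"` from [sample_state_path()].
#' @param config a [sim_config()]; the path must span at least
#'   `n_frames * frame_interval` seconds.
#' @param molecule_id identifier stored in the trace.
#' @return An object of class `"intensity_trace"`: list with `molecule_id`,
#'   `intensities` (length `n_frames`), `frame_interval` and
#'   `true_inactive` (per-frame fractional occupancy of the inactive
#'   conformation).
#' @export
integrate_to_frames <- function(path, config, molecule_id = 1L) {
  stopifnot(inherits(path, "state_path"), inherits(config, "sim_config"))
  occ <- frame_occupancy(path, config$n_frames, config$frame_interval)
  em <- config$emission
  if (config$polarity == "inactive-low") {
    mode_inact <- em$mode_low;  shape_inact <- em$shape_low
    mode_act   <- em$mode_high; shape_act   <- em$shape_high
  } else {
    mode_inact <- em$mode_high; shape_inact <- em$shape_high
    mode_act   <- em$mode_low;  shape_act   <- em$shape_low
  }
  level <- occ * mode_inact + (1 - occ) * mode_act
  shape <- occ * shape_inact + (1 - occ) * shape_act
  noisy <- ifelse(level > 0 & shape > 0,
                  stats::rlnorm(length(level),
                                meanlog = log(pmax(level, .Machine$double.xmin))
                                          + shape^2,
                                sdlog = shape),
                  level)
  structure(list(molecule_id = molecule_id,
                 intensities = em$baseline + noisy,
                 frame_interval = config$frame_interval,
                 true_inactive = occ),
            class = "intensity_trace")
}

#' Simulate an ensemble of single-molecule traces
#'
#' Draws `n_molecules` independent telegraph-process traces under one
#' seeded generator and returns them together with the ground truth a
#' downstream analysis should recover.
#'
#' @param config a [sim_config()].
#' @return An object of class `"trace_ensemble"`: list with
#'   `intensity` (`n_frames` x `n_molecules` matrix), `true_inactive`
#'   (matching matrix of per-frame inactive occupancies), `config`, and
#'   `truth` (stationary fractions, realized time-averaged inactive
#'   fraction, fraction of molecules with at least one transition during
#'   acquisition, and the seed).
#' @examples
#' cfg <- sim_config(two_state_rates(2.1, 2.4), n_molecules = 5, seed = 7)
#' ens <- simulate_ensemble(cfg)
#' ens$truth$realized_fraction_inactive
#' @export
simulate_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  span <- config$n_frames * config$frame_interval
  nm <- config$n_molecules
  intensity <- matrix(NA_real_, config$n_frames, nm)
  occ <- matrix(NA_real_, config$n_frames, nm)
  transitioned <- logical(nm)
  for (i in seq_len(nm)) {
    p <- sample_state_path(config$rates, span)
    tr <- integrate_to_frames(p, config, molecule_id = i)
    intensity[, i] <- tr$intensities
    occ[, i] <- tr$true_inactive
    transitioned[i] <- length(p$duration_s) > 1L
  }
  truth <- list(
    stationary_fraction_inactive = stationary_inactive(config$rates),
    realized_fraction_inactive = mean(occ),
    fraction_molecules_transitioning = mean(transitioned),
    k_active = config$rates$k_active,
    k_inactive = config$rates$k_inactive,
    seed = config$seed)
  structure(list(intensity = intensity, true_inactive = occ,
                 config = config, truth = truth),
            class = "trace_ensemble")
}

#' @export
print.trace_ensemble <- function(x, ...) {
  cfg <- x$config
  cat("Single-molecule trace ensemble:", cfg$n_molecules, "molecules x",
      cfg$n_frames, "frames @", cfg$frame_interval * 1000, "ms\n")
  cat("  rates: k_active =", cfg$rates$k_active, ", k_inactive =",
      cfg$rates$k_inactive, "s^-1 | polarity:", cfg$polarity,
      "| seed:", cfg$seed, "\n")
  cat("  realized inactive fraction:",
      format(x$truth$realized_fraction_inactive, digits = 4),
      "(stationary ",
      format(x$truth$stationary_fraction_inactive, digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.trace_ensemble <- function(x, ...) {
  nf <- x$config$n_frames
  nm <- x$config$n_molecules
  data.frame(molecule_id = rep(seq_len(nm), each = nf),
             frame = rep(seq_len(nf), nm),
             intensity = as.vector(x$intensity),
             true_inactive_fraction = as.vector(x$true_inactive))
}

#' Write / read a trace ensemble as CSV plus JSON sidecar
#'
#' The CSV holds one row per molecule and frame
#' (`molecule_id, frame, intensity, true_inactive_fraction`); the sidecar
#' (`<file>.json`) records the configuration, seed and ground-truth
#' summary.
#'
#' @param ensemble a `"trace_ensemble"`.
#' @param file path of the CSV to write; the sidecar goes to
#'   `paste0(file, ".json")`.
#' @return `file`, invisibly.
#' @export
write_traces <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "trace_ensemble"))
  utils::write.csv(as.data.frame(ensemble), file, row.names = FALSE)
  cfg <- ensemble$config
  meta <- list(
    rates = cfg$rates[c("k_active", "k_inactive")],
    emission = unclass(cfg$emission),
    frame_interval = cfg$frame_interval,
    n_frames = cfg$n_frames,
    n_molecules = cfg$n_molecules,
    polarity = cfg$polarity,
    seed = cfg$seed,
    truth = ensemble$truth)
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_traces
#' @return For `read_traces`, a data frame in the trace CSV dialect with
#'   attribute `"meta"` holding the sidecar contents if present.
#' @export
read_traces <- function(file) {
  df <- utils::read.csv(file)
  need <- c("molecule_id", "frame", "intensity")
  if (!all(need %in% names(df)))
    stop("trace file must have columns ", paste(need, collapse = ", "))
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar))
    attr(df, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df
}
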