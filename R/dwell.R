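#' State-assignment threshold from a two-log-normal fit
#'
#' Returns the intensity between the two fitted modes at which the two
#' weighted component densities are equal — a reproducible replacement for
#' manual boundary setting, justified because the transition amplitude is
#' much larger than the noise. If the densities do not cross between the
#' modes (extreme shape mismatch), the geometric mean of the modes is used
#' and a warning emitted.
#'
#' @param fit a `"lognorm2_fit"` with distinct, finite modes.
#' @return Threshold intensity (a.u.), with attribute `"rule"` recording
#'   whether the density crossing or the fallback was used.
#' @export
threshold_from_fit <- function(fit) {
  stopifnot(inherits(fit, "lognorm2_fit"))
  m1 <- unname(fit$modes["low"]); m2 <- unname(fit$modes["high"])
  if (!is.finite(m1) || !is.finite(m2) || m1 <= 0 || m1 >= m2)
    stop("degenerate fit: need finite modes with mode_low < mode_high")
  diffdens <- function(x) {
    fit$areas["low"] * dlnorm_mode(x, m1, fit$shapes["low"]) -
      fit$areas["high"] * dlnorm_mode(x, m2, fit$shapes["high"])
  }
  lo <- m1 * (1 + 1e-9); hi <- m2 * (1 - 1e-9)
  f_lo <- diffdens(lo); f_hi <- diffdens(hi)
  if (is.finite(f_lo) && is.finite(f_hi) && f_lo * f_hi < 0) {
    thr <- stats::uniroot(diffdens, c(lo, hi), tol = 1e-12)$root
    return(structure(thr, rule = "density-crossing"))
  }
  warning("no density crossing between the modes; falling back to the ",
          "geometric mean of the modes")
  structure(sqrt(m1 * m2), rule = "geometric-mean")
}

#' Assign framewise states by thresholding
#'
#' @param x an `"intensity_trace"`, a `"trace_ensemble"`, or a numeric
#'   vector/matrix of intensities (frames in rows for a matrix).
#' @param threshold intensity threshold (a.u.); frames strictly below it
#'   are labelled `"low"`, all others `"high"`.
#' @param frame_interval frame duration in seconds; taken from `x` when it
#'   carries one.
#' @return A character vector or matrix of `"low"`/`"high"` labels with
#'   attributes `threshold` and `frame_interval`.
#' @export
assign_states <- function(x, threshold, frame_interval = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  if (inherits(x, "trace_ensemble")) {
    v <- x$intensity
    frame_interval <- x$config$frame_interval
  } else if (inherits(x, "intensity_trace")) {
    v <- x$intensities
    frame_interval <- x$frame_interval
  } else v <- x
  rng <- range(v, finite = TRUE)
  if (threshold <= rng[1] || threshold >= rng[2])
    warning("threshold ", format(threshold),
            " lies outside the observed intensity range [",
            format(rng[1]), ", ", format(rng[2]), "]")
  lab <- ifelse(v < threshold, "low", "high")
  if (is.matrix(v)) dim(lab) <- dim(v)
  structure(lab, threshold = threshold, frame_interval = frame_interval)
}

#' Extract dwell times of one state
#'
#' Converts maximal runs of the requested state into durations
#' (run length times the frame interval). Runs touching the start or end
#' of a trace are of unknown full duration and are flagged censored;
#' censored dwells are excluded from rate fitting by default.
#'
#' @param labels a vector or matrix (frames x molecules) of
#'   `"low"`/`"high"` labels, e.g. from [assign_states()].
#' @param state which state's dwells to extract.
#' @param frame_interval frame duration in seconds; defaults to the
#'   attribute carried by `labels`.
#' @return An object of class `"dwell_set"`: data frame with columns
#'   `molecule`, `duration` (s) and `censored`, plus attributes `state`
#'   and `frame_interval`.
#' @export
extract_dwells <- function(labels, state = c("low", "high"),
                           frame_interval = NULL) {
  state <- match.arg(state)
  if (is.null(frame_interval))
    frame_interval <- attr(labels, "frame_interval")
  if (is.null(frame_interval))
    stop("frame_interval not supplied and not carried by labels")
  mat <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1L)
  if (nrow(mat) < 2L) stop("state path must have at least 2 frames")
  out <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    r <- rle(mat[, j] == state)
    idx <- which(r$values)
    if (length(idx) == 0L) next
    cens <- idx == 1L | idx == length(r$values)
    out[[j]] <- data.frame(molecule = j,
                           duration = r$lengths[idx] * frame_interval,
                           censored = cens)
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(molecule = integer(0), duration = numeric(0),
                     censored = logical(0))
  structure(df, state = state, frame_interval = frame_interval,
            class = c("dwell_set", "data.frame"))
}

#' Fit a single-exponential decay to dwell times
#'
#' Estimates the exit rate of the dwelt state. `"mle"` (default) is the
#' exact maximum-likelihood estimate for exponential dwells,
#' `k = 1/mean(duration)`, with analytic standard error `k/sqrt(n)`.
#' `"binned_lsq"` mirrors histogram-based fitting: the dwell-time
#' histogram (default bin width one frame) is fitted to `A * exp(-k t)` by
#' Levenberg--Marquardt least squares.
#'
#' @param dwells a `"dwell_set"`; censored dwells are excluded.
#' @param method `"mle"` or `"binned_lsq"`.
#' @param bin_width histogram bin width in seconds for `"binned_lsq"`;
#'   defaults to the frame interval.
#' @return An object of class `"rate_estimate"`: list with `k` (s^-1),
#'   `se`, `n_dwells` and `method`.
#' @export
fit_single_exponential <- function(dwells, method = c("mle", "binned_lsq"),
                                   bin_width = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(dwells, "dwell_set"))
  d <- dwells$duration[!dwells$censored]
  n <- length(d)
  if (n < 10L)
    stop("need at least 10 uncensored dwells for a reportable estimate, ",
         "got ", n)
  if (method == "mle") {
    k <- 1 / mean(d)
    se <- k / sqrt(n)
  } else {
    dt <- attr(dwells, "frame_interval")
    if (is.null(bin_width)) bin_width <- dt
    # start at the shortest dwell: durations below one frame cannot be
    # observed, and an empty leading bin would bias the decay fit
    edges <- seq(min(d), max(d) + bin_width, by = bin_width)
    h <- graphics::hist(d, breaks = edges, plot = FALSE, right = FALSE)
    dat <- data.frame(t = h$mids, y = h$counts)
    k0 <- 1 / mean(d)
    ft <- minpack.lm::nlsLM(y ~ A * exp(-k * t), data = dat,
                            start = list(A = max(h$counts), k = k0),
                            lower = c(0, 1e-12))
    cf <- stats::coef(ft)
    k <- unname(cf["k"])
    se <- tryCatch(unname(sqrt(diag(stats::vcov(ft)))["k"]),
                   error = function(e) NA_real_)
  }
  structure(list(k = k, se = se, n_dwells = n, method = method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate estimate (%s): k = %.3g +/- %.2g s^-1 (n = %d dwells)\n",
              x$method, x$k, x$se, x$n_dwells))
  invisible(x)
}

as_rate <- function(x) {
  if (inherits(x, "rate_estimate")) x
  else structure(list(k = as.numeric(x), se = 0, n_dwells = NA_integer_,
                      method = "given"), class = "rate_estimate")
}

#' Rate of adopting the inactive conformation, by detailed balance
#'
#' The inactive-state dwell analysis yields the inactive -> active rate
#' directly; the reverse rate follows from the equilibrium constant via
#' detailed balance, `k_inactive = k_active * K_eq` with
#' `K_eq = [inactive]/[active]`. Relative errors combine in quadrature.
#'
#' @param k_active a `"rate_estimate"` or numeric rate (s^-1).
#' @param K_eq an `"equilibrium_result"` or numeric equilibrium constant.
#' @return A `"rate_estimate"` for the active -> inactive rate.
#' @examples
#' derived_k_inactive(2.1, 52 / 46)  # ~2.4 s^-1
#' @export
derived_k_inactive <- function(k_active, K_eq) {
  ka <- as_rate(k_active)
  if (inherits(K_eq, "equilibrium_result")) {
    Kv <- K_eq$K_eq; Ks <- K_eq$se
  } else { Kv <- as.numeric(K_eq); Ks <- 0 }
  stopifnot(ka$k > 0, Kv > 0)
  k <- ka$k * Kv
  rel <- sqrt((ka$se / ka$k)^2 + (Ks / Kv)^2)
  structure(list(k = k, se = k * rel, n_dwells = ka$n_dwells,
                 method = "detailed-balance"),
            class = "rate_estimate")
}

#' Residence times of the two conformations
#'
#' The mean continuous time spent in a conformation before switching is
#' the reciprocal of its exit rate: `tau_inactive = 1/k_active` and
#' `tau_active = 1/k_inactive`.
#'
#' @param rates a [two_state_rates()] object (or anything coercible via
#'   `two_state_rates(k_active, k_inactive)`).
#' @return Named numeric vector `c(inactive = , active = )` in seconds.
#' @examples
#' residence_times(two_state_rates(2.1, 2.4))
#' @export
residence_times <- function(rates) {
  stopifnot(inherits(rates, "two_state_rates"))
  if (rates$k_inactive <= 0)
    stop("residence times need strictly positive rates")
  c(inactive = 1 / rates$k_active, active = 1 / rates$k_inactive)
}
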