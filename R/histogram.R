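#' Pool framewise intensities into a histogram
#'
#' Pools every frame of every molecule exactly once and bins the
#' intensities. Default binning is Freedman--Diaconis on the pooled
#' values.
#'
#' @param x a `"trace_ensemble"`, a trace data frame with an `intensity`
#'   column, or a numeric vector of pooled intensities.
#' @param bins number of bins, or `NULL` for Freedman--Diaconis.
#' @param breaks explicit vector of bin edges (overrides `bins`).
#' @return An object of class `"intensity_histogram"`: list with `breaks`,
#'   `counts`, `mids`, `n_pooled` and `n_molecules`.
#' @export
pool_histogram <- function(x, bins = NULL, breaks = NULL) {
  if (inherits(x, "trace_ensemble")) {
    v <- as.vector(x$intensity)
    nmol <- x$config$n_molecules
  } else if (is.data.frame(x)) {
    if (!"intensity" %in% names(x)) stop("data frame lacks 'intensity'")
    v <- x$intensity
    nmol <- if ("molecule_id" %in% names(x))
      length(unique(x$molecule_id)) else NA_integer_
  } else if (is.numeric(x)) {
    v <- as.vector(x)
    nmol <- NA_integer_
  } else stop("unsupported input of class ", paste(class(x), collapse = "/"))
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no finite intensities to pool")
  if (is.null(breaks)) {
    breaks <- if (is.null(bins)) fd_breaks(v) else
      seq(min(v), max(v), length.out = bins + 1L)
  }
  if (length(breaks) < 2L || any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing with >= 2 edges")
  h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 n_pooled = length(v), n_molecules = nmol),
            class = "intensity_histogram")
}

# Freedman-Diaconis bin edges spanning the data exactly
fd_breaks <- function(v) {
  bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(v)) / 30
  if (bw <= 0) bw <- max(abs(v), 1) * 1e-3       # all values identical
  n <- max(1L, ceiling(diff(range(v)) / bw))
  seq(min(v), max(v) + bw * 1e-8, length.out = n + 1L)
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat("Intensity histogram:", length(x$counts), "bins,",
      x$n_pooled, "pooled frames",
      if (!is.na(x$n_molecules)) paste("from", x$n_molecules, "molecules"),
      "\n")
  invisible(x)
}

# log-normal density parameterized by its mode m and log-scale shape s:
# meanlog = log(m) + s^2 puts the mode of the distribution at m.
dlnorm_mode <- function(x, mode, shape) {
  stats::dlnorm(x, meanlog = log(mode) + shape^2, sdlog = shape)
}

plnorm_mode <- function(q, mode, shape) {
  stats::plnorm(q, meanlog = log(mode) + shape^2, sdlog = shape)
}

#' Fit the sum of two log-normal components to an intensity histogram
#'
#' The fluorescence intensity histogram of a two-state quench reporter is
#' modelled as the sum of two log-normal peaks; the component areas carry
#' the conformational populations. Each component is parameterized by its
#' mode (peak position, a.u.) and log-scale shape. The default objective is
#' least squares on the binned counts, with each bin's expected count
#' computed from the bin-integrated component probability; `method =
#' "mle"` instead maximizes the mixture likelihood on the raw pooled
#' intensities (available only when raw data are supplied).
#'
#' Area fractions are the fitted component totals divided by the number of
#' pooled frames and are deliberately not renormalized to sum to one.
#'
#' @param x an `"intensity_histogram"`, a `"trace_ensemble"`, a trace data
#'   frame, or a numeric vector of intensities.
#' @param init optional list with starting values `modes` (length 2) and
#'   `shapes` (length 2). Defaults: modes at the 20th and 80th percentiles
#'   of the pooled intensity, shapes 0.2, equal areas.
#' @param method `"lsq"` (binned least squares, default) or `"mle"`.
#' @param bins,breaks passed to [pool_histogram()] when `x` is not already
#'   a histogram.
#' @return An object of class `"lognorm2_fit"` with components `modes`,
#'   `shapes`, `areas` (fractions, named `low`/`high`), `se_areas`,
#'   `se_modes`, `converged`, `degenerate`, `residual_norm`, `histogram`,
#'   `fitted_counts`, `n_pooled` and `method`.
#' @examples
#' set.seed(1)
#' v <- c(rlnorm(4000, log(1) + 0.04, 0.2), rlnorm(6000, log(10) + 0.04, 0.2))
#' f <- fit_two_lognormals(v)
#' coef(f)
#' @export
fit_two_lognormals <- function(x, init = NULL,
                               method = c("lsq", "mle"),
                               bins = NULL, breaks = NULL) {
  method <- match.arg(method)
  raw <- NULL
  if (inherits(x, "intensity_histogram")) {
    hist <- x
  } else {
    raw <- if (inherits(x, "trace_ensemble")) as.vector(x$intensity)
           else if (is.data.frame(x)) x$intensity
           else as.vector(x)
    raw <- raw[is.finite(raw)]
    hist <- pool_histogram(raw, bins = bins, breaks = breaks)
  }
  if (sum(hist$counts > 0) < 10 && method == "lsq")
    warning("fewer than 10 occupied bins; two-component fit may be ",
            "unreliable")
  if (is.null(init)) init <- default_init(hist, raw)
  fit <- if (method == "lsq") fit_ln2_lsq(hist, init)
         else fit_ln2_mle(hist, raw, init)
  # two overlapping components splitting one peak are a degenerate fit:
  # collapse to a single log-normal when the modes are not resolved
  sep <- log(fit$modes[["high"]] / fit$modes[["low"]])
  if (is.finite(sep) &&
      sep < 0.5 * (fit$shapes[["low"]] + fit$shapes[["high"]])) {
    fit <- fit_ln1_lsq(hist, fit)
  }
  fit$histogram <- hist
  fit$n_pooled <- hist$n_pooled
  fit$method <- method
  fit$degenerate <- min(fit$areas) < 0.02
  if (fit$degenerate)
    warning("degenerate two-component fit: one component area < 2% ",
            "(single-peak data?)")
  if (!fit$converged)
    warning("two-log-normal fit did not converge; inspect diagnostics")
  class(fit) <- "lognorm2_fit"
  fit
}

default_init <- function(hist, raw = NULL) {
  if (!is.null(raw)) {
    q <- stats::quantile(raw, c(0.2, 0.8), names = FALSE)
  } else {
    cdf <- cumsum(hist$counts) / sum(hist$counts)
    q <- c(hist$mids[which(cdf >= 0.2)[1]], hist$mids[which(cdf >= 0.8)[1]])
  }
  q <- sort(pmax(q, .Machine$double.eps))
  if (q[2] <= q[1]) q[2] <- q[1] * 1.5
  list(modes = q, shapes = c(0.2, 0.2))
}

fit_ln2_lsq <- function(hist, init) {
  lo <- hist$breaks[-length(hist$breaks)]
  hi <- hist$breaks[-1]
  counts <- hist$counts
  ntot <- sum(counts)
  model <- function(lm1, lm2, ls1, ls2, N1, N2) {
    m1 <- exp(lm1); m2 <- exp(lm2); s1 <- exp(ls1); s2 <- exp(ls2)
    N1 * (plnorm_mode(hi, m1, s1) - plnorm_mode(lo, m1, s1)) +
      N2 * (plnorm_mode(hi, m2, s2) - plnorm_mode(lo, m2, s2))
  }
  dat <- data.frame(lo = lo, hi = hi, counts = counts)
  start <- list(lm1 = log(init$modes[1]), lm2 = log(init$modes[2]),
                ls1 = log(max(init$shapes[1], 1e-3)),
                ls2 = log(max(init$shapes[2], 1e-3)),
                N1 = ntot / 2, N2 = ntot / 2)
  ok <- TRUE
  ft <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ model(lm1, lm2, ls1, ls2, N1, N2),
      data = dat, start = start,
      lower = c(-Inf, -Inf, log(1e-4), log(1e-4), 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) { ok <<- FALSE; e })
  if (!ok) {
    return(list(modes = c(low = NA_real_, high = NA_real_),
                shapes = c(low = NA_real_, high = NA_real_),
                areas = c(low = NA_real_, high = NA_real_),
                se_areas = c(low = NA_real_, high = NA_real_),
                se_modes = c(low = NA_real_, high = NA_real_),
                converged = FALSE, residual_norm = NA_real_,
                fitted_counts = rep(NA_real_, length(counts)),
                message = conditionMessage(ft)))
  }
  cf <- stats::coef(ft)
  vc <- tryCatch(stats::vcov(ft), error = function(e) NULL)
  modes <- exp(cf[c("lm1", "lm2")])
  shapes <- exp(cf[c("ls1", "ls2")])
  Ns <- cf[c("N1", "N2")]
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, 6)
  names(se) <- names(cf)
  ord <- order(modes)                       # low component first
  modes <- modes[ord]; shapes <- shapes[ord]; Ns <- Ns[ord]
  se_modes <- (modes * se[c("lm1", "lm2")])[ord]   # delta method on log-mode
  se_N <- se[c("N1", "N2")][ord]
  areas <- Ns / ntot
  conv <- isTRUE(ft$convInfo$isConv)
  fitted_counts <- stats::fitted(ft)
  list(modes = stats::setNames(as.numeric(modes), c("low", "high")),
       shapes = stats::setNames(as.numeric(shapes), c("low", "high")),
       areas = stats::setNames(as.numeric(areas), c("low", "high")),
       se_areas = stats::setNames(as.numeric(se_N / ntot), c("low", "high")),
       se_modes = stats::setNames(as.numeric(se_modes), c("low", "high")),
       converged = conv,
       residual_norm = sqrt(sum(stats::residuals(ft)^2)),
       fitted_counts = as.numeric(fitted_counts))
}

# single-component refit for unresolved (single-peak) data; the lone peak
# is reported as the high component and the low component carries zero
# area, so downstream population mapping sees one conformation only
fit_ln1_lsq <- function(hist, fit2) {
  lo <- hist$breaks[-length(hist$breaks)]
  hi <- hist$breaks[-1]
  counts <- hist$counts
  ntot <- sum(counts)
  m0 <- exp(mean(log(fit2$modes)))
  s0 <- mean(fit2$shapes)
  ft <- minpack.lm::nlsLM(
    counts ~ N * (plnorm_mode(hi, exp(lm), exp(ls)) -
                    plnorm_mode(lo, exp(lm), exp(ls))),
    data = data.frame(lo = lo, hi = hi, counts = counts),
    start = list(lm = log(m0), ls = log(max(s0, 1e-3)), N = ntot),
    lower = c(-Inf, log(1e-4), 0))
  cf <- stats::coef(ft)
  se <- tryCatch(sqrt(pmax(diag(stats::vcov(ft)), 0)),
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     names(cf)))
  m <- exp(cf[["lm"]]); s <- exp(cf[["ls"]]); N <- cf[["N"]]
  list(modes = c(low = m / 3, high = m),       # placeholder empty low side
       shapes = c(low = s, high = s),
       areas = c(low = 0, high = N / ntot),
       se_areas = c(low = 0, high = unname(se["N"]) / ntot),
       se_modes = c(low = NA_real_, high = m * unname(se["lm"])),
       converged = isTRUE(ft$convInfo$isConv),
       residual_norm = sqrt(sum(stats::residuals(ft)^2)),
       fitted_counts = as.numeric(stats::fitted(ft)))
}

fit_ln2_mle <- function(hist, raw, init) {
  if (is.null(raw))
    stop("method = \"mle\" requires raw intensities, not a histogram")
  negll <- function(par) {
    m1 <- exp(par[1]); m2 <- exp(par[2])
    s1 <- exp(par[3]); s2 <- exp(par[4])
    p <- stats::plogis(par[5])
    d <- suppressWarnings(p * dlnorm_mode(raw, m1, s1) +
                            (1 - p) * dlnorm_mode(raw, m2, s2))
    val <- -sum(log(pmax(d, 1e-300)))
    if (!is.finite(val)) 1e10 else val
  }
  par0 <- c(log(init$modes), log(pmax(init$shapes, 1e-3)), 0)
  opt <- stats::optim(par0, negll, method = "BFGS", hessian = TRUE)
  m <- exp(opt$par[1:2]); s <- exp(opt$par[3:4])
  p <- stats::plogis(opt$par[5])
  areas <- c(p, 1 - p)
  se_par <- tryCatch(sqrt(pmax(diag(solve(opt$hessian)), 0)),
                     error = function(e) rep(NA_real_, 5))
  se_p <- se_par[5] * p * (1 - p)            # delta method through logistic
  ord <- order(m)
  modes <- m[ord]; shapes <- s[ord]; areas <- areas[ord]
  se_modes <- (m * se_par[1:2])[ord]
  list(modes = stats::setNames(modes, c("low", "high")),
       shapes = stats::setNames(shapes, c("low", "high")),
       areas = stats::setNames(areas, c("low", "high")),
       se_areas = stats::setNames(rep(se_p, 2), c("low", "high")),
       se_modes = stats::setNames(se_modes, c("low", "high")),
       converged = opt$convergence == 0,
       residual_norm = NA_real_,
       fitted_counts = {
         lo <- hist$breaks[-length(hist$breaks)]; hi <- hist$breaks[-1]
         sum(hist$counts) *
           (areas[1] * (plnorm_mode(hi, modes[1], shapes[1]) -
                          plnorm_mode(lo, modes[1], shapes[1])) +
            areas[2] * (plnorm_mode(hi, modes[2], shapes[2]) -
                          plnorm_mode(lo, modes[2], shapes[2])))
       })
}

#' @export
print.lognorm2_fit <- function(x, digits = 4, ...) {
  cat("Two-log-normal intensity fit (", x$method, ", ",
      x$n_pooled, " pooled frames)\n", sep = "")
  m <- rbind(mode = x$modes, shape = x$shapes, area = x$areas,
             `se(area)` = x$se_areas)
  print(round(m, digits))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (isTRUE(x$degenerate)) cat("NOTE: degenerate (single-peak) fit\n")
  invisible(x)
}

#' @export
coef.lognorm2_fit <- function(object, ...) {
  c(mode_low = unname(object$modes["low"]),
    mode_high = unname(object$modes["high"]),
    shape_low = unname(object$shapes["low"]),
    shape_high = unname(object$shapes["high"]),
    area_low = unname(object$areas["low"]),
    area_high = unname(object$areas["high"]))
}

#' @export
summary.lognorm2_fit <- function(object, ...) {
  tab <- data.frame(
    component = c("low", "high"),
    mode = as.numeric(object$modes),
    se_mode = as.numeric(object$se_modes),
    shape = as.numeric(object$shapes),
    area_fraction = as.numeric(object$areas),
    se_area = as.numeric(object$se_areas))
  structure(list(table = tab, converged = object$converged,
                 degenerate = object$degenerate,
                 residual_norm = object$residual_norm,
                 n_pooled = object$n_pooled, method = object$method),
            class = "summary.lognorm2_fit")
}

#' @export
print.summary.lognorm2_fit <- function(x, ...) {
  cat("Two-log-normal intensity fit --", x$method, "on",
      x$n_pooled, "frames\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("converged:", x$converged, "| residual norm:",
      format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' @export
predict.lognorm2_fit <- function(object, newdata = NULL,
                                 type = c("density", "counts"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$histogram$mids
  dens <- object$areas["low"] *
    dlnorm_mode(newdata, object$modes["low"], object$shapes["low"]) +
    object$areas["high"] *
    dlnorm_mode(newdata, object$modes["high"], object$shapes["high"])
  if (type == "density") return(unname(dens))
  bw <- mean(diff(object$histogram$breaks))
  unname(dens * object$n_pooled * bw)
}

#' @export
residuals.lognorm2_fit <- function(object, ...) {
  object$histogram$counts - object$fitted_counts
}

#' @export
fitted.lognorm2_fit <- function(object, ...) object$fitted_counts

#' @export
plot.lognorm2_fit <- function(x, main = "Pooled intensity histogram", ...) {
  h <- x$histogram
  graphics::plot(h$mids, h$counts, type = "h", lwd = 2, col = "grey70",
                 xlab = "Intensity (a.u.)", ylab = "Frames", main = main,
                 ...)
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 400)
  bw <- mean(diff(h$breaks))
  graphics::lines(xs, x$n_pooled * bw * x$areas["low"] *
                    dlnorm_mode(xs, x$modes["low"], x$shapes["low"]),
                  col = "steelblue", lwd = 2)
  graphics::lines(xs, x$n_pooled * bw * x$areas["high"] *
                    dlnorm_mode(xs, x$modes["high"], x$shapes["high"]),
                  col = "firebrick", lwd = 2)
  graphics::lines(xs, x$n_pooled * bw * predict(x, xs), lwd = 2)
  invisible(x)
}

#' Conformational populations from a two-log-normal fit
#'
#' Maps the fitted peak areas onto activation-loop populations according
#' to the construct polarity: for an `"inactive-low"` reporter the
#' quenched (low) peak reports the inactive conformation; for the
#' inverted `"inactive-high"` construct the assignments swap. Fractions
#' are reported in percent, with errors propagated from the fitted area
#' standard errors; fractions are not renormalized to sum to 100.
#'
#' @param fit a `"lognorm2_fit"`.
#' @param polarity `"inactive-low"` or `"inactive-high"` (aliases
#'   `"K224C/S283C"` and `"M373C/S283C"` are accepted).
#' @return An object of class `"conformational_populations"`: list with
#'   `pct_inactive`, `se_inactive`, `pct_active`, `se_active`, `polarity`.
#' @export
populations_from_fit <- function(fit,
                                 polarity = c("inactive-low",
                                              "inactive-high",
                                              "K224C/S283C",
                                              "M373C/S283C")) {
  stopifnot(inherits(fit, "lognorm2_fit"))
  polarity <- match.arg(polarity)
  polarity <- switch(polarity,
                     "K224C/S283C" = "inactive-low",
                     "M373C/S283C" = "inactive-high",
                     polarity)
  if (any(!is.finite(fit$areas))) stop("fit has no valid areas")
  inact <- if (polarity == "inactive-low") "low" else "high"
  act <- setdiff(c("low", "high"), inact)
  structure(list(pct_inactive = 100 * unname(fit$areas[inact]),
                 se_inactive = 100 * unname(fit$se_areas[inact]),
                 pct_active = 100 * unname(fit$areas[act]),
                 se_active = 100 * unname(fit$se_areas[act]),
                 polarity = polarity),
            class = "conformational_populations")
}

#' @export
print.conformational_populations <- function(x, ...) {
  cat(sprintf("Conformational populations (%s): inactive %.1f +/- %.1f %%, active %.1f +/- %.1f %%\n",
              x$polarity, x$pct_inactive, x$se_inactive,
              x$pct_active, x$se_active))
  invisible(x)
}
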