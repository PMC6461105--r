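#' Fit the full two-state analysis to an ensemble of traces
#'
#' The flagship estimator: pools the framewise intensities, fits the
#' two-log-normal histogram model, converts peak areas into
#' conformational populations (via the construct polarity), derives the
#' equilibrium constant and free energy, thresholds the traces at the
#' fitted density crossing, extracts dwell times of the
#' inactive-reporting state and fits the single-exponential exit rate,
#' then completes the kinetics by detailed balance.
#'
#' @param x a `"trace_ensemble"`, a trace data frame
#'   (`molecule_id`, `frame`, `intensity`), or a numeric matrix of
#'   intensities (frames x molecules).
#' @param polarity construct polarity; taken from the ensemble config if
#'   available.
#' @param temperature kelvin, for the free-energy conversion.
#' @param frame_interval seconds; taken from the ensemble if available.
#' @param rate_method dwell-rate estimator, `"mle"` or `"binned_lsq"`.
#' @param bins,breaks histogram binning, passed to [pool_histogram()].
#' @return An object of class `"two_state_fit"`: list with `histogram_fit`
#'   (a `"lognorm2_fit"`), `populations`, `equilibrium`
#'   (an `"equilibrium_result"`), `threshold`, `k_active`, `k_inactive`
#'   (both `"rate_estimate"`), `residence` (named vector, s), `n_dwells`,
#'   `polarity`, `temperature`.
#' @examples
#' \donttest{
#' ens <- simulate_ensemble(sim_config(two_state_rates(2.1, 2.4),
#'                                     n_molecules = 60, seed = 2))
#' fit <- two_state_fit(ens)
#' summary(fit)
#' }
#' @export
two_state_fit <- function(x, polarity = NULL, temperature = 298.15,
                          frame_interval = NULL,
                          rate_method = c("mle", "binned_lsq"),
                          bins = NULL, breaks = NULL) {
  rate_method <- match.arg(rate_method)
  if (inherits(x, "trace_ensemble")) {
    mat <- x$intensity
    if (is.null(polarity)) polarity <- x$config$polarity
    frame_interval <- x$config$frame_interval
  } else if (is.data.frame(x)) {
    need <- c("molecule_id", "frame", "intensity")
    if (!all(need %in% names(x)))
      stop("trace data frame needs columns ", paste(need, collapse = ", "))
    mols <- sort(unique(x$molecule_id))
    nf <- max(x$frame)
    mat <- matrix(NA_real_, nf, length(mols))
    for (j in seq_along(mols)) {
      sub <- x[x$molecule_id == mols[j], ]
      mat[sub$frame, j] <- sub$intensity
    }
  } else if (is.matrix(x)) {
    mat <- x
  } else stop("unsupported input of class ", paste(class(x), collapse = "/"))
  if (is.null(polarity)) polarity <- "inactive-low"
  if (is.null(frame_interval)) frame_interval <- 0.08

  hfit <- fit_two_lognormals(as.vector(mat), bins = bins, breaks = breaks)
  pops <- populations_from_fit(hfit, polarity)
  eq <- equilibrium_constant(pops, temperature = temperature)
  thr <- threshold_from_fit(hfit)
  labels <- assign_states(mat, thr, frame_interval)
  # the inactive conformation reports on the low-intensity state for
  # "inactive-low" polarity and on the high state otherwise
  inact_state <- if (pops$polarity == "inactive-low") "low" else "high"
  dwells <- extract_dwells(labels, inact_state,
                           frame_interval = frame_interval)
  ka <- fit_single_exponential(dwells, method = rate_method)
  ki <- derived_k_inactive(ka, eq)
  res <- residence_times(two_state_rates(ka$k, ki$k))
  structure(list(histogram_fit = hfit, populations = pops,
                 equilibrium = eq, threshold = thr, dwells = dwells,
                 k_active = ka, k_inactive = ki, residence = res,
                 n_dwells = ka$n_dwells, polarity = pops$polarity,
                 temperature = temperature),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  p <- x$populations
  cat("Two-state conformational fit\n")
  cat(sprintf("  populations: inactive %.1f +/- %.1f %%, active %.1f +/- %.1f %% (%s)\n",
              p$pct_inactive, p$se_inactive, p$pct_active, p$se_active,
              x$polarity))
  cat(sprintf("  K_eq = %.2f +/- %.2f;  dG = %.2f kcal/mol at %.2f K\n",
              x$equilibrium$K_eq, x$equilibrium$se, x$equilibrium$dG,
              x$temperature))
  cat(sprintf("  k_active = %.2f +/- %.2f s^-1 (n = %d dwells); k_inactive = %.2f +/- %.2f s^-1\n",
              x$k_active$k, x$k_active$se, x$n_dwells,
              x$k_inactive$k, x$k_inactive$se))
  cat(sprintf("  residence: inactive %.2f s, active %.2f s\n",
              x$residence["inactive"], x$residence["active"]))
  invisible(x)
}

#' @export
summary.two_state_fit <- function(object, ...) {
  print(object)
  cat("\nHistogram fit:\n")
  print(summary(object$histogram_fit))
  invisible(object)
}

#' @export
coef.two_state_fit <- function(object, ...) {
  c(pct_inactive = object$populations$pct_inactive,
    pct_active = object$populations$pct_active,
    K_eq = object$equilibrium$K_eq,
    dG = object$equilibrium$dG,
    k_active = object$k_active$k,
    k_inactive = object$k_inactive$k,
    threshold = as.numeric(object$threshold))
}

#' @export
plot.two_state_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$histogram_fit)
  graphics::abline(v = x$threshold, lty = 2)
  d <- x$dwells$duration[!x$dwells$censored]
  if (length(d) > 0) {
    h <- graphics::hist(d, breaks = 20, plot = FALSE)
    graphics::plot(h$mids, h$counts, type = "h", lwd = 3, col = "grey70",
                   xlab = "Dwell time (s)", ylab = "Count",
                   main = "Inactive-state dwells")
    xs <- seq(0, max(d), length.out = 200)
    bw <- mean(diff(h$breaks))
    graphics::lines(xs, length(d) * bw * x$k_active$k *
                      exp(-x$k_active$k * xs), col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Run the end-to-end analysis for a set of conditions
#'
#' Each condition is either a simulation recipe (analyzed with
#' [simulate_ensemble()] then [two_state_fit()]), a trace CSV file (read
#' with [read_traces()]), or printed populations (converted directly to
#' thermodynamics). Conditions fail independently: an error in one is
#' recorded in its `status` without aborting the others. Re-running with
#' identical configuration and seeds reproduces the bundle exactly.
#'
#' @param conditions named list; each element a list with fields
#'   `phosphorylation` (`"phos"`/`"unphos"`), `ligand` and one of:
#'   `populations = c(pct_inactive, pct_active)` (optionally
#'   `se = c(se_inactive, se_active)`); `simulate = list(k_active,
#'   k_inactive, n_molecules, n_frames, seed, polarity, ...)`; or
#'   `traces = "<csv path>"` with optional `polarity`.
#' @param temperature kelvin.
#' @return An object of class `"results_bundle"`: list with `conditions`
#'   (per-condition results incl. `status`), `thermo` (data frame of
#'   populations, K_eq, dG per condition), `independence` (when both
#'   phosphorylation states are present for a ligand and apo),
#'   `discrimination_table` ([reproduce_table2()] output), `temperature`.
#' @export
run_pipeline <- function(conditions, temperature = 298.15) {
  if (length(conditions) == 0L) {
    warning("empty condition list; returning empty bundle")
    return(structure(list(conditions = list(),
                          thermo = data.frame(),
                          independence = NULL,
                          discrimination_table = reproduce_table2(),
                          temperature = temperature),
                     class = "results_bundle"))
  }
  if (is.null(names(conditions)))
    names(conditions) <- paste0("condition_", seq_along(conditions))
  per <- list()
  thermo_rows <- list()
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    res <- tryCatch({
      if (!is.null(cond$populations)) {
        se <- if (!is.null(cond$se)) cond$se else c(0, 0)
        eq <- equilibrium_constant(cond$populations[1],
                                   cond$populations[2],
                                   se[1], se[2], temperature)
        list(status = "ok", source = "populations", equilibrium = eq,
             pct_inactive = cond$populations[1],
             pct_active = cond$populations[2])
      } else if (!is.null(cond$simulate)) {
        s <- cond$simulate
        cfg <- sim_config(
          two_state_rates(s$k_active, s$k_inactive),
          emission = if (!is.null(s$emission)) s$emission
                     else emission_model(),
          frame_interval = if (!is.null(s$frame_interval))
            s$frame_interval else 0.08,
          n_frames = if (!is.null(s$n_frames)) s$n_frames else 500,
          n_molecules = if (!is.null(s$n_molecules)) s$n_molecules else 100,
          polarity = if (!is.null(s$polarity)) s$polarity
                     else "inactive-low",
          seed = if (!is.null(s$seed)) s$seed else 1L)
        fit <- two_state_fit(simulate_ensemble(cfg),
                             temperature = temperature)
        list(status = "ok", source = "simulation", fit = fit,
             equilibrium = fit$equilibrium,
             pct_inactive = fit$populations$pct_inactive,
             pct_active = fit$populations$pct_active, seed = cfg$seed)
      } else if (!is.null(cond$traces)) {
        df <- read_traces(cond$traces)
        fit <- two_state_fit(df,
                             polarity = if (!is.null(cond$polarity))
                               cond$polarity else "inactive-low",
                             temperature = temperature)
        list(status = "ok", source = "traces", fit = fit,
             equilibrium = fit$equilibrium,
             pct_inactive = fit$populations$pct_inactive,
             pct_active = fit$populations$pct_active)
      } else stop("condition has none of populations/simulate/traces")
    }, error = function(e) list(status = "error",
                                message = conditionMessage(e)))
    per[[nm]] <- res
    if (identical(res$status, "ok")) {
      thermo_rows[[nm]] <- data.frame(
        condition = nm,
        phosphorylation = if (!is.null(cond$phosphorylation))
          cond$phosphorylation else NA_character_,
        ligand = if (!is.null(cond$ligand)) cond$ligand else NA_character_,
        pct_inactive = res$pct_inactive, pct_active = res$pct_active,
        K_eq = res$equilibrium$K_eq, se_K = res$equilibrium$se,
        dG = res$equilibrium$dG, se_dG = res$equilibrium$se_dG)
    }
  }
  thermo <- if (length(thermo_rows)) do.call(rbind, thermo_rows)
            else data.frame()
  indep <- NULL
  if (nrow(thermo) > 0 && !all(is.na(thermo$ligand))) {
    has_both_apo <- all(c("phos", "unphos") %in%
                          thermo$phosphorylation[thermo$ligand == "apo"])
    ligs <- setdiff(unique(thermo$ligand), c("apo", NA))
    complete <- vapply(ligs, function(l)
      all(c("phos", "unphos") %in%
            thermo$phosphorylation[thermo$ligand == l]), logical(1))
    if (has_both_apo && length(ligs) > 0 && all(complete))
      indep <- independence_check(thermo)
  }
  structure(list(conditions = per, thermo = thermo, independence = indep,
                 discrimination_table = reproduce_table2(),
                 temperature = temperature),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("Results bundle:", length(x$conditions), "conditions at",
      x$temperature, "K\n")
  if (nrow(x$thermo) > 0) {
    tab <- x$thermo
    tab$K_eq <- round(tab$K_eq, 1)
    tab$dG <- round(tab$dG, 1)
    print(tab[, c("condition", "ligand", "pct_inactive", "pct_active",
                  "K_eq", "dG")], row.names = FALSE, digits = 3)
  }
  if (!is.null(x$independence))
    cat(sprintf("max thermodynamic-cycle deviation: %.2f kcal/mol (%s)\n",
                x$independence$max_deviation,
                x$independence$worst_ligand))
  invisible(x)
}

#' Write a results bundle to JSON
#'
#' Serializes the thermodynamic table, independence check and
#' discrimination table (full precision) to a JSON report.
#'
#' @param bundle a `"results_bundle"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bundle <- function(bundle, file) {
  stopifnot(inherits(bundle, "results_bundle"))
  out <- list(temperature = bundle$temperature,
              thermo = bundle$thermo,
              independence = bundle$independence$table,
              discrimination_table = bundle$discrimination_table,
              statuses = lapply(bundle$conditions, `[[`, "status"))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
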