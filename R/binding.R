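#' Ligand discrimination between conformations
#'
#' Under conformational selection with saturating ligand, the shift of the
#' conformational equilibrium measures how differently the ligand binds
#' the two conformations: discrimination
#' `D = K_d,inactive / K_d,active = K_eq,apo / K_eq,ligand`. Values below 1
#' mean tighter binding to the inactive conformation; the fold preference
#' is `1/D`.
#'
#' @param K_eq_apo conformational equilibrium constant without ligand.
#' @param K_eq_ligand equilibrium constant with saturating ligand.
#' @return An object of class `"discrimination"`: list with
#'   `discrimination` and `fold_preference` (unrounded).
#' @examples
#' ligand_discrimination(23 / 77, 99)  # fold preference ~331
#' @export
ligand_discrimination <- function(K_eq_apo, K_eq_ligand) {
  stopifnot(K_eq_apo > 0, K_eq_ligand > 0)
  D <- K_eq_apo / K_eq_ligand
  structure(list(discrimination = D, fold_preference = 1 / D),
            class = "discrimination")
}

#' @export
print.discrimination <- function(x, ...) {
  cat(sprintf("Ligand discrimination: %.3f (fold preference %.0f)\n",
              x$discrimination, x$fold_preference))
  invisible(x)
}

#' Discrimination required to reach a target inactive population
#'
#' Given the starting conformational equilibrium, computes the ligand
#' discrimination needed to drive the inactive-conformation population to
#' `target_fraction_inactive`: the target equilibrium constant is
#' `f/(1-f)` and the required discrimination `K_eq,start / K_eq,target`.
#'
#' @param K_eq_start starting equilibrium constant (> 0).
#' @param target_fraction_inactive target inactive fraction, strictly
#'   between 0 and 1.
#' @return A `"discrimination"` object (unrounded values; see
#'   [format_discrimination()] for the display convention).
#' @examples
#' required_discrimination(23 / 77, 0.99)$fold_preference  # ~331
#' @export
required_discrimination <- function(K_eq_start, target_fraction_inactive) {
  stopifnot(K_eq_start > 0)
  f <- target_fraction_inactive
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("target fraction must lie strictly between 0 and 1 ",
         "(0 or 1 would require infinite discrimination)")
  K_target <- f / (1 - f)
  ligand_discrimination(K_eq_start, K_target)
}

#' Display rounding for discrimination tables
#'
#' Fold preference is printed to the nearest integer and the
#' discrimination as the reciprocal of the printed fold, rounded to three
#' decimals — the published convention (fold preference = 1/ligand
#' discrimination) applied at print precision. Unrounded values remain in
#' the `"discrimination"` object.
#'
#' @param x a `"discrimination"` object.
#' @return List with `discrimination` (3 d.p.) and `fold_preference`
#'   (integer).
#' @export
format_discrimination <- function(x) {
  stopifnot(inherits(x, "discrimination"))
  fold <- round(x$fold_preference)
  list(discrimination = round(1 / fold, 3), fold_preference = fold)
}

#' Overall dissociation constant of a two-conformation target
#'
#' For a conformational-selection binding model in the trace-ligand limit,
#' the apparent dissociation constant measured over both conformations is
#' the population-weighted harmonic combination
#' \deqn{K_{d,overall} = \frac{1 + K_{eq,free}}{1/K_{d,active} +
#'   K_{eq,free}/K_{d,inactive}}}
#' which reduces to `K_d,active` as `K_eq -> 0` and to `K_d,inactive` as
#' `K_eq -> Inf`, and always lies between the two conformation-specific
#' constants.
#'
#' @param kd_active,kd_inactive conformation-specific dissociation
#'   constants (any consistent concentration unit; vectorized).
#' @param keq_free conformational equilibrium constant of the free
#'   protein, `[inactive]/[active]`.
#' @return `K_d,overall` in the same units as the inputs.
#' @examples
#' kd_overall(200, 50, 23 / 77)  # ~118.3
#' @export
kd_overall <- function(kd_active, kd_inactive, keq_free) {
  if (any(!is.finite(kd_active)) || any(kd_active <= 0) ||
      any(!is.finite(kd_inactive)) || any(kd_inactive <= 0) ||
      any(!is.finite(keq_free)) || any(keq_free <= 0))
    stop("kd_active, kd_inactive and keq_free must all be positive")
  (1 + keq_free) / (1 / kd_active + keq_free / kd_inactive)
}

#' Numerical four-species mass-balance oracle for the overall K_d
#'
#' Independent check of [kd_overall()]: the free protein conformers `A`
#' and `I` (with `I/A = keq_free`) and their complexes `AL = A*L/kd_active`
#' and `IL = I*L/kd_inactive` are balanced at free-ligand concentration
#' `L` (trace-protein limit); the overall dissociation constant is the `L`
#' at which half the protein is bound, found by root bisection — no use of
#' the closed form.
#'
#' @inheritParams kd_overall
#' @param tol relative root tolerance.
#' @return Numerically determined `K_d,overall`.
#' @export
kd_overall_numeric <- function(kd_active, kd_inactive, keq_free,
                               tol = 1e-10) {
  bound_minus_half <- function(L) {
    b <- L / kd_active + keq_free * L / kd_inactive
    b / ((1 + keq_free) + b) - 0.5
  }
  lo <- min(kd_active, kd_inactive) * 1e-4
  hi <- max(kd_active, kd_inactive) * 1e4
  stats::uniroot(bound_minus_half, c(lo, hi), tol = tol * min(kd_active,
                                                             kd_inactive))$root
}

#' Overall-K_d surface over conformation-specific constants
#'
#' Evaluates [kd_overall()] on a log-spaced grid of `K_d,active` and
#' `K_d,inactive` at fixed free-protein equilibrium constant. The surface
#' is monotone nondecreasing along both axes and symmetric under axis swap
#' when `keq_free = 1`.
#'
#' @param keq_free free-protein equilibrium constant.
#' @param kd_active_range,kd_inactive_range length-2 ranges (concentration
#'   units); defaults 1e-9 to 1e-5 (1 nM to 10 uM in molar).
#' @param n grid points per axis (>= 2), log-spaced.
#' @return An object of class `"binding_surface"`: list with axis vectors
#'   `kd_active`, `kd_inactive`, the `keq_free` used, and matrix `K`
#'   (rows index `kd_active`).
#' @export
kd_surface <- function(keq_free, kd_active_range = c(1e-9, 1e-5),
                       kd_inactive_range = c(1e-9, 1e-5), n = 50) {
  stopifnot(n >= 2, length(kd_active_range) == 2,
            length(kd_inactive_range) == 2,
            all(kd_active_range > 0), all(kd_inactive_range > 0))
  ka <- exp(seq(log(kd_active_range[1]), log(kd_active_range[2]),
                length.out = n))
  ki <- exp(seq(log(kd_inactive_range[1]), log(kd_inactive_range[2]),
                length.out = n))
  K <- outer(ka, ki, function(a, i) kd_overall(a, i, keq_free))
  structure(list(kd_active = ka, kd_inactive = ki, keq_free = keq_free,
                 K = K),
            class = "binding_surface")
}

#' @export
print.binding_surface <- function(x, ...) {
  cat("K_d,overall surface:", length(x$kd_active), "x",
      length(x$kd_inactive), "grid, K_eq,free =",
      format(x$keq_free, digits = 4), "\n")
  cat("  K_d,overall range:", format(min(x$K), digits = 3), "-",
      format(max(x$K), digits = 3), "\n")
  invisible(x)
}

#' @export
plot.binding_surface <- function(x, nlevels = 12, ...) {
  graphics::filled.contour(log10(x$kd_active), log10(x$kd_inactive),
                           log10(x$K), nlevels = nlevels,
                           xlab = "log10 K_d,active",
                           ylab = "log10 K_d,inactive",
                           main = sprintf("log10 K_d,overall (K_eq = %.2f)",
                                          x$keq_free), ...)
  invisible(x)
}

#' Axis-parallel distances from a point to a contour of the surface
#'
#' For a point uphill of the `c`-contour of the overall-K_d surface,
#' computes how much `K_d,active` must improve (with `K_d,inactive` fixed)
#' to reach the contour, and vice versa, by closed-form inversion of the
#' overall-K_d expression. A contour that cannot be reached along an axis
#' (the axis asymptote lies below `c`... i.e. the limit of the surface
#' along that axis never drops to `c`) yields an infinite distance.
#'
#' @param kd_active,kd_inactive the point (concentration units).
#' @param c contour value of `K_d,overall` to reach (`< kd_overall` at the
#'   point).
#' @param keq_free free-protein equilibrium constant.
#' @return List with `delta_active`, `delta_inactive` (reductions in K_d,
#'   same units; `Inf` when unreachable), and the axis targets
#'   `target_active`, `target_inactive`.
#' @export
contour_gap_distances <- function(kd_active, kd_inactive, c, keq_free) {
  stopifnot(kd_active > 0, kd_inactive > 0, c > 0, keq_free > 0)
  k0 <- kd_overall(kd_active, kd_inactive, keq_free)
  if (k0 < c - 1e-12 * c)
    stop("point lies below the requested contour (kd_overall = ",
         format(k0), " < c = ", format(c), ")")
  if (abs(k0 - c) <= 1e-12 * c)
    return(list(delta_active = 0, delta_inactive = 0,
                target_active = kd_active, target_inactive = kd_inactive))
  # invert kd_overall for each coordinate with the other fixed
  inv_a <- (1 + keq_free) / c - keq_free / kd_inactive
  target_a <- if (inv_a > 0) 1 / inv_a else Inf
  inv_i <- (1 + keq_free) / c - 1 / kd_active
  target_i <- if (inv_i > 0) keq_free / inv_i else Inf
  list(delta_active = kd_active - target_a,
       delta_inactive = kd_inactive - target_i,
       target_active = target_a, target_inactive = target_i)
}

# distance gaps with finiteness check, used by the equidistant tracer
gap_or_na <- function(kd_active, kd_inactive, c, keq_free) {
  g <- contour_gap_distances(kd_active, kd_inactive, c, keq_free)
  c(active = g$delta_active, inactive = g$delta_inactive)
}

#' Equidistant line of a contour on the overall-K_d surface
#'
#' Traces the locus of points that are equidistant — in axis-parallel
#' `K_d` units — from the `c`-contour of the surface: at each height `v`
#' above `c`, the point on the `v`-contour where the distance needed to
#' reach the `c`-contour by improving only `K_d,active` equals the
#' distance by improving only `K_d,inactive`. When `keq_free = 1` the
#' curve is the diagonal `K_d,inactive = K_d,active` for every `c`.
#'
#' The surface is homogeneous of degree one in the concentration
#' variables, so a curve sampled at heights proportional to `c` is the
#' same curve rescaled. The sense in which tighter contours approach the
#' diagonal is therefore at fixed surface height: pass the same absolute
#' `levels` for a decreasing sequence of `c` and the deviation
#' `|log(K_d,inactive / K_d,active)|` at each level decreases.
#'
#' The distance metric is linear in concentration (differences of `K_d`);
#' the metric tag is recorded in the result.
#'
#' @param c contour value (concentration units).
#' @param keq_free free-protein equilibrium constant.
#' @param domain length-2 range of `K_d` values delimiting the traced
#'   region (both axes).
#' @param n_levels number of surface heights at which to locate the locus.
#' @param levels optional explicit surface heights (each `> c`) at which
#'   to locate the locus; overrides `n_levels`.
#' @return An object of class `"equidistant_curve"`: data frame with
#'   columns `level`, `kd_active`, `kd_inactive`, `residual`
#'   (`delta_active - delta_inactive` at the solution), plus attributes
#'   `contour`, `keq_free` and `metric = "linear-Kd"`. Empty (with a
#'   warning) when no locus lies in the domain.
#' @export
equidistant_line <- function(c, keq_free, domain = c(1e-9, 1e-5),
                             n_levels = 25, levels = NULL) {
  stopifnot(c > 0, keq_free > 0, length(domain) == 2, all(domain > 0))
  vmax <- kd_overall(domain[2], domain[2], keq_free)
  if (c >= vmax) {
    warning("contour value c is not below the achievable surface range ",
            "on this domain; empty curve")
    return(empty_equidistant(c, keq_free))
  }
  if (is.null(levels))
    levels <- exp(seq(log(c * 1.1), log(vmax), length.out = n_levels))
  levels <- levels[levels > c]
  if (length(levels) == 0L) {
    warning("no requested level lies above the contour; empty curve")
    return(empty_equidistant(c, keq_free))
  }
  rows <- vector("list", length(levels))
  for (ii in seq_along(levels)) {
    v <- levels[ii]
    # parameterize the v-contour by kd_active; kd_inactive follows
    ki_on <- function(ka) {
      inv <- (1 + keq_free) / v - 1 / ka
      ifelse(inv > 0, keq_free / inv, NA_real_)
    }
    h <- function(ka) {
      ki <- ki_on(ka)
      if (!is.finite(ki) || ki <= 0) return(NA_real_)
      g <- gap_or_na(ka, ki, c, keq_free)
      if (!all(is.finite(g))) return(NA_real_)
      g["active"] - g["inactive"]
    }
    ka_min <- v / (1 + keq_free) * (1 + 1e-9)
    kas <- exp(seq(log(max(ka_min, domain[1] * 1e-3)),
                   log(domain[2] * 1e3), length.out = 400))
    hv <- vapply(kas, h, numeric(1))
    okv <- which(is.finite(hv))
    sgn <- which(diff(sign(hv[okv])) != 0)
    if (length(sgn) == 0L) next
    j <- okv[sgn[1]]; j2 <- okv[sgn[1] + 1L]
    root <- stats::uniroot(h, c(kas[j], kas[j2]), tol = c * 1e-12)$root
    ki <- ki_on(root)
    g <- gap_or_na(root, ki, c, keq_free)
    rows[[ii]] <- data.frame(level = v, kd_active = root, kd_inactive = ki,
                             residual = unname(g["active"] - g["inactive"]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no equidistant locus found on the domain; empty curve")
    return(empty_equidistant(c, keq_free))
  }
  structure(out, contour = c, keq_free = keq_free, metric = "linear-Kd",
            class = c("equidistant_curve", "data.frame"))
}

empty_equidistant <- function(c, keq_free) {
  structure(data.frame(level = numeric(0), kd_active = numeric(0),
                       kd_inactive = numeric(0), residual = numeric(0)),
            contour = c, keq_free = keq_free, metric = "linear-Kd",
            class = c("equidistant_curve", "data.frame"))
}

#' Plateau mask of logarithmic sensitivities
#'
#' The relative response of the overall dissociation constant to each
#' conformation-specific constant is
#' `S_active = d log K_d,overall / d log K_d,active =
#'  (1/K_d,active) / (1/K_d,active + K_eq/K_d,inactive)` and
#' `S_inactive = 1 - S_active`. Regions where a sensitivity is small are
#' plateaus: improving that conformation-specific affinity yields little
#' change in the overall K_d. The returned mask is `TRUE` where both
#' sensitivities fall below the threshold (non-empty only for thresholds
#' above 0.5, since the two sensitivities sum to one); the per-axis
#' sensitivity matrices are attached for single-axis plateau analysis.
#'
#' @param grid a `"binding_surface"` from [kd_surface()].
#' @param threshold sensitivity threshold in `[0, 1]`.
#' @return Logical matrix (same shape as `grid$K`) with attributes
#'   `sens_active` and `sens_inactive`.
#' @export
plateau_mask <- function(grid, threshold) {
  stopifnot(inherits(grid, "binding_surface"),
            is.numeric(threshold), threshold >= 0)
  sa <- outer(grid$kd_active, grid$kd_inactive, function(a, i) {
    (1 / a) / (1 / a + grid$keq_free / i)
  })
  si <- 1 - sa
  structure(sa < threshold & si < threshold,
            sens_active = sa, sens_inactive = si)
}

#' Required-discrimination table for target inactive populations
#'
#' Reproduces the published required-discrimination table: for each
#' starting condition, the ligand discrimination (and fold preference)
#' needed to drive the inactive conformation to 99%, 95% and 90%
#' occupancy. Starting equilibrium constants default to the unrounded
#' population ratios of the printed occupancy table. The
#' unphosphorylated+TPX2 condition is emitted twice: once from the
#' measured ratio 46/56 and once from its inverse 56/46, because the
#' published row is only reproduced by the inverse (flagged in the
#' `convention` column); the other rows use the measured ratio.
#'
#' @param K_eq_map named list/vector of starting equilibrium constants;
#'   default uses the printed occupancy table.
#' @param targets target inactive fractions.
#' @return Data frame with one row per condition (and convention) per
#'   target: columns `condition`, `convention`, `target_fraction`,
#'   `discrimination`, `fold_preference` (unrounded) and
#'   `discrimination_display`, `fold_display` (published rounding).
#' @export
reproduce_table2 <- function(K_eq_map = NULL,
                             targets = c(0.99, 0.95, 0.90)) {
  if (is.null(K_eq_map)) {
    K_eq_map <- list(
      "Phosphorylated kinase" = 23 / 77,
      "Unphosphorylated kinase" = 52 / 46,
      "Phosphorylated + TPX2" = 14 / 86,
      "Unphosphorylated + TPX2" = 46 / 56)
  }
  rows <- list()
  for (cond in names(K_eq_map)) {
    ks <- K_eq_map[[cond]]
    conventions <- list(measured = ks)
    if (cond == "Unphosphorylated + TPX2")
      conventions <- list(measured = ks, `inverted-as-printed` = 1 / ks)
    for (cv in names(conventions)) {
      for (f in targets) {
        d <- required_discrimination(conventions[[cv]], f)
        disp <- format_discrimination(d)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, convention = cv, target_fraction = f,
          discrimination = d$discrimination,
          fold_preference = d$fold_preference,
          discrimination_display = disp$discrimination,
          fold_display = disp$fold_preference)
      }
    }
  }
  do.call(rbind, rows)
}
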