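# gas constant in kcal mol^-1 K^-1
RGAS_KCAL <- 1.9872e-3

#' Conformational equilibrium constant from populations
#'
#' `K_eq = [inactive] / [active]`, computed from the fitted percent
#' populations (unrounded), with the error propagated in quadrature of the
#' relative population errors. For display, reported errors carry a floor
#' of 0.1 (one unit in the last printed digit); the stored values keep
#' full precision.
#'
#' @param pop a `"conformational_populations"` object, or the percent
#'   inactive population (with `pct_active`, `se_inactive`, `se_active`
#'   supplied separately).
#' @param pct_active,se_inactive,se_active populations/errors in percent
#'   when `pop` is numeric.
#' @param temperature kelvin; stored for the free-energy conversion.
#' @return An object of class `"equilibrium_result"`: list with `K_eq`,
#'   `se`, `dG` (kcal mol^-1), `se_dG`, `temperature`.
#' @examples
#' equilibrium_constant(52, 46, 1, 2)  # K_eq ~ 1.13, printed 1.1
#' @export
equilibrium_constant <- function(pop, pct_active = NULL, se_inactive = 0,
                                 se_active = 0, temperature = 298.15) {
  if (inherits(pop, "conformational_populations")) {
    pi <- pop$pct_inactive; pa <- pop$pct_active
    si <- pop$se_inactive; sa <- pop$se_active
  } else {
    pi <- as.numeric(pop); pa <- as.numeric(pct_active)
    si <- se_inactive; sa <- se_active
  }
  if (!is.finite(pa) || pa <= 0)
    stop("active population must be > 0 (K_eq would be infinite)")
  if (!is.finite(pi) || pi <= 0)
    stop("inactive population must be > 0")
  K <- pi / pa
  se <- K * sqrt((si / pi)^2 + (sa / pa)^2)
  fe <- free_energy(K, se, temperature)
  structure(list(K_eq = K, se = se, dG = fe$dG, se_dG = fe$se,
                 temperature = temperature),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("K_eq = %.1f +/- %.1f;  dG(inactive-active) = %.1f kcal/mol at %.2f K\n",
              round(x$K_eq, 1), max(round(x$se, 1), 0.1), x$dG,
              x$temperature))
  invisible(x)
}

#' Conformational free energy from an equilibrium constant
#'
#' `dG_inactive-active = -RT ln(K_eq)` with
#' `R = 1.9872e-3 kcal mol^-1 K^-1`; the error is `RT * se/K_eq`.
#'
#' @param K_eq equilibrium constant (> 0).
#' @param se standard error of `K_eq`.
#' @param temperature kelvin (default 298.15, i.e. 25 C).
#' @return List with `dG` (kcal mol^-1) and `se`.
#' @examples
#' free_energy(23 / 77)$dG  # ~ +0.72 kcal/mol
#' @export
free_energy <- function(K_eq, se = 0, temperature = 298.15) {
  stopifnot(is.numeric(K_eq), all(K_eq > 0), temperature > 0)
  RT <- RGAS_KCAL * temperature
  list(dG = -RT * log(K_eq), se = RT * se / K_eq)
}

#' Free-energy difference between two conditions
#'
#' `ddG = dG_ref - dG_other` (e.g. the ligand effect
#' `ddG_ligand = dG_apo - dG_ligand`), with errors combined in quadrature.
#'
#' @param dG_ref,dG_other free energies (kcal mol^-1), either numeric or
#'   lists with `dG` and `se` as returned by [free_energy()].
#' @return List with `ddG` and `se`.
#' @export
ddG <- function(dG_ref, dG_other) {
  g1 <- if (is.list(dG_ref)) dG_ref else list(dG = dG_ref, se = 0)
  g2 <- if (is.list(dG_other)) dG_other else list(dG = dG_other, se = 0)
  stopifnot(is.finite(g1$dG), is.finite(g2$dG))
  list(ddG = g1$dG - g2$dG, se = sqrt(g1$se^2 + g2$se^2))
}

#' Compose a conformational free energy from cycle components
#'
#' Because the ligand and phosphorylation contributions are experimentally
#' independent, the free energy for any combination of ligand and
#' phosphorylation state decomposes as
#' `dG_eq = dG_apo_unphosphorylated - ddG_phosphorylation - ddG_ligand`,
#' with either delta equal to zero for unphosphorylated or unliganded
#' kinase.
#'
#' @param dG_apo_unphos free energy of the unliganded unphosphorylated
#'   enzyme (kcal mol^-1).
#' @param ddG_phosphorylation,ddG_ligand cycle components (kcal mol^-1).
#' @return Composed `dG_eq` (kcal mol^-1).
#' @export
compose_free_energy <- function(dG_apo_unphos, ddG_phosphorylation = 0,
                                ddG_ligand = 0) {
  stopifnot(is.finite(dG_apo_unphos), is.finite(ddG_phosphorylation),
            is.finite(ddG_ligand))
  dG_apo_unphos - ddG_phosphorylation - ddG_ligand
}

#' Printed activation-loop occupancy table
#'
#' The published single-molecule occupancy table for the Aurora-A kinase
#' domain: percent inactive/active activation-loop populations (with
#' propagated fitting errors) for both reporter constructs, both
#' phosphorylation states and saturating ligands, together with the
#' printed equilibrium constants and free energies. These printed
#' populations serve as inputs to the thermodynamic-cycle and binding
#' analyses.
#'
#' Note the printed `K_eq`/`dG` columns were computed from unrounded
#' fitted areas, so recomputing them from the printed (rounded)
#' populations reproduces them to within one unit in the last printed
#' digit, not always exactly.
#'
#' @return A data frame with columns `construct`, `phosphorylation`
#'   (`"phos"`/`"unphos"`), `ligand`, `pct_inactive`, `se_inactive`,
#'   `pct_active`, `se_active`, `K_eq_printed`, `se_K_printed`,
#'   `dG_printed`.
#' @export
aurora_loop_occupancy <- function() {
  data.frame(
    construct = c(rep("K224C/S283C", 8), rep("M373C/S283C", 2)),
    phosphorylation = c("phos", "phos", "phos", "phos",
                        "unphos", "unphos", "unphos", "unphos",
                        "phos", "unphos"),
    ligand = c("apo", "TPX2", "MLN8054", "CD532",
               "apo", "TPX2", "MLN8054", "CD532", "apo", "apo"),
    pct_inactive = c(23, 14, 43, 64, 52, 46, 77, 83, 25, 51),
    se_inactive = c(1, 2, 2, 1, 1, 2, 1, 1, 2, 2),
    pct_active = c(77, 86, 57, 36, 46, 56, 21, 13, 72, 47),
    se_active = c(1, 2, 2, 2, 2, 4, 1, 1, 1, 1),
    K_eq_printed = c(0.3, 0.2, 0.7, 1.8, 1.1, 0.8, 3.7, 6.3, 0.3, 1.1),
    se_K_printed = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.2, 0.6, 0.1, 0.1),
    dG_printed = c(0.7, 1.1, 0.2, -0.4, -0.1, 0.1, -0.8, -1.1, 0.6, -0.0))
}

#' Equilibrium thermodynamics for a table of conditions
#'
#' Computes `K_eq`, its propagated error, and `dG` at the given
#' temperature for every row of an occupancy table.
#'
#' @param occupancy data frame with columns `pct_inactive`, `se_inactive`,
#'   `pct_active`, `se_active` (e.g. [aurora_loop_occupancy()]).
#' @param temperature kelvin.
#' @return The input with added columns `K_eq`, `se_K`, `dG`, `se_dG`.
#' @export
thermo_table <- function(occupancy = aurora_loop_occupancy(),
                         temperature = 298.15) {
  res <- lapply(seq_len(nrow(occupancy)), function(i) {
    r <- occupancy[i, ]
    eq <- equilibrium_constant(r$pct_inactive, r$pct_active,
                               r$se_inactive, r$se_active, temperature)
    data.frame(K_eq = eq$K_eq, se_K = eq$se, dG = eq$dG, se_dG = eq$se_dG)
  })
  cbind(occupancy, do.call(rbind, res))
}

#' Thermodynamic-cycle independence check
#'
#' For every ligand present in both phosphorylation states, computes the
#' ligand effect `ddG_ligand = dG_apo - dG_ligand` in each state and
#' reports the per-ligand deviation
#' `|ddG_ligand(phos) - ddG_ligand(unphos)|`. A small maximum deviation is
#' the signature that the ligand effect on the conformational equilibrium
#' is independent of phosphorylation.
#'
#' @param tab data frame with columns `phosphorylation`
#'   (`"phos"`/`"unphos"`), `ligand` (with `"apo"` rows present for both
#'   states) and `dG` (kcal mol^-1).
#' @return List with `max_deviation` (kcal mol^-1), `worst_ligand`, and
#'   `table` (per-ligand `ddG` in each state plus deviation).
#' @export
independence_check <- function(tab) {
  stopifnot(all(c("phosphorylation", "ligand", "dG") %in% names(tab)))
  ligands <- setdiff(unique(tab$ligand), "apo")
  get_dG <- function(ph, lig) {
    v <- tab$dG[tab$phosphorylation == ph & tab$ligand == lig]
    if (length(v) == 0L)
      stop("missing condition: ", ph, " / ", lig)
    v[1]
  }
  rows <- lapply(ligands, function(lig) {
    dd_p <- get_dG("phos", "apo") - get_dG("phos", lig)
    dd_u <- get_dG("unphos", "apo") - get_dG("unphos", lig)
    data.frame(ligand = lig, ddG_ligand_phos = dd_p,
               ddG_ligand_unphos = dd_u, deviation = abs(dd_p - dd_u))
  })
  res <- do.call(rbind, rows)
  i <- which.max(res$deviation)
  list(max_deviation = res$deviation[i], worst_ligand = res$ligand[i],
       table = res)
}

#' Per-ligand phosphorylation free-energy shift
#'
#' `ddG_phosphorylation = dG(unphos, ligand) - dG(phos, ligand)` for each
#' ligand (including apo). Constancy of this quantity across ligands is
#' the complementary face of the independence of the thermodynamic cycle.
#'
#' @inheritParams independence_check
#' @return Data frame with columns `ligand` and `ddG_phosphorylation`.
#' @export
phosphorylation_shift <- function(tab) {
  stopifnot(all(c("phosphorylation", "ligand", "dG") %in% names(tab)))
  ligands <- unique(tab$ligand)
  rows <- lapply(ligands, function(lig) {
    u <- tab$dG[tab$phosphorylation == "unphos" & tab$ligand == lig][1]
    p <- tab$dG[tab$phosphorylation == "phos" & tab$ligand == lig][1]
    if (is.na(u) || is.na(p)) return(NULL)
    data.frame(ligand = lig, ddG_phosphorylation = u - p)
  })
  do.call(rbind, rows)
}
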