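# One-dimensional membrane surrogate: a smooth double-well-plus-barrier
# free-energy profile along the membrane normal (two headgroup wells
# flanking a hydrophobic-core barrier) and a deterministic map from
# sequence features to its parameters.

#' Construct a 1-D membrane potential
#'
#' `U(z) = -w1 g(z; z_entry, s_w) - w2 g(z; z_exit, s_w) + B g(z; z_c, s_b)`
#' with Gaussian bumps `g`: attractive headgroup wells at the entry and
#' exit planes and a repulsive hydrophobic-core barrier between them.
#' Energies in kJ mol^-1, lengths in nm.
#'
#' @param barrier_height core barrier height B >= 0 (kJ mol^-1).
#' @param entry,exit membrane entry/exit coordinates (nm); `exit = Inf`
#'   gives an unbounded (e.g. flat) landscape with no exit event.
#' @param well_depth headgroup well depth (kJ mol^-1), applied to both
#'   leaflets.
#' @param well_sigma,barrier_sigma Gaussian widths (nm).
#' @param label free-text identifier.
#' @return An object of class `membrane_potential`.
#' @export
membrane_potential <- function(barrier_height, entry = 1, exit = 5,
                               well_depth = 20, well_sigma = 0.35,
                               barrier_sigma = 1.6, label = "membrane") {
  if (barrier_height < 0) stop_validation("barrier_height must be >= 0")
  if (is.finite(exit) && exit <= entry) stop_validation("exit must be > entry")
  structure(list(barrier_height = barrier_height, entry = entry, exit = exit,
                 center = if (is.finite(exit)) (entry + exit) / 2 else entry + 2,
                 well_depth = well_depth, well_sigma = well_sigma,
                 barrier_sigma = barrier_sigma, label = label,
                 form = "double-well-plus-gaussian-barrier"),
            class = "membrane_potential")
}

#' A flat (zero-force) potential
#'
#' The analytic control landscape: no wells, no barrier, no exit event.
#' A particle pulled across it at constant velocity settles to a steady
#' state in which the mean spring force equals friction x velocity.
#'
#' @return A `membrane_potential` with zero energy everywhere.
#' @export
flat_potential <- function() {
  membrane_potential(0, entry = 1, exit = Inf, well_depth = 0,
                     label = "flat")
}

#' @export
print.membrane_potential <- function(x, ...) {
  cat(sprintf(paste0("membrane potential '%s': barrier %.1f kJ/mol, wells ",
                     "%.1f kJ/mol at z = %.1f / %s nm\n"),
              x$label, x$barrier_height, x$well_depth, x$entry,
              format(x$exit)))
  invisible(x)
}

#' Potential energy at coordinate z
#' @param pot a `membrane_potential`.
#' @param z coordinate(s), nm.
#' @return Energy (kJ mol^-1), vectorized over `z`.
#' @export
potential_energy <- function(pot, z) {
  g <- function(mu, s) exp(-(z - mu)^2 / (2 * s^2))
  u <- -pot$well_depth * g(pot$entry, pot$well_sigma) +
    pot$barrier_height * g(pot$center, pot$barrier_sigma)
  if (is.finite(pot$exit)) {
    u <- u - pot$well_depth * g(pot$exit, pot$well_sigma)
  }
  u
}

#' Deterministic force -dU/dz at coordinate z
#' @inheritParams potential_energy
#' @return Force (kJ mol^-1 nm^-1), vectorized over `z`.
#' @export
potential_force <- function(pot, z) {
  dg <- function(mu, s) -(z - mu) / s^2 * exp(-(z - mu)^2 / (2 * s^2))
  f <- pot$well_depth * dg(pot$entry, pot$well_sigma) -
    pot$barrier_height * dg(pot$center, pot$barrier_sigma)
  if (is.finite(pot$exit)) {
    f <- f + pot$well_depth * dg(pot$exit, pot$well_sigma)
  }
  f
}

# Upper bound on |U''| used by the integrator stability check.
max_curvature <- function(pot) {
  pot$barrier_height / pot$barrier_sigma^2 +
    2 * pot$well_depth / pot$well_sigma^2
}

#' Coefficients mapping sequence features to the membrane potential
#'
#' Barrier height is an affine function of three features: hydrophobic
#' fraction (more hydrophobic, lower barrier), absolute net charge per
#' residue (desolvation penalty of buried charge) and the charged-position
#' dispersion of [charge_dispersion()] (well-dispersed charges can pair
#' with headgroups on both leaflets, lowering the barrier; the feature is
#' small when dispersion is good). Headgroup wells deepen with charged
#' fraction. All coefficients in kJ mol^-1.
#'
#' @param intercept baseline barrier for a feature-free sequence
#'   (default 1230).
#' @param hydrophobic barrier reduction per unit hydrophobic fraction
#'   (default 600).
#' @param charge barrier increase per unit |net charge| / length
#'   (default 400).
#' @param dispersion barrier increase per unit dispersion feature
#'   (default 700); set to 0 for a position-insensitive mapping.
#' @param well_intercept,well_charge headgroup well depth: intercept plus
#'   slope on charged fraction (defaults 20 and 30).
#' @param min_barrier floor on the mapped barrier (default 50).
#' @return A list of class `potential_mapping`.
#' @export
potential_mapping <- function(intercept = 1230, hydrophobic = 600,
                              charge = 400, dispersion = 700,
                              well_intercept = 20, well_charge = 30,
                              min_barrier = 50) {
  structure(list(intercept = intercept, hydrophobic = hydrophobic,
                 charge = charge, dispersion = dispersion,
                 well_intercept = well_intercept, well_charge = well_charge,
                 min_barrier = min_barrier),
            class = "potential_mapping")
}

#' Charged-position dispersion feature
#'
#' Sum of two position-only statistics of the charged residues (R, K, H, D,
#' E): the length of the mean unit vector of charged positions on an ideal
#' helical wheel (100 degrees per residue) - small when charges are spread
#' evenly around the helix - and the mean absolute deviation of the sorted
#' charged positions from an even-spacing template, normalized by the mean
#' spacing. Both terms are zero-ish for well-dispersed arrangements, so a
#' LOW value means well-dispersed charges. Sequences without charged
#' residues score 0.
#'
#' @inheritParams classify_residues
#' @return Non-negative dispersion feature (dimensionless).
#' @export
charge_dispersion <- function(seq) {
  chg <- charged_positions(seq)
  nc <- nrow(chg)
  if (nc == 0L) return(0)
  L <- classify_residues(seq)$length
  p <- sort(chg$position)
  ang <- (p - 1) * 100 * pi / 180
  wheel <- sqrt(sum(cos(ang))^2 + sum(sin(ang))^2) / nc
  template <- (seq_len(nc) - 0.5) * L / nc
  spacing <- mean(abs(p - template)) / (L / nc)
  wheel + spacing
}

#' Map a peptide sequence to its surrogate membrane potential
#'
#' @inheritParams classify_residues
#' @param mapping a [potential_mapping()].
#' @return A [membrane_potential()] labelled with the peptide id.
#' @export
sequence_to_potential <- function(seq, mapping = potential_mapping()) {
  seq <- as_single_peptide(seq)
  cls <- classify_residues(seq)
  hyd_frac <- cls$n_hydrophobic / cls$length
  net_charge <- cls$n_positive - cls$n_negative
  disp <- charge_dispersion(seq)
  barrier <- mapping$intercept - mapping$hydrophobic * hyd_frac +
    mapping$charge * abs(net_charge) / cls$length +
    mapping$dispersion * disp
  barrier <- max(barrier, mapping$min_barrier)
  charged_frac <- (cls$n_positive + cls$n_negative) / cls$length
  well <- mapping$well_intercept + mapping$well_charge * charged_frac
  membrane_potential(barrier_height = barrier, well_depth = well,
                     label = names(seq))
}
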