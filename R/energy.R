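# Coulomb constant in kcal*Angstrom/(mol*e^2)
.coulomb_k <- 332.0637

# Wimley-White interface scale: whole-residue transfer free energies,
# water -> POPC bilayer interface, kcal/mol (negative = partitions into the
# membrane). Charged residues at their neutral-pH charge state.
.ww_interface <- c(
  ALA =  0.17, ARG =  0.81, ASN =  0.42, ASP =  1.23, CYS = -0.24,
  GLN =  0.58, GLU =  2.02, GLY =  0.01, HIS =  0.17, ILE = -0.31,
  LEU = -0.56, LYS =  0.99, MET = -0.23, PHE = -1.13, PRO =  0.45,
  SER =  0.13, THR =  0.14, TRP = -1.85, TYR = -0.94, VAL =  0.07
)

.formal_charges <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0)

#' Parameters of the coarse-grained membrane energy function
#'
#' The energy of a [cg_structure()] is the sum of five transparent terms:
#' membrane burial (per-residue transfer free energy times a smooth membrane
#' depth switch on the side-chain centroid), screened Coulomb electrostatics
#' with a distance-dependent dielectric between charged centroids, an 8-6
#' contact attraction between centroids, a harmonic excluded-volume repulsion
#' between C-alpha beads, and ligand interaction (electrostatic + contact
#' between rigid hetero beads and residue centroids). Every constant is a
#' parameter here; see the methods vignette for the functional forms.
#'
#' @param membrane_z_min,membrane_z_max Membrane slab bounds along z, Angstrom.
#' @param hydrophobicity_scale Named vector, 3-letter code to transfer free
#'   energy (kcal/mol); default Wimley-White interface scale.
#' @param residue_charges Named vector of formal charges at neutral pH;
#'   residues not listed are neutral.
#' @param dielectric_eps0 Dielectric at contact (dimensionless, >= 1).
#' @param dielectric_slope Dielectric growth per Angstrom.
#' @param contact_epsilon Contact well scale, kcal/mol.
#' @param contact_radius Contact reference distance, Angstrom.
#' @param repulsion_radius Hard-core onset distance for C-alpha pairs, Angstrom.
#' @param repulsion_k Harmonic repulsion constant, kcal/mol/A^2.
#' @param min_seq_separation Minimum |i - j| along the chain for pair terms
#'   (pairs on different chains always qualify).
#' @param pair_cutoff Pair-interaction cutoff, Angstrom; electrostatic and
#'   contact terms are switched smoothly to zero over the
#'   `switch_width` Angstrom below the cutoff.
#' @param switch_width Width of the smooth truncation window, Angstrom.
#' @return A list of class `energy_params`.
#' @export
energy_params <- function(membrane_z_min = -15, membrane_z_max = 15,
                          hydrophobicity_scale = .ww_interface,
                          residue_charges = .formal_charges,
                          dielectric_eps0 = 4, dielectric_slope = 1,
                          contact_epsilon = 0.3, contact_radius = 5.0,
                          repulsion_radius = 4.0, repulsion_k = 10,
                          min_seq_separation = 3L, pair_cutoff = 12,
                          switch_width = 2) {
  p <- list(membrane_z_min = membrane_z_min, membrane_z_max = membrane_z_max,
            hydrophobicity_scale = hydrophobicity_scale,
            residue_charges = residue_charges,
            dielectric_eps0 = dielectric_eps0, dielectric_slope = dielectric_slope,
            contact_epsilon = contact_epsilon, contact_radius = contact_radius,
            repulsion_radius = repulsion_radius, repulsion_k = repulsion_k,
            min_seq_separation = as.integer(min_seq_separation),
            pair_cutoff = pair_cutoff, switch_width = switch_width)
  validate_energy_params(p)
  structure(p, class = "energy_params")
}

validate_energy_params <- function(p) {
  stopifnot(p$membrane_z_min < p$membrane_z_max,
            p$contact_radius > p$repulsion_radius, p$repulsion_radius > 0,
            p$dielectric_eps0 >= 1,
            p$pair_cutoff > p$contact_radius,
            p$switch_width > 0, p$switch_width < p$pair_cutoff)
  invisible(p)
}

# smoothstep: 1 for t <= 0, 0 for t >= 1, C1 in between
.smoothstep_down <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  1 - (3 * t^2 - 2 * t^3)
}

# membrane depth factor: 1 inside [z_min, z_max], smoothly 0 by 6 A outside
burial_switch <- function(z, p) {
  d_out <- pmax(p$membrane_z_min - z, z - p$membrane_z_max, 0)
  .smoothstep_down(d_out / 6)
}

# truncation switch on pair distances
pair_switch <- function(r, p) {
  .smoothstep_down((r - (p$pair_cutoff - p$switch_width)) / p$switch_width)
}

# screened Coulomb between unit charges q1*q2 at distance r (no switch)
.coulomb_pair <- function(q12, r, p) {
  .coulomb_k * q12 / ((p$dielectric_eps0 + p$dielectric_slope * r) * r)
}

# 8-6 contact potential; <= 0 for r >= contact_radius, repulsive core below
.contact_pair <- function(r, p) {
  x <- p$contact_radius / r
  p$contact_epsilon * (x^8 - 2 * x^6)
}

#' Evaluate the coarse-grained energy of a structure
#'
#' @param s A [cg_structure()].
#' @param p An [energy_params()] list.
#' @return A tibble of class `energy_breakdown` with one row and columns
#'   `total`, `membrane_burial`, `electrostatic`, `contact`,
#'   `excluded_volume`, `ligand_interaction` (kcal/mol). `total` is the exact
#'   sum of the five components.
#' @export
evaluate_energy <- function(s, p = energy_params()) {
  validate_energy_params(p)
  if (nrow(s) < 1) abort("cannot evaluate an empty structure")
  ca <- ca_matrix(s)
  cen <- cen_matrix(s)
  if (!all(is.finite(ca))) {
    abort(paste0("non-finite C-alpha coordinate at residue row ",
                 which(!is.finite(rowSums(ca)))[1]))
  }
  has_cen <- !is.na(cen[, 1])
  if (any(has_cen) && !all(is.finite(cen[has_cen, ]))) {
    abort(paste0("non-finite centroid coordinate at residue row ",
                 which(has_cen & !is.finite(rowSums(cen)))[1]))
  }

  h <- unname(p$hydrophobicity_scale[s$resname]); h[is.na(h)] <- 0
  q <- unname(p$residue_charges[s$resname]); q[is.na(q)] <- 0

  e_burial <- sum(h[has_cen] * burial_switch(cen[has_cen, 3], p))

  # eligible residue pairs: both centroids present, sequence separation rule
  n <- nrow(s)
  e_elec <- 0; e_contact <- 0
  idx <- which(has_cen)
  if (length(idx) >= 2) {
    cm <- cen[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(cm))
    sep_ok <- .seq_sep_ok(s, idx, p$min_seq_separation)
    ut <- upper.tri(D)
    ok <- ut & sep_ok & D <= p$pair_cutoff & D > 0
    if (any(ok)) {
      r <- D[ok]
      sw <- pair_switch(r, p)
      qq <- outer(q[idx], q[idx])[ok]
      charged <- qq != 0
      if (any(charged)) {
        e_elec <- sum(.coulomb_pair(qq[charged], r[charged], p) * sw[charged])
      }
      e_contact <- sum(.contact_pair(r, p) * sw)
    }
  }

  # C-alpha harmonic excluded volume
  e_rep <- 0
  if (n >= 2) {
    Dca <- as.matrix(stats::dist(ca))
    sep_ok_ca <- .seq_sep_ok(s, seq_len(n), p$min_seq_separation)
    ok <- upper.tri(Dca) & sep_ok_ca & Dca < p$repulsion_radius
    if (any(ok)) e_rep <- sum(p$repulsion_k * (p$repulsion_radius - Dca[ok])^2)
  }

  # ligand interaction: hetero beads vs residue centroids
  e_lig <- 0
  het <- cg_hetero(s)
  if (nrow(het) > 0 && length(idx) > 0) {
    hx <- as.matrix(het[, c("x", "y", "z")])
    cm <- cen[idx, , drop = FALSE]
    for (k in seq_len(nrow(het))) {
      dv <- sweep(cm, 2, hx[k, ])
      r <- sqrt(rowSums(dv^2))
      inr <- r <= p$pair_cutoff & r > 0
      if (!any(inr)) next
      rr <- r[inr]; sw <- pair_switch(rr, p)
      qq <- het$charge[k] * q[idx][inr]
      e_lig <- e_lig + sum(.coulomb_pair(qq, rr, p) * sw) +
        sum(.contact_pair(rr, p) * sw)
    }
  }

  out <- tibble(total = e_burial + e_elec + e_contact + e_rep + e_lig,
                membrane_burial = e_burial, electrostatic = e_elec,
                contact = e_contact, excluded_volume = e_rep,
                ligand_interaction = e_lig)
  class(out) <- c("energy_breakdown", class(out))
  out
}

# logical matrix over index set: TRUE where the pair passes the sequence
# separation rule (different chains always pass)
.seq_sep_ok <- function(s, idx, min_sep) {
  pos <- s$resno[idx]
  ch <- s$chain[idx]
  sep <- abs(outer(pos, pos, "-"))
  same <- outer(ch, ch, "==")
  (!same) | (sep >= min_sep)
}

#' Energy of a frame relative to a reference frame
#'
#' @param frame,reference [cg_structure()] objects evaluable under `p`.
#' @param p [energy_params()].
#' @return `total(frame) - total(reference)`, kcal/mol.
#' @export
relative_energy <- function(frame, reference, p = energy_params()) {
  evaluate_energy(frame, p)$total - evaluate_energy(reference, p)$total
}
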