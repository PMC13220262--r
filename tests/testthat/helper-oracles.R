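# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written as plain scalar loops / closed
# forms, independent of the package's vectorised implementations.

# column accessors used across test files
residue_keys_public <- function(s) paste(s$chain, s$resno, s$ins, sep = "|")
ca_xyz <- function(s) unname(as.matrix(s[, c("ca_x", "ca_y", "ca_z")]))
cen_xyz <- function(s) unname(as.matrix(s[, c("cen_x", "cen_y", "cen_z")]))

# random coarse-grained structure: n residues on a loose 3D random walk
random_structure <- function(n, seed, spread = 4, charged_every = 4) {
  set.seed(seed)
  aa <- c("ALA", "LEU", "TRP", "SER", "LYS", "GLU", "PHE", "ARG", "ASP", "GLY")
  resname <- sample(aa, n, replace = TRUE)
  ca <- matrix(cumsum(stats::rnorm(3 * n, 0, spread)), ncol = 3)
  dir <- matrix(stats::rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  cen <- ca + 2.0 * dir
  is_gly <- resname == "GLY"
  cen[is_gly, ] <- NA_real_
  cg_structure(tibble::tibble(
    chain = "A", resno = seq_len(n), ins = "", resname = resname,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    cen_x = cen[, 1], cen_y = cen[, 2], cen_z = cen[, 3],
    n_sc = ifelse(is_gly, 0L, 3L)
  ), label = paste0("rand", seed))
}

# brute-force double-loop energy oracle: mirrors the documented functional
# forms term by term with scalar arithmetic
oracle_energy <- function(s, p) {
  n <- nrow(s)
  h <- p$hydrophobicity_scale
  q <- p$residue_charges
  hv <- function(i) { v <- unname(h[s$resname[i]]); if (length(v) == 0 || is.na(v)) 0 else v }
  qv <- function(i) { v <- unname(q[s$resname[i]]); if (length(v) == 0 || is.na(v)) 0 else v }
  fz <- function(z) {
    d <- max(p$membrane_z_min - z, z - p$membrane_z_max, 0)
    t <- min(max(d / 6, 0), 1)
    1 - (3 * t^2 - 2 * t^3)
  }
  swf <- function(r) {
    t <- (r - (p$pair_cutoff - p$switch_width)) / p$switch_width
    t <- min(max(t, 0), 1)
    1 - (3 * t^2 - 2 * t^3)
  }
  cenv <- function(i) c(s$cen_x[i], s$cen_y[i], s$cen_z[i])
  cav <- function(i) c(s$ca_x[i], s$ca_y[i], s$ca_z[i])

  e_bur <- 0
  for (i in seq_len(n)) {
    if (!is.na(s$cen_x[i])) e_bur <- e_bur + hv(i) * fz(s$cen_z[i])
  }
  e_el <- 0; e_ct <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.na(s$cen_x[i]) || is.na(s$cen_x[j])) next
    same_chain <- s$chain[i] == s$chain[j]
    if (same_chain && abs(s$resno[i] - s$resno[j]) < p$min_seq_separation) next
    r <- sqrt(sum((cenv(i) - cenv(j))^2))
    if (r > p$pair_cutoff || r == 0) next
    sw <- swf(r)
    qq <- qv(i) * qv(j)
    if (qq != 0) {
      e_el <- e_el + 332.0637 * qq /
        ((p$dielectric_eps0 + p$dielectric_slope * r) * r) * sw
    }
    x <- p$contact_radius / r
    e_ct <- e_ct + p$contact_epsilon * (x^8 - 2 * x^6) * sw
  }
  e_rep <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_chain <- s$chain[i] == s$chain[j]
    if (same_chain && abs(s$resno[i] - s$resno[j]) < p$min_seq_separation) next
    r <- sqrt(sum((cav(i) - cav(j))^2))
    if (r < p$repulsion_radius && r > 0) {
      e_rep <- e_rep + p$repulsion_k * (p$repulsion_radius - r)^2
    }
  }
  e_lig <- 0
  het <- cg_hetero(s)
  if (nrow(het) > 0) {
    for (k in seq_len(nrow(het))) for (i in seq_len(n)) {
      if (is.na(s$cen_x[i])) next
      r <- sqrt(sum((cenv(i) - c(het$x[k], het$y[k], het$z[k]))^2))
      if (r > p$pair_cutoff || r == 0) next
      sw <- swf(r)
      qq <- het$charge[k] * qv(i)
      if (qq != 0) {
        e_lig <- e_lig + 332.0637 * qq /
          ((p$dielectric_eps0 + p$dielectric_slope * r) * r) * sw
      }
      x <- p$contact_radius / r
      e_lig <- e_lig + p$contact_epsilon * (x^8 - 2 * x^6) * sw
    }
  }
  e_bur + e_el + e_ct + e_rep + e_lig
}

# random proper rotation + translation
random_rigid_transform <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  list(rotation = R, translation = stats::rnorm(3, 0, 10))
}

# 3-residue hand-written PDB (GLY, ALA, TRP with full side chains)
write_three_residue_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  N   ALA A   2       3.300   1.500   0.200  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       4.000   2.800   0.300  1.00  0.00           C",
    "ATOM      7  CB  ALA A   2       5.200   2.700   1.250  1.00  0.00           C",
    "ATOM      8  C   ALA A   2       4.500   3.200  -1.100  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       4.600   2.400  -2.000  1.00  0.00           O",
    "ATOM     10  N   TRP A   3       4.800   4.500  -1.300  1.00  0.00           N",
    "ATOM     11  CA  TRP A   3       5.300   5.000  -2.600  1.00  0.00           C",
    "ATOM     12  CB  TRP A   3       6.800   4.700  -2.800  1.00  0.00           C",
    "ATOM     13  CG  TRP A   3       7.300   5.200  -4.100  1.00  0.00           C",
    "ATOM     14  CD1 TRP A   3       7.200   6.500  -4.500  1.00  0.00           C",
    "ATOM     15  CD2 TRP A   3       8.000   4.500  -5.200  1.00  0.00           C",
    "ATOM     16  NE1 TRP A   3       7.800   6.600  -5.800  1.00  0.00           N",
    "ATOM     17  CE2 TRP A   3       8.300   5.400  -6.200  1.00  0.00           C",
    "ATOM     18  CE3 TRP A   3       8.400   3.200  -5.500  1.00  0.00           C",
    "ATOM     19  CZ2 TRP A   3       9.000   5.000  -7.400  1.00  0.00           C",
    "ATOM     20  CZ3 TRP A   3       9.100   2.800  -6.600  1.00  0.00           C",
    "ATOM     21  CH2 TRP A   3       9.400   3.700  -7.600  1.00  0.00           C",
    "ATOM     22  C   TRP A   3       4.500   4.400  -3.800  1.00  0.00           C",
    "ATOM     23  O   TRP A   3       4.600   4.900  -4.900  1.00  0.00           O",
    "END"
  )
  writeLines(lines, path)
  path
}

# burial-only parameter set used by the planted-contribution fixtures:
# the planted lysine costs +3 kcal/mol inside the slab, alanine +0.3,
# everything else is membrane-silent
planted_params <- function(z_min = 22, z_max = 32) {
  energy_params(
    membrane_z_min = z_min, membrane_z_max = z_max,
    hydrophobicity_scale = c(LYS = 3, ALA = 0.3),
    residue_charges = c(NONE = 0),
    contact_epsilon = 0, repulsion_k = 0
  )
}

# two-state hairpin whose tip residue traverses the membrane slab only in
# mid-pathway frames (hinge flip of 180 degrees); tip is made LYS
planted_toy <- function(seed = 1) {
  toy <- make_toy_two_state(n_res = 40, hinge_angle = 180, seed = seed,
                            switch_flip = FALSE)
  tip <- nrow(toy$inactive)
  toy$inactive$resname[tip] <- "LYS"
  toy$active$resname[tip] <- "LYS"
  toy$tip <- tip
  toy
}

planted_morph_config <- function(seed = 1) {
  morph_config(n_steps = 120, relax_iters = 4, step_size = 0.15,
               k_steer = 2000, seed = seed)
}
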