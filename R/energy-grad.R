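# Analytic gradient of the CG energy with respect to bead coordinates.
# Returns list(ca = n x 3, cen = n x 3); rows for absent centroids are zero.
# Hetero beads are rigid and carry no gradient entries.
cg_energy_gradient <- function(s, p) {
  n <- nrow(s)
  ca <- ca_matrix(s)
  cen <- cen_matrix(s)
  has_cen <- !is.na(cen[, 1])
  g_ca <- matrix(0, n, 3)
  g_cen <- matrix(0, n, 3)

  h <- unname(p$hydrophobicity_scale[s$resname]); h[is.na(h)] <- 0
  q <- unname(p$residue_charges[s$resname]); q[is.na(q)] <- 0

  # burial: depends on centroid z only
  if (any(has_cen)) {
    z <- cen[has_cen, 3]
    g_cen[has_cen, 3] <- g_cen[has_cen, 3] + h[has_cen] * .burial_switch_dz(z, p)
  }

  # centroid pair terms (electrostatic + contact)
  idx <- which(has_cen)
  if (length(idx) >= 2) {
    X <- cen[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(X))
    mask <- .seq_sep_ok(s, idx, p$min_seq_separation) & D <= p$pair_cutoff & D > 0
    diag(mask) <- FALSE
    if (any(mask)) {
      dEdr <- matrix(0, length(idx), length(idx))
      r <- D[mask]
      sw <- pair_switch(r, p)
      dsw <- .pair_switch_dr(r, p)
      qq <- outer(q[idx], q[idx])[mask]
      raw_e <- ifelse(qq != 0, .coulomb_pair(qq, r, p), 0)
      draw_e <- ifelse(qq != 0, .coulomb_pair_dr(qq, r, p), 0)
      raw_c <- .contact_pair(r, p)
      draw_c <- .contact_pair_dr(r, p)
      dEdr[mask] <- (draw_e + draw_c) * sw + (raw_e + raw_c) * dsw
      W <- dEdr / D
      W[!mask] <- 0
      g <- X * rowSums(W) - W %*% X
      g_cen[idx, ] <- g_cen[idx, ] + g
    }
  }

  # C-alpha excluded volume
  Dca <- as.matrix(stats::dist(ca))
  mask <- .seq_sep_ok(s, seq_len(n), p$min_seq_separation) &
    Dca < p$repulsion_radius & Dca > 0
  diag(mask) <- FALSE
  if (any(mask)) {
    dEdr <- matrix(0, n, n)
    dEdr[mask] <- -2 * p$repulsion_k * (p$repulsion_radius - Dca[mask])
    W <- dEdr / Dca
    W[!mask] <- 0
    g_ca <- g_ca + ca * rowSums(W) - W %*% ca
  }

  # hetero beads pull on residue centroids (beads themselves are rigid)
  het <- cg_hetero(s)
  if (nrow(het) > 0 && length(idx) > 0) {
    X <- cen[idx, , drop = FALSE]
    for (k in seq_len(nrow(het))) {
      dv <- sweep(X, 2, as.numeric(het[k, c("x", "y", "z")]))
      r <- sqrt(rowSums(dv^2))
      inr <- r <= p$pair_cutoff & r > 0
      if (!any(inr)) next
      rr <- r[inr]
      sw <- pair_switch(rr, p); dsw <- .pair_switch_dr(rr, p)
      qq <- het$charge[k] * q[idx][inr]
      raw <- ifelse(qq != 0, .coulomb_pair(qq, rr, p), 0) + .contact_pair(rr, p)
      draw <- ifelse(qq != 0, .coulomb_pair_dr(qq, rr, p), 0) + .contact_pair_dr(rr, p)
      dEdr <- draw * sw + raw * dsw
      g_cen[idx[inr], ] <- g_cen[idx[inr], ] + dv[inr, , drop = FALSE] * (dEdr / rr)
    }
  }

  list(ca = g_ca, cen = g_cen)
}

# d/dz of the burial depth switch
.burial_switch_dz <- function(z, p) {
  out <- numeric(length(z))
  above <- z > p$membrane_z_max
  below <- z < p$membrane_z_min
  t_a <- (z[above] - p$membrane_z_max) / 6
  t_b <- (p$membrane_z_min - z[below]) / 6
  out[above] <- ifelse(t_a < 1, -t_a * (1 - t_a), 0)
  out[below] <- ifelse(t_b < 1, t_b * (1 - t_b), 0)
  out
}

.pair_switch_dr <- function(r, p) {
  t <- (r - (p$pair_cutoff - p$switch_width)) / p$switch_width
  ifelse(t > 0 & t < 1, -6 * t * (1 - t) / p$switch_width, 0)
}

.coulomb_pair_dr <- function(q12, r, p) {
  denom <- p$dielectric_eps0 * r + p$dielectric_slope * r^2
  -.coulomb_k * q12 * (p$dielectric_eps0 + 2 * p$dielectric_slope * r) / denom^2
}

.contact_pair_dr <- function(r, p) {
  x <- p$contact_radius / r
  -p$contact_epsilon * (p$contact_radius / r^2) * (8 * x^7 - 12 * x^5)
}
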