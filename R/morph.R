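#' Configuration of the steered morphing protocol
#'
#' The morph is a desk-scale surrogate of targeted molecular dynamics: a
#' harmonic restraint on the RMSD to the target conformation, whose center
#' decreases linearly from the start-target RMSD to zero over `n_steps`, is
#' added to the coarse-grained energy and the structure is relaxed by
#' steepest-descent moves at each step (optionally with seeded Gaussian
#' coordinate noise).
#'
#' @param n_steps Number of restraint steps (>= 2); the pathway has
#'   `n_steps + 1` frames including the start.
#' @param k_steer Restraint force constant, kcal/mol/A^2.
#' @param relax_iters Descent moves per restraint step.
#' @param step_size Maximum per-bead displacement per move, Angstrom.
#' @param noise_sd Gaussian coordinate noise per move, Angstrom (0 =
#'   deterministic descent).
#' @param seed Integer seed for the noise stream.
#' @param restrained_residues Optional character vector of residue keys
#'   (`"chain|resno|ins"`) held exactly fixed during the morph. Hetero beads
#'   are always rigid (mirroring positional restraints on a bound ligand).
#' @param convergence_tol Required final RMSD to the target, Angstrom.
#' @return A list of class `morph_config`.
#' @export
morph_config <- function(n_steps = 120L, k_steer = 2000, relax_iters = 5L,
                         step_size = 0.05, noise_sd = 0, seed = 1L,
                         restrained_residues = NULL, convergence_tol = 0.05) {
  stopifnot(n_steps >= 2, k_steer > 0, relax_iters >= 1,
            step_size > 0, noise_sd >= 0, convergence_tol > 0)
  structure(list(n_steps = as.integer(n_steps), k_steer = k_steer,
                 relax_iters = as.integer(relax_iters), step_size = step_size,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 restrained_residues = restrained_residues,
                 convergence_tol = convergence_tol),
            class = "morph_config")
}

#' Morph a structure toward a target conformation along a scheduled restraint
#'
#' Generates an ordered ensemble of conformations connecting `start` to
#' `target`. At step i the restraint center rho_i moves linearly from the
#' initial RMSD to 0, and the free beads descend on
#' `E_cg + 0.5 * k_steer * (rmsd_to_target - rho_i)^2`. Hetero beads stay
#' exactly where they are in `start`.
#'
#' The endpoints must already share a coordinate frame (membrane normal along
#' z for both, OPM-style): the morph never re-orients them, because a rigid
#' re-fit would silently change every bead's membrane depth. Use
#' [superpose()] + [apply_transform()] first when endpoints come from
#' different depositions; a warning is raised when the direct coordinate
#' deviation is grossly larger than the best-fit RMSD.
#'
#' @param start,target [cg_structure()] endpoints; at least 90% of the
#'   residues of `start` must pair with `target`.
#' @param p [energy_params()].
#' @param cfg [morph_config()].
#' @return A `cg_pathway`: list with `frames` (list of `cg_structure`),
#'   `stats` (tibble: `frame`, `s`, `rmsd_to_start`, `rmsd_to_target`) and
#'   `endpoints` (labels). `s` is the progress coordinate of
#'   [progress_coordinate()].
#' @export
targeted_morph <- function(start, target, p = energy_params(), cfg = morph_config()) {
  pairing <- pair_residues(start, target)
  if (nrow(pairing) < 0.9 * nrow(start)) {
    abort(sprintf("pairing covers %d/%d residues (< 90%%)", nrow(pairing), nrow(start)))
  }
  fit_rmsd <- rmsd_after_superposition(target, start,
                                       pair_residues(target, start))
  direct <- sqrt(mean(rowSums((ca_matrix(start)[pairing$idx_a, , drop = FALSE] -
                                 ca_matrix(target)[pairing$idx_b, , drop = FALSE])^2)))
  if (direct > 2 * fit_rmsd + 5) {
    warn(sprintf(paste0("endpoints may not share a coordinate frame ",
                        "(direct CA deviation %.1f A vs best-fit %.1f A); ",
                        "superpose them before morphing"), direct, fit_rmsd))
  }

  fixed_res <- residue_keys(start) %in% (cfg$restrained_residues %||% character())

  # steered coordinate blocks: paired CA beads + paired centroids present in
  # both endpoints; explicitly restrained residues are not steered
  free_pair <- !fixed_res[pairing$idx_a]
  ia <- pairing$idx_a[free_pair]; ib <- pairing$idx_b[free_pair]
  tgt_ca <- ca_matrix(target)[ib, , drop = FALSE]
  cen_a <- cen_matrix(start); cen_b <- cen_matrix(target)
  cen_both <- !is.na(cen_a[ia, 1]) & !is.na(cen_b[ib, 1])
  ia_cen <- ia[cen_both]; ib_cen <- ib[cen_both]
  tgt_cen <- cen_b[ib_cen, , drop = FALSE]
  n_beads <- length(ia) + length(ia_cen)

  steer_rmsd <- function(s) {
    dca <- ca_matrix(s)[ia, , drop = FALSE] - tgt_ca
    dcen <- cen_matrix(s)[ia_cen, , drop = FALSE] - tgt_cen
    sqrt((sum(dca^2) + sum(dcen^2)) / n_beads)
  }

  d0 <- steer_rmsd(start)
  if (d0 < 1e-9) {
    inform("start and target coincide: returning a single-frame pathway")
    stats <- tibble(frame = 0L, s = 0, rmsd_to_start = 0, rmsd_to_target = 0)
    return(new_cg_pathway(list(start), stats, c(cg_label(start), cg_label(target))))
  }

  use_noise <- cfg$noise_sd > 0
  if (use_noise) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(cfg$seed)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  }

  cur <- start
  frames <- vector("list", cfg$n_steps + 1L)
  frames[[1]] <- start
  free_ca <- which(!fixed_res)
  free_cen <- which(!is.na(cen_a[, 1]) & !fixed_res)

  for (step in seq_len(cfg$n_steps)) {
    rho <- d0 * (1 - step / cfg$n_steps)
    for (it in seq_len(cfg$relax_iters)) {
      g <- cg_energy_gradient(cur, p)
      # restraint gradient on the steered beads
      r <- steer_rmsd(cur)
      if (r > 1e-12) {
        coef <- cfg$k_steer * (r - rho) / (r * n_beads)
        g$ca[ia, ] <- g$ca[ia, ] + coef * (ca_matrix(cur)[ia, , drop = FALSE] - tgt_ca)
        g$cen[ia_cen, ] <- g$cen[ia_cen, ] +
          coef * (cen_matrix(cur)[ia_cen, , drop = FALSE] - tgt_cen)
      }
      gmax <- sqrt(max(rowSums(g$ca^2), if (length(free_cen)) rowSums(g$cen^2) else 0))
      alpha <- cfg$step_size / max(1, gmax)
      ca_new <- ca_matrix(cur)
      ca_new[free_ca, ] <- ca_new[free_ca, , drop = FALSE] -
        alpha * g$ca[free_ca, , drop = FALSE]
      cen_new <- cen_matrix(cur)
      cen_new[free_cen, ] <- cen_new[free_cen, , drop = FALSE] -
        alpha * g$cen[free_cen, , drop = FALSE]
      if (use_noise) {
        ca_new[free_ca, ] <- ca_new[free_ca, , drop = FALSE] +
          matrix(stats::rnorm(3 * length(free_ca), 0, cfg$noise_sd), ncol = 3)
        cen_new[free_cen, ] <- cen_new[free_cen, , drop = FALSE] +
          matrix(stats::rnorm(3 * length(free_cen), 0, cfg$noise_sd), ncol = 3)
      }
      cur <- set_coords(cur, ca = ca_new, cen = cen_new)
    }
    frames[[step + 1L]] <- cur
  }

  # the last restraint center is 0; allow extra descent rounds with a
  # geometrically stiffened restraint to close the residual gap
  extra <- 0L
  while (steer_rmsd(cur) > cfg$convergence_tol && extra < 40L * cfg$relax_iters) {
    g <- cg_energy_gradient(cur, p)
    r <- steer_rmsd(cur)
    k_eff <- min(cfg$k_steer * 2^(extra %/% cfg$relax_iters), 1e7)
    coef <- k_eff * r / (r * n_beads)
    g$ca[ia, ] <- g$ca[ia, ] + coef * (ca_matrix(cur)[ia, , drop = FALSE] - tgt_ca)
    g$cen[ia_cen, ] <- g$cen[ia_cen, ] +
      coef * (cen_matrix(cur)[ia_cen, , drop = FALSE] - tgt_cen)
    gmax <- sqrt(max(rowSums(g$ca^2), if (length(free_cen)) rowSums(g$cen^2) else 0))
    alpha <- cfg$step_size / max(1, gmax)
    ca_new <- ca_matrix(cur)
    ca_new[free_ca, ] <- ca_new[free_ca, , drop = FALSE] -
      alpha * g$ca[free_ca, , drop = FALSE]
    cen_new <- cen_matrix(cur)
    cen_new[free_cen, ] <- cen_new[free_cen, , drop = FALSE] -
      alpha * g$cen[free_cen, , drop = FALSE]
    cur <- set_coords(cur, ca = ca_new, cen = cen_new)
    extra <- extra + 1L
  }
  if (extra > 0L) frames[[cfg$n_steps + 1L]] <- cur

  final_rmsd <- steer_rmsd(cur)
  if (final_rmsd > cfg$convergence_tol) {
    abort(sprintf(
      "morph did not converge: final RMSD to target %.4f A > tol %.4f A",
      final_rmsd, cfg$convergence_tol), class = "cgpathway_convergence_error")
  }

  d_start <- vapply(frames, rmsd_after_superposition, numeric(1), b = start)
  d_tgt <- vapply(frames, rmsd_after_superposition, numeric(1), b = target)
  s_val <- d_start / (d_start + d_tgt)
  s_val[1] <- 0
  s_val[length(s_val)] <- 1  # converged within tolerance; anchor the endpoint
  stats <- tibble(frame = seq_along(frames) - 1L, s = s_val,
                  rmsd_to_start = d_start, rmsd_to_target = d_tgt)
  new_cg_pathway(frames, stats, c(cg_label(start), cg_label(target)))
}

new_cg_pathway <- function(frames, stats, endpoints) {
  structure(list(frames = frames, stats = stats, endpoints = endpoints),
            class = "cg_pathway")
}

#' @export
print.cg_pathway <- function(x, ...) {
  cat(sprintf("<cg_pathway> %d frames, %s -> %s\n", length(x$frames),
              x$endpoints[1], x$endpoints[2]))
  print(x$stats, n = 5)
  invisible(x)
}

#' @export
tidy.cg_pathway <- function(x, ...) x$stats

#' Progress coordinate of a frame between two endpoint conformations
#'
#' Defined as `s = d0 / (d0 + d1)` with `d0`/`d1` the optimal-superposition
#' C-alpha RMSDs of the frame to the start and target endpoints. Dimensionless
#' and endpoint-anchored: `s(start) = 0`, `s(target) = 1`.
#'
#' @param frame,start,target [cg_structure()] objects; `frame` must pair with
#'   both endpoints.
#' @return Scalar in `[0, 1]`.
#' @export
progress_coordinate <- function(frame, start, target) {
  if (rmsd_after_superposition(start, target) < 1e-12) {
    abort("progress coordinate undefined: start and target coincide")
  }
  d0 <- rmsd_after_superposition(frame, start)
  d1 <- rmsd_after_superposition(frame, target)
  d0 / (d0 + d1)
}

#' Extract intermediates nearest to a uniform progress grid
#'
#' Picks, for each value of the uniform grid `{0, 1/(n-1), ..., 1}`, the
#' pathway frame whose progress coordinate is nearest (ties resolved toward
#' the earlier frame). Endpoint frames are always included; frames selected
#' more than once are collapsed with a warning.
#'
#' @param path A `cg_pathway`.
#' @param n Number of intermediates (>= 2), default 30.
#' @return A `cg_pathway` with `n` (or fewer, after collapsing) frames and
#'   strictly increasing `s`.
#' @export
extract_intermediates <- function(path, n = 30L) {
  if (n < 2) abort("n must be >= 2")
  s <- path$stats$s
  m <- length(s)
  grid <- seq(0, 1, length.out = n)
  pick <- vapply(grid, function(g) which.min(abs(s - g)), integer(1))
  pick[1] <- 1L
  pick[n] <- m
  if (anyDuplicated(pick) > 0) {
    warn(sprintf("%d duplicate frame selections collapsed", sum(duplicated(pick))))
  }
  pick <- sort(unique(pick))
  # enforce strictly increasing s among kept frames
  keep <- c(TRUE, diff(s[pick]) > 0)
  pick <- pick[keep]
  new_cg_pathway(path$frames[pick], path$stats[pick, ], path$endpoints)
}

#' Write a pathway as multi-model PDB plus a stats TSV
#'
#' @param path A `cg_pathway`.
#' @param pdb_file,tsv_file Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list of files written.
#' @export
write_pathway <- function(path, pdb_file = NULL, tsv_file = NULL) {
  if (!is.null(pdb_file)) write_structure(path$frames, pdb_file)
  if (!is.null(tsv_file)) {
    utils::write.table(path$stats, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(pdb = pdb_file, tsv = tsv_file))
}
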