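# Mildly hydrophobic alphabet used for toy sequences; the switch site is
# always tryptophan (the side-chain-flip class of motion).
.toy_alphabet <- c("LEU", "ILE", "VAL", "PHE", "MET", "SER", "THR", "TYR")

#' Synthetic two-state membrane protein toy
#'
#' Builds an ideal two-helix hairpin (helical rise 1.5 Angstrom, 100 degrees
#' per residue, C-beta-like centroid beads) spanning a membrane slab centered
#' on z = 0, and derives the "active" state from the "inactive" one by two
#' motions with exact ground truth: a rigid hinge rotation of the second
#' helix about the inter-helix loop, and a discrete flip of one designated
#' switch residue's centroid orientation. Every coordinate difference between
#' the states is accounted for by `moving_residues` plus `switch_residue`.
#'
#' @param n_res Total residues (>= 12); split evenly into the two helices.
#' @param hinge_angle Hinge rotation, degrees; 0 plus `switch_flip = FALSE`
#'   makes the states identical.
#' @param seed Seed for the (deterministic) toy sequence.
#' @param switch_flip Flip the switch residue's centroid in the active state.
#' @param helix_separation Inter-helix distance, Angstrom.
#' @return A list of class `toy_two_state`: `inactive`, `active`
#'   ([cg_structure()]s), `moving_residues` (residue keys), `switch_residue`,
#'   `hinge_angle`, `seed`.
#' @export
make_toy_two_state <- function(n_res = 60L, hinge_angle = 15, seed = 1L,
                               switch_flip = TRUE, helix_separation = 10) {
  if (n_res < 12) abort("toy needs at least 12 residues")
  n1 <- n_res %/% 2L
  n2 <- n_res - n1
  set.seed(seed)
  seq3 <- sample(.toy_alphabet, n_res, replace = TRUE)
  switch_idx <- n1 %/% 2L
  seq3[switch_idx] <- "TRP"

  helix <- function(n, origin, direction_z, phase = 0) {
    i <- seq_len(n) - 1L
    theta <- phase + i * 100 * pi / 180
    z <- origin[3] + direction_z * i * 1.5
    ca <- cbind(origin[1] + 2.3 * cos(theta), origin[2] + 2.3 * sin(theta), z)
    cen <- cbind(origin[1] + 4.0 * cos(theta), origin[2] + 4.0 * sin(theta), z)
    list(ca = ca, cen = cen)
  }
  span1 <- (n1 - 1) * 1.5
  # helix 1 ascends to the loop at the top; helix 2 descends next to it
  h1 <- helix(n1, c(0, 0, -span1 / 2), +1)
  h2 <- helix(n2, c(helix_separation, 0, span1 / 2), -1, phase = pi + 0.5)
  ca <- rbind(h1$ca, h2$ca)
  cen <- rbind(h1$cen, h2$cen)

  res <- tibble(
    chain = "A", resno = seq_len(n_res), ins = "", resname = seq3,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    cen_x = cen[, 1], cen_y = cen[, 2], cen_z = cen[, 3],
    n_sc = 1L
  )
  inactive <- cg_structure(res, label = "toy_inactive")

  active <- inactive
  if (hinge_angle != 0) {
    hinge_point <- c(helix_separation / 2, 0, span1 / 2)
    R <- rotation_matrix(c(1, 0, 0), hinge_angle * pi / 180)
    move <- (n1 + 1L):n_res
    rot <- function(m) sweep(sweep(m, 2, hinge_point) %*% t(R), 2, hinge_point, "+")
    ca2 <- ca_matrix(active); cen2 <- cen_matrix(active)
    ca2[move, ] <- rot(ca2[move, , drop = FALSE])
    cen2[move, ] <- rot(cen2[move, , drop = FALSE])
    active <- set_coords(active, ca = ca2, cen = cen2)
  }
  if (switch_flip) {
    # rotate the switch centroid 150 degrees about the helix axis (z) around
    # its own C-alpha: a distinct, local rotamer change
    Rz <- rotation_matrix(c(0, 0, 1), 150 * pi / 180)
    caw <- c(active$ca_x[switch_idx], active$ca_y[switch_idx], active$ca_z[switch_idx])
    v <- c(active$cen_x[switch_idx] - caw[1], active$cen_y[switch_idx] - caw[2],
           active$cen_z[switch_idx] - caw[3])
    nv <- as.numeric(Rz %*% v) + caw
    active$cen_x[switch_idx] <- nv[1]
    active$cen_y[switch_idx] <- nv[2]
    active$cen_z[switch_idx] <- nv[3]
  }
  attr(active, "label") <- "toy_active"

  moving <- if (hinge_angle != 0) residue_keys(inactive)[(n1 + 1L):n_res] else character()
  structure(list(inactive = inactive, active = active,
                 moving_residues = moving,
                 switch_residue = residue_keys(inactive)[switch_idx],
                 hinge_angle = hinge_angle, seed = as.integer(seed)),
            class = "toy_two_state")
}

# Rodrigues rotation matrix about unit axis u by angle a (radians)
rotation_matrix <- function(u, a) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Analytic free-energy landscape with known stationary points
#'
#' A closed-form sum of Gaussian bumps (transition states) and wells
#' (intermediates) on `s` in `[0, 1]`, anchored so `G(0) = 0`. The default
#' `triple_well` shape has three interior maxima separating four minima, the
#' first barrier being the largest (rate-limiting) — the landscape class used
#' throughout the test suite as a ground-truth oracle. Construction fails if
#' the requested components merge (wrong interior-maximum count).
#'
#' @param kind `"double_well"` or `"triple_well"`.
#' @param centers,amplitudes,sigmas Component parameters: Gaussian centers in
#'   `[0, 1]`, amplitudes in kcal/mol (positive = bump, negative = well) and
#'   widths. Defaults depend on `kind`.
#' @return A list of class `analytic_landscape` with `fn` (vectorised
#'   closed form), the parameters, and `kind`.
#' @export
analytic_landscape <- function(kind = c("triple_well", "double_well"),
                               centers = NULL, amplitudes = NULL, sigmas = NULL) {
  kind <- match.arg(kind)
  if (is.null(centers)) {
    if (kind == "triple_well") {
      centers <- c(0.17, 0.33, 0.50, 0.66, 0.83)
      amplitudes <- c(12.4, -3.0, 2.5, -1.5, 5.5)
      sigmas <- c(0.06, 0.07, 0.06, 0.07, 0.06)
    } else {
      centers <- c(0.25, 0.5, 0.75)
      amplitudes <- c(-2.0, 4.0, -2.0)
      sigmas <- c(0.09, 0.08, 0.09)
    }
  }
  stopifnot(length(centers) == length(amplitudes),
            length(centers) == length(sigmas), all(sigmas > 0))
  fn <- function(s) {
    g <- rep(0, length(s))
    for (k in seq_along(centers)) {
      g <- g + amplitudes[k] * exp(-(s - centers[k])^2 / (2 * sigmas[k]^2))
    }
    g0 <- 0
    for (k in seq_along(centers)) {
      g0 <- g0 + amplitudes[k] * exp(-(0 - centers[k])^2 / (2 * sigmas[k]^2))
    }
    g - g0
  }
  L <- structure(list(kind = kind, centers = centers, amplitudes = amplitudes,
                      sigmas = sigmas, fn = fn),
                 class = "analytic_landscape")
  n_max <- sum(landscape_stationary_points(L)$type == "max")
  want <- if (kind == "triple_well") 3L else 1L
  if (n_max != want) {
    abort(sprintf("landscape components merge: %d interior maxima, expected %d",
                  n_max, want))
  }
  L
}

#' Ground-truth stationary points of an analytic landscape
#'
#' Dense-grid search refined by golden-section optimisation; endpoints count
#' as candidate minima, mirroring [find_stationary_points()].
#'
#' @param L An [analytic_landscape()].
#' @param n_grid Grid density (default 1e5).
#' @return Tibble with `type` (`"min"`/`"max"`), `s`, `G`, ordered along `s`.
#' @export
landscape_stationary_points <- function(L, n_grid = 1e5) {
  s <- seq(0, 1, length.out = n_grid)
  g <- L$fn(s)
  d <- diff(g)
  nz <- which(d != 0)  # skip flat runs (double-precision plateaus near extrema)
  sgn <- sign(d[nz])
  rows <- list()
  if (length(nz) == 0) return(tibble(type = "min", s = 0, G = L$fn(0)))
  if (sgn[1] > 0) rows[[length(rows) + 1L]] <- list(type = "min", s = 0)
  if (length(nz) >= 2) {
    for (k in seq_len(length(nz) - 1L)) {
      if (sgn[k] != sgn[k + 1]) {
        mid <- s[(nz[k] + 1L + nz[k + 1L]) %/% 2L]
        type <- if (sgn[k] > 0) "max" else "min"
        rows[[length(rows) + 1L]] <- list(type = type, s = mid,
                                          lo = s[nz[k]], hi = s[nz[k + 1L] + 1L])
      }
    }
  }
  if (sgn[length(sgn)] < 0) rows[[length(rows) + 1L]] <- list(type = "min", s = 1)
  out <- purrr::map(rows, function(r) {
    if (r$s > 0 && r$s < 1) {
      opt <- stats::optimize(L$fn, c(r$lo, r$hi), maximum = (r$type == "max"),
                             tol = 1e-10)
      sv <- if (r$type == "max") opt$maximum else opt$minimum
    } else {
      sv <- r$s
    }
    tibble(type = r$type, s = sv, G = L$fn(sv))
  }) |> bind_rows()
  out
}

#' Sample a noisy profile from an analytic landscape
#'
#' @param L An [analytic_landscape()].
#' @param n Number of uniform grid points (>= 3).
#' @param noise_sd I.i.d. Gaussian noise on G, kcal/mol.
#' @param seed Seed for the noise.
#' @return An `fe_profile` (re-anchored so the first value is 0).
#' @export
sample_profile <- function(L, n = 301L, noise_sd = 0, seed = 1L) {
  if (n < 3) abort("need at least 3 sample points")
  s <- seq(0, 1, length.out = n)
  g <- L$fn(s)
  if (noise_sd > 0) {
    set.seed(seed)
    g <- g + stats::rnorm(n, 0, noise_sd)
  }
  fe_profile(s = s, G = g - g[1], system_label = paste0("analytic_", L$kind))
}
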