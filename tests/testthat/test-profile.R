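fake_path <- function(frames, s) {
  structure(list(frames = frames,
                 stats = tibble::tibble(frame = seq_along(frames) - 1L, s = s,
                                        rmsd_to_start = s, rmsd_to_target = 1 - s),
                 endpoints = c("a", "b")), class = "cg_pathway")
}

test_that("profiles are relative to the first frame", {
  toy <- make_toy_two_state(16, 6, seed = 1)
  p <- energy_params()
  single <- fake_path(list(toy$inactive), 0)
  prof <- build_profile(single, p)
  expect_equal(prof$s, 0)
  expect_equal(prof$G, 0)

  same <- fake_path(rep(list(toy$inactive), 4), c(0, 0.3, 0.7, 1))
  prof2 <- build_profile(same, p)
  expect_equal(prof2$G, rep(0, 4))
})

test_that("burial-only three-frame profile matches hand arithmetic", {
  # single TRP residue at slab center, 3 A outside, far outside:
  # f = 1, 0.5, 0 so G = 0, -0.5*h, -h relative to the first frame
  p <- energy_params(contact_epsilon = 0, repulsion_k = 0,
                     residue_charges = c(NONE = 0))
  h <- p$hydrophobicity_scale[["TRP"]]
  mk <- function(z) cg_structure(tibble::tibble(
    chain = "A", resno = 1:2, ins = "", resname = c("TRP", "GLY"),
    ca_x = c(0, 5), ca_y = 0, ca_z = 0,
    cen_x = c(0, NA), cen_y = c(0, NA), cen_z = c(z, NA),
    n_sc = c(1L, 0L)))
  path <- fake_path(list(mk(0), mk(p$membrane_z_max + 3), mk(p$membrane_z_max + 30)),
                    c(0, 0.5, 1))
  prof <- build_profile(path, p)
  expect_equal(prof$G, c(0, -0.5 * h, -h), tolerance = 1e-12)
})

test_that("moving-average smoothing honours window semantics", {
  prof <- fe_profile(s = c(0, 0.5, 1), G = c(0, 3, 0))
  expect_equal(smooth_profile(prof, 1)$G_smoothed, prof$G)
  sm <- smooth_profile(prof, 3)
  # shrinking edge windows keep the endpoints; interior average is 1.0
  expect_equal(sm$G_smoothed, c(0, 1, 0))
  const <- fe_profile(s = seq(0, 1, 0.25), G = rep(0, 5))
  expect_equal(smooth_profile(const, 5)$G_smoothed, rep(0, 5))
  expect_error(smooth_profile(prof, 2), "odd")
  expect_error(smooth_profile(prof, 5), "odd|length")
})

test_that("monotone profiles have one minimum and no transition state", {
  prof <- fe_profile(s = seq(0, 1, length.out = 11),
                     G = seq(0, 5, length.out = 11))
  rep <- find_stationary_points(prof, 0.5)
  expect_equal(nrow(rep$maxima), 0)
  expect_equal(nrow(rep$minima), 1)
  expect_equal(rep$minima$index, 1)
  expect_true(is.na(rep$rate_limiting))
})

test_that("triple-well landscapes yield exactly 3 TS and 4 minima at grid accuracy", {
  L <- analytic_landscape("triple_well")
  truth <- landscape_stationary_points(L)
  prof <- sample_profile(L, n = 301, noise_sd = 0)
  rep <- find_stationary_points(prof, 0.5)
  expect_equal(nrow(rep$maxima), 3)
  expect_equal(nrow(rep$minima), 4)
  grid_spacing <- 1 / 300
  t_max <- truth[truth$type == "max", ]
  t_min <- truth[truth$type == "min", ]
  expect_equal(rep$maxima$s, t_max$s, tolerance = grid_spacing * 1.01)
  expect_equal(rep$minima$s, t_min$s, tolerance = grid_spacing * 1.01)
  # barrier errors bounded by the grid-induced bound
  true_barriers <- vapply(seq_len(3), function(i) {
    prev <- t_min$G[t_min$s < t_max$s[i]]
    t_max$G[i] - prev[length(prev)]
  }, numeric(1))
  expect_equal(rep$maxima$barrier, true_barriers, tolerance = 0.02)
  expect_equal(rep$rate_limiting, "TS1")
})

test_that("sub-threshold barriers are merged away", {
  # symmetric double well of depth d: one interior maximum of barrier d
  L <- analytic_landscape("double_well")
  prof <- sample_profile(L, n = 201, noise_sd = 0)
  d <- find_stationary_points(prof, 0.5)$maxima$barrier[1]
  expect_gt(d, 0.5)
  rep_hi <- find_stationary_points(prof, d + 0.5)
  expect_equal(nrow(rep_hi$maxima), 0)
})

test_that("barriers use the preceding minimum; ties go to the earliest TS", {
  # hand-built profile: minima at G = {0, 1}, maxima at {5, 2}
  s <- seq(0, 1, length.out = 5)
  prof <- fe_profile(s = s, G = c(0, 5, 1, 2, 0.5))
  rep <- find_stationary_points(prof, 0.1)
  expect_equal(rep$maxima$barrier, c(5, 1))
  expect_equal(rep$rate_limiting, "TS1")
  br <- barriers_and_rate_limiting(rep)
  expect_equal(br$barriers$barrier, c(5, 1))

  # single TS is rate-limiting
  prof1 <- fe_profile(s = seq(0, 1, length.out = 5), G = c(0, 1, 3, 1, 0))
  expect_equal(find_stationary_points(prof1, 0.1)$rate_limiting, "TS1")

  # exact tie: earliest TS wins
  prof2 <- fe_profile(s = seq(0, 1, length.out = 7), G = c(0, 2, 0, 2, 0, 2, 0))
  rep2 <- find_stationary_points(prof2, 0.1)
  expect_equal(rep2$maxima$barrier, c(2, 2, 2))
  expect_equal(rep2$rate_limiting, "TS1")
})

test_that("stationary detection is invariant to a constant offset after re-anchoring", {
  L <- analytic_landscape("triple_well")
  prof <- sample_profile(L, n = 201, noise_sd = 0)
  shifted <- fe_profile(s = prof$s, G = (prof$G + 7) - 7)
  r1 <- find_stationary_points(prof, 0.5)
  r2 <- find_stationary_points(shifted, 0.5)
  expect_equal(r1$maxima$index, r2$maxima$index)
  expect_equal(r1$maxima$barrier, r2$maxima$barrier)
})

test_that("profile reversal maps barriers to the closed-form reverse barriers", {
  L <- analytic_landscape("triple_well")
  prof <- sample_profile(L, n = 301, noise_sd = 0)
  fwd <- find_stationary_points(prof, 0.5)
  grev <- rev(prof$G)
  rev_prof <- fe_profile(s = prof$s, G = grev - grev[1])
  bwd <- find_stationary_points(rev_prof, 0.5)
  # brute-force oracle: reverse barrier of TS_k = G(TS_k) - G(following min)
  y <- prof$G
  oracle_rev <- vapply(rev(seq_len(nrow(fwd$maxima))), function(i) {
    following <- fwd$minima$G[fwd$minima$index > fwd$maxima$index[i]]
    fwd$maxima$G[i] - following[1]
  }, numeric(1))
  expect_equal(bwd$maxima$barrier, oracle_rev, tolerance = 1e-9)
})

test_that("plateaus collapse to their midpoint", {
  G <- c(0, 1, 2, 2, 2, 1, 0)
  prof <- fe_profile(s = seq(0, 1, length.out = 7), G = G)
  rep <- find_stationary_points(prof, 0.1)
  expect_equal(nrow(rep$maxima), 1)
  expect_equal(rep$maxima$index, 4)
})

test_that("smoothed series drives detection when present", {
  set.seed(8)
  L <- analytic_landscape("triple_well")
  noisy <- sample_profile(L, n = 301, noise_sd = 0.1, seed = 8)
  sm <- smooth_profile(noisy, 7)
  rep <- find_stationary_points(sm, 0.5)
  expect_equal(nrow(rep$maxima), 3)
})
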