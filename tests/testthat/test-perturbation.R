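test_that("alanine truncation renames, repositions the centroid, and is local", {
  s <- random_structure(12, seed = 1)
  site <- which(s$resname == "TRP")[1]
  m <- mutate_to_ala(s, "A", s$resno[site])
  expect_equal(m$resname[site], "ALA")
  v <- c(m$cen_x[site] - m$ca_x[site], m$cen_y[site] - m$ca_y[site],
         m$cen_z[site] - m$ca_z[site])
  expect_equal(sqrt(sum(v^2)), 1.52, tolerance = 1e-9)
  # direction preserved
  v0 <- c(s$cen_x[site] - s$ca_x[site], s$cen_y[site] - s$ca_y[site],
          s$cen_z[site] - s$ca_z[site])
  expect_equal(v / sqrt(sum(v^2)), v0 / sqrt(sum(v0^2)), tolerance = 1e-9)
  # exactly one residue differs
  diff_rows <- which(s$resname != m$resname |
                       s$cen_x != m$cen_x | is.na(s$cen_x) != is.na(m$cen_x))
  expect_equal(diff_rows, site)

  gly <- which(s$resname == "GLY")[1]
  expect_error(mutate_to_ala(s, "A", s$resno[gly]), "glycine")
  expect_error(mutate_to_ala(s, "A", 9999L), "no residue")
})

test_that("mutating an alanine is a warning no-op with identical energy", {
  s <- random_structure(12, seed = 2)
  site <- which(s$resname == "ALA")[1]
  expect_warning(m <- mutate_to_ala(s, "A", s$resno[site]), "already alanine")
  p <- energy_params()
  expect_identical(evaluate_energy(m, p)$total, evaluate_energy(s, p)$total)
})

test_that("alanine truncation shifts a burial-only energy by h(ALA) - h(TRP)", {
  p <- energy_params(contact_epsilon = 0, repulsion_k = 0,
                     residue_charges = c(NONE = 0))
  s <- cg_structure(tibble::tibble(
    chain = "A", resno = 1L, ins = "", resname = "TRP",
    ca_x = 0, ca_y = 0, ca_z = 0, cen_x = 1.7, cen_y = 0, cen_z = 0, n_sc = 1L))
  m <- mutate_to_ala(s, "A", 1L)
  dh <- p$hydrophobicity_scale[["ALA"]] - p$hydrophobicity_scale[["TRP"]]
  expect_equal(evaluate_energy(m, p)$total - evaluate_energy(s, p)$total, dh,
               tolerance = 1e-12)
})

test_that("rotamer transfer from an identical reference is the identity", {
  s <- random_structure(12, seed = 3)
  site <- which(s$resname != "GLY")[1]
  out <- set_sidechain_from_reference(s, "A", s$resno[site], "", s)
  expect_equal(as.data.frame(out), as.data.frame(s), tolerance = 1e-9)
})

test_that("rotamer transfer reproduces the reference side-chain vector in the local frame", {
  toy <- make_toy_two_state(24, 0, seed = 4, switch_flip = TRUE)
  # states differ only in the switch residue rotamer
  key <- strsplit(toy$switch_residue, "|", fixed = TRUE)[[1]]
  key <- c(key, "")[1:3]
  resno <- as.integer(key[2])
  switched <- set_sidechain_from_reference(toy$inactive, key[1], resno, key[3],
                                           toy$active)
  i <- match(toy$switch_residue, residue_keys_public(switched))
  # with identical local backbones the centroid must match the active state
  expect_equal(c(switched$cen_x[i], switched$cen_y[i], switched$cen_z[i]),
               c(toy$active$cen_x[i], toy$active$cen_y[i], toy$active$cen_z[i]),
               tolerance = 1e-6)
  # all other residues untouched
  expect_equal(cen_xyz(switched)[-i, ], cen_xyz(toy$inactive)[-i, ])

  s <- toy$inactive
  wrong <- s
  wrong$resname[i] <- "HIS"
  expect_error(set_sidechain_from_reference(wrong, key[1], resno, key[3], toy$active),
               "mismatch")
})

test_that("rotamer transfer follows the local backbone frame under rotation", {
  toy <- make_toy_two_state(24, 0, seed = 5, switch_flip = TRUE)
  key <- strsplit(toy$switch_residue, "|", fixed = TRUE)[[1]]
  key <- c(key, "")[1:3]
  resno <- as.integer(key[2])
  tf <- random_rigid_transform(11)
  moved <- apply_transform(toy$inactive, tf)
  switched <- set_sidechain_from_reference(moved, key[1], resno, key[3], toy$active)
  i <- match(toy$switch_residue, residue_keys_public(switched))
  # the Ca -> centroid vector must match the reference's after transforming
  # into the moved frame
  v_ref <- c(toy$active$cen_x[i] - toy$active$ca_x[i],
             toy$active$cen_y[i] - toy$active$ca_y[i],
             toy$active$cen_z[i] - toy$active$ca_z[i])
  v_out <- c(switched$cen_x[i] - switched$ca_x[i],
             switched$cen_y[i] - switched$ca_y[i],
             switched$cen_z[i] - switched$ca_z[i])
  expect_equal(v_out, as.numeric(tf$rotation %*% v_ref), tolerance = 1e-6)
})

test_that("identity mutation yields exactly zero barrier change at every TS", {
  toy <- planted_toy(seed = 1)
  p <- planted_params()
  cfg <- planted_morph_config()
  ala_site <- which(toy$inactive$resname == "ALA")
  if (length(ala_site) == 0) {
    toy$inactive$resname[2] <- "ALA"
    toy$active$resname[2] <- "ALA"
    ala_site <- 2L
  } else {
    ala_site <- ala_site[1]
  }
  sites <- tibble::tibble(chain = "A", resno = toy$inactive$resno[ala_site],
                          mode = "ALA")
  rep <- suppressWarnings(
    ddg_scan(toy$inactive, toy$active, sites, p, cfg, tau = 0.25,
             prominence_threshold = 0.05))
  expect_gt(nrow(rep), 0)
  expect_true(all(rep$ddg == 0))
  expect_true(all(rep$classification == "neutral"))
})

test_that("a planted membrane-crossing contribution is recovered as -c and classified", {
  toy <- planted_toy(seed = 1)
  p <- planted_params()
  cfg <- planted_morph_config()
  sites <- tibble::tibble(chain = "A", resno = toy$inactive$resno[toy$tip],
                          mode = "ALA")
  rep <- ddg_scan(toy$inactive, toy$active, sites, p, cfg, tau = 0.25,
                  prominence_threshold = 0.05)
  expect_equal(nrow(rep), 1)
  # planted contribution: lysine pays +3 inside the slab, alanine +0.3,
  # neither pays anything at the endpoints: c = 2.7
  expect_equal(rep$ddg, -2.7, tolerance = 0.15)
  expect_equal(rep$classification, "facilitates")
  expect_true(all(rep$ts_count_match))
})

test_that("scans are order-independent and seed-reproducible", {
  toy <- planted_toy(seed = 2)
  toy$inactive$resname[10] <- "LYS"; toy$active$resname[10] <- "LYS"
  p <- planted_params()
  cfg <- planted_morph_config(seed = 7)
  sites <- tibble::tibble(chain = "A", resno = c(toy$tip, 10L), mode = "ALA")
  r1 <- ddg_scan(toy$inactive, toy$active, sites, p, cfg, tau = 0.25,
                 prominence_threshold = 0.05)
  r2 <- ddg_scan(toy$inactive, toy$active, sites[2:1, ], p, cfg, tau = 0.25,
                 prominence_threshold = 0.05)
  expect_equal(dplyr::arrange(tibble::as_tibble(r1), resno, ts_label),
               dplyr::arrange(tibble::as_tibble(r2), resno, ts_label))
  r3 <- ddg_scan(toy$inactive, toy$active, sites, p, cfg, tau = 0.25,
                 prominence_threshold = 0.05)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r3))
})

test_that("per-site pipeline failures are recorded without aborting the scan", {
  toy <- planted_toy(seed = 3)
  gly_like <- 5L
  toy$inactive$resname[gly_like] <- "GLY"
  toy$inactive$cen_x[gly_like] <- NA; toy$inactive$cen_y[gly_like] <- NA
  toy$inactive$cen_z[gly_like] <- NA; toy$inactive$n_sc[gly_like] <- 0L
  toy$active$resname[gly_like] <- "GLY"
  toy$active$cen_x[gly_like] <- NA; toy$active$cen_y[gly_like] <- NA
  toy$active$cen_z[gly_like] <- NA; toy$active$n_sc[gly_like] <- 0L
  sites <- tibble::tibble(chain = "A", resno = c(gly_like, toy$tip), mode = "ALA")
  rep <- ddg_scan(toy$inactive, toy$active, sites, planted_params(),
                  planted_morph_config(), tau = 0.25, prominence_threshold = 0.05)
  expect_equal(unique(rep$resno), toy$tip)
  expect_match(attr(rep, "failures")[[paste0("A", gly_like)]], "glycine")
})

test_that("classification always agrees with the sign convention", {
  toy <- planted_toy(seed = 4)
  toy$inactive$resname[10] <- "LYS"; toy$active$resname[10] <- "LYS"
  sites <- tibble::tibble(chain = "A", resno = c(toy$tip, 10L, 3L), mode = "ALA")
  rep <- suppressWarnings(
    ddg_scan(toy$inactive, toy$active, sites, planted_params(),
             planted_morph_config(), tau = 0.25, prominence_threshold = 0.05))
  tau <- attr(rep, "tau")
  ok <- !is.na(rep$ddg)
  expect_true(all((rep$ddg[ok] > tau) == (rep$classification[ok] == "inhibits")))
  expect_true(all((rep$ddg[ok] < -tau) == (rep$classification[ok] == "facilitates")))
  expect_true(all((abs(rep$ddg[ok]) <= tau) == (rep$classification[ok] == "neutral")))
})

test_that("empty site lists give an empty report", {
  toy <- planted_toy(seed = 5)
  rep <- ddg_scan(toy$inactive, toy$active,
                  tibble::tibble(chain = character(), resno = integer(),
                                 mode = character()),
                  planted_params(), planted_morph_config(),
                  prominence_threshold = 0.05)
  expect_equal(nrow(rep), 0)
})
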