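#' Truncate a residue's side chain to alanine
#'
#' The residue is renamed `ALA` and its centroid bead is repositioned at the
#' C-beta distance (1.52 Angstrom) from the C-alpha along the original
#' C-alpha to centroid direction, so the side chain keeps its orientation but
#' loses its bulk. Energy parameters (hydrophobicity, charge) follow the new
#' residue name automatically.
#'
#' @param s A [cg_structure()].
#' @param chain,resno,ins Residue identifier (author numbering).
#' @return The mutated [cg_structure()]. Mutating an alanine is a warning
#'   no-op; glycine sites are an error (no side-chain direction to keep).
#' @export
mutate_to_ala <- function(s, chain, resno, ins = "") {
  i <- match(paste(chain, resno, ins, sep = "|"), residue_keys(s))
  if (is.na(i)) abort(sprintf("no residue %s %s%s in structure", chain, resno, ins))
  if (s$resname[i] == "GLY") {
    abort("cannot mutate glycine to alanine: no C-beta direction")
  }
  if (s$resname[i] == "ALA") {
    warn(sprintf("residue %s %s is already alanine; returned unchanged", chain, resno))
    return(s)
  }
  if (is.na(s$cen_x[i])) {
    abort("site has no side-chain centroid; cannot place the alanine bead")
  }
  v <- c(s$cen_x[i] - s$ca_x[i], s$cen_y[i] - s$ca_y[i], s$cen_z[i] - s$ca_z[i])
  v <- v / sqrt(sum(v^2)) * 1.52
  s$resname[i] <- "ALA"
  s$cen_x[i] <- s$ca_x[i] + v[1]
  s$cen_y[i] <- s$ca_y[i] + v[2]
  s$cen_z[i] <- s$ca_z[i] + v[3]
  s$n_sc[i] <- 1L
  s
}

#' Transfer a side-chain rotamer from a reference conformation
#'
#' Superposes the local backbone window (site +/- 2 residues, C-alpha only)
#' of the reference onto the structure and replaces the site's centroid by the
#' transformed reference centroid — the switch used to place a side chain in
#' its other-state orientation (e.g. a tryptophan from "flattened" to
#' "vertical") without touching anything else.
#'
#' @param s Structure to modify.
#' @param chain,resno,ins Site identifier; must exist in both structures with
#'   the same residue type.
#' @param ref Reference [cg_structure()] supplying the rotamer.
#' @return The modified [cg_structure()].
#' @export
set_sidechain_from_reference <- function(s, chain, resno, ins = "", ref) {
  key <- paste(chain, resno, ins, sep = "|")
  i <- match(key, residue_keys(s))
  j <- match(key, residue_keys(ref))
  if (is.na(i) || is.na(j)) abort(sprintf("site %s %s not present in both structures", chain, resno))
  if (s$resname[i] != ref$resname[j]) {
    abort(sprintf("residue type mismatch at %s %s: %s vs %s",
                  chain, resno, s$resname[i], ref$resname[j]))
  }
  if (s$resname[i] == "GLY") abort("glycine has no side chain to set")
  if (is.na(ref$cen_x[j])) abort("reference site has no side-chain centroid")

  win_s <- intersect(seq(i - 2L, i + 2L), seq_len(nrow(s)))
  keys_win <- residue_keys(s)[win_s]
  win_r <- match(keys_win, residue_keys(ref))
  ok <- !is.na(win_r)
  if (sum(ok) < 3) abort("fewer than 3 shared backbone positions around the site")
  fit <- kabsch_fit(ca_matrix(ref)[win_r[ok], , drop = FALSE],
                    ca_matrix(s)[win_s[ok], , drop = FALSE])
  cen_ref <- c(ref$cen_x[j], ref$cen_y[j], ref$cen_z[j])
  new_cen <- as.numeric(fit$rotation %*% cen_ref + fit$translation)
  s$cen_x[i] <- new_cen[1]; s$cen_y[i] <- new_cen[2]; s$cen_z[i] <- new_cen[3]
  s
}

#' Apply one mutation-site row to a structure
#'
#' @param s Structure to perturb.
#' @param site One-row tibble/list with `chain`, `resno`, optional `ins`,
#'   `mode` (`"ALA"` or `"ROTAMER_FROM_REFERENCE"`).
#' @param ref Reference structure for rotamer mode.
#' @return Perturbed structure.
#' @export
apply_mutation <- function(s, site, ref = NULL) {
  ins <- if ("ins" %in% names(site)) site$ins else ""
  if (is.null(ins) || is.na(ins)) ins <- ""
  mode <- toupper(site$mode %||% "ALA")
  if (length(mode) != 1 || is.na(mode)) mode <- "ALA"
  if (mode == "ALA") {
    mutate_to_ala(s, site$chain, site$resno, ins)
  } else if (mode == "ROTAMER_FROM_REFERENCE") {
    if (is.null(ref)) abort("rotamer mode needs a reference structure")
    set_sidechain_from_reference(s, site$chain, site$resno, ins, ref)
  } else {
    abort(paste0("unknown mutation mode: ", mode))
  }
}

#' Alanine-scanning / rotamer-switch barrier-change scan
#'
#' For each site, both endpoints are perturbed identically, the full pathway
#' pipeline (morph, uniform extraction, profile, smoothing, stationary-point
#' detection) is re-run with the same seed and configuration, transition
#' states are matched to the wild-type ones by rank order along the progress
#' coordinate, and the activation-barrier change `ddG = dG_mut - dG_wt` is
#' reported per matched TS. Positive `ddG` means the perturbation raises the
#' barrier (inhibits activation), negative means it lowers it (facilitates);
#' `|ddG| <= tau` is called neutral.
#'
#' @param start,target Wild-type endpoint [cg_structure()]s.
#' @param sites Tibble of sites: columns `chain`, `resno`, optional `ins`,
#'   optional `mode` (default `"ALA"`; `"ROTAMER_FROM_REFERENCE"` uses
#'   `reference_label` to pick the endpoint supplying the rotamer).
#' @param p [energy_params()].
#' @param cfg [morph_config()].
#' @param tau Neutrality tolerance, kcal/mol (default 0.25).
#' @param n_intermediates Frames kept per profile (default 30).
#' @param smooth_window Odd moving-average window (default 1 = none).
#' @param prominence_threshold Passed to [find_stationary_points()].
#' @return A `ddg_report` tibble: one row per (site, wild-type TS) with
#'   `site`, `chain`, `resno`, `mode`, `ts_label`, `dg_wt`, `dg_mut`, `ddg`,
#'   `classification` (`"inhibits"`, `"facilitates"`, `"neutral"`, or `NA`
#'   for a TS with no counterpart in the mutant profile) and `ts_count_match`.
#'   Attributes: `tau`, `wild_type` (the WT `stationary_report`), `failures`
#'   (named list of per-site error messages).
#' @export
ddg_scan <- function(start, target, sites, p = energy_params(),
                     cfg = morph_config(), tau = 0.25, n_intermediates = 30L,
                     smooth_window = 1L, prominence_threshold = 0.5) {
  run_pipeline <- function(a, b) {
    path <- targeted_morph(a, b, p, cfg)
    path <- extract_intermediates(path, n_intermediates)
    prof <- build_profile(path, p)
    if (smooth_window > 1L) prof <- smooth_profile(prof, smooth_window)
    find_stationary_points(prof, prominence_threshold)
  }
  wt <- run_pipeline(start, target)
  if (nrow(wt$maxima) == 0) {
    warn("wild-type profile has no transition state; report will be empty")
  }

  sites <- as_tibble(sites)
  failures <- list()
  rows <- list()
  for (k in seq_len(nrow(sites))) {
    site <- sites[k, ]
    ins_k <- if ("ins" %in% names(sites)) sites$ins[k] else ""
    site_id <- paste0(site$chain, site$resno,
                      if (is.null(ins_k) || is.na(ins_k)) "" else ins_k)
    res <- tryCatch({
      ref <- NULL
      if (toupper(site$mode %||% "ALA") == "ROTAMER_FROM_REFERENCE") {
        ref_label <- site$reference_label %||% cg_label(target)
        ref <- if (identical(ref_label, cg_label(start))) start else target
      }
      mut_start <- apply_mutation(start, site, ref)
      mut_target <- apply_mutation(target, site, ref)
      mut <- run_pipeline(mut_start, mut_target)
      n_wt <- nrow(wt$maxima); n_mut <- nrow(mut$maxima)
      match_ok <- n_wt == n_mut
      chain_v <- site$chain; resno_v <- site$resno
      mode_v <- toupper(site$mode %||% "ALA")
      purrr::map(seq_len(n_wt), function(i) {
        dg_wt <- wt$maxima$barrier[i]
        dg_mut <- if (i <= n_mut) mut$maxima$barrier[i] else NA_real_
        ddg <- dg_mut - dg_wt
        tibble(site = site_id, chain = chain_v, resno = resno_v,
               mode = mode_v,
               ts_label = wt$maxima$label[i],
               dg_wt = dg_wt, dg_mut = dg_mut, ddg = ddg,
               classification = classify_ddg(ddg, tau),
               ts_count_match = match_ok)
      }) |> bind_rows()
    }, error = function(e) {
      failures[[site_id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(site = character(), chain = character(), resno = integer(),
           mode = character(), ts_label = character(), dg_wt = double(),
           dg_mut = double(), ddg = double(), classification = character(),
           ts_count_match = logical())
  structure(out, class = c("ddg_report", class(tibble())),
            tau = tau, wild_type = wt, failures = failures)
}

classify_ddg <- function(ddg, tau) {
  dplyr::case_when(
    is.na(ddg) ~ NA_character_,
    ddg > tau ~ "inhibits",
    ddg < -tau ~ "facilitates",
    TRUE ~ "neutral"
  )
}

#' @export
glance.ddg_report <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$ts_label) |>
    summarise(n_inhibits = sum(.data$classification == "inhibits", na.rm = TRUE),
              n_facilitates = sum(.data$classification == "facilitates", na.rm = TRUE),
              n_neutral = sum(.data$classification == "neutral", na.rm = TRUE),
              .groups = "drop")
}

#' Bar plot of barrier changes per transition state
#'
#' @param report A `ddg_report`.
#' @param ts Optional TS label filter (e.g. `"TS1"`).
#' @return A ggplot object.
#' @export
plot_ddg <- function(report, ts = NULL) {
  df <- as_tibble(report)
  if (!is.null(ts)) df <- filter(df, .data$ts_label %in% ts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$ddg,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ts_label) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "barrier change (kcal/mol)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
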