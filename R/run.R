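#' Declarative configuration for a pathway run
#'
#' Bundles everything a run needs: endpoint structure files (or in-memory
#' structures), selection flags, energy and morph parameters, profile
#' settings and the master seed. The configuration round-trips losslessly
#' through JSON ([write_run_config()] / [read_run_config()]) and is echoed
#' into every output directory so runs are self-describing.
#'
#' @param start,target Paths to endpoint structure files, or
#'   [cg_structure()] objects.
#' @param chains Optional chain filter applied to both endpoints.
#' @param model_index Model number for multi-model files.
#' @param hetero Hetero residue names carried as rigid beads.
#' @param energy [energy_params()].
#' @param morph [morph_config()].
#' @param n_intermediates Uniformly extracted frames per profile (default 30).
#' @param smooth_window Odd moving-average window (default 1 = none).
#' @param prominence_threshold Barrier threshold for TS detection, kcal/mol.
#' @param tau Neutrality tolerance for barrier changes, kcal/mol.
#' @param align Superpose the target onto the start before morphing (default
#'   `TRUE`, for endpoints from different depositions; set `FALSE` when both
#'   inputs are already membrane-oriented in a common frame).
#' @param seed Master seed; all stochastic draws derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(start, target, chains = NULL, model_index = 1L,
                       hetero = NULL, energy = energy_params(),
                       morph = morph_config(), n_intermediates = 30L,
                       smooth_window = 1L, prominence_threshold = 0.5,
                       tau = 0.25, align = TRUE, seed = 1L) {
  morph$seed <- derive_seed(seed, 1L)
  structure(list(start = start, target = target, chains = chains,
                 model_index = as.integer(model_index), hetero = hetero,
                 energy = energy, morph = morph,
                 n_intermediates = as.integer(n_intermediates),
                 smooth_window = as.integer(smooth_window),
                 prominence_threshold = prominence_threshold,
                 tau = tau, align = isTRUE(align), seed = as.integer(seed)),
            class = "run_config")
}

# deterministic stream seeds below 2^31 derived from the master seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + stream * 8191L) %% 2147483563L
}

#' @rdname run_config
#' @param config A `run_config` (structure endpoints must be file paths for a
#'   lossless round-trip).
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$energy <- unclass(obj$energy)
  obj$energy$hydrophobicity_scale <- as.list(obj$energy$hydrophobicity_scale)
  obj$energy$residue_charges <- as.list(obj$energy$residue_charges)
  obj$morph <- unclass(obj$morph)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- do.call(energy_params, c(
    obj$energy[setdiff(names(obj$energy),
                       c("hydrophobicity_scale", "residue_charges"))],
    list(hydrophobicity_scale = unlist(obj$energy$hydrophobicity_scale),
         residue_charges = unlist(obj$energy$residue_charges))
  ))
  mc_fields <- obj$morph
  mc <- do.call(morph_config, mc_fields)
  run_config(start = obj$start, target = obj$target, chains = obj$chains,
             model_index = obj$model_index, hetero = obj$hetero,
             energy = ep, morph = mc, n_intermediates = obj$n_intermediates,
             smooth_window = obj$smooth_window,
             prominence_threshold = obj$prominence_threshold,
             tau = obj$tau, align = obj$align, seed = obj$seed)
}

load_endpoint <- function(x, config) {
  if (inherits(x, "cg_structure")) return(x)
  read_structure(x, model_index = config$model_index, chains = config$chains,
                 hetero = config$hetero)
}

# read both endpoints, optionally superposing the target onto the start
load_endpoints <- function(config) {
  start <- load_endpoint(config$start, config)
  target <- load_endpoint(config$target, config)
  if (isTRUE(config$align)) {
    target <- apply_transform(target, superpose(target, start))
  }
  list(start = start, target = target)
}

config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97L + 1L)) %% 100000L
}

#' Run the profile experiment: pathway, free-energy profile, barriers
#'
#' Reads the endpoints, morphs the start into the target, extracts
#' `n_intermediates` frames uniformly along the progress coordinate, scores
#' the free-energy profile and reports its stationary points. Outputs:
#' `profile.tsv`, `stationary.json`, `pathway.pdb`, `pathway.tsv` and
#' `config.json` in `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` writes
#'   nothing.
#' @return List with `pathway`, `profile`, `report`, invisibly when
#'   `out_dir` is given.
#' @export
run_profile <- function(config, out_dir = NULL) {
  ep <- load_endpoints(config)
  start <- ep$start; target <- ep$target
  inform(sprintf("cgpathway %s | config hash %05d | seed %d",
                 as.character(utils::packageVersion("cgpathway")),
                 config_hash(config), config$seed))
  path <- targeted_morph(start, target, config$energy, config$morph)
  inform(sprintf("morph: %d frames", length(path$frames)))
  if (length(path$frames) > 1) {
    path <- extract_intermediates(path, config$n_intermediates)
    inform(sprintf("extracted %d intermediates", length(path$frames)))
  }
  prof <- build_profile(path, config$energy)
  if (config$smooth_window > 1L && nrow(prof) >= config$smooth_window) {
    prof <- smooth_profile(prof, config$smooth_window)
  }
  report <- if (nrow(prof) >= 3) {
    find_stationary_points(prof, config$prominence_threshold)
  } else {
    inform("degenerate pathway: no stationary-point analysis")
    NULL
  }
  if (!is.null(report) && nrow(report$maxima) > 0) {
    inform(sprintf("barriers: %s | rate-limiting %s",
                   paste(sprintf("%s=%.2f", report$maxima$label,
                                 report$maxima$barrier), collapse = " "),
                   report$rate_limiting))
  }
  out <- list(pathway = path, profile = prof, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_tsv(prof, file.path(out_dir, "profile.tsv"))
    if (!is.null(report)) {
      write_stationary_json(report, file.path(out_dir, "stationary.json"))
    }
    write_pathway(path, file.path(out_dir, "pathway.pdb"),
                  file.path(out_dir, "pathway.tsv"))
    if (is.character(config$start)) {
      write_run_config(config, file.path(out_dir, "config.json"))
    }
    return(invisible(out))
  }
  out
}

#' Run the side-chain switch experiment
#'
#' Computes the wild-type profile, then re-runs the pipeline with the listed
#' sites' side chains set to their conformation in the reference endpoint
#' (rotamer transfer applied to both endpoints), and reports per-TS barrier
#' differences (switched minus wild-type). Outputs `wt_profile.tsv`,
#' `switched_profile.tsv` and `switch_differences.json`.
#'
#' @param config A [run_config()].
#' @param sites Tibble with `chain`, `resno`, optional `ins`.
#' @param reference Which endpoint supplies the rotamers: `"target"`
#'   (default) or `"start"`.
#' @param out_dir Optional output directory.
#' @return List with `wt`, `switched` (each: `profile`, `report`) and
#'   `differences` tibble (`ts_label`, `barrier_wt`, `barrier_switched`,
#'   `difference`; unmatched TS carry `NA`).
#' @export
run_switch <- function(config, sites, reference = c("target", "start"),
                       out_dir = NULL) {
  reference <- match.arg(reference)
  ep <- load_endpoints(config)
  start <- ep$start; target <- ep$target
  ref <- if (reference == "target") target else start
  sw_start <- start; sw_target <- target
  sites <- as_tibble(sites)
  for (k in seq_len(nrow(sites))) {
    ins <- if ("ins" %in% names(sites)) sites$ins[k] else ""
    if (is.null(ins) || is.na(ins)) ins <- ""
    sw_start <- set_sidechain_from_reference(sw_start, sites$chain[k],
                                             sites$resno[k], ins, ref)
    sw_target <- set_sidechain_from_reference(sw_target, sites$chain[k],
                                              sites$resno[k], ins, ref)
  }
  pipeline <- function(a, b) {
    path <- targeted_morph(a, b, config$energy, config$morph)
    path <- extract_intermediates(path, config$n_intermediates)
    prof <- build_profile(path, config$energy)
    if (config$smooth_window > 1L) prof <- smooth_profile(prof, config$smooth_window)
    list(profile = prof,
         report = find_stationary_points(prof, config$prominence_threshold))
  }
  wt <- pipeline(start, target)
  sw <- pipeline(sw_start, sw_target)
  n <- max(nrow(wt$report$maxima), nrow(sw$report$maxima))
  differences <- purrr::map(seq_len(n), function(i) {
    bw <- if (i <= nrow(wt$report$maxima)) wt$report$maxima$barrier[i] else NA_real_
    bs <- if (i <= nrow(sw$report$maxima)) sw$report$maxima$barrier[i] else NA_real_
    tibble(ts_label = paste0("TS", i), barrier_wt = bw, barrier_switched = bs,
           difference = bs - bw)
  }) |> bind_rows()
  if (nrow(differences) == 0) {
    differences <- tibble(ts_label = character(), barrier_wt = double(),
                          barrier_switched = double(), difference = double())
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_tsv(wt$profile, file.path(out_dir, "wt_profile.tsv"))
    write_profile_tsv(sw$profile, file.path(out_dir, "switched_profile.tsv"))
    jsonlite::write_json(differences, file.path(out_dir, "switch_differences.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(wt = wt, switched = sw, differences = differences)
}

#' Run the alanine-scanning experiment
#'
#' Wraps [ddg_scan()] over a site table (tibble or TSV file with columns
#' `chain`, `resno`, optional `ins`, `mode`). Outputs `ddg.tsv` and
#' `ddg_summary.json` (classification counts per TS plus per-site failures).
#'
#' @param config A [run_config()].
#' @param sites Tibble of sites or path to a TSV file.
#' @param out_dir Optional output directory.
#' @return The `ddg_report` from [ddg_scan()].
#' @export
run_alascan <- function(config, sites, out_dir = NULL) {
  if (is.character(sites)) {
    if (!file.exists(sites)) abort(paste0("cannot read sites file: ", sites))
    sites <- as_tibble(utils::read.delim(sites, sep = "\t",
                                         colClasses = c(chain = "character")))
  }
  ep <- load_endpoints(config)
  report <- ddg_scan(ep$start, ep$target, sites, config$energy, config$morph,
                     tau = config$tau, n_intermediates = config$n_intermediates,
                     smooth_window = config$smooth_window,
                     prominence_threshold = config$prominence_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as_tibble(report), file.path(out_dir, "ddg.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(counts = glance(report),
                    failures = attr(report, "failures"),
                    tau = attr(report, "tau"))
    jsonlite::write_json(summary, file.path(out_dir, "ddg_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
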