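#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr filter mutate arrange group_by ungroup summarise select left_join bind_rows row_number n
#' @importFrom generics tidy glance augment
NULL

# Backbone atom names excluded from the side-chain centroid.
.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

.aa3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Coarse-grained structure: one row per residue
#'
#' A `cg_structure` is a tibble with one row per amino-acid residue carrying a
#' C-alpha bead (`ca_x/ca_y/ca_z`) and, where the residue has resolved
#' side-chain heavy atoms, a side-chain centroid bead (`cen_x/cen_y/cen_z`,
#' `NA` otherwise, e.g. glycine). Rigid hetero beads (ligand or sterol atoms)
#' ride along as a tibble in the `hetero` attribute and never move during
#' morphing. The membrane normal is assumed along the axis named by the
#' `membrane_axis` attribute (default `"z"`, OPM-style pre-oriented input).
#'
#' @param residues Tibble (or data frame) with columns `chain`, `resno`,
#'   `ins`, `resname`, `ca_x`, `ca_y`, `ca_z`, `cen_x`, `cen_y`, `cen_z`,
#'   `n_sc`; optional `bw` (Ballesteros-Weinstein label such as `"6.48"`).
#' @param hetero Optional tibble of rigid hetero beads with columns `name`,
#'   `x`, `y`, `z`, `charge` (elementary units) and `radius` (Angstrom).
#' @param label Free-text label (e.g. source PDB id).
#' @param membrane_axis Axis of the membrane normal; only `"z"` is used by the
#'   energy model, the attribute records the convention.
#' @return A `cg_structure` tibble.
#' @export
cg_structure <- function(residues, hetero = NULL, label = "", membrane_axis = "z") {
  res <- as_tibble(residues)
  req <- c("chain", "resno", "ins", "resname",
           "ca_x", "ca_y", "ca_z", "cen_x", "cen_y", "cen_z", "n_sc")
  miss <- setdiff(req, names(res))
  if (length(miss) > 0) {
    abort(paste0("cg_structure residues lack column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"bw" %in% names(res)) res$bw <- NA_character_
  if (nrow(res) < 1) abort("cg_structure needs at least one residue")
  ca <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
  if (!all(is.finite(ca))) abort("non-finite C-alpha coordinate")
  has_cen <- !is.na(res$cen_x)
  if (any(has_cen != (res$n_sc > 0))) {
    abort("centroid must be present iff n_sc > 0")
  }
  key <- paste(res$chain, res$resno, res$ins)
  if (anyDuplicated(key) > 0) {
    abort("duplicate residue identifier (chain, resno, ins)")
  }
  het <- if (is.null(hetero)) {
    tibble(name = character(), x = double(), y = double(), z = double(),
           charge = double(), radius = double())
  } else {
    h <- as_tibble(hetero)
    if (nrow(h) > 0 && (any(!is.finite(as.matrix(h[, c("x", "y", "z")]))) || any(h$radius <= 0))) {
      abort("hetero beads need finite coordinates and positive radii")
    }
    h
  }
  structure(res,
            class = c("cg_structure", class(tibble())),
            hetero = het, label = label, membrane_axis = membrane_axis)
}

#' @export
print.cg_structure <- function(x, ...) {
  het <- cg_hetero(x)
  cat(sprintf("<cg_structure> %s: %d residues, %d hetero beads\n",
              if (nzchar(cg_label(x))) cg_label(x) else "(unlabelled)",
              nrow(x), nrow(het)))
  NextMethod()
}

#' @rdname cg_structure
#' @param x A `cg_structure`.
#' @export
cg_hetero <- function(x) attr(x, "hetero", exact = TRUE)

#' @rdname cg_structure
#' @export
cg_label <- function(x) attr(x, "label", exact = TRUE) %||% ""

# residue identifier strings "chain|resno|ins"
residue_keys <- function(x) paste(x$chain, x$resno, x$ins, sep = "|")

# n x 3 coordinate matrices for the two bead layers
ca_matrix <- function(x) unname(as.matrix(x[, c("ca_x", "ca_y", "ca_z")]))
cen_matrix <- function(x) unname(as.matrix(x[, c("cen_x", "cen_y", "cen_z")]))

# replace bead coordinates, keeping identifiers/attributes
set_coords <- function(x, ca = NULL, cen = NULL) {
  if (!is.null(ca)) {
    x$ca_x <- ca[, 1]; x$ca_y <- ca[, 2]; x$ca_z <- ca[, 3]
  }
  if (!is.null(cen)) {
    x$cen_x <- cen[, 1]; x$cen_y <- cen[, 2]; x$cen_z <- cen[, 3]
  }
  x
}

#' Read a structure file and coarse-grain it to two beads per residue
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}) and reduces each amino-acid
#' residue to its C-alpha position plus the unweighted mean of its resolved
#' side-chain heavy atoms (all non-hydrogen atoms beyond the backbone
#' N/CA/C/O). Residues without a C-alpha are skipped with a warning; residues
#' with no resolved side-chain heavy atoms (glycine, or unmodelled side
#' chains) carry no centroid bead.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param model_index 1-based model number for multi-model files.
#' @param chains Optional character vector of chain ids to keep.
#' @param hetero Optional character vector of hetero residue names (e.g.
#'   ligand codes) to carry as rigid beads, one bead per heavy atom.
#' @param hetero_charge,hetero_radius Partial charge and radius assigned to
#'   every requested hetero bead (single values; refine by editing the
#'   `hetero` attribute afterwards if needed).
#' @return A [cg_structure()].
#' @export
read_structure <- function(path, model_index = 1L, chains = NULL,
                           hetero = NULL, hetero_charge = 0, hetero_radius = 1.8) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse structure file ", path, ": ",
                                     conditionMessage(e)))
  )
  atoms <- as_tibble(pdb$atom)
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > n_models) {
    abort(sprintf("model %d requested but file has %d model(s)", model_index, n_models))
  }
  if (n_models > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  if (!is.null(chains)) atoms <- filter(atoms, .data$chain %in% chains)
  # drop hydrogens by element symbol when present, else by atom-name heuristic
  if ("elesy" %in% names(atoms)) {
    atoms <- filter(atoms, is.na(.data$elesy) | .data$elesy != "H")
  } else {
    atoms <- filter(atoms, !grepl("^[0-9]*H", .data$elety))
  }

  prot <- filter(atoms, .data$resid %in% .aa3)
  if (nrow(prot) == 0) abort("empty selection: no amino-acid residues after filtering")

  key <- paste(prot$chain, prot$resno, prot$insert, sep = "|")
  prot$.key <- factor(key, levels = unique(key))  # preserve file order
  split_res <- split(prot, prot$.key)
  rows <- purrr::map(split_res, function(r) {
    ca <- r[r$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) return(NULL)
    ca <- ca[1, ]
    sc <- r[!(r$elety %in% .backbone_atoms), , drop = FALSE]
    n_sc <- nrow(sc)
    tibble(
      chain = ca$chain, resno = as.integer(ca$resno), ins = ca$insert,
      resname = ca$resid,
      ca_x = ca$x, ca_y = ca$y, ca_z = ca$z,
      cen_x = if (n_sc > 0) mean(sc$x) else NA_real_,
      cen_y = if (n_sc > 0) mean(sc$y) else NA_real_,
      cen_z = if (n_sc > 0) mean(sc$z) else NA_real_,
      n_sc = as.integer(n_sc)
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("%d residue(s) lacked a C-alpha and were skipped", dropped))
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0) abort("empty selection: no residue with a C-alpha")
  if (any(res$n_sc == 0 & res$resname != "GLY")) {
    warn("residue(s) with no resolved side-chain heavy atoms treated as glycine-like")
  }

  het_tbl <- NULL
  if (!is.null(hetero)) {
    hrows <- filter(atoms, .data$type == "HETATM", .data$resid %in% hetero)
    het_tbl <- tibble(
      name = paste0(hrows$resid, ":", hrows$elety),
      x = hrows$x, y = hrows$y, z = hrows$z,
      charge = rep(hetero_charge, nrow(hrows)),
      radius = rep(hetero_radius, nrow(hrows))
    )
  }
  cg_structure(res, hetero = het_tbl,
               label = sub("\\.[^.]+$", "", basename(path)))
}

#' Write coarse-grained frames as a multi-model PDB
#'
#' Each residue is emitted as a `CA` atom plus (when present) a `CEN`
#' pseudo-atom at the side-chain centroid; hetero beads become `HETATM`
#' records. Multiple frames become `MODEL`/`ENDMDL` blocks, so pathways can be
#' inspected in any molecular viewer.
#'
#' @param x A [cg_structure()] or a list of them (frames).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  frames <- if (inherits(x, "cg_structure")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    lines <- character(0)
    for (i in seq_len(nrow(fr))) {
      serial <- serial + 1L
      lines <- c(lines, .pdb_atom_line("ATOM", serial, "CA", fr$resname[i],
                                       fr$chain[i], fr$resno[i], fr$ins[i],
                                       fr$ca_x[i], fr$ca_y[i], fr$ca_z[i], "C"))
      if (!is.na(fr$cen_x[i])) {
        serial <- serial + 1L
        lines <- c(lines, .pdb_atom_line("ATOM", serial, "CEN", fr$resname[i],
                                         fr$chain[i], fr$resno[i], fr$ins[i],
                                         fr$cen_x[i], fr$cen_y[i], fr$cen_z[i], "C"))
      }
    }
    het <- cg_hetero(fr)
    if (nrow(het) > 0) {
      for (i in seq_len(nrow(het))) {
        serial <- serial + 1L
        nm <- strsplit(het$name[i], ":", fixed = TRUE)[[1]]
        resid <- substr(nm[1], 1, 3)
        aname <- if (length(nm) > 1) nm[2] else "X"
        lines <- c(lines, .pdb_atom_line("HETATM", serial, aname, resid,
                                         "X", i, "", het$x[i], het$y[i], het$z[i], "C"))
      }
    }
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.pdb_atom_line <- function(rec, serial, aname, resname, chain, resno, ins, x, y, z, elem) {
  aname_f <- if (nchar(aname) < 4) sprintf(" %-3s", aname) else sprintf("%-4s", aname)
  sprintf("%-6s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000L, aname_f, resname,
          substr(paste0(chain, "A"), 1, 1), resno %% 10000L,
          substr(paste0(ins, " "), 1, 1), x, y, z, 1, 0, elem)
}

#' Pair residues of two structures by identifier
#'
#' Residues are matched on `(chain, resno, ins)`; order follows the first
#' structure. Unmatched residues of either structure are reported in the
#' `orphans_a` / `orphans_b` attributes of the result.
#'
#' @param a,b [cg_structure()] objects.
#' @return Tibble with columns `idx_a`, `idx_b` (row indices into `a` and
#'   `b`); attributes `orphans_a`, `orphans_b` list unmatched row indices.
#' @export
pair_residues <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) abort("cannot pair empty structures")
  ka <- residue_keys(a)
  kb <- residue_keys(b)
  idx_b <- match(ka, kb)
  keep <- !is.na(idx_b)
  if (!any(keep)) abort("pairing error: zero matched residues")
  out <- tibble(idx_a = which(keep), idx_b = idx_b[keep])
  attr(out, "orphans_a") <- which(!keep)
  attr(out, "orphans_b") <- setdiff(seq_len(nrow(b)), out$idx_b)
  out
}
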