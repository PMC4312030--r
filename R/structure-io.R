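#' Read a protein structure from a PDB file
#'
#' Parses a PDB-format file (via [bio3d::read.pdb()]) into a tidy atom table
#' and applies the model and alternate-location policies up front, so that
#' downstream geometry never sees duplicated atoms. Hydrogens are retained in
#' the table but flagged (`is_h`); waters and other HETATM records are kept
#' with their record `type` and excluded from residue iteration by default.
#'
#' @param path Path to a PDB-format text file.
#' @param model_policy `"first"` (default) keeps MODEL 1; `"index"` keeps the
#'   model given by `model_index`.
#' @param model_index Integer model number used when `model_policy = "index"`.
#' @param altloc_policy `"highest-occupancy"` (default) keeps, per atom, the
#'   alternate location with the largest occupancy (ties broken by altloc
#'   label order); `"label-A"` keeps blank or `"A"` altlocs only.
#' @param id Identifier stored on the structure; defaults to the file name.
#'
#' @return A `protein_structure`: a list with `id`, `atoms` (a tibble with one
#'   row per retained atom: `serial`, `atom_name`, `altloc`, `res_name`,
#'   `chain_id`, `res_seq`, `icode`, `x`, `y`, `z`, `occupancy`, `bfactor`,
#'   `element`, `is_h`, `type`, `model`) and `provenance` (source path and the
#'   policies applied).
#' @export
read_structure <- function(path,
                           model_policy = c("first", "index"),
                           model_index = 1L,
                           altloc_policy = c("highest-occupancy", "label-A"),
                           id = NULL) {
  model_policy <- match.arg(model_policy)
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) {
    stop_input(paste0("cannot read structure: file not found: ", path),
               class = "ssphot_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stop_input(paste0("failed to parse PDB file '", path, "': ",
                        conditionMessage(e)), class = "ssphot_parse_error")
    })

  n_models <- nrow(pdb$xyz)
  want <- if (model_policy == "first") 1L else as.integer(model_index)
  if (want < 1L || want > n_models) {
    stop_input(sprintf("model %d requested but file has %d model(s)",
                       want, n_models), class = "ssphot_input_error")
  }

  at <- pdb$atom
  xyz <- matrix(pdb$xyz[want, ], ncol = 3L, byrow = TRUE)
  atoms <- tibble(
    serial = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    altloc = at$alt,
    res_name = trimws(at$resid),
    chain_id = at$chain,
    res_seq = as.integer(at$resno),
    icode = at$insert,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = at$o,
    bfactor = at$b,
    element = .infer_element(at$elesy, at$elety),
    type = at$type
  )
  atoms$is_h <- atoms$element == "H"
  atoms$model <- want

  bad <- which(atoms$type %in% c("ATOM", "HETATM") &
                 (!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
  if (length(bad) > 0) {
    stop_input(sprintf(
      "malformed coordinate record: atom serial %s ('%s' %s %s%d) has non-numeric coordinates",
      atoms$serial[bad[1]], atoms$atom_name[bad[1]], atoms$res_name[bad[1]],
      atoms$chain_id[bad[1]] %||% "?", atoms$res_seq[bad[1]]),
      class = "ssphot_parse_error")
  }

  atoms <- .apply_altloc_policy(atoms, altloc_policy)
  if (sum(atoms$type == "ATOM") == 0) {
    stop_input(paste0("no protein (ATOM) records in ", path),
               class = "ssphot_empty_structure_error")
  }

  new_structure(atoms,
                id = id %||% sub("\\.pdb$", "", basename(path), ignore.case = TRUE),
                provenance = list(path = path, model_policy = model_policy,
                                  model_index = want,
                                  altloc_policy = altloc_policy))
}

.infer_element <- function(elesy, elety) {
  out <- toupper(trimws(elesy))
  miss <- is.na(out) | out == ""
  if (any(miss)) {
    nm <- gsub("[0-9']", "", trimws(elety[miss]))
    first <- toupper(substr(nm, 1L, 1L))
    two <- toupper(substr(nm, 1L, 2L))
    known2 <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE", "CA")
    # PDB atom names: a leading digit or 'H' means hydrogen; two-letter metals
    # only trusted when the full name is exactly the element symbol
    guess <- ifelse(two %in% known2 & nchar(nm) == 2L, two, first)
    out[miss] <- guess
  }
  out
}

.apply_altloc_policy <- function(atoms, altloc_policy) {
  if (altloc_policy == "label-A") {
    atoms <- atoms[is.na(atoms$altloc) | atoms$altloc %in% c("", "A"), ]
  } else {
    key <- paste(atoms$type, atoms$chain_id, atoms$res_seq,
                 ifelse(is.na(atoms$icode), "", atoms$icode),
                 atoms$res_name, atoms$atom_name, sep = "|")
    ord <- order(key, -atoms$occupancy,
                 ifelse(is.na(atoms$altloc), "", atoms$altloc))
    keep <- ord[!duplicated(key[ord])]
    atoms <- atoms[sort(keep), ]
  }
  atoms
}

#' Construct a protein_structure from an atom table
#'
#' @param atoms Tibble with at least `atom_name`, `res_name`, `chain_id`,
#'   `res_seq`, `x`, `y`, `z`. Missing bookkeeping columns are filled with
#'   defaults (full occupancy, model 1, element inferred from the atom name).
#' @param id Identifier string.
#' @param provenance Optional list describing the origin.
#' @return A `protein_structure`.
#' @export
new_structure <- function(atoms, id = "structure", provenance = list()) {
  atoms <- as_tibble(atoms)
  needed <- c("atom_name", "res_name", "chain_id", "res_seq", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0) {
    stop_input(paste0("atom table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"altloc" %in% names(atoms)) atoms$altloc <- NA_character_
  if (!"icode" %in% names(atoms)) atoms$icode <- NA_character_
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"bfactor" %in% names(atoms)) atoms$bfactor <- 0
  if (!"element" %in% names(atoms)) {
    atoms$element <- .infer_element(NA_character_[seq_len(nrow(atoms))], atoms$atom_name)
  }
  if (!"type" %in% names(atoms)) atoms$type <- "ATOM"
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  atoms$is_h <- atoms$element == "H"
  atoms$res_seq <- as.integer(atoms$res_seq)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  structure(list(id = id, atoms = atoms, provenance = provenance),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  res <- residues(x)
  cat("<protein_structure> ", x$id, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), " (", sum(x$atoms$is_h), " H)",
      "  residues: ", nrow(res),
      "  chains: ", paste(unique(res$chain_id), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' List the protein residues of a structure
#'
#' One row per residue, ATOM records only (waters/HETATM excluded).
#'
#' @param structure A `protein_structure`.
#' @param chain Optional chain id filter.
#' @return Tibble with `chain_id`, `res_seq`, `icode`, `res_name`.
#' @export
residues <- function(structure, chain = NULL) {
  at <- structure$atoms
  at <- at[at$type == "ATOM", ]
  if (!is.null(chain)) at <- at[at$chain_id %in% chain, ]
  out <- distinct(at, .data$chain_id, .data$res_seq, .data$icode, .data$res_name)
  arrange(out, .data$chain_id, .data$res_seq)
}

#' Reference to a single residue
#'
#' @param chain_id Chain identifier.
#' @param res_seq Author residue number.
#' @param icode Insertion code (default none).
#' @param res_name Optional 3-letter residue name (checked when given).
#' @return A one-row tibble usable wherever a residue reference is expected.
#' @export
residue_ref <- function(chain_id, res_seq, icode = NA_character_,
                        res_name = NA_character_) {
  tibble(chain_id = chain_id, res_seq = as.integer(res_seq),
         icode = icode, res_name = res_name)
}

.residue_atoms <- function(structure, ref, heavy_only = TRUE) {
  at <- structure$atoms
  sel <- at$type == "ATOM" &
    at$chain_id == ref$chain_id[1] &
    at$res_seq == ref$res_seq[1] &
    (is.na(ref$icode[1]) | (!is.na(at$icode) & at$icode == ref$icode[1]) |
       (is.na(at$icode) & is.na(ref$icode[1])))
  out <- at[sel, ]
  if (heavy_only) out <- out[!out$is_h, ]
  out
}

# atoms of the aromatic ring systems considered for proximity to disulphides:
# the indole of Trp and the benzene of Tyr (phenolic OH deliberately excluded)
.RING_ATOMS <- list(
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
)

#' Ring-atom coordinates of an aromatic residue
#'
#' For Trp the nine indole-ring atoms; for Tyr the six benzene-ring atoms
#' (the hydroxyl oxygen is not part of the ring and is excluded). Atoms absent
#' from the model are omitted with a warning.
#'
#' @param structure A `protein_structure`.
#' @param residue A residue reference ([residue_ref()] or a row of
#'   [residues()]); must be TRP or TYR.
#' @return Tibble with `atom_name`, `x`, `y`, `z`; attribute `n_missing`
#'   counts ring atoms absent from the model.
#' @export
ring_atoms <- function(structure, residue) {
  at <- .residue_atoms(structure, residue)
  rn <- unique(at$res_name)
  if (length(rn) == 0) stop_input("residue not found in structure")
  if (rn[1] %notin% names(.RING_ATOMS)) {
    stop_input(paste0("ring_atoms requires a TRP or TYR residue, got ", rn[1]),
               class = "ssphot_type_error")
  }
  want <- .RING_ATOMS[[rn[1]]]
  out <- at[at$atom_name %in% want, c("atom_name", "x", "y", "z")]
  n_missing <- length(want) - nrow(out)
  if (nrow(out) == 0) {
    stop_input(paste0("no ring atoms present for ", rn[1], " ",
                      residue$res_seq[1]), class = "ssphot_missing_atoms_error")
  }
  if (n_missing > 0) {
    warn(sprintf("%s %s%d: %d ring atom(s) missing from model", rn[1],
                 residue$chain_id[1], residue$res_seq[1], n_missing))
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Ortho-carbon coordinates of a tyrosine
#'
#' The two ring carbons ortho to the hydroxyl-bearing CZ (CE1 and CE2), the
#' positions through which dityrosine crosslinks form.
#'
#' @inheritParams ring_atoms
#' @return Tibble with `atom_name`, `x`, `y`, `z`.
#' @export
ortho_carbons <- function(structure, residue) {
  at <- .residue_atoms(structure, residue)
  rn <- unique(at$res_name)
  if (length(rn) == 0) stop_input("residue not found in structure")
  if (rn[1] != "TYR") {
    stop_input(paste0("ortho_carbons requires a TYR residue, got ", rn[1]),
               class = "ssphot_type_error")
  }
  out <- at[at$atom_name %in% c("CE1", "CE2"), c("atom_name", "x", "y", "z")]
  if (nrow(out) == 0) {
    stop_input(paste0("both ortho carbons missing for TYR ", residue$res_seq[1]),
               class = "ssphot_missing_atoms_error")
  }
  if (nrow(out) < 2) {
    warn(sprintf("TYR %s%d: one ortho carbon missing from model",
                 residue$chain_id[1], residue$res_seq[1]))
  }
  out
}

#' Cystine atom coordinates under a selection convention
#'
#' The atom set representing a disulphide bond in distance calculations:
#' `"all-atoms"` takes every heavy atom of both cysteine residues (backbone
#' included), `"sidechain"` takes CB and SG of both, `"sulfur-only"` the two
#' SG atoms.
#'
#' @param structure A `protein_structure`.
#' @param bond Either a row of [detect_disulfides()] output or a two-row
#'   residue-reference tibble; both residues must be CYS.
#' @param convention One of `"all-atoms"` (default), `"sidechain"`,
#'   `"sulfur-only"`.
#' @return Tibble with `atom_name`, `res_seq`, `x`, `y`, `z`.
#' @export
cystine_atoms <- function(structure, bond,
                          convention = c("all-atoms", "sidechain", "sulfur-only")) {
  convention <- match.arg(convention)
  refs <- .bond_refs(bond)
  parts <- lapply(seq_len(2), function(i) {
    at <- .residue_atoms(structure, refs[i, ])
    if (nrow(at) == 0 || unique(at$res_name)[1] != "CYS") {
      stop_input("cystine_atoms requires two CYS residues",
                 class = "ssphot_type_error")
    }
    keep <- switch(convention,
                   "all-atoms" = rep(TRUE, nrow(at)),
                   "sidechain" = at$atom_name %in% c("CB", "SG"),
                   "sulfur-only" = at$atom_name == "SG")
    at[keep, c("atom_name", "res_seq", "x", "y", "z")]
  })
  bind_rows(parts)
}

# accept either a detect_disulfides() row or a 2-row residue-ref tibble
.bond_refs <- function(bond) {
  if (all(c("cys1_res_seq", "cys2_res_seq") %in% names(bond))) {
    bond <- bond[1, ]
    bind_rows(
      residue_ref(bond$cys1_chain, bond$cys1_res_seq, bond$cys1_icode %||% NA_character_),
      residue_ref(bond$cys2_chain, bond$cys2_res_seq, bond$cys2_icode %||% NA_character_))
  } else if (nrow(bond) == 2 && all(c("chain_id", "res_seq") %in% names(bond))) {
    bond
  } else {
    stop_input("bond must be a disulfide-table row or a two-row residue reference")
  }
}

#' Write a structure to a PDB-format file
#'
#' Round-trip safe for the retained atom table: atom names, residue numbering
#' and coordinates (to 3 decimals) survive `read_structure(write_structure(s))`.
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                     type = at$type,
                     resno = at$res_seq,
                     resid = at$res_name,
                     eleno = at$serial,
                     elety = at$atom_name,
                     chain = at$chain_id,
                     insert = at$icode,
                     alt = at$altloc,
                     o = at$occupancy,
                     b = at$bfactor,
                     elesy = at$element)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_input(paste0("cannot write structure to '", path, "': ",
                      conditionMessage(ok)), class = "ssphot_io_error")
  }
  invisible(path)
}

# coordinate matrix from an atom/coordinate tibble
atom_xyz <- function(tbl) {
  unname(as.matrix(tbl[, c("x", "y", "z"), drop = FALSE]))
}

#' Restrict a structure to one chain
#'
#' Default chain is the one with the most cysteine residues, the chain a
#' disulphide analysis targets.
#'
#' @param structure A `protein_structure`.
#' @param chain Chain id; `NULL` picks the chain with the most CYS residues
#'   (ties broken alphabetically).
#' @return A `protein_structure` restricted to that chain.
#' @export
select_chain <- function(structure, chain = NULL) {
  res <- residues(structure)
  if (is.null(chain)) {
    cys <- res[res$res_name == "CYS", ]
    counts <- table(if (nrow(cys) > 0) cys$chain_id else res$chain_id)
    chain <- names(counts)[order(-counts, names(counts))][1]
  }
  at <- structure$atoms[structure$atoms$chain_id %in% chain |
                          structure$atoms$type != "ATOM", ]
  out <- structure
  out$atoms <- at
  out$provenance$chain <- chain
  out
}
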