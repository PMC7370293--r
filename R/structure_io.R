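# Reading one protein chain into the residue/atom model used by the
# contact-graph builder. One protein = one chain; heteroatoms, waters,
# hydrogens and non-standard residues are excluded up front.

#' @keywords internal
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' @keywords internal
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Read a protein chain from a PDB file
#'
#' Parses ATOM records of one chain into a `protein_structure`: an ordered
#' residue list with heavy-atom coordinates and a sequential residue index.
#' Hydrogens, waters, HETATM records and non-standard residues are dropped;
#' for NMR-style multi-model files only the first model is read. Where a
#' residue carries alternate conformers, exactly one is kept per
#' `altloc_policy`.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (single character). `NULL` selects the
#'   first chain in file order.
#' @param altloc_policy Currently `"highest-occupancy"`: keep the conformer
#'   with the largest occupancy; ties prefer altloc `"A"`, then the
#'   lexicographically smallest label.
#' @param seq_numbering `"sequential"` renumbers kept residues 1..L in file
#'   order (gaps in author numbering collapse); `"author"` keeps the
#'   author residue numbers as sequence positions for the proximity
#'   partition.
#' @return An object of class `protein_structure` with fields
#'   `structure_id`, `chain_id`, `atoms` (one row per atom), `seq_positions`
#'   (per-residue sequence position used for proximity) and `n_residues`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_fixture_pdb(generate_chain(chain_spec(5, seed = 1)), pdb)
#' s <- read_structure(pdb, chain = "A")
#' s$n_residues
#' @export
read_structure <- function(path, chain = NULL,
                           altloc_policy = "highest-occupancy",
                           seq_numbering = c("sequential", "author")) {
  seq_numbering <- match.arg(seq_numbering)
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("file not found: ", path)
  }
  if (!identical(altloc_policy, "highest-occupancy")) {
    stop("unknown altloc policy: ", altloc_policy)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         rm.insert = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty chain: no ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains) {
    stop("chain not found: '", chain, "' (file has: ",
         paste(chains, collapse = ", "), ")")
  }
  at <- at[at$chain == chain, , drop = FALSE]

  # element symbol: prefer columns 77-78, fall back to the atom name
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) {
    guess <- sub("^[0-9]*", "", trimws(at$elety[miss]))
    elem[miss] <- toupper(substr(guess, 1L, 1L))
  }
  keep <- !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]

  std <- at$resid %in% STANDARD_AA
  n_nonstd <- length(unique(paste(at$resno[!std], at$insert[!std])))
  if (n_nonstd > 0L) {
    warning("dropped ", n_nonstd, " non-standard residue(s) in chain ", chain)
  }
  at <- at[std, , drop = FALSE]
  elem <- elem[std]
  if (nrow(at) == 0L) stop("empty chain: no standard residues in chain ", chain)

  ins <- at$insert
  ins[is.na(ins)] <- ""
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1

  # altloc resolution: one conformer per (residue, atom name)
  key <- paste(at$resno, ins, trimws(at$elety), sep = "\r")
  keep_idx <- unsplit_pick(key, occ, alt)
  ord <- sort(keep_idx)
  at <- at[ord, , drop = FALSE]
  elem <- elem[ord]
  ins <- ins[ord]
  alt <- alt[ord]
  occ <- occ[ord]

  res_key <- paste(at$resno, ins, sep = "\r")
  res_node <- match(res_key, unique(res_key))
  atom_name <- trimws(at$elety)
  atoms <- data.frame(
    res_node = res_node,
    author_number = at$resno,
    insert = ins,
    res_name = at$resid,
    atom_name = atom_name,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occupancy = occ,
    altloc = alt,
    is_backbone = atom_name %in% BACKBONE_ATOMS,
    stringsAsFactors = FALSE
  )

  # every residue must carry at least one backbone atom
  has_bb <- tapply(atoms$is_backbone, atoms$res_node, any)
  bad <- as.integer(names(has_bb))[!has_bb]
  if (length(bad) > 0L) {
    warning("dropped ", length(bad), " residue(s) with no backbone atom")
    atoms <- atoms[!(atoms$res_node %in% bad), , drop = FALSE]
    if (nrow(atoms) == 0L) stop("empty chain: no residues survive filtering")
    atoms$res_node <- match(atoms$res_node, unique(atoms$res_node))
  }

  n_res <- max(atoms$res_node)
  first_rows <- match(seq_len(n_res), atoms$res_node)
  seq_positions <- switch(seq_numbering,
    sequential = seq_len(n_res),
    author = atoms$author_number[first_rows]
  )
  if (seq_numbering == "author" && any(diff(seq_positions) <= 0)) {
    warning("author numbering not strictly increasing; ",
            "falling back to sequential indexing")
    seq_positions <- seq_len(n_res)
  }

  structure(
    list(
      structure_id = paste0(sub("\\.(pdb|ent)$", "", basename(path),
                                ignore.case = TRUE), "_", chain),
      chain_id = chain,
      atoms = atoms,
      seq_positions = as.integer(seq_positions),
      n_residues = n_res
    ),
    class = "protein_structure"
  )
}

# pick one row index per key: highest occupancy, ties -> altloc "A",
# then lexicographic altloc
#' @keywords internal
unsplit_pick <- function(key, occ, alt) {
  idx <- seq_along(key)
  pref <- ifelse(alt == "" | alt == "A", 0L, 1L)
  picks <- vapply(split(idx, key), function(rows) {
    o <- order(-occ[rows], pref[rows], alt[rows], rows)
    rows[o[1L]]
  }, integer(1))
  unname(picks)
}

#' Select the atom subset used for contact computation
#'
#' `mode = "SC"` keeps all heavy atoms (backbone plus sidechain);
#' `mode = "noSC"` keeps the backbone atoms N, CA, C, O only.
#'
#' @param structure A `protein_structure`.
#' @param mode `"SC"` or `"noSC"`.
#' @return The structure's atom table filtered to the selected subset.
#' @export
select_atoms <- function(structure, mode = c("SC", "noSC")) {
  mode <- match.arg(mode)
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atoms
  if (mode == "noSC") at <- at[at$is_backbone, , drop = FALSE]
  left <- unique(at$res_node)
  missing <- setdiff(seq_len(structure$n_residues), left)
  if (length(missing) > 0L) {
    stop("atom selection empty for residue(s): ",
         paste(missing, collapse = ", "))
  }
  at
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure", x$structure_id, "- chain", x$chain_id, "-",
      x$n_residues, "residues,", nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Residue table of a structure
#'
#' One row per residue: sequence index, author numbering and residue name.
#'
#' @param structure A `protein_structure`.
#' @return A data frame with one row per residue.
#' @export
residue_table <- function(structure) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atoms
  first <- match(seq_len(structure$n_residues), at$res_node)
  data.frame(
    seq_index = structure$seq_positions,
    author_number = at$author_number[first],
    insert = at$insert[first],
    res_name = at$res_name[first],
    n_atoms = as.integer(table(at$res_node)),
    stringsAsFactors = FALSE
  )
}
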