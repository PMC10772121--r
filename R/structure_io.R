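#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses a structure file into a lightweight hierarchical model (chains,
#' residues, atoms) used by all downstream analyses. Only the first model of
#' multi-model files is read. Alternate-location duplicates are resolved to
#' the highest-occupancy conformer (ties broken toward altloc `"A"`), and
#' hydrogens are dropped by default so that all geometric criteria operate on
#' heavy atoms. Waters and non-polymer heteroatoms are retained but flagged
#' via the `is_hetero` column.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format One of `"auto"` (by file extension), `"pdb"`, `"mmcif"`.
#' @param keep_hydrogens Keep hydrogen/deuterium atoms (default drops them).
#' @return An object of class `epi_structure`: a list with elements `id`
#'   (file stem), `atoms` (data frame with columns `serial`, `name`,
#'   `element`, `x`, `y`, `z`, `occupancy`, `altloc`, `chain`, `resno`,
#'   `insert`, `resid`, `is_hetero`) and `source` (the input path).
#' @examples
#' pdb <- write_structure(make_toy_complex(n_res = 4)$structure,
#'                        tempfile(fileext = ".pdb"))
#' s <- read_structure(pdb)
#' s
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
      stop("cannot infer structure format from extension '.", ext,
           "'; pass format = \"pdb\" or \"mmcif\"")
    )
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (nrow(at) == 0L) stop("no atoms parsed from ", path)

  element <- at$elesy
  if (is.null(element)) element <- rep("", nrow(at))
  element <- toupper(trimws(element))
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- guess_element(at$elety[missing_el])

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", trimws(at$alt)),
    chain = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert) | at$insert == "", "", trimws(at$insert)),
    resid = toupper(trimws(at$resid)),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )

  if (!keep_hydrogens) atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- resolve_altloc(atoms)
  if (nrow(atoms) == 0L) stop("structure contains no (heavy) atoms: ", path)
  rownames(atoms) <- NULL

  new_epi_structure(
    id = tools::file_path_sans_ext(basename(path)),
    atoms = atoms, source = path
  )
}

new_epi_structure <- function(id, atoms, source = NA_character_) {
  stopifnot(is.data.frame(atoms))
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) stop("non-finite coordinates for atom serial(s): ",
                     paste(atoms$serial[bad], collapse = ", "))
  structure(list(id = id, atoms = atoms, source = source),
            class = "epi_structure")
}

# Element symbol from a PDB atom name when the element column is absent.
guess_element <- function(names) {
  vapply(names, function(nm) {
    nm <- gsub("[^A-Za-z]", "", trimws(nm))
    if (nchar(nm) == 0L) return("X")
    two <- toupper(substr(nm, 1, 2))
    if (two %in% c("FE", "ZN", "MG", "MN", "CU", "NI", "CO", "SE", "BR", "CL"))
      return(two)
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

# Keep one conformer per (residue, atom name): highest occupancy, ties to 'A'.
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' @export
print.epi_structure <- function(x, ...) {
  info <- structure_info(x)
  cat("<epi_structure> ", x$id, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), ", chains: ",
      paste(info$chains$chain, collapse = ", "), "\n", sep = "")
  for (i in seq_len(nrow(info$chains))) {
    ch <- info$chains[i, ]
    cat(sprintf("  chain %s: %d residues, %d atoms\n",
                ch$chain, ch$n_residues, ch$n_atoms))
  }
  if (nrow(info$hetero) > 0) {
    cat("  hetero: ",
        paste(sprintf("%s x%d", info$hetero$resid, info$hetero$n),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Summarise chains, residue counts and hetero content of a structure
#'
#' @param structure An `epi_structure`.
#' @return A list with data frames `chains` (chain, n_residues, n_atoms) and
#'   `hetero` (resid, n occurrences among hetero residues).
#' @export
structure_info <- function(structure) {
  at <- structure$atoms
  rkey <- residue_key(at$chain, at$resno, at$insert)
  chains <- unique(at$chain)
  ch <- do.call(rbind, lapply(chains, function(c0) {
    sub <- at[at$chain == c0, , drop = FALSE]
    data.frame(chain = c0,
               n_residues = length(unique(residue_key(sub$chain, sub$resno, sub$insert))),
               n_atoms = nrow(sub), stringsAsFactors = FALSE)
  }))
  het <- at[at$is_hetero, , drop = FALSE]
  if (nrow(het) > 0) {
    hkey <- unique(data.frame(resid = het$resid,
                              key = residue_key(het$chain, het$resno, het$insert),
                              stringsAsFactors = FALSE))
    tab <- table(hkey$resid)
    hetero <- data.frame(resid = names(tab), n = as.integer(tab),
                         stringsAsFactors = FALSE)
  } else {
    hetero <- data.frame(resid = character(0), n = integer(0))
  }
  list(chains = ch, hetero = hetero)
}

#' Subset a structure by chain, residue range and heteroatom status
#'
#' Returns a new structure containing exactly the atoms satisfying the
#' selection; the input is never modified. An empty result is an error, not a
#' silently empty structure.
#'
#' @param structure An `epi_structure`.
#' @param chains Character vector of chain ids to keep (`NULL` keeps all).
#' @param residues Optional integer vector of author residue numbers to keep
#'   (e.g. `1:101` for an N-terminal domain).
#' @param exclude_waters Drop water residues (HOH/WAT/DOD).
#' @param exclude_hetero Drop all HETATM records (includes waters, glycans,
#'   ions).
#' @return An `epi_structure` with the selected atoms.
#' @export
select_structure <- function(structure, chains = NULL, residues = NULL,
                             exclude_waters = FALSE, exclude_hetero = FALSE) {
  at <- structure$atoms
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(at$chain))
    if (length(missing) > 0)
      stop("chain id(s) not present in structure: ",
           paste(missing, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  if (!is.null(residues)) at <- at[at$resno %in% residues, , drop = FALSE]
  if (exclude_waters) at <- at[!is_water_name(at$resid), , drop = FALSE]
  if (exclude_hetero) at <- at[!at$is_hetero, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("selection matches no atoms (chains = ",
         paste(chains %||% "<all>", collapse = ","), ")")
  rownames(at) <- NULL
  new_epi_structure(structure$id, at, structure$source)
}

#' Write a structure to a PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals), so a
#' write/read round trip preserves atom count, names and coordinates to
#' 0.001 Angstrom.
#'
#' @param structure An `epi_structure`.
#' @param path Output file path.
#' @return `path`, invisibly... returned visibly for convenience in pipelines.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(at$is_hetero, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid, eleno = at$serial,
    elety = at$name, chain = ifelse(at$chain == " ", "", at$chain),
    insert = ifelse(at$insert == "", NA, at$insert),
    o = at$occupancy, b = rep(0, nrow(at)), elesy = at$element,
    end = TRUE
  )
  path
}

# n x 3 coordinate matrix of a structure's atoms.
coords_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# Unique residues in order of appearance: chain, resno, insert, resid, key.
residue_table <- function(structure) {
  at <- structure$atoms
  key <- residue_key(at$chain, at$resno, at$insert)
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             insert = at$insert[first], resid = at$resid[first],
             key = key[first], stringsAsFactors = FALSE)
}
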