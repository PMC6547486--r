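# PDB reading/writing and chain validation. Parsing is delegated to bio3d;
# everything after the raw atom table (filtering, typing, renumbering) is ours.

new_protein_chain <- function(atoms, chain_id) {
  stopifnot(is.data.frame(atoms))
  rownames(atoms) <- NULL
  res_idx <- unique(atoms$residue_index)
  structure(
    list(chain_id = chain_id,
         atoms = atoms,
         sequence = atoms$residue_name[!duplicated(atoms$residue_index)],
         length = length(res_idx)),
    class = "protein_chain")
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain %s: %d residues, %d heavy atoms>\n",
              x$chain_id, x$length, nrow(x$atoms)))
  invisible(x)
}

coords <- function(chain) {
  as.matrix(chain$atoms[, c("x", "y", "z")])
}

#' Read one protein chain from a PDB file
#'
#' Reads the first model of a PDB file, keeps the requested chain, and reduces
#' it to the atoms the potential is defined over: hydrogens, waters,
#' hetero-residues, terminal `OXT` and alternate locations other than
#' blank/`'A'` are dropped, and the remaining standard residues are renumbered
#' consecutively from 1. Every retained atom carries a valid heavy-atom type
#' index (see [atom_type_table()]).
#'
#' @param path Path to a PDB file.
#' @param chain_id Chain identifier; `NULL` takes the first chain present.
#' @return A `protein_chain`: list with `chain_id`, `atoms` (data frame with
#'   `residue_name`, `atom_name`, `residue_index`, `type_index`, `x`, `y`,
#'   `z`), `sequence` and `length`.
#' @export
read_pdb <- function(path, chain_id = NULL) {
  if (!file.exists(path))
    stop(andis_error("parse", paste("file not found:", path)))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e)
      stop(andis_error("parse", paste("cannot parse PDB:", conditionMessage(e)))))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain_id)) {
    chain_id <- at$chain[1]
    if (is.na(chain_id)) chain_id <- " "
  }
  keep_chain <- at$chain == chain_id | (is.na(at$chain) & chain_id == " ")
  if (!any(keep_chain, na.rm = TRUE))
    stop(andis_error("parse", paste("chain not found:", chain_id)))
  at <- at[which(keep_chain), , drop = FALSE]
  at <- at[at$resid %in% standard_residues(), , drop = FALSE]
  at <- at[at$alt %in% c("", " ", "A") | is.na(at$alt), , drop = FALSE]
  elem <- at$elesy
  hydro <- (!is.na(elem) & elem %in% c("H", "D")) |
    grepl("^[0-9]*H", at$elety)
  at <- at[!hydro, , drop = FALSE]
  known <- !is.na(type_lookup()[paste(at$resid, at$elety)])
  at <- at[known, , drop = FALSE]  # drops OXT and other non-typed names
  if (nrow(at) == 0L)
    stop(andis_error("parse", "no standard residues in chain"))
  res_key <- paste(at$resno, at$insert)
  residue_index <- match(res_key, unique(res_key))
  dup <- duplicated(paste(residue_index, at$elety))
  at <- at[!dup, , drop = FALSE]
  residue_index <- residue_index[!dup]
  atoms <- data.frame(
    residue_name = at$resid,
    atom_name = at$elety,
    residue_index = residue_index,
    type_index = atom_type(at$resid, at$elety),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  new_protein_chain(atoms, chain_id)
}

#' Write a protein chain to a PDB file
#'
#' @param chain A `protein_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chain, path) {
  a <- chain$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords(chain))),
    resno = a$residue_index,
    resid = a$residue_name,
    eleno = seq_len(nrow(a)),
    elety = a$atom_name,
    chain = substr(chain$chain_id, 1, 1))
  invisible(path)
}

#' Validate a chain for use in potential derivation
#'
#' Training chains must have between 30 and 1000 residues and every residue
#' must carry the complete heavy-atom set of its residue type; chains with
#' incomplete or (already filtered) nonstandard residues are rejected.
#'
#' @param chain A `protein_chain`.
#' @return A list with `ok` (logical) and `reason` (`NA` when valid).
#' @export
validate_training_chain <- function(chain) {
  n <- chain$length
  if (n < 30L) return(list(ok = FALSE, reason = "length < 30"))
  if (n > 1000L) return(list(ok = FALSE, reason = "length > 1000"))
  tab <- atom_type_table()
  expected <- table(tab$residue)[chain$sequence]
  got <- tabulate(chain$atoms$residue_index, nbins = n)
  if (any(got != as.integer(expected))) {
    bad <- which(got != as.integer(expected))[1]
    return(list(ok = FALSE,
                reason = sprintf("incomplete residue %d (%s)", bad,
                                 chain$sequence[bad])))
  }
  list(ok = TRUE, reason = NA_character_)
}
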