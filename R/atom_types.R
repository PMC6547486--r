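# Cache for the parsed atom-type table
.andis <- new.env(parent = emptyenv())

#' Residue-specific heavy-atom type table
#'
#' The 20 standard amino acids contain 167 distinct heavy (non-hydrogen)
#' atoms when atoms are distinguished by residue: `(residue, atom)` pairs such
#' as `("ALA", "CB")` each receive a unique type index in `1..167`. The table
#' also fixes, for every atom, the two bonded neighbours used to build its
#' local coordinate frame (the next-neighbour bonded atom stands in when an
#' atom has a single bonded heavy neighbour, e.g. backbone `O` uses `C` and
#' `CA`). Neighbour names prefixed `-`/`+` refer to the previous/next residue
#' (backbone `N` bonds the preceding `C`; backbone `C` the following `N`).
#'
#' The table ships as a plain-text file
#' (`system.file("extdata", "atom_types.tsv", package = "andis")`) so its
#' content can be inspected and asserted against.
#'
#' @return A data frame with columns `residue`, `atom`, `index`, `neighbor1`,
#'   `neighbor2`, one row per atom type (167 rows).
#' @export
#' @examples
#' tab <- atom_type_table()
#' nrow(tab) # 167
atom_type_table <- function() {
  if (is.null(.andis$type_table)) {
    path <- system.file("extdata", "atom_types.tsv", package = "andis")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 167L)
    idx <- tab$index
    names(idx) <- paste(tab$residue, tab$atom)
    .andis$type_table <- tab
    .andis$type_lookup <- idx
  }
  .andis$type_table
}

type_lookup <- function() {
  atom_type_table()
  .andis$type_lookup
}

#' Map a (residue, atom) pair to its heavy-atom type index
#'
#' @param residue_name Three-letter residue code(s), e.g. `"ALA"`.
#' @param atom_name PDB heavy-atom name(s), e.g. `"CB"`.
#' @return Integer type index (vectorised), each in `1..167`.
#' @export
#' @examples
#' atom_type("GLY", "CA")
atom_type <- function(residue_name, atom_name) {
  idx <- unname(type_lookup()[paste(residue_name, atom_name)])
  if (anyNA(idx)) {
    bad <- paste(residue_name, atom_name)[is.na(idx)]
    stop(andis_error("type",
      sprintf("unknown (residue, atom) pair(s): %s",
              paste(unique(bad), collapse = ", "))))
  }
  as.integer(idx)
}

#' Heavy-atom complement of a standard residue
#'
#' @param residue_name Three-letter residue code.
#' @return Character vector of heavy-atom names in canonical order.
#' @export
residue_atoms <- function(residue_name) {
  tab <- atom_type_table()
  out <- tab$atom[tab$residue == residue_name]
  if (length(out) == 0L)
    stop(andis_error("type", paste("unknown residue:", residue_name)))
  out
}

#' The 20 standard amino acids (three-letter codes)
#' @return Character vector of length 20.
#' @export
standard_residues <- function() unique(atom_type_table()$residue)

# Frame-defining neighbours of one atom type (names, possibly '-'/'+' prefixed)
frame_neighbors <- function(residue_name, atom_name) {
  tab <- atom_type_table()
  row <- which(tab$residue == residue_name & tab$atom == atom_name)
  if (length(row) != 1L)
    stop(andis_error("type",
      sprintf("unknown (residue, atom) pair: %s %s", residue_name, atom_name)))
  c(tab$neighbor1[row], tab$neighbor2[row])
}

# Structured condition helper shared across modules
andis_error <- function(kind, message) {
  structure(
    class = c(paste0("andis_", kind, "_error"), "andis_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1)))
}
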