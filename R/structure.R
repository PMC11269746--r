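# Structure-derived site groups: inter-chain interface residues and
# ligand-binding residues by an any-atom distance rule, and mapping of
# structure residue numbers to alignment columns.

#' Parse a PDB structure into an atom table
#'
#' Reads ATOM/HETATM records (via bio3d). Only the first alternate location
#' of each atom is kept (`altloc = "occupancy"` keeps the highest-occupancy
#' one instead) and waters are excluded by default.
#'
#' @param pdb PDB-format text (single string or character vector of lines)
#'   or a path to a PDB file.
#' @param keep_water keep HOH/WAT records (default FALSE).
#' @param altloc `"first"` (default) or `"occupancy"`.
#' @return data frame with columns `type`, `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`, `o`.
#' @export
parse_structure <- function(pdb, keep_water = FALSE, altloc = "first") {
  altloc <- match.arg(altloc, c("first", "occupancy"))
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || !file.exists(pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(paste(pdb, collapse = "\n"), path)
  }
  at <- bio3d::read.pdb(path)$atom
  if (!keep_water) at <- at[!at$resid %in% c("HOH", "WAT"), , drop = FALSE]
  key <- paste(at$chain, at$resno, at$elety, at$insert)
  if (anyDuplicated(key)) {
    ord <- if (altloc == "occupancy") order(-at$o) else seq_len(nrow(at))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety, at$insert)), ,
             drop = FALSE]
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("parse-error: non-finite atom coordinates")
  data.frame(type = at$type, chain = at$chain, resno = at$resno,
             resid = at$resid, elety = at$elety,
             x = at$x, y = at$y, z = at$z, o = at$o)
}

# minimum distance from each subject residue to any counterpart atom
.residue_min_dist <- function(subject, counterpart) {
  cxyz <- as.matrix(counterpart[, c("x", "y", "z")])
  res <- unique(subject[, c("chain", "resno", "resid")])
  res$min_distance <- vapply(seq_len(nrow(res)), function(i) {
    a <- subject[subject$resno == res$resno[i], c("x", "y", "z"), drop = FALSE]
    m <- Inf
    for (j in seq_len(nrow(a))) {
      d2 <- (cxyz[, 1] - a$x[j])^2 + (cxyz[, 2] - a$y[j])^2 + (cxyz[, 3] - a$z[j])^2
      m <- min(m, min(d2))
    }
    sqrt(m)
  }, 0)
  res
}

#' Inter-chain interface residues
#'
#' Residues of the subject chain with any atom within `cutoff` (inclusive)
#' of any atom of the counterpart chain.
#'
#' @param atoms atom table from [parse_structure()].
#' @param subject_chain,counterpart_chain chain identifiers.
#' @param cutoff distance in Angstrom (default 5.0, inclusive).
#' @return data frame with `chain`, `resno`, `resid`, `min_distance`, sorted
#'   by residue number.
#' @export
chain_interface <- function(atoms, subject_chain, counterpart_chain,
                            cutoff = 5.0) {
  s <- atoms[atoms$chain == subject_chain, , drop = FALSE]
  c_ <- atoms[atoms$chain == counterpart_chain, , drop = FALSE]
  if (!nrow(s)) stop("chain not found: ", subject_chain)
  if (!nrow(c_)) stop("chain not found: ", counterpart_chain)
  res <- .residue_min_dist(s, c_)
  out <- res[res$min_distance <= cutoff, , drop = FALSE]
  out[order(out$resno), , drop = FALSE]
}

#' Ligand-contact residues
#'
#' Residues of the subject chain with any atom within `cutoff` (inclusive)
#' of any atom of the named HETATM ligand.
#'
#' @param atoms atom table from [parse_structure()].
#' @param subject_chain chain identifier.
#' @param ligand_resname ligand residue name (e.g. `"NAD"`).
#' @param cutoff distance in Angstrom (default 5.0, inclusive).
#' @return data frame as in [chain_interface()].
#' @export
ligand_contacts <- function(atoms, subject_chain, ligand_resname,
                            cutoff = 5.0) {
  s <- atoms[atoms$chain == subject_chain & atoms$type == "ATOM", , drop = FALSE]
  lig <- atoms[atoms$resid == ligand_resname & atoms$type == "HETATM", ,
               drop = FALSE]
  if (!nrow(s)) stop("chain not found: ", subject_chain)
  if (!nrow(lig)) stop("ligand not found: ", ligand_resname)
  res <- .residue_min_dist(s, lig)
  out <- res[res$min_distance <= cutoff, , drop = FALSE]
  out[order(out$resno), , drop = FALSE]
}

#' Map structure residue numbers to alignment columns
#'
#' The k-th non-gap character of the reference alignment row corresponds to
#' residue number `offset + k`; residues outside the reference length are
#' reported as unmapped rather than failing.
#'
#' @param msa character matrix (sequences x columns).
#' @param reference_seq_id row name of the reference sequence.
#' @param residue_numbers integer residue numbers to map.
#' @param offset numbering offset (residue number of the first residue minus
#'   one; default 0).
#' @return data frame (`resno`, `column`) of mapped residues; unmapped
#'   residue numbers are in attribute `unmapped`.
#' @export
map_residues_to_msa <- function(msa, reference_seq_id, residue_numbers,
                                offset = 0) {
  if (!reference_seq_id %in% rownames(msa))
    stop("reference sequence not in MSA: ", reference_seq_id)
  cols <- which(msa[reference_seq_id, ] != "-")
  k <- residue_numbers - offset
  ok <- k >= 1 & k <= length(cols)
  out <- data.frame(resno = residue_numbers[ok], column = cols[k[ok]])
  attr(out, "unmapped") <- residue_numbers[!ok]
  out
}
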