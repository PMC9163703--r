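#' @importFrom stats rnorm runif setNames wilcox.test
#' @importFrom utils write.table head
NULL

# Internal atom-table convention (mirrors bio3d's pdb$atom):
#   elety  atom name (e.g. "CA", "OG", "OD1")
#   elesy  element symbol
#   resid  3-letter residue code
#   chain  chain identifier
#   resno  author residue number
#   x,y,z  coordinates, Angstrom

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

aa3to1 <- function(resid) {
  tbl <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  unname(tbl[toupper(resid)])
}

aa1to3 <- function(aa) {
  tbl <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  unname(tbl[toupper(aa)])
}

.is_hydrogen <- function(atom_df) {
  elesy <- atom_df$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(atom_df))
  h_by_elem <- !is.na(elesy) & toupper(trimws(elesy)) == "H"
  # fall back to atom-name heuristic where the element column is blank
  nm <- toupper(trimws(atom_df$elety))
  h_by_name <- grepl("^[0-9]*H", nm)
  ifelse(is.na(elesy) | trimws(elesy) == "", h_by_name, h_by_elem)
}

.atom_df_from_pdb <- function(pdb, model_xyz = NULL) {
  a <- pdb$atom
  xyz <- if (is.null(model_xyz)) cbind(a$x, a$y, a$z) else matrix(model_xyz, ncol = 3, byrow = TRUE)
  data.frame(elety = trimws(a$elety), elesy = trimws(a$elesy),
             resid = trimws(a$resid), chain = ifelse(is.na(a$chain), "A", a$chain),
             resno = a$resno, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Read an annotated protease receptor structure
#'
#' Reads a single-model PDB file and annotates the catalytic triad and the
#' S1-pocket anchor aspartate. Defaults correspond to the TMPRSS2 catalytic
#' domain: triad His296-Asp345-Ser441 and S1 aspartate Asp435 (author
#' numbering). Hydrogens are dropped; alternate locations other than the
#' first are dropped with a warning; insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param triad integer vector of length 3: author residue numbers of the
#'   catalytic histidine, aspartate and serine.
#' @param s1_anchor author residue number of the aspartate at the bottom of
#'   the S1 pocket.
#' @param numbering_scheme free-text provenance note for the numbering.
#' @return an object of class `protease_receptor`: a list with elements
#'   `atoms` (atom data frame), `triad`, `s1_anchor`, `numbering_scheme`.
#' @export
read_receptor <- function(path, triad = c(296L, 345L, 441L), s1_anchor = 435L,
                          numbering_scheme = "author") {
  stopifnot(length(triad) == 3L, length(s1_anchor) == 1L)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  if (any(!is.na(pdb$atom$insert) & trimws(pdb$atom$insert) != ""))
    stop("receptor contains insertion codes; renumber before use")
  atoms <- .atom_df_from_pdb(pdb)
  alt <- trimws(pdb$atom$alt)
  if (any(!is.na(alt) & alt != "" & alt != "A")) {
    warning("alternate locations present; keeping first altloc only")
    keep <- is.na(alt) | alt == "" | alt == "A"
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms <- atoms[!.is_hydrogen(atoms), , drop = FALSE]
  receptor <- structure(list(atoms = atoms,
                             triad = as.integer(triad),
                             s1_anchor = as.integer(s1_anchor),
                             numbering_scheme = numbering_scheme),
                        class = "protease_receptor")
  validate_receptor(receptor)
  receptor
}

#' Validate a protease receptor's anchor annotations
#'
#' Checks that the annotated triad and S1-anchor residues are present and
#' carry the atoms the selection criteria need: the catalytic serine's
#' hydroxyl oxygen OG and the S1 aspartate's carboxylate oxygens OD1/OD2.
#'
#' @param receptor a `protease_receptor`.
#' @return the receptor, invisibly; errors describe the missing residue/atom.
#' @export
validate_receptor <- function(receptor) {
  stopifnot(inherits(receptor, "protease_receptor"))
  atoms <- receptor$atoms
  for (rn in c(receptor$triad, receptor$s1_anchor)) {
    if (!any(atoms$resno == rn))
      stop("receptor is missing annotated residue ", rn)
  }
  ser <- atoms[atoms$resno == receptor$triad[3L], , drop = FALSE]
  if (!any(ser$elety == "OG"))
    stop("catalytic serine residue ", receptor$triad[3L], " lacks atom OG")
  asp <- atoms[atoms$resno == receptor$s1_anchor, , drop = FALSE]
  if (!all(c("OD1", "OD2") %in% asp$elety))
    stop("S1 anchor residue ", receptor$s1_anchor, " lacks carboxylate atoms OD1/OD2")
  invisible(receptor)
}

#' @export
print.protease_receptor <- function(x, ...) {
  cat("Protease receptor (", length(unique(x$atoms$resno)), " residues, ",
      nrow(x$atoms), " heavy atoms)\n", sep = "")
  cat("  catalytic triad: His", x$triad[1], " Asp", x$triad[2], " Ser", x$triad[3], "\n", sep = "")
  cat("  S1 anchor: Asp", x$s1_anchor, "\n", sep = "")
  cat("  numbering: ", x$numbering_scheme, "\n", sep = "")
  invisible(x)
}

.receptor_atoms <- function(receptor, resno, elety = NULL) {
  a <- receptor$atoms[receptor$atoms$resno == resno, , drop = FALSE]
  if (!is.null(elety)) a <- a[a$elety %in% elety, , drop = FALSE]
  a
}

.validate_pose_atoms <- function(atoms, where = "pose") {
  resnos <- sort(unique(atoms$resno))
  if (length(resnos) == 0L) stop(where, " contains no atoms")
  if (!all(diff(resnos) == 1L))
    stop(where, ": residue numbers are not a contiguous run")
  for (rn in resnos) {
    present <- atoms$elety[atoms$resno == rn]
    missing <- setdiff(.BACKBONE_ATOMS, present)
    if (length(missing) > 0L)
      stop(where, ": residue ", rn, " is missing backbone atom(s) ",
           paste(missing, collapse = ", "))
  }
  invisible(resnos)
}

#' Read a docked peptide pose ensemble from a multi-model PDB file
#'
#' Each MODEL in the file becomes one `peptide_pose`, numbered in file order.
#' `residue_offset` shifts the file's residue numbering into substrate
#' (author) numbering, e.g. an offset of 168 maps file residues 1-6 onto
#' substrate positions 169-174.
#'
#' @param path multi-model PDB file (single-model files give one pose).
#' @param peptide_label window name, e.g. `"GKARDF"`.
#' @param residue_offset integer added to file residue numbers.
#' @return an object of class `pose_set`: list with `peptide_label`,
#'   `receptor_ref`, and `poses` (list of `peptide_pose`, each holding
#'   `pose_id`, `peptide_label`, `atoms`, `source`, `engine_score`).
#' @export
read_pose_ensemble <- function(path, peptide_label, residue_offset = 0L,
                               receptor_ref = NA_character_) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmodel <- nrow(pdb$xyz)
  if (is.null(nmodel) || nmodel == 0L) stop("no models found in ", path)
  keep <- !.is_hydrogen(.atom_df_from_pdb(pdb))
  poses <- vector("list", nmodel)
  ref_resnos <- NULL
  for (m in seq_len(nmodel)) {
    atoms <- .atom_df_from_pdb(pdb, pdb$xyz[m, ])
    atoms <- atoms[keep, , drop = FALSE]
    atoms$resno <- atoms$resno + as.integer(residue_offset)
    resnos <- .validate_pose_atoms(atoms, where = paste0("model ", m))
    if (is.null(ref_resnos)) ref_resnos <- resnos
    else if (!identical(resnos, ref_resnos))
      stop("model ", m, " has a different residue set than model 1")
    poses[[m]] <- new_peptide_pose(pose_id = m, peptide_label = peptide_label,
                                   atoms = atoms,
                                   source = paste0(path, "#", m))
  }
  new_pose_set(peptide_label, poses, receptor_ref = receptor_ref)
}

#' Construct a peptide pose
#'
#' @param pose_id ordinal within the ensemble.
#' @param peptide_label window name.
#' @param atoms atom data frame (columns elety, elesy, resid, chain, resno, x, y, z).
#' @param source provenance string.
#' @param engine_score optional docking-engine affinity, kcal/mol.
#' @export
new_peptide_pose <- function(pose_id, peptide_label, atoms,
                             source = NA_character_, engine_score = NA_real_) {
  stopifnot(is.data.frame(atoms),
            all(c("elety", "resid", "resno", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("pose coordinates must be finite")
  structure(list(pose_id = as.integer(pose_id), peptide_label = peptide_label,
                 atoms = atoms, source = source,
                 engine_score = engine_score),
            class = "peptide_pose")
}

#' Construct a pose set
#' @param peptide_label shared window name.
#' @param poses list of `peptide_pose`.
#' @param receptor_ref identifier of the receptor frame the poses live in.
#' @export
new_pose_set <- function(peptide_label, poses, receptor_ref = NA_character_) {
  stopifnot(length(poses) > 0L)
  spans <- lapply(poses, function(p) sort(unique(p$atoms$resno)))
  if (length(unique(vapply(spans, paste, character(1), collapse = ","))) != 1L)
    stop("all poses in a set must share one residue-number span")
  labs <- unique(vapply(poses, function(p) p$peptide_label, character(1)))
  if (length(labs) != 1L || labs != peptide_label)
    stop("all poses must carry the set's peptide_label")
  structure(list(peptide_label = peptide_label, receptor_ref = receptor_ref,
                 poses = poses),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  span <- range(x$poses[[1]]$atoms$resno)
  cat("Pose set '", x$peptide_label, "': ", length(x$poses),
      " poses, residues ", span[1], "-", span[2], "\n", sep = "")
  invisible(x)
}

#' @export
length.pose_set <- function(x) length(x$poses)

#' Write a pose set as a multi-model PDB file
#'
#' @param pose_set a `pose_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pose_ensemble <- function(pose_set, path) {
  stopifnot(inherits(pose_set, "pose_set"))
  a0 <- pose_set$poses[[1]]$atoms
  xyz <- do.call(rbind, lapply(pose_set$poses, function(p) {
    stopifnot(identical(p$atoms$elety, a0$elety), identical(p$atoms$resno, a0$resno))
    as.vector(t(as.matrix(p$atoms[, c("x", "y", "z")])))
  }))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a0$resno, resid = a0$resid,
                   elety = a0$elety, chain = a0$chain)
  invisible(path)
}

#' Minimum pairwise distance between two atom groups
#'
#' The geometric primitive behind both selection criteria: the smallest
#' Euclidean distance between any atom of group A and any atom of group B.
#'
#' @param atoms_a,atoms_b atom data frames (with x/y/z columns) or n-by-3
#'   coordinate matrices.
#' @return minimum distance in Angstrom.
#' @export
min_group_distance <- function(atoms_a, atoms_b) {
  xa <- .coords(atoms_a); xb <- .coords(atoms_b)
  if (nrow(xa) == 0L || nrow(xb) == 0L)
    stop("min_group_distance requires non-empty atom groups")
  # squared cross-distance matrix via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

.coords <- function(x) {
  if (is.data.frame(x)) as.matrix(x[, c("x", "y", "z")])
  else matrix(as.numeric(x), ncol = 3)
}
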