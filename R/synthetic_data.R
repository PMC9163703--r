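# Synthetic receptors and pose ensembles with ground truth.
#
# The generator emulates the two binding-mode classes a docking campaign
# produces against a trypsin-like catalytic site: "productive" modes that
# form the P1/S1 salt bridge and present the scissile carbonyl to the
# catalytic serine (a tight cluster: small rigid-body jitter around one
# template), and "decoy" modes placed randomly in a large box with every
# basic side chain kept at least `margin` beyond the salt-bridge threshold.
# Every pose carries a ground-truth label, so downstream classification can
# be checked for exact recovery.

.rng_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.mk_res <- function(resno, resid, atoms) {
  # atoms: named list of 3-vectors
  data.frame(elety = names(atoms),
             elesy = substr(gsub("[0-9]", "", names(atoms)), 1, 1),
             resid = resid, chain = "A", resno = as.integer(resno),
             x = vapply(atoms, `[`, numeric(1), 1),
             y = vapply(atoms, `[`, numeric(1), 2),
             z = vapply(atoms, `[`, numeric(1), 3),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Construct a minimal mock protease receptor
#'
#' Four residues with TMPRSS2 author numbers: the catalytic triad His296,
#' Asp345, Ser441 and the S1-pocket aspartate Asp435. Ser441 carries its
#' hydroxyl OG, Asp435 its carboxylate OD1/OD2, and the OG-to-carboxylate
#' separation is ~7 Angstrom (catalytic-site scale). Intended as a stand-in
#' for a real receptor model in tests and simulations; it has no secondary
#' structure or pocket walls.
#'
#' @param triad triad author numbers (His, Asp, Ser).
#' @param s1_anchor S1 aspartate author number.
#' @param s1_shift 3-vector added to all S1-aspartate atoms, to relocate the
#'   carboxylate.
#' @return a `protease_receptor`.
#' @export
make_mock_receptor <- function(triad = c(296L, 345L, 441L), s1_anchor = 435L,
                               s1_shift = c(0, 0, 0)) {
  ser <- .mk_res(triad[3], "SER", list(
    N = c(-1.95, 2.35, -0.60), CA = c(0.00, 1.50, -1.00),
    C = c(1.20, 2.20, -1.40), O = c(1.30, 3.40, -1.30),
    CB = c(0.00, 0.70, 0.20), OG = c(0.00, 0.00, 0.00)))
  asp_s1 <- .mk_res(s1_anchor, "ASP", list(
    N = c(9.80, 1.60, -1.30), CA = c(8.90, 2.20, -0.90),
    C = c(9.30, 3.50, -0.40), O = c(10.40, 3.90, -0.70),
    CB = c(7.80, 1.80, -1.00), CG = c(7.30, 0.90, -0.30),
    OD1 = c(6.60, 0.00, -0.60), OD2 = c(7.60, 0.80, 0.90)))
  asp_s1[, c("x", "y", "z")] <- sweep(asp_s1[, c("x", "y", "z")], 2, s1_shift, "+")
  his <- .mk_res(triad[1], "HIS", list(
    N = c(0.80, -4.40, -2.20), CA = c(1.50, -3.50, -1.50),
    C = c(2.90, -3.90, -1.10), O = c(3.30, -5.00, -1.30),
    CB = c(1.50, -2.10, -1.90), CG = c(1.00, -1.10, -1.00),
    ND1 = c(0.20, -1.20, 0.05), NE2 = c(1.30, 0.10, -1.30)))
  asp_triad <- .mk_res(triad[2], "ASP", list(
    N = c(-3.90, -2.80, 1.40), CA = c(-3.00, -2.00, 2.00),
    C = c(-1.80, -2.70, 2.50), O = c(-1.80, -3.90, 2.70),
    CB = c(-3.50, -0.90, 2.90), CG = c(-2.80, 0.30, 3.00),
    OD1 = c(-1.70, 0.40, 2.50), OD2 = c(-3.40, 1.30, 3.50)))
  receptor <- structure(list(atoms = rbind(his, asp_triad, asp_s1, ser),
                             triad = as.integer(triad),
                             s1_anchor = as.integer(s1_anchor),
                             numbering_scheme = "TMPRSS2 author numbering (mock)"),
                        class = "protease_receptor")
  validate_receptor(receptor)
  receptor
}

#' Write a receptor to a PDB file
#' @param receptor a `protease_receptor`.
#' @param path output file.
#' @export
write_receptor <- function(receptor, path) {
  a <- receptor$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain)
  invisible(path)
}

#' Configuration for a synthetic pose ensemble
#'
#' Defaults mirror the docking campaign the analysis is built for: 90 binding
#' modes per peptide, productive modes forming the salt bridge at 3.0 A and
#' presenting the scissile carbonyl at 3.4 A (both comfortably inside the
#' 4 A thresholds), 0.3 A rigid-body jitter for the productive cluster, and
#' decoys scattered in a 40 A box kept at least 1 A beyond the salt-bridge
#' threshold.
#'
#' @param peptide_window 6-mer (or other) one-letter window string.
#' @param start_number substrate author number of the window's first residue.
#' @param n_poses ensemble size.
#' @param productive_fraction fraction of poses that satisfy both criteria.
#' @param salt_bridge_target charged-group to carboxylate distance of the
#'   productive template, Angstrom.
#' @param scissile_target carbonyl-C to Ser-OG distance of the template, Angstrom.
#' @param jitter_sd rigid-body jitter of productive modes, Angstrom.
#' @param decoy_box edge length of the decoy placement box, Angstrom.
#' @param margin minimum separation of every decoy basic side chain beyond
#'   the salt-bridge threshold, Angstrom.
#' @param occupant_position author position of the productive P1 residue;
#'   default is the window's first Arg, else its first Lys.
#' @param seed integer seed; the ensemble is a pure function of the config.
#' @return an object of class `synthetic_ensemble_config`.
#' @export
synthetic_ensemble_config <- function(peptide_window, start_number,
                                      n_poses = 90L, productive_fraction = 0.4,
                                      salt_bridge_target = 3.0,
                                      scissile_target = 3.4,
                                      jitter_sd = 0.3, decoy_box = 40,
                                      margin = 1.0, occupant_position = NULL,
                                      seed = 1L) {
  stopifnot(margin > 0, n_poses >= 1L,
            productive_fraction >= 0, productive_fraction <= 1)
  peptide_window <- toupper(peptide_window)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptide_window))
    stop("peptide_window must be one-letter amino-acid codes")
  aa <- strsplit(peptide_window, "")[[1]]
  if (is.null(occupant_position)) {
    idx <- c(which(aa == "R"), which(aa == "K"))[1]
    occupant_position <- if (is.na(idx)) NA_integer_ else start_number + idx - 1L
  }
  if (productive_fraction > 0) {
    if (is.na(occupant_position))
      stop("productive_fraction > 0 requires an Arg or Lys in the window")
    occ_aa <- aa[occupant_position - start_number + 1L]
    if (!occ_aa %in% c("R", "K"))
      stop("occupant_position ", occupant_position, " is not an Arg or Lys")
  }
  structure(list(peptide_window = peptide_window,
                 start_number = as.integer(start_number),
                 n_poses = as.integer(n_poses),
                 productive_fraction = productive_fraction,
                 n_productive = as.integer(round(productive_fraction * n_poses)),
                 salt_bridge_target = salt_bridge_target,
                 scissile_target = scissile_target,
                 jitter_sd = jitter_sd, decoy_box = decoy_box, margin = margin,
                 occupant_position = as.integer(occupant_position),
                 seed = as.integer(seed)),
            class = "synthetic_ensemble_config")
}

.unit <- function(v) v / sqrt(sum(v^2))

.pocket_frame <- function(receptor, criteria) {
  og <- as.numeric(.receptor_atoms(receptor, receptor$triad[3],
                                   criteria$ser_hydroxyl_atom)[1, c("x", "y", "z")])
  asp <- .receptor_atoms(receptor, receptor$s1_anchor, criteria$asp_charged_atoms)
  cen <- colMeans(asp[, c("x", "y", "z")])
  u <- .unit(cen - og)                      # serine -> S1 carboxylate
  zref <- c(0, 0, 1)
  if (abs(sum(zref * u)) > 0.9) zref <- c(0, 1, 0)
  w <- .unit(zref - sum(zref * u) * u)      # "up", out of the pocket
  e <- .unit(pracma_cross(u, w))            # chain axis
  list(og = og, asp = asp, u = u, w = w, e = e,
       center = (og + cen) / 2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Build the productive template pose: extended backbone along the chain axis,
# occupant side chain reaching into the S1 pocket so that the charged-group /
# carboxylate minimum distance equals salt_bridge_target and the occupant
# carbonyl C sits scissile_target from Ser OG.
.build_template <- function(config, receptor, criteria) {
  fr <- .pocket_frame(receptor, criteria)
  aa <- strsplit(config$peptide_window, "")[[1]]
  n <- length(aa)
  k <- config$occupant_position - config$start_number + 1L
  if (is.na(k)) k <- 1L  # decoy-only ensemble without basic residue: arbitrary anchor
  e <- fr$e; w <- fr$w; u <- fr$u
  c_occ <- fr$og + config$scissile_target * w
  # anchor carboxylate oxygen: the one most exposed along w
  wproj <- as.matrix(fr$asp[, c("x", "y", "z")]) %*% w
  o_anchor <- as.numeric(fr$asp[which.max(wproj), c("x", "y", "z")])
  q <- o_anchor + config$salt_bridge_target * w
  ca_occ <- c_occ - 1.30 * e + 0.25 * w
  rows <- list()
  for (i in seq_len(n)) {
    ca <- ca_occ + (i - k) * 3.5 * e
    atoms <- list(N = ca - 1.25 * e + 0.45 * w,
                  CA = ca,
                  C = ca + 1.30 * e - 0.25 * w,
                  O = ca + 1.30 * e - 0.25 * w + 1.23 * w)
    if (aa[i] != "G") atoms$CB <- ca + 1.53 * w
    if (i == k && aa[i] %in% c("R", "K")) {
      # side chain descends from CA to the charged-group anchor point q
      path <- function(t) ca + t * (q - ca)
      if (aa[i] == "R") {
        atoms$CB <- path(0.18) + 0.30 * u
        atoms$CG <- path(0.36) - 0.20 * u
        atoms$CD <- path(0.52) + 0.25 * u
        atoms$NE <- path(0.68) - 0.20 * u
        atoms$CZ <- path(0.85) + 0.15 * u
        atoms$NH1 <- q
        atoms$NH2 <- q + 1.10 * u + 0.55 * w
      } else {
        atoms$CB <- path(0.22) + 0.30 * u
        atoms$CG <- path(0.42) - 0.20 * u
        atoms$CD <- path(0.60) + 0.25 * u
        atoms$CE <- path(0.80) - 0.15 * u
        atoms$NZ <- q
      }
    } else if (aa[i] == "R") {
      atoms$CG <- atoms$CB + 1.40 * w + 0.30 * u
      atoms$CD <- atoms$CG + 1.40 * w - 0.30 * u
      atoms$NE <- atoms$CD + 1.30 * w
      atoms$CZ <- atoms$NE + 1.30 * w + 0.20 * u
      atoms$NH1 <- atoms$CZ + 1.20 * w
      atoms$NH2 <- atoms$CZ + 0.60 * w + 1.10 * u
    } else if (aa[i] == "K") {
      atoms$CG <- atoms$CB + 1.40 * w + 0.30 * u
      atoms$CD <- atoms$CG + 1.40 * w - 0.30 * u
      atoms$CE <- atoms$CD + 1.30 * w
      atoms$NZ <- atoms$CE + 1.30 * w
    }
    rows[[i]] <- .mk_res(config$start_number + i - 1L, aa1to3(aa[i]), atoms)
  }
  do.call(rbind, rows)
}

.basic_saltbridge_distances <- function(atoms, receptor, criteria) {
  asp <- .receptor_atoms(receptor, receptor$s1_anchor, criteria$asp_charged_atoms)
  out <- numeric(0)
  for (rn in unique(atoms$resno)) {
    res <- atoms[atoms$resno == rn, , drop = FALSE]
    aa <- aa3to1(res$resid[1])
    if (is.na(aa) || !aa %in% c("R", "K")) next
    charged <- res[res$elety %in% .charged_atom_names(aa, criteria), , drop = FALSE]
    if (nrow(charged) == 0L) next
    out[as.character(rn)] <- min_group_distance(charged, asp)
  }
  out
}

.template_is_productive <- function(atoms, config, receptor, criteria) {
  d <- .basic_saltbridge_distances(atoms, receptor, criteria)
  occ <- as.character(config$occupant_position)
  if (!occ %in% names(d)) return(FALSE)
  if (!.passes(d[[occ]], criteria$salt_bridge_max, criteria$strict_inequality))
    return(FALSE)
  # every other basic residue stays outside the pocket, so the occupant is unique
  if (any(d[setdiff(names(d), occ)] < criteria$salt_bridge_max)) return(FALSE)
  og <- .receptor_atoms(receptor, receptor$triad[3], criteria$ser_hydroxyl_atom)
  cc <- atoms[atoms$resno == config$occupant_position & atoms$elety == "C", , drop = FALSE]
  .passes(min_group_distance(cc, og), criteria$scissile_max, criteria$strict_inequality)
}

.rand_rotation <- function() {
  # uniform random rotation via a normalised quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         nrow = 3, byrow = TRUE)
}

.small_rotation <- function(sd_angle) {
  axis <- .unit(stats::rnorm(3))
  theta <- stats::rnorm(1, 0, sd_angle)
  kx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

.transform_atoms <- function(atoms, rot, shift, center) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, center) %*% t(rot), 2, center + shift, "+")
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Generate a synthetic pose ensemble with ground-truth labels
#'
#' Productive poses are small rigid-body perturbations of a template whose
#' occupant satisfies both selection criteria at the configured target
#' distances (jitter is resampled until the perturbed pose still satisfies
#' them, so labels are guaranteed by construction); decoys are uniformly
#' random rigid placements within the decoy box, resampled until every basic
#' side chain lies at least `margin` beyond the salt-bridge threshold.
#' Productive/decoy positions within the ensemble are randomly interleaved.
#' The result is a pure function of the config (including its seed).
#'
#' @param config a `synthetic_ensemble_config`.
#' @param receptor a `protease_receptor` (typically [make_mock_receptor()]).
#' @param criteria the `selection_criteria` the labels are guaranteed against.
#' @param max_attempts rejection-sampling cap per pose.
#' @return list with elements `poses` (a `pose_set`), `labels` (logical,
#'   `TRUE` = productive), and `config`.
#' @export
make_ensemble <- function(config, receptor = make_mock_receptor(),
                          criteria = selection_criteria(), max_attempts = 10000L) {
  stopifnot(inherits(config, "synthetic_ensemble_config"))
  if (config$salt_bridge_target >= criteria$salt_bridge_max ||
      config$scissile_target >= criteria$scissile_max)
    stop("infeasible geometry: target distances must lie below the selection thresholds")
  template <- .build_template(config, receptor, criteria)
  if (config$n_productive > 0L &&
      !.template_is_productive(template, config, receptor, criteria))
    stop("internal error: productive template violates the selection criteria")
  fr <- .pocket_frame(receptor, criteria)
  sd_angle <- config$jitter_sd / 10  # radians; ~jitter_sd displacement at a 10 A lever arm
  t_center <- colMeans(as.matrix(template[, c("x", "y", "z")]))
  .rng_local(config$seed, {
    labels <- rep(FALSE, config$n_poses)
    if (config$n_productive > 0L)
      labels[sample.int(config$n_poses, config$n_productive)] <- TRUE
    poses <- vector("list", config$n_poses)
    for (i in seq_len(config$n_poses)) {
      if (labels[i]) {
        for (att in seq_len(max_attempts)) {
          cand <- .transform_atoms(template, .small_rotation(sd_angle),
                                   stats::rnorm(3, 0, config$jitter_sd), t_center)
          if (.template_is_productive(cand, config, receptor, criteria)) break
          cand <- NULL
        }
        if (is.null(cand)) stop("could not jitter a productive pose within ",
                                max_attempts, " attempts")
      } else {
        for (att in seq_len(max_attempts)) {
          shift <- fr$center + stats::runif(3, -config$decoy_box / 2, config$decoy_box / 2) - t_center
          cand <- .transform_atoms(template, .rand_rotation(), shift, t_center)
          d <- .basic_saltbridge_distances(cand, receptor, criteria)
          if (length(d) == 0L || all(d >= criteria$salt_bridge_max + config$margin)) break
          cand <- NULL
        }
        if (is.null(cand)) stop("could not place a decoy pose within ",
                                max_attempts, " attempts; shrink margin or grow decoy_box")
      }
      poses[[i]] <- new_peptide_pose(pose_id = i, peptide_label = config$peptide_window,
                                     atoms = cand, source = "synthetic")
    }
    list(poses = new_pose_set(config$peptide_window, poses, receptor_ref = "mock"),
         labels = labels, config = config)
  })
}

#' Write a synthetic ensemble to disk
#'
#' Writes the mock receptor PDB, the multi-model pose PDB and a ground-truth
#' labels TSV.
#'
#' @param ensemble result of [make_ensemble()].
#' @param receptor the receptor the ensemble was generated against.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; defaults to the peptide window.
#' @return named character vector of the files written.
#' @export
write_ensemble_files <- function(ensemble, receptor, dir, prefix = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- ensemble$config$peptide_window
  f_rec <- file.path(dir, paste0(prefix, "_receptor.pdb"))
  f_pose <- file.path(dir, paste0(prefix, "_poses.pdb"))
  f_lab <- file.path(dir, paste0(prefix, "_labels.tsv"))
  write_receptor(receptor, f_rec)
  write_pose_ensemble(ensemble$poses, f_pose)
  utils::write.table(data.frame(pose_id = seq_along(ensemble$labels),
                                productive = ensemble$labels),
                     f_lab, sep = "\t", quote = FALSE, row.names = FALSE)
  c(receptor = f_rec, poses = f_pose, labels = f_lab)
}

#' Build the partially synthetic gamma-ENaC substrate fixture
#'
#' Assembles the region spanning residues 134-192 of the human gamma-ENaC
#' subunit from its published segments: 135-RKRR-138 (furin-region polybasic
#' tract), 153-RFSHRIPLLIF-163 (the key inhibitory 11-mer), K168,
#' 169-GKARDF-174, 175-FTGR-178, 177-GRKRKV-182 (prostasin-region tract) and
#' 187-IHKASN-192. Positions not covered by these segments are SYNTHETIC
#' alanine fill: alanine adds no Arg/Lys, so candidate-site enumeration over
#' this fixture is faithful, but the sequence is not the full native one and
#' its masses are placeholders outside the printed segments.
#'
#' @return a `substrate_sequence` spanning 134-192.
#' @export
mock_substrate <- function() {
  res <- rep("A", 192 - 134 + 1)
  put <- function(res, start, s) {
    idx <- start - 134 + seq_len(nchar(s))
    res[idx] <- strsplit(s, "")[[1]]
    res
  }
  res <- put(res, 135, "RKRR")
  res <- put(res, 153, "RFSHRIPLLIF")
  res <- put(res, 168, "K")
  res <- put(res, 169, "GKARDF")
  res <- put(res, 175, "FTGR")
  res <- put(res, 177, "GRKRKV")
  res <- put(res, 187, "IHKASN")
  substrate_sequence("gamma-ENaC-134-192-synthetic-fill",
                     paste(res, collapse = ""), 134L)
}
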