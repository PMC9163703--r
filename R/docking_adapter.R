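# Bridge to an external docking engine (AutoDock-Vina-style). The engine is
# never a build or test dependency: campaign planning and output ingest work
# on files alone, and invocation only activates when an engine executable is
# configured.

#' Plan a docking campaign around the catalytic site
#'
#' Defaults reproduce the reference campaign geometry: a 40 x 25 x 25 A grid
#' box centred on the catalytic triad (the centroid of the triad residues'
#' CA atoms), 10 independent runs with 9 binding modes each, i.e. 90 poses
#' per peptide.
#'
#' @param receptor a `protease_receptor`.
#' @param grid_center optional 3-vector override, Angstrom.
#' @param grid_dims grid box dimensions, Angstrom.
#' @param runs number of independent engine runs.
#' @param modes_per_run binding modes requested per run.
#' @param seed_list optional per-run engine seeds.
#' @param engine_path optional docking-engine executable.
#' @return an object of class `docking_campaign`.
#' @export
plan_campaign <- function(receptor, grid_center = NULL,
                          grid_dims = c(40, 25, 25), runs = 10L,
                          modes_per_run = 9L, seed_list = NULL,
                          engine_path = NULL) {
  stopifnot(inherits(receptor, "protease_receptor"), all(grid_dims > 0))
  if (is.null(grid_center)) {
    ca <- receptor$atoms[receptor$atoms$resno %in% receptor$triad &
                           receptor$atoms$elety == "CA", , drop = FALSE]
    if (nrow(ca) != 3L)
      stop("cannot centre grid: triad CA atoms not all present")
    grid_center <- colMeans(as.matrix(ca[, c("x", "y", "z")]))
  }
  if (!is.null(seed_list)) stopifnot(length(seed_list) == runs)
  structure(list(grid_center = as.numeric(grid_center),
                 grid_dims = as.numeric(grid_dims),
                 runs = as.integer(runs),
                 modes_per_run = as.integer(modes_per_run),
                 expected_poses = as.integer(runs) * as.integer(modes_per_run),
                 seed_list = seed_list, engine_path = engine_path),
            class = "docking_campaign")
}

#' @export
print.docking_campaign <- function(x, ...) {
  cat(sprintf("Docking campaign: %d runs x %d modes = %d poses\n",
              x$runs, x$modes_per_run, x$expected_poses))
  cat(sprintf("  grid %.0f x %.0f x %.0f A centred at (%.2f, %.2f, %.2f)\n",
              x$grid_dims[1], x$grid_dims[2], x$grid_dims[3],
              x$grid_center[1], x$grid_center[2], x$grid_center[3]))
  invisible(x)
}

#' Write an engine configuration file for one run
#'
#' Vina-style key-value text: receptor/ligand paths, grid centre and size,
#' requested mode count and optional seed. Engine search settings beyond
#' these are left at engine defaults.
#'
#' @param campaign a `docking_campaign`.
#' @param path output config file.
#' @param receptor_file,ligand_file file paths written into the config.
#' @param run 1-based run index (selects the per-run seed, if any).
#' @export
write_campaign_config <- function(campaign, path, receptor_file, ligand_file,
                                  run = 1L) {
  lines <- c(paste0("receptor = ", receptor_file),
             paste0("ligand = ", ligand_file),
             sprintf("center_x = %.3f", campaign$grid_center[1]),
             sprintf("center_y = %.3f", campaign$grid_center[2]),
             sprintf("center_z = %.3f", campaign$grid_center[3]),
             sprintf("size_x = %.1f", campaign$grid_dims[1]),
             sprintf("size_y = %.1f", campaign$grid_dims[2]),
             sprintf("size_z = %.1f", campaign$grid_dims[3]),
             paste0("num_modes = ", campaign$modes_per_run))
  if (!is.null(campaign$seed_list))
    lines <- c(lines, paste0("seed = ", campaign$seed_list[run]))
  writeLines(lines, path)
  invisible(path)
}

# PDBQT differs from PDB only in trailing charge/type columns (67+) and in
# engine bookkeeping records; truncating ATOM/HETATM lines to the PDB columns
# and keeping MODEL/ENDMDL yields a readable multi-model PDB.
.pdbqt_to_pdb_lines <- function(lines) {
  keep <- grepl("^(ATOM|HETATM|MODEL|ENDMDL|END)", lines)
  lines <- lines[keep]
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  lines[is_atom] <- substr(lines[is_atom], 1, 66)
  lines
}

.read_engine_file <- function(path, peptide_label, residue_offset) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("cannot read engine output ", path))
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("no atom records in engine output ", path)
  scores <- as.numeric(sub("^REMARK VINA RESULT:\\s+(\\S+).*$", "\\1",
                           grep("^REMARK VINA RESULT:", lines, value = TRUE)))
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(.pdbqt_to_pdb_lines(lines), tf)
  ps <- read_pose_ensemble(tf, peptide_label, residue_offset)
  if (length(scores) == length(ps$poses)) {
    for (i in seq_along(ps$poses)) ps$poses[[i]]$engine_score <- scores[i]
  }
  ps
}

#' Ingest per-run docking-engine output into one pose set
#'
#' Accepts multi-model PDB or PDBQT pose files, one per run, in run order.
#' Pose ids are assigned lexicographically by (run index, mode index)
#' regardless of filesystem ordering of the supplied paths, which are used
#' as given. A pose count differing from the campaign's expectation is a
#' warning, not an error.
#'
#' @param paths character vector of per-run pose files, in run order.
#' @param campaign a `docking_campaign`.
#' @param peptide_label window name.
#' @param residue_offset shift from file numbering to substrate numbering.
#' @return a `pose_set` concatenating all runs.
#' @export
ingest_engine_output <- function(paths, campaign, peptide_label,
                                 residue_offset = 0L) {
  if (length(paths) == 0L) stop("no engine output files supplied")
  per_run <- lapply(paths, .read_engine_file, peptide_label = peptide_label,
                    residue_offset = residue_offset)
  poses <- list()
  for (r in seq_along(per_run)) {
    for (p in per_run[[r]]$poses) {
      p$pose_id <- length(poses) + 1L
      p$source <- paste0("run", r, ":", p$source)
      poses[[length(poses) + 1L]] <- p
    }
  }
  if (length(poses) != campaign$expected_poses)
    warning("expected ", campaign$expected_poses, " poses but ingested ",
            length(poses))
  new_pose_set(peptide_label, poses)
}

#' Run a docking campaign through an external engine
#'
#' Only active when the campaign carries an `engine_path`; each run invokes
#' the engine with a generated config and the outputs are ingested with
#' [ingest_engine_output()]. The full invocation lines are recorded in the
#' returned attribute `"invocations"` for provenance.
#'
#' @param campaign a `docking_campaign` with `engine_path` set.
#' @param receptor_file prepared receptor file for the engine.
#' @param ligand_file prepared peptide ligand file.
#' @param workdir directory for configs and outputs.
#' @param peptide_label,residue_offset passed to [ingest_engine_output()].
#' @return a `pose_set`.
#' @export
run_campaign <- function(campaign, receptor_file, ligand_file, workdir,
                         peptide_label, residue_offset = 0L) {
  if (is.null(campaign$engine_path))
    stop("no docking engine configured (campaign$engine_path is NULL)")
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  outs <- character(campaign$runs)
  invocations <- character(campaign$runs)
  for (r in seq_len(campaign$runs)) {
    cfg <- file.path(workdir, sprintf("run%02d.conf", r))
    out <- file.path(workdir, sprintf("run%02d_out.pdbqt", r))
    write_campaign_config(campaign, cfg, receptor_file, ligand_file, run = r)
    cmd <- paste(shQuote(campaign$engine_path), "--config", shQuote(cfg),
                 "--out", shQuote(out))
    invocations[r] <- cmd
    status <- system(cmd)
    if (status != 0L) stop("docking engine failed on run ", r)
    outs[r] <- out
  }
  ps <- ingest_engine_output(outs, campaign, peptide_label, residue_offset)
  attr(ps, "invocations") <- invocations
  ps
}
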