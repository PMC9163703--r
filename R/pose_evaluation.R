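# Geometric selection criteria for docked peptide binding modes.
#
# A binding mode is "productive" (selected) when
#   (i)  a basic P1 side chain occupies the S1 pocket: the minimum distance
#        between its charged-group nitrogens (Arg NH1/NH2/NE; Lys NZ) and the
#        S1 aspartate's carboxylate oxygens OD1/OD2 is below the salt-bridge
#        threshold, and
#   (ii) that residue's backbone carbonyl carbon (the scissile carbon) lies
#        within the scissile threshold of the catalytic serine's OG.
# Both thresholds default to 4 A, strict inequality.

#' Selection criteria for productive binding modes
#'
#' @param salt_bridge_max maximum P1-charged-group to Asp-carboxylate
#'   distance, Angstrom.
#' @param scissile_max maximum scissile-carbonyl-C to Ser-OG distance, Angstrom.
#' @param arg_charged_atoms,lys_charged_atoms side-chain atoms regarded as the
#'   charged group of Arg / Lys.
#' @param asp_charged_atoms carboxylate oxygens of the S1 aspartate.
#' @param ser_hydroxyl_atom hydroxyl oxygen of the catalytic serine.
#' @param strict_inequality if `TRUE` (default) a distance exactly at the
#'   threshold fails; set `FALSE` for a non-strict bound in sensitivity
#'   analyses.
#' @return an object of class `selection_criteria`.
#' @export
selection_criteria <- function(salt_bridge_max = 4.0, scissile_max = 4.0,
                               arg_charged_atoms = c("NH1", "NH2", "NE"),
                               lys_charged_atoms = "NZ",
                               asp_charged_atoms = c("OD1", "OD2"),
                               ser_hydroxyl_atom = "OG",
                               strict_inequality = TRUE) {
  stopifnot(salt_bridge_max > 0, scissile_max > 0)
  structure(list(salt_bridge_max = salt_bridge_max, scissile_max = scissile_max,
                 arg_charged_atoms = arg_charged_atoms,
                 lys_charged_atoms = lys_charged_atoms,
                 asp_charged_atoms = asp_charged_atoms,
                 ser_hydroxyl_atom = ser_hydroxyl_atom,
                 strict_inequality = isTRUE(strict_inequality)),
            class = "selection_criteria")
}

.passes <- function(d, threshold, strict) {
  if (strict) d < threshold else d <= threshold
}

.charged_atom_names <- function(aa, criteria) {
  switch(aa, R = criteria$arg_charged_atoms, K = criteria$lys_charged_atoms,
         stop("no charged-group definition for residue type ", aa))
}

#' Evaluate one docked pose against the selection criteria
#'
#' For every Arg/Lys residue in the peptide the salt-bridge distance
#' (criterion i) and scissile distance (criterion ii) are computed. The S1
#' occupant is the basic residue passing criterion (i); when several pass,
#' the smallest salt-bridge distance wins, with ties broken by the rules' P1
#' preference (Arg before Lys), then lower residue number. The pose is
#' selected when an occupant exists and its scissile distance passes
#' criterion (ii); criterion (ii) is only consulted for the occupant, since
#' the scissile bond is defined by the residue sitting in S1.
#'
#' @param pose a `peptide_pose`.
#' @param receptor a `protease_receptor`.
#' @param criteria a `selection_criteria`.
#' @param rules a `specificity_rules` (supplies the P1 tie-break order).
#' @return an object of class `pose_evaluation`: list with `pose_id`,
#'   `s1_occupant` (author position or `NA`), `salt_bridge_distance`,
#'   `scissile_distance`, `selected`, `reason`, and `per_residue_detail`
#'   (data frame of both distances for every basic residue).
#' @export
evaluate_pose <- function(pose, receptor, criteria = selection_criteria(),
                          rules = specificity_rules()) {
  stopifnot(inherits(pose, "peptide_pose"), inherits(receptor, "protease_receptor"))
  validate_receptor(receptor)
  asp <- .receptor_atoms(receptor, receptor$s1_anchor, criteria$asp_charged_atoms)
  ser_og <- .receptor_atoms(receptor, receptor$triad[3L], criteria$ser_hydroxyl_atom)
  atoms <- pose$atoms
  resnos <- sort(unique(atoms$resno))
  detail <- list()
  for (rn in resnos) {
    res <- atoms[atoms$resno == rn, , drop = FALSE]
    aa <- aa3to1(res$resid[1])
    if (is.na(aa) || !aa %in% c("R", "K")) next
    charged <- res[res$elety %in% .charged_atom_names(aa, criteria), , drop = FALSE]
    if (nrow(charged) == 0L) {
      warning("residue ", rn, " (", aa, ") lacks charged side-chain atoms; skipped")
      next
    }
    sb <- min_group_distance(charged, asp)
    cc <- res[res$elety == "C", , drop = FALSE]
    if (nrow(cc) == 0L)
      stop("residue ", rn, " is missing backbone carbonyl carbon C")
    sc <- min_group_distance(cc, ser_og)
    detail[[length(detail) + 1L]] <- data.frame(
      position = rn, residue = aa, salt_bridge_distance = sb,
      scissile_distance = sc,
      s1_compatible = .passes(sb, criteria$salt_bridge_max, criteria$strict_inequality),
      stringsAsFactors = FALSE)
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(position = integer(), residue = character(),
               salt_bridge_distance = numeric(), scissile_distance = numeric(),
               s1_compatible = logical(), stringsAsFactors = FALSE)
  ev <- list(pose_id = pose$pose_id, s1_occupant = NA_integer_,
             salt_bridge_distance = NA_real_, scissile_distance = NA_real_,
             selected = FALSE, reason = "", per_residue_detail = detail)
  if (nrow(detail) == 0L) {
    ev$reason <- "no basic residue"
    return(structure(ev, class = "pose_evaluation"))
  }
  cand <- detail[detail$s1_compatible, , drop = FALSE]
  if (nrow(cand) == 0L) {
    ev$reason <- "no residue occupies S1"
    return(structure(ev, class = "pose_evaluation"))
  }
  pref <- match(cand$residue, rules$p1_preference_order)
  pref[is.na(pref)] <- length(rules$p1_preference_order) + 1L
  ord <- order(cand$salt_bridge_distance, pref, cand$position)
  occ <- cand[ord[1L], ]
  ev$s1_occupant <- occ$position
  ev$salt_bridge_distance <- occ$salt_bridge_distance
  ev$scissile_distance <- occ$scissile_distance
  if (.passes(occ$scissile_distance, criteria$scissile_max, criteria$strict_inequality)) {
    ev$selected <- TRUE
  } else {
    ev$reason <- "scissile carbonyl too far from catalytic serine"
  }
  structure(ev, class = "pose_evaluation")
}

#' @export
print.pose_evaluation <- function(x, ...) {
  cat("Pose ", x$pose_id, ": ", if (x$selected) "SELECTED" else "discarded", sep = "")
  if (!is.na(x$s1_occupant))
    cat(sprintf(" | S1 occupant %d (salt bridge %.2f A, scissile %.2f A)",
                x$s1_occupant, x$salt_bridge_distance, x$scissile_distance))
  if (nzchar(x$reason)) cat(" | ", x$reason, sep = "")
  cat("\n")
  invisible(x)
}

#' Evaluate every pose in a set
#'
#' @param pose_set a `pose_set`.
#' @param receptor a `protease_receptor`.
#' @param criteria a `selection_criteria`.
#' @param rules a `specificity_rules`.
#' @return list of `pose_evaluation`, in pose order.
#' @export
evaluate_pose_set <- function(pose_set, receptor, criteria = selection_criteria(),
                              rules = specificity_rules()) {
  stopifnot(inherits(pose_set, "pose_set"), length(pose_set$poses) > 0L)
  lapply(pose_set$poses, function(p) {
    tryCatch(evaluate_pose(p, receptor, criteria, rules),
             error = function(e) stop("pose ", p$pose_id, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
}

#' Tabulate a list of pose evaluations
#'
#' @param evaluations list of `pose_evaluation`.
#' @return data frame with one row per pose.
#' @export
evaluations_table <- function(evaluations) {
  do.call(rbind, lapply(evaluations, function(e) {
    data.frame(pose_id = e$pose_id,
               s1_occupant = e$s1_occupant,
               salt_bridge_distance = e$salt_bridge_distance,
               scissile_distance = e$scissile_distance,
               selected = e$selected, reason = e$reason,
               stringsAsFactors = FALSE)
  }))
}
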