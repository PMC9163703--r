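# Ensemble structure: pairwise RMSD contrasts, pass fractions, S1-occupancy
# breakdowns and site ranking.

#' Pairwise RMSD between two poses in the shared receptor frame
#'
#' Computed over matched atoms WITHOUT superposition: the poses already share
#' the receptor coordinate frame, and superposing them would erase exactly
#' the binding-site placement differences being compared. Atoms are matched
#' by (residue number, atom name).
#'
#' @param pose_a,pose_b `peptide_pose` objects with the same label and span.
#' @param atom_scope `"backbone"` (N, CA, C, O; default) or `"heavy"`
#'   (all heavy atoms).
#' @return RMSD in Angstrom.
#' @export
pairwise_rmsd <- function(pose_a, pose_b, atom_scope = c("backbone", "heavy")) {
  atom_scope <- match.arg(atom_scope)
  if (!identical(pose_a$peptide_label, pose_b$peptide_label))
    stop("poses belong to different peptides: ", pose_a$peptide_label,
         " vs ", pose_b$peptide_label)
  a <- pose_a$atoms
  b <- pose_b$atoms
  if (atom_scope == "backbone") {
    a <- a[a$elety %in% .BACKBONE_ATOMS, , drop = FALSE]
    b <- b[b$elety %in% .BACKBONE_ATOMS, , drop = FALSE]
  }
  key_a <- paste(a$resno, a$elety)
  key_b <- paste(b$resno, b$elety)
  miss <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
  if (length(miss) > 0L)
    stop("atom sets do not match; unmatched atoms: ", paste(miss, collapse = ", "))
  idx <- match(key_a, key_b)
  d <- .coords(a) - .coords(b)[idx, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

.all_pairs_rmsd <- function(poses, atom_scope) {
  n <- length(poses)
  if (n < 2L) return(numeric(0))
  out <- numeric(n * (n - 1L) / 2L)
  k <- 1L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    out[k] <- pairwise_rmsd(poses[[i]], poses[[j]], atom_scope)
    k <- k + 1L
  }
  out
}

.permutation_test <- function(rmsd_by_pose_pair, labels, n_perm = 1000L) {
  # label-permutation test on the difference of within-group mean pairwise RMSD
  n <- length(labels)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  stat <- function(lab) {
    within_sel <- lab[pair_idx[, 1]] & lab[pair_idx[, 2]]
    within_dis <- !lab[pair_idx[, 1]] & !lab[pair_idx[, 2]]
    if (sum(within_sel) == 0L || sum(within_dis) == 0L) return(NA_real_)
    mean(rmsd_by_pose_pair[within_sel]) - mean(rmsd_by_pose_pair[within_dis])
  }
  obs <- stat(labels)
  if (is.na(obs)) return(list(statistic = NA_real_, p_value = NA_real_))
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(labels)), numeric(1))
  perm <- perm[!is.na(perm)]
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + length(perm))
  list(statistic = obs, p_value = p)
}

#' Summarise an evaluated pose ensemble
#'
#' Computes the pass fraction (percent of binding modes satisfying both
#' selection criteria), the S1-occupancy count per P1 position among selected
#' modes, all-vs-all pairwise RMSD within the selected and within the
#' discarded group, and a two-group comparison of those RMSD lists. The
#' default comparison is a two-sided Mann-Whitney (Wilcoxon rank-sum) test; a
#' label-permutation alternative (1000 permutations on the difference of
#' within-group mean RMSD) is offered because pairwise distances sharing a
#' pose are not independent. Groups with fewer than 2 members yield empty
#' RMSD lists and a null comparison.
#'
#' @param evaluations list of `pose_evaluation`, aligned with `poses`.
#' @param poses the evaluated `pose_set`.
#' @param test `"mann_whitney"` (default) or `"permutation"`.
#' @param atom_scope RMSD atom scope, see [pairwise_rmsd()].
#' @param n_perm permutation count for `test = "permutation"`.
#' @return an object of class `ensemble_summary`.
#' @export
summarize_ensemble <- function(evaluations, poses,
                               test = c("mann_whitney", "permutation"),
                               atom_scope = "backbone", n_perm = 1000L) {
  test <- match.arg(test)
  stopifnot(inherits(poses, "pose_set"))
  if (length(evaluations) != length(poses$poses))
    stop("evaluations (", length(evaluations), ") and poses (",
         length(poses$poses), ") differ in length")
  selected <- vapply(evaluations, function(e) isTRUE(e$selected), logical(1))
  n_total <- length(selected)
  n_selected <- sum(selected)
  occ <- table(vapply(evaluations[selected], function(e) e$s1_occupant, integer(1)))
  occupancy <- stats::setNames(as.integer(occ), names(occ))
  rmsd_sel <- .all_pairs_rmsd(poses$poses[selected], atom_scope)
  rmsd_dis <- .all_pairs_rmsd(poses$poses[!selected], atom_scope)
  comparison <- NULL
  if (length(rmsd_sel) >= 1L && length(rmsd_dis) >= 1L) {
    if (test == "mann_whitney") {
      wt <- stats::wilcox.test(rmsd_sel, rmsd_dis, alternative = "two.sided",
                               exact = FALSE)
      comparison <- list(method = "Mann-Whitney (Wilcoxon rank-sum), two-sided",
                         statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      all_rmsd <- .pose_pair_rmsd_vector(poses$poses, atom_scope)
      pt <- .permutation_test(all_rmsd, selected, n_perm)
      comparison <- list(method = sprintf("label permutation (%d permutations), two-sided", n_perm),
                         statistic = pt$statistic, p_value = pt$p_value)
    }
  }
  structure(list(peptide_label = poses$peptide_label,
                 n_total = n_total, n_selected = n_selected,
                 pass_fraction_percent = 100 * n_selected / n_total,
                 occupancy_counts = occupancy,
                 rmsd_selected = rmsd_sel, rmsd_discarded = rmsd_dis,
                 group_comparison = comparison),
            class = "ensemble_summary")
}

.pose_pair_rmsd_vector <- function(poses, atom_scope) {
  # all-vs-all pairwise RMSD in upper.tri(arr.ind) order, for the permutation test
  n <- length(poses)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vapply(seq_len(nrow(pair_idx)), function(k)
    pairwise_rmsd(poses[[pair_idx[k, 1]]], poses[[pair_idx[k, 2]]], atom_scope),
    numeric(1))
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble '", x$peptide_label, "': ", x$n_selected, "/", x$n_total,
      " binding modes selected (", sprintf("%.1f", x$pass_fraction_percent),
      "%)\n", sep = "")
  if (length(x$occupancy_counts)) {
    cat("  S1 occupancy:",
        paste(sprintf("%s: %d", names(x$occupancy_counts), x$occupancy_counts),
              collapse = ", "), "\n")
  }
  if (length(x$rmsd_selected))
    cat(sprintf("  mean pairwise RMSD selected: %.2f A (n=%d pairs)\n",
                mean(x$rmsd_selected), length(x$rmsd_selected)))
  if (length(x$rmsd_discarded))
    cat(sprintf("  mean pairwise RMSD discarded: %.2f A (n=%d pairs)\n",
                mean(x$rmsd_discarded), length(x$rmsd_discarded)))
  if (!is.null(x$group_comparison))
    cat(sprintf("  group comparison: %s, p = %.3g\n",
                x$group_comparison$method, x$group_comparison$p_value))
  invisible(x)
}

#' Bar chart of pass fraction and S1 occupancy for one or more ensembles
#'
#' Mirrors the usual reporting of docking screens: one bar per peptide with
#' the percentage of binding modes fulfilling the selection criteria,
#' annotated with the dominant S1 occupant.
#'
#' @param x an `ensemble_summary` or list of them.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ensemble_summary <- function(x, ...) {
  summaries <- if (inherits(x, "ensemble_summary")) list(x) else x
  pf <- vapply(summaries, function(s) s$pass_fraction_percent, numeric(1))
  labs <- vapply(summaries, function(s) s$peptide_label, character(1))
  occ <- vapply(summaries, function(s) {
    if (length(s$occupancy_counts) == 0L) return("")
    names(s$occupancy_counts)[which.max(s$occupancy_counts)]
  }, character(1))
  bp <- graphics::barplot(pf, names.arg = labs, ylab = "binding modes selected (%)",
                          ylim = c(0, max(100, pf) * 1.05), ...)
  lab <- ifelse(nzchar(occ), paste0("S1: ", occ), "")
  graphics::text(bp, pf, labels = lab, pos = 3, cex = 0.8, xpd = NA)
  invisible(bp)
}

#' Rank candidate cleavage sites by S1-pocket occupancy
#'
#' P1 positions are ranked by their selected-mode occupancy count summed over
#' ensembles (descending); ties are broken by the rules' P1 preference order
#' (Arg before Lys), then lower position. Exclusion flags from a candidate
#' table can be carried through for annotation; excluded sites stay in the
#' ranking but are flagged.
#'
#' @param summaries list of `ensemble_summary`.
#' @param rules a `specificity_rules`.
#' @param candidates optional `cleavage_candidates` table supplying residue
#'   identity and exclusion flags.
#' @return data frame: rank, p1_position, p1_residue, occupancy, n_total,
#'   peptide_label, excluded, exclusion_reason.
#' @export
site_ranking <- function(summaries, rules = specificity_rules(), candidates = NULL) {
  stopifnot(length(summaries) >= 1L)
  rows <- list()
  for (s in summaries) {
    for (pos in names(s$occupancy_counts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        p1_position = as.integer(pos),
        occupancy = s$occupancy_counts[[pos]],
        n_total = s$n_total, peptide_label = s$peptide_label,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(rank = integer(), p1_position = integer(),
                      p1_residue = character(), occupancy = integer(),
                      n_total = integer(), peptide_label = character(),
                      excluded = logical(), exclusion_reason = character(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(tab, tab$p1_position), function(g)
    data.frame(p1_position = g$p1_position[1], occupancy = sum(g$occupancy),
               n_total = sum(g$n_total),
               peptide_label = paste(unique(g$peptide_label), collapse = ","),
               stringsAsFactors = FALSE)))
  if (!is.null(candidates)) {
    m <- match(agg$p1_position, candidates$p1_position)
    agg$p1_residue <- candidates$p1_residue[m]
    agg$excluded <- ifelse(is.na(m), FALSE, candidates$excluded[m])
    agg$exclusion_reason <- ifelse(is.na(m), "", candidates$exclusion_reason[m])
  } else {
    agg$p1_residue <- NA_character_
    agg$excluded <- FALSE
    agg$exclusion_reason <- ""
  }
  pref <- match(agg$p1_residue, rules$p1_preference_order)
  pref[is.na(pref)] <- length(rules$p1_preference_order) + 1L
  ord <- order(-agg$occupancy, pref, agg$p1_position)
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg[, c("rank", "p1_position", "p1_residue", "occupancy", "n_total",
          "peptide_label", "excluded", "exclusion_reason")]
}

#' Serialise an ensemble summary to JSON
#' @param summary an `ensemble_summary`.
#' @param path output file.
#' @export
write_summary_json <- function(summary, path) {
  x <- unclass(summary)
  x$occupancy_counts <- as.list(x$occupancy_counts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
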