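rec <- make_mock_receptor()

test_that("pairwise RMSD matches hand cases and the brute-force oracle", {
  pose <- make_bare_pose("GKARDF", 169L)
  expect_equal(pairwise_rmsd(pose, pose), 0)
  shifted <- rigid_transform_pose(pose, diag(3), c(3, 0, 0))
  expect_equal(pairwise_rmsd(pose, shifted), 3, tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:100) {
    a <- make_bare_pose("GKA", 1L)
    b <- a
    noise <- matrix(rnorm(nrow(b$atoms) * 3, 0, 2), ncol = 3)
    b$atoms[, c("x", "y", "z")] <- b$atoms[, c("x", "y", "z")] + noise
    expect_equal(pairwise_rmsd(a, b),
                 brute_rmsd(as.matrix(a$atoms[, c("x", "y", "z")]),
                            as.matrix(b$atoms[, c("x", "y", "z")])),
                 tolerance = 1e-9)
    expect_equal(pairwise_rmsd(a, b), pairwise_rmsd(b, a), tolerance = 1e-12)
  }
})

test_that("RMSD scope and mismatches are handled", {
  ens <- make_ensemble(synthetic_ensemble_config("GKARDF", 169L, n_poses = 2L,
                                                 productive_fraction = 1,
                                                 seed = 2L), rec)
  p1 <- ens$poses$poses[[1]]; p2 <- ens$poses$poses[[2]]
  # heavy-atom scope includes side chains, so it may differ from backbone scope
  expect_true(is.finite(pairwise_rmsd(p1, p2, atom_scope = "heavy")))
  broken <- p2
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 172L & broken$atoms$elety == "NH1"), ]
  expect_error(pairwise_rmsd(p1, broken, atom_scope = "heavy"), "NH1")
  other <- p2; other$peptide_label <- "IHKASN"
  expect_error(pairwise_rmsd(p1, other), "different peptides")
})

test_that("ensemble summary reports pass fraction, occupancy and a significant RMSD contrast", {
  ens <- make_ensemble(synthetic_ensemble_config("GKARDF", 169L, n_poses = 90L,
                                                 productive_fraction = 0.4,
                                                 jitter_sd = 0.3, decoy_box = 40,
                                                 seed = 17L), rec)
  evs <- evaluate_pose_set(ens$poses, rec)
  s <- summarize_ensemble(evs, ens$poses)
  expect_equal(s$pass_fraction_percent, 40.0)
  expect_identical(s$n_selected, 36L)
  expect_identical(sum(s$occupancy_counts), 36L)
  expect_identical(names(s$occupancy_counts), "172")
  expect_length(s$rmsd_selected, choose(36, 2))
  expect_length(s$rmsd_discarded, choose(54, 2))
  expect_lt(mean(s$rmsd_selected), mean(s$rmsd_discarded))
  expect_lt(s$group_comparison$p_value, 0.05)
  expect_match(s$group_comparison$method, "Mann-Whitney")
})

test_that("permutation and Mann-Whitney comparisons agree in direction", {
  ens <- make_ensemble(synthetic_ensemble_config("GKARDF", 169L, n_poses = 30L,
                                                 productive_fraction = 0.4,
                                                 seed = 23L), rec)
  evs <- evaluate_pose_set(ens$poses, rec)
  set.seed(1)
  sp <- summarize_ensemble(evs, ens$poses, test = "permutation", n_perm = 200L)
  expect_match(sp$group_comparison$method, "permutation")
  expect_lt(sp$group_comparison$statistic, 0)  # selected cluster tighter
  expect_lt(sp$group_comparison$p_value, 0.05)
  sm <- summarize_ensemble(evs, ens$poses)
  expect_lt(mean(sm$rmsd_selected) - mean(sm$rmsd_discarded), 0)
})

test_that("degenerate ensembles give empty RMSD lists and a null comparison", {
  ens <- make_ensemble(synthetic_ensemble_config("GKARDF", 169L, n_poses = 10L,
                                                 productive_fraction = 0,
                                                 seed = 3L), rec)
  evs <- evaluate_pose_set(ens$poses, rec)
  s <- summarize_ensemble(evs, ens$poses)
  expect_equal(s$pass_fraction_percent, 0)
  expect_length(s$occupancy_counts, 0L)
  expect_length(s$rmsd_selected, 0L)
  expect_null(s$group_comparison)
  expect_error(summarize_ensemble(evs[1:3], ens$poses), "differ in length")
})

test_that("pass fraction is invariant under pose reordering", {
  ens <- make_ensemble(synthetic_ensemble_config("GRKRKV", 177L, n_poses = 20L,
                                                 productive_fraction = 0.35,
                                                 seed = 31L), rec)
  evs <- evaluate_pose_set(ens$poses, rec)
  s1 <- summarize_ensemble(evs, ens$poses)
  perm <- rev(seq_along(evs))
  ps <- ens$poses; ps$poses <- ps$poses[perm]
  s2 <- summarize_ensemble(evs[perm], ps)
  expect_equal(s2$pass_fraction_percent, s1$pass_fraction_percent)
  expect_equal(sort(s2$rmsd_selected), sort(s1$rmsd_selected), tolerance = 1e-12)
})

test_that("site ranking orders by occupancy with the R-before-K tie-break", {
  mk_summary <- function(label, occ, n_total = 90L)
    structure(list(peptide_label = label, n_total = n_total,
                   n_selected = sum(occ),
                   pass_fraction_percent = 100 * sum(occ) / n_total,
                   occupancy_counts = occ, rmsd_selected = numeric(0),
                   rmsd_discarded = numeric(0), group_comparison = NULL),
              class = "ensemble_summary")
  cands <- enumerate_candidates(mock_substrate(), c(168L, 192L))
  r <- site_ranking(list(mk_summary("GKARDF", c(`172` = 38L)),
                         mk_summary("IHKASN", c(`189` = 7L))),
                    candidates = cands)
  expect_identical(r$p1_position, c(172L, 189L))
  expect_identical(r$rank, 1:2)
  # equal counts: the Arg site outranks the Lys site
  r2 <- site_ranking(list(mk_summary("GKARDF", c(`170` = 10L, `172` = 10L))),
                     candidates = cands)
  expect_identical(r2$p1_position[1], 172L)
  expect_identical(r2$p1_residue, c("R", "K"))
  # single summary, single occupant
  r3 <- site_ranking(list(mk_summary("IHKASN", c(`189` = 4L))), candidates = cands)
  expect_identical(r3$p1_position, 189L)
  # exclusion flags are carried through, not dropped
  r4 <- site_ranking(list(mk_summary("GRKRKV", c(`178` = 20L, `180` = 5L))),
                     candidates = cands)
  expect_true(r4$excluded[r4$p1_position == 180L])
  expect_false(r4$excluded[r4$p1_position == 178L])
})
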