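rec <- make_mock_receptor()
od1 <- receptor_anchor(rec, 435L, "OD1")
od2 <- receptor_anchor(rec, 435L, "OD2")
og <- receptor_anchor(rec, 441L, "OG")

# place an Arg side chain with NH1 at a chosen distance above the more exposed
# carboxylate oxygen (so the charged-group/carboxylate minimum equals d_salt)
# and the backbone carbonyl C at a chosen distance from OG
arg_pose <- function(d_salt, d_scissile) {
  up <- c(0, 0, 1)
  anchor <- if (od2[3] >= od1[3]) od2 else od1
  nh1 <- anchor + d_salt * up
  cpos <- og + d_scissile * up
  pose <- make_bare_pose("GKARDF", 169L, origin = c(0, 0, 30),
                         extra = list(`170` = list(CB = c(0, 3.5, 31.5),
                                                   NZ = c(0, 3.5, 35))))
  a <- pose$atoms
  a[a$resno == 172L & a$elety == "C", c("x", "y", "z")] <- as.list(cpos)
  extra <- data.frame(elety = c("NE", "CZ", "NH1", "NH2"), elesy = "N",
                      resid = "ARG", chain = "A", resno = 172L,
                      x = c(nh1[1] - 2, nh1[1] - 1, nh1[1], nh1[1] + 1.1),
                      y = c(nh1[2], nh1[2], nh1[2], nh1[2]),
                      z = c(nh1[3] + 2.4, nh1[3] + 1.2, nh1[3], nh1[3] + 0.6),
                      stringsAsFactors = FALSE)
  extra$elesy <- c("N", "C", "N", "N")
  pose$atoms <- rbind(a, extra)
  pose
}

test_that("constructed geometry is selected with the expected distances", {
  pose <- arg_pose(3.0, 3.5)
  ev <- evaluate_pose(pose, rec)
  expect_true(ev$selected)
  expect_identical(ev$s1_occupant, 172L)
  expect_equal(ev$salt_bridge_distance, 3.0, tolerance = 1e-9)
  expect_equal(ev$scissile_distance, 3.5, tolerance = 1e-9)
})

test_that("distances exactly at the threshold fail under strict inequality and pass without it", {
  pose <- arg_pose(3.0, 4.0)
  expect_false(evaluate_pose(pose, rec)$selected)
  expect_true(evaluate_pose(pose, rec,
                            selection_criteria(strict_inequality = FALSE))$selected)
  pose2 <- arg_pose(4.0, 3.5)
  ev2 <- evaluate_pose(pose2, rec)
  expect_false(ev2$selected)
  expect_true(is.na(ev2$s1_occupant))
})

test_that("far decoys have no occupant and no-basic peptides report a reason, not an error", {
  far <- make_bare_pose("GKARDF", 169L,
                        extra = list(`170` = list(CB = c(0, 3.5, 51.5), NZ = c(0, 3.5, 55)),
                                     `172` = list(CB = c(0, 10.5, 51.5), NH1 = c(0, 10.5, 55),
                                                  NH2 = c(1, 10.5, 55), NE = c(0, 10.5, 53.7))))
  ev <- evaluate_pose(far, rec)
  expect_false(ev$selected)
  expect_true(is.na(ev$s1_occupant))
  expect_match(ev$reason, "S1")

  nobasic <- make_bare_pose("GAAADF", 169L)
  ev2 <- evaluate_pose(nobasic, rec)
  expect_false(ev2$selected)
  expect_match(ev2$reason, "no basic residue")
})

test_that("criterion-2 failure keeps the occupant but rejects the pose", {
  pose <- arg_pose(3.5, 6.0)
  ev <- evaluate_pose(pose, rec)
  expect_identical(ev$s1_occupant, 172L)
  expect_false(ev$selected)
  expect_match(ev$reason, "scissile")
})

test_that("evaluation is invariant under a common rigid transform of receptor and pose", {
  pose <- arg_pose(3.2, 3.6)
  ev0 <- evaluate_pose(pose, rec)
  set.seed(5)
  for (rep in 1:5) {
    rot <- random_rotation_matrix()
    shift <- runif(3, -30, 30)
    ev <- evaluate_pose(rigid_transform_pose(pose, rot, shift),
                        rigid_transform_receptor(rec, rot, shift))
    expect_equal(ev$salt_bridge_distance, ev0$salt_bridge_distance, tolerance = 1e-9)
    expect_equal(ev$scissile_distance, ev0$scissile_distance, tolerance = 1e-9)
    expect_identical(ev$selected, ev0$selected)
  }
})

test_that("raising either threshold never decreases the selected count", {
  ens <- make_ensemble(synthetic_ensemble_config("GKARDF", 169L, n_poses = 30L,
                                                 productive_fraction = 0.5,
                                                 seed = 13L), rec)
  count_sel <- function(criteria)
    sum(vapply(evaluate_pose_set(ens$poses, rec, criteria), `[[`, logical(1), "selected"))
  base <- count_sel(selection_criteria())
  for (bump in c(0.5, 2, 10)) {
    expect_gte(count_sel(selection_criteria(salt_bridge_max = 4 + bump)), base)
    expect_gte(count_sel(selection_criteria(scissile_max = 4 + bump)), base)
  }
})

test_that("evaluate_pose agrees with a brute-force per-pair oracle on synthetic poses", {
  ens <- make_ensemble(synthetic_ensemble_config("GRKRKV", 177L, n_poses = 12L,
                                                 productive_fraction = 0.5,
                                                 seed = 21L), rec)
  crit <- selection_criteria()
  asp <- rec$atoms[rec$atoms$resno == 435L & rec$atoms$elety %in% c("OD1", "OD2"), ]
  og_row <- rec$atoms[rec$atoms$resno == 441L & rec$atoms$elety == "OG", ]
  for (pose in ens$poses$poses) {
    ev <- evaluate_pose(pose, rec, crit)
    # oracle: enumerate every (charged atom, carboxylate oxygen) pair per basic residue
    oracle <- list()
    for (rn in unique(pose$atoms$resno)) {
      res <- pose$atoms[pose$atoms$resno == rn, ]
      aa <- cleavedock:::aa3to1(res$resid[1])
      if (!aa %in% c("R", "K")) next
      charged <- res[res$elety %in% (if (aa == "R") c("NH1", "NH2", "NE") else "NZ"), ]
      sb <- brute_min_dist(as.matrix(charged[, c("x", "y", "z")]),
                           as.matrix(asp[, c("x", "y", "z")]))
      cc <- as.matrix(res[res$elety == "C", c("x", "y", "z")])
      sc <- brute_min_dist(cc, as.matrix(og_row[, c("x", "y", "z")]))
      oracle[[as.character(rn)]] <- c(sb = sb, sc = sc)
    }
    passing <- Filter(function(v) v["sb"] < 4, oracle)
    if (length(passing) == 0L) {
      expect_true(is.na(ev$s1_occupant))
      expect_false(ev$selected)
    } else {
      sbs <- vapply(passing, `[`, numeric(1), "sb")
      occ <- names(passing)[which.min(sbs)]
      expect_identical(as.character(ev$s1_occupant), occ)
      expect_equal(ev$salt_bridge_distance, min(sbs), tolerance = 1e-9)
      expect_identical(ev$selected, unname(passing[[occ]]["sc"] < 4))
    }
  }
})

test_that("synthetic ensembles are classified exactly by ground truth", {
  ens <- make_ensemble(synthetic_ensemble_config("GKARDF", 169L, n_poses = 90L,
                                                 productive_fraction = 0.4,
                                                 seed = 7L), rec)
  expect_identical(sum(ens$labels), 36L)
  evs <- evaluate_pose_set(ens$poses, rec)
  sel <- vapply(evs, `[[`, logical(1), "selected")
  expect_identical(sel, ens$labels)
  occ <- unique(vapply(evs[sel], `[[`, integer(1), "s1_occupant"))
  expect_identical(occ, 172L)
})

test_that("replicated poses evaluate identically", {
  pose <- arg_pose(3.1, 3.3)
  ps <- new_pose_set("GKARDF", lapply(1:5, function(i) { p <- pose; p$pose_id <- i; p }))
  evs <- evaluate_pose_set(ps, rec)
  expect_true(all(vapply(evs, `[[`, logical(1), "selected")))
  expect_length(unique(vapply(evs, `[[`, numeric(1), "salt_bridge_distance")), 1L)
})
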