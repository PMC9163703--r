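wt <- mock_substrate()

test_that("alanine substitutions apply cleanly and leave the input unchanged", {
  spec <- parse_mutant_name("RKRK178AAAA", wt)
  mut <- apply_mutations(wt, spec)
  expect_identical(cleavedock:::.subseq(mut, 177, 182), "GAAAAV")
  expect_identical(cleavedock:::.subseq(wt, 177, 182), "GRKRKV")

  r138a <- apply_mutations(wt, parse_mutant_name("R138A", wt))
  expect_identical(cleavedock:::.residue_at(r138a, 138L), "A")
  expect_identical(cleavedock:::.subseq(r138a, 135, 137), "RKR")

  noop <- apply_mutations(wt, mutant_spec(data.frame(position = integer(),
                                                     from_aa = character(),
                                                     to_aa = character())))
  expect_identical(noop$residues, wt$residues)

  bad <- mutant_spec(data.frame(position = 138L, from_aa = "K", to_aa = "A"))
  expect_error(apply_mutations(wt, bad), "'K'.*'R'|mismatch")
})

test_that("mutant names parse under both run anchorings and round-trip", {
  # printed position is the FIRST residue of the 178-RKRK-181 run
  s1 <- parse_mutant_name("RKRK178AAAA", wt)
  expect_identical(sort(s1$substitutions$position), 178:181)
  # ... but the LAST residue of the 135-RKRR-138 run
  s2 <- parse_mutant_name("RKRR138AAAA + R153A", wt)
  expect_identical(sort(s2$substitutions$position), c(135:138, 153L))
  expect_true(all(s2$substitutions$to_aa == "A"))

  s3 <- parse_mutant_name("K168A", wt)
  expect_identical(s3$substitutions$position, 168L)

  compound <- "RKRK178AAAA;K168A;K170A;R172A;K189A"
  s4 <- parse_mutant_name(compound, wt)
  expect_identical(sort(s4$substitutions$position), c(168L, 170L, 172L, 178:181, 189L))
  # round trip: reparse of the regenerated name gives the same substitution set
  s5 <- parse_mutant_name(format_mutant_name(s4), wt)
  expect_identical(s5$substitutions[order(s5$substitutions$position), ],
                   s4$substitutions[order(s4$substitutions$position), ],
                   ignore_attr = TRUE)

  expect_error(parse_mutant_name("R999A", wt), "R999A")
  expect_error(parse_mutant_name("178AAAA", wt), "parse")
})

test_that("distal-region enumeration finds the eight basic sites and excludes R180", {
  cands <- enumerate_candidates(wt, c(168L, 192L))
  expect_identical(cands$p1_position, c(168L, 170L, 172L, 178L, 179L, 180L, 181L, 189L))
  expect_identical(cands$p1_residue, c("K", "K", "R", "R", "K", "R", "K", "K"))
  excluded <- cands$p1_position[cands$excluded]
  expect_identical(excluded, 180L)
  expect_match(cands$exclusion_reason[cands$p1_position == 180L], "K")
  # windows are P4-P2prime 6-mers; R172's window is the canonical 169-174 one
  w172 <- cands[cands$p1_position == 172L, ]
  expect_identical(w172$window, "GKARDF")
  expect_identical(c(w172$window_start, w172$window_end), c(169L, 174L))
})

test_that("the quintuple alanine mutant removes every usable distal site", {
  mut <- apply_mutations(wt, parse_mutant_name("RKRK178AAAA;K168A;K170A;R172A;K189A", wt))
  cands <- enumerate_candidates(mut, c(168L, 192L))
  expect_identical(nrow(cands[!cands$excluded, ]), 0L)
})

test_that("candidate count equals an exhaustive R/K string scan and mutations never leave candidates at substituted positions", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    residues <- paste(sample(c("A", "G", "R", "K", "S", "T", "V"), n, replace = TRUE),
                      collapse = "")
    seq <- substrate_sequence("random", residues, 100L)
    region <- c(100L, 100L + n - 1L)
    cands <- suppressWarnings(enumerate_candidates(seq, region))
    oracle <- sum(strsplit(residues, "")[[1]] %in% c("R", "K"))
    expect_identical(nrow(cands), oracle)
    basic <- which(strsplit(residues, "")[[1]] %in% c("R", "K"))
    if (length(basic) > 0) {
      pos <- 99L + basic[1]
      spec <- mutant_spec(data.frame(position = pos,
                                     from_aa = substr(residues, basic[1], basic[1]),
                                     to_aa = "A"))
      cands2 <- suppressWarnings(enumerate_candidates(apply_mutations(seq, spec), region))
      expect_false(pos %in% cands2$p1_position)
    }
  }
  allala <- substrate_sequence("ala", strrep("A", 20), 1L)
  expect_identical(nrow(enumerate_candidates(allala, c(1L, 20L))), 0L)
})

test_that("region outside the sequence span is a range error", {
  expect_error(enumerate_candidates(wt, c(100L, 150L)), "outside")
})

test_that("docking windows dedupe by policy", {
  cands <- enumerate_candidates(wt, c(168L, 192L))
  # region_based with the three canonical anchors reproduces the docked 6-mers
  w <- suppressWarnings(docking_windows(cands, wt, policy = "region_based",
                                        anchors = c(169L, 177L, 187L)))
  expect_identical(w$window, c("GKARDF", "GRKRKV", "IHKASN"))
  expect_identical(w$p1_positions, c("170,172", "178,179,180,181", "189"))
  # K168 falls before every anchor window and is dropped with a warning
  expect_warning(docking_windows(cands, wt, policy = "region_based",
                                 anchors = c(169L, 177L, 187L)), "168")
  # p1-centered: R172 gets the same literal 169-174 window
  wp <- docking_windows(cands[cands$p1_position == 172L, , drop = FALSE], wt,
                        policy = "p1_centered")
  expect_identical(wp$window, "GKARDF")
  # truncation at the sequence start emits a shorter window plus warning
  short <- substrate_sequence("s", "ARDFGT", 1L)
  expect_warning(cands_s <- enumerate_candidates(short, c(1L, 6L)), "truncated")
  expect_lt(nchar(cands_s$window[1]), 6L)
  empty <- enumerate_candidates(wt, c(183L, 186L))
  expect_identical(nrow(docking_windows(empty, wt, policy = "p1_centered")), 0L)
})
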