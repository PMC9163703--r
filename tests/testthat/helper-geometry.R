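# Shared fixtures and independent oracles.

# brute-force double-loop minimum pairwise distance
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# brute-force RMSD over two equally ordered coordinate matrices
brute_rmsd <- function(xa, xb) {
  s <- 0
  for (i in seq_len(nrow(xa))) s <- s + sum((xa[i, ] - xb[i, ])^2)
  sqrt(s / nrow(xa))
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         nrow = 3, byrow = TRUE)
}

transform_coords <- function(x, rot, shift) sweep(x %*% t(rot), 2, shift, "+")

rigid_transform_atoms <- function(atoms, rot, shift) {
  xyz <- transform_coords(as.matrix(atoms[, c("x", "y", "z")]), rot, shift)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

rigid_transform_receptor <- function(receptor, rot, shift) {
  receptor$atoms <- rigid_transform_atoms(receptor$atoms, rot, shift)
  receptor
}

rigid_transform_pose <- function(pose, rot, shift) {
  pose$atoms <- rigid_transform_atoms(pose$atoms, rot, shift)
  pose
}

# minimal hand-built pose: backbone (plus optional side-chain atoms) placed at
# explicit coordinates, for constructed-geometry tests
make_bare_pose <- function(window, start_number, extra = list(), pose_id = 1L,
                           origin = c(0, 0, 50)) {
  aa <- strsplit(window, "")[[1]]
  rows <- list()
  for (i in seq_along(aa)) {
    resno <- start_number + i - 1L
    base <- origin + c(0, (i - 1) * 3.5, 0)
    atoms <- list(N = base + c(-1.2, 0, 0), CA = base,
                  C = base + c(1.3, 0, 0), O = base + c(1.3, 0, 1.2))
    if (!is.null(extra[[as.character(resno)]]))
      atoms <- c(atoms, extra[[as.character(resno)]])
    rows[[i]] <- data.frame(
      elety = names(atoms),
      elesy = substr(gsub("[0-9]", "", names(atoms)), 1, 1),
      resid = cleavedock:::aa1to3(aa[i]), chain = "A", resno = resno,
      x = vapply(atoms, `[`, numeric(1), 1),
      y = vapply(atoms, `[`, numeric(1), 2),
      z = vapply(atoms, `[`, numeric(1), 3),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  new_peptide_pose(pose_id, window, do.call(rbind, rows))
}

# place a single named atom at an exact offset from a receptor anchor atom
receptor_anchor <- function(receptor, resno, elety) {
  a <- receptor$atoms
  as.numeric(a[a$resno == resno & a$elety == elety, c("x", "y", "z")][1, ])
}
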