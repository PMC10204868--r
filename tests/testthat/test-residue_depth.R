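# Dot-surface construction and residue depth.

single_atom_structure <- function(x = 0, y = 0, z = 0) {
  clean_structure(sprintf(
    "ATOM      1  CA  ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
    x, y, z))
}

test_that("a single atom keeps all sample points at radius vdW + probe", {
  s <- single_atom_structure()
  cloud <- build_surface(s, probe_radius = 1.5, samples_per_atom = 100)
  expect_equal(nrow(cloud$points), 100)
  r <- sqrt(rowSums(cloud$points^2))
  expect_equal(r, rep(1.7 + 1.5, 100), tolerance = 1e-9)
})

test_that("two fully overlapping identical atoms give the one-atom cloud twice", {
  one <- single_atom_structure()
  two <- clean_structure(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"))
  c1 <- build_surface(one, 1.5, 64)
  c2 <- build_surface(two, 1.5, 64)
  expect_equal(nrow(c2$points), 2 * nrow(c1$points))
  r <- sqrt(rowSums(c2$points^2))
  expect_equal(r, rep(3.2, nrow(c2$points)), tolerance = 1e-9)
})

test_that("occlusion matches a brute-force all-pairs oracle", {
  set.seed(4)
  n <- 40
  xyz <- matrix(stats::rnorm(3 * n, sd = 4), ncol = 3)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3])
  s <- clean_structure(lines)
  cloud <- build_surface(s, 1.5, 120)

  # oracle: regenerate each atom's sphere in its local frame and test every
  # point against every other atom (no neighbor-list shortcut)
  unit <- ebdiff:::fibonacci_sphere(120)
  kept <- 0L
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    frame <- ebdiff:::canonical_frame(xyz[d2 <= 64, , drop = FALSE])
    p <- sweep((unit %*% t(frame)) * 3.2, 2, xyz[i, ], "+")
    ok <- rep(TRUE, nrow(p))
    for (j in seq_len(n)[-i]) {
      ok <- ok & (rowSums(sweep(p, 2, xyz[j, ], "-")^2) >= 3.2^2 - 1e-9)
    }
    kept <- kept + sum(ok)
  }
  expect_equal(nrow(cloud$points), kept)
})

test_that("a lone glycine is entirely at the surface", {
  g <- make_toy_structure(1, "extended", sequence = "G")
  dep <- residue_depth(g$structure, samples_per_atom = 240)
  expect_lt(dep$depth, 1.7 + 1.5 + 1e-9)
})

test_that("depth equals the brute-force nearest-surface-point oracle", {
  toy <- make_toy_structure(30, "ball",
                            sequence = paste(rep("A", 30), collapse = ""))
  s <- toy$structure
  cloud <- build_surface(s, 1.5, 240)
  dep <- residue_depth(s, cloud)
  a <- s$atoms[s$atoms$element != "H", ]
  pts <- cloud$points
  oracle <- vapply(split(seq_len(nrow(a)), a$renum_id), function(ix) {
    mean(vapply(ix, function(k) {
      min(sqrt((pts[, 1] - a$x[k])^2 + (pts[, 2] - a$y[k])^2 +
                 (pts[, 3] - a$z[k])^2))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(dep$depth, unname(oracle[as.character(dep$residue)]))
})

test_that("depth rank-tracks burial in the synthetic ball", {
  toy <- make_toy_structure(60, "ball",
                            sequence = paste(rep("A", 60), collapse = ""))
  s <- toy$structure
  dep <- residue_depth(s, samples_per_atom = 240)
  ca <- s$atoms[s$atoms$atom_name == "CA", ]
  cen <- c(mean(ca$x), mean(ca$y), mean(ca$z))
  cd <- sqrt((ca$x - cen[1])^2 + (ca$y - cen[2])^2 + (ca$z - cen[3])^2)
  rho <- stats::cor(dep$depth, cd[match(dep$residue, ca$renum_id)],
                    method = "spearman")
  # depth and centroid distance are anti-monotone: buried residues are deep
  expect_lt(rho, -0.95)
  # the centre-most residue is strictly deeper than the most peripheral
  expect_gt(dep$depth[which.min(cd)], dep$depth[which.max(cd)])
})

test_that("depths are rigid-motion invariant and insensitive to remote atoms", {
  toy <- make_toy_structure(20, "ball",
                            sequence = paste(rep("A", 20), collapse = ""))
  s <- toy$structure
  dep <- residue_depth(s, samples_per_atom = 240)

  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, byrow = TRUE)
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s2$atoms$x <- xyz[, 1] + 12.3
  s2$atoms$y <- xyz[, 2] - 7.1
  s2$atoms$z <- xyz[, 3] + 3.9
  dep2 <- residue_depth(s2, samples_per_atom = 240)
  expect_equal(dep2$depth, dep$depth, tolerance = 1e-6)

  # a far-away atom cluster changes nothing: append a copy shifted by much
  # more than 2 * (max vdW + probe)
  s3 <- s
  far <- s$atoms
  far$x <- far$x + 200
  far$renum_id <- far$renum_id + max(s$atoms$renum_id)
  far$author_seq_id <- far$renum_id
  s3$atoms <- rbind(s$atoms, far)
  s3$residues <- s3$atoms[!duplicated(s3$atoms$renum_id),
                          c("renum_id", "chain", "author_seq_id", "restype3")]
  dep3 <- residue_depth(s3, samples_per_atom = 240)
  near <- dep3$residue <= 20
  expect_equal(dep3$depth[near], dep$depth, tolerance = 1e-6)
})

test_that("depths are stable from 240 to 960 samples per atom", {
  toy <- make_toy_structure(60, "ball",
                            sequence = paste(rep("A", 60), collapse = ""))
  d240 <- residue_depth(toy$structure, samples_per_atom = 240)
  d960 <- residue_depth(toy$structure, samples_per_atom = 960)
  expect_lt(max(abs(d240$depth - d960$depth)), 0.2)
})

test_that("the depth-energy join lines up residues and flags missing sides", {
  mock <- make_mock_breakdown(small_plan(seed = 23))
  ref_t <- parse_breakdown(mock$ref_lines)
  mut_t <- parse_breakdown(mock$mut_lines)
  ref_s <- make_toy_structure(60, "ball",
                              sequence = mock$truth$sequence_ref)$structure
  mut_s <- make_toy_structure(60, "ball",
                              sequence = mock$truth$sequence_mut)$structure
  dref <- residue_depth(ref_s, samples_per_atom = 120)
  dmut <- residue_depth(mut_s, samples_per_atom = 120)
  j <- depth_energy_join(dref, dmut, ref_t, mut_t)
  expect_equal(nrow(j), 60)
  expect_true(all(j$status == "both"))
  expect_equal(j$delta_net, j$net_mut - j$net_ref)
  # identical inputs on both sides: all deltas zero
  j0 <- depth_energy_join(dref, dref, ref_t, ref_t)
  expect_true(all(j0$delta_net == 0))
  # conflicting restypes between structure and table are a hard error
  bad <- dref
  bad$restype3[1] <- setdiff(c("TRP", "GLY"), bad$restype3[1])[1]
  expect_error(depth_energy_join(bad, dmut, ref_t, mut_t),
               "renumbering mismatch")
})

test_that("a one-body-only perturbation moves net energy but nothing else", {
  rows <- list(ob(1, "ALA", -1), ob(2, "LEU", -2), ob(3, "VAL", -3),
               pr(1, "ALA", 2, "LEU", fa_atr = -0.5))
  ref_t <- parse_breakdown(mk_lines(rows))
  rows[[3]] <- ob(3, "VAL", -1)  # residue 3 onebody worsens by +2
  mut_t <- parse_breakdown(mk_lines(rows))
  s <- make_toy_structure(3, "extended", sequence = "ALV")$structure
  dep <- residue_depth(s, samples_per_atom = 120)
  j <- depth_energy_join(dep, dep, ref_t, mut_t)
  expect_equal(j$delta_net, c(0, 0, 2))
})
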