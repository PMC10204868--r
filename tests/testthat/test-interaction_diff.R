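# Category/type classification, table diffing, thresholds and summaries.

test_that("the category truth table is implemented exactly", {
  expect_equal(classify_category(TRUE, TRUE, FALSE, -0.8), "A")
  expect_equal(classify_category(TRUE, TRUE, TRUE, -0.8), "B")
  expect_equal(classify_category(TRUE, FALSE, FALSE, 0.4), "C")
  expect_equal(classify_category(TRUE, FALSE, TRUE, 0.4), "D")
  expect_equal(classify_category(FALSE, TRUE, FALSE, -3.32), "E")
  # a new salt bridge formed by mutating one member is category F
  expect_equal(classify_category(FALSE, TRUE, TRUE, -3.32), "F")
  # unchanged both-side pairs get no category
  expect_true(is.na(classify_category(TRUE, TRUE, FALSE, 0)))
  expect_true(is.na(classify_category(TRUE, TRUE, TRUE, 5e-7)))
  expect_error(classify_category(FALSE, FALSE, FALSE, 1), "impossible")
})

test_that("physical types follow the score-term rules", {
  expect_setequal(
    classify_type(c(hbond_sc = -1.1), "ARG", "ASP"),
    c("salt_bridge", "hb_sc_sc", "all"))
  expect_setequal(
    classify_type(c(dslf_fa13 = -2.0), "CYS", "CYS"),
    c("disulfide", "all"))
  expect_equal(classify_type(c(fa_atr = -1.0), "LEU", "VAL"), "all")
  # orientation of the charged pair does not matter
  expect_true("salt_bridge" %in% classify_type(c(hbond_sc = -0.2), "GLU", "LYS"))
  # no hydrogen bond term active -> charged pair is not a salt bridge
  expect_false("salt_bridge" %in% classify_type(c(fa_elec = -1.0), "ARG", "ASP"))
  # HIS counts as basic only in the default (non-strict) mode
  expect_true("salt_bridge" %in% classify_type(c(hbond_sc = -0.5), "HIS", "GLU"))
  expect_false("salt_bridge" %in%
                 classify_type(c(hbond_sc = -0.5), "HIS", "GLU",
                               strict_salt_bridge = TRUE))
})

test_that("identical tables diff to zero changes", {
  mock <- make_mock_breakdown(small_plan())
  t <- parse_breakdown(mock$ref_lines)
  d <- diff_tables(t, t, NULL)
  expect_equal(nrow(d$changes), 0)
  expect_equal(nrow(d$onebody_changes), 0)
})

test_that("planted category counts, types and deltas are recovered exactly", {
  mock <- make_mock_breakdown(small_plan(seed = 7))
  ref <- parse_breakdown(mock$ref_lines)
  mut <- parse_breakdown(mock$mut_lines)
  d <- diff_tables(ref, mut, mock$truth$mutations)
  truth <- mock$truth$pairs
  expect_equal(nrow(d$changes), nrow(truth))
  expect_equal(as.vector(table(factor(d$changes$category,
                                      levels = c("A", "B", "C", "D", "E", "F")))),
               c(12, 8, 5, 5, 7, 9))
  m <- match(pair_keys_of(truth), pair_keys_of(d$changes))
  expect_false(anyNA(m))
  expect_equal(d$changes$category[m], truth$category)
  expect_equal(d$changes$types[m], truth$types)
  expect_equal(d$changes$delta_total[m], truth$delta_total, tolerance = 1e-12)
})

test_that("a contradictory mutation list raises a renumbering mismatch", {
  mock <- make_mock_breakdown(small_plan())
  ref <- parse_breakdown(mock$ref_lines)
  mut <- parse_breakdown(mock$mut_lines)
  wrong <- mock$truth$mutations
  wrong$ref[1] <- setdiff(c("A", "W"), wrong$ref[1])[1]
  expect_error(diff_tables(ref, mut, wrong), "renumbering mismatch")
})

test_that("swapping ref and mut maps C<->E, D<->F and negates deltas", {
  mock <- make_mock_breakdown(small_plan(seed = 11))
  ref <- parse_breakdown(mock$ref_lines)
  mut <- parse_breakdown(mock$mut_lines)
  muts <- mock$truth$mutations
  muts_rev <- data.frame(position = muts$position, ref = muts$mut,
                         mut = muts$ref)
  d <- diff_tables(ref, mut, muts)
  d_rev <- diff_tables(mut, ref, muts_rev)
  m <- match(pair_keys_of(d$changes), pair_keys_of(d_rev$changes))
  expect_false(anyNA(m))
  map <- c(A = "A", B = "B", C = "E", D = "F", E = "C", F = "D")
  expect_equal(d_rev$changes$category[m], unname(map[d$changes$category]))
  expect_equal(d_rev$changes$delta_total[m], -d$changes$delta_total)
})

test_that("every pair key gets exactly one category or none (partition)", {
  for (seed in c(2, 9)) {
    mock <- make_mock_breakdown(small_plan(seed = seed))
    ref <- parse_breakdown(mock$ref_lines)
    mut <- parse_breakdown(mock$mut_lines)
    d <- diff_tables(ref, mut, mock$truth$mutations)
    rp <- ref$records[!ref$records$is_onebody, ]
    mp <- mut$records[!mut$records$is_onebody, ]
    union_keys <- union(paste(rp$resi1, rp$resi2), paste(mp$resi1, mp$resi2))
    ch_keys <- pair_keys_of(d$changes)
    expect_equal(anyDuplicated(ch_keys), 0)
    expect_true(all(ch_keys %in% union_keys))
    # unclassified pairs are exactly those present and unchanged
    un <- setdiff(union_keys, ch_keys)
    rtot <- stats::setNames(rp$total, paste(rp$resi1, rp$resi2))
    mtot <- stats::setNames(mp$total, paste(mp$resi1, mp$resi2))
    dd <- abs(ifelse(is.na(mtot[un]), 0, mtot[un]) -
                ifelse(is.na(rtot[un]), 0, rtot[un]))
    expect_true(all(dd <= d$change_eps))
  }
})

test_that("total energy change sums match a brute-force re-walk of the tables", {
  mock <- make_mock_breakdown(small_plan(seed = 13))
  ref <- parse_breakdown(mock$ref_lines)
  mut <- parse_breakdown(mock$mut_lines)
  d <- diff_tables(ref, mut, mock$truth$mutations, change_eps = 0)
  expect_equal(total_energy_changes(d, c("A", "B")),
               sum(d$changes$delta_total[d$changes$category %in% c("A", "B")]))
  # independent oracle: walk the raw union of pair keys
  rp <- ref$records[!ref$records$is_onebody, ]
  mp <- mut$records[!mut$records$is_onebody, ]
  keys <- union(paste(rp$resi1, rp$resi2), paste(mp$resi1, mp$resi2))
  rtot <- stats::setNames(rp$total, paste(rp$resi1, rp$resi2))
  mtot <- stats::setNames(mp$total, paste(mp$resi1, mp$resi2))
  brute <- sum(ifelse(is.na(mtot[keys]), 0, mtot[keys]) -
                 ifelse(is.na(rtot[keys]), 0, rtot[keys]))
  expect_equal(total_energy_changes(d), brute, tolerance = 1e-9)
})

test_that("simple delta sets add up as expected", {
  t_ref <- parse_breakdown(mk_lines(list(
    ob(1, "ALA", -1), ob(2, "LEU", -1), ob(3, "VAL", -1),
    pr(1, "ALA", 2, "LEU", fa_atr = -1.0),
    pr(2, "LEU", 3, "VAL", fa_atr = -1.0))))
  t_mut <- parse_breakdown(mk_lines(list(
    ob(1, "ALA", -1), ob(2, "LEU", -1), ob(3, "VAL", -1),
    pr(1, "ALA", 2, "LEU", fa_atr = -0.5),
    pr(2, "LEU", 3, "VAL", fa_atr = -1.99))))
  d <- diff_tables(t_ref, t_mut, NULL)
  expect_equal(total_energy_changes(d), 0.5 - 0.99)
  expect_equal(total_energy_changes(d, "B"), 0)
})

test_that("significance uses strict inequalities at the 1 REU threshold", {
  rows_ref <- list(ob(1, "ALA", -1), ob(2, "LEU", -1), ob(3, "VAL", -1),
                   ob(4, "SER", -1), ob(5, "THR", -1),
                   pr(1, "ALA", 2, "LEU", fa_atr = -1.0),
                   pr(2, "LEU", 3, "VAL", fa_atr = -1.0),
                   pr(3, "VAL", 4, "SER", fa_atr = -1.0),
                   pr(4, "SER", 5, "THR", fa_atr = -1.0))
  rows_mut <- list(ob(1, "ALA", -1), ob(2, "LEU", -1), ob(3, "VAL", -1),
                   ob(4, "SER", -1), ob(5, "THR", -1),
                   pr(1, "ALA", 2, "LEU", fa_atr = 0.5),    # delta +1.5
                   pr(2, "LEU", 3, "VAL", fa_atr = -3.0),   # delta -2.0
                   pr(3, "VAL", 4, "SER", fa_atr = -0.7),   # delta +0.3
                   pr(4, "SER", 5, "THR", fa_atr = -2.0))   # delta -1.0 exact
  d <- diff_tables(parse_breakdown(mk_lines(rows_ref)),
                   parse_breakdown(mk_lines(rows_mut)), NULL)
  sig <- significant_changes(d)
  # exactly -1.0 is NOT significant (strict inequality)
  expect_equal(sig$changes$delta_total, c(-2.0, 1.5))
  expect_equal(sig$sum, -0.5)
  # a higher threshold excludes everything here
  sig2 <- significant_changes(d, threshold = 2.5)
  expect_equal(nrow(sig2$changes), 0)
  # threshold 0 recovers the total sum
  expect_equal(significant_changes(d, threshold = 0)$sum,
               total_energy_changes(d))
})

test_that("the significant set shrinks monotonically with the threshold", {
  mock <- make_mock_breakdown(small_plan(seed = 21))
  d <- diff_tables(parse_breakdown(mock$ref_lines),
                   parse_breakdown(mock$mut_lines), mock$truth$mutations)
  sizes <- vapply(c(0, 0.5, 1.0, 2.0),
                  function(th) nrow(significant_changes(d, threshold = th)$changes),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted significant and insignificant changes separate exactly", {
  mock <- make_mock_breakdown(small_plan(seed = 17))
  d <- diff_tables(parse_breakdown(mock$ref_lines),
                   parse_breakdown(mock$mut_lines), mock$truth$mutations)
  sig <- significant_changes(d)
  truth <- mock$truth$pairs
  expect_setequal(pair_keys_of(sig$changes),
                  pair_keys_of(truth[truth$significant, ]))
})

test_that("the summary grid counts by category and type with correct marginals", {
  # empty diff -> all-zero grid
  mock <- make_mock_breakdown(small_plan())
  t <- parse_breakdown(mock$ref_lines)
  g0 <- summary_table(diff_tables(t, t, NULL))
  expect_true(all(g0$counts == 0) && all(g0$sums == 0))

  # one F-category salt bridge: its cell and the all column agree
  ref <- parse_breakdown(mk_lines(list(ob(135, "ILE", -1), ob(153, "ASP", -1))))
  mut <- parse_breakdown(mk_lines(list(
    ob(135, "ARG", -1), ob(153, "ASP", -1),
    pr(135, "ARG", 153, "ASP", hbond_sc = -1.2, fa_elec = -2.12))))
  muts <- data.frame(position = 135, ref = "I", mut = "R")
  g <- summary_table(diff_tables(ref, mut, muts))
  expect_equal(g$counts["F", "salt_bridge"], 1L)
  expect_equal(g$sums["F", "salt_bridge"], -3.32)
  expect_equal(g$counts["F", "all"], 1L)
  expect_equal(g$sums["F", "all"], -3.32)
  expect_equal(sum(g$counts[, setdiff(colnames(g$counts), "all")] > 0), 2)

  # marginals: the all column matches the per-category significant counts
  mock <- make_mock_breakdown(small_plan(seed = 19))
  d <- diff_tables(parse_breakdown(mock$ref_lines),
                   parse_breakdown(mock$mut_lines), mock$truth$mutations)
  g2 <- summary_table(d)
  for (cc in c("A", "B", "C", "D", "E", "F")) {
    expect_equal(g2$counts[cc, "all"],
                 nrow(significant_changes(d, categories = cc)$changes))
  }
})

test_that("interaction presence respects the epsilon rule", {
  t <- parse_breakdown(mk_lines(list(pr(1, "ALA", 2, "LEU", fa_atr = -0.4),
                                     pr(2, "LEU", 3, "VAL", total = 0))))
  expect_true(is_interacting(t, 1, 2))
  expect_true(is_interacting(t, 2, 1))
  expect_false(is_interacting(t, 2, 3))  # present with total exactly 0
  expect_false(is_interacting(t, 1, 9))  # absent
})
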