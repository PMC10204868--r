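# Shared builders for hand-written fixtures.

# Minimal breakdown-dialect text. `rows` is a list of ob()/pr() entries.
mk_lines <- function(rows, terms = c("fa_atr", "fa_elec", "hbond_sc",
                                     "hbond_bb_sc", "hbond_sr_bb",
                                     "hbond_lr_bb", "dslf_fa13")) {
  header <- paste("SCORE: pose_id resi1 pdbid1 restype1 resi2 pdbid2",
                  "restype2", paste(terms, collapse = " "),
                  "total description")
  body <- vapply(rows, function(r) {
    tv <- stats::setNames(numeric(length(terms)), terms)
    tv[names(r$terms)] <- unlist(r$terms)
    tot <- if (!is.null(r$total)) r$total else sum(tv)
    vals <- paste(sprintf("%.6f", c(tv, tot)), collapse = " ")
    if (is.null(r$j)) {
      sprintf("SCORE: 1 %d %dA %s -- -- onebody %s fx", r$i, r$i, r$rt1, vals)
    } else {
      sprintf("SCORE: 1 %d %dA %s %d %dA %s %s fx",
              r$i, r$i, r$rt1, r$j, r$j, r$rt2, vals)
    }
  }, character(1))
  c(header, body)
}

# One-body row; total defaults to the single fa_atr value given.
ob <- function(i, rt, total) {
  list(i = i, rt1 = rt, total = total, terms = list(fa_atr = total))
}

# Pair row; total defaults to the sum of the named terms.
pr <- function(i, rt1, j, rt2, ..., total = NULL) {
  list(i = i, rt1 = rt1, j = j, rt2 = rt2, total = total, terms = list(...))
}

# A small fully-specified plan for diff tests (the counts from the planted
# recovery example).
small_plan <- function(seed = 7) {
  fixture_plan(n_residues = 60, n_mutations = 6,
               category_counts = c(A = 12, B = 8, C = 5, D = 5, E = 7, F = 9),
               n_unchanged = 10, seed = seed)
}

pair_keys_of <- function(df) paste(df$resi1, df$resi2)
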