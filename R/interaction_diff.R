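#' Does a residue pair interact in a table?
#'
#' "Interacting" is operationalized as: the pair has a record in the table
#' and the magnitude of its total exceeds `presence_eps`. Breakdown
#' calculations omit pairs outside the interaction graph, so absence from
#' the table is the natural non-interaction signal; a recorded total of
#' exactly zero is also treated as non-interacting.
#'
#' @param t An `energy_table`.
#' @param i,j Renumbered residue ids of the pair (order irrelevant).
#' @param presence_eps Magnitude below which a recorded total counts as no
#'   interaction (REU, default `1e-9`).
#' @return `TRUE` or `FALSE`.
#' @export
is_interacting <- function(t, i, j, presence_eps = 1e-9) {
  stopifnot(inherits(t, "energy_table"))
  rec <- t$records
  pk <- pair_key(i, j)
  keys <- pair_key(rec$resi1[!rec$is_onebody], rec$resi2[!rec$is_onebody])
  tot <- rec$total[!rec$is_onebody][match(pk, keys)]
  !is.na(tot) && abs(tot) > presence_eps
}

#' Classify one changed pair into interaction categories A-F
#'
#' The six categories cross presence (in reference only / in mutant only /
#' in both with a changed energy) with whether the pair involves a mutated
#' residue:
#' \describe{
#'   \item{A}{interacts in both structures, energy differs, no member mutated}
#'   \item{B}{interacts in both, energy differs, at least one member mutated}
#'   \item{C}{interacts only in the reference, no member mutated}
#'   \item{D}{interacts only in the reference, at least one member mutated}
#'   \item{E}{interacts only in the mutant, no member mutated}
#'   \item{F}{interacts only in the mutant, at least one member mutated}
#' }
#' Pairs present on both sides whose total changes by no more than
#' `change_eps` are unchanged and get no category (`NA`). Pairs where both
#' members are mutated count as mutation-involving (B/D/F).
#'
#' @param in_ref,in_mut Presence flags (see [is_interacting()]).
#' @param involves_mutation Does the pair contain a mutated position?
#' @param delta_total Mutant minus reference total, REU (absent side = 0).
#' @param change_eps Tolerance below which a both-sides pair counts as
#'   unchanged (REU, default `1e-6`).
#' @return One of `"A"`..`"F"`, or `NA_character_` for an unchanged pair.
#' @export
classify_category <- function(in_ref, in_mut, involves_mutation,
                              delta_total = NA_real_, change_eps = 1e-6) {
  if (!in_ref && !in_mut) {
    stop("impossible state: pair interacts in neither structure",
         call. = FALSE)
  }
  if (in_ref && in_mut) {
    if (!is.na(delta_total) && abs(delta_total) <= change_eps) {
      return(NA_character_)
    }
    return(if (involves_mutation) "B" else "A")
  }
  if (in_ref) {
    return(if (involves_mutation) "D" else "C")
  }
  if (involves_mutation) "F" else "E"
}

#' Assign physical interaction types to a two-body record
#'
#' Types are read off the score-term decomposition of the record:
#' \itemize{
#'   \item `hb_sc_sc`: side-chain/side-chain hydrogen bond, `hbond_sc < 0`;
#'   \item `hb_bb_sc`: backbone/side-chain hydrogen bond, `hbond_bb_sc < 0`;
#'   \item `hb_bb_sr`: short-range backbone hydrogen bond, `hbond_sr_bb < 0`;
#'   \item `hb_bb_lr`: long-range backbone hydrogen bond, `hbond_lr_bb < 0`;
#'   \item `disulfide`: both residues CYS and `dslf_fa13 != 0`;
#'   \item `salt_bridge`: one residue basic (ARG/LYS/HIS; ARG/LYS only under
#'     `strict_salt_bridge`), the other acidic (ASP/GLU), and `hbond_sc < 0`
#'     (the charged side chains form a hydrogen-bonded ion pair);
#'   \item `all`: every pair.
#' }
#' The salt-bridge criterion (opposite formal charges plus an active
#' side-chain hydrogen-bond term) is this package's operational definition;
#' histidine is counted as basic by default because it is frequently
#' protonated in ion pairs, and a strict mode excludes it.
#'
#' @param terms Named numeric vector of score-term values (term names as in
#'   the table header); missing terms are treated as 0.
#' @param restype1,restype2 Three-letter residue types of the pair.
#' @param strict_salt_bridge Exclude HIS from the basic set.
#' @return Character vector of types in canonical order (always contains
#'   `"all"`).
#' @export
classify_type <- function(terms, restype1, restype2,
                          strict_salt_bridge = FALSE) {
  g <- function(nm) if (nm %in% names(terms)) unname(terms[[nm]]) else 0
  basic <- if (strict_salt_bridge) SALT_BASIC_STRICT else SALT_BASIC
  out <- c(
    salt_bridge = ((restype1 %in% basic & restype2 %in% SALT_ACIDIC) |
                     (restype2 %in% basic & restype1 %in% SALT_ACIDIC)) &
      g("hbond_sc") < 0,
    disulfide = restype1 == "CYS" && restype2 == "CYS" && g("dslf_fa13") != 0,
    hb_sc_sc = g("hbond_sc") < 0,
    hb_bb_sc = g("hbond_bb_sc") < 0,
    hb_bb_sr = g("hbond_sr_bb") < 0,
    hb_bb_lr = g("hbond_lr_bb") < 0,
    all = TRUE
  )
  INTERACTION_TYPES[out[INTERACTION_TYPES]]
}

#' Diff two energy tables into classified pair changes
#'
#' Walks the union of residue-pair keys of the reference and mutant tables,
#' classifies every changed pair into categories A-F (see
#' [classify_category()]) and physical types (see [classify_type()]), and
#' collects per-term deltas, the total delta, and one-body changes. Types
#' are evaluated on the structure where the pair exists; for pairs present
#' on both sides (A/B) the union of both evaluations is reported, so a bond
#' present in only one structure still shows up.
#'
#' @param ref,mut `energy_table` objects for the reference and the mutant,
#'   under the same 1..N renumbering.
#' @param mutations Data frame as returned by [detect_mutations()] (may have
#'   zero rows).
#' @param presence_eps Interaction-presence tolerance, REU.
#' @param change_eps Unchanged-pair tolerance for A/B and for one-body
#'   changes, REU.
#' @param strict_salt_bridge Exclude HIS from the salt-bridge basic set.
#' @return An object of class `diff_result`: list with `changes` (data frame
#'   sorted ascending by `delta_total`, columns `resi1`, `resi2`,
#'   `restype_ref1`, `restype_mut1`, `restype_ref2`, `restype_mut2`,
#'   `category`, `involves_mutation`, `types` (`;`-joined), one
#'   `delta_<term>` column per score term, `delta_total`), `onebody_changes`
#'   (data frame `residue`, `restype_ref`, `restype_mut`, `delta_total`),
#'   `mutations`, `terms`, `presence_eps`, `change_eps`.
#' @export
diff_tables <- function(ref, mut, mutations,
                        presence_eps = 1e-9, change_eps = 1e-6,
                        strict_salt_bridge = FALSE) {
  stopifnot(inherits(ref, "energy_table"), inherits(mut, "energy_table"))
  if (missing(mutations) || is.null(mutations)) {
    mutations <- data.frame(position = integer(), ref = character(),
                            mut = character(), stringsAsFactors = FALSE)
  }
  terms <- union(ref$terms, mut$terms)
  check_mutation_restypes(ref, mut, mutations)
  mut_pos <- mutations$position

  rr <- ref$records[!ref$records$is_onebody, , drop = FALSE]
  mr <- mut$records[!mut$records$is_onebody, , drop = FALSE]
  rkey <- pair_key(rr$resi1, rr$resi2)
  mkey <- pair_key(mr$resi1, mr$resi2)
  keys <- union(rkey, mkey)

  ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  ri <- match(keys, rkey); mi <- match(keys, mkey)

  tot_r <- ifelse(is.na(ri), 0, rr$total[ri])
  tot_m <- ifelse(is.na(mi), 0, mr$total[mi])
  in_ref <- !is.na(ri) & abs(tot_r) > presence_eps
  in_mut <- !is.na(mi) & abs(tot_m) > presence_eps
  delta <- tot_m - tot_r
  invmut <- (i %in% mut_pos) | (j %in% mut_pos)

  keep <- in_ref | in_mut
  category <- rep(NA_character_, length(keys))
  both <- in_ref & in_mut
  category[both & abs(delta) > change_eps & !invmut] <- "A"
  category[both & abs(delta) > change_eps & invmut] <- "B"
  category[in_ref & !in_mut & !invmut] <- "C"
  category[in_ref & !in_mut & invmut] <- "D"
  category[!in_ref & in_mut & !invmut] <- "E"
  category[!in_ref & in_mut & invmut] <- "F"
  keep <- keep & !is.na(category)

  idx <- which(keep)
  n <- length(idx)
  restype_of <- function(tab, side_idx, col) {
    out <- rep(NA_character_, n)
    ok <- !is.na(side_idx[idx])
    out[ok] <- tab[[col]][side_idx[idx][ok]]
    out
  }
  changes <- data.frame(
    resi1 = i[idx], resi2 = j[idx],
    restype_ref1 = restype_of(rr, ri, "restype1"),
    restype_ref2 = restype_of(rr, ri, "restype2"),
    restype_mut1 = restype_of(mr, mi, "restype1"),
    restype_mut2 = restype_of(mr, mi, "restype2"),
    category = category[idx],
    involves_mutation = invmut[idx],
    stringsAsFactors = FALSE
  )
  # A pair absent from one table still has residues there: fill the missing
  # side's residue types from that table's one-body records.
  fill_ob <- function(vals, t, res) {
    ob <- t$records[t$records$is_onebody, , drop = FALSE]
    miss <- is.na(vals)
    vals[miss] <- ob$restype1[match(res[miss], ob$resi1)]
    vals
  }
  changes$restype_ref1 <- fill_ob(changes$restype_ref1, ref, changes$resi1)
  changes$restype_ref2 <- fill_ob(changes$restype_ref2, ref, changes$resi2)
  changes$restype_mut1 <- fill_ob(changes$restype_mut1, mut, changes$resi1)
  changes$restype_mut2 <- fill_ob(changes$restype_mut2, mut, changes$resi2)

  # Per-term deltas (absent record or absent term = zero vector).
  side_term <- function(tab, side_idx, tm) {
    v <- numeric(n)
    if (tm %in% names(tab)) {
      ok <- !is.na(side_idx[idx])
      v[ok] <- tab[[tm]][side_idx[idx][ok]]
    }
    v
  }
  for (tm in terms) {
    changes[[paste0("delta_", tm)]] <-
      side_term(mr, mi, tm) - side_term(rr, ri, tm)
  }
  changes$delta_total <- delta[idx]

  # Physical types, evaluated per existing side (vectorized version of
  # classify_type(); the two must agree, which the tests assert).
  side_flags <- function(tab, side_idx, active) {
    use <- active & !is.na(side_idx[idx])
    row <- side_idx[idx]
    g <- function(tm) {
      v <- numeric(n)
      if (tm %in% names(tab)) v[use] <- tab[[tm]][row[use]]
      v
    }
    rt1 <- rt2 <- rep("", n)
    rt1[use] <- tab$restype1[row[use]]
    rt2[use] <- tab$restype2[row[use]]
    basic <- if (strict_salt_bridge) SALT_BASIC_STRICT else SALT_BASIC
    cbind(
      salt_bridge = use & ((rt1 %in% basic & rt2 %in% SALT_ACIDIC) |
                             (rt2 %in% basic & rt1 %in% SALT_ACIDIC)) &
        g("hbond_sc") < 0,
      disulfide = use & rt1 == "CYS" & rt2 == "CYS" & g("dslf_fa13") != 0,
      hb_sc_sc = use & g("hbond_sc") < 0,
      hb_bb_sc = use & g("hbond_bb_sc") < 0,
      hb_bb_sr = use & g("hbond_sr_bb") < 0,
      hb_bb_lr = use & g("hbond_lr_bb") < 0,
      all = use
    )
  }
  flags <- side_flags(rr, ri, in_ref[idx]) | side_flags(mr, mi, in_mut[idx])
  changes$types <- vapply(seq_len(n), function(k) {
    paste(INTERACTION_TYPES[flags[k, INTERACTION_TYPES]], collapse = ";")
  }, character(1))

  # Deterministic ordering: most stabilizing first, ties by pair key.
  ord <- order(changes$delta_total, changes$resi1, changes$resi2)
  changes <- changes[ord, , drop = FALSE]
  rownames(changes) <- NULL

  # One-body changes.
  rob <- ref$records[ref$records$is_onebody, , drop = FALSE]
  mob <- mut$records[mut$records$is_onebody, , drop = FALSE]
  obres <- union(rob$resi1, mob$resi1)
  oi <- match(obres, rob$resi1); oj <- match(obres, mob$resi1)
  dob <- ifelse(is.na(oj), 0, mob$total[oj]) -
    ifelse(is.na(oi), 0, rob$total[oi])
  okeep <- abs(dob) > change_eps
  onebody <- data.frame(
    residue = obres[okeep],
    restype_ref = ifelse(is.na(oi[okeep]), NA_character_,
                         rob$restype1[oi[okeep]]),
    restype_mut = ifelse(is.na(oj[okeep]), NA_character_,
                         mob$restype1[oj[okeep]]),
    delta_total = dob[okeep],
    stringsAsFactors = FALSE
  )
  onebody <- onebody[order(onebody$residue), , drop = FALSE]
  rownames(onebody) <- NULL

  structure(list(changes = changes, onebody_changes = onebody,
                 mutations = mutations, terms = terms,
                 presence_eps = presence_eps, change_eps = change_eps),
            class = "diff_result")
}

# The mutation list is the contract between the structure pipeline and the
# energy tables: where a table carries a one-body restype at a mutated
# position, it must agree with the list, else the renumberings diverged.
check_mutation_restypes <- function(ref, mut, mutations) {
  if (nrow(mutations) == 0L) return(invisible(TRUE))
  check_side <- function(t, col, label) {
    ob <- t$records[t$records$is_onebody, , drop = FALSE]
    hit <- match(mutations$position, ob$resi1)
    ok <- !is.na(hit)
    want <- aa_one_to_three(mutations[[col]][ok])
    got <- ob$restype1[hit[ok]]
    bad <- which(want != got)
    if (length(bad)) {
      p <- mutations$position[ok][bad[1]]
      stop(sprintf(paste0("renumbering mismatch: %s table has %s at position",
                          " %d but the mutation list expects %s"),
                   label, got[bad[1]], p, want[bad[1]]), call. = FALSE)
    }
  }
  check_side(ref, "ref", "reference")
  check_side(mut, "mut", "mutant")
  invisible(TRUE)
}

#' Sum of all pairwise energy changes in selected categories
#'
#' The total energy change: the sum of every pair delta, including the many
#' small ones, over the selected categories.
#'
#' @param d A `diff_result`.
#' @param categories Subset of `c("A","B","C","D","E","F")`.
#' @return Sum of `delta_total`, REU.
#' @export
total_energy_changes <- function(d, categories = INTERACTION_CATEGORIES) {
  stopifnot(inherits(d, "diff_result"), length(categories) > 0)
  sel <- d$changes$category %in% categories
  sum(d$changes$delta_total[sel])
}

#' Significant pairwise energy changes
#'
#' Thousands of small changes can mask the chemically important ones, so a
#' change only counts as significant when its total delta is larger than
#' `+threshold` or smaller than `-threshold` REU (strict inequalities; the
#' default threshold is 1.0 REU). Returns the sum over the significant
#' changes and the changes themselves, most stabilizing first.
#'
#' @param d A `diff_result`.
#' @param categories Subset of categories to include.
#' @param threshold Significance threshold in REU (non-negative).
#' @param types Optional: restrict to changes carrying one of these physical
#'   interaction types.
#' @return List with elements `sum` (REU) and `changes` (data frame sorted
#'   ascending by `delta_total`).
#' @export
significant_changes <- function(d, categories = INTERACTION_CATEGORIES,
                                threshold = 1.0, types = NULL) {
  stopifnot(inherits(d, "diff_result"), threshold >= 0)
  ch <- d$changes
  sel <- ch$category %in% categories &
    (ch$delta_total > threshold | ch$delta_total < -threshold)
  if (!is.null(types)) {
    sel <- sel & vapply(strsplit(ch$types, ";"),
                        function(ts) any(ts %in% types), logical(1))
  }
  ch <- ch[sel, , drop = FALSE]
  ch <- ch[order(ch$delta_total, ch$resi1, ch$resi2), , drop = FALSE]
  rownames(ch) <- NULL
  list(sum = sum(ch$delta_total), changes = ch)
}

#' Summary grid of significant changes by category and type
#'
#' For every interaction category (rows A-F) and physical type (columns),
#' the number of significant pair changes and their summed energy change.
#' A pair carrying several hydrogen-bond types is counted once per type
#' column it belongs to, but only once in the `all` column.
#'
#' @param d A `diff_result`.
#' @param threshold Significance threshold in REU.
#' @return An object of class `summary_grid`: list with `counts` and `sums`
#'   (6 x 7 matrices, rows A-F, columns the interaction types) and
#'   `threshold`.
#' @export
summary_table <- function(d, threshold = 1.0) {
  stopifnot(inherits(d, "diff_result"))
  sig <- significant_changes(d, threshold = threshold)$changes
  counts <- matrix(0L, nrow = 6, ncol = length(INTERACTION_TYPES),
                   dimnames = list(INTERACTION_CATEGORIES, INTERACTION_TYPES))
  sums <- matrix(0, nrow = 6, ncol = length(INTERACTION_TYPES),
                 dimnames = list(INTERACTION_CATEGORIES, INTERACTION_TYPES))
  if (nrow(sig)) {
    tlist <- strsplit(sig$types, ";")
    for (k in seq_len(nrow(sig))) {
      cc <- sig$category[k]
      for (tp in tlist[[k]]) {
        counts[cc, tp] <- counts[cc, tp] + 1L
        sums[cc, tp] <- sums[cc, tp] + sig$delta_total[k]
      }
    }
  }
  structure(list(counts = counts, sums = sums, threshold = threshold),
            class = "summary_grid")
}

#' @export
print.summary_grid <- function(x, ...) {
  cat(sprintf("significant energy changes (|delta| > %.2f REU)\n",
              x$threshold))
  cat("counts:\n"); print(x$counts)
  cat("summed REU:\n"); print(round(x$sums, 2))
  invisible(x)
}

#' @export
as.data.frame.summary_grid <- function(x, ...) {
  df <- expand.grid(category = INTERACTION_CATEGORIES,
                    type = INTERACTION_TYPES, stringsAsFactors = FALSE)
  df$count <- as.integer(x$counts[cbind(df$category, df$type)])
  df$sum_delta_total <- x$sums[cbind(df$category, df$type)]
  df
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("diff_result: %d changed pairs, %d one-body changes, %d mutations\n",
              nrow(x$changes), nrow(x$onebody_changes), nrow(x$mutations)))
  tab <- table(factor(x$changes$category, levels = INTERACTION_CATEGORIES))
  cat(" categories:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = " "), "\n")
  sig <- significant_changes(x)
  cat(sprintf(" significant (|delta| > 1 REU): %d pairs, sum %.2f REU\n",
              nrow(sig$changes), sig$sum))
  invisible(x)
}
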