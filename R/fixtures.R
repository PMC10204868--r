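# Synthetic, ground-truth-labelled inputs: toy structures and mock
# energy-breakdown tables. Every other module is testable against these
# without any external energy program or download.

MOCK_TERMS <- c("fa_atr", "fa_rep", "fa_sol", "fa_elec", "hbond_sr_bb",
                "hbond_lr_bb", "hbond_bb_sc", "hbond_sc", "dslf_fa13")

# Residue-type pools. "plain" residues trigger no physical type; the
# hydrogen-bond pool is polar but uncharged so a planted hbond_sc never
# fires the salt-bridge rule by accident.
PLAIN_POOL <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "TRP", "GLY",
                "PRO", "THR", "SER")
HB_POOL <- c("SER", "THR", "ASN", "GLN", "TYR")

TRUTH_TYPES <- c(plain = "all",
                 salt_bridge = "salt_bridge;hb_sc_sc;all",
                 disulfide = "disulfide;all",
                 hb_sc_sc = "hb_sc_sc;all",
                 hb_bb_sc = "hb_bb_sc;all",
                 hb_bb_sr = "hb_bb_sr;all",
                 hb_bb_lr = "hb_bb_lr;all")

#' Build a toy protein structure with ideal geometry
#'
#' Deterministic stand-in structures for tests and demonstrations: an ideal
#' alpha-helical trace (1.5 A rise, 100 degrees per residue), an extended
#' strand, or a compact "ball" that packs residues into a sphere along a
#' volumetric golden-angle spiral — every residue at a distinct distance
#' from the centre, atoms oriented radially — so burial order is known by
#' construction (the fixture for depth tests). Each residue gets backbone
#' atoms N, CA, C, O and a CB stub (except glycine).
#'
#' @param n_residues Number of residues (>= 1).
#' @param geometry `"helix"`, `"extended"` or `"ball"`.
#' @param sequence Optional one-letter sequence of length `n_residues`;
#'   drawn randomly from apolar/neutral types when omitted.
#' @param seed Seed for the random sequence draw (ignored when `sequence`
#'   is given).
#' @return List with `structure` (a `protein_structure`) and `pdb_text`
#'   (character vector of PDB lines; byte-identical for identical
#'   arguments).
#' @export
make_toy_structure <- function(n_residues, geometry = c("helix", "extended",
                                                        "ball"),
                               sequence = NULL, seed = 1) {
  stopifnot(n_residues >= 1)
  geometry <- match.arg(geometry)
  if (is.null(sequence)) {
    sequence <- with_seed(seed, paste(sample(aa_three_to_one(PLAIN_POOL),
                                             n_residues, replace = TRUE),
                                      collapse = ""))
  }
  if (nchar(sequence) != n_residues) {
    stop(sprintf("sequence length %d does not match n_residues = %d",
                 nchar(sequence), n_residues), call. = FALSE)
  }
  restypes <- aa_one_to_three(strsplit(sequence, "")[[1]])

  t <- seq_len(n_residues) - 1
  ca <- switch(geometry,
    helix = cbind(2.3 * cos(t * 100 * pi / 180),
                  2.3 * sin(t * 100 * pi / 180),
                  1.5 * t),
    extended = cbind(3.5 * t, 1.0 * (t %% 2), 0 * t),
    ball = ball_spiral(n_residues)
  )

  fixed_offsets <- rbind(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0),
                         C = c(1.2, 0.8, 0), O = c(1.8, 1.9, 0.3),
                         CB = c(0, -1.0, 1.2))
  radial_coef <- c(N = -1.5, CA = 0, C = 0.75, O = 1.5, CB = -0.75)
  elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

  lines <- character()
  eleno <- 0L
  for (i in seq_len(n_residues)) {
    names_i <- rownames(fixed_offsets)
    if (restypes[i] == "GLY") names_i <- setdiff(names_i, "CB")
    if (geometry == "ball") {
      nr <- sqrt(sum(ca[i, ]^2))
      u <- if (nr < 1e-9) c(0, 0, 1) else ca[i, ] / nr
    }
    for (nm in names_i) {
      eleno <- eleno + 1L
      p <- if (geometry == "ball") ca[i, ] + radial_coef[nm] * u
      else ca[i, ] + fixed_offsets[nm, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        eleno, nm, restypes[i], "A", i, p[1], p[2], p[3], 1.00, 0.00,
        elements[nm]))
    }
  }
  lines <- c(lines, "TER", "END")
  list(structure = clean_structure(lines,
                                   source_label = paste0("toy_", geometry)),
       pdb_text = lines)
}

# Concentric packing: residue positions along a volumetric golden-angle
# spiral filling a sphere (radius ~ i^(1/3), golden-angle directions), with
# a mean inter-residue spacing of 3.5 A. Residue 1 is the most buried;
# residue n the most peripheral; every residue sits at a distinct distance
# from the centre.
ball_spiral <- function(n, spacing = 3.5) {
  R <- spacing * (3 * n / (4 * pi))^(1 / 3)
  dirs <- fibonacci_sphere(n)
  radii <- R * ((seq_len(n) - 0.5) / n)^(1 / 3)
  dirs * radii
}

#' Define a synthetic breakdown-fixture plan
#'
#' A plan fixes everything the mock-table generator needs: protein size,
#' number of point mutations, how many residue pairs to plant in each
#' interaction category (plus unchanged distractor pairs), the mix of
#' physical interaction types among the planted changes, the fraction of
#' changes that are significant, and the seed. Planted significant changes
#' draw their magnitude from [1.2, 4.0] REU and insignificant ones from
#' [0.05, 0.9] REU, leaving the band around the 1.0 REU significance
#' threshold empty so that float rounding can never flip a label;
#' exact-boundary behaviour is exercised separately with hand-written
#' values.
#'
#' @param n_residues Protein length.
#' @param n_mutations Number of point mutations.
#' @param category_counts Named integer vector over `A`..`F`.
#' @param n_unchanged Pairs present in both tables with identical energies.
#' @param type_mix Named fractions over
#'   `c("plain","salt_bridge","disulfide","hb_sc_sc","hb_bb_sc","hb_bb_sr","hb_bb_lr")`.
#' @param p_significant Fraction of planted changes drawn from the
#'   significant magnitude band.
#' @param seed Integer seed; one generator stream per plan.
#' @return A `fixture_plan` object (validated list).
#' @export
fixture_plan <- function(n_residues = 120, n_mutations = 10,
                         category_counts = c(A = 40, B = 30, C = 25, D = 25,
                                             E = 25, F = 30),
                         n_unchanged = 25,
                         type_mix = c(plain = 0.55, salt_bridge = 0.10,
                                      disulfide = 0.05, hb_sc_sc = 0.10,
                                      hb_bb_sc = 0.10, hb_bb_sr = 0.05,
                                      hb_bb_lr = 0.05),
                         p_significant = 0.65, seed = 1) {
  stopifnot(n_residues >= 2, n_mutations >= 0, n_unchanged >= 0,
            p_significant >= 0, p_significant <= 1)
  category_counts <- category_counts[INTERACTION_CATEGORIES]
  names(category_counts) <- INTERACTION_CATEGORIES
  category_counts[is.na(category_counts)] <- 0L
  if (any(category_counts < 0)) {
    stop("infeasible plan: negative category count", call. = FALSE)
  }
  if (sum(category_counts[c("B", "D", "F")]) > 0 && n_mutations == 0) {
    stop("infeasible plan: categories B/D/F require at least one mutation",
         call. = FALSE)
  }
  if (n_mutations > n_residues) {
    stop("infeasible plan: more mutations than residues", call. = FALSE)
  }
  npairs <- sum(category_counts) + n_unchanged
  if (npairs > choose(n_residues, 2)) {
    stop("infeasible plan: more pairs requested than residue pairs exist",
         call. = FALSE)
  }
  n_free <- n_residues - n_mutations
  if (sum(category_counts[c("A", "C", "E")]) + n_unchanged >
      choose(n_free, 2)) {
    stop("infeasible plan: not enough unmutated residues for A/C/E pairs",
         call. = FALSE)
  }
  type_mix <- type_mix / sum(type_mix)
  structure(list(n_residues = as.integer(n_residues),
                 n_mutations = as.integer(n_mutations),
                 category_counts = category_counts,
                 n_unchanged = as.integer(n_unchanged),
                 type_mix = type_mix, p_significant = p_significant,
                 seed = as.integer(seed)),
            class = "fixture_plan")
}

#' Generate a paired mock breakdown-table fixture with planted ground truth
#'
#' Emits two parseable breakdown files (reference and mutant) whose pair
#' presence/absence, mutation flags, per-term values and totals realize
#' exactly the plan's category counts and type mix. Every total is
#' constructed as the sum of its planted score terms, and the grand total of
#' each file is accumulated independently while the rows are written, so the
#' parser can be checked against bookkeeping that never went through it.
#'
#' @param plan A [fixture_plan()].
#' @return List with `ref_lines` and `mut_lines` (breakdown file text),
#'   `truth` (list: `pairs` data frame with `resi1`, `resi2`, `category`,
#'   `types`, `delta_total`, `significant`; `onebody` data frame;
#'   `mutations` data frame as from [detect_mutations()]; `sequence_ref`
#'   and `sequence_mut`; independently accumulated `ref_grand_total` and
#'   `mut_grand_total`), and the `plan`.
#' @export
make_mock_breakdown <- function(plan) {
  stopifnot(inherits(plan, "fixture_plan"))
  with_seed(plan$seed, generate_mock(plan))
}

generate_mock <- function(plan) {
  n <- plan$n_residues
  mut_pos <- sort(sample.int(n, plan$n_mutations))
  is_mut <- seq_len(n) %in% mut_pos

  restype_ref <- sample(PLAIN_POOL, n, replace = TRUE)
  restype_mut <- restype_ref
  for (p in mut_pos) {
    restype_mut[p] <- sample(setdiff(PLAIN_POOL, restype_ref[p]), 1)
  }
  typed_used <- rep(FALSE, n)
  used_keys <- character()

  pick <- function(pool) if (length(pool) == 1) pool else sample(pool, 1)

  draw_pair <- function(need_mut, fresh) {
    for (try in 1:5000) {
      if (need_mut) {
        e1 <- pick(mut_pos)
        e2 <- pick(setdiff(seq_len(n), if (fresh) c(e1, which(is_mut),
                                                    which(typed_used))
                           else e1))
      } else {
        cand <- which(!is_mut & (!fresh | !typed_used))
        if (length(cand) < 2) return(NULL)
        e <- sample(cand, 2)
        e1 <- e[1]; e2 <- e[2]
      }
      if (fresh && (typed_used[e1] || typed_used[e2])) next
      k <- pair_key(e1, e2)
      if (!(k %in% used_keys)) {
        used_keys <<- c(used_keys, k)
        return(c(min(e1, e2), max(e1, e2)))
      }
    }
    stop("infeasible plan: could not place a residue pair after 5000 tries",
         call. = FALSE)
  }

  # --- plan every pair -----------------------------------------------------
  cats <- rep(INTERACTION_CATEGORIES, plan$category_counts)
  pair_rows <- list()
  for (cat in cats) {
    need_mut <- cat %in% c("B", "D", "F")
    type <- sample(names(plan$type_mix), 1, prob = plan$type_mix)
    fresh_ok <- TRUE
    if (type != "plain") {
      # Typed pairs need endpoints whose residue types they can dictate:
      # residues not already claimed by another typed pair (and for B/D/F a
      # fresh mutated endpoint). When none is available the pair falls back
      # to a plain interaction.
      if (need_mut) {
        fresh_ok <- any(is_mut & !typed_used) && any(!is_mut & !typed_used)
      } else {
        fresh_ok <- sum(!is_mut & !typed_used) >= 2
      }
      if (!fresh_ok) type <- "plain"
    }
    pr <- draw_pair(need_mut, fresh = type != "plain")
    if (is.null(pr)) stop("infeasible plan: ran out of residue pairs",
                          call. = FALSE)
    i <- pr[1]; j <- pr[2]

    if (type != "plain") typed_used[c(i, j)] <- TRUE
    pair_rows[[length(pair_rows) + 1]] <-
      list(i = i, j = j, category = cat, type = type)
  }
  for (k in seq_len(plan$n_unchanged)) {
    pr <- draw_pair(need_mut = FALSE, fresh = FALSE)
    if (is.null(pr)) stop("infeasible plan: ran out of residue pairs",
                          call. = FALSE)
    pair_rows[[length(pair_rows) + 1]] <-
      list(i = pr[1], j = pr[2], category = "unchanged", type = "plain")
  }

  # --- residue-type overrides for typed pairs ------------------------------
  for (pr in pair_rows) {
    if (pr$type == "plain") next
    i <- pr$i; j <- pr$j; cat <- pr$category
    roles <- switch(pr$type,
      salt_bridge = {
        basic <- pick(SALT_BASIC); acid <- pick(SALT_ACIDIC)
        r <- c(basic, acid)
        if (stats::runif(1) < 0.5) r else rev(r)
      },
      disulfide = c("CYS", "CYS"),
      hb_sc_sc = c(pick(HB_POOL), pick(HB_POOL)),
      NULL  # backbone hbond types carry no residue-type constraint
    )
    if (is.null(roles)) next
    role_of <- stats::setNames(roles, c(i, j))
    same_role_pool <- function(code) {
      pool <- if (code %in% SALT_BASIC) SALT_BASIC
      else if (code %in% SALT_ACIDIC) SALT_ACIDIC
      else if (code == "CYS") "CYS" else HB_POOL
      setdiff(pool, code)
    }
    for (e in c(i, j)) {
      code <- role_of[[as.character(e)]]
      if (!is_mut[e]) {
        restype_ref[e] <- restype_mut[e] <- code
      } else {
        # The mutated endpoint must satisfy the role on the side(s) where
        # the interaction exists, and still differ between ref and mut.
        if (cat %in% c("A")) {
          restype_ref[e] <- restype_mut[e] <- code  # A never hits mutations
        } else if (cat == "B") {
          alt <- same_role_pool(code)
          if (length(alt) == 0) {
            # CYS has no same-role partner: keep ref CYS, mutate away; the
            # disulfide is planted on the reference side only.
            restype_ref[e] <- code
            restype_mut[e] <- pick(setdiff(PLAIN_POOL, code))
          } else {
            restype_ref[e] <- code
            restype_mut[e] <- pick(alt)
          }
        } else if (cat == "D") {
          restype_ref[e] <- code
          restype_mut[e] <- pick(setdiff(PLAIN_POOL, code))
        } else if (cat == "F") {
          restype_mut[e] <- code
          restype_ref[e] <- pick(setdiff(PLAIN_POOL, code))
        }
      }
    }
  }

  # --- energies ------------------------------------------------------------
  draw_mag <- function(significant) {
    if (significant) stats::runif(1, 1.2, 4.0) else stats::runif(1, 0.05, 0.9)
  }

  ref_rows <- character(); mut_rows <- character()
  ref_sum <- 0; mut_sum <- 0
  truth_pairs <- list()

  emit <- function(side, i, restype1, j, restype2, terms) {
    total <- sum(terms)
    vals <- paste(sprintf("%.4f", c(terms, total)), collapse = " ")
    if (is.na(j)) {
      row <- sprintf("SCORE: 1 %d %dA %s -- -- onebody %s fixture",
                     i, i, restype1, vals)
    } else {
      row <- sprintf("SCORE: 1 %d %dA %s %d %dA %s %s fixture",
                     i, i, restype1, j, j, restype2, vals)
    }
    if (side == "ref") {
      ref_rows <<- c(ref_rows, row); ref_sum <<- ref_sum + total
    } else {
      mut_rows <<- c(mut_rows, row); mut_sum <<- mut_sum + total
    }
    total
  }

  # One-body rows: identical between the two files except at mutations.
  onebody_truth <- list()
  for (r in seq_len(n)) {
    tr <- round(make_mock_terms(stats::runif(1, -3, 1), "plain"), 4)
    t_ref <- emit("ref", r, restype_ref[r], NA, NA, tr)
    if (is_mut[r]) {
      tm <- round(make_mock_terms(stats::runif(1, -3, 1), "plain"), 4)
      t_mut <- emit("mut", r, restype_mut[r], NA, NA, tm)
      onebody_truth[[length(onebody_truth) + 1]] <-
        data.frame(residue = r, delta_total = t_mut - t_ref)
    } else {
      emit("mut", r, restype_mut[r], NA, NA, tr)
    }
  }

  maybe_rev <- function(side, i, j, terms) {
    # Occasionally list the pair in (high, low) order to exercise the
    # parser's normalization.
    r1 <- if (side == "ref") restype_ref else restype_mut
    if (stats::runif(1) < 0.3) {
      emit(side, j, r1[j], i, r1[i], terms)
    } else {
      emit(side, i, r1[i], j, r1[j], terms)
    }
  }

  for (pr in pair_rows) {
    i <- pr$i; j <- pr$j; cat <- pr$category; type <- pr$type
    if (cat == "unchanged") {
      tot <- 0
      while (abs(tot) < 0.01) tot <- stats::runif(1, -2, 2)
      terms <- round(make_mock_terms(tot, "plain"), 4)
      maybe_rev("ref", i, j, terms)
      maybe_rev("mut", i, j, terms)
      next
    }
    sig <- stats::runif(1) < plan$p_significant
    mag <- draw_mag(sig)
    typed <- type != "plain"
    # B-category disulfides live on the reference side only (the mutated
    # endpoint cannot stay CYS), so the mutant side reverts to plain terms.
    type_ref <- type; type_mut <- type
    if (type == "disulfide" && cat == "B") type_mut <- "plain"

    if (cat %in% c("A", "B")) {
      s <- if (stats::runif(1) < 0.5) -1 else 1
      delta <- s * mag
      base <- stats::runif(1, 0.2, 2.0)
      if (typed) {
        if (delta <= 0) { tot_ref <- -base; tot_mut <- tot_ref + delta }
        else { tot_mut <- -base; tot_ref <- tot_mut - delta }
      } else {
        # Keep both totals clear of zero so rounding can never make a
        # present pair look non-interacting.
        repeat {
          tot_ref <- stats::runif(1, -2, 2)
          tot_mut <- tot_ref + delta
          if (abs(tot_ref) >= 0.01 && abs(tot_mut) >= 0.01) break
        }
      }
      terms_ref <- round(make_mock_terms(tot_ref, type_ref), 4)
      terms_mut <- round(make_mock_terms(tot_mut, type_mut), 4)
      t1 <- maybe_rev("ref", i, j, terms_ref)
      t2 <- maybe_rev("mut", i, j, terms_mut)
      actual_delta <- t2 - t1
    } else if (cat %in% c("C", "D")) {
      tot_ref <- if (typed) -mag else (if (stats::runif(1) < 0.5) -mag else mag)
      terms_ref <- round(make_mock_terms(tot_ref, type_ref), 4)
      t1 <- maybe_rev("ref", i, j, terms_ref)
      actual_delta <- -t1
    } else {  # E, F
      tot_mut <- if (typed) -mag else (if (stats::runif(1) < 0.5) -mag else mag)
      terms_mut <- round(make_mock_terms(tot_mut, type_mut), 4)
      t2 <- maybe_rev("mut", i, j, terms_mut)
      actual_delta <- t2
    }
    side_types <- TRUTH_TYPES[[type]]
    truth_pairs[[length(truth_pairs) + 1]] <- data.frame(
      resi1 = i, resi2 = j, category = cat, types = side_types,
      delta_total = actual_delta, significant = sig,
      stringsAsFactors = FALSE)
  }

  header <- paste("SCORE: pose_id resi1 pdbid1 restype1 resi2 pdbid2",
                  "restype2", paste(MOCK_TERMS, collapse = " "),
                  "total description")
  truth_pairs <- if (length(truth_pairs)) do.call(rbind, truth_pairs)
  else data.frame(resi1 = integer(), resi2 = integer(),
                  category = character(), types = character(),
                  delta_total = numeric(), significant = logical())
  onebody_truth <- if (length(onebody_truth)) do.call(rbind, onebody_truth)
  else data.frame(residue = integer(), delta_total = numeric())

  mutations <- data.frame(position = mut_pos,
                          ref = aa_three_to_one(restype_ref[mut_pos]),
                          mut = aa_three_to_one(restype_mut[mut_pos]),
                          stringsAsFactors = FALSE)
  list(ref_lines = c(header, ref_rows),
       mut_lines = c(header, mut_rows),
       truth = list(pairs = truth_pairs, onebody = onebody_truth,
                    mutations = mutations,
                    sequence_ref = paste(aa_three_to_one(restype_ref),
                                         collapse = ""),
                    sequence_mut = paste(aa_three_to_one(restype_mut),
                                         collapse = ""),
                    ref_grand_total = ref_sum, mut_grand_total = mut_sum),
       plan = plan)
}

# Construct a score-term vector summing to `total`, with the signature term
# of `type` carrying the bulk (and the sign the type's classification rule
# requires). Minor terms are kept tiny for typed records so the signature
# term can never lose its required sign.
make_mock_terms <- function(total, type) {
  terms <- stats::setNames(numeric(length(MOCK_TERMS)), MOCK_TERMS)
  if (type == "plain") {
    terms["fa_sol"] <- round(stats::runif(1, -0.1, 0.1), 4)
    terms["fa_elec"] <- round(stats::runif(1, -0.1, 0.1), 4)
    terms["fa_rep"] <- round(stats::runif(1, 0, 0.1), 4)
    resid <- total - sum(terms)
    if (resid <= 0) terms["fa_atr"] <- resid
    else terms["fa_rep"] <- terms["fa_rep"] + resid
  } else {
    terms["fa_sol"] <- round(stats::runif(1, -0.01, 0.01), 4)
    terms["fa_rep"] <- round(stats::runif(1, 0, 0.01), 4)
    resid <- total - sum(terms)  # total <= -0.05 keeps resid < 0
    sig_term <- switch(type,
      salt_bridge = "hbond_sc", hb_sc_sc = "hbond_sc",
      hb_bb_sc = "hbond_bb_sc", hb_bb_sr = "hbond_sr_bb",
      hb_bb_lr = "hbond_lr_bb", disulfide = "dslf_fa13")
    terms[sig_term] <- resid
  }
  terms
}

#' Write a complete fixture set to disk
#'
#' Materializes a plan as the four input files the command-line workflow
#' consumes — reference/mutant toy PDBs (same geometry, sequences differing
#' at the planted mutations) and reference/mutant breakdown files — plus a
#' `truth.json` with the planted labels.
#'
#' @param plan A [fixture_plan()].
#' @param dir Output directory (created if missing).
#' @param geometry Toy-structure geometry (see [make_toy_structure()]).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_set <- function(plan, dir, geometry = "ball") {
  mock <- make_mock_breakdown(plan)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- make_toy_structure(plan$n_residues, geometry,
                            sequence = mock$truth$sequence_ref)
  mut <- make_toy_structure(plan$n_residues, geometry,
                            sequence = mock$truth$sequence_mut)
  paths <- c(ref_pdb = file.path(dir, "ref.pdb"),
             mut_pdb = file.path(dir, "mut.pdb"),
             ref_eb = file.path(dir, "ref_eb.out"),
             mut_eb = file.path(dir, "mut_eb.out"),
             truth = file.path(dir, "truth.json"))
  writeLines(ref$pdb_text, paths[["ref_pdb"]])
  writeLines(mut$pdb_text, paths[["mut_pdb"]])
  writeLines(mock$ref_lines, paths[["ref_eb"]])
  writeLines(mock$mut_lines, paths[["mut_eb"]])
  jsonlite::write_json(mock$truth, paths[["truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
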