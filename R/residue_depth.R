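# Element van der Waals radii (Angstrom) used for surface construction.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  unk <- is.na(r)
  if (any(unk)) {
    warning("unknown element(s) ", paste(unique(element[unk]), collapse = ", "),
            sprintf(": using default vdW radius %.2f A", VDW_DEFAULT),
            call. = FALSE)
    r[unk] <- VDW_DEFAULT
  }
  unname(r)
}

# Deterministic quasi-uniform points on the unit sphere (spherical spiral /
# golden-angle lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# A canonical orthonormal frame derived from a set of atom coordinates
# (principal axes, signs fixed by third moments, right-handed). Sampling
# directions are expressed per atom in the frame of its local neighborhood,
# so the dot surface — and therefore every depth — moves rigidly with the
# structure instead of depending on its orientation in the laboratory
# frame, while atoms far away have no influence. Exactly symmetric point
# sets (degenerate principal axes or vanishing third moments) have no
# canonical frame; for those the frame falls back to the identity and
# orientation invariance is only approximate.
canonical_frame <- function(coords) {
  x <- sweep(coords, 2, colMeans(coords))
  cv <- crossprod(x) / max(1, nrow(x))
  if (!all(is.finite(cv)) || sum(abs(cv)) < 1e-12) return(diag(3))
  v <- eigen(cv, symmetric = TRUE)$vectors
  for (k in 1:2) {
    m3 <- sum((x %*% v[, k])^3)
    if (m3 < 0) v[, k] <- -v[, k]
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  v
}

#' Build a dot-surface approximation of the molecular surface
#'
#' Constructs a deterministic solvent-accessible dot surface: each atom is
#' sampled with a fixed spherical-spiral lattice of `samples_per_atom` points
#' at radius (vdW + probe), and points buried inside any other atom's
#' expanded sphere are discarded. The sampling directions are expressed in a
#' canonical frame derived from the structure's principal axes, so the cloud
#' (and every depth computed from it) moves rigidly with the structure and
#' does not depend on its orientation in the input file. The solvent-accessible surface lies about
#' one probe radius outside the solvent-excluded surface, so depths measured
#' against it carry a systematic offset of roughly `probe_radius`; rankings
#' and comparisons between structures are unaffected.
#'
#' @param s A `protein_structure` with at least one atom.
#' @param probe_radius Probe sphere radius in Angstrom (default 1.5).
#' @param samples_per_atom Sphere sample count per atom (default 960).
#' @return An object of class `surface_cloud`: list with `points` (matrix
#'   n x 3, Angstrom), `probe_radius`, `samples_per_atom`.
#' @export
build_surface <- function(s, probe_radius = 1.5, samples_per_atom = 960) {
  stopifnot(inherits(s, "protein_structure"), probe_radius > 0,
            samples_per_atom >= 1)
  a <- s$atoms
  if (nrow(a) == 0L) stop("structure has no atoms", call. = FALSE)
  centers <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$element) + probe_radius
  unit <- fibonacci_sphere(samples_per_atom)
  frame_cutoff2 <- 8.0^2

  n <- nrow(centers)
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(centers, 2, centers[i, ], "-")^2)
    frame <- canonical_frame(centers[d2 <= frame_cutoff2, , drop = FALSE])
    p <- sweep((unit %*% t(frame)) * radii[i], 2, centers[i, ], "+")
    # Only atoms whose expanded spheres can reach atom i's sample sphere
    # need checking; points exactly on a neighboring sphere are kept
    # (buried means strictly inside, with a small boundary tolerance).
    nb <- which(d2 < (radii[i] + radii)^2 & seq_len(n) != i)
    keep <- rep(TRUE, nrow(p))
    for (j in nb) {
      keep <- keep &
        (rowSums(sweep(p, 2, centers[j, ], "-")^2) >= radii[j]^2 - 1e-9)
      if (!any(keep)) break
    }
    pts[[i]] <- p[keep, , drop = FALSE]
  }
  points <- do.call(rbind, pts)
  structure(list(points = points, probe_radius = probe_radius,
                 samples_per_atom = samples_per_atom),
            class = "surface_cloud")
}

#' Per-residue depth below the molecular surface
#'
#' The depth of a residue is the mean, over its heavy atoms, of the distance
#' from the atom center to the nearest surface point. Hydrogens are excluded
#' from the aggregation for robustness to protonation differences. Low
#' values indicate surface exposure; high values indicate burial in the
#' protein core.
#'
#' @param s A `protein_structure`.
#' @param cloud A `surface_cloud` built from `s` with [build_surface()];
#'   built on the fly when omitted.
#' @param probe_radius,samples_per_atom Passed to [build_surface()] when
#'   `cloud` is missing.
#' @return Data frame with columns `residue` (renumbered id), `restype3`,
#'   `depth` (Angstrom).
#' @export
residue_depth <- function(s, cloud = NULL, probe_radius = 1.5,
                          samples_per_atom = 960) {
  stopifnot(inherits(s, "protein_structure"))
  if (is.null(cloud)) {
    cloud <- build_surface(s, probe_radius, samples_per_atom)
  }
  stopifnot(inherits(cloud, "surface_cloud"))
  a <- s$atoms[s$atoms$element != "H", , drop = FALSE]
  px <- cloud$points[, 1]; py <- cloud$points[, 2]; pz <- cloud$points[, 3]
  atom_depth <- vapply(seq_len(nrow(a)), function(k) {
    sqrt(min((px - a$x[k])^2 + (py - a$y[k])^2 + (pz - a$z[k])^2))
  }, numeric(1))
  agg <- tapply(atom_depth, a$renum_id, mean)
  residue <- as.integer(names(agg))
  data.frame(residue = residue,
             restype3 = s$residues$restype3[match(residue,
                                                  s$residues$renum_id)],
             depth = as.numeric(agg),
             stringsAsFactors = FALSE)[order(residue), ]
}

#' Join residue depths with net interaction energies
#'
#' Combines per-residue depth and net energy (see [net_residue_energy()])
#' for the reference and mutant into one table, the data behind a
#' net-energy-versus-depth scatter plot. Residues present on only one side
#' are flagged in the `status` column rather than dropped.
#'
#' @param depths_ref,depths_mut Data frames from [residue_depth()].
#' @param table_ref,table_mut `energy_table` objects under the same
#'   renumbering as the depth tables.
#' @param half_pair Pair-energy convention for net energies (see
#'   [net_residue_energy()]).
#' @return Data frame with columns `residue`, `restype_ref`, `restype_mut`,
#'   `depth_ref`, `depth_mut`, `net_ref`, `net_mut`, `delta_net`, `status`
#'   (`"both"`, `"ref_only"` or `"mut_only"`).
#' @export
depth_energy_join <- function(depths_ref, depths_mut, table_ref, table_mut,
                              half_pair = FALSE) {
  stopifnot(inherits(table_ref, "energy_table"),
            inherits(table_mut, "energy_table"))
  nets_ref <- net_residue_energies(table_ref, half_pair)
  nets_mut <- net_residue_energies(table_mut, half_pair)
  check_depth_restypes(depths_ref, table_ref, "reference")
  check_depth_restypes(depths_mut, table_mut, "mutant")

  res <- sort(union(depths_ref$residue, depths_mut$residue))
  ir <- match(res, depths_ref$residue)
  im <- match(res, depths_mut$residue)
  out <- data.frame(
    residue = res,
    restype_ref = ifelse(is.na(ir), NA_character_, depths_ref$restype3[ir]),
    restype_mut = ifelse(is.na(im), NA_character_, depths_mut$restype3[im]),
    depth_ref = ifelse(is.na(ir), NA_real_, depths_ref$depth[ir]),
    depth_mut = ifelse(is.na(im), NA_real_, depths_mut$depth[im]),
    net_ref = as.numeric(nets_ref[as.character(res)]),
    net_mut = as.numeric(nets_mut[as.character(res)]),
    stringsAsFactors = FALSE
  )
  out$delta_net <- out$net_mut - out$net_ref
  out$status <- ifelse(!is.na(ir) & !is.na(im), "both",
                       ifelse(!is.na(ir), "ref_only", "mut_only"))
  out
}

check_depth_restypes <- function(depths, t, label) {
  ob <- t$records[t$records$is_onebody, , drop = FALSE]
  hit <- match(depths$residue, ob$resi1)
  ok <- !is.na(hit)
  bad <- which(depths$restype3[ok] != ob$restype1[hit[ok]])
  if (length(bad)) {
    r <- depths$residue[ok][bad[1]]
    stop(sprintf(paste0("renumbering mismatch: %s structure has %s at",
                        " position %d but the energy table has %s"),
                 label, depths$restype3[ok][bad[1]], r,
                 ob$restype1[hit[ok]][bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat(sprintf("surface_cloud: %d points (probe %.2f A, %d samples/atom)\n",
              nrow(x$points), x$probe_radius, x$samples_per_atom))
  invisible(x)
}
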