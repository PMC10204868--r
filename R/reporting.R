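#' Build the sparse energy-difference matrix
#'
#' Collects every pair change whose total delta exceeds the threshold in
#' magnitude into a sparse symmetric matrix keyed by residue pair, the data
#' behind the energy-difference heatmap. Masked (sub-threshold) entries are
#' absent, not zero.
#'
#' @param d A `diff_result`.
#' @param n Residue count (matrix dimension); every pair key must be `<= n`.
#' @param threshold Mask level in REU (strict inequality, as for
#'   [significant_changes()]).
#' @return An object of class `diff_matrix`: list with `n`, `threshold` and
#'   `entries` (data frame `i`, `j`, `delta` with `i < j`).
#' @export
build_matrix <- function(d, n, threshold = 1.0) {
  stopifnot(inherits(d, "diff_result"), n >= 1)
  ch <- significant_changes(d, threshold = threshold)$changes
  if (nrow(d$changes) && any(d$changes$resi1 > n | d$changes$resi2 > n)) {
    bad <- d$changes[d$changes$resi1 > n | d$changes$resi2 > n, ][1, ]
    stop(sprintf("pair (%d, %d) out of range for n = %d residues",
                 bad$resi1, bad$resi2, n), call. = FALSE)
  }
  entries <- data.frame(i = ch$resi1, j = ch$resi2, delta = ch$delta_total)
  entries <- entries[order(entries$i, entries$j), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(n = as.integer(n), threshold = threshold, entries = entries),
            class = "diff_matrix")
}

#' Query one cell of a difference matrix
#'
#' Symmetric lookup: `matrix_entry(m, j, i)` equals `matrix_entry(m, i, j)`.
#'
#' @param m A `diff_matrix`.
#' @param i,j Residue ids.
#' @return The entry's delta in REU, or `NA` if the pair is masked/absent.
#' @export
matrix_entry <- function(m, i, j) {
  stopifnot(inherits(m, "diff_matrix"))
  lo <- min(i, j); hi <- max(i, j)
  hit <- which(m$entries$i == lo & m$entries$j == hi)
  if (length(hit)) m$entries$delta[hit[1]] else NA_real_
}

#' @export
as.matrix.diff_matrix <- function(x, ...) {
  out <- matrix(NA_real_, x$n, x$n)
  if (nrow(x$entries)) {
    out[cbind(x$entries$i, x$entries$j)] <- x$entries$delta
    out[cbind(x$entries$j, x$entries$i)] <- x$entries$delta
  }
  out
}

#' Write a difference matrix as long-form CSV
#'
#' Long-form sparse export (`i`, `j`, `delta`) rather than a dense grid:
#' protein-size matrices are mostly empty. [read_matrix_csv()] reconstructs
#' the matrix exactly. Use `as.matrix()` for a dense export of small
#' matrices.
#'
#' @param m A `diff_matrix`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "diff_matrix"))
  out <- data.frame(i = m$entries$i, j = m$entries$j,
                    delta = format_full(m$entries$delta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("i,j,delta", con)
  if (nrow(out)) writeLines(paste(out$i, out$j, out$delta, sep = ","), con)
  invisible(path)
}

#' Re-read a long-form matrix CSV
#'
#' @param path CSV written by [write_matrix_csv()].
#' @param n Residue count of the matrix.
#' @param threshold Mask level recorded on the reconstructed matrix.
#' @return A `diff_matrix`.
#' @export
read_matrix_csv <- function(path, n, threshold = 1.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("i", "j", "delta") %in% names(df)))
  entries <- data.frame(i = as.integer(df$i), j = as.integer(df$j),
                        delta = as.numeric(df$delta))
  entries <- entries[order(entries$i, entries$j), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(n = as.integer(n), threshold = threshold, entries = entries),
            class = "diff_matrix")
}

#' Score-term breakdown of one pair change
#'
#' The per-term deltas of a changed pair, zero terms removed, in header
#' order — the data behind the per-interaction score-term bar chart.
#'
#' @param d A `diff_result`.
#' @param i,j Residue ids of a changed pair (order irrelevant).
#' @param zero_eps Terms with `|delta| <= zero_eps` are dropped.
#' @return Data frame with columns `term` and `delta` (REU).
#' @export
per_term_breakdown <- function(d, i, j, zero_eps = 1e-9) {
  stopifnot(inherits(d, "diff_result"))
  lo <- min(i, j); hi <- max(i, j)
  hit <- which(d$changes$resi1 == lo & d$changes$resi2 == hi)
  if (!length(hit)) {
    stop(sprintf("unknown pair (%d, %d): not among the changed pairs", lo, hi),
         call. = FALSE)
  }
  deltas <- vapply(d$terms, function(tm) d$changes[[paste0("delta_", tm)]][hit[1]],
                   numeric(1))
  keep <- abs(deltas) > zero_eps
  if (!any(keep)) {
    warning(sprintf("pair (%d, %d) has no non-zero term deltas", lo, hi),
            call. = FALSE)
  }
  data.frame(term = d$terms[keep], delta = unname(deltas[keep]),
             stringsAsFactors = FALSE)
}

#' Write the consolidated CSV report set for one run
#'
#' Writes, under `out_dir`: `interactions.csv` (every changed pair with
#' category, types and per-term deltas), `onebody_changes.csv`,
#' `summary_grid.csv` (category-by-type counts and sums of significant
#' changes), `matrix_long.csv` (the sparse difference matrix at the report
#' threshold), optionally `depth.csv` (from [depth_energy_join()]), and a
#' JSON `manifest.json` recording inputs, parameters, package version and a
#' timestamp. Data files contain no timestamps, so repeated runs on the same
#' inputs are byte-identical; only the manifest differs.
#'
#' @param d A `diff_result`.
#' @param depths Optional data frame from [depth_energy_join()].
#' @param out_dir Output directory (created if missing).
#' @param threshold Significance threshold used for the grid and matrix.
#' @param n Residue count for the matrix (default: largest pair id seen).
#' @param config Named list echoed verbatim into the manifest.
#' @return Named character vector of written file paths, invisibly.
#' @export
full_report <- function(d, depths = NULL, out_dir, threshold = 1.0,
                        n = NULL, config = list()) {
  stopifnot(inherits(d, "diff_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory '", out_dir, "'",
                  call. = FALSE)
  }
  if (is.null(n)) {
    ids <- c(d$changes$resi1, d$changes$resi2, d$onebody_changes$residue,
             if (!is.null(depths)) depths$residue)
    n <- if (length(ids)) max(ids) else 1L
  }
  paths <- c(
    interactions = file.path(out_dir, "interactions.csv"),
    onebody = file.path(out_dir, "onebody_changes.csv"),
    summary = file.path(out_dir, "summary_grid.csv"),
    matrix = file.path(out_dir, "matrix_long.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_csv_plain(d$changes, paths[["interactions"]])
  write_csv_plain(d$onebody_changes, paths[["onebody"]])
  write_csv_plain(as.data.frame(summary_table(d, threshold)),
                  paths[["summary"]])
  write_matrix_csv(build_matrix(d, n = n, threshold = threshold),
                   paths[["matrix"]])
  if (!is.null(depths)) {
    paths[["depth"]] <- file.path(out_dir, "depth.csv")
    write_csv_plain(depths, paths[["depth"]])
  }
  manifest <- list(
    tool = "ebdiff",
    version = as.character(utils::packageVersion("ebdiff")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = c(list(threshold = threshold, n = n,
                        presence_eps = d$presence_eps,
                        change_eps = d$change_eps), config),
    counts = list(changed_pairs = nrow(d$changes),
                  onebody_changes = nrow(d$onebody_changes),
                  mutations = nrow(d$mutations),
                  significant = nrow(significant_changes(
                    d, threshold = threshold)$changes))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# Deterministic CSV writer: full-precision numerics, no row names, no
# timestamps, stable column order.
write_csv_plain <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
      out[[cn]] <- format_full(out[[cn]])
    }
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Scatter plot of net residue energy versus depth
#'
#' @param x Data frame from [depth_energy_join()].
#' @param which `"ref"`, `"mut"` or `"both"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_depth_energy <- function(x, which = c("both", "ref", "mut"), ...) {
  which <- match.arg(which)
  xr <- range(c(x$depth_ref, x$depth_mut), na.rm = TRUE)
  yr <- range(c(x$net_ref, x$net_mut), na.rm = TRUE)
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "residue depth (A)",
                 ylab = "net interaction energy (REU)", ...)
  if (which %in% c("both", "ref")) {
    graphics::points(x$depth_ref, x$net_ref, pch = 1, col = "grey40")
  }
  if (which %in% c("both", "mut")) {
    graphics::points(x$depth_mut, x$net_mut, pch = 16, col = "firebrick")
  }
  if (which == "both") {
    graphics::legend("topright", legend = c("reference", "mutant"),
                     pch = c(1, 16), col = c("grey40", "firebrick"),
                     bty = "n")
  }
  invisible(x)
}

#' Heatmap of a difference matrix
#'
#' Dense rendering of the sparse matrix; stabilizing changes (negative REU)
#' plot blue, destabilizing red.
#'
#' @param x A `diff_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_diff_matrix <- function(x, ...) {
  stopifnot(inherits(x, "diff_matrix"))
  m <- as.matrix(x)
  lim <- max(abs(m), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(seq_len(x$n), seq_len(x$n), m, zlim = c(-lim, lim),
                  col = pal, xlab = "residue", ylab = "residue", ...)
  invisible(x)
}

#' @export
print.diff_matrix <- function(x, ...) {
  cat(sprintf("diff_matrix: %d x %d, %d entries above |%.2f| REU\n",
              x$n, x$n, nrow(x$entries), x$threshold))
  invisible(x)
}
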