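#' Parse a per-residue energy-breakdown score file
#'
#' Reads the whitespace-delimited score-line dialect written by per-residue
#' energy-breakdown calculations: every line starts with a `SCORE:` tag, the
#' first such line is a header naming the columns, and each following line
#' holds either a one-body record (single-residue internal energy; the
#' partner fields carry a placeholder token) or a two-body record (the
#' interaction energy of one residue pair), decomposed into named score terms
#' plus a `total` column in Rosetta Energy Units (REU).
#'
#' Score-term columns are not hard-coded: the set of terms is taken verbatim
#' from the file header, so tables produced under different scoring functions
#' load unchanged. Two-body records are normalized so that `resi1 < resi2`.
#' Totals are stored exactly as read, never recomputed. Rows whose total is
#' exactly zero are retained; whether a pair counts as "interacting" is
#' decided downstream (see [is_interacting()]).
#'
#' @param x Path to a breakdown file, or its text.
#' @param onebody_tokens Placeholder tokens marking the partner fields of a
#'   one-body row; the defaults cover the common variants.
#' @param source_label Free-text label stored with the table.
#' @return An object of class `energy_table`: a list with elements `records`
#'   (data frame with columns `resi1`, `restype1`, `resi2` (`NA` for one-body
#'   rows), `restype2` (`"onebody"` for one-body rows), one column per score
#'   term, `total`, and `is_onebody`), `terms` (term names in header order)
#'   and `source_label`.
#' @seealso [write_breakdown_csv()], [net_residue_energy()], [diff_tables()]
#' @export
parse_breakdown <- function(x, onebody_tokens = c("--", "onebody"),
                            source_label = NULL) {
  if (is.null(source_label)) {
    source_label <- if (length(x) == 1L && !grepl("\n", x) &&
                        file.exists(x)) basename(x) else "text"
  }
  lines <- as_text_lines(x)
  is_score <- grepl("^SCORE:", lines)
  if (!any(is_score)) {
    stop("missing header: no 'SCORE:' lines found in breakdown input",
         call. = FALSE)
  }
  score_idx <- which(is_score)
  header_line <- lines[score_idx[1]]
  cols <- strsplit(trimws(sub("^SCORE:", "", header_line)), "\\s+")[[1]]
  required <- c("resi1", "restype1", "resi2", "restype2", "total")
  if (!all(required %in% cols)) {
    stop("missing header: first SCORE: line must name columns ",
         paste(setdiff(required, cols), collapse = ", "), call. = FALSE)
  }
  id_cols <- c("pose_id", "resi1", "pdbid1", "restype1",
               "resi2", "pdbid2", "restype2", "total", "description")
  terms <- setdiff(cols, id_cols)

  data_idx <- score_idx[-1]
  if (length(data_idx) == 0L) {
    return(empty_energy_table(terms, source_label))
  }
  parts <- strsplit(trimws(sub("^SCORE:", "", lines[data_idx])), "\\s+")
  nf <- lengths(parts)
  if (any(nf != length(cols))) {
    bad <- data_idx[which(nf != length(cols))[1]]
    stop(sprintf("column-count mismatch at line %d: expected %d fields, got %d",
                 bad, length(cols), nf[which(nf != length(cols))[1]]),
         call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = length(cols), byrow = TRUE)
  colnames(m) <- cols

  ob <- m[, "resi2"] %in% onebody_tokens |
    m[, "restype2"] %in% onebody_tokens
  num_field <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(v) & !(m[, col] %in% c("NA", "nan")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d",
                   m[bad[1], col], col, data_idx[bad[1]]), call. = FALSE)
    }
    v
  }
  resi1 <- num_field("resi1")
  resi2 <- rep(NA_real_, nrow(m))
  if (any(!ob)) {
    v <- suppressWarnings(as.numeric(m[!ob, "resi2"]))
    if (anyNA(v)) {
      bad <- data_idx[!ob][which(is.na(v))[1]]
      stop(sprintf("non-numeric resi2 in two-body record at line %d", bad),
           call. = FALSE)
    }
    resi2[!ob] <- v
  }
  rec <- data.frame(resi1 = as.integer(resi1),
                    restype1 = m[, "restype1"],
                    resi2 = as.integer(resi2),
                    restype2 = ifelse(ob, "onebody", m[, "restype2"]),
                    stringsAsFactors = FALSE)
  for (tm in terms) rec[[tm]] <- num_field(tm)
  rec$total <- num_field("total")
  rec$is_onebody <- ob

  # Normalize two-body records to resi1 < resi2.
  swap <- !ob & rec$resi2 < rec$resi1
  if (any(swap)) {
    tmp <- rec$resi1[swap]; rec$resi1[swap] <- rec$resi2[swap]
    rec$resi2[swap] <- tmp
    tmp <- rec$restype1[swap]; rec$restype1[swap] <- rec$restype2[swap]
    rec$restype2[swap] <- tmp
  }

  key <- ifelse(ob, paste0("ob_", rec$resi1),
                pair_key(rec$resi1, rec$resi2))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate record for ", sub("^ob_", "one-body residue ", d),
         " in breakdown input", call. = FALSE)
  }
  rownames(rec) <- NULL
  structure(list(records = rec, terms = terms, source_label = source_label),
            class = "energy_table")
}

empty_energy_table <- function(terms, source_label) {
  rec <- data.frame(resi1 = integer(), restype1 = character(),
                    resi2 = integer(), restype2 = character(),
                    stringsAsFactors = FALSE)
  for (tm in terms) rec[[tm]] <- numeric()
  rec$total <- numeric()
  rec$is_onebody <- logical()
  structure(list(records = rec, terms = terms, source_label = source_label),
            class = "energy_table")
}

#' Grand total of an energy table
#'
#' Sum of all one-body and two-body totals, in REU.
#'
#' @param t An `energy_table`.
#' @return A number.
#' @export
grand_total <- function(t) {
  stopifnot(inherits(t, "energy_table"))
  sum(t$records$total)
}

#' Residue ids with a one-body record
#' @param t An `energy_table`.
#' @return Sorted integer vector of renumbered residue ids.
#' @export
table_residues <- function(t) {
  stopifnot(inherits(t, "energy_table"))
  sort(t$records$resi1[t$records$is_onebody])
}

#' Net interaction energy of one residue
#'
#' A residue's one-body total plus the summed totals of every pairwise
#' interaction it participates in. By default each pair contributes its full
#' total to both members (so summing net energies over all residues counts
#' every pair twice); set `half_pair = TRUE` to assign half of each pair
#' total to each member instead. The convention is exposed because published
#' per-residue net energies do not state it.
#'
#' @param t An `energy_table`.
#' @param residue Renumbered residue id (must have a one-body record).
#' @param half_pair Logical; halve pair contributions (default `FALSE`).
#' @return Net energy in REU.
#' @export
net_residue_energy <- function(t, residue, half_pair = FALSE) {
  stopifnot(inherits(t, "energy_table"), length(residue) == 1L)
  nets <- net_residue_energies(t, half_pair = half_pair)
  i <- match(as.character(residue), names(nets))
  if (is.na(i)) {
    stop("unknown residue ", residue, ": no one-body record in table",
         call. = FALSE)
  }
  unname(nets[i])
}

# Net energies for all residues at once (named by residue id).
net_residue_energies <- function(t, half_pair = FALSE) {
  rec <- t$records
  ob <- rec[rec$is_onebody, ]
  nets <- stats::setNames(ob$total, ob$resi1)
  pair <- rec[!rec$is_onebody, ]
  if (nrow(pair)) {
    w <- if (half_pair) 0.5 else 1
    for (side in c("resi1", "resi2")) {
      agg <- tapply(pair$total, pair[[side]], sum)
      hit <- match(names(agg), names(nets))
      ok <- !is.na(hit)
      nets[hit[ok]] <- nets[hit[ok]] + w * agg[ok]
    }
  }
  nets[order(as.integer(names(nets)))]
}

#' Write an energy table as CSV
#'
#' RFC 4180 CSV with one row per record: `resi1`, `restype1`, `resi2` (empty
#' for one-body rows), `restype2`, every score term in header order, then
#' `total`. Numbers are written at full precision so that
#' [read_breakdown_csv()] reproduces the table bit-exactly.
#'
#' @param t An `energy_table`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_breakdown_csv <- function(t, path) {
  stopifnot(inherits(t, "energy_table"))
  rec <- t$records
  cols <- c("resi1", "restype1", "resi2", "restype2", t$terms, "total")
  out <- data.frame(resi1 = as.character(rec$resi1),
                    restype1 = rec$restype1,
                    resi2 = ifelse(rec$is_onebody, "", as.character(rec$resi2)),
                    restype2 = rec$restype2,
                    stringsAsFactors = FALSE)
  for (tm in c(t$terms, "total")) out[[tm]] <- format_full(rec[[tm]])
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(out), list(sep = ","))), con)
  }
  invisible(path)
}

#' Re-read a CSV written by [write_breakdown_csv()]
#'
#' @param path CSV file path.
#' @param source_label Label for the resulting table.
#' @return An `energy_table`.
#' @export
read_breakdown_csv <- function(path, source_label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("resi1", "restype1", "resi2", "restype2", "total")
  if (!all(need %in% names(df))) {
    stop("not a breakdown CSV: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  terms <- setdiff(names(df), need)
  ob <- df$resi2 == "" | df$restype2 == "onebody"
  rec <- data.frame(resi1 = as.integer(df$resi1), restype1 = df$restype1,
                    resi2 = ifelse(ob, NA_integer_,
                                   suppressWarnings(as.integer(df$resi2))),
                    restype2 = ifelse(ob, "onebody", df$restype2),
                    stringsAsFactors = FALSE)
  for (tm in terms) rec[[tm]] <- as.numeric(df[[tm]])
  rec$total <- as.numeric(df$total)
  rec$is_onebody <- ob
  terms <- setdiff(terms, "total")
  structure(list(records = rec, terms = terms, source_label = source_label),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  rec <- x$records
  cat(sprintf("energy_table: %d one-body + %d pair records, %d score terms (%s)\n",
              sum(rec$is_onebody), sum(!rec$is_onebody), length(x$terms),
              x$source_label))
  cat(sprintf(" grand total: %.3f REU\n", grand_total(x)))
  invisible(x)
}
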