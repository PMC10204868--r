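#' Read and clean a protein structure from PDB input
#'
#' Parses PDB-format input and reduces it to the polypeptide content used by
#' all downstream analyses: water, ligand, ion and other `HETATM` records are
#' removed, only the first coordinate model is kept, alternate locations are
#' collapsed to the highest-occupancy conformer (ties keep the first listed),
#' and residues are renumbered so that the first residue in the file is at
#' position 1. The renumbering is a single global 1..N counter across all
#' chains in file order; insertion codes are dropped. The renumbered index is
#' the residue key used by every other module.
#'
#' Hydrogens, if present, are retained. `ATOM` records with a non-canonical
#' residue type (e.g. `MSE`) are rejected with an error rather than
#' translated.
#'
#' @param pdb Path to a PDB file, or PDB text (a single string or a character
#'   vector of lines).
#' @param source_label Free-text label stored with the structure (defaults to
#'   the file name, or `"text"` for literal input).
#' @return An object of class `protein_structure`: a list with elements
#'   `atoms` (data frame with columns `renum_id`, `chain`, `author_seq_id`,
#'   `restype3`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`, `b`),
#'   `residues` (one row per residue: `renum_id`, `chain`, `author_seq_id`,
#'   `restype3`) and `source_label`.
#' @examples
#' s <- make_toy_structure(5, "helix", sequence = "MKWTA", seed = 1)$structure
#' s$residues
#' @seealso [write_structure()], [extract_sequence()], [detect_mutations()]
#' @export
clean_structure <- function(pdb, source_label = NULL) {
  if (is.null(source_label)) {
    source_label <- if (length(pdb) == 1L && !grepl("\n", pdb) &&
                        file.exists(pdb)) basename(pdb) else "text"
  }
  lines <- as_text_lines(pdb)
  validate_pdb_lines(lines)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  p <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                        verbose = FALSE))
  at <- p$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no standard amino-acid ATOM records found in input", call. = FALSE)
  }
  bad <- !(at$resid %in% AA3)
  if (any(bad)) {
    stop("non-canonical residue type(s) in ATOM records: ",
         paste(unique(at$resid[bad]), collapse = ", "),
         " (non-standard residues are rejected, not translated)",
         call. = FALSE)
  }

  # Collapse alternate locations: keep the highest-occupancy conformer of
  # each (chain, author residue, insertion, atom name); ties keep the first.
  occ <- ifelse(is.na(at$o), 1, at$o)
  grp <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "|")
  ord <- order(grp, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE][!duplicated(grp[ord]), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  occ <- ifelse(is.na(at$o), 1, at$o)

  # Global renumbering 1..N in file order over (chain, author id, insertion).
  rid <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               sep = "|")
  renum <- match(rid, unique(rid))

  elem <- at$elesy
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[^A-Za-z].*", "", trimws(at$elety[miss])), 1, 1)
  elem <- toupper(elem)

  atoms <- data.frame(
    renum_id = renum,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    author_seq_id = at$resno,
    restype3 = at$resid,
    atom_name = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occupancy = occ,
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  residues <- atoms[!duplicated(atoms$renum_id),
                    c("renum_id", "chain", "author_seq_id", "restype3")]
  rownames(atoms) <- rownames(residues) <- NULL

  structure(list(atoms = atoms, residues = residues,
                 source_label = source_label),
            class = "protein_structure")
}

# Pre-parse validation so malformed coordinate records are reported with
# their line number (the downstream reader would silently coerce to NA).
validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in coord) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed PDB record at line %d: too short (%d chars)",
                   i, nchar(ln)), call. = FALSE)
    }
    fields <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54),
                substr(ln, 23, 26))
    if (anyNA(suppressWarnings(as.numeric(fields)))) {
      stop(sprintf("malformed PDB record at line %d: non-numeric field", i),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a cleaned structure as a PDB file
#'
#' Serializes a [clean_structure()] result back to fixed-width PDB `ATOM`
#' records, numbered by the unified 1..N residue index. Cleaning a structure
#' written by this function is a no-op (idempotence).
#'
#' @param s A `protein_structure`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$renum_id, resid = a$restype3,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain, o = a$occupancy, b = a$b,
                   elesy = a$element)
  invisible(path)
}

#' Serialize a structure to PDB text
#'
#' @param s A `protein_structure`.
#' @return A character vector of PDB lines.
#' @export
pdb_lines <- function(s) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  write_structure(s, tmp)
  readLines(tmp, warn = FALSE)
}

#' Extract the one-letter amino-acid sequence of a structure
#'
#' @param s A `protein_structure` with at least one residue.
#' @return A single string of one-letter codes, one per residue in
#'   renumbered order.
#' @export
extract_sequence <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  if (nrow(s$residues) == 0L) {
    stop("structure has no residues", call. = FALSE)
  }
  paste(aa_three_to_one(s$residues$restype3), collapse = "")
}

#' Detect point mutations between two equal-length sequences
#'
#' Compares the reference and mutant sequences position by position under the
#' unified renumbering and reports every substitution. Sequences of unequal
#' length are rejected: the intended use compares a design against the
#' template it was built on, which shares its length, and indel-tolerant
#' alignment is deliberately not attempted.
#'
#' @param ref_seq,mut_seq One-letter sequences (strings), or
#'   `protein_structure` objects (their sequences are extracted).
#' @return A data frame with columns `position` (renumbered index),
#'   `ref` and `mut` (one-letter codes), one row per differing position in
#'   ascending order; zero rows iff the sequences are identical.
#' @examples
#' detect_mutations("IACDE", "RACDE")
#' @export
detect_mutations <- function(ref_seq, mut_seq) {
  if (inherits(ref_seq, "protein_structure")) ref_seq <- extract_sequence(ref_seq)
  if (inherits(mut_seq, "protein_structure")) mut_seq <- extract_sequence(mut_seq)
  stopifnot(is.character(ref_seq), is.character(mut_seq),
            length(ref_seq) == 1L, length(mut_seq) == 1L)
  if (nchar(ref_seq) == 0L || nchar(mut_seq) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (nchar(ref_seq) != nchar(mut_seq)) {
    stop(sprintf(paste0("sequence length mismatch: reference has %d residues,",
                        " mutant has %d (indels are not supported)"),
                 nchar(ref_seq), nchar(mut_seq)), call. = FALSE)
  }
  a <- strsplit(ref_seq, "")[[1]]
  b <- strsplit(mut_seq, "")[[1]]
  pos <- which(a != b)
  data.frame(position = pos, ref = a[pos], mut = b[pos],
             stringsAsFactors = FALSE)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues, %d atoms (%s)\n",
              nrow(x$residues), nrow(x$atoms), x$source_label))
  cat(" chains:", paste(unique(x$residues$chain), collapse = " "), "\n")
  invisible(x)
}
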