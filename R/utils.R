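# Internal tables and small helpers shared across modules.

# Canonical amino-acid code tables.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- stats::setNames(AA3, AA1)

# The fixed order in which physical interaction types are reported.
INTERACTION_TYPES <- c("salt_bridge", "disulfide", "hb_sc_sc", "hb_bb_sc",
                       "hb_bb_sr", "hb_bb_lr", "all")

INTERACTION_CATEGORIES <- c("A", "B", "C", "D", "E", "F")

# Basic/acidic side-chain sets used by the salt-bridge rule.
SALT_BASIC <- c("ARG", "LYS", "HIS")
SALT_BASIC_STRICT <- c("ARG", "LYS")
SALT_ACIDIC <- c("ASP", "GLU")

aa_three_to_one <- function(x) {
  out <- AA1[x]
  bad <- is.na(out)
  if (any(bad)) {
    stop("cannot map residue type(s) to one-letter code: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

aa_one_to_three <- function(x) {
  out <- AA3_FROM_1[x]
  bad <- is.na(out)
  if (any(bad)) {
    stop("cannot map one-letter code(s) to residue type: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# global random state is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Full-precision number formatting for round-trippable text output.
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "_")

# Read input that may be a file path or already-split text lines.
as_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
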