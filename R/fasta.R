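# Residues accepted in a database entry: the 20 standard amino acids plus the
# ambiguity/rare codes B, J, O, U, X, Z.
VALID_RESIDUES <- "ACDEFGHIKLMNPQRSTVWYBJOUXZ"

#' Read a FASTA protein database
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file into a tibble with
#' one row per protein. UniProt-style headers of the form
#' `>db|ACCESSION|NAME description` yield the second pipe field as the
#' accession; for any other header the accession is the first
#' whitespace-delimited token after `>`. Sequences are uppercased and a
#' trailing stop character (`*`) is stripped.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `description`, `sequence` and
#'   `length`. Accessions are guaranteed unique.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P00001|T1 test protein", "MKV", "QW"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  if (!any(startsWith(readLines(path, warn = FALSE), ">"))) {
    abort(paste0("No FASTA records (missing '>' header) in: ", path))
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    abort(paste0("No FASTA records in: ", path))
  }
  headers <- names(aa)
  first_tok <- stringr::str_extract(headers, "^\\S+")
  first_tok[is.na(first_tok)] <- ""
  pipe_fields <- stringr::str_split(first_tok, stringr::fixed("|"))
  accession <- purrr::map2_chr(pipe_fields, first_tok, function(fields, tok) {
    if (length(fields) >= 3L && nzchar(fields[2])) fields[2] else tok
  })
  description <- stringr::str_trim(stringr::str_remove(headers, "^\\S*\\s*"))
  if (any(!nzchar(accession))) {
    abort(paste0("Empty accession in header of: ", path))
  }
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0L) {
    abort(paste0("Duplicate accession(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  sequence <- toupper(as.character(aa))
  sequence <- stringr::str_remove(sequence, "\\*+$")
  bad <- stringr::str_detect(sequence, paste0("[^", VALID_RESIDUES, "]"))
  if (any(bad)) {
    abort(paste0("Invalid residue characters in entries: ",
                 paste(accession[bad], collapse = ", ")))
  }
  if (any(!nzchar(sequence))) {
    abort(paste0("Zero-length sequence for: ",
                 paste(accession[!nzchar(sequence)], collapse = ", ")))
  }
  tibble(
    accession = unname(accession),
    description = unname(description),
    sequence = unname(sequence),
    length = nchar(unname(sequence))
  )
}

#' Write protein entries to a FASTA file
#'
#' Inverse of [read_fasta()]: writes `sp|ACC|ACC description` style headers so
#' that a read/write cycle is idempotent on accession/sequence pairs.
#'
#' @param proteins Tibble as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  lines <- purrr::pmap(proteins, function(accession, description, sequence, ...) {
    desc <- if (!is.null(description) && nzchar(description)) paste0(" ", description) else ""
    header <- paste0(">sp|", accession, "|", accession, desc)
    body <- stringr::str_sub(
      sequence,
      seq(1L, nchar(sequence), by = width),
      pmin(seq(width, nchar(sequence) + width - 1L, by = width), nchar(sequence))
    )
    c(header, body)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

# Fetch one protein row by accession; exact match first, then a
# case-insensitive fallback with a warning, then an error listing near misses.
get_protein <- function(proteins, accession) {
  hit <- proteins[proteins$accession == accession, ]
  if (nrow(hit) == 1L) {
    return(hit)
  }
  ci <- proteins[toupper(proteins$accession) == toupper(accession), ]
  if (nrow(ci) == 1L) {
    warn(paste0("Accession '", accession, "' matched '", ci$accession,
                "' case-insensitively."))
    return(ci)
  }
  near <- proteins$accession[agrepl(accession, proteins$accession, max.distance = 0.3)]
  msg <- paste0("Accession '", accession, "' not found in database.")
  if (length(near) > 0L) {
    msg <- paste0(msg, " Near matches: ", paste(utils::head(near, 5L), collapse = ", "))
  }
  abort(msg)
}
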