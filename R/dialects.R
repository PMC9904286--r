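PEP_DIALECTS <- c("peaks", "msfragger", "maxquant", "metamorpheus",
                  "proteome_discoverer", "generic")

# The header -> field mapping for every supported search-engine dialect lives
# in a shipped CSV (inst/extdata/dialect_map.csv) rather than in code, because
# vendors rename columns between versions and users should be able to edit the
# mapping without touching the package. Roles:
#   delim     "comma" or "tab"
#   sequence  exact name of the (possibly modified) peptide sequence column
#   replicate exact name of the sample column (long/generic layout only)
#   psm/intensity/area
#             exact column name (long layout) or a regex with one capture
#             group extracting the replicate label (wide layouts)
#   ptm       optional column of "offset:delta:name" triples (generic only)
dialect_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dialect_map.csv",
                                package = "pepprofile", mustWork = TRUE)
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dialect", "role", "pattern") %in% names(map)))
  as_tibble(map)
}

dialect_spec <- function(dialect, map = dialect_map()) {
  rows <- map[map$dialect == dialect, ]
  if (nrow(rows) == 0L) {
    abort(paste0("Unknown dialect '", dialect, "'. Supported: ",
                 paste(PEP_DIALECTS, collapse = ", ")))
  }
  get1 <- function(role) {
    x <- rows$pattern[rows$role == role]
    if (length(x) == 0L) NA_character_ else x[[1]]
  }
  list(
    dialect   = dialect,
    delim     = if (identical(get1("delim"), "tab")) "\t" else ",",
    sequence  = get1("sequence"),
    replicate = get1("replicate"),
    metrics   = list(psm = get1("psm"), intensity = get1("intensity"),
                     area = get1("area")),
    ptm       = get1("ptm"),
    long      = !is.na(get1("replicate"))
  )
}

# A dialect matches a header when its sequence column is present verbatim and,
# for wide layouts, at least one metric column matches its pattern.
dialect_matches_header <- function(spec, header) {
  if (!(spec$sequence %in% header)) {
    return(FALSE)
  }
  if (spec$long) {
    return(spec$replicate %in% header)
  }
  pats <- unlist(spec$metrics)
  pats <- pats[!is.na(pats)]
  any(purrr::map_lgl(pats, ~ any(stringr::str_detect(header, .x))))
}

detect_dialect <- function(header, map = dialect_map()) {
  hits <- purrr::keep(PEP_DIALECTS, function(d) {
    dialect_matches_header(dialect_spec(d, map), header)
  })
  if (length(hits) == 1L) {
    return(hits)
  }
  if (length(hits) > 1L) {
    abort(paste0("Ambiguous peptide-table header; matches dialects: ",
                 paste(hits, collapse = ", "),
                 ". Pass `dialect` explicitly."))
  }
  abort(paste0(
    "Unrecognized peptide-table header signature. Candidate dialects: ",
    paste(PEP_DIALECTS, collapse = ", "),
    ". Pass `dialect` explicitly or edit the dialect mapping table."))
}
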