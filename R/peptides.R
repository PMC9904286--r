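#' Parse a search-engine modified peptide sequence
#'
#' Splits a raw peptide string as printed by a search engine into the bare
#' residue sequence and a table of post-translational modifications (PTMs).
#' Flanking-residue decorations (`K.PEPTIDE.R`, exactly one dot on each side)
#' are stripped first; parenthetical mass-delta tokens of the form `(+57.02)`
#' or `(-.98)` immediately following a residue are then removed, each yielding
#' a PTM at that residue's 1-based offset within the peptide.
#'
#' @param raw A single non-empty peptide string.
#' @param dialect Source dialect (informational; all dialects share the
#'   parenthetical notation).
#' @return A list with `bare_sequence` (string) and `ptms`, a tibble with
#'   columns `offset`, `mass_delta` and `name`.
#' @examples
#' parse_modified_sequence("AN(+.98)VSK")
#' parse_modified_sequence("K.AM(+15.99)C(+57.02)R.L")
#' @export
parse_modified_sequence <- function(raw, dialect = "generic") {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) {
    abort("Empty peptide sequence string.")
  }
  seq <- strip_flanks(raw)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bare <- character(0)
  offsets <- integer(0)
  deltas <- numeric(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i
      depth <- 0L
      repeat {
        if (j > n) {
          abort(paste0("Unbalanced parentheses in peptide string: ", raw))
        }
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
        j <- j + 1L
      }
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!stringr::str_detect(inner, "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$")) {
        abort(paste0("Unrecognized modification token '(", inner,
                     ")' in peptide string: ", raw))
      }
      if (length(bare) == 0L) {
        abort(paste0("Modification token not following a residue in: ", raw))
      }
      offsets <- c(offsets, length(bare))
      deltas <- c(deltas, as.numeric(inner))
      i <- j + 1L
    } else if (ch == ")") {
      abort(paste0("Unbalanced parentheses in peptide string: ", raw))
    } else if (stringr::str_detect(toupper(ch), paste0("[", VALID_RESIDUES, "]"))) {
      bare <- c(bare, toupper(ch))
      i <- i + 1L
    } else {
      abort(paste0("Invalid residue character '", ch, "' in peptide string: ", raw))
    }
  }
  if (length(bare) == 0L) {
    abort(paste0("No residues in peptide string: ", raw))
  }
  list(
    bare_sequence = paste(bare, collapse = ""),
    ptms = tibble(offset = offsets, mass_delta = deltas,
                  name = rep("", length(offsets)))
  )
}

# `X.SEQ.Y` flank notation: exactly one dot on each side, single residue (or
# `-` for a protein terminus) outside each dot. Dots inside parenthetical
# tokens do not count. Anything else is left untouched.
strip_flanks <- function(raw) {
  masked <- gsub("\\([^()]*\\)", "", raw)
  if (stringr::str_detect(masked, "^[A-Za-z-]\\.[^.]+\\.[A-Za-z-]$")) {
    return(stringr::str_remove(stringr::str_remove(raw, "^[A-Za-z-]\\."),
                               "\\.[A-Za-z-]$"))
  }
  raw
}

PEP_METRICS <- c("psm", "intensity", "area")

# canonical key for a PTM set, used for aggregation/deduplication (deltas
# compared at 0.01 Da)
ptm_key <- function(ptms) {
  if (is.null(ptms) || nrow(ptms) == 0L) {
    return("")
  }
  ord <- order(ptms$offset, ptms$mass_delta)
  paste(sprintf("%d:%+.2f", ptms$offset[ord], ptms$mass_delta[ord]),
        collapse = ";")
}

parse_ptm_triples <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(tibble(offset = integer(0), mass_delta = numeric(0),
                  name = character(0)))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble(
    offset = as.integer(purrr::map_chr(parts, 1)),
    mass_delta = as.numeric(purrr::map_chr(parts, 2)),
    name = purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[[3]] else "")
  )
}

as_pep_observations <- function(df, dialect, replicate_labels) {
  attr(df, "source_dialect") <- dialect
  attr(df, "replicate_labels") <- replicate_labels
  class(df) <- unique(c("pep_observations", class(df)))
  df
}

#' Replicate labels of an observation table
#' @param table An observation table from [read_peptides()].
#' @return Character vector of replicate labels, in file order.
#' @export
replicate_labels <- function(table) {
  attr(table, "replicate_labels") %||% sort(unique(table$replicate))
}

#' Read a peptide-level search result table
#'
#' Reads a peptide table exported by PEAKS, MSFragger/FragPipe, MaxQuant,
#' MetaMorpheus or Proteome Discoverer, or a generic long-format CSV, into a
#' canonical observation tibble with one row per (peptide form, replicate).
#' Label-free quantification (LFQ) columns are mapped onto the `area` metric;
#' missing or blank metric cells are read as 0; rows whose metrics are all
#' zero (peptide not observed in that replicate) are dropped. Observations are
#' aggregated so that (bare sequence, PTM set, replicate) triples are unique.
#'
#' @param path Path to a CSV/TSV peptide table.
#' @param dialect One of `"peaks"`, `"msfragger"`, `"maxquant"`,
#'   `"metamorpheus"`, `"proteome_discoverer"`, `"generic"` or `"auto"`
#'   (detect from the header signature).
#' @param map Dialect header-mapping table; defaults to the mapping CSV
#'   shipped with the package (see `system.file("extdata", "dialect_map.csv",
#'   package = "pepprofile")`).
#' @return A tibble with columns `bare_sequence`, `raw_sequence`, `ptms`
#'   (list-column of PTM tibbles), `replicate`, `psm`, `intensity`, `area`,
#'   carrying the source dialect and the ordered replicate labels as
#'   attributes.
#' @export
read_peptides <- function(path, dialect = "auto", map = dialect_map()) {
  if (!file.exists(path)) {
    abort(paste0("Peptide file not found: ", path))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    abort(paste0("Empty peptide file: ", path))
  }
  delim_guess <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  header <- strsplit(first, delim_guess, fixed = TRUE)[[1]]
  header <- gsub("^\"|\"$", "", header)
  if (identical(dialect, "auto")) {
    dialect <- detect_dialect(header, map)
  }
  spec <- dialect_spec(dialect, map)
  df <- utils::read.table(path, sep = spec$delim, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "", fill = TRUE,
                          fileEncoding = "UTF-8")
  long <- if (spec$long) {
    read_long_dialect(df, spec)
  } else {
    read_wide_dialect(df, spec)
  }
  if (nrow(long) == 0L) {
    return(as_pep_observations(
      tibble(bare_sequence = character(0), raw_sequence = character(0),
             ptms = list(), replicate = character(0), psm = numeric(0),
             intensity = numeric(0), area = numeric(0)),
      dialect, character(0)))
  }
  parsed <- purrr::map(long$raw_sequence, parse_modified_sequence,
                       dialect = dialect)
  long$bare_sequence <- purrr::map_chr(parsed, "bare_sequence")
  inline <- purrr::map(parsed, "ptms")
  long$ptms <- purrr::map2(inline, long$ptms, function(a, b) {
    out <- bind_rows(a, b)
    out[order(out$offset, out$mass_delta), ]
  })
  bad <- purrr::map2_lgl(long$ptms, long$bare_sequence, function(p, s) {
    nrow(p) > 0L && any(p$offset < 1L | p$offset > nchar(s))
  })
  if (any(bad)) {
    abort(paste0("PTM offset outside peptide bounds for: ",
                 paste(unique(long$raw_sequence[bad]), collapse = ", ")))
  }
  long$.key <- purrr::map_chr(long$ptms, ptm_key)
  agg <- long |>
    group_by(.data$bare_sequence, .data$.key, .data$replicate) |>
    summarise(
      raw_sequence = dplyr::first(.data$raw_sequence),
      ptms = list(.data$ptms[[1]]),
      psm = sum(.data$psm), intensity = sum(.data$intensity),
      area = sum(.data$area),
      .groups = "drop"
    ) |>
    select("bare_sequence", "raw_sequence", "ptms", "replicate",
           "psm", "intensity", "area") |>
    arrange(.data$bare_sequence, .data$replicate)
  labels <- unique(long$replicate)
  as_pep_observations(agg, dialect, labels)
}

read_long_dialect <- function(df, spec) {
  for (col in c(spec$sequence, spec$replicate)) {
    if (!(col %in% names(df))) {
      abort(paste0("Required column '", col, "' absent from ", spec$dialect,
                   " peptide table."))
    }
  }
  metric_cols <- purrr::compact(purrr::imap(spec$metrics, function(col, m) {
    if (!is.na(col) && col %in% names(df)) col else NULL
  }))
  if (length(metric_cols) == 0L) {
    abort(paste0("No metric column (",
                 paste(unlist(spec$metrics), collapse = ", "),
                 ") present in ", spec$dialect, " peptide table."))
  }
  out <- tibble(
    raw_sequence = df[[spec$sequence]],
    replicate = df[[spec$replicate]]
  )
  for (m in PEP_METRICS) {
    col <- spec$metrics[[m]]
    out[[m]] <- if (!is.na(col) && col %in% names(df)) {
      num0(df[[col]])
    } else {
      0
    }
  }
  out$ptms <- if (!is.na(spec$ptm) && spec$ptm %in% names(df)) {
    purrr::map(df[[spec$ptm]], parse_ptm_triples)
  } else {
    purrr::map(seq_len(nrow(out)), ~ parse_ptm_triples(NA_character_))
  }
  out[rowSums(as.matrix(out[PEP_METRICS])) > 0, ]
}

read_wide_dialect <- function(df, spec) {
  if (!(spec$sequence %in% names(df))) {
    abort(paste0("Required column '", spec$sequence, "' absent from ",
                 spec$dialect, " peptide table."))
  }
  header <- names(df)
  hits <- purrr::compact(purrr::imap(spec$metrics, function(pat, m) {
    if (is.na(pat)) return(NULL)
    cols <- header[stringr::str_detect(header, pat)]
    if (length(cols) == 0L) return(NULL)
    tibble(metric = m, column = cols,
           label = stringr::str_match(cols, pat)[, 2])
  }))
  if (length(hits) == 0L) {
    abort(paste0("No per-sample metric columns matched the ", spec$dialect,
                 " header patterns."))
  }
  hits <- bind_rows(hits)
  labels <- unique(hits$label[order(match(hits$column, header))])
  rows <- purrr::map(labels, function(lab) {
    out <- tibble(raw_sequence = df[[spec$sequence]], replicate = lab)
    for (m in PEP_METRICS) {
      col <- hits$column[hits$metric == m & hits$label == lab]
      out[[m]] <- if (length(col) == 1L) num0(df[[col]]) else 0
    }
    out
  })
  out <- bind_rows(rows)
  out$ptms <- purrr::map(seq_len(nrow(out)), ~ parse_ptm_triples(NA_character_))
  out <- out[rowSums(as.matrix(out[PEP_METRICS])) > 0, ]
  # preserve file order of labels for attr computation downstream
  out$replicate <- factor(out$replicate, levels = labels)
  out$replicate <- as.character(out$replicate)
  out
}

num0 <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  y[is.na(y)] <- 0
  y
}
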