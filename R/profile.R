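#' Resolve replicate labels into named sample groups
#'
#' Matches each group's regular expression against the replicate labels of an
#' observation table (substring search, not full match). A label may fall into
#' several groups (with a warning); a group matching no label is an error.
#'
#' @param table Observation table from [read_peptides()].
#' @param groups Either a named character vector of regex patterns
#'   (`c(ctrl = "^ctrl", trt = "^trt")`) or a data frame with columns `name`,
#'   `pattern` and optionally `combine`.
#' @param combine How to combine replicates within a group: `"sum"` or
#'   `"mean"`. Recycled across groups; ignored when `groups` carries its own
#'   `combine` column.
#' @return A tibble with one row per group: `name`, `pattern`, `combine`,
#'   `replicate_labels` (list-column) and `n_replicates`.
#' @export
resolve_sample_groups <- function(table, groups, combine = "sum") {
  if (is.character(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
      abort("`groups` given as a character vector must be fully named.")
    }
    groups <- tibble(name = names(groups), pattern = unname(groups))
  }
  groups <- as_tibble(groups)
  if (!all(c("name", "pattern") %in% names(groups))) {
    abort("`groups` needs columns `name` and `pattern`.")
  }
  if (!("combine" %in% names(groups))) {
    groups$combine <- rep_len(combine, nrow(groups))
  }
  if (anyDuplicated(groups$name)) {
    abort("Group names must be unique.")
  }
  if (!all(groups$combine %in% c("sum", "mean"))) {
    abort("`combine` must be 'sum' or 'mean'.")
  }
  labels <- replicate_labels(table)
  groups$replicate_labels <- purrr::map(groups$pattern, function(p) {
    ok <- tryCatch(suppressWarnings(grepl(p, labels)), error = function(e) {
      abort(paste0("Invalid regular expression '", p, "': ",
                   conditionMessage(e)))
    })
    labels[ok]
  })
  empty <- purrr::map_int(groups$replicate_labels, length) == 0L
  if (any(empty)) {
    abort(paste0("No replicates matched for group(s): ",
                 paste(groups$name[empty], collapse = ", "),
                 ". Labels present: ", paste(labels, collapse = ", ")))
  }
  counts <- table(unlist(groups$replicate_labels))
  multi <- names(counts)[counts > 1L]
  if (length(multi) > 0L) {
    warn(paste0("Replicate label(s) matched by multiple groups: ",
                paste(multi, collapse = ", ")))
  }
  groups$n_replicates <- purrr::map_int(groups$replicate_labels, length)
  groups
}

#' Map peptides onto a protein sequence
#'
#' Locates every occurrence (including overlapping occurrences) of every
#' distinct bare peptide sequence in the observation table as an exact
#' substring of the target protein. Matching is exact after uppercasing; no
#' isoleucine/leucine equivalence is applied.
#'
#' @param protein One-row tibble from [read_fasta()] (or any list with
#'   `accession` and `sequence`).
#' @param table Observation table from [read_peptides()].
#' @return A tibble of matches with columns `bare_sequence`, `start`, `end`
#'   (1-based, inclusive) and `occurrence` (ordinal among this peptide's
#'   placements), sorted by (start, end). Peptides absent from the protein
#'   yield no rows.
#' @export
map_peptides <- function(protein, table) {
  seqs <- unique(table$bare_sequence)
  target <- protein$sequence[[1]]
  rows <- purrr::map(seqs, function(s) {
    starts <- find_all_substrings(target, s)
    if (length(starts) == 0L) {
      return(NULL)
    }
    tibble(bare_sequence = s, start = starts,
           end = starts + nchar(s) - 1L,
           occurrence = seq_along(starts))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(bare_sequence = character(0), start = integer(0),
                  end = integer(0), occurrence = integer(0)))
  }
  arrange(out, .data$start, .data$end, .data$bare_sequence)
}

# all (overlapping) start positions of `needle` in `haystack`, 1-based
find_all_substrings <- function(haystack, needle) {
  hits <- gregexpr(paste0("(?=", escape_regex(needle), ")"), haystack,
                   perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

escape_regex <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# Per-peptide group value: metric summed over all forms of the peptide within
# each replicate of the group, then summed (combine = "sum") or divided by
# the number of replicates in the group (combine = "mean"; non-observation
# counts as zero, so mean == sum / n).
peptide_group_values <- function(table, group, metric) {
  if (!(metric %in% PEP_METRICS)) {
    abort(paste0("Unknown metric '", metric, "'. Use one of: ",
                 paste(PEP_METRICS, collapse = ", ")))
  }
  if (!(metric %in% names(table))) {
    abort(paste0("Metric '", metric, "' absent from observation table."))
  }
  labels <- group$replicate_labels[[1]]
  sub <- table[table$replicate %in% labels, c("bare_sequence", metric)]
  vals <- sub |>
    group_by(.data$bare_sequence) |>
    summarise(value = sum(.data[[metric]]), .groups = "drop")
  if (identical(group$combine[[1]], "mean")) {
    vals$value <- vals$value / length(labels)
  }
  vals
}

#' Per-residue intensity profile for one sample group
#'
#' Assigns each amino-acid position the sum, over all peptide matches covering
#' that position, of the peptide's group metric value (PSM count, intensity or
#' LFQ area; replicates summed or averaged per the group definition). Each
#' occurrence of a multiply-occurring peptide contributes its full value at
#' every placement. Uncovered residues are 0.
#'
#' @param protein One-row tibble from [read_fasta()].
#' @param matches Match table from [map_peptides()].
#' @param table Observation table from [read_peptides()].
#' @param group A single row of [resolve_sample_groups()] output.
#' @param metric `"psm"`, `"intensity"` or `"area"`.
#' @return A tibble of class `residue_profile` with columns `position`,
#'   `residue` and `value`, one row per residue; accession, group name,
#'   metric and combine mode are carried as attributes.
#' @export
residue_profile <- function(protein, matches, table, group, metric) {
  L <- nchar(protein$sequence[[1]])
  vals <- peptide_group_values(table, group, metric)
  values <- numeric(L)
  if (nrow(matches) > 0L) {
    m <- left_join(matches, vals, by = "bare_sequence")
    m$value[is.na(m$value)] <- 0
    for (k in seq_len(nrow(m))) {
      idx <- m$start[k]:m$end[k]
      values[idx] <- values[idx] + m$value[k]
    }
  }
  out <- tibble(
    position = seq_len(L),
    residue = strsplit(protein$sequence[[1]], "", fixed = TRUE)[[1]],
    value = values
  )
  structure(out,
            class = c("residue_profile", class(out)),
            accession = protein$accession[[1]],
            group = group$name[[1]],
            metric = metric,
            combine = group$combine[[1]])
}

#' Percent sequence coverage
#'
#' Percentage of the protein's residues covered by at least one mapped
#' peptide.
#'
#' @param matches Match table from [map_peptides()].
#' @param L Protein length (residues), >= 1.
#' @return A single number in \[0, 100\].
#' @export
sequence_coverage <- function(matches, L) {
  stopifnot(L >= 1L)
  if (nrow(matches) == 0L) {
    return(0)
  }
  covered <- logical(L)
  for (k in seq_len(nrow(matches))) {
    covered[matches$start[k]:matches$end[k]] <- TRUE
  }
  100 * sum(covered) / L
}

UNIQUENESS_CLASSES <- c("uncovered", "unique", "repeated_within", "shared_other")

#' Classify residue coverage by peptide uniqueness
#'
#' Colors each residue of the target protein by the provenance of the
#' peptides covering it: `shared_other` if any covering peptide also occurs
#' in another proteome entry, else `repeated_within` if any covering peptide
#' occurs more than once in the target, else `unique`; residues covered by no
#' peptide are `uncovered`.
#'
#' @param protein One-row tibble for the target (must be present in
#'   `proteome`).
#' @param proteome Tibble of all database entries from [read_fasta()].
#' @param matches Match table from [map_peptides()].
#' @param table Observation table (peptides not mapped to the target are
#'   ignored).
#' @return A tibble of class `uniqueness_track` with columns `position`,
#'   `residue` and `class` (factor over uncovered/unique/repeated_within/
#'   shared_other).
#' @export
classify_uniqueness <- function(protein, proteome, matches, table) {
  acc <- protein$accession[[1]]
  if (!(acc %in% proteome$accession)) {
    abort(paste0("Target accession '", acc, "' missing from proteome."))
  }
  target_seq <- protein$sequence[[1]]
  L <- nchar(target_seq)
  others <- proteome$sequence[proteome$accession != acc]
  pep <- unique(matches$bare_sequence)
  flags <- tibble(
    bare_sequence = pep,
    shared_other = purrr::map_lgl(pep, function(s) {
      any(purrr::map_lgl(others, ~ grepl(s, .x, fixed = TRUE)))
    }),
    repeated_within = purrr::map_lgl(pep, function(s) {
      length(find_all_substrings(target_seq, s)) >= 2L
    })
  )
  # precedence: shared_other > repeated_within > unique
  rank <- numeric(L) # 0 uncovered, 1 unique, 2 repeated_within, 3 shared_other
  m <- left_join(matches, flags, by = "bare_sequence")
  for (k in seq_len(nrow(m))) {
    r <- if (m$shared_other[k]) 3 else if (m$repeated_within[k]) 2 else 1
    idx <- m$start[k]:m$end[k]
    rank[idx] <- pmax(rank[idx], r)
  }
  out <- tibble(
    position = seq_len(L),
    residue = strsplit(target_seq, "", fixed = TRUE)[[1]],
    class = factor(UNIQUENESS_CLASSES[rank + 1], levels = UNIQUENESS_CLASSES)
  )
  structure(out, class = c("uniqueness_track", class(out)), accession = acc)
}

#' @exportS3Method generics::glance
glance.residue_profile <- function(x, ...) {
  tibble(
    accession = attr(x, "accession"),
    group = attr(x, "group"),
    metric = attr(x, "metric"),
    length = nrow(x),
    covered = sum(x$value > 0),
    coverage_percent = 100 * sum(x$value > 0) / nrow(x),
    total = sum(x$value),
    max = max(x$value)
  )
}
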