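#' Stacked-peptide layout
#'
#' Arranges every peptide match (one row per occurrence) into horizontal
#' levels so that no two peptides on the same level come within `gap`
#' residues of each other, using a deterministic greedy first-fit: matches
#' are sorted by start, then descending length, then sequence, and each takes
#' the lowest level that keeps the required separation. Each row carries the
#' peptide's group metric value for colouring.
#'
#' @param matches Match table from [map_peptides()].
#' @param table Observation table from [read_peptides()].
#' @param group A single row of [resolve_sample_groups()] output.
#' @param metric `"psm"`, `"intensity"` or `"area"`.
#' @param gap Minimum number of free residues between neighbours on a level.
#' @return A tibble of class `stacked_layout` with columns `bare_sequence`,
#'   `start`, `end`, `occurrence`, `level` (0-based) and `color_value`.
#' @export
stack_peptides <- function(matches, table, group, metric, gap = 1L) {
  vals <- peptide_group_values(table, group, metric)
  m <- left_join(matches, vals, by = "bare_sequence")
  m$value[is.na(m$value)] <- 0
  m <- m[order(m$start, -(m$end - m$start + 1L), m$bare_sequence), ]
  level_end <- numeric(0) # rightmost occupied residue per level
  levels <- integer(nrow(m))
  for (k in seq_len(nrow(m))) {
    placed <- FALSE
    for (lv in seq_along(level_end)) {
      if (m$start[k] > level_end[lv] + gap) {
        levels[k] <- lv - 1L
        level_end[lv] <- max(level_end[lv], m$end[k])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      level_end <- c(level_end, m$end[k])
      levels[k] <- length(level_end) - 1L
    }
  }
  out <- tibble(
    bare_sequence = m$bare_sequence, start = m$start, end = m$end,
    occurrence = m$occurrence, level = levels, color_value = m$value
  )
  structure(out,
            class = c("stacked_layout", class(out)),
            group = group$name[[1]], metric = metric, gap = gap)
}

#' Per-residue tick positions
#'
#' Marker positions for the per-residue guides drawn on stacked and trace
#' plots (one vertical line per amino acid).
#'
#' @param L Protein length, >= 1.
#' @return Integer vector `1:L`.
#' @export
amino_acid_ticks <- function(L) {
  if (L < 1L) {
    abort("Protein length must be at least 1.")
  }
  seq_len(as.integer(L))
}

#' Peptide matches contributing to one residue position
#'
#' Returns every match whose interval covers residue `i` — the tabular
#' equivalent of inspecting a single position on an intensity trace.
#'
#' @param matches Match table from [map_peptides()].
#' @param i Residue position (1-based).
#' @param L Optional protein length for upper-bound validation.
#' @return The covering subset of `matches`.
#' @export
peptides_at_position <- function(matches, i, L = NULL) {
  if (i < 1L || (!is.null(L) && i > L)) {
    abort(paste0("Position ", i, " is outside the protein."))
  }
  matches[matches$start <= i & i <= matches$end, ]
}
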