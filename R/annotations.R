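# Predefined sequence-feature patterns. nglyco spans the whole N-X-S/T sequon
# (X any residue but proline); the protease patterns are point features at the
# residue N-terminal to the cut (K/R not before P for trypsin, F/W/Y not
# before P for chymotrypsin, E/D for Glu-C). chymotryptic and gluc are
# package-defined extras beyond the core motif set.
PREDEFINED_MOTIFS <- list(
  nglyco       = "N[^P][ST]",
  tryptic      = "[KR](?!P)",
  chymotryptic = "[FWY](?!P)",
  gluc         = "[ED]"
)

# Common PTM mass deltas (Da, rounded to the two decimals search engines
# print). Deamidation is the monoisotopic Asn -> Asp residue-mass difference
# left by PNGase F removal of N-glycans.
PTM_DELTAS <- c(
  deamidation      = 0.98,
  oxidation        = 15.99,
  carbamidomethyl  = 57.02,
  phospho          = 79.97,
  acetyl           = 42.01
)

#' Common PTM mass deltas
#'
#' The package's dictionary of common post-translational-modification
#' monoisotopic mass shifts, rounded to two decimals.
#'
#' @return A tibble with columns `name` and `mass_delta` (Da).
#' @export
ptm_library <- function() {
  tibble(name = names(PTM_DELTAS), mass_delta = unname(PTM_DELTAS))
}

new_annotation_track <- function(kind, features, label_default = "") {
  stopifnot(kind %in% c("motif", "ptm"))
  out <- as_tibble(features)
  structure(out, class = c("annotation_track", class(out)), kind = kind)
}

#' Locate sequence motifs on a protein
#'
#' Scans the sequence with a regular expression, reporting every match
#' including overlapping occurrences (the scan restarts one residue after
#' each match start). `pattern` may also name a predefined motif:
#' `"nglyco"` (the N-X-S/T N-glycosylation sequon, X != P), `"tryptic"`
#' (K/R not followed by P), `"chymotryptic"` (F/W/Y not followed by P) or
#' `"gluc"` (E/D).
#'
#' @param sequence Protein sequence string (or a one-row tibble from
#'   [read_fasta()]).
#' @param pattern Regex pattern or predefined motif name.
#' @param label Feature label; defaults to the predefined name or the
#'   pattern itself.
#' @return An `annotation_track` tibble (kind `"motif"`) with columns
#'   `start`, `end` (1-based inclusive), `label`, `mass_delta` (all `NA`).
#' @export
find_motifs <- function(sequence, pattern, label = NULL) {
  if (is.data.frame(sequence)) {
    sequence <- sequence$sequence[[1]]
  }
  if (pattern %in% names(PREDEFINED_MOTIFS)) {
    label <- label %||% pattern
    pattern <- PREDEFINED_MOTIFS[[pattern]]
  }
  label <- label %||% pattern
  ok <- tryCatch({suppressWarnings(grepl(pattern, "", perl = TRUE)); TRUE},
                 error = function(e) FALSE)
  if (!ok) {
    abort(paste0("Invalid regular expression: ", pattern))
  }
  L <- nchar(sequence)
  starts <- integer(0)
  ends <- integer(0)
  pos <- 1L
  while (pos <= L) {
    m <- regexpr(pattern, substr(sequence, pos, L), perl = TRUE)
    if (m == -1L) break
    len <- attr(m, "match.length")
    if (len < 1L) break # zero-length matches cannot form features
    start <- pos + as.integer(m) - 1L
    starts <- c(starts, start)
    ends <- c(ends, start + len - 1L)
    pos <- start + 1L
  }
  new_annotation_track("motif", tibble(
    start = starts, end = ends,
    label = rep(label, length(starts)),
    mass_delta = rep(NA_real_, length(starts))
  ))
}

#' Place search-reported PTMs at protein coordinates
#'
#' Lifts each peptide-level PTM onto the protein: for every placement of the
#' carrier peptide, the protein position is `match_start + offset - 1`.
#' Features are deduplicated across replicates and peptide forms by
#' (position, mass delta rounded to 0.01 Da); a peptide with several
#' placements yields one feature per placement.
#'
#' @param matches Match table from [map_peptides()].
#' @param table Observation table from [read_peptides()].
#' @return An `annotation_track` tibble (kind `"ptm"`) with `start == end`
#'   point features and their `mass_delta`.
#' @export
place_ptms <- function(matches, table) {
  has_ptm <- purrr::map_int(table$ptms, nrow) > 0L
  obs <- table[has_ptm, ]
  rows <- purrr::map2(obs$bare_sequence, obs$ptms, function(s, p) {
    hits <- matches[matches$bare_sequence == s, ]
    if (nrow(hits) == 0L) return(NULL)
    tidyr::crossing(start_match = hits$start, p) |>
      mutate(position = .data$start_match + .data$offset - 1L) |>
      select("position", "mass_delta", "name")
  })
  feats <- bind_rows(rows)
  if (nrow(feats) == 0L) {
    return(new_annotation_track("ptm", tibble(
      start = integer(0), end = integer(0), label = character(0),
      mass_delta = numeric(0))))
  }
  feats <- feats |>
    mutate(mass_delta = round(.data$mass_delta, 2)) |>
    group_by(.data$position, .data$mass_delta) |>
    summarise(label = {
      nm <- .data$name[nzchar(.data$name)]
      if (length(nm) > 0L) nm[[1]] else sprintf("%+.2f", .data$mass_delta[[1]])
    }, .groups = "drop") |>
    arrange(.data$position, .data$mass_delta)
  new_annotation_track("ptm", tibble(
    start = feats$position, end = feats$position,
    label = feats$label, mass_delta = feats$mass_delta
  ))
}

#' Positions where placed PTMs fall inside sequence motifs
#'
#' Intersects a PTM track with a motif track, optionally filtering PTMs by
#' mass delta. With the defaults this reports candidate N-glycosites:
#' deamidation (+0.98 Da) events inside an N-X-S/T sequon.
#'
#' @param ptms PTM `annotation_track` from [place_ptms()].
#' @param motifs Motif `annotation_track` from [find_motifs()].
#' @param mass_delta Mass filter centre (Da); `NULL` disables the filter.
#' @param tol Mass filter half-width (Da).
#' @return Sorted vector of unique protein positions.
#' @export
ptm_motif_intersection <- function(ptms, motifs, mass_delta = 0.98,
                                   tol = 0.01) {
  if (nrow(ptms) == 0L || nrow(motifs) == 0L) {
    return(integer(0))
  }
  keep <- ptms
  if (!is.null(mass_delta)) {
    keep <- keep[!is.na(keep$mass_delta) &
                   abs(keep$mass_delta - mass_delta) <= tol, ]
  }
  if (nrow(keep) == 0L) {
    return(integer(0))
  }
  inside <- purrr::map_lgl(keep$start, function(p) {
    any(motifs$start <= p & p <= motifs$end)
  })
  sort(unique(keep$start[inside]))
}
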