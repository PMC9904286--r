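# fixed number formatting for CSV export: 12 significant digits, stable under
# re-export (format(parse(format(x))) == format(x))
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 12, trim = TRUE, scientific = NA)
  }, character(1))
  out
}

write_view_csv <- function(df, path, meta) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0L) {
    cells <- purrr::map(df, function(col) {
      if (is.numeric(col)) fmt_num(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cells, sep = ",")), con)
  }
  invisible(path)
}

#' Export a view's backing data as CSV
#'
#' Every plottable result (profiles, overlays, differences, fold changes,
#' uniqueness tracks, stacked layouts, volcano tables, annotation tracks) can
#' be exported as a comma-delimited UTF-8 file: `#`-prefixed metadata lines
#' (accession, metric, group names, coordinate convention) followed by a
#' header row and one row per residue or per peptide. Numbers are written
#' with 12 significant digits, so export -> import -> export is
#' byte-identical.
#'
#' @param x A result object from this package.
#' @param path Output file path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path, ...) {
  UseMethod("export_csv")
}

base_meta <- function(x, view) {
  list(view = view,
       accession = attr(x, "accession") %||% "",
       metric = attr(x, "metric") %||% "",
       coordinates = "1-based inclusive residue positions")
}

#' @export
export_csv.residue_profile <- function(x, path, ...) {
  meta <- base_meta(x, "trace")
  meta$group <- attr(x, "group")
  df <- as_tibble(x)[, c("position", "residue", "value")]
  names(df)[3] <- attr(x, "group")
  write_view_csv(df, path, meta)
}

#' @export
export_csv.profile_overlay <- function(x, path, ...) {
  meta <- base_meta(x, "overlay")
  meta$groups <- paste(levels(x$group), collapse = ";")
  wide <- tidyr::pivot_wider(as_tibble(x), names_from = "group",
                             values_from = "value")
  write_view_csv(wide, path, meta)
}

#' @export
export_csv.difference_profile <- function(x, path, ...) {
  meta <- base_meta(x, "difference")
  meta$group <- attr(x, "group")
  meta$control <- attr(x, "control")
  write_view_csv(as_tibble(x), path, meta)
}

#' @export
export_csv.fold_change_profile <- function(x, path, ...) {
  meta <- base_meta(x, "foldchange")
  meta$group <- attr(x, "group")
  meta$control <- attr(x, "control")
  df <- as_tibble(x)
  df$ratio[!is.finite(df$ratio)] <- NA # flag column carries the sign
  df$flag <- as.character(df$flag)
  write_view_csv(df, path, meta)
}

#' @export
export_csv.uniqueness_track <- function(x, path, ...) {
  meta <- base_meta(x, "uniqueness")
  df <- as_tibble(x)
  df$class <- as.character(df$class)
  write_view_csv(df, path, meta)
}

#' @export
export_csv.stacked_layout <- function(x, path, ...) {
  meta <- base_meta(x, "stacked")
  meta$group <- attr(x, "group")
  meta$metric <- attr(x, "metric")
  write_view_csv(as_tibble(x), path, meta)
}

#' @export
export_csv.pep_volcano <- function(x, path, ...) {
  meta <- base_meta(x, "volcano")
  meta$group_a <- attr(x, "group_a")
  meta$group_b <- attr(x, "group_b")
  meta$metric <- attr(x, "metric")
  df <- as_tibble(x)
  df$flag <- dplyr::case_when(
    is.infinite(df$log2_fc) & df$log2_fc > 0 ~ "pos_inf",
    is.infinite(df$log2_fc) ~ "neg_inf",
    TRUE ~ "finite"
  )
  df$log2_fc[is.infinite(df$log2_fc)] <- NA
  write_view_csv(df, path, meta)
}

#' @export
export_csv.annotation_track <- function(x, path, accession = "", ...) {
  meta <- list(view = "annotation", kind = attr(x, "kind"),
               accession = accession,
               coordinates = "1-based inclusive residue positions")
  df <- tibble(accession = accession, start = x$start, end = x$end,
               label = x$label, delta = x$mass_delta)
  write_view_csv(df, path, meta)
}

#' Read back an exported view CSV
#'
#' Companion to [export_csv()]: skips the `#` metadata lines and returns the
#' data rows, with the metadata attached as the `"meta"` attribute.
#'
#' @param path File written by [export_csv()].
#' @return A tibble.
#' @export
read_export <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  meta <- stringr::str_match(meta_lines, "^# ([^:]+): (.*)$")
  out <- as_tibble(df)
  attr(out, "meta") <- setNames(as.list(meta[, 3]), meta[, 2])
  out
}
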