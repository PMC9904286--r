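# Colour conventions follow the field's figure style and are configurable in
# render_png(): green/red for positive/negative infinite fold changes, purple
# for motif annotations, orange for PTM features.
PLOT_COLORS <- list(
  pos_inf = "forestgreen", neg_inf = "firebrick",
  motif = "purple", ptm = "darkorange", ticks = "purple"
)

apply_y_scale <- function(p, y_scale) {
  if (identical(y_scale, "log")) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

# zeros become gaps on log axes
gap_zeros <- function(values, y_scale) {
  if (identical(y_scale, "log")) {
    values[values <= 0] <- NA
  }
  values
}

annotation_layers <- function(tracks, colors = PLOT_COLORS) {
  purrr::map(tracks, function(tr) {
    kind <- attr(tr, "kind") %||% "motif"
    col <- colors[[kind]] %||% "purple"
    if (nrow(tr) == 0L) {
      return(NULL)
    }
    positions <- unlist(purrr::map2(tr$start, tr$end, seq))
    ggplot2::geom_vline(xintercept = positions, colour = col,
                        alpha = if (kind == "ptm") 0.9 else 0.4,
                        linetype = if (kind == "ptm") "dashed" else "solid")
  })
}

#' @exportS3Method ggplot2::autoplot
autoplot.residue_profile <- function(object, y_scale = "linear",
                                     annotations = list(), ...) {
  df <- as_tibble(object)
  df$value <- gap_zeros(df$value, y_scale)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value)) +
    annotation_layers(annotations) +
    ggplot2::geom_step(colour = "steelblue", na.rm = TRUE) +
    ggplot2::labs(
      x = "Amino acid position",
      y = attr(object, "metric"),
      title = paste0(attr(object, "accession"), " — ",
                     attr(object, "group"))) +
    ggplot2::theme_minimal()
  apply_y_scale(p, y_scale)
}

#' @exportS3Method ggplot2::autoplot
autoplot.profile_overlay <- function(object, y_scale = "linear",
                                     annotations = list(), ...) {
  df <- as_tibble(object)
  df$value <- gap_zeros(df$value, y_scale)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                        colour = .data$group)) +
    annotation_layers(annotations) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::labs(x = "Amino acid position", y = attr(object, "metric"),
                  title = attr(object, "accession"), colour = "Group") +
    ggplot2::theme_minimal()
  apply_y_scale(p, y_scale)
}

#' @exportS3Method ggplot2::autoplot
autoplot.difference_profile <- function(object, annotations = list(), ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$difference)) +
    annotation_layers(annotations) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(
      x = "Amino acid position",
      y = paste0(attr(object, "metric"), " difference"),
      title = paste0(attr(object, "accession"), ": ", attr(object, "group"),
                     " − ", attr(object, "control"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fold_change_profile <- function(object, annotations = list(),
                                         colors = PLOT_COLORS, ...) {
  df <- as_tibble(object)
  df$flag <- as.character(df$flag)
  inf_rows <- df[df$flag %in% c("pos_inf", "neg_inf"), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$display_y)) +
    annotation_layers(annotations, colors) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
    ggplot2::geom_step(data = df[df$flag != "undefined", ], na.rm = TRUE,
                       colour = "grey40")
  if (nrow(inf_rows) > 0L) {
    p <- p +
      ggplot2::geom_point(
        data = inf_rows,
        ggplot2::aes(colour = .data$flag), size = 1.5, na.rm = TRUE) +
      ggplot2::scale_colour_manual(values = c(
        pos_inf = colors$pos_inf, neg_inf = colors$neg_inf))
  }
  p +
    ggplot2::labs(
      x = "Amino acid position",
      y = paste0(attr(object, "metric"), " fold change"),
      colour = "Infinite",
      title = paste0(attr(object, "accession"), ": ", attr(object, "group"),
                     " / ", attr(object, "control"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.uniqueness_track <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = 1,
                                   fill = .data$class)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_manual(values = c(
      uncovered = "grey85", unique = "steelblue",
      repeated_within = "goldenrod", shared_other = "firebrick"),
      drop = FALSE) +
    ggplot2::labs(x = "Amino acid position", y = NULL, fill = "Class",
                  title = attr(object, "accession")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.stacked_layout <- function(object, annotations = list(),
                                    show_ticks = TRUE, L = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df)
  if (show_ticks) {
    ticks <- amino_acid_ticks(L %||% max(c(df$end, 1L)))
    p <- p + ggplot2::geom_vline(xintercept = ticks,
                                 colour = PLOT_COLORS$ticks, alpha = 0.15)
  }
  p +
    annotation_layers(annotations) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start - 0.4, xend = .data$end + 0.4,
                   y = .data$level, yend = .data$level,
                   colour = .data$color_value),
      linewidth = 3, lineend = "butt") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "Amino acid position", y = "Stack level",
                  colour = attr(object, "metric"),
                  title = paste0("Stacked peptides — ",
                                 attr(object, "group"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pep_volcano <- function(object, p_threshold = 0.05,
                                 fc_threshold = 1, ...) {
  df <- as_tibble(object)
  finite <- df[is.finite(df$log2_fc) & !is.na(df$p_value), ]
  inf <- df[df$infinite, ]
  xmax <- if (nrow(finite) > 0L) max(abs(finite$log2_fc), 1) else 1
  ymax <- if (nrow(finite) > 0L) max(-log10(finite$p_value), 1) else 1
  inf$x <- ifelse(inf$log2_fc > 0, 1.25 * xmax, -1.25 * xmax)
  inf$y <- 1.05 * ymax
  p <- ggplot2::ggplot(finite,
                       ggplot2::aes(x = .data$log2_fc,
                                    y = -log10(.data$p_value))) +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_target), na.rm = TRUE)
  if (nrow(inf) > 0L) {
    p <- p + ggplot2::geom_point(
      data = inf, ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$in_target),
      shape = 17, na.rm = TRUE)
  }
  p +
    ggplot2::labs(
      x = paste0("log2 fold change (", attr(object, "group_a"), " / ",
                 attr(object, "group_b"), ")"),
      y = "-log10 p-value", colour = "On target",
      title = paste0("Peptide volcano: ", attr(object, "group_a"), " vs ",
                     attr(object, "group_b"))) +
    ggplot2::theme_minimal()
}

#' Render any view to a PNG file
#'
#' Dispatches to the view's `autoplot()` method and writes a static PNG at
#' the requested size and resolution. Fold-change views draw
#' negative-infinite residues at y = 0 in red and positive-infinite residues
#' at 1.25x the maximum finite value in green; annotation tracks are drawn as
#' vertical lines over any view; zeros become gaps on a log axis.
#'
#' @param x A plottable result object.
#' @param path Output PNG path.
#' @param width,height Plot size in inches.
#' @param dpi Resolution (default 300).
#' @param ... Passed to the view's `autoplot()` method (e.g. `y_scale`,
#'   `annotations`).
#' @return `path`, invisibly.
#' @export
render_png <- function(x, path, width = 10, height = 4, dpi = 300, ...) {
  if (is.null(attr(x, "class")) || !inherits(x, c(
    "residue_profile", "profile_overlay", "difference_profile",
    "fold_change_profile", "uniqueness_track", "stacked_layout",
    "pep_volcano"))) {
    abort(paste0("Don't know how to render an object of class ",
                 paste(class(x), collapse = "/"), "."))
  }
  p <- autoplot(x, ...)
  ggplot2::ggsave(path, plot = p, width = width, height = height,
                  dpi = dpi, device = "png")
  invisible(path)
}
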