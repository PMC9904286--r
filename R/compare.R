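check_comparable <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    abort("Profiles have different lengths and cannot be compared.")
  }
  if (!identical(attr(a, "accession"), attr(b, "accession"))) {
    abort("Profiles refer to different accessions.")
  }
  if (!identical(attr(a, "metric"), attr(b, "metric"))) {
    abort("Profiles use different metrics.")
  }
  invisible(TRUE)
}

#' Per-residue difference from a control profile
#'
#' Elementwise `a - control` across residues of two profiles of the same
#' protein and metric.
#'
#' @param a,control [residue_profile()] results; `control` is subtracted.
#' @return A tibble of class `difference_profile` with columns `position`,
#'   `residue` and `difference`.
#' @export
difference_profile <- function(a, control) {
  check_comparable(a, control)
  out <- tibble(position = a$position, residue = a$residue,
                difference = a$value - control$value)
  structure(out,
            class = c("difference_profile", class(out)),
            accession = attr(a, "accession"), metric = attr(a, "metric"),
            group = attr(a, "group"), control = attr(control, "group"))
}

FC_FLAGS <- c("finite", "pos_inf", "neg_inf", "undefined")

#' Per-residue fold change from a control profile
#'
#' Elementwise ratio `a / control` with the display conventions for
#' non-finite values: residues with signal only in `a` are positive-infinite
#' and displayed at 1.25 times the maximum finite plotted value (1.25 when no
#' finite ratio exists); residues with signal only in `control` are
#' negative-infinite and displayed at y = 0; residues with no signal in
#' either are undefined and rendered as gaps.
#'
#' @param a,control [residue_profile()] results; `control` is the denominator.
#' @return A tibble of class `fold_change_profile` with columns `position`,
#'   `residue`, `ratio` (may be `Inf`/`-Inf`/`NA`), `flag` (factor over
#'   finite/pos_inf/neg_inf/undefined) and `display_y` (finite; `NA` = gap).
#' @export
fold_change_profile <- function(a, control) {
  check_comparable(a, control)
  x <- a$value
  y <- control$value
  flag <- dplyr::case_when(
    x > 0 & y > 0 ~ "finite",
    x > 0 & y == 0 ~ "pos_inf",
    x == 0 & y > 0 ~ "neg_inf",
    TRUE ~ "undefined"
  )
  ratio <- dplyr::case_when(
    flag == "finite" ~ x / y,
    flag == "pos_inf" ~ Inf,
    flag == "neg_inf" ~ -Inf,
    TRUE ~ NA_real_
  )
  finite_vals <- ratio[flag == "finite"]
  pos_inf_y <- if (length(finite_vals) > 0L) 1.25 * max(finite_vals) else 1.25
  display_y <- dplyr::case_when(
    flag == "finite" ~ ratio,
    flag == "pos_inf" ~ pos_inf_y,
    flag == "neg_inf" ~ 0,
    TRUE ~ NA_real_
  )
  out <- tibble(position = a$position, residue = a$residue,
                ratio = ratio, flag = factor(flag, levels = FC_FLAGS),
                display_y = display_y)
  structure(out,
            class = c("fold_change_profile", class(out)),
            accession = attr(a, "accession"), metric = attr(a, "metric"),
            group = attr(a, "group"), control = attr(control, "group"),
            pos_inf_display = pos_inf_y)
}

#' Align several profiles into one long table for overlay plotting
#'
#' Stacks profiles of the same protein and metric into one long tibble, one
#' trace per group, preserving the input order. No arithmetic is performed.
#'
#' @param profiles List of [residue_profile()] results.
#' @return A tibble of class `profile_overlay` with columns `group`
#'   (factor, input order), `position`, `residue`, `value`.
#' @export
overlay_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  accs <- purrr::map_chr(profiles, attr, "accession")
  mets <- purrr::map_chr(profiles, attr, "metric")
  if (length(unique(accs)) != 1L) {
    abort("Cannot overlay profiles of different accessions.")
  }
  if (length(unique(mets)) != 1L) {
    abort("Cannot overlay profiles with different metrics.")
  }
  lens <- purrr::map_int(profiles, nrow)
  if (length(unique(lens)) != 1L) {
    abort("Cannot overlay profiles of different lengths.")
  }
  groups <- purrr::map_chr(profiles, attr, "group")
  out <- purrr::map2(profiles, groups, function(p, g) {
    tibble(group = g, position = p$position, residue = p$residue,
           value = p$value)
  }) |> bind_rows()
  out$group <- factor(out$group, levels = unique(groups))
  structure(out,
            class = c("profile_overlay", class(out)),
            accession = accs[[1]], metric = mets[[1]])
}
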