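# per-replicate metric value of each peptide (all modified forms summed)
# within one group; returns a list: bare_sequence -> numeric vector over the
# group's replicates (0 where unobserved)
replicate_value_matrix <- function(table, group, metric) {
  labels <- group$replicate_labels[[1]]
  sub <- table[table$replicate %in% labels,
               c("bare_sequence", "replicate", metric)]
  agg <- sub |>
    group_by(.data$bare_sequence, .data$replicate) |>
    summarise(value = sum(.data[[metric]]), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "replicate",
                             values_from = "value", values_fill = 0)
  missing <- setdiff(labels, names(wide))
  for (lab in missing) wide[[lab]] <- 0
  mat <- as.matrix(wide[, labels, drop = FALSE])
  rownames(mat) <- wide$bare_sequence
  mat
}

# Welch two-sided t-test on log2 values; both groups are guaranteed >= 2
# observations. When both groups have zero variance the statistic is
# undefined: equal means give p = 1 (no evidence of change), unequal means
# give NA (undefined rather than an out-of-domain p of 0).
welch_log2_p <- function(xa, xb) {
  la <- log2(xa)
  lb <- log2(xb)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else NA_real_)
  }
  stats::t.test(la, lb, var.equal = FALSE)$p.value
}

#' Peptide-level volcano comparison of two sample groups
#'
#' For every distinct bare peptide sequence observed in either group,
#' computes the log2 fold change of the mean metric over nonzero replicate
#' observations (group A over group B) and a two-sided Welch t-test p-value
#' on log2-transformed nonzero values when both groups have at least
#' `min_obs` nonzero observations. Peptides observed in exactly one group
#' carry an infinite fold change and no p-value. Peptides with enough
#' observations for the test in one group but not the other (>= 1 but <
#' `min_obs`) are flagged compromised.
#'
#' @param table Observation table from [read_peptides()].
#' @param groups Exactly two rows of [resolve_sample_groups()] output; the
#'   first is group A (numerator).
#' @param metric `"psm"`, `"intensity"` or `"area"`.
#' @param min_obs Minimum nonzero observations per group for the test
#'   (>= 2).
#' @param matches Optional match table from [map_peptides()]; peptides with
#'   at least one match are flagged `in_target`.
#' @param show_compromised Keep compromised rows (default) or drop them.
#' @param adjust `"none"` (default) or `"BH"` to append a
#'   Benjamini-Hochberg adjusted `q_value` column.
#' @return A tibble of class `pep_volcano`, one row per peptide:
#'   `bare_sequence`, `n_a`, `n_b` (nonzero observation counts), `mean_a`,
#'   `mean_b`, `log2_fc`, `p_value`, `infinite`, `compromised`, `in_target`.
#' @export
peptide_volcano <- function(table, groups, metric, min_obs = 2L,
                            matches = NULL, show_compromised = TRUE,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(groups) != 2L) {
    abort("A volcano comparison needs exactly two sample groups.")
  }
  if (min_obs < 2L) {
    abort("`min_obs` must be at least 2.")
  }
  if (!(metric %in% PEP_METRICS)) {
    abort(paste0("Unknown metric '", metric, "'."))
  }
  ma <- replicate_value_matrix(table, groups[1, ], metric)
  mb <- replicate_value_matrix(table, groups[2, ], metric)
  peptides <- union(rownames(ma), rownames(mb))
  rows <- purrr::map(peptides, function(s) {
    xa <- if (s %in% rownames(ma)) ma[s, ] else numeric(0)
    xb <- if (s %in% rownames(mb)) mb[s, ] else numeric(0)
    xa <- xa[xa > 0]
    xb <- xb[xb > 0]
    na <- length(xa)
    nb <- length(xb)
    if (na == 0L && nb == 0L) {
      return(NULL)
    }
    mean_a <- if (na > 0L) mean(xa) else NA_real_
    mean_b <- if (nb > 0L) mean(xb) else NA_real_
    log2_fc <- if (na > 0L && nb > 0L) {
      log2(mean_a / mean_b)
    } else if (na > 0L) Inf else -Inf
    p <- if (na >= min_obs && nb >= min_obs) {
      welch_log2_p(xa, xb)
    } else {
      NA_real_
    }
    tibble(
      bare_sequence = s, n_a = na, n_b = nb,
      mean_a = mean_a, mean_b = mean_b,
      log2_fc = log2_fc, p_value = p,
      infinite = xor(na == 0L, nb == 0L),
      compromised = xor(na >= min_obs, nb >= min_obs) && na >= 1L && nb >= 1L
    )
  })
  out <- bind_rows(rows)
  out$in_target <- if (!is.null(matches)) {
    out$bare_sequence %in% matches$bare_sequence
  } else {
    NA
  }
  if (adjust == "BH") {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  if (!show_compromised) {
    out <- out[!out$compromised, ]
  }
  out <- arrange(out, .data$bare_sequence)
  structure(out,
            class = c("pep_volcano", class(out)),
            group_a = groups$name[[1]], group_b = groups$name[[2]],
            metric = metric, min_obs = min_obs)
}

#' @exportS3Method generics::tidy
tidy.pep_volcano <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.pep_volcano <- function(x, ...) {
  tibble(
    group_a = attr(x, "group_a"),
    group_b = attr(x, "group_b"),
    metric = attr(x, "metric"),
    n_peptides = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
    n_infinite = sum(x$infinite),
    n_compromised = sum(x$compromised)
  )
}
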