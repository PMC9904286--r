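# Independent brute-force oracles and tiny in-code fixtures shared by the
# suite. These deliberately avoid the package's own code paths: profiles are
# recomputed by per-residue substring scans and motif hits by testing the
# pattern anchored at every start position.

# per-residue profile by scanning every position for every peptide
oracle_profile <- function(sequence, peptide_values) {
  L <- nchar(sequence)
  values <- numeric(L)
  for (i in seq_len(L)) {
    for (pep in names(peptide_values)) {
      w <- nchar(pep)
      # every occurrence covering residue i contributes once
      for (s in max(1L, i - w + 1L):i) {
        if (s + w - 1L <= L && substr(sequence, s, s + w - 1L) == pep) {
          values[i] <- values[i] + peptide_values[[pep]]
        }
      }
    }
  }
  values
}

# all (start, end) motif hits by testing the pattern anchored at each start
oracle_motifs <- function(sequence, pattern) {
  L <- nchar(sequence)
  hits <- list()
  for (i in seq_len(L)) {
    m <- regexpr(paste0("^(?:", pattern, ")"), substr(sequence, i, L),
                 perl = TRUE)
    if (m == 1L) {
      hits[[length(hits) + 1L]] <- c(i, i + attr(m, "match.length") - 1L)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  mat <- do.call(rbind, hits)
  data.frame(start = mat[, 1], end = mat[, 2])
}

random_aa_sequence <- function(L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, replace = TRUE),
        collapse = "")
}

make_protein <- function(sequence, accession = "TEST1") {
  tibble::tibble(accession = accession, description = "",
                 sequence = sequence, length = nchar(sequence))
}

empty_ptms <- function() {
  tibble::tibble(offset = integer(0), mass_delta = numeric(0),
                 name = character(0))
}

# build a pep_observations table by hand from (peptide, replicate, metrics)
make_obs <- function(df, labels = NULL) {
  df <- tibble::as_tibble(df)
  if (!("psm" %in% names(df))) df$psm <- 0
  if (!("intensity" %in% names(df))) df$intensity <- 0
  if (!("area" %in% names(df))) df$area <- 0
  if (!("raw_sequence" %in% names(df))) df$raw_sequence <- df$bare_sequence
  if (!("ptms" %in% names(df))) {
    df$ptms <- replicate(nrow(df), empty_ptms(), simplify = FALSE)
  }
  df <- df[, c("bare_sequence", "raw_sequence", "ptms", "replicate",
               "psm", "intensity", "area")]
  labels <- labels %||% unique(df$replicate)
  pepprofile:::as_pep_observations(df, "generic", labels)
}

# one-row sample-group tibble without going through regex resolution
make_group <- function(name, labels, combine = "sum") {
  tibble::tibble(name = name, pattern = name, combine = combine,
                 replicate_labels = list(labels),
                 n_replicates = length(labels))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random small analysis problem used by the property suites
random_case <- function(seed, L = 40L, n_peptides = 6L) {
  withr::with_seed(seed, {
    sequence <- random_aa_sequence(L)
    peps <- unique(replicate(n_peptides, {
      w <- sample(3:8, 1)
      s <- sample(L - w + 1L, 1)
      substr(sequence, s, s + w - 1L)
    }))
    labels <- c("a_1", "a_2", "b_1")
    rows <- expand.grid(bare_sequence = peps, replicate = labels,
                        stringsAsFactors = FALSE)
    rows$area <- round(stats::rlnorm(nrow(rows), 5, 1), 3)
    rows$psm <- 1 + stats::rpois(nrow(rows), 2)
    rows$intensity <- round(stats::rlnorm(nrow(rows), 3, 1), 3)
    list(protein = make_protein(sequence), table = make_obs(rows),
         group = make_group("a", c("a_1", "a_2")))
  })
}
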