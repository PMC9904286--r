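AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the fixture generator. The defaults emulate a small
#' label-free bottom-up experiment: a three-protein database, tryptic-like
#' peptides, two groups of three replicates with log-normally distributed
#' abundances, no regional effects, no PTMs and no dropout.
#'
#' @param seed Integer seed; fully determines the generated files.
#' @param n_proteins Number of database entries (the first is the target).
#' @param protein_length_range Length range (residues) to sample from.
#' @param n_peptides_per_protein Peptides sampled per protein.
#' @param replicate_groups Named integer vector: replicates per group.
#' @param meanlog,sdlog Log-normal abundance model for the intensity and
#'   area metrics, per observation. May be a single value or one per group.
#' @param effects Optional tibble/data.frame with columns `group`, `start`,
#'   `end`, `effect`: observations of target peptides whose origin interval
#'   overlaps \[start, end\] are multiplied by `effect` in that group.
#' @param ptms Optional tibble with columns `position` (target protein
#'   coordinate), `mass_delta`, `name`, `probability`: each target peptide
#'   covering `position` carries the PTM with that probability.
#' @param dropout Probability that a (peptide, replicate) observation is
#'   dropped (all metrics zero).
#' @param digestion `"tryptic"` (cut after K/R, up to `missed_cleavages`
#'   missed cuts) or `"nonspecific"` (uniform random substrings, the
#'   HDX-style use case).
#' @param missed_cleavages Maximum missed cleavages for tryptic digestion.
#' @param peptide_length_range Acceptable peptide lengths.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_proteins = 3L,
                           protein_length_range = c(150L, 250L),
                           n_peptides_per_protein = 40L,
                           replicate_groups = c(ctrl = 3L, trt = 3L),
                           meanlog = 14, sdlog = 0.3,
                           effects = NULL,
                           ptms = NULL,
                           dropout = 0,
                           digestion = c("tryptic", "nonspecific"),
                           missed_cleavages = 2L,
                           peptide_length_range = c(5L, 30L)) {
  digestion <- match.arg(digestion)
  stopifnot(dropout >= 0, dropout <= 1, n_proteins >= 1L,
            length(replicate_groups) >= 1L,
            !is.null(names(replicate_groups)))
  if (!is.null(ptms) && any(ptms$probability < 0 | ptms$probability > 1)) {
    abort("PTM probabilities must be in [0, 1].")
  }
  if (peptide_length_range[1] > protein_length_range[1]) {
    abort("Minimum peptide length exceeds the minimum protein length.")
  }
  structure(list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    protein_length_range = protein_length_range,
    n_peptides_per_protein = as.integer(n_peptides_per_protein),
    replicate_groups = replicate_groups,
    meanlog = meanlog, sdlog = sdlog,
    effects = if (is.null(effects)) NULL else as_tibble(effects),
    ptms = if (is.null(ptms)) NULL else as_tibble(ptms),
    dropout = dropout, digestion = digestion,
    missed_cleavages = as.integer(missed_cleavages),
    peptide_length_range = peptide_length_range
  ), class = "fixture_config")
}

random_protein <- function(length_range) {
  lo <- length_range[1]
  hi <- length_range[2]
  L <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  paste(sample(AA20, L, replace = TRUE), collapse = "")
}

# candidate fragments of one protein: tryptic (cut after K/R, with missed
# cleavages) or uniform random substrings
candidate_fragments <- function(sequence, config) {
  L <- nchar(sequence)
  lo <- config$peptide_length_range[1]
  hi <- config$peptide_length_range[2]
  if (config$digestion == "tryptic") {
    chars <- strsplit(sequence, "")[[1]]
    cuts <- which(chars %in% c("K", "R"))
    bounds <- unique(c(0L, cuts, L))
    frags <- list()
    for (i in seq_len(length(bounds) - 1L)) {
      for (mc in 0:config$missed_cleavages) {
        j <- i + 1L + mc
        if (j > length(bounds)) break
        s <- bounds[i] + 1L
        e <- bounds[j]
        if (e - s + 1L >= lo && e - s + 1L <= hi) {
          frags[[length(frags) + 1L]] <- c(s, e)
        }
      }
    }
    if (length(frags) == 0L) {
      return(tibble(start = integer(0), end = integer(0)))
    }
    mat <- do.call(rbind, frags)
    tibble(start = as.integer(mat[, 1]), end = as.integer(mat[, 2]))
  } else {
    n <- max(200L, 4L * config$n_peptides_per_protein)
    len <- sample(lo:min(hi, L), n, replace = TRUE)
    start <- purrr::map_int(len, ~ sample.int(L - .x + 1L, 1L))
    tibble(start = start, end = start + len - 1L)
  }
}

#' Generate a complete synthetic fixture
#'
#' Writes a random protein database (FASTA), one peptide table per supported
#' search-engine dialect, and ground-truth CSVs into a directory. Peptides
#' are sampled from each protein (tryptic-like or nonspecific), per-replicate
#' abundances are drawn log-normally, multiplied by any configured regional
#' effects, and zeroed by dropout. The ground truth contains the exact
#' expected per-residue profile of the target protein for every group and
#' metric (computed by a naive per-residue loop), so pipeline output can be
#' checked against it exactly. The same seed yields byte-identical files.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return A list with the written `paths`, the `proteins` tibble, the
#'   canonical `observations` table, the `ground_truth` profile tibble and
#'   the `config`.
#' @export
generate_fixture <- function(config = fixture_config(), dir = tempfile("fixture")) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, {
    proteins <- tibble(
      accession = sprintf("P%05d", seq_len(config$n_proteins)),
      description = c("synthetic target protein",
                      rep("synthetic decoy protein",
                          config$n_proteins - 1L))[seq_len(config$n_proteins)],
      sequence = purrr::map_chr(seq_len(config$n_proteins),
                                ~ random_protein(config$protein_length_range))
    )
    proteins$length <- nchar(proteins$sequence)

    peptides <- purrr::map2(proteins$accession, proteins$sequence,
                            function(acc, seq) {
      frags <- candidate_fragments(seq, config)
      if (nrow(frags) == 0L) {
        return(NULL)
      }
      take <- sample.int(nrow(frags),
                         min(config$n_peptides_per_protein, nrow(frags)))
      out <- frags[take, ]
      out$accession <- acc
      out$bare_sequence <- substr(rep(seq, nrow(out)), out$start, out$end)
      out
    }) |> bind_rows() |> distinct(.data$bare_sequence, .keep_all = TRUE)

    observations <- simulate_observations(peptides, proteins, config)
  })

  target <- proteins[1, ]
  ground_truth <- ground_truth_profiles(target, observations, config)

  paths <- list(fasta = file.path(dir, "database.fasta"))
  write_fasta(proteins, paths$fasta)
  for (d in PEP_DIALECTS) {
    ext <- if (dialect_spec(d)$delim == "\t") ".tsv" else ".csv"
    paths[[d]] <- file.path(dir, paste0("peptides_", d, ext))
    write_peptides(observations, paths[[d]], d)
  }
  paths$ground_truth <- file.path(dir, "ground_truth_profiles.csv")
  utils::write.csv(ground_truth, paths$ground_truth, row.names = FALSE)
  if (!is.null(config$effects)) {
    paths$effects <- file.path(dir, "true_effects.csv")
    utils::write.csv(config$effects, paths$effects, row.names = FALSE)
  }
  list(paths = paths, proteins = proteins, observations = observations,
       ground_truth = ground_truth, config = config)
}

simulate_observations <- function(peptides, proteins, config) {
  groups <- names(config$replicate_groups)
  meanlog <- rep_len(config$meanlog, length(groups))
  sdlog <- rep_len(config$sdlog, length(groups))
  target_acc <- proteins$accession[[1]]

  # decide PTM carriage per peptide (target coordinates)
  pep_ptms <- purrr::pmap(peptides, function(start, end, accession,
                                             bare_sequence, ...) {
    out <- tibble(offset = integer(0), mass_delta = numeric(0),
                  name = character(0))
    if (is.null(config$ptms) || accession != target_acc) {
      return(out)
    }
    for (k in seq_len(nrow(config$ptms))) {
      p <- config$ptms[k, ]
      if (p$position >= start && p$position <= end &&
          stats::runif(1) < p$probability) {
        out <- bind_rows(out, tibble(offset = as.integer(p$position - start + 1L),
                                     mass_delta = p$mass_delta,
                                     name = p$name))
      }
    }
    out
  })

  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (r in seq_len(config$replicate_groups[[g]])) {
      label <- paste0(g, "_", r)
      for (k in seq_len(nrow(peptides))) {
        if (stats::runif(1) < config$dropout) next
        eff <- 1
        if (!is.null(config$effects) && peptides$accession[k] == target_acc) {
          hit <- config$effects$group == g &
            config$effects$start <= peptides$end[k] &
            peptides$start[k] <= config$effects$end
          if (any(hit)) {
            eff <- prod(config$effects$effect[hit])
          }
        }
        area <- stats::rlnorm(1, meanlog[gi], sdlog[gi]) * eff
        intensity <- stats::rlnorm(1, meanlog[gi] - 2, sdlog[gi]) * eff
        psm <- 1L + stats::rpois(1, 2)
        rows[[length(rows) + 1L]] <- tibble(
          bare_sequence = peptides$bare_sequence[k],
          replicate = label,
          psm = psm, intensity = round(intensity, 4),
          area = round(area, 4),
          ptms = list(pep_ptms[[k]])
        )
      }
    }
  }
  obs <- bind_rows(rows)
  if (nrow(obs) == 0L) {
    obs <- tibble(bare_sequence = character(0), replicate = character(0),
                  psm = numeric(0), intensity = numeric(0),
                  area = numeric(0), ptms = list())
  }
  obs$raw_sequence <- purrr::map2_chr(obs$bare_sequence, obs$ptms,
                                      render_modified_sequence)
  obs <- obs[, c("bare_sequence", "raw_sequence", "ptms", "replicate",
                 "psm", "intensity", "area")]
  labels <- unlist(purrr::map(groups, function(g) {
    paste0(g, "_", seq_len(config$replicate_groups[[g]]))
  }))
  as_pep_observations(obs, "generic", labels)
}

# exact expected profile of the target, by a naive per-residue loop over all
# substring occurrences of each observed peptide
ground_truth_profiles <- function(target, observations, config) {
  seq <- target$sequence[[1]]
  L <- nchar(seq)
  groups <- names(config$replicate_groups)
  out <- list()
  for (g in groups) {
    labels <- paste0(g, "_", seq_len(config$replicate_groups[[g]]))
    for (metric in PEP_METRICS) {
      totals <- observations[observations$replicate %in% labels, ] |>
        group_by(.data$bare_sequence) |>
        summarise(value = sum(.data[[metric]]), .groups = "drop")
      values <- numeric(L)
      for (k in seq_len(nrow(totals))) {
        pep <- totals$bare_sequence[k]
        w <- nchar(pep)
        for (s in seq_len(L - w + 1L)) {
          if (substr(seq, s, s + w - 1L) == pep) {
            idx <- s:(s + w - 1L)
            values[idx] <- values[idx] + totals$value[k]
          }
        }
      }
      out[[length(out) + 1L]] <- tibble(
        group = g, metric = metric, position = seq_len(L),
        value = values)
    }
  }
  bind_rows(out)
}

# re-render a bare sequence + PTM table in parenthetical mass-delta notation
render_modified_sequence <- function(bare, ptms) {
  if (is.null(ptms) || nrow(ptms) == 0L) {
    return(bare)
  }
  chars <- strsplit(bare, "")[[1]]
  ptms <- ptms[order(ptms$offset), ]
  out <- character(0)
  for (i in seq_along(chars)) {
    out <- c(out, chars[i])
    for (k in which(ptms$offset == i)) {
      out <- c(out, sprintf("(%+.2f)", ptms$mass_delta[k]))
    }
  }
  paste(out, collapse = "")
}

#' Write an observation table in a search-engine dialect
#'
#' Serializes a canonical observation table into any supported dialect's
#' file shape (the same shapes [read_peptides()] reads). Modified peptides
#' are rendered in parenthetical mass-delta notation. Wide dialects write one
#' column set per replicate label with 0 for unobserved cells; metrics a
#' dialect has no column for are omitted.
#'
#' @param table Observation table.
#' @param path Output path.
#' @param dialect One of the supported dialect names.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(table, path, dialect) {
  spec <- dialect_spec(dialect)
  labels <- replicate_labels(table)
  tab <- table
  tab$raw_out <- purrr::map2_chr(tab$bare_sequence, tab$ptms,
                                 render_modified_sequence)
  if (dialect == "proteome_discoverer") {
    tab$raw_out <- paste0("-.", tab$raw_out, ".-")
  }
  if (spec$long) {
    df <- data.frame(
      peptide = tab$raw_out, sample = tab$replicate,
      psm = tab$psm, intensity = tab$intensity, area = tab$area,
      ptm = character(nrow(tab)), check.names = FALSE,
      stringsAsFactors = FALSE)
  } else {
    forms <- distinct(tibble(raw_out = tab$raw_out))
    df <- data.frame(forms$raw_out, stringsAsFactors = FALSE,
                     check.names = FALSE)
    names(df) <- spec$sequence
    if (dialect == "metamorpheus") {
      df[["Base Sequence"]] <- purrr::map_chr(
        forms$raw_out, ~ parse_modified_sequence(.x)$bare_sequence)
    }
    if (dialect == "msfragger") {
      df[["Protein"]] <- character(nrow(df))
    }
    for (lab in labels) {
      for (m in PEP_METRICS) {
        pat <- spec$metrics[[m]]
        if (is.na(pat)) next
        col <- wide_metric_column(pat, lab)
        vals <- numeric(nrow(forms))
        sub <- tab[tab$replicate == lab, ]
        idx <- match(sub$raw_out, forms$raw_out)
        vals[idx[!is.na(idx)]] <- sub[[m]][!is.na(idx)]
        df[[col]] <- vals
      }
    }
  }
  utils::write.table(df, path, sep = spec$delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# invert a wide metric regex like "^(.+) Spectral Count$" into a column name
wide_metric_column <- function(pattern, label) {
  core <- sub("^\\^", "", sub("\\$$", "", pattern))
  sub("(.+)", label, core, fixed = TRUE)
}

#' Two-domain fusion fixture
#'
#' Builds the classic two-domain demonstration: a fusion protein whose
#' N-terminal half is one domain and C-terminal half another, with one sample
#' group containing only peptides from the N-terminal half and the other only
#' peptides from the C-terminal half. Each group's profile is therefore zero
#' on the opposite half.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param half_length Residues per domain.
#' @param n_peptides Peptides sampled per domain (>= 1 guaranteed).
#' @param n_replicates Replicates per group.
#' @return Same structure as [generate_fixture()], with groups `nterm` and
#'   `cterm`.
#' @export
two_domain_fusion_fixture <- function(seed = 1L, dir = tempfile("fusion"),
                                      half_length = 150L, n_peptides = 20L,
                                      n_replicates = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- fixture_config(
    seed = seed, n_proteins = 1L,
    protein_length_range = c(2L * half_length, 2L * half_length),
    n_peptides_per_protein = n_peptides,
    replicate_groups = c(nterm = n_replicates, cterm = n_replicates))
  withr::with_seed(seed, {
    sequence <- random_protein(config$protein_length_range)
    proteins <- tibble(accession = "FUSION01",
                       description = "synthetic two-domain fusion protein",
                       sequence = sequence, length = nchar(sequence))
    frags <- candidate_fragments(sequence, config)
    nterm <- frags[frags$end <= half_length, ]
    cterm <- frags[frags$start > half_length, ]
    if (nrow(nterm) == 0L || nrow(cterm) == 0L) {
      abort("Fusion fixture could not place peptides in both halves; use a longer half_length.")
    }
    pick <- function(frg) frg[sample.int(nrow(frg), min(n_peptides, nrow(frg))), ]
    pep <- bind_rows(
      mutate(pick(nterm), domain = "nterm"),
      mutate(pick(cterm), domain = "cterm")
    )
    pep$accession <- "FUSION01"
    pep$bare_sequence <- substr(rep(sequence, nrow(pep)), pep$start, pep$end)
    pep <- distinct(pep, .data$bare_sequence, .keep_all = TRUE)
    # keep only peptides whose every placement stays inside their own half,
    # so each group's profile is zero on the opposite half by construction
    pure <- purrr::map2_lgl(pep$bare_sequence, pep$domain, function(s, d) {
      starts <- find_all_substrings(sequence, s)
      ends <- starts + nchar(s) - 1L
      if (d == "nterm") all(ends <= half_length) else all(starts > half_length)
    })
    pep <- pep[pure, ]
    if (!all(c("nterm", "cterm") %in% pep$domain)) {
      abort("Fusion fixture could not place peptides in both halves; use a longer half_length.")
    }
    rows <- list()
    for (g in c("nterm", "cterm")) {
      sub <- pep[pep$domain == g, ]
      for (r in seq_len(n_replicates)) {
        for (k in seq_len(nrow(sub))) {
          area <- stats::rlnorm(1, config$meanlog, config$sdlog)
          rows[[length(rows) + 1L]] <- tibble(
            bare_sequence = sub$bare_sequence[k],
            raw_sequence = sub$bare_sequence[k],
            ptms = list(tibble(offset = integer(0), mass_delta = numeric(0),
                               name = character(0))),
            replicate = paste0(g, "_", r),
            psm = 1L + stats::rpois(1, 2),
            intensity = round(area / 10, 4), area = round(area, 4))
        }
      }
    }
    observations <- as_pep_observations(
      bind_rows(rows), "generic",
      c(paste0("nterm_", seq_len(n_replicates)),
        paste0("cterm_", seq_len(n_replicates))))
  })
  ground_truth <- ground_truth_profiles(proteins[1, ], observations, config)
  paths <- list(fasta = file.path(dir, "database.fasta"),
                generic = file.path(dir, "peptides_generic.csv"))
  write_fasta(proteins, paths$fasta)
  write_peptides(observations, paths$generic, "generic")
  list(paths = paths, proteins = proteins, observations = observations,
       ground_truth = ground_truth, config = config,
       half_length = half_length)
}
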