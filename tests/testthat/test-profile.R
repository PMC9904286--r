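obs3 <- function() {
  make_obs(tibble::tibble(
    bare_sequence = c("KVQ", "KVQ", "KVQ"),
    replicate = c("ctrl_1", "ctrl_2", "trt_1"),
    area = c(5, 7, 2)))
}

test_that("sample groups resolve by regex search with clear errors", {
  tab <- obs3()
  g <- resolve_sample_groups(tab, c(ctrl = "ctrl"))
  expect_equal(g$replicate_labels[[1]], c("ctrl_1", "ctrl_2"))
  g2 <- resolve_sample_groups(tab, c(trt = "^trt_[0-9]+$"))
  expect_equal(g2$replicate_labels[[1]], "trt_1")
  expect_error(resolve_sample_groups(tab, c(bad = "xyz")), "No replicates matched")
  expect_error(resolve_sample_groups(tab, c(bad = "([")), "regular expression")
  expect_warning(resolve_sample_groups(tab, c(all = "_", ctrl = "ctrl")),
                 "multiple groups")
  expect_error(resolve_sample_groups(tab, c(a = "ctrl", a = "trt")), "unique")
})

test_that("peptides map to every occurrence, overlapping included", {
  prot <- make_protein("MKVQKVQ")
  m <- map_peptides(prot, make_obs(tibble::tibble(
    bare_sequence = "KVQ", replicate = "s1", area = 1)))
  expect_equal(m$start, c(2L, 5L))
  expect_equal(m$end, c(4L, 7L))
  expect_equal(m$occurrence, c(1L, 2L))

  prot2 <- make_protein("AAAA")
  m2 <- map_peptides(prot2, make_obs(tibble::tibble(
    bare_sequence = "AAA", replicate = "s1", area = 1)))
  expect_equal(m2$start, c(1L, 2L))
  expect_equal(m2$end, c(3L, 4L))

  m3 <- map_peptides(make_protein("MKVQ"), make_obs(tibble::tibble(
    bare_sequence = "WWW", replicate = "s1", area = 1)))
  expect_equal(nrow(m3), 0L)
})

test_that("residue profiles sum covering peptide group values", {
  prot <- make_protein("MKVQWE")
  tab <- make_obs(tibble::tibble(
    bare_sequence = "KVQ", replicate = "s1", area = 10))
  m <- map_peptides(prot, tab)
  prof <- residue_profile(prot, m, tab, make_group("g", "s1"), "area")
  expect_equal(prof$value, c(0, 10, 10, 10, 0, 0))
  expect_equal(prof$residue, strsplit("MKVQWE", "")[[1]])

  # overlapping intervals: (1,3) value 5 and (3,5) value 7
  prot2 <- make_protein("MKVQWE")
  tab2 <- make_obs(tibble::tibble(
    bare_sequence = c("MKV", "VQW"), replicate = "s1", area = c(5, 7)))
  m2 <- map_peptides(prot2, tab2)
  prof2 <- residue_profile(prot2, m2, tab2, make_group("g", "s1"), "area")
  expect_equal(prof2$value, c(5, 5, 12, 7, 7, 0))
})

test_that("combine=mean divides by all group replicates, missing counted as 0", {
  prot <- make_protein("MKVQ")
  tab <- make_obs(tibble::tibble(
    bare_sequence = "MKVQ", replicate = "s1", area = 3),
    labels = c("s1", "s2"))
  m <- map_peptides(prot, tab)
  prof <- residue_profile(prot, m, tab,
                          make_group("g", c("s1", "s2"), combine = "mean"),
                          "area")
  expect_equal(unique(prof$value), 1.5)
  expect_error(residue_profile(prot, m, tab, make_group("g", "s1"), "xyz"),
               "xyz")
})

test_that("profiles match the brute-force per-residue oracle on random cases", {
  for (seed in 1:30) {
    cs <- random_case(seed)
    m <- map_peptides(cs$protein, cs$table)
    prof <- residue_profile(cs$protein, m, cs$table, cs$group, "area")
    vals <- pepprofile:::peptide_group_values(cs$table, cs$group, "area")
    expected <- oracle_profile(cs$protein$sequence,
                               setNames(vals$value, vals$bare_sequence))
    expect_equal(prof$value, expected, info = paste("seed", seed))
  }
})

test_that("summed profiles conserve total peptide signal times match length", {
  for (seed in 31:45) {
    cs <- random_case(seed)
    m <- map_peptides(cs$protein, cs$table)
    prof <- residue_profile(cs$protein, m, cs$table, cs$group, "area")
    vals <- pepprofile:::peptide_group_values(cs$table, cs$group, "area")
    joined <- dplyr::left_join(m, vals, by = "bare_sequence")
    expect_equal(sum(prof$value),
                 sum(joined$value * (joined$end - joined$start + 1)),
                 info = paste("seed", seed))
  }
})

test_that("adding an observation never decreases the profile or coverage", {
  cs <- random_case(99)
  m <- map_peptides(cs$protein, cs$table)
  prof <- residue_profile(cs$protein, m, cs$table, cs$group, "area")
  cov <- sequence_coverage(m, nchar(cs$protein$sequence))
  extra <- make_obs(dplyr::bind_rows(
    tibble::as_tibble(cs$table),
    tibble::tibble(bare_sequence = substr(cs$protein$sequence, 1, 6),
                   raw_sequence = substr(cs$protein$sequence, 1, 6),
                   ptms = list(empty_ptms()),
                   replicate = "a_1", psm = 1, intensity = 1, area = 50)),
    labels = replicate_labels(cs$table))
  m2 <- map_peptides(cs$protein, extra)
  prof2 <- residue_profile(cs$protein, m2, extra, cs$group, "area")
  expect_true(all(prof2$value >= prof$value))
  expect_gte(sequence_coverage(m2, nchar(cs$protein$sequence)), cov)
})

test_that("with a single replicate, sum and mean profiles coincide", {
  cs <- random_case(7)
  m <- map_peptides(cs$protein, cs$table)
  g1 <- make_group("a", "a_1", combine = "sum")
  g2 <- make_group("a", "a_1", combine = "mean")
  expect_equal(residue_profile(cs$protein, m, cs$table, g1, "area")$value,
               residue_profile(cs$protein, m, cs$table, g2, "area")$value)
})

test_that("sequence coverage is the covered fraction of residues", {
  m1 <- tibble::tibble(bare_sequence = "X", start = 1L, end = 5L,
                       occurrence = 1L)
  expect_equal(sequence_coverage(m1, 10L), 50)
  m2 <- tibble::tibble(bare_sequence = c("X", "Y"), start = c(1L, 3L),
                       end = c(5L, 8L), occurrence = c(1L, 1L))
  expect_equal(sequence_coverage(m2, 10L), 80)
  expect_equal(sequence_coverage(m2[0, ], 10L), 0)
  # invariant to duplicating a match, bounded
  expect_equal(sequence_coverage(dplyr::bind_rows(m2, m2[1, ]), 10L), 80)
  for (seed in 1:5) {
    cs <- random_case(seed)
    cov <- sequence_coverage(map_peptides(cs$protein, cs$table),
                             nchar(cs$protein$sequence))
    expect_gte(cov, 0)
    expect_lte(cov, 100)
  }
})

test_that("uniqueness classes follow the shared > repeated > unique precedence", {
  # single-protein proteome, single occurrence: unique
  prot <- make_protein("MKVQWE")
  tab <- make_obs(tibble::tibble(bare_sequence = "KVQ", replicate = "s1",
                                 area = 1))
  m <- map_peptides(prot, tab)
  u <- classify_uniqueness(prot, prot, m, tab)
  expect_equal(as.character(u$class),
               c("uncovered", "unique", "unique", "unique", "uncovered",
                 "uncovered"))

  # repeated within the target only
  prot2 <- make_protein("MKVQKVQ")
  m2 <- map_peptides(prot2, tab)
  u2 <- classify_uniqueness(prot2, prot2, m2, tab)
  expect_equal(as.character(u2$class[2:4]), rep("repeated_within", 3))

  # shared with a decoy wins even where a unique peptide overlaps
  target <- make_protein("MKVQWE", "T1")
  decoy <- make_protein("AAKVQAA", "D1")
  proteome <- dplyr::bind_rows(target, decoy)
  tab3 <- make_obs(tibble::tibble(bare_sequence = c("KVQ", "VQWE"),
                                  replicate = "s1", area = 1))
  m3 <- map_peptides(target, tab3)
  u3 <- classify_uniqueness(target, proteome, m3, tab3)
  expect_equal(as.character(u3$class),
               c("uncovered", "shared_other", "shared_other", "shared_other",
                 "unique", "unique"))
  expect_error(classify_uniqueness(target, decoy, m3, tab3), "missing")
})

test_that("uncovered residues are exactly those with no covering match", {
  cs <- random_case(55)
  m <- map_peptides(cs$protein, cs$table)
  u <- classify_uniqueness(cs$protein, cs$protein, m, cs$table)
  L <- nchar(cs$protein$sequence)
  covered <- logical(L)
  for (k in seq_len(nrow(m))) covered[m$start[k]:m$end[k]] <- TRUE
  expect_equal(u$class == "uncovered", !covered)
})
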