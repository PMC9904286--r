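small_analysis <- function() {
  prot <- make_protein("MKV")
  tab <- make_obs(tibble::tibble(bare_sequence = "KV", replicate = "s1",
                                 area = 10))
  m <- map_peptides(prot, tab)
  list(protein = prot, table = tab, matches = m,
       profile = residue_profile(prot, m, tab, make_group("g", "s1"), "area"))
}

test_that("profile export writes one row per residue with metadata header", {
  sa <- small_analysis()
  f <- withr::local_tempfile(fileext = ".csv")
  export_csv(sa$profile, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "# accession: TEST1")))
  back <- read_export(f)
  expect_equal(back$position, 1:3)
  expect_equal(back$residue, c("M", "K", "V"))
  expect_equal(back$g, c(0, 10, 10))
})

test_that("export -> import -> export is byte-identical across view types", {
  sa <- small_analysis()
  fc <- fold_change_profile(sa$profile, sa$profile)
  lay <- stack_peptides(sa$matches, sa$table, make_group("g", "s1"), "area")
  views <- list(sa$profile, difference_profile(sa$profile, sa$profile), fc, lay)
  for (v in views) {
    f1 <- withr::local_tempfile(fileext = ".csv")
    export_csv(v, f1)
    back <- read_export(f1)
    # re-export the parsed numbers through the same formatter
    f2 <- withr::local_tempfile(fileext = ".csv")
    reread <- utils::read.csv(text = paste(readLines(f1)[
      !startsWith(readLines(f1), "# ")], collapse = "\n"),
      check.names = FALSE)
    body1 <- readLines(f1)[!startsWith(readLines(f1), "# ")]
    pepprofile:::write_view_csv(tibble::as_tibble(reread), f2, list(x = 1))
    body2 <- readLines(f2)[!startsWith(readLines(f2), "# ")]
    expect_identical(body1, body2)
  }
})

test_that("volcano export flags infinite rows and leaves p empty", {
  rows <- tibble::tibble(bare_sequence = c("AAA", "AAA", "BBB", "BBB"),
                         replicate = c("a_1", "a_2", "a_1", "a_2"),
                         area = c(5, 6, 7, 8))
  tab <- make_obs(rows, labels = c("a_1", "a_2", "b_1", "b_2"))
  groups <- dplyr::bind_rows(make_group("A", c("a_1", "a_2")),
                             make_group("B", c("b_1", "b_2")))
  v <- peptide_volcano(tab, groups, "area")
  f <- withr::local_tempfile(fileext = ".csv")
  export_csv(v, f)
  back <- read_export(f)
  expect_true(all(back$flag == "pos_inf"))
  expect_true(all(is.na(back$p_value)))
  expect_true(all(is.na(back$log2_fc)))
})

test_that("annotation tracks export as BED-like CSV", {
  tr <- find_motifs("ANVSANCS", "nglyco")
  f <- withr::local_tempfile(fileext = ".csv")
  export_csv(tr, f, accession = "T1")
  back <- read_export(f)
  expect_equal(names(back), c("accession", "start", "end", "label", "delta"))
  expect_equal(back$start, c(2L, 6L)) # ANVSA.. and ..NCS sequons
})

test_that("render_png writes a valid deterministic PNG and tolerates log axes", {
  sa <- small_analysis()
  f <- withr::local_tempfile(fileext = ".png")
  render_png(sa$profile, f, width = 5, height = 3, dpi = 96)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 0)
  magic <- readBin(f, "raw", 8)
  expect_identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                   0x0d, 0x0a, 0x1a, 0x0a)))
  # zero-valued residue on a log axis becomes a gap, no crash
  f2 <- withr::local_tempfile(fileext = ".png")
  expect_no_error(render_png(sa$profile, f2, width = 5, height = 3,
                             dpi = 96, y_scale = "log"))
  # determinism of pixel dimensions
  f3 <- withr::local_tempfile(fileext = ".png")
  render_png(sa$profile, f3, width = 5, height = 3, dpi = 96)
  d1 <- dim(png::readPNG(f))
  d3 <- dim(png::readPNG(f3))
  expect_identical(d1, d3)
  expect_error(render_png(tibble::tibble(x = 1), f), "render")
})

test_that("every view renders and exports", {
  sa <- small_analysis()
  ov <- overlay_profiles(list(sa$profile))
  uq <- classify_uniqueness(sa$protein, sa$protein, sa$matches, sa$table)
  lay <- stack_peptides(sa$matches, sa$table, make_group("g", "s1"), "area")
  rows <- tibble::tibble(bare_sequence = "KV",
                         replicate = c("a_1", "a_2", "b_1", "b_2"),
                         area = c(5, 6, 7, 8))
  tab <- make_obs(rows)
  v <- peptide_volcano(tab, dplyr::bind_rows(
    make_group("A", c("a_1", "a_2")), make_group("B", c("b_1", "b_2"))),
    "area", matches = sa$matches)
  views <- list(sa$profile, ov, difference_profile(sa$profile, sa$profile),
                fold_change_profile(sa$profile, sa$profile), uq, lay, v)
  for (vw in views) {
    fp <- withr::local_tempfile(fileext = ".png")
    fc <- withr::local_tempfile(fileext = ".csv")
    expect_no_error(render_png(vw, fp, width = 4, height = 3, dpi = 72))
    expect_no_error(export_csv(vw, fc))
    expect_gt(file.size(fp), 0)
    expect_gt(length(readLines(fc)), 1L)
  }
})
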