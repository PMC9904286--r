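volcano_case <- function(a_vals, b_vals, peptide = "MKVQR") {
  rows <- dplyr::bind_rows(
    tibble::tibble(bare_sequence = peptide,
                   replicate = paste0("a_", seq_along(a_vals)),
                   area = a_vals),
    tibble::tibble(bare_sequence = peptide,
                   replicate = paste0("b_", seq_along(b_vals)),
                   area = b_vals))
  labels <- c(paste0("a_", seq_along(a_vals)), paste0("b_", seq_along(b_vals)))
  tab <- make_obs(rows, labels = labels)
  groups <- dplyr::bind_rows(make_group("A", paste0("a_", seq_along(a_vals))),
                             make_group("B", paste0("b_", seq_along(b_vals))))
  peptide_volcano(tab, groups, "area")
}

test_that("log2 fold change is the log ratio of nonzero-observation means", {
  v <- volcano_case(c(4, 4), c(1, 1))
  expect_equal(v$log2_fc, 2)
  expect_equal(c(v$n_a, v$n_b), c(2L, 2L))
})

test_that("one-sided presence yields an infinite flag and no p-value", {
  rows <- tibble::tibble(bare_sequence = "MKVQR",
                         replicate = c("a_1", "a_2", "a_3"), area = 5)
  tab <- make_obs(rows, labels = c("a_1", "a_2", "a_3", "b_1", "b_2"))
  groups <- dplyr::bind_rows(make_group("A", paste0("a_", 1:3)),
                             make_group("B", paste0("b_", 1:2)))
  v <- peptide_volcano(tab, groups, "area")
  expect_true(v$infinite)
  expect_equal(v$log2_fc, Inf)
  expect_true(is.na(v$p_value))
})

test_that("identical groups give zero fold change and p = 1", {
  v <- volcano_case(c(2, 8, 4), c(2, 8, 4))
  expect_equal(v$log2_fc, 0)
  expect_equal(v$p_value, 1)
  expect_false(v$infinite)
  expect_false(v$compromised)
})

test_that("swapping the groups flips log2_fc and keeps the p-value", {
  withr::with_seed(21, {
    a <- round(stats::rlnorm(4, 5, 0.5), 3)
    b <- round(stats::rlnorm(5, 6, 0.5), 3)
  })
  v1 <- volcano_case(a, b)
  rows <- dplyr::bind_rows(
    tibble::tibble(bare_sequence = "MKVQR",
                   replicate = paste0("a_", seq_along(b)), area = b),
    tibble::tibble(bare_sequence = "MKVQR",
                   replicate = paste0("b_", seq_along(a)), area = a))
  tab <- make_obs(rows)
  groups <- dplyr::bind_rows(make_group("A", paste0("a_", seq_along(b))),
                             make_group("B", paste0("b_", seq_along(a))))
  v2 <- peptide_volcano(tab, groups, "area")
  expect_equal(v1$log2_fc, -v2$log2_fc)
  expect_equal(v1$p_value, v2$p_value)
})

test_that("compromised peptides have enough observations on one side only", {
  v <- volcano_case(c(4, 6, 5), c(3))
  expect_true(v$compromised)
  expect_false(v$infinite)
  expect_true(is.na(v$p_value))
  expect_equal(nrow(volcano_case(c(4, 6, 5), c(3)) |>
                      (\(x) x[!x$compromised, ])()), 0L)
  # the emission flag drops them entirely
  rows <- dplyr::bind_rows(
    tibble::tibble(bare_sequence = "MKVQR", replicate = paste0("a_", 1:3),
                   area = c(4, 6, 5)),
    tibble::tibble(bare_sequence = "MKVQR", replicate = "b_1", area = 3))
  tab <- make_obs(rows)
  groups <- dplyr::bind_rows(make_group("A", paste0("a_", 1:3)),
                             make_group("B", "b_1"))
  v2 <- peptide_volcano(tab, groups, "area", show_compromised = FALSE)
  expect_equal(nrow(v2), 0L)
})

test_that("volcano validates its inputs", {
  expect_error(volcano_case(c(4, 4), c(1, 1)) |> attr("nothing"), NA)
  rows <- tibble::tibble(bare_sequence = "MKVQR", replicate = "a_1", area = 1)
  tab <- make_obs(rows)
  g <- make_group("A", "a_1")
  expect_error(peptide_volcano(tab, g, "area"), "two sample groups")
  expect_error(peptide_volcano(tab, dplyr::bind_rows(g, make_group("B", "a_1")),
                               "area", min_obs = 1), "min_obs")
})

test_that("in_target reflects peptide matches and glance counts add up", {
  prot <- make_protein("MKVQRWE")
  rows <- dplyr::bind_rows(
    tibble::tibble(bare_sequence = "MKVQR", replicate = c("a_1", "a_2", "b_1", "b_2"),
                   area = c(4, 5, 1, 2)),
    tibble::tibble(bare_sequence = "CCCC", replicate = c("a_1", "a_2", "b_1", "b_2"),
                   area = c(9, 9, 9, 9)))
  tab <- make_obs(rows)
  groups <- dplyr::bind_rows(make_group("A", c("a_1", "a_2")),
                             make_group("B", c("b_1", "b_2")))
  m <- map_peptides(prot, tab)
  v <- peptide_volcano(tab, groups, "area", matches = m)
  expect_equal(v$in_target[v$bare_sequence == "MKVQR"], TRUE)
  expect_equal(v$in_target[v$bare_sequence == "CCCC"], FALSE)
  g <- glance(v)
  expect_equal(g$n_peptides, 2L)
  expect_equal(g$n_tested, 2L)
  expect_s3_class(tidy(v), "tbl_df")
})

test_that("Welch p agrees with a permutation test on equal-variance groups", {
  withr::with_seed(77, {
    a <- stats::rlnorm(8, 5, 0.4)
    b <- stats::rlnorm(8, 5.4, 0.4)
  })
  v <- volcano_case(round(a, 4), round(b, 4))
  la <- log2(round(a, 4))
  lb <- log2(round(b, 4))
  pooled <- c(la, lb)
  obs_t <- abs(stats::t.test(la, lb)$statistic)
  withr::with_seed(78, {
    perm <- replicate(4000, {
      idx <- sample(16, 8)
      abs(stats::t.test(pooled[idx], pooled[-idx])$statistic)
    })
  })
  p_perm <- mean(perm >= obs_t)
  expect_lt(abs(v$p_value - p_perm), 0.05)
})
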