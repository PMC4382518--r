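test_that("a toy Stockholm cohort reads back the stated 3b.3n pairs", {
  path <- withr::local_tempfile(fileext = ".sto")
  write_toy_stockholm(path, pairs = c("AG", "GC", "CG"))
  cmap <- stockholm_column_map(kt7_kturn())
  sites <- read_stockholm_cohort(path, cmap)
  expect_length(sites, 3L)
  codes <- vapply(sites, function(s) kturnfold:::pair_code(pair_at(s, 3)),
                  character(1))
  expect_identical(codes, c("AG", "GC", "CG"))
})

test_that("gap rows are flagged unclassifiable, never dropped", {
  path <- withr::local_tempfile(fileext = ".sto")
  kts <- write_toy_stockholm(path, pairs = c("AG", "AG"))
  lines <- readLines(path)
  cmap <- stockholm_column_map(kt7_kturn())
  # punch a gap at the 3n column of row2 (12-char name field + one space)
  col3n <- 13 + cmap[["3n"]]
  substr(lines[4], col3n, col3n) <- "-"
  writeLines(lines, path)
  sites <- read_stockholm_cohort(path, cmap)
  tab <- tabulate_pairs(sites)
  expect_identical(tab$total, 2L)
  expect_identical(unname(tab$counts[["unclassifiable"]]), 1L)
  expect_identical(unname(tab$counts[["AG"]]), 1L)
})

test_that("Stockholm reader errors carry context", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "row1 ACGU ACGU extra", "//"), path)
  expect_error(read_stockholm_cohort(path, c(`3b` = 1, `3n` = 2)),
               regexp = "line 2")
  writeLines(c("not stockholm", "row1 ACGU"), path)
  expect_error(read_stockholm_cohort(path, c(`3b` = 1, `3n` = 2)),
               class = "kt_format_error")
  write_toy_stockholm(path)
  expect_error(read_stockholm_cohort(path, c(`3b` = 9, `3n` = 1000000)),
               class = "kt_config_error")
  expect_error(read_stockholm_cohort(path, c(`3b` = 9)),
               class = "kt_config_error")
})

test_that("multi-block Stockholm rows are concatenated", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "row1 GGCGAAGAACC", "row2 GGCGAAGAGCC", "",
               "row1 GGGGAGCC", "row2 GGCGAGCC", "//"), path)
  cmap <- stockholm_column_map(kt7_kturn())
  sites <- read_stockholm_cohort(path, cmap)
  codes <- vapply(sites, function(s) kturnfold:::pair_code(pair_at(s, 3)),
                  character(1))
  expect_identical(codes, c("AG", "GC"))
})

test_that("tabulate_pairs counts exactly and handles the empty cohort", {
  cohort <- c(lapply(1:6, function(i) substitute_pair(kt7_kturn(), "A", "G")),
              lapply(1:3, function(i) substitute_pair(kt7_kturn(), "G", "C")),
              list(structure(list(name = "gap", bases = c(`3b` = "A", `3n` = "-")),
                             class = "kturn_site")))
  tab <- tabulate_pairs(cohort)
  expect_identical(unname(tab$counts[["AG"]]), 6L)
  expect_identical(unname(tab$counts[["GC"]]), 3L)
  expect_identical(unname(tab$counts[["unclassifiable"]]), 1L)
  expect_identical(tab$total, 10L)
  expect_identical(sum(tab$counts), tab$total)

  empty <- tabulate_pairs(list())
  expect_identical(sum(empty$counts), 0L)
  expect_identical(empty$total, 0L)
  expect_error(summarize_cohort(empty), class = "kt_empty_error")
})

test_that("summarize_cohort fractions match hand arithmetic and sum to 1", {
  cohort <- c(lapply(1:6, function(i) substitute_pair(kt7_kturn(), "A", "G")),
              lapply(1:3, function(i) substitute_pair(kt7_kturn(), "G", "C")),
              list(substitute_pair(kt7_kturn(), "C", "A")))
  s <- summarize_cohort(tabulate_pairs(cohort))
  expect_equal(s$frac_AG, 0.6)
  expect_equal(s$frac_nonfolders, 0.3)
  expect_equal(s$frac_folders, 0.7)
  expect_equal(s$frac_folders + s$frac_nonfolders + s$frac_indeterminate +
                 s$frac_unclassifiable, 1)

  only_gu <- list(substitute_pair(kt7_kturn(), "G", "U"))
  expect_equal(summarize_cohort(tabulate_pairs(only_gu))$frac_nonfolders, 1.0)
})

test_that("delegation consistency: cohort fractions equal per-sequence classification", {
  cohort <- generate_cohort(sam_like_profile(), 300, seed = 13)
  s <- summarize_cohort(tabulate_pairs(cohort))
  klass <- vapply(cohort, function(k) classify_pair(pair_at(k, 3))$klass,
                  character(1))
  expect_equal(s$frac_nonfolders, mean(klass == "non_folder"))
  expect_equal(s$frac_folders, mean(klass == "ion_folder"))
})

test_that("folding_spectrum ranks folders first by default and preserves counts", {
  cohort <- generate_cohort(sam_like_profile(), 500, seed = 21)
  tab <- tabulate_pairs(cohort)
  spec <- folding_spectrum(tab)
  expect_lt(which(spec$code == "AG"), which(spec$code == "GC"))
  expect_identical(spec$klass[1:6], rep("ion_folder", 6))
  expect_identical(sum(spec$count), tab$total)

  rev_rank <- rev(default_pair_ranking())
  spec_rev <- folding_spectrum(tab, ranking = rev_rank)
  expect_identical(spec_rev$code[1:16], rev_rank)
  expect_identical(sort(spec_rev$count), sort(spec$count))
  expect_error(folding_spectrum(tab, ranking = rep("AG", 16)),
               class = "kt_config_error")
})

test_that("determinism: identical inputs give identical tables", {
  path <- withr::local_tempfile(fileext = ".sto")
  write_toy_stockholm(path, pairs = c("AG", "GC", "UU", "CA"))
  cmap <- stockholm_column_map(kt7_kturn())
  t1 <- tabulate_pairs(read_stockholm_cohort(path, cmap))
  t2 <- tabulate_pairs(read_stockholm_cohort(path, cmap))
  expect_identical(t1$counts, t2$counts)
})

test_that("column maps load from plain config files", {
  path <- withr::local_tempfile(lines = c("# map", "3b=9", "3n=14"))
  cmap <- read_column_map(path)
  expect_identical(cmap, c(`3b` = 9L, `3n` = 14L))
  bad <- withr::local_tempfile(lines = "3b nine")
  expect_error(read_column_map(bad), class = "kt_config_error")
})
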