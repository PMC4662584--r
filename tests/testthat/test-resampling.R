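test_that("rarefying to the full depth is the identity", {
  expect_identical(rarefy_counts(c(a = 80L, b = 20L), 100),
                   c(a = 80L, b = 20L))
})

test_that("rarefied draws follow the hypergeometric expectation", {
  set.seed(1)
  draws <- replicate(10000, rarefy_counts(c(80, 20), 10)[1])
  m <- 10 * 80 / 100
  v <- 10 * 0.8 * 0.2 * (100 - 10) / (100 - 1)
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 10000))
  expect_true(all(draws <= 80))
})

test_that("absent taxa stay absent and excess depth errors", {
  set.seed(2)
  expect_identical(rarefy_counts(c(0, 50), 10)[1], 0L)
  expect_error(rarefy_counts(c(5, 5), 11), "only 10 reads")
})

test_that("table rarefaction hits the target depth or errors by sample", {
  tab <- separated_table()
  r <- rarefy_table(tab, 100, seed = 1)
  expect_true(all(colSums(r$counts) == 100L))
  expect_true(all(r$counts <= tab$counts))
  expect_error(rarefy_table(tab, 10000), "P1")
  same_depth <- taxon_count_table(make_counts(c(6, 4), c("a", "b"), "s1"))
  expect_identical(rarefy_table(same_depth, 10)$counts, same_depth$counts)
})

test_that("group pooling is additive and conserves totals", {
  tab <- tiny_table()
  tab <- suppressMessages(attach_metadata(tab, tiny_metadata()))
  pools <- pool_by_group(tab)
  expect_identical(unname(pools[, "productive"]), c(5L, 3L, 2L))
  expect_identical(sum(pools), sum(tab$counts))
  expect_error(pool_by_group(tiny_table()), "metadata")
})

test_that("in-silico libraries sum to L and stay within the pool", {
  pool <- c(Orbaceae = 7000L, Bifido = 2000L, firm4 = 900L, rare = 100L)
  libs <- insilico_libraries(pool, resampling_config(L = 1000, N = 400, seed = 1))
  expect_identical(dim(libs), c(400L, 4L))
  expect_true(all(rowSums(libs) == 1000L))
  expect_true(all(t(libs) <= pool))
  # with-replacement libraries are multinomial and may exceed rare pool counts
  wr <- insilico_libraries(pool, resampling_config(L = 1000, N = 400,
                                                   replacement = TRUE, seed = 1))
  expect_true(all(rowSums(wr) == 1000L))
  expect_error(insilico_libraries(c(a = 10L), resampling_config(L = 11)),
               "exceeds pool")
})

test_that("a single-taxon pool yields constant libraries with zero-width CI", {
  libs <- insilico_libraries(c(only = 500L), resampling_config(L = 100, N = 20, seed = 1))
  expect_true(all(libs == 100L))
  ci <- percentile_ci(libs)
  expect_equal(ci$lower, ci$upper)
})

test_that("percentile bounds follow the type-7 interpolation rule", {
  m <- cbind(u = 0:99, c = rep(7L, 100))
  ci <- percentile_ci(m, 0.95)
  expect_equal(ci$lower[ci$taxon == "u"], 2.475)   # 2.5th percentile, type 7
  expect_equal(ci$upper[ci$taxon == "u"], 96.525)
  expect_equal(ci[ci$taxon == "c", c("lower", "upper")],
               data.frame(lower = 7, upper = 7, row.names = 2L))
  expect_error(percentile_ci(m[1, , drop = FALSE]), "at least 2")
  expect_error(percentile_ci(m, 1.0), "strictly between")
})

test_that("interval overlap verdicts use strict disjointness", {
  ci <- function(taxon, lower, upper) data.frame(taxon, lower, upper)
  r <- ci_overlap_test(ci("t", 10, 20), ci("t", 30, 40))
  expect_true(r$flagged)
  # a shared endpoint counts as overlap
  r <- ci_overlap_test(ci("t", 10, 30), ci("t", 30, 40))
  expect_false(r$flagged)
  r <- ci_overlap_test(ci("t", 30, 40), ci("t", 10, 20))
  expect_true(r$flagged)
  expect_error(ci_overlap_test(ci("t", 1, 2), ci("s", 1, 2)), "different taxa")
})

test_that("resampling configuration rejects invalid parameters", {
  expect_error(resampling_config(N = 0), "N")
  expect_error(resampling_config(ci_level = 1), "strictly between")
})

test_that("group resampling CIs are reproducible and written as long TSV", {
  tab <- separated_table()
  cfg <- resampling_config(L = 200, N = 50, seed = 7)
  ci1 <- group_resampling_ci(tab, cfg)
  ci2 <- group_resampling_ci(tab, cfg)
  expect_identical(ci1, ci2)
  expect_true(ci1$flagged[ci1$taxon == "marker"])
  path <- tempfile()
  write_resampling_ci(ci1, path, seed = 7)
  back <- read.delim(path, comment.char = "#")
  expect_identical(nrow(back), 2L * nrow(ci1))
  expect_identical(readLines(path, 1), "# seed=7")
})
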