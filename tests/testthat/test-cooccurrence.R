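test_that("rho is exact on monotone, antitone and hand-computed cases", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_rho(1:5, c(10, 8, 6, 4, 2))$rho, -1, tolerance = 1e-12)
  # d^2 shortcut on untied data: 1 - 6*8 / (5*24)
  expect_equal(spearman_rho(1:5, c(3, 1, 2, 5, 4))$rho, 0.6, tolerance = 1e-12)
})

test_that("input contracts: length, size, constancy", {
  expect_error(spearman_rho(1:5, 1:4), "equal length")
  expect_error(spearman_rho(1:3, 3:1), "at least 4")
  expect_error(spearman_rho(rep(2, 5), 1:5), "constant")
})

test_that("exact permutation p at n = 5 matches independent enumeration", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(3, 1, 2, 5, 4)
  s <- spearman_rho(x, y)
  expect_identical(s$method, "exact permutation")
  # oracle: every permutation via expand.grid filtering, d^2 formula (no ties)
  P <- oracle_perms(5)
  rho_all <- apply(P, 1, function(idx) {
    d <- rank(x) - rank(y)[idx]
    1 - 6 * sum(d^2) / (5 * 24)
  })
  p_oracle <- mean(abs(rho_all) >= abs(0.6) - 1e-12)
  expect_equal(s$p, p_oracle, tolerance = 1e-12)
  # tied data: oracle switches to mid-rank Pearson over the same enumeration
  yt <- c(2, 2, 1, 5, 4)
  st <- spearman_rho(x, yt)
  rho_t <- apply(P, 1, function(idx) cor(rank(x), rank(yt)[idx]))
  expect_equal(st$p, mean(abs(rho_t) >= abs(st$rho) - 1e-12), tolerance = 1e-12)
})

test_that("large-sample p uses the t approximation and matches cor.test", {
  set.seed(8)
  x <- rnorm(14); y <- x + rnorm(14)
  s <- spearman_rho(x, y)
  expect_identical(s$method, "t approximation")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  t <- s$rho * sqrt(12 / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(t), 12), tolerance = 1e-12)
})

test_that("two taxa at fixed depth are perfectly anticorrelated", {
  set.seed(9)
  a <- as.integer(sample(10:90, 8))
  counts <- rbind(a = a, b = 100L - a)
  colnames(counts) <- paste0("s", 1:8)
  cm <- correlation_matrix(taxon_count_table(counts))
  expect_equal(cm$rho["a", "b"], -1, tolerance = 1e-12)
})

test_that("correlation matrices are symmetric, bounded, constant-taxa-safe", {
  tab <- separated_table()
  tab$counts <- rbind(tab$counts, flat = rep(4L, 14))
  expect_warning(cm <- correlation_matrix(tab), "flat")
  expect_identical(cm$skipped, "flat")
  expect_equal(cm$rho, t(cm$rho))
  expect_true(all(abs(cm$rho) <= 1, na.rm = TRUE))
  expect_true(all(is.na(diag(cm$rho))))
})

test_that("network edges respect the significance threshold", {
  tab <- separated_table()
  cm <- correlation_matrix(tab)
  expect_identical(nrow(build_network(cm, p_threshold = 0)$edges), 0L)
  nw <- build_network(cm, p_threshold = 1.0000001)
  expect_identical(nrow(nw$edges), 6L)
  expect_true(all(nw$edges$source < nw$edges$target))
  expect_equal(nw$edges$r_squared, nw$edges$rho^2, tolerance = 1e-12)
  expect_identical(nw$edges$sign, ifelse(nw$edges$rho >= 0, "positive", "negative"))
  nwbh <- build_network(cm, p_threshold = 0.05, adjust = "BH")
  expect_lte(nrow(nwbh$edges), nrow(build_network(cm, 0.05)$edges))
})

test_that("the edge set is invariant to sample order", {
  tab <- separated_table()
  perm <- sample(seq_len(14))
  tab2 <- tab
  tab2$counts <- tab2$counts[, perm]
  tab2$metadata <- tab2$metadata[perm, ]
  e1 <- build_network(correlation_matrix(tab))$edges
  e2 <- build_network(correlation_matrix(tab2))$edges
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("edge tables round-trip through TSV and SIF export lists signs", {
  tab <- separated_table()
  nw <- build_network(correlation_matrix(tab), p_threshold = 1.0000001)
  path <- tempfile()
  export_edges(nw, path)
  expect_identical(readLines(path, 1),
                   "source\ttarget\trho\tp\tr_squared\tsign")
  back <- read_edges(path, p_threshold = nw$p_threshold)
  expect_equal(back$edges, nw$edges, tolerance = 1e-12)
  expect_identical(back$nodes, sort(nw$nodes))
  sif <- tempfile()
  export_sif(nw, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(nw$edges))
  expect_true(all(grepl("\tcorr_(pos|neg)\t", lines)))
})
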