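test_that("generic TSV reads with preserved order and validated counts", {
  path <- write_tiny_tsv()
  tab <- read_count_table(path)
  expect_s3_class(tab, "taxon_count_table")
  expect_identical(as.integer(colSums(tab$counts)), c(10L, 20L))
  expect_identical(rownames(tab$counts), c("Gilliamella", "Frischella", "firm-4"))
  expect_identical(colnames(tab$counts), c("P1", "U1"))
})

test_that("malformed files and invalid cells are rejected with locations", {
  bad <- tempfile()
  writeLines(c("taxon\tP1\tU1", "Gilliamella\t5\t-4"), bad)
  expect_error(read_count_table(bad), "Gilliamella.*U1", ignore.case = TRUE)
  writeLines(c("taxon\tP1", "Gilliamella\t2.5"), bad)
  expect_error(read_count_table(bad), "not a non-negative integer")
  writeLines("justone", bad)
  expect_error(read_count_table(bad), "malformed header")
  expect_error(read_count_table(tempfile()), "no such file")
  writeLines(c("wrong\theader\there", "a\t1\t2"), bad)
  expect_error(read_count_table(bad, format = "mothur"), "mothur")
})

test_that("write/read round-trips are lossless in both dialects", {
  tab <- tiny_table()
  for (fmt in c("generic", "mothur")) {
    path <- tempfile(fileext = ".tsv")
    write_count_table(tab, path, format = fmt)
    back <- read_count_table(path, format = fmt)
    expect_identical(back$counts, tab$counts)
  }
})

test_that("tables without taxa cannot be constructed or written", {
  empty <- matrix(integer(0), nrow = 0, ncol = 1,
                  dimnames = list(NULL, "s1"))
  expect_error(taxon_count_table(empty), "no taxa")
  broken <- tiny_table()
  broken$counts <- broken$counts[0, , drop = FALSE]
  expect_error(write_count_table(broken, tempfile()), "0 taxa")
})

test_that("constructor enforces the count-table invariants", {
  expect_error(taxon_count_table(make_counts(c(1, -1), c("a", "b"), "s1")),
               "non-negative")
  expect_error(taxon_count_table(make_counts(c(1, 0), c("a", "a"), "s1")),
               "duplicated taxon")
  expect_error(taxon_count_table(
    matrix(c(1L, 0L, 1L, 0L), 2, dimnames = list(c("a", "b"), c("s", "s")))),
    "duplicated sample")
  expect_error(taxon_count_table(
    matrix(c(1L, 0L, 0L, 0L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))),
    "zero total")
})

test_that("metadata attaches with reported group sizes of 7 and 7", {
  ids <- c(paste0("P", 1:7), paste0("U", 1:7))
  counts <- make_counts(rep(1, 14), "Gilliamella", ids)
  counts <- rbind(counts, make_counts(rep(2, 14), "firm-4", ids))
  tab <- taxon_count_table(counts)
  expect_message(tab <- attach_metadata(tab, tiny_metadata(ids)),
                 "productive = 7.*unproductive = 7")
  expect_identical(as.integer(table(sample_groups(tab))), c(7L, 7L))
})

test_that("metadata mismatches are surfaced by sample id", {
  tab <- tiny_table()
  md <- tiny_metadata(c("P1", "U1", "X9"))
  expect_warning(attach_metadata(tab, md), "X9")
  expect_error(attach_metadata(tab, tiny_metadata("P1")), "U1")
  md_bad <- tiny_metadata(); md_bad$productivity[1] <- "middling"
  expect_error(attach_metadata(tab, md_bad), "P1")
})

test_that("aggregation sums children and conserves per-sample totals", {
  tab <- tiny_table()
  map <- c(Gilliamella = "Orbaceae", Frischella = "Orbaceae",
           "firm-4" = "Lactobacillaceae")
  fam <- aggregate_taxa(tab, map, "family")
  expect_identical(unname(fam$counts["Orbaceae", ]), c(8L, 10L))
  expect_identical(colSums(fam$counts), colSums(tab$counts))
  expect_identical(fam$level, "family")
  # Gilliamella and Frischella fold into a single Orbaceae row
  expect_identical(sum(rownames(fam$counts) == "Orbaceae"), 1L)
  # identity map leaves the table unchanged
  idmap <- setNames(rownames(tab$counts), rownames(tab$counts))
  expect_identical(aggregate_taxa(tab, idmap, tab$level)$counts, tab$counts)
  expect_error(aggregate_taxa(tab, map[-1]), "Gilliamella")
})
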