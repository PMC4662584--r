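# Small in-code fixtures shared across test files.

make_counts <- function(m, taxa, samples) {
  matrix(as.integer(m), nrow = length(taxa),
         dimnames = list(taxa, samples))
}

# 3 taxa x 2 samples with column sums 10 and 20
tiny_table <- function() {
  taxon_count_table(make_counts(c(5, 3, 2, 10, 0, 10),
                                c("Gilliamella", "Frischella", "firm-4"),
                                c("P1", "U1")))
}

tiny_metadata <- function(ids = c("P1", "U1")) {
  data.frame(sample_id = ids,
             apiary = paste0("A", seq_along(ids)),
             productivity = ifelse(grepl("^P", ids), "productive", "unproductive"),
             stringsAsFactors = FALSE)
}

write_tiny_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("taxon\tP1\tU1",
               "Gilliamella\t5\t10",
               "Frischella\t3\t0",
               "firm-4\t2\t10"), path)
  path
}

# grouped table with a hard group separation on one taxon
separated_table <- function(seed = 11) {
  set.seed(seed)
  n <- 14
  counts <- rbind(
    marker = c(rpois(7, 400), rpois(7, 40)),
    filler1 = rpois(n, 100),
    filler2 = rpois(n, 100),
    filler3 = rpois(n, 100))
  colnames(counts) <- c(paste0("P", 1:7), paste0("U", 1:7))
  storage.mode(counts) <- "integer"
  taxon_count_table(counts, metadata = tiny_metadata(colnames(counts)))
}

# independent permutation generator for oracles (lexicographic, via expand.grid)
oracle_perms <- function(n) {
  g <- do.call(expand.grid, rep(list(seq_len(n)), n))
  as.matrix(g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE])
}
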