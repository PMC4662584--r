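# Rarefaction and pooled in-silico library resampling.
#
# Without-replacement draws are sequential conditional hypergeometric: taxon
# by taxon, the number of reads taken is rhyper() given what remains of the
# pool and of the library.  Exact and memory-light for 10^5-read pools.

rmvhyper <- function(counts, L) {
  K <- sum(counts)
  out <- integer(length(counts))
  remK <- K
  remL <- as.integer(L)
  for (i in seq_along(counts)) {
    if (remL == 0L) break
    k <- counts[i]
    x <- rhyper(1, k, remK - k, remL)
    out[i] <- x
    remL <- remL - x
    remK <- remK - k
  }
  out
}

#' Rarefy a count vector to a fixed library size
#'
#' Draws `L` reads without replacement (multivariate hypergeometric), so the
#' result sums to `L` exactly and no taxon exceeds its input count.
#'
#' @param counts non-negative integer vector.
#' @param L target library size, `<= sum(counts)`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return integer vector, same names as `counts`.
#' @export
rarefy_counts <- function(counts, L, seed = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (L > total)
    stop("cannot rarefy to L = ", L, ": only ", total, " reads available")
  if (L == total) return(setNames(as.integer(counts), names(counts)))
  setNames(with_seed(seed, rmvhyper(as.integer(counts), L)), names(counts))
}

#' Rarefy every sample of a count table to a common depth
#'
#' @param table a `taxon_count_table`; every column sum must be `>= L`.
#' @param L target depth (default 10,000 reads per colony).
#' @param seed optional root seed; per-sample streams are derived from it.
#' @return a `taxon_count_table` in which every column sums to `L`.
#' @export
rarefy_table <- function(table, L = 10000, seed = NULL) {
  stopifnot(inherits(table, "taxon_count_table"))
  depths <- colSums(table$counts)
  low <- depths < L
  if (any(low))
    stop("samples below rarefaction depth ", L, ": ",
         paste(colnames(table$counts)[low], collapse = ", "))
  out <- table
  for (j in seq_len(ncol(table$counts))) {
    sj <- if (is.null(seed)) NULL
          else derive_seed(seed, paste0("rarefy_", colnames(table$counts)[j]))
    out$counts[, j] <- rarefy_counts(table$counts[, j], L, seed = sj)
  }
  out
}

#' Pool counts within productivity groups
#'
#' @param table a grouped `taxon_count_table`.
#' @return taxa x group matrix of pooled counts (row sums within group).
#' @export
pool_by_group <- function(table) {
  groups <- sample_groups(table)
  pools <- sapply(sort(unique(groups)), function(g)
    rowSums(table$counts[, groups == g, drop = FALSE]))
  rownames(pools) <- rownames(table$counts)
  storage.mode(pools) <- "integer"
  pools
}

#' Resampling configuration for pooled in-silico libraries
#'
#' Defaults follow the procedure as actually plotted (100 libraries of 10,000
#' reads drawn without replacement); the alternative count of 1,000
#' resamplings stated elsewhere in the source protocol is available by
#' setting `N = 1000`.
#'
#' @param L reads per in-silico library.
#' @param N number of libraries per group.
#' @param ci_level percentile-interval coverage, in (0, 1).
#' @param replacement draw with replacement?
#' @param seed optional seed.
#' @return an object of class `resampling_config`.
#' @export
resampling_config <- function(L = 10000, N = 100, ci_level = 0.95,
                              replacement = FALSE, seed = NULL) {
  if (!(N >= 1)) stop("N must be >= 1")
  if (!(L >= 1)) stop("L must be >= 1")
  if (!(ci_level > 0 && ci_level < 1))
    stop("ci_level must lie strictly between 0 and 1")
  structure(list(L = as.integer(L), N = as.integer(N), ci_level = ci_level,
                 replacement = replacement, seed = seed),
            class = "resampling_config")
}

#' Draw in-silico libraries from a pooled count vector
#'
#' Each row is one library of `config$L` reads drawn from the pool, without
#' replacement by default.
#'
#' @param pool named non-negative integer vector of pooled counts.
#' @param config a [resampling_config()].
#' @return `N` x taxa integer matrix; every row sums to `L`.
#' @export
insilico_libraries <- function(pool, config = resampling_config()) {
  stopifnot(inherits(config, "resampling_config"))
  pool <- setNames(as.integer(round(pool)), names(pool))
  if (!config$replacement && config$L > sum(pool))
    stop("library size ", config$L, " exceeds pool total ", sum(pool),
         " under without-replacement sampling")
  with_seed(config$seed, {
    m <- if (config$replacement) {
      t(rmultinom(config$N, config$L, pool / sum(pool)))
    } else {
      draws <- vapply(seq_len(config$N), function(i) rmvhyper(pool, config$L),
                      integer(length(pool)))
      t(matrix(draws, nrow = length(pool)))
    }
    colnames(m) <- names(pool)
    m
  })
}

#' Percentile confidence bounds of per-taxon library counts
#'
#' Empirical `(alpha/2, 1 - alpha/2)` percentiles of each taxon's counts
#' across libraries.  Percentile rule: linear interpolation between order
#' statistics (`quantile()` type 7), fixed for reproducibility.
#'
#' @param matrix libraries x taxa count matrix ([insilico_libraries()]).
#' @param ci_level coverage, in (0, 1).
#' @return `data.frame` with columns `taxon`, `lower`, `upper`.
#' @export
percentile_ci <- function(matrix, ci_level = 0.95) {
  if (nrow(matrix) < 2L) stop("need at least 2 libraries for percentile bounds")
  if (!(ci_level > 0 && ci_level < 1))
    stop("ci_level must lie strictly between 0 and 1")
  a <- (1 - ci_level) / 2
  q <- apply(matrix, 2, quantile, probs = c(a, 1 - a), names = FALSE, type = 7)
  data.frame(taxon = colnames(matrix), lower = q[1, ], upper = q[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag taxa whose group confidence intervals do not overlap
#'
#' A taxon is flagged iff the two intervals are strictly disjoint
#' (`upper_a < lower_b` or `upper_b < lower_a`); intervals sharing an
#' endpoint count as overlapping (conservative tie rule).
#'
#' @param ci_a,ci_b [percentile_ci()] frames over the same taxa.
#' @return `data.frame` with both intervals and a logical `flagged` column.
#' @export
ci_overlap_test <- function(ci_a, ci_b) {
  if (!setequal(ci_a$taxon, ci_b$taxon))
    stop("confidence-interval tables cover different taxa")
  b <- ci_b[match(ci_a$taxon, ci_b$taxon), ]
  data.frame(taxon = ci_a$taxon,
             lower_a = ci_a$lower, upper_a = ci_a$upper,
             lower_b = b$lower, upper_b = b$upper,
             flagged = ci_a$upper < b$lower | b$upper < ci_a$lower,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled-resampling confidence intervals between productivity groups
#'
#' The full procedure: pool counts within each group, draw `N` in-silico
#' libraries of `L` reads per group, take per-taxon percentile intervals and
#' test them for overlap.
#'
#' @param table a grouped `taxon_count_table` (raw, unrarefied counts).
#' @param config a [resampling_config()].
#' @return object of class `resampling_ci`: a `data.frame` with per-group
#'   bounds, the combined pool frequency of each taxon, and the overlap
#'   verdict; configuration stored as attributes.
#' @export
group_resampling_ci <- function(table, config = resampling_config()) {
  pools <- pool_by_group(table)
  if (ncol(pools) != 2L) stop("need exactly two productivity groups")
  ga <- colnames(pools)[1]; gb <- colnames(pools)[2]
  seed_for <- function(g) if (is.null(config$seed)) NULL
                          else derive_seed(config$seed, paste0("libraries_", g))
  cfg_a <- config; cfg_a$seed <- seed_for(ga)
  cfg_b <- config; cfg_b$seed <- seed_for(gb)
  ci_a <- percentile_ci(insilico_libraries(pools[, ga], cfg_a), config$ci_level)
  ci_b <- percentile_ci(insilico_libraries(pools[, gb], cfg_b), config$ci_level)
  res <- ci_overlap_test(ci_a, ci_b)
  names(res) <- c("taxon", paste0("lower_", ga), paste0("upper_", ga),
                  paste0("lower_", gb), paste0("upper_", gb), "flagged")
  res$pool_freq <- rowSums(pools)[res$taxon] / sum(pools)
  structure(res, groups = c(ga, gb), L = config$L, N = config$N,
            ci_level = config$ci_level, class = c("resampling_ci", "data.frame"))
}

#' @export
print.resampling_ci <- function(x, ...) {
  cat("resampling_ci:", attr(x, "N"), "libraries of", attr(x, "L"),
      "reads per group,", attr(x, "ci_level") * 100, "% percentile CIs\n")
  cat("  flagged taxa:", sum(x$flagged), "of", nrow(x), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write resampling CIs as a long-format TSV
#'
#' One row per taxon and group: `taxon`, `group`, `lower`, `upper`,
#' `flagged`.
#'
#' @param x a `resampling_ci`.
#' @param path output path.
#' @param seed optional seed recorded as a `#`-comment header.
#' @return `path`, invisibly.
#' @export
write_resampling_ci <- function(x, path, seed = NULL) {
  groups <- attr(x, "groups")
  long <- do.call(rbind, lapply(groups, function(g)
    data.frame(taxon = x$taxon, group = g,
               lower = x[[paste0("lower_", g)]],
               upper = x[[paste0("upper_", g)]],
               flagged = x$flagged, stringsAsFactors = FALSE)))
  write_stage_tsv(long, path, seed)
}

write_stage_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
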