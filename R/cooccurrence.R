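# Spearman co-occurrence analysis: rank correlations between taxa across
# samples, significance filtering, and Cytoscape-ready edge tables.

perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  rec <- function(v) {
    if (length(v) <= 1L) return(matrix(v, ncol = length(v)))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], rec(v[-i]))))
  }
  P <- rec(seq_len(n))
  perm_cache[[key]] <- P
  P
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' `rho` is the Pearson correlation of mid-ranks, which handles the heavy
#' ties of count data (the classic `1 - 6 sum(d^2) / (n(n^2-1))` shortcut is
#' only valid without ties and agrees in that case).  For `n < 10` the
#' two-sided p-value is computed by full permutation enumeration of the rank
#' vector (exact, conditional on the observed tie pattern); for `n >= 10`
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#'
#' @param x,y numeric vectors of equal length `n >= 4`, neither constant.
#' @return list: `rho`, `p`, `n`, `method`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n < 10L) {
    P <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryp <- matrix(ry[P], nrow = nrow(P))
    # permuting y leaves its mean and sum of squares unchanged
    den <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
    rho_perm <- drop(ryp %*% rxc) / den
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    r2 <- min(rho^2, 1)
    t <- if (r2 >= 1) sign(rho) * Inf else rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(t), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' All pairwise Spearman correlations between taxa
#'
#' Computed across samples at the table's taxonomic level (family by
#' default in the pipeline).  Taxa constant across all samples are skipped
#' with a warning listing them.
#'
#' @param table a `taxon_count_table` with at least 4 samples, typically
#'   rarefied.
#' @return object of class `cooccurrence_matrix`: symmetric `rho` and `p`
#'   matrices (diagonal `NA`), sample count, level, skipped taxa.
#' @export
correlation_matrix <- function(table) {
  stopifnot(inherits(table, "taxon_count_table"))
  X <- t(table$counts)
  if (nrow(X) < 4L) stop("need at least 4 samples")
  keep <- apply(X, 2, function(v) length(unique(v)) > 1L)
  skipped <- colnames(X)[!keep]
  if (length(skipped) > 0L)
    warning("constant taxa skipped: ", paste(skipped, collapse = ", "))
  X <- X[, keep, drop = FALSE]
  k <- ncol(X)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(X), colnames(X)))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        s <- spearman_rho(X[, i], X[, j])
        rho[i, j] <- rho[j, i] <- s$rho
        p[i, j] <- p[j, i] <- s$p
      }
    }
  }
  structure(list(rho = rho, p = p, n_samples = nrow(X), level = table$level,
                 skipped = skipped),
            class = "cooccurrence_matrix")
}

#' Build a significance-filtered correlation network
#'
#' Edges are the taxon pairs with `p < p_threshold` (unadjusted by default,
#' mirroring the original analysis; `adjust = "BH"` filters on
#' Benjamini-Hochberg adjusted p-values instead).  Each edge stores rho, p,
#' `R^2 = rho^2` (used for edge sizing) and the correlation sign.  Edges are
#' undirected and stored once with endpoints in label order.
#'
#' @param matrix a [correlation_matrix()] result.
#' @param p_threshold significance threshold (default 0.05).
#' @param adjust `"none"` or `"BH"`.
#' @return object of class `cooccurrence_network` with `nodes` and an edge
#'   `data.frame` (`source`, `target`, `rho`, `p`, `r_squared`, `sign`).
#' @export
build_network <- function(matrix, p_threshold = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(matrix, "cooccurrence_matrix"))
  taxa <- rownames(matrix$rho)
  ut <- upper.tri(matrix$p)
  idx <- which(ut, arr.ind = TRUE)
  p <- matrix$p[ut]
  if (adjust == "BH") p <- p.adjust(p, method = "BH")
  keep <- which(p < p_threshold)
  a <- taxa[idx[keep, 1]]
  b <- taxa[idx[keep, 2]]
  swap <- a > b
  src <- ifelse(swap, b, a)
  tgt <- ifelse(swap, a, b)
  rho <- matrix$rho[ut][keep]
  edges <- data.frame(source = src, target = tgt, rho = rho,
                      p = p[keep], r_squared = rho^2,
                      sign = ifelse(rho >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = taxa, edges = edges, p_threshold = p_threshold,
                 adjust = adjust),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", length(x$nodes), "taxa,",
      nrow(x$edges), "edges (p <", x$p_threshold, ")\n")
  if (nrow(x$edges) > 0L)
    cat("  positive:", sum(x$edges$sign == "positive"),
        " negative:", sum(x$edges$sign == "negative"), "\n")
  invisible(x)
}

#' Export / read a Cytoscape-loadable edge table
#'
#' Tab-delimited with columns `source`, `target`, `rho`, `p`, `r_squared`,
#' `sign`; loadable directly as a Cytoscape edge table and re-readable with
#' [read_edges()].
#'
#' @param network a `cooccurrence_network`.
#' @param path output path.
#' @param seed optional seed recorded as a `#`-comment header.
#' @return `path`, invisibly.
#' @export
export_edges <- function(network, path, seed = NULL) {
  stopifnot(inherits(network, "cooccurrence_network"))
  write_stage_tsv(network$edges, path, seed)
}

#' @rdname export_edges
#' @param p_threshold threshold recorded on the re-read network.
#' @export
read_edges <- function(path, p_threshold = 0.05) {
  edges <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("source", "target", "rho", "p", "r_squared", "sign")
  if (!all(need %in% colnames(edges)))
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  structure(list(nodes = sort(unique(c(edges$source, edges$target))),
                 edges = edges[need], p_threshold = p_threshold,
                 adjust = "none"),
            class = "cooccurrence_network")
}

#' Export a SIF interaction file
#'
#' One line per edge: `source corr_pos|corr_neg target`.
#'
#' @param network a `cooccurrence_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_sif <- function(network, path) {
  e <- network$edges
  lines <- paste(e$source,
                 ifelse(e$sign == "positive", "corr_pos", "corr_neg"),
                 e$target, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
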