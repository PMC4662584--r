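# Alpha diversity: Shannon H, richness S, Pielou evenness H/ln(S).
# Natural logarithm throughout (the evenness definition fixes the base).

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln p_i)` over nonzero proportions, natural log.
#'
#' @param counts non-negative count vector with positive total.
#' @return numeric H.
#' @examples
#' shannon(c(25, 25, 25, 25))  # log(4)
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("cannot compute diversity of an all-zero vector")
  unname(vegan::diversity(as.numeric(counts), index = "shannon"))
}

#' Pielou evenness
#'
#' `E = H / ln(S)` with `S` the number of nonzero taxa.  Undefined at
#' `S = 1`; returned as `NA` with a warning.
#'
#' @param counts non-negative count vector with positive total.
#' @return numeric E in `[0, 1]`, or `NA` when `S = 1`.
#' @export
evenness <- function(counts) {
  S <- sum(counts > 0)
  if (S == 0L) stop("cannot compute evenness of an all-zero vector")
  if (S == 1L) {
    warning("evenness undefined for a single-taxon sample; returning NA")
    return(NA_real_)
  }
  shannon(counts) / log(S)
}

#' Per-sample diversity, richness and evenness
#'
#' @param table a `taxon_count_table`, typically rarefied first.
#' @return `data.frame` with columns `sample_id`, `group` (`NA` when no
#'   metadata is attached), `H`, `S`, `E`.
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "taxon_count_table"))
  groups <- if (is.null(table$metadata)) NA_character_
            else sample_groups(table)[colnames(table$counts)]
  H <- apply(table$counts, 2, shannon)
  S <- colSums(table$counts > 0)
  E <- ifelse(S >= 2, H / log(pmax(S, 2)), NA_real_)
  data.frame(sample_id = colnames(table$counts), group = unname(groups),
             H = unname(H), S = unname(S), E = unname(E),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group medians of diversity statistics
#'
#' Even-sized groups use the midpoint of the central pair (the usual sample
#' median).
#'
#' @param div a [diversity_table()] result, or any `data.frame` with columns
#'   `group`, `H`, `S`, `E`.
#' @return `data.frame` with one row per group.
#' @export
group_medians <- function(div) {
  if (any(is.na(div$group))) stop("all samples need a group label")
  if (nrow(div) == 0L) stop("no samples")
  out <- aggregate(div[c("H", "S", "E")], by = list(group = div$group),
                   FUN = median, na.rm = TRUE)
  names(out) <- c("group", "median_H", "median_S", "median_E")
  out
}
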