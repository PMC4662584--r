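#' Construct a taxon-by-sample count table
#'
#' The central container of the package: an integer matrix of sequence counts
#' with taxa as rows and samples (colonies) as columns, a taxonomic level for
#' the rows, and optionally a sample metadata table attached by
#' [attach_metadata()].  Taxa observed in no sample are retained; richness on
#' rarefied tables is computed over nonzero taxa downstream, so provenance
#' stays explicit.
#'
#' @param counts numeric matrix of non-negative integers with unique row
#'   (taxon) and column (sample) names.
#' @param level taxonomic rank of the rows, e.g. `"genus"` or `"family"`.
#' @param metadata optional sample metadata `data.frame`; see
#'   [attach_metadata()].
#' @return an object of class `taxon_count_table`.
#' @examples
#' m <- matrix(c(5L, 3L, 2L, 10L, 0L, 10L), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' taxon_count_table(m)
#' @export
taxon_count_table <- function(counts, level = "genus", metadata = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  x <- structure(list(counts = counts, level = level, metadata = NULL),
                 class = "taxon_count_table")
  validate_count_table(x)
  storage.mode(x$counts) <- "integer"
  if (!is.null(metadata)) x <- attach_metadata(x, metadata)
  x
}

validate_count_table <- function(x) {
  counts <- x$counts
  if (nrow(counts) == 0L) stop("count table has no taxa")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated taxon labels at level '", x$level, "': ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("invalid count at (", rownames(counts)[bad[1, 1]], ", ",
         colnames(counts)[bad[1, 2]], "): counts must be non-negative integers")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("samples with zero total counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  invisible(x)
}

#' @export
print.taxon_count_table <- function(x, ...) {
  cat("taxon_count_table:", nrow(x$counts), "taxa (", x$level, ") x ",
      ncol(x$counts), "samples\n")
  depths <- colSums(x$counts)
  cat("  depth range:", format(min(depths), big.mark = ","), "-",
      format(max(depths), big.mark = ","), "\n")
  if (!is.null(x$metadata)) {
    tab <- table(x$metadata$productivity)
    cat("  groups:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.taxon_count_table <- function(object, ...) {
  print(object)
  cat("  taxa:", paste(head(rownames(object$counts), 8), collapse = ", "),
      if (nrow(object$counts) > 8) "...", "\n")
  invisible(object)
}

#' Number of taxa / samples in a count table
#' @param table a `taxon_count_table`.
#' @return integer.
#' @export
n_taxa <- function(table) nrow(table$counts)

#' @rdname n_taxa
#' @export
n_samples <- function(table) ncol(table$counts)

#' Productivity group of each sample
#'
#' @param table a `taxon_count_table` with metadata attached.
#' @return character vector of group labels, named by sample id.
#' @export
sample_groups <- function(table) {
  if (is.null(table$metadata))
    stop("no sample metadata attached; see attach_metadata()")
  setNames(as.character(table$metadata$productivity), table$metadata$sample_id)
}

#' Read a count table from TSV
#'
#' Two dialects are supported.  `"generic"`: first column the taxon label,
#' remaining columns one per sample; tab-delimited, no quoting.  `"mothur"`:
#' the mothur shared-file layout (columns `label`, `Group`, `numOtus`, then
#' one column per OTU, one row per sample), transposed on read so taxa become
#' rows.  Row and column order is preserved from the file.
#'
#' @param path file path.
#' @param format `"generic"` or `"mothur"`.
#' @param level taxonomic rank recorded on the returned table.
#' @return a `taxon_count_table`.
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path, format = c("generic", "mothur"),
                             level = "genus") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (format == "generic") {
    if (ncol(raw) < 2L) stop("malformed header: need taxon column plus >= 1 sample")
    taxa <- raw[[1]]
    m <- parse_count_cells(raw[-1], taxa, colnames(raw)[-1])
  } else {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% colnames(raw)[1:3]))
      stop("malformed mothur shared header: expected columns label, Group, numOtus")
    samples <- raw$Group
    otus <- setdiff(colnames(raw), need)
    if (length(otus) == 0L) stop("malformed mothur shared file: no OTU columns")
    m <- t(parse_count_cells(raw[otus], samples, otus))
  }
  taxon_count_table(m, level = level)
}

parse_count_cells <- function(df, row_labels, col_labels) {
  m <- matrix(NA_real_, nrow = length(row_labels), ncol = length(col_labels),
              dimnames = list(row_labels, col_labels))
  for (j in seq_along(col_labels)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0L)
      stop("invalid count at (", row_labels[bad[1]], ", ", col_labels[j],
           "): '", df[[j]][bad[1]], "' is not a non-negative integer")
    m[, j] <- v
  }
  m
}

#' Write a count table to TSV
#'
#' Lossless inverse of [read_count_table()] for both dialects.
#'
#' @param table a `taxon_count_table`.
#' @param path output path.
#' @param format `"generic"` or `"mothur"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, format = c("generic", "mothur")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "taxon_count_table"))
  if (nrow(table$counts) == 0L) stop("nothing to write: table has 0 taxa")
  if (format == "generic") {
    out <- data.frame(taxon = rownames(table$counts), table$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(label = "0.03", Group = colnames(table$counts),
                      numOtus = nrow(table$counts), t(table$counts),
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Read a sample metadata TSV
#'
#' Expects a header `sample_id`, `apiary`, `productivity`; productivity values
#' must be `productive` or `unproductive`.
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "apiary", "productivity")
  if (!all(need %in% colnames(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md
}

#' Attach sample metadata (productivity groups) to a count table
#'
#' Every sample in the table must appear exactly once in the metadata; extra
#' metadata rows are ignored with a warning.  Group sizes are reported.
#'
#' @param table a `taxon_count_table`.
#' @param metadata `data.frame` with columns `sample_id`, `apiary`,
#'   `productivity` (values `productive` / `unproductive`).
#' @return the table with `$metadata` set, rows aligned to sample order.
#' @export
attach_metadata <- function(table, metadata) {
  stopifnot(inherits(table, "taxon_count_table"), is.data.frame(metadata))
  need <- c("sample_id", "apiary", "productivity")
  if (!all(need %in% colnames(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  samples <- colnames(table$counts)
  missing <- setdiff(samples, metadata$sample_id)
  if (length(missing) > 0L)
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicated sample ids in metadata")
  extra <- setdiff(metadata$sample_id, samples)
  if (length(extra) > 0L)
    warning("metadata rows for unknown samples ignored: ",
            paste(extra, collapse = ", "))
  md <- metadata[match(samples, metadata$sample_id), need, drop = FALSE]
  bad <- !md$productivity %in% c("productive", "unproductive")
  if (any(bad))
    stop("invalid productivity label for: ",
         paste(md$sample_id[bad], collapse = ", "),
         " (must be 'productive' or 'unproductive')")
  rownames(md) <- NULL
  table$metadata <- md
  sizes <- table(md$productivity)
  message("group sizes: ", paste(names(sizes), sizes, sep = " = ", collapse = ", "))
  table
}

#' Aggregate a count table to a coarser taxonomic level
#'
#' Counts are summed within the parent label; per-sample totals are conserved
#' exactly.  The map must cover every taxon in the table.
#'
#' @param table a `taxon_count_table`.
#' @param taxonomy_map named character vector mapping child label to parent
#'   label (e.g. genus to family).
#' @param target_level rank recorded on the result.
#' @return a `taxon_count_table` at `target_level`, metadata preserved.
#' @examples
#' m <- matrix(c(3L, 4L), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
#' tab <- taxon_count_table(m)
#' fam <- aggregate_taxa(tab, c(g1 = "F", g2 = "F"), "family")
#' fam$counts  # single family row with count 7
#' @export
aggregate_taxa <- function(table, taxonomy_map, target_level = "family") {
  stopifnot(inherits(table, "taxon_count_table"))
  taxa <- rownames(table$counts)
  unmapped <- setdiff(taxa, names(taxonomy_map))
  if (length(unmapped) > 0L)
    stop("taxa missing from taxonomy map: ", paste(unmapped, collapse = ", "))
  parent <- taxonomy_map[taxa]
  agg <- rowsum(table$counts, group = parent, reorder = FALSE)
  out <- taxon_count_table(agg, level = target_level)
  out$metadata <- table$metadata
  out
}

#' Genus-to-family map for the core honey bee microbiome
#'
#' Covers the thirteen core phylotypes of [core_microbiome_profile()]:
#' Gilliamella, Frischella and gamma-2 fold into Orbaceae; Snodgrassella and
#' beta into Neisseriaceae; firm-4/firm-5 into Lactobacillaceae; alpha-2.1 and
#' alpha-2.2 into Acetobacteraceae; alpha-1 is kept as its own
#' Rhizobiales-like family bin.
#'
#' @return named character vector (genus -> family).
#' @export
default_taxonomy <- function() {
  c(Bifidobacterium        = "Bifidobacteriaceae",
    Frischella             = "Orbaceae",
    Gilliamella_apicola_wkB1  = "Orbaceae",
    Gilliamella_apicola_wkB11 = "Orbaceae",
    Gilliamella_apicola_wkB30 = "Orbaceae",
    "gamma-2"              = "Orbaceae",
    Snodgrassella          = "Neisseriaceae",
    beta                   = "Neisseriaceae",
    "alpha-1"              = "alpha-1",
    "alpha-2.1"            = "Acetobacteraceae",
    "alpha-2.2"            = "Acetobacteraceae",
    "firm-4"               = "Lactobacillaceae",
    "firm-5"               = "Lactobacillaceae")
}
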