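#' Average per-colony abundance profile of the core honey bee gut microbiome
#'
#' Thirteen core phylotypes with their average reads per colony in a deeply
#' sequenced 14-colony forager survey, dominated by *Gilliamella apicola*
#' (Orbaceae).  These averages seed the default synthetic community
#' composition.
#'
#' @return `data.frame` with columns `taxon`, `family`, `mean_reads`.
#' @export
core_microbiome_profile <- function() {
  taxa <- c("Bifidobacterium", "Frischella", "Gilliamella_apicola_wkB1",
            "Gilliamella_apicola_wkB11", "Gilliamella_apicola_wkB30",
            "Snodgrassella", "alpha-1", "alpha-2.1", "alpha-2.2", "beta",
            "firm-5", "firm-4", "gamma-2")
  mean_reads <- c(722.6, 637.7, 3200.9, 439.6, 1001.8, 573.7, 438.0, 146.4,
                  112.2, 2.1, 29.8, 92.9, 711.3)
  data.frame(taxon = taxa, family = unname(default_taxonomy()[taxa]),
             mean_reads = mean_reads, stringsAsFactors = FALSE)
}

#' Build a synthetic community configuration
#'
#' Colonies are modelled as Dirichlet-multinomial draws: colony `c` in group
#' `g` receives a composition `p_c ~ Dirichlet(theta * p_g)` and counts
#' `multinomial(depth_c, p_c)`.  `theta` (the concentration) controls
#' between-colony variability: larger means colonies hug the group mean,
#' `Inf` removes inter-colony dispersion entirely (pure multinomial
#' colonies).
#'
#' @param base_proportions named non-negative vector of per-taxon weights
#'   (normalised internally), or a two-column matrix with columns
#'   `productive` and `unproductive` for group-specific baselines.
#' @param concentration Dirichlet concentration `theta > 0`, or `Inf`.
#' @param library_sizes integer vector of per-colony read depths, length
#'   `2 * n_per_group` (productive colonies first).
#' @param n_per_group colonies per productivity group.
#' @param seed integer root seed; fixes the full generated output.
#' @return an object of class `synthetic_config`.
#' @seealso [default_synthetic_config()], [sample_table()]
#' @export
synthetic_config <- function(base_proportions, concentration = 18.3,
                             library_sizes, n_per_group = 7, seed = 1) {
  if (is.matrix(base_proportions)) {
    stopifnot(all(c("productive", "unproductive") %in% colnames(base_proportions)))
    p <- base_proportions[, c("productive", "unproductive")]
  } else {
    p <- cbind(productive = base_proportions, unproductive = base_proportions)
  }
  if (is.null(rownames(p))) stop("base_proportions must be named by taxon")
  if (any(p < 0) || any(!is.finite(p))) stop("proportions must be non-negative")
  if (any(colSums(p) <= 0)) stop("each group needs positive total weight")
  p <- sweep(p, 2, colSums(p), "/")
  stopifnot(all(abs(colSums(p) - 1) < 1e-12))
  if (!(length(concentration) == 1L && concentration > 0))
    stop("concentration must be a positive scalar (Inf allowed)")
  library_sizes <- as.integer(round(library_sizes))
  if (length(library_sizes) != 2L * n_per_group)
    stop("need one library size per colony (", 2L * n_per_group, ")")
  if (any(library_sizes < 1L)) stop("library sizes must be >= 1")
  structure(list(base_proportions = p, concentration = concentration,
                 library_sizes = library_sizes, n_per_group = n_per_group,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:", nrow(x$base_proportions), "taxa,",
      x$n_per_group, "colonies/group, theta =", x$concentration, "\n")
  cat("  depths:", format(min(x$library_sizes), big.mark = ","), "-",
      format(max(x$library_sizes), big.mark = ","), " seed:", x$seed, "\n")
  invisible(x)
}

#' Default study-design configuration
#'
#' Mirrors the surveyed design: 7 apiaries x (most, least productive) = 14
#' colony libraries; base composition proportional to the core-microbiome
#' per-colony averages ([core_microbiome_profile()]), identical in both
#' groups; per-colony depths drawn uniformly between 25,000 (the smallest
#' observed library) and 230,000 reads; concentration `theta = 18.3`, fixed
#' so that the Orbaceae family share (0.739) has a between-colony SD of about
#' 1,000 reads per 10,000 (`theta = p(1-p)/sigma^2 - 1`).
#'
#' @param seed integer root seed.
#' @param concentration override for the Dirichlet concentration.
#' @return a `synthetic_config`.
#' @export
default_synthetic_config <- function(seed = 1, concentration = 18.3) {
  prof <- core_microbiome_profile()
  depths <- with_seed(derive_seed(seed, "library_sizes"),
                      round(runif(14, 25000, 230000)))
  synthetic_config(setNames(prof$mean_reads, prof$taxon),
                   concentration = concentration,
                   library_sizes = depths, n_per_group = 7, seed = seed)
}

#' Declare a between-group abundance effect
#'
#' The enriched group's base proportion for `taxon` is multiplied by
#' `fold_change` and the composition renormalised (compositional closure:
#' libraries have fixed size, so enriching one taxon necessarily dilutes the
#' rest).
#'
#' @param taxon taxon label present in the configuration.
#' @param fold_change multiplicative enrichment, `> 0`.
#' @param group which group is enriched.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(taxon, fold_change,
                        group = c("productive", "unproductive")) {
  group <- match.arg(group)
  stopifnot(is.character(taxon), length(taxon) == 1L)
  if (!(is.numeric(fold_change) && fold_change > 0))
    stop("fold_change must be > 0")
  structure(list(taxon = taxon, fold_change = fold_change, group = group),
            class = "effect_spec")
}

apply_effects <- function(p, effects) {
  if (is.null(effects)) return(p)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (e in effects) {
    if (!e$taxon %in% rownames(p))
      stop("effect on unknown taxon: ", e$taxon)
    p[e$taxon, e$group] <- p[e$taxon, e$group] * e$fold_change
  }
  sweep(p, 2, colSums(p), "/")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {  # all-tiny shapes can underflow; fall back to the mean
    alpha / sum(alpha)
  } else {
    g / s
  }
}

#' Sample a synthetic colony count table
#'
#' Draws one library per colony under the Dirichlet-multinomial model of the
#' configuration, applies any [effect_spec()] enrichments to the group base
#' compositions first, and attaches productivity metadata (colonies `P1..Pn`
#' and `U1..Un`, apiary `A1..An` pairing one productive and one unproductive
#' colony, as in the surveyed design).  Fully reproducible from
#' `config$seed`; each colony uses its own derived stream.
#'
#' @param config a [synthetic_config()].
#' @param effects an [effect_spec()] or list of them, or `NULL`.
#' @return a `taxon_count_table` (genus level) with metadata attached.
#' @export
sample_table <- function(config, effects = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- apply_effects(config$base_proportions, effects)
  n <- config$n_per_group
  ids <- c(paste0("P", seq_len(n)), paste0("U", seq_len(n)))
  groups <- rep(c("productive", "unproductive"), each = n)
  counts <- matrix(0L, nrow = nrow(p), ncol = 2L * n,
                   dimnames = list(rownames(p), ids))
  for (i in seq_along(ids)) {
    counts[, i] <- with_seed(derive_seed(config$seed, paste0("colony_", ids[i])), {
      pc <- if (is.finite(config$concentration))
        rdirichlet1(config$concentration * p[, groups[i]])
      else p[, groups[i]]
      drop(rmultinom(1, config$library_sizes[i], pc))
    })
  }
  md <- data.frame(sample_id = ids,
                   apiary = paste0("A", rep(seq_len(n), 2)),
                   productivity = groups, stringsAsFactors = FALSE)
  tab <- taxon_count_table(counts, level = "genus")
  suppressMessages(attach_metadata(tab, md))
}

#' Dominance-gradient masking scenario
#'
#' Generates one count table per dominance value, all else held constant, to
#' expose compositional masking: at a fixed sequencing depth, a dominant
#' taxon's reads crowd out a fixed panel of rare taxa, lowering their
#' detection probability and inducing negative co-occurrence correlations
#' without any ecological interaction.  The generator is hierarchical: the
#' dominant share of colony `c` is `Beta(theta * d, theta * (1 - d))` while
#' the relative composition of the rare panel (geometric weights,
#' `decay^(i-1)`) is drawn with its own, larger concentration
#' `rare_concentration` - dominance fluctuates between colonies, the residual
#' community is comparatively stable, which is what couples every rare
#' taxon's counts negatively to the dominant one.
#'
#' @param dominance_grid dominant-taxon shares, each in `[0, 1)`.
#' @param depth library size per colony.
#' @param n_colonies colonies per table.
#' @param seed integer root seed.
#' @param n_rare size of the rare-taxon panel.
#' @param decay geometric decay of the rare panel weights, in (0, 1].
#' @param concentration Beta concentration of the dominant share.
#' @param rare_concentration Dirichlet concentration of the rare panel.
#' @return named list of `taxon_count_table`s, one per dominance value.
#' @export
masking_scenario <- function(dominance_grid, depth = 10000, n_colonies = 14,
                             seed = 1, n_rare = 30, decay = 0.7,
                             concentration = 18.3, rare_concentration = 200) {
  if (any(dominance_grid < 0 | dominance_grid >= 1))
    stop("dominance values must lie in [0, 1)")
  w <- decay^(seq_len(n_rare) - 1)
  w <- w / sum(w)
  taxa <- c("dominant", sprintf("rare_%02d", seq_len(n_rare)))
  out <- lapply(seq_along(dominance_grid), function(k) {
    d <- dominance_grid[k]
    counts <- with_seed(derive_seed(seed, paste0("dominance_", k)), {
      sapply(seq_len(n_colonies), function(i) {
        dc <- if (d == 0) 0 else rbeta(1, concentration * d, concentration * (1 - d))
        wr <- rdirichlet1(rare_concentration * w)
        drop(rmultinom(1, depth, c(dc, (1 - dc) * wr)))
      })
    })
    dimnames(counts) <- list(taxa, paste0("S", seq_len(n_colonies)))
    taxon_count_table(counts, level = "family")
  })
  names(out) <- paste0("dominance_", format(dominance_grid))
  out
}

#' Probability of detecting a rare taxon in a subsampled library
#'
#' For a taxon with `k` of `K` pooled reads and a library of `L` draws:
#' without replacement the miss probability is hypergeometric,
#' `choose(K - k, L) / choose(K, L)`; with replacement it is
#' `(1 - k/K)^L`.
#'
#' @param k reads of the taxon in the pool.
#' @param K total reads in the pool.
#' @param L library size.
#' @param replacement draw with replacement?
#' @return detection probability.
#' @export
rare_detection_prob <- function(k, K, L, replacement = FALSE) {
  stopifnot(k >= 0, K >= k, L >= 0, L <= K || replacement)
  if (replacement) 1 - (1 - k / K)^L
  else 1 - stats::dhyper(0, k, K - k, L)
}
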