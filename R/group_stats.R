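# Group-difference statistics: per-taxon Kruskal-Wallis tests and stepwise
# discriminant analysis on Wilks' lambda, with leave-one-out classification.

#' Kruskal-Wallis rank test
#'
#' Mid-ranks with tie correction; the H statistic is referred to a
#' chi-squared distribution on `groups - 1` degrees of freedom.  Computed by
#' `stats::kruskal.test()`; the tie-correction factor
#' `1 - sum(t^3 - t) / (n^3 - n)` is reported alongside.
#'
#' @param values numeric observations.
#' @param groups group labels, parallel to `values`; at least two non-empty
#'   groups.
#' @return list of class `kw_test`: `statistic`, `df`, `p.value`,
#'   `tie_correction`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least two non-empty groups")
  if (any(tabulate(groups) == 0L)) stop("every group needs observations")
  if (length(unique(values)) == 1L)
    stop("all values identical; statistic undefined")
  kt <- kruskal.test(values, groups)
  n <- length(values)
  t <- table(values)
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p.value = kt$p.value,
                 tie_correction = 1 - sum(t^3 - t) / (n^3 - n)),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Kruskal-Wallis tests for every taxon of a grouped table
#'
#' One test per taxon, comparing counts between productivity groups on the
#' (typically rarefied) table.  No multiplicity adjustment is applied by
#' default, mirroring the original single-subsampling analysis; set
#' `adjust = "BH"` for Benjamini-Hochberg corrected p-values in an extra
#' column.  Taxa with identical counts in every sample are reported as
#' degenerate with `NA` statistics.
#'
#' @param table a grouped `taxon_count_table`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` of class `kw_results`, sorted by p-value: `taxon`,
#'   `statistic`, `df`, `p`, `tie_correction`, `note`.
#' @export
kw_all_taxa <- function(table, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- sample_groups(table)
  rows <- lapply(rownames(table$counts), function(tx) {
    v <- table$counts[tx, ]
    if (length(unique(v)) == 1L)
      return(data.frame(taxon = tx, statistic = NA_real_, df = NA_integer_,
                        p = NA_real_, tie_correction = NA_real_,
                        note = "degenerate", stringsAsFactors = FALSE))
    kt <- kruskal_wallis(v, groups)
    data.frame(taxon = tx, statistic = kt$statistic, df = kt$df,
               p = kt$p.value, tie_correction = kt$tie_correction,
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, na.last = TRUE), ]
  rownames(out) <- NULL
  if (adjust == "BH") out$p_adjusted <- p.adjust(out$p, method = "BH")
  class(out) <- c("kw_results", "data.frame")
  out
}

# pooled within-group and total SSCP matrices
sscp_matrices <- function(X, groups) {
  X <- as.matrix(X)
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W <- matrix(0, ncol(X), ncol(X))
  for (g in unique(groups)) {
    Xg <- X[groups == g, , drop = FALSE]
    W <- W + crossprod(scale(Xg, center = TRUE, scale = FALSE))
  }
  dimnames(W) <- dimnames(Tm)
  list(W = W, T = Tm)
}

#' Wilks' lambda for a predictor set
#'
#' `Lambda = det(W) / det(T)` with `W` the pooled within-group and `T` the
#' total sum-of-squares-and-cross-products matrix over the selected
#' predictors.  Small values indicate group separation; a predictor set with
#' equal group means gives `Lambda = 1`.
#'
#' @param X samples x predictors numeric matrix or data frame.
#' @param groups group labels, length `nrow(X)`.
#' @param predictors columns to use (default: all).
#' @return numeric Lambda in (0, 1].
#' @export
wilks_lambda <- function(X, groups, predictors = colnames(X)) {
  X <- as.matrix(X)[, predictors, drop = FALSE]
  groups <- as.character(groups)
  g <- length(unique(groups))
  if (g < 2L) stop("need at least two groups")
  if (nrow(X) <= ncol(X) + g)
    stop("too few samples (", nrow(X), ") for ", ncol(X),
         " predictors and ", g, " groups")
  m <- sscp_matrices(X, groups)
  dT <- det(m$T)
  if (!is.finite(dT) || abs(dT) < .Machine$double.eps)
    stop("total scatter matrix is singular; remove constant or collinear predictors")
  det(m$W) / dT
}

# Rao's partial F for moving between nested predictor sets:
# p predictors already in the model, candidate makes p + 1.
partial_f <- function(lambda_small, lambda_big, n, g, p_in) {
  (lambda_small / lambda_big - 1) * (n - g - p_in) / (g - 1)
}

#' Stepwise discriminant analysis on Wilks' lambda
#'
#' Forward selection with backward removal, the classic stepwise rule: at
#' each step the candidate predictor minimising Wilks' lambda enters if its
#' partial F-to-enter reaches `f_enter`; after every entry, predictors whose
#' partial F-to-remove has fallen below `f_remove` are dropped.  Ties are
#' broken by taxon label order, so the trace is deterministic.  The final
#' model is summarised by Bartlett's chi-squared approximation,
#' `-(n - 1 - (p + g)/2) * ln(Lambda)` on `p * (g - 1)` degrees of freedom,
#' and by leave-one-out classification accuracy
#' ([loo_crossvalidate()]).
#'
#' Default thresholds are the classic `F`-to-enter 3.84 and `F`-to-remove
#' 2.71.
#'
#' @param x a grouped `taxon_count_table` (samples become rows, taxa
#'   predictors), or a samples x predictors matrix / data frame.
#' @param ... passed on between methods.
#' @return an object of class `stepwise_da`; see [print.stepwise_da()],
#'   `summary()`, [predict.stepwise_da()], `coef()`.
#' @export
stepwise_da <- function(x, ...) UseMethod("stepwise_da")

#' @rdname stepwise_da
#' @param f_enter minimum partial F for a predictor to enter.
#' @param f_remove partial F below which an entered predictor is removed.
#' @export
stepwise_da.taxon_count_table <- function(x, f_enter = 3.84, f_remove = 2.71, ...) {
  stepwise_da.default(t(x$counts), sample_groups(x),
                      f_enter = f_enter, f_remove = f_remove, ...)
}

#' @rdname stepwise_da
#' @param groups group labels, length `nrow(x)` (matrix method).
#' @export
stepwise_da.default <- function(x, groups, f_enter = 3.84, f_remove = 2.71, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(X))
  if (min(table(groups)) < 2L) stop("need at least two samples per group")
  n <- nrow(X)
  g <- length(unique(groups))
  candidates <- sort(colnames(X))
  candidates <- candidates[apply(X[, candidates, drop = FALSE], 2, var) > 0]

  selected <- character(0)
  lambda <- 1
  trace <- list()
  step <- 0L
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    p_in <- length(selected)
    if (length(pool) > 0L && (n - g - p_in) >= 1L) {
      lams <- vapply(pool, function(v) {
        tryCatch(wilks_lambda(X, groups, c(selected, v)),
                 error = function(e) NA_real_)
      }, numeric(1))
      ok <- which(!is.na(lams))
      if (length(ok) > 0L) {
        best <- ok[which.min(lams[ok])]  # ties: first in label order
        Fent <- unname(partial_f(lambda, lams[best], n, g, p_in))
        if (is.finite(Fent) && Fent >= f_enter) {
          step <- step + 1L
          selected <- c(selected, pool[best])
          lambda <- unname(lams[best])
          trace[[length(trace) + 1L]] <- data.frame(
            step = step, action = "enter", predictor = pool[best],
            lambda = lambda, F = Fent,
            p = pf(Fent, g - 1, n - g - p_in, lower.tail = FALSE),
            stringsAsFactors = FALSE)
          changed <- TRUE
        }
      }
    }
    while (length(selected) > 1L) {
      p_in <- length(selected)
      lams_wo <- vapply(selected, function(v)
        wilks_lambda(X, groups, setdiff(selected, v)), numeric(1))
      Frem <- partial_f(lams_wo, lambda, n, g, p_in - 1L)
      worst <- which.min(Frem)
      if (Frem[worst] < f_remove) {
        step <- step + 1L
        dropped <- selected[worst]
        selected <- setdiff(selected, dropped)
        lambda <- wilks_lambda(X, groups, selected)
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, action = "remove", predictor = dropped,
          lambda = lambda, F = unname(Frem[worst]),
          p = pf(unname(Frem[worst]), g - 1, n - g - p_in + 1L,
                 lower.tail = FALSE),
          stringsAsFactors = FALSE)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  trace <- if (length(trace)) do.call(rbind, trace)
           else data.frame(step = integer(), action = character(),
                           predictor = character(), lambda = numeric(),
                           F = numeric(), p = numeric())
  p_fin <- length(selected)
  if (p_fin == 0L) {
    warning("no predictor passed the entry criterion; model is empty")
    chisq <- df <- pval <- NA_real_
    accuracy <- NA_real_
    centroids <- pooled_cov <- NULL
  } else {
    chisq <- -(n - 1 - (p_fin + g) / 2) * log(lambda)
    df <- p_fin * (g - 1)
    pval <- pchisq(chisq, df, lower.tail = FALSE)
    fit <- discriminant_fit(X[, selected, drop = FALSE], groups)
    centroids <- fit$centroids
    pooled_cov <- fit$cov
    accuracy <- loo_crossvalidate(X, groups, selected)
  }
  structure(list(selected = selected, lambda = lambda, chisq = chisq,
                 df = df, p.value = pval, trace = trace,
                 accuracy = accuracy, n = n, groups = sort(unique(groups)),
                 group_sizes = table(groups), f_enter = f_enter,
                 f_remove = f_remove, centroids = centroids,
                 pooled_cov = pooled_cov),
            class = "stepwise_da")
}

discriminant_fit <- function(X, groups) {
  lev <- sort(unique(groups))
  centroids <- matrix(NA_real_, length(lev), ncol(X),
                      dimnames = list(lev, colnames(X)))
  for (g in lev) centroids[g, ] <- colMeans(X[groups == g, , drop = FALSE])
  W <- sscp_matrices(X, groups)$W
  list(centroids = centroids, cov = W / (nrow(X) - length(lev)))
}

mahalanobis_classify <- function(x, centroids, S) {
  Sinv <- tryCatch(solve(S), error = function(e) MASS::ginv(S))
  d2 <- apply(centroids, 1, function(m) {
    v <- x - m
    drop(t(v) %*% Sinv %*% v)
  })
  rownames(centroids)[which.min(d2)]  # ties: first group level
}

#' Leave-one-out classification accuracy of a discriminant predictor set
#'
#' For each sample, group centroids and the pooled within-group covariance
#' are refit without it; the held-out sample is assigned to the nearest
#' centroid by Mahalanobis distance.  Ties go to the first group level.
#'
#' @param x samples x predictors matrix or grouped `taxon_count_table`.
#' @param groups group labels (ignored for the table input).
#' @param predictors the fitted predictor set (non-empty).
#' @return fraction of samples classified into their own group.
#' @export
loo_crossvalidate <- function(x, groups = NULL, predictors) {
  if (inherits(x, "taxon_count_table")) {
    groups <- sample_groups(x)
    x <- t(x$counts)
  }
  X <- as.matrix(x)[, predictors, drop = FALSE]
  storage.mode(X) <- "double"
  groups <- as.character(groups)
  if (length(predictors) == 0L) stop("need a non-empty predictor set")
  n <- nrow(X)
  correct <- 0L
  for (i in seq_len(n)) {
    gtrain <- groups[-i]
    if (min(table(gtrain)) < 2L)
      stop("leave-one-out reduces group '", groups[i], "' below 2 samples")
    fit <- discriminant_fit(X[-i, , drop = FALSE], gtrain)
    pred <- mahalanobis_classify(X[i, ], fit$centroids, fit$cov)
    correct <- correct + (pred == groups[i])
  }
  correct / n
}

#' @export
print.stepwise_da <- function(x, ...) {
  cat("Stepwise discriminant analysis (Wilks' lambda)\n")
  cat("  n =", x$n, "samples;", paste(names(x$group_sizes),
      x$group_sizes, sep = " = ", collapse = ", "), "\n")
  if (length(x$selected) == 0L) {
    cat("  empty model: no predictor reached F-to-enter =", x$f_enter, "\n")
  } else {
    cat("  predictors:", paste(x$selected, collapse = ", "), "\n")
    cat(sprintf("  Wilks' lambda = %.3f; chi-squared = %.3f; df = %d; p = %.4g\n",
                x$lambda, x$chisq, x$df, x$p.value))
    cat(sprintf("  leave-one-out accuracy = %.3f\n", x$accuracy))
  }
  invisible(x)
}

#' @export
summary.stepwise_da <- function(object, ...) {
  print(object)
  if (nrow(object$trace) > 0L) {
    cat("\nStepwise trace:\n")
    print(object$trace, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.stepwise_da <- function(object, ...) {
  if (length(object$selected) == 0L) return(numeric(0))
  if (length(object$groups) != 2L)
    stop("discriminant coefficients implemented for two groups")
  d <- object$centroids[1, ] - object$centroids[2, ]
  Sinv <- tryCatch(solve(object$pooled_cov),
                   error = function(e) MASS::ginv(object$pooled_cov))
  drop(Sinv %*% d)
}

#' Classify new samples with a fitted stepwise discriminant model
#'
#' @param object a `stepwise_da` fit with a non-empty model.
#' @param newdata samples x predictors matrix/data frame containing the
#'   selected predictors, or a `taxon_count_table`.
#' @param ... unused.
#' @return character vector of predicted group labels.
#' @export
predict.stepwise_da <- function(object, newdata, ...) {
  if (length(object$selected) == 0L)
    stop("cannot predict from an empty model")
  if (inherits(newdata, "taxon_count_table")) newdata <- t(newdata$counts)
  X <- as.matrix(newdata)[, object$selected, drop = FALSE]
  apply(X, 1, mahalanobis_classify, centroids = object$centroids,
        S = object$pooled_cov)
}
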