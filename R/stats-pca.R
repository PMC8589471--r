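# Correlation-matrix PCA with iterative communality screening: components are
# retained by the Kaiser rule (eigenvalue > 1) and items whose retained
# communality falls below a threshold are dropped one at a time, worst first,
# until every remaining item is adequately represented.

#' PCA with communality screening
#'
#' Standardises the items, eigendecomposes their correlation matrix, retains
#' components with eigenvalue above the Kaiser threshold and computes loadings
#' (`eigenvector * sqrt(eigenvalue)`) and communalities (row sums of squared
#' loadings over retained components). If the lowest communality falls below
#' `communality_threshold`, that item is deleted and the analysis re-run;
#' every round is returned.
#'
#' The loading sign convention makes the largest-magnitude element of each
#' component positive. No rotation is applied.
#'
#' @param x data frame or matrix of items (columns) by observations (rows);
#'   at least 2 items, more rows than items.
#' @param kaiser eigenvalue retention threshold (default 1).
#' @param communality_threshold minimum acceptable communality (default 0.4).
#' @param max_rounds safety bound on screening rounds.
#' @return A list of class `pca_screening`; each element is one round with
#'   `eigenvalues`, `loadings`, `communalities`, `retained`, `dropped_item`
#'   (the item removed after that round, or `NA`), `threshold`.
#' @export
pca_with_screening <- function(x, kaiser = 1.0, communality_threshold = 0.4,
                               max_rounds = 20) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stopf("need at least 2 items")
  if (nrow(x) <= ncol(x)) stopf("need more observations than items")
  rounds <- list()
  items <- names(x)
  for (round in seq_len(max_rounds)) {
    z <- scale(as.matrix(x[, items, drop = FALSE]))
    cm <- cor(z)
    if (!all(is.finite(cm))) stopf("singular correlation matrix")
    ev <- eigen(cm, symmetric = TRUE)
    keep <- which(ev$values > kaiser)
    if (!length(keep)) keep <- 1L
    vecs <- ev$vectors[, keep, drop = FALSE]
    # sign convention: dominant element of each component positive
    for (j in seq_len(ncol(vecs))) {
      s <- sign(vecs[which.max(abs(vecs[, j])), j])
      if (s < 0) vecs[, j] <- -vecs[, j]
    }
    load <- sweep(vecs, 2, sqrt(ev$values[keep]), `*`)
    dimnames(load) <- list(items, paste0("PC", seq_along(keep)))
    comm <- rowSums(load^2)
    worst <- which.min(comm)
    drop_item <- if (comm[worst] < communality_threshold &&
                     length(items) > 2) items[worst] else NA_character_
    rounds[[round]] <- list(eigenvalues = ev$values,
                            loadings = load,
                            communalities = comm,
                            retained = length(keep),
                            dropped_item = drop_item,
                            threshold = communality_threshold)
    if (is.na(drop_item)) break
    items <- setdiff(items, drop_item)
  }
  structure(rounds, class = "pca_screening")
}

#' @export
print.pca_screening <- function(x, ...) {
  for (i in seq_along(x)) {
    r <- x[[i]]
    cat(sprintf("Round %d: %d items, %d component(s) retained\n", i,
                nrow(r$loadings), r$retained))
    tab <- cbind(round(r$loadings, 3), communality = round(r$communalities, 3))
    print(tab)
    if (!is.na(r$dropped_item)) {
      cat(sprintf("  -> dropping '%s' (communality %.3f < %.2f)\n",
                  r$dropped_item, min(r$communalities), r$threshold))
    }
  }
  invisible(x)
}

#' Items retained after communality screening
#'
#' @param screening a [pca_with_screening()] result.
#' @return Character vector of surviving item names.
#' @export
retained_items <- function(screening) {
  rownames(screening[[length(screening)]]$loadings)
}
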