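#' Principal component analysis of severity measures
#'
#' Standardizes each measure column (the instruments have incommensurate
#' scales, so the analysis is of the correlation structure) and
#' eigendecomposes it. Loading signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param severity A `utm_severity` tibble (or any data frame with a
#'   `participant_id` column and numeric measure columns).
#' @param measures Columns to include; default the eleven core instruments
#'   present in the table.
#' @return Object of class `utm_pca`: list with `loadings` (measures x
#'   components), `explained_variance_ratio`, `scores` (participants x
#'   components), `measures`, `center`, `scale`.
#' @export
fit_pca <- function(severity, measures = intersect(utm_measures_core, names(severity))) {
  if (length(measures) < 2) {
    abort("Need at least 2 measures.", class = "uritox_parameter_error")
  }
  x <- as.matrix(as.data.frame(severity)[, measures, drop = FALSE])
  if (nrow(x) < 3) {
    abort("Need at least 3 participants.", class = "uritox_parameter_error")
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant measure column(s): ",
                 paste(measures[sds == 0], collapse = ", ")),
          class = "uritox_degenerate_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  structure(list(
    loadings = rot,
    explained_variance_ratio = pc$sdev^2 / sum(pc$sdev^2),
    scores = scores, measures = measures,
    center = pc$center, scale = pc$scale
  ), class = "utm_pca")
}

#' @export
print.utm_pca <- function(x, ...) {
  cat("<utm_pca> ", length(x$measures), " measures; first two components ",
      "explain ", round(100 * sum(x$explained_variance_ratio[1:2]), 1),
      "% of variance\n", sep = "")
  invisible(x)
}

#' Group measures by the angular proximity of their leading loadings
#'
#' Clusters the measures' loading vectors on the first `k` components with
#' complete-linkage agglomeration on cosine distance
#' (`1 - cos(angle)`), cutting the tree at height `h_cut`. Groups of two or
#' more measures are reported as clusters; singletons are flagged as
#' outliers (measures distinct from every cluster).
#'
#' @param pca A `utm_pca`.
#' @param k Number of leading components to use (default 2).
#' @param h_cut Cosine-distance cut height (default 0.3, i.e. about 45
#'   degrees).
#' @return Tibble with `measure`, `cluster` (integer id, `NA` for
#'   outliers), `is_outlier`.
#' @export
cluster_measures <- function(pca, k = 2L, h_cut = 0.3) {
  L <- pca$loadings[, seq_len(min(k, ncol(pca$loadings))), drop = FALSE]
  if (nrow(L) == 1) {
    return(tibble::tibble(measure = rownames(L), cluster = 1L, is_outlier = FALSE))
  }
  norms <- sqrt(rowSums(L^2))
  U <- L / norms
  cosd <- 1 - tcrossprod(U)
  cosd[cosd < 0] <- 0
  hc <- hclust(as.dist(cosd), method = "complete")
  grp <- cutree(hc, h = h_cut)
  sizes <- table(grp)
  is_out <- sizes[as.character(grp)] < 2
  # canonical ids: clusters ordered by their alphabetically first measure,
  # so the labelling is invariant to column order
  keep <- unique(grp[!is_out])
  first_measure <- vapply(keep, function(g) min(rownames(L)[grp == g]), character(1))
  relab <- setNames(seq_along(keep), keep[order(first_measure)])
  tibble::tibble(
    measure = rownames(L),
    cluster = as.integer(ifelse(as.vector(is_out), NA_integer_,
                                unname(relab[as.character(grp)]))),
    is_outlier = as.vector(is_out)
  )
}
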