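# Interpolated Markov-model genomic signatures and PCA separation of core
# versus strain-specific genes.

DNA_BASES <- c("A", "C", "G", "T")

#' Interpolated Markov-model features for one sequence
#'
#' Estimates the 64 conditional probabilities P(b | c1 c2) over all 2-base
#' contexts with an add-`pseudocount` estimator.  A context observed fewer
#' than `fallback_min_count` times falls back to the 1st-order estimate
#' P(b | c2) (and to the 0th-order base composition if that context is also
#' sparse), so short genes still yield stable features.  Windows containing
#' non-ACGT characters are skipped.
#'
#' @param nt_seq nucleotide string, length >= `order + 1`.
#' @param order Markov order (only the default 2 is supported).
#' @param fallback_min_count minimum context occurrence count before falling
#'   back one order (the "40 bp" rule).
#' @param pseudocount added to every transition count.
#' @return A list with `values` (named numeric of length 64, names like
#'   `"AC>G"`), `fallback_order` (named integer per context: 2, 1 or 0) and
#'   `fallback_mask` (logical per context, `TRUE` where a fallback was
#'   used).  Within each context the four probabilities sum to 1.
#' @export
imm_features <- function(nt_seq, order = 2, fallback_min_count = 40,
                         pseudocount = 1) {
  stopifnot(order == 2)
  s <- toupper(nt_seq)
  if (nchar(s) < order + 1) {
    stop("sequence shorter than order + 1", call. = FALSE)
  }
  chars <- strsplit(s, "")[[1]]
  ok <- chars %in% DNA_BASES
  L <- length(chars)
  contexts2 <- paste0(rep(DNA_BASES, each = 4), DNA_BASES)

  # 3-mer transition counts (windows fully ACGT)
  i3 <- seq_len(L - 2)
  v3 <- ok[i3] & ok[i3 + 1] & ok[i3 + 2]
  tri <- paste0(chars[i3[v3]], chars[i3[v3] + 1], chars[i3[v3] + 2])
  n3 <- table(factor(tri, levels = paste0(rep(contexts2, each = 4),
                                          DNA_BASES)))
  # 2-mer transition counts
  i2 <- seq_len(L - 1)
  v2 <- ok[i2] & ok[i2 + 1]
  dinuc <- paste0(chars[i2[v2]], chars[i2[v2] + 1])
  n2 <- table(factor(dinuc, levels = paste0(rep(DNA_BASES, each = 4),
                                            DNA_BASES)))
  # base counts
  n1 <- table(factor(chars[ok], levels = DNA_BASES))

  p_order0 <- (as.numeric(n1) + pseudocount) /
    (sum(n1) + 4 * pseudocount)
  names(p_order0) <- DNA_BASES
  p_order1 <- function(c2) {
    ctx_counts <- as.numeric(n2[paste0(c2, DNA_BASES)])
    n_ctx <- sum(ctx_counts)
    if (n_ctx < fallback_min_count) return(list(p = p_order0, ord = 0L))
    list(p = setNames((ctx_counts + pseudocount) /
                        (n_ctx + 4 * pseudocount), DNA_BASES), ord = 1L)
  }

  values <- numeric(0)
  fallback_order <- setNames(integer(16), contexts2)
  for (ctx in contexts2) {
    ctx_counts <- as.numeric(n3[paste0(ctx, DNA_BASES)])
    n_ctx <- sum(ctx_counts)
    if (n_ctx >= fallback_min_count) {
      p <- (ctx_counts + pseudocount) / (n_ctx + 4 * pseudocount)
      fallback_order[ctx] <- 2L
    } else {
      fb <- p_order1(substr(ctx, 2, 2))
      p <- as.numeric(fb$p)
      fallback_order[ctx] <- fb$ord
    }
    names(p) <- paste0(ctx, ">", DNA_BASES)
    values <- c(values, p)
  }
  list(values = values, fallback_order = fallback_order,
       fallback_mask = fallback_order < 2L)
}

#' IMM feature matrix for a set of genes
#'
#' @param genes gene record table with nucleotide sequences, or a named
#'   character vector of sequences.
#' @param class_labels optional per-gene labels (e.g. core / specific),
#'   attached as attribute `class_labels`.
#' @inheritParams imm_features
#' @return Numeric matrix (genes x 64) with feature column names.
#' @export
imm_feature_matrix <- function(genes, class_labels = NULL, order = 2,
                               fallback_min_count = 40, pseudocount = 1) {
  seqs <- if (is.data.frame(genes)) {
    setNames(genes$nucleotide, genes$gene_id)
  } else genes
  if (anyNA(seqs)) stop("all genes need nucleotide sequences", call. = FALSE)
  feats <- t(vapply(seqs, function(s) {
    imm_features(s, order, fallback_min_count, pseudocount)$values
  }, numeric(64)))
  rownames(feats) <- names(seqs)
  if (!is.null(class_labels)) attr(feats, "class_labels") <- class_labels
  feats
}

#' Principal component projection of a feature matrix
#'
#' Columns are centered (not scaled) before the eigendecomposition.  Scores
#' are deterministic up to sign; the sign convention makes the largest-
#' magnitude loading of each component positive.  A constant feature matrix
#' yields zero scores and zero explained variance (not an error).
#'
#' @param x numeric matrix (genes x features), >= 2 rows.
#' @param n_components number of components to return.
#' @return A list with `scores` (genes x n_components), `loadings`,
#'   `explained_variance_ratio` (non-increasing, sums to <= 1).
#' @export
pca_projection <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  n_components <- min(n_components, ncol(x), nrow(x) - 1)
  total_var <- sum(apply(x, 2, var))
  if (total_var < 1e-24) {
    scores <- matrix(0, nrow(x), n_components,
                     dimnames = list(rownames(x),
                                     paste0("PC", seq_len(n_components))))
    return(list(scores = scores,
                loadings = matrix(0, ncol(x), n_components),
                explained_variance_ratio = rep(0, n_components)))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- p$rotation[, k, drop = FALSE]
  sco <- p$x[, k, drop = FALSE]
  for (j in k) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco, loadings = rot,
       explained_variance_ratio = (p$sdev^2 / sum(p$sdev^2))[k])
}

#' Separation of gene classes along the first principal component
#'
#' Reports the absolute difference of class means on PC1, the pooled
#' standard deviation, and the mean silhouette coefficient of the 1-D class
#' partition (positive silhouettes mean the classes occupy distinct ranges
#' of PC1).
#'
#' @param scores matrix or vector of PC scores (PC1 used) from
#'   [pca_projection()].
#' @param class_labels factor-like vector with exactly two classes present.
#' @return A list with `mean_difference`, `pooled_sd`, `silhouette`.
#' @export
signature_separation <- function(scores, class_labels) {
  pc1 <- if (is.matrix(scores)) scores[, 1] else as.numeric(scores)
  cls <- factor(class_labels)
  if (nlevels(droplevels(cls)) < 2) {
    stop("both classes must be represented", call. = FALSE)
  }
  by_cls <- split(pc1, cls)
  means <- vapply(by_cls, mean, numeric(1))
  vars <- vapply(by_cls, var, numeric(1))
  ns <- vapply(by_cls, length, numeric(1))
  pooled_sd <- sqrt(sum((ns - 1) * vars) / (sum(ns) - length(ns)))
  sil <- cluster::silhouette(as.integer(cls), dist(pc1))
  list(mean_difference = abs(diff(means))[[1]],
       pooled_sd = pooled_sd,
       silhouette = mean(sil[, "sil_width"]))
}
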