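# Core-gene concatenation, Poisson-corrected distances, neighbor-joining
# with bootstrap support, and average-linkage clustering of shared-gene
# patterns.

GAP_CHARS <- c("-", ".", "?")

#' Concatenate per-cluster core-gene alignments into a supermatrix
#'
#' Alignments are concatenated column-wise in deterministic cluster-id
#' order; every column containing a gap or missing character in any strain
#' is removed (complete deletion).  Per-gene column ranges are remapped to
#' post-deletion coordinates.
#'
#' @param alignments named list: cluster id -> named character vector
#'   (strain -> aligned protein string).  Every alignment must contain
#'   exactly one sequence per strain and all strains must agree across
#'   alignments.
#' @return An object of class `supermatrix`: list with `taxa`, `seqs`
#'   (named equal-length strings), `boundaries` (gene, start, end in
#'   post-deletion coordinates; `NA` when a gene lost all columns) and
#'   `n_removed_columns`.
#' @export
concatenate_core_alignments <- function(alignments) {
  if (!length(alignments) || is.null(names(alignments))) {
    stop("alignments must be a non-empty named list", call. = FALSE)
  }
  ord <- sort(names(alignments))
  taxa <- sort(names(alignments[[ord[1]]]))
  mats <- lapply(ord, function(cl) {
    aln <- alignments[[cl]]
    if (!setequal(names(aln), taxa) || anyDuplicated(names(aln))) {
      stop("alignment '", cl, "' must contain exactly one sequence per ",
           "strain (core genes are present in every strain)", call. = FALSE)
    }
    aln <- aln[taxa]
    w <- unique(nchar(aln))
    if (length(w) != 1) {
      stop("alignment '", cl, "' has rows of unequal length", call. = FALSE)
    }
    do.call(rbind, strsplit(aln, ""))
  })
  widths <- vapply(mats, ncol, integer(1))
  full <- do.call(cbind, mats)
  keep <- !apply(full, 2, function(col) any(col %in% GAP_CHARS))
  gene_of_col <- rep(ord, widths)
  boundaries <- df(gene = ord, start = NA_integer_, end = NA_integer_)
  kept_gene <- gene_of_col[keep]
  pos <- 0L
  for (i in seq_along(ord)) {
    w <- sum(kept_gene == ord[i])
    if (w > 0) {
      boundaries$start[i] <- pos + 1L
      boundaries$end[i] <- pos + w
      pos <- pos + w
    }
  }
  kept <- full[, keep, drop = FALSE]
  seqs <- setNames(apply(kept, 1, paste, collapse = ""), taxa)
  if (ncol(kept) == 0) seqs <- setNames(rep("", length(taxa)), taxa)
  structure(list(taxa = taxa, seqs = seqs, boundaries = boundaries,
                 n_removed_columns = sum(!keep)),
            class = "supermatrix")
}

#' Poisson-corrected distance matrix from a supermatrix
#'
#' For each pair of taxa, p is the proportion of differing columns and the
#' distance is the Poisson correction d = -ln(1 - p) (uniform rates among
#' sites).  Saturated pairs (p approaching 1) are an error naming the pair.
#'
#' @param sm a `supermatrix` with >= 2 taxa and width >= 1.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
poisson_distance_matrix <- function(sm) {
  stopifnot(inherits(sm, "supermatrix"))
  n <- length(sm$taxa)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  w <- unique(nchar(sm$seqs))
  if (length(w) != 1 || w == 0) {
    stop("supermatrix must have equal, positive width", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(unname(sm$seqs), ""))
  d <- matrix(0, n, n, dimnames = list(sm$taxa, sm$taxa))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      p <- mean(chars[i, ] != chars[j, ])
      if (p >= 1 - 1e-12) {
        stop("saturated pair (p -> 1): ", sm$taxa[i], " / ", sm$taxa[j],
             call. = FALSE)
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with Q-matrix minimization.  Ties in Q
#' are broken deterministically by the lexicographically smallest pair of
#' node labels (each active node is labelled by the smallest taxon in its
#' subtree).  Negative branch lengths are clamped to zero; the total clamped
#' deficit is recorded in attribute `negative_deficit`.  On an additive
#' matrix the generating topology and branch lengths are recovered exactly.
#'
#' @param dm symmetric distance matrix with dimnames, >= 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(rownames(dm))) stop("dm needs taxon dimnames", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-8) stop("dm must be symmetric", call. = FALSE)
  taxa <- rownames(dm)
  D <- dm
  node_str <- taxa                 # newick substring per active node
  node_lab <- taxa                 # smallest descendant taxon, for ties
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(D) > 3) {
    N <- nrow(D)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      paste(sort(node_lab[ij]), collapse = "\r")
    })
    sel <- cand[order(pair_key)[1], ]
    i <- sel[1]; j <- sel[2]
    li <- clamp(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (N - 2)))
    lj <- clamp(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (N - 2))))
    new_str <- sprintf("(%s:%s,%s:%s)", node_str[i], fmt(li),
                       node_str[j], fmt(lj))
    new_lab <- min(node_lab[i], node_lab[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(N), c(i, j))
    D2 <- matrix(0, N - 1, N - 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[N - 1, seq_along(keep)] <- D2[seq_along(keep), N - 1] <- dnew[keep]
    D <- D2
    node_str <- c(node_str[keep], new_str)
    node_lab <- c(node_lab[keep], new_lab)
  }
  # final three nodes: three-point formulas at the central node
  lx <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  ly <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lz <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  ord <- order(node_lab)
  lens <- c(lx, ly, lz)[ord]
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    node_str[ord[1]], fmt(lens[1]),
                    node_str[ord[2]], fmt(lens[2]),
                    node_str[ord[3]], fmt(lens[3]))
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_deficit") <- deficit
  tree
}

#' Bootstrap support for the neighbor-joining tree of a supermatrix
#'
#' Columns are resampled with replacement `replicates` times; a
#' neighbor-joining tree is built per replicate and each internal edge of
#' the full-data reference tree receives the percentage of replicate trees
#' containing the same bipartition (stored in `node.label`).  Replicates
#' whose resampled matrix is degenerate (e.g. a saturated pair) are skipped
#' with a warning and the denominator adjusted.
#'
#' @param sm a `supermatrix` (>= 4 taxa for internal edges to exist).
#' @param replicates bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return The reference `phylo` tree with `node.label` giving support in
#'   `[0, 100]` (`NA` on the unrooted basal node).
#' @export
bootstrap_support <- function(sm, replicates = 100, seed) {
  stopifnot(inherits(sm, "supermatrix"), replicates >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  ref <- neighbor_joining(poisson_distance_matrix(sm))
  chars <- do.call(rbind, strsplit(unname(sm$seqs), ""))
  rownames(chars) <- sm$taxa
  w <- ncol(chars)
  with_seed(seed, {
    boots <- list()
    for (r in seq_len(replicates)) {
      cols <- sample.int(w, w, replace = TRUE)
      bsm <- structure(list(taxa = sm$taxa,
                            seqs = setNames(apply(chars[, cols, drop = FALSE],
                                                  1, paste, collapse = ""),
                                            sm$taxa),
                            boundaries = NULL, n_removed_columns = 0L),
                       class = "supermatrix")
      tr <- tryCatch(neighbor_joining(poisson_distance_matrix(bsm)),
                     error = function(e) NULL)
      if (is.null(tr)) {
        warning("skipping degenerate bootstrap replicate ", r, call. = FALSE)
      } else {
        boots[[length(boots) + 1L]] <- tr
      }
    }
    if (!length(boots)) stop("all bootstrap replicates failed", call. = FALSE)
    counts <- ape::prop.clades(ref, boots, rooted = FALSE)
    ref$node.label <- 100 * counts / length(boots)
    ref
  })
}

#' Average-linkage dendrogram of the shared-gene matrix
#'
#' UPGMA-style average-linkage clustering on distance 1 - shared proportion;
#' taxa are sorted lexicographically beforehand so ties resolve
#' deterministically.  Merge heights are non-decreasing.
#'
#' @param sgm symmetric shared-gene proportion matrix ([shared_gene_matrix()]).
#' @return An `hclust` object.
#' @export
average_linkage_tree <- function(sgm) {
  sgm <- as.matrix(sgm)
  if (is.null(rownames(sgm))) stop("sgm needs dimnames", call. = FALSE)
  ord <- order(rownames(sgm))
  d <- 1 - sgm[ord, ord]
  hclust(as.dist(d), method = "average")
}
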