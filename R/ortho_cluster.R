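# Greedy incremental protein clustering at identity + shorter-sequence
# coverage thresholds, the orthologous-gene-cluster construction the rest of
# the pipeline builds on.

#' Pairwise protein identity and coverage
#'
#' Computes a global alignment with free end gaps (match +1, mismatch 0, gap
#' -1) between two proteins and reports the fraction of identical residues
#' and the coverage of the shorter sequence.  With the default
#' `identity_denominator = "shorter"` the identity is the number of identical
#' aligned pairs divided by the length of the shorter sequence (CD-HIT
#' semantics); `"alignment"` divides by the number of alignment columns
#' (gap columns included) inside the aligned span.  The function is symmetric
#' in its arguments: the pair is canonically ordered before alignment.
#'
#' @param a,b gene record rows (single-row data.frames) or plain protein
#'   strings.
#' @param identity_denominator `"shorter"` (default) or `"alignment"`.
#' @return A list with `identity`, `coverage_shorter` and `aligned_length`
#'   (residues of the shorter sequence inside the aligned span).
#' @export
pairwise_identity <- function(a, b,
                              identity_denominator = c("shorter", "alignment")) {
  identity_denominator <- match.arg(identity_denominator)
  pa <- if (is.data.frame(a)) a$protein else a
  pb <- if (is.data.frame(b)) b$protein else b
  assert_protein(c(pa, pb))
  r <- align_pair_cpp(pa, pb)
  list(identity = if (identity_denominator == "shorter") r$identity_shorter
       else r$identity_alignment,
       coverage_shorter = r$coverage_shorter,
       aligned_length = r$aligned_length)
}

#' Greedy incremental clustering of proteins
#'
#' Genes are processed in order of decreasing protein length (ties broken by
#' gene id); each gene joins the first existing cluster whose representative
#' it matches at both the identity and the shorter-sequence coverage
#' threshold, else it founds a new cluster with itself as representative.
#' Because the processing order is canonical, the result does not depend on
#' input order.  This reproduces the clustering contract of CD-HIT at desk
#' scale with exact alignments instead of word-filter heuristics.
#'
#' @param genes a gene record table ([gene_records()]).
#' @param identity_threshold,coverage_threshold fractions in `(0, 1]`.
#' @param identity_denominator see [pairwise_identity()].
#' @return An object of class `cluster_set`: list with `members` (gene_id,
#'   strain_id, species_id, cluster_id, representative_id, similarity,
#'   coverage, is_representative), `clusters` (cluster_id,
#'   representative_id, size) and `params`.
#' @export
greedy_cluster <- function(genes, identity_threshold = 0.7,
                           coverage_threshold = 0.7,
                           identity_denominator = c("shorter", "alignment")) {
  identity_denominator <- match.arg(identity_denominator)
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      coverage_threshold <= 0 || coverage_threshold > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  params <- list(identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 identity_denominator = identity_denominator)
  if (nrow(genes) == 0) {
    return(structure(list(members = df(gene_id = character(0),
                                       strain_id = character(0),
                                       species_id = character(0),
                                       protein_length = integer(0),
                                       cluster_id = character(0),
                                       representative_id = character(0),
                                       similarity = numeric(0),
                                       coverage = numeric(0),
                                       is_representative = logical(0)),
                          clusters = df(cluster_id = character(0),
                                        representative_id = character(0),
                                        size = integer(0)),
                          params = params),
                     class = "cluster_set"))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in input", call. = FALSE)
  }
  assert_protein(genes$protein)
  ord <- order(-nchar(genes$protein), genes$gene_id, method = "radix")
  g <- genes[ord, , drop = FALSE]
  res <- greedy_cluster_cpp(g$protein, identity_threshold,
                            coverage_threshold,
                            identity_denominator == "shorter")
  cluster_id <- sprintf("CL%05d", res$cluster)
  rep_gene <- g$gene_id[res$representative]  # by founding order
  members <- df(gene_id = g$gene_id,
                strain_id = if ("strain_id" %in% names(g)) g$strain_id
                else NA_character_,
                species_id = if ("species_id" %in% names(g)) g$species_id
                else NA_character_,
                protein_length = nchar(g$protein),
                cluster_id = cluster_id,
                representative_id = rep_gene[res$cluster],
                similarity = res$similarity,
                coverage = res$coverage,
                is_representative = g$gene_id == rep_gene[res$cluster])
  clusters <- df(cluster_id = sprintf("CL%05d", seq_along(rep_gene)),
                 representative_id = rep_gene,
                 size = as.integer(table(factor(res$cluster,
                                                levels = seq_along(rep_gene)))))
  structure(list(members = members, clusters = clusters, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d genes in %d clusters (identity >= %.2f, coverage >= %.2f, denominator = %s)\n",
              nrow(x$members), nrow(x$clusters),
              x$params$identity_threshold, x$params$coverage_threshold,
              x$params$identity_denominator))
  invisible(x)
}

#' Per-cluster similarity profile
#'
#' Mean member-to-representative similarity per cluster; singleton clusters
#' report 1.0 by convention (the representative is trivially identical to
#' itself).
#'
#' @param cs a `cluster_set`.
#' @return A data.frame with `cluster_id`, `size`, `mean_similarity`.
#' @export
cluster_similarity_profile <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  m <- cs$members
  out <- cs$clusters[, c("cluster_id", "size")]
  out$mean_similarity <- vapply(out$cluster_id, function(cl) {
    sims <- m$similarity[m$cluster_id == cl & !m$is_representative]
    if (!length(sims)) 1.0 else mean(sims)
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Cluster-count and similarity sweep over thresholds
#'
#' Runs [greedy_cluster()] once per threshold with identity and coverage set
#' equal (the paired sweep used to check that orthologous clusters are robust
#' to the threshold choice).
#'
#' @param genes gene record table.
#' @param thresholds ascending fractions in `(0, 1]`.
#' @param identity_denominator see [pairwise_identity()].
#' @return data.frame with `threshold`, `n_clusters`, `mean_similarity`
#'   (mean of per-cluster mean member-to-representative similarities).
#' @export
threshold_sweep <- function(genes, thresholds,
                            identity_denominator = c("shorter", "alignment")) {
  identity_denominator <- match.arg(identity_denominator)
  if (is.unsorted(thresholds)) {
    stop("thresholds must be sorted ascending", call. = FALSE)
  }
  rows <- lapply(thresholds, function(t) {
    cs <- greedy_cluster(genes, t, t, identity_denominator)
    prof <- cluster_similarity_profile(cs)
    df(threshold = t, n_clusters = nrow(cs$clusters),
       mean_similarity = mean(prof$mean_similarity))
  })
  do.call(rbind, rows)
}

#' Write a cluster set as TSV and CD-HIT-style .clstr text
#'
#' @param cs a `cluster_set`.
#' @param tsv_path,clstr_path output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_cluster_set <- function(cs, tsv_path = NULL, clstr_path = NULL) {
  stopifnot(inherits(cs, "cluster_set"))
  written <- character(0)
  if (!is.null(tsv_path)) {
    write.table(cs$members[, c("cluster_id", "representative_id", "gene_id",
                               "similarity")],
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv_path)
  }
  if (!is.null(clstr_path)) {
    con <- file(clstr_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(cs$clusters))) {
      cl <- cs$clusters$cluster_id[i]
      writeLines(sprintf(">Cluster %d", i - 1L), con)
      mem <- cs$members[cs$members$cluster_id == cl, ]
      mem <- mem[order(!mem$is_representative, mem$gene_id), ]
      for (j in seq_len(nrow(mem))) {
        tag <- if (mem$is_representative[j]) "*" else
          sprintf("at %.2f%%", 100 * mem$similarity[j])
        writeLines(sprintf("%d\t%daa, >%s... %s", j - 1L,
                           mem$protein_length[j], mem$gene_id[j], tag), con)
      }
    }
    written <- c(written, clstr_path)
  }
  invisible(written)
}
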