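# Core / dispensable / strain-specific classification of orthologous
# clusters, accumulation curves, genus-level core genes and the shared-gene
# matrix.

new_pan_genome_table <- function(presence, labels, paralogous, species_id,
                                 roster, counts, specific_includes_paralogs) {
  structure(list(presence = presence, labels = labels,
                 paralogous = paralogous, species_id = species_id,
                 strain_roster = roster, counts = counts,
                 specific_includes_paralogs = specific_includes_paralogs),
            class = "pan_genome_table")
}

#' Build a pan-genome table from a presence matrix
#'
#' Lower-level constructor used mainly in tests and for imported presence
#' data: rows are clusters, columns strains.  Labels follow the standard
#' definitions: a cluster with members from every strain is core; a cluster
#' confined to a single strain is strain-specific; anything else is
#' dispensable.  Multi-member single-strain clusters cannot be expressed
#' here (a presence matrix has no sizes), so `paralogous` is all-`FALSE`.
#'
#' @param presence logical matrix (clusters x strains) with dimnames.
#' @param species_id species label.
#' @return A `pan_genome_table`.
#' @export
pan_genome_table <- function(presence, species_id = NA_character_) {
  stopifnot(is.matrix(presence), !is.null(rownames(presence)),
            !is.null(colnames(presence)))
  presence <- presence > 0
  n_strains <- ncol(presence)
  n_present <- rowSums(presence)
  if (any(n_present == 0)) stop("empty cluster row", call. = FALSE)
  labels <- ifelse(n_present == n_strains, "core",
                   ifelse(n_present == 1, "strain_specific", "dispensable"))
  names(labels) <- rownames(presence)
  paralogous <- setNames(rep(FALSE, nrow(presence)), rownames(presence))
  counts <- c(n_core = sum(labels == "core"),
              n_dispensable = sum(labels == "dispensable"),
              n_specific = sum(labels == "strain_specific"),
              n_paralogous = 0L)
  new_pan_genome_table(presence, labels, paralogous, species_id,
                       colnames(presence), counts, FALSE)
}

#' Classify clusters into core, dispensable and strain-specific genes
#'
#' A cluster containing genes from every strain of the roster is a core
#' gene; a singleton cluster is a strain-specific gene; clusters spanning
#' some but not all strains are dispensable.  Multi-member clusters confined
#' to one strain (within-strain paralog families) are labelled
#' `strain_specific` with a `paralogous` flag; by default the summary counts
#' preserve the singleton definition and report paralogous clusters
#' separately (set `specific_includes_paralogs = TRUE` to count them as
#' specific).
#'
#' @param cs a `cluster_set` whose members carry `strain_id`.
#' @param roster character vector of all strains of the species.
#' @param specific_includes_paralogs logical, see above.
#' @return A `pan_genome_table` with `presence` (cluster x strain logical
#'   matrix), `labels`, `paralogous`, and `counts` (n_core, n_dispensable,
#'   n_specific, n_paralogous, plus per-strain specific counts in
#'   `attr(, "per_strain_specific")`).
#' @export
classify_clusters <- function(cs, roster,
                              specific_includes_paralogs = FALSE) {
  stopifnot(inherits(cs, "cluster_set"))
  m <- cs$members
  if (anyNA(m$strain_id)) stop("members lack strain_id", call. = FALSE)
  unknown <- setdiff(unique(m$strain_id), roster)
  if (length(unknown)) {
    stop("strain_id not in roster: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cl_levels <- cs$clusters$cluster_id
  presence <- table(factor(m$cluster_id, levels = cl_levels),
                    factor(m$strain_id, levels = roster)) > 0
  presence <- matrix(presence, nrow = length(cl_levels),
                     dimnames = list(cl_levels, roster))
  sizes <- setNames(cs$clusters$size, cs$clusters$cluster_id)
  n_present <- rowSums(presence)
  labels <- ifelse(n_present == length(roster), "core",
                   ifelse(n_present == 1, "strain_specific", "dispensable"))
  names(labels) <- cl_levels
  paralogous <- n_present == 1 & sizes[cl_levels] > 1
  names(paralogous) <- cl_levels
  singleton_specific <- labels == "strain_specific" & !paralogous
  n_specific <- if (specific_includes_paralogs) {
    sum(labels == "strain_specific")
  } else sum(singleton_specific)
  counts <- c(n_core = sum(labels == "core"),
              n_dispensable = sum(labels == "dispensable"),
              n_specific = n_specific,
              n_paralogous = sum(paralogous))
  out <- new_pan_genome_table(presence, labels, paralogous,
                              m$species_id[1], roster, counts,
                              specific_includes_paralogs)
  spec_cl <- names(labels)[if (specific_includes_paralogs)
    labels == "strain_specific" else singleton_specific]
  spec_strain <- apply(presence[spec_cl, , drop = FALSE], 1,
                       function(x) roster[which(x)[1]])
  attr(out, "per_strain_specific") <-
    table(factor(spec_strain, levels = roster))
  out
}

#' @export
print.pan_genome_table <- function(x, ...) {
  cat(sprintf("pan-genome table '%s': %d clusters x %d strains\n",
              x$species_id, nrow(x$presence), length(x$strain_roster)))
  print(x$counts)
  invisible(x)
}

#' Pan- and core-genome accumulation curves
#'
#' For each of `n_permutations` random strain orderings, pan(k) is the
#' number of clusters present in at least one of the first k strains and
#' core(k) the number present in all of them; means and standard deviations
#' over permutations are reported.
#'
#' @param table a `pan_genome_table`.
#' @param n_permutations number of random strain orderings (>= 1).
#' @param seed integer seed.
#' @return data.frame with `k`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`.
#' @export
accumulation_curves <- function(table, n_permutations = 100, seed) {
  stopifnot(inherits(table, "pan_genome_table"), n_permutations >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  P <- table$presence
  n <- ncol(P)
  with_seed(seed, {
    pan <- core <- matrix(0L, n_permutations, n)
    for (r in seq_len(n_permutations)) {
      ord <- sample(n)
      seen_any <- rep(FALSE, nrow(P))
      seen_all <- rep(TRUE, nrow(P))
      for (k in seq_len(n)) {
        col <- P[, ord[k]]
        seen_any <- seen_any | col
        seen_all <- seen_all & col
        pan[r, k] <- sum(seen_any)
        core[r, k] <- sum(seen_all)
      }
    }
    df(k = seq_len(n),
       pan_mean = colMeans(pan), pan_sd = apply(pan, 2, sd),
       core_mean = colMeans(core), core_sd = apply(core, 2, sd))
  })
}

#' Genus-level core genes from per-species core panels
#'
#' Pools the representative core genes of every species and reclusters them
#' at relaxed thresholds (40%/40% by default); genus-core clusters are those
#' containing at least one core gene from every species.
#'
#' @param core_panels named list (species -> gene record table of core
#'   representatives); at least two species.
#' @param identity_threshold,coverage_threshold clustering thresholds.
#' @return A list with `clusters` (cluster_id, n_species, genus_core,
#'   species), `genus_core_gene_ids` (panel gene ids belonging to genus-core
#'   clusters) and the underlying `cluster_set`.
#' @export
genus_core <- function(core_panels, identity_threshold = 0.40,
                       coverage_threshold = 0.40) {
  if (length(core_panels) < 2) {
    stop("genus core requires at least two species panels", call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(names(core_panels), function(sp) {
    g <- core_panels[[sp]]
    g$species_id <- sp
    g
  }))
  cs <- greedy_cluster(pooled, identity_threshold, coverage_threshold)
  m <- cs$members
  sp_per_cl <- tapply(m$species_id, m$cluster_id,
                      function(x) sort(unique(x)), simplify = FALSE)
  all_sp <- sort(names(core_panels))
  cl_ids <- cs$clusters$cluster_id
  gc_flag <- vapply(cl_ids,
                    function(cl) identical(sp_per_cl[[cl]], all_sp),
                    logical(1))
  clusters <- df(cluster_id = cl_ids,
                 n_species = vapply(cl_ids,
                                    function(cl) length(sp_per_cl[[cl]]),
                                    integer(1)),
                 genus_core = gc_flag,
                 species = vapply(cl_ids,
                                  function(cl) paste(sp_per_cl[[cl]],
                                                     collapse = ","),
                                  character(1)))
  list(clusters = clusters,
       genus_core_gene_ids = m$gene_id[m$cluster_id %in% cl_ids[gc_flag]],
       cluster_set = cs)
}

#' Shared-gene proportion matrix between strains
#'
#' For each pair of strains the proportion of shared gene clusters; the
#' default denominator is the smaller of the two strains' cluster counts
#' (configurable: `"mean"` or `"union"`/Jaccard).
#'
#' @param table a `pan_genome_table` (>= 2 strains).
#' @param denominator `"min"` (default), `"mean"` or `"union"`.
#' @return A symmetric strains x strains matrix with unit diagonal.
#' @export
shared_gene_matrix <- function(table, denominator = c("min", "mean", "union")) {
  stopifnot(inherits(table, "pan_genome_table"))
  denominator <- match.arg(denominator)
  P <- table$presence
  if (ncol(P) < 2) stop("need at least 2 strains", call. = FALSE)
  storage.mode(P) <- "double"
  both <- crossprod(P)              # shared cluster counts
  tot <- diag(both)                 # per-strain cluster counts
  denom <- switch(denominator,
                  min = outer(tot, tot, pmin),
                  mean = outer(tot, tot, `+`) / 2,
                  union = outer(tot, tot, `+`) - both)
  out <- both / denom
  diag(out) <- 1.0
  out
}
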