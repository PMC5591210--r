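# Core-gene recruitment profiling of metagenome gene sets: which species'
# core genes are reconstructed, at plain and exclusive definitions.

#' Filter predicted metagenome genes by nucleotide length
#'
#' Keeps genes strictly longer than `min_nt_len` bases ("longer than 500
#' bps": a 500 bp gene is removed, a 501 bp gene retained).
#'
#' @param genes gene record table; every record must carry `nt_length`.
#' @param min_nt_len length cutoff in bases.
#' @return The retained records, with attributes `n_input` and
#'   `n_retained`.
#' @export
filter_predicted_genes <- function(genes, min_nt_len = 500) {
  if (!"nt_length" %in% names(genes) || anyNA(genes$nt_length)) {
    stop("every gene needs nt_length", call. = FALSE)
  }
  out <- genes[genes$nt_length > min_nt_len, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(genes)
  attr(out, "n_retained") <- nrow(out)
  out
}

#' Recruit metagenome genes into species core-gene clusters
#'
#' Pools every species' core representative proteins with the metagenome
#' proteins and clusters them greedily at the given thresholds.  A species'
#' core cluster is RECRUITED when its pooled cluster contains at least one
#' metagenome gene (clusters count once however many metagenome genes join),
#' and EXCLUSIVE when additionally no other species' core gene shares the
#' cluster — the species-level-resolution definition.
#'
#' @param core_panels named list: species -> gene record table of core
#'   representatives (one row per core cluster of that species).
#' @param metagenome gene record table of (pre-filtered, translated)
#'   metagenome genes.
#' @param identity_threshold,coverage_threshold clustering thresholds in
#'   `(0, 1]`.
#' @param genus_core_ids optional character vector of panel gene ids that
#'   are genus-core (see [genus_core()]); when supplied, the number of
#'   recruited clusters that are genus-core is reported per species.
#' @return A data.frame of class `recruitment_report`: per species,
#'   `n_core_clusters`, `n_recruited`, `recruited_fraction`, `n_exclusive`,
#'   `exclusive_fraction`, `genus_core_overlap`; thresholds in
#'   `attr(, "params")`.
#' @export
recruit <- function(core_panels, metagenome, identity_threshold = 0.9,
                    coverage_threshold = 0.7, genus_core_ids = NULL) {
  if (!length(core_panels) || any(!vapply(core_panels, nrow, integer(1)))) {
    stop("core panels must be non-empty", call. = FALSE)
  }
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      coverage_threshold <= 0 || coverage_threshold > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  panel <- do.call(rbind, lapply(names(core_panels), function(sp) {
    g <- core_panels[[sp]]
    g$species_id <- sp
    g
  }))
  mg <- metagenome
  mg$species_id <- "metagenome"
  pooled <- rbind(panel[, c("gene_id", "strain_id", "species_id", "protein")],
                  mg[, c("gene_id", "strain_id", "species_id", "protein")])
  cs <- greedy_cluster(pooled, identity_threshold, coverage_threshold)
  m <- cs$members
  is_mg <- m$species_id == "metagenome"
  mg_clusters <- unique(m$cluster_id[is_mg])
  species_per_cluster <- tapply(m$species_id[!is_mg], m$cluster_id[!is_mg],
                                function(x) unique(x), simplify = FALSE)
  rows <- lapply(names(core_panels), function(sp) {
    mine <- m[m$species_id == sp, ]
    in_mg_cluster <- mine$cluster_id %in% mg_clusters
    alone <- vapply(mine$cluster_id, function(cl) {
      identical(species_per_cluster[[cl]], sp)
    }, logical(1))
    n_core <- nrow(mine)
    n_rec <- sum(in_mg_cluster)
    n_exc <- sum(in_mg_cluster & alone)
    gco <- if (is.null(genus_core_ids)) NA_integer_ else
      sum(in_mg_cluster & mine$gene_id %in% genus_core_ids)
    df(species = sp, n_core_clusters = n_core, n_recruited = n_rec,
       recruited_fraction = n_rec / n_core, n_exclusive = n_exc,
       exclusive_fraction = n_exc / n_core, genus_core_overlap = gco)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(identity_threshold = identity_threshold,
                              coverage_threshold = coverage_threshold)
  class(out) <- c("recruitment_report", class(out))
  out
}

#' Compare recruitment reports at two thresholds
#'
#' Side-by-side recruited and exclusive fractions at the permissive (e.g.
#' 70%) and stringent (e.g. 90%) thresholds.  A species is flagged as
#' collapsing when it is recruited at the permissive threshold (fraction >
#' 0.05) but shows essentially no exclusive recruitment at the stringent one
#' (< 0.05) — the signature of a species absent from the metagenome that is
#' recruited only through genus-core genes of a present relative.
#'
#' @param report70,report90 `recruitment_report`s over the same species.
#' @return data.frame with fractions at both thresholds, their differences
#'   and the `collapses` flag.
#' @export
compare_thresholds <- function(report70, report90) {
  if (!setequal(report70$species, report90$species)) {
    stop("reports cover different species sets", call. = FALSE)
  }
  r90 <- report90[match(report70$species, report90$species), ]
  df(species = report70$species,
     recruited_70 = report70$recruited_fraction,
     exclusive_70 = report70$exclusive_fraction,
     recruited_90 = r90$recruited_fraction,
     exclusive_90 = r90$exclusive_fraction,
     recruited_drop = report70$recruited_fraction - r90$recruited_fraction,
     exclusive_drop = report70$exclusive_fraction - r90$exclusive_fraction,
     collapses = report70$recruited_fraction > 0.05 &
       r90$exclusive_fraction < 0.05)
}

#' Extract per-species core panels from a classified pan-genome
#'
#' Convenience bridge from [classify_clusters()] to [recruit()]: returns the
#' representative gene record of every core cluster.
#'
#' @param cs the `cluster_set` the table was built from.
#' @param table the corresponding `pan_genome_table`.
#' @param genes the gene record table (for sequences).
#' @return Gene record table of core-cluster representatives.
#' @export
core_panel <- function(cs, table, genes) {
  core_cl <- names(table$labels)[table$labels == "core"]
  reps <- cs$clusters$representative_id[cs$clusters$cluster_id %in% core_cl]
  out <- genes[match(reps, genes$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
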