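# Core/dispensable/strain-specific classification, accumulation curves,
# genus core and the shared-gene matrix.

make_cluster_set <- function(memberships) {
  # memberships: list cluster -> character vector of "strain" member tags
  rows <- do.call(rbind, lapply(names(memberships), function(cl) {
    strains <- memberships[[cl]]
    df <- data.frame(gene_id = paste0(cl, "_", seq_along(strains)),
                     strain_id = strains, stringsAsFactors = FALSE)
    df$cluster_id <- cl
    df
  }))
  rows$species_id <- "sp"
  rows$similarity <- 1
  rows$coverage <- 1
  rows$protein_length <- 100L
  first <- !duplicated(rows$cluster_id)
  rows$representative_id <- rows$gene_id[first][match(rows$cluster_id,
                                                      rows$cluster_id[first])]
  rows$is_representative <- rows$gene_id == rows$representative_id
  clusters <- data.frame(cluster_id = rows$cluster_id[first],
                         representative_id = rows$gene_id[first],
                         size = as.integer(table(rows$cluster_id)[
                           rows$cluster_id[first]]),
                         stringsAsFactors = FALSE)
  structure(list(members = rows, clusters = clusters,
                 params = list(identity_threshold = 0.7,
                               coverage_threshold = 0.7,
                               identity_denominator = "shorter")),
            class = "cluster_set")
}

test_that("clusters are labelled by the strain-span definitions", {
  roster <- paste0("s", 1:4)
  cs <- make_cluster_set(list(
    all4 = c("s1", "s2", "s3", "s4"),   # core
    two = c("s1", "s3"),                # dispensable
    single = "s2",                      # strain-specific singleton
    paralog = c("s4", "s4")))           # one strain, two members
  tab <- classify_clusters(cs, roster)
  expect_equal(unname(tab$labels[c("all4", "two", "single", "paralog")]),
               c("core", "dispensable", "strain_specific", "strain_specific"))
  expect_true(tab$paralogous[["paralog"]])
  expect_equal(unname(tab$counts["n_specific"]), 1)
  expect_equal(unname(tab$counts["n_paralogous"]), 1)
  tab2 <- classify_clusters(cs, roster, specific_includes_paralogs = TRUE)
  expect_equal(unname(tab2$counts["n_specific"]), 2)
  expect_error(classify_clusters(cs, c("s1", "s2")), "roster")
  # label partition covers all clusters
  expect_equal(sum(tab$counts[c("n_core", "n_dispensable", "n_specific",
                                "n_paralogous")]), nrow(cs$clusters))
})

test_that("classification recovers the generator truth on a small genome", {
  pg <- tiny_pangenome(seed = 71)
  cs <- greedy_cluster(pg$genes, 0.7, 0.7)
  tab <- classify_clusters(cs, pg$strain_roster)
  truth_counts <- table(pg$families$class)
  expect_equal(unname(tab$counts["n_core"]), unname(truth_counts["core"]))
  expect_equal(unname(tab$counts["n_dispensable"]),
               unname(truth_counts["dispensable"]))
  expect_equal(unname(tab$counts["n_specific"]),
               unname(truth_counts["specific"]))
  # per-strain specific counts sum to the total
  expect_equal(sum(attr(tab, "per_strain_specific")),
               unname(tab$counts["n_specific"]))
})

test_that("removing a strain never decreases the core count", {
  pg <- tiny_pangenome(seed = 72)
  cs <- greedy_cluster(pg$genes)
  full <- classify_clusters(cs, pg$strain_roster)
  for (drop in pg$strain_roster) {
    kept <- setdiff(pg$strain_roster, drop)
    sub_genes <- pg$genes[pg$genes$strain_id %in% kept, ]
    sub_cs <- greedy_cluster(sub_genes)
    sub <- classify_clusters(sub_cs, kept)
    expect_gte(unname(sub$counts["n_core"]), unname(full$counts["n_core"]))
  }
})

test_that("accumulation curves match an independent set replay", {
  pg <- tiny_pangenome(seed = 73)
  cs <- greedy_cluster(pg$genes)
  tab <- classify_clusters(cs, pg$strain_roster)
  curves <- accumulation_curves(tab, n_permutations = 25, seed = 9)
  n <- length(pg$strain_roster)
  expect_equal(nrow(curves), n)
  # k = full roster: core equals the classified core count
  expect_equal(curves$core_mean[n], unname(tab$counts["n_core"]))
  expect_equal(curves$core_sd[n], 0)
  # replay with the same seed using plain set operations on the presence
  # matrix
  P <- tab$presence
  pan_r <- core_r <- matrix(0, 25, n)
  set.seed(9)
  for (r in 1:25) {
    ord <- sample(n)
    for (k in 1:n) {
      cols <- P[, ord[1:k], drop = FALSE]
      pan_r[r, k] <- sum(rowSums(cols) >= 1)
      core_r[r, k] <- sum(rowSums(cols) == k)
    }
  }
  expect_equal(curves$pan_mean, colMeans(pan_r))
  expect_equal(curves$core_mean, colMeans(core_r))
  # per-permutation monotonicity aggregates to the means
  expect_true(all(diff(curves$pan_mean) >= 0))
  expect_true(all(diff(curves$core_mean) <= 0))
})

test_that("k = 1 accumulation equals single-strain cluster counts", {
  pg <- tiny_pangenome(seed = 74)
  tab <- classify_clusters(greedy_cluster(pg$genes), pg$strain_roster)
  curves <- accumulation_curves(tab, n_permutations = 50, seed = 2)
  expect_equal(curves$pan_mean[1], curves$core_mean[1])
  expect_lte(curves$pan_mean[1], nrow(tab$presence))
})

test_that("genus core finds exactly the families shared across species", {
  pg <- tiny_pangenome(seed = 75)
  panel <- pg$genes[pg$truth$class == "core" &
                      pg$genes$strain_id == pg$strain_roster[1], ]
  # identical panels: every cluster genus-core
  panel_b <- panel
  panel_b$gene_id <- paste0("B_", panel_b$gene_id)
  res <- genus_core(list(A = panel, B = panel_b))
  expect_true(all(res$clusters$genus_core))
  # disjoint dissimilar panels: none
  set.seed(3)
  other <- gene_records(gene_id = paste0("x", 1:10),
                        protein = vapply(1:10,
                                         function(i) random_protein(120),
                                         character(1)))
  res2 <- genus_core(list(A = panel, B = other))
  expect_equal(sum(res2$clusters$genus_core), 0)
  expect_error(genus_core(list(A = panel)), "two species")
})

test_that("genus core recovers a constructed number of shared families", {
  genus <- generate_genus(c("spA", "spB"), n_shared_families = 10,
                          species_divergence = 0.15,
                          pangenome_sim_config(
                            n_strains = 3, n_core_families = 25,
                            n_dispensable_families = 0,
                            n_specific_per_strain = 0,
                            core_divergence = 0.02,
                            gene_length_range = c(100L, 200L), seed = 19))
  panels <- lapply(genus, function(pg) {
    pg$genes[pg$truth$class == "core" &
               pg$genes$strain_id == pg$strain_roster[1], ]
  })
  res <- genus_core(panels, 0.40, 0.40)
  expect_equal(sum(res$clusters$genus_core), 10)
  # shared-family members stay above 40% identity across species
  shared <- attr(genus, "shared_families")
  a <- panels$spA[grep(paste(shared, collapse = "|"),
                       panels$spA$gene_id), ]
  b <- panels$spB[grep(paste(shared, collapse = "|"),
                       panels$spB$gene_id), ]
  for (fam in shared[1:3]) {
    pa <- a$protein[grep(fam, a$gene_id, fixed = TRUE)]
    pb <- b$protein[grep(fam, b$gene_id, fixed = TRUE)]
    expect_gte(pairwise_identity(pa, pb)$identity, 0.40)
  }
})

test_that("shared-gene proportions count co-occurring clusters", {
  # constructed presence matrix: 20 shared core clusters, strain A has 5
  # extra, strain B has 2 extra
  P <- matrix(FALSE, 27, 2, dimnames = list(sprintf("c%02d", 1:27),
                                            c("A", "B")))
  P[1:20, ] <- TRUE
  P[21:25, "A"] <- TRUE
  P[26:27, "B"] <- TRUE
  tab <- pan_genome_table(P, "sp")
  sgm <- shared_gene_matrix(tab)
  expect_equal(sgm["A", "B"], 20 / 22)  # min denominator
  expect_equal(sgm, t(sgm))
  expect_equal(diag(sgm), c(A = 1, B = 1))
  expect_equal(shared_gene_matrix(tab, "mean")["A", "B"], 20 / 23.5)
  expect_equal(shared_gene_matrix(tab, "union")["A", "B"], 20 / 27)
  # identical strains share everything
  P2 <- matrix(TRUE, 5, 3, dimnames = list(paste0("c", 1:5),
                                           c("A", "B", "C")))
  expect_true(all(shared_gene_matrix(pan_genome_table(P2, "sp")) == 1))
})
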