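# Supermatrix assembly, Poisson distances, neighbor-joining, bootstrap,
# average linkage.

test_that("concatenation joins alignments and applies complete deletion", {
  aln <- list(g1 = c(s1 = "MKTAYIAKQR", s2 = "MKTAYIAKQL"),
              g2 = c(s1 = "WWDDEEFFGGHHIIKKLLMM", s2 = "WWDDEEFFGGHHIIKKLLMM"))
  sm <- concatenate_core_alignments(aln)
  expect_equal(unique(nchar(sm$seqs)), 30)
  expect_equal(sm$boundaries$start, c(1, 11))
  expect_equal(sm$boundaries$end, c(10, 30))
  # a gap column is removed and boundaries are remapped
  aln2 <- list(g1 = c(s1 = "MKT-YIAKQR", s2 = "MKTAYIAKQL"), g2 = aln$g2)
  sm2 <- concatenate_core_alignments(aln2)
  expect_equal(unique(nchar(sm2$seqs)), 29)
  expect_equal(sm2$n_removed_columns, 1)
  expect_equal(sm2$boundaries$end, c(9, 29))
  # a missing strain is an error: core genes exist in every strain
  expect_error(concatenate_core_alignments(
    list(g1 = c(s1 = "MK"), g2 = c(s1 = "MK", s2 = "MK"))), "every")
  # single-taxon supermatrix is allowed; tree operations reject it later
  sm3 <- concatenate_core_alignments(list(g1 = c(s1 = "MKTA")))
  expect_equal(sm3$taxa, "s1")
})

test_that("Poisson distances follow -ln(1 - p)", {
  sm <- structure(list(taxa = c("a", "b"),
                       seqs = c(a = strrep("A", 100),
                                b = paste0(strrep("A", 95), strrep("C", 5)))),
                  class = "supermatrix")
  d <- poisson_distance_matrix(sm)
  expect_equal(d["a", "b"], -log(1 - 0.05))
  expect_equal(d["a", "b"], 0.051293, tolerance = 1e-4)
  expect_equal(diag(d), c(a = 0, b = 0))
  # identical rows give zero distance
  sm2 <- structure(list(taxa = c("a", "b"), seqs = c(a = "MKTA", b = "MKTA")),
                   class = "supermatrix")
  expect_true(all(poisson_distance_matrix(sm2) == 0))
  # saturation is an error naming the pair
  sm3 <- structure(list(taxa = c("a", "b"), seqs = c(a = "AAAA", b = "CCCC")),
                   class = "supermatrix")
  expect_error(poisson_distance_matrix(sm3), "a / b")
})

test_that("three-taxon trees solve the three-point formulas exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("additive matrices are recovered exactly", {
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  d <- ape::cophenetic.phylo(ref)
  tr <- neighbor_joining(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), tr)), 0)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)] -
                         d)), 0, tolerance = 1e-12)
  expect_equal(attr(tr, "negative_deficit"), 0)
})

test_that("equal-distance ties resolve deterministically", {
  taxa <- c("A", "B", "C", "D")
  d <- matrix(1, 4, 4, dimnames = list(taxa, taxa)); diag(d) <- 0
  t1 <- ape::write.tree(neighbor_joining(d))
  t2 <- ape::write.tree(neighbor_joining(d[c(3, 1, 4, 2), c(3, 1, 4, 2)]))
  expect_identical(t1, t2)
})

test_that("negative branch lengths are clamped and logged", {
  taxa <- c("A", "B", "C", "D")
  # a non-additive matrix known to drive one NJ branch negative
  d <- matrix(c(0, 2, 2, 2,
                2, 0, 0.1, 2,
                2, 0.1, 0, 2,
                2, 2, 2, 0), 4, dimnames = list(taxa, taxa))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "negative_deficit"), 0)
})

test_that("neighbor joining agrees with ape on random additive trees", {
  set.seed(12)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    ref$tip.label <- paste0("t", seq_len(n))
    d <- ape::cophenetic.phylo(ref)
    mine <- neighbor_joining(d)
    theirs <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(mine, ape::unroot(theirs))), 0)
    expect_equal(as.numeric(ape::dist.topo(mine, ape::unroot(ref))), 0)
  }
})

test_that("bootstrap gives full support to unambiguous signal", {
  block <- c(a = "AAAAT", b = "AAACT", c = "GGGCT", d = "GGGGT")
  sm <- structure(list(taxa = names(block),
                       seqs = vapply(block, strrep, character(1), times = 20)),
                  class = "supermatrix")
  tr <- bootstrap_support(sm, replicates = 25, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  # one replicate: supports are 0 or 100
  tr1 <- bootstrap_support(sm, replicates = 1, seed = 6)
  sup1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
})

test_that("average linkage reproduces a hand-computed block trace", {
  taxa <- c("a1", "a2", "b1", "b2")
  sgm <- matrix(0.5, 4, 4, dimnames = list(taxa, taxa))
  sgm[1:2, 1:2] <- 0.9; sgm[3:4, 3:4] <- 0.9; diag(sgm) <- 1
  hc <- average_linkage_tree(sgm)
  # within-group merges at 0.1, final join at 0.5
  expect_equal(hc$height, c(0.1, 0.1, 0.5))
  groups <- cutree(hc, 2)
  expect_equal(unname(groups[c("a1", "a2")]), c(1, 1))
  expect_equal(unname(groups[c("b1", "b2")]), c(2, 2))
  # heights are monotone non-decreasing
  expect_true(all(diff(hc$height) >= 0))
  # clones merge first at height zero
  sgm2 <- sgm; sgm2["a1", "a2"] <- sgm2["a2", "a1"] <- 1
  hc2 <- average_linkage_tree(sgm2)
  expect_equal(hc2$height[1], 0)
})

test_that("core-gene tree groups match dispensable-sharing groups", {
  # two strain groups whose core genes diverge along the same split that
  # structures dispensable-gene sharing
  cfg <- pangenome_sim_config(n_strains = 6, n_core_families = 40,
                              n_dispensable_families = 0,
                              n_specific_per_strain = 0,
                              core_divergence = 0, seed = 23,
                              gene_length_range = c(80L, 120L))
  pg <- generate_pangenome(cfg)
  group <- rep(c(1, 2), each = 3)
  names(group) <- pg$strain_roster
  # core alignment: group 2 strains carry extra substitutions per family
  alns <- list()
  for (fam in unique(pg$truth$family_id)) {
    rows <- pg$truth$family_id == fam
    prots <- setNames(pg$genes$protein[rows], pg$genes$strain_id[rows])
    set.seed(sum(utf8ToInt(fam)))
    mutated <- mutate_protein(prots[[1]], 0.3)
    prots[group[names(prots)] == 2] <- mutated
    # small within-group noise
    for (s in names(prots)) {
      set.seed(sum(utf8ToInt(paste0(fam, s))))
      prots[s] <- mutate_protein(prots[[s]], 0.02)
    }
    alns[[fam]] <- prots
  }
  sm <- concatenate_core_alignments(alns)
  tr <- neighbor_joining(poisson_distance_matrix(sm))
  nj_groups <- cutree(hclust(as.dist(ape::cophenetic.phylo(tr)), "average"), 2)
  # dispensable sharing with the same block structure
  P <- matrix(FALSE, 60, 6, dimnames = list(sprintf("d%02d", 1:60),
                                            pg$strain_roster))
  P[1:25, group == 1] <- TRUE
  P[26:50, group == 2] <- TRUE
  P[51:60, ] <- TRUE
  al_groups <- cutree(average_linkage_tree(
    shared_gene_matrix(pan_genome_table(P, "sp"))), 2)
  expect_gt(rand_index(unname(nj_groups[pg$strain_roster]),
                       unname(al_groups[pg$strain_roster])), 0.9)
})
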