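# Synthetic pan-genome generator: multi-strain gene sets with known
# core/dispensable/strain-specific structure, used as ground truth for the
# clustering, classification, signature and profiling stages.

#' Simulation configuration for a synthetic pan-genome
#'
#' Defaults describe a compact but realistic single-species pan-genome: a few
#' hundred well-conserved core families, dispensable families present in a
#' random subset of strains, and composition-shifted strain-specific
#' singletons emulating horizontally acquired genes (host GC 0.45 versus
#' alien GC 0.60, a gap of the magnitude seen between bacterial hosts and
#' mobile elements).
#'
#' @param n_strains number of strains (>= 2).
#' @param n_core_families families with exactly one member in every strain.
#' @param n_dispensable_families families present in some strains only; each
#'   family's presence vector is Binomial(`n_strains`,
#'   `dispensable_presence_prob`) conditioned on 2..`n_strains - 1` members,
#'   so dispensable families are never degenerate (all-present families would
#'   be core; single-member families would be strain-specific).
#' @param dispensable_presence_prob per-strain inclusion probability.
#' @param n_specific_per_strain strain-specific singletons per strain, drawn
#'   fresh from the alien composition model.
#' @param core_divergence per-site substitution probability applied to each
#'   family member relative to the family ancestor (see [mutate_sequence()]);
#'   must lie in `[0, 0.5)`.  Keep it well below `1 - identity_threshold` of
#'   the downstream clustering if core families are to be recovered intact.
#' @param gene_length_range protein length range in amino acids (min >= 50;
#'   shorter genes make identity estimates too unstable to be useful).
#' @param host_gc,alien_gc GC fraction of the 0th-order composition model for
#'   host (core/dispensable) and alien (strain-specific) genes.
#' @param species_id species label stamped on every record.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `pangenome_sim_config`.
#' @export
pangenome_sim_config <- function(n_strains = 5, n_core_families = 100,
                                 n_dispensable_families = 50,
                                 dispensable_presence_prob = 0.5,
                                 n_specific_per_strain = 5,
                                 core_divergence = 0.02,
                                 gene_length_range = c(100L, 400L),
                                 host_gc = 0.45, alien_gc = 0.60,
                                 species_id = "speciesA", seed) {
  stopifnot(n_strains >= 2, n_core_families >= 0,
            n_dispensable_families >= 0, n_specific_per_strain >= 0)
  if (core_divergence < 0 || core_divergence >= 0.5) {
    stop("core_divergence must lie in [0, 0.5)", call. = FALSE)
  }
  if (dispensable_presence_prob <= 0 || dispensable_presence_prob >= 1) {
    stop("dispensable_presence_prob must lie in (0, 1)", call. = FALSE)
  }
  if (length(gene_length_range) != 2 || gene_length_range[1] < 50) {
    stop("gene_length_range minimum must be at least 50 aa", call. = FALSE)
  }
  if (gene_length_range[2] < gene_length_range[1]) {
    stop("gene_length_range must be (min, max)", call. = FALSE)
  }
  for (g in c(host_gc, alien_gc)) {
    if (g <= 0 || g >= 1) stop("GC fractions must lie in (0, 1)", call. = FALSE)
  }
  if (n_dispensable_families > 0 && n_strains < 3) {
    stop("dispensable families need n_strains >= 3 (a dispensable family ",
         "must have between 2 and n_strains - 1 members)", call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  structure(list(n_strains = as.integer(n_strains),
                 n_core_families = as.integer(n_core_families),
                 n_dispensable_families = as.integer(n_dispensable_families),
                 dispensable_presence_prob = dispensable_presence_prob,
                 n_specific_per_strain = as.integer(n_specific_per_strain),
                 core_divergence = core_divergence,
                 gene_length_range = as.integer(gene_length_range),
                 host_gc = host_gc, alien_gc = alien_gc,
                 species_id = species_id, seed = as.integer(seed)),
            class = "pangenome_sim_config")
}

# Random CDS under a 0th-order composition model parameterized by GC:
# ATG start, n_aa - 1 random non-stop codons, TAA stop.
random_cds <- function(n_aa, gc) {
  n_codons <- n_aa - 1L
  if (n_codons < 1L) stop("genes must be at least 2 aa", call. = FALSE)
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(k) {
    matrix(sample(names(base_prob), 3L * k, replace = TRUE, prob = base_prob),
           nrow = 3L)
  }
  m <- draw(n_codons)
  codons <- apply(m, 2, paste, collapse = "")
  repeat {
    bad <- which(codons %in% STOP_CODONS)
    if (!length(bad)) break
    m2 <- draw(length(bad))
    codons[bad] <- apply(m2, 2, paste, collapse = "")
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Mutate a coding sequence without breaking the reading frame
#'
#' Substitutions are biased toward the third codon position (probability
#' `divergence`) with the second position mutated at a quarter of that rate
#' and the first position never, so protein divergence stays well below
#' nucleotide divergence, mimicking purifying selection on real orthologs.
#' The start and stop codons are left untouched and codons that would become
#' internal stops are redrawn, so the output is always a translatable CDS of
#' the same length.
#'
#' @param nt_seq CDS string (A/C/G/T only).
#' @param divergence third-position substitution probability in `[0, 0.5)`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return The mutated sequence, with attribute `n_substitutions` holding the
#'   realized number of changed positions (equal to the Hamming distance from
#'   the input).
#' @export
mutate_sequence <- function(nt_seq, divergence, seed = NULL) {
  assert_nucleotide(nt_seq, "nt_seq")
  if (divergence < 0 || divergence >= 0.5) {
    stop("divergence must lie in [0, 0.5)", call. = FALSE)
  }
  if (nchar(nt_seq) %% 3L != 0L) {
    stop("nt_seq length must be a multiple of 3", call. = FALSE)
  }
  with_seed(seed, {
    chars <- strsplit(nt_seq, "")[[1]]
    n_codons <- length(chars) %/% 3L
    n_sub <- 0L
    if (divergence > 0 && n_codons > 2L) {
      bases <- c("A", "C", "G", "T")
      # interior codons only: codon 1 (start) and last codon (stop) untouched
      idx <- seq.int(2L, n_codons - 1L)
      h3 <- runif(length(idx)) < divergence
      h2 <- runif(length(idx)) < divergence * 0.25
      for (k in which(h3 | h2)) {
        cd <- idx[k]
        off <- (cd - 1L) * 3L
        hit3 <- h3[k]
        hit2 <- h2[k]
        old <- chars[(off + 1L):(off + 3L)]
        repeat {
          cand <- old
          if (hit3) cand[3] <- sample(setdiff(bases, old[3]), 1L)
          if (hit2) cand[2] <- sample(setdiff(bases, old[2]), 1L)
          if (!(paste(cand, collapse = "") %in% STOP_CODONS)) break
        }
        n_sub <- n_sub + sum(cand != old)
        chars[(off + 1L):(off + 3L)] <- cand
      }
    }
    structure(paste(chars, collapse = ""), n_substitutions = n_sub)
  })
}

prot_divergence <- function(protein, ancestor_protein) {
  a <- strsplit(protein, "")[[1]]
  b <- strsplit(ancestor_protein, "")[[1]]
  mean(a != b)
}

#' Generate a synthetic pan-genome with known truth
#'
#' Core and dispensable family members derive from a family ancestor via
#' [mutate_sequence()] at `core_divergence`; strain-specific singletons are
#' drawn fresh from the alien composition model, giving them a genomic
#' signature distinct from the host.  Gene ids follow
#' `"<strain>|<family>|<serial>"` so provenance never relies on FASTA
#' descriptions.
#'
#' @param config a [pangenome_sim_config()].
#' @param core_ancestors optional named character vector of ancestral CDS for
#'   the first core families (used to share families between species when
#'   simulating a genus); remaining core ancestors are drawn fresh.
#' @return An object of class `synthetic_pangenome`: a list with `genes` (a
#'   gene record table), `truth` (gene_id, strain_id, family_id, class,
#'   prot_divergence versus the family ancestor), `families` (family_id,
#'   class, ancestor_nt, ancestor_protein), `strain_roster`, `species_id`
#'   and `config`.
#' @export
generate_pangenome <- function(config, core_ancestors = NULL) {
  stopifnot(inherits(config, "pangenome_sim_config"))
  with_seed(config$seed, {
    strains <- sprintf("%s_s%02d", config$species_id, seq_len(config$n_strains))
    lens <- config$gene_length_range
    rand_len <- function() sample(seq.int(lens[1], lens[2]), 1L)

    fam_rows <- list(); gene_rows <- list(); serial <- 0L
    add_gene <- function(strain, family, nt, anc_prot) {
      serial <<- serial + 1L
      prot <- translate_cds(nt)
      gene_rows[[length(gene_rows) + 1L]] <<-
        df(gene_id = sprintf("%s|%s|%05d", strain, family, serial),
           strain_id = strain, family_id = family,
           protein = prot, nucleotide = nt,
           prot_divergence = prot_divergence(prot, anc_prot))
    }

    n_shared <- if (is.null(core_ancestors)) 0L else length(core_ancestors)
    if (n_shared > config$n_core_families) {
      stop("more core_ancestors than core families", call. = FALSE)
    }
    for (f in seq_len(config$n_core_families)) {
      fam <- sprintf("core%04d", f)
      anc <- if (f <= n_shared) core_ancestors[[f]] else
        random_cds(rand_len(), config$host_gc)
      anc_prot <- translate_cds(anc)
      fam_rows[[length(fam_rows) + 1L]] <-
        df(family_id = fam, class = "core", ancestor_nt = anc,
           ancestor_protein = anc_prot)
      for (s in strains) {
        add_gene(s, fam, mutate_sequence(anc, config$core_divergence), anc_prot)
      }
    }
    for (f in seq_len(config$n_dispensable_families)) {
      fam <- sprintf("disp%04d", f)
      anc <- random_cds(rand_len(), config$host_gc)
      anc_prot <- translate_cds(anc)
      fam_rows[[length(fam_rows) + 1L]] <-
        df(family_id = fam, class = "dispensable", ancestor_nt = anc,
           ancestor_protein = anc_prot)
      repeat {  # conditional binomial: 2 .. n_strains - 1 members
        present <- rbinom(config$n_strains, 1L,
                          config$dispensable_presence_prob) == 1L
        if (sum(present) >= 2L && sum(present) < config$n_strains) break
      }
      for (s in strains[present]) {
        add_gene(s, fam, mutate_sequence(anc, config$core_divergence), anc_prot)
      }
    }
    k <- 0L
    for (s in strains) {
      for (f in seq_len(config$n_specific_per_strain)) {
        k <- k + 1L
        fam <- sprintf("spec%04d", k)
        nt <- random_cds(rand_len(), config$alien_gc)
        fam_rows[[length(fam_rows) + 1L]] <-
          df(family_id = fam, class = "specific", ancestor_nt = nt,
             ancestor_protein = translate_cds(nt))
        add_gene(s, fam, nt, translate_cds(nt))
      }
    }

    truth <- do.call(rbind, gene_rows)
    families <- do.call(rbind, fam_rows)
    truth$class <- families$class[match(truth$family_id, families$family_id)]
    genes <- gene_records(gene_id = truth$gene_id, protein = truth$protein,
                          strain_id = truth$strain_id,
                          species_id = config$species_id,
                          nucleotide = truth$nucleotide)
    structure(list(genes = genes,
                   truth = truth[, c("gene_id", "strain_id", "family_id",
                                     "class", "prot_divergence")],
                   families = families,
                   strain_roster = strains,
                   species_id = config$species_id,
                   config = config),
              class = "synthetic_pangenome")
  })
}

#' @export
print.synthetic_pangenome <- function(x, ...) {
  cat(sprintf("synthetic pan-genome '%s': %d strains, %d genes (%d families)\n",
              x$species_id, length(x$strain_roster), nrow(x$genes),
              nrow(x$families)))
  print(table(x$families$class))
  invisible(x)
}

#' Generate a synthetic genus of related species
#'
#' The first `n_shared_families` core families of every species descend from
#' common genus ancestors, each species lineage diverging from the ancestor
#' by `species_divergence` (so cross-species protein identity of shared
#' families falls between typical clustering thresholds, emulating
#' genus-core genes shared across species); the remaining core families and
#' all other content are species-private.
#'
#' @param species_ids character vector of species labels (>= 2).
#' @param n_shared_families genus-core families shared by all species.
#' @param species_divergence per-lineage third-position substitution
#'   probability applied between the genus ancestor and each species
#'   ancestor.
#' @param config_template a [pangenome_sim_config()] whose counts, lengths,
#'   GC and divergence settings apply to every species; per-species seeds and
#'   species ids are derived from it.
#' @return A named list of `synthetic_pangenome` objects, with attribute
#'   `shared_families` naming the genus-core family ids.
#' @export
generate_genus <- function(species_ids, n_shared_families,
                           species_divergence, config_template) {
  stopifnot(inherits(config_template, "pangenome_sim_config"),
            length(species_ids) >= 2,
            n_shared_families <= config_template$n_core_families)
  with_seed(config_template$seed, {
    lens <- config_template$gene_length_range
    shared_anc <- lapply(seq_len(n_shared_families), function(i) {
      random_cds(sample(seq.int(lens[1], lens[2]), 1L), config_template$host_gc)
    })
    seeds <- sample.int(.Machine$integer.max, length(species_ids))
    out <- lapply(seq_along(species_ids), function(i) {
      sp_anc <- lapply(shared_anc, mutate_sequence,
                       divergence = species_divergence)
      cfg <- config_template
      cfg$species_id <- species_ids[i]
      cfg$seed <- seeds[i]
      generate_pangenome(cfg, core_ancestors = sp_anc)
    })
    names(out) <- species_ids
    attr(out, "shared_families") <- sprintf("core%04d",
                                            seq_len(n_shared_families))
    out
  })
}

#' Sample a metagenome gene pool from synthetic pan-genomes
#'
#' For each species in `species_mix`, a uniformly random subset of exactly
#' `round(fraction * n_core_families)` core families contributes one mutated
#' copy of a randomly chosen member; decoy genes unrelated to any species are
#' drawn from a composition model at `decoy_gc`.  This emulates genes
#' predicted from assembled metagenome contigs.
#'
#' @param pg a `synthetic_pangenome` or a named list of them (a genus, see
#'   [generate_genus()]).
#' @param species_mix named numeric vector: species id -> core-inclusion
#'   fraction in `[0, 1]`.
#' @param n_decoys number of decoy genes.
#' @param decoy_gc GC fraction for decoys.
#' @param mutation third-position substitution probability applied to sampled
#'   copies (see [mutate_sequence()]).
#' @param seed integer seed.
#' @return A list with `genes` (gene record table, strain/species set to
#'   `"metagenome"`) and `truth` (gene_id, source_species, source_family;
#'   decoys labelled `"decoy"`).
#' @export
generate_metagenome_genes <- function(pg, species_mix = numeric(0),
                                      n_decoys = 0, decoy_gc = 0.60,
                                      mutation = 0.02, seed) {
  if (inherits(pg, "synthetic_pangenome")) {
    pgs <- list(pg)
    names(pgs) <- pg$species_id
  } else {
    pgs <- pg
  }
  if (length(species_mix)) {
    if (is.null(names(species_mix)) ||
        !all(names(species_mix) %in% names(pgs))) {
      stop("species_mix names must be species present in pg", call. = FALSE)
    }
    if (any(species_mix < 0 | species_mix > 1)) {
      stop("core-inclusion fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    serial <- 0L
    for (sp in names(species_mix)) {
      spg <- pgs[[sp]]
      core_fams <- spg$families$family_id[spg$families$class == "core"]
      n_pick <- round(species_mix[[sp]] * length(core_fams))
      picked <- sample(core_fams, n_pick)
      for (fam in picked) {
        members <- spg$truth$gene_id[spg$truth$family_id == fam]
        src <- sample(members, 1L)
        nt <- spg$genes$nucleotide[spg$genes$gene_id == src]
        nt <- mutate_sequence(nt, mutation)
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <-
          df(gene_id = sprintf("mg|%05d|%s|%s", serial, sp, fam),
             nucleotide = unclass(nt), source_species = sp,
             source_family = fam)
      }
    }
    if (n_decoys > 0) {
      lens <- if (inherits(pgs[[1]], "synthetic_pangenome")) {
        pgs[[1]]$config$gene_length_range
      } else c(100L, 400L)
      for (i in seq_len(n_decoys)) {
        serial <- serial + 1L
        nt <- random_cds(sample(seq.int(lens[1], lens[2]), 1L), decoy_gc)
        rows[[length(rows) + 1L]] <-
          df(gene_id = sprintf("mg|%05d|decoy|d%04d", serial, i),
             nucleotide = nt, source_species = "decoy",
             source_family = "decoy")
      }
    }
    if (!length(rows)) {
      return(list(genes = gene_records(character(0), character(0))[0, ],
                  truth = df(gene_id = character(0),
                             source_species = character(0),
                             source_family = character(0))))
    }
    tab <- do.call(rbind, rows)
    genes <- gene_records(gene_id = tab$gene_id,
                          protein = translate_cds(tab$nucleotide),
                          strain_id = "metagenome", species_id = "metagenome",
                          nucleotide = tab$nucleotide)
    list(genes = genes,
         truth = tab[, c("gene_id", "source_species", "source_family")])
  })
}

#' Write a synthetic pan-genome to per-strain FASTA plus a truth table
#'
#' @param pg a `synthetic_pangenome`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_pangenome <- function(pg, dir) {
  stopifnot(inherits(pg, "synthetic_pangenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (s in pg$strain_roster) {
    sub <- pg$genes[pg$genes$strain_id == s, ]
    pp <- file.path(dir, paste0(s, ".faa"))
    np <- file.path(dir, paste0(s, ".fna"))
    write_gene_fasta(sub, pp, np)
    written <- c(written, pp, np)
  }
  tp <- file.path(dir, "truth.tsv")
  write.table(pg$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(written, tp))
}
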