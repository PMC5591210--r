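# COG assignment from ranked homology hits, fractional functional-category
# weighting with the mobilome transposase/phage split, and core-versus-
# specific enrichment.

COG_CATEGORY_LETTERS <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRSX", "")[[1]]

validate_hit_table <- function(hits) {
  need <- c("gene_id", "rank", "cog_id")
  if (!all(need %in% names(hits))) {
    stop("hit table needs columns gene_id, rank, cog_id", call. = FALSE)
  }
  key <- paste(hits$gene_id, hits$rank)
  if (anyDuplicated(key)) {
    stop("duplicate (gene_id, rank) in hit table", call. = FALSE)
  }
  by_gene <- split(hits$rank, hits$gene_id)
  ok <- vapply(by_gene, function(r) {
    length(r) <= 5 && identical(sort(as.integer(r)), seq_along(r))
  }, logical(1))
  if (!all(ok)) {
    stop("ranks must be contiguous from 1 with at most five hits per gene: ",
         paste(names(by_gene)[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign a COG to each gene from its ranked best hits
#'
#' A gene is assigned a COG when at least `min_agree` of its (up to five)
#' best hits name the same COG id; otherwise it is "uncharacterized".  The
#' result depends only on the multiset of hit COG ids, not their order.  In
#' the rare tie case (two COGs both reaching `min_agree`, possible only when
#' `min_agree <= 2`), the COG with the best (lowest) rank wins, then the
#' lexicographically smaller id.
#'
#' @param hits data.frame with `gene_id`, `rank` (1..5, contiguous per
#'   gene), `cog_id` and optionally `bitscore`.
#' @param min_agree agreement threshold, default 3.
#' @return data.frame with `gene_id`, `cog_id` ("uncharacterized" where no
#'   COG qualifies).
#' @export
assign_cog <- function(hits, min_agree = 3) {
  validate_hit_table(hits)
  genes <- unique(hits$gene_id)
  cog <- vapply(genes, function(g) {
    h <- hits[hits$gene_id == g, ]
    counts <- table(h$cog_id)
    top <- counts[counts >= min_agree]
    if (!length(top)) return("uncharacterized")
    cand <- names(top)[top == max(top)]
    if (length(cand) > 1) {
      best_rank <- vapply(cand, function(cg) min(h$rank[h$cog_id == cg]),
                          numeric(1))
      cand <- cand[best_rank == min(best_rank)]
      cand <- sort(cand)
    }
    cand[1]
  }, character(1))
  df(gene_id = genes, cog_id = unname(cog))
}

#' Fractional functional-category weights per gene
#'
#' Each assigned COG maps to a string of one or more functional-category
#' letters; a gene's unit weight is split equally among them (a COG of class
#' "EH" contributes 0.5 to E and 0.5 to H).  Mobilome (X) weights are
#' relabelled `X:t` when the COG product name matches a transposase keyword
#' and `X:p` when it matches a phage keyword.  Genes without a qualifying
#' COG carry weight 1 in the "uncharacterized" bin.
#'
#' @param assignments output of [assign_cog()] (gene_id, cog_id).
#' @param cog_meta data.frame with `cog_id`, `class_string`, `product_name`.
#' @param transposase_keywords,phage_keywords case-insensitive keyword sets
#'   for the mobilome split (data-driven, not hard-coded biology).
#' @return data.frame with `gene_id`, `category`, `weight`; weights sum to 1
#'   per gene.
#' @export
category_weights <- function(assignments, cog_meta,
                             transposase_keywords = c("transposase"),
                             phage_keywords = c("phage", "prophage")) {
  stopifnot(all(c("gene_id", "cog_id") %in% names(assignments)),
            all(c("cog_id", "class_string") %in% names(cog_meta)))
  if (!"product_name" %in% names(cog_meta)) cog_meta$product_name <- ""
  rows <- lapply(seq_len(nrow(assignments)), function(i) {
    g <- assignments$gene_id[i]
    cg <- assignments$cog_id[i]
    j <- match(cg, cog_meta$cog_id)
    if (cg == "uncharacterized" || is.na(j)) {
      if (cg != "uncharacterized") {
        warning("no metadata for ", cg, "; treating ", g,
                " as uncharacterized", call. = FALSE)
      }
      return(df(gene_id = g, category = "uncharacterized", weight = 1))
    }
    cls <- cog_meta$class_string[j]
    if (is.na(cls) || !nzchar(cls)) {
      stop("empty class_string for ", cg, call. = FALSE)
    }
    letters_ <- strsplit(cls, "")[[1]]
    bad <- setdiff(letters_, COG_CATEGORY_LETTERS)
    if (length(bad)) {
      stop("unknown COG category letter(s) ", paste(bad, collapse = ""),
           " for ", cg, call. = FALSE)
    }
    prod <- cog_meta$product_name[j]
    kw_hit <- function(kws) any(vapply(kws, grepl, logical(1), x = prod,
                                       ignore.case = TRUE))
    cats <- vapply(letters_, function(L) {
      if (L != "X") return(L)
      if (kw_hit(transposase_keywords)) "X:t"
      else if (kw_hit(phage_keywords)) "X:p"
      else "X"
    }, character(1))
    df(gene_id = g, category = unname(cats),
       weight = 1 / length(letters_))
  })
  do.call(rbind, rows)
}

#' Functional-category enrichment between core and strain-specific genes
#'
#' Summed category weights are converted to proportions for each gene class
#' and compared category by category.  The default test is a two-sided
#' Fisher exact test on the 2x2 table of rounded summed weights versus the
#' rounded remainder in each class (rounding fractional weights to integers
#' is an approximation; `method = "permutation"` permutes gene class labels
#' instead and needs no rounding).  Benjamini-Hochberg adjusted p-values are
#' reported alongside raw ones.  Categories absent from both classes are
#' omitted.
#'
#' @param core,specific [category_weights()] tables for the two gene
#'   classes.
#' @param method `"fisher"` (default) or `"permutation"`.
#' @param n_permutations,seed permutation-test controls.
#' @return data.frame with `category`, `core_weight`, `specific_weight`,
#'   `core_prop`, `specific_prop`, `p_value`, `p_adjust`.
#' @export
enrichment <- function(core, specific, method = c("fisher", "permutation"),
                       n_permutations = 1000, seed = 1) {
  method <- match.arg(method)
  if (!nrow(core) || !nrow(specific)) {
    stop("both weight sets must be non-empty", call. = FALSE)
  }
  tot_core <- sum(core$weight)
  tot_spec <- sum(specific$weight)
  if (tot_core <= 0 || tot_spec <= 0) {
    stop("zero total weight", call. = FALSE)
  }
  cats <- sort(unique(c(core$category, specific$category)))
  wsum <- function(w, cat) sum(w$weight[w$category == cat])
  out <- df(category = cats,
            core_weight = vapply(cats, wsum, numeric(1), w = core),
            specific_weight = vapply(cats, wsum, numeric(1), w = specific))
  out <- out[out$core_weight > 0 | out$specific_weight > 0, , drop = FALSE]
  out$core_prop <- out$core_weight / tot_core
  out$specific_prop <- out$specific_weight / tot_spec
  if (method == "fisher") {
    out$p_value <- vapply(seq_len(nrow(out)), function(i) {
      a <- round(out$core_weight[i])
      b <- round(tot_core) - a
      c_ <- round(out$specific_weight[i])
      d <- round(tot_spec) - c_
      fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    }, numeric(1))
  } else {
    out$p_value <- permutation_enrichment_p(core, specific, out$category,
                                            n_permutations, seed)
  }
  out$p_adjust <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

# Label-permutation p-value for the difference in category proportions.
permutation_enrichment_p <- function(core, specific, cats, n_permutations,
                                     seed) {
  all_w <- rbind(df(gene_id = core$gene_id, category = core$category,
                    weight = core$weight, class = "core"),
                 df(gene_id = specific$gene_id, category = specific$category,
                    weight = specific$weight, class = "specific"))
  genes <- unique(all_w$gene_id[all_w$class == "core"])
  sgenes <- unique(all_w$gene_id[all_w$class == "specific"])
  ids <- c(genes, sgenes)
  n_core <- length(genes)
  stat <- function(core_ids) {
    w_core <- all_w[all_w$gene_id %in% core_ids, ]
    w_spec <- all_w[!all_w$gene_id %in% core_ids, ]
    vapply(cats, function(cat) {
      sum(w_core$weight[w_core$category == cat]) / sum(w_core$weight) -
        sum(w_spec$weight[w_spec$category == cat]) / sum(w_spec$weight)
    }, numeric(1))
  }
  obs <- abs(stat(genes))
  with_seed(seed, {
    hits <- rep(0L, length(cats))
    for (r in seq_len(n_permutations)) {
      perm <- sample(ids, n_core)
      hits <- hits + (abs(stat(perm)) >= obs - 1e-12)
    }
    (hits + 1) / (n_permutations + 1)
  })
}
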