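# Independent reference implementations used to validate the package's
# compiled alignment/clustering path and its statistics.  Pure R, written
# directly from the scoring definitions, no shared code with R/ or src/.

# Overlap (free end-gap) alignment, match +1 / mismatch 0 / gap -1, with the
# documented deterministic conventions: canonical pair order (longer first,
# equal lengths lexicographically smaller first), fill preference
# diag > up > left, end cell = best score on last row/column with ties going
# to the smaller row then column index.
oracle_align <- function(a, b) {
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  s1 <- strsplit(a, "")[[1]]
  s2 <- strsplit(b, "")[[1]]
  n <- length(s1); m <- length(s2)
  H <- matrix(0L, n + 1, m + 1)
  TB <- matrix(0L, n + 1, m + 1)  # 0 start, 1 diag, 2 up, 3 left
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- H[i, j] + (s1[i] == s2[j])
      dir <- 1L
      up <- H[i, j + 1] - 1L
      if (up > best) { best <- up; dir <- 2L }
      left <- H[i + 1, j] - 1L
      if (left > best) { best <- left; dir <- 3L }
      H[i + 1, j + 1] <- best
      TB[i + 1, j + 1] <- dir
    }
  }
  bi <- bj <- NA; bscore <- -Inf
  for (i in 0:n) {
    js <- if (i < n) m else 0:m
    for (j in js) {
      if (H[i + 1, j + 1] > bscore) {
        bscore <- H[i + 1, j + 1]; bi <- i; bj <- j
      }
    }
  }
  i <- bi; j <- bj; matches <- 0L; cols <- 0L
  while (i > 0 && j > 0) {
    dir <- TB[i + 1, j + 1]
    if (dir == 1L) {
      if (s1[i] == s2[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (dir == 2L) i <- i - 1L else j <- j - 1L
    cols <- cols + 1L
  }
  span1 <- bi - i; span2 <- bj - j
  min_len <- min(n, m)
  span_short <- if (n > m) span2 else min(span1, span2)
  list(identity_shorter = matches / min_len,
       identity_alignment = if (cols > 0) matches / cols else 0,
       coverage_shorter = span_short / min_len,
       matches = matches)
}

# Replay of the greedy clustering rule on an independently computed
# all-pairs identity/coverage matrix.
oracle_greedy <- function(genes, identity_threshold, coverage_threshold) {
  ord <- order(-nchar(genes$protein), genes$gene_id, method = "radix")
  g <- genes[ord, , drop = FALSE]
  reps <- integer(0)
  assign <- integer(nrow(g))
  for (k in seq_len(nrow(g))) {
    hit <- 0L
    for (ci in seq_along(reps)) {
      al <- oracle_align(g$protein[reps[ci]], g$protein[k])
      if (al$identity_shorter >= identity_threshold &&
          al$coverage_shorter >= coverage_threshold) {
        hit <- ci
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, k)
      assign[k] <- length(reps)
    } else {
      assign[k] <- hit
    }
  }
  setNames(g$gene_id[reps][assign], g$gene_id)
}

# Two-sided Fisher exact p by hypergeometric enumeration (R's rule: sum of
# table probabilities <= observed * (1 + 1e-7)).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Plain Rand index between two partitions.
rand_index <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")
  same_y <- outer(y, y, "==")
  ut <- upper.tri(same_x)
  mean(same_x[ut] == same_y[ut])
}

random_protein <- function(n_aa) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n_aa,
               replace = TRUE), collapse = "")
}

# Mutate a protein at exactly round(frac * n) positions (always to a
# different residue) -- used to construct pairs with known identity.
mutate_protein <- function(protein, frac) {
  chars <- strsplit(protein, "")[[1]]
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  k <- round(frac * length(chars))
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1)
  paste(chars, collapse = "")
}

# Simulate from a strongly structured 2nd-order Markov chain: context c1 c2
# prefers to emit c1 again with probability 0.91 (0.03 for the others).
# That preference makes the context dynamics measure-preserving, so every
# context is visited about equally often and every conditional probability
# is estimated from a similar number of transitions.  Returns the sequence
# and the 64 generating conditional probabilities in feature order.
simulate_markov2 <- function(len, seed) {
  bases <- c("A", "C", "G", "T")
  contexts <- paste0(rep(bases, each = 4), bases)
  set.seed(seed)
  probs <- matrix(0.03, 16, 4, dimnames = list(contexts, bases))
  for (i in 1:16) probs[i, substr(contexts[i], 1, 1)] <- 0.91
  s <- character(len)
  s[1:2] <- sample(bases, 2, replace = TRUE)
  for (i in 3:len) {
    ctx <- paste0(s[i - 2], s[i - 1])
    s[i] <- sample(bases, 1, prob = probs[ctx, ])
  }
  truth <- as.vector(t(probs))
  names(truth) <- paste0(rep(contexts, each = 4), ">", bases)
  list(sequence = paste(s, collapse = ""), truth = truth)
}

# Small synthetic pan-genome shared by several test files.
tiny_pangenome <- function(seed = 42) {
  generate_pangenome(pangenome_sim_config(
    n_strains = 4, n_core_families = 15, n_dispensable_families = 8,
    dispensable_presence_prob = 0.5, n_specific_per_strain = 3,
    core_divergence = 0.02, gene_length_range = c(60L, 120L), seed = seed))
}
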