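# Internal helpers shared across modules.

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Amino-acid alphabet accepted in protein records.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

assert_protein <- function(protein, what = "protein") {
  if (!is.character(protein) || anyNA(protein) || any(!nzchar(protein))) {
    stop(what, " sequences must be non-empty character strings", call. = FALSE)
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), protein)
  if (any(bad)) {
    stop(what, " contains characters outside the 20-letter amino-acid ",
         "alphabet plus X (uppercase)", call. = FALSE)
  }
  invisible(TRUE)
}

assert_nucleotide <- function(nt, what = "nucleotide sequence") {
  if (!is.character(nt) || anyNA(nt) || any(!nzchar(nt))) {
    stop(what, " must be a non-empty character string", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", nt))) {
    stop(what, " must contain only A, C, G, T", call. = FALSE)
  }
  invisible(TRUE)
}

# Translate CDS strings (with trailing stop codon) to protein strings using
# the standard code (identical to bacterial table 11 for internal codons).
translate_cds <- function(nt) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                           if.fuzzy.codon = "error"))
  sub("\\*$", "", aa)
}

gc_content <- function(nt) {
  vapply(strsplit(nt, ""), function(x) mean(x %in% c("G", "C")), numeric(1))
}

# data.frame without factor surprises
df <- function(...) data.frame(..., stringsAsFactors = FALSE)
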