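#' Construct a gene record table
#'
#' Gene records are the common currency of the package: one row per gene with
#' strain and species provenance, the protein sequence and (optionally) the
#' coding nucleotide sequence.  All clustering and profiling functions accept
#' and return this shape.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param protein uppercase amino-acid sequences (20-letter alphabet plus X).
#' @param strain_id,species_id provenance labels (recycled if length 1).
#' @param nucleotide optional CDS strings (A/C/G/T, including the stop
#'   codon), or `NA` where unavailable.  When present, a CDS must have length
#'   `3 * nchar(protein) + 3`.
#' @return A `data.frame` with columns `gene_id`, `strain_id`, `species_id`,
#'   `protein`, `nucleotide`, `nt_length`.
#' @export
gene_records <- function(gene_id, protein, strain_id = NA_character_,
                         species_id = NA_character_,
                         nucleotide = NA_character_) {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique", call. = FALSE)
  assert_protein(protein)
  n <- length(gene_id)
  out <- df(gene_id = as.character(gene_id),
            strain_id = rep_len(as.character(strain_id), n),
            species_id = rep_len(as.character(species_id), n),
            protein = protein,
            nucleotide = rep_len(as.character(nucleotide), n))
  has_nt <- !is.na(out$nucleotide)
  if (any(has_nt)) {
    assert_nucleotide(out$nucleotide[has_nt])
    bad <- nchar(out$nucleotide[has_nt]) != 3L * nchar(out$protein[has_nt]) + 3L
    if (any(bad)) {
      stop("CDS length must equal 3 * protein length + 3 (stop codon) for: ",
           paste(head(out$gene_id[has_nt][bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  out$nt_length <- ifelse(has_nt, nchar(out$nucleotide), NA_integer_)
  rownames(out) <- NULL
  out
}

#' Write gene records to FASTA
#'
#' Headers follow the convention `"<gene_id> strain=<s> species=<sp>"` so that
#' provenance survives a round trip through plain FASTA.
#'
#' @param genes a gene record table (see [gene_records()]).
#' @param protein_path,nucleotide_path output paths; either may be `NULL` to
#'   skip that file.  Writing nucleotides requires every record to carry one.
#' @return Invisibly, the paths written.
#' @export
write_gene_fasta <- function(genes, protein_path = NULL,
                             nucleotide_path = NULL) {
  headers <- sprintf("%s strain=%s species=%s", genes$gene_id,
                     genes$strain_id, genes$species_id)
  written <- character(0)
  if (!is.null(protein_path)) {
    aa <- Biostrings::AAStringSet(genes$protein)
    names(aa) <- headers
    Biostrings::writeXStringSet(aa, protein_path)
    written <- c(written, protein_path)
  }
  if (!is.null(nucleotide_path)) {
    if (anyNA(genes$nucleotide)) {
      stop("cannot write nucleotide FASTA: some records lack a CDS",
           call. = FALSE)
    }
    nt <- Biostrings::DNAStringSet(genes$nucleotide)
    names(nt) <- headers
    Biostrings::writeXStringSet(nt, nucleotide_path)
    written <- c(written, nucleotide_path)
  }
  invisible(written)
}

#' Read gene records from FASTA
#'
#' @param protein_path protein multi-FASTA whose headers follow
#'   `"<gene_id> strain=<s> species=<sp>"`; bare identifiers are accepted
#'   (provenance then `NA`).
#' @param nucleotide_path optional matching nucleotide FASTA (same gene ids).
#' @return A gene record table.
#' @export
read_gene_fasta <- function(protein_path, nucleotide_path = NULL) {
  aa <- Biostrings::readAAStringSet(protein_path)
  hdr <- names(aa)
  gene_id <- sub("\\s.*$", "", hdr)
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(sprintf("%s=\\S+", key), hdr))
    out <- rep(NA_character_, length(hdr))
    hit <- grepl(sprintf("%s=\\S+", key), hdr)
    out[hit] <- sub(sprintf("^%s=", key), "", m)
    out
  }
  nucleotide <- NA_character_
  if (!is.null(nucleotide_path)) {
    nt <- Biostrings::readDNAStringSet(nucleotide_path)
    nt_id <- sub("\\s.*$", "", names(nt))
    nucleotide <- as.character(nt)[match(gene_id, nt_id)]
  }
  gene_records(gene_id = gene_id, protein = as.character(aa),
               strain_id = grab("strain"), species_id = grab("species"),
               nucleotide = nucleotide)
}
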