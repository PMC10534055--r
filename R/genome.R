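#' Load a reference genome from FASTA
#'
#' Reads a (possibly gzip-compressed) FASTA file into an in-memory genome
#' object. Contig names are taken from the header line up to the first
#' whitespace, sequences are uppercased, and IUPAC ambiguity codes other
#' than A/C/G/T are replaced by `N` (with a warning), so downstream code
#' can assume the `{A,C,G,T,N}` alphabet.
#'
#' @param fasta_path Path to a FASTA file.
#' @return An object of class `nmde_genome`: a named character vector of
#'   uppercase contig sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT test contig", "acgtACGT"), fa)
#' g <- load_genome(fa)
#' genome_seq(g, "chrT", 1, 4)
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  dss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dss) == 0L) abort("empty FASTA: no records")
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate contig name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(dss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warn("non-ACGTN characters in FASTA replaced by N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  names(seqs) <- nm
  structure(seqs, class = "nmde_genome")
}

#' @export
print.nmde_genome <- function(x, ...) {
  cat("<nmde_genome> ", length(x), " contig(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Extract genome sequence
#'
#' @param g An `nmde_genome`.
#' @param contig Contig name.
#' @param start,end 1-based closed genomic coordinates.
#' @return Uppercase nucleotide string.
#' @export
genome_seq <- function(g, contig, start, end) {
  if (!contig %in% names(g)) abort(paste0("contig not in genome: ", contig))
  s <- g[[contig]]
  if (start < 1L || end > nchar(s) || start > end) {
    abort(sprintf("coordinates [%d,%d] outside contig %s (1..%d)",
                  start, end, contig, nchar(s)))
  }
  substr(s, start, end)
}

contig_length <- function(g, contig) nchar(g[[contig]])

#' Write a genome object to FASTA
#'
#' @param g An `nmde_genome`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path, width = 60L) {
  dss <- Biostrings::DNAStringSet(unclass(g))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}
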