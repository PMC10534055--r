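#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# complement map covering the load-time alphabet
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  # strand flips are frequent on short alleles; chartr + reverse is cheap
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# strip/add "chr" so VCF and GTF contig vocabularies can be compared
normalize_contig <- function(x) {
  y <- sub("^chr", "", x)
  y[y == "M"] <- "MT"
  y
}

standard_contigs <- function() {
  base <- c(1:22, "X", "Y", "M", "MT")
  c(paste0("chr", base), as.character(base))
}

pad_width_for <- function(len) max(nchar(as.character(len)), 9L)

snv_key <- function(contig, pos, ref, alt, pad = 9L) {
  sprintf("%s:%0*d:%s>%s", contig, pad, pos, ref, alt)
}
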