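#' Read variants from a VCF file
#'
#' Parses a VCF (v4.x, optionally gzip/bgzip-compressed), splits
#' multiallelic records into one biallelic row per alternate allele, and
#' skips symbolic alleles (`<DEL>`, breakends), spanning-deletion `*`
#' alleles, and alleles containing characters outside A/C/G/T. Skip counts
#' are attached as the `"skipped"` attribute.
#'
#' @param vcf_path Path to a VCF file.
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `source_id` (the VCF ID, or a CHROM:POS:REF:ALT key when ID is "."),
#'   `allele_index` (1-based index into the original ALT list) and
#'   `multiallelic`.
#' @export
read_variants <- function(vcf_path) {
  if (!file.exists(vcf_path)) abort(paste0("VCF not found: ", vcf_path))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  skipped <- c(symbolic = 0L, star = 0L, non_acgt = 0L)
  if (nrow(fix) == 0L) {
    out <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), source_id = character(),
                  allele_index = integer(), multiallelic = logical())
    attr(out, "skipped") <- skipped
    return(out)
  }
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- toupper(fix$REF[i])
    id <- fix$ID[i]
    key <- if (!is.na(id) && nzchar(id) && id != ".") id
           else paste(fix$CHROM[i], fix$POS[i], ref, fix$ALT[i], sep = ":")
    multi <- length(alts) > 1L
    keep_k <- integer(0)
    for (k in seq_along(alts)) {
      a <- toupper(alts[k])
      if (grepl("[][<>]", a)) { skipped["symbolic"] <- skipped["symbolic"] + 1L; next }
      if (a == "*") { skipped["star"] <- skipped["star"] + 1L; next }
      if (grepl("[^ACGT]", a) || grepl("[^ACGT]", ref)) {
        skipped["non_acgt"] <- skipped["non_acgt"] + 1L; next
      }
      keep_k <- c(keep_k, k)
    }
    if (length(keep_k)) {
      rows[[i]] <- tibble(
        contig = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = ref,
        alt = toupper(alts[keep_k]),
        source_id = key,
        allele_index = keep_k,
        multiallelic = multi
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), source_id = character(),
                  allele_index = integer(), multiallelic = logical())
  }
  n_sk <- sum(skipped)
  if (n_sk > 0L) {
    inform(sprintf("read_variants: skipped %d allele(s) (symbolic=%d, '*'=%d, non-ACGT=%d)",
                   n_sk, skipped["symbolic"], skipped["star"], skipped["non_acgt"]))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Classify a normalized variant
#'
#' The class is determined solely from the allele lengths of a normalized
#' variant: (1,1) is an SNV; (1,k>1) with a shared leading anchor base an
#' insertion; (k>1,1) a deletion; anything else a delins.
#'
#' @param ref,alt Character vectors of reference/alternate alleles.
#' @return Character vector: `"snv"`, `"ins"`, `"del"` or `"delins"`.
#' @export
variant_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  dplyr::case_when(
    nr == 1L & na == 1L ~ "snv",
    nr == 1L & na > 1L & substr(alt, 1L, 1L) == ref ~ "ins",
    nr > 1L & na == 1L & substr(ref, 1L, 1L) == alt ~ "del",
    .default = "delins"
  )
}

# normalize one allele pair; genome is the contig sequence string
normalize_one <- function(pos, ref, alt, contig_seq) {
  repeat {
    # shared-suffix truncation
    while (nchar(ref) >= 1L && nchar(alt) >= 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    if (nchar(ref) >= 1L && nchar(alt) >= 1L) break
    if (pos <= 1L) abort("left-normalization underflowed the contig start")
    pos <- pos - 1L
    b <- substr(contig_seq, pos, pos)
    ref <- paste0(b, ref)
    alt <- paste0(b, alt)
  }
  # shared-prefix trimming
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-normalize variants
#'
#' Rewrites each variant to its leftmost-aligned, most parsimonious
#' representation: shared trailing bases are truncated (extending leftward
#' from the genome when an allele empties), then shared leading bases are
#' trimmed while both alleles keep at least one base. The biological edit
#' is unchanged and the operation is idempotent; SNVs are fixed points.
#'
#' @param variants A variants tibble (see [read_variants()]).
#' @param genome An `nmde_genome`.
#' @param on_mismatch What to do when REF does not match the genome at
#'   `pos`: drop the row with a warning (default) or error.
#' @return The tibble with `pos`, `ref`, `alt` normalized; dropped-row
#'   count in attribute `"n_mismatch"`.
#' @export
left_normalize <- function(variants, genome,
                           on_mismatch = c("drop", "error")) {
  on_mismatch <- match.arg(on_mismatch)
  n <- nrow(variants)
  keep <- rep(TRUE, n)
  pos <- variants$pos; ref <- toupper(variants$ref); alt <- toupper(variants$alt)
  for (i in seq_len(n)) {
    ctg <- variants$contig[i]
    if (!ctg %in% names(genome)) {
      if (on_mismatch == "error") abort(paste0("contig not in genome: ", ctg))
      keep[i] <- FALSE; next
    }
    cs <- genome[[ctg]]
    span_end <- pos[i] + nchar(ref[i]) - 1L
    if (pos[i] < 1L || span_end > nchar(cs) ||
        substr(cs, pos[i], span_end) != ref[i]) {
      if (on_mismatch == "error") {
        abort(sprintf("REF mismatch at %s:%d (%s)", ctg, pos[i], ref[i]))
      }
      keep[i] <- FALSE; next
    }
    if (ref[i] == alt[i]) {        # identity record: no edit to represent
      if (on_mismatch == "error") {
        abort(sprintf("degenerate variant (REF == ALT) at %s:%d", ctg, pos[i]))
      }
      keep[i] <- FALSE; next
    }
    if (nchar(ref[i]) == 1L && nchar(alt[i]) == 1L) next
    nv <- normalize_one(pos[i], ref[i], alt[i], cs)
    pos[i] <- nv$pos; ref[i] <- nv$ref; alt[i] <- nv$alt
  }
  out <- variants
  out$pos <- pos; out$ref <- ref; out$alt <- alt
  n_bad <- sum(!keep)
  if (n_bad > 0L) {
    warn(sprintf("left_normalize: dropped %d invalid variant(s) (REF/genome mismatch or REF == ALT)", n_bad))
    out <- out[keep, , drop = FALSE]
  }
  attr(out, "n_mismatch") <- n_bad
  out
}

AENMD_INFO_HEADER <- paste0(
  '##INFO=<ID=AENMD,Number=.,Type=String,Description=',
  '"transcript_id|is_ptc|last_exon|penultimate|css_proximal|exon407|single_exon">')

#' Write an annotated VCF
#'
#' Copies the input VCF, adds one `##INFO` header line, and appends an
#' `AENMD` INFO entry to every record with at least one PTC-generating
#' transcript annotation. Each entry has the form
#' `transcript_id|P|L|U|C|E|S` with 0/1 flags for is_ptc, last-exon,
#' penultimate, css-proximal, exon-407 and single-exon; multiple
#' transcripts are comma-separated. For originally multiallelic records
#' the transcript field carries an `#k` allele-index suffix. Records
#' without annotation pass through unmodified.
#'
#' @param vcf_path The input VCF the variants were read from.
#' @param annotations Annotation tibble from [annotate_variants()]; rows
#'   with `is_ptc == FALSE` are not written.
#' @param out_path Output VCF path (plain text).
#' @return `out_path`, invisibly.
#' @export
write_annotated_vcf <- function(vcf_path, annotations, out_path) {
  con <- if (grepl("\\.gz$", vcf_path)) gzfile(vcf_path, "rt")
         else file(vcf_path, "rt")
  lines <- readLines(con)
  close(con)

  ann <- annotations[annotations$is_ptc, , drop = FALSE]
  entry_map <- list()
  if (nrow(ann) > 0L) {
    tid <- ifelse(ann$multiallelic,
                  paste0(ann$transcript_id, "#", ann$allele_index),
                  ann$transcript_id)
    entries <- paste(tid,
                     as.integer(ann$is_ptc), as.integer(ann$last_exon),
                     as.integer(ann$penultimate), as.integer(ann$css_proximal),
                     as.integer(ann$exon407), as.integer(ann$single_exon),
                     sep = "|")
    entry_map <- split(entries, ann$source_id)
  }

  hdr <- startsWith(lines, "#")
  chrom_line <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_line) != 1L) abort("malformed VCF: no #CHROM header line")
  out <- c(lines[seq_len(chrom_line - 1L)], AENMD_INFO_HEADER,
           lines[chrom_line])

  body <- lines[!hdr]
  body <- body[nzchar(body)]
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    body <- vapply(f, function(x) {
      id <- x[3]
      key <- if (!is.na(id) && nzchar(id) && id != ".") id
             else paste(x[1], x[2], toupper(x[4]), x[5], sep = ":")
      e <- entry_map[[key]]
      if (!is.null(e)) {
        tag <- paste0("AENMD=", paste(e, collapse = ","))
        x[8] <- if (is.na(x[8]) || x[8] == "." || !nzchar(x[8])) tag
                else paste0(x[8], ";", tag)
      }
      paste(x, collapse = "\t")
    }, character(1))
  }
  writeLines(c(out, body), out_path)
  invisible(out_path)
}

# parse AENMD INFO entries of a VCF back into a tibble (round-trip checks
# and downstream tabular use)
#' Read AENMD annotations back from a VCF
#'
#' @param vcf_path An annotated VCF written by [write_annotated_vcf()].
#' @return Tibble with `source_id`, `transcript_id`, `allele_index` and the
#'   six 0/1 flags as logicals.
#' @export
read_aenmd_annotations <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    info <- fix$INFO[i]
    if (is.na(info) || !grepl("AENMD=", info, fixed = TRUE)) next
    val <- sub("^.*AENMD=([^;]*).*$", "\\1", info)
    id <- fix$ID[i]
    key <- if (!is.na(id) && nzchar(id) && id != ".") id
           else paste(fix$CHROM[i], fix$POS[i], toupper(fix$REF[i]),
                      fix$ALT[i], sep = ":")
    for (e in strsplit(val, ",", fixed = TRUE)[[1]]) {
      p <- strsplit(e, "|", fixed = TRUE)[[1]]
      tid <- p[1]; k <- 1L
      if (grepl("#", tid, fixed = TRUE)) {
        bits <- strsplit(tid, "#", fixed = TRUE)[[1]]
        tid <- bits[1]; k <- as.integer(bits[2])
      }
      rows[[length(rows) + 1L]] <- tibble(
        source_id = key, transcript_id = tid, allele_index = k,
        is_ptc = p[2] == "1", last_exon = p[3] == "1",
        penultimate = p[4] == "1", css_proximal = p[5] == "1",
        exon407 = p[6] == "1", single_exon = p[7] == "1"
      )
    }
  }
  dplyr::bind_rows(rows)
}
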