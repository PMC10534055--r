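#' Classify how a variant's reference span relates to a transcript
#'
#' A variant is analyzable (`"coding"`) when its reference span lies
#' entirely within a single CDS interval. Spans that cross an exon-intron
#' boundary, or that touch the intronic splice-region margin (the
#' `splice_margin` intronic bases flanking each junction; canonical
#' donor/acceptor dinucleotides by default) are `"splice_excluded"` and not
#' analyzed. Everything else (deep intronic, UTR-only, outside the
#' transcript) is `"noncoding"`. Exonic bases adjacent to junctions are not
#' excluded.
#'
#' @param v One-row variants tibble (or list) with `pos` and `ref`.
#' @param tm An `nmde_transcript`.
#' @param splice_margin Intronic margin width in bp (default 2).
#' @return `"coding"`, `"splice_excluded"` or `"noncoding"`.
#' @export
check_overlap <- function(v, tm, splice_margin = 2L) {
  s <- v$pos
  e <- v$pos + nchar(v$ref) - 1L
  ex <- tm$exons
  in_cds_one <- any(tm$cds$start <= s & tm$cds$end >= e)

  # does the span overlap an exon partially (boundary crossing)?
  ov <- pmax(ex$start, s) <= pmin(ex$end, e)
  crosses <- any(ov & (s < ex$start | e > ex$end))

  # intronic splice-margin bases: [start - m, start - 1] and
  # [end + 1, end + m] of each exon, clipped to true introns
  hits_margin <- FALSE
  if (splice_margin > 0L && nrow(ex) > 1L) {
    lo <- min(ex$start); hi <- max(ex$end)
    for (i in seq_len(nrow(ex))) {
      a1 <- ex$start[i] - splice_margin; b1 <- ex$start[i] - 1L
      a2 <- ex$end[i] + 1L; b2 <- ex$end[i] + splice_margin
      if (ex$start[i] > lo && s <= b1 && e >= a1) hits_margin <- TRUE
      if (ex$end[i] < hi && s <= b2 && e >= a2) hits_margin <- TRUE
    }
  }

  if (crosses || hits_margin) return("splice_excluded")
  if (in_cds_one) return("coding")
  "noncoding"
}

#' Reconstruct the mutant coding(+3'UTR) sequence for a variant
#'
#' Splices the reference CDS plus 3'UTR in transcript orientation and
#' substitutes the variant's alternate allele at the spliced-CDS position
#' of its transcript-5'-most affected base. On the minus strand the
#' genomic alleles are reverse-complemented first. The mutant sequence
#' extends through the annotated transcript 3' end so that frameshift PTCs
#' arising downstream of the canonical stop can be located.
#'
#' @param tm An `nmde_transcript`.
#' @param g An `nmde_genome`.
#' @param v One-row variants tibble (or list) with `pos`, `ref`, `alt`.
#' @param ts Optional `nmde_transcript_set` used to memoise the reference
#'   spliced sequence.
#' @return An `nmde_altcds` object with fields `alt_seq`, `var_cds_pos`,
#'   `alt_len`, `ref_len`, `delta`, `canonical_stop_cds_pos`, `cds_len`,
#'   and the transcript model `tm`.
#' @export
build_alt_cds <- function(tm, g, v, ts = NULL) {
  ref_len <- nchar(v$ref)
  anchor_g <- if (tm$strand == "+") v$pos else v$pos + ref_len - 1L
  var_cds_pos <- coordinate_map(tm, anchor_g, "g2c")
  if (is.na(var_cds_pos)) {
    abort("variant anchor is not inside a CDS interval; run check_overlap first")
  }
  ref_t <- if (tm$strand == "+") v$ref else revcomp(v$ref)
  alt_t <- if (tm$strand == "+") v$alt else revcomp(v$alt)

  ext <- if (!is.null(ts)) ext_sequence(ts, tm, g) else cds_utr3_sequence(tm, g)
  span <- substr(ext, var_cds_pos, var_cds_pos + ref_len - 1L)
  if (span != ref_t) {
    abort(sprintf("variant REF (%s) inconsistent with transcript sequence (%s) at CDS pos %d of %s",
                  ref_t, span, var_cds_pos, tm$transcript_id))
  }
  alt_seq <- paste0(substr(ext, 1L, var_cds_pos - 1L), alt_t,
                    substr(ext, var_cds_pos + ref_len, nchar(ext)))
  structure(list(
    alt_seq = alt_seq,
    var_cds_pos = var_cds_pos,
    ref_len = ref_len,
    alt_len = nchar(alt_t),
    delta = nchar(alt_t) - ref_len,
    canonical_stop_cds_pos = tm$cds_len - 2L,
    cds_len = tm$cds_len,
    tm = tm
  ), class = "nmde_altcds")
}

#' Map a mutant-CDS position back to reference-CDS coordinates
#'
#' Positions upstream of the variant map by identity; positions inside the
#' inserted/replaced span clamp to the variant anchor; positions downstream
#' shift by the length difference. Returned coordinates live in the
#' extended reference frame (values beyond the CDS length are spliced
#' 3'UTR positions).
#'
#' @param a An `nmde_altcds`.
#' @param alt_pos Position in `a$alt_seq` (1-based).
#' @return Reference-CDS (extended) coordinate.
#' @export
map_alt_to_ref <- function(a, alt_pos) {
  if (any(alt_pos < 1L | alt_pos > nchar(a$alt_seq))) {
    abort("alt_pos outside mutant sequence")
  }
  ifelse(alt_pos < a$var_cds_pos, alt_pos,
         ifelse(alt_pos <= a$var_cds_pos + a$alt_len - 1L, a$var_cds_pos,
                alt_pos - a$delta))
}

#' Locate the 5'-most novel premature termination codon
#'
#' Scans the mutant sequence codon by codon from position 1 and returns the
#' first stop codon, unless that stop is the canonical termination event
#' (it occupies the canonical stop's position after adjusting for the
#' variant's length change), in which case termination is not premature and
#' `NULL` is returned. `NULL` is also returned when no stop occurs before
#' the annotated transcript 3' end.
#'
#' @param a An `nmde_altcds` from [build_alt_cds()].
#' @return `NULL`, or an `nmde_ptc` list: `alt_first_nt`, `alt_last_nt`,
#'   `ref_first_nt`, `ref_last_nt`, `exon_ordinal`, `exon_width`, `in_cds`.
#' @export
find_ptc <- function(a) {
  n <- nchar(a$alt_seq)
  if (n < 3L) abort("mutant sequence shorter than one codon")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(a$alt_seq, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0L) return(NULL)
  f <- starts[hit[1]]
  r <- map_alt_to_ref(a, f)
  # canonical termination: stop sits where the canonical stop sits, frame
  # preserved under the variant's length change
  if (f == a$canonical_stop_cds_pos + a$delta && r <= a$canonical_stop_cds_pos) {
    return(NULL)
  }
  ex <- exon_of_ext_pos(a$tm, r)
  structure(list(
    alt_first_nt = f,
    alt_last_nt = f + 2L,
    ref_first_nt = r,
    ref_mid_nt = map_alt_to_ref(a, f + 1L),
    ref_last_nt = map_alt_to_ref(a, f + 2L),
    exon_ordinal = ex$exon_ordinal,
    exon_width = ex$exon_genomic_width,
    in_cds = r <= a$cds_len
  ), class = "nmde_ptc")
}
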