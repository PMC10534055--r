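#' Independent brute-force NMD-escape annotation
#'
#' A deliberately literal re-derivation used to validate the main
#' pipeline, sharing no code with [build_alt_cds()], [find_ptc()] or the
#' rule functions: the variant is applied to the genome sequence itself,
#' the annotation intervals downstream of the edit are shifted, the whole
#' mutant spliced transcript is rebuilt from a per-base genomic position
#' walk, translated codon by codon through the standard genetic code, and
#' the rule definitions are applied directly on per-base exon-membership
#' vectors.
#'
#' @param v One-row variants tibble (or list): `contig`, `pos`, `ref`,
#'   `alt` (normalized).
#' @param tm An `nmde_transcript`.
#' @param g An `nmde_genome`.
#' @param params A [rule_params()] object.
#' @return A list with `status` (`"coding"`, `"splice_excluded"`,
#'   `"noncoding"`), `flags` (one-row tibble as from [apply_rules()]; all
#'   `FALSE` when not coding or no PTC) and `ptc`
#'   (`list(alt_pos, ref_pos)` or `NULL`).
#' @export
oracle_annotate <- function(v, tm, g, params = rule_params()) {
  span_s <- v$pos
  span_e <- v$pos + nchar(v$ref) - 1L
  status <- oracle_status(tm, span_s, span_e, params$splice_margin)
  noflags <- tibble(is_ptc = FALSE, last_exon = FALSE, penultimate = FALSE,
                    css_proximal = FALSE, exon407 = FALSE,
                    single_exon = FALSE, escape_any = FALSE)
  if (status != "coding") {
    return(list(status = status, flags = noflags, ptc = NULL))
  }

  contig <- g[[v$contig]]
  if (substr(contig, span_s, span_e) != v$ref) {
    abort("oracle: REF does not match the genome")
  }
  delta_g <- nchar(v$alt) - nchar(v$ref)
  mut_contig <- paste0(substr(contig, 1L, span_s - 1L), v$alt,
                       substr(contig, span_e + 1L, nchar(contig)))

  # shift annotation intervals right of the edit
  shift_iv <- function(df) {
    out <- df
    for (i in seq_len(nrow(df))) {
      if (df$start[i] > span_e) out$start[i] <- df$start[i] + delta_g
      if (df$end[i] >= span_e) out$end[i] <- df$end[i] + delta_g
    }
    out
  }
  ex_g <- tm$exons[order(tm$exons$start), , drop = FALSE]
  mut_ex <- shift_iv(ex_g)

  # per-base walk: mutant spliced transcript in transcript orientation
  chars <- strsplit(mut_contig, "")[[1]]
  gpos <- unlist(lapply(seq_len(nrow(mut_ex)), function(i)
    seq(mut_ex$start[i], mut_ex$end[i])))
  bases <- chars[gpos]
  if (tm$strand == "-") bases <- unname(COMP[rev(bases)])
  widths_g <- ex_g$end - ex_g$start + 1L           # annotated (reference) widths
  widths_tx <- if (tm$strand == "-") rev(widths_g) else widths_g

  # 5'UTR length is untouched by a CDS-internal edit
  css_tx <- tm$css_tx
  ext <- paste(bases[css_tx:length(bases)], collapse = "")

  n <- nchar(ext)
  starts <- seq.int(1L, n - (n %% 3L) - 2L, by = 3L)
  codons <- substring(ext, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  hit <- which(aa == "*")
  if (length(hit) == 0L) {
    return(list(status = status, flags = noflags, ptc = NULL))
  }
  f <- starts[hit[1]]

  # explicit gapped-alignment bookkeeping: mutant ext pos -> reference ext pos
  ref_len <- nchar(v$ref); alt_len <- nchar(v$alt)
  anchor_g <- if (tm$strand == "+") span_s else span_e
  ref_gpos <- unlist(lapply(seq_len(nrow(ex_g)), function(i)
    seq(ex_g$start[i], ex_g$end[i])))
  if (tm$strand == "-") ref_gpos <- rev(ref_gpos)
  v_tx <- match(anchor_g, ref_gpos)
  v_ext <- v_tx - css_tx + 1L
  ref_ext_len <- length(ref_gpos) - css_tx + 1L
  align <- c(seq_len(v_ext - 1L), rep(v_ext, alt_len),
             if (v_ext + ref_len <= ref_ext_len)
               seq(v_ext + ref_len, ref_ext_len))
  r3 <- align[c(f, f + 1L, f + 2L)]
  r <- r3[1]

  cds_len <- tm$cds_len
  delta_c <- alt_len - ref_len
  if (f == cds_len - 2L + delta_c && r <= cds_len - 2L) {
    # termination at the canonical stop position: not premature
    return(list(status = status, flags = noflags, ptc = NULL))
  }

  # rule evaluation on per-base exon-membership vectors (tx orientation)
  exon_ord_ref <- if (tm$strand == "-") {
    rev((nrow(ex_g) + 1L) - rep(seq_len(nrow(ex_g)), widths_g))
  } else {
    rep(seq_len(nrow(ex_g)), widths_g)
  }
  # ordinal of the exon holding a reference ext position (clipped to 3' end)
  exon_of_ref_ext <- function(rp) {
    exon_ord_ref[min(css_tx + rp - 1L, length(exon_ord_ref))]
  }
  cds_ords <- exon_ord_ref[css_tx:(css_tx + cds_len - 1L)]
  last_coding_exon <- cds_ords[cds_len]
  exord <- exon_of_ref_ext(r)

  # first CDS base of the exon holding the canonical stop
  last_flag <- r >= min(which(cds_ords == last_coding_exon))
  pen_flag <- FALSE
  if (tm$n_exons >= 2L) {
    uniq <- unique(cds_ords)
    if (length(uniq) >= 2L) {
      pen_ex <- uniq[length(uniq) - 1L]
      B <- max(which(cds_ords == pen_ex))
      qs <- r3[r3 <= B]
      if (length(qs)) pen_flag <- (B - max(qs)) <= params$d_pen
    }
  }
  css_flag <- f <= params$d_css
  w407_flag <- widths_tx[exord] > params$exon_size_min
  single_flag <- tm$n_exons == 1L

  flags <- c(last_exon = last_flag, penultimate = pen_flag,
             css_proximal = css_flag, exon407 = w407_flag,
             single_exon = single_flag)
  out <- tibble(is_ptc = TRUE,
                last_exon = last_flag, penultimate = pen_flag,
                css_proximal = css_flag, exon407 = w407_flag,
                single_exon = single_flag,
                escape_any = any(flags[params$rules]))
  list(status = status, flags = out, ptc = list(alt_pos = f, ref_pos = r))
}

# overlap classification by literal per-base reasoning
oracle_status <- function(tm, span_s, span_e, margin) {
  ex <- tm$exons[order(tm$exons$start), , drop = FALSE]
  cds <- tm$cds[order(tm$cds$start), , drop = FALSE]
  bases <- seq(span_s, span_e)
  in_one_cds <- any(cds$start <= span_s & cds$end >= span_e)
  partial <- FALSE
  for (i in seq_len(nrow(ex))) {
    ov <- sum(bases >= ex$start[i] & bases <= ex$end[i])
    if (ov > 0L && ov < length(bases)) partial <- TRUE
    if (ov == length(bases) && (span_s < ex$start[i] || span_e > ex$end[i]))
      partial <- TRUE
  }
  in_margin <- FALSE
  if (nrow(ex) > 1L && margin > 0L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      don <- seq(ex$end[i] + 1L, min(ex$end[i] + margin, ex$start[i + 1L] - 1L))
      acc <- seq(max(ex$start[i + 1L] - margin, ex$end[i] + 1L),
                 ex$start[i + 1L] - 1L)
      if (any(bases %in% c(don, acc))) in_margin <- TRUE
    }
  }
  if (partial || in_margin) return("splice_excluded")
  if (in_one_cds) return("coding")
  "noncoding"
}
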