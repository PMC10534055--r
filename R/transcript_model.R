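#' @title Transcript models and coordinate arithmetic
#' @description Internal representation: a transcript model stores exon and
#'   CDS intervals (1-based, closed, genomic) ordered 5'->3' in transcript
#'   orientation, plus precomputed spliced-coordinate bookkeeping. All rule
#'   distances are evaluated in spliced-CDS coordinates, where position 1 is
#'   the first base of the start codon.
#' @name transcript_model
NULL

# Constructor. exons/cds are data.frames with start/end columns in
# genomic coordinates, ordered 5'->3' in transcript orientation
# (descending genomic coordinate on the minus strand).
new_transcript_model <- function(transcript_id, gene_id, contig, strand,
                                 exons, cds, tsl = NA_integer_,
                                 biotype = NA_character_) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L, nrow(cds) >= 1L)
  ord <- if (strand == "+") order(exons$start) else order(-exons$start)
  exons <- exons[ord, , drop = FALSE]
  ordc <- if (strand == "+") order(cds$start) else order(-cds$start)
  cds <- cds[ordc, , drop = FALSE]
  exon_w <- exons$end - exons$start + 1L
  cds_w <- cds$end - cds$start + 1L
  exon_cum <- cumsum(exon_w)
  tm <- structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    contig = contig,
    strand = strand,
    exons = exons,
    cds = cds,
    tsl = tsl,
    biotype = biotype,
    exon_widths = exon_w,
    exon_cum = exon_cum,
    tx_len = exon_cum[length(exon_cum)],
    cds_len = sum(cds_w),
    n_exons = nrow(exons)
  ), class = "nmde_transcript")
  tm$css_tx <- g2t(tm, if (strand == "+") cds$start[1] else cds$end[1])
  tm
}

#' @export
print.nmde_transcript <- function(x, ...) {
  cat(sprintf("<nmde_transcript> %s (%s) %s:%d-%d [%s] %d exon(s), CDS %d bp\n",
              x$transcript_id, x$gene_id %||% NA, x$contig,
              min(x$exons$start), max(x$exons$end), x$strand,
              x$n_exons, x$cds_len))
  invisible(x)
}

# genomic position -> 1-based spliced transcript position (NA if intronic
# or outside the transcript)
g2t <- function(tm, gpos) {
  hit <- which(tm$exons$start <= gpos & tm$exons$end >= gpos)
  if (length(hit) == 0L) return(NA_integer_)
  i <- hit[1]
  off <- if (tm$strand == "+") gpos - tm$exons$start[i] + 1L
         else tm$exons$end[i] - gpos + 1L
  base <- if (i == 1L) 0L else tm$exon_cum[i - 1L]
  base + off
}

# spliced transcript position -> genomic position
t2g <- function(tm, tpos) {
  if (tpos < 1L || tpos > tm$tx_len) {
    abort(sprintf("transcript position %d outside [1,%d]", tpos, tm$tx_len))
  }
  i <- findInterval(tpos - 1L, c(0L, tm$exon_cum), rightmost.closed = FALSE)
  off <- tpos - (if (i == 1L) 0L else tm$exon_cum[i - 1L])
  if (tm$strand == "+") tm$exons$start[i] + off - 1L
  else tm$exons$end[i] - off + 1L
}

# exon ordinal (1-based in transcript orientation, counting pure-UTR exons)
# containing a spliced transcript position
exon_of_tx_pos <- function(tm, tpos) {
  findInterval(tpos - 1L, c(0L, tm$exon_cum), rightmost.closed = FALSE)
}

#' Map between genomic and spliced-CDS coordinates
#'
#' Spliced-CDS coordinates are 1-based with position 1 at the first base of
#' the start codon; the map covers exactly the genomic positions inside the
#' transcript's CDS intervals and is a bijection onto `[1, CDS length]`.
#'
#' @param tm An `nmde_transcript`.
#' @param pos A single coordinate: genomic for `direction = "g2c"`,
#'   spliced-CDS for `direction = "c2g"`.
#' @param direction `"g2c"` or `"c2g"`.
#' @return For `"g2c"`, the 1-based spliced-CDS position or `NA` when `pos`
#'   is not inside a CDS interval. For `"c2g"`, the genomic position
#'   (errors when outside `[1, CDS length]`).
#' @export
coordinate_map <- function(tm, pos, direction = c("g2c", "c2g")) {
  direction <- match.arg(direction)
  if (direction == "g2c") {
    in_cds <- any(tm$cds$start <= pos & tm$cds$end >= pos)
    if (!in_cds) return(NA_integer_)
    g2t(tm, pos) - tm$css_tx + 1L
  } else {
    if (pos < 1L || pos > tm$cds_len) {
      abort(sprintf("CDS position %d outside [1,%d]", pos, tm$cds_len))
    }
    t2g(tm, pos + tm$css_tx - 1L)
  }
}

#' Exon containing a spliced-CDS position
#'
#' @param tm An `nmde_transcript`.
#' @param cds_pos 1-based spliced-CDS position.
#' @return A list with `exon_ordinal` (1-based in transcript orientation,
#'   counting pure-UTR exons) and `exon_genomic_width` (full annotated exon
#'   width in bp, UTR included).
#' @export
exon_of_cds_pos <- function(tm, cds_pos) {
  if (cds_pos < 1L || cds_pos > tm$cds_len) {
    abort(sprintf("CDS position %d outside [1,%d]", cds_pos, tm$cds_len))
  }
  i <- exon_of_tx_pos(tm, cds_pos + tm$css_tx - 1L)
  list(exon_ordinal = i, exon_genomic_width = tm$exon_widths[i])
}

# exon lookup for positions in the extended (CDS + 3'UTR) frame; positions
# beyond the CDS live in 3'UTR sequence (frameshift read-through)
exon_of_ext_pos <- function(tm, ext_pos) {
  tpos <- ext_pos + tm$css_tx - 1L
  if (tpos > tm$tx_len) tpos <- tm$tx_len
  i <- exon_of_tx_pos(tm, tpos)
  list(exon_ordinal = i, exon_genomic_width = tm$exon_widths[i])
}

# full spliced transcript sequence, transcript orientation
tx_sequence <- function(tm, g) {
  if (!tm$contig %in% names(g)) {
    abort(paste0("contig not in genome: ", tm$contig))
  }
  parts <- character(nrow(tm$exons))
  for (i in seq_len(nrow(tm$exons))) {
    s <- genome_seq(g, tm$contig, tm$exons$start[i], tm$exons$end[i])
    parts[i] <- if (tm$strand == "+") s else revcomp(s)
  }
  paste(parts, collapse = "")
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the CDS intervals in transcript orientation
#' (reverse-complementing on the minus strand). Includes the terminal stop
#' codon; length is a multiple of three for transcripts passing the default
#' filters.
#'
#' @param tm An `nmde_transcript`.
#' @param g An `nmde_genome`.
#' @return Nucleotide string.
#' @export
coding_sequence <- function(tm, g) {
  substr(tx_sequence(tm, g), tm$css_tx, tm$css_tx + tm$cds_len - 1L)
}

# CDS plus spliced 3'UTR: the scan space for PTC detection (frameshift
# PTCs can fall downstream of the canonical stop)
cds_utr3_sequence <- function(tm, g) {
  substr(tx_sequence(tm, g), tm$css_tx, tm$tx_len)
}

# ---------------------------------------------------------------------------
# TranscriptSet

new_transcript_set <- function(transcripts, counts = list()) {
  ts <- structure(list(
    transcripts = transcripts,
    counts = counts,
    cache = new.env(parent = emptyenv())
  ), class = "nmde_transcript_set")
  ts$cds_spans <- transcript_cds_spans(transcripts)
  ts
}

transcript_cds_spans <- function(transcripts) {
  if (length(transcripts) == 0L) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(transcripts, `[[`, character(1), "contig"),
    ranges = IRanges::IRanges(
      start = vapply(transcripts, function(t) as.integer(min(t$cds$start)),
                     integer(1)),
      end = vapply(transcripts, function(t) as.integer(max(t$cds$end)),
                   integer(1))
    )
  )
  S4Vectors::mcols(gr)$transcript_id <-
    vapply(transcripts, `[[`, character(1), "transcript_id")
  gr
}

#' @export
print.nmde_transcript_set <- function(x, ...) {
  cat("<nmde_transcript_set> ", length(x$transcripts), " transcript(s)\n",
      sep = "")
  if (length(x$counts)) {
    cat("  removal counts:",
        paste(names(x$counts), unlist(x$counts), sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
length.nmde_transcript_set <- function(x) length(x$transcripts)

get_transcript <- function(ts, id) ts$transcripts[[id]]

# transcript ids whose CDS span overlaps [start, end] on contig
overlapping_transcripts <- function(ts, contig, start, end) {
  if (length(ts$transcripts) == 0L) return(character(0))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, ts$cds_spans))
  S4Vectors::mcols(ts$cds_spans)$transcript_id[S4Vectors::subjectHits(hits)]
}

# memoised CDS+3'UTR sequence per transcript
ext_sequence <- function(ts, tm, g) {
  key <- tm$transcript_id
  if (!is.null(ts$cache[[key]])) return(ts$cache[[key]])
  s <- cds_utr3_sequence(tm, g)
  assign(key, s, envir = ts$cache)
  s
}

# ---------------------------------------------------------------------------
# Annotation loading

#' Load transcript models from GTF/GFF3
#'
#' Reads exon, CDS and (GTF dialect) stop_codon features, groups them per
#' transcript, and orients them 5'->3' in transcript orientation. Separate
#' `stop_codon` records (the GENCODE convention, where the CDS excludes the
#' terminal codon) are merged into the CDS so rules see the coding sequence
#' including its stop. Transcripts whose CDS is inconsistent with their exon
#' structure are skipped with a warning and counted.
#'
#' @param annotation_path Path to a GTF or GFF3 file (optionally gzipped).
#' @param dialect `"auto"` (by file extension), `"gtf"` or `"gff3"`.
#' @return An `nmde_transcript_set`.
#' @export
load_transcript_models <- function(annotation_path,
                                   dialect = c("auto", "gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(annotation_path)) {
    abort(paste0("annotation file not found: ", annotation_path))
  }
  if (dialect == "auto") {
    p <- sub("\\.gz$", "", annotation_path)
    dialect <- if (grepl("\\.(gff3?|gff)$", p, ignore.case = TRUE)) "gff3"
               else "gtf"
  }
  gr <- rtracklayer::import(annotation_path, format = dialect)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  tx_id <- extract_transcript_id(mc, dialect)
  keep <- type %in% c("exon", "CDS", "stop_codon") & !is.na(tx_id)
  if (!any(keep)) abort("annotation contains no exon/CDS features")

  feats <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    type = type[keep],
    transcript_id = tx_id[keep]
  )

  meta <- transcript_metadata(gr, mc, dialect)
  build_transcript_set(feats, meta)
}

extract_transcript_id <- function(mc, dialect) {
  if ("transcript_id" %in% names(mc) &&
      !all(is.na(mc$transcript_id))) {
    return(as.character(mc$transcript_id))
  }
  # GFF3 fallback: derive from Parent ("transcript:ENST..." or bare id)
  if ("Parent" %in% names(mc)) {
    par <- vapply(as.list(mc$Parent), function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p[[1]])
    }, character(1))
    return(sub("^transcript:", "", par))
  }
  rep(NA_character_, nrow(mc))
}

# gather per-transcript gene id / biotype / TSL from transcript-level rows
transcript_metadata <- function(gr, mc, dialect) {
  type <- as.character(mc$type)
  is_tx <- type %in% c("transcript", "mRNA")
  tx_id <- extract_transcript_id(mc, dialect)
  if ("ID" %in% names(mc)) {
    idcol <- sub("^transcript:", "", as.character(mc$ID))
    tx_id[is_tx & !is.na(idcol)] <- idcol[is_tx & !is.na(idcol)]
  }
  ids <- tx_id[is_tx]
  pick <- function(cols) {
    for (cl in cols) if (cl %in% names(mc)) {
      v <- as.character(mc[[cl]])[is_tx]
      if (!all(is.na(v))) return(v)
    }
    rep(NA_character_, sum(is_tx))
  }
  gene <- pick(c("gene_id", "gene"))
  biotype <- pick(c("transcript_biotype", "transcript_type", "biotype"))
  tsl_raw <- pick(c("transcript_support_level", "tsl"))
  tsl <- suppressWarnings(as.integer(sub("^\\s*(\\d+).*$", "\\1", tsl_raw)))
  ok <- !is.na(ids) & !duplicated(ids)
  list(ids = ids[ok], gene = gene[ok], biotype = biotype[ok], tsl = tsl[ok])
}

build_transcript_set <- function(feats, meta) {
  skipped <- 0L
  metapos <- match(unique(feats$transcript_id), meta$ids)
  split_feats <- split(feats, feats$transcript_id)
  transcripts <- list()
  for (id in names(split_feats)) {
    f <- split_feats[[id]]
    ex <- f[f$type == "exon", , drop = FALSE]
    cd <- f[f$type %in% c("CDS", "stop_codon"), , drop = FALSE]
    if (nrow(cd) == 0L) next            # non-coding transcript: ignore
    if (nrow(ex) == 0L) {
      warn(paste0("transcript ", id, " has CDS but no exons; skipped"))
      skipped <- skipped + 1L
      next
    }
    strand <- ex$strand[1]
    # merge CDS + stop_codon intervals; book-ended pieces fuse
    ir <- IRanges::reduce(IRanges::IRanges(cd$start, cd$end))
    cds_df <- data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
    exon_df <- data.frame(start = ex$start, end = ex$end)
    inside <- vapply(seq_len(nrow(cds_df)), function(i) {
      any(exon_df$start <= cds_df$start[i] & exon_df$end >= cds_df$end[i])
    }, logical(1))
    if (!all(inside)) {
      warn(paste0("transcript ", id,
                  " has CDS outside its exons; skipped"))
      skipped <- skipped + 1L
      next
    }
    mi <- match(id, meta$ids)
    tm <- new_transcript_model(
      transcript_id = id,
      gene_id = if (!is.na(mi)) meta$gene[mi] else NA_character_,
      contig = f$contig[1],
      strand = strand,
      exons = exon_df,
      cds = cds_df,
      tsl = if (!is.na(mi)) meta$tsl[mi] else NA_integer_,
      biotype = if (!is.na(mi)) meta$biotype[mi] else NA_character_
    )
    if (!cds_contiguous(tm)) {
      warn(paste0("transcript ", id,
                  " has a CDS that is not contiguous in spliced",
                  " coordinates; skipped"))
      skipped <- skipped + 1L
      next
    }
    transcripts[[id]] <- tm
  }
  new_transcript_set(transcripts, counts = list(skipped_malformed = skipped))
}

# the CDS must occupy one contiguous block of the spliced transcript
cds_contiguous <- function(tm) {
  tpos <- integer(0)
  for (i in seq_len(nrow(tm$cds))) {
    a <- g2t(tm, tm$cds$start[i]); b <- g2t(tm, tm$cds$end[i])
    if (is.na(a) || is.na(b)) return(FALSE)
    tpos <- c(tpos, seq(min(a, b), max(a, b)))
  }
  tpos <- sort(tpos)
  length(tpos) == tm$cds_len && all(diff(tpos) == 1L)
}

# ---------------------------------------------------------------------------
# Filtering

#' Transcript filter criteria
#'
#' Defaults reproduce the stringent high-confidence transcript set:
#' protein-coding transcripts on standard chromosomes with transcript
#' support level 1 (or missing TSL for single-exon transcripts) and a
#' coding-sequence length divisible by three. Transcripts whose reference
#' CDS contains an internal in-frame stop codon (e.g. annotated
#' readthrough) are also removed by default, since the 5'-most novel PTC is
#' undefined for them.
#'
#' @param require_biotype Character set of accepted biotypes; transcripts
#'   with a missing biotype but a CDS pass. `NULL` disables.
#' @param max_tsl Maximum transcript support level; `NULL` disables.
#' @param allow_missing_tsl_single_exon Keep single-exon transcripts with
#'   missing TSL.
#' @param require_cds_mod3 Require CDS length divisible by three.
#' @param require_clean_orf Require no internal in-frame stop codon in the
#'   reference CDS (needs `genome` at filter time).
#' @param contig_allowlist `"standard"` (chr1-22, X, Y, M and their
#'   non-"chr" aliases), `"all"`, or a character vector of contig names.
#' @return A `nmde_filter_criteria` list.
#' @export
filter_criteria <- function(require_biotype = "protein_coding",
                            max_tsl = 1L,
                            allow_missing_tsl_single_exon = TRUE,
                            require_cds_mod3 = TRUE,
                            require_clean_orf = TRUE,
                            contig_allowlist = "standard") {
  structure(list(
    require_biotype = require_biotype,
    max_tsl = max_tsl,
    allow_missing_tsl_single_exon = allow_missing_tsl_single_exon,
    require_cds_mod3 = require_cds_mod3,
    require_clean_orf = require_clean_orf,
    contig_allowlist = contig_allowlist
  ), class = "nmde_filter_criteria")
}

#' Filter a transcript set
#'
#' Applies the criteria of [filter_criteria()]; surviving transcripts
#' satisfy every enabled criterion. Removal counts per criterion are stored
#' in the returned set's `counts` field. The operation is idempotent.
#'
#' @param ts An `nmde_transcript_set`.
#' @param crit A [filter_criteria()] object.
#' @param genome Optional `nmde_genome`; required when
#'   `crit$require_clean_orf` is `TRUE`.
#' @return A filtered `nmde_transcript_set`.
#' @export
filter_transcript_set <- function(ts, crit = filter_criteria(),
                                  genome = NULL) {
  counts <- list(biotype = 0L, tsl = 0L, cds_mod3 = 0L, contig = 0L,
                 internal_stop = 0L)
  allow <- crit$contig_allowlist
  if (identical(allow, "standard")) allow <- standard_contigs()
  keep <- list()
  for (tm in ts$transcripts) {
    ok <- TRUE
    if (!is.null(crit$require_biotype) && !is.na(tm$biotype) &&
        !tm$biotype %in% crit$require_biotype) {
      counts$biotype <- counts$biotype + 1L; ok <- FALSE
    }
    if (ok && !is.null(crit$max_tsl)) {
      tsl_ok <- !is.na(tm$tsl) && tm$tsl <= crit$max_tsl
      if (!tsl_ok && is.na(tm$tsl) && crit$allow_missing_tsl_single_exon &&
          tm$n_exons == 1L) {
        tsl_ok <- TRUE
      }
      if (!tsl_ok) { counts$tsl <- counts$tsl + 1L; ok <- FALSE }
    }
    if (ok && crit$require_cds_mod3 && tm$cds_len %% 3L != 0L) {
      counts$cds_mod3 <- counts$cds_mod3 + 1L; ok <- FALSE
    }
    if (ok && !identical(allow, "all") &&
        !tm$contig %in% allow &&
        !normalize_contig(tm$contig) %in% normalize_contig(allow)) {
      counts$contig <- counts$contig + 1L; ok <- FALSE
    }
    if (ok && crit$require_clean_orf && !is.null(genome) &&
        tm$contig %in% names(genome)) {
      cds <- coding_sequence(tm, genome)
      n <- nchar(cds)
      if (n >= 6L) {
        starts <- seq.int(1L, n - 5L, by = 3L)  # internal codons only
        cod <- substring(cds, starts, starts + 2L)
        if (any(cod %in% STOP_CODONS)) {
          counts$internal_stop <- counts$internal_stop + 1L; ok <- FALSE
        }
      }
    }
    if (ok) keep[[tm$transcript_id]] <- tm
  }
  new_transcript_set(keep, counts = counts)
}
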