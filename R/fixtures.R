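#' @title Synthetic genome / annotation / variant fixtures
#' @description Deterministic generators for multi-exon protein-coding
#'   transcripts with valid CDS structure (length divisible by three, ATG
#'   start, single terminal stop, no internal in-frame stop), on both
#'   strands, written as standard FASTA and GENCODE-dialect GTF, plus
#'   variant placement with known rule-triggering structure.
#' @name fixtures
NULL

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                  c("A","C","G","T"), paste0)),
  STOP_CODONS)

#' Specify a synthetic transcript fixture set
#'
#' Either a purely random design (ranges below) or explicit
#' [transcript_layout()] entries via `layouts`; both are deterministic
#' given `seed`.
#'
#' @param n_transcripts Number of random transcripts (ignored when
#'   `layouts` is given).
#' @param exon_count_range Min/max exon count.
#' @param exon_length_range Min/max exon width in bp. The default maximum
#'   stays below 407 so the large-exon rule fires only when asked for via
#'   an explicit layout.
#' @param intron_length_range Min/max intron width in bp.
#' @param utr5_range,utr3_range UTR length ranges in bp (within the
#'   first/last exon).
#' @param strand_neg_frac Fraction of transcripts placed on the minus
#'   strand.
#' @param contig Contig name the transcripts are laid on.
#' @param seed Integer seed; all randomness derives from it.
#' @param layouts Optional list of [transcript_layout()] objects.
#' @return A `nmde_fixture_spec` list.
#' @export
fixture_spec <- function(n_transcripts = 6L,
                         exon_count_range = c(1L, 6L),
                         exon_length_range = c(120L, 400L),
                         intron_length_range = c(60L, 200L),
                         utr5_range = c(12L, 90L),
                         utr3_range = c(40L, 110L),
                         strand_neg_frac = 0.5,
                         contig = "chr1",
                         seed = 42L,
                         layouts = NULL) {
  structure(list(n_transcripts = n_transcripts,
                 exon_count_range = exon_count_range,
                 exon_length_range = exon_length_range,
                 intron_length_range = intron_length_range,
                 utr5_range = utr5_range, utr3_range = utr3_range,
                 strand_neg_frac = strand_neg_frac,
                 contig = contig, seed = as.integer(seed),
                 layouts = layouts),
            class = "nmde_fixture_spec")
}

#' Explicit transcript layout for engineered fixtures
#'
#' @param exon_widths Integer vector of exon widths (transcript
#'   orientation).
#' @param intron_widths Integer vector of intron widths
#'   (`length(exon_widths) - 1`).
#' @param utr5,utr3 UTR lengths in bp; must fit inside the first/last exon
#'   leaving at least 6 coding bases there.
#' @param strand `"+"` or `"-"`.
#' @param cds_codons Optional explicit codon string for the CDS interior
#'   (recycled); e.g. `"AAA"` gives a poly-lysine CDS in which every codon
#'   is one substitution away from a stop.
#' @param id Optional transcript id.
#' @return A `nmde_transcript_layout` list.
#' @export
transcript_layout <- function(exon_widths, intron_widths = integer(0),
                              utr5 = 20L, utr3 = 50L, strand = "+",
                              cds_codons = NULL, id = NULL) {
  stopifnot(length(intron_widths) == length(exon_widths) - 1L,
            strand %in% c("+", "-"))
  cds_len <- sum(exon_widths) - utr5 - utr3
  if (cds_len < 9L || cds_len %% 3L != 0L) {
    abort(sprintf("layout infeasible: CDS length %d must be >= 9 and divisible by 3",
                  cds_len))
  }
  structure(list(exon_widths = as.integer(exon_widths),
                 intron_widths = as.integer(intron_widths),
                 utr5 = as.integer(utr5), utr3 = as.integer(utr3),
                 strand = strand, cds_codons = cds_codons, id = id),
            class = "nmde_transcript_layout")
}

random_layout <- function(spec) {
  k <- sample(seq(spec$exon_count_range[1], spec$exon_count_range[2]), 1L)
  ew <- sample(seq(spec$exon_length_range[1], spec$exon_length_range[2]), k,
               replace = TRUE)
  iw <- if (k > 1L)
    sample(seq(spec$intron_length_range[1], spec$intron_length_range[2]),
           k - 1L, replace = TRUE)
  else integer(0)
  utr5 <- sample(seq(spec$utr5_range[1], spec$utr5_range[2]), 1L)
  utr3 <- sample(seq(spec$utr3_range[1], spec$utr3_range[2]), 1L)
  utr5 <- min(utr5, ew[1] - 12L)
  utr3 <- min(utr3, ew[k] - 12L)
  if (k == 1L) {
    # both UTRs share the single exon; keep at least 60 coding bases
    while (utr5 + utr3 > ew[1] - 60L && utr3 > 3L) utr3 <- utr3 - 3L
    while (utr5 + utr3 > ew[1] - 60L && utr5 > 3L) utr5 <- utr5 - 3L
  }
  # align CDS length to a codon boundary by nudging the 3'UTR
  rem <- (sum(ew) - utr5 - utr3) %% 3L
  utr3 <- utr3 + rem
  strand <- if (stats::runif(1) < spec$strand_neg_frac) "-" else "+"
  transcript_layout(ew, iw, utr5 = utr5, utr3 = utr3, strand = strand)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# CDS with ATG start, one terminal stop, no internal in-frame stop
make_cds_seq <- function(cds_len, cds_codons = NULL) {
  n_codons <- cds_len %/% 3L
  if (is.null(cds_codons)) {
    body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  } else {
    stopifnot(nchar(cds_codons) %% 3L == 0L)
    pool <- substring(cds_codons, seq(1L, nchar(cds_codons), 3L),
                      seq(3L, nchar(cds_codons), 3L))
    stopifnot(!any(pool %in% STOP_CODONS))
    body <- rep_len(pool, n_codons - 2L)
  }
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate a synthetic genome and annotation
#'
#' Lays the transcripts of a [fixture_spec()] sequentially on one contig
#' (separated by random intergenic gaps), writes a FASTA and a
#' GENCODE-dialect GTF (CDS excludes the stop codon; a separate
#' `stop_codon` feature carries it), and returns the paths plus the ground
#' truth used to build them. Deterministic given the spec's seed, which is
#' recorded in the file headers.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `fasta`, `gtf` (paths) and `truth` (per-transcript
#'   list: id, strand, exon/CDS genomic intervals, CDS sequence, UTR
#'   lengths).
#' @export
synth_genome_and_annotation <- function(spec, dir = tempfile("nmdefix")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    layouts <- spec$layouts %||% lapply(seq_len(spec$n_transcripts),
                                        function(i) random_layout(spec))
    contig_parts <- character(0)
    offset <- 0L
    truth <- list()
    gtf_lines <- character(0)
    for (i in seq_along(layouts)) {
      lay <- layouts[[i]]
      id <- lay$id %||% sprintf("TX%03d", i)
      gene <- sprintf("G%03d", i)
      cds_len <- sum(lay$exon_widths) - lay$utr5 - lay$utr3
      cds_seq <- make_cds_seq(cds_len, lay$cds_codons)
      tx_seq <- paste0(random_dna(lay$utr5), cds_seq, random_dna(lay$utr3))
      # split the spliced sequence into exon chunks (transcript orientation)
      ends <- cumsum(lay$exon_widths)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      chunks <- substring(tx_seq, starts, ends)

      gap <- sample(200:500, 1L)
      region_start <- offset + gap + 1L
      k <- length(chunks)
      if (lay$strand == "+") {
        genomic_chunks <- chunks
      } else {
        genomic_chunks <- rev(revcomp(chunks))
      }
      introns <- vapply(lay$intron_widths, random_dna, character(1))
      if (lay$strand == "-") introns <- rev(introns)
      pieces <- character(0)
      exon_iv <- matrix(0L, nrow = k, ncol = 2L)
      pos <- region_start
      for (j in seq_len(k)) {
        w <- nchar(genomic_chunks[j])
        exon_iv[j, ] <- c(pos, pos + w - 1L)
        pieces <- c(pieces, genomic_chunks[j])
        pos <- pos + w
        if (j < k) {
          pieces <- c(pieces, introns[j])
          pos <- pos + nchar(introns[j])
        }
      }
      region_seq <- paste(pieces, collapse = "")
      contig_parts <- c(contig_parts, random_dna(gap), region_seq)
      offset <- pos - 1L

      # exon intervals in transcript orientation
      exon_df <- as.data.frame(exon_iv)
      names(exon_df) <- c("start", "end")
      if (lay$strand == "-") exon_df <- exon_df[rev(seq_len(k)), , drop = FALSE]

      tm <- tm_from_layout(id, gene, spec$contig, lay, exon_df, cds_len)
      truth[[id]] <- list(id = id, gene = gene, strand = lay$strand,
                          exons = tm$exons, cds = tm$cds,
                          cds_seq = cds_seq, utr5 = lay$utr5,
                          utr3 = lay$utr3, tm = tm)
      gtf_lines <- c(gtf_lines, gtf_lines_for(tm, gene, spec$contig))
    }
    contig_seq <- paste(contig_parts, collapse = "")

    fasta <- file.path(dir, "genome.fa")
    writeLines(c(paste0(">", spec$contig, " synthetic seed=", spec$seed),
                 gsub("(.{70})", "\\1\n", contig_seq, perl = TRUE)),
               fasta)
    gtf <- file.path(dir, "annotation.gtf")
    writeLines(c(paste0("#!synthetic fixture seed=", spec$seed), gtf_lines),
               gtf)
    list(fasta = fasta, gtf = gtf, truth = truth)
  })
}

# transcript model straight from a layout (exon_df in transcript orientation)
tm_from_layout <- function(id, gene, contig, lay, exon_df, cds_len) {
  k <- nrow(exon_df)
  # CDS occupies spliced positions utr5+1 .. utr5+cds_len; carve out of exons
  ends <- cumsum(lay$exon_widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cds_lo <- lay$utr5 + 1L
  cds_hi <- lay$utr5 + cds_len
  cds_rows <- list()
  for (j in seq_len(k)) {
    a <- max(starts[j], cds_lo); b <- min(ends[j], cds_hi)
    if (a > b) next
    # spliced offsets within exon j -> genomic
    if (lay$strand == "+") {
      gs <- exon_df$start[j] + (a - starts[j])
      ge <- exon_df$start[j] + (b - starts[j])
    } else {
      gs <- exon_df$end[j] - (b - starts[j])
      ge <- exon_df$end[j] - (a - starts[j])
    }
    cds_rows[[length(cds_rows) + 1L]] <- data.frame(start = gs, end = ge)
  }
  cds_df <- do.call(rbind, cds_rows)
  new_transcript_model(id, gene, contig, lay$strand,
                       exons = exon_df, cds = cds_df,
                       tsl = if (k == 1L) NA_integer_ else 1L,
                       biotype = "protein_coding")
}

gtf_attr <- function(gene, id, tm, with_tsl) {
  tsl <- if (tm$n_exons == 1L) "NA" else "1"
  paste0('gene_id "', gene, '"; transcript_id "', id,
         '"; transcript_type "protein_coding";',
         if (with_tsl) paste0(' transcript_support_level "', tsl, '";') else "")
}

gtf_lines_for <- function(tm, gene, contig) {
  id <- tm$transcript_id
  fmt <- function(type, s, e, attr) {
    paste(contig, "synth", type, s, e, ".", tm$strand, ".", attr,
          sep = "\t")
  }
  lines <- c(
    fmt("gene", min(tm$exons$start), max(tm$exons$end),
        paste0('gene_id "', gene, '";')),
    fmt("transcript", min(tm$exons$start), max(tm$exons$end),
        gtf_attr(gene, id, tm, TRUE))
  )
  for (j in seq_len(nrow(tm$exons))) {
    lines <- c(lines, fmt("exon", tm$exons$start[j], tm$exons$end[j],
                          gtf_attr(gene, id, tm, FALSE)))
  }
  # GENCODE dialect: CDS excludes the stop codon; stop_codon is separate
  stop_g <- sort(c(coordinate_map(tm, tm$cds_len - 2L, "c2g"),
                   coordinate_map(tm, tm$cds_len, "c2g")))
  for (j in seq_len(nrow(tm$cds))) {
    s <- tm$cds$start[j]; e <- tm$cds$end[j]
    if (s <= stop_g[1] && e >= stop_g[2]) {
      if (tm$strand == "+") e <- stop_g[1] - 1L else s <- stop_g[2] + 1L
    }
    if (s <= e) {
      lines <- c(lines, fmt("CDS", s, e, gtf_attr(gene, id, tm, FALSE)))
    }
  }
  lines <- c(lines, fmt("stop_codon", stop_g[1], stop_g[2],
                        gtf_attr(gene, id, tm, FALSE)))
  lines
}

# ---------------------------------------------------------------------------
# Variant placement

#' Construct a stop-gain SNV at a CDS codon
#'
#' Finds a single-base substitution turning the codon containing `cds_pos`
#' into a stop codon, if one exists, and returns it as a genomic variant.
#'
#' @param tm An `nmde_transcript`.
#' @param g An `nmde_genome`.
#' @param cds_pos Spliced-CDS position inside the target codon.
#' @return One-row variants tibble, or `NULL` when no single edit of that
#'   codon yields a stop.
#' @export
stop_gain_snv_at <- function(tm, g, cds_pos) {
  cc <- (cds_pos - 1L) %/% 3L + 1L
  f <- 3L * (cc - 1L) + 1L
  if (f + 2L > tm$cds_len - 3L) return(NULL)  # keep clear of the stop codon
  cds <- coding_sequence(tm, g)
  codon <- substr(cds, f, f + 2L)
  for (s in sample(STOP_CODONS)) {
    d <- which(strsplit(codon, "")[[1]] != strsplit(s, "")[[1]])
    if (length(d) == 1L) {
      cp <- f + d - 1L
      gpos <- coordinate_map(tm, cp, "c2g")
      refb <- substr(codon, d, d)
      altb <- substr(s, d, d)
      if (tm$strand == "-") { refb <- COMP[[refb]]; altb <- COMP[[altb]] }
      return(tibble(contig = tm$contig, pos = gpos, ref = refb, alt = altb,
                    source_id = paste0(tm$transcript_id, ":stopgain:", f)))
    }
  }
  NULL
}

# genomic deletion of [lo, hi] with a left anchor base
genomic_del <- function(tm, g, lo, hi) {
  tibble(contig = tm$contig, pos = lo - 1L,
         ref = genome_seq(g, tm$contig, lo - 1L, hi),
         alt = genome_seq(g, tm$contig, lo - 1L, lo - 1L),
         source_id = paste0(tm$transcript_id, ":del:", lo))
}

# insertion of transcript-orientation sequence S after spliced-CDS pos a
tx_insertion_after <- function(tm, g, a, S) {
  if (tm$strand == "+") {
    gpos <- coordinate_map(tm, a, "c2g")
    anchor <- genome_seq(g, tm$contig, gpos, gpos)
    tibble(contig = tm$contig, pos = gpos, ref = anchor,
           alt = paste0(anchor, S),
           source_id = paste0(tm$transcript_id, ":ins:", a))
  } else {
    gpos <- coordinate_map(tm, a + 1L, "c2g")   # genomically left neighbour
    anchor <- genome_seq(g, tm$contig, gpos, gpos)
    tibble(contig = tm$contig, pos = gpos, ref = anchor,
           alt = paste0(anchor, revcomp(S)),
           source_id = paste0(tm$transcript_id, ":ins:", a))
  }
}

# expected flag profile per targeted rule
target_profile <- function(rule) {
  base <- c(last_exon = FALSE, penultimate = FALSE, css_proximal = FALSE,
            exon407 = FALSE, single_exon = FALSE)
  switch(rule,
    last_exon = replace(base, "last_exon", TRUE),
    penultimate = replace(base, "penultimate", TRUE),
    css_proximal = replace(base, "css_proximal", TRUE),
    exon407 = replace(base, "exon407", TRUE),
    single_exon = replace(base, c("single_exon", "last_exon"), TRUE),
    abort(paste0("unknown target rule: ", rule)))
}

#' Place variants with known rule-triggering structure
#'
#' For each placement `(transcript_id, target_rule, variant_class)` a
#' variant is constructed whose annotation triggers exactly the requested
#' rule profile, verified at generation time against the independent
#' brute-force oracle ([oracle_annotate()]); placements that cannot be
#' satisfied on the given transcript raise an error. `target_rule` may
#' also be `"none"` (a coding variant creating no PTC), `"splice"`
#' (a splice-excluded decoy) or `"intronic"` (deep intronic, not
#' analyzed).
#'
#' @param ts A filtered `nmde_transcript_set`.
#' @param g An `nmde_genome`.
#' @param placements A data.frame/tibble with columns `transcript_id`,
#'   `target_rule`, `variant_class` (`"snv"`, `"ins"`, `"del"`,
#'   `"delins"`).
#' @param vcf_path Optional path; when given, the variants are written as
#'   a VCF v4.2 file.
#' @param params Rule parameters used for verification.
#' @param seed Seed for the placement search.
#' @param max_tries Rejection-sampling budget per placement.
#' @return Variants tibble with an `expected_rule` column (and `vcf_path`
#'   attribute when written).
#' @export
synth_variants <- function(ts, g, placements, vcf_path = NULL,
                           params = rule_params(), seed = 7L,
                           max_tries = 400L) {
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(placements))) {
      pl <- placements[i, ]
      tm <- get_transcript(ts, pl$transcript_id)
      if (is.null(tm)) abort(paste0("unknown transcript: ", pl$transcript_id))
      v <- place_one(tm, ts, g, pl$target_rule, pl$variant_class, params,
                     max_tries)
      if (is.null(v)) {
        abort(sprintf("infeasible placement: %s / %s on %s",
                      pl$target_rule, pl$variant_class, pl$transcript_id))
      }
      v$expected_rule <- pl$target_rule
      rows[[i]] <- v
    }
    out <- dplyr::bind_rows(rows)
    out$source_id <- make.unique(out$source_id, sep = "_")
    if (!is.null(vcf_path)) {
      write_simple_vcf(out, vcf_path, g)
      attr(out, "vcf_path") <- vcf_path
    }
    out
  })
}

place_one <- function(tm, ts, g, rule, class, params, max_tries) {
  if (rule == "intronic") return(place_intronic(tm, g))
  if (rule == "splice") return(place_splice(tm, g))
  if (rule == "none") return(place_synonymous(tm, g, ts, params))
  want <- target_profile(rule)
  cand_pos <- candidate_positions(tm, rule, params)
  if (length(cand_pos) == 0L) return(NULL)
  tries <- sample(cand_pos, min(max_tries, length(cand_pos)))
  for (cp in tries) {
    v <- switch(class,
      snv = stop_gain_snv_at(tm, g, cp),
      ins = place_stop_insertion(tm, g, cp),
      del = place_frameshift_del(tm, g, cp),
      delins = place_delins(tm, g, cp),
      abort(paste0("unknown variant class: ", class)))
    if (is.null(v)) next
    ok <- verify_profile(v, tm, ts, g, params, want)
    if (ok) return(v)
  }
  NULL
}

# CDS windows where a PTC would trigger the target rule and nothing else
candidate_positions <- function(tm, rule, params) {
  L <- tm$cds_len - (tm$cds$end[nrow(tm$cds)] - tm$cds$start[nrow(tm$cds)] + 1L) + 1L
  B <- L - 1L
  n <- tm$cds_len
  all_pos <- seq(4L, n - 6L)
  w <- switch(rule,
    last_exon = all_pos[all_pos >= L & all_pos > params$d_css + 3L],
    penultimate = all_pos[all_pos <= B & all_pos >= B - params$d_pen + 3L &
                          all_pos > params$d_css + 3L],
    css_proximal = {
      p <- all_pos[all_pos <= params$d_css - 3L & all_pos < B - params$d_pen - 6L]
      if (nrow(tm$cds) < 2L) integer(0) else p   # avoid single/last overlap
    },
    exon407 = all_pos[all_pos > params$d_css + 3L],
    single_exon = if (tm$n_exons == 1L)
      all_pos[all_pos > params$d_css + 3L] else integer(0),
    integer(0))
  w
}

verify_profile <- function(v, tm, ts, g, params, want) {
  status <- check_overlap(v, tm, params$splice_margin)
  if (status != "coding") return(FALSE)
  o <- oracle_annotate(v, tm, g, params)
  if (!isTRUE(o$flags$is_ptc)) return(FALSE)
  got <- unlist(o$flags[, names(want)])
  all(got == want)
}

place_stop_insertion <- function(tm, g, cp) {
  a <- 3L * ((cp - 1L) %/% 3L)        # codon boundary at or before cp
  if (a < 3L || a > tm$cds_len - 9L) return(NULL)
  if (!same_exon_cds(tm, a, a + 1L)) return(NULL)
  S <- paste0("TAA", random_dna(3L))  # in-frame stop, then filler
  tx_insertion_after(tm, g, a, S)
}

place_frameshift_del <- function(tm, g, cp) {
  d <- sample(c(1L, 2L), 1L)   # frameshifting width
  if (cp + d - 1L > tm$cds_len) return(NULL)
  if (!same_exon_cds(tm, cp - 1L, cp + d - 1L)) return(NULL)
  gp <- vapply(seq(cp - 1L, cp + d - 1L), function(x)
    coordinate_map(tm, x, "c2g"), integer(1))
  genomic_del(tm, g, min(gp) + 1L, max(gp))
}

place_delins <- function(tm, g, cp) {
  k <- sample(2:4, 1L)
  if (cp + k > tm$cds_len - 3L) return(NULL)
  if (!same_exon_cds(tm, cp, cp + k - 1L)) return(NULL)
  gp <- vapply(seq(cp, cp + k - 1L), function(x)
    coordinate_map(tm, x, "c2g"), integer(1))
  lo <- min(gp); hi <- max(gp)
  ref <- genome_seq(g, tm$contig, lo, hi)
  m <- sample(c(k - 1L, k + 2L, 5L), 1L)
  alt <- random_dna(m)
  if (substr(alt, 1, 1) == substr(ref, 1, 1) ||
      substr(alt, m, m) == substr(ref, k, k)) return(NULL)
  tibble(contig = tm$contig, pos = lo, ref = ref, alt = alt,
         source_id = paste0(tm$transcript_id, ":delins:", lo))
}

same_exon_cds <- function(tm, a, b) {
  ga <- coordinate_map(tm, a, "c2g"); gb <- coordinate_map(tm, b, "c2g")
  any(tm$cds$start <= min(ga, gb) & tm$cds$end >= max(ga, gb))
}

place_synonymous <- function(tm, g, ts, params) {
  cds <- coding_sequence(tm, g)
  n_codons <- tm$cds_len %/% 3L
  for (cc in sample(2:(n_codons - 1L))) {
    f <- 3L * (cc - 1L) + 1L
    codon <- substr(cds, f, f + 2L)
    aa <- Biostrings::GENETIC_CODE[[codon]]
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, 3L, 3L)) next
      nc <- paste0(substr(codon, 1L, 2L), b)
      if (nc %in% STOP_CODONS) next
      if (Biostrings::GENETIC_CODE[[nc]] != aa) next
      cp <- f + 2L
      gpos <- coordinate_map(tm, cp, "c2g")
      refb <- substr(codon, 3L, 3L); altb <- b
      if (tm$strand == "-") { refb <- COMP[[refb]]; altb <- COMP[[altb]] }
      return(tibble(contig = tm$contig, pos = gpos, ref = refb, alt = altb,
                    source_id = paste0(tm$transcript_id, ":syn:", f)))
    }
  }
  NULL
}

place_splice <- function(tm, g, cp = NULL) {
  if (tm$n_exons < 2L) return(NULL)
  # deletion straddling the 3' end of an internal coding exon
  for (j in seq_len(nrow(tm$cds))) {
    e <- tm$cds$end[j]
    if (e < max(tm$exons$end) && e %in% tm$exons$end) {
      return(tibble(contig = tm$contig, pos = e - 2L,
                    ref = genome_seq(g, tm$contig, e - 2L, e + 2L),
                    alt = genome_seq(g, tm$contig, e - 2L, e - 2L),
                    source_id = paste0(tm$transcript_id, ":splice:", e)))
    }
  }
  NULL
}

place_intronic <- function(tm, g) {
  if (tm$n_exons < 2L) return(NULL)
  ex <- tm$exons[order(tm$exons$start), , drop = FALSE]
  for (j in seq_len(nrow(ex) - 1L)) {
    lo <- ex$end[j] + 1L; hi <- ex$start[j + 1L] - 1L
    mid <- (lo + hi) %/% 2L
    if (mid - lo >= 20L && hi - mid >= 20L) {
      refb <- genome_seq(g, tm$contig, mid, mid)
      altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
      return(tibble(contig = tm$contig, pos = mid, ref = refb, alt = altb,
                    source_id = paste0(tm$transcript_id, ":intron:", mid)))
    }
  }
  NULL
}

#' Write a minimal VCF v4.2 for a variants tibble
#'
#' @param variants Variants tibble (`contig`, `pos`, `ref`, `alt`,
#'   optionally `source_id` used as the ID column).
#' @param path Output path.
#' @param g Optional genome for contig header lines.
#' @return `path`, invisibly.
#' @export
write_simple_vcf <- function(variants, path, g = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(g))
             sprintf("##contig=<ID=%s,length=%d>", names(g), nchar(unclass(g))),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ids <- if ("source_id" %in% names(variants)) variants$source_id
         else rep(".", nrow(variants))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$contig, variants$pos, ids, variants$ref,
                  variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}
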