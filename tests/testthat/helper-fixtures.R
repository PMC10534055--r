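# Shared fixture machinery. Everything is generated in code at test time;
# fixtures are cached per session so test files can share them.

.fix_cache <- new.env(parent = emptyenv())

# standard random fixture: 8 transcripts, both strands, mixed exon counts
std_fixture <- function(seed = 11L, n = 8L) {
  key <- paste0("std", seed, "_", n)
  if (!is.null(.fix_cache[[key]])) return(.fix_cache[[key]])
  fx <- synth_genome_and_annotation(fixture_spec(n_transcripts = n, seed = seed))
  g <- load_genome(fx$fasta)
  ts <- filter_transcript_set(load_transcript_models(fx$gtf), genome = g)
  out <- list(fx = fx, g = g, ts = ts)
  .fix_cache[[key]] <- out
  out
}

# poly-lysine CDS layouts: every interior codon is AAA, one substitution
# away from TAA, so stop-gain SNVs can be placed at any codon
polyA_fixture <- function(layouts, seed = 5L) {
  fx <- synth_genome_and_annotation(
    fixture_spec(seed = seed, layouts = layouts))
  g <- load_genome(fx$fasta)
  ts <- filter_transcript_set(load_transcript_models(fx$gtf), genome = g)
  list(fx = fx, g = g, ts = ts)
}

polyA_layout <- function(exon_widths, intron_widths, utr5, utr3,
                         strand = "+", id = NULL) {
  transcript_layout(exon_widths, intron_widths, utr5 = utr5, utr3 = utr3,
                    strand = strand, cds_codons = "AAA", id = id)
}

# two-coding-exon poly-lysine transcripts whose junction position B covers
# all residues mod 3, so penultimate-rule distances reach every integer
pen_layouts <- function() {
  lapply(0:2, function(k) {
    polyA_layout(c(240L, 260L), 100L, utr5 = 30L - k, utr3 = 50L - 2L * k,
                 id = paste0("PEN", k))
  })
}

# hand-built two-codon-interior toy: genome and transcript created directly
# through the package internals, CDS "ATGAAATGA" with UTRs around it
toy_transcript <- function(strand = "+", utr5 = 5L, utr3 = 6L,
                           cds = "ATGAAATGA", contig = "chrT") {
  tx <- paste0(strsplit("GCGCGTCGA", "")[[1]][seq_len(utr5)] |> paste(collapse = ""),
               cds,
               strsplit("TTCCGGAACC", "")[[1]][seq_len(utr3)] |> paste(collapse = ""))
  if (strand == "+") {
    gseq <- paste0("NNNN", tx, "NNNN")
    exon <- data.frame(start = 5L, end = 4L + nchar(tx))
    cds_iv <- data.frame(start = 5L + utr5, end = 4L + utr5 + nchar(cds))
  } else {
    gseq <- paste0("NNNN", nmdescape:::revcomp(tx), "NNNN")
    exon <- data.frame(start = 5L, end = 4L + nchar(tx))
    cds_iv <- data.frame(start = 5L + utr3, end = 4L + utr3 + nchar(cds))
  }
  g <- structure(stats::setNames(gseq, contig), class = "nmde_genome")
  tm <- nmdescape:::new_transcript_model("TOY1", "GTOY", contig, strand,
                                         exons = exon, cds = cds_iv)
  list(g = g, tm = tm)
}

# random coding-region variants of all classes on a transcript set
random_variants <- function(ts, g, n_per_tx = 100L, seed = 99L,
                            classes = c("snv", "ins", "del", "delins")) {
  with_seed2(seed, {
    random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                    collapse = "")
    rows <- list()
    for (id in names(ts$transcripts)) {
      tm <- ts$transcripts[[id]]
      for (i in seq_len(n_per_tx)) {
        cp <- sample(2:(tm$cds_len - 4L), 1)
        gp <- coordinate_map(tm, cp, "c2g")
        cls <- sample(classes, 1)
        r1 <- genome_seq(g, tm$contig, gp, gp)
        v <- switch(cls,
          snv = tibble::tibble(contig = tm$contig, pos = gp, ref = r1,
                               alt = sample(setdiff(c("A","C","G","T"), r1), 1)),
          ins = tibble::tibble(contig = tm$contig, pos = gp, ref = r1,
                               alt = paste0(r1, random_dna(sample(1:6, 1)))),
          del = {
            w <- sample(1:5, 1)
            if (gp + w > nchar(g[[tm$contig]])) next
            tibble::tibble(contig = tm$contig, pos = gp,
                           ref = genome_seq(g, tm$contig, gp, gp + w),
                           alt = r1)
          },
          delins = {
            w <- sample(1:4, 1)
            tibble::tibble(contig = tm$contig, pos = gp,
                           ref = genome_seq(g, tm$contig, gp, gp + w),
                           alt = random_dna(sample(1:6, 1)))
          })
        v$tid <- id
        rows[[length(rows) + 1L]] <- v
      }
    }
    vs <- dplyr::bind_rows(rows)
    vs <- vs[vs$ref != vs$alt, , drop = FALSE]
    vs$source_id <- paste0("v", seq_len(nrow(vs)))
    vs
  })
}

with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# --- independent normalization oracle -------------------------------------
# enumerate every VCF representation of the same edit within a window and
# pick the minimal-position, minimal-length valid one
norm_oracle <- function(v, g, window = 20L) {
  S <- g[[v$contig]]
  lenS <- nchar(S)
  lr0 <- nchar(v$ref); la0 <- nchar(v$alt)
  delta <- la0 - lr0
  E <- paste0(substr(S, 1, v$pos - 1L), v$alt,
              substr(S, v$pos + lr0, lenS))
  ws <- max(1L, v$pos - window)
  we <- min(lenS, v$pos + lr0 + window)
  best <- NULL
  for (p in ws:we) {
    if (substr(S, ws, p - 1L) != substr(E, ws, p - 1L)) next
    for (lr in 1:(we - p + 1L)) {
      la <- lr + delta
      if (la < 1L) next
      r <- substr(S, p, p + lr - 1L)
      a <- substr(E, p, p + la - 1L)
      # remainder must align with the delta shift inside the window
      if (substr(S, p + lr, we) != substr(E, p + la, we + delta)) next
      # parsimony invariants of a normalized record
      if (substr(r, lr, lr) == substr(a, la, la)) next
      if (lr > 1L && la > 1L && substr(r, 1, 1) == substr(a, 1, 1)) next
      cand <- list(pos = p, ref = r, alt = a)
      if (is.null(best) || p < best$pos ||
          (p == best$pos && lr < nchar(best$ref))) {
        best <- cand
      }
    }
  }
  best
}
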