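test_that("overlap classification separates coding, splice and noncoding", {
  sf <- std_fixture()
  tm <- NULL
  for (t in sf$ts$transcripts) if (t$n_exons > 1L) { tm <- t; break }
  ex <- tm$exons[order(tm$exons$start), ]
  cds <- tm$cds[order(tm$cds$start), ]

  mid <- (cds$start[1] + cds$end[1]) %/% 2L
  snv <- list(pos = mid, ref = "A")
  expect_identical(check_overlap(snv, tm), "coding")

  straddle <- list(pos = cds$end[1] - 1L, ref = "AAAA")  # crosses exon end
  expect_identical(check_overlap(straddle, tm), "splice_excluded")

  margin_snv <- list(pos = ex$end[1] + 2L, ref = "A")    # canonical donor
  expect_identical(check_overlap(margin_snv, tm), "splice_excluded")

  deep <- list(pos = ex$end[1] + 40L, ref = "A")
  expect_identical(check_overlap(deep, tm), "noncoding")

  # exonic base adjacent to the junction is analyzable
  edge <- list(pos = cds$end[1], ref = "A")
  expect_identical(check_overlap(edge, tm), "coding")
})

test_that("mutant CDS reconstruction handles SNVs and insertions on both strands", {
  for (strand in c("+", "-")) {
    toy <- toy_transcript(strand = strand)       # CDS ATGAAATGA
    # A>T at CDS position 4 (transcript orientation)
    gp <- coordinate_map(toy$tm, 4L, "c2g")
    ref_g <- genome_seq(toy$g, "chrT", gp, gp)
    alt_g <- if (strand == "+") "T" else "A"     # complement on minus
    v <- list(contig = "chrT", pos = gp, ref = ref_g, alt = alt_g)
    a <- build_alt_cds(toy$tm, toy$g, v)
    expect_identical(substr(a$alt_seq, 1L, 9L), "ATGTAATGA")
    expect_identical(a$var_cds_pos, 4L)
    p <- find_ptc(a)
    expect_identical(p$alt_first_nt, 4L)
    expect_true(p$in_cds)
  }
})

test_that("insertion length propagates into the mutant sequence", {
  toy <- toy_transcript(strand = "+")
  gp <- coordinate_map(toy$tm, 6L, "c2g")
  anchor <- genome_seq(toy$g, "chrT", gp, gp)
  v <- list(contig = "chrT", pos = gp, ref = anchor, alt = paste0(anchor, "C"))
  a <- build_alt_cds(toy$tm, toy$g, v)
  expect_identical(a$delta, 1L)
  expect_identical(nchar(a$alt_seq), 9L + 6L + 1L)   # CDS + 3'UTR + inserted base
  expect_identical(substr(a$alt_seq, 1L, 10L), "ATGAAACTGA")
})

test_that("reference sequence yields no PTC (canonical termination)", {
  toy <- toy_transcript(strand = "+")
  gp <- coordinate_map(toy$tm, 5L, "c2g")
  b <- genome_seq(toy$g, "chrT", gp, gp)
  # synonymous-ish non-stop change: AAA -> AGA at codon 2
  v <- list(contig = "chrT", pos = gp, ref = b, alt = "G")
  a <- build_alt_cds(toy$tm, toy$g, v)
  expect_null(find_ptc(a))
})

test_that("frameshift deletions expose downstream out-of-frame stops", {
  sf <- std_fixture()
  found <- 0L
  for (tm in sf$ts$transcripts) {
    for (cp in seq(5L, min(tm$cds_len - 10L, 300L), by = 7L)) {
      gp0 <- coordinate_map(tm, cp - 1L, "c2g")
      gp1 <- coordinate_map(tm, cp, "c2g")
      lo <- min(gp0, gp1); hi <- max(gp0, gp1)
      if (hi - lo != 1L) next                   # same-exon single-base del
      v <- list(contig = tm$contig, pos = lo,
                ref = genome_seq(sf$g, tm$contig, lo, hi),
                alt = genome_seq(sf$g, tm$contig, lo, lo))
      if (check_overlap(v, tm) != "coding") next
      a <- build_alt_cds(tm, sf$g, v)
      p <- find_ptc(a)
      # independent codon walk over the literal mutant string
      s <- a$alt_seq
      starts <- seq(1L, nchar(s) - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      hits <- starts[codons %in% c("TAA", "TAG", "TGA")]
      hits <- hits[hits != a$canonical_stop_cds_pos + a$delta]
      if (is.null(p)) {
        expect_true(length(hits) == 0L ||
                    hits[1] > a$canonical_stop_cds_pos + a$delta)
      } else {
        expect_identical(p$alt_first_nt, hits[1])
        found <- found + 1L
      }
    }
  }
  expect_gte(found, 20L)
})

test_that("alt-to-ref mapping matches explicit alignment bookkeeping", {
  toy <- toy_transcript(strand = "+", utr3 = 9L)
  gp <- coordinate_map(toy$tm, 4L, "c2g")
  anchor <- genome_seq(toy$g, "chrT", gp, gp)
  v <- list(contig = "chrT", pos = gp, ref = anchor,
            alt = paste0(anchor, "GGG"))        # 3 bp insertion at CDS 4
  a <- build_alt_cds(toy$tm, toy$g, v)
  # explicit per-base alignment: ref ext positions of each mutant position
  align <- c(1:4, rep(4L, 3L), 5:(nchar(a$alt_seq) - 3L))
  for (ap in seq_len(nchar(a$alt_seq))) {
    expect_identical(map_alt_to_ref(a, ap), align[ap])
  }
  expect_identical(map_alt_to_ref(a, 3L), 3L)   # upstream: identity
  expect_identical(map_alt_to_ref(a, 6L), 4L)   # inside insertion: anchor
  # deletion: positions past the gap shift by its width
  v2 <- list(contig = "chrT", pos = gp,
             ref = genome_seq(toy$g, "chrT", gp, gp + 3L),
             alt = anchor)
  a2 <- build_alt_cds(toy$tm, toy$g, v2)
  expect_identical(map_alt_to_ref(a2, 10L), 13L)
  expect_error(map_alt_to_ref(a2, 0L))
})

test_that("stop-gain enumeration of a TAC codon finds exactly the two stop edits", {
  lay <- transcript_layout(c(300L), utr5 = 21L, utr3 = 45L, strand = "+",
                           cds_codons = "TAC")
  fx <- synth_genome_and_annotation(fixture_spec(seed = 9L, layouts = list(lay)))
  g <- load_genome(fx$fasta)
  ts <- filter_transcript_set(load_transcript_models(fx$gtf), genome = g)
  tm <- ts$transcripts[[1]]
  idx <- build_snv_ptc_index(ts, g)
  # codon 2 is TAC at CDS positions 4-6; only C>A (TAA) and C>G (TAG) at
  # position 6 generate a PTC
  g6 <- coordinate_map(tm, 6L, "c2g")
  expect_length(lookup_snv(idx, list(contig = tm$contig, pos = g6,
                                     ref = "C", alt = "A")), 1L)
  expect_length(lookup_snv(idx, list(contig = tm$contig, pos = g6,
                                     ref = "C", alt = "G")), 1L)
  expect_length(lookup_snv(idx, list(contig = tm$contig, pos = g6,
                                     ref = "C", alt = "T")), 0L)
  for (cp in 4:5) {
    gp <- coordinate_map(tm, cp, "c2g")
    r <- genome_seq(g, tm$contig, gp, gp)
    for (b in setdiff(c("A", "C", "G", "T"), r)) {
      expect_length(lookup_snv(idx, list(contig = tm$contig, pos = gp,
                                         ref = r, alt = b)), 0L)
    }
  }
})

test_that("index contents equal brute-force enumeration over all coding SNVs", {
  sf <- std_fixture(seed = 21L, n = 4L)
  idx <- build_snv_ptc_index(sf$ts, sf$g)
  n_checked <- 0L
  for (tm in sf$ts$transcripts) {
    for (cp in seq_len(tm$cds_len)) {
      gp <- coordinate_map(tm, cp, "c2g")
      r <- genome_seq(sf$g, tm$contig, gp, gp)
      for (b in setdiff(c("A", "C", "G", "T"), r)) {
        v <- list(contig = tm$contig, pos = gp, ref = r, alt = b)
        direct <- find_ptc(build_alt_cds(tm, sf$g, v, sf$ts))
        hits <- lookup_snv(idx, v)
        mine <- NULL
        for (e in hits) if (e$transcript_id == tm$transcript_id) mine <- e$ptc
        if (is.null(direct)) {
          expect_null(mine)
        } else {
          expect_identical(unclass(mine), unclass(direct))
        }
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 3000L)
})

test_that("SNVs on unannotated contigs and synonymous SNVs miss the index", {
  sf <- std_fixture(seed = 21L, n = 4L)
  idx <- build_snv_ptc_index(sf$ts, sf$g)
  expect_length(lookup_snv(idx, list(contig = "chrZ", pos = 5L,
                                     ref = "A", alt = "T")), 0L)
})

test_that("insertion content decides the PTC position (size is not enough)", {
  sf <- std_fixture()
  tm <- sf$ts$transcripts[[2]]
  a0 <- 30L                                     # codon boundary: 30 %% 3 == 0
  gp <- coordinate_map(tm, if (tm$strand == "+") a0 else a0 + 1L, "c2g")
  anchor <- genome_seq(sf$g, tm$contig, gp, gp)
  S_stop <- if (tm$strand == "+") "TAAGGG" else nmdescape:::revcomp("TAAGGG")
  S_plain <- if (tm$strand == "+") "CAAGGG" else nmdescape:::revcomp("CAAGGG")
  v1 <- list(contig = tm$contig, pos = gp, ref = anchor,
             alt = paste0(anchor, S_stop))
  v2 <- list(contig = tm$contig, pos = gp, ref = anchor,
             alt = paste0(anchor, S_plain))
  p1 <- find_ptc(build_alt_cds(tm, sf$g, v1))
  p2 <- find_ptc(build_alt_cds(tm, sf$g, v2))
  expect_false(is.null(p1))
  expect_identical(p1$alt_first_nt, 31L)        # inside the inserted sequence
  expect_true(is.null(p2) || p2$alt_first_nt != p1$alt_first_nt)
})

test_that("no in-frame stop exists upstream of a reported PTC", {
  sf <- std_fixture()
  vs <- random_variants(sf$ts, sf$g, n_per_tx = 30L, seed = 31L)
  vs <- suppressWarnings(left_normalize(vs, sf$g))
  for (i in seq_len(nrow(vs))) {
    tm <- sf$ts$transcripts[[vs$tid[i]]]
    if (check_overlap(vs[i, ], tm) != "coding") next
    a <- build_alt_cds(tm, sf$g, vs[i, ], sf$ts)
    p <- find_ptc(a)
    if (is.null(p)) next
    if (p$alt_first_nt == 1L) next
    starts <- seq(1L, p$alt_first_nt - 1L, by = 3L)
    starts <- starts[starts + 2L < p$alt_first_nt]
    if (!length(starts)) next
    upstream <- substring(a$alt_seq, starts, starts + 2L)
    expect_false(any(upstream %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("annotation output is identical with and without the index", {
  sf <- std_fixture(seed = 21L, n = 4L)
  idx <- build_snv_ptc_index(sf$ts, sf$g)
  vs <- random_variants(sf$ts, sf$g, n_per_tx = 60L, seed = 41L,
                        classes = "snv")
  vs <- suppressWarnings(left_normalize(vs, sf$g))
  a1 <- annotate_variants(vs, sf$ts, sf$g)
  a2 <- annotate_variants(vs, sf$ts, sf$g, index = idx)
  attr(a1, "pair_counts") <- NULL; attr(a2, "pair_counts") <- NULL
  expect_identical(as.data.frame(a1), as.data.frame(a2))
})

test_that("deep intronic variants produce no annotation rows", {
  sf <- std_fixture()
  tm <- NULL
  for (t in sf$ts$transcripts) if (t$n_exons > 1L) { tm <- t; break }
  ex <- tm$exons[order(tm$exons$start), ]
  v <- tibble::tibble(contig = tm$contig, pos = ex$end[1] + 30L,
                      ref = genome_seq(sf$g, tm$contig, ex$end[1] + 30L,
                                       ex$end[1] + 30L),
                      alt = "A")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  ann <- annotate_variants(v, sf$ts, sf$g)
  expect_identical(nrow(ann), 0L)
})

test_that("PTC index serialization round-trips and validates its fingerprint", {
  sf <- std_fixture(seed = 21L, n = 4L)
  idx <- build_snv_ptc_index(sf$ts, sf$g)
  p <- tempfile(fileext = ".tsv")
  save_ptc_index(idx, p)
  idx2 <- load_ptc_index(p, sf$ts)
  expect_identical(idx2$n_entries, idx$n_entries)
  ks <- ls(idx$env)
  expect_setequal(ks, ls(idx2$env))
  k <- ks[1]
  expect_identical(idx$env[[k]], idx2$env[[k]])
  other <- std_fixture(seed = 22L, n = 3L)
  expect_error(load_ptc_index(p, other$ts), "fingerprint")
})
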