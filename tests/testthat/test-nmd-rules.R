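test_that("penultimate rule flips exactly at d_pen on the spliced CDS", {
  fx <- polyA_fixture(list(polyA_layout(c(240L, 260L), 100L, utr5 = 30L,
                                        utr3 = 47L, id = "PEN")))
  tm <- fx$ts$transcripts$PEN
  B <- tm$cds_len - (tm$cds$end[2] - tm$cds$start[2] + 1L)
  observed <- integer(0); flags <- logical(0)
  for (cc in seq(2L, (B + 2L) %/% 3L)) {       # codons around the junction
    v <- stop_gain_snv_at(tm, fx$g, 3L * (cc - 1L) + 1L)
    if (is.null(v)) next
    ann <- annotate_variants(v, fx$ts, fx$g)
    p3 <- c(3L * cc - 2L, 3L * cc - 1L, 3L * cc)
    q <- max(p3[p3 <= B])
    observed <- c(observed, B - q)
    flags <- c(flags, ann$penultimate[1])
  }
  expect_true(all(flags[observed <= 50L]))
  expect_false(any(flags[observed > 50L]))
})

test_that("penultimate-rule distances cover every integer across frame-shifted junctions", {
  fx <- polyA_fixture(pen_layouts())
  dist_flag <- list()
  for (tm in fx$ts$transcripts) {
    B <- tm$cds_len - (tm$cds$end[2] - tm$cds$start[2] + 1L)
    for (cc in seq((B - 60L) %/% 3L, (B + 3L) %/% 3L)) {
      f <- 3L * (cc - 1L) + 1L
      v <- stop_gain_snv_at(tm, fx$g, f)
      if (is.null(v)) next
      ann <- annotate_variants(v, fx$ts, fx$g)
      ann <- ann[ann$transcript_id == tm$transcript_id, ]
      p3 <- c(f, f + 1L, f + 2L)
      if (!any(p3 <= B)) next
      d <- B - max(p3[p3 <= B])
      dist_flag[[length(dist_flag) + 1L]] <- c(d, ann$penultimate[1])
    }
  }
  m <- do.call(rbind, dist_flag)
  expect_true(all(seq(45L, 55L) %in% m[, 1]))   # dense coverage near the flip
  expect_identical(max(m[m[, 2] == 1L, 1]), 50L)
  expect_identical(min(m[m[, 2] == 0L, 1]), 51L)
})

test_that("junction-spanning PTC codons anchor at the junction-proximal base", {
  # B %% 3 == 1 so the codon containing B spans the junction
  fx <- polyA_fixture(list(polyA_layout(c(241L, 260L), 100L, utr5 = 30L,
                                        utr3 = 48L, id = "SPAN")))
  tm <- fx$ts$transcripts$SPAN
  B <- tm$cds_len - (tm$cds$end[2] - tm$cds$start[2] + 1L)
  expect_identical(B %% 3L, 1L)
  cc <- (B + 2L) %/% 3L                        # codon with 1 base before junction
  v <- stop_gain_snv_at(tm, fx$g, 3L * (cc - 1L) + 1L)
  ann <- annotate_variants(v, fx$ts, fx$g)
  expect_true(ann$penultimate[1])              # distance 0 via proximal base
})

test_that("css rule measures the mutant coding sequence inclusively", {
  fx <- polyA_fixture(list(polyA_layout(c(400L, 260L), 100L, utr5 = 30L,
                                        utr3 = 48L, id = "CSS")))
  tm <- fx$ts$transcripts$CSS
  v148 <- stop_gain_snv_at(tm, fx$g, 148L)
  v151 <- stop_gain_snv_at(tm, fx$g, 151L)
  a148 <- annotate_variants(v148, fx$ts, fx$g)
  a151 <- annotate_variants(v151, fx$ts, fx$g)
  expect_identical(a148$ptc_alt_pos[1], 148L)
  expect_identical(a151$ptc_alt_pos[1], 151L)
  expect_true(a148$css_proximal[1])
  expect_false(a151$css_proximal[1])
  # threshold sweep around the default recovers 150 as the largest d_css
  # that leaves the 151-probe unflagged
  flagged151 <- vapply(148:152, function(d) {
    annotate_variants(v151, fx$ts, fx$g,
                      params = rule_params(d_css = d))$css_proximal[1]
  }, logical(1))
  expect_identical(max((148:152)[!flagged151]), 150L)
  # a PTC inside inserted sequence is measured in mutant coordinates
  a0 <- 147L                                   # codon boundary
  gp <- coordinate_map(tm, a0, "c2g")
  anchor <- genome_seq(fx$g, tm$contig, gp, gp)
  vins <- tibble::tibble(contig = tm$contig, pos = gp, ref = anchor,
                         alt = paste0(anchor, "TAA"))
  ai <- annotate_variants(vins, fx$ts, fx$g)
  expect_identical(ai$ptc_alt_pos[1], 148L)
  expect_true(ai$css_proximal[1])
})

test_that("exon-size rule is strict at the 407 bp boundary", {
  lays <- lapply(c(406L, 407L, 408L, 409L), function(w) {
    utr3 <- 48L + (1L + w) %% 3L               # keeps CDS length %% 3 == 0
    polyA_layout(c(200L, w, 200L), c(90L, 90L), utr5 = 30L, utr3 = utr3,
                 id = paste0("W", w))
  })
  fx <- polyA_fixture(lays)
  for (w in c(406L, 407L, 408L, 409L)) {
    tm <- fx$ts$transcripts[[paste0("W", w)]]
    mid_cds <- 200L - 30L + w %/% 2L            # middle of exon 2 in CDS coords
    mid_cds <- mid_cds - (mid_cds %% 3L) + 1L
    v <- stop_gain_snv_at(tm, fx$g, mid_cds)
    ann <- annotate_variants(v, fx$ts, fx$g)
    ann <- ann[ann$transcript_id == tm$transcript_id, ]
    expect_identical(ann$exon407[1], w > 407L,
                     info = paste("width", w))
    expect_identical(ann$ptc_exon_width[1], w)
  }
})

test_that("single-exon transcripts escape via the intronless rule", {
  fx <- polyA_fixture(list(polyA_layout(300L, integer(0), utr5 = 21L,
                                        utr3 = 45L, id = "SGL"),
                           polyA_layout(c(200L, 200L), 80L, utr5 = 21L,
                                        utr3 = 49L, id = "DBL")))
  v <- stop_gain_snv_at(fx$ts$transcripts$SGL, fx$g, 60L)
  ann <- annotate_variants(v, fx$ts, fx$g)
  expect_true(ann$single_exon[1])
  expect_true(ann$last_exon[1])                # the only exon is the last
  v2 <- stop_gain_snv_at(fx$ts$transcripts$DBL, fx$g, 60L)
  ann2 <- annotate_variants(v2, fx$ts, fx$g)
  expect_false(ann2$single_exon[1])
})

test_that("apply_rules composes flags and their disjunction", {
  expect_false(any(unlist(apply_rules(NULL, NULL))))
  sf <- std_fixture()
  vs <- random_variants(sf$ts, sf$g, n_per_tx = 25L, seed = 51L)
  vs <- suppressWarnings(left_normalize(vs, sf$g))
  ann <- annotate_variants(vs, sf$ts, sf$g)
  rules <- c("last_exon", "penultimate", "css_proximal", "exon407",
             "single_exon")
  expect_identical(ann$escape_any,
                   apply(as.matrix(ann[, rules]), 1, any))
  expect_false(any(unlist(ann[!ann$is_ptc, rules])))
})

test_that("escape flags are monotone in d_pen and d_css", {
  sf <- std_fixture()
  vs <- random_variants(sf$ts, sf$g, n_per_tx = 20L, seed = 61L)
  vs <- suppressWarnings(left_normalize(vs, sf$g))
  base <- annotate_variants(vs, sf$ts, sf$g,
                            params = rule_params(d_pen = 30L, d_css = 100L))
  wide <- annotate_variants(vs, sf$ts, sf$g,
                            params = rule_params(d_pen = 80L, d_css = 200L))
  expect_true(all(wide$penultimate >= base$penultimate))
  expect_true(all(wide$css_proximal >= base$css_proximal))
  expect_true(all(wide$escape_any >= base$escape_any))
})

test_that("disabling rules changes only the disjunction, never the flags", {
  sf <- std_fixture()
  vs <- random_variants(sf$ts, sf$g, n_per_tx = 20L, seed = 71L)
  vs <- suppressWarnings(left_normalize(vs, sf$g))
  full <- annotate_variants(vs, sf$ts, sf$g)
  sub <- annotate_variants(vs, sf$ts, sf$g,
                           params = rule_params(rules = c("last_exon",
                                                          "penultimate")))
  rules <- c("last_exon", "penultimate", "css_proximal", "exon407",
             "single_exon")
  expect_identical(as.data.frame(full[, rules]), as.data.frame(sub[, rules]))
  expect_identical(sub$escape_any, sub$last_exon | sub$penultimate)
})
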