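#' Annotate variants for predicted escape from NMD
#'
#' The package's central operation. For every normalized, biallelic variant
#' and every overlapping transcript whose CDS fully contains the variant's
#' reference span (outside splice regions), the mutant coding sequence is
#' reconstructed, the 5'-most novel premature termination codon is located,
#' and the five NMD-escape rules are evaluated. SNVs can be resolved
#' through a precomputed [build_snv_ptc_index()] index; non-SNV variants
#' (insertions, deletions, delins, frameshifts) are always assessed by
#' explicit reconstruction, so both the size and the content of inserted
#' sequence are taken into account.
#'
#' @param variants Variants tibble ([read_variants()] /
#'   [left_normalize()] output, or any tibble with `contig`, `pos`, `ref`,
#'   `alt` and optionally `source_id`).
#' @param ts A filtered `nmde_transcript_set`.
#' @param genome An `nmde_genome`.
#' @param params A [rule_params()] object.
#' @param index Optional `nmde_ptc_index`; output is identical with or
#'   without it.
#' @return A tibble with one row per analyzable variant-transcript pair:
#'   the variant columns, `transcript_id`, `variant_class`, the rule flags
#'   (`is_ptc`, `last_exon`, `penultimate`, `css_proximal`, `exon407`,
#'   `single_exon`, `escape_any`) and PTC coordinates (`ptc_alt_pos`,
#'   `ptc_ref_pos`, `ptc_exon`, `ptc_exon_width`, `ptc_in_cds`; `NA` when
#'   `is_ptc` is `FALSE`). Counts of splice-excluded and noncoding pairs
#'   are attached as attribute `"pair_counts"`.
#' @examples
#' fx <- synth_genome_and_annotation(fixture_spec(n_transcripts = 2, seed = 1))
#' g <- load_genome(fx$fasta)
#' ts <- filter_transcript_set(load_transcript_models(fx$gtf), genome = g)
#' tm <- ts$transcripts[[1]]
#' v <- stop_gain_snv_at(tm, g, cds_pos = 10L)
#' if (!is.null(v)) annotate_variants(v, ts, g)
#' @export
annotate_variants <- function(variants, ts, genome, params = rule_params(),
                              index = NULL) {
  if (!"source_id" %in% names(variants)) {
    variants$source_id <- paste(variants$contig, variants$pos, variants$ref,
                                variants$alt, sep = ":")
  }
  if (!"allele_index" %in% names(variants)) variants$allele_index <- 1L
  if (!"multiallelic" %in% names(variants)) variants$multiallelic <- FALSE
  n <- nrow(variants)
  out <- vector("list", n)
  counts <- c(coding = 0L, splice_excluded = 0L, noncoding = 0L)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    cand <- overlapping_transcripts(ts, v$contig, v$pos,
                                    v$pos + nchar(v$ref) - 1L)
    if (length(cand) == 0L) next
    rows <- list()
    for (tid in cand) {
      tm <- get_transcript(ts, tid)
      status <- check_overlap(v, tm, params$splice_margin)
      if (status != "coding") {
        counts[status] <- counts[status] + 1L
        next
      }
      counts["coding"] <- counts["coding"] + 1L
      p <- resolve_ptc(v, tm, ts, genome, index)
      flags <- apply_rules(p, tm, params)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        v,
        tibble(transcript_id = tid,
               variant_class = variant_class(v$ref, v$alt)),
        flags,
        tibble(
          ptc_alt_pos = if (is.null(p)) NA_integer_ else p$alt_first_nt,
          ptc_ref_pos = if (is.null(p)) NA_integer_ else p$ref_first_nt,
          ptc_exon = if (is.null(p)) NA_integer_ else p$exon_ordinal,
          ptc_exon_width = if (is.null(p)) NA_integer_ else p$exon_width,
          ptc_in_cds = if (is.null(p)) NA else p$in_cds
        ))
    }
    if (length(rows)) out[[i]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- dplyr::bind_cols(
      variants[0, ],
      tibble(transcript_id = character(), variant_class = character(),
             is_ptc = logical(), last_exon = logical(),
             penultimate = logical(), css_proximal = logical(),
             exon407 = logical(), single_exon = logical(),
             escape_any = logical(), ptc_alt_pos = integer(),
             ptc_ref_pos = integer(), ptc_exon = integer(),
             ptc_exon_width = integer(), ptc_in_cds = logical()))
  }
  attr(res, "pair_counts") <- counts
  res
}

# SNVs go through the index when one is supplied; everything else is
# reconstructed explicitly
resolve_ptc <- function(v, tm, ts, genome, index) {
  is_snv <- nchar(v$ref) == 1L && nchar(v$alt) == 1L
  if (is_snv && !is.null(index)) {
    hits <- lookup_snv(index, v)
    for (e in hits) if (e$transcript_id == tm$transcript_id) return(e$ptc)
    return(NULL)
  }
  find_ptc(build_alt_cds(tm, genome, v, ts))
}

#' One-row summary of an annotation result
#'
#' Glance-style overview: pair counts by overlap status, PTC pairs,
#' per-rule escape counts and the any-rule escape count.
#'
#' @param annotations Output of [annotate_variants()].
#' @return A one-row tibble.
#' @export
summarize_annotation <- function(annotations) {
  pc <- attr(annotations, "pair_counts") %||%
    c(coding = nrow(annotations), splice_excluded = NA_integer_,
      noncoding = NA_integer_)
  tibble(
    n_pairs_coding = unname(pc["coding"]),
    n_pairs_splice_excluded = unname(pc["splice_excluded"]),
    n_pairs_noncoding = unname(pc["noncoding"]),
    n_ptc = sum(annotations$is_ptc),
    n_last_exon = sum(annotations$last_exon),
    n_penultimate = sum(annotations$penultimate),
    n_css_proximal = sum(annotations$css_proximal),
    n_exon407 = sum(annotations$exon407),
    n_single_exon = sum(annotations$single_exon),
    n_escape_any = sum(annotations$escape_any)
  )
}

#' Bar chart of per-rule NMD-escape counts
#'
#' @param annotations Output of [annotate_variants()].
#' @return A ggplot object.
#' @export
plot_rule_summary <- function(annotations) {
  rules <- c("last_exon", "penultimate", "css_proximal", "exon407",
             "single_exon", "escape_any")
  df <- annotations |>
    dplyr::filter(.data$is_ptc) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(rules), ~ sum(.x))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "rule",
                        values_to = "n_pairs")
  df$rule <- factor(df$rule, levels = rules)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rule, y = .data$n_pairs)) +
    ggplot2::geom_col(fill = "#5b4b8a") +
    ggplot2::labs(x = NULL, y = "PTC variant-transcript pairs",
                  title = "Predicted NMD escape by rule") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
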