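#' Rule parameters for NMD-escape prediction
#'
#' Defaults follow the established exon-junction-complex-based rule set:
#' a PTC escapes NMD when it lies in the last coding exon, within
#' `d_pen` = 50 bp upstream of the penultimate exon junction, within
#' `d_css` = 150 bp downstream of the coding start site, in an exon
#' spanning more than 407 bp, or on an intronless transcript. "Within
#' d bp" is inclusive (<= d); "more than 407 bp" is strict (> 407).
#'
#' @param d_pen Penultimate-junction distance in bp (default 50).
#' @param d_css Coding-start-site distance in bp (default 150).
#' @param exon_size_min Exon-size threshold in bp (default 407; flag fires
#'   for widths strictly greater).
#' @param splice_margin Intronic splice-region margin in bp (default 2).
#' @param rules Character subset of
#'   `c("last_exon","penultimate","css_proximal","exon407","single_exon")`
#'   entering the escape disjunction. Individual flags are always
#'   reported; disabled rules are only zeroed in `escape_any`.
#' @return A `nmde_rule_params` list.
#' @export
rule_params <- function(d_pen = 50L, d_css = 150L, exon_size_min = 407L,
                        splice_margin = 2L,
                        rules = c("last_exon", "penultimate", "css_proximal",
                                  "exon407", "single_exon")) {
  all_rules <- c("last_exon", "penultimate", "css_proximal", "exon407",
                 "single_exon")
  rules <- match.arg(rules, all_rules, several.ok = TRUE)
  stopifnot(d_pen >= 0L, d_css >= 0L, exon_size_min >= 0L, splice_margin >= 0L)
  structure(list(d_pen = as.integer(d_pen), d_css = as.integer(d_css),
                 exon_size_min = as.integer(exon_size_min),
                 splice_margin = as.integer(splice_margin), rules = rules),
            class = "nmde_rule_params")
}

#' Last-coding-exon rule
#'
#' A PTC at or downstream of the first base of the last coding exon (the
#' exon containing the canonical stop codon) escapes NMD: there is no
#' exon-junction complex downstream of termination. Frameshift PTCs in
#' 3'UTR sequence also qualify.
#'
#' @param p An `nmde_ptc`.
#' @param tm The transcript model.
#' @return Logical flag.
#' @export
rule_last_exon <- function(p, tm) {
  last_w <- tm$cds$end[nrow(tm$cds)] - tm$cds$start[nrow(tm$cds)] + 1L
  first_base_last_exon <- tm$cds_len - last_w + 1L
  p$ref_first_nt >= first_base_last_exon
}

#' Penultimate-exon rule (50-nt rule)
#'
#' A PTC within `d_pen` bp upstream of the 3' boundary of the penultimate
#' coding exon escapes NMD. The distance is measured along the spliced CDS
#' from the PTC nucleotide closest to (and not past) the junction, so a
#' PTC codon spanning the last junction anchors at its junction-proximal
#' base, and short penultimate exons let PTCs in earlier exons qualify.
#'
#' @param p An `nmde_ptc`.
#' @param tm The transcript model.
#' @param d_pen Distance threshold in bp (inclusive).
#' @return Logical flag (`FALSE` for transcripts with fewer than two
#'   coding exons).
#' @export
rule_penultimate <- function(p, tm, d_pen = 50L) {
  if (nrow(tm$cds) < 2L) return(FALSE)
  last_w <- tm$cds$end[nrow(tm$cds)] - tm$cds$start[nrow(tm$cds)] + 1L
  B <- tm$cds_len - last_w            # 3'-most coding base of penultimate exon
  nts <- unique(c(p$ref_first_nt, p$ref_mid_nt, p$ref_last_nt))
  nts <- nts[nts <= B]
  if (length(nts) == 0L) return(FALSE)
  q <- max(nts)
  (B - q) <= d_pen
}

#' Coding-start-site proximity rule
#'
#' A PTC whose 5'-most nucleotide lies within the first `d_css` bases of
#' the mutant coding sequence escapes NMD (translation reinitiation /
#' inefficient termination near the start). Measured in mutant-CDS
#' coordinates: the PTC may sit inside inserted sequence with no reference
#' coordinate.
#'
#' @param p An `nmde_ptc`.
#' @param d_css Distance threshold in bp (inclusive).
#' @return Logical flag.
#' @export
rule_css_proximal <- function(p, d_css = 150L) {
  p$alt_first_nt <= d_css
}

#' Large-exon rule (407 bp rule)
#'
#' A PTC inside an exon spanning more than `threshold` bp (full annotated
#' genomic width, UTR included) escapes NMD.
#'
#' @param p An `nmde_ptc`.
#' @param threshold Width threshold in bp; the flag fires for widths
#'   strictly greater (default 407).
#' @return Logical flag.
#' @export
rule_exon407 <- function(p, threshold = 407L) {
  p$exon_width > threshold
}

#' Single-exon (intronless) rule
#'
#' NMD is inefficient on intronless transcripts: any PTC on a single-exon
#' transcript escapes.
#'
#' @param tm The transcript model.
#' @return Logical flag.
#' @export
rule_single_exon <- function(tm) {
  tm$n_exons == 1L
}

#' Evaluate all NMD-escape rules for a located PTC
#'
#' Each rule is evaluated independently and reported; `escape_any` is the
#' disjunction over the rules enabled in `params$rules` (disabled rules
#' are zeroed only in the disjunction, never in their own flag). With
#' `p = NULL` (no PTC) all flags are `FALSE`.
#'
#' @param p An `nmde_ptc` or `NULL`.
#' @param tm The transcript model.
#' @param params A [rule_params()] object.
#' @return One-row tibble: `is_ptc`, `last_exon`, `penultimate`,
#'   `css_proximal`, `exon407`, `single_exon`, `escape_any`.
#' @export
apply_rules <- function(p, tm, params = rule_params()) {
  if (is.null(p)) {
    return(tibble(is_ptc = FALSE, last_exon = FALSE, penultimate = FALSE,
                  css_proximal = FALSE, exon407 = FALSE, single_exon = FALSE,
                  escape_any = FALSE))
  }
  flags <- c(
    last_exon = rule_last_exon(p, tm),
    penultimate = rule_penultimate(p, tm, params$d_pen),
    css_proximal = rule_css_proximal(p, params$d_css),
    exon407 = rule_exon407(p, params$exon_size_min),
    single_exon = rule_single_exon(tm)
  )
  tibble(is_ptc = TRUE,
         last_exon = flags[["last_exon"]],
         penultimate = flags[["penultimate"]],
         css_proximal = flags[["css_proximal"]],
         exon407 = flags[["exon407"]],
         single_exon = flags[["single_exon"]],
         escape_any = any(flags[params$rules]))
}
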