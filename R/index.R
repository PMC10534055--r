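#' @title Precomputed index of PTC-generating SNVs
#' @description For a filtered transcript set, every possible coding SNV is
#'   assessed once and the PTC-generating ones are stored under a string key
#'   `contig:zero-padded-pos:REF>ALT`, so lexicographic prefix order equals
#'   numeric position order. Lookup results are identical to on-the-fly
#'   computation via [build_alt_cds()] + [find_ptc()].
#' @name ptc_index
NULL

transcript_set_fingerprint <- function(ts) {
  ids <- sort(names(ts$transcripts))
  payload <- lapply(ids, function(id) {
    tm <- ts$transcripts[[id]]
    list(id = id, contig = tm$contig, strand = tm$strand,
         cds = as.matrix(tm$cds))
  })
  rlang::hash(payload)
}

new_ptc_index <- function(env, fingerprint, pad, n_entries) {
  structure(list(env = env, fingerprint = fingerprint, pad = pad,
                 n_entries = n_entries), class = "nmde_ptc_index")
}

#' @export
print.nmde_ptc_index <- function(x, ...) {
  cat("<nmde_ptc_index> ", x$n_entries, " stop-gain SNV entrie(s), fingerprint ",
      substr(x$fingerprint, 1, 8), "...\n", sep = "")
  invisible(x)
}

#' Build the index of all PTC-generating SNVs
#'
#' Enumerates, for every CDS position of every transcript and each of the
#' three alternative bases, whether the SNV creates a premature termination
#' codon, and stores the PTC location for the ones that do. SNVs inside
#' the canonical stop codon are assessed through full mutant-sequence
#' reconstruction (a destroyed stop can expose a downstream one).
#'
#' @param ts A filtered `nmde_transcript_set`.
#' @param g An `nmde_genome`.
#' @return An `nmde_ptc_index`.
#' @export
build_snv_ptc_index <- function(ts, g) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  pad <- pad_width_for(max(c(0L, nchar(unclass(g)))))
  n_entries <- 0L
  bases <- c("A", "C", "G", "T")
  for (tm in ts$transcripts) {
    cds <- coding_sequence(tm, g)
    n <- nchar(cds)
    n_codons <- n %/% 3L
    for (cc in seq_len(n_codons)) {
      f <- 3L * (cc - 1L) + 1L
      codon <- substr(cds, f, f + 2L)
      last_codon <- cc == n_codons
      for (j in 1:3) {
        cds_pos <- f + j - 1L
        refb <- substr(codon, j, j)
        if (!refb %in% bases) next
        gpos <- coordinate_map(tm, cds_pos, "c2g")
        for (altb in bases[bases != refb]) {
          gref <- if (tm$strand == "+") refb else COMP[[refb]]
          galt <- if (tm$strand == "+") altb else COMP[[altb]]
          if (last_codon) {
            # canonical stop codon: full reconstruction
            v <- list(contig = tm$contig, pos = gpos, ref = gref, alt = galt)
            p <- find_ptc(build_alt_cds(tm, g, v, ts))
          } else {
            newcodon <- codon
            substr(newcodon, j, j) <- altb
            if (!newcodon %in% STOP_CODONS) next
            ex <- exon_of_cds_pos(tm, f)
            p <- structure(list(
              alt_first_nt = f, alt_last_nt = f + 2L,
              ref_first_nt = f, ref_mid_nt = f + 1L, ref_last_nt = f + 2L,
              exon_ordinal = ex$exon_ordinal,
              exon_width = ex$exon_genomic_width,
              in_cds = TRUE), class = "nmde_ptc")
          }
          if (is.null(p)) next
          key <- snv_key(tm$contig, gpos, gref, galt, pad)
          cur <- env[[key]]
          entry <- list(transcript_id = tm$transcript_id, ptc = p)
          env[[key]] <- c(cur %||% list(), list(entry))
          n_entries <- n_entries + 1L
        }
      }
    }
  }
  new_ptc_index(env, transcript_set_fingerprint(ts), pad, n_entries)
}

#' Look up an SNV in the PTC index
#'
#' @param idx An `nmde_ptc_index`.
#' @param v One-row variants tibble (or list) with `contig`, `pos`, `ref`,
#'   `alt`; must be an SNV.
#' @return List of entries `list(transcript_id=, ptc=)`; empty for misses.
#' @export
lookup_snv <- function(idx, v) {
  key <- snv_key(v$contig, v$pos, v$ref, v$alt, idx$pad)
  idx$env[[key]] %||% list()
}

#' Serialize a PTC index to a flat text file
#'
#' One sorted line per SNV key, tab, then semicolon-separated per-transcript
#' payloads. The header records a fingerprint of the transcript set
#' (identifiers plus CDS spans); loading against a different set fails.
#'
#' @param idx An `nmde_ptc_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_ptc_index <- function(idx, path) {
  keys <- sort(ls(idx$env))
  lines <- vapply(keys, function(k) {
    entries <- idx$env[[k]]
    payload <- vapply(entries, function(e) {
      p <- e$ptc
      paste(e$transcript_id, p$alt_first_nt, p$ref_first_nt, p$ref_mid_nt,
            p$ref_last_nt, p$exon_ordinal, p$exon_width,
            as.integer(p$in_cds), sep = ",")
    }, character(1))
    paste0(k, "\t", paste(payload, collapse = ";"))
  }, character(1))
  writeLines(c("#nmdescape-ptc-index\tv1",
               paste0("#fingerprint\t", idx$fingerprint),
               paste0("#pad\t", idx$pad),
               lines), path)
  invisible(path)
}

#' Load a serialized PTC index
#'
#' @param path File written by [save_ptc_index()].
#' @param ts The transcript set the index must match; a fingerprint
#'   mismatch is a fatal error.
#' @return An `nmde_ptc_index`.
#' @export
load_ptc_index <- function(path, ts) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], "#nmdescape-ptc-index")) {
    abort("not a nmdescape PTC index file")
  }
  fp <- sub("^#fingerprint\t", "", lines[2])
  if (!is.null(ts)) {
    want <- transcript_set_fingerprint(ts)
    if (!identical(fp, want)) {
      abort(paste0("PTC index fingerprint mismatch: index was built for a ",
                   "different transcript set (", substr(fp, 1, 8), "... vs ",
                   substr(want, 1, 8), "...)"))
    }
  }
  pad <- as.integer(sub("^#pad\t", "", lines[3]))
  env <- new.env(parent = emptyenv(), hash = TRUE)
  n_entries <- 0L
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  for (ln in body) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    entries <- lapply(strsplit(parts[2], ";", fixed = TRUE)[[1]], function(e) {
      f <- strsplit(e, ",", fixed = TRUE)[[1]]
      list(transcript_id = f[1],
           ptc = structure(list(
             alt_first_nt = as.integer(f[2]),
             alt_last_nt = as.integer(f[2]) + 2L,
             ref_first_nt = as.integer(f[3]),
             ref_mid_nt = as.integer(f[4]),
             ref_last_nt = as.integer(f[5]),
             exon_ordinal = as.integer(f[6]),
             exon_width = as.integer(f[7]),
             in_cds = f[8] == "1"), class = "nmde_ptc"))
    })
    env[[parts[1]]] <- entries
    n_entries <- n_entries + length(entries)
  }
  new_ptc_index(env, fp, pad, n_entries)
}
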