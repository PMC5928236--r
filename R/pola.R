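# Pol I (family A DNA polymerase) lifestyle classification.
#
# The residue at position 762 of the reference polymerase (E. coli
# numbering; wildtype Phe) is a marker of phage lifestyle: Phe762 or Tyr762
# peptides are called generally virulent (lytic), Leu762 generally temperate
# (lysogenic). A candidate peptide is usable only when it spans the region
# of interest (ROI), reference positions 547 (Ile) to 923 (Asn). Peptides
# are mapped onto reference coordinates by deterministic semi-global
# pairwise alignment.

#' Region-of-interest specification for the Pol I classifier
#'
#' Validates, at construction, that the reference peptide carries the three
#' anchor residues: Ile at `roi_start`, Phe at `site`, Asn at `roi_end`.
#'
#' @param reference_id Reference sequence id.
#' @param reference_peptide Reference polymerase amino-acid string.
#' @param roi_start,roi_end 1-based ROI endpoints on the reference
#'   (defaults 547 and 923).
#' @param site 1-based position of the classifying residue (default 762).
#' @param expected_residues Named character vector of anchor residues, names
#'   `roi_start`, `site`, `roi_end`.
#' @return An object of class `RoiSpec`.
#' @export
roi_spec <- function(reference_id, reference_peptide, roi_start = 547L,
                     site = 762L, roi_end = 923L,
                     expected_residues = c(roi_start = "I", site = "F",
                                           roi_end = "N")) {
  roi_start <- as.integer(roi_start); site <- as.integer(site)
  roi_end <- as.integer(roi_end)
  stopifnot(roi_start >= 1L, roi_start < site, site < roi_end,
            roi_end <= nchar(reference_peptide))
  reference_peptide <- toupper(reference_peptide)
  got <- substring(reference_peptide, c(roi_start, site, roi_end),
                   c(roi_start, site, roi_end))
  want <- unname(expected_residues[c("roi_start", "site", "roi_end")])
  if (!identical(got, want)) {
    stop(sprintf(
      "reference fails anchor validation: positions %d/%d/%d are %s, expected %s",
      roi_start, site, roi_end, paste(got, collapse = "/"),
      paste(want, collapse = "/")))
  }
  structure(list(reference_id = as.character(reference_id),
                 reference_peptide = reference_peptide,
                 roi_start = roi_start, site = site, roi_end = roi_end,
                 expected_residues = expected_residues),
            class = "RoiSpec")
}

#' Filter Pol I candidate ORFs by hit significance and peptide length
#'
#' Keeps peptides with at least one qualifying hit against the polymerase
#' reference set (E-value at most `max_evalue`, inclusive) and a length of
#' at least `min_length` amino acids (inclusive).
#'
#' @param peptides Named character vector of candidate peptides.
#' @param hits Hit data.frame from the Pol I homology search.
#' @param min_length Minimum peptide length in amino acids (default 100).
#' @param max_evalue E-value cutoff (default 1e-5).
#' @return Character vector of surviving peptide ids, in input order.
#' @export
filter_pola_candidates <- function(peptides, hits, min_length = 100L,
                                   max_evalue = 1e-5) {
  hit_ok <- unique(hits$query_id[hits$evalue <= max_evalue])
  ids <- names(peptides)
  ids[nchar(peptides) >= min_length & ids %in% hit_ok]
}

# BLOSUM62 from Biostrings, cached per session.
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.encode_aa <- function(x, alphabet) {
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(idx)) {
    # fold rare/ambiguous letters onto X rather than failing the alignment
    idx[is.na(idx)] <- match("X", alphabet)
  }
  idx
}

#' Align a peptide to the reference polymerase
#'
#' Semi-global (ends-free) pairwise alignment with affine gap penalties:
#' overhangs of either sequence are unpenalized, and every reference
#' position occupies exactly one alignment column, so reference coordinates
#' map directly onto columns. The alignment is deterministic: traceback ties
#' are resolved in a fixed operation order (match/mismatch, then gap in the
#' query, then gap in the reference).
#'
#' @param peptide Non-empty amino-acid string.
#' @param roi A [roi_spec()].
#' @param substitution_matrix Substitution matrix (default BLOSUM62 from
#'   Biostrings).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`. Defaults 11 and 1 (the BLASTp defaults).
#' @return A list of class `pola_alignment` with elements `ref` and `query`
#'   (equal-length gapped strings, `-` for gaps), `score`, and the column
#'   index of each reference position (`ref_columns`).
#' @export
align_to_reference <- function(peptide, roi, substitution_matrix = NULL,
                               gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(roi, "RoiSpec"))
  peptide <- toupper(peptide)
  if (!nzchar(peptide)) stop("empty peptide")
  sub <- substitution_matrix %||% .blosum62()
  alphabet <- rownames(sub)
  r <- .encode_aa(roi$reference_peptide, alphabet)
  q <- .encode_aa(peptide, alphabet)
  aln <- semiglobal_align_cpp(r, q, sub, gap_open, gap_extend)
  rchars <- strsplit(roi$reference_peptide, "", fixed = TRUE)[[1]]
  qchars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  ref_row <- ifelse(aln$ref_idx == 0L, "-", rchars[pmax(aln$ref_idx, 1L)])
  qry_row <- ifelse(aln$qry_idx == 0L, "-", qchars[pmax(aln$qry_idx, 1L)])
  structure(list(ref = paste(ref_row, collapse = ""),
                 query = paste(qry_row, collapse = ""),
                 score = aln$score,
                 ref_columns = match(seq_along(rchars), aln$ref_idx)),
            class = "pola_alignment")
}

#' Query residue aligned at a reference position
#'
#' @param alignment A [align_to_reference()] result.
#' @param position 1-based reference position.
#' @return Single character: the query residue in the column carrying the
#'   reference's `position`-th residue, or `"-"` when the query is gapped
#'   there.
#' @export
residue_at_reference_position <- function(alignment, position) {
  stopifnot(inherits(alignment, "pola_alignment"))
  position <- as.integer(position)
  if (position < 1L || position > length(alignment$ref_columns)) {
    stop("reference position out of range: ", position)
  }
  substring(alignment$query, alignment$ref_columns[position],
            alignment$ref_columns[position])
}

#' Does an aligned peptide span the region of interest?
#'
#' True iff the query carries non-gap residues in the columns of both ROI
#' endpoints (reference positions `roi_start` and `roi_end`).
#'
#' @param alignment A [align_to_reference()] result.
#' @param roi A [roi_spec()].
#' @return Logical.
#' @export
spans_roi <- function(alignment, roi) {
  residue_at_reference_position(alignment, roi$roi_start) != "-" &&
    residue_at_reference_position(alignment, roi$roi_end) != "-"
}

#' Classify phage lifestyle from the residue at the 762 site
#'
#' Phe (F) or Tyr (Y) map to `"virulent"`, Leu (L) to `"temperate"`, and
#' anything else — another residue, an ambiguity code, or a gap — to
#' `"unclassified"`.
#'
#' @param residue Single character (amino acid or `"-"`).
#' @return `"virulent"`, `"temperate"` or `"unclassified"`.
#' @export
classify_lifestyle <- function(residue) {
  stopifnot(is.character(residue), nchar(residue) == 1L)
  switch(toupper(residue),
         F = "virulent", Y = "virulent", L = "temperate", "unclassified")
}

#' Classify a set of Pol I peptides
#'
#' Aligns each peptide to the reference, tests ROI spanning, reads the
#' residue at the classification site and calls the lifestyle. Lifestyle is
#' only defined for spanning peptides; non-spanning peptides get `NA`.
#'
#' @param peptides Named character vector of peptides (already filtered; see
#'   [filter_pola_candidates()]).
#' @param roi A [roi_spec()].
#' @param abundances Optional named numeric vector of normalized abundance
#'   per peptide id.
#' @param ... Passed to [align_to_reference()].
#' @return data.frame (orf_id, peptide_length, spans_roi, residue_762,
#'   lifestyle, normalized_abundance) with the per-peptide alignments
#'   attached as attribute `"alignments"`.
#' @export
classify_pola <- function(peptides, roi, abundances = NULL, ...) {
  alns <- lapply(peptides, align_to_reference, roi = roi, ...)
  span <- vapply(alns, spans_roi, logical(1), roi = roi)
  res <- vapply(alns, residue_at_reference_position, character(1),
                position = roi$site)
  out <- data.frame(
    orf_id = names(peptides),
    peptide_length = nchar(peptides),
    spans_roi = unname(span),
    residue_762 = unname(res),
    lifestyle = ifelse(span, vapply(res, classify_lifestyle, character(1)),
                       NA_character_),
    stringsAsFactors = FALSE
  )
  out$normalized_abundance <- if (is.null(abundances)) NA_real_ else
    unname(abundances[out$orf_id])
  rownames(out) <- NULL
  attr(out, "alignments") <- alns
  out
}

#' Summarize Pol I lifestyle classes
#'
#' Counts and total normalized abundance per lifestyle class over the
#' spanning peptides. The three classes partition the spanning set.
#'
#' @param classifications Output of [classify_pola()].
#' @return data.frame with one row per class (virulent, temperate,
#'   unclassified): n and total_abundance.
#' @export
summarize_pola <- function(classifications) {
  sp <- classifications[classifications$spans_roi, , drop = FALSE]
  classes <- c("virulent", "temperate", "unclassified")
  data.frame(
    lifestyle = classes,
    n = vapply(classes, function(cl) sum(sp$lifestyle == cl), integer(1)),
    total_abundance = vapply(classes, function(cl) {
      sum(sp$normalized_abundance[sp$lifestyle == cl], na.rm = TRUE)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Export the ROI-restricted alignment as FASTA
#'
#' Writes, for each spanning peptide, the query residues in the alignment
#' columns of reference positions `roi_start..roi_end` (gaps as `-`), plus
#' the reference ROI itself, for external tree building.
#'
#' @param classifications Output of [classify_pola()] (with its alignment
#'   attribute intact).
#' @param roi A [roi_spec()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_roi_alignment <- function(classifications, roi, path) {
  alns <- attr(classifications, "alignments")
  if (is.null(alns)) stop("classifications carry no alignments")
  keep <- classifications$orf_id[classifications$spans_roi]
  roi_cols <- roi$roi_start:roi$roi_end
  seqs <- vapply(alns[keep], function(a) {
    paste(vapply(roi_cols, function(p) {
      substring(a$query, a$ref_columns[p], a$ref_columns[p])
    }, character(1)), collapse = "")
  }, character(1))
  ref_roi <- substring(roi$reference_peptide, roi$roi_start, roi$roi_end)
  write_fasta(c(setNames(ref_roi, roi$reference_id), seqs), path)
}
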