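# Coverage and Gbp-normalized abundance.
#
# Coverage of a feature is its mean per-base read depth, zero-depth positions
# included. To compare features across samples of differing sequencing
# effort, coverage is divided by the gigabase pairs (Gbp) of reads recruited
# back to the assembly, giving a normalized abundance in coverage per Gbp.

#' Recruitment summary for one sample
#'
#' @param sample_id Sample label.
#' @param total_recruited_bases Total reference-aligned bases of all counted
#'   alignments (see [depth_from_sam()]), in bp.
#' @return A list with `sample_id`, `total_recruited_bases` and `gbp`
#'   (`total_recruited_bases / 1e9`), class `RecruitmentSummary`.
#' @export
recruitment_summary <- function(sample_id, total_recruited_bases) {
  stopifnot(length(total_recruited_bases) == 1L, total_recruited_bases >= 0)
  structure(list(sample_id = as.character(sample_id),
                 total_recruited_bases = as.numeric(total_recruited_bases),
                 gbp = as.numeric(total_recruited_bases) / 1e9),
            class = "RecruitmentSummary")
}

#' Mean per-base coverage of a contig
#'
#' @param profile Integer depth vector over every contig position.
#' @return Mean depth, zero-depth positions included.
#' @export
contig_coverage <- function(profile) {
  if (length(profile) < 1L) stop("empty depth profile")
  if (any(profile < 0)) stop("negative depth")
  sum(as.numeric(profile)) / length(profile)
}

#' Mean coverage of a contig within an ORF's coordinates
#'
#' Strand-independent: only the coordinate window matters.
#'
#' @param profile Integer depth vector for the ORF's contig.
#' @param start,end 1-based inclusive ORF coordinates on the contig.
#' @return Mean depth over positions `start..end`.
#' @export
orf_coverage <- function(profile, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > length(profile) || start > end) {
    stop("ORF coordinates outside contig bounds")
  }
  sum(as.numeric(profile[start:end])) / (end - start + 1L)
}

#' Normalize coverage per gigabase pair of recruited reads
#'
#' @param coverage Non-negative mean depth.
#' @param recruitment A [recruitment_summary()] with `gbp > 0`.
#' @return `coverage / gbp`.
#' @export
normalize_abundance <- function(coverage, recruitment) {
  stopifnot(inherits(recruitment, "RecruitmentSummary"))
  if (any(coverage < 0)) stop("negative coverage")
  if (recruitment$gbp <= 0) {
    stop("empty recruitment: Gbp is zero, normalization undefined")
  }
  coverage / recruitment$gbp
}

#' Log2-transformed normalized abundance
#'
#' Presentational transform used for plotting peptide abundances; the
#' pseudocount keeps zero abundances finite.
#'
#' @param normalized_abundance Non-negative abundance value(s).
#' @param pseudocount Positive offset added before taking logs.
#' @return `log2(normalized_abundance + pseudocount)`.
#' @export
log2_abundance <- function(normalized_abundance, pseudocount) {
  if (any(normalized_abundance < 0)) stop("negative abundance")
  stopifnot(pseudocount > 0)
  log2(normalized_abundance + pseudocount)
}

#' Per-sample abundance table for contigs and ORFs
#'
#' Computes coverage for every contig and (optionally) every ORF window, and
#' normalizes both by the one shared Gbp of the sample's recruitment.
#'
#' @param profiles Named list of depth vectors (one per contig), e.g. from
#'   [depth_from_sam()] or [read_depth()].
#' @param recruitment A [recruitment_summary()].
#' @param orfs Optional ORF data.frame (see [read_orf_table()]).
#' @return data.frame with columns feature_id, feature_kind
#'   (`"contig"`/`"orf"`), coverage, gbp, normalized_abundance.
#' @export
abundance_table <- function(profiles, recruitment, orfs = NULL) {
  cov_c <- vapply(profiles, contig_coverage, numeric(1))
  out <- data.frame(feature_id = names(profiles), feature_kind = "contig",
                    coverage = unname(cov_c), stringsAsFactors = FALSE)
  if (!is.null(orfs) && nrow(orfs) > 0L) {
    missing <- setdiff(orfs$contig_id, names(profiles))
    if (length(missing) > 0L) {
      stop("no depth profile for contig(s): ", paste(missing, collapse = ", "))
    }
    cov_o <- mapply(function(cid, s, e) orf_coverage(profiles[[cid]], s, e),
                    orfs$contig_id, orfs$start, orfs$end)
    out <- rbind(out, data.frame(feature_id = orfs$orf_id, feature_kind = "orf",
                                 coverage = unname(cov_o),
                                 stringsAsFactors = FALSE))
  }
  out$gbp <- recruitment$gbp
  out$normalized_abundance <- normalize_abundance(out$coverage, recruitment)
  rownames(out) <- NULL
  out
}
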