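# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA, SAM, samtools-depth TSV, BLAST tabular (outfmt 6), MetaGene-style
# ORF coordinate tables, and classic OTU tables. All coordinates at these
# interfaces are 1-based inclusive. All readers are deterministic.

#' Read a FASTA file
#'
#' Sequence ids are taken as the header token before the first whitespace;
#' any description is dropped. Sequences are uppercased.
#'
#' @param path Path to a FASTA file (nucleotide or peptide).
#' @return Named character vector of sequences, in file order, named by id.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

# Canonical column names of the twelve BLAST outfmt-6 fields.
.blast6_cols <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "query_start", "query_end",
  "subject_start", "subject_end", "evalue", "bit_score"
)
.blast6_numeric <- c(
  "percent_identity", "alignment_length", "mismatches", "gap_opens",
  "query_start", "query_end", "subject_start", "subject_end",
  "evalue", "bit_score"
)

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' The default schema is the standard twelve-column layout
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Annotation columns appended by the search pipeline are
#' named through `extra`: `"subject_taxid"` (integer NCBI taxid),
#' `"subject_subsystem"` (functional subsystem label) and
#' `"subject_is_viral"` (0/1 flag marking hits against the viral reference).
#'
#' @param path Path to a tab-separated hit file. An empty file yields an
#'   empty table.
#' @param extra Character vector naming annotation columns that follow the
#'   twelve standard columns, in file order.
#' @return A data.frame with one row per hit. `bit_score` and `evalue` are
#'   numeric; `subject_taxid` is integer (`NA` when absent);
#'   `subject_subsystem` is character (`NA` when absent, and the literal
#'   fields `""`, `"-"` and `"NA"` are read as missing); `subject_is_viral`
#'   is logical (`FALSE` when the column is absent).
#' @export
read_tabular_hits <- function(path, extra = character()) {
  stopifnot(file.exists(path))
  ok_extra <- c("subject_taxid", "subject_subsystem", "subject_is_viral")
  if (!all(extra %in% ok_extra)) {
    stop("unknown extra column(s): ", paste(setdiff(extra, ok_extra), collapse = ", "))
  }
  cols <- c(.blast6_cols, extra)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- empty_hits()
  if (length(lines) == 0L) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(cols))
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected %d tab-separated fields, found %d",
                 bad[1], length(cols), nf[bad[1]]))
  }
  mat <- matrix(unlist(parts), ncol = length(cols), byrow = TRUE,
                dimnames = list(NULL, cols))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  for (col in intersect(c(.blast6_numeric, "subject_taxid", "subject_is_viral"), cols)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("", "-", "NA")))
    if (length(bad) > 0L) {
      stop(sprintf("line %d: cannot parse %s value '%s' as a number",
                   bad[1], col, df[bad[1], col]))
    }
    df[[col]] <- v
  }
  if (any(df$bit_score < 0, na.rm = TRUE)) stop("negative bit score")
  if (any(df$evalue < 0, na.rm = TRUE)) stop("negative E-value")
  if (!"subject_taxid" %in% cols) df$subject_taxid <- NA_real_
  df$subject_taxid <- as.integer(df$subject_taxid)
  if (!"subject_subsystem" %in% cols) {
    df$subject_subsystem <- NA_character_
  } else {
    df$subject_subsystem[df$subject_subsystem %in% c("", "-", "NA")] <- NA_character_
  }
  if (!"subject_is_viral" %in% cols) {
    df$subject_is_viral <- FALSE
  } else {
    df$subject_is_viral <- df$subject_is_viral != 0
  }
  df[, c(.blast6_cols, ok_extra)]
}

# Zero-row hit table with the canonical columns.
empty_hits <- function() {
  data.frame(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), alignment_length = numeric(),
    mismatches = numeric(), gap_opens = numeric(),
    query_start = numeric(), query_end = numeric(),
    subject_start = numeric(), subject_end = numeric(),
    evalue = numeric(), bit_score = numeric(),
    subject_taxid = integer(), subject_subsystem = character(),
    subject_is_viral = logical(), stringsAsFactors = FALSE
  )
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' @param hits Hit data.frame as returned by [read_tabular_hits()].
#' @param path Output path.
#' @param extra Annotation columns to append after the twelve standard ones.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path, extra = character()) {
  df <- hits[, c(.blast6_cols, extra), drop = FALSE]
  if ("subject_is_viral" %in% extra) {
    df$subject_is_viral <- as.integer(df$subject_is_viral)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a MetaGene-style ORF coordinate table
#'
#' Five tab-separated columns with a header: orf_id, contig_id, start, end,
#' strand. Coordinates are 1-based inclusive on the contig forward strand.
#'
#' @param path Path to the TSV.
#' @param contig_lengths Optional named integer vector used to validate that
#'   every ORF lies within its contig.
#' @return data.frame with columns orf_id, contig_id, start, end, strand.
#' @export
read_orf_table <- function(path, contig_lengths = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("orf_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("ORF table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyDuplicated(df$orf_id)) {
    stop("duplicate ORF id(s): ",
         paste(unique(df$orf_id[duplicated(df$orf_id)]), collapse = ", "))
  }
  if (any(df$start < 1L) || any(df$start > df$end)) {
    stop("invalid ORF coordinates: require 1 <= start <= end")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(contig_lengths)) {
    missing <- setdiff(df$contig_id, names(contig_lengths))
    if (length(missing) > 0L) {
      stop("ORFs reference unknown contig(s): ", paste(missing, collapse = ", "))
    }
    over <- df$end > contig_lengths[df$contig_id]
    if (any(over)) {
      stop("ORF(s) extend past contig end: ",
           paste(df$orf_id[over], collapse = ", "))
    }
  }
  df
}

#' Read per-base depth in samtools-depth layout
#'
#' Three tab-separated columns without header: contig id, 1-based position,
#' depth. Positions absent from the file (samtools depth omits zero-depth
#' positions by default) are filled with depth 0, and every profile is padded
#' to the full contig length.
#'
#' @param path Path to the depth TSV; may be empty.
#' @param contig_lengths Named integer vector of contig lengths covering
#'   every contig referenced in the file. A profile is returned for every
#'   contig named here, all-zero when the file has no rows for it.
#' @return Named list of integer depth vectors, one per contig, each of the
#'   contig's full length.
#' @export
read_depth <- function(path, contig_lengths) {
  stopifnot(file.exists(path), is.numeric(contig_lengths),
            !is.null(names(contig_lengths)), all(contig_lengths >= 1))
  profiles <- lapply(contig_lengths, function(L) integer(L))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L)) {
      stop(sprintf("line %d: expected 3 tab-separated fields",
                   which(lengths(parts) != 3L)[1]))
    }
    mat <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
    ctg <- mat[, 1]
    pos <- as.integer(mat[, 2])
    dep <- as.integer(mat[, 3])
    if (anyNA(pos) || anyNA(dep)) stop("non-integer position or depth")
    if (any(dep < 0L)) stop("negative depth")
    unknown <- setdiff(unique(ctg), names(contig_lengths))
    if (length(unknown) > 0L) {
      stop("depth rows for unknown contig(s): ", paste(unknown, collapse = ", "))
    }
    if (any(pos < 1L) || any(pos > contig_lengths[ctg])) {
      stop("depth position outside contig bounds")
    }
    for (cid in unique(ctg)) {
      sel <- ctg == cid
      profiles[[cid]][pos[sel]] <- dep[sel]
    }
  }
  profiles
}

#' Write depth profiles in samtools-depth layout
#'
#' Zero-depth positions are omitted, matching `samtools depth` defaults.
#'
#' @param profiles Named list of integer depth vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in names(profiles)) {
    d <- profiles[[cid]]
    nz <- which(d > 0L)
    if (length(nz) > 0L) {
      writeLines(paste(cid, nz, d[nz], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Compute depth profiles and recruited bases from a SAM file
#'
#' Only primary, mapped alignments are counted: unmapped reads and
#' secondary/supplementary alignments contribute nothing, so each recruited
#' read is counted exactly once. Depth at a position is the number of counted
#' alignments whose reference-consuming CIGAR operations cover it, and the
#' recruited-base total is the sum of reference-aligned widths over counted
#' alignments (soft-clipped bases are excluded).
#'
#' @param path Path to a SAM file with an `@SQ` header for every contig.
#' @param contig_lengths Optional named integer vector; when supplied it must
#'   agree with the SAM header, and any aligned contig missing from it is an
#'   error.
#' @param bases How to count recruited bases: `"aligned"` (default) sums
#'   reference-aligned widths, so soft-clipped bases do not inflate the
#'   normalization denominator; `"read"` sums full read lengths.
#' @return A list with `profiles` (named list of integer depth vectors,
#'   padded to full contig length) and `total_recruited_bases` (numeric).
#' @export
depth_from_sam <- function(path, contig_lengths = NULL,
                           bases = c("aligned", "read")) {
  bases <- match.arg(bases)
  stopifnot(file.exists(path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (length(hdr) == 0L) stop("SAM file has no @SQ header lines")
  if (!is.null(contig_lengths)) {
    missing <- setdiff(names(hdr), names(contig_lengths))
    if (length(missing) > 0L) {
      stop("SAM header contig(s) absent from contig_lengths: ",
           paste(missing, collapse = ", "))
    }
    if (!all(contig_lengths[names(hdr)] == hdr)) {
      stop("contig_lengths disagree with SAM header lengths")
    }
  } else {
    contig_lengths <- hdr
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flags))
  cov <- GenomicAlignments::coverage(gal)
  profiles <- lapply(setNames(nm = names(contig_lengths)), function(cid) {
    L <- as.integer(contig_lengths[[cid]])
    if (cid %in% names(cov)) {
      d <- as.integer(cov[[cid]])
      length(d) <- L
      d[is.na(d)] <- 0L
      d
    } else {
      integer(L)
    }
  })
  cig <- GenomicAlignments::cigar(gal)
  total <- if (bases == "aligned") {
    sum(as.numeric(GenomicAlignments::cigarWidthAlongReferenceSpace(cig)))
  } else {
    sum(as.numeric(GenomicAlignments::cigarWidthAlongQuerySpace(cig)))
  }
  list(profiles = profiles, total_recruited_bases = total)
}

#' Construct an OTU table
#'
#' @param counts Integer matrix of counts, OTUs as rows, samples as columns,
#'   with row and column names.
#' @param taxonomy Character vector of lineage strings, one per OTU, named by
#'   OTU id (or unnamed and in row order).
#' @return An object of class `OtuTable`: a list with `counts` and
#'   `taxonomy`.
#' @export
OtuTable <- function(counts, taxonomy) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate OTU id(s)")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample id(s)")
  if (any(counts < 0)) stop("negative count(s)")
  if (any(counts != round(counts))) stop("non-integer count(s)")
  storage.mode(counts) <- "integer"
  if (is.null(names(taxonomy))) {
    stopifnot(length(taxonomy) == nrow(counts))
    names(taxonomy) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(taxonomy))) {
    stop("taxonomy missing for some OTU(s)")
  }
  structure(list(counts = counts, taxonomy = taxonomy[rownames(counts)]),
            class = "OtuTable")
}

#' @export
print.OtuTable <- function(x, ...) {
  cat(sprintf("OtuTable: %d OTUs x %d samples, %d reads total\n",
              nrow(x$counts), ncol(x$counts), sum(as.numeric(x$counts))))
  invisible(x)
}

#' Read a classic OTU table
#'
#' Tab-separated, one header line: first column the OTU id, then one column
#' per sample, and a final `taxonomy` column holding the lineage string.
#'
#' @param path Path to the TSV.
#' @return An [OtuTable()].
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "")
  if (ncol(df) < 3L) stop("OTU table needs id, >=1 sample, and taxonomy columns")
  if (tolower(names(df)[ncol(df)]) != "taxonomy") {
    stop("last column of the OTU table must be 'taxonomy'")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate OTU id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sample_cols <- names(df)[-c(1L, ncol(df))]
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  if (any(is.na(suppressWarnings(as.numeric(counts)))) ||
      any(as.numeric(counts) != round(as.numeric(counts)))) {
    stop("non-integer count in OTU table")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- ids
  OtuTable(counts, setNames(as.character(df[[ncol(df)]]), ids))
}

#' Write an OTU table in classic layout
#'
#' @param table An [OtuTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "OtuTable"))
  df <- data.frame(otu_id = rownames(table$counts), table$counts,
                   taxonomy = unname(table$taxonomy),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
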