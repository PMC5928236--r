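# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

rand_peptide <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Small reference satisfying the ROI anchor contract at arbitrary positions,
# so alignment tests stay fast.
toy_roi <- function(len = 60L, roi_start = 10L, site = 25L, roi_end = 40L) {
  ref <- strsplit(rand_peptide(len), "", fixed = TRUE)[[1]]
  ref[roi_start] <- "I"; ref[site] <- "F"; ref[roi_end] <- "N"
  roi_spec("toy_ref", paste(ref, collapse = ""), roi_start = roi_start,
           site = site, roi_end = roi_end)
}

# Hit-table rows in the canonical layout, from the fields that matter.
make_hits <- function(query_id, bit_score, evalue = 1e-10,
                      subject_taxid = NA_integer_,
                      subject_subsystem = NA_character_,
                      subject_is_viral = FALSE, subject_id = "subj") {
  n <- max(lengths(list(query_id, bit_score, evalue, subject_taxid)))
  data.frame(
    query_id = rep_len(query_id, n), subject_id = rep_len(subject_id, n),
    percent_identity = 90, alignment_length = 100, mismatches = 0,
    gap_opens = 0, query_start = 1, query_end = 100, subject_start = 1,
    subject_end = 100, evalue = rep_len(evalue, n),
    bit_score = rep_len(bit_score, n),
    subject_taxid = rep_len(as.integer(subject_taxid), n),
    subject_subsystem = rep_len(subject_subsystem, n),
    subject_is_viral = rep_len(subject_is_viral, n),
    stringsAsFactors = FALSE
  )
}

make_orfs <- function(orf_id, contig_id, start = 1L, end = 300L,
                      strand = "+") {
  n <- max(lengths(list(orf_id, contig_id, start, end)))
  data.frame(orf_id = rep_len(orf_id, n), contig_id = rep_len(contig_id, n),
             start = rep_len(as.integer(start), n),
             end = rep_len(as.integer(end), n),
             strand = rep_len(strand, n), stringsAsFactors = FALSE)
}

# Random OtuTable with placeholder lineages.
random_otu_table <- function(n_otu = 20L, n_sample = 5L, lambda = 30) {
  counts <- matrix(stats::rpois(n_otu * n_sample, lambda), n_otu, n_sample,
                   dimnames = list(sprintf("otu%03d", seq_len(n_otu)),
                                   sprintf("s%02d", seq_len(n_sample))))
  tax <- sprintf("k__Bacteria; p__P%d; c__C; o__O; f__F; g__G%d; s__",
                 seq_len(n_otu) %% 3L + 1L, seq_len(n_otu) %% 5L + 1L)
  OtuTable(counts, setNames(tax, rownames(counts)))
}

# Minimal SAM writer: reads given as (contig, pos, cigar, seq, flag).
write_sam <- function(path, contig_lengths, reads) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     contig_lengths))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (bitwAnd(r$flag, 4L) > 0L) {
      lines <- c(lines, paste(sprintf("r%04d", i), r$flag, "*", 0, 0,
                              "*", "*", 0, 0, r$seq, "*", sep = "\t"))
    } else {
      lines <- c(lines, paste(sprintf("r%04d", i), r$flag, r$contig, r$pos,
                              42, r$cigar, "*", 0, 0, r$seq, "*", sep = "\t"))
    }
  }
  writeLines(lines, path)
  path
}

# Reference-consumed width of a simple CIGAR (M/I/D/S/=/X operations).
cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDSX=]", cigar))[[1]]
  n <- as.integer(sub("[MIDSX=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "=", "X")])
}
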