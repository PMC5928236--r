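# ORF functional-subsystem assignment by maximum summed bit score, the
# viral-hit restriction, and rollups to top-level functional categories.

#' Assign one ORF to a functional subsystem
#'
#' Bit scores of the ORF's subsystem-labeled hits are summed per subsystem;
#' the subsystem with the maximum sum wins. Ties are broken toward the
#' lexicographically first label and flagged. Hits without a subsystem label
#' are ignored; with no qualifying hits the ORF is unassigned.
#'
#' @param hits_for_orf Hit data.frame restricted to one ORF, already
#'   E-value filtered.
#' @return One-row data.frame: subsystem (`NA` when unassigned),
#'   sum_bit_score, tie.
#' @export
assign_orf_subsystem <- function(hits_for_orf) {
  h <- hits_for_orf[!is.na(hits_for_orf$subject_subsystem), , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(subsystem = NA_character_, sum_bit_score = 0,
                      tie = FALSE, stringsAsFactors = FALSE))
  }
  sums <- rowsum(h$bit_score, group = h$subject_subsystem)  # sorted by label
  mx <- max(sums[, 1L])
  winners <- rownames(sums)[sums[, 1L] == mx]
  data.frame(subsystem = winners[1], sum_bit_score = mx,
             tie = length(winners) > 1L, stringsAsFactors = FALSE)
}

#' Assign subsystems for every ORF in a hit table
#'
#' @param hits E-value-filtered hit data.frame for any number of ORFs.
#' @param orf_ids ORF universe; ORFs without hits are reported unassigned.
#'   Defaults to the ORFs present in `hits`.
#' @param hierarchy Optional two-column data.frame (subsystem, category)
#'   mapping each subsystem to its top-level functional category; adds a
#'   `category` column (`NA` for subsystems absent from the hierarchy).
#' @return data.frame with columns orf_id, subsystem, category (if a
#'   hierarchy was given), sum_bit_score, tie.
#' @export
assign_orf_subsystems <- function(hits, orf_ids = NULL, hierarchy = NULL) {
  orf_ids <- orf_ids %||% unique(hits$query_id)
  rows <- lapply(orf_ids, function(oid) {
    assign_orf_subsystem(hits[hits$query_id == oid, , drop = FALSE])
  })
  out <- cbind(data.frame(orf_id = orf_ids, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  if (!is.null(hierarchy)) {
    stopifnot(all(c("subsystem", "category") %in% names(hierarchy)))
    out$category <- hierarchy$category[match(out$subsystem, hierarchy$subsystem)]
    out <- out[, c("orf_id", "subsystem", "category", "sum_bit_score", "tie")]
  }
  out
}

#' Restrict subsystem assignments to viral-supported functions
#'
#' Only functions associated with viral hits are retained. In `"strict"`
#' mode the per-subsystem sums are recomputed over viral-subject hits only
#' and the winner re-derived, so cellular homologs cannot contribute; in
#' `"lenient"` mode an ORF keeps its original assignment provided at least
#' one hit contributing to the winning subsystem has a viral subject.
#'
#' @param assignments Output of [assign_orf_subsystems()].
#' @param hits The hit table the assignments were derived from (with its
#'   `subject_is_viral` flags).
#' @param mode `"strict"` (default) or `"lenient"`.
#' @param hierarchy Optional hierarchy for re-deriving categories in strict
#'   mode.
#' @return Assignments of the same shape; ORFs failing the restriction
#'   become unassigned rows.
#' @export
restrict_to_viral <- function(assignments, hits, mode = c("strict", "lenient"),
                              hierarchy = NULL) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    return(assign_orf_subsystems(
      hits[hits$subject_is_viral, , drop = FALSE],
      orf_ids = assignments$orf_id, hierarchy = hierarchy))
  }
  keep <- vapply(seq_len(nrow(assignments)), function(k) {
    s <- assignments$subsystem[k]
    if (is.na(s)) return(FALSE)
    any(hits$query_id == assignments$orf_id[k] &
          !is.na(hits$subject_subsystem) & hits$subject_subsystem == s &
          hits$subject_is_viral)
  }, logical(1))
  out <- assignments
  out$subsystem[!keep] <- NA_character_
  out$sum_bit_score[!keep] <- 0
  out$tie[!keep] <- FALSE
  if ("category" %in% names(out)) out$category[!keep] <- NA_character_
  out
}

#' Roll ORF abundance up to functional categories
#'
#' @param assignments Subsystem assignments carrying a `category` column;
#'   unassigned ORFs are skipped. Assigned ORFs whose subsystem has no
#'   category fall under `"uncategorized"`.
#' @param orf_abundances Named numeric vector of normalized abundance per
#'   ORF, or an [abundance_table()] data.frame (orf rows are used).
#' @return data.frame with columns category, abundance, fraction; fractions
#'   are over the assigned ORF mass and sum to 1.
#' @export
rollup_function_abundance <- function(assignments, orf_abundances) {
  if (is.data.frame(orf_abundances)) {
    ab <- orf_abundances[orf_abundances$feature_kind == "orf", ]
    orf_abundances <- setNames(ab$normalized_abundance, ab$feature_id)
  }
  asg <- assignments[!is.na(assignments$subsystem), , drop = FALSE]
  if (nrow(asg) == 0L) {
    return(data.frame(category = character(), abundance = numeric(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  missing <- setdiff(asg$orf_id, names(orf_abundances))
  if (length(missing) > 0L) {
    stop("missing abundance for ORF(s): ", paste(missing, collapse = ", "))
  }
  cat <- if ("category" %in% names(asg)) asg$category else asg$subsystem
  cat[is.na(cat)] <- "uncategorized"
  agg <- rowsum(as.numeric(orf_abundances[asg$orf_id]), group = cat)
  out <- data.frame(category = rownames(agg), abundance = agg[, 1L],
                    stringsAsFactors = FALSE)
  out$fraction <- if (sum(out$abundance) > 0) out$abundance / sum(out$abundance) else 0
  rownames(out) <- NULL
  out[order(-out$abundance), ]
}
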