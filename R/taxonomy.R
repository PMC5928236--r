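# Contig taxonomy by the maximum-sum-bit-score rule.
#
# Every qualifying homology hit of every ORF on a contig contributes its bit
# score to the hit's subject taxid; the taxid with the largest per-contig sum
# is assigned to the contig. Lineage walks over a user-supplied nodes table
# support the viral/non-viral split and rank-level abundance rollups.

#' Build a taxonomy map from a nodes table
#'
#' @param nodes data.frame with columns taxid, parent_taxid, rank, name.
#'   Root nodes are their own parent (NCBI convention).
#' @param viral_roots Integer vector of taxids whose subtrees are viral
#'   (e.g. 10239, the Viruses superkingdom).
#' @return An object of class `TaxonomyMap`.
#' @export
taxonomy_map <- function(nodes, viral_roots = integer()) {
  need <- c("taxid", "parent_taxid", "rank", "name")
  stopifnot(all(need %in% names(nodes)))
  taxid <- as.integer(nodes$taxid)
  parent <- as.integer(nodes$parent_taxid)
  if (anyDuplicated(taxid)) stop("duplicate taxid in nodes table")
  if (!all(parent %in% taxid)) stop("parent taxid(s) missing from nodes table")
  idx <- setNames(seq_along(taxid), taxid)
  # every parent chain must terminate at a self-parent root, without cycles
  for (start in seq_along(taxid)) {
    seen <- integer()
    i <- start
    repeat {
      p <- idx[[as.character(parent[i])]]
      if (p == i) break
      if (p %in% seen) stop("cycle in taxonomy parent links at taxid ", taxid[i])
      seen <- c(seen, i)
      i <- p
      if (length(seen) > length(taxid)) stop("unterminated parent chain")
    }
  }
  viral_roots <- as.integer(viral_roots)
  if (!all(viral_roots %in% taxid)) stop("viral root(s) missing from nodes table")
  structure(list(taxid = taxid, parent = parent,
                 rank = as.character(nodes$rank),
                 name = as.character(nodes$name),
                 idx = idx, viral_roots = viral_roots),
            class = "TaxonomyMap")
}

#' Read a taxonomy nodes table from TSV
#'
#' Header line plus columns taxid, parent_taxid, rank, name.
#'
#' @param path Path to the TSV.
#' @param viral_roots Viral root taxids, passed to [taxonomy_map()].
#' @return A `TaxonomyMap`.
#' @export
read_taxonomy_nodes <- function(path, viral_roots = integer()) {
  taxonomy_map(read.delim(path, stringsAsFactors = FALSE), viral_roots)
}

# Indices of taxid's ancestor path (self first, root last).
.lineage_idx <- function(taxmap, taxid) {
  i <- unname(taxmap$idx[as.character(taxid)])
  if (is.na(i)) stop("unknown taxid: ", taxid)
  path <- i
  repeat {
    p <- taxmap$idx[[as.character(taxmap$parent[i])]]
    if (p == i) break
    path <- c(path, p)
    i <- p
  }
  path
}

#' Test whether a taxid lies in a viral subtree
#'
#' @param taxid Integer taxid present in the map.
#' @param taxmap A [taxonomy_map()].
#' @return `TRUE` iff walking parent links from `taxid` reaches one of the
#'   map's designated viral roots.
#' @export
is_viral <- function(taxid, taxmap) {
  stopifnot(inherits(taxmap, "TaxonomyMap"))
  any(taxmap$taxid[.lineage_idx(taxmap, taxid)] %in% taxmap$viral_roots)
}

#' Ancestor of a taxid at a given rank
#'
#' @param taxid Integer taxid.
#' @param taxmap A [taxonomy_map()].
#' @param rank Rank label, e.g. `"family"`.
#' @return The taxid of the ancestor (or self) whose rank equals `rank`, or
#'   `NA` when no ancestor carries that rank.
#' @export
taxon_at_rank <- function(taxid, taxmap, rank) {
  path <- .lineage_idx(taxmap, taxid)
  hit <- path[taxmap$rank[path] == rank]
  if (length(hit) == 0L) NA_integer_ else taxmap$taxid[hit[1]]
}

#' Human-readable lineage string for a taxid
#'
#' @inheritParams taxon_at_rank
#' @return Semicolon-delimited names, root first.
#' @export
taxon_lineage <- function(taxid, taxmap) {
  paste(rev(taxmap$name[.lineage_idx(taxmap, taxid)]), collapse = ";")
}

#' Filter hits by E-value
#'
#' The cutoff is inclusive: a hit at exactly `max_evalue` is kept.
#'
#' @param hits Hit data.frame (see [read_tabular_hits()]).
#' @param max_evalue Positive E-value cutoff; 1e-3 is the default used for
#'   subsystem searches.
#' @return The qualifying hits in their original order.
#' @export
filter_hits <- function(hits, max_evalue = 1e-3) {
  stopifnot(max_evalue > 0)
  hits[hits$evalue <= max_evalue, , drop = FALSE]
}

#' Assign contig taxonomy by maximum summed bit score
#'
#' For each contig, the bit scores of all its ORFs' taxid-annotated hits are
#' summed per taxid and the taxid with the maximum sum wins. Ties (two or
#' more taxids sharing the maximum sum) are broken toward the numerically
#' smallest taxid and flagged. Contigs whose ORFs have no qualifying hits
#' get `NA` taxid. Hits should already be E-value filtered (see
#' [filter_hits()]); hits without a subject taxid are ignored.
#'
#' @param orfs ORF data.frame mapping ORF ids to contigs
#'   (see [read_orf_table()]).
#' @param hits Hit data.frame; every `query_id` must be a known ORF.
#' @param taxmap Optional [taxonomy_map()]; when supplied, an `is_viral`
#'   column is added.
#' @param best_hit_only If `TRUE`, only each ORF's single best hit (highest
#'   bit score; ties toward the smaller taxid) enters the sums — a
#'   sensitivity-analysis mode. Default sums every hit.
#' @return data.frame with one row per contig: contig_id, taxid,
#'   sum_bit_score, tie, and optionally is_viral.
#' @export
assign_contig_taxonomy <- function(orfs, hits, taxmap = NULL,
                                   best_hit_only = FALSE) {
  contigs <- unique(orfs$contig_id)
  hits <- hits[!is.na(hits$subject_taxid), , drop = FALSE]
  unknown <- setdiff(hits$query_id, orfs$orf_id)
  if (length(unknown) > 0L) {
    stop("hit(s) reference unknown ORF(s): ", paste(unique(unknown), collapse = ", "))
  }
  if (best_hit_only && nrow(hits) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id), function(i) {
      h <- hits[i, ]
      best <- i[h$bit_score == max(h$bit_score)]
      best[order(hits$subject_taxid[best])][1]
    }), use.names = FALSE)
    hits <- hits[sort(keep), , drop = FALSE]
  }
  orf2ctg <- setNames(orfs$contig_id, orfs$orf_id)
  out <- data.frame(contig_id = contigs, taxid = NA_integer_,
                    sum_bit_score = 0, tie = FALSE, stringsAsFactors = FALSE)
  if (nrow(hits) > 0L) {
    sums <- rowsum(hits$bit_score,
                   group = paste(orf2ctg[hits$query_id], hits$subject_taxid,
                                 sep = "\r"))
    key <- strsplit(rownames(sums), "\r", fixed = TRUE)
    ctg <- vapply(key, `[`, character(1), 1L)
    tid <- as.integer(vapply(key, `[`, character(1), 2L))
    for (k in seq_len(nrow(out))) {
      sel <- which(ctg == out$contig_id[k])
      if (length(sel) == 0L) next
      s <- sums[sel, 1L]
      mx <- max(s)
      winners <- tid[sel][s == mx]
      out$taxid[k] <- min(winners)
      out$sum_bit_score[k] <- mx
      out$tie[k] <- length(winners) > 1L
    }
  }
  if (!is.null(taxmap)) {
    out$is_viral <- vapply(out$taxid, function(t) {
      if (is.na(t)) NA else is_viral(t, taxmap)
    }, logical(1))
  }
  out
}

#' Roll contig abundance up to a taxonomic rank
#'
#' Sums normalized abundance per ancestor group at the requested rank.
#' Unassigned contigs (no qualifying hits) are reported as a single
#' `"no known homolog"` group; assigned contigs whose lineage carries no
#' node at the requested rank are grouped under their own taxon name
#' prefixed `"unclassified"`. Fractions are over the total mass
#' (assigned + unassigned).
#'
#' @param assignments Output of [assign_contig_taxonomy()].
#' @param contig_abundances Named numeric vector of normalized abundance per
#'   contig, or an [abundance_table()] data.frame (contig rows are used).
#' @param taxmap A [taxonomy_map()].
#' @param rank Rank to roll up to (default `"family"`).
#' @return data.frame with columns group, taxid (NA for unassigned/
#'   unclassified groups), is_viral, abundance, fraction.
#' @export
rollup_taxon_abundance <- function(assignments, contig_abundances, taxmap,
                                   rank = "family") {
  if (is.data.frame(contig_abundances)) {
    ab <- contig_abundances[contig_abundances$feature_kind == "contig", ]
    contig_abundances <- setNames(ab$normalized_abundance, ab$feature_id)
  }
  missing <- setdiff(assignments$contig_id, names(contig_abundances))
  if (length(missing) > 0L) {
    stop("missing abundance for contig(s): ", paste(missing, collapse = ", "))
  }
  a <- contig_abundances[assignments$contig_id]
  grp_tax <- rep(NA_integer_, nrow(assignments))
  label <- character(nrow(assignments))
  viral <- logical(nrow(assignments))
  for (k in seq_len(nrow(assignments))) {
    t <- assignments$taxid[k]
    if (is.na(t)) {
      label[k] <- "no known homolog"
    } else {
      g <- taxon_at_rank(t, taxmap, rank)
      viral[k] <- is_viral(t, taxmap)
      if (is.na(g)) {
        label[k] <- paste("unclassified",
                          taxmap$name[taxmap$idx[[as.character(t)]]])
      } else {
        grp_tax[k] <- g
        label[k] <- taxmap$name[taxmap$idx[[as.character(g)]]]
      }
    }
  }
  agg <- rowsum(as.numeric(a), group = label)
  out <- data.frame(group = rownames(agg), abundance = agg[, 1L],
                    stringsAsFactors = FALSE)
  out$taxid <- grp_tax[match(out$group, label)]
  out$is_viral <- viral[match(out$group, label)]
  out$is_viral[out$group == "no known homolog"] <- NA
  total <- sum(out$abundance)
  out$fraction <- if (total > 0) out$abundance / total else 0
  rownames(out) <- NULL
  out[order(-out$abundance), c("group", "taxid", "is_viral", "abundance", "fraction")]
}

#' Assigned-taxonomy summary over contig count and abundance mass
#'
#' Reports the percentage of contigs with an assignment, and of assigned
#' mass that is viral, both by contig count and by abundance.
#'
#' @inheritParams rollup_taxon_abundance
#' @return One-row data.frame: pct_assigned_by_count, pct_assigned_by_mass,
#'   pct_viral_of_assigned_by_count, pct_viral_of_assigned_by_mass.
#' @export
assignment_summary <- function(assignments, contig_abundances, taxmap) {
  if (is.data.frame(contig_abundances)) {
    ab <- contig_abundances[contig_abundances$feature_kind == "contig", ]
    contig_abundances <- setNames(ab$normalized_abundance, ab$feature_id)
  }
  a <- contig_abundances[assignments$contig_id]
  assigned <- !is.na(assignments$taxid)
  viral <- vapply(assignments$taxid[assigned],
                  function(t) is_viral(t, taxmap), logical(1))
  data.frame(
    pct_assigned_by_count = 100 * mean(assigned),
    pct_assigned_by_mass = 100 * sum(a[assigned]) / sum(a),
    pct_viral_of_assigned_by_count = 100 * mean(viral),
    pct_viral_of_assigned_by_mass =
      100 * sum(a[assigned][viral]) / sum(a[assigned])
  )
}
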