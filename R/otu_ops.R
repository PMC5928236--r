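# OTU-table operations: relative abundance, taxonomic collapse, the >1%
# display filter, rarefaction, alpha diversity, Bray-Curtis dissimilarity,
# and core-OTU set algebra between sample groups.

.check_otu <- function(table) {
  stopifnot(inherits(table, "OtuTable"))
  table
}

#' Per-sample relative abundance
#'
#' @param table An [OtuTable()]; every sample must have a positive total.
#' @return Numeric matrix of fractions (OTUs x samples); each column sums
#'   to 1.
#' @export
relative_abundance <- function(table) {
  .check_otu(table)
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(table$counts)[totals == 0], collapse = ", "))
  }
  sweep(table$counts, 2L, totals, "/")
}

# Split a lineage string on its rank delimiter (';', optionally padded).
.split_lineage <- function(lineage, otu_id) {
  fields <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  if (length(fields) == 0L || !nzchar(fields[1])) {
    stop("malformed lineage for OTU ", otu_id, ": '", lineage, "'")
  }
  fields
}

# TRUE when a lineage field names a taxon (not an empty rank like "g__").
.named_field <- function(x) nzchar(sub("^[a-z]__", "", x))

#' Collapse an OTU table at a taxonomic rank
#'
#' Counts are summed over OTUs sharing the same lineage prefix of `level`
#' rank fields (QIIME-style levels: 1 = domain ... 6 = genus). OTUs whose
#' lineage is unnamed at the requested rank are grouped under their deepest
#' named ancestor.
#'
#' @param table An [OtuTable()] with rank-delimited (`;`) lineage strings.
#' @param level Number of rank fields to keep.
#' @return An [OtuTable()] whose rows are the collapsed groups; total counts
#'   are conserved.
#' @export
collapse_taxonomy <- function(table, level) {
  .check_otu(table)
  level <- as.integer(level)
  stopifnot(level >= 1L)
  keys <- vapply(rownames(table$counts), function(oid) {
    fields <- .split_lineage(table$taxonomy[[oid]], oid)
    fields <- fields[seq_len(min(level, length(fields)))]
    named <- which(.named_field(fields))
    if (length(named) == 0L) {
      stop("malformed lineage for OTU ", oid, ": no named rank")
    }
    paste(fields[seq_len(max(named))], collapse = ";")
  }, character(1))
  agg <- rowsum(table$counts, group = keys)
  OtuTable(agg, setNames(rownames(agg), rownames(agg)))
}

#' Filter rows by maximum relative abundance
#'
#' Keeps rows whose maximum across samples is strictly greater than the
#' threshold — the "greater than 1% in at least one sample" display filter.
#'
#' @param rel_table Matrix of relative abundances (rows = taxa).
#' @param threshold Fraction; default 0.01.
#' @return The qualifying rows of `rel_table`.
#' @export
filter_max_relabund <- function(rel_table, threshold = 0.01) {
  keep <- apply(rel_table, 1L, max) > threshold
  rel_table[keep, , drop = FALSE]
}

#' Rarefy an OTU table to an even sampling depth
#'
#' Each sample is subsampled uniformly at random without replacement down to
#' exactly `depth` reads. Samples whose total is below `depth` are dropped
#' with a warning naming them.
#'
#' @param table An [OtuTable()].
#' @param depth Positive target depth.
#' @param seed Integer seed fixing the subsample; global RNG state is left
#'   untouched.
#' @return A rarefied [OtuTable()]; every remaining sample sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  .check_otu(table)
  depth <- as.numeric(depth)
  if (depth <= 0) stop("rarefaction depth must be positive")
  totals <- colSums(table$counts)
  drop <- totals < depth
  if (all(drop)) stop("no sample reaches the rarefaction depth")
  if (any(drop)) {
    warning("dropping sample(s) below depth: ",
            paste(colnames(table$counts)[drop], collapse = ", "))
  }
  counts <- table$counts[, !drop, drop = FALSE]
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # transformed data); our inputs are genuine counts, so silence just that
  rar <- withCallingHandlers(
    local_seed(seed, vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  OtuTable(t(rar), table$taxonomy)
}

#' Shannon diversity (bits)
#'
#' `-sum(p_i * log2(p_i))` over OTUs with positive count. Log base 2, so a
#' uniform community of S OTUs scores log2(S).
#'
#' @param counts Non-negative count vector for one sample.
#' @return Shannon index in bits.
#' @export
shannon <- function(counts) {
  if (sum(counts) == 0) stop("all-zero sample")
  unname(vegan::diversity(counts, index = "shannon", base = 2))
}

#' Observed OTU richness
#'
#' @param counts Count vector for one sample.
#' @return Number of OTUs with count > 0.
#' @export
observed_otus <- function(counts) {
  sum(counts > 0)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum|a_i - b_i| / sum(a_i + b_i)`: 0 for identical samples, 1
#' for samples sharing no OTUs.
#'
#' @param table An [OtuTable()] (or a counts matrix, OTUs x samples) with at
#'   least two samples.
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  counts <- if (inherits(table, "OtuTable")) table$counts else table
  if (ncol(counts) < 2L) stop("need at least two samples")
  zero <- colSums(counts) == 0
  if (sum(zero) >= 2L) {
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  as.matrix(vegan::vegdist(t(counts), method = "bray"))
}

#' Core OTUs per sample group, shared and unique
#'
#' A group's core is the set of OTUs present (count > 0, on raw counts) in
#' 100% of the group's samples. The shared core is the intersection of all
#' group cores; a group's unique core is its core minus every other group's
#' core. The phylum breakdown counts OTUs per phylum (second lineage field)
#' within each set.
#'
#' @param table An [OtuTable()].
#' @param groups Named list partitioning the sample ids into groups.
#' @return An object of class `CoreResult`: list with `core_per_group`,
#'   `shared_core`, `unique_core_per_group` (each sets of OTU ids) and
#'   `phylum_breakdown` (data.frame set, phylum, n_otus).
#' @export
core_otus <- function(table, groups) {
  .check_otu(table)
  stopifnot(is.list(groups), !is.null(names(groups)), length(groups) >= 1L)
  all_samples <- unlist(groups, use.names = FALSE)
  if (any(lengths(groups) == 0L)) {
    stop("empty group(s): ", paste(names(groups)[lengths(groups) == 0L],
                                   collapse = ", "))
  }
  if (anyDuplicated(all_samples) ||
      !setequal(all_samples, colnames(table$counts))) {
    stop("groups must partition the table's sample ids")
  }
  present <- table$counts > 0L
  cores <- lapply(groups, function(ids) {
    rownames(present)[rowSums(present[, ids, drop = FALSE]) == length(ids)]
  })
  shared <- Reduce(intersect, cores)
  uniq <- lapply(names(cores), function(g) {
    setdiff(cores[[g]], unlist(cores[setdiff(names(cores), g)], use.names = FALSE))
  })
  names(uniq) <- names(cores)
  phylum_of <- function(ids) {
    vapply(ids, function(oid) {
      fields <- .split_lineage(table$taxonomy[[oid]], oid)
      if (length(fields) >= 2L && .named_field(fields[2])) {
        sub("^[a-z]__", "", fields[2])
      } else "unclassified"
    }, character(1))
  }
  sets <- c(list(shared = shared), setNames(uniq, paste0("unique_", names(uniq))))
  breakdown <- do.call(rbind, lapply(names(sets), function(s) {
    if (length(sets[[s]]) == 0L) return(NULL)
    tab <- base::table(phylum_of(sets[[s]]))
    data.frame(set = s, phylum = names(tab), n_otus = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  structure(list(core_per_group = cores, shared_core = shared,
                 unique_core_per_group = uniq,
                 phylum_breakdown = breakdown %||%
                   data.frame(set = character(), phylum = character(),
                              n_otus = integer(), stringsAsFactors = FALSE)),
            class = "CoreResult")
}

#' @export
print.CoreResult <- function(x, ...) {
  cat(sprintf("CoreResult: %d shared core OTU(s); unique cores: %s\n",
              length(x$shared_core),
              paste(sprintf("%s=%d", names(x$unique_core_per_group),
                            lengths(x$unique_core_per_group)), collapse = ", ")))
  invisible(x)
}
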