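# Seeded synthetic-data generators with planted ground truth.
#
# Three generators emulate the study's data layers without any download:
# a viral community (contigs, reads, depth, homology hits, taxonomy nodes),
# Pol I peptide sets with planted residue-762 states, and OTU tables with
# planted core membership and temporal trends. Outputs are deterministic
# given the spec's seed; all randomness runs through one seeded generator
# scope per call and global RNG state is never touched.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

.rand_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Surrogate Pol I reference peptide
#'
#' A fixed, seeded random peptide of length 1,000 carrying the three anchor
#' residues of the region of interest — Ile at 547, Phe at 762, Asn at
#' 923 — so it satisfies the [roi_spec()] anchor contract without shipping
#' the real E. coli polymerase sequence. Synthetic throughout; identical on
#' every call with the same arguments.
#'
#' @param length Peptide length (default 1000).
#' @param seed Internal seed (fixed default so the reference is a package
#'   constant).
#' @return Amino-acid string.
#' @export
surrogate_pola_reference <- function(length = 1000L, seed = 762001L) {
  stopifnot(length >= 923L)
  pep <- local_seed(seed, .rand_string(length, .AA20))
  substring(pep, 547, 547) <- "I"
  substring(pep, 762, 762) <- "F"
  substring(pep, 923, 923) <- "N"
  pep
}

# ---------------------------------------------------------------- community

#' Specification for a synthetic viral community
#'
#' The default community mirrors the structure the pipeline is built for: a
#' Caudovirales-dominated virome in which Siphoviridae outnumber Myoviridae
#' and then Podoviridae, plus a low-coverage non-viral (bacterial)
#' contaminant, five contigs of 5-20 kb per taxon with planted per-contig
#' coverages {50, 10, 5, 2}.
#'
#' @param seed Integer seed.
#' @param taxa data.frame with columns taxid, name, family, viral,
#'   n_contigs, min_length, max_length, coverage.
#' @param orfs_per_contig ORFs planted per contig.
#' @param decoy_taxid_count Number of decoy taxa every ORF also hits.
#' @param decoy_bitscore_fraction Decoy bit scores as a fraction of the
#'   planted hit's; must be in (0, 1) so the planted taxid always wins the
#'   per-contig bit-score sum.
#' @param read_length Read length in bp for the recruitment simulation.
#' @return A list of class `CommunitySpec`.
#' @export
community_spec <- function(seed = 1L,
                           taxa = NULL,
                           orfs_per_contig = 3L,
                           decoy_taxid_count = 3L,
                           decoy_bitscore_fraction = 0.5,
                           read_length = 100L) {
  taxa <- taxa %||% data.frame(
    taxid = c(1001L, 1002L, 1003L, 2001L),
    name = c("Siphophage pond sp.", "Myophage pond sp.",
             "Podophage pond sp.", "Pondibacter freshwater sp."),
    family = c("Siphoviridae", "Myoviridae", "Podoviridae",
               "Pondibacteraceae"),
    viral = c(TRUE, TRUE, TRUE, FALSE),
    n_contigs = 5L,
    min_length = 5000L, max_length = 20000L,
    coverage = c(50, 10, 5, 2),
    stringsAsFactors = FALSE
  )
  stopifnot(all(taxa$coverage > 0), all(taxa$n_contigs >= 1L),
            decoy_bitscore_fraction > 0, decoy_bitscore_fraction < 1,
            read_length >= 1L)
  if (any(taxa$min_length < read_length)) {
    stop("infeasible spec: contigs may be shorter than a read")
  }
  structure(list(seed = as.integer(seed), taxa = taxa,
                 orfs_per_contig = as.integer(orfs_per_contig),
                 decoy_taxid_count = as.integer(decoy_taxid_count),
                 decoy_bitscore_fraction = decoy_bitscore_fraction,
                 read_length = as.integer(read_length)),
            class = "CommunitySpec")
}

# toy subsystem -> category hierarchy used for planted functional labels
.toy_hierarchy <- function() {
  data.frame(
    subsystem = c("Phage capsid proteins", "Phage tail fiber proteins",
                  "Phage replication", "Phage integration and excision",
                  "Purine conversions", "Pyrimidine conversions",
                  "DNA repair, bacterial"),
    category = c("Phages, Prophages, Transposable elements",
                 "Phages, Prophages, Transposable elements",
                 "Phages, Prophages, Transposable elements",
                 "Phages, Prophages, Transposable elements",
                 "Nucleosides and Nucleotides",
                 "Nucleosides and Nucleotides",
                 "DNA Metabolism"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic viral community
#'
#' Writes, under `out_dir`: contigs FASTA, ORF coordinate TSV and peptide
#' FASTA, a SAM of simulated read recruitments, a samtools-depth-style TSV
#' (computed independently of the SAM reader, by direct interval stabbing
#' over the simulated read placements), a BLAST-tabular hit file with
#' taxid/subsystem/viral-flag annotation columns, a taxonomy nodes TSV, the
#' subsystem hierarchy TSV, and per-contig / per-ORF ground-truth tables.
#'
#' Reads are placed uniformly at random (never overhanging contig ends), so
#' each contig's realized mean depth equals `n_reads * read_length /
#' contig_length`, which matches the planted coverage up to read-count
#' rounding. Hit tables are constructed so the planted taxid's per-contig
#' bit-score sum strictly exceeds every decoy's.
#'
#' @param spec A [community_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with file `paths`, the `truth_contigs` and
#'   `truth_orfs` data.frames, `contig_lengths`, the planted
#'   `total_recruited_bases`, and `viral_root` taxid.
#' @export
generate_community <- function(spec, out_dir) {
  stopifnot(inherits(spec, "CommunitySpec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  local_seed(spec$seed, {
    tx <- spec$taxa
    rl <- spec$read_length
    contigs <- list(); truth <- list()
    k <- 0L
    for (t in seq_len(nrow(tx))) {
      for (j in seq_len(tx$n_contigs[t])) {
        k <- k + 1L
        L <- sample(tx$min_length[t]:tx$max_length[t], 1L)
        cid <- sprintf("contig_%03d", k)
        contigs[[cid]] <- .rand_string(L, c("A", "C", "G", "T"))
        n_reads <- max(1L, as.integer(round(tx$coverage[t] * L / rl)))
        truth[[cid]] <- data.frame(
          contig_id = cid, taxid = tx$taxid[t], family = tx$family[t],
          viral = tx$viral[t], length = L,
          planted_coverage = tx$coverage[t], n_reads = n_reads,
          realized_coverage = n_reads * rl / L, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    lens <- setNames(truth$length, truth$contig_id)

    # --- reads: SAM plus an independently computed depth table
    sam <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
    depth_lines <- character(0)
    for (cid in names(lens)) {
      L <- lens[[cid]]
      n <- truth$n_reads[truth$contig_id == cid]
      starts <- sample.int(L - rl + 1L, n, replace = TRUE)
      seqs <- substring(contigs[[cid]], starts, starts + rl - 1L)
      sam <- c(sam, sprintf("%s_read%05d\t0\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t*",
                            cid, seq_len(n), cid, starts, rl, seqs))
      # brute-force interval stabbing, independent of any SAM machinery
      d <- integer(L)
      for (s in starts) d[s:(s + rl - 1L)] <- d[s:(s + rl - 1L)] + 1L
      nz <- which(d > 0L)
      depth_lines <- c(depth_lines, paste(cid, nz, d[nz], sep = "\t"))
    }

    # --- ORFs: equal blocks per contig, one ORF per block
    hier <- .toy_hierarchy()
    orfs <- list(); peptides <- character(0); orf_truth <- list()
    for (cid in names(lens)) {
      L <- lens[[cid]]
      block <- L %/% spec$orfs_per_contig
      for (b in seq_len(spec$orfs_per_contig)) {
        lo <- (b - 1L) * block + 1L
        len_nt <- 3L * sample(100L:min(300L, (block - 10L) %/% 3L), 1L)
        start <- lo + sample.int(block - len_nt, 1L) - 1L
        oid <- sprintf("%s_orf%d", cid, b)
        ss <- sample(hier$subsystem, 1L)
        orfs[[oid]] <- data.frame(
          orf_id = oid, contig_id = cid, start = start,
          end = start + len_nt - 1L, strand = sample(c("+", "-"), 1L),
          stringsAsFactors = FALSE)
        peptides[oid] <- .rand_string(len_nt %/% 3L, .AA20)
        orf_truth[[oid]] <- data.frame(
          orf_id = oid, contig_id = cid, subsystem = ss,
          category = hier$category[hier$subsystem == ss],
          stringsAsFactors = FALSE)
      }
    }
    orfs <- do.call(rbind, orfs); rownames(orfs) <- NULL
    orf_truth <- do.call(rbind, orf_truth); rownames(orf_truth) <- NULL

    # --- hits: planted taxid/subsystem per ORF plus weaker decoys
    decoys <- 9000L + seq_len(spec$decoy_taxid_count)
    hit_lines <- character(0)
    viral_of <- setNames(truth$viral, truth$contig_id)
    taxid_of <- setNames(truth$taxid, truth$contig_id)
    for (i in seq_len(nrow(orfs))) {
      oid <- orfs$orf_id[i]; cid <- orfs$contig_id[i]
      plen <- nchar(peptides[[oid]])
      B <- round(runif(1, 80, 300), 1)
      ev <- sprintf("1e-%d", sample(10:80, 1L))
      line <- function(subj, pid, e, bs, taxid, ss, viral) {
        paste(oid, subj, pid, plen, 0, 0, 1, plen, 1, plen, e, bs,
              taxid, ss, as.integer(viral), sep = "\t")
      }
      hit_lines <- c(hit_lines, line(
        sprintf("SEED|tax%d", taxid_of[[cid]]), round(runif(1, 60, 99), 1),
        ev, B, taxid_of[[cid]], orf_truth$subsystem[i], viral_of[[cid]]))
      for (d in decoys) {
        # decoys challenge the taxonomy winner rule only; no subsystem label
        hit_lines <- c(hit_lines, line(
          sprintf("SEED|tax%d", d), round(runif(1, 40, 60), 1),
          "1e-8", round(B * spec$decoy_bitscore_fraction, 1), d, "-", FALSE))
      }
    }

    # --- taxonomy nodes
    fam <- unique(tx[, c("family", "viral")])
    fam$taxid <- 5000L + seq_len(nrow(fam))
    nodes <- rbind(
      data.frame(taxid = 1L, parent_taxid = 1L, rank = "no rank",
                 name = "root", stringsAsFactors = FALSE),
      data.frame(taxid = 10239L, parent_taxid = 1L, rank = "superkingdom",
                 name = "Viruses"),
      data.frame(taxid = 2L, parent_taxid = 1L, rank = "superkingdom",
                 name = "Bacteria"),
      data.frame(taxid = 28883L, parent_taxid = 10239L, rank = "order",
                 name = "Caudovirales"),
      data.frame(taxid = fam$taxid,
                 parent_taxid = ifelse(fam$viral, 28883L, 2L),
                 rank = "family", name = fam$family),
      data.frame(taxid = tx$taxid,
                 parent_taxid = fam$taxid[match(tx$family, fam$family)],
                 rank = "species", name = tx$name),
      data.frame(taxid = decoys, parent_taxid = 2L, rank = "species",
                 name = sprintf("Decoy bacterium %d", seq_along(decoys)))
    )

    paths <- list(
      contigs = file.path(out_dir, "contigs.fasta"),
      orfs = file.path(out_dir, "orfs.tsv"),
      orf_peptides = file.path(out_dir, "orfs.faa"),
      sam = file.path(out_dir, "reads.sam"),
      depth = file.path(out_dir, "depth.tsv"),
      hits = file.path(out_dir, "hits.tsv"),
      nodes = file.path(out_dir, "nodes.tsv"),
      hierarchy = file.path(out_dir, "subsystem_hierarchy.tsv"),
      truth_contigs = file.path(out_dir, "truth_contigs.tsv"),
      truth_orfs = file.path(out_dir, "truth_orfs.tsv")
    )
    write_fasta(unlist(contigs), paths$contigs)
    write.table(orfs, paths$orfs, sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(peptides, paths$orf_peptides)
    writeLines(sam, paths$sam)
    writeLines(depth_lines, paths$depth)
    writeLines(hit_lines, paths$hits)
    write.table(nodes, paths$nodes, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(.toy_hierarchy(), paths$hierarchy, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth, paths$truth_contigs, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(orf_truth, paths$truth_orfs, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(paths = paths, truth_contigs = truth,
                   truth_orfs = orf_truth, contig_lengths = lens,
                   total_recruited_bases = sum(as.numeric(truth$n_reads)) * rl,
                   viral_root = 10239L))
  })
}

# ------------------------------------------------------------------- Pol I

#' Specification for a synthetic Pol I peptide set
#'
#' Defaults mirror the class structure a late-season freshwater virome
#' shows: temperate (Leu762) peptides in the majority, then Tyr762, then
#' wildtype Phe762 (184/27/17).
#'
#' @param seed Integer seed.
#' @param n_phe,n_tyr,n_leu,n_other Peptides per planted residue-762 class
#'   (`other` draws a residue outside F/Y/L).
#' @param mutation_rate Per-site substitution probability at non-anchor
#'   sites; at most 0.1 to keep peptides alignable.
#' @param truncation_fraction Fraction of peptides truncated so they do not
#'   span the region of interest.
#' @param reference Reference peptide (default
#'   [surrogate_pola_reference()]).
#' @return A list of class `PolASpec` carrying the [roi_spec()] built from
#'   the reference.
#' @export
pola_spec <- function(seed = 1L, n_phe = 17L, n_tyr = 27L, n_leu = 184L,
                      n_other = 0L, mutation_rate = 0.05,
                      truncation_fraction = 0,
                      reference = surrogate_pola_reference()) {
  stopifnot(n_phe >= 0L, n_tyr >= 0L, n_leu >= 0L, n_other >= 0L,
            n_phe + n_tyr + n_leu + n_other >= 1L,
            mutation_rate >= 0, mutation_rate <= 0.1,
            truncation_fraction >= 0, truncation_fraction <= 1)
  roi <- roi_spec("surrogate_polA", reference)
  structure(list(seed = as.integer(seed), n_phe = as.integer(n_phe),
                 n_tyr = as.integer(n_tyr), n_leu = as.integer(n_leu),
                 n_other = as.integer(n_other),
                 mutation_rate = mutation_rate,
                 truncation_fraction = truncation_fraction,
                 roi = roi),
            class = "PolASpec")
}

#' Generate a synthetic Pol I peptide set
#'
#' Each peptide is a window of the reference covering the region of
#' interest (random flanks), with the planted class residue written at the
#' position homologous to site 762, random substitutions elsewhere at
#' `mutation_rate` (anchor positions excluded), and truncation inside the
#' ROI applied to the designated fraction so those peptides cannot span it.
#'
#' @param spec A [pola_spec()].
#' @param out_dir Optional output directory; when given, peptides FASTA,
#'   hits TSV and truth TSV are written there.
#' @return A list with `peptides` (named character vector), `hits`
#'   (data.frame), `truth` (data.frame: orf_id, class, residue, truncated),
#'   `roi`, and `paths` (when written).
#' @export
generate_pola_set <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "PolASpec"))
  roi <- spec$roi
  ref <- roi$reference_peptide
  len <- nchar(ref)
  classes <- c(rep("F", spec$n_phe), rep("Y", spec$n_tyr),
               rep("L", spec$n_leu), rep("other", spec$n_other))
  n <- length(classes)
  local_seed(spec$seed, {
    n_trunc <- round(spec$truncation_fraction * n)
    truncated <- seq_len(n) %in% sample.int(n, n_trunc)
    ids <- sprintf("pep_%04d", seq_len(n))
    peptides <- character(n)
    residues <- character(n)
    for (i in seq_len(n)) {
      start <- sample.int(roi$roi_start, 1L)
      end <- if (truncated[i]) {
        sample(roi$site:(roi$roi_end - 1L), 1L)
      } else {
        sample(roi$roi_end:len, 1L)
      }
      chars <- strsplit(substring(ref, start, end), "", fixed = TRUE)[[1]]
      coord <- start:end  # reference coordinate of each peptide position
      res <- if (classes[i] == "other") {
        sample(setdiff(.AA20, c("F", "Y", "L")), 1L)
      } else classes[i]
      chars[coord == roi$site] <- res
      residues[i] <- res
      mutable <- which(!(coord %in% c(roi$roi_start, roi$site, roi$roi_end)))
      hit <- mutable[runif(length(mutable)) < spec$mutation_rate]
      for (p in hit) chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
      peptides[i] <- paste(chars, collapse = "")
    }
    names(peptides) <- ids
    plen <- unname(nchar(peptides))
    hits <- data.frame(
      query_id = ids, subject_id = roi$reference_id,
      percent_identity = round(100 * (1 - spec$mutation_rate), 1),
      alignment_length = plen, mismatches = 0, gap_opens = 0,
      query_start = 1, query_end = plen, subject_start = 1,
      subject_end = plen, evalue = 1e-50, bit_score = round(plen * 1.9, 1),
      subject_taxid = NA_integer_, subject_subsystem = NA_character_,
      subject_is_viral = TRUE, stringsAsFactors = FALSE
    )
    truth <- data.frame(orf_id = ids, class = classes, residue = residues,
                        truncated = truncated, stringsAsFactors = FALSE)
    out <- list(peptides = peptides, hits = hits, truth = truth, roi = roi)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(peptides = file.path(out_dir, "pola_peptides.faa"),
                    hits = file.path(out_dir, "pola_hits.tsv"),
                    truth = file.path(out_dir, "pola_truth.tsv"))
      write_fasta(peptides, paths$peptides)
      write_tabular_hits(hits, paths$hits)
      write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

# --------------------------------------------------------------- OTU table

#' Specification for a synthetic OTU table
#'
#' The default emulates a two-filter-fraction (1 um particle-associated vs
#' 0.2 um free-living), three-month freshwater design with four replicate
#' samples per fraction-month: a shared core of 277 OTUs present in every
#' sample, unique cores of 147 (1 um) and 152 (0.2 um) OTUs present in all
#' samples of one fraction but not all of the other, and sporadic OTUs
#' bringing the total to 7,489.
#'
#' @param seed Integer seed.
#' @param groups Group (fraction) names.
#' @param n_months,n_reps Months and replicate samples per fraction-month.
#' @param n_core_shared OTUs in the shared core.
#' @param n_core_unique Integer vector (one per group) of unique-core sizes.
#' @param n_sporadic OTUs guaranteed absent from at least one sample of
#'   every group.
#' @param depth_range Per-sample sequencing depth is drawn uniformly from
#'   this range.
#' @param n_trending,trend_beta Number of OTUs given a planted log-linear
#'   temporal trend, and the trend coefficient (log-abundance change per
#'   month, alternating sign).
#' @return A list of class `OtuTableSpec`.
#' @export
otu_table_spec <- function(seed = 1L,
                           groups = c("frac_1um", "frac_0.2um"),
                           n_months = 3L, n_reps = 4L,
                           n_core_shared = 277L,
                           n_core_unique = c(147L, 152L),
                           n_sporadic = 6913L,
                           depth_range = c(60000L, 100000L),
                           n_trending = 20L, trend_beta = 0.5) {
  stopifnot(length(groups) >= 1L, length(n_core_unique) == length(groups),
            n_months >= 1L, n_reps >= 1L, n_core_shared >= 0L,
            all(n_core_unique >= 0L), n_sporadic >= 0L,
            depth_range[1] >= 1L, depth_range[2] >= depth_range[1])
  structure(list(seed = as.integer(seed), groups = groups,
                 n_months = as.integer(n_months), n_reps = as.integer(n_reps),
                 n_core_shared = as.integer(n_core_shared),
                 n_core_unique = as.integer(n_core_unique),
                 n_sporadic = as.integer(n_sporadic),
                 depth_range = as.integer(depth_range),
                 n_trending = as.integer(n_trending),
                 trend_beta = trend_beta),
            class = "OtuTableSpec")
}

.phylum_pool <- data.frame(
  phylum = c("Actinobacteria", "Proteobacteria", "Bacteroidetes", "TM7",
             "OD1", "Verrucomicrobia", "Firmicutes", "Chloroflexi",
             "Cyanobacteria", "Planctomycetes"),
  prob = c(0.45, 0.30, 0.15, 0.025, 0.02, 0.012, 0.012, 0.011, 0.01, 0.01),
  stringsAsFactors = FALSE
)

#' Generate a synthetic OTU table with planted core membership
#'
#' Counts are drawn by giving every OTU a log-normal base abundance,
#' applying each OTU's planted temporal trend (`exp(beta * (month - 2))`),
#' masking sporadic and foreign-core OTUs out of the samples they must be
#' absent from, reserving one read per must-be-present (core) OTU, and
#' drawing the rest of each sample's depth from a multinomial. Sample
#' totals equal the drawn depths exactly; core OTUs are present in every
#' sample of their defining group by construction, and sporadic OTUs are
#' absent from at least one sample of every group.
#'
#' @param spec An [otu_table_spec()].
#' @param out_dir Optional directory for otu_table.tsv / otu_truth.tsv.
#' @return A list with `table` (an [OtuTable()]), `truth` (otu_id, role,
#'   phylum, beta), `groups` (named list of sample ids per group),
#'   `sample_info` (sample_id, group, month, rep), and `paths` when written.
#' @export
generate_otu_table <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "OtuTableSpec"))
  local_seed(spec$seed, {
    g <- length(spec$groups)
    info <- expand.grid(rep = seq_len(spec$n_reps),
                        month = seq_len(spec$n_months),
                        group = spec$groups, stringsAsFactors = FALSE)
    info$sample_id <- sprintf("%s_m%d_r%d", info$group, info$month, info$rep)
    groups <- split(info$sample_id, info$group)[spec$groups]
    gsize <- spec$n_months * spec$n_reps

    roles <- c(rep("shared_core", spec$n_core_shared),
               unlist(lapply(seq_len(g), function(i) {
                 rep(paste0("core_", spec$groups[i]), spec$n_core_unique[i])
               })),
               rep("sporadic", spec$n_sporadic))
    n <- length(roles)
    ids <- sprintf("OTU_%06d", seq_len(n))
    phyla <- sample(.phylum_pool$phylum, n, replace = TRUE,
                    prob = .phylum_pool$prob)
    beta <- numeric(n)
    if (spec$n_trending > 0L) {
      tr <- sample.int(n, min(spec$n_trending, n))
      beta[tr] <- spec$trend_beta * rep_len(c(1, -1), length(tr))
    }
    base <- rlnorm(n, meanlog = 0, sdlog = 1.5)

    # presence mask: TRUE = allowed in that sample
    mask <- matrix(TRUE, n, nrow(info), dimnames = list(ids, info$sample_id))
    for (i in seq_len(n)) {
      if (roles[i] == "shared_core") next
      absent_from <- if (roles[i] == "sporadic") spec$groups else
        setdiff(spec$groups, sub("^core_", "", roles[i]))
      for (gr in absent_from) {
        out_n <- sample.int(gsize, 1L)
        mask[i, sample(groups[[gr]], out_n)] <- FALSE
      }
    }

    counts <- matrix(0L, n, nrow(info), dimnames = list(ids, info$sample_id))
    must <- roles == "shared_core" |
      roles %in% paste0("core_", spec$groups)
    for (j in seq_len(nrow(info))) {
      depth <- sample(spec$depth_range[1]:spec$depth_range[2], 1L)
      must_j <- must & mask[, j] &
        (roles == "shared_core" | roles == paste0("core_", info$group[j]))
      elig <- mask[, j]
      w <- base * exp(beta * (info$month[j] - 2))
      w[!elig] <- 0
      draw <- as.integer(rmultinom(1L, depth - sum(must_j), prob = w))
      draw[must_j] <- draw[must_j] + 1L
      counts[, j] <- draw
    }

    taxonomy <- vapply(seq_len(n), function(i) {
      genus <- if (i %% 7L == 0L) "g__" else sprintf("g__Genus%04d", (i - 1L) %/% 3L + 1L)
      p <- phyla[i]
      sprintf("k__Bacteria; p__%s; c__%sia; o__%sales; f__%saceae; %s; s__",
              p, p, p, p, genus)
    }, character(1))
    table <- OtuTable(counts, setNames(taxonomy, ids))
    truth <- data.frame(otu_id = ids, role = roles, phylum = phyla,
                        beta = beta, stringsAsFactors = FALSE)
    out <- list(table = table, truth = truth, groups = groups,
                sample_info = info[, c("sample_id", "group", "month", "rep")])
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(table = file.path(out_dir, "otu_table.tsv"),
                    truth = file.path(out_dir, "otu_truth.tsv"))
      write_otu_table(table, paths$table)
      write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}
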