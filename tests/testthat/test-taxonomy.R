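# Toy taxonomy: root(1) -> Viruses(10) -> fam(11) -> species 101,102
#                       -> Bacteria(2) -> fam(21) -> species 201
toy_taxmap <- function() {
  taxonomy_map(data.frame(
    taxid = c(1L, 10L, 2L, 11L, 21L, 101L, 102L, 201L),
    parent_taxid = c(1L, 1L, 1L, 10L, 2L, 11L, 11L, 21L),
    rank = c("no rank", "superkingdom", "superkingdom", "family", "family",
             "species", "species", "species"),
    name = c("root", "Viruses", "Bacteria", "Virofam", "Bactofam",
             "vsp1", "vsp2", "bsp1"),
    stringsAsFactors = FALSE), viral_roots = 10L)
}

test_that("E-value filtering is inclusive at the cutoff", {
  hits <- make_hits(c("a", "b", "c"), 100, evalue = c(1e-3, 2e-3, 1e-9))
  kept <- filter_hits(hits, 1e-3)
  expect_equal(kept$query_id, c("a", "c"))

  withr::with_seed(9, {
    h <- make_hits(sprintf("o%d", 1:200), 50, evalue = 10^-runif(200, 0, 8))
    cut <- 1e-4
    expect_equal(filter_hits(h, cut)$query_id,
                 h$query_id[sapply(h$evalue, function(e) e <= cut)])
  })
})

test_that("contig taxonomy follows the maximum summed bit score", {
  orfs <- make_orfs(c("orf1", "orf2"), "ctg")
  hits <- rbind(make_hits("orf1", 50, subject_taxid = 7L),
                make_hits("orf2", c(30, 100), subject_taxid = c(7L, 8L)))
  asg <- assign_contig_taxonomy(orfs, hits)
  expect_equal(asg$taxid, 8L)           # sums: 7 -> 80, 8 -> 100
  expect_equal(asg$sum_bit_score, 100)
  expect_false(asg$tie)

  hits2 <- rbind(make_hits("orf1", 80, subject_taxid = 8L),
                 make_hits("orf2", 80, subject_taxid = 7L))
  asg2 <- assign_contig_taxonomy(orfs, hits2)
  expect_equal(asg2$taxid, 7L)          # tie broken to the smaller taxid
  expect_true(asg2$tie)

  expect_error(assign_contig_taxonomy(orfs, make_hits("nope", 5,
                                                      subject_taxid = 1L)),
               "unknown ORF")
  none <- assign_contig_taxonomy(orfs, hits[0, ])
  expect_true(is.na(none$taxid))
})

test_that("assignment agrees with an exhaustive per-taxid oracle", {
  withr::with_seed(13, {
    for (i in 1:200) {
      n_orf <- sample(1:8, 1)
      orfs <- make_orfs(sprintf("o%d", 1:n_orf), "ctg")
      n_hit <- sample(1:20, 1)
      hits <- make_hits(sample(orfs$orf_id, n_hit, TRUE),
                        bit_score = sample(seq(10, 60, by = 10), n_hit, TRUE),
                        subject_taxid = sample(1:5, n_hit, TRUE))
      asg <- assign_contig_taxonomy(orfs, hits)
      sums <- c()
      for (t in unique(hits$subject_taxid)) {
        sums[as.character(t)] <- sum(hits$bit_score[hits$subject_taxid == t])
      }
      winners <- as.integer(names(sums)[sums == max(sums)])
      expect_equal(asg$taxid, min(winners))
      expect_equal(asg$tie, length(winners) > 1)
      expect_equal(asg$sum_bit_score, unname(max(sums)))
    }
  })
})

test_that("adding bit score to the winner never changes the winner", {
  withr::with_seed(17, {
    for (i in 1:30) {
      orfs <- make_orfs(c("o1", "o2"), "ctg")
      hits <- make_hits(sample(c("o1", "o2"), 10, TRUE),
                        bit_score = runif(10, 5, 80),
                        subject_taxid = sample(1:4, 10, TRUE))
      before <- assign_contig_taxonomy(orfs, hits)
      extra <- make_hits("o1", runif(1, 1, 50), subject_taxid = before$taxid)
      after <- assign_contig_taxonomy(orfs, rbind(hits, extra))
      expect_equal(after$taxid, before$taxid)
    }
  })
})

test_that("best-hit-only mode keeps one hit per ORF", {
  orfs <- make_orfs(c("o1", "o2"), "ctg")
  # o1: taxid 5 best (60); o2: taxid 9 best (50); all-hits sum favors 7
  hits <- rbind(make_hits("o1", c(60, 40, 40), subject_taxid = c(5L, 7L, 7L)),
                make_hits("o2", c(50, 45, 45), subject_taxid = c(9L, 7L, 7L)))
  expect_equal(assign_contig_taxonomy(orfs, hits)$taxid, 7L)
  best <- assign_contig_taxonomy(orfs, hits, best_hit_only = TRUE)
  expect_equal(best$taxid, 5L)  # sums now 5 -> 60, 9 -> 50
})

test_that("viral lineage test walks parents to the designated root", {
  tm <- toy_taxmap()
  expect_true(is_viral(101L, tm))
  expect_true(is_viral(11L, tm))
  expect_false(is_viral(201L, tm))
  expect_false(is_viral(2L, tm))
  expect_error(is_viral(999L, tm), "unknown taxid")

  withr::with_seed(21, {
    for (i in 1:20) {
      # random tree: node k's parent is uniform among 1..k-1
      n <- 40L
      parent <- c(1L, vapply(2:n, function(k) sample(1:(k - 1), 1),
                             integer(1)))
      viral_root <- sample(2:n, 1)
      tm2 <- taxonomy_map(data.frame(taxid = 1:n, parent_taxid = parent,
                                     rank = "no rank",
                                     name = paste0("t", 1:n)),
                          viral_roots = viral_root)
      for (t in sample(1:n, 10)) {
        anc <- t  # brute-force ancestor enumeration
        path <- t
        while (anc != parent[anc]) { anc <- parent[anc]; path <- c(path, anc) }
        expect_equal(is_viral(t, tm2), viral_root %in% path)
      }
    }
  })
})

test_that("rank rollup conserves abundance and separates unassigned mass", {
  tm <- toy_taxmap()
  asg <- data.frame(contig_id = c("c1", "c2", "c3"),
                    taxid = c(101L, 102L, NA), sum_bit_score = c(90, 80, 0),
                    tie = FALSE, stringsAsFactors = FALSE)
  ab <- c(c1 = 2.0, c2 = 3.0, c3 = 4.0)
  ru <- rollup_taxon_abundance(asg, ab, tm, "family")
  expect_equal(ru$abundance[ru$group == "Virofam"], 5.0)
  expect_equal(ru$abundance[ru$group == "no known homolog"], 4.0)
  expect_equal(sum(ru$abundance), sum(ab), tolerance = 1e-12)
  expect_equal(sum(ru$fraction), 1, tolerance = 1e-12)

  ru0 <- rollup_taxon_abundance(asg[3, ], ab["c3"], tm, "family")
  expect_equal(ru0$group, "no known homolog")
  expect_equal(ru0$fraction, 1)

  expect_error(rollup_taxon_abundance(asg, ab[1:2], tm), "missing abundance")
})

test_that("planted family fractions are recovered from a synthetic community", {
  d <- withr::local_tempdir()
  cm <- generate_community(community_spec(seed = 42), d)
  res <- depth_from_sam(cm$paths$sam, cm$contig_lengths)
  rec <- recruitment_summary("sim", res$total_recruited_bases)
  ab <- abundance_table(res$profiles, rec)
  orfs <- read_orf_table(cm$paths$orfs, cm$contig_lengths)
  hits <- read_tabular_hits(cm$paths$hits,
                            extra = c("subject_taxid", "subject_subsystem",
                                      "subject_is_viral"))
  tm <- read_taxonomy_nodes(cm$paths$nodes, viral_roots = cm$viral_root)
  asg <- assign_contig_taxonomy(orfs, filter_hits(hits), tm)
  ru <- rollup_taxon_abundance(asg, ab, tm, "family")
  # conservation against the input abundances
  expect_equal(sum(ru$abundance),
               sum(ab$normalized_abundance[ab$feature_kind == "contig"]),
               tolerance = 1e-9)
  # planted per-family fractions (coverage-weighted) within 5 percent
  tr <- cm$truth_contigs
  planted <- tapply(tr$planted_coverage * tr$length, tr$family, sum)
  planted <- planted / sum(planted)
  # compare on abundance-mass fractions; weights differ only by length sums
  got_cov <- tapply(ab$normalized_abundance[match(tr$contig_id, ab$feature_id)] *
                      tr$length, tr$family, sum)
  got_cov <- got_cov / sum(got_cov)
  for (fam in names(planted)) {
    expect_lt(abs(got_cov[[fam]] - planted[[fam]]) / planted[[fam]], 0.05)
  }
})
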