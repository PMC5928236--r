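test_that("relative abundance columns sum to one and reject empty samples", {
  tb <- OtuTable(matrix(c(2L, 2L, 5L, 0L), 2, 2,
                        dimnames = list(c("a", "b"), c("s1", "s2"))),
                 c(a = "k__B; p__X", b = "k__B; p__Y"))
  rel <- relative_abundance(tb)
  expect_equal(rel[, "s1"], c(a = 0.5, b = 0.5))
  expect_equal(rel[, "s2"], c(a = 1.0, b = 0.0))

  tb0 <- OtuTable(matrix(c(1L, 0L), 1, 2,
                         dimnames = list("a", c("s1", "s2"))),
                  c(a = "k__B"))
  expect_error(relative_abundance(tb0), "zero-total")

  withr::with_seed(73, {
    for (i in 1:10) {
      tb <- random_otu_table(sample(5:50, 1), sample(2:8, 1))
      expect_equal(unname(colSums(relative_abundance(tb))),
                   rep(1, ncol(tb$counts)), tolerance = 1e-12)
    }
  })
})

test_that("taxonomic collapse sums counts and conserves totals", {
  counts <- matrix(c(3L, 4L, 2L), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  tax <- c(a = "k__B; p__X; c__C; o__O; f__F; g__G1; s__",
           b = "k__B; p__X; c__C; o__O; f__F; g__G1; s__",
           c = "k__B; p__X; c__C; o__O; f__F; g__G2; s__")
  tb <- OtuTable(counts, tax)
  genus <- collapse_taxonomy(tb, 6)
  expect_equal(nrow(genus$counts), 2L)
  expect_equal(unname(genus$counts[grep("G1", rownames(genus$counts)), "s1"]), 7L)

  domain <- collapse_taxonomy(tb, 1)
  expect_equal(nrow(domain$counts), 1L)
  expect_equal(unname(domain$counts[1, 1]), 9L)

  # unnamed-at-rank OTUs group under the deepest named ancestor
  tax2 <- c(a = "k__B; p__X; c__C; o__O; f__F; g__; s__", b = tax[["b"]],
            c = tax[["c"]])
  tb2 <- OtuTable(counts, tax2)
  g2 <- collapse_taxonomy(tb2, 6)
  expect_true("k__B;p__X;c__C;o__O;f__F" %in% rownames(g2$counts))
  expect_equal(sum(g2$counts), sum(tb2$counts))

  bad <- OtuTable(counts[1, , drop = FALSE], c(a = " ; ; "))
  expect_error(collapse_taxonomy(bad, 2), "malformed lineage.*a")

  withr::with_seed(79, {
    for (i in 1:10) {
      tb <- random_otu_table(sample(10:60, 1), sample(2:6, 1))
      for (lvl in c(1, 2, 6)) {
        expect_equal(sum(collapse_taxonomy(tb, lvl)$counts), sum(tb$counts))
      }
    }
  })
})

test_that("the one-percent display filter is strictly greater-than", {
  rel <- rbind(a = c(0.015, 0.001), b = c(0.010, 0.010), c = c(0.5, 0.2))
  kept <- filter_max_relabund(rel, 0.01)
  expect_equal(rownames(kept), c("a", "c"))  # max exactly 0.01 is dropped

  withr::with_seed(83, {
    m <- matrix(runif(300, 0, 0.03), 50, 6,
                dimnames = list(paste0("t", 1:50), paste0("s", 1:6)))
    kept <- filter_max_relabund(m, 0.01)
    oracle <- character()
    for (r in rownames(m)) if (max(m[r, ]) > 0.01) oracle <- c(oracle, r)
    expect_equal(rownames(kept), oracle)
  })
})

test_that("rarefaction hits the requested depth exactly and drops shallow samples", {
  withr::with_seed(89, {
    tb <- random_otu_table(30, 5, lambda = 40)
    depth <- min(colSums(tb$counts))
    r <- rarefy(tb, depth, seed = 2)
    expect_true(all(colSums(r$counts) == depth))
    expect_true(all(r$counts <= tb$counts))

    # depth equal to a sample total leaves that sample's counts unchanged
    r2 <- rarefy(tb, depth, seed = 3)
    j <- which.min(colSums(tb$counts))
    expect_equal(r2$counts[, j], tb$counts[, j])

    shallow <- tb$counts; shallow[, 1] <- 0L; shallow[1, 1] <- 5L
    tbs <- OtuTable(shallow, tb$taxonomy)
    expect_warning(rs <- rarefy(tbs, depth, seed = 4), "dropping sample")
    expect_equal(ncol(rs$counts), 4L)
    expect_error(rarefy(tb, 0), "positive")
  })
})

test_that("rarefied counts follow the hypergeometric expectation", {
  counts <- matrix(c(10L, 30L, 60L), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  tb <- OtuTable(counts, setNames(rep("k__B", 3), c("a", "b", "c")))
  depth <- 20; N <- 100
  draws <- vapply(1:1000, function(s) rarefy(tb, depth, seed = s)$counts[, 1],
                  numeric(3))
  for (i in 1:3) {
    K <- counts[i, 1]
    mu <- depth * K / N
    sdv <- sqrt(depth * (K / N) * (1 - K / N) * (N - depth) / (N - 1))
    expect_lt(abs(mean(draws[i, ]) - mu), 3 * sdv / sqrt(1000))
  }
})

test_that("Shannon (bits) and observed richness match closed forms", {
  expect_equal(shannon(rep(5, 4)), 2, tolerance = 1e-12)
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_equal(observed_otus(c(3, 0, 1)), 2)
  expect_equal(observed_otus(c(0, 0)), 0)

  withr::with_seed(97, {
    for (i in 1:20) {
      x <- sample(0:40, 15, replace = TRUE)
      if (sum(x) == 0) next
      p <- x[x > 0] / sum(x)
      expect_equal(shannon(x), -sum(p * log2(p)), tolerance = 1e-12)
      expect_equal(observed_otus(x), sum(x != 0))
    }
  })
})

test_that("Bray-Curtis has zero diagonal, symmetry, and unit disjoint distance", {
  counts <- matrix(c(2L, 0L, 0L, 2L, 1L, 1L, 1L, 3L), 2, 4,
                   dimnames = list(c("a", "b"), c("s1", "s2", "s3", "s4")))
  tb <- OtuTable(counts, c(a = "k__B", b = "k__B"))
  d <- bray_curtis(tb)
  expect_equal(d["s1", "s2"], 1)          # (2,0) vs (0,2)
  expect_equal(d["s3", "s4"], 1 / 3)      # (1,1) vs (1,3)
  expect_true(all(diag(d) == 0))
  expect_true(isSymmetric(d))
  expect_equal(d["s1", "s1"], 0)

  dup <- OtuTable(cbind(counts, s5 = counts[, "s1"]),
                  c(a = "k__B", b = "k__B"))
  expect_equal(bray_curtis(dup)["s1", "s5"], 0)

  zz <- OtuTable(matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
                 c(a = "k__B", b = "k__B"))
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("core OTU algebra matches brute-force prevalence", {
  counts <- matrix(c(1L, 1L, 0L,
                     2L, 1L, 1L,
                     1L, 0L, 1L,
                     3L, 2L, 1L), 3, 4,
                   dimnames = list(c("o1", "o2", "o3"),
                                   c("a1", "a2", "b1", "b2")))
  tb <- OtuTable(counts, setNames(
    c("k__B; p__X", "k__B; p__X", "k__B; p__Y"), c("o1", "o2", "o3")))
  # presence: o1 everywhere; o2 absent in b1; o3 absent in a1
  res <- core_otus(tb, list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_equal(sort(res$core_per_group$A), c("o1", "o2"))   # present in all A
  expect_equal(sort(res$core_per_group$B), c("o1", "o3"))
  expect_equal(res$shared_core, "o1")
  expect_equal(res$unique_core_per_group$A, "o2")
  expect_equal(res$unique_core_per_group$B, "o3")
  expect_error(core_otus(tb, list(A = c("a1", "a2"), B = character())),
               "empty group")
  expect_error(core_otus(tb, list(A = c("a1", "a2"), B = "b1")),
               "partition")

  withr::with_seed(101, {
    for (i in 1:30) {
      n_s <- sample(4:12, 1); n_o <- sample(10:80, 1)
      tb <- random_otu_table(n_o, n_s, lambda = 1)  # sparse
      k <- sample(2:3, 1)
      grp <- split(colnames(tb$counts),
                   rep_len(paste0("g", 1:k), n_s))
      res <- core_otus(tb, grp)
      pres <- tb$counts > 0
      for (g in names(grp)) {
        oracle <- rownames(pres)[apply(pres[, grp[[g]], drop = FALSE], 1, all)]
        expect_equal(sort(res$core_per_group[[g]]), sort(oracle))
      }
      # two-group identity: |shared| + sum|unique| = sum|core| - overlap terms
      if (k == 2) {
        expect_equal(length(res$shared_core) +
                       sum(lengths(res$unique_core_per_group)),
                     sum(lengths(res$core_per_group)) -
                       length(res$shared_core))
      }
    }
  })
})
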