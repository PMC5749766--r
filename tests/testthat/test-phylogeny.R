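test_that("progressive alignment: identical, small-indel and planted cases", {
  rec <- gene_records(c("g1", "g2", "g3"), c("A", "B", "C"),
                     rep("MKVLITGGAGFI", 3))
  al <- align_core_cluster(rec)
  expect_false(any(grepl("-", al)))
  expect_named(al, c("A", "B", "C"))

  # ACDE vs ACE: one gap column, all non-gap columns identical; optimal
  # NW score verified against the exhaustive DP oracle
  rec2 <- gene_records(c("g1", "g2"), c("A", "B"), c("ACDE", "ACE"))
  al2 <- align_core_cluster(rec2)
  expect_equal(nchar(al2[["A"]]), 4)
  expect_equal(sum(strsplit(al2[["B"]], "")[[1]] == "-"), 1)
  cols <- cbind(strsplit(al2[["A"]], "")[[1]], strsplit(al2[["B"]], "")[[1]])
  nogap <- cols[, 2] != "-"
  expect_true(all(cols[nogap, 1] == cols[nogap, 2]))
  expect_equal(pairwise_identity("ACDE", "ACE")[["score"]],
               oracle_nw("ACDE", "ACE")[["score"]])

  # divergence-0 planted core cluster aligns gap-free with identical rows
  spec <- pangenome_spec(4, n_core = 1, n_dispensable = 0, divergence = 0,
                         seed = 2)
  pg <- generate_pangenome(spec)
  recs <- do.call(rbind, pg$proteomes)
  al3 <- align_core_cluster(recs)
  expect_length(unique(al3), 1)
  expect_false(any(grepl("-", al3)))

  expect_warning(align_core_cluster(rec[1, ]), "single sequence")
})

test_that("concatenation: widths, boundaries, missing strains", {
  strains <- c("s1", "s2")
  a1 <- c(s1 = strrep("A", 10), s2 = strrep("C", 10))
  a2 <- c(s1 = strrep("D", 15), s2 = strrep("E", 15))
  ca <- concatenate(list(c1 = a1, c2 = a2), strains)
  expect_equal(nchar(ca$sequences[["s1"]]), 25)
  expect_equal(ca$boundaries, c(0, 10, 25))

  expect_error(concatenate(list(c1 = a1[1]), strains), "missing strain 's2'")

  # column order is irrelevant to the distance matrix
  ca_rev <- concatenate(list(c1 = a1, c2 = a2), strains,
                        cluster_order = c("c2", "c1"))
  expect_equal(poisson_distance(ca), poisson_distance(ca_rev),
               ignore_attr = TRUE)

  # planted multi-cluster run: total width is the sum of widths
  spec <- pangenome_spec(5, n_core = 20, n_dispensable = 0, seed = 4,
                         protein_length = c(mean = 40, jitter = 5))
  pg <- generate_pangenome(spec)
  recs <- do.call(rbind, pg$proteomes)
  cs <- greedy_cluster(recs, cluster_params(0.4, 0.4))
  aligns <- lapply(split(cs$members$gene_id, cs$members$cluster_id),
                   function(g) align_core_cluster(recs[recs$id %in% g, ]))
  names(aligns) <- paste0("c", seq_along(aligns))
  ca20 <- concatenate(aligns, spec$strains)
  expect_equal(nchar(ca20$sequences[[1]]),
               sum(vapply(aligns, function(a) nchar(a[[1]]), numeric(1))))
  expect_equal(length(ca20$boundaries), 21)
})

test_that("poisson distance: closed form, pairwise deletion, saturation", {
  al <- c(x = "AAAAAAAAAA", y = "AAAAAAAAAA")
  D0 <- poisson_distance(al)
  expect_equal(D0["x", "y"], 0)

  # p = 0.3 -> d = -ln(0.7)
  al2 <- c(x = "AAAAAAAAAA", y = "CCCAAAAAAA")
  D2 <- poisson_distance(al2)
  expect_equal(attr(D2, "p")["x", "y"], 0.3)
  expect_equal(D2["x", "y"], 0.3566749439, tolerance = 1e-9)
  expect_gte(D2["x", "y"], attr(D2, "p")["x", "y"])  # correction inflates

  # pairwise-deletion bookkeeping
  al3 <- c(a = "AAAA", b = "AA--", c = "CCAA")
  D3 <- poisson_distance(al3)
  expect_equal(attr(D3, "p")["a", "b"], 0)   # 2 shared columns, 0 mismatch
  expect_equal(attr(D3, "p")["a", "c"], 0.5)

  # saturation flag and zero-shared-column error
  al4 <- c(a = "AAAA", b = "CCCC")
  D4 <- poisson_distance(al4)
  expect_true(attr(D4, "saturated")["a", "b"])
  expect_true(is.na(D4["a", "b"]))
  expect_error(poisson_distance(c(a = "AA--", b = "--CC")),
               "zero shared.*\\(a, b\\)")
  expect_error(neighbor_joining(matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3,
                                       dimnames = list(letters[1:3],
                                                       letters[1:3]))),
               "saturated")
})

test_that("neighbor joining: 3-taxon closed form and 4-taxon additivity", {
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- neighbor_joining(D3)
  expect_equal(length(tr3$tip.label), 3)
  # three-point formulas: b_a = (3+4-5)/2 = 1, b_b = 2, b_c = 3
  bl <- tr3$edge.length[match(match(c("a", "b", "c"), tr3$tip.label),
                              tr3$edge[, 2])]
  expect_equal(bl, c(1, 2, 3))

  # planted 4-taxon additive matrix: ((a,b),(c,d)) with branches 1,2,3,4
  # and internal branch 5
  D4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  b <- c(a = 1, b = 2, c = 3, d = 4)
  for (i in c("a", "b")) for (j in c("c", "d"))
    D4[i, j] <- D4[j, i] <- b[i] + 5 + b[j]
  D4["a", "b"] <- D4["b", "a"] <- 3
  D4["c", "d"] <- D4["d", "c"] <- 7
  tr4 <- neighbor_joining(D4)
  expect_equal(tree_bipartitions(tr4), "c,d")   # topology ab|cd
  expect_equal(cophenetic(tr4)[letters[1:4], letters[1:4]], D4,
               tolerance = 1e-12)               # branch lengths exact

  # negative-branch clamping is reported
  Dneg <- matrix(c(0, 1, 1, 10, 1, 0, 1, 10, 1, 1, 0, 1, 10, 10, 1, 0),
                 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_message(trc <- neighbor_joining(Dneg), "clamped")
  expect_true(all(trc$edge.length >= 0))
})

test_that("NJ consistency on additive inputs and taxon-order invariance", {
  # property: exact path-length matrices are recovered with RF = 0
  for (seed in 1:10) {
    pt <- generate_planted_tree(8, seed = seed)
    tr <- neighbor_joining(pt$dist)
    expect_equal(rf_distance(tr, pt$tree), 0)
    # cross-check our RF bookkeeping against phangorn once per tree
    expect_equal(phangorn::RF.dist(tr, pt$tree), 0)
  }
  # taxon input order must not matter
  pt <- generate_planted_tree(7, seed = 99)
  perm <- sample(7)
  Dp <- pt$dist[perm, perm]
  expect_equal(rf_distance(neighbor_joining(Dp),
                           neighbor_joining(pt$dist)), 0)
  expect_equal(sum(neighbor_joining(Dp)$edge.length),
               sum(neighbor_joining(pt$dist)$edge.length),
               tolerance = 1e-12)
})

# deterministic two-group alignment used by the bootstrap tests: 4 + 4
# strains, half the columns carry the group signal, plus per-strain
# private columns for within-group resolution
two_group_alignment <- function() {
  strains <- paste0("s", 1:8)
  width_signal <- 40; width_const <- 40
  m <- matrix("D", 8, width_signal + width_const + 8,
              dimnames = list(strains, NULL))
  m[1:4, seq_len(width_signal)] <- "A"
  m[5:8, seq_len(width_signal)] <- "C"
  for (i in 1:8) m[i, width_signal + width_const + i] <- "W"
  stats::setNames(apply(m, 1, paste, collapse = ""), strains)
}

test_that("bootstrap: clean-signal support, single replicate, invariances", {
  al <- two_group_alignment()
  bs <- bootstrap_support(al, n_replicates = 100, seed = 5)
  key <- paste(sort(paste0("s", 5:8)), collapse = ",")
  expect_true(key %in% names(bs$support))
  expect_equal(unname(bs$support[key]), 100)

  # deterministic for fixed seed
  bs2 <- bootstrap_support(al, n_replicates = 100, seed = 5)
  expect_identical(bs$support, bs2$support)

  # single replicate: supports are 0 or 100
  bs1 <- bootstrap_support(al, n_replicates = 1, seed = 3)
  expect_true(all(bs1$support %in% c(0, 100)))

  # column order invariance
  set.seed(8)
  perm <- sample(nchar(al[1]))
  al_perm <- vapply(al, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), character(1))
  bs3 <- bootstrap_support(al_perm, n_replicates = 50, seed = 5)
  expect_equal(sort(names(bs3$support)), sort(names(bs$support)))
  expect_equal(unname(bs3$support[key]), 100)

  expect_error(bootstrap_support(c(a = "A", b = "C"), 10, 1), ">= 2 columns")
})
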