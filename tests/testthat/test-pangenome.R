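# small helper: build a cluster_set-like object directly from a membership
# list so classification tests don't depend on the clustering stage
fake_cluster_set <- function(genes_by_cluster, sources) {
  rows <- do.call(rbind, lapply(seq_along(genes_by_cluster), function(k) {
    g <- genes_by_cluster[[k]]
    data.frame(cluster_id = k, gene_id = g, source = sources[g],
               length = 100L, identity = 1, coverage = 1,
               is_representative = seq_along(g) == 1,
               stringsAsFactors = FALSE)
  }))
  panmeta:::new_cluster_set(rows)
}

test_that("occupancy rule: core / dispensable / strain-specific", {
  src <- c(g1 = "A", g2 = "B", g3 = "C", g4 = "A", g5 = "B",
           g6 = "A", g7 = "A")
  cs <- fake_cluster_set(list(c("g1", "g2", "g3"),   # all strains -> core
                              c("g4", "g5"),          # subset -> dispensable
                              c("g6", "g7")),         # one strain (paralogs)
                         src)
  part <- classify_clusters(cs, src, strain_list = c("A", "B", "C"))
  expect_equal(unname(part$classes),
               c("core", "dispensable", "strain_specific"))
  expect_equal(sum(part$counts), 3)

  # unknown source is an error
  expect_error(classify_clusters(cs, src, strain_list = c("A", "B")),
               "unknown source")

  # degenerate single-strain input resolves to core with a warning
  src1 <- c(g1 = "A", g2 = "A")
  cs1 <- fake_cluster_set(list("g1", "g2"), src1)
  expect_warning(p1 <- classify_clusters(cs1, src1, strain_list = "A"),
                 "single-strain")
  expect_true(all(p1$classes == "core"))
})

test_that("planted pangenome partition counts match truth", {
  spec <- pangenome_spec(6, n_core = 10, n_dispensable = 12,
                         n_unique_per_strain = 3, seed = 31,
                         protein_length = c(mean = 80, jitter = 10))
  pg <- generate_pangenome(spec)
  recs <- do.call(rbind, pg$proteomes)
  cs <- greedy_cluster(recs, cluster_params(0.4, 0.4))
  part <- classify_clusters(cs, strain_list = spec$strains)
  expect_equal(unname(part$counts),
               c(10, 12, 6 * 3))
  expect_equal(sum(part$counts), n_clusters(cs))
})

test_that("jaccard matrix: examples and set-arithmetic oracle", {
  src <- c(a1 = "A", a2 = "A", a3 = "A", b2 = "B", b3 = "B", b4 = "B",
           c0 = "C", c4 = "C", x1 = "A", x2 = "B", x3 = "C")
  # dispensable clusters occupy {A,C},{A,B},{A,B},{B,C}; plus a core anchor
  cs <- fake_cluster_set(list(c("a1", "c0"),            # A,C
                              c("a2", "b2"),            # A,B
                              c("a3", "b3"),            # A,B
                              c("b4", "c4"),            # B,C
                              c("x1", "x2", "x3")),     # core
                         src)
  part <- classify_clusters(cs, src, strain_list = c("A", "B", "C"))
  J <- jaccard_matrix(part)
  # D_A = {1,2,3}, D_B = {2,3,4} -> J = 2/4
  expect_equal(J["A", "B"], 0.5)
  expect_equal(J["A", "C"], 0.25)    # D_C = {1,4}
  expect_equal(diag(J), c(A = 1, B = 1, C = 1))

  # identical and disjoint sets
  expect_equal(oracle_jaccard(list(A = 1:3, B = 1:3))["A", "B"], 1)
  expect_equal(oracle_jaccard(list(A = 1:3, B = 4:6))["A", "B"], 0)

  # 13-strain random presence/absence vs brute-force oracle
  set.seed(5)
  strains <- sprintf("s%02d", 1:13)
  pres <- matrix(rbinom(13 * 40, 1, 0.4), 13, 40,
                 dimnames = list(strains, paste0("cluster_", 1:40)))
  pres[, 1] <- 1  # keep one core column out of the dispensable set
  classes <- c("core", rep("dispensable", 39))
  names(classes) <- colnames(pres)
  part2 <- structure(list(classes = classes, presence = pres),
                     class = "pangenome_partition")
  J2 <- suppressWarnings(jaccard_matrix(part2))
  sets <- apply(pres[, -1], 1, function(r) which(r == 1), simplify = FALSE)
  expect_equal(J2, oracle_jaccard(sets), tolerance = 1e-12)

  # 1 - J satisfies the triangle inequality on these instances
  Dj <- 1 - J2
  for (i in 1:13) for (j in 1:13) for (k in 1:13)
    expect_lte(Dj[i, j], Dj[i, k] + Dj[k, j] + 1e-12)
})

test_that("removing a strain leaves recomputed pairwise J unchanged", {
  spec <- pangenome_spec(6, n_core = 5, n_dispensable = 15,
                         n_unique_per_strain = 1, seed = 41,
                         protein_length = c(mean = 60, jitter = 5))
  pg <- generate_pangenome(spec)
  recs <- do.call(rbind, pg$proteomes)
  part_all <- classify_clusters(greedy_cluster(recs, cluster_params(0.4, 0.4)),
                                strain_list = spec$strains)
  J_all <- jaccard_matrix(part_all)

  keep <- setdiff(spec$strains, "strain_6")
  # restrict to clusters still dispensable among the kept strains, then
  # recompute J from scratch on the reduced presence matrix
  pres <- part_all$presence[keep, , drop = FALSE]
  occ <- colSums(pres)
  disp <- occ > 1 & occ < length(keep)
  sets <- apply(pres[, disp, drop = FALSE], 1, function(r) which(r == 1),
                simplify = FALSE)
  J_reduced <- oracle_jaccard(sets)

  # direct recomputation from the same dispensable-restricted sets must
  # agree with package arithmetic on those sets
  classes <- ifelse(disp, "dispensable",
                    ifelse(occ == length(keep), "core", "strain_specific"))
  names(classes) <- colnames(pres)
  part_red <- structure(list(classes = classes, presence = pres),
                        class = "pangenome_partition")
  expect_equal(suppressWarnings(jaccard_matrix(part_red)), J_reduced,
               tolerance = 1e-12)
})

test_that("bi-clustering: trivial merges, oracle heights, planted blocks", {
  m <- matrix(c(0, 0, 0, 0, 5, 5), 3, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3"), c("c1", "c2")))
  bc <- biclust_order(m)
  # identical rows merge first at height 0: ((r1,r2),r3)
  expect_equal(bc$row_hclust$height[1], 0)
  expect_setequal(abs(bc$row_hclust$merge[1, ]), c(1, 2))  # r1 with r2
  expect_equal(abs(diff(match(c("r1", "r2"), bc$row_order))), 1)

  expect_error(biclust_order(m[1, , drop = FALSE]), ">= 2 rows")

  # merge heights equal the O(n^3) average-linkage oracle
  set.seed(9)
  X <- matrix(rnorm(64), 8, 8,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:8)))
  bc8 <- biclust_order(X)
  expect_equal(sort(bc8$row_hclust$height),
               oracle_average_linkage_heights(X), tolerance = 1e-9)
  expect_equal(sort(bc8$col_hclust$height),
               oracle_average_linkage_heights(t(X)), tolerance = 1e-9)

  # planted two-block matrix: leaf order separates the groups
  set.seed(11)
  grpA <- paste0("a", 1:4); grpB <- paste0("b", 1:4)
  B <- rbind(matrix(1 + rnorm(4 * 6, sd = 0.05), 4, 6),
             matrix(rnorm(4 * 6, sd = 0.05), 4, 6))
  dimnames(B) <- list(c(grpA, grpB), paste0("c", 1:6))
  ord <- biclust_order(B)$row_order
  posA <- range(match(grpA, ord)); posB <- range(match(grpB, ord))
  expect_true(posA[2] < posB[1] || posB[2] < posA[1])
})
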