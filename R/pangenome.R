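#' Partition clusters into core / dispensable / strain-specific
#'
#' Occupancy rule on the strain x cluster presence/absence matrix: a
#' cluster with genes from every strain is `core`; from exactly one strain
#' (paralogs count once) `strain_specific`; anything in between
#' `dispensable`.  With a single input strain the two rules coincide;
#' precedence goes to `core` with a warning.
#'
#' @param cluster_set a `cluster_set` from [greedy_cluster()]
#' @param gene_source_map named character vector gene id -> strain; when
#'   `NULL`, the `source` column carried by the cluster set is used
#' @param strain_list character vector of all strains (defines matrix row
#'   order); defaults to the sorted set of observed sources
#' @return list of class `pangenome_partition`: `classes` (named character
#'   per cluster id), `presence` (strain x cluster 0/1 matrix), `counts`
#'   (named vector core/dispensable/strain_specific)
#' @export
classify_clusters <- function(cluster_set, gene_source_map = NULL,
                              strain_list = NULL) {
  m <- cluster_set$members
  src <- if (is.null(gene_source_map)) {
    stats::setNames(m$source, m$gene_id)
  } else gene_source_map
  if (any(!m$gene_id %in% names(src)))
    stop("gene with no source mapping: ",
         m$gene_id[!m$gene_id %in% names(src)][1])
  gene_strain <- unname(src[m$gene_id])
  if (is.null(strain_list)) strain_list <- sort(unique(gene_strain))
  if (any(!gene_strain %in% strain_list))
    stop("gene with unknown source: ",
         m$gene_id[!gene_strain %in% strain_list][1])
  clusters <- sort(unique(m$cluster_id))
  presence <- matrix(0L, nrow = length(strain_list),
                     ncol = length(clusters),
                     dimnames = list(strain_list,
                                     paste0("cluster_", clusters)))
  idx <- cbind(match(gene_strain, strain_list), match(m$cluster_id, clusters))
  presence[idx] <- 1L
  occ <- colSums(presence)
  n <- length(strain_list)
  if (n == 1L) {
    warning("single-strain input: every cluster classified as core")
    classes <- rep("core", length(clusters))
  } else {
    classes <- ifelse(occ == n, "core",
                      ifelse(occ == 1L, "strain_specific", "dispensable"))
  }
  names(classes) <- colnames(presence)
  counts <- c(core = sum(classes == "core"),
              dispensable = sum(classes == "dispensable"),
              strain_specific = sum(classes == "strain_specific"))
  structure(list(classes = classes, presence = presence, counts = counts),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat("pangenome_partition:", paste(names(x$counts), x$counts,
                                    sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Write a pangenome partition as TSV
#'
#' Columns: cluster_id, class, occupancy (presence/absence bitstring in
#' strain order).
#' @param partition a `pangenome_partition`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_partition_tsv <- function(partition, path) {
  bits <- apply(partition$presence, 2, paste, collapse = "")
  out <- data.frame(cluster_id = colnames(partition$presence),
                    class = unname(partition$classes),
                    occupancy = unname(bits), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Jaccard similarity on dispensable gene content
#'
#' J(s, t) = |D_s intersect D_t| / |D_s union D_t| where D_x is the set of
#' dispensable clusters containing at least one gene of strain x.  The
#' diagonal is 1 by definition (also when D_s is empty, with a warning);
#' off-diagonal 0/0 is defined as 0.
#'
#' @param partition a `pangenome_partition` (>= 2 strains)
#' @return symmetric strain x strain matrix in `[0, 1]`
#' @export
jaccard_matrix <- function(partition) {
  pres <- partition$presence[, partition$classes == "dispensable",
                             drop = FALSE]
  strains <- rownames(pres)
  if (length(strains) < 2) stop("need >= 2 strains")
  empty <- rowSums(pres) == 0
  if (any(empty))
    warning("strain(s) with no dispensable clusters: ",
            paste(strains[empty], collapse = ", "))
  n <- length(strains)
  inter <- pres %*% t(pres)
  sizes <- rowSums(pres)
  uni <- outer(sizes, sizes, `+`) - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  diag(J) <- 1
  dimnames(J) <- list(strains, strains)
  J
}

#' Bi-cluster a labeled matrix
#'
#' Agglomerative average-linkage (UPGMA-style) clustering on Euclidean
#' distances between rows and, independently, between columns — the
#' ordering used for Jaccard / coverage heatmaps.  Rows and columns are
#' pre-sorted by label so ties resolve deterministically.
#'
#' @param mat square or rectangular labeled numeric matrix (>= 2 rows)
#' @return list with `row_hclust`, `col_hclust` (stats::hclust objects),
#'   `row_order`, `col_order` (label vectors in dendrogram order)
#' @export
biclust_order <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2) stop("matrix must have >= 2 rows")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must be labeled")
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  rh <- hclust(dist(mat, method = "euclidean"), method = "average")
  ch <- hclust(dist(t(mat), method = "euclidean"), method = "average")
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(mat)[rh$order],
       col_order = colnames(mat)[ch$order])
}

#' Export a bi-clustering dendrogram as Newick
#' @param hc an `hclust` object (e.g. from [biclust_order()])
#' @param path file path
#' @return `path`, invisibly
#' @export
write_dendrogram_newick <- function(hc, path) {
  write_newick(ape::as.phylo(hc), path)
}
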