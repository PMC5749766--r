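#' Clustering parameters
#'
#' @param identity identity threshold c in (0, 1]: minimum fraction of
#'   identical aligned residue pairs over the length of the shorter
#'   sequence (the "70 over 70" family of regimes uses 0.4/0.7/0.9/0.95)
#' @param coverage coverage threshold a in (0, 1]: minimum fraction of the
#'   shorter sequence aligned to residues (not gaps)
#' @param kmer_size word length of the lossless k-mer prefilter (>= 2)
#' @return validated list of class `cluster_params`
#' @export
cluster_params <- function(identity = 0.7, coverage = 0.7, kmer_size = 2L) {
  stopifnot(is.numeric(identity), length(identity) == 1L,
            identity > 0, identity <= 1,
            is.numeric(coverage), length(coverage) == 1L,
            coverage > 0, coverage <= 1,
            kmer_size >= 2)
  structure(list(identity = identity, coverage = coverage,
                 kmer_size = as.integer(kmer_size)),
            class = "cluster_params")
}

#' Pairwise global identity and coverage
#'
#' Global Needleman-Wunsch alignment (BLOSUM62, affine gaps open 11 /
#' extend 1, BLAST gap-cost convention; see [blosum62()]).  Identity is the
#' number of identical aligned residue pairs divided by the length of the
#' shorter sequence; coverage is the number of residue-residue aligned
#' positions of the shorter sequence divided by its length.  Among
#' score-optimal alignments the one maximising (identical pairs, aligned
#' pairs) lexicographically is scored, which makes both values
#' path-independent and exactly reproducible.  Symmetric in its arguments.
#'
#' @param seq_a,seq_b nonempty residue strings
#' @return named numeric vector: `identity`, `coverage`, `score`,
#'   `n_identical`, `n_aligned`
#' @examples
#' pairwise_identity("AAAAAAAAAA", "AAAAAAAAAC")["identity"]  # 0.9
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  gp <- gap_penalties()
  .nw_stats_cpp(seq_a, seq_b, .blosum62, aa_alphabet(),
                gp[["open"]], gp[["ext"]])
}

#' Lossless k-mer prefilter
#'
#' Fast screen used before full alignment.  Counts positions of the shorter
#' sequence whose k-mer occurs in the longer sequence and fails the pair
#' only when that count is provably below the minimum implied by the
#' identity threshold: with t = ceiling(c * m) identical alignment columns
#' (m = shorter length, n = longer length), the identical columns form runs
#' broken at most (n + m - 2t + 1) times, so at least
#' t - (k - 1) * (n + m - 2t + 1) intact shared k-mers must exist.  When the
#' bound is non-positive the filter passes unconditionally, so a pair that
#' meets the identity threshold is never excluded (no false negatives).
#'
#' @param seq_a,seq_b residue strings
#' @param params a [cluster_params()] object
#' @return `TRUE` (candidate pair) or `FALSE` (provably below threshold)
#' @export
kmer_prefilter <- function(seq_a, seq_b, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  .kmer_prefilter_cpp(seq_a, seq_b, aa_alphabet(), params$kmer_size,
                      params$identity)
}

new_cluster_set <- function(members) {
  stopifnot(is.data.frame(members))
  structure(list(members = members,
                 n_clusters = length(unique(members$cluster_id))),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", nrow(x$members), "genes in", x$n_clusters,
      "clusters\n")
  invisible(x)
}

#' Number of clusters in a cluster set
#' @param cluster_set a `cluster_set`
#' @return integer count
#' @export
n_clusters <- function(cluster_set) cluster_set$n_clusters

#' Greedy incremental clustering
#'
#' CD-HIT-style greedy clustering in accurate ("best matching
#' representative") mode.  Records are sorted by decreasing sequence length
#' (ties by id, C-locale); the first record founds cluster 1; each
#' subsequent record is compared (after the lossless k-mer prefilter) to
#' all existing representatives and joins the representative with the
#' highest identity among those meeting both the identity and coverage
#' thresholds, otherwise founds a new cluster.  Ties between equally good
#' representatives go to the lower cluster index.  The result is
#' deterministic and invariant to the input order.
#'
#' @param records gene-record data.frame (see [gene_records()])
#' @param params a [cluster_params()] object
#' @return a `cluster_set`: list with `members` (data.frame `cluster_id`,
#'   `gene_id`, `source`, `length`, `identity`, `coverage`,
#'   `is_representative`) and `n_clusters`
#' @export
greedy_cluster <- function(records, params = cluster_params()) {
  records <- validate_gene_records(records)
  stopifnot(inherits(params, "cluster_params"))
  len <- nchar(records$sequence)
  ord <- order(-len, records$id, method = "radix")
  records <- records[ord, , drop = FALSE]
  gp <- gap_penalties()
  res <- .greedy_cluster_cpp(records$sequence, .blosum62, aa_alphabet(),
                             gp[["open"]], gp[["ext"]],
                             params$identity, params$coverage,
                             params$kmer_size)
  members <- data.frame(
    cluster_id = res$cluster,
    gene_id = records$id,
    source = records$source,
    length = nchar(records$sequence),
    identity = res$identity,
    coverage = res$coverage,
    is_representative = res$is_representative,
    stringsAsFactors = FALSE)
  new_cluster_set(members)
}
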