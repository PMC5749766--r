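#' Joint clustering coverage profile
#'
#' Clusters the union of reference strain proteomes and metagenome sample
#' proteins with [greedy_cluster()], then reports for each strain s and
#' sample m the coverage ratio
#' `r_s(m) = 100 * (# genes of s in clusters containing >= 1 gene of m) /
#' (total genes of s)` — the "ratio of genes clustered (%)" heatmap
#' statistic.  Two companion identity matrices are computed (the averaging
#' convention is not uniquely defined in the field, so both are reported):
#' `identity`: for each counted strain gene, the maximum pairwise identity
#' to a sample gene of m in its cluster, averaged (percent);
#' `identity_rep`: mean identity-to-representative of m's sample genes in
#' clusters shared with s (percent).
#'
#' @param reference_proteomes named list of gene-record data.frames (one
#'   per strain, `source` = strain) or a single combined data.frame
#' @param sample_proteins gene-record data.frame (or named list) with
#'   `source` = sample label; several samples may be mixed
#' @param params a [cluster_params()]
#' @return list of class `coverage_profile`: `ratio`, `identity`,
#'   `identity_rep` (strain x sample matrices), `cluster_set`
#' @export
joint_cluster_profile <- function(reference_proteomes, sample_proteins,
                                  params = cluster_params()) {
  bind <- function(x, what) {
    if (is.data.frame(x)) {
      if (nrow(x) == 0) stop("empty ", what)
      return(x)
    }
    if (length(x) == 0) stop("empty ", what)
    empty <- vapply(x, function(e) nrow(e) == 0, logical(1))
    if (any(empty))
      stop("empty strain proteome: ",
           paste(names(x)[empty], collapse = ", "))
    do.call(rbind, unname(x))
  }
  refs <- validate_gene_records(bind(reference_proteomes,
                                     "reference proteomes"))
  smps <- validate_gene_records(bind(sample_proteins, "sample proteins"))
  strains <- unique(refs$source)
  samples <- unique(smps$source)
  all_rec <- validate_gene_records(rbind(refs, smps))
  cs <- greedy_cluster(all_rec, params)
  m <- cs$members
  seq_of <- stats::setNames(all_rec$sequence, all_rec$id)
  is_sample <- m$source %in% samples

  ratio <- identity <- identity_rep <-
    matrix(NA_real_, length(strains), length(samples),
           dimnames = list(strains, samples))
  for (q in samples) {
    q_clusters <- unique(m$cluster_id[m$source == q])
    for (s in strains) {
      sg <- m[m$source == s, , drop = FALSE]
      in_q <- sg$cluster_id %in% q_clusters
      ratio[s, q] <- 100 * sum(in_q) / nrow(sg)
      if (!sum(in_q)) {
        identity[s, q] <- NA_real_
        identity_rep[s, q] <- NA_real_
        next
      }
      best <- vapply(which(in_q), function(i) {
        qi <- m$gene_id[m$cluster_id == sg$cluster_id[i] & m$source == q]
        max(vapply(qi, function(g)
          pairwise_identity(seq_of[[sg$gene_id[i]]],
                            seq_of[[g]])[["identity"]], numeric(1)))
      }, numeric(1))
      identity[s, q] <- 100 * mean(best)
      shared <- m$cluster_id %in% sg$cluster_id[in_q]
      qm <- m[shared & m$source == q, , drop = FALSE]
      identity_rep[s, q] <- 100 * mean(qm$identity)
    }
  }
  structure(list(ratio = ratio, identity = identity,
                 identity_rep = identity_rep, cluster_set = cs),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", nrow(x$ratio), "strains x", ncol(x$ratio),
      "samples; ratio (%):\n")
  print(round(x$ratio, 1))
  invisible(x)
}

#' Contig best-hit homology summary
#'
#' From a 12-column tabular hit table: drops contigs shorter than
#' `min_contig_length`, drops hits failing the E-value / identity
#' thresholds, retains one best hit per contig (lowest E-value, ties by
#' highest bitscore, then highest identity, then subject id), and reports
#' per reference genome the retained-hit count, the percent of the genome
#' covered by the merged subject intervals (overlaps counted once;
#' reverse-strand coordinates normalised), and the mean percent identity.
#'
#' @param hits hit data.frame from [read_tabular_hits()]
#' @param min_identity minimum percent identity (e.g. 40)
#' @param max_evalue maximum E-value (e.g. 1e-10)
#' @param min_contig_length minimum contig length in bp (e.g. 1000)
#' @param contig_lengths named vector, contig id -> length
#' @param genome_lengths named vector, genome id -> length
#' @return data.frame with one row per genome in `genome_lengths`:
#'   `genome`, `n_contigs`, `covered_pct`, `mean_identity`
#' @export
summarize_contig_hits <- function(hits, min_identity = 40,
                                  max_evalue = 1e-10,
                                  min_contig_length = 1000,
                                  contig_lengths, genome_lengths) {
  unknown <- setdiff(unique(hits$sseqid), names(genome_lengths))
  if (length(unknown))
    stop("hit references unknown genome: ", paste(unknown, collapse = ", "))
  unknown <- setdiff(unique(hits$qseqid), names(contig_lengths))
  if (length(unknown))
    stop("hit references unknown contig: ", paste(unknown, collapse = ", "))
  keep <- contig_lengths[hits$qseqid] >= min_contig_length &
    hits$evalue <= max_evalue & hits$pident >= min_identity
  h <- hits[keep, , drop = FALSE]
  out <- data.frame(genome = names(genome_lengths), n_contigs = 0L,
                    covered_pct = 0, mean_identity = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(h)) {
    ord <- order(h$qseqid, h$evalue, -h$bitscore, -h$pident, h$sseqid,
                 method = "radix")
    h <- h[ord, , drop = FALSE]
    h <- h[!duplicated(h$qseqid), , drop = FALSE]  # per-contig best hit
    for (g in names(genome_lengths)) {
      hg <- h[h$sseqid == g, , drop = FALSE]
      if (!nrow(hg)) next
      s0 <- pmin(hg$sstart, hg$send)
      e0 <- pmax(hg$sstart, hg$send)
      merged <- IRanges::reduce(IRanges::IRanges(start = s0, end = e0))
      i <- out$genome == g
      out$n_contigs[i] <- nrow(hg)
      out$covered_pct[i] <-
        100 * sum(IRanges::width(merged)) / genome_lengths[[g]]
      out$mean_identity[i] <- mean(hg$pident)
    }
  }
  out
}
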