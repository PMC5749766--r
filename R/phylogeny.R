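#' Progressive multiple alignment of a core cluster
#'
#' Minimal progressive aligner: a 3-mer-sharing distance feeds a UPGMA
#' guide tree; profiles are merged by global profile-profile
#' Needleman-Wunsch (BLOSUM62 column means, affine gaps 11/1).  Parity with
#' production aligners is not a goal — tests use either prealigned input or
#' divergence regimes where the optimum is unambiguous.  A single sequence
#' is returned unchanged with a warning.
#'
#' @param records gene-record data.frame (>= 1 rows); rows of the result
#'   are named by `source` when sources are unique (the one-gene-per-strain
#'   core-cluster case), else by gene id
#' @return named character vector of equal-length aligned strings
#'   (gap symbol `-`)
#' @export
align_core_cluster <- function(records) {
  records <- validate_gene_records(records)
  nm <- if (!anyDuplicated(records$source)) records$source else records$id
  if (nrow(records) == 1L) {
    warning("single sequence: returned unaligned")
    return(stats::setNames(records$sequence, nm))
  }
  alpha <- strsplit(aa_alphabet(), "")[[1]]
  enc <- lapply(strsplit(records$sequence, ""), function(ch)
    matrix(match(ch, alpha) - 1L, nrow = 1))
  n <- length(enc)

  kmers <- lapply(records$sequence, function(s) {
    L <- nchar(s)
    if (L < 3) return(character(0))
    unique(substring(s, 1:(L - 2), 3:L))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(kmers[[i]], kmers[[j]]))
    lo <- min(length(kmers[[i]]), length(kmers[[j]]))
    d[i, j] <- d[j, i] <- if (lo == 0) 1 else 1 - shared / lo
  }
  hc <- hclust(stats::as.dist(d), method = "average")

  gp <- gap_penalties()
  profiles <- vector("list", n - 1)   # result of each merge step
  rows_of <- vector("list", n - 1)    # original record index per profile row
  fetch <- function(k) {
    if (k < 0) list(p = enc[[-k]], r = -k)
    else list(p = profiles[[k]], r = rows_of[[k]])
  }
  for (s in seq_len(nrow(hc$merge))) {
    a <- fetch(hc$merge[s, 1]); b <- fetch(hc$merge[s, 2])
    res <- .profile_nw_cpp(a$p, b$p, .blosum62, gp[["open"]], gp[["ext"]])
    w <- length(res$a_col)
    pa <- matrix(20L, nrow(a$p), w)
    ok <- !is.na(res$a_col)
    pa[, ok] <- a$p[, res$a_col[ok], drop = FALSE]
    pb <- matrix(20L, nrow(b$p), w)
    ok <- !is.na(res$b_col)
    pb[, ok] <- b$p[, res$b_col[ok], drop = FALSE]
    profiles[[s]] <- rbind(pa, pb)
    rows_of[[s]] <- c(a$r, b$r)
  }
  final <- profiles[[n - 1]]
  ord <- order(rows_of[[n - 1]])
  final <- final[ord, , drop = FALSE]
  symbols <- c(alpha, "-")
  out <- apply(final, 1, function(v) paste(symbols[v + 1L], collapse = ""))
  stats::setNames(out, nm)
}

#' Validate an externally produced alignment
#'
#' Accepts a named character vector of equal-length gapped residue strings
#' (e.g. read from a prealigned FASTA) and checks lengths, names and
#' alphabet.
#'
#' @param x named character vector
#' @return `x`, invisibly validated
#' @export
validate_alignment <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("alignment rows must be named")
  if (anyDuplicated(names(x))) stop("duplicate alignment row names")
  if (length(unique(nchar(x))) != 1L)
    stop("aligned sequences must have equal length")
  ok <- grepl(paste0("^[-", aa_alphabet(), "]+$"), x)
  if (any(!ok)) stop("alignment row '", names(x)[!ok][1],
                     "' contains invalid symbols")
  x
}

#' Concatenate per-cluster alignments into a supermatrix
#'
#' Joins each strain's aligned sequences over all core clusters in a fixed
#' cluster order and records the cluster boundary offsets.
#'
#' @param alignments named list of alignments (each a named character
#'   vector covering every strain exactly once)
#' @param strain_list strains (row order of the result)
#' @param cluster_order order in which clusters are joined; defaults to
#'   `names(alignments)`
#' @return list of class `concat_alignment`: `sequences` (named character),
#'   `boundaries` (0-based offsets, length `n_clusters + 1`),
#'   `cluster_order`
#' @export
concatenate <- function(alignments, strain_list,
                        cluster_order = names(alignments)) {
  stopifnot(length(alignments) >= 1, !is.null(names(alignments)))
  if (!all(cluster_order %in% names(alignments)))
    stop("cluster_order names unknown cluster(s)")
  parts <- stats::setNames(
    rep(list(character(0)), length(strain_list)), strain_list)
  widths <- integer(length(cluster_order))
  for (k in seq_along(cluster_order)) {
    cl <- cluster_order[k]
    al <- validate_alignment(alignments[[cl]])
    for (s in strain_list) {
      if (!s %in% names(al))
        stop("cluster '", cl, "' is missing strain '", s, "'")
      parts[[s]] <- c(parts[[s]], al[[s]])
    }
    widths[k] <- nchar(al[[1]])
  }
  seqs <- vapply(parts, paste, character(1), collapse = "")
  structure(list(sequences = seqs,
                 boundaries = c(0L, cumsum(widths)),
                 cluster_order = cluster_order),
            class = "concat_alignment")
}

# named character alignment -> single-character matrix (rows = taxa)
alignment_matrix <- function(x) {
  seqs <- if (inherits(x, "concat_alignment")) x$sequences else x
  validate_alignment(seqs)
  do.call(rbind, strsplit(seqs, ""))
}

# Poisson-corrected distances over selected columns of a char matrix
pairwise_poisson <- function(m, cols = seq_len(ncol(m))) {
  taxa <- rownames(m)
  n <- length(taxa)
  p <- d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  sub <- m[, cols, drop = FALSE]
  nog <- sub != "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- nog[i, ] & nog[j, ]
    nshared <- sum(use)
    if (nshared == 0)
      stop("zero shared (ungapped) columns for pair (", taxa[i], ", ",
           taxa[j], ")")
    pij <- sum(sub[i, use] != sub[j, use]) / nshared
    p[i, j] <- p[j, i] <- pij
    if (pij >= 1) {
      sat[i, j] <- sat[j, i] <- TRUE
      d[i, j] <- d[j, i] <- NA_real_
    } else d[i, j] <- d[j, i] <- -log(1 - pij)
  }
  list(d = d, p = p, saturated = sat)
}

#' Poisson-corrected distance matrix
#'
#' For each taxon pair only columns where both sequences are ungapped are
#' used (pairwise deletion); p = mismatches / used columns and
#' d = -ln(1 - p) (the Poisson correction, uniform rates).  A pair with
#' p = 1 is flagged saturated and gets `NA`; a pair with zero shared
#' columns is an error naming the pair.
#'
#' @param x a `concat_alignment` or named character alignment (>= 2 rows)
#' @return symmetric distance matrix `d` (zero diagonal) with attributes
#'   `p` (p-distance matrix) and `saturated` (logical matrix)
#' @export
poisson_distance <- function(x) {
  m <- alignment_matrix(x)
  if (nrow(m) < 2) stop("need >= 2 strains")
  res <- pairwise_poisson(m)
  structure(res$d, p = res$p, saturated = res$saturated)
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with the Studier-Keppler
#' Q-criterion.  Taxa are processed in sorted-label order and Q-ties break
#' on the lexicographically lowest pair of subtree label sets, so the
#' result is deterministic and invariant to taxon input order.  Negative
#' branch lengths are clamped to 0 (MEGA-compatible) with a message.
#'
#' @param D symmetric labeled distance matrix (>= 3 taxa); `NA` entries
#'   (saturated distances) are an error
#' @return unrooted `phylo` tree
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  labels <- rownames(D)
  if (length(labels) < 3) stop("need >= 3 taxa")
  if (anyNA(D))
    stop("saturated (NA) distances present; filter saturated pairs before ",
         "tree building")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")
  ord <- order(labels)
  D <- D[ord, ord, drop = FALSE]
  frag <- rownames(D)
  keyset <- as.list(rownames(D))   # sorted leaf labels per active node
  clamped <- FALSE
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      k <- sort(c(paste(keyset[[ij[1]]], collapse = ","),
                  paste(keyset[[ij[2]]], collapse = ",")))
      paste(k, collapse = "|")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0 || bj < 0) clamped <- TRUE
    bi <- max(bi, 0); bj <- max(bj, 0)
    newfrag <- paste0("(", frag[i], ":", fmt(bi), ",",
                      frag[j], ":", fmt(bj), ")")
    newkey <- sort(c(keyset[[i]], keyset[[j]]))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    keyset <- c(keyset[keep], list(newkey))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "internal")
    D <- D2
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (min(b1, b2, b3) < 0) clamped <- TRUE
  if (clamped) message("negative branch length(s) clamped to 0")
  nwk <- paste0("(", frag[1], ":", fmt(max(b1, 0)), ",",
                frag[2], ":", fmt(max(b2, 0)), ",",
                frag[3], ":", fmt(max(b3, 0)), ");")
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One canonical string per internal edge: the tip set on the side not
#' containing the lexicographically smallest tip, sorted and joined with
#' commas.  Used for bootstrap support and Robinson-Foulds comparisons.
#'
#' @param tree a `phylo`
#' @return character vector of canonical splits (possibly empty)
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character(0))
  anchor <- sort(tree$tip.label)[1]
  desc <- function(node) {
    # tips below each internal node via one postorder pass
    kids <- split(tree$edge[, 2], tree$edge[, 1])
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v <= ntip) out <- c(out, v)
      else stack <- c(kids[[as.character(v)]], stack)
    }
    out
  }
  internal <- tree$edge[tree$edge[, 2] > ntip, 2]
  splits <- character(0)
  for (node in internal) {
    tips <- tree$tip.label[desc(node)]
    if (length(tips) < 2 || length(tips) > ntip - 2) next
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    splits <- c(splits, paste(sort(side), collapse = ","))
  }
  unique(splits)
}

#' Bootstrap support for a concatenated-alignment NJ tree
#'
#' Resamples alignment columns with replacement (whole columns, across all
#' strains), rebuilds Poisson-distance NJ trees, and reports for each
#' internal bipartition of the original tree the percentage of replicates
#' containing it.  Deterministic for a fixed seed.
#'
#' @param concat_alignment a `concat_alignment` or named character
#'   alignment with >= 2 columns
#' @param n_replicates number of bootstrap replicates (>= 1)
#' @param seed integer seed
#' @return list of class `bootstrap_tree`: `tree` (original NJ `phylo`
#'   with `node.label` set to supports), `support` (named vector,
#'   split -> percent in `[0, 100]`), `n_replicates`
#' @export
bootstrap_support <- function(concat_alignment, n_replicates = 100L,
                              seed = 1L) {
  stopifnot(n_replicates >= 1)
  m <- alignment_matrix(concat_alignment)
  if (ncol(m) < 2) stop("alignment must have >= 2 columns")
  tree <- neighbor_joining(pairwise_poisson(m)$d)
  orig <- tree_bipartitions(tree)
  hits <- stats::setNames(numeric(length(orig)), orig)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tb <- neighbor_joining(pairwise_poisson(m, cols)$d)
      found <- tree_bipartitions(tb)
      hits[orig %in% found] <- hits[orig %in% found] + 1
    }
  })
  support <- 100 * hits / n_replicates
  # annotate internal nodes of the original tree
  ntip <- length(tree$tip.label)
  tree$node.label <- rep("", tree$Nnode)
  anchor <- sort(tree$tip.label)[1]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc_tips <- function(node) {
    out <- character(0); stack <- node
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v <= ntip) out <- c(out, tree$tip.label[v])
      else stack <- c(kids[[as.character(v)]], stack)
    }
    out
  }
  for (node in unique(tree$edge[tree$edge[, 2] > ntip, 2])) {
    tips <- desc_tips(node)
    if (length(tips) < 2 || length(tips) > ntip - 2) next
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    key <- paste(sort(side), collapse = ",")
    if (key %in% names(support))
      tree$node.label[node - ntip] <- format(support[[key]])
  }
  structure(list(tree = tree, support = support,
                 n_replicates = as.integer(n_replicates)),
            class = "bootstrap_tree")
}

#' @export
print.bootstrap_tree <- function(x, ...) {
  cat("bootstrap_tree:", length(x$tree$tip.label), "taxa,",
      x$n_replicates, "replicates; support:",
      paste(sprintf("%g", unname(x$support)), collapse = " "), "\n")
  invisible(x)
}
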