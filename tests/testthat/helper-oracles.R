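# Independent reference implementations used to cross-check the package.
# They share only the *definitions* (BLOSUM62, BLAST gap costs, the
# lexicographic (score, identical, aligned) objective), never the code.

# quadratic-DP global aligner, pure R
oracle_nw <- function(a, b, sm = blosum62(), open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  mk <- function() list(s = matrix(NEG, n + 1, m + 1),
                        id = matrix(0L, n + 1, m + 1),
                        al = matrix(0L, n + 1, m + 1))
  M <- mk(); E <- mk(); F <- mk()
  M$s[1, 1] <- 0
  for (i in seq_len(n)) E$s[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) F$s[1, j + 1] <- -(open + ext * j)
  pick <- function(...) {
    cands <- list(...)
    best <- cands[[1]]
    for (k in 2:length(cands)) {
      ck <- cands[[k]]
      if (ck[1] > best[1] ||
          (ck[1] == best[1] && ck[2] > best[2]) ||
          (ck[1] == best[1] && ck[2] == best[2] && ck[3] > best[3]))
        best <- ck
    }
    best
  }
  at <- function(X, i, j) c(X$s[i, j], X$id[i, j], X$al[i, j])
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- sm[A[i - 1], B[j - 1]]
    inc <- as.integer(A[i - 1] == B[j - 1])
    d <- pick(at(M, i - 1, j - 1), at(E, i - 1, j - 1), at(F, i - 1, j - 1))
    if (d[1] > NEG / 2) {
      M$s[i, j] <- d[1] + sc; M$id[i, j] <- d[2] + inc; M$al[i, j] <- d[3] + 1
    }
    e <- pick(at(M, i - 1, j) - c(open + ext, 0, 0),
              at(E, i - 1, j) - c(ext, 0, 0),
              at(F, i - 1, j) - c(open + ext, 0, 0))
    E$s[i, j] <- e[1]; E$id[i, j] <- e[2]; E$al[i, j] <- e[3]
    f <- pick(at(M, i, j - 1) - c(open + ext, 0, 0),
              at(F, i, j - 1) - c(ext, 0, 0),
              at(E, i, j - 1) - c(open + ext, 0, 0))
    F$s[i, j] <- f[1]; F$id[i, j] <- f[2]; F$al[i, j] <- f[3]
  }
  fin <- pick(at(M, n + 1, m + 1), at(E, n + 1, m + 1), at(F, n + 1, m + 1))
  c(score = fin[1], n_identical = fin[2], n_aligned = fin[3],
    identity = fin[2] / min(n, m), coverage = fin[3] / min(n, m))
}

# brute-force average linkage: sorted merge heights on Euclidean distances
oracle_average_linkage_heights <- function(X) {
  d <- as.matrix(dist(X))
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- Inf; bi <- bj <- 0L
    for (ii in seq_len(length(active) - 1))
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    for (k in setdiff(active, c(bi, bj)))
      d[bi, k] <- d[k, bi] <-
        (size[bi] * d[bi, k] + size[bj] * d[bj, k]) / (size[bi] + size[bj])
    size[bi] <- size[bi] + size[bj]
    active <- setdiff(active, bj)
  }
  sort(heights)
}

# per-base bitmap genome coverage
oracle_bitmap_coverage <- function(starts, ends, genome_length) {
  hit <- logical(genome_length)
  for (k in seq_along(starts)) {
    s <- min(starts[k], ends[k]); e <- max(starts[k], ends[k])
    hit[s:e] <- TRUE
  }
  100 * mean(hit)
}

# set-arithmetic Jaccard on dispensable membership lists
oracle_jaccard <- function(sets) {
  n <- length(sets)
  J <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- union(sets[[i]], sets[[j]])
    J[i, j] <- if (i == j) 1
      else if (length(u) == 0) 0
      else length(intersect(sets[[i]], sets[[j]])) / length(u)
  }
  J
}

# union-find single linkage at threshold: partition where genes join iff
# identity >= c and coverage >= a (edges from the already-verified aligner)
oracle_single_linkage <- function(records, c_thr, a_thr) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- pairwise_identity(records$sequence[i], records$sequence[j])
    if (w[["identity"]] >= c_thr - 1e-12 && w[["coverage"]] >= a_thr - 1e-12) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(records$id, comp)
}

# canonical partition representation for comparing clusterings
partition_key <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

cluster_set_groups <- function(cs) {
  unname(split(cs$members$gene_id, cs$members$cluster_id))
}

# Robinson-Foulds distance from canonical bipartition sets
rf_distance <- function(t1, t2) {
  b1 <- tree_bipartitions(t1); b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

random_seq <- function(n, alphabet = strsplit(aa_alphabet(), "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# point-mutate a sequence at a given per-site rate (no indels)
mutate_seq <- function(s, rate) {
  alpha <- strsplit(aa_alphabet(), "")[[1]]
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(alpha, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

make_hits <- function(qseqid, sseqid, pident, evalue, bitscore,
                      sstart = 1, send = 100, qstart = 1, qend = 100,
                      length = 100) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = 0, gapopen = 0,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}
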