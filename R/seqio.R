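#' Gene record collections
#'
#' The pipeline's basic container is a plain `data.frame` with columns
#' `id` (unique, nonempty), `source` (strain or sample label) and
#' `sequence` (nonempty residue string over the 20-letter alphabet of
#' [aa_alphabet()]).  `gene_records()` builds and validates one.
#'
#' @param id character vector of unique gene identifiers
#' @param source character vector (or scalar) of strain/sample labels
#' @param sequence character vector of residue strings
#' @return a validated `data.frame` with columns `id`, `source`, `sequence`
#' @export
gene_records <- function(id, source, sequence) {
  if (length(source) == 1L) source <- rep(source, length(id))
  df <- data.frame(id = as.character(id), source = as.character(source),
                   sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  validate_gene_records(df)
}

#' @rdname gene_records
#' @param records data.frame to validate
#' @export
validate_gene_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "source", "sequence") %in% names(records)))
  if (any(!nzchar(records$id))) stop("gene id must be nonempty")
  dup <- records$id[duplicated(records$id)]
  if (length(dup))
    stop("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(records$sequence))) {
    bad <- records$id[!nzchar(records$sequence)][1]
    stop("empty sequence for gene '", bad, "'")
  }
  ok <- grepl(paste0("^[", aa_alphabet(), "]+$"), records$sequence)
  if (any(!ok))
    stop("sequence of gene '", records$id[!ok][1],
         "' contains residues outside the alphabet ", aa_alphabet())
  records
}

#' Read and write protein FASTA
#'
#' `read_fasta()` parses a (optionally gzipped) FASTA file into gene
#' records.  The id is the header token before the first whitespace;
#' wrapped sequence lines are joined.  Duplicate ids and empty files are
#' errors, never repaired.
#'
#' @param path file path
#' @param source_label label recorded in the `source` column
#' @return `read_fasta()`: a gene-record data.frame; `write_fasta()`:
#'   `path`, invisibly
#' @export
read_fasta <- function(path, source_label) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  gene_records(ids, source_label, as.character(set))
}

#' @rdname read_fasta
#' @param records gene-record data.frame
#' @export
write_fasta <- function(records, path) {
  records <- validate_gene_records(records)
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read 12-column BLAST-style tabular hits
#'
#' Parses the standard "outfmt 6" layout: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' Malformed lines are reported with their line number; an empty file is an
#' empty table, not an error.  Coordinates are kept 1-based inclusive as in
#' BLAST (subject coordinates may be reversed on the minus strand).
#'
#' @param path file path (plain or gzipped TSV)
#' @return data.frame with typed columns named as above
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12), cols), stringsAsFactors = FALSE)
    num <- c(3:10, 11, 12)
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stop("line ", i, ": expected 12 tab-separated columns, got ", nf[i])
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (j in 3:12) out[[cols[j]]] <- as.numeric(m[, j])
  bad <- which(is.na(out$pident) | out$pident < 0 | out$pident > 100)
  if (length(bad)) stop("line ", bad[1], ": percent identity out of [0,100]")
  bad <- which(is.na(out$evalue) | out$evalue < 0)
  if (length(bad)) stop("line ", bad[1], ": evalue must be >= 0")
  coord <- c("qstart", "qend", "sstart", "send")
  bad <- which(apply(is.na(out[coord]) | out[coord] < 1, 1, any))
  if (length(bad)) stop("line ", bad[1], ": coordinates must be positive")
  out
}

#' @rdname read_tabular_hits
#' @param hits hit table as returned by `read_tabular_hits()`
#' @export
write_tabular_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cluster-file exchange (CD-HIT ".clstr" style)
#'
#' `write_cluster_file()` serialises a cluster set in the familiar `.clstr`
#' block layout (representative flagged `*`, members annotated with their
#' identity to the representative, written at full precision);
#' `read_cluster_file()` inverts it.  Membership, representative flags and
#' identity values round-trip exactly; member coverage is not carried by
#' this format (use [write_cluster_tsv()] for the full table).
#'
#' @param cluster_set a cluster set (see [greedy_cluster()])
#' @param path file path
#' @return `read_cluster_file()`: a cluster set; writers return `path`
#'   invisibly
#' @export
write_cluster_file <- function(cluster_set, path) {
  m <- cluster_set$members
  con <- file(path, "wt")
  on.exit(close(con))
  for (cl in sort(unique(m$cluster_id))) {
    block <- m[m$cluster_id == cl, , drop = FALSE]
    rep_row <- block[block$is_representative, , drop = FALSE]
    if (nrow(rep_row) != 1L)
      stop("cluster ", cl, " must have exactly one representative")
    writeLines(sprintf(">Cluster %d", cl - 1L), con)
    block <- block[order(!block$is_representative, block$gene_id), ,
                   drop = FALSE]
    k <- 0L
    for (i in seq_len(nrow(block))) {
      tail <- if (block$is_representative[i]) "*" else
        sprintf("at %.10g%%", 100 * block$identity[i])
      writeLines(sprintf("%d\t%daa, >%s... %s", k, block$length[i],
                         block$gene_id[i], tail), con)
      k <- k + 1L
    }
  }
  invisible(path)
}

#' @rdname write_cluster_file
#' @export
read_cluster_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- list()
  cl <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">Cluster")) {
      cl <- as.integer(sub("^>Cluster\\s+", "", ln)) + 1L
      if (is.na(cl)) stop("line ", i, ": malformed cluster header")
      next
    }
    if (cl == 0L) stop("line ", i, ": member line before any cluster header")
    m <- regmatches(ln, regexec(
      "^\\d+\t(\\d+)aa, >(.+)\\.\\.\\. (\\*|at ([0-9.eE+-]+)%)$", ln))[[1]]
    if (length(m) == 0L) stop("line ", i, ": malformed member line")
    is_rep <- m[4] == "*"
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cl, gene_id = m[3], length = as.integer(m[2]),
      identity = if (is_rep) 1.0 else as.numeric(m[5]) / 100,
      coverage = NA_real_, is_representative = is_rep,
      stringsAsFactors = FALSE)
  }
  members <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), gene_id = character(0),
               length = integer(0), identity = numeric(0),
               coverage = numeric(0), is_representative = logical(0),
               stringsAsFactors = FALSE)
  new_cluster_set(members)
}

#' @rdname write_cluster_file
#' @export
write_cluster_tsv <- function(cluster_set, path) {
  m <- cluster_set$members
  out <- data.frame(gene_id = m$gene_id, cluster_id = m$cluster_id,
                    identity = m$identity, coverage = m$coverage)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Labeled numeric matrix TSV
#'
#' Fixed exchange layout: first row = column labels, first column = row
#' labels, tab separated, "." decimal separator.  Duplicate labels are
#' rejected.
#'
#' @param mat numeric matrix with row and column names
#' @param path file path
#' @return `read_matrix_tsv()`: the matrix; `write_matrix_tsv()`: `path`,
#'   invisibly
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("duplicate row or column labels")
  df <- data.frame(label = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("", colnames(mat)), dec = ".")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs a label column and >= 1 column")
  rn <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  if (anyDuplicated(rn) || anyDuplicated(colnames(m)))
    stop("duplicate row or column labels")
  m
}

#' Newick tree I/O
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] so every
#' module exchanges trees through one door.
#'
#' @param path file path
#' @return `read_newick()`: an [ape::read.tree()] `phylo`;
#'   `write_newick()`: `path`, invisibly
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
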