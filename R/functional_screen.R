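#' Bundled KO catalogs
#'
#' Two curated KEGG-ortholog catalogs ship with the package as versioned
#' TSVs (columns `ko_id`, `symbol`, `family`), so screening never queries
#' KEGG at run time:
#'
#' * `"phycobilisome"` — the light-harvesting antenna gene set: 6
#'   allophycocyanin (apcA-apcF), 7 phycocyanin (cpcA-cpcG incl. the linker
#'   cpcD = K02287), 11 phycoerythrin (cpeA-cpeZ incl. cpeU = K05384,
#'   cpeS, cpeT), 2 phycoerythrobilin biosynthesis (pebA, pebB); 26 KOs.
#' * `"recombination"` — the recBCD / homologous-recombination and
#'   replication-restart set: recB/recC/recD (K03581-K03583) plus the
#'   exodeoxyribonuclease-V ortholog K01144, the DNA-polymerase-III
#'   subunits (DPO3A2, rnhA-dnaQ, DPO3T, DPO3C, DPO3P, DPO3E) and the
#'   primosomal genes priB, priC, dnaT.
#'
#' @param name catalog name
#' @return data.frame of class `ko_catalog` with columns `ko_id`,
#'   `symbol`, `family`, in catalog row order
#' @export
ko_catalog <- function(name = c("phycobilisome", "recombination")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("ko_catalog_", name, ".tsv"),
                      package = "panmeta", mustWork = TRUE)
  cat_df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("ko_id", "symbol", "family") %in% names(cat_df)))
  if (anyDuplicated(cat_df$ko_id))
    stop("duplicate KO id in catalog ", name)
  structure(cat_df, class = c("ko_catalog", "data.frame"), name = name)
}

normalize_ko_map <- function(ko_map) {
  if (is.data.frame(ko_map)) {
    stopifnot(all(c("protein_id", "ko_id") %in% names(ko_map)))
    stats::setNames(as.character(ko_map$ko_id),
                    as.character(ko_map$protein_id))
  } else ko_map
}

#' Assign a KO to one query from its alignment hits
#'
#' Hits are filtered by the active thresholds (strain-protein mode:
#' `evalue < max_evalue`; metagenome mode additionally
#' `pident > min_identity`), then ranked by E-value ascending, identity
#' descending, subject id ascending.  The rank-1 hit's subject KO is
#' assigned; when the rank-1 subject has no KO mapping the rank-2 hit is
#' consulted once (no deeper fallback); otherwise the query is unassigned.
#'
#' @param hits_for_query hit data.frame rows for a single query
#' @param ko_map named character vector (subject id -> KO id) or a
#'   data.frame with columns `protein_id`, `ko_id`
#' @param max_evalue E-value cutoff (hits must be strictly below)
#' @param min_identity percent-identity cutoff (strictly above), or `NULL`
#'   to skip the identity filter (strain-protein mode)
#' @return one-row data.frame: `query_id`, `ko_id` (`NA` if unassigned),
#'   `rank` (1, 2 or `NA`), `subject_id`, `evalue`, `pident`
#' @export
assign_ko <- function(hits_for_query, ko_map, max_evalue = 1e-10,
                      min_identity = NULL) {
  ko_map <- normalize_ko_map(ko_map)
  if (nrow(hits_for_query) == 0)
    return(data.frame(query_id = NA_character_, ko_id = NA_character_,
                      rank = NA_integer_, subject_id = NA_character_,
                      evalue = NA_real_, pident = NA_real_,
                      stringsAsFactors = FALSE))
  qid <- unique(hits_for_query$qseqid)
  if (length(qid) != 1) stop("hits_for_query must cover a single query")
  h <- hits_for_query[hits_for_query$evalue < max_evalue, , drop = FALSE]
  if (!is.null(min_identity))
    h <- h[h$pident > min_identity, , drop = FALSE]
  unassigned <- data.frame(query_id = qid, ko_id = NA_character_,
                           rank = NA_integer_, subject_id = NA_character_,
                           evalue = NA_real_, pident = NA_real_,
                           stringsAsFactors = FALSE)
  if (nrow(h) == 0) return(unassigned)
  h <- h[order(h$evalue, -h$pident, h$sseqid, method = "radix"), ,
         drop = FALSE]
  for (rank in seq_len(min(2L, nrow(h)))) {
    sid <- h$sseqid[rank]
    ko <- if (sid %in% names(ko_map)) ko_map[[sid]] else NA_character_
    if (!is.na(ko))
      return(data.frame(query_id = qid, ko_id = ko, rank = rank,
                        subject_id = h$sseqid[rank],
                        evalue = h$evalue[rank], pident = h$pident[rank],
                        stringsAsFactors = FALSE))
  }
  unassigned
}

#' @rdname assign_ko
#' @param hits hit data.frame covering many queries
#' @return `assign_ko_table()`: one row per distinct query, in sorted
#'   query order
#' @export
assign_ko_table <- function(hits, ko_map, max_evalue = 1e-10,
                            min_identity = NULL) {
  queries <- sort(unique(hits$qseqid))
  do.call(rbind, lapply(queries, function(q)
    assign_ko(hits[hits$qseqid == q, , drop = FALSE], ko_map,
              max_evalue, min_identity)))
}

#' KO presence/absence matrix
#'
#' Rows are catalog KOs in catalog order, columns the entities (strains or
#' samples) in the given order; a cell is 1 iff at least one query of the
#' entity was assigned that KO.  Assigned KOs absent from the catalog are
#' ignored with a message.
#'
#' @param assignments_by_entity data.frame with columns `entity` and
#'   `ko_id` (e.g. an [assign_ko_table()] result joined with entity
#'   labels); `NA` KOs are skipped
#' @param catalog a [ko_catalog()]
#' @param entities column order; defaults to order of first appearance
#' @return 0/1 integer matrix, KOs x entities
#' @export
presence_matrix <- function(assignments_by_entity, catalog,
                            entities = NULL) {
  stopifnot(all(c("entity", "ko_id") %in% names(assignments_by_entity)))
  a <- assignments_by_entity[!is.na(assignments_by_entity$ko_id), ,
                             drop = FALSE]
  if (is.null(entities)) entities <- unique(assignments_by_entity$entity)
  stray <- setdiff(unique(a$ko_id), catalog$ko_id)
  if (length(stray)) {
    message("ignoring KO(s) absent from catalog: ",
            paste(stray, collapse = ", "))
    a <- a[a$ko_id %in% catalog$ko_id, , drop = FALSE]
  }
  m <- matrix(0L, nrow(catalog), length(entities),
              dimnames = list(catalog$ko_id, entities))
  if (nrow(a))
    m[cbind(match(a$ko_id, catalog$ko_id), match(a$entity, entities))] <- 1L
  m
}

#' Per-family presence summary
#'
#' Collapses a KO presence/absence matrix to gene-family level: for each
#' entity and catalog family, the number of KOs present, the family size,
#' and the missing gene symbols.
#'
#' @param presence 0/1 matrix from [presence_matrix()]
#' @param catalog the matching [ko_catalog()]
#' @return data.frame: `entity`, `family`, `present`, `total`, `missing`
#'   (comma-separated symbols, empty when complete)
#' @export
family_summary <- function(presence, catalog) {
  if (!all(rownames(presence) == catalog$ko_id))
    stop("presence matrix rows must match the catalog")
  fams <- unique(catalog$family)
  out <- list()
  for (e in colnames(presence)) for (f in fams) {
    rows <- catalog$family == f
    here <- presence[rows, e] == 1L
    out[[length(out) + 1L]] <- data.frame(
      entity = e, family = f, present = sum(here), total = sum(rows),
      missing = paste(catalog$symbol[rows][!here], collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
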