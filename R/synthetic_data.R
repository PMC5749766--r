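#' Planted-pangenome specification
#'
#' Describes a synthetic world of `n_strains` proteomes related by a random
#' tree, with planted core families (present in every strain), dispensable
#' families (present in a proper subset of >= 2 strains) and strain-unique
#' genes, at a controlled sequence divergence.  Defaults give families whose
#' within-family identity stays above 70% on every leaf pair (branch
#' lengths are drawn in [0.02, 0.10], so the deepest leaf-to-leaf path of a
#' typical tree keeps expected p-distance below 0.3 at `divergence = 0.5`)
#' while unrelated sequences sit near the ~5% random-identity floor.
#'
#' @param n_strains number of strains (>= 3)
#' @param n_core number of core gene families
#' @param n_dispensable number of dispensable families
#' @param dispensable_strain_subsets optional list of integer/character
#'   vectors, one per dispensable family, each a proper subset of the
#'   strains with size >= 2; drawn at random when `NULL`
#' @param n_unique_per_strain strain-specific (unique) genes per strain
#' @param protein_length `c(mean =, jitter =)` residues; lengths are drawn
#'   uniformly in `mean +/- jitter`
#' @param divergence expected substitution events per site per unit branch
#'   length (>= 0)
#' @param seed integer seed; the whole generated world is a pure function
#'   of the spec including the seed
#' @return validated list of class `pangenome_spec`
#' @export
pangenome_spec <- function(n_strains, n_core, n_dispensable,
                           dispensable_strain_subsets = NULL,
                           n_unique_per_strain = 0L,
                           protein_length = c(mean = 150, jitter = 30),
                           divergence = 0.5, seed = 1L) {
  stopifnot(n_strains >= 3, n_core >= 0, n_dispensable >= 0,
            n_unique_per_strain >= 0, divergence >= 0,
            protein_length[["mean"]] - protein_length[["jitter"]] >= 10)
  strains <- paste0("strain_", seq_len(n_strains))
  if (!is.null(dispensable_strain_subsets)) {
    if (length(dispensable_strain_subsets) != n_dispensable)
      stop("need one strain subset per dispensable family")
    dispensable_strain_subsets <- lapply(dispensable_strain_subsets,
                                         function(s) {
      if (is.numeric(s)) s <- strains[s]
      s <- unique(as.character(s))
      if (!all(s %in% strains)) stop("unknown strain in dispensable subset")
      if (length(s) < 2 || length(s) >= n_strains)
        stop("dispensable subset must be a proper subset with size >= 2")
      sort(s)
    })
  }
  structure(list(n_strains = as.integer(n_strains),
                 n_core = as.integer(n_core),
                 n_dispensable = as.integer(n_dispensable),
                 dispensable_strain_subsets = dispensable_strain_subsets,
                 n_unique_per_strain = as.integer(n_unique_per_strain),
                 protein_length = protein_length,
                 divergence = divergence, seed = as.integer(seed),
                 strains = strains),
            class = "pangenome_spec")
}

random_protein <- function(length) {
  paste(sample(strsplit(aa_alphabet(), "")[[1]], length, replace = TRUE),
        collapse = "")
}

draw_length <- function(protein_length) {
  m <- protein_length[["mean"]]; j <- protein_length[["jitter"]]
  sample(seq.int(m - j, m + j), 1L)
}

#' Generate a random planted strain tree
#'
#' Draws a uniformly random unrooted binary topology over
#' `strain_1..strain_N` with branch lengths uniform in [0.02, 0.10], and
#' returns it together with its leaf-to-leaf path-length matrix.
#' Deterministic for a fixed seed.
#'
#' @param n_strains number of leaves (>= 3)
#' @param seed integer seed, or `NULL` to use the ambient RNG stream
#' @return list with `tree` (ape `phylo`, unrooted) and `dist` (pairwise
#'   path-length matrix in strain order)
#' @export
generate_planted_tree <- function(n_strains, seed = NULL) {
  if (n_strains < 3) stop("too few taxa")
  gen <- function() {
    tr0 <- ape::rtopology(n_strains, rooted = FALSE)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.02, 0.10)
    # rtopology labels tips t1..tN
    tr0$tip.label <- sub("^t", "strain_", tr0$tip.label)
    tr0
  }
  tr <- if (is.null(seed)) gen() else with_seed(seed, gen())
  strains <- paste0("strain_", seq_len(n_strains))
  d <- cophenetic(tr)[strains, strains]
  list(tree = tr, dist = d)
}

#' Evolve one gene family along a tree
#'
#' Simulates a Poisson substitution process: along a branch of length b
#' each site experiences a substitution event with probability
#' 1 - exp(-b * divergence); an event redraws the residue uniformly from
#' all 20 amino acids (so a fraction 1/20 of events are silent, the
#' one-step back-substitution of the uniform-replacement chain).  The
#' expected p-distance between leaves joined by total path length T is
#' therefore (19/20) * (1 - exp(-divergence * T)) in closed form.
#'
#' @param ancestral_sequence nonempty residue string placed at the root
#' @param tree ape `phylo` with branch lengths (rooted or unrooted; an
#'   unrooted tree is traversed from its basal node)
#' @param divergence substitution-event rate per site per unit branch
#'   length (>= 0)
#' @param seed integer seed, or `NULL` to use the ambient RNG stream
#' @return named character vector: one sequence per leaf, in
#'   `tree$tip.label` order
#' @export
evolve_family <- function(ancestral_sequence, tree, divergence,
                          seed = NULL) {
  if (!nzchar(ancestral_sequence)) stop("empty ancestral sequence")
  stopifnot(divergence >= 0)
  run <- function() {
    alpha <- strsplit(aa_alphabet(), "")[[1]]
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- length(tr$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tr$Nnode)
    seqs[[root]] <- strsplit(ancestral_sequence, "")[[1]]
    L <- length(seqs[[root]])
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      b <- tr$edge.length[e]
      s <- seqs[[p]]
      hit <- runif(L) < (1 - exp(-b * divergence))
      if (any(hit))
        s[hit] <- sample(alpha, sum(hit), replace = TRUE)
      seqs[[ch]] <- s
    }
    out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(out) <- tr$tip.label
    out[tree$tip.label]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a planted pangenome
#'
#' Builds `n_strains` proteomes: every core family contributes one gene to
#' every strain, every dispensable family one gene to each strain of its
#' planted subset, and each strain carries `n_unique_per_strain` unrelated
#' random genes.  Family members are the ancestral sequence evolved along
#' the planted tree (see [evolve_family()]); unique genes are i.i.d.
#' uniform sequences, ~5% identity to everything else.  Byte-identical
#' output for identical spec + seed.
#'
#' @param spec a [pangenome_spec()]
#' @param dir optional directory; when given, per-strain FASTA files
#'   (`<strain>.faa`), `truth.tsv` and `tree.nwk` are written there
#' @return list of class `planted_pangenome` with `proteomes` (named list
#'   of gene-record data.frames), `truth` (data.frame `gene_id`,
#'   `family_id`, `class`, `strain`), `tree` (ape `phylo`), `tree_dist`,
#'   and `spec`
#' @export
generate_pangenome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "pangenome_spec"))
  out <- with_seed(spec$seed, {
    strains <- spec$strains
    pt <- generate_planted_tree(spec$n_strains, seed = NULL)
    subsets <- spec$dispensable_strain_subsets
    if (is.null(subsets) && spec$n_dispensable > 0)
      subsets <- lapply(seq_len(spec$n_dispensable), function(i) {
        k <- sample(2:(spec$n_strains - 1L), 1L)
        sort(sample(strains, k))
      })
    counters <- stats::setNames(rep(0L, length(strains)), strains)
    genes <- stats::setNames(
      lapply(strains, function(s) list()), strains)
    truth <- list()
    add_gene <- function(strain, seq, family, class) {
      counters[[strain]] <<- counters[[strain]] + 1L
      gid <- sprintf("%s_g%04d", strain, counters[[strain]])
      genes[[strain]][[length(genes[[strain]]) + 1L]] <<-
        c(id = gid, sequence = seq)
      truth[[length(truth) + 1L]] <<-
        data.frame(gene_id = gid, family_id = family, class = class,
                   strain = strain, stringsAsFactors = FALSE)
    }
    emit_family <- function(family, class, members) {
      anc <- random_protein(draw_length(spec$protein_length))
      leaves <- evolve_family(anc, pt$tree, spec$divergence, seed = NULL)
      for (s in members) add_gene(s, leaves[[s]], family, class)
    }
    for (i in seq_len(spec$n_core))
      emit_family(sprintf("core_%04d", i), "core", strains)
    for (i in seq_len(spec$n_dispensable))
      emit_family(sprintf("disp_%04d", i), "dispensable", subsets[[i]])
    for (s in strains)
      for (i in seq_len(spec$n_unique_per_strain)) {
        fam <- sprintf("uniq_%s_%03d", s, i)
        add_gene(s, random_protein(draw_length(spec$protein_length)),
                 fam, "strain_specific")
      }
    proteomes <- lapply(strains, function(s) {
      g <- genes[[s]]
      gene_records(vapply(g, `[[`, "", "id"), s,
                   vapply(g, `[[`, "", "sequence"))
    })
    names(proteomes) <- strains
    list(proteomes = proteomes, truth = do.call(rbind, truth),
         tree = pt$tree, tree_dist = pt$dist,
         subsets = subsets)
  })
  pg <- structure(list(proteomes = out$proteomes, truth = out$truth,
                       tree = out$tree, tree_dist = out$tree_dist,
                       dispensable_strain_subsets = out$subsets,
                       spec = spec),
                  class = "planted_pangenome")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(pg$proteomes))
      write_fasta(pg$proteomes[[s]], file.path(dir, paste0(s, ".faa")))
    write_truth(pg$truth, file.path(dir, "truth.tsv"))
    write_newick(pg$tree, file.path(dir, "tree.nwk"))
  }
  pg
}

#' @export
print.planted_pangenome <- function(x, ...) {
  cat("planted_pangenome:", x$spec$n_strains, "strains,",
      nrow(x$truth), "genes in",
      length(unique(x$truth$family_id)), "families\n")
  invisible(x)
}

#' Generate a synthetic metagenome sample
#'
#' A sample is a mixture of strain proteomes plus unrelated noise: for each
#' strain in `mixture`, `floor(inclusion_fraction * n_genes)` genes are
#' chosen by a seeded shuffle (deterministic rounding rule) and relabeled
#' sample-side; `noise_count` i.i.d. random proteins are appended.  The
#' returned truth table maps every sample gene to its origin.
#'
#' @param pangenome a `planted_pangenome` (see [generate_pangenome()])
#' @param mixture character vector of strain labels included in the sample
#' @param noise_count number of unrelated noise proteins (>= 0)
#' @param inclusion_fraction fraction of each mixed strain's genes included
#'   (in `[0, 1]`)
#' @param seed integer seed
#' @param sample_label label used as `source` and gene-id prefix
#' @return list with `records` (gene-record data.frame) and `truth`
#'   (data.frame `gene_id`, `origin_gene`, `strain`, `family_id`, `class`;
#'   noise rows carry class `"noise"`)
#' @export
generate_metagenome_sample <- function(pangenome, mixture, noise_count = 0L,
                                       inclusion_fraction = 1,
                                       seed = 1L,
                                       sample_label = "sample_1") {
  stopifnot(inherits(pangenome, "planted_pangenome"),
            inclusion_fraction >= 0, inclusion_fraction <= 1,
            noise_count >= 0)
  unknown <- setdiff(mixture, names(pangenome$proteomes))
  if (length(unknown))
    stop("unknown strain: ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    origin <- character(0); strain <- character(0)
    for (s in mixture) {
      prot <- pangenome$proteomes[[s]]
      n_take <- floor(inclusion_fraction * nrow(prot))
      take <- sample(nrow(prot))[seq_len(n_take)]
      ids <- c(ids, prot$id[take])
      seqs <- c(seqs, prot$sequence[take])
      origin <- c(origin, prot$id[take])
      strain <- c(strain, rep(s, n_take))
    }
    if (noise_count > 0) {
      noise <- vapply(seq_len(noise_count), function(i)
        random_protein(draw_length(pangenome$spec$protein_length)),
        character(1))
      ids <- c(ids, sprintf("noise_%04d", seq_len(noise_count)))
      seqs <- c(seqs, noise)
      origin <- c(origin, rep(NA_character_, noise_count))
      strain <- c(strain, rep(NA_character_, noise_count))
    }
    n <- length(ids)
    sample_ids <- sprintf("%s_m%05d", sample_label, seq_len(n))
    tmap <- pangenome$truth
    fam <- tmap$family_id[match(origin, tmap$gene_id)]
    cls <- tmap$class[match(origin, tmap$gene_id)]
    cls[is.na(origin)] <- "noise"
    records <- if (n > 0)
      gene_records(sample_ids, sample_label, seqs)
    else
      gene_records(character(0), character(0), character(0))
    list(records = records,
         truth = data.frame(gene_id = sample_ids, origin_gene = origin,
                            strain = strain, family_id = fam, class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Write a truth table as TSV
#' @param truth truth data.frame from the generators
#' @param path file path
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a pangenome spec as a flat key-value config
#'
#' Plain `key: value` lines; dispensable subsets are encoded one family
#' per `subset:` line as comma-separated strain labels.
#'
#' @param spec a [pangenome_spec()]
#' @param path file path
#' @return `read_pangenome_spec()`: a `pangenome_spec`; the writer returns
#'   `path` invisibly
#' @export
write_pangenome_spec <- function(spec, path) {
  ln <- c(sprintf("n_strains: %d", spec$n_strains),
          sprintf("n_core: %d", spec$n_core),
          sprintf("n_dispensable: %d", spec$n_dispensable),
          sprintf("n_unique_per_strain: %d", spec$n_unique_per_strain),
          sprintf("protein_length_mean: %g", spec$protein_length[["mean"]]),
          sprintf("protein_length_jitter: %g",
                  spec$protein_length[["jitter"]]),
          sprintf("divergence: %g", spec$divergence),
          sprintf("seed: %d", spec$seed))
  if (!is.null(spec$dispensable_strain_subsets))
    ln <- c(ln, vapply(spec$dispensable_strain_subsets, function(s)
      sprintf("subset: %s", paste(s, collapse = ",")), character(1)))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_pangenome_spec
#' @export
read_pangenome_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+):\\s*(.*)$", lines))
  if (any(lengths(kv) == 0)) stop("malformed spec line: ",
                                  lines[which(lengths(kv) == 0)[1]])
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  get1 <- function(k, default = NULL) {
    v <- vals[keys == k]
    if (!length(v)) {
      if (is.null(default)) stop("missing key: ", k)
      return(default)
    }
    as.numeric(v[1])
  }
  subsets <- strsplit(vals[keys == "subset"], ",\\s*")
  if (!length(subsets)) subsets <- NULL
  pangenome_spec(
    n_strains = get1("n_strains"), n_core = get1("n_core"),
    n_dispensable = get1("n_dispensable"),
    dispensable_strain_subsets = subsets,
    n_unique_per_strain = get1("n_unique_per_strain", 0),
    protein_length = c(mean = get1("protein_length_mean", 150),
                       jitter = get1("protein_length_jitter", 30)),
    divergence = get1("divergence", 0.5),
    seed = get1("seed", 1))
}
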