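#' Simulation settings for fixture genome sets
#'
#' The defaults describe the standard validation scenario: 8 genomes related
#' by a random species tree of expected root-to-leaf depth 0.5 substitutions
#' per site, 10 universal single-copy marker families of 200 residues, 3
#' multi-copy families (duplicated in at least one genome), 2 patchy
#' families (absent from at least one genome), decoy cross-hits on 10% of
#' genes at e-value 1e-3, and 2 family-less decoy genes per genome.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param n_marker_families Universal single-copy families planted.
#' @param n_multicopy_families Families duplicated in >= 1 genome.
#' @param n_patchy_families Families absent from >= 1 genome.
#' @param seq_length Root sequence length in residues.
#' @param tree_depth Expected root-to-leaf path length (substitutions/site).
#' @param decoy_fraction Fraction of genes receiving an extra weak decoy
#'   hit (e-value `decoy_evalue`).
#' @param decoy_evalue E-value of decoy hits (default 1e-3, above the
#'   pipeline's 1e-10 cutoff).
#' @param n_decoy_genes Family-less random genes added per genome.
#' @param seed Integer seed; all fixture randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genomes = 8, n_marker_families = 10,
                       n_multicopy_families = 3, n_patchy_families = 2,
                       seq_length = 200, tree_depth = 0.5,
                       decoy_fraction = 0.1, decoy_evalue = 1e-3,
                       n_decoy_genes = 2, seed = 42) {
  stopifnot(n_genomes >= 2, n_marker_families >= 0,
            n_multicopy_families >= 0, n_patchy_families >= 0,
            seq_length >= 1, tree_depth >= 0, decoy_fraction >= 0,
            decoy_fraction <= 1, !is.null(seed))
  structure(list(n_genomes = as.integer(n_genomes),
                 n_marker_families = as.integer(n_marker_families),
                 n_multicopy_families = as.integer(n_multicopy_families),
                 n_patchy_families = as.integer(n_patchy_families),
                 seq_length = as.integer(seq_length),
                 tree_depth = tree_depth,
                 decoy_fraction = decoy_fraction,
                 decoy_evalue = decoy_evalue,
                 n_decoy_genes = as.integer(n_decoy_genes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random species tree
#'
#' Topology by sequential random attachment (each new leaf splits a
#' uniformly chosen edge); branch lengths are exponential with the mean
#' scaled so the expected root-to-leaf path length equals `depth` on the
#' drawn topology.
#'
#' @param n_genomes Number of leaves (>= 2); labels `G01`, `G02`, ...
#' @param depth Expected root-to-leaf path length in substitutions/site.
#' @param seed Optional integer seed (`NULL` to use the current RNG
#'   state).
#' @return A rooted, bifurcating `phylo` tree.
#' @export
simulate_species_tree <- function(n_genomes, depth = 0.5, seed = NULL) {
  stopifnot(n_genomes >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_genomes)
  root <- n + 1L
  parent <- c(root, root)
  child <- c(1L, 2L)
  next_int <- n + 2L
  if (n >= 3) {
    for (k in 3:n) {
      e <- sample.int(length(parent), 1)
      w <- next_int
      next_int <- next_int + 1L
      old_child <- child[e]
      child[e] <- w
      parent <- c(parent, w, w)
      child <- c(child, old_child, k)
    }
  }
  tr <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                       tip.label = sprintf("G%02d", seq_len(n)),
                       Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  # edges on each root-to-leaf path, to calibrate the exponential mean
  depth_edges <- ape::node.depth.edgelength(
    within_unit_lengths(tr))
  mean_h <- mean(depth_edges[seq_len(n)])
  mean_edge <- if (depth > 0) depth / mean_h else 0
  tr$edge.length <- if (mean_edge > 0) {
    rexp(nrow(tr$edge), rate = 1 / mean_edge)
  } else {
    rep(0, nrow(tr$edge))
  }
  tr
}

# helper: copy of the tree with unit edge lengths (for edge-count depths)
within_unit_lengths <- function(tr) {
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Evolve a protein family along a tree
#'
#' The root sequence is drawn uniformly from the 20-letter alphabet; along
#' each branch of length `b` every site changes with probability
#' `(19/20) * (1 - exp(-20 b / 19))` — the 20-state symmetric substitution
#' model, which composes exactly across branches — and a changed site is
#' replaced uniformly by one of the other 19 residues.
#'
#' @param tree A `phylo` tree with edge lengths.
#' @param root_length Sequence length in residues.
#' @param seed Optional integer seed (`NULL` to use the current RNG state).
#' @return Named character vector of leaf sequences.
#' @export
evolve_family <- function(tree, root_length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), root_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  L <- as.integer(root_length)
  nt <- length(tr$tip.label)
  seqs <- vector("list", nt + tr$Nnode)
  seqs[[nt + 1]] <- sample(20L, L, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    b <- tr$edge.length[e]
    s <- seqs[[par]]
    p_change <- (19 / 20) * (1 - exp(-20 * b / 19))
    mut <- which(stats::runif(L) < p_change)
    if (length(mut) > 0) {
      shift <- sample.int(19L, length(mut), replace = TRUE)
      s[mut] <- ((s[mut] - 1L + shift) %% 20L) + 1L
    }
    seqs[[ch]] <- s
  }
  out <- vapply(seq_len(nt), function(i) {
    paste(AA20[seqs[[i]]], collapse = "")
  }, "")
  setNames(out, tr$tip.label)
}

#' Generate a fixture genome set with known marker structure
#'
#' Simulates a species tree, evolves every gene family along it, plants the
#' configured marker/multi-copy/patchy structure, and emits per-genome
#' protein FASTA plus matching HMMER3 domain tables: every true gene gets a
#' strong hit (e-value 1e-50) to its family profile, a `decoy_fraction` of
#' genes get an extra weak cross-hit, and a few family-less decoy genes are
#' added per genome with only weak hits. All output is bit-reproducible
#' given the seed.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, `<genome>.faa`,
#'   `<genome>.domtblout`, `true_tree.nwk` and `truth.json` are written
#'   there.
#' @return A `marker_fixture` list: `truth` (species `tree`, `families`
#'   tibble with per-family status, `assignments` tibble of true gene ->
#'   profile links), `proteomes` and `hits` tibbles for all genomes, and
#'   `files` (per-genome paths, when `dir` was given).
#' @export
generate_fixture <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genomes
  tree <- simulate_species_tree(n, config$tree_depth)
  genomes <- tree$tip.label

  fam_acc <- function(k, offset) {
    if (k == 0) character(0) else sprintf("PF%05d", offset + seq_len(k))
  }
  markers <- fam_acc(config$n_marker_families, 0)
  multicopy <- fam_acc(config$n_multicopy_families, 100)
  patchy <- fam_acc(config$n_patchy_families, 200)
  decoy_pool <- sprintf("PF%05d", 9000 + seq_len(20))

  families <- tibble(
    profile_acc = c(markers, multicopy, patchy),
    status = c(rep("marker", length(markers)),
               rep("multicopy", length(multicopy)),
               rep("patchy", length(patchy))))

  genes <- list()
  for (i in seq_len(nrow(families))) {
    acc <- families$profile_acc[i]
    status <- families$status[i]
    leaves <- evolve_family(tree, config$seq_length)
    present <- genomes
    if (status == "patchy") {
      n_miss <- sample.int(max(1L, min(2L, n - 1L)), 1)
      present <- setdiff(genomes, sample(genomes, n_miss))
    }
    genes[[length(genes) + 1]] <- tibble(
      genome_id = present,
      gene_id = paste0(present, "_", acc, "_1"),
      profile_acc = acc,
      residues = unname(leaves[present]))
    if (status == "multicopy") {
      extra <- evolve_family(tree, config$seq_length)
      n_dup <- sample.int(max(1L, min(2L, n)), 1)
      dups <- sample(genomes, n_dup)
      genes[[length(genes) + 1]] <- tibble(
        genome_id = dups,
        gene_id = paste0(dups, "_", acc, "_2"),
        profile_acc = acc,
        residues = unname(extra[dups]))
    }
  }
  genes <- bind_rows(genes)

  # family-less decoy genes, present in some genomes only
  if (config$n_decoy_genes > 0) {
    decoys <- lapply(genomes, function(g) {
      tibble(genome_id = g,
             gene_id = paste0(g, "_dec", seq_len(config$n_decoy_genes)),
             profile_acc = NA_character_,
             residues = vapply(seq_len(config$n_decoy_genes), function(i) {
               paste(sample(AA20, config$seq_length, replace = TRUE),
                     collapse = "")
             }, ""))
    })
    genes <- bind_rows(genes, bind_rows(decoys))
  }
  genes <- arrange(genes, .data$genome_id, .data$gene_id)

  true_hits <- genes |>
    filter(!is.na(.data$profile_acc)) |>
    mutate(profile_name = .data$profile_acc,
           full_evalue = 1e-50, full_score = 250.0)
  weak_sources <- genes |>
    mutate(is_decoy_gene = is.na(.data$profile_acc)) |>
    filter(.data$is_decoy_gene |
             stats::runif(dplyr::n()) < config$decoy_fraction)
  weak_hits <- weak_sources |>
    mutate(profile_acc = sample(decoy_pool, dplyr::n(), replace = TRUE),
           profile_name = .data$profile_acc,
           full_evalue = config$decoy_evalue, full_score = 15.0) |>
    select(-"is_decoy_gene")
  hits <- bind_rows(true_hits, weak_hits) |>
    select("genome_id", "gene_id", "profile_acc", "profile_name",
           "full_evalue", "full_score") |>
    arrange(.data$genome_id, .data$gene_id, .data$full_evalue)

  truth <- list(
    tree = tree,
    families = families,
    assignments = true_hits |>
      select("genome_id", "gene_id", "profile_acc"))

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- lapply(setNames(genomes, genomes), function(g) {
      fa <- file.path(dir, paste0(g, ".faa"))
      dt <- file.path(dir, paste0(g, ".domtblout"))
      write_fasta(filter(genes, .data$genome_id == g), fa)
      write_domtblout(filter(hits, .data$genome_id == g), dt)
      list(proteins = fa, domtblout = dt)
    })
    write_newick(tree, file.path(dir, "true_tree.nwk"))
    jsonlite::write_json(
      list(families = families,
           assignments = truth$assignments,
           seed = config$seed),
      file.path(dir, "truth.json"))
  }

  structure(list(truth = truth,
                 proteomes = select(genes, "genome_id", "gene_id", "residues"),
                 hits = hits,
                 config = config,
                 dir = dir,
                 files = files),
            class = "marker_fixture")
}

#' @export
print.marker_fixture <- function(x, ...) {
  cat("Synthetic genome set: ", x$config$n_genomes, " genomes, ",
      nrow(x$truth$families), " planted families (",
      sum(x$truth$families$status == "marker"), " markers)\n", sep = "")
  invisible(x)
}
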