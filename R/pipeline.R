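#' Run the full marker-gene to species-tree pipeline
#'
#' Reads per-genome protein FASTA and HMMER3 domain tables, keeps the best
#' profile hit per gene at the e-value cutoff, selects PFAM profiles that
#' are single-copy in every genome, aligns each marker family, concatenates
#' the alignments, removes highly variable or gapped blocks, and infers a
#' bootstrapped neighbor-joining tree. Optionally maps the marker profiles
#' to COG categories through shared GO terms. All outputs are written under
#' `out` when given; every random step flows from `seed`.
#'
#' @param proteins Directory containing one protein FASTA per genome
#'   (`.faa`/`.fa`/`.fasta`, optionally gzipped), or a named character
#'   vector of file paths (names = genome ids).
#' @param domtblout Directory of matching `<genome>.domtblout` tables, or a
#'   named character vector of paths. Required: the pipeline consumes
#'   precomputed `hmmsearch --domtblout` output.
#' @param out Optional output directory (created if needed).
#' @param evalue_cutoff Best-hit e-value cutoff (default `1e-10`).
#' @param aligner `"builtin"` for the progressive aligner, or an external
#'   command template with `{input}`/`{output}` placeholders.
#' @param trim A [trim_config()], `"default"`, or `"none"` to skip
#'   trimming.
#' @param tree_method `"nj"` for bootstrapped neighbor joining, or an
#'   external command template with `{input}`/`{output}` placeholders (no
#'   bootstrap supports are added in that case).
#' @param bootstrap Number of bootstrap replicates (default 100).
#' @param seed Integer seed (default 42).
#' @param pfam2go,cog2go,cognames Optional paths to GO cross-reference and
#'   COG definition files; COG categorization runs only when all three are
#'   given.
#' @param midpoint_root Midpoint-root the written tree for display
#'   (default `FALSE`; the tree itself is unrooted).
#' @return A `marker_run` object; see [tidy.marker_run()] and
#'   [glance.marker_run()].
#' @export
run_pipeline <- function(proteins, domtblout, out = NULL,
                         evalue_cutoff = 1e-10, aligner = "builtin",
                         trim = "default", tree_method = "nj",
                         bootstrap = 100, seed = 42,
                         pfam2go = NULL, cog2go = NULL, cognames = NULL,
                         midpoint_root = FALSE) {
  stopifnot(evalue_cutoff > 0, bootstrap >= 1)
  protein_files <- resolve_genome_files(proteins, c("faa", "fa", "fasta"))
  domtbl_files <- resolve_genome_files(domtblout, "domtblout")
  genomes <- sort(names(protein_files))
  if (length(genomes) < 2) {
    abort("need at least 2 genomes")
  }
  missing_dt <- setdiff(genomes, names(domtbl_files))
  if (length(missing_dt) > 0) {
    abort(paste0("no domtblout table for genome ", missing_dt[[1]],
                 "; run hmmsearch --domtblout against PFAM first"))
  }
  log_lines <- c(
    paste0("markertree ", as.character(utils::packageVersion("markertree"))),
    paste0("genomes: ", length(genomes)),
    paste0("evalue_cutoff: ", format(evalue_cutoff)),
    paste0("aligner: ", aligner),
    paste0("tree_method: ", tree_method),
    paste0("bootstrap: ", bootstrap),
    paste0("seed: ", seed))

  # --- annotation ---
  proteomes <- bind_rows(lapply(genomes, function(g) {
    read_fasta(protein_files[[g]], genome_id = g)
  }))
  kind <- detect_input_kind(proteomes)
  if (kind == "nucleotide") {
    abort(paste0("inputs look like nucleotide sequences; gene prediction ",
                 "is out of scope — predict proteins first (e.g. with ",
                 "prodigal) and rerun on the protein FASTA"))
  }
  hits <- bind_rows(lapply(genomes, function(g) {
    parse_domtblout(domtbl_files[[g]], genome_id = g)
  }))
  assignments <- hits |>
    dplyr::group_split(.data$genome_id) |>
    purrr::map(select_top_hits, evalue_cutoff = evalue_cutoff) |>
    bind_rows()
  log_lines <- c(log_lines,
                 paste0("raw hits: ", nrow(hits)),
                 paste0("assigned genes: ", nrow(assignments)))

  # --- marker selection ---
  copy_matrix <- build_copy_matrix(assignments, genome_ids = genomes)
  markers <- suppressWarnings(select_markers(copy_matrix))
  log_lines <- c(log_lines, paste0("markers: ", length(markers)))
  report_tbl <- marker_report(markers, assignments)
  outdir <- NULL
  files <- list()
  if (!is.null(out)) {
    outdir <- out
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files$markers <- file.path(outdir, "markers.tsv")
    readr::write_tsv(report_tbl, files$markers)
  }
  if (length(markers) == 0) {
    warn("no markers shared by all genomes; stopping before alignment")
    if (!is.null(outdir)) {
      files$log <- file.path(outdir, "run.log")
      writeLines(c(log_lines, "status: no markers"), files$log)
    }
    return(new_marker_run(genomes, copy_matrix, markers, assignments,
                          report_tbl, alignment = NULL, trimmed = NULL,
                          tree = NULL, cogs = NULL, files = files,
                          params = list(evalue_cutoff = evalue_cutoff,
                                        bootstrap = bootstrap, seed = seed),
                          no_markers = TRUE))
  }

  # --- alignment ---
  families <- collect_marker_families(markers, proteomes, assignments)
  fam_seqs <- family_seq_list(families)
  fam_seqs <- fam_seqs[sort(names(fam_seqs))]
  aligned <- lapply(fam_seqs, function(seqs) {
    if (identical(aligner, "builtin")) {
      progressive_align(seqs)
    } else {
      external_aligner_adapter(seqs, aligner)
    }
  })
  concat <- concatenate_alignments(aligned)
  if (!is.null(outdir)) {
    adir <- file.path(outdir, "alignments")
    dir.create(adir, showWarnings = FALSE)
    for (acc in names(aligned)) {
      write_fasta(aligned[[acc]], file.path(adir, paste0(acc, ".afa")))
    }
    files$concatenated <- file.path(outdir, "concatenated.afa")
    files$partitions <- file.path(outdir, "partitions.txt")
    write_concat_alignment(concat, fasta = files$concatenated,
                           phylip = file.path(outdir, "concatenated.phy"),
                           partitions = files$partitions)
  }
  log_lines <- c(log_lines,
                 paste0("concatenated columns: ", nchar(concat$rows[[1]])))

  # --- trimming ---
  trimmed <- NULL
  tree_alignment <- concat
  if (!identical(trim, "none")) {
    cfg <- if (inherits(trim, "trim_config")) trim else trim_config()
    trimmed <- trim_alignment(concat, cfg)
    tree_alignment <- trimmed$alignment
    log_lines <- c(log_lines,
                   paste0("trimmed columns: ", length(trimmed$mask)))
    if (!is.null(outdir)) {
      files$trimmed <- file.path(outdir, "trimmed.afa")
      write_concat_alignment(trimmed$alignment, fasta = files$trimmed,
                             partitions = file.path(outdir, "partitions_trimmed.txt"))
      files$mask <- file.path(outdir, "trim_mask.txt")
      writeLines(as.character(trimmed$mask), files$mask)
    }
  }

  # --- tree ---
  if (identical(tree_method, "nj")) {
    tree <- bootstrap_tree(tree_alignment, n_replicates = bootstrap,
                           seed = seed)
    bs <- attr(tree, "bootstrap")
    log_lines <- c(log_lines,
                   paste0("bootstrap replicates: ", bs$n_replicates,
                          " (skipped ", bs$n_skipped, ")"))
  } else {
    tree <- external_tree_adapter(tree_alignment, tree_method)
  }
  out_tree <- if (midpoint_root) phangorn::midpoint(tree) else tree
  if (!is.null(outdir)) {
    files$tree <- file.path(outdir, "tree.nwk")
    write_newick(out_tree, files$tree)
    bs <- attr(tree, "bootstrap")
    if (!is.null(bs)) {
      readr::write_tsv(tibble(n_replicates = bs$n_replicates,
                              n_skipped = bs$n_skipped),
                       file.path(outdir, "bootstrap_report.tsv"))
    }
  }

  # --- COG categorization (optional) ---
  cogs <- NULL
  if (!is.null(pfam2go) && !is.null(cog2go) && !is.null(cognames)) {
    p2c <- map_pfam_to_cog(parse_go_mapping(pfam2go),
                           parse_go_mapping(cog2go))
    cogs <- categorize_markers(markers, p2c, parse_cognames(cognames))
    log_lines <- c(log_lines,
                   paste0("mapped markers: ", nrow(cogs$marker_cogs),
                          " / unmapped: ", length(cogs$unmapped)))
    if (!is.null(outdir)) {
      files$category_counts <- file.path(outdir, "category_counts.tsv")
      readr::write_tsv(cogs$category_counts, files$category_counts)
      readr::write_tsv(cogs$marker_cogs, file.path(outdir, "marker_cogs.tsv"))
    }
  }

  if (!is.null(outdir)) {
    files$log <- file.path(outdir, "run.log")
    writeLines(c(log_lines, "status: ok"), files$log)
  }
  new_marker_run(genomes, copy_matrix, markers, assignments, report_tbl,
                 alignment = concat, trimmed = trimmed, tree = tree,
                 cogs = cogs, files = files,
                 params = list(evalue_cutoff = evalue_cutoff,
                               bootstrap = bootstrap, seed = seed),
                 no_markers = FALSE)
}

# locate per-genome files: a directory (genome id = file stem) or a named
# character vector of paths
resolve_genome_files <- function(x, extensions) {
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    pat <- paste0("\\.(", paste(extensions, collapse = "|"), ")(\\.gz)?$")
    paths <- list.files(x, pattern = pat, full.names = TRUE,
                        ignore.case = TRUE)
    if (length(paths) == 0) {
      abort(paste0("no .", extensions[[1]], " files found in ", x))
    }
    ids <- sub(pat, "", basename(paths), ignore.case = TRUE)
    return(setNames(paths, ids))
  }
  if (is.character(x) && !is.null(names(x))) {
    missing <- x[!file.exists(x)]
    if (length(missing) > 0) {
      abort(paste0("input file not found: ", missing[[1]]))
    }
    return(x)
  }
  abort("inputs must be a directory or a named vector of file paths")
}

new_marker_run <- function(genomes, copy_matrix, markers, assignments,
                           report_tbl, alignment, trimmed, tree, cogs,
                           files, params, no_markers) {
  structure(list(genomes = genomes,
                 copy_matrix = copy_matrix,
                 markers = markers,
                 assignments = assignments,
                 marker_table = report_tbl,
                 alignment = alignment,
                 trimmed = trimmed,
                 tree = tree,
                 cogs = cogs,
                 files = files,
                 params = params,
                 no_markers = no_markers),
            class = "marker_run")
}

#' @export
print.marker_run <- function(x, ...) {
  cat("Marker-gene pipeline run\n")
  cat("  genomes:  ", length(x$genomes), "\n", sep = "")
  cat("  markers:  ", length(x$markers), "\n", sep = "")
  if (!is.null(x$alignment)) {
    cat("  columns:  ", nchar(x$alignment$rows[[1]]),
        if (!is.null(x$trimmed)) paste0(" (", length(x$trimmed$mask),
                                        " after trimming)"),
        "\n", sep = "")
  }
  if (!is.null(x$tree)) {
    cat("  tree:     ", length(x$tree$tip.label), " leaves",
        if (!is.null(attr(x$tree, "bootstrap"))) {
          paste0(", ", attr(x$tree, "bootstrap")$n_replicates,
                 " bootstrap replicates")
        }, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy the per-marker results of a pipeline run
#'
#' @param x A `marker_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with one row per marker: `profile_acc`, alignment
#'   widths before/after trimming (when available) and the COG categories
#'   the marker mapped to (when COG inputs were given).
#' @method tidy marker_run
#' @export
tidy.marker_run <- function(x, ...) {
  out <- tibble(profile_acc = as.character(x$markers))
  if (!is.null(x$trimmed)) {
    out <- left_join(out, x$trimmed$report, by = "profile_acc")
  } else if (!is.null(x$alignment)) {
    p <- x$alignment$partitions
    out <- left_join(out,
                     tibble(profile_acc = p$profile_acc,
                            input_width = p$end - p$start + 1L),
                     by = "profile_acc")
  }
  if (!is.null(x$cogs)) {
    out <- left_join(out,
                     select(x$cogs$marker_cogs, "profile_acc", "categories"),
                     by = "profile_acc")
  }
  out
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.marker_run
#' @return A one-row tibble: genome/profile/marker counts, alignment and
#'   trimmed widths, bootstrap settings and seed.
#' @method glance marker_run
#' @export
glance.marker_run <- function(x, ...) {
  bs <- if (!is.null(x$tree)) attr(x$tree, "bootstrap") else NULL
  tibble(n_genomes = length(x$genomes),
         n_profiles = ncol(x$copy_matrix),
         n_markers = length(x$markers),
         alignment_cols = if (!is.null(x$alignment)) nchar(x$alignment$rows[[1]]) else NA_integer_,
         trimmed_cols = if (!is.null(x$trimmed)) length(x$trimmed$mask) else NA_integer_,
         n_bootstrap = if (!is.null(bs)) bs$n_replicates else NA_integer_,
         n_skipped = if (!is.null(bs)) bs$n_skipped else NA_integer_,
         seed = x$params$seed)
}
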