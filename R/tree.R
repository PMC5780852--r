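# ---- distances ---------------------------------------------------------

#' Kimura-corrected protein distance between two aligned rows
#'
#' Columns where either row holds a gap or X are excluded. With mismatch
#' fraction `p` over the comparable columns, the distance is
#' `-ln(1 - p - 0.2 p^2)`; when the argument drops to 0.05 or below the
#' formula is undefined and a fixed cap of 5.2 is returned.
#'
#' @param a,b Equal-length gapped strings.
#' @param labels Optional pair of names used in error messages.
#' @return A non-negative distance.
#' @examples
#' kimura_protein_distance("MKVLA", "MKVLA") # 0
#' @export
kimura_protein_distance <- function(a, b, labels = c("a", "b")) {
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  comparable <- !(ca %in% c(GAP, "X")) & !(cb %in% c(GAP, "X"))
  if (!any(comparable)) {
    abort(paste0("no comparable columns between ", labels[[1]], " and ",
                 labels[[2]]))
  }
  p <- mean(ca[comparable] != cb[comparable])
  arg <- 1 - p - 0.2 * p^2
  if (arg <= 0.05) 5.2 else -log(arg)
}

#' Pairwise Kimura distance matrix of an alignment
#'
#' @param rows Named character vector of equal-length gapped rows (or a
#'   `concat_alignment`).
#' @return Symmetric numeric matrix with zero diagonal, labelled by row
#'   names.
#' @export
kimura_distance_matrix <- function(rows) {
  if (inherits(rows, "concat_alignment")) rows <- rows$rows
  n <- length(rows)
  stopifnot(n >= 2, !is.null(names(rows)))
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kimura_protein_distance(
        rows[[i]], rows[[j]], labels = names(rows)[c(i, j)])
    }
  }
  D
}

# ---- neighbor joining --------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Labels are sorted before joining so
#' the result is independent of input label order; negative branch lengths
#' are clamped to zero (the total clamped deficit is recorded in the
#' `clamped_deficit` attribute). Exact on additive matrices.
#'
#' @param D Symmetric labelled distance matrix with at least 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  if (nrow(D) < 3) {
    abort("neighbor joining needs at least 3 taxa")
  }
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tr <- ape::nj(D)
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

# canonical string keys for the nontrivial bipartitions of an unrooted tree:
# for each internal non-root node, the tip set below it, complemented so the
# key never contains the alphabetically smallest tip
tree_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  if (tree$Nnode < 2) return(character(0))
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[[1]]
  root <- nt + 1
  internal <- setdiff(unique(tree$edge[, 1]), root)
  internal <- internal[internal > nt]
  keys <- vapply(internal, function(node) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
    side <- if (anchor %in% tips) setdiff(all_tips, tips) else tips
    paste(sort(side), collapse = "\r")
  }, "")
  names(keys) <- as.character(internal)
  keys[vapply(strsplit(keys, "\r", fixed = TRUE),
              function(s) length(s) >= 2 && length(s) <= nt - 2, TRUE)]
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of nontrivial bipartitions; both trees must share
#' one leaf set.
#'
#' @param t1,t2 `phylo` trees.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees have different leaf sets")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

# ---- bootstrap ---------------------------------------------------------

#' Bootstrapped neighbor-joining tree from an alignment
#'
#' Builds the point-estimate tree from Kimura-corrected distances, then
#' resamples alignment columns with replacement `n_replicates` times,
#' rebuilds a tree per replicate, and annotates each internal edge of the
#' point tree with the percentage (rounded) of completed replicates whose
#' tree contains the same bipartition. Replicates in which some pair has no
#' comparable columns are skipped and counted.
#'
#' @param alignment Named character vector of gapped rows, or a
#'   `concat_alignment`; at least 3 rows.
#' @param n_replicates Number of bootstrap replicates (>= 1; default 100).
#' @param seed Integer seed controlling the column resampling (default 42).
#' @return An unrooted `phylo` with integer supports in `node.label`
#'   (root label empty) and an attached `bootstrap` attribute listing
#'   `n_replicates` and `n_skipped`.
#' @export
bootstrap_tree <- function(alignment, n_replicates = 100, seed = 42) {
  if (inherits(alignment, "concat_alignment")) alignment <- alignment$rows
  stopifnot(length(alignment) >= 3, n_replicates >= 1)
  m <- aln_char_matrix(alignment)
  n <- nrow(m)
  L <- ncol(m)
  pairs <- utils::combn(n, 2)
  # per-pair column-wise comparability and mismatch, computed once
  comp <- matrix(FALSE, ncol(pairs), L)
  mism <- matrix(FALSE, ncol(pairs), L)
  excl <- m == GAP | m == "X"
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    comp[k, ] <- !excl[i, ] & !excl[j, ]
    mism[k, ] <- comp[k, ] & (m[i, ] != m[j, ])
  }
  dist_from_cols <- function(idx) {
    nc <- rowSums(comp[, idx, drop = FALSE])
    if (any(nc == 0)) return(NULL)
    p <- rowSums(mism[, idx, drop = FALSE]) / nc
    arg <- 1 - p - 0.2 * p^2
    d <- rep(5.2, length(arg))
    ok <- arg > 0.05
    d[ok] <- -log(arg[ok])
    D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    D[t(pairs)] <- d
    D[t(pairs)[, 2:1, drop = FALSE]] <- d
    D
  }
  D0 <- dist_from_cols(seq_len(L))
  if (is.null(D0)) {
    abort("some genome pair has no comparable alignment columns")
  }
  point <- nj_tree(D0)
  point_keys <- tree_bipartitions(point)
  counts <- setNames(rep(0L, length(point_keys)), unname(point_keys))
  set.seed(seed)
  skipped <- 0L
  completed <- 0L
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    Dr <- dist_from_cols(idx)
    if (is.null(Dr)) {
      skipped <- skipped + 1L
      next
    }
    completed <- completed + 1L
    rk <- unique(unname(tree_bipartitions(nj_tree(Dr))))
    hit <- names(counts) %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  support <- if (completed > 0) as.integer(round(100 * counts / completed)) else rep(NA_integer_, length(counts))
  nt <- length(point$tip.label)
  labels <- rep("", point$Nnode)
  node_ids <- as.integer(names(point_keys))
  labels[node_ids - nt] <- as.character(support[match(unname(point_keys), names(counts))])
  point$node.label <- labels
  attr(point, "bootstrap") <- list(n_replicates = n_replicates,
                                   n_skipped = skipped)
  point
}

# ---- Newick I/O --------------------------------------------------------

quote_newick_label <- function(x) {
  needs <- grepl("[][(){}:;,'\"[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a tree as a Newick string or file
#'
#' Branch lengths are formatted `%.6f`; internal-node labels (bootstrap
#' supports) are emitted after the closing parenthesis; labels containing
#' Newick metacharacters are single-quoted.
#'
#' @param tree A `phylo` tree.
#' @param path Optional output file; when `NULL` the string is returned.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  node_lab <- tree$node.label %||% rep("", tree$Nnode)
  render <- function(node, edge_idx) {
    if (node <= nt) {
      lab <- quote_newick_label(tree$tip.label[[node]])
    } else {
      sub <- vapply(kids[[as.character(node)]], function(e) {
        render(tree$edge[e, 2], e)
      }, "")
      lab <- paste0("(", paste(sub, collapse = ","), ")",
                    quote_newick_label(node_lab[[node - nt]]))
    }
    if (!is.null(edge_idx) && has_len) {
      lab <- paste0(lab, ":", sprintf("%.6f", tree$edge.length[[edge_idx]]))
    }
    lab
  }
  s <- paste0(render(nt + 1, NULL), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a Newick tree
#'
#' @param x A file path or a Newick string (detected by the presence of a
#'   terminal `;`).
#' @return A `phylo` tree.
#' @export
read_newick <- function(x) {
  tr <- tryCatch({
    if (grepl(";\\s*$", x[[1]])) ape::read.tree(text = x) else ape::read.tree(file = x)
  }, error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort(paste0("malformed Newick input: ",
                 substr(paste(x, collapse = ""), 1, 60)))
  }
  unquote <- function(lab) {
    q <- grepl("^'.*'$", lab)
    lab[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[q]))
    lab
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}

#' Run an external tree builder via a command template
#'
#' Writes the alignment to FASTA, substitutes `{input}`/`{output}` in the
#' template, runs it, parses the resulting Newick and checks the leaf set.
#'
#' @param alignment Named character vector of gapped rows or a
#'   `concat_alignment`.
#' @param command_template Shell command with `{input}` and `{output}`
#'   placeholders, e.g. `"fasttree {input} > {output}"`.
#' @return A `phylo` tree with the alignment's leaf set.
#' @export
external_tree_adapter <- function(alignment, command_template) {
  if (inherits(alignment, "concat_alignment")) alignment <- alignment$rows
  infile <- tempfile(fileext = ".afa")
  outfile <- tempfile(fileext = ".nwk")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  write_fasta(alignment, infile)
  cmd <- gsub("{input}", infile, command_template, fixed = TRUE)
  cmd <- gsub("{output}", outfile, cmd, fixed = TRUE)
  err <- tempfile()
  status <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = FALSE, stderr = err)
  )
  if (status != 0 || !file.exists(outfile)) {
    msg <- if (file.exists(err)) paste(readLines(err, warn = FALSE), collapse = "\n") else ""
    abort(paste0("external tree builder failed (exit ", status, "): ", msg))
  }
  tr <- read_newick(outfile)
  if (!setequal(tr$tip.label, names(alignment))) {
    abort("external tree builder returned a different leaf set")
  }
  tr
}
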