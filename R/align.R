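# ---- scoring -----------------------------------------------------------

# alignment alphabet: 20 amino acids, unknown X, gap
aln_alphabet <- function() c(AA20, "X", GAP)

# BLOSUM62 (from Biostrings) extended so X and the gap character score 0
# against everything; B/Z/U/O/J/* are mapped to X before scoring
scoring_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  S0 <- e[[name]]
  ab <- aln_alphabet()
  S <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
  S[AA20, AA20] <- S0[AA20, AA20]
  S
}

# replace anything outside the 20-letter alphabet (and gap) with X
sanitize_protein <- function(x) {
  gsub(paste0("[^", paste(AA20, collapse = ""), "\\", GAP, "]"), "X", toupper(x))
}

# residue-count profile of an alignment: |alphabet| x L integer matrix
profile_counts <- function(rows) {
  m <- aln_char_matrix(sanitize_protein(rows))
  ab <- aln_alphabet()
  t(vapply(ab, function(a) .colSums(m == a, nrow(m), ncol(m)), numeric(ncol(m))))
}

#' Sum-of-pairs score of a protein alignment
#'
#' Scores every within-column residue pair with the substitution matrix;
#' pairs involving a gap or X contribute 0. No gap penalties are applied —
#' this is the raw column-score used to compare alignments.
#'
#' @param rows Named character vector of equal-length gapped rows.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @return A single numeric score.
#' @export
alignment_sp_score <- function(rows, matrix = "BLOSUM62") {
  S <- scoring_matrix(matrix)
  C <- profile_counts(rows)
  diag_s <- diag(S)
  # per column: (c' S c - sum_r c_r * S[r,r]) / 2 pairs
  quad <- colSums(C * (S %*% C))
  self <- colSums(C * diag_s)
  sum((quad - self) / 2)
}

# ---- pairwise and progressive alignment --------------------------------

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch over the full sequences. A gap run of length `k` costs
#' `gap_open + k * gap_extend`; end gaps are penalized. Residues outside the
#' 20-letter alphabet are scored as X (0 against everything) but emitted
#' unchanged.
#'
#' @param a,b Non-empty protein strings.
#' @param gap_open,gap_extend Non-positive gap penalties (defaults -11, -1).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @return A list with `a`, `b` (gapped strings of equal length) and
#'   `score`.
#' @examples
#' pairwise_global_align("MKVLA", "MKLA")
#' @export
pairwise_global_align <- function(a, b, gap_open = -11, gap_extend = -1,
                                  matrix = "BLOSUM62") {
  stopifnot(nchar(a) > 0, nchar(b) > 0, gap_open <= 0, gap_extend <= 0)
  S <- scoring_matrix(matrix)
  ca <- strsplit(sanitize_protein(a), "")[[1]]
  cb <- strsplit(sanitize_protein(b), "")[[1]]
  sm <- S[ca, cb, drop = FALSE]
  res <- .nw_affine(sm, gap_open, gap_extend)
  oa <- strsplit(a, "")[[1]]
  ob <- strsplit(b, "")[[1]]
  ga <- ifelse(res$path_a > 0, oa[pmax(res$path_a, 1)], GAP)
  gb <- ifelse(res$path_b > 0, ob[pmax(res$path_b, 1)], GAP)
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = res$score)
}

# align two sub-alignments (named character vectors) by profile-profile NW;
# column-pair scores are averaged over residue pairs so the fixed gap
# penalties stay on the single-sequence scale
merge_alignments <- function(rows_a, rows_b, S, gap_open, gap_extend) {
  ca <- profile_counts(rows_a)
  cb <- profile_counts(rows_b)
  sm <- crossprod(ca, S %*% cb) / (length(rows_a) * length(rows_b))
  res <- .nw_affine(sm, gap_open, gap_extend)
  expand <- function(rows, path) {
    m <- aln_char_matrix(rows)
    out <- matrix(GAP, nrow = nrow(m), ncol = length(path),
                  dimnames = list(rownames(m), NULL))
    out[, path > 0] <- m[, path[path > 0], drop = FALSE]
    char_matrix_to_rows(out)
  }
  c(expand(rows_a, res$path_a), expand(rows_b, res$path_b))
}

# 3-mer count vectors and cosine distances for the guide tree
kmer_distance <- function(seqs, k = 3) {
  counts <- lapply(seqs, function(s) {
    s <- sanitize_protein(s)
    kk <- min(k, nchar(s))
    table(substring(s, seq_len(nchar(s) - kk + 1),
                    seq_len(nchar(s) - kk + 1) + kk - 1))
  })
  kmers <- sort(unique(unlist(lapply(counts, names))))
  V <- vapply(counts, function(ct) {
    v <- setNames(numeric(length(kmers)), kmers)
    v[names(ct)] <- as.numeric(ct)
    v
  }, numeric(length(kmers)))
  nrm <- sqrt(colSums(V^2))
  cs <- crossprod(V) / outer(nrm, nrm)
  d <- 1 - cs
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Progressive multiple alignment of a marker family
#'
#' Builds a guide tree from 3-mer count cosine distances clustered by UPGMA,
#' then merges sub-alignments leaf-to-root with profile-profile
#' Needleman-Wunsch (average-of-pairs column scores; gap and X characters
#' score 0 against everything). Members are sorted by name first, so the
#' result does not depend on input order. De-gapping any output row
#' reproduces its input sequence.
#'
#' @param seqs Named character vector of at least 2 protein sequences
#'   (names are typically genome ids).
#' @inheritParams pairwise_global_align
#' @return Named character vector of equal-length gapped rows, in sorted
#'   name order.
#' @export
progressive_align <- function(seqs, gap_open = -11, gap_extend = -1,
                              matrix = "BLOSUM62") {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)), all(nchar(seqs) > 0))
  seqs <- seqs[order(names(seqs))]
  S <- scoring_matrix(matrix)
  if (length(seqs) == 2) {
    pw <- pairwise_global_align(seqs[[1]], seqs[[2]], gap_open, gap_extend,
                                matrix)
    return(setNames(c(pw$a, pw$b), names(seqs)))
  }
  d <- kmer_distance(seqs)
  hc <- hclust(as.dist(d), method = "average")
  nodes <- vector("list", nrow(hc$merge))
  pick <- function(id) {
    if (id < 0) seqs[-id] else nodes[[id]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- pick(hc$merge[i, 1])
    b <- pick(hc$merge[i, 2])
    nodes[[i]] <- merge_alignments(a, b, S, gap_open, gap_extend)
  }
  out <- nodes[[length(nodes)]]
  out[order(names(out))]
}

#' Collect each marker's one-sequence-per-genome protein family
#'
#' @param markers Marker accessions from [select_markers()].
#' @param proteomes Combined protein table (`genome_id`, `gene_id`,
#'   `residues`) from [read_fasta()] over all genomes.
#' @param assignments Combined best-hit table from [select_top_hits()].
#' @return A tibble with columns `profile_acc`, `genome_id`, `gene_id`,
#'   `residues`, ordered by marker then genome. Errors if an assigned gene
#'   id is missing from its proteome.
#' @export
collect_marker_families <- function(markers, proteomes, assignments) {
  fam <- assignments |>
    filter(.data$profile_acc %in% markers) |>
    select("profile_acc", "genome_id", "gene_id") |>
    left_join(proteomes, by = c("genome_id", "gene_id")) |>
    arrange(.data$profile_acc, .data$genome_id)
  if (anyNA(fam$residues)) {
    bad <- fam[is.na(fam$residues), ][1, ]
    abort(paste0("gene ", bad$gene_id, " assigned in genome ", bad$genome_id,
                 " is missing from its proteome FASTA"))
  }
  fam
}

# split a family tibble into named sequence vectors keyed by marker
family_seq_list <- function(families) {
  split(setNames(families$residues, families$genome_id),
        families$profile_acc)
}

#' Run an external aligner on one family via a command template
#'
#' Writes the family to a FASTA file, substitutes `{input}` and `{output}`
#' in the template, runs it through the shell, and parses/validates the
#' aligned FASTA (equal row lengths; de-gapped rows identical to the
#' inputs).
#'
#' @param seqs Named character vector of protein sequences.
#' @param command_template Shell command containing `{input}` and
#'   `{output}` placeholders, e.g.
#'   `"muscle -align {input} -output {output}"`.
#' @return Named character vector of aligned rows (sorted by name).
#' @export
external_aligner_adapter <- function(seqs, command_template) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  infile <- tempfile(fileext = ".faa")
  outfile <- tempfile(fileext = ".afa")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  write_fasta(seqs, infile)
  cmd <- gsub("{input}", infile, command_template, fixed = TRUE)
  cmd <- gsub("{output}", outfile, cmd, fixed = TRUE)
  err <- tempfile()
  status <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = FALSE, stderr = err)
  )
  if (status != 0 || !file.exists(outfile)) {
    msg <- if (file.exists(err)) paste(readLines(err, warn = FALSE), collapse = "\n") else ""
    abort(paste0("external aligner failed (exit ", status, "): ", msg))
  }
  aligned <- read_fasta(outfile, genome_id = "external")
  rows <- setNames(aligned$residues, aligned$gene_id)
  if (!setequal(names(rows), names(seqs))) {
    abort("external aligner changed the sequence name set")
  }
  rows <- rows[sort(names(rows))]
  if (length(unique(nchar(rows))) != 1) {
    abort("external aligner produced rows of unequal length")
  }
  degapped <- gsub(GAP, "", rows, fixed = TRUE)
  degapped_in <- gsub(GAP, "", toupper(seqs[names(rows)]), fixed = TRUE)
  if (!identical(unname(degapped), unname(degapped_in))) {
    abort("external aligner output does not de-gap to its input sequences")
  }
  rows
}

# ---- concatenation -----------------------------------------------------

#' Concatenate per-marker alignments into one partitioned alignment
#'
#' @param alignments Named list of multiple alignments (named character
#'   vectors sharing one genome set); names are marker accessions and fix
#'   the concatenation order.
#' @return A `concat_alignment`: list with `rows` (named character vector)
#'   and `partitions` (tibble `profile_acc`, `start`, `end`, 1-based
#'   inclusive, tiling the full length).
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1,
            !is.null(names(alignments)))
  gset <- sort(names(alignments[[1]]))
  for (i in seq_along(alignments)) {
    gi <- sort(names(alignments[[i]]))
    if (!identical(gi, gset)) {
      diffs <- c(setdiff(gset, gi), setdiff(gi, gset))
      abort(paste0("genome sets differ between alignments: ",
                   paste(diffs, collapse = ", ")))
    }
  }
  lens <- vapply(alignments, function(a) unique(nchar(a))[[1]], numeric(1))
  ends <- cumsum(lens)
  starts <- c(1, utils::head(ends, -1) + 1)
  rows <- setNames(vapply(gset, function(g) {
    paste(vapply(alignments, function(a) a[[g]], ""), collapse = "")
  }, ""), gset)
  structure(
    list(rows = rows,
         partitions = tibble(profile_acc = names(alignments),
                             start = as.integer(starts),
                             end = as.integer(ends))),
    class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat("Concatenated alignment: ", length(x$rows), " genomes x ",
      nchar(x$rows[[1]]), " columns, ", nrow(x$partitions),
      " marker partitions\n", sep = "")
  invisible(x)
}

#' Write a concatenated alignment and its partition map
#'
#' Writes aligned FASTA, relaxed PHYLIP, and a RAxML-style partition file
#' (`PROT, PF00012 = 1-120` per marker).
#'
#' @param x A `concat_alignment`.
#' @param fasta,phylip,partitions Output paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_concat_alignment <- function(x, fasta = NULL, phylip = NULL,
                                   partitions = NULL) {
  stopifnot(inherits(x, "concat_alignment"))
  written <- character()
  if (!is.null(fasta)) {
    write_fasta(x$rows, fasta)
    written <- c(written, fasta)
  }
  if (!is.null(phylip)) {
    con <- file(phylip, "w")
    writeLines(paste(length(x$rows), nchar(x$rows[[1]])), con)
    writeLines(paste(names(x$rows), x$rows), con)
    close(con)
    written <- c(written, phylip)
  }
  if (!is.null(partitions)) {
    writeLines(sprintf("PROT, %s = %d-%d", x$partitions$profile_acc,
                       x$partitions$start, x$partitions$end), partitions)
    written <- c(written, partitions)
  }
  invisible(written)
}
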