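#' Parse an HMMER3 `--domtblout` domain table
#'
#' Reads the whitespace-delimited per-domain table produced by
#' `hmmsearch --domtblout` (or `hmmscan`). One row is returned per data line;
#' no best-hit filtering happens here (see [select_top_hits()]). The gene id
#' is the target-name column, the profile accession the query-accession
#' column (falling back to the query name when the accession field is `-`),
#' and the e-value/bit score are the full-sequence columns. Version suffixes
#' (`.NN`) are stripped from PFAM accessions so counts aggregate across
#' database point releases.
#'
#' @param path Path to a domtblout file (lines starting with `#` are
#'   comments).
#' @param genome_id Genome label attached to every hit.
#' @return A tibble with columns `genome_id`, `gene_id`, `profile_acc`,
#'   `profile_name`, `full_evalue`, `full_score`.
#' @export
parse_domtblout <- function(path, genome_id) {
  if (!file.exists(path)) {
    abort(paste0("domtblout file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(genome_id = character(), gene_id = character(),
                  profile_acc = character(), profile_name = character(),
                  full_evalue = double(), full_score = double()))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 8)) {
    bad <- idx[which(nf < 8)[[1]]]
    abort(paste0("malformed domtblout row at line ", bad, " of ", path,
                 ": fewer than 8 columns"))
  }
  gene_id <- vapply(fields, `[[`, "", 1L)
  profile_name <- vapply(fields, `[[`, "", 4L)
  acc <- vapply(fields, `[[`, "", 5L)
  acc <- ifelse(acc == "-", profile_name, acc)
  acc <- sub("\\.\\d+$", "", acc)
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 8L)))
  if (anyNA(evalue) || anyNA(score)) {
    bad <- idx[which(is.na(evalue) | is.na(score))[[1]]]
    abort(paste0("malformed domtblout row at line ", bad, " of ", path,
                 ": non-numeric e-value or score"))
  }
  if (any(evalue <= 0)) {
    bad <- idx[which(evalue <= 0)[[1]]]
    abort(paste0("non-positive e-value at line ", bad, " of ", path))
  }
  tibble(genome_id = genome_id, gene_id = gene_id, profile_acc = acc,
         profile_name = profile_name, full_evalue = evalue, full_score = score)
}

#' Write hits in HMMER3 `--domtblout` layout
#'
#' Emits a syntactically valid 23-column domain table (one domain per gene
#' hit) that [parse_domtblout()] reads back. Used by the fixture generator.
#'
#' @param hits Tibble with `gene_id`, `profile_acc`, `profile_name`,
#'   `full_evalue`, `full_score` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
               "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"),
             con)
  if (nrow(hits) > 0) {
    rows <- sprintf("%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
                    hits$gene_id, "-", 100L, hits$profile_name,
                    hits$profile_acc, 100L, hits$full_evalue, hits$full_score,
                    0.0, 1L, 1L, hits$full_evalue, hits$full_evalue,
                    hits$full_score, 0.0, 1L, 100L, 1L, 100L, 1L, 100L,
                    0.95, "-")
    writeLines(rows, con)
  }
  writeLines("#", con)
  invisible(path)
}

#' Keep the best profile assignment per gene
#'
#' Discards hits whose full-sequence e-value exceeds the cutoff (hits exactly
#' at the cutoff are kept), then keeps, per gene, the hit with the smallest
#' e-value. Ties are broken by larger bit score, then lexicographically
#' smallest profile accession, so the result is independent of input order.
#'
#' @param hits Tibble of hits for a single genome, as from
#'   [parse_domtblout()].
#' @param evalue_cutoff Positive e-value threshold (default `1e-10`).
#' @return A tibble with one row per assigned gene (columns as `hits`);
#'   genes with no surviving hit are absent. The cutoff is recorded in the
#'   `evalue_cutoff` attribute.
#' @export
select_top_hits <- function(hits, evalue_cutoff = 1e-10) {
  stopifnot(is.numeric(evalue_cutoff), evalue_cutoff > 0)
  if (nrow(hits) > 0 && length(unique(hits$genome_id)) > 1) {
    abort("select_top_hits() expects hits from a single genome; got multiple genome_ids")
  }
  out <- hits |>
    filter(.data$full_evalue <= evalue_cutoff) |>
    arrange(.data$gene_id, .data$full_evalue, desc(.data$full_score),
            .data$profile_acc) |>
    distinct(.data$gene_id, .keep_all = TRUE)
  attr(out, "evalue_cutoff") <- evalue_cutoff
  out
}

#' Count genes assigned to each profile
#'
#' @param assignments A best-hit table from [select_top_hits()], or several
#'   genomes' tables bound together.
#' @return A tibble with columns `genome_id`, `profile_acc`, `n` (number of
#'   genes assigned to that profile in that genome). Profiles with no
#'   assigned gene are absent (implicit count 0).
#' @export
count_profiles <- function(assignments) {
  assignments |>
    dplyr::count(.data$genome_id, .data$profile_acc, name = "n")
}
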