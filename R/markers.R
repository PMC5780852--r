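#' Build the genome-by-profile copy-number matrix
#'
#' @param counts Per-genome profile counts: either the output of
#'   [count_profiles()] (columns `genome_id`, `profile_acc`, `n`) or a
#'   combined best-hit assignment table (columns `genome_id`, `gene_id`,
#'   `profile_acc`), in which case genes are counted first. Genomes that
#'   contributed hits but have no surviving assignment still need a row
#'   elsewhere; pass their ids through `genome_ids` to keep all-zero rows.
#' @param genome_ids Optional character vector of all genome ids in the run
#'   (defaults to those present in `counts`).
#' @return An integer matrix of class `copy_matrix` with sorted genome rows
#'   and sorted profile columns; missing entries are 0.
#' @export
build_copy_matrix <- function(counts, genome_ids = NULL) {
  stopifnot(is.data.frame(counts))
  if (!"n" %in% names(counts)) {
    counts <- count_profiles(counts)
  }
  counts <- filter(counts, .data$n > 0)
  gids <- sort(unique(c(counts$genome_id, genome_ids)))
  if (anyDuplicated(genome_ids %||% character())) {
    abort("duplicate genome ids")
  }
  if (length(gids) < 2) {
    abort("need at least 2 genomes to build a copy-number matrix")
  }
  pids <- sort(unique(counts$profile_acc))
  m <- matrix(0L, nrow = length(gids), ncol = length(pids),
              dimnames = list(gids, pids))
  if (nrow(counts) > 0) {
    m[cbind(match(counts$genome_id, gids), match(counts$profile_acc, pids))] <-
      as.integer(counts$n)
  }
  class(m) <- c("copy_matrix", class(m))
  m
}

#' Select profiles single-copy in every genome
#'
#' A PFAM profile is a marker when its copy number is exactly 1 in each
#' genome of the matrix: profiles appearing more than once in any genome are
#' discarded, and the remainder must be present in all genomes.
#'
#' @param matrix A `copy_matrix` from [build_copy_matrix()].
#' @return A sorted character vector of marker profile accessions with an
#'   `n_genomes` attribute. An empty result raises a warning, not an error.
#' @export
select_markers <- function(matrix) {
  stopifnot(is.matrix(matrix))
  keep <- apply(matrix == 1L, 2, all)
  markers <- sort(colnames(matrix)[keep])
  if (length(markers) == 0) {
    warn("no single-copy marker profiles shared by all genomes")
  }
  attr(markers, "n_genomes") <- nrow(matrix)
  markers
}

#' Marker counts across a range of e-value cutoffs
#'
#' Re-runs best-hit selection, profile counting and marker selection from the
#' raw hits at each cutoff, mirroring how the pipeline's default cutoff
#' balances sensitivity and specificity.
#'
#' @param hits Raw hits for all genomes bound together (as from
#'   [parse_domtblout()] per genome plus `dplyr::bind_rows()`).
#' @param cutoffs Numeric vector of positive e-value cutoffs.
#' @return A tibble with columns `cutoff`, `n_markers` in input cutoff order.
#' @export
evalue_sweep <- function(hits, cutoffs) {
  stopifnot(length(cutoffs) > 0, all(cutoffs > 0))
  gids <- sort(unique(hits$genome_id))
  if (length(gids) < 2) {
    abort("need at least 2 genomes for an e-value sweep")
  }
  n_markers <- vapply(cutoffs, function(ct) {
    assignments <- hits |>
      dplyr::group_split(.data$genome_id) |>
      purrr::map(select_top_hits, evalue_cutoff = ct) |>
      bind_rows()
    if (nrow(assignments) == 0) {
      return(0L)
    }
    m <- build_copy_matrix(assignments, genome_ids = gids)
    length(suppressWarnings(select_markers(m)))
  }, integer(1))
  tibble(cutoff = cutoffs, n_markers = n_markers)
}

#' Tabulate the gene carrying each marker in each genome
#'
#' @param markers Marker accessions from [select_markers()].
#' @param assignments Combined best-hit table covering all genomes.
#' @return A tibble with a `profile_acc` column followed by one column per
#'   genome (sorted) holding the carrying gene id. Empty marker sets give a
#'   header-only table.
#' @export
marker_report <- function(markers, assignments) {
  gids <- sort(unique(assignments$genome_id))
  missing <- setdiff(markers, unique(assignments$profile_acc))
  if (length(missing) > 0) {
    abort(paste0("marker not present in assignments: ", missing[[1]]))
  }
  if (length(markers) == 0) {
    out <- tibble(profile_acc = character())
    for (g in gids) out[[g]] <- character()
    return(out)
  }
  rows <- assignments |>
    filter(.data$profile_acc %in% markers) |>
    select("profile_acc", "genome_id", "gene_id")
  bad <- rows |>
    dplyr::count(.data$profile_acc, .data$genome_id) |>
    filter(.data$n != 1)
  if (nrow(bad) > 0 || nrow(rows) != length(markers) * length(gids)) {
    abort("marker_report() requires exactly one assigned gene per genome per marker")
  }
  rows |>
    tidyr::pivot_wider(names_from = "genome_id", values_from = "gene_id",
                       names_sort = TRUE) |>
    arrange(.data$profile_acc)
}
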