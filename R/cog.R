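#' Parse a GO external2go cross-reference file
#'
#' Reads `pfam2go`/`cog2go`-style mappings, e.g.
#' `Pfam:PF00012 HSP70 > GO:protein folding ; GO:0006457`. Comment lines
#' start with `!`. Multiple lines for one source id are aggregated; the
#' `Pfam:`/`COG:` prefix and any version suffix are stripped.
#'
#' @param path Path to an external2go file.
#' @return A tibble with columns `source_id`, `go_id` (one row per pair,
#'   duplicates removed).
#' @export
parse_go_mapping <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("mapping file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^!", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(source_id = character(), go_id = character()))
  }
  out <- lapply(idx, function(i) {
    line <- lines[[i]]
    parts <- strsplit(line, ">", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      abort(paste0("malformed external2go line ", i, " in ", path,
                   ": no '>' separator"))
    }
    src <- strsplit(trimws(parts[[1]]), "\\s+")[[1]][[1]]
    src <- sub("^[A-Za-z_]+:", "", src)
    src <- sub("\\.\\d+$", "", src)
    gos <- unlist(regmatches(parts[[2]], gregexpr("GO:\\d{7}", parts[[2]])))
    if (length(gos) == 0) {
      abort(paste0("malformed external2go line ", i, " in ", path,
                   ": no GO id"))
    }
    tibble(source_id = src, go_id = gos)
  })
  distinct(bind_rows(out))
}

#' Map PFAM profiles to COGs through shared GO terms
#'
#' A PFAM maps to every COG annotated with at least one of the same GO
#' terms; PFAMs sharing no GO term with any COG are absent from the result.
#'
#' @param pfam_refs,cog_refs Tibbles from [parse_go_mapping()].
#' @return A tibble with columns `profile_acc`, `cog_id` (distinct pairs).
#' @export
map_pfam_to_cog <- function(pfam_refs, cog_refs) {
  pfam_refs |>
    dplyr::rename(profile_acc = "source_id") |>
    inner_join(dplyr::rename(cog_refs, cog_id = "source_id"),
               by = "go_id", relationship = "many-to-many") |>
    distinct(.data$profile_acc, .data$cog_id) |>
    arrange(.data$profile_acc, .data$cog_id)
}

#' Parse a COG category definition table
#'
#' Expects the NCBI `cognames`-style tab-separated layout: COG id, one or
#' more one-letter functional categories, description. Comment lines start
#' with `#`.
#'
#' @param path Path to the definitions file.
#' @return A tibble with columns `cog_id`, `categories` (string of
#'   uppercase letters), `description`.
#' @export
parse_cognames <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("COG definitions file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(paste0("malformed COG definitions line: ", lines[[bad[[1]]]]))
  }
  tibble(cog_id = vapply(fields, `[[`, "", 1L),
         categories = toupper(vapply(fields, `[[`, "", 2L)),
         description = vapply(fields, function(f) {
           if (length(f) >= 3) f[[3]] else ""
         }, ""))
}

#' Tally COG functional categories over a marker set
#'
#' Each marker contributes once to every distinct category in the union of
#' its mapped COGs' categories; markers mapping to no COG are reported
#' separately (only a fraction of profiles can typically be mapped).
#'
#' @param markers Marker accessions from [select_markers()].
#' @param pfam2cog Mapping from [map_pfam_to_cog()].
#' @param category_table COG definitions from [parse_cognames()].
#' @return A `cog_categorization` list: `category_counts` (tibble
#'   `category`, `n_markers`), `marker_cogs` (tibble `profile_acc`,
#'   `cog_ids`, `categories`), `unmapped` (character vector).
#' @export
categorize_markers <- function(markers, pfam2cog, category_table) {
  markers <- sort(unique(as.character(markers)))
  mapped <- pfam2cog |>
    filter(.data$profile_acc %in% markers) |>
    left_join(category_table, by = "cog_id")
  per_marker <- mapped |>
    group_by(.data$profile_acc) |>
    summarise(
      cog_ids = paste(sort(unique(.data$cog_id)), collapse = ","),
      categories = paste(sort(unique(unlist(
        strsplit(.data$categories[!is.na(.data$categories)], "")))),
        collapse = ""),
      .groups = "drop")
  unmapped <- setdiff(markers, per_marker$profile_acc)
  cat_long <- per_marker |>
    filter(nzchar(.data$categories)) |>
    mutate(category = strsplit(.data$categories, "")) |>
    tidyr::unnest("category")
  counts <- cat_long |>
    dplyr::count(.data$category, name = "n_markers") |>
    arrange(desc(.data$n_markers), .data$category)
  structure(list(category_counts = counts,
                 marker_cogs = per_marker,
                 unmapped = unmapped),
            class = "cog_categorization")
}

#' @export
print.cog_categorization <- function(x, ...) {
  cat("COG categorization: ", nrow(x$marker_cogs), " mapped markers, ",
      length(x$unmapped), " unmapped\n", sep = "")
  print(x$category_counts)
  invisible(x)
}
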