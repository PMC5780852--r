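#' Configuration for conserved-block alignment trimming
#'
#' Defaults follow the classic conserved-block method for protein
#' alignments: a position is conserved when its most frequent residue
#' reaches a strict majority (`floor(n/2) + 1` sequences) and highly
#' conserved at 85% of sequences (ceiling); runs of more than 8 contiguous
#' nonconserved positions are rejected; surviving blocks must span at least
#' 10 positions; and by default no gap-containing column survives.
#'
#' @param min_conserved_frac `NULL` for the strict-majority default, or a
#'   fraction in (0, 1]: the conserved threshold becomes
#'   `ceiling(frac * n)`.
#' @param min_flank_frac Fraction for the highly-conserved (flank)
#'   threshold, `ceiling(frac * n)`; default 0.85.
#' @param max_nonconserved_run Longest tolerated run of contiguous
#'   nonconserved columns (default 8).
#' @param min_block_len Minimum surviving block length (default 10).
#' @param allow_gaps `"none"` (any gap character flags the column),
#'   `"half"` (more than `n/2` gaps flags it), or `"all"` (gaps never flag
#'   a column).
#' @return A `trim_config` list.
#' @export
trim_config <- function(min_conserved_frac = NULL, min_flank_frac = 0.85,
                        max_nonconserved_run = 8, min_block_len = 10,
                        allow_gaps = c("none", "half", "all")) {
  allow_gaps <- match.arg(allow_gaps)
  stopifnot(max_nonconserved_run >= 1, min_block_len >= 2,
            min_flank_frac > 0, min_flank_frac <= 1)
  if (!is.null(min_conserved_frac)) {
    stopifnot(min_conserved_frac > 0, min_conserved_frac <= 1)
  }
  structure(list(min_conserved_frac = min_conserved_frac,
                 min_flank_frac = min_flank_frac,
                 max_nonconserved_run = as.integer(max_nonconserved_run),
                 min_block_len = as.integer(min_block_len),
                 allow_gaps = allow_gaps),
            class = "trim_config")
}

# per-n thresholds (counts of sequences)
trim_thresholds <- function(n, config) {
  conserved <- if (is.null(config$min_conserved_frac)) {
    floor(n / 2) + 1
  } else {
    ceiling(config$min_conserved_frac * n)
  }
  flank <- ceiling(config$min_flank_frac * n)
  if (flank < conserved) {
    abort("highly-conserved (flank) threshold must be >= conserved threshold")
  }
  list(conserved = conserved, flank = flank)
}

#' Classify alignment columns for trimming
#'
#' Each column is labelled `gap` (per the gap rule), else by the count `f`
#' of its most frequent residue: `nonconserved` when `f` is below the
#' conserved threshold, `highly_conserved` when `f` reaches the flank
#' threshold, `conserved` otherwise.
#'
#' @param alignment Named character vector of gapped rows, or a
#'   `concat_alignment`.
#' @param config A [trim_config()].
#' @return Character vector of per-column labels.
#' @export
classify_columns <- function(alignment, config = trim_config()) {
  rows <- if (inherits(alignment, "concat_alignment")) alignment$rows else alignment
  stopifnot(length(rows) >= 2)
  m <- aln_char_matrix(rows)
  n <- nrow(m)
  th <- trim_thresholds(n, config)
  gap_count <- .colSums(m == GAP, n, ncol(m))
  is_gap <- switch(config$allow_gaps,
                   none = gap_count > 0,
                   half = gap_count > n / 2,
                   all = rep(FALSE, ncol(m)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != GAP]
    if (length(col) == 0) 0L else max(tabulate(factor(col)))
  }, integer(1))
  labels <- ifelse(f < th$conserved, "nonconserved",
                   ifelse(f >= th$flank, "highly_conserved", "conserved"))
  labels[is_gap] <- "gap"
  labels
}

#' Select conserved blocks from column classifications
#'
#' Applies, in order: (1) reject gap columns together with the maximal runs
#' of nonconserved columns touching them; (2) reject maximal runs of more
#' than `max_nonconserved_run` contiguous surviving nonconserved columns;
#' (3) trim each surviving segment inward until both ends are highly
#' conserved; (4) drop segments shorter than `min_block_len`.
#'
#' @param classes Character vector of labels from [classify_columns()].
#' @param config A [trim_config()].
#' @return Sorted integer vector of retained 1-based column indices
#'   (possibly empty, with a warning).
#' @export
select_blocks <- function(classes, config = trim_config()) {
  stopifnot(all(classes %in% c("gap", "nonconserved", "conserved",
                               "highly_conserved")))
  n <- length(classes)
  rejected <- classes == "gap"
  # (1) extend rejection through nonconserved runs adjacent to gap columns
  r <- rle(classes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] == "nonconserved") {
      left_gap <- k > 1 && r$values[k - 1] == "gap"
      right_gap <- k < length(r$values) && r$values[k + 1] == "gap"
      if (left_gap || right_gap) rejected[starts[k]:ends[k]] <- TRUE
    }
  }
  # (2) over-long runs of surviving nonconserved columns
  nc <- !rejected & classes == "nonconserved"
  r2 <- rle(nc)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1
  for (k in seq_along(r2$values)) {
    if (r2$values[k] && r2$lengths[k] > config$max_nonconserved_run) {
      rejected[s2[k]:e2[k]] <- TRUE
    }
  }
  # (3) + (4) segments flanked by highly conserved columns, long enough
  keep <- integer(0)
  r3 <- rle(!rejected)
  e3 <- cumsum(r3$lengths)
  s3 <- e3 - r3$lengths + 1
  for (k in seq_along(r3$values)) {
    if (!r3$values[k]) next
    seg <- s3[k]:e3[k]
    hc <- which(classes[seg] == "highly_conserved")
    if (length(hc) == 0) next
    seg <- seg[hc[1]:hc[length(hc)]]
    if (length(seg) >= config$min_block_len) keep <- c(keep, seg)
  }
  if (length(keep) == 0) {
    warn("no alignment columns retained by block selection")
  }
  keep
}

#' Trim an alignment to its conserved blocks
#'
#' Removes highly variable or gapped positions, recomputes the partition map
#' in post-trim coordinates (markers whose retained width is 0 are dropped),
#' and reports per-marker retained/input widths.
#'
#' @param alignment A `concat_alignment` (from [concatenate_alignments()]).
#' @param config A [trim_config()].
#' @return A `trim_result` list: `alignment` (trimmed `concat_alignment`),
#'   `mask` (retained original 1-based column indices) and `report`
#'   (tibble `profile_acc`, `input_width`, `retained_width`). Errors when
#'   every column is removed.
#' @export
trim_alignment <- function(alignment, config = trim_config()) {
  stopifnot(inherits(alignment, "concat_alignment"))
  classes <- classify_columns(alignment$rows, config)
  keep <- suppressWarnings(select_blocks(classes, config))
  if (length(keep) == 0) {
    abort(paste0("empty alignment after trimming; relax trim_config() ",
                 "(e.g. allow_gaps, min_block_len) or use trim = \"none\""))
  }
  m <- aln_char_matrix(alignment$rows)[, keep, drop = FALSE]
  rows <- char_matrix_to_rows(m)
  p <- alignment$partitions
  retained <- vapply(seq_len(nrow(p)), function(i) {
    sum(keep >= p$start[i] & keep <= p$end[i])
  }, integer(1))
  report <- tibble(profile_acc = p$profile_acc,
                   input_width = p$end - p$start + 1L,
                   retained_width = retained)
  nonzero <- retained > 0
  ends <- cumsum(retained[nonzero])
  new_p <- tibble(profile_acc = p$profile_acc[nonzero],
                  start = as.integer(c(1, utils::head(ends, -1) + 1)),
                  end = as.integer(ends))
  structure(list(alignment = structure(list(rows = rows, partitions = new_p),
                                       class = "concat_alignment"),
                 mask = keep,
                 report = report),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat("Trimmed alignment: ", length(x$mask), " of ",
      sum(x$report$input_width), " columns retained across ",
      sum(x$report$retained_width > 0), " markers\n", sep = "")
  invisible(x)
}
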