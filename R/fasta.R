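#' Read a protein (or nucleotide) FASTA file into a tibble
#'
#' Reads one genome's sequences. Record ids are the first
#' whitespace-delimited token of each header and must be unique within the
#' file. Residues are uppercased, line breaks joined, and a single trailing
#' stop character (`*`) is stripped.
#'
#' @param path Path to a FASTA file, plain or gzip-compressed.
#' @param genome_id Genome label attached to every record. Defaults to the
#'   file name without its FASTA extension.
#' @return A tibble with columns `genome_id`, `gene_id`, `residues`, one row
#'   per record in file order.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 hypothetical", "MKV", "LA", ">g2", "MACDE"), fa)
#' read_fasta(fa, genome_id = "G1")
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|faa|fna|fasta)(\\.gz)?$", "",
                     basename(path), ignore.case = TRUE)
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("no sequences in ", path, " (", conditionMessage(e), ")"))
  )
  if (length(seqs) == 0) {
    abort(paste0("no sequences in ", path))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(ids == "")) {
    abort(paste0("empty sequence id in ", path))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id in ", path, ": ", dup[[1]]))
  }
  residues <- toupper(as.character(seqs))
  residues <- sub("\\*$", "", residues)
  if (any(nchar(residues) == 0)) {
    abort(paste0("empty sequence for id ", ids[nchar(residues) == 0][[1]], " in ", path))
  }
  tibble(genome_id = genome_id, gene_id = unname(ids), residues = unname(residues))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (names become headers) or a tibble with
#'   `gene_id` and `residues` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.data.frame(seqs)) {
    seqs <- setNames(seqs$residues, seqs$gene_id)
  }
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Classify input sequences as nucleotide or protein
#'
#' Pools the residues of all records; if at least 95% fall in
#' `{A, C, G, T, N, U}` the input is called nucleotide, otherwise protein.
#'
#' @param records A tibble with a `residues` column (as from [read_fasta()])
#'   or a character vector of sequences.
#' @return `"nucleotide"` or `"protein"`.
#' @examples
#' detect_input_kind(c("ACGTACGT"))
#' detect_input_kind(c("MKVLAWHE"))
#' @export
detect_input_kind <- function(records) {
  residues <- if (is.data.frame(records)) records$residues else records
  if (length(residues) == 0 || all(nchar(residues) == 0)) {
    abort("no sequences to classify")
  }
  chars <- unlist(strsplit(toupper(residues), "", fixed = TRUE), use.names = FALSE)
  frac <- mean(chars %in% DNA_CHARS)
  if (frac >= 0.95) "nucleotide" else "protein"
}
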