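
# ---- File formats -----------------------------------------------------------
#
# TSV everywhere, with '#'-prefixed metadata lines; FASTA for codon
# alignments; newick for trees. Codon positions and alignment columns are
# 1-based.

QUANT_COLUMNS <- c("species", "individual", "run", "peptide", "protein",
                   "is_standard", "ria")

#' Read a peptide quantification table
#'
#' Reads the quant TSV dialect (columns `species`, `individual`, `run`,
#' `peptide`, `protein`, `is_standard`, `ria`; `#` lines are metadata).
#' Rows with non-positive RIA values are collected into an error report
#' attached as attribute `"malformed"` and dropped; a wrong column set is an
#' error.
#'
#' @param path File path.
#' @return Validated tibble of measurements.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  missing <- setdiff(QUANT_COLUMNS, names(df))
  if (length(missing)) {
    stop("quant table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$is_standard <- as.logical(df$is_standard)
  bad <- !is.na(df$ria) & df$ria <= 0
  out <- df[!bad, QUANT_COLUMNS]
  attr(out, "malformed") <- df[bad, ]
  out
}

#' Write a peptide quantification table
#' @param data Quant tibble.
#' @param path Output path.
#' @param meta Optional named character vector written as `# key: value`.
#' @export
write_quant_table <- function(data, path, meta = NULL) {
  write_stage_tsv(data, path, meta)
}

write_stage_tsv <- function(data, path, meta = NULL) {
  # fixed 12-significant-digit formatting keeps reruns byte-identical
  fmt <- data
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.12g", fmt[[j]])
  }
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), path)
    readr::write_tsv(fmt, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(fmt, path)
  }
  invisible(path)
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences; errors on unequal
#'   lengths, out-of-frame length, or internal stop codons.
#' @export
read_codon_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  aln <- toupper(vapply(fa, `[[`, character(1), 1L))
  names(aln) <- names(fa)
  codon_index_matrix(aln)   # validates frame, lengths, stops
  aln
}

#' Write a codon alignment to FASTA
#' @param alignment Named character vector of sequences.
#' @param path Output path.
#' @export
write_codon_fasta <- function(alignment, path) {
  seqinr::write.fasta(as.list(unname(alignment)), names = names(alignment),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Parse a newick tree
#'
#' @param x A file path or a newick string.
#' @return A rooted `phylo`; newick syntax errors are reported as such.
#' @export
parse_newick <- function(x) {
  tr <- tryCatch(
    if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("newick syntax error in: ", substr(x, 1, 60), call. = FALSE)
  }
  tr
}

#' Read a per-species character table
#'
#' @param path TSV with a `species` column plus character columns.
#' @return Tibble.
#' @export
read_character_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"species" %in% names(df)) stop("character table needs a `species` column", call. = FALSE)
  df
}
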