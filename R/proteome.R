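# Gene-by-gene proteome comparison: the essentiality-conservation check
# between two strains' protein FASTA files.

#' Compare two proteomes gene by gene
#'
#' For each gene in `gene_list`, pairs the protein records of the two FASTA
#' files by gene name and reports exact matches, point substitutions (for
#' equal-length pairs), length mismatches, and genes present in only one
#' proteome. Genes are processed in lexicographic order and the four
#' categories partition the list. Positions are 1-based.
#'
#' @param fasta_a,fasta_b paths to protein FASTA files
#' @param gene_list character vector of gene names to compare (non-empty)
#' @param gene_pattern regular expression extracting the gene key from a
#'   FASTA header; the first match is used (default: the first
#'   whitespace-delimited token)
#' @return an object of class `mismatch_report` with fields:
#'   \describe{
#'     \item{identical}{genes with identical sequences}
#'     \item{substitutions}{named list: gene -> data.frame(position,
#'       residue_a, residue_b)}
#'     \item{length_mismatch}{named list: gene -> c(len_a, len_b)}
#'     \item{unmatched}{genes present in only one (or neither) proteome}
#'   }
#' @export
compare_proteomes <- function(fasta_a, fasta_b, gene_list,
                              gene_pattern = "^\\S+") {
  stopifnot(length(gene_list) >= 1L)
  a <- read_proteome(fasta_a, gene_pattern)
  b <- read_proteome(fasta_b, gene_pattern)
  genes <- sort(unique(as.character(gene_list)))
  rep <- list(identical = character(0), substitutions = list(),
              length_mismatch = list(), unmatched = character(0))
  for (g in genes) {
    in_a <- g %in% names(a)
    in_b <- g %in% names(b)
    if (!in_a || !in_b) {
      rep$unmatched <- c(rep$unmatched, g)
      next
    }
    sa <- a[[g]]
    sb <- b[[g]]
    if (nchar(sa) != nchar(sb)) {
      rep$length_mismatch[[g]] <- c(len_a = nchar(sa), len_b = nchar(sb))
    } else if (sa == sb) {
      rep$identical <- c(rep$identical, g)
    } else {
      ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
      cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
      pos <- which(ca != cb)
      rep$substitutions[[g]] <- data.frame(position = pos, residue_a = ca[pos],
                                           residue_b = cb[pos])
    }
  }
  structure(rep, class = "mismatch_report",
            gene_list = genes, files = c(a = fasta_a, b = fasta_b))
}

# Read a protein FASTA into a named character vector keyed by gene name.
read_proteome <- function(path, gene_pattern) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  m <- regmatches(names(seqs), regexpr(gene_pattern, names(seqs), perl = TRUE))
  if (length(m) != length(seqs) || any(!nzchar(m)))
    stop("gene_pattern failed to match every FASTA header in ", path)
  dup <- unique(m[duplicated(m)])
  if (length(dup))
    stop("duplicate gene name(s) in ", path, ": ", paste(dup, collapse = ", "))
  s <- toupper(as.character(seqs))
  if (any(nchar(s) == 0L)) stop("empty sequence in ", path)
  stats::setNames(s, m)
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf(paste0("<mismatch_report> %d genes: %d identical, %d with ",
                     "substitutions, %d length mismatches, %d unmatched\n"),
              length(attr(x, "gene_list")), length(x$identical),
              length(x$substitutions), length(x$length_mismatch),
              length(x$unmatched)))
  invisible(x)
}

#' Flatten a mismatch report to a table
#'
#' One row per gene (plus one row per substitution), suitable for writing as
#' TSV.
#'
#' @param report a [compare_proteomes()] result
#' @return a data.frame with columns `gene`, `status`, `position`,
#'   `residue_a`, `residue_b`, `len_a`, `len_b`
#' @export
mismatch_report_table <- function(report) {
  stopifnot(inherits(report, "mismatch_report"))
  rows <- list()
  empty <- data.frame(gene = character(0), status = character(0),
                      position = integer(0), residue_a = character(0),
                      residue_b = character(0), len_a = integer(0),
                      len_b = integer(0))
  for (g in report$identical)
    rows[[length(rows) + 1L]] <- data.frame(gene = g, status = "identical",
      position = NA_integer_, residue_a = NA_character_,
      residue_b = NA_character_, len_a = NA_integer_, len_b = NA_integer_)
  for (g in names(report$substitutions)) {
    s <- report$substitutions[[g]]
    rows[[length(rows) + 1L]] <- data.frame(gene = g, status = "substitution",
      position = s$position, residue_a = s$residue_a, residue_b = s$residue_b,
      len_a = NA_integer_, len_b = NA_integer_)
  }
  for (g in names(report$length_mismatch)) {
    l <- report$length_mismatch[[g]]
    rows[[length(rows) + 1L]] <- data.frame(gene = g, status = "length_mismatch",
      position = NA_integer_, residue_a = NA_character_,
      residue_b = NA_character_, len_a = l[["len_a"]], len_b = l[["len_b"]])
  }
  for (g in report$unmatched)
    rows[[length(rows) + 1L]] <- data.frame(gene = g, status = "unmatched",
      position = NA_integer_, residue_a = NA_character_,
      residue_b = NA_character_, len_a = NA_integer_, len_b = NA_integer_)
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out[order(out$gene, out$position), , drop = FALSE]
}
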