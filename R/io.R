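## Alignment and population-map I/O.
##
## Alignments are plain character matrices over {T,C,A,G} with sequence labels
## as row names and an optional "locus_kind" attribute ("mitochondrial" or
## "nuclear"); simulated data contain no gaps or ambiguity codes.

.DNA_ALPHABET <- c("T", "C", "A", "G")

#' Validate an alignment matrix
#' @param aln character matrix, rows = sequences.
#' @return the alignment, invisibly, after validation.
#' @export
validate_alignment <- function(aln) {
  stopifnot(is.matrix(aln), is.character(aln))
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln)))
    stop("alignment rows must carry unique sequence labels")
  if (!all(aln %in% .DNA_ALPHABET))
    stop("alignment characters must be in {T,C,A,G}")
  invisible(aln)
}

.as_dnabin <- function(aln) {
  ape::as.DNAbin(tolower(aln))
}

.from_dnabin <- function(dna) {
  m <- toupper(as.character(as.matrix(dna)))
  validate_alignment(m)
  m
}

#' Read / write FASTA alignments
#' @param file path.
#' @rdname fasta
#' @export
read_fasta <- function(file) .from_dnabin(ape::read.dna(file, format = "fasta"))

#' @param aln alignment matrix.
#' @rdname fasta
#' @export
write_fasta <- function(aln, file) {
  validate_alignment(aln)
  ape::write.dna(.as_dnabin(aln), file, format = "fasta", colsep = "")
  invisible(file)
}

#' Read / write sequential PHYLIP alignments
#' @param file path.
#' @rdname phylip
#' @export
read_phylip <- function(file) {
  .from_dnabin(ape::read.dna(file, format = "sequential"))
}

#' @param aln alignment matrix.
#' @rdname phylip
#' @export
write_phylip <- function(aln, file) {
  validate_alignment(aln)
  ape::write.dna(.as_dnabin(aln), file, format = "sequential",
                 colsep = "", nbcol = -1)
  invisible(file)
}

#' Read a population map (Imap-style)
#'
#' Two whitespace-delimited columns: sequence label, population label.
#'
#' @param file path.
#' @return named character vector: `popmap[sequence] = population`.
#' @export
read_popmap <- function(file) {
  tab <- utils::read.table(file, header = FALSE, col.names = c("seq", "pop"),
                           colClasses = "character")
  if (anyDuplicated(tab$seq)) stop("duplicate sequence labels in population map")
  setNames(tab$pop, tab$seq)
}

#' Write a population map (Imap-style)
#' @param popmap named character vector (names = sequence labels).
#' @param file path.
#' @export
write_popmap <- function(popmap, file) {
  utils::write.table(data.frame(names(popmap), unname(popmap)),
                     file, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(file)
}

.check_popmap <- function(aln_labels, popmap) {
  missing <- setdiff(aln_labels, names(popmap))
  if (length(missing))
    stop("sequences missing from population map: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
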