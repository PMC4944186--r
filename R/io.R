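#' Read and write FASTA / FASTQ files
#'
#' Thin wrappers around Biostrings that return plain data frames: one row
#' per record with columns `id` (first whitespace-delimited token of the
#' header), `seq` (upper-case DNA string) and, for FASTQ, `qual` (a list
#' column of integer Phred scores, Phred+33 -- the only dialect supported).
#'
#' @param path Path to the file.
#' @param records A data frame with columns `id`, `seq` and (for FASTQ)
#'   `qual`.
#' @return `read_fasta()` / `read_fastq()`: a data frame as described.
#'   The writers return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(data.frame(id = "r1", seq = "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(x))
  if (any(w <- Biostrings::width(x) == 0L)) {
    stop("empty sequence for record '", ids[which(w)[1]], "' (record ",
         which(w)[1], ") in '", path, "'")
  }
  data.frame(id = ids, seq = toupper(as.character(x)), row.names = NULL)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred")),
    error = function(e) stop("malformed FASTQ in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(x))
  quals <- tryCatch({
    qw <- Biostrings::width(Biostrings::quality(x))
    if (any(qw != Biostrings::width(x))) stop("length mismatch")
    as(Biostrings::quality(x), "IntegerList")
  }, error = function(e) {
    stop("malformed FASTQ in '", path, "': sequence/quality length mismatch ",
         "or undecodable quality string", call. = FALSE)
  })
  out <- data.frame(id = ids, seq = toupper(as.character(x)),
                    row.names = NULL)
  out$qual <- as.list(quals)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  if (is.null(qual)) stop("records must carry a 'qual' column to write FASTQ")
  qstr <- vapply(qual, function(q) intToUtf8(q + 33L), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(records$seq, records$id)),
    Biostrings::PhredQuality(qstr))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read and write taxonomy maps (sequence id to lineage string)
#'
#' The on-disk shape is the GreenGenes taxonomy file: two tab-separated
#' columns, `id` and a GreenGenes-style lineage string, one header row.
#'
#' @param path Path to the TSV file.
#' @param db A `reference_db` (see [generate_reference_db()]).
#' @return A data frame with columns `id` and `lineage` (string form).
#' @export
read_taxonomy_map <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  names(d) <- c("id", "lineage")
  invisible(lapply(d$lineage, parse_lineage)) # validate
  d
}

#' @rdname read_taxonomy_map
#' @export
write_taxonomy_map <- function(db, path) {
  d <- data.frame(id = db$records$id,
                  lineage = vapply(db$records$lineage, format_lineage,
                                   character(1)))
  write_tsv(d, path)
  invisible(path)
}

# single-header-row TSV, never quoted, never rownames
write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
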