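#' Read a FASTA file
#'
#' Validates the file record structure (reporting the offending line number on
#' malformed input) and returns the records, uppercased, in file order.
#' Parsing is delegated to [Biostrings::readDNAStringSet()] after validation.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence` (uppercase).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(lines[nonempty[1]], ">"))
    stop_input("malformed FASTA at line ", nonempty[1],
               ": expected a '>' header before sequence data")
  headers <- which(startsWith(lines, ">"))
  for (h in headers) {
    if (!nzchar(trimws(substring(lines[h], 2))))
      stop_input("malformed FASTA at line ", h, ": empty header")
  }
  ## a header immediately followed by another header (or EOF) has no sequence
  nxt <- c(headers[-1], length(lines) + 1L)
  for (k in seq_along(headers)) {
    body <- lines[seq(headers[k] + 1L, length.out = nxt[k] - headers[k] - 1L)]
    if (!any(nzchar(trimws(body))))
      stop_input("malformed FASTA at line ", headers[k],
                 ": record has no sequence")
  }
  set <- Biostrings::readBStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(set)),
             sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param ids Character vector of record ids (may include description text).
#' @param seqs Character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

## TSV with '# key=value' comment headers; stable byte-level output
write_tsv_commented <- function(df, path, headers = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(headers)) writeLines(paste0("# ", headers), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

read_tsv_commented <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
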