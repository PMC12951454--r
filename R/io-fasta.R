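AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and whitespace-stripped; characters outside the
#' 20 one-letter amino-acid codes plus `X` are rejected with the offending
#' record named.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, one element per record, in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0) stop("no FASTA records in ", path)
  seqs <- toupper(gsub("[[:space:]]", "", vapply(recs, `[[`, "", 1)))
  names(seqs) <- names(recs)
  for (i in seq_along(seqs)) check_sequence(seqs[i], names(seqs)[i])
  seqs
}

check_sequence <- function(seq, id = "<sequence>") {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("record %s contains illegal character(s): %s",
                 dQuote(id), paste(bad, collapse = ", ")))
  }
  invisible(seq)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  seqinr::write.fasta(as.list(seqs), names = names(seqs), file.out = path)
  invisible(path)
}
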