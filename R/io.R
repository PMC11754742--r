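# Format plumbing: FASTA/FASTQ input via Biostrings, TSV/JSON output.
#
# All tabular outputs are tab-separated UTF-8 with '#'-prefixed provenance
# comments and a single header row; column order is frozen so reruns on
# identical inputs are byte-identical.

#' Read a pre-edited/fully-edited reference pair from multi-FASTA
#'
#' The file must contain paired records named `<name>_preedited` and
#' `<name>_edited`.  With `name = NULL` the file must contain exactly one
#' such pair.
#'
#' @param path FASTA file.
#' @param name Transcript name; `NULL` to auto-detect a unique pair.
#' @return List with `name`, `pre`, `edited` (character sequences).
#' @export
read_reference_pair <- function(path, name = NULL) {
  if (!file.exists(path))
    stop_editpause(sprintf("reference FASTA not found: %s", path), "reference")
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  ids <- sub("\\s.*$", "", ids)
  pre_names <- sub("_preedited$", "", ids[grepl("_preedited$", ids)])
  if (is.null(name)) {
    if (length(pre_names) != 1L)
      stop_editpause(sprintf("expected exactly one *_preedited record, found %d",
                             length(pre_names)), "reference")
    name <- pre_names
  }
  want <- paste0(name, c("_preedited", "_edited"))
  miss <- setdiff(want, ids)
  if (length(miss))
    stop_editpause(sprintf("reference records missing from %s: %s", path,
                           paste(miss, collapse = ", ")), "reference")
  list(name = name,
       pre = as.character(seqs[[match(want[1], ids)]]),
       edited = as.character(seqs[[match(want[2], ids)]]))
}

#' Write a reference pair as multi-FASTA
#'
#' @param ref List with `name`, `pre`, `edited` (as from
#'   [read_reference_pair()] or [simulate_reference()]).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_reference_pair <- function(ref, path) {
  seqs <- Biostrings::DNAStringSet(c(ref$pre, ref$edited))
  names(seqs) <- paste0(ref$name, c("_preedited", "_edited"))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read amplicon reads from FASTA or FASTQ
#'
#' Format is inferred from the extension (`.fastq`/`.fq`, optionally
#' `.gz`-compressed, read as FASTQ; anything else as FASTA).  Qualities are
#' ignored.
#'
#' @param path Read file.
#' @return Named character vector of sequences.
#' @export
read_reads <- function(path) {
  if (!file.exists(path))
    stop_editpause(sprintf("read file not found: %s", path), "read_file")
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

# TSV with provenance comments; deterministic, never quoted.
write_tsv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, na = "NA")
  invisible(path)
}

#' Export a scaffold's per-ES table as TSV
#'
#' @param s An `editing_scaffold`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scaffold_tsv <- function(s, path) {
  write_tsv_commented(scaffold_table(s), path,
                      comments = sprintf("editing scaffold '%s': %d editing sites, ES1 = 3'-most gap",
                                         s$name, s$n_es))
}
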