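# Editing-site coordinate system.
#
# A U-indel editing substrate is represented by its "backbone": the sequence
# of non-T residues (A/C/G) shared between the pre-edited and the fully
# (canonically) edited version of a transcript.  Editing sites (ES) are the
# gaps between consecutive backbone residues, numbered 1..n_es from the 3'
# end (ES1 is the gap between the two 3'-most residues), matching the
# overall 3'-to-5' direction of editing.  Each ES carries a pre-edited and a
# canonical U count; interleaving the backbone with either count vector
# reconstructs the corresponding input sequence exactly.

.normalize_seq <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_editpause(sprintf("%s must be a single character string", what), "bad_input")
  x <- toupper(gsub("[[:space:]]", "", x))
  x <- chartr("U", "T", x)
  bad <- unique(strsplit(gsub("[ACGT]", "", x), "")[[1]])
  if (length(bad))
    stop_editpause(sprintf("%s contains unsupported characters (%s); degenerate/IUPAC bases are rejected",
                           what, paste(bad, collapse = ",")), "degenerate_base")
  x
}

.trim_terminal_t <- function(x) gsub("^T+|T+$", "", x)

.strip_t <- function(x) gsub("T", "", x)

# T-run lengths at the internal gaps of a terminally-trimmed sequence,
# returned in ES order (3'-most gap first).
.gap_runs <- function(x) {
  n_res <- nchar(.strip_t(x))
  pieces <- strsplit(x, "[^T]")[[1]]
  pieces <- c(pieces, character(n_res - length(pieces)))  # trailing empties dropped by strsplit
  rev(nchar(pieces[2:n_res]))
}

#' Build an editing-site scaffold from a pre-edited/fully-edited pair
#'
#' Aligns a pre-edited and a canonically edited sequence of the same
#' transcript by their shared non-T backbone and records, for every editing
#' site (ES), the pre-edited and canonical U count.  ES indices are 1-based
#' and numbered from the 3' end, so ES windows quoted in the editing
#' literature (e.g. ES121-126) map directly.
#'
#' Terminal T's (5' of the first or 3' of the last non-T residue) are trimmed
#' before construction: editing sites are defined between residues, and real
#' amplicons are primer-delimited in never-edited sequence.  `U` is accepted
#' and mapped to `T`; lowercase is accepted; degenerate (IUPAC) bases are
#' rejected.
#'
#' @param pre_seq Pre-edited nucleotide sequence (single string, DNA or RNA
#'   alphabet).
#' @param edited_seq Fully edited (canonical) sequence of the same
#'   transcript.
#' @param name Transcript identifier.
#' @return An object of class `editing_scaffold` with fields `name`,
#'   `backbone`, `n_es`, `pre_u`, `can_u` (U counts in ES order), and the
#'   trimmed input sequences.
#' @examples
#' s <- build_scaffold("GATTCGTA", "GTATTCTTTGA", "toy")
#' s$pre_u  # ES1..ES4
#' s$can_u
#' @export
build_scaffold <- function(pre_seq, edited_seq, name = "transcript") {
  pre <- .trim_terminal_t(.normalize_seq(pre_seq, "pre-edited sequence"))
  edt <- .trim_terminal_t(.normalize_seq(edited_seq, "edited sequence"))
  bb_pre <- .strip_t(pre)
  bb_edt <- .strip_t(edt)
  if (nchar(bb_pre) < 2L || nchar(bb_edt) < 2L)
    stop_editpause("each sequence needs at least two non-T residues", "empty_input")
  if (bb_pre != bb_edt)
    stop_editpause(sprintf("non-T backbones differ ('%s' vs '%s'): sequences are not an editing pair",
                           substr(bb_pre, 1, 40), substr(bb_edt, 1, 40)),
                   "backbone_mismatch")
  n_es <- nchar(bb_pre) - 1L
  structure(list(name = name, backbone = bb_pre, n_es = n_es,
                 pre_u = .gap_runs(pre), can_u = .gap_runs(edt),
                 pre_seq = pre, edited_seq = edt),
            class = "editing_scaffold")
}

#' Reconstruct a sequence from a scaffold and a U-count vector
#'
#' Inverse of [build_scaffold()]: interleaves the backbone residues (5' to
#' 3') with T-runs whose lengths are given per editing site.  Reconstructing
#' with `s$pre_u` returns the (trimmed) pre-edited input;  with `s$can_u`,
#' the fully edited input.
#'
#' @param s An `editing_scaffold`.
#' @param u Integer vector of U counts, length `s$n_es`, in ES order
#'   (ES1 = 3'-most gap).
#' @return A nucleotide string.
#' @export
reconstruct_sequence <- function(s, u) {
  stopifnot(inherits(s, "editing_scaffold"))
  if (length(u) != s$n_es)
    stop_editpause(sprintf("u has length %d but scaffold has %d editing sites",
                           length(u), s$n_es), "length_mismatch")
  if (any(is.na(u)) || any(u < 0))
    stop_editpause("U counts must be non-negative", "bad_input")
  res <- strsplit(s$backbone, "")[[1]]
  n <- length(res)
  paste0(paste0(res[-n], strrep("T", rev(u)), collapse = ""), res[n])
}

# Backbone index (count of non-T residues) at each position covered so far.
.nonT_count <- function(x, upto) nchar(.strip_t(substr(x, 1L, upto)))

.locate_primer <- function(ref, primer, what) {
  hits <- gregexpr(primer, ref, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop_editpause(sprintf("%s primer '%s' not found on reference", what, primer),
                   "primer_not_found")
  if (length(hits) > 1L)
    stop_editpause(sprintf("%s primer '%s' matches %d reference locations", what,
                           primer, length(hits)), "ambiguous_primer")
  as.integer(hits[1])
}

#' Restrict a scaffold to the editing sites covered by an amplicon
#'
#' Locates a forward and a reverse primer on the pre-edited reference (the
#' forward primer targets pre-edited sequence; the reverse primer lies in
#' never-edited sequence, identical in both references) and returns the
#' maximal inclusive ES range strictly between the two primer footprints.
#' Read classification ("fully edited up to the forward primer") is
#' evaluated only over this range.
#'
#' Both primers are given in sense-strand orientation, i.e. as they appear
#' reading the mRNA 5' to 3' (the reverse primer is the reverse complement
#' of the physical oligo).  The forward primer must end, and the reverse
#' primer begin, on a non-T base so the boundary between primer footprint
#' and scored T-runs is unambiguous.
#'
#' @param s An `editing_scaffold`.
#' @param fwd,rev Primer sequences (sense strand).
#' @return An `amplicon_window` with fields `fwd`, `rev`, `es_lo`, `es_hi`
#'   (inclusive ES range), and backbone footprint bounds.
#' @seealso [full_window()] for primer-free, whole-molecule analysis.
#' @export
restrict_to_amplicon <- function(s, fwd, rev) {
  stopifnot(inherits(s, "editing_scaffold"))
  fwd <- .normalize_seq(fwd, "forward primer")
  rev <- .normalize_seq(rev, "reverse primer")
  if (!nzchar(fwd) || !nzchar(rev))
    stop_editpause("primers must be non-empty (use full_window() for primer-free input)",
                   "bad_input")
  fpos <- .locate_primer(s$pre_seq, fwd, "forward")
  rpos <- .locate_primer(s$pre_seq, rev, "reverse")
  fend <- fpos + nchar(fwd) - 1L
  if (rpos <= fend)
    stop_editpause("reverse primer footprint does not lie 3' of the forward primer",
                   "bad_input")
  if (substr(s$pre_seq, fend, fend) == "T")
    stop_editpause("forward primer must end on a non-T base", "primer_boundary")
  if (substr(s$pre_seq, rpos, rpos) == "T")
    stop_editpause("reverse primer must start on a non-T base", "primer_boundary")
  f2 <- .nonT_count(s$pre_seq, fend)        # backbone index of last fwd-footprint residue
  r1 <- .nonT_count(s$pre_seq, rpos)        # backbone index of first rev-footprint residue
  if (r1 - 1L < f2)
    stop_editpause("no editing sites between the primer footprints", "empty_window")
  structure(list(fwd = fwd, rev = rev,
                 es_lo = s$n_es + 1L - (r1 - 1L),
                 es_hi = s$n_es + 1L - f2,
                 bb_from = f2, bb_to = r1, has_primers = TRUE),
            class = "amplicon_window")
}

#' Whole-molecule window for primer-free reads
#'
#' Covers every editing site of the scaffold; reads are expected to span the
#' whole (terminally T-trimmed) molecule with primers already removed.
#'
#' @param s An `editing_scaffold`.
#' @return An `amplicon_window` covering ES `1..n_es`.
#' @export
full_window <- function(s) {
  stopifnot(inherits(s, "editing_scaffold"))
  structure(list(fwd = "", rev = "", es_lo = 1L, es_hi = s$n_es,
                 bb_from = 1L, bb_to = s$n_es + 1L, has_primers = FALSE),
            class = "amplicon_window")
}

#' Per-editing-site table of a scaffold
#'
#' @param s An `editing_scaffold`.
#' @return A data frame with columns `es`, `pre_u`, `can_u` (ES ascending,
#'   i.e. 3' to 5').
#' @export
scaffold_table <- function(s) {
  stopifnot(inherits(s, "editing_scaffold"))
  data.frame(es = seq_len(s$n_es), pre_u = s$pre_u, can_u = s$can_u)
}

#' @export
print.editing_scaffold <- function(x, ...) {
  cat(sprintf("editing_scaffold '%s': %d backbone residues, %d editing sites\n",
              x$name, nchar(x$backbone), x$n_es))
  cat(sprintf("  pre-edited U total: %d   canonical U total: %d   sites with editing action: %d\n",
              sum(x$pre_u), sum(x$can_u), sum(x$pre_u != x$can_u)))
  invisible(x)
}

#' @export
print.amplicon_window <- function(x, ...) {
  cat(sprintf("amplicon_window: ES%d-ES%d (%d sites)%s\n", x$es_lo, x$es_hi,
              x$es_hi - x$es_lo + 1L,
              if (x$has_primers) sprintf(", primers %dnt/%dnt", nchar(x$fwd), nchar(x$rev))
              else ", primer-free"))
  invisible(x)
}
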