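# Read reduction, exclusion filtering, classification and junction calling.
#
# Each amplicon read is reduced to its observed per-ES U-count vector by
# exact non-T backbone matching between the primer footprints.  Any read
# whose non-T residue string differs from the reference backbone over the
# window (a non-T SNP or indel relative to the canonical sequence) is
# excluded rather than error-corrected; exclusions are reason-coded so
# counts stay auditable.

READ_CLASSES <- c("EXCLUDED", "PRE_EDITED", "PARTIALLY_EDITED", "FULLY_EDITED")

.window_k <- function(w) w$es_hi - w$es_lo + 1L

.window_pre <- function(s, w) s$pre_u[w$es_lo:w$es_hi]
.window_can <- function(s, w) s$can_u[w$es_lo:w$es_hi]

# Parse T-run lengths from insert strings whose non-T residues have already
# been verified against the backbone.  `n_runs` runs are returned per read,
# 5'->3' (leading run first); `lead` says whether the leading piece is a
# scored run (primer-delimited insert) or a residue-anchored start
# (primer-free, terminally trimmed read).  A sentinel residue appended to
# each insert makes every read split into the same number of pieces, so the
# run lengths unlist into a matrix without per-read handling.
.parse_runs <- function(inserts, n_runs, lead) {
  if (lead) {
    # sentinel keeps a trailing empty run from being dropped
    pieces <- strsplit(paste0(inserts, "A"), "[^T]")
    matrix(nchar(unlist(pieces)), length(inserts), n_runs, byrow = TRUE)
  } else {
    # reads end on a residue: always 1 leading piece + n_runs internal runs
    pieces <- strsplit(inserts, "[^T]")
    m <- matrix(nchar(unlist(pieces)), length(inserts), n_runs + 1L, byrow = TRUE)
    m[, -1L, drop = FALSE]
  }
}

# Vectorised core: reduce a character vector of reads to a U-count matrix.
# Returns list(u = n x k integer matrix (NA rows for excluded reads),
# excluded, reason).
.align_core <- function(s, w, reads, min_length = 0L) {
  n <- length(reads)
  reads <- toupper(chartr("Uu", "Tt", reads))
  k <- .window_k(w)
  reason <- rep(NA_character_, n)
  u <- matrix(NA_integer_, n, k)

  reason[nchar(reads) < min_length] <- "too-short"
  ok <- is.na(reason)

  if (w$has_primers) {
    insert <- rep(NA_character_, n)
    expected_bb <- substr(s$backbone, w$bb_from + 1L, w$bb_to - 1L)
    fhits <- gregexpr(w$fwd, reads, fixed = TRUE)
    f1 <- vapply(fhits, function(h) if (h[1] == -1L || length(h) > 1L) NA_integer_
                 else as.integer(h[1]), integer(1))
    bad <- ok & is.na(f1)
    reason[bad] <- "primer-missing"
    ok <- is.na(reason)
    fend <- f1 + nchar(w$fwd) - 1L
    tail_part <- ifelse(ok, substr(reads, fend + 1L, nchar(reads)), "")
    rhits <- gregexpr(w$rev, tail_part, fixed = TRUE)
    r1 <- vapply(rhits, function(h) if (h[1] == -1L || length(h) > 1L) NA_integer_
                 else as.integer(h[1]), integer(1))
    bad <- ok & is.na(r1)
    reason[bad] <- "primer-missing"
    ok <- is.na(reason)
    insert[ok] <- substr(tail_part[ok], 1L, r1[ok] - 1L)
    bad <- ok & gsub("T", "", insert) != expected_bb
    reason[bad] <- "backbone-mismatch"
    ok <- is.na(reason)
    if (any(ok)) {
      runs <- .parse_runs(insert[ok], k, lead = TRUE)
      u[ok, ] <- runs[, k:1L, drop = FALSE]   # 5'->3' gaps -> ES ascending
    }
  } else {
    trimmed <- .trim_terminal_t(reads)
    bad <- ok & gsub("T", "", trimmed) != s$backbone
    reason[bad] <- "backbone-mismatch"
    ok <- is.na(reason)
    if (any(ok)) {
      runs <- .parse_runs(trimmed[ok], s$n_es, lead = FALSE)
      u[ok, ] <- runs[, s$n_es:1L, drop = FALSE]
    }
  }
  list(u = u, excluded = !is.na(reason), reason = reason)
}

#' Reduce a single read to its per-ES U-count vector
#'
#' Locates both primer footprints on the read (exact match; the read is
#' assumed sense-strand, see [orient_reads()]), extracts the non-T residue
#' string between them, and — if and only if it equals the reference
#' backbone over the amplicon window — returns the T-run length at each ES.
#' All failure modes are encoded as exclusion reasons (`"primer-missing"`,
#' `"backbone-mismatch"`, `"too-short"`) rather than raised, so exclusion
#' counts are auditable downstream.
#'
#' @param s An `editing_scaffold`.
#' @param w An `amplicon_window`.  For a primer-free window
#'   ([full_window()]) the read must span the whole trimmed molecule.
#' @param read Nucleotide string.
#' @param min_length Reads shorter than this are excluded as `"too-short"`.
#' @param read_id Optional identifier carried through to output.
#' @return An `aligned_read`: list with `read_id`, `u_obs` (named integer
#'   vector over `es_lo..es_hi`, or `NULL` if excluded), `excluded`,
#'   `reason`.
#' @examples
#' s <- build_scaffold("GATTCGTA", "GTATTCTTTGA", "toy")
#' align_read(s, full_window(s), "GACTTTGA")$u_obs
#' @export
align_read <- function(s, w, read, min_length = 0L, read_id = NULL) {
  core <- .align_core(s, w, read, min_length)
  u <- if (core$excluded[1]) NULL else {
    v <- core$u[1L, ]
    names(v) <- paste0("ES", w$es_lo:w$es_hi)
    v
  }
  structure(list(read_id = read_id, u_obs = u,
                 excluded = core$excluded[1], reason = core$reason[1]),
            class = "aligned_read")
}

# Vectorised classification of a U-count matrix against window references
# (u is n x k; references recycle column-major via rep(..., each = n)).
.classify_u <- function(u, pre_w, can_w) {
  n <- nrow(u)
  is_full <- rowSums(u != rep(can_w, each = n)) == 0L
  is_pre <- rowSums(u != rep(pre_w, each = n)) == 0L
  ifelse(is_full, "FULLY_EDITED", ifelse(is_pre, "PRE_EDITED", "PARTIALLY_EDITED"))
}

# Vectorised junction boundaries.  jss: smallest ES (3'-most, since editing
# runs 3'->5') whose U count fails the canonical sequence; jes: largest ES
# with any editing action (U count differing from pre-edited).  Both NA for
# reads that are wholly pre-edited or wholly canonical over the window.
.junction_u <- function(u, pre_w, can_w, es) {
  n <- nrow(u)
  d_can <- u != rep(can_w, each = n)     # n x k
  d_pre <- u != rep(pre_w, each = n)
  cls <- ifelse(rowSums(d_can) == 0L, "FULLY_EDITED",
                ifelse(rowSums(d_pre) == 0L, "PRE_EDITED", "PARTIALLY_EDITED"))
  jss <- es[max.col(d_can, ties.method = "first")]
  jes <- es[max.col(d_pre, ties.method = "last")]
  partial <- cls == "PARTIALLY_EDITED"
  jss[!partial] <- NA_integer_
  jes[!partial] <- NA_integer_
  list(class = cls, jss = jss, jes = jes)
}

.check_aligned <- function(a) {
  if (!inherits(a, "aligned_read"))
    stop_editpause("expected an aligned_read", "bad_input")
  if (a$excluded)
    stop_editpause(sprintf("read is excluded (%s)", a$reason), "excluded_read")
}

#' Classify an aligned read over the amplicon window
#'
#' A read is `FULLY_EDITED` iff its U counts match the canonical counts at
#' every ES in the window ("fully edited up to the forward primer"),
#' `PRE_EDITED` iff they match the pre-edited counts everywhere, and
#' `PARTIALLY_EDITED` otherwise.  Sites where the pre-edited and canonical
#' counts coincide are consistent with both and constrain neither call; a
#' read matching both references is reported `FULLY_EDITED`.
#'
#' @param a An `aligned_read` (not excluded).
#' @param s,w Scaffold and window used for the alignment.
#' @return One of `"PRE_EDITED"`, `"PARTIALLY_EDITED"`, `"FULLY_EDITED"`.
#' @export
classify_read <- function(a, s, w) {
  .check_aligned(a)
  .classify_u(matrix(a$u_obs, 1L), .window_pre(s, w), .window_can(s, w))
}

#' Call junction boundaries for an aligned read
#'
#' The junction start site (JSS) is the first ES that, moving 3' to 5'
#' (i.e. in ascending ES order), fails to match the canonical fully edited
#' sequence; the junction end site (JES) is the 5'-most ES with any editing
#' action — a U count differing from pre-edited — whether canonical or not.
#' Both are `NA` for pre-edited and fully edited reads.  `jes == jss - 1`
#' encodes an empty junction: canonical editing up to `jes` followed
#' directly by pre-edited sequence; such reads still contribute their JES
#' to pause profiles.
#'
#' @inheritParams classify_read
#' @return List with integer `jss` and `jes` (`NA` when undefined).
#' @export
call_junction <- function(a, s, w) {
  .check_aligned(a)
  j <- .junction_u(matrix(a$u_obs, 1L), .window_pre(s, w), .window_can(s, w),
                   w$es_lo:w$es_hi)
  list(jss = j$jss, jes = j$jes)
}

#' Align, filter, classify and junction-call a set of reads
#'
#' Vectorised pipeline stage combining [align_read()], [classify_read()] and
#' [call_junction()] over a read set.
#'
#' @param s An `editing_scaffold`.
#' @param w An `amplicon_window`.
#' @param reads Character vector of read sequences (sense strand).
#' @param ids Read identifiers (defaults to `read1..readN`).
#' @param min_length Minimum read length; shorter reads are excluded.
#' @param force_exclude Optional character vector (length of `reads`):
#'   non-`NA` entries exclude the read with that reason before alignment
#'   (used e.g. for orientation-ambiguous reads).
#' @return A `read_calls` data frame with columns `read_id`, `class`
#'   (`EXCLUDED`/`PRE_EDITED`/`PARTIALLY_EDITED`/`FULLY_EDITED`), `jss`,
#'   `jes`, `u` (comma-joined U counts, ES ascending), `exclusion_reason`.
#' @export
call_reads <- function(s, w, reads, ids = NULL, min_length = 0L,
                       force_exclude = NULL) {
  n <- length(reads)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  if (n == 0L) {
    out <- data.frame(read_id = character(0), class = character(0),
                      jss = integer(0), jes = integer(0), u = character(0),
                      exclusion_reason = character(0), stringsAsFactors = FALSE)
    attr(out, "window") <- c(w$es_lo, w$es_hi)
    class(out) <- c("read_calls", "data.frame")
    return(out)
  }
  core <- .align_core(s, w, reads, min_length)
  if (!is.null(force_exclude)) {
    pre <- !is.na(force_exclude)
    core$excluded[pre] <- TRUE
    core$reason[pre] <- force_exclude[pre]
    core$u[pre, ] <- NA_integer_
  }
  ok <- !core$excluded
  cls <- rep("EXCLUDED", n)
  jss <- rep(NA_integer_, n)
  jes <- rep(NA_integer_, n)
  ustr <- rep(NA_character_, n)
  if (any(ok)) {
    j <- .junction_u(core$u[ok, , drop = FALSE], .window_pre(s, w),
                     .window_can(s, w), w$es_lo:w$es_hi)
    cls[ok] <- j$class
    jss[ok] <- j$jss
    jes[ok] <- j$jes
    uok <- core$u[ok, , drop = FALSE]
    ustr[ok] <- do.call(paste, c(asplit(uok, 2L), sep = ","))
  }
  out <- data.frame(read_id = ids, class = cls, jss = jss, jes = jes,
                    u = ustr, exclusion_reason = core$reason,
                    stringsAsFactors = FALSE)
  attr(out, "window") <- c(w$es_lo, w$es_hi)
  class(out) <- c("read_calls", "data.frame")
  out
}

#' Orient reads against an amplicon's primer pair
#'
#' In `"auto"` mode a read is reverse-complemented when the primer pair
#' matches the reverse complement but not the read as given; reads matching
#' both orientations (pathological, e.g. palindromic primers) or flagged for
#' neither are left untouched and marked ambiguous/unmatched so the caller
#' can exclude them as `"primer-missing"`.
#'
#' @param reads Character vector of read sequences.
#' @param w An `amplicon_window` with primers.
#' @param policy `"as-is"` (default) or `"auto"`.
#' @return List with `reads` (oriented), `flipped` (logical), and
#'   `ambiguous` (logical: matched both orientations).
#' @export
orient_reads <- function(reads, w, policy = c("as-is", "auto")) {
  policy <- match.arg(policy)
  n <- length(reads)
  if (policy == "as-is" || !isTRUE(w$has_primers))
    return(list(reads = reads, flipped = logical(n), ambiguous = logical(n)))
  up <- toupper(chartr("Uu", "Tt", reads))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
  fwd_ok <- grepl(w$fwd, up, fixed = TRUE) & grepl(w$rev, up, fixed = TRUE)
  rev_ok <- grepl(w$fwd, rc, fixed = TRUE) & grepl(w$rev, rc, fixed = TRUE)
  flipped <- rev_ok & !fwd_ok
  out <- up
  out[flipped] <- rc[flipped]
  list(reads = out, flipped = flipped, ambiguous = fwd_ok & rev_ok)
}
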