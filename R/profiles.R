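# Normalized per-sample profiles and differential pause-site detection.
#
# Read counts are scaled so that the non-excluded reads of every sample sum
# to 100,000, allowing relative abundances of specific sequences and
# junction end sites to be compared across samples.  Normalized counts are
# kept as non-integer weights internally; conservation invariants hold
# exactly pre-rounding.

NORM_TOTAL <- 1e5

#' Normalize a sample's read calls into a per-ES junction-end profile
#'
#' Weights every non-excluded read by `100000 / n_non_excluded`, tallies the
#' normalized read-class counts, the per-ES histogram of junction end sites
#' (JES), and a per-distinct-U-vector sequence table.  Excluded reads are
#' reported but carry no weight.
#'
#' @param calls A `read_calls` data frame from [call_reads()].
#' @param sample_id Sample identifier.
#' @param condition Condition label (e.g. `"induced"`/`"uninduced"`).
#' @param replicate Replicate index.
#' @return A `sample_profile`: list with `class_norm` (normalized class
#'   counts), `jes_hist` (normalized JES counts, named by ES over the
#'   window), `seq_table` (distinct U vectors with class, jss, jes and
#'   normalized count), raw tallies and exclusion reasons.
#' @export
normalize_sample <- function(calls, sample_id = "sample", condition = NA_character_,
                             replicate = NA_integer_) {
  win <- attr(calls, "window")
  if (is.null(win))
    stop_editpause("calls must come from call_reads() (missing window attribute)",
                   "bad_input")
  ok <- calls$class != "EXCLUDED"
  n_ok <- sum(ok)
  if (n_ok == 0L)
    stop_editpause(sprintf("sample '%s' has no non-excluded reads", sample_id),
                   "empty_sample")
  wgt <- NORM_TOTAL / n_ok

  cls <- factor(calls$class[ok], levels = setdiff(READ_CLASSES, "EXCLUDED"))
  class_norm <- as.numeric(table(cls)) * wgt
  names(class_norm) <- levels(cls)

  es_domain <- win[1]:win[2]
  jes_ok <- calls$jes[ok]
  jes_hist <- as.numeric(table(factor(jes_ok, levels = es_domain))) * wgt
  names(jes_hist) <- es_domain

  kept <- calls[ok, c("u", "class", "jss", "jes"), drop = FALSE]
  key <- paste(kept$u, kept$class, sep = "\x1f")   # u + class determine jss/jes
  first <- !duplicated(key)
  n_per <- tabulate(match(key, key[first]), nbins = sum(first))
  seq_table <- data.frame(u = kept$u[first], class = kept$class[first],
                          jss = kept$jss[first], jes = kept$jes[first],
                          count_norm = n_per * wgt,
                          stringsAsFactors = FALSE)
  seq_table <- seq_table[order(-seq_table$count_norm, seq_table$u), , drop = FALSE]
  rownames(seq_table) <- NULL

  reasons <- table(calls$exclusion_reason[!ok])
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = replicate, window = win,
                 n_reads = nrow(calls), n_excluded = sum(!ok),
                 exclusion_reasons = reasons,
                 class_norm = class_norm, jes_hist = jes_hist,
                 seq_table = seq_table),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("sample_profile '%s' (%s, rep %s): %d reads, %d excluded\n",
              x$sample_id, x$condition, x$replicate, x$n_reads, x$n_excluded))
  cat("  normalized classes:",
      paste(sprintf("%s=%.1f", names(x$class_norm), x$class_norm), collapse = "  "), "\n")
  invisible(x)
}

.profile_matrix <- function(profiles) {
  wins <- unique(lapply(profiles, function(p) p$window))
  if (length(wins) != 1L)
    stop_editpause("profiles cover different ES windows", "bad_input")
  do.call(rbind, lapply(profiles, function(p) p$jes_hist))
}

# Fold change with the pseudocount policy: a pseudocount of 1 normalized
# read is added to both means only when the denominator is zero, keeping
# fold changes finite and monotone without perturbing well-covered sites.
.fold_change <- function(num, den) ifelse(den > 0, num / den, (num + 1) / (den + 1))

#' Detect exacerbated junction end sites (EJES) between two conditions
#'
#' An ES is called an EJES — operationally, an editing pause site — when its
#' mean normalized JES count in the induced (perturbed) condition is at
#' least `fold_min` times the uninduced mean, and at least `min_replicates`
#' induced replicates carry `min_norm_reads` or more normalized JES reads at
#' that site.  The full per-ES table is returned regardless of pass status.
#'
#' @param induced,uninduced Lists of `sample_profile` objects (one per
#'   replicate) for the perturbed and control condition.
#' @param fold_min Minimum induced/uninduced fold change (default 3).
#' @param min_norm_reads Minimum normalized JES count per qualifying induced
#'   replicate (default 100).
#' @param min_replicates Number of induced replicates that must clear
#'   `min_norm_reads` (default 2).
#' @return An `ejes_table` data frame with columns `es`, `mean_induced`,
#'   `mean_uninduced`, `fold_change`, `n_induced_ge_min`, `pass`.
#' @export
detect_ejes <- function(induced, uninduced, fold_min = 3, min_norm_reads = 100,
                        min_replicates = 2) {
  if (min_replicates >= 2 && (length(induced) < 2L || length(uninduced) < 2L))
    stop_editpause("each condition needs at least two replicate profiles",
                   "replicate_mismatch")
  if (length(induced) < min_replicates)
    stop_editpause(sprintf("min_replicates=%d exceeds the %d induced replicates",
                           min_replicates, length(induced)), "replicate_mismatch")
  mi <- .profile_matrix(induced)
  mu <- .profile_matrix(uninduced)
  if (!identical(colnames(mi), colnames(mu)))
    stop_editpause("conditions cover different ES windows", "bad_input")
  mean_i <- colMeans(mi)
  mean_u <- colMeans(mu)
  fold <- .fold_change(mean_i, mean_u)
  n_ge <- colSums(mi >= min_norm_reads)
  out <- data.frame(es = as.integer(colnames(mi)),
                    mean_induced = unname(mean_i),
                    mean_uninduced = unname(mean_u),
                    fold_change = unname(fold),
                    n_induced_ge_min = unname(n_ge),
                    pass = unname(fold >= fold_min & n_ge >= min_replicates))
  class(out) <- c("ejes_table", "data.frame")
  out
}

.check_window <- function(window, domain) {
  if (length(window) != 2L || any(is.na(window)) || window[1] > window[2])
    stop_editpause("window must be c(es_lo, es_hi) with es_lo <= es_hi", "bad_input")
  if (window[2] < domain[1] || window[1] > domain[2])
    stop_editpause(sprintf("window ES%d-ES%d lies outside the profiled range ES%d-ES%d",
                           window[1], window[2], domain[1], domain[2]),
                   "empty_window")
}

#' Filter distinct sequences pausing inside an ES window
#'
#' Returns the distinct U vectors whose JES falls inside `window` (inclusive
#' on both ends), whose mean normalized count in the induced (depleted)
#' condition is at least `min_reads`, and whose induced/uninduced mean ratio
#' is at least `fold_min` — the per-sequence view of a pause region.
#'
#' @inheritParams detect_ejes
#' @param window Inclusive ES range, `c(lo, hi)`.
#' @param min_reads Minimum mean normalized count in the induced condition.
#' @return Data frame with columns `u`, `class`, `jss`, `jes`,
#'   `mean_induced`, `mean_uninduced`, `fold_change`, sorted by induced
#'   count descending.
#' @export
filter_window_sequences <- function(induced, uninduced, window, fold_min = 3,
                                    min_reads = 100) {
  all_prof <- c(induced, uninduced)
  wins <- unique(lapply(all_prof, function(p) p$window))
  if (length(wins) != 1L)
    stop_editpause("profiles cover different ES windows", "bad_input")
  .check_window(window, wins[[1]])

  cond_means <- function(profiles) {
    tabs <- lapply(profiles, function(p) p$seq_table)
    pooled <- do.call(rbind, tabs)
    pooled <- pooled[!is.na(pooled$jes), , drop = FALSE]  # only junction-bearing reads
    if (nrow(pooled) == 0L)
      return(data.frame(u = character(0), class = character(0),
                        jss = integer(0), jes = integer(0), mean = numeric(0)))
    agg <- stats::aggregate(list(total = pooled$count_norm),
                            by = pooled[c("u", "class", "jss", "jes")],
                            FUN = sum)
    agg$mean <- agg$total / length(profiles)
    agg$total <- NULL
    agg
  }
  ind <- cond_means(induced)
  uni <- cond_means(uninduced)
  merged <- merge(ind, uni, by = c("u", "class", "jss", "jes"), all = TRUE,
                  suffixes = c("_induced", "_uninduced"))
  merged$mean_induced <- ifelse(is.na(merged$mean_induced), 0, merged$mean_induced)
  merged$mean_uninduced <- ifelse(is.na(merged$mean_uninduced), 0, merged$mean_uninduced)
  merged$fold_change <- .fold_change(merged$mean_induced, merged$mean_uninduced)
  keep <- !is.na(merged$jes) & merged$jes >= window[1] & merged$jes <= window[2] &
    merged$mean_induced >= min_reads & merged$fold_change >= fold_min
  out <- merged[keep, c("u", "class", "jss", "jes", "mean_induced",
                        "mean_uninduced", "fold_change"), drop = FALSE]
  out <- out[order(-out$mean_induced, out$u), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- wins[[1]]
  out
}

#' Percentage of a sample's reads with JES inside an ES window
#'
#' `100 * (normalized reads with JES in window) / 100000`, i.e. the percent
#' of all non-excluded reads in the sample whose editing pauses inside the
#' window.
#'
#' @param p A `sample_profile`.
#' @param window Inclusive ES range, `c(lo, hi)`.
#' @return A percentage in `[0, 100]`.
#' @export
percent_jes_in_window <- function(p, window) {
  stopifnot(inherits(p, "sample_profile"))
  .check_window(window, p$window)
  es <- as.integer(names(p$jes_hist))
  100 * sum(p$jes_hist[es >= window[1] & es <= window[2]]) / NORM_TOTAL
}

#' Compare per-replicate window percentages between two conditions
#'
#' Two-sample Student's t-test (equal variance, two-sided) on per-replicate
#' window percentages; Welch's correction available by flag.  When the
#' pooled variance is zero the statistic is undefined: identical group means
#' are reported as `t = 0, p = 1`, differing means as a degenerate result
#' with `NA` statistic.
#'
#' @param x,y Numeric vectors of per-replicate percentages (length >= 2
#'   each).
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @return List with `t`, `df`, `p_value`, `mean_x`, `mean_y`, `degenerate`.
#' @export
compare_conditions <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop_editpause("each condition needs at least two replicate values",
                   "replicate_mismatch")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2L, p_value = 1,
                  mean_x = mean(x), mean_y = mean(y), degenerate = FALSE))
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                mean_x = mean(x), mean_y = mean(y), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y),
       degenerate = FALSE)
}

#' Render distinct window sequences against the references
#'
#' Text rendering of filtered U vectors aligned with the pre-edited (PRE)
#' and fully edited (EDIT) rows: at each ES the inserted U's are written as
#' lowercase `u`, padded with `-` to a per-column width, with backbone
#' residues between.  ES ascend right-to-left (3' end at the right),
#' following the 3'-to-5' direction of editing.
#'
#' @param s An `editing_scaffold`.
#' @param seqs Data frame from [filter_window_sequences()] (columns `u`,
#'   `mean_induced`, `mean_uninduced`, `fold_change`), or `NULL` to render
#'   only the reference rows.
#' @param window Inclusive ES range to display.
#' @return Character vector of display lines.
#' @export
render_window_sequences <- function(s, seqs, window) {
  stopifnot(inherits(s, "editing_scaffold"))
  .check_window(window, c(1L, s$n_es))
  es <- window[1]:window[2]
  prof_w <- attr(seqs, "window")
  rows <- list(PRE = s$pre_u[es], EDIT = s$can_u[es])
  labels <- c("PRE", "EDIT")
  extras <- character(0)
  if (!is.null(seqs) && nrow(seqs)) {
    swin <- seq.int(window[1], window[2])
    for (i in seq_len(nrow(seqs))) {
      uv <- as.integer(strsplit(seqs$u[i], ",", fixed = TRUE)[[1]])
      # seq_table u vectors span the profile window; subset to display range
      base_lo <- if (!is.null(prof_w)) prof_w[1] else 1L
      rows[[length(rows) + 1L]] <- uv[swin - base_lo + 1L]
      labels <- c(labels, sprintf("seq%02d", i))
      extras <- c(extras,
                  sprintf("  ind=%.1f unind=%.1f FC=%.1f", seqs$mean_induced[i],
                          seqs$mean_uninduced[i], seqs$fold_change[i]))
    }
  }
  widths <- do.call(pmax, rows)
  # 3' end rightmost: ES ascending right-to-left
  render_row <- function(u) {
    cells <- vapply(seq_along(u), function(j)
      paste0(substr(s$backbone, s$n_es + 1L - es[j], s$n_es + 1L - es[j]),
             strrep("u", u[j]), strrep("-", widths[j] - u[j])),
      character(1))
    paste(rev(cells), collapse = "")
  }
  body <- vapply(rows, render_row, character(1))
  pad <- formatC(labels, width = max(nchar(labels)) + 2L, flag = "-")
  lines <- paste0(pad, body)
  if (length(extras)) lines[-(1:2)] <- paste0(lines[-(1:2)], extras)
  c(sprintf("# ES%d (5') .. ES%d (3'), u = inserted U", window[2], window[1]), lines)
}
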