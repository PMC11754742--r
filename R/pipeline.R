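# End-to-end pipeline: references + sample sheet -> per-read calls,
# normalized profiles, EJES table, filtered window sequences, summary JSON.

#' Build a validated pipeline configuration
#'
#' @param reference Path to the reference multi-FASTA (paired
#'   `<name>_preedited` / `<name>_edited` records).
#' @param sample_sheet Path to a TSV with columns `sample_id`, `condition`,
#'   `replicate`, `path` (read files, relative to the sheet's directory).
#' @param fwd_primer,rev_primer Primer pair (sense strand); both `NULL` for
#'   primer-free whole-molecule reads.
#' @param out_dir Output directory.
#' @param transcript Transcript name in the reference FASTA (`NULL` to
#'   auto-detect).
#' @param induced,uninduced Condition labels in the sample sheet naming the
#'   perturbed and control condition.
#' @param fold_min,min_norm_reads,min_replicates EJES thresholds; see
#'   [detect_ejes()].
#' @param analysis_window Inclusive ES range `c(lo, hi)` for the windowed
#'   percent-of-reads statistic and sequence filter; `NULL` uses the whole
#'   amplicon window.
#' @param orientation Read orientation policy, `"as-is"` or `"auto"` (see
#'   [orient_reads()]).
#' @param min_read_length Reads shorter than this are excluded.
#' @param welch Use Welch's t-test for the window-percentage comparison.
#' @return A `run_config` list.
#' @export
run_config <- function(reference, sample_sheet, fwd_primer = NULL,
                       rev_primer = NULL, out_dir = "editpause_out",
                       transcript = NULL, induced = "induced",
                       uninduced = "uninduced", fold_min = 3,
                       min_norm_reads = 100, min_replicates = 2,
                       analysis_window = NULL,
                       orientation = c("as-is", "auto"),
                       min_read_length = 0L, welch = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(reference))
    stop_editpause(sprintf("reference not found: %s", reference), "config")
  if (!file.exists(sample_sheet))
    stop_editpause(sprintf("sample sheet not found: %s", sample_sheet), "config")
  if (xor(is.null(fwd_primer), is.null(rev_primer)))
    stop_editpause("give both primers or neither", "config")
  structure(list(reference = reference, sample_sheet = sample_sheet,
                 fwd_primer = fwd_primer, rev_primer = rev_primer,
                 out_dir = out_dir, transcript = transcript,
                 induced = induced, uninduced = uninduced,
                 fold_min = fold_min, min_norm_reads = min_norm_reads,
                 min_replicates = min_replicates,
                 analysis_window = analysis_window,
                 orientation = orientation,
                 min_read_length = as.integer(min_read_length),
                 welch = isTRUE(welch)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()]; entries in `overrides`
#' replace the file's values.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    stop_editpause(sprintf("config file not found: %s", path), "config")
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  if (!is.null(vals$analysis_window))
    vals$analysis_window <- as.integer(unlist(vals$analysis_window))
  do.call(run_config, vals)
}

.read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate", "path")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    stop_editpause(sprintf("sample sheet lacks columns: %s",
                           paste(miss, collapse = ", ")), "config")
  if (nrow(sheet) == 0L)
    stop_editpause("sample sheet is empty", "config")
  sheet$path <- ifelse(grepl("^/", sheet$path), sheet$path,
                       file.path(dirname(path), sheet$path))
  sheet
}

.log_line <- function(con, msg, warn = FALSE) {
  line <- sprintf("[%s] %s%s", format(Sys.time(), "%H:%M:%S"),
                  if (warn) "WARN " else "", msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full amplicon editing-analysis pipeline
#'
#' Reads the reference pair and sample sheet, reduces every read to its
#' per-ES U-count vector, classifies and junction-calls it, normalizes each
#' sample to 100,000 counts, detects EJES between the induced and uninduced
#' condition, filters window sequences, and writes per-read TSVs, per-sample
#' profile TSVs, the EJES table, the filtered-sequence table, a summary JSON
#' and a log to the output directory.
#'
#' @param cfg A `run_config` (or a YAML path accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the scaffold, window, per-sample profiles,
#'   `ejes` table, filtered `window_sequences`, and the `summary` list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  .log_line(log_con, sprintf("editpause %s",
                             as.character(utils::packageVersion("editpause"))))
  .log_line(log_con, sprintf("thresholds: fold_min=%g min_norm_reads=%g min_replicates=%d",
                             cfg$fold_min, cfg$min_norm_reads, cfg$min_replicates))

  ref <- read_reference_pair(cfg$reference, cfg$transcript)
  s <- build_scaffold(ref$pre, ref$edited, ref$name)
  w <- if (is.null(cfg$fwd_primer)) full_window(s)
       else restrict_to_amplicon(s, cfg$fwd_primer, cfg$rev_primer)
  .log_line(log_con, sprintf("scaffold '%s': %d ES; amplicon window ES%d-ES%d",
                             s$name, s$n_es, w$es_lo, w$es_hi))
  awin <- cfg$analysis_window %||% c(w$es_lo, w$es_hi)
  .check_window(awin, c(w$es_lo, w$es_hi))

  sheet <- .read_sample_sheet(cfg$sample_sheet)
  profiles <- list()
  for (i in seq_len(nrow(sheet))) {
    sm <- sheet[i, ]
    reads <- read_reads(sm$path)
    ori <- orient_reads(reads, w, cfg$orientation)
    force_ex <- ifelse(ori$ambiguous, "primer-missing", NA_character_)
    calls <- call_reads(s, w, ori$reads, ids = names(reads),
                        min_length = cfg$min_read_length,
                        force_exclude = force_ex)
    write_tsv_commented(as.data.frame(calls),
                        file.path(cfg$out_dir, paste0(sm$sample_id, "_reads.tsv")),
                        comments = sprintf("per-read calls for %s (ES%d-ES%d)",
                                           sm$sample_id, w$es_lo, w$es_hi))
    p <- normalize_sample(calls, sm$sample_id, sm$condition, sm$replicate)
    profiles[[sm$sample_id]] <- p
    excl_pct <- 100 * p$n_excluded / p$n_reads
    .log_line(log_con, sprintf("%s: %d reads, %d excluded (%.1f%%) [%s]",
                               sm$sample_id, p$n_reads, p$n_excluded, excl_pct,
                               paste(sprintf("%s=%d", names(p$exclusion_reasons),
                                             p$exclusion_reasons), collapse = " ")))
    for (rs in names(p$exclusion_reasons))
      if (p$exclusion_reasons[[rs]] > 0.1 * p$n_reads)
        .log_line(log_con, sprintf("%s: exclusion class '%s' exceeds 10%% of reads",
                                   sm$sample_id, rs), warn = TRUE)
    prof_df <- data.frame(es = as.integer(names(p$jes_hist)),
                          normalized_jes_count = unname(p$jes_hist))
    write_tsv_commented(prof_df,
                        file.path(cfg$out_dir, paste0(sm$sample_id, "_profile.tsv")),
                        comments = sprintf("normalized JES profile for %s (total reads scaled to 100000)",
                                           sm$sample_id))
  }

  ind <- profiles[sheet$sample_id[sheet$condition == cfg$induced]]
  uni <- profiles[sheet$sample_id[sheet$condition == cfg$uninduced]]
  if (!length(ind) || !length(uni))
    stop_editpause(sprintf("sample sheet has no '%s' or no '%s' samples",
                           cfg$induced, cfg$uninduced), "config")

  ejes <- detect_ejes(ind, uni, cfg$fold_min, cfg$min_norm_reads,
                      cfg$min_replicates)
  write_tsv_commented(as.data.frame(ejes), file.path(cfg$out_dir, "ejes.tsv"),
                      comments = sprintf("EJES table: induced='%s' vs uninduced='%s'",
                                         cfg$induced, cfg$uninduced))
  .log_line(log_con, sprintf("EJES passing thresholds: %d", sum(ejes$pass)))

  seqs <- filter_window_sequences(ind, uni, awin, cfg$fold_min,
                                  cfg$min_norm_reads)
  write_tsv_commented(seqs, file.path(cfg$out_dir, "window_sequences.tsv"),
                      comments = sprintf("distinct sequences with JES in ES%d-ES%d passing filters",
                                         awin[1], awin[2]))
  writeLines(render_window_sequences(s, seqs, awin),
             file.path(cfg$out_dir, "window_sequences.txt"))

  pct_ind <- vapply(ind, percent_jes_in_window, numeric(1), window = awin)
  pct_uni <- vapply(uni, percent_jes_in_window, numeric(1), window = awin)
  ttest <- if (length(ind) >= 2L && length(uni) >= 2L)
    compare_conditions(pct_ind, pct_uni, cfg$welch) else NULL

  summary <- list(
    transcript = s$name,
    amplicon_window = c(w$es_lo, w$es_hi),
    analysis_window = awin,
    samples = lapply(profiles, function(p) list(
      sample_id = p$sample_id, condition = p$condition,
      replicate = p$replicate, n_reads = p$n_reads,
      n_excluded = p$n_excluded,
      class_fraction = as.list(p$class_norm / NORM_TOTAL),
      pct_jes_in_window = percent_jes_in_window(p, awin))),
    pct_jes_in_window = list(induced = as.list(pct_ind),
                             uninduced = as.list(pct_uni)),
    window_percent_test = ttest,
    n_ejes_pass = sum(ejes$pass),
    ejes_pass = ejes$es[ejes$pass])
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(log_con, sprintf("done; outputs in %s", cfg$out_dir))

  invisible(list(scaffold = s, window = w, profiles = profiles, ejes = ejes,
                 window_sequences = seqs, summary = summary))
}
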