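# Synthetic amplicon read generator.
#
# Emulates the read populations the analysis assumes: a mixture of
# pre-edited, fully edited and partially edited molecules, the latter with a
# 3' block of canonical editing, an optional junction of non-canonical U
# counts at the leading edge, and pre-edited sequence 5' of the junction.
# Editing halts (the junction end site, JES) at an ES drawn from a
# pause-weighted distribution, so condition-dependent pause sites can be
# planted.  Substitution errors hitting backbone or primer bases force read
# exclusion downstream; errors landing inside U-runs instead perturb the
# observed U count by +/-1 — the realistic failure mode that creates
# spurious non-canonical calls.

#' Configuration for the synthetic read generator
#'
#' @param n_reads Reads per sample.
#' @param frac_pre,frac_full Fraction of pre-edited and fully edited reads;
#'   the remainder is partially edited.  Defaults (0.2 / 0.1) reflect
#'   steady-state pan-edited mRNA populations, which are dominated by
#'   partially edited intermediates.
#' @param pause_weights Named numeric vector: per-ES multiplier on the
#'   probability that editing halts with its JES at that ES (names are ES
#'   indices).  Unlisted sites have weight 1.
#' @param junction_len_mean Mean junction length in ES (geometric
#'   distribution, default 2; length 0 = empty junction, canonical editing
#'   directly abutting pre-edited sequence).
#' @param noncanonical_extra Junction U counts are drawn uniformly from
#'   `0..max(pre_u, can_u) + noncanonical_extra`, excluding the canonical
#'   value (default 2).
#' @param error_rate Per-base substitution probability (default 0.001,
#'   typical for Illumina amplicon data).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads = 20000L, frac_pre = 0.2, frac_full = 0.1,
                       pause_weights = NULL, junction_len_mean = 2,
                       noncanonical_extra = 2L, error_rate = 0.001) {
  if (frac_pre < 0 || frac_full < 0 || frac_pre + frac_full > 1)
    stop_editpause("class fractions must be in [0,1] and sum to at most 1",
                   "config")
  if (!is.null(pause_weights)) {
    if (is.null(names(pause_weights)) || any(is.na(as.integer(names(pause_weights)))))
      stop_editpause("pause_weights must be named by ES index", "config")
    if (any(pause_weights <= 0))
      stop_editpause("pause_weights must be positive", "config")
  }
  if (junction_len_mean <= 0 || error_rate < 0 || error_rate >= 1)
    stop_editpause("junction_len_mean must be > 0 and error_rate in [0,1)",
                   "config")
  structure(list(n_reads = as.integer(n_reads), frac_pre = frac_pre,
                 frac_full = frac_full, pause_weights = pause_weights,
                 junction_len_mean = junction_len_mean,
                 noncanonical_extra = as.integer(noncanonical_extra),
                 error_rate = error_rate),
            class = "sim_config")
}

# Draw clean (error-free) per-read U matrices for one sample.
.sim_u_matrix <- function(s, w, cfg, n) {
  es <- w$es_lo:w$es_hi
  k <- length(es)
  pre_w <- .window_pre(s, w)
  can_w <- .window_can(s, w)

  cls <- sample(c("pre", "full", "partial"), n, replace = TRUE,
                prob = c(cfg$frac_pre, cfg$frac_full,
                         1 - cfg$frac_pre - cfg$frac_full))
  u <- matrix(rep(pre_w, each = n), n, k)
  u[cls == "full", ] <- matrix(rep(can_w, each = sum(cls == "full")),
                               sum(cls == "full"), k)

  part <- which(cls == "partial")
  jes_target <- rep(NA_integer_, n)
  if (length(part)) {
    wts <- rep(1, k)
    if (!is.null(cfg$pause_weights)) {
      idx <- match(as.integer(names(cfg$pause_weights)), es)
      wts[idx[!is.na(idx)]] <- cfg$pause_weights[!is.na(idx)]
    }
    jes <- sample(es, length(part), replace = TRUE, prob = wts)
    jes_target[part] <- jes
    len <- stats::rgeom(length(part), prob = 1 / (1 + cfg$junction_len_mean))
    # an empty junction needs an editing action at its JES: if the site is
    # never edited (pre == can) grow the junction so the JES carries a
    # non-canonical, non-pre-edited U count
    jcol <- jes - w$es_lo + 1L
    len[len == 0L & pre_w[jcol] == can_w[jcol]] <- 1L
    jss <- ifelse(len == 0L, jes + 1L, pmax(w$es_lo, jes - len + 1L))

    for (j in seq_len(k)) {
      e <- es[j]
      canonical <- part[e < jss]
      u[canonical, j] <- can_w[j]
      in_junc <- e >= jss & e <= jes
      hi <- max(pre_w[j], can_w[j]) + cfg$noncanonical_extra
      at_jes <- part[in_junc & e == jes & len > 0L]
      mid <- part[in_junc & !(e == jes & len > 0L)]
      if (length(mid)) {
        allowed <- setdiff(0:hi, can_w[j])
        u[mid, j] <- allowed[sample.int(length(allowed), length(mid), replace = TRUE)]
      }
      if (length(at_jes)) {
        allowed <- setdiff(0:hi, c(can_w[j], pre_w[j]))
        u[at_jes, j] <- allowed[sample.int(length(allowed), length(at_jes),
                                           replace = TRUE)]
      }
      # e > jes rows keep their pre-edited initialisation
    }
  }
  list(u = u, jes_target = jes_target)
}

# Render U-count matrix rows into amplicon strings for a window.
.render_reads <- function(s, w, u) {
  n <- nrow(u)
  k <- ncol(u)
  res <- strsplit(s$backbone, "")[[1]]
  if (w$has_primers) {
    # insert = run(gap f2) res(f2+1) run ... res(r1-1) run(gap r1-1)
    comps <- vector("list", 2L * (w$bb_to - w$bb_from - 1L) + 1L)
    ci <- 1L
    for (g in w$bb_from:(w$bb_to - 1L)) {
      comps[[ci]] <- strrep("T", u[, s$n_es + 1L - g - w$es_lo + 1L])
      ci <- ci + 1L
      if (g < w$bb_to - 1L) {
        comps[[ci]] <- rep(res[g + 1L], n)
        ci <- ci + 1L
      }
    }
    paste0(w$fwd, do.call(paste0, comps), w$rev)
  } else {
    comps <- vector("list", 2L * s$n_es + 1L)
    comps[[1L]] <- rep(res[1L], n)
    for (g in seq_len(s$n_es)) {
      comps[[2L * g]] <- strrep("T", u[, s$n_es + 1L - g])
      comps[[2L * g + 1L]] <- rep(res[g + 1L], n)
    }
    do.call(paste0, comps)
  }
}

.OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate one sample of amplicon reads with per-read ground truth
#'
#' Draws each read's class and, for partially edited reads, a junction end
#' site from the pause-weighted distribution and a geometric junction
#' length; renders the sequence through [reconstruct_sequence()]'s
#' interleaving with primers attached; then applies substitution errors.
#' An error on a backbone or primer base substitutes a random different
#' base (forcing exclusion downstream); an error on a U-run base
#' lengthens or shortens that run by one.
#'
#' @param s An `editing_scaffold`.
#' @param w An `amplicon_window` (with or without primers).
#' @param cfg A [sim_config()].
#' @param n Number of reads (defaults to `cfg$n_reads`).
#' @param id_prefix Prefix for read identifiers.
#' @return List with `reads` (character), `ids`, and `truth`: a data frame
#'   with the error-free class/jss/jes/U vector of every read, the drawn
#'   pause site `jes_target` (the categorical sampler's draw; equals `jes`
#'   except for the rare draws whose realisation is fully canonical over
#'   the window), plus `backbone_error` (an error hit a backbone/primer
#'   base) and `u_run_error` (an error perturbed a U count).
#' @export
simulate_reads <- function(s, w, cfg, n = cfg$n_reads, id_prefix = "read") {
  stopifnot(inherits(s, "editing_scaffold"), inherits(w, "amplicon_window"),
            inherits(cfg, "sim_config"))
  k <- .window_k(w)
  ids <- sprintf("%s%06d", id_prefix, seq_len(n))
  if (n == 0L)
    return(list(reads = character(0), ids = character(0),
                truth = data.frame(read_id = character(0), class = character(0),
                                   jss = integer(0), jes = integer(0),
                                   jes_target = integer(0),
                                   u = character(0), backbone_error = logical(0),
                                   u_run_error = logical(0))))
  sim <- .sim_u_matrix(s, w, cfg, n)
  u <- sim$u
  j <- .junction_u(u, .window_pre(s, w), .window_can(s, w), w$es_lo:w$es_hi)

  # U-run errors: each existing T is hit independently; a hit deletes or
  # duplicates that T with equal probability.  Drawn as a per-read binomial
  # total thinned onto T positions, which is distributionally identical to
  # per-T Bernoulli trials.
  u_err <- u
  u_changed <- logical(n)
  if (cfg$error_rate > 0) {
    tot <- rowSums(u)
    n_hits <- stats::rbinom(n, tot, cfg$error_rate)
    for (i in which(n_hits > 0L)) {
      sites <- rep.int(seq_len(k), u[i, ])
      hit <- sites[sample.int(tot[i], n_hits[i])]
      dup <- stats::rbinom(n_hits[i], 1L, 0.5) == 1L
      u_err[i, ] <- u[i, ] + tabulate(hit[dup], k) - tabulate(hit[!dup], k)
      u_changed[i] <- any(u_err[i, ] != u[i, ])
    }
  }
  reads <- .render_reads(s, w, u_err)

  # backbone/primer errors: reads with >= 1 hit on a non-T (or primer) base
  # get one uniformly-placed substitution, which is what decides exclusion
  nb <- nchar(w$fwd) + nchar(w$rev) + (w$bb_to - w$bb_from - 1L) +
    (!w$has_primers) * 2L   # primer-free reads expose all n_es + 1 residues
  bb_hit <- if (cfg$error_rate > 0) stats::rbinom(n, nb, cfg$error_rate) > 0L
            else rep(FALSE, n)
  for (i in which(bb_hit)) {
    rd <- reads[i]
    len <- nchar(rd)
    lf <- nchar(w$fwd)
    lr <- nchar(w$rev)
    core <- substr(rd, lf + 1L, len - lr)
    nonT <- gregexpr("[^T]", core)[[1]] + lf
    cand <- c(seq_len(lf), nonT, if (lr) (len - lr + 1L):len)
    pos <- cand[sample.int(length(cand), 1L)]
    old <- substr(rd, pos, pos)
    substr(reads[i], pos, pos) <- sample(.OTHER_BASES[[old]], 1L)
  }

  truth <- data.frame(read_id = ids, class = j$class, jss = j$jss, jes = j$jes,
                      jes_target = sim$jes_target,
                      u = do.call(paste, c(asplit(u, 2L), sep = ",")),
                      backbone_error = bb_hit,
                      u_run_error = u_changed,
                      stringsAsFactors = FALSE)
  list(reads = reads, ids = ids, truth = truth)
}

#' Simulate a single read
#'
#' Convenience wrapper around [simulate_reads()] with `n = 1`.
#'
#' @inheritParams simulate_reads
#' @return List with `read` (string) and `truth` (one-row data frame).
#' @export
simulate_read <- function(s, w, cfg) {
  sim <- simulate_reads(s, w, cfg, n = 1L)
  list(read = sim$reads[1], truth = sim$truth[1, , drop = FALSE])
}

#' Generate a random reference pair with primer landing sites
#'
#' Builds a synthetic transcript for pipeline exercises: non-T primer
#' regions flank an editable core whose per-ES pre-edited and canonical U
#' counts are drawn to resemble a pan-edited substrate (sparse pre-edited
#' U's, canonical insertions of up to several U's, occasional deletions).
#'
#' @param n_core_es Number of editing sites between the primer footprints
#'   (the amplicon window of the returned reference).
#' @param primer_len Length of each non-T primer region.
#' @param name Transcript name.
#' @return List with `pre`, `edited`, `fwd`, `rev`, `name`; feed `pre` and
#'   `edited` to [build_scaffold()] and the primers to
#'   [restrict_to_amplicon()].
#' @export
simulate_reference <- function(n_core_es = 50L, primer_len = 15L,
                               name = "synthA6") {
  bases <- c("A", "C", "G")
  rand_bb <- function(len) paste(sample(bases, len, replace = TRUE), collapse = "")
  repeat {
    fwd <- rand_bb(primer_len)
    rev <- rand_bb(primer_len)
    core_bb <- rand_bb(n_core_es - 1L)
    backbone <- paste0(fwd, core_bb, rev)
    n_es <- nchar(backbone) - 1L
    pre_u <- integer(n_es)
    can_u <- integer(n_es)
    # gaps within the core (between primer footprints), ES order
    core_gaps <- (n_es + 1L - (nchar(backbone) - primer_len)):(n_es + 1L - primer_len)
    pre_u[core_gaps] <- sample(0:2, length(core_gaps), replace = TRUE,
                               prob = c(0.6, 0.3, 0.1))
    can_u[core_gaps] <- sample(0:6, length(core_gaps), replace = TRUE,
                               prob = c(0.15, 0.25, 0.2, 0.15, 0.1, 0.1, 0.05))
    s <- build_scaffold(reconstruct_sequence_raw(backbone, pre_u),
                        reconstruct_sequence_raw(backbone, can_u), name)
    # primers must sit uniquely on the pre-edited reference
    ok <- tryCatch({
      restrict_to_amplicon(s, fwd, rev)
      TRUE
    }, editpause_error = function(e) FALSE)
    if (ok)
      return(list(pre = s$pre_seq, edited = s$edited_seq, fwd = fwd, rev = rev,
                  name = name))
  }
}

# interleave helper usable before a scaffold exists
reconstruct_sequence_raw <- function(backbone, u) {
  res <- strsplit(backbone, "")[[1]]
  n <- length(res)
  paste0(paste0(res[-n], strrep("T", rev(u)), collapse = ""), res[n])
}

#' Simulate a two-condition replicated amplicon experiment to disk
#'
#' Writes one FASTQ per replicate (constant Q30 qualities; the pipeline
#' ignores quality by default), a ground-truth TSV joined on `read_id`, and
#' a sample sheet.  Per-replicate seeds are derived deterministically from
#' the master seed, so a fixed seed reproduces the files byte for byte.
#'
#' @param s,w Scaffold and amplicon window (the window must carry primers).
#' @param cfg_induced,cfg_uninduced [sim_config()]s for the two conditions.
#' @param replicates Replicates per condition (default 2).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param conditions Condition labels, `c(induced, uninduced)`.
#' @return List with `sample_sheet`, `truth`, and per-sample FASTQ paths.
#' @export
simulate_experiment <- function(s, w, cfg_induced, cfg_uninduced,
                                replicates = 2L, out_dir, seed = 1L,
                                conditions = c("induced", "uninduced")) {
  if (replicates < 1L)
    stop_editpause("need at least one replicate per condition", "config")
  if (!w$has_primers)
    stop_editpause("simulate_experiment needs a primer-delimited window", "config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * replicates)
  cfgs <- list(cfg_induced, cfg_uninduced)
  sheet <- NULL
  truths <- list()
  files <- character(0)
  si <- 1L
  for (ci in 1:2) {
    for (r in seq_len(replicates)) {
      sample_id <- sprintf("%s_rep%d", conditions[ci], r)
      set.seed(seeds[si]); si <- si + 1L
      sim <- simulate_reads(s, w, cfgs[[ci]], id_prefix = paste0(sample_id, "_r"))
      fp <- file.path(out_dir, paste0(sample_id, ".fastq"))
      dna <- Biostrings::DNAStringSet(sim$reads)
      names(dna) <- sim$ids
      qual <- Biostrings::BStringSet(strrep("?", nchar(sim$reads)))
      Biostrings::writeXStringSet(dna, fp, format = "fastq", qualities = qual)
      tr <- sim$truth
      tr$sample_id <- if (nrow(tr)) sample_id else character(0)
      truths[[sample_id]] <- tr
      sheet <- rbind(sheet, data.frame(sample_id = sample_id,
                                       condition = conditions[ci],
                                       replicate = r,
                                       path = basename(fp),
                                       stringsAsFactors = FALSE))
      files <- c(files, fp)
    }
  }
  sheet_fp <- file.path(out_dir, "samples.tsv")
  truth_fp <- file.path(out_dir, "truth.tsv")
  write_tsv_commented(sheet, sheet_fp,
                      comments = sprintf("simulated sample sheet (seed %d)", seed))
  write_tsv_commented(do.call(rbind, truths), truth_fp,
                      comments = sprintf("per-read ground truth (seed %d)", seed))
  list(sample_sheet = sheet_fp, truth = truth_fp, files = files)
}
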