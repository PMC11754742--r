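# Shared fixtures and independent (scalar, definition-scan) oracles used to
# cross-check the vectorised implementation.

# 4-ES toy: pre "GATTCGTA", edited "GTATTCTTTGA"
#   backbone GACGA, pre_u = (1,0,2,0), can_u = (0,3,2,1)
toy_scaffold <- function() build_scaffold("GATTCGTA", "GTATTCTTTGA", "toy")

# toy embedded in unique primer flanks (backbone CCGGACGAAGG)
toy_amplicon <- function() {
  s <- build_scaffold("CCGGATTCGTAAGG", "CCGGTATTCTTTGAAGG", "toyamp")
  list(s = s, w = restrict_to_amplicon(s, "CCG", "AGG"))
}

# Brute-force classification: direct comparison against both references.
oracle_classify <- function(u, pre, can) {
  if (all(u == can)) return("FULLY_EDITED")
  if (all(u == pre)) return("PRE_EDITED")
  "PARTIALLY_EDITED"
}

# Brute-force junction call: explicit scan moving 3' to 5' (ES ascending)
# for the first canonical failure, and 5' to 3' for the last editing action.
oracle_junction <- function(u, pre, can, es) {
  if (oracle_classify(u, pre, can) != "PARTIALLY_EDITED")
    return(list(jss = NA_integer_, jes = NA_integer_))
  jss <- NA_integer_
  for (i in seq_along(es)) {
    if (u[i] != can[i]) { jss <- es[i]; break }
  }
  jes <- NA_integer_
  for (i in rev(seq_along(es))) {
    if (u[i] != pre[i]) { jes <- es[i]; break }
  }
  list(jss = jss, jes = jes)
}

# Random scaffold for property tests: random A/C/G backbone and U counts.
random_scaffold <- function(n_res = 8L, max_u = 4L, name = "rand") {
  backbone <- paste(sample(c("A", "C", "G"), n_res, replace = TRUE),
                    collapse = "")
  n_es <- n_res - 1L
  pre_u <- sample(0:max_u, n_es, replace = TRUE)
  can_u <- sample(0:max_u, n_es, replace = TRUE)
  res <- strsplit(backbone, "")[[1]]
  interleave <- function(u)
    paste0(paste0(res[-n_res], strrep("T", rev(u)), collapse = ""), res[n_res])
  build_scaffold(interleave(pre_u), interleave(can_u), name)
}

# Hand-built read_calls data frame for profile tests (bypasses alignment).
fake_calls <- function(classes, jes, window, jss = jes) {
  df <- data.frame(read_id = paste0("r", seq_along(classes)), class = classes,
                   jss = as.integer(jss), jes = as.integer(jes),
                   u = ifelse(classes == "EXCLUDED", NA_character_, "0"),
                   exclusion_reason = ifelse(classes == "EXCLUDED",
                                             "backbone-mismatch", NA_character_),
                   stringsAsFactors = FALSE)
  attr(df, "window") <- as.integer(window)
  class(df) <- c("read_calls", "data.frame")
  df
}

# Profile with a prescribed JES histogram (already normalized counts).
fake_profile <- function(jes_hist, window, sample_id = "s", condition = NA,
                         replicate = NA, seq_table = NULL) {
  es <- window[1]:window[2]
  h <- numeric(length(es))
  names(h) <- es
  h[names(jes_hist)] <- jes_hist
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = replicate, window = as.integer(window),
                 n_reads = NA_integer_, n_excluded = 0L,
                 exclusion_reasons = table(character(0)),
                 class_norm = c(PRE_EDITED = 0, PARTIALLY_EDITED = sum(h),
                                FULLY_EDITED = 0),
                 jes_hist = h,
                 seq_table = seq_table %||%
                   data.frame(u = character(0), class = character(0),
                              jss = integer(0), jes = integer(0),
                              count_norm = numeric(0))),
            class = "sample_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
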