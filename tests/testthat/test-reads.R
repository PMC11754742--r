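test_that("align_read reduces primer-free reads to U-count vectors", {
  s <- toy_scaffold()
  w <- full_window(s)
  a <- align_read(s, w, "GACTTTGA")
  expect_false(a$excluded)
  expect_equal(unname(a$u_obs), c(0L, 3L, 0L, 0L))

  a2 <- align_read(s, w, "GATTCGTA")   # the pre-edited reference itself
  expect_equal(unname(a2$u_obs), s$pre_u)

  a3 <- align_read(s, w, "GACCGA")     # non-T SNP: backbone GACGA vs GACCGA
  expect_true(a3$excluded)
  expect_equal(a3$reason, "backbone-mismatch")

  a4 <- align_read(s, w, "GACTTTGA", min_length = 20L)
  expect_equal(a4$reason, "too-short")
})

test_that("align_read handles primer-delimited reads and exclusion coding", {
  toy <- toy_amplicon()
  s <- toy$s; w <- toy$w
  rd <- paste0("CCG", "GACTTTGA", "AGG")
  a <- align_read(s, w, rd)
  expect_equal(unname(a$u_obs), c(0L, 0L, 3L, 0L, 0L, 0L))
  expect_equal(names(a$u_obs), paste0("ES", 3:8))

  # missing 5' primer: excluded, not truncated
  a2 <- align_read(s, w, paste0("GACTTTGA", "AGG"))
  expect_equal(a2$reason, "primer-missing")
  a3 <- align_read(s, w, paste0("CCG", "GACTTTGA"))
  expect_equal(a3$reason, "primer-missing")
  # substitution inside the insert backbone
  a4 <- align_read(s, w, paste0("CCG", "GAGTTTGA", "AGG"))
  expect_equal(a4$reason, "backbone-mismatch")
})

test_that("classification matches both-reference comparison and errors on excluded reads", {
  s <- toy_scaffold()
  w <- full_window(s)
  mk <- function(u) align_read(s, w, reconstruct_sequence(s, u))
  expect_equal(classify_read(mk(c(0, 3, 2, 1)), s, w), "FULLY_EDITED")
  expect_equal(classify_read(mk(c(1, 0, 2, 0)), s, w), "PRE_EDITED")
  expect_equal(classify_read(mk(c(0, 3, 0, 0)), s, w), "PARTIALLY_EDITED")

  ex <- align_read(s, w, "GACCGA")
  expect_error(classify_read(ex, s, w), class = "editpause_excluded_read")
  expect_error(call_junction(ex, s, w), class = "editpause_excluded_read")
})

test_that("junction boundaries follow the 3'-to-5' definitions", {
  s <- toy_scaffold()
  w <- full_window(s)
  mk <- function(u) align_read(s, w, reconstruct_sequence(s, u))

  # non-canonical U count at ES3
  j <- call_junction(mk(c(0, 3, 5, 0)), s, w)
  expect_equal(j$jss, 3L)
  expect_equal(j$jes, 3L)

  # U deletion at ES3 (0 observed vs 2 pre-edited) is an editing action
  j2 <- call_junction(mk(c(0, 3, 0, 0)), s, w)
  expect_equal(j2$jss, 3L)
  expect_equal(j2$jes, 3L)

  # empty junction: canonical through ES1, pre-edited 5' of it
  j3 <- call_junction(mk(c(0, 0, 2, 0)), s, w)
  expect_equal(j3$jss, 2L)
  expect_equal(j3$jes, 1L)

  # pre-edited and fully edited reads carry no junction
  expect_equal(call_junction(mk(c(1, 0, 2, 0)), s, w),
               list(jss = NA_integer_, jes = NA_integer_))
  expect_equal(call_junction(mk(c(0, 3, 2, 1)), s, w),
               list(jss = NA_integer_, jes = NA_integer_))
})

test_that("exhaustive oracle equivalence over all 625 u vectors on the 4-ES toy", {
  s <- toy_scaffold()
  w <- full_window(s)
  grid <- as.matrix(expand.grid(0:4, 0:4, 0:4, 0:4))
  reads <- apply(grid, 1L, function(u) reconstruct_sequence(s, u))
  calls <- call_reads(s, w, reads)
  expect_false(any(calls$class == "EXCLUDED"))
  for (i in seq_len(nrow(grid))) {
    u <- grid[i, ]
    expect_identical(calls$class[i], oracle_classify(u, s$pre_u, s$can_u))
    oj <- oracle_junction(u, s$pre_u, s$can_u, 1:4)
    expect_identical(calls$jss[i], oj$jss)
    expect_identical(calls$jes[i], oj$jes)
    expect_identical(calls$u[i], paste(u, collapse = ","))
  }
})

test_that("junction consistency: jss/jes defined exactly for partially edited reads", {
  s <- toy_scaffold()
  w <- full_window(s)
  grid <- as.matrix(expand.grid(0:4, 0:4, 0:4, 0:4))
  reads <- apply(grid, 1L, function(u) reconstruct_sequence(s, u))
  calls <- call_reads(s, w, reads)
  partial <- calls$class == "PARTIALLY_EDITED"
  expect_true(all(!is.na(calls$jss[partial]) & !is.na(calls$jes[partial])))
  expect_true(all(is.na(calls$jss[!partial]) & is.na(calls$jes[!partial])))
  # empty junctions are legal and encoded as jes = jss - 1
  expect_true(any(calls$jes[partial] == calls$jss[partial] - 1L))
})

test_that("class partition is exhaustive over any read set", {
  toy <- toy_amplicon()
  set.seed(7)
  reads <- c(paste0("CCG", "GACTTTGA", "AGG"),    # partial
             "CCGGATTCGTAAGG",                    # pre-edited with primers
             "CCGGTATTCTTTGAAGG",                 # fully edited
             "CCGGACCGAAGG",                      # backbone SNP -> excluded
             "GGGGGG")                            # no primers -> excluded
  calls <- call_reads(toy$s, toy$w, reads)
  expect_equal(nrow(calls), length(reads))
  expect_equal(sum(table(calls$class)), length(reads))
  expect_setequal(unique(calls$class),
                  c("PARTIALLY_EDITED", "PRE_EDITED", "FULLY_EDITED", "EXCLUDED"))
})

test_that("round trip: reconstructed reads re-align to their u vector exactly", {
  set.seed(103)
  for (rep in 1:25) {
    s <- random_scaffold(n_res = sample(4:15, 1), max_u = 6L)
    w <- full_window(s)
    for (j in 1:16) {
      u <- sample(0:6, s$n_es, replace = TRUE)
      a <- align_read(s, w, reconstruct_sequence(s, u))
      expect_false(a$excluded)
      expect_equal(unname(a$u_obs), as.integer(u))
    }
  }
})

test_that("orient_reads auto mode recovers reverse-complemented reads", {
  toy <- toy_amplicon()
  s <- toy$s; w <- toy$w
  rd <- paste0("CCG", "GACTTTGA", "AGG")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(rd)))
  ori <- orient_reads(c(rd, rc, "GGGG"), w, policy = "auto")
  expect_equal(ori$flipped, c(FALSE, TRUE, FALSE))
  expect_false(any(ori$ambiguous))
  a <- align_read(s, w, ori$reads[2])
  expect_equal(unname(a$u_obs), c(0L, 0L, 3L, 0L, 0L, 0L))
  # neither orientation matches -> excluded downstream as primer-missing
  calls <- call_reads(s, w, ori$reads,
                      force_exclude = ifelse(ori$ambiguous, "primer-missing", NA))
  expect_equal(calls$exclusion_reason[3], "primer-missing")
})
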