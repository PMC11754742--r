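test_that("normalization scales non-excluded reads to 100,000", {
  # 2 reads, one with JES=ES2, one pre-edited
  calls <- fake_calls(c("PARTIALLY_EDITED", "PRE_EDITED"), jes = c(2L, NA),
                      window = c(1, 4))
  p <- normalize_sample(calls)
  expect_equal(unname(p$jes_hist["2"]), 50000)
  expect_equal(sum(p$class_norm), 1e5)

  # 4 reads all fully edited
  p2 <- normalize_sample(fake_calls(rep("FULLY_EDITED", 4), jes = rep(NA, 4),
                                    window = c(1, 4)))
  expect_equal(unname(p2$class_norm["FULLY_EDITED"]), 1e5)
  expect_true(all(p2$jes_hist == 0))

  # 3 reads with JES ES2, 1 with JES ES3
  p3 <- normalize_sample(fake_calls(rep("PARTIALLY_EDITED", 4),
                                    jes = c(2L, 2L, 2L, 3L), window = c(1, 4)))
  expect_equal(unname(p3$jes_hist[c("2", "3")]), c(75000, 25000))

  # excluded reads are reported but carry no weight
  p4 <- normalize_sample(fake_calls(c("PARTIALLY_EDITED", "EXCLUDED"),
                                    jes = c(2L, NA), window = c(1, 4)))
  expect_equal(unname(p4$jes_hist["2"]), 1e5)
  expect_equal(p4$n_excluded, 1L)

  expect_error(normalize_sample(fake_calls("EXCLUDED", NA, c(1, 4))),
               class = "editpause_empty_sample")
})

test_that("normalization conservation holds exactly pre-rounding", {
  toy <- toy_amplicon()
  set.seed(11)
  cfg <- sim_config(n_reads = 700L, frac_pre = 0.3, frac_full = 0.2,
                    error_rate = 0.01)
  sim <- simulate_reads(toy$s, toy$w, cfg)
  calls <- call_reads(toy$s, toy$w, sim$reads)
  p <- normalize_sample(calls)
  expect_equal(sum(p$class_norm), 1e5)
  expect_equal(sum(p$seq_table$count_norm), 1e5)
  expect_lte(sum(p$jes_hist), 1e5 + 1e-9)
  # jes histogram counts exactly the partially edited reads
  expect_equal(sum(p$jes_hist), unname(p$class_norm["PARTIALLY_EDITED"]))
})

test_that("detect_ejes applies fold and replicate-floor criteria", {
  win <- c(100, 130)
  ind <- list(fake_profile(c("121" = 400), win), fake_profile(c("121" = 440), win))
  uni <- list(fake_profile(c("121" = 10), win), fake_profile(c("121" = 12), win))
  tab <- detect_ejes(ind, uni)
  row <- tab[tab$es == 121, ]
  expect_equal(row$fold_change, 420 / 11, tolerance = 1e-12)
  expect_true(row$pass)
  expect_equal(sum(tab$pass), 1L)

  # only one induced replicate clears the 100-read floor -> fail
  ind2 <- list(fake_profile(c("50" = 120), win), fake_profile(c("50" = 90), win))
  uni2 <- list(fake_profile(c("50" = 1), win), fake_profile(c("50" = 1), win))
  tab2 <- detect_ejes(ind2, uni2)
  expect_false(tab2$pass[tab2$es == 50])
  expect_equal(tab2$n_induced_ge_min[tab2$es == 50], 1L)

  # identical conditions -> fold 1 everywhere, zero passes
  tab3 <- detect_ejes(ind, ind)
  expect_equal(sum(tab3$pass), 0L)

  expect_error(detect_ejes(ind[1], uni), class = "editpause_replicate_mismatch")
})

test_that("zero-denominator fold changes use the pseudocount policy", {
  win <- c(1, 10)
  ind <- list(fake_profile(c("5" = 299), win), fake_profile(c("5" = 301), win))
  uni <- list(fake_profile(numeric(0), win), fake_profile(numeric(0), win))
  tab <- detect_ejes(ind, uni)
  expect_equal(tab$fold_change[tab$es == 5], 301)  # (300+1)/(0+1)
  expect_true(tab$pass[tab$es == 5])
})

test_that("EJES detection is monotone in fold_min and min_norm_reads", {
  win <- c(1, 30)
  set.seed(12)
  mk <- function() {
    h <- round(runif(15, 0, 500))
    names(h) <- sample(win[1]:win[2], 15)
    fake_profile(h, win)
  }
  ind <- list(mk(), mk()); uni <- list(mk(), mk())
  folds <- c(1.5, 3, 6); floors <- c(50, 100, 400)
  n_pass <- sapply(folds, function(f)
    sapply(floors, function(m) sum(detect_ejes(ind, uni, f, m)$pass)))
  expect_true(all(apply(n_pass, 1, diff) <= 0))  # raising fold_min
  expect_true(all(apply(n_pass, 2, diff) <= 0))  # raising the floor
})

test_that("label-swap null: identical samples under random labels give zero EJES", {
  win <- c(1, 40)
  set.seed(13)
  for (iter in 1:25) {
    h <- round(runif(20, 0, 800))
    names(h) <- sample(win[1]:win[2], 20)
    pool <- replicate(4, fake_profile(h, win), simplify = FALSE)
    idx <- sample(4, 2)
    tab <- detect_ejes(pool[idx], pool[-idx], fold_min = 1 + 1e-9)
    expect_equal(sum(tab$pass), 0L)
  }
})

test_that("filter_window_sequences applies JES-window, floor and fold filters", {
  win <- c(1, 10)
  st <- function(u, jes, count) data.frame(u = u, class = "PARTIALLY_EDITED",
                                           jss = jes, jes = jes,
                                           count_norm = count,
                                           stringsAsFactors = FALSE)
  ind <- list(fake_profile(numeric(0), win, seq_table = st("0,0,9,0", 5L, 280)),
              fake_profile(numeric(0), win, seq_table = st("0,0,9,0", 5L, 320)))
  uni <- list(fake_profile(numeric(0), win, seq_table = st("0,0,9,0", 5L, 40)),
              fake_profile(numeric(0), win, seq_table = st("0,0,9,0", 5L, 60)))
  out <- filter_window_sequences(ind, uni, window = c(4, 6))
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_induced, 300)
  expect_equal(out$fold_change, 6)

  # fold below threshold -> dropped
  uni2 <- list(fake_profile(numeric(0), win, seq_table = st("0,0,9,0", 5L, 140)),
               fake_profile(numeric(0), win, seq_table = st("0,0,9,0", 5L, 160)))
  expect_equal(nrow(filter_window_sequences(ind, uni2, window = c(4, 6))), 0L)

  # JES outside the window -> dropped regardless of counts
  expect_equal(nrow(filter_window_sequences(ind, uni, window = c(7, 9))), 0L)

  expect_error(filter_window_sequences(ind, uni, window = c(90, 95)),
               class = "editpause_empty_window")
})

test_that("percent_jes_in_window reproduces hand arithmetic", {
  p <- fake_profile(c("121" = 10000, "124" = 2100), c(100, 130))
  expect_equal(percent_jes_in_window(p, c(121, 126)), 12.1)
  expect_equal(percent_jes_in_window(fake_profile(numeric(0), c(100, 130)),
                                     c(121, 126)), 0)
  p3 <- fake_profile(c("123" = 1e5), c(100, 130))
  expect_equal(percent_jes_in_window(p3, c(121, 126)), 100)
  expect_error(percent_jes_in_window(p, c(200, 210)),
               class = "editpause_empty_window")
})

test_that("condition comparison matches the closed-form Student's t", {
  # identical values across conditions
  r <- compare_conditions(c(10, 14), c(10, 14))
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)

  # zero pooled variance with differing means is degenerate, not an error
  r2 <- compare_conditions(c(12, 12), c(26, 26))
  expect_true(r2$degenerate)
  expect_true(is.na(r2$t))

  # closed form: x={10,14}, y={24,28}; sp2=8, se=sqrt(8), t=-14/sqrt(8)
  r3 <- compare_conditions(c(10, 14), c(24, 28))
  expect_equal(r3$t, -14 / sqrt(8), tolerance = 1e-12)
  expect_equal(r3$df, 2)
  expect_equal(r3$p_value, 2 * pt(-abs(-14 / sqrt(8)), df = 2), tolerance = 1e-12)

  expect_error(compare_conditions(5, c(1, 2)),
               class = "editpause_replicate_mismatch")
})

test_that("window sequence rendering aligns U runs against PRE and EDIT rows", {
  s <- toy_scaffold()
  lines <- render_window_sequences(s, NULL, c(1, 4))
  expect_length(lines, 3L)
  expect_match(lines[2], "^PRE")
  expect_match(lines[3], "^EDIT")
  # canonical row spells out 3 U's at ES2 as lowercase u
  expect_match(lines[3], "uuu")
})
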