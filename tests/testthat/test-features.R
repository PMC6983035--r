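test_that("a window yields one value per (index, IMF) pair", {
  rec <- synthesize_ecg(synth_config("normal", duration_s = 60, seed = 13))
  w <- random_normal_window(rec, 1L)
  fv <- extract_features(w)
  expect_equal(nrow(fv), 30L)
  expect_setequal(unique(fv$index), c("KI", "HI", "BDI", "SEI", "PEI"))
  expect_setequal(unique(fv$imf), 1:6)
  expect_true(all(is.finite(fv$value)))
})

test_that("extracted features equal the corresponding single-index calls", {
  rec <- synthesize_ecg(synth_config("normal", duration_s = 60, seed = 14))
  w <- random_normal_window(rec, 2L)
  cfg <- emd_config(); p <- index_params()
  fv <- extract_features(w, cfg, p)
  d <- emd_decompose(w$samples, cfg)
  expect_equal(fv$value[fv$index == "HI" & fv$imf == 3],
               higuchi_fd(d$imfs[[3]], p))
  expect_equal(fv$value[fv$index == "PEI" & fv$imf == 5],
               permutation_entropy(d$imfs[[5]], p))
  expect_equal(fv$value[fv$index == "KI" & fv$imf == 1],
               katz_fd(d$imfs[[1]]))
  # deterministic pipeline: identical on repeat
  expect_identical(fv, extract_features(w, cfg, p))
})

test_that("feature table counts follow the windowing rules", {
  recs <- small_cohort()
  tab <- build_feature_table(recs, n_minutes = 3L, seed = 1L)
  # 3 normal windows + 3 subjects x 3 minutes, 30 features each
  expect_equal(nrow(tab), (3 + 9) * 30)
  expect_equal(sort(unique(tab$minute[tab$label == "scd"])), 1:3)
  expect_identical(tab, build_feature_table(recs, n_minutes = 3L, seed = 1L))
  expect_error(build_feature_table(recs[1:3], n_minutes = 3L),
               class = "scdemd_config_error")
})

test_that("one-way ANOVA reproduces the textbook worked example", {
  res <- one_way_anova(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pf(1.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(res$p_value, 3), 0.288)
})

test_that("ANOVA handles degenerate groups", {
  same <- one_way_anova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  sep <- one_way_anova(c(0, 0), c(1, 1))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p_value, 0)
  expect_error(one_way_anova(c(1, 1), c(1, 1)),
               class = "scdemd_undefined_index")
})

test_that("F equals the squared pooled-variance t statistic", {
  set.seed(15)
  for (i in 1:100) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = runif(1))
    res <- one_way_anova(a, b)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
    expect_equal(res$F, naive_anova_F(a, b), tolerance = 1e-9)
  }
})

# builds a synthetic tidy feature table with seeded N(0,1) values and an
# optional mean shift on one feature for the SCD group
fake_table <- function(n_per_class = 20, shift_index = NULL, shift_imf = NULL,
                       shift = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(index = c("KI", "HI", "BDI", "SEI", "PEI"), imf = 1:6,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(2 * n_per_class), function(i) {
    lab <- if (i <= n_per_class) "normal" else "scd"
    v <- rnorm(nrow(grid))
    if (lab == "scd" && !is.null(shift_index))
      v[grid$index == shift_index & grid$imf == shift_imf] <-
        v[grid$index == shift_index & grid$imf == shift_imf] - shift
    data.frame(subject_id = sprintf("%s%02d", lab, i), label = lab,
               minute = if (lab == "scd") 1L else 0L,
               index = grid$index, imf = grid$imf, value = v)
  })
  do.call(rbind, rows)
}

test_that("a constructed mean shift is ranked first", {
  tab <- fake_table(shift_index = "HI", shift_imf = 3, shift = 4, seed = 2)
  sel <- select_features(tab, k = 2)
  expect_equal(sel$top$index[1], "HI")
  expect_equal(sel$top$imf[1], 3)
  expect_lt(sel$top$p[1], 1e-6)
})

test_that("a >= 3 SD shift always wins the ranking (randomised tables)", {
  for (s in 1:20) {
    grid <- expand.grid(index = c("KI", "HI", "BDI", "SEI", "PEI"), imf = 1:6,
                        stringsAsFactors = FALSE)
    pick <- grid[sample(nrow(grid), 1), ]
    tab <- fake_table(n_per_class = 25, shift_index = pick$index,
                      shift_imf = pick$imf, shift = 3, seed = 100 + s)
    sel <- select_features(tab, k = 1)
    expect_equal(unname(sel$top$index[1]), pick$index)
    expect_equal(unname(sel$top$imf[1]), pick$imf)
  }
})

test_that("k = 30 returns the full ordered ranking", {
  tab <- fake_table(seed = 3)
  sel <- select_features(tab, k = 30)
  expect_equal(nrow(sel$top), 30L)
  expect_true(!is.unsorted(sel$top$p))
})

test_that("per-minute scope reports one block per pre-onset minute", {
  recs <- small_cohort()
  tab <- build_feature_table(recs, n_minutes = 3L, seed = 1L)
  sel <- select_features(tab, k = 2, scope = "per_minute")
  expect_setequal(unique(sel$report$minute), 1:3)
  expect_equal(nrow(sel$report), 3 * 30)
})

test_that("undefined feature values are excluded pairwise, with warning", {
  tab <- fake_table(seed = 4)
  tab$value[tab$index == "KI" & tab$imf == 6] <- NA_real_
  expect_warning(sel <- select_features(tab, k = 30), "excluded")
  expect_equal(nrow(sel$top), 29L)
})

test_that("feature_matrix pivots the selected features wide", {
  recs <- small_cohort()
  tab <- build_feature_table(recs, n_minutes = 3L, seed = 1L)
  sel <- data.frame(index = c("HI", "PEI"), imf = c(3L, 5L))
  fm <- feature_matrix(tab, sel)
  expect_equal(nrow(fm), 12L)        # 3 normal + 9 scd windows
  expect_true(all(c("HI.imf3", "PEI.imf5") %in% names(fm)))
  one <- tab$value[tab$subject_id == fm$subject_id[1] &
                     tab$minute == fm$minute[1] &
                     tab$index == "HI" & tab$imf == 3]
  expect_equal(fm$HI.imf3[1], one)
})
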