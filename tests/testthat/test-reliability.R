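sim_table <- function(n_roi, n_feat, noise_sd, seed,
                      conditions = "c1") {
  # subject effects shared by scan and rescan; rater noise on top
  set.seed(seed)
  rows <- list()
  for (cond in conditions) {
    base <- matrix(rnorm(n_roi * n_feat, 100, 10), n_roi, n_feat)
    for (rep_ in c("scan", "rescan")) {
      vals <- base + matrix(rnorm(n_roi * n_feat, 0, noise_sd),
                            n_roi, n_feat)
      for (i in seq_len(n_roi)) {
        rows[[length(rows) + 1L]] <- data.frame(
          roi_id = i, condition = cond, replicate = rep_,
          feature_name = sprintf("f%03d", seq_len(n_feat)),
          value = vals[i, ])
      }
    }
  }
  do.call(rbind, rows)
}

test_that("identical scan and rescan make every varying feature robust", {
  tbl <- sim_table(6, 30, noise_sd = 0, seed = 1)
  rep_ <- screen_features(tbl)
  expect_true(all(rep_$records$label[!rep_$records$degenerate] == "robust"))
  expect_true(all(rep_$records$icc[!rep_$records$degenerate] == 1))
  # a constant feature is degenerate and excluded from robust sets
  tbl2 <- tbl
  tbl2$value[tbl2$feature_name == "f001"] <- 3.14
  rep2 <- screen_features(tbl2)
  expect_true(rep2$records$degenerate[rep2$records$feature_name == "f001"])
  expect_false("f001" %in% rep2$robust_sets[[1]])
})

test_that("robust counts fall as rater noise grows", {
  counts <- vapply(c(2, 8, 32), function(s) {
    rep_ <- screen_features(sim_table(8, 40, noise_sd = s, seed = 7))
    length(rep_$robust_sets[[1]])
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[3])
})

test_that("robust-set intersections follow set algebra", {
  sets <- list(a = c("a", "b", "c"), b = c("b", "c", "d"))
  out <- robust_intersections(sets)
  expect_identical(out$robust_count[out$condition_set == "a"], 3L)
  expect_identical(out$robust_count[out$condition_set == "a+b"], 2L)
  three <- robust_intersections(list(x = c("a", "b"), y = c("b", "c"),
                                     z = c("b")))
  expect_identical(three$robust_count[three$condition_set == "x+y+z"], 1L)
  expect_true("x+y" %in% three$condition_set)
})

test_that("reproducibility screening uses conditions as raters", {
  tbl <- sim_table(6, 20, noise_sd = 0, seed = 3,
                   conditions = c("bw10", "bw25", "bw50", "bw100"))
  rep_ <- reproducibility_screen(tbl)
  expect_identical(nrow(rep_$records), 20L)
  expect_identical(rep_$form, "average")
  # identical conditions -> ICC 1 (the per-condition base is redrawn, so
  # rebuild with one shared base)
  set.seed(9)
  base <- data.frame(roi_id = rep(1:5, each = 4),
                     condition = rep(c("a", "b", "c", "d"), 5),
                     feature_name = "f1",
                     value = rep(rnorm(5, 50, 5), each = 4))
  r1 <- reproducibility_screen(base)
  expect_equal(r1$records$icc, 1)
  expect_error(reproducibility_screen(base[base$condition == "a", ]),
               ">= 2 conditions")
})

test_that("volume correlation flags the signed rule exactly", {
  vols <- c(27.68, 34.38, 41.71, 92.24, 237.5)
  set.seed(5)
  perm <- sample(vols)
  tbl <- rbind(
    data.frame(feature_name = "prop", volume = vols, value = 2 * vols),
    data.frame(feature_name = "anti", volume = vols, value = -vols),
    data.frame(feature_name = "perm", volume = vols, value = perm),
    data.frame(feature_name = "flat", volume = vols, value = 1))
  out <- volume_correlation(tbl)
  expect_true(out$flagged[out$feature_name == "prop"])
  expect_equal(out$r[out$feature_name == "prop"], 1)
  # r = -1 is NOT flagged under the signed rule
  expect_false(out$flagged[out$feature_name == "anti"])
  expect_equal(out$r[out$feature_name == "anti"], -1)
  # |r| option flips that
  out_abs <- volume_correlation(tbl, absolute = TRUE)
  expect_true(out_abs$flagged[out_abs$feature_name == "anti"])
  # closed-form Pearson oracle for the permuted feature
  r_oracle <- sum((vols - mean(vols)) * (perm - mean(perm))) /
    sqrt(sum((vols - mean(vols))^2) * sum((perm - mean(perm))^2))
  expect_equal(out$r[out$feature_name == "perm"], r_oracle,
               tolerance = 1e-12)
  # constant feature is degenerate, not flagged
  expect_true(out$degenerate[out$feature_name == "flat"])
  expect_false(out$flagged[out$feature_name == "flat"])
  expect_error(volume_correlation(tbl[tbl$volume < 30, ]), ">= 3")
  # invariance under positive affine rescaling of the feature
  tbl2 <- tbl[tbl$feature_name == "perm", ]
  tbl2$value <- 3.7 * tbl2$value + 11
  out2 <- volume_correlation(rbind(tbl2, tbl[tbl$feature_name == "prop", ]))
  expect_equal(out2$r[out2$feature_name == "perm"], r_oracle,
               tolerance = 1e-12)
})

test_that("cohort comparison matches the closed-form paired t-test", {
  mk <- function(vals_a, vals_b, fn = "f1") {
    rbind(data.frame(cohort = "A", subject = seq_along(vals_a),
                     feature_name = fn, value = vals_a),
          data.frame(cohort = "B", subject = seq_along(vals_b),
                     feature_name = fn, value = vals_b))
  }
  # identical arms: zero differences -> t = 0, p = 1
  out0 <- compare_cohorts(mk(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
  expect_false(out0$significant)
  # constant non-zero difference: |t| -> Inf, p -> 0
  outc <- compare_cohorts(mk(c(1, 2, 3), c(2, 3, 4)))
  expect_true(is.infinite(outc$t) && outc$t < 0)
  expect_equal(outc$p, 0)
  # non-degenerate case against the hand formula
  x <- c(1, 2, 4); y <- c(2, 3, 3)
  outn <- compare_cohorts(mk(x, y))
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(outn$t, t_oracle, tolerance = 1e-12)
  expect_equal(outn$p, 2 * pt(-abs(t_oracle), df = 2), tolerance = 1e-12)
  # unequal arms cannot be paired
  bad <- rbind(mk(c(1, 2, 3), c(1, 2, 3)),
               data.frame(cohort = "B", subject = 4, feature_name = "f1",
                          value = 9))
  expect_error(compare_cohorts(bad), "unequal")
  # robust_set filtering
  two <- rbind(mk(c(1, 2, 3), c(5, 6, 9), "f1"),
               mk(c(1, 2, 3), c(5, 6, 9), "f2"))
  expect_identical(compare_cohorts(two, robust_set = "f2")$feature_name,
                   "f2")
})

test_that("null cohorts reject about 5 percent of independent features", {
  set.seed(77)
  frac <- replicate(5, {
    n_feat <- 200; n <- 9
    tbl <- rbind(
      data.frame(cohort = "A",
                 subject = rep(seq_len(n), n_feat),
                 feature_name = rep(sprintf("f%03d", seq_len(n_feat)),
                                    each = n),
                 value = rnorm(n * n_feat)),
      data.frame(cohort = "B",
                 subject = rep(seq_len(n), n_feat),
                 feature_name = rep(sprintf("f%03d", seq_len(n_feat)),
                                    each = n),
                 value = rnorm(n * n_feat)))
    mean(compare_cohorts(tbl)$significant)
  })
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})
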