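ancient4 <- list(
  a1 = sub_profile("a1", 73, age = 100),
  a2 = sub_profile("a2", 150, age = 200),
  a3 = sub_profile("a3", 263, age = 5000),
  a4 = sub_profile("a4", 750, age = 6000))

test_that("explicit edges assign samples to half-open age intervals", {
  bins <- assign_periods(ancient4, edges = c(0, 1000, 10000))
  expect_length(bins, 2)
  expect_setequal(bins[[1]]$ancients, c("a1", "a2"))
  expect_setequal(bins[[2]]$ancients, c("a3", "a4"))
  expect_lte(bins[[1]]$mean_age, bins[[2]]$mean_age)
  expect_error(assign_periods(ancient4, edges = c(0, 50, 1000, 10000)),
               "empty")
  expect_error(assign_periods(ancient4, edges = c(0, 1000)), "outside")
})

test_that("quantile binning splits into equal-count, age-ordered bins", {
  bins1 <- assign_periods(ancient4, target_bins = 1)
  expect_length(bins1, 1)
  expect_length(bins1[[1]]$ancients, 4)

  set.seed(31)
  ages <- round(runif(100, 50, 45000))
  profs <- lapply(seq_along(ages), function(i) {
    sub_profile(paste0("s", i), 73, age = ages[i])
  })
  names(profs) <- paste0("s", seq_along(ages))
  bins <- assign_periods(profs, target_bins = 10)
  expect_length(bins, 10)
  expect_true(all(vapply(bins, function(b) length(b$ancients), 0L) == 10))
  # oracle: sort ages and average consecutive blocks of ten
  oracle <- colMeans(matrix(sort(ages), nrow = 10))
  expect_equal(vapply(bins, `[[`, 0, "mean_age"), oracle)
})

test_that("period mean ages are weighted by pair participation", {
  one <- list(index = 1, ancients = "a1",
              pairs = data.frame(ancient = rep("a1", 5),
                                 modern = paste0("m", 1:5)))
  anc <- list(a1 = sub_profile("a1", 73, age = 1000))
  expect_equal(weighted_mean_age(one, anc),
               c(mean_age = 1000, age_sd = 0))

  two <- list(index = 1, ancients = c("a1", "a2"),
              pairs = data.frame(ancient = c("a1", "a2"),
                                 modern = c("m1", "m2")))
  anc2 <- list(a1 = sub_profile("a1", 73, age = 1000),
               a2 = sub_profile("a2", 73, age = 3000))
  expect_equal(weighted_mean_age(two, anc2),
               c(mean_age = 2000, age_sd = 1000))

  uneven <- list(index = 1, ancients = c("a1", "a2"),
                 pairs = data.frame(ancient = c("a1", "a1", "a1", "a2"),
                                    modern = paste0("m", 1:4)))
  wa <- weighted_mean_age(uneven, anc2)
  expect_equal(wa[["mean_age"]], 1500)
  expect_equal(wa[["age_sd"]], 866.03, tolerance = 1e-4)
})

test_that("moderns are matched by longest haplogroup-prefix", {
  anc <- sub_profile("a", 73, age = 900, hap = "U5a", macro = "R")
  pool <- list(m1 = sub_profile("m1", 73, hap = "U5a1"),
               m2 = sub_profile("m2", 150, hap = "U5b"),
               m3 = sub_profile("m3", 263, hap = "H1"))
  got <- match_modern(anc, pool)
  expect_length(got, 1)
  expect_equal(got[[1]]$id, "m1")

  anc_h <- sub_profile("a2", 73, age = 900, hap = "H")
  tie <- list(m1 = sub_profile("m1", 73, hap = "H"),
              m2 = sub_profile("m2", 150, hap = "H"))
  expect_length(match_modern(anc_h, tie), 2)

  anc_m <- sub_profile("a3", 73, age = 900, hap = "M7", macro = "M")
  far <- list(m1 = sub_profile("m1", 73, hap = "R0"),
              m2 = sub_profile("m2", 150, hap = "N1"))
  expect_warning(got <- match_modern(anc_m, far), "no modern")
  expect_length(got, 0)
})

test_that("difference summaries pool group means by pair count", {
  # direct pooling identities on published per-group values
  expect_equal(round(pooled_mean(c(1.67, 0.34, 0.65), c(3, 18, 119)), 2),
               0.63)
  expect_equal(round(pooled_mean(c(1.86, 2.90, 3.61), c(8, 8, 32)), 2),
               3.20)
  expect_equal(pooled_mean(4.2, 17), 4.2)
  # invariance to group ordering
  expect_equal(pooled_mean(c(0.65, 1.67, 0.34), c(119, 3, 18)),
               pooled_mean(c(1.67, 0.34, 0.65), c(3, 18, 119)))

  # end-to-end on a tiny paired bin with known variant sets
  ancients <- list(
    x1 = sub_profile("x1", c(73, 263), age = 1000, hap = "M7", macro = "M"),
    x2 = sub_profile("x2", 73, age = 1200, hap = "R0", macro = "R"))
  moderns <- list(
    y1 = sub_profile("y1", 73, hap = "M7", macro = "M"),
    y2 = sub_profile("y2", c(73, 150, 263), hap = "R0", macro = "R"))
  bin <- assign_periods(ancients, edges = c(0, 2000))[[1]]
  bin <- build_pairs(bin, ancients, moderns)
  s <- summarize_differences(bin, c(ancients, moderns))
  expect_equal(s$n_pairs, 2)
  expect_equal(s$per_group$mean_d[s$per_group$macrohaplogroup == "M"], 1)
  expect_equal(s$per_group$mean_d[s$per_group$macrohaplogroup == "R"], 2)
  expect_equal(s$pooled_mean, 1.5)
})

test_that("expected differences extrapolate the anchor rate linearly", {
  anchor <- list(pooled_mean = 0.63, mean_age = 1119)
  expect_equal(round(expected_differences(list(mean_age = 13017), anchor), 2),
               7.33)
  expect_equal(round(expected_differences(list(mean_age = 40160), anchor), 2),
               22.61)
  expect_equal(expected_differences(list(mean_age = 1119), anchor), 0.63)
  # linear in age
  expect_equal(expected_from_anchor(0.63, 1119, 2 * 5000),
               2 * expected_from_anchor(0.63, 1119, 5000))
  expect_error(expected_from_anchor(0.63, 0, 5000), "non-zero")
})

test_that("published pooled and expected columns are reproduced row-wise", {
  tab <- period_difference_table()
  for (k in seq_len(nrow(tab))) {
    means <- c(tab$m_mean[k], tab$n_mean[k], tab$r_mean[k])
    ns <- c(tab$m_n[k], tab$n_n[k], tab$r_n[k])
    keep <- !is.na(means)
    got <- round(pooled_mean(means[keep], ns[keep]), 2)
    if (k == 4) {
      # the published total (1.51) was pooled from unrounded group means;
      # the printed 2-d.p. group means give 1.49
      expect_lte(abs(got - tab$total_mean[k]), 0.025)
    } else {
      expect_equal(got, tab$total_mean[k])
    }
  }
  anchor_mean <- tab$total_mean[1]
  anchor_age <- tab$mean_age[1]
  got <- expected_from_anchor(anchor_mean, anchor_age, tab$mean_age)
  # row 8 was printed truncated rather than rounded (8.9951 -> 8.99);
  # all other rows agree to 2 decimals
  expect_true(all(abs(got - tab$expected) <= 0.0055))
  expect_equal(round(got[-8], 2), tab$expected[-8])
})

test_that("rate homogeneity uses Welch's test on the extreme group pair", {
  same <- list(M = c(0, 1, 2, 3), R = c(0, 1, 2, 3))
  res <- homogeneity_test(same)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)

  apart <- list(M = c(0, 0, 0, 0), R = c(10, 10, 10, 10))
  expect_lt(homogeneity_test(apart)$p_value, 0.001)

  expect_error(homogeneity_test(list(M = c(1, 2))), "two")

  # the most divergent of three groups is the pair actually compared
  three <- list(M = c(1, 2, 1, 2), N = c(5, 6, 5, 6), R = c(2, 3, 2, 3))
  expect_setequal(homogeneity_test(three)$groups, c("M", "N"))
})
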