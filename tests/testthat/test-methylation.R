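test_that("the four-type truth table is total over all 8 triplets", {
  grid <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  got <- classify_band(grid$x, grid$y, grid$z)
  expect_equal(sum(got == "unclassifiable"), 4)  # exactly the x = 0 half
  expect_true(all(got[grid$x == 0] == "unclassifiable"))
  expect_equal(sort(got[grid$x == 1]), c("I", "II", "III", "IV"))

  # the published classification, case by case
  expect_equal(classify_band(1, 0, 0), "I")    # both enzymes cut
  expect_equal(classify_band(1, 0, 1), "II")   # HpaII cuts, MspI blocked
  expect_equal(classify_band(1, 1, 0), "III")  # HpaII blocked, MspI cuts
  expect_equal(classify_band(1, 1, 1), "IV")   # both blocked
  expect_equal(methylation_pattern(c("I", "II", "III", "IV")),
               c("non-methylation", "semi-methylation",
                 "full-methylation", "full-methylation"))
  expect_error(classify_band(1, 2, 0), class = "credra_validation_error")
  expect_error(methylation_pattern("V"), class = "credra_lookup_error")
})

test_that("type tallies match the triplets and preserve the band count", {
  m <- credra_from_triplets(list(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0),
                                 c(1, 1, 1)))
  expect_equal(type_counts(m, "Cu20"),
               c(I = 1L, II = 1L, III = 1L, IV = 1L, unclassifiable = 0L))

  m2 <- credra_from_triplets(c(rep(list(c(1, 1, 1)), 4), list(c(0, 1, 1))))
  ct <- type_counts(m2, "Cu20")
  expect_equal(ct[["unclassifiable"]], 1L)
  expect_equal(ct[["IV"]], 4L)
  expect_equal(sum(ct), 5L)  # conservation: every band lands in a category

  m3 <- credra_from_triplets(rep(list(c(1, 1, 1)), 20))
  expect_equal(type_counts(m3, "Cu20")[["IV"]], 20L)
})

test_that("type percentages exclude unclassifiable bands and sum to 100", {
  expect_equal(type_percentages(c(I = 1, II = 1, III = 1, IV = 1)),
               c(I = 25, II = 25, III = 25, IV = 25))
  expect_equal(type_percentages(c(I = 0, II = 0, III = 0, IV = 50)),
               c(I = 0, II = 0, III = 0, IV = 100))
  expect_equal(type_percentages(c(I = 2, II = 3, III = 5, IV = 90)),
               c(I = 2, II = 3, III = 5, IV = 90))
  pc <- type_percentages(c(I = 3, II = 1, III = 4, IV = 1,
                           unclassifiable = 7))
  expect_equal(sum(pc), 100)
  expect_error(type_percentages(c(I = 0, II = 0, III = 0, IV = 0,
                                  unclassifiable = 3)),
               class = "credra_domain_error")
})

test_that("pattern ratios from counts follow the share formulas", {
  expect_equal(pattern_ratios_from_counts(c(I = 1, II = 1, III = 1, IV = 1)),
               c(total = 75, full = 50, semi = 25, non = 25))
  expect_equal(pattern_ratios_from_counts(c(I = 0, II = 0, III = 0, IV = 10)),
               c(total = 100, full = 100, semi = 0, non = 0))
  expect_equal(pattern_ratios_from_counts(c(I = 2, II = 3, III = 5, IV = 90)),
               c(total = 98, full = 95, semi = 3, non = 2))
})

test_that("the percent-vector pathway is the linear-sum reading", {
  r <- pattern_ratios_from_percent_vector(2.60, 3.40, 5.10, 86.60)
  expect_equal(r[["total"]], 95.10)
  expect_equal(r[["full"]], 91.70)
  expect_equal(r[["semi"]], 3.40)
  expect_equal(r[["non"]], 2.60)
  expect_equal(unname(pattern_ratios_from_percent_vector(0, 0, 0, 0)),
               c(0, 0, 0, 0))
  expect_error(pattern_ratios_from_percent_vector(-1, 0, 0, 0),
               class = "credra_domain_error")
})

test_that("count and percent-vector pathways agree when shares sum to 100", {
  set.seed(16)
  for (i in 1:200) {
    ct <- setNames(c(sample(0:50, 4, replace = TRUE),
                     sample(0:5, 1)),
                   c("I", "II", "III", "IV", "unclassifiable"))
    if (sum(ct[1:4]) == 0) ct[["IV"]] <- 1
    pc <- type_percentages(ct)
    from_counts <- pattern_ratios_from_counts(ct)
    from_pct <- pattern_ratios_from_percent_vector(pc[["I"]], pc[["II"]],
                                                   pc[["III"]], pc[["IV"]])
    expect_equal(from_counts, from_pct)
    # exact conservation identities
    expect_identical(from_counts[["total"]],
                     from_counts[["full"]] + from_counts[["semi"]])
    expect_identical(from_counts[["non"]] + from_counts[["total"]], 100)
  }
})

test_that("type_counts agrees with brute-force triplet enumeration", {
  set.seed(17)
  for (i in 1:40) {
    k <- sample(1:6, 1)
    tri <- replicate(k, sample(0:1, 3, replace = TRUE), simplify = FALSE)
    m <- credra_from_triplets(tri)
    expected <- table(factor(
      vapply(tri, function(t) oracle_classify(t[1], t[2], t[3]),
             character(1)),
      levels = c("I", "II", "III", "IV", "unclassifiable")))
    expect_equal(type_counts(m, "Cu20"),
                 setNames(as.integer(expected), names(expected)))
  }
})

test_that("methylation_table reports per-sample shares in both modes", {
  m <- credra_from_triplets(list(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0),
                                 c(1, 1, 1)))
  for (mode in c("average", "pooled")) {
    tbl <- methylation_table(m, mode = mode)
    expect_equal(nrow(tbl), 2)
    trt <- tbl[tbl$sample_id == "Cu20", ]
    expect_equal(trt$type_I, 25)
    expect_equal(trt$total, 75)
    expect_equal(trt$full, 50)
    expect_equal(trt$semi, 25)
    expect_equal(trt$n_bands, 4)
  }
  wide <- format_methylation_table(methylation_table(m))
  expect_equal(names(wide), c("metric", "control", "Cu20"))
  expect_equal(wide$Cu20[wide$metric == "Total methylated bands ratio (%)"],
               75)
})

test_that("report rounding is half-up at two decimals", {
  # 0.125 is exactly representable: half-up gives .13 where round() banks to .12
  expect_equal(credra:::round_half_up(0.125, 2), 0.13)
  expect_equal(round(0.125, 2), 0.12)
  expect_equal(credra:::round_half_up(-0.125, 2), -0.13)
})
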