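# Comparison ratios, mobility shares, validation discrepancies

test_that("ROM and stress ratios reproduce their printed forms", {
  t2 <- table2_rom()
  rep <- compare_summaries(t2$pre, t2$post)
  fused <- rep[rep$scope == "T10-L4", ]
  expect_equal(fused$percent, 21.1)
  expect_equal(fused$direction, "decrease")
  cranial <- rep[rep$scope == "C7-T10", ]
  expect_equal(cranial$times, 1.7)
  caudal <- rep[rep$scope == "L4-L5", ]
  expect_equal(caudal$percent, 39.2)

  st <- compare_summaries(
    data.frame(scope = "endplate:L4_inf", value = 6430),
    data.frame(scope = "endplate:L4_inf", value = 1710))
  expect_equal(st$percent, 26.6)

  eq <- compare_summaries(data.frame(scope = "x", value = 3.2),
                          data.frame(scope = "x", value = 3.2))
  expect_equal(eq$percent, 100)
  expect_equal(eq$direction, "unchanged")

  expect_error(compare_summaries(data.frame(scope = "a", value = 1),
                                 data.frame(scope = "b", value = 1)),
               "scope mismatch")
  flagged <- compare_summaries(data.frame(scope = "a", value = 0),
                               data.frame(scope = "a", value = 1))
  expect_true(is.na(flagged$ratio))
  expect_match(flagged$flag, "nonpositive")
})

test_that("ratios are scale invariant", {
  t2 <- table2_rom()
  r1 <- compare_summaries(t2$pre, t2$post)
  t2$pre$value <- t2$pre$value * 3.7
  t2$post$value <- t2$post$value * 3.7
  r2 <- compare_summaries(t2$pre, t2$post)
  expect_equal(r2$percent, r1$percent)
  expect_equal(r2$times, r1$times)
})

test_that("mobility shares follow the non-overlapping block definition", {
  t2 <- table2_rom()
  expect_equal(mobility_share(t2$pre, "C7-T10"), 52.2)
  expect_equal(mobility_share(t2$post, "C7-T10"), 87.7)
  single <- data.frame(scope = "C7-L5", value = 12.3)
  expect_equal(mobility_share(single, "C7-L5"), 100)
  set.seed(5)
  rows <- data.frame(scope = c("C7-T10", "T10-L4", "L4-L5"),
                     value = stats::runif(3, 1, 30))
  blk <- "T10-L4"
  expect_equal(mobility_share(rows, blk),
               round(100 * rows$value[2] / sum(rows$value), 1))
  overlap <- rbind(t2$pre, data.frame(scope = "T9-T10", value = 1.71))
  expect_error(mobility_share(overlap, "C7-T10"), "overlap")
})

test_that("validation summaries report absolute discrepancies", {
  model <- data.frame(angle = c("Cobb", "TLK"), timepoint = "pre",
                      value_deg = c(45.5, 10.0))
  xray <- data.frame(angle = c("Cobb", "TLK"), timepoint = "pre",
                     value_deg = c(52, 4.6))
  v <- validation_summary(model, xray)
  expect_equal(v$discrepancy_deg[v$angle == "Cobb"], 6.5)
  expect_equal(v$discrepancy_deg[v$angle == "TLK"], 5.4)
  same <- validation_summary(model, model)
  expect_equal(same$discrepancy_deg, c(0, 0))
  expect_error(validation_summary(model, xray[1, ]), "pair")
})

test_that("config hashes are stable 8-digit hex strings", {
  h1 <- spinefe:::config_hash(list(a = 1, b = "x"))
  h2 <- spinefe:::config_hash(list(a = 1, b = "x"))
  expect_identical(h1, h2)
  expect_match(h1, "^[0-9a-f]{8}$")
  expect_false(identical(h1, spinefe:::config_hash(list(a = 2, b = "x"))))
})

test_that("comparison reports are written in three formats", {
  t2 <- table2_rom()
  rep <- compare_summaries(t2$pre, t2$post)
  base <- tempfile()
  paths <- write_comparison_report(rep, base, meta = list(seed = 1))
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(back$percent, rep$percent)
  js <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(js$rows$percent, rep$percent)
})
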