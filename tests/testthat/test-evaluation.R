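test_that("confusion counts follow the positive-cancerous convention", {
  y <- c(1, 1, -1, -1, 1)
  expect_equal(unclass(confusion(y, y))[c("tp", "fn", "fp", "tn")],
               list(tp = 3L, fn = 0L, fp = 0L, tn = 2L))
  cm <- confusion(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(1, 1, 1, 1))
  all_pos <- confusion(c(1, -1, -1), c(1, 1, 1))
  expect_equal(c(all_pos$fn, all_pos$tn), c(0, 0))
  expect_error(confusion(c(1, -1), c(1)), "equal length")
  # 40-image hold-out: 19/20 cancerous and 18/20 healthy correct
  cm <- confusion(rep(c(1, -1), each = 20),
                  c(rep(1, 19), -1, 1, 1, rep(-1, 18)))
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(19, 1, 2, 18))
})

test_that("metrics reproduce the reference confusion-matrix values", {
  m <- cm_metrics(confusion_from_counts(19, 1, 2, 18))
  expect_equal(m$accuracy, 92.50)
  expect_equal(m$precision, 90.47, tolerance = 0.01 / 90)
  expect_equal(m$recall, 95)
  expect_equal(m$f1, 92.68, tolerance = 0.01 / 92)
  m2 <- cm_metrics(confusion_from_counts(18, 2, 3, 17))
  expect_equal(m2$accuracy, 87.5)
  expect_equal(m2$precision, 85.71, tolerance = 0.01 / 85)
  expect_equal(m2$recall, 90)
  expect_equal(m2$f1, 87.80, tolerance = 0.01 / 87)
  p <- cm_metrics(confusion_from_counts(5, 0, 0, 5))
  expect_equal(unlist(p), c(accuracy = 100, precision = 100,
                            recall = 100, f1 = 100))
})

test_that("zero denominators yield explicit undefined markers", {
  m <- cm_metrics(confusion_from_counts(0, 0, 0, 10))
  expect_true(is.na(m$precision))      # no predicted positives
  expect_true(is.na(m$recall))         # no actual positives
  expect_true(is.na(m$f1))
  expect_equal(m$accuracy, 100)
  expect_error(cm_metrics(confusion_from_counts(0, 0, 0, 0)), "empty")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(3)
  for (rep in 1:25) {
    cm <- confusion_from_counts(sample(1:30, 1), sample(1:30, 1),
                                sample(1:30, 1), sample(1:30, 1))
    m <- cm_metrics(cm)
    # f1 is the harmonic mean: between min and the arithmetic mean
    expect_lte(m$f1, (m$precision + m$recall) / 2 + 1e-12)
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    # perfect predictions give all-100
    y <- c(rep(1, 5), rep(-1, 5))
    expect_equal(unlist(cm_metrics(confusion(y, y))),
                 c(accuracy = 100, precision = 100, recall = 100, f1 = 100))
  }
})

test_that("boxplot_table gives interpolated five-number summaries", {
  ft <- as.data.frame(matrix(0, 5, 8, dimnames = list(NULL, FEATURE_NAMES)))
  ft$entropy <- 1:5
  tab <- boxplot_table(ft)
  expect_equal(nrow(tab), 8)           # no HOG block present
  row <- tab[tab$feature == "entropy", ]
  expect_equal(unlist(row[c("min", "q1", "median", "q3", "max")]),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  # a single vector collapses all five numbers onto the value
  one <- ft[1, ]
  tab1 <- boxplot_table(one)
  expect_true(all(tab1$min == tab1$max))
  # with HOG columns present the summary gains the ninth row
  ft$hog_1 <- 0.5; ft$hog_2 <- 0.1
  tab9 <- boxplot_table(ft)
  expect_equal(nrow(tab9), 9)
  expect_equal(tab9$median[tab9$feature == "hog"], 0.3)
  expect_error(boxplot_table(ft[0, ]), "non-empty")
})
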