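test_that("interval extraction matches the hand-enumerated toy table", {
  lab <- extract_intervals(toy_visits())
  expect_equal(nrow(lab), 3)
  lab <- lab[order(lab$subject_id), ]
  expect_equal(lab$interval_days, c(100L, 400L, NA_integer_))
  expect_equal(lab$followup_days, c(100L, 400L, 250L))
  expect_equal(lab$baseline_date, rep("2020-01-01", 3))
})

test_that("interval extraction is invariant to row order and handles exclusions", {
  v <- toy_visits()
  set.seed(1)
  shuf <- v[sample(nrow(v)), ]
  expect_equal(extract_intervals(shuf), extract_intervals(v),
               ignore_attr = TRUE)
  # AD strictly before any MCI visit -> excluded and reported
  v2 <- rbind(v, data.frame(subject_id = "D",
                            visit_date = c("2020-01-01", "2020-06-01"),
                            diagnosis = c("AD", "MCI"), mmse = c(18, 17),
                            cdr = c(1, 1)))
  lab2 <- extract_intervals(v2)
  expect_false("D" %in% lab2$subject_id)
  expect_equal(attr(lab2, "excluded_subjects"), "D")
  expect_error(extract_intervals(v[0, ]), "empty")
  bad <- v; bad$visit_date[1] <- "not-a-date"
  expect_error(extract_intervals(bad), "unparseable")
})

test_that("horizon labels are exhaustive and exclusive on a small grid", {
  for (interval in c(NA, 1L, 150L, 365L, 366L, 800L))
    for (followup in c(0L, 179L, 365L, 800L))
      for (h in c(180L, 365L, 730L)) {
        fu <- if (!is.na(interval)) max(interval, followup) else followup
        lab <- label_at_horizon(interval, fu, h)
        is_one <- !is.na(interval) && interval <= h
        is_zero <- !is_one && (fu >= h || (!is.na(interval) && interval > h))
        expected <- if (is_one) 1L else if (is_zero) 0L else NA_integer_
        expect_identical(lab, expected)
      }
})

test_that("horizon boundary and censoring cases follow the declared rules", {
  expect_identical(label_at_horizon(200L, 200L, 365L), 1L)
  expect_identical(label_at_horizon(200L, 200L, 180L), 0L)  # conversion documents follow-up
  expect_identical(label_at_horizon(365L, 365L, 365L), 1L)  # boundary counts
  expect_identical(label_at_horizon(NA, 300L, 365L), NA_integer_)
  expect_identical(label_at_horizon(NA, 365L, 365L), 0L)
  expect_error(label_at_horizon(10L, 10L, 0L), ">= 1")
})

test_that("horizon label table drops censored rows but counts them", {
  lab <- extract_intervals(toy_visits())
  tab <- horizon_label_table(lab, c(180L, 365L, 730L))
  expect_true(all(tab$label %in% c(0L, 1L)))
  # A: 1/1/1 ; B: 0/0/1 ; C: censored at every horizon except none
  a <- tab[tab$subject_id == "A", "label"]
  b <- tab[tab$subject_id == "B", "label"]
  expect_equal(a, c(1L, 1L, 1L))
  expect_equal(b, c(0L, 0L, 1L))
  expect_equal(sum(tab$subject_id == "C"), 1)  # only 180-day horizon observed
  expect_equal(attr(tab, "n_censored"), 2)
})

test_that("interval binning honors the 150-365 / 365-1095 ranges", {
  expect_equal(bin_interval(c(150, 365, 366, 1095, 1200, 149, 0)),
               c("short", "short", "long", "long", "out_of_range",
                 "out_of_range", "out_of_range"))
})

test_that("numeric transform equals the per-feature affine oracle", {
  d <- 4L
  W <- matrix(seq_len(3 * d) / 10, 3, d)
  b <- matrix(rnorm(3 * d), 3, d)
  x <- c(0.5, -1, 2)
  out <- transform_numeric(x, W, b)
  for (i in 1:3)
    expect_equal(out[i, ], x[i] * W[i, ] + b[i, ], tolerance = 1e-6)
  # identity and constant degenerate cases
  expect_equal(transform_numeric(c(1, 1), matrix(1, 2, 1), matrix(0, 2, 1)),
               matrix(1, 2, 1))
  expect_equal(transform_numeric(c(3, 7), matrix(0, 2, 2),
                                 matrix(5, 2, 2)), matrix(5, 2, 2))
  expect_error(transform_numeric(c(1, NA), W[1:2, ], b[1:2, ]), "non-finite")
  expect_error(transform_numeric(1:2, W, b), "shape")
})

test_that("categorical embedding looks up rows with a missing fallback", {
  tab <- make_embedding_table(3, 5, seed = 2)
  expect_equal(dim(tab), c(4, 5))
  e <- embed_categorical(c(2L, 2L), tab)
  expect_identical(e[1, ], e[2, ])
  expect_equal(embed_categorical(NA, tab)[1, ], tab[1, ])
  expect_equal(dim(embed_categorical(c(1L, 3L), tab)), c(2, 5))
  expect_error(embed_categorical(9L, tab), "out of vocabulary")
})

test_that("multimodal assembly concatenates blocks in fixed order", {
  d <- 8L
  cat_t <- matrix(1, 2, d); num_t <- matrix(2, 3, d); img_t <- matrix(3, 4, d)
  z <- assemble_multimodal(cat_t, num_t, img_t)
  expect_equal(dim(z), c(9L, d))
  expect_equal(attr(z, "p"), 2L)
  expect_equal(attr(z, "q"), 3L)
  expect_equal(attr(z, "r"), 4L)
  expect_equal(z[1:2, ], cat_t, ignore_attr = TRUE)
  expect_equal(z[6:9, ], img_t, ignore_attr = TRUE)
  # ablating the image stream shrinks the assembly accordingly
  z2 <- assemble_multimodal(cat_t, num_t, NULL)
  expect_equal(dim(z2), c(5L, d))
  # permuting rows within one block permutes only those assembly rows
  img_p <- img_t; img_p[c(1, 4), ] <- img_t[c(4, 1), ]
  z3 <- assemble_multimodal(cat_t, num_t, img_p)
  expect_equal(z3[1:5, ], z[1:5, ], ignore_attr = TRUE)
  expect_error(assemble_multimodal(cat_t, matrix(1, 2, d + 1), NULL),
               "dimension d")
})

test_that("standardization statistics come from the training split only", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3)
  st <- fit_standardizer(x[1:10, ])
  a <- apply_standardizer(x, st)
  # perturbing validation rows must not alter the transform of other rows
  x2 <- x; x2[15, ] <- x2[15, ] + 100
  st2 <- fit_standardizer(x2[1:10, ])
  expect_identical(st, st2)
  expect_identical(apply_standardizer(x2, st2)[1:10, ], a[1:10, ])
  sd_train <- apply(apply_standardizer(x[1:10, ], st), 2, sd)
  expect_equal(sd_train, rep(1, 3), tolerance = 1e-6, ignore_attr = TRUE)
})
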