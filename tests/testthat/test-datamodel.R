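test_that("dataset construction validates labels and values", {
  x <- array(rnorm(24), c(4, 3, 2))
  ds <- transposable_dataset(x)
  expect_s3_class(ds, "transposable_dataset")
  expect_equal(dim(ds), c(4L, 3L, 2L))
  expect_equal(n_rows(ds), 4L)
  expect_equal(n_cols(ds), 3L)
  expect_equal(n_subjects(ds), 2L)

  expect_error(transposable_dataset(array(c(1, NA), c(1, 2, 1))), "finite")
  expect_error(transposable_dataset(x, row_ids = c("a", "a", "b", "c")),
               "duplicate")
  expect_error(transposable_dataset(x, row_ids = c("", "a", "b", "c")),
               "empty")
  # a single matrix becomes an N = 1 dataset
  expect_equal(n_subjects(transposable_dataset(matrix(1:6, 2, 3))), 1L)
})

test_that("long-format round trip preserves values, labels and order", {
  ds <- make_gaussian_ds(r = 5, cc = 3, N = 4, seed = 11)
  f <- tempfile(fileext = ".tsv")
  write_dataset(ds, f, "long")
  # line count = N r c + header
  expect_length(readLines(f), 5 * 3 * 4 + 1)
  ds2 <- load_long_table(f)
  expect_equal(ds2$row_ids, ds$row_ids)
  expect_equal(ds2$col_ids, ds$col_ids)
  expect_equal(ds2$subject_ids, ds$subject_ids)
  expect_lt(max(abs(ds2$values - ds$values)), 1e-12)
})

test_that("long loader reports incomplete cubes, duplicates, bad values", {
  ds <- make_gaussian_ds(r = 2, cc = 2, N = 2, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_dataset(ds, f, "long")
  lines <- readLines(f)
  expect_equal(load_long_table(f)$values, ds$values)

  writeLines(lines[-5], f)
  expect_error(load_long_table(f), "incomplete cube: missing triple")

  writeLines(c(lines, lines[2]), f)
  expect_error(load_long_table(f), "duplicate triple")

  bad <- lines; bad[3] <- sub("\t[^\t]*$", "\tnot_a_number", bad[3])
  writeLines(bad, f)
  expect_error(load_long_table(f), "non-numeric")
})

test_that("wide-format round trip and label reconciliation", {
  ds <- make_gaussian_ds(r = 5, cc = 4, N = 3, seed = 21)
  d <- tempfile(); write_dataset(ds, d, "wide")
  ds2 <- load_wide_matrices(file.path(d, "manifest.tsv"))
  expect_equal(ds2$values, ds$values)
  expect_equal(ds2$subject_ids, ds$subject_ids)

  # permuting one subject's columns must be undone by label matching
  f2 <- file.path(d, paste0(ds$subject_ids[2], ".tsv"))
  tab <- read.delim(f2, check.names = FALSE)
  tabp <- tab[, c(1, 4, 2, 3, 5)]
  names(tabp) <- c("row_id", ds$col_ids[c(3, 1, 2, 4)])
  write.table(tabp, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  ds3 <- load_wide_matrices(file.path(d, "manifest.tsv"))
  expect_lt(max(abs(ds3$values - ds$values)), 1e-12)

  # dropping a row label from one file is a label-set mismatch
  writeLines(readLines(f2)[-3], f2)
  expect_error(load_wide_matrices(file.path(d, "manifest.tsv")),
               "label-set mismatch.*s2")
})

test_that("subset is label-driven, order-preserving and composable", {
  ds <- make_gaussian_ds(r = 6, cc = 4, N = 3, seed = 5)
  s1 <- subset(ds, cols = ds$col_ids[c(2, 4)])
  expect_equal(n_cols(s1), 2L)
  expect_equal(s1$values[, 1, ], ds$values[, 2, ])

  rev_rows <- rev(ds$row_ids)
  s2 <- subset(ds, rows = rev_rows)
  expect_equal(s2$values[1, , ], ds$values[6, , ])

  # subset(subset(ds, A), B) = subset(ds, B) when B is in A
  A <- ds$row_ids[c(1, 3, 4, 6)]
  B <- c(ds$row_ids[4], ds$row_ids[1])
  expect_equal(subset(subset(ds, rows = A), rows = B)$values,
               subset(ds, rows = B)$values)

  expect_error(subset(ds, rows = "nope"), "unknown row")
  expect_error(subset(ds, cols = character(0)), "empty column selection")
})

test_that("expression filter matches a brute-force recount", {
  # deterministic tiny case: row sums (0.05, 0.2) against threshold 0.1
  ds <- transposable_dataset(array(c(0.02, 0.1, 0.03, 0.1), c(2, 2, 1)))
  fl <- filter_rows_by_total(ds, 0.1)
  expect_equal(fl$dropped_rows, ds$row_ids[1])
  expect_equal(n_rows(fl$dataset), 1L)

  # threshold 0 keeps every row of nonnegative data
  dsn <- transposable_dataset(abs(array(rnorm(60), c(5, 4, 3))))
  expect_length(filter_rows_by_total(dsn, 0)$dropped_rows, 0L)

  # random fixture vs independent loop oracle, both reductions
  ds2 <- make_gaussian_ds(r = 40, cc = 5, N = 6, seed = 33, M = 0.1)
  for (red in c("mean_over_subjects", "per_subject_any")) {
    fl2 <- filter_rows_by_total(ds2, 0.5, red)
    keep <- logical(40)
    for (a in 1:40) {
      tots <- sapply(1:6, function(i) sum(ds2$values[a, , i]))
      keep[a] <- if (red == "mean_over_subjects") mean(tots) >= 0.5
                 else all(tots >= 0.5)
    }
    expect_equal(fl2$dataset$row_ids, ds2$row_ids[keep])
    expect_equal(fl2$dropped_rows, ds2$row_ids[!keep])
  }
  expect_error(filter_rows_by_total(ds2, 1e9), "every row")
})

test_that("pair differences are antisymmetric and zero for identical subjects", {
  ds <- make_gaussian_ds(r = 4, cc = 3, N = 5, seed = 8)
  expect_equal(pair_difference(ds, 1, 2), -pair_difference(ds, 2, 1))
  expect_error(pair_difference(ds, 2, 2), "distinct")

  v <- ds$values; v[, , 2] <- v[, , 1]
  dup <- transposable_dataset(v)
  expect_equal(max(abs(pair_difference(dup, 1, 2))), 0)
})
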