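write_pair <- function(mat_lines, meta_lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "m.tsv"); sp <- file.path(dir, "s.tsv")
  writeLines(mat_lines, mp)
  writeLines(meta_lines, sp)
  c(mp, sp)
}

small_meta <- c("sample_id\tsubject_id\ttime_hours",
                "a\ts1\t0", "b\ts1\t2", "c\ts2\t0")

test_that("reading a matrix flags missing cells and validates inputs", {
  p <- write_pair(c("gene_id\ta\tb\tc", "g1\t1.0\tNA\t3.0", "g2\t4\t5\t6"),
                  small_meta)
  x <- suppressMessages(read_expression_matrix(p[1], p[2]))
  expect_equal(sum(!is.na(x$values)), 5)
  expect_equal(x$genes, c("g1", "g2"))
  expect_equal(x$time_offset, 1)  # min time 0 triggers the +1 offset

  # empty markers count as missing too
  p2 <- write_pair(c("gene_id\ta\tb\tc", "g1\t1.0\t\t3.0"), small_meta)
  x2 <- suppressMessages(read_expression_matrix(p2[1], p2[2]))
  expect_equal(sum(is.na(x2$values)), 1)

  expect_error(suppressMessages(read_expression_matrix(
    write_pair(c("gene_id\ta\tb\tc"), small_meta)[1],
    write_pair(c("gene_id\ta\tb\tc"), small_meta)[2])), "no genes")
  expect_error(suppressMessages(read_expression_matrix(
    write_pair(c("id\ta\tb\tc", "g1\t1\t2\t3"), small_meta)[1],
    write_pair(c("id\ta\tb\tc", "g1\t1\t2\t3"), small_meta)[2])), "malformed")
  expect_error(suppressMessages(read_expression_matrix(
    write_pair(c("gene_id\ta\tb\tc", "g1\t1\t2\t3", "g1\t4\t5\t6"), small_meta)[1],
    write_pair(c("gene_id\ta\tb\tc", "g1\t1\t2\t3", "g1\t4\t5\t6"), small_meta)[2])),
    "duplicate gene")
  expect_error(suppressMessages(read_expression_matrix(
    write_pair(c("gene_id\ta\tb\tc", "g1\t1\toops\t3"), small_meta)[1],
    write_pair(c("gene_id\ta\tb\tc", "g1\t1\toops\t3"), small_meta)[2])),
    "non-numeric")
  meta_short <- c("sample_id\tsubject_id\ttime_hours", "a\ts1\t0", "b\ts1\t2")
  expect_error(suppressMessages(read_expression_matrix(
    write_pair(c("gene_id\ta\tb\tc", "g1\t1\t2\t3"), meta_short)[1],
    write_pair(c("gene_id\ta\tb\tc", "g1\t1\t2\t3"), meta_short)[2])),
    "without metadata")
})

test_that("duplicate subject-time chips and bad times are rejected", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(time_course_data(v, data.frame(
    sample_id = c("a", "b"), subject_id = "s1", time_hours = c(2, 2))),
    "duplicate \\(subject_id, time_hours\\)")
  expect_error(time_course_data(v, data.frame(
    sample_id = c("a", "b"), subject_id = "s1", time_hours = c(-1, 2))),
    "non-negative")
  # no offset is applied when times are already positive
  x <- time_course_data(v, data.frame(
    sample_id = c("a", "b"), subject_id = c("s1", "s2"), time_hours = c(1, 2)))
  expect_equal(x$time_offset, 0)
})

test_that("long-format extraction omits missing cells in subject-time order", {
  fx <- make_fixture_dataset(n_null = 2, n_down = 1, n_up = 0, seed = 4)
  x <- fx$dataset
  long <- tc_long(x, x$genes[1])
  expect_equal(nrow(long), 21)  # the incomplete epidermis design
  expect_false(is.unsorted(long$subject_id))
  for (s in unique(long$subject_id)) {
    expect_false(is.unsorted(long$time_hours[long$subject_id == s]))
  }
  # blank one gene entirely: its long format is empty, others untouched
  x$values[2, ] <- NA_real_
  expect_equal(nrow(tc_long(x, x$genes[2])), 0)
  expect_equal(nrow(tc_long(x, x$genes[1])), 21)
  expect_error(tc_long(x, "nope"), "unknown gene_id")
})

test_that("observation pattern accounting matches the stored mask", {
  # complete two-subject design
  v <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("g1", "g2"), c("a", "b", "c", "d")))
  s <- data.frame(sample_id = c("a", "b", "c", "d"),
                  subject_id = rep(c("s1", "s2"), each = 2),
                  time_hours = rep(c(1, 2), 2))
  x <- time_course_data(v, s)
  op <- observation_pattern(x)
  expect_equal(attr(op, "n_present"), 4)

  # single subject, single time
  x1 <- time_course_data(matrix(1, 1, 1, dimnames = list("g", "a")),
                         data.frame(sample_id = "a", subject_id = "s1",
                                    time_hours = 1))
  expect_equal(attr(observation_pattern(x1), "n_present"), 1)

  # sum of per-gene long lengths equals the observed cell count
  fx <- make_fixture_dataset(seed = 8)
  tot <- sum(vapply(fx$dataset$genes,
                    function(g) nrow(tc_long(fx$dataset, g)), numeric(1)))
  expect_equal(tot, sum(!is.na(fx$dataset$values)))
  # with chip-level missingness, sum over subjects of n_i matches the grid
  expect_equal(attr(observation_pattern(fx$dataset), "n_present") *
                 length(fx$dataset$genes), tot)
})

test_that("write then read round-trips values, mask and metadata exactly", {
  fx <- make_fixture_dataset(n_null = 3, n_down = 2, n_up = 1, seed = 21)
  x <- fx$dataset
  x$values[1, 3] <- NA_real_  # add a cell-level hole
  d <- withr::local_tempdir()
  write_expression_matrix(x, file.path(d, "m.tsv"), file.path(d, "s.tsv"))
  y <- read_expression_matrix(file.path(d, "m.tsv"), file.path(d, "s.tsv"),
                              quiet = TRUE)
  expect_equal(y$values, x$values)
  expect_equal(y$samples, x$samples)
  expect_equal(y$genes, x$genes)
  expect_equal(y$time_offset, x$time_offset)
})

test_that("subjects with no observed value anywhere are dropped with a warning", {
  v <- matrix(c(1, 2, NA, NA), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  s <- data.frame(sample_id = c("a", "b"), subject_id = c("s1", "s2"),
                  time_hours = c(1, 2))
  expect_warning(x <- time_course_data(v, s), "no observed values")
  expect_equal(unique(x$samples$subject_id), "s1")
})
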