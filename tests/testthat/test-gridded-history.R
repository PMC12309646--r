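test_that("week index maps season dates to 18 offset weeks from June 1", {
  d <- as.Date(c("2020-06-01", "2020-06-07", "2020-06-08", "2020-09-28",
                 "2020-09-30", "2020-10-01", "2020-05-31", "2021-06-01"))
  expect_identical(week_index(d),
                   c(0L, 0L, 1L, 17L, 17L, NA_integer_, NA_integer_, 0L))
})

test_that("grid construction gives symmetric Moore adjacency with corner/edge sets", {
  g <- lattice_grid(3, 3)
  expect_identical(lengths(g$adj)[c(1, 2, 5)], c(3L, 5L, 8L))
  expect_silent(autoccu:::validate_grid(g))
  # read_grid from row/col attributes reproduces the same adjacency
  at <- data.frame(cell_id = g$cell_ids, cu = g$cu, row = g$row, col = g$col)
  g2 <- read_grid(at)
  expect_identical(g2$adj, g$adj)
  # explicit edge list, one direction only, is symmetrized
  ed <- data.frame(cell_id = c("1", "1", "2"), neighbor_id = c("2", "4", "4"))
  g3 <- read_grid(data.frame(cell_id = as.character(1:4), cu = c(1, 1, 0, 0)),
                  adjacency = ed)
  expect_identical(g3$adj[[4]], c(1L, 2L))
})

test_that("records with known cell ids pass through; coordinates use half-open cells", {
  g <- tiny_grid()
  rec <- data.frame(species_tag = "focal", cell_id = "3",
                    date = as.Date("2020-06-01"))
  out <- assign_to_grid(rec, g)
  expect_identical(out$cell_id, "3")
  # the shared interior corner (1,1) belongs to exactly one cell: row 2, col 2
  corner <- data.frame(species_tag = "focal", lon = 1, lat = 1,
                       date = as.Date("2020-06-01"))
  expect_identical(assign_to_grid(corner, g)$cell_id, "4")
  # west/south edges inclusive, east/north exclusive
  west <- data.frame(species_tag = "focal", lon = 0, lat = 0.5,
                     date = as.Date("2020-06-01"))
  expect_identical(assign_to_grid(west, g)$cell_id, "1")
  east <- data.frame(species_tag = "focal", lon = 2, lat = 0.5,
                     date = as.Date("2020-06-01"))
  expect_identical(attr(assign_to_grid(east, g), "assignment_report")$n_outside, 1L)
})

test_that("out-of-grid and malformed records are dropped and reported", {
  g <- tiny_grid()
  rec <- data.frame(species_tag = "focal",
                    lon = c(0.5, 1.5, 0.2, 5, -1), lat = c(0.5, 1.2, 1.9, 0.5, 0.5),
                    date = as.Date("2020-06-01") + 0:4)
  out <- assign_to_grid(rec, g)
  rep <- attr(out, "assignment_report")
  expect_identical(nrow(out), 3L)
  expect_identical(rep$n_outside, 2L)
  bad <- data.frame(species_tag = "focal", lon = c("x", "0.5"), lat = c("1", "0.5"),
                    date = as.Date("2020-06-01"))
  out2 <- assign_to_grid(bad, g)
  expect_identical(attr(out2, "assignment_report")$n_bad_coord, 1L)
  expect_error(assign_to_grid(data.frame(species_tag = "focal", cell_id = "99",
                                         date = as.Date("2020-06-01")), g),
               "unknown cell_id")
})

test_that("detection history applies the 1/0/missing coding rule exactly", {
  g <- tiny_grid()
  r <- tiny_records()
  h <- build_history(r$focal, r$nonfocal, g, 2020:2021)
  expect_s3_class(h, "occu_history")
  # hand enumeration of the full 4 x 2 x 18 lattice
  expected <- array(NA_integer_, c(4, 2, 18))
  expected[1, 1, 1] <- 1L   # focal Jun 3-4 + nonfocal Jun 2, week 0
  expected[2, 1, 3] <- 0L   # nonfocal Jun 20/21, week 2
  expected[3, 1, 9] <- 0L   # nonfocal Aug 1, week 8
  expected[1, 2, 2] <- 0L   # nonfocal Jun 10 2021, week 1
  expected[4, 2, 7] <- 1L   # focal Jul 15 2021 + nonfocal Jul 16, week 6
  expected[4, 2, 18] <- 0L  # nonfocal Sep 29 2021, week 17
  expect_identical(h$y, expected)
  # effort counts exclude focal records
  expect_identical(h$count, matrix(c(1L, 2L, 1L, 0L, 1L, 0L, 0L, 2L), 4, 2))
  expect_identical(h$surveyed, matrix(c(TRUE, TRUE, TRUE, FALSE,
                                        TRUE, FALSE, FALSE, TRUE), 4, 2))
})

test_that("history builder validates inputs and drops out-of-window records with a tally", {
  g <- tiny_grid()
  r <- tiny_records()
  expect_error(build_history(r$focal[0, ], r$nonfocal[0, ], g, 2020:2021),
               "no observation data")
  expect_error(build_history(r$focal, r$nonfocal, g, c(2020, 2022)), "consecutive")
  extra <- rbind(r$nonfocal,
                 data.frame(species_tag = "nonfocal", cell_id = "1",
                            date = as.Date(c("2020-10-15", "2019-07-01"))))
  h <- build_history(r$focal, extra, g, 2020:2021)
  expect_identical(attr(h, "dropped")$out_of_season, 1L)
  expect_identical(attr(h, "dropped")$out_of_years, 1L)
  expect_identical(h$count, build_history(r$focal, r$nonfocal, g, 2020:2021)$count)
})

test_that("coding is monotone in added records and order-invariant", {
  g <- tiny_grid()
  r <- tiny_records()
  h0 <- build_history(r$focal, r$nonfocal, g, 2020:2021)
  # permutation invariance
  set.seed(1)
  h1 <- build_history(r$focal[sample(nrow(r$focal)), ],
                      r$nonfocal[sample(nrow(r$nonfocal)), ], g, 2020:2021)
  expect_identical(h1$y, h0$y)
  expect_identical(h1$count, h0$count)
  # adding a focal record never turns a 1 into 0/missing; adding a nonfocal
  # record never changes a 1
  set.seed(42)
  for (rep in 1:20) {
    newrec <- data.frame(species_tag = "x", cell_id = sample(g$cell_ids, 1),
                         date = as.Date("2020-06-01") + sample(0:121, 1))
    hf <- build_history(rbind(r$focal, newrec), r$nonfocal, g, 2020:2021)
    expect_true(all(hf$y[h0$y == 1L & !is.na(h0$y)] == 1L))
    hn <- build_history(r$focal, rbind(r$nonfocal, newrec), g, 2020:2021)
    expect_true(all(hn$y[h0$y == 1L & !is.na(h0$y)] == 1L))
    expect_identical(hn$count >= h0$count, matrix(TRUE, 4, 2))
  }
})

test_that("random record fixtures satisfy the coding partition and count identity", {
  g <- lattice_grid(3, 3)
  set.seed(7)
  for (rep in 1:5) {
    nf <- data.frame(species_tag = "nonfocal",
                     cell_id = sample(g$cell_ids, 40, replace = TRUE),
                     date = as.Date("2020-06-01") + sample(0:121, 40, replace = TRUE))
    fo <- data.frame(species_tag = "focal",
                     cell_id = sample(g$cell_ids, 6, replace = TRUE),
                     date = as.Date("2020-06-01") + sample(0:121, 6, replace = TRUE))
    h <- build_history(fo, nf, g, 2020)
    # every entry is exactly one of 1 / 0 / NA, reproducible from the records
    for (i in seq_len(9)) for (j in 1:18) {
      w <- week_index(nf$date) == (j - 1) & nf$cell_id == g$cell_ids[i]
      wf <- week_index(fo$date) == (j - 1) & fo$cell_id == g$cell_ids[i]
      expected <- if (any(wf)) 1L else if (any(w)) 0L else NA_integer_
      expect_identical(h$y[i, 1, j], expected)
    }
    expect_identical(as.vector(h$count),
                     as.vector(table(factor(nf$cell_id, levels = g$cell_ids))))
  }
})

test_that("history CSV round-trips through write_history / read_history", {
  g <- tiny_grid()
  r <- tiny_records()
  h <- build_history(r$focal, r$nonfocal, g, 2020:2021)
  dir <- tempfile()
  write_history(h, dir)
  h2 <- read_history(dir, g, 2020:2021)
  expect_identical(h2$y, h$y)
  expect_identical(h2$count, h$count)
  expect_identical(h2$surveyed, h$surveyed)
})

test_that("record reader parses dates and eliminates incomplete records with a tally", {
  # synthetic example shipped with the package
  f <- system.file("extdata", "example_records.csv", package = "autoccu")
  rec <- read_records(f)
  rep <- attr(rec, "read_report")
  expect_identical(rep$n_input, 8L)
  expect_identical(rep$n_bad_date, 1L)      # unparseable date
  expect_identical(rep$n_no_location, 1L)   # neither cell_id nor lon/lat
  expect_identical(nrow(rec), 6L)
  expect_s3_class(rec$date, "Date")
  # the cleaned records flow into assignment and history building
  g <- tiny_grid()
  fo <- assign_to_grid(rec[rec$species_tag == "focal", ], g)
  nf <- assign_to_grid(rec[rec$species_tag == "nonfocal", ], g)
  h <- build_history(fo, nf, g, 2020)
  expect_identical(sum(h$y == 1L, na.rm = TRUE), 2L)
  expect_identical(sum(h$count), 4L)
})
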