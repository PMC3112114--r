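make_seqs <- function() {
  seq_set(c("ACGTACGTACGT", "TTTTAAAACCCCG"), ids = c("s1", "s2"))
}

test_that("PSP write/read round trip is the identity", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    seqs <- random_seqs(sample(1:4, 1), 15, k)
    p <- random_psp(seqs, k)
    f <- withr::local_tempfile(fileext = ".psp")
    write_psp(p, f)
    p2 <- read_psp(f, seqs, k)
    expect_equal(p2$prob, p$prob, tolerance = 1e-9)
    expect_identical(p2$id, p$id)
    expect_identical(p2$start, p$start)
  }
})

test_that("zero entries are floored to prob_floor at load", {
  seqs <- make_seqs()
  k <- 8
  nwin <- nchar(seqs$seq) - k + 1
  long <- data.frame(id = rep(seqs$id, nwin),
                     start = c(0:(nwin[1] - 1), 0:(nwin[2] - 1)),
                     prob = 0.5)
  long$prob[1] <- 0
  p <- as_psp(long, seqs, k, prob_floor = 1e-10)
  expect_identical(p$prob[1], 1e-10)
  f <- withr::local_tempfile(fileext = ".psp")
  write_psp(p, f)
  expect_identical(read_psp(f, seqs, k, prob_floor = 1e-10)$prob[1], 1e-10)
})

test_that("PSP validation names the offending sequence", {
  seqs <- make_seqs()
  k <- 8
  nwin <- nchar(seqs$seq) - k + 1
  good <- data.frame(id = rep(seqs$id, nwin),
                     start = c(0:(nwin[1] - 1), 0:(nwin[2] - 1)),
                     prob = 0.1)
  expect_s3_class(as_psp(good, seqs, k), "psp")
  # a row of length n instead of n - k + 1
  bad_len <- data.frame(id = rep(seqs$id, nchar(seqs$seq)),
                        start = c(seq_len(nchar(seqs$seq[1])) - 1,
                                  seq_len(nchar(seqs$seq[2])) - 1),
                        prob = 0.1)
  expect_error(as_psp(bad_len, seqs, k), "s1.*expected n - k \\+ 1")
  expect_error(as_psp(good[good$id == "s1", ], seqs, k), "no prior row.*s2")
  extra <- rbind(good, data.frame(id = "ghost", start = 0, prob = 0.1))
  expect_error(as_psp(extra, seqs, k), "unknown sequence.*ghost")
  neg <- good; neg$prob[2] <- -0.1
  expect_error(as_psp(neg, seqs, k), "negative")
  expect_error(as_psp(good[0, ], seqs, k), "empty")
})

test_that("PSP files declare their width and fail on mismatch", {
  seqs <- make_seqs()
  p <- uniform_psp(seqs, 8)
  f <- withr::local_tempfile(fileext = ".psp")
  write_psp(p, f)
  expect_match(readLines(f, n = 1), "^#k=8$")
  expect_error(read_psp(f, seqs, 6), "declares k=8")
  writeLines(sub("^#k=8", "", readLines(f)), f)
  expect_error(read_psp(f, seqs, 8), "missing width")
})

test_that("the uniform prior is flat at 1/(n - k + 1) per sequence", {
  seqs <- seq_set(c("ACGTACGTACGT", "ACGTACGTACGTACGTACGT"))
  p <- uniform_psp(seqs, 8)
  rows <- split(p$prob, p$id)[unique(p$id)]
  expect_identical(lengths(rows), c(seq_1 = 5L, seq_2 = 13L))
  expect_equal(unname(rows[[1]]), rep(0.2, 5))
  expect_equal(unname(rows[[2]]), rep(1 / 13, 13))
})

test_that("weight normalisation yields a convex combination", {
  expect_equal(normalize_weights(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(normalize_weights(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_error(normalize_weights(c(0, 0)), "zero")
  expect_error(normalize_weights(c(-1, 2)), "non-negative")
  set.seed(41)
  for (rep in 1:25) {
    w <- normalize_weights(runif(sample(1:6, 1), 0, 5) + 1e-3)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("the peak prior is a normalised, symmetric t step function", {
  seqs <- seq_set(paste(rep("ACGT", 60), collapse = ""))  # 240 bp
  k <- 8
  summit <- 120L
  p <- peak_psp(tibble::tibble(id = seqs$id, summit = summit), seqs, k)
  expect_equal(sum(p$prob), 1, tolerance = 1e-9)
  centre <- p$start + k %/% 2
  step_idx <- floor(abs(centre - summit) / 25)
  # step-constancy: one value per step index
  expect_true(all(tapply(p$prob, step_idx, function(v)
    diff(range(v)) == 0)))
  # symmetry: equidistant windows left/right of the summit agree
  left <- p$prob[match(summit - 30 - k %/% 2, p$start)]
  right <- p$prob[match(summit + 30 - k %/% 2, p$start)]
  expect_equal(left, right)
  # step values proportional to t3 densities at the step midpoints
  vals <- tapply(p$prob, step_idx, `[`, 1)
  dens <- stats::dt((as.numeric(names(vals)) + 0.5) * 25, df = 3)
  ratios <- vals / dens
  expect_equal(max(ratios) / min(ratios), 1, tolerance = 1e-9)
  expect_error(peak_psp(tibble::tibble(id = seqs$id, summit = summit),
                        seqs, k, step = 0), "config error")
  expect_error(peak_psp(tibble::tibble(id = seqs$id, summit = 999),
                        seqs, k), "out of bounds")
})

test_that("peak-prior properties hold for randomised summits and lengths", {
  set.seed(51)
  for (rep in 1:15) {
    n <- sample(60:300, 1)
    k <- sample(4:8, 1)
    seqs <- random_seqs(2, n, k)
    summits <- vapply(nchar(seqs$seq), function(len) sample(len, 1) - 1L,
                      integer(1))
    p <- peak_psp(tibble::tibble(id = seqs$id, summit = summits), seqs, k)
    for (i in 1:2) {
      row <- p[p$id == seqs$id[i], ]
      expect_equal(sum(row$prob), 1, tolerance = 1e-9)
      idx <- floor(abs(row$start + k %/% 2 - summits[i]) / 25)
      expect_true(all(tapply(row$prob, idx, function(v)
        diff(range(v)) == 0)))
      expect_true(all(diff(tapply(row$prob, idx, `[`, 1)) <= 0))
    }
  }
})
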