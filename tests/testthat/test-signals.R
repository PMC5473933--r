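test_that("signals round-trip through plain-text files", {
  sch <- acquisition_schedule()
  sig <- simulate_response(c(comp = 3), clean_channel(), sch, seed = 1,
                           sample_name = "test sample")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signal(sig, path)
  back <- read_signal(path)
  expect_equal(back$times, sig$times, tolerance = 1e-10)
  expect_equal(back$values, sig$values, tolerance = 1e-10)
  expect_equal(back$channel_name, sig$channel_name)
  expect_equal(back$sample_name, sig$sample_name)
  expect_equal(back$schedule$injection_start_times,
               sig$schedule$injection_start_times)
})

test_that("degenerate or malformed signal files are rejected", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_signal(empty), "empty")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\tsignal_mV", "0\t1", "0.05\t1", "0.3\t1"), bad)
  expect_error(suppressWarnings(read_signal(bad)), "non-uniform")
})

test_that("the standard 120 s schedule yields 2400 samples at 20 Hz", {
  sch <- acquisition_schedule()
  expect_equal(sch$total_duration, 120)
  expect_equal(length(sch$times), 2400)
  expect_equal(sch$injection_start_times, c(20, 40, 60, 80, 100))
})

test_that("cycle anchor points are read at the nearest sample instants", {
  sch1 <- acquisition_schedule(baseline_duration = 0, n_cycles = 1)
  # constant trace
  const <- make_signal(rep(7, length(sch1$times)), sch1)
  pts <- extract_cycle_points(const, 0)
  expect_equal(unlist(pts[c("a", "b", "c", "d", "e")]),
               c(a = 7, b = 7, c = 7, d = 7, e = 7))
  # piecewise-linear triangle: rise 0 -> 10 over 10 s, fall back
  tri <- make_signal(pmin(sch1$times, 20 - sch1$times), sch1)
  pts <- extract_cycle_points(tri, 0)
  expect_equal(unlist(pts[c("a", "b", "c", "d", "e")]),
               c(a = 0, b = 1, c = 10, d = 9, e = 10))
  # single-exponential cycle against direct closed-form evaluation
  s <- 2; conc <- 5; ta <- 4; td <- 7
  sch <- acquisition_schedule(n_cycles = 2)
  sig <- simulate_response(c(comp = conc), clean_channel(s, ta, td), sch)
  pts <- extract_cycle_points(sig, 20)
  rise <- function(t) s * conc * (1 - exp(-t / ta))
  expect_equal(pts$a, rise(0), tolerance = 1e-12)
  expect_equal(pts$b, rise(1), tolerance = 1e-12)
  expect_equal(pts$c, rise(10), tolerance = 1e-12)
  expect_equal(pts$d, rise(10) * exp(-1 / td), tolerance = 1e-12)
  expect_equal(pts$e, rise(10), tolerance = 1e-12)
  expect_error(extract_cycle_points(sig, 100), "outside")
})

test_that("cycle parameters follow the slope/height definitions", {
  mk_pts <- function(a, b, c, d, e)
    structure(list(t_a = 0, t_b = 1, t_c = 10, t_d = 11,
                   a = a, b = b, c = c, d = d, e = e),
              class = "cycle_points")
  expect_equal(compute_parameters(mk_pts(0, 1, 10, 9, 10)),
               c(p1 = 1, p2 = 1, p3 = -1, p4 = 10))
  expect_equal(compute_parameters(mk_pts(7, 7, 7, 7, 7)),
               c(p1 = 0, p2 = 0, p3 = 0, p4 = 0))
  expect_equal(compute_parameters(mk_pts(2, 2, 2, 2, 5)),
               c(p1 = 0, p2 = 0, p3 = 0, p4 = 3))
  bad <- structure(list(t_a = 0, t_b = 0, t_c = 10, t_d = 11,
                        a = 1, b = 2, c = 3, d = 4, e = 5),
                   class = "cycle_points")
  expect_error(compute_parameters(bad), "coincident")
})

test_that("parameters are offset-invariant and scale linearly with amplitude", {
  sch <- acquisition_schedule()
  sig <- simulate_response(c(comp = 5), clean_channel(), sch, seed = 1)
  base <- compute_parameters(extract_cycle_points(sig, 60))
  shifted <- sig; shifted$values <- sig$values + 12.3
  expect_equal(compute_parameters(extract_cycle_points(shifted, 60)), base,
               tolerance = 1e-12)
  scaled <- sig; scaled$values <- sig$values * 2.5
  expect_equal(compute_parameters(extract_cycle_points(scaled, 60)),
               2.5 * base, tolerance = 1e-12)
})

test_that("feature extraction produces the expected observation counts", {
  ds <- default_dataset(seed = 1)
  one_chan <- ds$signals[vapply(ds$signals, `[[`, "", "channel_name") == "c18_np"]
  fm1 <- extract_features(one_chan, ds$metadata)
  expect_equal(dim(fm1$x), c(105, 4))
  expect_equal(sum(fm1$known), 96)
  fm <- extract_features(ds)
  expect_equal(dim(fm$x), c(105, 16))
  expect_equal(colnames(fm$x)[1:5],
               c("c18_np:p1", "c18_np:p2", "c18_np:p3", "c18_np:p4",
                 "phenyl_np:p1"))
  # one sample, four channels, three cycles
  meta1 <- ds$metadata[1, , drop = FALSE]
  sigs1 <- ds$signals[vapply(ds$signals, `[[`, "", "sample_name") == meta1$sample]
  fm3 <- extract_features(sigs1, meta1)
  expect_equal(dim(fm3$x), c(3, 16))
  # missing channel errors with the gap named
  expect_no_error(extract_features(one_chan, ds$metadata[1:2, ], t_a = 60))
  expect_error(extract_features(one_chan[-1], ds$metadata),
               ds$metadata$sample[1], fixed = TRUE)
})

test_that("permuting the requested cycle starts permutes the rows accordingly", {
  ds <- default_dataset(seed = 1)
  fm_abc <- extract_features(ds, t_a = c(60, 80, 100))
  fm_cba <- extract_features(ds, t_a = c(100, 80, 60))
  for (s in unique(fm_abc$sample)) {
    for (tt in c(60, 80, 100)) {
      expect_equal(fm_abc$x[fm_abc$sample == s & fm_abc$t_a == tt, ],
                   fm_cba$x[fm_cba$sample == s & fm_cba$t_a == tt, ])
    }
  }
})

test_that("normalization divides by the divisor-n training sd and is idempotent", {
  fm <- make_fm(cbind(c(0, 2, 0, 2), c(1, 2, 3, 4)), a = c(0, 1, 0, 1))
  nf <- normalize_features(fm, reference_rows = 1:4)
  # sd({0,2,0,2}) with divisor n is 1: column unchanged
  expect_equal(nf$x[, 1], c(0, 2, 0, 2))
  expect_equal(nf$normalization_sds[[1]], 1)
  # already-unit-sd column is unchanged on renormalisation
  nf2 <- normalize_features(make_fm(nf$x, a = nf$a), reference_rows = 1:4)
  expect_equal(nf2$x, nf$x)
  # random matrix: every column has unit sd over the reference rows
  set.seed(42)
  big <- make_fm(matrix(rnorm(96 * 16, sd = runif(16, 0.1, 9)[rep(1:16, each = 96)]),
                        96, 16), a = rnorm(96))
  nb <- normalize_features(big, reference_rows = 1:96)
  sds <- apply(nb$x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(sds, rep(1, 16), tolerance = 1e-9, ignore_attr = TRUE)
  # zero-variance column is reported by name
  cfm <- make_fm(cbind(`ch:p1` = c(1, 1, 1), `ch:p2` = c(1, 2, 3)),
                 a = 1:3)
  expect_error(normalize_features(cfm, reference_rows = 1:3), "ch:p1")
})
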