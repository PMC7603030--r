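test_that("ratio trace validates its inputs", {
  expect_error(ratio_trace(c(0, 1, 1), c(1, 1, 1)),
               class = "secrflux_input_error")      # non-increasing time
  expect_error(ratio_trace(0:2, c(1, -1, 1), basal_window_s = c(0, 2)),
               class = "secrflux_input_error")      # non-positive ratio
  expect_error(ratio_trace(0:2, c(1, 1, 1), basal_window_s = c(0, 5)),
               class = "secrflux_input_error")      # window beyond span
  tr <- ratio_trace(0:10, rep(1, 11), basal_window_s = c(0, 5))
  expect_s3_class(tr, "ratio_trace")
})

test_that("compute_ratio divides channels and names the bad sample", {
  tr <- compute_ratio(0:3, c(2, 4, 6, 8), c(2, 2, 2, 2),
                      basal_window_s = c(0, 1))
  expect_equal(tr$ratio, c(1, 2, 3, 4))
  err <- tryCatch(compute_ratio(0:3, rep(1, 4), c(1, 1, 0, 1),
                                basal_window_s = c(0, 1)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "index 3")
})

test_that("max ratio change = basal mean minus nearest endpoint sample", {
  tr <- ratio_trace(seq(0, 100, by = 10), c(rep(1, 4), seq(0.95, 0.6,
                                                           length.out = 7)),
                    basal_window_s = c(0, 30))
  mc <- max_ratio_change(tr, 100)
  expect_equal(mc$basal_mean, 1)
  expect_equal(mc$endpoint_value, 0.6)
  expect_equal(mc$change, 0.4)
  # endpoint snaps to the nearest sample and echoes the actual time
  mc2 <- max_ratio_change(tr, 97)
  expect_equal(mc2$endpoint_time_s, 100)
  expect_error(max_ratio_change(tr, 10), class = "secrflux_input_error")
  expect_error(max_ratio_change(tr, 101), class = "secrflux_input_error")
})

test_that("planted decline is recovered from a generated trace", {
  tr <- generate_ratio_trace(1.1, 0.7, n_points = 361, noise_sd = 0)
  mc <- max_ratio_change(tr, 3600)
  expect_equal(mc$change, 0.4, tolerance = 1e-9)
})

test_that("stimulus epochs report extrema against their reference", {
  time_s <- 0:100
  ratio <- rep(1, 101)
  ratio[41:60] <- 0.5       # trough during the stimulus epoch
  ratio[61:101] <- 0.9
  tr <- ratio_trace(time_s, ratio, basal_window_s = c(0, 30))
  ep <- data.frame(label = c("stim", "wash"), start_s = c(40, 60),
                   end_s = c(59, 100))
  sr <- stimulus_response(tr, ep)
  expect_equal(sr$min[1], 0.5)
  expect_equal(sr$reference[1], 1)       # last sample before the epoch
  expect_equal(sr$max_deviation[1], 0.5)
  expect_equal(sr$reference[2], 0.5)     # last sample before wash epoch
  expect_error(stimulus_response(tr, data.frame(label = "a", start_s = 50,
                                                end_s = 40)),
               class = "secrflux_input_error")
  expect_error(
    stimulus_response(tr, data.frame(label = c("a", "b"),
                                     start_s = c(10, 15),
                                     end_s = c(20, 25))),
    class = "secrflux_input_error")      # overlapping epochs
})

test_that("trace CSV round-trips exactly", {
  tr <- generate_ratio_trace(1.05, 0.66, n_points = 50, noise_sd = 0.01,
                             seed = 8)
  f <- tempfile(fileext = ".csv")
  write_ratio_trace(tr, f)
  tr2 <- read_ratio_trace(f, basal_window_s = tr$basal_window_s)
  expect_equal(tr2$ratio, tr$ratio, tolerance = 1e-12)
  expect_equal(tr2$time_s, tr$time_s)
})

test_that("read_ratio_trace derives the ratio from channel columns", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 0:9, donor = rep(2, 10),
                       acceptor = seq(2, 4, length.out = 10)),
            f, row.names = FALSE)
  tr <- read_ratio_trace(f, numerator = "acceptor", denominator = "donor",
                         basal_window_s = c(0, 5))
  expect_equal(tr$ratio, seq(1, 2, length.out = 10))
  expect_error(read_ratio_trace(f, basal_window_s = c(0, 5)),
               class = "secrflux_input_error")
})
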