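# random stream with a fixed component support, for property-style tests
random_stream <- function(temperature = stats::runif(1, 10, 90),
                          pressure = 1.01) {
  comps <- component_names()
  k <- sample(seq(2, length(comps)), 1)
  flows <- stats::setNames(stats::runif(k, 0.01, 100),
                           sample(comps, k))
  process_stream(temperature, pressure, flows)
}

expect_stream_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$flows, b$flows, tolerance = tol)
  expect_equal(a$temperature, b$temperature, tolerance = tol)
}
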