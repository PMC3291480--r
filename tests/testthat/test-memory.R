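test_that("encoding creates one chunk per experience kind and advances the clock", {
  m <- memory_store()
  m <- encode_event(m, "cache", 3L)
  expect_length(m$chunks, 1L)
  expect_identical(m$chunks[[1]]$use_steps, 0L)
  expect_identical(m$clock, 1L)

  # re-encoding the same experience updates the chunk, never duplicates it
  m2 <- encode_event(m, "cache", 3L)
  expect_length(m2$chunks, 1L)
  expect_identical(m2$chunks[[1]]$use_steps, c(0L, 1L))

  # a recovery at the same site is a different kind of experience
  m3 <- encode_event(m, "recovery", 3L, success = TRUE)
  expect_length(m3$chunks, 2L)

  # failed and successful recoveries at one site are distinct chunks
  m4 <- encode_event(m3, "recovery", 3L, success = FALSE)
  expect_length(m4$chunks, 3L)

  expect_error(encode_event(m, "cache", 3L, success = TRUE), "success")
  expect_error(encode_event(m, "recovery", 3L), "success")
})

test_that("after k encodings of one key there is exactly one chunk with k uses", {
  for (k in c(1L, 3L, 7L)) {
    m <- memory_store()
    for (i in seq_len(k)) m <- encode_event(m, "recovery", 5L, success = TRUE)
    expect_length(m$chunks, 1L)
    expect_length(m$chunks[[1]]$use_steps, k)
    expect_true(all(diff(m$chunks[[1]]$use_steps) > 0))
    expect_gte(m$clock, max(m$chunks[[1]]$use_steps))
  }
})

test_that("activation reproduces the base-level learning sum", {
  # one use, one step ago: ln(1^-d) = 0
  expect_equal(chunk_activation(list(use_steps = 0L), now = 1L, d = 0.2), 0)
  # uses at elapsed 1 and 2 steps
  expect_equal(chunk_activation(list(use_steps = c(0L, 1L)), now = 2L, d = 0.2),
               log(1 + 2^-0.2))
  # elapsed time is clamped at one step, so same-step evaluation is finite
  expect_true(is.finite(chunk_activation(list(use_steps = 4L), now = 4L, d = 0.2)))
})

test_that("activation agrees with the brute-force oracle on random stores", {
  set.seed(101)
  for (rep in 1:25) {
    store <- random_store()
    now <- store$clock + sample.int(10, 1)
    for (ch in store$chunks) {
      expect_equal(chunk_activation(ch, now, d = 0.2),
                   brute_activation(ch$use_steps, now, d = 0.2),
                   tolerance = 1e-12)
    }
  }
})

test_that("activation decays with time and grows with extra uses", {
  set.seed(7)
  ch <- list(use_steps = c(0L, 3L, 5L))
  acts <- vapply(6:40, function(now) chunk_activation(ch, now, 0.2), numeric(1))
  expect_true(all(diff(acts) <= 0))
  # adding a use never decreases activation at any later step
  ch2 <- list(use_steps = c(0L, 3L, 5L, 6L))
  for (now in 7:40) {
    expect_gte(chunk_activation(ch2, now, 0.2), chunk_activation(ch, now, 0.2))
  }
})

test_that("inhibition of return is non-positive, type-filtered and session-scoped", {
  m <- memory_store()
  expect_identical(inhibition_of_return(m, 1L, "cache", d = 0.2), 0)

  # a recovery chunk at the site does not inhibit caching there
  m <- encode_event(m, "recovery", 1L, success = TRUE)
  expect_identical(inhibition_of_return(m, 1L, "cache", d = 0.2), 0)
  expect_lt(inhibition_of_return(m, 1L, "recovery", d = 0.2), 0)

  # a cache chunk inhibits caching, strictly
  m <- encode_event(m, "cache", 1L)
  expect_lt(inhibition_of_return(m, 1L, "cache", d = 0.2), 0)

  # uses before the session start do not inhibit
  expect_identical(
    inhibition_of_return(m, 1L, "cache", d = 0.2, since_step = m$clock), 0)

  # non-positivity on random histories
  set.seed(33)
  for (rep in 1:20) {
    store <- random_store()
    for (s in 1:6) {
      expect_lte(inhibition_of_return(store, s, "cache", d = 0.3), 0)
      expect_lte(inhibition_of_return(store, s, "recovery", d = 0.3), 0)
    }
  }
})

test_that("stronger matching memories inhibit more", {
  m1 <- encode_event(memory_store(), "cache", 1L)
  m2 <- encode_event(m1, "cache", 1L)
  expect_lt(inhibition_of_return(m2, 1L, "cache", now = 3L, d = 0.2),
            inhibition_of_return(m1, 1L, "cache", now = 3L, d = 0.2))
})

test_that("transient noise is logistic with scale n, centered and symmetric", {
  expect_identical(transient_noise(0, 0.123), 0)
  expect_identical(transient_noise(0.3, 0.5), 0)
  expect_equal(transient_noise(0.3, 0.25), 0.3 * log(0.75 / 0.25))
  expect_error(transient_noise(0.3, 0), "between")
  expect_error(transient_noise(0.3, 1), "between")

  set.seed(202)
  r <- stats::runif(1e5)
  x <- transient_noise(0.3, r)
  se <- 0.3 * pi / sqrt(3) / sqrt(length(x))
  expect_lt(abs(mean(x)), 3 * se)
  # symmetry: sign test
  k <- sum(x > 0)
  expect_lt(abs(k - length(x) / 2), 3 * sqrt(length(x) / 4))
  # quartiles of logistic(0, n): +/- n*log(3)
  expect_equal(unname(stats::quantile(x, 0.75)), 0.3 * log(3), tolerance = 0.02)
})

test_that("memory serializes to a plain chunk-key -> use-steps list", {
  m <- encode_event(memory_store(), "cache", 2L)
  m <- encode_event(m, "recovery", 2L, success = FALSE)
  l <- memory_as_list(m)
  expect_identical(l$clock, 2L)
  expect_named(l$chunks, c("cache:2", "recovery:2:u"))
  expect_no_error(jsonlite::toJSON(l))
})
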