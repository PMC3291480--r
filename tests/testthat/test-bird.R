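params0 <- bird_params(n = 0)   # noise off: decisions are deterministic
w2 <- make_world(c("near", "far"))

test_that("onlooker aversion applies only to near-tray sites under ranked onlookers", {
  p <- bird_params()
  near_site <- tray_sites(w2, 1L)[1]
  far_site <- tray_sites(w2, 2L)[1]
  ctx_d <- onlooker_context("dominant", near_tray_id = 1L)
  ctx_s <- onlooker_context("subordinate", near_tray_id = 1L)
  expect_equal(onlooker_aversion(near_site, w2, ctx_d, p), -1.25)
  expect_equal(onlooker_aversion(near_site, w2, ctx_s, p), -0.5)
  expect_equal(onlooker_aversion(far_site, w2, ctx_d, p), 0)
  expect_equal(onlooker_aversion(far_site, w2, ctx_s, p), 0)
  expect_equal(onlooker_aversion(near_site, w2, onlooker_context("none"), p), 0)
  expect_equal(onlooker_aversion(near_site, w2, onlooker_context("observer"), p), 0)
})

test_that("cache attractiveness is zero on a fresh store and negative after caching", {
  ctx <- onlooker_context("none")
  m <- memory_store()
  for (s in tray_sites(w2, 1L)) {
    expect_equal(cache_attractiveness(s, m, w2, ctx, params0), 0)
  }
  m <- encode_event(m, "cache", 1L)
  expect_lt(cache_attractiveness(1L, m, w2, ctx, params0), 0)
})

test_that("with a dominant onlooker and no noise the far tray is always chosen", {
  ctx <- onlooker_context("dominant", near_tray_id = 1L)
  set.seed(1)
  for (i in 1:10) {
    s <- choose_cache_site(tray_sites(w2, c(1L, 2L)), memory_store(), w2,
                           ctx, params0)
    expect_true(s %in% tray_sites(w2, 2L))
  }
})

test_that("site choice is the argmax and avoids inhibited sites", {
  ctx <- onlooker_context("none")
  expect_identical(
    choose_cache_site(5L, memory_store(), w2, ctx, params0), 5L)
  expect_error(choose_cache_site(integer(0), memory_store(), w2, ctx, params0))

  m <- encode_event(memory_store(), "cache", 2L)
  set.seed(2)
  for (i in 1:10) {
    expect_false(choose_cache_site(1:4, m, w2, ctx, params0) == 2L)
  }
})

test_that("noise-free repeated caching disperses over sites instead of stacking", {
  ctx <- onlooker_context("none")
  m <- memory_store()
  set.seed(3)
  chosen <- integer(0)
  sites <- tray_sites(w2, 1L)
  for (i in 1:8) {
    s <- choose_cache_site(sites, m, w2, ctx, params0)
    chosen <- c(chosen, s)
    m <- encode_event(m, "cache", s)
  }
  expect_length(unique(chosen), 8L)
})

test_that("cache relocation effect tracks the strength of the cache memory", {
  p <- bird_params()
  m <- memory_store()
  expect_equal(cache_relocation(9L, m, params = p), 0)
  m <- encode_event(m, "cache", 9L)
  # one cache, one step ago: activation ln(1) = 0, strength 1
  expect_equal(chunk_activation(m$chunks[["cache:9"]], m$clock, p$d), 0)
  expect_equal(cache_relocation(9L, m, params = p), 1)
  # twice-cached beats once-cached at equal recency
  m2 <- encode_event(memory_store(), "cache", 1L)
  m2 <- encode_event(m2, "cache", 1L)
  m2 <- encode_event(m2, "cache", 2L)
  expect_gt(cache_relocation(1L, m2, params = p),
            cache_relocation(2L, m2, params = p))
})

test_that("recovery attractiveness favors cached sites and suppresses revisits", {
  m <- memory_store()
  for (s in 1:4) expect_equal(recovery_attractiveness(s, m, params0), 0)
  m <- encode_event(m, "cache", 2L)
  set.seed(4)
  expect_identical(choose_recovery_site(1:6, m, params0), 2L)
  # an already-recovered cached site ranks below an unrecovered cached site
  m <- encode_event(m, "cache", 3L)
  m <- encode_event(m, "recovery", 2L, success = TRUE)
  expect_lt(recovery_attractiveness(2L, m, params0, noise = 0),
            recovery_attractiveness(3L, m, params0, noise = 0))
})

test_that("immediate re-cache odds follow the onlooker and are capped", {
  p <- bird_params()
  expect_equal(recache_odds(onlooker_context("none"), p), 0)
  expect_equal(recache_odds(onlooker_context("observer"), p), 0.6)
  expect_equal(recache_odds(onlooker_context("dominant"), p), 0.8)
  expect_equal(recache_odds(onlooker_context("subordinate"), p), 0.4)

  set.seed(5)
  expect_false(any(vapply(1:50, function(i) {
    maybe_immediate_recache(onlooker_context("none"), p)
  }, logical(1))))

  # degenerate odds: the chain cap guards nontermination
  p1 <- bird_params(cr_w = 1)
  expect_false(maybe_immediate_recache(onlooker_context("observer"), p1,
                                       chain = p1$recache_cap))
  expect_true(maybe_immediate_recache(onlooker_context("observer"), p1,
                                      chain = 0L))

  # empirical frequency tracks cr_w
  set.seed(6)
  hits <- mean(vapply(1:2000, function(i) {
    maybe_immediate_recache(onlooker_context("observer"), p)
  }, logical(1)))
  expect_lt(abs(hits - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))
})

test_that("safety risk is a normalized failure ratio over qualifying sites", {
  p <- bird_params()
  m <- memory_store()
  expect_equal(safety_risk(m, 1:4, p), 0)

  # only successes: no risk
  m <- encode_event(m, "recovery", 1L, success = TRUE)
  m <- encode_event(m, "recovery", 2L, success = TRUE)
  expect_equal(safety_risk(m, 1:4, p), 0)

  # one failure and one success at equal recency: one half
  m2 <- memory_store()
  m2$chunks <- list()
  m2 <- encode_event(m2, "recovery", 1L, success = TRUE)
  m2 <- encode_event(m2, "recovery", 2L, success = FALSE)
  m2$chunks[["recovery:1:s"]]$use_steps <- 5L
  m2$chunks[["recovery:2:u"]]$use_steps <- 5L
  m2$clock <- 6L
  expect_equal(safety_risk(m2, 1:2, p), 0.5)

  # only recovery experiences at qualifying sites count
  expect_equal(safety_risk(m2, 3:4, p), 0)
  expect_equal(safety_risk(m2, 2L, p), 1)

  # uses before since_step are ignored
  expect_equal(safety_risk(m2, 1:2, p, since_step = 6L), 0)

  # bounds on arbitrary histories
  set.seed(44)
  for (rep in 1:20) {
    store <- random_store(30)
    S <- safety_risk(store, 1:6, p)
    expect_gte(S, 0)
    expect_lte(S, 1)
  }
})

test_that("the stress decision is a strict threshold", {
  expect_true(decide_recache(0.7, 0.6))
  expect_false(decide_recache(0.6, 0.6))
  expect_false(decide_recache(1, 1))
  expect_error(decide_recache(1.2, 0.6))
})

test_that("parameter validation enforces the documented bounds", {
  expect_error(bird_params(d = 0))
  expect_error(bird_params(d = 1))
  expect_error(bird_params(n = -0.1))
  expect_error(bird_params(st = 1.5))
  expect_error(bird_params(oa_d = -0.1, oa_s = -0.5))  # oa_d <= oa_s
  expect_error(bird_params(oa_s = 0.2))
  expect_error(bird_params(cr_w = 1.2))
  d <- bird_params()
  expect_equal(
    unlist(d[c("d", "n", "st", "oa_d", "oa_s", "cr_w", "cr_d", "cr_s")]),
    c(d = 0.2, n = 0.3, st = 0.6, oa_d = -1.25, oa_s = -0.5,
      cr_w = 0.6, cr_d = 0.8, cr_s = 0.4))
})
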