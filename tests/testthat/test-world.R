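test_that("worlds have unique sites on per-tray grids", {
  w <- make_world(c("near", "far"), rows = 2, cols = 8)
  expect_equal(nrow(w$sites), 32L)
  expect_false(any(duplicated(w$sites$site_id)))
  expect_equal(w$trays$distance_class, c("near", "far"))
  expect_error(make_world("middle"))
  expect_error(make_world("near", rows = 0))
})

test_that("experiment designs build the documented session plans", {
  p1 <- build_world("exp1a")
  expect_length(p1$trials, 6L)
  expect_equal(vapply(p1$trials, `[[`, "", "condition"),
               rep(c("watched", "private"), 3))
  expect_true(all(vapply(p1$trials, function(t) nrow(t$world$trays), 0L) == 1L))
  expect_equal(p1$n_caches, 8L)

  p1b <- build_world("exp1b")
  expect_length(p1b$trials, 2L)
  expect_equal(p1b$trials[[1]]$recovery_trays, c(1L, 2L))
  expect_length(p1b$trials[[1]]$caching_phases, 2L)
  # phase order is counterbalanced across the two trials
  expect_equal(p1b$trials[[1]]$caching_phases[[1]]$trays, 1L)
  expect_equal(p1b$trials[[2]]$caching_phases[[1]]$trays, 2L)

  p2 <- build_world("exp2")
  expect_length(p2$trials, 3L)
  expect_equal(vapply(p2$trials, `[[`, "", "condition"),
               c("dominant", "subordinate", "private"))
  expect_equal(p2$trials[[1]]$world$trays$distance_class, c("near", "far"))
  expect_equal(p2$trials[[1]]$caching_phases[[1]]$context$near_tray_id, 1L)
  expect_true(is.na(p2$trials[[3]]$caching_phases[[1]]$context$near_tray_id))
  expect_equal(p2$n_caches, 17L)

  expect_error(build_world("exp3"))
})

test_that("qualifying sites are cached sites plus same-tray grid neighbors", {
  w <- make_world("neutral", rows = 2, cols = 8)
  expect_identical(qualifying_sites(w, 1L), integer(0))
  # cache in the corner site (row 1, col 1)
  corner <- w$sites$site_id[w$sites$row == 1 & w$sites$col == 1]
  w$actually_cached[corner] <- TRUE
  qs <- qualifying_sites(w, 1L)
  expected <- w$sites$site_id[w$sites$row <= 2 & w$sites$col <= 2]
  expect_setequal(qs, expected)
})

test_that("a private caching session makes exactly n_caches caches and no recoveries", {
  p <- bird_params()
  w <- make_world("neutral")
  set.seed(10)
  res <- run_caching_session(memory_store(), w, 1L,
                             onlooker_context("none"), 5L, p)
  expect_equal(sum(res$log$action == "cache"), 5L)
  expect_equal(sum(res$log$action == "recover_success"), 0L)
  expect_equal(sum(res$world$worms_at), 5L)
  expect_identical(check_conservation(res$world), TRUE)
})

test_that("a watched caching session immediately recovers some caches, all successfully", {
  p <- bird_params()
  w <- make_world("neutral")
  set.seed(11)
  res <- run_caching_session(memory_store(), w, 1L,
                             onlooker_context("observer"), 8L, p)
  expect_gte(nrow(as.data.frame(res$log)), 8L)
  expect_gt(sum(res$log$action == "recache_immediate"), 0L)
  # every caching-session recovery is a pickup of a just-made cache
  expect_equal(sum(res$log$action == "recover_success"),
               sum(res$log$action == "recache_immediate"))
  expect_equal(sum(res$world$worms_at), 8L)
})

test_that("a deterministic unstressed bird recovers exactly where it cached", {
  p <- bird_params(n = 0, cr_w = 0, cr_d = 0, cr_s = 0, st = 1)
  plan <- build_world("exp1a")
  set.seed(12)
  res <- run_trial(plan$trials[[1]], 8L, p, engine = "r")
  lg <- res$log
  cached <- lg$site[lg$action == "cache"]
  recovered <- lg$site[lg$action == "recover_success"]
  expect_setequal(recovered, cached)
  expect_equal(sum(lg$action == "recover_fail"), 0L)
  expect_equal(sum(lg$action == "recache_recovery"), 0L)
  expect_equal(res$world$eaten, 8L)
})

test_that("memory/world divergence is the only source of recovery failures", {
  # with no immediate re-caching and no noise, zero failures in any design
  p <- bird_params(n = 0, cr_w = 0, cr_d = 0, cr_s = 0)
  for (design in c("exp1a", "exp1b", "exp2")) {
    plan <- build_world(design)
    set.seed(13)
    for (trial in plan$trials[1:2]) {
      res <- run_trial(trial, plan$n_caches, p, engine = "cpp")
      expect_equal(sum(res$log$action == "recover_fail"), 0L)
    }
  }
})

test_that("worms are conserved under randomized parameters (fuzz)", {
  set.seed(14)
  for (rep in 1:15) {
    p <- bird_params(
      d = stats::runif(1, 0.05, 0.95),
      n = stats::runif(1, 0, 1),
      st = stats::runif(1, 0, 1),
      oa_d = -stats::runif(1, 1, 2),
      oa_s = -stats::runif(1, 0, 1),
      cr_w = stats::runif(1),
      cr_d = stats::runif(1),
      cr_s = stats::runif(1)
    )
    design <- sample(c("exp1a", "exp1b", "exp2"), 1)
    plan <- build_world(design)
    trial <- plan$trials[[sample(length(plan$trials), 1)]]
    res <- run_trial(trial, plan$n_caches, p, engine = "r")
    # the R engine asserts conservation after every event; re-check finals
    w <- res$world
    expect_equal(w$worms_given, sum(w$worms_at) + w$out_of_tray + w$eaten)
    if (!res$flagged) {
      # all caches end up recovered (eaten) or re-cached out of tray
      expect_equal(sum(w$worms_at), 0L)
      lg <- res$log
      expect_equal(sum(lg$action == "recache_recovery") + w$eaten,
                   sum(lg$action %in% c("cache")))
    }
  }
})

test_that("the recovery circuit breaker flags pathological sessions", {
  # a memory full of phantom caches with zero noise: the bird insists on
  # revisiting stale sites; the session still terminates (inhibition decays
  # choices away eventually) or is flagged, never hangs
  p <- bird_params(n = 0, st = 1)
  w <- make_world("neutral", rows = 1, cols = 2)
  store <- memory_store()
  for (i in 1:30) store <- encode_event(store, "cache", 1L)
  w$worms_at[2] <- 1L
  w$worms_given <- 1L
  w$actually_cached[2] <- TRUE
  res <- run_recovery_session(store, w, 1L, p)
  expect_true(res$flagged || sum(res$world$worms_at) == 0L)
})
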