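# Bridge between the session plans and the compiled engine.

action_names <- c("cache", "recache_immediate", "recover_success",
                  "recover_fail", "recache_recovery")
session_names <- c("caching", "recovery")

events_from_store <- function(store) {
  if (length(store$chunks) == 0L) {
    return(list(type = integer(0), site = integer(0),
                succ = integer(0), step = integer(0)))
  }
  rows <- do.call(rbind, lapply(store$chunks, function(ch) {
    data.frame(
      type = if (ch$event_type == "cache") 0L else 1L,
      site = ch$site_id,
      succ = if (isTRUE(ch$success)) 1L else 0L,
      step = ch$use_steps
    )
  }))
  rows <- rows[order(rows$step), , drop = FALSE]
  list(type = rows$type, site = rows$site, succ = rows$succ, step = rows$step)
}

store_from_events <- function(type, site, succ, step, clock) {
  store <- memory_store()
  o <- order(step)
  for (i in o) {
    key <- if (type[i] == 0L) chunk_key("cache", site[i])
           else chunk_key("recovery", site[i], succ[i] == 1L)
    ch <- store$chunks[[key]]
    if (is.null(ch)) {
      ch <- list(
        event_type = if (type[i] == 0L) "cache" else "recovery",
        site_id = as.integer(site[i]),
        success = if (type[i] == 1L) succ[i] == 1L else NULL,
        use_steps = integer(0)
      )
    }
    ch$use_steps <- c(ch$use_steps, as.integer(step[i]))
    store$chunks[[key]] <- ch
  }
  store$clock <- as.integer(clock)
  store
}

run_trial_cpp <- function(trial, n_caches, params, store = memory_store(),
                          want_store = FALSE, want_log = TRUE) {
  world <- trial$world
  phases <- lapply(trial$caching_phases, function(ph) {
    ctx <- ph$context
    oa <- switch(ctx$rank, dominant = params$oa_d,
                 subordinate = params$oa_s, 0)
    list(sites = as.integer(tray_sites(world, ph$trays)),
         oa = as.numeric(oa),
         near_tray = if (is.na(ctx$near_tray_id)) 0L else ctx$near_tray_id,
         cr = as.numeric(recache_odds(ctx, params)))
  })
  init <- events_from_store(store)
  out <- cpp_run_trial(
    site_tray = as.integer(world$sites$tray_id),
    site_row = as.integer(world$sites$row),
    site_col = as.integer(world$sites$col),
    phases = phases,
    recovery_sites = as.integer(tray_sites(world, trial$recovery_trays)),
    n_caches = as.integer(n_caches),
    par = list(d = params$d, n = params$n, st = params$st,
               recache_cap = params$recache_cap,
               risk_session = params$risk_scope == "session"),
    init_type = as.integer(init$type), init_site = as.integer(init$site),
    init_succ = as.integer(init$succ), init_step = as.integer(init$step),
    init_clock = as.integer(store$clock)
  )
  world$worms_at <- out$worms_at
  world$actually_cached <- tabulate(
    out$ev_site[out$ev_type == 0L], nbins = nrow(world$sites)) > 0
  world$out_of_tray <- out$out_of_tray
  world$eaten <- out$eaten
  world$worms_given <- out$worms_given
  lg <- if (want_log) {
    data.frame(
      step = out$log_step,
      session = session_names[out$log_session + 1L],
      action = action_names[out$log_action + 1L],
      tray = out$log_tray,
      site = out$log_site,
      stringsAsFactors = FALSE
    )
  }
  list(log = lg, world = world,
       counts = list(initial = out$ct_initial, placements = out$ct_place,
                     immediate = out$ct_imm, fail = out$ct_fail,
                     recached = out$ct_recached),
       store = if (want_store) {
         store_from_events(out$ev_type, out$ev_site, out$ev_succ,
                           out$ev_step, out$clock)
       },
       flagged = out$flagged)
}
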