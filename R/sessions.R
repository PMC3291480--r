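# R reference implementation of the session engines. Built directly on the
# exported memory/decision operations; used for unit tests and as the
# behavioral oracle for the compiled engine (both consume the RNG stream in
# the same order, so logs must agree exactly under a common seed).

new_log <- function() {
  list(step = integer(0), session = character(0), action = character(0),
       tray = integer(0), site = integer(0))
}

log_add <- function(lg, step, session, action, tray, site) {
  lg$step <- c(lg$step, step)
  lg$session <- c(lg$session, session)
  lg$action <- c(lg$action, action)
  lg$tray <- c(lg$tray, tray)
  lg$site <- c(lg$site, site)
  lg
}

#' Run one caching session (R reference engine)
#'
#' The bird makes `n_caches` caches. Each decision evaluates all offered
#' sites and takes the one with the highest cache attractiveness. While
#' watched, every completed cache has a chance (set by the onlooker's
#' rank) of being immediately recovered and cached again — the
#' replacement cache is itself subject to the same rule, up to
#' `params$recache_cap` times per worm. Every cache and recovery event is
#' encoded in memory and advances the model clock by one step.
#'
#' @param store A [memory_store()].
#' @param world A [make_world()] object.
#' @param offered_trays Tray ids the bird may cache in.
#' @param context An [onlooker_context()].
#' @param n_caches Number of worms given to the bird.
#' @param params A [bird_params()].
#' @param session_start Step at which the caching session began (for the
#'   within-session scope of inhibition of return); defaults to the store
#'   clock at entry.
#' @return A list with the updated `store`, `world`, and an event `log`
#'   (data-frame-able list with step, session, action, tray, site).
#' @export
run_caching_session <- function(store, world, offered_trays, context,
                                n_caches, params,
                                session_start = store$clock) {
  offered <- tray_sites(world, offered_trays)
  stopifnot(length(offered) >= 1L, n_caches >= 1L)
  lg <- new_log()
  tray_of <- world$sites$tray_id
  for (worm in seq_len(n_caches)) {
    world$worms_given <- world$worms_given + 1L
    chain <- 0L
    repeat {
      site <- choose_cache_site(offered, store, world, context, params,
                                session_start = session_start)
      world$worms_at[site] <- world$worms_at[site] + 1L
      world$actually_cached[site] <- TRUE
      lg <- log_add(lg, store$clock, "caching",
                    if (chain == 0L) "cache" else "recache_immediate",
                    tray_of[site], site)
      store <- encode_event(store, "cache", site)
      if (maybe_immediate_recache(context, params, chain)) {
        world$worms_at[site] <- world$worms_at[site] - 1L
        lg <- log_add(lg, store$clock, "caching", "recover_success",
                      tray_of[site], site)
        store <- encode_event(store, "recovery", site, success = TRUE)
        chain <- chain + 1L
        next
      }
      break
    }
    check_conservation(world)
  }
  list(store = store, world = world, log = lg)
}

#' Run one recovery session (R reference engine)
#'
#' The bird keeps choosing the offered site with the highest recovery
#' attractiveness until all worms in the offered trays are recovered.
#' Probing a site that holds no worm encodes an unsuccessful recovery.
#' Finding a worm encodes a successful recovery; the bird then assesses
#' the safety risk of that tray (over recovery experiences at its actual
#' cache sites or their neighbors) and, if the risk exceeds the stress
#' threshold, re-caches the worm in an out-of-tray location, where it is
#' never recovered again. A circuit breaker (50 steps per offered site)
#' guards against nontermination; a tripped run is flagged.
#'
#' @inheritParams run_caching_session
#' @param offered_trays Tray ids returned to the bird.
#' @return A list with updated `store`, `world`, event `log`, and
#'   `flagged` (circuit breaker tripped).
#' @export
run_recovery_session <- function(store, world, offered_trays, params) {
  offered <- tray_sites(world, offered_trays)
  stopifnot(length(offered) >= 1L)
  lg <- new_log()
  tray_of <- world$sites$tray_id
  session_start <- store$clock
  since <- if (params$risk_scope == "session") session_start else 0L
  breaker <- 50L * length(offered)
  steps <- 0L
  flagged <- FALSE
  while (sum(world$worms_at[offered]) > 0L) {
    steps <- steps + 1L
    if (steps > breaker) {
      flagged <- TRUE
      break
    }
    site <- choose_recovery_site(offered, store, params,
                                 session_start = session_start)
    if (world$worms_at[site] > 0L) {
      world$worms_at[site] <- world$worms_at[site] - 1L
      lg <- log_add(lg, store$clock, "recovery", "recover_success",
                    tray_of[site], site)
      store <- encode_event(store, "recovery", site, success = TRUE)
      qs <- qualifying_sites(world, tray_of[site])
      S <- safety_risk(store, qs, params, now = store$clock, since_step = since)
      if (decide_recache(S, params$st)) {
        world$out_of_tray <- world$out_of_tray + 1L
        lg <- log_add(lg, store$clock - 1L, "recovery", "recache_recovery",
                      tray_of[site], site)
      } else {
        world$eaten <- world$eaten + 1L
      }
    } else {
      lg <- log_add(lg, store$clock, "recovery", "recover_fail",
                    tray_of[site], site)
      store <- encode_event(store, "recovery", site, success = FALSE)
    }
    check_conservation(world)
  }
  list(store = store, world = world, log = lg, flagged = flagged)
}

#' Run one full trial (caching phase(s) + recovery session)
#'
#' @param trial One element of `build_world()$trials`.
#' @param n_caches Worms per caching phase.
#' @param params A [bird_params()].
#' @param store Initial memory (default: fresh).
#' @param engine `"cpp"` (compiled, fast) or `"r"` (reference).
#' @param want_store Reconstruct the final [memory_store()]? (Always
#'   available from the R engine; skipped by default for the compiled
#'   engine to keep replicate harnesses fast.)
#' @return A list with the event `log` (data.frame), final `world`,
#'   final `store` (`NULL` from the compiled engine unless
#'   `want_store = TRUE`), and `flagged`.
#' @export
run_trial <- function(trial, n_caches, params, store = memory_store(),
                      engine = c("cpp", "r"), want_store = FALSE,
                      want_log = TRUE) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    return(run_trial_cpp(trial, n_caches, params, store, want_store, want_log))
  }
  world <- trial$world
  logs <- list()
  caching_start <- store$clock
  for (ph in trial$caching_phases) {
    res <- run_caching_session(store, world, ph$trays, ph$context,
                               n_caches, params,
                               session_start = caching_start)
    store <- res$store
    world <- res$world
    logs[[length(logs) + 1L]] <- res$log
  }
  res <- run_recovery_session(store, world, trial$recovery_trays, params)
  store <- res$store
  world <- res$world
  logs[[length(logs) + 1L]] <- res$log
  lg <- do.call(rbind, lapply(logs, as.data.frame, stringsAsFactors = FALSE))
  list(log = lg, world = world, store = store, flagged = res$flagged)
}
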