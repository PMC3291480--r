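#' Onlooker aversion of a site
#'
#' A previously learned preference for caching far away from conspecifics,
#' incorporated directly into the model: sites in the tray nearest a
#' dominant onlooker carry bias `oa_d`, sites in the tray nearest a
#' subordinate onlooker carry `oa_s`, and every other site (far tray,
#' unspecified-rank onlooker, or in private) carries `0`.
#'
#' @param site_id Integer site identifier.
#' @param world A world from [build_world()] (or any list with a `sites`
#'   data frame mapping `site_id` to `tray_id`).
#' @param context An [onlooker_context()].
#' @param params A [bird_params()].
#' @return One of `oa_d`, `oa_s` or `0`.
#' @export
onlooker_aversion <- function(site_id, world, context, params) {
  if (is.na(context$near_tray_id)) return(0)
  tray <- world$sites$tray_id[match(site_id, world$sites$site_id)]
  if (is.na(tray) || tray != context$near_tray_id) return(0)
  switch(context$rank,
         dominant = params$oa_d,
         subordinate = params$oa_s,
         0)
}

draw_noise <- function(n) {
  if (n == 0) return(0)
  r <- stats::runif(1)
  while (r <= 0 || r >= 1) r <- stats::runif(1)
  n * log((1 - r) / r)
}

#' Cache attractiveness of a site
#'
#' During caching sessions the bird repeatedly chooses the offered tray
#' section with the highest cache attractiveness
#' \deqn{C_k = O_k + I_k + noise}
#' where \eqn{O_k} is the onlooker aversion, \eqn{I_k} the inhibition of
#' return over cache chunks at the site, and *noise* a fresh logistic
#' draw per site per decision.
#'
#' @inheritParams onlooker_aversion
#' @param store A [memory_store()].
#' @param noise Optional fixed noise value (for analysis); if `NULL`, one
#'   fresh draw is taken.
#' @param session_start Step at which the current caching session began;
#'   only uses since then inhibit (see [inhibition_of_return()]).
#' @return The attractiveness value.
#' @export
cache_attractiveness <- function(site_id, store, world, context, params,
                                 noise = NULL, session_start = 0L) {
  if (is.null(noise)) noise <- draw_noise(params$n)
  onlooker_aversion(site_id, world, context, params) +
    inhibition_of_return(store, site_id, "cache", store$clock, params$d,
                         session_start) +
    noise
}

argmax_with_ties <- function(util, ids) {
  m <- max(util)
  ties <- ids[util == m]
  if (length(ties) == 1L) return(ties[1L])
  u <- stats::runif(1)
  ties[min(floor(u * length(ties)) + 1L, length(ties))]
}

#' Choose where to cache
#'
#' Evaluates the cache attractiveness of every offered site (one fresh
#' noise draw per site) and returns the argmax; exact ties are broken
#' uniformly at random.
#'
#' @param offered_sites Non-empty integer vector of candidate site ids,
#'   evaluated in the given order.
#' @inheritParams cache_attractiveness
#' @return The chosen site id.
#' @export
choose_cache_site <- function(offered_sites, store, world, context, params,
                              session_start = 0L) {
  stopifnot(length(offered_sites) >= 1L)
  util <- vapply(offered_sites, function(s) {
    cache_attractiveness(s, store, world, context, params,
                         session_start = session_start)
  }, numeric(1))
  argmax_with_ties(util, offered_sites)
}

#' Cache relocation effect of a site
#'
#' The pull toward recovering where the memory of having cached is
#' strong: the memory strength (exponentiated base-level activation) of
#' the site's cache chunk, or `0` if the bird has never cached there.
#'
#' @inheritParams cache_attractiveness
#' @param now Current step; defaults to the store clock.
#' @return A non-negative real number.
#' @export
cache_relocation <- function(site_id, store, now = store$clock, params) {
  ch <- store$chunks[[chunk_key("cache", site_id)]]
  if (is.null(ch)) return(0)
  chunk_strength(ch, now, params$d)
}

#' Recovery attractiveness of a site
#'
#' During recovery sessions the bird chooses the offered site with the
#' highest recovery attractiveness
#' \deqn{R_k = F_k + I_k + noise}
#' where \eqn{F_k} is the cache relocation effect and \eqn{I_k} the
#' inhibition of return over *recovery* chunks at the site (successful or
#' not).
#'
#' @inheritParams cache_relocation
#' @param noise Optional fixed noise value; if `NULL`, one fresh draw.
#' @param session_start Step at which the current recovery session began;
#'   only recovery uses since then inhibit (the cache relocation pull, by
#'   contrast, spans the whole memory).
#' @return The attractiveness value.
#' @export
recovery_attractiveness <- function(site_id, store, params, noise = NULL,
                                    session_start = 0L) {
  if (is.null(noise)) noise <- draw_noise(params$n)
  cache_relocation(site_id, store, store$clock, params) +
    inhibition_of_return(store, site_id, "recovery", store$clock, params$d,
                         session_start) +
    noise
}

#' Choose where to recover
#'
#' @inheritParams choose_cache_site
#' @return The chosen site id.
#' @export
choose_recovery_site <- function(offered_sites, store, params,
                                 session_start = 0L) {
  stopifnot(length(offered_sites) >= 1L)
  util <- vapply(offered_sites, function(s) {
    recovery_attractiveness(s, store, params, session_start = session_start)
  }, numeric(1))
  argmax_with_ties(util, offered_sites)
}

#' Whether the bird would immediately re-cache a just-made cache
#'
#' While watched, a bird that has just cached has a chance — `cr_w`,
#' `cr_d` or `cr_s` depending on the onlooker — of immediately recovering
#' the worm and caching it elsewhere; in private the chance is zero. The
#' replacement cache is itself subject to the same rule (geometric
#' chaining), bounded by `params$recache_cap` per worm.
#'
#' @param context An [onlooker_context()].
#' @param params A [bird_params()].
#' @param chain Number of immediate re-caches this worm has already
#'   undergone in this session.
#' @return `TRUE` or `FALSE`.
#' @export
maybe_immediate_recache <- function(context, params, chain = 0L) {
  cr <- recache_odds(context, params)
  if (cr <= 0 || chain >= params$recache_cap) return(FALSE)
  stats::runif(1) < cr
}

#' Safety risk of a tray
#'
#' After finding a worm, the bird assesses how risky the tray feels: the
#' ratio of the total memory strength of *unsuccessful* recovery
#' experiences to that of all recovery experiences,
#' \deqn{S_k = \frac{A_u}{A_u + A_s}}
#' restricted to recovery experiences directed at its actual cache sites
#' or their lateral neighbors within the tray (strengths are the
#' exponentiated base-level activations at the decision step). When no
#' qualifying recovery experience exists the risk is `0` — no evidence of
#' danger yet.
#'
#' @param store A [memory_store()].
#' @param qualifying_sites Integer vector of sites in the tray whose
#'   recovery experiences count (see [qualifying_sites()]).
#' @param params A [bird_params()].
#' @param now Current step; defaults to the store clock.
#' @param since_step Only recovery uses at steps `>= since_step` count;
#'   the session engines pass the recovery-session start when
#'   `params$risk_scope == "session"`.
#' @return A value in `[0, 1]`.
#' @export
safety_risk <- function(store, qualifying_sites, params,
                        now = store$clock, since_step = 0L) {
  a_u <- 0
  a_s <- 0
  for (s in qualifying_sites) {
    for (succ in c(TRUE, FALSE)) {
      ch <- store$chunks[[chunk_key("recovery", s, succ)]]
      if (is.null(ch)) next
      uses <- ch$use_steps[ch$use_steps >= since_step]
      if (length(uses) == 0L) next
      w <- sum(pmax(now - uses, 1)^(-params$d))
      if (succ) a_s <- a_s + w else a_u <- a_u + w
    }
  }
  if (a_u + a_s <= 0) return(0)
  a_u / (a_u + a_s)
}

#' Stress decision: re-cache a just-recovered worm?
#'
#' The bird re-caches if the safety risk strictly exceeds the stress
#' threshold.
#'
#' @param S Safety risk in `[0, 1]`.
#' @param st Stress threshold in `[0, 1]`.
#' @return `TRUE` if `S > st`.
#' @export
decide_recache <- function(S, st) {
  stopifnot(S >= 0, S <= 1)
  S > st
}
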