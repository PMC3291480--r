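#' Virtual-bird model parameters
#'
#' All tunable quantities of the cognitive model, with defaults at the
#' model's operating point. Three parameters are "free" (tuned once,
#' shared across experiments): the memory decay `d`, the noise scale `n`,
#' and the stress threshold `st`. The remainder are fixed settings of the
#' behavioral rules.
#'
#' @param d Memory decay, `0 < d < 1`. Default `0.2`.
#' @param n Transient-noise scale, `n >= 0`. Default `0.3`.
#' @param st Stress threshold in `[0, 1]` above which a recovering bird
#'   re-caches the worm it just found. Default `0.6`.
#' @param oa_d Onlooker aversion for sites in the near tray when watched
#'   by a dominant onlooker (a learned negative bias). Default `-1.25`.
#' @param oa_s Onlooker aversion for near-tray sites with a subordinate
#'   onlooker. Default `-0.5`. Must satisfy `oa_d <= oa_s <= 0`.
#' @param cr_w Odds of immediately re-caching a just-made cache when
#'   watched by an onlooker of unspecified rank. Default `0.6`.
#' @param cr_d Immediate-recache odds with a dominant onlooker. Default `0.8`.
#' @param cr_s Immediate-recache odds with a subordinate onlooker. Default `0.4`.
#' @param recache_cap Hard cap on the number of immediate re-caches of a
#'   single worm within a caching session (nontermination guard for
#'   degenerate odds). Default `10`.
#' @param risk_scope Which recovery experiences enter the safety-risk
#'   ratio: `"session"` (default) restricts it to recovery events of the
#'   current recovery session; `"all"` also counts immediate recoveries
#'   made during earlier caching sessions. See the methods vignette.
#' @return A validated list of class `bird_params`.
#' @export
#' @examples
#' p <- bird_params()            # operating point
#' p2 <- bird_params(st = 1)     # a bird that never re-caches at recovery
bird_params <- function(d = 0.2, n = 0.3, st = 0.6,
                        oa_d = -1.25, oa_s = -0.5,
                        cr_w = 0.6, cr_d = 0.8, cr_s = 0.4,
                        recache_cap = 10L,
                        risk_scope = c("session", "all")) {
  risk_scope <- match.arg(risk_scope)
  p <- list(d = d, n = n, st = st, oa_d = oa_d, oa_s = oa_s,
            cr_w = cr_w, cr_d = cr_d, cr_s = cr_s,
            recache_cap = as.integer(recache_cap), risk_scope = risk_scope)
  validate_bird_params(p)
  structure(p, class = "bird_params")
}

validate_bird_params <- function(p) {
  stopifnot(
    p$d > 0, p$d < 1,
    p$n >= 0,
    p$st >= 0, p$st <= 1,
    p$oa_d <= p$oa_s, p$oa_s <= 0,
    p$cr_w >= 0, p$cr_w <= 1,
    p$cr_d >= 0, p$cr_d <= 1,
    p$cr_s >= 0, p$cr_s <= 1,
    p$recache_cap >= 1
  )
  invisible(p)
}

#' @export
print.bird_params <- function(x, ...) {
  cat("<bird_params>",
      sprintf("d=%g n=%g st=%g | oa_d=%g oa_s=%g | cr_w=%g cr_d=%g cr_s=%g",
              x$d, x$n, x$st, x$oa_d, x$oa_s, x$cr_w, x$cr_d, x$cr_s),
      sprintf("| recache_cap=%d risk_scope=%s", x$recache_cap, x$risk_scope),
      "\n")
  invisible(x)
}

#' Social context of a caching session
#'
#' Describes who (if anyone) is watching the bird while it caches, and —
#' in distance designs — which tray is adjacent to the onlooker.
#'
#' @param rank `"dominant"`, `"subordinate"`, `"observer"` (an onlooker of
#'   unspecified dominance) or `"none"` (in private).
#' @param near_tray_id Optional tray id adjacent to the onlooker; only
#'   meaningful in distance designs, where onlooker aversion applies to
#'   its sites.
#' @return A list of class `onlooker_context` with fields `watched`,
#'   `rank` and `near_tray_id`.
#' @export
onlooker_context <- function(rank = c("none", "observer", "dominant", "subordinate"),
                             near_tray_id = NULL) {
  rank <- match.arg(rank)
  structure(list(
    watched = rank != "none",
    rank = rank,
    near_tray_id = if (is.null(near_tray_id)) NA_integer_ else as.integer(near_tray_id)
  ), class = "onlooker_context")
}

#' Immediate-recache odds implied by a social context
#'
#' `cr_w` when watched by an onlooker of unspecified rank, `cr_d` with a
#' dominant onlooker, `cr_s` with a subordinate one, and `0` in private:
#' only watched birds are stressed into immediately recovering and
#' re-caching worms they have just cached.
#'
#' @param context An [onlooker_context()].
#' @param params A [bird_params()].
#' @return A probability in `[0, 1]`.
#' @export
recache_odds <- function(context, params) {
  switch(context$rank,
         none = 0,
         observer = params$cr_w,
         dominant = params$cr_d,
         subordinate = params$cr_s)
}
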