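#' Create an empty declarative memory store
#'
#' The memory store is the sole substrate of a virtual bird's decisions.
#' Every caching and recovery event the bird experiences is encoded in a
#' *chunk*: one chunk per kind of experience at one site (caching there,
#' recovering there successfully, or recovering there unsuccessfully).
#' Re-experiencing the same kind of event at the same site does not create
#' a second chunk; the existing chunk receives an additional *use*.
#'
#' Time is measured in discrete model steps: every cache or recovery event
#' advances the store's clock by one step, and time outside experimental
#' sessions is not counted (decay over the hours between sessions is
#' negligible on the retention scales simulated here).
#'
#' @return An object of class `memory_store`: a list with elements
#'   `chunks` (a named list of chunks, keyed by event type, site and, for
#'   recovery chunks, success) and `clock` (the current integer step).
#' @seealso [encode_event()], [chunk_activation()], [inhibition_of_return()]
#' @export
#' @examples
#' m <- memory_store()
#' m <- encode_event(m, "cache", site_id = 3L)
#' m$clock
memory_store <- function() {
  structure(list(chunks = list(), clock = 0L), class = "memory_store")
}

chunk_key <- function(event_type, site_id, success = NULL) {
  if (identical(event_type, "cache")) {
    paste0("cache:", site_id)
  } else {
    paste0("recovery:", site_id, ":", if (isTRUE(success)) "s" else "u")
  }
}

#' Encode a caching or recovery event in memory
#'
#' Creates the appropriate chunk for the event, or, if a chunk with the
#' same key (event type, site, and success for recovery events) already
#' exists, appends a new use to it. The store clock is advanced by one
#' step: every cache or recovery event counts as one step.
#'
#' @param store A [memory_store()].
#' @param event_type `"cache"` or `"recovery"`.
#' @param site_id Integer site identifier.
#' @param success For recovery events only: `TRUE` if a cache was actually
#'   found, `FALSE` otherwise. Must be `NULL` for cache events.
#' @return The updated `memory_store`.
#' @export
encode_event <- function(store, event_type, site_id, success = NULL) {
  stopifnot(inherits(store, "memory_store"))
  event_type <- match.arg(event_type, c("cache", "recovery"))
  if (event_type == "cache" && !is.null(success)) {
    stop("'success' must not be supplied for cache events")
  }
  if (event_type == "recovery" && (is.null(success) || is.na(success))) {
    stop("'success' must be supplied for recovery events")
  }
  key <- chunk_key(event_type, site_id, success)
  ch <- store$chunks[[key]]
  if (is.null(ch)) {
    ch <- list(
      event_type = event_type,
      site_id = as.integer(site_id),
      success = if (event_type == "recovery") isTRUE(success) else NULL,
      use_steps = integer(0)
    )
  }
  ch$use_steps <- c(ch$use_steps, store$clock)
  store$chunks[[key]] <- ch
  store$clock <- store$clock + 1L
  store
}

#' Base-level activation of a chunk
#'
#' A chunk's activation reflects the recency and frequency of its use:
#' \deqn{A_h = \ln \sum_j t_j^{-d}}
#' where \eqn{t_j} is the elapsed time (in model steps) since use \eqn{j}
#' of the chunk and \eqn{d} is the decay parameter. This is the base-level
#' learning rule of the ACT-R cognitive architecture. Elapsed times are
#' clamped to a minimum of one step, so a chunk can be evaluated on the
#' step it was last used without a singularity.
#'
#' @param chunk A chunk from a [memory_store()], or any list with a
#'   `use_steps` element.
#' @param now Current step (the store clock at decision time).
#' @param d Decay parameter, `0 < d < 1`.
#' @return The activation, a finite real number.
#' @seealso [chunk_strength()] for the exponentiated activation used as the
#'   common currency of the behavioral rules.
#' @export
#' @examples
#' ch <- list(use_steps = c(0L, 1L))
#' chunk_activation(ch, now = 2L, d = 0.2)  # log(1 + 2^-0.2)
chunk_activation <- function(chunk, now, d) {
  log(chunk_strength(chunk, now, d))
}

#' Memory strength (exponentiated activation) of a chunk
#'
#' The power-law trace \eqn{\exp(A_h) = \sum_j t_j^{-d}}, with elapsed
#' times clamped to at least one step. This quantity, rather than the
#' log-scale activation itself, is what the behavioral rules sum and
#' compare: it is strictly positive for any used chunk, additive over
#' uses, increases with frequency of use and decays toward zero with
#' recency, so site-level biases built from it are well defined and
#' correctly signed (see [inhibition_of_return()], [cache_relocation()],
#' [safety_risk()]).
#'
#' @inheritParams chunk_activation
#' @param since_step Count only uses at steps `>= since_step` (default 0,
#'   all uses).
#' @return A positive real number; `0` if the chunk has no (counted) uses.
#' @export
chunk_strength <- function(chunk, now, d, since_step = 0L) {
  uses <- chunk$use_steps
  if (since_step > 0L) uses <- uses[uses >= since_step]
  if (length(uses) == 0L) return(0)
  t <- pmax(now - uses, 1)
  sum(t^(-d))
}

#' Inhibition of return at a site
#'
#' A negative bias against revisiting a site *with the same purpose*: in a
#' caching session only cache chunks at the site inhibit, in a recovery
#' session only recovery chunks (successful or not) do. The bias is minus
#' the summed memory strength of the matching chunks,
#' \eqn{I_k = -\sum_l e^{A_l}}, so it is `0` when no matching chunk
#' exists, always `<= 0`, and strictly more negative the stronger the
#' matching memories.
#'
#' Inhibition of return is a transient, within-session phenomenon: only
#' uses encoded during the current session (steps `>= since_step`)
#' inhibit. An immediate recovery made hours earlier, during the caching
#' session, does not suppress a later recovery visit to that site — it is
#' precisely those stale cache memories that draw failed recovery
#' attempts.
#'
#' @param store A [memory_store()].
#' @param site_id Integer site identifier.
#' @param session_type `"cache"` or `"recovery"` — the current session's
#'   type, which selects which chunks inhibit.
#' @param now Current step; defaults to the store clock.
#' @param d Decay parameter.
#' @param since_step Session start step; only uses at `>= since_step`
#'   count (default 0, i.e. all).
#' @return A non-positive real number.
#' @export
inhibition_of_return <- function(store, site_id, session_type,
                                 now = store$clock, d, since_step = 0L) {
  session_type <- match.arg(session_type, c("cache", "recovery"))
  keys <- if (session_type == "cache") {
    chunk_key("cache", site_id)
  } else {
    c(chunk_key("recovery", site_id, TRUE), chunk_key("recovery", site_id, FALSE))
  }
  s <- 0
  for (k in keys) {
    ch <- store$chunks[[k]]
    if (!is.null(ch)) s <- s + chunk_strength(ch, now, d, since_step)
  }
  -s
}

#' Logistic transient noise
#'
#' Transient error in the evaluation of a site's attractiveness, drawn
#' according to the ACT-R transient-noise rule
#' \deqn{\epsilon = n \, \ln\frac{1-r}{r}}
#' where `r` is uniform on (0, 1); the result is a sample from a logistic
#' distribution with mean 0 and scale `n`. With `n = 0` the noise is
#' identically zero.
#'
#' @param n Noise scale parameter, `n >= 0`.
#' @param r Optional uniform draw(s) in (0, 1). If `NULL`, one draw is
#'   taken from the session RNG; values at the endpoints are resampled so
#'   the noise is always finite.
#' @return Numeric noise value(s).
#' @export
transient_noise <- function(n, r = NULL) {
  stopifnot(n >= 0)
  if (is.null(r)) {
    r <- stats::runif(1)
    while (r <= 0 || r >= 1) r <- stats::runif(1)
  }
  if (any(r <= 0 | r >= 1)) stop("'r' must lie strictly between 0 and 1")
  if (n == 0) return(rep(0, length(r)))
  n * log((1 - r) / r)
}

#' Serialize a memory store to a plain list (JSON-ready)
#'
#' @param store A [memory_store()].
#' @return A list with the clock and one `use_steps` vector per chunk key,
#'   suitable for `jsonlite::toJSON()`.
#' @export
memory_as_list <- function(store) {
  list(
    clock = store$clock,
    chunks = lapply(store$chunks, function(ch) ch$use_steps)
  )
}

#' @export
print.memory_store <- function(x, ...) {
  cat("<memory_store> clock =", x$clock, "|", length(x$chunks), "chunks\n")
  invisible(x)
}
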