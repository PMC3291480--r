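#' Construct a world of ice-cube trays
#'
#' Ground truth of the physical setup: trays divided into a grid of
#' discrete cache sites, worm counts per site, and an out-of-tray sink
#' for worms re-cached out of reach. The bird's memory can diverge from
#' this state — that divergence is the sole source of recovery failures.
#'
#' @param distance_class Character vector, one entry per tray:
#'   `"near"`, `"far"` or `"neutral"`.
#' @param rows,cols Grid dimensions of each tray (recycled).
#' @return A list of class `world` with elements `trays` and `sites`
#'   (data frames), `worms_at` (integer worm count per site),
#'   `actually_cached` (logical per site), `out_of_tray`, `eaten` and
#'   `worms_given` counters.
#' @export
#' @examples
#' w <- make_world(c("near", "far"))
#' nrow(w$sites)  # 32 sites
make_world <- function(distance_class = "neutral", rows = 2L, cols = 8L) {
  k <- length(distance_class)
  rows <- rep_len(as.integer(rows), k)
  cols <- rep_len(as.integer(cols), k)
  stopifnot(all(rows >= 1L), all(cols >= 1L),
            all(distance_class %in% c("near", "far", "neutral")))
  trays <- data.frame(tray_id = seq_len(k), distance_class = distance_class,
                      rows = rows, cols = cols, stringsAsFactors = FALSE)
  sites <- do.call(rbind, lapply(seq_len(k), function(i) {
    g <- expand.grid(row = seq_len(rows[i]), col = seq_len(cols[i]))
    data.frame(tray_id = i, row = g$row, col = g$col)
  }))
  sites <- cbind(site_id = seq_len(nrow(sites)), sites)
  n <- nrow(sites)
  structure(list(
    trays = trays, sites = sites,
    worms_at = integer(n),
    actually_cached = logical(n),
    out_of_tray = 0L, eaten = 0L, worms_given = 0L
  ), class = "world")
}

#' Sites of one tray
#' @param world A [make_world()] object.
#' @param tray_id Tray identifier.
#' @return Integer vector of site ids.
#' @export
tray_sites <- function(world, tray_id) {
  world$sites$site_id[world$sites$tray_id %in% tray_id]
}

#' Worm-conservation check
#'
#' Every worm given to the bird is, at every step, either in a tray site,
#' re-cached out of tray, or eaten/held by the bird.
#'
#' @param world A [make_world()] object.
#' @return `TRUE` invisibly; errors if conservation is violated.
#' @export
check_conservation <- function(world) {
  lhs <- world$worms_given
  rhs <- sum(world$worms_at) + world$out_of_tray + world$eaten
  if (lhs != rhs) {
    stop(sprintf("worm conservation violated: given %d != located %d", lhs, rhs))
  }
  invisible(TRUE)
}

#' Qualifying sites for the safety-risk assessment
#'
#' The safety risk of a tray counts only recovery experiences directed at
#' the bird's actual cache sites or their neighbors: sites at Chebyshev
#' distance at most `radius` from an actually-cached site within the same
#' tray's grid.
#'
#' @param world A [make_world()] object.
#' @param tray_id The tray being assessed.
#' @param radius Neighborhood radius on the tray grid (default 1,
#'   lateral/diagonal adjacency).
#' @return Integer vector of qualifying site ids within the tray.
#' @export
qualifying_sites <- function(world, tray_id, radius = 1L) {
  s <- world$sites[world$sites$tray_id == tray_id, ]
  cached <- s[world$actually_cached[s$site_id], , drop = FALSE]
  if (nrow(cached) == 0L) return(integer(0))
  ok <- vapply(seq_len(nrow(s)), function(i) {
    any(abs(cached$row - s$row[i]) <= radius & abs(cached$col - s$col[i]) <= radius)
  }, logical(1))
  s$site_id[ok]
}

#' Build the world and session plan for a named experiment design
#'
#' Three designs are available, mirroring the two classic onlooker
#' experiments:
#' \describe{
#'   \item{`exp1a`}{Alternating trials: six trials (three watched by an
#'     onlooker of unspecified rank, three in private, alternating,
#'     watched first), one neutral tray per trial; recovery in private.}
#'   \item{`exp1b`}{Two trials; in each, the bird caches in two trays one
#'     after the other — one while watched, one in private (phase order
#'     counterbalanced across trials) — and both trays are returned
#'     simultaneously for recovery in private.}
#'   \item{`exp2`}{Three trials, one per condition (dominant onlooker,
#'     subordinate onlooker, private); two trays offered simultaneously,
#'     one near the adjacent bird and one farther away; recovery in
#'     private with both trays.}
#' }
#' Trays are fresh in every trial and, by default, the bird's memory is
#' reset between trials (trials were run on different days with distinct
#' trays).
#'
#' @param design `"exp1a"`, `"exp1b"` or `"exp2"`.
#' @param rows,cols Tray grid dimensions (default 2 x 8, an ice-cube
#'   tray of 16 sections).
#' @param n_caches Worms cached per caching phase. The default is
#'   design-specific, reconstructing the (unpublished) per-experiment
#'   empirical cache counts: 8 for the single-tray Experiment-1 designs,
#'   and 17 for the two-tray distance design, at which density the
#'   printed onlooker-aversion settings yield the published near-tray
#'   share of roughly 25 percent in each watched condition.
#' @return A list of class `session_plan`: the design name, `n_caches`,
#'   and `trials`, each trial holding a fresh `world`, a list of
#'   `caching_phases` (offered trays + [onlooker_context()]), the
#'   `recovery_trays`, a `condition` label and per-tray condition labels.
#' @export
build_world <- function(design = c("exp1a", "exp1b", "exp2"),
                        rows = 2L, cols = 8L, n_caches = NULL) {
  design <- match.arg(design)
  if (is.null(n_caches)) n_caches <- default_caches(design)
  trials <- switch(
    design,
    exp1a = lapply(1:6, function(i) {
      watched <- i %% 2L == 1L
      list(
        trial = i,
        condition = if (watched) "watched" else "private",
        world = make_world("neutral", rows, cols),
        caching_phases = list(list(
          trays = 1L,
          context = onlooker_context(if (watched) "observer" else "none")
        )),
        recovery_trays = 1L,
        tray_condition = c("watched", "private")[2L - watched]
      )
    }),
    exp1b = lapply(1:2, function(i) {
      phases <- list(
        list(trays = 1L, context = onlooker_context("observer")),
        list(trays = 2L, context = onlooker_context("none"))
      )
      if (i == 2L) phases <- rev(phases)
      list(
        trial = i,
        condition = "mixed",
        world = make_world(c("neutral", "neutral"), rows, cols),
        caching_phases = phases,
        recovery_trays = c(1L, 2L),
        tray_condition = c("watched", "private")
      )
    }),
    exp2 = {
      conds <- c("dominant", "subordinate", "private")
      lapply(seq_along(conds), function(i) {
        rank <- c("dominant", "subordinate", "none")[i]
        list(
          trial = i,
          condition = conds[i],
          world = make_world(c("near", "far"), rows, cols),
          caching_phases = list(list(
            trays = c(1L, 2L),
            context = onlooker_context(rank, near_tray_id = if (rank == "none") NULL else 1L)
          )),
          recovery_trays = c(1L, 2L),
          tray_condition = c("near", "far")
        )
      })
    }
  )
  structure(list(design = design, n_caches = as.integer(n_caches),
                 rows = rows, cols = cols, trials = trials),
            class = "session_plan")
}
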