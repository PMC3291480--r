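default_birds <- function(design) {
  switch(design, exp1a = 7L, exp1b = 7L, exp2 = 9L)
}

default_caches <- function(design) {
  switch(design, exp1a = 8L, exp1b = 8L, exp2 = 17L)
}

trial_counts <- function(res, trial) {
  trays <- sort(unique(res$world$sites$tray_id))
  if (!is.null(res$counts)) {
    ct <- res$counts
    n_initial <- ct$initial[trays]
    n_place <- ct$placements[trays]
    n_imm <- ct$immediate[trays]
    n_fail <- ct$fail[trays]
    n_recached <- ct$recached[trays]
  } else {
    lg <- res$log
    caching <- lg$session == "caching"
    cnt <- function(keep) {
      vapply(trays, function(t) sum(keep & lg$tray == t), integer(1))
    }
    n_initial <- cnt(lg$action == "cache")
    n_place <- cnt(caching & lg$action %in% c("cache", "recache_immediate"))
    n_imm <- cnt(caching & lg$action == "recover_success")
    n_fail <- cnt(lg$action == "recover_fail")
    n_recached <- cnt(lg$action == "recache_recovery")
  }
  data.frame(
    trial = trial$trial,
    condition = trial$condition,
    tray = trays,
    tray_label = trial$tray_condition[trays],
    n_initial = n_initial,
    n_placements = n_place,
    n_immediate = n_imm,
    worms_recovery = n_place - n_imm,
    n_fail = n_fail,
    n_recached = n_recached,
    flagged = res$flagged,
    stringsAsFactors = FALSE
  )
}

#' Run a replicated simulated experiment
#'
#' Runs `n_runs` independent replicates of one experimental design, each
#' with `n_birds` virtual birds (defaults match the original sample
#' sizes: 7 for the Experiment-1 designs, 9 for Experiment 2). All
#' randomness flows from the single master `seed`: a run-level substream
#' seed is drawn per replicate, so results are bit-reproducible and runs
#' are independent.
#'
#' @param design `"exp1a"`, `"exp1b"` or `"exp2"` (see [build_world()]).
#' @param params A [bird_params()].
#' @param n_birds Virtual birds per run (default: original sample size).
#' @param n_runs Number of replicate runs (default 100).
#' @param seed Master seed.
#' @param engine `"cpp"` or `"r"`.
#' @param rows,cols,n_caches World geometry and caches per caching phase
#'   (`n_caches = NULL` uses the design-specific default, see
#'   [build_world()]).
#' @param carry_memory Carry the memory store across the trials of one
#'   bird (default `FALSE`: memory is reset between trials, which used
#'   distinct trays on distinct days).
#' @return A data frame, one row per run x bird x trial x tray, with
#'   event tallies (`n_initial`, `n_placements`, `n_immediate`,
#'   `worms_recovery`, `n_fail`, `n_recached`) and a `flagged` column
#'   marking circuit-breaker trips.
#' @export
#' @examples
#' res <- run_experiment("exp1a", n_runs = 2, seed = 1)
#' head(res)
run_experiment <- function(design, params = bird_params(), n_birds = NULL,
                           n_runs = 100L, seed = 1L,
                           engine = c("cpp", "r"),
                           rows = 2L, cols = 8L, n_caches = NULL,
                           carry_memory = FALSE) {
  engine <- match.arg(engine)
  if (is.null(n_birds)) n_birds <- default_birds(design)
  plan <- build_world(design, rows = rows, cols = cols, n_caches = n_caches)
  n_trials <- length(plan$trials)
  trays_of <- lapply(plan$trials, function(tr) sort(unique(tr$world$sites$tray_id)))
  rows_per_bird <- sum(lengths(trays_of))
  meta <- list(
    trial = unlist(lapply(seq_len(n_trials),
                          function(i) rep(i, length(trays_of[[i]])))),
    condition = unlist(lapply(plan$trials,
                              function(tr) rep(tr$condition, length(tr$tray_condition)))),
    tray = unlist(trays_of),
    tray_label = unlist(lapply(plan$trials, function(tr) tr$tray_condition))
  )
  set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_runs)
  nrow_tot <- n_runs * n_birds * rows_per_bird
  col_init <- col_place <- col_imm <- col_fail <- col_rec <- integer(nrow_tot)
  col_flag <- logical(nrow_tot)
  pos <- 0L
  for (run in seq_len(n_runs)) {
    set.seed(run_seeds[run])
    for (bird in seq_len(n_birds)) {
      store <- memory_store()
      for (ti in seq_len(n_trials)) {
        trial <- plan$trials[[ti]]
        res <- run_trial(trial, plan$n_caches, params,
                         store = if (carry_memory) store else memory_store(),
                         engine = engine,
                         want_store = carry_memory && engine == "cpp",
                         want_log = engine == "r")
        if (carry_memory) store <- res$store
        trays <- trays_of[[ti]]
        idx <- pos + seq_along(trays)
        if (!is.null(res$counts)) {
          ct <- res$counts
          col_init[idx] <- ct$initial[trays]
          col_place[idx] <- ct$placements[trays]
          col_imm[idx] <- ct$immediate[trays]
          col_fail[idx] <- ct$fail[trays]
          col_rec[idx] <- ct$recached[trays]
        } else {
          tc <- trial_counts(res, trial)
          col_init[idx] <- tc$n_initial
          col_place[idx] <- tc$n_placements
          col_imm[idx] <- tc$n_immediate
          col_fail[idx] <- tc$n_fail
          col_rec[idx] <- tc$n_recached
        }
        col_flag[idx] <- res$flagged
        pos <- pos + length(trays)
      }
    }
  }
  per_run_rows <- n_birds * rows_per_bird
  out <- data.frame(
    design = design,
    run = rep(seq_len(n_runs), each = per_run_rows),
    seed = rep(run_seeds, each = per_run_rows),
    bird = rep(rep(seq_len(n_birds), each = rows_per_bird), times = n_runs),
    trial = rep(meta$trial, times = n_runs * n_birds),
    condition = rep(meta$condition, times = n_runs * n_birds),
    tray = rep(meta$tray, times = n_runs * n_birds),
    tray_label = rep(meta$tray_label, times = n_runs * n_birds),
    n_initial = col_init,
    n_placements = col_place,
    n_immediate = col_imm,
    worms_recovery = col_place - col_imm,
    n_fail = col_fail,
    n_recached = col_rec,
    flagged = col_flag,
    stringsAsFactors = FALSE
  )
  out
}

drop_flagged <- function(results) {
  bad <- unique(results$run[results$flagged])
  if (length(bad) > 0) {
    warning(sprintf("excluding %d flagged run(s): circuit breaker tripped",
                    length(bad)))
    results <- results[!results$run %in% bad, , drop = FALSE]
  }
  results
}

#' Per-bird re-cache proportions by analysis cell
#'
#' Aggregates recovery-session re-caches over the grouping variables and
#' divides by the number of worms present at the start of the recovery
#' session, per run and bird.
#'
#' @param results Output of [run_experiment()].
#' @param by Grouping column(s): `"condition"` (default), `"tray_label"`,
#'   or both.
#' @return Data frame with columns `run`, `bird`, the grouping columns,
#'   and `prop`.
#' @export
bird_props <- function(results, by = "condition") {
  results <- drop_flagged(results)
  f <- results[, c("run", "bird", by), drop = FALSE]
  num <- stats::aggregate(results$n_recached, f, sum)
  den <- stats::aggregate(results$worms_recovery, f, sum)
  num$prop <- ifelse(den$x > 0, num$x / den$x, NA_real_)
  num$x <- NULL
  num
}

#' Per-run mean re-cache proportions by analysis cell
#'
#' @inheritParams bird_props
#' @return Data frame with columns `run`, the grouping columns, and
#'   `mean_prop` (mean across birds).
#' @export
run_means <- function(results, by = "condition") {
  bp <- bird_props(results, by)
  out <- stats::aggregate(bp$prop, bp[, c("run", by), drop = FALSE],
                          mean, na.rm = TRUE)
  names(out)[names(out) == "x"] <- "mean_prop"
  out
}

#' Across-run summary of re-cache proportions
#'
#' Grand mean and standard error (across runs) of the per-run mean
#' re-cache proportion for each analysis cell.
#'
#' @inheritParams bird_props
#' @return Data frame with the grouping columns, `mean`, `se` and
#'   `n_runs`.
#' @export
experiment_summary <- function(results, by = "condition") {
  rm_ <- run_means(results, by)
  agg <- stats::aggregate(rm_$mean_prop, rm_[, by, drop = FALSE],
                          function(v) c(mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v)),
                                        n = length(v)))
  out <- cbind(agg[, by, drop = FALSE], as.data.frame(agg$x))
  names(out) <- c(by, "mean", "se", "n_runs")
  out
}

#' Select the representative run
#'
#' The replicate whose cell-level mean re-cache proportions are closest
#' (mean absolute difference) to the across-run grand means; ties are
#' broken by the lowest run id.
#'
#' @inheritParams bird_props
#' @return The selected run id (integer).
#' @export
select_representative_run <- function(results, by = "condition") {
  rm_ <- run_means(results, by)
  cells <- interaction(rm_[, by, drop = FALSE], drop = TRUE)
  grand <- tapply(rm_$mean_prop, cells, mean, na.rm = TRUE)
  rm_$dev <- abs(rm_$mean_prop - grand[as.character(cells)])
  dd <- stats::aggregate(rm_$dev, list(run = rm_$run), mean, na.rm = TRUE)
  dd$run[which.min(dd$x)]
}

#' Mean immediate re-caches per cached worm
#'
#' Number of immediate (caching-session) re-caches divided by the number
#' of initially cached worms, over the rows matching `condition`.
#'
#' @param results Output of [run_experiment()].
#' @param condition Condition label(s) to include (default `"watched"`).
#' @return A single number.
#' @export
immediate_recache_rate <- function(results, condition = "watched") {
  results <- drop_flagged(results)
  keep <- results$condition %in% condition
  sum(results$n_immediate[keep]) / sum(results$n_initial[keep])
}

#' Share of initial caches placed in the near tray
#'
#' @param results Output of [run_experiment()] for the `exp2` design.
#' @return Data frame with `condition` and `near_share` (fraction of all
#'   initial cache placements landing in the near tray).
#' @export
near_tray_share <- function(results) {
  results <- drop_flagged(results)
  tot <- stats::aggregate(results$n_initial,
                          list(condition = results$condition), sum)
  nr <- results[results$tray_label == "near", , drop = FALSE]
  near <- stats::aggregate(nr$n_initial, list(condition = nr$condition), sum)
  m <- merge(tot, near, by = "condition", suffixes = c("_tot", "_near"))
  data.frame(condition = m$condition, near_share = m$x_near / m$x_tot,
             stringsAsFactors = FALSE)
}

#' Run all three experiment designs at one parameter setting
#'
#' @inheritParams run_experiment
#' @return A named list of [run_experiment()] results
#'   (`exp1a`, `exp1b`, `exp2`).
#' @export
run_all_designs <- function(params = bird_params(), n_runs = 100L,
                            seed = 1L, engine = "cpp",
                            rows = 2L, cols = 8L, n_caches = NULL) {
  set.seed(seed)
  seeds <- sample.int(2147483646L, 3)
  list(
    exp1a = run_experiment("exp1a", params, n_runs = n_runs, seed = seeds[1],
                           engine = engine, rows = rows, cols = cols,
                           n_caches = n_caches),
    exp1b = run_experiment("exp1b", params, n_runs = n_runs, seed = seeds[2],
                           engine = engine, rows = rows, cols = cols,
                           n_caches = n_caches),
    exp2 = run_experiment("exp2", params, n_runs = n_runs, seed = seeds[3],
                          engine = engine, rows = rows, cols = cols,
                          n_caches = n_caches)
  )
}

#' Check the five directional re-caching patterns
#'
#' Evaluates, on across-run grand means, the five qualitative effects the
#' model is expected to reproduce at its operating point:
#' \enumerate{
#'   \item alternating-trials design: watched trials show a higher mean
#'     re-cache proportion than private trials;
#'   \item two-tray design: more re-caching from the watched tray than
#'     the private tray;
#'   \item distance design: more re-caching with a dominant onlooker than
#'     a subordinate one;
#'   \item distance design: more re-caching with a dominant onlooker than
#'     in private;
#'   \item distance design: within the watched conditions, a higher
#'     re-cache proportion from the near tray than the far tray.
#' }
#'
#' @param designs A named list as returned by [run_all_designs()].
#' @return Named logical vector with the five pattern flags and
#'   `all_patterns`.
#' @export
check_patterns <- function(designs) {
  s1 <- experiment_summary(designs$exp1a, by = "condition")
  p1 <- s1$mean[s1$condition == "watched"] > s1$mean[s1$condition == "private"]
  s2 <- experiment_summary(designs$exp1b, by = "tray_label")
  p2 <- s2$mean[s2$tray_label == "watched"] > s2$mean[s2$tray_label == "private"]
  s3 <- experiment_summary(designs$exp2, by = "condition")
  p3 <- s3$mean[s3$condition == "dominant"] > s3$mean[s3$condition == "subordinate"]
  p4 <- s3$mean[s3$condition == "dominant"] > s3$mean[s3$condition == "private"]
  watched <- designs$exp2[designs$exp2$condition %in%
                            c("dominant", "subordinate"), , drop = FALSE]
  s5 <- experiment_summary(watched, by = "tray_label")
  p5 <- s5$mean[s5$tray_label == "near"] > s5$mean[s5$tray_label == "far"]
  flags <- c(
    watched_gt_private = isTRUE(p1),
    watched_tray_gt_private_tray = isTRUE(p2),
    dominant_gt_subordinate = isTRUE(p3),
    dominant_gt_private = isTRUE(p4),
    near_gt_far_watched = isTRUE(p5)
  )
  c(flags, all_patterns = all(flags))
}

#' Robustness sweep over decay, noise and stress threshold
#'
#' Re-runs all three designs on a grid of `(d, n, st)` values and records
#' which of the five directional patterns hold in each cell.
#'
#' @param d_values,n_values,st_values Grid values for the three free
#'   parameters (defaults reconstruct the published robustness grid:
#'   d and n in 0.1..0.5, st in 0.4..0.7).
#' @param base A [bird_params()] supplying the fixed settings.
#' @param n_runs Replicates per design per cell (default 20; the sweep is
#'   a screening pass, not an estimation pass).
#' @param seed Master seed; each cell receives a derived subseed.
#' @param engine,rows,cols,n_caches Passed to [run_experiment()].
#' @return Data frame: one row per cell with `d`, `n`, `st`, the five
#'   pattern flags and `all_patterns`.
#' @export
parameter_sweep <- function(d_values = seq(0.1, 0.5, by = 0.1),
                            n_values = seq(0.1, 0.5, by = 0.1),
                            st_values = c(0.4, 0.5, 0.6, 0.7),
                            base = bird_params(), n_runs = 20L, seed = 1L,
                            engine = "cpp", rows = 2L, cols = 8L,
                            n_caches = NULL) {
  grid <- expand.grid(d = d_values, n = n_values, st = st_values,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(2147483646L, nrow(grid))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- bird_params(d = grid$d[i], n = grid$n[i], st = grid$st[i],
                     oa_d = base$oa_d, oa_s = base$oa_s, cr_w = base$cr_w,
                     cr_d = base$cr_d, cr_s = base$cr_s,
                     recache_cap = base$recache_cap,
                     risk_scope = base$risk_scope)
    designs <- run_all_designs(p, n_runs = n_runs, seed = cell_seeds[i],
                               engine = engine, rows = rows, cols = cols,
                               n_caches = n_caches)
    flags <- check_patterns(designs)
    out[[i]] <- cbind(grid[i, , drop = FALSE],
                      as.data.frame(as.list(flags)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
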