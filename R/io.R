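#' Write a results table or summary as CSV
#'
#' @param x Data frame (event tallies from [run_experiment()], a summary
#'   from [experiment_summary()], or a sweep from [parameter_sweep()]).
#' @param path Output file path (directories are created).
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records everything needed to reproduce a batch bit-identically: the
#' package version, the master seed and the full configuration.
#'
#' @param path Output JSON path.
#' @param seed Master seed.
#' @param config Named list of configuration values.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "corvidcache",
    version = as.character(utils::packageVersion("corvidcache")),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

read_config_file <- function(path) {
  if (is.null(path)) return(list())
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

num <- function(x, default) if (is.null(x)) default else as.numeric(x)
int <- function(x, default) if (is.null(x)) default else as.integer(x)

params_from_opts <- function(opts, config) {
  get <- function(key, default) {
    v <- opts[[key]]
    if (is.null(v)) v <- config[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  bird_params(
    d = get("d", 0.2), n = get("n", 0.3), st = get("st", 0.6),
    oa_d = get("oa_d", -1.25), oa_s = get("oa_s", -0.5),
    cr_w = get("cr_w", 0.6), cr_d = get("cr_d", 0.8), cr_s = get("cr_s", 0.4)
  )
}

#' Command-line entry point
#'
#' Thin command-line interface over the simulation harness, used by the
#' `inst/cli/virtualbird.R` script. Subcommands:
#' \describe{
#'   \item{`run`}{One design: `--design exp1a|exp1b|exp2`, `--runs`,
#'     `--seed`, `--outdir`, optional `--config` (YAML or JSON) and
#'     parameter overrides (`--d`, `--n`, `--st`, `--oa-d`, `--oa-s`,
#'     `--cr-w`, `--cr-d`, `--cr-s`, `--rows`, `--cols`, `--caches`).
#'     Writes the per-run tallies, the condition summary and a manifest.}
#'   \item{`reproduce`}{All three designs plus the pattern flags and the
#'     representative-run report.}
#'   \item{`sweep`}{The (d, n, st) robustness grid; `--runs` sets the
#'     replicates per cell.}
#'   \item{`selftest`}{Engine-parity and conservation spot checks.}
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
vb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: virtualbird <run|reproduce|sweep|selftest> [--options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- cli_options(args[-1])
  config <- read_config_file(opts$config)
  seed <- int(opts$seed, 1L)
  outdir <- if (is.null(opts$outdir)) "virtualbird_out" else opts$outdir
  params <- params_from_opts(opts, config)
  rows <- int(opts$rows, 2L)
  cols <- int(opts$cols, 8L)
  caches <- if (is.null(opts$caches)) NULL else as.integer(opts$caches)

  if (cmd == "run") {
    design <- if (is.null(opts$design)) stop("--design is required") else opts$design
    res <- run_experiment(design, params, n_runs = int(opts$runs, 100L),
                          seed = seed, rows = rows, cols = cols,
                          n_caches = caches)
    write_results_csv(res, file.path(outdir, paste0(design, "_results.csv")))
    write_results_csv(experiment_summary(res),
                      file.path(outdir, paste0(design, "_summary.csv")))
    write_manifest(file.path(outdir, "manifest.json"), seed,
                   c(list(command = "run", design = design,
                          runs = int(opts$runs, 100L)), unclass(params)))
    message("wrote ", outdir)
    return(invisible(0L))
  }

  if (cmd == "reproduce") {
    n_runs <- int(opts$runs, 100L)
    des <- run_all_designs(params, n_runs = n_runs, seed = seed,
                           rows = rows, cols = cols, n_caches = caches)
    for (d in names(des)) {
      write_results_csv(des[[d]], file.path(outdir, paste0(d, "_results.csv")))
      write_results_csv(experiment_summary(des[[d]]),
                        file.path(outdir, paste0(d, "_summary.csv")))
    }
    write_results_csv(
      experiment_summary(des$exp1b, by = "tray_label"),
      file.path(outdir, "exp1b_tray_summary.csv"))
    write_results_csv(
      experiment_summary(des$exp2[des$exp2$condition != "private", ],
                         by = c("condition", "tray_label")),
      file.path(outdir, "exp2_tray_summary.csv"))
    flags <- check_patterns(des)
    write_results_csv(data.frame(pattern = names(flags), holds = flags,
                                 row.names = NULL),
                      file.path(outdir, "patterns.csv"))
    rep_run <- select_representative_run(des$exp1a)
    bp <- bird_props(des$exp1a)
    x <- bp[bp$run == rep_run & bp$condition == "watched", ]
    y <- bp[bp$run == rep_run & bp$condition == "private", ]
    x <- x[order(x$bird), ]
    y <- y[order(y$bird), ]
    wt <- wilcoxon_matched_pairs(x$prop, y$prop)
    bp2 <- bird_props(des$exp2)
    mat <- stats::reshape(bp2[bp2$run == select_representative_run(des$exp2), ],
                          idvar = "bird", timevar = "condition",
                          direction = "wide")
    ft <- friedman_rank_test(as.matrix(mat[, -(1:2)]))
    report <- list(
      representative_run_exp1a = rep_run,
      wilcoxon_watched_vs_private = wt,
      friedman_exp2 = ft,
      immediate_recaches_per_watched_worm =
        immediate_recache_rate(des$exp1a, "watched"),
      near_tray_share = near_tray_share(des$exp2)
    )
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_manifest(file.path(outdir, "manifest.json"), seed,
                   c(list(command = "reproduce", runs = n_runs),
                     unclass(params)))
    message("wrote ", outdir)
    return(invisible(0L))
  }

  if (cmd == "sweep") {
    vals <- function(key, default) {
      v <- opts[[key]]
      if (is.null(v)) default else as.numeric(strsplit(v, ",")[[1]])
    }
    sw <- parameter_sweep(
      d_values = vals("d_values", seq(0.1, 0.5, by = 0.1)),
      n_values = vals("n_values", seq(0.1, 0.5, by = 0.1)),
      st_values = vals("st_values", c(0.4, 0.5, 0.6, 0.7)),
      base = params, n_runs = int(opts$runs, 20L), seed = seed,
      rows = rows, cols = cols, n_caches = caches)
    write_results_csv(sw, file.path(outdir, "sweep.csv"))
    write_manifest(file.path(outdir, "manifest.json"), seed,
                   c(list(command = "sweep", runs = int(opts$runs, 20L)),
                     unclass(params)))
    message("wrote ", outdir)
    return(invisible(0L))
  }

  if (cmd == "selftest") {
    plan <- build_world("exp2")
    ok <- TRUE
    for (s in 1:3) {
      set.seed(s)
      a <- run_trial(plan$trials[[1]], plan$n_caches, params, engine = "r")
      set.seed(s)
      b <- run_trial(plan$trials[[1]], plan$n_caches, params, engine = "cpp")
      ok <- ok && identical(a$log, b$log)
      w <- b$world
      ok <- ok && w$worms_given == sum(w$worms_at) + w$out_of_tray + w$eaten
    }
    message(if (ok) "selftest passed" else "selftest FAILED")
    return(invisible(if (ok) 0L else 1L))
  }

  message("unknown subcommand: ", cmd)
  invisible(1L)
}
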