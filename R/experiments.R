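#' Deterministic child seed for one run of a sweep
#'
#' Counter-based derivation: a Lehmer multiplicative step applied to the
#' master seed, offset by the cell and replicate indices, reduced modulo
#' the Mersenne prime 2^31 - 1. The same (master, cell, replicate) triple
#' always yields the same child seed, on every platform, and distinct
#' triples yield distinct seeds for all sweep sizes used here
#' (`replicate < 104729`).
#'
#' @param master_seed Integer master seed.
#' @param cell Setting (grid-row) index, from 1.
#' @param replicate Replicate index within the cell, from 1.
#' @return A positive integer seed below 2^31.
#' @export
child_seed <- function(master_seed, cell, replicate) {
  m <- 2147483647
  h <- (as.double(master_seed) %% m) * 48271 %% m
  h <- (h + as.double(cell) * 104729 + as.double(replicate)) %% m
  as.integer(h) + 1L
}

#' Run a parameter sweep
#'
#' Executes every combination of a settings grid and a replicate index,
#' each run seeded with its own [child_seed()], and returns tidy per-run
#' and per-setting tables. A failing run is recorded with
#' `status = "error"` and its message; it does not abort the sweep.
#'
#' @param grid A `data.frame`; each row is one setting (cell) and each
#'   column must be a [sim_config()] argument (e.g. `proportion_active`,
#'   `N`, `scheduler`, `stopping`, `response` as `"type_I"`/`"type_II"`).
#' @param replicates Replicate runs per cell.
#' @param master_seed Master seed from which all child seeds derive.
#' @param constants Named list of [sim_config()] arguments shared by all
#'   cells (grid columns take precedence).
#' @param out_dir If non-`NULL`, `runs.csv` and `summary.csv` are written
#'   there (directory created if needed).
#' @param progress If `TRUE`, log one line per cell to stderr.
#' @return An `ifd_batch` (see [summarize_batch()]) whose `runs` table
#'   carries the grid columns, `replicate`, `seed` and `status`, and
#'   whose `summary` aggregates within grid cells.
#' @examples
#' grid <- expand.grid(proportion_active = c(0, 1), stringsAsFactors = FALSE)
#' run_sweep(grid, replicates = 3, master_seed = 1,
#'           constants = list(N = 10))$summary
#' @export
run_sweep <- function(grid, replicates = 100L, master_seed = 1L,
                      constants = list(), out_dir = NULL, progress = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L, replicates >= 1L)
  metric_cols <- c("time_to_stop", "stop_reason", "reached_true_ifd",
                   "time_to_ifd", "total_moves", "max_moves",
                   "intake_variance", "matching_slope")
  rows <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (cell in seq_len(nrow(grid))) {
    cell_args <- utils::modifyList(constants,
                                   lapply(grid[cell, , drop = FALSE], function(col) {
                                     v <- col[[1L]]
                                     if (is.factor(v)) as.character(v) else v
                                   }))
    if (progress)
      message(sprintf("sweep cell %d/%d: %s", cell, nrow(grid),
                      paste(names(cell_args), unlist(cell_args),
                            sep = "=", collapse = ", ")))
    for (rep in seq_len(replicates)) {
      seed <- child_seed(master_seed, cell, rep)
      res <- tryCatch(
        run_sim(do.call(sim_config, c(cell_args, list(seed = seed)))),
        error = function(e) e
      )
      base <- cbind(grid[cell, , drop = FALSE],
                    data.frame(replicate = rep, seed = seed),
                    row.names = NULL)
      if (inherits(res, "error")) {
        vals <- as.data.frame(stats::setNames(as.list(rep(NA, length(metric_cols))),
                                              metric_cols))
        vals$status <- "error"
        vals$message <- conditionMessage(res)
      } else {
        df <- as.data.frame(res)
        vals <- df[metric_cols]
        vals$status <- "ok"
        vals$message <- ""
      }
      k <- k + 1L
      rows[[k]] <- cbind(base, vals, row.names = NULL)
    }
  }
  runs <- do.call(rbind, rows)
  ok <- runs[runs$status == "ok", , drop = FALSE]
  batch <- summarize_batch(ok, by = names(grid))
  batch$runs <- runs
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(runs, file.path(out_dir, "runs.csv"), row.names = FALSE)
    utils::write.csv(batch$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  batch
}

#' Preset sweep scenarios
#'
#' Ready-made grids for the three standard experiments, at desk-scale
#' replicate counts (pass a larger `replicates` for full-scale runs):
#'
#' * `"activity_mixture"` — N = 40 consumers with activities 0.8/0.2,
#'   proportion active 0 to 1, both schedulers, exact IFD stopping: how
#'   the presence of inefficient movers slows the approach to the IFD.
#' * `"stopping_bias"` — activities 0.9/0.1, mostly-inactive populations,
#'   discrete scheduler, quiescence-50 stopping versus exact stopping:
#'   how counting 50 still steps as "equilibrium" mistakes reluctance to
#'   move for the IFD.
#' * `"population_size"` — event-based scheduler, rates 0.8/0.2, 49
#'   patches, N in 8..1000: on a natural time scale the IFD is reached
#'   *faster* in large populations, because each departure alleviates
#'   within-patch competition for everyone left behind.
#'
#' @param name Preset name.
#' @param replicates Replicates per cell (defaults: 200, 200, 100).
#' @return A list with `grid`, `constants`, `replicates`, ready for
#'   `do.call(run_sweep, preset)`.
#' @examples
#' p <- sweep_preset("activity_mixture", replicates = 2)
#' b <- do.call(run_sweep, c(p, list(master_seed = 1)))
#' @export
sweep_preset <- function(name = c("activity_mixture", "stopping_bias",
                                  "population_size"),
                         replicates = NULL) {
  name <- match.arg(name)
  if (!is.null(replicates)) replicates <- as.integer(replicates)
  switch(name,
    activity_mixture = list(
      grid = expand.grid(proportion_active = c(0, 0.25, 0.5, 0.75, 1),
                         scheduler = c("discrete", "gillespie"),
                         stringsAsFactors = FALSE),
      constants = list(N = 40L, activity_high = 0.8, activity_low = 0.2,
                       stopping = "true_ifd"),
      replicates = replicates %||% 200L
    ),
    stopping_bias = list(
      grid = expand.grid(proportion_active = c(0, 0.1, 0.2, 0.3),
                         stopping = c("quiescence", "true_ifd"),
                         stringsAsFactors = FALSE),
      constants = list(N = 40L, activity_high = 0.9, activity_low = 0.1,
                       scheduler = "discrete", quiescence_K = 50L),
      replicates = replicates %||% 200L
    ),
    population_size = list(
      grid = expand.grid(N = c(8L, 40L, 100L, 1000L),
                         proportion_active = c(0, 0.25, 0.5, 0.75, 1),
                         stringsAsFactors = FALSE),
      constants = list(scheduler = "gillespie", activity_high = 0.8,
                       activity_low = 0.2, stopping = "true_ifd"),
      replicates = replicates %||% 100L
    )
  )
}
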