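# Configuration-driven orchestration: simulate (optional) -> extract ->
# ensemble statistics -> Bell-Evans fit -> kinetics, plus optional bootstrap
# replica-sufficiency sweep and MMPBSA hotspot classification. Every random
# draw is traceable to the master seed through the manifest.

#' Read and validate a pipeline configuration file
#'
#' YAML with top-level keys: `seed`, `spring_k` (kJ/mol/nm^2), `temperature`
#' (K), `velocities` (nm/ps, distinct, > 0), `n_replicas` (>= 2),
#' `estimator` (`intercept_ratio` | `exponential`), and a `systems` list.
#' Each system has an `id` plus exactly one of: `simulate` (generator
#' parameters `k_off_true`, `x_b_true`, optional `noise_sd`,
#' `post_rupture_decay`), `data_dir` (a tree of `pullf_v*_r*.xvg` /
#' `pullx_v*_r*.xvg` files), or `summary_csv` (a pre-computed per-velocity
#' summary table for fit-only runs). Optional blocks: `bootstrap` (`B`,
#' `n_grid`, `velocity`), `hotspots` (`decomp_a`, `pocket_a`, `decomp_b`,
#' `pocket_b`, optional `threshold`).
#'
#' @param path YAML config file.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list built in code.
#' @export
validate_pipeline_config <- function(cfg) {
  defaults <- list(spring_k = 600, temperature = 303.15,
                   estimator = "intercept_ratio", seed = 1L, n_replicas = 2L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$systems) || length(cfg$systems) == 0)
    stop("config error: at least one system required")
  fitonly <- vapply(cfg$systems, function(s) !is.null(s$summary_csv), logical(1))
  if (!all(fitonly)) {
    v <- unlist(cfg$velocities)
    if (is.null(v) || any(v <= 0) || anyDuplicated(v))
      stop("config error: velocities must be positive and distinct")
    if (cfg$n_replicas < 2) stop("config error: n_replicas must be >= 2")
    cfg$velocities <- v
  }
  for (s in cfg$systems) {
    if (is.null(s$id)) stop("config error: every system needs an id")
    n_src <- sum(!is.null(s$simulate), !is.null(s$data_dir),
                 !is.null(s$summary_csv))
    if (n_src != 1L)
      stop("config error: system ", s$id, " must have exactly one of ",
           "simulate / data_dir / summary_csv")
  }
  cfg$estimator <- match.arg(cfg$estimator, c("intercept_ratio", "exponential"))
  structure(cfg, class = "pipeline_config")
}

# read one (velocity, replica) pullf/pullx pair from a write_ensemble tree
.read_replica <- function(dir, velocity, replica, spring_k, temperature) {
  vtag <- formatC(velocity, format = "g")
  fpath <- file.path(dir, sprintf("pullf_v%s_r%02d.xvg", vtag, replica))
  xpath <- file.path(dir, sprintf("pullx_v%s_r%02d.xvg", vtag, replica))
  if (!file.exists(fpath))
    stop("missing replica file: ", fpath)
  force <- read_xvg(fpath, "force", velocity = velocity, spring_k = spring_k,
                    temperature = temperature, replica_id = replica)
  dist <- if (file.exists(xpath)) read_xvg(xpath, "distance") else NULL
  list(force = force, distance = dist)
}

# velocity ensembles for one system, from a directory tree of XVG files
.system_ensembles <- function(dir, cfg) {
  lapply(cfg$velocities, function(v) {
    events <- lapply(seq_len(cfg$n_replicas), function(r) {
      rep <- .read_replica(dir, v, r, cfg$spring_k, cfg$temperature)
      extract_rupture(rep$force, rep$distance)
    })
    ensemble_stats(events, v, cfg$spring_k)
  })
}

.table1_rows <- function(id, ensembles) {
  do.call(rbind, lapply(ensembles, function(e) {
    data.frame(system = id, velocity = e$velocity, n = e$n, ln_lr = e$ln_lr,
               f_max_mean = e$mean[["f_max"]], f_max_sd = e$sd[["f_max"]],
               t_max_mean = e$mean[["t_max"]], t_max_sd = e$sd[["t_max"]],
               d_max_mean = e$mean[["d_max"]], d_max_sd = e$sd[["d_max"]])
  }))
}

.table2_row <- function(id, fit) {
  data.frame(system = id,
             y_intercept = unname(fit$coefficients["y_intercept"]),
             slope = unname(fit$coefficients["slope"]),
             x_intercept = fit$x_intercept,
             r_squared = fit$r_squared,
             k_off = fit$kinetics$k_off,
             residence_time = fit$kinetics$residence_time)
}

#' Run the residence-time pipeline
#'
#' Executes the configured stages and writes the report bundle into the
#' output directory: `table1.csv` (per-velocity ensemble summaries, with
#' unpaired t-test p-values when exactly two systems share the velocity
#' grid), `table2.csv` (regression + kinetics per system), optional
#' `bootstrap_<system>.csv` and hotspot reports, and `manifest.yaml` for
#' bit-exact reruns. On any stage failure an `INCOMPLETE` marker naming the
#' failed stage is left in the output directory and the error is re-raised.
#'
#' @param config a `pipeline_config` (or path to one).
#' @param out_dir output directory (default `config$out_dir`).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return List with `table1`, `table2`, `fits`, and optional `bootstrap`,
#'   `hotspots`, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, overwrite = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: no output directory given")
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("refusing to write into non-empty directory ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  fail <- function(e) {
    writeLines(c(paste("failed at stage:", stage), conditionMessage(e)),
               file.path(out_dir, "INCOMPLETE"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  res <- tryCatch({
    fits <- list(); table1 <- NULL; ens_by_system <- list()
    for (i in seq_along(config$systems)) {
      s <- config$systems[[i]]
      if (!is.null(s$summary_csv)) {
        stage <- paste0("fit-only:", s$id)
        message("[bellevans] ", stage, ": ", s$summary_csv)
        tab <- read_table_csv(s$summary_csv)
        need <- c("ln_lr", "f_max_mean")
        if (!all(need %in% names(tab)))
          stop("summary table needs columns: ", paste(need, collapse = ", "))
        if ("system" %in% names(tab) && any(tab$system == s$id))
          tab <- tab[tab$system == s$id, , drop = FALSE]
        fits[[s$id]] <- bell_evans(tab$ln_lr, tab$f_max_mean,
                                   temperature = config$temperature,
                                   estimator = config$estimator)
        if (!("system" %in% names(tab))) tab <- cbind(system = s$id, tab)
        tab$system <- s$id
        table1 <- rbind(table1, tab)
        next
      }
      if (!is.null(s$simulate)) {
        stage <- paste0("simulate:", s$id)
        message("[bellevans] ", stage)
        grid <- lapply(config$velocities, function(v)
          bell_params(k_off_true = s$simulate$k_off_true,
                      x_b_true = s$simulate$x_b_true,
                      temperature = config$temperature,
                      spring_k = config$spring_k, velocity = v,
                      noise_sd = s$simulate$noise_sd %||% 20,
                      post_rupture_decay = s$simulate$post_rupture_decay %||% 50))
        sim_dir <- file.path(out_dir, paste0("sim_", s$id))
        write_ensemble(grid, config$n_replicas, sim_dir,
                       seed = child_seed(config$seed, i), overwrite = TRUE)
        data_dir <- sim_dir
      } else data_dir <- s$data_dir
      stage <- paste0("extract+stats:", s$id)
      message("[bellevans] ", stage)
      ens <- .system_ensembles(data_dir, config)
      ens_by_system[[s$id]] <- ens
      table1 <- rbind(table1, .table1_rows(s$id, ens))
      stage <- paste0("fit:", s$id)
      pts <- .table1_rows(s$id, ens)
      fits[[s$id]] <- bell_evans(pts$ln_lr, pts$f_max_mean,
                                 temperature = config$temperature,
                                 estimator = config$estimator)
    }
    stage <- "t-tests"
    if (length(ens_by_system) == 2L) {
      a <- ens_by_system[[1]]; b <- ens_by_system[[2]]
      tt <- do.call(rbind, lapply(seq_along(a), function(j) {
        data.frame(velocity = a[[j]]$velocity,
                   p_f_max = unpaired_t_test(
                     a[[j]]$mean[["f_max"]], a[[j]]$sd[["f_max"]], a[[j]]$n,
                     b[[j]]$mean[["f_max"]], b[[j]]$sd[["f_max"]], b[[j]]$n)$p_value,
                   p_t_max = unpaired_t_test(
                     a[[j]]$mean[["t_max"]], a[[j]]$sd[["t_max"]], a[[j]]$n,
                     b[[j]]$mean[["t_max"]], b[[j]]$sd[["t_max"]], b[[j]]$n)$p_value)
      }))
      table1 <- merge(table1, tt, by = "velocity", sort = FALSE)
    }
    stage <- "write-tables"
    table2 <- do.call(rbind, lapply(names(fits), function(id)
      .table2_row(id, fits[[id]])))
    write_table_csv(table1, file.path(out_dir, "table1.csv"), digits = 9)
    write_table_csv(table2, file.path(out_dir, "table2.csv"), digits = 9)
    boot <- NULL
    if (!is.null(config$bootstrap) && length(ens_by_system) > 0) {
      stage <- "bootstrap"
      message("[bellevans] ", stage)
      bv <- config$bootstrap$velocity %||% config$velocities[[length(config$velocities)]]
      boot <- lapply(names(ens_by_system), function(id) {
        j <- which(vapply(ens_by_system[[id]], `[[`, numeric(1), "velocity") == bv)
        if (length(j) != 1) stop("bootstrap velocity not in grid")
        out <- bootstrap_convergence(
          ens_by_system[[id]][[j]]$events$f_max,
          B = config$bootstrap$B %||% 10000,
          n_grid = unlist(config$bootstrap$n_grid),
          seed = child_seed(config$seed, 10000L))
        write_table_csv(out, file.path(out_dir, paste0("bootstrap_", id, ".csv")),
                        digits = 9)
        out
      })
      names(boot) <- names(ens_by_system)
    }
    hs <- NULL
    if (!is.null(config$hotspots)) {
      stage <- "hotspots"
      message("[bellevans] ", stage)
      h <- config$hotspots
      hs <- classify_hotspots(
        read_residue_decomposition(h$decomp_a), unlist(h$pocket_a),
        read_residue_decomposition(h$decomp_b), unlist(h$pocket_b),
        favorable_threshold = h$threshold %||% -1.00)
      writeLines(c(paste("hotspots:", paste(hs$hotspots, collapse = ", ")),
                   paste("anti-hotspots:", paste(hs$anti_hotspots, collapse = ", "))),
                 file.path(out_dir, "hotspots.txt"))
      write_table_csv(hs$rankings$a, file.path(out_dir, "ranking_a.csv"), digits = 9)
      write_table_csv(hs$rankings$b, file.path(out_dir, "ranking_b.csv"), digits = 9)
    }
    stage <- "manifest"
    yaml::write_yaml(list(seed = config$seed,
                          config = unclass(config)),
                     file.path(out_dir, "manifest.yaml"))
    list(table1 = table1, table2 = table2, fits = fits,
         bootstrap = boot, hotspots = hs)
  }, error = fail)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
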