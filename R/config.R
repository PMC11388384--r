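#' Parse a pipeline configuration file
#'
#' Configurations are YAML with a `stage`, a `seed`, an optional `out_dir`
#' and a stage-specific `params` block. Unknown keys (top-level or inside
#' `params`) are rejected with field-level messages; defaults are filled in
#' and the effective configuration carries a content hash so outputs can be
#' traced to the exact settings that produced them.
#'
#' Stages: `simulate-deff`, `simulate-jeff`, `sweep`, `spt-simulate`,
#' `spt-hist`, `spt-hmm`, `gradient`.
#'
#' @param path Path to a YAML file, or a named list already in memory.
#' @return A `run_config` with elements `stage`, `seed`, `out_dir`,
#'   `params`, `hash`.
#' @export
parse_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  allowed_top <- c("stage", "seed", "out_dir", "params")
  extra <- setdiff(names(raw), allowed_top)
  if (length(extra) > 0)
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  stages <- c("simulate-deff", "simulate-jeff", "sweep", "spt-simulate",
              "spt-hist", "spt-hmm", "gradient")
  if (is.null(raw$stage) || !raw$stage %in% stages)
    stop("config field 'stage' must be one of: ",
         paste(stages, collapse = ", "))
  if (is.null(raw$seed))
    stop("config field 'seed' is required: every stochastic stage needs an explicit seed")
  seed <- as.integer(raw$seed)
  params <- raw$params %||% list()
  allowed <- stage_param_names(raw$stage)
  extra <- setdiff(names(params), allowed)
  if (length(extra) > 0)
    stop("unknown params for stage '", raw$stage, "': ",
         paste(extra, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  if (!is.null(params$k_eq) && (params$k_eq <= 0 || params$k_eq >= 1))
    stop("params.k_eq must lie strictly between 0 and 1")
  eff <- list(stage = raw$stage, seed = seed,
              out_dir = raw$out_dir %||% ".",
              params = params)
  eff$hash <- rlang::hash(eff[c("stage", "seed", "params")])
  class(eff) <- "run_config"
  eff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_param_names <- function(stage) {
  sim <- c("dt_s", "D_free_um2s", "D_con_um2s", "k_eq", "switch_scale",
           "p0", "ratio20", "mode", "cell_edge_um", "arrangement",
           "extent_cells", "n_agents", "n_steps", "source_count")
  switch(stage,
    "simulate-deff" = sim,
    "simulate-jeff" = sim,
    "sweep" = c(sim, "scales", "modes", "protocol"),
    "spt-simulate" = c("frame_dt_s", "n_tracks", "mean_track_len_frames",
                       "sigma_loc_um", "catalysis_factor", "occupancies",
                       "lifetimes_s"),
    "spt-hist" = c("tracks_csv", "window_lengths", "frame_dt_s"),
    "spt-hmm" = c("tracks_csv", "K", "frame_dt_s", "n_restarts", "folds",
                  "jackknife"),
    "gradient" = c("amplitude", "lambda_um", "n_cells", "bin_um", "span_um",
                   "distances_csv"))
}

sim_params_from_config <- function(cfg, mode_default = "topology") {
  p <- cfg$params
  lat <- lattice_spec(
    cell_edge_um = p$cell_edge_um %||% 5,
    arrangement = p$arrangement %||% "monolayer",
    extent_cells = p$extent_cells %||% 200L)
  sim_params(
    dt_s = p$dt_s %||% 0.006,
    D_free_um2s = p$D_free_um2s %||% 1.0,
    D_con_um2s = p$D_con_um2s %||% 0.5,
    k_eq = p$k_eq %||% 0.05,
    switch_scale = p$switch_scale %||% 1.0,
    p0 = p$p0 %||% 0.005,
    ratio20 = p$ratio20 %||% FALSE,
    mode = p$mode %||% mode_default,
    lattice = lat,
    n_agents = p$n_agents %||% 5000L,
    n_steps = p$n_steps %||% 20000L,
    source_count = p$source_count %||% 2000L,
    seed = cfg$seed)
}

write_table_with_header <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s seed=%d hash=%s", cfg$stage, cfg$seed,
                     cfg$hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a configured pipeline stage
#'
#' Executes the configured stage, writes its result tables (tab-separated,
#' with a header comment recording the seed and config hash) into
#' `out_dir`, plus a JSON run manifest (seed, hash, package version, wall
#' time). Given the same configuration and seed, outputs are byte-identical.
#'
#' @param config A `run_config` from [parse_config()] (or a path/list
#'   accepted by it).
#' @return Invisibly, a list of the written file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else parse_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  files <- character(0)
  out <- function(name) file.path(cfg$out_dir, name)
  p <- cfg$params

  if (cfg$stage == "simulate-deff") {
    sp <- sim_params_from_config(cfg)
    est <- estimate_deff(run_msd_protocol(sp))
    df <- data.frame(mode = sp$mode, arrangement = sp$lattice$arrangement,
                     k_eq = sp$k_eq, switch_scale = sp$switch_scale,
                     deff_um2s = est$value, se = est$se,
                     n_agents = sp$n_agents, n_steps = sp$n_steps,
                     seed = sp$seed)
    files <- write_table_with_header(df, out("deff.tsv"), cfg)
  } else if (cfg$stage == "simulate-jeff") {
    sp <- sim_params_from_config(cfg)
    if (is.null(p$n_steps)) sp$n_steps <- 40000L
    est <- run_flux_protocol(sp)
    df <- data.frame(mode = sp$mode, arrangement = sp$lattice$arrangement,
                     k_eq = sp$k_eq, switch_scale = sp$switch_scale,
                     jeff_per_s = est$value, se = est$se,
                     source_count = sp$source_count, n_steps = sp$n_steps,
                     seed = sp$seed)
    files <- write_table_with_header(df, out("jeff.tsv"), cfg)
  } else if (cfg$stage == "sweep") {
    sp <- sim_params_from_config(cfg)
    df <- sweep_transition_scale(
      sp, scales = unlist(p$scales %||% 10^seq(-1, 1, by = 0.5)),
      modes = unlist(p$modes %||% c("classic", "topology")),
      protocol = p$protocol %||% "deff")
    files <- write_table_with_header(df, out("sweep.tsv"), cfg)
  } else if (cfg$stage == "spt-simulate") {
    model <- default_shh_state_model(
      occupancies = unlist(p$occupancies %||% c(0.10, 0.40, 0.30, 0.20)),
      lifetimes_s = unlist(p$lifetimes_s %||% c(0.030, 0.060, 0.060, 0.060)),
      frame_dt_s = p$frame_dt_s %||% 0.006,
      sigma_loc_um = p$sigma_loc_um %||% 0.035)
    if (!is.null(p$catalysis_factor))
      model <- scale_transition_rates(model, p$catalysis_factor)
    acq <- acquisition_spec(frame_dt_s = p$frame_dt_s %||% 0.006,
                            n_tracks = p$n_tracks %||% 1000L,
                            mean_track_len_frames =
                              p$mean_track_len_frames %||% 15)
    tracks <- simulate_tracks(model, acq, seed = cfg$seed)
    write_tracks(tracks, out("tracks.csv"))
    files <- out("tracks.csv")
  } else if (cfg$stage == "spt-hist") {
    tracks <- read_tracks(p$tracks_csv, frame_dt_s = p$frame_dt_s %||% NA)
    h <- diffusion_histograms(
      tracks, window_lengths = unlist(p$window_lengths %||% c(3L, 5L, 8L, 12L)))
    files <- write_table_with_header(h$histogram, out("diffusion_hist.tsv"),
                                     cfg)
  } else if (cfg$stage == "spt-hmm") {
    tracks <- read_tracks(p$tracks_csv, frame_dt_s = p$frame_dt_s %||% NA)
    fit <- fit_state_hmm(tracks, K = p$K %||% 4L,
                         n_restarts = p$n_restarts %||% 5L, seed = cfg$seed)
    df <- data.frame(state = seq_along(fit$D_um2s), D_um2s = fit$D_um2s,
                     occupancy = fit$occupancy, lifetime_s = fit$lifetime_s,
                     sigma_um = fit$sigma_um, loglik = fit$loglik,
                     converged = fit$converged)
    files <- write_table_with_header(df, out("hmm_fit.tsv"), cfg)
    A <- as.data.frame(fit$A)
    names(A) <- paste0("to_", seq_len(ncol(A)))
    files <- c(files, write_table_with_header(
      cbind(from = seq_len(nrow(A)), A), out("hmm_transitions.tsv"), cfg))
    if (isTRUE(p$jackknife)) {
      jk <- jackknife_intervals(
        tracks, function(tr) fit_state_hmm(tr, K = p$K %||% 4L,
                                           n_restarts = 2L,
                                           seed = cfg$seed),
        folds = p$folds %||% 10L, seed = cfg$seed)
      files <- c(files, write_table_with_header(jk$summary,
                                                out("hmm_jackknife.tsv"),
                                                cfg))
    }
  } else if (cfg$stage == "gradient") {
    if (!is.null(p$distances_csv)) {
      dd <- utils::read.csv(p$distances_csv)
      sets <- split(dd$distance_um, dd$cell_id)
    } else {
      sets <- simulate_gradient_particles(
        amplitude = p$amplitude %||% 50, lambda_um = p$lambda_um %||% 17,
        n_cells = p$n_cells %||% 30, bin_um = p$bin_um %||% 3,
        seed = cfg$seed)
    }
    max_um <- (p$bin_um %||% 3) *
      ceiling(max(unlist(sets), 1) / (p$bin_um %||% 3) + 1e-9)
    profiles <- lapply(sets, radial_particle_counts,
                       bin_um = p$bin_um %||% 3, max_um = max_um)
    profiles <- lapply(profiles, smooth_profile, span_um = p$span_um %||% 9)
    meta <- meta_gradient(profiles, use = "count")
    fit <- fit_exponential_gradient(
      structure(data.frame(bin_center_um = meta$bin_center_um,
                           count = meta$mean, smoothed = meta$mean),
                class = c("radial_profile", "data.frame"),
                bin_um = p$bin_um %||% 3, n_cells = length(profiles)))
    files <- write_table_with_header(meta, out("meta_gradient.tsv"), cfg)
    fd <- data.frame(amplitude = fit$amplitude, lambda_um = fit$lambda_um,
                     baseline = fit$baseline,
                     half_decay_um = fit$half_decay_um,
                     no_gradient = fit$no_gradient)
    files <- c(files, write_table_with_header(fd, out("gradient_fit.tsv"),
                                              cfg))
  }

  manifest <- list(stage = cfg$stage, seed = cfg$seed, hash = cfg$hash,
                   package_version =
                     as.character(utils::packageVersion("topolimit")),
                   wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
                   files = basename(files))
  mpath <- out("manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, mpath))
}
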