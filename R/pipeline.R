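#' Default pipeline configuration
#'
#' Returns the full configuration list of [run_pipeline()] with every
#' stage's parameters at its default. Any element can be overridden via
#' `...` (nested lists are merged shallowly per stage).
#'
#' @param ... Named overrides, e.g. `synth = list(n_subjects = 4)`.
#' @return Named list with components `synth`, `preprocess`, `connectivity`,
#'   `graph`, `stats`, `seed`.
#' @export
default_config <- function(...) {
  cfg <- list(
    synth = list(
      n_subjects = 10, tests = paste0("T", 1:4), scenarios = paste0("L", 0:3),
      trials_per_scenario = 4, n_channels = 24, sample_rate = 1000,
      duration = 60, rest_duration = 120, noise_sd = 1,
      effect_map = NULL
    ),
    preprocess = list(
      band = c(0.5, 48), target_rate = 250, min_segment_s = 30,
      alpha_window = c(7.5, 12.5)
    ),
    connectivity = list(trim_s = 1, method = "pool"),
    graph = list(n_surrogates = 100),
    stats = list(exclude_scenarios = "L3", alpha = 0.05),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror [default_config()].
#' @return Configuration list (defaults filled in for absent keys).
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full synthetic-study pipeline
#'
#' Simulate -> preprocess -> individualized theta band -> wPLI connectivity
#' -> median-threshold graphs -> graph metrics -> repeated-measures ANOVA,
#' writing tidy CSV outputs, a log and a JSON manifest into `out_dir`. The
#' manifest (config, package version, seed) is sufficient to regenerate
#' every output bit-identically.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @param out_dir Output directory (created if missing).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory stage outputs
#'   (`connectivity`, `metrics`, `metrics_nodes`, `anova`, `iapf`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run_"),
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(line)
  }

  logf("stage simulate: %d subjects, %d tests x %d scenarios x %d trials",
       config$synth$n_subjects, length(config$synth$tests),
       length(config$synth$scenarios), config$synth$trials_per_scenario)
  design <- study_design(
    n_subjects = config$synth$n_subjects, tests = config$synth$tests,
    scenarios = config$synth$scenarios,
    trials_per_scenario = config$synth$trials_per_scenario,
    effect_map = config$synth$effect_map,
    n_channels = config$synth$n_channels,
    sample_rate = config$synth$sample_rate,
    duration = config$synth$duration,
    rest_duration = config$synth$rest_duration,
    noise_sd = config$synth$noise_sd, seed = config$seed)
  study <- generate_study(design)
  labels <- study$labels

  pp <- config$preprocess
  target_rate <- pp$target_rate
  logf("stage preprocess: band %g-%g Hz, %g -> %g Hz, min segment %g s",
       pp$band[1], pp$band[2], config$synth$sample_rate, target_rate,
       pp$min_segment_s)

  # session iAPF and theta band per (subject, test)
  iapf_rows <- list()
  theta_of <- list()
  for (s in seq_len(design$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (tlab in design$tests) {
      profs <- lapply(1:2, function(k) {
        r <- study$rest[[sprintf("%s_%s_rest%d", sid, tlab, k)]]
        r <- bandpass_and_decimate(r, pp$band, target_rate)
        estimate_iapf_cog(r, pp$alpha_window)
      })
      ia <- session_iapf(profs[[1]], profs[[2]])
      theta_of[[paste(sid, tlab)]] <- theta_band(ia)
      iapf_rows[[length(iapf_rows) + 1L]] <- data.frame(
        subject = sid, test = tlab, iapf = ia,
        theta_low = 4, theta_high = 0.8 * ia, stringsAsFactors = FALSE)
    }
  }
  iapf_tab <- do.call(rbind, iapf_rows)
  utils::write.csv(iapf_tab, file.path(out_dir, "iapf.csv"), row.names = FALSE)

  # connectivity per (subject, test, scenario), pooling trial segments
  logf("stage connectivity: wPLI in individualized theta bands (%s aggregation)",
       config$connectivity$method)
  conn <- list()
  kept <- 0L
  dropped <- 0L
  conds <- unique(labels[, c("subject", "test", "scenario")])
  for (r in seq_len(nrow(conds))) {
    sid <- conds$subject[r]; tlab <- conds$test[r]; slab <- conds$scenario[r]
    ids <- labels$id[labels$subject == sid & labels$test == tlab &
                       labels$scenario == slab]
    band <- theta_of[[paste(sid, tlab)]]
    segs <- list()
    for (id in ids) {
      rec <- bandpass_and_decimate(study$task[[id]], pp$band, target_rate)
      pieces <- withCallingHandlers(
        segment_by_events(rec, pp$min_segment_s),
        message = function(m) invokeRestart("muffleMessage"))
      dropped <- dropped + (nrow(rec$events) - length(pieces))
      for (p in pieces) {
        segs[[length(segs) + 1L]] <- analytic_signals(p, band,
                                                      config$connectivity$trim_s)
        kept <- kept + 1L
      }
    }
    conn[[paste(sid, tlab, slab, sep = "_")]] <- connectivity_matrix(
      segs, labels = study$task[[ids[1]]]$channel_labels, band = band,
      condition = list(subject = sid, test = tlab, scenario = slab),
      method = config$connectivity$method)
  }
  logf("  segments kept: %d, discarded: %d", kept, dropped)
  conn_long <- do.call(rbind, lapply(conn, function(cm) {
    ut <- which(upper.tri(cm$values), arr.ind = TRUE)
    data.frame(subject = cm$condition$subject, test = cm$condition$test,
               scenario = cm$condition$scenario,
               ch_i = cm$channel_labels[ut[, 1]],
               ch_j = cm$channel_labels[ut[, 2]],
               wpli = cm$values[ut], stringsAsFactors = FALSE)
  }))
  utils::write.csv(conn_long, file.path(out_dir, "connectivity.csv"),
                   row.names = FALSE)

  # graphs: per-(subject, test) pooled median threshold, then metrics
  logf("stage graph: median threshold per (subject, test), %d surrogates",
       config$graph$n_surrogates)
  met_rows <- list()
  node_rows <- list()
  unreach_total <- 0L
  for (s in seq_len(design$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (ti in seq_along(design$tests)) {
      tlab <- design$tests[ti]
      group <- conn[paste(sid, tlab, design$scenarios, sep = "_")]
      thr <- median_threshold(group)
      for (si in seq_along(design$scenarios)) {
        slab <- design$scenarios[si]
        g <- binarize(group[[si]], thr)
        gm <- graph_metrics(g, n_surrogates = config$graph$n_surrogates,
                            seed = derive_seed(config$seed, s, ti, si, 7L))
        unreach_total <- unreach_total + gm$unreachable_pairs
        met_rows[[length(met_rows) + 1L]] <- data.frame(
          subject = sid, test = tlab, scenario = slab,
          density = g$density, threshold = thr,
          L = gm$L, E_global = gm$E_global, E_local = gm$E_local_mean,
          C = gm$C, gamma = gm$gamma, lambda = gm$lambda, sigma = gm$sigma,
          unreachable_pairs = gm$unreachable_pairs, stringsAsFactors = FALSE)
        node_rows[[length(node_rows) + 1L]] <- data.frame(
          subject = sid, test = tlab, scenario = slab,
          channel = names(gm$E_local_per_node),
          E_local = unname(gm$E_local_per_node), stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, met_rows)
  metrics_nodes <- do.call(rbind, node_rows)
  logf("  unreachable ordered pairs excluded from L (total): %d", unreach_total)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(metrics_nodes, file.path(out_dir, "metrics_nodes.csv"),
                   row.names = FALSE)

  # statistics: RM-ANOVA per network metric, configured scenarios excluded
  st <- config$stats
  keep <- !(metrics$scenario %in% st$exclude_scenarios)
  logf("stage stats: scenarios excluded: %s",
       paste(st$exclude_scenarios, collapse = ", "))
  anova_rows <- list()
  if (config$synth$n_subjects >= 3) {
    for (metric in c("E_global", "E_local", "sigma")) {
      dat <- metrics[keep, c("subject", "test", "scenario", metric)]
      names(dat)[4] <- "value"
      if (anyNA(dat$value)) {
        logf("  %s skipped: missing values (surrogate normalizers unavailable)",
             metric)
        next
      }
      res <- rm_anova_2way(dat)
      res$metric <- metric
      anova_rows[[metric]] <- res
    }
  } else {
    logf("  skipped: fewer than 3 subjects")
  }
  anova_tab <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL
  if (!is.null(anova_tab)) {
    utils::write.csv(anova_tab, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "thetanet",
    version = as.character(utils::packageVersion("thetanet")),
    seed = config$seed,
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  logf("run complete: %s", out_dir)
  invisible(list(connectivity = conn, conn_long = conn_long,
                 metrics = metrics, metrics_nodes = metrics_nodes,
                 anova = anova_tab, iapf = iapf_tab, out_dir = out_dir))
}

#' Summarize a completed pipeline run
#'
#' Reads the CSV outputs of [run_pipeline()] and returns per-condition
#' means of the network metrics plus the ANOVA table; optionally draws a
#' scalp map of per-channel local efficiency.
#'
#' @param out_dir Run directory written by [run_pipeline()].
#' @return list with `condition_means` (test x scenario means of E_global,
#'   E_local, sigma), `anova` (or NULL), `iapf`.
#' @export
summarize_run <- function(out_dir) {
  need <- c("metrics.csv", "iapf.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    stop("incomplete run; missing: ", paste(missing, collapse = ", "))
  }
  metrics <- utils::read.csv(file.path(out_dir, "metrics.csv"))
  agg <- stats::aggregate(metrics[, c("E_global", "E_local", "sigma")],
                          by = list(test = metrics$test,
                                    scenario = metrics$scenario), FUN = mean)
  anova_path <- file.path(out_dir, "anova.csv")
  anova_tab <- if (file.exists(anova_path)) utils::read.csv(anova_path) else NULL
  list(condition_means = agg[order(agg$test, agg$scenario), ],
       anova = anova_tab,
       iapf = utils::read.csv(file.path(out_dir, "iapf.csv")))
}

#' Scalp scatter map of per-channel values
#'
#' Draws the montage electrodes on a schematic head circle, colouring each
#' point by `values` — a minimal topographic rendering for per-channel
#' local efficiency.
#'
#' @param values Named numeric vector; names must match montage channels.
#' @param layout Electrode layout data.frame from [montage_layout()].
#' @param main Plot title.
#' @export
plot_scalp <- function(values, layout = montage_layout(), main = "") {
  stopifnot(!is.null(names(values)))
  idx <- match(layout$channel, names(values))
  v <- values[idx]
  pal <- grDevices::hcl.colors(64, "viridis")
  col_idx <- if (diff(range(v, na.rm = TRUE)) == 0) rep(32L, length(v)) else
    as.integer(cut(v, breaks = 64))
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::lines(c(-0.08, 0, 0.08), c(0.997, 1.08, 0.997))  # nose
  graphics::points(layout$x, layout$y, pch = 21, cex = 2.2,
                   bg = pal[col_idx])
  graphics::text(layout$x, layout$y - 0.11, layout$channel, cex = 0.55)
  invisible(NULL)
}
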