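#' Default pipeline run configuration
#'
#' Nested list of every stage toggle and parameter, with the package
#' defaults. [run_pipeline()] merges a user configuration (R list or YAML
#' file) onto this template; unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "cycloc_run",
    input = list(manifest = NULL),
    stages = list(simulate = TRUE, preprocess = TRUE, minmax = TRUE,
                  occupancy = TRUE, depth = TRUE),
    simulate = list(
      image_shape = c(256L, 256L), n_sites = 300L, n_domains = 40L,
      channel_affinities = c(0.9, 0.9, 0.9), background_site_rate = 60L,
      label_prob = 0.9, residual_fraction = 0.055, round_gain = 1.15,
      psf_sigma = 1.5, spot_amplitude = 12000, noise_sigma = 40,
      background_amplitude = 1500, drift_per_round = c(2, -1),
      domain_sigma = 2, n_rounds = 3L),
    background = list(radius = 50),
    register = list(subpixel = FALSE, reference_channel = NULL),
    minmax = list(round_a = 1L, round_b = 3L, channel = NULL,
                  n_bins = 64L, pseudocount = 1),
    occupancy = list(round = 1L, sweep_from = 0.01, sweep_to = 0.95,
                     sweep_by = 0.01),
    depth = list(bin_width = 1, smooth_sigma = 2))
}

# Merge user config onto defaults, rejecting unknown keys at any level.
merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    where <- if (length(path)) paste0(" under '", paste(path, collapse = "."), "'") else ""
    stop("unknown configuration key", if (length(unknown) > 1) "s", where,
         ": ", paste(unknown, collapse = ", "))
  }
  for (key in names(user)) {
    defaults[[key]] <- if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      merge_config(defaults[[key]], user[[key]], c(path, key))
    } else user[[key]]
  }
  defaults
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [default_run_config()]
#'   keys.
#' @return Full configuration list (defaults filled in).
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

pipeline_log <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
}

run_stage <- function(name, log_path, fun) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(fun(), error = function(e) {
    pipeline_log(log_path, "stage ", name, " FAILED: ", conditionMessage(e))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  pipeline_log(log_path, "stage ", name, " done in ",
               sprintf("%.2f s", proc.time()[["elapsed"]] - t0))
  result
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> minmax / occupancy / depth with a
#' single configuration and seed, writing all artifacts (TIFFs, manifest,
#' CSV tables, a YAML config echo, a JSON summary and a text log) into
#' `output_dir`. Given the same configuration and seed the CSV/JSON
#' outputs are byte-identical across runs. When the simulate stage is
#' disabled an input manifest must point at an existing dataset.
#'
#' @param config a configuration list (any subset of
#'   [default_run_config()]), or a path to a YAML file of one.
#' @return Invisibly, a list with the run `summary` and the paths of the
#'   written artifacts.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  pipeline_log(log_path, "cycloc ", as.character(utils::packageVersion("cycloc")),
               " | R ", R.version$major, ".", R.version$minor,
               " | seed ", cfg$seed)
  yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"))
  summary <- list(seed = cfg$seed)
  post_imgs <- NULL

  # --- simulate or load ------------------------------------------------
  if (isTRUE(cfg$stages$simulate)) {
    sim <- run_stage("simulate", log_path, function() {
      sc <- cfg$simulate
      conf <- scene_config(
        image_shape = sc$image_shape, n_sites = sc$n_sites,
        n_domains = sc$n_domains, channel_affinities = sc$channel_affinities,
        background_site_rate = sc$background_site_rate,
        label_prob = sc$label_prob, residual_fraction = sc$residual_fraction,
        round_gain = sc$round_gain, psf_sigma = sc$psf_sigma,
        spot_amplitude = sc$spot_amplitude, noise_sigma = sc$noise_sigma,
        background_amplitude = sc$background_amplitude,
        drift_per_round = sc$drift_per_round, domain_sigma = sc$domain_sigma,
        seed = cfg$seed)
      out <- simulate_dataset(conf, n_rounds = sc$n_rounds,
                              post_elution = TRUE)
      write_dataset(out$dataset, file.path(out_dir, "images"))
      out
    })
    ds <- sim$dataset
    post_imgs <- sim$post_elution
  } else {
    ds <- run_stage("load", log_path, function() {
      if (is.null(cfg$input$manifest)) {
        stop("no input manifest and simulate stage disabled")
      }
      read_dataset(cfg$input$manifest)
    })
  }
  channels <- ds$channels
  ref_channel <- cfg$register$reference_channel
  if (is.null(ref_channel)) ref_channel <- channels[1]

  # --- preprocess ------------------------------------------------------
  valid <- array(TRUE, dim = ds$shape)
  proc <- ds$images
  if (isTRUE(cfg$stages$preprocess)) {
    pre <- run_stage("preprocess", log_path, function() {
      proc_imgs <- lapply(ds$images, rolling_ball_subtract,
                          radius = cfg$background$radius)
      ref_img <- proc_imgs[[dataset_key(1, ref_channel)]]
      vmask <- array(TRUE, dim = ds$shape)
      shifts <- list()
      for (r in ds$rounds) {
        if (r == 1) { shifts[[r]] <- c(0, 0); next }
        reg <- register_rounds(ref_img, proc_imgs[[dataset_key(r, ref_channel)]],
                               subpixel = isTRUE(cfg$register$subpixel))
        shifts[[r]] <- reg$shift
        for (ch in channels) {
          al <- apply_shift(proc_imgs[[dataset_key(r, ch)]], -reg$shift)
          proc_imgs[[dataset_key(r, ch)]] <- al$image
        }
        al_mask <- apply_shift(matrix(1, ds$shape[1], ds$shape[2]), -reg$shift)
        vmask <- vmask & al_mask$valid
      }
      list(images = proc_imgs, valid = vmask, shifts = shifts)
    })
    proc <- pre$images
    valid <- pre$valid
    shift_df <- do.call(rbind, lapply(ds$rounds, function(r) {
      data.frame(round = r, dy = pre$shifts[[r]][1], dx = pre$shifts[[r]][2])
    }))
    write_table(shift_df, file.path(out_dir, "registration.csv"))
  }

  # --- minmax round comparison ----------------------------------------
  if (isTRUE(cfg$stages$minmax)) {
    mm <- run_stage("minmax", log_path, function() {
      ch <- cfg$minmax$channel
      if (is.null(ch)) ch <- ref_channel
      a <- proc[[dataset_key(cfg$minmax$round_a, ch)]]
      b <- proc[[dataset_key(cfg$minmax$round_b, ch)]]
      b_eq <- equalize_means(a, b, mask = valid)
      res <- minmax_decompose(a, b_eq, mask = valid,
                              n_bins = cfg$minmax$n_bins,
                              pseudocount = cfg$minmax$pseudocount)
      tiff::writeTIFF(list(pmin(res$shared, 65535) / 65535,
                           pmin(res$difference, 65535) / 65535),
                      file.path(out_dir, "minmax_composite.tif"),
                      bits.per.sample = 16L)
      write_table(data.frame(bin_center = res$ratio_histogram$mids,
                             count = res$ratio_histogram$counts),
                  file.path(out_dir, "ratio_histogram.csv"))
      res
    })
    efficiency <- NA_real_
    if (!is.null(post_imgs)) {
      ch <- cfg$minmax$channel
      if (is.null(ch)) ch <- ref_channel
      ch_i <- match(ch, channels)
      pre_img <- rolling_ball_subtract(
        ds$images[[dataset_key(1, ch)]], radius = cfg$background$radius)
      post_img <- rolling_ball_subtract(
        post_imgs[[1]][[ch_i]], radius = cfg$background$radius)
      efficiency <- elution_efficiency(pre_img, post_img, mask = valid)
    }
    write_table(data.frame(pearson_r = mm$pearson_r,
                           elution_efficiency_pct = efficiency),
                file.path(out_dir, "minmax_summary.csv"))
    summary$pearson_r <- mm$pearson_r
    summary$elution_efficiency_pct <- efficiency
  }

  # --- occupancy statistics -------------------------------------------
  if (isTRUE(cfg$stages$occupancy)) {
    occ <- run_stage("occupancy", log_path, function() {
      r <- cfg$occupancy$round
      imgs <- lapply(channels, function(ch) proc[[dataset_key(r, ch)]])
      thr <- vapply(imgs, function(im) otsu_threshold(im, mask = valid), 0)
      masks <- lapply(seq_along(imgs), function(i) imgs[[i]] > thr[i])
      tab <- build_occupancy_table(masks, valid = valid,
                                   channel_names = channels,
                                   thresholds = thr)
      test <- chi2_mutual_independence(tab)
      sweep <- exceedance_sweep(
        imgs, percentiles = seq(cfg$occupancy$sweep_from,
                                cfg$occupancy$sweep_to,
                                by = cfg$occupancy$sweep_by),
        valid = valid, channel_names = channels)
      write_table(as.data.frame(tab), file.path(out_dir, "occupancy_table.csv"))
      write_table(data.frame(statistic = test$statistic, df = test$df,
                             p_value = test$p_value, n_pixels = test$n_pixels,
                             min_expected = test$min_expected),
                  file.path(out_dir, "chi2_summary.csv"))
      write_table(sweep$curve, file.path(out_dir, "exceedance_curve.csv"))
      list(table = tab, test = test, sweep = sweep)
    })
    summary$chi2_statistic <- occ$test$statistic
    summary$chi2_df <- occ$test$df
    summary$chi2_p_value <- occ$test$p_value
  }

  # --- depth profile ---------------------------------------------------
  if (isTRUE(cfg$stages$depth)) {
    dp <- run_stage("depth", log_path, function() {
      r <- 1L
      total <- Reduce(`+`, lapply(channels,
                                  function(ch) proc[[dataset_key(r, ch)]]))
      mask <- make_cell_mask(total, smooth_sigma = cfg$depth$smooth_sigma)
      if (!any(mask) || all(mask)) {
        stop("degenerate specimen mask; supply a mask or adjust smoothing")
      }
      dist <- exterior_distance_map(mask)
      prof <- profile_by_depth(total, dist, bin_width = cfg$depth$bin_width)
      write_table(prof$profile, file.path(out_dir, "depth_profile.csv"))
      prof
    })
    summary$depth_bins <- nrow(dp$profile)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(log_path, "run complete")
  invisible(list(summary = summary, output_dir = out_dir))
}
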