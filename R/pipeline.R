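#' Declarative run configuration
#'
#' One document holding every module's settings (grid, physics constants,
#' sequence, dictionary, phantom, reconstruction, seeds). A content hash of
#' the configuration travels with every artifact the pipeline writes, so any
#' output is traceable to the exact configuration that produced it.
#'
#' @param ... named settings overriding the defaults (nested lists are
#'   merged shallowly per section).
#' @param file optional YAML file to read settings from (overridden by
#'   `...`).
#' @return A `vmrf_config` list with a `hash` attribute.
#' @export
run_config <- function(..., file = NULL) {
  defaults <- list(
    grid = list(shape = c(32, 32, 48), spacing = 2.5),
    physics = list(
      b0_tesla = 4.7, dchi_deoxy_ppm = 3.318, hct = 0.42,
      dchi_ca_ppm = 0.5, adc = 1000
    ),
    sequence = list(
      tr_ms = 4000, n_echoes = 32, delta_te_ms = 3.3, se_ms = 60,
      dt_sim_ms = 0.3
    ),
    dictionary = list(
      n = 200, family = "cylinders",
      bvf_range = c(0.5, 12), radius_range = c(2, 10),
      so2_range = c(35, 90), t2_range = c(45, 110)
    ),
    phantom = list(
      enabled = TRUE, snr = 30,
      regions = list(
        list(region = 1, name = "contra", bvf = 3, radius = 5, so2 = 70, t2 = 65),
        list(region = 2, name = "tumor", bvf = 8, radius = 7, so2 = 80, t2 = 80)
      ),
      nx = 8, ny = 8
    ),
    recon = list(methods = c("dbm", "dbl"), n_components = 12),
    seed = 1L
  )
  # like modifyList, but an unnamed list (e.g. the region list) replaces the
  # default wholesale instead of being silently ignored
  merge_cfg <- function(base, override) {
    for (nm in names(override)) {
      both_named <- is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])) && !is.null(names(override[[nm]]))
      base[[nm]] <- if (both_named) {
        merge_cfg(base[[nm]], override[[nm]])
      } else {
        override[[nm]]
      }
    }
    base
  }
  # YAML 1.1 reads a bare `n:` mapping key as boolean FALSE; restore it so
  # config files can say `n: 200` without quoting the key
  fix_yaml_keys <- function(x) {
    if (!is.list(x)) return(x)
    nms <- names(x)
    if (!is.null(nms)) names(x) <- ifelse(nms == "FALSE", "n", nms)
    lapply(x, fix_yaml_keys)
  }
  cfg <- defaults
  if (!is.null(file)) {
    cfg <- merge_cfg(cfg, fix_yaml_keys(yaml::read_yaml(file)))
  }
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_cfg(cfg, overrides)
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "vmrf_config"
  cfg
}

config_hash <- function(config) attr(config, "hash")

log_line <- function(log_path, stage, hash, ...) {
  rec <- c(
    list(
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      stage = stage, config_hash = hash
    ),
    list(...)
  )
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
    file = log_path, append = TRUE, sep = ""
  )
}

#' Run the end-to-end fingerprinting pipeline
#'
#' Executes geometry generation, dictionary build, (optionally) phantom
#' simulation, reconstruction by the configured methods, and ROI statistics
#' comparing the phantom regions. All intermediates are written under
#' `out_dir` together with the configuration, its content hash, and a
#' JSON-lines log of stages, timings and seeds. Reruns with the same
#' configuration are deterministic.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param steps which stages to run; later stages load earlier artifacts
#'   from `out_dir` and fail cleanly, naming the missing file, if a required
#'   artifact is absent.
#' @return Invisibly, a list of the in-memory artifacts (dictionary, model,
#'   phantom, maps, roi stats).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         steps = c("dictionary", "phantom", "recon", "stats")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run_log.jsonl")
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  writeLines(hash, file.path(out_dir, "config.hash"))

  grid <- grid_spec(config$grid$shape, config$grid$spacing)
  physics <- do.call(physics_constants, config$physics)
  seqspec <- do.call(sequence_spec, config$sequence)
  dict_path <- file.path(out_dir, "dictionary.vdict")
  out <- list(config = config)

  if ("dictionary" %in% steps) {
    t0 <- Sys.time()
    dict <- make_dictionary(
      n = config$dictionary$n, family = config$dictionary$family, grid = grid,
      bvf_range = config$dictionary$bvf_range,
      radius_range = config$dictionary$radius_range,
      so2_range = config$dictionary$so2_range,
      t2_range = config$dictionary$t2_range,
      seq = seqspec, physics = physics, seed = config$seed
    )
    save_dictionary(dict, dict_path)
    utils::write.csv(dict$params, file.path(out_dir, "dictionary_params.csv"),
      row.names = FALSE
    )
    log_line(log_path, "dictionary", hash,
      n = nrow(dict$params),
      seed = config$seed, seconds = as.numeric(Sys.time() - t0, units = "secs")
    )
    out$dictionary <- dict
  }

  phantom_path <- file.path(out_dir, "phantom.rds")
  if ("phantom" %in% steps && isTRUE(config$phantom$enabled)) {
    t0 <- Sys.time()
    regions <- dplyr::bind_rows(lapply(config$phantom$regions, as_tibble))
    region_map <- matrix(1L, config$phantom$nx, config$phantom$ny)
    cx <- seq(max(1, config$phantom$nx %/% 4 + 1), length.out = max(1, config$phantom$nx %/% 2))
    cy <- seq(max(1, config$phantom$ny %/% 4 + 1), length.out = max(1, config$phantom$ny %/% 2))
    region_map[cx, cy] <- 2L
    ph <- make_phantom(
      regions = regions, region_map = region_map, snr = config$phantom$snr,
      grid = grid, seq = seqspec, physics = physics,
      family = config$dictionary$family, seed = config$seed + 1L,
      dict_ranges = list(
        bvf = config$dictionary$bvf_range, radius = config$dictionary$radius_range,
        so2 = config$dictionary$so2_range, t2 = config$dictionary$t2_range
      )
    )
    saveRDS(ph, phantom_path)
    write_series_nifti(ph$series, file.path(out_dir, "phantom_series.nii.gz"))
    utils::write.csv(ph$truth, file.path(out_dir, "phantom_truth.csv"), row.names = FALSE)
    log_line(log_path, "phantom", hash,
      voxels = nrow(ph$truth), snr = config$phantom$snr,
      seconds = as.numeric(Sys.time() - t0, units = "secs")
    )
    out$phantom <- ph
  }

  if ("recon" %in% steps) {
    if (!file.exists(dict_path)) {
      abort(sprintf("reconstruction needs the dictionary artifact, but %s is missing", dict_path))
    }
    if (!file.exists(phantom_path)) {
      abort(sprintf("reconstruction needs the phantom artifact, but %s is missing", phantom_path))
    }
    dict <- out$dictionary %||% load_dictionary(dict_path)
    ph <- out$phantom %||% readRDS(phantom_path)
    for (method in config$recon$methods) {
      t0 <- Sys.time()
      ref <- if (method == "dbl") {
        model <- dbl_train(dict,
          n_components = config$recon$n_components,
          seed = config$seed + 2L
        )
        out$dbl_model <- model
        model
      } else {
        dict
      }
      maps <- reconstruct_maps(ph$series, ref, method = method)
      out[[paste0("maps_", method)]] <- maps
      write_maps_nifti(maps, file.path(out_dir, paste0("maps_", method)))
      utils::write.csv(tidy(maps),
        file.path(out_dir, paste0("maps_", method, ".csv")),
        row.names = FALSE
      )
      log_line(log_path, paste0("recon_", method), hash,
        voxels = maps$provenance$n_voxels,
        seconds = as.numeric(Sys.time() - t0, units = "secs")
      )
    }
  }

  if ("stats" %in% steps) {
    ph <- out$phantom %||% (if (file.exists(phantom_path)) readRDS(phantom_path) else NULL)
    if (is.null(ph)) {
      abort(sprintf("ROI statistics need the phantom artifact, but %s is missing", phantom_path))
    }
    stats_rows <- list()
    for (method in config$recon$methods) {
      maps <- out[[paste0("maps_", method)]]
      if (is.null(maps)) next
      est <- tidy(maps)
      est$region <- as.integer(ph$region_map[cbind(est$x, est$y)])
      # each image row is treated as one unit for the per-unit averaging
      est$unit <- est$x
      for (p in c("bvf", "radius", "so2", "t2")) {
        rc <- roi_compare(est, p, "region", "unit")
        rc$method <- method
        stats_rows[[length(stats_rows) + 1]] <- rc
      }
    }
    if (length(stats_rows)) {
      roi_stats <- dplyr::bind_rows(stats_rows)
      utils::write.csv(roi_stats, file.path(out_dir, "roi_stats.csv"), row.names = FALSE)
      out$roi_stats <- roi_stats
      log_line(log_path, "stats", hash, rows = nrow(roi_stats))
    }
  }

  invisible(out)
}
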