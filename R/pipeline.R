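# Orchestration: YAML configuration with validated defaults, stage-wise
# execution with manifests, JSON-lines logging, config-hash resumability
# and a single seed fanned out to per-stage derived seeds.

config_schema <- function() {
  list(
    seed = 1L,
    out_dir = "maaseg_run",
    synth = list(n_tiles = 4L, width = 775L, height = 522L, n_glands = 6L,
                 radius_min = 30, radius_max = 60, lumen_ratio = 0.5,
                 axis_ratio_min = 0.6, axis_ratio_max = 1, noise_sigma = 0),
    tiling = list(patch_size = 112L, stride = 56L),
    encoder = list(preset = "tiny", channels = NULL, heads = NULL,
                   reduction = NULL, blocks_per_layer = 2L),
    maf = list(fuse_layers = c(3L, 5L, 6L), common_dim = 32L, epochs = 200L,
               batch_size = 16L, lr = 0.002, augment = TRUE),
    affinity = list(beta_low = 0.3, beta_high = 0.6, r = 8, beta_power = 8,
                    walk_iters = 4L, par_iters = 10L, epochs = 30L,
                    lr = 0.01, hidden = 64L, embed_dim = 8L,
                    max_pairs = 1500L),
    segmentation = list(iterations = 10000L, batch_size = 32L, lr = 5e-4,
                        channels = c(16L, 32L), ppm_dim = 8L, oeem = TRUE,
                        oeem_scope = "image", augment = TRUE),
    eval = list(sd_type = "sample")
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a named list), fills defaults (patch 112,
#' stride 56, beta_low 0.3, beta_high 0.6, r 8, learning rates
#' 0.002/0.0005, batch sizes 16/32) and rejects unknown keys and invalid
#' values.
#'
#' @param x Path to a YAML file, a named list, or `NULL` for pure
#'   defaults.
#' @return Normalized configuration list of class `run_config`.
#' @export
validate_config <- function(x = NULL) {
  user <- if (is.null(x)) {
    list()
  } else if (is.character(x)) {
    yaml::read_yaml(x) %||% list()
  } else if (is.list(x)) {
    x
  } else {
    stop_maaseg("config must be a YAML path or a named list",
                class = "maaseg_config_error")
  }
  schema <- config_schema()
  check_keys <- function(user, schema, path) {
    unknown <- setdiff(names(user), names(schema))
    if (length(unknown)) {
      stop_maaseg("unknown config key: ",
                  paste0(path, unknown, collapse = ", "),
                  class = "maaseg_config_error")
    }
    for (nm in names(user)) {
      if (is.list(schema[[nm]]) && !is.null(names(schema[[nm]]))) {
        if (!is.list(user[[nm]])) {
          stop_maaseg("config key ", path, nm, " must be a mapping",
                      class = "maaseg_config_error")
        }
        check_keys(user[[nm]], schema[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check_keys(user, schema, "")
  cfg <- utils::modifyList(schema, user)
  if (cfg$affinity$beta_low >= cfg$affinity$beta_high) {
    stop_maaseg("affinity.beta_low must be below affinity.beta_high",
                class = "maaseg_config_error")
  }
  if (cfg$affinity$beta_low <= 0 || cfg$affinity$beta_high >= 1) {
    stop_maaseg("affinity thresholds must lie in (0, 1)",
                class = "maaseg_config_error")
  }
  if (cfg$tiling$patch_size < 1L || cfg$tiling$stride < 1L ||
      cfg$tiling$stride > cfg$tiling$patch_size) {
    stop_maaseg("tiling.stride must lie in [1, patch_size]",
                class = "maaseg_config_error")
  }
  if (cfg$affinity$r < 1) {
    stop_maaseg("affinity.r must be >= 1", class = "maaseg_config_error")
  }
  # exercise the encoder config checks early
  encoder_config(cfg$encoder$preset, cfg$encoder$channels, cfg$encoder$heads,
                 cfg$encoder$reduction, cfg$encoder$blocks_per_layer)
  class(cfg) <- c("run_config", "list")
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

log_stage <- function(out_dir, stage, elapsed, hash) {
  line <- jsonlite::toJSON(list(stage = stage,
                                elapsed_s = round(elapsed, 3),
                                config_hash = hash,
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(out_dir, "pipeline.log.jsonl"),
      append = TRUE)
}

# Run `fn` unless the stage's manifest says it already ran under the same
# configuration hash; the manifest records where the artifacts live.
run_stage <- function(out_dir, stage, cfg_slice, fn) {
  hash <- config_hash(cfg_slice)
  marker <- file.path(out_dir, paste0(stage, ".done.json"))
  if (file.exists(marker)) {
    prev <- jsonlite::read_json(marker)
    if (identical(prev$config_hash, hash) &&
        all(vapply(unlist(prev$artifacts), file.exists, logical(1)))) {
      return(invisible(NULL))
    }
  }
  t0 <- proc.time()[["elapsed"]]
  artifacts <- fn()
  log_stage(out_dir, stage, proc.time()[["elapsed"]] - t0, hash)
  jsonlite::write_json(list(stage = stage, config_hash = hash,
                            artifacts = as.list(artifacts)),
                       marker, auto_unbox = TRUE)
  invisible(NULL)
}

#' Save / load a model checkpoint
#'
#' Checkpoints store a version tag, the rebuild configuration and all
#' parameter values; loading reconstructs the model and restores the
#' parameters.
#'
#' @param model A `maf_model`, `affinity_head` or `psp_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  type <- class(model)[1L]
  meta <- switch(type,
    maf_model = list(encoder = model$encoder$config,
                     fuse_layers = model$fuse_layers,
                     common_dim = model$common_dim, norm = model$norm),
    affinity_head = list(feature_dim = model$feature_dim,
                         hidden = ncol(model$fc1$W$value),
                         embed_dim = model$embed_dim),
    psp_model = list(channels = model$channels, ppm_dim = model$ppm_dim,
                     ppm_bins = model$ppm_bins, norm = model$norm),
    stop_maaseg("unknown model type: ", type, class = "maaseg_value_error"))
  saveRDS(list(version = "maaseg-checkpoint-1", type = type, meta = meta,
               values = params_values(unclass(model))), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the reconstructed model.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$version, "maaseg-checkpoint-1")) {
    stop_maaseg("unsupported checkpoint version", class = "maaseg_value_error")
  }
  model <- switch(ck$type,
    maf_model = {
      m <- maf_new(ck$meta$encoder, ck$meta$fuse_layers, ck$meta$common_dim)
      m$norm <- ck$meta$norm
      m
    },
    affinity_head = affinity_head_new(ck$meta$feature_dim, ck$meta$hidden,
                                      ck$meta$embed_dim),
    psp_model = {
      m <- psp_new(ck$meta$channels, ck$meta$ppm_dim, ck$meta$ppm_bins)
      m$norm <- ck$meta$norm
      m
    })
  params_restore(unclass(model), ck$values)
  model
}

#' Run the full two-stage pipeline
#'
#' Executes synth -> tile -> train-cam -> make-cam -> refine -> train-seg
#' -> infer -> eval under one configuration. Every stage writes its
#' artifacts plus a manifest with a configuration hash under
#' `config$out_dir`; rerunning skips stages whose manifest matches, so
#' deleting a stage's marker (or artifacts) recomputes only that stage
#' and those after it that depend on its outputs.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param stop_after Optional stage name (`"synth"`, `"tile"`,
#'   `"train-cam"`, `"make-cam"`, `"refine"`, `"train-seg"`, `"infer"`);
#'   the pipeline stops after that stage and returns its artifacts so
#'   stages can be driven one at a time.
#' @return List with the evaluation `report` (when the pipeline ran to
#'   completion), the `out_dir`, and paths of the main artifacts.
#' @export
run_pipeline <- function(config = NULL, stop_after = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  done <- function(stage) {
    if (identical(stop_after, stage)) {
      return(TRUE)
    }
    FALSE
  }
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- list(tiles = file.path(out, "tiles"),
                patches = file.path(out, "patches"),
                cam_ckpt = file.path(out, "cam_model.rds"),
                cams = file.path(out, "cams.rds"),
                aff_ckpt = file.path(out, "affinity_head.rds"),
                pseudo = file.path(out, "pseudo"),
                seg_ckpt = file.path(out, "seg_model.rds"),
                pred = file.path(out, "pred_masks"),
                truth = file.path(out, "truth_masks"),
                report = file.path(out, "report.json"))

  run_stage(out, "synth", cfg["synth"], function() {
    specs <- lapply(seq_len(cfg$synth$n_tiles), function(k) {
      synthetic_spec(seed = derive_seed(cfg$seed, k),
                     width = cfg$synth$width, height = cfg$synth$height,
                     n_glands = cfg$synth$n_glands,
                     radius_range = c(cfg$synth$radius_min, cfg$synth$radius_max),
                     lumen_ratio = cfg$synth$lumen_ratio,
                     axis_ratio = c(cfg$synth$axis_ratio_min,
                                    cfg$synth$axis_ratio_max),
                     noise_sigma = cfg$synth$noise_sigma)
    })
    generate_dataset(specs, paths$tiles)
    file.path(paths$tiles, "manifest.csv")
  })
  if (done("synth")) return(invisible(list(out_dir = out, paths = paths)))


  run_stage(out, "tile", cfg[c("synth", "tiling")], function() {
    tiles <- utils::read.csv(file.path(paths$tiles, "manifest.csv"))
    tile_dataset(tiles, paths$patches, cfg$tiling$patch_size,
                 cfg$tiling$stride)
    file.path(paths$patches, "patches.csv")
  })
  if (done("tile")) return(invisible(list(out_dir = out, paths = paths)))


  patches_csv <- function() utils::read.csv(file.path(paths$patches, "patches.csv"))

  run_stage(out, "train-cam", cfg[c("synth", "tiling", "encoder", "maf")],
            function() {
    enc <- encoder_config(cfg$encoder$preset, cfg$encoder$channels,
                          cfg$encoder$heads, cfg$encoder$reduction,
                          cfg$encoder$blocks_per_layer)
    fit <- train_cam_stage(patches_csv(),
                           c(cfg$maf[c("fuse_layers", "common_dim", "epochs",
                                       "batch_size", "lr", "augment")],
                             list(encoder = enc,
                                  seed = derive_seed(cfg$seed, 101L))))
    save_checkpoint(fit$model, paths$cam_ckpt)
    utils::write.csv(fit$log, file.path(out, "cam_log.csv"), row.names = FALSE)
    paths$cam_ckpt
  })
  if (done("train-cam")) return(invisible(list(out_dir = out, paths = paths)))


  run_stage(out, "make-cam", cfg[c("synth", "tiling", "encoder", "maf")],
            function() {
    model <- load_checkpoint(paths$cam_ckpt)
    cams <- lapply(patches_csv()$image_path,
                   function(p) generate_cam(model, read_image(p)))
    saveRDS(cams, paths$cams)
    paths$cams
  })
  if (done("make-cam")) return(invisible(list(out_dir = out, paths = paths)))


  run_stage(out, "refine",
            cfg[c("synth", "tiling", "encoder", "maf", "affinity")],
            function() {
    cams <- readRDS(paths$cams)
    man <- patches_csv()
    aff_cfg <- c(cfg$affinity, list(seed = derive_seed(cfg$seed, 102L)))
    fit <- train_affinity_stage(cams, aff_cfg,
                                images = lapply(man$image_path, read_image))
    save_checkpoint(fit$head, paths$aff_ckpt)
    if (!dir.exists(paths$pseudo)) dir.create(paths$pseudo)
    rows <- lapply(seq_len(nrow(man)), function(k) {
      ref <- refine_pseudo_label(cams[[k]], read_image(man$image_path[k]),
                                 fit$head, aff_cfg)
      pp <- file.path(paths$pseudo,
                      paste0(tools::file_path_sans_ext(basename(man$image_path[k])),
                             "_pseudo.png"))
      write_pseudo(ref$pseudo, pp)
      data.frame(image_path = man$image_path[k], pseudo_path = pp,
                 tile = man$tile[k], x = man$x[k], y = man$y[k],
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(paths$pseudo, "pseudo.csv"), row.names = FALSE)
    file.path(paths$pseudo, "pseudo.csv")
  })
  if (done("refine")) return(invisible(list(out_dir = out, paths = paths)))


  run_stage(out, "train-seg",
            cfg[c("synth", "tiling", "encoder", "maf", "affinity",
                  "segmentation")],
            function() {
    pm <- utils::read.csv(file.path(paths$pseudo, "pseudo.csv"))
    fit <- train_seg_stage(pm, c(cfg$segmentation,
                                 list(seed = derive_seed(cfg$seed, 103L))))
    save_checkpoint(fit$model, paths$seg_ckpt)
    utils::write.csv(fit$log, file.path(out, "seg_log.csv"), row.names = FALSE)
    paths$seg_ckpt
  })
  if (done("train-seg")) return(invisible(list(out_dir = out, paths = paths)))


  run_stage(out, "infer", cfg[setdiff(names(cfg), c("eval", "out_dir"))],
            function() {
    model <- load_checkpoint(paths$seg_ckpt)
    man <- patches_csv()
    tiles <- utils::read.csv(file.path(paths$tiles, "manifest.csv"))
    for (d in c(paths$pred, paths$truth)) if (!dir.exists(d)) dir.create(d)
    for (tid in sort(unique(man$tile))) {
      sub <- man[man$tile == tid, ]
      grid <- compute_patch_grid(tiles$width[tid], tiles$height[tid],
                                 cfg$tiling$patch_size, cfg$tiling$stride)
      scores <- vector("list", nrow(sub))
      k <- 0L
      for (x in grid$starts_x) for (y in grid$starts_y) {
        k <- k + 1L
        row <- sub[sub$x == x & sub$y == y, ]
        logits <- psp_forward(model, read_image(row$image_path[1L]))
        scores[[k]] <- sigmoid(logits[, , 2L] - logits[, , 1L])
      }
      stitched <- stitch_patches(scores, grid)
      name <- sprintf("tile_%04d.png", tid)
      write_mask((stitched > 0.5) * 1L, file.path(paths$pred, name))
      file.copy(tiles$mask_path[tid], file.path(paths$truth, name),
                overwrite = TRUE)
    }
    c(paths$pred, paths$truth)
  })
  if (done("infer")) return(invisible(list(out_dir = out, paths = paths)))


  report <- evaluate_masks(paths$pred, paths$truth, cfg$eval$sd_type)
  jsonlite::write_json(list(mean_iou = report$mean_iou,
                            std_iou = report$std_iou,
                            mean_dice = report$mean_dice,
                            std_dice = report$std_dice,
                            per_image = report$per_image),
                       paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  list(report = report, out_dir = out, paths = paths)
}
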