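# End-to-end study pipeline: simulate -> pair -> train -> translate ->
# measure -> evaluate, driven by one YAML config with a manifest and
# checksum-gated stage skipping.

#' Default pipeline configuration
#'
#' Desk-scale defaults: a small phantom cohort at 0.1 mm voxels with
#' 64 x 64 slices; every stage's knobs are exposed in the returned list
#' (serializable to YAML).
#'
#' @return a nested list.
#' @export
default_run_config <- function() {
  list(
    output_dir = "trabeculagen_run",
    seed = 1L,
    phantom = list(n_train = 2L, n_test = 1L,
                   extent_mm = c(2.4, 6.4, 6.4), voxel_mm = 0.1,
                   target_bvtv = 0.18, target_tbth_mm = 0.218,
                   target_tbsp_mm = 0.934),
    pairing = list(use_keypoints = TRUE),
    training = list(iterations = 200L, img_size = 64L, base_width = 4L,
                    d_width = 4L, lambda_r = 0.1, lambda_f = 1.0, lr = 1e-4),
    voi = list(diameter_mm = 4, height_mm = 1.6),
    evaluation = list(scopes = c("overall", "cancellous"), embed_seed = 7L)
  )
}

#' Validate a pipeline configuration
#'
#' Schema and invariant checks with no side effects.
#'
#' @param config nested list as from [default_run_config()] or
#'   `yaml::read_yaml()`.
#' @return character vector of problems (empty when the config is valid).
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(cond, msg) {
    if (!isTRUE(cond)) problems <<- c(problems, msg)
  }
  need(is.list(config) && length(config) > 0, "config is empty")
  if (!is.list(config) || length(config) == 0) return(problems)
  need(!is.null(config$output_dir), "missing output_dir")
  need(!is.null(config$seed), "missing seed")
  ph <- config$phantom
  need(!is.null(ph), "missing phantom section")
  if (!is.null(ph)) {
    need(isTRUE(ph$n_train >= 1), "phantom$n_train must be >= 1")
    need(isTRUE(ph$n_test >= 1), "phantom$n_test must be >= 1")
    if (!is.null(ph$train_ids) && !is.null(ph$test_ids)) {
      need(length(intersect(ph$train_ids, ph$test_ids)) == 0,
           "train and test vertebra ID sets overlap")
    }
    need(isTRUE(ph$target_bvtv > 0 && ph$target_bvtv < 1),
         "phantom$target_bvtv must be in (0,1)")
    need(isTRUE(ph$voxel_mm > 0), "phantom$voxel_mm must be positive")
  }
  tr <- config$training
  need(!is.null(tr), "missing training section")
  if (!is.null(tr)) {
    need(isTRUE(tr$iterations >= 0), "training$iterations must be >= 0")
    need(isTRUE(tr$img_size %% 16 == 0),
         "training$img_size must be divisible by 16")
  }
  vo <- config$voi
  if (!is.null(vo) && !is.null(ph)) {
    need(isTRUE(vo$diameter_mm < min(ph$extent_mm[2:3])),
         "voi$diameter_mm does not fit in the phantom extent")
  }
  ev <- config$evaluation
  if (!is.null(ev)) {
    need(all(ev$scopes %in% c("overall", "cancellous")),
         "evaluation$scopes must be subset of {overall, cancellous}")
  }
  problems
}

.stage_token <- function(dir, stage) file.path(dir, paste0(".done_", stage))

.stage_done <- function(dir, stage, hash) {
  tok <- .stage_token(dir, stage)
  file.exists(tok) && identical(readLines(tok, warn = FALSE)[1], hash)
}

.stage_mark <- function(dir, stage, hash) {
  writeLines(hash, .stage_token(dir, stage))
}

#' Run the full study pipeline
#'
#' Executes simulate, pair, train, translate, measure and evaluate in order,
#' writing a manifest (config hash, seeds, per-stage timings) to the run
#' directory. Completed stages whose config hash is unchanged are skipped on
#' rerun.
#'
#' @param config nested list (see [default_run_config()]) or path to a YAML
#'   file.
#' @param verbose print per-stage progress.
#' @return the run directory, invisibly. Key outputs: `phantoms/`,
#'   `pairs/pairs.csv`, `model/checkpoint.rds`, `translated/`,
#'   `morphometry.csv`, `report/`, `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  probs <- validate_config(config)
  if (length(probs) > 0) {
    stop("invalid config:\n", paste(" -", probs, collapse = "\n"))
  }
  cfgtxt <- paste(deparse(config), collapse = "")
  tmp <- tempfile()
  writeLines(cfgtxt, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) cat(sprintf(...), "\n")
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  ph <- config$phantom
  n_all <- ph$n_train + ph$n_test
  template <- phantom_spec(
    extent_mm = ph$extent_mm, voxel_mm = ph$voxel_mm,
    target_bvtv = ph$target_bvtv, target_tbth_mm = ph$target_tbth_mm,
    target_tbsp_mm = ph$target_tbsp_mm, seed = config$seed)

  # -- simulate ------------------------------------------------------------
  study <- NULL
  clock("simulate", {
    say("[simulate] %d phantoms", n_all)
    study <- make_study_set(n_all, template, seed = config$seed)
    if (!.stage_done(dir, "simulate", hash)) {
      pdir <- file.path(dir, "phantoms")
      for (rec in study) write_phantom(rec, pdir)
      .stage_mark(dir, "simulate", hash)
    }
  })
  train_set <- study[seq_len(ph$n_train)]
  test_set <- study[ph$n_train + seq_len(ph$n_test)]

  # -- pair ----------------------------------------------------------------
  pairings <- list()
  clock("pair", {
    say("[pair] %d test stacks", length(test_set))
    for (rec in test_set) {
      pr <- if (isTRUE(config$pairing$use_keypoints)) {
        pair_stacks(rec$mdct, rec$micro)
      } else {
        n_mdct <- dim(rec$mdct$data)[1]
        n_micro <- dim(rec$micro$data)[1]
        dm <- abs(outer(seq_len(n_mdct) * 2, seq_len(n_micro), `-`))
        pair_stacks(rec$mdct, rec$micro, distance_matrix = dm)
      }
      pairings[[as.character(rec$id)]] <- pr
    }
    if (!.stage_done(dir, "pair", hash)) {
      pdir <- file.path(dir, "pairs")
      dir.create(pdir, showWarnings = FALSE)
      all_pairs <- do.call(rbind, lapply(names(pairings), function(id) {
        cbind(vertebra = id, pairings[[id]]$pairs)
      }))
      write.csv(all_pairs, file.path(pdir, "pairs.csv"), row.names = FALSE)
      .stage_mark(dir, "pair", hash)
    }
  })

  # -- train ---------------------------------------------------------------
  trc <- config$training
  model <- NULL
  ckpt <- file.path(dir, "model", "checkpoint.rds")
  clock("train", {
    tcfg <- translator_config(
      img_size = trc$img_size, base_width = trc$base_width,
      d_width = trc$d_width %||% trc$base_width,
      lambda_r = trc$lambda_r, lambda_f = trc$lambda_f, lr = trc$lr,
      seed = config$seed)
    if (.stage_done(dir, "train", hash) && file.exists(ckpt)) {
      say("[train] checkpoint up to date, skipping")
      model <- load_translator(ckpt)
    } else {
      say("[train] %d iterations", trc$iterations)
      sz <- trc$img_size
      grab <- function(vol, resize) {
        lapply(seq_len(dim(vol$data)[1]), function(k) {
          m <- vol$data[k, , ]
          if (resize || !all(dim(m) == c(sz, sz))) {
            m <- .bicubic_resize(m, sz, sz)
          }
          m
        })
      }
      mdct_imgs <- unlist(lapply(train_set, function(r) grab(r$mdct, TRUE)),
                          recursive = FALSE)
      micro_imgs <- unlist(lapply(train_set, function(r) grab(r$micro, FALSE)),
                           recursive = FALSE)
      model <- train_translator(mdct_imgs, micro_imgs,
                                 iterations = trc$iterations, config = tcfg)
      dir.create(dirname(ckpt), showWarnings = FALSE)
      save_translator(model, ckpt)
      .stage_mark(dir, "train", hash)
    }
  })

  # -- translate -----------------------------------------------------------
  translated <- list()
  clock("translate", {
    say("[translate] %d test stacks", length(test_set))
    tdir <- file.path(dir, "translated")
    dir.create(tdir, showWarnings = FALSE)
    for (rec in test_set) {
      tv <- translate_stack(model, rec$mdct, rec$micro)
      translated[[as.character(rec$id)]] <- tv
      if (!.stage_done(dir, "translate", hash)) {
        write_stack_tiff(tv, file.path(tdir,
                                       sprintf("vertebra_%03d_microlike.tif",
                                               rec$id)))
      }
    }
    .stage_mark(dir, "translate", hash)
  })

  # -- measure -------------------------------------------------------------
  morpho <- NULL
  clock("measure", {
    say("[measure] morphometry in %.2g x %.2g mm VOIs",
        config$voi$diameter_mm, config$voi$height_mm)
    rows <- list()
    for (rec in test_set) {
      ctr <- dim(rec$micro$data) * rec$micro$voxel_size / 2
      voi <- cylindrical_voi(ctr, config$voi$diameter_mm,
                             config$voi$height_mm)
      stacks <- list(micro_ct = rec$micro,
                     micro_ct_like = translated[[as.character(rec$id)]],
                     mdct = rec$mdct)
      for (m in names(stacks)) {
        res <- measure_stack(stacks[[m]], voi)
        rows[[length(rows) + 1L]] <- data.frame(
          id = rec$id, method = m, bvtv = res$bvtv, tbth_mm = res$tbth_mm,
          tbsp_mm = res$tbsp_mm, threshold = res$threshold_used,
          n_fg = res$n_foreground, n_total = res$n_total,
          bvtv_true = rec$gt$bvtv_true, tbth_true_mm = rec$gt$tbth_true_mm)
      }
    }
    morpho <- do.call(rbind, rows)
    write.csv(morpho, file.path(dir, "morphometry.csv"), row.names = FALSE)
    .stage_mark(dir, "measure", hash)
  })

  # -- evaluate ------------------------------------------------------------
  clock("evaluate", {
    say("[evaluate] similarity metrics and statistics")
    sz <- trc$img_size
    es <- config$evaluation$embed_seed %||% 7L
    for (scope in config$evaluation$scopes) {
      ssim_bm <- list(micro_ct_like = numeric(), mdct_bicubic = numeric())
      micro_imgs <- list()
      gen_imgs <- list()
      up_imgs <- list()
      for (rec in test_set) {
        tv <- translated[[as.character(rec$id)]]
        crop2d <- function(m, body2d) {
          if (scope == "overall") return(m)
          # cancellous scope: central body interior bounding box
          ix <- which(body2d, arr.ind = TRUE)
          sh <- as.integer(0.15 * (max(ix[, 1]) - min(ix[, 1])))
          m[(min(ix[, 1]) + sh):(max(ix[, 1]) - sh),
            (min(ix[, 2]) + sh):(max(ix[, 2]) - sh)]
        }
        body2d <- rec$gt$body_mask$data[1, , ] > 0
        for (j in seq_len(dim(tv$data)[1])) {
          # ground-truth correspondence: MDCT slice j covers micro 2j-1
          mj <- min(2L * j - 1L, dim(rec$micro$data)[1])
          mic <- rec$micro$data[mj, , ]
          gen <- tv$data[j, , ]
          upb <- .bicubic_resize(rec$mdct$data[j, , ], sz, sz)
          if (!all(dim(mic) == dim(gen))) mic <- .bicubic_resize(mic, sz, sz)
          micc <- crop2d(mic, body2d)
          genc <- crop2d(gen, body2d)
          upc <- crop2d(upb, body2d)
          ssim_bm$micro_ct_like <- c(ssim_bm$micro_ct_like, ssim(genc, micc))
          ssim_bm$mdct_bicubic <- c(ssim_bm$mdct_bicubic, ssim(upc, micc))
          micro_imgs[[length(micro_imgs) + 1L]] <- micc
          gen_imgs[[length(gen_imgs) + 1L]] <- genc
          up_imgs[[length(up_imgs) + 1L]] <- upc
        }
      }
      fid_bm <- c(
        micro_ct_like = fid(embed_images(gen_imgs, es),
                            embed_images(micro_imgs, es)),
        mdct_bicubic = fid(embed_images(up_imgs, es),
                           embed_images(micro_imgs, es)))
      full_report(ssim_bm, fid_bm, morpho,
                  file.path(dir, "report", scope), scope = scope)
    }
    .stage_mark(dir, "evaluate", hash)
  })

  manifest <- list(config = config, config_hash = hash,
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion(
                     "trabeculagen")),
                   timings_sec = timings,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
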