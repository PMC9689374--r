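# End-to-end experiment orchestration on synthetic phantom cases:
# phantom -> fusion -> split -> train per (architecture, plane) -> infer ->
# evaluate -> compare.

#' Configuration of an end-to-end phantom experiment
#'
#' @param n_train,n_eval,n_test Cases per split (phantom cases are generated
#'   with seeds derived from `seed`; splits are disjoint by construction).
#' @param architectures Character vector of architecture names.
#' @param planes Character vector of planes to train/infer on.
#' @param phantom Template [phantom_spec()]; each case reuses it with a fresh
#'   seed.
#' @param configs Named list of [train_config()] objects, one per
#'   architecture; defaults are desk-scale profiles that keep the structural
#'   settings (patch pipeline, loss, clipping) while shrinking batches and
#'   epochs.
#' @param n_feats Feature width for all networks.
#' @param output_dir Directory for artifacts (created); `NULL` keeps
#'   everything in memory.
#' @param write_dicom Also write HR/LR/SR series as DICOM under `output_dir`.
#' @param seed Global seed; all per-case and per-model seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_train = 2L, n_eval = 1L, n_test = 2L,
                       architectures = "EDSR",
                       planes = "sagittal",
                       phantom = phantom_spec(size = c(48, 48, 30),
                                              body_axes = c(20, 17),
                                              lung_axes = c(7, 8, 8),
                                              lung_offsets = rbind(c(-9.5, -1.5, 0),
                                                                   c(9.5, -1.5, 0)),
                                              n_vessels = 4L, n_nodules = 2L),
                       configs = NULL,
                       n_feats = 8L,
                       output_dir = NULL,
                       write_dicom = FALSE,
                       seed = 1L) {
  stopifnot(n_train >= 1, n_eval >= 1, n_test >= 1)
  architectures <- match.arg(architectures,
                             c("EDSR", "SRCNN", "VDSR", "SRResNet"),
                             several.ok = TRUE)
  planes <- match.arg(planes, c("axial", "coronal", "sagittal"),
                      several.ok = TRUE)
  if (is.null(configs)) {
    configs <- lapply(architectures, function(a)
      train_config(a, patch_size = 24L, batch_size = 4L,
                   batches_per_epoch = 8L, total_epochs = 3L,
                   learning_rate = 1e-3, eval_max_slices = 4L))
    names(configs) <- architectures
  }
  structure(list(n_train = n_train, n_eval = n_eval, n_test = n_test,
                 architectures = architectures, planes = planes,
                 phantom = phantom, configs = configs,
                 n_feats = as.integer(n_feats),
                 output_dir = output_dir, write_dicom = write_dicom,
                 seed = as.integer(seed)),
            class = "run_config")
}

.case_split <- function(cfg) {
  n <- cfg$n_train + cfg$n_eval + cfg$n_test
  ids <- sprintf("case%02d", seq_len(n))
  split <- rep(c("train", "eval", "test"),
               c(cfg$n_train, cfg$n_eval, cfg$n_test))
  tibble::tibble(case_id = ids, split = split,
                 case_seed = cfg$seed * 1000L + seq_len(n))
}

#' Run the end-to-end phantom experiment
#'
#' Generates the phantom triplets, validates each against the admission
#' rules, fuses the thick pairs into LR volumes on the thin-axial grid,
#' trains each requested architecture on each requested plane using the
#' train/eval split, infers SR volumes for the test cases, evaluates ROI-aware
#' PSNR/SSIM records (LR baseline included), and assembles comparison
#' matrices. Re-running with the same configuration reproduces the records.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress.
#' @return An object of class `experiment_result`: list with `records`
#'   (quality tibble), `models`, `comparisons` (list of
#'   [comparison_matrix()]s), `split`, and `manifest`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  split <- .case_split(cfg)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage phantom: generating %d cases", nrow(split))
  cases <- lapply(seq_len(nrow(split)), function(i) {
    spec <- cfg$phantom
    spec$seed <- split$case_seed[i]
    trip <- make_triplet(spec)
    rep <- validate_triplet(trip$thin_axial, trip$thick_axial, trip$thick_coronal)
    if (!triplet_accepted(rep))
      stop("stage phantom, case ", split$case_id[i], ": triplet rejected")
    trip
  })
  names(cases) <- split$case_id

  say("stage fusion")
  pairs <- lapply(split$case_id, function(id) {
    trip <- cases[[id]]
    fr <- fuse_series(trip$thick_axial, trip$thick_coronal,
                      trip$thin_axial$geometry)
    list(hr = trip$thin_axial, lr = fr$lr)
  })
  names(pairs) <- split$case_id
  tr <- pairs[split$case_id[split$split == "train"]]
  ev <- pairs[split$case_id[split$split == "eval"]]
  te <- pairs[split$case_id[split$split == "test"]]

  models <- list()
  records <- list()
  say("stage evaluate: LR baseline")
  rois <- lapply(te, function(case) segment_rois(case$hr))
  for (id in names(te)) {
    records[[paste0(id, ".LR")]] <-
      evaluate_case(te[[id]]$hr, te[[id]]$lr, case_id = id, condition = "LR",
                    rois = rois[[id]])
  }
  for (arch in cfg$architectures) {
    for (plane in cfg$planes) {
      key <- paste(arch, plane, sep = "-")
      say("stage train: %s", key)
      config <- cfg$configs[[arch]]
      config$plane <- plane
      config$seed <- cfg$seed
      model <- build_model(architecture_spec(arch, n_feats = cfg$n_feats),
                           seed = cfg$seed)
      model <- train_sr(model, tr, ev, config, verbose = verbose)
      models[[key]] <- model
      say("stage infer/evaluate: %s", key)
      for (id in names(te)) {
        sr <- infer_volume(model, te[[id]]$lr, plane)
        records[[paste0(id, ".", key)]] <-
          evaluate_case(te[[id]]$hr, sr, case_id = id, condition = key,
                        rois = rois[[id]])
        if (isTRUE(cfg$write_dicom) && !is.null(cfg$output_dir))
          write_dicom_series(sr, file.path(cfg$output_dir, "dicom", id, key))
      }
    }
  }
  records <- dplyr::bind_rows(records)

  say("stage compare")
  comparisons <- list()
  n_cond <- length(unique(records$condition))
  if (n_cond >= 2 && length(unique(records$case_id)) >= 2) {
    for (m in c("psnr", "ssim")) {
      comparisons[[paste0(m, "_plane")]] <-
        comparison_matrix(records, metric = m, mode = "plane")
      comparisons[[paste0(m, "_roi")]] <-
        comparison_matrix(records, metric = m, mode = "roi")
    }
  }

  manifest <- list(
    seed = cfg$seed,
    architectures = cfg$architectures,
    planes = cfg$planes,
    split = as.data.frame(split),
    phantom = unclass(cfg$phantom),
    configs = lapply(cfg$configs, unclass),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ctsr")),
    files = character(0))

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    rec_path <- file.path(cfg$output_dir, "quality_records.csv")
    utils::write.csv(records, rec_path, row.names = FALSE)
    files <- rec_path
    for (nm in names(comparisons)) {
      p <- file.path(cfg$output_dir, paste0("comparison_", nm, ".csv"))
      utils::write.csv(tidy(comparisons[[nm]]), p, row.names = FALSE)
      files <- c(files, p)
    }
    manifest$files <- files
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(records = records, models = models,
                 comparisons = comparisons, split = split,
                 manifest = manifest),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", nrow(x$split), "cases;",
      length(x$models), "trained models;",
      nrow(x$records), "quality rows\n")
  invisible(x)
}
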