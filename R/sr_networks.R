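#' Architecture specification for the four SR networks
#'
#' Structural constants follow the modified 1:1 (no-upsampling) variants used
#' for thin-slice synthesis: SRCNN keeps its three convolution stages but the
#' bicubic pre-interpolation is skipped; VDSR keeps 20 weight layers with
#' residual learning; SRResNet keeps 16 residual blocks with batch
#' normalization but the sub-pixel upsampling blocks are replaced by 1:1
#' output; EDSR is deepened to 32 residual blocks with no normalization
#' layers and residual scaling 0.1. Feature width is configurable; 64 is the
#' conventional width of these networks.
#'
#' @param name One of `"SRCNN"`, `"VDSR"`, `"SRResNet"`, `"EDSR"`.
#' @param n_feats Feature width (filters per convolution).
#' @param n_blocks Residual-block count (SRResNet/EDSR) or total weight
#'   layers (VDSR); defaults are the structural constants above.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(name = c("SRCNN", "VDSR", "SRResNet", "EDSR"),
                              n_feats = 64L, n_blocks = NULL) {
  name <- match.arg(name)
  n_blocks <- as.integer(n_blocks %||% switch(name, SRCNN = 3L, VDSR = 20L,
                                              SRResNet = 16L, EDSR = 32L))
  structure(list(name = name, n_feats = as.integer(n_feats),
                 n_blocks = n_blocks,
                 residual_scaling = if (name == "EDSR") 0.1 else 1,
                 batch_norm = name == "SRResNet",
                 upsampling = "identity"),
            class = "architecture_spec")
}

#' Instantiate an (untrained) SR network
#'
#' All four networks map a 1-channel H x W image to a 1-channel H x W image
#' (1:1, fully convolutional). The three residual formulations (VDSR,
#' SRResNet, EDSR) carry a global input skip, so zeroing the final layer's
#' weights makes the network the exact identity; SRCNN, which has no skip, is
#' initialised with a delta-kernel pass-through path plus small random
#' weights so that it starts near the identity.
#'
#' @param spec An [architecture_spec()].
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `sr_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  f <- spec$n_feats
  .with_seed(seed, {
    model <- switch(spec$name,
      SRCNN = {
        f2 <- max(f %/% 2L, 1L)
        c1 <- .conv_set_delta(.conv_layer(9, 1, f, "small"))
        c2 <- .conv_set_delta(.conv_layer(5, f, f2, "small"))
        c3 <- .conv_set_delta(.conv_layer(5, f2, 1, "small"))
        list(stem = list(c1, .relu_layer(), c2, .relu_layer(), c3),
             blocks = list(), mid = list(), tail = list(),
             input_skip = FALSE, long_skip = FALSE, res_scale = 1)
      },
      VDSR = {
        layers <- list(.conv_layer(3, 1, f), .relu_layer())
        for (i in seq_len(spec$n_blocks - 2L)) {
          layers <- c(layers, list(.conv_layer(3, f, f), .relu_layer()))
        }
        layers <- c(layers, list(.conv_layer(3, f, 1, "zero")))
        list(stem = layers, blocks = list(), mid = list(), tail = list(),
             input_skip = TRUE, long_skip = FALSE, res_scale = 1)
      },
      SRResNet = {
        blocks <- lapply(seq_len(spec$n_blocks), function(i) {
          list(.conv_layer(3, f, f), .bn_layer(f), .prelu_layer(f),
               .conv_layer(3, f, f), .bn_layer(f))
        })
        list(stem = list(.conv_layer(9, 1, f), .prelu_layer(f)),
             blocks = blocks,
             mid = list(.conv_layer(3, f, f), .bn_layer(f)),
             tail = list(.conv_layer(9, f, 1, "zero")),
             input_skip = TRUE, long_skip = TRUE, res_scale = 1)
      },
      EDSR = {
        blocks <- lapply(seq_len(spec$n_blocks), function(i) {
          list(.conv_layer(3, f, f), .relu_layer(), .conv_layer(3, f, f))
        })
        list(stem = list(.conv_layer(3, 1, f)),
             blocks = blocks,
             mid = list(.conv_layer(3, f, f)),
             tail = list(.conv_layer(3, f, 1, "zero")),
             input_skip = TRUE, long_skip = TRUE,
             res_scale = spec$residual_scaling)
      })
  })
  model$spec <- spec
  model$norm_window <- c(-1024, 3071)
  model$patch_counter <- 0L
  structure(model, class = "sr_model")
}

#' @export
print.sr_model <- function(x, ...) {
  cat("<sr_model>", x$spec$name, "| width", x$spec$n_feats,
      "| residual blocks:", length(x$blocks),
      "| patches trained:", x$patch_counter, "\n")
  invisible(x)
}

#' Forward pass of an SR network
#'
#' @param model An [sr_model()][build_model].
#' @param x 2D matrix or 4D array (H, W, 1, N) of normalized intensities.
#' @param training Use batch statistics in normalization layers.
#' @return Output of the same shape as `x`.
#' @export
forward_model <- function(model, x, training = FALSE) {
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(dim(x), 1L, 1L))
  y <- .model_forward(model, x, training = training, keep = FALSE)$y
  if (was_mat) y <- y[, , 1L, 1L]
  y
}

.model_forward <- function(model, x, training, keep = TRUE) {
  caches <- list()
  x0 <- x
  r <- .forward_seq(model$stem, x, training)
  h <- r$y; if (keep) caches$stem <- r$caches
  if (training) model$stem <- r$layers
  if (model$long_skip) f0 <- h
  if (length(model$blocks)) {
    caches$blocks <- vector("list", length(model$blocks))
    for (i in seq_along(model$blocks)) {
      rb <- .forward_seq(model$blocks[[i]], h, training)
      if (keep) caches$blocks[[i]] <- rb$caches
      if (training) model$blocks[[i]] <- rb$layers
      h <- h + model$res_scale * rb$y
    }
  }
  if (length(model$mid)) {
    rm_ <- .forward_seq(model$mid, h, training)
    if (keep) caches$mid <- rm_$caches
    if (training) model$mid <- rm_$layers
    h <- rm_$y
  }
  if (model$long_skip) h <- h + f0
  if (length(model$tail)) {
    rt <- .forward_seq(model$tail, h, training)
    if (keep) caches$tail <- rt$caches
    if (training) model$tail <- rt$layers
    h <- rt$y
  }
  y <- if (model$input_skip) h + x0 else h
  list(y = y, caches = caches, model = model)
}

.model_backward <- function(model, caches, dy) {
  grads <- list()
  d <- dy
  if (length(model$tail)) {
    rt <- .backward_seq(model$tail, caches$tail, d)
    grads$tail <- rt$grads; d <- rt$dx
  }
  if (model$long_skip) df0 <- d
  if (length(model$mid)) {
    rm_ <- .backward_seq(model$mid, caches$mid, d)
    grads$mid <- rm_$grads; d <- rm_$dx
  }
  if (length(model$blocks)) {
    grads$blocks <- vector("list", length(model$blocks))
    for (i in rev(seq_along(model$blocks))) {
      rb <- .backward_seq(model$blocks[[i]], caches$blocks[[i]],
                          model$res_scale * d)
      grads$blocks[[i]] <- rb$grads
      d <- d + rb$dx
    }
  }
  if (model$long_skip) d <- d + df0
  rs <- .backward_seq(model$stem, caches$stem, d)
  grads$stem <- rs$grads
  grads
}

.flatten_grads <- function(model, grads) {
  out <- list()
  put <- function(sn, glist) {
    for (i in seq_along(glist)) {
      for (pn in names(glist[[i]])) {
        out[[paste(sn, i, pn, sep = ".")]] <<- glist[[i]][[pn]]
      }
    }
  }
  if (!is.null(grads$stem)) put("stem", grads$stem)
  if (!is.null(grads$mid)) put("mid", grads$mid)
  if (!is.null(grads$tail)) put("tail", grads$tail)
  for (i in seq_along(grads$blocks)) put(paste0("block", i), grads$blocks[[i]])
  out
}

# structural audits -------------------------------------------------------

#' Structural audit of an SR network
#'
#' @param model An `sr_model`.
#' @return A list with the residual-block count, total convolution (weight)
#'   layer count, whether any normalization layer is present, and the
#'   residual scaling factor.
#' @export
model_audit <- function(model) {
  all_layers <- c(model$stem, unlist(model$blocks, recursive = FALSE),
                  model$mid, model$tail)
  types <- vapply(all_layers, function(l) l$type, "")
  list(name = model$spec$name,
       n_residual_blocks = length(model$blocks),
       n_weight_layers = sum(types == "conv"),
       has_norm_layers = any(types == "bn"),
       residual_scaling = model$res_scale,
       input_skip = model$input_skip)
}

# plane handling ----------------------------------------------------------

#' Extract 2D slices along an anatomical plane
#'
#' For a volume stored `[left-right, anterior-posterior, inferior-superior]`:
#' axial slices are (x, y) matrices (one per z), coronal slices are (x, z)
#' matrices (one per y), sagittal slices are (y, z) matrices (one per x).
#' The same convention is applied to HR and LR partners, so patch locations
#' correspond.
#'
#' @param vol A [ct_volume()] or 3D array.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return List of 2D matrices.
#' @export
extract_plane_slices <- function(vol, plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  a <- if (inherits(vol, "ct_volume")) vol$data else vol
  d <- dim(a)
  switch(plane,
    axial = lapply(seq_len(d[3]), function(k) a[, , k]),
    coronal = lapply(seq_len(d[2]), function(j) a[, j, ]),
    sagittal = lapply(seq_len(d[1]), function(i) a[i, , ]))
}

#' Restack plane slices into a 3D array
#'
#' Inverse of [extract_plane_slices()].
#'
#' @param slices List of 2D matrices.
#' @param plane Plane the slices were extracted along.
#' @param dims Target 3D dimensions.
#' @return 3D array.
#' @export
restack_plane_slices <- function(slices, plane = c("axial", "coronal", "sagittal"),
                                 dims) {
  plane <- match.arg(plane)
  a <- array(0, dims)
  for (s in seq_along(slices)) {
    switch(plane,
      axial = a[, , s] <- slices[[s]],
      coronal = a[, s, ] <- slices[[s]],
      sagittal = a[s, , ] <- slices[[s]])
  }
  a
}

.reflect_pad <- function(m, target) {
  # reflect-pad a matrix up to at least `target` in each dimension
  while (nrow(m) < target) {
    add <- min(nrow(m) - 1L, target - nrow(m))
    m <- rbind(m, m[nrow(m) - seq_len(add), , drop = FALSE])
  }
  while (ncol(m) < target) {
    add <- min(ncol(m) - 1L, target - ncol(m))
    m <- cbind(m, m[, ncol(m) - seq_len(add), drop = FALSE])
  }
  m
}

#' Sample an aligned HR/LR patch pair
#'
#' Crops the same random location from both slices; slices smaller than the
#' patch are reflect-padded first. Offsets are uniform over the valid range
#' and drawn from the current RNG stream.
#'
#' @param hr_slice,lr_slice 2D matrices of equal size.
#' @param patch Patch side length (pixels).
#' @return List with `hr`, `lr` (patch x patch matrices) and the 1-based
#'   top-left `offset`.
#' @export
sample_patch_pair <- function(hr_slice, lr_slice, patch = 96L) {
  stopifnot(all(dim(hr_slice) == dim(lr_slice)))
  patch <- as.integer(patch)
  if (nrow(hr_slice) < patch || ncol(hr_slice) < patch) {
    hr_slice <- .reflect_pad(hr_slice, patch)
    lr_slice <- .reflect_pad(lr_slice, patch)
  }
  oi <- sample.int(nrow(hr_slice) - patch + 1L, 1L)
  oj <- sample.int(ncol(hr_slice) - patch + 1L, 1L)
  ri <- oi:(oi + patch - 1L); rj <- oj:(oj + patch - 1L)
  list(hr = hr_slice[ri, rj], lr = lr_slice[ri, rj], offset = c(oi, oj))
}

# training ----------------------------------------------------------------

#' Training configuration
#'
#' Field names follow the conventional training-settings table for these
#' networks (patch size, batch size, batches per epoch, total epochs, initial
#' learning rate, loss). `total_patches()` of a full-scale configuration is
#' `batch_size * batches_per_epoch * total_epochs`.
#'
#' @param architecture Architecture name; fills the loss and learning-rate
#'   defaults (EDSR: L1, lr 1e-4; SRCNN: MSE, lr 1e-4; VDSR: MSE, lr 1e-5;
#'   SRResNet: MSE, lr 1e-4).
#' @param patch_size Patch side (pixels).
#' @param batch_size Patches per batch.
#' @param batches_per_epoch Batches per epoch.
#' @param total_epochs Epochs to run.
#' @param learning_rate Initial Adam step size.
#' @param loss `"L1"` or `"MSE"`.
#' @param plane Training plane (`"axial"`, `"coronal"`, `"sagittal"`).
#' @param grad_clip Global-norm gradient clip; `NA` disables. VDSR defaults
#'   to 1.0, the others to none.
#' @param normalization_window HU interval mapped to \[0, 1\].
#' @param eval_max_slices Cap on slices per evaluation volume used for the
#'   per-epoch evaluation PSNR (evenly subsampled).
#' @param seed RNG seed for patch sampling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(architecture = c("EDSR", "SRCNN", "VDSR", "SRResNet"),
                         patch_size = 96L, batch_size = 16L,
                         batches_per_epoch = NULL, total_epochs = NULL,
                         learning_rate = NULL, loss = NULL,
                         plane = c("sagittal", "axial", "coronal"),
                         grad_clip = NULL,
                         normalization_window = c(-1024, 3071),
                         eval_max_slices = 8L,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  plane <- match.arg(plane)
  defaults <- switch(architecture,
    EDSR     = list(bpe = 7500L, ep = 20L,  lr = 1e-4, loss = "L1"),
    SRCNN    = list(bpe = 1000L, ep = 200L, lr = 1e-4, loss = "MSE"),
    VDSR     = list(bpe = 1000L, ep = 240L, lr = 1e-5, loss = "MSE"),
    SRResNet = list(bpe = 1000L, ep = 180L, lr = 1e-4, loss = "MSE"))
  loss <- match.arg(loss %||% defaults$loss, c("L1", "MSE"))
  grad_clip <- grad_clip %||% if (architecture == "VDSR") 1.0 else NA_real_
  structure(list(architecture = architecture,
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 batches_per_epoch = as.integer(batches_per_epoch %||% defaults$bpe),
                 total_epochs = as.integer(total_epochs %||% defaults$ep),
                 learning_rate = learning_rate %||% defaults$lr,
                 loss = loss, plane = plane, grad_clip = grad_clip,
                 normalization_window = normalization_window,
                 eval_max_slices = eval_max_slices,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Total patches consumed by a training configuration
#'
#' @param config A [train_config()].
#' @return `batch_size * batches_per_epoch * total_epochs`.
#' @export
total_patches <- function(config) {
  config$batch_size * config$batches_per_epoch * config$total_epochs
}

#' Full-scale training settings of the four architectures
#'
#' @return A tibble with one row per architecture holding the full-scale
#'   patch/batch/epoch/learning-rate/loss settings and the implied total
#'   patch count.
#' @export
table_training_settings <- function() {
  cfgs <- lapply(c("EDSR", "SRCNN", "VDSR", "SRResNet"), train_config)
  tibble::tibble(
    Model = vapply(cfgs, function(c) c$architecture, ""),
    `Patch Size` = vapply(cfgs, function(c) sprintf("%d x %d", c$patch_size, c$patch_size), ""),
    `Batch Size` = vapply(cfgs, function(c) c$batch_size, 1L),
    `Batches Per Epoch` = vapply(cfgs, function(c) c$batches_per_epoch, 1L),
    `Total Epochs` = vapply(cfgs, function(c) c$total_epochs, 1L),
    `Total Patches Trained` = vapply(cfgs, total_patches, 1),
    `Initial Learning Rate` = vapply(cfgs, function(c) c$learning_rate, 1),
    Loss = vapply(cfgs, function(c) c$loss, ""))
}

.normalize_hu <- function(x, window) {
  pmin(pmax((x - window[1]) / (window[2] - window[1]), 0), 1)
}
.denormalize_hu <- function(x, window) {
  pmin(pmax(x, 0), 1) * (window[2] - window[1]) + window[1]
}

#' Train an SR network on HR/LR volume pairs
#'
#' Per epoch, `batches_per_epoch` batches of `batch_size` aligned patch pairs
#' are drawn from the configured plane of randomly chosen training cases,
#' the L1 or MSE loss on window-normalized intensities is minimised with
#' Adam (global-norm gradient clipping when configured), and the evaluation
#' PSNR of the inferred SR against HR is computed on the evaluation cases.
#' The checkpoint with the best evaluation PSNR is returned.
#'
#' @param model An untrained or previously trained `sr_model`.
#' @param train_cases,eval_cases Lists of `list(hr = , lr = )` pairs of
#'   [ct_volume()]s on a common grid.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The trained `sr_model` with `$train_log` (tibble: epoch, loss,
#'   eval_psnr), `$patch_counter`, and `$config`.
#' @export
train_sr <- function(model, train_cases, eval_cases, config, verbose = FALSE) {
  stopifnot(inherits(model, "sr_model"), inherits(config, "train_config"))
  if (length(eval_cases) == 0) stop("evaluation set is empty")
  w <- config$normalization_window
  model$norm_window <- w
  prep <- function(case) list(
    hr = extract_plane_slices(.normalize_hu(case$hr$data, w), config$plane),
    lr = extract_plane_slices(.normalize_hu(case$lr$data, w), config$plane))
  tr <- lapply(train_cases, prep)
  ev <- lapply(eval_cases, prep)

  params <- .collect_params(model)
  state <- .adam_init(params)
  P <- config$patch_size
  log <- vector("list", config$total_epochs)
  best_psnr <- -Inf; best_model <- model

  eval_psnr_now <- function() {
    ps <- vapply(ev, function(case) {
      ns <- length(case$lr)
      idx <- unique(round(seq(1, ns, length.out = min(ns, config$eval_max_slices))))
      se <- 0; npx <- 0
      for (s in idx) {
        x <- array(case$lr[[s]], c(dim(case$lr[[s]]), 1L, 1L))
        y <- .model_forward(model, x, training = FALSE, keep = FALSE)$y
        se <- se + sum((pmin(pmax(y[, , 1, 1], 0), 1) - case$hr[[s]])^2)
        npx <- npx + length(y)
      }
      mse <- se / npx
      if (mse == 0) 100 else min(10 * log10(1 / mse), 100)
    }, 0)
    mean(ps)
  }

  .with_seed(config$seed, {
    for (epoch in seq_len(config$total_epochs)) {
      epoch_loss <- 0
      for (b in seq_len(config$batches_per_epoch)) {
        xb <- array(0, c(P, P, 1L, config$batch_size))
        tb <- array(0, c(P, P, 1L, config$batch_size))
        for (s in seq_len(config$batch_size)) {
          ci <- sample.int(length(tr), 1L)
          si <- sample.int(length(tr[[ci]]$lr), 1L)
          pp <- sample_patch_pair(tr[[ci]]$hr[[si]], tr[[ci]]$lr[[si]], P)
          xb[, , 1L, s] <- pp$lr
          tb[, , 1L, s] <- pp$hr
        }
        fw <- .model_forward(model, xb, training = TRUE, keep = TRUE)
        model <- fw$model                   # batch-norm running statistics
        resid <- fw$y - tb
        npx <- length(resid)
        if (config$loss == "L1") {
          loss <- mean(abs(resid)); dy <- sign(resid) / npx
        } else {
          loss <- mean(resid^2); dy <- 2 * resid / npx
        }
        grads <- .flatten_grads(model, .model_backward(model, fw$caches, dy))
        if (is.finite(config$grad_clip)) {
          gn <- .grad_global_norm(grads)
          if (gn > config$grad_clip) {
            grads <- lapply(grads, function(g) g * (config$grad_clip / gn))
          }
        }
        upd <- .adam_step(params, grads, state, config$learning_rate)
        params <- upd$params; state <- upd$state
        model <- .assign_params(model, params)
        model$patch_counter <- model$patch_counter + config$batch_size
        epoch_loss <- epoch_loss + loss
      }
      ep <- eval_psnr_now()
      if (ep > best_psnr) { best_psnr <- ep; best_model <- model }
      log[[epoch]] <- tibble::tibble(epoch = epoch,
                                     loss = epoch_loss / config$batches_per_epoch,
                                     eval_psnr = ep)
      if (verbose)
        message(sprintf("[%s/%s] epoch %d  loss %.5g  eval PSNR %.3f dB",
                        model$spec$name, config$plane, epoch,
                        epoch_loss / config$batches_per_epoch, ep))
    }
  })
  best_model$patch_counter <- model$patch_counter
  model <- best_model
  model$train_log <- dplyr::bind_rows(log)
  model$config <- config
  model
}

#' Apply a trained SR network to a whole volume
#'
#' Every slice along the requested plane is passed through the network at
#' full slice size (the networks are fully convolutional), the outputs are
#' restacked, de-normalized to HU and clipped to the normalization window.
#' Geometry is copied from the input. Running on a plane other than the
#' training plane raises a warning, not an error (cross-plane inference is a
#' legitimate experiment).
#'
#' @param model A trained `sr_model`.
#' @param lr A [ct_volume()] on the thin grid.
#' @param plane Plane along which slices are processed.
#' @param chunk Number of slices forwarded per batch.
#' @return A [ct_volume()] of identical size and geometry.
#' @export
infer_volume <- function(model, lr, plane = c("sagittal", "axial", "coronal"),
                         chunk = 8L) {
  plane <- match.arg(plane)
  if (!is.null(model$config) && !identical(model$config$plane, plane))
    warning(sprintf("model was trained on the %s plane, inferring on %s",
                    model$config$plane, plane))
  w <- model$norm_window
  slices <- extract_plane_slices(.normalize_hu(lr$data, w), plane)
  ns <- length(slices)
  out <- vector("list", ns)
  for (start in seq(1, ns, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ns)
    x <- array(0, c(dim(slices[[1]]), 1L, length(idx)))
    for (q in seq_along(idx)) x[, , 1L, q] <- slices[[idx[q]]]
    y <- .model_forward(model, x, training = FALSE, keep = FALSE)$y
    for (q in seq_along(idx)) out[[idx[q]]] <- y[, , 1L, q]
  }
  hu <- .denormalize_hu(restack_plane_slices(out, plane, dim(lr$data)), w)
  ct_volume(hu, lr$geometry,
            tags = utils::modifyList(lr$tags %||% list(), list(
              SeriesDescription = sprintf("SR (%s, %s plane)",
                                          model$spec$name, plane),
              DerivationDescription = sprintf(
                "super-resolved with %s on the %s plane", model$spec$name, plane))))
}

#' @rdname sr_model_tidiers
#' @method tidy sr_model
#' @export
tidy.sr_model <- function(x, ...) {
  if (is.null(x$train_log)) return(tibble::tibble(epoch = integer(),
                                                  loss = numeric(),
                                                  eval_psnr = numeric()))
  x$train_log
}

#' Tidiers for trained SR networks
#'
#' `tidy()` returns the per-epoch training log; `glance()` a one-row summary.
#'
#' @param x An `sr_model`.
#' @param ... Unused.
#' @name sr_model_tidiers
#' @method glance sr_model
#' @export
glance.sr_model <- function(x, ...) {
  tibble::tibble(
    architecture = x$spec$name,
    n_feats = x$spec$n_feats,
    n_residual_blocks = length(x$blocks),
    patches_trained = x$patch_counter,
    epochs = if (is.null(x$train_log)) 0L else nrow(x$train_log),
    best_eval_psnr = if (is.null(x$train_log)) NA_real_ else max(x$train_log$eval_psnr))
}
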