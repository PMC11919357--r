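# Orchestration: Adam training with best-validation checkpointing, full-frame
# inference with patch stitching, and the evaluation harness.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Patches per optimization step (default 16).
#' @param epochs Training epochs (default 200; use a small value for smoke
#'   runs).
#' @param seed Master seed: fixes weight initialization, shuffling and every
#'   other random draw of the run.
#' @param checkpoint `"best"` keeps the weights with the lowest validation
#'   combined loss, `"last"` the final weights.
#' @param adam_beta1,adam_beta2,adam_epsilon Adam moment decay rates and
#'   stabilizer (framework-typical defaults, recorded in the manifest).
#' @return An object of class `esdm_train_config`.
#' @export
esdm_train_config <- function(learning_rate = 0.001, batch_size = 16L,
                              epochs = 200L, seed = 1L,
                              checkpoint = c("best", "last"),
                              adam_beta1 = 0.9, adam_beta2 = 0.999,
                              adam_epsilon = 1e-7) {
  checkpoint <- match.arg(checkpoint)
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint = checkpoint, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_epsilon = adam_epsilon),
            class = "esdm_train_config")
}

pairs_to_batch <- function(pairs, idx, K) {
  H <- nrow(pairs[[idx[1L]]]$noisy); W <- ncol(pairs[[idx[1L]]]$noisy)
  B <- length(idx)
  noisy <- array(0, c(H, W, 1L, B))
  target <- array(0, c(H, W, 1L, B))
  soft <- array(0, c(H, W, K, B))
  for (j in seq_along(idx)) {
    p <- pairs[[idx[j]]]
    noisy[, , 1L, j] <- p$noisy
    target[, , 1L, j] <- p$target
    soft[, , , j] <- p$soft_label
  }
  list(noisy = noisy, target = target, soft = soft)
}

# combined loss and gradients on one batch
esdm_loss_grads <- function(model, batch, loss_cfg, want_grads = TRUE) {
  cfg <- model$config
  out <- forward_esdm(model, batch$noisy, train = want_grads)
  LD <- 0; Lseg <- 0
  dden <- NULL; dlogits <- NULL
  if (cfg$enable_denoise_decoder) {
    dl <- denoise_loss_grad(batch$target, out$denoised, loss_cfg)
    LD <- dl$value
    dden <- dl$dout
  }
  if (cfg$enable_seg_decoder) {
    d <- dim(out$logits)
    p <- esdm_softmax_k(out$logits)
    npix <- d[1L] * d[2L] * d[4L]
    Lseg <- -sum(batch$soft * log(pmax(p, 1e-12))) / npix
    dlogits <- (p - batch$soft) / npix
  }
  Lc <- LD + Lseg
  grads <- if (want_grads) backward_esdm(model, out$cache, dden, dlogits)
  list(Lc = Lc, LD = LD, Lseg = Lseg, grads = grads)
}

esdm_val_loss <- function(model, pairs, loss_cfg, batch_size) {
  if (length(pairs) == 0L) return(NA_real_)
  K <- model$config$n_classes
  idx_all <- seq_along(pairs)
  chunks <- split(idx_all, ceiling(idx_all / batch_size))
  tot <- 0
  for (ch in chunks) {
    b <- pairs_to_batch(pairs, ch, K)
    r <- esdm_loss_grads(model, b, loss_cfg, want_grads = FALSE)
    tot <- tot + r$Lc * length(ch)
  }
  tot / length(pairs)
}

# light content fingerprint of the training inputs, recorded in the manifest
dataset_fingerprint <- function(dataset) {
  s <- 0; sq <- 0; n <- 0
  for (role in c("train", "val", "test")) for (p in dataset[[role]]) {
    s <- s + sum(p$noisy); sq <- sq + sum(p$noisy^2); n <- n + length(p$noisy)
  }
  sprintf("n%d-s%.6e-q%.6e", n, s, sq)
}

#' Train the segmentation-denoising model
#'
#' Optimizes the combined loss (denoising + soft-label cross entropy; single
#' task for ablation variants) with Adam.  After every epoch the validation
#' combined loss is computed and, under the `"best"` checkpoint policy, the
#' best-so-far weights are retained.  The run is fully determined by
#' `train_config$seed`.
#'
#' @param dataset A [make_dataset()] result (non-empty `train`; `val` used
#'   for checkpoint selection).
#' @param config An [esdm_config()]; its input shape must match the patches.
#' @param train_config An [esdm_train_config()].
#' @param loss_cfg A [loss_config()].
#' @param verbose Print one line per epoch.
#' @return A trained `esdm` object whose `manifest` records the
#'   configuration echo, seeds, data fingerprint, per-epoch loss trajectory,
#'   selected checkpoint epoch and complexity report.
#' @export
esdm_train <- function(dataset, config = esdm_config(),
                       train_config = esdm_train_config(),
                       loss_cfg = loss_config(), verbose = FALSE) {
  stopifnot(inherits(train_config, "esdm_train_config"),
            inherits(loss_cfg, "loss_config"))
  if (length(dataset$train) == 0L) stop("empty training split")
  model <- esdm_model(config, init_seed = train_config$seed)
  K <- config$n_classes
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(train_config$seed + 1L)

  traj <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), LD = numeric(), Lseg = numeric())
  best <- list(params = model$params, val = Inf, epoch = 0L)
  if (train_config$epochs > 0L) {
    mstate <- lapply(model$params, function(p) p * 0)
    vstate <- mstate
    t <- 0L
    b1 <- train_config$adam_beta1; b2 <- train_config$adam_beta2
    eps <- train_config$adam_epsilon; lr <- train_config$learning_rate
    ntr <- length(dataset$train)
    for (epoch in seq_len(train_config$epochs)) {
      ord <- sample.int(ntr)
      chunks <- split(ord, ceiling(seq_along(ord) / train_config$batch_size))
      ep_loss <- 0; ep_ld <- 0; ep_ls <- 0
      for (ch in chunks) {
        b <- pairs_to_batch(dataset$train, ch, K)
        r <- esdm_loss_grads(model, b, loss_cfg)
        if (!is.finite(r$Lc))
          stop("training diverged at epoch ", epoch,
               " (combined loss = ", r$Lc, "); lower the learning rate")
        t <- t + 1L
        c1 <- 1 - b1^t; c2 <- 1 - b2^t
        for (nm in names(r$grads)) {
          g <- r$grads[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g * g
          model$params[[nm]] <- model$params[[nm]] -
            lr * (mstate[[nm]] / c1) / (sqrt(vstate[[nm]] / c2) + eps)
        }
        w <- length(ch) / ntr
        ep_loss <- ep_loss + r$Lc * w
        ep_ld <- ep_ld + r$LD * w
        ep_ls <- ep_ls + r$Lseg * w
      }
      vl <- esdm_val_loss(model, dataset$val, loss_cfg,
                          train_config$batch_size)
      traj <- rbind(traj, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = vl, LD = ep_ld,
                                     Lseg = ep_ls))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, ep_loss, vl))
      if (is.finite(vl) && vl < best$val) {
        best <- list(params = model$params, val = vl, epoch = epoch)
      }
    }
    if (train_config$checkpoint == "best" && best$epoch > 0L)
      model$params <- best$params
  }
  model$trained <- train_config$epochs > 0L
  model$loss_config <- loss_cfg
  model$manifest <- list(
    config = unclass(config),
    train_config = unclass(train_config),
    loss = list(alpha = loss_cfg$alpha, beta = loss_cfg$beta,
                confidence = loss_cfg$confidence,
                feature_extractor = loss_cfg$feature_extractor$mode,
                feature_seed = loss_cfg$feature_extractor$seed),
    adam = list(beta1 = train_config$adam_beta1,
                beta2 = train_config$adam_beta2,
                epsilon = train_config$adam_epsilon),
    seed = train_config$seed,
    data_fingerprint = dataset_fingerprint(dataset),
    trajectory = traj,
    best_epoch = if (best$epoch > 0L) best$epoch else NA_integer_,
    best_val_loss = if (is.finite(best$val)) best$val else NA_real_,
    parameters_millions = count_parameters(model)$millions)
  model
}

#' Save / load a model checkpoint
#'
#' The weights (with configuration and manifest) are serialized to an RDS
#' file; a JSON sidecar `<path>.json` carries the human-readable architecture
#' manifest (configuration echo plus parameter breakdown) for
#' reproducibility.
#'
#' @param model A trained or untrained `esdm` object.
#' @param path Checkpoint path (conventionally `.rds`).
#' @return `esdm_save` returns `path` invisibly; `esdm_load` the model.
#' @export
esdm_save <- function(model, path) {
  stopifnot(inherits(model, "esdm"))
  saveRDS(model, path)
  cp <- count_parameters(model)
  jsonlite::write_json(
    list(config = unclass(model$config),
         trainable_parameters = cp$trainable_parameters,
         millions = cp$millions,
         per_component = cp$per_component,
         manifest = if (!is.null(model$manifest))
           model$manifest[setdiff(names(model$manifest), "trajectory")]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname esdm_save
#' @export
esdm_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "esdm"))
  model
}

#' Full-frame inference on a volume
#'
#' Runs the model on every frame of a single-repetition acquisition: patches
#' are extracted per the crop specification, forward-passed, the denoised
#' patches clipped to `[0, 1]` and stitched (overlapping pixels averaged),
#' and the segmentation obtained as the per-pixel argmax of the stitched
#' softmax probabilities (ties broken toward the lowest class index).
#' Pixels outside every crop window keep the input intensity and receive
#' label 0.
#'
#' @param model A trained `esdm` object.
#' @param volume An [oct_volume()]; only repetition 1 is used.
#' @param spec A [crop_spec()]; defaults to the lens protocol of the volume.
#'   Frames incompatible with the windows raise an error.
#' @return An object of class `esdm_prediction`: list with `denoised`
#'   (`F x Z x X`), `masks` (`F x Z x X`, values `0:(K-1)`) and `covered`
#'   (`Z x X` logical).
#' @export
infer <- function(model, volume, spec = NULL) {
  stopifnot(inherits(model, "esdm"), inherits(volume, "oct_volume"))
  if (is.null(spec)) spec <- default_crop_spec(volume$lens_tag)
  d <- dim(volume$data)
  Fn <- d[1L]; Z <- d[3L]; X <- d[4L]
  K <- model$config$n_classes
  den <- array(0, c(Fn, Z, X))
  msk <- array(0L, c(Fn, Z, X))
  covered <- NULL
  for (f in seq_len(Fn)) {
    frame <- volume$data[f, 1L, , , drop = TRUE]
    patches <- extract_patches(frame, spec)
    nw <- length(patches)
    xb <- array(0, c(spec$patch_height, spec$patch_width, 1L, nw))
    for (w in seq_len(nw)) xb[, , 1L, w] <- patches[[w]]
    out <- forward_esdm(model, xb, train = FALSE)
    dn_patches <- list(); pr_patches <- vector("list", K)
    for (w in seq_len(nw)) {
      if (!is.null(out$denoised)) {
        p <- pmin(pmax(out$denoised[, , 1L, w], 0), 1)
        attr(p, "window") <- attr(patches[[w]], "window")
        dn_patches[[w]] <- p
      }
      if (!is.null(out$logits)) {
        probs <- esdm_softmax_k(out$logits[, , , w, drop = FALSE])
        for (k in seq_len(K)) {
          q <- probs[, , k, 1L]
          attr(q, "window") <- attr(patches[[w]], "window")
          pr_patches[[k]] <- c(pr_patches[[k]], list(q))
        }
      }
    }
    if (length(dn_patches)) {
      canvas <- stitch_patches(dn_patches, Z, X)
      miss <- is.na(canvas)
      canvas[miss] <- frame[miss]
      den[f, , ] <- canvas
      if (is.null(covered)) covered <- !miss
    } else den[f, , ] <- frame
    if (!is.null(out$logits)) {
      prob_canvas <- lapply(pr_patches, stitch_patches, depth = Z, width = X)
      pc <- simplify2array(prob_canvas)   # Z x X x K
      lab <- apply(pc, c(1L, 2L), function(v)
        if (all(is.na(v))) 1L else which.max(v)) - 1L
      msk[f, , ] <- lab
      if (is.null(covered)) covered <- !is.na(prob_canvas[[1L]])
    }
  }
  structure(list(denoised = den, masks = msk, covered = covered,
                 spec = spec),
            class = "esdm_prediction")
}

#' @export
predict.esdm <- function(object, newdata, spec = NULL, ...) {
  if (inherits(newdata, "oct_volume")) return(infer(object, newdata, spec))
  # a patch, a (H, W, N) stack or a (H, W, 1, N) batch
  x <- newdata
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3L])
  out <- forward_esdm(object, x, train = FALSE)
  res <- list()
  if (!is.null(out$denoised))
    res$denoised <- pmin(pmax(out$denoised, 0), 1)
  if (!is.null(out$logits)) {
    probs <- esdm_softmax_k(out$logits)
    res$probabilities <- probs
    res$masks <- apply(probs, c(1L, 2L, 4L), which.max) - 1L
  }
  res
}

#' Evaluate a model on held-out data pairs
#'
#' Runs inference on every pair's noisy patch, then computes the per-image
#' quality metrics against the frame-averaged targets, the segmentation
#' metrics against the reference labels, and the thickness mean absolute
#' error between predicted and reference masks.
#'
#' @param model A trained `esdm` object.
#' @param pairs Non-empty list of data pairs (held out by volume).
#' @param ssim_cfg An [ssim_config()].
#' @param thickness_cfg A [thickness_config()].
#' @param out_dir Optional directory for the metric report and thickness CSV.
#' @param batch_size Forward batch size.
#' @return A list with `metrics` (a `metric_report`), `thickness_mae` and
#'   `outputs` (per-pair denoised patch and predicted mask).
#' @export
evaluate_model <- function(model, pairs, ssim_cfg = ssim_config(),
                           thickness_cfg = thickness_config(),
                           out_dir = NULL, batch_size = 16L) {
  if (length(pairs) == 0L) stop("empty test set")
  K <- model$config$n_classes
  idx_all <- seq_along(pairs)
  chunks <- split(idx_all, ceiling(idx_all / batch_size))
  outputs <- vector("list", length(pairs))
  for (ch in chunks) {
    b <- pairs_to_batch(pairs, ch, K)
    out <- forward_esdm(model, b$noisy, train = FALSE)
    for (j in seq_along(ch)) {
      o <- list()
      if (!is.null(out$denoised))
        o$denoised <- pmin(pmax(out$denoised[, , 1L, j], 0), 1)
      if (!is.null(out$logits)) {
        probs <- esdm_softmax_k(out$logits[, , , j, drop = FALSE])
        o$mask <- apply(probs[, , , 1L], c(1L, 2L), which.max) - 1L
      }
      outputs[[ch[j]]] <- o
    }
  }
  metrics <- evaluate_dataset(pairs, outputs, ssim_cfg, K)
  tmae <- NULL
  if (!is.null(outputs[[1L]]$mask)) {
    pred_prof <- lapply(outputs, function(o)
      measure_thickness(o$mask, thickness_cfg))
    ref_prof <- lapply(pairs, function(p)
      measure_thickness(p$label, thickness_cfg))
    tmae <- tryCatch(thickness_mae(pred_prof, ref_prof), error = function(e) NULL)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metric_report(metrics, file.path(out_dir, "metrics"))
    if (!is.null(tmae))
      write_thickness_csv(lapply(outputs, function(o)
        measure_thickness(o$mask, thickness_cfg)),
        file.path(out_dir, "thickness.csv"), mae = tmae)
  }
  list(metrics = metrics, thickness_mae = tmae, outputs = outputs)
}

#' @export
plot.esdm <- function(x, ...) {
  tr <- x$manifest$trajectory
  if (is.null(tr) || nrow(tr) == 0L) {
    message("no training trajectory to plot")
    return(invisible(x))
  }
  rng <- range(c(tr$train_loss, tr$val_loss), finite = TRUE)
  graphics::plot(tr$epoch, tr$train_loss, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "combined loss", ylim = rng, ...)
  graphics::lines(tr$epoch, tr$val_loss, lwd = 2, lty = 2,
                  col = "firebrick")
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   lwd = 2, col = c("black", "firebrick"), bty = "n")
  if (!is.na(x$manifest$best_epoch))
    graphics::abline(v = x$manifest$best_epoch, col = "grey60", lty = 3)
  invisible(x)
}
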