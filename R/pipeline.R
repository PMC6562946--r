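# End-to-end train / predict / evaluate orchestration.
#
# One training iteration runs: (optional) augmentation -> backbone ->
# feature pyramid -> region-proposal head (objectness + box deltas over the
# anchor grid) -> proposal selection -> ROI sampling against ground truth ->
# ROI-align -> classification/box/mask heads -> multi-task loss -> clipped
# amsgrad step.  The dilated backbone keeps its pyramid levels at one fine
# resolution, so the proposal and ROI heads read the finest fused level with
# the full scale x ratio anchor set per location.  Ground-truth boxes are
# always derived from the instance masks, never stored separately.

#' Training configuration
#'
#' Defaults are the package's reference regime: a staged learning-rate schedule of
#' 1e-4 / 1e-5 / 1e-6 with stage boundaries at 20 / 40 / 75 epochs, the
#' amsgrad optimizer, gradient clipping at global norm 5.0, and batch size 1
#' with group normalization (which keeps single-image batches stable).
#'
#' @param learning_rates positive, non-increasing per-stage learning rates.
#' @param epochs cumulative epoch boundaries of the schedule stages.
#' @param iterations optional explicit iteration budget (overrides
#'   epoch-derived length).
#' @param optimizer `"amsgrad"`.
#' @param clip_norm global gradient-norm clip (> 0).
#' @param batch_size images per step (>= 1; the pipeline iterates
#'   single-image steps within a batch).
#' @param normalization `"group"` or `"batch"`.
#' @param augment apply the stochastic augmentation protocol during
#'   training.
#' @param rpn_iou_hi,rpn_iou_lo anchor assignment thresholds.
#' @param rpn_lambda balance weight of the RPN regression term.
#' @param rpn_batch sampled anchors per image (1:1 positive:negative).
#' @param pre_nms_top_k,proposal_nms_iou,post_nms_train,post_nms_infer
#'   proposal selection parameters (train / inference maxima).
#' @param roi_pos_iou proposal-vs-ground-truth IoU to count as positive.
#' @param rois_per_image sampled ROIs per step (1:1 positive:negative).
#' @param pool_size,mask_pool_size class/box and mask head pooling sizes.
#' @param score_threshold,final_nms_iou,mask_threshold inference settings.
#' @param seed master seed; all training randomness derives from it.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rates = c(1e-4, 1e-5, 1e-6),
                         epochs = c(20L, 40L, 75L),
                         iterations = NULL,
                         optimizer = "amsgrad",
                         clip_norm = 5.0,
                         batch_size = 1L,
                         normalization = c("group", "batch"),
                         augment = FALSE,
                         rpn_iou_hi = 0.7, rpn_iou_lo = 0.3,
                         rpn_lambda = 1, rpn_batch = 256L,
                         pre_nms_top_k = 1000L, proposal_nms_iou = 0.7,
                         post_nms_train = 64L, post_nms_infer = 200L,
                         roi_pos_iou = 0.5, rois_per_image = 16L,
                         pool_size = 7L, mask_pool_size = 14L,
                         score_threshold = 0.5, final_nms_iou = 0.3,
                         mask_threshold = 0.5,
                         seed = 0L) {
  normalization <- match.arg(normalization)
  if (any(learning_rates <= 0) || is.unsorted(rev(learning_rates)))
    stopf("learning rates must be positive and non-increasing")
  if (clip_norm <= 0) stopf("`clip_norm` must be positive")
  if (batch_size < 1L) stopf("`batch_size` must be >= 1")
  structure(as.list(environment()), class = "train_config")
}

## ---- model -----------------------------------------------------------------

backbone_total_stride <- function(config) {
  s <- 1L
  if (!is.null(config$stem))
    s <- s * (if (isTRUE(config$stem$pool)) 2L else 1L) * config$stem$conv_stride
  for (st in config$stages) s <- s * (st$stride %||% 1L)
  s
}

#' Assemble a trainable nuclei instance segmentation model
#'
#' Builds the backbone, pyramid fusion, proposal head and the three
#' detection branches with seeded random initialization.
#'
#' @param backbone_cfg a [backbone_config()] (e.g. [tiny_backbone_config()],
#'   [d_resnet64_config()]).
#' @param fpn_channels pyramid channel width.
#' @param anchor_scales,anchor_ratios anchor set applied at every location of
#'   the finest pyramid level.
#' @param config a [train_config()] (normalization kind is read from it).
#' @param seed initialization seed.
#' @return Object of class `nuclei_model`.
#' @export
build_nuclei_model <- function(backbone_cfg = tiny_backbone_config(),
                               fpn_channels = 64L,
                               anchor_scales = c(8, 12, 18),
                               anchor_ratios = c(0.5, 1, 2),
                               config = train_config(),
                               seed = 0L) {
  build_spec <- list(backbone_cfg = backbone_cfg, fpn_channels = fpn_channels,
                     anchor_scales = anchor_scales,
                     anchor_ratios = anchor_ratios,
                     normalization = config$normalization,
                     pool_size = config$pool_size,
                     mask_pool_size = config$mask_pool_size, seed = seed)
  with_seed(seed, {
    backbone_cfg$normalization <- config$normalization
    backbone <- build_backbone(backbone_cfg, in_channels = 3L)
    fpn <- build_fpn(backbone$out_channels, fpn_channels)
    A <- length(anchor_scales) * length(anchor_ratios)
    rpn_conv <- new_conv_layer(3L, fpn_channels, fpn_channels)
    rpn_cls <- new_conv_layer(1L, fpn_channels, A)
    rpn_reg <- new_conv_layer(1L, fpn_channels, 4L * A)
    S <- config$pool_size
    box_fc <- new_linear_layer(S * S * fpn_channels, 256L)
    cls_out <- new_linear_layer(256L, 2L)
    box_out <- new_linear_layer(256L, 4L)
    mask_head <- build_mask_head(fpn_channels, 64L, 1L)
    model <- structure(list(
      backbone = backbone, fpn = fpn,
      rpn_conv = rpn_conv, rpn_cls = rpn_cls, rpn_reg = rpn_reg,
      box_fc = box_fc, cls_out = cls_out, box_out = box_out,
      mask_head = mask_head,
      anchor_scales = anchor_scales, anchor_ratios = anchor_ratios,
      n_anchors = A,
      stride = backbone_total_stride(backbone_cfg),
      build_spec = build_spec,
      cache = new.env(parent = emptyenv())),
      class = "nuclei_model")
    model$params <- collect_params(model[c("backbone", "fpn", "rpn_conv",
                                           "rpn_cls", "rpn_reg", "box_fc",
                                           "cls_out", "box_out", "mask_head")])
    model
  })
}

#' @export
print.nuclei_model <- function(x, ...) {
  n_w <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("nuclei_model: %d weight layers backbone, stride %d, %d anchors/location, %s parameters\n",
              count_weight_layers(x$backbone$config), x$stride, x$n_anchors,
              format(n_w, big.mark = ",")))
  invisible(x)
}

model_anchors <- function(model, H, W) {
  key <- paste(H, W, sep = "x")
  if (is.null(model$cache[[key]])) {
    hf <- H %/% model$stride; wf <- W %/% model$stride
    anchors <- generate_anchors(model$anchor_scales, model$anchor_ratios,
                                c(hf, wf), model$stride, order = "anchor")
    # flat gather indices of the 4 delta components per anchor
    n <- nrow(anchors)
    hw <- hf * wf
    a_ix <- rep(seq_len(model$n_anchors), each = hw)
    pos_ix <- rep(seq_len(hw), model$n_anchors)
    didx <- sapply(1:4, function(cc) pos_ix + ((a_ix - 1L) * 4L + cc - 1L) * hw)
    model$cache[[key]] <- list(anchors = anchors, hf = hf, wf = wf,
                               delta_idx = didx)
  }
  model$cache[[key]]
}

model_forward_features <- function(model, image, training = TRUE) {
  x <- ag_node(image / 255 - 0.5)
  stages <- backbone_forward(model$backbone, x, training = training)
  levels <- fuse(model$fpn, stages)
  levels[[1]]  # finest fused level feeds the proposal and ROI heads
}

rpn_forward <- function(model, feat) {
  h <- ag_relu(conv_fwd(model$rpn_conv, feat))
  list(logits = conv_fwd(model$rpn_cls, h),
       deltas = conv_fwd(model$rpn_reg, h))
}

gt_boxes_from_labels <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) return(list(boxes = matrix(0, 0, 4), ids = integer(0)))
  boxes <- t(vapply(ids, function(i) mask_to_bbox(labels == i), numeric(4)))
  list(boxes = boxes, ids = ids)
}

# nearest-neighbour 0/1 mask target of one instance on an MxM grid over `box`
mask_target_grid <- function(labels, id, box, M) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  xs <- box[1] + (seq_len(M) - 0.5) / M * w
  ys <- box[2] + (seq_len(M) - 0.5) / M * h
  cc <- clamp(floor(xs) + 1L, 1L, ncol(labels))
  rr <- clamp(floor(ys) + 1L, 1L, nrow(labels))
  (labels[rr, cc, drop = FALSE] == id) * 1
}

sample_balanced <- function(pos_pool, neg_pool, total, pos_fraction = 0.5) {
  n_pos <- min(length(pos_pool), ceiling(total * pos_fraction))
  pos <- if (n_pos > 0L) sample(pos_pool, n_pos) else integer(0)
  n_neg <- min(length(neg_pool), total - n_pos)
  neg <- if (n_neg > 0L) sample(neg_pool, n_neg) else integer(0)
  list(pos = pos, neg = neg)
}

# one optimization step on a single image; returns loss components
train_step <- function(model, image, labels, opt, cfg, lr) {
  H <- dim(image)[1]; W <- dim(image)[2]
  ai <- model_anchors(model, H, W)
  gt <- gt_boxes_from_labels(labels)
  ag_tape_begin()
  on.exit(if (ag_tape_active()) ag_tape_end(), add = TRUE)
  feat <- model_forward_features(model, image, training = TRUE)
  rpn <- rpn_forward(model, feat)
  n_anch <- nrow(ai$anchors)

  assignment <- assign_anchors(ai$anchors, gt$boxes, cfg$rpn_iou_hi, cfg$rpn_iou_lo)
  pos_pool <- which(assignment$label == "positive")
  neg_pool <- which(assignment$label == "negative")
  sm <- sample_balanced(pos_pool, neg_pool, cfg$rpn_batch)
  sampled <- c(sm$pos, sm$neg)
  targets <- as.numeric(seq_along(sampled) <= length(sm$pos))
  logits_flat <- ag_reshape(rpn$logits, c(n_anch, 1L))
  rpn_cls_loss <- ag_bce_logits(ag_gather(logits_flat, matrix(sampled, ncol = 1)),
                                matrix(targets, ncol = 1))
  pos <- sm$pos
  if (length(pos) > 0L) {
    t_star <- encode_boxes(gt$boxes[assignment$gt_index[pos], , drop = FALSE],
                           ai$anchors[pos, , drop = FALSE])
    deltas_flat <- ag_reshape(rpn$deltas, c(n_anch * 4L, 1L))
    pred <- ag_reshape(ag_gather(deltas_flat,
                                 matrix(ai$delta_idx[pos, ], ncol = 1)),
                       c(length(pos), 4L))
    rpn_reg_loss <- ag_smooth_l1_loss(pred, t_star, scale = 1 / length(pos))
  } else rpn_reg_loss <- ag_node(0)

  # proposals from the current predictions (boxes treated as constants)
  scores <- as.vector(1 / (1 + exp(-ag_value(rpn$logits))))
  dvals <- ag_value(rpn$deltas)
  dim(dvals) <- c(ai$hf * ai$wf, 4L * model$n_anchors)
  dmat <- matrix(dvals[matrix(ai$delta_idx, ncol = 1)], n_anch, 4L)
  prop <- suppressWarnings(decode_boxes(dmat, ai$anchors, clip_to = c(W, H)))
  keepable <- which(prop[, 3] - prop[, 1] >= 1 & prop[, 4] - prop[, 2] >= 1)
  sel <- select_proposals(prop[keepable, , drop = FALSE], scores[keepable],
                          cfg$pre_nms_top_k, cfg$proposal_nms_iou,
                          cfg$post_nms_train)
  rois <- rbind(sel$boxes, gt$boxes)  # ground-truth boxes join the ROI pool

  cls_loss <- box_loss <- mask_loss <- ag_node(0)
  if (nrow(gt$boxes) > 0L && nrow(rois) > 0L) {
    iou <- box_iou(rois, gt$boxes)
    max_iou <- apply(iou, 1, max)
    roi_gt <- apply(iou, 1, which.max)
    sm2 <- sample_balanced(which(max_iou >= cfg$roi_pos_iou),
                           which(max_iou < cfg$roi_pos_iou),
                           cfg$rois_per_image)
    take <- c(sm2$pos, sm2$neg)
    if (length(take) > 0L) {
      rois_t <- rois[take, , drop = FALSE]
      roi_labels <- c(rep(2L, length(sm2$pos)), rep(1L, length(sm2$neg)))
      pooled <- ag_roi_align(feat, rois_t, cfg$pool_size, 1 / model$stride)
      Cp <- model$fpn$pyramid_channels
      flat <- ag_rbind(lapply(pooled, function(p)
        ag_reshape(p, c(1L, cfg$pool_size^2 * Cp))))
      hfc <- ag_relu(linear_fwd(model$box_fc, flat))
      cls_logits <- linear_fwd(model$cls_out, hfc)
      box_pred <- linear_fwd(model$box_out, hfc)
      cls_loss <- ag_softmax_ce(cls_logits, roi_labels)
      npos <- length(sm2$pos)
      if (npos > 0L) {
        pidx <- seq_len(npos)
        gtb <- gt$boxes[roi_gt[take[pidx]], , drop = FALSE]
        t_star2 <- encode_boxes(gtb, rois_t[pidx, , drop = FALSE])
        flatidx <- matrix(outer(pidx, (0:3) * length(take), "+"), ncol = 1)
        bp <- ag_reshape(ag_gather(ag_reshape(box_pred, c(length(take) * 4L, 1L)),
                                   flatidx), c(npos, 4L))
        box_loss <- ag_smooth_l1_loss(bp, t_star2, scale = 1 / npos)
        Mp <- cfg$mask_pool_size
        pooled_m <- ag_roi_align(feat, rois_t[pidx, , drop = FALSE], Mp,
                                 1 / model$stride)
        mlogits <- ag_rbind(lapply(pooled_m, function(p)
          ag_reshape(mask_head_forward(model$mask_head, p),
                     c(1L, (2L * Mp)^2))))
        mtarg <- do.call(rbind, lapply(pidx, function(i)
          as.vector(mask_target_grid(labels, gt$ids[roi_gt[take[i]]],
                                     rois_t[i, ], 2L * Mp))))
        mask_loss <- ag_bce_logits(mlogits, mtarg)
      }
    }
  }

  total <- ag_weighted_sum(list(rpn_cls_loss, rpn_reg_loss, cls_loss,
                                box_loss, mask_loss))
  comps <- c(total = ag_value(total),
             rpn_cls = ag_value(rpn_cls_loss), rpn_reg = ag_value(rpn_reg_loss),
             cls = ag_value(cls_loss), box = ag_value(box_loss),
             mask = ag_value(mask_loss))
  if (any(!is.finite(comps)))
    stopf("training diverged: non-finite loss (%s)",
          paste(names(comps), round(comps, 4), collapse = ", "))
  ag_backward(total)
  ag_tape_end()
  optimizer_step(opt, lr = lr)
  ag_zero_grads(opt$params)
  comps
}

lr_for_iteration <- function(cfg, iteration, n_scenes) {
  epoch <- ceiling(iteration / max(1L, n_scenes))
  stage <- findInterval(epoch - 1e-9, cfg$epochs) + 1L
  cfg$learning_rates[min(stage, length(cfg$learning_rates))]
}

#' Train a nuclei model on a set of scenes
#'
#' Runs single-image optimization steps cycling through the scenes,
#' deterministic for a fixed config seed. Training aborts with a diagnostic
#' if the loss becomes non-finite.
#'
#' @param model a [build_nuclei_model()] result (updated in place; parameter
#'   nodes have reference semantics).
#' @param scenes list of `synthetic_scene`s or lists with `image` and
#'   `labels`.
#' @param config a [train_config()]; `iterations` (or the epoch schedule)
#'   sets the step budget.
#' @param start_iteration resume counter (e.g. from a checkpoint).
#' @param verbose print progress every 25 iterations.
#' @return List with `model` and `trace` (per-iteration loss components).
#' @export
train_nuclei <- function(model, scenes, config = train_config(),
                         start_iteration = 0L, verbose = FALSE) {
  stopifnot(inherits(model, "nuclei_model"), length(scenes) > 0L)
  n <- length(scenes)
  total_iter <- config$iterations %||% (max(config$epochs) * n)
  opt <- model$cache$optimizer
  if (is.null(opt)) {
    opt <- new_optimizer(model$params, lr = config$learning_rates[1],
                         clip_norm = config$clip_norm)
    model$cache$optimizer <- opt
  }
  trace <- vector("list", total_iter)
  for (k in seq_len(total_iter)) {
    it <- start_iteration + k
    set.seed(derive_seed(config$seed, it))
    sc <- scenes[[(it - 1L) %% n + 1L]]
    image <- sc$image; labels <- sc$labels
    if (isTRUE(config$augment)) {
      aug <- suppressWarnings(random_augment(image, labels,
                                             seed = derive_seed(config$seed, it, 7L)))
      image <- aug$image; labels <- aug$labels
    }
    lr <- lr_for_iteration(config, it, n)
    comps <- train_step(model, image, labels, opt, config, lr)
    trace[[k]] <- c(iteration = it, lr = lr, comps)
    if (verbose && (k %% 25L == 0L || k == 1L))
      message(sprintf("iter %d/%d total %.4f", it, start_iteration + total_iter,
                      comps[["total"]]))
  }
  list(model = model, trace = as.data.frame(do.call(rbind, trace)))
}

## ---- inference --------------------------------------------------------------

#' Detect and segment nuclei in an image
#'
#' Proposal generation, head scoring, final per-class non-maximum
#' suppression and mask pasting. Deterministic: the same image always yields
#' the same result.
#'
#' @param model a trained `nuclei_model`.
#' @param image (H, W, 3) integer image (0..255).
#' @param config a [train_config()] supplying inference settings.
#' @param auto_pad pad images whose sides are not multiples of the model
#'   stride (edge replication) instead of erroring.
#' @return Object of class `detection_result`: list with `boxes`, `scores`,
#'   `masks` (list of logical matrices) and `label_map` (instances pasted in
#'   score order; overlaps kept by the higher-scoring instance).
#' @export
predict_nuclei <- function(model, image, config = train_config(),
                           auto_pad = FALSE) {
  H0 <- dim(image)[1]; W0 <- dim(image)[2]
  stride <- model$stride
  if (H0 %% stride != 0L || W0 %% stride != 0L || H0 < 2L * stride ||
      W0 < 2L * stride) {
    if (!auto_pad)
      stopf("image %dx%d is not a multiple of the model stride (%d); enable auto_pad",
            H0, W0, stride)
    H <- max(2L * stride, ceiling(H0 / stride) * stride)
    W <- max(2L * stride, ceiling(W0 / stride) * stride)
    padded <- array(0L, c(H, W, dim(image)[3]))
    padded[seq_len(H), seq_len(W), ] <-
      image[clamp(seq_len(H), 1, H0), clamp(seq_len(W), 1, W0), , drop = FALSE]
    image <- padded
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  ai <- model_anchors(model, H, W)
  feat_node <- model_forward_features(model, image, training = FALSE)
  feat <- ag_value(feat_node)
  rpn <- rpn_forward(model, ag_node(feat))
  n_anch <- nrow(ai$anchors)
  scores <- as.vector(1 / (1 + exp(-ag_value(rpn$logits))))
  dvals <- ag_value(rpn$deltas)
  dim(dvals) <- c(ai$hf * ai$wf, 4L * model$n_anchors)
  dmat <- matrix(dvals[matrix(ai$delta_idx, ncol = 1)], n_anch, 4L)
  prop <- suppressWarnings(decode_boxes(dmat, ai$anchors, clip_to = c(W, H)))
  ok <- which(prop[, 3] - prop[, 1] >= 1 & prop[, 4] - prop[, 2] >= 1)
  sel <- select_proposals(prop[ok, , drop = FALSE], scores[ok],
                          config$pre_nms_top_k, config$proposal_nms_iou,
                          config$post_nms_infer)
  empty <- structure(list(boxes = matrix(0, 0, 4), scores = numeric(0),
                          masks = list(), label_map = matrix(0L, H0, W0)),
                     class = "detection_result")
  if (nrow(sel$boxes) == 0L) return(empty)
  pooled <- roi_align(feat, sel$boxes / model$stride, config$pool_size)
  flat <- do.call(rbind, lapply(pooled, function(p) matrix(p, 1)))
  hfc <- pmax(sweep(flat %*% model$box_fc$w$value, 2,
                    model$box_fc$b$value, "+"), 0)
  cls_logits <- sweep(hfc %*% model$cls_out$w$value, 2,
                      model$cls_out$b$value, "+")
  probs <- exp(cls_logits - apply(cls_logits, 1, max))
  probs <- probs / rowSums(probs)
  fg <- probs[, 2]
  box_d <- sweep(hfc %*% model$box_out$w$value, 2, model$box_out$b$value, "+")
  boxes <- suppressWarnings(decode_boxes(box_d, sel$boxes, clip_to = c(W, H)))
  keep <- which(fg >= config$score_threshold &
                boxes[, 3] - boxes[, 1] >= 1 & boxes[, 4] - boxes[, 2] >= 1)
  if (length(keep) == 0L) return(empty)
  fin <- select_proposals(boxes[keep, , drop = FALSE], fg[keep],
                          length(keep), config$final_nms_iou, length(keep))
  fboxes <- fin$boxes; fscores <- fin$scores
  Mp <- config$mask_pool_size
  pooled_m <- roi_align(feat, fboxes / model$stride, Mp)
  label_map <- matrix(0L, H, W)
  masks <- list()
  kept_boxes <- matrix(0, 0, 4); kept_scores <- numeric(0)
  nid <- 0L
  for (i in order(-fscores)) {
    logits <- mask_head_logits(model$mask_head, pooled_m[[i]])[, , 1]
    pr <- 1 / (1 + exp(-logits))
    m <- paste_mask(pr, fboxes[i, ], H, W, config$mask_threshold)
    m <- m & label_map == 0L  # higher-scoring instances keep contested pixels
    if (sum(m) == 0L) next
    nid <- nid + 1L
    label_map[m] <- nid
    masks[[nid]] <- m[seq_len(H0), seq_len(W0), drop = FALSE]
    kept_boxes <- rbind(kept_boxes, fboxes[i, ])
    kept_scores <- c(kept_scores, fscores[i])
  }
  structure(list(boxes = kept_boxes, scores = kept_scores, masks = masks,
                 label_map = label_map[seq_len(H0), seq_len(W0), drop = FALSE]),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: %d instances (scores %s)\n", length(x$scores),
              if (length(x$scores)) paste(round(range(x$scores), 3), collapse = "-")
              else "-"))
  invisible(x)
}

#' Convert a detection result (or image + labels) to a writable scene
#'
#' @param image (H, W, 3) integer image.
#' @param labels integer label map (e.g. `detection_result$label_map`).
#' @return List accepted by [write_instance_layout()].
#' @export
as_scene <- function(image, labels) list(image = image, labels = labels)

## ---- checkpoints -------------------------------------------------------------

collect_norm_states <- function(x) {
  if (is.environment(x)) return(list())
  if (is.list(x)) {
    if (identical(x$type, "norm")) return(list(x$state))
    if (inherits(x, "nuclei_model"))
      return(collect_norm_states(unclass(x)[c("backbone", "fpn", "rpn_conv",
                                              "rpn_cls", "rpn_reg", "box_fc",
                                              "cls_out", "box_out", "mask_head")]))
    return(do.call(c, lapply(x, collect_norm_states)))
  }
  list()
}

#' Save model weights, configuration and iteration counter
#'
#' @param model a `nuclei_model`.
#' @param path output file (RDS).
#' @param config the [train_config()] in use.
#' @param iteration iteration counter to store.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, config = NULL, iteration = 0L) {
  states <- lapply(collect_norm_states(model), function(e)
    list(mean = e$mean, var = e$var))
  saveRDS(list(build_spec = model$build_spec,
               weights = lapply(model$params, function(p) p$value),
               norm_states = states,
               config = config, iteration = as.integer(iteration)),
          path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' Rebuilds the model from its stored build specification and restores all
#' weights; predictions after loading are bitwise identical to those before
#' saving.
#'
#' @param path checkpoint file.
#' @return List with `model`, `config`, `iteration`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  bs <- ck$build_spec
  cfg <- ck$config %||% train_config()
  cfg$normalization <- bs$normalization
  model <- build_nuclei_model(bs$backbone_cfg, bs$fpn_channels,
                              bs$anchor_scales, bs$anchor_ratios,
                              config = cfg, seed = bs$seed)
  stopifnot(length(model$params) == length(ck$weights))
  for (i in seq_along(ck$weights)) model$params[[i]]$value <- ck$weights[[i]]
  sts <- collect_norm_states(model)
  for (i in seq_along(ck$norm_states)) {
    sts[[i]]$mean <- ck$norm_states[[i]]$mean
    sts[[i]]$var <- ck$norm_states[[i]]$var
  }
  list(model = model, config = ck$config, iteration = ck$iteration)
}

## ---- evaluation --------------------------------------------------------------

# accept a named list of label maps, or a directory of per-image layouts
load_label_maps <- function(x) {
  if (is.character(x)) {
    subs <- list.dirs(x, recursive = FALSE)
    if (length(subs) == 0L) stopf("no image layouts found under '%s'", x)
    out <- lapply(subs, read_instance_layout)
    names(out) <- basename(subs)
    out
  } else {
    stopifnot(is.list(x))
    x
  }
}

#' Score predicted against ground-truth instance layouts
#'
#' Computes per-image and mean object-level F1 (IoU >= 0.5 matching) and
#' pixel-level AJI.
#'
#' @param pred,gt named lists of label maps, or directories containing one
#'   instance-layout subdirectory per image. Names/inventories must match.
#' @param iou_threshold object-match threshold for F1.
#' @param report_path optional path for a tab-delimited report.
#' @return Data frame with one row per image plus a `mean` row (columns
#'   `image`, `f1`, `aji`).
#' @export
evaluate_layouts <- function(pred, gt, iou_threshold = 0.5,
                             report_path = NULL) {
  pred <- load_label_maps(pred)
  gt <- load_label_maps(gt)
  if (is.null(names(pred))) names(pred) <- sprintf("image_%03d", seq_along(pred))
  if (is.null(names(gt))) names(gt) <- sprintf("image_%03d", seq_along(gt))
  missing <- setdiff(names(gt), names(pred))
  extra <- setdiff(names(pred), names(gt))
  if (length(missing) || length(extra))
    stopf("image inventories differ (missing: %s; extra: %s)",
          paste(missing, collapse = ",") , paste(extra, collapse = ","))
  rows <- lapply(names(gt), function(nm) {
    f1 <- f1_score(match_instances(gt[[nm]], pred[[nm]], iou_threshold))
    data.frame(image = nm, f1 = f1, aji = aji(gt[[nm]], pred[[nm]]))
  })
  rep <- do.call(rbind, rows)
  rep <- rbind(rep, data.frame(image = "mean", f1 = mean(rep$f1),
                               aji = mean(rep$aji)))
  if (!is.null(report_path))
    utils::write.table(rep, report_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  rep
}
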