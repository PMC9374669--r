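#' Training configuration
#'
#' @param batch_size minibatch size (deployed protocol: 20).
#' @param step_size optimizer learning rate (deployed protocol: 1e-3).
#' @param epochs maximum epochs.
#' @param augmentation_factor recorded dataset-protocol constant (10); the
#'   tenfold augmentation itself is done by [augment()] before training.
#' @param seed seed for shuffling, mirroring and any weight initialization.
#' @param loss_weights c(localization, objectness, no_object); the classic
#'   grid-detector weighting 5 / 1 / 0.5.
#' @param patience early-stopping patience in epochs on validation loss.
#' @return list of class `wce_train_config`.
#' @export
train_config <- function(batch_size = 20L, step_size = 1e-3, epochs = 20L,
                         augmentation_factor = 10L, seed = 1L,
                         loss_weights = c(localization = 5, objectness = 1,
                                          no_object = 0.5),
                         patience = 10L) {
  stopifnot(batch_size >= 1, step_size >= 0, epochs >= 1,
            augmentation_factor >= 1, length(loss_weights) == 3,
            all(loss_weights >= 0))
  structure(list(batch_size = as.integer(batch_size), step_size = step_size,
                 epochs = as.integer(epochs),
                 augmentation_factor = as.integer(augmentation_factor),
                 seed = as.integer(seed), loss_weights = loss_weights,
                 patience = as.integer(patience)),
            class = "wce_train_config")
}

# Assign each ground-truth box to the cell holding its center and the
# best-IoU anchor; returns integer matrix (row, col, anchor) + target values.
assign_targets <- function(boxes, config, grid_size) {
  cell <- config$image_size / grid_size
  n <- nrow(boxes)
  if (n == 0)
    return(list(idx = matrix(integer(), 0, 3), tx = numeric(), ty = numeric(),
                tw = numeric(), th = numeric()))
  cx <- boxes$x + boxes$w / 2
  cy <- boxes$y + boxes$h / 2
  col <- pmin(pmax(floor(cx / cell), 0), grid_size - 1)
  row <- pmin(pmax(floor(cy / cell), 0), grid_size - 1)
  anchor <- vapply(seq_len(n), function(i) {
    ious <- vapply(1:3, function(a) {
      aw <- config$anchors[a, 1]; ah <- config$anchors[a, 2]
      inter <- min(boxes$w[i], aw) * min(boxes$h[i], ah)
      inter / (boxes$w[i] * boxes$h[i] + aw * ah - inter)
    }, numeric(1))
    which.max(ious)
  }, integer(1))
  eps <- 1e-4
  list(idx = cbind(row + 1L, col + 1L, anchor),
       tx = pmin(pmax(cx / cell - col, eps), 1 - eps),
       ty = pmin(pmax(cy / cell - row, eps), 1 - eps),
       tw = log(boxes$w / config$anchors[anchor, 1]),
       th = log(boxes$h / config$anchors[anchor, 2]),
       gx = cx, gy = cy, gw = boxes$w, gh = boxes$h)
}

#' Derive anchor priors from ground-truth box dimensions
#'
#' Lloyd k-means on (w, h) under the IoU distance (1 - IoU of
#' center-aligned boxes), the YOLOv2 convention for picking priors that
#' match the data's size distribution. Deterministic: initialized at the
#' size quantiles.
#'
#' @param frames list of `wce_frame` (their ground-truth boxes are pooled).
#' @param k number of anchors (the head uses 3).
#' @param iters Lloyd iterations.
#' @return k x 2 matrix of (w, h) priors, sorted by area.
#' @export
anchors_from_boxes <- function(frames, k = 3L, iters = 25L) {
  wh <- do.call(rbind, lapply(frames, function(f)
    if (nrow(f$boxes) > 0) cbind(f$boxes$w, f$boxes$h)))
  if (is.null(wh) || nrow(wh) < k)
    stop("need at least ", k, " ground-truth boxes to fit anchors")
  ctr <- wh[order(wh[, 1] * wh[, 2]), , drop = FALSE]
  qs <- stats::quantile(seq_len(nrow(ctr)), probs = (seq_len(k) - 0.5) / k,
                        type = 1)
  centers <- ctr[as.integer(qs), , drop = FALSE]
  d_iou <- function(a, b) { # center-aligned IoU distance
    inter <- pmin(a[, 1], b[1]) * pmin(a[, 2], b[2])
    1 - inter / (a[, 1] * a[, 2] + b[1] * b[2] - inter)
  }
  for (it in seq_len(iters)) {
    D <- vapply(seq_len(k), function(j) d_iou(wh, centers[j, ]), numeric(nrow(wh)))
    assign <- max.col(-matrix(D, nrow(wh), k), ties.method = "first")
    for (j in seq_len(k)) {
      m <- assign == j
      if (any(m)) centers[j, ] <- colMeans(wh[m, , drop = FALSE])
    }
  }
  centers[order(centers[, 1] * centers[, 2]), , drop = FALSE]
}

# Composite grid-detection loss and its gradient at the raw output grid.
# out: (g, g, 15, N); targets: list per image from assign_targets.
# Localization on a matched anchor combines an IoU loss on the decoded box
# (differentiated through center and size, so small boxes are held to the
# absolute precision the AP metric demands) with a 0.25-weighted
# squared-error term in offset space that keeps gradients alive when boxes
# barely overlap. The objectness target is the predicted box's IoU with its
# ground truth (constant w.r.t. the gradient), so the confidence learns to
# rank well-localized boxes first.
detection_loss <- function(out, targets, weights, config, grid_size) {
  d <- dim(out); g1 <- d[1]; g2 <- d[2]; N <- d[4]
  lw <- weights[1]; ow <- weights[2]; nw <- weights[3]
  cell <- config$image_size / grid_size
  grad <- array(0, dim = d)
  loss <- 0
  score_ch <- c(1L, 6L, 11L)
  for (i in seq_len(N)) {
    tgt <- targets[[i]]
    resp <- matrix(FALSE, g1 * g2, 3)
    if (nrow(tgt$idx) > 0) {
      for (b in seq_len(nrow(tgt$idx))) {
        r <- tgt$idx[b, 1]; cc <- tgt$idx[b, 2]; a <- tgt$idx[b, 3]
        resp[r + g1 * (cc - 1L), a] <- TRUE
        base <- (a - 1L) * 5L
        raw <- out[r, cc, base + (2:5), i]
        sx <- sigmoid(raw[1]); sy <- sigmoid(raw[2])
        pcx <- (cc - 1 + sx) * cell
        pcy <- (r - 1 + sy) * cell
        clamped_w <- raw[3] < -4 || raw[3] > 4
        clamped_h <- raw[4] < -4 || raw[4] > 4
        pw <- config$anchors[a, 1] * exp(min(max(raw[3], -4), 4))
        ph <- config$anchors[a, 2] * exp(min(max(raw[4], -4), 4))
        gw <- tgt$gw[b]; gh <- tgt$gh[b]
        gl <- tgt$gx[b] - gw / 2; grr <- tgt$gx[b] + gw / 2
        gt_ <- tgt$gy[b] - gh / 2; gb <- tgt$gy[b] + gh / 2
        pl <- pcx - pw / 2; pr <- pcx + pw / 2
        pt <- pcy - ph / 2; pb <- pcy + ph / 2
        iw <- min(pr, grr) - max(pl, gl)
        ih <- min(pb, gb) - max(pt, gt_)
        U0 <- pw * ph + gw * gh
        if (iw > 0 && ih > 0) {
          I <- iw * ih
          U <- U0 - I
          iou_pg <- I / U
          # partials of the intersection edges
          diw_dpcx <- (pr < grr) - (pl > gl)
          diw_dpw <- 0.5 * ((pr < grr) + (pl > gl))
          dih_dpcy <- (pb < gb) - (pt > gt_)
          dih_dph <- 0.5 * ((pb < gb) + (pt > gt_))
          dI <- c(ih * diw_dpcx, iw * dih_dpcy, ih * diw_dpw, iw * dih_dph)
          dAp <- c(0, 0, ph, pw)
          diou <- (dI * (U + I) - I * dAp) / U^2
        } else {
          I <- 0; iou_pg <- 0
          diou <- c(0, 0, 0, 0)
        }
        # objectness toward the (constant) predicted-box IoU
        ts <- out[r, cc, base + 1L, i]
        p <- sigmoid(ts)
        loss <- loss + ow * (-iou_pg * log(max(p, 1e-12)) -
                               (1 - iou_pg) * log(max(1 - p, 1e-12)))
        grad[r, cc, base + 1L, i] <- grad[r, cc, base + 1L, i] +
          ow * (p - iou_pg)
        # localization: IoU loss + 0.25 * squared error in offset space
        errs <- c(sx - tgt$tx[b], sy - tgt$ty[b],
                  raw[3] - tgt$tw[b], raw[4] - tgt$th[b])
        loss <- loss + lw * ((1 - iou_pg) + 0.25 * sum(errs^2))
        # chain to the raw activations
        dsx <- sx * (1 - sx); dsy <- sy * (1 - sy)
        g_tx <- lw * (-diou[1] * cell * dsx + 0.5 * errs[1] * dsx)
        g_ty <- lw * (-diou[2] * cell * dsy + 0.5 * errs[2] * dsy)
        g_tw <- lw * ((if (clamped_w) 0 else -diou[3] * pw) + 0.5 * errs[3])
        g_th <- lw * ((if (clamped_h) 0 else -diou[4] * ph) + 0.5 * errs[4])
        grad[r, cc, base + 2L, i] <- grad[r, cc, base + 2L, i] + g_tx
        grad[r, cc, base + 3L, i] <- grad[r, cc, base + 3L, i] + g_ty
        grad[r, cc, base + 4L, i] <- grad[r, cc, base + 4L, i] + g_tw
        grad[r, cc, base + 5L, i] <- grad[r, cc, base + 5L, i] + g_th
      }
    }
    # no-object term over all non-responsible anchors
    for (a in 1:3) {
      sc <- out[, , score_ch[a], i]
      p <- sigmoid(as.vector(sc))
      mask <- !resp[, a]
      loss <- loss + nw * sum(-log(pmax(1 - p[mask], 1e-12)))
      gsc <- numeric(g1 * g2)
      gsc[mask] <- nw * p[mask]
      grad[, , score_ch[a], i] <- grad[, , score_ch[a], i] +
        matrix(gsc, g1, g2)
    }
  }
  list(loss = unname(loss) / N, grad = grad / N)
}

frames_to_batch <- function(frames, mirror = FALSE) {
  S <- dim(frames[[1]]$pixels)[1]
  N <- length(frames)
  x <- array(0, dim = c(S, S, 3, N))
  boxes <- vector("list", N)
  for (i in seq_len(N)) {
    f <- frames[[i]]
    if (mirror && runif(1) < 0.5) {
      px <- f$pixels[, S:1, , drop = FALSE]
      b <- f$boxes
      if (nrow(b) > 0) b$x <- S - b$x - b$w
      x[, , , i] <- px
      boxes[[i]] <- b
    } else {
      x[, , , i] <- f$pixels
      boxes[[i]] <- f$boxes
    }
  }
  list(x = x, boxes = boxes)
}

# --- Adam over the network's named tensors ------------------------------

param_slots <- function(l) {
  if (l$type == "conv") {
    s <- c("w", if (!is.null(l$bias)) "bias")
    if (!is.null(l$bn)) s <- c(s, "bn.gamma", "bn.beta")
  } else {
    s <- c("dw", "pw")
    if (!is.null(l$bn1)) s <- c(s, "bn1.gamma", "bn1.beta")
    if (!is.null(l$bn2)) s <- c(s, "bn2.gamma", "bn2.beta")
  }
  s
}

get_slot <- function(l, slot) {
  p <- strsplit(slot, ".", fixed = TRUE)[[1]]
  if (length(p) == 1) l[[p]] else l[[p[1]]][[p[2]]]
}

set_slot <- function(l, slot, value) {
  p <- strsplit(slot, ".", fixed = TRUE)[[1]]
  if (length(p) == 1) l[[p]] <- value else l[[p[1]]][[p[2]]] <- value
  l
}

grad_slot <- function(gr, slot) {
  switch(slot, w = gr$w, bias = gr$bias, dw = gr$dw, pw = gr$pw,
         bn.gamma = gr$gamma, bn.beta = gr$beta,
         bn1.gamma = gr$gamma1, bn1.beta = gr$beta1,
         bn2.gamma = gr$gamma2, bn2.beta = gr$beta2)
}

adam_init <- function(network) {
  lapply(network$layers, function(l)
    lapply(setNames(nm = param_slots(l)), function(s) {
      v <- get_slot(l, s)
      list(m = array(0, dim = dim(v) %||% length(v)),
           v = array(0, dim = dim(v) %||% length(v)))
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(network, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (k in seq_along(network$layers)) {
    l <- network$layers[[k]]
    for (s in param_slots(l)) {
      g <- grad_slot(grads[[k]], s)
      st <- state[[k]][[s]]
      st$m <- beta1 * st$m + (1 - beta1) * as.vector(g)
      st$v <- beta2 * st$v + (1 - beta2) * as.vector(g)^2
      upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      val <- get_slot(l, s)
      val[] <- as.vector(val) - as.vector(upd)
      l <- set_slot(l, s, val)
      state[[k]][[s]] <- st
    }
    network$layers[[k]] <- l
  }
  list(network = network, state = state)
}

#' Train the grid detector
#'
#' Minimizes the composite grid-detection loss (squared-error localization
#' on the matched cell/anchor, binary-cross-entropy objectness, down-weighted
#' no-object term) with Adam at the configured step size, random horizontal
#' mirroring at training time, per-epoch validation, and early stopping.
#' Returns the best-on-validation weights.
#'
#' @param network a `wce_network` whose input size matches the frames.
#' @param split a [split_by_patient()] result (train non-empty; validation
#'   may be empty, in which case the final weights are returned).
#' @param config a [train_config()].
#' @param head a [head_config()] supplying anchors and image size for
#'   target assignment.
#' @param verbose print per-epoch losses?
#' @return list with `network` (trained), `history` (data.frame epoch /
#'   train_loss / val_loss).
#' @export
train_detector <- function(network, split, config = train_config(),
                           head = head_config(), verbose = FALSE) {
  stopifnot(inherits(network, "wce_network"), length(split$train) > 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  grid_size <- infer_shapes(network$spec)[[length(network$layers)]][1]
  state <- adam_init(network)
  n <- length(split$train)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, network = network)
  bad_epochs <- 0L
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      take <- idx[start:min(start + config$batch_size - 1L, n)]
      batch <- frames_to_batch(split$train[take], mirror = TRUE)
      fw <- net_forward_batch(network, batch$x, training = TRUE,
                              keep_cache = TRUE)
      network <- fw$network # running BN stats advanced
      targets <- lapply(batch$boxes, assign_targets, config = head,
                        grid_size = grid_size)
      ll <- detection_loss(fw$out, targets, config$loss_weights, head,
                           grid_size)
      if (!is.finite(ll$loss))
        stop("training diverged at epoch ", epoch, " (non-finite loss)")
      grads <- net_backward(network, fw$caches, ll$grad)
      t_step <- t_step + 1L
      upd <- adam_step(network, grads, state, config$step_size, t_step)
      network <- upd$network; state <- upd$state
      ep_loss <- ep_loss + ll$loss; n_batches <- n_batches + 1L
    }
    val_loss <- if (length(split$validation) > 0)
      evaluate_loss(network, split$validation, config, head, grid_size)
    else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_batches,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %s", epoch,
                      ep_loss / n_batches,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    if (!is.na(val_loss)) {
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, network = network)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) break
      }
    }
  }
  net <- if (is.finite(best$loss)) best$network else network
  net$version <- "trained"
  list(network = net, history = history)
}

# Mean detection loss over a frame list with inference-mode batch norm.
evaluate_loss <- function(network, frames, config, head, grid_size) {
  tot <- 0; nb <- 0L
  for (start in seq(1, length(frames), by = config$batch_size)) {
    take <- start:min(start + config$batch_size - 1L, length(frames))
    batch <- frames_to_batch(frames[take], mirror = FALSE)
    out <- net_forward_batch(network, batch$x, training = FALSE)$out
    targets <- lapply(batch$boxes, assign_targets, config = head,
                      grid_size = grid_size)
    tot <- tot + detection_loss(out, targets, config$loss_weights, head,
                                grid_size)$loss *
      length(take)
    nb <- nb + length(take)
  }
  tot / nb
}
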