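#' Balance polyp frames with an equal number of normals
#'
#' @param polyp_images list of polyp `wce_frame`s.
#' @param normal_pool list of normal frames to sample from (must be at least
#'   as large as `polyp_images`).
#' @param seed sampling seed.
#' @return list of length `2 * length(polyp_images)`: all polyp frames plus
#'   an equal-count random sample of normals.
#' @export
balance_dataset <- function(polyp_images, normal_pool, seed = 1L) {
  n <- length(polyp_images)
  if (n == 0) return(list())
  if (length(normal_pool) < n)
    stop("need at least ", n, " normal frames, have ", length(normal_pool))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  c(polyp_images, normal_pool[sample.int(length(normal_pool), n)])
}

# 3x3 affine helpers, coordinates (x = col, y = row), 0-based pixel centers.
aff_id <- function() diag(3)
aff_translate <- function(tx, ty) matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3)
aff_rot_scale_flip <- function(angle, scale, fx, fy) {
  ct <- cos(angle) * scale; st <- sin(angle) * scale
  matrix(c(ct * fx, st * fx, 0, -st * fy, ct * fy, 0, 0, 0, 1), 3)
}

# Sample one augmentation transform. Returns the forward 3x3 matrix
# (input -> output pixel coords) plus a descriptor.
sample_transform <- function(S, allow_crop = TRUE, flips_only = FALSE) {
  if (flips_only) {
    fx <- sample(c(-1, 1), 1); fy <- sample(c(-1, 1), 1)
    c0 <- (S - 1) / 2
    A <- aff_translate(c0, c0) %*% aff_rot_scale_flip(0, 1, fx, fy) %*%
      aff_translate(-c0, -c0)
    return(A)
  }
  angle <- runif(1, -pi, pi)
  scale <- runif(1, 0.8, 1.2)
  tx <- runif(1, -0.1, 0.1) * S
  ty <- runif(1, -0.1, 0.1) * S
  fx <- sample(c(-1, 1), 1); fy <- sample(c(-1, 1), 1)
  c0 <- (S - 1) / 2
  A <- aff_translate(c0 + tx, c0 + ty) %*%
    aff_rot_scale_flip(angle, scale, fx, fy) %*% aff_translate(-c0, -c0)
  if (allow_crop && runif(1) < 0.5) {
    cs <- S * sqrt(runif(1, 0.8, 1)) # crop keeps >= 80% of the area
    ox <- runif(1, 0, S - cs); oy <- runif(1, 0, S - cs)
    k <- (S - 1) / (cs - 1)
    A <- aff_translate(0, 0) %*%
      matrix(c(k, 0, 0, 0, k, 0, -ox * k, -oy * k, 1), 3) %*% A
  }
  A
}

transform_boxes <- function(boxes, A, S) {
  if (nrow(boxes) == 0) return(boxes)
  out <- boxes[0, ]
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    corners <- rbind(c(b$x, b$y), c(b$x + b$w, b$y), c(b$x, b$y + b$h),
                     c(b$x + b$w, b$y + b$h))
    tc <- t(A %*% t(cbind(corners, 1)))
    x1 <- min(tc[, 1]); x2 <- max(tc[, 1])
    y1 <- min(tc[, 2]); y2 <- max(tc[, 2])
    full <- (x2 - x1) * (y2 - y1)
    cx1 <- max(x1, 0); cy1 <- max(y1, 0)
    cx2 <- min(x2, S); cy2 <- min(y2, S)
    # minimum surviving size: 2 px, but never more than the source box had
    if (cx2 - cx1 < min(2, b$w) || cy2 - cy1 < min(2, b$h)) next
    if ((cx2 - cx1) * (cy2 - cy1) < 0.3 * full) next # mostly cropped out
    out <- rbind(out, bounding_boxes(cx1, cy1, cx2 - cx1, cy2 - cy1,
                                     score = b$score))
  }
  out
}

warp_frame <- function(frame, A, fill = 0.05) {
  S <- dim(frame$pixels)[1]
  inv <- solve(A)
  px <- .cpp_warp_affine(frame$pixels, S, S, 3L,
                         c(inv[1, 1], inv[1, 2], inv[1, 3],
                           inv[2, 1], inv[2, 2], inv[2, 3]), S, S, fill)
  px <- pmin(pmax(px, 0), 1)
  boxes <- transform_boxes(frame$boxes, A, S)
  annotated_image(px, boxes, frame$patient_id, frame$modality,
                  frame$cleanliness)
}

#' Augment a dataset by a fixed factor
#'
#' Each source frame contributes `factor` variants: the original plus
#' `factor - 1` random compositions of rotation (±180°), scaling (0.8–1.2),
#' translation (±10%), horizontal/vertical flips and cropping (crop keeps at
#' least 80% of the area). Ground-truth boxes are transformed with the
#' pixels. A transform that would crop out every polyp of a polyp frame is
#' rejected and resampled (bounded retries, then a flip-only fallback), so
#' augmentation never turns a polyp frame into a normal one. Patient ids,
#' modality and cleanliness are preserved.
#'
#' @param dataset list of `wce_frame`.
#' @param factor variants per source frame (10 reproduces the tenfold
#'   protocol: 1,528 balanced frames -> 15,280).
#' @param seed RNG seed.
#' @param max_retries transform resampling attempts per variant.
#' @return list of `length(dataset) * factor` frames, source-major order.
#' @export
augment <- function(dataset, factor = 10L, seed = 1L, max_retries = 8L) {
  stopifnot(factor >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- vector("list", length(dataset) * factor)
  k <- 0L
  for (frame in dataset) {
    S <- dim(frame$pixels)[1]
    had_polyp <- nrow(frame$boxes) > 0
    for (v in seq_len(factor)) {
      k <- k + 1L
      if (v == 1L) { # keep the original in the database
        out[[k]] <- frame
        next
      }
      aug <- NULL
      for (try in seq_len(max_retries)) {
        cand <- warp_frame(frame, sample_transform(S))
        if (!had_polyp || nrow(cand$boxes) > 0) {
          aug <- cand
          break
        }
      }
      if (is.null(aug)) # fall back to a transform that cannot lose boxes
        aug <- warp_frame(frame, sample_transform(S, flips_only = TRUE))
      out[[k]] <- aug
    }
  }
  out
}

#' Patient-wise 80/10/10 split with balanced validation and test sets
#'
#' Patients — never individual frames — are assigned to the three parts, so
#' no patient leaks across them. Patients are shuffled and assigned
#' greedily until each part's image-count target is reached; validation and
#' test are then class-rebalanced by down-sampling their majority class.
#'
#' @param dataset list of `wce_frame` with patient ids.
#' @param fractions target image fractions, default c(0.8, 0.1, 0.1).
#' @param seed shuffle seed; a fixed seed gives an identical split.
#' @return object of class `wce_split`: list(train, validation, test,
#'   fractions).
#' @export
split_by_patient <- function(dataset, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  pids <- vapply(dataset, `[[`, character(1), "patient_id")
  patients <- unique(pids)
  if (length(patients) < 3)
    stop("patient-wise split needs at least 3 distinct patients, have ",
         length(patients))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  shuffled <- sample(patients)
  counts <- table(pids)[shuffled]
  cum <- cumsum(as.numeric(counts)) / length(dataset)
  # first patient whose cumulative count passes each boundary closes the part
  i1 <- which(cum >= fractions[1])[1]
  i2 <- which(cum >= fractions[1] + fractions[2])[1]
  if (is.na(i2) || i2 >= length(shuffled)) i2 <- length(shuffled) - 1L
  if (is.na(i1) || i1 >= i2) i1 <- i2 - 1L
  if (i1 < 1L) i1 <- 1L
  parts <- list(train = shuffled[seq_len(i1)],
                validation = shuffled[seq(i1 + 1L, i2)],
                test = shuffled[seq(i2 + 1L, length(shuffled))])
  sets <- lapply(parts, function(ps) dataset[pids %in% ps])
  sets$validation <- rebalance_classes(sets$validation)
  sets$test <- rebalance_classes(sets$test)
  structure(list(train = sets$train, validation = sets$validation,
                 test = sets$test, fractions = fractions,
                 patients = parts),
            class = "wce_split")
}

rebalance_classes <- function(frames) {
  lab <- vapply(frames, `[[`, character(1), "label")
  np <- sum(lab == "polyp"); nn <- sum(lab == "normal")
  if (np == 0 || nn == 0)
    stop("cannot class-balance a part containing only ",
         if (np == 0) "normal" else "polyp", " frames")
  keep_n <- min(np, nn)
  idx_p <- which(lab == "polyp")[seq_len(keep_n)]
  idx_n <- which(lab == "normal")[seq_len(keep_n)]
  frames[sort(c(idx_p, idx_n))]
}

#' @export
print.wce_split <- function(x, ...) {
  for (p in c("train", "validation", "test")) {
    lab <- vapply(x[[p]], `[[`, character(1), "label")
    cat(sprintf("  %-10s %4d frames (%d polyp / %d normal), %d patients\n",
                p, length(lab), sum(lab == "polyp"), sum(lab == "normal"),
                length(x$patients[[p]])))
  }
  invisible(x)
}
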