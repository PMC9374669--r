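#' Annotated frame container
#'
#' @param pixels numeric array (S, S, 3) in \[0, 1\].
#' @param boxes ground-truth [bounding_boxes()] (score 1), empty for a
#'   normal frame.
#' @param patient_id character patient identifier.
#' @param modality `"WLI"` or `"NBI"`.
#' @param cleanliness ordinal colon-cleanliness grade, 0 = clean.
#' @return list of class `wce_frame`; `label` is `"polyp"` iff any box.
#' @export
annotated_image <- function(pixels, boxes = bounding_boxes(),
                            patient_id = NA_character_, modality = "WLI",
                            cleanliness = 0L) {
  d <- dim(pixels)
  stopifnot(length(d) == 3, d[3] == 3)
  modality <- match.arg(modality, c("WLI", "NBI"))
  if (nrow(boxes) > 0 &&
      (any(boxes$x < 0) || any(boxes$y < 0) ||
       any(boxes$x + boxes$w > d[2]) || any(boxes$y + boxes$h > d[1])))
    stop("ground-truth boxes must lie within the frame")
  structure(list(pixels = pixels, boxes = boxes,
                 patient_id = as.character(patient_id), modality = modality,
                 cleanliness = as.integer(cleanliness),
                 label = if (nrow(boxes) > 0) "polyp" else "normal"),
            class = "wce_frame")
}

#' Synthetic dataset configuration
#'
#' The generator emulates the statistical shape of a capsule-endoscopy polyp
#' database: patients with their own mucosa hue / vasculature, frames with
#' or without polyps (elliptical protrusions with brightness gradient and
#' specular highlight), graded cleanliness (occluding debris), and WLI
#' illumination with an NBI rendering available via [render_nbi()]. It makes
#' no claim of photorealism.
#'
#' @param n_patients number of synthetic patients.
#' @param frames_per_patient frames per patient.
#' @param polyp_prevalence probability a frame carries at least one polyp
#'   (0.5 mirrors the class-balanced training database).
#' @param polyp_size_range (min, max) box side in pixels at 240-px scale,
#'   drawn log-uniformly; scaled proportionally for other frame sizes.
#' @param polyps_per_frame maximum polyps per positive frame.
#' @param cleanliness_levels number of ordinal grades (uniformly assigned).
#' @param seed master seed; every frame derives its own substream, so the
#'   dataset is reproducible byte-for-byte.
#' @param frame_size frame side in pixels (240 = capsule resolution; smaller
#'   values render the same world scaled down).
#' @return list of class `wce_synth_config`.
#' @export
synth_config <- function(n_patients = 20L, frames_per_patient = 40L,
                         polyp_prevalence = 0.5,
                         polyp_size_range = c(24, 96),
                         polyps_per_frame = 1L, cleanliness_levels = 4L,
                         seed = 1L, frame_size = 240L) {
  stopifnot(n_patients >= 1, frames_per_patient >= 1,
            polyp_prevalence >= 0, polyp_prevalence <= 1,
            length(polyp_size_range) == 2,
            polyp_size_range[1] > 0, polyp_size_range[2] < 240,
            polyp_size_range[1] <= polyp_size_range[2],
            polyps_per_frame >= 1, cleanliness_levels >= 1, frame_size >= 16)
  structure(list(n_patients = as.integer(n_patients),
                 frames_per_patient = as.integer(frames_per_patient),
                 polyp_prevalence = polyp_prevalence,
                 polyp_size_range = polyp_size_range,
                 polyps_per_frame = as.integer(polyps_per_frame),
                 cleanliness_levels = as.integer(cleanliness_levels),
                 seed = as.integer(seed), frame_size = as.integer(frame_size)),
            class = "wce_synth_config")
}

# Per-patient appearance parameters (drawn from the patient's own substream):
# mucosa base color, texture amplitude, vessel density, illumination center.
patient_style <- function() {
  list(base = c(r = runif(1, 0.52, 0.72), g = runif(1, 0.28, 0.44),
                b = runif(1, 0.26, 0.40)),
       texture_amp = runif(1, 0.04, 0.10),
       vessel_rate = runif(1, 5, 14),
       light_center = runif(2, 0.3, 0.7))
}

#' Generate one synthetic endoscopy frame
#'
#' Renders a frame from the current RNG stream: low-frequency mucosa
#' texture with an illumination falloff, curvilinear vessel strokes, optional
#' elliptical polyps (each with a tight ground-truth box), and debris blobs
#' scaling with the cleanliness grade. Identical RNG state gives a
#' pixel-identical frame.
#'
#' @param has_polyp plant 1..`max_polyps` polyps?
#' @param cleanliness ordinal grade, 0 = perfectly clean.
#' @param modality `"WLI"` (native) — NBI frames come from [render_nbi()].
#' @param size frame side in pixels.
#' @param style per-patient style list (internal); fresh random if NULL.
#' @param size_range polyp box-side range at 240-px scale.
#' @param max_polyps maximum polyp count for a positive frame.
#' @param patient_id recorded in the frame.
#' @return a `wce_frame`; attribute `vessel_mask` marks vessel pixels
#'   (a generator diagnostic used by the NBI contrast checks).
#' @export
generate_frame <- function(has_polyp = FALSE, cleanliness = 0L,
                           modality = "WLI", size = 240L, style = NULL,
                           size_range = c(24, 96), max_polyps = 1L,
                           patient_id = NA_character_) {
  stopifnot(identical(modality, "WLI"))
  if (is.null(style)) style <- patient_style()
  S <- as.integer(size)
  X <- matrix(rep(seq_len(S), each = S), S) # column index
  Y <- matrix(rep(seq_len(S), times = S), S) # row index
  # mucosa base + low-frequency texture (bilinear-upsampled coarse noise)
  coarse <- array(runif(6 * 6, -1, 1), dim = c(6, 6, 1))
  sc <- 5 / (S - 1)
  tex <- .cpp_warp_affine(coarse, 6L, 6L, 1L, c(sc, 0, 0, 0, sc, 0), S, S, 0)
  tex <- matrix(tex, S) * style$texture_amp
  lc <- style$light_center * S
  r2 <- ((X - lc[1])^2 + (Y - lc[2])^2) / (2 * (0.75 * S)^2)
  illum <- 1 - pmin(r2, 1) * 0.55
  img <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- (style$base[ch] + tex) * illum
  # vessels: quadratic Bezier strokes, darker and slightly blue-shifted
  n_ves <- stats::rpois(1, style$vessel_rate)
  vessel <- matrix(FALSE, S, S)
  for (v in seq_len(n_ves)) {
    p <- matrix(runif(6, 1, S), 2)
    t <- seq(0, 1, length.out = 4L * S)
    bez <- outer(c(1, 0), (1 - t)^2) * p[, 1] +
      2 * outer(c(1, 0), t * (1 - t)) * p[, 2] +
      outer(c(1, 0), t^2) * p[, 3]
    px <- round(bez[1, ]); py <- round(bez[2, ])
    th <- sample(0:1, 1)
    for (dx in -th:th) for (dy in -th:th) {
      xx <- px + dx; yy <- py + dy
      ok <- xx >= 1 & xx <= S & yy >= 1 & yy <= S
      vessel[cbind(yy[ok], xx[ok])] <- TRUE
    }
  }
  vfac <- c(0.70, 0.55, 0.60)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[vessel] <- pl[vessel] * vfac[ch]
    img[, , ch] <- pl
  }
  # polyps: shaded elliptical protrusions with a specular highlight
  boxes <- bounding_boxes()
  polyp_mask <- matrix(FALSE, S, S)
  if (has_polyp) {
    n_pol <- sample.int(max_polyps, 1)
    for (pp in seq_len(n_pol)) {
      sr <- size_range * S / 240 # stated at capsule scale
      side <- exp(runif(1, log(sr[1]), log(sr[2])))
      a <- side / 2
      b <- a * (1 - runif(1, 0, 0.45))
      theta <- runif(1, 0, pi)
      m <- max(a, b) + 2
      cx <- runif(1, m + 1, S - m); cy <- runif(1, m + 1, S - m)
      ct <- cos(theta); st <- sin(theta)
      U <- ((X - cx) * ct + (Y - cy) * st) / a
      V <- (-(X - cx) * st + (Y - cy) * ct) / b
      q <- U^2 + V^2
      mask <- q <= 1
      if (!any(mask)) next
      elev <- sqrt(pmax(1 - q, 0))
      ldir <- runif(1, 0, 2 * pi)
      shade <- 0.16 * elev + 0.10 * elev * (U * cos(ldir) + V * sin(ldir))
      hx <- cx + 0.3 * a * cos(ldir); hy <- cy + 0.3 * b * sin(ldir)
      spec <- 0.35 * exp(-(((X - hx)^2 + (Y - hy)^2) / (0.015 * side^2 + 2)))
      tint <- c(0.10, 0.02, 0.03) # a shade pinker than the mucosa
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[mask] <- pl[mask] + shade[mask] + tint[ch]
        pl <- pl + spec * (q <= 1.05)
        img[, , ch] <- pl
      }
      polyp_mask <- polyp_mask | mask
      cols <- range(X[mask]); rows <- range(Y[mask])
      boxes <- rbind(boxes, bounding_boxes(
        x = cols[1] - 1, y = rows[1] - 1,
        w = cols[2] - cols[1] + 1, h = rows[2] - rows[1] + 1))
    }
  }
  # debris: yellow-brown occluding blobs, more and larger with worse grade
  if (cleanliness > 0) {
    n_blobs <- stats::rpois(1, 2 * cleanliness)
    for (bl in seq_len(n_blobs)) {
      br <- runif(1, 0.015, 0.035 + 0.01 * cleanliness) * S
      bx <- runif(1, 1, S); by <- runif(1, 1, S)
      dmask <- ((X - bx)^2 + (Y - by)^2) <= br^2
      alpha <- runif(1, 0.55, 0.85)
      dcol <- c(0.55, 0.45, 0.18) + runif(3, -0.05, 0.05)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[dmask] <- (1 - alpha) * pl[dmask] + alpha * dcol[ch]
        img[, , ch] <- pl
      }
    }
  }
  img <- pmin(pmax(img, 0), 1)
  fr <- annotated_image(img, boxes, patient_id = patient_id,
                        modality = "WLI", cleanliness = cleanliness)
  attr(fr, "vessel_mask") <- vessel
  attr(fr, "polyp_mask") <- polyp_mask
  fr
}

#' Re-render a WLI frame under narrow-band illumination
#'
#' Deterministic color transform emulating blue/green narrow-band LEDs:
#' the red channel is strongly attenuated and the green/blue channels are
#' contrast-stretched about fixed pivots, which raises the vessel-to-mucosa
#' contrast (vessels are darker in green). Geometry, boxes and grades are
#' unchanged; modality becomes `"NBI"`.
#'
#' @param frame a WLI `wce_frame`.
#' @return the NBI `wce_frame`.
#' @export
render_nbi <- function(frame) {
  stopifnot(inherits(frame, "wce_frame"))
  if (frame$modality != "WLI")
    stop("render_nbi expects a WLI frame, got ", frame$modality)
  img <- frame$pixels
  out <- img
  out[, , 1] <- 0.30 * img[, , 1]
  out[, , 2] <- pmin(pmax(0.45 + 1.7 * (img[, , 2] - 0.40), 0), 1)
  out[, , 3] <- pmin(pmax(0.45 + 1.5 * (img[, , 3] - 0.35), 0), 1)
  nf <- annotated_image(out, frame$boxes, frame$patient_id, "NBI",
                        frame$cleanliness)
  attr(nf, "vessel_mask") <- attr(frame, "vessel_mask")
  nf
}

#' Generate a full synthetic dataset
#'
#' Every patient gets a persistent style (hue, vasculature, illumination) so
#' between-patient appearance variation exceeds within-patient variation —
#' patient-wise splitting is therefore meaningful and leakage detectable.
#' Frame substreams make the output independent of evaluation order.
#'
#' @param config a [synth_config()].
#' @return list of `wce_frame` with attribute `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "wce_synth_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  pat_seeds <- sample.int(2^31 - 2, config$n_patients)
  frames <- vector("list", config$n_patients * config$frames_per_patient)
  k <- 0L
  for (p in seq_len(config$n_patients)) {
    set.seed(pat_seeds[p])
    style <- patient_style()
    frame_seeds <- sample.int(2^31 - 2, config$frames_per_patient)
    pid <- sprintf("P%03d", p)
    for (f in seq_len(config$frames_per_patient)) {
      set.seed(frame_seeds[f])
      has_polyp <- runif(1) < config$polyp_prevalence
      grade <- sample.int(config$cleanliness_levels, 1) - 1L
      k <- k + 1L
      frames[[k]] <- generate_frame(
        has_polyp = has_polyp, cleanliness = grade, size = config$frame_size,
        style = style, size_range = config$polyp_size_range,
        max_polyps = config$polyps_per_frame, patient_id = pid)
    }
  }
  attr(frames, "config") <- config
  frames
}

#' Resize a frame (and its boxes) to a new side length
#'
#' Bilinear resampling; used to run the detector at reduced resolution.
#'
#' @param frame a `wce_frame`.
#' @param size new side in pixels.
#' @return the resized `wce_frame`.
#' @export
resize_frame <- function(frame, size) {
  d <- dim(frame$pixels)
  if (d[1] == size) return(frame)
  sc <- d[1] / size
  inv <- c(sc, 0, (sc - 1) / 2, 0, sc, (sc - 1) / 2)
  px <- .cpp_warp_affine(frame$pixels, d[1], d[2], 3L, inv, as.integer(size),
                         as.integer(size), 0)
  px <- pmin(pmax(px, 0), 1)
  b <- frame$boxes
  if (nrow(b) > 0) {
    f <- size / d[1]
    b$x <- b$x * f; b$y <- b$y * f; b$w <- b$w * f; b$h <- b$h * f
    b$w <- pmin(b$w, size - b$x); b$h <- pmin(b$h, size - b$y)
  }
  annotated_image(px, b, frame$patient_id, frame$modality, frame$cleanliness)
}
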