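# Image and annotation I/O. PNG via the png package; BMP (the capsule
# camera's native output dialect) as minimal 24-bit uncompressed BI_RGB.

#' Write / read an image
#'
#' Format chosen by extension: `.png` (default interchange format) or
#' `.bmp` (24-bit uncompressed, the capsule's on-device format).
#'
#' @param img numeric array (H, W, 3) in \[0, 1\].
#' @param path output path ending in .png or .bmp.
#' @return `read_image` returns the (H, W, 3) array.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         bmp = write_bmp(img, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = {
           img <- png::readPNG(path)
           if (length(dim(img)) == 3 && dim(img)[3] == 4)
             img <- img[, , 1:3, drop = FALSE]
           img
         },
         bmp = read_bmp(path),
         stop("unsupported image format: .", ext))
}

write_bmp <- function(img, path) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  rowbytes <- W * 3L
  pad <- (4L - rowbytes %% 4L) %% 4L
  datasize <- (rowbytes + pad) * H
  q <- function(v) as.raw(pmax(pmin(round(v * 255), 255), 0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(54 + datasize), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(54L, con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little") # BITMAPINFOHEADER
  writeBin(as.integer(W), con, size = 4, endian = "little")
  writeBin(as.integer(H), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(datasize), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4, endian = "little")
  # pixel rows bottom-up, BGR
  rows <- raw((rowbytes + pad) * H)
  idx <- 0L
  for (r in H:1) {
    bgr <- as.vector(rbind(q(img[r, , 3]), q(img[r, , 2]), q(img[r, , 1])))
    rows[idx + seq_len(rowbytes)] <- bgr
    idx <- idx + rowbytes + pad
  }
  writeBin(rows, con)
  invisible(path)
}

read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  stopifnot(rawToChar(raw[1:2]) == "BM")
  le32 <- function(off) sum(as.integer(raw[off + 0:3]) * 256^(0:3))
  le16 <- function(off) sum(as.integer(raw[off + 0:1]) * 256^(0:1))
  offset <- le32(11)
  W <- le32(19); H <- le32(23)
  stopifnot(le16(29) == 24, le32(31) == 0) # 24-bit uncompressed only
  rowbytes <- W * 3L
  pad <- (4L - rowbytes %% 4L) %% 4L
  img <- array(0, dim = c(H, W, 3))
  idx <- offset
  for (r in H:1) {
    v <- as.integer(raw[idx + seq_len(rowbytes)]) / 255
    m <- matrix(v, nrow = 3)
    img[r, , 1] <- m[3, ]; img[r, , 2] <- m[2, ]; img[r, , 3] <- m[1, ]
    idx <- idx + rowbytes + pad
  }
  img
}

#' Write / read dataset annotations
#'
#' One JSON file per dataset (schema-versioned): per image its path,
#' patient id, modality, cleanliness grade and ground-truth boxes in the
#' repo-wide convention (0-based upper-left origin, x/y/w/h pixels).
#'
#' @param frames list of `wce_frame`.
#' @param image_paths character vector of stored image paths (relative to
#'   the annotation file).
#' @param path annotation JSON path.
#' @return `read_annotations` returns the parsed records (list with
#'   `images`); `write_annotations` the path, invisibly.
#' @export
write_annotations <- function(frames, image_paths, path) {
  stopifnot(length(frames) == length(image_paths))
  recs <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    list(image_path = image_paths[i], patient_id = f$patient_id,
         modality = f$modality, cleanliness = f$cleanliness,
         label = f$label,
         boxes = if (nrow(f$boxes) > 0)
           lapply(seq_len(nrow(f$boxes)), function(j)
             list(x = f$boxes$x[j], y = f$boxes$y[j],
                  w = f$boxes$w[j], h = f$boxes$h[j]))
         else list())
  })
  jsonlite::write_json(list(schema = "wcepolyp-annotations-1", images = recs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "wcepolyp-annotations-1"))
    stop("unrecognized annotation schema in ", path)
  obj
}

#' Load a dataset written by [cli_generate()]
#'
#' @param dir dataset directory containing images and `annotations.json`.
#' @return list of `wce_frame`.
#' @export
read_dataset <- function(dir) {
  ann <- read_annotations(file.path(dir, "annotations.json"))
  lapply(ann$images, function(rec) {
    img_path <- file.path(dir, rec$image_path)
    if (!file.exists(img_path)) stop("missing image: ", img_path)
    px <- read_image(img_path)
    boxes <- if (length(rec$boxes) > 0)
      do.call(rbind, lapply(rec$boxes, function(b)
        bounding_boxes(b$x, b$y, b$w, b$h)))
    else bounding_boxes()
    annotated_image(px, boxes, rec$patient_id, rec$modality, rec$cleanliness)
  })
}

draw_boxes <- function(img, boxes, color = c(0, 1, 0), width = 2L) {
  d <- dim(img)
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    x1 <- max(round(b$x) + 1L, 1L); y1 <- max(round(b$y) + 1L, 1L)
    x2 <- min(round(b$x + b$w), d[2]); y2 <- min(round(b$y + b$h), d[1])
    for (t in seq_len(width) - 1L) {
      rr <- c(min(y1 + t, d[1]), max(y2 - t, 1L))
      cc <- c(min(x1 + t, d[2]), max(x2 - t, 1L))
      for (ch in 1:3) {
        img[rr, x1:x2, ch] <- color[ch]
        img[y1:y2, cc, ch] <- color[ch]
      }
    }
  }
  img
}
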