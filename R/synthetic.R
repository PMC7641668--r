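# MNIST-style IDX container I/O and a seeded synthetic oriented-stroke digit
# generator. The generator renders anti-aliased line segments whose dominant
# orientations are distinct per class, so the classes are separable by the
# orientation content the V2 layer extracts -- the same signature that makes
# a handwritten "1" light up the vertical pool.

#' Labeled image set
#'
#' @param images integer array `n x H x W`, intensities 0--255.
#' @param labels integer vector of length `n`, values 0--9.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels) {
  if (length(dim(images)) != 3) stop("images must be an n x H x W array")
  n <- dim(images)[1]
  if (length(labels) != n) stop("images and labels have different lengths")
  if (n > 0 && (min(images) < 0 || max(images) > 255)) stop("intensities must be 0-255")
  if (n > 0 && (min(labels) < 0 || max(labels) > 9)) stop("labels must be 0-9")
  structure(list(images = images, labels = as.integer(labels)),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("labeled_image_set: %d images of %d x %d, classes {%s}\n",
              d[1], d[2], d[3], paste(sort(unique(x$labels)), collapse = ",")))
  invisible(x)
}

#' Extract one image as a matrix
#'
#' @param set a [labeled_image_set()].
#' @param i sample index.
#' @return `H x W` numeric matrix.
#' @export
get_image <- function(set, i) {
  matrix(set$images[i, , ], dim(set$images)[2], dim(set$images)[3])
}

.read_be_int <- function(con, n = 1) readBin(con, "integer", n = n, size = 4, endian = "big")

#' Read MNIST-style IDX files
#'
#' Parses the big-endian IDX containers of the MNIST distribution: magic
#' 2051 for the `n x rows x cols` unsigned-byte image tensor, magic 2049 for
#' the label vector. Malformed files are rejected with a diagnostic naming
#' the byte offset of the violation.
#'
#' @param images_path path to the image file.
#' @param labels_path path to the label file.
#' @return A [labeled_image_set()] (bit-exact pixel values).
#' @export
read_idx <- function(images_path, labels_path) {
  con <- file(images_path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- .read_be_int(con)
  if (length(magic) != 1 || magic != 2051)
    stop(sprintf("%s: bad image magic %s at offset 0 (expected 2051)",
                 images_path, format(magic)))
  dims <- .read_be_int(con, 3)
  if (length(dims) != 3 || any(dims < 0))
    stop(sprintf("%s: truncated header at offset 4", images_path))
  need <- prod(dims)
  px <- readBin(con, "raw", n = need)
  if (length(px) != need)
    stop(sprintf("%s: truncated pixel data at offset %d (expected %d bytes, got %d)",
                 images_path, 16 + length(px), need, length(px)))
  con2 <- file(labels_path, "rb")
  on.exit(close(con2), add = TRUE)
  magic2 <- .read_be_int(con2)
  if (length(magic2) != 1 || magic2 != 2049)
    stop(sprintf("%s: bad label magic %s at offset 0 (expected 2049)",
                 labels_path, format(magic2)))
  nlab <- .read_be_int(con2)
  if (length(nlab) != 1)
    stop(sprintf("%s: truncated header at offset 4", labels_path))
  if (nlab != dims[1])
    stop(sprintf("image/label count mismatch: %d images but %d labels", dims[1], nlab))
  lab <- readBin(con2, "raw", n = nlab)
  if (length(lab) != nlab)
    stop(sprintf("%s: truncated label data at offset %d", labels_path, 8 + length(lab)))
  # IDX stores images row-major: pixel order is (row within image, col).
  imgs <- array(as.integer(px), c(dims[3], dims[2], dims[1])) # cols, rows, n
  imgs <- aperm(imgs, c(3, 2, 1))                             # n, rows, cols
  labeled_image_set(imgs, as.integer(lab))
}

#' Write MNIST-style IDX files
#'
#' Emits spec-compliant big-endian IDX containers readable by [read_idx()]
#' and by third-party MNIST loaders.
#'
#' @param set a [labeled_image_set()].
#' @param images_path,labels_path output paths.
#' @return The two paths, invisibly.
#' @export
write_idx <- function(set, images_path, labels_path) {
  d <- dim(set$images)
  con <- file(images_path, "wb")
  writeBin(c(2051L, d[1], d[2], d[3]), con, size = 4, endian = "big")
  if (d[1] > 0) {
    px <- as.vector(aperm(set$images, c(3, 2, 1))) # row-major within image
    writeBin(as.raw(px), con)
  }
  close(con)
  con <- file(labels_path, "wb")
  writeBin(c(2049L, d[1]), con, size = 4, endian = "big")
  if (d[1] > 0) writeBin(as.raw(set$labels), con)
  close(con)
  invisible(c(images_path, labels_path))
}

#' Render anti-aliased oriented strokes
#'
#' Draws line segments onto a zero canvas. Each stroke is a list with
#' `angle` (degrees, 0 = horizontal, measured with the y axis pointing up),
#' `length` and `width` (pixels), and optional `center` (`c(col, row)`
#' offsets from the image center) and `intensity` (0--255, default 255).
#' Coverage falls off linearly over one pixel at the stroke edge (sub-pixel
#' anti-aliasing); overlapping strokes combine by maximum.
#'
#' @param strokes list of stroke descriptions.
#' @param grid canvas size `(rows, cols)`.
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
render_strokes <- function(strokes, grid = c(28, 28)) {
  H <- grid[1]; W <- grid[2]
  canvas <- matrix(0, H, W)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- matrix(rep(seq_len(W), each = H), H)   # column coordinate
  ys <- matrix(rep(H:1, times = W), H)         # row -> y up
  for (s in strokes) {
    if (is.null(s$length) || s$length <= 0) stop("degenerate stroke: non-positive length")
    w <- if (is.null(s$width)) 2 else s$width
    if (w <= 0) stop("degenerate stroke: non-positive width")
    inten <- if (is.null(s$intensity)) 255 else s$intensity
    ctr <- if (is.null(s$center)) c(0, 0) else s$center
    th <- s$angle * pi / 180
    x0 <- cx + ctr[1] - s$length / 2 * cos(th); y0 <- cy + ctr[2] - s$length / 2 * sin(th)
    x1 <- cx + ctr[1] + s$length / 2 * cos(th); y1 <- cy + ctr[2] + s$length / 2 * sin(th)
    dx <- x1 - x0; dy <- y1 - y0
    L2 <- dx * dx + dy * dy
    t <- pmin(pmax(((xs - x0) * dx + (ys - y0) * dy) / L2, 0), 1)
    dist <- sqrt((xs - (x0 + t * dx))^2 + (ys - (y0 + t * dy))^2)
    cov <- pmin(pmax(w / 2 + 0.5 - dist, 0), 1)
    canvas <- pmax(canvas, inten * cov)
  }
  canvas
}

#' Synthetic class specification
#'
#' Defines the oriented-stroke templates of each class together with the
#' jitter and noise of the renderer. The default four classes carry one
#' dominant stroke each at 0, 45, 90 and 135 degrees (class labels 0--3), so
#' each class's orientation signature lands in a distinct V2 pool -- class 2
#' is the "1"-like vertical-stroke class.
#'
#' @param classes named list: one entry per class, each a list of stroke
#'   templates as in [render_strokes()].
#' @param pos_jitter positional jitter of each stroke center, s.d. in pixels.
#' @param angle_jitter angular jitter, s.d. in degrees.
#' @param noise background noise level: additive uniform on `[0, noise]`,
#'   clipped to 0--255.
#' @return An object of class `synthetic_class_spec`.
#' @export
synthetic_class_spec <- function(classes = NULL, pos_jitter = 1.5,
                                 angle_jitter = 5, noise = 20) {
  if (is.null(classes)) {
    classes <- lapply(c(0, 45, 90, 135), function(a)
      list(list(angle = a, length = 18, width = 2.5)))
    names(classes) <- c("horizontal", "right_diagonal", "vertical", "left_diagonal")
  }
  for (cl in classes) for (s in cl)
    if (is.null(s$length) || s$length <= 0) stop("degenerate stroke template")
  structure(list(classes = classes, pos_jitter = pos_jitter,
                 angle_jitter = angle_jitter, noise = noise),
            class = "synthetic_class_spec")
}

#' Generate a synthetic oriented-stroke digit set
#'
#' Renders `n_per_class` jittered, noisy samples of every class template.
#' Deterministic under `seed`. Labels are `0 .. n_classes - 1` in template
#' order.
#'
#' @param n_per_class samples per class.
#' @param spec a [synthetic_class_spec()].
#' @param seed RNG seed.
#' @param grid image size.
#' @return A [labeled_image_set()].
#' @export
generate_synthetic_digits <- function(n_per_class, spec = synthetic_class_spec(),
                                      seed = NULL, grid = c(28, 28)) {
  if (n_per_class < 1) stop("n_per_class must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  ncls <- length(spec$classes)
  n <- n_per_class * ncls
  images <- array(0L, c(n, grid[1], grid[2]))
  labels <- integer(n)
  k <- 0L
  for (ci in seq_len(ncls)) {
    for (r in seq_len(n_per_class)) {
      k <- k + 1L
      strokes <- lapply(spec$classes[[ci]], function(s) {
        s$angle <- s$angle + stats::rnorm(1, 0, spec$angle_jitter)
        ctr <- if (is.null(s$center)) c(0, 0) else s$center
        s$center <- ctr + stats::rnorm(2, 0, spec$pos_jitter)
        s
      })
      img <- render_strokes(strokes, grid = grid)
      if (spec$noise > 0)
        img <- img + stats::runif(length(img), 0, spec$noise)
      images[k, , ] <- as.integer(round(pmin(pmax(img, 0), 255)))
      labels[k] <- ci - 1L
    }
  }
  labeled_image_set(images, labels)
}

#' Stroke templates for ten digit-like classes
#'
#' Seven-segment-style templates of the digits 0--9 (plus a diagonal for the
#' "7"), built from the same oriented strokes as the default class set. The
#' classes share most of their orientation content (horizontal and vertical
#' segments) and differ mainly in the spatial arrangement of the segments,
#' which makes the task markedly harder than the four single-stroke classes
#' and closer to handwritten digits.
#'
#' @return A named list of ten class templates suitable for
#'   [synthetic_class_spec()].
#' @export
synthetic_digit_templates <- function() {
  seg <- function(which) {
    H <- 10; V <- 8; W <- 2.5
    switch(which,
      top = list(angle = 0, length = H, width = W, center = c(0, 8)),
      mid = list(angle = 0, length = H, width = W, center = c(0, 0)),
      bot = list(angle = 0, length = H, width = W, center = c(0, -8)),
      tl = list(angle = 90, length = V, width = W, center = c(-5, 4)),
      tr = list(angle = 90, length = V, width = W, center = c(5, 4)),
      bl = list(angle = 90, length = V, width = W, center = c(-5, -4)),
      br = list(angle = 90, length = V, width = W, center = c(5, -4)),
      diag7 = list(angle = 70, length = 15, width = W, center = c(1, -2)))
  }
  segments <- list(
    `0` = c("top", "bot", "tl", "tr", "bl", "br"),
    `1` = c("tr", "br"),
    `2` = c("top", "tr", "mid", "bl", "bot"),
    `3` = c("top", "tr", "mid", "br", "bot"),
    `4` = c("tl", "mid", "tr", "br"),
    `5` = c("top", "tl", "mid", "br", "bot"),
    `6` = c("top", "tl", "mid", "bl", "br", "bot"),
    `7` = c("top", "diag7"),
    `8` = c("top", "mid", "bot", "tl", "tr", "bl", "br"),
    `9` = c("top", "tl", "tr", "mid", "br", "bot"))
  lapply(segments, function(ss) lapply(ss, seg))
}

#' Export an image as PNG for visual inspection
#'
#' @param image `H x W` matrix, 0--255.
#' @param path output path.
#' @export
write_image_png <- function(image, path) {
  grDevices::png(path, width = ncol(image), height = nrow(image))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(image[nrow(image):1, ]), zlim = c(0, 255),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
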