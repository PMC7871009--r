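#' Label connected foreground components of a binary image
#'
#' Breadth-first labeling with selectable 4- or 8-connectivity.
#'
#' @param image logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8 (default 8, the particle-analysis convention).
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(image, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  nr <- nrow(image); nc <- ncol(image)
  labels <- matrix(0L, nr, nc)
  fg <- which(image)
  if (length(fg) == 0L) return(labels)
  is_fg <- rep(FALSE, nr * nc); is_fg[fg] <- TRUE
  visited <- rep(FALSE, nr * nc)
  lab <- 0L
  for (s in fg) {
    if (visited[s]) next
    lab <- lab + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      labels[cur] <- lab
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      nb <- c(cur[r > 1L] - 1L, cur[r < nr] + 1L,
              cur[cc > 1L] - nr, cur[cc < nc] + nr)
      if (connectivity == 8L) {
        nb <- c(nb,
                cur[r > 1L & cc > 1L] - 1L - nr,
                cur[r > 1L & cc < nc] - 1L + nr,
                cur[r < nr & cc > 1L] + 1L - nr,
                cur[r < nr & cc < nc] + 1L + nr)
      }
      nb <- unique(nb[is_fg[nb] & !visited[nb]])
      visited[nb] <- TRUE
      queue <- nb
    }
  }
  labels
}

#' Measure fragments in a binary mask
#'
#' Replicates particle analysis of impact-assay images: connected
#' components of the foreground are labeled at the stated connectivity and
#' components smaller than the minimum-area threshold are discarded
#' (components with area >= `min_area` are kept; the default 500 px cut
#' removes imaging noise while keeping the smallest real fragments).
#'
#' @param image logical matrix, or numeric matrix with values exactly 0/1.
#' @param min_area minimum kept component area in pixels.
#' @param connectivity 4 or 8.
#' @return object of class `"fragment_measurement"`: `n_fragments`,
#'   `areas_px` (sorted decreasing), `min_area`, `connectivity`.
#' @export
measure_fragments <- function(image, min_area = 500L, connectivity = 8L) {
  if (is.numeric(image)) {
    if (!all(image %in% c(0, 1)))
      stop("image is not binary: threshold it to 0/1 before measuring")
    image <- image == 1
  }
  if (!is.logical(image) || !is.matrix(image))
    stop("image must be a logical (or 0/1 numeric) matrix")
  labels <- label_components(image, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  kept <- sort(sizes[sizes >= min_area], decreasing = TRUE)
  structure(list(n_fragments = length(kept), areas_px = as.integer(kept),
                 min_area = as.integer(min_area),
                 connectivity = as.integer(connectivity)),
            class = "fragment_measurement")
}

#' @export
print.fragment_measurement <- function(x, ...) {
  cat(sprintf(
    "Fragment measurement: %d fragment(s) >= %d px (connectivity %d)\n",
    x$n_fragments, x$min_area, x$connectivity))
  if (x$n_fragments > 0L)
    cat("  areas:", paste(x$areas_px, collapse = ", "), "px\n")
  invisible(x)
}

#' Read a binary fragment mask from PNG or TIFF
#'
#' Any channel dimension is collapsed by the maximum; the result must be
#' strictly binary.
#'
#' @param path path to a PNG or TIFF mask (foreground = white).
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF masks requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported mask format: '", ext, "' (use PNG or TIFF)"))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), max)
  if (!all(arr %in% c(0, 1)))
    stop("mask is not binary: threshold it to 0/1 before measuring")
  arr == 1
}

#' Write a binary mask as PNG
#'
#' @param image logical matrix.
#' @param path output path.
#' @export
write_mask <- function(image, path) {
  png::writePNG(image * 1, path)
  invisible(path)
}

#' Measure a batch of mask images
#'
#' Processes images in filename order; unreadable files are skipped with a
#' warning and listed in the result. Output tables use the standard counts
#' and areas CSV schemas keyed by image name (counts are raw measurement
#' counts: a zero-fragment image is recorded as 0 here; the recode of
#' intact lemmas to count 1 belongs to model-input assembly, not to
#' measurement).
#'
#' @param paths image file paths.
#' @param min_area,connectivity as in [measure_fragments()].
#' @return list with data frames `counts` (image, n_fragments) and `areas`
#'   (image, fragment_area_px), plus `skipped` (character).
#' @export
measure_batch <- function(paths, min_area = 500L, connectivity = 8L) {
  paths <- paths[order(basename(paths))]
  counts <- data.frame(image = character(0), n_fragments = integer(0))
  areas <- data.frame(image = character(0), fragment_area_px = integer(0))
  skipped <- character(0)
  for (p in paths) {
    m <- tryCatch(measure_fragments(read_mask(p), min_area, connectivity),
                  error = function(e) {
                    warning("skipping unreadable mask '", p, "': ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(m)) { skipped <- c(skipped, p); next }
    counts <- rbind(counts, data.frame(image = basename(p),
                                       n_fragments = m$n_fragments))
    if (m$n_fragments > 0L)
      areas <- rbind(areas, data.frame(image = basename(p),
                                       fragment_area_px = m$areas_px))
  }
  list(counts = counts, areas = areas, skipped = skipped)
}
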