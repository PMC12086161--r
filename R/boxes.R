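#' Construct a tibble of scored bounding boxes
#'
#' The unit of currency of the package: an axis-aligned box with a detector
#' confidence score and a stable integer id. Coordinates are real-valued
#' pixel coordinates under the half-open convention
#' `[x_min, x_max) x [y_min, y_max)` (see [rgb_image()]).
#'
#' @param x_min,y_min,x_max,y_max numeric vectors of box corners;
#'   `x_max > x_min` and `y_max > y_min` elementwise.
#' @param score detector confidence in `[0, 1]`.
#' @param id stable integer identifiers; defaults to `seq_along(x_min)`.
#' @return a tibble with columns `id`, `x_min`, `y_min`, `x_max`, `y_max`,
#'   `score`.
#' @examples
#' boxes(c(0, 5), c(0, 0), c(10, 15), c(10, 10), score = c(0.9, 0.6))
#' @export
boxes <- function(x_min, y_min, x_max, y_max, score = 1, id = seq_along(x_min)) {
  b <- tibble::tibble(
    id = as.integer(id),
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    score = rep_len(as.numeric(score), length(x_min))
  )
  validate_boxes(b)
}

validate_boxes <- function(b) {
  stopifnot(is.data.frame(b),
            all(c("id", "x_min", "y_min", "x_max", "y_max", "score") %in% names(b)))
  if (nrow(b) > 0) {
    if (any(b$x_max <= b$x_min) || any(b$y_max <= b$y_min)) {
      stop("degenerate box: need x_max > x_min and y_max > y_min", call. = FALSE)
    }
    if (any(b$score < 0 | b$score > 1)) {
      stop("box scores must lie in [0, 1]", call. = FALSE)
    }
    if (anyDuplicated(b$id)) stop("box ids must be unique", call. = FALSE)
  }
  tibble::as_tibble(b)
}

empty_boxes <- function() {
  tibble::tibble(id = integer(), x_min = numeric(), y_min = numeric(),
                 x_max = numeric(), y_max = numeric(), score = numeric())
}

#' Box areas and diagonals
#'
#' Areas are computed in continuous coordinates, consistent with the
#' half-open pixel semantics (a box `[0,10) x [0,10)` has area 100 and
#' covers exactly 100 integer pixel indices).
#'
#' @param b a box tibble (see [boxes()]).
#' @return numeric vector.
#' @export
box_area <- function(b) (b$x_max - b$x_min) * (b$y_max - b$y_min)

#' @rdname box_area
#' @export
box_diagonal <- function(b) sqrt((b$x_max - b$x_min)^2 + (b$y_max - b$y_min)^2)

# pairwise intersection areas: nrow(a) x nrow(b) matrix
intersection_matrix <- function(a, b) {
  iw <- pmax(outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax), 0)
  ih <- pmax(outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax), 0)
  iw * ih
}

#' Intersection-over-Union and Relative IoU between box sets
#'
#' `box_iou()` is the standard Jaccard overlap, intersection / union.
#' `box_riou()` is the Relative IoU: intersection area divided by the area
#' of the *smaller* of the two boxes, so a small box fully nested inside a
#' large one scores 1 regardless of the area ratio. RIoU is what the
#' VC-NMS decay stage uses to catch nested duplicate detections that plain
#' IoU under-rates.
#'
#' @param a,b box tibbles (see [boxes()]).
#' @return an `nrow(a) x nrow(b)` numeric matrix of overlaps in `[0, 1]`.
#' @examples
#' a <- boxes(0, 0, 10, 10)
#' b <- boxes(c(5, 2), c(0, 2), c(15, 8), c(10, 8))
#' box_iou(a, b)   # 1/3 for the half-overlap, 36/100 for the nested box
#' box_riou(a, b)  # 0.5 and 1
#' @export
box_iou <- function(a, b) {
  inter <- intersection_matrix(a, b)
  un <- outer(box_area(a), box_area(b), `+`) - inter
  out <- inter / un
  out[un == 0] <- 0
  out
}

#' @rdname box_iou
#' @export
box_riou <- function(a, b) {
  inter <- intersection_matrix(a, b)
  mn <- outer(box_area(a), box_area(b), pmin)
  out <- inter / mn
  out[mn == 0] <- 0
  out
}

#' Build the overlap graph over a set of boxes
#'
#' Two boxes overlap iff their intersection area is strictly positive
#' (touching along an edge does not count). The per-box overlap count
#' (`oven`) is the node degree, and `max_oven` its maximum; both feed the
#' stage-1 attenuation of VC-NMS, while the adjacency feeds NCGI
#' normalization.
#'
#' @param b a box tibble.
#' @return a list of class `"overlap_graph"` with elements `adjacency`
#'   (logical `n x n` matrix, no self-edges), `oven` (integer degrees) and
#'   `max_oven`.
#' @export
overlap_graph <- function(b) {
  n <- nrow(b)
  if (n == 0) {
    adj <- matrix(logical(0), 0, 0)
  } else {
    adj <- intersection_matrix(b, b) > 0
    diag(adj) <- FALSE
  }
  oven <- as.integer(rowSums(adj))
  structure(list(adjacency = adj, oven = oven,
                 max_oven = if (n) max(oven) else 0L, ids = b$id),
            class = "overlap_graph")
}

#' Read and write boxes in COCO-detection JSON and CSV
#'
#' COCO detection layout: a JSON array of records with `bbox = [x, y, w, h]`
#' and `score`. The CSV layout uses corner columns
#' `x_min, y_min, x_max, y_max, score`. Round trips are bit-exact.
#'
#' @param b a box tibble.
#' @param path file path.
#' @param image_id optional image id recorded in each COCO record.
#' @export
write_boxes_coco <- function(b, path, image_id = 1L) {
  b <- b[c("id", "x_min", "y_min", "x_max", "y_max", "score")]
  recs <- purrr::pmap(b, function(id, x_min, y_min, x_max, y_max, score) {
    list(id = id, image_id = image_id, category_id = 1L,
         bbox = c(x_min, y_min, x_max - x_min, y_max - y_min), score = score)
  })
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_boxes_coco
#' @export
read_boxes_coco <- function(path) {
  recs <- jsonlite::read_json(path)
  if (length(recs) == 0) return(empty_boxes())
  purrr::map_dfr(recs, function(r) {
    bb <- unlist(r$bbox)
    tibble::tibble(id = as.integer(r$id %||% NA_integer_),
                   x_min = bb[1], y_min = bb[2],
                   x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
                   score = as.numeric(r$score %||% 1))
  }) |>
    (\(d) { if (anyNA(d$id)) d$id <- seq_len(nrow(d)); validate_boxes(d) })()
}

#' @rdname write_boxes_coco
#' @export
write_boxes_csv <- function(b, path) {
  cols <- c("x_min", "y_min", "x_max", "y_max", "score")
  d <- as.data.frame(lapply(b[cols], function(x) sprintf("%.17g", x)))
  names(d) <- cols
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boxes_coco
#' @export
read_boxes_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = "numeric")
  d$id <- seq_len(nrow(d))
  validate_boxes(tibble::as_tibble(d)[c("id", "x_min", "y_min", "x_max",
                                        "y_max", "score")])
}

# clip boxes to an image of given height/width (pixel coordinate space)
clip_boxes <- function(b, height, width) {
  dplyr::mutate(b,
    x_min = pmax(.data$x_min, 0), y_min = pmax(.data$y_min, 0),
    x_max = pmin(.data$x_max, width), y_max = pmin(.data$y_max, height))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
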