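# ROI masks: H x W logicals plus traced contours. The periprostatic-fat ROI
# is an annulus, so a mask usually has one foreground component (the fat
# ring) enclosing one hole (the prostate); the outer contour (drawn green)
# lies on the outermost ROI pixels and the inner contour (drawn red) on the
# rim of the hole.

# 4-connected flood fill over a logical matrix, seeded at `seeds` (linear
# indices); returns logical matrix of reached cells. Pure R; grids here are
# small (<= a few hundred px a side).
flood_fill4 <- function(open, seeds) {
  h <- nrow(open); w <- ncol(open)
  reached <- matrix(FALSE, h, w)
  frontier <- unique(seeds[open[seeds] & !is.na(seeds)])
  reached[frontier] <- TRUE
  # vectorized frontier expansion; a few dozen sweeps for grids used here
  while (length(frontier)) {
    r <- ((frontier - 1L) %% h) + 1L
    c <- ((frontier - 1L) %/% h) + 1L
    cand <- c((frontier - 1L)[r > 1L],                 # up
              (frontier + 1L)[r < h],                  # down
              (frontier - h)[c > 1L],                  # left
              (frontier + h)[c < w])                   # right
    cand <- unique(cand[open[cand] & !reached[cand]])
    reached[cand] <- TRUE
    frontier <- cand
  }
  reached
}

# Label 4-connected components of a logical matrix; returns an integer
# matrix (0 = background) and the component count.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nlab <- 0L
  todo <- which(mask)
  for (i in todo) {
    if (lab[i] == 0L) {
      nlab <- nlab + 1L
      comp <- flood_fill4(mask & (lab == 0L), i)
      lab[comp] <- nlab
    }
  }
  list(labels = lab, n = nlab)
}

# Moore-neighbor boundary tracing (8-connected boundary, clockwise in image
# coordinates with rows increasing downward), with Jacob's stopping
# criterion. Returns an ordered closed path as an n x 2 matrix (row, col) on
# foreground pixels. A single isolated pixel yields a length-1 path.
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(t(mask))  # row-major scan
  if (!length(idx)) return(matrix(integer(0), 0, 2))
  r0 <- ((idx[1L] - 1L) %/% w) + 1L
  c0 <- ((idx[1L] - 1L) %% w) + 1L
  # clockwise Moore offsets starting west
  off <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
               c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  fg <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]

  step_from <- function(p, bdir) {
    # scan clockwise from the backtrack direction; return the first
    # foreground neighbour and the direction of the background cell examined
    # just before it (which becomes the next backtrack, seen from the new p)
    for (k in 0:7) {
      d <- ((bdir - 1L + k) %% 8L) + 1L
      rr <- p[1L] + off[d, 1L]; cc <- p[2L] + off[d, 2L]
      if (fg(rr, cc)) {
        prev <- ((d - 2L + 8L) %% 8L) + 1L
        bg <- c(p[1L] + off[prev, 1L], p[2L] + off[prev, 2L])
        delta <- c(bg[1L] - rr, bg[2L] - cc)
        nb <- which(off[, 1L] == delta[1L] & off[, 2L] == delta[2L])
        return(list(p = c(rr, cc), bdir = if (length(nb)) nb[1L] else 1L,
                    dir = d))
      }
    }
    NULL
  }

  start <- c(r0, c0)
  first <- step_from(start, 1L)  # west neighbour is background by scan order
  if (is.null(first)) return(matrix(start, 1L, 2L, dimnames = NULL))

  path <- matrix(start, 1L, 2L)
  p <- first$p; bdir <- first$bdir
  first_dir <- first$dir
  maxsteps <- 4L * h * w + 8L
  for (i in seq_len(maxsteps)) {
    if (p[1L] == r0 && p[2L] == c0) {
      # Jacob's criterion: back at the start, about to leave the same way
      nxt <- step_from(p, bdir)
      if (is.null(nxt) || nxt$dir == first_dir) break
      path <- rbind(path, p)
      p <- nxt$p; bdir <- nxt$bdir
    } else {
      path <- rbind(path, p)
      nxt <- step_from(p, bdir)
      if (is.null(nxt)) break
      p <- nxt$p; bdir <- nxt$bdir
    }
  }
  dimnames(path) <- NULL
  path
}

#' Construct a region-of-interest mask with traced contours
#'
#' Builds an `RoiMask` from an H x W logical matrix. Foreground components
#' are 4-connected; holes are background regions not reachable from the image
#' border. The outer contour is the traced boundary of each foreground
#' component (including its holes, i.e. the silhouette); the inner contour is
#' the traced rim of each hole. For the usual annular periprostatic-fat ROI
#' this yields one closed outer path and one closed inner path.
#'
#' @param in_roi logical matrix; `TRUE` marks ROI voxels. Must contain at
#'   least one `TRUE` cell.
#' @return a list of class `RoiMask` with elements `in_roi` (logical matrix),
#'   `outer_contour` and `inner_contour` (n x 2 integer matrices of
#'   (row, col) path points; zero rows when absent), and `n_components`.
#' @examples
#' m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE; m[5, 5] <- FALSE
#' rm <- roi_mask(m)
#' nrow(rm$inner_contour)  # the single-pixel hole rim
#' @export
roi_mask <- function(in_roi) {
  if (!is.matrix(in_roi) || !is.logical(in_roi))
    stop("`in_roi` must be a logical matrix", call. = FALSE)
  if (anyNA(in_roi)) stop("mask contains NA", call. = FALSE)
  h <- nrow(in_roi); w <- ncol(in_roi)
  if (!any(in_roi)) {
    # an empty mask is representable (zeroing everything); file readers and
    # the extraction stage reject it where the contracts require content
    empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    return(structure(list(in_roi = in_roi, outer_contour = empty,
                          inner_contour = empty, n_components = 0L),
                     class = "RoiMask"))
  }

  # holes: background not 4-reachable from the border
  border <- unique(c(which(row(in_roi) == 1L), which(row(in_roi) == h),
                     which(col(in_roi) == 1L), which(col(in_roi) == w)))
  outside <- flood_fill4(!in_roi, border)
  holes <- (!in_roi) & (!outside)

  comp <- label_components(in_roi)
  if (comp$n > 1L)
    warning(sprintf("mask has %d connected ROI components; contours traced per component",
                    comp$n), call. = FALSE)

  outer <- matrix(integer(0), 0, 2)
  for (k in seq_len(comp$n)) {
    # silhouette: component plus any holes it encloses
    sil <- flood_fill4(comp$labels == k | holes, which(comp$labels == k)[1L])
    outer <- rbind(outer, trace_boundary(sil))
  }
  inner <- matrix(integer(0), 0, 2)
  hc <- label_components(holes)
  for (k in seq_len(hc$n)) inner <- rbind(inner, trace_boundary(hc$labels == k))

  colnames(outer) <- colnames(inner) <- c("row", "col")
  structure(list(in_roi = in_roi, outer_contour = outer,
                 inner_contour = inner, n_components = comp$n),
            class = "RoiMask")
}

#' @export
print.RoiMask <- function(x, ...) {
  cat(sprintf("<RoiMask %dx%d, %d ROI voxels, %d component(s), outer path %d px, inner path %d px>\n",
              nrow(x$in_roi), ncol(x$in_roi), sum(x$in_roi), x$n_components,
              nrow(x$outer_contour), nrow(x$inner_contour)))
  invisible(x)
}
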