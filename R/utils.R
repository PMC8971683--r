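# Internal numerical helpers shared across modules.

#' Bilinear image interpolation
#'
#' Samples an intensity image at continuous coordinates. The pixel grid is
#' taken to have pixel centres at `(col - 0.5, row - 0.5) * pixel_size`
#' micrometres; coordinates outside the image are clamped to the border
#' (replicate padding).
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param x,y numeric vectors of sample coordinates in micrometres.
#' @param pixel_size pixel edge length in micrometres.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
#' @noRd
bilinear_sample <- function(img, x, y, pixel_size) {
  nr <- nrow(img)
  nc <- ncol(img)
  # continuous pixel coordinates (1-based pixel centres)
  cx <- x / pixel_size + 0.5
  cy <- y / pixel_size + 0.5
  cx <- pmin(pmax(cx, 1), nc)
  cy <- pmin(pmax(cy, 1), nr)
  c0 <- pmin(floor(cx), nc - 1L)
  r0 <- pmin(floor(cy), nr - 1L)
  fx <- cx - c0
  fy <- cy - r0
  i00 <- img[cbind(r0, c0)]
  i01 <- img[cbind(r0, c0 + 1L)]
  i10 <- img[cbind(r0 + 1L, c0)]
  i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Total length of the union of closed intervals
#'
#' @param starts,ends interval endpoints (same length); intervals may overlap
#'   or be unsorted.
#' @return total covered length.
#' @keywords internal
#' @noRd
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0)
  o <- order(starts)
  s <- starts[o]
  e <- ends[o]
  total <- 0
  cur_s <- s[1]
  cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]
      cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Breadth-first reachability on an undirected edge list
#'
#' @param from,to integer node indices per edge.
#' @param n_nodes number of nodes.
#' @param start starting node index.
#' @return logical vector: reachable from `start`.
#' @keywords internal
#' @noRd
bfs_reachable <- function(from, to, n_nodes, start) {
  adj <- vector("list", n_nodes)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  seen <- logical(n_nodes)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

# linear interpolation of a polyline: given cumulative arclength table,
# return x/y at arbitrary arclengths (clamped to the trace ends)
polyline_point <- function(vx, vy, cumlen, s) {
  s <- pmin(pmax(s, 0), cumlen[length(cumlen)])
  x <- stats::approx(cumlen, vx, xout = s, rule = 2)$y
  y <- stats::approx(cumlen, vy, xout = s, rule = 2)$y
  cbind(x = x, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
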