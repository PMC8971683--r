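# Otsu multilevel thresholding, mask overlap, and component-area filtering.
#
# The colocalization quantifier is deliberately simple: per-channel multilevel
# Otsu segmentation, a manually chosen threshold level per channel, pixelwise
# mask conjunction, and removal of connected components outside a 20-500
# pixel effective-area window (autofluorescence speckle below, large
# structures above). Pixel counts are the authoritative filter unit; areas in
# um^2 are reported alongside.

#' Multilevel Otsu thresholds
#'
#' Thresholds maximizing the between-class variance of the intensity
#' histogram. For up to four classes the optimum is found by exhaustive
#' search over the observed intensity levels (guaranteed global optimum).
#' Thresholds are returned ascending; a pixel belongs to class k when its
#' intensity is >= the (k-1)-th threshold and < the k-th.
#'
#' @param image numeric matrix of non-negative intensities (integer-valued;
#'   8- or 16-bit data).
#' @param n_classes number of classes, 2..4.
#' @return numeric vector of `n_classes - 1` thresholds (intensity values).
#' @export
otsu_thresholds <- function(image, n_classes = 2) {
  if (n_classes < 2 || n_classes > 4) {
    stop("`n_classes` must be 2, 3 or 4", call. = FALSE)
  }
  vals <- as.vector(image)
  if (any(vals < 0)) stop("intensities must be non-negative", call. = FALSE)
  lv <- sort(unique(round(vals)))
  if (length(lv) < n_classes) {
    stop("degenerate histogram: fewer distinct intensities than classes",
         call. = FALSE)
  }
  cnt <- tabulate(match(round(vals), lv), nbins = length(lv))
  p <- cnt / sum(cnt)
  # cumulative weight and first moment over the level axis
  cw <- cumsum(p)
  cm <- cumsum(p * lv)
  m <- length(lv)
  # between-class variance is maximized iff sum_k m_k^2 / w_k is (total mean
  # and variance are partition-independent)
  score2 <- function(a, b) {
    # class = levels (a..b], zero-based split indices over 1..m; a, b may be
    # vectors (vectorized over candidate cuts)
    wa <- ifelse(a > 0, cw[pmax(a, 1L)], 0)
    ma <- ifelse(a > 0, cm[pmax(a, 1L)], 0)
    w <- cw[b] - wa
    mm <- cm[b] - ma
    ifelse(w > 0, mm^2 / w, 0)
  }
  best <- -Inf
  best_cut <- NULL
  if (n_classes == 2) {
    t1 <- seq_len(m - 1L)
    sc <- score2(0L, t1) + score2(t1, m)
    k <- which.max(sc)
    best_cut <- t1[k]
  } else if (n_classes == 3) {
    for (t1 in seq_len(m - 2L)) {
      t2 <- (t1 + 1L):(m - 1L)
      sc <- score2(0L, t1) + score2(t1, t2) + score2(t2, m)
      k <- which.max(sc)
      if (sc[k] > best) {
        best <- sc[k]
        best_cut <- c(t1, t2[k])
      }
    }
  } else {
    for (t1 in seq_len(m - 3L)) {
      for (t2 in (t1 + 1L):(m - 2L)) {
        t3 <- (t2 + 1L):(m - 1L)
        sc <- score2(0L, t1) + score2(t1, t2) + score2(t2, t3) + score2(t3, m)
        k <- which.max(sc)
        if (sc[k] > best) {
          best <- sc[k]
          best_cut <- c(t1, t2, t3[k])
        }
      }
    }
  }
  # report each threshold as the lowest intensity of the upper class
  lv[best_cut + 1L]
}

#' Binarize with a chosen threshold level
#'
#' Foreground is every pixel with intensity >= the selected threshold.
#'
#' @param image numeric matrix.
#' @param thresholds ascending thresholds from [otsu_thresholds()].
#' @param level index into `thresholds`; default the highest level (the
#'   brightest class), mirroring a manually selected level.
#' @return logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(image, thresholds, level = length(thresholds)) {
  if (level < 1L || level > length(thresholds)) {
    stop("`level` out of range", call. = FALSE)
  }
  image >= thresholds[level]
}

#' Overlap of two binary masks
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return logical matrix, the pixelwise conjunction.
#' @export
overlap_mask <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask shapes differ", call. = FALSE)
  }
  mask_a & mask_b
}

#' Label connected components of a binary mask
#'
#' Breadth-first labelling with 4- or 8-connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default).
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L)
    dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  cur <- 0L
  todo <- which(mask)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      cl <- ((frontier - 1L) %/% nr) + 1L
      nbr <- integer(0)
      for (k in seq_along(dr)) {
        rr <- r + dr[k]
        cc <- cl + dc[k]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * nr + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[mask[nbr] & lab[nbr] == 0L]
      lab[nbr] <- cur
      frontier <- nbr
    }
  }
  lab
}

#' Filter connected components by pixel area
#'
#' Removes components whose pixel count lies outside `[min_px, max_px]`
#' (bounds inclusive; the default 20-500 px window corresponds to the
#' published effective-area filter). Areas are reported both in pixels
#' (authoritative) and in um^2 (`count * pixel_size^2`).
#'
#' @param mask logical matrix.
#' @param min_px,max_px inclusive pixel-count bounds. Defaults 20 and 500.
#' @param connectivity 4 or 8 (default).
#' @param pixel_size um per pixel, for the um^2 report. Default 1.136.
#' @return list: `mask` (filtered), `components` (data frame: id, pixel_count,
#'   area_um2, kept).
#' @export
filter_components <- function(mask, min_px = 20, max_px = 500,
                              connectivity = 8, pixel_size = 1.136) {
  if (min_px > max_px) stop("`min_px` must be <= `max_px`", call. = FALSE)
  lab <- label_components(mask, connectivity)
  n_comp <- max(lab)
  if (n_comp == 0L) {
    return(list(mask = mask & FALSE,
                components = data.frame(id = integer(0),
                                        pixel_count = integer(0),
                                        area_um2 = numeric(0),
                                        kept = logical(0))))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
  kept <- sizes >= min_px & sizes <= max_px
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  keep_ids <- which(kept)
  out[lab %in% keep_ids] <- TRUE
  list(mask = out,
       components = data.frame(id = seq_len(n_comp), pixel_count = sizes,
                               area_um2 = sizes * pixel_size^2, kept = kept))
}
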