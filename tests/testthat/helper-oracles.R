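# Independent brute-force oracles. These deliberately use the most naive
# formulation of each rule so that agreement with the package implementation
# is informative.

# nearest-neighbour linking by full pairwise enumeration
oracle_link <- function(s_t, s_t1, cutoff, fps) {
  out <- NULL
  for (s in s_t) {
    d <- abs(s_t1 - s)
    j <- which.min(d)
    if (d[j] <= cutoff) {
      out <- rbind(out, data.frame(from_um = s, to_um = s_t1[j],
                                   displacement_um = s_t1[j] - s,
                                   speed_cms = (s_t1[j] - s) * fps * 1e-4))
    }
  }
  if (is.null(out)) {
    out <- data.frame(from_um = numeric(0), to_um = numeric(0),
                      displacement_um = numeric(0), speed_cms = numeric(0))
  }
  out
}

# single-linkage clustering by iterated pairwise merging of cluster sets
oracle_single_linkage <- function(peaks, radius) {
  clusters <- as.list(sort(peaks))
  repeat {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        gap <- min(abs(outer(clusters[[i]], clusters[[j]], "-")))
        if (gap < radius) {
          clusters[[i]] <- c(clusters[[i]], clusters[[j]])
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sort(vapply(clusters, mean, numeric(1)))
}

# exhaustive Otsu: minimize total within-class variance over all cut tuples
oracle_otsu <- function(image, n_classes) {
  v <- sort(round(as.vector(image)))
  lv <- unique(v)
  wcv <- function(cuts) {
    bounds <- c(-Inf, lv[cuts], Inf)
    tot <- 0
    for (k in seq_len(length(bounds) - 1L)) {
      cls <- v[v > bounds[k] & v <= bounds[k + 1L]]
      if (length(cls)) tot <- tot + sum((cls - mean(cls))^2)
    }
    tot
  }
  m <- length(lv)
  combs <- utils::combn(m - 1L, n_classes - 1L)
  scores <- apply(combs, 2, wcv)
  cuts <- combs[, which.min(scores)]
  lv[cuts + 1L]   # lowest intensity of each upper class
}

# stack-based flood fill labelling
oracle_flood_fill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r <- p[1] + o[1]; cc <- p[2] + o[2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# quantile by explicit sort-and-interpolate (type-7 convention)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# canonical component sizes irrespective of label numbering
comp_size_multiset <- function(lab) {
  if (max(lab) == 0L) return(integer(0))
  sort(tabulate(lab[lab > 0L]))
}
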