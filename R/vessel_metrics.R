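# --- small raster helpers -------------------------------------------------

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(M, dr, dc, fill = 0L) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- M[rs - dr, cs - dc, drop = FALSE]
  out
}

# Number of TRUE 8-neighbours of every pixel (out-of-image = FALSE).
neighbor_count8 <- function(mask) {
  M <- mask * 1L
  tot <- matrix(0L, nrow(M), ncol(M))
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0L || dc != 0L) tot <- tot + shift_mat(M, dr, dc)
  tot
}

# Sum of non-overlapping ws x ws blocks; trailing partial blocks dropped.
block_sum <- function(M, ws) {
  ny <- nrow(M) %/% ws; nx <- ncol(M) %/% ws
  M <- M[seq_len(ny * ws), seq_len(nx * ws), drop = FALSE]
  ri <- rep(seq_len(ny), each = ws)
  ci <- rep(seq_len(nx), each = ws)
  t(rowsum(t(rowsum(M + 0, ri, reorder = TRUE)), ci, reorder = TRUE))
}

#' Merge artery and vein masks into the large-vessel mask
#'
#' @param artery,vein Logical matrices of equal size.
#' @return Logical matrix, the pixelwise union.
#' @export
merge_large_vessel <- function(artery, vein) {
  if (!identical(dim(artery), dim(vein)))
    stop("geometry mismatch: artery and vein masks differ in size",
         call. = FALSE)
  artery | vein
}

#' Binary skeleton (Guo-Hall thinning)
#'
#' Iteratively peels border pixels with the two-subiteration Guo-Hall
#' scheme until stable, leaving a 1-pixel-wide, 8-connected medial line.
#' The skeleton is always a subset of the input mask; an empty mask yields
#' an empty skeleton.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same size.
#' @export
binary_skeleton <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  M <- mask * 1L
  h <- nrow(M); w <- ncol(M)
  neighbours <- function(M) {
    # p1=N p2=NE p3=E p4=SE p5=S p6=SW p7=W p8=NW (rows grow southward)
    list(p1 = shift_mat(M,  1,  0), p2 = shift_mat(M,  1, -1),
         p3 = shift_mat(M,  0, -1), p4 = shift_mat(M, -1, -1),
         p5 = shift_mat(M, -1,  0), p6 = shift_mat(M, -1,  1),
         p7 = shift_mat(M,  0,  1), p8 = shift_mat(M,  1,  1))
  }
  it <- 0L
  repeat {
    changed <- FALSE
    for (odd in c(TRUE, FALSE)) {
      n <- neighbours(M)
      C <- (1L - n$p1) * (n$p2 | n$p3) + (1L - n$p3) * (n$p4 | n$p5) +
           (1L - n$p5) * (n$p6 | n$p7) + (1L - n$p7) * (n$p8 | n$p1)
      N1 <- (n$p1 | n$p2) + (n$p3 | n$p4) + (n$p5 | n$p6) + (n$p7 | n$p8)
      N2 <- (n$p2 | n$p3) + (n$p4 | n$p5) + (n$p6 | n$p7) + (n$p8 | n$p1)
      Nm <- pmin(N1, N2)
      m3 <- if (odd) (n$p2 | n$p3 | (1L - n$p5)) * n$p4
            else     (n$p6 | n$p7 | (1L - n$p1)) * n$p8
      del <- M == 1L & C == 1L & Nm >= 2L & Nm <= 3L & m3 == 0L
      if (any(del)) { M[del] <- 0L; changed <- TRUE }
    }
    it <- it + 1L
    if (!changed || it > max(h, w)) break
  }
  M == 1L
}

# Vessel pixels 4-adjacent to background. Out-of-image neighbours are
# treated as vessel continuation (replicate padding), so the image frame
# itself never counts as boundary.
boundary_mask <- function(mask) {
  M <- mask * 1L
  edge <- function(dr, dc) {
    s <- shift_mat(M, dr, dc, fill = NA)
    s[is.na(s)] <- M[is.na(s)]  # replicate padding
    s
  }
  mask & (edge(1, 0) == 0 | edge(-1, 0) == 0 |
          edge(0, 1) == 0 | edge(0, -1) == 0)
}

# Branch points: skeleton pixels with >= 3 skeleton 8-neighbours.
branch_points <- function(skeleton) {
  skeleton & neighbor_count8(skeleton) >= 3L
}

# Mean-filter a coordinate sequence with a centred 5-point window that
# shrinks at the path ends; suppresses pixel-lattice jaggedness before
# differentiating.
smooth5 <- function(v) {
  n <- length(v)
  vapply(seq_len(n), function(i) mean(v[max(1, i - 2):min(n, i + 2)]),
         numeric(1))
}

# |curvature| samples along one ordered path of pixel coordinates
# (matrix with columns row, col). Central finite differences on the
# smoothed coordinates; paths shorter than 5 pixels yield no samples.
path_curvature <- function(coords) {
  n <- nrow(coords)
  if (n < 5) return(numeric(0))
  x <- smooth5(coords[, 2]); y <- smooth5(coords[, 1])
  i <- 2:(n - 1)
  xp <- (x[i + 1] - x[i - 1]) / 2;  yp <- (y[i + 1] - y[i - 1]) / 2
  xpp <- x[i + 1] - 2 * x[i] + x[i - 1]
  ypp <- y[i + 1] - 2 * y[i] + y[i - 1]
  den <- (xp^2 + yp^2)^1.5
  k <- ifelse(den == 0, 0, (xp * ypp - yp * xpp) / den)
  abs(k)
}

# Decompose a small skeleton patch into simple paths: remove branch pixels,
# then walk each remaining arc from an endpoint. Returns a list of ordered
# coordinate matrices. Closed loops without endpoints are skipped.
skeleton_paths <- function(sub) {
  if (!any(sub)) return(list())
  deg_all <- neighbor_count8(sub)
  keep <- sub & deg_all < 3L
  if (!any(keep)) return(list())
  deg <- neighbor_count8(keep) * keep
  h <- nrow(keep); w <- ncol(keep)
  visited <- matrix(FALSE, h, w)
  # 4-adjacent first so the walk prefers the tighter connection
  offs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  next_px <- function(r, c) {
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
          keep[rr, cc] && !visited[rr, cc]) return(c(rr, cc))
    }
    NULL
  }
  ends <- which(keep & deg <= 1L, arr.ind = TRUE)
  paths <- list()
  if (nrow(ends) > 0) {
    for (e in seq_len(nrow(ends))) {
      r <- ends[e, 1]; c <- ends[e, 2]
      if (visited[r, c]) next
      path <- matrix(numeric(0), 0, 2)
      repeat {
        visited[r, c] <- TRUE
        path <- rbind(path, c(r, c))
        nx <- next_px(r, c)
        if (is.null(nx)) break
        r <- nx[1]; c <- nx[2]
      }
      paths[[length(paths) + 1]] <- path
    }
  }
  paths
}

#' Windowed vessel index maps
#'
#' Tiles the mask into non-overlapping `window_size` x `window_size`
#' windows (trailing partial windows are dropped) and computes, per window:
#' \describe{
#'   \item{VAD}{vessel area density: vessel pixels / window pixels.}
#'   \item{VSD}{vessel skeleton density: skeleton pixels / window pixels.}
#'   \item{VPI}{vessel perimeter index: vessel pixels 4-adjacent to
#'     background / window pixels.}
#'   \item{VDI}{vessel diameter index: VAD / VSD (0 where the window has no
#'     skeleton).}
#'   \item{VCI}{vessel complexity index: VPI^2 / (4 pi VAD) (0 where the
#'     window has no vessel).}
#'   \item{VCP}{vessel complexity: branch points / skeleton pixels (0 where
#'     the window has no skeleton); a branch point is a skeleton pixel with
#'     at least three skeleton 8-neighbours.}
#'   \item{SP}{shape parameter: mean |curvature| over simple skeleton paths
#'     of at least 5 pixels inside the window (0 if none); curvature is
#'     `(x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)` by central differences on
#'     5-point-smoothed path coordinates.}
#' }
#' The skeleton, boundary and branch points are computed once on the whole
#' mask and then counted per window, so window borders do not cut vessels.
#'
#' @param mask Logical matrix, at least `window_size` in both dimensions.
#' @param window_size Window edge in pixels (default 20).
#' @return Object of class `local_index_maps`: list of seven numeric
#'   matrices (one value per window) plus `window_size`.
#' @export
local_index_maps <- function(mask, window_size = 20) {
  if (nrow(mask) < window_size || ncol(mask) < window_size)
    stop("window larger than image", call. = FALSE)
  ws2 <- window_size^2
  skel <- binary_skeleton(mask)
  bnd <- boundary_mask(mask)
  bp <- branch_points(skel)

  vad <- block_sum(mask, window_size) / ws2
  vsd_cnt <- block_sum(skel, window_size)
  vsd <- vsd_cnt / ws2
  vpi <- block_sum(bnd, window_size) / ws2
  bp_cnt <- block_sum(bp, window_size)
  vdi <- ifelse(vsd > 0, vad / vsd, 0)
  vci <- ifelse(vad > 0, vpi^2 / (4 * pi * vad), 0)
  vcp <- ifelse(vsd_cnt > 0, bp_cnt / vsd_cnt, 0)

  ny <- nrow(vad); nx <- ncol(vad)
  sp <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      rs <- ((i - 1) * window_size + 1):(i * window_size)
      cs <- ((j - 1) * window_size + 1):(j * window_size)
      sub <- skel[rs, cs, drop = FALSE]
      if (sum(sub) < 5) next
      ks <- unlist(lapply(skeleton_paths(sub), path_curvature))
      if (length(ks) > 0) sp[i, j] <- mean(ks)
    }
  }
  structure(list(VAD = vad, VSD = vsd, VPI = vpi, VDI = vdi,
                 VCI = vci, VCP = vcp, SP = sp,
                 window_size = window_size),
            class = "local_index_maps")
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts the number `N(r)` of `r` x `r` boxes containing at least one
#' foreground pixel over dyadic box sizes `r = 2, 4, ..., <= min(H, W)/4`
#' and returns the least-squares slope of `log N(r)` versus `log(1/r)`:
#' about 0 for a point, 1 for a curve and 2 for a filled region.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return Scalar fractal dimension.
#' @export
box_counting_fd <- function(mask) {
  if (!any(mask))
    stop("empty structure: fractal dimension undefined", call. = FALSE)
  mx <- min(dim(mask))
  kmax <- floor(log2(mx / 4))
  if (kmax < 2)
    stop("image too small for box counting (need min dimension >= 16)",
         call. = FALSE)
  sizes <- 2^(1:kmax)
  counts <- vapply(sizes, function(r) {
    ri <- (seq_len(nrow(mask)) - 1L) %/% r
    ci <- (seq_len(ncol(mask)) - 1L) %/% r
    blocks <- rowsum(t(rowsum(mask + 0, ri, reorder = TRUE)), ci,
                     reorder = TRUE)
    sum(blocks > 0)
  }, numeric(1))
  unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
}

#' Distribution summary of an index map
#'
#' @param map Numeric matrix or vector with at least 2 values.
#' @return Named vector: `max`, `mean`, `median`, `std` (sample, n-1
#'   denominator), `skew` (Fisher-Pearson, population moments) and `kur`
#'   (Pearson, non-excess; 3 for a normal distribution). Skewness and
#'   kurtosis of a constant map are defined as 0.
#' @export
distribution_summary <- function(map) {
  v <- as.vector(map)
  if (length(v) < 2)
    stop("insufficient windows: need at least 2 values", call. = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  sk <- if (m2 == 0) 0 else mean((v - m)^3) / m2^1.5
  ku <- if (m2 == 0) 0 else mean((v - m)^4) / m2^2
  c(max = max(v), mean = m, median = median(v), std = sd(v),
    skew = sk, kur = ku)
}

#' The 43 vessel features of one structure
#'
#' Six distribution summaries of each of the seven windowed index maps
#' (42 values) plus the box-counting fractal dimension of the whole mask.
#' Summaries are taken over all windows, including vessel-free ones.
#'
#' @param mask Logical vessel mask.
#' @param structure Name used as feature prefix, e.g. `"capillary"` or
#'   `"large_vessel"`.
#' @param window_size Window edge in pixels (default 20).
#' @return Named numeric vector of length 43
#'   (`"<structure>_<index>_<stat>"`, plus `"<structure>_FD"`).
#' @export
vessel_feature_set <- function(mask, structure, window_size = 20) {
  maps <- local_index_maps(mask, window_size)
  out <- numeric(0)
  for (idx in VESSEL_INDICES) {
    s <- distribution_summary(maps[[idx]])
    names(s) <- paste(structure, idx, SUMMARY_STATS, sep = "_")
    out <- c(out, s)
  }
  fd <- box_counting_fd(mask)
  names(fd) <- paste0(structure, "_FD")
  c(out, fd)
}
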