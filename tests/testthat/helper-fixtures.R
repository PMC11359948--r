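# Shared fixtures: analytic shapes, brute-force LBP oracle, tiny cohorts.

disk_mask <- function(size, r, cx = size / 2, cy = size / 2) {
  xs <- matrix(rep(seq_len(size), each = size), size)   # columns
  ys <- matrix(rep(seq_len(size), times = size), size)  # rows
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

rect_mask <- function(size, rows, cols) {
  m <- matrix(FALSE, size, size)
  m[rows, cols] <- TRUE
  m
}

ellipse_mask <- function(size, a, b, cx = size / 2, cy = size / 2) {
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), times = size), size)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Independent per-pixel LBP coder: literal double loop over pixels and
# neighbours (p = 0 east, counter-clockwise), s(x) = 1 iff x > 0.
brute_lbp_codes <- function(image) {
  h <- nrow(image); w <- ncol(image)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  out <- matrix(NA_integer_, h - 2, w - 2)
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      code <- 0L
      for (p in 0:7) {
        o <- offs[[p + 1]]
        if (image[r + o[1], c + o[2]] > image[r, c])
          code <- code + as.integer(2^p)
      }
      out[r - 1, c - 1] <- code
    }
  }
  out
}

# Independent uniformity classifier: count circular 0<->1 transitions of
# the 8-bit code written as a character string.
brute_transitions <- function(code) {
  bits <- integer(8)
  for (i in 1:8) {
    bits[i] <- code %% 2
    code <- code %/% 2
  }
  n <- 0L
  for (i in 1:8) if (bits[i] != bits[i %% 8 + 1]) n <- n + 1L
  n
}

brute_histogram <- function(codes) {
  tr <- vapply(0:255, brute_transitions, integer(1))
  uni <- which(tr <= 2) - 1L
  bins <- numeric(59)
  for (code in as.vector(codes)) {
    i <- match(code, uni)
    if (is.na(i)) i <- 59L
    bins[i] <- bins[i] + 1
  }
  bins / length(codes)
}

# Small image-level cohort cached across tests (expensive to build).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_per_group = c(control = 3, DR = 3),
                          image_size = 96, faz_radius = c(control = 16,
                                                          DR = 14),
                          seed = 42)
      cache <<- synth_cohort(spec)
    }
    cache
  }
})
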