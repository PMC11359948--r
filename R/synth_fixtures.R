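# Seeded synthetic eye records: procedural vessel networks, parametric FAZ
# blobs and Gaussian-random-field textures with controllable group
# structure. Statistical controllability, not biophysical realism, is the
# design goal; every generator is a pure function of (seed, parameters).

# Gaussian random field: white noise low-pass filtered in the frequency
# domain with a Gaussian kernel of standard deviation `sigma` pixels.
gauss_field <- function(size, sigma) {
  z <- matrix(rnorm(size^2), size)
  if (sigma > 0) {
    half <- size %/% 2
    fx <- c(0:half, if (size - half - 1 > 0) -((size - half - 1):1)) / size
    g <- exp(-2 * pi^2 * sigma^2 * fx^2)
    z <- Re(fft(fft(z) * outer(g, g), inverse = TRUE) / size^2)
  }
  z
}

# 0-255 texture image with tunable autocorrelation (smoothness) and mean
# offset; LBP histograms respond to the autocorrelation length.
synth_texture <- function(seed, size, smoothness = 2, offset = 0,
                          contrast = 40) {
  withr::with_seed(seed, {
    z <- gauss_field(size, smoothness)
    z <- (z - mean(z)) / sd(z)
    img <- round(128 + offset + contrast * z)
    matrix(as.integer(pmin(pmax(img, 0), 255)), size)
  })
}

# Stamp a polyline onto a mask with a disc footprint of diameter `width`.
stamp_path <- function(mask, pts, width) {
  size <- nrow(mask)
  r <- round(pts[, 1]); c <- round(pts[, 2])
  ok <- r >= 1 & r <= size & c >= 1 & c <= size
  r <- r[ok]; c <- c[ok]
  rad <- width / 2
  rng <- -floor(rad):floor(rad)
  for (dr in rng) for (dc in rng) {
    if (dr^2 + dc^2 > rad^2 && (dr != 0 || dc != 0)) next
    rr <- pmin(pmax(r + dr, 1), size)
    cc <- pmin(pmax(c + dc, 1), size)
    mask[cbind(rr, cc)] <- TRUE
  }
  mask
}

# One meandering stroke: a correlated random walk across the image.
random_stroke <- function(size) {
  pos <- runif(2, size * 0.1, size * 0.9)
  ang <- runif(1, 0, 2 * pi)
  L <- round(size * runif(1, 0.6, 1.4))
  pts <- matrix(0, L, 2)
  for (i in seq_len(L)) {
    ang <- ang + rnorm(1, 0, 0.15)
    pos <- pos + c(sin(ang), cos(ang))
    pos <- pmin(pmax(pos, 2), size - 1)
    pts[i, ] <- pos
  }
  pts
}

#' Synthetic vessel mask
#'
#' With `branching > 0`, correlated random-walk strokes of width 1-4 pixels
#' (each optionally spawning `~Poisson(branching)` child strokes) are added
#' until the global vessel fraction reaches `density`; crossings create
#' branch points. With `branching = 0`, disjoint smooth horizontal paths in
#' separate bands are drawn instead, so the skeleton has no branch points.
#' Deterministic given `seed`; the realised fraction is within 20% of the
#' target or an error is raised.
#'
#' @param seed Integer seed.
#' @param size Image edge in pixels.
#' @param density Target vessel fraction, in (0, 0.6).
#' @param branching Mean number of child strokes per stroke (default 2).
#' @param widths Candidate stroke widths in pixels.
#' @return Logical `size` x `size` matrix.
#' @export
synth_vessel_mask <- function(seed, size, density, branching = 2,
                              widths = 1:4) {
  if (density <= 0 || density >= 0.6)
    stop("density must be in (0, 0.6)", call. = FALSE)
  withr::with_seed(seed, {
    mask <- matrix(FALSE, size, size)
    if (branching == 0) {
      width <- 3
      nb <- max(1, round(density * size / width))
      spacing <- size / nb
      if (spacing < width + 3)
        stop("unreachable density for non-branching vessels", call. = FALSE)
      amp <- spacing / 2 - width / 2 - 1
      for (b in seq_len(nb)) {
        centre <- (b - 0.5) * spacing
        jit <- cumsum(rnorm(size, 0, 0.4))
        jit <- jit - mean(jit)
        if (max(abs(jit)) > 0) jit <- jit * min(1, amp / max(abs(jit)))
        pts <- cbind(centre + jit, seq_len(size))
        mask <- stamp_path(mask, pts, width)
      }
    } else {
      strokes <- 0
      while (mean(mask) < density && strokes < 500) {
        w <- sample(widths, 1)
        pts <- random_stroke(size)
        mask <- stamp_path(mask, pts, w)
        n_child <- stats::rpois(1, branching)
        for (k in seq_len(n_child)) {
          if (mean(mask) >= density) break
          start <- pts[sample(nrow(pts), 1), ]
          ang <- runif(1, 0, 2 * pi)
          L <- round(size * runif(1, 0.2, 0.6))
          child <- matrix(0, L, 2)
          pos <- start
          for (i in seq_len(L)) {
            ang <- ang + rnorm(1, 0, 0.15)
            pos <- pos + c(sin(ang), cos(ang))
            pos <- pmin(pmax(pos, 2), size - 1)
            child[i, ] <- pos
          }
          mask <- stamp_path(mask, child, sample(widths, 1))
        }
        strokes <- strokes + 1
      }
      if (mean(mask) < 0.8 * density)
        stop("unreachable density: got ", round(mean(mask), 3),
             " of target ", density, call. = FALSE)
    }
    mask
  })
}

#' Synthetic FAZ mask
#'
#' A rasterised ellipse of the requested equivalent radius and
#' eccentricity, with a smooth random radial boundary perturbation of
#' relative amplitude `noise` (a band-limited Fourier series in the polar
#' angle). Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param size Image edge in pixels.
#' @param radius Equivalent circle radius in pixels (>= 10).
#' @param eccentricity Target ellipse eccentricity in [0, 1).
#' @param noise Relative boundary perturbation amplitude (0 = smooth).
#' @return Logical `size` x `size` matrix.
#' @export
synth_faz_mask <- function(seed, size, radius = 40, eccentricity = 0,
                           noise = 0) {
  if (radius < 10) stop("radius must be >= 10", call. = FALSE)
  withr::with_seed(seed, {
    a <- radius * (1 - eccentricity^2)^(-1 / 4)
    b <- radius * (1 - eccentricity^2)^(1 / 4)
    ks <- 2:6
    amp <- rnorm(length(ks)) / ks
    phi <- runif(length(ks), 0, 2 * pi)
    norm <- sqrt(sum(amp^2) / 2)  # sd of the cosine series over angle
    if (norm == 0) norm <- 1
    cx <- size / 2 + 0.5; cy <- size / 2 + 0.5
    dx <- matrix(rep(seq_len(size), each = size), size) - cx   # col offset
    dy <- matrix(rep(seq_len(size), times = size), size) - cy  # row offset
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    g <- Reduce(`+`, lapply(seq_along(ks), function(i)
      amp[i] * cos(ks[i] * theta + phi[i]))) / norm
    r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    rb <- pmax(r_ell * (1 + noise * g), 3)
    rho <= rb
  })
}

#' Cohort specification for the synthetic generators
#'
#' Group-wise generator parameters; scalars are recycled across groups.
#' The defaults emulate a small OCTA-style cohort: 304-pixel grids, a
#' capillary bed occupying roughly a fifth of the image with mild disease
#' rarefaction, a FAZ of a few percent of the image area that is smaller,
#' more eccentric and more irregular in disease, and textures whose
#' autocorrelation shortens with disease.
#'
#' @param n_per_group Named integer vector, eyes per group.
#' @param image_size Image edge in pixels.
#' @param vessel_density Capillary vessel fraction per group.
#' @param large_vessel_density Combined artery+vein fraction (split evenly).
#' @param faz_radius,faz_eccentricity,faz_noise FAZ shape per group.
#' @param texture_smoothness,texture_offset Texture field parameters per
#'   group (autocorrelation sigma in pixels; mean intensity offset).
#' @param seed Integer master seed; fixes every draw.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(control = 20, AMD = 8, DR = 8,
                                        other = 8),
                        image_size = 304,
                        vessel_density = c(control = 0.22, AMD = 0.19,
                                           DR = 0.17, other = 0.18),
                        large_vessel_density = 0.10,
                        faz_radius = c(control = 28, AMD = 24, DR = 23,
                                       other = 24),
                        faz_eccentricity = c(control = 0.47, AMD = 0.55,
                                             DR = 0.55, other = 0.55),
                        faz_noise = c(control = 0.05, AMD = 0.12,
                                      DR = 0.15, other = 0.12),
                        texture_smoothness = c(control = 2.0, AMD = 1.6,
                                               DR = 1.5, other = 1.7),
                        texture_offset = c(control = 0, AMD = 5, DR = 8,
                                           other = 4),
                        seed = 1) {
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% GROUP_LABELS))
    stop("n_per_group must be named with labels among: ",
         paste(GROUP_LABELS, collapse = ", "), call. = FALSE)
  per_group <- function(x) {
    if (length(x) == 1 && is.null(names(x)))
      return(stats::setNames(rep(x, length(groups)), groups))
    if (!all(groups %in% names(x)))
      stop("per-group parameter missing a group", call. = FALSE)
    x[groups]
  }
  structure(list(
    n_per_group = n_per_group, image_size = image_size,
    vessel_density = per_group(vessel_density),
    large_vessel_density = per_group(large_vessel_density),
    faz_radius = per_group(faz_radius),
    faz_eccentricity = per_group(faz_eccentricity),
    faz_noise = per_group(faz_noise),
    texture_smoothness = per_group(texture_smoothness),
    texture_offset = per_group(texture_offset),
    seed = seed), class = "cohort_spec")
}

# One synthetic eye: six textured projections and four masks. OCTA
# projections overlay the vessel masks on the texture so their LBP
# histograms carry a vascular signal; OCT projections are pure texture.
synth_eye_record <- function(seed, eye_id, size, vessel_density,
                             large_vessel_density, faz_radius, faz_ecc,
                             faz_noise, tex_smooth, tex_offset, label) {
  sub <- withr::with_seed(seed, sample.int(1073741823L, 12))
  capillary <- synth_vessel_mask(sub[1], size, vessel_density,
                                 branching = 2)
  artery <- synth_vessel_mask(sub[2], size, large_vessel_density / 2,
                              branching = 1, widths = 3:4)
  vein <- synth_vessel_mask(sub[3], size, large_vessel_density / 2,
                            branching = 1, widths = 3:4)
  faz <- synth_faz_mask(sub[4], size, faz_radius, faz_ecc, faz_noise)
  capillary <- capillary & !faz  # the FAZ is capillary-free
  large <- artery | vein
  overlay <- function(tex, mask, gain = 90) {
    img <- tex + gain * mask
    matrix(as.integer(pmin(pmax(img, 0), 255)), size)
  }
  projections <- list()
  for (i in seq_along(LAYERS)) {
    tex <- synth_texture(sub[4 + i], size, tex_smooth * c(1, 0.9, 0.8)[i],
                         tex_offset)
    projections[[paste0("OCT_", LAYERS[i])]] <- tex
  }
  octa_masks <- list(capillary | large, capillary, capillary)
  for (i in seq_along(LAYERS)) {
    tex <- synth_texture(sub[7 + i], size, tex_smooth * 0.7, tex_offset,
                         contrast = 25)
    projections[[paste0("OCTA_", LAYERS[i])]] <-
      overlay(tex, octa_masks[[i]])
  }
  eye_record(eye_id, projections,
             list(capillary = capillary, artery = artery, vein = vein,
                  FAZ = faz),
             label)
}

#' Generate a synthetic cohort of eye records
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (list of [eye_record()]) and `labels`
#'   (data frame `eye_id`, `label`).
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(spec$n_per_group)
  seeds <- withr::with_seed(spec$seed,
                            sample.int(1073741823L, n_total))
  records <- vector("list", n_total)
  labels <- character(n_total)
  i <- 0
  for (g in names(spec$n_per_group)) {
    for (k in seq_len(spec$n_per_group[[g]])) {
      i <- i + 1
      eye_id <- sprintf("S%03d", i)
      records[[i]] <- synth_eye_record(
        seeds[i], eye_id, spec$image_size,
        spec$vessel_density[[g]], spec$large_vessel_density[[g]],
        spec$faz_radius[[g]], spec$faz_eccentricity[[g]],
        spec$faz_noise[[g]], spec$texture_smoothness[[g]],
        spec$texture_offset[[g]], g)
      labels[i] <- g
    }
  }
  list(records = records,
       labels = data.frame(eye_id = sprintf("S%03d", seq_len(n_total)),
                           label = labels, stringsAsFactors = FALSE))
}

#' Feature-space synthetic cohort with designated signal features
#'
#' Draws a full 452-column feature table of standard normal noise and adds
#' a mean shift of `effect_size` standard deviations to the designated
#' signal features in every non-control group. This places the group
#' signal exactly where the experiment wants it, which image-space
#' generators cannot do feature-by-feature; it is the workhorse for the
#' selection and importance-recovery simulations.
#'
#' @param n_per_group Named integer vector (first group is the reference).
#' @param signal_features Character vector of canonical feature names.
#' @param effect_size Mean shift in noise standard deviations (default 3).
#' @param seed Integer seed.
#' @return A feature table (see [build_feature_table()]).
#' @export
synth_signal_table <- function(n_per_group = c(control = 30, DR = 30),
                               signal_features, effect_size = 3,
                               seed = 1) {
  nm <- feature_names()
  bad <- setdiff(signal_features, nm)
  if (length(bad) > 0)
    stop("unknown signal feature(s): ", paste(head(bad, 3), collapse = ", "),
         call. = FALSE)
  groups <- names(n_per_group)
  n_total <- sum(n_per_group)
  x <- withr::with_seed(seed, matrix(rnorm(n_total * length(nm)), n_total))
  colnames(x) <- nm
  labels <- rep(groups, n_per_group)
  shift_rows <- labels != groups[1]
  x[shift_rows, signal_features] <-
    x[shift_rows, signal_features] + effect_size
  tab <- data.frame(eye_id = sprintf("S%03d", seq_len(n_total)), x,
                    label = labels, check.names = FALSE,
                    stringsAsFactors = FALSE)
  validate_feature_table(tab)
  tab
}
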