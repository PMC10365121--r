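# Synthetic contrast-enhanced T1 head phantoms.
#
# A phantom is a nested pair of ellipsoids (head / brain) with bright
# extra-axial ellipsoidal tumors placed in a shell around the brain surface,
# vessel-like bright random-walk tubes inside the brain as distractors, a
# smooth multiplicative bias field, and additive Gaussian noise. Tumor
# volumes follow a truncated log-normal calibrated by moment matching to the
# cohort statistics (mean 18.33 ml, SD 27.20 ml, range [0.07, 167.99] ml).

# closed-form moments of a log-normal truncated to [a, b]
.trunc_lnorm_moments <- function(log_mu, log_sigma, a, b) {
  if (log_sigma <= 0) return(c(mean = exp(log_mu), sd = 0))
  la <- (log(a) - log_mu) / log_sigma
  lb <- (log(b) - log_mu) / log_sigma
  z <- stats::pnorm(lb) - stats::pnorm(la)
  m1 <- exp(log_mu + log_sigma^2 / 2) *
    (stats::pnorm(lb - log_sigma) - stats::pnorm(la - log_sigma)) / z
  m2 <- exp(2 * log_mu + 2 * log_sigma^2) *
    (stats::pnorm(lb - 2 * log_sigma) - stats::pnorm(la - 2 * log_sigma)) / z
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

#' Calibrate the tumor volume distribution
#'
#' Finds the parameters of a log-normal, truncated to
#' `[clip_min, clip_max]`, whose mean and standard deviation match the
#' target cohort statistics (numeric moment matching on the closed-form
#' truncated moments).
#'
#' @param target_mean target mean volume in ml.
#' @param target_sd target standard deviation in ml; `0` gives the
#'   degenerate distribution at `target_mean`.
#' @param clip_min,clip_max truncation bounds in ml.
#' @return a `tumor_volume_distribution` with `log_mu`, `log_sigma`, the
#'   clip bounds, targets and achieved moments.
#' @export
calibrate_volume_distribution <- function(target_mean = 18.33,
                                          target_sd = 27.20,
                                          clip_min = 0.07,
                                          clip_max = 167.99) {
  stopifnot(clip_min > 0, clip_min < clip_max,
            target_mean > clip_min, target_mean < clip_max, target_sd >= 0)
  make <- function(mu, sg, mom) {
    structure(list(log_mu = mu, log_sigma = sg, clip_min = clip_min,
                   clip_max = clip_max, target_mean = target_mean,
                   target_sd = target_sd, achieved_mean = mom[["mean"]],
                   achieved_sd = mom[["sd"]]),
              class = "tumor_volume_distribution")
  }
  if (target_sd == 0) {
    return(make(log(target_mean), 0,
                c(mean = target_mean, sd = 0)))
  }
  # untruncated log-normal start values
  mu0 <- log(target_mean^2 / sqrt(target_mean^2 + target_sd^2))
  s0 <- sqrt(log(1 + target_sd^2 / target_mean^2))
  obj <- function(par) {
    mom <- .trunc_lnorm_moments(par[1], exp(par[2]), clip_min, clip_max)
    ((mom[["mean"]] - target_mean) / target_mean)^2 +
      ((mom[["sd"]] - target_sd) / target_sd)^2
  }
  fit <- stats::optim(c(mu0, log(s0)), obj,
                      control = list(maxit = 2000, reltol = 1e-14))
  mu <- fit$par[1]
  sg <- exp(fit$par[2])
  mom <- .trunc_lnorm_moments(mu, sg, clip_min, clip_max)
  if (abs(mom[["mean"]] - target_mean) > 0.01 * target_mean ||
      abs(mom[["sd"]] - target_sd) > 0.05 * target_sd) {
    stop(sprintf(paste0("volume-distribution calibration failed: achieved ",
                        "mean %.3f (target %.3f), sd %.3f (target %.3f)"),
                 mom[["mean"]], target_mean, mom[["sd"]], target_sd))
  }
  make(mu, sg, mom)
}

#' @export
print.tumor_volume_distribution <- function(x, ...) {
  cat(sprintf(paste0("<tumor_volume_distribution> log-normal(mu=%.4f, ",
                     "sigma=%.4f) truncated to [%.2f, %.2f] ml\n",
                     "  mean %.3f ml (target %.2f), sd %.3f ml (target %.2f)\n"),
              x$log_mu, x$log_sigma, x$clip_min, x$clip_max,
              x$achieved_mean, x$target_mean, x$achieved_sd, x$target_sd))
  invisible(x)
}

#' Truncated log-normal CDF of the calibrated distribution
#' @param dist a `tumor_volume_distribution`.
#' @param q quantiles (ml).
#' @return cumulative probabilities.
#' @export
volume_distribution_cdf <- function(dist, q) {
  if (dist$log_sigma == 0) return(as.numeric(q >= exp(dist$log_mu)))
  pa <- stats::plnorm(dist$clip_min, dist$log_mu, dist$log_sigma)
  pb <- stats::plnorm(dist$clip_max, dist$log_mu, dist$log_sigma)
  p <- (stats::plnorm(q, dist$log_mu, dist$log_sigma) - pa) / (pb - pa)
  pmin(pmax(p, 0), 1)
}

#' Sample tumor volumes
#'
#' Inverse-CDF sampling from the truncated log-normal; all draws lie inside
#' `[clip_min, clip_max]` and are reproducible under the caller's RNG state.
#'
#' @param dist a calibrated `tumor_volume_distribution`.
#' @param n number of draws.
#' @return numeric vector of volumes in ml.
#' @export
sample_tumor_volume <- function(dist, n = 1) {
  stopifnot(inherits(dist, "tumor_volume_distribution"))
  if (dist$log_sigma == 0) return(rep(exp(dist$log_mu), n))
  pa <- stats::plnorm(dist$clip_min, dist$log_mu, dist$log_sigma)
  pb <- stats::plnorm(dist$clip_max, dist$log_mu, dist$log_sigma)
  u <- stats::runif(n, pa, pb)
  pmin(pmax(stats::qlnorm(u, dist$log_mu, dist$log_sigma),
            dist$clip_min), dist$clip_max)
}

#' Phantom specification
#'
#' Geometry, tissue and artifact parameters of the synthetic head. Defaults
#' describe the test-scale 64x64x72 grid at 2 mm; a full-scale
#' 256x256x192 at 1 mm phantom is obtained by overriding `grid_shape` and
#' `spacing`.
#'
#' @param grid_shape voxels per axis.
#' @param spacing mm per axis.
#' @param head_axes,brain_axes ellipsoid semi-axes in mm; the brain must lie
#'   strictly inside the head.
#' @param tissue_intensities named list of `c(mean, sd)` pairs for
#'   `background`, `scalp`, `brain`, `tumor`, `vessel` (arbitrary units).
#'   Tumors must be brighter than brain (contrast enhancement) and vessel
#'   mean must be within 10% of tumor mean (confusable distractor).
#' @param n_tumor_probs probabilities of 1, 2, ... tumors per case.
#' @param n_vessels number of vessel tubes.
#' @param vessel_radius tube radius in mm.
#' @param bias_field_strength multiplicative bias-field amplitude (fraction).
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 72L),
                         spacing = c(2, 2, 2),
                         head_axes = NULL,
                         brain_axes = NULL,
                         tissue_intensities = list(
                           background = c(0, 0),
                           scalp = c(60, 3),
                           brain = c(100, 3),
                           tumor = c(200, 5),
                           vessel = c(200, 5)),
                         n_tumor_probs = c(0.90, 0.08, 0.02),
                         n_vessels = 6L,
                         vessel_radius = 2,
                         bias_field_strength = 0.2,
                         noise_sigma = 4) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  fov <- grid_shape * spacing
  if (is.null(head_axes)) head_axes <- 0.42 * fov
  if (is.null(brain_axes)) brain_axes <- 0.78 * head_axes
  if (!all(brain_axes < head_axes)) {
    stop("brain ellipsoid must lie strictly inside the head ellipsoid")
  }
  ti <- tissue_intensities
  if (ti$tumor[1] <= ti$brain[1]) {
    stop("tumor intensity must exceed brain intensity (contrast enhancement)")
  }
  if (abs(ti$vessel[1] - ti$tumor[1]) > 0.10 * ti$tumor[1]) {
    stop("vessel intensity must be within 10% of tumor intensity")
  }
  if (any(head_axes > fov / 2)) {
    stop("head ellipsoid does not fit inside the grid")
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 head_axes = head_axes, brain_axes = brain_axes,
                 tissue_intensities = ti, n_tumor_probs = n_tumor_probs,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius = vessel_radius,
                 bias_field_strength = bias_field_strength,
                 noise_sigma = noise_sigma),
            class = "phantom_spec")
}

# mm coordinates of voxel centres relative to the grid centre, per axis
.axis_mm <- function(n, sp) (seq_len(n) - (n + 1) / 2) * sp

# radius of an ellipsoid along unit direction u
.ellipsoid_radius <- function(axes, u) 1 / sqrt(sum((u / axes)^2))

#' Rasterize one phantom case
#'
#' Places tumors of the requested volumes extra-axially (centres in a shell
#' of thickness 20% of the brain semi-axis around the brain surface),
#' vessel tubes inside the brain, then applies the bias field and noise to
#' the image only; labels stay noise-free instance masks.
#'
#' @param spec a [phantom_spec()].
#' @param volumes_ml requested tumor volumes (ml), one per tumor.
#' @param case_id identifier string.
#' @param max_retries placement retries per tumor before failing.
#' @return a `phantom_case`: `image` and `labels` [volume_grid()]s plus
#'   per-tumor metadata.
#' @export
rasterize_case <- function(spec, volumes_ml, case_id = "case",
                           max_retries = 200L) {
  gs <- spec$grid_shape
  sp <- spec$spacing
  xs <- .axis_mm(gs[1], sp[1])
  ys <- .axis_mm(gs[2], sp[2])
  zs <- .axis_mm(gs[3], sp[3])
  ex <- function(axes) {
    outer(outer((xs / axes[1])^2, (ys / axes[2])^2, `+`),
          (zs / axes[3])^2, `+`)
  }
  head_m <- ex(spec$head_axes) <= 1
  brain_m <- ex(spec$brain_axes) <= 1

  ti <- spec$tissue_intensities
  img <- array(ti$background[1], dim = gs)
  img[head_m] <- ti$scalp[1]
  img[brain_m] <- ti$brain[1]
  tex <- array(0, dim = gs)
  if (ti$scalp[2] > 0) {
    tex[head_m & !brain_m] <- stats::rnorm(sum(head_m & !brain_m),
                                           0, ti$scalp[2])
  }
  if (ti$brain[2] > 0) {
    tex[brain_m] <- stats::rnorm(sum(brain_m), 0, ti$brain[2])
  }
  img <- img + tex

  # vessels: random-walk polyline tubes inside the brain (image only)
  if (spec$n_vessels > 0) {
    vr <- spec$vessel_radius
    for (v in seq_len(spec$n_vessels)) {
      pos <- spec$brain_axes * stats::runif(3, -0.3, 0.3)
      dirv <- stats::rnorm(3)
      dirv <- dirv / sqrt(sum(dirv^2))
      step <- min(sp) * 1.5
      for (s in seq_len(40L)) {
        dirv <- dirv + stats::rnorm(3, 0, 0.35)
        dirv <- dirv / sqrt(sum(dirv^2))
        cand <- pos + step * dirv
        if (sum((cand / (0.9 * spec$brain_axes))^2) > 1) {
          dirv <- -dirv
          next
        }
        pos <- cand
        ix <- which(abs(xs - pos[1]) <= vr)
        iy <- which(abs(ys - pos[2]) <= vr)
        iz <- which(abs(zs - pos[3]) <= vr)
        for (a in ix) for (b in iy) for (cc in iz) {
          if ((xs[a] - pos[1])^2 + (ys[b] - pos[2])^2 +
              (zs[cc] - pos[3])^2 <= vr^2) {
            img[a, b, cc] <- ti$vessel[1] +
              if (ti$vessel[2] > 0) stats::rnorm(1, 0, ti$vessel[2]) else 0
          }
        }
      }
    }
  }

  labels <- array(0L, dim = gs)
  tumors <- list()
  for (i in seq_along(volumes_ml)) {
    v <- volumes_ml[i]
    r0 <- (3 * v * 1000 / (4 * pi))^(1 / 3)  # equivalent-sphere radius, mm
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      ax <- stats::runif(3, 0.75, 1.3)
      ax <- r0 * ax / prod(ax)^(1 / 3)  # semi-axes with exact target volume
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      rb <- .ellipsoid_radius(spec$brain_axes, u)
      rh <- .ellipsoid_radius(spec$head_axes, u)
      # extra-axial placement: centre in a shell around the brain surface;
      # tumors too large for the shell shift inward along the placement
      # direction (large lesions indent the brain)
      crad <- min(rb * stats::runif(1, 0.9, 1.1),
                  max(0, rh - 1.05 * max(ax)))
      centre <- crad * u
      # tumor must fit inside the head along its principal directions
      ok <- TRUE
      for (d in 1:3) {
        for (sgn in c(-1, 1)) {
          pt <- centre
          pt[d] <- pt[d] + sgn * ax[d]
          if (sum((pt / spec$head_axes)^2) > 1) ok <- FALSE
        }
      }
      if (!ok) next
      m <- outer(outer(((xs - centre[1]) / ax[1])^2,
                       ((ys - centre[2]) / ax[2])^2, `+`),
                 ((zs - centre[3]) / ax[3])^2, `+`) <= 1
      if (!any(m)) next
      if (any(labels[m] != 0)) next  # overlap with an earlier instance
      labels[m] <- i
      img[m] <- ti$tumor[1] +
        if (ti$tumor[2] > 0) stats::rnorm(sum(m), 0, ti$tumor[2]) else 0
      cvox <- round(centre / sp + (gs + 1) / 2)
      tumors[[i]] <- list(center_voxel = as.integer(cvox),
                          semi_axes_mm = ax, volume_ml = v,
                          rasterized_ml = voxels_to_ml(sum(m), sp))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf("could not place tumor of %.2f ml after %d retries",
                   v, max_retries))
    }
  }

  if (spec$bias_field_strength > 0) {
    coarse <- array(stats::runif(4 * 4 * 4, -1, 1), dim = c(4, 4, 4, 1))
    field <- cpp_resize_tril(coarse, c(4L, 4L, 4L, 1L),
                             as.integer(c(gs, 1L)), FALSE)
    img <- img * (1 + spec$bias_field_strength * as.vector(field))
    dim(img) <- gs
  }
  if (spec$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
  }

  structure(list(image = volume_grid(img, sp),
                 labels = volume_grid(labels, sp, is_label = TRUE),
                 tumors = tumors, case_id = case_id),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s: %s voxels, %d tumor(s) [%s ml]\n",
              x$case_id, paste(dim(x$image$data), collapse = "x"),
              length(x$tumors),
              paste(sprintf("%.2f", vapply(x$tumors, `[[`, 0, "volume_ml")),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Draws tumor counts and volumes, rasterizes each case and (optionally)
#' writes NIfTI image/label pairs. Fully reproducible given `seed`.
#'
#' @param n_cases number of cases.
#' @param spec a [phantom_spec()].
#' @param dist a calibrated tumor volume distribution.
#' @param seed integer RNG seed.
#' @param out_dir if non-`NULL`, directory for `*_img.nii.gz` /
#'   `*_lab.nii.gz` files and `manifest.csv`.
#' @return list with `cases` (list of `phantom_case`; `NULL` entries when
#'   written to disk with `keep_cases = FALSE`) and `manifest` (data.frame).
#' @param keep_cases keep rasterized cases in memory.
#' @export
generate_cohort <- function(n_cases, spec = phantom_spec(),
                            dist = calibrate_volume_distribution(),
                            seed = 42L, out_dir = NULL, keep_cases = TRUE) {
  stopifnot(n_cases >= 1)
  set.seed(as.integer(seed))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  cases <- vector("list", n_cases)
  rows <- vector("list", n_cases)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_len(n_cases)) {
    set.seed(case_seeds[i])
    id <- sprintf("case%04d", i)
    nt <- sample.int(length(spec$n_tumor_probs), 1,
                     prob = spec$n_tumor_probs)
    vols <- sample_tumor_volume(dist, nt)
    cs <- rasterize_case(spec, vols, case_id = id)
    ip <- lp <- NA_character_
    if (!is.null(out_dir)) {
      ip <- file.path(out_dir, paste0(id, "_img.nii.gz"))
      lp <- file.path(out_dir, paste0(id, "_lab.nii.gz"))
      write_volume(cs$image, ip)
      write_volume(cs$labels, lp)
    }
    rows[[i]] <- data.frame(
      case_id = id, image_path = ip, label_path = lp, n_tumors = nt,
      tumor_volumes_ml = paste(sprintf("%.4f", vols), collapse = ";"),
      total_volume_ml = sum(vols), stringsAsFactors = FALSE)
    if (keep_cases) cases[[i]] <- cs
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(cases = cases, manifest = manifest)
}

#' Assign volume-balanced cross-validation folds
#'
#' Cases are sorted by total tumor volume and dealt serpentine-wise
#' (1..k, k..1, ...) so every fold sees a similar volume distribution.
#'
#' @param manifest cohort manifest with a `total_volume_ml` column.
#' @param k number of folds.
#' @return the manifest with an integer `fold` column (1-based).
#' @export
assign_folds <- function(manifest, k = 5L) {
  k <- as.integer(k)
  n <- nrow(manifest)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds than cases")
  ord <- order(manifest$total_volume_ml, decreasing = TRUE)
  cycle <- c(seq_len(k), rev(seq_len(k)))
  fold <- integer(n)
  fold[ord] <- cycle[(seq_len(n) - 1L) %% (2L * k) + 1L]
  manifest$fold <- fold
  manifest
}
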