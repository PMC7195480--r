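#' Titration design concentrations
#'
#' The 13 free-calcium concentrations (uM) of the in-situ N2a titration
#' used to calibrate the mitochondrial cameleon sensor.
#'
#' @export
titration_concentrations_um <- c(0, 0.2, 0.575, 1, 2, 5.7, 10, 20, 53, 100,
                                 200, 500, 1000)

#' Generate a synthetic titration table
#'
#' Forward-models YFP/CFP ratios at known free calcium concentrations from a
#' calibration curve, optionally perturbed by multiplicative Gaussian noise
#' (`ratio * (1 + cv * N(0,1))`).
#'
#' @param curve Generating [calibration_curve()].
#' @param conc_um Non-negative increasing concentrations in uM; defaults to
#'   the 13-point titration design.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0 = noise-free).
#' @param seed Optional integer seed.
#' @return Tibble `free_ca_um`, `ratio` with the generating curve attached as
#'   attribute `"truth"`.
#' @export
generate_titration <- function(curve = default_calibration(),
                               conc_um = titration_concentrations_um,
                               noise_cv = 0, seed = NULL) {
  if (any(conc_um < 0) || any(diff(conc_um) <= 0))
    abort("`conc_um` must be non-negative and strictly increasing.")
  r <- ca_to_ratio(conc_um * 1000, curve)
  r <- local_seed(seed, r * (1 + noise_cv * rnorm(length(r))))
  out <- tibble(free_ca_um = conc_um, ratio = r)
  attr(out, "truth") <- curve
  out
}

# Rasterize an axis-aligned ellipsoid into a logical array: voxel centers
# inside (z-c)^2/az^2 + ... <= 1. Returns linear indices.
ellipsoid_voxels <- function(center_um, semi_um, dims, vs) {
  lo <- pmax(1L, floor((center_um - semi_um) / vs - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center_um + semi_um) / vs + 0.5))
  if (any(lo > hi)) return(integer(0))
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  g <- expand.grid(z = zz, y = yy, x = xx)
  inside <- ((g$z - 0.5) * vs[1] - center_um[1])^2 / semi_um[1]^2 +
            ((g$y - 0.5) * vs[2] - center_um[2])^2 / semi_um[2]^2 +
            ((g$x - 0.5) * vs[3] - center_um[3])^2 / semi_um[3]^2 <= 1
  g <- g[inside, , drop = FALSE]
  g$z + (g$y - 1L) * dims[1] + (g$x - 1L) * dims[1] * dims[2]
}

#' Generate a synthetic two-channel z-stack with ground truth
#'
#' Emulates an in-vivo multiphoton acquisition of mitochondria expressing a
#' ratiometric cameleon sensor. Ellipsoidal objects (small elongated neuritic
#' mitochondria and larger somatic clusters) are placed without overlap; each
#' object's per-voxel intensities encode its true YFP/CFP ratio exactly via
#' the forward model `CFP = I / (1 + R)`, `YFP = I * R / (1 + R)`.
#' Slice-wise background offsets are added to both channels, then Poisson
#' shot noise and Gaussian read noise. Spherical plaques, when requested, are
#' rendered into the `RED` channel.
#'
#' The defaults emulate the wild-type study conditions: object ratios drawn
#' from N(0.67, 0.16^2) truncated to the sensor's dynamic range, per-voxel
#' signal ~150 counts over a background of ~10 counts, 0.5 um lateral and
#' 1 um axial sampling.
#'
#' @param n_objects Number of mitochondria (default 50).
#' @param dims Stack dimensions `(nz, ny, nx)` (default `c(16, 256, 256)`).
#' @param voxel_size `(dz, dy, dx)` in um (default `c(1, 0.5, 0.5)`).
#' @param ratio_mean,ratio_sd Mean and SD of the true object ratios
#'   (default 0.67, 0.16), realized as a shifted lognormal bounded below by
#'   the sensor floor `r_min + 0.02` (see Details).
#' @param ratios Optional explicit vector of true ratios (length
#'   `n_objects`), overriding the normal draw.
#' @param frac_soma Fraction of objects generated as large somatic clusters
#'   (default 0.2); the rest are small elongated neuritic mitochondria.
#' @param intensity Mean per-voxel total signal (CFP+YFP) in counts
#'   (default 150).
#' @param intensity_cv Lognormal coefficient of variation of per-object
#'   intensity (default 0.2).
#' @param background Per-slice additive offset for CFP and YFP: scalar,
#'   length-`nz` vector, or function of z index (default 10).
#' @param poisson Apply Poisson shot noise (default TRUE).
#' @param read_sd Gaussian read noise SD in counts (default 2).
#' @param plaques Optional tibble of spherical plaques with columns
#'   `center_z_um`, `center_y_um`, `center_x_um`, `radius_um`.
#' @param plaque_intensity RED-channel intensity inside plaques (default 100).
#' @param min_separation_um Minimum distance between object centers
#'   (default 8).
#' @param curve Calibration curve bounding the ratio truncation.
#' @param seed Optional integer seed; the output is a pure function of the
#'   arguments and this seed.
#' @return List with `stack` (an [image_stack()]) and `truth` (object table
#'   with geometry, compartment, true ratio and concentration; truth label
#'   volume; plaque table; per-slice background offsets; the seed).
#' @export
generate_stack <- function(n_objects = 50, dims = c(16, 256, 256),
                           voxel_size = c(1, 0.5, 0.5),
                           ratio_mean = 0.67, ratio_sd = 0.16, ratios = NULL,
                           frac_soma = 0.2, intensity = 150,
                           intensity_cv = 0.2, background = 10,
                           poisson = TRUE, read_sd = 2, plaques = NULL,
                           plaque_intensity = 100, min_separation_um = 8,
                           curve = default_calibration(), seed = NULL) {
  local_seed(seed, {
    vs <- as.numeric(voxel_size)
    dims <- as.integer(dims)
    field_um <- dims * vs

    # True ratios follow a shifted lognormal above the sensor floor: real
    # ratio histograms are bounded below near r_min and right-skewed, and a
    # normal truncated at the floor would inflate the realized mean. The
    # lognormal is parameterized so the realized mean and sd equal
    # `ratio_mean` and `ratio_sd`.
    if (is.null(ratios)) {
      lo <- curve$r_min + 0.02
      hi <- curve$r_max - 0.02
      m <- ratio_mean - lo
      if (m <= 0)
        abort("`ratio_mean` must exceed the sensor floor (r_min + 0.02).")
      sigma2 <- log(1 + (ratio_sd / m)^2)
      mu <- log(m) - sigma2 / 2
      ratios <- lo + stats::rlnorm(n_objects, mu, sqrt(sigma2))
      while (any(ratios > hi)) {
        bad <- ratios > hi
        ratios[bad] <- lo + stats::rlnorm(sum(bad), mu, sqrt(sigma2))
      }
    } else if (length(ratios) != n_objects) {
      abort("`ratios` must have length `n_objects`.")
    }

    # geometry: somatic clusters vs elongated neuritic mitochondria.
    # Each object is re-drawn until its rasterization holds at least
    # `min_voxels` voxel centers, so every ground-truth object actually
    # exists in the rendered image (sub-voxel ellipsoids are a raster
    # artifact, not an object).
    min_voxels <- max(1L, ceiling(1.25 / prod(vs)))
    is_soma <- seq_len(n_objects) <= round(frac_soma * n_objects)
    semi <- matrix(0, n_objects, 3)
    centers <- matrix(NA_real_, n_objects, 3)
    vox_list <- vector("list", n_objects)
    max_margin <- 2.5 + 1  # largest possible semi-axis + clearance
    tries <- 0L
    for (i in seq_len(n_objects)) {
      repeat {
        tries <- tries + 1L
        if (tries > 50000L)
          abort("Could not place objects without overlap; reduce n_objects.",
                class = "mitofret_generator_error")
        s <- if (is_soma[i]) runif(3, 1.5, 2.5)
             else c(runif(1, 0.4, 0.6), runif(1, 0.3, 0.5),
                    runif(1, 1.0, 2.0))
        cand <- runif(3, pmin(max_margin, field_um / 2),
                      pmax(field_um - max_margin, field_um / 2))
        if (i > 1) {
          d <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) -
                               cand)^2))
          if (min(d) < min_separation_um) next
        }
        vox <- ellipsoid_voxels(cand, s, dims, vs)
        if (length(vox) < min_voxels) next
        semi[i, ] <- s
        centers[i, ] <- cand
        vox_list[[i]] <- vox
        break
      }
    }

    obj_int <- intensity * exp(rnorm(n_objects, 0, intensity_cv) -
                                 intensity_cv^2 / 2)

    cfp <- array(0, dims)
    yfp <- array(0, dims)
    truth_labels <- array(0L, dims)
    vox_count <- integer(n_objects)
    for (i in seq_len(n_objects)) {
      vox <- vox_list[[i]]
      vox_count[i] <- length(vox)
      truth_labels[vox] <- i
      cfp[vox] <- obj_int[i] / (1 + ratios[i])
      yfp[vox] <- obj_int[i] * ratios[i] / (1 + ratios[i])
    }

    # slice-wise background offsets
    bg <- if (is.function(background)) background(seq_len(dims[1]))
          else rep(background, length.out = dims[1])
    for (z in seq_len(dims[1])) {
      cfp[z, , ] <- cfp[z, , ] + bg[z]
      yfp[z, , ] <- yfp[z, , ] + bg[z]
    }

    # plaque (RED) channel
    red <- array(0, dims)
    plq <- tibble(plaque_id = integer(), center_z_um = numeric(),
                  center_y_um = numeric(), center_x_um = numeric(),
                  radius_um = numeric())
    if (!is.null(plaques) && nrow(plaques) > 0) {
      for (k in seq_len(nrow(plaques))) {
        ctr <- c(plaques$center_z_um[k], plaques$center_y_um[k],
                 plaques$center_x_um[k])
        vox <- ellipsoid_voxels(ctr, rep(plaques$radius_um[k], 3), dims, vs)
        red[vox] <- plaque_intensity
      }
      plq <- dplyr::mutate(plaques, plaque_id = dplyr::row_number(),
                           .before = 1)
    }

    add_noise <- function(a) {
      if (poisson) a[] <- rpois(length(a), lambda = a)
      if (read_sd > 0) a[] <- pmax(a + rnorm(length(a), 0, read_sd), 0)
      a
    }
    cfp <- add_noise(cfp)
    yfp <- add_noise(yfp)
    red <- add_noise(red)

    stack <- image_stack(list(CFP = cfp, YFP = yfp, RED = red), vs,
                         metadata = list(synthetic = TRUE, seed = seed))
    truth <- list(
      objects = tibble(
        object_id = seq_len(n_objects),
        center_z_um = centers[, 1], center_y_um = centers[, 2],
        center_x_um = centers[, 3],
        semi_z_um = semi[, 1], semi_y_um = semi[, 2], semi_x_um = semi[, 3],
        compartment = ifelse(is_soma, "soma", "neurite"),
        true_ratio = ratios,
        true_ca_nm = ratio_to_ca(ratios, curve),
        intensity = obj_int,
        voxel_count = vox_count
      ),
      labels = label_volume(truth_labels, vs),
      plaques = plq,
      background = tibble(z = seq_len(dims[1]), offset = bg),
      noise = list(poisson = poisson, read_sd = read_sd),
      seed = seed
    )
    list(stack = stack, truth = truth)
  })
}

#' Generate a hierarchical object-level cohort
#'
#' Draws per-mitochondrion YFP/CFP ratios for a mice -> volumes -> objects
#' hierarchy. Each group is described by a mixture of normals on the object
#' ratio plus a normal mouse-level random intercept. The default two-group
#' design echoes the study's printed anchors: a wild-type-like group with
#' object ratios N(0.67, 0.16^2) (volume-mean ratio 0.67, ~2.3% of objects
#' above 0.99) and a transgenic-like group mixing 96% N(0.71, 0.13^2) with a
#' 4% high-calcium component N(1.25, 0.10^2) (volume mean ~0.73, ~5.5%
#' overload). These are generator settings for synthetic demonstrations, not
#' claims of reproducing animal data.
#'
#' @param groups Named list; each element is a list with `n_mice`,
#'   `n_volumes` (per mouse), `n_objects` (per volume), `means`, `sds`,
#'   `weights` (mixture components on the object ratio) and `sd_mouse`
#'   (random-intercept SD).
#' @param seed Optional integer seed.
#' @return Tibble `group`, `mouse_id`, `volume_id`, `object_id`, `ratio`,
#'   with the generator parameters attached as attribute `"truth"`.
#' @export
generate_cohort <- function(groups = cohort_defaults(), seed = NULL) {
  local_seed(seed, {
    out <- purrr::imap_dfr(groups, function(gs, gname) {
      purrr::map_dfr(seq_len(gs$n_mice), function(m) {
        mouse_id <- sprintf("%s_m%02d", gname, m)
        shift <- rnorm(1, 0, gs$sd_mouse)
        purrr::map_dfr(seq_len(gs$n_volumes), function(v) {
          n <- gs$n_objects
          comp <- sample.int(length(gs$weights), n, replace = TRUE,
                             prob = gs$weights)
          tibble(
            group = gname,
            mouse_id = mouse_id,
            volume_id = sprintf("%s_v%02d", mouse_id, v),
            object_id = seq_len(n),
            ratio = rnorm(n, gs$means[comp] + shift, gs$sds[comp])
          )
        })
      })
    })
    attr(out, "truth") <- groups
    out
  })
}

#' @rdname generate_cohort
#' @export
cohort_defaults <- function() {
  list(
    Wt = list(n_mice = 11, n_volumes = 9, n_objects = 150,
              means = 0.67, sds = 0.16, weights = 1, sd_mouse = 0.03),
    Tg = list(n_mice = 7, n_volumes = 10, n_objects = 150,
              means = c(0.71, 1.25), sds = c(0.13, 0.10),
              weights = c(0.96, 0.04), sd_mouse = 0.03)
  )
}

#' Generate synthetic fluorescence time courses
#'
#' Seeded traces emulating the study's in-vitro and topical-application
#' recordings: a depolarization-like step (`"step"`, fast saturating rise
#' after onset), a conditioned-media-like slow rise (`"slow_rise"`), or an
#' exponential decay (`"decay"`, e.g. a mitochondrial membrane-potential dye
#' after an insult).
#'
#' @param type Trace shape.
#' @param n_points Number of samples (default 60).
#' @param dt Sampling interval (time units of your choice; default 1).
#' @param baseline Pre-treatment level (default 0.7).
#' @param amplitude Relative amplitude of the response: the step/rise
#'   plateaus at `baseline * (1 + amplitude)` (default 0.3); ignored for
#'   decays.
#' @param onset Index of treatment onset (default 11; samples before it sit
#'   at baseline).
#' @param rate Kinetic rate constant per time unit (step/rise time constant,
#'   or decay rate; default 0.5 for `"step"`, 0.05 for `"slow_rise"` and
#'   `"decay"`).
#' @param noise_sd Additive Gaussian noise SD (default 0).
#' @param seed Optional integer seed.
#' @return Tibble `time`, `value` with attribute `"truth"` (the arguments).
#' @export
generate_timelapse <- function(type = c("step", "slow_rise", "decay"),
                               n_points = 60, dt = 1, baseline = 0.7,
                               amplitude = 0.3, onset = 11, rate = NULL,
                               noise_sd = 0, seed = NULL) {
  type <- match.arg(type)
  if (is.null(rate)) rate <- if (type == "step") 0.5 else 0.05
  t <- (seq_len(n_points) - 1) * dt
  v <- switch(type,
    step = ,
    slow_rise = {
      resp <- pmax(t - t[onset], 0)
      baseline * (1 + amplitude * (1 - exp(-rate * resp)))
    },
    decay = baseline * exp(-rate * t)
  )
  v <- local_seed(seed, v + rnorm(n_points, 0, noise_sd))
  out <- tibble(time = t, value = v)
  attr(out, "truth") <- list(type = type, baseline = baseline,
                             amplitude = amplitude, onset = onset,
                             rate = rate, noise_sd = noise_sd, seed = seed)
  out
}

#' Generate paired longitudinal sessions with rule-driven disappearance
#'
#' Creates a baseline session of soma-scale objects with known centroids and
#' ratios, then a follow-up session in which objects disappear according to
#' a ratio rule (by default, every object with baseline ratio above `cut`
#' disappears and no other object does) and surviving centroids are jittered.
#'
#' @param n Number of baseline objects (default 40).
#' @param field_um Cubic field side in um (default 200).
#' @param ratio_mean,ratio_sd Baseline ratio distribution (default
#'   N(0.9, 0.25^2) truncated to the packaged curve's range) -- a neuronal
#'   population in which a small fraction sits above the death-associated
#'   ratio.
#' @param ratios Optional explicit baseline ratios (length `n`).
#' @param cut Disappearance ratio cut (default 1.4). `Inf` disables
#'   disappearance.
#' @param p_disappear_above,p_disappear_below Disappearance probabilities
#'   above/below the cut (defaults 1 and 0: the deterministic rule).
#' @param jitter_um SD of the centroid jitter between sessions (default 1).
#' @param min_separation_um Minimum distance between baseline centroids
#'   (default 15, soma scale).
#' @param seed Optional integer seed.
#' @return List `baseline`, `followup` (object tables usable by
#'   [match_sessions()]) and `truth` (per-object disappearance flags and the
#'   true correspondence).
#' @export
generate_longitudinal <- function(n = 40, field_um = 200, ratio_mean = 0.9,
                                  ratio_sd = 0.25, ratios = NULL, cut = 1.4,
                                  p_disappear_above = 1,
                                  p_disappear_below = 0, jitter_um = 1,
                                  min_separation_um = 15, seed = NULL) {
  local_seed(seed, {
    curve <- default_calibration()
    if (is.null(ratios)) {
      ratios <- rnorm(n, ratio_mean, ratio_sd)
      lo <- curve$r_min + 0.02
      hi <- curve$r_max - 0.02
      while (any(ratios < lo | ratios > hi)) {
        bad <- ratios < lo | ratios > hi
        ratios[bad] <- rnorm(sum(bad), ratio_mean, ratio_sd)
      }
    }
    centers <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 50000L)
        abort("Could not place objects; reduce n or min_separation_um.",
              class = "mitofret_generator_error")
      cand <- runif(3, 0, field_um)
      if (placed > 0) {
        d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                             cand)^2))
        if (min(d) < min_separation_um) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    baseline <- tibble(
      object_id = seq_len(n),
      centroid_z_um = centers[, 1],
      centroid_y_um = centers[, 2],
      centroid_x_um = centers[, 3],
      ratio = ratios
    )
    p_dis <- ifelse(ratios > cut, p_disappear_above, p_disappear_below)
    disappeared <- runif(n) < p_dis
    surv <- which(!disappeared)
    followup <- tibble(
      object_id = seq_along(surv),
      centroid_z_um = centers[surv, 1] + rnorm(length(surv), 0, jitter_um),
      centroid_y_um = centers[surv, 2] + rnorm(length(surv), 0, jitter_um),
      centroid_x_um = centers[surv, 3] + rnorm(length(surv), 0, jitter_um),
      ratio = ratios[surv]
    )
    # shuffle follow-up ordering so matching cannot rely on indices
    perm <- sample.int(nrow(followup))
    followup <- followup[perm, ]
    followup$object_id <- seq_len(nrow(followup))
    truth_map <- tibble(
      baseline_id = seq_len(n),
      disappeared = disappeared,
      followup_id = NA_integer_
    )
    truth_map$followup_id[surv[perm]] <- seq_len(nrow(followup))
    list(baseline = baseline, followup = followup,
         truth = list(map = truth_map, cut = cut, seed = seed))
  })
}

#' Score a segmentation against ground-truth labels
#'
#' Matches every ground-truth object to the segmented label with the largest
#' voxel overlap and reports recall, per-object intersection-over-union and
#' centroid error.
#'
#' @param labels Segmented [label_volume()].
#' @param truth_labels Ground-truth [label_volume()] (e.g.
#'   `generate_stack()$truth$labels`).
#' @return Tibble with one row per true object: `true_id`, `matched_label`
#'   (`NA` if undetected), `iou`, `centroid_error_um`, `detected`.
#' @export
evaluate_segmentation <- function(labels, truth_labels) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(truth_labels, "label_volume"))
  tl <- truth_labels$labels
  sl <- labels$labels
  vs <- labels$voxel_size
  dims <- dim(tl)
  centroid_um <- function(arr, k) {
    co <- arrayInd(which(arr == k), dims)
    c(mean((co[, 1] - 0.5) * vs[1]), mean((co[, 2] - 0.5) * vs[2]),
      mean((co[, 3] - 0.5) * vs[3]))
  }
  purrr::map_dfr(seq_len(truth_labels$object_count), function(k) {
    tv <- which(tl == k)
    ov <- sl[tv]
    ov <- ov[ov > 0]
    if (length(ov) == 0)
      return(tibble(true_id = k, matched_label = NA_integer_, iou = 0,
                    centroid_error_um = NA_real_, detected = FALSE))
    best <- as.integer(names(which.max(table(ov))))
    sv <- which(sl == best)
    iou <- length(intersect(tv, sv)) / length(union(tv, sv))
    ce <- sqrt(sum((centroid_um(tl, k) - centroid_um(sl, best))^2))
    tibble(true_id = k, matched_label = best, iou = iou,
           centroid_error_um = ce, detected = TRUE)
  })
}
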