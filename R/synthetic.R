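# Synthetic foliar-lesion image generator. Images are green-dominant
# textured backgrounds with class-parameterized elliptical lesions (solid or
# ring, with angular boundary roughness). The generator reproduces the
# statistical structure relevant to federated experiments - multiple
# visually distinct classes, configurable class imbalance, per-client sensor
# heterogeneity, label-skewed partitions - not botanical realism.

#' Named class-imbalance profiles
#'
#' Per-class sampling ratios matching the printed category distributions of
#' three public tomato-disease collections, plus a uniform profile. When
#' `num_classes` is smaller than the profile length, the `num_classes`
#' largest ratios are kept and renormalized (preserving the dominance
#' structure of the original distribution).
#'
#' @param name One of `"ccmt"`, `"taiwan"`, `"plantvillage"`, `"uniform"`.
#' @param num_classes Required for `"uniform"`; optional truncation for the
#'   named profiles.
#' @return Named numeric vector of ratios summing to 1.
#' @export
imbalance_profile <- function(name, num_classes = NULL) {
  profiles <- list(
    ccmt = c("Healthy" = 9.20, "Leaf blight" = 23.94, "Leaf curl" = 9.53,
             "Septoria leaf spot" = 43.11, "Verticillium wilt" = 14.22),
    taiwan = c("Bacterial spot" = 17.68, "Black leaf mold" = 10.77,
               "Gray leaf spot" = 13.50, "Healthy" = 17.04,
               "Late blight" = 15.76, "Powdery mildew" = 25.24),
    plantvillage = c("Bacterial spot" = 11.71, "Early blight" = 5.51,
                     "Late blight" = 10.51, "Leaf Mold" = 5.24,
                     "Septoria leaf spot" = 9.75, "Spider mites" = 9.23,
                     "Target Spot" = 7.73, "Yellow Leaf Curl Virus" = 29.50,
                     "Tomato mosaic virus" = 2.05, "Healthy" = 8.76))
  if (identical(name, "uniform")) {
    if (is.null(num_classes)) stop("uniform profile needs num_classes")
    return(stats::setNames(rep(1 / num_classes, num_classes),
                           paste0("class", seq_len(num_classes))))
  }
  if (!name %in% names(profiles)) stop("unknown imbalance profile: ", name)
  p <- profiles[[name]]
  if (!is.null(num_classes) && num_classes < length(p))
    p <- sort(p, decreasing = TRUE)[seq_len(num_classes)]
  p / sum(p)
}

#' Default lesion phenotypes
#'
#' Supplies up to ten pairwise-distinct phenotype parameter sets: lesion
#' count range, radius range (pixels), RGB color mean and jitter, ring vs
#' solid shape, and boundary roughness.
#'
#' @param num_classes Number of classes (<= 10).
#' @return List of phenotype lists.
#' @export
default_lesion_phenotypes <- function(num_classes) {
  base <- list(
    list(n_lesions = c(4L, 8L), radius = c(1.5, 3),
         color = c(0.52, 0.33, 0.10), color_sd = 0.03, ring = FALSE,
         roughness = 0.3),
    list(n_lesions = c(2L, 4L), radius = c(5, 8),
         color = c(0.08, 0.07, 0.06), color_sd = 0.02, ring = TRUE,
         roughness = 0.5),
    list(n_lesions = c(1L, 2L), radius = c(6, 10),
         color = c(0.75, 0.70, 0.25), color_sd = 0.04, ring = FALSE,
         roughness = 0.7),
    list(n_lesions = c(4L, 8L), radius = c(1.5, 3),
         color = c(0.55, 0.55, 0.50), color_sd = 0.03, ring = FALSE,
         roughness = 0.2),
    list(n_lesions = c(2L, 4L), radius = c(3, 6),
         color = c(0.35, 0.12, 0.10), color_sd = 0.04, ring = TRUE,
         roughness = 0.3),
    list(n_lesions = c(1L, 2L), radius = c(5, 9),
         color = c(0.60, 0.45, 0.15), color_sd = 0.05, ring = TRUE,
         roughness = 0.6),
    list(n_lesions = c(5L, 9L), radius = c(1.5, 2.5),
         color = c(0.20, 0.20, 0.20), color_sd = 0.02, ring = FALSE,
         roughness = 0.4),
    list(n_lesions = c(2L, 3L), radius = c(4, 8),
         color = c(0.80, 0.80, 0.75), color_sd = 0.03, ring = FALSE,
         roughness = 0.5),
    list(n_lesions = c(1L, 3L), radius = c(3, 5),
         color = c(0.50, 0.35, 0.40), color_sd = 0.04, ring = TRUE,
         roughness = 0.2),
    list(n_lesions = c(3L, 5L), radius = c(2, 5),
         color = c(0.65, 0.55, 0.05), color_sd = 0.04, ring = FALSE,
         roughness = 0.6))
  if (num_classes > length(base))
    stop("default phenotypes cover at most ", length(base), " classes")
  base[seq_len(num_classes)]
}

#' Synthetic dataset specification
#'
#' @param num_classes Number of lesion classes.
#' @param image_size Spatial size (scalar or `c(H, W)`); default 32.
#' @param n_total Total sample count, distributed over classes by
#'   `imbalance` (largest-remainder rounding, at least 1 per class).
#' @param counts Explicit per-class counts (overrides `n_total`).
#' @param imbalance Profile name for [imbalance_profile()] or a numeric
#'   ratio vector of length `num_classes`.
#' @param phenotypes List of per-class phenotype lists; defaults to
#'   [default_lesion_phenotypes()].
#' @param background List with `base_color` (RGB), `texture_sd` (coarse blob
#'   contrast), `noise_sd` (fine per-pixel texture).
#' @param seed Integer seed; generation is a deterministic function of the
#'   spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(num_classes = 3L, image_size = 32L,
                           n_total = 150L, counts = NULL,
                           imbalance = "uniform", phenotypes = NULL,
                           background = list(base_color = c(0.20, 0.50, 0.16),
                                             texture_sd = 0.05,
                                             noise_sd = 0.02),
                           seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(as.integer(image_size), 2L)
  if (is.null(counts)) {
    ratios <- if (is.character(imbalance))
      imbalance_profile(imbalance, num_classes)
    else imbalance / sum(imbalance)
    if (length(ratios) != num_classes)
      stop("imbalance ratios must have one entry per class")
    raw <- n_total * ratios
    counts <- floor(raw)
    rem <- n_total - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    counts <- pmax(1L, as.integer(counts))
  }
  stopifnot(length(counts) == num_classes, all(counts >= 1))
  if (is.null(phenotypes)) phenotypes <- default_lesion_phenotypes(num_classes)
  stopifnot(length(phenotypes) == num_classes)
  max_r <- max(vapply(phenotypes, function(p) max(p$radius), numeric(1)))
  if (2 * max_r + 2 > min(image_size))
    stop("image too small for max lesion radius ", max_r)
  structure(list(num_classes = as.integer(num_classes),
                 image_size = image_size, counts = as.integer(counts),
                 phenotypes = phenotypes, background = background,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Bilinear resize of a single matrix to (H2, W2).
resize_bilinear <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  ri <- if (H2 == 1) rep(1, 1) else seq(1, H, length.out = H2)
  ci <- if (W2 == 1) rep(1, 1) else seq(1, W, length.out = W2)
  r0 <- pmin(floor(ri), H - 1L); r0[H == 1] <- 1L
  c0 <- pmin(floor(ci), W - 1L); c0[W == 1] <- 1L
  if (H == 1) { r0 <- rep(1L, H2); fr <- rep(0, H2) } else fr <- ri - r0
  if (W == 1) { c0 <- rep(1L, W2); fc <- rep(0, W2) } else fc <- ci - c0
  r1 <- pmin(r0 + 1L, H); c1 <- pmin(c0 + 1L, W)
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  cc <- m[r1, c0, drop = FALSE]; d <- m[r1, c1, drop = FALSE]
  fr <- matrix(fr, H2, W2); fc <- matrix(fc, H2, W2, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * (1 - fr) * fc + cc * fr * (1 - fc) +
    d * fr * fc
}

render_lesion_image <- function(H, W, phen, bg) {
  img <- array(0, dim = c(H, W, 3))
  base <- clamp01(bg$base_color + stats::rnorm(3, sd = 0.02))
  for (ch in 1:3) {
    coarse <- matrix(stats::rnorm(16, sd = bg$texture_sd), 4, 4)
    img[, , ch] <- base[ch] + resize_bilinear(coarse, H, W) +
      stats::rnorm(H * W, sd = bg$noise_sd)
  }
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  n_les <- sample(seq(phen$n_lesions[1], phen$n_lesions[2]), 1)
  for (l in seq_len(n_les)) {
    rx <- stats::runif(1, phen$radius[1], phen$radius[2])
    ry <- rx * stats::runif(1, 0.7, 1.3)
    margin <- max(rx, ry) + 1
    cx <- stats::runif(1, margin, W - margin)
    cy <- stats::runif(1, margin, H - margin)
    th <- stats::runif(1, 0, pi)
    dx <- X - cx; dy <- Y - cy
    u <- (dx * cos(th) + dy * sin(th)) / rx
    v <- (-dx * sin(th) + dy * cos(th)) / ry
    ang <- atan2(dy, dx)
    f <- sample(2:5, 2); ph <- stats::runif(2, 0, 2 * pi)
    wob <- 1 + phen$roughness * 0.25 *
      (sin(f[1] * ang + ph[1]) + 0.6 * sin(f[2] * ang + ph[2])) / 1.6
    dd <- sqrt(u^2 + v^2) / wob
    edge <- 1.5 / max(min(rx, ry), 1)
    alpha <- if (isTRUE(phen$ring))
      clamp01((0.18 - abs(dd - 0.85)) / edge)
    else clamp01((1 - dd) / edge)
    col <- clamp01(phen$color + stats::rnorm(3, sd = phen$color_sd))
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - alpha) + col[ch] * alpha
  }
  clamp01(img)
}

#' Generate a labeled synthetic lesion dataset
#'
#' Renders `sum(spec$counts)` images; class `j` (label `j - 1`) gets
#' `spec$counts[j]` images with phenotype `spec$phenotypes[[j]]`. Bitwise
#' reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `images` (array `(n, H, W, 3)` in `[0, 1]`), `labels`
#'   (integer vector in `0 .. num_classes - 1`), and `manifest` (data frame
#'   with `path`, `label`, `client_id`).
#' @export
generate_lesion_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  n <- sum(spec$counts)
  images <- array(0, dim = c(n, H, W, 3))
  labels <- integer(n)
  paths <- character(n)
  with_seed(spec$seed, {
    i <- 0L
    for (cl in seq_len(spec$num_classes)) {
      for (r in seq_len(spec$counts[cl])) {
        i <- i + 1L
        images[i, , , ] <- render_lesion_image(H, W, spec$phenotypes[[cl]],
                                               spec$background)
        labels[i] <- cl - 1L
        paths[i] <- sprintf("class_%d/img_%05d.png", cl - 1L, r)
      }
    }
  })
  list(images = images, labels = labels,
       manifest = data.frame(path = paths, label = labels,
                             client_id = NA_integer_,
                             stringsAsFactors = FALSE))
}

#' Sensor model
#'
#' @param scale Resolution scale factor (> 0); values below 1 emulate a
#'   lower-resolution camera (downsample then upsample back).
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param gain Per-channel color gain (length 1 or 3).
#' @param gamma Illumination gamma applied as `x^gamma`.
#' @return Object of class `sensor_model`.
#' @export
sensor_model <- function(scale = 1, noise_sd = 0, gain = 1, gamma = 1) {
  stopifnot(scale > 0, noise_sd >= 0, all(gain > 0), gamma > 0)
  if (length(gain) == 1) gain <- rep(gain, 3)
  structure(list(scale = scale, noise_sd = noise_sd, gain = gain,
                 gamma = gamma), class = "sensor_model")
}

#' Apply a sensor model to images
#'
#' Applies, in fixed order: resolution rescaling, additive Gaussian noise,
#' per-channel gain, and gamma; pixel values are clamped to `[0, 1]`.
#' The identity sensor leaves images bitwise unchanged.
#'
#' @param images Array `(n, H, W, 3)`.
#' @param sensor A [sensor_model()].
#' @param seed Seed for the noise draw.
#' @return Transformed image array, same shape.
#' @export
apply_sensor_model <- function(images, sensor, seed = 1L) {
  stopifnot(inherits(sensor, "sensor_model"))
  d <- dim(images)
  out <- images
  if (sensor$scale != 1) {
    H2 <- max(2L, round(d[2] * sensor$scale))
    W2 <- max(2L, round(d[3] * sensor$scale))
    for (i in seq_len(d[1]))
      for (ch in 1:3)
        out[i, , , ch] <- resize_bilinear(
          resize_bilinear(out[i, , , ch], H2, W2), d[2], d[3])
  }
  if (sensor$noise_sd > 0)
    out <- out + with_seed(derive_seed(seed, 4201L),
                           array(stats::rnorm(prod(d), sd = sensor$noise_sd),
                                 dim = d))
  if (any(sensor$gain != 1))
    out <- out * rep(sensor$gain, each = prod(d[1:3]))
  out <- clamp01(out)
  if (sensor$gamma != 1) out <- out^sensor$gamma
  clamp01(out)
}

#' Heterogeneous per-client sensor models
#'
#' A deterministic family of distinct sensors emulating acquisition
#' heterogeneity across clients (resolution, noise level, color balance,
#' illumination).
#'
#' @param K Number of clients.
#' @return List of `K` [sensor_model()] objects.
#' @export
client_sensor_models <- function(K) {
  base <- list(
    sensor_model(scale = 1, noise_sd = 0.01, gain = c(1, 1, 1), gamma = 1),
    sensor_model(scale = 0.5, noise_sd = 0.03, gain = c(1.05, 0.95, 1),
                 gamma = 0.9),
    sensor_model(scale = 0.75, noise_sd = 0.02, gain = c(0.95, 1.05, 1.05),
                 gamma = 1.15),
    sensor_model(scale = 1, noise_sd = 0.05, gain = c(1.1, 1, 0.9),
                 gamma = 1),
    sensor_model(scale = 0.6, noise_sd = 0.01, gain = c(1, 1.1, 0.95),
                 gamma = 0.8))
  lapply(seq_len(K), function(k) base[[(k - 1L) %% length(base) + 1L]])
}

#' Client partition specification
#'
#' @param num_clients Number of clients K.
#' @param mode `"iid"` (shuffled round-robin) or `"dirichlet"` (per-class
#'   client proportions drawn from `Dirichlet(alpha * 1_K)`).
#' @param dirichlet_alpha Concentration parameter (> 0); small values give
#'   strong label skew.
#' @param seed Integer seed.
#' @return Object of class `partition_spec`.
#' @export
partition_spec <- function(num_clients, mode = c("iid", "dirichlet"),
                           dirichlet_alpha = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(num_clients >= 1, dirichlet_alpha > 0)
  structure(list(num_clients = as.integer(num_clients), mode = mode,
                 dirichlet_alpha = dirichlet_alpha, seed = as.integer(seed)),
            class = "partition_spec")
}

#' Partition samples into client shards
#'
#' Returns disjoint index sets whose union covers the dataset. In
#' `"dirichlet"` mode each class's samples are split according to
#' proportions drawn from `Dirichlet(alpha * 1_K)` (largest-remainder
#' rounding); a client left empty receives one sample from the largest
#' shard.
#'
#' @param labels Label vector (any coding); length must be >= K.
#' @param spec A [partition_spec()].
#' @return List of K integer index vectors.
#' @export
partition_clients <- function(labels, spec) {
  stopifnot(inherits(spec, "partition_spec"))
  n <- length(labels)
  K <- spec$num_clients
  if (K > n) stop("more clients than samples")
  shards <- with_seed(spec$seed, {
    sh <- vector("list", K)
    if (spec$mode == "iid") {
      ord <- sample.int(n)
      for (k in seq_len(K)) sh[[k]] <- ord[seq(k, n, by = K)]
    } else {
      for (k in seq_len(K)) sh[[k]] <- integer(0)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        g <- stats::rgamma(K, shape = spec$dirichlet_alpha)
        if (sum(g) == 0) g <- rep(1, K)
        pr <- g / sum(g)
        raw <- length(idx) * pr
        cnt <- floor(raw)
        rem <- length(idx) - sum(cnt)
        if (rem > 0) {
          extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
          cnt[extra] <- cnt[extra] + 1
        }
        pos <- 0L
        for (k in seq_len(K)) {
          if (cnt[k] > 0) {
            sh[[k]] <- c(sh[[k]], idx[(pos + 1L):(pos + cnt[k])])
            pos <- pos + cnt[k]
          }
        }
      }
    }
    sh
  })
  # repair empty shards: move one sample from the largest shard
  repeat {
    empty <- which(vapply(shards, length, integer(1)) == 0L)
    if (length(empty) == 0L) break
    big <- which.max(vapply(shards, length, integer(1)))
    shards[[empty[1]]] <- shards[[big]][1]
    shards[[big]] <- shards[[big]][-1]
  }
  lapply(shards, sort)
}

#' Generate, partition, and sensor-distort a federated dataset
#'
#' Convenience pipeline: renders the synthetic dataset, partitions it into
#' client shards, and (optionally) passes each shard's images through that
#' client's sensor model.
#'
#' @param spec A [synthetic_spec()].
#' @param part A [partition_spec()].
#' @param sensors `NULL`, or a list of one [sensor_model()] per client.
#' @return List with `data` (list `x`, `y` for [lsnet_fl_model()]),
#'   `shards`, and `manifest` (with `client_id` filled in).
#' @export
synthesize_federated <- function(spec, part, sensors = NULL) {
  ds <- generate_lesion_dataset(spec)
  shards <- partition_clients(ds$labels, part)
  if (!is.null(sensors)) {
    stopifnot(length(sensors) == part$num_clients)
    for (k in seq_along(shards)) {
      idx <- shards[[k]]
      ds$images[idx, , , ] <- apply_sensor_model(
        ds$images[idx, , , , drop = FALSE], sensors[[k]],
        seed = derive_seed(spec$seed, 6007L, k))
    }
  }
  for (k in seq_along(shards)) ds$manifest$client_id[shards[[k]]] <- k
  list(data = list(x = ds$images, y = ds$labels), shards = shards,
       manifest = ds$manifest)
}
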