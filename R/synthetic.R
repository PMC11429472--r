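# Deterministic generator of fundus-like test images.
#
# Real fundus-tumor photographs are private clinical data, so the package
# ships a procedural generator that reproduces the statistical structure the
# segmentation model is built for: a dark circular fundus field with
# curvilinear vessel-like structures, and a single connected, irregularly
# bounded lesion whose area spans a wide (log-uniform) range across images,
# labelled benign or malignant.  Everything is a pure function of
# (config, index); the cosmetics are non-clinical by design.

#' Configuration for the synthetic fundus generator
#'
#' @param image_size square image edge in pixels (default 448).
#' @param n_images number of samples in the dataset.
#' @param benign_fraction probability that a sample is labelled benign
#'   (default 0.4055, the benign share of a 103/151 benign/malignant split).
#' @param lesion_area_fraction_range min/max lesion area as a fraction of the
#'   image area.  The defaults 0.015--0.27 correspond to lesions of 287,061
#'   to 5,000,119 pixels on a 4304 x 4306 source frame, an 17-fold spread.
#' @param vessel_count number of vessel-like curves drawn per image.
#' @param seed integer master seed; each sample derives its own stream.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(image_size = 448L, n_images = 16L,
                         benign_fraction = 0.4055,
                         lesion_area_fraction_range = c(0.015, 0.27),
                         vessel_count = 4L, seed = 1L) {
  r <- lesion_area_fraction_range
  stopifnot(length(r) == 2L, r[1] > 0, r[1] < r[2], r[2] < 1,
            benign_fraction >= 0, benign_fraction <= 1, n_images >= 1L,
            image_size >= 16L)
  if (r[1] * image_size^2 < 9) {
    stop(sprintf(paste0("minimum lesion area fraction %.4g yields fewer than ",
                        "9 pixels at image size %d; no connected blob fits"),
                 r[1], image_size))
  }
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 benign_fraction = benign_fraction,
                 lesion_area_fraction_range = as.numeric(r),
                 vessel_count = as.integer(vessel_count),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Run expr under a private RNG stream; the caller's RNG state is untouched.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

sample_seed <- function(cfg, index) {
  (cfg$seed %% 65536L) * 32749L + index * 7L + 13L
}

# Radial boundary r(theta) = R (1 + sum_k a_k sin(k theta + phi_k)), k <= 6.
lesion_radius_fun <- function(a, phi) {
  function(theta) {
    r <- rep(1, length(theta))
    for (k in seq_along(a)) r <- r + a[k] * sin(k * theta + phi[k])
    r
  }
}

#' Generate one synthetic fundus sample
#'
#' @param cfg a [synth_config()].
#' @param index zero-based sample index in `[0, cfg$n_images)`.
#' @return a list of class `sample_record`: `image` (`[3, H, W]`, values in
#'   `[0, 1]` quantised to 8 bits), `mask` (`[H, W]` binary matrix), `label`
#'   (`"benign"` or `"malignant"`), `lesion_area` (pixels), `id`.
#' @export
generate_sample <- function(cfg, index) {
  stopifnot(inherits(cfg, "synth_config"),
            index >= 0L, index < cfg$n_images)
  S <- cfg$image_size
  rng <- cfg$lesion_area_fraction_range
  with_private_seed(sample_seed(cfg, index), {
    label <- if (stats::runif(1) < cfg$benign_fraction) "benign" else "malignant"
    # malignant lesions: stronger edge perturbation and a darker core, so the
    # class is learnable from pixels alone
    amp <- if (label == "malignant") 0.32 else 0.16
    a <- stats::runif(6, -amp, amp) / sqrt(seq_len(6))
    a <- pmin(pmax(a, -0.35), 0.35)
    # keep sum|a_k| bounded so the radial boundary stays positive and the
    # rasterised star-shaped region cannot pinch apart
    if (sum(abs(a)) > 0.6) a <- a * 0.6 / sum(abs(a))
    phi <- stats::runif(6, 0, 2 * pi)
    rad <- lesion_radius_fun(a, phi)

    # log-uniform target area within the configured fraction range
    target <- exp(stats::runif(1, log(rng[1]), log(rng[2]))) * S^2
    R <- sqrt(target / (pi * (1 + sum(a^2) / 2)))
    margin <- R * (1 + sum(abs(a)))
    field_r <- 0.48 * S
    ctr <- c(S / 2, S / 2)
    free <- max(field_r - margin, 0)
    th0 <- stats::runif(1, 0, 2 * pi)
    rr0 <- sqrt(stats::runif(1)) * free
    cy <- ctr[1] + rr0 * sin(th0)
    cx <- ctr[2] + rr0 * cos(th0)

    ys <- matrix(rep(seq_len(S), times = S) - cy, S, S)        # row offsets
    xs <- matrix(rep(seq_len(S), each = S) - cx, S, S)         # col offsets
    dist <- sqrt(ys^2 + xs^2)
    theta <- atan2(ys, xs)
    rb <- rad(theta)
    # adjust R until the rasterised area fraction lands inside the range
    mask <- NULL
    for (it in 1:40) {
      mask <- (dist <= R * rb) * 1
      frac <- sum(mask) / S^2
      if (frac >= rng[1] && frac <= rng[2]) break
      aim <- if (frac < rng[1]) rng[1] * 1.1 else rng[2] * 0.9
      R <- R * sqrt(aim / max(frac, 1e-9))
    }
    area <- sum(mask)

    # background: dark circular field with a low-frequency illumination ramp
    dctr <- sqrt((ys + cy - ctr[1])^2 + (xs + cx - ctr[2])^2)
    infield <- dctr <= field_r
    gx <- stats::runif(1, 0.3, 0.7) * S
    gy <- stats::runif(1, 0.3, 0.7) * S
    illum <- 1 - 0.35 * ((ys + cy - gy)^2 + (xs + cx - gx)^2) / S^2
    base <- c(0.82, 0.42, 0.20)
    img <- array(0, c(3, S, S))
    for (ch in 1:3) img[ch, , ] <- base[ch] * illum * infield

    # vessel-like cubic Bezier curves radiating from a disc-like point
    dy0 <- ctr[1] + stats::runif(1, -0.25, 0.25) * S
    dx0 <- ctr[2] + stats::runif(1, -0.25, 0.25) * S
    vcol <- c(0.45, 0.12, 0.08)
    tseq <- seq(0, 1, length.out = 6L * S)
    half <- max(1L, round(S / 180))
    for (v in seq_len(cfg$vessel_count)) {
      ang <- stats::runif(1, 0, 2 * pi)
      p1 <- c(dy0, dx0)
      p4 <- ctr + field_r * 0.95 * c(sin(ang), cos(ang))
      p2 <- p1 + (p4 - p1) / 3 + stats::rnorm(2, 0, 0.08 * S)
      p3 <- p1 + 2 * (p4 - p1) / 3 + stats::rnorm(2, 0, 0.08 * S)
      bez <- function(i) (1 - tseq)^3 * p1[i] + 3 * (1 - tseq)^2 * tseq * p2[i] +
        3 * (1 - tseq) * tseq^2 * p3[i] + tseq^3 * p4[i]
      by <- round(bez(1)); bx <- round(bez(2))
      for (oy in -half:half) for (ox in -half:half) {
        yy <- by + oy; xx <- bx + ox
        ok <- yy >= 1 & yy <= S & xx >= 1 & xx <= S
        idx <- cbind(yy[ok], xx[ok])
        for (ch in 1:3) {
          pl <- img[ch, , ]
          pl[idx] <- vcol[ch] * illum[idx]
          img[ch, , ] <- pl
        }
      }
    }

    # lesion appearance: radial blend towards the class-specific tint
    tint <- if (label == "malignant") c(0.30, 0.15, 0.10) else c(0.88, 0.62, 0.30)
    prof <- pmin(pmax(1 - dist / pmax(R * rb, 1e-9), 0), 1)    # 1 at core
    w <- mask * (0.55 + 0.4 * prof)
    if (label == "malignant") w <- mask * (0.65 + 0.35 * prof)
    for (ch in 1:3) {
      img[ch, , ] <- img[ch, , ] * (1 - w) + tint[ch] * illum * w
    }
    img <- img + stats::runif(length(img), -0.01, 0.01)
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255      # 8-bit quantisation: PNG round trips
    structure(list(image = img, mask = mask, label = label,
                   lesion_area = area,
                   id = sprintf("sample_%04d", index)),
              class = "sample_record")
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes one RGB PNG and one binary mask PNG per sample plus a manifest CSV
#' with columns `id,image_path,mask_path,label` (paths relative to the
#' manifest).  On failure, files written so far are removed.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly a character scalar.
#' @export
generate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character(0)
  rows <- vector("list", cfg$n_images)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  for (i in seq_len(cfg$n_images)) {
    s <- generate_sample(cfg, i - 1L)
    ip <- file.path(out_dir, paste0(s$id, "_image.png"))
    mp <- file.path(out_dir, paste0(s$id, "_mask.png"))
    tryCatch({
      png::writePNG(aperm(s$image, c(2, 3, 1)), ip)
      png::writePNG(s$mask, mp)
    }, error = function(e) {
      stop("I/O failure while writing sample ", s$id, ": ",
           conditionMessage(e))
    })
    written <- c(written, ip, mp)
    rows[[i]] <- data.frame(id = s$id,
                            image_path = basename(ip),
                            mask_path = basename(mp),
                            label = s$label,
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  ok <- TRUE
  manifest
}

#' Read a dataset manifest
#'
#' @param manifest path to a manifest CSV.
#' @return data frame with `id`, `image_path`, `mask_path`, `label`.
#' @export
read_manifest <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "image_path", "mask_path", "label")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' Load one sample listed in a manifest
#'
#' @param row one-row slice of a manifest data frame.
#' @param base_dir directory the manifest paths are relative to.
#' @return a `sample_record` (see [generate_sample()]).
#' @export
load_sample <- function(row, base_dir) {
  img <- png::readPNG(file.path(base_dir, row$image_path))
  msk <- png::readPNG(file.path(base_dir, row$mask_path))
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  msk <- round(msk)
  structure(list(image = aperm(img, c(3, 1, 2)), mask = msk,
                 label = row$label, lesion_area = sum(msk), id = row$id),
            class = "sample_record")
}

#' Class balance of a dataset manifest
#'
#' @param manifest path to a manifest CSV (or a manifest data frame).
#' @return data frame with one row per class: `label`, `count`, `percentage`
#'   (percentage of total, rounded to 2 decimals).
#' @export
summarize_manifest <- function(manifest) {
  df <- if (is.data.frame(manifest)) manifest else read_manifest(manifest)
  if (nrow(df) < 1L) stop("manifest has no rows")
  bad <- which(!df$label %in% c("benign", "malignant"))
  if (length(bad)) {
    stop(sprintf("unknown label '%s' in manifest row %d (id %s)",
                 df$label[bad[1]], bad[1], df$id[bad[1]]))
  }
  counts <- c(benign = sum(df$label == "benign"),
              malignant = sum(df$label == "malignant"))
  data.frame(label = names(counts),
             count = as.integer(counts),
             percentage = round(100 * counts / sum(counts), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
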