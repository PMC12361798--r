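#' Configuration for the synthetic echocardiography phantom
#'
#' Describes one synthetic cine video: a fan/sector-shaped imaging zone on a
#' black background containing two curved leaflet bands (anterior leaflet, AL,
#' above a horizontal annulus chord; posterior leaflet, PL, below) that open
#' during diastole and coapt during systole. In MVP cases a bulge of prolapse
#' tissue crosses the annulus line during systolic frames within one of six
#' sub-zones (A1-A3 on AL, P1-P3 on PL, left to right).
#'
#' Defaults emulate clinical 3D transesophageal cine data: 2-5 cardiac cycles
#' per video, video lengths of a few dozen frames, and roughly half of each
#' cycle in systole. The test-scale frame size is 192 x 192 so CPU runs are
#' fast; the native 800 x 600 acquisition size is available via `image_size`.
#'
#' @param image_size integer `(width, height)` in pixels.
#' @param n_cycles number of cardiac cycles (>= 1).
#' @param frames_per_cycle frames per cardiac cycle (>= 2).
#' @param systole_fraction fraction of each cycle spent in systole, in (0, 1).
#' @param mvp_case logical; does this video show mitral valve prolapse?
#' @param prolapse_amplitude displacement of the bulge past the annulus line,
#'   in pixels; must be > 0 exactly when `mvp_case` is TRUE (>= 2 px mirrors
#'   the >= 2 mm displacement criterion used clinically).
#' @param prolapse_zone sub-zone carrying the prolapse, one of
#'   `"A1","A2","A3","P1","P2","P3"`; ignored for control cases.
#' @param speckle_sigma scale of the multiplicative Rayleigh speckle noise.
#' @param blur_sigma Gaussian blur (pixels) applied to images after speckle.
#' @param seed integer seed making the case fully reproducible.
#' @return An object of class `echo_phantom_config`.
#' @export
echo_phantom_config <- function(image_size = c(192, 192),
                                n_cycles = 3,
                                frames_per_cycle = 18,
                                systole_fraction = 0.5,
                                mvp_case = FALSE,
                                prolapse_amplitude = if (mvp_case) 10 else 0,
                                prolapse_zone = "P2",
                                speckle_sigma = 0.2,
                                blur_sigma = 0.8,
                                seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), n_cycles = as.integer(n_cycles),
              frames_per_cycle = as.integer(frames_per_cycle),
              systole_fraction = systole_fraction, mvp_case = isTRUE(mvp_case),
              prolapse_amplitude = prolapse_amplitude,
              prolapse_zone = prolapse_zone, speckle_sigma = speckle_sigma,
              blur_sigma = blur_sigma, seed = as.integer(seed))
  class(cfg) <- "echo_phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$image_size) != 2 || any(cfg$image_size < 32))
    stop("invalid config: image_size must be (width, height) with both >= 32")
  if (cfg$n_cycles < 1)
    stop("invalid config: n_cycles >= 1 is violated")
  if (cfg$frames_per_cycle < 2)
    stop("invalid config: frames_per_cycle >= 2 is violated")
  if (!(cfg$systole_fraction > 0 && cfg$systole_fraction < 1))
    stop("invalid config: 0 < systole_fraction < 1 is violated")
  if (cfg$mvp_case != (cfg$prolapse_amplitude > 0))
    stop("invalid config: prolapse_amplitude > 0 iff mvp_case is violated")
  if (cfg$mvp_case && !cfg$prolapse_zone %in% c("A1","A2","A3","P1","P2","P3"))
    stop("invalid config: prolapse_zone must be one of A1,A2,A3,P1,P2,P3")
  invisible(cfg)
}

# Per-frame phase labels: each cycle is a diastole run followed by a systole
# run; systole gets round(frames_per_cycle * systole_fraction) frames, clamped
# so both runs are nonempty.
phase_labels_for_config <- function(cfg) {
  n_sys <- round(cfg$frames_per_cycle * cfg$systole_fraction)
  n_sys <- min(max(n_sys, 1L), cfg$frames_per_cycle - 1L)
  n_dia <- cfg$frames_per_cycle - n_sys
  rep(c(rep("diastole", n_dia), rep("systole", n_sys)), cfg$n_cycles)
}

# Deterministic geometry of one case (drawn once per case from its seed).
phantom_geometry <- function(cfg) {
  w <- cfg$image_size[1]; h <- cfg$image_size[2]
  list(
    apex = c(x = w / 2 + runif(1, -2, 2), y = 0.04 * h),
    half_angle = (38 + runif(1, -3, 3)) * pi / 180,
    radius = 0.92 * h,
    annulus_y = round(0.55 * h + runif(1, -2, 2)),
    band_thickness = max(3L, round(0.028 * h)),
    coapt_gap = 2L,
    open_max = 0.11 * h,
    bulge_radius = max(5, round(0.07 * h)),
    tissue_level = 0.85,
    chamber_level = 0.28
  )
}

# Render ground-truth mask + clean image for one frame.
# phase_pos: for diastole, position in (0,1] within the diastolic run.
render_frame <- function(cfg, geom, systolic, phase_pos) {
  w <- cfg$image_size[1]; h <- cfg$image_size[2]
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  yy <- matrix(seq_len(h), h, w)
  dx <- xx - geom$apex["x"]; dy <- yy - geom$apex["y"]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy)  # angle from downward vertical
  sector <- r <= geom$radius & abs(ang) <= geom$half_angle & dy >= 0

  ya <- geom$annulus_y
  # lateral extent of the annulus chord inside the sector, inset slightly
  half_w_at_ya <- (ya - geom$apex["y"]) * tan(geom$half_angle)
  xl <- geom$apex["x"] - 0.92 * half_w_at_ya
  xr <- geom$apex["x"] + 0.92 * half_w_at_ya
  span <- xr - xl
  arc <- pmax(0, sin(pi * (xx - xl) / span))  # 0 at ends, 1 mid-leaflet
  in_span <- xx >= xl & xx <= xr

  d_open <- if (systolic) 0 else geom$open_max * sin(pi * phase_pos)
  th <- geom$band_thickness
  gap <- geom$coapt_gap
  y_al <- ya - gap - th / 2 - d_open * arc  # AL band centreline
  y_pl <- ya + gap + th / 2 + d_open * arc  # PL band centreline

  al <- in_span & sector & abs(yy - y_al) <= th / 2
  pl <- in_span & sector & abs(yy - y_pl) <= th / 2
  mvp <- matrix(FALSE, h, w)

  if (cfg$mvp_case && systolic) {
    zone <- cfg$prolapse_zone
    j <- as.integer(substring(zone, 2, 2))
    anterior <- substring(zone, 1, 1) == "A"
    xc <- xl + (j - 0.5) * span / 3
    rad <- geom$bulge_radius
    amp <- cfg$prolapse_amplitude
    # The prolapsing segment crosses the annulus line to the opposite side
    # (coaptation failure): half-ellipse past the line plus a neck joining it
    # to its own leaflet band. The opposing leaflet is locally interrupted.
    if (anterior) {
      bulge <- ((xx - xc) / rad)^2 + ((yy - ya) / amp)^2 <= 1 & yy >= ya
      neck <- abs(xx - xc) <= 0.8 * rad & yy >= (ya - gap - th) & yy < ya
      carve <- pl & abs(xx - xc) <= rad + 6
      pl <- pl & !carve
    } else {
      bulge <- ((xx - xc) / rad)^2 + ((yy - ya) / amp)^2 <= 1 & yy <= ya
      neck <- abs(xx - xc) <= 0.8 * rad & yy <= (ya + gap + th) & yy > ya
      carve <- al & abs(xx - xc) <= rad + 6
      al <- al & !carve
    }
    mvp <- (bulge | neck) & sector
  }

  mask <- matrix(0L, h, w)
  mask[al] <- 1L
  mask[pl] <- 2L
  mask[mvp] <- 3L  # prolapse overrides leaflet labels

  img <- matrix(0, h, w)
  img[sector] <- geom$chamber_level
  img[mask > 0] <- geom$tissue_level
  list(image = img, mask = mask)
}

#' Generate one synthetic echocardiography case
#'
#' Renders the full cine sequence with per-frame phase labels and pixel masks
#' (0 = background, 1 = AL, 2 = PL, 3 = MVP). Multiplicative Rayleigh speckle
#' (normalised to unit mean) and Gaussian blur are applied to the images only,
#' never to the masks. Class-3 pixels appear only on systolic frames of MVP
#' cases. Fully deterministic for a fixed config (including its seed).
#'
#' @param config an [echo_phantom_config()].
#' @return An object of class `echo_case`: list with `frames` (list of
#'   `[0,1]` intensity matrices), `masks` (list of integer label matrices),
#'   `phases` (character vector, `"systole"`/`"diastole"`), `mvp_truth`,
#'   `severe_zone_truth` (`NA` for controls), `annulus_y`, and `config`.
#' @export
generate_case <- function(config) {
  validate_phantom_config(config)
  run_with_seed(config$seed, {
    geom <- phantom_geometry(config)
    phases <- phase_labels_for_config(config)
    n <- length(phases)
    frames <- vector("list", n)
    masks <- vector("list", n)
    # position of each diastolic frame inside its run, for leaflet motion
    runs <- rle(phases)
    pos <- numeric(n)
    idx <- 1L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      pos[idx:(idx + len - 1L)] <- seq_len(len) / (len + 1)
      idx <- idx + len
    }
    for (i in seq_len(n)) {
      rf <- render_frame(config, geom, phases[i] == "systole", pos[i])
      img <- rf$image
      if (config$speckle_sigma > 0) {
        # Rayleigh speckle with unit mean: sigma*sqrt(-2 log U)/(sigma*sqrt(pi/2))
        u <- matrix(stats::runif(length(img)), nrow(img), ncol(img))
        img <- img * sqrt(-2 * log(u)) / sqrt(pi / 2)
      }
      if (config$blur_sigma > 0) img <- blur_gaussian(img, config$blur_sigma)
      frames[[i]] <- clamp01(img)
      masks[[i]] <- rf$mask
    }
    structure(list(frames = frames, masks = masks, phases = phases,
                   mvp_truth = config$mvp_case,
                   severe_zone_truth = if (config$mvp_case) config$prolapse_zone else NA_character_,
                   annulus_y = geom$annulus_y,
                   config = config),
              class = "echo_case")
  })
}

#' @export
print.echo_case <- function(x, ...) {
  cat(sprintf("<echo_case> %d frames %dx%d, %d systolic, mvp=%s zone=%s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              sum(x$phases == "systole"), x$mvp_truth,
              ifelse(is.na(x$severe_zone_truth), "-", x$severe_zone_truth)))
  invisible(x)
}

#' Generate a synthetic dataset of cases with a train/val/test split
#'
#' Per-case configurations are drawn reproducibly from `config_ranges`; cases
#' are assigned to train/validation/test splits in `split_ratio` proportions
#' (default 3:2:3), stratified by MVP status.
#'
#' @param n_control,n_mvp number of control and MVP cases (>= 0).
#' @param config_ranges list of sampling ranges: `n_cycles` (integer vector),
#'   `frames_per_cycle` (integer vector), `prolapse_amplitude` (numeric
#'   range), and scalars `image_size`, `systole_fraction`, `speckle_sigma`,
#'   `blur_sigma` overriding the phantom defaults.
#' @param seed integer seed for the whole dataset.
#' @param split_ratio numeric length-3 vector of train/val/test weights.
#' @return list of `echo_case` objects, each with a `$split` element.
#' @export
generate_dataset <- function(n_control, n_mvp, config_ranges = list(),
                             seed = 1L, split_ratio = c(3, 2, 3)) {
  stopifnot(n_control >= 0, n_mvp >= 0)
  rng <- utils::modifyList(list(
    n_cycles = 2:5, frames_per_cycle = 13:26,
    prolapse_amplitude = c(8, 14), image_size = c(192, 192),
    systole_fraction = 0.5, speckle_sigma = 0.2, blur_sigma = 0.8
  ), config_ranges)
  n <- n_control + n_mvp
  if (n == 0) return(list())
  run_with_seed(seed, {
    status <- c(rep(FALSE, n_control), rep(TRUE, n_mvp))
    zones <- c("A1","A2","A3","P1","P2","P3")
    cases <- vector("list", n)
    case_seeds <- sample.int(.Machine$integer.max, n)
    for (i in seq_len(n)) {
      mvp <- status[i]
      cfg <- echo_phantom_config(
        image_size = rng$image_size,
        n_cycles = sample(rng$n_cycles, 1),
        frames_per_cycle = sample(rng$frames_per_cycle, 1),
        systole_fraction = rng$systole_fraction,
        mvp_case = mvp,
        prolapse_amplitude = if (mvp) round(stats::runif(1, rng$prolapse_amplitude[1],
                                                         rng$prolapse_amplitude[2])) else 0,
        prolapse_zone = if (mvp) sample(zones, 1) else "P2",
        speckle_sigma = rng$speckle_sigma, blur_sigma = rng$blur_sigma,
        seed = case_seeds[i])
      cases[[i]] <- generate_case(cfg)
    }
    # stratified split assignment in split_ratio proportions
    p <- split_ratio / sum(split_ratio)
    assign_split <- function(idx) {
      m <- length(idx)
      n_tr <- round(m * p[1]); n_va <- round(m * p[2])
      n_va <- min(n_va, m - n_tr)
      lab <- c(rep("train", n_tr), rep("val", n_va),
               rep("test", m - n_tr - n_va))
      idx_shuf <- sample(idx)
      stats::setNames(lab, idx_shuf)
    }
    splits <- c(assign_split(which(!status)), assign_split(which(status)))
    for (i in seq_len(n)) cases[[i]]$split <- unname(splits[as.character(i)])
    cases
  })
}

#' Write a synthetic case to disk in the package's on-disk layout
#'
#' Writes `frames/NNNN.png` (8-bit grayscale), `masks/NNNN.png` (indexed,
#' stored byte values 0-3), `phases.csv` (`frame_index,label`) and
#' `manifest.json`.
#'
#' @param case an `echo_case`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- length(case$frames)
  for (i in seq_len(n)) {
    png::writePNG(round(case$frames[[i]] * 255) / 255,
                  file.path(dir, "frames", sprintf("%04d.png", i)))
    png::writePNG(case$masks[[i]] / 255,
                  file.path(dir, "masks", sprintf("%04d.png", i)))
  }
  utils::write.csv(data.frame(frame_index = seq_len(n) - 1L, label = case$phases),
                   file.path(dir, "phases.csv"), row.names = FALSE)
  manifest <- list(n_frames = n,
                   width = ncol(case$frames[[1]]), height = nrow(case$frames[[1]]),
                   mvp_truth = case$mvp_truth,
                   severe_zone_truth = case$severe_zone_truth,
                   annulus_y = case$annulus_y,
                   split = if (is.null(case$split)) NA else case$split,
                   seed = case$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(dir)
}

#' Read a case previously written by [write_case()]
#'
#' @param dir case directory.
#' @return an `echo_case` (without the generating config).
#' @export
read_case <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ff <- sort(list.files(file.path(dir, "frames"), full.names = TRUE))
  mf <- sort(list.files(file.path(dir, "masks"), full.names = TRUE))
  frames <- lapply(ff, function(f) as.matrix(png::readPNG(f)))
  masks <- lapply(mf, function(f) {
    m <- round(png::readPNG(f) * 255)
    storage.mode(m) <- "integer"
    m
  })
  phases <- utils::read.csv(file.path(dir, "phases.csv"))$label
  structure(list(frames = frames, masks = masks, phases = phases,
                 mvp_truth = isTRUE(manifest$mvp_truth),
                 severe_zone_truth = if (is.null(manifest$severe_zone_truth))
                   NA_character_ else manifest$severe_zone_truth,
                 annulus_y = manifest$annulus_y,
                 split = manifest$split,
                 config = NULL),
            class = "echo_case")
}
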