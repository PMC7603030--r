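#' Transport kinetics for a synthetic ER-to-Golgi series
#'
#' Defines what fraction of the total cargo fluorescence sits in the Golgi
#' at each acquisition timepoint, together with how the ER-resident
#' remainder is split between aggregated puncta and the diffuse ER network.
#' Cargo intensity is conserved across timepoints (before background and
#' noise), mimicking redistribution of a fixed fluorophore pool after
#' solubilizer addition.
#'
#' @param timepoints_min acquisition times in minutes, strictly increasing,
#'   starting at 0 (transport initiation). Default `c(0, 3, 7, 15, 30)`.
#' @param golgi_fraction fraction of total cargo in the Golgi at each
#'   timepoint, each in `[0, 1]`; `golgi_fraction[1]` is the small
#'   pre-transport baseline (default 0.02).
#' @param cargo_total_intensity total integrated cargo signal per cell,
#'   counts. Conserved exactly at every timepoint before noise.
#' @param er_puncta_fraction per-timepoint fraction of the ER cargo held in
#'   puncta (the rest is diffuse network signal); decreasing values emulate
#'   solubilizer-driven disaggregation.
#' @param puncta_aspect per-timepoint axis ratio of the (equal-area)
#'   elliptical puncta; values above 1 make early aggregates irregular and
#'   elongated so their circularity rises as disaggregation proceeds.
#' @return An object of class `transport_kinetics`.
#' @seealso [kinetics_preset()] for the per-class presets,
#'   [predict_ti()] for the closed-form transport index they imply.
#' @export
transport_kinetics <- function(timepoints_min = c(0, 3, 7, 15, 30),
                               golgi_fraction = NULL,
                               cargo_total_intensity = 1.5e6,
                               er_puncta_fraction = NULL,
                               puncta_aspect = NULL) {
  if (length(timepoints_min) < 1L || timepoints_min[1] != 0)
    stop_param("timepoints_min must start at 0 (transport initiation)")
  if (any(diff(timepoints_min) <= 0))
    stop_param("timepoints_min must be strictly increasing")
  nt <- length(timepoints_min)
  if (is.null(golgi_fraction))
    golgi_fraction <- fraction_for_ti(c(1, 1.6, 2.8, 5, 7)[seq_len(nt)])
  if (length(golgi_fraction) != nt)
    stop_param("golgi_fraction must match timepoints_min in length")
  if (any(golgi_fraction < 0 | golgi_fraction > 1))
    stop_param("golgi_fraction must lie in [0, 1]")
  if (cargo_total_intensity <= 0)
    stop_param("cargo_total_intensity must be > 0")
  if (is.null(er_puncta_fraction))
    er_puncta_fraction <- seq(0.8, 0.05, length.out = nt)
  if (is.null(puncta_aspect))
    puncta_aspect <- seq(4, 1, length.out = nt)
  if (length(er_puncta_fraction) != nt || length(puncta_aspect) != nt)
    stop_param("er_puncta_fraction and puncta_aspect must match timepoints")
  if (any(er_puncta_fraction < 0 | er_puncta_fraction > 1))
    stop_param("er_puncta_fraction must lie in [0, 1]")
  if (any(puncta_aspect < 1))
    stop_param("puncta_aspect must be >= 1")
  structure(list(timepoints_min = timepoints_min,
                 golgi_fraction = golgi_fraction,
                 cargo_total_intensity = cargo_total_intensity,
                 er_puncta_fraction = er_puncta_fraction,
                 puncta_aspect = puncta_aspect),
            class = "transport_kinetics")
}

#' Closed-form transport index implied by planted Golgi fractions
#'
#' With a fraction `f(t)` of the conserved cargo pool in the Golgi and the
#' rest in the ER, the Golgi/non-Golgi intensity ratio is `f/(1-f)` and the
#' normalized transport index is
#' \deqn{TI(t) = \frac{f(t)\,(1-f_0)}{f_0\,(1-f(t))}.}
#' This is the independent predictor against which the image-based pipeline
#' is validated (valid whenever the Golgi mask captures the planted Golgi
#' footprint and no ER signal).
#'
#' @param golgi_fraction numeric vector of fractions in `(0, 1)`, first
#'   entry the baseline.
#' @return Numeric vector of transport-index values (first entry 1).
#' @export
predict_ti <- function(golgi_fraction) {
  f <- golgi_fraction
  if (any(f <= 0 | f >= 1))
    stop_param("closed form needs fractions strictly inside (0, 1)")
  f0 <- f[1]
  (f * (1 - f0)) / (f0 * (1 - f))
}

#' Golgi fraction that yields a target transport index
#'
#' Inverse of [predict_ti()]: `f = TI * k / (1 + TI * k)` with
#' `k = f0 / (1 - f0)`.
#'
#' @param ti target transport-index values.
#' @param baseline_fraction pre-transport Golgi fraction `f0`.
#' @return Numeric vector of Golgi fractions.
#' @export
fraction_for_ti <- function(ti, baseline_fraction = 0.02) {
  if (any(ti < 0)) stop_param("ti must be >= 0")
  k <- baseline_fraction / (1 - baseline_fraction)
  (ti * k) / (1 + ti * k)
}

# target TI trajectories per transport-efficiency class; decision times are
# 30 min (soluble) and 15 min (transmembrane)
.preset_ti <- list(
  soluble = list(very_high = c(1, 2.0, 4.5, 9.0, 14.0),
                 high      = c(1, 1.6, 2.8, 5.0, 7.0),
                 moderate  = c(1, 1.2, 1.8, 2.5, 3.2),
                 none      = c(1, 1.0, 1.0, 1.0, 1.0)),
  transmembrane = list(very_high = c(1, 3.0, 7.0, 14.0, 18.0),
                       high      = c(1, 1.8, 4.0, 8.0, 9.5),
                       moderate  = c(1, 1.4, 2.5, 5.0, 6.0),
                       none      = c(1, 1.0, 1.0, 1.0, 1.0)))

#' Kinetics preset for a transport-efficiency class
#'
#' Returns a [transport_kinetics()] whose planted Golgi fractions put the
#' closed-form transport index well inside the stated class interval at the
#' decision time of the given cargo type (30 min for soluble cargo,
#' 15 min for transmembrane cargo).
#'
#' @param class one of `"very_high"`, `"high"`, `"moderate"`, `"none"`.
#' @param cargo_type `"soluble"` or `"transmembrane"`.
#' @param ... passed to [transport_kinetics()].
#' @return A `transport_kinetics` object.
#' @export
kinetics_preset <- function(class = c("very_high", "high", "moderate",
                                      "none"),
                            cargo_type = c("soluble", "transmembrane"),
                            ...) {
  class <- match.arg(class)
  cargo_type <- match.arg(cargo_type)
  ti <- .preset_ti[[cargo_type]][[class]]
  transport_kinetics(golgi_fraction = fraction_for_ti(ti), ...)
}

#' Generate a two-channel ER-to-Golgi transport image series
#'
#' Renders, per timepoint, a cargo channel and a static Golgi-marker
#' channel for each cell of the scene. The planted Golgi fraction of the
#' conserved cargo pool is spread uniformly over a core disc inside the
#' marker footprint; the ER remainder is split between elliptical puncta
#' and a diffuse component, both confined to the cell and kept clear of the
#' Golgi. Emits a ground-truth record (label masks, planted fractions,
#' puncta positions) keyed to the same parameters and seed.
#'
#' @param scene a [scene_params()].
#' @param kinetics a [transport_kinetics()].
#' @return A list with `stack` (an [image_stack()] with channels `"cargo"`
#'   and `"golgi_marker"`, one frame per timepoint) and `truth`
#'   (class `ground_truth`).
#' @export
generate_transport_series <- function(scene, kinetics) {
  stopifnot(inherits(scene, "scene_params"),
            inherits(kinetics, "transport_kinetics"))
  shape <- scene$image_shape
  nt <- length(kinetics$timepoints_min)
  grid <- pixel_grid(shape)
  geo <- scene_geometry(scene)

  cell_lab <- matrix(0L, shape[1], shape[2])
  golgi_lab <- matrix(0L, shape[1], shape[2])
  marker <- matrix(0, shape[1], shape[2])
  regions <- vector("list", length(geo))
  for (g in geo) {
    cm <- ellipse_mask(grid, g)
    cell_lab[cm] <- g$label
    d <- sqrt((grid$y - g$gy)^2 + (grid$x - g$gx)^2)
    gm <- d <= scene$golgi_radius_px
    golgi_lab[gm] <- g$label
    core <- d <= scene$golgi_radius_px - scene$cargo_core_margin_px
    er <- cm & d > scene$golgi_radius_px + scene$golgi_clearance_px
    # plateau disc with a Gaussian shoulder outside the rim
    mk <- ifelse(gm, scene$marker_peak,
                 scene$marker_peak *
                   exp(-(d - scene$golgi_radius_px)^2 /
                         (2 * scene$marker_edge_sigma_px^2)))
    mk[!cm & mk < 1e-3 * scene$marker_peak] <- 0
    marker <- marker + mk
    regions[[g$label]] <- list(geom = g, cell = cm, golgi = gm, core = core,
                               er = er)
  }

  arr <- array(0, c(nt, 2L, shape[1], shape[2]))
  truth_puncta <- NULL
  with_seed(scene$seed, {
    # puncta geometry drawn once per cell, shared across timepoints
    for (rg in regions) {
      np <- scene$puncta_count
      if (np > 0) {
        idx <- which(rg$er)
        pick <- idx[sample.int(length(idx), min(np, length(idx)))]
        rg$py <- grid$y[pick]; rg$px <- grid$x[pick]
        rg$ptheta <- runif(length(pick), 0, pi)
        truth_puncta <- rbind(truth_puncta,
                              data.frame(cell_label = rg$geom$label,
                                         y = rg$py, x = rg$px))
      } else {
        rg$py <- numeric(0); rg$px <- numeric(0); rg$ptheta <- numeric(0)
      }
      regions[[rg$geom$label]] <- rg
    }
    for (t in seq_len(nt)) {
      cargo <- matrix(0, shape[1], shape[2])
      f <- kinetics$golgi_fraction[t]
      pf <- kinetics$er_puncta_fraction[t]
      aspect <- kinetics$puncta_aspect[t]
      for (rg in regions) {
        total <- kinetics$cargo_total_intensity
        # Golgi-resident cargo: uniform over the core disc
        ncore <- sum(rg$core)
        cargo[rg$core] <- cargo[rg$core] + f * total / ncore
        er_total <- (1 - f) * total
        # aggregated puncta (equal mass each, exact by normalization)
        npk <- length(rg$py)
        if (npk > 0 && pf > 0) {
          pm <- er_total * pf / npk
          for (i in seq_len(npk)) {
            cargo <- cargo + render_punctum(shape, rg, rg$py[i], rg$px[i],
                                            rg$ptheta[i],
                                            scene$puncta_sigma_px, aspect,
                                            pm)
          }
          diffuse_mass <- er_total * (1 - pf)
        } else {
          diffuse_mass <- er_total
        }
        # diffuse ER network component: uniform over the eligible region
        ner <- sum(rg$er)
        cargo[rg$er] <- cargo[rg$er] + diffuse_mass / ner
      }
      fr_cargo <- cargo + scene$background_level
      fr_marker <- marker + scene$background_level
      arr[t, 1L, , ] <- apply_noise(fr_cargo, scene)
      arr[t, 2L, , ] <- apply_noise(fr_marker, scene)
    }
  })

  stack <- image_stack(arr, pixel_size_um = scene$pixel_size_um,
                       timepoints_min = kinetics$timepoints_min,
                       channel_names = c("cargo", "golgi_marker"))
  truth <- structure(list(
    golgi_mask_true = golgi_lab, cell_masks_true = cell_lab,
    golgi_fraction_true = kinetics$golgi_fraction,
    er_puncta_fraction_true = kinetics$er_puncta_fraction,
    puncta_aspect_true = kinetics$puncta_aspect,
    timepoints_min = kinetics$timepoints_min,
    cargo_total_intensity = kinetics$cargo_total_intensity,
    puncta = truth_puncta, seed = scene$seed,
    predicted_ti = tryCatch(predict_ti(kinetics$golgi_fraction),
                            error = function(e) NULL)
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}

# additive elliptical Gaussian punctum confined to the cell's ER region,
# normalized to carry exactly `mass`
render_punctum <- function(shape, rg, cy, cx, theta, sigma, aspect, mass) {
  s_major <- sigma * sqrt(aspect); s_minor <- sigma / sqrt(aspect)
  h <- ceiling(3 * s_major)
  y0 <- max(1, floor(cy) + 1 - h); y1 <- min(shape[1], floor(cy) + 1 + h)
  x0 <- max(1, floor(cx) + 1 - h); x1 <- min(shape[2], floor(cx) + 1 + h)
  yy <- (y0:y1) - 1; xx <- (x0:x1) - 1
  dy <- outer(yy - cy, rep(1, length(xx)))
  dx <- outer(rep(1, length(yy)), xx - cx)
  u <- cos(theta) * dx + sin(theta) * dy
  w <- -sin(theta) * dx + cos(theta) * dy
  k <- exp(-0.5 * ((u / s_major)^2 + (w / s_minor)^2))
  k <- k * rg$er[y0:y1, x0:x1, drop = FALSE]   # confined to ER region
  s <- sum(k)
  out <- matrix(0, shape[1], shape[2])
  if (s > 0) out[y0:y1, x0:x1] <- k / s * mass
  out
}
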