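#' Uniform wavenumber grid
#'
#' @param start,stop range in cm^-1 (grid covers `start` up to the largest
#'   `start + k*spacing <= stop`).
#' @param spacing grid spacing in cm^-1.
#' @return Object of class `wavenumber_grid`: ascending points plus the
#'   spacing, covering the instrument range 4000-9999 cm^-1 by default.
#' @export
wavenumber_grid <- function(start = 4000, stop = 9999, spacing = 4) {
  if (spacing <= 0 || stop <= start) stop("invalid grid", call. = FALSE)
  pts <- seq(start, stop, by = spacing)
  structure(list(points = pts, spacing = spacing), class = "wavenumber_grid")
}

#' Gaussian band set of one pure component
#'
#' A stand-in pure NIR absorbance spectrum: a sum of Gaussian bands, each
#' (center cm^-1, width-SD cm^-1, height AU).
#'
#' @param name component name.
#' @param centers,widths,heights equal-length numeric vectors; widths > 0,
#'   heights >= 0.
#' @return A `band_set` object.
#' @export
band_set <- function(name, centers, widths, heights) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(heights))
  if (any(widths <= 0) || any(heights < 0))
    stop("widths must be > 0 and heights >= 0", call. = FALSE)
  structure(list(name = name, centers = centers, widths = widths,
                 heights = heights), class = "band_set")
}

#' Evaluate a pure-component spectrum on a grid
#'
#' A(nu) = sum_b height * exp(-(nu - center)^2 / (2 width^2)).
#'
#' @param bands a [band_set].
#' @param grid a [wavenumber_grid].
#' @return Absorbance vector (AU), one value per grid point.
#' @export
pure_spectrum <- function(bands, grid) {
  stopifnot(inherits(bands, "band_set"), inherits(grid, "wavenumber_grid"))
  nu <- grid$points
  a <- numeric(length(nu))
  for (b in seq_along(bands$centers)) {
    a <- a + bands$heights[b] *
      exp(-(nu - bands$centers[b])^2 / (2 * bands$widths[b]^2))
  }
  a
}

#' Default component band library
#'
#' Band sets for azithromycin (AZ), artesunate (AS), microcrystalline
#' cellulose, colloidal silica and the AS degradant dihydroartemisinin
#' (DHA). Band positions are loosely placed at typical C-H/O-H
#' overtone/combination regions; heights are balanced so that at label
#' composition the blend spectrum is dominated by the AZ features, and
#' both APIs carry bands inside each of the two analysis regions
#' (5311-6811 and 7200-9999 cm^-1). DHA shares the AS band pattern shifted
#' by `dha_shift` cm^-1 with heights scaled by `dha_height_factor`, so a
#' degradant spike perturbs band positions rather than just intensity.
#'
#' @param seed optional integer; when given, band centers and heights are
#'   jittered deterministically (centers SD 2 cm^-1, heights 2% relative).
#'   `NULL` returns the fixed reference library.
#' @param dha_shift wavenumber shift of DHA bands relative to AS (cm^-1).
#' @param dha_height_factor relative height of DHA bands vs AS.
#' @return Named list of [band_set] objects
#'   (`AZ`, `AS`, `cellulose`, `silica`, `DHA`).
#' @export
default_library <- function(seed = NULL, dha_shift = 30,
                            dha_height_factor = 0.9) {
  az <- band_set("AZ",
    centers = c(4350, 5600, 6050, 6600, 7450, 8400, 9200),
    widths  = c(150, 120, 140, 110, 180, 220, 260),
    heights = c(0.60, 0.55, 0.50, 0.30, 0.40, 0.35, 0.20))
  as_ <- band_set("AS",
    centers = c(4500, 5450, 5850, 6300, 7700, 8800),
    widths  = c(130, 55, 60, 70, 120, 200),
    heights = c(0.40, 0.28, 0.35, 0.30, 0.25, 0.20))
  cel <- band_set("cellulose",
    centers = c(4750, 5180, 6350, 6950, 8300),
    widths  = c(200, 140, 170, 180, 300),
    heights = c(0.30, 0.35, 0.12, 0.15, 0.10))
  sil <- band_set("silica",
    centers = c(5250, 7100),
    widths  = c(300, 300),
    heights = c(0.05, 0.03))
  lib <- list(AZ = az, AS = as_, cellulose = cel, silica = sil)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    for (nm in names(lib)) {
      k <- length(lib[[nm]]$centers)
      lib[[nm]]$centers <- lib[[nm]]$centers + stats::rnorm(k, 0, 2)
      lib[[nm]]$heights <- lib[[nm]]$heights * (1 + stats::rnorm(k, 0, 0.02))
    }
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
  }
  lib$DHA <- band_set("DHA",
    centers = lib$AS$centers + dha_shift,
    widths = lib$AS$widths,
    heights = lib$AS$heights * dha_height_factor)
  lib
}

#' Instrumental and sampling noise model
#'
#' The disturbances the pre-treatments are meant to remove: a per-spectrum
#' log-normal multiplicative gain (scatter / packing density), a random
#' linear baseline (offset + slope over the normalized wavenumber axis),
#' iid additive detector noise, a relative weighing error on component
#' masses, and an optional between-series gain shared by all spectra of a
#' series (day-to-day repack/operator effect).
#'
#' @param gain_sd relative SD of the multiplicative gain (log scale).
#' @param offset_sd,slope_sd SD of baseline offset and slope (AU; slope per
#'   unit of normalized wavenumber).
#' @param additive_sd SD of iid additive noise (AU).
#' @param weighing_sd relative SD of component weighing errors.
#' @param series_gain_sd relative SD of the between-series gain.
#' @return A `noise_model` object.
#' @export
noise_model <- function(gain_sd = 0.005, offset_sd = 5e-4, slope_sd = 5e-4,
                        additive_sd = 1e-4, weighing_sd = 0.0015,
                        series_gain_sd = 0) {
  v <- c(gain_sd, offset_sd, slope_sd, additive_sd, weighing_sd, series_gain_sd)
  if (any(v < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(gain_sd = gain_sd, offset_sd = offset_sd,
                 slope_sd = slope_sd, additive_sd = additive_sd,
                 weighing_sd = weighing_sd, series_gain_sd = series_gain_sd),
            class = "noise_model")
}

#' Noise-free noise model
#' @return A [noise_model] with every SD zero.
#' @export
noise_free <- function() {
  noise_model(0, 0, 0, 0, 0, 0)
}

# Pure spectra of library components as a matrix (components x points).
component_matrix <- function(library, grid) {
  t(vapply(library, pure_spectrum, numeric(length(grid$points)), grid = grid))
}

#' Simulate one mixture spectrum
#'
#' Beer-Lambert-like additive mixing of the component spectra weighted by
#' mass fraction, then scatter gain, linear baseline and additive noise:
#' A = g * sum_i f_i A_i(nu) + b0 + b1 * nu_tilde + eps(nu), with
#' g ~ LogNormal(0, gain_sd), b0, b1 Gaussian, eps iid Gaussian and
#' nu_tilde the wavenumber normalized to \[0, 1\]. Draws from the current
#' R random stream.
#'
#' @param fractions named mass fractions (>= 0) over library components;
#'   missing components count as 0.
#' @param library band library as from [default_library()].
#' @param grid a [wavenumber_grid].
#' @param noise a [noise_model]; weighing and series terms are ignored here
#'   (they act at the sample level, see [simulate_set()]).
#' @return Absorbance vector.
#' @export
mixture_spectrum <- function(fractions, library, grid, noise = noise_model()) {
  if (any(fractions < 0))
    stop("invalid composition: negative fraction", call. = FALSE)
  comp <- component_matrix(library, grid)
  f <- numeric(nrow(comp))
  names(f) <- rownames(comp)
  if (!all(names(fractions) %in% names(f)))
    stop("fractions name components missing from the library", call. = FALSE)
  f[names(fractions)] <- fractions
  base <- drop(f %*% comp)
  n <- length(base)
  g <- if (noise$gain_sd > 0) exp(stats::rnorm(1, 0, noise$gain_sd)) else 1
  b0 <- if (noise$offset_sd > 0) stats::rnorm(1, 0, noise$offset_sd) else 0
  b1 <- if (noise$slope_sd > 0) stats::rnorm(1, 0, noise$slope_sd) else 0
  eps <- if (noise$additive_sd > 0) stats::rnorm(n, 0, noise$additive_sd) else numeric(n)
  nu_t <- (grid$points - grid$points[1]) / (grid$points[n] - grid$points[1])
  g * base + b0 + b1 * nu_t + eps
}

#' Spectra set container
#'
#' @param grid a [wavenumber_grid].
#' @param absorbance numeric matrix, samples x grid points.
#' @param meta data.frame of per-sample metadata (one row per spectrum),
#'   must contain a `sample` column of unique labels.
#' @return A `spectra_set` object.
#' @export
spectra_set <- function(grid, absorbance, meta) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(grid$points))
    stop("absorbance columns must match grid points", call. = FALSE)
  if (nrow(absorbance) != nrow(meta))
    stop("meta rows must match spectra", call. = FALSE)
  if (is.null(meta$sample) || anyDuplicated(meta$sample))
    stop("meta must carry unique sample labels", call. = FALSE)
  rownames(absorbance) <- meta$sample
  structure(list(grid = grid, absorbance = absorbance, meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d points (%g-%g cm-1, step %g)\n",
              nrow(x$absorbance), ncol(x$absorbance), min(x$grid$points),
              max(x$grid$points), x$grid$spacing))
  invisible(x)
}

#' Combine spectra sets sharing a grid
#' @param ... `spectra_set` objects on identical grids.
#' @return A single `spectra_set`.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  g <- sets[[1]]$grid
  for (s in sets) {
    stopifnot(inherits(s, "spectra_set"))
    if (!isTRUE(all.equal(s$grid$points, g$points)))
      stop("grids differ", call. = FALSE)
  }
  metas <- lapply(sets, `[[`, "meta")
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) {
    for (cl in setdiff(cols, names(m))) m[[cl]] <- NA
    m[cols]
  })
  spectra_set(g, do.call(rbind, lapply(sets, `[[`, "absorbance")),
              do.call(rbind, metas))
}

# fractions + true percent-of-label from (possibly perturbed) masses
masses_to_fractions <- function(masses, form) {
  tot <- sum(masses)
  f <- masses / tot
  pct <- 100 * f[form$apis] / form$fractions[form$apis]
  list(fractions = f, pct = pct)
}

#' Simulate NIR spectra for a design table
#'
#' For each row of a design table the component masses are perturbed by a
#' relative weighing error, converted to mass fractions (placebo is split
#' into cellulose and silica at the excipient-mixture ratio), and the
#' recorded spectrum is the average of `repacks` independent
#' [mixture_spectrum()] draws of the same blend — emulating triplicate
#' recording with repacking between scans. Rows carrying a `series_id`
#' additionally share a per-series multiplicative gain when
#' `noise$series_gain_sd > 0`.
#'
#' @param tab design table from [design_table()] or [validation_table()].
#' @param form the [formulation] the table was built from.
#' @param library band library.
#' @param grid a [wavenumber_grid].
#' @param noise a [noise_model].
#' @param repacks spectra averaged per sample (default 3).
#' @param seed optional integer seed; when `NULL` the current random
#'   stream is used (as inside [run_full_study()]).
#' @return A [spectra_set] whose metadata carries nominal and
#'   gravimetric ("true") percent-of-label per API, level, series and
#'   replicate identifiers.
#' @export
simulate_set <- function(tab, form, library = default_library(),
                         grid = wavenumber_grid(), noise = noise_model(),
                         repacks = 3, seed = NULL) {
  stopifnot(inherits(form, "formulation"))
  if (!is.null(seed)) set.seed(seed)
  comp_names <- names(library)
  psplit <- placebo_split()
  n <- nrow(tab)
  has_series <- !is.null(tab$series_id)
  series_gain <- NULL
  if (has_series && noise$series_gain_sd > 0) {
    ids <- sort(unique(tab$series_id))
    series_gain <- stats::setNames(exp(stats::rnorm(length(ids), 0,
                                                    noise$series_gain_sd)), ids)
  }
  A <- matrix(0, n, length(grid$points))
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    masses <- c(
      AZ = tab[[paste0("mass_AZ_mg")]][i],
      AS = tab[[paste0("mass_AS_mg")]][i],
      DHA = if (!is.null(tab$mass_DHA_mg)) tab$mass_DHA_mg[i] else 0,
      cellulose = tab$mass_placebo_mg[i] * psplit[["cellulose"]],
      silica = tab$mass_placebo_mg[i] * psplit[["silica"]])
    masses[is.na(masses)] <- 0
    if (noise$weighing_sd > 0) {
      werr <- stats::rnorm(length(masses), 0, noise$weighing_sd)
      masses <- masses * (1 + werr * (masses > 0))
    }
    mf <- masses_to_fractions(masses[names(form$components)], form)
    frac_all <- masses / sum(masses)
    draws <- matrix(0, repacks, length(grid$points))
    for (r in seq_len(repacks))
      draws[r, ] <- mixture_spectrum(frac_all[comp_names], library, grid, noise)
    sp <- colMeans(draws)
    if (!is.null(series_gain))
      sp <- sp * series_gain[[as.character(tab$series_id[i])]]
    A[i, ] <- sp
    varied <- if (!is.null(tab$varied_api)) tab$varied_api[i] else NA_character_
    fixed <- if (!is.na(varied)) setdiff(form$apis, varied) else NA_character_
    nominal <- c(AZ = 100, AS = 100)
    if (!is.na(varied)) nominal[varied] <- tab$level_percent[i]
    meta[[i]] <- data.frame(
      sample = sprintf("%s_%s_L%03d_s%d_r%d",
                       substr(tab$role[i], 1, 3),
                       ifelse(is.na(varied), "mix", varied),
                       round(tab$level_percent[i]),
                       if (has_series) tab$series_id[i] else 1L,
                       tab$replicate_id[i]),
      role = tab$role[i],
      varied_api = varied,
      level_percent = tab$level_percent[i],
      series_id = if (has_series) tab$series_id[i] else 1L,
      replicate_id = tab$replicate_id[i],
      nominal_AZ_pct = nominal[["AZ"]],
      nominal_AS_pct = nominal[["AS"]],
      true_AZ_pct = mf$pct[["AZ"]],
      true_AS_pct = mf$pct[["AS"]],
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  meta$sample <- make.unique(meta$sample, sep = "_")
  spectra_set(grid, A, meta)
}

#' Simulate the specificity proof-set
#'
#' Spectra of the challenge mixtures from [specificity_mixtures()]
#' (placebo, 10% DHA spike, pure AS, pure AZ), one spectrum per mixture
#' per repeat.
#'
#' @param library,grid,noise,repacks,seed as in [simulate_set()].
#' @param repeats independent preparations per challenge.
#' @return A [spectra_set] with `label` metadata.
#' @export
simulate_challenges <- function(library = default_library(),
                                grid = wavenumber_grid(),
                                noise = noise_model(), repacks = 3,
                                repeats = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mixes <- specificity_mixtures()
  psplit <- placebo_split()
  rows <- mixes[rep(seq_len(nrow(mixes)), each = repeats), ]
  A <- matrix(0, nrow(rows), length(grid$points))
  for (i in seq_len(nrow(rows))) {
    masses <- c(AZ = rows$mass_AZ_mg[i], AS = rows$mass_AS_mg[i],
                DHA = rows$mass_DHA_mg[i],
                cellulose = rows$mass_placebo_mg[i] * psplit[["cellulose"]],
                silica = rows$mass_placebo_mg[i] * psplit[["silica"]])
    if (noise$weighing_sd > 0)
      masses <- masses * (1 + stats::rnorm(length(masses), 0, noise$weighing_sd) *
                            (masses > 0))
    frac <- masses / sum(masses)
    draws <- matrix(0, repacks, length(grid$points))
    for (r in seq_len(repacks))
      draws[r, ] <- mixture_spectrum(frac[names(library)], library, grid, noise)
    A[i, ] <- colMeans(draws)
  }
  meta <- data.frame(
    sample = make.unique(paste0("chal_", rows$label), sep = "_"),
    label = rows$label, role = "challenge",
    stringsAsFactors = FALSE)
  spectra_set(grid, A, meta)
}
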