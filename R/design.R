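#' Powder formulation for a hard gelatin capsule
#'
#' A formulation is a named list of component masses (mg per capsule) plus
#' the set of component names that are active pharmaceutical ingredients
#' (APIs). The label mass fractions derived from it drive every blend
#' design downstream.
#'
#' @param components named numeric vector of masses in mg per unit; names
#'   must be unique and all masses strictly positive.
#' @param apis character vector naming the API components (must be a subset
#'   of `names(components)`).
#' @return An object of class `formulation` with elements `components`,
#'   `apis`, `total_mg` and `fractions` (label mass fractions, summing to 1).
#' @examples
#' form <- hgc_formulation()
#' formulation_percentages(form)
#' @export
formulation <- function(components, apis) {
  if (is.null(names(components)) || anyDuplicated(names(components)))
    stop("component names must be present and unique", call. = FALSE)
  if (any(!is.finite(components)) || any(components <= 0))
    stop("invalid formulation: all component masses must be > 0", call. = FALSE)
  if (!all(apis %in% names(components)))
    stop("apis must name formulation components", call. = FALSE)
  total <- sum(components)
  structure(
    list(components = components, apis = apis, total_mg = total,
         fractions = components / total),
    class = "formulation")
}

#' Reference azithromycin/artesunate capsule formulation
#'
#' The fixed-dose combination fill: azithromycin dihydrate 419 mg,
#' artesunate 300 mg, microcrystalline cellulose 100 mg and colloidal
#' silica 1.638 mg per capsule. AZ and AS are the APIs; cellulose plus
#' silica form the placebo (excipient) phase.
#'
#' @return A [formulation] object.
#' @export
hgc_formulation <- function() {
  formulation(
    c(AZ = 419, AS = 300, cellulose = 100, silica = 1.638),
    apis = c("AZ", "AS"))
}

#' Component percentages (w/w) of a formulation
#'
#' @param form a [formulation] object.
#' @return Named numeric vector of percentages, summing to 100.
#' @export
formulation_percentages <- function(form) {
  stopifnot(inherits(form, "formulation"))
  if (form$total_mg <= 0)
    stop("invalid formulation: total mass must be > 0", call. = FALSE)
  100 * form$components / form$total_mg
}

# Cellulose:silica split of the excipient (placebo) phase, taken from the
# placebo mixture used for specificity work (4998.9 mg cellulose + 122.7 mg
# colloidal silica).
placebo_split <- function() {
  m <- c(cellulose = 4998.9, silica = 122.7)
  m / sum(m)
}

#' Generate a one-API-varied blend design
#'
#' Builds the reconstituted powder-blend design used for calibration and
#' validation: the varied API is weighed at each level (percent of label),
#' the other API stays at 100% of label, and placebo fills to the total
#' blend mass ("qsp" construction).
#'
#' @param form a [formulation] object with exactly two APIs.
#' @param varied_api name of the API whose content varies.
#' @param levels percent-of-label levels, strictly increasing, in (0, 200].
#' @param total_mg total blend mass in mg.
#' @param cal_replicates,val_replicates vials per level for the calibration
#'   and validation roles.
#' @return A `blend_design` object: per-level nominal masses of the varied
#'   API, fixed API and placebo, plus replicate counts.
#' @examples
#' bd <- blend_design(hgc_formulation(), "AZ")
#' set_sizes(bd)
#' @export
blend_design <- function(form, varied_api,
                         levels = seq(80, 120, by = 5),
                         total_mg = 2053.64,
                         cal_replicates = 6, val_replicates = 3) {
  stopifnot(inherits(form, "formulation"))
  if (!varied_api %in% form$apis)
    stop("varied_api must be one of the formulation APIs", call. = FALSE)
  if (length(form$apis) != 2L)
    stop("blend_design expects a two-API formulation", call. = FALSE)
  if (total_mg <= 0) stop("total_mg must be > 0", call. = FALSE)
  if (any(levels <= 0) || any(levels > 200) || is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing and within (0, 200]", call. = FALSE)

  fixed_api <- setdiff(form$apis, varied_api)
  w_v <- form$fractions[[varied_api]]
  w_f <- form$fractions[[fixed_api]]

  varied_mg <- levels / 100 * w_v * total_mg
  fixed_mg <- rep(w_f * total_mg, length(levels))
  placebo_mg <- total_mg - varied_mg - fixed_mg
  if (any(placebo_mg < 0))
    stop("infeasible design: placebo mass would be negative at level ",
         levels[which(placebo_mg < 0)[1]], "%", call. = FALSE)

  structure(
    list(formulation = form, varied_api = varied_api, fixed_api = fixed_api,
         levels = levels, total_mg = total_mg,
         varied_mg = varied_mg, fixed_mg = fixed_mg, placebo_mg = placebo_mg,
         cal_replicates = cal_replicates, val_replicates = val_replicates),
    class = "blend_design")
}

#' @export
print.blend_design <- function(x, ...) {
  cat(sprintf("Blend design: %s varied over %g-%g%% (%d levels), %s fixed at 100%%\n",
              x$varied_api, min(x$levels), max(x$levels), length(x$levels),
              x$fixed_api))
  cat(sprintf("  total %0.2f mg; %d calibration / %d validation vials per level\n",
              x$total_mg, x$cal_replicates, x$val_replicates))
  invisible(x)
}

#' Calibration/validation sample counts of a design
#'
#' @param design a [blend_design].
#' @return Named integer vector `c(calibration =, validation =)` equal to
#'   levels times replicates per role.
#' @export
set_sizes <- function(design) {
  stopifnot(inherits(design, "blend_design"))
  nl <- length(design$levels)
  c(calibration = as.integer(nl * design$cal_replicates),
    validation = as.integer(nl * design$val_replicates))
}

#' Expand a blend design into a per-sample table
#'
#' One row per (level, replicate) with the nominal component masses. This
#' long format is the interchange format of the package (written/read as
#' CSV) and the direct input of the spectra simulator.
#'
#' @param design a [blend_design].
#' @param role `"calibration"` or `"validation"`.
#' @return A data.frame with columns `level_percent`,
#'   `mass_<varied>_mg`, `mass_<fixed>_mg`, `mass_placebo_mg`, `total_mg`,
#'   `role`, `replicate_id`, `varied_api`.
#' @export
design_table <- function(design, role = c("calibration", "validation")) {
  stopifnot(inherits(design, "blend_design"))
  role <- match.arg(role)
  reps <- if (role == "calibration") design$cal_replicates else design$val_replicates
  nl <- length(design$levels)
  idx <- rep(seq_len(nl), each = reps)
  out <- data.frame(
    level_percent = design$levels[idx],
    v1 = design$varied_mg[idx],
    v2 = design$fixed_mg[idx],
    mass_placebo_mg = design$placebo_mg[idx],
    total_mg = design$total_mg,
    role = role,
    replicate_id = rep(seq_len(reps), times = nl),
    varied_api = design$varied_api,
    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mass_", c(design$varied_api, design$fixed_api), "_mg")
  out
}

#' Expand a blend design into a multi-series validation-study table
#'
#' The intermediate-precision validation study: a subset of levels, each
#' prepared independently in `series` runs (days/operators) of
#' `replicates` preparations. Nominal masses are scaled from the design's
#' label fractions.
#'
#' @param design a [blend_design].
#' @param levels levels to validate at (default 80/100/120% of label).
#' @param series number of independent series (days).
#' @param replicates preparations per series and level.
#' @param total_mg blend mass of each validation preparation.
#' @return A data.frame like [design_table()] with an extra `series_id`.
#' @export
validation_table <- function(design, levels = c(80, 100, 120),
                             series = 3, replicates = 3,
                             total_mg = 1026.82) {
  stopifnot(inherits(design, "blend_design"))
  if (!all(levels %in% design$levels))
    stop("validation levels must be design levels", call. = FALSE)
  if (series < 2 || replicates < 2)
    stop("need at least 2 series and 2 replicates per series", call. = FALSE)
  sub <- blend_design(design$formulation, design$varied_api, levels = levels,
                      total_mg = total_mg, cal_replicates = 1,
                      val_replicates = 1)
  nl <- length(levels)
  idx <- rep(seq_len(nl), each = series * replicates)
  out <- data.frame(
    level_percent = levels[idx],
    v1 = sub$varied_mg[idx],
    v2 = sub$fixed_mg[idx],
    mass_placebo_mg = sub$placebo_mg[idx],
    total_mg = total_mg,
    role = "validation_study",
    series_id = rep(rep(seq_len(series), each = replicates), times = nl),
    replicate_id = rep(seq_len(replicates), times = nl * series),
    varied_api = design$varied_api,
    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mass_", c(sub$varied_api, sub$fixed_api), "_mg")
  out
}

#' Degradant fraction of a specificity mixture
#'
#' Percent of dihydroartemisinin (DHA) relative to the artesunate + DHA
#' pool, the labelling convention for degradant-challenge mixtures (a
#' "10% DHA" blend has DHA at 10% of AS + DHA).
#'
#' @param as_mg,dha_mg masses (mg) of artesunate and DHA in the mixture.
#' @return Percent DHA of (AS + DHA).
#' @export
dha_fraction <- function(as_mg, dha_mg) {
  if (as_mg < 0 || dha_mg < 0) stop("masses must be >= 0", call. = FALSE)
  if (as_mg + dha_mg <= 0)
    stop("undefined fraction: AS + DHA mass is zero", call. = FALSE)
  100 * dha_mg / (as_mg + dha_mg)
}

#' Specificity proof-set compositions
#'
#' Challenge mixtures used to probe identification specificity: the
#' excipient placebo, a "10% DHA" degradant spike (261.88 mg AZ, 168.75 mg
#' AS, 18.75 mg DHA, 64.04 mg placebo), and the two pure APIs.
#'
#' @return A data.frame of component masses (mg) per challenge, one row per
#'   mixture, columns `label`, `mass_AZ_mg`, `mass_AS_mg`, `mass_DHA_mg`,
#'   `mass_placebo_mg`.
#' @export
specificity_mixtures <- function() {
  data.frame(
    label = c("placebo", "DHA10", "pure_AS", "pure_AZ"),
    mass_AZ_mg = c(0, 261.88, 0, 500),
    mass_AS_mg = c(0, 168.75, 500, 0),
    mass_DHA_mg = c(0, 18.75, 0, 0),
    mass_placebo_mg = c(5121.6, 64.04, 0, 0),
    stringsAsFactors = FALSE)
}

#' Write or read a design table as CSV
#'
#' @param tab a design table from [design_table()] or [validation_table()].
#' @param path file path.
#' @return `read_design_csv` returns the data.frame.
#' @export
write_design_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level_percent", "total_mg", "role", "replicate_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("malformed design CSV, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab
}
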