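# Shared fixtures, built in code at test time.

# coarse grid for fast unit tests (375 points over the instrument range)
coarse_grid <- function() wavenumber_grid(4000, 9999, 16)

# tiny two-component library (named after the APIs so design tables map
# onto it); excipients carry no bands
toy_library <- function() {
  list(
    AZ = band_set("AZ", centers = c(5500, 8000), widths = c(200, 250),
                  heights = c(0.6, 0.4)),
    AS = band_set("AS", centers = c(6200, 9000), widths = c(180, 300),
                  heights = c(0.5, 0.3)))
}

# default-condition AZ-varied calibration spectra, 54 samples
sim_calibration <- function(api = "AZ", seed = 17, noise = noise_model(),
                            role = "calibration") {
  form <- hgc_formulation()
  design <- blend_design(form, api)
  simulate_set(design_table(design, role), form, default_library(),
               wavenumber_grid(), noise, repacks = 3, seed = seed)
}

# published weighing records of the blend designs (mg): columns are
# varied API, fixed API, placebo, total; one table per API and role
printed_design_tables <- function() {
  list(
    AZ_cal = matrix(c(836.6, 750.0, 465.2, 2051.8, 889.1, 749.6, 413.5, 2052.2,
                      942.5, 750.6, 360.6, 2053.7, 993.5, 750.5, 308.2, 2052.2,
                      1046.5, 750.3, 256.3, 2053.1, 1099.5, 750.1, 203.4, 2053.0,
                      1150.8, 750.2, 151.4, 2052.4, 1206.4, 750.1, 98.8, 2055.3,
                      1256.6, 750.2, 46.5, 2053.3), ncol = 4, byrow = TRUE),
    AZ_val = matrix(c(418.6, 375.5, 232.4, 1026.5, 445.5, 375.2, 205.8, 1026.4,
                      471.5, 375.4, 180.2, 1027.1, 496.2, 375.3, 154.5, 1026.0,
                      523.4, 374.9, 128.1, 1026.4, 549.2, 375.6, 101.6, 1026.4,
                      577.8, 375.4, 76.1, 1029.3, 602.9, 375.6, 49.6, 1028.1,
                      628.3, 375.3, 23.6, 1027.2), ncol = 4, byrow = TRUE),
    AS_cal = matrix(c(602.1, 1046.5, 405.0, 2053.6, 637.5, 1046.1, 368.1, 2051.7,
                      675.6, 1047.0, 330.7, 2053.3, 712.6, 1046.1, 293.7, 2052.4,
                      749.9, 1045.0, 256.4, 2051.3, 787.8, 1047.3, 217.6, 2052.7,
                      824.6, 1045.9, 181.0, 2051.5, 862.3, 1047.7, 143.5, 2053.5,
                      900.1, 1045.5, 105.9, 2051.5), ncol = 4, byrow = TRUE),
    AS_val = matrix(c(301.8, 535.5, 202.9, 1040.2, 319.6, 524.1, 184.4, 1028.1,
                      338.0, 523.4, 165.5, 1026.9, 356.8, 523.0, 146.2, 1026.0,
                      375.6, 523.8, 127.7, 1027.1, 395.4, 522.9, 109.2, 1027.5,
                      412.6, 523.1, 90.8, 1026.5, 431.9, 523.3, 71.1, 1026.3,
                      450.3, 523.2, 53.5, 1027.0), ncol = 4, byrow = TRUE))
}

# cache the default seed-17 study so acceptance tests share one run
study_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(study_cache$report))
    study_cache$report <- run_full_study(run_config(seed = 17))
  study_cache$report
}
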