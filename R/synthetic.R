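#' Parameters for a synthetic pre/post-operative cohort
#'
#' Describes one cohort of eyes with a known ground-truth correction ratio,
#' emulating the three demonstration cohorts (with-the-rule,
#' against-the-rule, oblique; 25 eyes each). Defaults reflect typical
#' laser-refractive-surgery populations: mean preoperative cylinder 1.50 D
#' (SD 0.50 D, truncated at 0.25 D), axes tightly grouped around the
#' sector center (SD 5 degrees), a slight average undercorrection
#' (correction ratio 0.95), treatment-axis noise of 5 degrees, and an even
#' split of right and left eyes.
#'
#' @param astig_type `"WTR"`, `"ATR"` or `"oblique"`; sets the default axis
#'   center (90, 180 and 45 degrees respectively; 180 is the same meridian
#'   as 0).
#' @param n_eyes Number of eyes (>= 1).
#' @param preop_mag_mean,preop_mag_sd Mean and SD (diopters) of the
#'   preoperative cylinder magnitude, drawn from a normal truncated at
#'   0.25 D.
#' @param axis_center Center of the preoperative axis distribution
#'   (degrees); defaults by `astig_type`.
#' @param axis_spread_sd SD (degrees) of the wrapped-normal axis spread.
#' @param correction_ratio Ground-truth correction index: the achieved
#'   treatment magnitude as a fraction of the intended one.
#' @param postop_axis_noise_sd SD (degrees) of the treatment-axis
#'   misalignment.
#' @param os_fraction Fraction of left (OS) eyes.
#' @param cylinder_sign Notation used when emitting readings: `"negative"`
#'   (clinical refraction convention) or `"positive"`.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(astig_type = c("WTR", "ATR", "oblique"),
                          n_eyes = 25,
                          preop_mag_mean = 1.5,
                          preop_mag_sd = 0.5,
                          axis_center = NULL,
                          axis_spread_sd = 5,
                          correction_ratio = 0.95,
                          postop_axis_noise_sd = 5,
                          os_fraction = 0.5,
                          cylinder_sign = c("negative", "positive"),
                          seed = 1L) {
  astig_type <- match.arg(astig_type)
  cylinder_sign <- match.arg(cylinder_sign)
  axis_center <- axis_center %||%
    switch(astig_type, WTR = 90, ATR = 180, oblique = 45)
  p <- list(astig_type = astig_type, n_eyes = as.integer(n_eyes),
            preop_mag_mean = preop_mag_mean, preop_mag_sd = preop_mag_sd,
            axis_center = axis_center, axis_spread_sd = axis_spread_sd,
            correction_ratio = correction_ratio,
            postop_axis_noise_sd = postop_axis_noise_sd,
            os_fraction = os_fraction, cylinder_sign = cylinder_sign,
            seed = as.integer(seed))
  stopifnot(p$n_eyes >= 1L, p$preop_mag_mean > 0, p$preop_mag_sd >= 0,
            p$correction_ratio >= 0, p$axis_spread_sd >= 0,
            p$postop_axis_noise_sd >= 0,
            p$os_fraction >= 0, p$os_fraction <= 1)
  class(p) <- "cohort_params"
  p
}

rnorm_trunc_low <- function(n, mean, sd, low) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < low)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

round_step <- function(x, step) round(x / step) * step

#' Generate a synthetic cohort with known ground truth
#'
#' For each eye: the side is drawn by `os_fraction`; the preoperative
#' magnitude from a truncated normal; the preoperative axis from a wrapped
#' normal around the sector center. The postoperative reading is
#' constructed so that the achieved change (SIA) has magnitude
#' `correction_ratio` times the intended one (TIA), applied at the intended
#' axis perturbed by the treatment-axis noise: the applied treatment is
#' subtracted from the preoperative vector in doubled-angle rectangular
#' space and the remainder converted back to a cylinder reading in the
#' chosen sign convention.
#'
#' With `round_clinical = TRUE` (default) magnitudes are rounded to 0.25 D
#' steps and axes to whole degrees, mimicking clinical refraction
#' granularity. Rounding happens after outcome construction, so exact
#' recovery of the correction ratio (every defined CI equal to it when the
#' axis noise is zero) holds only with rounding disabled.
#'
#' @param params A [cohort_params()] object.
#' @param round_clinical Round emitted readings to clinical granularity.
#' @return An `astig_dataset` of `params$n_eyes` records.
#' @examples
#' p <- cohort_params("WTR", n_eyes = 5, correction_ratio = 0.9,
#'                    postop_axis_noise_sd = 0, seed = 7)
#' analyze_eyes(generate_cohort(p, round_clinical = FALSE))$ci  # all 0.9
#' @export
generate_cohort <- function(params, round_clinical = TRUE) {
  stopifnot(inherits(params, "cohort_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)

  n <- params$n_eyes
  eye <- ifelse(stats::runif(n) < params$os_fraction, "OS", "OD")
  pre_mag <- rnorm_trunc_low(n, params$preop_mag_mean, params$preop_mag_sd, 0.25)
  pre_axis <- wrap_axis(stats::rnorm(n, params$axis_center, params$axis_spread_sd))

  # applied treatment: ratio x TIA magnitude at the intended axis + noise
  treat_mag <- params$correction_ratio * pre_mag
  treat_axis <- wrap_axis(pre_axis + stats::rnorm(n, 0, params$postop_axis_noise_sd))
  pre_r <- polar_to_rect(pre_mag, pre_axis)
  tr_r <- polar_to_rect(treat_mag, treat_axis)
  post <- rect_to_polar(pre_r$x - tr_r$x, pre_r$y - tr_r$y)
  post_mag <- post$magnitude
  post_axis <- post$axis

  if (round_clinical) {
    pre_mag <- round_step(pre_mag, 0.25)
    post_mag <- round_step(post_mag, 0.25)
    pre_axis <- wrap_axis(round(pre_axis))
    post_axis <- wrap_axis(round(post_axis))
  }

  if (params$cylinder_sign == "negative") {
    records <- tibble::tibble(
      eye = eye,
      preop_mag = -pre_mag, preop_axis = wrap_axis(pre_axis + 90),
      postop_mag = -post_mag, postop_axis = wrap_axis(post_axis + 90)
    )
  } else {
    records <- tibble::tibble(
      eye = eye,
      preop_mag = pre_mag, preop_axis = pre_axis,
      postop_mag = post_mag, postop_axis = post_axis
    )
  }
  records$source_row <- seq_len(n)
  new_astig_dataset(records)
}

#' Write the three demonstration cohorts to disk
#'
#' Emits `WTR`, `ATR` and `Oblique` files of 25 synthetic eyes each, with
#' fixed documented seeds (101, 102, 103) and default cohort parameters, in
#' the same dialects [read_dataset()] reads. Re-running produces identical
#' file contents.
#'
#' @param outdir Output directory (created if needed).
#' @param dialect `"xlsx"` (default) or `"csv"`.
#' @return Character vector of the three written paths.
#' @export
emit_demo_files <- function(outdir, dialect = c("xlsx", "csv")) {
  dialect <- match.arg(dialect)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  seeds <- c(WTR = 101L, ATR = 102L, Oblique = 103L)
  types <- c(WTR = "WTR", ATR = "ATR", Oblique = "oblique")
  paths <- character(0)
  for (nm in names(seeds)) {
    d <- generate_cohort(cohort_params(types[[nm]], n_eyes = 25, seed = seeds[[nm]]))
    path <- file.path(outdir, paste0(nm, ".", dialect))
    write_dataset(d, path, dialect)
    paths <- c(paths, path)
  }
  paths
}
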