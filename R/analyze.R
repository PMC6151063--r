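#' Target-induced astigmatism vector under an emmetropic target
#'
#' The TIA is the astigmatic change the surgery intended to induce. With an
#' emmetropic target (the only target this tool supports; the input format
#' carries no target column) the intended change is the full preoperative
#' astigmatism, so the TIA equals the normalized, mirrored preoperative
#' vector.
#'
#' @param magnitude,axis Preoperative positive-cylinder vector(s), already
#'   mirrored for left eyes.
#' @return A tibble with columns `magnitude` and `axis`.
#' @export
compute_tia <- function(magnitude, axis) {
  stopifnot(is.numeric(magnitude), is.numeric(axis),
            length(magnitude) == length(axis))
  tibble::tibble(magnitude = magnitude, axis = axis)
}

#' Surgically-induced astigmatism vector
#'
#' The SIA is the astigmatic change actually achieved: the postoperative
#' vector subtracted from the preoperative vector in doubled-angle
#' rectangular coordinates, with magnitude `sqrt(SIA_x^2 + SIA_y^2)`.
#'
#' @param pre_magnitude,pre_axis Preoperative positive-cylinder vector(s).
#' @param post_magnitude,post_axis Postoperative positive-cylinder vector(s).
#' @return A tibble with columns `magnitude` and `axis`.
#' @export
compute_sia <- function(pre_magnitude, pre_axis, post_magnitude, post_axis) {
  pre <- polar_to_rect(pre_magnitude, pre_axis)
  post <- polar_to_rect(post_magnitude, post_axis)
  rect_to_polar(pre$x - post$x, pre$y - post$y)
}

#' Difference vector
#'
#' The DV is the remaining astigmatic error: TIA minus SIA as a vectorial
#' difference in doubled-angle space. A perfect outcome has a null DV. Under
#' an emmetropic target the DV equals the (normalized, mirrored)
#' postoperative vector.
#'
#' @param tia_magnitude,tia_axis TIA vector(s).
#' @param sia_magnitude,sia_axis SIA vector(s).
#' @return A tibble with columns `magnitude` and `axis`.
#' @export
compute_dv <- function(tia_magnitude, tia_axis, sia_magnitude, sia_axis) {
  tia <- polar_to_rect(tia_magnitude, tia_axis)
  sia <- polar_to_rect(sia_magnitude, sia_axis)
  rect_to_polar(tia$x - sia$x, tia$y - sia$y)
}

#' Correction index
#'
#' CI = SIA magnitude / TIA magnitude. A value of 1 indicates an optimal
#' correction; values above 1 indicate overcorrection and below 1
#' undercorrection. Eyes with zero TIA magnitude (no intended treatment)
#' have an undefined CI, returned as `NA`.
#'
#' @param sia_magnitude,tia_magnitude Numeric vectors of SIA and TIA
#'   magnitudes (diopters).
#' @return Numeric vector of correction indices, `NA` where TIA is zero.
#' @export
compute_ci <- function(sia_magnitude, tia_magnitude) {
  stopifnot(is.numeric(sia_magnitude), is.numeric(tia_magnitude),
            length(sia_magnitude) == length(tia_magnitude))
  ifelse(tia_magnitude > 0, sia_magnitude / tia_magnitude, NA_real_)
}

#' Run the full Alpins per-eye analysis on a dataset
#'
#' Pipeline per eye: convert both readings to positive cylinder, mirror the
#' axes of left (OS) eyes, take the TIA as the preoperative vector
#' (emmetropic target), compute the SIA by doubled-angle rectangular
#' subtraction, the DV as TIA minus SIA, and the CI as the SIA/TIA magnitude
#' ratio. All quantities are computed in one consistent (mirrored) frame,
#' which is also the frame in which they are plotted.
#'
#' @param dataset An `astig_dataset` (from [read_dataset()] or
#'   [generate_cohort()]), or any data frame with columns `eye`,
#'   `preop_mag`, `preop_axis`, `postop_mag`, `postop_axis`.
#' @return A tibble of class `astig_results` with one row per eye and
#'   columns `eye`, `tia_mag`, `tia_axis`, `sia_mag`, `sia_axis`, `dv_mag`,
#'   `dv_axis`, `ci` (NA for zero-TIA eyes).
#' @examples
#' d <- generate_cohort(cohort_params("WTR", n_eyes = 5, seed = 1))
#' analyze_eyes(d)
#' @export
analyze_eyes <- function(dataset) {
  need <- c("eye", "preop_mag", "preop_axis", "postop_mag", "postop_axis")
  if (!all(need %in% names(dataset))) {
    stop("dataset must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(dataset) == 0L) stop("dataset has no records to analyze")
  eye <- toupper(dataset$eye)

  pre <- to_positive_cylinder(dataset$preop_mag, dataset$preop_axis)
  post <- to_positive_cylinder(dataset$postop_mag, dataset$postop_axis)
  pre$axis <- mirror_os_axis(pre$axis, eye)
  post$axis <- mirror_os_axis(post$axis, eye)

  tia <- compute_tia(pre$magnitude, pre$axis)
  sia <- compute_sia(pre$magnitude, pre$axis, post$magnitude, post$axis)
  dv <- compute_dv(tia$magnitude, tia$axis, sia$magnitude, sia$axis)
  ci <- compute_ci(sia$magnitude, tia$magnitude)

  out <- tibble::tibble(
    eye = eye,
    tia_mag = tia$magnitude, tia_axis = tia$axis,
    sia_mag = sia$magnitude, sia_axis = sia$axis,
    dv_mag = dv$magnitude, dv_axis = dv$axis,
    ci = ci
  )
  class(out) <- c("astig_results", class(out))
  out
}

#' Summarize a population of astigmatism vectors
#'
#' Computes the arithmetic means and sample standard deviations of the
#' doubled-angle X and Y components (the quantities shown in the plot
#' call-out boxes), the vector mean (the polar vector recovered from the
#' component means, plotted as the red diamond), and the arithmetic mean of
#' the magnitudes.
#'
#' @param magnitude,axis Numeric vectors describing >= 1 astigmatism
#'   vector(s).
#' @return A list of class `astig_cohort_summary` with elements `mean_x`,
#'   `mean_y`, `sd_x`, `sd_y` (diopters; SDs use the n-1 denominator and are
#'   0 when n = 1), `vector_mean` (one-row tibble `magnitude`/`axis`),
#'   `arith_mean_magnitude`, and `n`.
#' @export
summarize_vectors <- function(magnitude, axis) {
  stopifnot(length(magnitude) == length(axis))
  if (length(magnitude) == 0L) stop("cannot summarize an empty vector population")
  r <- polar_to_rect(magnitude, axis)
  n <- length(magnitude)
  sdz <- function(v) if (n == 1L) 0 else stats::sd(v)
  out <- list(
    mean_x = mean(r$x), mean_y = mean(r$y),
    sd_x = sdz(r$x), sd_y = sdz(r$y),
    vector_mean = rect_to_polar(mean(r$x), mean(r$y)),
    arith_mean_magnitude = mean(magnitude),
    n = n
  )
  class(out) <- "astig_cohort_summary"
  out
}

#' Summarize correction indices
#'
#' The CI panel reports a geometric mean, which is only defined over
#' strictly positive values: undefined (`NA`, zero-TIA eyes) and zero CIs
#' are excluded and counted.
#'
#' @param ci Numeric vector of correction indices (may contain `NA`).
#' @return A list of class `astig_ci_summary` with elements
#'   `geometric_mean`, `n_defined`, `n_excluded`.
#' @export
summarize_ci <- function(ci) {
  stopifnot(is.numeric(ci))
  if (length(ci) == 0L) stop("cannot summarize an empty CI collection")
  ok <- !is.na(ci) & ci > 0
  if (!any(ok)) {
    stop("no positive, defined correction indices to summarize ",
         "(all eyes had zero TIA or zero SIA)")
  }
  out <- list(
    geometric_mean = exp(mean(log(ci[ok]))),
    n_defined = sum(ok),
    n_excluded = sum(!ok)
  )
  class(out) <- "astig_ci_summary"
  out
}

#' @export
print.astig_cohort_summary <- function(x, ...) {
  cat(sprintf("Vector population summary (n = %d)\n", x$n))
  cat(sprintf("  X: %.2f ± %.2f D   Y: %.2f ± %.2f D\n",
              x$mean_x, x$sd_x, x$mean_y, x$sd_y))
  cat(sprintf("  vector mean: %.2f D @ %.0f°   arithmetic mean |v|: %.2f D\n",
              x$vector_mean$magnitude, x$vector_mean$axis,
              x$arith_mean_magnitude))
  invisible(x)
}

#' @export
print.astig_ci_summary <- function(x, ...) {
  cat(sprintf("Correction index summary: geometric mean %.2f (n = %d, excluded %d)\n",
              x$geometric_mean, x$n_defined, x$n_excluded))
  invisible(x)
}
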