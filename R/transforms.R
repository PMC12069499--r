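#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector onto standard-normal quantiles using the Blom
#' rank offset: \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}, where \eqn{r} is the
#' 1-based rank among non-missing values (ties get the average rank) and
#' \eqn{n} the number of non-missing values. The transformation is the
#' standard pre-processing step for skewed quantitative traits before
#' regression, and is invariant under any strictly monotone transform of
#' its input.
#'
#' @param values Numeric vector; `NA`s propagate to the output.
#' @return A numeric vector of the same length with attribute `transform`
#'   set to `"inverse_normal"`.
#' @examples
#' inverse_normal_transform(c(1, 2, 3))
#' @export
inverse_normal_transform <- function(values) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2L) stop("inverse normal transform needs >= 2 non-missing values",
                   call. = FALSE)
  out <- rep_len(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  structure(out, transform = "inverse_normal")
}

#' Apply a named transform to a trait vector
#'
#' Dispatch for the per-trait transform registry: `"none"`, `"log"`
#' (natural log), `"log2"`, `"inverse_normal"` or `"zscore"`. Logs require
#' strictly positive non-missing inputs.
#'
#' @param values Numeric vector.
#' @param transform One of `"none"`, `"log"`, `"log2"`, `"inverse_normal"`,
#'   `"zscore"`.
#' @return Transformed numeric vector.
#' @export
transform_trait <- function(values,
                            transform = c("none", "log", "log2",
                                          "inverse_normal", "zscore")) {
  transform <- match.arg(transform)
  if (transform %in% c("log", "log2") && any(values <= 0, na.rm = TRUE))
    stop(sprintf("'%s' transform requires strictly positive values", transform),
         call. = FALSE)
  switch(transform,
         none = values,
         log = log(values),
         log2 = log2(values),
         inverse_normal = inverse_normal_transform(values),
         zscore = zscore(values))
}

#' Default per-trait transform registry
#'
#' Lipid and insulin-axis traits are log-transformed; skewed anthropometric
#' traits (skinfolds) get the inverse normal transform; the remainder are
#' left untouched. Override by passing a named character vector wherever a
#' `transforms` argument is accepted.
#'
#' @return Named character vector mapping trait name to transform.
#' @export
default_transforms <- function() {
  c(fasting_insulin = "log", homa2b = "log", homa2s = "log",
    triglycerides = "log", cholesterol = "log", hdl_cholesterol = "log",
    ldl_cholesterol = "log", skinfolds = "inverse_normal")
}

transform_for <- function(trait, transforms) {
  if (!is.null(transforms) && trait %in% names(transforms))
    unname(transforms[[trait]]) else "none"
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_m Height in metres.
#' @return BMI in kg/m^2.
#' @export
derive_bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0, na.rm = TRUE))
    stop("height must be positive", call. = FALSE)
  if (any(weight_kg <= 0, na.rm = TRUE))
    stop("weight must be positive", call. = FALSE)
  weight_kg / height_m^2
}

#' Waist-to-hip ratio
#'
#' @param waist_cm Waist circumference (cm).
#' @param hip_cm Hip circumference (cm).
#' @return Waist/hip ratio.
#' @export
derive_whr <- function(waist_cm, hip_cm) {
  if (any(hip_cm <= 0, na.rm = TRUE))
    stop("hip circumference must be positive", call. = FALSE)
  if (any(waist_cm <= 0, na.rm = TRUE))
    stop("waist circumference must be positive", call. = FALSE)
  waist_cm / hip_cm
}

#' LDL-cholesterol by the Friedewald formula
#'
#' LDL = TC - HDL - TG/divisor. With concentrations in mmol/l the divisor
#' is 2.2; with mg/dl use 5. The formula is invalid at high triglyceride
#' concentrations: values above `tg_max` yield `NA` and a warning.
#'
#' @param total_chol Total cholesterol.
#' @param hdl HDL-cholesterol.
#' @param triglycerides Triglycerides.
#' @param divisor 2.2 for mmol/l (default) or 5 for mg/dl.
#' @param tg_max Triglyceride validity bound (default 4.5 mmol/l).
#' @return Numeric vector of LDL-cholesterol; `NA` where triglycerides
#'   exceed the bound.
#' @export
derive_ldl_friedewald <- function(total_chol, hdl, triglycerides,
                                  divisor = 2.2, tg_max = 4.5) {
  ldl <- total_chol - hdl - triglycerides / divisor
  high <- !is.na(triglycerides) & triglycerides > tg_max
  if (any(high)) {
    ldl[high] <- NA_real_
    warning(sprintf(
      "%d value(s) with triglycerides > %g: Friedewald formula invalid, set to NA",
      sum(high), tg_max), call. = FALSE)
  }
  ldl
}
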