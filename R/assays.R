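#' Four-parameter logistic dose-response function
#'
#' `viability(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`.
#' With `hill > 0` viability falls with dose from `top` to `bottom`, and
#' `viability(ic50) = (top + bottom) / 2`.
#'
#' @param dose positive dose(s), in the units of `ic50`.
#' @param ic50 midpoint dose.
#' @param hill slope.
#' @param top,bottom asymptotic viabilities (percent of vehicle control).
#' @export
four_pl <- function(dose, ic50, hill = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Construct a dose-response curve
#'
#' @param dose,viability equal-length numeric vectors (dose in µM, viability
#'   in percent of vehicle control); replicate measurements repeat the dose.
#' @param sample label.
#' @return a `dose_response` data frame.
#' @export
dose_response <- function(dose, viability, sample = NA_character_) {
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop_input("doses must be positive and finite")
  }
  if (any(!is.finite(viability))) stop_input("viability must be finite")
  structure(data.frame(dose = dose, viability = viability),
            class = c("dose_response", "data.frame"), sample = sample)
}

#' Read dose-response viability tables from CSV
#'
#' Expects columns `sample`, `dose_uM`, `replicate`, `viability_pct`.
#'
#' @param path CSV file.
#' @return named list of `dose_response`, one per sample.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "dose_uM", "replicate", "viability_pct")
  if (!all(need %in% names(df))) {
    stop_format("dose-response CSV needs columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$sample), function(d) {
    dose_response(d$dose_uM, d$viability_pct, sample = d$sample[[1L]])
  })
}

#' Fit a four-parameter logistic and estimate the IC50
#'
#' Least-squares 4PL fit on log10 dose by Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Starting values: `top = max(viability)`,
#' `bottom = min(viability)`, `ic50 = median dose`, `hill = 1`; the midpoint
#' is bounded in `(0, 10 x max dose]`. The IC50 is the dose at the half-way
#' point between the fitted top and bottom.
#'
#' The `converged` flag is honest: it is `FALSE` when the optimiser fails
#' *or* when the fitted curve is not a decreasing viability curve
#' (`hill <= 0` or `top <= bottom`), e.g. on viability that rises with dose.
#' No exception is thrown for non-convergence.
#'
#' @param curve a [dose_response()] with >= 4 distinct doses.
#' @return an `ic50_fit` with components `coefficients` (named `top`,
#'   `bottom`, `hill`, `ic50`), `converged`, `rss`, `data`.
#' @export
fit_ic50 <- function(curve) {
  d <- as.data.frame(curve)
  if (length(unique(d$dose)) < 4L) {
    stop_input("need >= 4 distinct doses to fit a 4PL; got ",
               length(unique(d$dose)))
  }
  ld <- log10(d$dose)
  start <- list(top = max(d$viability), bottom = min(d$viability),
                hill = 1, lic = log10(stats::median(d$dose)))
  upper <- c(top = Inf, bottom = Inf, hill = Inf,
             lic = log10(10 * max(d$dose)))
  lower <- c(top = -Inf, bottom = -Inf, hill = -Inf, lic = -12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      viability ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - lic))),
      data = data.frame(viability = d$viability, ld = ld),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    co <- c(top = NA_real_, bottom = NA_real_, hill = NA_real_,
            ic50 = NA_real_)
    return(structure(list(coefficients = co, converged = FALSE, rss = NA_real_,
                          data = d, sample = attr(curve, "sample")),
                     class = "ic50_fit"))
  }
  cf <- stats::coef(fit)
  co <- c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
          hill = unname(cf["hill"]), ic50 = unname(10^cf["lic"]))
  ok <- isTRUE(fit$convInfo$isConv) && co["top"] > co["bottom"] &&
    co["hill"] > 0
  structure(list(coefficients = co, converged = unname(ok),
                 rss = sum(stats::residuals(fit)^2), data = d,
                 sample = attr(curve, "sample")),
            class = "ic50_fit")
}

#' @export
coef.ic50_fit <- function(object, ...) object$coefficients

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  co <- x$coefficients
  cat(sprintf("<ic50_fit>%s IC50 = %s uM (top %s, bottom %s, hill %s)%s\n",
              if (!is.na(x$sample %||% NA)) paste0(" ", x$sample) else "",
              format(co["ic50"], digits = digits),
              format(co["top"], digits = digits),
              format(co["bottom"], digits = digits),
              format(co["hill"], digits = digits),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose %||% newdata
  four_pl(dose, co["ic50"], co["hill"], co["top"], co["bottom"])
}

#' @export
residuals.ic50_fit <- function(object, ...) {
  object$data$viability - predict(object)
}

#' @export
plot.ic50_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$dose, d$viability, log = "x", xlab = "dose (uM)",
                 ylab = "viability (%)", ...)
  dd <- 10^seq(log10(min(d$dose)), log10(max(d$dose)), length.out = 200)
  graphics::lines(dd, predict(x, dd))
  graphics::abline(v = x$coefficients["ic50"], lty = 2)
  invisible(x)
}

significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' Summarize replicate IC50s and compare against a reference group
#'
#' Arithmetic mean of the replicate IC50s and a two-sided independent
#' two-sample t-test against the reference group (classic pooled Student test
#' by default; Welch available). Stars follow the usual convention
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). Display rounding of the
#' mean is to 2 decimals; stored values keep full precision.
#'
#' @param ic50s numeric replicate IC50s, or a list of `ic50_fit`s.
#' @param reference the comparison group, same forms; `NULL` to skip the test.
#' @param var_equal use the pooled-variance Student test (default `TRUE`).
#' @return an `ic50_summary`: `ic50s`, `mean`, `reference_mean`, `p_value`,
#'   `stars`.
#' @export
summarize_ic50 <- function(ic50s, reference = NULL, var_equal = TRUE) {
  pull <- function(x) {
    if (is.numeric(x)) x
    else vapply(x, function(f) unname(coef(f)["ic50"]), numeric(1))
  }
  v <- pull(ic50s)
  r <- if (is.null(reference)) NULL else pull(reference)
  p <- NA_real_
  if (!is.null(r)) {
    if (length(v) < 2L || length(r) < 2L) {
      warning("singleton group: t-test skipped, reporting means only")
    } else {
      p <- stats::t.test(v, r, var.equal = var_equal)$p.value
    }
  }
  structure(list(ic50s = v, mean = mean(v),
                 reference_mean = if (is.null(r)) NA_real_ else mean(r),
                 p_value = p, stars = significance_stars(p),
                 var_equal = var_equal),
            class = "ic50_summary")
}

#' @export
print.ic50_summary <- function(x, ...) {
  cat(sprintf("<ic50_summary> mean IC50 %.2f uM (n = %d)%s\n",
              round(x$mean, 2), length(x$ic50s),
              if (!is.na(x$p_value))
                sprintf("  vs reference %.2f: p = %.4g %s",
                        round(x$reference_mean, 2), x$p_value, x$stars)
              else ""))
  invisible(x)
}

#' Delta-Ct relative quantification
#'
#' `delta_ct = mean Ct(reference assay) - mean Ct(target assay)`, and
#' `relative_expression = 2^delta_ct`. Triplicate Cts are expected but any
#' positive number of values per assay works. When the corresponding parental
#' measurement is supplied, expression is additionally normalised so that the
#' parental sample itself reads 1.
#'
#' @param target_ct numeric Ct values for the assay of interest.
#' @param reference_ct numeric Ct values for the reference assay (e.g.
#'   RNU48 for miRNAs, GAPDH for genes).
#' @param target,sample labels.
#' @param parental an optional `qpcr_measurement` of the parental sample.
#' @return a `qpcr_measurement`: `delta_ct`, `relative_expression`, and
#'   `relative_to_parental` when `parental` is given.
#' @export
delta_ct <- function(target_ct, reference_ct, target = NA_character_,
                     sample = NA_character_, parental = NULL) {
  if (is.null(reference_ct) || !length(reference_ct)) {
    stop_input("reference Ct values are required")
  }
  if (!length(target_ct)) stop_input("target Ct values are required")
  if (any(c(target_ct, reference_ct) <= 0)) stop_input("Ct values must be positive")
  dct <- mean(reference_ct) - mean(target_ct)
  rel <- 2^dct
  rtp <- if (!is.null(parental)) rel / parental$relative_expression else NA_real_
  structure(list(target = target, sample = sample, delta_ct = dct,
                 relative_expression = rel, relative_to_parental = rtp),
            class = "qpcr_measurement")
}

#' @export
print.qpcr_measurement <- function(x, ...) {
  cat(sprintf("<qpcr_measurement> %s/%s  dCt = %.3f  2^dCt = %.4g%s\n",
              x$target, x$sample, x$delta_ct, x$relative_expression,
              if (!is.na(x$relative_to_parental))
                sprintf("  (%.4g x parental)", x$relative_to_parental) else ""))
  invisible(x)
}

#' Compare relative expression between two groups (Mann-Whitney)
#'
#' Wilcoxon rank-sum test on per-replicate relative-expression values, the
#' customary non-parametric comparison for qPCR triplicates.
#'
#' @param x,y numeric relative-expression values for the two groups.
#' @return htest object from [stats::wilcox.test()].
#' @export
qpcr_compare <- function(x, y) {
  stats::wilcox.test(x, y, exact = TRUE)
}

#' Read qPCR Ct tables from CSV and quantify per sample
#'
#' Expects columns `sample`, `assay`, `role` (`target` or `reference`), `ct`.
#' Each sample must carry exactly one target and one reference assay.
#'
#' @param path CSV file.
#' @param parental_sample optional sample label used to normalise the others.
#' @return named list of `qpcr_measurement`.
#' @export
read_qpcr <- function(path, parental_sample = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "assay", "role", "ct")
  if (!all(need %in% names(df))) {
    stop_format("qPCR CSV needs columns: ", paste(need, collapse = ", "))
  }
  one <- function(d, parental = NULL) {
    tg <- d[d$role == "target", , drop = FALSE]
    rf <- d[d$role == "reference", , drop = FALSE]
    if (!nrow(rf)) stop_input("sample ", d$sample[[1L]], " has no reference Cts")
    delta_ct(tg$ct, rf$ct, target = tg$assay[[1L]], sample = d$sample[[1L]],
             parental = parental)
  }
  by_sample <- split(df, df$sample)
  par_m <- NULL
  if (!is.null(parental_sample)) {
    if (!parental_sample %in% names(by_sample)) {
      stop_input("parental sample '", parental_sample, "' not in file")
    }
    par_m <- one(by_sample[[parental_sample]])
  }
  lapply(by_sample, one, parental = par_m)
}
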