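#' Normalize raw viability readings against the plate controls
#'
#' Converts raw plate-reader luminescence into percent viability using the
#' plate's own controls: the NDNL group (no drug, no light) defines 100%
#' viability, the MO group (media only, no cells) defines 0%:
#' \deqn{v = 100\,(raw - \overline{MO}) / (\overline{NDNL} - \overline{MO})}
#'
#' @param table Data frame with columns `well`, `group`, `role`,
#'   `dose_Jcm2`, `luminescence` (a "ViabilityTable"); NDNL and MO must each
#'   be present with at least 2 replicates.
#' @return The table with a `viability_pct` column added.
#' @export
normalize_viability <- function(table) {
  need <- c("group", "role", "dose_Jcm2", "luminescence")
  if (!all(need %in% names(table))) {
    abort(sprintf("viability table needs columns %s",
                  paste(need, collapse = ", ")))
  }
  for (role in c("NDNL", "MO")) {
    if (sum(table$role == role) < 2) {
      abort(sprintf("control group %s needs at least 2 replicates", role))
    }
  }
  m_ndnl <- mean(table$luminescence[table$role == "NDNL"])
  m_mo <- mean(table$luminescence[table$role == "MO"])
  if (m_ndnl <= m_mo) {
    abort("NDNL control mean must exceed MO control mean: controls are degenerate")
  }
  dplyr::mutate(
    as_tibble(table),
    viability_pct = 100 * (.data$luminescence - m_mo) / (m_ndnl - m_mo)
  )
}

# 4PL predictor: v(d) = bottom + (top - bottom) / (1 + (d / ec50)^h)
# ec50 carried as log10 internally; d = 0 maps to v = top for h > 0.
pl4_predict <- function(d, top, bottom, log10_ec50, hill) {
  frac <- ifelse(d <= 0, 0, exp(hill * (log(d) - log(10) * log10_ec50)))
  bottom + (top - bottom) / (1 + frac)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the variable-slope (four-parameter) logistic model
#' \deqn{v(d) = bottom + \frac{top - bottom}{1 + (d/EC_{50})^{h}}}
#' to viability-versus-dose data, the same model Prism calls "Inhibitor vs.
#' normalized response - Variable slope". At d = EC50 the fitted curve
#' equals (top + bottom)/2 exactly. EC50 is fitted on a log10 scale;
#' starting values are: top/bottom from the extreme-dose means, EC50 from
#' the interpolated 50%-crossing of group means, hill = 1.
#'
#' @param doses Dose vector (J/cm2), >= 0; at least 4 distinct values.
#' @param viabilities Percent viabilities, same length.
#' @param constrain_top,constrain_bottom Optional fixed values (e.g. 100 and
#'   0) to fit the constrained variants; default both free.
#' @return An object of class `pdt_4pl` with elements `top`, `bottom`,
#'   `ec50`, `hill`, a coefficient table with standard errors, `sigma`,
#'   `data`, and the underlying `nls` object. Methods: [tidy()], [glance()],
#'   `predict()`, [autoplot()].
#' @examples
#' d <- rep(c(1, 2, 4, 8, 16, 32), each = 3)
#' v <- 100 / (1 + (d / 6)^2)
#' fit_4pl(d, v)
#' @export
fit_4pl <- function(doses, viabilities, constrain_top = NULL,
                    constrain_bottom = NULL) {
  if (length(doses) != length(viabilities)) {
    abort("doses and viabilities must have the same length")
  }
  keep <- is.finite(doses) & is.finite(viabilities)
  doses <- doses[keep]
  viabilities <- viabilities[keep]
  if (length(unique(doses)) < 4) {
    abort("need at least 4 distinct doses to fit a 4PL model")
  }
  if (any(doses < 0)) abort("doses must be non-negative")

  means <- dplyr::summarise(
    dplyr::group_by(tibble(d = doses, v = viabilities), .data$d),
    v = mean(.data$v), .groups = "drop"
  ) |>
    dplyr::arrange(.data$d)
  if (max(means$v) - min(means$v) < 1e-8 || var(viabilities) == 0) {
    abort("no dose effect: response is flat across doses")
  }

  top0 <- constrain_top %||% means$v[1]
  bottom0 <- constrain_bottom %||% means$v[nrow(means)]
  # EC50 start: dose where the group means cross halfway between extremes
  halfway <- (top0 + bottom0) / 2
  pos <- means[means$d > 0, ]
  cross <- which(diff(sign(pos$v - halfway)) != 0)
  ec50_0 <- if (length(cross) > 0) {
    i <- cross[1]
    exp(approx(pos$v[c(i, i + 1)], log(pos$d[c(i, i + 1)]), xout = halfway,
               ties = "ordered")$y)
  } else {
    exp(mean(log(pos$d)))
  }
  if (!is.finite(ec50_0) || ec50_0 <= 0) ec50_0 <- stats::median(pos$d)

  dat <- tibble(d = doses, v = viabilities)
  start <- list(log10_ec50 = log10(ec50_0), hill = 1)
  if (is.null(constrain_top)) start$top <- top0
  if (is.null(constrain_bottom)) start$bottom <- bottom0

  formula_rhs <- "pl4_predict(d, top, bottom, log10_ec50, hill)"
  env <- new.env(parent = environment())
  if (!is.null(constrain_top)) assign("top", constrain_top, envir = env)
  if (!is.null(constrain_bottom)) assign("bottom", constrain_bottom, envir = env)
  fml <- stats::as.formula(paste("v ~", formula_rhs), env = env)

  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(sprintf("4PL fit did not converge: %s", conditionMessage(e)))
    }
  )
  est <- as.list(coef(fit))
  cf <- summary(fit)$coefficients
  top <- constrain_top %||% est$top
  bottom <- constrain_bottom %||% est$bottom
  ec50 <- 10^est$log10_ec50
  if (!(bottom < top)) {
    abort("4PL fit degenerate: fitted bottom is not below fitted top")
  }

  # delta-method SE for EC50 from the log10 fit scale
  se <- setNames(cf[, "Std. Error"], rownames(cf))
  ec50_se <- if ("log10_ec50" %in% names(se)) {
    ec50 * log(10) * se[["log10_ec50"]]
  } else {
    NA_real_
  }
  coef_tbl <- tibble(
    term = c("top", "bottom", "ec50", "hill"),
    estimate = c(top, bottom, ec50, est$hill),
    std.error = c(
      if ("top" %in% names(se)) se[["top"]] else NA_real_,
      if ("bottom" %in% names(se)) se[["bottom"]] else NA_real_,
      ec50_se,
      if ("hill" %in% names(se)) se[["hill"]] else NA_real_
    )
  )
  structure(
    list(top = top, bottom = bottom, ec50 = ec50, hill = est$hill,
         coefficients = coef_tbl, sigma = summary(fit)$sigma,
         data = dat, fit = fit,
         constrained = c(top = !is.null(constrain_top),
                         bottom = !is.null(constrain_bottom))),
    class = "pdt_4pl"
  )
}

#' @export
print.pdt_4pl <- function(x, ...) {
  cat(sprintf(
    "<4PL dose-response fit>\n  top: %.4g%%  bottom: %.4g%%\n  EC50: %.4g J/cm2  hill: %.4g\n  residual SD: %.4g\n",
    x$top, x$bottom, x$ec50, x$hill, x$sigma
  ))
  invisible(x)
}

#' @export
tidy.pdt_4pl <- function(x, ...) x$coefficients

#' @export
glance.pdt_4pl <- function(x, ...) {
  tibble(
    ec50 = x$ec50, hill = x$hill, top = x$top, bottom = x$bottom,
    sigma = x$sigma, nobs = nrow(x$data),
    df.residual = nrow(x$data) - nrow(x$coefficients) +
      sum(x$constrained)
  )
}

#' @export
predict.pdt_4pl <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$d else
    if (is.data.frame(newdata)) newdata$d else as.numeric(newdata)
  pl4_predict(d, object$top, object$bottom, log10(object$ec50), object$hill)
}

#' @export
autoplot.pdt_4pl <- function(object, n = 200, ...) {
  pos <- object$data$d[object$data$d > 0]
  grid <- 10^seq(log10(min(pos)) - 0.3, log10(max(pos)) + 0.3,
                 length.out = n)
  curve <- tibble(d = grid, v = predict(object, grid))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$d, .data$v)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$ec50, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "light dose (J/cm²)", y = "viability (%)") +
    ggplot2::theme_minimal()
}

#' Convert a fitted EC50 to an effective EC50
#'
#' Scales the fitted EC50 by the spectral efficiency so LED-array doses are
#' comparable with laser doses; a laser fit uses epsilon = 1 and is
#' unchanged.
#'
#' @param fit A [fit_4pl()] result (or a bare EC50 in J/cm2).
#' @param eff A [spectral_efficiency()] result or bare numeric epsilon.
#' @return Effective EC50 in J/cm2.
#' @examples
#' effective_ec50(10, 0.6198)  # 6.198
#' @export
effective_ec50 <- function(fit, eff) {
  ec50 <- if (inherits(fit, "pdt_4pl")) fit$ec50 else as.numeric(fit)
  effective_dose(ec50, eff)
}

#' Fit a dose-response curve straight from a plate-reader table
#'
#' Convenience pipeline: [normalize_viability()] then [fit_4pl()] on the
#' treatment + LND wells (doses include the LND control at its delivered
#' dose; DNL/NDNL/MO are used only for normalization).
#'
#' @param table A raw viability table (see [normalize_viability()]).
#' @param ... Passed to [fit_4pl()].
#' @return A `pdt_4pl`.
#' @export
fit_dose_response <- function(table, ...) {
  norm <- normalize_viability(table)
  use <- norm[norm$role == "treatment", ]
  fit_4pl(use$dose_Jcm2, use$viability_pct, ...)
}
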