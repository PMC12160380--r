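# Multiple linear regression of median pellet diameter on cultivation
# parameters: ln transforms, OLS fit with adjusted R^2, assumption
# diagnostics, multicollinearity (correlation matrix + VIF), backward
# elimination, and the back-transformed prediction equation.

#' Build the regression dataset from replicate summaries
#'
#' Rows flagged as excluded (fewer than 30 pellets) or multimodal are
#' dropped; the median diameter, spore concentration and shaking frequency
#' are ln-transformed; talc stays on its natural scale; the baffle flag is
#' encoded 0/1. Each flask replicate is one observation.
#'
#' @param summaries data.frame with columns \code{spore_conc},
#'   \code{agitation_rpm}, \code{talc_g_per_l}, \code{baffled},
#'   \code{replicate_id}, \code{median_ed_um}, \code{n_pellets} and
#'   \code{modality}.
#' @return data.frame with the admissible rows plus \code{ln_pd},
#'   \code{ln_spore}, \code{ln_agitation}, \code{talc}, \code{baffle}.
#' @export
build_regression_dataset <- function(summaries) {
  need <- c("spore_conc", "agitation_rpm", "talc_g_per_l", "baffled",
            "replicate_id", "median_ed_um", "n_pellets", "modality")
  miss <- setdiff(need, names(summaries))
  if (length(miss) > 0)
    stop("`summaries` is missing columns: ", paste(miss, collapse = ", "))
  keep <- summaries$n_pellets >= 30L &
    !is.na(summaries$modality) & summaries$modality == "unimodal" &
    is.finite(summaries$median_ed_um) & summaries$median_ed_um > 0
  out <- summaries[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no admissible rows (all excluded or multimodal)")
  out$ln_pd <- log(out$median_ed_um)
  out$ln_spore <- log(out$spore_conc)
  out$ln_agitation <- log(out$agitation_rpm)
  out$talc <- out$talc_g_per_l
  out$baffle <- as.integer(out$baffled)
  rownames(out) <- NULL
  out
}

#' Fit the median-diameter regression by ordinary least squares
#'
#' Fits \code{ln_pd} (or a raw-scale response) on the requested predictors
#' with \code{stats::lm} and bundles the coefficient table, adjusted R^2,
#' predictor correlation matrix and VIFs.
#'
#' @param dataset output of \code{\link{build_regression_dataset}} (or any
#'   data.frame containing the response and predictors).
#' @param predictors character vector of predictor column names.
#' @param response response column name (default \code{"ln_pd"}).
#' @return object of class \code{pellet_lm}: \code{fit} (the lm),
#'   \code{coefficients} (estimate, std.error, t, p), \code{r2},
#'   \code{adj_r2}, \code{vif}, \code{correlation_matrix},
#'   \code{predictors}, \code{response}, \code{n}.
#' @export
fit_diameter_model <- function(dataset,
                               predictors = c("ln_spore", "ln_agitation",
                                              "talc", "baffle"),
                               response = "ln_pd") {
  miss <- setdiff(c(response, predictors), names(dataset))
  if (length(miss) > 0)
    stop("dataset is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(dataset)
  p <- length(predictors)
  if (n <= p + 1L) stop("too few observations for the requested predictors")
  form <- stats::reformulate(if (p > 0) predictors else "1", response)
  fit <- lm(form, data = dataset)
  X <- stats::model.matrix(fit)
  qr_rank <- fit$qr$rank
  if (qr_rank < ncol(X)) {
    aliased <- names(which(is.na(coef(fit))))
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  if (!is.finite(sm$r.squared) || stats::var(dataset[[response]]) < 1e-24) {
    # constant response: nothing to explain
    sm$r.squared <- 0
    sm$adj.r.squared <- 0
  }
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "std.error", "t", "p")
  vifs <- if (p >= 2L) vif(dataset[, predictors, drop = FALSE]) else
    setNames(rep(NA_real_, p), predictors)
  cm <- if (p >= 2L) cor(dataset[, predictors, drop = FALSE]) else NULL
  structure(list(fit = fit, coefficients = ct,
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 vif = vifs, correlation_matrix = cm,
                 predictors = predictors, response = response, n = n),
            class = "pellet_lm")
}

#' @export
print.pellet_lm <- function(x, ...) {
  cat(sprintf("Median-diameter regression: %s ~ %s  (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  print(round(x$coefficients, 5))
  cat(sprintf("R^2 = %.4f, adjusted R^2 = %.4f\n", x$r2, x$adj_r2))
  if (!all(is.na(x$vif))) {
    cat("VIF:\n"); print(round(x$vif, 4))
  }
  invisible(x)
}

#' Variance inflation factors
#'
#' \code{VIF_j = 1 / (1 - R^2_j)} where \code{R^2_j} comes from regressing
#' predictor j on the remaining predictors. Values near 1 mean the
#' predictor carries independent information; above 10 is the conventional
#' multicollinearity alarm. Perfect collinearity is reported as \code{Inf}
#' with a warning.
#'
#' @param design data.frame or matrix of >= 2 predictor columns.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  p <- ncol(design)
  if (p < 2L) stop("VIF needs at least 2 predictors")
  out <- setNames(numeric(p), names(design))
  for (j in seq_len(p)) {
    fit_j <- lm(stats::reformulate(names(design)[-j], names(design)[j]),
                data = design)
    r2j <- summary(fit_j)$r.squared
    if (r2j >= 1 - 1e-12) {
      warning(sprintf("predictor '%s' is perfectly collinear with the others",
                      names(design)[j]))
      out[j] <- Inf
    } else out[j] <- 1 / (1 - r2j)
  }
  out
}

#' Regression assumption diagnostics
#'
#' Produces the data behind the standard visual checks plus two numeric
#' scores: a heteroscedasticity score (Pearson correlation of the absolute
#' residuals with the fitted values; a pronounced funnel gives a large
#' positive value) and a normality statistic (correlation of the sorted
#' residuals with the corresponding normal quantiles; near 1 when residuals
#' are normal). Both are descriptive operationalisations of otherwise
#' visual judgements and are reported, never auto-enforced.
#'
#' @param model a \code{pellet_lm}.
#' @return list with \code{residual_vs_fitted} (data.frame), \code{qq}
#'   (data.frame of theoretical and sample quantiles),
#'   \code{heteroscedasticity_score}, \code{normality_r} and
#'   \code{degenerate} (TRUE when all residuals are numerically zero).
#' @export
model_diagnostics <- function(model) {
  if (!inherits(model, "pellet_lm")) stop("`model` must be a pellet_lm")
  res <- stats::residuals(model$fit)
  fitv <- stats::fitted(model$fit)
  degenerate <- max(abs(res)) < 1e-10 * max(1, max(abs(fitv)))
  het <- if (degenerate || stats::sd(abs(res)) == 0 || stats::sd(fitv) == 0)
    NA_real_ else cor(abs(res), fitv)
  srt <- sort(res)
  qth <- qnorm(ppoints(length(res)))
  norm_r <- if (degenerate || stats::sd(srt) == 0) NA_real_ else cor(srt, qth)
  list(residual_vs_fitted = data.frame(fitted = fitv, residual = res),
       qq = data.frame(theoretical = qth, sample = srt),
       heteroscedasticity_score = het,
       normality_r = norm_r,
       degenerate = degenerate)
}

#' Backward elimination of non-significant predictors
#'
#' Starting from the full model, repeatedly drops the predictor with the
#' largest p value above \code{alpha} and refits, recording the elimination
#' trace. With all predictors eliminated an intercept-only model is
#' returned with a warning.
#'
#' @param dataset regression dataset.
#' @param predictors starting predictor set.
#' @param alpha significance level for retention.
#' @param response response column.
#' @return the final \code{pellet_lm} with an \code{elimination_trace}
#'   element (data.frame of dropped predictors and their p values).
#' @export
eliminate_nonsignificant <- function(dataset,
                                     predictors = c("ln_spore",
                                                    "ln_agitation", "talc",
                                                    "baffle"),
                                     alpha = 0.05, response = "ln_pd") {
  trace <- data.frame(dropped = character(0), p = numeric(0))
  current <- predictors
  repeat {
    if (length(current) == 0L) {
      warning("all predictors eliminated; returning intercept-only model")
      model <- fit_diameter_model(dataset, character(0), response)
      break
    }
    model <- fit_diameter_model(dataset, current, response)
    pv <- model$coefficients$p[-1] # drop intercept
    names(pv) <- rownames(model$coefficients)[-1]
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    trace <- rbind(trace, data.frame(dropped = names(pv)[worst],
                                     p = unname(pv[worst])))
    current <- setdiff(current, names(pv)[worst])
  }
  model$elimination_trace <- trace
  model
}

#' Predict median pellet diameter from agitation and talc
#'
#' Back-transformed prediction equation of the reduced model:
#' \code{PD = exp(b0 + bA * ln(A) + bT * T)} with agitation A in rpm and
#' talc T in g/L. The default coefficients are the fitted reduced-model
#' values (15.863, -1.7769, -0.10856). The model is trusted for predicted
#' diameters between 150 and 1200 um; predictions outside that range are
#' flagged via the \code{"in_validity_range"} attribute.
#'
#' @param agitation shaking frequency (rpm, > 0).
#' @param talc talc concentration (g/L, >= 0).
#' @param coefficients c(b0, bA, bT).
#' @return predicted diameter(s) in um with attribute
#'   \code{in_validity_range}.
#' @export
predict_diameter <- function(agitation, talc = 0,
                             coefficients = c(15.863, -1.7769, -0.10856)) {
  if (any(agitation <= 0)) stop("agitation must be positive")
  if (any(talc < 0)) stop("talc must be >= 0")
  pd <- exp(coefficients[1] + coefficients[2] * log(agitation) +
              coefficients[3] * talc)
  attr(pd, "in_validity_range") <- pd >= 150 & pd <= 1200
  pd
}
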