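# Gradient trend models: GLM fits along the depth and hillslope gradients
# with estimated marginal means and Tukey-adjusted contrasts against the
# gradient baseline (5 cm depth or shoulder position).

#' Fit a gradient trend model
#'
#' Fits an additive model of the response on the focal gradient factor plus
#' the available covariates among position/depth, catchment and sample_type.
#' A focal-by-other-gradient interaction is fitted first and dropped when a
#' drop test gives p > 0.05. Families:
#' \describe{
#'   \item{binomial-overdispersed}{counts (successes out of trials) via
#'     quasibinomial GLM; overdispersion handled by quasi-likelihood
#'     dispersion scaling, reported in the result.}
#'   \item{gaussian-logit}{proportions of continuous quantities,
#'     logit-transformed then Gaussian.}
#'   \item{gaussian-log}{positive continuous responses, log-transformed.}
#'   \item{gaussian}{untransformed.}
#' }
#' Marginal means are equal-weight averages of model predictions over the
#' levels of the non-focal factors, back-transformed to the response scale,
#' with 95% confidence intervals. All pairwise contrasts of the focal
#' factor are Tukey-adjusted (multivariate-t reference distribution); the
#' result also extracts the contrasts against the baseline level.
#'
#' @param data Data frame with the response column(s) and factor columns;
#'   factors among depth, position, catchment, sample_type are used when
#'   present and non-constant.
#' @param response Name of the response column. For the binomial family,
#'   name of the successes column.
#' @param trials For the binomial family, name of the trials column.
#' @param family One of "binomial-overdispersed", "gaussian-logit",
#'   "gaussian-log", "gaussian".
#' @param focal Name of the gradient factor to profile ("depth" or
#'   "position").
#' @param baseline Baseline level for reported contrasts; default is the
#'   first level of the focal factor (5 cm or shoulder under the natural
#'   orderings).
#' @return A `trend_result`: list with `emmeans` (level, estimate, lower,
#'   upper on the response scale), `contrasts` (all Tukey-adjusted pairwise
#'   contrasts), `baseline_contrasts`, `dispersion`, `df_residual`,
#'   `interaction_p` and `interaction_dropped`, plus the fitted `model`.
#' @export
fit_trend <- function(data, response, trials = NULL,
                      family = c("binomial-overdispersed", "gaussian-logit",
                                 "gaussian-log", "gaussian"),
                      focal = "depth", baseline = NULL) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  if (!"depth" %in% names(data) && "depth_cm" %in% names(data)) {
    data$depth <- data$depth_cm
  }
  if (!focal %in% names(data)) {
    stop("focal factor '", focal, "' not found in data", call. = FALSE)
  }
  fac_candidates <- c("depth", "position", "catchment", "sample_type")
  present <- intersect(fac_candidates, names(data))
  for (f in present) {
    if (!is.factor(data[[f]])) {
      lev <- if (f == "depth") sort(unique(as.numeric(data[[f]])))
             else if (f == "position") intersect(c("shoulder", "back", "foot",
                                                   "toe", "stream"),
                                                 unique(data[[f]]))
             else sort(unique(data[[f]]))
      data[[f]] <- factor(data[[f]], levels = lev)
    }
  }
  usable <- present[vapply(present, function(f) {
    nlevels(droplevels(data[[f]])) >= 2 && !anyNA(data[[f]])
  }, logical(1))]
  if (!focal %in% usable) {
    stop("focal factor '", focal, "' needs >= 2 levels without NAs",
         call. = FALSE)
  }
  covars <- setdiff(usable, focal)
  tran <- NULL
  if (family == "binomial-overdispersed") {
    stopifnot(!is.null(trials))
    data$.fail <- data[[trials]] - data[[response]]
    lhs <- sprintf("cbind(%s, .fail)", response)
    glm_family <- stats::quasibinomial()
  } else {
    y <- data[[response]]
    if (family == "gaussian-logit") {
      stopifnot(all(y > 0 & y < 1))
      data$.y <- stats::qlogis(y)
      tran <- "logit"
    } else if (family == "gaussian-log") {
      stopifnot(all(y > 0))
      data$.y <- log(y)
      tran <- "log"
    } else {
      data$.y <- y
    }
    lhs <- ".y"
    glm_family <- stats::gaussian()
  }
  rhs <- paste(c(focal, covars), collapse = " + ")
  form <- stats::as.formula(paste(lhs, "~", rhs))
  # interaction between the two gradient factors, tested then dropped
  other_gradient <- intersect(c("depth", "position"), covars)
  interaction_p <- NA_real_
  interaction_dropped <- NA
  fit <- stats::glm(form, family = glm_family, data = data)
  if (length(other_gradient) == 1L) {
    form_int <- stats::update(form,
      stats::as.formula(paste(". ~ . +", focal, ":", other_gradient)))
    fit_int <- try(stats::glm(form_int, family = glm_family, data = data),
                   silent = TRUE)
    if (!inherits(fit_int, "try-error") && fit_int$df.residual > 0) {
      a <- stats::anova(fit, fit_int, test = "F")
      interaction_p <- a[2, "Pr(>F)"]
      if (is.finite(interaction_p) && interaction_p <= 0.05) {
        fit <- fit_int
        interaction_dropped <- FALSE
      } else {
        interaction_dropped <- TRUE
      }
    }
  }
  if (family == "binomial-overdispersed" && fit$df.residual == 0) {
    # saturated design: no residual df to estimate a dispersion from
    message("zero residual df; dispersion fixed at 1 (plain binomial)")
    fit <- stats::glm(stats::formula(fit), family = stats::binomial(),
                      data = data)
  }
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular fit; aliased terms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rg <- emmeans::ref_grid(fit, data = data)
  if (!is.null(tran)) rg <- stats::update(rg, tran = tran)
  emm <- emmeans::emmeans(rg, specs = focal, type = "response")
  emm_df <- as.data.frame(emm)
  est_col <- intersect(c("response", "prob", "emmean", "rate"), names(emm_df))[1]
  lcl <- grep("lower|LCL", names(emm_df), value = TRUE, ignore.case = TRUE)[1]
  ucl <- grep("upper|UCL", names(emm_df), value = TRUE, ignore.case = TRUE)[1]
  means <- data.frame(level = as.character(emm_df[[focal]]),
                      estimate = emm_df[[est_col]],
                      lower = emm_df[[lcl]],
                      upper = emm_df[[ucl]],
                      stringsAsFactors = FALSE)
  ctr <- try(as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                             adjust = "tukey")),
             silent = TRUE)
  if (inherits(ctr, "try-error")) {
    ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "holm"))
    message("Tukey adjustment unavailable (singular contrast covariance); ",
            "fell back to Holm")
  }
  # a saturated or zero-variance fit gives 0/0 test statistics; a zero
  # estimated difference with zero uncertainty carries no evidence against
  # equality, so those p-values are reported as 1
  delta <- if (!is.null(ctr$estimate)) ctr$estimate
           else if (!is.null(ctr$odds.ratio)) ctr$odds.ratio - 1
           else if (!is.null(ctr$ratio)) ctr$ratio - 1 else Inf
  zero_disp <- summary(fit)$dispersion <
    1e-12 * max(1, max(abs(stats::fitted(fit))))
  fix <- abs(delta) < 1e-10 & (is.nan(ctr$p.value) | zero_disp)
  ctr$p.value[fix] <- 1
  if (is.null(baseline)) baseline <- levels(droplevels(data[[focal]]))[1]
  # contrast labels are "A - B" or "A / B"; numeric-like levels carry the
  # factor name as a prefix (e.g. "depth5 / depth60")
  toks <- strsplit(as.character(ctr$contrast), " [-/] ")
  base_rows <- vapply(toks, function(t)
    any(t %in% c(baseline, paste0(focal, baseline))), logical(1))
  structure(list(
    emmeans = means,
    contrasts = ctr,
    baseline_contrasts = ctr[base_rows, , drop = FALSE],
    baseline = baseline,
    dispersion = summary(fit)$dispersion,
    df_residual = fit$df.residual,
    interaction_p = interaction_p,
    interaction_dropped = interaction_dropped,
    family = family,
    focal = focal,
    model = fit
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("trend along", x$focal, "(", x$family, "family )\n")
  print(x$emmeans, row.names = FALSE)
  cat("contrasts vs", x$baseline, "(Tukey-adjusted):\n")
  print(x$baseline_contrasts, row.names = FALSE)
  invisible(x)
}

#' Difference between the extreme marginal means of a trend
#'
#' Convenience: last-level minus first-level estimated marginal mean on the
#' response scale, e.g. the 60 cm minus 5 cm universal intensity share.
#'
#' @param tr A `trend_result`.
#' @return Numeric scalar.
#' @export
trend_extreme_shift <- function(tr) {
  est <- tr$emmeans$estimate
  est[length(est)] - est[1]
}
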