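#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` with `k` the number of estimated
#' parameters (including the Gaussian scale or the negative-binomial
#' dispersion, as counted by `logLik`). Undefined (`NA`) when `n <= k + 1`.
#'
#' @param fit a fitted `lm`, `glm` or `negbin` model.
#' @return The AICc value, or `NA` with a message attribute when undefined.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) {
    return(structure(NA_real_, note = "AICc undefined: n <= k + 1"))
  }
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

build_formula <- function(response, predictors) {
  rhs <- if (length(predictors) == 0) "1" else paste(predictors, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

fit_one <- function(formula, data, family, link) {
  if (family == "gaussian" && link == "identity") {
    stats::lm(formula, data = data)
  } else if (family == "gaussian" && link == "log") {
    stats::glm(formula, data = data,
               family = stats::gaussian(link = "log"),
               start = NULL)
  } else if (family == "negative_binomial") {
    MASS::glm.nb(formula, data = data)
  } else {
    value_error(sprintf("unsupported family/link: %s/%s", family, link))
  }
}

#' Fixed-effects land-use model with a global land-use test
#'
#' Fits the response against land use (optionally plus cluster and their
#' interaction) and tests the land-use term against the nested model without
#' it: an F test for Gaussian families, a likelihood-ratio chi-square for the
#' negative binomial (dispersion re-estimated by maximum likelihood in both
#' models). With a balanced one-factor design the Gaussian case reduces to
#' classical one-way ANOVA (e.g. 4 land uses over 28 plots gives F on 3 and
#' 24 degrees of freedom).
#'
#' @param data data frame holding the response column and `land_use` (and
#'   `cluster` if used as a predictor).
#' @param response name of the response column.
#' @param family `"gaussian"` or `"negative_binomial"`.
#' @param link `"identity"` or `"log"`. The negative binomial always uses the
#'   log link; a Gaussian log link requires a strictly positive response
#'   (zero or negative values are an error, not silently offset).
#' @param predictors character vector of model terms including `"land_use"`,
#'   e.g. `c("land_use", "cluster")` or `c("land_use", "cluster",
#'   "land_use:cluster")`.
#' @return An object of class `landuse_fit`: list with `model`, `response`,
#'   `family`, `link`, `predictors`, `statistic`, `test` ("F" or "LR"),
#'   `df1`, `df2` (`NA` for the chi-square), `p_value`, `aicc`, `n`,
#'   `converged`.
#' @export
fit_landuse_model <- function(data, response, family = "gaussian",
                              link = if (family == "gaussian") "identity" else "log",
                              predictors = "land_use") {
  if (!"land_use" %in% predictors) {
    value_error("'land_use' must be among the predictors")
  }
  if (!response %in% names(data)) {
    schema_error(sprintf("response column '%s' not found", response))
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  y <- data[[response]]
  if (length(unique(data$land_use)) < 2) {
    value_error("response must be defined for at least two land uses")
  }
  if (link == "log" && any(y <= 0) && family == "gaussian") {
    value_error("log link requires a strictly positive response")
  }
  if (family == "negative_binomial" &&
      any(abs(y - round(y)) > 1e-8 | y < 0)) {
    value_error("negative-binomial family requires non-negative integer counts")
  }
  data$land_use <- factor(data$land_use)
  if ("cluster" %in% names(data)) data$cluster <- factor(data$cluster)

  full_f <- build_formula(response, predictors)
  null_preds <- setdiff(predictors,
                        c("land_use", grep("land_use", predictors,
                                           value = TRUE)))
  null_f <- build_formula(response, null_preds)

  converged <- TRUE
  fit <- tryCatch(fit_one(full_f, data, family, link),
                  warning = function(w) {
                    converged <<- FALSE
                    suppressWarnings(fit_one(full_f, data, family, link))
                  })
  fit0 <- suppressWarnings(fit_one(null_f, data, family, link))

  if (family == "gaussian" && link == "identity") {
    a <- stats::anova(fit0, fit)
    statistic <- a$F[2]
    df1 <- a$Df[2]
    df2 <- a$Res.Df[2]
    p <- a$`Pr(>F)`[2]
    test <- "F"
    # a (numerically) constant response carries no signal
    if (is.na(statistic) ||
        stats::var(y) <= .Machine$double.eps * (1 + mean(y)^2)) {
      statistic <- 0; p <- 1
    }
  } else if (family == "gaussian" && link == "log") {
    a <- stats::anova(fit0, fit, test = "F")
    statistic <- a$F[2]
    df1 <- a$Df[2]
    df2 <- fit$df.residual
    p <- a$`Pr(>F)`[2]
    test <- "F"
    if (is.na(statistic)) { statistic <- 0; p <- 1 }
  } else {
    lr <- 2 * (as.numeric(stats::logLik(fit)) -
                 as.numeric(stats::logLik(fit0)))
    lr <- max(lr, 0)
    df1 <- attr(stats::logLik(fit), "df") - attr(stats::logLik(fit0), "df")
    statistic <- lr
    df2 <- NA_real_
    p <- stats::pchisq(lr, df1, lower.tail = FALSE)
    test <- "LR"
  }

  structure(list(
    model = fit, response = response, family = family, link = link,
    predictors = predictors, test = test,
    statistic = as.numeric(statistic), df1 = as.numeric(df1),
    df2 = as.numeric(df2), p_value = as.numeric(p),
    aicc = as.numeric(aicc(fit)), n = stats::nobs(fit),
    converged = converged
  ), class = "landuse_fit")
}

#' @export
print.landuse_fit <- function(x, ...) {
  dfs <- if (x$test == "F") sprintf("%g,%g", x$df1, x$df2) else
    sprintf("%g", x$df1)
  cat(sprintf("landuse_fit: %s ~ %s  [%s/%s]\n", x$response,
              paste(x$predictors, collapse = " + "), x$family, x$link))
  cat(sprintf("  %s_%s = %.4g, p = %.3g, AICc = %.4g, n = %d%s\n",
              x$test, dfs, x$statistic, x$p_value, x$aicc, x$n,
              if (x$converged) "" else "  (convergence flagged)"))
  invisible(x)
}

#' AICc-based model simplification
#'
#' Starting from the full model `land_use * cluster`, evaluates the nested
#' candidate ladder (drop the interaction, then drop cluster) and returns the
#' candidate with the smallest AICc; ties go to the model with fewer
#' parameters. Candidates whose AICc is undefined (`n <= k + 1`) are excluded
#' with a note.
#'
#' @inheritParams fit_landuse_model
#' @param candidates list of predictor vectors, most complex first. The
#'   default ladder is interaction, additive, land-use only.
#' @return List with `best` (a `landuse_fit`), and `table` (data frame:
#'   `model`, `k`, `aicc`, `note`).
#' @export
aicc_select <- function(data, response, family = "gaussian",
                        link = if (family == "gaussian") "identity" else "log",
                        candidates = list(
                          c("land_use", "cluster", "land_use:cluster"),
                          c("land_use", "cluster"),
                          "land_use")) {
  fits <- lapply(candidates, function(pr) {
    suppressWarnings(fit_landuse_model(data, response, family, link,
                                       predictors = pr))
  })
  ks <- vapply(fits, function(f) attr(stats::logLik(f$model), "df"),
               numeric(1))
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  tab <- data.frame(
    model = vapply(candidates, paste, character(1), collapse = " + "),
    k = ks, aicc = aiccs,
    note = ifelse(is.na(aiccs), "AICc undefined: n <= k + 1", ""),
    stringsAsFactors = FALSE
  )
  ok <- which(!is.na(aiccs))
  if (length(ok) == 0) value_error("no candidate with defined AICc")
  # ties (within numerical noise) resolved toward fewer parameters
  best_aicc <- min(aiccs[ok])
  tied <- ok[aiccs[ok] <= best_aicc + 1e-9]
  best <- tied[which.min(ks[tied])]
  list(best = fits[[best]], table = tab)
}

#' Land-use tests for every standard response
#'
#' Runs the response family map over the per-plot metric tables: total
#' abundance as negative binomial with log link; richness and rarity as
#' Gaussian with identity link; the eight isotope metrics as Gaussian with
#' identity link, except the D15N range which uses a Gaussian log link
#' (positive, right-skewed). Each response is first simplified over the AICc
#' ladder (interaction, additive, land-use only), then the land-use term of
#' the selected model is tested globally.
#'
#' @param community per-plot community metrics ([community_metrics()]).
#' @param isotopes per-plot isotope metrics joined with `land_use` and
#'   `cluster` columns, or `NULL` to test community responses only. Rows with
#'   `NA` for a metric (e.g. Range on single-species plots) are dropped for
#'   that metric.
#' @param families optional named list overriding `list(family, link)` per
#'   response.
#' @return Data frame with one row per response: `response`, `family`,
#'   `link`, `selected_model`, `test`, `statistic`, `df1`, `df2`, `p_value`,
#'   `aicc`, `n`.
#' @export
run_all_responses <- function(community, isotopes = NULL, families = NULL) {
  specs <- list(
    total_count = list(family = "negative_binomial", link = "log"),
    richness = list(family = "gaussian", link = "identity"),
    rarity = list(family = "gaussian", link = "identity")
  )
  if (!is.null(isotopes)) {
    for (m in grep("^(average|maximum|minimum|range)_",
                   names(isotopes), value = TRUE)) {
      specs[[m]] <- if (m == "range_D15N") {
        list(family = "gaussian", link = "log")
      } else {
        list(family = "gaussian", link = "identity")
      }
    }
  }
  for (nm in names(families)) specs[[nm]] <- families[[nm]]

  rows <- lapply(names(specs), function(resp) {
    data <- if (resp %in% names(community)) community else isotopes
    sp <- specs[[resp]]
    sel <- tryCatch(
      aicc_select(data, resp, sp$family, sp$link),
      error = function(e) NULL
    )
    if (is.null(sel)) {
      return(data.frame(response = resp, family = sp$family, link = sp$link,
                        selected_model = NA_character_, test = NA_character_,
                        statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                        p_value = NA_real_, aicc = NA_real_, n = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    f <- sel$best
    data.frame(response = resp, family = sp$family, link = sp$link,
               selected_model = paste(f$predictors, collapse = " + "),
               test = f$test, statistic = f$statistic, df1 = f$df1,
               df2 = f$df2, p_value = f$p_value, aicc = f$aicc,
               n = f$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format p values for reporting
#'
#' Three significant digits, with the conventional `"<0.001"` only in the
#' rendered form; stored results always keep the raw number.
#'
#' @param p numeric vector of p values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", signif(p, 3))
}
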