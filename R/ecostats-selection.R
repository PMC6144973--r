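#' AICc model selection over spatio-temporal and environmental model sets
#'
#' Candidate models are described as lists of terms (linear covariates, raw
#' centered polynomials of a standardized covariate, or penalized smooths),
#' fitted with a site random intercept by the profiled-likelihood machinery,
#' and compared by AICc with Akaike weights. Marginal and conditional
#' R-squared are reported for the parametric models.
#'
#' @name ecostats-selection
NULL

#' Term constructors for candidate models
#'
#' @param var covariate column name.
#' @param degree polynomial degree (powers 1..degree of the standardized
#'   covariate).
#' @param k smooth basis dimension cap.
#' @return a term description list.
#' @export
term_linear <- function(var) list(type = "linear", var = var, label = var)

#' @rdname term_linear
#' @export
term_poly <- function(var, degree) {
  list(type = "poly", var = var, degree = degree,
       label = sprintf("%s^%d", var, degree))
}

#' @rdname term_linear
#' @export
term_smooth <- function(var, k = 5) {
  list(type = "smooth", var = var, k = k, label = sprintf("s(%s)", var))
}

#' Fit one candidate model on a trait table
#'
#' Covariates are standardized (mean 0, SD 1) before entering the design;
#' linear-term coefficients are also reported back on the raw covariate
#' scale. Smooth terms contribute their standardized covariate as an
#' unpenalized linear column plus a penalized deviation block with its own
#' variance ratio.
#'
#' @param table trait table (one row per egg) with a `site` column.
#' @param response response column name (e.g. "PC1").
#' @param terms list of term descriptions; empty list = null model.
#' @param criterion "ML" (fixed-effect selection) or "REML".
#' @param random_site include the site random intercept (TRUE for every
#'   study model; FALSE only for the random-effect assessment).
#' @param label model label for comparison tables.
#' @return an `ovo_lmm` with `term_index` recording each term's design
#'   columns, `edf` per smooth, and raw-scale linear coefficients in
#'   `coefficients_raw`.
#' @export
fit_model <- function(table, response, terms = list(),
                      criterion = c("ML", "REML"), random_site = TRUE,
                      label = NULL) {
  criterion <- match.arg(criterion)
  if (!response %in% names(table)) stop("schema error: missing column ", response)
  needed <- c("site", vapply(terms, function(t) t$var, ""))
  miss <- setdiff(needed, names(table))
  if (length(miss) > 0) stop("schema error: missing column ", paste(miss, collapse = ", "))
  y <- table[[response]]
  n <- length(y)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Zlist <- list()
  zlabels <- character(0)
  smooth_info <- list()
  term_index <- list()
  n_lambda <- 0L
  scale_info <- list()

  if (random_site) {
    site <- factor(table$site)
    if (nlevels(site) < 2) stop("at least 2 sites are required for the random intercept")
    Zlist$site <- stats::model.matrix(~ site - 1)
    zlabels <- "site"
  }

  for (tm in terms) {
    v <- table[[tm$var]]
    mu <- mean(v); sdv <- stats::sd(v)
    if (sdv == 0) stop("covariate ", tm$var, " is constant")
    z <- (v - mu) / sdv
    if (tm$type == "linear") {
      X <- cbind(X, z)
      colnames(X)[ncol(X)] <- tm$var
      term_index[[tm$label]] <- list(x_cols = ncol(X), smooth_id = NA_integer_)
      scale_info[[tm$var]] <- c(mean = mu, sd = sdv)
    } else if (tm$type == "poly") {
      cols <- integer(0)
      for (d in seq_len(tm$degree)) {
        X <- cbind(X, z^d)
        colnames(X)[ncol(X)] <- sprintf("%s^%d", tm$var, d)
        cols <- c(cols, ncol(X))
      }
      term_index[[tm$label]] <- list(x_cols = cols, smooth_id = NA_integer_)
      scale_info[[tm$var]] <- c(mean = mu, sd = sdv)
    } else if (tm$type == "smooth") {
      sb <- smooth_basis(v, tm$k)
      X <- cbind(X, z)
      colnames(X)[ncol(X)] <- tm$var
      Zlist[[paste0("s_", tm$var)]] <- sb$Z
      zlabels <- c(zlabels, paste0("s_", tm$var))
      n_lambda <- n_lambda + 1L
      smooth_info[[length(smooth_info) + 1L]] <-
        list(basis = sb, theta_index = length(Zlist), x_col = ncol(X),
             var = tm$var, label = tm$label)
      term_index[[tm$label]] <- list(x_cols = ncol(X),
                                     smooth_id = length(smooth_info))
      scale_info[[tm$var]] <- c(mean = mu, sd = sdv)
    } else stop("unknown term type")
  }

  fit <- fit_gauss_mixed(y, X, Zlist, criterion, labels = zlabels)
  k <- ncol(X) + 1L + as.integer(random_site) + n_lambda
  if (is.null(label)) {
    label <- if (length(terms) == 0) "Null model" else
      paste(vapply(terms, function(t) t$label, ""), collapse = " + ")
  }
  out <- new_ovo_lmm(fit, y = y, X = X, Zlist = Zlist, k = k, label = label,
                     response = response,
                     site_component = if (random_site) 1L else NA_integer_,
                     smooth_info = smooth_info)
  out$term_index <- term_index
  out$edf <- if (length(smooth_info) > 0) smooth_edf(out) else numeric(0)
  # raw-scale coefficients for linear terms
  raw <- out$coefficients
  for (v in names(scale_info)) {
    i <- match(v, raw$term)
    if (!is.na(i)) {
      raw$estimate[i] <- raw$estimate[i] / scale_info[[v]]["sd"]
      raw$se[i] <- raw$se[i] / scale_info[[v]]["sd"]
    }
  }
  out$coefficients_raw <- raw
  out$scale_info <- scale_info
  out
}

#' Akaike weights from AICc differences
#'
#' w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2).
#'
#' @param delta_aicc vector of AICc differences from the best model (or raw
#'   AICc values: only differences matter).
#' @return weights summing to 1.
#' @export
akaike_weights <- function(delta_aicc) {
  d <- delta_aicc - min(delta_aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Compare fitted models by AICc
#'
#' @param models list of `ovo_lmm` fits sharing a response and criterion.
#' @return an object of class `model_comparison`: data.frame with label,
#'   df (the parameter count k), AICc, dAICc, weight, R2m, R2c (NA for
#'   smooth models), `best` and `competitive` (dAICc <= 2) flags.
#' @export
compare_models <- function(models) {
  stopifnot(length(models) >= 1, all(vapply(models, inherits, TRUE, "ovo_lmm")))
  crit <- unique(vapply(models, function(m) m$criterion, ""))
  if (length(crit) > 1) stop("invalid comparison: models mix ML and REML likelihoods")
  resp <- unique(vapply(models, function(m) m$response, ""))
  if (length(resp) > 1) stop("invalid comparison: models fit different responses")
  a <- vapply(models, function(m) aicc(m$loglik, m$k, m$n), 0)
  d <- a - min(a)
  w <- akaike_weights(a)
  r2 <- t(vapply(models, function(m) {
    if (length(m$smooth_info) > 0) c(R2m = NA_real_, R2c = NA_real_) else r2_nakagawa(m)
  }, c(R2m = 0, R2c = 0)))
  out <- data.frame(label = vapply(models, function(m) m$label, ""),
                    df = vapply(models, function(m) m$k, 0L),
                    AICc = a, dAICc = d, weight = w,
                    R2m = r2[, 1], R2c = r2[, 2],
                    best = d == 0, competitive = d <= 2,
                    row.names = NULL)
  structure(list(table = out, criterion = crit, response = resp, models = models),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> response %s, %s likelihood\n", x$response, x$criterion))
  tab <- x$table
  tab$AICc <- round(tab$AICc, 2); tab$dAICc <- round(tab$dAICc, 2)
  tab$weight <- round(tab$weight, 3)
  tab$R2m <- round(tab$R2m, 2); tab$R2c <- round(tab$R2c, 2)
  print(tab[, c("label", "df", "AICc", "dAICc", "weight", "R2m", "R2c")])
  invisible(x)
}

spatio_temporal_terms <- function() {
  list("Year + s(latitude)" = list(term_linear("year"), term_smooth("latitude")),
       "Year + latitude" = list(term_linear("year"), term_linear("latitude")),
       "Latitude" = list(term_linear("latitude")),
       "Year" = list(term_linear("year")),
       "Null model" = list())
}

environmental_terms <- function(response) {
  if (response == "PC1") {
    list("Year + sv + s(insolation) + s(temperature)" =
           list(term_linear("year"), term_linear("sv"),
                term_smooth("insolation"), term_smooth("temperature")),
         "Year + s(insolation) + s(temperature)" =
           list(term_linear("year"), term_smooth("insolation"), term_smooth("temperature")),
         "sv + s(insolation) + s(temperature)" =
           list(term_linear("sv"), term_smooth("insolation"), term_smooth("temperature")),
         "Year + sv + s(insolation)" =
           list(term_linear("year"), term_linear("sv"), term_smooth("insolation")),
         "Year + sv + s(temperature)" =
           list(term_linear("year"), term_linear("sv"), term_smooth("temperature")),
         "Year + sv + insolation^3" =
           list(term_linear("year"), term_linear("sv"), term_poly("insolation", 3)),
         "Year + sv + insolation^4" =
           list(term_linear("year"), term_linear("sv"), term_poly("insolation", 4)),
         "Null model" = list())
  } else {
    list("s(insolation) + s(temperature)" =
           list(term_smooth("insolation"), term_smooth("temperature")),
         "s(insolation)" = list(term_smooth("insolation")),
         "s(temperature)" = list(term_smooth("temperature")),
         "Insolation" = list(term_linear("insolation")),
         "Temperature" = list(term_linear("temperature")),
         "Null model" = list())
  }
}

#' Run the full model-selection workflow on a trait table
#'
#' Three stages: (i) a REML AICc assessment of the site random intercept
#' under the full parametric fixed model (year + latitude); (ii) an ML AICc
#' comparison of the spatio-temporal candidate set {Year + s(latitude),
#' Year + latitude, Latitude, Year, Null}; (iii) an ML AICc comparison of
#' the environmental candidate set, where smooth terms are also refit as
#' cubic/quartic raw-polynomial alternatives for the first trait axis.
#'
#' @param table trait table with columns site, latitude, year, insolation,
#'   temperature, sv and the response.
#' @param response "PC1" or "PC2".
#' @return list with `random_effect` (REML AICc with/without the site
#'   intercept and their difference), `spatio_temporal` and `environmental`
#'   (`model_comparison` objects).
#' @export
run_selection <- function(table, response = c("PC1", "PC2")) {
  response <- match.arg(response)
  needed <- c("site", "latitude", "year", "insolation", "temperature", "sv", response)
  miss <- setdiff(needed, names(table))
  if (length(miss) > 0) stop("schema error: missing column ", paste(miss, collapse = ", "))

  full <- list(term_linear("year"), term_linear("latitude"))
  with_re <- fit_model(table, response, full, criterion = "REML", random_site = TRUE,
                       label = "Year + latitude + (1|site)")
  without_re <- fit_model(table, response, full, criterion = "REML", random_site = FALSE,
                          label = "Year + latitude")
  a_with <- aicc(with_re$loglik, with_re$k, with_re$n)
  a_without <- aicc(without_re$loglik, without_re$k, without_re$n)
  random_effect <- list(aicc_with = a_with, aicc_without = a_without,
                        delta_aicc = a_without - a_with,
                        improves = a_with < a_without)

  st <- lapply(names(spatio_temporal_terms()), function(lbl) {
    fit_model(table, response, spatio_temporal_terms()[[lbl]],
              criterion = "ML", label = lbl)
  })
  et <- lapply(names(environmental_terms(response)), function(lbl) {
    fit_model(table, response, environmental_terms(response)[[lbl]],
              criterion = "ML", label = lbl)
  })
  list(random_effect = random_effect,
       spatio_temporal = compare_models(st),
       environmental = compare_models(et))
}
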