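#' Linear interface-conservation models
#'
#' Interface conservation (IC) — the Matthews correlation between interface
#' labels transferred from a template and a query's true labels — is well
#' approximated by a linear function of a few alignment statistics. The
#' package ships the two fitted models used for template ranking:
#'
#' * `kind = "nps"`: `IC = b0 + b1*log_eval + b2*positive_score +
#'   b3*log_lal` with coefficients (-0.5655, -0.0004, 0.0037, 0.1057);
#' * `kind = "ps"`: `IC = b0 + b1*avg_log_eval + b2*avg_positive +
#'   b3*frac_aa + b4*frac_bb` with coefficients (-0.505, 0.001, 0.009,
#'   0.341, 0.205).
#'
#' Positive scores enter on the 0-100 percent scale and the PS fractions on
#' the 0-1 scale; the coefficient magnitudes only make sense on those
#' scales. Predicted IC is used solely to rank candidate templates and is
#' deliberately not clipped to `[-1, 1]`.
#'
#' @param kind `"nps"` or `"ps"`.
#' @param coefficients Optional replacement coefficient vector (length 4 for
#'   NPS, 5 for PS, intercept first).
#' @return An object of class `ic_model`.
#' @export
ic_model <- function(kind = c("nps", "ps"), coefficients = NULL) {
  kind <- match.arg(kind)
  default <- switch(kind,
    nps = c(intercept = -0.5655, log_eval = -0.0004,
            positive_score = 0.0037, log_lal = 0.1057),
    ps = c(intercept = -0.505, avg_log_eval = 0.001, avg_positive = 0.009,
           frac_aa = 0.341, frac_bb = 0.205)
  )
  if (is.null(coefficients)) {
    coefficients <- default
    provenance <- "default"
  } else {
    if (length(coefficients) != length(default)) {
      abort(sprintf("a %s IC model needs %d coefficients", kind, length(default)),
            class = "homint_config_error")
    }
    coefficients <- setNames(as.numeric(coefficients), names(default))
    provenance <- "custom"
  }
  structure(list(kind = kind, coefficients = coefficients,
                 provenance = provenance),
            class = "ic_model")
}

#' @export
print.ic_model <- function(x, ...) {
  cat(sprintf("<ic_model kind=%s provenance=%s>\n", x$kind, x$provenance))
  print(x$coefficients)
  invisible(x)
}

# predictor column names for a model kind (intercept excluded)
ic_terms <- function(kind) {
  switch(kind,
    nps = c("log_eval", "positive_score", "log_lal"),
    ps = c("avg_log_eval", "avg_positive", "frac_aa", "frac_bb")
  )
}

#' Predict interface conservation for a set of hits
#'
#' Evaluates the linear IC model on each row of `stats`. Inputs must be
#' finite (`log_eval` of exactly-zero expectation values is already floored
#' at -450 upstream).
#'
#' @param model An [ic_model()].
#' @param stats Tibble carrying the model's predictor columns
#'   (`log_eval`, `positive_score`, `log_lal` for NPS; `avg_log_eval`,
#'   `avg_positive`, `frac_aa`, `frac_bb` for PS).
#' @return Numeric vector of predicted IC values (unclipped).
#' @export
predict_ic <- function(model, stats) {
  stopifnot(inherits(model, "ic_model"))
  terms <- ic_terms(model$kind)
  missing <- setdiff(terms, names(stats))
  if (length(missing) > 0) {
    abort(paste0("stats is missing model input column(s): ",
                 paste(missing, collapse = ", ")),
          class = "homint_config_error")
  }
  x <- as.matrix(as.data.frame(stats)[, terms, drop = FALSE])
  if (!all(is.finite(x))) {
    abort("non-finite model input", class = "homint_domain_error")
  }
  drop(cbind(1, x) %*% model$coefficients)
}

#' Fit an interface-conservation model by ordinary least squares
#'
#' Refits the linear IC model on observed (statistics, IC) pairs, e.g. when
#' recalibrating for obligate complexes. Plain OLS via [stats::lm()];
#' the returned object carries coefficient estimates, standard errors and
#' t-values accessible through [tidy()] / [glance()].
#'
#' @param data Tibble with the predictor columns for `kind` plus an `ic`
#'   response column.
#' @param kind `"nps"` or `"ps"`.
#' @return An object of class `ic_fit`.
#' @export
fit_ic <- function(data, kind = c("nps", "ps")) {
  kind <- match.arg(kind)
  terms <- ic_terms(kind)
  missing <- setdiff(c(terms, "ic"), names(data))
  if (length(missing) > 0) {
    abort(paste0("data is missing column(s): ", paste(missing, collapse = ", ")),
          class = "homint_config_error")
  }
  p <- length(terms) + 1
  if (nrow(data) < p + 1) {
    abort(sprintf("need at least %d observations to fit a %s IC model (%d coefficients)",
                  p + 1, kind, p),
          class = "homint_fit_error")
  }
  x <- cbind(1, as.matrix(as.data.frame(data)[, terms, drop = FALSE]))
  if (qr(x)$rank < p) {
    # name the offending columns the way a user can act on
    drop_one_rank <- vapply(seq_along(terms), function(i) {
      qr(x[, -(i + 1), drop = FALSE])$rank
    }, integer(1))
    collinear <- terms[drop_one_rank == qr(x)$rank]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(collinear, collapse = ", ")),
          class = "homint_fit_error")
  }
  fml <- stats::reformulate(terms, response = "ic")
  fit <- lm(fml, data = data)
  structure(list(kind = kind, fit = fit, n = nrow(data)), class = "ic_fit")
}

#' @export
print.ic_fit <- function(x, ...) {
  cat(sprintf("<ic_fit kind=%s n=%d>\n", x$kind, x$n))
  print(tidy(x))
  invisible(x)
}

#' Broom-style accessors for fitted IC models
#'
#' `tidy()` returns one row per coefficient (`term`, `estimate`,
#' `std.error`, `statistic`, `p.value`); `glance()` returns a one-row model
#' summary.
#'
#' @param x An `ic_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ic_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", ic_terms(x$kind)),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' @rdname tidy.ic_fit
#' @export
glance.ic_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    nobs = x$n,
    df.residual = x$fit$df.residual
  )
}

#' Convert a fitted IC model into a usable ranking model
#'
#' @param fit An `ic_fit` object.
#' @return An [ic_model()] with `provenance = "refit"`.
#' @export
as_ic_model <- function(fit) {
  stopifnot(inherits(fit, "ic_fit"))
  m <- ic_model(fit$kind, coefficients = unname(coef(fit$fit)))
  m$provenance <- "refit"
  m
}

#' Rank candidate templates by predicted interface conservation
#'
#' Orders hits by decreasing predicted IC and keeps the top `k` (the
#' at-most-K-nearest-template rule, default K = 10). Deterministic
#' tie-break: lower raw expectation value first, then template id
#' lexicographically.
#'
#' @param hits Tibble of zone-filtered hits with the model's predictor
#'   columns, plus `eval` and `template_id` for tie-breaking.
#' @param model An [ic_model()].
#' @param k Maximum number of templates to keep.
#' @return `hits` reordered, truncated to `k` rows, with a `predicted_ic`
#'   column appended.
#' @export
rank_templates <- function(hits, model = ic_model("nps"), k = 10) {
  if (nrow(hits) == 0) {
    return(dplyr::mutate(hits, predicted_ic = numeric(0)))
  }
  hits |>
    dplyr::mutate(predicted_ic = predict_ic(model, hits)) |>
    dplyr::arrange(dplyr::desc(.data$predicted_ic), .data$eval, .data$template_id) |>
    dplyr::slice_head(n = k)
}

#' Serialize IC model coefficients
#'
#' Key-value YAML storage for model coefficients so a recalibrated model can
#' be shared as a small config file.
#'
#' @param model An [ic_model()].
#' @param path YAML file path.
#' @export
write_ic_config <- function(model, path) {
  yaml::write_yaml(list(kind = model$kind,
                        coefficients = as.list(model$coefficients)), path)
  invisible(path)
}

#' @rdname write_ic_config
#' @export
read_ic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ic_model(cfg$kind, coefficients = unlist(cfg$coefficients))
}
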