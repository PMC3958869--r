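# Ordinary-least-squares machinery for the log10 Kfw QSPR: model fitting,
# the published-equation registry, prediction and test-set validation.

#' Fit a log10 Kfw regression model
#'
#' Ordinary least squares of `log10(Kfw)` on molecular descriptors, the
#' central estimator of the package. The left-hand side defaults to
#' `log_kfw`; a data set carrying only `kfw` gets the log10 transform
#' applied automatically. Internally the fit is delegated to [stats::lm()]
#' (QR decomposition); a rank-deficient design is an error naming the
#' aliased columns rather than a silently dropped coefficient.
#'
#' @param formula Model formula, e.g. `log_kfw ~ phi + chi1 + indicator`.
#'   The default fits the three-descriptor form on the supplied data.
#' @param data A data.frame with the descriptor columns and `log_kfw` (or
#'   `kfw`), typically [kfw_training()].
#' @return An object of class `kfw_model`: a list with `intercept`,
#'   `coefficients` (named, slopes only), `r` (multiple correlation
#'   coefficient, `sqrt(1 - SSE/SST)`), `r_signed` (for simple regressions,
#'   `r` carrying the slope's sign), `n`, `response`, `source = "refit"`,
#'   and the underlying `lm` fit in `$fit`.
#' @seealso [kfw_published()] for the verbatim published equations,
#'   [predict.kfw_model()], [kfw_validate()].
#' @examples
#' m <- kfw_fit(log_kfw ~ phi + chi1 + indicator, kfw_training())
#' coef(m)
#' m$r  # 0.989
#' @export
kfw_fit <- function(formula = log_kfw ~ phi + chi1 + indicator, data) {
  stopifnot(is.data.frame(data))
  resp <- all.vars(formula)[1]
  if (!resp %in% names(data)) {
    if (resp == "log_kfw" && "kfw" %in% names(data)) {
      data$log_kfw <- log10(data$kfw)
    } else {
      stop("response column '", resp, "' not found in `data`", call. = FALSE)
    }
  }
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  p <- ncol(X)
  if (nrow(X) <= p + 1L) {
    stop("need more observations than coefficients + 1", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("collinear design: column(s) ", paste(aliased, collapse = ", "),
         " are linearly dependent on the others", call. = FALSE)
  }
  fit <- stats::lm(formula, data)
  cf <- stats::coef(fit)
  y <- stats::model.response(mf)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  r2 <- min(max(r2, 0), 1)
  slopes <- cf[setdiff(names(cf), "(Intercept)")]
  r <- sqrt(r2)
  r_signed <- if (length(slopes) == 1L) sign(slopes[[1]]) * r else r

  structure(
    list(intercept = unname(cf[["(Intercept)"]]),
         coefficients = slopes,
         r = r, r_signed = unname(r_signed),
         n = nrow(X),
         response = resp,
         source = "refit",
         fit = fit,
         call = match.call()),
    class = "kfw_model"
  )
}

# published-equation registry: printed coefficients, never refit
.PUBLISHED <- list(
  eq4 = list(intercept = 1.545,
             coefficients = c(phi = 0.724, chi1 = 0.292, indicator = -0.227,
                              ws = 0.001),
             r = 0.99, n = 61L),
  eq5 = list(intercept = 1.447,
             coefficients = c(phi = 0.728, chi1 = 0.316, indicator = -0.224),
             r = 0.989, n = 61L),
  eq6 = list(intercept = 1.502,
             coefficients = c(phi = 0.918, chi1 = 0.177),
             r = 0.984, n = 61L),
  table1_phi = list(intercept = 1.933, coefficients = c(phi = 1.026),
                    r = 0.977, n = 61L),
  table1_kow = list(intercept = 0.319, coefficients = c(log_kow = 0.881),
                    r = 0.774, n = 61L),
  table1_chi = list(intercept = 0.750, coefficients = c(chi1 = 0.862),
                    r = 0.743, n = 61L),
  table1_I   = list(intercept = 4.144, coefficients = c(indicator = -0.846),
                    r = 0.583, n = 61L),
  table1_ws  = list(intercept = 3.936, coefficients = c(ws = -0.002),
                    r = 0.559, n = 61L),
  table1_mw  = list(intercept = 1.859, coefficients = c(mw = 0.017),
                    r = 0.474, n = 61L)
)

#' Published log10 Kfw equations, verbatim
#'
#' Returns one of the published regression models with its printed
#' coefficients, without refitting: the three multi-descriptor equations
#' (`eq4`: phi, chi1, indicator, ws; `eq5`: phi, chi1, indicator; `eq6`:
#' phi, chi1) and the six single-descriptor correlations
#' (`table1_phi`, `table1_kow`, `table1_chi`, `table1_I`, `table1_ws`,
#' `table1_mw`). The `r` stored is the printed (unsigned) correlation
#' coefficient. Note that `eq4`'s water-solubility coefficient is printed
#' as +0.001 even though the single-parameter WS slope is negative; it is
#' kept verbatim, so `eq4` extrapolates poorly to very soluble compounds.
#'
#' @param which Model identifier (see above).
#' @return A `kfw_model` with `source = "published"` and no `$fit`.
#' @examples
#' kfw_published("eq5")
#' @export
kfw_published <- function(which = c("eq4", "eq5", "eq6", "table1_phi",
                                    "table1_kow", "table1_chi", "table1_I",
                                    "table1_ws", "table1_mw")) {
  which <- match.arg(which)
  spec <- .PUBLISHED[[which]]
  structure(
    list(intercept = spec$intercept,
         coefficients = spec$coefficients,
         r = spec$r,
         r_signed = if (length(spec$coefficients) == 1L)
           sign(spec$coefficients[[1]]) * spec$r else spec$r,
         n = spec$n,
         response = "log_kfw",
         source = "published",
         id = which,
         fit = NULL,
         call = match.call()),
    class = "kfw_model"
  )
}

#' @export
coef.kfw_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict log10 Kfw (and Kfw) for new compounds
#'
#' @param object A `kfw_model`.
#' @param newdata A data.frame (or one-row descriptor set from
#'   [compute_descriptors()]) carrying every descriptor the model names.
#' @param type `"log"` for log10 Kfw (default) or `"kfw"` for the partition
#'   coefficient itself (`10^log`).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @examples
#' benzene <- data.frame(phi = 0.165, chi1 = 2, indicator = 1)
#' predict(kfw_published("eq5"), benzene)  # 1.975
#' @export
predict.kfw_model <- function(object, newdata, type = c("log", "kfw"), ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(newdata))
  need <- names(object$coefficients)
  missing <- setdiff(need, names(newdata))
  if (length(missing)) {
    stop("newdata lacks descriptor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[need])
  if (!is.numeric(X)) stop("descriptor columns must be numeric", call. = FALSE)
  pred <- object$intercept + drop(X %*% object$coefficients)
  if (type == "kfw") 10^pred else pred
}

#' @export
fitted.kfw_model <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("published models carry no training data; use predict()", call. = FALSE)
  }
  stats::fitted(object$fit)
}

#' @export
residuals.kfw_model <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("published models carry no training data", call. = FALSE)
  }
  stats::residuals(object$fit)
}

#' @export
print.kfw_model <- function(x, ...) {
  terms <- paste(sprintf("%+.3f %s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("<kfw_model, %s> log10(Kfw) = %.3f %s\n",
              x$source, x$intercept, terms))
  cat(sprintf("  r = %.3f, n = %d\n", x$r, x$n))
  invisible(x)
}

#' @export
summary.kfw_model <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    cat("\n")
    print(summary(object$fit))
  }
  invisible(object)
}

#' @export
plot.kfw_model <- function(x, ...) {
  if (is.null(x$fit)) {
    stop("published models carry no training data to plot", call. = FALSE)
  }
  obs <- stats::model.response(stats::model.frame(x$fit))
  pred <- stats::fitted(x$fit)
  plot(pred, obs, xlab = "predicted log10 Kfw", ylab = "observed log10 Kfw",
       main = sprintf("training fit (r = %.3f)", x$r), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.kfw_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fit)) {
    stop("published models carry no residual scale to simulate from",
         call. = FALSE)
  }
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation via [stats::cor.test()]'s t-transform.
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return A list with `r`, `p` (two-sided), `n`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)$r  # 1
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Single-descriptor correlation table
#'
#' One simple regression of `log10(Kfw)` on each descriptor over the
#' training set, reproducing the published correlation table. The returned
#' models report the refit intercept, slope and correlation; each model's
#' `r` is unsigned (the published convention) with the signed value in
#' `r_signed` and the p-value in `p`.
#'
#' @param data Training table (default [kfw_training()]).
#' @param descriptors Columns to regress on.
#' @return Named list of `kfw_model` objects.
#' @examples
#' tab <- single_parameter_models(kfw_training())
#' tab$phi$r  # 0.977
#' @export
single_parameter_models <- function(data = kfw_training(),
                                    descriptors = c("phi", "log_kow", "chi1",
                                                    "indicator", "ws", "mw")) {
  stopifnot(all(descriptors %in% names(data)))
  models <- lapply(descriptors, function(v) {
    m <- kfw_fit(stats::as.formula(paste("log_kfw ~", v)), data)
    m$p <- summary(m$fit)$coefficients[v, "Pr(>|t|)"]
    m
  })
  stats::setNames(models, descriptors)
}

#' Correlation between two raw descriptor columns
#'
#' @param data Compound table.
#' @param a,b Descriptor column names.
#' @return A list with `r`, `p`, `n` (see [pearson_r()]).
#' @examples
#' cross_descriptor_r(kfw_training(), "chi1", "phi")$r  # 0.676
#' @export
cross_descriptor_r <- function(data = kfw_training(), a, b) {
  stopifnot(a %in% names(data), b %in% names(data))
  pearson_r(data[[a]], data[[b]])
}

#' Within-group correlation of log10 Kfw with molecular weight
#'
#' Pooled over all training compounds, log10 Kfw and molecular weight
#' correlate only weakly; split into chemical families the correlation is
#' strong within each. The default grouping parses each SMILES and labels a
#' compound `aromatic` when it contains an aromatic ring, `alkane`
#' otherwise (cycloalkanes count as alkanes).
#'
#' @param data Training table with `mw` (default [kfw_training()]).
#' @param groups Optional factor/character vector of group labels, one per
#'   row, overriding the default structural grouping.
#' @return A data.frame with one row per group (`group`, `n`, `r`, `p`)
#'   plus a `pooled` attribute holding the ungrouped correlation.
#' @examples
#' grouped_mw_correlation(kfw_training())
#' @export
grouped_mw_correlation <- function(data = kfw_training(), groups = NULL) {
  stopifnot("mw" %in% names(data))
  if (is.null(groups)) {
    groups <- vapply(data$smiles, function(s) {
      if (parse_smiles(s)$aromatic_ring_count > 0L) "aromatic" else "alkane"
    }, character(1), USE.NAMES = FALSE)
  }
  stopifnot(length(groups) == nrow(data))
  y <- log10(data$kfw)
  out <- lapply(split(seq_len(nrow(data)), groups), function(idx) {
    if (length(idx) < 3L) {
      stop("group with fewer than 3 members", call. = FALSE)
    }
    pr <- pearson_r(data$mw[idx], y[idx])
    data.frame(n = pr$n, r = pr$r, p = pr$p)
  })
  res <- do.call(rbind, out)
  res <- cbind(group = rownames(res), res)
  rownames(res) <- NULL
  pooled <- pearson_r(data$mw, y)
  attr(res, "pooled") <- pooled
  res
}

#' Validate a model against a test set
#'
#' Predicts log10 Kfw for every test record and compares with the observed
#' values. Two agreement coefficients are reported: the ordinary (centered)
#' Pearson correlation `r`, and `r_origin`, the uncentered correlation
#' equivalent to the fit of a regression line through the origin in the
#' observed-vs-predicted plane. On the log scale `r_origin` is the
#' statistic that reproduces the published test-set agreement values (see
#' `vignette("spme-kfw-methods")`); `r` is the conventional measure and is
#' considerably lower here because the test-set dynamic range is narrow.
#'
#' @param model A `kfw_model`.
#' @param test Test table (default [kfw_test()]); must carry the model's
#'   descriptors and `kfw`.
#' @param scale Compare on `"log"` (log10 Kfw, default) or `"linear"` (Kfw).
#' @return An object of class `kfw_validation`: list with `table`
#'   (name/observed/predicted/residual), `r`, `p`, `r_origin`, `slope`,
#'   `intercept` (observed ~ predicted regression), `n`, `scale`.
#' @examples
#' kfw_validate(kfw_published("eq5"))
#' @export
kfw_validate <- function(model, test = kfw_test(),
                         scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(model, "kfw_model"), "kfw" %in% names(test))
  pred_log <- predict(model, test)
  if (scale == "log") {
    obs <- log10(test$kfw); pred <- pred_log
  } else {
    obs <- test$kfw; pred <- 10^pred_log
  }
  pr <- pearson_r(pred, obs)
  r_origin <- sum(obs * pred) / sqrt(sum(obs^2) * sum(pred^2))
  ols <- stats::lm(obs ~ pred)
  tab <- data.frame(
    name = if ("name" %in% names(test)) test$name else seq_along(obs),
    observed = obs, predicted = pred, residual = obs - pred,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, r = pr$r, p = pr$p, r_origin = r_origin,
         slope = unname(stats::coef(ols)[2]),
         intercept = unname(stats::coef(ols)[1]),
         n = length(obs), scale = scale),
    class = "kfw_validation"
  )
}

#' @export
print.kfw_validation <- function(x, ...) {
  cat(sprintf("<kfw_validation> n = %d compounds, %s scale\n", x$n, x$scale))
  cat(sprintf("  Pearson r (centered)       = %.3f\n", x$r))
  cat(sprintf("  r through origin           = %.3f\n", x$r_origin))
  cat(sprintf("  observed ~ predicted: slope %.3f, intercept %.3f\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Forward stepwise descriptor selection
#'
#' Forward selection on a descriptor pool with an entry threshold on the
#' new term's t-test p-value, approximating the stepwise procedure of
#' common statistics packages with a 95% confidence entry criterion.
#'
#' @param data Training table (default [kfw_training()]).
#' @param pool Candidate descriptor columns.
#' @param alpha Entry p-value threshold (default 0.05).
#' @return A `kfw_model` for the selected descriptor set, with the
#'   selection order in `$path`.
#' @examples
#' forward_selection(kfw_training())$path
#' @export
forward_selection <- function(data = kfw_training(),
                              pool = c("phi", "chi1", "indicator", "ws"),
                              alpha = 0.05) {
  if (!"log_kfw" %in% names(data)) data$log_kfw <- log10(data$kfw)
  selected <- character(0)
  repeat {
    remaining <- setdiff(pool, selected)
    if (!length(remaining)) break
    pvals <- vapply(remaining, function(v) {
      f <- stats::as.formula(paste("log_kfw ~",
                                   paste(c(selected, v), collapse = " + ")))
      summary(stats::lm(f, data))$coefficients[v, "Pr(>|t|)"]
    }, numeric(1))
    best <- names(which.min(pvals))
    if (pvals[best] > alpha) break
    selected <- c(selected, best)
  }
  if (!length(selected)) {
    stop("no descriptor met the entry criterion", call. = FALSE)
  }
  m <- kfw_fit(stats::as.formula(
    paste("log_kfw ~", paste(selected, collapse = " + "))), data)
  m$path <- selected
  m
}
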