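#' Fit a B-spline mixed model to one longitudinal feature
#'
#' Mean structure: group x cubic B-spline of session time, with the basis
#' saturated on the observed session grid (boundary knots at the first and
#' last session, `n_sessions - 4` interior knots at evenly spaced interior
#' grid points), so the fitted group trajectories can reproduce any set of
#' per-session group means exactly.  Random structure: one intercept per
#' device.  Fitting is restricted maximum likelihood via [lme4::lmer()],
#' deterministic given the data.
#'
#' @param data data.frame with one row per device x session.
#' @param feature name of the response column.
#' @param group name of the grouping factor column (e.g. culture or
#'   treatment arm).
#' @param time name of the session column (days in vitro, hours
#'   post-exposure, ...).
#' @param device name of the device-identifier column.
#' @return object of class `"splineLmeFit"`: list with the fitted
#'   `model` (a lmerTest fit, so Satterthwaite degrees of freedom are
#'   available to the contrast stage), the basis generator `basis(t)`,
#'   `grid`, `groupLevels`, `converged` and `singular` flags, and the
#'   column names used.
#' @export
fitSplineLme <- function(data, feature, group = "culture",
                         time = "session", device = "device") {
  need <- c(feature, group, time, device)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data.frame(
    y = data[[feature]],
    g = factor(data[[group]]),
    t = as.numeric(data[[time]]),
    dev = factor(data[[device]])
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  grid <- sort(unique(df$t))
  if (length(grid) < 2L) stop("need at least two sessions")
  nInterior <- max(0L, length(grid) - 4L)
  interior <- if (nInterior > 0L) {
    inner <- grid[-c(1L, length(grid))]
    inner[round(seq(1L, length(inner), length.out = nInterior))]
  } else {
    numeric()
  }
  boundary <- range(grid)
  basis <- function(t) {
    splines::bs(t, knots = interior, Boundary.knots = boundary, degree = 3L)
  }
  B <- basis(df$t)
  colnames(B) <- paste0("B", seq_len(ncol(B)))
  md <- cbind(df, B)
  form <- stats::as.formula(paste(
    "y ~ 0 + g +", paste0("g:", colnames(B), collapse = " + "), "+ (1 | dev)"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = md, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(model = NULL, converged = FALSE, singular = NA,
                message = conditionMessage(fit))
  } else {
    # upgrade to a lmerTest fit when possible so contrasts can use
    # Satterthwaite df; degenerate (e.g. zero-variance) fits stay plain
    # lme4 and the contrast stage falls back to residual df
    sat <- tryCatch(
      suppressWarnings(suppressMessages(lmerTest::as_lmerModLmerTest(fit))),
      error = function(e) NULL)
    if (!is.null(sat)) fit <- sat
    conv <- length(fit@optinfo$conv$lme4) == 0L
    out <- list(model = fit, converged = conv,
                singular = lme4::isSingular(fit))
  }
  out <- c(out, list(basis = basis, grid = grid,
                     groupLevels = levels(df$g), feature = feature,
                     columns = list(group = group, time = time,
                                    device = device),
                     nObs = nrow(df)))
  class(out) <- "splineLmeFit"
  out
}

#' @export
print.splineLmeFit <- function(x, ...) {
  cat(sprintf(
    "splineLmeFit: %s ~ %s x bs(%s), %d obs, groups: %s; converged: %s%s\n",
    x$feature, x$columns$group, x$columns$time, x$nObs,
    paste(x$groupLevels, collapse = "/"), x$converged,
    if (isTRUE(x$singular)) " (singular random effect)" else ""))
  invisible(x)
}

# fixed-effect design row for (group, time), aligned to coefficient names
.emmRow <- function(fit, g, t) {
  B <- fit$basis(t)
  cf <- names(lme4::fixef(fit$model))
  row <- stats::setNames(numeric(length(cf)), cf)
  row[paste0("g", g)] <- 1
  for (k in seq_len(ncol(B))) {
    nm <- paste0("g", g, ":B", k)
    if (!nm %in% cf) stop("unexpected coefficient layout: ", nm)
    row[nm] <- B[1L, k]
  }
  row
}

#' Estimated-marginal-mean contrasts with Holm adjustment
#'
#' Marginal means per group at each grid timepoint are linear functions of
#' the fixed effects; contrasts get delta-method standard errors from the
#' fixed-effect covariance and t-tests on Satterthwaite degrees of freedom
#' ([lmerTest::contest1D()]), which correctly distinguishes between-device
#' comparisons (few effective degrees of freedom) from within-device ones.
#' If the Satterthwaite computation fails for a contrast, a residual
#' approximation (observations minus fixed-effect rank) is used and
#' flagged in the `dfMethod` column.  Within the feature's comparison
#' family, the raw p-values are Holm step-down adjusted
#' ([stats::p.adjust()]).
#'
#' @param fit a `"splineLmeFit"` from [fitSplineLme()].
#' @param timepoints grid timepoints to evaluate (default: all observed
#'   sessions).
#' @param comparisons subset of `"vs-baseline"` (each later timepoint vs
#'   the first, within group) and `"between-groups"` (all group pairs at
#'   each timepoint); the two sets form one Holm family per feature.
#' @return data.frame of class `"contrastResult"` with columns `feature`,
#'   `comparison`, `group`, `timepoint`, `estimate`, `se`, `df`, `t`,
#'   `p`, `pAdjusted`.
#' @export
emmContrastsHolm <- function(fit, timepoints = fit$grid,
                             comparisons = c("vs-baseline",
                                             "between-groups")) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  if (!isTRUE(fit$converged) || is.null(fit$model))
    stop("model did not converge; contrasts suppressed")
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  p <- length(beta)
  dfResid <- max(1L, fit$nObs - p)
  rows <- list()
  addContrast <- function(L, comparison, group, timepoint) {
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    sat <- tryCatch(
      suppressMessages(lmerTest::contest1D(fit$model, L,
                                           ddf = "Satterthwaite")),
      error = function(e) NULL)
    if (!is.null(sat) && is.finite(sat$df) && sat$df > 0 &&
        is.finite(sat$`Pr(>|t|)`)) {
      df <- sat$df
      tv <- sat$`t value`
      pv <- sat$`Pr(>|t|)`
      method <- "satterthwaite"
    } else {
      df <- dfResid
      tv <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
      pv <- if (se > 0) 2 * stats::pt(-abs(tv), df) else as.numeric(est == 0)
      method <- "residual"
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = fit$feature, comparison = comparison, group = group,
      timepoint = timepoint, estimate = est, se = se, df = df,
      t = tv, p = pv, dfMethod = method, stringsAsFactors = FALSE)
  }
  base <- min(fit$grid)
  if ("vs-baseline" %in% comparisons) {
    for (g in fit$groupLevels) {
      for (tp in setdiff(timepoints, base)) {
        L <- .emmRow(fit, g, tp) - .emmRow(fit, g, base)
        addContrast(L, sprintf("vs-baseline(%g)", base), g, tp)
      }
    }
  }
  if ("between-groups" %in% comparisons && length(fit$groupLevels) > 1L) {
    gl <- fit$groupLevels
    for (i in seq_len(length(gl) - 1L)) {
      for (j in seq.int(i + 1L, length(gl))) {
        for (tp in timepoints) {
          L <- .emmRow(fit, gl[i], tp) - .emmRow(fit, gl[j], tp)
          addContrast(L, "between-groups",
                      paste(gl[i], "-", gl[j]), tp)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$pAdjusted <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  class(out) <- c("contrastResult", class(out))
  out
}

#' Estimated marginal means at grid timepoints
#'
#' @param fit a `"splineLmeFit"`.
#' @param timepoints timepoints to evaluate.
#' @return data.frame with `group`, `timepoint`, `emmean`, `se`.
#' @export
estimatedMarginalMeans <- function(fit, timepoints = fit$grid) {
  if (!isTRUE(fit$converged) || is.null(fit$model))
    stop("model did not converge")
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  rows <- list()
  for (g in fit$groupLevels) {
    for (tp in timepoints) {
      L <- .emmRow(fit, g, tp)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, timepoint = tp, emmean = sum(L * beta),
        se = sqrt(drop(t(L) %*% V %*% L)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample pooled-variance t-test
#'
#' Classical Student's t-test (equal-variance), as used to compare
#' trough-to-peak durations or E/I percentages between two culture types
#' at a single timepoint.  Degenerate zero-variance samples with equal
#' means give t = 0, p = 1.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return list with `t`, `df`, `p`, and the two sample means.
#' @export
twoSampleTtest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least two observations")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (sp2 == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = df, p = 1, meanA = mean(a), meanB = mean(b)))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                meanA = mean(a), meanB = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = mean(a), meanB = mean(b))
}
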