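#' Assemble an aligned 1-km predictor stack
#'
#' Brings base-resolution predictor layers onto the 1-km template: continuous
#' layers by block mean, circular layers (aspect, degrees) by the circular
#' mean of unit vectors (so a block of {350, 10} degrees averages to 0, not
#' 180), categorical layers by majority. Layers already on the template
#' geometry pass through unchanged.
#'
#' @param layers named list of [Grid-class]s at base or template resolution.
#' @param template the 1-km [Grid-class].
#' @param circular names of circular (degree) layers.
#' @param categorical names of categorical layers.
#' @return named list of [Grid-class]s aligned to the template.
#' @export
buildStack <- function(layers, template, circular = "aspect",
                       categorical = "landcover") {
  out <- lapply(names(layers), function(nm) {
    g <- layers[[nm]]
    if (sameGeometry(g, template)) return(g)
    f <- template@cellSize / g@cellSize
    if (abs(f - round(f)) > 1e-9 || f < 1)
      stop("layer '", nm, "' cell size ", g@cellSize,
           " does not divide the template cell size")
    if (nrow(g@values) * g@cellSize < nrow(template@values) * template@cellSize - 1e-6 ||
        ncol(g@values) * g@cellSize < ncol(template@values) * template@cellSize - 1e-6)
      stop("layer '", nm, "' does not cover the template extent")
    stat <- if (nm %in% circular) "circular_mean"
            else if (nm %in% categorical) "majority" else "mean"
    agg <- aggregateGrid(g, round(f), stat)
    stopIfMisaligned(agg, template, paste0("aggregated layer '", nm, "'"))
    agg
  })
  names(out) <- names(layers)
  out
}

#' Sample complete 1-km cells for driver analysis
#'
#' Uniform random sample without replacement over the cells where every
#' predictor and the richness response are non-nodata. When fewer complete
#' cells exist than requested, all of them are used with a warning.
#'
#' @param stack named list of aligned predictor [Grid-class]s.
#' @param richness response [Grid-class] on the same geometry.
#' @param n sample size (the study design uses 1500 pixels).
#' @param seed integer seed; identical seeds give identical samples.
#' @return a \code{driverSample}: list with \code{cells} (row-major cell
#'   ids), \code{X} (data.frame of predictors) and \code{y} (richness).
#' @export
sampleCells <- function(stack, richness, n = 1500, seed = 1) {
  for (nm in names(stack)) stopIfMisaligned(stack[[nm]], richness,
                                            paste0("layer '", nm, "'"))
  nr <- nrow(richness@values); nc <- ncol(richness@values)
  # row-major cell ids to match the PAM convention
  vals <- lapply(stack, function(g) as.vector(t(g@values)))
  X <- as.data.frame(vals)
  y <- as.vector(t(richness@values))
  ok <- complete.cases(X) & is.finite(y)
  if (!any(ok)) stop("no complete cells to sample")
  ids <- which(ok)
  if (length(ids) < n) {
    warning("only ", length(ids), " complete cells available (requested ", n,
            "): using all")
    sel <- ids
  } else {
    set.seed(seed)
    sel <- sort(sample(ids, n))
  }
  structure(list(cells = sel, X = X[sel, , drop = FALSE], y = y[sel]),
            class = "driverSample")
}

#' @export
print.driverSample <- function(x, ...) {
  cat(sprintf("driverSample: %d cells x %d predictors (richness %g-%g)\n",
              length(x$cells), ncol(x$X), min(x$y), max(x$y)))
  invisible(x)
}

#' Support vector regression of richness on the predictor stack
#'
#' Radial-kernel epsilon-SVR with internal standardisation; cost and kernel
#' width are tuned over a small grid by k-fold cross-validated RMSE, with a
#' fixed fold assignment derived from \code{seed} so the tuned parameters
#' are reproducible. The cross-validated R-squared
#' (\eqn{1 - SSE/SS_{tot}} of the pooled out-of-fold predictions) is
#' reported as the honest model skill.
#'
#' @param sample a \code{driverSample} from [sampleCells()].
#' @param folds cross-validation folds.
#' @param seed integer seed.
#' @param costs,gammas tuning grids (gammas default to 1/p scaled by 0.5,
#'   1 and 2).
#' @return list with \code{model} (the fitted \code{e1071::svm}),
#'   \code{cvR2}, \code{best} (tuned parameters) and the fold assignment.
#' @export
svrFit <- function(sample, folds = 10, seed = 1, costs = c(1, 10, 100),
                   gammas = NULL) {
  X <- sample$X; y <- sample$y
  if (sd(y) == 0) stop("degenerate response: richness is constant")
  p <- ncol(X)
  if (is.null(gammas)) gammas <- c(0.5, 1, 2) / p
  n <- nrow(X)
  set.seed(seed)
  foldId <- base::sample(rep(seq_len(folds), length.out = n))
  tuneGrid <- expand.grid(cost = costs, gamma = gammas)
  cvRmse <- numeric(nrow(tuneGrid))
  for (gi in seq_len(nrow(tuneGrid))) {
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      tr <- foldId != f
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "radial", cost = tuneGrid$cost[gi],
                      gamma = tuneGrid$gamma[gi], scale = TRUE)
      pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
    }
    cvRmse[gi] <- sqrt(mean((pred - y)^2))
  }
  best <- tuneGrid[which.min(cvRmse), ]
  pred <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    m <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                    kernel = "radial", cost = best$cost, gamma = best$gamma,
                    scale = TRUE)
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
  }
  cvR2 <- 1 - sum((pred - y)^2) / sum((y - mean(y))^2)
  model <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      cost = best$cost, gamma = best$gamma, scale = TRUE)
  list(model = model, cvR2 = cvR2, best = as.list(best), foldId = foldId,
       cvRmse = cvRmse, tuneGrid = tuneGrid)
}

#' Rank richness drivers by smoother R-squared
#'
#' For each predictor independently, a univariate local-regression smoother
#' (loess, span 0.75) of richness on that predictor is fitted and its
#' R-squared against the intercept-only null model computed:
#' \code{raw = max(0, 1 - SSE_smoother / SSE_null)}. Raw scores are rescaled
#' so the best predictor scores 100 (all-zero scores stay 0). Constant
#' predictors score 0. The ranking is invariant to affine rescaling of any
#' predictor.
#'
#' @param sample a \code{driverSample}.
#' @param span loess span of the smoother.
#' @param rescale rescale the maximum to 100 (set FALSE for raw R-squared).
#' @return named numeric vector of scores, sorted decreasing, with the raw
#'   R-squared values attached as \code{attr(, "raw")}.
#' @export
rankImportance <- function(sample, span = 0.75, rescale = TRUE) {
  if (nrow(sample$X) < 30) stop("need at least 30 rows to rank importance")
  y <- sample$y
  sseNull <- sum((y - mean(y))^2)
  raw <- vapply(names(sample$X), function(nm) {
    x <- sample$X[[nm]]
    if (!is.finite(sd(x)) || sd(x) == 0) return(0)
    fit <- tryCatch(loess(y ~ x, span = span, degree = 2,
                          family = "gaussian"),
                    error = function(e) NULL)
    if (is.null(fit)) return(0)
    max(0, 1 - sum(fit$residuals^2) / sseNull)
  }, numeric(1))
  scores <- raw
  if (rescale && max(raw) > 0) scores <- raw / max(raw) * 100
  ord <- order(scores, decreasing = TRUE)
  out <- scores[ord]
  attr(out, "raw") <- raw[ord]
  out
}

#' Partial-dependence curve of one predictor
#'
#' For each of \code{nPoints} evenly spaced values across the predictor's
#' observed range, the model prediction is averaged over all sample rows
#' with that predictor clamped to the value, marginalising the others.
#' By default the curve is computed on a random-forest surrogate refit to
#' the sample (the standard partial-plot practice); pass the \code{model}
#' element of [svrFit()] to compute it on the SVR handle instead.
#'
#' @param sample a \code{driverSample}.
#' @param predictor predictor name.
#' @param nPoints number of evaluation points.
#' @param model prediction model; \code{NULL} fits a random-forest surrogate
#'   (seeded for reproducibility).
#' @param seed seed for the surrogate forest.
#' @return data.frame with columns \code{x} and \code{yhat}.
#' @export
partialDependence <- function(sample, predictor, nPoints = 50, model = NULL,
                              seed = 1) {
  if (!predictor %in% names(sample$X))
    stop("predictor not in the sample: ", predictor)
  if (is.null(model)) {
    set.seed(seed)
    model <- randomForest::randomForest(sample$X, sample$y, ntree = 300)
  }
  xs <- seq(min(sample$X[[predictor]]), max(sample$X[[predictor]]),
            length.out = nPoints)
  yhat <- vapply(xs, function(v) {
    Xc <- sample$X
    Xc[[predictor]] <- v
    mean(predict(model, Xc))
  }, numeric(1))
  data.frame(x = xs, yhat = yhat)
}

#' Direction of a predictor's effect on richness
#'
#' Pearson correlation of richness with the predictor plus the classical
#' two-sided p-value. The p-value here is spatially uncorrected; the
#' autocorrelation-corrected test lives in [dutilleulCorrelation()].
#'
#' @param sample a \code{driverSample}.
#' @param predictor predictor name.
#' @return list with \code{r}, \code{p} and a significance label.
#' @export
directionOfEffect <- function(sample, predictor) {
  if (!predictor %in% names(sample$X))
    stop("predictor not in the sample: ", predictor)
  ct <- cor.test(sample$X[[predictor]], sample$y)
  lab <- if (ct$p.value < 0.01) "p<0.01"
         else if (ct$p.value < 0.05) "p<0.05" else "ns"
  list(r = unname(ct$estimate), p = ct$p.value, label = lab)
}
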