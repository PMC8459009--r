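# Quadratic response-surface regression of assay accuracy on normalized
# membrane parameters (no cross terms), with a vertex-form rewriter.

#' QuadraticSurfaceFit: accuracy as a quadratic in each predictor
#'
#' @slot intercept fitted intercept.
#' @slot coefficients data.frame with one row per predictor: `predictor`,
#'   `linear`, `quadratic`.
#' @slot residuals fit residuals.
#' @slot fitted fitted values.
#' @slot predictors predictor names.
#' @exportClass QuadraticSurfaceFit
setClass("QuadraticSurfaceFit",
         representation(intercept = "numeric", coefficients = "data.frame",
                        residuals = "numeric", fitted = "numeric",
                        predictors = "character"))

#' @describeIn QuadraticSurfaceFit-class compact description.
#' @param object a `QuadraticSurfaceFit`.
#' @export
setMethod("show", "QuadraticSurfaceFit", function(object) {
  cat("Quadratic response surface: accuracy ~ intercept + sum(b x + g x^2)\n")
  cat("  intercept:", format(object@intercept, digits = 4), "\n")
  print(object@coefficients, row.names = FALSE, digits = 4)
  cat("  residual sd:", format(sd(object@residuals), digits = 4), "\n")
  invisible(NULL)
})

#' Fit a quadratic response surface without cross terms
#'
#' Fits `accuracy = b0 + sum_i b_i x_i + sum_i g_i x_i^2` over the given
#' predictors. The model is linear in its 2p+1 coefficients, so the default
#' is ordinary least squares; `method = "iterative"` instead runs an
#' iterative (Gauss-Newton) least-squares solve started from all-ones
#' coefficients, which converges to the same solution and is retained only
#' for parity with descriptions of the procedure.
#'
#' @param samples data.frame holding the predictor columns (normalized to
#'   [0, 1]) and the response column.
#' @param predictors predictor column names; default every column except the
#'   response.
#' @param response response column name (default `"accuracy"`).
#' @param method `"ols"` or `"iterative"`.
#' @return a [QuadraticSurfaceFit-class] object.
#' @examples
#' x <- seq(0, 1, length.out = 11)
#' d <- data.frame(x1 = x, accuracy = 70 + 3 * x - 2 * x^2)
#' fitQuadraticResponse(d, "x1")
#' @export
fitQuadraticResponse <- function(samples, predictors = NULL,
                                 response = "accuracy",
                                 method = c("ols", "iterative")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(samples), response %in% names(samples))
  if (is.null(predictors)) predictors <- setdiff(names(samples), response)
  stopifnot(all(predictors %in% names(samples)))
  p <- length(predictors)
  if (nrow(samples) < 2 * p + 1) {
    stop(sprintf("need at least %d samples for %d predictors (2p + 1 free coefficients)",
                 2 * p + 1, p))
  }
  for (pr in predictors) {
    if (sd(samples[[pr]]) == 0) {
      stop("predictor constant across samples (rank-deficient design): ", pr)
    }
  }
  X <- as.matrix(samples[, predictors, drop = FALSE])
  design <- cbind(1, X, X^2)
  if (qr(design)$rank < ncol(design)) {
    stop("rank-deficient design: predictors and their squares are collinear")
  }
  y <- as.numeric(samples[[response]])
  if (method == "ols") {
    beta <- qr.solve(design, y)
  } else {
    # Gauss-Newton on a model linear in its coefficients: the Jacobian is
    # the design matrix, so from any start (all ones) one step lands on the
    # least-squares solution; iterate to tolerance anyway for form
    beta <- rep(1, ncol(design))
    for (it in 1:25) {
      r <- y - design %*% beta
      step <- qr.solve(design, r)
      beta <- beta + step
      if (max(abs(step)) < 1e-12) break
    }
    beta <- as.vector(beta)
  }
  beta <- unname(as.vector(beta))
  fittedv <- as.vector(design %*% beta)
  new("QuadraticSurfaceFit",
      intercept = beta[1L],
      coefficients = data.frame(predictor = predictors,
                                linear = beta[1L + seq_len(p)],
                                quadratic = beta[1L + p + seq_len(p)]),
      residuals = y - fittedv, fitted = fittedv,
      predictors = predictors)
}

#' Predict accuracy from a fitted response surface
#'
#' @param object a [QuadraticSurfaceFit-class] object.
#' @param newdata data.frame with the predictor columns.
#' @param ... unused.
#' @return numeric vector of predicted accuracies.
#' @export
setMethod("predict", "QuadraticSurfaceFit", function(object, newdata, ...) {
  X <- as.matrix(newdata[, object@predictors, drop = FALSE])
  as.vector(object@intercept + X %*% object@coefficients$linear +
              X^2 %*% object@coefficients$quadratic)
})

#' Vertex (parabola) form of a fitted surface
#'
#' Rewrites each predictor's contribution `b x + g x^2` by completing the
#' square: `g (x - h)^2` with vertex `h = -b / (2 g)`, and accumulates the
#' constants into a single shifted intercept
#' `b0 - sum_i b_i^2 / (4 g_i)`. The sign of `g` tells whether accuracy
#' rises (positive curvature, vertex is a minimum) or falls away from the
#' vertex.
#'
#' @param fit a [QuadraticSurfaceFit-class] object.
#' @return data.frame with `predictor`, `curvature` (g), `vertex` (h), and
#'   attribute `"constant"` (the shifted intercept).
#' @export
vertexForm <- function(fit) {
  co <- fit@coefficients
  if (any(co$quadratic == 0)) {
    stop("vertex form undefined for zero quadratic coefficient(s)")
  }
  h <- -co$linear / (2 * co$quadratic)
  out <- data.frame(predictor = co$predictor, curvature = co$quadratic,
                    vertex = h)
  attr(out, "constant") <- fit@intercept -
    sum(co$linear^2 / (4 * co$quadratic))
  out
}

# the five predictors of the surface experiment: (population, field) pairs
.SURFACE_PREDICTORS <- list(
  C_L5PC = list(population = "L5 PC", param = "C"),
  C_L6PC = list(population = "L6 PC", param = "C"),
  Vth_L23LLIN = list(population = "L2/3 LL-IN", param = "V_th"),
  Vth_L5LLIN = list(population = "L5 LL-IN", param = "V_th"),
  Vth_L6LLIN = list(population = "L6 LL-IN", param = "V_th"))

#' Table at a normalized point between two species
#'
#' Interpolates the five surface parameters (capacitance of L5/L6 pyramidal
#' cells, threshold of the three LL-IN populations) linearly between the
#' rodent table (x = 0) and the human table (x = 1), leaving every other
#' field at the base (rodent) value.
#'
#' @param config configuration list.
#' @param x named or ordered numeric vector of length 5 in [0, 1], order
#'   `C_L5PC`, `C_L6PC`, `Vth_L23LLIN`, `Vth_L5LLIN`, `Vth_L6LLIN`.
#' @param base,target species names (default rodent -> human).
#' @return interpolated parameter table.
#' @export
surfaceTable <- function(config, x, base = "rodent", target = "human") {
  stopifnot(length(x) == length(.SURFACE_PREDICTORS))
  tb <- speciesTable(config, base)
  tg <- speciesTable(config, target)
  keys <- populationKey(tb$layer, tb$cell_class)
  tkeys <- populationKey(tg$layer, tg$cell_class)
  for (i in seq_along(.SURFACE_PREDICTORS)) {
    pd <- .SURFACE_PREDICTORS[[i]]
    r <- which(keys == pd$population)
    rt <- which(tkeys == pd$population)
    v0 <- tb[[pd$param]][r]
    v1 <- tg[[pd$param]][rt]
    tb[[pd$param]][r] <- v0 + x[i] * (v1 - v0)
  }
  # LBC rows mirror the PC rows of their layer
  completeAeifTable(tb[tb$cell_class != "LBC", , drop = FALSE])
}

#' Response-surface experiment
#'
#' Samples the five normalized parameters with a Latin hypercube over
#' [0, 1]^5 (rodent values at 0, human at 1), runs the assay at each sample
#' point, and fits the no-cross-term quadratic surface to the measured
#' accuracies.
#'
#' @inheritParams runAssay
#' @param n_samples number of Latin-hypercube sample points.
#' @param n_repeats assay repeats averaged per sample point.
#' @param pattern input pattern (default the square).
#' @param seed master seed (controls both the hypercube and the repeats).
#' @param ... passed to [runAssay()].
#' @return list with `samples` (data.frame of predictors + accuracy) and
#'   `fit` (a [QuadraticSurfaceFit-class]).
#' @export
responseSurface <- function(config, n_samples = 30, n_repeats = 3,
                            pattern = loadPattern("square"), seed = 1, ...) {
  set.seed(as.integer(seed))
  X <- lhs::randomLHS(n_samples, length(.SURFACE_PREDICTORS))
  colnames(X) <- names(.SURFACE_PREDICTORS)
  seeds <- repeatSeeds(seed + 1, n_repeats)
  acc <- vapply(seq_len(n_samples), function(i) {
    tb <- surfaceTable(config, X[i, ])
    mean(vapply(seeds, function(s) {
      runAssay(config, tb, pattern, s, ...)$accuracy
    }, numeric(1)))
  }, numeric(1))
  samples <- cbind(as.data.frame(X), accuracy = acc)
  list(samples = samples, fit = fitQuadraticResponse(
    samples, predictors = names(.SURFACE_PREDICTORS)))
}
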