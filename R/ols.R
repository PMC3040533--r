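## Ordinary least squares for X-Y coordinate data: the demo's analytic
## payload.  Closed form: slope = S_xy / S_xx, intercept = ybar - slope*xbar;
## exact for collinear input.

.notFittable <- function(msg) {
  stop(structure(class = c("sadishare_not_fittable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Fit a line to X-Y coordinate data by ordinary least squares
#'
#' @param x,y numeric vectors of equal length; at least two distinct x
#'   values are required (OLS is undefined below that) — otherwise a
#'   \code{sadishare_not_fittable} error is raised, which annotation
#'   services translate into a per-subject skip.
#' @return a \code{\linkS4class{LinearRegressionModel}}.
#' @examples
#' m <- olsFit(c(0, 1, 2), c(1, 2, 3))
#' slope(m)      # 1
#' intercept(m)  # 1
#' @export
olsFit <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    .notFittable("non-finite coordinates")
  if (length(unique(x)) < 2L)
    .notFittable("need at least 2 distinct x values to fit a line")
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  b <- sxy / sxx
  new("LinearRegressionModel", slope = b, intercept = ybar - b * xbar)
}

#' Accessors for regression models
#'
#' @param m a \code{LinearRegressionModel}.
#' @return numeric(1).
#' @export
slope <- function(m) m@slope

#' @rdname slope
#' @export
intercept <- function(m) m@intercept

setMethod("show", "LinearRegressionModel", function(object) {
  cat(sprintf("LinearRegressionModel: y = %.6g + %.6g * x\n",
              object@intercept, object@slope))
})
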