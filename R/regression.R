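## Damage-vs-mutation regression and prediction-interval outlier analysis.

.checkPairs <- function(pairs) {
    need <- c("context", "damage", "mutation")
    if (!all(need %in% names(pairs)))
        stop("pairs needs columns: ", paste(need, collapse = ", "))
    if (any(pairs$damage < 0) || any(pairs$mutation < 0))
        stop("damage and mutation frequencies must be >= 0")
    pairs
}

#' Least-squares regression of mutation on damage frequency
#'
#' Ordinary least squares of per-context C>T mutation frequency on
#' per-context CPD frequency, with the Pearson correlation and its
#' two-sided p-value (t distribution). Contexts enter unweighted; an
#' optional context can be excluded before fitting (e.g. a suspected
#' outlier such as TCG).
#'
#' @param pairs data.frame with columns \code{context}, \code{damage},
#'   \code{mutation}.
#' @param exclude optional context label to leave out.
#' @return List with \code{fit} (the lm object), \code{slope},
#'   \code{intercept}, \code{r}, \code{pValue}, \code{n},
#'   \code{excluded}.
#' @export
fitDamageMutationRegression <- function(pairs, exclude = NULL) {
    pairs <- .checkPairs(pairs)
    if (!is.null(exclude)) {
        hit <- pairs$context %in% exclude
        if (!any(hit)) stop("context to exclude not present: ", exclude)
        pairs <- pairs[!hit, , drop = FALSE]
    }
    if (nrow(pairs) < 3L) stop("need at least 3 pairs after exclusion")
    if (var(pairs$damage) == 0) stop("zero variance in damage frequency")
    fit <- lm(mutation ~ damage, data = pairs)
    ct <- stats::cor.test(pairs$damage, pairs$mutation)
    list(fit = fit, slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         r = unname(ct$estimate), pValue = ct$p.value,
         n = nrow(pairs), excluded = exclude)
}

#' Predict with a 95% interval at a new damage frequency
#'
#' Returns the regression prediction at \code{x0} with the half-width of
#' the \eqn{1-\alpha} interval. The default is the prediction interval
#' for a new observation,
#' \eqn{t_{1-\alpha/2,n-2}\, s \sqrt{1 + 1/n + (x_0-\bar x)^2/S_{xx}}},
#' the conservative reading of "confidence interval of the predicted
#' value"; \code{type = "confidence"} gives the mean-response interval
#' instead.
#'
#' @param fit result of [fitDamageMutationRegression()].
#' @param x0 damage frequency at which to predict.
#' @param alpha interval level is \code{1 - alpha} (default 0.05).
#' @param type \code{"prediction"} or \code{"confidence"}.
#' @return List with \code{predicted} and \code{halfWidth}.
#' @export
predictWithInterval <- function(fit, x0, alpha = 0.05,
                                type = c("prediction", "confidence")) {
    type <- match.arg(type)
    lmfit <- fit$fit
    n <- fit$n
    if (n <= 2L) stop("need more than 2 points for an interval")
    pr <- suppressWarnings(predict(lmfit,
        newdata = data.frame(damage = x0),
        interval = type, level = 1 - alpha))
    list(predicted = unname(pr[1L, "fit"]),
         halfWidth = unname(pr[1L, "fit"] - pr[1L, "lwr"]))
}

#' Fold-enrichment outlier report for one context
#'
#' Tests whether a context's mutation frequency exceeds what its damage
#' frequency predicts. The regression is fitted leaving the tested
#' context out (so a true outlier does not inflate its own prediction;
#' \code{includeSelf = TRUE} reproduces an all-points fit for
#' comparison), the \eqn{1-\alpha} prediction interval is evaluated at
#' the context's damage frequency, and the fold enrichment is
#' observed/predicted.
#'
#' @param pairs data.frame with columns \code{context}, \code{damage},
#'   \code{mutation}.
#' @param context the context to test (e.g. \code{"TCG"}).
#' @param alpha interval level is \code{1 - alpha}.
#' @param includeSelf fit on all points including the tested context.
#' @param type interval type, see [predictWithInterval()].
#' @return List with \code{context}, \code{observed}, \code{predicted},
#'   \code{halfWidth}, \code{fold}, \code{outsideInterval}, \code{rWith},
#'   \code{rWithout}, \code{pWith}, \code{pWithout}.
#' @export
outlierReport <- function(pairs, context, alpha = 0.05,
                          includeSelf = FALSE, type = "prediction") {
    pairs <- .checkPairs(pairs)
    row <- pairs[pairs$context == context, , drop = FALSE]
    if (nrow(row) != 1L) stop("context not present exactly once: ", context)
    fitAll <- fitDamageMutationRegression(pairs)
    fitLoo <- fitDamageMutationRegression(pairs, exclude = context)
    fit <- if (includeSelf) fitAll else fitLoo
    pr <- predictWithInterval(fit, row$damage, alpha = alpha, type = type)
    y0 <- row$mutation
    yhat <- pr$predicted
    fold <- if (yhat > 0) y0 / yhat else NA_real_
    list(context = context, observed = y0, predicted = yhat,
         halfWidth = pr$halfWidth, fold = fold,
         outsideInterval = abs(y0 - yhat) > pr$halfWidth,
         rWith = fitAll$r, rWithout = fitLoo$r,
         pWith = fitAll$pValue, pWithout = fitLoo$pValue)
}
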