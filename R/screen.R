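# Spearman screening of every feature against the UCLA score, with
# optional rank-based partial correlation controlling age and sex, and the
# Fisher-z post-hoc power computation.

midRanks <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with t-approximation p-value
#'
#' \eqn{\rho} is the Pearson correlation of mid-ranks; the two-sided
#' p-value uses \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees
#' of freedom. An exact permutation p-value (full enumeration) is available
#' for \eqn{n \le 8}.
#'
#' @param x,y numeric vectors of equal length \eqn{n \ge 4}; ties allowed.
#' @param exact if TRUE, enumerate all \eqn{n!} permutations
#'   (supported for \eqn{n \le 8}).
#' @return list with \code{rho} and \code{p_value}.
#' @export
spearmanRho <- function(x, y, exact = FALSE) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 4L) stop("need n >= 4")
    rx <- midRanks(x); ry <- midRanks(y)
    if (sd(rx) == 0 || sd(ry) == 0) stop("zero rank variance")
    rho <- cor(rx, ry)
    if (exact) {
        if (n > 8L) stop("exact permutation mode supports n <= 8")
        perms <- permuteAll(n)
        obs <- abs(rho)
        rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
        p <- mean(abs(rhos) >= obs - 1e-12)
    } else {
        tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
        p <- 2 * pt(-abs(tt), df = n - 2)
        p <- max(p, .Machine$double.xmin)
    }
    list(rho = rho, p_value = p)
}

# All permutations of 1..n as rows (n <= 8).
permuteAll <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- permuteAll(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0L
    for (i in seq_len(n)) {
        rows <- r + seq_len(nrow(sub))
        out[rows, 1L] <- i
        rest <- setdiff(seq_len(n), i)
        out[rows, -1L] <- matrix(rest[sub], nrow(sub))
        r <- r + nrow(sub)
    }
    out
}

#' Rank-based partial Spearman correlation
#'
#' Rank-transforms \code{x} and \code{y}, residualizes each on an intercept
#' plus the confounder columns by least squares, and correlates the
#' residuals; the t-test uses \eqn{n - 2 - k} degrees of freedom for
#' \eqn{k} confounders.
#'
#' @param x,y numeric vectors.
#' @param confounders numeric matrix or data.frame (e.g. age and 0/1 sex),
#'   one row per observation.
#' @return list with \code{rho} and \code{p_value} for the adjusted
#'   association.
#' @export
partialSpearman <- function(x, y, confounders) {
    confounders <- as.matrix(confounders)
    n <- length(x)
    k <- ncol(confounders)
    stopifnot(length(y) == n, nrow(confounders) == n, n > k + 2L)
    Z <- cbind(1, confounders)
    if (qr(Z)$rank < ncol(Z)) stop("collinear confounders")
    rx <- midRanks(x); ry <- midRanks(y)
    ex <- lm.fit(Z, rx)$residuals
    ey <- lm.fit(Z, ry)$residuals
    if (sd(ex) == 0 || sd(ey) == 0) stop("zero residual variance")
    rho <- cor(ex, ey)
    df <- n - 2L - k
    tt <- rho * sqrt(df / max(1 - rho^2, 1e-300))
    list(rho = rho, p_value = max(2 * pt(-abs(tt), df), .Machine$double.xmin))
}

#' Screen all features against the loneliness score
#'
#' Spearman correlation of every feature with the UCLA score; p-values are
#' deliberately unadjusted (each feature is tested at \code{alpha}), with a
#' Benjamini--Hochberg column available on request. Optionally adds
#' age/sex-partialled correlations.
#'
#' @param x a [SpeechFeatureSet-class], or a numeric matrix/data.frame with
#'   participants as rows and named feature columns.
#' @param scores UCLA scores (taken from \code{colData} for a
#'   \code{SpeechFeatureSet}).
#' @param alpha significance level (default 0.05).
#' @param confounders optional confounder matrix; for a
#'   \code{SpeechFeatureSet}, \code{adjust = TRUE} uses age and 0/1-coded
#'   sex from \code{colData}.
#' @param adjust if TRUE, compute partial correlations (needs confounders
#'   or a \code{SpeechFeatureSet}).
#' @param bh if TRUE, add Benjamini--Hochberg adjusted p-values (off by
#'   default: screening mirrors the unadjusted protocol).
#' @return data.frame (one row per feature, sorted by \eqn{|\rho|}
#'   descending, ties by name) with columns \code{feature}, \code{rho},
#'   \code{p}, \code{significant}, and optionally \code{adjusted_rho},
#'   \code{adjusted_p}, \code{p_bh}. Constant features get \code{rho = NA}
#'   and are never flagged.
#' @export
screenFeatures <- function(x, scores = NULL, alpha = 0.05,
                           confounders = NULL, adjust = FALSE, bh = FALSE) {
    if (is(x, "SpeechFeatureSet")) {
        if (is.null(scores)) scores <- uclaScores(x)
        if (adjust && is.null(confounders)) {
            cd <- SummarizedExperiment::colData(x)
            confounders <- cbind(age = cd$age,
                                 sex = as.numeric(factor(cd$sex)) - 1)
        }
        x <- featureMatrix(x)
    }
    x <- as.matrix(x)
    stopifnot(!is.null(colnames(x)), length(scores) == nrow(x))
    res <- lapply(colnames(x), function(f) {
        v <- x[, f]
        r <- tryCatch(spearmanRho(v, scores),
                      error = function(e) list(rho = NA_real_,
                                               p_value = NA_real_))
        adj <- if (adjust)
            tryCatch(partialSpearman(v, scores, confounders),
                     error = function(e) list(rho = NA_real_,
                                              p_value = NA_real_))
        else list(rho = NA_real_, p_value = NA_real_)
        data.frame(feature = f, rho = r$rho, p = r$p_value,
                   adjusted_rho = adj$rho, adjusted_p = adj$p_value)
    })
    out <- do.call(rbind, res)
    out$significant <- !is.na(out$p) & out$p < alpha
    if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
    if (!adjust) out$adjusted_rho <- out$adjusted_p <- NULL
    out <- out[order(-abs(out$rho), out$feature), ]
    rownames(out) <- NULL
    out
}

#' Post-hoc power for a Spearman correlation
#'
#' Fisher-z normal approximation for a two-sided test at level \code{alpha}:
#' \deqn{power = \Phi(\sqrt{n-3}\,|\mathrm{atanh}\,\rho| - z_{1-\alpha/2}).}
#'
#' @param rho assumed correlation, \eqn{|\rho| < 1}.
#' @param n sample size, \eqn{n > 3}.
#' @param alpha significance level (default 0.05).
#' @return power in \eqn{[0, 1]}.
#' @examples
#' posthocPower(0.41, 57)  # ~0.89
#' @export
posthocPower <- function(rho, n, alpha = 0.05) {
    stopifnot(is.finite(rho), abs(rho) < 1, n > 3, alpha > 0, alpha < 1)
    pnorm(sqrt(n - 3) * abs(atanh(rho)) - qnorm(1 - alpha / 2))
}
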