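# Model evaluation protocol: mean + 1SD cutoff, per-training-fold top-16
# acoustic pre-selection, sequential forward selection against an inner-CV
# objective, kNN / random-forest / SVM fits, and iterated stratified
# 10-fold cross-validation with t-interval confidence bounds over the
# iteration means.
#
# Leakage discipline: imputation medians, standardization moments, the
# acoustic pre-selection, SFS and any grid search are computed on training
# rows only, inside each fold.

#' High-loneliness cutoff score
#'
#' The binary-classification cutoff is the sample mean plus one sample
#' (n-1) standard deviation of the cohort's UCLA scores, rounded to the
#' nearest integer; participants scoring greater than or equal to the
#' cutoff form the high-loneliness class.
#'
#' @param scores numeric vector of UCLA total scores, \eqn{n \ge 2}.
#' @return integer cutoff score.
#' @examples
#' determineCutoff(c(rep(37 - 8.6, 28), rep(37 + 8.6, 29)))
#' @export
determineCutoff <- function(scores) {
    stopifnot(length(scores) >= 2L, all(is.finite(scores)))
    as.integer(round(mean(scores) + sd(scores)))
}

#' High-loneliness class labels
#'
#' @param scores UCLA scores.
#' @param cutoff cutoff score; default [determineCutoff()] of
#'   \code{scores}.
#' @return factor with levels \code{c("low", "high")}; \code{"high"} for
#'   scores \eqn{\ge} cutoff.
#' @export
makeClassLabels <- function(scores, cutoff = determineCutoff(scores)) {
    factor(ifelse(scores >= cutoff, "high", "low"),
           levels = c("low", "high"))
}

# Training-fold Spearman |rho| of each column against the scores;
# constant columns count as 0.
.absSpearman <- function(x, scores) {
    rs <- midRanks(scores)
    apply(x, 2, function(v) {
        rv <- midRanks(v)
        if (sd(rv) == 0) return(0)
        abs(cor(rv, rs))
    })
}

#' Top-k acoustic features by training-set correlation
#'
#' Ranks the acoustic feature columns (names starting \code{"ac."}) by the
#' absolute Spearman correlation with the scores, computed on the rows
#' given (a training fold), and returns the top \code{k} names; ties break
#' alphabetically. Together with the 16 prosodic and 16 linguistic
#' features this forms the fixed 48-candidate input set.
#'
#' @param x numeric matrix, participants x features, named columns.
#' @param scores UCLA scores for the same rows.
#' @param k number of acoustic features to keep (default 16).
#' @return character vector of \code{k} feature names ordered by
#'   decreasing \eqn{|\rho|} (all acoustic names, ordered, when \code{k}
#'   is not smaller than their count).
#' @export
selectAcousticSubset <- function(x, scores, k = 16) {
    x <- as.matrix(x)
    ac <- grep("^ac\\.", colnames(x), value = TRUE)
    if (!length(ac)) stop("no acoustic features present")
    rho <- .absSpearman(x[, ac, drop = FALSE], scores)
    ord <- order(-rho, ac)
    ac[ord][seq_len(min(k, length(ac)))]
}

# Fold assignment: shuffled blocks for regression, per-class round-robin
# for classification so every fold mirrors the class balance.
.foldAssignment <- function(y, k, task) {
    n <- length(y)
    stopifnot(n >= k)
    folds <- integer(n)
    if (task == "classification") {
        for (cl in levels(y)) {
            idx <- sample(which(y == cl))
            folds[idx] <- rep_len(seq_len(k), length(idx))
        }
        for (f in seq_len(k))
            if (length(unique(y[folds != f])) < 2L)
                stop("a training split lacks one of the classes")
    } else {
        folds <- sample(rep_len(seq_len(k), n))
    }
    folds
}

.defaultHyper <- function(family, task) {
    switch(family,
           knn = list(k = 5),
           random_forest = list(ntree = 300, maxnodes = NA),
           svm = if (task == "regression")
               list(kernel = "linear", cost = 1, gamma_mult = 1,
                    epsilon = 1)
           else list(kernel = "linear", cost = 10, gamma_mult = 1,
                     balanced = TRUE))
}

#' Default hyperparameter grid
#'
#' The grid searched (on training data only) when [runCV()] is called with
#' \code{tune = TRUE}: neighbour counts for kNN; tree count and depth for
#' the random forest; RBF cost, kernel-width multiplier and either the
#' epsilon loss margin (regression) or balanced class weights on/off
#' (classification) for the SVM.
#'
#' @param family \code{"knn"}, \code{"random_forest"} or \code{"svm"}.
#' @param task \code{"regression"} or \code{"classification"}.
#' @return data.frame, one row per hyperparameter combination.
#' @export
defaultModelGrid <- function(family, task) {
    switch(family,
           knn = data.frame(k = c(3, 5, 7)),
           random_forest = expand.grid(ntree = c(100, 300),
                                       maxnodes = c(8, 32, NA)),
           svm = if (task == "regression")
               expand.grid(kernel = c("linear", "radial"),
                           cost = c(0.1, 1, 10),
                           gamma_mult = c(0.5, 1, 2),
                           epsilon = c(0.5, 1, 2),
                           stringsAsFactors = FALSE)
           else expand.grid(kernel = c("linear", "radial"),
                            cost = c(0.1, 1, 10),
                            gamma_mult = c(0.5, 1, 2),
                            balanced = c(TRUE, FALSE),
                            stringsAsFactors = FALSE))
}

# Fit on (X_tr, y_tr), predict X_te. Features are assumed already imputed
# and (for knn/svm) standardized by the caller. RF consumes raw features:
# its axis-aligned splits are invariant to per-feature monotone scaling.
.fitPredict <- function(X_tr, y_tr, X_te, task, family, hyper) {
    if (family == "knn") {
        k <- max(1L, min(as.integer(hyper$k), nrow(X_tr)))
        if (task == "regression")
            predict(caret::knnreg(X_tr, y_tr, k = k), X_te)
        else
            class::knn(X_tr, X_te, y_tr, k = k, use.all = TRUE)
    } else if (family == "random_forest") {
        args <- list(x = X_tr, y = y_tr, ntree = as.integer(hyper$ntree))
        if (!is.null(hyper$maxnodes) && !is.na(hyper$maxnodes))
            args$maxnodes <- as.integer(hyper$maxnodes)
        predict(do.call(randomForest::randomForest, args), X_te)
    } else if (family == "svm") {
        kern <- if (is.null(hyper$kernel)) "radial" else hyper$kernel
        gamma <- hyper$gamma_mult / ncol(X_tr)
        if (task == "regression") {
            m <- e1071::svm(X_tr, y_tr, type = "eps-regression",
                            kernel = kern, cost = hyper$cost,
                            gamma = gamma, epsilon = hyper$epsilon,
                            scale = FALSE)
        } else {
            cw <- NULL
            if (isTRUE(hyper$balanced)) {
                tb <- table(y_tr)
                cw <- setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
            }
            m <- e1071::svm(X_tr, y_tr, type = "C-classification",
                            kernel = kern, cost = hyper$cost,
                            gamma = gamma, class.weights = cw,
                            scale = FALSE)
        }
        predict(m, X_te)
    } else stop("unknown model family: ", family)
}

# Pooled inner-CV objective (R^2 for regression, accuracy for
# classification) of a feature subset, under a fixed fold assignment.
.innerObjective <- function(X, y, cols, task, family, hyper, folds) {
    preds <- if (task == "classification")
        factor(rep(levels(y)[1L], length(y)), levels = levels(y))
    else numeric(length(y))
    for (f in sort(unique(folds))) {
        tr <- folds != f
        p <- .fitPredict(X[tr, cols, drop = FALSE], y[tr],
                         X[!tr, cols, drop = FALSE], task, family, hyper)
        preds[!tr] <- p
    }
    if (task == "regression") {
        sst <- sum((y - mean(y))^2)
        if (sst == 0) return(NA_real_)
        1 - sum((y - preds)^2) / sst
    } else mean(preds == y)
}

#' Sequential forward feature selection
#'
#' Greedy subset search: starting from the empty set, repeatedly add the
#' candidate that maximizes the inner cross-validated objective (pooled
#' R\eqn{^2} for regression, accuracy for classification); stop when no
#' candidate strictly improves the objective or \code{max_features} is
#' reached. Objective ties break alphabetically by candidate name, and the
#' inner fold assignment is fixed once per call, so the result is
#' deterministic given the RNG state.
#'
#' @param x numeric matrix, rows = training participants, named columns.
#' @param y target vector (numeric scores or class factor).
#' @param candidates candidate feature names (columns of \code{x}).
#' @param task \code{"regression"} or \code{"classification"}.
#' @param family model family evaluated inside the search (default svm).
#' @param hyper hyperparameter list; defaults per family.
#' @param inner_folds inner CV fold count (default 5).
#' @param max_features maximum subset size (default 12).
#' @param min_features minimum subset size (default 1): up to this size the
#'   best candidate is added even when it does not improve the objective,
#'   as in fixed-size forward selectors; beyond it, strict improvement is
#'   required.
#' @return character vector of selected feature names, in selection order.
#' @export
sequentialForwardSelection <- function(x, y, candidates,
                                       task = c("regression",
                                                "classification"),
                                       family = "svm", hyper = NULL,
                                       inner_folds = 5, max_features = 12,
                                       min_features = 1) {
    task <- match.arg(task)
    x <- as.matrix(x)
    stopifnot(length(candidates) >= 1L,
              all(candidates %in% colnames(x)))
    if (is.null(hyper)) hyper <- .defaultHyper(family, task)
    if (task == "classification") {
        y <- as.factor(y)
        if (min(table(y)) < 2L) stop("degenerate data: a class has < 2 members")
        inner_folds <- min(inner_folds, min(table(y)))
    }
    if (task == "regression" && sd(y) == 0)
        stop("degenerate data: constant target")
    folds <- .foldAssignment(y, min(inner_folds, length(y)), task)
    candidates <- sort(candidates)
    selected <- character(0)
    best <- -Inf
    while (length(selected) < max_features && length(candidates)) {
        objs <- vapply(candidates, function(cn) {
            .innerObjective(x, y, c(selected, cn), task, family, hyper,
                            folds)
        }, numeric(1))
        objs[is.na(objs)] <- -Inf
        top <- which(objs >= max(objs) - 1e-10)[1L]
        if (length(selected) >= min_features && objs[top] <= best + 1e-10)
            break
        best <- max(best, objs[top])
        selected <- c(selected, candidates[top])
        candidates <- candidates[-top]
    }
    selected
}

#' Regression metrics
#'
#' \eqn{MAE = \frac{1}{n}\sum|y_i - \hat y_i|},
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum(y_i - \hat y_i)^2}},
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}, and explained
#' variance \eqn{EV = 1 - Var(y - \hat y)/Var(y)} (which equals
#' \eqn{R^2} when the residuals have zero mean).
#'
#' @param y actual scores.
#' @param yhat estimated scores, same length.
#' @return named numeric vector \code{c(r2, ev, mae, rmse)}.
#' @export
regressionMetrics <- function(y, yhat) {
    stopifnot(length(y) == length(yhat), length(y) >= 1L)
    if (var(y) == 0) stop("constant actual scores: R^2 and EV undefined")
    res <- y - yhat
    c(r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
      ev = 1 - var(res) / var(y),
      mae = mean(abs(res)),
      rmse = sqrt(mean(res^2)))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity and F1 from (possibly fractional,
#' e.g. iteration-averaged) confusion counts.
#'
#' @param tp,fn,fp,tn confusion counts; alternatively pass a single named
#'   vector \code{c(tp=, fn=, fp=, tn=)} as \code{tp}.
#' @return named numeric vector
#'   \code{c(accuracy, sensitivity, specificity, f1)}, as fractions in
#'   \eqn{[0, 1]}.
#' @examples
#' round(100 * classificationMetrics(9, 1, 1.504, 45.496), 1)
#' @export
classificationMetrics <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
    if (is.null(fn) && length(tp) == 4L) {
        v <- tp
        tp <- v[["tp"]]; fn <- v[["fn"]]; fp <- v[["fp"]]; tn <- v[["tn"]]
    }
    stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
    if (tp + fn == 0) stop("sensitivity undefined: empty positive class")
    if (tn + fp == 0) stop("specificity undefined: empty negative class")
    c(accuracy = (tp + tn) / (tp + fn + fp + tn),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      f1 = 2 * tp / (2 * tp + fp + fn))
}

.confusionCounts <- function(truth, pred) {
    c(tp = sum(pred == "high" & truth == "high"),
      fn = sum(pred == "low" & truth == "high"),
      fp = sum(pred == "high" & truth == "low"),
      tn = sum(pred == "low" & truth == "low"))
}

#' Iterated k-fold cross-validation of a speech-feature model
#'
#' The full evaluation protocol: per iteration the cohort is reshuffled
#' into \code{k_folds} folds (stratified by class for classification); per
#' fold, missing values are imputed with training medians, features are
#' z-scored on training moments (kNN/SVM), the acoustic candidates are
#' reduced to the top-\code{n_acoustic} by training-set \eqn{|\rho|},
#' sequential forward selection picks the model inputs, an optional grid
#' search tunes hyperparameters on the training rows, and the fitted model
#' predicts the held-out rows. Metrics are computed per iteration over the
#' pooled test predictions; the report carries the mean and a 95\%
#' t-interval (\eqn{mean \pm t_{0.975, I-1} SD/\sqrt{I}}) over the
#' \eqn{I} iteration values.
#'
#' @param x a [SpeechFeatureSet-class] or numeric matrix
#'   (participants x named features).
#' @param targets numeric UCLA scores (regression) or class labels
#'   coercible to a two-level factor with \code{"high"} as the positive
#'   class (classification). Defaults to the UCLA scores / cutoff labels of
#'   a \code{SpeechFeatureSet}.
#' @param task \code{"regression"} or \code{"classification"}.
#' @param family \code{"svm"} (default), \code{"knn"} or
#'   \code{"random_forest"}.
#' @param hyper hyperparameter list; family defaults when NULL.
#' @param tune if TRUE, grid-search \code{grid} per fold on training data.
#' @param grid hyperparameter data.frame; [defaultModelGrid()] when NULL.
#' @param n_iter iterations (default 20).
#' @param k_folds folds per iteration (default 10).
#' @param seed root seed; every source of randomness derives from it.
#' @param n_acoustic acoustic pre-selection size (default 16).
#' @param preselect_scores optional numeric scores used for the acoustic
#'   pre-selection ranking (the UCLA scores); defaults to the regression
#'   targets, or to the 0/1 class indicator for classification when no
#'   scores are supplied. For a \code{SpeechFeatureSet} the UCLA scores
#'   are always used.
#' @param sfs_inner_folds,sfs_max_features,sfs_min_features forwarded to
#'   [sequentialForwardSelection()].
#' @return An [EvalReport-class].
#' @export
runCV <- function(x, targets = NULL,
                  task = c("regression", "classification"),
                  family = c("svm", "knn", "random_forest"),
                  hyper = NULL, tune = FALSE, grid = NULL,
                  n_iter = 20, k_folds = 10, seed = 1,
                  n_acoustic = 16, sfs_inner_folds = 5,
                  sfs_max_features = 12, sfs_min_features = 1,
                  preselect_scores = NULL) {
    task <- match.arg(task)
    family <- match.arg(family)
    if (is(x, "SpeechFeatureSet")) {
        if (is.null(targets))
            targets <- if (task == "regression") uclaScores(x)
                       else makeClassLabels(uclaScores(x))
        if (is.null(preselect_scores)) preselect_scores <- uclaScores(x)
        x <- featureMatrix(x)
    }
    x <- as.matrix(x)
    stopifnot(!is.null(colnames(x)), nrow(x) >= k_folds)
    if (task == "classification") {
        targets <- as.factor(targets)
        if (!all(levels(targets) %in% c("low", "high")))
            targets <- factor(ifelse(targets == levels(targets)[2L] |
                                     targets %in% c("high", "TRUE", "1"),
                                     "high", "low"),
                              levels = c("low", "high"))
        targets <- factor(targets, levels = c("low", "high"))
        y_num <- as.numeric(targets == "high")
    } else {
        targets <- as.numeric(targets)
        y_num <- targets
    }
    stopifnot(length(targets) == nrow(x))
    if (is.null(hyper)) hyper <- .defaultHyper(family, task)
    if (tune && is.null(grid)) grid <- defaultModelGrid(family, task)
    standardize <- family %in% c("knn", "svm")
    has_ac <- any(grepl("^ac\\.", colnames(x)))

    metric_names <- if (task == "regression")
        c("r2", "ev", "mae", "rmse")
    else c("accuracy", "sensitivity", "specificity", "f1")
    perIter <- matrix(NA_real_, n_iter, length(metric_names),
                      dimnames = list(NULL, metric_names))
    confIter <- matrix(NA_real_, n_iter, 4,
                       dimnames = list(NULL, c("tp", "fn", "fp", "tn")))
    predMat <- matrix(NA_real_, n_iter, nrow(x))
    selected <- vector("list", n_iter)

    for (it in seq_len(n_iter)) {
        set.seed(deriveSeed(seed, "cv", it))
        folds <- .foldAssignment(targets, k_folds, task)
        preds <- if (task == "classification")
            factor(rep("low", nrow(x)), levels = c("low", "high"))
        else numeric(nrow(x))
        sel_it <- list()
        for (f in seq_len(k_folds)) {
            tr <- folds != f
            med <- apply(x[tr, , drop = FALSE], 2, median, na.rm = TRUE)
            Xtr <- medianImpute(x[tr, , drop = FALSE], med)
            Xte <- medianImpute(x[!tr, , drop = FALSE], med)
            if (standardize) {
                mu <- colMeans(Xtr)
                sg <- apply(Xtr, 2, sd)
                sg[sg == 0 | !is.finite(sg)] <- 1
                Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
                Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
            }
            cands <- colnames(x)
            if (has_ac) {
                ps <- if (!is.null(preselect_scores)) preselect_scores
                      else y_num
                keep_ac <- selectAcousticSubset(Xtr, ps[tr],
                                                k = n_acoustic)
                cands <- c(keep_ac, grep("^ac\\.", colnames(x),
                                         value = TRUE, invert = TRUE))
            }
            sel <- sequentialForwardSelection(
                Xtr, targets[tr], cands, task = task, family = family,
                hyper = hyper, inner_folds = sfs_inner_folds,
                max_features = sfs_max_features,
                min_features = sfs_min_features)
            if (!length(sel)) sel <- cands[1L]
            hy <- hyper
            if (tune && nrow(grid) > 1L) {
                ifolds <- .foldAssignment(targets[tr],
                                          min(sfs_inner_folds,
                                              sum(tr)), task)
                objs <- vapply(seq_len(nrow(grid)), function(g) {
                    .innerObjective(Xtr, targets[tr], sel, task, family,
                                    as.list(grid[g, , drop = FALSE]),
                                    ifolds)
                }, numeric(1))
                hy <- as.list(grid[which.max(objs), , drop = FALSE])
            }
            p <- .fitPredict(Xtr[, sel, drop = FALSE], targets[tr],
                             Xte[, sel, drop = FALSE], task, family, hy)
            preds[!tr] <- p
            attr(sel, "n_candidates") <- length(cands)
            sel_it[[f]] <- sel
        }
        if (task == "regression") {
            perIter[it, ] <- regressionMetrics(targets, preds)
            predMat[it, ] <- preds
        } else {
            cc <- .confusionCounts(targets, preds)
            confIter[it, ] <- cc
            perIter[it, ] <- classificationMetrics(cc)
            predMat[it, ] <- as.numeric(preds == "high")
        }
        selected[[it]] <- sel_it
    }
    ci <- .iterationCI(perIter)
    new("EvalReport", task = task, family = family, metrics = ci,
        perIteration = perIter,
        confusion = if (task == "classification") colMeans(confIter)
                    else numeric(0),
        selected = selected, predictions = predMat, truth = y_num,
        nIter = as.integer(n_iter), nFolds = as.integer(k_folds),
        seed = as.integer(seed))
}

# Mean and 95% t-interval over iteration values.
.iterationCI <- function(perIter) {
    I <- nrow(perIter)
    m <- colMeans(perIter)
    se <- apply(perIter, 2, sd) / sqrt(I)
    half <- if (I > 1L) qt(0.975, I - 1L) * se else rep(0, length(m))
    data.frame(metric = colnames(perIter), mean = m, lower = m - half,
               upper = m + half, row.names = NULL)
}

#' Per-group (e.g. per-sex) evaluation of a cross-validation report
#'
#' Recomputes the pooled-test-prediction metrics of an [EvalReport-class]
#' restricted to each group, with 95\% t-intervals over iterations.
#'
#' @param report an [EvalReport-class] from [runCV()].
#' @param groups group label per participant (factor or character).
#' @return named list of metric data.frames, one per group; groups with
#'   fewer than 2 members (or, for classification, a missing class) are
#'   skipped with a warning.
#' @export
evaluateByGroup <- function(report, groups) {
    stopifnot(is(report, "EvalReport"),
              length(groups) == ncol(report@predictions))
    groups <- as.factor(groups)
    out <- list()
    for (g in levels(groups)) {
        idx <- which(groups == g)
        if (length(idx) < 2L) {
            warning("group '", g, "' has < 2 members; skipped")
            next
        }
        y <- report@truth[idx]
        vals <- try(t(apply(report@predictions[, idx, drop = FALSE], 1,
                            function(p) {
            if (report@task == "regression") regressionMetrics(y, p)
            else classificationMetrics(.confusionCounts(
                factor(ifelse(y == 1, "high", "low"),
                       levels = c("low", "high")),
                factor(ifelse(p == 1, "high", "low"),
                       levels = c("low", "high"))))
        })), silent = TRUE)
        if (inherits(vals, "try-error")) {
            warning("group '", g, "' metrics undefined; skipped")
            next
        }
        out[[g]] <- .iterationCI(vals)
    }
    out
}
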