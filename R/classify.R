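# Leave-one-out cross-validated classification of subjects from per-region
# delta-SUV features.
#
# Three model kinds mirror the common toolbox choices at this sample size:
#   linear-logistic    maximum-likelihood logistic regression
#   max-margin         linear soft-margin SVM (primal subgradient descent;
#                      no SVM package is available in the target environment)
#   gradient-boosting  GentleBoost (Friedman et al. 2000) with regression
#                      stumps, implemented from the weight updates directly
# Hyperparameters (SVM cost, boosting rounds) are selected inside each
# training fold by stratified internal cross-validation, so the held-out
# subject never influences its own model.

MODEL_KINDS <- c("linear-logistic", "max-margin", "gradient-boosting")

validate_feature_table <- function(features) {
  assert_that(is.data.frame(features) &&
                all(c("subject_id", "group") %in% names(features)),
              "feature table needs subject_id and group columns")
  fcols <- setdiff(names(features), c("subject_id", "group"))
  assert_that(length(fcols) >= 1, "no feature columns")
  assert_that(!anyNA(features[fcols]), "missing feature values")
  assert_that(all(vapply(features[fcols], is.numeric, logical(1))),
              "feature columns must be numeric")
  cls <- table(features$group)
  assert_that(length(cls) == 2, "need exactly two classes")
  assert_that(all(cls >= 2), "need >= 2 subjects per class")
  fcols
}

# negative/positive convention: CON is the negative class when present,
# otherwise the alphabetically first label
class_roles <- function(groups) {
  labs <- sort(unique(groups))
  if ("CON" %in% labs) {
    neg <- "CON"; pos <- setdiff(labs, "CON")
  } else {
    neg <- labs[1]; pos <- labs[2]
  }
  c(negative = neg, positive = pos)
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(apply = function(Z) sweep(sweep(Z, 2, mu), 2, sd, `/`))
}

## --- linear logistic -------------------------------------------------------

fit_llr <- function(X, y01) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y01, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(predict_score = function(Z) {
    eta <- drop(cbind(1, Z) %*% beta)
    1 / (1 + exp(-eta))
  })
}

## --- linear soft-margin SVM ------------------------------------------------

# deterministic full-batch subgradient descent (batch Pegasos) on
#   lambda/2 ||w||^2 + (1/n) sum hinge(y w.x),  lambda = 1/(C n).
# The bias rides along as a regularized constant column; with standardized
# features the shrinkage on it is immaterial at these C values.
fit_svm_linear <- function(X, ypm, C = 1, n_iter = 500) {
  Xa <- cbind(X, 1)
  n <- nrow(Xa)
  lambda <- 1 / (C * n)
  w <- numeric(ncol(Xa))
  for (t in seq_len(n_iter)) {
    viol <- ypm * drop(Xa %*% w) < 1
    g <- lambda * w - colSums(Xa[viol, , drop = FALSE] * ypm[viol]) / n
    w <- w - g / (lambda * (t + 1))
  }
  list(predict_score = function(Z) drop(cbind(Z, 1) %*% w), w = w)
}

## --- GentleBoost with regression stumps ------------------------------------

# weighted least-squares stump: piecewise constants on x <= theta / x > theta
best_stump <- function(X, y, w) {
  n <- nrow(X)
  best <- list(sse = Inf)
  tw <- sum(w); twy <- sum(w * y); twy2 <- sum(w * y^2)
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xs <- X[o, j]; ys <- y[o]; ws <- w[o]
    cw <- cumsum(ws); cwy <- cumsum(ws * ys)
    # candidate splits between distinct consecutive values
    distinct <- which(diff(xs) > 0)
    if (length(distinct) == 0) next
    wl <- cw[distinct]; wyl <- cwy[distinct]
    wr <- tw - wl; wyr <- twy - wyl
    sse <- twy2 - wyl^2 / wl - wyr^2 / wr
    i <- which.min(sse)
    if (sse[i] < best$sse) {
      best <- list(sse = sse[i], feature = j,
                   threshold = (xs[distinct[i]] + xs[distinct[i] + 1]) / 2,
                   c_left = wyl[i] / wl[i], c_right = wyr[i] / wr[i])
    }
  }
  if (!is.finite(best$sse)) {
    # all features constant: stump degenerates to the weighted mean
    best <- list(sse = twy2 - twy^2 / tw, feature = 1L, threshold = Inf,
                 c_left = twy / tw, c_right = 0)
  }
  best
}

stump_predict <- function(stump, X) {
  ifelse(X[, stump$feature] <= stump$threshold, stump$c_left, stump$c_right)
}

fit_gentleboost <- function(X, ypm, n_rounds = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  Fx <- numeric(n)
  stumps <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    st <- best_stump(X, ypm, w)
    f <- stump_predict(st, X)
    Fx <- Fx + f
    w <- w * exp(-ypm * f)
    s <- sum(w)
    if (!is.finite(s) || s <= 0) {
      stumps <- stumps[seq_len(m)]
      break
    }
    w <- w / s
    stumps[[m]] <- st
  }
  stumps <- Filter(Negate(is.null), stumps)
  list(stumps = stumps,
       predict_score = function(Z) {
         Fz <- numeric(nrow(Z))
         for (st in stumps) Fz <- Fz + stump_predict(st, Z)
         1 / (1 + exp(-2 * Fz))
       },
       staged_margin = function(Z) {
         # matrix: rows = observations, cols = cumulative rounds
         out <- matrix(0, nrow(Z), length(stumps))
         Fz <- numeric(nrow(Z))
         for (m in seq_along(stumps)) {
           Fz <- Fz + stump_predict(stumps[[m]], Z)
           out[, m] <- Fz
         }
         out
       })
}

## --- inner hyperparameter selection ----------------------------------------

stratified_folds <- function(y01, k) {
  folds <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- which(y01 == cls)
    folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  folds
}

select_and_fit <- function(X, y01, model_kind, fold_seed) {
  ypm <- ifelse(y01 == 1, 1, -1)
  if (model_kind == "linear-logistic") {
    return(fit_llr(X, y01))
  }
  k <- min(5L, min(table(y01)))
  set.seed(fold_seed)
  folds <- stratified_folds(y01, k)
  if (model_kind == "max-margin") {
    grid <- c(0.1, 1, 10)
    acc <- vapply(grid, function(C) {
      hits <- 0L
      for (f in seq_len(k)) {
        tr <- folds != f
        if (length(unique(y01[tr])) < 2) next
        m <- fit_svm_linear(X[tr, , drop = FALSE], ypm[tr], C = C)
        pred <- m$predict_score(X[!tr, , drop = FALSE]) > 0
        hits <- hits + sum(pred == (y01[!tr] == 1))
      }
      hits
    }, numeric(1))
    C_best <- grid[which.max(acc)]
    return(fit_svm_linear(X, ypm, C = C_best))
  }
  # gradient-boosting: staged evaluation picks the round count
  grid <- c(10L, 30L, 50L)
  hits <- numeric(length(grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y01[tr])) < 2) next
    m <- fit_gentleboost(X[tr, , drop = FALSE], ypm[tr], n_rounds = max(grid))
    stg <- m$staged_margin(X[!tr, , drop = FALSE])
    for (gi in seq_along(grid)) {
      col <- min(grid[gi], ncol(stg))
      pred <- stg[, col] > 0
      hits[gi] <- hits[gi] + sum(pred == (y01[!tr] == 1))
    }
  }
  fit_gentleboost(X, ypm, n_rounds = grid[which.max(hits)])
}

## --- LOOCV driver -----------------------------------------------------------

#' Leave-one-out cross-validated classification
#'
#' One fold per subject: the model is fitted on the other N - 1 subjects
#' (feature standardization and hyperparameter selection happen inside the
#' training fold) and predicts the held-out subject. Scores are pooled
#' across folds: class-1 probability for the logistic and boosting models,
#' signed margin for the max-margin model.
#'
#' @param features feature table (`subject_id`, `group`, numeric feature
#'   columns), e.g. from [feature_table()].
#' @param model_kind one of `"linear-logistic"`, `"max-margin"`,
#'   `"gradient-boosting"`.
#' @param seed RNG seed (drives the internal CV fold assignment only).
#' @return data.frame of class `loocv_outcome`: `subject_id`, `truth`
#'   (negative/positive role), `score` (larger = more positive), `pred`;
#'   attributes `model_kind`, `seed`, `roles`.
#' @export
loocv_classify <- function(features, model_kind = MODEL_KINDS, seed = 1L) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  fcols <- validate_feature_table(features)
  roles <- class_roles(features$group)
  X <- as.matrix(features[fcols])
  y01 <- as.integer(features$group == roles[["positive"]])
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr_X <- X[-i, , drop = FALSE]
    tr_y <- y01[-i]
    assert_that(length(unique(tr_y)) == 2,
                sprintf("training fold %d is missing a class", i),
                "betapet_fold_error")
    std <- standardizer(tr_X)
    model <- select_and_fit(std$apply(tr_X), tr_y, model_kind,
                            fold_seed = derive_seed(seed, i))
    scores[i] <- model$predict_score(std$apply(X[i, , drop = FALSE]))
  }
  cut <- if (model_kind == "max-margin") 0 else 0.5
  out <- data.frame(subject_id = features$subject_id,
                    truth = ifelse(y01 == 1, "positive", "negative"),
                    score = scores,
                    pred = ifelse(scores > cut, "positive", "negative"),
                    stringsAsFactors = FALSE)
  attr(out, "model_kind") <- model_kind
  attr(out, "seed") <- seed
  attr(out, "roles") <- roles
  class(out) <- c("loocv_outcome", "data.frame")
  out
}

#' Confusion rates from a LOOCV outcome
#'
#' Percentages of each true class: `tn_rate + fp_rate = 100` over true
#' negatives and `fn_rate + tp_rate = 100` over true positives.
#'
#' @param outcome a `loocv_outcome`.
#' @return list with `tn_rate`, `fp_rate`, `fn_rate`, `tp_rate`
#'   (percentages) and the integer `counts` behind them.
#' @export
confusion_rates <- function(outcome) {
  tn <- sum(outcome$truth == "negative" & outcome$pred == "negative")
  fp <- sum(outcome$truth == "negative" & outcome$pred == "positive")
  fn <- sum(outcome$truth == "positive" & outcome$pred == "negative")
  tp <- sum(outcome$truth == "positive" & outcome$pred == "positive")
  nneg <- tn + fp; npos <- fn + tp
  assert_that(nneg > 0 && npos > 0, "both true classes must be present")
  list(tn_rate = 100 * tn / nneg, fp_rate = 100 * fp / nneg,
       fn_rate = 100 * fn / npos, tp_rate = 100 * tp / npos,
       counts = c(tn = tn, fp = fp, fn = fn, tp = tp))
}

#' ROC curve from pooled LOOCV scores
#'
#' Threshold swept over the pooled scores (predict positive when
#' `score >= threshold`); AUC by the trapezoid rule, which equals the
#' pairwise concordance probability with ties counted 1/2.
#'
#' @param outcome a `loocv_outcome` (or any data.frame with `truth` and
#'   `score`).
#' @param variant label stored on the curve (`"real"` or `"scrambled"`).
#' @return list of class `roc_curve` with `points` (data.frame `fpr`, `tpr`,
#'   `threshold`), `auc`, `variant`.
#' @export
roc_from_scores <- function(outcome, variant = "real") {
  pos <- outcome$truth == "positive"
  assert_that(any(pos) && any(!pos), "need both classes for a ROC curve")
  o <- order(outcome$score, decreasing = TRUE)
  s <- outcome$score[o]; y <- pos[o]
  # step only at distinct score values (ties move diagonally)
  keep <- c(diff(s) != 0, TRUE)
  tpr <- cumsum(y)[keep] / sum(pos)
  fpr <- cumsum(!y)[keep] / sum(!pos)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, s[keep]))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, variant = variant),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve %s  AUC = %.3f  (%d points)>\n",
              x$variant, x$auc, nrow(x$points)))
  invisible(x)
}

#' Scrambled-label control
#'
#' Per repetition, class labels are permuted once across subjects, the full
#' LOOCV is rerun against the scrambled labels, and the resulting AUC is
#' recorded. With informative features the scrambled AUCs concentrate
#' around 0.5 while the real-label AUC does not.
#'
#' @param features feature table as for [loocv_classify()].
#' @param model_kind model kind.
#' @param n_reps number of label permutations (0 gives an empty vector).
#' @param seed RNG seed; fixed seed gives an identical AUC sequence.
#' @return numeric vector of AUCs, one per repetition.
#' @export
scrambled_label_control <- function(features, model_kind = MODEL_KINDS,
                                    n_reps = 50, seed = 1L) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  validate_feature_table(features)
  if (n_reps == 0) return(numeric(0))
  aucs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    scr <- features
    repeat {
      scr$group <- sample(features$group)
      if (all(table(scr$group) >= 2)) break
    }
    out <- loocv_classify(scr, model_kind, seed = derive_seed(seed, r))
    aucs[r] <- roc_from_scores(out, variant = "scrambled")$auc
  }
  aucs
}
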