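#' Classifier configuration
#'
#' Parameters of one member of the classifier bank.  Defaults follow the
#' published training settings: a single hidden layer of 10 units for the
#' MLP; an adaptively boosted tree ensemble with 100 learning cycles and
#' at most 10 split nodes per tree; a linear-kernel SVM with kernel scale
#' 1 and posterior-probability output; Gaussian class-conditional
#' densities for naive Bayes; one-versus-one (OVO) multiclass coding
#' throughout.
#'
#' @param method One of `"mlp"`, `"rf"`, `"svm"`, `"nb"`.
#' @param mlp_hidden Hidden-layer size (default 10).
#' @param rf_cycles Boosting cycles / number of trees (default 100).
#' @param rf_max_nodes Maximum split nodes per tree (default 10).
#' @param rf_aggregation `"boost"` (adaptive boosting, the default) or
#'   `"bag"` (a bagging random forest).
#' @param svm_kernel `"linear"` (default) or `"rbf"`.
#' @param svm_scale Kernel scale for the RBF kernel,
#'   `K = exp(-||x - y||^2 / scale^2)`, applied on standardized features.
#' @param coding `"ovo"` (default) or `"ova"`.
#' @param class_weight `NULL` (no reweighting, the default) or
#'   `"balanced"`.
#' @param seed Integer seed controlling every stochastic element of the
#'   fit.
#' @return List of class `"model_config"`.
#' @export
model_config <- function(method = c("mlp", "rf", "svm", "nb"),
                         mlp_hidden = 10, rf_cycles = 100, rf_max_nodes = 10,
                         rf_aggregation = c("boost", "bag"),
                         svm_kernel = c("linear", "rbf"), svm_scale = 1,
                         coding = c("ovo", "ova"), class_weight = NULL,
                         seed = 1) {
  method <- match.arg(method)
  svm_kernel <- match.arg(svm_kernel)
  coding <- match.arg(coding)
  rf_aggregation <- match.arg(rf_aggregation)
  stopifnot(mlp_hidden >= 1, rf_cycles >= 1, rf_max_nodes >= 1,
            svm_scale > 0)
  structure(list(method = method, mlp_hidden = mlp_hidden,
                 rf_cycles = rf_cycles, rf_max_nodes = rf_max_nodes,
                 rf_aggregation = rf_aggregation, svm_kernel = svm_kernel,
                 svm_scale = svm_scale, coding = coding,
                 class_weight = class_weight, seed = as.integer(seed)),
            class = "model_config")
}

feature_matrix <- function(features) {
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Train a pattern model on centroid features
#'
#' Fits one binary learner per unordered class pair (OVO coding; `C(k,2)`
#' learners for `k` classes) or per class against the rest (OVA).
#' Features are z-scored with parameters estimated from the training data
#' and stored in the model, so prediction is self-contained.  Each binary
#' learner outputs a posterior-like probability: the MLP minimises
#' cross-entropy; the boosted ensemble converts its margin through a
#' logistic link; the SVM is Platt-calibrated; naive Bayes is an exact
#' Gaussian posterior.  The fit is deterministic under a fixed
#' `config$seed`.
#'
#' @param features A [feature_table()] with labels (at least 2 classes,
#'   at least 5 records per class, no missing values).
#' @param config A [model_config()].
#' @return Object of class `"pattern_model"`.
#' @export
train_model <- function(features, config = model_config()) {
  x <- feature_matrix(features)
  y <- as.integer(features$label)
  if (any(!is.finite(x))) stop("NaN or missing features")
  check_labels(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  tab <- table(y)
  if (any(tab < 5L)) stop("need at least 5 records per class")

  centre <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, centre), 2, scale, "/")

  tasks <- if (config$coding == "ovo") {
    cmb <- utils::combn(classes, 2)
    lapply(seq_len(ncol(cmb)), function(j) list(a = cmb[1, j], b = cmb[2, j]))
  } else {
    lapply(classes, function(c) list(a = -1L, b = c))   # b versus rest
  }
  learners <- lapply(seq_along(tasks), function(j) {
    tk <- tasks[[j]]
    if (config$coding == "ovo") {
      idx <- y %in% c(tk$a, tk$b)
      pos <- y[idx] == tk$b
    } else {
      idx <- rep(TRUE, length(y))
      pos <- y == tk$b
    }
    set.seed(config$seed * 1000L + j)
    w <- NULL
    if (identical(config$class_weight, "balanced")) {
      w <- ifelse(pos, 0.5 / max(sum(pos), 1), 0.5 / max(sum(!pos), 1))
      w <- w * length(pos)
    }
    fit <- switch(config$method,
                  mlp = fit_mlp(xs[idx, , drop = FALSE], pos, config, w),
                  rf = fit_boost(xs[idx, , drop = FALSE], pos, config, w),
                  svm = fit_svm(xs[idx, , drop = FALSE], pos, config, w),
                  nb = fit_gnb(xs[idx, , drop = FALSE], pos, w))
    list(a = tk$a, b = tk$b, fit = fit)
  })
  structure(list(config = config, classes = classes,
                 scaling = list(centre = centre, scale = scale),
                 learners = learners,
                 meta = list(n_per_class = as.integer(tab),
                             class_ids = as.integer(names(tab)),
                             seed = config$seed,
                             format = "ecghht-model-1")),
            class = "pattern_model")
}

fit_mlp <- function(x, pos, config, w = NULL) {
  fit <- nnet::nnet(x, as.numeric(pos), size = config$mlp_hidden,
                    entropy = TRUE, maxit = 500, abstol = 1e-6,
                    reltol = 1e-8, trace = FALSE,
                    weights = if (is.null(w)) rep(1, length(pos)) else w)
  list(kind = "mlp", net = fit)
}

# Discrete AdaBoost.M1 over depth-limited CART stumps/trees; each tree is
# grown with cp = 0 then pruned back to at most `rf_max_nodes` splits.
fit_boost <- function(x, pos, config, w = NULL) {
  if (config$rf_aggregation == "bag") {
    fit <- randomForest::randomForest(
      x, factor(pos, levels = c(FALSE, TRUE)),
      ntree = config$rf_cycles, maxnodes = config$rf_max_nodes + 1L,
      classwt = if (is.null(w)) NULL else c(0.5, 0.5))
    return(list(kind = "bag", forest = fit))
  }
  n <- nrow(x)
  yy <- ifelse(pos, 1, -1)
  wt <- if (is.null(w)) rep(1 / n, n) else w / sum(w)
  dat <- data.frame(x, .y = factor(pos, levels = c(FALSE, TRUE)))
  trees <- list(); alphas <- numeric()
  for (m in seq_len(config$rf_cycles)) {
    tr <- rpart::rpart(.y ~ ., data = dat, weights = wt * n,
                       method = "class",
                       control = rpart::rpart.control(cp = 0, xval = 0,
                                                      minsplit = 2,
                                                      minbucket = 1,
                                                      maxdepth = 10))
    cpt <- tr$cptable
    ok <- cpt[cpt[, "nsplit"] <= config$rf_max_nodes, , drop = FALSE]
    if (nrow(ok) < nrow(cpt))
      tr <- rpart::prune(tr, cp = ok[nrow(ok), "CP"] + 1e-12)
    h <- ifelse(predict(tr, dat, type = "class") == "TRUE", 1, -1)
    err <- sum(wt[h != yy])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    trees[[m]] <- tr
    alphas[m] <- alpha
    if (err < 1e-8) break                      # perfect learner; stop early
    wt <- wt * exp(-alpha * yy * h)
    wt <- wt / sum(wt)
  }
  list(kind = "boost", trees = trees, alphas = alphas,
       alpha_sum = sum(abs(alphas)))
}

fit_svm <- function(x, pos, config, w = NULL) {
  fit <- e1071::svm(x, factor(pos, levels = c(FALSE, TRUE)),
                    kernel = if (config$svm_kernel == "rbf") "radial"
                             else "linear",
                    gamma = 1 / config$svm_scale^2,
                    probability = TRUE, scale = FALSE,
                    class.weights = if (is.null(w)) NULL
                                    else c("FALSE" = 0.5 / max(mean(!pos), 1e-9),
                                           "TRUE" = 0.5 / max(mean(pos), 1e-9)))
  list(kind = "svm", svm = fit)
}

# Gaussian naive Bayes fitted directly so that posteriors are exact
# class-conditional normal densities (no density flooring).
fit_gnb <- function(x, pos, w = NULL) {
  stat <- function(idx) {
    m <- colMeans(x[idx, , drop = FALSE])
    s <- apply(x[idx, , drop = FALSE], 2, stats::sd)
    s[!is.finite(s) | s < 1e-9] <- 1e-9
    list(mean = m, sd = s)
  }
  list(kind = "gnb",
       pos = stat(pos), neg = stat(!pos),
       prior_pos = mean(pos))
}

learner_prob <- function(fit, xs) {
  switch(fit$kind,
    mlp = as.numeric(predict(fit$net, xs)),
    boost = {
      dat <- as.data.frame(xs)
      F <- numeric(nrow(xs))
      for (m in seq_along(fit$trees)) {
        h <- ifelse(predict(fit$trees[[m]], dat, type = "class") == "TRUE",
                    1, -1)
        F <- F + fit$alphas[m] * h
      }
      1 / (1 + exp(-2 * F))
    },
    bag = predict(fit$forest, xs, type = "prob")[, "TRUE"],
    svm = {
      pr <- attr(predict(fit$svm, xs, probability = TRUE), "probabilities")
      pr[, "TRUE"]
    },
    gnb = {
      lp <- function(st) {
        acc <- numeric(nrow(xs))
        for (j in seq_len(ncol(xs)))
          acc <- acc + stats::dnorm(xs[, j], st$mean[j], st$sd[j], log = TRUE)
        acc
      }
      a <- lp(fit$pos) + log(max(fit$prior_pos, 1e-12))
      b <- lp(fit$neg) + log(max(1 - fit$prior_pos, 1e-12))
      1 / (1 + exp(b - a))
    },
    stop("unknown learner kind"))
}

#' Predict symptom labels and class scores
#'
#' Applies the stored feature scaling, evaluates every binary learner and
#' aggregates: under OVO, the pair `(a, b)` contributes its posterior for
#' `b` to class `b`'s score and the complement to class `a`; scores are
#' normalised to sum to 1.  The label is the argmax; exact ties resolve to
#' the lower symptom ID.
#'
#' @param object A trained [train_model()] result.
#' @param features Feature table or 6-column matrix.
#' @param ... Unused.
#' @return Data frame with `label` and one `score_<class>` column per
#'   model class.
#' @export
predict.pattern_model <- function(object, features, ...) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  if (ncol(x) != 6L) stop("feature dimension must be 6")
  xs <- sweep(sweep(x, 2, object$scaling$centre), 2, object$scaling$scale, "/")
  k <- length(object$classes)
  scores <- matrix(0, nrow(xs), k,
                   dimnames = list(NULL, paste0("score_", object$classes)))
  for (ln in object$learners) {
    p <- learner_prob(ln$fit, xs)
    jb <- match(ln$b, object$classes)
    scores[, jb] <- scores[, jb] + p
    if (ln$a > 0) {                     # OVO: complement goes to class a
      ja <- match(ln$a, object$classes)
      scores[, ja] <- scores[, ja] + (1 - p)
    }
  }
  scores <- scores / rowSums(scores)
  label <- object$classes[max.col(scores, ties.method = "first")]
  cbind(data.frame(label = label), as.data.frame(scores))
}

#' Save / load a trained pattern model
#'
#' The bundle records the configuration, scaling, fitted learners, seed
#' and a format version, so `load_model(save_model(m))` predicts
#' identically to `m`.
#'
#' @param model A [train_model()] result.
#' @param path File path.
#' @return `load_model` returns the `"pattern_model"`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pattern_model"))
  saveRDS(list(format = "ecghht-model-1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot load model file: ", path))
  if (!is.list(obj) || !identical(obj$format, "ecghht-model-1") ||
      !inherits(obj$model, "pattern_model"))
    stop("not an ecghht model bundle (or version mismatch): ", path)
  obj$model
}
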