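# Feed-forward classifier separating pathway-like (MIA) from conserved
# (non-MIA) expression profiles.
#
# The network is a small fully connected net — input = one column per atlas
# sample, two hidden ReLU layers (40 and 20 units), a 2-unit softmax output
# trained by backpropagation on the cross-entropy (logloss), with dropout
# 0.1 on the input and 0.5 on each hidden layer for regularization. It is
# implemented directly on base matrix operations so that training is a
# deterministic function of the seed.

#' Classifier configuration
#'
#' Defaults follow the reference protocol for this screen: hidden layers of
#' 40 and 20 units, input/hidden dropout 0.1/0.5, 1500 epochs, a stratified
#' 70/30 train/validation split with seed 666, 5-fold cross-validation and
#' logloss as the monitored metric.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param dropout_input,dropout_hidden dropout rates in `[0, 1)`.
#' @param epochs full passes over the training partition.
#' @param split fraction of labeled data used for training (rest validates).
#' @param cv_folds stratified cross-validation folds (0 disables CV).
#' @param seed RNG seed controlling the split, initialization, dropout and
#'   batch order.
#' @param learning_rate,batch_size Adam learning rate and minibatch size.
#' @param class_weights inverse-frequency class weighting of the loss, for
#'   the strong positive/negative imbalance of this screen.
#' @param patience epochs of consecutively rising validation logloss after
#'   which divergence is flagged (training still runs to `epochs`).
#' @param threshold posterior probability above which a transcript is
#'   called MIA-related.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(hidden_sizes = c(40, 20),
                              dropout_input = 0.1,
                              dropout_hidden = 0.5,
                              epochs = 1500,
                              split = 0.7,
                              cv_folds = 5,
                              seed = 666,
                              learning_rate = 1e-3,
                              batch_size = 32,
                              class_weights = TRUE,
                              patience = 50,
                              threshold = 0.5) {
  cfg <- as.list(environment())
  if (length(cfg$hidden_sizes) == 0) {
    stop_param("config error: hidden_sizes must be nonempty")
  }
  if (cfg$split <= 0 || cfg$split >= 1) {
    stop_param("config error: split must be in (0, 1)")
  }
  if (cfg$dropout_input < 0 || cfg$dropout_input >= 1 ||
      cfg$dropout_hidden < 0 || cfg$dropout_hidden >= 1) {
    stop_param("config error: dropout must be in [0, 1)")
  }
  if (cfg$epochs < 1) stop_param("config error: epochs must be >= 1")
  structure(cfg, class = "classifier_config")
}

#' Build the classifier feature matrix from an atlas
#'
#' Features are log2(TPM + 1) profiles, z-scored per transcript with the
#' population standard deviation so every profile contributes shape rather
#' than magnitude. Columns are samples, or per-tissue means when
#' `collapse_replicates = TRUE`. Zero-variance transcripts carry no shape
#' and are dropped with a warning.
#'
#' @param atlas a filtered [expression_atlas()].
#' @param collapse_replicates average replicates within each tissue.
#' @return numeric matrix, transcripts x feature columns.
#' @export
make_features <- function(atlas, collapse_replicates = FALSE) {
  stopifnot(inherits(atlas, "expression_atlas"))
  x <- log2(atlas$tpm + 1)
  if (collapse_replicates) {
    tissues <- unique(atlas$meta$tissue)
    rn <- rownames(x)
    x <- vapply(tissues, function(t)
      rowMeans(x[, atlas$meta$sample_id[atlas$meta$tissue == t],
                 drop = FALSE]),
      numeric(nrow(x)))
    x <- matrix(x, ncol = length(tissues),
                dimnames = list(rn, tissues))
  }
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  if (any(sd_pop == 0)) {
    warning("make_features: zero-variance transcript(s) dropped: ",
            sum(sd_pop == 0))
    x <- x[sd_pop > 0, , drop = FALSE]
    mu <- mu[sd_pop > 0]
    sd_pop <- sd_pop[sd_pop > 0]
  }
  (x - mu) / sd_pop
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of `scores` against binary labels.
#'
#' @param scores numeric vector.
#' @param y binary labels (1 = positive).
#' @return AUC in `[0, 1]`, or `NA` if one class is absent.
#' @export
auc_score <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- internal MLP -----------------------------------------------------

.mlp_init <- function(d, hidden, n_out = 2L) {
  sizes <- c(d, hidden, n_out)
  params <- list(sizes = sizes, W = list(), b = list())
  for (l in seq_len(length(sizes) - 1L)) {
    params$W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                         sqrt(2 / sizes[l])),
                            sizes[l], sizes[l + 1L])
    params$b[[l]] <- rep(0, sizes[l + 1L])
  }
  params
}

.mlp_probs <- function(params, x) {
  nl <- length(params$W)
  a <- x
  for (l in seq_len(nl)) {
    a <- sweep(a %*% params$W[[l]], 2, params$b[[l]], "+")
    if (l < nl) a <- pmax(a, 0)
  }
  zmax <- apply(a, 1, max)
  ez <- exp(a - zmax)
  ez / rowSums(ez)
}

.logloss <- function(p_pos, y, eps = 1e-12) {
  p <- pmin(pmax(p_pos, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# One Adam training run. x: n x d, y: 0/1. Deterministic given the RNG
# state at entry. Returns params and per-epoch logloss (train and optional
# validation set evaluated without dropout).
.mlp_train <- function(x, y, cfg, x_val = NULL, y_val = NULL) {
  n <- nrow(x)
  params <- .mlp_init(ncol(x), cfg$hidden_sizes)
  nl <- length(params$W)
  adam <- list(m = lapply(params$W, function(w) w * 0),
               v = lapply(params$W, function(w) w * 0),
               mb = lapply(params$b, function(b) b * 0),
               vb = lapply(params$b, function(b) b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  w_class <- if (cfg$class_weights) {
    c(n / (2 * max(1, sum(y == 0))), n / (2 * max(1, sum(y == 1))))
  } else c(1, 1)
  ll_train <- ll_val <- rep(NA_real_, cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n, n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (bi in batches) {
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi]
      nb <- length(bi)
      # forward with inverted dropout
      acts <- vector("list", nl + 1L)
      masks <- vector("list", nl)
      a <- xb
      if (cfg$dropout_input > 0) {
        m0 <- matrix(stats::rbinom(length(a), 1, 1 - cfg$dropout_input),
                     nb) / (1 - cfg$dropout_input)
        a <- a * m0
      }
      acts[[1L]] <- a
      zs <- vector("list", nl)
      for (l in seq_len(nl)) {
        z <- sweep(a %*% params$W[[l]], 2, params$b[[l]], "+")
        zs[[l]] <- z
        if (l < nl) {
          a <- pmax(z, 0)
          if (cfg$dropout_hidden > 0) {
            m <- matrix(stats::rbinom(length(a), 1, 1 - cfg$dropout_hidden),
                        nb) / (1 - cfg$dropout_hidden)
            a <- a * m
            masks[[l]] <- m
          }
        } else {
          a <- z
        }
        acts[[l + 1L]] <- a
      }
      zmax <- apply(a, 1, max)
      ez <- exp(a - zmax)
      p <- ez / rowSums(ez)
      tgt <- cbind(1 - yb, yb)
      wv <- w_class[yb + 1L]
      dz <- (p - tgt) * wv / nb
      # backward
      step <- step + 1L
      for (l in rev(seq_len(nl))) {
        dW <- crossprod(acts[[l]], dz)
        db <- colSums(dz)
        if (l > 1L) {
          da <- tcrossprod(dz, params$W[[l]])
          if (!is.null(masks[[l - 1L]])) da <- da * masks[[l - 1L]]
          dz <- da * (zs[[l - 1L]] > 0)
        }
        adam$m[[l]] <- b1 * adam$m[[l]] + (1 - b1) * dW
        adam$v[[l]] <- b2 * adam$v[[l]] + (1 - b2) * dW^2
        adam$mb[[l]] <- b1 * adam$mb[[l]] + (1 - b1) * db
        adam$vb[[l]] <- b2 * adam$vb[[l]] + (1 - b2) * db^2
        mhat <- adam$m[[l]] / (1 - b1^step)
        vhat <- adam$v[[l]] / (1 - b2^step)
        mbh <- adam$mb[[l]] / (1 - b1^step)
        vbh <- adam$vb[[l]] / (1 - b2^step)
        params$W[[l]] <- params$W[[l]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        params$b[[l]] <- params$b[[l]] - cfg$learning_rate * mbh / (sqrt(vbh) + eps)
      }
    }
    ll_train[epoch] <- .logloss(.mlp_probs(params, x)[, 2L], y)
    if (!is.null(x_val) && nrow(x_val) > 0) {
      ll_val[epoch] <- .logloss(.mlp_probs(params, x_val)[, 2L], y_val)
    }
  }
  list(params = params, ll_train = ll_train, ll_val = ll_val)
}

.stratified_split <- function(ids, y, frac) {
  train <- character(0)
  for (cls in unique(y)) {
    pool <- ids[y == cls]
    k <- round(frac * length(pool))
    train <- c(train, resample(pool, k))
  }
  train
}

#' Train the MIA/non-MIA transcript classifier
#'
#' Splits the labeled transcripts into stratified 70/30 train/validation
#' partitions under `config$seed`, trains the feed-forward network to
#' `config$epochs` full passes, records the logloss trajectory on both
#' partitions, flags early divergence (validation logloss rising for
#' `patience` consecutive epochs) without stopping, and optionally reports
#' stratified k-fold cross-validated AUC.
#'
#' @param features matrix from [make_features()].
#' @param labels a [label_set()]; labeled transcripts absent from
#'   `features` (e.g. removed by the TPM filter) are dropped with a warning.
#' @param config a [classifier_config()].
#' @return object of class `mia_classifier` with elements `params`,
#'   `config`, `feature_names`, `train_ids`, `val_ids` and `report`
#'   (confusion matrices, AUCs, logloss trajectory, divergence epoch).
#' @export
train_classifier <- function(features, labels, config = classifier_config()) {
  stopifnot(is.matrix(features), inherits(labels, "label_set"))
  if (length(labels$positives) == 0) {
    stop_param("training error: empty positive set")
  }
  if (length(labels$negatives) == 0) {
    stop_param("training error: empty negative set")
  }
  lab_ids <- c(labels$positives, labels$negatives)
  missing <- setdiff(lab_ids, rownames(features))
  if (length(missing)) {
    warning("train_classifier: ", length(missing),
            " labeled transcript(s) absent from features; dropped")
    lab_ids <- intersect(lab_ids, rownames(features))
  }
  y_all <- stats::setNames(as.integer(lab_ids %in% labels$positives), lab_ids)
  if (length(unique(y_all)) < 2) {
    stop_param("training error: need both classes among labeled features")
  }

  with_seed(config$seed, {
    train_ids <- .stratified_split(lab_ids, y_all, config$split)
    val_ids <- setdiff(lab_ids, train_ids)
    xt <- features[train_ids, , drop = FALSE]
    yt <- y_all[train_ids]
    xv <- features[val_ids, , drop = FALSE]
    yv <- y_all[val_ids]
    fit <- .mlp_train(xt, yt, config, xv, yv)

    p_train <- .mlp_probs(fit$params, xt)[, 2L]
    p_val <- .mlp_probs(fit$params, xv)[, 2L]
    conf <- function(p, y) {
      table(predicted = factor(p > config$threshold, c(FALSE, TRUE),
                               c("non-MIA", "MIA")),
            truth = factor(y == 1, c(FALSE, TRUE), c("non-MIA", "MIA")))
    }
    diverged <- NA_integer_
    dv <- diff(fit$ll_val)
    if (config$patience > 0 && length(dv) >= config$patience &&
        !anyNA(fit$ll_val)) {
      runs <- rle(dv > 0)
      hit <- which(runs$values & runs$lengths >= config$patience)
      if (length(hit)) {
        diverged <- sum(runs$lengths[seq_len(hit[1] - 1)]) + 1L
      }
    }

    cv_auc <- numeric(0)
    if (config$cv_folds >= 2) {
      folds <- integer(length(lab_ids))
      names(folds) <- lab_ids
      for (cls in c(0L, 1L)) {
        pool <- resample(lab_ids[y_all == cls], sum(y_all == cls))
        folds[pool] <- rep_len(seq_len(config$cv_folds), length(pool))
      }
      cv_auc <- vapply(seq_len(config$cv_folds), function(f) {
        tr <- lab_ids[folds != f]
        te <- lab_ids[folds == f]
        cvfit <- .mlp_train(features[tr, , drop = FALSE], y_all[tr], config)
        auc_score(.mlp_probs(cvfit$params, features[te, , drop = FALSE])[, 2L],
                  y_all[te])
      }, numeric(1))
    }

    report <- list(
      auc = c(train = auc_score(p_train, yt),
              validation = auc_score(p_val, yv),
              cv_mean = if (length(cv_auc)) mean(cv_auc) else NA_real_),
      cv_auc = cv_auc,
      confusion = list(train = conf(p_train, yt), validation = conf(p_val, yv)),
      logloss = data.frame(epoch = seq_len(config$epochs),
                           train = fit$ll_train, validation = fit$ll_val),
      divergence_epoch = diverged)

    structure(list(params = fit$params, config = config,
                   feature_names = colnames(features),
                   train_ids = sort(train_ids), val_ids = sort(val_ids),
                   report = report),
              class = "mia_classifier")
  })
}

#' @export
print.mia_classifier <- function(x, ...) {
  cat("Feed-forward MIA classifier (",
      paste(x$config$hidden_sizes, collapse = "/"), " hidden units, ",
      x$config$epochs, " epochs)\n", sep = "")
  cat("  train/validation: ", length(x$train_ids), "/", length(x$val_ids),
      " transcripts\n", sep = "")
  a <- round(x$report$auc, 3)
  cat("  AUC: train ", a[["train"]], ", validation ", a[["validation"]],
      if (!is.na(a[["cv_mean"]])) paste0(", CV mean ", a[["cv_mean"]]),
      "\n", sep = "")
  invisible(x)
}

#' Posterior MIA probabilities for new profiles
#'
#' @param object a trained `mia_classifier`.
#' @param newdata feature matrix with the same columns as used in training.
#' @param ... unused.
#' @return named numeric vector of P(MIA) in `[0, 1]`.
#' @export
predict.mia_classifier <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!identical(colnames(newdata), object$feature_names)) {
    stop_param("validation error: feature columns do not match training schema")
  }
  if (nrow(newdata) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  stats::setNames(.mlp_probs(object$params, newdata)[, 2L], rownames(newdata))
}

#' Predict MIA-related transcripts among the unlabeled set
#'
#' @param model a trained `mia_classifier`.
#' @param features feature matrix from [make_features()].
#' @param labels the [label_set()] used in training.
#' @param threshold probability cutoff (defaults to the trained config's).
#' @return list with `scores` (named P(MIA) for every unlabeled transcript
#'   present in `features`) and `predicted_mia` (ids with score above the
#'   threshold).
#' @export
predict_unlabeled <- function(model, features, labels,
                              threshold = model$config$threshold) {
  stopifnot(inherits(model, "mia_classifier"), inherits(labels, "label_set"))
  ids <- intersect(labels$unlabeled, rownames(features))
  scores <- predict(model, features[ids, , drop = FALSE])
  list(scores = scores,
       predicted_mia = sort(names(scores)[scores > threshold]))
}
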