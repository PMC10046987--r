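#' Registry of the 22 shallow-classifier presets
#'
#' Five families: 3 decision trees (Fine/Medium/Coarse, split budgets
#' 100/20/4), 2 naive Bayes (Gaussian, Kernel), 6 support vector machines
#' (Linear, Quadratic, Cubic, Fine/Medium/Coarse Gaussian with kernel scale
#' sqrt(P)/4, sqrt(P), 4*sqrt(P) for P features), 6 k-nearest neighbors
#' (Fine k=1, Medium k=10, Coarse k=100, Cosine, Cubic (Minkowski p=3) and
#' distance-Weighted, each k=10) and 5 neural networks (hidden layouts 10, 25,
#' 100, 10-10, 10-10-10). Scale-sensitive families (SVM, kNN, NN) standardize
#' inputs inside each training fold.
#'
#' @return List of 22 `"classifier_config"` objects with unique `preset_name`s.
#' @export
classifier_registry <- function() {
  cfg <- function(family, name, standardize, ...) {
    structure(list(family = family, preset_name = name,
                   hyperparameters = list(...), standardize_inputs = standardize),
              class = "classifier_config")
  }
  list(
    cfg("decision_tree", "Fine Tree", FALSE, max_splits = 100L),
    cfg("decision_tree", "Medium Tree", FALSE, max_splits = 20L),
    cfg("decision_tree", "Coarse Tree", FALSE, max_splits = 4L),
    cfg("naive_bayes", "Gaussian Naive Bayes", FALSE, kernel = FALSE),
    cfg("naive_bayes", "Kernel Naive Bayes", FALSE, kernel = TRUE),
    cfg("svm", "Linear SVM", TRUE, kernel = "linear"),
    cfg("svm", "Quadratic SVM", TRUE, kernel = "polynomial", degree = 2L),
    cfg("svm", "Cubic SVM", TRUE, kernel = "polynomial", degree = 3L),
    cfg("svm", "Fine Gaussian SVM", TRUE, kernel = "radial", scale_factor = 0.25),
    cfg("svm", "Medium Gaussian SVM", TRUE, kernel = "radial", scale_factor = 1),
    cfg("svm", "Coarse Gaussian SVM", TRUE, kernel = "radial", scale_factor = 4),
    cfg("knn", "Fine KNN", TRUE, k = 1L, distance = "euclidean", weighted = FALSE),
    cfg("knn", "Medium KNN", TRUE, k = 10L, distance = "euclidean", weighted = FALSE),
    cfg("knn", "Coarse KNN", TRUE, k = 100L, distance = "euclidean", weighted = FALSE),
    cfg("knn", "Cosine KNN", TRUE, k = 10L, distance = "cosine", weighted = FALSE),
    cfg("knn", "Cubic KNN", TRUE, k = 10L, distance = "minkowski3", weighted = FALSE),
    cfg("knn", "Weighted KNN", TRUE, k = 10L, distance = "euclidean", weighted = TRUE),
    cfg("neural_network", "Narrow Neural Network", TRUE, hidden = 10L),
    cfg("neural_network", "Medium Neural Network", TRUE, hidden = 25L),
    cfg("neural_network", "Wide Neural Network", TRUE, hidden = 100L),
    cfg("neural_network", "Bilayered Neural Network", TRUE, hidden = c(10L, 10L)),
    cfg("neural_network", "Trilayered Neural Network", TRUE, hidden = c(10L, 10L, 10L))
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  cat(sprintf("classifier preset '%s' (%s)\n", x$preset_name, x$family))
  invisible(x)
}

# --- fit / predict -----------------------------------------------------------
# fit_classifier returns an opaque model; predict_classifier returns
# list(class = 0/1 vector, score = continuous score, larger = more CAD-like).

fit_classifier <- function(config, X, y, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  hp <- config$hyperparameters
  model <- switch(config$family,
    decision_tree = {
      df <- data.frame(X); df$.y <- factor(y, levels = c(0, 1))
      # rpart has no direct split-count budget; depth ~ log2(splits + 1)
      depth <- max(1L, ceiling(log2(hp$max_splits + 1)))
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(maxdepth = depth, cp = 1e-4,
                                                  minsplit = 4, xval = 0))
    },
    naive_bayes = {
      if (isTRUE(hp$kernel)) fit_kernel_nb(X, y)
      else {
        keep <- apply(X, 2, function(v) stats::var(v) > 0)
        df <- data.frame(X[, keep, drop = FALSE])
        list(nb = e1071::naiveBayes(df, factor(y, levels = c(0, 1))), keep = keep)
      }
    },
    svm = {
      p <- ncol(X)
      args <- list(x = X, y = factor(y, levels = c(0, 1)), scale = FALSE,
                   kernel = hp$kernel, cost = 1)
      if (hp$kernel == "polynomial") {
        args$degree <- hp$degree; args$gamma <- 1 / p; args$coef0 <- 1
      }
      if (hp$kernel == "radial") {
        ks <- hp$scale_factor * sqrt(p) # MATLAB-style kernel scale
        args$gamma <- 1 / ks^2
      }
      do.call(e1071::svm, args)
    },
    knn = list(X = X, y = y, k = min(hp$k, nrow(X)), distance = hp$distance,
               weighted = isTRUE(hp$weighted)),
    neural_network = fit_mlp(X, y, hidden = hp$hidden, seed = seed),
    iristex_error("unknown classifier family", "iristex_config_error")
  )
  structure(list(family = config$family, model = model,
                 preset_name = config$preset_name),
            class = "iristex_model")
}

predict_classifier <- function(fit, X) {
  X <- as.matrix(X)
  switch(fit$family,
    decision_tree = {
      pr <- stats::predict(fit$model, data.frame(X), type = "prob")[, "1"]
      list(class = as.integer(pr >= 0.5), score = pr)
    },
    naive_bayes = {
      if (inherits(fit$model, "iristex_kernel_nb")) predict_kernel_nb(fit$model, X)
      else {
        df <- data.frame(X[, fit$model$keep, drop = FALSE])
        pr <- stats::predict(fit$model$nb, df, type = "raw")[, "1"]
        list(class = as.integer(pr >= 0.5), score = pr)
      }
    },
    svm = {
      pred <- stats::predict(fit$model, X, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # e1071's decision value is signed towards the first level of the pair
      # named in the attribute's column; orient so larger = class "1"
      if (startsWith(colnames(attr(pred, "decision.values"))[1], "0")) dv <- -dv
      list(class = as.integer(as.character(pred)), score = dv)
    },
    knn = predict_knn(fit$model, X),
    neural_network = {
      pr <- predict_mlp(fit$model, X)
      list(class = as.integer(pr >= 0.5), score = pr)
    }
  )
}

# --- k-nearest neighbors (cosine / cubic / weighted variants) ---------------

predict_knn <- function(model, X) {
  tr <- model$X
  D <- switch(model$distance,
    euclidean = {
      cross <- X %*% t(tr)
      d2 <- outer(rowSums(X^2), rowSums(tr^2), `+`) - 2 * cross
      sqrt(pmax(d2, 0))
    },
    minkowski3 = {
      D <- matrix(0, nrow(X), nrow(tr))
      for (i in seq_len(nrow(X))) {
        D[i, ] <- colSums(abs(t(tr) - X[i, ])^3)^(1 / 3)
      }
      D
    },
    cosine = {
      nx <- sqrt(rowSums(X^2)); nt <- sqrt(rowSums(tr^2))
      nx[nx == 0] <- 1; nt[nt == 0] <- 1
      1 - (X %*% t(tr)) / outer(nx, nt)
    },
    iristex_error("unknown kNN distance", "iristex_config_error")
  )
  k <- model$k
  score <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    nb <- order(D[i, ], seq_len(nrow(tr)))[seq_len(k)]
    if (model$weighted) {
      w <- 1 / (D[i, nb]^2 + 1e-12)
      score[i] <- sum(w * (model$y[nb] == 1)) / sum(w)
    } else {
      score[i] <- mean(model$y[nb] == 1)
    }
  }
  list(class = as.integer(score >= 0.5), score = score)
}

# --- kernel naive Bayes ------------------------------------------------------
# Per-class, per-feature Gaussian kernel density estimate; posteriors from the
# product of feature likelihoods and the class priors.

fit_kernel_nb <- function(X, y) {
  classes <- c(0L, 1L)
  dens <- lapply(classes, function(cl) {
    lapply(seq_len(ncol(X)), function(j) {
      v <- X[y == cl, j]
      bw <- tryCatch(stats::bw.nrd0(v), error = function(e) 0)
      if (!is.finite(bw) || bw <= 0) bw <- max(1e-6 * (diff(range(X[, j])) + 1e-9), 1e-9)
      d <- stats::density(v, bw = bw, n = 512,
                          from = min(v) - 3 * bw, to = max(v) + 3 * bw)
      list(x = d$x, y = d$y)
    })
  })
  structure(list(dens = dens, prior = c(mean(y == 0), mean(y == 1))),
            class = "iristex_kernel_nb")
}

predict_kernel_nb <- function(model, X) {
  loglik <- matrix(0, nrow(X), 2)
  for (cl in 1:2) {
    for (j in seq_len(ncol(X))) {
      d <- model$dens[[cl]][[j]]
      f <- stats::approx(d$x, d$y, xout = X[, j], yleft = 0, yright = 0)$y
      loglik[, cl] <- loglik[, cl] + log(pmax(f, 1e-12))
    }
    loglik[, cl] <- loglik[, cl] + log(model$prior[cl])
  }
  pr <- 1 / (1 + exp(loglik[, 1] - loglik[, 2])) # posterior of class 1
  list(class = as.integer(pr >= 0.5), score = pr)
}

# --- multilayer perceptron ---------------------------------------------------
# Fully connected ReLU network with sigmoid output, trained full-batch with
# Adam on cross-entropy + L2 (1e-4); deterministic given the seed. Written
# in-package because the preset list includes two- and three-hidden-layer nets.

fit_mlp <- function(X, y, hidden, seed = 1L, epochs = 300L, lr = 0.01,
                    lambda = 1e-4) {
  sizes <- c(ncol(X), hidden, 1L)
  nl <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(nl), function(l) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(nl), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    n <- nrow(X)
    for (t in seq_len(epochs)) {
      # forward
      A <- vector("list", nl + 1); A[[1]] <- X
      Z <- vector("list", nl)
      for (l in seq_len(nl)) {
        Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], `+`)
        A[[l + 1]] <- if (l < nl) pmax(Z[[l]], 0) else Z[[l]]
      }
      p <- 1 / (1 + exp(-A[[nl + 1]]))
      # backward
      delta <- (p - y) / n # d(CE)/d(logit)
      gW <- vector("list", nl); gb <- vector("list", nl)
      for (l in rev(seq_len(nl))) {
        gW[[l]] <- t(A[[l]]) %*% delta + lambda * W[[l]]
        gb[[l]] <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (Z[[l - 1]] > 0)
      }
      # Adam update
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (l in seq_len(nl)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - b1^t)) /
          (sqrt(vW[[l]] / (1 - b2^t)) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - b1^t)) /
          (sqrt(vb[[l]] / (1 - b2^t)) + eps)
      }
    }
    structure(list(W = W, b = b), class = "iristex_mlp")
  })
}

predict_mlp <- function(model, X) {
  A <- X
  nl <- length(model$W)
  for (l in seq_len(nl)) {
    A <- sweep(A %*% model$W[[l]], 2, model$b[[l]], `+`)
    if (l < nl) A <- pmax(A, 0)
  }
  as.vector(1 / (1 + exp(-A)))
}
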