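#' Row-subset a GEM to a gene set
#'
#' @param gem a [gem].
#' @param gene_set character vector of gene ids; order is preserved.
#' @return the sub-GEM (genes present, in `gene_set` order); absent genes
#'   are reported in `attr(, "absent")`. Zero overlap is an error.
#' @export
subset_gem <- function(gem, gene_set) {
  stopifnot(is_gem(gem))
  present <- gene_set[gene_set %in% gene_ids(gem)]
  if (!length(present)) stop("no gene of the set is present in the GEM")
  out <- gem(gem$values[present, , drop = FALSE], gem$scale)
  attr(out, "absent") <- setdiff(gene_set, present)
  out
}

#' Classifier configuration
#'
#' A multilayer perceptron with three ReLU hidden layers (512, 256, 128
#' units) and a softmax output, trained on a stratified random 70%
#' split and evaluated on the held-out 30%.
#'
#' @param hidden_sizes hidden layer widths.
#' @param train_fraction fraction of samples used for training.
#' @param epochs,learning_rate,batch_size,l2 training hyperparameters
#'   (Adam optimiser, L2 weight penalty).
#' @param seed integer seed controlling the split, initial weights and
#'   batch order.
#' @return named list of class `"classifier_config"`.
#' @export
classifier_config <- function(hidden_sizes = c(512, 256, 128),
                              train_fraction = 0.70, epochs = 60,
                              learning_rate = 1e-3, batch_size = 32,
                              l2 = 1e-4, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(hidden_sizes = hidden_sizes,
                 train_fraction = train_fraction, epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size,
                 l2 = l2, seed = seed), class = "classifier_config")
}

#' Train an MLP on a sub-GEM and report held-out classification
#'
#' Samples are the observations (features = genes, log2 scale; missing
#' values imputed to 0 for the classifier only, count recorded). The
#' split is stratified per class so every class appears in both splits.
#' Deterministic for fixed (seed, data).
#'
#' @param subgem a [gem] restricted to the gene set of interest.
#' @param annot annotation data frame (>= 2 classes, >= 5 samples each).
#' @param cfg a [classifier_config].
#' @return list of class `"classification_report"`: `confusion` (true x
#'   predicted counts), `per_class_accuracy`, `overall_accuracy`,
#'   `n_train`, `n_test`, `n_imputed`.
#' @export
train_evaluate <- function(subgem, annot, cfg = classifier_config()) {
  stopifnot(is_gem(subgem), inherits(cfg, "classifier_config"))
  check_annotation(subgem, annot)
  y_all <- factor(annot$condition[match(sample_ids(subgem), annot$sample)])
  classes <- levels(y_all)
  if (length(classes) < 2) stop("need >= 2 classes")
  if (any(table(y_all) < 5)) stop("every class needs >= 5 samples")
  X <- t(subgem$values)
  n_imputed <- sum(is.na(X))
  X[is.na(X)] <- 0

  set.seed(cfg$seed)
  idx_train <- unlist(lapply(classes, function(cl) {
    ix <- which(y_all == cl)
    sample(ix, max(1L, floor(cfg$train_fraction * length(ix))))
  }))
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(y_all), idx_train)
  if (length(unique(y_all[idx_train])) < length(classes))
    stop("a class is absent from the training split; change seed or fraction")

  mu <- colMeans(X[idx_train, , drop = FALSE])
  sg <- apply(X[idx_train, , drop = FALSE], 2, stats::sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")

  model <- mlp_fit(Xs[idx_train, , drop = FALSE],
                   as.integer(y_all[idx_train]), length(classes), cfg)
  pred <- mlp_predict(model, Xs[idx_test, , drop = FALSE])
  truth <- y_all[idx_test]
  confusion <- table(true = truth,
                     predicted = factor(classes[pred], levels = classes))
  per_class <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion,
                 per_class_accuracy = per_class,
                 overall_accuracy = sum(diag(confusion)) / length(idx_test),
                 n_train = length(idx_train), n_test = length(idx_test),
                 n_imputed = n_imputed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("MLP classification: overall accuracy %.3f (%d train / %d test)\n",
              x$overall_accuracy, x$n_train, x$n_test))
  print(x$confusion)
  invisible(x)
}

# ---- minimal MLP (ReLU hidden layers, softmax output, Adam) -------------
# implemented in plain matrix code; sized for desk-scale expression panels

mlp_fit <- function(X, y, n_class, cfg) {
  sizes <- c(ncol(X), cfg$hidden_sizes, n_class)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {     # He initialisation for the ReLU layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                  sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; epsadam <- 1e-8; t_step <- 0
  n <- nrow(X)
  Y <- matrix(0, n, n_class); Y[cbind(seq_len(n), y)] <- 1

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1, n)]
      A <- list(X[bi, , drop = FALSE]); Z <- vector("list", L)
      for (l in seq_len(L)) {
        Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
        A[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else softmax(Z[[l]])
      }
      delta <- (A[[L + 1]] - Y[bi, , drop = FALSE]) / length(bi)
      t_step <- t_step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + cfg$l2 * W[[l]]
        gb <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(W[[l]])) * (Z[[l - 1]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr <- sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
        W[[l]] <- W[[l]] - cfg$learning_rate * corr * mW[[l]] /
          (sqrt(vW[[l]]) + epsadam)
        b[[l]] <- b[[l]] - cfg$learning_rate * corr * mb[[l]] /
          (sqrt(vb[[l]]) + epsadam)
      }
    }
  }
  list(W = W, b = b, L = L)
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

mlp_predict <- function(model, X) {
  A <- X
  for (l in seq_len(model$L)) {
    A <- sweep(A %*% model$W[[l]], 2, model$b[[l]], "+")
    if (l < model$L) A <- pmax(A, 0)
  }
  max.col(A, ties.method = "first")
}
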