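# Spectral hypergraph neural network classifier.
#
# Each layer applies the hypergraph convolution
#   X' = sigma( Dv^{-1/2} H W De^{-1} H^t Dv^{-1/2} X Theta + b )
# where H is the n x E incidence matrix, W = diag(edge weights),
# De = diag(edge degrees), Dv = diag(weighted node degrees). The
# propagation matrix aggregates node features into hyperedges (mean over
# members), scales by edge weight, and redistributes to member nodes, with
# symmetric degree normalization -- the node-edge-node transformation.
# Training is full-batch gradient descent with the adaptive-moment (Adam)
# update on a cross-entropy objective over the (transductive) training
# nodes; gradients are computed in closed form.

#' HGNN hyperparameters
#'
#' @param k nodes per hyperedge for continuous features (used by the
#'   hypergraph builder, kept with the model config for provenance).
#' @param hidden_dim hidden layer width.
#' @param n_layers number of convolution layers (the last maps to the 2
#'   class logits).
#' @param dropout dropout probability on hidden activations during
#'   training.
#' @param learning_rate Adam step size.
#' @param max_epochs,patience training length and early-stopping patience
#'   on validation AUC.
#' @param seed RNG seed controlling initialization, dropout and any fold
#'   assignment; identical config + seed reproduces the fit exactly.
#' @return List of class `hgnn_config`.
#' @export
hgnn_config <- function(k = 12L, hidden_dim = 32L, n_layers = 2L,
                        dropout = 0.5, learning_rate = 0.01,
                        max_epochs = 300L, patience = 30L, seed = 1L) {
  stopifnot(hidden_dim >= 2L, n_layers >= 1L, dropout >= 0, dropout < 1,
            learning_rate > 0, max_epochs >= 1L, patience >= 1L)
  structure(list(k = as.integer(k), hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers), dropout = dropout,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "hgnn_config")
}

# Symmetric normalized propagation matrix G (n x n, symmetric).
hgnn_propagation <- function(hg) {
  H <- hg$incidence
  w <- hg$edge_weights
  de <- colSums(H)
  dv <- as.vector(H %*% w)
  zero <- which(dv == 0)
  if (length(zero)) {
    stop("node(s) with zero hypergraph degree: ",
         paste(utils::head(zero, 5), collapse = ", "))
  }
  Hw <- sweep(H, 2L, w / de, "*")
  G <- H %*% t(Hw)                      # H W De^-1 H^t
  sweep(sweep(G, 1L, sqrt(dv), "/"), 2L, sqrt(dv), "/")
}

relu <- function(z) pmax(z, 0)

# Forward pass; returns activations needed for backprop.
hgnn_forward <- function(G, X, params, dropout_masks = NULL) {
  L <- length(params)
  acts <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]])) {
      A <- A * dropout_masks[[l]]
    }
    GA <- G %*% A
    Z <- GA %*% params[[l]]$theta +
      matrix(params[[l]]$b, nrow(GA), length(params[[l]]$b), byrow = TRUE)
    acts[[l]] <- list(A = A, GA = GA, Z = Z)
    A <- if (l < L) relu(Z) else Z
  }
  list(logits = A, acts = acts)
}

softmax2 <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Train and evaluate the HGNN classifier
#'
#' Transductive protocol: all subjects are nodes of one hypergraph and
#' enter every forward pass; only the training labels contribute to the
#' loss. The epoch with the best validation AUC is kept (falling back to
#' the lowest training loss when no validation split is given), and the
#' report is computed on the test split with the class-probability
#' threshold 0.5.
#'
#' @param hg `hypergraph` over all subjects.
#' @param x numeric node-feature matrix (subjects x features), typically
#'   the standardized selected features.
#' @param labels binary outcome (factor or 0/1); second level / 1 is the
#'   positive class.
#' @param split list with integer elements `train`, `validation`, `test`
#'   (validation may be empty).
#' @param config an [hgnn_config()].
#' @return A `classifier_report`: `auc`, `sensitivity`, `specificity`,
#'   `confusion` (2x2), `per_subject_scores`, `split_sizes`, `history`,
#'   `best_epoch`.
#' @export
hgnn_train_eval <- function(hg, x, labels, split, config = hgnn_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(nrow(hg$incidence) == n)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (!all(y[c(split$train, split$validation, split$test)] %in% c(0L, 1L))) {
    stop("labels must be binary on all split members")
  }
  G <- hgnn_propagation(hg)
  test_deg <- rowSums(hg$incidence)[split$test]
  if (any(test_deg == 0)) {
    stop("test node(s) with zero degree: ",
         paste(split$test[test_deg == 0], collapse = ", "))
  }
  L <- config$n_layers
  dims <- c(ncol(x), rep(config$hidden_dim, max(0L, L - 1L)), 2L)

  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(config$seed)
  params <- lapply(seq_len(L), function(l) {
    fan <- dims[l] + dims[l + 1L]
    list(theta = matrix(stats::runif(dims[l] * dims[l + 1L],
                                     -sqrt(6 / fan), sqrt(6 / fan)),
                        dims[l], dims[l + 1L]),
         b = rep(0, dims[l + 1L]))
  })
  adam <- lapply(params, function(p) {
    list(mt = p$theta * 0, vt = p$theta * 0,
         mb = p$b * 0, vb = p$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tr <- split$train; va <- split$validation
  onehot <- cbind(1 - y, y)
  best <- list(metric = -Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    masks <- NULL
    if (config$dropout > 0) {
      masks <- lapply(seq_len(L), function(l) {
        if (l == 1L) return(NULL)  # no dropout on raw inputs
        m <- matrix(stats::rbinom(n * dims[l], 1L, 1 - config$dropout),
                    n, dims[l]) / (1 - config$dropout)
        m
      })
    }
    fw <- hgnn_forward(G, x, params, masks)
    P <- softmax2(fw$logits)
    if (any(!is.finite(P))) stop("non-finite probabilities at epoch ", epoch,
                                 "; reduce the learning rate")
    loss <- -mean(log(pmax(P[cbind(tr, y[tr] + 1L)], 1e-12)))
    # backprop
    dZ <- matrix(0, n, 2L)
    dZ[tr, ] <- (P[tr, , drop = FALSE] - onehot[tr, , drop = FALSE]) /
      length(tr)
    grads <- vector("list", L)
    for (l in rev(seq_len(L))) {
      act <- fw$acts[[l]]
      grads[[l]] <- list(theta = t(act$GA) %*% dZ, b = colSums(dZ))
      if (l > 1L) {
        dA <- (G %*% dZ) %*% t(params[[l]]$theta)  # G is symmetric
        if (!is.null(masks) && !is.null(masks[[l]])) dA <- dA * masks[[l]]
        dZ <- dA * (fw$acts[[l - 1L]]$Z > 0)
      }
    }
    t_adam <- epoch
    for (l in seq_len(L)) {
      adam[[l]]$mt <- b1 * adam[[l]]$mt + (1 - b1) * grads[[l]]$theta
      adam[[l]]$vt <- b2 * adam[[l]]$vt + (1 - b2) * grads[[l]]$theta^2
      adam[[l]]$mb <- b1 * adam[[l]]$mb + (1 - b1) * grads[[l]]$b
      adam[[l]]$vb <- b2 * adam[[l]]$vb + (1 - b2) * grads[[l]]$b^2
      mhat <- adam[[l]]$mt / (1 - b1^t_adam)
      vhat <- adam[[l]]$vt / (1 - b2^t_adam)
      params[[l]]$theta <- params[[l]]$theta -
        config$learning_rate * mhat / (sqrt(vhat) + eps)
      mbh <- adam[[l]]$mb / (1 - b1^t_adam)
      vbh <- adam[[l]]$vb / (1 - b2^t_adam)
      params[[l]]$b <- params[[l]]$b -
        config$learning_rate * mbh / (sqrt(vbh) + eps)
    }
    # model selection
    if (length(va)) {
      Pe <- softmax2(hgnn_forward(G, x, params)$logits)
      metric <- auc_score(Pe[va, 2L], y[va])
    } else {
      metric <- -loss
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = loss,
                                         val_auc = if (length(va)) metric
                                                   else NA_real_))
    if (is.na(metric)) metric <- -loss
    if (metric > best$metric + 1e-12) {
      best <- list(metric = metric, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  scores <- softmax2(hgnn_forward(G, x, best$params)$logits)[, 2L]
  te <- split$test
  pred <- as.integer(scores[te] >= 0.5)
  confusion <- matrix(c(sum(pred == 0 & y[te] == 0), sum(pred == 0 & y[te] == 1),
                        sum(pred == 1 & y[te] == 0), sum(pred == 1 & y[te] == 1)),
                      2L, 2L,
                      dimnames = list(truth = c("0", "1"),
                                      predicted = c("0", "1")))
  sens <- if (sum(y[te] == 1)) sum(pred == 1 & y[te] == 1) / sum(y[te] == 1)
          else NA_real_
  spec <- if (sum(y[te] == 0)) sum(pred == 0 & y[te] == 0) / sum(y[te] == 0)
          else NA_real_
  structure(list(auc = auc_score(scores[te], y[te]),
                 sensitivity = sens, specificity = spec,
                 confusion = confusion, per_subject_scores = scores,
                 split_sizes = vapply(split, length, integer(1)),
                 history = history, best_epoch = best$epoch,
                 config = config),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> test AUC = %.3f, sensitivity = ",
                     "%.3f, specificity = %.3f (splits %s)\n"),
              x$auc, x$sensitivity, x$specificity,
              paste(x$split_sizes, collapse = "/")))
  invisible(x)
}

#' Scan the hyperedge size k on the validation split
#'
#' Rebuilds the continuous-feature hypergraphs and retrains the model for
#' every k in the grid; the k with the best validation AUC is returned
#' together with the full curve. Ties go to the smallest k.
#'
#' @param features feature data frame/matrix passed to
#'   [build_multifeature_hypergraph()].
#' @param continuous,categorical feature names by kind.
#' @param weights per-feature edge weights.
#' @param x node-feature matrix.
#' @param labels binary outcome.
#' @param split list `train` / `validation` / `test`; validation must be
#'   non-empty.
#' @param config an [hgnn_config()] (its `k` is overridden by the grid).
#' @param k_grid candidate values, default 5:13.
#' @return List: `k_best`, `curve` (data frame `k`, `val_auc`),
#'   `reports` (per-k classifier reports).
#' @export
scan_k <- function(features, continuous, categorical, weights, x, labels,
                   split, config = hgnn_config(), k_grid = 5:13) {
  if (!length(k_grid)) stop("empty k grid")
  if (!length(split$validation)) stop("scan_k needs a validation split")
  reports <- list()
  val_auc <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    cfg <- config
    cfg$k <- as.integer(k_grid[i])
    hg <- build_multifeature_hypergraph(features, continuous, categorical,
                                        weights, k = cfg$k)
    rep_i <- hgnn_train_eval(hg, x, labels, split, cfg)
    y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
    val_auc[i] <- auc_score(rep_i$per_subject_scores[split$validation],
                            y[split$validation])
    reports[[as.character(k_grid[i])]] <- rep_i
  }
  best <- which.max(val_auc)  # first max -> smallest k on ties
  list(k_best = k_grid[best],
       curve = data.frame(k = k_grid, val_auc = val_auc),
       reports = reports)
}
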