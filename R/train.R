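#' Run configuration
#'
#' All tunable settings of the pipeline in one validated list. Defaults
#' follow the training protocol the model family uses: initial learning
#' rate 0.005, batch size 32, at most 50 epochs, learning rate halved on a
#' validation plateau with patience 10, L2 weight decay 1e-6, top-30
#' supra-threshold neighbours per ROI (edge threshold 0.001), and a
#' visualization threshold of 0.52 on the learned mask.
#'
#' @param q Parcellation size (number of ROIs).
#' @param k Graph sparsity: neighbours kept per node.
#' @param threshold Edge threshold for graph construction.
#' @param lambda1,lambda2,lambda3 Mask-penalty weights (L1, squared
#'   Frobenius, orthonormality).
#' @param alpha Manifold-regularization weight.
#' @param lr Initial learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Plateau-scheduler patience (epochs).
#' @param lr_factor Multiplicative learning-rate decay on plateau.
#' @param min_lr Learning-rate floor.
#' @param weight_decay L2 coefficient on all parameters.
#' @param manifold_floor Manifold-monitor threshold: when the batch-mean
#'   manifold loss drops below it, `alpha` is halved (oversmoothing guard).
#' @param vis_threshold Mask visualization threshold, in (0, 1).
#' @param seed Master seed for all randomness.
#' @param task `"regression"` or `"classification"`.
#' @param modalities Subset of `c("FC", "SC", "AS")`.
#' @param n_targets Number of regression targets.
#' @param d1,d2,d_hidden Layer widths.
#' @param pooling Graph pooling: `"mean"`, `"sum"` or `"max"`.
#' @param graph_from Which connectivity defines the edges; default FC for
#'   multimodal runs, SC for SC-only runs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(q = 40, k = 30, threshold = 0.001,
                       lambda1 = 1e-3, lambda2 = 1e-3, lambda3 = 1e-2,
                       alpha = 1e-4, lr = 0.005, batch_size = 32,
                       max_epochs = 50, patience = 10, lr_factor = 0.5,
                       min_lr = 1e-5, weight_decay = 1e-6,
                       manifold_floor = 1e-4, vis_threshold = 0.52,
                       seed = 1,
                       task = c("regression", "classification"),
                       modalities = c("FC", "SC", "AS"),
                       n_targets = 1, d1 = 64, d2 = 64, d_hidden = 32,
                       pooling = "mean", graph_from = NULL) {
  task <- match.arg(task)
  stopifnot(q >= 2, k >= 1, threshold >= 0,
            lambda1 >= 0, lambda2 >= 0, lambda3 >= 0, alpha >= 0,
            lr > 0, batch_size >= 1, max_epochs >= 1,
            vis_threshold > 0, vis_threshold < 1,
            length(modalities) >= 1,
            all(modalities %in% c("FC", "SC", "AS")))
  if (identical(sort(modalities), "AS"))
    stop("run_config: at least one connectivity modality (FC or SC) is required")
  structure(as.list(environment()), class = "run_config")
}

#' Train/validation/test split of a cohort
#'
#' Draws a seeded split at the given proportions (default 70/10/20).
#' Classification splits are stratified by label so the extreme-group
#' balance is preserved in every subset.
#'
#' @param ids Character vector of subject ids.
#' @param proportions Length-3 vector summing to 1.
#' @param seed Seed for the permutation.
#' @param labels Optional class labels (switches on stratification).
#' @return List of class `split_plan`: `train`, `val`, `test` id vectors.
#' @export
make_splits <- function(ids, proportions = c(0.70, 0.10, 0.20), seed = 1,
                        labels = NULL) {
  n <- length(ids)
  if (n < 10) stop("make_splits: need at least 10 subjects")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("make_splits: proportions must sum to 1")
  set.seed(derive_seed(seed, "split"))
  split_idx <- function(idx) {
    m <- length(idx)
    idx <- sample(idx)
    n_tr <- round(proportions[1] * m)
    n_va <- round(proportions[2] * m)
    n_tr <- min(n_tr, m - 1)
    list(train = idx[seq_len(n_tr)],
         val = idx[n_tr + seq_len(min(n_va, m - n_tr))],
         test = idx[setdiff(seq_len(m), seq_len(n_tr + n_va))])
  }
  if (is.null(labels)) {
    parts <- split_idx(seq_len(n))
  } else {
    parts <- list(train = integer(0), val = integer(0), test = integer(0))
    for (lv in unique(labels)) {
      p <- split_idx(which(labels == lv))
      parts$train <- c(parts$train, p$train)
      parts$val <- c(parts$val, p$val)
      parts$test <- c(parts$test, p$test)
    }
  }
  if (any(lengths(parts) == 0))
    stop("make_splits: a split would be empty at these proportions")
  structure(list(train = ids[sort(parts$train)], val = ids[sort(parts$val)],
                 test = ids[sort(parts$test)], proportions = proportions,
                 seed = seed),
            class = "split_plan")
}

# Build per-subject graphs + targets for the configured task/modalities.
prepare_graphs <- function(cohort, config) {
  if (is.null(cohort$features)) cohort <- featurize_cohort(cohort)
  keep <- vapply(cohort$subjects, function(su) {
    if (config$task == "classification") !is.na(su$label) else !is.na(su$y[1])
  }, logical(1))
  subjects <- cohort$subjects[keep]
  feats <- cohort$features[keep]
  graphs <- lapply(feats, function(fe)
    build_graph(fc = fe$fc_scaled, sc = fe$sc_norm, as_table = fe$as_table,
                k = config$k, threshold = config$threshold,
                modalities = config$modalities,
                graph_from = config$graph_from))
  laps <- lapply(graphs, function(g) graph_laplacian(g$A))
  ids <- vapply(subjects, `[[`, character(1), "id")
  y <- if (config$task == "regression") {
    matrix(unlist(lapply(subjects, function(su)
      rep_len(su$y, config$n_targets))),
      nrow = length(subjects), ncol = config$n_targets, byrow = TRUE)
  } else {
    matrix(vapply(subjects, `[[`, integer(1), "label"), ncol = 1)
  }
  list(ids = ids, graphs = graphs, laplacians = laps, y = y)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

param_names <- c("V", "Theta1", "Theta2", "W1", "b1", "W2", "b2")

# Loss (and optionally gradients) over a set of subject indices.
batch_pass <- function(state, data, idx, config, alpha, with_grads = TRUE) {
  b <- length(idx)
  grads <- NULL
  l_e <- 0
  l_man <- 0
  for (s in idx) {
    fw <- model_forward(data$graphs[[s]], state, keep_cache = TRUE)
    ys <- data$y[s, ]
    l_e <- l_e + prediction_loss(matrix(fw$yhat, 1), matrix(ys, 1), config$task)
    if (alpha > 0)
      l_man <- l_man + manifold_loss(fw$H2, data$graphs[[s]]$A)
    if (with_grads) {
      dy <- prediction_loss_grad(fw$yhat, ys, config$task) / b
      g <- model_backward(fw, state, dy, alpha = alpha / b,
                          lap = data$laplacians[[s]])
      if (is.null(grads)) {
        grads <- g[param_names]
      } else {
        for (nm in param_names) grads[[nm]] <- grads[[nm]] + g[[nm]]
      }
    }
  }
  m <- mask_from_params(state$V)
  l_mask <- mask_penalty(m, config$lambda1, config$lambda2, config$lambda3)
  if (with_grads) {
    gpen <- mask_penalty_grad(m, config$lambda1, config$lambda2, config$lambda3)
    dz <- gpen * m * (1 - m)
    grads$V <- grads$V + dz + t(dz)
    for (nm in param_names)
      grads[[nm]] <- grads[[nm]] + config$weight_decay * state[[nm]]
  }
  list(l_e = l_e / b, l_manifold = l_man / b, l_mask = l_mask,
       total = l_e / b + alpha * l_man / b + l_mask, grads = grads)
}

#' Fit a masked graph neural network to a cohort
#'
#' The main fitting function. Derives features (if not already present),
#' builds per-subject graphs, splits the cohort 70/10/20, and jointly
#' optimizes the layer weights, the readout and the free mask parameters V
#' with Adam under the composite objective (prediction error + manifold
#' smoothness + mask penalty). The learning rate is reduced on a
#' validation-loss plateau; the manifold monitor halves `alpha` whenever
#' the batch-mean manifold loss falls below the configured floor; the
#' best-validation parameters are returned.
#'
#' @param cohort A `maskgnn_cohort`.
#' @param config A [run_config()].
#' @param splits Optional precomputed [make_splits()] plan.
#' @param verbose Print per-epoch progress.
#' @return Object of class `maskgnn` with elements `state` (parameters),
#'   `mask` (the learned M), `config`, `splits`, `history` (per-epoch loss
#'   breakdown), `metrics` (test-set evaluation), `predictions` (test-set
#'   predictions) and `events` (scheduler/monitor log).
#' @export
maskgnn <- function(cohort, config = run_config(), splits = NULL,
                    verbose = FALSE) {
  stopifnot(inherits(cohort, "maskgnn_cohort"), inherits(config, "run_config"))
  data <- prepare_graphs(cohort, config)
  n <- length(data$ids)
  labels <- if (config$task == "classification") data$y[, 1] else NULL
  if (is.null(splits))
    splits <- make_splits(data$ids, seed = config$seed, labels = labels)
  tr <- match(splits$train, data$ids)
  va <- match(splits$val, data$ids)
  te <- match(splits$test, data$ids)
  if (anyNA(c(tr, va, te)))
    stop("maskgnn: split plan refers to subjects absent from the cohort")

  q <- nrow(data$graphs[[1]]$A)
  d0 <- ncol(data$graphs[[1]]$H0)
  dc <- ncol(data$graphs[[1]]$C)
  n_out <- if (config$task == "classification") 2L else config$n_targets
  set.seed(derive_seed(config$seed, "init"))
  state <- init_model_state(q, d0, dc, d1 = config$d1, d2 = config$d2,
                            d_hidden = config$d_hidden, n_out = n_out,
                            task = config$task, pooling = config$pooling)
  opt <- adam_init(state[param_names])
  lr <- config$lr
  alpha <- config$alpha
  best_val <- Inf
  best_state <- state
  wait <- 0
  events <- character(0)
  hist <- vector("list", config$max_epochs)

  set.seed(derive_seed(config$seed, "train"))
  for (epoch in seq_len(config$max_epochs)) {
    order_tr <- sample(tr)
    nb <- ceiling(length(order_tr) / config$batch_size)
    ep_e <- ep_man <- ep_mask <- 0
    for (bi in seq_len(nb)) {
      idx <- order_tr[((bi - 1) * config$batch_size + 1):
                        min(bi * config$batch_size, length(order_tr))]
      bp <- batch_pass(state, data, idx, config, alpha)
      if (!is.finite(bp$total))
        stop(sprintf("maskgnn: non-finite loss at epoch %d (l_e=%g, l_manifold=%g, l_mask=%g)",
                     epoch, bp$l_e, bp$l_manifold, bp$l_mask))
      upd <- adam_step(state[param_names], bp$grads, opt, lr)
      state[param_names] <- upd$params
      opt <- upd$opt
      ep_e <- ep_e + bp$l_e; ep_man <- ep_man + bp$l_manifold
      ep_mask <- bp$l_mask
    }
    ep_e <- ep_e / nb; ep_man <- ep_man / nb

    # manifold monitor: guard against oversmoothing collapse
    if (alpha > 0 && ep_man < config$manifold_floor) {
      alpha <- alpha / 2
      events <- c(events, sprintf("epoch %d: manifold loss %.3g below floor; alpha halved to %g",
                                  epoch, ep_man, alpha))
    }

    vp <- batch_pass(state, data, va, config, alpha, with_grads = FALSE)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr, alpha = alpha,
                                train_e = ep_e, train_manifold = ep_man,
                                mask_penalty = ep_mask, val_e = vp$l_e,
                                val_total = vp$total)
    if (verbose)
      message(sprintf("epoch %3d  train_e %.4f  val_e %.4f  lr %.4g",
                      epoch, ep_e, vp$l_e, lr))
    if (vp$total < best_val - 1e-12) {
      best_val <- vp$total
      best_state <- state
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience && lr > config$min_lr) {
        lr <- max(lr * config$lr_factor, config$min_lr)
        wait <- 0
        events <- c(events, sprintf("epoch %d: plateau; lr reduced to %g", epoch, lr))
      }
    }
  }

  state <- best_state
  preds <- predict_indices(state, data, te)
  metrics <- compute_metrics(preds, data$y[te, , drop = FALSE], config$task)
  structure(list(state = state, mask = mask_from_params(state$V),
                 config = config, splits = splits,
                 history = do.call(rbind, hist), metrics = metrics,
                 predictions = preds, test_ids = data$ids[te],
                 events = events, task = config$task),
            class = "maskgnn")
}

predict_indices <- function(state, data, idx) {
  out <- lapply(idx, function(s) model_forward(data$graphs[[s]], state))
  matrix(unlist(out), nrow = length(idx), ncol = state$dims$n_out,
         byrow = TRUE)
}

#' Ranking AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted half.
#'
#' @param scores Numeric ranking scores.
#' @param positive Logical vector marking positives.
#' @return AUC in [0, 1].
#' @export
ranking_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("ranking_auc: need both classes")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

compute_metrics <- function(pred, y, task) {
  if (nrow(pred) == 0) stop("evaluate: empty test set")
  if (task == "regression") {
    err <- pred - y
    rmse <- sqrt(colMeans(err^2))
    mae <- colMeans(abs(err))
    list(rmse = mean(rmse), mae = mean(mae),
         rmse_per_target = rmse, mae_per_target = mae)
  } else {
    labels <- y[, 1]
    score <- pred[, 2] - pred[, 1]      # logit margin for the high group
    cls <- ifelse(score > 0, 2L, 1L)
    acc <- mean(cls == labels)
    tp <- sum(cls == 2 & labels == 2)
    fp <- sum(cls == 2 & labels == 1)
    fn <- sum(cls == 1 & labels == 2)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    list(accuracy = acc, f1 = f1, auc = ranking_auc(score, labels == 2))
  }
}

#' Evaluate a fitted model on held-out subjects
#'
#' @param fit A `maskgnn` object.
#' @param cohort The cohort to evaluate on.
#' @param ids Subject ids (default: the fit's test split).
#' @return Regression: list with RMSE and MAE (per target and averaged).
#'   Classification: accuracy, F1 (positive = high group) and ranking AUC.
#' @export
evaluate <- function(fit, cohort, ids = NULL) {
  stopifnot(inherits(fit, "maskgnn"))
  data <- prepare_graphs(cohort, fit$config)
  if (is.null(ids)) ids <- fit$splits$test
  idx <- match(ids, data$ids)
  if (anyNA(idx)) stop("evaluate: unknown subject ids")
  if (length(idx) == 0) stop("evaluate: empty test set")
  preds <- predict_indices(fit$state, data, idx)
  compute_metrics(preds, data$y[idx, , drop = FALSE], fit$config$task)
}

#' Repeated training with re-drawn splits
#'
#' Runs `n_reps` independent repetitions, each with a freshly drawn
#' 70/10/20 split and re-seeded initialization/training, and reports each
#' metric's mean and standard deviation across repetitions. A Welch t-test
#' helper ([compare_runs()]) supports model-to-model comparisons.
#'
#' @param cohort A `maskgnn_cohort`.
#' @param config A [run_config()].
#' @param n_reps Number of repetitions (>= 2).
#' @return Object of class `metrics_report`: `per_rep` data.frame plus
#'   `mean` and `sd` named vectors.
#' @export
bootstrap_runs <- function(cohort, config, n_reps = 10) {
  if (n_reps < 2) stop("bootstrap_runs: n_reps must be >= 2")
  if (is.null(cohort$features)) cohort <- featurize_cohort(cohort)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    fit <- maskgnn(cohort, cfg)
    m <- fit$metrics
    rows[[r]] <- if (config$task == "regression")
      data.frame(rep = r, rmse = m$rmse, mae = m$mae)
    else
      data.frame(rep = r, accuracy = m$accuracy, f1 = m$f1, auc = m$auc)
  }
  per_rep <- do.call(rbind, rows)
  vals <- per_rep[, -1, drop = FALSE]
  structure(list(per_rep = per_rep,
                 mean = colMeans(vals),
                 sd = apply(vals, 2, stats::sd)),
            class = "metrics_report")
}

#' Welch t-test between two repetition reports
#'
#' @param a,b `metrics_report` objects.
#' @param metric Metric column to compare (default first shared metric).
#' @return The `htest` result of [stats::t.test()].
#' @export
compare_runs <- function(a, b, metric = NULL) {
  stopifnot(inherits(a, "metrics_report"), inherits(b, "metrics_report"))
  if (is.null(metric))
    metric <- intersect(names(a$mean), names(b$mean))[1]
  stats::t.test(a$per_rep[[metric]], b$per_rep[[metric]])
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", nrow(x$per_rep), "repetitions\n")
  for (nm in names(x$mean))
    cat(sprintf("  %-10s %.4f +/- %.4f\n", nm, x$mean[nm], x$sd[nm]))
  invisible(x)
}

#' Modality and loss-term ablation grid
#'
#' Re-trains the model over modality subsets (FC, SC, FC+SC, FC+SC+AS by
#' default) and loss-term settings (both regularizers, manifold only, mask
#' only, neither), each via [bootstrap_runs()].
#'
#' @param cohort A `maskgnn_cohort`.
#' @param config Base [run_config()].
#' @param modality_subsets List of modality vectors.
#' @param loss_settings Character subset of
#'   `c("both", "manifold_only", "mask_only", "neither")`.
#' @param n_reps Repetitions per cell.
#' @return data.frame with one row per (modality subset, loss setting):
#'   metric means and sds.
#' @export
ablate <- function(cohort, config = run_config(),
                   modality_subsets = list(c("FC"), c("SC"), c("FC", "SC"),
                                           c("FC", "SC", "AS")),
                   loss_settings = "both", n_reps = 5) {
  if (is.null(cohort$features)) cohort <- featurize_cohort(cohort)
  rows <- list()
  for (mods in modality_subsets) {
    for (ls in loss_settings) {
      cfg <- config
      cfg$modalities <- mods
      cfg$graph_from <- if ("FC" %in% mods) "FC" else "SC"
      if (ls %in% c("mask_only", "neither")) cfg$alpha <- 0
      if (ls %in% c("manifold_only", "neither")) {
        cfg$lambda1 <- 0; cfg$lambda2 <- 0; cfg$lambda3 <- 0
      }
      rep <- bootstrap_runs(cohort, cfg, n_reps = n_reps)
      row <- data.frame(modalities = paste(mods, collapse = "+"),
                        loss = ls)
      for (nm in names(rep$mean)) {
        row[[paste0(nm, "_mean")]] <- rep$mean[[nm]]
        row[[paste0(nm, "_sd")]] <- rep$sd[[nm]]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
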