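#' Hyperparameters for the haplotype convolutional imputation model
#'
#' Defaults are the package's own choices (usable on desktop CPUs); all are
#' overridable. The sub-validation fraction used for early stopping defaults
#' to 5\% of samples.
#'
#' @param conv1_filters,conv2_filters filters per convolutional layer.
#' @param kernel1,kernel2 kernel sizes.
#' @param pool max-pooling width (and stride).
#' @param shared_fc_units width of the shared fully-connected layer.
#' @param dropout_rate dropout probability on conv and FC layers.
#' @param batch_size,learning_rate,max_epochs,patience Adam/early-stop knobs.
#' @param val_fraction fraction of samples held out for early stopping.
#' @param seed master seed for splits, init, shuffling and dropout.
#' @return A \code{model_hyperparams} list.
#' @export
model_hyperparams <- function(conv1_filters = 128L, conv2_filters = 64L,
                              kernel1 = 7L, kernel2 = 5L, pool = 2L,
                              shared_fc_units = 256L, dropout_rate = 0.25,
                              batch_size = 64L, learning_rate = 1e-3,
                              max_epochs = 200L, patience = 20L,
                              val_fraction = 0.05, seed = 1L) {
  hp <- list(conv1_filters = conv1_filters, conv2_filters = conv2_filters,
             kernel1 = kernel1, kernel2 = kernel2, pool = pool,
             shared_fc_units = shared_fc_units, dropout_rate = dropout_rate,
             batch_size = batch_size, learning_rate = learning_rate,
             max_epochs = max_epochs, patience = patience,
             val_fraction = val_fraction, seed = as.integer(seed))
  stopifnot(all(unlist(hp[1:11]) > 0), dropout_rate < 1,
            val_fraction > 0, val_fraction < 0.5)
  structure(hp, class = "model_hyperparams")
}

# labels of gene g at resolution res, falling back to the coarser typing when
# the requested resolution is untyped ("set their upper resolution instead")
resolve_labels <- function(panel, gene, res) {
  for (r in seq(res, 2L, by = -2L)) {
    v <- panel$hla_labels[[gene]][[as.character(r)]]
    if (!is.null(v) && !all(v == "unknown")) return(v)
  }
  NULL
}

shared_params_init <- function(hp, W, seed) {
  P1 <- W - hp$kernel1 + 1L; Q1 <- P1 %/% hp$pool
  P2 <- Q1 - hp$kernel2 + 1L; Q2 <- P2 %/% hp$pool
  if (Q2 < 1L) stop("window of ", W, " SNVs too short for this architecture")
  list(conv1 = conv_init(2L, hp$kernel1, hp$conv1_filters,
                         sub_seed(seed, "conv1")),
       conv2 = conv_init(hp$conv1_filters, hp$kernel2, hp$conv2_filters,
                         sub_seed(seed, "conv2")),
       fc = dense_init(hp$conv2_filters * Q2, hp$shared_fc_units,
                       sub_seed(seed, "fc")))
}

# forward through the shared stack; returns h (N x U) and caches.
# `training` switches batch-norm to batch statistics; `dropout` switches the
# dropout layers on (kept separate so MC-dropout prediction can keep dropout
# active while batch-norm stays on running statistics).
shared_forward <- function(pars, X, hp, training, dropout = training) {
  idx1 <- attr(pars, "idx1"); idx2 <- attr(pars, "idx2")
  c1 <- conv_forward(pars$conv1, X, idx1, hp$kernel1)
  b1 <- bn_forward(pars$conv1, c1$y, training)
  r1 <- relu_forward(b1$y)
  o1 <- dropout_forward(r1$y, hp$dropout_rate, dropout)
  p1 <- pool_forward(o1$y, hp$pool)
  c2 <- conv_forward(pars$conv2, p1$y, idx2, hp$kernel2)
  b2 <- bn_forward(pars$conv2, c2$y, training)
  r2 <- relu_forward(b2$y)
  o2 <- dropout_forward(r2$y, hp$dropout_rate, dropout)
  p2 <- pool_forward(o2$y, hp$pool)
  d <- dim(p2$y)
  flat <- p2$y; dim(flat) <- c(d[1] * d[2], d[3]); flat <- t(flat)
  z <- sweep(flat %*% pars$fc$W, 2L, pars$fc$b, "+")
  rf <- relu_forward(z)
  of <- dropout_forward(rf$y, hp$dropout_rate, dropout)
  list(h = of$y, flat = flat, flatdim = d,
       c1 = c1, b1 = b1, r1 = r1, o1 = o1, p1 = p1,
       c2 = c2, b2 = b2, r2 = r2, o2 = o2, p2 = p2, rf = rf, of = of)
}

# backward from dh through the shared stack
shared_backward <- function(pars, hp, cache, dh, need_input_grad = FALSE) {
  idx1 <- attr(pars, "idx1"); idx2 <- attr(pars, "idx2")
  dz <- relu_backward(cache$rf, dropout_backward(cache$of, dh))
  gW_fc <- crossprod(cache$flat, dz)
  gb_fc <- colSums(dz)
  dflat <- tcrossprod(dz, pars$fc$W)
  d <- cache$flatdim
  dp2 <- t(dflat); dim(dp2) <- d
  do2 <- pool_backward(cache$p2, dp2)
  dr2 <- dropout_backward(cache$o2, do2)
  db2 <- relu_backward(cache$r2, dr2)
  bb2 <- bn_backward(cache$b2, db2)
  cc2 <- conv_backward(pars$conv2, cache$c2, bb2$dx, idx2, hp$kernel2)
  dp1 <- pool_backward(cache$p1, cc2$dx)
  dr1 <- dropout_backward(cache$o1, dp1)
  db1 <- relu_backward(cache$r1, dr1)
  bb1 <- bn_backward(cache$b1, db1)
  cc1 <- conv_backward(pars$conv1, cache$c1, bb1$dx, idx1, hp$kernel1,
                       need_dx = need_input_grad)
  list(grads = list(conv1 = list(W = cc1$dW, b = cc1$db,
                                 gamma = bb1$dgamma, beta = bb1$dbeta),
                    conv2 = list(W = cc2$dW, b = cc2$db,
                                 gamma = bb2$dgamma, beta = bb2$dbeta),
                    fc = list(W = gW_fc, b = gb_fc)),
       dX = cc1$dx)
}

#' Fit the multitask convolutional imputation model for one gene group
#'
#' Trains a shared conv/conv/FC representation over the one-hot encoded SNV
#' window with one softmax output head per HLA gene of the group. Per-task
#' categorical cross-entropy losses are balanced each step by min-norm
#' task weighting (\code{\link{mgda_ub_weights}}, gradients taken with respect
#' to the shared representation output); optimization is Adam with early
#' stopping on a sample-level sub-validation split, keeping the parameter
#' snapshot at the best sub-validation loss.
#'
#' @param panel a labeled \code{\link{phased_panel}}.
#' @param group a \code{\link{gene_group}}.
#' @param resolution 2, 4 or 6 (digit resolution of the output alleles).
#' @param hp a \code{\link{model_hyperparams}}.
#' @param init optional fitted \code{hla_cnn} whose shared-part parameters
#'   initialize this fit (hierarchical fine-tuning).
#' @return An object of class \code{hla_cnn}.
#' @export
hla_cnn <- function(panel, group, resolution = 4L, hp = model_hyperparams(),
                    init = NULL) {
  stopifnot(inherits(panel, "phased_panel"), inherits(group, "gene_group"))
  X <- encode_window(panel, group)
  variant_ids <- attr(X, "variant_ids")
  W <- dim(X)[2]; n_hap <- dim(X)[3]
  genes <- character(0); labels <- list(); levels_g <- list()
  for (g in group$genes) {
    v <- resolve_labels(panel, g, resolution)
    if (is.null(v)) { warning("gene ", g, " untyped; dropped"); next }
    keep <- !(v %in% c("unknown", "inconsistent"))
    if (!all(keep)) stop("train panel has unknown/inconsistent labels at ", g,
                         "; run exclude_inconsistent() first")
    lev <- sort(unique(v))
    if (length(lev) < 2L) {
      warning("gene ", g, " has < 2 alleles at ", resolution,
              "-digit; dropped")
      next
    }
    genes <- c(genes, g)
    levels_g[[g]] <- lev
    labels[[g]] <- match(v, lev)
  }
  if (!length(genes)) stop("no trainable genes in group '", group$name, "'")

  seed <- sub_seed(hp$seed, paste0("train_", group$name, "_", resolution))
  with_seed(seed, {
    pars <- if (!is.null(init)) {
      stopifnot(inherits(init, "hla_cnn"))
      if (!identical(init$variant_ids, variant_ids))
        stop("init model was trained on a different SNV window")
      init$params[c("conv1", "conv2", "fc")]
    } else shared_params_init(hp, W, seed)
    attr(pars, "idx1") <- im2col_idx(2L, W, hp$kernel1)
    attr(pars, "idx2") <- im2col_idx(hp$conv1_filters,
                                     (W - hp$kernel1 + 1L) %/% hp$pool,
                                     hp$kernel2)
    pars$heads <- lapply(genes, function(g)
      dense_init(hp$shared_fc_units, length(levels_g[[g]]),
                 sub_seed(seed, paste0("head_", g))))
    names(pars$heads) <- genes

    n_samp <- n_hap %/% 2L
    n_val <- max(1L, round(hp$val_fraction * n_samp))
    val_s <- sample.int(n_samp, n_val)
    val_h <- sort(c(2L * val_s - 1L, 2L * val_s))
    tr_h <- setdiff(seq_len(n_hap), val_h)
    Xval <- X[, , val_h, drop = FALSE]

    opt <- NULL; t_adam <- 0L
    best <- list(loss = Inf, pars = pars, epoch = 0L)
    log <- NULL; mgda_log <- NULL
    epochs_since <- 0L
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample(tr_h)
      nb <- ceiling(length(ord) / hp$batch_size)
      tr_loss <- 0
      for (b in seq_len(nb)) {
        rows <- ord[((b - 1L) * hp$batch_size + 1L):
                      min(b * hp$batch_size, length(ord))]
        Xb <- X[, , rows, drop = FALSE]
        fw <- shared_forward(pars, Xb, hp, training = TRUE)
        pars$conv1[c("rmean", "rvar")] <- fw$b1$layer[c("rmean", "rvar")]
        pars$conv2[c("rmean", "rvar")] <- fw$b2$layer[c("rmean", "rvar")]
        N <- length(rows)
        head_grads <- list(); Gt <- list(); loss_b <- 0
        for (g in genes) {
          lg <- labels[[g]][rows]
          logit <- sweep(fw$h %*% pars$heads[[g]]$W, 2L,
                         pars$heads[[g]]$b, "+")
          pr <- softmax(logit)
          loss_b <- loss_b + ce_loss(pr, lg)
          dlogit <- pr
          dlogit[cbind(seq_len(N), lg)] <- dlogit[cbind(seq_len(N), lg)] - 1
          dlogit <- dlogit / N
          head_grads[[g]] <- list(W = crossprod(fw$h, dlogit),
                                  b = colSums(dlogit))
          Gt[[g]] <- tcrossprod(dlogit, pars$heads[[g]]$W)
        }
        wts <- mgda_ub_weights(lapply(Gt, as.numeric))
        mgda_log <- rbind(mgda_log, wts)
        dh <- Reduce(`+`, Map(function(w, G) w * G, wts, Gt))
        bk <- shared_backward(pars, hp, fw, dh)
        grads <- bk$grads; grads$heads <- head_grads
        if (is.null(opt)) opt <- adam_like(grads)
        t_adam <- t_adam + 1L
        u <- adam_apply(pars[names(grads)], grads, opt, hp$learning_rate,
                        t_adam)
        pars[names(grads)] <- u$param; opt <- u$state
        tr_loss <- tr_loss + loss_b / length(genes)
      }
      tr_loss <- tr_loss / nb
      # sub-validation loss in inference mode
      fv <- shared_forward(pars, Xval, hp, training = FALSE)
      val_loss <- 0
      for (g in genes) {
        logit <- sweep(fv$h %*% pars$heads[[g]]$W, 2L, pars$heads[[g]]$b, "+")
        val_loss <- val_loss + ce_loss(softmax(logit), labels[[g]][val_h])
      }
      val_loss <- val_loss / length(genes)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, pars = pars, epoch = epoch)
        epochs_since <- 0L
      } else epochs_since <- epochs_since + 1L
      if (epochs_since >= hp$patience) break
    }
    pars <- best$pars
    attr(pars, "idx1") <- im2col_idx(2L, W, hp$kernel1)
    attr(pars, "idx2") <- im2col_idx(hp$conv1_filters,
                                     (W - hp$kernel1 + 1L) %/% hp$pool,
                                     hp$kernel2)
    colnames(mgda_log) <- genes
    structure(list(params = pars, group = group,
                   resolution = as.integer(resolution),
                   genes = genes, allele_levels = levels_g,
                   variant_ids = variant_ids, hp = hp,
                   log = log, mgda_log = mgda_log,
                   best_epoch = best$epoch, stopped_epoch = nrow(log),
                   best_val_loss = best$loss),
              class = "hla_cnn")
  })
}

#' @export
print.hla_cnn <- function(x, ...) {
  cat("Multitask convolutional HLA imputation model\n")
  cat("Group:", x$group$name, "(", paste(x$genes, collapse = ", "), ") at",
      x$resolution, "digit\n")
  cat("Window:", length(x$variant_ids), "SNVs; heads:",
      paste(vapply(x$allele_levels, length, 1L), collapse = "/"),
      "alleles\n")
  cat("Stopped at epoch", x$stopped_epoch, "(best sub-validation loss",
      format(x$best_val_loss, digits = 4), "at epoch", x$best_epoch, ")\n")
  invisible(x)
}

#' @export
summary.hla_cnn <- function(object, ...) {
  cat("Training log (last 5 epochs):\n")
  print(utils::tail(object$log, 5L), row.names = FALSE)
  cat("Mean MGDA-UB task weights:\n")
  print(round(colMeans(object$mgda_log), 4))
  invisible(object)
}

#' @export
plot.hla_cnn <- function(x, ...) {
  plot(x$log$epoch, x$log$train_loss, type = "l", xlab = "epoch",
       ylab = "cross-entropy loss", ylim = range(x$log[, 2:3]), ...)
  graphics::lines(x$log$epoch, x$log$val_loss, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey")
  graphics::legend("topright", c("training", "sub-validation"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

# align a target panel (or 0/1 matrix) onto the model's variant list
# -> one-hot array (2, W, H); absent variants become reference one-hot
align_target <- function(model, newdata,
                         missing_variants = c("ref_fill", "error"),
                         min_overlap = 0.5) {
  missing_variants <- match.arg(missing_variants)
  if (inherits(newdata, "phased_panel")) {
    ids <- newdata$variants$id
    hap <- newdata$haplotypes
  } else {
    hap <- as.matrix(newdata)
    ids <- colnames(hap)
  }
  m <- match(model$variant_ids, ids)
  frac <- mean(!is.na(m))
  if (frac < min_overlap)
    stop(sprintf("only %.0f%% of the model's %d window SNVs are present in ",
                 100 * frac, length(model$variant_ids)),
         "the target (threshold ", 100 * min_overlap, "%)")
  H <- nrow(hap)
  filled <- matrix(0L, H, length(model$variant_ids))
  hit <- !is.na(m)
  filled[, hit] <- hap[, m[hit], drop = FALSE]
  if (any(!hit)) {
    if (missing_variants == "error")
      stop(sum(!hit), " model variants absent from target")
    message(sum(!hit), " model variants absent from target; ",
            "filled with the reference allele")
  }
  x <- encode_haplotypes(filled, model$variant_ids)
  attr(x, "sample_ids") <- if (inherits(newdata, "phased_panel"))
    newdata$sample_ids else rownames(hap)[seq(1, H, 2)] %||%
    paste0("I", seq_len(H %/% 2L))
  x
}

#' Impute allele probabilities for target haplotypes
#'
#' Runs the fitted model in inference mode (dropout off, batch normalization
#' on running statistics) and returns per-haplotype, per-gene probability
#' vectors over the gene's alleles (each summing to 1).
#'
#' @param object fitted \code{\link{hla_cnn}}.
#' @param newdata a \code{\link{phased_panel}} (labels ignored) or 0/1
#'   haplotype matrix with variant-id column names.
#' @param missing_variants what to do with model window SNVs absent from the
#'   target: fill with the reference one-hot (logged) or error.
#' @param min_overlap minimum fraction of model SNVs that must be present.
#' @param ... unused.
#' @return An \code{allele_probs} object: list of haplotype-by-allele
#'   probability matrices, one per gene.
#' @export
predict.hla_cnn <- function(object, newdata,
                            missing_variants = c("ref_fill", "error"),
                            min_overlap = 0.5, ...) {
  X <- align_target(object, newdata, missing_variants, min_overlap)
  fw <- shared_forward(object$params, X, object$hp, training = FALSE)
  out <- lapply(object$genes, function(g) {
    logit <- sweep(fw$h %*% object$params$heads[[g]]$W, 2L,
                   object$params$heads[[g]]$b, "+")
    pr <- softmax(logit)
    colnames(pr) <- object$allele_levels[[g]]
    pr
  })
  names(out) <- object$genes
  structure(out, class = "allele_probs",
            sample_ids = attr(X, "sample_ids"))
}

#' Monte Carlo dropout sampling of best-guess genotypes
#'
#' Keeps dropout active at prediction time and performs \code{T} stochastic
#' forward passes; each pass yields a best-guess diploid genotype per gene and
#' individual. The agreement count between sampled genotypes and the
#' deterministic best guess feeds the entropy uncertainty index
#' (\code{\link{mc_entropy}}).
#'
#' @param model fitted \code{\link{hla_cnn}}.
#' @param newdata target haplotypes (see \code{\link{predict.hla_cnn}}).
#' @param T number of stochastic passes (default 200).
#' @param seed seed for the dropout masks.
#' @return List per gene with elements \code{best} (deterministic best-guess
#'   genotype strings), \code{draws} (individuals x T genotype strings) and
#'   \code{t_match} (agreement counts out of T).
#' @export
mc_dropout_sample <- function(model, newdata, T = 200L, seed = 1L) {
  if (T < 1L) stop("T must be >= 1")
  X <- align_target(model, newdata)
  n_ind <- dim(X)[3] %/% 2L
  det <- predict(model, newdata)
  geno_str <- function(pr) {
    a <- colnames(pr)[max.col(pr, ties.method = "first")]
    paste(pmin(a[c(TRUE, FALSE)], a[c(FALSE, TRUE)]),
          pmax(a[c(TRUE, FALSE)], a[c(FALSE, TRUE)]), sep = "/")
  }
  out <- lapply(model$genes, function(g) {
    best <- geno_str(det[[g]])
    list(best = best,
         draws = matrix(NA_character_, n_ind, T),
         t_match = integer(n_ind))
  })
  names(out) <- model$genes
  with_seed(sub_seed(seed, "mc_dropout"), {
    for (s in seq_len(T)) {
      # fresh dropout masks in every layer; batch-norm on running statistics
      fw <- shared_forward(model$params, X, model$hp, training = FALSE,
                           dropout = TRUE)
      for (g in model$genes) {
        logit <- sweep(fw$h %*% model$params$heads[[g]]$W, 2L,
                       model$params$heads[[g]]$b, "+")
        pr <- softmax(logit)
        colnames(pr) <- model$allele_levels[[g]]
        out[[g]]$draws[, s] <- geno_str(pr)
      }
    }
  })
  for (g in model$genes)
    out[[g]]$t_match <- rowSums(out[[g]]$draws == out[[g]]$best)
  out
}

#' @rdname mc_dropout_sample
#' @param object fitted model (generic-method alias of \code{model}).
#' @param nsim number of stochastic passes.
#' @param ... unused.
#' @export
simulate.hla_cnn <- function(object, nsim = 200L, seed = 1L, newdata, ...) {
  mc_dropout_sample(object, newdata, T = nsim, seed = seed %||% 1L)
}

#' Hierarchical fine-tuning across allele resolutions
#'
#' Trains the 2-digit model first, then initializes each finer resolution's
#' shared part from the coarser model's final shared parameters (2 to 4 to 6
#' digit). Genes untyped at a finer resolution reuse their coarser labels.
#'
#' @param panel labeled \code{\link{phased_panel}}.
#' @param group a \code{\link{gene_group}}.
#' @param hp a \code{\link{model_hyperparams}}.
#' @param resolutions which resolutions to train (default: those typed).
#' @return \code{hla_cnn_hierarchy}: named list of \code{hla_cnn} models.
#' @export
hla_cnn_hierarchy <- function(panel, group, hp = model_hyperparams(),
                              resolutions = NULL) {
  if (is.null(resolutions)) {
    resolutions <- sort(unique(as.integer(unlist(lapply(
      panel$hla_labels[group$genes], names)))))
  }
  stopifnot(length(resolutions) >= 1L)
  models <- list(); prev <- NULL
  for (r in sort(resolutions)) {
    m <- hla_cnn(panel, group, resolution = r, hp = hp, init = prev)
    models[[as.character(r)]] <- m
    prev <- m
  }
  structure(models, class = "hla_cnn_hierarchy")
}

#' @export
print.hla_cnn_hierarchy <- function(x, ...) {
  cat("Hierarchically fine-tuned models at resolutions:",
      paste(names(x), collapse = ", "), "digit\n")
  for (m in x) print(m)
  invisible(x)
}

# per-sample |dLoss/dInput| for one gene/allele in inference mode; the
# SmoothGrad building block. X is a (2, W, H) one-hot (or noised) array.
input_gradient <- function(model, X, gene, allele) {
  hp <- model$hp; pars <- model$params
  fw <- shared_forward(pars, X, hp, training = FALSE)
  k <- match(allele, model$allele_levels[[gene]])
  if (is.na(k)) stop("allele ", allele, " not in the ", gene, " head")
  logit <- sweep(fw$h %*% pars$heads[[gene]]$W, 2L, pars$heads[[gene]]$b, "+")
  pr <- softmax(logit)
  dlogit <- pr
  dlogit[, k] <- dlogit[, k] - 1       # CE gradient, per haplotype
  dh <- tcrossprod(dlogit, pars$heads[[gene]]$W)
  bk <- shared_backward(pars, hp, fw, dh, need_input_grad = TRUE)
  bk$dX
}
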