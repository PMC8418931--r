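## Feature enhancement (FS_GAN): rank ADR features by random-forest Gini
## importance, keep the top k, train a generative adversarial network on the
## selected PRR submatrix, and append one generated feature block to the
## signal matrix. Original features are never removed -- enhancement only
## widens the feature space.

#' Gini impurity of a class distribution
#'
#' `1 - sum(p^2)`, the probability that two draws from the node disagree.
#' A pure node has impurity 0; a 50/50 binary node has 0.5.
#'
#' @param p class probabilities (or non-negative counts, which are
#'   normalized).
#' @return Impurity in `[0, 1)`.
#' @export
gini_impurity <- function(p) {
  if (any(p < 0)) stop("probabilities/counts must be non-negative",
                       call. = FALSE)
  s <- sum(p)
  if (s == 0) return(0)
  p <- p / s
  1 - sum(p^2)
}

#' Rank features by accumulated Gini importance
#'
#' Fits a random forest of `n_trees` trees (bootstrap sampling,
#' `floor(sqrt(d))` candidate features per split, grown to purity) and
#' scores each feature by the total Gini impurity decrease accumulated over
#' all splits that use it, summed across trees. Tree `j` is fit with seed
#' `seed + j`, so the forest total is exactly the sum of the corresponding
#' single-tree importances. Features are ranked in descending score order;
#' ties break toward the lower feature index.
#'
#' @param x a `signal_matrix`/`enhanced_matrix`, or a numeric matrix (then
#'   supply `labels`).
#' @param labels integer class labels (ignored when `x` carries labels).
#' @param n_trees number of trees in the auxiliary forest.
#' @param seed integer; base seed for the per-tree seeds.
#' @return An object of class `importance_ranking`: a list with `ranking`
#'   (data.table of `feature_index`, `feature`, `importance`, sorted),
#'   `n_trees` and `seed`.
#' @export
rank_features <- function(x, labels = NULL, n_trees = 100L, seed = 1L) {
  if (inherits(x, c("signal_matrix", "enhanced_matrix"))) {
    labels <- x$labels
    x <- x$values
  }
  n_trees <- check_count(n_trees, "n_trees")
  if (length(unique(labels)) < 2L) {
    stop("cannot rank features: training data has a single class",
         call. = FALSE)
  }
  d <- ncol(x)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(d))
  y <- factor(labels)
  total <- numeric(d)
  for (j in seq_len(n_trees)) {
    fit <- ranger::ranger(x = df, y = y, num.trees = 1L,
                          mtry = max(1L, floor(sqrt(d))),
                          min.node.size = 1L, replace = TRUE,
                          importance = "impurity",
                          seed = seed + j, num.threads = 1L)
    total <- total + fit$variable.importance
  }
  ranking <- data.table::data.table(
    feature_index = seq_len(d),
    feature = if (is.null(colnames(x))) paste0("f", seq_len(d)) else
      colnames(x),
    importance = unname(total)
  )
  data.table::setorder(ranking, -importance, feature_index)
  structure(list(ranking = ranking, n_trees = n_trees, seed = seed),
            class = "importance_ranking")
}

#' Select the top-k features of an importance ranking
#'
#' @param ranking an [rank_features()] result.
#' @param k number of features to keep, `k <= d`.
#' @return Integer vector of the first `k` feature indices, in ranking
#'   order.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "importance_ranking"))
  k <- check_count(k, "k")
  d <- nrow(ranking$ranking)
  if (k > d) stop(sprintf("k = %d exceeds the number of features (%d)", k, d),
                  call. = FALSE)
  ranking$ranking$feature_index[seq_len(k)]
}

#' GAN training configuration
#'
#' A minimal fully-connected GAN for tabular PRR features. The generator
#' maps `noise_dim`-dimensional Gaussian noise through ReLU hidden layers to
#' a sigmoid output in per-feature min--max normalized `[0, 1]` space; the
#' discriminator mirrors it down to a single sigmoid probability. Training
#' alternates `d_steps` discriminator ascent steps with one generator step
#' per minibatch (Adam for both).
#'
#' @param noise_dim dimension of the generator's noise input.
#' @param hidden hidden-layer widths shared by generator and discriminator.
#' @param epochs number of full passes over the training rows.
#' @param batch_size minibatch size (training requires at least this many
#'   rows).
#' @param lr_g,lr_d Adam learning rates for generator/discriminator.
#' @param d_steps discriminator updates per generator update.
#' @param generator_loss `"nonsaturating"` (default; the generator maximizes
#'   `log D(G(z))`, the standard stable variant) or `"minimax"` (it
#'   minimizes `log(1 - D(G(z)))` exactly as in the two-player objective).
#' @param output_activation generator output nonlinearity.
#'   `"sparse_sigmoid"` (default) is `max(0, sigmoid(s) - tau) / (1 - tau)`:
#'   a sigmoid with a dead zone that can emit exact zeros, which PRR feature
#'   matrices are overwhelmingly made of; a plain `"sigmoid"` generator has
#'   to drive pre-activations to huge negative values to approximate zeros
#'   and in practice never matches the real data's sparsity.
#' @param sparsity_shift the dead-zone width `tau` of the sparse sigmoid.
#' @param seed integer seed; training and generation are deterministic.
#' @param zero_threshold sparsity threshold on the PRR scale used when
#'   comparing generated and real nonzero fractions.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(noise_dim = 64L, hidden = c(128L, 128L),
                       epochs = 2000L, batch_size = 64L,
                       lr_g = 2e-4, lr_d = 2e-4, d_steps = 1L,
                       generator_loss = c("nonsaturating", "minimax"),
                       output_activation = c("sparse_sigmoid", "sigmoid"),
                       sparsity_shift = 0.05,
                       seed = 1L, zero_threshold = 0.01) {
  stopifnot(lr_g > 0, lr_d > 0, zero_threshold > 0,
            sparsity_shift >= 0, sparsity_shift < 1)
  structure(list(noise_dim = check_count(noise_dim, "noise_dim"),
                 hidden = vapply(hidden, check_count, integer(1), "hidden"),
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 lr_g = lr_g, lr_d = lr_d,
                 d_steps = check_count(d_steps, "d_steps"),
                 generator_loss = match.arg(generator_loss),
                 output_activation = match.arg(output_activation),
                 sparsity_shift = sparsity_shift,
                 seed = as.integer(seed),
                 zero_threshold = zero_threshold),
            class = "gan_config")
}

## ---- small MLP machinery (base R + BLAS) ----

mlp_init <- function(sizes, out_bias = NULL) {
  L <- length(sizes) - 1L
  params <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    params[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1L]),
      b = numeric(sizes[l + 1L])
    )
  }
  if (!is.null(out_bias)) params[[L]]$b <- out_bias
  params
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## final-layer activation: plain sigmoid (tau = 0) or sparse sigmoid with a
## dead zone of width tau that maps to exact 0
final_act <- function(s, tau = 0) {
  if (tau <= 0) sigmoid(s) else pmax(sigmoid(s) - tau, 0) / (1 - tau)
}

## its derivative w.r.t. the pre-activation
final_act_grad <- function(s, tau = 0) {
  p <- sigmoid(s)
  if (tau <= 0) p * (1 - p) else (p > tau) * p * (1 - p) / (1 - tau)
}

## forward pass; hidden layers ReLU, final layer (sparse) sigmoid
mlp_forward <- function(params, X, tau = 0) {
  L <- length(params)
  S <- vector("list", L)   # pre-activations
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    S[[l]] <- sweep(A[[l]] %*% params[[l]]$W, 2L, params[[l]]$b, `+`)
    A[[l + 1L]] <- if (l < L) pmax(S[[l]], 0) else final_act(S[[l]], tau)
  }
  list(S = S, A = A)
}

## backprop from the gradient w.r.t. the final pre-activation; returns
## per-layer parameter gradients and the gradient w.r.t. the input
mlp_backward <- function(params, cache, d_out) {
  L <- length(params)
  grads <- vector("list", L)
  dS <- d_out
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$A[[l]], dS), b = colSums(dS))
    if (l > 1L) {
      dA <- tcrossprod(dS, params[[l]]$W)
      dS <- dA * (cache$S[[l - 1L]] > 0)
    } else {
      dX <- tcrossprod(dS, params[[l]]$W)
    }
  }
  list(grads = grads, dX = dX)
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(params)) {
    g <- grads[[l]]
    st <- state[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    params[[l]]$W <- params[[l]]$W - lr * (st$mW / c1) /
      (sqrt(st$vW / c2) + eps)
    params[[l]]$b <- params[[l]]$b - lr * (st$mb / c1) /
      (sqrt(st$vb / c2) + eps)
    state[[l]] <- st
  }
  list(params = params, state = state)
}

#' Train a GAN on a selected PRR submatrix
#'
#' The submatrix is min--max normalized per feature to `[0, 1]`; the
#' generator's sigmoid output lives in the same space and generated samples
#' are inverse-transformed back to the PRR scale, which also guarantees they
#' stay inside each feature's observed range. The generator's output bias is
#' initialized at the logit of the per-feature means so training starts from
#' the right marginal intensity of this very sparse data. Per minibatch the
#' discriminator takes `d_steps` ascent steps on
#' `log D(x) + log(1 - D(G(z)))`, then the generator takes one step.
#'
#' @param x numeric matrix (drugs x selected features), all finite, with at
#'   least `batch_size` rows.
#' @param config a [gan_config()].
#' @return An object of class `adr_gan`: generator and discriminator
#'   parameters, per-feature `mins`/`ranges` of the training data, the
#'   config, the feature names, and a per-epoch training `log` (mean D(x),
#'   mean D(G(z)), discriminator and generator losses).
#' @export
train_gan <- function(x, config = gan_config()) {
  stopifnot(inherits(config, "gan_config"))
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("training submatrix must be finite",
                               call. = FALSE)
  m <- nrow(x)
  if (m < config$batch_size) {
    stop(sprintf("need at least batch_size = %d rows, got %d",
                 config$batch_size, m), call. = FALSE)
  }
  k <- ncol(x)
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  ranges <- pmax(maxs - mins, .Machine$double.eps)
  xn <- sweep(sweep(x, 2L, mins), 2L, ranges, `/`)

  with_seed(config$seed, {
    tau <- if (config$output_activation == "sparse_sigmoid")
      config$sparsity_shift else 0
    ## start at the per-feature marginal means, kept above the dead zone so
    ## every output unit has gradient at initialization
    out_bias <- stats::qlogis(pmin(pmax(tau + colMeans(xn) * (1 - tau),
                                        tau + 1e-3, 1e-3), 1 - 1e-3))
    G <- mlp_init(c(config$noise_dim, config$hidden, k), out_bias = out_bias)
    D <- mlp_init(c(k, config$hidden, 1L))
    sG <- adam_init(G)
    sD <- adam_init(D)
    tG <- 0L; tD <- 0L
    trace <- vector("list", config$epochs)
    bs <- config$batch_size
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(m)
      n_batches <- m %/% bs
      ep <- c(d_real = 0, d_fake = 0, d_loss = 0, g_loss = 0)
      for (b in seq_len(n_batches)) {
        xb <- xn[perm[((b - 1L) * bs + 1L):(b * bs)], , drop = FALSE]
        ## discriminator ascent step(s)
        for (s in seq_len(config$d_steps)) {
          z <- matrix(stats::rnorm(bs * config$noise_dim), bs)
          xf <- mlp_forward(G, z, tau)$A[[length(G) + 1L]]
          xa <- rbind(xb, xf)
          yv <- c(rep(1, bs), rep(0, bs))
          fw <- mlp_forward(D, xa)
          p <- fw$A[[length(D) + 1L]]
          d_out <- (p - yv) / (2 * bs)       # d(BCE)/d(logit)
          bk <- mlp_backward(D, fw, d_out)
          tD <- tD + 1L
          upd <- adam_step(D, bk$grads, sD, config$lr_d, tD)
          D <- upd$params; sD <- upd$state
          if (s == config$d_steps) {
            eps <- 1e-12
            ep["d_real"] <- ep["d_real"] + mean(p[seq_len(bs)])
            ep["d_fake"] <- ep["d_fake"] + mean(p[bs + seq_len(bs)])
            ep["d_loss"] <- ep["d_loss"] -
              mean(yv * log(p + eps) + (1 - yv) * log(1 - p + eps))
          }
        }
        ## generator step
        z <- matrix(stats::rnorm(bs * config$noise_dim), bs)
        fwG <- mlp_forward(G, z, tau)
        xf <- fwG$A[[length(G) + 1L]]
        fwD <- mlp_forward(D, xf)
        p <- fwD$A[[length(D) + 1L]]
        if (config$generator_loss == "nonsaturating") {
          g_loss <- -mean(log(p + 1e-12))
          dD_out <- (p - 1) / bs
        } else {
          g_loss <- mean(log(1 - p + 1e-12))
          dD_out <- -p / bs
        }
        dXf <- mlp_backward(D, fwD, dD_out)$dX
        ## through the generator's output nonlinearity
        SL <- fwG$S[[length(G)]]
        dSL <- dXf * final_act_grad(SL, tau)
        bkG <- mlp_backward(G, fwG, dSL)
        tG <- tG + 1L
        upd <- adam_step(G, bkG$grads, sG, config$lr_g, tG)
        G <- upd$params; sG <- upd$state
        ep["g_loss"] <- ep["g_loss"] + g_loss
      }
      ep <- ep / n_batches
      if (!all(is.finite(ep))) {
        stop(sprintf("GAN training diverged (non-finite loss) at epoch %d",
                     epoch), call. = FALSE)
      }
      trace[[epoch]] <- data.table::data.table(
        epoch = epoch, d_real = ep[["d_real"]], d_fake = ep[["d_fake"]],
        d_loss = ep[["d_loss"]], g_loss = ep[["g_loss"]])
    }
    structure(list(generator = G, discriminator = D,
                   mins = mins, ranges = ranges,
                   feature_names = colnames(x),
                   config = config, log = data.table::rbindlist(trace)),
              class = "adr_gan")
  })
}

#' Generate artificial feature rows from a trained GAN
#'
#' Draws `n_rows` seeded noise vectors, maps them through the generator and
#' inverse-min--max-transforms the output to the PRR scale, so every
#' generated value lies within the per-feature range of the training data.
#' Row `i` of the block is appended to drug row `i` (fixed drug order); the
#' generated columns carry no per-drug meaning beyond sharing the training
#' distribution.
#'
#' @param gan a trained [train_gan()] model.
#' @param n_rows number of rows to generate.
#' @param seed integer seed for the noise draws.
#' @return `n_rows x k` numeric matrix, columns named `gen_<feature>`.
#' @export
generate_features <- function(gan, n_rows, seed = 1L) {
  stopifnot(inherits(gan, "adr_gan"))
  n_rows <- check_count(n_rows, "n_rows")
  with_seed(seed, {
    tau <- if (gan$config$output_activation == "sparse_sigmoid")
      gan$config$sparsity_shift else 0
    z <- matrix(stats::rnorm(n_rows * gan$config$noise_dim), n_rows)
    yn <- mlp_forward(gan$generator, z, tau)$A[[length(gan$generator) + 1L]]
    y <- sweep(sweep(yn, 2L, gan$ranges, `*`), 2L, gan$mins, `+`)
    colnames(y) <- paste0("gen_", if (is.null(gan$feature_names))
      seq_len(ncol(y)) else gan$feature_names)
    y
  })
}

#' Discriminator probabilities for a set of rows (PRR scale)
#'
#' @param gan a trained [train_gan()] model.
#' @param x matrix on the PRR scale with the GAN's feature columns.
#' @return Vector of probabilities in `(0, 1)` that each row is real.
#' @export
discriminate <- function(gan, x) {
  stopifnot(inherits(gan, "adr_gan"))
  xn <- sweep(sweep(as.matrix(x), 2L, gan$mins), 2L, gan$ranges, `/`)
  as.vector(mlp_forward(gan$discriminator, xn)$A[[length(gan$discriminator) + 1L]])
}

#' Append a generated feature block to a signal matrix
#'
#' Column-wise concatenation: all original features are retained, labels are
#' unchanged, and per-column provenance flags record which columns are real
#' and which are generated.
#'
#' @param matrix a `signal_matrix` (or `enhanced_matrix`).
#' @param block numeric matrix with one row per drug row of `matrix`; may
#'   have zero columns (identity).
#' @return An object of class `enhanced_matrix` with fields `drugs`,
#'   `adr_terms` (now including generated column names), `values`, `labels`
#'   and `provenance` (`"real"`/`"generated"` per column).
#' @export
append_features <- function(matrix, block) {
  stopifnot(inherits(matrix, c("signal_matrix", "enhanced_matrix")))
  block <- as.matrix(block)
  if (ncol(block) > 0L && nrow(block) != nrow(matrix$values)) {
    stop(sprintf("row mismatch: matrix has %d rows, generated block has %d",
                 nrow(matrix$values), nrow(block)), call. = FALSE)
  }
  prov <- matrix$provenance
  if (is.null(prov)) prov <- rep("real", ncol(matrix$values))
  values <- if (ncol(block) > 0L) cbind(matrix$values, block) else
    matrix$values
  structure(list(drugs = matrix$drugs,
                 adr_terms = colnames(values),
                 values = values,
                 labels = matrix$labels,
                 provenance = c(prov, rep("generated", ncol(block)))),
            class = "enhanced_matrix")
}

#' Run the full feature-enhancement stage on a signal matrix
#'
#' Ranks features with an auxiliary forest fit on the (imbalanced) signal
#' matrix, selects the top `k`, trains the GAN on the selected submatrix and
#' appends one generated row per drug.
#'
#' @param matrix a labeled `signal_matrix`.
#' @param top_k number of features to select (and hence generated columns).
#' @param config a [gan_config()].
#' @param n_trees trees for the importance ranking.
#' @param seed base seed for ranking and generation (GAN training uses
#'   `config$seed`).
#' @return A list with the `enhanced` matrix, the `ranking`, `selected`
#'   feature indices, the trained `gan` and the generated `block`.
#' @export
enhance_signal_matrix <- function(matrix, top_k = 200L,
                                  config = gan_config(),
                                  n_trees = 100L, seed = 1L) {
  ranking <- rank_features(matrix, n_trees = n_trees, seed = seed)
  selected <- select_top_k(ranking, top_k)
  sub <- matrix$values[, selected, drop = FALSE]
  gan <- train_gan(sub, config)
  block <- generate_features(gan, nrow(matrix$values), seed = seed + 1L)
  list(enhanced = append_features(matrix, block),
       ranking = ranking, selected = selected, gan = gan, block = block)
}

#' @rdname append_features
#' @param x an `enhanced_matrix`.
#' @param path output CSV path; a `provenance` header row follows the
#'   column names, then one row per drug with the final `label` column.
#' @export
write_enhanced_matrix <- function(x, path) {
  header <- paste(c("drug_name", x$adr_terms, "label"), collapse = ",")
  prov <- paste(c("provenance", x$provenance, "label"), collapse = ",")
  body <- data.table::as.data.table(x$values)
  body <- cbind(data.table::data.table(drug_name = x$drugs), body,
                data.table::data.table(label = x$labels))
  writeLines(c(header, prov), path)
  data.table::fwrite(body, path, append = TRUE, col.names = FALSE)
  invisible(path)
}
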