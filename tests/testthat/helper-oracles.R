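# Independent oracles and fixture builders. These deliberately share no
# code with the package implementations they cross-check.

# projected-gradient solver for 0.5*||s - X c||^2 + lambda*||c||_1,
# c >= 0, vectorized over the columns of S; slow but simple
pg_lasso_oracle <- function(S, X, lambda, iters = 20000L) {
  G <- crossprod(X)
  B <- crossprod(X, S)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  eta <- 1 / L
  C <- matrix(0, ncol(X), ncol(S))
  for (i in seq_len(iters)) {
    C <- C - eta * (G %*% C - B + lambda)
    C[C < 0] <- 0
  }
  C
}

lasso_objective <- function(S, X, C, lambda) {
  C <- as.matrix(C)
  0.5 * colSums((S - X %*% C)^2) + lambda * colSums(abs(C))
}

# minimal NIPALS PLS2-DA: one-hot Y, centered; X assumed pre-scaled.
# Returns training-set predicted dummy Y (class means added back).
pls2da_oracle_predict <- function(X, labels, A) {
  classes <- sort(unique(labels))
  Y <- outer(labels, classes, "==") * 1
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  Xd <- X; Yd <- Yc
  Yhat <- matrix(rep(ym, each = nrow(X)), nrow(X))
  for (a in seq_len(A)) {
    u <- Yd[, which.max(apply(Yd, 2, var))]
    repeat {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      t_ <- Xd %*% w
      c_ <- crossprod(Yd, t_) / sum(t_^2)
      u_new <- Yd %*% c_ / sum(c_^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-12 * max(1, sqrt(sum(u_new^2)))) {
        u <- u_new; break
      }
      u <- u_new
    }
    p_ <- crossprod(Xd, t_) / sum(t_^2)
    Yhat <- Yhat + tcrossprod(as.numeric(t_), as.numeric(c_))
    Xd <- Xd - tcrossprod(as.numeric(t_), as.numeric(p_))
    Yd <- Yd - tcrossprod(as.numeric(t_), as.numeric(c_))
  }
  colnames(Yhat) <- classes
  Yhat
}

# Gaussian class fixture: K classes, p features, class means `sep`
# (in s.d. units) apart along the first min(K-1, p) feature axes
make_sep_features <- function(K, n_per_class, sep, p = 5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(K * n_per_class * p), K * n_per_class, p)
    labels <- rep(paste0("class", seq_len(K)), each = n_per_class)
    for (k in seq_len(K)) {
      ax <- ((k - 1) %% p) + 1
      rows <- labels == paste0("class", k)
      X[rows, ax] <- X[rows, ax] + k * sep
    }
    list(X = X, labels = labels)
  })
}

# small spectral axis keeps unmixing fixtures fast
small_library <- function(n_channels = 51L) {
  synthetic_library(spectral_axis(2800, 3050, n_channels))
}

# render a tiny one-class field entirely in memory
tiny_field <- function(lib, class_label = "AML-M3", n_cells = 3,
                       size = 96L, noise_sigma = 0, background = 0,
                       intensity_cv = 0, seed = 1) {
  prof <- default_class_profiles()
  prof <- prof[prof$class_label == class_label, ]
  cfg <- cohort_config(classes = prof, cells_per_class = n_cells,
                       image_size = c(size, size),
                       noise_sigma = noise_sigma,
                       background_level = background,
                       intensity_cv = intensity_cv, seed = seed)
  cells <- sample_cells(prof, n_cells, seed = seed,
                        intensity_cv = intensity_cv)
  render_field(cells, lib, cfg, seed = seed + 1L)
}
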