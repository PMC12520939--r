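#' Autoscale a feature matrix
#'
#' Column-wise mean-centering and unit-variance scaling (sample s.d.,
#' n-1 denominator), the conventional preprocessing for multivariate
#' projection models on features of mixed units. Constant columns are
#' centered and their s.d. recorded as 1, so they become zero columns.
#'
#' @param raw n x p numeric matrix, n >= 2.
#' @return A \code{scaled_matrix}: list with \code{X} (scaled),
#'   \code{means}, \code{sds}, \code{scaling = "uv"}.
#' @export
autoscale <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L)
    stop("autoscale needs at least 2 rows", call. = FALSE)
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("feature matrix must be finite numeric", call. = FALSE)
  means <- colMeans(raw)
  sds <- apply(raw, 2, stats::sd)
  sds[sds == 0] <- 1
  X <- sweep(sweep(raw, 2, means), 2, sds, "/")
  structure(list(X = X, means = means, sds = sds, scaling = "uv"),
            class = "scaled_matrix")
}

#' Apply a stored scaler to new data
#'
#' @param scaler A \code{scaled_matrix} (its \code{means}/\code{sds})
#'   or a list with \code{means} and \code{sds}.
#' @param raw New n x p matrix with matching columns.
#' @return Scaled matrix.
#' @export
apply_scaler <- function(scaler, raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != length(scaler$means))
    stop("column count does not match scaler", call. = FALSE)
  sweep(sweep(raw, 2, scaler$means), 2, scaler$sds, "/")
}

one_hot <- function(labels, class_labels) {
  Y <- matrix(0, length(labels), length(class_labels),
              dimnames = list(NULL, class_labels))
  Y[cbind(seq_along(labels), match(labels, class_labels))] <- 1
  Y
}

fix_sign <- function(w) if (w[which.max(abs(w))] < 0) -w else w

# first PLS2 component weight by NIPALS on (X, Y); deterministic init
# from the Y column with largest variance
nipals_component <- function(X, Y, tol = 1e-10, max_iter = 500L) {
  u <- Y[, which.max(apply(Y, 2, stats::var))]
  w <- NULL
  for (i in seq_len(max_iter)) {
    w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
    t <- X %*% w
    c_ <- crossprod(Y, t) / sum(t^2)
    u_new <- Y %*% c_ / sum(c_^2)
    if (sqrt(sum((u_new - u)^2)) / max(sqrt(sum(u_new^2)), 1e-300) < tol) {
      u <- u_new; break
    }
    u <- u_new
  }
  s <- if (w[which.max(abs(w))] < 0) -1 else 1
  w <- s * w
  t <- X %*% w
  c_ <- crossprod(Y, t) / sum(t^2)
  list(w = as.numeric(w), t = as.numeric(t), c = as.numeric(c_))
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis,
#' implemented from first principles for a multi-class one-hot dummy
#' response. For each of \code{A_ortho} rounds, the first PLS2 weight
#' and its X-loading are computed on the current (deflated) X; the
#' loading is orthogonalized against the span of \code{X'Y} — which
#' guarantees the resulting orthogonal scores are exactly uncorrelated
#' with every dummy-Y column — normalized, and the corresponding
#' component removed from X. \code{A_pred} predictive PLS2 components
#' are then fitted on the filtered X by NIPALS (deflating X and Y).
#' With \code{A_ortho = 0} the model is exactly a PLS2-DA.
#'
#' @param X_scaled A \code{scaled_matrix} from \code{\link{autoscale}}
#'   (or a plain pre-scaled matrix, in which case an identity scaler is
#'   stored).
#' @param labels Class label per row; every class needs >= 2 samples.
#' @param A_pred Number of predictive components, 1 <= A_pred <=
#'   min(K-1, p); default min(K-1, p - A_ortho), enough to resolve all
#'   K classes when the features allow it.
#' @param A_ortho Number of orthogonal components, >= 0. Orthogonal
#'   filtering requires feature directions outside the span of
#'   \code{X'Y}; when K - 1 >= p no such direction exists and
#'   \code{A_ortho} must be 0 (a rank-error otherwise).
#' @return An \code{oplsda_model} with weights/loadings/scores
#'   (\code{W_pred}, \code{P_pred}, \code{C}, \code{W_ortho},
#'   \code{P_ortho}, \code{T_pred}, \code{T_ortho}), the scaler, class
#'   labels and dummy-Y column means.
#' @export
fit_oplsda <- function(X_scaled, labels, A_pred = NULL, A_ortho = 1L) {
  if (inherits(X_scaled, "scaled_matrix")) {
    X <- X_scaled$X
    scaler <- list(means = X_scaled$means, sds = X_scaled$sds)
  } else {
    X <- as.matrix(X_scaled)
    scaler <- list(means = rep(0, ncol(X)), sds = rep(1, ncol(X)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("labels length must equal rows of X", call. = FALSE)
  class_labels <- sort(unique(labels))
  K <- length(class_labels); p <- ncol(X); n <- nrow(X)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 samples", call. = FALSE)
  A_ortho <- as.integer(A_ortho)
  # default: as many predictive components as the dummy response can
  # support within the feature rank left after orthogonal filtering
  if (is.null(A_pred)) A_pred <- max(1L, min(K - 1L, p - A_ortho))
  A_pred <- as.integer(A_pred)
  if (A_pred < 1L || A_pred > min(K - 1L, p))
    stop("rank-error: A_pred must lie in [1, min(K-1, p)]", call. = FALSE)
  if (A_ortho < 0L || A_pred + A_ortho > p)
    stop("rank-error: A_pred + A_ortho exceeds feature rank",
         call. = FALSE)
  Y <- one_hot(labels, class_labels)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)

  W_o <- P_o <- matrix(0, p, 0); T_o <- matrix(0, n, 0)
  Xf <- X
  for (j in seq_len(A_ortho)) {
    comp <- nipals_component(Xf, Yc)
    p_load <- as.numeric(crossprod(Xf, comp$t) / sum(comp$t^2))
    XtY <- crossprod(Xf, Yc)
    qrd <- qr(XtY)
    Q <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
    w_o <- p_load - Q %*% crossprod(Q, p_load)
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12)
      stop("rank-error: no Y-orthogonal variation left for component ",
           j, call. = FALSE)
    w_o <- fix_sign(as.numeric(w_o / nrm))
    t_o <- as.numeric(Xf %*% w_o)
    p_o <- as.numeric(crossprod(Xf, t_o) / sum(t_o^2))
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }

  W <- P <- matrix(0, p, 0); Cm <- matrix(0, K, 0)
  T_p <- matrix(0, n, 0)
  Xd <- Xf; Yd <- Yc
  for (a in seq_len(A_pred)) {
    comp <- nipals_component(Xd, Yd)
    p_load <- as.numeric(crossprod(Xd, comp$t) / sum(comp$t^2))
    Xd <- Xd - tcrossprod(comp$t, p_load)
    Yd <- Yd - tcrossprod(comp$t, comp$c)
    W <- cbind(W, comp$w); P <- cbind(P, p_load)
    Cm <- cbind(Cm, comp$c); T_p <- cbind(T_p, comp$t)
  }

  structure(list(class_labels = class_labels, scaler = scaler,
                 feature_names = colnames(X),
                 A_pred = A_pred, A_ortho = A_ortho,
                 W_pred = W, P_pred = P, C = Cm,
                 W_ortho = W_o, P_ortho = P_o,
                 T_pred = T_p, T_ortho = T_o,
                 y_means = y_means, X_filtered = Xf),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    "oplsda_model: %d classes, %d features, A_pred = %d, A_ortho = %d\n",
    length(x$class_labels), length(x$scaler$means), x$A_pred, x$A_ortho))
  invisible(x)
}

#' Predict classes with a fitted OPLS-DA model
#'
#' Applies the stored scaler, removes the orthogonal components
#' sequentially with the model's weights/loadings, projects onto the
#' predictive components (using \eqn{R = W (P'W)^{-1}}), and predicts
#' \eqn{\hat Y = T C' + \bar y}. The label is the argmax dummy column;
#' ties resolve to the lowest class index.
#'
#' @param model An \code{oplsda_model}.
#' @param X_new Raw feature matrix with the model's p columns.
#' @return list with \code{predicted_label}, \code{predicted_Y}
#'   (n x K), \code{scores_pred} (n x A), \code{scores_ortho}
#'   (n x A_ortho).
#' @export
predict_oplsda <- function(model, X_new) {
  X <- apply_scaler(model$scaler, X_new)
  T_o <- matrix(0, nrow(X), 0)
  for (j in seq_len(model$A_ortho)) {
    t_o <- X %*% model$W_ortho[, j]
    X <- X - tcrossprod(as.numeric(t_o), model$P_ortho[, j])
    T_o <- cbind(T_o, as.numeric(t_o))
  }
  R <- model$W_pred %*% solve(crossprod(model$P_pred, model$W_pred))
  T_p <- X %*% R
  Yhat <- T_p %*% t(model$C)
  Yhat <- sweep(Yhat, 2, model$y_means, "+")
  colnames(Yhat) <- model$class_labels
  lab <- model$class_labels[max.col(Yhat, ties.method = "first")]
  list(predicted_label = lab, predicted_Y = Yhat,
       scores_pred = T_p, scores_ortho = T_o)
}

#' Score coordinates for the 2-D scores plot
#'
#' Returns the per-sample coordinates of the standard OPLS-DA scatter:
#' the first two predictive scores when \code{A_pred >= 2}; with a
#' single predictive component the second coordinate falls back to the
#' first orthogonal score (the usual t1 vs t_o1 display).
#'
#' @param model A fitted \code{oplsda_model}.
#' @param labels Optional class label per training sample to attach.
#' @return data.frame with \code{score1}, \code{score2}, \code{class}.
#' @export
scores_plot_data <- function(model, labels = NULL) {
  s1 <- model$T_pred[, 1]
  s2 <- if (model$A_pred >= 2L) {
    model$T_pred[, 2]
  } else if (model$A_ortho >= 1L) {
    model$T_ortho[, 1]
  } else {
    stop("need A_pred >= 2 or A_ortho >= 1 for a 2-D scores plot",
         call. = FALSE)
  }
  data.frame(score1 = s1, score2 = s2,
             class = if (is.null(labels)) NA_character_
                     else as.character(labels),
             stringsAsFactors = FALSE)
}

#' Save / load an OPLS-DA model as JSON
#'
#' All matrices, the scaler, labels and hyperparameters are serialized;
#' training scores are included so scores plots can be re-drawn.
#'
#' @param model An \code{oplsda_model}.
#' @param path JSON path.
#' @return \code{path} (write) or the model (read).
#' @export
write_oplsda_json <- function(model, path) {
  out <- model[c("class_labels", "scaler", "feature_names", "A_pred",
                 "A_ortho", "W_pred", "P_pred", "C", "W_ortho",
                 "P_ortho", "T_pred", "T_ortho", "y_means")]
  out$format_version <- "1.0"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_oplsda_json
#' @export
read_oplsda_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("W_pred", "P_pred", "C", "W_ortho", "P_ortho", "T_pred",
              "T_ortho"))
    m[[f]] <- if (length(m[[f]]) == 0) matrix(0, 0, 0) else as.matrix(m[[f]])
  m$scaler <- list(means = as.numeric(m$scaler$means),
                   sds = as.numeric(m$scaler$sds))
  m$format_version <- NULL
  structure(m, class = "oplsda_model")
}
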