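#' Random hidden basis for an extreme learning machine
#'
#' An ELM is a single-hidden-layer network whose hidden weights are never
#' trained: each hidden node `i` has a random weight vector `a_i` and bias
#' `b_i`, drawn here i.i.d. uniform on `[-1, 1]` — bounded, standard in the
#' ELM literature, and well matched to `[0, 1]`-normalized inputs. A basis
#' can be generated once and reused across trainings as long as the input
#' dimension and node count are unchanged.
#'
#' @param L number of hidden nodes (default 200).
#' @param d input dimension (default 8, one per strap channel).
#' @param seed integer seed; the same seed reproduces the basis exactly.
#' @return an object of class `hidden_basis`: list with `A` (L x d), `b`
#'   (length L), `L`, `d`, `seed`.
#' @export
random_basis <- function(L = 200, d = 8, seed = 1L) {
  stop_if_not(is_count(L), "L must be a positive integer")
  stop_if_not(is_count(d), "d must be a positive integer")
  with_seed(seed, {
    A <- matrix(runif(L * d, -1, 1), nrow = L, ncol = d)
    b <- runif(L, -1, 1)
    structure(list(A = A, b = b, L = as.integer(L), d = as.integer(d),
                   seed = as.integer(seed)),
              class = "hidden_basis")
  })
}

#' Sigmoid hidden-layer map
#'
#' Maps input vectors into the L-dimensional hidden space: component `i` is
#' `1 / (1 + exp(-(a_i . x + b_i)))`. All outputs lie strictly in (0, 1)
#' for finite inputs.
#'
#' @param x length-`d` feature vector or (n x d) matrix of features.
#' @param basis a [random_basis()].
#' @return length-`L` vector, or (n x L) matrix for matrix input.
#' @export
hidden_map <- function(x, basis) {
  stopifnot(inherits(basis, "hidden_basis"))
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = length(x)) else as.matrix(x)
  stop_if_not(ncol(xm) == basis$d,
              "input has %d features but the basis expects %d",
              ncol(xm), basis$d)
  z <- xm %*% t(basis$A)
  z <- sweep(z, 2, basis$b, "+")
  h <- 1 / (1 + exp(-z))
  if (vec) drop(h) else h
}

#' Train an ELM by closed-form regularized least squares
#'
#' Only the output weights `beta` (L x K) are learned. With hidden-layer
#' matrix `H` (N x L) and 1-of-K target matrix `T`, `beta` solves the ridge
#' problem `min ||H beta - T||^2 + ||beta||^2 / C`; `C` is an inverse
#' penalty, so larger `C` means weaker regularization. Two algebraically
#' equivalent closed forms exist:
#'
#' * dual, inverting an N x N system: `beta = H' (I/C + H H')^{-1} T`;
#' * primal, inverting an L x L system: `beta = (I/C + H' H)^{-1} H' T`.
#'
#' The cheaper one is solved (dual when `N <= L`, primal otherwise); the
#' two agree to numerical precision. Training is a single linear solve —
#' fast enough to retrain every time the strap is put on.
#'
#' @param x normalized training features (N x d).
#' @param y training class labels (length N).
#' @param basis a [random_basis()] with `d` matching `x`.
#' @param C regularization parameter, > 0 (default `2^7`).
#' @param class_labels ordered label set defining the output columns;
#'   defaults to `sort(unique(y))`. Prediction ties break toward the
#'   earliest label in this order.
#' @param norm optional [fit_normalization()] parameters to store with the
#'   model for test-time use.
#' @return an object of class `elm_model`: list with `basis`, `beta`
#'   (L x K), `C`, `class_labels`, `norm`.
#' @export
elm_train <- function(x, y, basis, C = 2^7, class_labels = NULL, norm = NULL) {
  stopifnot(inherits(basis, "hidden_basis"))
  xm <- as.matrix(x)
  stop_if_not(is_number(C) && C > 0, "C must be a positive number")
  stop_if_not(nrow(xm) == length(y),
              "features and labels disagree: %d rows vs %d labels",
              nrow(xm), length(y))
  if (is.null(class_labels)) class_labels <- sort(unique(y))
  stop_if_not(all(y %in% class_labels),
              "labels outside the declared class set")
  K <- length(class_labels)
  N <- nrow(xm)
  stop_if_not(K >= 2, "need at least 2 classes")
  stop_if_not(N >= K, "need at least as many samples as classes")

  Tm <- one_of_k(y, class_labels)
  H <- hidden_map(xm, basis)
  beta <- ridge_solve(H, Tm, C)
  colnames(beta) <- as.character(class_labels)
  structure(list(basis = basis, beta = beta, C = C,
                 class_labels = class_labels, norm = norm),
            class = "elm_model")
}

#' Closed-form ridge solution for the ELM output weights
#'
#' Solves `min ||H beta - T||^2 + ||beta||^2 / C` in whichever of the two
#' equivalent closed forms is cheaper: the dual `H' (I/C + H H')^{-1} T`
#' when the N x N system is smaller (`N <= L`), the primal
#' `(I/C + H' H)^{-1} H' T` otherwise. For finite `C > 0` both systems are
#' symmetric positive definite, so the solve cannot be singular.
#'
#' @param H hidden-layer output matrix (N x L).
#' @param Tm target matrix (N x K).
#' @param C inverse regularization strength, > 0.
#' @param form `"auto"` (default), or force `"dual"` / `"primal"`.
#' @return L x K weight matrix.
#' @export
ridge_solve <- function(H, Tm, C, form = c("auto", "dual", "primal")) {
  form <- match.arg(form)
  H <- as.matrix(H)
  Tm <- as.matrix(Tm)
  stop_if_not(nrow(H) == nrow(Tm), "H and T must have matching rows")
  stop_if_not(is_number(C) && C > 0, "C must be a positive number")
  N <- nrow(H)
  L <- ncol(H)
  if (form == "auto") form <- if (N <= L) "dual" else "primal"
  if (form == "dual") {
    t(H) %*% solve(diag(N) / C + tcrossprod(H), Tm)
  } else {
    solve(diag(L) / C + crossprod(H), crossprod(H, Tm))
  }
}

#' 1-of-K target encoding
#' @param y labels.
#' @param class_labels ordered label set.
#' @return N x K indicator matrix: one 1 per row, in the target's column.
#' @keywords internal
one_of_k <- function(y, class_labels) {
  Tm <- matrix(0, length(y), length(class_labels))
  Tm[cbind(seq_along(y), match(y, class_labels))] <- 1
  Tm
}

#' Predict classes with a trained ELM
#'
#' Scores are `h(x) beta`; the predicted class is the output column with
#' the highest score, ties broken toward the earliest label in
#' `class_labels`.
#'
#' @param object an [elm_train()] model.
#' @param x feature vector or matrix, already on the model's normalized
#'   scale (use [apply_normalization()] with `object$norm`).
#' @param type `"class"` (default) for labels, `"score"` for the raw
#'   K-column score matrix, `"both"` for a list of the two.
#' @param ... unused.
#' @return labels, scores, or both.
#' @export
predict.elm_model <- function(object, x, type = c("class", "score", "both"),
                              ...) {
  type <- match.arg(type)
  H <- hidden_map(x, object$basis)
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  scores <- H %*% object$beta
  labels <- object$class_labels[apply(scores, 1, which.max)]
  switch(type,
         class = labels,
         score = scores,
         both = list(class = labels, score = scores))
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> L = %d hidden nodes, C = %g, %d classes (%s), d = %d\n",
              x$basis$L, x$C, length(x$class_labels),
              paste(x$class_labels, collapse = " "), x$basis$d))
  invisible(x)
}

#' Save / load an ELM model
#'
#' The whole model — hidden basis `A`, `b`, output weights `beta`, `C`,
#' class labels, normalization parameters and the basis seed — round-trips
#' through a single JSON file at full double precision.
#'
#' @param model an `elm_model`.
#' @param path file path (conventionally `.json`).
#' @return `write_elm_model` returns `path` invisibly; `read_elm_model`
#'   returns the restored `elm_model`.
#' @export
write_elm_model <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  payload <- list(
    format = "fmgposture-elm-model",
    version = 1L,
    L = model$basis$L, d = model$basis$d, seed = model$basis$seed,
    C = model$C,
    class_labels = model$class_labels,
    A = model$basis$A, b = model$basis$b,
    beta = unname(model$beta),
    norm = if (!is.null(model$norm))
      list(min = model$norm$min, max = model$norm$max,
           degenerate = model$norm$degenerate)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_elm_model
#' @export
read_elm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if_not(identical(p$format, "fmgposture-elm-model"),
              "%s is not an fmgposture model file", path)
  basis <- structure(list(A = matrix(p$A, nrow = p$L, ncol = p$d),
                          b = as.numeric(p$b),
                          L = as.integer(p$L), d = as.integer(p$d),
                          seed = as.integer(p$seed)),
                     class = "hidden_basis")
  norm <- if (!is.null(p$norm))
    structure(list(min = as.numeric(p$norm$min),
                   max = as.numeric(p$norm$max),
                   degenerate = as.logical(p$norm$degenerate)),
              class = "norm_params")
  beta <- matrix(p$beta, nrow = p$L)
  colnames(beta) <- as.character(p$class_labels)
  structure(list(basis = basis, beta = beta, C = p$C,
                 class_labels = p$class_labels, norm = norm),
            class = "elm_model")
}
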