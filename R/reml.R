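#' Restricted maximum likelihood with the direct Average Information
#' algorithm
#'
#' Fits the variance components of the mixed model
#' `y = X b + g + e`, `g ~ N(0, K sigma_g^2)`, `e ~ N(0, I sigma_e^2)`
#' where K is any relationship matrix (pedigree A, genomic G, or
#' single-step H) over the phenotyped individuals. Estimation maximizes
#' the restricted likelihood with Average Information (quasi-Newton)
#' updates on the variance scale, falling back to an EM step whenever an
#' AI step proposes a negative component, with step halving if a proposal
#' would decrease the log-likelihood or make the phenotypic covariance
#' indefinite.
#'
#' The solver works in the eigenbasis of K: after one symmetric
#' eigendecomposition each iteration costs O(n), and K may be indefinite
#' (as arises for unblended genomic matrices) as long as
#' `K sigma_g^2 + I sigma_e^2` stays positive definite along the path —
#' this is the "direct" AI-REML property that makes blending optional.
#'
#' @param y numeric phenotype vector; NA entries are dropped (together
#'   with the matching rows of `X` and row/columns of `K`).
#' @param K relationship matrix with id dimnames matching `names(y)` (or
#'   taken positionally when unnamed), or a precomputed [reml_eigen]
#'   object.
#' @param X fixed-effect design matrix; default intercept only.
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param max_iter maximum iterations (default 100); `max_iter = 0`
#'   evaluates the model at `start` without updating (useful for BLUP at
#'   fixed variances).
#' @param start optional starting values `c(sigma_g2, sigma_e2)`; default
#'   splits var(y) equally.
#' @param verbose print the log-likelihood trajectory.
#' @return object of class `hblup_fit`: list with `sigma_g2`, `sigma_e2`,
#'   `h2`, `logL`, `AIC`, `n_params`, `fixed_effects`, `blup` (genetic
#'   values of the phenotyped individuals), `Py` (projected residuals,
#'   used for prediction), `ids`, `converged`, `n_iter`, `boundary`,
#'   `trajectory`.
#' @seealso [predict_blup], [aic]
#' @export
fit_hreml <- function(y, K, X = NULL, tol = 1e-6, max_iter = 100L,
                      start = NULL, verbose = FALSE) {
  ids <- names(y)
  if (inherits(K, "reml_eigen")) {
    eig <- K
    if (is.null(ids)) ids <- eig$ids
    if (!identical(ids, eig$ids))
      stop("phenotype ids do not match the eigendecomposition ids")
    if (anyNA(y)) stop("precomputed eigendecomposition requires complete y")
  } else {
    if (is.null(ids)) {
      if (length(y) != nrow(K)) stop("length(y) != nrow(K)")
      ids <- rownames(K)
      if (is.null(ids)) ids <- as.character(seq_along(y))
    }
    keep <- !is.na(y)
    if (!any(keep)) stop("no non-missing phenotypes")
    y <- y[keep]; ids <- ids[keep]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    Ksub <- if (!is.null(rownames(K))) unclass(K)[ids, ids, drop = FALSE]
            else unclass(K)[keep, keep, drop = FALSE]
    eig <- reml_eigen(Ksub, ids)
  }
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  p <- ncol(X)
  lam <- eig$values
  ys <- drop(crossprod(eig$vectors, y))
  Xs <- crossprod(eig$vectors, X)

  vy <- stats::var(y)
  floor_val <- 1e-8 * vy
  theta <- if (is.null(start)) c(vy / 2, vy / 2) else as.numeric(start)
  names(theta) <- c("sigma_g2", "sigma_e2")

  # restricted log-likelihood and derived quantities at (sg, se)
  eval_point <- function(theta) {
    v <- theta[1L] * lam + theta[2L]
    if (any(v <= 0)) return(NULL)
    wy <- ys / v
    Xv <- Xs / v
    T_ <- crossprod(Xs, Xv)
    cf <- tryCatch(chol(T_), error = function(e) NULL)
    if (is.null(cf)) return(NULL)
    b <- backsolve(cf, backsolve(cf, crossprod(Xs, wy), transpose = TRUE))
    r <- ys - Xs %*% b
    Py <- drop(r) / v
    ll <- -0.5 * ((n - p) * log(2 * pi) + sum(log(v)) +
                  2 * sum(log(diag(cf))) + sum(drop(r) * Py))
    list(ll = ll, v = v, Py = Py, b = drop(b), cf = cf, Xv = Xv)
  }

  # P %*% s in the rotated basis
  Pdot <- function(s, st) {
    ws <- s / st$v
    ws - st$Xv %*% backsolve(st$cf, backsolve(st$cf, crossprod(st$Xv * st$v,
                             ws), transpose = TRUE))
  }

  state <- eval_point(theta)
  if (is.null(state)) {
    theta <- c(vy / 2, vy / 2)
    state <- eval_point(theta)
    if (is.null(state)) stop("could not initialize REML (indefinite V)")
  }
  trajectory <- state$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    v <- state$v; Py <- state$Py
    # score vector: dl/dtheta_i = -0.5 (tr(P K_i) - y' P K_i P y)
    trPK <- sum(lam / v) - tr_quad(state, lam)
    trPI <- sum(1 / v) - tr_quad(state, rep(1, n))
    yPKPy <- sum(lam * Py^2)
    yPPy <- sum(Py^2)
    score <- -0.5 * c(trPK - yPKPy, trPI - yPPy)
    # average information matrix
    sg_vec <- lam * Py
    se_vec <- Py
    Psg <- drop(Pdot(sg_vec, state))
    Pse <- drop(Pdot(se_vec, state))
    AI <- 0.5 * matrix(c(sum(sg_vec * Psg), sum(sg_vec * Pse),
                         sum(se_vec * Psg), sum(se_vec * Pse)), 2L, 2L)
    # active-set handling: a component pinned at the floor whose score
    # points further down stays pinned; the AI (Newton) step is taken in
    # the free components only
    pinned <- theta <= floor_val * (1 + 1e-8) & score < 0
    delta_ai <- NULL
    if (all(pinned)) {
      converged <- TRUE
      break
    } else if (any(pinned)) {
      free <- which(!pinned)
      delta_ai <- c(0, 0)
      delta_ai[free] <- tryCatch(solve(AI[free, free, drop = FALSE],
                                       score[free]),
                                 error = function(e) NA_real_)
      if (anyNA(delta_ai)) delta_ai <- NULL
    } else {
      delta_ai <- tryCatch(drop(solve(AI, score)), error = function(e) NULL)
    }
    delta_em <- c(theta[1L]^2 * (yPKPy - trPK) / n,
                  theta[2L]^2 * (yPPy - trPI) / n)
    # try the AI direction first (projected onto the feasible region by the
    # floor), falling back to the EM direction; halve steps that leave V
    # indefinite or decrease the log-likelihood
    cand <- NULL
    for (delta in Filter(Negate(is.null), list(delta_ai, delta_em))) {
      step <- 1
      while (step >= 1e-6) {
        prop <- pmax(theta + step * delta, floor_val)
        cand <- eval_point(prop)
        if (!is.null(cand) && cand$ll > state$ll) break
        cand <- NULL
        step <- step / 2
      }
      if (!is.null(cand)) break
    }
    if (is.null(cand)) { converged <- TRUE; break }  # no improving step left
    dll <- cand$ll - state$ll
    theta <- prop; state <- cand
    trajectory <- c(trajectory, state$ll)
    if (verbose)
      message(sprintf("iter %d logL %.6f sg2 %.5g se2 %.5g", iter,
                      state$ll, theta[1L], theta[2L]))
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  if (max_iter == 0L) {
    converged <- NA
  } else if (!converged) {
    warning("AI-REML did not converge in ", max_iter, " iterations")
  }
  Py_orig <- drop(eig$vectors %*% state$Py)
  blup <- theta[1L] * drop(eig$vectors %*% (lam * state$Py))
  names(blup) <- ids
  h2 <- theta[1L] / sum(theta)
  n_params <- 2L
  logL <- state$ll
  fit <- list(sigma_g2 = unname(theta[1L]), sigma_e2 = unname(theta[2L]),
              h2 = unname(h2), logL = logL, AIC = aic(logL, n_params),
              n_params = n_params,
              fixed_effects = stats::setNames(state$b, colnames(X)),
              blup = blup, Py = stats::setNames(Py_orig, ids), ids = ids,
              converged = converged, n_iter = iter,
              boundary = any(theta <= floor_val), trajectory = trajectory)
  class(fit) <- "hblup_fit"
  fit
}

# tr(T^-1 X'V^-1 diag(w) V^-1 X) given the current evaluation state
tr_quad <- function(st, w) {
  M <- crossprod(st$Xv, st$Xv * w)
  Tin <- backsolve(st$cf, backsolve(st$cf, M, transpose = TRUE))
  sum(diag(as.matrix(Tin)))
}

#' Precompute the eigendecomposition of a relationship matrix
#'
#' Useful when many REML fits share the same K (e.g. replicated phenotype
#' simulations): the O(n^3) decomposition is done once.
#'
#' @param K symmetric relationship matrix.
#' @param ids individual ids (default rownames).
#' @return object of class `reml_eigen` (values, vectors, ids).
#' @export
reml_eigen <- function(K, ids = rownames(K)) {
  K <- unclass(K)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(K)))
  structure(list(values = e$values, vectors = e$vectors,
                 ids = as.character(ids)), class = "reml_eigen")
}

#' @export
print.hblup_fit <- function(x, ...) {
  cat("HREML fit:", length(x$ids), "records\n")
  cat(sprintf("  sigma_g2 = %.5g  sigma_e2 = %.5g  h2 = %.4f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  cat(sprintf("  logL = %.4f  AIC = %.4f  iterations = %d  converged: %s\n",
              x$logL, x$AIC, x$n_iter, x$converged))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = 2 P - 2 logL`. For a univariate REML fit the parameter count P
#' is taken as the number of variance components (2); only differences in
#' AIC across models on the same data are meaningful, so the convention
#' cancels.
#'
#' @param logL (restricted) log-likelihood.
#' @param P number of parameters (>= 1).
#' @return numeric AIC value.
#' @export
aic <- function(logL, P = 2L) {
  if (P < 1) stop("P must be >= 1")
  2 * P - 2 * logL
}

#' BLUP of genetic values for unphenotyped (target) individuals
#'
#' Given estimated variance components and the full relationship matrix,
#' predicts `g_target = sigma_g2 * K[target, observed] %*% V^-1 (y - X b)`
#' where V is the phenotypic covariance over the observed individuals.
#' When `fit` is a [fit_hreml] result the projected residual `V^-1(y - Xb)`
#' is reused from the fit, so prediction costs one matrix-vector product.
#'
#' @param fit an `hblup_fit` (its `ids` must equal `observed_ids`).
#' @param K_full relationship matrix containing both observed and target
#'   individuals (id dimnames required).
#' @param observed_ids ids of the phenotyped individuals used in the fit.
#' @param target_ids ids to predict; must be disjoint from
#'   `observed_ids`.
#' @return named numeric vector of predicted genetic values.
#' @export
predict_blup <- function(fit, K_full, observed_ids, target_ids) {
  observed_ids <- as.character(observed_ids)
  target_ids <- as.character(target_ids)
  if (length(intersect(observed_ids, target_ids)))
    stop("observed and target ids overlap")
  ids <- rownames(K_full)
  bad <- setdiff(c(observed_ids, target_ids), ids)
  if (length(bad))
    stop("ids absent from K_full: ", paste(bad, collapse = ", "))
  if (!identical(fit$ids, observed_ids))
    stop("fit$ids do not match observed_ids")
  ghat <- fit$sigma_g2 *
    drop(unclass(K_full)[target_ids, observed_ids, drop = FALSE] %*% fit$Py)
  stats::setNames(ghat, target_ids)
}
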