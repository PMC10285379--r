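#' Pearson correlation between observed and predicted values
#'
#' Standard prediction-accuracy metric ("R-value"): the correlation
#' between observed phenotypes and predicted genetic values in a target
#' set.
#'
#' @param a,b numeric vectors of equal length (>= 3), no NA.
#' @return correlation coefficient.
#' @export
pearson_r <- function(a, b) {
  check_metric_args(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero variance input")
  stats::cor(a, b)
}

#' Root mean squared error
#' @param a,b numeric vectors of equal length (>= 3), no NA.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  check_metric_args(a, b)
  sqrt(mean((a - b)^2))
}

check_metric_args <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (length(a) < 3L) stop("need at least 3 paired values")
  if (anyNA(a) || anyNA(b)) stop("NA values not allowed")
  invisible(TRUE)
}

#' Bundle pedigree, genotypes and phenotypes for evaluation
#'
#' Precomputes the numerator relationship matrix and its partition around
#' the genotyped individuals so that cross-validation and grid search can
#' rebuild only the genomic part per hyper-parameter configuration.
#'
#' @param ped a [pedigree] (or data.frame id/sire/dam).
#' @param gm a [genotype_matrix]; its ids must appear in the pedigree.
#' @param phen data.frame with columns `id` and `y` (NA allowed = not
#'   phenotyped).
#' @return object of class `hblup_data`: list with `ped`, `A`, `blocks`,
#'   `gm`, `y` (named vector over phenotyped ids), `genotyped_ids`,
#'   `phenotyped_ids`.
#' @export
hblup_data <- function(ped, gm, phen) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped[[1]], ped[[2]], ped[[3]])
  A <- build_nrm(ped)
  bad <- setdiff(gm$ids, ped$id)
  if (length(bad))
    stop("genotyped ids missing from pedigree: ", paste(bad, collapse = ", "))
  blocks <- partition_nrm(A, gm$ids)
  y <- stats::setNames(phen$y, as.character(phen$id))
  y <- y[!is.na(y)]
  bad <- setdiff(names(y), ped$id)
  if (length(bad))
    stop("phenotyped ids missing from pedigree: ", paste(bad, collapse = ", "))
  structure(list(ped = ped, A = A, blocks = blocks, gm = gm, y = y,
                 genotyped_ids = gm$ids, phenotyped_ids = names(y)),
            class = "hblup_data")
}

#' K-fold cross-validation design
#'
#' Randomly partitions a target pool (typically the genotyped-and-
#' phenotyped individuals of the youngest generations) into `k` disjoint
#' folds. In each round one fold is the target set and every other
#' phenotyped individual is discovery.
#'
#' @param target_ids pool of candidate target individuals.
#' @param k number of folds (default 5).
#' @param seed integer seed for the random partition.
#' @return object of class `cv_design`: list of k character vectors.
#' @export
cv_design <- function(target_ids, k = 5L, seed = 1L) {
  target_ids <- as.character(target_ids)
  if (k < 2L || k > length(target_ids)) stop("invalid fold count")
  set.seed(as.integer(seed))
  grp <- sample(rep(seq_len(k), length.out = length(target_ids)))
  folds <- split(target_ids, grp)
  names(folds) <- paste0("fold", seq_len(k))
  structure(folds, class = "cv_design", seed = as.integer(seed))
}

#' Cross-validated HBLUP accuracy for one hyper-parameter configuration
#'
#' For each fold: the fold's phenotypes are masked (the individuals stay
#' in H), variance components are re-estimated on the discovery set by
#' [fit_hreml], genetic values of the fold are predicted by
#' [predict_blup], and accuracy is summarized as the Pearson correlation
#' (and RMSE) between observed phenotypes and predicted genetic values.
#'
#' @param data an [hblup_data] bundle.
#' @param design a [cv_design] over (a subset of) the phenotyped ids.
#' @param alpha,theta,tune,order hyper-parameters, see [adjust_grm] and
#'   [compute_grm].
#' @param H optional prebuilt `hmatrix` for this configuration (skips
#'   GRM/H construction, used by [grid_search]).
#' @param normalization GRM normalization.
#' @param tol,max_iter REML controls.
#' @return object of class `hblup_cv`: data.frame with one row per fold
#'   (fold, n_target, r, rmse, h2, converged) plus attributes `mean_r`,
#'   `mean_rmse` (means over converged folds) and the configuration.
#' @export
run_cv <- function(data, design, alpha = -0.5, theta = 1, tune = 0,
                   order = "blend_then_tune", H = NULL,
                   normalization = "empirical", tol = 1e-6,
                   max_iter = 100L) {
  if (is.null(H))
    H <- build_hmatrix(data$A, data$gm, alpha = alpha, theta = theta,
                       tune = tune, order = order,
                       normalization = normalization)
  y <- data$y
  rows <- lapply(seq_along(design), function(f) {
    targets <- design[[f]]
    obs <- setdiff(names(y), targets)
    fit <- tryCatch(
      suppressWarnings(fit_hreml(y[obs], unclass(H)[obs, obs], tol = tol,
                                 max_iter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(fold = names(design)[f], n_target = length(targets),
                        r = NA_real_, rmse = NA_real_, h2 = NA_real_,
                        converged = FALSE))
    ghat <- predict_blup(fit, H, obs, targets)
    data.frame(fold = names(design)[f], n_target = length(targets),
               r = pearson_r(y[targets], ghat),
               rmse = rmse(y[targets], ghat), h2 = fit$h2,
               converged = isTRUE(fit$converged))
  })
  out <- do.call(rbind, rows)
  if (!all(out$converged))
    warning(sum(!out$converged), " fold(s) did not converge; ",
            "summary uses converged folds only")
  ok <- out$converged & !is.na(out$r)
  structure(out, class = c("hblup_cv", "data.frame"),
            mean_r = mean(out$r[ok]), mean_rmse = mean(out$rmse[ok]),
            config = list(alpha = alpha, theta = theta, tune = tune,
                          order = order))
}

#' Default hyper-parameter grids
#'
#' The blending grid runs 0 to 1 in steps of 0.1, refined to steps of
#' 0.02 between 0.9 and 1.0; the scale-factor grid runs -1 to 1 in steps
#' of 0.1. Together with tune in \{0, 1, 2\} this gives 945
#' configurations.
#'
#' @return numeric vector (sorted, deduplicated).
#' @export
default_theta_grid <- function() {
  sort(unique(round(c(seq(0, 1, by = 0.1), seq(0.9, 1, by = 0.02)), 10)))
}

#' @rdname default_theta_grid
#' @export
default_alpha_grid <- function() {
  round(seq(-1, 1, by = 0.1), 10)
}

#' Exhaustive grid search over (tune, theta, alpha)
#'
#' Evaluates every hyper-parameter configuration by cross-validated
#' prediction accuracy ([run_cv]) and selects the configuration with the
#' highest mean fold correlation. Exact ties are broken in favour of
#' parsimony: smaller |alpha|, then larger theta, then smaller tune
#' index. The GRM is computed once per alpha and reused across theta and
#' tune.
#'
#' @param data an [hblup_data] bundle.
#' @param design a [cv_design].
#' @param tune vector of tuning methods to try (default 0:2).
#' @param theta_grid,alpha_grid numeric grids (defaults:
#'   [default_theta_grid], [default_alpha_grid]).
#' @param order,normalization,tol,max_iter passed to [run_cv].
#' @param verbose print one line per configuration.
#' @return object of class `hblup_grid`: data.frame with one row per
#'   configuration (tune, theta, alpha, mean_r, sd_r, mean_rmse,
#'   sd_rmse, n_converged) plus attributes `best` (the selected row) and
#'   `folds` (per-fold detail).
#' @export
grid_search <- function(data, design, tune = 0:2,
                        theta_grid = default_theta_grid(),
                        alpha_grid = default_alpha_grid(),
                        order = "blend_then_tune",
                        normalization = "empirical", tol = 1e-6,
                        max_iter = 100L, verbose = FALSE) {
  tune <- sort(unique(as.integer(tune)))
  theta_grid <- sort(unique(theta_grid))
  alpha_grid <- sort(unique(alpha_grid))
  if (!all(tune %in% 0:2)) stop("tune must be in {0, 1, 2}")
  res <- list(); det <- list()
  for (a in alpha_grid) {
    G <- compute_grm(data$gm, alpha = a, normalization = normalization)
    for (th in theta_grid) {
      for (tu in tune) {
        G_adj <- adjust_grm(G, data$blocks$A22, theta = th, tune = tu,
                            order = order)
        H <- assemble_h(data$blocks, G_adj, warn_indefinite = FALSE)
        cv <- suppressWarnings(
          run_cv(data, design, alpha = a, theta = th, tune = tu,
                 order = order, H = H, tol = tol, max_iter = max_iter))
        ok <- cv$converged & !is.na(cv$r)
        row <- data.frame(tune = tu, theta = th, alpha = a,
                          mean_r = attr(cv, "mean_r"),
                          sd_r = stats::sd(cv$r[ok]),
                          mean_rmse = attr(cv, "mean_rmse"),
                          sd_rmse = stats::sd(cv$rmse[ok]),
                          n_converged = sum(ok))
        if (verbose)
          message(sprintf("tune=%d theta=%.2f alpha=%+.2f  R=%.4f RMSE=%.4f",
                          tu, th, a, row$mean_r, row$mean_rmse))
        res[[length(res) + 1L]] <- row
        cvd <- as.data.frame(cv)
        cvd$tune <- tu; cvd$theta <- th; cvd$alpha <- a
        det[[length(det) + 1L]] <- cvd
      }
    }
  }
  res <- do.call(rbind, res)
  best <- select_best(res)
  structure(res, class = c("hblup_grid", "data.frame"), best = best,
            folds = do.call(rbind, det))
}

# max mean_r; exact ties -> smaller |alpha|, larger theta, smaller tune
select_best <- function(res) {
  res <- res[!is.na(res$mean_r), , drop = FALSE]
  if (!nrow(res)) stop("no configuration produced a valid accuracy")
  ord <- order(-res$mean_r, abs(res$alpha), -res$theta, res$tune)
  res[ord[1L], , drop = FALSE]
}

#' @export
print.hblup_grid <- function(x, ...) {
  cat("hyper-parameter grid search:", nrow(x), "configurations\n")
  b <- attr(x, "best")
  cat(sprintf("best: tune=%d theta=%g alpha=%g  mean R=%.4f mean RMSE=%.4f\n",
              b$tune, b$theta, b$alpha, b$mean_r, b$mean_rmse))
  invisible(x)
}

#' Full-data AIC profile over the hyper-parameter grid
#'
#' Fits HREML on all phenotyped individuals for every configuration and
#' reports AIC and `dAIC = AIC - min(AIC)` (the optimum row has dAIC = 0).
#' This is the model-fit counterpart of the accuracy-based grid search:
#' a configuration whose H matrix fits the data better achieves a lower
#' AIC.
#'
#' @inheritParams grid_search
#' @return data.frame with one row per configuration: tune, theta,
#'   alpha, logL, AIC, dAIC, h2, converged.
#' @export
aic_profile <- function(data, tune = 0:2,
                        theta_grid = default_theta_grid(),
                        alpha_grid = default_alpha_grid(),
                        order = "blend_then_tune",
                        normalization = "empirical", tol = 1e-6,
                        max_iter = 100L, verbose = FALSE) {
  tune <- sort(unique(as.integer(tune)))
  theta_grid <- sort(unique(theta_grid))
  alpha_grid <- sort(unique(alpha_grid))
  y <- data$y
  rows <- list()
  for (a in alpha_grid) {
    G <- compute_grm(data$gm, alpha = a, normalization = normalization)
    for (th in theta_grid) {
      for (tu in tune) {
        G_adj <- adjust_grm(G, data$blocks$A22, theta = th, tune = tu,
                            order = order)
        H <- assemble_h(data$blocks, G_adj, warn_indefinite = FALSE)
        fit <- tryCatch(
          suppressWarnings(fit_hreml(y, unclass(H)[names(y), names(y)],
                                     tol = tol, max_iter = max_iter)),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          tune = tu, theta = th, alpha = a,
          logL = if (is.null(fit)) NA_real_ else fit$logL,
          AIC = if (is.null(fit)) NA_real_ else fit$AIC,
          h2 = if (is.null(fit)) NA_real_ else fit$h2,
          converged = !is.null(fit) && isTRUE(fit$converged))
        if (verbose && !is.null(fit))
          message(sprintf("tune=%d theta=%.2f alpha=%+.2f  AIC=%.3f",
                          tu, th, a, fit$AIC))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$dAIC <- out$AIC - min(out$AIC, na.rm = TRUE)
  out
}
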