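#' L1-penalized selection on a collapsed design
#'
#' Fits the LASSO of the phenotype on the collapsed rare-variant
#' indicators `X` and uncollapsed common carriers `U` jointly, i.e.
#' minimizes `||Y - Xb - Ug||^2 + lambda * (||b||_1 + ||g||_1)` with an
#' unpenalized intercept, via glmnet. Both coefficient blocks share one
#' penalty. With `lambda = NULL` the penalty is chosen by k-fold
#' cross-validation at the minimum mean CV error over a geometric grid of
#' `nlambda` points down to `lambda_min_ratio * lambda_max`. Columns are
#' standardized internally; zero-variance columns are excluded from the fit
#' and reported back.
#'
#' A selected `X` column marks every rare variant of its subgroup as
#' selected (the per-variant attribution that makes stabilities per
#' variant possible); a selected `U` column marks its single common variant.
#'
#' @param y numeric phenotype vector, length `nrow(design$X)`.
#' @param design a `collapsed_design` from [build_design()].
#' @param cv_folds number of CV folds (default 10); ignored when `lambda`
#'   is supplied.
#' @param lambda optional fixed penalty value (skips cross-validation).
#' @param fold_seed seed for the CV fold assignment (its own RNG stream,
#'   independent of the collapsing randomness).
#' @param nlambda,lambda_min_ratio the penalty grid (defaults 100, 0.001).
#' @param zero_tol coefficients with magnitude above this count as selected
#'   (default 1e-8; coordinate descent returns exact zeros, the tolerance
#'   only guards alternative solvers).
#' @param standardize standardize design columns inside glmnet (default TRUE).
#' @return list of class `sorc_selection`: `selected_rare`,
#'   `selected_common` (character vectors), `selected_columns` (labels of
#'   nonzero design columns), `lambda_used`, `n_nonzero`, `coefficients`
#'   (named, original scale, excluded columns as 0), `dropped_columns`
#'   (zero-variance).
#' @export
lasso_select <- function(y, design, cv_folds = 10, lambda = NULL,
                         fold_seed = NULL, nlambda = 100,
                         lambda_min_ratio = 0.001, zero_tol = 1e-8,
                         standardize = TRUE) {
  stopifnot(inherits(design, "collapsed_design"))
  Z <- cbind(design$X, design$U)
  if (!is.null(design$u_ids) && length(design$u_ids)) {
    colnames(Z) <- c(colnames(design$X), design$u_ids)
  }
  if (length(y) != nrow(Z)) abort("phenotype length does not match design rows.")
  if (anyNA(y) || any(!is.finite(y))) abort("phenotype must be finite.")

  keep <- apply(Z, 2, function(col) var(col) > 0)
  dropped <- colnames(Z)[!keep]
  Zk <- Z[, keep, drop = FALSE]
  if (ncol(Zk) < 2) {
    abort("fewer than two non-constant design columns; nothing to select over.")
  }

  if (is.null(lambda)) {
    if (cv_folds < 2 || cv_folds > length(y)) {
      abort("`cv_folds` must lie in [2, N].")
    }
    foldid <- with_seed(fold_seed %||% sample.int(.Machine$integer.max - 1L, 1),
                        sample(rep_len(seq_len(cv_folds), length(y))))
    cvfit <- glmnet::cv.glmnet(Zk, y, family = "gaussian", foldid = foldid,
                               nlambda = nlambda,
                               lambda.min.ratio = lambda_min_ratio,
                               standardize = standardize)
    lambda_used <- cvfit$lambda.min
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
  } else {
    fit <- glmnet::glmnet(Zk, y, family = "gaussian", lambda = lambda,
                          standardize = standardize, thresh = 1e-12)
    lambda_used <- lambda
    beta <- as.numeric(coef(fit, s = lambda))[-1]
  }
  names(beta) <- colnames(Zk)

  nz_cols <- colnames(Zk)[abs(beta) > zero_tol]
  x_labels <- colnames(design$X)
  sel_x <- intersect(nz_cols, x_labels)
  sel_rare <- sort(unique(unlist(
    design$column_map$variants[match(sel_x, paste0(design$column_map$gene, ".s",
                                                   design$column_map$subgroup))],
    use.names = FALSE
  ))) %||% character()
  sel_common <- sort(intersect(nz_cols, design$u_ids))

  full_coef <- stats::setNames(numeric(ncol(Z)), colnames(Z))
  full_coef[names(beta)] <- beta
  structure(
    list(
      selected_rare = as.character(sel_rare),
      selected_common = as.character(sel_common),
      selected_columns = nz_cols,
      lambda_used = lambda_used,
      n_nonzero = length(nz_cols),
      coefficients = full_coef,
      dropped_columns = dropped
    ),
    class = "sorc_selection"
  )
}
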