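#' Screen a feature matrix for collinear pairs
#'
#' Flags every pair of encoded predictors whose absolute Pearson correlation
#' exceeds 0.70 and, for each flagged pair, drops the later-listed column
#' (deterministic auto-drop; callers may override the retained set).
#' Zero-variance columns are dropped with a warning before correlation.
#'
#' @param x numeric matrix or data.frame of encoded predictors.
#' @param threshold absolute correlation above which a pair is flagged
#'   (strict \code{>}).
#' @return list with \code{flagged} (data.frame: col1, col2, r),
#'   \code{dropped} and \code{retained} column names.
#' @export
screen_collinearity <- function(x, threshold = 0.70) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 columns", call. = FALSE)
  vars <- apply(x, 2, stats::var)
  zero <- colnames(x)[vars == 0]
  if (length(zero))
    warning("dropping zero-variance column(s): ", paste(zero, collapse = ", "),
            call. = FALSE)
  x <- x[, vars > 0, drop = FALSE]
  r <- stats::cor(x)
  flagged <- list()
  p <- ncol(x)
  drop <- logical(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      # strict > with a tolerance so a pair engineered to sit exactly on the
      # threshold is not flagged through floating-point noise
      if (abs(r[i, j]) > threshold + 1e-10) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          col1 = colnames(x)[i], col2 = colnames(x)[j], r = r[i, j],
          stringsAsFactors = FALSE)
        if (!drop[i]) drop[j] <- TRUE
      }
    }
  }
  list(
    flagged = if (length(flagged)) do.call(rbind, flagged) else
      data.frame(col1 = character(), col2 = character(), r = numeric()),
    dropped = c(zero, colnames(x)[drop]),
    retained = colnames(x)[!drop])
}

#' Encode cohort features into a model matrix
#'
#' Builds the per-infant design matrix for one abundance model. Feature names
#' use a \code{type} or \code{type:taxon} vocabulary:
#' \describe{
#'   \item{\code{maternal_abundance:<taxon>}}{mother's prenatal abundance (\%).}
#'   \item{\code{strain_shared:<taxon>}}{sharing boolean at the model
#'     timepoint, encoded 0/1.}
#'   \item{\code{abundance:<taxon>}}{infant abundance at the model timepoint.}
#'   \item{\code{abundance_1m:<taxon>}}{infant abundance at one month (for
#'     six-month models).}
#'   \item{\code{presence:<taxon>}}{infant presence (> 0.01\%) at the model
#'     timepoint, 0/1.}
#'   \item{\code{feeding_type}}{full one-hot indicators (no reference level
#'     dropped; the L1 penalty resolves the redundancy).}
#'   \item{\code{feeding_frequency}}{daily milk feeds.}
#'   \item{\code{bifido_diversity}}{number of bifidobacterial taxa present
#'     (> 0.01\%) in the infant sample.}
#'   \item{any column of \code{extra}}{merged by \code{pair_id}; character /
#'     factor columns are one-hot encoded (e.g. an \code{hmg_profile}
#'     assignment).}
#' }
#' Missing numeric cells are imputed with the column mean and flagged.
#'
#' @param cohort cohort table.
#' @param metadata pair metadata.
#' @param model list with \code{response} (focal taxon), \code{timepoint}
#'   (\code{"1m"}/\code{"6m"}) and \code{features} (character vector).
#' @param extra optional data.frame keyed by \code{pair_id} with additional
#'   per-pair features.
#' @return list with \code{x} (numeric matrix), \code{y} (response, \%),
#'   \code{pair_id}, \code{imputed} (logical matrix), \code{onehot_groups}.
#' @export
encode_features <- function(cohort, metadata, model, extra = NULL) {
  stopifnot(is.list(model), !is.null(model$response), !is.null(model$timepoint))
  tp <- model$timepoint
  infants <- cohort[cohort$role == "infant" & cohort$timepoint == tp, ]
  if (!model$response %in% cohort_taxa(cohort))
    stop("unknown response taxon: ", model$response, call. = FALSE)
  y <- infants[[model$response]]
  pid <- infants$pair_id
  mothers <- cohort[cohort$role == "mother", ]
  inf1 <- cohort[cohort$role == "infant" & cohort$timepoint == "1m", ]
  taxa <- cohort_taxa(cohort)

  onehot <- function(v, prefix) {
    v <- as.character(v)
    levs <- sort(unique(v[!is.na(v)]))
    m <- vapply(levs, function(l) as.numeric(v == l), numeric(length(v)))
    colnames(m) <- paste0(prefix, "_", levs)
    m
  }

  cols <- list(); groups <- list()
  add <- function(name, value) cols[[name]] <<- value
  for (f in model$features) {
    parts <- strsplit(f, ":", fixed = TRUE)[[1]]
    type <- parts[1]
    tax <- if (length(parts) > 1) parts[2] else NA
    if (!is.na(tax) && type != "extra" && !tax %in% taxa)
      stop("unknown taxon in feature '", f, "'", call. = FALSE)
    switch(type,
      maternal_abundance = add(paste0("maternal_", tax),
                               mothers[[tax]][match(pid, mothers$pair_id)]),
      strain_shared = {
        col <- paste0("shared_", tax, "_", tp)
        stop_if_not_cols(metadata, col, "pair metadata")
        add(paste0("shared_", tax),
            as.numeric(metadata[[col]][match(pid, metadata$pair_id)]))
      },
      abundance = add(paste0("abundance_", tax), infants[[tax]]),
      abundance_1m = add(paste0("abundance1m_", tax),
                         inf1[[tax]][match(pid, inf1$pair_id)]),
      presence = add(paste0("presence_", tax),
                     as.numeric(infants[[tax]] > 0.01)),
      feeding_type = {
        m <- onehot(metadata$feeding_type[match(pid, metadata$pair_id)],
                    "feeding")
        groups[["feeding_type"]] <- colnames(m)
        for (cn in colnames(m)) add(cn, m[, cn])
      },
      feeding_frequency = add(
        "feeding_frequency",
        metadata$feeding_frequency_per_day[match(pid, metadata$pair_id)]),
      bifido_diversity = add(
        "bifido_diversity",
        rowSums(infants[, taxa, drop = FALSE] > 0.01)),
      {
        if (is.null(extra) || !f %in% names(extra))
          stop("unknown feature name: ", f, call. = FALSE)
        v <- extra[[f]][match(pid, extra$pair_id)]
        if (is.numeric(v) || is.logical(v)) add(f, as.numeric(v))
        else {
          m <- onehot(v, f)
          groups[[f]] <- colnames(m)
          for (cn in colnames(m)) add(cn, m[, cn])
        }
      })
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  rownames(x) <- pid
  if (anyDuplicated(colnames(x)))
    stop("duplicate encoded column names", call. = FALSE)
  imputed <- is.na(x)
  for (j in seq_len(ncol(x))) {
    if (any(imputed[, j])) {
      mu <- mean(x[, j], na.rm = TRUE)
      if (!is.finite(mu))
        stop("feature column '", colnames(x)[j], "' is entirely missing",
             call. = FALSE)
      x[imputed[, j], j] <- mu
    }
  }
  list(x = x, y = y, pair_id = pid, imputed = imputed, onehot_groups = groups)
}

#' Cross-validated LASSO fit for feature selection
#'
#' Fits an L1-penalized linear regression of the focal taxon's abundance on
#' the encoded predictors over a 100-point log-spaced penalty grid spanning
#' four decades below the smallest all-zero penalty. Cross-validated mean
#' squared error is either a ten-times-repeated 10-fold estimate (fold
#' assignments redrawn each repeat, per-repeat error curves averaged before
#' selection) or leave-one-out; the selected penalty \code{lambda_min}
#' minimizes the (averaged) error curve. Predictors are standardized
#' internally; coefficients are reported on the original scale. Results are
#' intended for feature identification, not prediction.
#'
#' @param x numeric predictor matrix (rows = infants).
#' @param y numeric response (relative abundance, \%).
#' @param scheme \code{"repeated_kfold"} or \code{"loocv"}.
#' @param nfolds,repeats k-fold scheme parameters.
#' @param seed RNG seed for fold assignment.
#' @return object of class \code{"lasso_result"}: \code{lambda} (grid),
#'   \code{cvm} (averaged CV error per grid point), \code{lambda_min},
#'   \code{beta} (named coefficients at \code{lambda_min}),
#'   \code{intercept}, \code{nzero} (nonzero count along the grid),
#'   \code{scheme}, \code{seed}.
#' @export
fit_lasso_cv <- function(x, y, scheme = c("repeated_kfold", "loocv"),
                         nfolds = 10, repeats = 10, seed = 1L) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in x or y", call. = FALSE)
  n <- nrow(x)
  if (scheme == "repeated_kfold" && n < nfolds)
    stop("n < nfolds", call. = FALSE)
  if (stats::var(y) == 0) {
    # degenerate constant response: the penalized fit is the intercept
    beta <- setNames(numeric(ncol(x)), colnames(x))
    res <- list(lambda = NA_real_, cvm = NA_real_, lambda_min = NA_real_,
                beta = beta, intercept = y[1], nzero = 0L, scheme = scheme,
                seed = seed)
    class(res) <- "lasso_result"
    return(res)
  }
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1, nlambda = 100,
                        lambda.min.ratio = 1e-4)
  grid <- fit$lambda
  cvm_mat <- with_seed(seed, {
    if (scheme == "loocv") {
      cv <- glmnet::cv.glmnet(x, y, lambda = grid, foldid = seq_len(n),
                              grouped = FALSE, type.measure = "mse")
      matrix(cv$cvm[match(grid, cv$lambda)], ncol = 1)
    } else {
      vapply(seq_len(repeats), function(r) {
        foldid <- sample(rep_len(seq_len(nfolds), n))
        cv <- glmnet::cv.glmnet(x, y, lambda = grid, foldid = foldid,
                                type.measure = "mse")
        cv$cvm[match(grid, cv$lambda)]
      }, numeric(length(grid)))
    }
  })
  cvm <- rowMeans(cvm_mat, na.rm = TRUE)
  lambda_min <- grid[which.min(cvm)]
  co <- as.matrix(stats::coef(fit, s = lambda_min, exact = FALSE))
  beta <- setNames(co[-1, 1], rownames(co)[-1])
  res <- list(lambda = grid, cvm = cvm, lambda_min = lambda_min,
              beta = beta, intercept = co[1, 1],
              nzero = as.integer(fit$df), scheme = scheme, seed = seed)
  class(res) <- "lasso_result"
  res
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("LASSO feature selection (%s): lambda_min = %.5g, %d/%d nonzero\n",
              x$scheme, x$lambda_min, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' Report the important (nonzero) features of a LASSO fit
#'
#' Features whose coefficient was not shrunk to zero at the selected penalty,
#' ordered by decreasing coefficient magnitude, with the association sign.
#'
#' @param result a [fit_lasso_cv()] result.
#' @return data.frame: \code{feature}, \code{beta}, \code{sign}
#'   (\code{"positive"} / \code{"negative"}).
#' @export
select_features <- function(result) {
  stopifnot(inherits(result, "lasso_result"))
  nz <- result$beta[result$beta != 0]
  nz <- nz[order(abs(nz), decreasing = TRUE)]
  data.frame(feature = names(nz), beta = unname(nz),
             sign = ifelse(nz > 0, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}
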