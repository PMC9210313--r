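# Midparent heterosis, gene-trait correlations on scaled expression, the four
# prediction gene sets, closed-form ridge regression, and replicated nested
# cross-validation.

#' Midparent heterosis
#'
#' Percent deviation of the hybrid from the midparent value:
#' `100 * (f1 - MP) / MP` with `MP = (p1 + p2) / 2`. Vectorized; a zero
#' midparent makes the value undefined (`NA` with a warning).
#'
#' @param f1 hybrid trait value(s).
#' @param p1,p2 parent trait values.
#' @return Heterosis percentage(s).
#' @examples
#' midparent_heterosis(15, 10, 10)  # 50
#' @export
midparent_heterosis <- function(f1, p1, p2) {
  mp <- (p1 + p2) / 2
  out <- 100 * (f1 - mp) / mp
  if (any(mp == 0)) {
    warning("midparent value is 0 for some entries; heterosis undefined (NA)")
    out[mp == 0] <- NA_real_
  }
  out
}

#' Midparent heterosis table from a trait table
#'
#' @param traits a [trait_table()] containing the two parents and the
#'   progeny.
#' @param p1,p2 genotype ids of the parents.
#' @return data.frame with `trait`, `individual`, `heterosis` (percent), one
#'   row per trait per progeny genotype.
#' @export
heterosis_table <- function(traits, p1 = "P1", p2 = "P2") {
  out <- list()
  for (tr in unique(traits$trait)) {
    sub <- traits[traits$trait == tr, ]
    v <- stats::setNames(sub$value, sub$genotype)
    if (!all(c(p1, p2) %in% names(v)))
      .stopf("trait '%s' lacks parent values", tr)
    prog <- setdiff(names(v), c(p1, p2))
    out[[tr]] <- data.frame(trait = tr, individual = prog,
                            heterosis = midparent_heterosis(v[prog], v[p1], v[p2]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genotype-mean CPM matrix
#'
#' Collapses a count matrix to one CPM column per genotype by averaging CPM
#' over its replicates.
#'
#' @param m a [count_matrix()].
#' @return genes x genotypes matrix of mean CPM.
#' @export
genotype_cpm <- function(m) {
  cpm_all <- cpm(m)
  geno <- unique(as.character(m$samples$genotype))
  out <- vapply(geno, function(g)
    rowMeans(cpm_all[, samples_for(m, g), drop = FALSE]),
    numeric(nrow(cpm_all)))
  colnames(out) <- geno
  out
}

#' Standardized log2(CPM + 1) expression
#'
#' Per gene across individuals: `log2(CPM + 1)` centered to mean 0 and
#' scaled to SD 1 (n-1 denominator). Genes with zero variance are dropped.
#'
#' @param cpm_matrix genes x individuals CPM matrix.
#' @return Standardized matrix (possibly fewer rows).
#' @export
scale_expression <- function(cpm_matrix) {
  if (any(cpm_matrix < 0)) .stopf("CPM values must be non-negative")
  l <- log2(cpm_matrix + 1)
  sds <- apply(l, 1, stats::sd)
  keep <- sds > 0
  (l[keep, , drop = FALSE] - rowMeans(l[keep, , drop = FALSE])) / sds[keep]
}

#' Gene-trait Pearson correlations
#'
#' Correlates each gene's scaled expression across individuals with each
#' trait's heterosis values, with a two-sided t-distribution p-value and a
#' significance mask at `alpha`.
#'
#' @param scaled_expr genes x individuals matrix (see [scale_expression()]).
#' @param het data.frame from [heterosis_table()].
#' @param alpha significance level for the mask (default 0.01).
#' @return data.frame with `gene_id`, `trait`, `r`, `p`, `significant`.
#' @export
gene_trait_correlations <- function(scaled_expr, het, alpha = 0.01) {
  out <- list()
  for (tr in unique(het$trait)) {
    sub <- het[het$trait == tr & is.finite(het$heterosis), ]
    ids <- intersect(colnames(scaled_expr), sub$individual)
    if (length(ids) < 3) .stopf("trait '%s' has < 3 paired observations", tr)
    y <- sub$heterosis[match(ids, sub$individual)]
    x <- scaled_expr[, ids, drop = FALSE]
    sdx <- apply(x, 1, stats::sd)
    x <- x[sdx > 0, , drop = FALSE]
    n <- length(ids)
    r <- as.numeric(stats::cor(t(x), y))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    out[[tr]] <- data.frame(gene_id = rownames(x), trait = tr, r = r, p = p,
                            significant = p < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the four prediction gene sets
#'
#' (1) `random`: a seeded random sample of genes; (2) `top`: the most highly
#' expressed genes by mean CPM; (3) `de_any_pair`: genes significantly DE
#' between at least one pair of family parents (union over the supplied DE
#' tables); (4) `de_common`: genes DE in every table (intersection).
#'
#' @param de_tables list of [run_pairwise_de()] results (one per parent
#'   pair/family).
#' @param expr_cpm genes x individuals CPM matrix (for the random and top
#'   sets).
#' @param n_random,n_top set sizes (default 5000; capped, with a warning, at
#'   the number of available genes).
#' @param seed seed for the random draw.
#' @return Named list of four character vectors of gene ids.
#' @export
build_gene_sets <- function(de_tables, expr_cpm, n_random = 5000,
                            n_top = 5000, seed = 1L) {
  if (length(de_tables) < 1) .stopf("need at least one DE table")
  sig <- lapply(de_tables, function(d) d$gene_id[d$significant])
  genes <- rownames(expr_cpm)
  if (n_random > length(genes) || n_top > length(genes)) {
    warning(sprintf("requested set size exceeds the %d available genes; capping",
                    length(genes)))
    n_random <- min(n_random, length(genes))
    n_top <- min(n_top, length(genes))
  }
  set.seed(seed)
  list(random = sort(sample(genes, n_random)),
       top = genes[order(rowMeans(expr_cpm), decreasing = TRUE)][seq_len(n_top)],
       de_any_pair = sort(Reduce(union, sig)),
       de_common = sort(Reduce(intersect, sig)))
}

#' Closed-form ridge regression
#'
#' Minimizes `(1/(2n)) * sum((y - b0 - X b)^2) + lambda * sum(b^2)` with an
#' unpenalized intercept, by solving the normal equations on centered data
#' (or their kernel dual when there are more predictors than observations).
#' `lambda = 0` reduces to ordinary least squares.
#'
#' @param X n x p predictor matrix.
#' @param y response vector of length n.
#' @param lambda ridge penalty (>= 0).
#' @return List with `beta` (length p), `intercept`, `lambda`.
#' @export
ridge_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)) || !is.finite(lambda))
    .stopf("X, y and lambda must be finite")
  if (lambda < 0) .stopf("lambda must be non-negative")
  n <- nrow(X)
  if (n < 2 || length(y) != n) .stopf("need n >= 2 rows with matching y")
  p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  if (lambda == 0) {
    beta <- stats::lm.fit(Xc, yc)$coefficients
    if (anyNA(beta))
      .stopf("X is rank deficient; use lambda > 0")
  } else if (p <= n) {
    beta <- solve(crossprod(Xc) / n + diag(2 * lambda, p), crossprod(Xc, yc) / n)
  } else {
    beta <- crossprod(Xc, solve(tcrossprod(Xc) + diag(2 * lambda * n, n), yc))
  }
  beta <- as.numeric(beta)
  list(beta = beta, intercept = ym - sum(xm * beta), lambda = lambda)
}

#' @rdname ridge_fit
#' @param fit a `ridge_fit()` result.
#' @param newdata matrix with the same columns as `X`.
#' @export
ridge_predict <- function(fit, newdata) {
  as.numeric(fit$intercept + as.matrix(newdata) %*% fit$beta)
}

#' @noRd
#' Validation-set predictions for a whole lambda path via one SVD of the
#' centered training matrix. Columns of the result follow `lambdas`.
.ridge_path_predict <- function(Xtr, ytr, Xval, lambdas) {
  n <- nrow(Xtr)
  xm <- colMeans(Xtr)
  ym <- mean(ytr)
  sv <- svd(sweep(Xtr, 2, xm))
  d <- sv$d
  w <- crossprod(sv$u, ytr - ym) * d            # r x 1
  denom <- outer(d^2, 2 * lambdas * n, "+")     # r x nl
  coefs <- as.numeric(w) / denom                # r x nl
  M <- sweep(Xval, 2, xm) %*% sv$v              # nv x r
  M %*% coefs + ym
}

#' Replicated nested cross-validation ridge prediction
#'
#' For each of `reps` replications, individuals are partitioned into `outer`
#' folds; within each outer training set, `inner`-fold cross-validation
#' picks the penalty minimizing mean squared error over a glmnet-style grid
#' (100 values, log-spaced over 4 decades down from
#' `lambda_max = max|X'y|/n`), and the tuned model predicts the held-out
#' fold. Per-individual predictions are averaged over replications, and
#' accuracy is the R-squared of the linear regression of observed on mean
#' predicted values (the conventional 1 - SSE/SST is also reported). Fold
#' assignment is fully seeded.
#'
#' @param X individuals x genes predictor matrix (standardized expression).
#' @param y heterosis values, length `nrow(X)`.
#' @param outer,inner fold counts (reduced automatically, with a message,
#'   when n is too small).
#' @param reps number of replications.
#' @param lambda_grid optional penalty grid; computed from the data when
#'   `NULL`.
#' @param seed integer seed.
#' @return List with `predictions` (data.frame: `individual`, `observed`,
#'   `mean_predicted`), `r2` (regression R-squared), `r2_classic`,
#'   `lambda_grid`, `chosen_lambdas`, `seed`.
#' @export
nested_cv_predict <- function(X, y, outer = 10, inner = 10, reps = 10,
                              lambda_grid = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) .stopf("need at least 3 individuals")
  if (length(y) != n) .stopf("y must match rows of X")
  if (outer > n) {
    message(sprintf("reducing outer folds from %d to n = %d", outer, n))
    outer <- n
  }
  if (is.null(lambda_grid)) {
    yc <- y - mean(y)
    lmax <- max(abs(crossprod(sweep(X, 2, colMeans(X)), yc))) / n
    if (lmax <= 0) lmax <- 1
    lambda_grid <- 10^seq(log10(lmax), log10(lmax) - 4, length.out = 100)
  }
  set.seed(seed)
  pred_mat <- matrix(NA_real_, n, reps)
  chosen <- numeric(0)
  for (rep_i in seq_len(reps)) {
    fold <- sample(rep(seq_len(outer), length.out = n))
    for (f in seq_len(outer)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      kin <- min(inner, length(tr))
      if (kin < 2) kin <- 2
      ifold <- sample(rep(seq_len(kin), length.out = length(tr)))
      sse <- numeric(length(lambda_grid))
      for (g in seq_len(kin)) {
        itr <- tr[ifold != g]
        ite <- tr[ifold == g]
        pv <- .ridge_path_predict(X[itr, , drop = FALSE], y[itr],
                                  X[ite, , drop = FALSE], lambda_grid)
        sse <- sse + colSums((pv - y[ite])^2)
      }
      best <- lambda_grid[which.min(sse)]
      chosen <- c(chosen, best)
      pred_mat[te, rep_i] <- .ridge_path_predict(X[tr, , drop = FALSE], y[tr],
                                                 X[te, , drop = FALSE], best)
    }
  }
  mean_pred <- rowMeans(pred_mat)
  r2 <- if (stats::sd(mean_pred) > 0)
    summary(stats::lm(y ~ mean_pred))$r.squared else 0
  r2_classic <- 1 - sum((y - mean_pred)^2) / sum((y - mean(y))^2)
  list(predictions = data.frame(individual = rownames(X) %||% seq_len(n),
                                observed = y, mean_predicted = mean_pred,
                                stringsAsFactors = FALSE),
       r2 = r2, r2_classic = r2_classic,
       lambda_grid = lambda_grid, chosen_lambdas = chosen, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
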