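.NMF_EPS <- 1e-9

.as_intensity <- function(X) {
  if (inherits(X, "intensity_matrix")) X$values
  else if (inherits(X, "spectrum_counts")) X$counts
  else as.matrix(X)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative intensity matrix `X` (classes x samples) as
#' `W H` with `W >= 0` (96 x k signature weights) and `H >= 0` (k x n
#' per-sample loadings), using the multiplicative update rules for the
#' Euclidean (Frobenius) objective, whose value is non-increasing across
#' iterations. Initialization is either ICA-based (see [ica_init()]) or
#' random. Factors are reordered by descending total loading so the
#' ordering is deterministic.
#'
#' @param X intensity matrix (an `intensity_matrix`, `spectrum_counts` or
#'   plain non-negative matrix).
#' @param rank factorization rank k, `1 <= k <= min(nrow, ncol)`.
#' @param init `"ica"` or `"random"`.
#' @param seed optional integer seed (controls the initialization).
#' @param max_iter maximum iterations (default 2000).
#' @param tol convergence threshold on the relative change of the objective
#'   (default 1e-6).
#' @param init_values optional list with `W`, `H` to start from (overrides
#'   `init`).
#' @return object of class `signature_set`: list with `weights` (96 x k),
#'   `loadings` (k x n), `rank`, `rss` (squared Frobenius reconstruction
#'   error), `n_iterations`, `objective` (per-iteration trace) and `init`.
#' @export
nmf_fit <- function(X, rank, init = c("ica", "random"), seed = NULL,
                    max_iter = 2000, tol = 1e-6, init_values = NULL) {
  init <- match.arg(init)
  X <- .as_intensity(X)
  if (any(X < 0)) stop("X must be non-negative")
  if (any(rowSums(X) == 0) || any(colSums(X) == 0)) {
    stop("X has an all-zero row or column; drop empty classes/samples ",
         "before factorizing")
  }
  if (rank < 1 || rank > min(dim(X))) {
    stop("rank must be between 1 and min(dim(X))")
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(init_values)) {
    W <- pmax(init_values$W, .NMF_EPS)
    H <- pmax(init_values$H, .NMF_EPS)
  } else if (init == "ica" && rank > 1) {
    iv <- ica_init(X, rank)
    W <- pmax(iv$W, .NMF_EPS)
    H <- pmax(iv$H, .NMF_EPS)
  } else {
    sc <- sqrt(mean(X) / rank)
    W <- matrix(stats::runif(nrow(X) * rank, 0, 2 * sc), ncol = rank)
    H <- matrix(stats::runif(rank * ncol(X), 0, 2 * sc), nrow = rank)
  }
  obj <- numeric(max_iter)
  prev <- sum((X - W %*% H)^2)
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + .NMF_EPS)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + .NMF_EPS)
    cur <- sum((X - W %*% H)^2)
    obj[it] <- cur
    if (prev > 0 && (prev - cur) / prev < tol) break
    prev <- cur
  }
  obj <- obj[seq_len(it)]
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  dimnames(W) <- list(rownames(X), paste0("S", seq_len(rank)))
  dimnames(H) <- list(paste0("S", seq_len(rank)), colnames(X))
  structure(list(weights = W, loadings = H, rank = rank,
                 rss = obj[length(obj)], n_iterations = it,
                 objective = obj, init = if (!is.null(init_values))
                   "custom" else init),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set: rank", x$rank, "| rss", format(x$rss, digits = 4),
      "|", x$n_iterations, "iterations (", x$init, "init )\n")
  invisible(x)
}

#' ICA-based non-negative initialization for NMF
#'
#' Runs a fixed-point independent component analysis (symmetric
#' decorrelation, tanh contrast) on the intensity matrix, chooses each
#' component's sign so that its sum is positive, and zeroes the remaining
#' negative entries. A small positive floor (a fraction `floor_frac` of each
#' component's mean absolute value) is then added: multiplicative updates
#' rescale entries by ratios, so entries clamped to a negligible value would
#' stay frozen near zero and drag out convergence. Loadings are obtained by
#' least squares on the non-negative components, clamped the same way. If
#' the ICA iteration fails to converge, a random initialization is returned
#' instead (with a warning).
#'
#' @param X non-negative matrix (classes x samples).
#' @param k number of components.
#' @param seed optional integer seed.
#' @param floor_frac relative positive floor applied after clamping
#'   (default 0.01).
#' @return list with `W` (classes x k), `H` (k x samples), both strictly
#'   positive, and `converged` (logical; FALSE when the random fallback was
#'   used).
#' @export
ica_init <- function(X, k, seed = NULL, floor_frac = 0.01) {
  X <- .as_intensity(X)
  if (!is.null(seed)) set.seed(seed)
  S <- tryCatch(.fastica(X, k), error = function(e) NULL)
  if (is.null(S)) {
    warning("ICA failed to converge; falling back to random initialization")
    sc <- sqrt(mean(X) / k)
    return(list(W = matrix(stats::runif(nrow(X) * k, 0, 2 * sc), ncol = k),
                H = matrix(stats::runif(k * ncol(X), 0, 2 * sc), nrow = k),
                converged = FALSE))
  }
  # orient each component so its sum is positive, then clamp
  sgn <- ifelse(colSums(S) >= 0, 1, -1)
  S <- sweep(S, 2, sgn, "*")
  fl <- floor_frac * colMeans(abs(S)) + .NMF_EPS
  W <- pmax(S, 0) + rep(fl, each = nrow(S))
  H <- tryCatch(qr.solve(W, X), error = function(e) {
    MASS::ginv(W) %*% X
  })
  H <- pmax(H, 0) + .NMF_EPS
  list(W = W, H = H, converged = TRUE)
}

# Fixed-point ICA with symmetric decorrelation and tanh contrast.
# X: p x n; returns estimated source matrix S (p x k). Restarts from fresh
# random rotations a few times before declaring failure.
.fastica <- function(X, k, max_iter = 200, tol = 1e-4, restarts = 3) {
  p <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)  # center each sample column
  sv <- svd(Xc, nu = 0, nv = k)
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-12)) stop("rank-deficient input for ICA")
  Z <- Xc %*% sv$v[, seq_len(k), drop = FALSE] %*% diag(sqrt(p) / d, k)
  for (r in seq_len(restarts)) {
    W <- .sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
    for (i in seq_len(max_iter)) {
      G <- tanh(Z %*% W)
      Gp <- 1 - G^2
      W1 <- crossprod(Z, G) / p - W %*% diag(colMeans(Gp), k)
      W1 <- .sym_decorrelate(W1)
      delta <- max(abs(abs(colSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) return(Z %*% W)
    }
  }
  stop("ICA did not converge")
}

.sym_decorrelate <- function(W) {
  e <- eigen(crossprod(W), symmetric = TRUE)
  W %*% e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                           length(e$values)) %*% t(e$vectors)
}

#' Rank-selection diagnostics for NMF
#'
#' For each candidate rank, runs the factorization from `n_starts` random
#' initializations and reports: the consensus-matrix dispersion (mean of
#' `4 (C - 1/2)^2` over the consensus co-clustering matrix; 1 = perfectly
#' reproducible cluster structure across runs), the best residual sum of
#' squares, and the mean silhouette width of the sample-to-dominant-factor
#' assignment (distance = 1 - Pearson correlation of loading profiles),
#' averaged over starts.
#'
#' To make the best rss exactly non-increasing in rank, each rank beyond the
#' first candidate also gets one warm start: the best factorization of the
#' previous rank padded with one small extra factor, which multiplicative
#' updates can only improve.
#'
#' @param X intensity matrix.
#' @param ranks integer vector of candidate ranks (default 2:8).
#' @param n_starts random starts per rank (default 50).
#' @param seed integer seed.
#' @param max_iter,tol passed to [nmf_fit()].
#' @return object of class `rank_diagnostics`: data.frame with columns
#'   `rank`, `dispersion`, `rss`, `silhouette`; attribute `n_starts`.
#' @export
rank_diagnostics <- function(X, ranks = 2:8, n_starts = 50, seed = 1,
                             max_iter = 500, tol = 1e-5) {
  if (n_starts < 2) stop("n_starts must be >= 2")
  X <- .as_intensity(X)
  n <- ncol(X)
  out <- data.frame(rank = ranks, dispersion = NA_real_, rss = NA_real_,
                    silhouette = NA_real_)
  prev_best <- NULL
  for (ri in seq_along(ranks)) {
    r <- ranks[ri]
    consensus <- matrix(0, n, n)
    sil <- numeric(0)
    best <- NULL
    for (s in seq_len(n_starts)) {
      fit <- nmf_fit(X, r, init = "random", seed = seed + 1000 * ri + s,
                     max_iter = max_iter, tol = tol)
      assign <- apply(fit$loadings, 2, which.max)
      consensus <- consensus + outer(assign, assign, "==")
      sil <- c(sil, .loading_silhouette(fit$loadings, assign))
      if (is.null(best) || fit$rss < best$rss) best <- fit
    }
    if (!is.null(prev_best)) {
      pad_w <- matrix(.NMF_EPS, nrow(X), 1)
      pad_h <- matrix(.NMF_EPS, 1, n)
      warm <- nmf_fit(X, r, max_iter = max_iter, tol = tol,
                      init_values = list(W = cbind(prev_best$weights, pad_w),
                                         H = rbind(prev_best$loadings, pad_h)))
      if (warm$rss < best$rss) best <- warm
    }
    consensus <- consensus / n_starts
    out$dispersion[ri] <- mean(4 * (consensus - 0.5)^2)
    out$rss[ri] <- best$rss
    out$silhouette[ri] <- if (length(sil) > 0) mean(sil) else NA_real_
    prev_best <- best
  }
  attr(out, "n_starts") <- n_starts
  class(out) <- c("rank_diagnostics", "data.frame")
  out
}

# Mean silhouette of cluster assignment with d = 1 - cor(loading profiles);
# NA when fewer than two clusters are occupied.
.loading_silhouette <- function(H, assign) {
  if (length(unique(assign)) < 2) return(NA_real_)
  d <- stats::as.dist(1 - stats::cor(H))
  mean(cluster::silhouette(assign, d)[, "sil_width"])
}

#' Rescale signature weights by trinucleotide context frequencies
#'
#' Multiplies each class's weight by the genome frequency of its context, the
#' scaling used for plotting signatures and for comparison with catalogs
#' built on genome-scaled weights. The resulting scale is not directly
#' interpretable.
#'
#' @param weights 96 x k matrix (or 96-vector) of signature weights with
#'   class-label rownames/names.
#' @param trinuc_freqs named frequencies of the 32 canonical contexts, all
#'   positive.
#' @return rescaled weights of the same shape.
#' @export
rescale_signature <- function(weights, trinuc_freqs) {
  vec <- is.null(dim(weights))
  W <- if (vec) matrix(weights, ncol = 1,
                       dimnames = list(names(weights), NULL))
       else as.matrix(weights)
  ctx <- substr(rownames(W), 1, 3)
  miss <- setdiff(unique(ctx), names(trinuc_freqs))
  if (length(miss) > 0) {
    stop("missing context frequency for: ", paste(miss, collapse = ", "))
  }
  f <- trinuc_freqs[ctx]
  if (any(f <= 0)) stop("context frequencies must be positive")
  out <- W * f
  if (vec) setNames(as.numeric(out), rownames(W)) else out
}

# "A[C>A]A" (COSMIC style) -> "ACA>A"
.parse_cosmic_label <- function(x) {
  m <- regmatches(x, regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", x))
  vapply(m, function(p) {
    if (length(p) == 0) NA_character_
    else paste0(p[2], p[3], p[5], ">", p[4])
  }, character(1))
}

.normalize_class_labels <- function(labels) {
  cosmic <- grepl("\\[", labels)
  labels[cosmic] <- .parse_cosmic_label(labels[cosmic])
  if (anyNA(labels)) stop("unparseable class label(s)")
  labels
}

#' Read a signature catalog from TSV
#'
#' Expects 96 rows (class label in the first column, plain `"ACA>A"` or
#' COSMIC-style `"A[C>A]A"` labels) and one column per catalog signature.
#' Rows are reordered to [enumerate_classes()] order and columns normalized
#' to sum to 1.
#'
#' @param path TSV file.
#' @return matrix 96 x n_signatures with class-label rownames.
#' @export
read_catalog <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  labs <- .normalize_class_labels(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- labs
  all96 <- enumerate_classes()
  if (!setequal(labs, all96)) stop("catalog must cover the 96 classes")
  m <- m[all96, , drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Compare one signature with a catalog by Pearson correlation
#'
#' @param weights numeric 96-vector of signature weights (class-label names
#'   optional; [enumerate_classes()] order assumed if absent).
#' @param catalog matrix from [read_catalog()] (or any 96 x m matrix with
#'   matching row order).
#' @return data.frame with `name` and `rho`, sorted descending; the best
#'   match first.
#' @export
compare_catalog <- function(weights, catalog) {
  w <- as.numeric(weights)
  if (length(w) != nrow(catalog)) stop("class order/length mismatch")
  if (!is.null(names(weights)) && !is.null(rownames(catalog))) {
    if (!identical(names(weights), rownames(catalog))) {
      w <- as.numeric(weights[rownames(catalog)])
    }
  }
  if (stats::sd(w) == 0) stop("zero-variance signature: correlation undefined")
  rho <- apply(catalog, 2, function(cc) {
    if (stats::sd(cc) == 0) NA_real_ else stats::cor(w, cc)
  })
  out <- data.frame(name = colnames(catalog), rho = as.numeric(rho),
                    stringsAsFactors = FALSE)
  out[order(-out$rho, na.last = TRUE), , drop = FALSE]
}

#' Principal component analysis of the intensity matrix
#'
#' Scales each class row to unit variance (constant rows are dropped with a
#' message) and returns the principal components of the samples.
#'
#' @param X intensity matrix (classes x samples).
#' @return list with `scores` (samples x PCs), `rotation`, `sdev`,
#'   `dropped` (labels of constant rows).
#' @export
pca_spectrum <- function(X) {
  X <- .as_intensity(X)
  if (ncol(X) < 2) stop("need at least 2 samples for PCA")
  v <- apply(X, 1, stats::var)
  dropped <- rownames(X)[v == 0]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " constant row(s)")
    X <- X[v > 0, , drop = FALSE]
    v <- v[v > 0]
  }
  Xs <- X / sqrt(v)
  pr <- stats::prcomp(t(Xs), center = TRUE, scale. = FALSE)
  list(scores = pr$x, rotation = pr$rotation, sdev = pr$sdev,
       dropped = dropped)
}

#' Remove the shared CpG floor from a set of signatures
#'
#' For each CpG class (ancestral C immediately followed by G), subtracts the
#' minimum weight across signatures from every signature's weight in that
#' class, so at least one signature has weight 0 there. This corrects the
#' model-fitting artifact in which every factor absorbs a constant amount of
#' the dominant CpG classes. Non-CpG classes are untouched; the operation is
#' idempotent.
#'
#' @param signatures a `signature_set` from [nmf_fit()] (rank >= 2), or a
#'   96 x k weight matrix.
#' @return the input with corrected weights (a `signature_set` gains
#'   attribute `cpg_floor_removed`).
#' @export
subtract_cpg_floor <- function(signatures) {
  is_set <- inherits(signatures, "signature_set")
  W <- if (is_set) signatures$weights else as.matrix(signatures)
  if (ncol(W) < 2) stop("need rank >= 2 to define an across-signature floor")
  ct <- mutation_class_table()
  cpg_rows <- which(ct$cpg[match(rownames(W), ct$label)])
  if (length(cpg_rows) > 0) {
    mins <- apply(W[cpg_rows, , drop = FALSE], 1, min)
    W[cpg_rows, ] <- W[cpg_rows, ] - mins
  }
  if (is_set) {
    signatures$weights <- W
    attr(signatures, "cpg_floor_removed") <- TRUE
    signatures
  } else W
}
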