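#' Simulate a genealogy under the standard coalescent
#'
#' Simulates the genealogy of `n` haplotypes under the standard (constant
#' population size) coalescent. While `k` lineages remain, the waiting time to
#' the next coalescence is exponential with rate `k(k-1)/2` (each pair
#' coalesces at rate 1 per coalescent unit, i.e. 2Ne generations), and a
#' uniformly chosen pair of lineages merges.
#'
#' Nodes `1..n` are leaves (time 0); internal nodes `n+1..2n-1` are numbered
#' in coalescence order, the root being node `2n-1`.
#'
#' @param n number of haplotypes (leaves), at least 2.
#' @param seed optional integer seed for reproducibility.
#' @return object of class `coalescent_tree`: list with `n`, `parent`
#'   (integer vector, 0 for the root), `times` (node times in coalescent
#'   units), `children` (2 x (n-1) matrix of the pair merged at each internal
#'   node), `nleaf` (number of leaves below each node) and `rescaled_times`
#'   (NULL until [rescale_growth()] is applied).
#' @export
#' @examples
#' tr <- simulate_tree(4, seed = 1)
#' tr$times[7]  # root time
simulate_tree <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("n must be a single integer >= 2")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  times <- numeric(n_nodes)
  nleaf <- c(rep(1L, n), integer(n - 1L))
  children <- matrix(0L, nrow = 2L, ncol = n - 1L)
  active <- seq_len(n)
  t <- 0
  for (k in n:2) {
    t <- t + stats::rexp(1L, k * (k - 1) / 2)
    idx <- sample.int(k, 2L)
    node <- 2L * n - k + 1L
    pair <- active[idx]
    parent[pair] <- node
    times[node] <- t
    nleaf[node] <- nleaf[pair[1L]] + nleaf[pair[2L]]
    children[, node - n] <- pair
    active <- c(active[-idx], node)
  }
  structure(list(n = n, parent = parent, times = times, children = children,
                 nleaf = nleaf, rescaled_times = NULL),
            class = "coalescent_tree")
}

#' Exponential growth model for time rescaling
#'
#' Describes N-fold exponential population growth starting (backwards in
#' time) at `onset` coalescent units before the present, with growth rate
#' `g = log(fold) / onset`.
#'
#' @param fold N-fold growth factor, at least 1 (1 = constant size).
#' @param onset growth onset `s` in coalescent units, positive.
#' @return object of class `growth_model` with fields `fold`, `onset`,
#'   `rate`.
#' @export
growth_model <- function(fold, onset) {
  if (fold < 1) stop("fold must be >= 1")
  if (onset <= 0) stop("onset must be positive")
  structure(list(fold = fold, onset = onset, rate = log(fold) / onset),
            class = "growth_model")
}

#' Rescale coalescent node times for exponential growth
#'
#' Maps each standard-coalescent node time `t` to the growth-model time
#' `t' = (1/g)(exp(g t) - 1)` for `t <= s`, and
#' `t' = (1/g)(exp(g s) - 1) + (t - s)` for `t > s`, where `g = log(N)/s`
#' for N-fold growth starting at time `s`. The mapping is continuous and
#' strictly increasing; with `fold = 1` (g -> 0) it is the identity.
#'
#' @param tree a [simulate_tree()] result.
#' @param model a [growth_model()].
#' @return the tree with `rescaled_times` filled in.
#' @export
rescale_growth <- function(tree, model) {
  stopifnot(inherits(tree, "coalescent_tree"), inherits(model, "growth_model"))
  tree$rescaled_times <- growth_time_map(tree$times, model)
  tree$growth <- model
  tree
}

#' The growth time-rescaling map itself
#'
#' @param t numeric vector of standard-coalescent times.
#' @param model a [growth_model()].
#' @return rescaled times `t'`.
#' @export
growth_time_map <- function(t, model) {
  g <- model$rate
  s <- model$onset
  if (g == 0) return(t)
  ifelse(t <= s,
         (exp(g * t) - 1) / g,
         (exp(g * s) - 1) / g + (t - s))
}

# branch lengths for all non-root nodes; uses rescaled times when asked
.branch_lengths <- function(tree, use_rescaled = FALSE) {
  times <- if (use_rescaled) {
    if (is.null(tree$rescaled_times)) stop("tree has no rescaled times")
    tree$rescaled_times
  } else tree$times
  idx <- seq_len(2L * tree$n - 2L)
  times[tree$parent[idx]] - times[idx]
}

#' Leaves below a node of a coalescent tree
#' @param tree a [simulate_tree()] result.
#' @param node node index.
#' @return integer vector of leaf indices under `node` (the node itself if a
#'   leaf).
#' @export
leaf_set <- function(tree, node) {
  n <- tree$n
  if (node <= n) return(node)
  stack <- node
  leaves <- integer(0)
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n) leaves <- c(leaves, v)
    else stack <- c(stack, tree$children[, v - n])
  }
  sort(leaves)
}

# TRUE if node a is an ancestor of (or equal to) node b
.is_ancestor <- function(tree, a, b) {
  v <- b
  while (v != 0L) {
    if (v == a) return(TRUE)
    v <- tree$parent[v]
  }
  FALSE
}

#' Place mutations on a genealogy as a Poisson process
#'
#' On each branch, the number of mutations is Poisson with mean
#' `theta/2 * branch length`. Each mutation's carriers are the leaves below
#' the branch; its derived allele count is the size of that set.
#'
#' @param tree a [simulate_tree()] result.
#' @param theta population-scaled mutation rate (mean pairwise diversity
#'   scale); only the spectrum shape matters downstream, the default is 2.
#' @param use_rescaled use growth-rescaled branch lengths.
#' @param seed optional integer seed.
#' @return data.frame with one row per mutation: `branch` (node index below
#'   the mutated branch), `count` (derived allele count), and a list-column
#'   `carriers` of leaf index vectors.
#' @export
place_mutations <- function(tree, theta = 2, use_rescaled = FALSE, seed = NULL) {
  stopifnot(inherits(tree, "coalescent_tree"))
  if (theta <= 0) stop("theta must be positive")
  if (!is.null(seed)) set.seed(seed)
  len <- .branch_lengths(tree, use_rescaled)
  k <- stats::rpois(length(len), theta / 2 * len)
  branch <- rep(seq_along(len), k)
  out <- data.frame(branch = branch, count = tree$nleaf[branch])
  out$carriers <- lapply(branch, function(b) leaf_set(tree, b))
  out
}

#' Place repeat (recurrent) mutation events on a genealogy
#'
#' A repeat event consists of two independent mutation placements on the same
#' tree, each landing on a branch with probability proportional to its length;
#' the event's genotype vector is the OR (union) of the two carrier sets, so
#' nested and non-nested pairs are captured with their correct probabilities.
#' Events whose union covers every leaf are flagged `fixed` and are excluded
#' from segregating-site spectra.
#'
#' @inheritParams place_mutations
#' @param n_events number of repeat events; if NULL, Poisson with mean
#'   `theta/2 * total tree length`.
#' @return data.frame with one row per event: `count` (size of the union),
#'   `fixed` (logical), and a list-column `carriers`.
#' @export
or_repeat <- function(tree, theta = 2, use_rescaled = FALSE, seed = NULL,
                      n_events = NULL) {
  stopifnot(inherits(tree, "coalescent_tree"))
  if (!is.null(seed)) set.seed(seed)
  len <- .branch_lengths(tree, use_rescaled)
  if (is.null(n_events)) {
    n_events <- stats::rpois(1L, theta / 2 * sum(len))
  }
  if (n_events == 0) {
    return(data.frame(count = integer(0), fixed = logical(0)))
  }
  b1 <- sample.int(length(len), n_events, replace = TRUE, prob = len)
  b2 <- sample.int(length(len), n_events, replace = TRUE, prob = len)
  count <- integer(n_events)
  carriers <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    u <- .union_count(tree, b1[i], b2[i])
    count[i] <- u
    carriers[[i]] <- sort(union(leaf_set(tree, b1[i]), leaf_set(tree, b2[i])))
  }
  out <- data.frame(count = count, fixed = count == tree$n)
  out$carriers <- carriers
  out
}

# Union size of the leaf sets below two branches. In a tree two clades are
# either nested or disjoint, so no explicit set union is needed.
.union_count <- function(tree, a, b) {
  if (a == b) return(tree$nleaf[a])
  if (.is_ancestor(tree, a, b)) return(tree$nleaf[a])
  if (.is_ancestor(tree, b, a)) return(tree$nleaf[b])
  tree$nleaf[a] + tree$nleaf[b]
}

#' Pool site frequency spectra over independent genealogies
#'
#' Simulates `n_trees` independent coalescent trees of `n` haplotypes
#' (optionally time-rescaled for exponential growth), places single mutations
#' and/or repeat (recurrent) mutation events on each, and pools the derived
#' allele count spectra. Allele counts 0 and n (absent/fixed) are excluded.
#'
#' @param n haplotype sample size.
#' @param n_trees number of independent genealogies.
#' @param theta population-scaled mutation rate (shape-only; default 2).
#' @param model optional [growth_model()]; NULL for constant size.
#' @param kinds which spectra to compute: `"single"`, `"repeat"` or both.
#' @param seed optional integer seed.
#' @return list of objects of class `sfs` keyed by kind; each has `counts`
#'   (length n-1, by derived allele count), `kind`, `n`, `n_trees` and
#'   `n_fixed` (repeat events excluded as fixed).
#' @export
aggregate_sfs <- function(n, n_trees, theta = 2, model = NULL,
                          kinds = c("single", "repeat"), seed = NULL) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  use_rescaled <- !is.null(model)
  sfs_single <- numeric(n - 1)
  sfs_repeat <- numeric(n - 1)
  n_fixed <- 0L
  n_branch <- 2L * n - 2L
  for (i in seq_len(n_trees)) {
    tree <- simulate_tree(n)
    if (use_rescaled) tree <- rescale_growth(tree, model)
    len <- .branch_lengths(tree, use_rescaled)
    if ("single" %in% kinds) {
      k <- stats::rpois(n_branch, theta / 2 * len)
      nz <- which(k > 0L)
      if (length(nz) > 0) {
        tab <- rowsum(k[nz], tree$nleaf[nz])
        cnt <- as.integer(rownames(tab))
        keep <- cnt < n
        sfs_single[cnt[keep]] <- sfs_single[cnt[keep]] + tab[keep]
      }
    }
    if ("repeat" %in% kinds) {
      m <- stats::rpois(1L, theta / 2 * sum(len))
      if (m > 0) {
        b1 <- sample.int(n_branch, m, replace = TRUE, prob = len)
        b2 <- sample.int(n_branch, m, replace = TRUE, prob = len)
        for (j in seq_len(m)) {
          u <- .union_count(tree, b1[j], b2[j])
          if (u >= n) n_fixed <- n_fixed + 1L
          else sfs_repeat[u] <- sfs_repeat[u] + 1
        }
      }
    }
  }
  out <- list()
  if ("single" %in% kinds) {
    out$single <- structure(list(counts = sfs_single, kind = "single", n = n,
                                 n_trees = n_trees, n_fixed = 0L),
                            class = "sfs")
  }
  if ("repeat" %in% kinds) {
    out$`repeat` <- structure(list(counts = sfs_repeat, kind = "repeat", n = n,
                                   n_trees = n_trees, n_fixed = n_fixed),
                              class = "sfs")
  }
  out
}

#' Scale an SFS by the constant-size single-mutation expectation
#'
#' Divides each entry of the normalized spectrum by `1/i` scaled to unit sum
#' over `i = 1..n-1` (the expected frequency of single mutations under
#' constant size), the scaling used for plotting growth spectra.
#'
#' @param sfs an `sfs` object.
#' @return data.frame with `allele_count`, `proportion`, `scaled`.
#' @export
scale_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "sfs"))
  i <- seq_len(sfs$n - 1)
  p <- sfs$counts / sum(sfs$counts)
  expect <- (1 / i) / sum(1 / i)
  data.frame(allele_count = i, proportion = p, scaled = p / expect)
}

#' Model the CpG proportion of variants by allele count
#'
#' Mixes a single-mutation spectrum S and a repeat-mutation spectrum R
#' (each normalized to unit total within kind) under the assumptions that a
#' fraction `frac_cpg` of all mutations are CpGs and a fraction `frac_repeat`
#' of CpG mutations are repeat mutations. The proportion of variants at
#' allele count i that are CpG is
#' `P_i = frac_cpg ((1-frac_repeat) S_i + frac_repeat R_i) /
#'   [frac_cpg ((1-frac_repeat) S_i + frac_repeat R_i) + (1-frac_cpg) S_i]`.
#' Counts where both spectra are empty give NA.
#'
#' @param sfs_single,sfs_repeat `sfs` objects on the same `n`.
#' @param frac_cpg fraction of all mutations at CpG sites (default 0.15).
#' @param frac_repeat fraction of CpG mutations that are repeat mutations
#'   (default 0.10).
#' @return data.frame with `allele_count` and `p_cpg`.
#' @export
cpg_proportion_model <- function(sfs_single, sfs_repeat,
                                 frac_cpg = 0.15, frac_repeat = 0.10) {
  stopifnot(inherits(sfs_single, "sfs"), inherits(sfs_repeat, "sfs"))
  if (sfs_single$n != sfs_repeat$n) stop("spectra must share the same n")
  S <- sfs_single$counts
  R <- sfs_repeat$counts
  if (sum(S) > 0) S <- S / sum(S)
  if (sum(R) > 0) R <- R / sum(R)
  cpg <- frac_cpg * ((1 - frac_repeat) * S + frac_repeat * R)
  tot <- cpg + (1 - frac_cpg) * S
  p <- ifelse(tot > 0, cpg / tot, NA_real_)
  data.frame(allele_count = seq_along(S), p_cpg = p)
}

#' Convert coalescent-unit times to years
#'
#' One coalescent unit is `2 Ne` generations for diploids, so
#' `years = s * 2 * Ne * generation_years`.
#'
#' @param s time in coalescent units.
#' @param Ne effective population size (diploid).
#' @param generation_years years per generation.
#' @return time in years.
#' @export
#' @examples
#' coalescent_to_years(0.01, 15000, 30)  # 9000
coalescent_to_years <- function(s, Ne, generation_years) {
  if (any(s < 0) || Ne <= 0 || generation_years <= 0) {
    stop("s must be >= 0 and Ne, generation_years positive")
  }
  s * 2 * Ne * generation_years
}
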