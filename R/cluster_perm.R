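#' Set of 2D spatial maps with group labels
#'
#' Container for per-subject 2D maps (e.g. space-covered occupancy grids)
#' belonging to two conditions, the input of the cluster-based permutation
#' test.
#'
#' @param maps numeric array `n_subjects x H x W`, or a list of `H x W`
#'   matrices.
#' @param labels character/factor vector of length `n_subjects` with exactly
#'   two levels; both must be non-empty.
#' @param mask optional `H x W` logical matrix of valid cells (default all
#'   valid).
#' @return An object of class `"spatial_map_set"`.
#' @export
spatial_map_set <- function(maps, labels, mask = NULL) {
  if (is.list(maps)) {
    dims <- dim(maps[[1L]])
    maps <- aperm(simplify2array(maps), c(3L, 1L, 2L))
    stopifnot(all(dim(maps)[2:3] == dims))
  }
  stopifnot(is.array(maps), length(dim(maps)) == 3L)
  labels <- as.character(labels)
  if (length(labels) != dim(maps)[1L])
    stop("one label per map row required")
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("exactly two condition labels required (got ", length(lv), ")")
  if (min(table(labels)) < 2L)
    stop("precondition error: each condition needs >= 2 maps")
  H <- dim(maps)[2L]; W <- dim(maps)[3L]
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  stopifnot(all(dim(mask) == c(H, W)))
  structure(list(maps = maps, labels = labels, levels = lv, mask = mask,
                 H = H, W = W),
            class = "spatial_map_set")
}

# flatten maps to n x (H*W), column-major over (row, col)
flatten_maps <- function(set) {
  matrix(set$maps, nrow = dim(set$maps)[1L])
}

# pooled-variance two-sample t per column of an n x m matrix, given logical
# group-1 selector; returns list(t, mask of defined cells)
pooled_t_cols <- function(X, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  ss1 <- colSums(X[g1, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X[!g1, , drop = FALSE]^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  list(t = t, defined = se > 0)
}

#' Pointwise two-sample t map
#'
#' Computes the per-cell two-sample t statistic (pooled variance,
#' `df = n1 + n2 - 2`) between the two conditions of a map set. Cells with
#' zero variance in both groups are masked (set to `NA`). A Welch variant is
#' available but the pooled statistic is the default used by the permutation
#' test.
#'
#' @param set a [spatial_map_set()].
#' @param welch use Welch's unequal-variance t instead of pooled variance.
#' @return `H x W` matrix of t values (`NA` where masked), with attribute
#'   `df`.
#' @export
pointwise_t_map <- function(set, welch = FALSE) {
  stopifnot(inherits(set, "spatial_map_set"))
  X <- flatten_maps(set)
  g1 <- set$labels == set$levels[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (welch) {
    m1 <- colMeans(X[g1, , drop = FALSE])
    m2 <- colMeans(X[!g1, , drop = FALSE])
    v1 <- apply(X[g1, , drop = FALSE], 2, stats::var)
    v2 <- apply(X[!g1, , drop = FALSE], 2, stats::var)
    se <- sqrt(v1 / n1 + v2 / n2)
    tv <- (m1 - m2) / se
    tv[se == 0] <- NA_real_
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    pt <- pooled_t_cols(X, g1)
    tv <- pt$t
    tv[!pt$defined] <- NA_real_
    df <- n1 + n2 - 2
  }
  tv[!as.vector(set$mask)] <- NA_real_
  tm <- matrix(tv, set$H, set$W)
  attr(tm, "df") <- df
  tm
}

# connected components (4-connectivity) of a logical matrix; returns list of
# integer cell-index vectors (column-major indices into the matrix)
connected_components <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  comps <- list()
  nxt <- 0L
  idx <- which(bin)
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      r <- (cur - 1L) %% H + 1L
      cc <- (cur - 1L) %/% H + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc2 <- cc + d[2L]
        if (rr >= 1L && rr <= H && cc2 >= 1L && cc2 <= W) {
          ni <- rr + (cc2 - 1L) * H
          if (bin[ni] && lab[ni] == 0L) {
            lab[ni] <- nxt
            stack <- c(stack, ni)
          }
        }
      }
    }
    comps[[nxt]] <- sort(members)
  }
  comps
}

#' Form suprathreshold clusters from a t map
#'
#' Thresholds a t map at the two-sided critical value for the cluster-forming
#' p, then extracts 4-connected components separately for positive and
#' negative t. Components smaller than `min_size` cells are discarded (the
#' spatial extent rule: a cluster must have at least 2 adjacent
#' suprathreshold points). Each cluster's mass is the sum of |t| over its
#' member cells.
#'
#' @param t_map `H x W` t matrix (as from [pointwise_t_map()]); `NA` cells
#'   are never suprathreshold.
#' @param df degrees of freedom for the p-to-t conversion; defaults to the
#'   map's `df` attribute.
#' @param threshold_p two-sided cluster-forming threshold (default 0.01).
#' @param min_size minimum cluster extent in cells (default 2).
#' @return list of clusters, each a list with `cells` (column-major indices),
#'   `sign` (+1/-1), and `mass` (sum of |t|); ordered by decreasing mass.
#' @export
form_clusters <- function(t_map, df = NULL, threshold_p = 0.01,
                          min_size = 2L) {
  if (is.null(df)) df <- attr(t_map, "df")
  if (is.null(df)) stop("degrees of freedom required for the threshold")
  t_crit <- stats::qt(1 - threshold_p / 2, df = df)
  out <- list()
  for (sgn in c(1, -1)) {
    bin <- !is.na(t_map) & (sgn * t_map) > t_crit
    comps <- connected_components(bin)
    for (cells in comps) {
      if (length(cells) < min_size) next
      out[[length(out) + 1L]] <- list(cells = cells, sign = sgn,
                                      mass = sum(abs(t_map[cells])))
    }
  }
  if (length(out))
    out <- out[order(vapply(out, `[[`, numeric(1), "mass"),
                     decreasing = TRUE)]
  out
}

# max cluster mass of a flattened t vector (NA-safe), given precomputed
# critical t; avoids matrix attr bookkeeping in the permutation loop
max_cluster_mass <- function(tv, H, W, t_crit, min_size) {
  best <- 0
  for (sgn in c(1, -1)) {
    sel <- !is.na(tv) & (sgn * tv) > t_crit
    if (sum(sel) < min_size) next
    comps <- connected_components(matrix(sel, H, W))
    for (cells in comps) {
      if (length(cells) < min_size) next
      m <- sum(abs(tv[cells]))
      if (m > best) best <- m
    }
  }
  best
}

#' Cluster-based permutation test on 2D spatial maps
#'
#' Nonparametric two-sample test between two conditions of per-subject 2D
#' maps that controls for multiple comparisons while respecting spatial
#' dependence. Clusters of adjacent cells exceeding the cluster-forming
#' threshold are summarised by their mass (sum of |t|), and each observed
#' cluster mass is compared against the null distribution of the maximum
#' cluster mass obtained by shuffling condition labels across rows.
#' Permutation p-values use the +1 convention,
#' `p = (1 + #(perm max >= observed)) / (n_perm + 1)`, so they are never
#' exactly zero. The test is deterministic given `seed`.
#'
#' @param set a [spatial_map_set()].
#' @param n_perm number of label permutations (default 5000).
#' @param seed RNG seed for the permutations.
#' @param threshold_p cluster-forming threshold, two-sided (default 0.01).
#' @param min_size minimum cluster extent in cells (default 2).
#' @param alpha significance level reported for convenience (default 0.05).
#' @return An object of class `"cluster_result"`: list with `clusters` (each
#'   with `cells`, `sign`, `mass`, `p_value`), `t_map`, `df`,
#'   `null_max_mass`, `n_permutations`, `threshold_p`, `alpha`,
#'   `any_significant`.
#' @export
permutation_test <- function(set, n_perm = 5000L, seed = 1L,
                             threshold_p = 0.01, min_size = 2L,
                             alpha = 0.05) {
  stopifnot(inherits(set, "spatial_map_set"))
  if (n_perm < 2L) stop("n_perm must be >= 2")
  if (n_perm < 100L)
    warning("n_perm < 100 gives a very coarse p-value resolution")
  X <- flatten_maps(set)
  n <- nrow(X)
  g1_obs <- set$labels == set$levels[1L]
  n1 <- sum(g1_obs)
  df <- n - 2L
  t_crit <- stats::qt(1 - threshold_p / 2, df = df)
  mask_v <- as.vector(set$mask)

  t_of <- function(g1) {
    pt <- pooled_t_cols(X, g1)
    tv <- pt$t
    tv[!pt$defined | !mask_v] <- NA_real_
    tv
  }
  tv_obs <- t_of(g1_obs)
  t_map <- matrix(tv_obs, set$H, set$W)
  attr(t_map, "df") <- df
  clusters <- form_clusters(t_map, df = df, threshold_p = threshold_p,
                            min_size = min_size)

  null_max <- numeric(n_perm)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
            assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    g1 <- logical(n)
    g1[sample.int(n, n1)] <- TRUE
    null_max[b] <- max_cluster_mass(t_of(g1), set$H, set$W, t_crit, min_size)
  }
  for (i in seq_along(clusters)) {
    m <- clusters[[i]]$mass
    clusters[[i]]$p_value <- (1 + sum(null_max >= m)) / (n_perm + 1)
  }
  structure(list(clusters = clusters, t_map = t_map, df = df,
                 null_max_mass = null_max, n_permutations = n_perm,
                 threshold_p = threshold_p, alpha = alpha,
                 any_significant = length(clusters) > 0 &&
                   any(vapply(clusters, `[[`, numeric(1), "p_value") <
                         alpha)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations, df = %d\n",
              length(x$clusters), x$n_permutations, x$df))
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: %d cells, mass %.2f, p = %.4g\n",
                if (cl$sign > 0) "positive" else "negative",
                length(cl$cells), cl$mass, cl$p_value))
  invisible(x)
}
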