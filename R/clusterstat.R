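## Nonparametric cluster-based permutation comparison of two epoch sets
## across contacts and time (max-cluster-mass null).

## Fast pooled-variance two-sample t over all (contact, time) cells.
## X: trials x cells matrices flattened from the epoch arrays. Group
## sums via one BLAS matrix-vector product per moment, with the totals
## precomputable across permutations.
.tmap_from_flat <- function(X, labA, X2 = X^2,
                            tot1 = colSums(X), tot2 = colSums(X2)) {
  nA <- sum(labA); nB <- length(labA) - nA
  w <- as.numeric(labA)
  s1A <- drop(w %*% X)
  s2A <- drop(w %*% X2)
  s1B <- tot1 - s1A
  s2B <- tot2 - s2A
  mA <- s1A / nA; mB <- s1B / nB
  sp2 <- ((s2A - nA * mA^2) + (s2B - nB * mB^2)) / (nA + nB - 2)
  (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
}

.flatten_epochs <- function(epochs) {
  d <- epochs$data[epochs$keep_mask, , , drop = FALSE]
  matrix(d, nrow = dim(d)[1])  # cells ordered contact-fastest, then time
}

#' Pointwise t map between two epoch sets
#'
#' Unpaired pooled-variance two-sample t statistic at every (contact,
#' time) cell over the kept trials of both conditions.
#'
#' @param epochsA,epochsB `epoch_set`s on identical contact/time axes.
#' @return a `t_map`: `t [contacts x time]`, `df`, `n_A`, `n_B`, `t_ms`.
#' @export
pointwise_tmap <- function(epochsA, epochsB) {
  if (!identical(dim(epochsA$data)[-1], dim(epochsB$data)[-1]) ||
      !identical(epochsA$t_ms, epochsB$t_ms))
    stop("epoch sets have mismatching contact/time axes")
  nA <- sum(epochsA$keep_mask); nB <- sum(epochsB$keep_mask)
  if (nA < 2 || nB < 2) stop("need at least 2 kept trials per condition")
  X <- rbind(.flatten_epochs(epochsA), .flatten_epochs(epochsB))
  tv <- .tmap_from_flat(X, c(rep(TRUE, nA), rep(FALSE, nB)))
  nc <- dim(epochsA$data)[2]
  structure(list(t = matrix(tv, nrow = nc), df = nA + nB - 2,
                 n_A = nA, n_B = nB, t_ms = epochsA$t_ms),
            class = "t_map")
}

## Connected supra-threshold clusters from a logical matrix
## [contacts x time]: runs of consecutive time samples within a contact,
## merged across neighboring contacts when they overlap in time
## (spatiotemporal adjacency). Union-find over runs.
.label_clusters <- function(supra, spatial) {
  nc <- nrow(supra); nt <- ncol(supra)
  runs <- list(); run_contact <- integer(0)
  for (i in seq_len(nc)) {
    r <- rle(supra[i, ])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    sel <- which(r$values)
    for (s in sel) {
      runs[[length(runs) + 1]] <- c(starts[s], ends[s])
      run_contact <- c(run_contact, i)
    }
  }
  n_r <- length(runs)
  if (!n_r) return(list())
  parent <- seq_len(n_r)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (spatial && n_r > 1) {
    for (a in seq_len(n_r - 1)) for (b in (a + 1):n_r) {
      if (abs(run_contact[a] - run_contact[b]) != 1) next
      if (runs[[a]][1] <= runs[[b]][2] && runs[[b]][1] <= runs[[a]][2]) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n_r), find, integer(1))
  lapply(unique(roots), function(rt) {
    members <- which(roots == rt)
    do.call(rbind, lapply(members, function(m)
      cbind(contact = run_contact[m],
            time = runs[[m]][1]:runs[[m]][2])))
  })
}

#' Find supra-threshold clusters in a t map
#'
#' Cells with `|t|` above the two-sided cluster-forming threshold
#' (pointwise alpha on the t distribution with the map's df) are grouped
#' along adjacent time samples within a contact and, under
#' `"spatiotemporal"` adjacency (default), across neighboring contacts
#' at overlapping times. Positive and negative clusters are kept
#' separate; each cluster's mass is the sum of its member t values.
#'
#' @param tmap a `t_map`.
#' @param forming_alpha pointwise two-sided alpha forming the threshold.
#' @param adjacency `"spatiotemporal"` or `"temporal"`.
#' @return list of clusters, each `list(cells, mass, sign)`; attribute
#'   `threshold` carries the forming threshold.
#' @export
find_clusters <- function(tmap, forming_alpha = 0.05,
                          adjacency = c("spatiotemporal", "temporal")) {
  adjacency <- match.arg(adjacency)
  if (forming_alpha <= 0 || forming_alpha >= 1)
    stop("forming_alpha must be in (0, 1)")
  if (!all(is.finite(tmap$t))) stop("non-finite t values")
  thr <- stats::qt(1 - forming_alpha / 2, df = tmap$df)
  spatial <- adjacency == "spatiotemporal"
  out <- list()
  for (sgn in c(1, -1)) {
    cl <- .label_clusters(sgn * tmap$t > thr, spatial)
    for (cells in cl) {
      mass <- sum(tmap$t[cells])
      out[[length(out) + 1]] <- list(cells = cells, mass = mass, sign = sgn)
    }
  }
  attr(out, "threshold") <- thr
  out
}

## Max |cluster mass| of a t vector reshaped to the map grid; the fast
## inner step of the permutation null.
.max_cluster_mass <- function(tv, nc, thr, spatial) {
  tm <- matrix(tv, nrow = nc)
  best <- 0
  for (sgn in c(1, -1)) {
    cl <- .label_clusters(sgn * tm > thr, spatial)
    for (cells in cl) best <- max(best, abs(sum(tm[cells])))
  }
  best
}

#' Cluster-based permutation test between two conditions
#'
#' Observed clusters come from [pointwise_tmap()] + [find_clusters()].
#' Each permutation shuffles the condition labels across the pooled kept
#' trials and records the maximum absolute cluster mass; cluster
#' `p = (#{null >= |mass|} + 1) / (n_perm + 1)`, significant iff
#' `p < alpha`.
#'
#' @param epochsA,epochsB `epoch_set`s on identical axes.
#' @param n_perm permutation count (>= 100; default 2000).
#' @param alpha cluster-level critical value (default 0.01).
#' @param forming_alpha pointwise cluster-forming alpha (default 0.05).
#' @param adjacency `"spatiotemporal"` (default) or `"temporal"`.
#' @param seed RNG seed for the label shuffles.
#' @return a `cluster_result`: `clusters` (each with `cells, mass, sign,
#'   p, significant`), `table` (data frame for export), `n_perm, alpha,
#'   adjacency, threshold`.
#' @export
cluster_permutation_test <- function(epochsA, epochsB, n_perm = 2000,
                                     alpha = 0.01, forming_alpha = 0.05,
                                     adjacency = c("spatiotemporal",
                                                   "temporal"),
                                     seed = 1L) {
  adjacency <- match.arg(adjacency)
  if (n_perm < 100) stop("n_perm must be >= 100")
  tmap <- pointwise_tmap(epochsA, epochsB)
  clusters <- find_clusters(tmap, forming_alpha, adjacency)
  thr <- attr(clusters, "threshold")
  nc <- dim(epochsA$data)[2]
  spatial <- adjacency == "spatiotemporal"
  X <- rbind(.flatten_epochs(epochsA), .flatten_epochs(epochsB))
  X2 <- X^2
  tot1 <- colSums(X); tot2 <- colSums(X2)
  nA <- tmap$n_A; ntot <- nrow(X)
  set.seed(seed)
  null_mass <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    lab <- logical(ntot)
    lab[sample.int(ntot, nA)] <- TRUE
    null_mass[b] <- .max_cluster_mass(
      .tmap_from_flat(X, lab, X2, tot1, tot2), nc, thr, spatial)
  }
  tab <- NULL
  for (i in seq_along(clusters)) {
    m <- abs(clusters[[i]]$mass)
    p <- (sum(null_mass >= m) + 1) / (n_perm + 1)
    clusters[[i]]$p <- p
    clusters[[i]]$significant <- p < alpha
    cells <- clusters[[i]]$cells
    tab <- rbind(tab, data.frame(
      cluster = i, sign = clusters[[i]]$sign,
      contact_min = min(cells[, "contact"]),
      contact_max = max(cells[, "contact"]),
      time_min_ms = tmap$t_ms[min(cells[, "time"])],
      time_max_ms = tmap$t_ms[max(cells[, "time"])],
      n_cells = nrow(cells), mass = clusters[[i]]$mass,
      p = p, significant = p < alpha, adjacency = adjacency))
  }
  structure(list(clusters = clusters, table = tab, n_perm = n_perm,
                 alpha = alpha, adjacency = adjacency, threshold = thr,
                 null_mass = null_mass, tmap = tmap),
            class = "cluster_result")
}
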