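#' Signed maxmean gene-set statistic
#'
#' With per-gene scores z restricted to the set, let
#' `s+ = mean(max(z, 0))` and `s- = mean(max(-z, 0))` (means over the whole
#' set). The statistic is `s+` when `s+ >= s-` and `-s-` otherwise, so its
#' sign indicates the dominant direction of the set's regulation.
#'
#' @param set_genes Character vector of gene ids.
#' @param scores Named numeric vector of per-gene scores.
#' @return Signed maxmean score.
#' @export
maxmean <- function(set_genes, scores) {
  z <- scores[intersect(unique(set_genes), names(scores))]
  if (length(z) == 0)
    stop("data error: gene set is empty after restriction to scored genes",
         call. = FALSE)
  s_pos <- mean(pmax(z, 0))
  s_neg <- mean(pmax(-z, 0))
  if (s_pos >= s_neg) s_pos else -s_neg
}

# maxmean for many equally-sized random index sets at once; idx is an
# m x K matrix of row indices into z
maxmean_many <- function(z, idx) {
  zp <- pmax(z, 0); zn <- pmax(-z, 0)
  sp <- colMeans(matrix(zp[idx], nrow = nrow(idx)))
  sn <- colMeans(matrix(zn[idx], nrow = nrow(idx)))
  ifelse(sp >= sn, sp, -sn)
}

#' Gene Set Analysis with restandardization and permutation p-values
#'
#' Per-gene scores are the SAM d-statistics of [sam_statistic()]. For each
#' set, the observed maxmean is standardized ("restandardized") by the mean
#' and SD of maxmean over random gene sets of the same size drawn from all
#' scored genes (row randomization). The same construction is applied under
#' each sample-label permutation, and the two-sided p-value is the fraction
#' of permutations whose standardized score is at least as extreme
#' (with the +1 correction). FDR is the permutation ratio: the average
#' permutation count of sets scoring beyond |z_k|, divided by the observed
#' count.
#'
#' @param catalog A `gene_set_catalog`.
#' @param matrix Genes x samples expression matrix.
#' @param labels Two-group labels.
#' @param n_perm Number of label permutations (a warning below 50:
#'   unstable p).
#' @param seed Integer seed.
#' @param n_random_sets Random sets per size for restandardization.
#' @param p_significant Significance threshold on p (default 0.01).
#' @param s0 SAM fudge factor; estimated when NULL.
#' @return Data frame (name, size, score, z, p, fdr, significant), ordered
#'   by |z| decreasing.
#' @export
gsa <- function(catalog, matrix, labels, n_perm = 200, seed = 1L,
                n_random_sets = 1000, p_significant = 0.01, s0 = NULL) {
  stopifnot(inherits(catalog, "gene_set_catalog"))
  if (n_perm < 50)
    warning("n_perm < 50: permutation p-values will be unstable")
  labels <- as_group_factor(labels)
  genes <- rownames(matrix)
  sets <- lapply(catalog$sets, function(g) which(genes %in% g))
  keep <- vapply(sets, length, 0L) > 0
  if (any(!keep))
    warning("skipping sets empty after restriction: ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  if (length(sets) == 0)
    stop("data error: no non-empty gene sets", call. = FALSE)
  sizes <- vapply(sets, length, 0L)
  usizes <- sort(unique(sizes))

  scores0 <- sam_statistic(matrix, labels, s0 = if (is.null(s0)) 0 else s0)
  if (is.null(s0)) s0 <- estimate_s0(scores0$s, scores0$numerator)
  G <- nrow(matrix)
  n <- ncol(matrix)
  n1 <- sum(labels == levels(labels)[1])

  set.seed(seed)
  # fixed random index sets per size, reused across permutations
  rand_idx <- lapply(usizes, function(m)
    vapply(seq_len(n_random_sets), function(i) sample.int(G, m), integer(m)))
  names(rand_idx) <- as.character(usizes)

  standardized <- function(d) {
    obs <- vapply(sets, function(ix) {
      z <- d[ix]
      sp <- mean(pmax(z, 0)); sn <- mean(pmax(-z, 0))
      if (sp >= sn) sp else -sn
    }, 0)
    z <- numeric(length(sets))
    for (m in usizes) {
      rnd <- maxmean_many(d, matrix(rand_idx[[as.character(m)]], nrow = m))
      sel <- sizes == m
      z[sel] <- (obs[sel] - mean(rnd)) / stats::sd(rnd)
    }
    list(score = obs, z = z)
  }

  d_obs <- d_for_split(matrix, which(labels == levels(labels)[1]), s0)
  obs <- standardized(d_obs)

  perms <- label_permutations(n, n1, n_perm, seed)
  B <- nrow(perms)
  zperm <- matrix(0, length(sets), B)
  for (b in seq_len(B))
    zperm[, b] <- standardized(d_for_split(matrix, perms[b, ], s0))$z

  absz <- abs(obs$z)
  p <- (1 + rowSums(abs(zperm) >= absz - 1e-12)) / (B + 1)
  n_beyond_obs <- vapply(absz, function(a) sum(absz >= a - 1e-12), 0)
  n_beyond_perm <- vapply(absz, function(a)
    sum(abs(zperm) >= a - 1e-12) / B, 0)
  fdr <- pmin(n_beyond_perm / n_beyond_obs, 1)

  res <- data.frame(name = names(sets), size = sizes, score = obs$score,
                    z = obs$z, p = p, fdr = fdr,
                    significant = p < p_significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(-abs(res$z)), ]
}

#' Consensus signature across significant gene sets
#'
#' Genes appearing in at least `min_fraction` of the sets form the consensus
#' signature; the membership cutoff is the smallest integer count at or
#' above `min_fraction * n_sets` (so 25% of 23 sets requires membership in
#' at least 6).
#'
#' @param sets Named list of character vectors (or a `gene_set_catalog`).
#' @param min_fraction Required fraction of sets, in (0, 1].
#' @return List with `min_fraction`, `n_sets`, `min_count`, and `members`
#'   (data frame gene_id, count, ordered by count decreasing).
#' @export
consensus_signature <- function(sets, min_fraction = 0.25) {
  if (inherits(sets, "gene_set_catalog")) sets <- sets$sets
  if (length(sets) < 1)
    stop("data error: at least one gene set required", call. = FALSE)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("configuration error: min_fraction must be in (0, 1]", call. = FALSE)
  n_sets <- length(sets)
  min_count <- as.integer(ceiling(min_fraction * n_sets - 1e-9))
  counts <- table(unlist(lapply(sets, unique)))
  members <- data.frame(gene_id = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  members <- members[members$count >= min_count, ]
  members <- members[order(-members$count, members$gene_id), ]
  rownames(members) <- NULL
  list(min_fraction = min_fraction, n_sets = n_sets,
       min_count = min_count, members = members)
}

#' Direction-matched intersection of two signed gene lists
#'
#' @param list_a,list_b Data frames with columns gene_id and direction
#'   (values "up"/"down").
#' @return Data frame (gene_id, direction) of genes present in both lists
#'   with the same direction.
#' @export
directional_overlap <- function(list_a, list_b) {
  for (l in list(list_a, list_b)) {
    if (!all(c("gene_id", "direction") %in% names(l)))
      stop("data error: lists need gene_id and direction columns",
           call. = FALSE)
    if (!all(l$direction %in% c("up", "down")))
      stop("data error: direction must be up or down", call. = FALSE)
  }
  m <- merge(list_a[c("gene_id", "direction")],
             list_b[c("gene_id", "direction")], by = "gene_id")
  m <- m[m$direction.x == m$direction.y, ]
  res <- data.frame(gene_id = m$gene_id, direction = m$direction.x,
                    stringsAsFactors = FALSE)
  res[order(res$gene_id), , drop = FALSE]
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n) (k successes when drawing n
#' from a universe of N containing K). Summation is done in log space for
#' numerical stability.
#'
#' @param N Universe size.
#' @param K Number of "special" elements.
#' @param n Draw size.
#' @param k Observed successes.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (N < 0 || K < 0 || n < 0 || k < 0 || K > N || n > N)
    stop("data error: inconsistent hypergeometric counts", call. = FALSE)
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  lo_i <- pmax(0, n - (N - K))
  i <- i[i >= lo_i]
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Overlap of two signed gene lists with a hypergeometric p-value
#'
#' The direction-matched intersection is tested against the upper tail of
#' the hypergeometric distribution with the two list sizes as margins over
#' a universe of `n_universe` genes (by default the genes present in both
#' analyses).
#'
#' @param list_a,list_b Signed gene lists as in [directional_overlap()].
#' @param n_universe Universe size.
#' @return List with n_universe, size_a, size_b, k_observed, p_hypergeom,
#'   and the overlapping genes.
#' @export
overlap_test <- function(list_a, list_b, n_universe) {
  ov <- directional_overlap(list_a, list_b)
  size_a <- length(unique(list_a$gene_id))
  size_b <- length(unique(list_b$gene_id))
  k <- nrow(ov)
  list(n_universe = n_universe, size_a = size_a, size_b = size_b,
       k_observed = k,
       p_hypergeom = hypergeom_tail(n_universe, size_a, size_b, k),
       genes = ov)
}

#' Right-tailed Fisher's exact enrichment of a gene list in a set
#'
#' Builds the 2x2 table of hit/set membership over the universe and returns
#' the right-tailed exact p (equal to the hypergeometric upper tail at the
#' observed intersection) together with the sample odds ratio; 0.5 is added
#' to every cell only when some cell is zero.
#'
#' @param hits,set Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of gene ids.
#' @return List with `odds_ratio`, `p`, and `table` (2x2 matrix).
#' @export
fisher_enrichment <- function(hits, set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0)
    stop("data error: empty universe", call. = FALSE)
  hits <- unique(hits); set <- unique(set)
  if (!all(hits %in% universe) || !all(set %in% universe))
    stop("data error: hits and set must be subsets of the universe",
         call. = FALSE)
  a <- length(intersect(hits, set))
  b <- length(setdiff(hits, set))
  cc <- length(setdiff(set, hits))
  d <- length(universe) - a - b - cc
  p <- hypergeom_tail(length(universe), length(set), length(hits), a)
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(hit = c("yes", "no"),
                                in_set = c("yes", "no")))
  cont <- if (any(tab == 0)) 0.5 else 0
  or <- (a + cont) * (d + cont) / ((b + cont) * (cc + cont))
  list(odds_ratio = or, p = p, table = tab)
}
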