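# Independent, deliberately naive reference implementations used as oracles.

# O(n^3) Lance-Williams agglomeration returning the cophenetic matrix of
# merge heights (average = UPGMA, complete, ward = ward.D2 recurrence).
naive_cophenetic <- function(d, method) {
  d <- as.matrix(d)
  labs <- rownames(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  act <- rep(TRUE, n)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  cur <- d
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    idx <- which(act)
    for (i in idx) for (j in idx) if (i < j && cur[i, j] < bestv) {
      bestv <- cur[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- bestv
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(act)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      cur[i, k] <- cur[k, i] <- switch(method,
        average = (ni * cur[i, k] + nj * cur[j, k]) / (ni + nj),
        complete = max(cur[i, k], cur[j, k]),
        ward = sqrt(((ni + nk) * cur[i, k]^2 + (nj + nk) * cur[j, k]^2 -
                       nk * bestv^2) / (ni + nj + nk)))
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- ni + nj
    act[j] <- FALSE
  }
  coph
}

# naive Lloyd k-means with random restarts; returns best inertia
naive_lloyd <- function(points, k, n_init, seed) {
  points <- as.matrix(points)
  best <- Inf
  set.seed(seed)
  for (rep in seq_len(n_init)) {
    cent <- points[sample(nrow(points), k), , drop = FALSE]
    for (it in 1:100) {
      dm <- outer(seq_len(nrow(points)), seq_len(k), Vectorize(function(i, j)
        sum((points[i, ] - cent[j, ])^2)))
      cl <- max.col(-dm)
      newc <- cent
      for (j in seq_len(k))
        if (any(cl == j)) newc[j, ] <- colMeans(points[cl == j, , drop = FALSE])
      if (all(abs(newc - cent) < 1e-12)) break
      cent <- newc
    }
    inertia <- sum(vapply(seq_len(nrow(points)), function(i)
      sum((points[i, ] - cent[cl[i], ])^2), numeric(1)))
    if (inertia < best) best <- inertia
  }
  best
}

# direct evaluation of the Weir-Cockerham component formulas for one locus
# from per-population genotype count triples (list of c(rr, het, aa))
naive_theta_one_locus <- function(count_list) {
  r <- length(count_list)
  ni <- sapply(count_list, sum)
  pi <- sapply(count_list, function(ct) (2 * ct[1] + ct[2]) / (2 * sum(ct)))
  hi <- sapply(count_list, function(ct) ct[2] / sum(ct))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# build a genotype_matrix from per-population count triples at one locus
gm_from_counts <- function(..., locus = "L01") {
  cts <- list(...)
  pops <- names(cts)
  calls <- unlist(lapply(cts, function(ct) rep(0:2, times = ct)))
  genotype_matrix(matrix(calls, ncol = 1,
                         dimnames = list(NULL, locus)),
                  population = rep(pops, times = sapply(cts, sum)))
}

# a small deterministic two-population, three-locus matrix
toy_matrix <- function() {
  calls <- rbind(c(0, 1, 2), c(1, 0, 2), c(0, 0, 1),
                 c(2, 1, 0), c(2, 2, 1), c(1, 2, 0))
  genotype_matrix(calls, population = rep(c("A", "B"), each = 3),
                  type = rep(c("river", "swamp"), each = 3))
}
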