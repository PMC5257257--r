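# Independent oracles, deliberately implemented differently from the package.

# One-sided enrichment p-value by exhaustive enumeration of all 2x2 tables
# with the observed margins: sum hypergeometric point masses over j >= k.
oracle_fisher <- function(k, N, m, M) {
  K <- k + m                 # gene-column margin
  total <- N + M
  j <- 0:min(N, K)
  logp <- lchoose(K, j) + lchoose(total - K, N - j) - lchoose(total, N)
  valid <- (N - j) <= (total - K)
  p <- exp(logp[valid])
  j <- j[valid]
  sum(p[j >= k])
}

# O(n^2) collapse: connected components of the "within max_gap on the same
# chrom+strand" graph, then the retained-member rule per component.
oracle_collapse <- function(sites, max_gap = 2L) {
  n <- nrow(sites)
  if (!n) return(sites)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- sites$chrom[i] == sites$chrom[j] &&
        sites$strand[i] == sites$strand[j] &&
        abs(sites$position[i] - sites$position[j]) <= max_gap
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- cid
      frontier <- nb
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix) {
    sub <- sites[ix, ]
    rep_i <- ix[order(-sub$read_support, sub$position)[1]]
    data.frame(chrom = sites$chrom[rep_i], position = sites$position[rep_i],
               strand = sites$strand[rep_i],
               read_support = sum(sub$read_support),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

# Naive complete linkage on L1 distances: cluster distances recomputed from
# scratch over all member pairs at every step; ties broken by the lowest
# original index of the first member, then the second. Returns leaf order.
oracle_linkage_order <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  l1 <- function(i, j) sum(abs(x[i, ] - x[j, ]))
  cdist <- function(a, b) {
    max(vapply(a, function(i) max(vapply(b, function(j) l1(i, j), 0)), 0))
  }
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- cdist(clusters[[a]], clusters[[b]])
        la <- min(clusters[[a]]); lb <- min(clusters[[b]])
        key <- c(d, min(la, lb), max(la, lb))
        bkey <- if (is.null(best)) c(Inf, Inf, Inf) else best$key
        if (key[1] < bkey[1] ||
            (key[1] == bkey[1] && (key[2] < bkey[2] ||
              (key[2] == bkey[2] && key[3] < bkey[3])))) {
          best <- list(a = a, b = b, key = key)
          best_d <- d
        }
      }
    }
    a <- best$a; b <- best$b
    first <- if (min(clusters[[a]]) <= min(clusters[[b]])) a else b
    second <- if (first == a) b else a
    merged <- c(clusters[[first]], clusters[[second]])
    clusters <- clusters[-c(a, b)]
    clusters[[length(clusters) + 1L]] <- merged
    # keep list ordered by lead index so the next sweep's a<b enumeration
    # matches the package's lowest-index bookkeeping
    clusters <- clusters[order(vapply(clusters, min, 0L))]
  }
  clusters[[1]]
}
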