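# independent oracles used to cross-check the implementation

# brute-force conditional NB exact test: plain enumeration of all K + 1
# splits on the probability scale
brute_nb_exact <- function(ka, kb, mu_a, mu_b, alpha, n_a = 1, n_b = 1) {
  K <- ka + kb
  if (K == 0) return(1)
  dens <- function(x, mu, n) {
    if (alpha == 0) dpois(x, mu) else dnbinom(x, mu = mu, size = n / alpha)
  }
  a <- 0:K
  pr <- dens(a, mu_a, n_a) * dens(K - a, mu_b, n_b)
  p_obs <- pr[a == ka]
  sum(pr[pr <= p_obs * (1 + 1e-7)]) / sum(pr)
}

# brute-force agglomerative complete linkage: at each step merge the pair
# of clusters with the smallest maximal pairwise distance
brute_complete_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best_h <- Inf
    best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Rand index between two flat clusterings
rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  s / choose(n, 2)
}

# hand reverse complement (RNA seed -> DNA match string), written
# independently of the package's internals
oracle_rc <- function(rna) {
  map <- c(A = "T", C = "G", G = "C", U = "A")
  paste(rev(map[strsplit(rna, "")[[1]]]), collapse = "")
}

# random strictly positive marker panel
random_panel <- function(n) {
  data.frame(
    sample_id = sprintf("S%d", seq_len(n)),
    COL1A1 = rlnorm(n, 0, 1),
    FN1 = rlnorm(n, 0, 1),
    ACTA2 = rlnorm(n, 0, 1),
    stringsAsFactors = FALSE
  )
}
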