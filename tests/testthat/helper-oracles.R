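# Independent brute-force oracles and fixture builders. These stay
# deliberately naive (set arithmetic, transitive closure, pair counting)
# so they share no code path with the implementation they check.

# Shared-face matrix by explicit pairwise patient-set intersection.
bf_shared_face <- function(M) {
  nd <- ncol(M)
  S <- matrix(NA_integer_, nd, nd, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      pi <- which(M[, i] == 1)
      pj <- which(M[, j] == 1)
      S[i, j] <- length(intersect(pi, pj)) - 1L
    }
  }
  S
}

# q-connected components by transitive closure of the q-nearness
# relation (repeated boolean matrix products until fixpoint).
bf_q_components <- function(S, q) {
  active <- which(diag(S) >= q)
  if (!length(active)) return(list())
  R <- (S[active, active, drop = FALSE] >= q)
  diag(R) <- TRUE
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  groups <- unique(apply(R, 1, function(row) paste(which(row), collapse = ",")))
  comps <- lapply(groups, function(g)
    sort(colnames(S)[active][as.integer(strsplit(g, ",")[[1]])]))
  comps
}

# Canonical form of a partition: sorted list of sorted member vectors.
canon_partition <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, "", 1L))]
}

# Partition at level q extracted from a q_profile's membership record.
profile_partition <- function(profile, q) {
  ids <- profile$membership[[q + 1L]]
  if (is.null(ids) || !length(ids)) return(list())
  comps <- split(names(ids), ids)
  names(comps) <- NULL
  comps
}

# AUC as the concordant-pair fraction (ties count one half).
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (g in neg) {
    total <- total + if (p > g) 1 else if (p == g) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Unweighted average-linkage agglomeration with cophenetic record,
# written from the definition: cluster distance = mean pairwise
# distance between original points.
bf_average_linkage_cophenetic <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    a <- clusters[[best[2]]]; b <- clusters[[best[3]]]
    coph[a, b] <- best[1]; coph[b, a] <- best[1]
    clusters[[best[2]]] <- c(a, b)
    clusters[[best[3]]] <- NULL
  }
  coph
}

# Random 0/1 incidence with named columns.
random_incidence <- function(n_patients, n_descriptors, p = 0.4) {
  M <- matrix(rbinom(n_patients * n_descriptors, 1L, p),
              n_patients, n_descriptors)
  colnames(M) <- paste0("D", seq_len(n_descriptors))
  rownames(M) <- paste0("P", seq_len(n_patients))
  M
}

# Incidence with a 12-descriptor core sharing patients 1..708 (pairwise
# shared-face dimension 707) plus staggered satellite descriptors on
# patient prefixes 1..k. A satellite with k patients stays attached to
# the core up to q = k - 1, so the core component's membership keeps
# changing below q = 529 (runs of at most 40 levels) and is exactly the
# 12 core members on [529, 707] -- the constructed stability plateau.
plateau_fixture <- function() {
  n <- 708
  ks <- c(seq(40, 520, by = 40), 529)
  M <- matrix(0L, n, 12 + length(ks))
  colnames(M) <- c(paste0("core", 1:11), "Final diagnosis[1]",
                   paste0("sat", seq_along(ks)))
  M[, 1:12] <- 1L
  for (i in seq_along(ks)) M[seq_len(ks[i]), 12 + i] <- 1L
  M
}

# A small cohort with every schema column and hand-set values.
tiny_cohort <- function() {
  cohort <- generate_cohort(synthetic_config(n_patients = 6, seed = 99,
                                             missing_rates = numeric(0),
                                             effect_sizes = numeric(0)))
  cohort
}

# Names of the 26 clinical indicator columns (everything but ID/label).
clinical_names <- function() {
  s <- cohort_schema()
  s$name[!s$role %in% c("id", "label")]
}
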