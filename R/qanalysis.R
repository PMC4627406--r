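# Q-analysis of the patient-descriptor incidence relation.
#
# Each descriptor is a simplex whose vertices are the patients
# exhibiting it; a descriptor occurring in n patients is an
# (n-1)-dimensional simplex. Two descriptors are q-near when they share
# at least q+1 patients (a shared face of dimension >= q), and
# q-connected when a chain of pairwise q-near descriptors links them.
# The component structure across all q levels is the structural
# "backcloth" of the relation.

#' Shared-face matrix of descriptor simplices
#'
#' `S[i, j]` is the dimension of the shared face between descriptor
#' simplices i and j: the number of patients carrying both, minus one
#' (so -1 means no shared patient). The diagonal `S[i, i]` is the
#' dimension of descriptor i's own simplex, its occurrence count minus
#' one -- a descriptor present in 819 patients has dimension 818 and can
#' be q-connected at most up to q = 818.
#'
#' @param incidence An `augmented_incidence` (or a 0/1 matrix with
#'   descriptor column names).
#' @return Symmetric integer matrix of class `shared_face_matrix`.
#' @export
shared_face_matrix <- function(incidence) {
  M <- if (inherits(incidence, "augmented_incidence")) incidence$matrix else
    as.matrix(incidence)
  if (length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L)
    stop("empty incidence")
  storage.mode(M) <- "integer"
  S <- crossprod(M) - 1L
  storage.mode(S) <- "integer"   # matrix products promote to double
  structure(S, class = c("shared_face_matrix", class(S)))
}

#' @export
print.shared_face_matrix <- function(x, ...) {
  cat("Shared-face matrix over", ncol(x), "descriptors; simplex dimensions",
      min(diag(x)), "to", max(diag(x)), "\n")
  invisible(x)
}

as_sfm <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be a square matrix")
  if (is.null(colnames(S))) colnames(S) <- rownames(S) <- paste0("D", seq_len(ncol(S)))
  S
}

#' q-connected components at one level
#'
#' Vertices are the descriptors whose own simplex dimension is at least
#' `q`; edges join pairs with shared-face dimension at least `q`.
#' Components of this graph are the q-connected classes; survivors with
#' no q-near partner count as singleton components.
#'
#' @param S A [shared_face_matrix()].
#' @param q Level, between 0 and the maximal diagonal entry.
#' @return List of character vectors (descriptor names), ordered by
#'   decreasing size then first member.
#' @export
q_components <- function(S, q) {
  S <- as_sfm(S)
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0 || q > max(diag(S)))
    stop("q out of range [0, ", max(diag(S)), "]")
  active <- which(diag(S) >= q)
  if (!length(active)) return(list())
  A <- S[active, active, drop = FALSE] >= q
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  memb <- igraph::components(g)$membership
  comps <- split(colnames(S)[active], memb)
  comps <- lapply(comps, sort)
  names(comps) <- NULL
  comps[order(-lengths(comps), vapply(comps, `[`, "", 1L))]
}

#' Component structure across every q level
#'
#' Evaluates the q-connected component structure for every q from 0 up
#' to the maximal simplex dimension, using a single pass of an
#' incremental union-find: descriptors and shared-face edges are
#' activated in decreasing q order, so each level's partition is
#' maintained rather than recomputed. The result is identical to calling
#' [q_components()] level by level.
#'
#' @param S A [shared_face_matrix()].
#' @return Object of class `q_profile`: list with `levels` (data frame
#'   `q`, `n_components`, `max_component_size`), `max_members` (list of
#'   the maximal component's members per level), `membership` (per level,
#'   named integer vector of component ids over active descriptors) and
#'   `dimensions` (the diagonal of `S`).
#' @export
structure_profile <- function(S) {
  S <- as_sfm(S)
  nd <- ncol(S)
  dims <- diag(S)
  names(dims) <- colnames(S)
  q_max <- max(dims)
  # upper-triangle edges with a non-empty shared face
  ut <- which(upper.tri(S) & S >= 0, arr.ind = TRUE)
  edge_val <- S[cbind(ut[, 1], ut[, 2])]
  edge_ord <- order(edge_val, decreasing = TRUE)
  ut <- ut[edge_ord, , drop = FALSE]
  edge_val <- edge_val[edge_ord]
  vert_ord <- order(dims, decreasing = TRUE)

  parent <- seq_len(nd)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ei <- 1L; vi <- 1L
  active <- logical(nd)
  levels <- vector("list", q_max + 1L)
  membership <- vector("list", q_max + 1L)
  max_members <- vector("list", q_max + 1L)
  for (q in seq(q_max, 0)) {
    while (vi <= nd && dims[vert_ord[vi]] >= q) {
      active[vert_ord[vi]] <- TRUE
      vi <- vi + 1L
    }
    while (ei <= length(edge_val) && edge_val[ei] >= q) {
      ra <- find(ut[ei, 1]); rb <- find(ut[ei, 2])
      if (ra != rb) parent[ra] <- rb
      ei <- ei + 1L
    }
    idx <- which(active)
    roots <- vapply(idx, find, 1L)
    ids <- match(roots, unique(roots))
    names(ids) <- colnames(S)[idx]
    sizes <- tabulate(ids)
    big <- which.max(sizes)
    membership[[q + 1L]] <- ids
    max_members[[q + 1L]] <- sort(names(ids)[ids == big])
    levels[[q + 1L]] <- c(q = q, n_components = length(sizes),
                          max_component_size = max(sizes))
  }
  lv <- as.data.frame(do.call(rbind, levels))
  structure(list(levels = lv, max_members = max_members,
                 membership = membership, dimensions = dims),
            class = "q_profile")
}

#' @export
print.q_profile <- function(x, ...) {
  cat("Q-profile over", length(x$dimensions), "descriptors, q = 0 ..",
      max(x$levels$q), "\n")
  cat("  max component size:", x$levels$max_component_size[1], "at q = 0;",
      "singletons from q =",
      min(x$levels$q[x$levels$max_component_size == 1], Inf), "\n")
  invisible(x)
}

#' Plot the maximal-component-size profile
#'
#' The signature curve of the backcloth: size of the maximal q-connected
#' component as a function of q. Plateaus are stability zones of the
#' structure.
#'
#' @param x A `q_profile`.
#' @param ... Passed to [plot()].
#' @export
plot.q_profile <- function(x, ...) {
  plot(x$levels$q, x$levels$max_component_size, type = "s",
       xlab = "q dimension", ylab = "size of maximal connected component",
       ...)
  invisible(x)
}

# Members of the component containing `anchor` at level q (q+1 index),
# or NULL if the anchor is inactive there.
anchor_members <- function(profile, anchor, q) {
  ids <- profile$membership[[q + 1L]]
  if (is.null(ids) || !(anchor %in% names(ids))) return(NULL)
  sort(names(ids)[ids == ids[[anchor]]])
}

#' Stability plateau of an anchor descriptor's component
#'
#' Scans all q levels where `anchor` is active and finds the longest
#' consecutive q-interval over which the membership of the anchor's
#' q-connected component is unchanged and has at least two members (ties
#' broken toward the higher-q interval -- the stability zone of interest
#' sits high in the structure). The members over that interval are the
#' "connected higher dimensional set".
#'
#' @param profile A [structure_profile()] result.
#' @param anchor Descriptor name, e.g. `"Final diagnosis[1]"`.
#' @return Object of class `plateau_report`: list with `q_lo`, `q_hi`,
#'   `members`, `contains_positive_diagnosis`, `empty`.
#' @export
plateau <- function(profile, anchor) {
  if (!(anchor %in% names(profile$dimensions)))
    stop("anchor ", anchor, " not among the profile's descriptors")
  qs <- profile$levels$q
  keys <- vapply(qs, function(q) {
    mm <- anchor_members(profile, anchor, q)
    if (is.null(mm) || length(mm) < 2L) NA_character_ else
      paste(mm, collapse = "\x1f")
  }, "")
  best <- NULL
  i <- 1L
  while (i <= length(keys)) {
    if (is.na(keys[i])) { i <- i + 1L; next }
    j <- i
    while (j < length(keys) && !is.na(keys[j + 1L]) && keys[j + 1L] == keys[i])
      j <- j + 1L
    # >= : later (higher-q) run wins ties
    if (is.null(best) || (j - i) >= (best[2] - best[1])) best <- c(i, j)
    i <- j + 1L
  }
  if (is.null(best)) {
    warning("anchor ", anchor, " is never in a component of size >= 2; ",
            "empty plateau report")
    return(structure(list(q_lo = NA_integer_, q_hi = NA_integer_,
                          members = character(0),
                          contains_positive_diagnosis = FALSE, empty = TRUE),
                     class = "plateau_report"))
  }
  members <- strsplit(keys[best[1]], "\x1f", fixed = TRUE)[[1]]
  structure(list(q_lo = qs[best[1]], q_hi = qs[best[2]], members = members,
                 contains_positive_diagnosis =
                   "Final diagnosis[1]" %in% members,
                 empty = FALSE),
            class = "plateau_report")
}

#' @export
print.plateau_report <- function(x, ...) {
  if (x$empty) {
    cat("Empty plateau report (anchor never in a component of size >= 2)\n")
  } else {
    cat(sprintf("Plateau q = [%d, %d]: %d members\n", x$q_lo, x$q_hi,
                length(x$members)))
    cat(" ", paste(x$members, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split descriptors into connected and unconnected high-dimensional sets
#'
#' The plateau members (minus the diagnosis descriptors) form the
#' connected higher dimensional set -- descriptors shared by so many
#' patients that they are general and non-discriminative. The remaining
#' feature descriptors form the unconnected set, the one that carries
#' the diagnostic "traffic". The two sets partition the feature
#' descriptors.
#'
#' @param plateau_report A [plateau()] result.
#' @param all_descriptors All descriptor names in the analysis view.
#' @return List with `connected` and `unconnected` character vectors.
#' @export
split_feature_sets <- function(plateau_report, all_descriptors) {
  feats <- setdiff(all_descriptors, diagnosis_descriptors())
  connected <- intersect(plateau_report$members, feats)
  list(connected = connected, unconnected = setdiff(feats, connected))
}

#' Hierarchical clustering of the shared-face matrix
#'
#' Agglomerative clustering of descriptor rows of S under Euclidean
#' distance, for heatmap rendering of the block structure (highly
#' co-occurring descriptor groups cluster together).
#'
#' @param S A [shared_face_matrix()].
#' @param method Linkage; average by default.
#' @return List with `hclust` (the [stats::hclust] tree) and `order`
#'   (leaf descriptor names, left to right).
#' @export
cluster_shared_faces <- function(S, method = "average") {
  S <- as_sfm(S)
  hc <- stats::hclust(stats::dist(S), method = method)
  list(hclust = hc, order = colnames(S)[hc$order])
}

#' Write Q-analysis artifacts as CSV
#'
#' The profile is written tidily: one row per q with component count,
#' maximal component size, and the anchor's component membership
#' (semicolon-joined) when an anchor is given.
#'
#' @param profile A `q_profile`.
#' @param path Output CSV path.
#' @param anchor Optional anchor descriptor.
#' @return `path`, invisibly.
#' @export
write_q_profile_csv <- function(profile, path, anchor = NULL) {
  df <- profile$levels
  if (!is.null(anchor)) {
    df$anchor_component <- vapply(df$q, function(q) {
      mm <- anchor_members(profile, anchor, q)
      if (is.null(mm)) "" else paste(mm, collapse = ";")
    }, "")
  }
  df$max_component <- vapply(df$q + 1L, function(i)
    paste(profile$max_members[[i]], collapse = ";"), "")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_q_profile_csv
#' @param S A shared-face matrix.
#' @export
write_shared_face_csv <- function(S, path) {
  utils::write.csv(as.data.frame(unclass(as_sfm(S))), path, row.names = TRUE)
  invisible(path)
}
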