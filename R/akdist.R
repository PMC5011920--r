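# Alignment-free k-mer comparison of short elements (3'-UTR stem-loops):
# Jaccard distance over k-mer sets, all-pairs distance matrices, and
# agglomerative clustering with deterministic lexicographic tie-breaking.

#' Jaccard k-mer distance between two sequences
#'
#' `1 - |Ka intersect Kb| / |Ka union Kb|` over the (forward-strand) k-mer
#' sets of the two sequences. A metric: zero iff the k-mer sets are equal,
#' symmetric, and satisfying the triangle inequality.
#'
#' @param a,b Nucleotide sequences of length >= k.
#' @param k Word length (default 4, giving 13 k-mers for a 16-nt stem-loop
#'   element).
#' @return Distance in \[0, 1\].
#' @export
kmer_distance <- function(a, b, k = 4) {
  if (nchar(a) < k || nchar(b) < k) {
    abort(sprintf("both sequences must be at least k = %d long", k))
  }
  ka <- unique(seq_kmers(a, k))
  kb <- unique(seq_kmers(b, k))
  1 - length(intersect(ka, kb)) / length(union(ka, kb))
}

#' All-pairs k-mer distance matrix
#'
#' @param elements Named character vector of sequences, or a tibble with
#'   `id` and `residues`.
#' @param k Word length (default 4).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = element
#'   labels. Duplicate labels raise an error.
#' @export
all_pairs <- function(elements, k = 4) {
  if (is.data.frame(elements)) {
    elements <- setNames(elements$residues, elements$id)
  }
  if (length(elements) < 2) {
    abort("need at least two elements")
  }
  labels <- names(elements)
  if (is.null(labels) || anyDuplicated(labels)) {
    abort("elements must carry unique labels")
  }
  n <- length(elements)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- kmer_distance(elements[[i]], elements[[j]], k)
    }
  }
  d
}

#' Agglomerative clustering with deterministic tie-breaking
#'
#' Single- or average-linkage agglomeration of a distance matrix. When
#' several pairs are tied at the minimal distance, the pair whose
#' (lexicographically smallest member label, then second label) sorts first
#' is merged, so the dendrogram is invariant under input order.
#'
#' @param d Symmetric distance matrix with labelled dimnames (from
#'   [all_pairs()]).
#' @param linkage `"average"` (default) or `"single"`.
#' @return List of class `ak_dendrogram`: `merges` (tibble `a`, `b`,
#'   `height`, where `a`/`b` are the lexicographically smallest leaf labels
#'   of the merged clusters), `labels`, `members` (leaf sets per merge) and
#'   `linkage`.
#' @export
ak_cluster <- function(d, linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  labels <- rownames(d)
  stopifnot(!is.null(labels), identical(rownames(d), colnames(d)))
  n <- length(labels)
  clusters <- as.list(labels) # leaf label sets
  reps <- labels # lexicographically smallest member per cluster
  sizes <- rep(1L, n)
  dm <- d
  merges <- tibble(
    a = character(0), b = character(0), height = numeric(0)
  )
  members <- list()
  active <- seq_len(n)
  while (length(active) > 1) {
    # minimal distance among active cluster pairs, ties by sorted rep labels
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]
        j <- active[jj]
        dij <- dm[i, j]
        key <- sort(c(reps[i], reps[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
            (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i
    j <- best$j
    new_members <- c(clusters[[i]], clusters[[j]])
    merges <- bind_rows(merges, tibble(
      a = best$key[1], b = best$key[2], height = best$d
    ))
    members <- c(members, list(sort(new_members)))
    # Lance-Williams update into slot i
    for (kk in setdiff(active, c(i, j))) {
      dm[i, kk] <- dm[kk, i] <- switch(linkage,
        single = min(dm[i, kk], dm[j, kk]),
        average = (sizes[i] * dm[i, kk] + sizes[j] * dm[j, kk]) /
          (sizes[i] + sizes[j])
      )
    }
    clusters[[i]] <- new_members
    reps[i] <- min(reps[i], reps[j])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  structure(
    list(
      merges = merges, labels = labels, members = members, linkage = linkage
    ),
    class = "ak_dendrogram"
  )
}

#' Convert an `ak_dendrogram` to an `hclust` object
#'
#' @param x An `ak_dendrogram`.
#' @return An object of class `hclust` (usable with [stats::plot.hclust()],
#'   `ape::as.phylo()`, ...).
#' @export
as_hclust <- function(x) {
  stopifnot(inherits(x, "ak_dendrogram"))
  labels <- x$labels
  n <- length(labels)
  merge <- matrix(0L, n - 1, 2)
  # map: which merge produced the cluster currently represented by a label
  produced_by <- setNames(rep(NA_integer_, n), labels)
  for (m in seq_len(n - 1)) {
    idx <- vapply(c(x$merges$a[m], x$merges$b[m]), function(lbl) {
      prev <- produced_by[[lbl]]
      if (is.na(prev)) -match(lbl, labels) else prev
    }, integer(1))
    merge[m, ] <- sort(idx)
    for (lbl in x$members[[m]]) {
      produced_by[[lbl]] <- m
    }
  }
  order <- leaf_order(merge, labels)
  structure(
    list(
      merge = merge, height = x$merges$height, order = order,
      labels = labels, method = x$linkage,
      call = match.call(), dist.method = "kmer_jaccard"
    ),
    class = "hclust"
  )
}

leaf_order <- function(merge, labels) {
  walk <- function(node) {
    if (node < 0) {
      return(-node)
    }
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Write a dendrogram in Newick format
#'
#' @param x An `ak_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  hc <- as_hclust(x)
  if (requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(hc), file = path)
  } else {
    # minimal fallback: branch lengths from merge heights
    build <- function(node, parent_h) {
      if (node < 0) {
        return(sprintf("%s:%g", hc$labels[-node], parent_h))
      }
      h <- hc$height[node]
      sprintf(
        "(%s,%s):%g",
        build(hc$merge[node, 1], h), build(hc$merge[node, 2], h),
        parent_h - h
      )
    }
    root <- nrow(hc$merge)
    writeLines(sprintf(
      "(%s,%s);",
      build(hc$merge[root, 1], hc$height[root]),
      build(hc$merge[root, 2], hc$height[root])
    ), path)
  }
  invisible(path)
}
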