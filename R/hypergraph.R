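# Multi-feature hypergraph construction. Subjects are nodes; each
# categorical feature contributes one hyperedge per category (a partition
# of the cohort) and each continuous feature contributes a k-uniform
# hypergraph: one edge per subject containing that subject and its k-1
# nearest neighbours in the feature value. Per-feature hypergraphs are
# concatenated horizontally with edge weights taken from normalized ridge
# coefficients.

new_hypergraph <- function(incidence, weights, provenance) {
  stopifnot(nrow(provenance) == ncol(incidence),
            length(weights) == ncol(incidence), all(weights > 0),
            all(colSums(incidence) >= 2L))
  structure(list(incidence = incidence, edge_weights = weights,
                 edge_provenance = provenance),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("<hypergraph> ", nrow(x$incidence), " subjects x ",
      ncol(x$incidence), " hyperedges (features: ",
      paste(unique(x$edge_provenance$feature), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Hyperedges from a categorical feature
#'
#' One hyperedge per category containing exactly its members; categories
#' with a single subject are dropped with a warning (a singleton edge
#' carries no connectivity). The retained edges of one feature partition
#' the subjects they cover.
#'
#' @param values categorical vector, length n subjects.
#' @param feature name used in the edge provenance.
#' @return A `hypergraph` with unit edge weights.
#' @export
build_categorical_edges <- function(values, feature = "categorical") {
  values <- as.character(values)
  n <- length(values)
  cats <- unique(values)
  counts <- table(values)
  drop <- names(counts)[counts < 2L]
  if (length(drop)) {
    warning("dropping singleton categor", if (length(drop) > 1) "ies: " else "y: ",
            paste(drop, collapse = ", "))
    cats <- setdiff(cats, drop)
  }
  if (!length(cats)) stop("no category has >= 2 subjects")
  H <- vapply(cats, function(cc) as.integer(values == cc), integer(n))
  H <- matrix(H, nrow = n)
  prov <- data.frame(feature = feature, rule = "categorical",
                     category = cats, k = NA_integer_,
                     stringsAsFactors = FALSE)
  new_hypergraph(H, rep(1, ncol(H)), prov)
}

#' k-uniform hyperedges from a continuous feature
#'
#' One hyperedge per subject, containing the subject plus its k-1 nearest
#' neighbours by absolute difference in the (standardized) feature value;
#' ties are broken by ascending subject index, so construction is
#' deterministic. Every edge has exactly k members.
#'
#' @param values standardized continuous vector, length n; must not be
#'   constant.
#' @param k nodes per hyperedge, `2 <= k <= n`.
#' @param feature name used in the edge provenance.
#' @return A `hypergraph` with n edges of unit weight.
#' @export
build_knn_edges <- function(values, k, feature = "continuous") {
  n <- length(values)
  k <- as.integer(k)
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  if (k < 2L) stop("k must be >= 2")
  if (stats::sd(values) == 0) {
    stop("constant feature '", feature,
         "': nearest neighbours are arbitrary, rejecting")
  }
  H <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    d <- abs(values - values[i])
    d[i] <- -Inf  # the subject itself always belongs to its edge
    ord <- order(d, seq_len(n))  # ties -> ascending subject index
    H[ord[seq_len(k)], i] <- 1L
  }
  prov <- data.frame(feature = feature, rule = "knn",
                     category = NA_character_, k = k,
                     stringsAsFactors = FALSE)
  new_hypergraph(H, rep(1, n), prov[rep(1, n), , drop = FALSE])
}

#' Concatenate per-feature hypergraphs with ridge-derived edge weights
#'
#' Horizontal concatenation of the incidence matrices; every edge inherits
#' the normalized ridge weight of the feature it was built from.
#'
#' @param parts named list of `hypergraph` objects (names = feature
#'   names), all over the same subject ordering.
#' @param weights named numeric vector of per-feature weights (> 0), one
#'   per part.
#' @return The combined `hypergraph`.
#' @export
combine_hypergraphs <- function(parts, weights) {
  if (is.null(names(parts)) || any(!nzchar(names(parts)))) {
    stop("`parts` must be a named list")
  }
  ns <- vapply(parts, function(p) nrow(p$incidence), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("subject counts differ across parts: ",
         paste(ns, collapse = ", "))
  }
  miss <- setdiff(names(parts), names(weights))
  if (length(miss)) stop("no weight for feature(s): ",
                         paste(miss, collapse = ", "))
  if (any(weights[names(parts)] <= 0)) stop("feature weights must be > 0")
  H <- do.call(cbind, lapply(parts, function(p) p$incidence))
  w <- unlist(lapply(names(parts), function(f) {
    rep(weights[[f]], ncol(parts[[f]]$incidence))
  }))
  prov <- do.call(rbind, lapply(names(parts), function(f) {
    pr <- parts[[f]]$edge_provenance
    pr$feature <- f
    pr
  }))
  rownames(prov) <- NULL
  new_hypergraph(H, w, prov)
}

#' Build the multi-feature hypergraph for a cohort
#'
#' Convenience wrapper: categorical features go through
#' [build_categorical_edges()], continuous features through
#' [build_knn_edges()] with a shared `k`, and everything is combined with
#' [combine_hypergraphs()].
#'
#' @param features data frame or matrix of feature columns (standardized
#'   continuous, categorical as-is).
#' @param continuous,categorical character vectors naming the columns of
#'   each kind.
#' @param weights named per-feature weights; features without a weight get
#'   1.
#' @param k nodes per hyperedge for the continuous features.
#' @return A `hypergraph`.
#' @export
build_multifeature_hypergraph <- function(features, continuous, categorical,
                                          weights = NULL, k = 12L) {
  feats <- c(categorical, continuous)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(feats)), feats)
  w <- stats::setNames(rep(1, length(feats)), feats)
  w[names(weights)] <- weights
  parts <- list()
  for (f in categorical) {
    parts[[f]] <- build_categorical_edges(features[, f], feature = f)
  }
  for (f in continuous) {
    parts[[f]] <- build_knn_edges(as.numeric(features[, f]), k = k,
                                  feature = f)
  }
  combine_hypergraphs(parts, w)
}

#' Serialize / load a hypergraph as plain text
#'
#' The incidence matrix is written in sparse coordinate form (`row`,
#' `col`, `value`) and the edge table (`edge_id`, `feature`, `rule`,
#' `category`, `k`, `weight`) as TSV.
#'
#' @param hg a `hypergraph`.
#' @param incidence_path,edges_path output TSV paths.
#' @return The paths (write) or the `hypergraph` (read), invisibly.
#' @export
write_hypergraph <- function(hg, incidence_path, edges_path) {
  nz <- which(hg$incidence != 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(row = nz[, 1], col = nz[, 2], value = 1L),
    incidence_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ed <- cbind(edge_id = seq_len(ncol(hg$incidence)), hg$edge_provenance,
              weight = hg$edge_weights)
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(incidence_path, edges_path))
}

#' @rdname write_hypergraph
#' @param n_subjects number of rows of the incidence matrix.
#' @export
read_hypergraph <- function(incidence_path, edges_path, n_subjects) {
  coo <- utils::read.delim(incidence_path)
  ed <- utils::read.delim(edges_path)
  H <- matrix(0L, n_subjects, nrow(ed))
  H[cbind(coo$row, coo$col)] <- 1L
  new_hypergraph(H, ed$weight,
                 ed[, c("feature", "rule", "category", "k")])
}
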