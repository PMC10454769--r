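# Weighted residue-interaction network and eigenvector centrality.
#
# The graph's edge weights are bootstrap-averaged contact frequencies; an
# edge exists for a non-zero frequency between residues separated by at
# least `min_sequence_gap` positions in sequence (inter-chain pairs are
# always eligible).  Centrality is the Perron eigenvector of the weighted
# adjacency matrix, normalized to unit Euclidean norm.

#' Build the residue-interaction graph
#'
#' @param freqs a [bootstrap_frequencies()] result (or any data.frame with
#'   `res_i`, `res_j`, `chain_i`, `chain_j`, `freq`).
#' @param min_sequence_gap minimum sequence separation `|i - j|` for an
#'   intra-chain edge (default 2: immediate neighbors are excluded).
#' @return An object of class `residue_graph`: node table, edge table and
#'   dense weighted adjacency matrix.
#' @export
build_graph <- function(freqs, min_sequence_gap = 2L) {
  tab <- if (inherits(freqs, "contact_freqs")) freqs$pairs else as.data.frame(freqs)
  key_i <- paste(tab$chain_i, tab$res_i, sep = ":")
  key_j <- paste(tab$chain_j, tab$res_j, sep = ":")
  nodes_key <- sort(unique(c(key_i, key_j)))
  if (length(nodes_key) == 0L) {
    nodes <- data.frame(chain = character(), resid = integer(),
                        key = character(), stringsAsFactors = FALSE)
  } else {
    # order nodes by chain then residue number
    parts <- do.call(rbind, strsplit(nodes_key, ":", fixed = TRUE))
    ord <- order(parts[, 1], as.integer(parts[, 2]))
    nodes_key <- nodes_key[ord]
    nodes <- data.frame(chain = parts[ord, 1], resid = as.integer(parts[ord, 2]),
                        key = nodes_key, stringsAsFactors = FALSE)
  }

  eligible <- tab$freq > 0 &
    (tab$chain_i != tab$chain_j |
       abs(tab$res_i - tab$res_j) >= min_sequence_gap)
  edges <- tab[eligible, c("res_i", "res_j", "chain_i", "chain_j", "freq")]
  rownames(edges) <- NULL

  n <- nrow(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes$key, nodes$key))
  if (nrow(edges)) {
    ii <- match(paste(edges$chain_i, edges$res_i, sep = ":"), nodes$key)
    jj <- match(paste(edges$chain_j, edges$res_j, sep = ":"), nodes$key)
    W[cbind(ii, jj)] <- edges$freq
    W[cbind(jj, ii)] <- edges$freq
  }
  structure(list(nodes = nodes, edges = edges, adjacency = W,
                 min_sequence_gap = min_sequence_gap),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("residue_graph: %d nodes, %d edges (sequence gap >= %d)\n",
              nrow(x$nodes), nrow(x$edges), x$min_sequence_gap))
  invisible(x)
}

# connected components of a symmetric adjacency matrix (BFS), integer label
# per node
.graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  adj <- W > 0
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Perron eigenvector of a symmetric non-negative matrix by shifted power
# iteration.  The shift (W + cI) leaves the eigenvector unchanged but makes
# the leading eigenvalue strictly dominant in magnitude, so the iteration
# also converges on bipartite graphs (e.g. stars) where the unshifted
# spectrum is symmetric.  Residual criterion: ||Wx - lambda x|| <= tol.
.perron_vector <- function(W, tol = 1e-10, max_iter = 100000L) {
  n <- nrow(W)
  if (n == 1L) return(list(vector = 1, value = W[1, 1]))
  shift <- 1
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.vector(W %*% x) + shift * x
    ny <- .vnorm(y)
    if (ny == 0) .stopf("power iteration collapsed to the zero vector")
    x_new <- y / ny
    x <- x_new
    lam <- as.numeric(crossprod(x, W %*% x))
    if (.vnorm(as.vector(W %*% x) - lam * x) <= tol)
      return(list(vector = abs(x), value = lam))
  }
  # deflation-free fallback: dense symmetric eigendecomposition
  if (n <= 500L) {
    e <- eigen(W, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (sum(v) < 0) v <- -v
    return(list(vector = abs(v), value = e$values[1]))
  }
  .stopf("eigenvector centrality did not converge in %d iterations", max_iter)
}

#' Eigenvector centrality of a residue graph
#'
#' Computes the principal eigenvector of the weighted adjacency matrix
#' (`W x = lambda x`, largest eigenvalue), with entries non-negative and
#' the full score vector normalized to unit Euclidean norm.  On a
#' disconnected graph the scores are computed on the largest connected
#' component (ties broken by first occurrence); other nodes score zero.
#'
#' @param g a [build_graph()] result.
#' @param tol convergence tolerance on the eigen-residual.
#' @return Named numeric vector of scores (names are `chain:resid` keys),
#'   with attributes `eigenvalue`, `component_size` and `normalization`.
#' @export
eigenvector_centrality <- function(g, tol = 1e-10) {
  W <- g$adjacency
  if (nrow(W) == 0L) .stopf("empty graph")
  comp <- .graph_components(W)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  idx <- which(comp == main)
  scores <- numeric(nrow(W))
  pv <- .perron_vector(W[idx, idx, drop = FALSE], tol = tol)
  scores[idx] <- pv$vector
  names(scores) <- g$nodes$key
  attr(scores, "eigenvalue") <- pv$value
  attr(scores, "component_size") <- length(idx)
  attr(scores, "normalization") <- "L2"
  scores
}

#' Centrality from bootstrap contact frequencies
#'
#' Follows the averaged-matrix procedure: the graph is built from the
#' sample-averaged contact-frequency matrix and centrality computed on it.
#' Per-sample centralities are additionally computed from each bootstrap
#' sample's frequencies and their standard deviation reported as a
#' diagnostic spread (it is not the score's estimator).
#'
#' @param freqs a [bootstrap_frequencies()] result.
#' @param min_sequence_gap see [build_graph()].
#' @return data.frame with `chain`, `resid`, `score`, `spread`.
#' @export
centrality_with_bootstrap <- function(freqs, min_sequence_gap = 2L) {
  g <- build_graph(freqs, min_sequence_gap)
  score <- eigenvector_centrality(g)
  ns <- ncol(freqs$per_sample)
  per <- matrix(NA_real_, length(score), ns)
  for (s in seq_len(ns)) {
    tab_s <- freqs$pairs
    tab_s$freq <- freqs$per_sample[, s]
    gs <- build_graph(tab_s, min_sequence_gap)
    sc <- eigenvector_centrality(gs)
    per[, s] <- sc[match(names(score), names(sc))]
  }
  spread <- apply(per, 1, stats::sd)
  if (ns == 1L) spread <- rep(0, length(score))
  data.frame(chain = g$nodes$chain, resid = g$nodes$resid,
             score = as.numeric(score), spread = spread,
             stringsAsFactors = FALSE)
}

#' Compare centrality scores between two conditions
#'
#' Produces the published-table layout: per-residue scores in each
#' condition, the signed difference `condition1 - condition2`, its absolute
#' value, and a highlight flag for absolute differences exceeding the
#' threshold.  Optionally the table is filtered to residues scoring at
#' least `min_score` in either condition.
#'
#' @param t1,t2 named score vectors ([eigenvector_centrality()]) or
#'   data.frames from [centrality_with_bootstrap()] for condition 1 and 2.
#' @param highlight highlight threshold on the absolute difference
#'   (strictly exceeded; default 0.005).
#' @param min_score optional filter: keep rows with a score `>= min_score`
#'   in at least one condition (the published table uses 0.10).
#' @param bw optional [bw_map()] used to annotate rows.
#' @return An object of class `centrality_table` (a data.frame with
#'   columns `chain`, `resid`, `bw`, `score_1`, `score_2`, `signed_diff`,
#'   `abs_diff`, `highlighted`).
#' @export
compare_conditions <- function(t1, t2, highlight = 0.005, min_score = NULL,
                               bw = NULL) {
  norm <- function(t) {
    if (is.data.frame(t)) {
      data.frame(chain = t$chain, resid = t$resid, score = t$score)
    } else {
      parts <- strsplit(names(t), ":", fixed = TRUE)
      data.frame(chain = vapply(parts, `[[`, "", 1),
                 resid = as.integer(vapply(parts, `[[`, "", 2)),
                 score = as.numeric(t))
    }
  }
  a <- norm(t1); b <- norm(t2)
  ka <- paste(a$chain, a$resid); kb <- paste(b$chain, b$resid)
  if (length(ka) != length(kb) || !setequal(ka, kb))
    .stopf("node universes differ between the two conditions")
  b <- b[match(ka, kb), ]
  tab <- data.frame(chain = a$chain, resid = a$resid,
                    bw = if (!is.null(bw)) suppressWarnings(bw_index(bw, a$resid)) else NA_character_,
                    score_1 = a$score, score_2 = b$score)
  tab$signed_diff <- tab$score_1 - tab$score_2
  tab$abs_diff <- abs(tab$signed_diff)
  tab$highlighted <- tab$abs_diff > highlight
  if (!is.null(min_score))
    tab <- tab[pmax(tab$score_1, tab$score_2) >= min_score, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("centrality_table", "data.frame")
  attr(tab, "highlight") <- highlight
  attr(tab, "min_score") <- min_score
  tab
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("centrality_table: %d residues, %d highlighted (|diff| > %g)\n",
              nrow(x), sum(x$highlighted), attr(x, "highlight")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
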