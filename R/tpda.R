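#' Gaussian conditional mutual information
#'
#' For continuous variables the conditional mutual information of `x` and
#' `y` given a conditioning set is `-0.5 log(1 - rho^2)` with `rho` their
#' partial correlation given the set; the p-value comes from the Fisher-z
#' test of `rho` (`z = atanh(rho) sqrt(n - |S| - 3)`).  This instantiates
#' the dependency test of the three-phase structure learner for
#' linear-Gaussian data.
#'
#' @param data a data frame of numeric variables.
#' @param x,y variable names.
#' @param cond character vector of conditioning variable names.
#' @return A one-row tibble: `cmi` (>= 0, in nats), `rho`, `p`, `n`.
#' @examples
#' d <- data.frame(a = rnorm(200), b = rnorm(200))
#' gaussian_cmi(d, "a", "b")
#' @export
gaussian_cmi <- function(data, x, y, cond = character()) {
  stopifnot(all(c(x, y, cond) %in% names(data)))
  d <- data[stats::complete.cases(data[, c(x, y, cond), drop = FALSE]),
            c(x, y, cond), drop = FALSE]
  n <- nrow(d)
  if (n <= length(cond) + 3L) stop("need n > |conditioning set| + 3", call. = FALSE)
  if (length(cond) == 0L) {
    rho <- stats::cor(d[[x]], d[[y]])
  } else {
    C <- as.matrix(d[, cond, drop = FALSE])
    if (qr(cbind(1, C))$rank < ncol(C) + 1L) {
      stop("conditioning set is collinear (degenerate)", call. = FALSE)
    }
    rx <- as.numeric(residualize(matrix(d[[x]], ncol = 1L), C))
    ry <- as.numeric(residualize(matrix(d[[y]], ncol = 1L), C))
    rho <- stats::cor(rx, ry)
  }
  rho <- min(max(rho, -R_CLAMP), R_CLAMP)
  z <- atanh(rho) * sqrt(max(n - length(cond) - 3L, 1L))
  tibble::tibble(cmi = -0.5 * log(1 - rho^2), rho = rho,
                 p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Edge determination coefficient
#'
#' Squared Pearson correlation of the two joined variables, the magnitude
#' measure attached to every learned edge.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return `cor(x, y)^2`.
#' @export
edge_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; determination coefficient undefined", call. = FALSE)
  }
  stats::cor(x, y)^2
}

## -- graph helpers on a named adjacency matrix -------------------------------

# Is there an adjacency path between a and b (excluding the direct edge)?
has_path <- function(adj, a, b, exclude_direct = FALSE) {
  if (exclude_direct) adj[a, b] <- adj[b, a] <- FALSE
  seen <- a
  frontier <- a
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
    nxt <- setdiff(nxt, seen)
    if (b %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# Neighbors of a lying on some adjacency path from a to b (graph minus a
# must connect them to b).
path_neighbors <- function(adj, a, b) {
  nb <- setdiff(which(adj[a, ]), b)
  adj_wo_a <- adj
  adj_wo_a[a, ] <- adj_wo_a[, a] <- FALSE
  nb[vapply(nb, function(v) v == b || has_path(adj_wo_a, v, b), logical(1))]
}

all_subsets <- function(s) {
  if (length(s) == 0L) return(list(integer(0)))
  out <- list(integer(0))
  for (k in seq_along(s)) {
    # index via seq_along: combn(x, k) with scalar x would expand 1:x
    out <- c(out, lapply(utils::combn(seq_along(s), k, simplify = FALSE),
                         function(ix) s[ix]))
  }
  out
}

#' Three-phase dependency Bayesian network structure learning
#'
#' Learns a network over continuous variables with the draft / thicken /
#' thin procedure, using the Gaussian conditional-mutual-information test
#' ([gaussian_cmi()]) at level `alpha` as the dependency oracle:
#'
#' * **Drafting** ranks all marginally dependent pairs by mutual information
#'   and adds an edge when no adjacency path yet connects the pair;
#'   remaining dependent pairs are deferred.
#' * **Thickening** adds each deferred pair unless some cut set drawn from
#'   the path-adjacent neighbours of either endpoint renders it
#'   conditionally independent (the cut-set search is exhaustive over those
#'   bounded candidate sets).
#' * **Thinning** re-examines every edge whose endpoints stay connected
#'   without it and removes it if such a cut set separates the pair.
#'
#' Edges are then oriented by collider detection (a common neighbour absent
#' from the separating set of a non-adjacent pair) followed by Meek-style
#' propagation; orientations that cannot be derived are reported as
#' bidirected.  Each edge carries the determination coefficient (squared
#' Pearson correlation) of its endpoints.  Pair order is deterministic
#' (mutual-information rank, ties lexicographic on names), so the learned
#' skeleton does not depend on column order.
#'
#' @param data a data frame of numeric variables (>= 3 columns, n >= 30).
#' @param alpha significance level of the dependency tests (default 0.05).
#' @return An object of class `bn_graph`: a list with `nodes` and `edges`
#'   (tibble: `from`, `to`, `direction` in `forward` / `bidirected`,
#'   `r2`, `p_marginal`).
#' @export
tpda_learn <- function(data, alpha = 0.05) {
  data <- as.data.frame(data)
  vars <- names(data)
  p <- length(vars)
  if (p < 3L) stop("need at least 3 variables", call. = FALSE)
  n <- sum(stats::complete.cases(data))
  if (n < 30L) stop("need n >= 30 complete cases", call. = FALSE)
  const <- vars[vapply(vars, function(v) stats::sd(data[[v]], na.rm = TRUE) == 0,
                       logical(1))]
  if (length(const) > 0L) {
    stop("constant variable(s): ", paste(const, collapse = ", "), call. = FALSE)
  }

  ci <- function(i, j, S) gaussian_cmi(data, vars[i], vars[j], vars[S])

  pairs <- utils::combn(p, 2L)
  marg <- lapply(seq_len(ncol(pairs)), function(k) ci(pairs[1L, k], pairs[2L, k], integer(0)))
  mi <- vapply(marg, `[[`, numeric(1), "cmi")
  pv <- vapply(marg, `[[`, numeric(1), "p")
  pair_names <- apply(pairs, 2L, function(ij) paste(sort(vars[ij]), collapse = "|"))
  ord <- order(-mi, pair_names)

  adj <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  sepsets <- list()   # named by "i|j" with i < j; integer vector of node indices
  set_sep <- function(i, j, S) {
    sepsets[[paste(sort(c(i, j)), collapse = "|")]] <<- S
  }
  get_sep <- function(i, j) sepsets[[paste(sort(c(i, j)), collapse = "|")]]

  dependent <- ord[pv[ord] < alpha]
  for (k in ord[pv[ord] >= alpha]) set_sep(pairs[1L, k], pairs[2L, k], integer(0))

  # Phase 1: drafting
  deferred <- integer(0)
  for (k in dependent) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    if (!has_path(adj, a, b)) adj[a, b] <- adj[b, a] <- TRUE
    else deferred <- c(deferred, k)
  }

  # exhaustive cut-set search over path-adjacent candidate sets
  try_separate <- function(a, b, graph) {
    for (base in list(path_neighbors(graph, a, b), path_neighbors(graph, b, a))) {
      base <- setdiff(sort(base), c(a, b))
      for (S in all_subsets(base)) {
        if (length(S) == 0L) next   # marginal dependence already established
        if (ci(a, b, S)$p >= alpha) return(S)
      }
    }
    NULL
  }

  # Phase 2: thickening
  for (k in deferred) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    S <- try_separate(a, b, adj)
    if (is.null(S)) adj[a, b] <- adj[b, a] <- TRUE else set_sep(a, b, S)
  }

  # Phase 3: thinning
  edge_list <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(edge_list) > 0L) {
    ord_e <- order(vars[edge_list[, 1L]], vars[edge_list[, 2L]])
    for (e in ord_e) {
      a <- edge_list[e, 1L]; b <- edge_list[e, 2L]
      adj2 <- adj; adj2[a, b] <- adj2[b, a] <- FALSE
      if (!has_path(adj2, a, b)) next
      S <- try_separate(a, b, adj2)
      if (!is.null(S)) { adj[a, b] <- adj[b, a] <- FALSE; set_sep(a, b, S) }
    }
  }

  # Orientation: colliders, then Meek propagation
  arrow <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  for (c_ in seq_len(p)) {
    nbrs <- which(adj[c_, ])
    if (length(nbrs) < 2L) next
    for (ab in utils::combn(sort(nbrs), 2L, simplify = FALSE)) {
      a <- ab[1L]; b <- ab[2L]
      if (adj[a, b]) next
      S <- get_sep(a, b)
      if (!is.null(S) && !(c_ %in% S)) {
        arrow[a, c_] <- TRUE
        arrow[b, c_] <- TRUE
      }
    }
  }
  arrow <- meek_propagate(adj, arrow)

  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(edges)), function(e) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    fw <- arrow[a, b]; bw <- arrow[b, a]
    if (fw && !bw) { from <- a; to <- b; dir <- "forward" }
    else if (bw && !fw) { from <- b; to <- a; dir <- "forward" }
    else { from <- min(a, b); to <- max(a, b); dir <- "bidirected" }
    k <- which(pairs[1L, ] == min(a, b) & pairs[2L, ] == max(a, b))
    tibble::tibble(from = vars[from], to = vars[to], direction = dir,
                   r2 = edge_r2(data[[vars[a]]], data[[vars[b]]]),
                   p_marginal = pv[k])
  })
  edges_tb <- if (length(rows) == 0L) {
    tibble::tibble(from = character(), to = character(), direction = character(),
                   r2 = numeric(), p_marginal = numeric())
  } else dplyr::arrange(dplyr::bind_rows(rows), .data$from, .data$to)
  structure(list(nodes = vars, edges = edges_tb, alpha = alpha),
            class = "bn_graph")
}

# Meek orientation rules R1-R3; arrows only ever added to undirected edges,
# never reversing an existing arrow.  A doubly-arrowed pair (from conflicting
# colliders) is left as-is and reported bidirected downstream.
meek_propagate <- function(adj, arrow) {
  p <- nrow(adj)
  directed <- function(a, b) arrow[a, b] && !arrow[b, a]
  undirected <- function(a, b) adj[a, b] && !arrow[a, b] && !arrow[b, a]
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (a == b || !undirected(a, b)) next
      orient <- FALSE
      for (c_ in seq_len(p)) {
        if (c_ == a || c_ == b) next
        # R1: c -> a, a - b, c and b non-adjacent  =>  a -> b
        if (directed(c_, a) && !adj[c_, b]) orient <- TRUE
        # R2: a -> c -> b and a - b  =>  a -> b
        if (directed(a, c_) && directed(c_, b)) orient <- TRUE
        if (orient) break
      }
      if (!orient) {
        # R3: a - c1 -> b, a - c2 -> b, c1, c2 non-adjacent  =>  a -> b
        cs <- which(vapply(seq_len(p), function(c_)
          c_ != a && c_ != b && undirected(a, c_) && directed(c_, b), logical(1)))
        if (length(cs) >= 2L) {
          prs <- utils::combn(cs, 2L)
          if (any(!adj[cbind(prs[1L, ], prs[2L, ])])) orient <- TRUE
        }
      }
      if (orient) { arrow[a, b] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  arrow
}

#' @export
print.bn_graph <- function(x, ...) {
  cat(sprintf("<bn_graph> %d nodes, %d edge(s) (%d directed, %d bidirected)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$direction == "forward"),
              sum(x$edges$direction == "bidirected")))
  if (nrow(x$edges) > 0L) {
    sym <- ifelse(x$edges$direction == "forward", "->", "<->")
    cat(paste0("  ", x$edges$from, " ", sym, " ", x$edges$to,
               sprintf("  (R2 = %.2f)", x$edges$r2), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a learned network as DOT and edge-list TSV
#'
#' @param graph a `bn_graph`.
#' @param dot_path,tsv_path output paths (`NULL` skips that format).
#' @return `graph`, invisibly.
#' @export
write_bn_graph <- function(graph, dot_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(graph, "bn_graph"))
  if (!is.null(dot_path)) {
    lines <- c("digraph bn {")
    lines <- c(lines, paste0("  \"", graph$nodes, "\";"))
    if (nrow(graph$edges) > 0L) {
      attr_ <- ifelse(graph$edges$direction == "bidirected", " [dir=both]", "")
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;  // R2=%.3f",
                                graph$edges$from, graph$edges$to, attr_,
                                graph$edges$r2))
    }
    writeLines(c(lines, "}"), dot_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(graph$edges, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(graph)
}
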