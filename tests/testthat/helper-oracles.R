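# Brute-force graphical oracles, independent of the package's
# moralized-ancestral-graph implementation: explicit path enumeration with
# the chain/fork/collider blocking rules, and exhaustive subset search for
# the backdoor criterion.

random_dag <- function(n = 6, p_edge = 0.35, p_latent = 0.25) {
  nodes <- sample(LETTERS[seq_len(n)])
  ep <- character(); ec <- character()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (stats::runif(1) < p_edge) {
        ep <- c(ep, nodes[i]); ec <- c(ec, nodes[j])
      }
    }
  }
  latent <- nodes[stats::runif(n) < p_latent]
  causal_dag(nodes, data.frame(parent = ep, child = ec), latent = latent)
}

# all simple paths between x and y in the skeleton, as node sequences
enumerate_paths <- function(dag, x, y) {
  e <- dag_edges(dag)
  nbrs <- function(v) unique(c(e$child[e$parent == v], e$parent[e$child == v]))
  paths <- list()
  dfs <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in setdiff(nbrs(v), path)) dfs(c(path, w))
  }
  dfs(x)
  paths
}

path_blocked <- function(dag, path, given) {
  if (length(path) == 2L) return(FALSE)
  e <- dag_edges(dag)
  is_parent <- function(a, b) any(e$parent == a & e$child == b)
  for (k in seq(2L, length(path) - 1L)) {
    a <- path[k - 1L]; b <- path[k]; cc <- path[k + 1L]
    if (is_parent(a, b) && is_parent(cc, b)) {   # collider
      if (!(b %in% given) &&
          !any(dag_descendants(dag, b) %in% given)) return(TRUE)
    } else {                                     # chain or fork
      if (b %in% given) return(TRUE)
    }
  }
  FALSE
}

oracle_d_separated <- function(dag, x, y, given = character()) {
  all(vapply(enumerate_paths(dag, x, y), path_blocked, logical(1L),
             dag = dag, given = given))
}

# backdoor criterion checked path-by-path: no descendant of the exposure in
# the set, and every path entering the exposure through a parent is blocked
oracle_backdoor_valid <- function(dag, exposure, outcome, members) {
  if (exposure %in% members || outcome %in% members) return(FALSE)
  if (any(members %in% dag_descendants(dag, exposure))) return(FALSE)
  e <- dag_edges(dag)
  for (path in enumerate_paths(dag, exposure, outcome)) {
    into_exposure <- any(e$parent == path[2L] & e$child == exposure)
    if (into_exposure && !path_blocked(dag, path, members)) return(FALSE)
  }
  TRUE
}

oracle_minimal_backdoor_sets <- function(dag, exposure, outcome) {
  observed <- dag$nodes[dag$observed[dag$nodes]]
  pool <- setdiff(observed, c(exposure, outcome))
  valid <- list()
  for (k in 0:length(pool)) {
    sets <- if (k == 0L) list(character()) else
      utils::combn(pool, k, simplify = FALSE)
    for (s in sets) {
      if (oracle_backdoor_valid(dag, exposure, outcome, s)) {
        valid <- c(valid, list(sort(s)))
      }
    }
  }
  is_min <- vapply(valid, function(s)
    !any(vapply(valid, function(t)
      length(t) < length(s) && all(t %in% s), logical(1L))), logical(1L))
  valid[is_min]
}

set_list_identical <- function(a, b) {
  norm <- function(l) sort(vapply(l, function(s)
    paste(sort(s), collapse = ","), character(1L)))
  identical(norm(a), norm(b))
}
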