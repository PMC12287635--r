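#' Construct a causal directed acyclic graph
#'
#' A `causal_dag` stores a node set with observed/latent flags and a set of
#' directed edges, and underpins d-separation queries, backdoor adjustment-set
#' enumeration and implied-independence extraction. Nodes are stored in sorted
#' order so that structurally identical graphs compare identical regardless of
#' declaration order.
#'
#' @param nodes Character vector of node names (unique, non-empty).
#' @param edges Two-column data frame or matrix with columns `parent`, `child`.
#'   May have zero rows.
#' @param latent Character vector naming the unobserved nodes (subset of
#'   `nodes`). All other nodes are observed.
#'
#' @return An object of class `causal_dag` with elements `nodes` (sorted
#'   character), `observed` (named logical), `parents` and `children` (named
#'   lists of character vectors).
#' @examples
#' g <- causal_dag(c("A", "B", "C"),
#'                 data.frame(parent = c("A", "B"), child = c("B", "C")))
#' d_separated(g, "A", "C", "B")
#' @export
causal_dag <- function(nodes, edges = NULL, latent = character()) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a causal_dag needs at least one node", call. = FALSE)
  if (anyDuplicated(nodes)) {
    stop("duplicate node name(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(nodes))) stop("empty node name", call. = FALSE)
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    names(edges)[1:2] <- c("parent", "child")
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
    bad <- setdiff(unique(c(edges$parent, edges$child)), nodes)
    if (length(bad)) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(edges$parent == edges$child)) {
      stop("self-loop detected at node ",
           edges$parent[edges$parent == edges$child][1L], call. = FALSE)
    }
    edges <- unique(edges[, c("parent", "child")])
  }
  if (!all(latent %in% nodes)) {
    stop("latent name(s) not among nodes: ",
         paste(setdiff(latent, nodes), collapse = ", "), call. = FALSE)
  }
  nodes <- sort(nodes)
  observed <- stats::setNames(!(nodes %in% latent), nodes)
  parents <- lapply(stats::setNames(nodes, nodes), function(v)
    sort(edges$parent[edges$child == v]))
  children <- lapply(stats::setNames(nodes, nodes), function(v)
    sort(edges$child[edges$parent == v]))
  dag <- structure(
    list(nodes = nodes, observed = observed, parents = parents,
         children = children),
    class = "causal_dag"
  )
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("graph is cyclic: ", paste(cyc, collapse = " -> "), call. = FALSE)
  }
  dag
}

# Returns NULL if acyclic, else one cycle as a character vector ending where
# it starts (used to build the parse error message).
find_cycle <- function(dag) {
  indeg <- vapply(dag$parents, length, integer(1L))
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in dag$children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen == length(dag$nodes)) return(NULL)
  # walk backwards through the residual (all-cyclic) subgraph until a repeat
  residual <- names(indeg)[indeg > 0L]
  v <- residual[1L]
  path <- v
  repeat {
    v <- intersect(dag$parents[[v]], residual)[1L]
    if (v %in% path) {
      cyc <- c(v, rev(path[seq(which(path == v), length(path))]))
      return(rev(cyc))
    }
    path <- c(path, v)
  }
}

#' @export
print.causal_dag <- function(x, ...) {
  n_lat <- sum(!x$observed)
  n_edge <- sum(vapply(x$children, length, integer(1L)))
  cat(sprintf("<causal_dag> %d nodes (%d latent), %d edges\n",
              length(x$nodes), n_lat, n_edge))
  invisible(x)
}

#' @rdname causal_dag
#' @param x Object to test.
#' @export
is_causal_dag <- function(x) inherits(x, "causal_dag")

#' Edge list of a causal DAG
#'
#' @param dag A [causal_dag()].
#' @return Data frame with columns `parent` and `child`, sorted.
#' @export
dag_edges <- function(dag) {
  stopifnot(is_causal_dag(dag))
  parent <- rep(dag$nodes, vapply(dag$children[dag$nodes], length, integer(1L)))
  child <- unlist(dag$children[dag$nodes], use.names = FALSE)
  if (is.null(child)) child <- character()
  data.frame(parent = parent, child = child)
}

#' Parse a causal DAG from edge-list text
#'
#' The format is one statement per line: `A -> B` declares a directed edge,
#' `A [latent]` declares an unobserved node, and a bare `A` declares an
#' observed node. Nodes first seen in an edge default to observed. `#` starts
#' a comment. [dag_to_text()] writes the same format back in canonical sorted
#' order, and `parse_dag(dag_to_text(g))` reproduces `g` exactly.
#'
#' @param text A character scalar (possibly with embedded newlines) or a
#'   character vector of lines.
#' @return A [causal_dag()].
#' @seealso [read_dag()] to read from a file, [dag_to_text()] for the inverse.
#' @examples
#' parse_dag("A -> B\nB -> C\nU [latent]\nU -> C")
#' @export
parse_dag <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  nodes <- character()
  latent <- character()
  ep <- character(); ec <- character()
  declare <- function(name, is_latent) {
    if (name %in% nodes) {
      stop("duplicate node declaration: ", name, call. = FALSE)
    }
    nodes <<- c(nodes, name)
    if (is_latent) latent <<- c(latent, name)
  }
  for (ln in lines) {
    if (grepl("->", ln, fixed = TRUE)) {
      m <- regmatches(ln, regexec("^(\\S+)\\s*->\\s*(\\S+)$", ln))[[1L]]
      if (length(m) != 3L) stop("cannot parse edge line: '", ln, "'", call. = FALSE)
      ep <- c(ep, m[2L]); ec <- c(ec, m[3L])
    } else {
      m <- regmatches(ln, regexec(
        "^(\\S+)\\s*(\\[(latent|unobserved|observed)\\])?$", ln))[[1L]]
      if (length(m) == 0L) stop("cannot parse line: '", ln, "'", call. = FALSE)
      declare(m[2L], m[4L] %in% c("latent", "unobserved"))
    }
  }
  implicit <- setdiff(unique(c(ep, ec)), nodes)
  nodes <- c(nodes, implicit)
  causal_dag(nodes, data.frame(parent = ep, child = ec), latent = latent)
}

#' @rdname parse_dag
#' @param path Path to a DAG text file.
#' @export
read_dag <- function(path) {
  parse_dag(readLines(path, warn = FALSE))
}

#' Serialize a causal DAG to canonical edge-list text
#'
#' @param dag A [causal_dag()].
#' @return A character scalar: latent declarations, then isolated observed
#'   nodes, then edges, each block sorted.
#' @export
dag_to_text <- function(dag) {
  stopifnot(is_causal_dag(dag))
  e <- dag_edges(dag)
  e <- e[order(e$parent, e$child), , drop = FALSE]
  lat <- sort(names(dag$observed)[!dag$observed])
  connected <- unique(c(e$parent, e$child))
  isolated <- sort(setdiff(dag$nodes[dag$observed[dag$nodes]], connected))
  lines <- c(if (length(lat)) paste(lat, "[latent]"), isolated,
             if (nrow(e)) paste(e$parent, "->", e$child))
  paste(lines, collapse = "\n")
}

#' @rdname dag_to_text
#' @param path File to write.
#' @export
write_dag <- function(dag, path) {
  writeLines(dag_to_text(dag), path)
  invisible(path)
}

check_nodes <- function(dag, tokens) {
  bad <- setdiff(tokens, dag$nodes)
  if (length(bad)) {
    stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Ancestors and descendants of DAG nodes
#'
#' Transitive closures over the directed edges; `nodes` themselves are not
#' included in the result.
#'
#' @param dag A [causal_dag()].
#' @param nodes Character vector of node names.
#' @return Sorted character vector.
#' @export
dag_ancestors <- function(dag, nodes) {
  closure(dag, nodes, "parents")
}

#' @rdname dag_ancestors
#' @export
dag_descendants <- function(dag, nodes) {
  closure(dag, nodes, "children")
}

closure <- function(dag, nodes, direction) {
  check_nodes(dag, nodes)
  out <- character()
  frontier <- nodes
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(dag[[direction]][frontier], use.names = FALSE)),
                   c(out, nodes))
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

#' Test d-separation
#'
#' Decides whether `x` and `y` are d-separated given the conditioning set
#' `given`, using the moralized-ancestral-graph criterion: restrict to the
#' ancestral set of `{x, y} U given`, moralize (drop directions and marry
#' co-parents), delete the conditioned nodes, and test disconnection. This is
#' equivalent to the path-blocking rules (chains/forks blocked iff the middle
#' node is conditioned on; colliders blocked iff neither the collider nor any
#' of its descendants is conditioned on).
#'
#' @param dag A [causal_dag()].
#' @param x,y Node names, distinct and not in `given`.
#' @param given Character vector of conditioning nodes (may be empty).
#' @return `TRUE` if every path between `x` and `y` is blocked.
#' @examples
#' chain <- parse_dag("A -> B\nB -> C")
#' d_separated(chain, "A", "C", "B")   # TRUE
#' d_separated(chain, "A", "C")        # FALSE
#' @export
d_separated <- function(dag, x, y, given = character()) {
  stopifnot(is_causal_dag(dag))
  given <- as.character(given)
  check_nodes(dag, c(x, y, given))
  if (x == y) stop("x and y must differ", call. = FALSE)
  if (x %in% given || y %in% given) {
    stop("x and y must not be in the conditioning set", call. = FALSE)
  }
  anc <- union(c(x, y, given), dag_ancestors(dag, c(x, y, given)))
  # moralized adjacency within the ancestral set
  adj <- stats::setNames(vector("list", length(anc)), anc)
  add <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (v in anc) {
    pv <- intersect(dag$parents[[v]], anc)
    for (p in pv) add(p, v)
    if (length(pv) > 1L) {
      prs <- utils::combn(pv, 2L)
      for (k in seq_len(ncol(prs))) add(prs[1L, k], prs[2L, k])
    }
  }
  keep <- setdiff(anc, given)
  reached <- x
  frontier <- x
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(adj[frontier], use.names = FALSE)),
                             keep), reached)
    if (y %in% nxt) return(FALSE)
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  TRUE
}

# DAG with all edges out of `node` removed: the graph in which d-separation of
# exposure and outcome given S (S containing no descendant of the exposure) is
# the backdoor criterion.
remove_outgoing <- function(dag, node) {
  e <- dag_edges(dag)
  e <- e[e$parent != node, , drop = FALSE]
  causal_dag(dag$nodes, e, latent = names(dag$observed)[!dag$observed])
}

#' Check a candidate backdoor adjustment set
#'
#' `members` is a valid adjustment set for the total effect of `exposure` on
#' `outcome` when it contains no descendant of the exposure and d-separates
#' exposure from outcome in the graph with the exposure's outgoing edges
#' removed (so that only backdoor paths remain).
#'
#' @param dag A [causal_dag()].
#' @param exposure,outcome Node names.
#' @param members Character vector (possibly empty) of adjustment variables.
#' @return Logical scalar.
#' @export
is_adjustment_set <- function(dag, exposure, outcome, members = character()) {
  stopifnot(is_causal_dag(dag))
  members <- as.character(members)
  check_nodes(dag, c(exposure, outcome, members))
  if (exposure == outcome) stop("exposure and outcome must differ", call. = FALSE)
  if (exposure %in% members || outcome %in% members) return(FALSE)
  if (length(intersect(members, dag_descendants(dag, exposure)))) return(FALSE)
  d_separated(remove_outgoing(dag, exposure), exposure, outcome, members)
}

#' Enumerate minimal backdoor adjustment sets
#'
#' Returns every minimal (no valid proper subset) set of *observed* nodes
#' satisfying the backdoor criterion for the total effect of `exposure` on
#' `outcome`. Candidates are restricted to observed non-descendants of the
#' exposure lying in the ancestral set of the exposure or outcome (minimal
#' separators contain only such nodes), and enumeration proceeds by increasing
#' set size, skipping supersets of sets already found.
#'
#' A result containing `character(0)` means no adjustment is needed; an empty
#' list means no valid observed adjustment set exists.
#'
#' @param dag A [causal_dag()].
#' @param exposure,outcome Distinct node names.
#' @param max_candidates Refuse enumeration when the candidate pool exceeds
#'   this many nodes (guards against exponential blow-up; default 25).
#' @return List of sorted character vectors, ordered by size then
#'   lexicographically; attributes `exposure` and `outcome` are set.
#' @examples
#' g <- parse_dag("Z -> X\nZ -> Y\nX -> Y")
#' minimal_adjustment_sets(g, "X", "Y")  # list("Z")
#' @export
minimal_adjustment_sets <- function(dag, exposure, outcome, max_candidates = 25L) {
  stopifnot(is_causal_dag(dag))
  check_nodes(dag, c(exposure, outcome))
  if (exposure == outcome) stop("exposure and outcome must differ", call. = FALSE)
  de <- dag_descendants(dag, exposure)
  g2 <- remove_outgoing(dag, exposure)
  anc <- dag_ancestors(g2, c(exposure, outcome))
  pool <- setdiff(intersect(dag$nodes[dag$observed[dag$nodes]], anc),
                  c(exposure, outcome, de))
  if (length(pool) > max_candidates) {
    stop("adjustment-set enumeration refused: ", length(pool),
         " candidate nodes exceed max_candidates = ", max_candidates,
         call. = FALSE)
  }
  found <- list()
  for (k in 0:length(pool)) {
    sets <- if (k == 0L) list(character()) else
      utils::combn(pool, k, simplify = FALSE)
    for (s in sets) {
      if (any(vapply(found, function(m) all(m %in% s), logical(1L)))) next
      if (d_separated(g2, exposure, outcome, s)) found <- c(found, list(s))
    }
  }
  structure(found, exposure = exposure, outcome = outcome)
}

#' Conditional independences implied by a DAG
#'
#' Emits, for every non-adjacent node pair, one independence claim
#' `x _||_ y | given` with a minimal separating set (smallest cardinality,
#' lexicographic tie-break). With `observed_only = TRUE` both the pair and the
#' separating set are restricted to observed nodes, and pairs that cannot be
#' separated by observed nodes are omitted.
#'
#' @param dag A [causal_dag()].
#' @param observed_only Restrict to observed nodes (default `TRUE`).
#' @return Data frame of class `independence_claims` with columns `x`, `y`,
#'   `given` (list column of character vectors), `p_value`, `rejected`,
#'   `skipped`.
#' @export
implied_independences <- function(dag, observed_only = TRUE) {
  stopifnot(is_causal_dag(dag))
  pool_all <- if (observed_only) dag$nodes[dag$observed[dag$nodes]] else dag$nodes
  e <- dag_edges(dag)
  adjacent <- function(a, b) {
    any(e$parent == a & e$child == b) || any(e$parent == b & e$child == a)
  }
  xs <- character(); ys <- character(); givens <- list()
  if (length(pool_all) >= 2L) {
    prs <- utils::combn(sort(pool_all), 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      if (adjacent(a, b)) next
      cand <- setdiff(intersect(pool_all,
                                dag_ancestors(dag, c(a, b))), c(a, b))
      sep <- minimal_separator(dag, a, b, cand)
      if (is.null(sep)) next
      xs <- c(xs, a); ys <- c(ys, b); givens <- c(givens, list(sep))
    }
  }
  out <- data.frame(x = xs, y = ys, stringsAsFactors = FALSE)
  out$given <- givens
  out$p_value <- rep(NA_real_, nrow(out))
  out$rejected <- rep(NA, nrow(out))
  out$skipped <- rep(FALSE, nrow(out))
  class(out) <- c("independence_claims", "data.frame")
  out
}

# Smallest-cardinality separating subset of `candidates`, lexicographic
# tie-break; NULL when none exists.
minimal_separator <- function(dag, x, y, candidates) {
  candidates <- sort(candidates)
  for (k in 0:length(candidates)) {
    sets <- if (k == 0L) list(character()) else
      utils::combn(candidates, k, simplify = FALSE)
    for (s in sets) {
      if (d_separated(dag, x, y, s)) return(s)
    }
  }
  NULL
}

#' Simulate linear-Gaussian data from a DAG
#'
#' Each node is generated in topological order as a linear combination of its
#' parents plus Gaussian noise. The resulting joint distribution is faithful
#' to the graph for generic coefficients, so the DAG's implied conditional
#' independences hold exactly and can be used to calibrate
#' [test_independences()].
#'
#' @param dag A [causal_dag()].
#' @param n Number of rows.
#' @param coef Edge coefficient (scalar, applied to every edge).
#' @param noise_sd Standard deviation of each node's noise term.
#' @param seed Optional integer seed.
#' @return Data frame with one column per node (latent nodes included;
#'   attribute `observed` lists the observed ones).
#' @export
simulate_dag_gaussian <- function(dag, n, coef = 0.6, noise_sd = 1, seed = NULL) {
  stopifnot(is_causal_dag(dag), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ord <- topological_order(dag)
  dat <- matrix(0, nrow = n, ncol = length(ord),
                dimnames = list(NULL, ord))
  for (v in ord) {
    mu <- 0
    for (p in dag$parents[[v]]) mu <- mu + coef * dat[, p]
    dat[, v] <- mu + stats::rnorm(n, sd = noise_sd)
  }
  out <- as.data.frame(dat)
  attr(out, "observed") <- dag$nodes[dag$observed[dag$nodes]]
  out
}

topological_order <- function(dag) {
  indeg <- vapply(dag$parents, length, integer(1L))
  out <- character()
  queue <- sort(names(indeg)[indeg == 0L])
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in dag$children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- sort(c(queue, w))
    }
  }
  out
}

#' Bundled dog-activity DAG
#'
#' Path to (or parsed form of) the package's editable fixture encoding the
#' hypothesized data-generating process for daily active minutes: dog
#' attributes (age, breed size, sex, neuter status, weight status), health
#' mediators (unhealthy diagnosis, injury), owner and environmental variables
#' (owner age, location type, climate, latitude, season, day type) and one
#' latent node (exercise opportunity). It is a working hypothesis shipped as
#' data, not ground truth, and can be replaced by any file in the same format.
#'
#' @param parse If `TRUE` (default) return the parsed [causal_dag()];
#'   otherwise return the file path.
#' @return A `causal_dag` or a path.
#' @export
activity_dag <- function(parse = TRUE) {
  path <- system.file("extdata", "activity_dag.txt", package = "caniact",
                      mustWork = TRUE)
  if (parse) read_dag(path) else path
}
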