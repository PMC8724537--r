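## EC-number metabolic network: pathway retrieval by query enzymes,
## product->substrate directed edges (currency cofactors excluded), the
## five per-node topology measures, Tukey degree-outlier hubs and
## multi-resolution (HiDeF-style persistence) communities.

.ecPattern <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

#' Extract EC numbers from an annotated gene set
#'
#' Keeps unique, syntactically valid EC numbers (`d.d.d.d`, trailing `-`
#' allowed but flagged as partial) with the contributing genes; malformed
#' strings are rejected with a warning, genes without an EC are skipped.
#'
#' @param annot data.frame with columns `gene_id` and `EC` (possibly
#'   `;`/`,`-separated).
#' @return data.frame (`ec`, `genes` `;`-separated, `partial`).
#' @export
extractEC <- function(annot) {
  recs <- list()
  bad <- character()
  for (i in seq_len(nrow(annot))) {
    ecs <- .splitTerms(as.character(annot$EC[i] %||% ""))
    for (e in ecs) {
      if (!grepl(.ecPattern, e)) { bad <- c(bad, e); next }
      recs[[e]] <- union(recs[[e]], annot$gene_id[i])
    }
  }
  if (length(bad))
    warning("malformed EC string(s) rejected: ",
            paste(unique(bad), collapse = ", "))
  if (!length(recs))
    return(data.frame(ec = character(), genes = character(),
                      partial = logical()))
  data.frame(ec = names(recs),
             genes = vapply(recs, paste, "", collapse = ";"),
             partial = grepl("-$", names(recs)),
             row.names = NULL, stringsAsFactors = FALSE)
}

.compounds <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)[[1]]
  out[nzchar(out)]
}

#' Build the enzyme network from query ECs and a pathway database
#'
#' Retrieves every pathway containing at least one query EC and includes
#' *all* enzymes of the retrieved pathways as nodes (the neighbourhood of
#' the query set, not just the queries). A directed edge `a -> b` is
#' created when a product compound of a reaction of `a` is a substrate of
#' a reaction of `b` within the same pathway, excluding the currency
#' cofactors of [currencyCompounds()]. Disconnected nodes are retained.
#'
#' @param ecs data.frame from [extractEC()] (or character vector of query
#'   ECs).
#' @param pathways pathway data.frame (`pathway_id`, `reaction_id`, `ec`,
#'   `substrates`, `products`) as from [simulatePathwayDb()] /
#'   [readPathwayDb()].
#' @param currency compound exclusion list.
#' @return An [EnzymeNetwork-class] object (empty, with a warning, when no
#'   pathway matches).
#' @export
buildEnzymeNetwork <- function(ecs, pathways,
                               currency = currencyCompounds()) {
  if (is.data.frame(ecs)) {
    queryEc <- ecs$ec
    geneOf <- setNames(ecs$genes, ecs$ec)
  } else {
    queryEc <- as.character(ecs)
    geneOf <- setNames(rep("", length(queryEc)), queryEc)
  }
  pwHit <- unique(pathways$pathway_id[pathways$ec %in% queryEc])
  if (length(pwHit) == 0) {
    warning("no pathway contains a query EC: empty network")
    g <- igraph::make_empty_graph(directed = TRUE)
    return(new("EnzymeNetwork", graph = g,
               simple = igraph::as_undirected(g),
               nodes = data.frame(ec = character(), pathways = character(),
                                  genes = character(), query = logical())))
  }
  db <- pathways[pathways$pathway_id %in% pwHit, , drop = FALSE]
  nodeEc <- unique(db$ec)
  edges <- list()
  for (pw in pwHit) {
    rx <- db[db$pathway_id == pw, , drop = FALSE]
    for (i in seq_len(nrow(rx))) for (j in seq_len(nrow(rx))) {
      if (rx$ec[i] == rx$ec[j]) next
      shared <- intersect(setdiff(.compounds(rx$products[i]), currency),
                          setdiff(.compounds(rx$substrates[j]), currency))
      if (length(shared))
        edges[[length(edges) + 1]] <- c(rx$ec[i], rx$ec[j])
    }
  }
  el <- if (length(edges)) unique(do.call(rbind, edges)) else
    matrix(character(), 0, 2)
  pwOf <- vapply(nodeEc, function(e)
    paste(sort(unique(db$pathway_id[db$ec == e])), collapse = ";"), "")
  nodes <- data.frame(ec = nodeEc, pathways = pwOf,
                      genes = ifelse(nodeEc %in% names(geneOf),
                                     geneOf[nodeEc], ""),
                      query = nodeEc %in% queryEc,
                      row.names = NULL, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(as.data.frame(el), directed = TRUE,
                                     vertices = data.frame(name = nodeEc))
  simple <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  new("EnzymeNetwork", graph = g, simple = simple, nodes = nodes)
}

## Brandes-style BFS from each source: hop distances and shortest-path
## counts for all pairs of an undirected graph given as adjacency list.
.pathCounts <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  Sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- rep(0, n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sig[w] <- sig[w] + sig[v]
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist; Sig[s, ] <- sig
  }
  list(D = D, Sig = Sig)
}

#' Per-node and graph-level topology of an enzyme network
#'
#' Degree in/out/total on the directed graph; betweenness (normalized by
#' `(n-1)(n-2)/2`) and stress (raw shortest-path counts through the node)
#' on the undirected simple graph; eccentricity and mean shortest path
#' per node within each connected component; neighborhood connectivity as
#' the mean total degree of a node's neighbors; diameter as the maximum
#' eccentricity over the largest component. The graph-level mean neighbor
#' count is reported both as distinct neighbors on the simple graph
#' (`mean.neighbors`, equal to 2E/N) and as the mean total directed
#' degree (`mean.degree.directed`) — the two conventions differ on
#' multi-edge/directed source data.
#'
#' @param N [EnzymeNetwork-class] or an igraph (undirected graphs are
#'   treated as their own simple graph).
#' @return A [TopologyReport-class] object.
#' @export
networkTopology <- function(N) {
  if (is(N, "EnzymeNetwork")) {
    g <- N@graph; simple <- N@simple
  } else {
    g <- N
    simple <- igraph::simplify(igraph::as_undirected(N, mode = "collapse"))
  }
  n <- igraph::vcount(simple)
  if (n == 0) stop("empty network")
  nm <- igraph::V(simple)$name %||% as.character(seq_len(n))
  degIn <- igraph::degree(g, mode = "in")
  degOut <- igraph::degree(g, mode = "out")
  degTot <- igraph::degree(g, mode = "all")
  degSimple <- igraph::degree(simple)

  adj <- igraph::as_adj_list(simple)
  adj <- lapply(adj, as.integer)
  pc <- .pathCounts(adj)
  D <- pc$D; Sig <- pc$Sig

  stress <- numeric(n)
  for (v in seq_len(n)) {
    onPath <- outer(D[, v], D[v, ], "+") == D & is.finite(D)
    cnt <- outer(Sig[, v], Sig[v, ]) * onPath
    cnt[v, ] <- 0; cnt[, v] <- 0
    diag(cnt) <- 0
    stress[v] <- sum(cnt[upper.tri(cnt)])
  }
  btw <- igraph::betweenness(simple, directed = FALSE,
                             normalized = n > 2)
  finD <- D; finD[is.infinite(finD)] <- NA
  diag(finD) <- NA
  ecc <- apply(finD, 1, function(z)
    if (all(is.na(z))) 0 else max(z, na.rm = TRUE))
  apl <- apply(finD, 1, function(z)
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  nbc <- vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    if (!length(nb)) NA_real_ else mean(degTot[nb])
  }, numeric(1))

  comp <- igraph::components(simple)
  big <- which.max(comp$csize)
  diam <- max(ecc[comp$membership == big])
  new("TopologyReport",
      nodeTable = data.frame(
        node = nm, degree.in = as.integer(degIn),
        degree.out = as.integer(degOut), degree = as.integer(degTot),
        betweenness = as.numeric(btw), stress = stress,
        eccentricity = as.numeric(ecc), avg.path.length = as.numeric(apl),
        neighborhood.connectivity = nbc,
        row.names = NULL, stringsAsFactors = FALSE),
      graphStats = list(n.nodes = n,
                        n.edges = igraph::ecount(simple),
                        mean.neighbors = mean(degSimple),
                        mean.degree.directed = mean(degTot),
                        diameter = as.numeric(diam)))
}

#' Degree-outlier network hubs (Tukey rule)
#'
#' Hubs are nodes whose total degree exceeds `Q3 + k * IQR` of the total
#' degree distribution (strict inequality, so uniform-degree graphs have
#' no hubs). The rule is scale-invariant in the degrees.
#'
#' @param report [TopologyReport-class] (>= 4 nodes).
#' @param k Tukey multiplier (default 1.5).
#' @return character vector of hub node ids.
#' @export
detectHubs <- function(report, k = 1.5) {
  tab <- report@nodeTable
  if (nrow(tab) < 4) stop("need >= 4 nodes for the outlier rule")
  q <- stats::quantile(tab$degree, c(0.25, 0.75), type = 7)
  cut <- q[2] + k * (q[2] - q[1])
  tab$node[tab$degree > cut]
}

#' Multi-resolution persistent communities (HiDeF-style)
#'
#' Louvain modularity partitions at each resolution of a grid, matched
#' across consecutive resolutions by Jaccard similarity: a community is
#' reported when it persists (Jaccard >= `jaccard` with a community of
#' the previous resolution) through at least `persistenceMin` consecutive
#' resolutions and has at least `minSize` members. Containment edges link
#' reported communities across levels (child strictly inside a larger
#' parent). Reported communities may overlap across levels, never within
#' one level.
#'
#' @param N [EnzymeNetwork-class] or igraph with >= 1 edge.
#' @param resolutions resolution grid (default 20 log-spaced values in
#'   [0.1, 10]).
#' @param persistenceMin minimum consecutive-resolution persistence
#'   (default 2).
#' @param minSize minimum community size (default 4).
#' @param jaccard matching threshold (default 0.75).
#' @param seed RNG seed (Louvain refinement), making reruns identical.
#' @return A [CommunityHierarchy-class] object.
#' @export
detectCommunities <- function(N, resolutions = NULL, persistenceMin = 2,
                              minSize = 4, jaccard = 0.75, seed = 1) {
  g <- if (is(N, "EnzymeNetwork")) N@simple else
    igraph::simplify(igraph::as_undirected(N, mode = "collapse"))
  if (igraph::ecount(g) == 0) {
    warning("edgeless network: no communities reported")
    return(new("CommunityHierarchy",
               table = data.frame(label = character(), size = integer(),
                                  res.min = numeric(), res.max = numeric(),
                                  persistence = integer()),
               members = list(), containment = data.frame(
                 parent = character(), child = character())))
  }
  if (is.null(resolutions))
    resolutions <- exp(seq(log(0.1), log(10), length.out = 20))
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))

  partitions <- lapply(resolutions, function(res) {
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = res)
    split(nm, igraph::membership(cl))
  })

  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  tracks <- list()   # each: members (first occurrence), resIdx (vector)
  prevIdx <- integer()  # track index per community of previous level
  for (li in seq_along(partitions)) {
    curIdx <- integer(length(partitions[[li]]))
    for (ci in seq_along(partitions[[li]])) {
      mem <- partitions[[li]][[ci]]
      matched <- 0L
      if (li > 1) for (ti in unique(prevIdx)) {
        if (ti == 0) next
        if (jac(mem, tracks[[ti]]$members) >= jaccard) { matched <- ti; break }
      }
      if (matched) {
        tracks[[matched]]$resIdx <- c(tracks[[matched]]$resIdx, li)
      } else {
        tracks[[length(tracks) + 1]] <- list(members = mem, resIdx = li)
        matched <- length(tracks)
      }
      curIdx[ci] <- matched
    }
    prevIdx <- curIdx
  }

  keep <- vapply(tracks, function(tr)
    length(tr$resIdx) >= persistenceMin &&
      length(tr$members) >= minSize, logical(1))
  tracks <- tracks[keep]
  if (!length(tracks))
    return(new("CommunityHierarchy",
               table = data.frame(label = character(), size = integer(),
                                  res.min = numeric(), res.max = numeric(),
                                  persistence = integer()),
               members = list(), containment = data.frame(
                 parent = character(), child = character())))
  labels <- sprintf("c%03d", seq_along(tracks))
  tab <- data.frame(
    label = labels,
    size = vapply(tracks, function(tr) length(tr$members), 0L),
    res.min = vapply(tracks, function(tr) resolutions[min(tr$resIdx)], 0),
    res.max = vapply(tracks, function(tr) resolutions[max(tr$resIdx)], 0),
    persistence = vapply(tracks, function(tr) length(tr$resIdx), 0L),
    stringsAsFactors = FALSE)
  members <- setNames(lapply(tracks, `[[`, "members"), labels)
  cont <- list()
  for (i in seq_along(tracks)) for (j in seq_along(tracks)) {
    if (i == j) next
    a <- tracks[[i]]$members; b <- tracks[[j]]$members
    if (length(b) < length(a) && all(b %in% a) &&
        min(tracks[[i]]$resIdx) < min(tracks[[j]]$resIdx))
      cont[[length(cont) + 1]] <- data.frame(parent = labels[i],
                                             child = labels[j])
  }
  containment <- if (length(cont)) do.call(rbind, cont) else
    data.frame(parent = character(), child = character())
  new("CommunityHierarchy", table = tab, members = members,
      containment = containment)
}
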