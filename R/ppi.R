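# Ortholog-filtered protein-interaction mapping and cluster-induced
# subnetworks.

#' Map human interaction edges to mouse under the one-to-one ortholog rule
#'
#' An edge `(a, b)` is emitted as `(m(a), m(b))` iff both endpoints map to
#' *exactly one* mouse identifier; edges with a missing or ambiguous
#' endpoint are dropped. Mapped edges are undirected and deduplicated;
#' self-loops (homodimers) are preserved.
#'
#' @param human_edges a two-column data.frame (or matrix) of human
#'   protein ids, one interaction per row.
#' @param orthologs a data.frame with columns `human_id`, `mouse_id`, one
#'   row per ortholog pair (a human id absent from the table maps to
#'   nothing).
#' @return a data.frame with columns `mouse_a`, `mouse_b` (unordered,
#'   deduplicated; `mouse_a <= mouse_b` lexicographically).
#' @export
map_orthologs <- function(human_edges, orthologs) {
  human_edges <- as.data.frame(human_edges, stringsAsFactors = FALSE)
  if (ncol(human_edges) < 2L) stop("malformed edge rows")
  stopifnot(all(c("human_id", "mouse_id") %in% names(orthologs)))
  a <- as.character(human_edges[[1L]])
  b <- as.character(human_edges[[2L]])
  if (any(is.na(a)) || any(is.na(b)) || any(!nzchar(a)) || any(!nzchar(b))) {
    stop("malformed edge rows")
  }
  maps <- split(as.character(orthologs$mouse_id),
                as.character(orthologs$human_id))
  maps <- lapply(maps, unique)
  one <- vapply(maps, length, integer(1)) == 1L
  m <- unlist(maps[one])
  ok <- a %in% names(m) & b %in% names(m)
  if (!any(ok)) {
    return(data.frame(mouse_a = character(), mouse_b = character(),
                      stringsAsFactors = FALSE))
  }
  ma <- unname(m[a[ok]])
  mb <- unname(m[b[ok]])
  lo <- pmin(ma, mb)
  hi <- pmax(ma, mb)
  unique(data.frame(mouse_a = lo, mouse_b = hi, stringsAsFactors = FALSE))
}

#' Cluster-induced interaction subnetwork (distance 0)
#'
#' Keeps exactly the edges whose *both* endpoints are in `gene_list`;
#' nodes are the genes of retained edges (isolated list members are
#' excluded by default, as only interacting modules are of interest), and
#' connected components are computed.
#'
#' @param edges a two-column data.frame of mouse gene ids.
#' @param gene_list gene ids of the selected cluster (may be empty).
#' @param keep_isolated if `TRUE`, list members without a retained edge
#'   are kept as singleton components.
#' @return a list of class `interaction_network`: `edges` (retained
#'   two-column data.frame), `nodes`, and `components` (named integer
#'   membership vector).
#' @export
induced_subgraph <- function(edges, gene_list, keep_isolated = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  keep <- a %in% gene_list & b %in% gene_list
  kept <- data.frame(mouse_a = a[keep], mouse_b = b[keep],
                     stringsAsFactors = FALSE)
  nodes <- unique(c(kept$mouse_a, kept$mouse_b))
  if (keep_isolated) nodes <- unique(c(nodes, gene_list))
  if (length(nodes) == 0L) {
    return(structure(list(edges = kept, nodes = character(),
                          components = setNames(integer(), character())),
                     class = "interaction_network"))
  }
  g <- igraph::graph_from_data_frame(kept, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)$membership
  structure(list(edges = kept, nodes = nodes,
                 components = setNames(as.integer(comp), names(comp))),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges, %d component(s)\n",
              length(x$nodes), nrow(x$edges),
              length(unique(x$components))))
  invisible(x)
}

#' Simulate a human interactome with a controlled ortholog table
#'
#' Samples `n_edges` distinct unordered protein pairs (self-loops allowed,
#' each at most once) among `n_human_proteins` human proteins. Each human
#' protein independently gets a non-one-to-one mapping with probability
#' `frac_ambiguous_orthologs` (split evenly between no mouse ortholog and
#' two mouse orthologs) and a single mouse ortholog otherwise. The truth
#' table marks which edges survive the one-to-one rule.
#'
#' @param n_human_proteins,n_edges positive counts; `n_edges` may not
#'   exceed `n (n + 1) / 2`.
#' @param frac_ambiguous_orthologs fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a list of class `ppi_sim`: `human_edges` (data.frame `human_a`,
#'   `human_b`), `orthologs` (data.frame `human_id`, `mouse_id`),
#'   `edge_truth` (the human edges with `survives` flag and the mapped
#'   `mouse_a`, `mouse_b` where surviving), and `seed`.
#' @export
simulate_ppi <- function(n_human_proteins, n_edges,
                         frac_ambiguous_orthologs = 0, seed = 1L) {
  stopifnot(n_human_proteins >= 1L, n_edges >= 1L,
            frac_ambiguous_orthologs >= 0, frac_ambiguous_orthologs <= 1)
  np <- as.integer(n_human_proteins)
  max_edges <- np * (np + 1) / 2
  if (n_edges > max_edges) stop("n_edges exceeds possible pairs")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  prot <- sprintf("h%05d", seq_len(np))
  # sample unordered pairs (i <= j) without replacement via linear indices
  idx <- sample(max_edges, n_edges)
  # invert the triangular index: pair (i, j), i <= j
  j <- ceiling((sqrt(8 * idx + 1) - 1) / 2)
  i <- idx - j * (j - 1) / 2
  human_edges <- data.frame(human_a = prot[i], human_b = prot[j],
                            stringsAsFactors = FALSE)

  amb <- runif(np) < frac_ambiguous_orthologs
  kind <- ifelse(!amb, "one", ifelse(runif(np) < 0.5, "none", "many"))
  orth <- list()
  for (p in seq_len(np)) {
    orth[[p]] <- switch(
      kind[p],
      one = data.frame(human_id = prot[p],
                       mouse_id = sprintf("m%05d", p),
                       stringsAsFactors = FALSE),
      many = data.frame(human_id = prot[p],
                        mouse_id = sprintf("m%05d%s", p, c("a", "b")),
                        stringsAsFactors = FALSE),
      none = NULL
    )
  }
  orthologs <- do.call(rbind, orth[!vapply(orth, is.null, logical(1))])
  if (is.null(orthologs)) {
    orthologs <- data.frame(human_id = character(), mouse_id = character(),
                            stringsAsFactors = FALSE)
  }

  m_of <- setNames(ifelse(kind == "one", sprintf("m%05d", seq_len(np)),
                          NA_character_), prot)
  surv <- !is.na(m_of[human_edges$human_a]) &
    !is.na(m_of[human_edges$human_b])
  edge_truth <- human_edges
  edge_truth$survives <- unname(surv)
  edge_truth$mouse_a <- ifelse(surv, unname(
    pmin(m_of[human_edges$human_a], m_of[human_edges$human_b])),
    NA_character_)
  edge_truth$mouse_b <- ifelse(surv, unname(
    pmax(m_of[human_edges$human_a], m_of[human_edges$human_b])),
    NA_character_)
  structure(list(human_edges = human_edges, orthologs = orthologs,
                 edge_truth = edge_truth, seed = as.integer(seed)),
            class = "ppi_sim")
}

#' Write a simulated interactome as TSV files
#'
#' @param sim a `ppi_sim` from [simulate_ppi()].
#' @param dir output directory.
#' @param header optional comment line for each file.
#' @return `dir`, invisibly.
#' @export
write_ppi_files <- function(sim, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$human_edges, file.path(dir, "human_edges.tsv"), header)
  write_tsv(sim$orthologs, file.path(dir, "orthologs.tsv"), header)
  write_tsv(sim$edge_truth, file.path(dir, "ppi_truth.tsv"), header)
  invisible(dir)
}
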